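# internal helpers shared across modules

abort_param <- function(msg) abort(msg, class = "birn_error_parameter")
abort_precondition <- function(msg) abort(msg, class = "birn_error_precondition")
abort_degenerate <- function(msg) abort(msg, class = "birn_error_degenerate")
abort_validation <- function(msg, ...) abort(msg, class = "birn_error_validation", ...)

check_number <- function(x, name, lower = -Inf, upper = Inf,
                         strict_lower = FALSE, strict_upper = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    abort_param(sprintf("`%s` must be a single finite number.", name))
  }
  lo_ok <- if (strict_lower) x > lower else x >= lower
  hi_ok <- if (strict_upper) x < upper else x <= upper
  if (!lo_ok || !hi_ok) {
    abort_param(sprintf(
      "`%s` = %g is outside the allowed range %s%g, %g%s.",
      name, x, if (strict_lower) "(" else "[", lower, upper,
      if (strict_upper) ")" else "]"
    ))
  }
  invisible(x)
}

check_columns <- function(df, cols, what) {
  missing <- setdiff(cols, names(df))
  if (length(missing) > 0L) {
    abort_param(sprintf(
      "%s is missing required column(s): %s.", what,
      paste0("`", missing, "`", collapse = ", ")
    ))
  }
  invisible(df)
}

# Deterministic substream seed: every generator phase (geometry, placement,
# noise, ...) draws under its own seed derived from (seed, name), so adding a
# stream never shifts the draws of another.
substream_seed <- function(seed, name) {
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed)) {
    abort_param("`seed` must be a single finite number.")
  }
  s <- as.double(seed %% 2147483629)
  for (ch in utf8ToInt(name)) s <- (s * 31 + ch) %% 2147483629
  as.integer(s) + 1L
}

with_substream <- function(seed, name, code) {
  withr::with_seed(substream_seed(seed, name), code,
                   .rng_kind = "Mersenne-Twister",
                   .rng_normal_kind = "Inversion",
                   .rng_sample_kind = "Rejection")
}

r_squared <- function(observed, fitted) {
  ss_res <- sum((observed - fitted)^2)
  ss_tot <- sum((observed - mean(observed))^2)
  if (ss_tot == 0) return(if (ss_res == 0) 1 else 0)
  1 - ss_res / ss_tot
}
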