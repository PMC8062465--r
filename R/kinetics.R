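#' Assemble a pulse-chase or release time course
#'
#' Validates and tags a time-course table. Internalization courses are
#' recorded in minutes, release courses in hours; the unit tag travels
#' with the data so the two cannot be mixed silently.
#'
#' @param data Data frame with columns `time`, `value` (fractions in
#'   `[0, 1]`) and optionally `replicate`.
#' @param kind `"internalization"` or `"release"`.
#' @param unit Time unit; defaults to `"min"` for internalization and
#'   `"h"` for release.
#' @return A tibble of class `birn_timecourse` with attributes `kind` and
#'   `unit`.
#' @export
time_course <- function(data, kind = c("internalization", "release"),
                        unit = NULL) {
  kind <- match.arg(kind)
  if (is.null(unit)) unit <- if (kind == "internalization") "min" else "h"
  check_columns(data, c("time", "value"), "time course")
  d <- as_tibble(data)
  if (!"replicate" %in% names(d)) d$replicate <- 1L
  if (any(d$time < 0)) abort_param("times must be non-negative.")
  if (any(d$value < 0 | d$value > 1)) abort_param("values must be fractions in [0, 1].")
  ord <- d |> group_by(.data$replicate) |>
    summarise(ok = !is.unsorted(.data$time), .groups = "drop")
  if (!all(ord$ok)) abort_param("times must be non-decreasing within each replicate.")
  structure(d, kind = kind, unit = unit,
            class = c("birn_timecourse", class(d)))
}

#' Fit mono-exponential internalization kinetics
#'
#' Fits `value(t) = plateau * (1 - exp(-k * t))` by nonlinear least
#' squares over all replicate points and reports the rate `k`, the
#' half-time `t_half = ln(2) / k`, the plateau and a coefficient of
#' determination. An empirical half-time (linear interpolation of the
#' 50%-of-plateau crossing of the per-time means) is reported alongside
#' the model-based one.
#'
#' The plateau and rate are jointly identifiable only when the sampled
#' span covers at least two half-times; below that a warning is issued
#' (class `birn_warning_identifiability`). Data with no visible curvature
#' trigger a degeneracy warning and the fit is still returned for
#' inspection.
#'
#' @param tc A [time_course()] of kind `"internalization"` (a plain data
#'   frame with `time`/`value` columns is accepted and tagged).
#' @return An object of class `birn_kinetics_fit` with elements `k`,
#'   `t_half`, `t_half_empirical`, `plateau`, `goodness`, `unit`, `n`.
#' @examples
#' tc <- gen_pulse_chase(t_half = 10, noise = 0, seed = 1)
#' fit_internalization(tc)
#' @export
fit_internalization <- function(tc) {
  if (!inherits(tc, "birn_timecourse")) tc <- time_course(tc, "internalization")
  if (attr(tc, "kind") != "internalization") {
    abort_param("expected a time course of kind `internalization`.")
  }
  d <- as_tibble(tc)
  times <- sort(unique(d$time))
  if (length(times) < 5L) abort_precondition("need at least 5 distinct time points.")

  means <- d |> group_by(.data$time) |>
    summarise(value = mean(.data$value), .groups = "drop") |> arrange(.data$time)
  plateau0 <- max(means$value)
  if (plateau0 <= 0) abort_degenerate("all values are zero.")
  t50 <- empirical_half_time(means$time, means$value, plateau0)
  k0 <- log(2) / max(t50, diff(range(times)) / 10)

  # curvature check: a straight line explaining the means as well as any
  # saturating curve means k is unidentifiable
  lin <- lm(value ~ time, data = means)
  if (suppressWarnings(summary(lin)$r.squared) > 0.999) {
    warn("time course shows no curvature; rate and plateau are not identifiable.",
         class = "birn_warning_degenerate")
  }
  fit <- minpack.lm::nlsLM(
    value ~ plateau * (1 - exp(-k * time)), data = d,
    start = list(plateau = min(plateau0, 1), k = k0),
    lower = c(plateau = 1e-8, k = 1e-8),
    upper = c(plateau = 1, k = Inf),
    control = minpack.lm::nls.lm.control(ptol = 1e-10, ftol = 1e-12,
                                         maxiter = 500, maxfev = 10000))
  est <- coef(fit)
  if (max(times) < 2 * log(2) / unname(est["k"])) {
    warn("sampled span is below two half-times; plateau and rate are weakly identifiable.",
         class = "birn_warning_identifiability")
  }
  structure(
    list(k = unname(est["k"]), t_half = log(2) / unname(est["k"]),
         t_half_empirical = t50,
         plateau = unname(est["plateau"]),
         goodness = r_squared(d$value, predict(fit)),
         unit = attr(tc, "unit"), kind = "internalization",
         n = nrow(d), data = d),
    class = "birn_kinetics_fit")
}

empirical_half_time <- function(time, value, plateau) {
  half <- plateau / 2
  cross <- which(diff(sign(value - half)) > 0)
  if (length(cross) == 0L) return(NA_real_)
  i <- cross[1]
  approx(value[c(i, i + 1)], time[c(i, i + 1)], xout = half)$y
}

#' @export
print.birn_kinetics_fit <- function(x, ...) {
  cat(sprintf(
    "<birn_kinetics_fit> %s: t_half = %.3f %s (k = %.4g /%s), plateau = %.3f, R^2 = %.4f\n",
    x$kind, x$t_half, x$unit, x$k, x$unit, x$plateau, x$goodness))
  invisible(x)
}

#' First-order release fraction
#'
#' Cumulative released fraction of a first-order process with half-time
#' `t_half`: `1 - 2^(-t / t_half)`. The survival fraction halves exactly
#' every `t_half`.
#'
#' @param t_half Release half-time, positive (same unit as `t`).
#' @param t Time(s), non-negative.
#' @return Released fraction(s) in `[0, 1)`.
#' @examples
#' release_fraction(4.52, 24)  # > 0.90
#' @export
release_fraction <- function(t_half, t) {
  check_number(t_half, "t_half", lower = 0, strict_lower = TRUE)
  if (any(t < 0)) abort_param("`t` must be non-negative.")
  1 - 2^(-t / t_half)
}

#' Fit a four-parameter logistic dose-response curve
#'
#' Fits viability against log10 concentration with the 4PL model
#' `viability = bottom + (top - bottom) / (1 + 10^(hill * (log10(conc) - log10(ic50))))`,
#' so that the fitted viability at the IC50 is exactly the midpoint of top
#' and bottom. `top` is bounded at 1.05 and `bottom` at -0.05.
#'
#' @param dr Data frame with columns `conc` (positive, molar or µM) and
#'   `viability` (fractions), optionally `replicate`.
#' @return An object of class `birn_dose_fit` with elements `ic50`,
#'   `hill`, `top`, `bottom`, `goodness`, `n`.
#' @examples
#' dr <- data.frame(conc = 10^seq(-3, 1.5, length.out = 8))
#' dr$viability <- 1 / (1 + (dr$conc / 1.25))
#' fit_dose_response(dr)
#' @export
fit_dose_response <- function(dr) {
  check_columns(dr, c("conc", "viability"), "dose-response data")
  d <- as_tibble(dr)
  if (any(d$conc <= 0)) abort_param("concentrations must be positive.")
  if (length(unique(d$conc)) < 5L) {
    abort_precondition("need at least 5 distinct concentrations.")
  }
  rng <- range(d$viability)
  span <- rng[2] - rng[1]
  # the observed drop must cover a substantial part of the response,
  # otherwise the data sit on one plateau and the IC50 is extrapolation
  if (span < 0.3) {
    abort_precondition("dose-response data do not span the transition.")
  }
  d$lc <- log10(d$conc)
  means <- d |> group_by(.data$lc) |>
    summarise(v = mean(.data$viability), .groups = "drop") |> arrange(.data$lc)
  half <- rng[1] + span / 2
  lc50_0 <- {
    cross <- which(diff(sign(means$v - half)) != 0)
    if (length(cross) == 0L) stats::median(means$lc) else {
      i <- cross[1]
      approx(means$v[c(i, i + 1)], means$lc[c(i, i + 1)], xout = half)$y
    }
  }
  # Levenberg-Marquardt first; on rank-check failures (which happen when
  # the optimizer lands on an exactly-interpolating solution) retry with
  # shifted starts and finally with the bounded port algorithm
  lower <- c(top = -0.05, bottom = -0.05, hill = 1e-3, lic50 = min(d$lc) - 3)
  upper <- c(top = 1.05, bottom = 1.05, hill = 20, lic50 = max(d$lc) + 3)
  starts <- unique(c(lc50_0, stats::median(d$lc), lc50_0 + 0.3, lc50_0 - 0.3))
  fit <- NULL
  for (l0 in starts) {
    st <- list(top = rng[2], bottom = rng[1], hill = 1, lic50 = l0)
    fit <- tryCatch(
      minpack.lm::nlsLM(
        viability ~ bottom + (top - bottom) / (1 + 10^(hill * (lc - lic50))),
        data = d, start = st, lower = lower, upper = upper,
        control = minpack.lm::nls.lm.control(ptol = 1e-10, ftol = 1e-12,
                                             maxiter = 500, maxfev = 10000)),
      error = function(e) NULL)
    if (!is.null(fit)) break
  }
  if (is.null(fit)) {
    for (l0 in starts) {
      st <- list(top = rng[2], bottom = rng[1], hill = 1, lic50 = l0)
      fit <- tryCatch(
        stats::nls(
          viability ~ bottom + (top - bottom) / (1 + 10^(hill * (lc - lic50))),
          data = d, start = st, algorithm = "port",
          lower = unname(lower), upper = unname(upper),
          control = stats::nls.control(maxiter = 500, tol = 1e-9)),
        error = function(e) NULL)
      if (!is.null(fit)) break
    }
  }
  if (is.null(fit)) abort_degenerate("dose-response fit failed to converge.")
  est <- coef(fit)
  structure(
    list(ic50 = 10^unname(est["lic50"]), hill = unname(est["hill"]),
         top = unname(est["top"]), bottom = unname(est["bottom"]),
         goodness = r_squared(d$viability, predict(fit)),
         n = nrow(d), data = d),
    class = "birn_dose_fit")
}

#' @export
print.birn_dose_fit <- function(x, ...) {
  cat(sprintf(
    "<birn_dose_fit> IC50 = %.4g, hill = %.3f, top = %.3f, bottom = %.3f, R^2 = %.4f\n",
    x$ic50, x$hill, x$top, x$bottom, x$goodness))
  invisible(x)
}

#' Percent decrease in potency between two IC50 values
#'
#' `100 * (1 - ic50_ref / ic50_test)`: the potency loss when the IC50
#' rises from the reference condition to the test condition (for example
#' after blocking endocytosis).
#'
#' @param ic50_ref Reference IC50, positive.
#' @param ic50_test Test IC50, positive and at least `ic50_ref`.
#' @return Percent decrease in `[0, 100)`.
#' @examples
#' potency_decrease(1.25, 12.87)  # ~90.3
#' @export
potency_decrease <- function(ic50_ref, ic50_test) {
  check_number(ic50_ref, "ic50_ref", lower = 0, strict_lower = TRUE)
  check_number(ic50_test, "ic50_test", lower = 0, strict_lower = TRUE)
  if (ic50_test < ic50_ref) {
    abort(
      "ic50_test is below ic50_ref: potency increased, not decreased.",
      class = "birn_error_sign")
  }
  100 * (1 - ic50_ref / ic50_test)
}
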