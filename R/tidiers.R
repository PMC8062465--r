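# broom-style tidiers for the fitted-object classes

#' Tidy a titration fit
#'
#' @param x A `birn_titration_fit`.
#' @param ... Unused.
#' @return One row per parameter: `term`, `estimate`.
#' @export
tidy.birn_titration_fit <- function(x, ...) {
  tibble(
    term = c("ph_t", "width_10_90", "f_max", "f_min", "r_f"),
    estimate = c(x$ph_t_hat, x$width_10_90_hat, x$f_max_hat, x$f_min_hat,
                 x$r_f_hat))
}

#' @rdname tidy.birn_titration_fit
#' @export
glance.birn_titration_fit <- function(x, ...) {
  tibble(channel = x$channel, role = x$role, r.squared = x$goodness,
         flat = x$flat, always_on_ok = x$always_on_ok, nobs = x$n)
}

#' Tidy a calibration curve
#'
#' @param x A `birn_calibration`.
#' @param ... Unused.
#' @return One row per coefficient.
#' @export
tidy.birn_calibration <- function(x, ...) {
  tibble(term = c("intercept", "slope"),
         estimate = c(x$intercept, x$slope))
}

#' @rdname tidy.birn_calibration
#' @export
glance.birn_calibration <- function(x, ...) {
  tibble(tissue = x$tissue, r = x$r, n_points = x$n_points,
         n_levels = length(x$f_grid))
}

#' Tidy a kinetics fit
#'
#' @param x A `birn_kinetics_fit`.
#' @param ... Unused.
#' @return One row per parameter.
#' @export
tidy.birn_kinetics_fit <- function(x, ...) {
  tibble(
    term = c("k", "t_half", "t_half_empirical", "plateau"),
    estimate = c(x$k, x$t_half, x$t_half_empirical, x$plateau))
}

#' @rdname tidy.birn_kinetics_fit
#' @export
glance.birn_kinetics_fit <- function(x, ...) {
  tibble(kind = x$kind, unit = x$unit, r.squared = x$goodness, nobs = x$n)
}

#' Tidy a dose-response fit
#'
#' @param x A `birn_dose_fit`.
#' @param ... Unused.
#' @return One row per parameter.
#' @export
tidy.birn_dose_fit <- function(x, ...) {
  tibble(term = c("ic50", "hill", "top", "bottom"),
         estimate = c(x$ic50, x$hill, x$top, x$bottom))
}

#' @rdname tidy.birn_dose_fit
#' @export
glance.birn_dose_fit <- function(x, ...) {
  tibble(r.squared = x$goodness, nobs = x$n)
}

#' Tidy a correlation result
#'
#' @param x A `birn_correlation`.
#' @param ... Unused.
#' @return A one-row tibble with `r`, `p`, `slope`, `intercept`, `n`.
#' @export
tidy.birn_correlation <- function(x, ...) {
  tibble(r = x$r, p.value = x$p, slope = x$slope,
         intercept = x$intercept, n = x$n)
}

#' @rdname tidy.birn_correlation
#' @export
glance.birn_correlation <- function(x, ...) tidy.birn_correlation(x)
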