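#' Mixture O/A ratio of partially internalized probe
#'
#' Models the calibration standards used to map the O/A ratio onto a
#' turn-ON (endocytosis) percentage: a fraction `f_on` of the probe sits at
#' the unimer reference pH (endocytic, fully ON) and the remainder at the
#' micelle reference pH (extracellular, OFF). The well-level ratio is
#'
#' \deqn{Ratio = \frac{F_{O}(7.4) + F_{O}(5.4)}{F_{A}(7.4) + F_{A}(5.4)}}
#'
#' with each channel intensity the molar-fraction-weighted mixture
#' `(1 - f_on) * F(ph_micelle_ref) + f_on * F(ph_unimer_ref)`. When the
#' always-ON module is pH-flat the ratio is exactly linear in `f_on`, and
#' it is independent of concentration because both channels scale with it.
#'
#' @param probe A [birn_probe()].
#' @param f_on Turn-ON fraction(s) in `[0, 1]`.
#' @param concentration Total probe concentration, positive.
#' @return O/A ratio, same length as `f_on`.
#' @examples
#' mixture_ratio(birn_probe(), c(0, 0.5, 1))
#' @export
mixture_ratio <- function(probe, f_on, concentration = 1) {
  stopifnot(inherits(probe, "birn_probe"))
  if (!is.numeric(f_on) || any(!is.finite(f_on)) ||
      any(f_on < 0 | f_on > 1)) {
    abort_param("`f_on` must be in [0, 1].")
  }
  check_number(concentration, "concentration", lower = 0, strict_lower = TRUE)
  ch <- function(module, frac) {
    (1 - f_on) * module_fluorescence(module, probe$ph_micelle_ref,
                                     concentration * frac) +
      f_on * module_fluorescence(module, probe$ph_unimer_ref,
                                 concentration * frac)
  }
  num <- ch(probe$off_on, probe$molar_fraction_off_on)
  den <- ch(probe$always_on, 1 - probe$molar_fraction_off_on)
  if (any(den <= 0)) {
    abort_degenerate("always-ON channel signal is zero; ratio undefined.")
  }
  num / den
}

#' Build a per-tissue calibration curve from standards
#'
#' Ordinary least-squares line of the O/A ratio against the turn-ON
#' fraction, fitted on per-replicate well ratios (no pre-averaging).
#' A curve is usable only when the correlation coefficient reaches the
#' acceptance gate `r >= 0.95`; below the gate a validation error carrying
#' the fitted values is raised. Per-level mean ratios are reported in the
#' `levels` element for diagnostics.
#'
#' @param standards Data frame with columns `f_on` (fraction in `[0, 1]`),
#'   `ch_off_on`, `ch_always_on`, and optionally `replicate`,
#'   `concentration`, `tissue`.
#' @param tissue Tissue label the curve belongs to. Defaults to the single
#'   tissue present in `standards`.
#' @return An object of class `birn_calibration` with elements `slope`,
#'   `intercept`, `r`, `tissue`, `n_points`, `f_grid` and `levels`.
#' @examples
#' probe <- birn_probe()
#' plate <- gen_calibration_plate(probe, noise = 0, seed = 1)
#' build_calibration(plate)
#' @export
build_calibration <- function(standards, tissue = NULL) {
  check_columns(standards, c("f_on", "ch_off_on", "ch_always_on"),
                "calibration standards")
  d <- as_tibble(standards)
  if (is.null(tissue)) {
    tissue <- if ("tissue" %in% names(d)) unique(d$tissue) else "unspecified"
    if (length(tissue) != 1L) {
      abort_param("standards contain several tissues; pass `tissue` explicitly.")
    }
  } else if ("tissue" %in% names(d)) {
    d <- dplyr::filter(d, .data$tissue == !!tissue)
    if (nrow(d) == 0L) abort_param(sprintf("no standards for tissue `%s`.", tissue))
  }
  if (any(d$f_on < 0 | d$f_on > 1)) abort_param("`f_on` must be in [0, 1].")
  if (any(d$ch_off_on < 0 | d$ch_always_on < 0)) {
    abort_param("channel intensities must be non-negative.")
  }
  f_levels <- sort(unique(d$f_on))
  if (length(f_levels) < 4L || !any(f_levels == 0)) {
    abort_precondition(
      "need at least 4 distinct turn-ON levels including f_on = 0.")
  }
  if (any(d$ch_always_on == 0)) {
    abort_degenerate("always-ON intensity of zero in standards; ratio undefined.")
  }
  d$ratio <- d$ch_off_on / d$ch_always_on
  fit <- lm(ratio ~ f_on, data = d)
  slope <- unname(coef(fit)[2])
  intercept <- unname(coef(fit)[1])
  r <- cor(d$f_on, d$ratio)
  levels_tbl <- d |>
    group_by(.data$f_on) |>
    summarise(mean_ratio = mean(.data$ratio), n = dplyr::n(), .groups = "drop")
  curve <- structure(
    list(slope = slope, intercept = intercept, r = r, tissue = tissue,
         n_points = nrow(d), f_grid = f_levels, levels = levels_tbl),
    class = "birn_calibration")
  if (!is.finite(r) || r < 0.95) {
    abort_validation(
      sprintf("calibration r = %.4f is below the 0.95 acceptance gate.", r),
      curve = curve)
  }
  if (slope <= 0) {
    abort_validation("calibration slope is not positive.", curve = curve)
  }
  curve
}

#' @export
print.birn_calibration <- function(x, ...) {
  cat(sprintf(
    "<birn_calibration> tissue %s: ratio = %.4f + %.4f * f_on, r = %.4f (n = %d)\n",
    x$tissue, x$intercept, x$slope, x$r, x$n_points))
  invisible(x)
}

#' Invert a calibration curve to an endocytosis fraction
#'
#' Maps an observed O/A ratio back to the turn-ON (endocytosis) fraction
#' through `f = (ratio - intercept) / slope`, clipped to `[0, 1]`. Clipping
#' is reported in the `out_of_range` column rather than silently hidden.
#'
#' @param curve A valid [build_calibration()] result.
#' @param observed_ratio Observed O/A ratio(s).
#' @param tissue Optional tissue label of the sample; a mismatch with the
#'   curve's tissue is an error unless `force = TRUE`.
#' @param force Allow a tissue mismatch.
#' @return A tibble with columns `ratio`, `f_hat` and `out_of_range`.
#' @examples
#' probe <- birn_probe()
#' curve <- build_calibration(gen_calibration_plate(probe, noise = 0, seed = 1))
#' invert_calibration(curve, mixture_ratio(probe, 0.175))
#' @export
invert_calibration <- function(curve, observed_ratio, tissue = NULL,
                               force = FALSE) {
  stopifnot(inherits(curve, "birn_calibration"))
  if (!is.finite(curve$r) || curve$r < 0.95) {
    abort_validation("calibration curve is below the r >= 0.95 gate.")
  }
  if (curve$slope <= 0) abort_validation("calibration slope must be positive.")
  if (!is.null(tissue) && !identical(tissue, curve$tissue) && !force) {
    abort_validation(sprintf(
      "sample tissue `%s` does not match curve tissue `%s` (use force = TRUE to override).",
      tissue, curve$tissue))
  }
  raw <- (observed_ratio - curve$intercept) / curve$slope
  tibble(
    ratio = observed_ratio,
    f_hat = pmin(pmax(raw, 0), 1),
    out_of_range = raw < 0 | raw > 1
  )
}
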