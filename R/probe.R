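#' Define one fluorescence module of a binary ratiometric nanoreporter
#'
#' A BiRN probe carries two fluorescence modules on the same pH-sensitive
#' micelle. The OFF-ON module is quenched in the assembled micelle (above the
#' transition pH) and fully fluorescent once the micelle dissociates into
#' unimers below the transition; the always-ON module fluoresces equally in
#' both states and serves as the internal standard of the ratiometric
#' readout. Each module is described phenomenologically by its fully-ON and
#' fully-OFF brightness per unit concentration (`f_max`, `f_min`), its
#' transition pH (`ph_t`) and the pH span over which the response rises from
#' 10% to 90% of the transition (`width_10_90`).
#'
#' @param label Channel label, e.g. `"off_on"` or a fluorophore name.
#' @param role Either `"off_on"` or `"always_on"`.
#' @param f_max Fluorescence per unit concentration in the fully-ON (unimer)
#'   state; arbitrary units, must be positive.
#' @param f_min Fluorescence per unit concentration in the fully-OFF
#'   (micelle) state; arbitrary units, must be positive.
#' @param ph_t Transition pH, in (4, 8).
#' @param width_10_90 pH span between 10% and 90% of the ON transition;
#'   must be positive.
#'
#' @return An object of class `birn_module`.
#'
#' @details The activation ratio `R_F = f_max / f_min` must be at least
#'   100 for a valid OFF-ON module and within `[0.9, 1.1]` for a valid
#'   always-ON module; those gates are enforced by [birn_probe()], not here,
#'   so that intermediate fitted values can be represented.
#'
#' @examples
#' probe_module("Cy5", "off_on", f_max = 111, f_min = 1,
#'              ph_t = 6.28, width_10_90 = 0.21)
#' @export
probe_module <- function(label, role = c("off_on", "always_on"),
                         f_max, f_min, ph_t, width_10_90) {
  role <- match.arg(role)
  check_number(f_max, "f_max", lower = 0, strict_lower = TRUE)
  check_number(f_min, "f_min", lower = 0, strict_lower = TRUE)
  check_number(ph_t, "ph_t", lower = 4, upper = 8,
               strict_lower = TRUE, strict_upper = TRUE)
  check_number(width_10_90, "width_10_90", lower = 0, strict_lower = TRUE)
  if (role == "off_on" && f_max < f_min) {
    abort_param("an OFF-ON module requires `f_max >= f_min`.")
  }
  structure(
    list(label = label, role = role, f_max = f_max, f_min = f_min,
         ph_t = ph_t, width_10_90 = width_10_90),
    class = "birn_module"
  )
}

#' @export
print.birn_module <- function(x, ...) {
  cat(sprintf(
    "<birn_module> %s (%s): pH_t %.3f, width(10-90%%) %.3f, R_F %.3g\n",
    x$label, x$role, x$ph_t, x$width_10_90, x$f_max / x$f_min
  ))
  invisible(x)
}

#' Assemble a two-module BiRN probe
#'
#' Combines an OFF-ON and an always-ON module into one probe and enforces
#' the design gates of a working binary reporter: activation ratio of the
#' OFF-ON module at least 100-fold, always-ON flatness within
#' `[0.9, 1.1]`, transition width below 0.25 pH units, and the transition
#' pH bracketed by the micelle (pH 7.4) and unimer (pH 5.4) reference
#' buffers used to anchor the normalized readout.
#'
#' Called with no arguments it returns the reference probe with the
#' characterized near-infra-red parameter set: transition pH 6.28,
#' 10-90% width 0.21 pH units, 111-fold activation, and an exactly flat
#' always-ON module.
#'
#' @param off_on A `birn_module` with role `"off_on"`.
#' @param always_on A `birn_module` with role `"always_on"`.
#' @param molar_fraction_off_on Molar fraction of the OFF-ON modular polymer
#'   in the nanoparticle, in (0, 1]. The characterized probe uses a 9:1
#'   OFF-ON to always-ON molar ratio.
#' @param ph_micelle_ref Reference pH of the assembled-micelle state
#'   (default 7.4); the normalized O/A response is 0 here by construction.
#' @param ph_unimer_ref Reference pH of the dissociated-unimer state
#'   (default 5.4); the normalized O/A response is 1 here by construction.
#'
#' @return An object of class `birn_probe`.
#' @examples
#' p <- birn_probe()
#' oa_response(p, c(7.4, 6.6, 6.28, 6.0, 5.4))
#' @export
birn_probe <- function(off_on = probe_module("off_on", "off_on",
                                             f_max = 111, f_min = 1,
                                             ph_t = 6.28, width_10_90 = 0.21),
                       always_on = probe_module("always_on", "always_on",
                                                f_max = 1, f_min = 1,
                                                ph_t = 6.28, width_10_90 = 0.21),
                       molar_fraction_off_on = 0.9,
                       ph_micelle_ref = 7.4,
                       ph_unimer_ref = 5.4) {
  stopifnot(inherits(off_on, "birn_module"), inherits(always_on, "birn_module"))
  if (off_on$role != "off_on" || always_on$role != "always_on") {
    abort_param("module roles do not match their slots.")
  }
  check_number(molar_fraction_off_on, "molar_fraction_off_on",
               lower = 0, upper = 1, strict_lower = TRUE)
  rf_oo <- off_on$f_max / off_on$f_min
  if (rf_oo < 100) {
    abort_validation(sprintf(
      "OFF-ON activation ratio %.3g is below the 100-fold gate.", rf_oo))
  }
  rf_ao <- always_on$f_max / always_on$f_min
  if (rf_ao < 0.9 || rf_ao > 1.1) {
    abort_validation(sprintf(
      "always-ON flatness %.3g is outside [0.9, 1.1].", rf_ao))
  }
  if (off_on$width_10_90 >= 0.25) {
    abort_validation("OFF-ON transition width must be below 0.25 pH units.")
  }
  if (!(ph_unimer_ref < off_on$ph_t && off_on$ph_t < ph_micelle_ref)) {
    abort_param("transition pH must lie between the unimer and micelle reference pH.")
  }
  structure(
    list(off_on = off_on, always_on = always_on,
         molar_fraction_off_on = molar_fraction_off_on,
         ph_micelle_ref = ph_micelle_ref, ph_unimer_ref = ph_unimer_ref),
    class = "birn_probe"
  )
}

#' @export
print.birn_probe <- function(x, ...) {
  cat("<birn_probe>\n")
  print(x$off_on)
  print(x$always_on)
  cat(sprintf("  molar fraction OFF-ON: %.2f; reference pH %.1f (micelle) / %.1f (unimer)\n",
              x$molar_fraction_off_on, x$ph_micelle_ref, x$ph_unimer_ref))
  invisible(x)
}

#' Convert a 10-90% transition width into the logistic steepness exponent
#'
#' The two-state protonation response is modelled as a base-10 logistic in
#' pH. Its steepness exponent `n_H` and the 10-90% width `w` are linked by
#' `n_H * w = log10(81)`, because the logistic runs from 10% to 90% over
#' `log10(81) / n_H` pH units.
#'
#' @param width_10_90 pH span between 10% and 90% response; positive.
#' @return The dimensionless steepness exponent.
#' @seealso [hill_to_width()] for the inverse.
#' @examples
#' width_to_hill(0.21)      # ~9.09
#' width_to_hill(log10(81)) # exactly 1
#' @export
width_to_hill <- function(width_10_90) {
  if (!is.numeric(width_10_90) || any(!is.finite(width_10_90)) ||
      any(width_10_90 <= 0)) {
    abort_param("`width_10_90` must be positive and finite.")
  }
  log10(81) / width_10_90
}

#' @rdname width_to_hill
#' @param n_h Steepness exponent; positive.
#' @export
hill_to_width <- function(n_h) {
  if (!is.numeric(n_h) || any(!is.finite(n_h)) || any(n_h <= 0)) {
    abort_param("`n_h` must be positive and finite.")
  }
  log10(81) / n_h
}

# Two-state ON fraction theta(pH): 1 below the transition, 0 above,
# crossing 0.5 at ph_t with 10-90% span width_10_90.
theta_on <- function(ph, ph_t, width_10_90) {
  1 / (1 + 10^(width_to_hill(width_10_90) * (ph - ph_t)))
}

#' Fluorescence of one probe module at a given pH and concentration
#'
#' Evaluates the phenomenological two-state model
#' `F(pH) = c * (f_min + (f_max - f_min) * theta(pH))` with
#' `theta(pH) = 1 / (1 + 10^(n_H * (pH - pH_t)))` and
#' `n_H = log10(81) / width_10_90`. The response is non-increasing in pH
#' (fully ON below the transition) and exactly linear in concentration.
#'
#' @param module A [probe_module()].
#' @param ph pH value(s) at which to evaluate.
#' @param concentration Probe concentration (arbitrary mass/volume units),
#'   non-negative. Default 1 gives per-unit-concentration brightness.
#' @return Fluorescence intensity, same length as `ph`.
#' @examples
#' m <- probe_module("Cy5", "off_on", 111, 1, 6.28, 0.21)
#' module_fluorescence(m, c(7.4, 6.28, 5.4))
#' @export
module_fluorescence <- function(module, ph, concentration = 1) {
  stopifnot(inherits(module, "birn_module"))
  if (!is.numeric(ph) || any(!is.finite(ph))) {
    abort_param("`ph` must be finite numeric.")
  }
  if (!is.numeric(concentration) || any(!is.finite(concentration)) ||
      any(concentration < 0)) {
    abort_param("`concentration` must be finite and non-negative.")
  }
  th <- theta_on(ph, module$ph_t, module$width_10_90)
  concentration * (module$f_min + (module$f_max - module$f_min) * th)
}

#' Normalized O/A response of a BiRN probe
#'
#' The raw ratiometric signal is the OFF-ON over always-ON intensity at
#' equal probe concentration (module brightnesses weighted by their molar
#' fractions). It is normalized against the two reference buffers so that
#' the response is exactly 0 at the micelle reference pH (7.4) and exactly
#' 1 at the unimer reference pH (5.4):
#' `OA(pH) = (ratio(pH) - ratio(7.4)) / (ratio(5.4) - ratio(7.4))`.
#' For a sharp probe the result is near-binary: close to 0 throughout the
#' tumour extracellular range (pH > 6.4) and close to 1 at early-endosomal
#' pH (< 6.2).
#'
#' @param probe A [birn_probe()].
#' @param ph pH value(s).
#' @return Normalized O/A response, same length as `ph`.
#' @examples
#' oa_response(birn_probe(), c(6.6, 6.0))
#' @export
oa_response <- function(probe, ph) {
  stopifnot(inherits(probe, "birn_probe"))
  raw <- function(p) {
    module_fluorescence(probe$off_on, p, probe$molar_fraction_off_on) /
      module_fluorescence(probe$always_on, p, 1 - probe$molar_fraction_off_on)
  }
  r0 <- raw(probe$ph_micelle_ref)
  r1 <- raw(probe$ph_unimer_ref)
  if (abs(r1 - r0) < .Machine$double.eps * max(1, abs(r0))) {
    abort_degenerate("probe has zero dynamic range between the reference pH values.")
  }
  (raw(ph) - r0) / (r1 - r0)
}

#' Fit the two-state pH-response model to titration data
#'
#' Fits the four-parameter model of [module_fluorescence()] to a titration
#' table by nonlinear least squares, jointly over all replicate points
#' (no pre-averaging, unweighted). Per-record concentrations multiply the
#' model so titrations acquired at any (or mixed) concentrations can be
#' fitted. Returns the characterization triple of a BiRN module: fitted
#' transition pH, 10-90% width and activation ratio, with asymptotes and a
#' coefficient of determination.
#'
#' Starting values: transition pH from linear interpolation of the
#' half-range crossing, width 0.2 pH units, asymptotes from the observed
#' extremes; parameter tolerance 1e-10, at most 10^4 function evaluations.
#'
#' An always-ON channel is typically flat; when the dynamic range of the
#' data is below 5% (`max/min < 1.05`) the sigmoid is unidentifiable. For
#' `channel` fitted as always-ON this returns a flatness summary
#' (`flat = TRUE`, `r_f_hat` from the observed extremes, `ph_t_hat = NA`);
#' for an OFF-ON channel flat data raises a degeneracy error.
#'
#' @param data A data frame with columns `ph`, `channel`, `intensity` and
#'   optionally `replicate` and `concentration` (assumed 1 when absent).
#' @param channel Which channel label to fit.
#' @param role Role the channel is expected to play: `"off_on"` (default)
#'   or `"always_on"`; controls the handling of flat data and the flatness
#'   flag `[0.9, 1.1]` reported for always-ON channels.
#' @return An object of class `birn_titration_fit` with elements
#'   `ph_t_hat`, `width_10_90_hat`, `f_max_hat`, `f_min_hat`, `r_f_hat`,
#'   `goodness`, `flat`, `n` and the fitted data. [tidy()] and [glance()]
#'   methods are provided.
#' @examples
#' probe <- birn_probe()
#' tit <- gen_titration(probe, ph = seq(5, 7.4, 0.1), noise = 0, seed = 1)
#' fit_titration(tit, channel = "off_on")
#' @export
fit_titration <- function(data, channel, role = c("off_on", "always_on")) {
  role <- match.arg(role)
  check_columns(data, c("ph", "channel", "intensity"), "titration data")
  d <- dplyr::filter(data, .data$channel == !!channel)
  if (nrow(d) == 0L) {
    abort_param(sprintf("no rows with channel `%s`.", channel))
  }
  if (!"concentration" %in% names(d)) d$concentration <- 1
  if (any(d$intensity < 0)) abort_param("intensities must be non-negative.")
  if (length(unique(d$ph)) < 6L) {
    abort_precondition("need at least 6 distinct pH values.")
  }

  # per-unit-concentration intensities drive the range/spanning checks;
  # flatness is judged on per-pH replicate means so replicate noise alone
  # cannot fake a transition
  y_unit <- d$intensity / d$concentration
  rng <- range(y_unit)
  mean_rng <- range(tapply(y_unit, d$ph, mean))
  flat <- mean_rng[2] / max(mean_rng[1], .Machine$double.eps) < 1.05
  if (flat) {
    if (role == "off_on") {
      abort_degenerate(
        "flat titration (max/min < 1.05): OFF-ON channel shows no transition.")
    }
    res <- structure(
      list(channel = channel, role = role,
           ph_t_hat = NA_real_, width_10_90_hat = NA_real_,
           f_max_hat = mean_rng[2], f_min_hat = mean_rng[1],
           r_f_hat = mean_rng[2] / mean_rng[1],
           goodness = r_squared(y_unit, rep(mean(y_unit), length(y_unit))),
           flat = TRUE,
           always_on_ok = mean_rng[2] / mean_rng[1] >= 0.9 &&
             mean_rng[2] / mean_rng[1] <= 1.1,
           n = nrow(d), data = as_tibble(d)),
      class = "birn_titration_fit")
    return(res)
  }

  span <- rng[2] - rng[1]
  means <- d |>
    group_by(.data$ph) |>
    summarise(y = mean(.data$intensity / .data$concentration), .groups = "drop") |>
    arrange(.data$ph)

  # both plateaus must be represented beyond the extreme grid points,
  # otherwise the asymptotes (hence R_F) are not identifiable
  interior <- means$y[-c(1L, nrow(means))]
  if (!any(interior <= rng[1] + 0.25 * span) ||
      !any(interior >= rng[1] + 0.75 * span)) {
    abort_precondition(
      "titration does not span the transition (need interior points below 25% and above 75% of the intensity range).")
  }
  half <- rng[1] + span / 2
  ph_t0 <- {
    y <- means$y
    cross <- which(diff(sign(y - half)) != 0)
    if (length(cross) == 0L) stats::median(means$ph) else {
      i <- cross[1]
      approx(y[c(i, i + 1)], means$ph[c(i, i + 1)], xout = half)$y
    }
  }

  fit <- minpack.lm::nlsLM(
    intensity ~ concentration *
      (f_min + (f_max - f_min) / (1 + 10^((log10(81) / width) * (ph - ph_t)))),
    data = d,
    start = list(f_min = rng[1], f_max = rng[2], ph_t = ph_t0, width = 0.2),
    lower = c(f_min = 1e-12, f_max = 1e-12, ph_t = 4, width = 1e-4),
    upper = c(f_min = Inf, f_max = Inf, ph_t = 8, width = 5),
    control = minpack.lm::nls.lm.control(
      ptol = 1e-10, ftol = 1e-12, maxiter = 500, maxfev = 10000)
  )
  est <- coef(fit)
  rf <- unname(est["f_max"] / est["f_min"])
  structure(
    list(channel = channel, role = role,
         ph_t_hat = unname(est["ph_t"]),
         width_10_90_hat = unname(est["width"]),
         f_max_hat = unname(est["f_max"]),
         f_min_hat = unname(est["f_min"]),
         r_f_hat = rf,
         goodness = r_squared(d$intensity, predict(fit)),
         flat = FALSE,
         always_on_ok = if (role == "always_on") rf >= 0.9 && rf <= 1.1 else NA,
         n = nrow(d), data = as_tibble(d)),
    class = "birn_titration_fit")
}

#' @export
print.birn_titration_fit <- function(x, ...) {
  cat(sprintf("<birn_titration_fit> channel %s (%s), n = %d\n",
              x$channel, x$role, x$n))
  if (x$flat) {
    cat(sprintf("  flat channel: R_F = %.3f (always-ON gate %s), R^2 = %.4f\n",
                x$r_f_hat, if (isTRUE(x$always_on_ok)) "pass" else "fail",
                x$goodness))
  } else {
    cat(sprintf(
      "  pH_t = %.3f, width(10-90%%) = %.3f, R_F = %.1f, R^2 = %.4f\n",
      x$ph_t_hat, x$width_10_90_hat, x$r_f_hat, x$goodness))
  }
  invisible(x)
}
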