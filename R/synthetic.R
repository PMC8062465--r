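# Synthetic-data generators. Every generator is a pure function of its
# arguments and `seed`: draws happen under named substreams derived from
# (seed, stream name), so adding one noise source never shifts the draws
# of another, and identical inputs give identical outputs.

rtruncnorm <- function(n, mean, sd, lower = -Inf, upper = Inf) {
  if (sd == 0) {
    if (mean < lower || mean > upper) {
      abort_param("degenerate truncated normal: mean outside bounds at sd = 0.")
    }
    return(rep(mean, n))
  }
  plo <- pnorm(lower, mean, sd)
  phi <- pnorm(upper, mean, sd)
  if (phi <= plo) abort_param("empty truncation interval.")
  qnorm(stats::runif(n, plo, phi), mean, sd)
}

#' Simulate a pH titration of both probe modules
#'
#' Evaluates each module of the probe on a pH grid at the stated
#' concentration and applies multiplicative Gaussian noise,
#' `intensity = model * (1 + noise * eps)`, independently per record,
#' clamped at zero. The default grid is the wet-lab titration protocol
#' (pH 5.4 to 7.2 in 0.2 steps at 100 µg/mL).
#'
#' @param probe A [birn_probe()].
#' @param ph pH grid; must span the OFF-ON transition.
#' @param noise Multiplicative noise fraction (0.05 = 5%).
#' @param replicates Number of replicate measurements per pH.
#' @param concentration Probe concentration (µg/mL).
#' @param seed Integer seed.
#' @return A tibble with columns `ph`, `channel`, `intensity`,
#'   `replicate`, `concentration`.
#' @export
gen_titration <- function(probe, ph = seq(5.4, 7.2, by = 0.2), noise = 0.05,
                          replicates = 3, concentration = 100, seed) {
  stopifnot(inherits(probe, "birn_probe"))
  if (min(ph) >= probe$off_on$ph_t || max(ph) <= probe$off_on$ph_t) {
    abort_precondition("pH grid must span the OFF-ON transition.")
  }
  check_number(noise, "noise", lower = 0)
  grid <- tidyr::expand_grid(
    ph = ph, channel = c("off_on", "always_on"),
    replicate = seq_len(replicates))
  modules <- list(off_on = probe$off_on, always_on = probe$always_on)
  grid$concentration <- concentration
  model <- purrr::map2_dbl(grid$channel, grid$ph, function(chan, p) {
    module_fluorescence(modules[[chan]], p, concentration)
  })
  eps <- with_substream(seed, "noise", rnorm(nrow(grid)))
  grid$intensity <- pmax(model * (1 + noise * eps), 0)
  grid[, c("ph", "channel", "intensity", "replicate", "concentration")]
}

#' Simulate a calibration plate of mixture standards
#'
#' For each turn-ON fraction on the grid (default the standard plate:
#' 0, 5, 10, 20, 30, 40, 50 and 100%), each concentration and each
#' replicate well, draws the two channel intensities from the mixture
#' model with independent multiplicative Gaussian noise per channel.
#'
#' @param probe A [birn_probe()].
#' @param f_grid Turn-ON fractions in `[0, 1]`.
#' @param concentrations One or more probe concentrations (µg/mL).
#' @param noise Multiplicative noise fraction.
#' @param replicates Replicate wells per (fraction, concentration).
#' @param tissue Tissue label stamped on the standards.
#' @param seed Integer seed.
#' @return A tibble with columns `f_on`, `ch_off_on`, `ch_always_on`,
#'   `replicate`, `concentration`, `tissue`.
#' @export
gen_calibration_plate <- function(probe,
                                  f_grid = c(0, .05, .10, .20, .30, .40, .50, 1),
                                  concentrations = 50, noise = 0.05,
                                  replicates = 3, tissue = "tumour", seed) {
  stopifnot(inherits(probe, "birn_probe"))
  if (any(f_grid < 0 | f_grid > 1)) abort_param("`f_grid` must be in [0, 1].")
  check_number(noise, "noise", lower = 0)
  wells <- tidyr::expand_grid(
    f_on = f_grid, concentration = concentrations,
    replicate = seq_len(replicates))
  ch <- function(module, frac) {
    (1 - wells$f_on) *
      module_fluorescence(module, probe$ph_micelle_ref,
                          wells$concentration * frac) +
      wells$f_on *
      module_fluorescence(module, probe$ph_unimer_ref,
                          wells$concentration * frac)
  }
  o <- ch(probe$off_on, probe$molar_fraction_off_on)
  a <- ch(probe$always_on, 1 - probe$molar_fraction_off_on)
  eps_o <- with_substream(seed, "noise_off_on", rnorm(nrow(wells)))
  eps_a <- with_substream(seed, "noise_always_on", rnorm(nrow(wells)))
  wells$ch_off_on <- pmax(o * (1 + noise * eps_o), 0)
  wells$ch_always_on <- pmax(a * (1 + noise * eps_a), 0)
  wells$tissue <- tissue
  wells[, c("f_on", "ch_off_on", "ch_always_on", "replicate",
            "concentration", "tissue")]
}

#' Configuration of a synthetic dual-channel tissue scene
#'
#' Describes the compartment geometry and optics of a simulated tumour
#' field: vessels (blood pH 7.4), extracellular space (interstitial pH
#' drawn from a normal with mean 6.78 and sd 0.20, truncated above the
#' probe transition pH — the validity condition of the readout), and
#' endosomal puncta (pH drawn around 6.0, truncated below the transition
#' pH since internalized probe is in the activated state). Probe mass is
#' split to hit `f_target` internalized: the endosomal share is divided
#' equally among puncta, the remainder between vessels
#' (`vessel_share`) and extracellular space. Rendering applies the
#' channel optical model, a Gaussian point-spread function, Poisson shot
#' noise and Gaussian read noise.
#'
#' @param shape Image dimensions `(rows, cols)`.
#' @param f_target Target internalized mass fraction in `[0, 1]`.
#' @param n_vessels,vessel_width Number and pixel width of straight
#'   vessels.
#' @param n_puncta,puncta_radius Number and pixel radius of endosomal
#'   puncta.
#' @param endosome_ph_mean,endosome_ph_sd Endosomal pH distribution.
#' @param extracellular_ph_mean,extracellular_ph_sd Interstitial pH
#'   distribution.
#' @param vessel_share Share of the non-internalized mass placed in
#'   vessels.
#' @param psf_sigma Gaussian PSF standard deviation in pixels.
#' @param shot_noise Apply Poisson shot noise?
#' @param read_noise_sd Gaussian read noise sd in detector counts.
#' @param mean_always_on Target mean always-ON intensity (counts) over
#'   probe-bearing pixels; sets the exposure scale.
#' @return A list of class `birn_scene_config`.
#' @export
tissue_scene_config <- function(shape = c(96, 96), f_target = 0.155,
                                n_vessels = 2, vessel_width = 3,
                                n_puncta = 30, puncta_radius = 2,
                                endosome_ph_mean = 6.0, endosome_ph_sd = 0.2,
                                extracellular_ph_mean = 6.78,
                                extracellular_ph_sd = 0.20,
                                vessel_share = 0.2, psf_sigma = 1,
                                shot_noise = TRUE, read_noise_sd = 2,
                                mean_always_on = 200) {
  check_number(f_target, "f_target", lower = 0, upper = 1)
  if (f_target > 0 && n_puncta < 1) {
    abort_param("target internalized fraction is unreachable with zero puncta.")
  }
  structure(
    list(shape = shape, f_target = f_target, n_vessels = n_vessels,
         vessel_width = vessel_width, n_puncta = n_puncta,
         puncta_radius = puncta_radius,
         endosome_ph_mean = endosome_ph_mean, endosome_ph_sd = endosome_ph_sd,
         extracellular_ph_mean = extracellular_ph_mean,
         extracellular_ph_sd = extracellular_ph_sd,
         vessel_share = vessel_share, psf_sigma = psf_sigma,
         shot_noise = shot_noise, read_noise_sd = read_noise_sd,
         mean_always_on = mean_always_on),
    class = "birn_scene_config")
}

gaussian_blur <- function(m, sigma) {
  if (sigma <= 0) return(m)
  out <- EBImage::gblur(m, sigma = sigma)
  matrix(as.numeric(out), nrow(m), ncol(m))
}

#' Render a synthetic dual-channel tissue image with ground truth
#'
#' Builds the compartment scene of [tissue_scene_config()], draws
#' per-pixel pH values, renders both channels through the probe's optical
#' model (molar-fraction weighted), blurs with the Gaussian PSF and adds
#' Poisson shot noise plus Gaussian read noise. The returned
#' [birn_image()] carries per-pixel `truth_labels` and the attributes
#' `f_true` (realized internalized mass fraction) and `scene_config`.
#'
#' @param cfg A [tissue_scene_config()].
#' @param probe A [birn_probe()].
#' @param seed Integer seed.
#' @return A `birn_image` with truth labels.
#' @export
gen_tissue_image <- function(cfg = tissue_scene_config(), probe = birn_probe(),
                             seed) {
  stopifnot(inherits(cfg, "birn_scene_config"), inherits(probe, "birn_probe"))
  nr <- cfg$shape[1]; nc <- cfg$shape[2]
  labels <- matrix("extracellular", nr, nc)

  # vessels: straight bands, alternating orientation
  if (cfg$n_vessels > 0) {
    pos <- with_substream(seed, "geometry", {
      list(horiz = stats::runif(cfg$n_vessels) < 0.5,
           row_start = sample.int(nr - cfg$vessel_width, cfg$n_vessels,
                                  replace = TRUE),
           col_start = sample.int(nc - cfg$vessel_width, cfg$n_vessels,
                                  replace = TRUE))
    })
    for (i in seq_len(cfg$n_vessels)) {
      if (pos$horiz[i]) {
        labels[pos$row_start[i] + seq_len(cfg$vessel_width) - 1L, ] <- "vessel"
      } else {
        labels[, pos$col_start[i] + seq_len(cfg$vessel_width) - 1L] <- "vessel"
      }
    }
  }

  # endosomal puncta: disks centred away from vessels
  if (cfg$n_puncta > 0) {
    centres <- with_substream(seed, "placement", {
      free <- which(labels != "vessel")
      sample(free, cfg$n_puncta, replace = FALSE)
    })
    rr <- (centres - 1L) %% nr + 1L
    cc <- (centres - 1L) %/% nr + 1L
    R <- cfg$puncta_radius
    for (i in seq_len(cfg$n_puncta)) {
      rows <- pmax(1L, rr[i] - R):pmin(nr, rr[i] + R)
      cols <- pmax(1L, cc[i] - R):pmin(nc, cc[i] + R)
      for (r in rows) for (co in cols) {
        if ((r - rr[i])^2 + (co - cc[i])^2 <= R^2) labels[r, co] <- "intracellular"
      }
    }
  }

  n_endo <- sum(labels == "intracellular")
  n_ext <- sum(labels == "extracellular")
  n_ves <- sum(labels == "vessel")
  if (cfg$f_target > 0 && n_endo == 0) {
    abort_param("no endosomal pixels: target fraction unreachable.")
  }

  # mass per pixel, exact by construction
  mass <- matrix(0, nr, nc)
  f <- cfg$f_target
  if (n_endo > 0) mass[labels == "intracellular"] <- f / n_endo
  extra <- (1 - f) * if (n_ves > 0) (1 - cfg$vessel_share) else 1
  if (n_ext > 0) mass[labels == "extracellular"] <- extra / n_ext
  if (n_ves > 0) mass[labels == "vessel"] <- (1 - f) * cfg$vessel_share / n_ves
  f_true <- if (n_endo > 0) sum(mass[labels == "intracellular"]) / sum(mass) else 0

  # per-pixel pH: vessels at blood pH; extracellular truncated above the
  # transition pH (hard validity condition of the readout); endosomal pH
  # truncated at the probe's 99%-ON point — internalized probe is modelled
  # as fully switched, which is the reporter's binary premise
  eps_ph <- 1e-6
  ph <- matrix(probe$ph_micelle_ref, nr, nc)
  ph_t <- probe$off_on$ph_t
  ph_on99 <- ph_t - log10(99) / width_to_hill(probe$off_on$width_10_90)
  ph_draws <- with_substream(seed, "ph", {
    list(
      ext = rtruncnorm(n_ext, cfg$extracellular_ph_mean,
                       cfg$extracellular_ph_sd, lower = ph_t + eps_ph),
      endo = if (n_endo > 0)
        rtruncnorm(n_endo, cfg$endosome_ph_mean, cfg$endosome_ph_sd,
                   upper = ph_on99) else numeric(0))
  })
  ph[labels == "extracellular"] <- ph_draws$ext
  if (n_endo > 0) ph[labels == "intracellular"] <- ph_draws$endo
  stopifnot(all(ph[labels == "extracellular"] > ph_t))

  # optical model per channel, molar-fraction weighted
  th <- theta_on(ph, ph_t, probe$off_on$width_10_90)
  oo <- probe$off_on
  raw_o <- mass * probe$molar_fraction_off_on *
    (oo$f_min + (oo$f_max - oo$f_min) * th)
  ao <- probe$always_on
  th_a <- theta_on(ph, ao$ph_t, ao$width_10_90)
  raw_a <- mass * (1 - probe$molar_fraction_off_on) *
    (ao$f_min + (ao$f_max - ao$f_min) * th_a)

  scale <- cfg$mean_always_on / mean(raw_a[mass > 0])
  img_o <- gaussian_blur(raw_o * scale, cfg$psf_sigma)
  img_a <- gaussian_blur(raw_a * scale, cfg$psf_sigma)

  img_o <- with_substream(seed, "noise_off_on",
                          add_detector_noise(img_o, cfg))
  img_a <- with_substream(seed, "noise_always_on",
                          add_detector_noise(img_a, cfg))

  out <- birn_image(img_o, img_a, truth_labels = labels)
  attr(out, "f_true") <- f_true
  attr(out, "scene_config") <- cfg
  out
}

add_detector_noise <- function(m, cfg) {
  if (cfg$shot_noise) {
    m <- matrix(as.numeric(rpois(length(m), pmax(m, 0))), nrow(m), ncol(m))
  }
  if (cfg$read_noise_sd > 0) {
    m <- m + matrix(rnorm(length(m), 0, cfg$read_noise_sd), nrow(m), ncol(m))
  }
  pmax(m, 0)
}

#' Simulate a pulse-chase internalization time course
#'
#' Mono-exponential mean `plateau * (1 - 2^(-t / t_half))` with
#' multiplicative Gaussian noise per measurement, clamped to `[0, 1]`.
#'
#' @param t_half Internalization half-time (minutes), positive.
#' @param plateau Plateau ON-fraction in (0, 1].
#' @param timepoints Chase times (minutes).
#' @param replicates Number of replicates.
#' @param noise Multiplicative noise fraction.
#' @param seed Integer seed.
#' @return A [time_course()] of kind `"internalization"`.
#' @export
gen_pulse_chase <- function(t_half, plateau = 1,
                            timepoints = seq(0, 120, by = 10),
                            replicates = 3, noise = 0.05, seed) {
  check_number(t_half, "t_half", lower = 0, strict_lower = TRUE)
  check_number(plateau, "plateau", lower = 0, upper = 1, strict_lower = TRUE)
  d <- tidyr::expand_grid(replicate = seq_len(replicates), time = sort(timepoints))
  model <- plateau * (1 - 2^(-d$time / t_half))
  eps <- with_substream(seed, "noise", rnorm(nrow(d)))
  d$value <- pmin(pmax(model * (1 + noise * eps), 0), 1)
  time_course(d[, c("time", "value", "replicate")], kind = "internalization")
}

#' Simulate a subject cohort with a built-in exposure-response effect
#'
#' Draws per-subject tumour accumulation (log-normal, clipped to the
#' observed 0.50-2.56 %ID/g range) and endocytosis fraction (Beta scaled
#' over the observed 10.7-28.2% range) independently — accumulation and
#' internalization efficiency are decoupled — computes the internalized
#' dose as their product and generates the outcome through
#' `outcome = a + b * log(internalized_dose) + N(0, sigma)`, an
#' inhibition-percent scale where higher is better.
#'
#' @param n_subjects Number of subjects (at least 3).
#' @param acc_meanlog,acc_sdlog Log-normal parameters of accumulation.
#' @param acc_range Clipping range of accumulation (%ID/g).
#' @param f_shape1,f_shape2 Beta shape parameters of the endocytosis
#'   fraction.
#' @param f_range Support of the scaled endocytosis fraction.
#' @param effect_intercept,effect_slope,effect_sigma Outcome-model
#'   parameters (`a`, `b` >= 0, noise sd).
#' @param seed Integer seed.
#' @return A `birn_cohort` tibble with attribute `effect` carrying the
#'   generating parameters.
#' @export
gen_cohort <- function(n_subjects = 24,
                       acc_meanlog = log(1.2), acc_sdlog = 0.4,
                       acc_range = c(0.50, 2.56),
                       f_shape1 = 2, f_shape2 = 2,
                       f_range = c(0.107, 0.282),
                       effect_intercept = 80, effect_slope = 25,
                       effect_sigma = 7.5, seed) {
  if (n_subjects < 3L) abort_precondition("need at least 3 subjects.")
  if (effect_slope < 0) abort_param("`effect_slope` must be non-negative.")
  acc <- with_substream(seed, "accumulation",
                        rlnorm(n_subjects, acc_meanlog, acc_sdlog))
  acc <- pmin(pmax(acc, acc_range[1]), acc_range[2])
  f <- with_substream(seed, "endocytosis",
                      rbeta(n_subjects, f_shape1, f_shape2))
  f <- f_range[1] + diff(f_range) * f
  dose <- acc * f
  noise <- with_substream(seed, "outcome",
                          rnorm(n_subjects, 0, effect_sigma))
  outcome <- effect_intercept + effect_slope * log(dose) + noise
  cohort <- as_cohort(tibble(
    subject_id = sprintf("S%03d", seq_len(n_subjects)),
    accumulation_pct_id_g = acc,
    endocytosis_fraction = f,
    outcome = outcome,
    outcome_type = "inhibition_percent"
  ))
  attr(cohort, "effect") <- list(intercept = effect_intercept,
                                 slope = effect_slope, sigma = effect_sigma)
  cohort
}
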