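#' Build a fluorometry standard curve
#'
#' Linear regression of fluorescence intensity against nanoparticle
#' concentration in spiked tissue-homogenate standards. The curve is
#' usable only when `r >= 0.95`.
#'
#' @param standards Data frame with columns `conc` (mass/volume) and
#'   `intensity`.
#' @return An object of class `birn_fluorometry` with `slope`,
#'   `intercept`, `r` and `grid` (the concentrations used).
#' @export
build_fluorometry <- function(standards) {
  check_columns(standards, c("conc", "intensity"), "fluorometry standards")
  d <- as_tibble(standards)
  if (length(unique(d$conc)) < 3L) {
    abort_precondition("need at least 3 distinct concentrations.")
  }
  fit <- lm(intensity ~ conc, data = d)
  r <- cor(d$conc, d$intensity)
  curve <- structure(
    list(slope = unname(coef(fit)[2]), intercept = unname(coef(fit)[1]),
         r = r, grid = sort(unique(d$conc))),
    class = "birn_fluorometry")
  if (!is.finite(r) || r < 0.95) {
    abort_validation(sprintf(
      "fluorometry r = %.4f is below the 0.95 gate.", r), curve = curve)
  }
  if (curve$slope <= 0) abort_validation("fluorometry slope is not positive.")
  curve
}

#' Tissue accumulation in percent injected dose per gram
#'
#' Converts a homogenate fluorescence reading into a nanoparticle
#' concentration through the fluorometry standard curve, then into the
#' biodistribution unit %ID/g:
#' `100 * concentration * homogenate_volume / (injected_dose * tissue_mass)`.
#' Intensities below the curve intercept clip to zero concentration and
#' are flagged.
#'
#' @param curve A [build_fluorometry()] curve (or any list with `slope`,
#'   `intercept`, `r`).
#' @param sample_intensity Measured fluorescence of the homogenate
#'   supernatant.
#' @param homogenate_volume_ml Homogenate volume in mL.
#' @param tissue_mass_g Tissue mass in g.
#' @param injected_dose_ug Injected nanoparticle dose in µg.
#' @return A tibble with columns `conc`, `pct_id_g`, `clipped`.
#' @examples
#' curve <- list(slope = 100, intercept = 0, r = 1)
#' # 1.392 ug recovered in 0.2 g tumour after a 400 ug injection -> 1.74 %ID/g
#' accumulation_from_fluorometry(curve, 1.392 * 100, 1, 0.2, 400)
#' @export
accumulation_from_fluorometry <- function(curve, sample_intensity,
                                          homogenate_volume_ml,
                                          tissue_mass_g, injected_dose_ug) {
  if (!is.null(curve$r) && (!is.finite(curve$r) || curve$r < 0.95)) {
    abort_validation("fluorometry curve is below the r >= 0.95 gate.")
  }
  if (curve$slope <= 0) abort_validation("fluorometry slope must be positive.")
  check_number(homogenate_volume_ml, "homogenate_volume_ml", 0, strict_lower = TRUE)
  check_number(tissue_mass_g, "tissue_mass_g", 0, strict_lower = TRUE)
  check_number(injected_dose_ug, "injected_dose_ug", 0, strict_lower = TRUE)
  conc_raw <- (sample_intensity - curve$intercept) / curve$slope
  conc <- pmax(conc_raw, 0)
  tibble(
    conc = conc,
    pct_id_g = 100 * conc * homogenate_volume_ml /
      (injected_dose_ug * tissue_mass_g),
    clipped = conc_raw < 0
  )
}

#' Intracellular (internalized) nanoparticle dose
#'
#' The canonical intracellular-exposure measure: tissue accumulation in
#' %ID/g multiplied by the endocytosis fraction measured by the
#' ratiometric readout. Report at two decimals for tabulation.
#'
#' @param accumulation Accumulation in %ID/g, non-negative.
#' @param endocytosis_fraction Fraction in `[0, 1]`.
#' @return Internalized dose in %ID/g.
#' @examples
#' round(internalized_dose(1.74, 0.155), 2)  # 0.27
#' @export
internalized_dose <- function(accumulation, endocytosis_fraction) {
  if (any(accumulation < 0)) abort_param("`accumulation` must be non-negative.")
  if (any(endocytosis_fraction < 0 | endocytosis_fraction > 1)) {
    abort_param("`endocytosis_fraction` must be in [0, 1].")
  }
  accumulation * endocytosis_fraction
}

#' Validate a cohort table
#'
#' Checks per-subject records: unique subject ids, accumulation >= 0,
#' endocytosis fraction in `[0, 1]`, and recomputes the internalized dose
#' as accumulation x fraction (the conservation invariant
#' `internalized <= accumulation` then holds by construction; a supplied
#' `internalized_pct_id_g` column inconsistent with the product is an
#' error).
#'
#' @param data Data frame with columns `subject_id`,
#'   `accumulation_pct_id_g`, `endocytosis_fraction`, `outcome`, and
#'   optionally `internalized_pct_id_g`, `group`.
#' @return A validated tibble of class `birn_cohort`.
#' @export
as_cohort <- function(data) {
  check_columns(data, c("subject_id", "accumulation_pct_id_g",
                        "endocytosis_fraction", "outcome"), "cohort table")
  d <- as_tibble(data)
  if (anyDuplicated(d$subject_id)) abort_param("subject ids must be unique.")
  if (nrow(d) < 2L) abort_precondition("a cohort needs at least 2 subjects.")
  if (any(d$accumulation_pct_id_g < 0)) {
    abort_param("accumulation must be non-negative.")
  }
  if (any(d$endocytosis_fraction < 0 | d$endocytosis_fraction > 1)) {
    abort_param("endocytosis fractions must be in [0, 1].")
  }
  product <- d$accumulation_pct_id_g * d$endocytosis_fraction
  if ("internalized_pct_id_g" %in% names(d)) {
    # tolerance covers the 2-decimal reporting convention at I/O
    if (any(abs(d$internalized_pct_id_g - product) >
            0.005 + 1e-6 * product)) {
      abort_validation(
        "internalized_pct_id_g is inconsistent with accumulation x fraction.")
    }
  }
  d$internalized_pct_id_g <- product
  if (any(d$internalized_pct_id_g > d$accumulation_pct_id_g + 1e-12)) {
    abort_validation("internalized dose exceeds accumulation.")
  }
  structure(d, class = c("birn_cohort", class(d)))
}

#' Stratify a cohort by a numeric key
#'
#' Median split assigns the lower `ceiling(n/2)` subjects (ties at the
#' median go low) to group `"low"` and the rest to `"high"`. Terciles
#' rank-split into `"low"`, `"medium"`, `"high"` with any remainder going
#' to the lower groups. Ties are broken by subject order in the table, so
#' stratification is deterministic.
#'
#' @param cohort A cohort table (coerced through [as_cohort()]).
#' @param key Name of the numeric column to stratify on (default the
#'   internalized dose).
#' @param scheme `"median_split"` or `"terciles"`.
#' @return The cohort tibble with a `group` factor column added.
#' @examples
#' cohort <- gen_cohort(n_subjects = 24, seed = 1)
#' table(stratify(cohort)$group)
#' @export
stratify <- function(cohort, key = "internalized_pct_id_g",
                     scheme = c("median_split", "terciles")) {
  scheme <- match.arg(scheme)
  d <- as_cohort(cohort)
  if (!key %in% names(d)) abort_param(sprintf("no column `%s`.", key))
  x <- d[[key]]
  if (!is.numeric(x) || any(!is.finite(x))) {
    abort_param("stratification key must be finite numeric for all subjects.")
  }
  n <- length(x)
  if (scheme == "terciles" && n < 3L) {
    abort_precondition("terciles need at least 3 subjects.")
  }
  if (length(unique(x)) == 1L) {
    abort_degenerate("all key values are equal; stratification is degenerate.")
  }
  ord <- order(x, seq_len(n))   # stable: ties by subject order
  rank_pos <- match(seq_len(n), ord)
  if (scheme == "median_split") {
    n_low <- ceiling(n / 2)
    grp <- ifelse(rank_pos <= n_low, "low", "high")
    d$group <- factor(grp, levels = c("low", "high"))
  } else {
    base <- n %/% 3L
    rem <- n %% 3L
    sizes <- c(base + (rem >= 1L), base + (rem >= 2L), base)
    cuts <- cumsum(sizes)
    grp <- cut(rank_pos, breaks = c(0, cuts),
               labels = c("low", "medium", "high"))
    d$group <- factor(as.character(grp), levels = c("low", "medium", "high"))
  }
  d
}

#' Simple linear correlation between two measurements
#'
#' Pearson correlation with the simple-linear-regression slope and a
#' two-sided p-value for slope != 0, as used for exposure-response
#' analyses.
#'
#' @param x,y Numeric vectors of equal length (at least 3), each with
#'   nonzero variance.
#' @return An object of class `birn_correlation` with `r`, `p`, `slope`,
#'   `intercept`, `n`.
#' @examples
#' correlate(1:10, 2 * (1:10) + 1)
#' @export
correlate <- function(x, y) {
  if (length(x) != length(y)) abort_param("`x` and `y` must have equal length.")
  if (length(x) < 3L) abort_precondition("need at least 3 observations.")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    abort_degenerate("zero variance in x or y.")
  }
  fit <- lm(y ~ x)
  ct <- suppressWarnings(cor.test(x, y, method = "pearson"))
  structure(
    list(r = unname(ct$estimate), p = ct$p.value,
         slope = unname(coef(fit)[2]), intercept = unname(coef(fit)[1]),
         n = length(x)),
    class = "birn_correlation")
}

#' @export
print.birn_correlation <- function(x, ...) {
  cat(sprintf("<birn_correlation> r = %.4f, p = %.3g, slope = %.4g (n = %d)\n",
              x$r, x$p, x$slope, x$n))
  invisible(x)
}

#' Welch comparison of an outcome between two cohort groups
#'
#' Welch two-sample t-test of `outcome` between two stratification
#' groups, two-sided, no multiple-testing correction (none is applied in
#' this analysis; adjust downstream if several outcomes are tested).
#'
#' @param cohort A stratified cohort (with a `group` column).
#' @param outcome Name of the outcome column.
#' @param groups The two group labels to compare (default low vs high).
#' @return A one-row tibble: group means, `difference` (second minus
#'   first), `statistic`, `df`, `p_value`.
#' @examples
#' cohort <- stratify(gen_cohort(n_subjects = 24, seed = 1))
#' compare_groups(cohort)
#' @export
compare_groups <- function(cohort, outcome = "outcome",
                           groups = c("low", "high")) {
  if (!"group" %in% names(cohort)) {
    abort_param("cohort has no `group` column; run stratify() first.")
  }
  if (!outcome %in% names(cohort)) {
    abort_param(sprintf("no outcome column `%s`.", outcome))
  }
  if (length(groups) != 2L) abort_param("exactly two groups must be selected.")
  g1 <- cohort[[outcome]][cohort$group == groups[1]]
  g2 <- cohort[[outcome]][cohort$group == groups[2]]
  if (length(g1) < 2L || length(g2) < 2L) {
    abort_precondition("each group needs at least 2 subjects.")
  }
  tt <- t.test(g2, g1, var.equal = FALSE, alternative = "two.sided")
  tibble(
    group_1 = groups[1], group_2 = groups[2],
    mean_1 = mean(g1), mean_2 = mean(g2),
    difference = mean(g2) - mean(g1),
    statistic = unname(tt$statistic),
    df = unname(tt$parameter),
    p_value = tt$p.value
  )
}
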