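# File interfaces. Percentages live in files and fractions in memory:
# readers divide, writers multiply, so no 100x slips through the API.

#' Read and write titration tables
#'
#' CSV with columns `ph`, `channel`, `intensity`, `replicate`,
#' `concentration_ug_per_ml` (header required).
#'
#' @param path File path.
#' @return A tibble with column `concentration` (µg/mL).
#' @export
read_titration_csv <- function(path) {
  d <- readr::read_csv(path, show_col_types = FALSE)
  check_columns(d, c("ph", "channel", "intensity"), "titration CSV")
  if ("concentration_ug_per_ml" %in% names(d)) {
    d <- dplyr::rename(d, concentration = "concentration_ug_per_ml")
  }
  d
}

#' @rdname read_titration_csv
#' @param data Titration tibble (as from [gen_titration()]).
#' @export
write_titration_csv <- function(data, path) {
  d <- as_tibble(data)
  if ("concentration" %in% names(d)) {
    d <- dplyr::rename(d, concentration_ug_per_ml = "concentration")
  }
  readr::write_csv(d, path)
  invisible(path)
}

#' Read and write calibration-standard plates
#'
#' CSV with columns `f_on_percent`, `ch_off_on`, `ch_always_on`,
#' `replicate`, `concentration_ug_per_ml`, `tissue`. Percent on disk,
#' fraction (`f_on`) in memory.
#'
#' @param path File path.
#' @return A tibble with `f_on` as a fraction.
#' @export
read_standards_csv <- function(path) {
  d <- readr::read_csv(path, show_col_types = FALSE)
  check_columns(d, c("f_on_percent", "ch_off_on", "ch_always_on"),
                "standards CSV")
  d$f_on <- d$f_on_percent / 100
  d$f_on_percent <- NULL
  if ("concentration_ug_per_ml" %in% names(d)) {
    d <- dplyr::rename(d, concentration = "concentration_ug_per_ml")
  }
  d
}

#' @rdname read_standards_csv
#' @param data Standards tibble (as from [gen_calibration_plate()]).
#' @export
write_standards_csv <- function(data, path) {
  d <- as_tibble(data)
  d$f_on_percent <- d$f_on * 100
  d$f_on <- NULL
  if ("concentration" %in% names(d)) {
    d <- dplyr::rename(d, concentration_ug_per_ml = "concentration")
  }
  readr::write_csv(d, path)
  invisible(path)
}

#' Read and write a probe definition as YAML
#'
#' Keys `off_on` and `always_on` each hold `f_max`, `f_min`, `ph_t`,
#' `width_10_90`; `molar_fraction_off_on` at top level.
#'
#' @param path File path.
#' @return A [birn_probe()].
#' @export
read_probe_yaml <- function(path) {
  y <- yaml::read_yaml(path)
  mod <- function(key, role) {
    m <- y[[key]]
    probe_module(key, role, f_max = m$f_max, f_min = m$f_min,
                 ph_t = m$ph_t, width_10_90 = m$width_10_90)
  }
  birn_probe(
    off_on = mod("off_on", "off_on"),
    always_on = mod("always_on", "always_on"),
    molar_fraction_off_on = y$molar_fraction_off_on %||% 0.9
  )
}

#' @rdname read_probe_yaml
#' @param probe A [birn_probe()].
#' @export
write_probe_yaml <- function(probe, path) {
  stopifnot(inherits(probe, "birn_probe"))
  strip <- function(m) m[c("f_max", "f_min", "ph_t", "width_10_90")]
  yaml::write_yaml(
    list(off_on = strip(probe$off_on), always_on = strip(probe$always_on),
         molar_fraction_off_on = probe$molar_fraction_off_on),
    path)
  invisible(path)
}

#' Read and write a calibration curve as JSON
#'
#' JSON object with `tissue`, `slope`, `intercept`, `r`, `n_points`,
#' `f_grid_percent`.
#'
#' @param path File path.
#' @return A `birn_calibration`.
#' @export
read_curve_json <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(
    list(slope = j$slope, intercept = j$intercept, r = j$r,
         tissue = j$tissue, n_points = j$n_points,
         f_grid = j$f_grid_percent / 100, levels = NULL),
    class = "birn_calibration")
}

#' @rdname read_curve_json
#' @param curve A `birn_calibration`.
#' @export
write_curve_json <- function(curve, path) {
  stopifnot(inherits(curve, "birn_calibration"))
  jsonlite::write_json(
    list(tissue = curve$tissue, slope = curve$slope,
         intercept = curve$intercept, r = curve$r,
         n_points = curve$n_points, f_grid_percent = curve$f_grid * 100),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read and write dual-channel TIFF images
#'
#' Either one two-page TIFF (page 1 = OFF-ON, page 2 = always-ON) or two
#' single-channel files. Intensities are detector counts on the 16-bit
#' scale: on disk they are stored normalized by the 16-bit full scale
#' (65535), as 16-bit integers (values clipped at the ceiling, never
#' wrapped) or as 32-bit floats, which preserve fractional synthetic
#' counts; the reader restores counts.
#'
#' @param path Path of the (first) TIFF.
#' @param path_always_on Optional second file holding the always-ON
#'   channel.
#' @return A [birn_image()].
#' @export
read_dual_channel_tiff <- function(path, path_always_on = NULL) {
  if (is.null(path_always_on)) {
    pages <- tiff::readTIFF(path, all = TRUE)
    if (length(pages) < 2L) {
      abort_param("expected a 2-page TIFF or two single-channel files.")
    }
    birn_image(as_raster(pages[[1]]), as_raster(pages[[2]]))
  } else {
    birn_image(as_raster(tiff::readTIFF(path)),
               as_raster(tiff::readTIFF(path_always_on)))
  }
}

as_raster <- function(x) {
  if (length(dim(x)) == 3L) x <- x[, , 1]
  matrix(as.numeric(x) * 65535, nrow(x), ncol(x))
}

#' @rdname read_dual_channel_tiff
#' @param img A [birn_image()].
#' @param bits Either 32 (float; default, keeps fractional counts) or 16
#'   (integer counts, values clipped to 65535).
#' @export
write_dual_channel_tiff <- function(img, path, bits = 32) {
  stopifnot(inherits(img, "birn_image"))
  scale <- 65535
  pages <- list(pmin(img$ch_off_on, scale) / scale,
                pmin(img$ch_always_on, scale) / scale)
  tiff::writeTIFF(pages, path, bits.per.sample = bits, reduce = FALSE)
  invisible(path)
}

#' Read and write time-course tables
#'
#' CSV with columns `time`, `value`, `replicate`, `kind`, `unit`.
#'
#' @param path File path.
#' @return A [time_course()].
#' @export
read_timecourse_csv <- function(path) {
  d <- readr::read_csv(path, show_col_types = FALSE)
  check_columns(d, c("time", "value", "kind"), "time-course CSV")
  kind <- unique(d$kind)
  if (length(kind) != 1L) abort_param("mixed time-course kinds in one file.")
  unit <- if ("unit" %in% names(d)) unique(d$unit)[1] else NULL
  time_course(d[, intersect(names(d), c("time", "value", "replicate"))],
              kind = kind, unit = unit)
}

#' @rdname read_timecourse_csv
#' @param tc A [time_course()].
#' @export
write_timecourse_csv <- function(tc, path) {
  stopifnot(inherits(tc, "birn_timecourse"))
  d <- as_tibble(tc)
  d$kind <- attr(tc, "kind")
  d$unit <- attr(tc, "unit")
  readr::write_csv(d, path)
  invisible(path)
}

#' Read and write cohort tables
#'
#' CSV with columns `subject_id`, `accumulation_pct_id_g`,
#' `endocytosis_fraction`, optional `internalized_pct_id_g` (recomputed
#' and checked on read), `outcome`, `outcome_type`. Internalized doses
#' are written at two decimals.
#'
#' @param path File path.
#' @return A `birn_cohort` tibble.
#' @export
read_cohort_csv <- function(path) {
  as_cohort(readr::read_csv(path, show_col_types = FALSE))
}

#' @rdname read_cohort_csv
#' @param cohort A cohort table.
#' @export
write_cohort_csv <- function(cohort, path) {
  d <- as_cohort(cohort)
  d$internalized_pct_id_g <- round(d$internalized_pct_id_g, 2)
  readr::write_csv(d, path)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
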