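#' Paired dual-channel fluorescence rasters
#'
#' Bundles the OFF-ON and always-ON channel images of one acquisition,
#' with an optional pixel size and, for synthetic scenes, per-pixel
#' ground-truth compartment labels (`"background"`, `"vessel"`,
#' `"extracellular"`, `"intracellular"`).
#'
#' @param ch_off_on,ch_always_on Numeric matrices of identical dimensions,
#'   finite and non-negative.
#' @param pixel_size Optional physical pixel size (length per pixel).
#' @param truth_labels Optional character or factor matrix of compartment
#'   labels, same dimensions.
#' @return An object of class `birn_image`.
#' @export
birn_image <- function(ch_off_on, ch_always_on, pixel_size = NULL,
                       truth_labels = NULL) {
  if (!is.matrix(ch_off_on) || !is.matrix(ch_always_on)) {
    abort_param("channels must be matrices.")
  }
  if (!identical(dim(ch_off_on), dim(ch_always_on))) {
    abort_param("channel rasters must have identical dimensions.")
  }
  if (any(!is.finite(ch_off_on)) || any(!is.finite(ch_always_on)) ||
      any(ch_off_on < 0) || any(ch_always_on < 0)) {
    abort_param("channel values must be finite and non-negative.")
  }
  if (!is.null(truth_labels) && !identical(dim(truth_labels), dim(ch_off_on))) {
    abort_param("`truth_labels` must match the channel dimensions.")
  }
  structure(
    list(ch_off_on = ch_off_on, ch_always_on = ch_always_on,
         pixel_size = pixel_size, truth_labels = truth_labels),
    class = "birn_image")
}

#' @export
print.birn_image <- function(x, ...) {
  cat(sprintf("<birn_image> %d x %d pixels%s\n",
              nrow(x$ch_off_on), ncol(x$ch_off_on),
              if (is.null(x$truth_labels)) "" else " (with truth labels)"))
  invisible(x)
}

# Accept an ROI as a logical mask or a two-column (row, col) table of
# 0-based coordinates; return linear indices into the raster.
roi_indices <- function(img, roi) {
  dims <- dim(img$ch_off_on)
  if (is.matrix(roi) && is.logical(roi)) {
    if (!identical(dim(roi), dims)) abort_param("ROI mask dimensions differ from image.")
    idx <- which(roi)
  } else {
    roi <- as.data.frame(roi)
    if (ncol(roi) < 2L) abort_param("ROI coordinates need (row, col) columns.")
    r <- roi[[1]]; c <- roi[[2]]
    if (any(r < 0 | r >= dims[1] | c < 0 | c >= dims[2])) {
      abort_param("ROI coordinates fall outside the image (0-based row, col).")
    }
    idx <- (r + 1) + c * dims[1]
  }
  if (length(idx) == 0L) abort_param("ROI is empty.")
  idx
}

#' Normalization bounds for the ratio scale
#'
#' The binary mask thresholds the ratio on a normalized scale anchored at
#' the fully-OFF (`f_on = 0`) and fully-ON (`f_on = 1`) ratios. Bounds are
#' taken from a calibration curve's endpoints when one is available, else
#' from the probe model at its two reference pH values.
#'
#' @param x A `birn_calibration` or `birn_probe`.
#' @return Numeric length-2 vector `(ratio_at_f0, ratio_at_f1)`.
#' @export
norm_bounds <- function(x) {
  if (inherits(x, "birn_calibration")) {
    c(x$intercept, x$intercept + x$slope)
  } else if (inherits(x, "birn_probe")) {
    c(mixture_ratio(x, 0), mixture_ratio(x, 1))
  } else {
    abort_param("`x` must be a calibration curve or a probe.")
  }
}

#' Validity gate for shot-noise-limited images
#'
#' Smallest background-subtracted always-ON intensity `a` (in detector
#' counts) satisfying `a >= k * sqrt(a + read_noise_sd^2)`, i.e. the
#' denominator exceeds `k` times its own Poisson-plus-read noise standard
#' deviation. Use as `min_denominator` when the image is photon-counting;
#' for images without shot noise the classic `k * read_noise_sd` applies.
#'
#' @param read_noise_sd Gaussian read-noise standard deviation (counts).
#' @param k Gate multiple (default 3).
#' @return Minimum valid denominator in counts.
#' @examples
#' suggest_min_denominator(2)  # 12
#' @export
suggest_min_denominator <- function(read_noise_sd = 2, k = 3) {
  check_number(read_noise_sd, "read_noise_sd", lower = 0)
  check_number(k, "k", lower = 0, strict_lower = TRUE)
  (k^2 + sqrt(k^4 + 4 * k^2 * read_noise_sd^2)) / 2
}

#' Pixelwise O/A ratio image
#'
#' Background-subtracts both channels and forms the OFF-ON over always-ON
#' ratio on pixels whose subtracted denominator reaches `min_denominator`;
#' all other pixels are marked invalid (the ratio is meaningless where no
#' probe is present). Negative subtracted numerators clamp to zero.
#'
#' @param img A [birn_image()].
#' @param background Per-channel background offsets, either a single value
#'   or `c(off_on =, always_on =)`.
#' @param min_denominator Validity gate on the subtracted always-ON
#'   intensity; a practical default is 3x the background standard
#'   deviation of the always-ON channel.
#' @param bounds Optional normalization bounds from [norm_bounds()];
#'   required later by [binarize_ratio()].
#' @return An object of class `birn_ratio` with elements `ratio` (matrix,
#'   `NA` where invalid), `valid_mask` and `bounds`.
#' @export
ratio_image <- function(img, background = 0, min_denominator = 1,
                        bounds = NULL) {
  stopifnot(inherits(img, "birn_image"))
  bg <- if (length(background) == 1L) {
    c(off_on = background, always_on = background)
  } else {
    if (is.null(names(background))) names(background) <- c("off_on", "always_on")
    background[c("off_on", "always_on")]
  }
  if (any(bg < 0)) abort_param("`background` must be non-negative.")
  check_number(min_denominator, "min_denominator", lower = 0, strict_lower = TRUE)
  num <- pmax(img$ch_off_on - bg[["off_on"]], 0)
  den <- img$ch_always_on - bg[["always_on"]]
  valid <- den >= min_denominator
  if (!any(valid)) abort_degenerate("no probe signal: all pixels invalid.")
  ratio <- matrix(NA_real_, nrow(num), ncol(num))
  ratio[valid] <- num[valid] / den[valid]
  if (!is.null(bounds)) {
    if (length(bounds) != 2L || bounds[2] <= bounds[1]) {
      abort_param("`bounds` must be increasing (ratio_at_f0, ratio_at_f1).")
    }
  }
  structure(list(ratio = ratio, valid_mask = valid, bounds = bounds),
            class = "birn_ratio")
}

#' Binary internalization mask from a ratio image
#'
#' Normalizes the ratio between the fully-OFF and fully-ON bounds and
#' thresholds at `threshold_norm` (default 0.5, the maximally separating
#' midpoint of a near-binary response). The output is strictly two-valued:
#' 1 on valid pixels at or above threshold, 0 elsewhere.
#'
#' @param res A [ratio_image()] result.
#' @param threshold_norm Threshold on the normalized ratio scale, in (0, 1).
#' @param bounds Normalization bounds, overriding any stored in `res`.
#' @return An integer 0/1 matrix.
#' @export
binarize_ratio <- function(res, threshold_norm = 0.5, bounds = NULL) {
  stopifnot(inherits(res, "birn_ratio"))
  b <- if (!is.null(bounds)) bounds else res$bounds
  if (is.null(b)) abort_param("normalization bounds are required (see norm_bounds()).")
  if (length(b) != 2L || b[2] <= b[1]) {
    abort_param("bounds must satisfy ratio_at_f1 > ratio_at_f0.")
  }
  check_number(threshold_norm, "threshold_norm", lower = 0, upper = 1,
               strict_lower = TRUE, strict_upper = TRUE)
  normed <- (res$ratio - b[1]) / (b[2] - b[1])
  mask <- matrix(0L, nrow(normed), ncol(normed))
  on <- res$valid_mask & !is.na(normed) & normed >= threshold_norm
  mask[on] <- 1L
  mask
}

#' Count internalization puncta in a binary mask
#'
#' Labels connected components of ON pixels (8- or 4-connectivity) and
#' keeps those of at least `min_area` pixels. Components are numbered
#' deterministically in row-major order of their first pixel. Centroids
#' are 0-based `(row, col)`.
#'
#' @param mask Binary (0/1 or logical) matrix.
#' @param min_area Minimum component area in pixels.
#' @param connectivity 8 (default) or 4.
#' @param ratio_norm Optional matrix of normalized ratios used to report a
#'   per-punctum mean ratio.
#' @return A tibble with one row per punctum: `punctum`, `area`,
#'   `centroid_row`, `centroid_col`, `mean_ratio`.
#' @export
count_puncta <- function(mask, min_area = 4, connectivity = c(8, 4),
                         ratio_norm = NULL) {
  connectivity <- as.integer(match.arg(as.character(connectivity[1]), c("8", "4")))
  if (!is.matrix(mask)) abort_param("`mask` must be a matrix.")
  vals <- unique(as.vector(mask))
  if (!all(vals %in% c(0, 1, TRUE, FALSE))) {
    abort_param("`mask` must be binary.")
  }
  labels <- label_components(mask != 0, connectivity)
  if (max(labels) == 0L) {
    return(tibble(punctum = integer(), area = integer(),
                  centroid_row = double(), centroid_col = double(),
                  mean_ratio = double()))
  }
  keep <- which(tabulate(labels[labels > 0L]) >= min_area)
  if (length(keep) == 0L) {
    return(tibble(punctum = integer(), area = integer(),
                  centroid_row = double(), centroid_col = double(),
                  mean_ratio = double()))
  }
  out <- purrr::map_dfr(seq_along(keep), function(i) {
    idx <- which(labels == keep[i])
    rows <- (idx - 1L) %% nrow(mask)      # 0-based
    cols <- (idx - 1L) %/% nrow(mask)
    tibble(
      punctum = i,
      area = length(idx),
      centroid_row = mean(rows),
      centroid_col = mean(cols),
      mean_ratio = if (is.null(ratio_norm)) NA_real_ else
        mean(ratio_norm[idx], na.rm = TRUE)
    )
  })
  out
}

# Connected-component labelling by iterative minimum-label propagation.
# ON pixels start with their row-major linear index; each sweep assigns
# every ON pixel the minimum label among itself and its ON neighbours
# until a fixed point, then labels are renumbered 1..k in row-major order
# of each component's first pixel.
label_components <- function(on, connectivity = 8L) {
  nr <- nrow(on); nc <- ncol(on)
  lab <- matrix(Inf, nr, nc)
  # row-major index so final renumbering is row-major deterministic
  rm_index <- matrix(seq_len(nr * nc), nr, nc, byrow = TRUE)
  lab[on] <- rm_index[on]

  shifts <- list(c(1L, 0L), c(-1L, 0L), c(0L, 1L), c(0L, -1L))
  if (connectivity == 8L) {
    shifts <- c(shifts, list(c(1L, 1L), c(1L, -1L), c(-1L, 1L), c(-1L, -1L)))
  }
  shift_mat <- function(m, dr, dc, fill = Inf) {
    out <- matrix(fill, nr, nc)
    rs <- seq_len(nr); cs <- seq_len(nc)
    out[rs[rs + dr >= 1 & rs + dr <= nr], cs[cs + dc >= 1 & cs + dc <= nc]] <-
      m[rs[rs + dr >= 1 & rs + dr <= nr] + dr, cs[cs + dc >= 1 & cs + dc <= nc] + dc]
    out
  }
  repeat {
    new_lab <- lab
    for (s in shifts) {
      new_lab <- pmin(new_lab, shift_mat(lab, s[1], s[2]))
    }
    new_lab[!on] <- Inf
    if (identical(new_lab, lab)) break
    lab <- new_lab
  }
  out <- matrix(0L, nr, nc)
  if (any(on)) {
    roots <- lab[on]
    # order component ids by row-major position of their first pixel
    uniq <- sort(unique(roots))
    out[on] <- match(roots, uniq)
  }
  out
}

#' Region-level endocytosis fraction
#'
#' Quantifies the internalized fraction over a region of interest by the
#' region-mean convention: mean background-subtracted intensity per
#' channel over the ROI, ROI-level O/A ratio from those means (not the
#' noise-biased mean of per-pixel ratios), inverted through the tissue's
#' calibration curve.
#'
#' @inheritParams ratio_image
#' @param roi ROI as a logical mask or a 0-based `(row, col)` table.
#' @param curve A valid [build_calibration()] curve.
#' @param tissue Optional tissue label checked against the curve.
#' @param force Allow a tissue mismatch.
#' @return A one-row tibble: `f_hat`, `ratio`, `n_pixels`, `out_of_range`.
#' @export
region_endocytosis <- function(img, roi, curve, background = 0,
                               min_denominator = 1, tissue = NULL,
                               force = FALSE) {
  stopifnot(inherits(img, "birn_image"), inherits(curve, "birn_calibration"))
  idx <- roi_indices(img, roi)
  bg <- if (length(background) == 1L) rep(background, 2) else background
  num <- pmax(img$ch_off_on[idx] - bg[[1]], 0)
  den <- img$ch_always_on[idx] - bg[[2]]
  if (!any(den >= min_denominator)) {
    abort_degenerate("ROI contains no valid probe pixels.")
  }
  mean_o <- mean(num)
  mean_a <- mean(den)
  if (mean_a < min_denominator) {
    abort_degenerate("ROI mean always-ON signal is below the validity gate.")
  }
  ratio <- mean_o / mean_a
  inv <- invert_calibration(curve, ratio, tissue = tissue, force = force)
  tibble(f_hat = inv$f_hat, ratio = ratio, n_pixels = length(idx),
         out_of_range = inv$out_of_range)
}

#' Tumour-to-normal contrast of one channel
#'
#' Mean intensity of the chosen channel over the tumour ROI divided by its
#' mean over the normal-tissue ROI.
#'
#' @inheritParams region_endocytosis
#' @param tumour_roi,normal_roi ROIs (logical mask or 0-based coordinates).
#' @param channel `"off_on"` or `"always_on"`.
#' @return The T/N contrast ratio (single number).
#' @export
tn_contrast <- function(img, tumour_roi, normal_roi,
                        channel = c("off_on", "always_on")) {
  stopifnot(inherits(img, "birn_image"))
  channel <- match.arg(channel)
  ch <- if (channel == "off_on") img$ch_off_on else img$ch_always_on
  m_t <- mean(ch[roi_indices(img, tumour_roi)])
  m_n <- mean(ch[roi_indices(img, normal_roi)])
  if (m_n <= 0) abort_degenerate("normal-region mean is zero; contrast undefined.")
  m_t / m_n
}
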