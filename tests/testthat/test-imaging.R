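test_that("ratio image divides valid pixels and flags the rest", {
  img <- birn_image(matrix(c(0, 10, 0, 10), 2, 2, byrow = TRUE),
                    matrix(c(10, 10, 10, 0), 2, 2, byrow = TRUE))
  res <- ratio_image(img, background = 0, min_denominator = 1)
  expect_equal(res$ratio[1, ], c(0, 1))
  expect_equal(res$ratio[2, 1], 0)
  expect_true(is.na(res$ratio[2, 2]))
  expect_identical(res$valid_mask,
                   matrix(c(TRUE, TRUE, TRUE, FALSE), 2, 2, byrow = TRUE))
  dark <- birn_image(matrix(1, 2, 2), matrix(0, 2, 2))
  expect_error(ratio_image(dark, min_denominator = 1),
               class = "birn_error_degenerate")
})

test_that("binarization is strictly two-valued at the midpoint threshold", {
  res <- structure(
    list(ratio = matrix(c(0.1, 0.9, 0.49, 0.51), 2, 2, byrow = TRUE),
         valid_mask = matrix(TRUE, 2, 2), bounds = c(0, 1)),
    class = "birn_ratio")
  mask <- binarize_ratio(res, 0.5)
  expect_identical(mask, matrix(c(0L, 1L, 0L, 1L), 2, 2, byrow = TRUE))
  expect_true(all(mask %in% c(0L, 1L)))
  expect_error(binarize_ratio(res, bounds = c(1, 0)),
               class = "birn_error_parameter")
})

test_that("ratio, mask and region estimate are invariant to global gain", {
  p <- reference_probe()
  curve <- noiseless_curve(p)
  img <- gen_tissue_image(tissue_scene_config(shape = c(64, 64)), p, seed = 11)
  gained <- birn_image(img$ch_off_on * 7.3, img$ch_always_on * 7.3)
  r1 <- ratio_image(img, 0, 1e-6, bounds = norm_bounds(curve))
  r2 <- ratio_image(gained, 0, 1e-6, bounds = norm_bounds(curve))
  common <- r1$valid_mask & r2$valid_mask
  expect_equal(r1$ratio[common], r2$ratio[common], tolerance = 1e-12)
  roi <- matrix(TRUE, 64, 64)
  f1 <- region_endocytosis(img, roi, curve, 0, 1e-6)$f_hat
  f2 <- region_endocytosis(gained, roi, curve, 0, 1e-6)$f_hat
  expect_equal(f1, f2, tolerance = 1e-12)
})

test_that("puncta counting matches the trivial cases", {
  m <- matrix(0L, 8, 8)
  m[3:5, 4:6] <- 1L
  ps <- count_puncta(m, min_area = 4)
  expect_equal(nrow(ps), 1L)
  expect_equal(ps$area, 9L)
  expect_equal(ps$centroid_row, 3)  # 0-based centre of rows 3:5
  expect_equal(ps$centroid_col, 4)
  expect_equal(nrow(count_puncta(matrix(0L, 8, 8))), 0L)
  # min_area filter removes a 2-pixel speck
  m[1, 1:2] <- 1L
  expect_equal(nrow(count_puncta(m, min_area = 4)), 1L)
  expect_equal(nrow(count_puncta(m, min_area = 1)), 2L)
})

test_that("puncta labelling agrees with an independent flood-fill oracle", {
  withr::with_seed(42, {
    for (i in 1:60) {
      dens <- stats::runif(1, 0.1, 0.6)
      m <- matrix(as.integer(stats::runif(32 * 32) < dens), 32, 32)
      for (conn in c(8, 4)) {
        got <- count_puncta(m, min_area = 1, connectivity = conn)
        expect_equal(nrow(got), flood_fill_components(m, conn))
        expect_equal(sort(got$area), flood_fill_sizes(m, conn))
      }
    }
  })
})

test_that("diagonal blobs merge under 8- but not 4-connectivity", {
  m <- matrix(0L, 4, 4)
  m[1, 1] <- 1L; m[2, 2] <- 1L
  expect_equal(nrow(count_puncta(m, min_area = 1, connectivity = 8)), 1L)
  expect_equal(nrow(count_puncta(m, min_area = 1, connectivity = 4)), 2L)
})

test_that("pure scenes drive the binary mask to its floor and ceiling", {
  p <- reference_probe()
  curve <- noiseless_curve(p)
  ext_cfg <- tissue_scene_config(shape = c(64, 64), f_target = 0,
                                 n_puncta = 0, n_vessels = 1)
  gate <- suggest_min_denominator(2)  # Poisson + read-noise aware gate
  ext <- gen_tissue_image(ext_cfg, p, seed = 2)
  res <- ratio_image(ext, 0, gate, bounds = norm_bounds(curve))
  mask <- binarize_ratio(res)
  expect_lte(mean(mask[res$valid_mask]), 0.01)

  endo_cfg <- tissue_scene_config(shape = c(64, 64), f_target = 1,
                                  n_puncta = 25, n_vessels = 0)
  endo <- gen_tissue_image(endo_cfg, p, seed = 2)
  res2 <- ratio_image(endo, 0, gate, bounds = norm_bounds(curve))
  mask2 <- binarize_ratio(res2)
  expect_gte(mean(mask2[res2$valid_mask]), 0.99)
})

test_that("region estimates hit pure-compartment extremes", {
  p <- reference_probe()
  curve <- noiseless_curve(p)
  ext <- gen_tissue_image(
    tissue_scene_config(f_target = 0, n_puncta = 0, n_vessels = 0), p, seed = 9)
  f_ext <- region_endocytosis(ext, ext$truth_labels == "extracellular",
                              curve, 0, 1)$f_hat
  expect_lte(f_ext, 0.02)
  endo <- gen_tissue_image(
    tissue_scene_config(f_target = 1, n_puncta = 40, n_vessels = 0), p, seed = 9)
  f_endo <- region_endocytosis(endo, endo$truth_labels == "intracellular",
                               curve, 0, 1)$f_hat
  expect_gte(f_endo, 0.98)
})

test_that("a zero-noise, zero-blur scene is recovered almost exactly", {
  p <- reference_probe()
  curve <- noiseless_curve(p)
  cfg <- tissue_scene_config(psf_sigma = 0, shot_noise = FALSE,
                             read_noise_sd = 0, endosome_ph_sd = 0,
                             extracellular_ph_sd = 0)
  img <- gen_tissue_image(cfg, p, seed = 1)
  roi <- matrix(TRUE, nrow(img$ch_off_on), ncol(img$ch_off_on))
  f_hat <- region_endocytosis(img, roi, curve, 0, 1e-9)$f_hat
  expect_lt(abs(f_hat - attr(img, "f_true")), 1e-3)
})

test_that("region estimates are nearly unbiased across internalized fractions", {
  p <- reference_probe()
  curve <- noiseless_curve(p)
  roi <- matrix(TRUE, 96, 96)
  for (f in c(0.05, 0.2)) {
    est <- vapply(1:8, function(s) {
      img <- gen_tissue_image(tissue_scene_config(f_target = f), p,
                              seed = 100 * f + s)
      region_endocytosis(img, roi, curve, 0, 1)$f_hat
    }, numeric(1))
    expect_lt(abs(mean(est) - f), 0.02)
  }
})

test_that("tumour-to-normal contrast is a ratio of ROI means", {
  img <- birn_image(matrix(c(rep(30, 8), rep(10, 8)), 4, 4),
                    matrix(1, 4, 4))
  tum <- matrix(c(rep(TRUE, 8), rep(FALSE, 8)), 4, 4)
  expect_equal(tn_contrast(img, tum, !tum, "off_on"), 3)
  expect_equal(tn_contrast(img, tum, tum, "off_on"), 1)
  dark <- birn_image(matrix(0, 4, 4), matrix(1, 4, 4))
  expect_error(tn_contrast(dark, tum, !tum, "off_on"),
               class = "birn_error_degenerate")
})

test_that("synthetic scenes reproduce a generator-set contrast", {
  # build a two-compartment contrast directly: tumour region at 4x the
  # normal-region probe density
  p <- reference_probe()
  img <- gen_tissue_image(
    tissue_scene_config(shape = c(48, 48), f_target = 0, n_puncta = 0,
                        n_vessels = 0), p, seed = 5)
  contrast <- 4
  boosted <- img$ch_always_on
  boosted[, 1:24] <- boosted[, 1:24] * contrast
  img2 <- birn_image(img$ch_off_on, boosted)
  tum <- matrix(FALSE, 48, 48); tum[, 1:24] <- TRUE
  got <- tn_contrast(img2, tum, !tum, "always_on")
  expect_equal(got, contrast, tolerance = 0.05)
})
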