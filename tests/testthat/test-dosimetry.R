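test_that("fluorometry conversion follows the %ID/g arithmetic", {
  curve <- list(slope = 100, intercept = 0, r = 1)
  # intensity at the intercept reads zero dose
  expect_equal(
    accumulation_from_fluorometry(curve, 0, 1, 0.2, 400)$pct_id_g, 0)
  # 6.96 ug recovered in a 0.2 g tumour after a 400 ug injection
  got <- accumulation_from_fluorometry(curve, 6.96 * 100, 1, 0.2, 400)
  expect_equal(got$pct_id_g, 100 * 6.96 / (400 * 0.2))
  # 1.392 ug recovered -> the characteristic 1.74 %ID/g tumour level
  expect_equal(
    accumulation_from_fluorometry(curve, 1.392 * 100, 1, 0.2, 400)$pct_id_g,
    1.74)
  # doubling the tissue mass halves the per-gram dose
  a1 <- accumulation_from_fluorometry(curve, 500, 1, 0.2, 400)$pct_id_g
  a2 <- accumulation_from_fluorometry(curve, 500, 1, 0.4, 400)$pct_id_g
  expect_equal(a1, 2 * a2)
  # sub-intercept intensities clip to zero with a flag
  below <- accumulation_from_fluorometry(list(slope = 100, intercept = 50, r = 1),
                                         10, 1, 0.2, 400)
  expect_equal(below$pct_id_g, 0)
  expect_true(below$clipped)
})

test_that("fluorometry standards build a gated linear curve", {
  d <- data.frame(conc = c(0, 0.01, 0.05, 0.1, 0.5, 1, 5, 10))
  d$intensity <- 3 + 120 * d$conc
  curve <- build_fluorometry(d)
  expect_equal(curve$slope, 120)
  expect_equal(curve$intercept, 3)
  expect_equal(curve$r, 1)
  d$intensity <- withr::with_seed(1, stats::runif(8, 0, 100))
  expect_error(build_fluorometry(d), class = "birn_error_validation")
})

test_that("internalized dose is the accumulation-fraction product", {
  expect_equal(round(internalized_dose(1.74, 0.155), 2), 0.27)
  expect_equal(internalized_dose(c(1, 2.5), 0), c(0, 0))
  expect_equal(internalized_dose(c(1, 2.5), 1), c(1, 2.5))
  expect_error(internalized_dose(1, 1.2), class = "birn_error_parameter")
  expect_error(internalized_dose(-1, 0.5), class = "birn_error_parameter")
})

test_that("cohort validation enforces conservation and uniqueness", {
  co <- gen_cohort(n_subjects = 12, seed = 3)
  expect_true(all(co$internalized_pct_id_g <= co$accumulation_pct_id_g))
  bad <- co
  bad$subject_id[2] <- bad$subject_id[1]
  expect_error(as_cohort(bad), class = "birn_error_parameter")
  wrong <- as.data.frame(co)
  wrong$internalized_pct_id_g <- wrong$internalized_pct_id_g + 0.5
  expect_error(as_cohort(wrong), class = "birn_error_validation")
})

test_that("median split puts ties low and balances group sizes", {
  co <- gen_cohort(n_subjects = 24, seed = 1)
  s <- stratify(co, scheme = "median_split")
  expect_equal(as.integer(table(s$group)), c(12L, 12L))
  # explicit tiny case: low group is {1, 2}
  tiny <- tibble::tibble(
    subject_id = paste0("S", 1:4),
    accumulation_pct_id_g = c(1, 2, 3, 4),
    endocytosis_fraction = rep(0.2, 4), outcome = 1:4)
  st <- stratify(tiny, key = "accumulation_pct_id_g")
  expect_equal(as.character(st$group), c("low", "low", "high", "high"))
  # odd n: ceiling(n/2) subjects go low
  odd <- gen_cohort(n_subjects = 9, seed = 2)
  expect_equal(as.integer(table(stratify(odd)$group)), c(5L, 4L))
})

test_that("terciles split 15 subjects into 5/5/5 and put remainders low", {
  co <- gen_cohort(n_subjects = 15, seed = 4)
  s <- stratify(co, scheme = "terciles")
  expect_equal(as.integer(table(s$group)), c(5L, 5L, 5L))
  co16 <- gen_cohort(n_subjects = 16, seed = 4)
  expect_equal(as.integer(table(stratify(co16, scheme = "terciles")$group)),
               c(6L, 5L, 5L))
})

test_that("stratification is deterministic and rejects degenerate keys", {
  co <- gen_cohort(n_subjects = 10, seed = 6)
  expect_identical(stratify(co)$group, stratify(co)$group)
  flat <- tibble::tibble(
    subject_id = paste0("S", 1:4),
    accumulation_pct_id_g = rep(1, 4),
    endocytosis_fraction = rep(0.2, 4), outcome = 1:4)
  expect_error(stratify(flat, key = "accumulation_pct_id_g"),
               class = "birn_error_degenerate")
})

test_that("correlation recovers exact linear relations", {
  x <- seq(1, 24)
  r1 <- correlate(x, 2 * x + 1)
  expect_equal(r1$r, 1)
  expect_lt(r1$p, 1e-12)
  expect_equal(r1$slope, 2)
  expect_equal(r1$intercept, 1)
  expect_equal(correlate(x, -x)$r, -1)
  expect_equal(correlate(x, 0.5 * x + 3)$r, 1)
  expect_error(correlate(x, rep(1, 24)), class = "birn_error_degenerate")
  expect_error(correlate(1:3, 1:4), class = "birn_error_parameter")
})

test_that("independent Gaussians rarely reach the observed correlation", {
  hits <- withr::with_seed(99, {
    vapply(1:1000, function(i) {
      abs(cor(rnorm(24), rnorm(24))) >= 0.86
    }, logical(1))
  })
  expect_lt(mean(hits), 0.001 + 1e-9)
})

test_that("group comparison is a Welch test with location invariance", {
  co <- gen_cohort(n_subjects = 24, seed = 8)
  s <- stratify(co)
  res <- compare_groups(s)
  shifted <- s
  shifted$outcome <- shifted$outcome + 100
  res2 <- compare_groups(shifted)
  expect_equal(res$statistic, res2$statistic)
  expect_equal(res$p_value, res2$p_value)
  expect_equal(res2$difference, res$difference)

  # identical groups: zero difference, p = 1
  same <- tibble::tibble(
    subject_id = paste0("S", 1:8),
    accumulation_pct_id_g = rep(c(1, 1.5, 2, 2.5), 2),
    endocytosis_fraction = rep(0.2, 8),
    outcome = rep(c(10, 20, 30, 40), 2),
    group = factor(rep(c("low", "high"), each = 4), c("low", "high")))
  res3 <- compare_groups(same)
  expect_equal(res3$difference, 0)
  expect_equal(res3$p_value, 1)

  # well-separated groups are detected decisively
  sep <- withr::with_seed(5, tibble::tibble(
    subject_id = paste0("S", 1:24),
    accumulation_pct_id_g = rep(1, 24),
    endocytosis_fraction = rep(0.2, 24),
    outcome = c(rnorm(12, 0, 1), rnorm(12, 5, 1)),
    group = factor(rep(c("low", "high"), each = 12), c("low", "high"))))
  expect_lt(compare_groups(sep)$p_value, 0.001)
})
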