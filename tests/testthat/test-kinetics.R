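test_that("mono-exponential fits round-trip noiseless data", {
  tc <- gen_pulse_chase(t_half = 10, plateau = 1,
                        timepoints = seq(0, 60, by = 5), noise = 0, seed = 1)
  fit <- fit_internalization(tc)
  expect_equal(fit$t_half, 10, tolerance = 1e-9)
  expect_equal(fit$plateau, 1, tolerance = 1e-9)
  expect_equal(fit$t_half * fit$k, log(2), tolerance = 1e-12)
  expect_gte(fit$goodness, 1 - 1e-10)
  # empirical 50%-crossing readout agrees on clean data
  expect_equal(fit$t_half_empirical, 10, tolerance = 0.2)
})

test_that("the half-time identity holds for every fit", {
  for (s in 1:5) {
    tc <- gen_pulse_chase(t_half = 5 + 3 * s, plateau = 0.9,
                          timepoints = seq(0, 120, by = 10),
                          noise = 0.05, seed = s)
    fit <- fit_internalization(tc)
    expect_equal(fit$t_half * fit$k, log(2), tolerance = 1e-12)
    expect_lte(fit$plateau, 1)
  }
})

test_that("short sampling spans trigger the identifiability warning", {
  tc <- gen_pulse_chase(t_half = 60, plateau = 1,
                        timepoints = seq(0, 50, by = 10), noise = 0, seed = 1)
  expect_warning(fit_internalization(tc),
                 class = "birn_warning_identifiability")
  # a span of many half-times fits silently
  tc2 <- gen_pulse_chase(t_half = 10, plateau = 1,
                         timepoints = seq(0, 60, by = 10), noise = 0, seed = 1)
  expect_silent(fit_internalization(tc2))
})

test_that("linear (curvature-free) data trigger the degeneracy warning", {
  d <- data.frame(time = seq(0, 50, by = 10),
                  value = seq(0, 50, by = 10) * 0.004)
  # linear data also leave the rate unidentifiable, so both warnings fire
  expect_warning(
    expect_warning(fit_internalization(time_course(d, "internalization")),
                   class = "birn_warning_degenerate"),
    class = "birn_warning_identifiability")
})

test_that("fits recover half-times under realistic noise", {
  est <- vapply(1:30, function(s) {
    tc <- gen_pulse_chase(t_half = 11.89, plateau = 1,
                          timepoints = seq(0, 60, length.out = 12),
                          replicates = 3, noise = 0.05, seed = s)
    fit_internalization(tc)$t_half
  }, numeric(1))
  expect_lt(abs(median(est) / 11.89 - 1), 0.1)
})

test_that("cell-line half-time ordering survives simulation and refit", {
  half_times <- c(A549 = 11.89, `4T1` = 13.81, BxPC3 = 9.79,
                  Panc02 = 7.73, MCF7 = 7.13)
  hits <- vapply(1:40, function(s) {
    refit <- vapply(half_times, function(th) {
      tc <- gen_pulse_chase(t_half = th, plateau = 1,
                            timepoints = seq(0, 60, by = 5),
                            replicates = 3, noise = 0.05,
                            seed = s * 1000 + round(th * 100))
      fit_internalization(tc)$t_half
    }, numeric(1))
    identical(order(refit), order(half_times))
  }, logical(1))
  expect_gte(mean(hits), 0.95)
})

test_that("first-order release obeys its closed form and invariants", {
  expect_equal(release_fraction(4.52, 4.52), 0.5)
  expect_equal(release_fraction(4.52, 24), 1 - 2^(-24 / 4.52))
  expect_equal(release_fraction(4.52, 24), 0.9748, tolerance = 1e-4)
  expect_gt(release_fraction(4.52, 24), 0.90)
  expect_identical(release_fraction(3, 0), 0)
  t <- seq(0, 48, by = 0.5)
  r <- release_fraction(4.52, t)
  expect_true(all(diff(r) > 0))
  # survival halves exactly every half-time
  expect_equal((1 - release_fraction(4.52, t + 4.52)) /
                 (1 - release_fraction(4.52, t)),
               rep(0.5, length(t)))
})

test_that("4PL dose-response fits round-trip and honour the midpoint", {
  conc <- 10^seq(-3, 1.5, length.out = 9)
  viability <- 0 + (1 - 0) / (1 + 10^(1 * (log10(conc) - log10(1.25))))
  fit <- fit_dose_response(data.frame(conc = conc, viability = viability))
  expect_equal(fit$ic50, 1.25, tolerance = 1e-6)
  expect_equal(fit$hill, 1, tolerance = 1e-6)
  v_at_ic50 <- fit$bottom + (fit$top - fit$bottom) / 2
  model_at_ic50 <- fit$bottom + (fit$top - fit$bottom) /
    (1 + 10^(fit$hill * (log10(fit$ic50) - log10(fit$ic50))))
  expect_equal(model_at_ic50, v_at_ic50, tolerance = 1e-9)
})

test_that("4PL fitting rejects inadequate designs", {
  conc <- 10^seq(-3, 1.5, length.out = 4)
  v <- 1 / (1 + conc / 1.25)
  expect_error(fit_dose_response(data.frame(conc = conc, viability = v)),
               class = "birn_error_precondition")
  # all concentrations far below the IC50: no transition covered
  conc2 <- 10^seq(-5, -3, length.out = 6)
  v2 <- 1 / (1 + conc2 / 1.25)
  expect_error(fit_dose_response(data.frame(conc = conc2, viability = v2)),
               class = "birn_error_precondition")
})

test_that("noisy dose-response data recover the IC50 within 15%", {
  conc <- rep(10^seq(-2.5, 1.5, length.out = 8), each = 6)
  est <- vapply(1:30, function(s) {
    v <- withr::with_seed(s, {
      mu <- 1 / (1 + 10^(log10(conc) - log10(1.25)))
      pmin(pmax(mu * (1 + 0.05 * rnorm(length(conc))), 0), 1.05)
    })
    fit_dose_response(data.frame(conc = conc, viability = v))$ic50
  }, numeric(1))
  expect_lt(abs(median(est) / 1.25 - 1), 0.15)
})

test_that("potency decrease is the relative IC50 shift in percent", {
  expect_equal(potency_decrease(1, 1), 0)
  expect_equal(potency_decrease(1, 10), 90)
  expect_equal(potency_decrease(1.25, 12.87), 90.3, tolerance = 1e-3)
  expect_error(potency_decrease(10, 1), class = "birn_error_sign")
})
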