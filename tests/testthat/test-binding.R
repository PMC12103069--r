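# Fraction bound, isotherm fitting and fold changes

test_that("fraction bound solves the mass-action equilibrium exactly", {
  expect_equal(fraction_bound(0, 1e-8, 1e-6), 0)
  # negligible depletion at l = kd gives half-saturation
  expect_equal(fraction_bound(1e-6, 1e-12, 1e-6), 0.5, tolerance = 1e-3)

  set.seed(8)
  for (rep in 1:40) {
    l <- 10^runif(1, -9, -3)
    r <- 10^runif(1, -10, -5)
    kd <- 10^runif(1, -9, -4)
    expect_equal(fraction_bound(l, r, kd), bisect_fraction_bound(l, r, kd),
                 tolerance = 1e-10)
  }
  expect_error(fraction_bound(-1e-9, 1e-8, 1e-6), ">= 0")
  expect_error(fraction_bound(1e-9, 0, 1e-6), "> 0")
})

test_that("fraction bound is monotone in ligand and antitone in Kd", {
  l_grid <- 10^seq(-9, -3, length.out = 60)
  kd_grid <- 10^seq(-8, -4, length.out = 25)
  for (kd in c(1e-7, 1e-5)) {
    f <- fraction_bound(l_grid, 1e-8, kd)
    expect_true(all(diff(f) >= 0))
  }
  for (l in c(1e-7, 1e-5)) {
    f <- vapply(kd_grid, function(kd) fraction_bound(l, 1e-8, kd),
                numeric(1))
    expect_true(all(diff(f) <= 0))
  }
  # depletion limit: r -> 0 recovers the hyperbola l / (l + kd)
  kd <- 2e-6
  l <- 10^seq(-8, -4, length.out = 30)
  f <- fraction_bound(l, kd * 1e-6, kd)
  expect_equal(f, l / (l + kd), tolerance = 1e-3)
})

test_that("serial dilutions are geometric", {
  expect_equal(serial_dilution(16, 5, 2), c(16, 8, 4, 2, 1))
  s <- serial_dilution(1e-4, 16, 2)
  expect_equal(s[16], 1e-4 / 32768)
  expect_true(all(diff(s) < 0))
  expect_equal(s[-16] / s[-1], rep(2, 15), tolerance = 1e-12)
  expect_error(serial_dilution(1, 16, 1), "factor")
})

test_that("fraction-bound transformation inverts the forward model", {
  ts <- simulate_titration(4.2e-6, noise_pct = 0, seed = 1)
  fit <- fit_isotherm(ts, n_boot = 0)
  fb <- to_fraction_bound(ts, fit)
  expect_equal(fb, fraction_bound(ts$ligand_conc, ts$receptor_conc, 4.2e-6),
               tolerance = 1e-9)

  flat <- fit
  flat$baseline <- 1000
  flat$amplitude <- 300
  ts_base <- ts
  ts_base$signal <- rep(1000, 16)
  expect_equal(to_fraction_bound(ts_base, flat), rep(0, 16))
  ts_top <- ts
  ts_top$signal <- rep(1300, 16)
  expect_equal(to_fraction_bound(ts_top, flat), rep(1, 16))
  flat$amplitude <- 0
  expect_error(to_fraction_bound(ts, flat), "amplitude")
})

test_that("noiseless titrations are recovered to numerical precision", {
  for (kd in c(8e-8, 4.2e-6, 2.6e-5)) {
    ts <- simulate_titration(kd, noise_pct = 0, seed = 2)
    fit <- fit_isotherm(ts, n_boot = 0)
    expect_equal(fit$kd, kd, tolerance = 1e-6)
    expect_equal(fit$baseline, 1000, tolerance = 1e-6)
    expect_equal(fit$amplitude, 300, tolerance = 1e-6)
    expect_true(fit$converged)
  }
})

test_that("log-Kd bias shrinks as noise shrinks", {
  kd <- 4.2e-6
  bias <- vapply(c(0.08, 0.02, 0.005), function(noise) {
    lk <- vapply(1:40, function(i) {
      ts <- simulate_titration(kd, noise_pct = noise, seed = 9000 + i)
      log10(fit_isotherm(ts, n_boot = 0, warn_span = FALSE)$kd)
    }, numeric(1))
    abs(mean(lk) - log10(kd))
  }, numeric(1))
  expect_true(all(diff(bias) < 0))
})

test_that("constant signal is flagged unreliable by signal-to-noise", {
  l <- serial_dilution(1e-4, 16, 2)
  set.seed(3)
  ts <- titration_series(l, rnorm(16, 1000, 2))
  fit <- suppressWarnings(fit_isotherm(ts, n_boot = 0, warn_span = FALSE))
  expect_lt(fit$snr, 10)
  expect_false(fit$reliable)

  good <- fit_isotherm(simulate_titration(4.2e-6, seed = 4), n_boot = 0)
  expect_gt(good$snr, 10)
  expect_true(good$reliable)
})

test_that("bootstrap confidence intervals are seeded and reproducible", {
  ts <- simulate_titration(4.2e-6, seed = 5)
  f1 <- fit_isotherm(ts, n_boot = 150, seed = 42)
  f2 <- fit_isotherm(ts, n_boot = 150, seed = 42)
  expect_identical(f1$kd_ci, f2$kd_ci)
  expect_identical(f1$boot_kd, f2$boot_kd)
  f3 <- fit_isotherm(ts, n_boot = 150, seed = 43)
  expect_false(identical(f1$kd_ci, f3$kd_ci))
  expect_true(f1$kd_ci[1] <= f1$kd && f1$kd <= f1$kd_ci[2])
  # the global RNG stream is left untouched
  set.seed(7); before <- rnorm(1)
  set.seed(7); invisible(fit_isotherm(ts, n_boot = 20, seed = 1))
  expect_identical(rnorm(1), before)
})

test_that("Kd recovery at 2% noise keeps the truth inside the bootstrap CI", {
  kd <- 4.2e-6
  hits <- 0
  kds <- numeric(25)
  for (i in 1:25) {
    ts <- simulate_titration(kd, seed = 300 + i)
    fit <- fit_isotherm(ts, n_boot = 200, seed = i)
    kds[i] <- fit$kd
    if (fit$kd_ci[1] <= kd && kd <= fit$kd_ci[2]) hits <- hits + 1
  }
  expect_lt(abs(median(kds) / kd - 1), 0.10)
  expect_gte(hits, 21)     # ~95% nominal coverage, allow sampling slack
})

test_that("fold changes divide fitted Kds with paired bootstrap CIs", {
  ts <- simulate_titration(8e-8, seed = 6)
  fit <- fit_isotherm(ts, n_boot = 100, seed = 2)
  same <- fold_change(fit, fit)
  expect_equal(same$ratio, 1)

  wt <- fit_isotherm(simulate_titration(8e-8, noise_pct = 0), n_boot = 0)
  mut <- fit_isotherm(simulate_titration(6.9e-6, noise_pct = 0), n_boot = 0)
  fc <- fold_change(wt, mut)
  expect_equal(fc$ratio, 86.25, tolerance = 1e-4)
  expect_true(all(is.na(fc$ci)))

  bad <- wt
  bad$converged <- FALSE
  expect_error(fold_change(bad, mut), "converged")
})

test_that("titration CSV input reconstructs replicate series", {
  ts1 <- simulate_titration(1e-6, seed = 7, replicate_id = "r1")
  ts2 <- simulate_titration(1e-6, seed = 8, replicate_id = "r2")
  f <- tempfile(fileext = ".csv")
  write.csv(data.frame(
    replicate_id = rep(c("r1", "r2"), each = 16),
    ligand_conc_molar = c(ts1$ligand_conc, ts2$ligand_conc),
    signal = c(ts1$signal, ts2$signal)), f, row.names = FALSE)
  got <- read_titration_csv(f)
  expect_named(got, c("r1", "r2"))
  expect_equal(got$r1$signal, ts1$signal)
  pooled <- fit_isotherm(got, n_boot = 0)
  expect_equal(pooled$n_points, 32)
  expect_equal(pooled$kd, 1e-6, tolerance = 0.15)
})
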