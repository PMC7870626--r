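test_that("noise-free Hill parameters are recovered essentially exactly", {
  ds <- make_clean_dataset(ec50 = 1e-6, hill = 1.5)
  fit <- fit_hill(ds)
  expect_true(fit$converged)
  expect_lt(abs(fit$ec50 - 1e-6) / 1e-6, 1e-6)
  expect_lt(abs(fit$hill_coef - 1.5) / 1.5, 1e-5)
  expect_equal(fit$top, 100)
  expect_equal(fit$bottom, 0)
})

test_that("flat curves are refused and degenerate input errors", {
  grid <- conc_grid(1e-4, sqrt(10), 6)
  flat <- dr_dataset("c", "V", "LUHMES", rep(grid, each = 3),
                     rep(100, 18))
  fit <- fit_hill(flat)
  expect_false(fit$converged)
  expect_true(fit$flat)
  expect_true(is.na(fit$ec50))
  expect_error(effective_concentration(fit, 25), "UndefinedEC")

  few <- dr_dataset("c", "V", "LUHMES", rep(c(1e-6, 1e-5, 1e-4), each = 3),
                    rep(50, 9))
  expect_error(fit_hill(few), "DegenerateInput")
})

test_that("effective concentrations follow the analytic Hill inversion", {
  ds <- make_clean_dataset(ec50 = 2e-6, hill = 1)
  fit <- fit_hill(ds)
  # midpoint identity
  expect_equal(effective_concentration(fit, 50)$concentration, fit$ec50,
               tolerance = 1e-9)
  # h = 1, x = 25 -> EC50 / 3
  expect_equal(effective_concentration(fit, 25)$concentration, fit$ec50 / 3,
               tolerance = 1e-9)
  # h = 2, x = 10 -> EC50 / 3
  ds2 <- make_clean_dataset(ec50 = 2e-6, hill = 2)
  fit2 <- fit_hill(ds2)
  expect_equal(effective_concentration(fit2, 10)$concentration,
               fit2$ec50 / 3, tolerance = 1e-7)
  # pEC convention
  ec <- effective_concentration(fit, 50)
  expect_equal(ec$pec, -log10(ec$concentration))
})

test_that("analytic ECx agrees with bisection on the fitted curve", {
  set.seed(11)
  for (i in 1:25) {
    ec50 <- 10^runif(1, -8, -4)
    hill <- runif(1, 0.3, 6)
    x <- runif(1, 2, 98)
    fit <- structure(list(ec50 = ec50, hill_coef = hill, top = 100,
                          bottom = 0, converged = TRUE,
                          direction = "decreasing",
                          conc_range = c(1e-12, 1), endpoint = "V",
                          compound_id = "x"),
                     class = "hill_fit")
    analytic <- effective_concentration(fit, x)$concentration
    brute <- ecx_bisect(ec50, hill, x)
    expect_lt(abs(analytic - brute) / brute, 1e-9)
  }
})

test_that("ECx is monotone in x and scale-equivariant", {
  ds <- make_clean_dataset(ec50 = 5e-7, hill = 2.2)
  fit <- fit_hill(ds)
  xs <- c(5, 10, 25, 50, 75, 90)
  ecs <- vapply(xs, function(x)
    effective_concentration(fit, x)$concentration, numeric(1))
  expect_true(all(diff(ecs) > 0))

  k <- 1000
  ds_k <- ds
  ds_k$data$concentration <- ds$data$concentration * k
  fit_k <- fit_hill(ds_k)
  expect_equal(fit_k$ec50, fit$ec50 * k, tolerance = 1e-6)
  expect_equal(effective_concentration(fit_k, 10)$concentration,
               effective_concentration(fit, 10)$concentration * k,
               tolerance = 1e-6)
})

test_that("EC50 recovery under replicate noise meets the accuracy target", {
  # 200 simulated datasets, 8 concentrations, n = 3, 5% noise
  errs <- vapply(1:200, function(i) {
    set.seed(7000 + i)
    ec50 <- 10^runif(1, -7, -5)
    h <- runif(1, 0.8, 3)
    sp <- compound_spec("x", "cI", ec50 = ec50, hill = h,
                        max_test_conc = ec50 * 100)
    ds <- generate_dose_response(sp, "NA", conc_grid(ec50 * 100, sqrt(10), 8),
                                 noise_sd = 5, n_replicates = 3,
                                 seed = 7000 + i)
    abs(log10(fit_hill(ds)$ec50 / ec50))
  }, numeric(1))
  expect_lt(median(errs), 0.1)
})

test_that("benchmark concentration matches the analytic ECx when noise-free", {
  ds <- make_clean_dataset(ec50 = 1e-6, hill = 1)
  b <- benchmark_concentration(ds, benchmark_response = 10,
                               n_bootstrap = 50, seed = 1)
  expect_equal(b$bmc, 1e-6 * (10 / 90), tolerance = 1e-6)
  # noise-free resamples are all identical: CI collapses onto the estimate
  expect_lt(b$ci_upper / b$ci_lower - 1, 1e-6)
  # the point estimate is seed-free
  b2 <- benchmark_concentration(ds, benchmark_response = 10,
                                n_bootstrap = 50, seed = 99)
  expect_identical(b$bmc, b2$bmc)
})

test_that("bootstrap CIs from different seeds agree to Monte Carlo accuracy", {
  sp <- compound_spec("demo", "cI", ec50 = 1e-6, hill = 1.5,
                      max_test_conc = 1e-4)
  ds <- generate_dose_response(sp, "NA", noise_sd = 5, seed = 5)
  b1 <- benchmark_concentration(ds, 10, n_bootstrap = 400, seed = 1)
  b2 <- benchmark_concentration(ds, 10, n_bootstrap = 400, seed = 2)
  expect_identical(b1$bmc, b2$bmc)
  expect_lt(abs(log10(b1$ci_lower / b2$ci_lower)), 0.1)
  expect_lt(abs(log10(b1$ci_upper / b2$ci_upper)), 0.1)
})

test_that("potency shifts are linear-scale fold changes", {
  mk <- function(conc) structure(list(x = 25, concentration = conc,
                                      pec = -log10(conc),
                                      extrapolated = FALSE),
                                 class = "ec_estimate")
  expect_equal(potency_shift(mk(1e-5), mk(1e-5)), 1)
  expect_equal(potency_shift(mk(1e-5), mk(1e-6)), 10)
  # pEC 6 vs pEC 7 is a 10-fold shift
  expect_equal(potency_shift(mk(10^-6), mk(10^-7)), 10)
  bad <- mk(NA_real_)
  expect_error(potency_shift(bad, mk(1e-6)), "UndefinedEC")
})
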