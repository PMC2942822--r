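topo <- build_topology()
truth <- diet_parameters("adequate")$best_fit

# small shared fixtures: noise-free and noisy synthetic datasets
noisefree <- generate_dataset(
  truth, study_design(cv = 0, seed = 1), dose_jitter = 0,
  normalize = FALSE)$dataset

test_that("weighted_distance evaluates the stated criterion", {
  tr <- simulate_tracer(topo, truth, sort(unique(noisefree$time)))
  ds <- floor_sd(noisefree)
  d <- weighted_distance(ds, tr)
  expect_equal(d$fval_chi_sqr, 0, tolerance = 1e-12)
  expect_equal(d$fit_quality, 0, tolerance = 1e-12)

  # single point: mean 10, sd 2, pred 12 -> (12-10)^2 / 2 = 2
  one <- tracer_dataset(data.frame(organ = "liver", time = 1, mean = 10,
                                   sd = 2, n = 3))
  fake <- structure(list(times = 1,
                         content = matrix(12, 1, 1,
                                          dimnames = list("liver", NULL)),
                         external_loss = 0), class = "fk_trajectory")
  d1 <- weighted_distance(one, fake)
  expect_equal(d1$fval_chi_sqr, 2)
  expect_equal(d1$fit_quality, sqrt(2))

  # doubling every SD halves the criterion (inverse-SD weighting)
  two <- one
  two$sd <- 4
  expect_equal(weighted_distance(two, fake)$fval_chi_sqr, 1)
  # inverse-variance mode divides by sd^2 instead
  expect_equal(weighted_distance(one, fake, weighting = "var")$fval_chi_sqr,
               1)
  # missing prediction is an error
  miss <- tracer_dataset(data.frame(organ = "kidney", time = 1,
                                    mean = 1, sd = 1, n = 3))
  expect_error(weighted_distance(miss, fake), "lacks predictions")
})

test_that("criterion at the truth never increases when adding an exact point", {
  times <- sort(unique(noisefree$time))
  tr <- simulate_tracer(topo, truth, times)
  ds <- floor_sd(noisefree)
  base_rows <- ds[ds$organ != "heart" | ds$time != times[3], ]
  base <- floor_sd(tracer_dataset(base_rows))
  extra <- floor_sd(tracer_dataset(ds))
  expect_lte(weighted_distance(base, tr)$fval_chi_sqr,
             weighted_distance(extra, tr)$fval_chi_sqr + 1e-12)
})

test_that("sd flooring gives every observation a positive weight", {
  ds <- floor_sd(noisefree, frac = 0.01)
  expect_true(all(ds$sd > 0))
  for (org in unique(ds$organ)) {
    mx <- max(noisefree$mean[noisefree$organ == org], 0.01)
    expect_true(all(ds$sd[ds$organ == org] >= 0.01 * mx - 1e-12))
  }
})

test_that("fit with all parameters fixed evaluates without searching", {
  fit <- fit_rates(noisefree, fixed = truth, seed = 1)
  expect_identical(fit$n_starts, 0L)
  expect_equal(fit$rates, truth)
  tr <- simulate_tracer(topo, truth, sort(unique(noisefree$time)))
  expect_equal(fit$fval_chi_sqr,
               weighted_distance(floor_sd(noisefree), tr)$fval_chi_sqr,
               tolerance = 1e-10)
})

test_that("fitting enforces the plasma-clearance constraint exactly and is seeded", {
  # tiny search budget: this block checks the contract, not accuracy
  fit <- fit_rates(noisefree, n_starts = 1, seed = 42, maxit = 15,
                   polish = FALSE)
  expect_equal(total_plasma_clearance(fit$rates), 20, tolerance = 1e-9)
  expect_true(all(fit$rates >= 0))
  fit2 <- fit_rates(noisefree, n_starts = 1, seed = 42, maxit = 15,
                    polish = FALSE)
  expect_identical(fit$rates, fit2$rates)
  expect_identical(fit$fval_chi_sqr, fit2$fval_chi_sqr)
})

test_that("fit validates inputs", {
  expect_error(fit_rates(noisefree, total_clearance = -1), "> 0")
  short <- tracer_dataset(noisefree[noisefree$organ != "liver", ])
  expect_error(fit_rates(short), "coverage")
  expect_error(fit_rates(noisefree, fixed = c(bogus = 1)), "unknown")
  expect_error(fit_rates(noisefree, n_starts = 0, informed_start = FALSE),
               "no starting point")
})

test_that("resampling preserves SD=0 cells and validates n_replicates", {
  expect_error(resample_fit(noisefree, n_replicates = 1), ">= 2")
  # with SD == 0 everywhere the replicates equal the original data, so
  # every replicate fit reproduces the point fit (all-fixed: no search)
  ens <- resample_fit(noisefree, n_replicates = 2, seed = 1,
                      fixed = truth)
  expect_identical(nrow(ens$estimates), 2L)
  for (f in ens$fits) expect_equal(f$rates, ens$point$rates)
})

test_that("sextile bounds follow the documented quantile convention", {
  est <- matrix(1:6, ncol = 1, dimnames = list(NULL, "k"))
  b <- parameter_bounds(est)
  # brute-force type-7 quantiles of {1..6} at 1/6 and 5/6
  expect_equal(b$lower, unname(quantile(1:6, 1 / 6, type = 7)))
  expect_equal(b$upper, unname(quantile(1:6, 5 / 6, type = 7)))

  same <- matrix(2.5, nrow = 4, ncol = 1, dimnames = list(NULL, "k"))
  bs <- parameter_bounds(same)
  expect_equal(bs$lower, 2.5)
  expect_equal(bs$upper, 2.5)
})

test_that("end-to-end fit on noisy synthetic data recovers the marrow share", {
  # the stated experimental world: 8 timepoints, 5 animals, 30% CV
  des <- study_design(n_animals = 5, cv = 0.30, seed = 1)
  g <- generate_dataset(truth, des)
  fit <- fit_rates(g$dataset, n_starts = 1, seed = 1, maxit = 120)
  est <- plasma_shares(fit$rates)[["bone_marrow"]]
  gen <- plasma_shares(truth)[["bone_marrow"]]
  expect_lt(abs(est - gen), 0.05)  # within 5 percentage points
})

test_that("the point fit lies inside its own resampled sextile bounds", {
  # scaled down from the full 200-replicate procedure to stay inside the
  # test budget; self-consistency of the uncertainty machinery does not
  # depend on the replicate count
  des <- study_design(n_animals = 5, cv = 0.30, seed = 2)
  g <- generate_dataset(truth, des)
  ens <- resample_fit(g$dataset, n_replicates = 12, seed = 2,
                      n_starts = 1, maxit = 60)
  b <- parameter_bounds(ens)
  point <- ens$point$rates[b$param]
  inside <- point >= b$lower - 1e-9 & point <= b$upper + 1e-9
  expect_gte(mean(inside), 0.8)
})

test_that("sextile width approaches 1.93 sigma for Gaussian estimates", {
  set.seed(99)
  sigma <- 0.7
  est <- matrix(rnorm(20000, 3, sigma), ncol = 1,
                dimnames = list(NULL, "k"))
  b <- parameter_bounds(est)
  width <- b$upper - b$lower
  expect_equal(width, (qnorm(5 / 6) - qnorm(1 / 6)) * sigma,
               tolerance = 0.03)
  expect_equal(width / sigma, 1.93, tolerance = 0.03)
})
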