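test_that("generators are pure functions of their seed", {
  dr <- default_dr()
  a <- make_dose_response_observations(dr, cv = 0.05, seed = 42)
  b <- make_dose_response_observations(dr, cv = 0.05, seed = 42)
  c <- make_dose_response_observations(dr, cv = 0.05, seed = 43)
  expect_identical(a$observed, b$observed)
  expect_false(identical(a$observed, c$observed))
  expect_identical(a$truth, c$truth)  # no noise leakage into the truth
  # the caller's RNG state is untouched
  set.seed(7); before <- .Random.seed
  invisible(make_dose_response_observations(dr, cv = 0.1, seed = 1))
  expect_identical(.Random.seed, before)

  t1 <- make_wildtype_timecourse(seed = 9)
  t2 <- make_wildtype_timecourse(seed = 9)
  expect_identical(t1, t2)
})

test_that("noise-free observations reproduce the deterministic truth", {
  dr <- default_dr()
  obs <- make_dose_response_observations(dr, cv = 0, seed = 1)
  expect_identical(obs$observed, obs$truth)
  expect_equal(goodness_of_agreement(obs$observed, obs$truth), 0)
  expect_equal(obs$truth, unname(dr$derived[, "total_KinA"]))

  tc <- make_wildtype_timecourse(sigma = 0, seed = 1)
  a <- subset(tc, species == "Spo0A")
  f <- linear_fit(a$time, a$observed)
  expect_equal(f$slope, 0.25)
  expect_equal(f$intercept, 0)
  expect_equal(f$r_squared, 1)
})

test_that("the mean relative distance of noisy replicates matches its closed form", {
  # for multiplicative noise o = m (1 + cv Z), the distance is mean |cv Z|
  # with expectation cv sqrt(2/pi)
  dr <- default_dr()
  cv <- 0.05
  n_seeds <- 200
  d <- vapply(seq_len(n_seeds), function(s) {
    obs <- make_dose_response_observations(dr, cv = cv, seed = s)
    goodness_of_agreement(obs$observed, obs$truth)
  }, numeric(1))
  expected <- cv * sqrt(2 / pi)
  se <- cv * sqrt((1 - 2 / pi) / (length(dr$grid) * n_seeds))
  expect_lt(abs(mean(d) - expected), 3 * se)
})

test_that("synthetic wild-type courses give the intended R^2 regime", {
  # sigma chosen from the closed-form signal/noise split for E[R^2] ~ 0.95
  # on the default Spo0A slope and grid
  t_grid <- seq(0, 150, by = 10)
  sig_var <- 0.25^2 * mean((t_grid - mean(t_grid))^2)
  sigma <- sqrt(sig_var * 0.05 / 0.95)
  r2 <- vapply(1:50, function(s) {
    tc <- make_wildtype_timecourse(slopes = c(Spo0A = 0.25),
                                   intercepts = c(Spo0A = 0),
                                   sigma = sigma, t_grid = t_grid, seed = s)
    linear_fit(tc$time, tc$observed)$r_squared
  }, numeric(1))
  expect_gt(median(r2), 0.9)
  expect_lt(median(r2), 0.99)
  expect_gt(min(r2), 0.85)
})

test_that("identifiable parameters are recovered from noisy observations", {
  m <- default_model()
  # noiseless single-parameter refit from a doubled starting point
  rec0 <- parameter_recovery_study(m, "tl2.k", cv = 0, seed = 1, n_rep = 1,
                                   grid = seq(0, 20, length.out = 5))
  expect_true(all(rec0$converged))
  expect_lt(rec0$rel_error, 0.01)
})

test_that("a structurally non-identifiable pair is recovered only as a product", {
  m <- default_model()
  # tr4.k and tl4.k enter steady-state Spo0B only via their product with the
  # turnover constants, so the joint refit pins the product, not the factors
  rec <- parameter_recovery_study(m, c("tr4.k", "tl4.k"), cv = 0.02,
                                  seed = 2, n_rep = 1,
                                  grid = c(0, 10, 20), form = "total_Spo0B")
  prod_true <- prod(rec$true)
  prod_rec <- prod(rec$recovered)
  expect_lt(abs(prod_rec - prod_true) / prod_true, 0.05)
  expect_gt(max(rec$rel_error), 0.2)
})
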