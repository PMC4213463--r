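test_that("the goodness-of-agreement metric matches hand arithmetic", {
  expect_equal(goodness_of_agreement(c(3, 7, 11), c(3, 7, 11)), 0)
  expect_equal(goodness_of_agreement(c(1, 2), c(1.1, 1.8)), 0.10)
  expect_equal(goodness_of_agreement(2, 0), 1.0)
  expect_error(goodness_of_agreement(c(1, 0), c(1, 1)), "positive")
  expect_error(goodness_of_agreement(c(1, 2), 1), "equal-length")
})

test_that("dose-response scans reduce to steady states and respond monotonically", {
  m <- default_model()
  single <- dose_response(m, "IPTG", grid = 7)
  direct <- steady_state(m, iptg = 7)
  expect_equal(single$states[1, ], direct$state, tolerance = 1e-8)

  dr <- default_dr()
  for (f in c("KinA2P", "Spo0FP", "Spo0AP", "total_KinA")) {
    series <- if (f %in% colnames(dr$derived)) dr$derived[, f] else dr$states[, f]
    expect_false(is.unsorted(series), label = paste(f, "non-decreasing"))
  }
  # warm-started scans show no hysteresis against a cold start
  expect_lt(dr$hysteresis, 1e-4)

  # the signal-driven arm responds near-linearly at fixed zero induction
  drs <- dose_response(m, "SS", grid = seq(0, 2, length.out = 9))
  k2p <- drs$states[, "KinA2P"]
  expect_false(is.unsorted(k2p))
  mid <- (k2p[1] + k2p[9]) / 2
  expect_equal(k2p[5], mid, tolerance = 0.15)
})

test_that("steady-state panels show weak basal and induced activation", {
  panel <- cached("panel", steady_state_panel(default_model()))
  expect_identical(rownames(panel$phospho),
                   c("KinA2P", "Spo0FP", "Spo0BP", "Spo0AP"))
  # weak basal activation: all effectors present without induction
  expect_true(all(panel$effectors[, "IPTG=0"] > 0))
  # induction raises every effector and every phospho-form
  expect_true(all(panel$effectors[, "IPTG=10"] >=
                    panel$effectors[, "IPTG=0"]))
  expect_true(all(panel$phospho[, "IPTG=20"] > panel$phospho[, "IPTG=0"]))
})

test_that("the feedback knockout attenuates but preserves the response", {
  m <- default_model()
  ko <- feedback_knockout(m)
  expect_identical(feedback_knockout(ko)$params, ko$params)
  dr <- default_dr()
  drk <- cached("dr_ko", dose_response(ko, "IPTG"))
  # reduced intensity at every grid point
  expect_true(all(drk$states[, "KinA2P"] < dr$states[, "KinA2P"]))
  # but qualitatively the same induced activation
  a <- drk$states[, "Spo0AP"]
  expect_false(is.unsorted(a))
  expect_gt(a[21] / a[1], 5)
})

test_that("refitting the repression parameters against the intact model recovers them", {
  m <- default_model()
  ref <- dose_response(m, "IPTG", grid = seq(0, 20, length.out = 7))
  fit <- compensate_repression_params(ref, m)
  expect_equal(fit$k2, m$params[["tr2.k2"]], tolerance = 1e-2)
  expect_equal(fit$KL, m$params[["tr2.KL"]], tolerance = 1e-2)
  expect_lt(fit$distance, 1e-4)
})

test_that("ordinary least squares fits report slope, intercept and R^2", {
  f <- linear_fit(1:10, 3 + 2 * (1:10))
  expect_equal(f$slope, 2)
  expect_equal(f$intercept, 3)
  expect_equal(f$r_squared, 1)

  tc <- make_wildtype_timecourse(slopes = c(X = 0), intercepts = c(X = 5),
                                 sigma = 1, t_grid = seq(0, 99, by = 1),
                                 seed = 11)
  f0 <- linear_fit(tc$time, tc$observed)
  expect_lt(f0$r_squared, 0.1)
  expect_lt(abs(f0$slope), 3 * f0$slope_se)

  tc2 <- make_wildtype_timecourse(seed = 3)
  a <- subset(tc2, species == "Spo0A")
  fa <- linear_fit(a$time, a$observed)
  expect_lt(abs(fa$slope - 0.25), 3 * fa$slope_se)

  expect_warning(fz <- linear_fit(1:5, rep(2, 5)), "zero variance")
  expect_true(is.na(fz$r_squared))
})

test_that("the wild-type report quantifies the accumulation ceiling", {
  rep <- cached("wt_report",
                wildtype_discrepancy_report(default_model(),
                                            iptg_grid = seq(0, 20, length.out = 11),
                                            ss_grid = seq(0, 2, length.out = 11),
                                            widen = 10))
  expect_lt(rep$max_total_spo0A_uM, 4.5)
  expect_lt(rep$max_total_spo0A_uM_wide, 4.5)
  expect_gt(rep$benchmark_ratio, 8)
  # the unstimulated corner cannot beat the envelope maximum
  corner <- steady_state(default_model(), iptg = 0, ss = 0)
  expect_lte((corner$state[["Spo0A"]] + corner$state[["Spo0AP"]]) / 1000,
             rep$max_total_spo0A_uM + 1e-12)
})
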