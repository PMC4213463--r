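test_that("degenerate networks integrate to closed-form trajectories", {
  # all rate constants zero: nothing moves
  keys <- names(spore_parameters())
  rate_keys <- c(grep("\\.k[0-9]?$", keys, value = TRUE),
                 "d_mRNA", "d_prot")
  zero_net <- build_reference_network(
    spore_parameters(stats::setNames(rep(0, length(rate_keys)), rate_keys)))
  init <- spore_state(c(LacI = 5, Spo0F = 3))
  tr <- simulate(zero_net, init, iptg = 2, ss = 1, duration = 1000,
                 n_points = 11)
  expect_true(all(apply(tr$states, 2, function(x) all(x == x[1]))))

  # constitutive transcription only, no turnover: linear accumulation
  tr1_only <- set_parameters(zero_net, c("tr1.k" = 0.1))
  tr <- simulate(tr1_only, spore_state(), duration = 1000, n_points = 21)
  expect_equal(tr$states[, "lacI_t"], 0.1 * tr$times, tolerance = 1e-8)
  # with first-order turnover: saturating exponential
  turn <- set_parameters(tr1_only, c(d_mRNA = 0.01))
  tr <- simulate(turn, spore_state(), duration = 600, n_points = 13)
  expect_equal(tr$states[, "lacI_t"], 10 * (1 - exp(-0.01 * tr$times)),
               tolerance = 1e-7)
})

test_that("long-time integration and the steady-state solver agree", {
  m <- default_model()
  guess <- NULL
  for (iptg in c(0, 5, 10, 20)) {
    ss <- steady_state(m, iptg = iptg, guess = guess)
    guess <- ss$state
    expect_lte(ss$residual, 1e-9)
    tr <- simulate(m, iptg = iptg, duration = 5e6, n_points = 6)
    final <- tr$states[nrow(tr$states), m$forms]
    free <- setdiff(m$forms, c("IPTG", "SS"))
    expect_equal(final[free], ss$state[free], tolerance = 1e-3)
  }
})

test_that("trajectories are solver-tolerance robust and nonnegative", {
  m <- default_model()
  a <- simulate(m, iptg = 10, duration = 2e4, n_points = 41)
  b <- simulate(m, iptg = 10, duration = 2e4, n_points = 41,
                rtol = 5e-9, atol = 5e-11)
  scale <- pmax(abs(b$states), 1)
  expect_lt(max(abs(a$states - b$states) / scale), 1e-6)
  expect_true(min(a$states) >= -1e-9)
  # tidy export shape
  df <- as.data.frame(a)
  expect_identical(names(df), c("time", "form", "concentration"))
  expect_identical(nrow(df), 41L * 27L)
})

test_that("pre-equilibration yields a weakly activated basal state", {
  m <- default_model()
  basal <- basal_state()
  expect_gt(basal[["Spo0AP"]], 0)
  expect_gt(basal[["KinA2P"]], 0)
  # idempotence: solving again from the basal state returns it
  again <- steady_state(m, iptg = 0, guess = basal)
  expect_equal(again$state, basal, tolerance = 1e-8)
  # no sporulation signal, no induction: no phosphorylation source at all
  quiet <- steady_state(m, iptg = 0, ss = 0)
  expect_equal(quiet$state[["KinA2P"]], 0, tolerance = 1e-12)
  expect_equal(quiet$state[["Spo0AP"]], 0, tolerance = 1e-12)
})

test_that("a zero-synthesis network settles to the empty state", {
  keys <- names(spore_parameters())
  synth <- c("tr1.k", "tr2.k1", "tr2.k2", "tr3.k1", "tr3.k2", "tr4.k",
             "tr5.k1", "tr5.k2", "tr6.k1", "tr6.k2", "tr7.k1", "tr7.k2",
             "tr8.k1", "tr8.k2")
  m <- build_reference_network(
    spore_parameters(stats::setNames(rep(0, length(synth)), synth)))
  ss <- steady_state(m, iptg = 0, guess = spore_state(c(LacI = 50, Spo0F = 10)))
  expect_lt(max(abs(ss$state[setdiff(m$forms, "SS")])), 1e-6)
})
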