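test_that("the reference network has the published inventory", {
  m <- default_model()
  expect_length(m$forms, 27)
  expect_length(m$reactions, 55)
  expect_identical(dim(m$stoich), c(27L, 55L))
  # clamped inputs never change
  expect_true(all(m$stoich[c("IPTG", "SS"), ] == 0))
  # knockout leaves the structure untouched
  ko <- feedback_knockout(m)
  expect_identical(vapply(ko$reactions, `[[`, "", "id"),
                   vapply(m$reactions, `[[`, "", "id"))
  expect_identical(ko$params[["tr2.k3"]], 0)
})

test_that("rate laws reproduce hand-substituted values", {
  m <- default_model()
  rx <- m$reactions
  names(rx) <- vapply(rx, `[[`, "", "id")
  zero <- spore_state()
  # kinA transcription at zero repressor / zero feedback: k1 + k2
  expect_equal(evaluate_rate(rx$tr2, zero, m$params), 0.2675)
  # spo0F transcription at half-saturating Spo0A~P
  expect_equal(evaluate_rate(rx$tr3, spore_state(c(Spo0AP = 50)), m$params),
               0.07)
  # spo0A transcription with no activator: basal first term only
  expect_equal(evaluate_rate(rx$tr5, zero, m$params), 0.01388)
  # mass action with zero substrate
  expect_equal(evaluate_rate(rx$k5, spore_state(c(SS = 1)), m$params), 0)
  # negative concentrations are rejected
  bad <- spore_state(); bad[["Spo0FP"]] <- -1
  expect_error(evaluate_rate(rx$k7, bad, m$params), "negative")
  expect_error(time_derivatives(m, bad), "negative")
})

test_that("time derivatives at the zero state carry only unregulated synthesis", {
  m <- default_model()
  d <- time_derivatives(m, spore_state())
  expect_equal(d[["lacI_t"]], 0.1)
  expect_equal(d[["kinA_t"]], 0.2675)
  expect_equal(d[["spo0B_t"]], 0.2384)
  expect_equal(d[["Spo0FP"]], 0)
  expect_equal(d[["IPTG"]], 0)
  expect_equal(d[["SS"]], 0)
})

test_that("every rate law matches the independent brute-force evaluator", {
  m <- default_model()
  set.seed(421)
  for (i in 1:100) {
    st <- random_state()
    want <- oracle_rates(st, m$params)
    got_fast <- sporelay:::.reaction_rates(m, st[m$forms])
    got_eval <- vapply(m$reactions, evaluate_rate, numeric(1),
                       state = st, params = m$params)
    expect_equal(unname(got_fast), unname(want), tolerance = 1e-12)
    expect_equal(unname(got_eval), unname(want), tolerance = 1e-12)
  }
})

test_that("phosphotransfer conserves each protein's phospho-total exactly", {
  core <- phosphotransfer_only_model()
  set.seed(77)
  for (i in 1:20) {
    d <- time_derivatives(core, random_state())
    # zero up to floating-point accumulation on kilo-nM/s fluxes
    expect_lt(abs(d[["Spo0F"]] + d[["Spo0FP"]]), 1e-9)
    expect_lt(abs(d[["Spo0B"]] + d[["Spo0BP"]]), 1e-9)
    expect_lt(abs(d[["Spo0A"]] + d[["Spo0AP"]]), 1e-9)
    expect_lt(abs(d[["KinA"]] + 2 * d[["KinA2"]] + 2 * d[["KinA2P"]]), 1e-9)
  }
})

test_that("tr2.k3 = 0 severs the Spo0A~P edge onto kinA transcription", {
  ko <- feedback_knockout(default_model())
  set.seed(5)
  st <- random_state()
  st2 <- st
  st2[["Spo0AP"]] <- st[["Spo0AP"]] * 10 + 1
  d1 <- time_derivatives(ko, st)
  d2 <- time_derivatives(ko, st2)
  # kinA_t sees Spo0AP only through the (removed) feedback and its own level
  expect_identical(d1[["kinA_t"]] + ko$params[["deg_kinA_t.k"]] * st[["kinA_t"]],
                   d2[["kinA_t"]] + ko$params[["deg_kinA_t.k"]] * st2[["kinA_t"]])
  # the intact model does depend on Spo0AP
  m <- default_model()
  expect_gt(time_derivatives(m, st2)[["kinA_t"]] -
              time_derivatives(m, st)[["kinA_t"]] -
              m$params[["deg_kinA_t.k"]] * (st2[["kinA_t"]] - st[["kinA_t"]]),
            0)
})

test_that("parameter validation and overrides behave", {
  expect_error(spore_parameters(c(nonsense = 1)), "unknown")
  expect_error(validate_parameters(spore_parameters(c("tr2.KL" = 0))),
               "tr2.KL")
  expect_error(validate_parameters(spore_parameters(c("k5.k" = -1))), "k5.k")
  m <- default_model()
  m2 <- set_parameters(m, c(d_prot = 1e-3))
  expect_equal(m2$params[["deg_Spo0B.k"]], 1e-3)
  expect_equal(m2$params[["deg_lacI_t.k"]], m$params[["d_mRNA"]])
  f <- withr::local_tempfile(lines = c("# comment", "tr2.k3=0",
                                       "  d_prot = 2e-4 "))
  ov <- read_parameter_overrides(f)
  expect_equal(ov, c("tr2.k3" = 0, d_prot = 2e-4))
})
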