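test_that("tentative gamma estimation is consistent and handles edge cases", {
  set.seed(11)
  x <- rgamma(1e5, shape = 2.5, rate = 0.29)
  p <- fit_tentative_gamma(x)
  # asymptotic MLE standard errors at n = 1e5 are ~0.011 (shape), ~0.0014 (rate)
  expect_lt(abs(p$shape0 - 2.5), 0.04)
  expect_lt(abs(p$rate0 - 0.29), 0.005)
  # an exponential sample is gamma with shape 1
  e <- fit_tentative_gamma(rexp(2e4, 0.5))
  expect_lt(abs(e$shape0 - 1), 0.05)
  # constant sample: degenerate MLE falls back with a warning
  expect_warning(cst <- fit_tentative_gamma(rep(2, 50)), "degenerate")
  expect_lt(abs(cst$shape0 / cst$rate0 - 2), 1e-6)  # proposal mean preserved
})

test_that("a track of T locations yields T - 2 choice sets with the used step in row 0", {
  d <- make_scenario_data(1, T = 200, M = 5, seed = 61)
  cc <- d$cc
  expect_equal(cc$nsets, 198)
  # row-0 covariates equal those of the observed steps
  st <- steps_from_track(d$sim$track[c("x", "y")])
  used <- seq(1, cc$nsets * (cc$M + 1), by = cc$M + 1)
  expect_equal(unname(cc$C[used, "log_l"]), log(st$length[-1]))
  expect_equal(unname(cc$C[used, "cos_a"]), cos(st$angle[-1]))
  # and row-0 endpoints are the observed locations x_3..x_T
  expect_equal(cc$x[used], d$sim$track$x[3:200])
  expect_equal(cc$y[used], d$sim$track$y[3:200])
  # habitat covariate of row 0 equals lookup at the observed endpoint
  expect_equal(unname(cc$Z[used, "z"]),
               covariate_at(d$field, d$sim$track$x[3:200], d$sim$track$y[3:200]))
})

test_that("a degenerate copy-the-used-step proposal gives choice probability 1/2", {
  d <- make_scenario_data(1, T = 50, M = 5, seed = 62)
  cc <- build_case_control(d$sim$track[c("x", "y")], d$field, M = 1,
                           proposal = cc_proposal <- ssa_proposal(2, 1),
                           copy_used = TRUE)
  lp <- choice_log_probabilities(cc$C[1:2, ], cc$Z[1:2, , drop = FALSE],
                                 d$scenario$model, cc$proposal)
  expect_equal(unname(lp), rep(log(0.5), 2))
})

test_that("control steps are drawn from the stated proposal distributions", {
  d <- make_scenario_data(1, T = 60, M = 400, seed = 63)
  prop <- ssa_proposal(1.7, 0.4)
  cc <- build_case_control(d$sim$track[c("x", "y")], d$field, M = 400,
                           proposal = prop, seed = 5)
  m1 <- cc$M + 1
  ctrl <- setdiff(seq_len(nrow(cc$C)), seq(1, cc$nsets * m1, by = m1))
  len <- -cc$C[ctrl, "neg_l"]
  ang <- acos(pmin(pmax(cc$C[ctrl, "cos_a"], -1), 1))
  expect_gt(ks.test(len, pgamma, shape = 1.7, rate = 0.4)$p.value, 0.01)
  # |angle| of a uniform angle is uniform on (0, pi)
  expect_gt(ks.test(ang, punif, 0, pi)$p.value, 0.01)
})

test_that("growing M extends choice sets without reshuffling earlier draws", {
  d <- make_scenario_data(1, T = 40, M = 2, seed = 64)
  tr <- d$sim$track[c("x", "y")]
  prop <- ssa_proposal(2, 0.5)
  cc5 <- build_case_control(tr, d$field, M = 5, proposal = prop, seed = 99)
  cc9 <- build_case_control(tr, d$field, M = 9, proposal = prop, seed = 99)
  pick <- function(cc, m) {
    m1 <- cc$M + 1
    as.vector(vapply(seq_len(cc$nsets), function(s)
      cc$C[(s - 1) * m1 + 1 + seq_len(m), "log_l"], numeric(m)))
  }
  expect_equal(pick(cc5, 5), pick(cc9, 5))
})

test_that("the recovery map inverts the proposal tilting algebra", {
  p <- ssa_proposal(2, 1)
  expect_equal(recover_movement_parameters(c(0, 0, 0), p),
               list(shape = 2, rate = 1, kappa = 0))
  expect_equal(recover_movement_parameters(c(0.5, -0.71, 1.0), p),
               list(shape = 2.5, rate = 0.29, kappa = 1.0))
  expect_error(recover_movement_parameters(c(-3, 0, 0), p), "natural space")
  # von Mises proposal shifts the concentration reference
  pv <- ssa_proposal(2, 1, kappa0 = 0.8)
  expect_equal(recover_movement_parameters(c(0, 0, 0.2), pv)$kappa, 1.0)
})

test_that("recovered parameters do not depend on the proposal used", {
  d <- make_scenario_data(4, T = 800, M = 50, seed = 65)
  tr <- d$sim$track[c("x", "y")]
  lens <- steps_from_track(tr)$length
  pA <- fit_tentative_gamma(lens)
  pB <- ssa_proposal(pA$shape0 * 1.6, pA$rate0 * 0.7)
  fA <- hmm_issa(build_case_control(tr, d$field, 50, pA, seed = 1),
                 n_states = 1, n_starts = 2, seed = 2)
  fB <- hmm_issa(build_case_control(tr, d$field, 50, pB, seed = 1),
                 n_states = 1, n_starts = 2, seed = 2)
  cA <- coef(fA); cB <- coef(fB)
  expect_lt(max(abs(cA - cB)[c("shape", "kappa", "beta_z"), ]), 0.25)
  expect_lt(abs(cA["rate", ] - cB["rate", ]), 0.06)
})

test_that("case-control CSV files round-trip", {
  d <- make_scenario_data(1, T = 30, M = 3, seed = 66)
  path <- withr::local_tempfile(fileext = ".csv")
  write_cc_csv(d$cc, path)
  back <- read_cc_csv(path)
  expect_equal(back$C, d$cc$C, tolerance = 1e-12)
  expect_equal(back$Z, d$cc$Z, tolerance = 1e-12)
  expect_equal(back$M, d$cc$M)
  expect_equal(back$step, d$cc$step)
  expect_equal(back$proposal$shape0, d$cc$proposal$shape0)
  writeLines("x,y", path)
  expect_error(read_cc_csv(path), "line 1")
})
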