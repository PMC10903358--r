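test_that("choice probabilities collapse to known values in symmetric cases", {
  m <- make_toy_model(N = 2)
  prop <- ssa_proposal(2, 1)
  # identical rows: every state gives 1/(M+1)
  C <- movement_covariates(rep(1.3, 5), rep(0.4, 5))
  Z <- matrix(0.2, 5, 1)
  expect_equal(unname(choice_log_probabilities(C, Z, m, prop)),
               rep(log(1 / 5), 2))
  # theta = beta = 0 (model equal to proposal, no selection): 1/(M+1)
  m0 <- hmm_issa_model(matrix(1), list(list(shape = 2, rate = 1, kappa = 0,
                                            beta = 0)))
  cc <- make_toy_cc(nsets = 1, M = 3)
  expect_equal(unname(choice_log_probabilities(cc$C[1:4, ], cc$Z[1:4, , drop = FALSE],
                                               m0, prop)), log(1 / 4))
  # M = 1 with weight difference 0.5: logistic probability
  mb <- hmm_issa_model(matrix(1), list(list(shape = 2, rate = 1, kappa = 0,
                                            beta = 1)))
  C1 <- movement_covariates(c(1, 1), c(0, 0))
  Z1 <- cbind(c(0.5, 0))
  expect_equal(exp(choice_log_probabilities(C1, Z1, mb, prop))[1],
               1 / (1 + exp(-0.5)))
})

test_that("forward likelihood equals brute-force enumeration", {
  # N = 2, four choice sets (2^4 sequences)
  cc <- make_toy_cc(nsets = 4, M = 2, seed = 101)
  m <- make_toy_model(N = 2, seed = 102)
  expect_lt(abs(cc_loglik(cc, m) - oracle_loglik(cc, m)), 1e-10)
  # N = 3, five sets, two habitat covariates
  cc3 <- make_toy_cc(nsets = 5, M = 3, p_Z = 2, seed = 103)
  m3 <- make_toy_model(N = 3, p_Z = 2, seed = 104)
  expect_lt(abs(cc_loglik(cc3, m3) - oracle_loglik(cc3, m3)), 1e-10)
  # bursts multiply independent forward passes
  ccb <- make_toy_cc(nsets = 6, M = 2, seed = 105, burst = c(1, 1, 1, 2, 2, 2))
  expect_lt(abs(cc_loglik(ccb, m) - oracle_loglik(ccb, m)), 1e-10)
})

test_that("Viterbi decoding equals the enumeration argmax", {
  for (seed in 1:5) {
    cc <- make_toy_cc(nsets = 4, M = 2, seed = 200 + seed)
    m <- make_toy_model(N = 2, seed = 300 + seed)
    expect_equal(as.integer(viterbi(m, cc)), oracle_viterbi(cc, m))
  }
  cc3 <- make_toy_cc(nsets = 5, M = 2, seed = 210)
  m3 <- make_toy_model(N = 3, seed = 310)
  expect_equal(as.integer(viterbi(m3, cc3)), oracle_viterbi(cc3, m3))
})

test_that("the likelihood reduces correctly for N = 1 and identical states", {
  cc <- make_toy_cc(nsets = 6, M = 3, seed = 111)
  m1 <- make_toy_model(N = 1, seed = 112)
  # N = 1: sum of log choice probabilities
  m1sets <- sum(vapply(seq_len(cc$nsets), function(s) {
    rows <- (s - 1) * 4 + 1:4
    choice_log_probabilities(cc$C[rows, ], cc$Z[rows, , drop = FALSE],
                             m1, cc$proposal)
  }, numeric(1)))
  expect_equal(cc_loglik(cc, m1), m1sets, tolerance = 1e-12)
  # two identical states equal the single state model
  st <- m1$states[[1]]
  m2 <- hmm_issa_model(matrix(c(.7, .3, .2, .8), 2, byrow = TRUE), list(st, st))
  expect_equal(cc_loglik(cc, m2), cc_loglik(cc, m1), tolerance = 1e-10)
})

test_that("the likelihood is invariant under state label permutation", {
  cc <- make_toy_cc(nsets = 6, M = 2, seed = 121)
  m <- make_toy_model(N = 3, seed = 122)
  perm <- c(3, 1, 2)
  mp <- hmm_issa_model(m$tpm[perm, perm], m$states[perm],
                       delta = m$delta[perm])
  expect_equal(cc_loglik(cc, mp), cc_loglik(cc, m), tolerance = 1e-12)
})

test_that("N = 1 estimates match an independent conditional-logistic solver", {
  skip_if_not_installed("survival")
  suppressPackageStartupMessages(library(survival))
  d <- make_scenario_data(4, T = 500, M = 20, seed = 71)
  fit <- hmm_issa(d$cc, n_states = 1, n_starts = 2, seed = 72)
  m1 <- d$cc$M + 1
  df <- data.frame(set = rep(seq_len(d$cc$nsets), each = m1),
                   used = rep(c(1, rep(0, d$cc$M)), d$cc$nsets),
                   log_l = d$cc$C[, "log_l"], neg_l = d$cc$C[, "neg_l"],
                   cos_a = d$cc$C[, "cos_a"], z = d$cc$Z[, "z"])
  cl <- survival::clogit(used ~ log_l + neg_l + cos_a + z +
                           survival::strata(set), data = df)
  ours <- c(fit$natural[[1]]$shape - d$cc$proposal$shape0,
            fit$natural[[1]]$rate - d$cc$proposal$rate0,
            fit$natural[[1]]$kappa, fit$natural[[1]]$beta)
  expect_equal(unname(ours), unname(coef(cl)), tolerance = 1e-4)
  expect_equal(fit$logLik, as.numeric(logLik(cl)), tolerance = 1e-6)
})

test_that("label permutation of a fitted model leaves its likelihood unchanged", {
  d <- make_scenario_data(1, T = 300, M = 10, seed = 73)
  fit <- hmm_issa(d$cc, n_states = 2, n_starts = 2, seed = 74)
  m <- hmm_issa_model(fit$tpm, fit$natural, delta = fit$delta)
  mp <- hmm_issa_model(fit$tpm[2:1, 2:1], fit$natural[2:1],
                       delta = fit$delta[2:1])
  expect_equal(cc_loglik(d$cc, mp), cc_loglik(d$cc, m), tolerance = 1e-10)
  expect_equal(cc_loglik(d$cc, m), fit$logLik, tolerance = 1e-8)
})

test_that("duplicating the data shrinks standard errors by about 1/sqrt(2)", {
  cc <- make_toy_cc(nsets = 150, M = 10, seed = 131,
                    proposal = ssa_proposal(2, 1))
  dup <- cc
  dup$C <- rbind(cc$C, cc$C)
  dup$Z <- rbind(cc$Z, cc$Z)
  dup$x <- c(cc$x, cc$x); dup$y <- c(cc$y, cc$y)
  dup$step <- c(cc$step, cc$step)
  dup$burst <- c(cc$burst, cc$burst + 1L)
  dup$nsets <- 2L * cc$nsets
  f1 <- hmm_issa(cc, n_states = 1, n_starts = 1)
  f2 <- hmm_issa(dup, n_states = 1, n_starts = 1)
  se1 <- wald_inference(f1, all = TRUE)$se
  se2 <- wald_inference(f2, all = TRUE)$se
  expect_equal(se2 / se1, rep(1 / sqrt(2), length(se1)), tolerance = 0.02)
})

test_that("Wald machinery produces the normal-approximation p-values", {
  cc <- make_toy_cc(nsets = 120, M = 8, seed = 141)
  fit <- hmm_issa(cc, n_states = 1, n_starts = 1)
  w <- wald_inference(fit)
  expect_equal(w$z, w$estimate / w$se)
  expect_equal(w$p_value, 2 * pnorm(-abs(w$z)))
  expect_equal(w$term, "beta_z1")
})

test_that("information criteria follow their definitions and the logLik method", {
  d <- make_scenario_data(1, T = 200, M = 5, seed = 151)
  fit <- hmm_issa(d$cc, n_states = 2, n_starts = 2, seed = 152)
  expect_equal(fit$np, 10)  # 2 x (3 movement + 1 selection) + 2 transition
  expect_equal(fit$AIC, -2 * fit$logLik + 2 * fit$np)
  expect_equal(fit$BIC, -2 * fit$logLik + fit$np * log(fit$n))
  expect_equal(AIC(fit), fit$AIC)
  expect_equal(BIC(fit), fit$BIC)
  expect_equal(unname(information_criteria(fit)), c(fit$AIC, fit$BIC))
  # example arithmetic: ll = -100, p = 5, n = 100
  expect_equal(-2 * -100 + 2 * 5, 210)
  expect_equal(-2 * -100 + 5 * log(100), 223.0259, tolerance = 1e-4)
})

test_that("near-persistent chains with separated emissions decode as blocks", {
  # construct choice sets whose used steps alternate between two regimes
  set.seed(161)
  n_half <- 15; M <- 6; m1 <- M + 1
  len_used <- c(rgamma(n_half, 40, rate = 40),     # short steps, mean 1
                rgamma(n_half, 40, rate = 4))      # long steps, mean 10
  nsets <- 2 * n_half
  len <- matrix(rgamma(nsets * m1, 2, 1), m1, nsets)
  len[1, ] <- len_used
  ang <- matrix(runif(nsets * m1, -pi, pi), m1, nsets)
  cc <- structure(list(
    C = movement_covariates(as.vector(len), as.vector(ang)),
    Z = NULL, M = M, nsets = nsets, step = seq_len(nsets) + 1L,
    burst = rep(1L, nsets), x = numeric(nsets * m1), y = numeric(nsets * m1),
    angle_model = "von_mises", proposal = ssa_proposal(2, 1)),
    class = "cc_data")
  m <- hmm_issa_model(matrix(c(.999, .001, .001, .999), 2),
                      list(list(shape = 40, rate = 40, kappa = 0, beta = numeric(0)),
                           list(shape = 40, rate = 4, kappa = 0, beta = numeric(0))))
  dec <- as.integer(viterbi(m, cc))
  expect_equal(sum(diff(dec) != 0), 1)  # exactly one regime change
  expect_equal(dec, rep(1:2, each = n_half))
})

test_that("the analytic likelihood gradient matches numerical differentiation", {
  cc <- make_toy_cc(nsets = 30, M = 5, seed = 191)
  m <- make_toy_model(N = 2, seed = 192)
  X <- cbind(cc$C, cc$Z)
  coef <- msissa:::model_coef_matrix(m, cc$proposal)
  burst <- as.integer(cc$burst)
  res <- msissa:::cc_nll_grad_cpp(X, coef, cc$M + 1L, m$tpm, m$delta, burst)
  nll_at <- function(cf) {
    lp <- msissa:::cc_state_logprob_cpp(X, cf, cc$M + 1L)
    msissa:::hmm_forward_nll_cpp(lp, m$tpm, m$delta, burst)
  }
  expect_equal(res$nll, nll_at(coef), tolerance = 1e-12)
  h <- 1e-6
  num <- coef * 0
  for (j in seq_len(nrow(coef))) for (i in seq_len(ncol(coef))) {
    cp <- coef; cp[j, i] <- cp[j, i] + h
    cm <- coef; cm[j, i] <- cm[j, i] - h
    num[j, i] <- (nll_at(cp) - nll_at(cm)) / (2 * h)
  }
  expect_equal(res$grad_coef, num, tolerance = 1e-5)
})

test_that("the multi-start fit records per-start diagnostics", {
  d <- make_scenario_data(1, T = 250, M = 5, seed = 171)
  fit <- hmm_issa(d$cc, n_states = 2, n_starts = 3, seed = 172)
  expect_equal(nrow(fit$starts), 3)
  expect_true(any(fit$starts$converged))
  expect_equal(min(fit$starts$nll[fit$starts$converged]), -fit$logLik,
               tolerance = 1e-9)
  expect_true(is.finite(fit$loglik_spread))
  s <- summary(fit)
  expect_s3_class(s, "summary.hmm_issa")
  expect_output(print(s), "selection coefficients")
})

test_that("fit JSON serialisation captures the model", {
  d <- make_scenario_data(1, T = 250, M = 5, seed = 181)
  fit <- hmm_issa(d$cc, n_states = 2, n_starts = 2, seed = 182)
  path <- withr::local_tempfile(fileext = ".json")
  write_fit_json(fit, path)
  doc <- jsonlite::read_json(path)
  expect_equal(doc$n_states, 2)
  expect_equal(doc$model, "HMM-iSSA")
  expect_equal(doc$logLik, fit$logLik, tolerance = 1e-8)
  expect_length(doc$natural, 2)
  expect_length(doc$tpm, 2)
})
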