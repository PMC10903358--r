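test_that("step geometry matches an independent trigonometric recomputation", {
  set.seed(4)
  xy <- cbind(cumsum(rnorm(20)), cumsum(rnorm(20)))
  st <- steps_from_track(xy)
  # recompute with complex arithmetic
  z <- complex(real = xy[, 1], imaginary = xy[, 2])
  dz <- diff(z)
  expect_equal(st$length, Mod(dz))
  expect_equal(st$heading, Arg(dz))
  turn <- Arg(dz[-1] / dz[-length(dz)])  # heading change in (-pi, pi]
  expect_equal(st$angle[-1], turn)
  expect_true(is.na(st$angle[1]))
  expect_equal(nrow(st), nrow(xy) - 1)
})

test_that("straight paths and right-angle turns give the expected angles", {
  line <- cbind(seq(0, 5), seq(0, 10, by = 2))
  expect_equal(steps_from_track(line)$angle[-1], rep(0, 4))
  left <- rbind(c(0, 0), c(1, 0), c(1, 1))  # 90 degree left turn
  expect_equal(steps_from_track(left)$angle[2], pi / 2)
  right <- rbind(c(0, 0), c(1, 0), c(1, -1))
  expect_equal(steps_from_track(right)$angle[2], -pi / 2)
})

test_that("zero-length steps follow the configured policy", {
  xy <- rbind(c(0, 0), c(1, 0), c(1, 0), c(2, 1))
  expect_error(steps_from_track(xy, zero_length = "error"), "zero-length")
  expect_message(st <- steps_from_track(xy, zero_length = "floor"), "floored")
  expect_true(all(st$length > 0))
})

test_that("movement covariates take the kernel-specific linear form", {
  expect_equal(unname(movement_covariates(1, 0)), cbind(0, -1, 1))
  expect_equal(unname(movement_covariates(2, pi)), cbind(log(2), -2, -1))
  expect_equal(unname(movement_covariates(exp(1), angle_model = "uniform")),
               cbind(1, -exp(1)))
  expect_error(movement_covariates(1, NA, "von_mises"), "angle")
})

test_that("log step weights reproduce hand arithmetic", {
  # theta = 0, beta = 0 under the unadjusted map means shape 1, rate 0
  s0 <- list(shape = 1, rate = 0, kappa = 0, beta = 0)
  C <- movement_covariates(c(0.5, 2, 7), c(0.1, -2, 3))
  expect_equal(log_step_weight(C, cbind(rnorm(3)), s0), rep(0, 3))
  # shape 2, rate 1, kappa 0, beta 0 at l = 1: (2-1)*0 + 1*(-1) = -1
  s1 <- list(shape = 2, rate = 1, kappa = 0, beta = numeric(0))
  expect_equal(log_step_weight(movement_covariates(1, 0.7), NULL, s1), -1)
  # Scenario-1 state-2 parameters at l = 1, a = 0, z = 1:
  # 1.5*0 + 0.29*(-1) + 1*1 + 2*1 = 2.71
  s2 <- list(shape = 2.5, rate = 0.29, kappa = 1, beta = 2)
  expect_equal(log_step_weight(movement_covariates(1, 0), cbind(1), s2), 2.71)
})

test_that("stationary distributions solve delta' Gamma = delta'", {
  expect_equal(stationary_distribution(matrix(c(.9, .1, .1, .9), 2)), c(.5, .5))
  expect_equal(stationary_distribution(matrix(c(.8, .2, .4, .6), 2, byrow = TRUE)),
               c(2 / 3, 1 / 3))
  expect_warning(d <- stationary_distribution(diag(2)), "uniform")
  expect_equal(d, c(.5, .5))
  set.seed(1)
  G <- matrix(runif(9), 3, 3); G <- G / rowSums(G)
  d <- stationary_distribution(G)
  expect_equal(drop(d %*% G), d)
  expect_equal(sum(d), 1)
})

test_that("von Mises density normalises and the sampler matches its moments", {
  for (kappa in c(0.3, 1, 4)) {
    expect_equal(integrate(dvonmises, -pi, pi, kappa = kappa)$value, 1,
                 tolerance = 1e-6)
  }
  set.seed(9)
  n <- 40000
  x <- rvonmises(n, mu = 0, kappa = 1)
  a1 <- besselI(1, 1) / besselI(1, 0)  # E[cos X] for kappa = 1
  expect_lt(abs(mean(cos(x)) - a1), 3 * sd(cos(x)) / sqrt(n))
  expect_lt(abs(mean(sin(x))), 3 * sd(sin(x)) / sqrt(n))
  expect_true(all(x > -pi & x <= pi))
})

test_that("a flat selection surface yields exact kernel sampling", {
  # with a constant field the resampling weights are uniform, so simulated
  # steps are exact draws from the gamma/von Mises kernel for any K
  m <- hmm_issa_model(matrix(1), list(list(shape = 2.5, rate = 0.29,
                                           kappa = 1, beta = 2)))
  f <- covariate_field(matrix(0.7, 10, 10), resolution = 10)
  sim <- simulate_track(m, f, T = 1500, K = 120, seed = 21)
  st <- steps_from_track(sim$track[c("x", "y")])
  expect_gt(ks.test(st$length, pgamma, shape = 2.5, rate = 0.29)$p.value, 0.01)
  a1 <- besselI(1, 1) / besselI(1, 0)
  ca <- cos(st$angle[-1])
  expect_lt(abs(mean(ca) - a1), 3 * sd(ca) / sqrt(length(ca)))
  expect_true(all(sim$states == 1))
})

test_that("the simulated state chain has the model's frequencies and persistence", {
  d <- make_scenario_data(1, T = 3000, M = 1, seed = 31, K = 200)
  S <- d$sim$states
  expect_lt(abs(mean(S == 1) - 0.5), 0.08)
  expect_lt(abs(mean(S[-1] == S[-length(S)]) - 0.9), 0.03)
})

test_that("positive selection concentrates the track on high covariate values", {
  sc <- scenario_parameters(4)  # single state, beta = 2
  field <- simulate_grf(sc$grf, seed = 41)
  m0 <- hmm_issa_model(matrix(1), list(list(shape = 2.5, rate = 0.29,
                                            kappa = 1, beta = 0)))
  sim_sel <- simulate_track(sc$model, field, T = 600, K = 300, seed = 42)
  sim_null <- simulate_track(m0, field, T = 600, K = 300, seed = 42)
  z_sel <- covariate_at(field, sim_sel$track$x, sim_sel$track$y)
  z_null <- covariate_at(field, sim_null$track$x, sim_null$track$y)
  expect_gt(mean(z_sel), mean(z_null) + 0.2)
})

test_that("equal-parameter states reduce to the single-state model", {
  st <- list(shape = 2.5, rate = 0.29, kappa = 1, beta = 2)
  m2 <- hmm_issa_model(matrix(c(.9, .1, .1, .9), 2), list(st, st))
  m1 <- hmm_issa_model(matrix(1), list(st))
  field <- simulate_grf(grf_config(nx = 50, ny = 50), seed = 51)
  s2 <- simulate_track(m2, field, T = 1200, K = 200, seed = 52)
  s1 <- simulate_track(m1, field, T = 1200, K = 200, seed = 53)
  st2 <- steps_from_track(s2$track[c("x", "y")])
  st1 <- steps_from_track(s1$track[c("x", "y")])
  expect_gt(ks.test(st1$length, st2$length)$p.value, 0.01)
  expect_lt(abs(mean(cos(st1$angle[-1])) - mean(cos(st2$angle[-1]))), 0.08)
})

test_that("track CSV files round-trip and reject malformed input", {
  path <- withr::local_tempfile(fileext = ".csv")
  tr <- data.frame(t = 1:5, x = rnorm(5), y = rnorm(5))
  write_track_csv(tr, path, id = "a1")
  back <- read_track_csv(path)
  expect_equal(back$x, tr$x)
  expect_equal(back$id, rep("a1", 5))
  write.csv(data.frame(u = 1:3), path, row.names = FALSE)
  expect_error(read_track_csv(path), "columns id, t, x, y")
})
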