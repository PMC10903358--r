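# Small synthetic fixtures built in code.

# artificial case-control data with random covariates (not from a track)
make_toy_cc <- function(nsets = 4L, M = 2L, angle_model = "von_mises",
                        p_Z = 1L, seed = 1L, burst = NULL,
                        proposal = ssa_proposal(2, 1)) {
  set.seed(seed)
  n <- nsets * (M + 1L)
  len <- rgamma(n, 2, 1)
  ang <- runif(n, -pi, pi)
  C <- movement_covariates(len, ang, angle_model)
  Z <- if (p_Z > 0L) {
    matrix(rnorm(n * p_Z), n, p_Z, dimnames = list(NULL, paste0("z", seq_len(p_Z))))
  } else NULL
  structure(list(C = C, Z = Z, M = as.integer(M), nsets = as.integer(nsets),
                 step = seq_len(nsets) + 1L,
                 burst = burst %or% rep(1L, nsets),
                 x = rep(0, n), y = rep(0, n),
                 angle_model = angle_model, proposal = proposal),
            class = "cc_data")
}

make_toy_model <- function(N = 2L, p_Z = 1L, seed = 2L) {
  set.seed(seed)
  states <- lapply(seq_len(N), function(i) {
    list(shape = runif(1, 0.8, 3), rate = runif(1, 0.3, 1.5),
         kappa = runif(1, -0.5, 1.5), beta = runif(p_Z, -1.5, 1.5))
  })
  tpm <- matrix(runif(N * N, 0.5, 1), N, N)
  diag(tpm) <- diag(tpm) + 2
  tpm <- tpm / rowSums(tpm)
  hmm_issa_model(tpm, states)
}

# simulate a scenario track plus its case-control data
make_scenario_data <- function(id = 1L, T = 500L, M = 20L, seed = 7L,
                               K = 500L) {
  sc <- scenario_parameters(id)
  field <- simulate_grf(sc$grf, seed = seed)
  sim <- simulate_track(sc$model, field, T = T, K = K, seed = seed + 1L)
  cc <- build_case_control(sim$track[c("x", "y")], field, M = M,
                           seed = seed + 2L)
  list(scenario = sc, field = field, sim = sim, cc = cc)
}
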