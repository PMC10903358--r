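# Brute-force oracles, written from the model definitions with plain
# arithmetic (no shared code with the package's likelihood path).

`%or%` <- function(a, b) if (is.null(a)) b else a

# state-dependent choice probabilities of every choice set, by direct
# exponentiation and summation of the proposal-relative weights
oracle_choice_probs <- function(data, model) {
  m1 <- data$M + 1L
  k0 <- data$proposal$shape0; r0 <- data$proposal$rate0
  kap0 <- data$proposal$kappa0
  P <- matrix(0, data$nsets, model$n_states)
  for (s in seq_len(data$nsets)) {
    rows <- (s - 1L) * m1 + seq_len(m1)
    for (i in seq_len(model$n_states)) {
      st <- model$states[[i]]
      w <- (st$shape - k0) * data$C[rows, "log_l"] +
           (st$rate - r0) * data$C[rows, "neg_l"]
      if (data$angle_model == "von_mises") {
        w <- w + (st$kappa - kap0) * data$C[rows, "cos_a"]
      }
      if (length(st$beta)) {
        w <- w + drop(data$Z[rows, , drop = FALSE] %*% st$beta)
      }
      P[s, i] <- exp(w[1]) / sum(exp(w))
    }
  }
  P
}

# all state sequences of length n over 1..N
oracle_sequences <- function(n, N) {
  as.matrix(expand.grid(rep(list(seq_len(N)), n)))
}

# likelihood by full enumeration over state sequences (bursts supported)
oracle_loglik <- function(data, model) {
  P <- oracle_choice_probs(data, model)
  N <- model$n_states
  total_log <- 0
  for (b in unique(data$burst)) {
    idx <- which(data$burst == b)
    seqs <- oracle_sequences(length(idx), N)
    tot <- 0
    for (q in seq_len(nrow(seqs))) {
      sq <- seqs[q, ]
      pr <- model$delta[sq[1]] * P[idx[1], sq[1]]
      if (length(idx) > 1L) for (t in 2:length(idx)) {
        pr <- pr * model$tpm[sq[t - 1L], sq[t]] * P[idx[t], sq[t]]
      }
      tot <- tot + pr
    }
    total_log <- total_log + log(tot)
  }
  total_log
}

# most likely state sequence by enumeration (single burst)
oracle_viterbi <- function(data, model) {
  stopifnot(length(unique(data$burst)) == 1L)
  P <- oracle_choice_probs(data, model)
  seqs <- oracle_sequences(data$nsets, model$n_states)
  best <- NULL; best_pr <- -Inf
  for (q in seq_len(nrow(seqs))) {
    sq <- seqs[q, ]
    pr <- log(model$delta[sq[1]]) + log(P[1, sq[1]])
    if (data$nsets > 1L) for (t in 2:data$nsets) {
      pr <- pr + log(model$tpm[sq[t - 1L], sq[t]]) + log(P[t, sq[t]])
    }
    if (pr > best_pr) { best_pr <- pr; best <- sq }
  }
  unname(best)
}
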