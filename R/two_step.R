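#' Fit a movement HMM to step lengths and turning angles
#'
#' The first stage of the two-step analysis: an N-state hidden Markov
#' model fitted directly to the observed steps, with state-dependent gamma
#' step-length and mean-zero von Mises turning-angle densities (or uniform
#' angles), no habitat covariate. Maximum likelihood via the scaled
#' forward algorithm with multi-start initialisation; the Viterbi-decoded
#' state sequence is attached.
#'
#' @param track Track coordinates (see [steps_from_track()]); a data frame
#'   may carry a `burst` column.
#' @param n_states Number of states N (>= 1).
#' @param n_starts Number of starting value sets.
#' @param seed Integer seed for random starts.
#' @param angle_model `"von_mises"` or `"uniform"`.
#' @param control Optimiser settings as in [hmm_issa()].
#' @return Object of class `movement_hmm`: per-state `shape`, `rate`,
#'   `kappa`, transition matrix, stationary initial distribution,
#'   log-likelihood, AIC/BIC, decoded states (one per step) and the step
#'   data used.
#' @export
fit_movement_hmm <- function(track, n_states = 2L, n_starts = 10L, seed = NULL,
                             angle_model = c("von_mises", "uniform"),
                             control = list()) {
  angle_model <- match.arg(angle_model)
  stopifnot(n_states >= 1L, n_starts >= 1L)
  if (!is.null(seed)) set.seed(seed)
  ctrl <- utils::modifyList(list(maxit = 2000L, reltol = 1e-9), control)
  xy <- track_coords(track)
  burst_loc <- if (is.data.frame(track) && !is.null(track$burst)) {
    track$burst
  } else rep(1L, nrow(xy))
  pieces <- split(seq_len(nrow(xy)), burst_loc)
  len <- c(); ang <- c(); burst <- c()
  for (b in seq_along(pieces)) {
    rows <- pieces[[b]]
    if (length(rows) < 3L) next
    st <- steps_from_track(xy[rows, , drop = FALSE])
    len <- c(len, st$length); ang <- c(ang, st$angle)
    burst <- c(burst, rep(b, nrow(st)))
  }
  n_obs <- length(len)
  N <- n_states
  has_kappa <- angle_model == "von_mises"
  # working parameters: per state log k, log r, [log kappa]; then tpm logits
  per_state <- 2L + has_kappa
  npar <- N * per_state + N * (N - 1L)
  logdens <- function(k, r, kap) {
    ld <- stats::dgamma(len, shape = k, rate = r, log = TRUE)
    if (has_kappa) {
      ok <- !is.na(ang)
      ld[ok] <- ld[ok] + dvonmises(ang[ok], mu = 0, kappa = kap, log = TRUE)
    }
    ld
  }
  nll <- function(par) {
    lp <- matrix(0, n_obs, N)
    for (i in seq_len(N)) {
      off <- (i - 1L) * per_state
      lp[, i] <- logdens(exp(par[off + 1L]), exp(par[off + 2L]),
                         if (has_kappa) exp(par[off + 3L]))
    }
    if (N > 1L) {
      tpm <- logits_to_tpm(par[N * per_state + seq_len(N * (N - 1L))], N)
      delta <- stationary_quiet(tpm)
    } else { tpm <- matrix(1, 1, 1); delta <- 1 }
    hmm_forward_nll_cpp(lp, tpm, delta, as.integer(burst))
  }
  # moment-based centre, then random multi-start around it
  grp <- if (N == 1L) rep(1L, n_obs) else {
    cut(len, stats::quantile(len, seq(0, 1, length.out = N + 1)),
        labels = FALSE, include.lowest = TRUE)
  }
  centre <- numeric(0)
  for (i in seq_len(N)) {
    li <- len[grp == i]
    m <- mean(li); v <- stats::var(li)
    centre <- c(centre, log(max(m^2 / v, 0.05)), log(max(m / v, 1e-3)))
    if (has_kappa) centre <- c(centre, log(0.7))
  }
  if (N > 1L) centre <- c(centre, rep(log((1 - 0.9) / (N - 1L) / 0.9), N * (N - 1L)))
  runs <- vector("list", n_starts)
  for (s in seq_len(n_starts)) {
    par0 <- centre
    if (s > 1L) {
      par0[seq_len(N * per_state)] <- par0[seq_len(N * per_state)] +
        stats::runif(N * per_state, log(1 / 4), log(4))
      if (N > 1L) {
        d <- stats::runif(N, 0.7, 0.95)
        par0[N * per_state + seq_len(N * (N - 1L))] <-
          rep(log((1 - d) / (N - 1L) / d), each = N - 1L)
      }
    }
    runs[[s]] <- tryCatch(
      suppressWarnings(  # NaN densities while the optimiser probes bad regions
        stats::optim(par0, nll, method = "BFGS",
                     control = list(maxit = ctrl$maxit, reltol = ctrl$reltol))),
      error = function(e) list(value = Inf, convergence = 99L,
                               message = conditionMessage(e)))
  }
  vals <- vapply(runs, function(r) r$value, numeric(1))
  conv <- vapply(runs, function(r) identical(r$convergence, 0L), logical(1))
  if (all(!is.finite(vals))) {
    stop("all movement-HMM starts failed:\n",
         paste(vapply(runs, function(r) r$message %||% "", character(1)),
               collapse = "\n"))
  }
  pick_from <- if (any(conv)) which(conv) else which(is.finite(vals))
  best <- runs[[pick_from[which.min(vals[pick_from])]]]
  par <- best$par
  states <- vector("list", N)
  lp <- matrix(0, n_obs, N)
  for (i in seq_len(N)) {
    off <- (i - 1L) * per_state
    states[[i]] <- list(shape = exp(par[off + 1L]), rate = exp(par[off + 2L]),
                        kappa = if (has_kappa) exp(par[off + 3L]) else NULL)
    lp[, i] <- logdens(states[[i]]$shape, states[[i]]$rate, states[[i]]$kappa)
  }
  if (N > 1L) {
    tpm <- logits_to_tpm(par[N * per_state + seq_len(N * (N - 1L))], N)
    delta <- stationary_quiet(tpm)
  } else { tpm <- matrix(1, 1, 1); delta <- 1 }
  decoded <- viterbi_path(lp, tpm, delta, burst)
  structure(list(n_states = N, angle_model = angle_model,
                 states = states, tpm = tpm, delta = delta,
                 logLik = -best$value, np = npar,
                 AIC = 2 * best$value + 2 * npar,
                 BIC = 2 * best$value + npar * log(n_obs),
                 decoded = decoded, n = n_obs,
                 steps = data.frame(length = len, angle = ang, burst = burst),
                 starts = data.frame(start = seq_len(n_starts), nll = vals,
                                     converged = conv),
                 convergence = best$convergence),
            class = "movement_hmm")
}

#' @export
print.movement_hmm <- function(x, ...) {
  cat(sprintf("movement_hmm: %d state(s) on %d steps, %s angles\n",
              x$n_states, x$n, x$angle_model))
  for (i in seq_len(x$n_states)) {
    s <- x$states[[i]]
    cat(sprintf("  state %d: shape %.4g, rate %.4g%s\n", i, s$shape, s$rate,
                if (!is.null(s$kappa)) sprintf(", kappa %.4g", s$kappa) else ""))
  }
  cat(sprintf("  logLik %.3f  AIC %.2f  BIC %.2f\n", x$logLik, x$AIC, x$BIC))
  invisible(x)
}

#' @rdname viterbi
#' @export
viterbi.movement_hmm <- function(object, ...) object$decoded

#' @export
logLik.movement_hmm <- function(object, ...) {
  structure(object$logLik, df = object$np, nobs = object$n, class = "logLik")
}

#' Two-step step-selection analysis (TS-iSSA)
#'
#' The classification-based competitor: a movement HMM is fitted to the
#' steps, the Viterbi sequence splits the steps into state-specific data
#' sets, and a single-state conditional logistic iSSA is fitted per state.
#' Control steps for state s are sampled from that state's fitted gamma
#' and von Mises distributions; movement coefficients are therefore
#' corrections relative to those state-specific proposals, and the
#' recovered natural parameters account for this.
#'
#' Classification uncertainty is not propagated: the second-stage standard
#' errors and p-values treat the decoded states as known. Quantifying the
#' consequences of that assumption is exactly what comparing this
#' estimator against the joint [hmm_issa()] shows.
#'
#' @param track Track coordinates.
#' @param field A [covariate_field()].
#' @param n_states States for the first-stage HMM.
#' @param M Controls per used step in the second stage.
#' @param n_starts Starts for the first-stage HMM.
#' @param seed Integer seed.
#' @param min_steps States decoded to fewer steps than this are skipped
#'   (with a warning).
#' @param boundary Boundary policy for covariate lookup.
#' @return Object of class `ts_issa`: the first-stage `movement_hmm` and a
#'   list `fits` of per-state `hmm_issa` (N = 1) fits (`NULL` when
#'   skipped).
#' @export
ts_issa <- function(track, field, n_states = 2L, M = 100L, n_starts = 10L,
                    seed = NULL, min_steps = 30L, boundary = "toroidal") {
  if (!is.null(seed)) set.seed(seed)
  mhmm <- fit_movement_hmm(track, n_states = n_states, n_starts = n_starts)
  fits <- ts_stage2(mhmm, track, field, M = M, min_steps = min_steps,
                    boundary = boundary, seed = sample.int(2^31 - 2, 1))
  structure(list(mhmm = mhmm, fits = fits, n_states = n_states, M = M),
            class = "ts_issa")
}

# second stage of the two-step analysis given a fitted movement HMM
ts_stage2 <- function(mhmm, track, field, M, min_steps = 30L,
                      boundary = "toroidal", seed = 1L) {
  n_states <- mhmm$n_states
  decoded <- mhmm$decoded
  fits <- vector("list", n_states)
  for (s in seq_len(n_states)) {
    steps_s <- which(decoded == s & !is.na(mhmm$steps$angle))
    if (length(steps_s) < min_steps) {
      warning(sprintf("state %d has only %d decoded steps (< %d); skipping its iSSA",
                      s, length(steps_s), min_steps))
      next
    }
    st <- mhmm$states[[s]]
    prop <- ssa_proposal(st$shape, st$rate,
                         kappa0 = if (mhmm$angle_model == "von_mises") st$kappa else 0)
    cc <- build_case_control(track, field, M = M, proposal = prop,
                             seed = seed + s,
                             angle_model = mhmm$angle_model,
                             boundary = boundary, include = steps_s)
    fits[[s]] <- hmm_issa(cc, n_states = 1L, n_starts = 2L, keep_data = FALSE)
  }
  fits
}

#' @export
print.ts_issa <- function(x, ...) {
  cat(sprintf("ts_issa: two-step analysis, %d state(s), M = %d\n",
              x$n_states, x$M))
  print(x$mhmm)
  for (s in seq_len(x$n_states)) {
    cat(sprintf("-- state %d iSSA: ", s))
    if (is.null(x$fits[[s]])) cat("skipped (too few decoded steps)\n")
    else { cat("\n"); print(x$fits[[s]]) }
  }
  invisible(x)
}
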