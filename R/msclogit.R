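#' Fit a Markov-switching conditional logistic regression (HMM-iSSA)
#'
#' Jointly estimates behavioural states, state-dependent movement kernel
#' parameters and habitat-selection coefficients from a case-control data
#' set by numerical maximum likelihood. The likelihood is the hidden Markov
#' form
#' \deqn{L = \delta^\top P(\tilde x_3)\Gamma P(\tilde x_4)\Gamma\cdots\Gamma P(\tilde x_T)\mathbf{1},}
#' where \eqn{P(\tilde x_t)} is the diagonal matrix of state-dependent
#' case-control choice probabilities, evaluated with the scaled forward
#' algorithm. Bursts are treated as independent likelihood segments each
#' restarted at the initial distribution \eqn{\delta}, which is fixed to
#' the stationary distribution of the transition matrix \eqn{\Gamma}.
#'
#' Movement parameters are kept in their natural space structurally: the
#' gamma shape and rate are optimised on the log scale, so the working
#' coefficient on \eqn{\log l} is `shape - shape0` (relative to the
#' proposal) with positivity of the shape guaranteed. With `n_states = 1`
#' the model is the plain integrated step-selection analysis (iSSA) and is
#' fitted with an analytic-gradient conditional-logistic path; with
#' `use_selection = FALSE` it is the movement-HMM approximation fitted to
#' the same case-control data (the "HMM" candidate for model selection).
#'
#' Optimisation is multi-start: the first start is a deterministic
#' moment-based initialisation from an `n_states`-quantile split of the
#' used step lengths; further starts draw shape/rate/concentration
#' log-uniformly within \[1/4, 4\] times those moment estimates, selection
#' coefficients uniformly on (-2, 2) and transition-matrix diagonals
#' uniformly on (0.7, 0.95). Two converged starts within `1e-4` of each
#' other in log-likelihood count as the same optimum; the spread across
#' starts is kept as a multimodality diagnostic.
#'
#' @param data A `cc_data` object from [build_case_control()].
#' @param n_states Number of hidden states N (>= 1).
#' @param use_selection Include the habitat covariates? (`FALSE` fits the
#'   no-selection HMM candidate.)
#' @param n_starts Number of starting value sets (default 50).
#' @param seed Integer seed for the random starts.
#' @param control List of optimiser settings: `maxit` (2000), `reltol`
#'   (1e-9).
#' @param keep_data Keep the data inside the fit (needed for [viterbi()]).
#' @return An object of class `hmm_issa`; see [summary.hmm_issa()],
#'   [coef.hmm_issa()], [viterbi()], [wald_inference()].
#' @export
hmm_issa <- function(data, n_states = 2L, use_selection = TRUE,
                     n_starts = 50L, seed = NULL, control = list(),
                     keep_data = TRUE) {
  stopifnot(inherits(data, "cc_data"), n_states >= 1L, n_starts >= 1L)
  if (is.null(data$Z)) use_selection <- FALSE
  if (!is.null(seed)) set.seed(seed)
  ctrl <- utils::modifyList(list(maxit = 2000L, reltol = 1e-9), control)
  info <- fit_info(data, n_states, use_selection)
  nll <- make_nll(data, info)
  mom <- moment_init(data, n_states)
  starts <- lapply(seq_len(n_starts), function(s)
    start_values(mom, info, random = s > 1L))
  runs <- vector("list", n_starts)
  for (s in seq_len(n_starts)) {
    runs[[s]] <- tryCatch(
      run_start(starts[[s]], data, info, nll, ctrl),
      error = function(e) list(ok = FALSE, message = conditionMessage(e)))
  }
  ok <- vapply(runs, function(r) isTRUE(r$ok), logical(1))
  conv <- ok & vapply(runs, function(r) isTRUE(r$convergence == 0L), logical(1))
  if (!any(ok)) {
    stop("no start converged; per-start messages:\n",
         paste(vapply(runs, function(r) r$message %||% "ok", character(1)),
               collapse = "\n"))
  }
  vals <- vapply(runs, function(r) if (isTRUE(r$ok)) r$value else Inf, numeric(1))
  pick_from <- if (any(conv)) which(conv) else which(ok)
  best_i <- pick_from[which.min(vals[pick_from])]
  best <- runs[[best_i]]
  if (!conv[best_i]) {
    warning("best start hit the iteration cap; estimates may not be at the optimum")
  }
  starts_df <- data.frame(
    start = seq_len(n_starts),
    nll = vals,
    converged = conv,
    message = vapply(runs, function(r)
      if (isTRUE(r$ok)) "" else (r$message %||% ""), character(1)))
  H <- tryCatch(stats::optimHess(best$par, nll, control = ctrl["maxit"]),
                error = function(e) NULL)
  V <- if (!is.null(H)) tryCatch(solve(H), error = function(e) NULL) else NULL
  u <- unpack_par(best$par, info, data$proposal)
  fit <- structure(list(
    call = match.call(), n_states = n_states,
    angle_model = data$angle_model, use_selection = use_selection,
    proposal = data$proposal, M = data$M, n = data$nsets,
    par = best$par, natural = u$states, tpm = u$tpm, delta = u$delta,
    logLik = -best$value, np = length(best$par),
    AIC = 2 * best$value + 2 * length(best$par),
    BIC = 2 * best$value + length(best$par) * log(data$nsets),
    hessian = H, vcov = V, info = info,
    starts = starts_df, convergence = best$convergence,
    loglik_spread = diff(range(vals[is.finite(vals)])),
    data = if (keep_data) data else NULL), class = "hmm_issa")
  fit
}

`%||%` <- function(a, b) if (is.null(a)) b else a

fit_info <- function(data, N, use_selection) {
  p_C <- ncol(data$C)
  p_Z <- if (use_selection) ncol(data$Z) else 0L
  z_names <- if (p_Z) colnames(data$Z) else character(0)
  has_kappa <- data$angle_model == "von_mises"
  per_state <- 2L + has_kappa + p_Z
  nm <- character(0)
  for (i in seq_len(N)) {
    nm <- c(nm, paste0(c("log_shape", "log_rate",
                         if (has_kappa) "kappa",
                         if (p_Z) paste0("beta_", z_names)), ".", i))
  }
  if (N > 1L) {
    for (i in seq_len(N)) for (j in seq_len(N)) {
      if (i != j) nm <- c(nm, sprintf("tpm.%d.%d", i, j))
    }
  }
  list(N = N, p_C = p_C, p_Z = p_Z, z_names = z_names,
       has_kappa = has_kappa, per_state = per_state, par_names = nm,
       npar = N * per_state + N * (N - 1L))
}

# working parameter vector -> natural-scale pieces + proposal-relative coef
unpack_par <- function(par, info, proposal) {
  N <- info$N
  states <- vector("list", N)
  coef <- matrix(0, info$p_C + info$p_Z, N)
  for (i in seq_len(N)) {
    off <- (i - 1L) * info$per_state
    k <- exp(par[off + 1L]); r <- exp(par[off + 2L])
    kap <- if (info$has_kappa) par[off + 3L] else NULL
    beta <- if (info$p_Z) par[off + 2L + info$has_kappa + seq_len(info$p_Z)] else numeric(0)
    states[[i]] <- list(shape = unname(k), rate = unname(r),
                        kappa = unname(kap),
                        beta = stats::setNames(unname(beta), info$z_names))
    coef[, i] <- c(k - proposal$shape0, r - proposal$rate0,
                   if (info$has_kappa) kap - proposal$kappa0, beta)
  }
  if (N > 1L) {
    lg <- par[N * info$per_state + seq_len(N * (N - 1L))]
    tpm <- logits_to_tpm(lg, N)
    delta <- stationary_quiet(tpm)
  } else {
    tpm <- matrix(1, 1, 1); delta <- 1
  }
  list(states = states, coef = coef, tpm = tpm, delta = delta)
}

logits_to_tpm <- function(lg, N) {
  tpm <- diag(N)
  idx <- 1L
  for (i in seq_len(N)) {
    e <- numeric(N); e[i] <- 0
    for (j in seq_len(N)) if (i != j) { e[j] <- lg[idx]; idx <- idx + 1L }
    row <- exp(e - max(e)); row <- row / sum(row)
    tpm[i, ] <- row
  }
  tpm
}

tpm_to_logits <- function(tpm) {
  N <- nrow(tpm)
  lg <- numeric(0)
  for (i in seq_len(N)) for (j in seq_len(N)) {
    if (i != j) lg <- c(lg, log(tpm[i, j] / tpm[i, i]))
  }
  lg
}

stationary_quiet <- function(tpm) {
  N <- nrow(tpm)
  d <- tryCatch(solve(t(diag(N) - tpm + 1), rep(1, N)), error = function(e) NULL)
  if (is.null(d) || any(!is.finite(d)) || any(d < 0)) return(rep(1 / N, N))
  d / sum(d)
}

make_nll <- function(data, info) {
  X <- cbind(data$C, if (info$p_Z) data$Z)
  m1 <- data$M + 1L
  burst <- as.integer(data$burst)
  proposal <- data$proposal
  function(par) {
    u <- unpack_par(par, info, proposal)
    logp <- cc_state_logprob_cpp(X, u$coef, m1)
    hmm_forward_nll_cpp(logp, u$tpm, u$delta, burst)
  }
}

run_start <- function(par0, data, info, nll, ctrl) {
  if (info$N == 1L) {
    res <- fit_clogit_path(par0, data, info, ctrl)
  } else {
    res <- suppressWarnings(  # overflow while the optimiser probes bad regions
      fit_forward_path(par0, data, info, ctrl))
  }
  list(ok = TRUE, par = stats::setNames(res$par, info$par_names),
       value = res$value, convergence = res$convergence)
}

# N >= 2: forward-algorithm likelihood with analytic gradient. The
# coefficient gradient comes from the forward-backward state posteriors;
# the N(N-1) transition logits are differenced centrally, which only
# requires rerunning the O(T N^2) forward recursion on the cached
# choice-probability matrix.
fit_forward_path <- function(par0, data, info, ctrl) {
  X <- cbind(data$C, if (info$p_Z) data$Z)
  m1 <- data$M + 1L
  burst <- as.integer(data$burst)
  proposal <- data$proposal
  cache <- new.env(parent = emptyenv())
  eval_at <- function(par) {
    if (is.null(cache$par) || !identical(par, cache$par)) {
      u <- unpack_par(par, info, proposal)
      cache$res <- cc_nll_grad_cpp(X, u$coef, m1, u$tpm, u$delta, burst)
      cache$par <- par
    }
    cache$res
  }
  fn <- function(par) eval_at(par)$nll
  gr <- function(par) {
    res <- eval_at(par)
    g <- numeric(length(par))
    if (!isTRUE(res$ok)) return(g)
    gc <- res$grad_coef
    for (i in seq_len(info$N)) {
      off <- (i - 1L) * info$per_state
      g[off + 1L] <- gc[1L, i] * exp(par[off + 1L])  # d coef1 / d log shape
      g[off + 2L] <- gc[2L, i] * exp(par[off + 2L])
      if (info$has_kappa) g[off + 3L] <- gc[3L, i]
      if (info$p_Z) {
        g[off + 2L + info$has_kappa + seq_len(info$p_Z)] <-
          gc[2L + info$has_kappa + seq_len(info$p_Z), i]
      }
    }
    ntr <- info$N * (info$N - 1L)
    base <- info$N * info$per_state
    h <- 1e-6
    lg0 <- par[base + seq_len(ntr)]
    for (q in seq_len(ntr)) {
      vs <- vapply(c(h, -h), function(d) {
        lg <- lg0; lg[q] <- lg[q] + d
        tpm <- logits_to_tpm(lg, info$N)
        hmm_forward_nll_cpp(res$logp, tpm, stationary_quiet(tpm), burst)
      }, numeric(1))
      g[base + q] <- (vs[1] - vs[2]) / (2 * h)
    }
    g
  }
  stats::optim(par0, fn, gr, method = "BFGS",
               control = list(maxit = ctrl$maxit, reltol = ctrl$reltol))
}

# N = 1: conditional logistic regression with analytic gradient
fit_clogit_path <- function(par0, data, info, ctrl) {
  X <- cbind(data$C, if (info$p_Z) data$Z)
  m1 <- data$M + 1L
  k0 <- data$proposal$shape0; r0 <- data$proposal$rate0
  kap0 <- data$proposal$kappa0
  to_coef <- function(par) {
    c(exp(par[1]) - k0, exp(par[2]) - r0,
      if (info$has_kappa) par[3] - kap0,
      if (info$p_Z) par[2L + info$has_kappa + seq_len(info$p_Z)])
  }
  jac <- function(par) c(exp(par[1]), exp(par[2]),
                         rep(1, info$has_kappa + info$p_Z))
  # optim evaluates fn and gr at the same point; share the C++ call
  cache <- new.env(parent = emptyenv())
  eval_at <- function(par) {
    if (is.null(cache$par) || !identical(par, cache$par)) {
      cache$res <- cc_clogit_nll_grad_cpp(X, to_coef(par), m1)
      cache$par <- par
    }
    cache$res
  }
  fn <- function(par) eval_at(par)$nll
  gr <- function(par) eval_at(par)$grad * jac(par)
  stats::optim(par0, fn, gr, method = "BFGS",
               control = list(maxit = ctrl$maxit, reltol = ctrl$reltol))
}

# moment-based initialisation from an N-quantile split of used step lengths
moment_init <- function(data, N) {
  m1 <- data$M + 1L
  used <- seq(1L, data$nsets * m1, by = m1)
  len <- -data$C[used, "neg_l"]
  cosa <- if ("cos_a" %in% colnames(data$C)) data$C[used, "cos_a"] else NULL
  grp <- if (N == 1L) rep(1L, length(len)) else {
    cut(len, breaks = stats::quantile(len, probs = seq(0, 1, length.out = N + 1)),
        labels = FALSE, include.lowest = TRUE)
  }
  out <- vector("list", N)
  for (i in seq_len(N)) {
    li <- len[grp == i]
    m <- mean(li); v <- stats::var(li)
    k <- max(m^2 / v, 0.05); r <- max(m / v, 1e-3)
    kap <- 0.5
    if (!is.null(cosa)) {
      Rbar <- max(mean(cosa[grp == i]), 0.01)
      kap <- if (Rbar < 0.53) 2 * Rbar + Rbar^3 + 5 * Rbar^5 / 6
             else if (Rbar < 0.85) -0.4 + 1.39 * Rbar + 0.43 / (1 - Rbar)
             else 1 / (Rbar^3 - 4 * Rbar^2 + 3 * Rbar)
      kap <- max(kap, 0.05)
    }
    out[[i]] <- c(shape = k, rate = r, kappa = kap)
  }
  out
}

start_values <- function(mom, info, random) {
  N <- info$N
  par <- numeric(0)
  for (i in seq_len(N)) {
    f <- function(x) if (random) x * exp(stats::runif(1, log(1 / 4), log(4))) else x
    par <- c(par, log(f(mom[[i]]["shape"])), log(f(mom[[i]]["rate"])))
    if (info$has_kappa) par <- c(par, f(mom[[i]]["kappa"]))
    if (info$p_Z) {
      par <- c(par, if (random) stats::runif(info$p_Z, -2, 2) else rep(0, info$p_Z))
    }
  }
  if (N > 1L) {
    for (i in seq_len(N)) {
      d <- if (random) stats::runif(1, 0.7, 0.95) else 0.9
      par <- c(par, rep(log((1 - d) / (N - 1L) / d), N - 1L))
    }
  }
  stats::setNames(par, info$par_names)
}

#' Forward-algorithm log-likelihood of a model on case-control data
#'
#' Evaluates the Markov-switching conditional logistic log-likelihood of a
#' natural-scale model on a case-control data set (the quantity maximised
#' by [hmm_issa()]). Movement coefficients are taken relative to the data's
#' proposal distribution.
#'
#' @param data A `cc_data` object.
#' @param model A [hmm_issa_model()] whose `angle_model` and covariate
#'   dimension match `data`.
#' @return Log-likelihood (numeric scalar).
#' @export
cc_loglik <- function(data, model) {
  stopifnot(inherits(data, "cc_data"), inherits(model, "hmm_issa_model"),
            model$angle_model == data$angle_model)
  coef <- model_coef_matrix(model, data$proposal)
  X <- cbind(data$C, if (model$n_covariates > 0L) data$Z)
  logp <- cc_state_logprob_cpp(X, coef, data$M + 1L)
  -hmm_forward_nll_cpp(logp, model$tpm, model$delta, as.integer(data$burst))
}

model_coef_matrix <- function(model, proposal) {
  has_kappa <- model$angle_model == "von_mises"
  vapply(model$states, function(s) {
    c(s$shape - proposal$shape0, s$rate - proposal$rate0,
      if (has_kappa) s$kappa - proposal$kappa0, s$beta)
  }, numeric(2L + has_kappa + model$n_covariates))
}

#' State-dependent log choice probabilities of one choice set
#'
#' Computes \eqn{\log p_{0,t,i} = w_0 - \mathrm{logsumexp}(w_0,\dots,w_M)}
#' for each state, with \eqn{w_m = C_m^\top\theta_i + Z_m^\top\beta_i}
#' (movement coefficients relative to the proposal).
#'
#' @param C Movement covariate matrix of the choice set ((M+1) x p_C, row
#'   1 = used step).
#' @param Z Habitat covariate matrix ((M+1) x p_Z) or `NULL`.
#' @param model A [hmm_issa_model()].
#' @param proposal An [ssa_proposal()].
#' @return Numeric vector of length N with the log probabilities.
#' @export
choice_log_probabilities <- function(C, Z = NULL, model, proposal) {
  stopifnot(inherits(model, "hmm_issa_model"))
  vapply(model$states, function(s) {
    w <- log_step_weight(C, Z, s, model$angle_model,
                         proposal_adjusted = TRUE, proposal = proposal)
    if (any(!is.finite(w))) stop("non-finite choice-set weight")
    w[1] - logsumexp(w)
  }, numeric(1))
}

logsumexp <- function(x) {
  m <- max(x)
  m + log(sum(exp(x - m)))
}

#' Viterbi decoding of the hidden state sequence
#'
#' Computes the jointly most likely state sequence given a fitted model
#' and its case-control data, by log-space dynamic programming. Ties are
#' broken toward the lower state index; bursts are decoded independently.
#'
#' @param object A fitted `hmm_issa` or `movement_hmm` object.
#' @param data Case-control data (defaults to the data stored in the fit).
#' @param ... Unused.
#' @return Integer vector of decoded states, one per choice set (aligned
#'   to steps 2..T-1 of the track), with attribute `"step"` giving the
#'   step index of each entry.
#' @export
viterbi <- function(object, ...) UseMethod("viterbi")

#' @rdname viterbi
#' @export
viterbi.hmm_issa <- function(object, data = NULL, ...) {
  data <- data %||% object$data
  if (is.null(data)) stop("no data stored in the fit; supply `data`")
  u <- unpack_par(object$par, object$info, data$proposal)
  X <- cbind(data$C, if (object$info$p_Z) data$Z)
  logp <- cc_state_logprob_cpp(X, u$coef, data$M + 1L)
  out <- viterbi_path(logp, u$tpm, u$delta, data$burst)
  attr(out, "step") <- data$step
  out
}

#' @rdname viterbi
#' @export
viterbi.hmm_issa_model <- function(object, data, ...) {
  stopifnot(inherits(data, "cc_data"))
  coef <- model_coef_matrix(object, data$proposal)
  X <- cbind(data$C, if (object$n_covariates > 0L) data$Z)
  logp <- cc_state_logprob_cpp(X, coef, data$M + 1L)
  out <- viterbi_path(logp, object$tpm, object$delta, data$burst)
  attr(out, "step") <- data$step
  out
}

# generic log-space Viterbi DP over rows of logp; restarts per burst
viterbi_path <- function(logp, tpm, delta, burst) {
  n <- nrow(logp); N <- ncol(logp)
  if (N == 1L) return(rep(1L, n))
  lG <- log(tpm); ld <- log(delta)
  states <- integer(n)
  xi <- matrix(0, n, N); back <- matrix(0L, n, N)
  for (s in seq_len(n)) {
    if (s == 1L || burst[s] != burst[s - 1L]) {
      xi[s, ] <- ld + logp[s, ]
      back[s, ] <- 0L
    } else {
      cand <- xi[s - 1L, ] + lG  # cand[i, j]
      best <- apply(cand, 2L, which.max)  # first max = lower index
      xi[s, ] <- cand[cbind(best, seq_len(N))] + logp[s, ]
      back[s, ] <- best
    }
  }
  # trace back within bursts
  ends <- c(which(diff(burst) != 0), n)
  starts <- c(1L, utils::head(ends, -1L) + 1L)
  for (b in seq_along(ends)) {
    e <- ends[b]
    states[e] <- which.max(xi[e, ])
    if (e > starts[b]) for (s in (e - 1L):starts[b]) {
      states[s] <- back[s + 1L, states[s + 1L]]
    }
  }
  states
}

#' Wald inference for the selection coefficients
#'
#' Standard errors from the inverse observed information (numerical Hessian
#' of the negative log-likelihood at the optimum, working scale) and
#' two-sided normal-approximation p-values. Selection coefficients are
#' identical on the working and natural scales, so their Wald tests are
#' reported directly; set `all = TRUE` to also list the movement and
#' transition parameters with working-scale standard errors (no p-values).
#'
#' @param fitted An `hmm_issa` fit.
#' @param all Report all working parameters instead of only the selection
#'   coefficients?
#' @return Data frame with columns `term`, `state`, `estimate`, `se`, `z`,
#'   `p_value`.
#' @export
wald_inference <- function(fitted, all = FALSE) {
  stopifnot(inherits(fitted, "hmm_issa"))
  V <- fitted$vcov
  if (is.null(V) || any(!is.finite(diag(V))) || any(diag(V) < 0)) {
    warning("observed information is singular or unavailable; reporting NA standard errors")
    se <- rep(NA_real_, fitted$np)
  } else {
    se <- sqrt(diag(V))
  }
  nm <- names(fitted$par)
  is_beta <- startsWith(nm, "beta_")
  df <- data.frame(term = sub("\\.[0-9]+$", "", nm),
                   state = ifelse(grepl("^tpm", nm), NA,
                                  as.integer(sub("^.*\\.", "", nm))),
                   estimate = unname(fitted$par), se = se)
  df$z <- ifelse(is_beta, df$estimate / df$se, NA_real_)
  df$p_value <- ifelse(is_beta, 2 * stats::pnorm(-abs(df$z)), NA_real_)
  if (!all) df <- df[is_beta, , drop = FALSE]
  rownames(df) <- NULL
  df
}

#' Information criteria of a fit
#'
#' AIC = -2 logL + 2 p and BIC = -2 logL + p log(n) with p the number of
#' estimated working parameters and n the number of choice sets. Also
#' available through [stats::AIC()]/[stats::BIC()] via the [logLik()]
#' method.
#'
#' @param fitted An `hmm_issa` or `movement_hmm` fit.
#' @return Named numeric vector `c(AIC, BIC)`.
#' @export
information_criteria <- function(fitted) {
  c(AIC = fitted$AIC, BIC = fitted$BIC)
}

#' @export
logLik.hmm_issa <- function(object, ...) {
  structure(object$logLik, df = object$np, nobs = object$n, class = "logLik")
}

#' @export
vcov.hmm_issa <- function(object, ...) object$vcov

#' Extract coefficients from an HMM-iSSA fit
#'
#' @param object An `hmm_issa` fit.
#' @param type `"natural"` (per-state shape, rate, concentration and
#'   selection coefficients) or `"working"` (the optimised parameter
#'   vector).
#' @param ... Unused.
#' @return For `"natural"`, a matrix with one column per state; for
#'   `"working"`, a named numeric vector.
#' @export
coef.hmm_issa <- function(object, type = c("natural", "working"), ...) {
  type <- match.arg(type)
  if (type == "working") return(object$par)
  rows <- c("shape", "rate", if (object$info$has_kappa) "kappa",
            if (object$info$p_Z) paste0("beta_", object$info$z_names))
  out <- vapply(object$natural, function(s) {
    c(s$shape, s$rate, if (object$info$has_kappa) s$kappa, s$beta)
  }, numeric(length(rows)))
  out <- matrix(out, nrow = length(rows),
                dimnames = list(rows, paste0("state", seq_len(object$n_states))))
  out
}

#' @export
print.hmm_issa <- function(x, ...) {
  kind <- if (x$n_states == 1L) {
    "iSSA (single-state conditional logistic)"
  } else if (!x$use_selection) {
    sprintf("%d-state movement HMM (no selection, case-control form)", x$n_states)
  } else {
    sprintf("%d-state HMM-iSSA", x$n_states)
  }
  cat(kind, "\n", sep = "")
  cat(sprintf("  %d choice sets (1 used + %d controls), %s angles\n",
              x$n, x$M, x$angle_model))
  cat(sprintf("  logLik %.3f  (np = %d)  AIC %.2f  BIC %.2f\n",
              x$logLik, x$np, x$AIC, x$BIC))
  cat("  natural-scale estimates:\n")
  print(round(coef(x), 4))
  if (x$n_states > 1L) {
    cat("  transition probability matrix:\n")
    print(round(x$tpm, 3))
  }
  invisible(x)
}

#' Summarise an HMM-iSSA fit
#'
#' @param object An `hmm_issa` fit.
#' @param ... Unused.
#' @return A `summary.hmm_issa` object: the fit plus the Wald table for
#'   the selection coefficients and start-value diagnostics.
#' @export
summary.hmm_issa <- function(object, ...) {
  structure(list(fit = object,
                 wald = if (object$use_selection) wald_inference(object) else NULL,
                 n_converged = sum(object$starts$converged),
                 n_starts = nrow(object$starts),
                 loglik_spread = object$loglik_spread),
            class = "summary.hmm_issa")
}

#' @export
print.summary.hmm_issa <- function(x, ...) {
  print(x$fit)
  if (!is.null(x$wald)) {
    cat("  selection coefficients (Wald):\n")
    print(cbind(x$wald[c("term", "state")],
                round(x$wald[c("estimate", "se", "z", "p_value")], 4)))
  }
  cat(sprintf("  starts: %d/%d converged, log-likelihood spread %.3g\n",
              x$n_converged, x$n_starts, x$loglik_spread))
  invisible(x)
}

#' Plot the fitted state-dependent step-length distributions
#'
#' Draws the estimated gamma step-length densities per state over a
#' histogram of the observed (used) step lengths.
#'
#' @param x An `hmm_issa` fit with stored data.
#' @param ... Passed to [graphics::hist()].
#' @export
plot.hmm_issa <- function(x, ...) {
  if (is.null(x$data)) stop("no data stored in the fit")
  m1 <- x$data$M + 1L
  used <- seq(1L, x$data$nsets * m1, by = m1)
  len <- -x$data$C[used, "neg_l"]
  graphics::hist(len, freq = FALSE, breaks = 40, col = "grey90",
                 main = "State-dependent step-length distributions",
                 xlab = "step length", ...)
  xs <- seq(1e-6, max(len), length.out = 400)
  for (i in seq_len(x$n_states)) {
    st <- x$natural[[i]]
    graphics::lines(xs, x$delta[i] * stats::dgamma(xs, st$shape, st$rate),
                    col = i + 1, lwd = 2)
  }
  graphics::legend("topright", legend = paste("state", seq_len(x$n_states)),
                   col = seq_len(x$n_states) + 1, lwd = 2, bty = "n")
  invisible(x)
}

#' Serialise a fit to JSON
#'
#' Writes natural and working estimates, log-likelihood, information
#' criteria, standard errors and the convergence log to a JSON document.
#'
#' @param fit An `hmm_issa` fit.
#' @param path File path.
#' @return `path`, invisibly.
#' @export
write_fit_json <- function(fit, path) {
  stopifnot(inherits(fit, "hmm_issa"))
  se <- if (!is.null(fit$vcov)) sqrt(pmax(diag(fit$vcov), 0)) else NULL
  doc <- list(
    model = if (fit$n_states == 1L) "iSSA"
            else if (!fit$use_selection) "HMM (no selection)" else "HMM-iSSA",
    n_states = fit$n_states, angle_model = fit$angle_model,
    M = fit$M, n_choice_sets = fit$n,
    proposal = unclass(fit$proposal),
    natural = fit$natural, tpm = fit$tpm, delta = fit$delta,
    working = as.list(fit$par),
    se_working = if (!is.null(se)) as.list(stats::setNames(se, names(fit$par))),
    logLik = fit$logLik, np = fit$np, AIC = fit$AIC, BIC = fit$BIC,
    selection_wald = if (fit$use_selection) wald_inference(fit),
    starts = fit$starts)
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
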