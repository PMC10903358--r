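#' Simulation-study scenario definitions
#'
#' The four data-generating scenarios of the comparison study. Scenarios
#' 1-3 are 2-state hidden Markov step-selection models with transition
#' probabilities \eqn{\gamma_{11} = \gamma_{22} = 0.9}:
#' \describe{
#'   \item{1 (active-inactive)}{state 1: beta 0, shape 1.20, rate 1.25,
#'     kappa 0.30; state 2: beta 2, shape 2.50, rate 0.29, kappa 1.00.}
#'   \item{2 (switching preferences)}{shared kernel (2.50, 0.29, 1.00);
#'     beta -2 in state 1, +2 in state 2.}
#'   \item{3 (HMM)}{kernels as scenario 1; beta 0 in both states.}
#'   \item{4 (iSSA)}{single state, beta 2, kernel (2.50, 0.29, 1.00).}
#' }
#' The habitat covariate is a Gaussian random field with variance 1 and
#' range 10 on a 100 x 100 unit-resolution grid.
#'
#' @param id Scenario id in 1..4.
#' @return Object of class `sim_scenario`: list with `id`, `label`,
#'   `model` (a [hmm_issa_model()]), `grf` (a [grf_config()]) and `truth`
#'   (data frame of true parameter values per state and term).
#' @export
scenario_parameters <- function(id) {
  stopifnot(length(id) == 1L, id %in% 1:4)
  tpm2 <- matrix(c(0.9, 0.1, 0.1, 0.9), 2, 2, byrow = TRUE)
  spec <- switch(as.character(id),
    "1" = list(label = "active-inactive",
               states = list(list(shape = 1.20, rate = 1.25, kappa = 0.30, beta = 0),
                             list(shape = 2.50, rate = 0.29, kappa = 1.00, beta = 2))),
    "2" = list(label = "switching preferences",
               states = list(list(shape = 2.50, rate = 0.29, kappa = 1.00, beta = -2),
                             list(shape = 2.50, rate = 0.29, kappa = 1.00, beta = 2))),
    "3" = list(label = "HMM",
               states = list(list(shape = 1.20, rate = 1.25, kappa = 0.30, beta = 0),
                             list(shape = 2.50, rate = 0.29, kappa = 1.00, beta = 0))),
    "4" = list(label = "iSSA",
               states = list(list(shape = 2.50, rate = 0.29, kappa = 1.00, beta = 2))))
  N <- length(spec$states)
  model <- hmm_issa_model(tpm = if (N == 2L) tpm2 else matrix(1, 1, 1),
                          states = spec$states, angle_model = "von_mises")
  truth <- do.call(rbind, lapply(seq_len(N), function(i) {
    s <- spec$states[[i]]
    data.frame(state = i,
               term = c("shape", "rate", "kappa", "beta_z"),
               truth = c(s$shape, s$rate, s$kappa, s$beta))
  }))
  structure(list(id = id, label = spec$label, model = model,
                 grf = grf_config(nx = 100L, ny = 100L, variance = 1,
                                  range = 10, resolution = 1),
                 truth = truth),
            class = "sim_scenario")
}

#' @export
print.sim_scenario <- function(x, ...) {
  cat(sprintf("sim_scenario %d (%s)\n", x$id, x$label))
  print(x$model)
  invisible(x)
}

#' State misclassification rate after optimal label permutation
#'
#' Percentage of decoded states differing from the true simulated states,
#' minimised over all permutations of the state labels (the likelihood is
#' invariant to label switching, so decoded labels are arbitrary).
#'
#' @param decoded,truth Integer state sequences of equal length.
#' @return Misclassification rate in percent.
#' @seealso [align_states()] for the permutation itself.
#' @export
misclassification_rate <- function(decoded, truth) {
  align_states(decoded, truth)$rate
}

#' Optimal label alignment of a decoded state sequence
#'
#' @param decoded,truth Integer state sequences of equal length.
#' @return List with `rate` (misclassification percent) and `perm`
#'   (integer vector: decoded label j corresponds to true label
#'   `perm[j]`).
#' @export
align_states <- function(decoded, truth) {
  stopifnot(length(decoded) == length(truth))
  N <- max(decoded, truth)
  perms <- all_permutations(N)
  best <- NULL; best_rate <- Inf
  for (p in perms) {
    rate <- 100 * mean(p[decoded] != truth)
    if (rate < best_rate) { best_rate <- rate; best <- p }
  }
  list(rate = best_rate, perm = best)
}

all_permutations <- function(N) {
  if (N == 1L) return(list(1L))
  out <- list()
  for (i in seq_len(N)) {
    for (rest in all_permutations(N - 1L)) {
      out[[length(out) + 1L]] <- c(i, ifelse(rest >= i, rest + 1L, rest))
    }
  }
  out
}

#' Run the simulation study
#'
#' For each simulation run a fresh habitat field and track are simulated
#' from the scenario's model, a tentative gamma proposal is fitted to the
#' observed step lengths, case-control data are built at each requested
#' number of controls M, and the requested estimators are fitted:
#' \describe{
#'   \item{`issa`}{single-state iSSA (conditional logistic).}
#'   \item{`hmm_issa`}{the joint 2-state Markov-switching fit.}
#'   \item{`hmm_nosel`}{the HMM-iSSA without habitat covariates (the
#'     movement-HMM approximation on the same case-control data), used as
#'     the third candidate in AIC/BIC model selection.}
#'   \item{`mhmm`}{the movement HMM fitted directly to steps.}
#'   \item{`ts_issa`}{the two-step analysis.}
#' }
#' Per run and method the natural-scale estimates (label-aligned against
#' the simulation truth), Wald p-values of the selection coefficients,
#' AIC/BIC and the Viterbi misclassification rate are recorded.
#'
#' @param scenario A [scenario_parameters()] object or scenario id.
#' @param tasks Data frame with columns `method`, `M`, `n_runs`; method
#'   `m` is fitted at `M` controls in runs `1..n_runs`. `M` is ignored for
#'   `mhmm`.
#' @param T Track length (locations) per run.
#' @param K Candidate steps of the importance-resampling simulator.
#' @param n_starts Starting value sets per likelihood optimisation.
#' @param seed Master seed; runs derive independent sub-seeds from it, so
#'   the per-run records do not depend on which other tasks are requested.
#' @param verbose Print progress?
#' @return Object of class `sim_study` with data frames `fits` (one row
#'   per run x method x M) and `params` (one row per estimated parameter),
#'   aggregated by [summarize_significance()],
#'   [summarize_misclassification()], [summarize_model_selection()] and
#'   [summarize_bias()].
#' @export
run_simulation_study <- function(scenario, tasks, T = 1000L, K = 1000L,
                                 n_starts = 3L, seed = 1L, verbose = FALSE) {
  if (!inherits(scenario, "sim_scenario")) scenario <- scenario_parameters(scenario)
  stopifnot(is.data.frame(tasks), all(c("method", "M", "n_runs") %in% names(tasks)))
  bad <- setdiff(tasks$method, c("issa", "hmm_issa", "hmm_nosel", "mhmm", "ts_issa"))
  if (length(bad)) stop("unknown method(s): ", paste(bad, collapse = ", "))
  n_total <- max(tasks$n_runs)
  fits <- list(); params <- list()
  for (r in seq_len(n_total)) {
    rs <- (seed %% 100000L) * 20000L + scenario$id * 5000L + 13L * r
    if (verbose) message(sprintf("scenario %d run %d/%d", scenario$id, r, n_total))
    field <- simulate_grf(scenario$grf, seed = rs, method = "fft")
    sim <- simulate_track(scenario$model, field, T = T, K = K, seed = rs + 1L)
    truth <- sim$states
    steps <- steps_from_track(sim$track[c("x", "y")])
    proposal <- fit_tentative_gamma(steps$length)
    active <- tasks[tasks$n_runs >= r, , drop = FALSE]
    if (nrow(active) == 0L) next
    cc_cache <- list()
    get_cc <- function(M) {
      key <- as.character(M)
      if (is.null(cc_cache[[key]])) {
        cc_cache[[key]] <<- build_case_control(sim$track[c("x", "y")], field,
                                               M = M, proposal = proposal,
                                               seed = rs + 2L)
      }
      cc_cache[[key]]
    }
    mh <- NULL
    if (any(active$method %in% c("mhmm", "ts_issa"))) {
      mh <- tryCatch(fit_movement_hmm(sim$track[c("x", "y")],
                                      n_states = scenario$model$n_states,
                                      n_starts = n_starts, seed = rs + 3L),
                     error = function(e) NULL)
    }
    for (a in seq_len(nrow(active))) {
      method <- active$method[a]; M <- active$M[a]
      rec <- tryCatch(
        run_one_method(method, M, scenario, sim, truth, field, proposal,
                       get_cc, mh, n_starts, rs),
        error = function(e) list(
          fit = data.frame(run = r, method = method, M = M, n_states = NA,
                           logLik = NA, np = NA, AIC = NA, BIC = NA,
                           misclass = NA, converged = FALSE),
          par = NULL))
      rec$fit$run <- r
      fits[[length(fits) + 1L]] <- rec$fit
      if (!is.null(rec$par) && nrow(rec$par)) {
        rec$par$run <- r
        params[[length(params) + 1L]] <- rec$par
      }
    }
  }
  fits <- do.call(rbind, fits)
  params <- if (length(params)) do.call(rbind, params) else NULL
  fits$scenario <- scenario$id
  if (!is.null(params)) params$scenario <- scenario$id
  structure(list(scenario = scenario, tasks = tasks, T = T, K = K,
                 seed = seed, fits = fits, params = params),
            class = "sim_study")
}

run_one_method <- function(method, M, scenario, sim, truth, field, proposal,
                           get_cc, mh, n_starts, rs) {
  T_ <- nrow(sim$track)
  if (method == "mhmm") {
    if (is.null(mh)) stop("movement HMM failed")
    al <- align_states(mh$decoded, truth)
    M <- 0L  # fitted to steps directly; no control steps involved
    fitrow <- data.frame(run = NA, method = method, M = M,
                         n_states = mh$n_states, logLik = mh$logLik,
                         np = mh$np, AIC = mh$AIC, BIC = mh$BIC,
                         misclass = al$rate,
                         converged = mh$convergence == 0L)
    par <- do.call(rbind, lapply(seq_len(mh$n_states), function(j) {
      s <- mh$states[[j]]
      data.frame(run = NA, method = method, M = M,
                 state = al$perm[j],
                 term = c("shape", "rate", "kappa"),
                 estimate = c(s$shape, s$rate, s$kappa),
                 se = NA_real_, p_value = NA_real_)
    }))
    return(list(fit = fitrow, par = par))
  }
  if (method == "ts_issa") {
    if (is.null(mh)) stop("movement HMM failed")
    al <- align_states(mh$decoded, truth)
    fits2 <- suppressWarnings(
      ts_stage2(mh, sim$track[c("x", "y")], field, M = M, seed = rs + 7L))
    ll <- NA_real_
    par <- list()
    for (j in seq_along(fits2)) {
      f <- fits2[[j]]
      if (is.null(f)) next
      par[[length(par) + 1L]] <- natural_param_rows(f, method, M, al$perm[j])
    }
    fitrow <- data.frame(run = NA, method = method, M = M,
                         n_states = mh$n_states, logLik = NA_real_,
                         np = NA_integer_, AIC = NA_real_, BIC = NA_real_,
                         misclass = al$rate,
                         converged = !all(vapply(fits2, is.null, logical(1))))
    return(list(fit = fitrow, par = do.call(rbind, par)))
  }
  cc <- get_cc(M)
  fit <- switch(method,
    issa = hmm_issa(cc, n_states = 1L, n_starts = n_starts,
                    seed = rs + 4L, keep_data = TRUE),
    hmm_issa = hmm_issa(cc, n_states = scenario$model$n_states,
                        n_starts = n_starts, seed = rs + 5L, keep_data = TRUE),
    hmm_nosel = hmm_issa(cc, n_states = scenario$model$n_states,
                         use_selection = FALSE, n_starts = n_starts,
                         seed = rs + 6L, keep_data = TRUE))
  if (fit$n_states > 1L) {
    dec <- viterbi(fit)
    al <- align_states(dec, truth[2:(T_ - 1L)])
    rate <- al$rate; perm <- al$perm
  } else {
    rate <- NA_real_; perm <- 1L
  }
  fitrow <- data.frame(run = NA, method = method, M = M,
                       n_states = fit$n_states, logLik = fit$logLik,
                       np = fit$np, AIC = fit$AIC, BIC = fit$BIC,
                       misclass = rate, converged = fit$convergence == 0L)
  par <- do.call(rbind, lapply(seq_len(fit$n_states), function(j) {
    natural_param_rows_state(fit, j, method, M,
                             if (fit$n_states > 1L) perm[j] else 0L)
  }))
  list(fit = fitrow, par = par)
}

# parameter rows of a single-state (N = 1) fit, labelled `state`
natural_param_rows <- function(fit, method, M, state) {
  natural_param_rows_state(fit, 1L, method, M, state)
}

natural_param_rows_state <- function(fit, j, method, M, state) {
  s <- fit$natural[[j]]
  terms <- c("shape", "rate",
             if (fit$info$has_kappa) "kappa",
             if (fit$info$p_Z) paste0("beta_", fit$info$z_names))
  est <- c(s$shape, s$rate, if (fit$info$has_kappa) s$kappa, s$beta)
  se <- p <- rep(NA_real_, length(terms))
  if (fit$info$p_Z) {
    w <- wald_inference(fit)
    w <- w[w$state == j, , drop = FALSE]
    idx <- match(w$term, terms)
    se[idx] <- w$se; p[idx] <- w$p_value
  }
  data.frame(run = NA, method = method, M = M, state = state,
             term = terms, estimate = est, se = se, p_value = p)
}

#' @export
print.sim_study <- function(x, ...) {
  cat(sprintf("sim_study: scenario %d (%s), T = %d, seed = %d\n",
              x$scenario$id, x$scenario$label, x$T, x$seed))
  tab <- stats::aggregate(run ~ method + M, x$fits, function(z) length(unique(z)))
  names(tab)[3] <- "runs"
  print(tab)
  invisible(x)
}

#' Aggregate simulation-study results
#'
#' `summarize_significance` gives the percentage of runs with Wald
#' p < `alpha` per selection coefficient; `summarize_misclassification`
#' the mean (sd) Viterbi misclassification per method;
#' `summarize_model_selection` the percentage of runs each candidate
#' (iSSA / no-selection HMM / HMM-iSSA) wins by AIC and by BIC;
#' `summarize_bias` the mean estimate minus truth per parameter after
#' label alignment. All are pure functions of the per-run records.
#'
#' @param study A `sim_study` object.
#' @param alpha Significance level.
#' @return A data frame.
#' @export
summarize_significance <- function(study, alpha = 0.05) {
  p <- study$params
  p <- p[startsWith(p$term, "beta_") & !is.na(p$p_value), , drop = FALSE]
  if (!nrow(p)) return(NULL)
  out <- stats::aggregate(p_value ~ method + M + state + term, p,
                          function(z) 100 * mean(z < alpha), na.action = NULL)
  names(out)[names(out) == "p_value"] <- "pct_significant"
  n <- stats::aggregate(p_value ~ method + M + state + term, p, length,
                        na.action = NULL)
  out$n_runs <- n$p_value
  out[order(out$method, out$M, out$state), ]
}

#' @rdname summarize_significance
#' @export
summarize_misclassification <- function(study) {
  f <- study$fits[!is.na(study$fits$misclass), , drop = FALSE]
  if (!nrow(f)) return(NULL)
  mean_tab <- stats::aggregate(misclass ~ method + M, f, mean, na.action = NULL)
  sd_tab <- stats::aggregate(misclass ~ method + M, f, stats::sd, na.action = NULL)
  n_tab <- stats::aggregate(misclass ~ method + M, f, length, na.action = NULL)
  out <- mean_tab
  names(out)[3] <- "mean"
  out$sd <- sd_tab$misclass
  out$n_runs <- n_tab$misclass
  out
}

#' @rdname summarize_significance
#' @export
summarize_model_selection <- function(study) {
  f <- study$fits
  cand <- c("issa", "hmm_nosel", "hmm_issa")
  f <- f[f$method %in% cand & !is.na(f$AIC), , drop = FALSE]
  if (!nrow(f)) return(NULL)
  out <- list()
  for (M in sort(unique(f$M))) {
    fM <- f[f$M == M, , drop = FALSE]
    runs <- Reduce(intersect, lapply(cand, function(m) fM$run[fM$method == m]))
    if (!length(runs)) next
    winner <- function(crit) {
      vapply(runs, function(r) {
        v <- vapply(cand, function(m)
          fM[[crit]][fM$method == m & fM$run == r][1], numeric(1))
        cand[which.min(v)]
      }, character(1))
    }
    wa <- winner("AIC"); wb <- winner("BIC")
    out[[length(out) + 1L]] <- data.frame(
      M = M, candidate = cand,
      pct_AIC = 100 * vapply(cand, function(m) mean(wa == m), numeric(1)),
      pct_BIC = 100 * vapply(cand, function(m) mean(wb == m), numeric(1)),
      n_runs = length(runs))
  }
  do.call(rbind, out)
}

#' @rdname summarize_significance
#' @export
summarize_bias <- function(study) {
  p <- study$params
  p <- p[!is.na(p$estimate), , drop = FALSE]
  truth <- study$scenario$truth
  p <- merge(p, truth, by = c("state", "term"))
  if (!nrow(p)) return(NULL)
  p$err <- p$estimate - p$truth
  out <- stats::aggregate(err ~ method + M + state + term, p, mean,
                          na.action = NULL)
  names(out)[names(out) == "err"] <- "bias"
  n <- stats::aggregate(err ~ method + M + state + term, p, length,
                        na.action = NULL)
  out$n_runs <- n$err
  out[order(out$method, out$M, out$state, out$term), ]
}
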