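#' Proposal distribution for control steps
#'
#' Control steps are drawn in polar coordinates from a gamma proposal for
#' step length and (by default) a uniform proposal for turning angle.
#' Fitted movement coefficients are corrections relative to these tentative
#' parameters (see [recover_movement_parameters()]). A von Mises angle
#' proposal with concentration `kappa0` (mean 0) is used by the two-step
#' analysis, which samples controls from state-specific fitted kernels.
#'
#' @param shape0,rate0 Tentative gamma shape and rate (> 0).
#' @param kappa0 Angle-proposal von Mises concentration (0 = uniform).
#' @return An object of class `ssa_proposal`.
#' @export
ssa_proposal <- function(shape0, rate0, kappa0 = 0) {
  stopifnot(shape0 > 0, rate0 > 0, kappa0 >= 0)
  structure(list(shape0 = shape0, rate0 = rate0, kappa0 = kappa0),
            class = "ssa_proposal")
}

#' @export
print.ssa_proposal <- function(x, ...) {
  cat(sprintf("ssa_proposal: gamma(shape %.4g, rate %.4g), %s angles\n",
              x$shape0, x$rate0,
              if (x$kappa0 > 0) sprintf("von Mises(kappa %.4g)", x$kappa0)
              else "uniform"))
  invisible(x)
}

#' Tentative gamma parameters from observed step lengths
#'
#' Maximum-likelihood gamma fit to the pooled observed step lengths,
#' used as the proposal distribution for drawing control steps. Falls back
#' to method-of-moments estimates (with a warning) if the MLE does not
#' converge.
#'
#' @param lengths Positive step lengths (at least 10).
#' @return An [ssa_proposal()] with uniform angle proposal.
#' @export
fit_tentative_gamma <- function(lengths) {
  stopifnot(length(lengths) >= 10L, all(lengths > 0), all(is.finite(lengths)))
  if (stats::var(lengths) < 1e-12 * mean(lengths)^2) {
    # (near-)constant sample: gamma MLE diverges; use a sharply peaked proposal
    warning("step lengths are (near-)constant; gamma MLE is degenerate, ",
            "using a sharply concentrated proposal")
    return(ssa_proposal(1e6, 1e6 / mean(lengths)))
  }
  mom <- c(shape = mean(lengths)^2 / stats::var(lengths),
           rate = mean(lengths) / stats::var(lengths))
  est <- tryCatch(
    suppressWarnings(MASS::fitdistr(lengths, "gamma", start = as.list(mom),
                                    lower = c(1e-8, 1e-8))$estimate),
    error = function(e) NULL)
  if (is.null(est) || any(!is.finite(est)) || any(est <= 0)) {
    if (any(!is.finite(mom)) || any(mom <= 0)) {
      stop("could not obtain gamma proposal parameters (degenerate lengths)")
    }
    warning("gamma MLE did not converge; using method-of-moments estimates")
    est <- mom
  }
  ssa_proposal(est[[1]], est[[2]])
}

#' Build a case-control data set from a track
#'
#' For every step with a defined turning angle (steps 2..T-1 of each burst)
#' a choice set of the used step plus `M` control steps is formed. Controls
#' are drawn from the proposal distribution as (length, angle) pairs,
#' converted to endpoints using the step's start point and the observed
#' previous heading, and habitat covariates are extracted at the endpoints.
#' Row 0 of each choice set is the used step.
#'
#' Control draws use per-choice-set substreams derived from `seed` by a
#' counter, so increasing `M` extends each choice set without reshuffling
#' earlier draws.
#'
#' @param track Track coordinates (see [steps_from_track()]); a data frame
#'   may carry a `burst` column marking independent segments.
#' @param field A [covariate_field()] (or `NULL` for no habitat covariate).
#' @param M Number of control steps per used step (>= 1).
#' @param proposal An [ssa_proposal()]; defaults to [fit_tentative_gamma()]
#'   on the observed lengths.
#' @param seed Integer master seed for the control draws.
#' @param angle_model `"von_mises"` (movement covariates log l, -l, cos a)
#'   or `"uniform"` (log l, -l).
#' @param boundary Boundary policy for covariate lookup, see
#'   [covariate_at()].
#' @param include Optional integer vector of step indices (within the
#'   concatenated step sequence) to restrict the choice sets to, e.g. the
#'   steps decoded into one state by a prior classification.
#' @param copy_used If `TRUE`, every control step is an exact copy of the
#'   used step (a degenerate proposal useful for validation).
#' @return An object of class `cc_data`: list with movement covariates `C`
#'   ((nsets * (M+1)) x p_C), habitat covariates `Z` (or `NULL`), `M`,
#'   `nsets`, per-set `step` index, `burst`, endpoint coordinates and the
#'   `proposal` used.
#' @export
build_case_control <- function(track, field, M, proposal = NULL, seed = 1L,
                               angle_model = c("von_mises", "uniform"),
                               boundary = "toroidal", include = NULL,
                               copy_used = FALSE) {
  angle_model <- match.arg(angle_model)
  stopifnot(M >= 1L)
  xy <- track_coords(track)
  burst_loc <- if (is.data.frame(track) && !is.null(track$burst)) {
    track$burst
  } else rep(1L, nrow(xy))
  pieces <- split(seq_len(nrow(xy)), burst_loc)
  all_len <- c(); step_rows <- list()
  # gather steps per burst: start point, previous heading, used (l, a), endpoint
  step_df <- NULL; offset <- 0L
  for (b in seq_along(pieces)) {
    rows <- pieces[[b]]
    if (length(rows) < 3L) next
    st <- steps_from_track(xy[rows, , drop = FALSE])
    nb <- nrow(st)
    all_len <- c(all_len, st$length)
    j <- 2:nb  # steps with defined turning angle
    step_df <- rbind(step_df, data.frame(
      step = offset + j, burst = b,
      x0 = xy[rows[j], 1], y0 = xy[rows[j], 2],
      href = st$heading[j - 1L],
      len = st$length[j], ang = st$angle[j],
      xe = xy[rows[j + 1L], 1], ye = xy[rows[j + 1L], 2]))
    offset <- offset + nb
  }
  if (is.null(step_df) || nrow(step_df) == 0L) {
    stop("track too short to form any choice set")
  }
  if (is.null(proposal)) proposal <- fit_tentative_gamma(all_len)
  stopifnot(inherits(proposal, "ssa_proposal"))
  if (!is.null(include)) {
    step_df <- step_df[step_df$step %in% include, , drop = FALSE]
    if (nrow(step_df) == 0L) stop("no choice sets left after 'include' filter")
  }
  nsets <- nrow(step_df)
  m1 <- M + 1L
  # control draws: one substream per choice set
  len <- matrix(0, m1, nsets); ang <- matrix(0, m1, nsets)
  len[1, ] <- step_df$len; ang[1, ] <- step_df$ang
  if (copy_used) {
    len[-1, ] <- rep(step_df$len, each = M)
    ang[-1, ] <- rep(step_df$ang, each = M)
  } else {
    for (s in seq_len(nsets)) {
      set.seed((as.integer(seed) + 1000003 * step_df$step[s]) %% 2147483647L)
      len[-1, s] <- stats::rgamma(M, shape = proposal$shape0,
                                  rate = proposal$rate0)
      ang[-1, s] <- if (proposal$kappa0 > 0) {
        rvonmises(M, mu = 0, kappa = proposal$kappa0)
      } else {
        stats::runif(M, -pi, pi)
      }
    }
  }
  dir <- sweep(ang, 2, step_df$href, "+")
  ex <- sweep(len * cos(dir), 2, step_df$x0, "+")
  ey <- sweep(len * sin(dir), 2, step_df$y0, "+")
  ex[1, ] <- step_df$xe; ey[1, ] <- step_df$ye
  lv <- as.vector(len); av <- as.vector(ang)
  C <- movement_covariates(lv, av, angle_model)
  Z <- if (!is.null(field)) {
    cbind(z = covariate_at(field, as.vector(ex), as.vector(ey),
                           boundary = boundary))
  } else NULL
  structure(list(C = C, Z = Z, M = as.integer(M), nsets = nsets,
                 step = step_df$step, burst = step_df$burst,
                 x = as.vector(ex), y = as.vector(ey),
                 angle_model = angle_model, proposal = proposal),
            class = "cc_data")
}

#' @export
print.cc_data <- function(x, ...) {
  cat(sprintf("cc_data: %d choice sets x (1 used + %d controls), %s angles, %d habitat covariate(s)\n",
              x$nsets, x$M, x$angle_model,
              if (is.null(x$Z)) 0L else ncol(x$Z)))
  print(x$proposal)
  invisible(x)
}

# subset a cc_data to the given choice-set indices (internal)
cc_subset <- function(data, sets) {
  m1 <- data$M + 1L
  rows <- as.vector(outer(seq_len(m1), (sets - 1L) * m1, "+"))
  structure(list(C = data$C[rows, , drop = FALSE],
                 Z = if (is.null(data$Z)) NULL else data$Z[rows, , drop = FALSE],
                 M = data$M, nsets = length(sets),
                 step = data$step[sets], burst = data$burst[sets],
                 x = data$x[rows], y = data$y[rows],
                 angle_model = data$angle_model, proposal = data$proposal),
            class = "cc_data")
}

#' Map working movement coefficients back to natural parameters
#'
#' With a gamma(shape0, rate0) length proposal and a uniform (or mean-zero
#' von Mises with concentration kappa0) angle proposal, the conditional
#' logistic coefficients on `(log l, -l, cos a)` estimate the differences
#' to the proposal parameters; the natural movement parameters are
#' recovered as `shape = shape0 + theta[1]`, `rate = rate0 + theta[2]`,
#' `kappa = kappa0 + theta[3]`.
#'
#' @param theta_hat Working coefficient vector on the movement covariates
#'   (length 3 for the von Mises model, 2 for uniform angles).
#' @param proposal An [ssa_proposal()].
#' @param angle_model `"von_mises"` or `"uniform"`.
#' @return List with `shape`, `rate` and (von Mises) `kappa`.
#' @export
recover_movement_parameters <- function(theta_hat, proposal,
                                        angle_model = c("von_mises", "uniform")) {
  angle_model <- match.arg(angle_model)
  stopifnot(inherits(proposal, "ssa_proposal"))
  p <- if (angle_model == "von_mises") 3L else 2L
  stopifnot(length(theta_hat) == p)
  k <- proposal$shape0 + theta_hat[1]
  r <- proposal$rate0 + theta_hat[2]
  if (k <= 0 || r <= 0) {
    stop(sprintf("recovered gamma parameters outside natural space (shape %.4g, rate %.4g)",
                 k, r))
  }
  out <- list(shape = unname(k), rate = unname(r))
  if (angle_model == "von_mises") out$kappa <- unname(proposal$kappa0 + theta_hat[3])
  out
}

#' Read and write case-control data as CSV
#'
#' Long format with one row per (choice set, alternative): columns `step`,
#' `burst`, `row` (0 = used), `is_used`, `x`, `y`, `log_l`, `neg_l`,
#' optionally `cos_a`, then one column per habitat covariate. The proposal
#' parameters and `M` are stored in `#`-comment header lines so the file
#' round-trips.
#'
#' @param data A `cc_data` object.
#' @param path File path.
#' @return `read_cc_csv` returns a `cc_data` object.
#' @export
write_cc_csv <- function(data, path) {
  stopifnot(inherits(data, "cc_data"))
  m1 <- data$M + 1L
  df <- data.frame(step = rep(data$step, each = m1),
                   burst = rep(data$burst, each = m1),
                   row = rep(0:data$M, times = data$nsets),
                   is_used = rep(c(1L, rep(0L, data$M)), times = data$nsets),
                   x = data$x, y = data$y)
  df <- cbind(df, as.data.frame(data$C))
  if (!is.null(data$Z)) df <- cbind(df, as.data.frame(data$Z))
  con <- file(path, "w"); on.exit(close(con))
  writeLines(sprintf("# msissa cc_data M=%d angle_model=%s shape0=%.15g rate0=%.15g kappa0=%.15g",
                     data$M, data$angle_model, data$proposal$shape0,
                     data$proposal$rate0, data$proposal$kappa0), con)
  utils::write.csv(df, con, row.names = FALSE)
  invisible(path)
}

#' @rdname write_cc_csv
#' @export
read_cc_csv <- function(path) {
  hdr <- readLines(path, n = 1L)
  if (!startsWith(hdr, "# msissa cc_data")) {
    stop("not a case-control CSV written by write_cc_csv (line 1)")
  }
  kv <- regmatches(hdr, gregexpr("[A-Za-z_0-9]+=[^ ]+", hdr))[[1]]
  meta <- stats::setNames(sub("^[^=]+=", "", kv), sub("=.*$", "", kv))
  M <- as.integer(meta[["M"]]); angle_model <- meta[["angle_model"]]
  df <- utils::read.csv(path, comment.char = "#")
  m1 <- M + 1L
  if (nrow(df) %% m1 != 0L) stop("row count is not a multiple of M + 1")
  ccols <- intersect(c("log_l", "neg_l", "cos_a"), names(df))
  zcols <- setdiff(names(df), c("step", "burst", "row", "is_used", "x", "y", ccols))
  used <- df$row == 0L
  structure(list(C = as.matrix(df[ccols]),
                 Z = if (length(zcols)) as.matrix(df[zcols]) else NULL,
                 M = M, nsets = nrow(df) %/% m1,
                 step = df$step[used], burst = df$burst[used],
                 x = df$x, y = df$y, angle_model = angle_model,
                 proposal = ssa_proposal(as.numeric(meta[["shape0"]]),
                                         as.numeric(meta[["rate0"]]),
                                         as.numeric(meta[["kappa0"]]))),
            class = "cc_data")
}
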