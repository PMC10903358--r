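#' State-switching step-selection model specification
#'
#' Defines an N-state hidden Markov step-selection model: a Markov chain
#' over behavioural states, and per state a movement kernel (gamma step
#' lengths, von Mises or uniform turning angles) weighted by an exponential
#' habitat-selection function \eqn{\exp(Z^\top \beta_i)}.
#'
#' @param tpm N x N row-stochastic transition probability matrix.
#' @param states List of N state parameter lists, each with elements
#'   `shape` (> 0), `rate` (> 0), `kappa` (von Mises concentration; its sign
#'   encodes mean 0 vs pi; ignored when `angle_model = "uniform"`), and
#'   `beta` (numeric selection coefficient vector, may be length 0).
#' @param angle_model `"von_mises"` or `"uniform"` turning angles.
#' @param delta Initial state distribution; defaults to the stationary
#'   distribution of `tpm`.
#' @return An object of class `hmm_issa_model`.
#' @examples
#' m <- hmm_issa_model(
#'   tpm = matrix(c(0.9, 0.1, 0.1, 0.9), 2, byrow = TRUE),
#'   states = list(list(shape = 1.2, rate = 1.25, kappa = 0.3, beta = 0),
#'                 list(shape = 2.5, rate = 0.29, kappa = 1.0, beta = 2)))
#' m
#' @export
hmm_issa_model <- function(tpm, states, angle_model = c("von_mises", "uniform"),
                           delta = NULL) {
  angle_model <- match.arg(angle_model)
  tpm <- as.matrix(tpm)
  N <- nrow(tpm)
  stopifnot(ncol(tpm) == N, all(tpm >= 0),
            max(abs(rowSums(tpm) - 1)) < 1e-8,
            is.list(states), length(states) == N)
  p_beta <- unique(vapply(states, function(s) length(s$beta), integer(1)))
  stopifnot(length(p_beta) == 1L)
  for (s in states) {
    stopifnot(is.numeric(s$shape), s$shape > 0,
              is.numeric(s$rate), s$rate > 0,
              all(is.finite(s$beta)))
    if (angle_model == "von_mises") stopifnot(is.numeric(s$kappa), is.finite(s$kappa))
  }
  if (is.null(delta)) delta <- stationary_distribution(tpm)
  stopifnot(length(delta) == N, abs(sum(delta) - 1) < 1e-8)
  structure(list(n_states = N, tpm = tpm, delta = as.numeric(delta),
                 states = states, angle_model = angle_model,
                 n_covariates = p_beta),
            class = "hmm_issa_model")
}

#' @export
print.hmm_issa_model <- function(x, ...) {
  cat(sprintf("hmm_issa_model: %d state(s), %s turning angles, %d habitat covariate(s)\n",
              x$n_states, x$angle_model, x$n_covariates))
  for (i in seq_len(x$n_states)) {
    s <- x$states[[i]]
    cat(sprintf("  state %d: shape %.3g, rate %.3g%s, beta (%s)\n", i,
                s$shape, s$rate,
                if (x$angle_model == "von_mises")
                  sprintf(", kappa %.3g", s$kappa) else "",
                paste(signif(s$beta, 3), collapse = ", ")))
  }
  if (x$n_states > 1L) {
    cat("  transition probability matrix:\n")
    print(round(x$tpm, 3))
  }
  invisible(x)
}

#' Stationary distribution of a transition probability matrix
#'
#' Solves \eqn{\delta^\top \Gamma = \delta^\top} with \eqn{\sum_i \delta_i = 1}.
#' For a reducible or otherwise degenerate chain the uniform distribution is
#' returned with a warning.
#'
#' @param tpm Row-stochastic square matrix.
#' @return Numeric stationary distribution.
#' @export
stationary_distribution <- function(tpm) {
  tpm <- as.matrix(tpm)
  N <- nrow(tpm)
  if (N == 1L) return(1)
  # delta' (I - Gamma + 1) = 1'
  d <- tryCatch(solve(t(diag(N) - tpm + 1), rep(1, N)),
                error = function(e) NULL)
  if (is.null(d) || any(!is.finite(d)) || any(d < -1e-10) ||
      max(abs(drop(d %*% tpm) - d)) > 1e-8) {
    warning("transition matrix has no unique stationary distribution; using uniform")
    return(rep(1 / N, N))
  }
  pmax(d, 0) / sum(pmax(d, 0))
}

#' Step lengths and turning angles of a track
#'
#' A track of T locations yields T-1 steps with lengths, headings (absolute
#' directions) and, for steps 2..T-1, turning angles: the change in heading
#' between consecutive steps, counterclockwise positive, wrapped to
#' (-pi, pi]. The first step has no turning angle (`NA`).
#'
#' @param track A two-column matrix/data frame of (x, y) locations, or a
#'   data frame with columns `x` and `y` (ordered in time, regular
#'   intervals).
#' @param zero_length `"floor"` (replace zero lengths with
#'   `1e-6 * median(length)` so `log(l)` stays finite, with a message) or
#'   `"error"`.
#' @return A data frame with columns `length`, `heading`, `angle`
#'   (one row per step).
#' @export
steps_from_track <- function(track, zero_length = c("floor", "error")) {
  zero_length <- match.arg(zero_length)
  xy <- track_coords(track)
  T_ <- nrow(xy)
  stopifnot(T_ >= 3L)
  dx <- diff(xy[, 1]); dy <- diff(xy[, 2])
  len <- sqrt(dx^2 + dy^2)
  if (any(len == 0)) {
    if (zero_length == "error") stop("zero-length step at position ",
                                     which(len == 0)[1])
    eps <- 1e-6 * stats::median(len[len > 0])
    message(sum(len == 0), " zero-length step(s) floored at ", signif(eps, 3))
    len[len == 0] <- eps
  }
  heading <- atan2(dy, dx)
  angle <- c(NA_real_, wrap_angle(diff(heading)))
  data.frame(length = len, heading = heading, angle = angle)
}

track_coords <- function(track) {
  if (is.data.frame(track) && all(c("x", "y") %in% names(track))) {
    xy <- cbind(track$x, track$y)
  } else {
    xy <- as.matrix(track)
    stopifnot(ncol(xy) == 2L)
  }
  stopifnot(all(is.finite(xy)))
  xy
}

# wrap to (-pi, pi]
wrap_angle <- function(a) {
  a <- (a + pi) %% (2 * pi) - pi
  a[a == -pi] <- pi
  a
}

#' Movement covariate vector of a step
#'
#' Under the gamma/von Mises movement kernel the log weight of a step is
#' linear in `(log(l), -l, cos(alpha))`; under the uniform-angle kernel the
#' cosine term drops, leaving `(log(l), -l)`.
#'
#' @param length Step length(s) (> 0).
#' @param angle Turning angle(s) in radians (may be omitted under the
#'   uniform model).
#' @param angle_model `"von_mises"` or `"uniform"`.
#' @return Matrix with columns `log_l`, `neg_l` and (von Mises) `cos_a`.
#' @export
movement_covariates <- function(length, angle = NULL,
                                angle_model = c("von_mises", "uniform")) {
  angle_model <- match.arg(angle_model)
  stopifnot(all(length > 0))
  if (angle_model == "von_mises") {
    if (is.null(angle) || anyNA(angle)) {
      stop("turning angles are required under the von Mises angle model")
    }
    cbind(log_l = log(length), neg_l = -length, cos_a = cos(angle))
  } else {
    cbind(log_l = log(length), neg_l = -length)
  }
}

#' Log selection weight of a step
#'
#' Computes \eqn{C^\top\theta_i + Z^\top\beta_i} where
#' \eqn{\theta_i = (k_i - 1, r_i, \kappa_i)} under the von Mises kernel
#' (or \eqn{(k_i - 1, r_i)} under uniform angles). When
#' `proposal_adjusted = TRUE` the movement coefficients are taken relative
#' to gamma proposal parameters `(shape0, rate0)` (and angle-proposal
#' concentration `kappa0`), the form entering the case-control choice
#' probability where control steps are drawn in polar coordinates and the
#' \eqn{-\log(l)} Jacobian term cancels.
#'
#' @param C Movement covariate matrix from [movement_covariates()].
#' @param Z Habitat covariate matrix (rows matching `C`), or `NULL`.
#' @param state State parameter list (`shape`, `rate`, `kappa`, `beta`).
#' @param angle_model `"von_mises"` or `"uniform"`.
#' @param proposal_adjusted Logical; see Details.
#' @param proposal Proposal parameter list with `shape0`, `rate0` and
#'   optionally `kappa0` (default 0, i.e. uniform angles); required when
#'   `proposal_adjusted = TRUE`.
#' @return Numeric vector of log weights.
#' @export
log_step_weight <- function(C, Z = NULL, state,
                            angle_model = c("von_mises", "uniform"),
                            proposal_adjusted = FALSE, proposal = NULL) {
  angle_model <- match.arg(angle_model)
  C <- rbind(C)
  stopifnot(all(is.finite(C)))
  if (proposal_adjusted) {
    stopifnot(!is.null(proposal))
    k0 <- proposal$shape0; r0 <- proposal$rate0
    kap0 <- if (is.null(proposal$kappa0)) 0 else proposal$kappa0
  } else {
    k0 <- 1; r0 <- 0; kap0 <- 0
  }
  theta <- if (angle_model == "von_mises") {
    c(state$shape - k0, state$rate - r0, state$kappa - kap0)
  } else {
    c(state$shape - k0, state$rate - r0)
  }
  stopifnot(ncol(C) == length(theta))
  w <- drop(C %*% theta)
  if (length(state$beta)) {
    Z <- rbind(Z)
    stopifnot(ncol(Z) == length(state$beta), all(is.finite(Z)))
    w <- w + drop(Z %*% state$beta)
  }
  w
}

## von Mises distribution (mean mu, concentration kappa >= 0) ------------

#' von Mises density and sampler
#'
#' Density and random generation for the von Mises distribution on
#' (-pi, pi]. `rvonmises` uses the Best-Fisher (1979) wrapped-Cauchy
#' rejection algorithm, vectorised.
#'
#' @param x,n Angles / number of draws.
#' @param mu Mean direction.
#' @param kappa Concentration (>= 0; 0 is the circular uniform).
#' @param log Return log density?
#' @return Density values / angles in (-pi, pi].
#' @export
dvonmises <- function(x, mu = 0, kappa = 1, log = FALSE) {
  stopifnot(kappa >= 0)
  # log I0(kappa) computed from the exponentially scaled Bessel function
  logI0 <- log(besselI(kappa, 0, expon.scaled = TRUE)) + kappa
  ld <- kappa * cos(x - mu) - log(2 * pi) - logI0
  if (log) ld else exp(ld)
}

#' @rdname dvonmises
#' @export
rvonmises <- function(n, mu = 0, kappa = 1) {
  stopifnot(kappa >= 0)
  if (n == 0L) return(numeric(0))
  if (kappa < 1e-8) return(stats::runif(n, -pi, pi))
  a <- 1 + sqrt(1 + 4 * kappa^2)
  b <- (a - sqrt(2 * a)) / (2 * kappa)
  r <- (1 + b^2) / (2 * b)
  out <- numeric(0)
  while (length(out) < n) {
    m <- max(n - length(out), 16L)
    m <- ceiling(m / 0.65)  # ~ acceptance rate
    u1 <- stats::runif(m); u2 <- stats::runif(m); u3 <- stats::runif(m)
    z <- cos(pi * u1)
    f <- (1 + r * z) / (r + z)
    cc <- kappa * (r - f)
    ok <- (cc * (2 - cc) - u2 > 0) | (log(cc / u2) + 1 - cc >= 0)
    theta <- sign(u3[ok] - 0.5) * acos(f[ok])
    out <- c(out, theta)
  }
  wrap_angle(mu + out[seq_len(n)])
}

#' Simulate a track from a state-switching step-selection model
#'
#' Simulates the hidden state chain from `(delta, tpm)` and, given state i,
#' draws each consecutive location from the state-dependent step-selection
#' density by importance resampling: `K` candidate steps are drawn from the
#' state's movement kernel (gamma length, von Mises/uniform angle) and one
#' is selected with probability proportional to \eqn{\exp(Z^\top\beta_i)}
#' at its endpoint. The scheme is exact as K grows and exact for any K on a
#' field with constant selection weight.
#'
#' Coordinates are continuous and unconstrained; covariate lookups wrap
#' toroidally, so the animal effectively moves on a torus.
#'
#' @param model A [hmm_issa_model()].
#' @param field A [covariate_field()] supplying the habitat covariate
#'   (single covariate), or `NULL` when the model has no selection part.
#' @param T Number of locations (>= 3).
#' @param x0 Starting location; defaults to the domain centre.
#' @param heading0 Initial heading in radians; drawn uniformly if `NULL`.
#' @param K Candidate steps per draw (>= 100; default 1000).
#' @param seed Integer seed for reproducibility.
#' @return A list with `track` (data frame `t`, `x`, `y`) and `states`
#'   (integer vector of length T-1, state of each step).
#' @export
simulate_track <- function(model, field, T, x0 = NULL, heading0 = NULL,
                           K = 1000L, seed = NULL) {
  stopifnot(inherits(model, "hmm_issa_model"), T >= 3L, K >= 100L)
  use_sel <- model$n_covariates > 0L
  if (use_sel) {
    stopifnot(inherits(field, "covariate_field"), model$n_covariates == 1L)
  }
  if (!is.null(seed)) set.seed(seed)
  N <- model$n_states
  n_steps <- T - 1L
  # state chain
  S <- integer(n_steps)
  S[1] <- sample.int(N, 1L, prob = model$delta)
  if (n_steps > 1L) for (t in 2:n_steps) {
    S[t] <- sample.int(N, 1L, prob = model$tpm[S[t - 1L], ])
  }
  # pre-draw kernel candidates per state in bulk
  counts <- tabulate(S, N)
  len_pool <- vector("list", N); ang_pool <- vector("list", N)
  for (i in seq_len(N)) {
    ni <- counts[i] * K
    if (ni == 0L) next
    st <- model$states[[i]]
    len_pool[[i]] <- stats::rgamma(ni, shape = st$shape, rate = st$rate)
    ang_pool[[i]] <- if (model$angle_model == "uniform") {
      stats::runif(ni, -pi, pi)
    } else {
      mu <- if (st$kappa < 0) pi else 0
      rvonmises(ni, mu = mu, kappa = abs(st$kappa))
    }
  }
  used <- integer(N)
  if (is.null(x0)) {
    x0 <- if (use_sel) {
      e <- field_extent(field); c(mean(e[1:2]), mean(e[3:4]))
    } else c(0, 0)
  }
  if (is.null(heading0)) heading0 <- stats::runif(1, -pi, pi)
  xs <- numeric(T); ys <- numeric(T)
  xs[1] <- x0[1]; ys[1] <- x0[2]
  heading <- heading0
  ess_warned <- FALSE
  for (t in seq_len(n_steps)) {
    i <- S[t]
    idx <- used[i] + seq_len(K); used[i] <- used[i] + K
    l <- len_pool[[i]][idx]; a <- ang_pool[[i]][idx]
    dir <- heading + a
    ex <- xs[t] + l * cos(dir); ey <- ys[t] + l * sin(dir)
    if (use_sel) {
      z <- covariate_at(field, ex, ey, boundary = "toroidal")
      lw <- z * model$states[[i]]$beta
      w <- exp(lw - max(lw))
      ess <- sum(w)^2 / sum(w^2)
      if (ess < 10 && !ess_warned) {
        warning("effective sample size of resampling weights fell below 10; ",
                "consider increasing K")
        ess_warned <- TRUE
      }
      pick <- sample.int(K, 1L, prob = w)
    } else {
      pick <- sample.int(K, 1L)
    }
    xs[t + 1L] <- ex[pick]; ys[t + 1L] <- ey[pick]
    heading <- dir[pick]
  }
  list(track = data.frame(t = seq_len(T), x = xs, y = ys),
       states = S)
}

#' Read and write tracks as CSV
#'
#' Columns `id`, `t`, `x`, `y` (one row per location, regular time steps);
#' an optional `burst` column marks independent track segments.
#'
#' @param track Data frame with at least `x` and `y`; `id`, `t`, `burst`
#'   added/kept as present.
#' @param path File path.
#' @param id Track identifier used when `track` lacks an `id` column.
#' @return `read_track_csv` returns the track data frame.
#' @export
write_track_csv <- function(track, path, id = "sim") {
  df <- as.data.frame(track)
  if (is.null(df$id)) df$id <- id
  if (is.null(df$t)) df$t <- seq_len(nrow(df))
  cols <- intersect(c("id", "t", "x", "y", "burst"), names(df))
  utils::write.csv(df[cols], path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_track_csv
#' @export
read_track_csv <- function(path) {
  df <- utils::read.csv(path)
  need <- c("id", "t", "x", "y")
  if (!all(need %in% names(df))) {
    stop("track CSV must have columns id, t, x, y (got: ",
         paste(names(df), collapse = ", "), ")")
  }
  if (anyNA(df$x) || anyNA(df$y)) stop("track CSV contains missing coordinates")
  df[order(df$id, df$t), , drop = FALSE]
}
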