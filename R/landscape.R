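#' Gaussian random field configuration
#'
#' Bundles the parameters of the simulated habitat covariate field: a
#' stationary zero-mean Gaussian random field with (by default) exponential
#' covariance \eqn{\mathrm{Cov}(d) = \sigma^2 \exp(-d/\phi)} between cell
#' centres at distance \eqn{d}.
#'
#' @param nx,ny Grid dimensions (cells), each at least 2.
#' @param variance Marginal variance \eqn{\sigma^2} of the field (>= 0).
#' @param range Correlation range \eqn{\phi} in coordinate units (> 0).
#' @param resolution Cell size in coordinate units (> 0).
#' @param origin Numeric length-2, coordinates of the lower-left grid corner.
#' @param covariance_model Either the string `"exponential"` or a function
#'   `function(d)` returning the covariance at distance `d` (must give
#'   `variance` at `d = 0`).
#' @return An object of class `grf_config`.
#' @seealso [simulate_grf()]
#' @export
grf_config <- function(nx = 100L, ny = 100L, variance = 1, range = 10,
                       resolution = 1, origin = c(0, 0),
                       covariance_model = "exponential") {
  nx <- as.integer(nx); ny <- as.integer(ny)
  stopifnot(nx >= 2L, ny >= 2L, is.numeric(variance), variance >= 0,
            is.numeric(range), range > 0, resolution > 0,
            length(origin) == 2L, all(is.finite(origin)))
  if (!is.function(covariance_model) &&
      !identical(covariance_model, "exponential")) {
    stop("covariance_model must be \"exponential\" or a function of distance")
  }
  structure(list(nx = nx, ny = ny, variance = variance, range = range,
                 resolution = resolution, origin = as.numeric(origin),
                 covariance_model = covariance_model),
            class = "grf_config")
}

cov_fun <- function(config) {
  if (is.function(config$covariance_model)) return(config$covariance_model)
  function(d) config$variance * exp(-d / config$range)
}

#' Gridded habitat covariate field
#'
#' A regular grid of scalar covariate values over a rectangular spatial
#' domain. Cell (i, j) (1-based) has its centre at
#' `origin + (c(i, j) - 0.5) * resolution`.
#'
#' @param values Numeric matrix (nx rows = x cells, ny columns = y cells),
#'   all finite, at least 2 x 2.
#' @param origin Numeric length-2 lower-left corner of the grid.
#' @param resolution Cell size (> 0).
#' @return An object of class `covariate_field`.
#' @export
covariate_field <- function(values, origin = c(0, 0), resolution = 1) {
  values <- as.matrix(values)
  stopifnot(nrow(values) >= 2L, ncol(values) >= 2L, all(is.finite(values)),
            resolution > 0, length(origin) == 2L, all(is.finite(origin)))
  structure(list(values = values, origin = as.numeric(origin),
                 resolution = as.numeric(resolution)),
            class = "covariate_field")
}

#' @export
print.covariate_field <- function(x, ...) {
  e <- field_extent(x)
  cat(sprintf("covariate_field: %d x %d cells, resolution %g\n",
              nrow(x$values), ncol(x$values), x$resolution))
  cat(sprintf("  domain: [%g, %g] x [%g, %g]\n", e[1], e[2], e[3], e[4]))
  cat(sprintf("  values: mean %.3f, sd %.3f, range [%.3f, %.3f]\n",
              mean(x$values), stats::sd(x$values),
              min(x$values), max(x$values)))
  invisible(x)
}

#' Spatial extent of a covariate field
#'
#' @param field A [covariate_field()].
#' @return Numeric `c(xmin, xmax, ymin, ymax)`.
#' @export
field_extent <- function(field) {
  nx <- nrow(field$values); ny <- ncol(field$values)
  c(field$origin[1], field$origin[1] + nx * field$resolution,
    field$origin[2], field$origin[2] + ny * field$resolution)
}

#' Simulate a Gaussian random field on a grid
#'
#' Draws a stationary zero-mean Gaussian random field over the grid defined
#' in `config`. Distances between cell centres are measured on the torus
#' (wrap-around), consistent with the toroidal boundary policy used when
#' simulated animals query the field; for ranges well below the domain size
#' the wrap contribution is negligible.
#'
#' Two samplers are available: `"fft"` (default for larger grids) exploits
#' the block-circulant structure of the torus covariance via the
#' two-dimensional FFT; `"dense"` forms and factors the full covariance
#' matrix by eigendecomposition and is only feasible for small grids
#' (`nx * ny <= 4096`). The torus covariance of the exponential model is
#' not exactly positive semi-definite on coarse grids; small negative
#' eigenvalues (up to 5% of the positive mass) are clamped to zero and the
#' spectrum rescaled so the marginal variance is preserved exactly, while
#' grossly indefinite configurations are an error.
#'
#' @param config A [grf_config()].
#' @param seed Integer seed; the field is reproducible for a fixed seed.
#' @param method `"auto"`, `"fft"` or `"dense"`.
#' @return A [covariate_field()].
#' @export
simulate_grf <- function(config, seed = NULL, method = c("auto", "fft", "dense")) {
  stopifnot(inherits(config, "grf_config"))
  method <- match.arg(method)
  nx <- config$nx; ny <- config$ny
  if (method == "auto") method <- if (nx * ny <= 2500L) "dense" else "fft"
  if (!is.null(seed)) set.seed(seed)
  if (config$variance == 0 && !is.function(config$covariance_model)) {
    return(covariate_field(matrix(0, nx, ny), config$origin, config$resolution))
  }
  cf <- cov_fun(config)
  vals <- if (method == "fft") grf_fft(config, cf) else grf_dense(config, cf)
  covariate_field(vals, config$origin, config$resolution)
}

# torus distance grids of the first covariance row/column
torus_lags <- function(n, res) {
  k <- 0:(n - 1L)
  pmin(k, n - k) * res
}

# clamp small negative eigenvalues, rescale to preserve total variance
psd_project <- function(lam) {
  pos <- sum(lam[lam > 0]); neg <- -sum(lam[lam < 0])
  if (neg > 0.05 * pos) {
    stop(sprintf(paste0("covariance is far from positive semi-definite ",
                        "(negative eigenvalue mass %.1f%% of positive); ",
                        "use a finer grid or a shorter range"),
                 100 * neg / pos))
  }
  lam <- pmax(lam, 0)
  lam * (pos - neg) / pos
}

grf_fft <- function(config, cf) {
  nx <- config$nx; ny <- config$ny
  dx <- torus_lags(nx, config$resolution)
  dy <- torus_lags(ny, config$resolution)
  C1 <- cf(sqrt(outer(dx^2, dy^2, "+")))  # first block-circulant row
  lam <- psd_project(Re(stats::fft(C1)))
  w <- matrix(stats::rnorm(nx * ny), nx, ny)
  Re(stats::fft(sqrt(lam) * stats::fft(w), inverse = TRUE)) / (nx * ny)
}

grf_dense <- function(config, cf) {
  nx <- config$nx; ny <- config$ny
  if (nx * ny > 4096L) {
    stop("grid too large for the dense sampler; use method = \"fft\"")
  }
  res <- config$resolution
  cx <- ((seq_len(nx)) - 0.5) * res
  cy <- ((seq_len(ny)) - 0.5) * res
  pts <- cbind(rep(cx, times = ny), rep(cy, each = nx))
  wx <- nx * res; wy <- ny * res
  ddx <- abs(outer(pts[, 1], pts[, 1], "-")); ddx <- pmin(ddx, wx - ddx)
  ddy <- abs(outer(pts[, 2], pts[, 2], "-")); ddy <- pmin(ddy, wy - ddy)
  C <- cf(sqrt(ddx^2 + ddy^2))
  e <- eigen(C, symmetric = TRUE)
  lam <- psd_project(e$values)
  x <- e$vectors %*% (sqrt(lam) * stats::rnorm(nx * ny))
  matrix(drop(x), nx, ny)
}

#' Look up covariate values at continuous locations
#'
#' Nearest-cell (raster-semantics) lookup of a [covariate_field()] at
#' arbitrary continuous coordinates. Under the `"toroidal"` boundary policy
#' coordinates are wrapped modulo the domain; under `"error"` any point
#' outside the extent is an error.
#'
#' @param field A [covariate_field()].
#' @param x Numeric vector of x coordinates, or a 2-column matrix of (x, y).
#' @param y Numeric vector of y coordinates (ignored if `x` is a matrix).
#' @param boundary `"toroidal"` (default) or `"error"`.
#' @return Numeric vector of covariate values, one per point.
#' @export
covariate_at <- function(field, x, y = NULL, boundary = c("toroidal", "error")) {
  stopifnot(inherits(field, "covariate_field"))
  boundary <- match.arg(boundary)
  if (is.matrix(x)) { y <- x[, 2]; x <- x[, 1] }
  stopifnot(length(x) == length(y), all(is.finite(x)), all(is.finite(y)))
  nx <- nrow(field$values); ny <- ncol(field$values)
  res <- field$resolution
  ix <- floor((x - field$origin[1]) / res)
  iy <- floor((y - field$origin[2]) / res)
  if (boundary == "toroidal") {
    ix <- ix %% nx
    iy <- iy %% ny
  } else {
    bad <- ix < 0 | ix >= nx | iy < 0 | iy >= ny
    if (any(bad)) {
      b <- which(bad)[1]
      stop(sprintf("point (%g, %g) lies outside the field domain", x[b], y[b]))
    }
  }
  field$values[cbind(ix + 1L, iy + 1L)]
}

#' Read and write covariate fields as plain-text grids
#'
#' The format is a single header line `nx ny origin_x origin_y resolution`
#' followed by `ny` rows of `nx` whitespace-separated values; row `j` holds
#' the cells with y index `j` (bottom row first).
#'
#' @param field A [covariate_field()].
#' @param path File path.
#' @return `read_field_grid` returns a [covariate_field()];
#'   `write_field_grid` returns `path` invisibly.
#' @export
write_field_grid <- function(field, path) {
  stopifnot(inherits(field, "covariate_field"))
  nx <- nrow(field$values); ny <- ncol(field$values)
  con <- file(path, "w"); on.exit(close(con))
  writeLines(paste(nx, ny, field$origin[1], field$origin[2],
                   field$resolution), con)
  utils::write.table(t(field$values), con, row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}

#' @rdname write_field_grid
#' @export
read_field_grid <- function(path) {
  header <- scan(path, nlines = 1, quiet = TRUE)
  if (length(header) != 5L) {
    stop("malformed grid header (line 1): expected 'nx ny origin_x origin_y resolution'")
  }
  nx <- as.integer(header[1]); ny <- as.integer(header[2])
  vals <- scan(path, skip = 1, quiet = TRUE)
  if (length(vals) != nx * ny) {
    stop(sprintf("grid body has %d values, expected %d x %d = %d",
                 length(vals), nx, ny, nx * ny))
  }
  covariate_field(t(matrix(vals, ny, nx, byrow = TRUE)),
                  origin = header[3:4], resolution = header[5])
}
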