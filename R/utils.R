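# Internal numerical helpers

# x*log(p) with the 0*log(0) = 0 convention
.xlogy <- function(x, y) {
  out <- numeric(length(x))
  nz <- x != 0
  out[nz] <- x[nz] * log(y[nz])
  out
}

# binomial log-likelihood (kernel only; the binomial coefficient cancels in
# likelihood ratios)
.binom_loglik <- function(k, n, p) {
  .xlogy(k, p) + .xlogy(n - k, 1 - p)
}

# tricube kernel on |d| <= h; zero outside
.tricube <- function(d, h) {
  u <- abs(d) / h
  w <- (1 - u^3)^3
  w[u >= 1] <- 0
  w
}

# Local-linear smoother with a tricube kernel of fixed half-width (genomic
# bandwidth). Linear in y, so it commutes exactly with affine maps of y.
# Falls back to a local constant (weighted mean) where the design is
# degenerate (e.g. a single support point).
.local_linear_smooth <- function(x, y, xout, half_width) {
  stopifnot(length(x) == length(y), half_width > 0)
  n_out <- length(xout)
  fit <- numeric(n_out)
  # dense cross-distance formulation; inputs are per-chromosome so sizes stay
  # modest
  D <- outer(xout, x, "-")
  W <- .tricube(D, half_width)
  sw <- W %*% rep(1, length(x))
  swx <- W %*% x
  swy <- W %*% y
  swxx <- W %*% (x * x)
  swxy <- W %*% (x * y)
  xbar <- swx / sw
  # weighted covariance terms
  sxx <- swxx - sw * xbar^2
  sxy <- swxy - xbar * swy
  slope <- ifelse(sxx > .Machine$double.eps * pmax(1, swxx), sxy / sxx, 0)
  intercept <- swy / sw - slope * xbar
  fit <- as.numeric(intercept + slope * xout)
  no_support <- as.numeric(sw) <= 0
  if (any(no_support)) {
    # no kernel support: fall back to nearest observation
    idx <- vapply(xout[no_support], function(x0) which.min(abs(x - x0)), 1L)
    fit[no_support] <- y[idx]
  }
  fit
}

# Stream reproducible per-stage sub-seeds from one master seed. Keeps all
# seeds below 2^31 so they remain valid R integers.
seed_stream <- function(master_seed, n) {
  old <- if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(master_seed))
  sample.int(.Machine$integer.max - 1L, n)
}

# inner join of two data frames on key columns, base R
.inner_join <- function(a, b, by, suffixes = c(".x", ".y")) {
  merge(a, b, by = by, suffixes = suffixes, sort = FALSE)
}
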