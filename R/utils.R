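# Internal argument checks and small numeric helpers.

check_scalar_number <- function(x, name, lower = -Inf, upper = Inf,
                                integerish = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    abort(sprintf("`%s` must be a single finite number.", name),
          class = "gcnet_invalid_argument")
  }
  if (integerish && abs(x - round(x)) > 1e-8) {
    abort(sprintf("`%s` must be a whole number.", name),
          class = "gcnet_invalid_argument")
  }
  if (x < lower || x > upper) {
    abort(sprintf("`%s` must be in [%s, %s], got %s.", name,
                  format(lower), format(upper), format(x)),
          class = "gcnet_invalid_argument")
  }
  invisible(x)
}

check_matrix_symmetric <- function(m, name, tol = 1e-8) {
  if (!is.matrix(m) || nrow(m) != ncol(m)) {
    abort(sprintf("`%s` must be a square matrix.", name),
          class = "gcnet_invalid_argument")
  }
  asym <- any(abs(m - t(m)) > tol, na.rm = TRUE) ||
    any(is.na(m) != t(is.na(m)))
  if (asym) {
    abort(sprintf("`%s` must be symmetric.", name),
          class = "gcnet_invalid_argument")
  }
  invisible(m)
}

# Positive semi-definiteness check on a symmetric matrix.
is_psd <- function(m, tol = 1e-8) {
  ev <- eigen((m + t(m)) / 2, symmetric = TRUE, only.values = TRUE)$values
  min(ev) >= -tol * max(1, max(abs(ev)))
}

# Multivariate normal draws via eigendecomposition; tolerates singular
# (PSD) covariance targets such as a genetic correlation of exactly 1.
rmvn_eigen <- function(n, sigma) {
  k <- nrow(sigma)
  e <- eigen((sigma + t(sigma)) / 2, symmetric = TRUE)
  vals <- pmax(e$values, 0)
  z <- matrix(rnorm(n * k), n, k)
  z %*% (t(e$vectors) * sqrt(vals))
}

# Derive a per-stage RNG seed from a base seed, kept inside 32-bit range.
derive_seed <- function(seed, offset) {
  as.integer((as.numeric(seed) * 1009 + offset * 9973) %% 2147483647)
}

# Median of the chi-square distribution with 1 df, to 5 decimals; fixed
# denominator of the genomic-control lambda.
CHISQ1_MEDIAN <- 0.45494
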