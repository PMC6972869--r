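# Cross-phenotype combined test statistics for correlated GWAS summary
# statistics: the homogeneous-effect statistic S_Hom (chi-square, 1 df
# under the null), the heterogeneous-effect statistic S_Het (a maximum of
# truncated combined statistics over magnitude thresholds, null calibrated
# by Monte Carlo with a beta-distribution tail map), and estimation of the
# between-statistic correlation matrix R from null SNPs.

# Solve with a logged ridge when near-singular.
solve_ridged <- function(m, rhs, label = "matrix") {
  kappa_val <- tryCatch(kappa(m, exact = FALSE), error = function(e) Inf)
  if (!is.finite(kappa_val) || kappa_val > 1e12) {
    inform(sprintf("Near-singular %s: adding 1e-8 ridge.", label))
    m <- m + diag(1e-8, nrow(m))
  }
  solve(m, rhs)
}

#' Estimate the between-trait statistic correlation matrix R
#'
#' Under the null the vector of Wald statistics across traits is
#' multivariate normal with a correlation matrix R induced by sample
#' overlap and phenotypic correlation. R is estimated as the sample
#' correlation of per-SNP Z-scores across traits over SNPs whose maximum
#' `|Z|` is below `z_cutoff` (excluding associated loci), then projected
#' to the nearest correlation matrix if any eigenvalue is negative.
#'
#' @param z Matrix of aligned Z-scores, SNPs by traits (e.g. the `z`
#'   element of [align_module_stats()]), or a named list of
#'   summary-statistics tibbles which is aligned first.
#' @param z_cutoff Null-SNP `|Z|` cutoff (default 1.96).
#' @return Correlation matrix with attributes `n_snps_used` and
#'   `z_cutoff`.
#' @export
estimate_stat_correlation <- function(z, z_cutoff = 1.96) {
  if (is.list(z) && !is.matrix(z)) z <- align_module_stats(z)$z
  check_scalar_number(z_cutoff, "z_cutoff", lower = 0)
  if (nrow(z) < 500L) {
    abort(sprintf("Only %d shared SNPs (need >= 500 to estimate R).",
                  nrow(z)),
          class = "gcnet_invalid_argument")
  }
  null_rows <- apply(abs(z), 1L, max) < z_cutoff
  if (sum(null_rows) < 100L) {
    abort(sprintf(paste("Only %d null SNPs below |Z| = %g;",
                        "consider a larger cutoff."),
                  sum(null_rows), z_cutoff),
          class = "gcnet_invalid_argument")
  }
  r <- cor(z[null_rows, , drop = FALSE])
  ev <- eigen(r, symmetric = TRUE)
  if (min(ev$values) < 0) {
    vals <- pmax(ev$values, 1e-8)
    r <- ev$vectors %*% (t(ev$vectors) * vals)
    dsc <- 1 / sqrt(diag(r))
    r <- r * tcrossprod(dsc)
    dimnames(r) <- dimnames(cor(z))
  }
  r <- (r + t(r)) / 2
  diag(r) <- 1
  attr(r, "n_snps_used") <- sum(null_rows)
  attr(r, "z_cutoff") <- z_cutoff
  r
}

#' Homogeneous-effect combined statistic S_Hom
#'
#' Combines a vector of Wald statistics for one SNP across traits (and
#' cohorts) into a single fixed-effect-style statistic that accounts for
#' the correlation R of the statistics:
#' `S_Hom = (e'(RW)^-1 T)^2 / (e'(WRW)^-1 e)`, with `W = diag(w)` the
#' sample-size weights (`w = sqrt(n)`) and `e` the ones vector. Under the
#' null S_Hom is chi-square with 1 df.
#'
#' @param t_vec Numeric vector of Wald statistics (length J*K).
#' @param R Statistic correlation matrix of matching dimension.
#' @param w Positive weights (default all 1, i.e. equal sample sizes).
#' @return One-row tibble with `s_hom` and `p`.
#' @examples
#' s_hom(2, matrix(1))            # T^2 = 4
#' s_hom(c(1, 1), diag(2))        # (sum T)^2 / 2 = 2
#' @export
s_hom <- function(t_vec, R, w = rep(1, length(t_vec))) {
  k <- length(t_vec)
  if (!is.matrix(R) || nrow(R) != k || ncol(R) != k || length(w) != k) {
    abort("Dimensions of `t_vec`, `R` and `w` must agree.",
          class = "gcnet_invalid_argument")
  }
  if (any(w <= 0)) {
    abort("Weights must be positive.", class = "gcnet_invalid_argument")
  }
  coefs <- shom_coefs(R, w)
  s <- drop(crossprod(coefs$a, t_vec))^2 / coefs$den
  tibble(s_hom = s, p = pchisq(s, df = 1, lower.tail = FALSE))
}

# Coefficients of the linear form underlying S_Hom on a component set:
# a = (RW)^-T e and den = e'(WRW)^-1 e, so S = (a.T)^2 / den.
shom_coefs <- function(R, w) {
  e <- rep(1, nrow(R))
  rw <- R * rep(w, each = nrow(R))        # R %*% diag(w)
  a <- solve_ridged(t(rw), e, "RW")
  wrw <- rw * w                           # diag(w) %*% R %*% diag(w)
  den <- drop(crossprod(e, solve_ridged(wrw, e, "WRW")))
  list(a = a, den = den)
}

#' Heterogeneous-effect statistic S_Het
#'
#' Allows different effect directions and magnitudes across traits by
#' maximizing the truncated combined statistic over magnitude thresholds:
#' for each threshold tau the statistic `S(tau)` is computed on the
#' sub-vector with `|T| > tau` (with the corresponding sub-matrices of R
#' and W), and `S_Het` is the maximum. The scan visits the nested
#' top-q subsets in decreasing magnitude order (q = 1..K), which covers
#' every subset the supremum over tau can select; `tau_star` is the
#' largest excluded magnitude (0 when all components are retained).
#'
#' @inheritParams s_hom
#' @return One-row tibble with `s_het`, `tau_star`, `k_retained`, and a
#'   list-column `retained` of component indices.
#' @examples
#' s_het(3, matrix(1))                  # singleton: T^2 = 9
#' s_het(c(3, 0.1), diag(2))            # drops the weak component: 9
#' s_het(c(3, -3), diag(2))             # opposite signs: 9, where S_Hom = 0
#' @export
s_het <- function(t_vec, R, w = rep(1, length(t_vec))) {
  k <- length(t_vec)
  if (!is.matrix(R) || nrow(R) != k || ncol(R) != k || length(w) != k) {
    abort("Dimensions of `t_vec`, `R` and `w` must agree.",
          class = "gcnet_invalid_argument")
  }
  ord <- order(abs(t_vec), decreasing = TRUE)
  best <- -Inf
  best_q <- 1L
  for (q in seq_len(k)) {
    idx <- sort(ord[seq_len(q)])
    cf <- shom_coefs(R[idx, idx, drop = FALSE], w[idx])
    s <- drop(crossprod(cf$a, t_vec[idx]))^2 / cf$den
    if (s > best + 1e-12) {
      best <- s
      best_q <- q
    }
  }
  retained <- sort(ord[seq_len(best_q)])
  tau_star <- if (best_q == k) 0 else abs(t_vec[ord[best_q + 1L]])
  tibble(s_het = best, tau_star = tau_star, k_retained = best_q,
         retained = list(retained))
}

# S_Het for many draws at once (rows of z). Precomputes the S_Hom linear
# coefficients of every magnitude-ordered subset lazily, keyed by the
# sorted index set. With `details = TRUE` also returns the maximizing
# threshold and retained-component count per row.
shet_stat_batch <- function(z, R, w = rep(1, ncol(R)), details = FALSE) {
  k <- ncol(R)
  n <- nrow(z)
  if (k == 1L) {
    s <- drop(z)^2
    if (!details) return(s)
    return(list(s = s, tau_star = rep(0, n), k_retained = rep(1L, n)))
  }
  cache <- new.env(hash = TRUE, parent = emptyenv())
  get_coefs <- function(idx) {
    key <- paste(idx, collapse = ",")
    cf <- cache[[key]]
    if (is.null(cf)) {
      cf <- shom_coefs(R[idx, idx, drop = FALSE], w[idx])
      cache[[key]] <- cf
    }
    cf
  }
  out <- numeric(n)
  tau_star <- numeric(n)
  k_ret <- integer(n)
  for (i in seq_len(n)) {
    ti <- z[i, ]
    ord <- order(abs(ti), decreasing = TRUE)
    best <- -Inf
    best_q <- 1L
    for (q in seq_len(k)) {
      idx <- sort(ord[seq_len(q)])
      cf <- get_coefs(idx)
      s <- (sum(cf$a * ti[idx]))^2 / cf$den
      if (s > best + 1e-12) {
        best <- s
        best_q <- q
      }
    }
    out[i] <- best
    if (details) {
      tau_star[i] <- if (best_q == k) 0 else abs(ti[ord[best_q + 1L]])
      k_ret[i] <- best_q
    }
  }
  if (!details) return(out)
  list(s = out, tau_star = tau_star, k_retained = k_ret)
}

#' Calibrate the S_Het null distribution
#'
#' Draws `B` vectors from the zero-mean multivariate normal with
#' correlation `R`, computes S_Het for each, stores the sorted null draws
#' for empirical P-values, and fits a beta distribution by maximum
#' likelihood to the chi-square(1)-tail transform
#' `X = P_chi2(S_Het)` in (0, 1), giving a smooth tail-extrapolating P
#' map. For a single trait S_Het is exactly chi-square(1) and the fitted
#' beta is close to (1, 1).
#'
#' @param R Statistic correlation matrix (must be PSD).
#' @param B Number of Monte Carlo draws (at least 10,000 for calibrated
#'   use; smaller values are allowed with a warning).
#' @param seed Integer seed; the null model is bit-reproducible.
#' @param w Weights used for the statistics (default equal).
#' @return An `shet_null` object: `R`, `w`, `B`, `seed`, sorted null
#'   draws, and fitted `beta` parameters `(a, b)`.
#' @export
calibrate_shet_null <- function(R, B = 10000L, seed = 1L,
                                w = rep(1, nrow(R))) {
  check_matrix_symmetric(R, "R")
  if (!is_psd(R, tol = 1e-10)) {
    abort("`R` is not positive semi-definite; repair it first.",
          class = "gcnet_invalid_argument")
  }
  check_scalar_number(B, "B", lower = 100, integerish = TRUE)
  if (B < 10000) {
    warn("B < 10,000: the null model is only roughly calibrated.")
  }
  B <- as.integer(B)
  draws <- withr::with_seed(as.integer(seed), rmvn_eigen(B, R))
  stats <- shet_stat_batch(draws, R, w)
  x <- pchisq(stats, df = 1, lower.tail = FALSE)
  x <- pmin(pmax(x, 1e-12), 1 - 1e-12)
  beta_par <- fit_beta_mle(x)
  structure(
    list(R = R, w = w, B = B, seed = as.integer(seed),
         sorted_stats = sort(stats), beta = beta_par),
    class = "shet_null"
  )
}

# Beta MLE via L-BFGS-B on the log-parameter scale, moment start.
fit_beta_mle <- function(x) {
  mu <- mean(x)
  v <- var(x)
  common <- max(mu * (1 - mu) / max(v, 1e-12) - 1, 1e-3)
  start <- log(pmax(c(mu * common, (1 - mu) * common), 1e-3))
  nll <- function(lp) {
    a <- exp(lp[1]); b <- exp(lp[2])
    -sum(stats::dbeta(x, a, b, log = TRUE))
  }
  fit <- optim(start, nll, method = "L-BFGS-B",
               lower = log(1e-6), upper = log(1e6))
  setNames(exp(fit$par), c("a", "b"))
}

#' @export
print.shet_null <- function(x, ...) {
  cat(sprintf("<shet_null> K = %d, B = %d, beta map (a = %.3f, b = %.3f)\n",
              nrow(x$R), x$B, x$beta["a"], x$beta["b"]))
  invisible(x)
}

#' P-value of an S_Het statistic against a calibrated null
#'
#' The empirical P-value `(r + 1) / (B + 1)` (with `r` the number of null
#' draws at or above the statistic) is primary; when it hits its floor
#' `1 / (B + 1)` the beta-approximated tail P takes over.
#'
#' @param statistic S_Het value(s).
#' @param null An `shet_null` from [calibrate_shet_null()].
#' @param R Optional correlation matrix to check against the null model's
#'   fingerprint.
#' @return Tibble with `p` (the reported P), `p_empirical`, `p_beta`.
#' @export
shet_pvalue <- function(statistic, null, R = NULL) {
  stopifnot(inherits(null, "shet_null"))
  if (!is.null(R)) {
    if (!isTRUE(all.equal(unname(unclass(R)), unname(unclass(null$R)),
                          tolerance = 1e-8, check.attributes = FALSE))) {
      abort("`R` does not match the null model's correlation matrix.",
            class = "gcnet_invalid_argument")
    }
  }
  b <- null$B
  n_less <- findInterval(statistic, null$sorted_stats, left.open = TRUE)
  r <- b - n_less
  p_emp <- (r + 1) / (b + 1)
  p_beta <- pbeta(pchisq(statistic, df = 1, lower.tail = FALSE),
                  null$beta["a"], null$beta["b"])
  p <- ifelse(p_emp <= 1 / (b + 1) + 1e-15, p_beta, p_emp)
  tibble(p = unname(p), p_empirical = unname(p_emp),
         p_beta = unname(p_beta))
}

#' Intersect and allele-align summary statistics across module traits
#'
#' Joins the traits' summary statistics by SNP id, aligns every trait's
#' alleles to the first trait (flipping Z and BETA when A1/A2 are
#' swapped), and drops SNPs with mismatched allele pairs or flagged
#' records in any trait.
#'
#' @param stats_list Named list of summary-statistics tibbles.
#' @return List with `meta` (tibble `SNP`, `CHR`, `BP`), `z` (SNPs x
#'   traits matrix), `n_bar` (per-trait mean sample size), `n_dropped`.
#' @export
align_module_stats <- function(stats_list) {
  stopifnot(length(stats_list) >= 1L)
  traits <- names(stats_list) %||% sprintf("trait%02d", seq_along(stats_list))
  clean <- purrr::map(stats_list, function(s) {
    if ("flag" %in% names(s)) s <- s[s$flag == "ok", ]
    s[is.finite(s$Z), ]
  })
  ref <- clean[[1]]
  ids <- ref$SNP
  for (s in clean[-1]) ids <- intersect(ids, s$SNP)
  if (length(ids) == 0) {
    abort("Empty SNP intersection across module traits.",
          class = "gcnet_invalid_argument")
  }
  ref <- ref[match(ids, ref$SNP), ]
  z <- matrix(NA_real_, length(ids), length(traits),
              dimnames = list(ids, traits))
  z[, 1] <- ref$Z
  keep <- rep(TRUE, length(ids))
  for (ti in seq_along(clean)[-1]) {
    s <- clean[[ti]][match(ids, clean[[ti]]$SNP), ]
    same <- s$A1 == ref$A1 & s$A2 == ref$A2
    swapped <- s$A1 == ref$A2 & s$A2 == ref$A1
    zi <- s$Z
    zi[swapped] <- -zi[swapped]
    keep <- keep & (same | swapped)
    z[, ti] <- zi
  }
  n_dropped <- sum(!keep)
  meta <- ref[keep, c("SNP", "CHR", "BP")]
  z <- z[keep, , drop = FALSE]
  n_bar <- vapply(seq_along(clean), function(ti) {
    mean(clean[[ti]]$N[match(meta$SNP, clean[[ti]]$SNP)])
  }, numeric(1))
  list(meta = meta, z = z, n_bar = setNames(n_bar, traits),
       n_dropped = n_dropped)
}

#' Cross-phenotype scan of a module's traits
#'
#' For every SNP shared by the module's traits, computes both combined
#' statistics and their P-values: S_Hom against the chi-square(1)
#' reference and S_Het against a Monte Carlo null (empirical P primary,
#' beta-approximated P as tail fallback). Weights are the square roots of
#' the per-trait mean sample sizes. SNPs whose smaller P-value is at or
#' below `threshold` are flagged significant; the conventional genome-wide
#' line at 5e-8 is reported alongside.
#'
#' @param stats_list Named list of the module traits' summary statistics.
#' @param R Optional precomputed statistic correlation matrix (estimated
#'   from null SNPs when missing).
#' @param null Optional precomputed `shet_null` for this R and weights.
#' @param threshold Module-scan significance threshold (default 1e-7).
#' @param B Null draws when `null` is missing.
#' @param seed Seed for the null calibration.
#' @param z_cutoff Null-SNP cutoff for estimating R.
#' @return Tibble with columns `SNP, CHR, BP, S_HOM, P_HOM, S_HET,
#'   TAU_STAR, K_RETAINED, P_HET_EMP, P_HET_BETA, P_HET, SIGNIFICANT,
#'   GENOME_WIDE`; the R matrix and null model ride along as attributes.
#' @export
module_scan <- function(stats_list, R = NULL, null = NULL,
                        threshold = 1e-7, B = 10000L, seed = 1L,
                        z_cutoff = 1.96) {
  check_scalar_number(threshold, "threshold", lower = 0, upper = 1)
  al <- align_module_stats(stats_list)
  k <- ncol(al$z)
  w <- sqrt(al$n_bar)
  if (is.null(R)) R <- estimate_stat_correlation(al$z, z_cutoff = z_cutoff)
  if (is.null(null)) {
    null <- calibrate_shet_null(unclass_attr(R), B = B, seed = seed, w = w)
  }

  cf <- shom_coefs(unclass_attr(R), w)
  s_hom_v <- drop(al$z %*% cf$a)^2 / cf$den
  p_hom <- pchisq(s_hom_v, df = 1, lower.tail = FALSE)

  het <- shet_stat_batch(al$z, unclass_attr(R), w, details = TRUE)
  s_het_v <- het$s
  tau_star <- het$tau_star
  k_ret <- het$k_retained
  pv <- shet_pvalue(s_het_v, null)

  out <- dplyr::bind_cols(
    al$meta,
    tibble(S_HOM = s_hom_v, P_HOM = p_hom,
           S_HET = s_het_v, TAU_STAR = tau_star, K_RETAINED = k_ret,
           P_HET_EMP = pv$p_empirical, P_HET_BETA = pv$p_beta,
           P_HET = pv$p)
  )
  out$SIGNIFICANT <- pmin(out$P_HOM, out$P_HET) <= threshold
  out$GENOME_WIDE <- pmin(out$P_HOM, out$P_HET) <= 5e-8
  attr(out, "R") <- R
  attr(out, "null") <- null
  attr(out, "threshold") <- threshold
  attr(out, "weights") <- w
  out
}

# strip attributes added by estimate_stat_correlation
unclass_attr <- function(R) {
  attr(R, "n_snps_used") <- NULL
  attr(R, "z_cutoff") <- NULL
  R
}
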