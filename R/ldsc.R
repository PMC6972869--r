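# Simplified LD score regression: unweighted OLS of per-SNP chi-square
# (or cross-trait z-products) on LD scores, with block-jackknife errors.
# This is deliberately lighter than the published estimator (no iterative
# heteroskedasticity weights, no reference-panel scores) and is intended
# for the synthetic regimes this package generates.

# The sample-overlap offset of the z-product regression is estimated from
# the median of the per-SNP products z1*z2: the median is robust to the
# minority of causal SNPs, unlike a mean or a truncated correlation. For a
# standard bivariate normal with correlation r the median of the product
# is a strictly increasing function g(r) (g(0) = 0; g(1) = the chi-square
# 1-df median); r is recovered as g^{-1}(median). g is computed once by
# quadrature of P(z1 * z2 <= t) over the first margin and cached.
.product_median_cache <- new.env(parent = emptyenv())

product_median_curve <- function() {
  f <- .product_median_cache$curve
  if (!is.null(f)) return(f)
  x <- seq(-8, 8, by = 0.004)
  x <- x[abs(x) > 1e-9]
  wdens <- stats::dnorm(x) * 0.004
  prod_cdf <- function(t, r) {
    s <- sqrt(1 - r^2)
    z <- (t / x - r * x) / s
    p <- stats::pnorm(z)
    p[x < 0] <- 1 - p[x < 0]
    sum(p * wdens)
  }
  r_grid <- seq(0, 0.99, by = 0.01)
  med <- vapply(r_grid, function(r) {
    if (r == 0) return(0)
    stats::uniroot(function(t) prod_cdf(t, r) - 0.5,
                   lower = -1, upper = 2, tol = 1e-10)$root
  }, numeric(1))
  # exact endpoint: at r = 1 the product is chi-square with 1 df
  med <- c(med, stats::qchisq(0.5, df = 1))
  r_grid <- c(r_grid, 1)
  inv <- stats::approxfun(med, r_grid, rule = 2)
  f <- function(observed_median) {
    sign(observed_median) * inv(min(abs(observed_median), max(med)))
  }
  .product_median_cache$curve <- f
  f
}

# Contiguous block ids for the delete-a-block jackknife.
jackknife_blocks <- function(m, n_blocks = 200L) {
  n_blocks <- if (m < 400L) max(floor(m / 2), 2L) else n_blocks
  n_blocks <- min(n_blocks, m)
  as.integer(cut(seq_len(m), breaks = n_blocks, labels = FALSE))
}

jackknife_se <- function(estimates) {
  b <- sum(is.finite(estimates))
  if (b < 2L) return(NA_real_)
  est <- estimates[is.finite(estimates)]
  sqrt((b - 1) / b * sum((est - mean(est))^2))
}

# Slope of y ~ l with a free intercept, from sufficient sums.
slope_from_sums <- function(n, sl, sy, sll, sly) {
  denom <- sll - sl^2 / n
  if (denom <= 1e-12) return(NA_real_)
  (sly - sl * sy / n) / denom
}

#' Heritability from summary statistics (simplified LD score regression)
#'
#' Regresses the per-SNP Wald chi-square `Z^2` on the LD score `l_j` and
#' converts the slope: `h2 = slope * M / mean(N)`, with `M` the total
#' number of scored SNPs. With varying LD scores the intercept is free
#' (absorbing confounding); when the scores are numerically constant (the
#' independent-SNP regime, all `l_j = 1`) the free-intercept regression is
#' singular and the intercept is constrained to its exact null value of 1,
#' so the slope becomes `mean(Z^2) - 1` per unit LD score. Standard errors
#' come from a delete-a-block jackknife over contiguous SNP blocks.
#'
#' @param stats Summary-statistics tibble (`Z`, `N`; flagged rows dropped).
#' @param ld LD-score tibble from [make_ld_scores()] (columns `SNP`, `L`,
#'   attribute `M`).
#' @param n_blocks Jackknife blocks (default 200; `floor(m/2)` when the SNP
#'   count m is below 400).
#' @return One-row tibble: `trait`, `h2`, `se`, `intercept`, `slope`,
#'   `n_snps`, `M`, `mean_n`, `constrained`.
#' @export
estimate_h2 <- function(stats, ld, n_blocks = 200L) {
  trait <- attr(stats, "trait_id") %||% "trait"
  if ("flag" %in% names(stats)) stats <- stats[stats$flag == "ok", ]
  stats <- stats[is.finite(stats$Z), ]
  if (!all(stats$SNP %in% ld$SNP)) {
    abort("Some SNPs in `stats` are not scored in `ld`.",
          class = "gcnet_invalid_argument")
  }
  m <- nrow(stats)
  if (m < 200L) {
    abort(sprintf("Refusing to estimate h2 from %d SNPs (need >= 200).", m),
          class = "gcnet_invalid_argument")
  }
  big_m <- attr(ld, "M") %||% nrow(ld)
  l <- ld$L[match(stats$SNP, ld$SNP)]
  chi2 <- stats$Z^2
  mean_n <- mean(stats$N)
  constrained <- sd(l) <= 1e-8

  blocks <- jackknife_blocks(m, n_blocks)
  bs <- rowsum(cbind(1, l, chi2, l^2, l * chi2), blocks)
  tot <- colSums(bs)
  est_from <- function(s) {
    if (constrained) {
      (s[3] / s[1] - 1) / (s[2] / s[1])
    } else {
      slope_from_sums(s[1], s[2], s[3], s[4], s[5])
    }
  }
  slope <- unname(est_from(tot))
  jack <- apply(bs, 1L, function(b) est_from(tot - b))
  scale_fac <- big_m / mean_n
  intercept <- if (constrained) 1 else unname(mean(chi2) - slope * mean(l))

  tibble(
    trait = trait,
    h2 = slope * scale_fac,
    se = jackknife_se(jack) * scale_fac,
    intercept = intercept,
    slope = slope,
    n_snps = m,
    M = big_m,
    mean_n = mean_n,
    constrained = constrained
  )
}

# Intersect two summary-stat sets by SNP id and align alleles to the first:
# identical (A1,A2) keeps the sign, swapped (A1<->A2) flips the sign of Z
# and BETA of the second, anything else is dropped and counted.
align_sumstats_pair <- function(stats1, stats2) {
  j <- dplyr::inner_join(
    stats1[c("SNP", "CHR", "BP", "A1", "A2", "BETA", "Z", "N")],
    stats2[c("SNP", "A1", "A2", "BETA", "Z", "N")],
    by = "SNP", suffix = c("_1", "_2")
  )
  same <- j$A1_1 == j$A1_2 & j$A2_1 == j$A2_2
  swapped <- j$A1_1 == j$A2_2 & j$A2_1 == j$A1_2
  n_mismatch <- sum(!(same | swapped))
  j <- j[same | swapped, , drop = FALSE]
  flip <- j$A1_1 == j$A2_2 & j$A2_1 == j$A1_2
  j$Z_2[flip] <- -j$Z_2[flip]
  j$BETA_2[flip] <- -j$BETA_2[flip]
  list(aligned = j, n_mismatch = n_mismatch)
}

#' Pairwise genetic correlation (simplified cross-trait LD score regression)
#'
#' Intersects two traits' summary statistics by SNP id (aligning alleles,
#' flipping the sign of Z when A1/A2 are swapped, dropping mismatched
#' pairs), regresses the per-SNP product `z1*z2` on the LD score, and
#' converts the slope to a genetic covariance
#' `rho_g = slope * M / sqrt(mean(N1) * mean(N2))` and correlation
#' `r_g = rho_g / sqrt(h2_1 * h2_2)`. With varying LD scores the intercept
#' is free, absorbing the sample-overlap term; with constant scores it is
#' constrained to an overlap offset recovered from the median of the
#' per-SNP z-products (robust to the causal minority), which is exactly 1
#' for a trait paired with itself and 0 for disjoint cohorts. If either
#' heritability estimate is non-positive the result is the NA sentinel
#' with `valid = FALSE`.
#'
#' @param stats1,stats2 Summary-statistics tibbles.
#' @param ld LD-score tibble covering the intersection.
#' @param h2_1,h2_2 Optional precomputed heritability point estimates (rows
#'   from [estimate_h2()] or plain numbers); estimated from `stats1` /
#'   `stats2` when missing.
#' @param n_blocks Jackknife blocks.
#' @param intercept `"auto"` (free when LD scores vary, overlap offset
#'   otherwise), `"free"`, `"offset"`, or `"zero"` — the latter fixes the
#'   intercept at 0 for cohorts known to share no samples, as the
#'   published estimator's no-intercept mode does.
#' @return One-row tibble: `trait1`, `trait2`, `rg`, `se`, `p`, `rho_g`,
#'   `se_rho`, `h2_1`, `h2_2`, `n_snps`, `n_allele_mismatch`, `valid`.
#' @export
estimate_rg_pair <- function(stats1, stats2, ld, h2_1 = NULL, h2_2 = NULL,
                             n_blocks = 200L,
                             intercept = c("auto", "free", "offset",
                                           "zero")) {
  intercept <- match.arg(intercept)
  t1 <- attr(stats1, "trait_id") %||% "trait1"
  t2 <- attr(stats2, "trait_id") %||% "trait2"
  if ("flag" %in% names(stats1)) stats1 <- stats1[stats1$flag == "ok", ]
  if ("flag" %in% names(stats2)) stats2 <- stats2[stats2$flag == "ok", ]

  al <- align_sumstats_pair(stats1, stats2)
  j <- al$aligned
  if (nrow(j) == 0) {
    abort("No SNPs left after allele alignment: all allele pairs mismatch.",
          class = "gcnet_invalid_argument")
  }
  if (nrow(j) < 200L) {
    abort(sprintf("Only %d intersecting SNPs (need >= 200).", nrow(j)),
          class = "gcnet_invalid_argument")
  }
  h2v <- function(h, st) {
    if (is.null(h)) h <- estimate_h2(st, ld, n_blocks)
    if (is.data.frame(h)) h$h2 else as.numeric(h)
  }
  h2_1 <- h2v(h2_1, stats1)
  h2_2 <- h2v(h2_2, stats2)

  big_m <- attr(ld, "M") %||% nrow(ld)
  l <- ld$L[match(j$SNP, ld$SNP)]
  if (anyNA(l)) {
    abort("Some intersecting SNPs are not scored in `ld`.",
          class = "gcnet_invalid_argument")
  }
  z1 <- j$Z_1
  z2 <- j$Z_2
  y <- z1 * z2
  m <- length(y)
  use_free <- if (intercept == "auto") sd(l) > 1e-8 else intercept == "free"
  if (use_free && sd(l) <= 1e-8) {
    abort("LD scores are constant: the free-intercept fit is singular.",
          class = "gcnet_invalid_argument")
  }

  blocks <- jackknife_blocks(m, n_blocks)
  full <- rowsum(cbind(1, l, y, l^2, l * y), blocks)
  tot_full <- colSums(full)

  if (use_free) {
    est_from <- function(sf) {
      slope_from_sums(sf[1], sf[2], sf[3], sf[4], sf[5])
    }
    slope <- unname(est_from(tot_full))
    jack <- vapply(seq_len(nrow(full)), function(b) {
      est_from(tot_full - full[b, ])
    }, numeric(1))
  } else {
    offset_of <- if (intercept == "zero") {
      function(yy) 0
    } else {
      g_inv <- product_median_curve()
      function(yy) g_inv(median(yy))
    }
    slope <- (mean(y) - offset_of(y)) / mean(l)
    block_ids <- sort(unique(blocks))
    jack <- vapply(block_ids, function(b) {
      keep <- blocks != b
      (mean(y[keep]) - offset_of(y[keep])) / mean(l[keep])
    }, numeric(1))
  }

  scale_fac <- big_m / sqrt(mean(j$N_1) * mean(j$N_2))
  rho <- slope * scale_fac
  se_rho <- jackknife_se(jack) * scale_fac

  if (is.finite(h2_1) && is.finite(h2_2) && h2_1 > 0 && h2_2 > 0) {
    denom <- sqrt(h2_1 * h2_2)
    rg <- rho / denom
    se_rg <- se_rho / denom
    p <- 2 * pnorm(-abs(rg / se_rg))
    valid <- TRUE
  } else {
    rg <- se_rg <- p <- NA_real_
    valid <- FALSE
  }

  tibble(
    trait1 = t1, trait2 = t2, rg = rg, se = se_rg, p = p,
    rho_g = rho, se_rho = se_rho, h2_1 = h2_1, h2_2 = h2_2,
    n_snps = m, n_allele_mismatch = al$n_mismatch, valid = valid
  )
}

#' Build the trait-by-trait genetic correlation matrix
#'
#' Estimates every pairwise genetic correlation and marks as invalid any
#' pair whose estimate is the NA sentinel, above 1 or below -1 — the same
#' filter applied to incorrectly estimated pairs in small-cohort summary
#' data. Invalid entries carry `NA` in the matrix and `valid = FALSE` in
#' the long table; the diagonal is exactly 1.
#'
#' @param stats_list Named list of summary-statistics tibbles (3 or more
#'   traits).
#' @param ld LD-score tibble.
#' @inheritParams estimate_rg_pair
#' @return An `rg_matrix` object: trait ids, square `rg`/`se`/`p`/`valid`
#'   matrices, the long pair table (including out-of-range raw estimates),
#'   per-trait heritabilities, and the invalid-pair count.
#' @export
build_rg_matrix <- function(stats_list, ld, n_blocks = 200L,
                            intercept = c("auto", "free", "offset",
                                          "zero")) {
  intercept <- match.arg(intercept)
  k <- length(stats_list)
  if (k < 3L) {
    abort("Need at least 3 traits to build a correlation network.",
          class = "gcnet_invalid_argument")
  }
  traits <- names(stats_list) %||% sprintf("trait%02d", seq_len(k))
  if (is.null(names(stats_list))) names(stats_list) <- traits

  h2_tbl <- purrr::map_dfr(traits, function(tr) {
    out <- estimate_h2(stats_list[[tr]], ld, n_blocks)
    out$trait <- tr
    out
  })

  pair_idx <- utils::combn(k, 2)
  pairs <- purrr::map_dfr(seq_len(ncol(pair_idx)), function(pi) {
    i <- pair_idx[1, pi]
    jj <- pair_idx[2, pi]
    res <- estimate_rg_pair(
      stats_list[[i]], stats_list[[jj]], ld,
      h2_1 = h2_tbl$h2[i], h2_2 = h2_tbl$h2[jj],
      n_blocks = n_blocks, intercept = intercept
    )
    res$trait1 <- traits[i]
    res$trait2 <- traits[jj]
    res
  })

  pairs$valid <- pairs$valid & !is.na(pairs$rg) &
    pairs$rg <= 1 & pairs$rg >= -1

  rg <- se <- p <- matrix(NA_real_, k, k, dimnames = list(traits, traits))
  valid <- matrix(FALSE, k, k, dimnames = list(traits, traits))
  for (r in seq_len(nrow(pairs))) {
    i <- match(pairs$trait1[r], traits)
    jj <- match(pairs$trait2[r], traits)
    if (pairs$valid[r]) {
      rg[i, jj] <- rg[jj, i] <- pairs$rg[r]
      se[i, jj] <- se[jj, i] <- pairs$se[r]
      valid[i, jj] <- valid[jj, i] <- TRUE
    }
    p[i, jj] <- p[jj, i] <- pairs$p[r]
  }
  diag(rg) <- 1
  diag(valid) <- TRUE

  new_rg_matrix(traits = traits, rg = rg, se = se, p = p, valid = valid,
                pairs = pairs, h2 = h2_tbl,
                n_invalid = sum(!pairs$valid))
}

new_rg_matrix <- function(traits, rg, se, p, valid, pairs = NULL, h2 = NULL,
                          n_invalid = NULL) {
  structure(
    list(traits = traits, rg = rg, se = se, p = p, valid = valid,
         pairs = pairs, h2 = h2,
         n_invalid = n_invalid %||% sum(!valid[upper.tri(valid)])),
    class = "rg_matrix"
  )
}

#' Construct a genetic-correlation matrix from known values
#'
#' Wraps precomputed (or planted) pairwise genetic correlations in the
#' container the network stage consumes. Useful for supplying an external
#' r_g estimate, or block-structured ground truth in simulations.
#'
#' @param rg Symmetric numeric matrix with unit diagonal (`NA` allowed off
#'   the diagonal for invalid pairs).
#' @param p Matrix of pair P-values (default 0 wherever `rg` is not `NA`,
#'   so every entry survives any P threshold).
#' @param valid Logical matrix (default: wherever `rg` is finite and in
#'   `[-1, 1]`).
#' @param se Optional matrix of standard errors.
#' @return An `rg_matrix`.
#' @export
rg_matrix <- function(rg, p = NULL, valid = NULL, se = NULL) {
  check_matrix_symmetric(rg, "rg")
  traits <- rownames(rg) %||% sprintf("trait%02d", seq_len(nrow(rg)))
  dimnames(rg) <- list(traits, traits)
  if (any(abs(diag(rg) - 1) > 1e-8)) {
    abort("`rg` must have a unit diagonal.", class = "gcnet_invalid_argument")
  }
  if (is.null(valid)) {
    valid <- is.finite(rg) & abs(rg) <= 1
    diag(valid) <- TRUE
  }
  if (is.null(p)) {
    p <- matrix(0, nrow(rg), ncol(rg))
    p[!valid] <- NA_real_
  }
  if (is.null(se)) se <- matrix(NA_real_, nrow(rg), ncol(rg))
  dimnames(p) <- dimnames(valid) <- dimnames(se) <- dimnames(rg)
  rg[!valid] <- NA_real_
  diag(rg) <- 1
  new_rg_matrix(traits = traits, rg = rg, se = se, p = p, valid = valid)
}

#' @export
print.rg_matrix <- function(x, ...) {
  k <- length(x$traits)
  cat(sprintf("<rg_matrix> %d traits, %d pair(s) invalid of %d\n",
              k, x$n_invalid, k * (k - 1) / 2))
  invisible(x)
}
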