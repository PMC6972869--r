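# Combined cross-phenotype statistics, R estimation, null calibration.

# Independent implementation of the combined statistic on an arbitrary
# component subset, straight from the printed formulas.
s_subset_oracle <- function(t_vec, R, w, idx) {
  e <- rep(1, length(idx))
  Rs <- R[idx, idx, drop = FALSE]
  Ws <- diag(w[idx], nrow = length(idx))
  num <- drop(t(e) %*% solve(Rs %*% Ws) %*% t_vec[idx])^2
  den <- drop(t(e) %*% solve(Ws %*% Rs %*% Ws) %*% e)
  num / den
}

# Brute force over every magnitude-ordered subset (top-q by |T|).
s_het_oracle <- function(t_vec, R, w = rep(1, length(t_vec))) {
  ord <- order(abs(t_vec), decreasing = TRUE)
  max(vapply(seq_along(t_vec), function(q) {
    s_subset_oracle(t_vec, R, w, sort(ord[seq_len(q)]))
  }, numeric(1)))
}

random_corr <- function(k, seed) {
  withr::with_seed(seed, {
    a <- matrix(rnorm(k * k), k)
    r <- cov2cor(crossprod(a) + diag(k) * 0.5)
  })
  r
}

test_that("S_Hom matches its closed forms", {
  r <- s_hom(2, matrix(1))
  expect_equal(r$s_hom, 4)
  expect_equal(r$p, pchisq(4, 1, lower.tail = FALSE), tolerance = 1e-10)

  expect_equal(s_hom(c(1, 1), diag(2))$s_hom, 2, tolerance = 1e-12)
  expect_equal(s_hom(c(1, -1), diag(2))$s_hom, 0, tolerance = 1e-12)

  # weights cancel at K = 1
  expect_equal(s_hom(2, matrix(1), w = 37)$s_hom, 4, tolerance = 1e-12)
  expect_error(s_hom(c(1, 2), matrix(1)), class = "gcnet_invalid_argument")
})

test_that("S_Het visits magnitude subsets and handles heterogeneity", {
  expect_equal(s_het(3, matrix(1))$s_het, 9)

  r <- s_het(c(3, 0.1), diag(2))
  expect_equal(r$s_het, 9, tolerance = 1e-12)
  expect_equal(r$k_retained, 1L)
  expect_equal(r$tau_star, 0.1)

  # opposite effects: the homogeneous statistic dies, S_Het survives
  r2 <- s_het(c(3, -3), diag(2))
  expect_equal(r2$s_het, 9, tolerance = 1e-12)
  expect_equal(s_hom(c(3, -3), diag(2))$s_hom, 0, tolerance = 1e-12)

  # full retention when all components carry signal
  r3 <- s_het(c(2, 2.1), diag(2))
  expect_equal(r3$k_retained, 2L)
  expect_equal(r3$tau_star, 0)
  expect_equal(r3$s_het, (4.1)^2 / 2, tolerance = 1e-12)
})

test_that("S_Het equals the brute-force subset oracle for K <= 4", {
  for (s in 1:25) {
    k <- 2 + (s %% 3)
    R <- random_corr(k, 5000 + s)
    w <- withr::with_seed(6000 + s, runif(k, 0.5, 2))
    t_vec <- withr::with_seed(7000 + s, rnorm(k, sd = 2))
    expect_equal(s_het(t_vec, R, w)$s_het, s_het_oracle(t_vec, R, w),
                 tolerance = 1e-10)
    # and S_Hom matches the full-set oracle
    expect_equal(s_hom(t_vec, R, w)$s_hom,
                 s_subset_oracle(t_vec, R, w, seq_len(k)),
                 tolerance = 1e-10)
  }
})

test_that("both statistics are invariant to trait permutation", {
  k <- 5
  R <- random_corr(k, 11)
  w <- withr::with_seed(12, runif(k, 0.5, 2))
  t_vec <- withr::with_seed(13, rnorm(k, sd = 1.5))
  perm <- withr::with_seed(14, sample(k))
  expect_equal(s_hom(t_vec, R, w)$s_hom,
               s_hom(t_vec[perm], R[perm, perm], w[perm])$s_hom,
               tolerance = 1e-10)
  expect_equal(s_het(t_vec, R, w)$s_het,
               s_het(t_vec[perm], R[perm, perm], w[perm])$s_het,
               tolerance = 1e-10)
})

test_that("S_Het dominates the largest single-component chi-square", {
  for (s in 1:20) {
    k <- 3 + (s %% 4)
    R <- random_corr(k, 8000 + s)
    t_vec <- withr::with_seed(9000 + s, rnorm(k, sd = 2))
    expect_gte(s_het(t_vec, R)$s_het + 1e-10, max(t_vec^2))
  }
})

test_that("at K = 1 both statistics reduce to T^2 with chi-square P", {
  for (t_val in c(-2.5, 0.3, 1.96)) {
    expect_equal(s_hom(t_val, matrix(1))$s_hom, t_val^2, tolerance = 1e-12)
    expect_equal(s_het(t_val, matrix(1))$s_het, t_val^2, tolerance = 1e-12)
  }
  null <- calibrate_shet_null(matrix(1), B = 20000, seed = 3)
  stat <- 1.7^2
  pv <- shet_pvalue(stat, null)
  expect_lt(abs(pv$p_empirical - pchisq(stat, 1, lower.tail = FALSE)),
            0.01)
  # fitted beta near (1, 1): the transform of a chi-square(1) is uniform
  expect_equal(unname(null$beta), c(1, 1), tolerance = 0.05)
})

test_that("R estimation: identical traits give 1, disjoint cohorts give ~0", {
  z0 <- withr::with_seed(21, matrix(rnorm(4000), 2000, 2))
  z_dup <- cbind(z0[, 1], z0[, 1])
  r_dup <- estimate_stat_correlation(z_dup)
  expect_equal(r_dup[1, 2], 1, tolerance = 1e-10)

  r0 <- estimate_stat_correlation(z0)
  expect_lt(abs(r0[1, 2]), 3 / sqrt(2000))

  expect_error(estimate_stat_correlation(z0[1:100, ]),
               class = "gcnet_invalid_argument")
})

test_that("full sample overlap transfers phenotypic correlation to R", {
  # two null traits (h2 = 0) with environmental correlation 0.6 measured
  # on the same cohort: the statistic correlation equals the phenotypic
  # correlation. With no truncation the estimate is sharp; the default
  # |Z| < 1.96 null cutoff attenuates it moderately.
  rho <- diag(2)
  gw <- simulate_gwas_set(n = 1000, m = 5000, h2 = c(0, 0), rho = rho,
                          env_cor = 0.6, seed = 31)
  al <- align_module_stats(gw$stats)
  r_full <- estimate_stat_correlation(al$z, z_cutoff = 50)
  expect_lt(abs(r_full[1, 2] - 0.6), 0.05)
  r_trunc <- estimate_stat_correlation(al$z)
  expect_lt(abs(r_trunc[1, 2] - 0.6), 0.12)
  expect_lte(abs(r_trunc[1, 2]), abs(r_full[1, 2]))
})

test_that("null calibration is deterministic and its quantiles behave", {
  R <- matrix(0.5, 3, 3); diag(R) <- 1
  n1 <- suppressWarnings(calibrate_shet_null(R, B = 5000, seed = 7))
  n2 <- suppressWarnings(calibrate_shet_null(R, B = 5000, seed = 7))
  expect_identical(n1$sorted_stats, n2$sorted_stats)
  expect_identical(n1$beta, n2$beta)

  # empirical P of the 95th-percentile draw is 0.05 by construction
  q95 <- stats::quantile(n1$sorted_stats, 0.95, names = FALSE)
  expect_equal(shet_pvalue(q95, n1)$p_empirical, 0.05,
               tolerance = 2 / sqrt(5000))

  # a statistic below the null minimum has empirical P ~ 1
  expect_equal(shet_pvalue(min(n1$sorted_stats) - 1, n1)$p_empirical, 1,
               tolerance = 1 / 5001)

  # monotonicity of both P maps
  ss <- seq(0.5, 25, length.out = 40)
  pv <- shet_pvalue(ss, n1)
  expect_true(all(diff(pv.empirical <- pv$p_empirical) <= 0))
  expect_true(all(diff(pv$p_beta) <= 0))

  # the empirical floor hands over to the beta tail
  huge <- max(n1$sorted_stats) + 10
  pvh <- shet_pvalue(huge, n1)
  expect_equal(pvh$p, pvh$p_beta)
  expect_lt(pvh$p, 1 / 5001)

  expect_error(calibrate_shet_null(matrix(c(1, 2, 2, 1), 2), B = 5000),
               class = "gcnet_invalid_argument")
  expect_error(shet_pvalue(1, n1, R = diag(3)),
               class = "gcnet_invalid_argument")
})

test_that("module scan aligns alleles, applies thresholds, exports tables", {
  gw <- simulate_gwas_set(n = 500, m = 1000, h2 = c(0.3, 0.3),
                          rho = matrix(c(1, 0.8, 0.8, 1), 2),
                          n_causal = 100, seed = 41)
  scan <- suppressWarnings(module_scan(gw$stats, B = 2000, seed = 5))
  expect_true(all(c("S_HOM", "P_HOM", "S_HET", "P_HET", "SIGNIFICANT")
                  %in% names(scan)))
  expect_equal(nrow(scan), 1000)
  expect_true(all(scan$S_HOM >= 0))
  expect_true(all(scan$S_HET + 1e-10 >= scan$TAU_STAR * 0))

  # allele flips in one trait leave the scan invariant
  s2 <- gw$stats
  s2[[2]]$A1 <- gw$stats[[2]]$A2
  s2[[2]]$A2 <- gw$stats[[2]]$A1
  s2[[2]]$Z <- -gw$stats[[2]]$Z
  s2[[2]]$BETA <- -gw$stats[[2]]$BETA
  scan2 <- suppressWarnings(module_scan(s2, B = 2000, seed = 5))
  expect_equal(scan2$S_HOM, scan$S_HOM, tolerance = 1e-10)
  expect_equal(scan2$S_HET, scan$S_HET, tolerance = 1e-10)

  tabs <- export_association_table(scan)
  expect_true(!is.unsorted(tabs$association$BP))
  m <- nrow(tabs$association)
  expect_equal(tabs$qq$expected[1:m], -log10((seq_len(m) - 0.5) / m))

  # the 5e-8 genome-wide flag is inclusive
  fake <- scan[1:3, ]
  fake$P_HOM <- c(5e-8, 6e-8, 1e-9)
  fake$P_HET <- 1
  tf <- export_association_table(fake, threshold = 1e-7)
  expect_equal(tf$association$GENOME_WIDE[order(tf$association$SNP)],
               c(TRUE, FALSE, TRUE))
  expect_error(export_association_table(scan[0, ]),
               class = "gcnet_invalid_argument")
})

test_that("empty SNP intersections are an error", {
  s1 <- make_sumstats(rnorm(10))
  s2 <- make_sumstats(rnorm(10))
  s2$SNP <- paste0("other_", s2$SNP)
  expect_error(align_module_stats(list(a = s1, b = s2)),
               class = "gcnet_invalid_argument")
})
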