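# Fixture builders shared across test files. Everything is generated in
# code under fixed seeds; nothing is read from disk.

# Minimal geno_table built directly from a dosage matrix.
make_geno <- function(dosage, chr = NULL, a1 = NULL, a2 = NULL) {
  n <- nrow(dosage)
  m <- ncol(dosage)
  snp <- sprintf("snp_%05d", seq_len(m))
  samples <- sprintf("IID%05d", seq_len(n))
  dimnames(dosage) <- list(samples, snp)
  gcnet:::new_geno_table(
    dosage = dosage,
    variants = tibble::tibble(
      SNP = snp,
      CHR = chr %||% rep(1L, m),
      BP = seq_len(m) * 1000L,
      A1 = a1 %||% rep("A", m),
      A2 = a2 %||% rep("G", m),
      MAF = colMeans(dosage, na.rm = TRUE) / 2
    ),
    samples = samples
  )
}

`%||%` <- function(x, y) if (is.null(x)) y else x

# Summary-statistics tibble from raw vectors (defaults make a clean table).
make_sumstats <- function(z, n = 1000, beta = NULL, se = NULL,
                          a1 = NULL, a2 = NULL, trait_id = "trait") {
  m <- length(z)
  se <- se %||% rep(0.05, m)
  beta <- beta %||% (z * se)
  out <- tibble::tibble(
    SNP = sprintf("snp_%05d", seq_len(m)),
    CHR = 1L, BP = seq_len(m) * 1000L,
    A1 = a1 %||% rep("A", m), A2 = a2 %||% rep("G", m),
    BETA = beta, SE = se, Z = z,
    P = 2 * stats::pnorm(-abs(z)), N = rep(n, m)
  )
  attr(out, "trait_id") <- trait_id
  out
}

# Constant LD-score track (independent-SNP regime).
make_ld_unit <- function(m) {
  out <- tibble::tibble(SNP = sprintf("snp_%05d", seq_len(m)), L = rep(1, m))
  attr(out, "M") <- m
  out
}

# One cohort + GWAS per trait, sharing a truth across cohorts when
# `separate_cohorts` (disjoint samples, so no overlap term in the
# cross-trait regression).
simulate_gwas_set <- function(n = 1000, m = 2000, h2 = c(0.5, 0.5),
                              rho = NULL, n_causal = 200, env_cor = 0,
                              seed = 1, separate_cohorts = FALSE,
                              covariates = character(),
                              signal_effects = NULL) {
  k <- length(h2)
  geno1 <- simulate_genotypes(n, m, maf_range = c(0.1, 0.5), seed = seed)
  truth <- simulation_truth(geno1$variants$SNP, h2 = h2, rho_g = rho,
                            n_causal = n_causal, env_cor = env_cor,
                            signal_effects = signal_effects,
                            seed = seed + 1000L)
  stats <- vector("list", k)
  names(stats) <- truth$trait_ids
  if (separate_cohorts) {
    for (j in seq_len(k)) {
      gj <- if (j == 1) geno1 else {
        simulate_genotypes(n, variants = geno1$variants,
                           seed = seed + 17L * j)
      }
      pj <- simulate_phenotypes(gj, truth,
                                seed = seed + 31L * j + 7L)
      stats[[j]] <- gwas_scan(gj, pj, truth$trait_ids[j],
                              covariates = covariates,
                              trait_id = truth$trait_ids[j])
    }
  } else {
    pheno <- simulate_phenotypes(geno1, truth, seed = seed + 7L)
    stats <- gwas_scan_all(geno1, pheno, truth$trait_ids,
                           covariates = covariates)
  }
  ld <- make_ld_unit(m)
  list(stats = stats, ld = ld, truth = truth, genotypes = geno1)
}

# Adjusted Rand index oracle (mclust) with a plain fallback for exact
# agreement checks.
ari <- function(a, b) mclust::adjustedRandIndex(a, b)
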