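#' Simulate a genotype table
#'
#' Draws a cohort of unrelated samples at mostly independent biallelic SNPs
#' under an additive 0/1/2 dosage coding (copies of the effect allele A1).
#' Each SNP receives its own allele frequency, uniform on `maf_range`, and
#' genotypes are binomial(2, MAF) independently per sample. An optional LD
#' mode induces block-autocorrelated dosages through a Gaussian copula, which
#' is useful when a varying LD-score regressor is wanted.
#'
#' @param n_samples Number of samples (> 0).
#' @param n_snps Number of SNPs (> 0).
#' @param maf_range Length-2 numeric range for per-SNP allele frequencies,
#'   within (0, 0.5]. A degenerate range (equal endpoints) fixes the MAF.
#' @param missing_rate Fraction of dosages set missing uniformly at random,
#'   in \[0, 0.2\].
#' @param seed Integer seed; output is bit-reproducible given the seed.
#' @param n_chr Number of chromosomes the SNPs are split across (contiguous
#'   blocks, 1-based positions strictly increasing within a chromosome).
#' @param ld `NULL` for independent SNPs (the default), or a list with
#'   elements `block_size` and `rho_range`: within each block of
#'   `block_size` consecutive SNPs the latent Gaussians follow an AR(1)
#'   process whose coefficient is drawn uniformly from `rho_range`, giving
#'   blocks of varying LD strength.
#' @param variants Optional variant table from a previously simulated
#'   `geno_table` (columns `SNP`, `CHR`, `BP`, `A1`, `A2`, `MAF`). Use it
#'   to draw a second cohort of the same variants — same ids, alleles and
#'   population allele frequencies — with fresh genotypes, the
#'   multi-cohort mode. Overrides `n_snps`, `maf_range` and `n_chr`.
#'
#' @return A `geno_table`: list with `dosage` (samples x SNPs integer matrix,
#'   `NA` for missing), `variants` (tibble with `SNP`, `CHR`, `BP`, `A1`,
#'   `A2`, `MAF`), and `samples` (character IDs).
#' @examples
#' g <- simulate_genotypes(50, 10, maf_range = c(0.2, 0.5), seed = 1)
#' g
#' @export
simulate_genotypes <- function(n_samples, n_snps = NULL,
                               maf_range = c(0.05, 0.5),
                               missing_rate = 0, seed = 1L, n_chr = 1L,
                               ld = NULL, variants = NULL) {
  check_scalar_number(n_samples, "n_samples", lower = 1, integerish = TRUE)
  if (!is.null(variants)) {
    need <- c("SNP", "CHR", "BP", "A1", "A2", "MAF")
    if (!all(need %in% names(variants))) {
      abort("`variants` must carry SNP, CHR, BP, A1, A2 and MAF columns.",
            class = "gcnet_invalid_argument")
    }
    n_snps <- nrow(variants)
  }
  if (is.null(n_snps)) {
    abort("Provide either `n_snps` or a `variants` template.",
          class = "gcnet_invalid_argument")
  }
  check_scalar_number(n_snps, "n_snps", lower = 1, integerish = TRUE)
  check_scalar_number(missing_rate, "missing_rate", lower = 0, upper = 0.2)
  check_scalar_number(n_chr, "n_chr", lower = 1, upper = 22, integerish = TRUE)
  if (!is.numeric(maf_range) || length(maf_range) != 2L ||
      any(!is.finite(maf_range)) || maf_range[1] > maf_range[2] ||
      maf_range[1] <= 0 || maf_range[2] > 0.5) {
    abort("`maf_range` must be an increasing range within (0, 0.5].",
          class = "gcnet_invalid_argument")
  }
  n_samples <- as.integer(n_samples)
  n_snps <- as.integer(n_snps)

  withr::with_seed(as.integer(seed), {
    maf <- if (is.null(variants)) {
      runif(n_snps, maf_range[1], maf_range[2])
    } else {
      variants$MAF
    }
    if (is.null(ld)) {
      dose <- matrix(rbinom(n_samples * n_snps, 2L, rep(maf, each = n_samples)),
                     nrow = n_samples, ncol = n_snps)
    } else {
      dose <- simulate_ld_dosages(n_samples, n_snps, maf, ld)
    }
    if (missing_rate > 0) {
      miss <- runif(n_samples * n_snps) < missing_rate
      dose[miss] <- NA_integer_
    }
    alleles <- t(vapply(seq_len(n_snps), function(i) {
      sample(c("A", "C", "G", "T"), 2L)
    }, character(2)))
  })

  if (is.null(variants)) {
    chr <- rep(seq_len(n_chr), length.out = n_snps)
    chr <- sort(chr)
    bp <- integer(n_snps)
    for (c_i in unique(chr)) {
      idx <- which(chr == c_i)
      bp[idx] <- seq_along(idx) * 1000L
    }
    snp <- sprintf("snp_%05d", seq_len(n_snps))
    variants <- tibble(SNP = snp, CHR = chr, BP = bp,
                       A1 = alleles[, 1], A2 = alleles[, 2], MAF = maf)
  } else {
    variants <- as_tibble(variants[c("SNP", "CHR", "BP", "A1", "A2",
                                     "MAF")])
  }
  samples <- sprintf("IID%05d", seq_len(n_samples))
  dimnames(dose) <- list(samples, variants$SNP)

  new_geno_table(dosage = dose, variants = variants, samples = samples)
}

# Gaussian-copula AR(1) blocks: latent z autocorrelated within blocks,
# mapped through the binomial quantile function to preserve the margins.
simulate_ld_dosages <- function(n_samples, n_snps, maf, ld) {
  block_size <- ld$block_size %||% 50L
  rho_range <- ld$rho_range %||% c(0.2, 0.9)
  check_scalar_number(block_size, "ld$block_size", lower = 2, integerish = TRUE)
  z <- matrix(rnorm(n_samples * n_snps), n_samples, n_snps)
  starts <- seq(1L, n_snps, by = as.integer(block_size))
  for (s in starts) {
    e <- min(s + block_size - 1L, n_snps)
    if (e == s) next
    rho <- runif(1, rho_range[1], rho_range[2])
    for (j in (s + 1L):e) {
      z[, j] <- rho * z[, j - 1L] + sqrt(1 - rho^2) * z[, j]
    }
  }
  u <- pnorm(z)
  dose <- matrix(0L, n_samples, n_snps)
  for (j in seq_len(n_snps)) {
    dose[, j] <- as.integer(stats::qbinom(u[, j], 2L, maf[j]))
  }
  dose
}

new_geno_table <- function(dosage, variants, samples) {
  structure(list(dosage = dosage, variants = variants, samples = samples),
            class = "geno_table")
}

#' @export
print.geno_table <- function(x, ...) {
  cat(sprintf("<geno_table> %d samples x %d SNPs (%d chromosome%s)\n",
              length(x$samples), nrow(x$variants),
              length(unique(x$variants$CHR)),
              if (length(unique(x$variants$CHR)) > 1) "s" else ""))
  miss <- mean(is.na(x$dosage))
  cat(sprintf("  missing dosages: %.2f%%\n", 100 * miss))
  invisible(x)
}

#' @export
dim.geno_table <- function(x) dim(x$dosage)

# Subset a genotype table by SNP ids (keeps variant order of `snps`).
subset_geno <- function(genotypes, snps) {
  idx <- match(snps, genotypes$variants$SNP)
  if (anyNA(idx)) {
    abort("Unknown SNP ids in subset.", class = "gcnet_invalid_argument")
  }
  new_geno_table(
    dosage = genotypes$dosage[, idx, drop = FALSE],
    variants = genotypes$variants[idx, , drop = FALSE],
    samples = genotypes$samples
  )
}

#' LD scores from a genotype table
#'
#' Computes per-SNP LD scores `l_j = 1 + sum(r^2)` over neighbouring SNPs on
#' the same chromosome within a fixed SNP-count window, where `r` is the
#' Pearson correlation of dosages. With `window_snps = 0` every score is
#' exactly 1, the independent-SNP regime. A SNP with zero dosage variance
#' contributes 0 to its neighbours' scores (with a warning).
#'
#' @param genotypes A `geno_table`.
#' @param window_snps Non-negative window half-width in SNPs.
#' @return A tibble with columns `SNP`, `L`, carrying attributes `M` (number
#'   of scored SNPs) and `window_snps`.
#' @export
make_ld_scores <- function(genotypes, window_snps = 0L) {
  check_scalar_number(window_snps, "window_snps", lower = 0, integerish = TRUE)
  window_snps <- as.integer(window_snps)
  m <- nrow(genotypes$variants)
  l <- rep(1, m)
  if (window_snps > 0L && m > 1L) {
    x <- genotypes$dosage
    # standardize columns; zero-variance columns become all-zero
    mu <- colMeans(x, na.rm = TRUE)
    xc <- sweep(x, 2L, mu)
    xc[is.na(xc)] <- 0
    nobs <- colSums(!is.na(x))
    ss <- colSums(xc^2)
    zero_var <- ss <= 1e-12
    if (any(zero_var)) {
      warn(sprintf("%d SNP(s) with zero dosage variance contribute 0 to LD scores.",
                   sum(zero_var)))
    }
    sdv <- sqrt(ss / pmax(nobs - 1, 1))
    sdv[zero_var] <- Inf
    xs <- sweep(xc, 2L, sdv, "/")
    chr <- genotypes$variants$CHR
    n1 <- pmax(nobs - 1, 1)
    for (d in seq_len(min(window_snps, m - 1L))) {
      i <- seq_len(m - d)
      j <- i + d
      r <- colSums(xs[, i, drop = FALSE] * xs[, j, drop = FALSE]) /
        pmax(pmin(n1[i], n1[j]), 1)
      r[chr[i] != chr[j]] <- 0
      r2 <- r^2
      l[i] <- l[i] + r2
      l[j] <- l[j] + r2
    }
  }
  out <- tibble(SNP = genotypes$variants$SNP, L = l)
  attr(out, "M") <- m
  attr(out, "window_snps") <- window_snps
  out
}
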