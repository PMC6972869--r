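#' Hardy-Weinberg equilibrium goodness-of-fit test
#'
#' One-degree-of-freedom chi-square test of the observed genotype counts
#' against the expectation under Hardy-Weinberg proportions at the allele
#' frequency estimated from the same counts. Returns the upper-tail P.
#'
#' @param n_AA,n_Aa,n_aa Non-negative genotype counts (A1 homozygote,
#'   heterozygote, A2 homozygote). `n_AA` may also be a length-3 vector of
#'   all three counts.
#' @return A list with `chisq` and `p`.
#' @examples
#' hwe_test(25, 50, 25)  # exact HWE proportions: chisq 0, p 1
#' hwe_test(30, 40, 30)  # chisq 4
#' @export
hwe_test <- function(n_AA, n_Aa = NULL, n_aa = NULL) {
  if (is.null(n_Aa) && length(n_AA) == 3L) {
    counts <- as.numeric(n_AA)
  } else {
    counts <- c(n_AA, n_Aa, n_aa)
  }
  if (length(counts) != 3L || any(!is.finite(counts)) || any(counts < 0)) {
    abort("Genotype counts must be three non-negative numbers.",
          class = "gcnet_invalid_argument")
  }
  n <- sum(counts)
  if (n <= 0) {
    abort("Total genotype count must be positive.",
          class = "gcnet_invalid_argument")
  }
  p <- (2 * counts[1] + counts[2]) / (2 * n)
  expected <- n * c(p^2, 2 * p * (1 - p), (1 - p)^2)
  term <- ifelse(expected > 0, (counts - expected)^2 / expected, 0)
  chisq <- sum(term)
  list(chisq = chisq, p = pchisq(chisq, df = 1, lower.tail = FALSE))
}

#' Per-SNP quality control
#'
#' Retains exactly the SNPs passing all of: call rate at or above
#' `min_call_rate`, minor allele frequency at or above `min_maf` (computed
#' on the observed genotypes of the analyzed samples), and Hardy-Weinberg
#' P at or above `min_hwe_p`. Thresholds are inclusive. The report names,
#' for every excluded SNP, the first failing rule in the order
#' call rate, MAF, HWE.
#'
#' @param genotypes A `geno_table`.
#' @param min_call_rate,min_maf,min_hwe_p Inclusive thresholds; defaults
#'   0.98, 0.01 and 1e-6.
#' @return A list with `genotypes` (the filtered `geno_table`) and `report`
#'   (tibble: `SNP`, `call_rate`, `maf`, `hwe_p`, `pass`, `fail_rule`).
#' @export
snp_qc <- function(genotypes, min_call_rate = 0.98, min_maf = 0.01,
                   min_hwe_p = 1e-6) {
  stopifnot(inherits(genotypes, "geno_table"))
  check_scalar_number(min_call_rate, "min_call_rate", 0, 1)
  check_scalar_number(min_maf, "min_maf", 0, 1)
  check_scalar_number(min_hwe_p, "min_hwe_p", 0, 1)
  dose <- genotypes$dosage
  if (length(dose) == 0) {
    abort("`genotypes` is empty.", class = "gcnet_invalid_argument")
  }
  n <- nrow(dose)
  n_obs <- colSums(!is.na(dose))
  call_rate <- n_obs / n
  n2 <- colSums(dose == 2L, na.rm = TRUE)
  n1 <- colSums(dose == 1L, na.rm = TRUE)
  n0 <- n_obs - n1 - n2
  p1 <- ifelse(n_obs > 0, (2 * n2 + n1) / (2 * n_obs), NA_real_)
  maf <- pmin(p1, 1 - p1)
  hwe_p <- vapply(seq_along(n_obs), function(j) {
    if (n_obs[j] == 0) return(NA_real_)
    hwe_test(c(n2[j], n1[j], n0[j]))$p
  }, numeric(1))

  fail_rule <- rep(NA_character_, length(call_rate))
  fail_rule[!is.na(hwe_p) & hwe_p < min_hwe_p] <- "hwe"
  fail_rule[is.na(maf) | maf < min_maf] <- "maf"
  fail_rule[call_rate < min_call_rate] <- "call_rate"
  pass <- is.na(fail_rule)

  report <- tibble(
    SNP = genotypes$variants$SNP,
    call_rate = call_rate, maf = maf, hwe_p = hwe_p,
    pass = pass, fail_rule = fail_rule
  )
  list(genotypes = subset_geno(genotypes, report$SNP[pass]), report = report)
}

#' Additive-model association scan
#'
#' For every SNP, ordinary least squares of the phenotype on the A1 dosage
#' plus covariates plus an intercept. Samples with a missing dosage are
#' casewise-deleted for that SNP only; samples missing the phenotype or any
#' covariate are dropped up front. The Wald statistic is `Z = BETA/SE`, with
#' a two-sided P from the standard-normal reference by default (exact t via
#' `p_reference = "t"`). SNPs whose post-deletion dosage has (numerically)
#' zero variance, or whose fit is residual-free, are emitted with a
#' diagnostic `flag` and undefined statistics; [write_summary_stats()]
#' excludes them from downstream files.
#'
#' @param genotypes A QC'ed `geno_table`.
#' @param phenotypes Tibble with `IID`, the trait column, and covariates.
#' @param trait Name of the phenotype column.
#' @param covariates Character vector of covariate column names (may be
#'   empty).
#' @param trait_id Label stored in the `trait_id` attribute.
#' @param p_reference `"normal"` (default) or `"t"`.
#' @return Summary-statistics tibble `SNP CHR BP A1 A2 BETA SE Z P N flag`.
#' @export
gwas_scan <- function(genotypes, phenotypes, trait,
                      covariates = character(), trait_id = trait,
                      p_reference = c("normal", "t")) {
  stopifnot(inherits(genotypes, "geno_table"))
  p_reference <- match.arg(p_reference)
  cols <- c("IID", trait, covariates)
  missing_cols <- setdiff(cols, names(phenotypes))
  if (length(missing_cols) > 0) {
    abort(sprintf("Phenotype table lacks column(s): %s",
                  paste(missing_cols, collapse = ", ")),
          class = "gcnet_invalid_argument")
  }
  ph <- phenotypes[cols]
  ph <- ph[match(genotypes$samples, ph$IID), , drop = FALSE]
  if (anyNA(ph$IID)) {
    abort("Phenotype table does not cover all genotyped samples.",
          class = "gcnet_invalid_argument")
  }
  keep <- complete.cases(ph)
  ph <- ph[keep, , drop = FALSE]
  dose <- genotypes$dosage[keep, , drop = FALSE]
  n <- nrow(ph)
  q <- cbind(`(Intercept)` = 1,
             as.matrix(ph[, covariates, drop = FALSE]))
  if (n < ncol(q) + 2L) {
    abort("Too few complete samples for the covariate model.",
          class = "gcnet_invalid_argument")
  }
  y <- ph[[trait]]
  qr_q <- qr(q)
  ry <- qr.resid(qr_q, y)
  ssy <- sum(ry^2)
  df <- n - ncol(q) - 1L

  m <- ncol(dose)
  beta <- se <- rep(NA_real_, m)
  n_used <- rep(n, m)
  flag <- rep("ok", m)
  has_na <- colSums(is.na(dose)) > 0L

  complete_idx <- which(!has_na)
  if (length(complete_idx) > 0) {
    x <- dose[, complete_idx, drop = FALSE]
    rx <- qr.resid(qr_q, x)
    ssx <- colSums(rx^2)
    b <- colSums(rx * ry) / ifelse(ssx > 0, ssx, NA_real_)
    rss <- pmax(ssy - b^2 * ssx, 0)
    s2 <- rss / df
    beta[complete_idx] <- b
    se[complete_idx] <- sqrt(s2 / ssx)
    zero_var <- ssx <= 1e-10
    perfect <- !zero_var & rss <= 1e-10 * ssy
    flag[complete_idx[zero_var]] <- "zero_variance"
    flag[complete_idx[perfect]] <- "perfect_fit"
  }

  for (j in which(has_na)) {
    obs <- !is.na(dose[, j])
    nj <- sum(obs)
    n_used[j] <- nj
    if (nj < ncol(q) + 2L) {
      flag[j] <- "zero_variance"
      next
    }
    fit <- stats::lm.fit(cbind(dose = dose[obs, j], q[obs, , drop = FALSE]),
                         y[obs])
    if (is.na(fit$coefficients[1]) || fit$df.residual <= 0) {
      flag[j] <- "zero_variance"
      next
    }
    res <- fit$residuals
    rssj <- sum(res^2)
    xobs <- dose[obs, j]
    rxj <- qr.resid(qr(q[obs, , drop = FALSE]), xobs)
    ssxj <- sum(rxj^2)
    if (ssxj <= 1e-10) {
      flag[j] <- "zero_variance"
      next
    }
    beta[j] <- fit$coefficients[1]
    s2j <- rssj / fit$df.residual
    se[j] <- sqrt(s2j / ssxj)
    if (rssj <= 1e-10 * sum(qr.resid(qr(q[obs, , drop = FALSE]), y[obs])^2)) {
      flag[j] <- "perfect_fit"
    }
  }

  z <- beta / se
  p <- if (p_reference == "normal") {
    2 * pnorm(-abs(z))
  } else {
    2 * stats::pt(-abs(z), df = pmax(n_used - ncol(q) - 1L, 1L))
  }
  z[flag != "ok" & flag != "perfect_fit"] <- NA_real_
  p[flag != "ok"] <- NA_real_
  se[flag == "zero_variance"] <- NA_real_

  out <- dplyr::bind_cols(
    genotypes$variants[c("SNP", "CHR", "BP", "A1", "A2")],
    tibble(BETA = beta, SE = se, Z = z, P = p, N = n_used, flag = flag)
  )
  attr(out, "trait_id") <- trait_id
  out
}

#' Run the association scan for several traits
#'
#' @param genotypes A QC'ed `geno_table`.
#' @param phenotypes Tibble with `IID`, trait and covariate columns.
#' @param traits Character vector of trait column names.
#' @inheritParams gwas_scan
#' @return Named list of summary-statistics tibbles.
#' @export
gwas_scan_all <- function(genotypes, phenotypes, traits,
                          covariates = character(),
                          p_reference = c("normal", "t")) {
  p_reference <- match.arg(p_reference)
  stats <- purrr::map(traits, function(tr) {
    gwas_scan(genotypes, phenotypes, tr, covariates = covariates,
              trait_id = tr, p_reference = p_reference)
  })
  setNames(stats, traits)
}

#' Genomic-control inflation factor
#'
#' `lambda = median(Z^2) / 0.45494`, the median of the observed Wald
#' chi-squares over the chi-square(1 df) median. Flagged (degenerate) SNP
#' records are ignored.
#'
#' @param stats Summary-statistics tibble with a `Z` column.
#' @return The scalar lambda.
#' @export
genomic_control_lambda <- function(stats) {
  z <- stats$Z
  if ("flag" %in% names(stats)) z <- z[stats$flag == "ok"]
  z <- z[is.finite(z)]
  if (length(z) == 0) {
    abort("No usable test statistics for lambda.",
          class = "gcnet_invalid_argument")
  }
  if (length(z) < 100) {
    warn("Fewer than 100 SNPs: lambda estimate will be noisy.")
  }
  median(z^2) / CHISQ1_MEDIAN
}
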