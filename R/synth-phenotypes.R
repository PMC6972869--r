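#' Define the genetic ground truth of a simulated cohort
#'
#' Fixes everything that defines the genetic architecture of a set of
#' correlated quantitative traits: per-trait heritability, the target
#' genetic-correlation matrix, the causal SNP sets, and the realized causal
#' effect sizes (drawn once, here, so that several cohorts phenotyped from
#' the same truth share identical genetic effects — the multi-cohort mode).
#'
#' Effects are drawn per causal SNP from a zero-mean multivariate normal
#' whose trait-by-trait covariance is
#' `rho_g[k,l] * sqrt(h2[k]/c_k * h2[l]/c_l)` (with `c_k` the causal count of
#' trait k), then masked to each trait's causal set. With a shared causal set
#' the expected genetic covariance between traits k and l is exactly
#' `rho_g[k,l] * sqrt(h2[k]*h2[l])`; disjoint sets give genetically
#' independent traits regardless of `rho_g`.
#'
#' @param snp_ids Character vector of available SNP ids.
#' @param h2 Numeric vector of per-trait heritabilities in \[0, 1\]; its
#'   length sets the number of traits K.
#' @param rho_g K x K positive semi-definite genetic-correlation target
#'   matrix with unit diagonal (default: identity).
#' @param n_causal Causal-set size when `causal_sets` is not given; one set
#'   of this size is sampled and shared by all traits.
#' @param causal_sets Optional list of K character vectors of causal SNP ids
#'   (one per trait); overrides `n_causal`.
#' @param env_cor Environmental correlation between every trait pair,
#'   applied on the residual scale.
#' @param covariate_effects Optional named numeric vector of effects for the
#'   generated covariates (`age`, `sex`, `edu`, `hand`, `pc1`, `pc2`, `pc3`),
#'   added to every trait after standardization.
#' @param signal_effects Optional tibble/data.frame with columns `SNP`,
#'   `trait` (integer index) and `beta`: extra fixed "signal" effects on the
#'   standardized-dosage scale, e.g. a pleiotropic SNP hitting several traits
#'   of one module. Added on top of the polygenic draw.
#' @param trait_ids Optional character vector of trait names (default
#'   `trait01`, `trait02`, ...).
#' @param seed Integer seed; the causal sets and effect sizes are drawn here
#'   and are bit-reproducible.
#'
#' @return A `sim_truth` object.
#' @export
simulation_truth <- function(snp_ids, h2, rho_g = NULL, n_causal = 100L,
                             causal_sets = NULL, env_cor = 0,
                             covariate_effects = NULL, signal_effects = NULL,
                             trait_ids = NULL, seed = 1L) {
  if (!is.character(snp_ids) || length(snp_ids) < 1L) {
    abort("`snp_ids` must be a non-empty character vector.",
          class = "gcnet_invalid_argument")
  }
  k <- length(h2)
  if (k < 1L || any(!is.finite(h2)) || any(h2 < 0) || any(h2 > 1)) {
    abort("`h2` must be heritabilities in [0, 1].",
          class = "gcnet_invalid_argument")
  }
  if (is.null(rho_g)) rho_g <- diag(k)
  check_matrix_symmetric(rho_g, "rho_g")
  if (nrow(rho_g) != k || any(abs(diag(rho_g) - 1) > 1e-8) ||
      any(abs(rho_g) > 1 + 1e-8)) {
    abort("`rho_g` must be K x K with unit diagonal and entries in [-1, 1].",
          class = "gcnet_invalid_argument")
  }
  if (!is_psd(rho_g)) {
    abort("`rho_g` target matrix is not positive semi-definite.",
          class = "gcnet_invalid_argument")
  }
  check_scalar_number(env_cor, "env_cor", lower = -1, upper = 1)
  if (is.null(trait_ids)) trait_ids <- sprintf("trait%02d", seq_len(k))

  withr::with_seed(as.integer(seed), {
    if (is.null(causal_sets)) {
      check_scalar_number(n_causal, "n_causal", lower = 0,
                          upper = length(snp_ids), integerish = TRUE)
      shared <- if (n_causal > 0) sample(snp_ids, n_causal) else character()
      causal_sets <- rep(list(shared), k)
    } else {
      if (!is.list(causal_sets) || length(causal_sets) != k) {
        abort("`causal_sets` must be a list of K character vectors.",
              class = "gcnet_invalid_argument")
      }
      bad <- setdiff(unlist(causal_sets), snp_ids)
      if (length(bad) > 0) {
        abort(sprintf("Causal SNPs not in `snp_ids`: %s ...", bad[1]),
              class = "gcnet_invalid_argument")
      }
    }
    cc <- vapply(causal_sets, length, integer(1))
    if (any(h2 > 0 & cc == 0)) {
      abort("A trait with h2 > 0 needs a non-empty causal set.",
            class = "gcnet_invalid_argument")
    }

    union_set <- unique(unlist(causal_sets))
    effects <- matrix(0, nrow = length(union_set), ncol = k,
                      dimnames = list(union_set, trait_ids))
    if (length(union_set) > 0) {
      per_snp_sd <- ifelse(h2 > 0, sqrt(h2 / pmax(cc, 1)), 0)
      sigma <- rho_g * tcrossprod(per_snp_sd)
      draws <- rmvn_eigen(length(union_set), sigma)
      mask <- vapply(seq_len(k),
                     function(j) union_set %in% causal_sets[[j]],
                     logical(length(union_set)))
      mask <- matrix(mask, nrow = length(union_set))
      effects <- draws * mask
      dimnames(effects) <- list(union_set, trait_ids)
    }
    if (!is.null(signal_effects)) {
      signal_effects <- as_tibble(signal_effects)
      stopifnot(all(c("SNP", "trait", "beta") %in% names(signal_effects)))
      extra <- setdiff(signal_effects$SNP, rownames(effects))
      if (length(extra) > 0) {
        effects <- rbind(effects,
                         matrix(0, length(extra), k,
                                dimnames = list(extra, trait_ids)))
      }
      for (i in seq_len(nrow(signal_effects))) {
        effects[signal_effects$SNP[i], signal_effects$trait[i]] <-
          effects[signal_effects$SNP[i], signal_effects$trait[i]] +
          signal_effects$beta[i]
      }
    }
  })

  structure(
    list(trait_ids = trait_ids, h2 = h2, rho_g = rho_g,
         causal_sets = causal_sets, effects = effects, env_cor = env_cor,
         covariate_effects = covariate_effects,
         signal_effects = signal_effects, seed = as.integer(seed)),
    class = "sim_truth"
  )
}

#' @export
print.sim_truth <- function(x, ...) {
  cat(sprintf("<sim_truth> %d traits, %d causal SNPs (union), seed %d\n",
              length(x$trait_ids), nrow(x$effects), x$seed))
  cat("  h2:", paste(format(x$h2, digits = 3), collapse = " "), "\n")
  invisible(x)
}

#' Simulate correlated quantitative traits on a genotyped cohort
#'
#' Builds each trait as the sum of its genetic value (causal effects times
#' standardized dosages, as fixed in the `sim_truth`) and correlated Gaussian
#' environmental noise, standardizes every trait to unit sample variance,
#' and then adds covariate contributions if the truth specifies them.
#' Covariates mimic a clinical neuroimaging cohort: age, a sex indicator,
#' years of education, a handedness indicator, and three placeholder
#' principal-component scores.
#'
#' @param genotypes A `geno_table` whose variants contain the truth's causal
#'   SNPs.
#' @param truth A `sim_truth`.
#' @param seed Integer seed for the environmental noise and covariates
#'   (default: the truth's seed plus one, so two cohorts generated from the
#'   same truth with different genotypes get distinct noise).
#' @return A tibble with `IID`, one column per trait, and covariate columns
#'   `age`, `sex`, `edu`, `hand`, `pc1`, `pc2`, `pc3`. The matrix of realized
#'   genetic values is attached as attribute `"genetic_values"`.
#' @export
simulate_phenotypes <- function(genotypes, truth, seed = NULL) {
  stopifnot(inherits(genotypes, "geno_table"), inherits(truth, "sim_truth"))
  if (is.null(seed)) seed <- derive_seed(truth$seed, 1L)
  missing_causal <- setdiff(rownames(truth$effects), genotypes$variants$SNP)
  if (length(missing_causal) > 0) {
    abort(sprintf("Causal SNP(s) absent from genotypes: %s ...",
                  missing_causal[1]),
          class = "gcnet_invalid_argument")
  }
  n <- length(genotypes$samples)
  k <- length(truth$trait_ids)

  # genetic values from standardized dosages (missing mean-imputed for
  # generation only; file readers never impute)
  g <- matrix(0, n, k, dimnames = list(genotypes$samples, truth$trait_ids))
  if (nrow(truth$effects) > 0) {
    idx <- match(rownames(truth$effects), genotypes$variants$SNP)
    x <- genotypes$dosage[, idx, drop = FALSE]
    mu <- colMeans(x, na.rm = TRUE)
    xc <- sweep(x, 2L, mu)
    xc[is.na(xc)] <- 0
    sdv <- sqrt(colSums(xc^2) / pmax(n - 1, 1))
    sdv[sdv < 1e-12] <- 1
    xs <- sweep(xc, 2L, sdv, "/")
    g <- xs %*% truth$effects
  }

  e_sd <- sqrt(pmax(1 - truth$h2, 0))
  sigma_e <- truth$env_cor * tcrossprod(e_sd)
  diag(sigma_e) <- pmax(1 - truth$h2, 0)
  if (!is_psd(sigma_e)) {
    abort("Environmental covariance implied by `env_cor` and `h2` is not PSD.",
          class = "gcnet_invalid_argument")
  }

  withr::with_seed(as.integer(seed), {
    e <- rmvn_eigen(n, sigma_e)
    y <- g + e
    ysd <- apply(y, 2L, sd)
    ysd[ysd < 1e-12] <- 1
    y <- sweep(y, 2L, ysd, "/")
    g <- sweep(g, 2L, ysd, "/")   # keep genetic values on the trait scale
    covar <- tibble(
      age = rnorm(n, 75, 7),
      sex = rbinom(n, 1L, 0.45),
      edu = rnorm(n, 16, 3),
      hand = rbinom(n, 1L, 0.9),
      pc1 = rnorm(n), pc2 = rnorm(n), pc3 = rnorm(n)
    )
  })
  if (!is.null(truth$covariate_effects)) {
    ce <- truth$covariate_effects
    bad <- setdiff(names(ce), names(covar))
    if (length(bad) > 0) {
      abort(sprintf("Unknown covariate in `covariate_effects`: %s", bad[1]),
            class = "gcnet_invalid_argument")
    }
    contrib <- as.matrix(covar[names(ce)]) %*% matrix(ce, ncol = 1)
    y <- y + contrib[, rep(1L, k), drop = FALSE]
  }

  out <- dplyr::bind_cols(
    tibble(IID = genotypes$samples),
    as_tibble(`colnames<-`(y, truth$trait_ids)),
    covar
  )
  attr(out, "genetic_values") <- g
  out
}
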