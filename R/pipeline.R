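# End-to-end driver: synthetic cohort -> QC -> per-trait GWAS -> genetic
# correlations -> trait network and modules -> cross-phenotype module
# scans -> plot-ready report tables. All randomness flows from the single
# config seed through named per-stage substreams; re-running with the same
# config reproduces byte-identical outputs.

PIPELINE_STAGES <- c("synth", "qc", "sumstats", "rg", "network",
                     "cpassoc", "report")

#' Pipeline configuration
#'
#' Assembles and validates every tunable of the pipeline. Defaults follow
#' the conventional settings of this analysis: QC at call rate 0.98, MAF
#' 0.01, HWE P 1e-6; soft powers `{2, 4, 6, 8}` against correlation
#' P-value thresholds `{0.5, 0.3, 0.2, 0.1}`; minimum module size 3; a
#' module-scan significance threshold of 1e-7 alongside the 5e-8
#' genome-wide line. The synthetic cohort defaults to 10 traits in three
#' genetically correlated blocks (within-block genetic correlation 0.8)
#' measured on one cohort of 2,000 samples at 5,000 SNPs, with two
#' pleiotropic signal SNPs planted in the first block.
#'
#' @param n_traits,n_samples,n_snps,maf_range,missing_rate,n_chr Cohort
#'   dimensions passed to [simulate_genotypes()].
#' @param h2 Per-trait heritability (scalar recycled to `n_traits`).
#' @param n_causal Shared causal-set size.
#' @param module_blocks Integer partition of the traits into genetic
#'   blocks (must sum to `n_traits`).
#' @param within_rho,between_rho Genetic correlation inside / between
#'   blocks.
#' @param env_cor Flat environmental correlation between traits.
#' @param n_signal,signal_effect Number and standardized effect size of
#'   pleiotropic signal SNPs planted on the first block's traits.
#' @param min_call_rate,min_maf,min_hwe_p QC thresholds.
#' @param covariates Covariate columns used in the association model.
#' @param ld_window LD-score window in SNPs (0 = independent-SNP regime).
#' @param beta_grid,threshold_grid,n_bins Network selection grid.
#' @param min_module_size,cut_fraction Module extraction settings.
#' @param cpassoc_b,cpassoc_threshold,z_cutoff Cross-phenotype scan
#'   settings.
#' @param seed Master seed for all stages.
#' @return A validated `pipeline_config` list.
#' @export
pipeline_config <- function(n_traits = 10L, n_samples = 2000L,
                            n_snps = 5000L, maf_range = c(0.01, 0.5),
                            missing_rate = 0, n_chr = 1L,
                            h2 = 0.5, n_causal = 500L,
                            module_blocks = c(4L, 3L, 3L),
                            within_rho = 0.8, between_rho = 0,
                            env_cor = 0.2,
                            n_signal = 2L, signal_effect = 0.15,
                            min_call_rate = 0.98, min_maf = 0.01,
                            min_hwe_p = 1e-6,
                            covariates = c("age", "sex", "edu", "hand",
                                           "pc1", "pc2", "pc3"),
                            ld_window = 0L,
                            beta_grid = c(2, 4, 6, 8),
                            threshold_grid = c(0.5, 0.3, 0.2, 0.1),
                            n_bins = 10L,
                            min_module_size = 3L, cut_fraction = 0.95,
                            cpassoc_b = 10000L, cpassoc_threshold = 1e-7,
                            z_cutoff = 1.96,
                            seed = 42L) {
  config <- list(
    n_traits = as.integer(n_traits), n_samples = as.integer(n_samples),
    n_snps = as.integer(n_snps), maf_range = as.numeric(maf_range),
    missing_rate = missing_rate, n_chr = as.integer(n_chr),
    h2 = rep_len(h2, n_traits), n_causal = as.integer(n_causal),
    module_blocks = as.integer(module_blocks),
    within_rho = within_rho, between_rho = between_rho, env_cor = env_cor,
    n_signal = as.integer(n_signal), signal_effect = signal_effect,
    min_call_rate = min_call_rate, min_maf = min_maf,
    min_hwe_p = min_hwe_p, covariates = covariates,
    ld_window = as.integer(ld_window),
    beta_grid = as.numeric(beta_grid),
    threshold_grid = as.numeric(threshold_grid),
    n_bins = as.integer(n_bins),
    min_module_size = as.integer(min_module_size),
    cut_fraction = cut_fraction,
    cpassoc_b = as.integer(cpassoc_b),
    cpassoc_threshold = cpassoc_threshold,
    z_cutoff = z_cutoff, seed = as.integer(seed)
  )
  validate_pipeline_config(config)
  structure(config, class = "pipeline_config")
}

validate_pipeline_config <- function(config) {
  check_scalar_number(config$n_traits, "n_traits", lower = 3,
                      integerish = TRUE)
  check_scalar_number(config$n_samples, "n_samples", lower = 50,
                      integerish = TRUE)
  check_scalar_number(config$n_snps, "n_snps", lower = 500,
                      integerish = TRUE)
  check_scalar_number(config$min_call_rate, "min_call_rate", 0, 1)
  check_scalar_number(config$min_maf, "min_maf", 0, 1)
  check_scalar_number(config$min_hwe_p, "min_hwe_p", 0, 1)
  check_scalar_number(config$cut_fraction, "cut_fraction", 0, 1)
  check_scalar_number(config$cpassoc_threshold, "cpassoc_threshold", 0, 1)
  check_scalar_number(config$missing_rate, "missing_rate", 0, 0.2)
  if (sum(config$module_blocks) != config$n_traits) {
    abort("`module_blocks` must sum to `n_traits`.",
          class = "gcnet_invalid_argument")
  }
  if (any(config$h2 < 0 | config$h2 > 1)) {
    abort("`h2` must lie in [0, 1].", class = "gcnet_invalid_argument")
  }
  if (any(config$beta_grid < 1)) {
    abort("`beta_grid` powers must be >= 1.",
          class = "gcnet_invalid_argument")
  }
  if (any(config$threshold_grid <= 0 | config$threshold_grid > 1)) {
    abort("`threshold_grid` must lie in (0, 1].",
          class = "gcnet_invalid_argument")
  }
  invisible(config)
}

# Block-structured genetic correlation target for the synthetic traits.
block_rho_matrix <- function(blocks, within, between) {
  k <- sum(blocks)
  labels <- rep(seq_along(blocks), blocks)
  rho <- matrix(between, k, k)
  for (b in seq_along(blocks)) {
    idx <- which(labels == b)
    rho[idx, idx] <- within
  }
  diag(rho) <- 1
  rho
}

config_hash <- function(config) {
  tmp <- tempfile(fileext = ".yaml")
  on.exit(unlink(tmp))
  yaml::write_yaml(unclass(config), tmp, precision = 12)
  unname(tools::md5sum(tmp))
}

pipeline_log <- function(state, stage, event, ...) {
  msg <- sprintf("[%s] %s %s", stage, event, paste(..., collapse = " "))
  inform(msg)
  if (!is.null(state$log_path)) {
    cat(msg, "\n", file = state$log_path, append = TRUE, sep = "")
  }
  invisible(NULL)
}

stage_files <- function(outdir, stage, config) {
  p <- function(...) file.path(outdir, ...)
  switch(stage,
    synth = p("synth", c("genotypes.tsv", "phenotypes.tsv", "truth.yaml",
                         "ldscores.tsv")),
    qc = p("qc", "qc_report.tsv"),
    sumstats = c(p("sumstats", paste0(sprintf("trait%02d",
                                              seq_len(config$n_traits)),
                                      ".sumstats.tsv")),
                 p("sumstats", "lambda_gc.tsv")),
    rg = p("rg", c("rg_pairs.tsv", "rg_matrix.tsv", "h2.tsv")),
    network = p("network", c("grid_fits.tsv", "selected.yaml",
                             "adjacency.tsv", "tom.tsv", "modules.tsv",
                             "merges.tsv")),
    cpassoc = p("cpassoc", "scans_done.yaml"),
    report = p("report", "report_done.yaml")
  )
}

#' Run the full pipeline
#'
#' Executes synth, QC, per-trait GWAS, genetic-correlation, network,
#' cross-phenotype and report stages in order, writing every stage's
#' outputs under `outdir` and a manifest of seeds, timings and output
#' checksums. With `resume = TRUE` a stage whose outputs already exist
#' (under an identical config hash) is loaded from disk instead of
#' recomputed; any recomputed stage forces recomputation of its
#' descendants. A stage failure is re-raised with the stage named.
#'
#' @param config A `pipeline_config`.
#' @param outdir Output directory (created if needed).
#' @param resume Reuse existing stage outputs when the config matches.
#' @return A `run_manifest`: config hash, per-stage seeds, timings and
#'   file checksums, plus the in-memory results of the final stages.
#' @export
run_pipeline <- function(config, outdir, resume = TRUE) {
  validate_pipeline_config(config)
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  for (sub in c("synth", "qc", "sumstats", "rg", "network", "cpassoc",
                "report")) {
    dir.create(file.path(outdir, sub), showWarnings = FALSE)
  }
  state <- new.env(parent = emptyenv())
  state$log_path <- file.path(outdir, "pipeline.log")
  cat("", file = state$log_path)

  hash <- config_hash(config)
  hash_path <- file.path(outdir, "config_hash.txt")
  hash_ok <- file.exists(hash_path) &&
    identical(readLines(hash_path, warn = FALSE)[1], unname(hash))
  if (!hash_ok) resume <- FALSE
  yaml::write_yaml(unclass(config), file.path(outdir, "config.yaml"),
                   precision = 12)
  writeLines(hash, hash_path)

  seeds <- c(genotypes = derive_seed(config$seed, 1L),
             truth = derive_seed(config$seed, 2L),
             phenotypes = derive_seed(config$seed, 3L),
             cpassoc = derive_seed(config$seed, 4L))
  timings <- numeric(0)
  dirty <- FALSE
  res <- list()

  run_stage <- function(stage, compute, load) {
    files <- stage_files(outdir, stage, config)
    t0 <- proc.time()[["elapsed"]]
    if (resume && !dirty && all(file.exists(files))) {
      pipeline_log(state, stage, "resume", "loading cached outputs")
      out <- load()
    } else {
      dirty <<- TRUE
      out <- withCallingHandlers(
        compute(),
        error = function(e) {
          abort(sprintf("Pipeline stage '%s' failed: %s", stage,
                        conditionMessage(e)),
                class = "gcnet_stage_error", parent = e)
        }
      )
      pipeline_log(state, stage, "done", "")
    }
    timings[stage] <<- proc.time()[["elapsed"]] - t0
    out
  }

  # --- synth -------------------------------------------------------------
  res$synth <- run_stage("synth",
    compute = function() {
      geno <- simulate_genotypes(
        config$n_samples, config$n_snps, maf_range = config$maf_range,
        missing_rate = config$missing_rate, seed = seeds[["genotypes"]],
        n_chr = config$n_chr
      )
      rho <- block_rho_matrix(config$module_blocks, config$within_rho,
                              config$between_rho)
      signal <- NULL
      if (config$n_signal > 0) {
        block1 <- seq_len(config$module_blocks[1])
        signal_snps <- geno$variants$SNP[
          round(seq(0.25, 0.75, length.out = config$n_signal) *
                  config$n_snps)]
        signal <- tidyr::expand_grid(SNP = signal_snps, trait = block1)
        signal$beta <- config$signal_effect
      }
      truth <- simulation_truth(
        geno$variants$SNP, h2 = config$h2, rho_g = rho,
        n_causal = config$n_causal, env_cor = config$env_cor,
        signal_effects = signal, seed = seeds[["truth"]]
      )
      pheno <- simulate_phenotypes(geno, truth,
                                   seed = seeds[["phenotypes"]])
      ld <- make_ld_scores(geno, window_snps = config$ld_window)
      write_genotypes(geno, file.path(outdir, "synth", "genotypes.tsv"))
      write_phenotypes(pheno, file.path(outdir, "synth", "phenotypes.tsv"))
      write_truth(truth, file.path(outdir, "synth", "truth.yaml"))
      write_tsv_exact(ld, file.path(outdir, "synth", "ldscores.tsv"))
      pipeline_log(state, "synth", "generated",
                   sprintf("n=%d m=%d traits=%d", config$n_samples,
                           config$n_snps, config$n_traits))
      list(genotypes = geno, phenotypes = pheno, truth = truth, ld = ld)
    },
    load = function() {
      ld <- read_tsv_exact(file.path(outdir, "synth", "ldscores.tsv"),
                           "cd")
      attr(ld, "M") <- nrow(ld)
      list(
        genotypes = read_genotypes(file.path(outdir, "synth",
                                             "genotypes.tsv")),
        phenotypes = read_phenotypes(file.path(outdir, "synth",
                                               "phenotypes.tsv")),
        truth = read_truth(file.path(outdir, "synth", "truth.yaml")),
        ld = ld
      )
    })

  # --- qc ----------------------------------------------------------------
  res$qc <- run_stage("qc",
    compute = function() {
      qc <- snp_qc(res$synth$genotypes,
                   min_call_rate = config$min_call_rate,
                   min_maf = config$min_maf,
                   min_hwe_p = config$min_hwe_p)
      write_tsv_exact(qc$report, file.path(outdir, "qc", "qc_report.tsv"))
      pipeline_log(state, "qc", "filtered",
                   sprintf("kept=%d excluded=%d", sum(qc$report$pass),
                           sum(!qc$report$pass)))
      qc
    },
    load = function() {
      report <- read_tsv_exact(file.path(outdir, "qc", "qc_report.tsv"),
                               "cdddlc")
      list(genotypes = subset_geno(res$synth$genotypes,
                                   report$SNP[report$pass]),
           report = report)
    })

  trait_ids <- res$synth$truth$trait_ids

  # --- sumstats ----------------------------------------------------------
  res$sumstats <- run_stage("sumstats",
    compute = function() {
      stats <- gwas_scan_all(res$qc$genotypes, res$synth$phenotypes,
                             trait_ids, covariates = config$covariates)
      for (tr in trait_ids) {
        write_summary_stats(stats[[tr]],
                            file.path(outdir, "sumstats",
                                      paste0(tr, ".sumstats.tsv")))
      }
      lambdas <- tibble(
        trait = trait_ids,
        lambda_gc = vapply(stats, genomic_control_lambda, numeric(1))
      )
      write_tsv_exact(lambdas,
                      file.path(outdir, "sumstats", "lambda_gc.tsv"))
      pipeline_log(state, "sumstats", "scanned",
                   sprintf("traits=%d lambda=[%.3f, %.3f]",
                           length(trait_ids), min(lambdas$lambda_gc),
                           max(lambdas$lambda_gc)))
      list(stats = stats, lambdas = lambdas)
    },
    load = function() {
      stats <- purrr::map(trait_ids, function(tr) {
        read_summary_stats(file.path(outdir, "sumstats",
                                     paste0(tr, ".sumstats.tsv")),
                           trait_id = tr)
      })
      names(stats) <- trait_ids
      lambdas <- read_tsv_exact(
        file.path(outdir, "sumstats", "lambda_gc.tsv"), "cd")
      list(stats = stats, lambdas = lambdas)
    })

  # --- rg ----------------------------------------------------------------
  res$rg <- run_stage("rg",
    compute = function() {
      rg <- build_rg_matrix(res$sumstats$stats, res$synth$ld)
      write_tsv_exact(rg$pairs, file.path(outdir, "rg", "rg_pairs.tsv"))
      sq <- as_tibble(rg$rg, rownames = "trait")
      write_tsv_exact(sq, file.path(outdir, "rg", "rg_matrix.tsv"))
      write_tsv_exact(rg$h2, file.path(outdir, "rg", "h2.tsv"))
      pipeline_log(state, "rg", "estimated",
                   sprintf("pairs=%d invalid=%d", nrow(rg$pairs),
                           rg$n_invalid))
      rg
    },
    load = function() {
      pairs <- read_tsv_exact(file.path(outdir, "rg", "rg_pairs.tsv"),
                              "ccdddddddiil")
      h2 <- read_tsv_exact(file.path(outdir, "rg", "h2.tsv"),
                           "cddddiidl")
      rg_from_pairs(pairs, trait_ids, h2)
    })

  # --- network -----------------------------------------------------------
  res$network <- run_stage("network",
    compute = function() {
      sel <- select_network_config(res$rg, beta_grid = config$beta_grid,
                                   threshold_grid = config$threshold_grid,
                                   n_bins = config$n_bins)
      adj <- power_adjacency(res$rg, sel$beta, sel$p_threshold)
      tom <- tom_dissimilarity(adj)
      part <- detect_modules(tom, min_size = config$min_module_size,
                             cut_fraction = config$cut_fraction)
      write_tsv_exact(sel$grid,
                      file.path(outdir, "network", "grid_fits.tsv"))
      yaml::write_yaml(list(beta = sel$beta,
                            p_threshold = sel$p_threshold,
                            r_squared = sel$r_squared),
                       file.path(outdir, "network", "selected.yaml"),
                       precision = 12)
      write_tsv_exact(as_tibble(unclass(adj), rownames = "trait"),
                      file.path(outdir, "network", "adjacency.tsv"))
      write_tsv_exact(as_tibble(tom$w, rownames = "trait"),
                      file.path(outdir, "network", "tom.tsv"))
      readr::write_tsv(part$assignments,
                       file.path(outdir, "network", "modules.tsv"),
                       progress = FALSE)
      merges <- if (!is.null(part$hclust)) {
        tibble(step = seq_along(part$hclust$height),
               left = part$hclust$merge[, 1],
               right = part$hclust$merge[, 2],
               height = part$hclust$height)
      } else {
        tibble(step = integer(), left = integer(), right = integer(),
               height = numeric())
      }
      write_tsv_exact(merges, file.path(outdir, "network", "merges.tsv"))
      pipeline_log(state, "network", "selected",
                   sprintf("beta=%g threshold=%g R2=%.3f modules=%d",
                           sel$beta, sel$p_threshold, sel$r_squared,
                           length(part$modules)))
      list(selection = sel, adjacency = adj, tom = tom, partition = part)
    },
    load = function() {
      sel_y <- yaml::read_yaml(file.path(outdir, "network",
                                         "selected.yaml"))
      adj <- power_adjacency(res$rg, sel_y$beta, sel_y$p_threshold)
      tom <- tom_dissimilarity(adj)
      assignments <- read_tsv_exact(
        file.path(outdir, "network", "modules.tsv"), "ci")
      mods <- split(assignments$trait[assignments$module > 0],
                    assignments$module[assignments$module > 0])
      part <- structure(list(assignments = assignments, modules = mods,
                             hclust = NULL, cut_height = NA_real_,
                             min_size = config$min_module_size,
                             cut_fraction = config$cut_fraction),
                        class = "module_partition")
      list(selection = sel_y, adjacency = adj, tom = tom, partition = part)
    })

  # --- cpassoc -----------------------------------------------------------
  res$cpassoc <- run_stage("cpassoc",
    compute = function() {
      scans <- purrr::imap(res$network$partition$modules,
                           function(members, mod_id) {
        scan <- module_scan(
          res$sumstats$stats[members],
          threshold = config$cpassoc_threshold,
          B = config$cpassoc_b,
          seed = derive_seed(seeds[["cpassoc"]], as.integer(mod_id)),
          z_cutoff = config$z_cutoff
        )
        write_tsv_exact(scan,
                        file.path(outdir, "cpassoc",
                                  sprintf("module%s.cpassoc.tsv", mod_id)))
        pipeline_log(state, "cpassoc", "scanned",
                     sprintf("module=%s traits=%d snps=%d significant=%d",
                             mod_id, length(members), nrow(scan),
                             sum(scan$SIGNIFICANT)))
        scan
      })
      yaml::write_yaml(list(modules = names(scans)),
                       file.path(outdir, "cpassoc", "scans_done.yaml"))
      scans
    },
    load = function() {
      mods <- yaml::read_yaml(file.path(outdir, "cpassoc",
                                        "scans_done.yaml"))$modules
      scans <- purrr::map(mods, function(mod_id) {
        read_tsv_exact(file.path(outdir, "cpassoc",
                                 sprintf("module%s.cpassoc.tsv", mod_id)),
                       "ciiddddidddll")
      })
      names(scans) <- mods
      scans
    })

  # --- report ------------------------------------------------------------
  res$report <- run_stage("report",
    compute = function() {
      tables <- purrr::imap(res$cpassoc, function(scan, mod_id) {
        exp_tab <- export_association_table(
          scan, threshold = config$cpassoc_threshold)
        write_tsv_exact(exp_tab$association,
                        file.path(outdir, "report",
                                  sprintf("assoc_module%s.tsv", mod_id)))
        write_tsv_exact(exp_tab$qq,
                        file.path(outdir, "report",
                                  sprintf("qq_module%s.tsv", mod_id)))
        exp_tab
      })
      yaml::write_yaml(list(modules = names(tables)),
                       file.path(outdir, "report", "report_done.yaml"))
      tables
    },
    load = function() {
      mods <- yaml::read_yaml(file.path(outdir, "report",
                                        "report_done.yaml"))$modules
      purrr::map(setNames(mods, mods), function(mod_id) {
        list(
          association = read_tsv_exact(
            file.path(outdir, "report",
                      sprintf("assoc_module%s.tsv", mod_id)),
            "ciiddddidddlldd"),
          qq = read_tsv_exact(
            file.path(outdir, "report", sprintf("qq_module%s.tsv", mod_id)),
            "cdd")
        )
      })
    })

  all_files <- unlist(lapply(PIPELINE_STAGES, stage_files,
                             outdir = outdir, config = config))
  all_files <- c(all_files,
                 list.files(file.path(outdir, c("cpassoc", "report")),
                            full.names = TRUE, pattern = "\\.tsv$"))
  all_files <- sort(unique(all_files[file.exists(all_files)]))
  checksums <- tibble(
    file = sub(paste0("^", outdir, "/?"), "", all_files),
    md5 = unname(tools::md5sum(all_files))
  )
  manifest <- structure(
    list(config_hash = unname(hash), seeds = seeds, timings = timings,
         version = as.character(utils::packageVersion("gcnet")),
         checksums = checksums, results = res),
    class = "run_manifest"
  )
  yaml::write_yaml(
    list(config_hash = unname(hash), seeds = as.list(seeds),
         timings = as.list(round(timings, 3)),
         version = manifest$version,
         checksums = setNames(as.list(checksums$md5), checksums$file)),
    file.path(outdir, "manifest.yaml"))
  manifest
}

#' @export
print.run_manifest <- function(x, ...) {
  cat(sprintf("<run_manifest> config %s, %d files, %.1fs total\n",
              substr(x$config_hash, 1, 8), nrow(x$checksums),
              sum(x$timings)))
  invisible(x)
}

# Rebuild an rg_matrix object from its serialized long pair table.
rg_from_pairs <- function(pairs, traits, h2 = NULL) {
  k <- length(traits)
  rg <- se <- p <- matrix(NA_real_, k, k, dimnames = list(traits, traits))
  valid <- matrix(FALSE, k, k, dimnames = list(traits, traits))
  for (r in seq_len(nrow(pairs))) {
    i <- match(pairs$trait1[r], traits)
    j <- match(pairs$trait2[r], traits)
    if (isTRUE(pairs$valid[r])) {
      rg[i, j] <- rg[j, i] <- pairs$rg[r]
      se[i, j] <- se[j, i] <- pairs$se[r]
      valid[i, j] <- valid[j, i] <- TRUE
    }
    p[i, j] <- p[j, i] <- pairs$p[r]
  }
  diag(rg) <- 1
  diag(valid) <- TRUE
  new_rg_matrix(traits = traits, rg = rg, se = se, p = p, valid = valid,
                pairs = pairs, h2 = h2, n_invalid = sum(!pairs$valid))
}

#' Plot-ready association and QQ tables
#'
#' Sorts a module scan by chromosome and position, adds `-log10(P)`
#' columns for both combined statistics and inclusive significance flags
#' at the 5e-8 genome-wide line and the configured module threshold, and
#' builds the expected-vs-observed QQ table
#' (`expected = -log10((i - 0.5) / m)`).
#'
#' @param scan A [module_scan()] result.
#' @param threshold Module significance threshold (default: the scan's).
#' @return List with `association` and `qq` tibbles.
#' @export
export_association_table <- function(scan, threshold = NULL) {
  if (nrow(scan) == 0) {
    abort("Empty scan results.", class = "gcnet_invalid_argument")
  }
  threshold <- threshold %||% attr(scan, "threshold") %||% 1e-7
  assoc <- dplyr::arrange(as_tibble(scan), .data$CHR, .data$BP)
  assoc$LOG10P_HOM <- -log10(assoc$P_HOM)
  assoc$LOG10P_HET <- -log10(assoc$P_HET)
  assoc$SIGNIFICANT <- pmin(assoc$P_HOM, assoc$P_HET) <= threshold
  assoc$GENOME_WIDE <- pmin(assoc$P_HOM, assoc$P_HET) <= 5e-8
  m <- nrow(assoc)
  expected <- -log10((seq_len(m) - 0.5) / m)
  qq <- dplyr::bind_rows(
    tibble(statistic = "S_HOM", expected = expected,
           observed = sort(assoc$LOG10P_HOM, decreasing = TRUE)),
    tibble(statistic = "S_HET", expected = expected,
           observed = sort(assoc$LOG10P_HET, decreasing = TRUE))
  )
  list(association = assoc, qq = qq)
}
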