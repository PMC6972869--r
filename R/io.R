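# File formats: tab-delimited summary statistics (PLINK-style header),
# sample-by-SNP dosage tables with a two-row variant header, phenotype
# tables keyed by IID, YAML ground-truth configs, and a minimal VCF export.

SUMSTATS_REQUIRED <- c("SNP", "CHR", "BP", "A1", "A2", "BETA", "SE", "P", "N")
SUMSTATS_NUMERIC <- c("CHR", "BP", "BETA", "SE", "Z", "P", "N")

# Tab-delimited writer that formats double columns with 17 significant
# digits, so write -> read reproduces every double bit for bit (needed for
# byte-identical pipeline resumes; plain writers round at the last ulp).
write_tsv_exact <- function(df, path) {
  for (nm in names(df)) {
    if (is.double(df[[nm]])) {
      v <- df[[nm]]
      s <- sprintf("%.17g", v)
      s[is.na(v)] <- NA_character_
      df[[nm]] <- s
    }
  }
  readr::write_tsv(df, path, progress = FALSE, na = "NA")
  invisible(path)
}

# Companion reader: columns come in as text and are converted with base
# R's correctly rounding parser, so the write/read pair is bit-exact.
# `spec` is one letter per column: c(haracter), d(ouble), i(nteger),
# l(ogical).
read_tsv_exact <- function(path, spec) {
  raw <- readr::read_tsv(path, col_types = readr::cols(.default = "c"),
                         progress = FALSE)
  stopifnot(nchar(spec) == ncol(raw))
  for (k in seq_len(ncol(raw))) {
    raw[[k]] <- switch(substr(spec, k, k),
                       d = as.numeric(raw[[k]]),
                       i = as.integer(raw[[k]]),
                       l = as.logical(raw[[k]]),
                       raw[[k]])
  }
  raw
}

#' Read GWAS summary statistics
#'
#' Reads a tab-delimited summary-statistics file with header columns
#' `SNP CHR BP A1 A2 BETA SE Z P N` (`Z` optional, recomputed as `BETA/SE`
#' when absent). Rows with non-parsable numeric fields are rejected with a
#' row-indexed error; duplicate SNP ids and missing required columns are
#' format errors.
#'
#' @param path Path to a tab-delimited file with header.
#' @param trait_id Optional trait label attached as an attribute (defaults
#'   to the file name without extension).
#' @return A tibble with columns `SNP CHR BP A1 A2 BETA SE Z P N`.
#' @export
read_summary_stats <- function(path, trait_id = NULL) {
  raw <- readr::read_tsv(path, col_types = readr::cols(.default = "c"),
                         progress = FALSE)
  missing_cols <- setdiff(SUMSTATS_REQUIRED, names(raw))
  if (length(missing_cols) > 0) {
    abort(sprintf("Summary-statistics file is missing required column(s): %s",
                  paste(missing_cols, collapse = ", ")),
          class = "gcnet_format_error")
  }
  if (anyDuplicated(raw$SNP)) {
    dup <- raw$SNP[duplicated(raw$SNP)][1]
    abort(sprintf("Duplicate SNP id in summary statistics: %s", dup),
          class = "gcnet_format_error")
  }
  out <- raw
  bad_rows <- integer()
  for (col in intersect(SUMSTATS_NUMERIC, names(raw))) {
    parsed <- suppressWarnings(as.numeric(raw[[col]]))
    bad <- which(is.na(parsed) & !is.na(raw[[col]]))
    bad_rows <- union(bad_rows, bad)
    out[[col]] <- parsed
  }
  if (length(bad_rows) > 0) {
    abort(sprintf("Non-parsable numeric value(s) in row(s): %s",
                  paste(sort(bad_rows), collapse = ", ")),
          class = "gcnet_format_error")
  }
  if (!"Z" %in% names(out)) out$Z <- out$BETA / out$SE
  out <- out[c("SNP", "CHR", "BP", "A1", "A2", "BETA", "SE", "Z", "P", "N")]
  attr(out, "trait_id") <- trait_id %||% sub("\\.[^.]*$", "", basename(path))
  out
}

#' Write GWAS summary statistics
#'
#' Writes the standard tab-delimited format. Rows flagged as degenerate by
#' [gwas_scan()] (zero dosage variance or a perfect fit) are excluded from
#' the file, with a message.
#'
#' @param stats Summary-statistics tibble.
#' @param path Output path.
#' @return Invisibly, the path.
#' @export
write_summary_stats <- function(stats, path) {
  if ("flag" %in% names(stats)) {
    n_bad <- sum(stats$flag != "ok")
    if (n_bad > 0) {
      inform(sprintf("Excluding %d degenerate SNP record(s) from %s.",
                     n_bad, basename(path)))
      stats <- dplyr::filter(stats, .data$flag == "ok")
    }
    stats$flag <- NULL
  }
  write_tsv_exact(stats[c("SNP", "CHR", "BP", "A1", "A2",
                          "BETA", "SE", "Z", "P", "N")], path)
  invisible(path)
}

#' Write / read a dosage genotype table
#'
#' The on-disk format is a tab-delimited sample-by-SNP table whose first
#' column is `IID`, preceded by a two-row variant header: a `#ALLELE` row of
#' `A1/A2` pairs and a `#POS` row of `CHR:BP` coordinates. Missing dosages
#' are written as the single sentinel `NA` and are never imputed on read.
#'
#' @param genotypes A `geno_table`.
#' @param path Output path.
#' @return `write_genotypes()`: the path, invisibly. `read_genotypes()`: a
#'   `geno_table`.
#' @export
write_genotypes <- function(genotypes, path) {
  v <- genotypes$variants
  hdr1 <- paste(c("#ALLELE", paste0(v$A1, "/", v$A2)), collapse = "\t")
  hdr2 <- paste(c("#POS", paste0(v$CHR, ":", v$BP)), collapse = "\t")
  body_header <- paste(c("IID", v$SNP), collapse = "\t")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(hdr1, hdr2, body_header), con)
  dose <- genotypes$dosage
  lines <- vapply(seq_len(nrow(dose)), function(i) {
    paste(c(genotypes$samples[i], ifelse(is.na(dose[i, ]), "NA", dose[i, ])),
          collapse = "\t")
  }, character(1))
  writeLines(lines, con)
  invisible(path)
}

#' @rdname write_genotypes
#' @export
read_genotypes <- function(path) {
  lines <- readr::read_lines(path, progress = FALSE)
  if (length(lines) < 3L || !startsWith(lines[1], "#ALLELE") ||
      !startsWith(lines[2], "#POS")) {
    abort("Genotype file lacks the two-row #ALLELE/#POS variant header.",
          class = "gcnet_format_error")
  }
  al <- strsplit(lines[1], "\t", fixed = TRUE)[[1]][-1]
  pos <- strsplit(lines[2], "\t", fixed = TRUE)[[1]][-1]
  header <- strsplit(lines[3], "\t", fixed = TRUE)[[1]]
  snp <- header[-1]
  a_split <- strsplit(al, "/", fixed = TRUE)
  p_split <- strsplit(pos, ":", fixed = TRUE)
  variants <- tibble(
    SNP = snp,
    CHR = as.integer(vapply(p_split, `[`, character(1), 1L)),
    BP = as.integer(vapply(p_split, `[`, character(1), 2L)),
    A1 = vapply(a_split, `[`, character(1), 1L),
    A2 = vapply(a_split, `[`, character(1), 2L)
  )
  body <- strsplit(lines[-(1:3)], "\t", fixed = TRUE)
  samples <- vapply(body, `[`, character(1), 1L)
  dose <- t(vapply(body, function(row) {
    vals <- suppressWarnings(as.integer(row[-1]))
    vals
  }, integer(length(snp))))
  ok <- is.na(dose) | dose %in% c(0L, 1L, 2L)
  if (!all(ok)) {
    abort("Dosage values outside {0, 1, 2, NA} in genotype file.",
          class = "gcnet_format_error")
  }
  dimnames(dose) <- list(samples, snp)
  new_geno_table(dosage = dose, variants = variants, samples = samples)
}

#' Write / read a phenotype-and-covariate table
#'
#' Plain tab-delimited text keyed by an `IID` column; all other columns are
#' read as numeric.
#'
#' @param phenotypes Tibble with an `IID` column.
#' @param path File path.
#' @return `write_phenotypes()`: the path, invisibly; `read_phenotypes()`:
#'   a tibble.
#' @export
write_phenotypes <- function(phenotypes, path) {
  stopifnot("IID" %in% names(phenotypes))
  write_tsv_exact(as_tibble(phenotypes), path)
}

#' @rdname write_phenotypes
#' @export
read_phenotypes <- function(path) {
  raw <- readr::read_tsv(path, col_types = readr::cols(.default = "c"),
                         progress = FALSE)
  if (!"IID" %in% names(raw)) {
    abort("Phenotype file is missing the IID key column.",
          class = "gcnet_format_error")
  }
  for (nm in setdiff(names(raw), "IID")) {
    raw[[nm]] <- as.numeric(raw[[nm]])
  }
  raw
}

#' Serialize / restore a simulation truth as YAML
#'
#' Captures every field of the ground truth (heritabilities, genetic
#' correlation targets, causal sets, realized effect sizes, environmental
#' correlation, covariate effects, seed) so a run can be reproduced from
#' its config file. Numeric values round-trip to about 12 significant
#' digits.
#'
#' @param truth A `sim_truth`.
#' @param path YAML file path.
#' @return `write_truth()`: the path, invisibly; `read_truth()`: a
#'   `sim_truth`.
#' @export
write_truth <- function(truth, path) {
  stopifnot(inherits(truth, "sim_truth"))
  payload <- list(
    trait_ids = truth$trait_ids,
    h2 = truth$h2,
    rho_g = apply(truth$rho_g, 1L, as.numeric, simplify = FALSE),
    causal_sets = truth$causal_sets,
    effect_snps = rownames(truth$effects),
    effects = apply(truth$effects, 1L, as.numeric, simplify = FALSE),
    env_cor = truth$env_cor,
    covariate_effects = as.list(truth$covariate_effects %||% list()),
    seed = truth$seed
  )
  yaml::write_yaml(payload, path, precision = 12)
  invisible(path)
}

#' @rdname write_truth
#' @export
read_truth <- function(path) {
  p <- yaml::read_yaml(path)
  k <- length(p$trait_ids)
  rho <- do.call(rbind, lapply(p$rho_g, as.numeric))
  effects <- do.call(rbind, lapply(p$effects, as.numeric))
  if (is.null(effects)) {
    effects <- matrix(0, 0, k, dimnames = list(NULL, p$trait_ids))
  } else {
    dimnames(effects) <- list(p$effect_snps, p$trait_ids)
  }
  cov_eff <- if (length(p$covariate_effects) > 0) {
    unlist(p$covariate_effects)
  }
  structure(
    list(trait_ids = p$trait_ids, h2 = as.numeric(p$h2), rho_g = rho,
         causal_sets = lapply(p$causal_sets, as.character),
         effects = effects, env_cor = as.numeric(p$env_cor),
         covariate_effects = cov_eff, signal_effects = NULL,
         seed = as.integer(p$seed)),
    class = "sim_truth"
  )
}

#' Export genotypes as a minimal VCF
#'
#' GT-only, unphased VCFv4.2 text: `A2` is written as REF and `A1` as ALT,
#' so the ALT allele count equals the package's dosage coding. Missing
#' dosages become `./.`.
#'
#' @param genotypes A `geno_table`.
#' @param path Output path (uncompressed `.vcf`).
#' @return The path, invisibly.
#' @export
write_vcf <- function(genotypes, path) {
  v <- genotypes$variants
  gt_codes <- c(`0` = "0/0", `1` = "0/1", `2` = "1/1")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##source=gcnet",
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", genotypes$samples), collapse = "\t")
  ), con)
  dose <- genotypes$dosage
  lines <- vapply(seq_len(nrow(v)), function(j) {
    gt <- gt_codes[as.character(dose[, j])]
    gt[is.na(gt)] <- "./."
    paste(c(v$CHR[j], v$BP[j], v$SNP[j], v$A2[j], v$A1[j], ".", "PASS", ".",
            "GT", gt), collapse = "\t")
  }, character(1))
  writeLines(lines, con)
  invisible(path)
}
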