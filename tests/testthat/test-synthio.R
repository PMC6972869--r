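# Synthetic cohort generator and file formats.

test_that("genotype simulation is bit-reproducible for a fixed seed", {
  g1 <- simulate_genotypes(4, 2, maf_range = c(0.5, 0.5), seed = 11)
  g2 <- simulate_genotypes(4, 2, maf_range = c(0.5, 0.5), seed = 11)
  expect_identical(g1$dosage, g2$dosage)
  expect_identical(g1$variants, g2$variants)
  g3 <- simulate_genotypes(4, 2, maf_range = c(0.5, 0.5), seed = 12)
  expect_false(identical(g1$dosage, g3$dosage))
})

test_that("realized allele frequency stays within the binomial 3-sigma bound", {
  # sd of the mean allele frequency: sqrt(p(1-p)/(2n)) ~ 0.00725 at p=0.3
  g <- simulate_genotypes(2000, 1, maf_range = c(0.3, 0.3), seed = 2)
  af <- mean(g$dosage) / 2
  expect_lt(abs(af - 0.3), 3 * sqrt(0.3 * 0.7 / (2 * 2000)))
})

test_that("generator rejects invalid arguments", {
  expect_error(simulate_genotypes(10, 5, missing_rate = 0.5),
               class = "gcnet_invalid_argument")
  expect_error(simulate_genotypes(0, 5), class = "gcnet_invalid_argument")
  expect_error(simulate_genotypes(10, 5, maf_range = c(0, 0.6)),
               class = "gcnet_invalid_argument")
})

test_that("positions are strictly increasing within chromosomes, ids unique", {
  g <- simulate_genotypes(5, 100, seed = 3, n_chr = 4)
  expect_false(anyDuplicated(g$variants$SNP) > 0)
  by_chr <- split(g$variants$BP, g$variants$CHR)
  for (bp in by_chr) expect_true(all(diff(bp) > 0))
  expect_true(all(g$dosage %in% c(0L, 1L, 2L)))
})

test_that("null-heritability traits are independent of genotype (lambda ~ 1)", {
  set <- simulate_gwas_set(n = 500, m = 5000, h2 = c(0, 0), seed = 4)
  lambdas <- vapply(set$stats, genomic_control_lambda, numeric(1))
  expect_true(all(abs(lambdas - 1) < 0.1))
})

test_that("identical causal sets with rho_g = 1 give near-identical genetic values", {
  g <- simulate_genotypes(500, 500, seed = 5)
  rho <- matrix(1, 2, 2)
  truth <- simulation_truth(g$variants$SNP, h2 = c(0.5, 0.5), rho_g = rho,
                            n_causal = 100, seed = 6)
  ph <- simulate_phenotypes(g, truth)
  gv <- attr(ph, "genetic_values")
  expect_gte(cor(gv[, 1], gv[, 2]), 0.99)
})

test_that("realized heritability matches its target on average", {
  # fraction of trait variance explained by the genetic values, averaged
  # over seeds at n=2000, m=5000, 500 causal SNPs, target 0.5
  fracs <- vapply(1:20, function(s) {
    g <- simulate_genotypes(2000, 5000, seed = 100 + s)
    truth <- simulation_truth(g$variants$SNP, h2 = 0.5, n_causal = 500,
                              seed = 200 + s)
    ph <- simulate_phenotypes(g, truth)
    gv <- attr(ph, "genetic_values")
    var(gv[, 1]) / var(ph$trait01)
  }, numeric(1))
  expect_lt(abs(mean(fracs) - 0.5), 0.05)
})

test_that("realized genetic correlation matches the rho_g target on average", {
  rho <- matrix(c(1, 0.4, 0.4, 1), 2, 2)
  cors <- vapply(1:20, function(s) {
    g <- simulate_genotypes(1000, 2000, seed = 300 + s)
    truth <- simulation_truth(g$variants$SNP, h2 = c(0.5, 0.5), rho_g = rho,
                              n_causal = 200, seed = 400 + s)
    ph <- simulate_phenotypes(g, truth)
    gv <- attr(ph, "genetic_values")
    cor(gv[, 1], gv[, 2])
  }, numeric(1))
  expect_lt(abs(mean(cors) - 0.4), 0.05)
})

test_that("non-PSD genetic correlation targets are rejected", {
  bad <- matrix(c(1, 0.9, -0.9, 0.9, 1, 0.9, -0.9, 0.9, 1), 3, 3)
  g <- simulate_genotypes(20, 50, seed = 7)
  expect_error(
    simulation_truth(g$variants$SNP, h2 = rep(0.5, 3), rho_g = bad,
                     n_causal = 10),
    class = "gcnet_invalid_argument"
  )
})

test_that("LD scores: window 0 gives exactly 1, duplicated SNPs get 2", {
  g <- simulate_genotypes(100, 10, seed = 8)
  expect_true(all(make_ld_scores(g, 0)$L == 1))

  dosage <- g$dosage[, c(1, 1)]
  g2 <- make_geno(dosage)
  l <- make_ld_scores(g2, window_snps = 1)$L
  expect_equal(l, c(2, 2), tolerance = 1e-12)
})

test_that("LD scores of independent SNPs match the sampling-noise expectation", {
  # each squared sample correlation has expectation ~ 1/(n-1); with a
  # two-sided window the mean neighbour count over m SNPs is
  # 2*w - w*(w+1)/m (edge deficit)
  n <- 2000; m <- 1000; w <- 50
  g <- simulate_genotypes(n, m, seed = 9)
  l <- make_ld_scores(g, window_snps = w)$L
  expected <- 1 + (2 * w - w * (w + 1) / m) / (n - 1)
  expect_lt(abs(mean(l) - expected), 0.02)
})

test_that("LD mode produces elevated, varying LD scores", {
  g <- simulate_genotypes(800, 400, seed = 10,
                          ld = list(block_size = 40,
                                    rho_range = c(0.3, 0.9)))
  l <- make_ld_scores(g, window_snps = 20)$L
  expect_gt(mean(l), 1.3)
  expect_gt(sd(l), 0.1)
})

test_that("summary statistics round-trip losslessly and validate on read", {
  s <- make_sumstats(c(1.5, -2, 0.3), n = 750)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_summary_stats(s, path)
  r <- read_summary_stats(path)
  expect_equal(as.data.frame(r), as.data.frame(s), tolerance = 1e-12,
               ignore_attr = TRUE)

  # missing required column is named in the error
  s2 <- s[, setdiff(names(s), "SE")]
  path2 <- withr::local_tempfile(fileext = ".tsv")
  readr::write_tsv(s2, path2)
  expect_error(read_summary_stats(path2), "SE", class = "gcnet_format_error")

  # Z recomputed from BETA/SE when absent
  s3 <- s[, setdiff(names(s), "Z")]
  s3$BETA <- 0.1; s3$SE <- 0.05
  path3 <- withr::local_tempfile(fileext = ".tsv")
  readr::write_tsv(s3, path3)
  expect_equal(read_summary_stats(path3)$Z, rep(2, 3))

  # duplicate SNP id
  s4 <- s; s4$SNP[2] <- s4$SNP[1]
  path4 <- withr::local_tempfile(fileext = ".tsv")
  readr::write_tsv(s4, path4)
  expect_error(read_summary_stats(path4), "Duplicate",
               class = "gcnet_format_error")

  # non-parsable numeric rows are reported by row index
  lines <- readr::read_lines(path)
  lines[3] <- sub("\t-2\t", "\tnot_a_number\t", lines[3])
  path5 <- withr::local_tempfile(fileext = ".tsv")
  readr::write_lines(lines, path5)
  expect_error(read_summary_stats(path5), "row",
               class = "gcnet_format_error")
})

test_that("genotype, phenotype and truth files round-trip", {
  g <- simulate_genotypes(15, 8, missing_rate = 0.1, seed = 12)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_genotypes(g, path)
  r <- read_genotypes(path)
  expect_identical(r$dosage, g$dosage)
  expect_equal(r$variants$SNP, g$variants$SNP)
  expect_equal(r$variants$A1, g$variants$A1)
  expect_equal(r$variants$BP, g$variants$BP)

  truth <- simulation_truth(g$variants$SNP, h2 = c(0.4, 0.6),
                            n_causal = 5, env_cor = 0.2, seed = 13)
  ph <- simulate_phenotypes(g, truth)
  ppath <- withr::local_tempfile(fileext = ".tsv")
  write_phenotypes(ph, ppath)
  ph2 <- read_phenotypes(ppath)
  expect_equal(as.data.frame(ph2), as.data.frame(ph), tolerance = 1e-9,
               ignore_attr = TRUE)

  tpath <- withr::local_tempfile(fileext = ".yaml")
  write_truth(truth, tpath)
  t2 <- read_truth(tpath)
  expect_equal(t2$h2, truth$h2)
  expect_equal(t2$rho_g, truth$rho_g, tolerance = 1e-9)
  expect_equal(t2$effects, truth$effects, tolerance = 1e-9)
  expect_identical(t2$causal_sets, truth$causal_sets)
})

test_that("VCF export encodes dosage and missingness as GT", {
  dosage <- matrix(c(0L, 1L, 2L, NA), 2, 2)
  g <- make_geno(dosage, a1 = c("T", "C"), a2 = c("A", "G"))
  path <- withr::local_tempfile(fileext = ".vcf")
  write_vcf(g, path)
  lines <- readLines(path)
  body <- lines[!startsWith(lines, "#")]
  f1 <- strsplit(body[1], "\t")[[1]]
  expect_equal(f1[4], "A")        # REF = A2
  expect_equal(f1[5], "T")        # ALT = A1
  expect_equal(f1[10:11], c("0/0", "0/1"))
  f2 <- strsplit(body[2], "\t")[[1]]
  expect_equal(f2[10:11], c("1/1", "./."))
})
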