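# Power adjacency, scale-free selection, topological overlap, modules.

# planted rg matrix with block structure plus uniform noise
planted_rg <- function(blocks, within = 0.9, noise = 0, seed = 1) {
  k <- sum(blocks)
  labels <- rep(seq_along(blocks), blocks)
  withr::with_seed(seed, {
    rg <- matrix(stats::runif(k * k, -noise, noise), k, k)
    rg[] <- (rg + t(rg)) / 2
    for (b in seq_along(blocks)) {
      idx <- which(labels == b)
      rg[idx, idx] <- within
    }
    diag(rg) <- 1
  })
  list(rg = rg_matrix(rg), labels = labels)
}

test_that("power adjacency follows the soft-threshold definition", {
  rgm <- rg_matrix(matrix(c(1, 0.5, 0.5, 1), 2))
  a <- power_adjacency(rgm, beta = 6)
  expect_equal(a[1, 2], 0.5^6, tolerance = 1e-15)
  expect_equal(diag(unclass(a)), rep(0, 2), ignore_attr = TRUE)

  # negative correlations connect as strongly as positive ones
  rgn <- rg_matrix(matrix(c(1, -0.5, -0.5, 1), 2))
  expect_equal(power_adjacency(rgn, 6)[1, 2], 0.5^6)

  # a pair whose P exceeds the threshold is zeroed
  p <- matrix(c(0, 0.3, 0.3, 0), 2)
  rgp <- rg_matrix(matrix(c(1, 0.9, 0.9, 1), 2), p = p)
  expect_equal(power_adjacency(rgp, 6, p_threshold = 0.2)[1, 2], 0)
  expect_equal(power_adjacency(rgp, 6, p_threshold = 0.3)[1, 2], 0.9^6)

  expect_error(power_adjacency(rgm, beta = 0.5),
               class = "gcnet_invalid_argument")
})

test_that("adjacency is monotone in |rg| and in beta", {
  r_seq <- seq(0.1, 0.9, by = 0.1)
  for (beta in c(2, 6)) {
    a <- vapply(r_seq, function(r) {
      power_adjacency(rg_matrix(matrix(c(1, r, r, 1), 2)), beta)[1, 2]
    }, numeric(1))
    expect_true(all(diff(a) > 0))
  }
  # larger beta weakens sub-unit correlations, fixes a = 1 at |rg| = 1
  a2 <- power_adjacency(rg_matrix(matrix(c(1, 0.7, 0.7, 1), 2)), 2)[1, 2]
  a8 <- power_adjacency(rg_matrix(matrix(c(1, 0.7, 0.7, 1), 2)), 8)[1, 2]
  expect_lt(a8, a2)
  expect_equal(power_adjacency(rg_matrix(matrix(1, 2, 2)), 8)[1, 2], 1)
})

test_that("an exact power-law degree sequence fits with R^2 = 1, slope -1", {
  # 15 nodes with degrees 8x1, 4x2, 2x4, 1x8: frequencies (8/15) * k^-1
  edges <- rbind(
    c(1, 2), c(1, 3), c(1, 4), c(1, 5), c(1, 6), c(1, 7), c(1, 8), c(1, 9),
    c(2, 3), c(2, 10), c(2, 11),
    c(3, 12), c(3, 13),
    c(4, 14), c(5, 15), c(6, 7)
  )
  a <- matrix(0, 15, 15)
  for (r in seq_len(nrow(edges))) {
    a[edges[r, 1], edges[r, 2]] <- a[edges[r, 2], edges[r, 1]] <- 0.5
  }
  k <- colSums(a > 0)
  expect_equal(sort(unname(table(k)), decreasing = TRUE),
               c(8, 4, 2, 1), ignore_attr = TRUE)
  fit <- scale_free_fit(a, n_bins = 8)
  expect_equal(fit$r_squared, 1, tolerance = 1e-12)
  expect_equal(fit$slope, -1, tolerance = 1e-12)
})

test_that("degenerate degree distributions are refused", {
  complete <- matrix(0.5, 6, 6); diag(complete) <- 0
  expect_error(scale_free_fit(complete), class = "gcnet_degenerate_fit")
})

test_that("dense random networks are not scale-free (low R^2)", {
  hits <- vapply(1:20, function(s) {
    withr::with_seed(2000 + s, {
      n <- 100
      a <- matrix(0, n, n)
      up <- upper.tri(a)
      a[up] <- (runif(sum(up)) < 0.5) * 0.5
      a <- a + t(a)
    })
    fit <- tryCatch(scale_free_fit(a),
                    gcnet_degenerate_fit = function(e) NULL)
    is.null(fit) || fit$r_squared < 0.5
  }, logical(1))
  expect_gte(mean(hits), 0.9)
})

test_that("TOM matches hand calculations and the brute-force oracle", {
  # 3 nodes fully connected with a = 1: w = 1, d = 0
  a3 <- matrix(1, 3, 3); diag(a3) <- 0
  t3 <- tom_dissimilarity(a3)
  expect_equal(t3$w[1, 2], 1)
  expect_equal(t3$d[1, 2], 0)

  # 2 nodes, single edge a = 0.5: w = 0.5/(0.5 + 1 - 0.5) = 0.5
  a2 <- matrix(c(0, 0.5, 0.5, 0), 2)
  expect_equal(tom_dissimilarity(a2)$w[1, 2], 0.5)

  # random 6x6 adjacencies against a triple-loop oracle
  tom_oracle <- function(a) {
    n <- nrow(a)
    w <- matrix(1, n, n)
    for (i in seq_len(n)) for (j in seq_len(n)) {
      if (i == j) next
      l_ij <- 0
      for (u in seq_len(n)) {
        if (u != i && u != j) l_ij <- l_ij + a[i, u] * a[u, j]
      }
      k_i <- sum(a[i, -i]); k_j <- sum(a[j, -j])
      w[i, j] <- (l_ij + a[i, j]) / (min(k_i, k_j) + 1 - a[i, j])
    }
    w
  }
  for (s in 1:10) {
    a <- withr::with_seed(3000 + s, {
      x <- matrix(runif(36), 6, 6)
      x <- (x + t(x)) / 2; diag(x) <- 0; x
    })
    t6 <- tom_dissimilarity(a)
    expect_equal(unname(t6$w), tom_oracle(a), tolerance = 1e-12)
    expect_true(all(t6$w >= -1e-12 & t6$w <= 1 + 1e-12))
    expect_equal(t6$d, 1 - t6$w)
  }
})

test_that("network outputs are equivariant under trait permutation", {
  pl <- planted_rg(c(3, 3, 4), within = 0.8, noise = 0.1, seed = 4)
  k <- 10
  perm <- withr::with_seed(5, sample(k))
  rg_p <- rg_matrix(pl$rg$rg[perm, perm])
  a <- power_adjacency(pl$rg, 6, 1)
  a_p <- power_adjacency(rg_p, 6, 1)
  expect_equal(unname(unclass(a)[perm, perm]), unname(unclass(a_p)),
               tolerance = 1e-12, ignore_attr = TRUE)
  w <- tom_dissimilarity(a)$w
  w_p <- tom_dissimilarity(a_p)$w
  expect_equal(unname(w[perm, perm]), unname(w_p), tolerance = 1e-12,
               ignore_attr = TRUE)
})

test_that("grid selection equals an exhaustive recomputation oracle", {
  pl <- planted_rg(c(4, 3, 3), within = 0.85, noise = 0.35, seed = 6)
  # give pairs varying P so the threshold axis matters
  k <- 10
  p <- withr::with_seed(7, {
    x <- matrix(runif(k * k, 0, 0.6), k, k)
    x <- (x + t(x)) / 2; diag(x) <- 0; x
  })
  rgm <- rg_matrix(pl$rg$rg, p = p)
  sel <- select_network_config(rgm, beta_grid = c(2, 4, 6, 8),
                               threshold_grid = c(0.5, 0.3, 0.2, 0.1),
                               n_bins = 5)
  # oracle: recompute every cell independently
  best <- NULL
  for (beta in c(2, 4, 6, 8)) {
    for (thr in c(0.5, 0.3, 0.2, 0.1)) {
      fit <- tryCatch(
        scale_free_fit(power_adjacency(rgm, beta, thr), n_bins = 5),
        gcnet_degenerate_fit = function(e) NULL)
      if (is.null(fit) || fit$slope >= 0) next
      if (is.null(best) || fit$r_squared > best$r2 + 1e-12) {
        best <- list(beta = beta, thr = thr, r2 = fit$r_squared)
      }
    }
  }
  expect_equal(sel$beta, best$beta)
  expect_equal(sel$p_threshold, best$thr)
  expect_equal(sel$r_squared, best$r2, tolerance = 1e-12)
})

test_that("ties in the grid resolve to smaller beta then larger threshold", {
  # disconnected blocks of sizes 2,2,2,2,3,3,5 give a decreasing degree
  # distribution; the count connectivity is identical for every beta and
  # every threshold (all pair P = 0), so the whole grid ties exactly
  pl <- planted_rg(c(2, 2, 2, 2, 3, 3, 5), within = 0.8, noise = 0,
                   seed = 8)
  sel <- select_network_config(pl$rg, beta_grid = c(2, 4),
                               threshold_grid = c(0.5, 0.1), n_bins = 4)
  expect_equal(sel$beta, 2)
  expect_equal(sel$p_threshold, 0.5)
})

test_that("planted blocks are recovered as modules (ARI 1 in the clean case)", {
  pl <- planted_rg(c(4, 3, 3), within = 0.9, noise = 0, seed = 9)
  adj <- power_adjacency(pl$rg, 6, 1)
  part <- detect_modules(tom_dissimilarity(adj))
  expect_equal(length(part$modules), 3)
  expect_equal(ari(part$assignments$module, pl$labels), 1)
})

test_that("module recovery is robust to noise across seeds", {
  aris <- vapply(1:20, function(s) {
    pl <- planted_rg(c(4, 3, 3), within = 0.75, noise = 0.1,
                     seed = 4000 + s)
    adj <- power_adjacency(pl$rg, 6, 1)
    part <- detect_modules(tom_dissimilarity(adj))
    ari(part$assignments$module, pl$labels)
  }, numeric(1))
  expect_gte(mean(aris >= 0.9), 0.9)
})

test_that("uniform networks collapse to one module; isolated nodes get label 0", {
  a <- matrix(0.5, 6, 6); diag(a) <- 0
  part <- detect_modules(tom_dissimilarity(a))
  expect_equal(length(part$modules), 1)
  expect_true(all(part$assignments$module == 1))

  # append two isolated nodes to a clean 3-block structure
  pl <- planted_rg(c(4, 3, 3), within = 0.9, noise = 0, seed = 10)
  k <- 10
  rg_big <- diag(k + 2)
  rg_big[1:k, 1:k] <- pl$rg$rg
  part0 <- detect_modules(tom_dissimilarity(power_adjacency(pl$rg, 6, 1)))
  part2 <- detect_modules(
    tom_dissimilarity(power_adjacency(rg_matrix(rg_big), 6, 1)))
  expect_equal(part2$assignments$module[k + 1:2], c(0L, 0L))
  expect_equal(part2$assignments$module[1:k], part0$assignments$module)
})

test_that("small clusters fall back to label 0", {
  pl <- planted_rg(c(4, 2), within = 0.9, noise = 0, seed = 11)
  part <- detect_modules(tom_dissimilarity(power_adjacency(pl$rg, 6, 1)),
                         min_size = 3)
  expect_equal(length(part$modules), 1)
  expect_equal(sum(part$assignments$module == 0), 2)
})
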