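# Weighted trait network over the genetic-correlation matrix: soft
# thresholding, scale-free model selection over a (beta, P-threshold)
# grid, topological overlap, and average-linkage module extraction.

#' Soft-threshold power adjacency
#'
#' `a_ij = |r_g(ij)|^beta` for valid pairs whose P-value is at or below
#' `p_threshold`; all other entries (and the diagonal) are 0. Thresholding
#' a pair sets its connection strength to zero rather than dropping the
#' node.
#'
#' @param rg An `rg_matrix`.
#' @param beta Soft power, at least 1.
#' @param p_threshold P-value threshold in (0, 1].
#' @return An `adjacency` matrix (base matrix with attributes `beta` and
#'   `p_threshold`).
#' @export
power_adjacency <- function(rg, beta, p_threshold = 1) {
  stopifnot(inherits(rg, "rg_matrix"))
  if (!is.numeric(beta) || length(beta) != 1L || !is.finite(beta) ||
      beta < 1) {
    abort("`beta` must be a single number >= 1.",
          class = "gcnet_invalid_argument")
  }
  check_scalar_number(p_threshold, "p_threshold", lower = 1e-300, upper = 1)
  keep <- rg$valid & !is.na(rg$p) & rg$p <= p_threshold
  a <- abs(rg$rg)^beta
  a[!keep] <- 0
  a[is.na(a)] <- 0
  diag(a) <- 0
  dimnames(a) <- list(rg$traits, rg$traits)
  structure(a, beta = beta, p_threshold = p_threshold,
            class = c("adjacency", class(matrix())))
}

#' Scale-free topology fit
#'
#' Computes each node's count connectivity `k` (number of nonzero
#' adjacencies), bins the nodes with `k > 0` into equal-width bins, and
#' regresses `log10(p(k))` on `log10(mean k)` over the non-empty bins. The
#' fit's R-squared is the scale-free model-selection index; the slope
#' estimates `-gamma` of the power law `p(k) ~ k^-gamma`.
#'
#' @param adj An adjacency matrix from [power_adjacency()].
#' @param n_bins Number of equal-width degree bins (default 10).
#' @return A `scale_free_fit`: list with `r_squared`, `slope`, `bins`
#'   (tibble of bin mean degree and frequency), `k` (per-node count
#'   connectivity) and `n_k0` (nodes with zero degree).
#' @export
scale_free_fit <- function(adj, n_bins = 10L) {
  check_scalar_number(n_bins, "n_bins", lower = 2, integerish = TRUE)
  k <- colSums(adj > 0)
  n_k0 <- sum(k == 0)
  kk <- k[k > 0]
  if (length(kk) < 2L || diff(range(kk)) < 1e-12) {
    abort("Degenerate degree distribution: all connected nodes share one degree.",
          class = "gcnet_degenerate_fit")
  }
  breaks <- seq(min(kk), max(kk), length.out = n_bins + 1L)
  bin <- cut(kk, breaks = breaks, include.lowest = TRUE, labels = FALSE)
  counts <- tabulate(bin, nbins = n_bins)
  mean_k <- vapply(seq_len(n_bins), function(b) {
    if (counts[b] == 0) NA_real_ else mean(kk[bin == b])
  }, numeric(1))
  keep <- counts > 0
  freq <- counts[keep] / sum(counts)
  mean_k <- mean_k[keep]
  if (sum(keep) < 2L) {
    abort("Fewer than 2 non-empty degree bins: scale-free fit is degenerate.",
          class = "gcnet_degenerate_fit")
  }
  if (sd(log10(freq)) < 1e-12) {
    abort("Constant bin frequencies: the log-log fit is degenerate.",
          class = "gcnet_degenerate_fit")
  }
  fit <- lm(log10(freq) ~ log10(mean_k))
  r2 <- suppressWarnings(summary(fit)$r.squared)  # exact fits are legal
  structure(
    list(r_squared = r2,
         slope = unname(stats::coef(fit)[2]),
         bins = tibble(mean_k = mean_k, freq = freq),
         k = k, n_k0 = n_k0, n_bins = n_bins),
    class = "scale_free_fit"
  )
}

#' @export
print.scale_free_fit <- function(x, ...) {
  cat(sprintf("<scale_free_fit> R^2 = %.3f, slope = %.3f, %d node(s) with k = 0\n",
              x$r_squared, x$slope, x$n_k0))
  invisible(x)
}

#' Select the network configuration by scale-free fit
#'
#' Evaluates every combination of soft power and genetic-correlation
#' P-value threshold, fits the scale-free index to each resulting network,
#' and returns the combination with the largest R-squared among fits with
#' a negative slope (a rising degree distribution is not scale-free).
#' R-squared ties within 1e-12 resolve to the smaller beta, then the
#' larger threshold — the less aggressive transformation.
#'
#' @param rg An `rg_matrix`.
#' @param beta_grid Candidate soft powers (default `c(2, 4, 6, 8)`).
#' @param threshold_grid Candidate P-value thresholds (default
#'   `c(0.5, 0.3, 0.2, 0.1)`).
#' @param n_bins Bins passed to [scale_free_fit()].
#' @return A `network_config`: list with the selected `beta`,
#'   `p_threshold`, `r_squared`, `slope`, and `grid`, the full tibble of
#'   fits (`NA` R-squared for degenerate cells).
#' @export
select_network_config <- function(rg, beta_grid = c(2, 4, 6, 8),
                                  threshold_grid = c(0.5, 0.3, 0.2, 0.1),
                                  n_bins = 10L) {
  stopifnot(inherits(rg, "rg_matrix"))
  if (length(beta_grid) == 0 || length(threshold_grid) == 0) {
    abort("Both grids must be non-empty.", class = "gcnet_invalid_argument")
  }
  grid <- tidyr::expand_grid(beta = sort(beta_grid),
                             threshold = sort(threshold_grid,
                                              decreasing = TRUE))
  fits <- purrr::pmap_dfr(grid, function(beta, threshold) {
    res <- tryCatch(
      scale_free_fit(power_adjacency(rg, beta, threshold), n_bins = n_bins),
      gcnet_degenerate_fit = function(e) NULL
    )
    tibble(beta = beta, threshold = threshold,
           r_squared = res$r_squared %||% NA_real_,
           slope = res$slope %||% NA_real_,
           n_k0 = res$n_k0 %||% NA_integer_,
           degenerate = is.null(res))
  })
  eligible <- dplyr::filter(fits, !.data$degenerate,
                            is.finite(.data$r_squared), .data$slope < 0)
  if (nrow(eligible) == 0) {
    abort(paste("Every grid cell is degenerate or rising;",
                "configure beta and the P threshold manually."),
          class = "gcnet_no_config")
  }
  best_r2 <- max(eligible$r_squared)
  cand <- dplyr::arrange(
    dplyr::filter(eligible, .data$r_squared >= best_r2 - 1e-12),
    .data$beta, dplyr::desc(.data$threshold)
  )
  sel <- cand[1, ]
  structure(
    list(beta = sel$beta, p_threshold = sel$threshold,
         r_squared = sel$r_squared, slope = sel$slope, grid = fits),
    class = "network_config"
  )
}

#' @export
print.network_config <- function(x, ...) {
  cat(sprintf("<network_config> beta = %g, P threshold = %g (R^2 = %.3f)\n",
              x$beta, x$p_threshold, x$r_squared))
  invisible(x)
}

#' Topological overlap dissimilarity
#'
#' Transforms an adjacency matrix into the topological overlap matrix
#' `w_ij = (l_ij + a_ij) / (min(k_i, k_j) + 1 - a_ij)` with
#' `l_ij = sum_u a_iu a_uj` (u over third parties) and weighted
#' connectivity `k_i = sum_u a_iu`, plus the dissimilarity `d = 1 - w`.
#' `w` is symmetric, has a unit diagonal, and lies in `[0, 1]` for any
#' adjacency in `[0, 1]`.
#'
#' @param adj Adjacency matrix (symmetric, zero diagonal, entries in
#'   `[0, 1]`).
#' @return A `tom` object: list with `w`, `d`, `l`, `k`, `traits`.
#' @export
tom_dissimilarity <- function(adj) {
  a <- unclass(adj)
  check_matrix_symmetric(a, "adj")
  if (any(a < 0 | a > 1)) {
    abort("Adjacency entries must lie in [0, 1].",
          class = "gcnet_invalid_argument")
  }
  diag(a) <- 0
  l <- a %*% a          # zero diagonal removes u = i and u = j terms
  k <- colSums(a)
  kmin <- outer(k, k, pmin)
  w <- (l + a) / (kmin + 1 - a)
  diag(w) <- 1
  d <- 1 - w
  traits <- rownames(a) %||% sprintf("trait%02d", seq_len(nrow(a)))
  dimnames(w) <- dimnames(d) <- dimnames(l) <- list(traits, traits)
  names(k) <- traits
  structure(list(w = w, d = d, l = l, k = k, traits = traits),
            class = "tom")
}

#' @export
print.tom <- function(x, ...) {
  cat(sprintf("<tom> %d traits, mean overlap %.3f\n",
              length(x$traits), mean(x$w[upper.tri(x$w)])))
  invisible(x)
}

#' Extract modules by average-linkage clustering
#'
#' Runs average-linkage agglomerative clustering on the TOM dissimilarity
#' of the connected (`k > 0`) subgraph and cuts the dendrogram at
#' `cut_fraction` of the maximum merge height. Clusters smaller than
#' `min_size` are merged into label 0, as are isolated nodes; remaining
#' modules are labelled 1, 2, ... in decreasing size order (ties broken by
#' first member). A dendrogram whose merge heights are all equal (a
#' perfectly uniform network) yields a single module.
#'
#' @param tom A `tom` object.
#' @param min_size Minimum module size (default 3).
#' @param cut_fraction Fraction of the maximum merge height at which to cut
#'   (default 0.95).
#' @return A `module_partition`: list with `assignments` (tibble `trait`,
#'   `module`), `modules` (list of member vectors), `hclust` (the tree, or
#'   `NULL`), `cut_height`.
#' @export
detect_modules <- function(tom, min_size = 3L, cut_fraction = 0.95) {
  stopifnot(inherits(tom, "tom"))
  check_scalar_number(min_size, "min_size", lower = 2, integerish = TRUE)
  check_scalar_number(cut_fraction, "cut_fraction", lower = 0, upper = 1)
  traits <- tom$traits
  active <- tom$k > 1e-12
  labels <- setNames(rep(0L, length(traits)), traits)
  hc <- NULL
  cut_height <- NA_real_

  if (sum(active) < min_size) {
    warn("Fewer connected traits than the minimum module size; all label 0.")
  } else {
    d <- tom$d[active, active, drop = FALSE]
    hc <- hclust(as.dist(d), method = "average")
    hts <- hc$height
    if (diff(range(hts)) < 1e-12) {
      raw <- setNames(rep(1L, sum(active)), traits[active])
      cut_height <- max(hts)
    } else {
      cut_height <- cut_fraction * max(hts)
      raw <- cutree(hc, h = cut_height)
    }
    sizes <- table(raw)
    keep_ids <- names(sizes)[sizes >= min_size]
    raw[!(as.character(raw) %in% keep_ids)] <- 0L
    kept <- sort(unique(raw[raw != 0]))
    if (length(kept) > 0) {
      ord <- order(-as.integer(table(factor(raw[raw != 0],
                                            levels = kept))),
                   vapply(kept, function(id) min(which(raw == id)),
                          numeric(1)))
      relabel <- setNames(seq_along(kept), kept[ord])
      raw[raw != 0] <- relabel[as.character(raw[raw != 0])]
    }
    labels[names(raw)] <- as.integer(raw)
  }

  assignments <- tibble(trait = traits, module = unname(labels[traits]))
  mods <- split(assignments$trait[assignments$module > 0],
                assignments$module[assignments$module > 0])
  structure(
    list(assignments = assignments, modules = mods, hclust = hc,
         cut_height = cut_height, min_size = min_size,
         cut_fraction = cut_fraction),
    class = "module_partition"
  )
}

#' @export
print.module_partition <- function(x, ...) {
  n_mod <- length(x$modules)
  sizes <- vapply(x$modules, length, integer(1))
  cat(sprintf("<module_partition> %d module(s)%s; %d unassigned\n",
              n_mod,
              if (n_mod > 0) paste0(" (sizes ",
                                    paste(sizes, collapse = ", "), ")")
              else "",
              sum(x$assignments$module == 0)))
  invisible(x)
}
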