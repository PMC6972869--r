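# broom-style tidy()/glance() methods for the package's result objects.

#' @rdname gcnet_tidiers
#' @param x A fitted gcnet object.
#' @param ... Unused.
#' @export
tidy.rg_matrix <- function(x, ...) {
  if (!is.null(x$pairs)) return(as_tibble(x$pairs))
  ut <- which(upper.tri(x$rg), arr.ind = TRUE)
  tibble(
    trait1 = x$traits[ut[, 1]], trait2 = x$traits[ut[, 2]],
    rg = x$rg[ut], se = x$se[ut], p = x$p[ut], valid = x$valid[ut]
  )
}

#' Tidiers for gcnet result objects
#'
#' `tidy()` returns the per-element long table of a result (pairwise
#' genetic correlations, degree bins, module assignments, grid fits);
#' `glance()` returns a one-row summary.
#'
#' @name gcnet_tidiers
#' @param x A fitted gcnet object.
#' @param ... Unused.
#' @export
glance.rg_matrix <- function(x, ...) {
  k <- length(x$traits)
  off <- x$rg[upper.tri(x$rg)]
  tibble(
    n_traits = k,
    n_pairs = k * (k - 1) / 2,
    n_invalid = x$n_invalid,
    mean_abs_rg = mean(abs(off), na.rm = TRUE)
  )
}

#' @rdname gcnet_tidiers
#' @export
tidy.scale_free_fit <- function(x, ...) as_tibble(x$bins)

#' @rdname gcnet_tidiers
#' @export
glance.scale_free_fit <- function(x, ...) {
  tibble(r_squared = x$r_squared, slope = x$slope, n_k0 = x$n_k0,
         n_bins = x$n_bins)
}

#' @rdname gcnet_tidiers
#' @export
tidy.network_config <- function(x, ...) as_tibble(x$grid)

#' @rdname gcnet_tidiers
#' @export
glance.network_config <- function(x, ...) {
  tibble(beta = x$beta, p_threshold = x$p_threshold,
         r_squared = x$r_squared, slope = x$slope)
}

#' @rdname gcnet_tidiers
#' @export
tidy.module_partition <- function(x, ...) as_tibble(x$assignments)

#' @rdname gcnet_tidiers
#' @export
glance.module_partition <- function(x, ...) {
  sizes <- vapply(x$modules, length, integer(1))
  tibble(
    n_modules = length(x$modules),
    largest = if (length(sizes)) max(sizes) else NA_integer_,
    smallest = if (length(sizes)) min(sizes) else NA_integer_,
    n_unassigned = sum(x$assignments$module == 0),
    cut_height = x$cut_height
  )
}

#' @rdname gcnet_tidiers
#' @export
glance.shet_null <- function(x, ...) {
  tibble(k = nrow(x$R), B = x$B, seed = x$seed,
         beta_a = unname(x$beta["a"]), beta_b = unname(x$beta["b"]))
}

#' @rdname gcnet_tidiers
#' @export
tidy.shet_null <- function(x, ...) {
  probs <- c(0.5, 0.9, 0.95, 0.99, 0.999)
  tibble(quantile = probs,
         s_het = stats::quantile(x$sorted_stats, probs, names = FALSE))
}
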