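#' Count connected components
#'
#' Isolated nodes count as components (a component is either a network
#' fragment or an individual node); an empty graph has 0 components.
#'
#' @param g An igraph graph.
#' @return Integer component count.
#' @export
count_components <- function(g) {
  if (igraph::vcount(g) == 0) return(0L)
  as.integer(igraph::components(g)$no)
}

#' Random node-removal fragmentation curve
#'
#' For each proportion p on a grid, removes `floor(p * n)` uniformly
#' chosen nodes, counts the components of the remainder, and repeats
#' `n_reps` times; the curve reports the mean and standard error per
#' proportion. The default grid runs from 0 to 0.70 in steps of 0.05
#' (until only 30% of nodes remain).
#'
#' @param g An igraph graph with at least 2 nodes (typically the
#'   single-mode roost projection).
#' @param max_removed_fraction Largest proportion of nodes removed.
#' @param step Grid step (> 0).
#' @param n_reps Replicates per proportion (default 1000).
#' @param seed Integer seed.
#' @return A `removal_curve` object; `tidy()` gives the tibble
#'   (`proportion`, `n_removed`, `mean_components`, `se_components`).
#' @export
random_removal_curve <- function(g, max_removed_fraction = 0.70, step = 0.05,
                                 n_reps = 1000, seed = 1L) {
  n <- igraph::vcount(g)
  if (n < 2) abort("removal simulation needs at least 2 nodes")
  if (!is.finite(step) || step <= 0) abort("step must be positive")
  props <- seq(0, max_removed_fraction, by = step)
  curve <- with_stage_seed(seed, "removal", {
    purrr::map_dfr(props, function(p) {
      k <- floor(p * n)
      comps <- if (k == 0) {
        rep(count_components(g), n_reps)
      } else {
        vapply(seq_len(n_reps), function(r) {
          keep <- setdiff(seq_len(n), sample.int(n, k))
          count_components(igraph::induced_subgraph(g, keep))
        }, integer(1))
      }
      tibble::tibble(
        proportion = p,
        n_removed = k,
        mean_components = mean(comps),
        se_components = stats::sd(comps) / sqrt(n_reps)
      )
    })
  })
  structure(list(curve = curve, n_nodes = n, n_reps = n_reps, seed = seed),
            class = "removal_curve")
}

#' @export
print.removal_curve <- function(x, ...) {
  cat("<removal_curve> ", x$n_nodes, " nodes, ", x$n_reps,
      " reps per proportion\n", sep = "")
  print(x$curve)
  invisible(x)
}

#' @method tidy removal_curve
#' @export
tidy.removal_curve <- function(x, ...) x$curve

#' @method glance removal_curve
#' @export
glance.removal_curve <- function(x, ...) {
  tibble::tibble(n_nodes = x$n_nodes, n_reps = x$n_reps, seed = x$seed,
                 max_proportion = max(x$curve$proportion))
}

#' Targeted removal of the most degree-central nodes
#'
#' Removes the `k` highest-degree nodes (ties broken by smallest node
#' name, recorded in the result) and counts the remaining components.
#'
#' @param g An igraph graph.
#' @param k Number of nodes to remove (`k < n`).
#' @return List with `removed` (node names or indices), `components`
#'   (count after removal) and `tie_broken` (was a degree tie resolved
#'   lexicographically?).
#' @export
targeted_removal <- function(g, k = 1) {
  n <- igraph::vcount(g)
  if (n < 1) abort("graph has no nodes")
  if (k >= n) abort("k must be smaller than the number of nodes")
  deg <- igraph::degree(g)
  ids <- igraph::V(g)$name %||% as.character(seq_len(n))
  ord <- order(-deg, ids)
  removed <- ord[seq_len(k)]
  tie <- k < n && deg[ord[k]] == deg[ord[k + 1]]
  g2 <- igraph::delete_vertices(g, removed)
  list(removed = ids[removed], components = count_components(g2),
       tie_broken = tie)
}

#' Plot a removal-fragmentation curve
#'
#' Mean number of components versus proportion of nodes removed, with a
#' mean +/- SE ribbon.
#'
#' @param object A `removal_curve`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot removal_curve
#' @export
autoplot.removal_curve <- function(object, ...) {
  ggplot2::ggplot(object$curve, ggplot2::aes(x = .data$proportion,
                                             y = .data$mean_components)) +
    ggplot2::geom_ribbon(ggplot2::aes(
      ymin = .data$mean_components - .data$se_components,
      ymax = .data$mean_components + .data$se_components
    ), alpha = 0.3) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "Proportion of roosts removed",
                  y = "Mean number of components") +
    ggplot2::theme_minimal()
}
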