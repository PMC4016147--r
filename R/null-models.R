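#' Sample an Erdos-Renyi random graph matched to observed dimensions
#'
#' Single-mode `G(n, p)`: each of the `n(n-1)/2` node pairs is an edge
#' independently with probability `p`. Two-mode: each bat-roost pair is
#' an edge independently with probability `p`, keeping the observed node
#' set sizes.
#'
#' @param n Either a single node count, or a length-2 vector
#'   `c(n_bats, n_roosts)` for a two-mode null network.
#' @param p Link probability in `[0, 1]`.
#' @return An igraph graph (bipartite with a `type` attribute when `n`
#'   has length 2). Uses the current RNG stream; seed with `set.seed()`
#'   or [withr::with_seed()] for reproducibility.
#' @export
sample_er_graph <- function(n, p) {
  if (!is.finite(p) || p < 0 || p > 1) abort("p must lie in [0, 1]")
  if (length(n) == 2) {
    igraph::sample_bipartite(n[1], n[2], type = "gnp", p = p)
  } else {
    igraph::sample_gnp(n, p)
  }
}

#' Monte Carlo permutation test of an observed metric against null draws
#'
#' With `N` null values and `b` exceedances in the heavier-loaded tail
#' (ties counted as exceedances), the tail p-value is the add-one
#' estimator `(b + 1) / (N + 1)`, so the smallest attainable p with 500
#' simulations is 1/501 (printed as 0.002). The default report gives the
#' smaller tail's p with its direction (`">"` when the observed value
#' sits above the null distribution, `"<"` below, `"="` when the tails
#' balance); `two_tailed = TRUE` doubles the smaller tail (capped at 1).
#'
#' @param observed Observed metric value (finite scalar).
#' @param null_values Numeric vector of null metric values.
#' @param two_tailed Double the smaller tail probability?
#' @return A list with `direction`, `p_value`, `p_upper`, `p_lower`, `n`.
#' @export
monte_carlo_test <- function(observed, null_values, two_tailed = FALSE) {
  if (!is.finite(observed)) abort("observed metric must be finite")
  null_values <- null_values[is.finite(null_values)]
  N <- length(null_values)
  if (N == 0) abort("no finite null values")
  p_upper <- (sum(null_values >= observed) + 1) / (N + 1)
  p_lower <- (sum(null_values <= observed) + 1) / (N + 1)
  direction <- if (p_upper < p_lower) ">" else if (p_lower < p_upper) "<" else "="
  p <- min(p_upper, p_lower)
  if (two_tailed) p <- min(1, 2 * p)
  list(direction = direction, p_value = p, p_upper = p_upper,
       p_lower = p_lower, n = N)
}

# Metric dispatch used by the null-model suite. Returns NA when the
# metric is undefined on a particular draw (the draw is then resampled).
compute_metric <- function(g, name, homophily_attr = "age_class") {
  val <- tryCatch(
    switch(name,
      density = net_density(g),
      mean_degree = net_mean_degree(g),
      mean_degree_bats = net_mean_degree(g, "bats"),
      mean_degree_roosts = net_mean_degree(g, "roosts"),
      clustering = suppressWarnings(net_clustering(g)),
      degree_centralization = net_degree_centralization(g),
      modularity = modularity_leading_eigenvector(g)$Q,
      mean_shortest_path = as.numeric(net_mean_shortest_path(g)),
      homophily = net_assortativity(g, homophily_attr),
      abort(paste0("unknown metric '", name, "'"))
    ),
    error = function(e) {
      if (grepl("unknown metric", conditionMessage(e))) stop(e)
      NA_real_
    }
  )
  as.numeric(val)
}

default_null_metrics <- function(g) {
  if (is_two_mode(g)) {
    c("density", "clustering", "degree_centralization")
  } else {
    c("density", "clustering", "degree_centralization", "modularity",
      "mean_shortest_path")
  }
}

#' Compare observed network metrics to Erdos-Renyi null networks
#'
#' Generates `n_sims` random networks with the same node set sizes as the
#' observed network and a constant link probability (by default the
#' observed density), computes each metric on every draw, and reports a
#' Monte Carlo permutation test per metric. Draws on which a metric is
#' undefined (e.g. a null draw with no connected pair) are resampled for
#' that metric so every test uses exactly `n_sims` null values; the
#' resample count is reported.
#'
#' @param g Observed igraph network (two-mode or single-mode).
#' @param metrics Character vector of metric names (see
#'   [monte_carlo_test()] callers: `"density"`, `"clustering"`,
#'   `"degree_centralization"`, `"modularity"`, `"mean_shortest_path"`,
#'   `"homophily"`, ...). Defaults depend on the network kind.
#' @param n_sims Number of null networks (default 500).
#' @param p Link probability; default `NULL` matches observed density.
#' @param seed Integer seed for the null stream.
#' @param two_tailed Passed to [monte_carlo_test()].
#' @param homophily_attr Vertex attribute used for the homophily metric;
#'   the observed attribute vector is carried onto null draws.
#' @return A `null_suite` object; `tidy()` returns one row per metric.
#' @export
run_null_suite <- function(g, metrics = NULL, n_sims = 500, p = NULL,
                           seed = 1L, two_tailed = FALSE,
                           homophily_attr = "age_class") {
  metrics <- metrics %||% default_null_metrics(g)
  p <- p %||% net_density(g)
  dims <- if (is_two_mode(g)) {
    c(sum(!igraph::V(g)$type), sum(igraph::V(g)$type))
  } else {
    igraph::vcount(g)
  }
  attrs <- igraph::vertex_attr(g, homophily_attr)
  draw <- function() {
    gg <- sample_er_graph(dims, p)
    if (!is.null(attrs) && "homophily" %in% metrics) {
      gg <- igraph::set_vertex_attr(gg, homophily_attr, value = attrs)
    }
    gg
  }
  observed <- vapply(metrics, function(mn) compute_metric(g, mn, homophily_attr),
                     numeric(1))
  if (any(!is.finite(observed))) {
    abort(paste0("observed metric undefined: ",
                 paste(metrics[!is.finite(observed)], collapse = ", ")))
  }
  res <- with_stage_seed(seed, "nulls", {
    nulls <- matrix(NA_real_, n_sims, length(metrics),
                    dimnames = list(NULL, metrics))
    for (i in seq_len(n_sims)) {
      gg <- draw()
      nulls[i, ] <- vapply(metrics, function(mn) compute_metric(gg, mn, homophily_attr),
                           numeric(1))
    }
    resampled <- stats::setNames(integer(length(metrics)), metrics)
    for (mn in metrics) {
      guard <- 0
      while (anyNA(nulls[, mn])) {
        i <- which(is.na(nulls[, mn]))[1]
        nulls[i, mn] <- compute_metric(draw(), mn, homophily_attr)
        resampled[mn] <- resampled[mn] + 1L
        guard <- guard + 1
        if (guard > 50 * n_sims) abort(paste0("metric '", mn, "' undefined on almost all null draws"))
      }
    }
    list(nulls = nulls, resampled = resampled)
  })
  tests <- lapply(metrics, function(mn) {
    monte_carlo_test(observed[[mn]], res$nulls[, mn], two_tailed = two_tailed)
  })
  structure(list(
    metrics = metrics, observed = observed, null_values = res$nulls,
    tests = tests, resampled = res$resampled,
    config = list(n_sims = n_sims, p = p, seed = seed, dims = dims,
                  two_tailed = two_tailed,
                  convention = if (two_tailed) "doubled smaller tail (add-one)"
                               else "smaller tail with direction (add-one)")
  ), class = "null_suite")
}

#' @export
print.null_suite <- function(x, ...) {
  cat("<null_suite> ", x$config$n_sims, " ER nulls, p = ",
      signif(x$config$p, 3), "\n", sep = "")
  print(tidy(x))
  invisible(x)
}

#' Tidy a null-model suite into one row per metric
#'
#' @param x A `null_suite`.
#' @param ... Unused.
#' @return Tibble: metric, observed, null mean/sd, direction, p-value,
#'   resample count.
#' @method tidy null_suite
#' @export
tidy.null_suite <- function(x, ...) {
  tibble::tibble(
    metric = x$metrics,
    observed = unname(x$observed),
    null_mean = unname(colMeans(x$null_values)),
    null_sd = unname(apply(x$null_values, 2, stats::sd)),
    direction = unname(vapply(x$tests, `[[`, character(1), "direction")),
    p_value = unname(vapply(x$tests, `[[`, numeric(1), "p_value")),
    n_resampled = unname(x$resampled)
  )
}

#' @export
#' @rdname tidy.null_suite
#' @method glance null_suite
glance.null_suite <- function(x, ...) {
  tibble::tibble(
    n_sims = x$config$n_sims,
    p = x$config$p,
    seed = x$config$seed,
    two_tailed = x$config$two_tailed,
    n_metrics = length(x$metrics)
  )
}
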