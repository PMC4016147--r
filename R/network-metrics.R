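#' Network density
#'
#' Single-mode: `2L / (n(n-1))`. Two-mode: `L / (n_bats * n_roosts)`,
#' the fraction of possible bat-roost edges realised.
#'
#' @param g An igraph graph; two-mode networks are recognised by their
#'   `type` vertex attribute.
#' @return Density in `[0, 1]`.
#' @export
net_density <- function(g) {
  if (is_two_mode(g)) {
    n1 <- sum(!igraph::V(g)$type)
    n2 <- sum(igraph::V(g)$type)
    if (n1 < 1 || n2 < 1) abort("two-mode density needs both node sets non-empty")
    igraph::ecount(g) / (n1 * n2)
  } else {
    n <- igraph::vcount(g)
    if (n < 2) abort("density needs at least 2 nodes")
    2 * igraph::ecount(g) / (n * (n - 1))
  }
}

#' Mean degree
#'
#' Average degree over a node set: all nodes for a single-mode graph, or
#' one side (`"bats"`/`"roosts"`) of a two-mode network. In a two-mode
#' network the roost-side mean degree is the mean number of tagged bats
#' visiting a roost.
#'
#' @param g An igraph graph.
#' @param node_set `"all"`, `"bats"` or `"roosts"`.
#' @return Mean degree (0 for an empty graph with nodes).
#' @export
net_mean_degree <- function(g, node_set = c("all", "bats", "roosts")) {
  node_set <- match.arg(node_set)
  deg <- igraph::degree(g)
  keep <- switch(node_set,
    all = rep(TRUE, igraph::vcount(g)),
    bats = !igraph::V(g)$type,
    roosts = igraph::V(g)$type
  )
  if (!any(keep)) abort("empty node set")
  mean(deg[keep])
}

# Maximum of sum(dmax - d_i) over all bipartite graphs with part sizes
# n1, n2: attained by a star whose hub (in one set) is adjacent to every
# node of the other set, the hub set chosen so the leaf set is the larger.
bipartite_centralization_max <- function(n1, n2) {
  max(n1, n2) * (n1 + n2 - 2)
}

#' Degree centralization
#'
#' Single-mode: Freeman's index, `sum(dmax - d_i) / ((n-1)(n-2))` --- 0
#' for regular graphs, 1 for a star. Two-mode: the same numerator taken
#' over both node sets, normalised by the maximum attainable in a
#' bipartite graph of identical dimensions (the star configuration), in
#' the spirit of the two-mode formulation of Borgatti & Everett.
#'
#' @param g An igraph graph.
#' @return Centralization in `[0, 1]`.
#' @export
net_degree_centralization <- function(g) {
  deg <- igraph::degree(g)
  if (is_two_mode(g)) {
    n1 <- sum(!igraph::V(g)$type)
    n2 <- sum(igraph::V(g)$type)
    if (n1 < 2 || n2 < 2) abort("two-mode centralization needs both sets of size >= 2")
    sum(max(deg) - deg) / bipartite_centralization_max(n1, n2)
  } else {
    n <- igraph::vcount(g)
    if (n < 3) abort("centralization needs at least 3 nodes")
    sum(max(deg) - deg) / ((n - 1) * (n - 2))
  }
}

# Count 4-paths (v1-u1-v2-u2-v3 with primary ends) and closed 4-paths in
# a two-mode incidence matrix B (primary rows x secondary columns). A
# 4-path is closed when its end nodes share a secondary neighbour
# distinct from the two inner secondary nodes, i.e. the path sits on at
# least one 6-cycle.
count_four_paths <- function(B) {
  np <- nrow(B)
  ns <- ncol(B)
  nbr_p <- lapply(seq_len(ns), function(u) which(B[, u] > 0))
  nbr_s <- lapply(seq_len(np), function(v) which(B[v, ] > 0))
  total <- 0
  closed <- 0
  for (v2 in seq_len(np)) {
    us <- nbr_s[[v2]]
    if (length(us) < 2) next
    for (u1 in us) {
      for (u2 in us) {
        if (u1 == u2) next
        v1s <- setdiff(nbr_p[[u1]], v2)
        v3s <- setdiff(nbr_p[[u2]], v2)
        for (v1 in v1s) {
          for (v3 in v3s) {
            if (v1 == v3) next
            total <- total + 1
            commons <- which(B[v1, ] > 0 & B[v3, ] > 0)
            if (length(setdiff(commons, c(u1, u2))) > 0) closed <- closed + 1
          }
        }
      }
    }
  }
  c(paths = total, closed = closed)
}

#' Clustering coefficient
#'
#' Single-mode: mean Watts-Strogatz local clustering over nodes of degree
#' at least 2 (lower-degree nodes are excluded from the average, not
#' counted as zero). Two-mode: Opsahl's coefficient, the fraction of
#' 4-paths (paths on 3 same-mode and 2 opposite-mode nodes) that are
#' closed into a 6-cycle; paths anchored in either node set are pooled.
#'
#' @param g An igraph graph.
#' @return Clustering in `[0, 1]`; 0 with a warning when no node or path
#'   is eligible.
#' @export
net_clustering <- function(g) {
  if (is_two_mode(g)) {
    B <- igraph::as_biadjacency_matrix(g, sparse = FALSE)
    counts <- count_four_paths(B) + count_four_paths(t(B))
    if (counts[["paths"]] == 0) {
      warn("no 4-paths in two-mode network; clustering defined as 0")
      return(0)
    }
    counts[["closed"]] / counts[["paths"]]
  } else {
    if (igraph::vcount(g) < 3) abort("clustering needs at least 3 nodes")
    loc <- igraph::transitivity(g, type = "local", isolates = "NaN")
    loc <- loc[igraph::degree(g) >= 2]
    loc <- loc[is.finite(loc)]
    if (length(loc) == 0) {
      warn("no nodes of degree >= 2; clustering defined as 0")
      return(0)
    }
    mean(loc)
  }
}

#' Mean shortest path length
#'
#' Average geodesic distance over all unordered node pairs within the
#' same component; disconnected pairs are excluded from the average and
#' their count is attached as attribute `n_excluded_pairs`.
#'
#' @param g An igraph graph (single-mode).
#' @return Mean geodesic distance (>= 1 for a graph with edges).
#' @export
net_mean_shortest_path <- function(g) {
  if (igraph::vcount(g) < 2) abort("mean shortest path needs at least 2 nodes")
  d <- igraph::distances(g)
  d <- d[upper.tri(d)]
  finite <- is.finite(d)
  if (!any(finite)) abort("no connected node pair")
  structure(mean(d[finite]), n_excluded_pairs = sum(!finite))
}

#' Nominal assortativity (homophily)
#'
#' Newman's nominal assortativity coefficient on the edge mixing matrix
#' of a categorical vertex attribute (here typically age class):
#' `r = (sum(e_ii) - sum(a_i * b_i)) / (1 - sum(a_i * b_i))`, in
#' `[-1, 1]`. Positive values indicate preference for same-class
#' partners, negative values avoidance.
#'
#' @param g An igraph graph.
#' @param attribute Name of a categorical vertex attribute.
#' @return Assortativity coefficient.
#' @export
net_assortativity <- function(g, attribute = "age_class") {
  vals <- igraph::vertex_attr(g, attribute)
  if (is.null(vals)) abort(paste0("vertex attribute '", attribute, "' not found"))
  ends <- igraph::as_edgelist(g, names = FALSE)
  classes <- unique(vals[unique(c(ends))])
  if (length(classes) < 2) abort("homophily undefined: fewer than 2 attribute classes among connected nodes")
  igraph::assortativity_nominal(g, types = as.integer(factor(vals)))
}

#' Full metric report for one network
#'
#' Computes the standard metric suite on a two-mode bat-roost network or
#' a single-mode projection and returns it as a one-row tibble shaped
#' like a row of the study's summary tables.
#'
#' @param g An igraph graph.
#' @param network_id Label for the network (e.g. `"roost_2009"`).
#' @param homophily_attr Vertex attribute for assortativity on
#'   single-mode graphs; skipped (NA) if absent or single-class.
#' @return A one-row tibble.
#' @export
network_metrics <- function(g, network_id = "network", homophily_attr = "age_class") {
  if (is_two_mode(g)) {
    tibble::tibble(
      network_id = network_id,
      kind = "two-mode",
      n_bats = sum(!igraph::V(g)$type),
      n_roosts = sum(igraph::V(g)$type),
      n_edges = igraph::ecount(g),
      mean_degree_bats = net_mean_degree(g, "bats"),
      mean_degree_roosts = net_mean_degree(g, "roosts"),
      density = net_density(g),
      clustering = suppressWarnings(net_clustering(g)),
      degree_centralization = net_degree_centralization(g)
    )
  } else {
    mod <- if (igraph::ecount(g) > 0) modularity_leading_eigenvector(g) else NULL
    hom <- tryCatch(net_assortativity(g, homophily_attr), error = function(e) NA_real_)
    msp <- tryCatch(as.numeric(net_mean_shortest_path(g)), error = function(e) NA_real_)
    tibble::tibble(
      network_id = network_id,
      kind = "single-mode",
      n_nodes = igraph::vcount(g),
      n_edges = igraph::ecount(g),
      mean_degree = net_mean_degree(g),
      density = net_density(g),
      clustering = suppressWarnings(net_clustering(g)),
      degree_centralization = net_degree_centralization(g),
      modularity_Q = if (is.null(mod)) NA_real_ else mod$Q,
      n_communities = if (is.null(mod)) NA_integer_ else max(mod$membership),
      mean_shortest_path = msp,
      homophily_r = hom
    )
  }
}
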