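#' Build the two-mode bat-roost network from relocations
#'
#' Bats and roosts form the two node sets; an unweighted edge joins bat b
#' and roost r iff b was relocated at r at least once (repeated use
#' collapses to a single edge). Every bat and roost observed in the table
#' becomes a node.
#'
#' @param relocations Data frame with columns `bat_id`, `date`,
#'   `roost_id` (one row per bat-day relocation).
#' @param bat_attrs Optional data frame with `bat_id` plus attribute
#'   columns (e.g. `age_class`) copied onto bat vertices.
#' @return An igraph bipartite graph; vertex attribute `type` is `FALSE`
#'   for bats and `TRUE` for roosts, `mode` is `"bat"`/`"roost"`.
#' @export
#' @examples
#' rel <- tibble::tibble(
#'   bat_id = c("b1", "b1", "b2"),
#'   date = as.Date("2009-06-01") + 0:2,
#'   roost_id = c("r1", "r2", "r1")
#' )
#' g <- build_bipartite(rel)
#' igraph::ecount(g) # 3
build_bipartite <- function(relocations, bat_attrs = NULL) {
  if (is.null(relocations) || nrow(relocations) == 0) {
    abort("no relocations: cannot build a network from an empty table")
  }
  stopifnot(all(c("bat_id", "roost_id") %in% names(relocations)))
  edges <- dplyr::distinct(relocations, .data$bat_id, .data$roost_id)
  bats <- sort(unique(relocations$bat_id))
  roosts <- sort(unique(relocations$roost_id))
  if (length(intersect(bats, roosts))) {
    abort("bat and roost identifiers must not overlap")
  }
  g <- igraph::make_empty_graph(n = 0, directed = FALSE)
  g <- igraph::add_vertices(g, length(bats), name = bats,
                            type = FALSE, mode = "bat")
  g <- igraph::add_vertices(g, length(roosts), name = roosts,
                            type = TRUE, mode = "roost")
  g <- igraph::add_edges(g, rbind(match(edges$bat_id, bats),
                                  match(edges$roost_id, roosts) + length(bats)))
  if (!is.null(bat_attrs)) {
    idx <- match(bats, bat_attrs$bat_id)
    for (col in setdiff(names(bat_attrs), "bat_id")) {
      vals <- rep(NA_character_, igraph::vcount(g))
      vals[seq_along(bats)] <- as.character(bat_attrs[[col]][idx])
      g <- igraph::set_vertex_attr(g, col, value = vals)
    }
  }
  g
}

is_two_mode <- function(g) "type" %in% igraph::vertex_attr_names(g)

#' Project a two-mode network onto one node set
#'
#' Two same-mode nodes become adjacent iff they share at least one
#' opposite-mode neighbour (coincident roost use for bats; shared
#' occupants for roosts). The projection is simple and unweighted, and
#' nodes sharing no partner are retained as isolates so that density and
#' component denominators reflect the full node set.
#'
#' @param bipartite A bipartite igraph from [build_bipartite()].
#' @param mode `"bats"` or `"roosts"`.
#' @return An undirected simple igraph graph.
#' @export
project <- function(bipartite, mode = c("bats", "roosts")) {
  if (!is_two_mode(bipartite)) abort("project() expects a two-mode network")
  mode <- tryCatch(match.arg(mode), error = function(e) {
    abort("mode must be 'bats' or 'roosts'")
  })
  proj <- igraph::bipartite_projection(bipartite, multiplicity = FALSE)
  # igraph returns proj1 = type FALSE (bats), proj2 = type TRUE (roosts)
  g <- if (mode == "bats") proj[[1]] else proj[[2]]
  igraph::simplify(g)
}

#' Write a network as GraphML and as a two-column edge list
#'
#' The bipartite file carries the `mode` vertex attribute distinguishing
#' bats from roosts.
#'
#' @param g An igraph graph.
#' @param path_graphml,path_edges Output paths; `NULL` skips that format.
#' @return Invisibly, the paths written.
#' @export
write_network <- function(g, path_graphml = NULL, path_edges = NULL) {
  if (!is.null(path_graphml)) {
    igraph::write_graph(g, path_graphml, format = "graphml")
  }
  if (!is.null(path_edges)) {
    el <- igraph::as_edgelist(g)
    readr::write_csv(tibble::tibble(from = el[, 1], to = el[, 2]), path_edges)
  }
  invisible(c(graphml = path_graphml, edges = path_edges))
}
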