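#' Isopleth (home-range contour) of a utilization distribution
#'
#' The smallest set of highest-mass cells whose cumulative probability
#' reaches `level`; its area is the cell count times the cell area.
#'
#' @param ud A `ud_grid`.
#' @param level Isopleth level in (0, 1] (default 0.95).
#' @return List with `mask` (logical matrix), `area_ha` (hectares;
#'   1 ha = 1e4 m^2), `level` and `mass` (probability actually enclosed).
#' @export
isopleth <- function(ud, level = 0.95) {
  stopifnot(inherits(ud, "ud_grid"))
  if (!is.finite(level) || level <= 0 || level > 1) {
    abort("level must lie in (0, 1]")
  }
  m <- as.vector(ud$mass)
  ord <- order(m, decreasing = TRUE)
  cum <- cumsum(m[ord])
  k <- which(cum >= level * sum(m) - 1e-12)[1]
  mask <- matrix(FALSE, nrow(ud$mass), ncol(ud$mass))
  mask[ord[seq_len(k)]] <- TRUE
  list(mask = mask, area_ha = k * ud$cell^2 / 1e4, level = level,
       mass = cum[k])
}

#' Truncate a UD at an isopleth and renormalize
#'
#' @param ud A `ud_grid`.
#' @param level Isopleth level.
#' @return A `ud_grid` with mass outside the level isopleth set to zero
#'   and the remainder rescaled to sum to 1.
#' @export
truncate_ud <- function(ud, level = 0.95) {
  iso <- isopleth(ud, level)
  mass <- ud$mass
  mass[!iso$mask] <- 0
  new_ud_grid(ud$x, ud$y, ud$cell, mass / sum(mass),
              c(ud$meta, list(truncated_at = level)))
}

check_common_grid <- function(ud_a, ud_b) {
  stopifnot(inherits(ud_a, "ud_grid"), inherits(ud_b, "ud_grid"))
  if (!same_grid(ud_a, ud_b)) abort("UDs are not on a common grid")
}

#' Utilization distribution overlap index (UDOI)
#'
#' `UDOI = A_overlap * sum(d_a * d_b * cell_area)` where `A_overlap` is
#' the intersection area of the two `level` isopleths and `d_a`, `d_b`
#' are the UD densities. With the default `truncate = TRUE` the
#' densities are the level-truncated, renormalised UDs (overlap of the
#' 95% distributions). Values near 1 arise for uniform independent use
#' of the same area; values above 1 indicate concentrated joint use.
#'
#' @param ud_a,ud_b `ud_grid`s on a common grid.
#' @param level Isopleth level (default 0.95).
#' @param truncate Truncate-and-renormalise at `level` before taking the
#'   product integral? (`FALSE` uses the full UDs.)
#' @return Non-negative scalar, symmetric in its arguments.
#' @export
udoi <- function(ud_a, ud_b, level = 0.95, truncate = TRUE) {
  check_common_grid(ud_a, ud_b)
  iso_a <- isopleth(ud_a, level)
  iso_b <- isopleth(ud_b, level)
  cell_area <- ud_a$cell^2
  a_overlap <- sum(iso_a$mask & iso_b$mask) * cell_area
  if (a_overlap == 0) return(0)
  if (truncate) {
    ud_a <- truncate_ud(ud_a, level)
    ud_b <- truncate_ud(ud_b, level)
  }
  da <- ud_a$mass / cell_area
  db <- ud_b$mass / cell_area
  a_overlap * sum(da * db) * cell_area
}

#' Bhattacharyya affinity between two utilization distributions
#'
#' `BA = sum(sqrt(d_a * d_b) * cell_area)`, in `[0, 1]`: 0 for disjoint
#' distributions, 1 iff the distributions agree cell-wise. Used to
#' compare the same colony's space use across years.
#'
#' @param ud_a,ud_b `ud_grid`s on a common grid.
#' @return Scalar in `[0, 1]`.
#' @export
bhattacharyya_affinity <- function(ud_a, ud_b) {
  check_common_grid(ud_a, ud_b)
  min(1, sum(sqrt(ud_a$mass * ud_b$mass)))
}

#' Weighted centroid of a point set
#'
#' @param points Data frame with `x_m`, `y_m`.
#' @param weights Non-negative weights (default equal).
#' @return Named numeric `c(x, y)`.
#' @export
ud_centroid <- function(points, weights = NULL) {
  stopifnot(nrow(points) >= 1)
  w <- rep_len(weights %||% 1, nrow(points))
  if (sum(w) <= 0) abort("weights must have positive sum")
  c(x = sum(w * points$x_m) / sum(w), y = sum(w * points$y_m) / sum(w))
}

#' Euclidean distance between two centroids, in meters
#'
#' @param c1,c2 Named numeric `c(x, y)` as from [ud_centroid()].
#' @return Distance in meters.
#' @export
centroid_shift <- function(c1, c2) {
  sqrt((c1[["x"]] - c2[["x"]])^2 + (c1[["y"]] - c2[["y"]])^2)
}

#' Foraging-overlap network from individual UDs
#'
#' One node per UD-eligible bat (eligibility --- at least 40 fixes --- is
#' enforced upstream when the UDs are built); an edge joins a dyad iff
#' its UDOI strictly exceeds `threshold`.
#'
#' @param uds Named list of `ud_grid`s (names are bat ids), all on a
#'   common grid.
#' @param threshold UDOI edge threshold (default 1, strict inequality;
#'   values equal to the threshold up to a 1e-9 numerical tolerance do
#'   not create an edge).
#' @param level Isopleth level passed to [udoi()].
#' @param truncate Passed to [udoi()].
#' @return List with `graph` (igraph, isolates retained), `dyads`
#'   (tibble `bat_a`, `bat_b`, `udoi`, `edge`) and
#'   `fraction_over_threshold`.
#' @export
foraging_overlap_network <- function(uds, threshold = 1.0, level = 0.95,
                                     truncate = TRUE) {
  if (length(uds) < 2) abort("need at least 2 UD-eligible bats")
  ids <- names(uds)
  stopifnot(!is.null(ids), !anyDuplicated(ids))
  pairs <- utils::combn(ids, 2)
  dyads <- purrr::map_dfr(seq_len(ncol(pairs)), function(k) {
    a <- pairs[1, k]; b <- pairs[2, k]
    tibble::tibble(bat_a = a, bat_b = b,
                   udoi = udoi(uds[[a]], uds[[b]], level, truncate))
  })
  dyads$edge <- dyads$udoi > threshold + 1e-9
  g <- igraph::make_empty_graph(length(ids), directed = FALSE)
  g <- igraph::set_vertex_attr(g, "name", value = ids)
  if (any(dyads$edge)) {
    el <- rbind(match(dyads$bat_a[dyads$edge], ids),
                match(dyads$bat_b[dyads$edge], ids))
    g <- igraph::add_edges(g, el)
  }
  list(graph = g, dyads = dyads,
       fraction_over_threshold = mean(dyads$edge))
}
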