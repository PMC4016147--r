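#' Modularity of a given partition
#'
#' Direct evaluation of `Q = sum_c (e_cc - a_c^2)` where `e_cc` is the
#' fraction of edges inside community c and `a_c` its fraction of edge
#' endpoints.
#'
#' @param g An igraph graph with at least one edge.
#' @param membership Integer community labels, one per vertex.
#' @return Modularity Q.
#' @export
modularity_q <- function(g, membership) {
  m <- igraph::ecount(g)
  if (m == 0) abort("modularity undefined for an edgeless graph")
  stopifnot(length(membership) == igraph::vcount(g))
  ends <- igraph::as_edgelist(g, names = FALSE)
  comms <- sort(unique(membership))
  deg <- igraph::degree(g)
  Q <- 0
  for (c in comms) {
    inside <- membership[ends[, 1]] == c & membership[ends[, 2]] == c
    e_cc <- sum(inside) / m
    a_c <- sum(deg[membership == c]) / (2 * m)
    Q <- Q + e_cc - a_c^2
  }
  Q
}

# Kernighan-Lin style fine-tuning of a bisection vector s over the
# (generalized) modularity matrix Bg: repeatedly sweep over vertices,
# flipping each at most once per pass in order of best gain, and keep the
# best intermediate state. Gains maximise f(s) = s' Bg s.
kl_refine <- function(Bg, s) {
  n <- length(s)
  fval <- function(s) drop(crossprod(s, Bg %*% s))
  best_s <- s
  best_f <- fval(s)
  repeat {
    cur <- best_s
    cur_f <- best_f
    Bs <- drop(Bg %*% cur)
    moved <- rep(FALSE, n)
    pass_best_f <- best_f
    pass_best_s <- best_s
    for (step in seq_len(n)) {
      # gain of flipping i: -4 s_i * (Bs_i - B_ii s_i)
      gains <- -4 * cur * (Bs - diag(Bg) * cur)
      gains[moved] <- -Inf
      i <- which.max(gains)
      cur_f <- cur_f + gains[i]
      Bs <- Bs - 2 * cur[i] * Bg[, i]
      cur[i] <- -cur[i]
      moved[i] <- TRUE
      if (cur_f > pass_best_f && any(cur > 0) && any(cur < 0)) {
        pass_best_f <- cur_f
        pass_best_s <- cur
      }
    }
    if (pass_best_f > best_f + 1e-12) {
      best_f <- pass_best_f
      best_s <- pass_best_s
    } else {
      break
    }
  }
  best_s
}

# Attempt to bisect the vertex subset idx using the leading eigenvector
# of the generalized modularity matrix. Returns a sign vector over idx,
# or NULL when no Q-increasing split exists.
leading_eigen_split <- function(B, idx, m2) {
  Bg <- B[idx, idx, drop = FALSE]
  diag(Bg) <- diag(Bg) - rowSums(Bg)
  e <- eigen(Bg, symmetric = TRUE)
  if (e$values[1] <= 1e-10) return(NULL)
  s <- ifelse(e$vectors[, 1] >= 0, 1, -1)
  s <- kl_refine(Bg, s)
  dQ <- drop(crossprod(s, Bg %*% s)) / (2 * m2)
  if (dQ <= 1e-10 || all(s > 0) || all(s < 0)) NULL else s
}

#' Leading-eigenvector community detection
#'
#' Newman's spectral method: the modularity matrix
#' `B = A - k k' / 2m` is bisected recursively along the sign of its
#' leading eigenvector (with Kernighan-Lin style fine-tuning of each
#' split); a split is accepted only when it increases Q, and subdivision
#' stops when no Q-increasing split exists. Indivisible graphs (e.g. a
#' complete graph) remain one community with Q = 0.
#'
#' @param g An undirected simple igraph graph with at least one edge.
#' @return A list with `membership` (integer labels), `Q` (modularity of
#'   the returned partition) and `n_communities`.
#' @export
modularity_leading_eigenvector <- function(g) {
  if (igraph::ecount(g) == 0) abort("modularity undefined for an edgeless graph")
  n <- igraph::vcount(g)
  A <- igraph::as_adjacency_matrix(g, sparse = FALSE)
  k <- colSums(A)
  m2 <- sum(k) # 2m
  B <- A - outer(k, k) / m2
  membership <- integer(n)
  next_id <- 0L
  queue <- list(seq_len(n))
  while (length(queue)) {
    idx <- queue[[1]]
    queue <- queue[-1]
    s <- if (length(idx) > 1) leading_eigen_split(B, idx, m2) else NULL
    if (is.null(s)) {
      next_id <- next_id + 1L
      membership[idx] <- next_id
    } else {
      queue <- c(queue, list(idx[s > 0]), list(idx[s < 0]))
    }
  }
  membership <- refine_membership(B, m2 / 2, membership)
  # relabel communities consecutively
  membership <- as.integer(factor(membership))
  list(membership = membership,
       Q = modularity_q(g, membership),
       n_communities = max(membership))
}

# Final fine-tuning pass over the whole partition: greedily move single
# vertices between communities while modularity increases. Q for a
# membership vector equals sum over same-community pairs of B_ij / 2m,
# so moves are evaluated directly on the modularity matrix.
refine_membership <- function(B, m, membership) {
  qval <- function(mem) {
    s <- 0
    for (c in unique(mem)) {
      idx <- which(mem == c)
      s <- s + sum(B[idx, idx])
    }
    s / (2 * m)
  }
  best_q <- qval(membership)
  repeat {
    improved <- FALSE
    for (v in seq_along(membership)) {
      current <- membership[v]
      for (target in setdiff(unique(membership), current)) {
        trial <- membership
        trial[v] <- target
        q <- qval(trial)
        if (q > best_q + 1e-12) {
          membership <- trial
          best_q <- q
          improved <- TRUE
        }
      }
    }
    if (!improved) break
  }
  membership
}
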