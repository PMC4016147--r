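# Independent oracles used across the test suite. These deliberately
# re-derive quantities from first principles (enumeration, brute force,
# quadrature, Newton iteration) without calling the package's own
# implementation of the quantity under test.

# --- graph builders -------------------------------------------------------

graph_from_pairs <- function(pairs, n = max(pairs)) {
  g <- igraph::make_empty_graph(n, directed = FALSE)
  if (length(pairs)) g <- igraph::add_edges(g, t(pairs))
  g
}

two_k4_bridge <- function() {
  el <- rbind(t(utils::combn(1:4, 2)), t(utils::combn(5:8, 2)), c(4, 5))
  graph_from_pairs(el, 8)
}

bipartite_from_incidence <- function(B) {
  nb <- nrow(B); nr <- ncol(B)
  g <- igraph::make_empty_graph(nb + nr, directed = FALSE)
  g <- igraph::set_vertex_attr(g, "type", value = c(rep(FALSE, nb), rep(TRUE, nr)))
  g <- igraph::set_vertex_attr(g, "name",
                               value = c(sprintf("b%02d", seq_len(nb)),
                                         sprintf("r%02d", seq_len(nr))))
  idx <- which(B > 0, arr.ind = TRUE)
  if (nrow(idx)) g <- igraph::add_edges(g, rbind(idx[, 1], idx[, 2] + nb))
  g
}

small_relocations <- function() {
  tibble::tibble(
    bat_id = c("b1", "b1", "b2", "b2", "b3"),
    date = as.Date("2009-06-01") + c(0, 1, 0, 1, 0),
    roost_id = c("r1", "r2", "r1", "r2", "r2")
  )
}

# --- modularity oracles ---------------------------------------------------

# hand formula Q = sum_c(e_cc - a_c^2), written independently of
# modularity_q()
hand_modularity <- function(g, membership) {
  m <- igraph::ecount(g)
  el <- igraph::as_edgelist(g, names = FALSE)
  deg <- igraph::degree(g)
  q <- 0
  for (c in unique(membership)) {
    e_cc <- sum(membership[el[, 1]] == c & membership[el[, 2]] == c) / m
    a_c <- sum(deg[membership == c]) / (2 * m)
    q <- q + e_cc - a_c^2
  }
  q
}

# brute force over every partition of the vertex set (restricted growth
# strings); feasible for n <= 8 (Bell(8) = 4140)
brute_force_modularity <- function(g) {
  n <- igraph::vcount(g)
  best <- 0 # trivial one-community partition has Q = 0
  rec <- function(assign, k) {
    i <- length(assign) + 1L
    if (i > n) {
      q <- hand_modularity(g, assign)
      if (q > best) best <<- q
      return(invisible())
    }
    for (c in seq_len(k + 1L)) rec(c(assign, c), max(k, c))
  }
  rec(integer(0), 0L)
  best
}

# brute force over all 2-community splits only
brute_force_bipartition_Q <- function(g) {
  n <- igraph::vcount(g)
  best <- 0
  for (code in 0:(2^(n - 1) - 1)) {
    side <- c(0L, as.integer(intToBits(code))[seq_len(n - 1)]) + 1L
    q <- hand_modularity(g, side)
    if (q > best) best <- q
  }
  best
}

# --- mean shortest path: own breadth-first search -------------------------

bfs_mean_path <- function(g) {
  n <- igraph::vcount(g)
  adj <- lapply(seq_len(n), function(v) as.integer(igraph::neighbors(g, v)))
  tot <- 0; cnt <- 0
  for (s in seq_len(n)) {
    dist <- rep(NA_integer_, n); dist[s] <- 0L
    queue <- s
    while (length(queue)) {
      v <- queue[1]; queue <- queue[-1]
      for (w in adj[[v]]) if (is.na(dist[w])) {
        dist[w] <- dist[v] + 1L
        queue <- c(queue, w)
      }
    }
    reach <- which(!is.na(dist) & seq_len(n) > s)
    tot <- tot + sum(dist[reach]); cnt <- cnt + length(reach)
  }
  tot / cnt
}

# --- two-mode centralization: exhaustive normalization oracle -------------

# max over all bipartite graphs with part sizes n1 x n2 of
# sum(dmax - d_i); enumeration feasible for n1 * n2 <= 12
enum_bipartite_central_max <- function(n1, n2) {
  best <- 0
  for (code in 0:(2^(n1 * n2) - 1)) {
    B <- matrix(as.integer(intToBits(code))[seq_len(n1 * n2)], n1, n2)
    deg <- c(rowSums(B), colSums(B))
    best <- max(best, sum(max(deg) - deg))
  }
  best
}

# --- Poisson GLM: independent Newton-Raphson on the log-likelihood --------

newton_poisson <- function(x, y, tol = 1e-12) {
  X <- cbind(1, x)
  beta <- c(log(mean(y)), 0)
  for (it in 1:200) {
    eta <- drop(X %*% beta)
    mu <- exp(eta)
    grad <- drop(t(X) %*% (y - mu))
    H <- t(X) %*% (X * mu)
    step <- solve(H, grad)
    beta <- beta + step
    if (max(abs(step)) < tol) break
  }
  mu <- exp(drop(X %*% beta))
  dev <- 2 * sum(ifelse(y > 0, y * log(y / mu), 0) - (y - mu))
  mu0 <- mean(y)
  dev0 <- 2 * sum(ifelse(y > 0, y * log(y / mu0), 0) - (y - mu0))
  list(beta = unname(beta), deviance = dev, null_deviance = dev0)
}

# --- BRB oracles ----------------------------------------------------------

# fine-grid quadrature of the bridge density: time integral over each
# non-unusable segment of the isotropic Gaussian with variance
# hmin^2 + 2 D T p (1 - p) (resting segments: point kernels at the fixes)
quadrature_brb <- function(track, D, xc, yc, n_steps = 800) {
  params <- track$params
  fx <- track$fixes
  seg <- track$segments[track$segments$status != "unusable", , drop = FALSE]
  dens <- matrix(0, length(xc), length(yc))
  gauss <- function(mux, muy, sd) {
    stats::dnorm(xc, mux, sd) %o% stats::dnorm(yc, muy, sd)
  }
  total_w <- 0
  for (s in seq_len(nrow(seg))) {
    i0 <- seg$i0[s]; i1 <- seg$i1[s]; dur <- seg$duration_min[s]
    if (seg$status[s] == "resting") {
      dens <- dens + (dur / 2) * gauss(fx$x_m[i0], fx$y_m[i0], params$hmin)
      dens <- dens + (dur / 2) * gauss(fx$x_m[i1], fx$y_m[i1], params$hmin)
    } else {
      p <- (seq_len(n_steps) - 0.5) / n_steps
      for (j in seq_len(n_steps)) {
        mux <- (1 - p[j]) * fx$x_m[i0] + p[j] * fx$x_m[i1]
        muy <- (1 - p[j]) * fx$y_m[i0] + p[j] * fx$y_m[i1]
        sd <- sqrt(params$hmin^2 + 2 * D * dur * p[j] * (1 - p[j]))
        dens <- dens + (dur / n_steps) * gauss(mux, muy, sd)
      }
    }
    total_w <- total_w + dur
  }
  m <- dens / total_w * (xc[2] - xc[1])^2
  m / sum(m)
}

# leave-one-out bridge log-likelihood as an explicit function of D,
# maximised by 1-D grid search
loo_bridge_loglik <- function(track, D) {
  fx <- track$fixes
  seg <- track$segments
  tsec <- as.numeric(fx$timestamp)
  idx <- which(seg$status[-nrow(seg)] == "usable" & seg$status[-1] == "usable") + 1L
  ll <- 0
  for (i in idx) {
    delta <- (tsec[i + 1] - tsec[i - 1]) / 60
    p <- (tsec[i] - tsec[i - 1]) / (tsec[i + 1] - tsec[i - 1])
    v <- 2 * D * delta * p * (1 - p)
    mux <- (1 - p) * fx$x_m[i - 1] + p * fx$x_m[i + 1]
    muy <- (1 - p) * fx$y_m[i - 1] + p * fx$y_m[i + 1]
    ll <- ll + stats::dnorm(fx$x_m[i], mux, sqrt(v), log = TRUE) +
      stats::dnorm(fx$y_m[i], muy, sqrt(v), log = TRUE)
  }
  ll
}

gridsearch_D <- function(track, lo = 1e-2, hi = 1e5, n = 4000) {
  Ds <- exp(seq(log(lo), log(hi), length.out = n))
  ll <- vapply(Ds, function(D) loo_bridge_loglik(track, D), numeric(1))
  Ds[which.max(ll)]
}

# toy 3-fix track used by the BRB oracle checks
toy_track <- function(params = brb_params()) {
  fixes <- tibble::tibble(
    timestamp = as.POSIXct("2009-07-01 22:00:00", tz = "UTC") + c(0, 20, 45) * 60,
    x_m = c(0, 300, 650),
    y_m = c(0, 120, 260)
  )
  segment_track(fixes, params)
}

# small synthetic colony configuration for fast tests
fast_config <- function(seed = 1, ...) {
  defaults <- list(n_tagged_bats = 8, n_roosts = 10, season_days = 40,
                   tracking_days_per_bat = list(mean = 8, sd = 3, min = 3, max = 15),
                   fixes_per_night = 6, n_exit_count_nights = 25, seed = seed)
  do.call(colony_config, utils::modifyList(defaults, list(...)))
}

expect_tv_less_than <- function(a, b, tv) {
  expect_lt(0.5 * sum(abs(a - b)), tv)
}
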