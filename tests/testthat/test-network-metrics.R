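test_that("density matches closed forms for single- and two-mode graphs", {
  expect_equal(net_density(igraph::make_full_graph(5)), 1)
  # printed node counts: 21 bats x 33 roosts with 64 edges -> 0.09 (2 dp)
  set.seed(1)
  B <- matrix(0, 21, 33)
  B[sample.int(21 * 33, 64)] <- 1
  g <- bipartite_from_incidence(B)
  expect_equal(round(net_density(g), 2), 0.09)
  # 21 nodes, 84 edges -> 0.40
  g2 <- igraph::sample_gnm(21, 84)
  expect_equal(net_density(g2), 0.40)
  expect_error(net_density(igraph::make_empty_graph(1, directed = FALSE)),
               "2 nodes")
})

test_that("mean degree sums the right node set", {
  set.seed(2)
  B <- matrix(0, 21, 33)
  B[sample.int(21 * 33, 64)] <- 1
  g <- bipartite_from_incidence(B)
  expect_equal(round(net_mean_degree(g, "roosts"), 2), 1.94)
  expect_equal(net_mean_degree(g, "bats"), 64 / 21)
  g2 <- igraph::sample_gnm(25, 245)
  expect_equal(net_mean_degree(g2), 19.60)
  expect_equal(net_mean_degree(igraph::make_empty_graph(4, directed = FALSE)), 0)
})

test_that("degree centralization is 1 for stars, 0 for regular graphs", {
  expect_equal(net_degree_centralization(igraph::make_star(10, mode = "undirected")), 1)
  expect_equal(net_degree_centralization(igraph::make_ring(10)), 0)
  # biregular bipartite: all degrees equal within sets -> 0
  B <- matrix(1, 3, 3)
  expect_equal(net_degree_centralization(bipartite_from_incidence(B)), 0)
})

test_that("two-mode centralization normalization equals the exhaustive maximum", {
  # enumerate every bipartite graph of small dimensions and confirm the
  # star-configuration maximum used for normalization
  for (dims in list(c(2, 3), c(3, 3), c(2, 5))) {
    enum_max <- enum_bipartite_central_max(dims[1], dims[2])
    expect_equal(enum_max, max(dims) * (sum(dims) - 2))
  }
  # an irregular case stays within [0, 1] and matches a direct computation
  B <- matrix(0, 3, 3); B[1, ] <- 1; B[2, 1] <- 1
  g <- bipartite_from_incidence(B)
  deg <- igraph::degree(g)
  expect_equal(net_degree_centralization(g),
               sum(max(deg) - deg) / enum_bipartite_central_max(3, 3))
})

test_that("clustering follows Watts-Strogatz (single) and Opsahl 4-paths (two-mode)", {
  expect_equal(net_clustering(igraph::make_full_graph(6)), 1)
  expect_equal(net_clustering(igraph::make_tree(7, children = 2, mode = "undirected")), 0)
  # K3,3: every 4-path has a distinct closing node -> coefficient 1
  expect_equal(net_clustering(bipartite_from_incidence(matrix(1, 3, 3))), 1)
  # a 4-path with no closure -> 0
  Bpath <- matrix(0, 3, 2)
  Bpath[1, 1] <- Bpath[2, 1] <- Bpath[2, 2] <- Bpath[3, 2] <- 1
  expect_warning(cl <- net_clustering(bipartite_from_incidence(Bpath)), NA)
  expect_equal(cl, 0)
  # degree-1 nodes are excluded, not counted as zero: triangle + pendant
  g <- graph_from_pairs(rbind(c(1, 2), c(2, 3), c(1, 3), c(3, 4)), 4)
  loc <- igraph::transitivity(g, type = "local", isolates = "NaN")
  expect_equal(net_clustering(g), mean(loc[igraph::degree(g) >= 2]))
})

test_that("mean shortest path averages reachable pairs and matches a BFS oracle", {
  expect_equal(as.numeric(net_mean_shortest_path(graph_from_pairs(rbind(c(1, 2), c(2, 3)), 3))),
               4 / 3)
  expect_equal(as.numeric(net_mean_shortest_path(igraph::make_full_graph(7))), 1)
  set.seed(3)
  for (rep in 1:10) {
    g <- igraph::sample_gnp(12, 0.25)
    if (igraph::ecount(g) == 0) next
    expect_equal(as.numeric(net_mean_shortest_path(g)), bfs_mean_path(g))
  }
  # disconnected pairs excluded and counted
  g2 <- graph_from_pairs(rbind(c(1, 2)), 3)
  msp <- net_mean_shortest_path(g2)
  expect_equal(as.numeric(msp), 1)
  expect_equal(attr(msp, "n_excluded_pairs"), 2)
})

test_that("nominal assortativity matches the hand mixing-matrix formula", {
  # edges only within classes -> 1
  g <- graph_from_pairs(rbind(c(1, 2), c(3, 4)), 4)
  g <- igraph::set_vertex_attr(g, "age_class", value = c("a", "a", "j", "j"))
  expect_equal(net_assortativity(g), 1)
  # complete bipartite between two equal classes: e_ii = 0, a_i = 0.5 -> -1
  g2 <- igraph::make_full_bipartite_graph(3, 3)
  g2 <- igraph::delete_vertex_attr(g2, "type")
  g2 <- igraph::set_vertex_attr(g2, "age_class", value = rep(c("a", "j"), each = 3))
  expect_equal(net_assortativity(g2), -1)
  # single class -> error
  g3 <- igraph::set_vertex_attr(g, "age_class", value = rep("a", 4))
  expect_error(net_assortativity(g3), "homophily undefined")
  # random graph: r equals (sum e_ii - sum a_i b_i) / (1 - sum a_i b_i)
  set.seed(4)
  g4 <- igraph::sample_gnp(10, 0.4)
  cls <- sample(c("a", "j"), 10, replace = TRUE)
  g4 <- igraph::set_vertex_attr(g4, "age_class", value = cls)
  el <- igraph::as_edgelist(g4, names = FALSE)
  ends <- rbind(cbind(cls[el[, 1]], cls[el[, 2]]), cbind(cls[el[, 2]], cls[el[, 1]]))
  e <- table(factor(ends[, 1], c("a", "j")), factor(ends[, 2], c("a", "j"))) / nrow(ends)
  r_hand <- (sum(diag(e)) - sum(rowSums(e) * colSums(e))) /
    (1 - sum(rowSums(e) * colSums(e)))
  expect_equal(net_assortativity(g4), r_hand)
})

test_that("bounded metrics stay in range on random graphs and identities hold", {
  set.seed(5)
  for (rep in 1:300) {
    n <- sample(5:12, 1)
    g <- igraph::sample_gnp(n, runif(1, 0.15, 0.8))
    d <- net_density(g)
    expect_gte(d, 0); expect_lte(d, 1)
    expect_equal(d, net_mean_degree(g) / (n - 1)) # exact identity
    if (n >= 3) {
      c0 <- net_degree_centralization(g)
      expect_gte(c0, 0); expect_lte(c0, 1)
      cl <- suppressWarnings(net_clustering(g))
      expect_gte(cl, 0); expect_lte(cl, 1)
    }
  }
  for (rep in 1:100) {
    B <- matrix(rbinom(5 * 6, 1, runif(1, 0.2, 0.6)), 5, 6)
    g <- bipartite_from_incidence(B)
    d <- net_density(g)
    expect_equal(d, net_mean_degree(g, "roosts") / 5) # roost mean degree / n_bats
    expect_gte(d, 0); expect_lte(d, 1)
    cl <- suppressWarnings(net_clustering(g))
    expect_gte(cl, 0); expect_lte(cl, 1)
    c2 <- net_degree_centralization(g)
    expect_gte(c2, 0); expect_lte(c2, 1)
  }
})

test_that("metrics are invariant under node relabeling", {
  set.seed(6)
  g <- igraph::sample_gnp(9, 0.4)
  perm <- sample(9)
  gp <- igraph::permute(g, perm)
  expect_equal(net_density(g), net_density(gp))
  expect_equal(net_degree_centralization(g), net_degree_centralization(gp))
  expect_equal(suppressWarnings(net_clustering(g)),
               suppressWarnings(net_clustering(gp)))
  expect_equal(as.numeric(net_mean_shortest_path(g)),
               as.numeric(net_mean_shortest_path(gp)))
})

test_that("network_metrics returns table rows shaped like the study's summaries", {
  col <- generate_colony(fast_config(seed = 81))
  bip <- build_bipartite(col$relocations, col$bats)
  m2 <- network_metrics(bip, "roost_y1")
  expect_named(m2, c("network_id", "kind", "n_bats", "n_roosts", "n_edges",
                     "mean_degree_bats", "mean_degree_roosts", "density",
                     "clustering", "degree_centralization"))
  m1 <- network_metrics(project(bip, "bats"), "social_y1")
  expect_equal(m1$kind, "single-mode")
  expect_true(all(c("modularity_Q", "mean_shortest_path", "homophily_r") %in% names(m1)))
})
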