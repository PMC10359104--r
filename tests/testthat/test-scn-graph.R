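cov_table <- function(df, group = "g", tbv) {
  volume_table(cbind(data.frame(animal_id = sprintf("a%02d", seq_len(nrow(df))),
                                group = group, tbv = tbv), df),
               groups = unique(group))
}

test_that("covariance construction: perfect, negative and degenerate cases", {
  set.seed(8)
  tbv <- runif(10, 900, 1100)
  e <- rnorm(10)
  df <- data.frame(a = 0.10 * tbv + e,
                   b = 0.20 * tbv + 2 * e,      # = 2x the residual of a
                   c = 0.10 * tbv - e,          # anti-correlated residual
                   d = 0.05 * tbv + rnorm(10))
  cv <- build_covariance(cov_table(df, tbv = tbv), "g")
  expect_equal(unname(cv["a", "b"]), 1, tolerance = 1e-10)
  expect_equal(unname(cv["a", "c"]), 0)          # negative correlation removed
  expect_true(all(diag(cv) == 0))
  expect_true(all(cv >= 0 & cv <= 1 + 1e-12))
  expect_identical(cv, t(cv))
  # zero-variance region is named
  df$flat <- 100    # constant volume, zero residual variance
  expect_error(build_covariance(cov_table(df, tbv = tbv), "g"), "flat")
})

test_that("block-structured cohorts yield ordered covariance blocks", {
  co <- generate_cohort(cohort_config(
    n_per_group = c(200L, 4L, 4L), within_community_r = 0.8,
    between_community_r = 0.1, seed = 41))
  cv <- build_covariance(co$volumes, "young")
  comm <- unlist(co$truth$planted_partition)[rownames(cv)]
  same <- outer(comm, comm, "==") & upper.tri(cv)
  diff <- !outer(comm, comm, "==") & upper.tri(cv)
  expect_gt(mean(cv[same]), mean(cv[diff]))
})

test_that("density thresholding keeps the right number of strongest edges", {
  set.seed(9)
  n <- 32
  m <- matrix(runif(n * n, 0.01, 1), n, n)
  m[lower.tri(m)] <- t(m)[lower.tri(m)]
  diag(m) <- 0
  dimnames(m) <- list(sprintf("r%02d", 1:n), sprintf("r%02d", 1:n))
  full <- threshold_at_density(m, 1.0)
  expect_equal(full$k_realized, 496L)            # complete graph
  low <- threshold_at_density(m, 0.05)
  expect_equal(low$k_realized, 25L)              # round(24.8) half-up
  # edges are exactly the top-k correlations
  vals <- sort(m[upper.tri(m)], decreasing = TRUE)
  expect_equal(sort(low$edges$r, decreasing = TRUE), vals[1:25])
  expect_error(threshold_at_density(m, 0), "\\(0, 1\\]")
})

test_that("thresholded edge sets are nested across the density sweep", {
  co <- generate_cohort(cohort_config(seed = 42))
  cv <- build_covariance(co$volumes, "young")
  prev <- character(0)
  for (d in density_grid()) {
    net <- threshold_at_density(cv, d)
    cur <- paste(net$edges$region_a, net$edges$region_b)
    expect_true(all(prev %in% cur))
    expect_lte(abs(net$k_realized - round(d * 496)), 1)
    prev <- cur
  }
})

test_that("a shortfall of positive entries yields all positives plus warning", {
  n <- 10
  m <- matrix(0, n, n, dimnames = list(letters[1:n], letters[1:n]))
  picks <- cbind(1:5, 6:10)
  m[picks] <- seq(0.5, 0.9, length.out = 5)
  m <- pmax(m, t(m))
  expect_warning(net <- threshold_at_density(m, 0.5), "positive entries")
  expect_equal(net$k_realized, 5L)               # only 5 positives exist
  expect_equal(net$k_target, 23)                 # half-up: round(22.5) = 23
})

test_that("correlation ties break deterministically by region-name pair", {
  n <- 6
  m <- matrix(0.5, n, n, dimnames = list(letters[1:n], letters[1:n]))
  diag(m) <- 0
  net <- threshold_at_density(m, 3 / 15)          # 3 of 15 tied edges
  expect_equal(net$edges$region_a, c("a", "a", "a"))
  expect_equal(net$edges$region_b, c("b", "c", "d"))
  expect_identical(threshold_at_density(m, 3 / 15)$adjacency, net$adjacency)
})

test_that("graph metrics match closed forms on canonical graphs", {
  k4 <- net_from_adjacency(matrix(1, 4, 4, dimnames = list(letters[1:4],
                                                           letters[1:4])) -
                             diag(4))
  expect_equal(unname(degree_centrality(k4)), rep(3L, 4))
  expect_equal(network_mean_distance(k4), 1.0)
  expect_equal(network_transitivity(k4), 1.0)
  tri <- matrix(0, 3, 3, dimnames = list(letters[1:3], letters[1:3]))
  tri[cbind(c(1, 2, 1), c(2, 3, 3))] <- 1
  tri <- tri + t(tri)
  expect_equal(unname(degree_centrality(net_from_adjacency(tri))), rep(2L, 3))
  star <- matrix(0, 4, 4, dimnames = list(letters[1:4], letters[1:4]))
  star[1, 2:4] <- 1
  star <- star + t(star)
  expect_equal(unname(degree_centrality(net_from_adjacency(star))),
               c(3L, 1L, 1L, 1L))
  expect_equal(network_transitivity(net_from_adjacency(star)), 0)
  # path graph a-b-c: distances 1, 1, 2 over unordered pairs
  path <- matrix(0, 3, 3, dimnames = list(letters[1:3], letters[1:3]))
  path[cbind(c(1, 2), c(2, 3))] <- 1
  path <- path + t(path)
  expect_equal(network_mean_distance(net_from_adjacency(path)), 4 / 3)
  # two disjoint edges: unreachable pairs excluded
  two <- matrix(0, 4, 4, dimnames = list(letters[1:4], letters[1:4]))
  two[cbind(c(1, 3), c(2, 4))] <- 1
  two <- two + t(two)
  expect_equal(network_mean_distance(net_from_adjacency(two)), 1.0)
})

test_that("modularity matches hand evaluations and handles no-edge graphs", {
  # two disjoint K4 cliques under the true partition: Q = 0.5
  adj <- matrix(0, 8, 8, dimnames = list(letters[1:8], letters[1:8]))
  adj[1:4, 1:4] <- 1
  adj[5:8, 5:8] <- 1
  diag(adj) <- 0
  net <- net_from_adjacency(adj)
  mem <- setNames(rep(1:2, each = 4), letters[1:8])
  expect_equal(network_modularity(net, mem), 0.5)
  expect_equal(network_modularity(net, setNames(rep(1, 8), letters[1:8])), 0)
  empty <- net_from_adjacency(matrix(0, 3, 3,
                                     dimnames = list(letters[1:3],
                                                     letters[1:3])))
  expect_true(is.na(network_modularity(empty, setNames(1:3, letters[1:3]))))
  expect_warning(md <- network_mean_distance(empty), "no edges")
  expect_true(is.na(md))
})

test_that("walktrap finds planted structure and degenerate partitions", {
  # two disjoint triangles
  adj <- matrix(0, 6, 6, dimnames = list(letters[1:6], letters[1:6]))
  adj[1:3, 1:3] <- 1
  adj[4:6, 4:6] <- 1
  diag(adj) <- 0
  wt <- walktrap_communities(net_from_adjacency(adj))
  expect_equal(length(unique(wt$membership)), 2L)
  expect_equal(as.vector(table(wt$membership)), c(3L, 3L))
  expect_equal(wt$Q, 0.5)
  # complete graph: single community, Q = 0
  k5 <- net_from_adjacency(matrix(1, 5, 5, dimnames = list(letters[1:5],
                                                           letters[1:5])) -
                             diag(5))
  wt5 <- walktrap_communities(k5)
  expect_equal(length(unique(wt5$membership)), 1L)
  expect_equal(wt5$Q, 0)
  # isolated node becomes its own singleton community
  iso <- matrix(0, 4, 4, dimnames = list(letters[1:4], letters[1:4]))
  iso[1:3, 1:3] <- 1
  diag(iso) <- 0
  wti <- walktrap_communities(net_from_adjacency(iso))
  expect_equal(sum(wti$membership == wti$membership[["d"]]), 1L)
  # empty network: all singletons, Q = 0, flagged
  empty <- net_from_adjacency(matrix(0, 3, 3,
                                     dimnames = list(letters[1:3],
                                                     letters[1:3])))
  expect_warning(wte <- walktrap_communities(empty), "singleton")
  expect_true(wte$degenerate)
  expect_equal(wte$Q, 0)
  expect_equal(length(unique(wte$membership)), 3L)
})

test_that("walktrap's cut never scores below the all-in-one partition", {
  set.seed(10)
  for (i in 1:20) {
    adj <- random_adjacency(16, runif(1, 0.1, 0.4))
    net <- net_from_adjacency(adj)
    if (net$k_realized == 0L) next
    wt <- suppressWarnings(walktrap_communities(net))
    expect_gte(wt$Q, 0 - 1e-12)
  }
})

test_that("metrics agree with brute force on random graphs", {
  set.seed(11)
  for (i in 1:30) {
    n <- sample(5:32, 1)
    adj <- random_adjacency(n, runif(1, 0.1, 0.6))
    net <- net_from_adjacency(adj)
    expect_identical(unname(degree_centrality(net)), as.integer(bf_degree(adj)))
    expect_equal(network_transitivity(net), bf_transitivity(adj),
                 tolerance = 1e-12)
    md <- suppressWarnings(network_mean_distance(net))
    expect_equal(md, bf_mean_distance(adj), tolerance = 1e-12)
    mem <- sample(1:3, n, replace = TRUE)
    names(mem) <- rownames(adj)
    if (net$k_realized > 0L) {
      expect_equal(network_modularity(net, mem), bf_modularity(adj, mem),
                   tolerance = 1e-12)
    }
  }
})

test_that("metrics are invariant under node relabeling", {
  set.seed(12)
  adj <- random_adjacency(20, 0.25)
  perm <- sample(20)
  padj <- adj[perm, perm]
  net <- net_from_adjacency(adj)
  pnet <- net_from_adjacency(padj)
  expect_equal(sort(unname(degree_centrality(net))),
               sort(unname(degree_centrality(pnet))))
  expect_equal(network_transitivity(net), network_transitivity(pnet))
  expect_equal(network_mean_distance(net), network_mean_distance(pnet))
  mem <- setNames(sample(1:3, 20, replace = TRUE), rownames(adj))
  expect_equal(network_modularity(net, mem),
               network_modularity(pnet, mem[rownames(padj)]))
})

test_that("cartography computes z, P and hub roles from the definitions", {
  # node with all edges inside its community: P = 0
  adj <- matrix(0, 8, 8, dimnames = list(letters[1:8], letters[1:8]))
  adj[1:4, 1:4] <- 1
  adj[5:8, 5:8] <- 1
  diag(adj) <- 0
  net <- net_from_adjacency(adj)
  mem <- setNames(rep(1:2, each = 4), letters[1:8])
  ca <- cartography(net, mem)
  expect_true(all(ca$nodes$participation == 0))
  # z-scores standardized within each community (here all degrees equal -> 0)
  expect_true(all(ca$nodes$z == 0))
  # degree-4 node split 2/2 across two communities: P = 0.5
  adj2 <- matrix(0, 5, 5, dimnames = list(letters[1:5], letters[1:5]))
  adj2[1, 2:5] <- 1
  adj2 <- adj2 + t(adj2)
  mem2 <- setNames(c(1, 1, 1, 2, 2), letters[1:5])
  ca2 <- cartography(net_from_adjacency(adj2), mem2)
  expect_equal(ca2$nodes$participation[1], 0.5)
  expect_equal(ca2$nodes$participation[1],
               bf_participation(adj2, mem2, 1))
})

test_that("clique-plus-bridge cartography: bridge has max P, clique cores max z", {
  # two K5s (nodes 1-5, 6-10) plus bridge node 11 tied to 2 nodes in each
  n <- 11
  nms <- sprintf("n%02d", 1:n)
  adj <- matrix(0, n, n, dimnames = list(nms, nms))
  adj[1:5, 1:5] <- 1
  adj[6:10, 6:10] <- 1
  diag(adj) <- 0
  adj[11, c(1, 2, 6, 7)] <- 1
  adj[c(1, 2, 6, 7), 11] <- 1
  mem <- setNames(c(rep(1, 5), rep(2, 5), 1), nms)
  net <- net_from_adjacency(adj)
  ca <- cartography(net, mem)
  # brute-force P for every node
  p_bf <- vapply(1:n, function(i) bf_participation(adj, mem, i), numeric(1))
  expect_equal(ca$nodes$participation, p_bf)
  expect_equal(which.max(ca$nodes$participation), 11L)
  # within community 1 the bridged clique nodes (1, 2) carry the top z
  z1 <- ca$nodes$z[ca$nodes$community == ca$nodes$community[1]]
  top <- ca$nodes$node[ca$nodes$z == max(z1)]
  expect_setequal(top, c("n01", "n02"))
  # z standardization property within sizeable communities
  for (cc in unique(ca$nodes$community)) {
    zz <- ca$nodes$z[ca$nodes$community == cc]
    if (length(zz) >= 2 && sd(ca$nodes$within_degree[
      ca$nodes$community == cc]) > 0) {
      expect_equal(mean(zz), 0, tolerance = 1e-12)
      expect_equal(sd(zz), 1, tolerance = 1e-12)
    }
  }
})

test_that("hub labels respect the configured thresholds", {
  n <- 11
  nms <- sprintf("n%02d", 1:n)
  adj <- matrix(0, n, n, dimnames = list(nms, nms))
  adj[1:5, 1:5] <- 1
  adj[6:10, 6:10] <- 1
  diag(adj) <- 0
  adj[11, c(1, 2, 6, 7)] <- 1
  adj[c(1, 2, 6, 7), 11] <- 1
  mem <- setNames(c(rep(1, 5), rep(2, 5), 1), nms)
  ca <- cartography(net_from_adjacency(adj), mem,
                    z_hub_min = 0.5, p_connector_min = 0.30)
  nodes <- ca$nodes
  expect_true(all(nodes$hub[nodes$z >= 0.5 & nodes$participation >= 0.3] ==
                    "connector"))
  expect_true(all(nodes$hub[nodes$z >= 0.5 & nodes$participation < 0.3] ==
                    "provincial"))
  expect_true(all(nodes$hub[nodes$z < 0.5] == "none"))
})
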