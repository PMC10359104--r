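#' Build a group's structural covariance matrix
#'
#' Pearson correlation, between every pair of regions, of the
#' TBV-residualized volumes of the animals in one age group. The TBV
#' adjustment is fit on the full table passed in (it is label-free), the
#' correlation on the group's animals only. Negative correlations are set
#' to zero — the resulting matrix is "unweighted and unsigned ready":
#' zeroed entries can never become edges — and the diagonal is zero.
#'
#' @param table a [volume_table()] (all animals the residualization
#'   should pool over, typically the two groups being compared or the
#'   full cohort).
#' @param group the group label whose animals are correlated.
#' @return symmetric regions x regions matrix of class
#'   `covariance_matrix` with attributes `group` and `n_animals`.
#' @export
build_covariance <- function(table, group) {
  stopifnot(inherits(table, "volume_table"))
  if (!group %in% levels(table$group)) stop("unknown group: ", group)
  in_group <- as.character(table$group) == group
  if (sum(in_group) < 4L) stop("group '", group, "' has < 4 animals")
  raw <- as.matrix(as.data.frame(table)[regions(table)])[in_group, ,
                                                         drop = FALSE]
  sds <- apply(raw, 2L, sd)
  res <- residualize_on_tbv(table)[in_group, , drop = FALSE]
  # a region constant within the group (or exactly proportional to TBV)
  # has no residual variance to correlate
  degenerate <- sds == 0 | apply(res, 2L, sd) <= 1e-10 * pmax(sds, 1e-300)
  if (any(degenerate)) {
    stop("zero-variance region(s) within group '", group, "': ",
         paste(colnames(res)[degenerate], collapse = ", "))
  }
  r <- cor(res)
  r[r < 0] <- 0
  diag(r) <- 0
  structure(r, group = group, n_animals = sum(in_group),
            class = c("covariance_matrix", "matrix"))
}

# --- shared edge machinery -------------------------------------------------
# upper-triangle pair bookkeeping for a fixed region order, including the
# deterministic tie-break rank: ties at the correlation boundary are broken
# by the lexicographic order of the (alphabetically sorted) region-name pair
pair_index <- function(region_names) {
  n <- length(region_names)
  ui <- rep(seq_len(n - 1L), times = (n - 1L):1L)
  uj <- sequence((n - 1L):1L) + ui
  a <- region_names[ui]
  b <- region_names[uj]
  lo <- pmin(a, b)
  hi <- pmax(a, b)
  rank_lex <- integer(length(ui))
  rank_lex[order(lo, hi)] <- seq_along(ui)
  list(ui = ui, uj = uj, rank_lex = rank_lex, n = n)
}

# indices (into the upper-triangle vectors) of the k strongest positive
# entries, half-up rounding and lexicographic tie-break; attribute
# "shortfall" carries the number of missing edges when positives run out
top_edges <- function(rvec, k, pidx) {
  ord <- order(-rvec, pidx$rank_lex)
  ord <- ord[rvec[ord] > 0]
  k_eff <- min(k, length(ord))
  structure(ord[seq_len(k_eff)], shortfall = k - k_eff)
}

round_half_up <- function(x) floor(x + 0.5)

#' Threshold a covariance matrix at a target edge density
#'
#' Keeps the `k = round(density * n(n-1)/2)` strongest positive
#' correlations as unweighted, undirected edges (half-up rounding;
#' density 0.05 on 32 regions gives `round(24.8) = 25` edges). Ties at
#' the boundary are broken by lexicographic region-name-pair order, so
#' the edge set is deterministic and nested across densities. If fewer
#' positive entries exist than requested, the network is built from all
#' of them and a warning records the shortfall.
#'
#' @param cov a [build_covariance()] matrix.
#' @param density fraction of all possible edges to retain, in `(0, 1]`.
#' @return list of class `scn_network`: `adjacency` (binary symmetric),
#'   `edges` (data.frame region_a, region_b, r), `density`, `k_target`,
#'   `k_realized`, `group`.
#' @export
threshold_at_density <- function(cov, density) {
  stopifnot(is.matrix(cov), nrow(cov) == ncol(cov))
  if (!(density > 0 && density <= 1)) stop("density must lie in (0, 1]")
  rn <- rownames(cov)
  pidx <- pair_index(rn)
  rvec <- cov[cbind(pidx$ui, pidx$uj)]
  k <- round_half_up(density * length(rvec))
  sel <- top_edges(rvec, k, pidx)
  if (attr(sel, "shortfall") > 0L) {
    warning(sprintf(paste0("only %d positive entries available for %d ",
                           "requested edges (density %.2f): network built ",
                           "from all positives"),
                    length(sel), k, density))
  }
  adj <- matrix(0L, pidx$n, pidx$n, dimnames = list(rn, rn))
  adj[cbind(pidx$ui[sel], pidx$uj[sel])] <- 1L
  adj <- adj + t(adj)
  structure(list(adjacency = adj,
                 edges = data.frame(region_a = rn[pidx$ui[sel]],
                                    region_b = rn[pidx$uj[sel]],
                                    r = rvec[sel], stringsAsFactors = FALSE),
                 density = density, k_target = k, k_realized = length(sel),
                 group = attr(cov, "group", exact = TRUE)),
            class = "scn_network")
}

#' @export
print.scn_network <- function(x, ...) {
  cat(sprintf("scn_network: %d nodes, %d edges (density %.2f%s)\n",
              nrow(x$adjacency), x$k_realized, x$density,
              if (is.null(x$group)) "" else paste0(", group ", x$group)))
  invisible(x)
}

#' Convert a thresholded network to an igraph graph
#' @param net an `scn_network`.
#' @return an undirected igraph graph with one vertex per region.
#' @export
as_igraph <- function(net) {
  stopifnot(inherits(net, "scn_network"))
  igraph::graph_from_adjacency_matrix(net$adjacency, mode = "undirected")
}

#' Degree centrality
#'
#' Per-node edge count — the node-level "interconnectedness" statistic
#' compared between groups across the density sweep.
#'
#' @param net an `scn_network`.
#' @return named integer vector, one entry per region.
#' @export
degree_centrality <- function(net) {
  g <- as_igraph(net)
  deg <- igraph::degree(g)
  storage.mode(deg) <- "integer"
  deg
}

#' Mean shortest-path distance
#'
#' Average geodesic length over all reachable node pairs (unreachable
#' pairs are excluded rather than counted as infinite, keeping the
#' statistic finite on sparse low-density networks). `NA` with a warning
#' when the network has no edges.
#'
#' @param net an `scn_network`.
#' @return nonnegative real, or `NA` for an empty network.
#' @export
network_mean_distance <- function(net) {
  if (net$k_realized == 0L) {
    warning("network has no edges: mean distance undefined")
    return(NA_real_)
  }
  igraph::mean_distance(as_igraph(net), directed = FALSE, unconnected = TRUE)
}

#' Global transitivity
#'
#' 3 x triangles / connected triples; 0 when the network has no
#' connected triples.
#'
#' @param net an `scn_network`.
#' @return real in `[0, 1]`.
#' @export
network_transitivity <- function(net) {
  tr <- igraph::transitivity(as_igraph(net), type = "global")
  if (is.nan(tr)) 0 else tr
}

#' Newman-Girvan modularity of a partition
#'
#' `Q = sum_c [ e_c / m - (d_c / 2m)^2 ]` over communities c, with m
#' edges, e_c intra-community edges and d_c the community degree sum.
#' `NA` (reported missing) when the network has no edges.
#'
#' @param net an `scn_network`.
#' @param membership named community ids covering every node.
#' @return real in `[-0.5, 1]`, or `NA` for an empty network.
#' @export
network_modularity <- function(net, membership) {
  stopifnot(length(membership) == nrow(net$adjacency))
  if (net$k_realized == 0L) return(NA_real_)
  if (!is.null(names(membership))) {
    membership <- membership[rownames(net$adjacency)]
  }
  igraph::modularity(as_igraph(net), as.integer(factor(membership)))
}

#' Walktrap community detection
#'
#' Random-walk agglomerative communities (Pons-Latapy): node distances
#' from `steps`-step transition probabilities, Ward-style agglomeration,
#' partition cut at maximum modularity. Isolated nodes become singleton
#' communities. Deterministic given the adjacency and `steps`.
#'
#' @param net an `scn_network` (at least one edge for a meaningful
#'   partition; an empty network yields all-singletons with Q = 0 and a
#'   warning).
#' @param steps random-walk length (default 4).
#' @return list of class `walktrap_partition`: `membership` (named
#'   integer), `Q` (modularity of the chosen cut), `steps`, `degenerate`.
#' @export
walktrap_communities <- function(net, steps = 4L) {
  stopifnot(inherits(net, "scn_network"), steps >= 1L)
  rn <- rownames(net$adjacency)
  if (net$k_realized == 0L) {
    warning("empty network: every node a singleton community, Q = 0")
    return(structure(list(membership = setNames(seq_along(rn), rn),
                          Q = 0, steps = steps, degenerate = TRUE),
                     class = "walktrap_partition"))
  }
  g <- as_igraph(net)
  deg <- igraph::degree(g)
  isolated <- which(deg == 0)
  if (length(isolated) > 0L) {
    sub <- igraph::delete_vertices(g, isolated)
    wt <- igraph::cluster_walktrap(sub, steps = steps)
    membership <- integer(length(rn))
    membership[-isolated] <- igraph::membership(wt)
    membership[isolated] <- max(igraph::membership(wt)) + seq_along(isolated)
  } else {
    wt <- igraph::cluster_walktrap(g, steps = steps)
    membership <- as.integer(igraph::membership(wt))
  }
  names(membership) <- rn
  structure(list(membership = membership,
                 Q = igraph::modularity(g, membership),
                 steps = steps, degenerate = FALSE),
            class = "walktrap_partition")
}

#' Community cartography: hub roles from z and P
#'
#' For a given partition, computes each node's within-community degree
#' z-score `z_i` (its link count into its own community, standardized
#' over that community; 0 when the community SD is zero or the community
#' is a singleton) and participation coefficient
#' `P_i = 1 - sum_c (k_ic / k_i)^2` (0 for isolated nodes). Nodes with
#' `z >= z_hub_min` are hubs: provincial when `P < p_connector_min`
#' (within-community integrators), connector when `P >= p_connector_min`
#' (between-community integrators). The thresholds are conventions, not
#' estimates — defaults follow the functional-cartography literature and
#' are always reported in the output. Per community, the "most
#' prominent" provincial hub is the one with the highest z and the most
#' prominent connector hub the one with the highest P.
#'
#' @param net an `scn_network`.
#' @param membership named community ids (e.g. from
#'   [walktrap_communities()]`$membership`); default recomputed by
#'   Walktrap.
#' @param z_hub_min hub threshold on z (default 1.0).
#' @param p_connector_min connector threshold on P (default 0.30).
#' @return list of class `community_cartography`: `nodes` (data.frame
#'   node, community, degree, within_degree, z, participation, hub),
#'   `Q`, `most_prominent`, `z_hub_min`, `p_connector_min`.
#' @export
cartography <- function(net, membership = NULL, z_hub_min = 1.0,
                        p_connector_min = 0.30) {
  stopifnot(inherits(net, "scn_network"))
  adj <- net$adjacency
  rn <- rownames(adj)
  if (is.null(membership)) {
    membership <- walktrap_communities(net)$membership
  }
  if (!is.null(names(membership))) membership <- membership[rn]
  if (anyNA(membership)) stop("membership must cover all nodes")
  comm <- as.integer(factor(membership))
  k <- rowSums(adj)

  # links from each node into each community
  k_ic <- vapply(sort(unique(comm)), function(cc) {
    rowSums(adj[, comm == cc, drop = FALSE])
  }, numeric(length(rn)))
  within_deg <- k_ic[cbind(seq_along(rn), comm)]

  z <- numeric(length(rn))
  for (cc in unique(comm)) {
    idx <- which(comm == cc)
    s <- sd(within_deg[idx])
    z[idx] <- if (length(idx) < 2L || is.na(s) || s == 0) 0 else
      (within_deg[idx] - mean(within_deg[idx])) / s
  }
  p <- ifelse(k == 0, 0, 1 - rowSums((k_ic / pmax(k, 1))^2))

  hub <- rep("none", length(rn))
  hub[z >= z_hub_min & p < p_connector_min] <- "provincial"
  hub[z >= z_hub_min & p >= p_connector_min] <- "connector"

  nodes <- data.frame(node = rn, community = comm, degree = k,
                      within_degree = within_deg, z = z, participation = p,
                      hub = hub, stringsAsFactors = FALSE)
  prominent <- do.call(rbind, lapply(split(nodes, nodes$community), function(d) {
    out <- d[0, ]
    prov <- d[d$hub == "provincial", ]
    conn <- d[d$hub == "connector", ]
    if (nrow(prov) > 0L) out <- rbind(out, prov[which.max(prov$z), ])
    if (nrow(conn) > 0L) out <- rbind(out, conn[which.max(conn$participation), ])
    out
  }))
  rownames(prominent) <- NULL
  structure(list(nodes = nodes,
                 Q = network_modularity(net, membership),
                 most_prominent = prominent,
                 z_hub_min = z_hub_min, p_connector_min = p_connector_min),
            class = "community_cartography")
}

#' @export
print.community_cartography <- function(x, ...) {
  cat(sprintf("community_cartography: %d nodes, %d communities, Q = %.3f\n",
              nrow(x$nodes), length(unique(x$nodes$community)),
              if (is.na(x$Q)) NA else x$Q))
  cat(sprintf("hubs (z >= %.2f, P split at %.2f): %d provincial, %d connector\n",
              x$z_hub_min, x$p_connector_min,
              sum(x$nodes$hub == "provincial"), sum(x$nodes$hub == "connector")))
  if (nrow(x$most_prominent) > 0L) {
    print(x$most_prominent[c("node", "community", "z", "participation", "hub")],
          ...)
  }
  invisible(x)
}

#' Write a covariance or adjacency matrix as delimited text
#'
#' Square matrix with a region-name header row and column.
#'
#' @param m matrix with region dimnames.
#' @param path output file.
#' @param sep field separator (default comma).
#' @return `path`, invisibly.
#' @export
write_matrix <- function(m, path, sep = ",") {
  write.table(as.matrix(m), path, sep = sep, col.names = NA, quote = FALSE)
  invisible(path)
}
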