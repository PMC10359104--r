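# Brute-force reference implementations, independent of the package (and of
# igraph): used as oracles for the graph metrics, Holm correction and
# alternation scoring.

# Erdos-Renyi-ish random adjacency matrix with named nodes
random_adjacency <- function(n, p_edge = 0.2) {
  a <- matrix(0L, n, n)
  a[upper.tri(a)] <- as.integer(runif(n * (n - 1) / 2) < p_edge)
  a <- a + t(a)
  dimnames(a) <- list(sprintf("r%02d", seq_len(n)), sprintf("r%02d", seq_len(n)))
  a
}

# wrap a bare adjacency matrix as the package's network object
net_from_adjacency <- function(adj, density = NA_real_) {
  ut <- which(upper.tri(adj) & adj == 1, arr.ind = TRUE)
  structure(list(adjacency = adj,
                 edges = data.frame(region_a = rownames(adj)[ut[, 1]],
                                    region_b = colnames(adj)[ut[, 2]],
                                    r = rep(NA_real_, nrow(ut)),
                                    stringsAsFactors = FALSE),
                 density = density, k_target = nrow(ut), k_realized = nrow(ut),
                 group = NULL),
            class = "scn_network")
}

bf_degree <- function(adj) rowSums(adj)

# enumerate all node triples: transitivity = 3 * closed / connected triples
bf_transitivity <- function(adj) {
  n <- nrow(adj)
  if (n < 3L) return(0)
  tri <- utils::combn(n, 3L)
  e12 <- adj[cbind(tri[1, ], tri[2, ])]
  e13 <- adj[cbind(tri[1, ], tri[3, ])]
  e23 <- adj[cbind(tri[2, ], tri[3, ])]
  closed <- sum(e12 * e13 * e23)
  triples <- sum(e12 * e13 + e12 * e23 + e13 * e23)
  if (triples == 0) 0 else 3 * closed / triples
}

# BFS shortest paths from every node; average over reachable ordered pairs
bf_mean_distance <- function(adj) {
  n <- nrow(adj)
  total <- 0
  count <- 0L
  for (s in seq_len(n)) {
    dist <- rep(NA_integer_, n)
    dist[s] <- 0L
    frontier <- s
    while (length(frontier) > 0L) {
      nxt <- integer(0)
      for (v in frontier) {
        for (w in which(adj[v, ] == 1L)) {
          if (is.na(dist[w])) {
            dist[w] <- dist[v] + 1L
            nxt <- c(nxt, w)
          }
        }
      }
      frontier <- nxt
    }
    reach <- dist[-s]
    total <- total + sum(reach, na.rm = TRUE)
    count <- count + sum(!is.na(reach))
  }
  if (count == 0L) NA_real_ else total / count
}

# explicit double sum over node pairs
bf_modularity <- function(adj, membership) {
  m <- sum(adj) / 2
  if (m == 0) return(NA_real_)
  k <- rowSums(adj)
  q <- 0
  n <- nrow(adj)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (membership[i] == membership[j]) {
        q <- q + adj[i, j] - k[i] * k[j] / (2 * m)
      }
    }
  }
  unname(q / (2 * m))
}

# explicit step-down: sort, multiply, running max, cap
bf_holm <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- p[o] * (m - seq_len(m) + 1)
  adj <- cummax(adj)
  adj <- pmin(adj, 1)
  out <- numeric(m)
  out[o] <- adj
  out
}

bf_alternations <- function(choices) {
  ch <- strsplit(choices, "")[[1]]
  sum(ch[-1] != ch[-length(ch)])
}

# participation coefficient / within-community degree straight from the
# definitions, one node at a time
bf_participation <- function(adj, membership, i) {
  k <- sum(adj[i, ])
  if (k == 0) return(0)
  1 - sum(vapply(unique(membership), function(cc) {
    (sum(adj[i, membership == cc]) / k)^2
  }, numeric(1)))
}

# a small null cohort (no planted group effects) used by several tests
null_cohort <- function(seed, n_per_group = c(10L, 10L, 9L), ...) {
  generate_cohort(cohort_config(n_per_group = n_per_group, seed = seed, ...))
}

behavior_from_scores <- function(scores) {
  data.frame(animal_id = scores$animal_id,
             successes = scores$n_alternations,
             trials = scores$n_scorable)
}
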