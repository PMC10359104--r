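#' Density grid for the network sweep
#'
#' Densities 0.05 to 0.40 in steps of 0.01 (36 values) by default,
#' computed on an integer grid so the values are exact.
#'
#' @param min,max,step grid limits and increment (fractions of all
#'   possible edges).
#' @return strictly increasing numeric vector.
#' @export
density_grid <- function(min = 0.05, max = 0.40, step = 0.01) {
  stopifnot(min > 0, max <= 1, step > 0, min <= max)
  seq(round(min * 100), round(max * 100), by = round(step * 100)) / 100
}

#' Group-label permutations
#'
#' Draws `n_perm` reshuffles of the animals' group labels within the
#' pooled two-group sample, preserving the group sizes. Downstream, each
#' relabeling is pushed through the identical pipeline as the observed
#' data (correlation, negative removal, thresholding, metric), and one
#' relabeling drives one full density sweep so cross-density dependence
#' is preserved.
#'
#' @param table a [volume_table()].
#' @param groups character vector of the two group labels.
#' @param n_perm number of permutations (>= 1).
#' @param seed RNG seed; a fixed seed gives an identical permutation
#'   sequence across runs.
#' @return list: `table` (the pooled two-group subset), `observed`
#'   (its labels), `labels` (n_perm x n_animals character matrix of
#'   relabelings).
#' @export
permute_groups <- function(table, groups, n_perm, seed = 1L) {
  stopifnot(inherits(table, "volume_table"), length(groups) == 2L,
            n_perm >= 1L)
  sub <- table[as.character(table$group) %in% groups, , drop = FALSE]
  n <- nrow(sub)
  if (n < 8L) {
    stop("pooled two-group sample has ", n,
         " animals (< 8): correlations unstable")
  }
  obs <- as.character(sub$group)
  set.seed(seed)
  labels <- t(vapply(seq_len(n_perm), function(i) sample(obs),
                     character(n)))
  list(table = sub, observed = obs, labels = labels)
}

#' Empirical two-tailed permutation p-value
#'
#' Add-one rule on absolute differences:
#' `p = (1 + #\{|null| >= |observed|\}) / (1 + N)`, which can never reach
#' zero. Missing null draws (degenerate networks) are dropped with N
#' reduced; if every null is missing the p-value is undefined (`NA`,
#' treated as non-significant by the run rule).
#'
#' @param observed observed group difference (finite scalar).
#' @param null_sample numeric vector of permutation-null differences.
#' @return p in `(0, 1]`, or `NA` if no usable nulls remain.
#' @export
empirical_p <- function(observed, null_sample) {
  if (length(null_sample) == 0L) stop("null_sample is empty")
  if (!is.finite(observed)) stop("observed must be finite")
  nulls <- null_sample[is.finite(null_sample)]
  if (length(nulls) == 0L) return(NA_real_)
  (1 + sum(abs(nulls) >= abs(observed))) / (1 + length(nulls))
}

#' Consecutive-density significance rule
#'
#' A profile is significant only when its per-density p-values fall below
#' `alpha` at `run_min` or more adjacent densities — a family-wise
#' criterion that exploits the positive dependence of neighbouring
#' densities. Undefined p-values (`NA`) break runs.
#'
#' @param p_values p-values ordered by density.
#' @param alpha per-density level (default 0.05).
#' @param run_min minimum run length (default 5).
#' @param densities optional density values used to label the runs.
#' @return list: `significant` (logical) and `runs`, a data.frame of all
#'   maximal qualifying runs with from/to indices (and densities when
#'   given).
#' @export
consecutive_run_rule <- function(p_values, alpha = 0.05, run_min = 5L,
                                 densities = NULL) {
  if (length(p_values) == 0L) stop("empty p-value vector")
  if (!is.null(densities)) stopifnot(length(densities) == length(p_values))
  below <- !is.na(p_values) & p_values < alpha
  r <- rle(below)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values & r$lengths >= run_min
  runs <- data.frame(from = starts[keep], to = ends[keep],
                     length = r$lengths[keep])
  if (!is.null(densities) && nrow(runs) > 0L) {
    runs$density_from <- densities[runs$from]
    runs$density_to <- densities[runs$to]
  }
  list(significant = nrow(runs) > 0L, runs = runs)
}

# --- density-sweep statistic engine ---------------------------------------

# per-group statistic across all densities from a residual matrix subset;
# 'metric' is one of degree / modularity / transitivity / mean_distance.
# Returns densities x nodes matrix for degree, densities-length vector
# otherwise. NA correlations (possible only in degenerate permuted
# subgroups) are treated as non-edges.
sweep_group_stat <- function(res_rows, metric, ks, pidx, walktrap_steps) {
  r <- cor(res_rows)
  rvec <- r[cbind(pidx$ui, pidx$uj)]
  rvec[is.na(rvec) | rvec < 0] <- 0
  ord <- order(-rvec, pidx$rank_lex)
  ord <- ord[rvec[ord] > 0]
  n <- pidx$n
  if (metric == "degree") {
    out <- matrix(NA_real_, length(ks), n)
    for (d in seq_along(ks)) {
      idx <- ord[seq_len(min(ks[d], length(ord)))]
      out[d, ] <- tabulate(c(pidx$ui[idx], pidx$uj[idx]), nbins = n)
    }
    return(out)
  }
  if (metric == "transitivity") {
    # adjacency-algebra fast path: tr(A^3) / sum_i k_i (k_i - 1)
    out <- numeric(length(ks))
    adj <- matrix(0, n, n)
    prev <- integer(0)
    for (d in seq_along(ks)) {
      idx <- ord[seq_len(min(ks[d], length(ord)))]
      new <- setdiff(idx, prev)
      adj[cbind(pidx$ui[new], pidx$uj[new])] <- 1
      adj[cbind(pidx$uj[new], pidx$ui[new])] <- 1
      prev <- idx
      k <- rowSums(adj)
      triples2 <- sum(k * (k - 1))
      out[d] <- if (triples2 == 0) 0 else sum(adj * (adj %*% adj)) / triples2
    }
    return(out)
  }
  out <- numeric(length(ks))
  for (d in seq_along(ks)) {
    idx <- ord[seq_len(min(ks[d], length(ord)))]
    if (length(idx) == 0L) {
      out[d] <- NA_real_
      next
    }
    g <- igraph::make_graph(rbind(pidx$ui[idx], pidx$uj[idx]), n = n,
                            directed = FALSE)
    out[d] <- switch(metric,
      mean_distance = igraph::mean_distance(g, directed = FALSE,
                                            unconnected = TRUE),
      modularity = {
        deg <- igraph::degree(g)
        gg <- g
        iso <- which(deg == 0)
        if (length(iso) > 0L) gg <- igraph::delete_vertices(g, iso)
        wt <- igraph::cluster_walktrap(gg, steps = walktrap_steps)
        mem <- integer(n)
        if (length(iso) > 0L) {
          mem[-iso] <- igraph::membership(wt)
          mem[iso] <- max(igraph::membership(wt)) + seq_along(iso)
        } else {
          mem <- as.integer(igraph::membership(wt))
        }
        igraph::modularity(g, mem)
      },
      stop("unknown metric: ", metric))
  }
  out
}

#' Permutation comparison of a network metric across the density sweep
#'
#' The full group-comparison pipeline for one metric: TBV-residualize the
#' pooled two-group sample once (the adjustment is label-free), build
#' each group's covariance matrix, remove negative correlations,
#' threshold across the density grid, and take the group difference
#' (first group minus second) of the metric at every density. The same
#' pipeline is re-run on `n_perm` group-label permutations — one
#' relabeling drives one full density sweep — giving per-density
#' empirical two-tailed p-values ([empirical_p()]) and the
#' consecutive-density significance rule ([consecutive_run_rule()]).
#' Modularity is recomputed per relabeling with a fresh Walktrap
#' partition (the statistic is "max-modularity of the relabeled
#' network").
#'
#' @param table a [volume_table()] containing both groups.
#' @param groups the two group labels, younger first; differences are
#'   `groups[1]` minus `groups[2]`.
#' @param metric one of `"degree"`, `"modularity"`, `"transitivity"`,
#'   `"mean_distance"`.
#' @param nodes for `"degree"`, the region(s) whose profiles to return
#'   (default all regions); ignored for global metrics.
#' @param densities density grid (default [density_grid()]).
#' @param n_perm number of permutations (5000 for a-priori/global
#'   analyses, 1000 for brain-wide degree in the reference design).
#' @param alpha per-density significance level.
#' @param run_min minimum consecutive-density run length.
#' @param seed RNG seed for the permutation stream.
#' @param walktrap_steps walk length for modularity re-partitioning.
#' @return a `density_profile` (global metrics, or degree at a single
#'   node) or a named list of them with class `density_profile_list`
#'   (degree at several nodes).
#' @export
compare_metric <- function(table, groups,
                           metric = c("degree", "modularity",
                                      "transitivity", "mean_distance"),
                           nodes = NULL, densities = density_grid(),
                           n_perm = 1000L, alpha = 0.05, run_min = 5L,
                           seed = 1L, walktrap_steps = 4L) {
  metric <- match.arg(metric)
  stopifnot(all(diff(densities) > 0), run_min <= length(densities))
  perms <- permute_groups(table, groups, n_perm, seed)
  sub <- perms$table
  res <- residualize_on_tbv(sub)
  rn <- colnames(res)
  pidx <- pair_index(rn)
  n_pairs <- length(pidx$ui)
  ks <- round_half_up(densities * n_pairs)

  if (metric == "degree") {
    if (is.null(nodes)) nodes <- rn
    bad <- setdiff(nodes, rn)
    if (length(bad) > 0L) stop("unknown node(s): ", paste(bad, collapse = ", "))
  }

  stat_diff <- function(labels) {
    a <- sweep_group_stat(res[labels == groups[1L], , drop = FALSE],
                          metric, ks, pidx, walktrap_steps)
    b <- sweep_group_stat(res[labels == groups[2L], , drop = FALSE],
                          metric, ks, pidx, walktrap_steps)
    a - b
  }

  observed <- stat_diff(perms$observed)
  nulls <- lapply(seq_len(n_perm), function(i) stat_diff(perms$labels[i, ]))

  make_profile <- function(obs_vec, null_mat, node_label) {
    p <- vapply(seq_along(densities), function(d) {
      if (!is.finite(obs_vec[d])) return(NA_real_)
      empirical_p(obs_vec[d], null_mat[, d])
    }, numeric(1L))
    rr <- consecutive_run_rule(p, alpha, run_min, densities)
    structure(list(metric = metric, node = node_label, groups = groups,
                   densities = densities, observed_diff = obs_vec,
                   null_diffs = null_mat, p = p,
                   significant = rr$significant, runs = rr$runs,
                   alpha = alpha, run_min = run_min, n_perm = n_perm,
                   seed = seed),
              class = "density_profile")
  }

  if (metric == "degree") {
    cols <- match(nodes, rn)
    profiles <- lapply(seq_along(nodes), function(j) {
      null_mat <- t(vapply(nulls, function(m) m[, cols[j]],
                           numeric(length(densities))))
      make_profile(observed[, cols[j]], null_mat, nodes[j])
    })
    names(profiles) <- nodes
    if (length(profiles) == 1L) return(profiles[[1L]])
    return(structure(profiles, class = "density_profile_list"))
  }
  null_mat <- do.call(rbind, nulls)
  make_profile(observed, null_mat, "global")
}

#' @export
print.density_profile <- function(x, ...) {
  cat(sprintf("density_profile: %s (%s), %s vs %s, %d permutations\n",
              x$metric, x$node, x$groups[1L], x$groups[2L], x$n_perm))
  if (x$significant) {
    iv <- sprintf("%d-%d%% density", round(100 * x$runs$density_from),
                  round(100 * x$runs$density_to))
    cat("significant (p <", x$alpha, "at >=", x$run_min,
        "consecutive densities):", paste(iv, collapse = ", "), "\n")
  } else {
    cat("not significant under the consecutive-density rule\n")
  }
  invisible(x)
}

#' @export
print.density_profile_list <- function(x, ...) {
  cat(sprintf("density_profile_list: %d nodes (%s)\n", length(x),
              x[[1L]]$metric))
  for (pr in x) {
    if (pr$significant) print(pr)
  }
  invisible(x)
}

#' Long-format view of a density profile
#'
#' @param x a `density_profile`.
#' @param ... unused.
#' @return data.frame: metric, node, density, observed_diff, p,
#'   in_significant_run.
#' @export
as.data.frame.density_profile <- function(x, ...) {
  in_run <- rep(FALSE, length(x$densities))
  if (nrow(x$runs) > 0L) {
    for (i in seq_len(nrow(x$runs))) {
      in_run[x$runs$from[i]:x$runs$to[i]] <- TRUE
    }
  }
  data.frame(metric = x$metric, node = x$node, density = x$densities,
             observed_diff = x$observed_diff, p = x$p,
             in_significant_run = in_run, stringsAsFactors = FALSE)
}

#' @export
as.data.frame.density_profile_list <- function(x, ...) {
  do.call(rbind, c(lapply(x, as.data.frame), list(make.row.names = FALSE)))
}

#' Summary of significant profiles
#'
#' The machine-readable companion of the density-profile tables: every
#' node (or global metric) whose profile satisfies the run rule, with its
#' significant density interval(s).
#'
#' @param profiles a `density_profile` or `density_profile_list`.
#' @return data.frame: metric, node, density_from, density_to,
#'   run_length (zero rows when nothing is significant).
#' @export
significant_profiles <- function(profiles) {
  if (inherits(profiles, "density_profile")) profiles <- list(profiles)
  out <- do.call(rbind, lapply(profiles, function(pr) {
    if (!pr$significant) return(NULL)
    data.frame(metric = pr$metric, node = pr$node,
               density_from = pr$runs$density_from,
               density_to = pr$runs$density_to,
               run_length = pr$runs$length, stringsAsFactors = FALSE)
  }))
  if (is.null(out)) {
    out <- data.frame(metric = character(), node = character(),
                      density_from = numeric(), density_to = numeric(),
                      run_length = integer(), stringsAsFactors = FALSE)
  }
  rownames(out) <- NULL
  out
}
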