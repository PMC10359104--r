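#' Average fine-region volumes across hemispheres
#'
#' Hemisphere-tagged columns are named `"<region>_left"` and
#' `"<region>_right"`; each pair is replaced by a single bilateral column
#' holding the arithmetic mean of the two. Untagged columns pass through
#' unchanged. Minimizes the multiple-testing burden before reduction to
#' ROIs.
#'
#' @param table a [volume_table()] whose region columns may carry
#'   hemisphere suffixes.
#' @return a `volume_table` with one column per bilateral region.
#' @export
average_hemispheres <- function(table) {
  stopifnot(inherits(table, "volume_table"))
  regs <- regions(table)
  is_left <- grepl("_left$", regs)
  is_right <- grepl("_right$", regs)
  base_left <- sub("_left$", "", regs[is_left])
  base_right <- sub("_right$", "", regs[is_right])
  orphans <- c(setdiff(base_left, base_right), setdiff(base_right, base_left))
  if (length(orphans) > 0L) {
    stop("region(s) present in only one hemisphere: ",
         paste(sort(orphans), collapse = ", "))
  }
  untagged <- regs[!is_left & !is_right]
  bilateral <- sort(unique(base_left))
  out <- table[c("animal_id", "group", "tbv")]
  out <- as.data.frame(out)
  for (rg in bilateral) {
    out[[rg]] <- (table[[paste0(rg, "_left")]] +
                    table[[paste0(rg, "_right")]]) / 2
  }
  for (rg in untagged) out[[rg]] <- table[[rg]]
  volume_table(out, regions = c(bilateral, untagged),
               groups = levels(table$group))
}

#' Reduce fine regions to ROIs through a hierarchy
#'
#' Each ROI volume is the sum of its member fine-region volumes, so total
#' measured volume is conserved. The hierarchy must cover every fine
#' region present in the input.
#'
#' @param table a [volume_table()] at fine-region granularity.
#' @param hierarchy a [read_roi_hierarchy()] table (default the shipped
#'   32-ROI mapping).
#' @return a `volume_table` whose region columns are exactly the
#'   hierarchy's ROI list.
#' @export
reduce_to_rois <- function(table, hierarchy = default_roi_hierarchy()) {
  stopifnot(inherits(table, "volume_table"))
  regs <- regions(table)
  unmapped <- setdiff(regs, hierarchy$fine_region)
  if (length(unmapped) > 0L) {
    stop("fine region(s) not mapped by the hierarchy: ",
         paste(unmapped, collapse = ", "))
  }
  rois <- unique(hierarchy$roi)
  out <- as.data.frame(table[c("animal_id", "group", "tbv")])
  for (roi in rois) {
    members <- intersect(hierarchy$fine_region[hierarchy$roi == roi], regs)
    if (length(members) == 0L) next
    out[[roi]] <- rowSums(as.matrix(as.data.frame(table)[members]))
  }
  volume_table(out, regions = setdiff(names(out), c("animal_id", "group", "tbv")),
               groups = levels(table$group))
}

#' Residualize a region's volume on total brain volume
#'
#' Ordinary least-squares residuals of region volume on intercept + TBV,
#' over the full sample. Residuals sum to zero and are uncorrelated with
#' TBV; they are the adjusted volumes used by the association and network
#' stages.
#'
#' @param table a [volume_table()].
#' @param region region column name (omit to residualize every region).
#' @return numeric residual vector (one region) or an animals x regions
#'   residual matrix (all regions).
#' @export
residualize_on_tbv <- function(table, region = NULL) {
  stopifnot(inherits(table, "volume_table"))
  if (nrow(table) < 3L) stop("need >= 3 animals to residualize")
  if (sd(table$tbv) == 0) stop("tbv is constant: rank-deficient design")
  x <- qr(cbind(1, table$tbv))
  cols <- if (is.null(region)) regions(table) else region
  bad <- setdiff(cols, regions(table))
  if (length(bad) > 0L) stop("unknown region(s): ", paste(bad, collapse = ", "))
  y <- as.matrix(as.data.frame(table)[cols])
  res <- qr.resid(x, y)
  rownames(res) <- NULL
  if (length(cols) == 1L) drop(res) else res
}

#' Covariate-adjusted pairwise group contrast for one region
#'
#' Fits `volume ~ group + tbv` on the two groups' animals only and
#' returns the t statistic of the group indicator (coded 1 for the second,
#' older group), so a negative t means the older group is smaller. p is
#' two-tailed from the t distribution with n - 3 df.
#'
#' @param table a [volume_table()].
#' @param region region column name.
#' @param pair character vector of two group labels, younger first.
#' @return one-row data.frame: region, comparison, t, df, p_raw,
#'   direction.
#' @export
glm_group_contrast <- function(table, region, pair) {
  stopifnot(inherits(table, "volume_table"), length(pair) == 2L)
  if (!all(pair %in% levels(table$group))) {
    stop("unknown group label(s): ",
         paste(setdiff(pair, levels(table$group)), collapse = ", "))
  }
  if (!region %in% regions(table)) stop("unknown region: ", region)
  sub <- table[as.character(table$group) %in% pair, , drop = FALSE]
  if (any(table(factor(as.character(sub$group), levels = pair)) < 3L)) {
    stop("both groups need >= 3 animals")
  }
  ind <- as.numeric(as.character(sub$group) == pair[2L])
  y <- sub[[region]]
  fit <- lm(y ~ ind + sub$tbv)
  if (any(is.na(coef(fit)))) {
    stop("singular design (tbv constant within the pair?)")
  }
  sm <- summary(fit)$coefficients
  tval <- sm["ind", "t value"]
  df <- nrow(sub) - 3L
  data.frame(region = region,
             comparison = paste(pair, collapse = " vs "),
             t = tval, df = df,
             p_raw = 2 * pt(-abs(tval), df),
             direction = ifelse(tval < 0, "second group smaller",
                                "second group larger"),
             stringsAsFactors = FALSE)
}

#' Bonferroni-Holm step-down adjustment
#'
#' Step-down Holm: sort ascending, multiply the i-th smallest p by
#' (m - i + 1), enforce the running maximum, cap at 1 and return in the
#' original order. Adjusted values are never below the raw ones.
#'
#' @param p_values numeric vector of p-values in `[0, 1]`.
#' @return adjusted p-values, same order as the input.
#' @export
holm_adjust <- function(p_values) {
  if (length(p_values) == 0L) return(numeric(0))
  if (anyNA(p_values) || any(p_values < 0 | p_values > 1)) {
    stop("p-values must lie in [0, 1]")
  }
  p.adjust(p_values, method = "holm")
}

#' Pairwise contrasts over a family of regions
#'
#' Runs [glm_group_contrast()] for every region x pair combination and
#' Holm-adjusts within the declared correction family: `"all"` corrects
#' over every test jointly (the a-priori design: 3 ROIs x 2 comparisons =
#' 6 tests) while `"per_comparison"` corrects each group pair over its
#' regions separately (the brain-wide design: 32 per comparison).
#'
#' @param table a [volume_table()].
#' @param pairs list of group pairs, each younger first.
#' @param rois regions to test (default all).
#' @param family `"all"` or `"per_comparison"`.
#' @return data.frame with one row per region x comparison, including
#'   `p_adj`.
#' @export
volume_contrast_table <- function(table, pairs, rois = regions(table),
                                  family = c("per_comparison", "all")) {
  family <- match.arg(family)
  res <- do.call(rbind, lapply(pairs, function(pr) {
    do.call(rbind, lapply(rois, function(rg) glm_group_contrast(table, rg, pr)))
  }))
  res$p_adj <- NA_real_
  if (family == "all") {
    res$p_adj <- holm_adjust(res$p_raw)
  } else {
    for (cmp in unique(res$comparison)) {
      i <- res$comparison == cmp
      res$p_adj[i] <- holm_adjust(res$p_raw[i])
    }
  }
  res$family <- family
  rownames(res) <- NULL
  res
}

#' Sample-wide association between regional volume and alternation
#'
#' For each region, fits a binomial (optionally quasi-binomial) regression
#' of per-animal alternation successes out of scorable trials on the
#' region's TBV-residualized volume over the full pooled sample, and
#' reports the signed Wald statistic for the slope (sign = sign of the
#' fitted slope) with its two-tailed asymptotic p. Note this signed Wald z
#' is often printed under a "chi-squared" heading in the field's tables;
#' a literal chi-squared cannot be negative, so the signed z is what we
#' expose. p-values are Holm-adjusted over the requested family of
#' regions.
#'
#' @param table a [volume_table()].
#' @param behavior data.frame with columns `animal_id`, `successes`,
#'   `trials` (see [alternation_scores()]).
#' @param rois family of regions to test and correct over (a-priori: the
#'   3 [apriori_rois()]; brain-wide: all 32).
#' @param dispersion `"binomial"` (default) or `"quasibinomial"` for a
#'   dispersion-adjusted Wald statistic.
#' @return data.frame: region, stat (signed Wald z), p_raw, p_adj,
#'   converged, family_size.
#' @export
associate_with_behavior <- function(table, behavior, rois = apriori_rois(),
                                    dispersion = c("binomial",
                                                   "quasibinomial")) {
  dispersion <- match.arg(dispersion)
  stopifnot(inherits(table, "volume_table"),
            all(c("animal_id", "successes", "trials") %in% names(behavior)))
  if (any(behavior$trials < 1L)) stop("every animal needs >= 1 scorable trial")
  idx <- match(table$animal_id, behavior$animal_id)
  if (anyNA(idx)) {
    stop("behavior records missing for animal(s): ",
         paste(table$animal_id[is.na(idx)], collapse = ", "))
  }
  succ <- behavior$successes[idx]
  fail <- behavior$trials[idx] - succ
  if (any(fail < 0)) stop("successes exceed trials")

  rows <- lapply(rois, function(rg) {
    res <- residualize_on_tbv(table, rg)
    fit <- suppressWarnings(
      glm(cbind(succ, fail) ~ res, family = dispersion))
    sm <- summary(fit)$coefficients
    est <- sm["res", 1L]
    se <- sm["res", 2L]
    # separation / degenerate outcomes: the slope (per SD of predictor)
    # drifts to the logit boundary or its SE blows up; no honest Wald
    # statistic exists there, so the region is flagged instead
    s <- sd(res)
    converged <- isTRUE(fit$converged) && !isTRUE(fit$boundary) &&
      is.finite(est) && is.finite(se) && se > 0 &&
      abs(est) * s < 20 && se * s < 100
    z <- if (converged) est / se else NA_real_
    data.frame(region = rg, stat = z,
               p_raw = if (converged) 2 * pnorm(-abs(z)) else NA_real_,
               converged = converged, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$p_adj <- NA_real_
  ok <- !is.na(out$p_raw)
  out$p_adj[ok] <- holm_adjust(out$p_raw[ok])
  out$family_size <- sum(ok)
  rownames(out) <- NULL
  out
}
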