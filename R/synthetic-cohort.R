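#' Configuration for a synthetic lifespan cohort
#'
#' Describes the statistical structure the downstream analyses assume:
#' age groups of roughly ten animals, 32 brain regions whose volumes scale
#' with total brain volume (so the TBV covariate genuinely matters),
#' group mean shifts on selected regions expressed in units of the
#' residual noise SD, block-structured between-animal correlation
#' (planted covariance communities), and seven Bernoulli goal-arm choices
#' per animal whose alternation probability may depend on selected
#' region volumes.
#'
#' @param n_per_group integer count of animals per group; either a scalar
#'   or a vector of `length(groups)` (the study design is 10/10/9, one
#'   old animal excluded).
#' @param groups ordered age-group labels, youngest first.
#' @param region_names region identifiers; default the 32 ROIs of
#'   [default_rois()].
#' @param tbv_mean,tbv_sd total-brain-volume distribution (mm^3).
#' @param effect_table named list: key `"g1:g2"` for consecutive group
#'   pairs, value a named numeric vector of standardized mean shifts
#'   (units of `noise_sd`) applied to the second group relative to the
#'   first.
#' @param community_assignment named integer/character vector mapping each
#'   region to a planted community; default 4 equal blocks over the
#'   regions in order.
#' @param within_community_r,between_community_r target correlations of
#'   the residual noise inside and between planted communities; must
#'   satisfy `within > between`, both in `[0, 1)`.
#' @param noise_sd residual volume noise SD (mm^3).
#' @param n_trials Y-maze trials per animal (>= 2).
#' @param behavior_link named numeric vector of slopes on the logit of the
#'   per-trial alternation probability, per unit of standardized
#'   TBV-residualized volume of the named region. Empty = no
#'   brain--behavior coupling, giving chance-level P(alternate) = 0.5.
#' @param attenuation optional planted connectivity drop:
#'   `list(group =, region =, factor =)` multiplies the named region's
#'   correlations with its own community by `factor` (in `[0, 1]`) in
#'   that group only.
#' @param seed RNG seed; fixed seed gives byte-identical cohorts.
#' @return list of class `cohort_config`.
#' @export
cohort_config <- function(n_per_group = c(10L, 10L, 9L),
                          groups = c("young", "middle", "old"),
                          region_names = default_rois(),
                          tbv_mean = 450, tbv_sd = 18,
                          effect_table = list(),
                          community_assignment = NULL,
                          within_community_r = 0.5,
                          between_community_r = 0.10,
                          noise_sd = 0.5,
                          n_trials = 7L,
                          behavior_link = c(),
                          attenuation = NULL,
                          seed = 1L) {
  if (length(n_per_group) == 1L) n_per_group <- rep(n_per_group, length(groups))
  stopifnot(length(n_per_group) == length(groups))
  names(n_per_group) <- groups
  if (any(n_per_group < 3L)) stop("n_per_group must be >= 3 in every group")
  if (n_trials < 2L) stop("n_trials must be >= 2")
  if (!(within_community_r >= 0 && within_community_r < 1) ||
      !(between_community_r >= 0 && between_community_r < 1)) {
    stop("community correlations must lie in [0, 1)")
  }
  if (within_community_r < between_community_r) {
    stop("within_community_r must be >= between_community_r")
  }
  if (is.null(community_assignment)) {
    # equal contiguous blocks in region order
    n_comm <- min(4L, length(region_names))
    community_assignment <- setNames(
      sort(rep(seq_len(n_comm), length.out = length(region_names))),
      region_names)
  }
  if (!all(names(community_assignment) %in% region_names) ||
      !all(region_names %in% names(community_assignment))) {
    stop("community_assignment must cover exactly the region_names")
  }
  for (key in names(effect_table)) {
    pair <- strsplit(key, ":", fixed = TRUE)[[1L]]
    if (length(pair) != 2L || !all(pair %in% groups)) {
      stop("effect_table key not a 'g1:g2' group pair: ", key)
    }
    if (match(pair[2L], groups) != match(pair[1L], groups) + 1L) {
      stop("effect_table keys must name consecutive groups: ", key)
    }
    bad <- setdiff(names(effect_table[[key]]), region_names)
    if (length(bad) > 0L) {
      stop("effect_table names unknown region(s): ", paste(bad, collapse = ", "))
    }
  }
  if (length(behavior_link) > 0L &&
      !all(names(behavior_link) %in% region_names)) {
    stop("behavior_link names unknown region(s)")
  }
  if (!is.null(attenuation)) {
    stopifnot(is.list(attenuation),
              all(c("group", "region", "factor") %in% names(attenuation)))
    if (!attenuation$group %in% groups) stop("attenuation group unknown")
    if (!attenuation$region %in% region_names) stop("attenuation region unknown")
  }
  structure(list(
    n_per_group = n_per_group, groups = groups, region_names = region_names,
    tbv_mean = tbv_mean, tbv_sd = tbv_sd, effect_table = effect_table,
    community_assignment = community_assignment[region_names],
    within_community_r = within_community_r,
    between_community_r = between_community_r,
    noise_sd = noise_sd, n_trials = as.integer(n_trials),
    behavior_link = behavior_link, attenuation = attenuation,
    seed = as.integer(seed)), class = "cohort_config")
}

# deterministic baseline volume fractions: regions span a modest size range
# and jointly account for 95% of TBV, so every region co-scales with TBV
region_baseline_fraction <- function(n_regions) {
  w <- seq(2, 5, length.out = n_regions)
  0.95 * w / sum(w)
}

# block-constant correlation matrix for one group, with optional planted
# attenuation of one region's within-community correlations
block_correlation <- function(config, group) {
  comm <- config$community_assignment
  n <- length(comm)
  same <- outer(comm, comm, "==")
  r <- matrix(config$between_community_r, n, n,
              dimnames = list(names(comm), names(comm)))
  r[same] <- config$within_community_r
  att <- config$attenuation
  if (!is.null(att) && identical(att$group, group)) {
    i <- match(att$region, names(comm))
    mates <- which(comm == comm[i])
    r[i, mates] <- r[i, mates] * att$factor
    r[mates, i] <- r[mates, i] * att$factor
  }
  diag(r) <- 1
  r
}

group_mean_offsets <- function(config) {
  g <- config$groups
  nr <- length(config$region_names)
  off <- matrix(0, length(g), nr, dimnames = list(g, config$region_names))
  for (i in seq_along(g)[-1L]) {
    off[i, ] <- off[i - 1L, ]
    key <- paste(g[i - 1L], g[i], sep = ":")
    shift <- config$effect_table[[key]]
    if (!is.null(shift)) off[i, names(shift)] <- off[i, names(shift)] + shift
  }
  off
}

#' Generate a synthetic cohort
#'
#' Draws, per animal: a total brain volume; region volumes as a
#' TBV-proportional baseline plus the group's planted mean shift plus
#' correlated Gaussian noise whose correlation matrix is block-constant
#' over the planted communities; and an ordered sequence of goal-arm
#' choices in which each post-first trial alternates with probability
#' `plogis(sum(slopes * standardized TBV-residualized volume))` (0.5 when
#' no brain--behavior link is configured). Deterministic for a fixed seed.
#'
#' @param config a [cohort_config()].
#' @return list of class `synthetic_cohort` with elements `volumes` (a
#'   [volume_table()]), `trials` (data.frame: animal_id, group, choices)
#'   and `truth` (planted effects, partition, behavior slopes, seed).
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  set.seed(config$seed)
  nr <- length(config$region_names)
  frac <- region_baseline_fraction(nr)
  offsets <- group_mean_offsets(config)

  chol_by_group <- lapply(config$groups, function(g) {
    r <- block_correlation(config, g)
    tryCatch(chol(r), error = function(e) {
      stop(sprintf(paste0("implied correlation matrix not positive definite ",
                          "(within_community_r = %.3f, between_community_r = %.3f",
                          "%s)"),
                   config$within_community_r, config$between_community_r,
                   if (is.null(config$attenuation)) "" else
                     sprintf(", attenuation factor = %.3f on '%s'",
                             config$attenuation$factor,
                             config$attenuation$region)),
           call. = FALSE)
    })
  })
  names(chol_by_group) <- config$groups

  rows <- list()
  for (g in config$groups) {
    n_g <- config$n_per_group[[g]]
    tbv <- rnorm(n_g, config$tbv_mean, config$tbv_sd)
    z <- matrix(rnorm(n_g * nr), n_g, nr) %*% chol_by_group[[g]]
    vol <- outer(tbv, frac) +
      config$noise_sd * (matrix(offsets[g, ], n_g, nr, byrow = TRUE) + z)
    colnames(vol) <- config$region_names
    rows[[g]] <- data.frame(
      animal_id = sprintf("%s_%02d", g, seq_len(n_g)),
      group = g, tbv = tbv, check.names = FALSE)
    rows[[g]] <- cbind(rows[[g]], as.data.frame(vol, check.names = FALSE))
  }
  volumes <- volume_table(do.call(rbind, c(rows, list(make.row.names = FALSE))),
                          regions = config$region_names,
                          groups = config$groups)

  # per-trial alternation probability from standardized TBV residuals
  eta <- rep(0, nrow(volumes))
  if (length(config$behavior_link) > 0L) {
    for (rg in names(config$behavior_link)) {
      res <- residualize_on_tbv(volumes, rg)
      eta <- eta + config$behavior_link[[rg]] * (res / sd(res))
    }
  }
  p_alt <- plogis(eta)
  arms <- c("A", "B")
  choices <- vapply(seq_len(nrow(volumes)), function(i) {
    seqs <- character(config$n_trials)
    seqs[1L] <- sample(arms, 1L)
    for (t in 2L:config$n_trials) {
      alt <- runif(1L) < p_alt[i]
      prev <- seqs[t - 1L]
      seqs[t] <- if (alt) setdiff(arms, prev) else prev
    }
    paste(seqs, collapse = "")
  }, character(1L))
  trials <- data.frame(animal_id = volumes$animal_id,
                       group = as.character(volumes$group),
                       choices = choices, stringsAsFactors = FALSE)

  planted <- lapply(config$effect_table,
                    function(shift) as.list(shift[shift != 0]))
  truth <- list(
    planted_effects = planted,
    planted_partition = as.list(config$community_assignment),
    behavior_slopes = as.list(config$behavior_link),
    attenuation = config$attenuation,
    groups = as.list(config$groups),
    seed = config$seed)

  structure(list(volumes = volumes, trials = trials, truth = truth),
            class = "synthetic_cohort")
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat(sprintf("synthetic_cohort: %d animals (%s), %d regions, %d trials/animal\n",
              nrow(x$volumes),
              paste(table(x$volumes$group), collapse = "/"),
              length(regions(x$volumes)),
              nchar(x$trials$choices[1L])))
  invisible(x)
}

#' Write a cohort to disk
#'
#' Emits `volumes.csv` (animal_id, group, tbv, one column per region),
#' `trials.csv` (animal_id, group, choices as a string over A/B) and
#' `truth.json` recording the planted ground truth for test harnesses.
#'
#' @param cohort a [generate_cohort()] result.
#' @param directory output directory, created if absent.
#' @return named character vector of the three paths, invisibly.
#' @export
write_cohort <- function(cohort, directory) {
  stopifnot(inherits(cohort, "synthetic_cohort"))
  if (!dir.exists(directory)) {
    ok <- dir.create(directory, recursive = TRUE, showWarnings = FALSE)
    if (!ok) stop("cannot create directory: ", directory)
  }
  paths <- c(volumes = file.path(directory, "volumes.csv"),
             trials = file.path(directory, "trials.csv"),
             truth = file.path(directory, "truth.json"))
  # volumes serialized at 17 significant digits so a write/read round trip
  # reproduces every double bit-exactly
  vols <- as.data.frame(cohort$volumes)
  for (cl in names(vols)) {
    if (is.numeric(vols[[cl]])) vols[[cl]] <- sprintf("%.17g", vols[[cl]])
  }
  tryCatch({
    write.csv(vols, paths[["volumes"]], row.names = FALSE, quote = FALSE)
    write.csv(cohort$trials, paths[["trials"]], row.names = FALSE)
    jsonlite::write_json(cohort$truth, paths[["truth"]],
                         auto_unbox = TRUE, digits = NA, null = "null")
  }, error = function(e) {
    stop("failed writing cohort under ", directory, ": ", conditionMessage(e),
         call. = FALSE)
  })
  invisible(paths)
}

#' Read a cohort written by [write_cohort()]
#'
#' @param directory directory containing `volumes.csv`, `trials.csv` and
#'   (optionally) `truth.json`.
#' @return a `synthetic_cohort` list; `truth` is `NULL` when absent.
#' @export
read_cohort <- function(directory) {
  vpath <- file.path(directory, "volumes.csv")
  tpath <- file.path(directory, "trials.csv")
  if (!file.exists(vpath)) stop("no volumes.csv under ", directory)
  truth <- NULL
  jpath <- file.path(directory, "truth.json")
  if (file.exists(jpath)) truth <- jsonlite::read_json(jpath)
  vols <- read.csv(vpath, check.names = FALSE, stringsAsFactors = FALSE)
  groups <- if (!is.null(truth$groups)) unlist(truth$groups) else NULL
  volumes <- volume_table(vols, groups = groups)
  trials <- if (file.exists(tpath)) {
    read.csv(tpath, check.names = FALSE, stringsAsFactors = FALSE,
             colClasses = c(choices = "character"))
  } else NULL
  structure(list(volumes = volumes, trials = trials, truth = truth),
            class = "synthetic_cohort")
}
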