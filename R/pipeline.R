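#' Default run configuration
#'
#' Returns the full configuration the pipeline runs with, as a nested
#' list. Either supply `input` paths (volumes/trials/hierarchy files) or
#' leave the `simulation` block in place to analyze a synthetic cohort.
#' Defaults mirror the reference design: three age groups, the three
#' a-priori ROIs, maturational (young vs middle) and aging-related
#' (middle vs old) pairs, densities 0.05--0.40 in 1% steps, alpha 0.05
#' with a 5-density run criterion, and 5000 permutations for
#' a-priori/global analyses (1000 for brain-wide degree).
#'
#' @param ... named overrides, merged recursively into the defaults
#'   (e.g. `analysis = list(n_perm_apriori = 500)`).
#' @return nested list of class `run_config`.
#' @export
run_config <- function(...) {
  defaults <- list(
    input = list(volumes = NULL, trials = NULL, hierarchy = NULL),
    simulation = list(),              # cohort_config() overrides
    analysis = list(
      apriori_rois = apriori_rois(),
      pairs = list(c("young", "middle"), c("middle", "old")),
      density_min = 0.05, density_max = 0.40, density_step = 0.01,
      alpha = 0.05, run_min = 5L,
      n_perm_apriori = 5000L, n_perm_brainwide = 1000L,
      z_hub_min = 1.0, p_connector_min = 0.30,
      cartography_density = 0.20,
      denominator_rule = "trials_minus_one",
      dispersion = "binomial",
      walktrap_steps = 4L),
    seed = 1L)
  cfg <- merge_config(defaults, list(...))
  class(cfg) <- c("run_config", "list")
  cfg
}

merge_config <- function(base, override) {
  for (nm in names(override)) {
    if (is.list(base[[nm]]) && is.list(override[[nm]]) &&
        !is.null(names(override[[nm]]))) {
      base[[nm]] <- merge_config(base[[nm]], override[[nm]])
    } else {
      base[[nm]] <- override[[nm]]
    }
  }
  base
}

#' Read a run configuration from YAML
#'
#' @param path YAML file of overrides, matching the [run_config()]
#'   structure.
#' @return a `run_config`.
#' @export
read_run_config <- function(path) {
  do.call(run_config, yaml::read_yaml(path))
}

validate_run_config <- function(config) {
  a <- config$analysis
  dens <- density_grid(a$density_min, a$density_max, a$density_step)
  if (a$run_min > length(dens)) {
    stop("run_min (", a$run_min, ") exceeds the number of densities (",
         length(dens), ")")
  }
  if (a$n_perm_apriori < 100L || a$n_perm_brainwide < 100L) {
    stop("n_perm must be >= 100 for any inferential run")
  }
  if (!(a$alpha > 0 && a$alpha < 1)) stop("alpha must lie in (0, 1)")
  invisible(dens)
}

#' Validate input files for consistency
#'
#' Checks header and animal-ID consistency between the volumes and
#' trials files, hierarchy totality over the volume columns, positivity
#' of all volume cells, and validity of the choice alphabet. All
#' problems are collected and returned, not just the first.
#'
#' @param volumes path to a volumes table (animal_id, group, tbv, one
#'   column per region).
#' @param trials path to a trials table (animal_id, group, choices).
#' @param hierarchy optional path to a region hierarchy file.
#' @return character vector of problems (empty when clean).
#' @export
validate_inputs <- function(volumes, trials = NULL, hierarchy = NULL) {
  problems <- character(0)
  note <- function(...) problems <<- c(problems, sprintf(...))
  if (!file.exists(volumes)) {
    return(sprintf("volumes file not found: %s", volumes))
  }
  vols <- read.csv(volumes, check.names = FALSE, stringsAsFactors = FALSE)
  needed <- c("animal_id", "group", "tbv")
  for (cl in setdiff(needed, names(vols))) {
    note("volumes: missing column '%s'", cl)
  }
  reg_cols <- setdiff(names(vols), needed)
  if (all(needed %in% names(vols))) {
    if (anyDuplicated(vols$animal_id)) {
      note("volumes: duplicated animal_id(s): %s",
           paste(unique(vols$animal_id[duplicated(vols$animal_id)]),
                 collapse = ", "))
    }
    for (cl in c(reg_cols, "tbv")) {
      bad <- which(!is.finite(vols[[cl]]) | vols[[cl]] <= 0)
      for (i in bad) {
        note("volumes: non-positive or missing cell at row %d, column '%s'",
             i, cl)
      }
    }
  }
  if (!is.null(hierarchy)) {
    if (!file.exists(hierarchy)) {
      note("hierarchy file not found: %s", hierarchy)
    } else {
      h <- tryCatch(read_roi_hierarchy(hierarchy),
                    error = function(e) {
                      note("hierarchy: %s", conditionMessage(e))
                      NULL
                    })
      if (!is.null(h)) {
        bare <- sub("_(left|right)$", "", reg_cols)
        unmapped <- setdiff(unique(bare), h$fine_region)
        if (length(unmapped) > 0L &&
            length(setdiff(unique(bare), h$roi)) > 0L) {
          for (rg in setdiff(unmapped, h$roi)) {
            note("hierarchy: volume column '%s' unmapped", rg)
          }
        }
      }
    }
  }
  if (!is.null(trials)) {
    if (!file.exists(trials)) {
      note("trials file not found: %s", trials)
    } else {
      tr <- read.csv(trials, check.names = FALSE, stringsAsFactors = FALSE,
                     colClasses = c(choices = "character"))
      for (cl in setdiff(c("animal_id", "choices"), names(tr))) {
        note("trials: missing column '%s'", cl)
      }
      if (all(c("animal_id", "choices") %in% names(tr))) {
        if ("animal_id" %in% names(vols)) {
          for (id in setdiff(tr$animal_id, vols$animal_id)) {
            note("animal '%s' present in trials but not volumes", id)
          }
          for (id in setdiff(vols$animal_id, tr$animal_id)) {
            note("animal '%s' present in volumes but not trials", id)
          }
        }
        for (i in seq_len(nrow(tr))) {
          ch <- strsplit(tr$choices[i], "")[[1L]]
          if (length(unique(ch)) > 2L || length(ch) < 2L) {
            note("trials: invalid choice sequence for '%s': %s",
                 tr$animal_id[i], tr$choices[i])
          }
        }
      }
    }
  }
  problems
}

#' Run the full analysis pipeline
#'
#' simulate/load -> volumetrics -> behavior -> SCN cartography ->
#' permutation inference, writing result tables, density profiles, a
#' significant-findings summary and a machine-readable manifest under
#' `out_dir`. Idempotent: a rerun with the same config and seed produces
#' byte-identical outputs.
#'
#' @param config a [run_config()] (or YAML path).
#' @param out_dir output directory, created if absent.
#' @return list of results, invisibly; files under `out_dir` are the
#'   primary product.
#' @export
run_pipeline <- function(config = run_config(), out_dir) {
  if (is.character(config)) config <- read_run_config(config)
  stopifnot(inherits(config, "run_config"))
  dens <- validate_run_config(config)
  a <- config$analysis
  a$pairs <- lapply(a$pairs, function(p) as.character(unlist(p)))  # from YAML
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  stages_done <- character(0)
  # the manifest must suffice to reproduce the run: full config + seed +
  # input hashes
  manifest <- list(package = "scnaging",
                   version = as.character(utils::packageVersion("scnaging")),
                   seed = config$seed, config = unclass(config),
                   complete = FALSE)
  finish_manifest <- function() {
    manifest$stages <- stages_done
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE,
                         null = "null")
  }
  on.exit(finish_manifest())
  stage <- function(name, expr) {
    out <- tryCatch(expr, error = function(e) {
      stop("stage '", name, "': ", conditionMessage(e), call. = FALSE)
    })
    stages_done <<- c(stages_done, name)
    out
  }

  # ---- data ----
  data <- stage("input", {
    if (!is.null(config$input$volumes)) {
      probs <- validate_inputs(config$input$volumes, config$input$trials,
                               config$input$hierarchy)
      if (length(probs) > 0L) {
        stop("input validation failed:\n  ", paste(probs, collapse = "\n  "))
      }
      vols <- read.csv(config$input$volumes, check.names = FALSE,
                       stringsAsFactors = FALSE)
      volumes <- volume_table(vols)
      if (any(grepl("_(left|right)$", regions(volumes)))) {
        volumes <- average_hemispheres(volumes)
      }
      hier <- if (!is.null(config$input$hierarchy)) {
        read_roi_hierarchy(config$input$hierarchy)
      } else default_roi_hierarchy()
      # reduce only when the input is at fine-region granularity
      if (!all(regions(volumes) %in% hier$roi)) {
        volumes <- reduce_to_rois(volumes, hier)
      }
      trials <- if (!is.null(config$input$trials)) {
        read.csv(config$input$trials, check.names = FALSE,
                 stringsAsFactors = FALSE,
                 colClasses = c(choices = "character"))
      } else NULL
      list(volumes = volumes, trials = trials)
    } else {
      sim_args <- merge_config(list(seed = config$seed), config$simulation)
      cohort <- generate_cohort(do.call(cohort_config, sim_args))
      list(volumes = cohort$volumes, trials = cohort$trials,
           truth = cohort$truth)
    }
  })
  volumes <- data$volumes
  groups <- levels(volumes$group)
  write.csv(as.data.frame(volumes), file.path(out_dir, "volumes_used.csv"),
            row.names = FALSE)
  manifest$input_md5 <- as.vector(tools::md5sum(file.path(out_dir,
                                                          "volumes_used.csv")))

  # ---- behavior ----
  behavior <- stage("behavior", {
    if (is.null(data$trials)) NULL else {
      scores <- alternation_scores(data$trials, a$denominator_rule)
      write.csv(scores, file.path(out_dir, "behavior_scores.csv"),
                row.names = FALSE)
      tests <- list(anova = group_anova(scores),
                    wald = group_wald_logistic(scores))
      jsonlite::write_json(tests, file.path(out_dir, "behavior_tests.json"),
                           auto_unbox = TRUE, digits = NA, pretty = TRUE,
                           null = "null")
      list(scores = scores, tests = tests)
    }
  })

  # ---- volumetrics ----
  volumetrics <- stage("volumetrics", {
    apriori <- intersect(a$apriori_rois, regions(volumes))
    out <- list(
      contrasts_apriori = volume_contrast_table(volumes, a$pairs, apriori,
                                                family = "all"),
      contrasts_brainwide = volume_contrast_table(volumes, a$pairs,
                                                  regions(volumes),
                                                  family = "per_comparison"))
    if (!is.null(behavior)) {
      beh <- data.frame(animal_id = behavior$scores$animal_id,
                        successes = behavior$scores$n_alternations,
                        trials = behavior$scores$n_scorable)
      out$associations_apriori <-
        associate_with_behavior(volumes, beh, apriori,
                                dispersion = a$dispersion)
      out$associations_brainwide <-
        associate_with_behavior(volumes, beh, regions(volumes),
                                dispersion = a$dispersion)
    }
    for (nm in names(out)) {
      write.csv(out[[nm]], file.path(out_dir, paste0(nm, ".csv")),
                row.names = FALSE)
    }
    out
  })

  # ---- SCN cartography per group ----
  cartographies <- stage("scn", {
    out <- list()
    for (g in groups) {
      cv <- build_covariance(volumes, g)
      write_matrix(cv, file.path(out_dir, paste0("covariance_",
                                                 gsub("\\W", "_", g), ".csv")))
      net <- threshold_at_density(cv, a$cartography_density)
      carto <- cartography(net, z_hub_min = a$z_hub_min,
                           p_connector_min = a$p_connector_min)
      write.csv(carto$nodes,
                file.path(out_dir, paste0("cartography_",
                                          gsub("\\W", "_", g), ".csv")),
                row.names = FALSE)
      out[[g]] <- carto
    }
    out
  })

  # ---- permutation inference ----
  profiles <- stage("permutation", {
    out <- list()
    long <- list()
    seed_k <- 0L
    for (pr in a$pairs) {
      key <- paste(pr, collapse = "_vs_")
      seed_k <- seed_k + 1L
      deg <- compare_metric(volumes, pr, "degree", nodes = regions(volumes),
                            densities = dens, n_perm = a$n_perm_brainwide,
                            alpha = a$alpha, run_min = a$run_min,
                            seed = config$seed + 100L * seed_k,
                            walktrap_steps = a$walktrap_steps)
      out[[paste0("degree_", key)]] <- deg
      long[[paste0("degree_", key)]] <- as.data.frame(deg)
      for (m in c("modularity", "transitivity", "mean_distance")) {
        seed_k <- seed_k + 1L
        pf <- compare_metric(volumes, pr, m, densities = dens,
                             n_perm = a$n_perm_apriori, alpha = a$alpha,
                             run_min = a$run_min,
                             seed = config$seed + 100L * seed_k,
                             walktrap_steps = a$walktrap_steps)
        out[[paste0(m, "_", key)]] <- pf
        long[[paste0(m, "_", key)]] <- as.data.frame(pf)
      }
    }
    long_df <- do.call(rbind, c(unname(long), list(make.row.names = FALSE)))
    write.csv(long_df, file.path(out_dir, "density_profiles.csv"),
              row.names = FALSE)
    sig <- do.call(rbind, c(lapply(names(out), function(nm) {
      s <- significant_profiles(out[[nm]])
      if (nrow(s) > 0L) cbind(comparison = nm, s) else NULL
    }), list(make.row.names = FALSE)))
    if (is.null(sig)) sig <- list()
    jsonlite::write_json(sig, file.path(out_dir, "significant.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE,
                         null = "null")
    out
  })

  manifest$complete <- TRUE
  invisible(list(volumes = volumes, behavior = behavior,
                 volumetrics = volumetrics, cartography = cartographies,
                 profiles = profiles, out_dir = out_dir))
}
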