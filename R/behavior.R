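#' Score spontaneous alternation for one animal
#'
#' An alternation is a trial whose goal-arm choice differs from the
#' immediately preceding trial's (discrete-trial, forced-start Y-maze
#' variant with two goal arms). The percent alternation index is
#' `100 * n_alternations / n_scorable`.
#'
#' The first trial has no predecessor, so only `length - 1` trials are
#' scorable; with the default `"trials_minus_one"` denominator a random
#' chooser scores 50% in expectation, matching the task's stated chance
#' level. The literal `"trials"` denominator (divide by the full trial
#' count) is available for comparability with protocols that report it.
#'
#' @param choices character vector of single-arm labels, or one string
#'   (e.g. `"ABBABAB"`); exactly two distinct arm labels are allowed.
#' @param denominator_rule `"trials_minus_one"` (default) or `"trials"`.
#' @param animal_id optional identifier carried into the result.
#' @return list of class `alternation_score`: animal_id, n_alternations,
#'   n_scorable, percent.
#' @export
score_alternation <- function(choices,
                              denominator_rule = c("trials_minus_one",
                                                   "trials"),
                              animal_id = NA_character_) {
  denominator_rule <- match.arg(denominator_rule)
  if (length(choices) == 1L && nchar(choices) > 1L) {
    choices <- strsplit(choices, "")[[1L]]
  }
  n <- length(choices)
  if (n < 2L) stop("need at least 2 trials to score alternation")
  if (length(unique(choices)) > 2L) {
    stop("choices must use exactly 2 distinct arm labels; saw: ",
         paste(unique(choices), collapse = ", "))
  }
  n_alt <- sum(choices[-1L] != choices[-n])
  n_scorable <- if (denominator_rule == "trials_minus_one") n - 1L else n
  structure(list(animal_id = animal_id,
                 n_alternations = n_alt,
                 n_scorable = n_scorable,
                 percent = 100 * n_alt / n_scorable),
            class = "alternation_score")
}

#' Score alternation for a trials table
#'
#' @param trials data.frame with columns `animal_id`, `group`, `choices`
#'   (string over two arm labels), as produced by [generate_cohort()] or
#'   read from a trials file.
#' @inheritParams score_alternation
#' @return data.frame: animal_id, group, n_alternations, n_scorable
#'   (doubling as `successes`/`trials` for the binomial models), percent.
#' @export
alternation_scores <- function(trials,
                               denominator_rule = c("trials_minus_one",
                                                    "trials")) {
  denominator_rule <- match.arg(denominator_rule)
  stopifnot(all(c("animal_id", "choices") %in% names(trials)))
  sc <- lapply(seq_len(nrow(trials)), function(i) {
    score_alternation(trials$choices[i], denominator_rule,
                      animal_id = trials$animal_id[i])
  })
  data.frame(animal_id = trials$animal_id,
             group = if ("group" %in% names(trials)) trials$group else NA,
             n_alternations = vapply(sc, `[[`, integer(1L), "n_alternations"),
             n_scorable = vapply(sc, `[[`, integer(1L), "n_scorable"),
             percent = vapply(sc, `[[`, numeric(1L), "percent"),
             stringsAsFactors = FALSE)
}

#' One-way ANOVA on percent alternation across groups
#'
#' Standard fixed-effects one-way ANOVA on the percent scores. When the
#' within-group variance is zero (all scores constant within every group)
#' the F ratio is undefined; this is reported as a degenerate result
#' rather than letting NaN propagate.
#'
#' @param scores an [alternation_scores()] data.frame with a `group`
#'   column.
#' @return list: F, df_between, df_within, p, degenerate (logical).
#' @export
group_anova <- function(scores) {
  stopifnot(all(c("group", "percent") %in% names(scores)))
  g <- factor(scores$group)
  if (nlevels(g) < 2L) stop("need >= 2 groups")
  if (any(table(g) < 2L)) stop("every group needs >= 2 animals")
  fit <- aov(scores$percent ~ g)
  tab <- anova(fit)
  ss_within <- tab["Residuals", "Sum Sq"]
  if (ss_within < .Machine$double.eps * sum(scores$percent^2 + 1)) {
    return(list(F = NA_real_, df_between = tab[1L, "Df"],
                df_within = tab["Residuals", "Df"], p = NA_real_,
                degenerate = TRUE))
  }
  list(F = tab[1L, "F value"], df_between = tab[1L, "Df"],
       df_within = tab["Residuals", "Df"], p = tab[1L, "Pr(>F)"],
       degenerate = FALSE)
}

#' Joint Wald test for group differences in alternation
#'
#' Binomial regression of per-animal alternation successes out of
#' scorable trials on group indicators, followed by the joint Wald
#' chi-squared test of all group coefficients (df = n_groups - 1). Used
#' alongside the ANOVA because the proportion scores are bounded and
#' non-normal.
#'
#' @param scores an [alternation_scores()] data.frame with a `group`
#'   column.
#' @return list: chi2, df, p, converged.
#' @export
group_wald_logistic <- function(scores) {
  stopifnot(all(c("group", "n_alternations", "n_scorable") %in% names(scores)))
  g <- factor(scores$group)
  if (nlevels(g) < 2L) stop("need >= 2 groups (no contrast with one)")
  fail <- scores$n_scorable - scores$n_alternations
  fit <- suppressWarnings(
    glm(cbind(scores$n_alternations, fail) ~ g, family = binomial()))
  b <- coef(fit)[-1L]
  v <- vcov(fit)[-1L, -1L, drop = FALSE]
  converged <- isTRUE(fit$converged) && !isTRUE(fit$boundary) &&
    all(is.finite(b)) && all(abs(b) < 20) && all(is.finite(v)) &&
    all(diag(v) < 1e4)
  if (!converged) {
    return(list(chi2 = NA_real_, df = nlevels(g) - 1L, p = NA_real_,
                converged = FALSE))
  }
  chi2 <- drop(t(b) %*% solve(v, b))
  df <- nlevels(g) - 1L
  list(chi2 = chi2, df = df, p = pchisq(chi2, df, lower.tail = FALSE),
       converged = TRUE)
}
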