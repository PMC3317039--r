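#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

# Aggregate neuron-level records to subject x side x distance cell means and
# set up factors with sum-to-zero contrasts (type-III-friendly coding).
aggregate_cells <- function(records, vars) {
  needed <- c("subject_id", "dose_um", "side", "distance_um", vars)
  missing <- setdiff(needed, names(records))
  if (length(missing)) {
    stop_punctate(paste("records lack columns:", paste(missing, collapse = ", ")),
                  "punctate_validation_error")
  }
  cells <- records |>
    dplyr::group_by(.data$subject_id, .data$dose_um, .data$side,
                    .data$distance_um) |>
    dplyr::summarise(dplyr::across(dplyr::all_of(vars), mean),
                     .groups = "drop")
  cells$dose <- factor(cells$dose_um)
  cells$side_f <- factor(cells$side, levels = c("injected", "contralateral"))
  cells$distance_f <- factor(cells$distance_um)
  if (nlevels(cells$dose) > 1) {
    stats::contrasts(cells$dose) <- stats::contr.sum(nlevels(cells$dose))
  }
  if (nlevels(cells$side_f) > 1) {
    stats::contrasts(cells$side_f) <- stats::contr.sum(2)
  }
  if (nlevels(cells$distance_f) > 1) {
    stats::contrasts(cells$distance_f) <-
      stats::contr.sum(nlevels(cells$distance_f))
  }
  cells
}

# TRUE when every subject fills the full side x distance grid exactly once.
design_balanced <- function(cells) {
  full <- nlevels(cells$side_f) * nlevels(cells$distance_f)
  counts <- table(cells$subject_id, cells$side_f, cells$distance_f)
  all(counts == 1L) && all(table(cells$subject_id) == full)
}

check_design <- function(cells) {
  if (nlevels(cells$dose) < 2L) {
    stop_punctate("need at least 2 dose levels", "punctate_validation_error")
  }
  by_subj <- cells |>
    dplyr::group_by(.data$subject_id) |>
    dplyr::summarise(n_sides = dplyr::n_distinct(.data$side), .groups = "drop")
  if (any(by_subj$n_sides < 2L)) {
    stop_punctate("every subject must contribute both sides",
                  "punctate_validation_error")
  }
  balanced <- design_balanced(cells)
  if (!balanced) {
    rlang::warn(paste("unbalanced design: missing subject x side x distance",
                      "cells; falling back to a mixed model with type-III",
                      "sums of squares"))
  }
  balanced
}

# Collect (term, df, den_df, F, p) rows from a summary.aovlist, innermost
# stratum winning when a term (a covariate) projects onto several strata.
strata_table <- function(fit, rename = character()) {
  s <- summary(fit)
  rows <- list()
  for (stratum in s) {
    tab <- stratum[[1]]
    res_df <- tab["Residuals", "Df"]
    for (rn in rownames(tab)) {
      term <- trimws(rn)
      if (term == "Residuals") next
      rows[[term]] <- tibble::tibble(
        term = term, df = tab[rn, "Df"], den_df = res_df,
        statistic = tab[rn, "F value"], p.value = tab[rn, "Pr(>F)"])
    }
  }
  out <- dplyr::bind_rows(rows)
  for (nm in names(rename)) {
    out$term <- gsub(nm, rename[[nm]], out$term, fixed = TRUE)
  }
  out
}

# lmer fallback for unbalanced designs: type-III F with Satterthwaite ddf.
lmer_table <- function(fml, cells, rename) {
  fit <- suppressMessages(lmerTest::lmer(fml, data = cells))
  at <- suppressMessages(stats::anova(fit, type = 3, ddf = "Satterthwaite"))
  tab <- tibble::tibble(term = rownames(at), df = at$NumDF, den_df = at$DenDF,
                        statistic = at$`F value`, p.value = at$`Pr(>F)`)
  for (nm in names(rename)) {
    tab$term <- gsub(nm, rename[[nm]], tab$term, fixed = TRUE)
  }
  list(table = tab, fit = fit)
}

#' Mixed-design ANOVA on cohort measurements
#'
#' Fits the study's mixed design: dose is a between-subject factor; injection
#' side and rostrocaudal distance are within-subject factors. Neuron-level
#' records are first aggregated to subject x side x distance cell means (the
#' subject is the experimental unit). Balanced designs use the classical
#' repeated-measures partitioning — `aov` with error strata
#' `Error(subject/(side*distance))`, so the dose F is tested against
#' between-subject variation and each within factor against its own
#' subject-interaction stratum. Unbalanced designs fall back to a linear
#' mixed model (subject random intercept) with type-III sums of squares and
#' Satterthwaite denominator df, with a warning.
#'
#' Reported effects: dose, side, distance main effects and the dose x side
#' interaction.
#'
#' @param records tibble of neuron-level measurements with columns
#'   `subject_id`, `dose_um`, `side`, `distance_um` and the outcome.
#' @param outcome name of the outcome column (string).
#' @return Object of class `punctate_anova` with a `table` tibble
#'   (`term`, `df`, `den_df`, `statistic`, `p.value`), the fit, and the
#'   engine used (`"aov_strata"` or `"lmer"`).
#' @export
mixed_anova <- function(records, outcome) {
  cells <- aggregate_cells(records, outcome)
  balanced <- check_design(cells)
  cells$.y <- cells[[outcome]]
  rename <- c(side_f = "side", distance_f = "distance")

  if (stats::var(cells$.y) == 0) {
    # constant outcome: no variance to partition; report F = 0, p = 1
    terms <- c("dose", "side", "distance", "dose:side")
    tab <- tibble::tibble(term = terms, df = NA_real_, den_df = NA_real_,
                          statistic = 0, p.value = 1)
    return(structure(list(table = tab, fit = NULL, outcome = outcome,
                          engine = "degenerate"),
                     class = "punctate_anova"))
  }

  has_dist <- nlevels(cells$distance_f) > 1
  if (balanced) {
    fml <- if (has_dist) {
      .y ~ dose * side_f + distance_f + Error(subject_id / (side_f * distance_f))
    } else {
      .y ~ dose * side_f + Error(subject_id / side_f)
    }
    fit <- suppressWarnings(stats::aov(fml, data = cells))
    tab <- strata_table(fit, rename)
    engine <- "aov_strata"
  } else {
    fml <- if (has_dist) {
      .y ~ dose * side_f + distance_f + (1 | subject_id)
    } else {
      .y ~ dose * side_f + (1 | subject_id)
    }
    res <- lmer_table(fml, cells, rename)
    fit <- res$fit; tab <- res$table
    engine <- "lmer"
  }
  keep <- c("dose", "side", "distance", "dose:side")
  tab <- tab[match(intersect(keep, tab$term), tab$term), ]
  structure(list(table = tab, fit = fit, outcome = outcome, engine = engine),
            class = "punctate_anova")
}

#' @export
print.punctate_anova <- function(x, ...) {
  cat(sprintf("<mixed ANOVA> outcome: %s (%s)\n", x$outcome, x$engine))
  print(as.data.frame(x$table), row.names = FALSE, digits = 4)
  invisible(x)
}

#' @export
tidy.punctate_anova <- function(x, ...) x$table

#' @export
glance.punctate_anova <- function(x, ...) {
  tibble::tibble(outcome = x$outcome, engine = x$engine,
                 n_terms = nrow(x$table))
}

#' Tukey HSD post-hoc contrasts on subject means
#'
#' Aggregates each subject to a single mean of the outcome (over both sides
#' and all distances), then runs Tukey's honestly-significant-difference test
#' across dose groups — the post-hoc battery used once the omnibus dose
#' effect is established.
#'
#' @inheritParams mixed_anova
#' @return Tibble with one row per dose pair: `contrast` (higher dose minus
#'   lower, labelled `"b-a"`), `estimate`, `conf.low`, `conf.high`,
#'   `adj.p.value`.
#' @export
tukey_posthoc <- function(records, outcome) {
  needed <- c("subject_id", "dose_um", outcome)
  if (!all(needed %in% names(records))) {
    stop_punctate("records lack subject_id/dose_um/outcome columns",
                  "punctate_validation_error")
  }
  subj <- records |>
    dplyr::group_by(.data$subject_id, .data$dose_um) |>
    dplyr::summarise(.y = mean(.data[[outcome]]), .groups = "drop")
  subj$dose <- factor(subj$dose_um)
  if (nlevels(subj$dose) < 3L) {
    stop_punctate("Tukey post-hoc needs at least 3 dose levels",
                  "punctate_validation_error")
  }
  hsd <- stats::TukeyHSD(stats::aov(.y ~ dose, data = subj))$dose
  tibble::tibble(contrast = rownames(hsd),
                 estimate = hsd[, "diff"],
                 conf.low = hsd[, "lwr"], conf.high = hsd[, "upr"],
                 adj.p.value = hsd[, "p adj"])
}

#' ANCOVA: dose effect adjusted for total receptor signal
#'
#' Distinguishes receptor trafficking from bulk synthesis: a dose effect on a
#' synaptic measure that survives adjustment for the total receptor signal
#' reflects redistribution of receptors between pools rather than a change in
#' their overall amount. The model is
#' `outcome ~ covariate + dose + side (+ dose:side)` on subject x side x
#' distance cell means with the same error strata as [mixed_anova()]; the
#' covariate slope (and its standard error) is estimated from the matching
#' mixed model with a subject random intercept.
#'
#' @inheritParams mixed_anova
#' @param covariate name of the covariate column (typically the matching
#'   total-signal measure).
#' @param interaction also include the dose x side interaction.
#' @return Object of class `punctate_ancova`: `table` (F-tests, the dose row
#'   adjusted for the covariate), `slope` and `slope_se`, and the fits.
#' @export
ancova <- function(records, outcome, covariate, interaction = FALSE) {
  cells <- aggregate_cells(records, c(outcome, covariate))
  balanced <- check_design(cells)
  cells$.y <- cells[[outcome]]
  cells$.cov <- cells[[covariate]]
  if (stats::var(cells$.cov) == 0) {
    stop_punctate("covariate is constant; ANCOVA adjustment is undefined",
                  "punctate_validation_error")
  }
  rename <- c(side_f = "side", distance_f = "distance",
              .cov = "covariate")
  has_dist <- nlevels(cells$distance_f) > 1
  err <- if (has_dist) {
    quote(Error(subject_id / (side_f * distance_f)))
  } else {
    quote(Error(subject_id / side_f))
  }
  rhs <- if (interaction) quote(.cov + dose * side_f) else quote(.cov + dose + side_f)
  if (balanced) {
    fml <- stats::as.formula(bquote(.y ~ .(rhs) + .(err)))
    fit <- suppressWarnings(stats::aov(fml, data = cells))
    tab <- strata_table(fit, rename)
    engine <- "aov_strata"
  } else {
    fml <- stats::as.formula(bquote(.y ~ .(rhs) + (1 | subject_id)))
    res <- lmer_table(fml, cells, rename)
    fit <- res$fit; tab <- res$table
    engine <- "lmer"
  }
  slope_fml <- stats::as.formula(bquote(.y ~ .(rhs) + (1 | subject_id)))
  slope_fit <- suppressMessages(lme4::lmer(slope_fml, data = cells))
  coefs <- summary(slope_fit)$coefficients
  structure(list(table = tab, slope = coefs[".cov", "Estimate"],
                 slope_se = coefs[".cov", "Std. Error"],
                 fit = fit, slope_fit = slope_fit, engine = engine,
                 outcome = outcome, covariate = covariate),
            class = "punctate_ancova")
}

#' @export
print.punctate_ancova <- function(x, ...) {
  cat(sprintf("<ANCOVA> %s adjusted for %s (slope %.4g +/- %.3g, %s)\n",
              x$outcome, x$covariate, x$slope, x$slope_se, x$engine))
  print(as.data.frame(x$table), row.names = FALSE, digits = 4)
  invisible(x)
}

#' @export
tidy.punctate_ancova <- function(x, ...) x$table

#' @export
glance.punctate_ancova <- function(x, ...) {
  tibble::tibble(outcome = x$outcome, covariate = x$covariate,
                 slope = x$slope, slope_se = x$slope_se, engine = x$engine)
}
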