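# phenotype_interactions: relative fitness, multiplicative expectation,
# interaction scores and screen hit calls from fitness-assay plates.
#
# A plate table has one row per well: strain, rnai, experiment, replicate,
# population (and optional per-worm size metrics tof, ext). Population
# averages are taken across technical replicates before any normalisation.

#' Construct/validate a fitness plate table
#' @param df data frame with columns `strain`, `rnai`, `experiment`,
#'   `replicate`, `population` (optional `tof`, `ext`).
#' @param control_rnai non-targeting control (default `"GFP"`).
#' @param reference_strain wild-type strain label (default `"WT"`).
#' @return object of class `fitness_plate`.
#' @export
fitness_plate <- function(df, control_rnai = "GFP", reference_strain = "WT") {
  need <- c("strain", "rnai", "experiment", "replicate", "population")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("fitness_plate: missing columns: ", paste(miss, collapse = ", "))
  if (any(df$population < 0)) stop("fitness_plate: populations must be >= 0")
  for (s in unique(df$strain)) {
    if (!any(df$strain == s & df$rnai == control_rnai)) {
      stop("fitness_plate: no ", control_rnai, " control wells for strain ", s)
    }
  }
  df <- as.data.frame(df)
  attr(df, "control_rnai") <- control_rnai
  attr(df, "reference_strain") <- reference_strain
  class(df) <- c("fitness_plate", "data.frame")
  df
}

#' Read a fitness plate table (tab-separated wells)
#' @param path TSV with columns strain, rnai, experiment, replicate,
#'   population (optional tof, ext); `#` comments allowed.
#' @inheritParams fitness_plate
#' @export
read_fitness_plate <- function(path, control_rnai = "GFP", reference_strain = "WT") {
  fitness_plate(utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE),
                control_rnai = control_rnai, reference_strain = reference_strain)
}

mean_pop <- function(plate, strain, rnai, experiment = NULL) {
  sel <- plate$strain == strain & plate$rnai == rnai
  if (!is.null(experiment)) sel <- sel & plate$experiment == experiment
  if (!any(sel)) return(NA_real_)
  mean(plate$population[sel])
}

#' Within-strain relative fitness
#'
#' `w(strain, rnai)` = mean population under the RNAi divided by the mean
#' population under the non-targeting control, technical replicates averaged
#' first. One experiment at a time (pass `experiment` when the plate holds
#' several).
#'
#' @param plate a [fitness_plate()].
#' @param experiment restrict to one experiment (default: all wells pooled).
#' @return data frame `strain`, `rnai`, `relative_fitness`.
#' @export
relative_fitness <- function(plate, experiment = NULL) {
  ctrl <- attr(plate, "control_rnai")
  grid <- unique(plate[, c("strain", "rnai")])
  w <- vapply(seq_len(nrow(grid)), function(i) {
    denom <- mean_pop(plate, grid$strain[i], ctrl, experiment)
    if (is.na(denom) || denom == 0) stop("zero or missing control mean for strain ",
                                         grid$strain[i])
    mean_pop(plate, grid$strain[i], grid$rnai[i], experiment) / denom
  }, 0)
  data.frame(strain = grid$strain, rnai = grid$rnai, relative_fitness = w,
             stringsAsFactors = FALSE)
}

#' Genetic-interaction score for a (mutant, RNAi) pair
#'
#' Per experiment, the expected double-perturbation fitness follows the
#' multiplicative model (relative fitness of the RNAi in the wild type
#' times the relative fitness of the mutant under control RNAi); the score
#' is actual/expected, which reduces to
#' `w(mutant, rnai) / w(wild-type, rnai)`. A score of 1 means no genetic
#' interaction; 0 a maximal negative interaction. The overall score is the
#' mean across experiments. Significance compares per-experiment log scores
#' against the per-experiment log control-ratios (control RNAi in place of
#' the target); when the control ratios are structurally constant this is
#' the one-sample t-test against their common value.
#'
#' @param plate a [fitness_plate()] with an `experiment` column.
#' @param mutant mutant strain label.
#' @param rnai target RNAi label.
#' @param paired use a paired t-test across experiments (default FALSE,
#'   Welch).
#' @return one-row data frame: `mutant`, `rnai`, `score`, `log_ratio`,
#'   `p_value`, `n_experiments`.
#' @export
interaction_score <- function(plate, mutant, rnai, paired = FALSE) {
  ctrl <- attr(plate, "control_rnai")
  ref <- attr(plate, "reference_strain")
  scores <- c(); ctrl_ratios <- c()
  for (e in unique(plate$experiment)) {
    vals <- c(wt_r = mean_pop(plate, ref, rnai, e),
              wt_c = mean_pop(plate, ref, ctrl, e),
              mu_r = mean_pop(plate, mutant, rnai, e),
              mu_c = mean_pop(plate, mutant, ctrl, e))
    if (anyNA(vals) || any(vals[c("wt_c", "mu_c", "wt_r")] == 0)) {
      warning("experiment ", e, " missing a condition for (", mutant, ", ", rnai,
              "); skipped")
      next
    }
    w_mut <- vals[["mu_r"]] / vals[["mu_c"]]
    w_wt <- vals[["wt_r"]] / vals[["wt_c"]]
    scores <- c(scores, w_mut / w_wt)
    ctrl_ratios <- c(ctrl_ratios, 1)  # control RNAi in place of the target
  }
  n <- length(scores)
  if (!n) stop("no usable experiments for (", mutant, ", ", rnai, ")")
  p <- NA_real_
  if (n >= 2) {
    ls <- log(scores); lc <- log(ctrl_ratios)
    p <- if (stats::sd(lc) < 1e-12) {
      if (stats::sd(ls) < 1e-12) {
        if (abs(mean(ls) - mean(lc)) < 1e-12) 1 else 0
      } else stats::t.test(ls, mu = mean(lc))$p.value
    } else if (paired) {
      stats::t.test(ls, lc, paired = TRUE)$p.value
    } else {
      stats::t.test(ls, lc)$p.value
    }
  }
  data.frame(mutant = mutant, rnai = rnai, score = mean(scores),
             log_ratio = mean(log(scores)), p_value = p, n_experiments = n,
             stringsAsFactors = FALSE)
}

#' Interaction scores for a grid of mutants and RNAi targets
#' @inheritParams interaction_score
#' @param mutants,rnais labels to combine (defaults: every non-reference
#'   strain, every non-control RNAi).
#' @return data frame, one row per (mutant, rnai).
#' @export
interaction_table <- function(plate, mutants = NULL, rnais = NULL, paired = FALSE) {
  ctrl <- attr(plate, "control_rnai")
  ref <- attr(plate, "reference_strain")
  mutants <- mutants %||% setdiff(unique(plate$strain), ref)
  rnais <- rnais %||% setdiff(unique(plate$rnai), ctrl)
  do.call(rbind, lapply(mutants, function(m) {
    do.call(rbind, lapply(rnais, function(r) interaction_score(plate, m, r, paired)))
  }))
}

#' Screen summary and hit list
#'
#' Averages scores per (mutant class, RNAi) pair — strains mapped to the
#' same class (e.g. two alleles of one gene) are averaged — and calls hits
#' where the mean interaction score is strictly below `threshold`
#' (default 0.7), sorted ascending.
#'
#' @param results rows from [interaction_score()]/[interaction_table()].
#' @param threshold hit threshold (default 0.7, strict `<`).
#' @param strain_class optional named character vector mapping strain ->
#'   class label.
#' @return list with `summary` (per-pair mean scores, `hit` flag) and
#'   `hits` (hit rows sorted by score).
#' @export
screen_summary <- function(results, threshold = 0.7, strain_class = NULL) {
  cls <- results$mutant
  if (!is.null(strain_class)) {
    mapped <- strain_class[results$mutant]
    cls <- ifelse(is.na(mapped), results$mutant, mapped)
  }
  key <- paste(cls, results$rnai, sep = "\r")
  agg_mean <- tapply(results$score, key, mean)
  parts <- strsplit(names(agg_mean), "\r", fixed = TRUE)
  summary <- data.frame(mutant = vapply(parts, `[`, "", 1),
                        rnai = vapply(parts, `[`, "", 2),
                        score = as.numeric(agg_mean), stringsAsFactors = FALSE)
  summary$hit <- summary$score < threshold
  summary <- summary[order(summary$score), , drop = FALSE]
  rownames(summary) <- NULL
  list(summary = summary, hits = summary[summary$hit, , drop = FALSE])
}
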