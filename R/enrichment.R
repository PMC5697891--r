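# enrichment: motif enrichment against PSI-matched controls, positional
# bias, motif co-occurrence, dinucleotide composition control, and
# intron-length-matched functional-term enrichment.

FLANKING_INTRON_LABELS <- c("upstream_intron_5p", "upstream_intron_3p",
                            "downstream_intron_5p", "downstream_intron_3p")

#' PSI-matched control sets
#'
#' Draws `n` random control sets from the background whose wild-type PSI
#' histogram (bins of `bin_width` percentage points) matches the case set;
#' within a set, sampling is without replacement. When a case bin has no
#' background events, the nearest non-empty bin is used instead (logged with
#' a message).
#'
#' @param case_psi named numeric vector: wild-type PSI per case event.
#' @param background_psi named numeric vector: PSI per background event
#'   (cases excluded by the caller).
#' @param n number of control sets (default 100).
#' @param bin_width PSI bin width in percentage points (default 5).
#' @param seed integer seed.
#' @return list of `n` character vectors of background event ids.
#' @export
sample_matched_controls <- function(case_psi, background_psi, n = 100,
                                    bin_width = 5, seed = 1) {
  background_psi <- background_psi[!names(background_psi) %in% names(case_psi)]
  if (length(background_psi) < length(case_psi)) {
    stop("background smaller than the case set")
  }
  bin_of <- function(psi) pmin(floor(psi / bin_width), floor(100 / bin_width) - 1)
  case_bins <- table(bin_of(case_psi))
  bg_bin <- bin_of(background_psi)
  bg_by_bin <- split(names(background_psi), bg_bin)
  avail_bins <- as.integer(names(bg_by_bin))
  with_substream(seed, "matched_controls", {
    lapply(seq_len(n), function(k) {
      picked <- character(0)
      for (b in names(case_bins)) {
        need <- case_bins[[b]]
        target <- as.integer(b)
        pool_bin <- if (as.character(target) %in% names(bg_by_bin)) target else {
          nb <- avail_bins[which.min(abs(avail_bins - target))]
          message("PSI bin ", target, " empty in background; using bin ", nb)
          nb
        }
        pool <- setdiff(bg_by_bin[[as.character(pool_bin)]], picked)
        if (length(pool) < need) {
          # spill into nearest bins, still without replacement within the set
          ord <- avail_bins[order(abs(avail_bins - target))]
          for (ob in ord) {
            pool <- union(pool, setdiff(bg_by_bin[[as.character(ob)]], picked))
            if (length(pool) >= need) break
          }
        }
        picked <- c(picked, sample(pool, need))
      }
      picked
    })
  })
}

events_with_hit <- function(hits, events, motif, labels, conserved_only) {
  h <- hits[hits$motif == motif & hits$label %in% labels, , drop = FALSE]
  if (conserved_only) {
    if (is.null(h$conserved)) stop("hits carry no conservation calls")
    h <- h[h$conserved, , drop = FALSE]
  }
  intersect(events, unique(h$event_id))
}

#' Motif enrichment at differentially spliced events
#'
#' Compares the proportion of case events carrying at least one qualifying
#' motif hit against PSI-matched control sets (the reported control value is
#' the mean over the `n` randomisations). The Fisher test is one-sided
#' toward enrichment; in `"averaged"` mode (default) the control column of
#' the 2x2 table is the rounded mean count over control sets, in `"pooled"`
#' mode the totals over all sets.
#'
#' @param calls differential-calls table from [differential_table()].
#' @param background_psi named numeric vector of wild-type PSI over the
#'   background event universe (alternatively spliced, e.g. 5-95 PSI).
#' @param hits `motif_hits` with conservation columns.
#' @param motif motif name as it appears in `hits`.
#' @param region_policy `"introns"` (flanking introns only) or
#'   `"introns_exon"` (alternative exon additionally considered).
#' @param conserved_only restrict to conserved hits (default TRUE).
#' @param direction `"all"`, `"increased_inclusion"` or
#'   `"increased_skipping"`; restricts the case set by call direction.
#' @param n number of control randomisations (default 100).
#' @param seed integer seed for control sampling.
#' @param mode `"averaged"` or `"pooled"` control comparison.
#' @return one-row data frame: case/control proportions and the one-sided
#'   Fisher p-value, with the policy and direction recorded.
#' @export
motif_enrichment <- function(calls, background_psi, hits, motif,
                             region_policy = c("introns", "introns_exon"),
                             conserved_only = TRUE,
                             direction = c("all", "increased_inclusion",
                                           "increased_skipping"),
                             n = 100, seed = 1, mode = c("averaged", "pooled")) {
  region_policy <- match.arg(region_policy)
  direction <- match.arg(direction)
  mode <- match.arg(mode)
  labels <- FLANKING_INTRON_LABELS
  if (region_policy == "introns_exon") labels <- c(labels, "alt_exon")
  cases <- calls$event_id[calls$called]
  if (direction != "all") {
    cases <- calls$event_id[calls$called & calls$direction == direction]
  }
  if (!length(cases)) stop("empty case set")
  case_psi <- stats::setNames(calls$psi_wt[match(cases, calls$event_id)], cases)
  case_psi <- case_psi[!is.na(case_psi)]
  ctrl_sets <- sample_matched_controls(case_psi, background_psi, n = n, seed = seed)
  n_cases <- length(case_psi)
  case_with <- length(events_with_hit(hits, names(case_psi), motif, labels, conserved_only))
  ctrl_with <- vapply(ctrl_sets, function(s) {
    length(events_with_hit(hits, s, motif, labels, conserved_only))
  }, 0L)
  ctrl_prop <- mean(ctrl_with) / n_cases
  if (mode == "averaged") {
    cw <- round(mean(ctrl_with)); cn <- n_cases
  } else {
    cw <- sum(ctrl_with); cn <- n_cases * n
  }
  tab <- matrix(c(case_with, n_cases - case_with, cw, cn - cw), nrow = 2, byrow = TRUE)
  p <- stats::fisher.test(tab, alternative = "greater")$p.value
  data.frame(motif = motif, n_cases = n_cases, cases_with_motif = case_with,
             case_proportion = case_with / n_cases,
             control_proportion = ctrl_prop, p_value = p,
             region_policy = region_policy, conserved_only = conserved_only,
             direction = direction, n_randomizations = n, mode = mode,
             stringsAsFactors = FALSE)
}

#' Positional bias of conserved motif hits
#'
#' Among events with at least one conserved hit of the motif anywhere,
#' reports the proportion with a conserved hit in each region class
#' (alternative exon, upstream/downstream intron, constitutive exons).
#' An event can contribute to several classes, so proportions need not
#' sum to 1.
#'
#' @param hits `motif_hits` with conservation calls.
#' @param motif motif name.
#' @return data frame of region-class proportions (empty when no conserved
#'   hits exist).
#' @export
positional_bias <- function(hits, motif) {
  h <- hits[hits$motif == motif & hits$conserved, , drop = FALSE]
  if (!nrow(h)) return(data.frame(region = character(0), proportion = numeric(0)))
  coarse <- c(alt_exon = "alt_exon",
              upstream_intron_5p = "upstream_intron", upstream_intron_3p = "upstream_intron",
              downstream_intron_5p = "downstream_intron", downstream_intron_3p = "downstream_intron",
              constitutive_up = "constitutive_exon", constitutive_down = "constitutive_exon")
  h$region <- coarse[h$label]
  evs <- unique(h$event_id)
  regions <- c("alt_exon", "upstream_intron", "downstream_intron", "constitutive_exon")
  data.frame(region = regions,
             proportion = vapply(regions, function(r) {
               length(unique(h$event_id[h$region == r])) / length(evs)
             }, 0), row.names = NULL, stringsAsFactors = FALSE)
}

#' Motif co-occurrence statistics
#'
#' Two motifs co-occur in an event when one or more (conserved) hits of each
#' are present within either flanking intron. The expected count follows the
#' multiplicative model `N * (n_a/N) * (n_b/N)`; significance is the upper
#' tail of the cumulative hypergeometric distribution,
#' `P(X >= observed)` with `X ~ Hypergeometric(N, n_a, n_b)`.
#'
#' @param hits `motif_hits` (with conservation columns when
#'   `conserved_only`).
#' @param events character vector: the event universe considered.
#' @param motif_a,motif_b motif names.
#' @param conserved_only restrict to conserved hits (default TRUE).
#' @return one-row data frame: `N`, `n_a`, `n_b`, `observed`, `expected`,
#'   `p_value`.
#' @export
cooccurrence <- function(hits, events, motif_a, motif_b, conserved_only = TRUE) {
  N <- length(unique(events))
  if (N == 0) stop("empty event universe")
  ea <- events_with_hit(hits, events, motif_a, FLANKING_INTRON_LABELS, conserved_only)
  eb <- events_with_hit(hits, events, motif_b, FLANKING_INTRON_LABELS, conserved_only)
  obs <- length(intersect(ea, eb))
  n_a <- length(ea); n_b <- length(eb)
  expected <- N * (n_a / N) * (n_b / N)
  p <- cum_hyper_upper(obs, N, n_a, n_b)
  data.frame(motif_a = motif_a, motif_b = motif_b, N = N, n_a = n_a, n_b = n_b,
             observed = obs, expected = expected, p_value = p,
             stringsAsFactors = FALSE)
}

#' Co-occurrence over every motif pair
#' @inheritParams cooccurrence
#' @param motifs character vector of motif names.
#' @return data frame, one row per unordered pair.
#' @export
cooccurrence_table <- function(hits, events, motifs, conserved_only = TRUE) {
  pairs <- utils::combn(motifs, 2)
  do.call(rbind, lapply(seq_len(ncol(pairs)), function(i) {
    cooccurrence(hits, events, pairs[1, i], pairs[2, i], conserved_only)
  }))
}

dinucleotide_freqs <- function(seq) {
  s <- toupper(chartr("U", "T", seq))
  n <- nchar(s)
  bases <- c("A", "C", "G", "T")
  dints <- as.vector(outer(bases, bases, paste0))
  out <- stats::setNames(rep(NA_real_, 16), dints)
  if (n < 2) return(out)
  chars <- strsplit(s, "")[[1]]
  di <- paste0(chars[-n], chars[-1])
  tab <- table(factor(di, levels = dints))
  out[] <- as.numeric(tab) / (n - 1)
  out
}

#' Dinucleotide-composition comparison between two region sets
#'
#' For each of the 16 overlapping dinucleotides (denominator length-1),
#' compares per-region frequencies between the two sets with a two-sided
#' Mann-Whitney U test and reports the fold difference of means. Regions
#' shorter than 2 nt are skipped.
#'
#' @param regions_a,regions_b character vectors of region sequences.
#' @return data frame: `dinucleotide` (RNA alphabet), `mean_a`, `mean_b`,
#'   `fold`, `p_value`.
#' @export
dinucleotide_comparison <- function(regions_a, regions_b) {
  if (!length(regions_a) || !length(regions_b)) stop("both region sets must be non-empty")
  fa <- t(vapply(regions_a, dinucleotide_freqs, numeric(16)))
  fb <- t(vapply(regions_b, dinucleotide_freqs, numeric(16)))
  fa <- fa[stats::complete.cases(fa), , drop = FALSE]
  fb <- fb[stats::complete.cases(fb), , drop = FALSE]
  dints <- colnames(fa)
  do.call(rbind, lapply(seq_along(dints), function(j) {
    a <- fa[, j]; b <- fb[, j]
    p <- if (length(a) && length(b)) {
      suppressWarnings(stats::wilcox.test(a, b, exact = FALSE)$p.value)
    } else NA_real_
    data.frame(dinucleotide = chartr("T", "U", dints[j]),
               mean_a = mean(a), mean_b = mean(b),
               fold = if (mean(b) > 0) mean(a) / mean(b) else NA_real_,
               p_value = p, stringsAsFactors = FALSE)
  }))
}

#' Functional-term enrichment with intron-length-matched controls
#'
#' For each term with at least 3 genes: the proportion of term genes flagged
#' (carrying co-occurring motifs) is compared with the mean proportion over
#' `n` random gene sets drawn from non-term genes matched on total intron
#' length (quantile bins). A plain hypergeometric enrichment p-value over
#' the gene universe is reported alongside.
#'
#' @param term_map data frame with columns `gene` and `term`.
#' @param flags named logical vector: gene -> has co-occurring motifs.
#' @param intron_lengths named numeric vector: total intron length per gene
#'   (must cover all genes).
#' @param n number of random control sets (default 1000).
#' @param bins number of intron-length quantile bins (default 10).
#' @param seed integer seed.
#' @return data frame, one row per term kept; terms with fewer than 3 genes
#'   are skipped with a note column in the attribute `skipped`.
#' @export
term_enrichment_length_matched <- function(term_map, flags, intron_lengths,
                                           n = 1000, bins = 10, seed = 1) {
  universe <- names(flags)
  if (!all(universe %in% names(intron_lengths))) {
    stop("intron lengths must be available for all genes")
  }
  qs <- stats::quantile(intron_lengths[universe], probs = seq(0, 1, length.out = bins + 1))
  qs[1] <- -Inf; qs[length(qs)] <- Inf
  bin_of <- cut(intron_lengths[universe], qs, labels = FALSE)
  names(bin_of) <- universe
  terms <- unique(term_map$term)
  skipped <- character(0)
  rows <- list()
  with_substream(seed, "term_controls", {
    for (tm in terms) {
      tg <- intersect(unique(term_map$gene[term_map$term == tm]), universe)
      if (length(tg) < 3) { skipped <- c(skipped, tm); next }
      pool <- setdiff(universe, tg)
      pool_by_bin <- split(pool, bin_of[pool])
      prop_term <- mean(flags[tg])
      need <- table(bin_of[tg])
      ctrl_props <- vapply(seq_len(n), function(k) {
        picked <- character(0)
        for (b in names(need)) {
          cand <- pool_by_bin[[b]]
          if (is.null(cand) || length(cand) < need[[b]]) {
            cand <- unique(c(cand, pool))
          }
          picked <- c(picked, sample(cand, need[[b]]))
        }
        mean(flags[picked])
      }, 0)
      flagged <- universe[flags[universe]]
      p_hyper <- cum_hyper_upper(sum(flags[tg]), length(universe),
                                 length(flagged), length(tg))
      rows[[length(rows) + 1L]] <- data.frame(
        term = tm, n_genes = length(tg), prop_flagged = prop_term,
        control_prop = mean(ctrl_props), p_hyper = p_hyper,
        stringsAsFactors = FALSE)
    }
  })
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(term = character(0), n_genes = integer(0),
               prop_flagged = numeric(0), control_prop = numeric(0),
               p_hyper = numeric(0))
  attr(out, "skipped") <- skipped
  out
}
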