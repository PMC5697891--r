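# differential_splicing: PSI, testability filters, wild-type vs mutant calls.

event_support <- function(event, counts) {
  incl <- sum(jc_count(counts, event$inclusion_junctions$seq_id,
                       event$inclusion_junctions$donor, event$inclusion_junctions$acceptor))
  excl <- sum(jc_count(counts, event$exclusion_junctions$seq_id,
                       event$exclusion_junctions$donor, event$exclusion_junctions$acceptor))
  c(inclusion = incl, exclusion = excl)
}

#' Percent spliced in (PSI) for one event in one sample
#'
#' PSI = 100 * (half the summed inclusion-junction reads) divided by (the
#' same half-sum plus the skip-junction reads). The half accounts for each
#' included molecule spanning two inclusion junctions. For mutually-exclusive
#' events the exclusion sum is halved as well (each excluding molecule also
#' spans two junctions). Supports are recorded unhalved. Absent junction keys
#' count 0; when all counts are 0 the PSI is missing.
#'
#' @param event an `as_event`.
#' @param counts a [junction_counts()] table.
#' @return data frame row: `event_id`, `sample_id`, `psi`,
#'   `inclusion_support`, `exclusion_support`.
#' @export
compute_psi <- function(event, counts) {
  s <- event_support(event, counts)
  incl <- s[["inclusion"]]; excl <- s[["exclusion"]]
  excl_eff <- if (identical(event$type, "mutually_exclusive")) excl / 2 else excl
  psi <- if (incl + excl == 0) NA_real_ else 100 * (incl / 2) / (incl / 2 + excl_eff)
  data.frame(event_id = event$event_id, sample_id = attr(counts, "sample_id") %||% "sample",
             psi = psi, inclusion_support = incl, exclusion_support = excl,
             stringsAsFactors = FALSE)
}

#' PSI records for a whole catalog
#' @param catalog an `as_catalog`.
#' @param counts a [junction_counts()] table (one sample).
#' @return data frame, one row per event.
#' @export
psi_table <- function(catalog, counts) {
  do.call(rbind, lapply(catalog, compute_psi, counts = counts))
}

#' Testability filter for a differential comparison
#'
#' An event is testable when both samples have at least `min_reads` combined
#' reads across the two splice forms, and (for cassette and
#' mutually-exclusive events) the two adjacent inclusion junctions differ by
#' no more than `max_imbalance`-fold in both samples. A ratio of exactly
#' `max_imbalance` passes (the rule excludes a *greater than* 30-fold
#' difference); one adjacent junction at 0 with the other positive fails.
#'
#' @param event an `as_event`.
#' @param wt_counts,mut_counts [junction_counts()] tables.
#' @param min_reads combined-read threshold (default 10).
#' @param max_imbalance adjacent-junction fold threshold (default 30).
#' @return list with `testable` (flag) and `reason` (`NA` when testable,
#'   otherwise `"min_reads"` or `"adjacent_imbalance"`).
#' @export
filter_testable <- function(event, wt_counts, mut_counts, min_reads = 10,
                            max_imbalance = 30) {
  for (counts in list(wt_counts, mut_counts)) {
    s <- event_support(event, counts)
    if (sum(s) < min_reads) {
      return(list(testable = FALSE, reason = "min_reads"))
    }
  }
  if (event$type %in% c("cassette", "mutually_exclusive")) {
    adj <- event$inclusion_junctions[event$inclusion_junctions$role %in% c("C1A", "AC2"), ]
    for (counts in list(wt_counts, mut_counts)) {
      v <- jc_count(counts, adj$seq_id, adj$donor, adj$acceptor)
      if (length(v) == 2 && any(v > 0)) {
        if (min(v) == 0 || max(v) / min(v) > max_imbalance) {
          return(list(testable = FALSE, reason = "adjacent_imbalance"))
        }
      }
    }
  }
  list(testable = TRUE, reason = NA_character_)
}

#' Differential-splicing call for one event
#'
#' Builds the 2x2 table of unhalved integer inclusion/exclusion read sums for
#' the two samples, applies the two-sided Fisher exact test, and calls the
#' event when `p < alpha` and `|delta PSI| >= min_delta` (a change of exactly
#' `min_delta` satisfies the rule).
#'
#' @param event an `as_event`.
#' @param wt_counts,mut_counts [junction_counts()] tables.
#' @param alpha significance threshold (default 0.05).
#' @param min_delta minimum |PSI change| in percentage points (default 15).
#' @param check_testable error on untestable events (default TRUE).
#' @return data frame row: `event_id`, `type`, `psi_wt`, `psi_mut`,
#'   `delta_psi`, `p_value`, `called`, `direction`.
#' @export
call_differential <- function(event, wt_counts, mut_counts, alpha = 0.05,
                              min_delta = 15, check_testable = TRUE) {
  if (check_testable) {
    ft <- filter_testable(event, wt_counts, mut_counts)
    if (!ft$testable) {
      stop("event ", event$event_id, " is not testable (", ft$reason,
           "); see filter_testable()")
    }
  }
  s_wt <- event_support(event, wt_counts)
  s_mut <- event_support(event, mut_counts)
  tab <- matrix(c(s_wt, s_mut), nrow = 2, byrow = TRUE)
  p <- stats::fisher.test(tab, alternative = "two.sided")$p.value
  psi_wt <- compute_psi(event, wt_counts)$psi
  psi_mut <- compute_psi(event, mut_counts)$psi
  delta <- psi_mut - psi_wt
  called <- !is.na(delta) && p < alpha && abs(delta) >= min_delta
  direction <- if (is.na(delta) || delta == 0) NA_character_
               else if (delta > 0) "increased_inclusion" else "increased_skipping"
  data.frame(event_id = event$event_id, type = event$type,
             psi_wt = psi_wt, psi_mut = psi_mut, delta_psi = delta,
             p_value = p, called = called, direction = direction,
             stringsAsFactors = FALSE)
}

#' Differential calls for a whole catalog
#'
#' Applies [filter_testable()] and [call_differential()] to every event;
#' untestable events are reported with their exclusion reason and no call.
#'
#' @inheritParams call_differential
#' @param catalog an `as_catalog`.
#' @return data frame mirroring the per-event calls table: `event_id`,
#'   `type`, `psi_wt`, `psi_mut`, `delta_psi`, `p_value`, `called`,
#'   `direction`, `testable`, `exclusion_reason`.
#' @export
differential_table <- function(catalog, wt_counts, mut_counts, alpha = 0.05,
                               min_delta = 15) {
  rows <- lapply(catalog, function(ev) {
    ft <- filter_testable(ev, wt_counts, mut_counts)
    if (!ft$testable) {
      data.frame(event_id = ev$event_id, type = ev$type,
                 psi_wt = compute_psi(ev, wt_counts)$psi,
                 psi_mut = compute_psi(ev, mut_counts)$psi,
                 delta_psi = NA_real_, p_value = NA_real_, called = FALSE,
                 direction = NA_character_, testable = FALSE,
                 exclusion_reason = ft$reason, stringsAsFactors = FALSE)
    } else {
      r <- call_differential(ev, wt_counts, mut_counts, alpha = alpha,
                             min_delta = min_delta, check_testable = FALSE)
      r$testable <- TRUE
      r$exclusion_reason <- NA_character_
      r
    }
  })
  do.call(rbind, rows)
}

#' Enrichment of the overlap between two call sets
#'
#' One-tailed hypergeometric test of the overlap between two event sets
#' drawn from a common background. Fold = observed / (|a|*|b|/|background|).
#'
#' @param calls_a,calls_b character vectors of event ids (subsets of
#'   `background`).
#' @param background character vector of event ids.
#' @return list with `overlap`, `fold`, `p`.
#' @export
overlap_enrichment <- function(calls_a, calls_b, background) {
  if (!length(background)) stop("empty background")
  a <- unique(calls_a); b <- unique(calls_b); bg <- unique(background)
  if (!all(a %in% bg) || !all(b %in% bg)) {
    stop("call sets must be subsets of the background")
  }
  obs <- length(intersect(a, b))
  expected <- length(a) * length(b) / length(bg)
  fold <- if (expected > 0) obs / expected else NA_real_
  p <- cum_hyper_upper(obs, length(bg), length(a), length(b))
  list(overlap = obs, fold = fold, p = p)
}

#' Pearson correlation of PSI values between two samples
#'
#' @param records_a,records_b PSI tables from [psi_table()] (or named numeric
#'   vectors of PSI keyed by event id). Events missing in either sample, or
#'   with undefined PSI, are dropped.
#' @return Pearson correlation coefficient.
#' @export
psi_correlation <- function(records_a, records_b) {
  as_vec <- function(x) {
    if (is.data.frame(x)) stats::setNames(x$psi, x$event_id) else x
  }
  va <- as_vec(records_a); vb <- as_vec(records_b)
  shared <- intersect(names(va), names(vb))
  va <- va[shared]; vb <- vb[shared]
  keep <- !is.na(va) & !is.na(vb)
  if (sum(keep) < 3) stop("need at least 3 shared events with defined PSI")
  stats::cor(va[keep], vb[keep], method = "pearson")
}
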