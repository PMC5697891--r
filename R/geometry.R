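# geometry: inter-motif spacing, spacing conservation across species,
# ordering conservation, and relative-position analyses.

#' All splice-proximal regions of a catalog
#' @param catalog an `as_catalog`.
#' @param genome named sequences (or NULL).
#' @param window region window (default 300).
#' @return data frame of regions for every event.
#' @export
event_regions_table <- function(catalog, genome = NULL, window = 300) {
  do.call(rbind, lapply(catalog, event_regions, genome = genome, window = window))
}

# sense-axis coordinate of a position given its region and 0-based offset:
# monotone increasing along the pre-mRNA for either strand
sense_coord <- function(region_start, region_end, strand, offset) {
  ifelse(strand == "+", region_start + offset, offset - region_end)
}

#' Closest-pair spacing between two motifs
#'
#' Among all cross pairs of motif instances where one lies fully upstream of
#' the other, picks the pair with the smallest spacing (end of the upstream
#' motif to start of the downstream motif). Overlapping pairs are not
#' eligible; adjacent motifs give spacing 0.
#'
#' @param starts_a,starts_b 0-based start offsets of the two motifs within
#'   one region (sense coordinates).
#' @param len_a,len_b motif lengths.
#' @return list with `spacing`, `start_up`, `start_down`, `upstream`
#'   (`"a"` or `"b"`), or `NULL` when no non-overlapping pair exists.
#' @export
pair_spacing <- function(starts_a, len_a, starts_b, len_b) {
  best <- NULL
  for (sa in starts_a) {
    for (sb in starts_b) {
      if (sb >= sa + len_a) {
        sp <- sb - (sa + len_a); up <- "a"; su <- sa; sd <- sb
      } else if (sa >= sb + len_b) {
        sp <- sa - (sb + len_b); up <- "b"; su <- sb; sd <- sa
      } else next
      if (is.null(best) || sp < best$spacing) {
        best <- list(spacing = sp, start_up = su, start_down = sd, upstream = up)
      }
    }
  }
  best
}

#' Spacing records for a motif pair across a catalog
#'
#' One record per (event, intronic sub-region) in which both motifs occur;
#' the closest-instance rule of [pair_spacing()] selects the measured pair.
#' Pairs whose instances sit in different sub-regions yield no record.
#'
#' @param hits `motif_hits` table.
#' @param regions region table from [event_regions_table()].
#' @param motif_a,motif_b motif names.
#' @param conserved_only restrict to conserved hits (default FALSE).
#' @return data frame of spacing records with region coordinates attached.
#' @export
spacing_table <- function(hits, regions, motif_a, motif_b, conserved_only = FALSE) {
  h <- hits[hits$label %in% INTRON_LABELS & hits$motif %in% c(motif_a, motif_b), , drop = FALSE]
  if (conserved_only) h <- h[h$conserved, , drop = FALSE]
  if (!nrow(h)) return(NULL)
  keys <- unique(h[, c("event_id", "label")])
  rows <- list()
  for (i in seq_len(nrow(keys))) {
    hh <- h[h$event_id == keys$event_id[i] & h$label == keys$label[i], , drop = FALSE]
    ha <- hh[hh$motif == motif_a, , drop = FALSE]
    hb <- hh[hh$motif == motif_b, , drop = FALSE]
    if (!nrow(ha) || !nrow(hb)) next
    ps <- pair_spacing(ha$offset, ha$length[1], hb$offset, hb$length[1])
    if (is.null(ps)) next
    reg <- regions[regions$event_id == keys$event_id[i] &
                     regions$label == keys$label[i], , drop = FALSE][1, ]
    off_a <- if (ps$upstream == "a") ps$start_up else ps$start_down
    off_b <- if (ps$upstream == "b") ps$start_up else ps$start_down
    both_cons <- if (!is.null(hh$conserved)) {
      any(ha$conserved[ha$offset == off_a]) && any(hb$conserved[hb$offset == off_b])
    } else NA
    rows[[length(rows) + 1L]] <- data.frame(
      event_id = keys$event_id[i], label = keys$label[i],
      seq_id = reg$seq_id, region_start = reg$start, region_end = reg$end,
      strand = reg$strand, motif_a = motif_a, motif_b = motif_b,
      len_a = ha$length[1], len_b = hb$length[1],
      spacing = ps$spacing, upstream_motif = if (ps$upstream == "a") motif_a else motif_b,
      offset_up = ps$start_up, offset_down = ps$start_down,
      both_conserved = both_cons, stringsAsFactors = FALSE)
  }
  if (!length(rows)) return(NULL)
  do.call(rbind, rows)
}

#' Spacing conservation across species
#'
#' A spacing record is conserved when at least `min_species` other species
#' contain both motifs in the aligned region with a spacing within
#' `tolerance` (default 20%) of the reference spacing. Per species, the
#' cross pair whose spacing is most similar to the reference spacing is
#' used. A reference spacing of 0 requires spacing 0 in the other species.
#'
#' @param record one row of [spacing_table()].
#' @param alignments an `alignment_set`.
#' @param motifs named motif list (names as in the record).
#' @param tolerance relative tolerance (default 0.20).
#' @param min_species species needed (default 2).
#' @return list with `conserved`, `n_supporting`, `species_spacings`
#'   (named numeric, NA when a species lacks a motif), and `note`
#'   (`"unaligned"` when the region has no alignment block).
#' @export
spacing_conservation <- function(record, alignments, motifs, tolerance = 0.20,
                                 min_species = 2) {
  ma <- as_motif(motifs[[record$motif_a]])
  mb <- as_motif(motifs[[record$motif_b]])
  sa <- species_region_matches(alignments, record$seq_id, record$region_start,
                               record$region_end, record$strand, ma)
  sb <- species_region_matches(alignments, record$seq_id, record$region_start,
                               record$region_end, record$strand, mb)
  if (is.null(sa) || is.null(sb)) {
    return(list(conserved = FALSE, n_supporting = 0L,
                species_spacings = numeric(0), note = "unaligned"))
  }
  others <- setdiff(names(sa), alignments$reference)
  ref_sp <- record$spacing
  spac <- stats::setNames(rep(NA_real_, length(others)), others)
  for (sp in others) {
    a <- sa[[sp]]; b <- sb[[sp]]
    if (!length(a) || !length(b)) next
    cand <- c()
    for (x in a) for (y in b) {
      if (y >= x + ma$length) cand <- c(cand, y - (x + ma$length))
      else if (x >= y + mb$length) cand <- c(cand, x - (y + mb$length))
    }
    if (length(cand)) spac[sp] <- cand[which.min(abs(cand - ref_sp))]
  }
  ok <- !is.na(spac) & abs(spac - ref_sp) <= tolerance * ref_sp
  list(conserved = sum(ok) >= min_species, n_supporting = sum(ok),
       species_spacings = spac, note = NA_character_)
}

#' Cumulative conservation-by-distance curve
#'
#' For each distance threshold, the proportion of motif-pair records with
#' spacing at most that threshold whose two motifs are both conserved. The
#' value at the maximum distance equals the overall proportion, reported as
#' the reference line.
#'
#' @param records data frame with `spacing` and `both_conserved` columns.
#' @param thresholds distance thresholds; defaults to the sorted unique
#'   spacings.
#' @return data frame `threshold`, `n_pairs`, `prop_conserved`, with the
#'   overall proportion in attribute `overall`.
#' @export
conservation_by_distance <- function(records, thresholds = NULL) {
  stopifnot(nrow(records) >= 1)
  if (is.null(thresholds)) thresholds <- sort(unique(records$spacing))
  out <- do.call(rbind, lapply(thresholds, function(x) {
    sel <- records$spacing <= x
    data.frame(threshold = x, n_pairs = sum(sel),
               prop_conserved = if (any(sel)) mean(records$both_conserved[sel]) else NA_real_)
  }))
  attr(out, "overall") <- mean(records$both_conserved)
  out
}

# species matches near a reference hit: offsets within `window` nt of the
# reference offset in the region's sense coordinates
qualifying_species_match <- function(matches, ref_offset, window) {
  if (!length(matches)) return(NA_integer_)
  d <- abs(matches - ref_offset)
  if (min(d) > window) return(NA_integer_)
  matches[which.min(d)]
}

#' Ordering conservation for one motif pair
#'
#' Considers every event where both motifs occur (anywhere) in the flanking
#' introns. Per event, the closest-pair instances define the reference
#' order; per other species carrying both motifs within `window` nt of the
#' reference instances, the order is recorded as preserved or reversed.
#' Order preservation is tested pair-wide by a chi-squared test of
#' preserved:reversed against 50:50 over all (event, species) observations;
#' when significant, the pair is `unidirectional` if one reference order
#' dominates across events (two-sided binomial test), else `bidirectional`;
#' otherwise `not_conserved`.
#'
#' @param hits `motif_hits` table.
#' @param regions region table from [event_regions_table()].
#' @param alignments an `alignment_set`.
#' @param motifs named motif list.
#' @param motif_a,motif_b motif names.
#' @param window species-match window in nt (default 25).
#' @param alpha significance threshold for both tests (default 0.05).
#' @return one-row data frame with the observation counts, test p-values
#'   and classification (plus a `note` for insufficient events).
#' @export
ordering_conservation <- function(hits, regions, alignments, motifs,
                                  motif_a, motif_b, window = 25, alpha = 0.05) {
  h <- hits[hits$label %in% INTRON_LABELS & hits$motif %in% c(motif_a, motif_b), , drop = FALSE]
  evs <- intersect(unique(h$event_id[h$motif == motif_a]),
                   unique(h$event_id[h$motif == motif_b]))
  n_pres <- 0L; n_rev <- 0L
  ref_orders <- character(0)
  n_events_obs <- 0L
  for (ev in evs) {
    ha <- h[h$event_id == ev & h$motif == motif_a, , drop = FALSE]
    hb <- h[h$event_id == ev & h$motif == motif_b, , drop = FALSE]
    reg_of <- function(r) {
      regions[regions$event_id == ev & regions$label == r$label &
                regions$part == r$part, , drop = FALSE][1, ]
    }
    pos <- function(r) {
      reg <- reg_of(r)
      sense_coord(reg$start, reg$end, reg$strand, r$offset)
    }
    pa <- vapply(seq_len(nrow(ha)), function(i) pos(ha[i, ]), 0)
    pb <- vapply(seq_len(nrow(hb)), function(i) pos(hb[i, ]), 0)
    d <- outer(pa, pb, function(x, y) abs(x - y))
    ij <- which(d == min(d), arr.ind = TRUE)[1, ]
    ra <- ha[ij[1], ]; rb <- hb[ij[2], ]
    if (pa[ij[1]] == pb[ij[2]]) next  # identical starts: order undefined
    ref_ab <- pa[ij[1]] < pb[ij[2]]
    ref_orders <- c(ref_orders, if (ref_ab) "ab" else "ba")
    n_events_obs <- n_events_obs + 1L
    # per-species observations
    rega <- reg_of(ra); regb <- reg_of(rb)
    sma <- species_region_matches(alignments, rega$seq_id, rega$start, rega$end,
                                  rega$strand, motifs[[motif_a]])
    smb <- species_region_matches(alignments, regb$seq_id, regb$start, regb$end,
                                  regb$strand, motifs[[motif_b]])
    if (is.null(sma) || is.null(smb)) next
    others <- setdiff(intersect(names(sma), names(smb)), alignments$reference)
    for (sp in others) {
      qa <- qualifying_species_match(sma[[sp]], ra$offset, window)
      qb <- qualifying_species_match(smb[[sp]], rb$offset, window)
      if (is.na(qa) || is.na(qb)) next
      spa <- sense_coord(rega$start, rega$end, rega$strand, qa)
      spb <- sense_coord(regb$start, regb$end, regb$strand, qb)
      if (spa == spb) next
      sp_ab <- spa < spb
      if (sp_ab == ref_ab) n_pres <- n_pres + 1L else n_rev <- n_rev + 1L
    }
  }
  res <- data.frame(motif_a = motif_a, motif_b = motif_b,
                    n_events = n_events_obs, n_preserved = n_pres,
                    n_reversed = n_rev, chi_p = NA_real_,
                    direction_p = NA_real_, classification = "not_conserved",
                    note = NA_character_, stringsAsFactors = FALSE)
  if (n_events_obs < 3) {
    res$note <- "insufficient_events"
    return(res)
  }
  if (n_pres + n_rev == 0) return(res)
  chi <- suppressWarnings(stats::chisq.test(c(n_pres, n_rev), p = c(0.5, 0.5)))
  res$chi_p <- chi$p.value
  if (chi$p.value < alpha && n_pres > n_rev) {
    n_ab <- sum(ref_orders == "ab")
    bt <- stats::binom.test(n_ab, length(ref_orders), p = 0.5,
                            alternative = "two.sided")
    res$direction_p <- bt$p.value
    res$classification <- if (bt$p.value < alpha) "unidirectional" else "bidirectional"
  }
  res
}

#' Ordering-conservation screen over every motif pair
#'
#' Runs [ordering_conservation()] for each unordered pair of the supplied
#' motifs; one record per pair (so `k` motifs yield `choose(k, 2)` rows).
#'
#' @inheritParams ordering_conservation
#' @param motifs named motif list; all pairs of `names(motifs)` are tested.
#' @return data frame, one row per pair.
#' @export
ordering_screen <- function(hits, regions, alignments, motifs, window = 25,
                            alpha = 0.05) {
  nm <- names(motifs)
  pairs <- utils::combn(nm, 2)
  do.call(rbind, lapply(seq_len(ncol(pairs)), function(i) {
    ordering_conservation(hits, regions, alignments, motifs,
                          pairs[1, i], pairs[2, i], window = window, alpha = alpha)
  }))
}

#' Relative positions of one motif around another
#'
#' Per event with both motifs in the flanking introns, the signed sense
#' offset `start(other) - start(anchor)` of the closest-pair instances; a
#' positive value places the other motif downstream of the anchor. The
#' upstream/downstream bias is tested with a two-sided binomial test on the
#' sign counts (zero offsets are excluded from the test and reported
#' separately).
#'
#' @param hits `motif_hits` table.
#' @param regions region table.
#' @param anchor_motif,other_motif motif names.
#' @return list with `offsets` (named by event), `n_zero`, `p_bias`.
#' @export
relative_positions <- function(hits, regions, anchor_motif, other_motif) {
  h <- hits[hits$label %in% INTRON_LABELS & hits$motif %in% c(anchor_motif, other_motif), , drop = FALSE]
  evs <- intersect(unique(h$event_id[h$motif == anchor_motif]),
                   unique(h$event_id[h$motif == other_motif]))
  offs <- numeric(0)
  for (ev in evs) {
    ha <- h[h$event_id == ev & h$motif == anchor_motif, , drop = FALSE]
    hb <- h[h$event_id == ev & h$motif == other_motif, , drop = FALSE]
    pos <- function(r) {
      reg <- regions[regions$event_id == ev & regions$label == r$label &
                       regions$part == r$part, , drop = FALSE][1, ]
      sense_coord(reg$start, reg$end, reg$strand, r$offset)
    }
    pa <- vapply(seq_len(nrow(ha)), function(i) pos(ha[i, ]), 0)
    pb <- vapply(seq_len(nrow(hb)), function(i) pos(hb[i, ]), 0)
    d <- outer(pa, pb, function(x, y) abs(x - y))
    ij <- which(d == min(d), arr.ind = TRUE)[1, ]
    offs[ev] <- pb[ij[2]] - pa[ij[1]]
  }
  nz <- offs[offs != 0]
  p <- if (length(nz)) {
    stats::binom.test(sum(nz > 0), length(nz), p = 0.5,
                      alternative = "two.sided")$p.value
  } else NA_real_
  list(offsets = offs, n_zero = sum(offs == 0), p_bias = p)
}
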