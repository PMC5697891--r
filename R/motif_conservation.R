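# motif_conservation: splice-proximal regions, motif scanning, and
# conservation calls against the multi-species alignment.
#
# Region labels (sense orientation): alt_exon, upstream_intron_5p,
# upstream_intron_3p, downstream_intron_5p, downstream_intron_3p,
# constitutive_up, constitutive_down. Each region is at most `window`
# (default 300) nt, anchored at its proximal splice site; introns shorter
# than twice the window are split at the midpoint so the two sub-regions
# stay disjoint.

INTRON_LABELS <- c("upstream_intron_5p", "upstream_intron_3p",
                   "downstream_intron_5p", "downstream_intron_3p")

split_intron_region <- function(lo, hi, window, five_prime_left) {
  len <- hi - lo
  if (len <= 0) return(NULL)
  if (len >= 2 * window) {
    left <- c(lo, lo + window)
    right <- c(hi - window, hi)
  } else {
    mid <- lo + len %/% 2
    left <- c(lo, mid)
    right <- c(mid, hi)
  }
  out <- rbind(left, right)
  suffix <- if (five_prime_left) c("5p", "3p") else c("3p", "5p")
  data.frame(suffix = suffix, start = out[, 1], end = out[, 2],
             stringsAsFactors = FALSE)
}

# genomic geometry of an event: left/right flank and alternative span
event_geometry <- function(event) {
  fu <- event$flank_up; fd <- event$flank_down
  if (fu[["start"]] <= fd[["start"]]) { lf <- fu; rf <- fd } else { lf <- fd; rf <- fu }
  j <- rbind(event$inclusion_junctions, event$exclusion_junctions)
  pts <- c(j$donor, j$acceptor, event$alt_region$start, event$alt_region$end)
  inner <- pts[pts > lf[["end"]] & pts < rf[["start"]]]
  if (!length(inner)) inner <- c(event$alt_region$start, event$alt_region$end)
  list(lf = lf, rf = rf, a_lo = min(inner), a_hi = max(inner))
}

#' Splice-proximal regions of an event
#'
#' Emits up to seven labelled regions: the alternative exon(s), the two
#' sub-regions of each flanking intron (5'- and 3'-splice-site proximal),
#' and the splice-site-proximal ends of the flanking constitutive exons.
#' Sequences are reported on the pre-mRNA sense strand (reverse complemented
#' for minus-strand genes).
#'
#' @param event an `as_event`.
#' @param genome named sequence vector from [read_genome()] (`NULL` to skip
#'   sequence extraction).
#' @param window maximum distance from the anchoring splice site (default
#'   300 nt).
#' @return data frame with `event_id`, `label`, `part`, `seq_id`, `start`,
#'   `end` (0-based half-open genomic), `strand`, `anchor`, `seq`.
#' @export
event_regions <- function(event, genome = NULL, window = 300) {
  geo <- event_geometry(event)
  plus <- event$strand == "+"
  rows <- list()
  add <- function(label, part, lo, hi, anchor) {
    if (hi <= lo) return()
    rows[[length(rows) + 1L]] <<- data.frame(
      event_id = event$event_id, label = label, part = part,
      seq_id = event$seq_id, start = as.integer(lo), end = as.integer(hi),
      strand = event$strand, anchor = anchor, stringsAsFactors = FALSE)
  }

  # alternative exon(s), clipped to `window` from the sense-5' end
  alt <- event$alt_region
  if (event$type %in% c("alt5", "alt3")) {
    alt <- data.frame(start = geo$a_lo, end = geo$a_hi)
  }
  for (i in seq_len(nrow(alt))) {
    lo <- alt$start[i]; hi <- alt$end[i]
    if (hi - lo > window) {
      if (plus) hi <- lo + window else lo <- hi - window
    }
    add("alt_exon", i, lo, hi, "alt_exon")
  }

  # flanking introns, split into splice-site-proximal sub-regions
  up_g <- c(geo$lf[["end"]], geo$a_lo)     # genomic-left intron
  down_g <- c(geo$a_hi, geo$rf[["start"]]) # genomic-right intron
  if (plus) {
    up <- split_intron_region(up_g[1], up_g[2], window, five_prime_left = TRUE)
    if (!is.null(up)) for (i in seq_len(nrow(up))) {
      add(paste0("upstream_intron_", up$suffix[i]), 1L, up$start[i], up$end[i],
          "upstream_intron")
    }
    dn <- split_intron_region(down_g[1], down_g[2], window, five_prime_left = TRUE)
    if (!is.null(dn)) for (i in seq_len(nrow(dn))) {
      add(paste0("downstream_intron_", dn$suffix[i]), 1L, dn$start[i], dn$end[i],
          "downstream_intron")
    }
  } else {
    # on the minus strand the sense-upstream intron is the genomic-right one
    up <- split_intron_region(down_g[1], down_g[2], window, five_prime_left = FALSE)
    if (!is.null(up)) for (i in seq_len(nrow(up))) {
      add(paste0("upstream_intron_", up$suffix[i]), 1L, up$start[i], up$end[i],
          "upstream_intron")
    }
    dn <- split_intron_region(up_g[1], up_g[2], window, five_prime_left = FALSE)
    if (!is.null(dn)) for (i in seq_len(nrow(dn))) {
      add(paste0("downstream_intron_", dn$suffix[i]), 1L, dn$start[i], dn$end[i],
          "downstream_intron")
    }
  }

  # constitutive flank ends facing the event
  fu <- event$flank_up; fd <- event$flank_down
  if (plus) {
    add("constitutive_up", 1L, max(fu[["start"]], fu[["end"]] - window), fu[["end"]],
        "constitutive_up_donor")
    add("constitutive_down", 1L, fd[["start"]], min(fd[["end"]], fd[["start"]] + window),
        "constitutive_down_acceptor")
  } else {
    add("constitutive_up", 1L, fu[["start"]], min(fu[["end"]], fu[["start"]] + window),
        "constitutive_up_donor")
    add("constitutive_down", 1L, max(fd[["start"]], fd[["end"]] - window), fd[["end"]],
        "constitutive_down_acceptor")
  }

  out <- do.call(rbind, rows)
  if (is.null(out)) stop("event ", event$event_id, " yields no regions")
  if (!is.null(genome)) {
    if (!event$seq_id %in% names(genome)) stop("sequence ", event$seq_id, " not in genome")
    L <- nchar(genome[[event$seq_id]])
    if (any(out$end > L) || any(out$start < 0)) {
      stop("event ", event$event_id, " outside sequence bounds")
    }
    out$seq <- vapply(seq_len(nrow(out)), function(i) {
      s <- seq_slice(genome, out$seq_id[i], out$start[i], out$end[i])
      if (plus) s else revcomp(s)
    }, "")
  }
  out
}

#' Scan event regions for motif occurrences
#'
#' @param catalog an `as_catalog` (or a list of events).
#' @param genome named sequence vector from [read_genome()].
#' @param motifs list of motif patterns (or pattern strings); names default
#'   to the pattern text.
#' @param window region window passed to [event_regions()].
#' @return data frame of class `motif_hits`: `event_id`, `gene_id`, `motif`,
#'   `label` (region), `part`, `offset` (0-based within the sense-strand
#'   region), `seq_id`, `gstart` (genomic leftmost, 0-based), `strand`,
#'   `length`.
#' @export
scan_event_motifs <- function(catalog, genome, motifs, window = 300) {
  motifs <- lapply(motifs, as_motif)
  if (is.null(names(motifs)) || any(!nzchar(names(motifs)))) {
    names(motifs) <- vapply(motifs, function(m) m$name, "")
  }
  rows <- list()
  for (ev in catalog) {
    regs <- event_regions(ev, genome, window = window)
    for (i in seq_len(nrow(regs))) {
      for (mn in names(motifs)) {
        m <- motifs[[mn]]
        offs <- scan_sequence(m, regs$seq[i])
        if (!length(offs)) next
        gstart <- if (ev$strand == "+") regs$start[i] + offs
                  else regs$end[i] - offs - m$length
        rows[[length(rows) + 1L]] <- data.frame(
          event_id = ev$event_id, gene_id = ev$gene_id, motif = mn,
          label = regs$label[i], part = regs$part[i], offset = offs,
          seq_id = regs$seq_id[i], gstart = as.integer(gstart),
          strand = ev$strand, length = m$length, stringsAsFactors = FALSE)
      }
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(event_id = character(0), gene_id = character(0),
               motif = character(0), label = character(0), part = integer(0),
               offset = integer(0), seq_id = character(0), gstart = integer(0),
               strand = character(0), length = integer(0))
  class(out) <- c("motif_hits", "data.frame")
  out
}

# per-(block, species) cache of ungapped sequence and column index
block_species_cache <- function(block) {
  cache <- list()
  for (sp in names(block$rows)) {
    chars <- strsplit(block$rows[[sp]], "")[[1]]
    idx <- which(chars != "-")
    cache[[sp]] <- list(chars = chars, nongap = idx,
                        ungapped = paste(chars[idx], collapse = ""))
  }
  cache
}

# columns of genomic-leftmost bases of motif matches in one species row
species_match_columns <- function(sp_cache, motif, strand) {
  ung <- sp_cache$ungapped
  L <- nchar(ung)
  m <- as_motif(motif)
  if (strand == "+") {
    left <- scan_sequence(m, ung)
  } else {
    rc <- scan_sequence(m, revcomp(ung))
    left <- L - rc - m$length
  }
  if (!length(left)) return(integer(0))
  sp_cache$nongap[left + 1L]
}

#' Conservation calls for motif hits
#'
#' A motif hit is conserved when the motif is present in `min_species` or
#' more other species within `window` alignment columns of the reference
#' position. The reference start is mapped to its alignment column; each
#' other species' row is scanned ungapped (on the gene's sense strand) and a
#' species supports the hit if any match starts within the column window.
#' Hits not covered by any alignment block get `species_support = 0` and
#' `aligned = FALSE`.
#'
#' @param hits a `motif_hits` table from [scan_event_motifs()].
#' @param alignments an `alignment_set` from [read_alignments()].
#' @param motifs the motif list used for scanning (named as in `hits`).
#' @param min_species species support needed to call conservation (default 2).
#' @param window alignment-column window (default 25).
#' @return `hits` with columns `species_support`, `conserved`, `aligned`.
#' @export
assess_conservation <- function(hits, alignments, motifs, min_species = 2,
                                window = 25) {
  motifs <- lapply(motifs, as_motif)
  if (is.null(names(motifs)) || any(!nzchar(names(motifs)))) {
    names(motifs) <- vapply(motifs, function(m) m$name, "")
  }
  n <- nrow(hits)
  support <- integer(n)
  aligned <- logical(n)
  caches <- list()     # block idx -> species cache
  colmaps <- list()    # block idx -> colmap
  matchcols <- list()  # "block|species|motif|strand" -> columns
  for (i in seq_len(n)) {
    bi <- block_covering(alignments, hits$seq_id[i], hits$gstart[i],
                         hits$gstart[i] + hits$length[i])
    if (is.na(bi)) { support[i] <- 0L; aligned[i] <- FALSE; next }
    aligned[i] <- TRUE
    key <- as.character(bi)
    if (is.null(caches[[key]])) {
      caches[[key]] <- block_species_cache(alignments$blocks[[bi]])
      colmaps[[key]] <- block_colmap(alignments$blocks[[bi]])
    }
    b <- alignments$blocks[[bi]]
    c_ref <- colmaps[[key]][hits$gstart[i] - b$start + 1L]
    others <- setdiff(names(b$rows), alignments$reference)
    supp <- 0L
    for (sp in others) {
      mkey <- paste(bi, sp, hits$motif[i], hits$strand[i], sep = "|")
      if (is.null(matchcols[[mkey]])) {
        matchcols[[mkey]] <- species_match_columns(caches[[key]][[sp]],
                                                   motifs[[hits$motif[i]]],
                                                   hits$strand[i])
      }
      mc <- matchcols[[mkey]]
      if (length(mc) && any(abs(mc - c_ref) <= window)) supp <- supp + 1L
    }
    support[i] <- supp
  }
  hits$species_support <- support
  hits$conserved <- aligned & support >= min_species
  hits$aligned <- aligned
  hits
}

#' Motif matches of every species within a genomic interval
#'
#' Used by the spacing/ordering analyses: for a splice-proximal region,
#' returns each species' motif match positions in that species' own
#' (ungapped) sense coordinates relative to the region's sense start,
#' so inter-motif spacings are measured in each species' nucleotides.
#'
#' @param alignments an `alignment_set`.
#' @param seq_id,start,end genomic interval (0-based half-open, reference).
#' @param strand gene strand.
#' @param motif motif pattern.
#' @return named list per species (reference included) of 0-based sense
#'   offsets, or `NULL` when the interval is not covered by one block.
#' @export
species_region_matches <- function(alignments, seq_id, start, end, strand, motif) {
  bi <- block_covering(alignments, seq_id, start, end)
  if (is.na(bi)) return(NULL)
  b <- alignments$blocks[[bi]]
  cm <- block_colmap(b)
  c_lo <- cm[start - b$start + 1L]
  c_hi <- cm[end - b$start]  # column of the last included base
  m <- as_motif(motif)
  out <- list()
  for (sp in names(b$rows)) {
    chars <- strsplit(substr(b$rows[[sp]], c_lo, c_hi), "")[[1]]
    sub <- paste(chars[chars != "-"], collapse = "")
    if (strand == "+") {
      out[[sp]] <- scan_sequence(m, sub)
    } else {
      out[[sp]] <- scan_sequence(m, revcomp(sub))
    }
  }
  out
}
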