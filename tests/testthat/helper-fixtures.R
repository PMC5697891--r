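# Shared in-code fixtures.

# the canonical three-exon cassette gene of the worked examples:
# exons [100,200), [300,400), [500,600); T2 skips the middle exon
h_cassette_models <- function(strand = "+") {
  gene_models(data.frame(
    gene_id = "g1",
    transcript_id = rep(c("t1", "t2"), c(3, 2)),
    seq_id = "chrI", strand = strand,
    start = c(100, 300, 500, 100, 500),
    end = c(200, 400, 600, 200, 600)))
}

h_cassette_event <- function(strand = "+") {
  build_catalog(h_cassette_models(strand))[[1]]
}

# junction table for the canonical cassette event
h_cassette_counts <- function(c1a, ac2, c1c2, sample_id = "s") {
  junction_counts(data.frame(
    seq_id = "chrI",
    donor = c(200, 400, 200),
    acceptor = c(300, 500, 500),
    strand = "+",
    count = c(c1a, ac2, c1c2)), sample_id = sample_id)
}

# wrap hand-built gapped rows into an alignment set (reference row first)
h_alignment <- function(rows, chrom = "chrI", start = 0L,
                        reference = names(rows)[1]) {
  ref_len <- nchar(gsub("-", "", rows[[reference]], fixed = TRUE))
  structure(list(blocks = list(list(chrom = chrom, start = as.integer(start),
                                    size = ref_len, rows = unlist(rows))),
                 reference = reference, species = names(rows)),
            class = "alignment_set")
}

h_motifs <- function(patterns = c("GCAUG", "GCACA", "U(A|G|U)(A|G)GUU")) {
  m <- lapply(patterns, parse_motif)
  stats::setNames(m, vapply(m, function(x) x$name, ""))
}

# minimal hits table row
h_hit <- function(event_id, motif, label, offset, gstart, strand = "+",
                  length = 5L, conserved = TRUE, part = 1L) {
  data.frame(event_id = event_id, gene_id = event_id, motif = motif,
             label = label, part = part, offset = offset, seq_id = "chrI",
             gstart = gstart, strand = strand, length = length,
             species_support = if (conserved) 3L else 0L,
             conserved = conserved, aligned = TRUE, stringsAsFactors = FALSE)
}

# synthetic ordering fixture: n events, each with both motifs in one intron
# region; all species carry the motifs at the reference offsets (order
# preserved); `n_ab` events have motif a upstream of motif b
h_ordering_fixture <- function(n = 10, n_ab = 9, species = paste0("s", 2:5)) {
  hits <- list(); regions <- list(); blocks <- list()
  for (i in seq_len(n)) {
    ab <- i <= n_ab
    start <- (i - 1) * 1000L
    row <- strrep("A", 200)
    off_a <- if (ab) 20L else 80L
    off_b <- if (ab) 80L else 20L
    substr(row, off_a + 1, off_a + 5) <- "GCACA"
    substr(row, off_b + 1, off_b + 6) <- "TAGGTT"
    rows <- c(list(ref = row), stats::setNames(rep(list(row), length(species)), species))
    blocks[[i]] <- list(chrom = "chrI", start = start, size = 200L,
                        rows = unlist(rows))
    ev <- sprintf("E%02d", i)
    regions[[i]] <- data.frame(event_id = ev, label = "upstream_intron_5p",
                               part = 1L, seq_id = "chrI", start = start,
                               end = start + 200L, strand = "+",
                               anchor = "upstream_intron",
                               stringsAsFactors = FALSE)
    hits[[length(hits) + 1L]] <- h_hit(ev, "GCACA", "upstream_intron_5p",
                                       off_a, start + off_a)
    hits[[length(hits) + 1L]] <- h_hit(ev, "U(A|G|U)(A|G)GUU",
                                       "upstream_intron_5p", off_b,
                                       start + off_b, length = 6L)
  }
  list(hits = do.call(rbind, hits), regions = do.call(rbind, regions),
       aln = structure(list(blocks = blocks, reference = "ref",
                            species = c("ref", species)),
                       class = "alignment_set"))
}

# like h_ordering_fixture but each species independently preserves or
# reverses the reference order (order shuffled across species)
h_ordering_fixture_random <- function(n = 10, species = paste0("s", 2:4)) {
  hits <- list(); regions <- list(); blocks <- list()
  # motifs sit close together so a reversed copy still falls inside the
  # 25nt qualification window around the reference positions
  mk_row <- function(ab) {
    row <- strrep("A", 200)
    off_a <- if (ab) 40L else 49L
    off_b <- if (ab) 48L else 38L
    substr(row, off_a + 1, off_a + 5) <- "GCACA"
    substr(row, off_b + 1, off_b + 6) <- "TAGGTT"
    row
  }
  for (i in seq_len(n)) {
    ab <- stats::runif(1) < 0.5
    start <- (i - 1) * 1000L
    rows <- c(list(ref = mk_row(ab)),
              stats::setNames(lapply(species, function(s) mk_row(stats::runif(1) < 0.5)),
                              species))
    blocks[[i]] <- list(chrom = "chrI", start = start, size = 200L,
                        rows = unlist(rows))
    ev <- sprintf("E%02d", i)
    regions[[i]] <- data.frame(event_id = ev, label = "upstream_intron_5p",
                               part = 1L, seq_id = "chrI", start = start,
                               end = start + 200L, strand = "+",
                               anchor = "upstream_intron",
                               stringsAsFactors = FALSE)
    off_a <- if (ab) 40L else 49L
    off_b <- if (ab) 48L else 38L
    hits[[length(hits) + 1L]] <- h_hit(ev, "GCACA", "upstream_intron_5p",
                                       off_a, start + off_a)
    hits[[length(hits) + 1L]] <- h_hit(ev, "U(A|G|U)(A|G)GUU",
                                       "upstream_intron_5p", off_b,
                                       start + off_b, length = 6L)
  }
  list(hits = do.call(rbind, hits), regions = do.call(rbind, regions),
       aln = structure(list(blocks = blocks, reference = "ref",
                            species = c("ref", species)),
                       class = "alignment_set"))
}
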