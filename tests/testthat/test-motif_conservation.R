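# Motif parsing, scanning, splice regions and conservation calls.

test_that("motif patterns parse to position sets", {
  m <- parse_motif("GCAUG")
  expect_equal(m$length, 5L)
  expect_true(all(lengths(m$sets) == 1L))
  expect_equal(unlist(m$sets), c("G", "C", "A", "T", "G"))

  e <- parse_motif("U(A|G|U)(A|G)GUU")
  expect_equal(e$length, 6L)
  expect_equal(e$sets[[2]], c("A", "G", "T"))
  expect_equal(e$sets[[3]], c("A", "G"))

  y <- parse_motif("GCAYG")
  expect_equal(y$sets[[4]], c("C", "T"))

  expect_error(parse_motif("GC(A|)G"), "alternation")
  expect_error(parse_motif("GC(AG"), "parenthes")
  expect_error(parse_motif("GCJG"), "IUPAC")
  expect_equal(motif_rna(e), "U(A|G|U)(A|G)GUU")
})

test_that("scanner reports all (overlapping) matches", {
  expect_equal(scan_sequence("GCAUG", "AAGCAUGAA"), 2L)
  expect_equal(scan_sequence("GCAUG", "GCAUGCAUG"), c(0L, 4L))
  expect_equal(scan_sequence("GCAUG", "GCA"), integer(0))
})

test_that("scanner agrees with a regex oracle on random sequences", {
  set.seed(21)
  pats <- c("GCAUG", "GCACA", "U(A|G|U)(A|G)GUU", "GCAYG", "WGGWG")
  for (i in 1:200) {
    seq <- paste(sample(c("A", "C", "G", "T"), 300, replace = TRUE), collapse = "")
    p <- sample(pats, 1)
    expect_identical(scan_sequence(p, seq), oracle_scan(p, seq))
  }
})

test_that("long introns give two disjoint 300nt splice-proximal sub-regions", {
  gm <- gene_models(data.frame(
    gene_id = "g", transcript_id = rep(c("t1", "t2"), c(3, 2)),
    seq_id = "chrI", strand = "+",
    start = c(100, 1200, 2000, 100, 2000),
    end = c(200, 1300, 2100, 200, 2100)))
  ev <- build_catalog(gm)[[1]]
  regs <- event_regions(ev)
  up5 <- regs[regs$label == "upstream_intron_5p", ]
  up3 <- regs[regs$label == "upstream_intron_3p", ]
  expect_equal(c(up5$start, up5$end), c(200L, 500L))   # first 300nt
  expect_equal(c(up3$start, up3$end), c(900L, 1200L))  # last 300nt
})

test_that("short introns split at the midpoint into disjoint sub-regions", {
  gm <- gene_models(data.frame(
    gene_id = "g", transcript_id = rep(c("t1", "t2"), c(3, 2)),
    seq_id = "chrI", strand = "+",
    start = c(100, 600, 1200, 100, 1200),
    end = c(200, 700, 1300, 200, 1300)))
  ev <- build_catalog(gm)[[1]]
  regs <- event_regions(ev)
  up5 <- regs[regs$label == "upstream_intron_5p", ]
  up3 <- regs[regs$label == "upstream_intron_3p", ]
  expect_equal(up5$end - up5$start, 200L)
  expect_equal(up3$end - up3$start, 200L)
  expect_equal(up5$end, up3$start)  # disjoint at the midpoint
  expect_true(all(regs$end - regs$start <= 300))
})

test_that("minus-strand region sequences are reverse complements", {
  genome <- c(chrI = paste(sample(c("A", "C", "G", "T"), 1000, replace = TRUE),
                           collapse = ""))
  gm <- gene_models(data.frame(
    gene_id = "g", transcript_id = rep(c("t1", "t2"), c(3, 2)),
    seq_id = "chrI", strand = "-",
    start = c(100, 400, 700, 100, 700),
    end = c(200, 500, 800, 200, 800)))
  ev <- build_catalog(gm)[[1]]
  regs <- event_regions(ev, genome)
  for (i in seq_len(nrow(regs))) {
    slice <- substr(genome[["chrI"]], regs$start[i] + 1, regs$end[i])
    expect_equal(regs$seq[i], oracle_revcomp(slice))
  }
  # sense-upstream intron of a minus-strand gene is the genomic-right intron
  up <- regs[regs$label == "upstream_intron_5p", ]
  expect_true(up$start >= 500)
})

test_that("conservation needs >=2 other species within the 25nt column window", {
  ref <- paste0(strrep("A", 40), "GCATG", strrep("A", 40))
  mk_row <- function(pos, n = 85) {
    x <- strrep("C", n)
    substr(x, pos + 1, pos + 5) <- "GCATG"
    x
  }
  motifs <- h_motifs("GCAUG")
  hit <- h_hit("E1", "GCAUG", "upstream_intron_5p", 40L, 40L)
  # exactly 2 supporting species at the same column -> conserved
  aln2 <- h_alignment(list(ref = ref, s2 = mk_row(40), s3 = mk_row(40),
                           s4 = strrep("C", 85)))
  h <- assess_conservation(hit, aln2, motifs)
  expect_equal(h$species_support, 2L)
  expect_true(h$conserved)
  # only one species -> not conserved
  aln1 <- h_alignment(list(ref = ref, s2 = mk_row(40), s3 = strrep("C", 85)))
  expect_false(assess_conservation(hit, aln1, motifs)$conserved)
  # window boundary: +25 supports, +26 does not
  h25 <- assess_conservation(hit, h_alignment(list(ref = paste0(ref, strrep("A", 30)),
    s2 = mk_row(65, 115), s3 = mk_row(65, 115))), motifs)
  expect_true(h25$conserved)
  h26 <- assess_conservation(hit, h_alignment(list(ref = paste0(ref, strrep("A", 30)),
    s2 = mk_row(66, 115), s3 = mk_row(66, 115))), motifs)
  expect_equal(h26$species_support, 0L)
  # position not covered by any block
  h_un <- assess_conservation(h_hit("E1", "GCAUG", "alt_exon", 0L, 5000L), aln2, motifs)
  expect_false(h_un$aligned)
  expect_equal(h_un$species_support, 0L)
})

test_that("inserting pure-gap columns changes no conservation call", {
  set.seed(9)
  motifs <- h_motifs("GCAUG")
  for (i in 1:25) {
    ref_seq <- paste(sample(c("A", "C", "G", "T"), 80, replace = TRUE), collapse = "")
    at <- sample(10:60, 1)
    substr(ref_seq, at, at + 4) <- "GCATG"  # guarantee at least one hit
    blk <- simulate_alignment_block(
      ref_seq,
      species = c("ref", "s2", "s3", "s4"), substitution_rate = 0.1,
      indel_rate = 0.03, chrom = "chrI", start = 0L)
    aln <- structure(list(blocks = list(blk), reference = "ref",
                          species = c("ref", "s2", "s3", "s4")),
                     class = "alignment_set")
    offs <- scan_sequence("GCAUG", gsub("-", "", blk$rows[["ref"]]))
    hits <- do.call(rbind, lapply(offs, function(o) h_hit("E1", "GCAUG", "alt_exon", o, o)))
    if (is.null(hits)) next
    before <- assess_conservation(hits, aln, motifs)
    # splice an all-gap column into every row
    at <- sample(nchar(blk$rows[[1]]), 1)
    blk2 <- blk
    blk2$rows <- vapply(blk$rows, function(r) {
      paste0(substr(r, 1, at), "-", substr(r, at + 1, nchar(r)))
    }, "")
    aln2 <- aln; aln2$blocks[[1]] <- blk2
    after <- assess_conservation(hits, aln2, motifs)
    expect_equal(before$species_support, after$species_support)
    expect_equal(before$conserved, after$conserved)
  }
})
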