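# formats_io: coordinate conventions, readers/writers, round trips.

test_that("GFF3 coordinates convert to 0-based half-open and back", {
  path <- withr::local_tempfile(fileext = ".gff3")
  writeLines(c(
    "##gff-version 3",
    "chrI\tsrc\tgene\t100\t600\t.\t+\t.\tID=g1",
    "chrI\tsrc\tmRNA\t100\t600\t.\t+\t.\tID=t1;Parent=g1",
    "chrI\tsrc\texon\t100\t200\t.\t+\t.\tParent=t1",
    "chrI\tsrc\texon\t300\t400\t.\t+\t.\tParent=t1"), path)
  gm <- read_gene_models(path)
  expect_equal(gm$start, c(99L, 299L))
  expect_equal(gm$end, c(200L, 400L))
  # export restores 1-based inclusive starts
  out <- withr::local_tempfile(fileext = ".gff3")
  write_gene_models(gm, out)
  exon_lines <- grep("\texon\t", readLines(out), value = TRUE)
  expect_equal(as.integer(sapply(strsplit(exon_lines, "\t"), `[`, 4)), c(100L, 300L))
})

test_that("two transcripts sharing flanking exons give one gene, two transcripts", {
  gm <- h_cassette_models()
  expect_equal(length(unique(gm$gene_id)), 1L)
  expect_equal(length(unique(gm$transcript_id)), 2L)
  expect_error(gene_models(transform(as.data.frame(gm), start = end)),
               "start < end")
})

test_that("GTF attribute dialect yields the same gene models as GFF3", {
  gm <- h_cassette_models()
  gff <- withr::local_tempfile(fileext = ".gff3")
  write_gene_models(gm, gff)
  gtf <- withr::local_tempfile(fileext = ".gtf")
  df <- as.data.frame(gm)
  writeLines(sprintf(
    'chrI\tsrc\texon\t%d\t%d\t.\t%s\t.\tgene_id "%s"; transcript_id "%s";',
    df$start + 1L, df$end, df$strand, df$gene_id, df$transcript_id), gtf)
  a <- read_gene_models(gff)
  b <- read_gene_models(gtf)
  expect_equal(as.data.frame(a), as.data.frame(b))
})

test_that("malformed annotation lines are reported with their line number", {
  path <- withr::local_tempfile(fileext = ".gff3")
  writeLines(c("##gff-version 3", "chrI broken line"), path)
  expect_error(read_gene_models(path), "line 2")
})

test_that("junction reader sums duplicates and validates columns", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("seq_id\tdonor\tacceptor\tstrand\tcount",
               "chrI\t200\t300\t+\t10",
               "chrI\t200\t300\t+\t5"), path)
  jc <- read_junction_counts(path)
  expect_equal(nrow(jc), 1L)
  expect_equal(jc$count, 15L)

  empty <- withr::local_tempfile(fileext = ".tsv")
  writeLines("seq_id\tdonor\tacceptor\tstrand\tcount", empty)
  expect_equal(nrow(read_junction_counts(empty)), 0L)

  expect_error(junction_counts(data.frame(seq_id = "c", donor = 1, acceptor = 2,
                                          strand = "+", count = -1)),
               "non-negative")
  expect_error(junction_counts(data.frame(seq_id = "c", donor = 1, acceptor = 2,
                                          strand = "+", count = 1.5)),
               "integer")
  expect_error(junction_counts(data.frame(seq_id = "c", donor = 1, count = 2)),
               "missing columns")
})

test_that("junction totals match an independent column sum over random rows", {
  set.seed(11)
  df <- data.frame(seq_id = sample(c("chrI", "chrII"), 1000, replace = TRUE),
                   donor = sample(1e5, 1000, replace = TRUE),
                   acceptor = sample(1e5, 1000, replace = TRUE) + 2e5,
                   strand = sample(c("+", "-"), 1000, replace = TRUE),
                   count = sample(0:50, 1000, replace = TRUE))
  path <- withr::local_tempfile(fileext = ".tsv")
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  jc <- read_junction_counts(path)
  expect_equal(sum(jc$count), sum(df$count))
  # round trip
  out <- withr::local_tempfile(fileext = ".tsv")
  write_junction_counts(jc, out)
  jc2 <- read_junction_counts(out, sample_id = attr(jc, "sample_id"))
  expect_equal(as.data.frame(jc), as.data.frame(jc2))
})

test_that("MAF reader builds column maps and keeps configured species", {
  path <- withr::local_tempfile(fileext = ".maf")
  seqs <- c("AACCGGTTAA", "AAC-GGTTAA", "AACCGGTT--")
  writeLines(c("##maf version=1", "",
               "a score=0",
               paste("s ref.chrI 10 10 + 1000", seqs[1]),
               paste("s sp2.chrI 0 9 + 900", seqs[2]),
               paste("s sp3.chrI 0 8 + 800", seqs[3]),
               paste("s spX.chrI 0 10 + 800", seqs[1])), path)
  aln <- read_alignments(path, species = c("ref", "sp2", "sp3"))
  b <- aln$blocks[[1]]
  expect_equal(names(b$rows), c("ref", "sp2", "sp3"))
  expect_equal(b$start, 10L)
  expect_equal(length(block_colmap(b)), 10L)
})

test_that("column map skips reference gaps and is a monotone bijection", {
  aln <- h_alignment(list(ref = "AC-GT", sp2 = "ACTGT"))
  cm <- block_colmap(aln$blocks[[1]])
  expect_equal(cm, c(1L, 2L, 4L, 5L))  # ungapped offset 2 -> column 4 (1-based)
  set.seed(5)
  for (i in 1:20) {
    n <- sample(10:60, 1)
    chars <- sample(c("A", "C", "G", "T", "-"), n, replace = TRUE,
                    prob = c(.2, .2, .2, .2, .2))
    if (all(chars == "-")) chars[1] <- "A"
    row <- paste(chars, collapse = "")
    cm <- block_colmap(list(rows = list(ref = row)))
    expect_true(all(diff(cm) > 0))
    # map inverse composed with map is the identity on ungapped positions
    expect_equal(match(cm, which(chars != "-")), seq_along(cm))
  }
})

test_that("blocks on the reference minus strand are normalised forward", {
  path <- withr::local_tempfile(fileext = ".maf")
  writeLines(c("##maf version=1", "",
               "a score=0",
               "s ref.chrI 10 5 - 100 ACGTT",
               "s sp2.chrI 0 5 + 900 ACGTA"), path)
  aln <- read_alignments(path, species = c("ref", "sp2"))
  b <- aln$blocks[[1]]
  expect_equal(b$start, 85L)  # srcSize - start - size
  expect_equal(unname(b$rows[["ref"]]), "AACGT")
  expect_equal(unname(b$rows[["sp2"]]), "TACGT")
})

test_that("blocks lacking the reference row are skipped with a warning", {
  path <- withr::local_tempfile(fileext = ".maf")
  writeLines(c("##maf version=1", "",
               "a score=0",
               "s sp2.chrI 0 4 + 900 ACGT"), path)
  expect_warning(aln <- read_alignments(path, species = c("ref", "sp2")),
                 "without reference")
  expect_equal(length(aln$blocks), 0L)
})

test_that("alignment write/read round-trips blocks exactly", {
  st <- simulate_study(sim_config(n_genes = 6, seed = 2))
  path <- withr::local_tempfile(fileext = ".maf")
  write_alignments(st$alignments, path)
  aln <- read_alignments(path, species = st$config$species)
  expect_equal(length(aln$blocks), length(st$alignments$blocks))
  for (i in seq_along(aln$blocks)) {
    expect_equal(aln$blocks[[i]]$rows, st$alignments$blocks[[i]]$rows)
    expect_equal(aln$blocks[[i]]$start, st$alignments$blocks[[i]]$start)
  }
})

test_that("genome FASTA round-trips and T/U are interchangeable on input", {
  path <- withr::local_tempfile(fileext = ".fa")
  writeLines(c(">chrI here be dragons", "ACGUACGU"), path)
  g <- read_genome(path)
  expect_equal(names(g), "chrI")
  expect_equal(unname(g[["chrI"]]), "ACGTACGT")
})
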