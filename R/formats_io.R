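# formats_io: file formats and the shared coordinate conventions.
#
# All internal coordinates are 0-based half-open; conversion to/from the
# 1-based inclusive conventions of GFF3/GTF happens only at file boundaries.
# Junction keys are the intronic boundaries (end of the upstream exon, start
# of the downstream exon, in genomic order), with strand carried separately.

#' Construct a set of gene models
#'
#' A gene model set is a data frame with one row per exon and columns
#' `gene_id`, `transcript_id`, `seq_id`, `strand`, `start`, `end`
#' (0-based half-open genomic coordinates). Exons within a transcript must be
#' non-overlapping; they are stored sorted in genomic order.
#'
#' @param exons data frame with the columns above.
#' @return object of class `gene_models`.
#' @export
gene_models <- function(exons) {
  need <- c("gene_id", "transcript_id", "seq_id", "strand", "start", "end")
  miss <- setdiff(need, names(exons))
  if (length(miss)) stop("gene_models: missing columns: ", paste(miss, collapse = ", "))
  exons <- as.data.frame(exons)[need]
  exons$start <- as.integer(exons$start)
  exons$end <- as.integer(exons$end)
  if (any(exons$start >= exons$end)) stop("gene_models: every exon must have start < end")
  if (!all(exons$strand %in% c("+", "-"))) stop("gene_models: strand must be '+' or '-'")
  exons <- exons[order(exons$gene_id, exons$transcript_id, exons$start), , drop = FALSE]
  by_tx <- split(seq_len(nrow(exons)), exons$transcript_id)
  for (idx in by_tx) {
    s <- exons$start[idx]; e <- exons$end[idx]
    if (length(idx) > 1 && any(s[-1] < e[-length(e)])) {
      stop("gene_models: overlapping exons in transcript ", exons$transcript_id[idx[1]])
    }
  }
  rownames(exons) <- NULL
  class(exons) <- c("gene_models", "data.frame")
  exons
}

#' Read gene models from a GFF3 or GTF annotation
#'
#' Understands both the GFF3 `ID`/`Parent` hierarchy (gene, mRNA/transcript,
#' exon) and the GTF `gene_id`/`transcript_id` attribute dialect. File
#' coordinates (1-based inclusive) are converted to internal 0-based
#' half-open. Features on unplaced sequences are retained.
#'
#' @param path annotation file (`.gff3`/`.gff` or `.gtf`).
#' @return a [gene_models()] data frame.
#' @export
read_gene_models <- function(path) {
  lines <- readLines(path)
  body <- which(!grepl("^#", lines) & nzchar(lines))
  for (i in body) {
    if (length(strsplit(lines[i], "\t", fixed = TRUE)[[1]]) < 8) {
      stop("malformed annotation line ", i, " in ", path)
    }
  }
  fmt <- if (grepl("\\.gtf(\\.gz)?$", path, ignore.case = TRUE)) "gtf" else "gff3"
  gr <- rtracklayer::import(path, format = fmt)
  md <- S4Vectors::mcols(gr)
  ex <- gr[tolower(md$type) == "exon"]
  if (!length(ex)) stop("no exon features in ", path)
  exd <- S4Vectors::mcols(ex)
  if (!is.null(exd$transcript_id) && !all(is.na(exd$transcript_id))) {
    tx_id <- as.character(exd$transcript_id)
    g_id <- as.character(exd$gene_id)
  } else {
    # GFF3: exon Parent -> transcript; transcript Parent -> gene
    par <- exd$Parent
    if (is.null(par)) stop("exon without parent transcript in ", path)
    tx_id <- vapply(par, function(p) if (length(p)) as.character(p[1]) else NA_character_, "")
    if (anyNA(tx_id)) stop("exon without parent transcript in ", path)
    txs <- gr[tolower(md$type) %in% c("mrna", "transcript")]
    txd <- S4Vectors::mcols(txs)
    tx2gene <- vapply(txd$Parent, function(p) if (length(p)) as.character(p[1]) else NA_character_, "")
    names(tx2gene) <- as.character(txd$ID)
    g_id <- unname(tx2gene[tx_id])
    g_id[is.na(g_id)] <- tx_id[is.na(g_id)]
  }
  gene_models(data.frame(
    gene_id = g_id,
    transcript_id = tx_id,
    seq_id = as.character(GenomicRanges::seqnames(ex)),
    strand = as.character(GenomicRanges::strand(ex)),
    start = GenomicRanges::start(ex) - 1L,
    end = GenomicRanges::end(ex),
    stringsAsFactors = FALSE
  ))
}

#' Write gene models as GFF3
#'
#' Emits a gene / mRNA / exon hierarchy; internal 0-based half-open
#' coordinates become 1-based inclusive on export.
#'
#' @param models a [gene_models()] object.
#' @param path output `.gff3` path.
#' @export
write_gene_models <- function(models, path) {
  rows <- list()
  for (g in unique(models$gene_id)) {
    gm <- models[models$gene_id == g, , drop = FALSE]
    rows[[length(rows) + 1L]] <- data.frame(
      seq_id = gm$seq_id[1], type = "gene", start = min(gm$start), end = max(gm$end),
      strand = gm$strand[1], ID = g, Parent = NA_character_)
    for (tx in unique(gm$transcript_id)) {
      tm <- gm[gm$transcript_id == tx, , drop = FALSE]
      rows[[length(rows) + 1L]] <- data.frame(
        seq_id = tm$seq_id[1], type = "mRNA", start = min(tm$start), end = max(tm$end),
        strand = tm$strand[1], ID = tx, Parent = g)
      for (i in seq_len(nrow(tm))) {
        rows[[length(rows) + 1L]] <- data.frame(
          seq_id = tm$seq_id[i], type = "exon", start = tm$start[i], end = tm$end[i],
          strand = tm$strand[i], ID = NA_character_, Parent = tx)
      }
    }
  }
  tab <- do.call(rbind, rows)
  attr_str <- function(id, parent) {
    parts <- character(0)
    if (!is.na(id)) parts <- c(parts, paste0("ID=", id))
    if (!is.na(parent)) parts <- c(parts, paste0("Parent=", parent))
    if (!length(parts)) "." else paste(parts, collapse = ";")
  }
  lines <- c("##gff-version 3",
             vapply(seq_len(nrow(tab)), function(i) {
               paste(tab$seq_id[i], "splicecomb", tab$type[i], tab$start[i] + 1L, tab$end[i],
                     ".", tab$strand[i], ".", attr_str(tab$ID[i], tab$Parent[i]), sep = "\t")
             }, ""))
  writeLines(lines, path)
  invisible(path)
}

#' Build a junction-count table
#'
#' @param df data frame with columns `seq_id`, `donor`, `acceptor`, `strand`,
#'   `count`. `donor`/`acceptor` are the 0-based half-open intron boundaries;
#'   keys are stored in genomic order (`donor < acceptor`). Duplicate keys are
#'   summed.
#' @param sample_id sample label attached to the table.
#' @return object of class `junction_counts`.
#' @export
junction_counts <- function(df, sample_id = "sample") {
  need <- c("seq_id", "donor", "acceptor", "strand", "count")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("junction_counts: missing columns: ", paste(miss, collapse = ", "))
  df <- as.data.frame(df)[need]
  if (any(!is_wholenumber(df$count)) || any(df$count < 0)) {
    stop("junction_counts: counts must be non-negative integers")
  }
  df$count <- as.integer(round(df$count))
  swap <- df$donor > df$acceptor
  if (any(swap)) {
    tmp <- df$donor[swap]; df$donor[swap] <- df$acceptor[swap]; df$acceptor[swap] <- tmp
  }
  df$donor <- as.integer(df$donor); df$acceptor <- as.integer(df$acceptor)
  key <- paste(df$seq_id, df$donor, df$acceptor, sep = ":")
  agg <- rowsum(df$count, key)
  first <- !duplicated(key)
  out <- df[first, , drop = FALSE]
  out$count <- as.integer(agg[paste(out$seq_id, out$donor, out$acceptor, sep = ":"), 1])
  out <- out[order(out$seq_id, out$donor, out$acceptor), , drop = FALSE]
  rownames(out) <- NULL
  counts <- out$count
  names(counts) <- paste(out$seq_id, out$donor, out$acceptor, sep = ":")
  attr(out, "sample_id") <- sample_id
  attr(out, "lookup") <- counts
  class(out) <- c("junction_counts", "data.frame")
  out
}

#' Read a junction-count table
#'
#' Expects a tab-separated file with columns `seq_id`, `donor`, `acceptor`,
#' `strand`, `count` (one sample per file; `#` comment lines allowed).
#' Duplicate keys are summed.
#'
#' @param path input file.
#' @param sample_id sample label; defaults to the file base name.
#' @return a [junction_counts()] table.
#' @export
read_junction_counts <- function(path, sample_id = NULL) {
  sample_id <- sample_id %||% sub("\\.[^.]*$", "", basename(path))
  df <- utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
  junction_counts(df, sample_id = sample_id)
}

#' Write a junction-count table
#' @param jc a [junction_counts()] table.
#' @param path output path.
#' @param meta optional metadata for the commented header.
#' @export
write_junction_counts <- function(jc, path, meta = NULL) {
  write_tsv_commented(as.data.frame(jc), path,
                      meta = c(list(sample_id = attr(jc, "sample_id")), meta))
}

# count for a junction key; absent keys count 0
jc_count <- function(jc, seq_id, donor, acceptor) {
  lut <- attr(jc, "lookup")
  lo <- pmin(donor, acceptor); hi <- pmax(donor, acceptor)
  v <- lut[paste(seq_id, lo, hi, sep = ":")]
  v[is.na(v)] <- 0L
  unname(v)
}

# ---- multi-species alignments (MAF) --------------------------------------

#' Read a multiple alignment from a MAF file
#'
#' Only rows for the configured species are retained. Species names are the
#' `src` component before the first dot. Blocks on the reference minus strand
#' are normalised to reference forward orientation. Blocks lacking the
#' reference row are skipped with a warning.
#'
#' @param path MAF file.
#' @param species character vector of species to keep (reference first);
#'   `NULL` keeps every species seen.
#' @param reference reference species; defaults to `species[1]` or the first
#'   species of the first block.
#' @return object of class `alignment_set`: a list with `blocks`,
#'   `reference` and `species`. Each block has `chrom`, `start`, `size`
#'   (reference, 0-based half-open) and `rows` (named gapped sequences).
#' @export
read_alignments <- function(path, species = NULL, reference = NULL) {
  lines <- readLines(path)
  blocks <- list()
  cur <- NULL
  flush <- function(cur) {
    if (is.null(cur) || !length(cur$species)) return(NULL)
    cur
  }
  raw_blocks <- list()
  for (ln in lines) {
    if (grepl("^a( |$)", ln)) {
      if (!is.null(cur)) raw_blocks[[length(raw_blocks) + 1L]] <- cur
      cur <- list(species = character(0), chrom = character(0), start = integer(0),
                  size = integer(0), strand = character(0), src_size = integer(0),
                  text = character(0))
    } else if (grepl("^s ", ln)) {
      if (is.null(cur)) stop("MAF 's' line outside block")
      f <- strsplit(trimws(ln), "[ \t]+")[[1]]
      if (length(f) < 7) stop("malformed MAF 's' line: ", ln)
      src <- f[2]
      sp <- sub("\\..*$", "", src)
      chrom <- sub("^[^.]*\\.", "", src)
      cur$species <- c(cur$species, sp)
      cur$chrom <- c(cur$chrom, chrom)
      cur$start <- c(cur$start, as.integer(f[3]))
      cur$size <- c(cur$size, as.integer(f[4]))
      cur$strand <- c(cur$strand, f[5])
      cur$src_size <- c(cur$src_size, as.integer(f[6]))
      cur$text <- c(cur$text, toupper(chartr("U", "T", f[7])))
    }
  }
  if (!is.null(cur)) raw_blocks[[length(raw_blocks) + 1L]] <- cur
  if (is.null(reference)) {
    reference <- if (!is.null(species)) species[1] else raw_blocks[[1]]$species[1]
  }
  out <- list()
  seen_species <- character(0)
  for (b in raw_blocks) {
    keep <- if (is.null(species)) seq_along(b$species) else which(b$species %in% species)
    ri <- which(b$species == reference)
    if (!length(ri)) {
      warning("MAF block without reference row (", reference, ") skipped")
      next
    }
    ri <- ri[1]
    keep <- union(ri, keep)
    widths <- nchar(b$text[keep])
    if (length(unique(widths)) != 1L) stop("inconsistent row lengths in MAF block")
    rows <- b$text[keep]
    names(rows) <- b$species[keep]
    start <- b$start[ri]; size <- b$size[ri]
    if (b$strand[ri] == "-") {
      rows <- vapply(rows, revcomp_gapped, "")
      start <- b$src_size[ri] - start - size
    }
    # reference row first
    rows <- rows[c(reference, setdiff(names(rows), reference))]
    out[[length(out) + 1L]] <- list(chrom = b$chrom[ri], start = start, size = size,
                                    rows = rows)
    seen_species <- union(seen_species, names(rows))
  }
  structure(list(blocks = out, reference = reference,
                 species = species %||% seen_species),
            class = "alignment_set")
}

#' Write an alignment set as MAF
#' @param aln an `alignment_set`.
#' @param path output path.
#' @param src_sizes named integer vector of source sequence sizes per
#'   `species.chrom` reference; unknown sizes default to 0.
#' @export
write_alignments <- function(aln, path, src_sizes = NULL) {
  con <- file(path, "wt")
  on.exit(close(con))
  writeLines("##maf version=1", con)
  for (b in aln$blocks) {
    writeLines("", con)
    writeLines("a score=0.0", con)
    for (sp in names(b$rows)) {
      txt <- b$rows[[sp]]
      ungapped <- nchar(gsub("-", "", txt, fixed = TRUE))
      start <- if (sp == aln$reference) b$start else 0L
      src <- paste0(sp, ".", b$chrom)
      size_src <- if (!is.null(src_sizes) && src %in% names(src_sizes)) src_sizes[[src]] else 0L
      writeLines(paste("s", src, start, ungapped, "+", size_src, txt), con)
    }
  }
  invisible(path)
}

revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

revcomp_gapped <- function(x) {
  chars <- rev(strsplit(x, "")[[1]])
  comp <- chartr("ACGTN-", "TGCAN-", paste(chars, collapse = ""))
  comp
}

#' Column map of an alignment block
#'
#' @param block one element of `alignment_set$blocks`.
#' @return integer vector: for each ungapped reference position (1..size),
#'   its 1-based alignment column. A strictly monotone bijection.
#' @export
block_colmap <- function(block) {
  chars <- strsplit(block$rows[[1]], "")[[1]]
  which(chars != "-")
}

# find the index of a block covering reference interval [start, end)
block_covering <- function(aln, chrom, start, end = start + 1L) {
  for (i in seq_along(aln$blocks)) {
    b <- aln$blocks[[i]]
    if (b$chrom == chrom && b$start <= start && end <= b$start + b$size) return(i)
  }
  NA_integer_
}

#' Read a genome FASTA
#' @param path FASTA file (DNA; `U` accepted and stored as `T`).
#' @return named character vector of uppercase sequences (names truncated at
#'   the first whitespace).
#' @export
read_genome <- function(path) {
  ss <- Biostrings::readBStringSet(path)  # BString: tolerate RNA 'U' on input
  seqs <- chartr("U", "T", toupper(as.character(ss)))
  names(seqs) <- sub("\\s.*$", "", names(ss))
  seqs
}

#' Write a genome FASTA
#' @param seqs named character vector of sequences.
#' @param path output path.
#' @export
write_genome <- function(seqs, path) {
  ss <- Biostrings::DNAStringSet(seqs)
  Biostrings::writeXStringSet(ss, path, width = 70L)
  invisible(path)
}

# 0-based half-open substring of a chromosome
seq_slice <- function(seqs, seq_id, start, end) {
  substr(seqs[[seq_id]], start + 1L, end)
}
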