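# Independent oracles: deliberately written with different machinery than
# the package (choose()-based enumeration, regexes, per-window loops).

# exact two-sided Fisher p for a 2x2 table by enumeration of the
# conditional (hypergeometric) distribution over tables with fixed margins
oracle_fisher2x2 <- function(a, b, c, d) {
  m <- a + b; n <- c + d; k <- a + c
  lo <- max(0, k - n); hi <- min(k, m)
  xs <- lo:hi
  probs <- choose(m, xs) * choose(n, k - xs) / choose(m + n, k)
  p_obs <- probs[match(a, xs)]
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# P(X >= q), X ~ Hypergeometric(N population, K marked, n drawn)
oracle_cum_hyper <- function(q, N, K, n) {
  ks <- seq(max(0, q, n - (N - K)), min(K, n))
  ks <- ks[ks >= q]
  if (!length(ks)) return(0)
  sum(choose(K, ks) * choose(N - K, n - ks)) / choose(N, n)
}

# independent degenerate-pattern -> regex converter (RNA in, DNA regex out)
oracle_motif_regex <- function(pattern) {
  x <- toupper(pattern)
  x <- gsub("\\(([ACGUT|]+)\\)", "[\\1]", x)
  x <- gsub("|", "", x, fixed = TRUE)
  iupac <- c(R = "[AG]", Y = "[CT]", S = "[CG]", W = "[AT]", K = "[GT]",
             M = "[AC]", B = "[CGT]", D = "[AGT]", H = "[ACT]", V = "[ACG]",
             N = "[ACGT]")
  for (code in names(iupac)) x <- gsub(code, iupac[[code]], x, fixed = TRUE)
  chartr("U", "T", x)
}

# all 0-based match offsets of a regex with overlap, via lookahead
oracle_scan <- function(pattern, seq) {
  rx <- paste0("(?=", oracle_motif_regex(pattern), ")")
  s <- toupper(chartr("U", "T", seq))
  m <- gregexpr(rx, s, perl = TRUE)[[1]]
  if (m[1] == -1) integer(0) else as.integer(m) - 1L
}

oracle_revcomp <- function(s) {
  paste(rev(strsplit(chartr("ACGT", "TGCA", toupper(s)), "")[[1]]), collapse = "")
}

# brute-force species support for a motif occurrence at reference position
# `gstart` (0-based) in a block: per species, slide over every ungapped
# window, regex-match on the gene strand, compare alignment columns
oracle_block_support <- function(block, reference, pattern, gstart, strand,
                                 window = 25) {
  len <- nchar(gsub("\\[[^]]*\\]", "N", oracle_motif_regex(pattern)))
  ref_chars <- strsplit(block$rows[[reference]], "")[[1]]
  ref_cols <- which(ref_chars != "-")
  c_ref <- ref_cols[gstart - block$start + 1]
  supp <- 0L
  for (sp in setdiff(names(block$rows), reference)) {
    chars <- strsplit(block$rows[[sp]], "")[[1]]
    cols <- which(chars != "-")
    ung <- paste(chars[cols], collapse = "")
    L <- nchar(ung)
    found <- FALSE
    if (L >= len) {
      for (i in 1:(L - len + 1)) {
        w <- substr(ung, i, i + len - 1)
        probe <- if (strand == "+") w else oracle_revcomp(w)
        if (grepl(paste0("^", oracle_motif_regex(pattern), "$"), probe)) {
          if (abs(cols[i] - c_ref) <= window) { found <- TRUE; break }
        }
      }
    }
    supp <- supp + found
  }
  supp
}

# Mann-Whitney U by naive pairwise comparison (ties counted half)
oracle_u_stat <- function(x, y) {
  sum(outer(x, y, function(a, b) (a > b) + 0.5 * (a == b)))
}
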