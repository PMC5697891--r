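# Degenerate RNA motif patterns and the core sequence scanner.
#
# Patterns are written in RNA (GCAUG), with parenthesised alternations
# (U(A|G|U)(A|G)GUU) and IUPAC one-letter degeneracy codes. Internally all
# sequence is DNA (T); motifs are presented back in RNA.

IUPAC_SETS <- list(
  A = "A", C = "C", G = "G", T = "T", U = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "T")
)

#' Parse a degenerate RNA motif pattern
#'
#' Accepts RNA or DNA letters (`T` and `U` are interchangeable),
#' parenthesised alternations such as `U(A|G|U)(A|G)GUU`, and IUPAC
#' degeneracy codes (`GCAYG`).
#'
#' @param pattern pattern text.
#' @param name motif name; defaults to the pattern text.
#' @return object of class `motif_pattern` with fields `name`, `pattern`,
#'   `sets` (list of allowed DNA bases per position) and `length`.
#' @export
parse_motif <- function(pattern, name = pattern) {
  txt <- toupper(gsub("\\s", "", pattern))
  chars <- strsplit(txt, "")[[1]]
  sets <- list()
  i <- 1L
  while (i <= length(chars)) {
    ch <- chars[i]
    if (ch == "(") {
      j <- i
      depth <- 0L
      repeat {
        if (j > length(chars)) stop("unbalanced parentheses in motif pattern: ", pattern)
        if (chars[j] == "(") depth <- depth + 1L
        if (chars[j] == ")") {
          depth <- depth - 1L
          if (depth == 0L) break
        }
        j <- j + 1L
      }
      inner <- paste(chars[(i + 1L):(j - 1L)], collapse = "")
      alts <- strsplit(inner, "|", fixed = TRUE)[[1]]
      alts <- alts[nzchar(alts)]
      if (!length(alts) || grepl("\\|\\||^\\||\\|$", inner) || inner == "") {
        stop("empty alternation in motif pattern: ", pattern)
      }
      if (any(nchar(alts) != 1L)) stop("alternations must be single bases: ", pattern)
      bases <- unique(unlist(IUPAC_SETS[alts]))
      if (anyNA(bases) || is.null(bases)) stop("unknown base in alternation: ", inner)
      sets[[length(sets) + 1L]] <- sort(bases)
      i <- j + 1L
    } else if (ch == ")") {
      stop("unbalanced parentheses in motif pattern: ", pattern)
    } else {
      s <- IUPAC_SETS[[ch]]
      if (is.null(s)) stop("unknown IUPAC code '", ch, "' in motif pattern: ", pattern)
      sets[[length(sets) + 1L]] <- sort(s)
      i <- i + 1L
    }
  }
  if (!length(sets)) stop("empty motif pattern")
  structure(list(name = name, pattern = pattern, sets = sets,
                 length = length(sets)),
            class = "motif_pattern")
}

as_motif <- function(x) {
  if (inherits(x, "motif_pattern")) x else parse_motif(x)
}

#' Scan a sequence for motif matches
#'
#' Reports every start offset whose window matches the motif at all
#' positions; overlapping matches are all reported.
#'
#' @param motif a [parse_motif()] pattern (or pattern text).
#' @param seq sequence text (DNA or RNA; case-insensitive).
#' @return integer vector of 0-based start offsets (empty if the sequence is
#'   shorter than the motif).
#' @export
scan_sequence <- function(motif, seq) {
  motif <- as_motif(motif)
  chars <- strsplit(toupper(chartr("U", "T", seq)), "")[[1]]
  L <- length(chars)
  m <- motif$length
  if (L < m) return(integer(0))
  ok <- rep(TRUE, L - m + 1L)
  for (i in seq_len(m)) {
    ok <- ok & chars[i:(L - m + i)] %in% motif$sets[[i]]
  }
  which(ok) - 1L
}

#' Present a motif pattern as RNA text
#' @param motif a `motif_pattern`.
#' @return character pattern with `U` for `T` and alternations restored.
#' @export
motif_rna <- function(motif) {
  motif <- as_motif(motif)
  parts <- vapply(motif$sets, function(s) {
    s <- chartr("T", "U", paste(s, collapse = "|"))
    if (nchar(s) > 1L) paste0("(", s, ")") else s
  }, "")
  paste(parts, collapse = "")
}

# one concrete DNA instance of a motif (first allowed base per position)
motif_instance <- function(motif) {
  motif <- as_motif(motif)
  paste(vapply(motif$sets, `[`, "", 1L), collapse = "")
}
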