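# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Derive a named random-number substream from a master seed
#'
#' All stochastic stages draw their seed from one master seed plus a stage
#' name, so stages are reproducible in isolation while a single `seed`
#' controls the whole study.
#'
#' @param seed master integer seed.
#' @param name character stage name.
#' @return an integer seed in `[0, 2^31 - 2]`.
#' @export
substream_seed <- function(seed, name) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(name))
  h <- 0
  for (ch in utf8ToInt(name)) h <- (h * 31 + ch) %% 2147483647
  as.integer((abs(seed) + h) %% 2147483647)
}

with_substream <- function(seed, name, expr) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  }
  set.seed(substream_seed(seed, name))
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  })
  force(expr)
}

#' Write a result table as tab-separated text with a commented header
#'
#' Missing values are written as `'.'`; header lines (run parameters, seed)
#' are prefixed with `#` so the file remains a valid single-header TSV.
#'
#' @param df data frame to write.
#' @param path output path.
#' @param meta named character/list of metadata written as `# key: value`.
#' @export
write_tsv_commented <- function(df, path, meta = NULL) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  if (length(meta)) {
    for (k in names(meta)) {
      writeLines(sprintf("# %s: %s", k, paste(format(meta[[k]]), collapse = " ")), con)
    }
  }
  out <- as.data.frame(df)
  for (j in seq_along(out)) {
    v <- out[[j]]
    if (is.numeric(v)) v <- ifelse(is.na(v), ".", format(v, digits = 15, trim = TRUE, scientific = FALSE))
    else {
      v <- as.character(v)
      v[is.na(v)] <- "."
    }
    out[[j]] <- v
  }
  writeLines(paste(names(out), collapse = "\t"), con)
  if (nrow(out)) {
    writeLines(do.call(paste, c(unname(out), sep = "\t")), con)
  }
  invisible(path)
}

#' Read a tab-separated table written by [write_tsv_commented()]
#'
#' @param path file path.
#' @return data frame; `'.'` entries become `NA`, numeric-looking columns are
#'   converted.
#' @export
read_tsv_commented <- function(path) {
  df <- utils::read.delim(path, comment.char = "#", na.strings = ".",
                          stringsAsFactors = FALSE, check.names = FALSE)
  df
}

# upper-tail cumulative hypergeometric P(X >= q) for overlap of a size-n draw
# with K marked among N.
cum_hyper_upper <- function(q, N, K, n) {
  stats::phyper(q - 1, K, N - K, n, lower.tail = FALSE)
}

is_wholenumber <- function(x, tol = 1e-8) {
  is.numeric(x) & is.finite(x) & abs(x - round(x)) < tol
}
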