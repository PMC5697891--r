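# event_catalog: non-redundant alternative-splicing events from gene models.
#
# Every internal exon of every transcript seeds a candidate trio
# (C1, A, C2); cross-isoform comparison assigns the event type. Events are
# keyed by junction coordinates so annotation dialect differences collapse.

# sense helpers: the acceptor of an exon is its sense-5' boundary, the donor
# its sense-3' boundary.
exon_acceptor <- function(start, end, strand) if (strand == "+") start else end
exon_donor <- function(start, end, strand) if (strand == "+") end else start

jkey <- function(seq_id, a, b) {
  data.frame(donor = min(a, b), acceptor = max(a, b), seq_id = seq_id,
             stringsAsFactors = FALSE)
}

junction_df <- function(seq_id, roles, lo, hi) {
  data.frame(role = roles, seq_id = seq_id, donor = pmin(lo, hi),
             acceptor = pmax(lo, hi), stringsAsFactors = FALSE)
}

new_event <- function(gene_id, seq_id, strand, type, alt_region, flank_up,
                      flank_down, inclusion, exclusion) {
  structure(list(event_id = NA_character_, gene_id = gene_id, seq_id = seq_id,
                 strand = strand, type = type, alt_region = alt_region,
                 flank_up = flank_up, flank_down = flank_down,
                 inclusion_junctions = inclusion, exclusion_junctions = exclusion,
                 novel = FALSE),
            class = "as_event")
}

event_key <- function(ev) {
  j <- rbind(ev$inclusion_junctions, ev$exclusion_junctions)
  ks <- sort(paste(j$donor, j$acceptor, sep = "-"))
  paste(ev$type, ev$seq_id, paste(ks, collapse = ";"))
}

#' Build the alternative-splicing event catalog
#'
#' Compares every pair of isoforms within each gene: a middle exon absent in
#' another isoform gives a cassette event (two or more consecutive absent
#' exons a multi-cassette); a shared acceptor with different donors an
#' alternative 5' splice-site event (alt3 for the acceptor side); two middle
#' exons that never co-occur across isoforms a mutually-exclusive event.
#' Redundant events (identical junction sets) are collapsed; events are
#' sorted by genomic position with deterministic ids.
#'
#' @param models a [gene_models()] set.
#' @return object of class `as_catalog` (list of events).
#' @export
build_catalog <- function(models) {
  stopifnot(inherits(models, "gene_models") || is.data.frame(models))
  events <- list()
  for (g in unique(models$gene_id)) {
    gm <- models[models$gene_id == g, , drop = FALSE]
    strand <- gm$strand[1]
    seq_id <- gm$seq_id[1]
    isoforms <- lapply(split(gm, gm$transcript_id), function(tm) {
      tm <- tm[order(tm$start), , drop = FALSE]
      cbind(start = tm$start, end = tm$end)
    })
    introns_of <- lapply(isoforms, function(ex) {
      n <- nrow(ex)
      if (n < 2) return(character(0))
      paste(ex[-n, "end"], ex[-1, "start"], sep = "-")
    })
    all_exons <- unique(do.call(rbind, isoforms))
    # exon co-occurrence for the mutually-exclusive test
    exon_id <- function(ex) paste(ex[, "start"], ex[, "end"], sep = "-")
    iso_sets <- lapply(isoforms, exon_id)

    for (i1 in seq_along(isoforms)) {
      ex1 <- isoforms[[i1]]
      n1 <- nrow(ex1)
      if (n1 < 3) next
      for (i2 in seq_along(isoforms)) {
        if (i2 == i1) next
        ex2 <- isoforms[[i2]]
        intr2 <- introns_of[[i2]]
        # cassette / multi-cassette: internal run of ex1 skipped in ex2
        for (a in 2:(n1 - 1)) {
          for (b in a:(n1 - 1)) {
            c1 <- ex1[a - 1, ]; c2 <- ex1[b + 1, ]
            skip <- paste(c1["end"], c2["start"], sep = "-")
            if (!(skip %in% intr2)) next
            alt <- ex1[a:b, , drop = FALSE]
            type <- if (b == a) "cassette" else "multi_cassette"
            incl <- junction_df(seq_id, c("C1A", "AC2"),
                                c(c1["end"], alt[nrow(alt), "end"]),
                                c(alt[1, "start"], c2["start"]))
            excl <- junction_df(seq_id, "C1C2", c1["end"], c2["start"])
            if (strand == "-") {  # sense roles flip on the minus strand
              incl$role <- rev(c("C1A", "AC2"))
              fu <- c2; fd <- c1
            } else {
              fu <- c1; fd <- c2
            }
            events[[length(events) + 1L]] <- new_event(
              g, seq_id, strand, type,
              data.frame(start = alt[, "start"], end = alt[, "end"]),
              fu, fd, incl, excl)
          }
        }
        # alternative donor/acceptor on a middle exon: same one boundary,
        # different other boundary
        if (nrow(ex2) < 3) next
        for (a in 2:(n1 - 1)) {
          for (b in 2:(nrow(ex2) - 1)) {
            e1 <- ex1[a, ]; e2 <- ex2[b, ]
            if (e1["start"] == e2["start"] && e1["end"] != e2["end"]) {
              shared <- "start"
            } else if (e1["end"] == e2["end"] && e1["start"] != e2["start"]) {
              shared <- "end"
            } else next
            # require shared flanking junction partners on the shared side
            c1_1 <- ex1[a - 1, ]; c2_1 <- ex1[a + 1, ]
            c1_2 <- ex2[b - 1, ]; c2_2 <- ex2[b + 1, ]
            if (shared == "start" && c1_1["end"] != c1_2["end"]) next
            if (shared == "end" && c2_1["start"] != c2_2["start"]) next
            # genomic-right boundary differs when shared == "start"
            if (shared == "start") {
              # alternative donors on + strand (alt5), acceptors on - (alt3)
              type <- if (strand == "+") "alt5" else "alt3"
              lo <- min(e1["end"], e2["end"]); hi <- max(e1["end"], e2["end"])
              alt_region <- data.frame(start = lo, end = hi)
              incl <- rbind(
                junction_df(seq_id, "CiA", c1_1["end"], e1["start"]),
                junction_df(seq_id, "ACj", e1["end"], c2_1["start"]),
                junction_df(seq_id, "ACj", e2["end"], c2_2["start"]))
              skip_lo <- c1_1["end"]
              skip_hi <- max(c2_1["start"], c2_2["start"])
              excl <- junction_df(seq_id, "CiCj", skip_lo, skip_hi)
              fu <- c1_1; fd <- c2_1
            } else {
              type <- if (strand == "+") "alt3" else "alt5"
              lo <- min(e1["start"], e2["start"]); hi <- max(e1["start"], e2["start"])
              alt_region <- data.frame(start = lo, end = hi)
              incl <- rbind(
                junction_df(seq_id, "CiA", c1_1["end"], e1["start"]),
                junction_df(seq_id, "CiA", c1_2["end"], e2["start"]),
                junction_df(seq_id, "ACj", e1["end"], c2_1["start"]))
              skip_lo <- min(c1_1["end"], c1_2["end"])
              skip_hi <- c2_1["start"]
              excl <- junction_df(seq_id, "CiCj", skip_lo, skip_hi)
              fu <- c1_1; fd <- c2_1
            }
            if (strand == "-") { tmp <- fu; fu <- fd; fd <- tmp }
            events[[length(events) + 1L]] <- new_event(
              g, seq_id, strand, type, alt_region, fu, fd,
              unique(incl), unique(excl))
          }
        }
        # mutually exclusive exons
        for (a in 2:(n1 - 1)) {
          for (b in 2:(nrow(ex2) - 1)) {
            a1 <- ex1[a, ]; a2 <- ex2[b, ]
            if (a1["end"] <= a2["start"] || a2["end"] <= a1["start"]) {
              c1_1 <- ex1[a - 1, ]; c2_1 <- ex1[a + 1, ]
              c1_2 <- ex2[b - 1, ]; c2_2 <- ex2[b + 1, ]
              if (c1_1["end"] != c1_2["end"] || c2_1["start"] != c2_2["start"]) next
              id1 <- paste(a1["start"], a1["end"], sep = "-")
              id2 <- paste(a2["start"], a2["end"], sep = "-")
              cooc <- any(vapply(iso_sets, function(s) all(c(id1, id2) %in% s), TRUE))
              if (cooc) next
              # orient: A1 is the genomically 5' exon; PSI measures its inclusion
              if (a1["start"] > a2["start"]) { tmp <- a1; a1 <- a2; a2 <- tmp }
              c1 <- c1_1; c2 <- c2_1
              incl <- junction_df(seq_id, c("C1A", "AC2"),
                                  c(c1["end"], a1["end"]),
                                  c(a1["start"], c2["start"]))
              excl <- junction_df(seq_id, c("C1C2", "C1C2"),
                                  c(c1["end"], a2["end"]),
                                  c(a2["start"], c2["start"]))
              fu <- if (strand == "+") c1 else c2
              fd <- if (strand == "+") c2 else c1
              events[[length(events) + 1L]] <- new_event(
                g, seq_id, strand, "mutually_exclusive",
                data.frame(start = c(a1["start"], a2["start"]),
                           end = c(a1["end"], a2["end"])),
                fu, fd, incl, excl)
            }
          }
        }
      }
    }
  }
  # collapse redundant events (identical type + junction sets)
  keys <- vapply(events, event_key, "")
  events <- events[!duplicated(keys)]
  # deterministic order and ids
  ord <- order(vapply(events, function(e) e$seq_id, ""),
               vapply(events, function(e) min(e$alt_region$start), 0),
               vapply(events, function(e) e$type, ""))
  events <- events[ord]
  for (i in seq_along(events)) events[[i]]$event_id <- sprintf("EV%05d", i)
  structure(events, class = "as_catalog")
}

#' Role-labelled junction keys of an event
#'
#' Cassette events carry `C1A`, `AC2` (inclusion) and `C1C2` (exclusion);
#' alternative-site events enumerate `CiA`/`ACj` inclusion combinations and
#' `CiCj` skip junctions; multi-cassette events use the two outermost
#' inclusion junctions plus the single full-skip junction; mutually-exclusive
#' events the two junction pairs.
#'
#' @param event an `as_event`.
#' @return data frame with columns `class` (`inclusion`/`exclusion`),
#'   `role`, `seq_id`, `donor`, `acceptor`.
#' @export
event_junctions <- function(event) {
  if (is.null(event$type) || is.na(event$type)) stop("untyped event")
  rbind(cbind(class = "inclusion", event$inclusion_junctions),
        cbind(class = "exclusion", event$exclusion_junctions))
}

#' @export
print.as_event <- function(x, ...) {
  cat(sprintf("<as_event %s> %s %s:%s [%s] %s\n", x$event_id, x$type, x$seq_id,
              x$strand, x$gene_id,
              paste(sprintf("%d-%d", x$alt_region$start, x$alt_region$end), collapse = ",")))
  invisible(x)
}

#' @export
print.as_catalog <- function(x, ...) {
  tab <- table(vapply(x, function(e) e$type, ""))
  cat(sprintf("<as_catalog> %d events (%s)\n", length(x),
              paste(names(tab), tab, sep = ":", collapse = ", ")))
  invisible(x)
}

ser_junc <- function(j) paste(sprintf("%s:%d-%d", j$role, j$donor, j$acceptor), collapse = ";")
deser_junc <- function(s, seq_id) {
  parts <- strsplit(s, ";", fixed = TRUE)[[1]]
  m <- regmatches(parts, regexec("^([^:]+):(\\d+)-(\\d+)$", parts))
  data.frame(role = vapply(m, `[`, "", 2), seq_id = seq_id,
             donor = as.integer(vapply(m, `[`, "", 3)),
             acceptor = as.integer(vapply(m, `[`, "", 4)),
             stringsAsFactors = FALSE)
}

#' Flatten a catalog to a data frame
#' @param x an `as_catalog`.
#' @param ... unused.
#' @return one row per event with serialised junction columns.
#' @method as.data.frame as_catalog
#' @export
as.data.frame.as_catalog <- function(x, ...) {
  do.call(rbind, lapply(x, function(e) {
    data.frame(event_id = e$event_id, gene_id = e$gene_id, seq_id = e$seq_id,
               strand = e$strand, type = e$type,
               alt_starts = paste(e$alt_region$start, collapse = ","),
               alt_ends = paste(e$alt_region$end, collapse = ","),
               flank_up_start = e$flank_up[["start"]], flank_up_end = e$flank_up[["end"]],
               flank_down_start = e$flank_down[["start"]], flank_down_end = e$flank_down[["end"]],
               inclusion = ser_junc(e$inclusion_junctions),
               exclusion = ser_junc(e$exclusion_junctions),
               novel = e$novel, stringsAsFactors = FALSE)
  }))
}

#' Write an event catalog as TSV
#' @param catalog an `as_catalog`.
#' @param path output path.
#' @param meta optional header metadata.
#' @export
write_catalog <- function(catalog, path, meta = NULL) {
  write_tsv_commented(as.data.frame(catalog), path, meta = meta)
}

#' Read an event catalog written by [write_catalog()]
#' @param path TSV path.
#' @return an `as_catalog`.
#' @export
read_catalog <- function(path) {
  df <- read_tsv_commented(path)
  events <- lapply(seq_len(nrow(df)), function(i) {
    r <- df[i, ]
    ev <- new_event(r$gene_id, r$seq_id, r$strand, r$type,
                    data.frame(start = as.integer(strsplit(as.character(r$alt_starts), ",")[[1]]),
                               end = as.integer(strsplit(as.character(r$alt_ends), ",")[[1]])),
                    c(start = r$flank_up_start, end = r$flank_up_end),
                    c(start = r$flank_down_start, end = r$flank_down_end),
                    deser_junc(r$inclusion, r$seq_id), deser_junc(r$exclusion, r$seq_id))
    ev$event_id <- r$event_id
    ev$novel <- isTRUE(r$novel)
    ev
  })
  structure(events, class = "as_catalog")
}

#' Export catalog events as GFF3 features for browser inspection
#' @param catalog an `as_catalog`.
#' @param path output path.
#' @export
catalog_gff3 <- function(catalog, path) {
  lines <- c("##gff-version 3")
  for (e in catalog) {
    for (i in seq_len(nrow(e$alt_region))) {
      lines <- c(lines, paste(e$seq_id, "splicecomb", "AS_event",
                              e$alt_region$start[i] + 1L, e$alt_region$end[i], ".",
                              e$strand, ".",
                              sprintf("ID=%s.%d;event=%s;type=%s;gene=%s",
                                      e$event_id, i, e$event_id, e$type, e$gene_id),
                              sep = "\t"))
    }
  }
  writeLines(lines, path)
  invisible(path)
}
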