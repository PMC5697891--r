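# synthetic_data: seeded generation of complete synthetic studies --
# genome, annotation, junction tables, multi-species alignments with
# planted motifs, fitness plates -- together with a truth table.
#
# All randomness flows through named substreams of one master seed
# (substream_seed), so a fixed seed gives byte-identical bundles while
# stages stay reproducible in isolation.

#' Configuration for a synthetic study
#'
#' Defaults describe a compact nematode-like study: short internal exons,
#' log-normal introns, cassette exons as the dominant event class, five
#' aligned species, and a differential contrast between a wild-type and one
#' mutant sample.
#'
#' @param n_genes number of genes.
#' @param exons_per_gene integer range (min, max) of exons per gene.
#' @param exon_length integer range of exon lengths (nt).
#' @param intron_meanlog,intron_sdlog log-normal intron length parameters.
#' @param intron_min minimum intron length (nt).
#' @param gc genome GC content.
#' @param minus_fraction fraction of genes on the minus strand.
#' @param cassette_fraction,multi_fraction,alt5_fraction,alt3_fraction,mxe_fraction
#'   fractions of genes carrying each event class (the remainder are
#'   constitutive).
#' @param samples sample ids; the first is the reference (wild type).
#' @param diff_fraction fraction of events that are differential between the
#'   reference and every other sample.
#' @param delta_psi planted |PSI change| for differential events.
#' @param depth expected junction reads per event.
#' @param species species names; the first is the reference.
#' @param substitution_rate per-base substitution probability in other
#'   species.
#' @param indel_rate per-base indel initiation probability.
#' @param indel_meanlen mean indel length (geometric).
#' @param planted_motifs list of single-motif planting specs: fields
#'   `pattern`, `name`, `region` (a region label), `prob_case`,
#'   `prob_background`, `conservation_species` (k other species carry the
#'   motif), `jitter` (max column offset of the conserved copies, <= 25).
#' @param planted_pairs list of motif-pair planting specs: fields `name_a`,
#'   `name_b`, `region`, `spacing`, `order` (`"ab"` in sense direction),
#'   `prob`, `conservation_species`, `jitter`, `spacing_conserved` (other
#'   species within +/-20% or deliberately outside).
#' @param fitness list: `strains` (named effects, reference first), `rnais`
#'   (named effects, control first), `epistasis` (data frame strain, rnai,
#'   factor), `baseline`, `noise_sd` (log-normal sd), `experiments`,
#'   `replicates`, `exp_effect_sd`.
#' @param seed master integer seed.
#' @return a `sim_config` list.
#' @export
sim_config <- function(n_genes = 60,
                       exons_per_gene = c(3, 6),
                       exon_length = c(80, 250),
                       intron_meanlog = log(200), intron_sdlog = 0.5,
                       intron_min = 60,
                       gc = 0.36,
                       minus_fraction = 0.5,
                       cassette_fraction = 0.4,
                       multi_fraction = 0.05,
                       alt5_fraction = 0.05,
                       alt3_fraction = 0.05,
                       mxe_fraction = 0.05,
                       samples = c("wt", "mut"),
                       diff_fraction = 0.3,
                       delta_psi = 40,
                       depth = 200,
                       species = c("C_elegans", "C_briggsae", "C_remanei",
                                   "C_sp11", "C_brenneri"),
                       substitution_rate = 0.15,
                       indel_rate = 0.02,
                       indel_meanlen = 2,
                       planted_motifs = list(
                         list(pattern = "GCAUG", name = "GCAUG",
                              region = "downstream_intron_5p",
                              prob_case = 0.6, prob_background = 0.1,
                              conservation_species = 3, jitter = 5),
                         list(pattern = "GCACA", name = "GCACA",
                              region = "upstream_intron_3p",
                              prob_case = 0.6, prob_background = 0.1,
                              conservation_species = 3, jitter = 5)
                       ),
                       planted_pairs = list(
                         list(name_a = "GCACA", name_b = "U(A|G|U)(A|G)GUU",
                              region = "upstream_intron_5p", spacing = 30,
                              order = "ab", prob = 0.35,
                              conservation_species = 3, jitter = 5,
                              spacing_conserved = TRUE)
                       ),
                       fitness = list(
                         strains = c(WT = 1.0, mutA = 0.8, mutB = 0.9),
                         rnais = c(GFP = 1.0, r1 = 0.7, r2 = 0.9, r3 = 0.5),
                         epistasis = data.frame(strain = "mutA", rnai = "r1",
                                                factor = 0.6),
                         baseline = 200, noise_sd = 0.1, experiments = 4,
                         replicates = 3, exp_effect_sd = 0.1),
                       seed = 1) {
  cfg <- as.list(environment())
  probs <- c(cfg$cassette_fraction, cfg$multi_fraction, cfg$alt5_fraction,
             cfg$alt3_fraction, cfg$mxe_fraction)
  if (any(probs < 0) || sum(probs) > 1) stop("event fractions must be in [0,1] and sum <= 1")
  if (cfg$diff_fraction < 0 || cfg$diff_fraction > 1) stop("diff_fraction in [0,1]")
  for (m in cfg$planted_motifs) {
    if ((m$jitter %||% 0) > 25) stop("planting jitter must be <= 25")
    if (m$conservation_species > length(cfg$species) - 1) {
      stop("conservation_species exceeds the number of other species")
    }
  }
  class(cfg) <- "sim_config"
  cfg
}

# sample one element of x (safe for length-1 vectors, unlike sample())
sample1 <- function(x) if (length(x) == 1L) x else sample(x, 1L)

random_dna <- function(n, gc = 0.36) {
  paste(sample(c("A", "T", "G", "C"), n, replace = TRUE,
               prob = c((1 - gc) / 2, (1 - gc) / 2, gc / 2, gc / 2)),
        collapse = "")
}

random_instance <- function(motif) {
  motif <- as_motif(motif)
  paste(vapply(motif$sets, function(s) sample(s, 1), ""), collapse = "")
}

# does `s` (genomic substring, length == motif length) match on `strand`?
genomic_submatch <- function(s, motif, strand) {
  m <- as_motif(motif)
  if (nchar(s) != m$length) return(FALSE)
  probe <- if (strand == "+") s else revcomp(s)
  length(scan_sequence(m, probe)) > 0
}

# change one base of a genomic window so it no longer matches the motif on
# the given strand; positions listed in `avoid` (1-based, e.g. overlapping a
# planted copy that must survive) are not touched
break_match <- function(s, motif, strand, avoid = integer(0)) {
  chars <- strsplit(s, "")[[1]]
  for (j in setdiff(seq_along(chars), avoid)) {
    for (b in setdiff(c("A", "C", "G", "T"), chars[j])) {
      cand <- chars; cand[j] <- b
      if (!genomic_submatch(paste(cand, collapse = ""), motif, strand)) {
        return(paste(cand, collapse = ""))
      }
    }
  }
  s
}

#' Simulate junction counts for one cassette-like event
#'
#' An included molecule spans the two inclusion junctions, a skipped
#' molecule only the skip junction, so with true inclusion fraction
#' `p/100` the probability that a junction read is an inclusion read is
#' `2p / (100 + p)`. Inclusion reads split evenly between the two adjacent
#' junctions.
#'
#' @param p true PSI in `[0, 100]`.
#' @param depth total junction reads at the event.
#' @param seed optional seed (set before drawing when given).
#' @return named integer vector `C1A`, `AC2`, `C1C2`.
#' @export
simulate_junction_counts <- function(p, depth, seed = NULL) {
  stopifnot(p >= 0, p <= 100, depth > 0)
  if (!is.null(seed)) set.seed(seed)
  q <- 2 * p / (100 + p)
  I <- stats::rbinom(1, depth, q)
  c1a <- stats::rbinom(1, I, 0.5)
  c(C1A = c1a, AC2 = I - c1a, C1C2 = depth - I)
}

#' Simulate a fitness-assay plate
#'
#' Populations follow `baseline * strain_effect * rnai_effect *
#' epistasis(strain, rnai) * experiment_effect * lognormal noise`; the
#' epistasis factor is 1 for the reference strain and for the control RNAi.
#'
#' @param fitness fitness block of a [sim_config()].
#' @param seed integer seed.
#' @return a [fitness_plate()] (reference strain and control RNAi taken from
#'   the first `strains`/`rnais` entries).
#' @export
simulate_fitness_plate <- function(fitness, seed = 1) {
  stopifnot(fitness$baseline > 0, fitness$replicates >= 2)
  strains <- fitness$strains; rnais <- fitness$rnais
  epi <- function(s, r) {
    if (s == names(strains)[1] || r == names(rnais)[1]) return(1)
    e <- fitness$epistasis
    hit <- which(e$strain == s & e$rnai == r)
    if (length(hit)) e$factor[hit[1]] else 1
  }
  rows <- list()
  with_substream(seed, "fitness", {
    for (e in seq_len(fitness$experiments)) {
      exp_eff <- exp(stats::rnorm(1, 0, fitness$exp_effect_sd %||% 0))
      for (s in names(strains)) for (r in names(rnais)) {
        for (rep in seq_len(fitness$replicates)) {
          noise <- if ((fitness$noise_sd %||% 0) > 0) {
            exp(stats::rnorm(1, 0, fitness$noise_sd))
          } else 1
          rows[[length(rows) + 1L]] <- data.frame(
            strain = s, rnai = r, experiment = e, replicate = rep,
            population = fitness$baseline * strains[[s]] * rnais[[r]] *
              epi(s, r) * exp_eff * noise,
            stringsAsFactors = FALSE)
        }
      }
    }
  })
  fitness_plate(do.call(rbind, rows),
                control_rnai = names(rnais)[1],
                reference_strain = names(strains)[1])
}

#' Simulate one alignment block
#'
#' Non-reference rows are derived from the reference by per-base
#' substitutions and geometric-length indels. Positions listed in `protect`
#' never receive indels (in any species), so planted motifs keep an exact
#' column correspondence; `writes` overwrite species characters at
#' reference-aligned positions after mutation.
#'
#' @param ref_seq reference sequence of the block.
#' @param species species names, reference first.
#' @param substitution_rate,indel_rate,indel_meanlen mutation parameters.
#' @param protect integer vector of 0-based reference positions excluded
#'   from indels.
#' @param writes named list (per species) of lists with `offset` (0-based
#'   reference position) and `text` (genomic characters to place there).
#' @param chrom,start reference placement of the block.
#' @param seed optional seed.
#' @return a block as stored in an `alignment_set`.
#' @export
simulate_alignment_block <- function(ref_seq, species,
                                     substitution_rate = 0.15,
                                     indel_rate = 0.02, indel_meanlen = 2,
                                     protect = integer(0), writes = NULL,
                                     chrom = "chrI", start = 0L, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  refchars <- strsplit(toupper(ref_seq), "")[[1]]
  L <- length(refchars)
  protected <- rep(FALSE, L)
  protect <- protect[protect >= 0 & protect < L]
  protected[protect + 1L] <- TRUE
  others <- species[-1]
  rowchars <- list()
  ins_len <- matrix(0L, nrow = length(others), ncol = L + 1,
                    dimnames = list(others, NULL))
  ins_seq <- matrix("", nrow = length(others), ncol = L + 1,
                    dimnames = list(others, NULL))
  for (sp in others) {
    ch <- refchars
    subs <- which(stats::runif(L) < substitution_rate)
    for (i in subs) ch[i] <- sample(setdiff(c("A", "C", "G", "T"), ch[i]), 1)
    # deletions (gaps in the species row)
    dstart <- which(stats::runif(L) < indel_rate / 2 & !protected)
    for (d in dstart) {
      len <- 1L + stats::rgeom(1, 1 / indel_meanlen)
      for (i in d:min(L, d + len - 1L)) {
        if (protected[i]) break
        ch[i] <- "-"
      }
    }
    # insertions (extra columns, gaps in all other rows)
    slots <- which(stats::runif(L + 1) < indel_rate / 2) - 1L  # 0..L
    bad <- vapply(slots, function(g) {
      g > 0 && g < L && protected[g] && protected[g + 1L]
    }, TRUE)
    slots <- slots[!bad]
    for (g in slots) {
      len <- 1L + stats::rgeom(1, 1 / indel_meanlen)
      ins_len[sp, g + 1L] <- len
      ins_seq[sp, g + 1L] <- random_dna(len, gc = 0.5)
    }
    if (!is.null(writes[[sp]])) {
      for (w in writes[[sp]]) {
        tchars <- strsplit(w$text, "")[[1]]
        idx <- w$offset + seq_along(tchars)
        if (any(idx < 1 | idx > L)) stop("write outside block")
        ch[idx] <- tchars
      }
    }
    rowchars[[sp]] <- ch
  }
  # weave insertion columns into the base rows
  base <- c(stats::setNames(list(refchars), species[1]), rowchars)
  slots_used <- which(colSums(ins_len) > 0) - 1L
  rows <- vapply(names(base), function(r) {
    parts <- character(0)
    prev <- 0L
    for (g in slots_used) {
      if (g > prev) parts <- c(parts, paste(base[[r]][(prev + 1L):g], collapse = ""))
      chunk <- ""
      for (sp in others) {
        l2 <- ins_len[sp, g + 1L]
        if (l2 > 0) {
          chunk <- paste0(chunk, if (identical(sp, r)) ins_seq[sp, g + 1L]
                          else strrep("-", l2))
        }
      }
      parts <- c(parts, chunk)
      prev <- g
    }
    if (prev < L) parts <- c(parts, paste(base[[r]][(prev + 1L):L], collapse = ""))
    paste(parts, collapse = "")
  }, "")
  list(chrom = chrom, start = as.integer(start), size = L, rows = rows)
}

# remove motif matches from one species row of a block, inside a column
# predicate, keeping matches that start at `keep_cols`
scrub_block_matches <- function(block, sp, motif, strand, keep_cols = integer(0),
                                col_lo = 1L, col_hi = NULL, center = NULL,
                                window = 25) {
  m <- as_motif(motif)
  if (is.null(col_hi)) col_hi <- nchar(block$rows[[1]])
  for (iter in 1:100) {
    cache <- block_species_cache(block)[[sp]]
    cols <- species_match_columns(cache, m, strand)
    if (!is.null(center)) {
      viol <- cols[abs(cols - center) <= window & !(cols %in% keep_cols)]
    } else {
      viol <- cols[cols >= col_lo & cols <= col_hi & !(cols %in% keep_cols)]
    }
    if (!length(viol)) break
    v <- viol[1]
    idx0 <- match(v, cache$nongap) - 1L       # 0-based ungapped leftmost
    span_cols <- cache$nongap[idx0 + seq_len(m$length)]
    # never substitute inside a kept (planted) copy overlapping this match
    kept_spans <- unlist(lapply(keep_cols, function(k) {
      ki <- match(k, cache$nongap)
      if (is.na(ki)) return(integer(0))
      cache$nongap[ki + seq_len(m$length) - 1L]
    }))
    avoid <- which(span_cols %in% kept_spans)
    s <- paste(cache$chars[span_cols], collapse = "")
    s2 <- break_match(s, m, strand, avoid = avoid)
    ch2 <- strsplit(s2, "")[[1]]
    row <- block$rows[[sp]]
    for (j in seq_along(span_cols)) {
      substr(row, span_cols[j], span_cols[j]) <- ch2[j]
    }
    block$rows[[sp]] <- row
  }
  block
}

# remove motif matches from a plain genomic string within [lo, hi) (0-based),
# keeping matches starting at keep_gstarts (0-based leftmost)
scrub_seq_matches <- function(seq, motif, strand, lo, hi, keep_gstarts = integer(0)) {
  m <- as_motif(motif)
  for (iter in 1:100) {
    window <- substr(seq, lo + 1L, hi)
    probe <- if (strand == "+") window else revcomp(window)
    offs <- scan_sequence(m, probe)
    if (strand == "+") left <- lo + offs else left <- hi - offs - m$length
    viol <- left[!(left %in% keep_gstarts)]
    if (!length(viol)) break
    v <- viol[1]
    kept <- unlist(lapply(keep_gstarts, function(k) k + seq_len(m$length) - 1L))
    avoid <- which((v + seq_len(m$length) - 1L) %in% kept)
    s <- substr(seq, v + 1L, v + m$length)
    substr(seq, v + 1L, v + m$length) <- break_match(s, m, strand, avoid = avoid)
  }
  seq
}

# -------------------------------------------------------------------------

pick_gene_types <- function(cfg, n) {
  probs <- c(cassette = cfg$cassette_fraction, multi_cassette = cfg$multi_fraction,
             alt5 = cfg$alt5_fraction, alt3 = cfg$alt3_fraction,
             mutually_exclusive = cfg$mxe_fraction)
  probs <- c(probs, none = 1 - sum(probs))
  sample(names(probs), n, replace = TRUE, prob = probs)
}

build_gene_structures <- function(cfg) {
  types <- pick_gene_types(cfg, cfg$n_genes)
  cursor <- 0L
  genes <- list()
  for (i in seq_len(cfg$n_genes)) {
    type <- types[i]
    min_ex <- switch(type, cassette = 3L, alt5 = 3L, alt3 = 3L,
                     multi_cassette = 4L, mutually_exclusive = 4L, 1L)
    lo <- max(min_ex, cfg$exons_per_gene[1])
    hi <- max(lo, cfg$exons_per_gene[2])
    n_ex <- if (hi > lo) sample(lo:hi, 1) else lo
    ex_len <- sample(cfg$exon_length[1]:cfg$exon_length[2], n_ex, replace = TRUE)
    in_len <- pmax(cfg$intron_min,
                   round(stats::rlnorm(max(0, n_ex - 1), cfg$intron_meanlog,
                                       cfg$intron_sdlog)))
    cursor <- cursor + sample1(200:400)
    starts <- integer(n_ex); ends <- integer(n_ex)
    pos <- cursor
    for (k in seq_len(n_ex)) {
      starts[k] <- pos; ends[k] <- pos + ex_len[k]
      pos <- ends[k] + if (k < n_ex) in_len[k] else 0L
    }
    cursor <- pos
    strand <- if (stats::runif(1) < cfg$minus_fraction) "-" else "+"
    # position of the alternative exon (internal)
    k_alt <- if (type %in% c("multi_cassette", "mutually_exclusive")) {
      if (n_ex < 4) 2L else sample1(2:(n_ex - 2))
    } else if (type != "none") {
      sample1(2:(n_ex - 1))
    } else NA_integer_
    genes[[i]] <- list(gene_id = sprintf("gene%03d", i), type = type,
                       strand = strand, starts = starts, ends = ends,
                       k_alt = k_alt)
  }
  genes
}

gene_transcripts <- function(g, cfg) {
  n_ex <- length(g$starts)
  all_idx <- seq_len(n_ex)
  t1 <- all_idx; t2 <- NULL
  s2 <- g$starts; e2 <- g$ends
  if (g$type == "cassette") {
    t2 <- setdiff(all_idx, g$k_alt)
  } else if (g$type == "multi_cassette") {
    t2 <- setdiff(all_idx, c(g$k_alt, g$k_alt + 1L))
  } else if (g$type == "mutually_exclusive") {
    t1 <- setdiff(all_idx, g$k_alt + 1L)
    t2 <- setdiff(all_idx, g$k_alt)
  } else if (g$type %in% c("alt5", "alt3")) {
    k <- g$k_alt
    ext <- sample1(20:min(60, g$ends[k] - g$starts[k] - 30L))
    shared_start <- (g$type == "alt5") == (g$strand == "+")
    if (shared_start) e2[k] <- g$ends[k] - ext else s2[k] <- g$starts[k] + ext
    t2 <- all_idx
  }
  tx <- list(list(id = paste0(g$gene_id, ".t1"), starts = g$starts[t1], ends = g$ends[t1]))
  if (!is.null(t2)) {
    tx[[2]] <- list(id = paste0(g$gene_id, ".t2"), starts = s2[t2], ends = e2[t2])
  }
  tx
}

simulate_event_counts <- function(ev, p, depth) {
  incl <- ev$inclusion_junctions
  excl <- ev$exclusion_junctions
  add <- function(j, n) cbind(j[, c("seq_id", "donor", "acceptor")], count = n)
  if (ev$type == "mutually_exclusive") {
    I <- stats::rbinom(1, depth, p / 100)
    E <- depth - I
    i1 <- stats::rbinom(1, I, 0.5)
    e1 <- stats::rbinom(1, E, 0.5)
    return(rbind(add(incl[1, ], i1), add(incl[2, ], I - i1),
                 add(excl[1, ], e1), add(excl[2, ], E - e1)))
  }
  q <- 2 * p / (100 + p)
  I <- stats::rbinom(1, depth, q)
  skip <- depth - I
  if (ev$type %in% c("cassette", "multi_cassette")) {
    c1a <- stats::rbinom(1, I, 0.5)
    return(rbind(add(incl[incl$role == "C1A", ][1, ], c1a),
                 add(incl[incl$role == "AC2", ][1, ], I - c1a),
                 add(excl[1, ], skip)))
  }
  # alt5/alt3: split inclusion reads between the two sides, then among the
  # enumerated variants of each side
  side_a <- incl[incl$role == "CiA", , drop = FALSE]
  side_j <- incl[incl$role == "ACj", , drop = FALSE]
  ia <- stats::rbinom(1, I, 0.5)
  ij <- I - ia
  split_side <- function(side, total) {
    if (nrow(side) == 1) return(add(side, total))
    parts <- as.vector(stats::rmultinom(1, total, rep(1, nrow(side))))
    do.call(rbind, lapply(seq_len(nrow(side)), function(r) add(side[r, ], parts[r])))
  }
  rbind(split_side(side_a, ia), split_side(side_j, ij), add(excl[1, ], skip))
}

#' Simulate a complete synthetic study
#'
#' Generates a genome, annotation, per-sample junction tables, a
#' multi-species alignment with motifs planted at controlled conservation,
#' spacing and ordering, and a fitness plate — writing every file in the
#' dialects the package readers accept, plus truth tables listing every
#' planted signal. Deterministic for a fixed `config$seed`.
#'
#' @param config a [sim_config()].
#' @param dir output directory (created if needed); `NULL` keeps everything
#'   in memory only.
#' @return a `sim_study` list: `genome`, `models`, `catalog`, `counts`
#'   (named list of junction tables), `alignments`, `plate`, `truth`
#'   (list of `events`, `motifs`, `pairs`, `fitness` data frames),
#'   `paths` (when written) and `config`.
#' @export
simulate_study <- function(config, dir = NULL) {
  cfg <- config
  chrom <- "chrI"
  genes <- with_substream(cfg$seed, "structure", build_gene_structures(cfg))
  tx_rows <- list()
  with_substream(cfg$seed, "isoforms", {
    for (g in genes) {
      for (t in gene_transcripts(g, cfg)) {
        tx_rows[[length(tx_rows) + 1L]] <- data.frame(
          gene_id = g$gene_id, transcript_id = t$id, seq_id = chrom,
          strand = g$strand, start = t$starts, end = t$ends,
          stringsAsFactors = FALSE)
      }
    }
  })
  models <- gene_models(do.call(rbind, tx_rows))
  catalog <- build_catalog(models)
  ev_by_gene <- split(seq_along(catalog), vapply(catalog, function(e) e$gene_id, ""))

  glen <- max(models$end) + 400L
  genome_seq <- with_substream(cfg$seed, "genome_seq", random_dna(glen, cfg$gc))

  # true PSI per event and sample
  truth_events <- NULL
  psi <- list()
  with_substream(cfg$seed, "psi", {
    rows <- list()
    for (ev in catalog) {
      base <- stats::runif(1, 20, 80)
      is_diff <- stats::runif(1) < cfg$diff_fraction
      pvec <- stats::setNames(rep(base, length(cfg$samples)), cfg$samples)
      if (is_diff && length(cfg$samples) > 1) {
        shift <- if (base + cfg$delta_psi <= 95) cfg$delta_psi else -cfg$delta_psi
        pvec[-1] <- min(95, max(5, base + shift))
      }
      psi[[ev$event_id]] <- pvec
      rows[[length(rows) + 1L]] <- data.frame(
        event_id = ev$event_id, gene_id = ev$gene_id, type = ev$type,
        strand = ev$strand, differential = is_diff,
        delta_psi = unname(pvec[length(pvec)] - pvec[1]),
        t(pvec), stringsAsFactors = FALSE, check.names = FALSE)
    }
    truth_events <- if (length(rows)) do.call(rbind, rows) else
      data.frame(event_id = character(0))
  })

  # ---- motif planting -----------------------------------------------------
  motif_objs <- list()
  for (m in cfg$planted_motifs) motif_objs[[m$name]] <- parse_motif(m$pattern, m$name)
  for (p in cfg$planted_pairs) {
    for (nm in c(p$name_a, p$name_b)) {
      if (is.null(motif_objs[[nm]])) motif_objs[[nm]] <- parse_motif(nm, nm)
    }
  }
  others <- cfg$species[-1]
  plant_state <- list()   # per gene: occupied, protect, writes, scrubs
  for (g in genes) {
    plant_state[[g$gene_id]] <- list(occupied = NULL, protect = integer(0),
                                     writes = stats::setNames(
                                       vector("list", length(others)), others),
                                     scrubs = list())
  }
  truth_motifs <- list()
  truth_pairs <- list()

  regions_by_event <- lapply(catalog, event_regions, genome = NULL, window = 300)
  names(regions_by_event) <- vapply(catalog, function(e) e$event_id, "")

  overlaps <- function(occ, lo, hi) {
    !is.null(occ) && any(occ[, 1] < hi & lo < occ[, 2])
  }

  with_substream(cfg$seed, "planting", {
    for (ev in catalog) {
      g <- genes[[match(ev$gene_id, vapply(genes, function(x) x$gene_id, ""))]]
      st <- plant_state[[ev$gene_id]]
      regs <- regions_by_event[[ev$event_id]]
      is_case <- isTRUE(truth_events$differential[truth_events$event_id == ev$event_id])
      for (m in cfg$planted_motifs) {
        prob <- if (is_case) m$prob_case %||% 0.5 else m$prob_background %||% 0.1
        if (stats::runif(1) >= prob) next
        reg <- regs[regs$label == m$region, , drop = FALSE]
        if (!nrow(reg)) next
        reg <- reg[1, ]
        mo <- motif_objs[[m$name]]
        jit <- m$jitter %||% 5
        len <- mo$length
        if (reg$end - reg$start < len) next
        gpos <- NA
        for (try in 1:40) {
          cand <- sample1(reg$start:(reg$end - len))
          if (!overlaps(st$occupied, cand - jit - 2L, cand + len + jit + 2L)) {
            gpos <- cand; break
          }
        }
        if (is.na(gpos)) next
        inst <- random_instance(mo)
        text <- if (ev$strand == "+") inst else revcomp(inst)
        substr(genome_seq, gpos + 1L, gpos + len) <- text
        st$occupied <- rbind(st$occupied, c(gpos - jit - 2L, gpos + len + jit + 2L))
        st$protect <- c(st$protect, (gpos - jit - 1L):(gpos + len + jit))
        k <- m$conservation_species
        supp <- if (k > 0) sample(others, k) else character(0)
        for (sp in supp) {
          delta <- if (jit > 0) sample1((-jit):jit) else 0L
          st$writes[[sp]] <- c(st$writes[[sp]],
                               list(list(offset = gpos + delta, text = text)))
        }
        for (sp in setdiff(others, supp)) {
          st$scrubs[[length(st$scrubs) + 1L]] <- list(
            sp = sp, motif = m$name, strand = ev$strand,
            center_g = gpos, window = 25L)
        }
        truth_motifs[[length(truth_motifs) + 1L]] <- data.frame(
          event_id = ev$event_id, gene_id = ev$gene_id, motif = m$name,
          label = m$region, gstart = gpos, strand = ev$strand,
          conservation_species = k, stringsAsFactors = FALSE)
      }
      for (pp in cfg$planted_pairs) {
        if (stats::runif(1) >= (pp$prob %||% 0.3)) next
        reg <- regs[regs$label == pp$region, , drop = FALSE]
        if (!nrow(reg)) next
        reg <- reg[1, ]
        ma <- motif_objs[[pp$name_a]]; mb <- motif_objs[[pp$name_b]]
        la <- ma$length; lb <- mb$length
        s <- pp$spacing
        total <- la + s + lb
        jit <- pp$jitter %||% 5
        slack <- as.integer(ceiling(0.5 * s)) + 4L
        # keep the jittered species copies inside the region, which bounds
        # the cross-species spacing search
        margin <- jit + slack
        if (reg$end - reg$start < total + 2L * margin) next
        gleft <- NA
        for (try in 1:40) {
          cand <- sample1((reg$start + margin):(reg$end - total - margin))
          if (!overlaps(st$occupied, cand - margin, cand + total + margin)) {
            gleft <- cand; break
          }
        }
        if (is.na(gleft)) next
        ab <- identical(pp$order %||% "ab", "ab")
        # sense-upstream motif sits genomic-left on '+', genomic-right on '-'
        first_is_a <- (ab && ev$strand == "+") || (!ab && ev$strand == "-")
        m_left <- if (first_is_a) ma else mb
        m_right <- if (first_is_a) mb else ma
        inst_left <- random_instance(m_left)
        inst_right <- random_instance(m_right)
        t_left <- if (ev$strand == "+") inst_left else revcomp(inst_left)
        t_right <- if (ev$strand == "+") inst_right else revcomp(inst_right)
        g_right <- gleft + m_left$length + s
        substr(genome_seq, gleft + 1L, gleft + m_left$length) <- t_left
        substr(genome_seq, g_right + 1L, g_right + m_right$length) <- t_right
        st$occupied <- rbind(st$occupied,
                             c(gleft - jit - slack, gleft + total + jit + slack))
        st$protect <- c(st$protect, (gleft - jit - slack):(gleft + total + jit + slack - 1L))
        k <- pp$conservation_species
        supp <- if (k > 0) sample(others, k) else character(0)
        cons_ok <- isTRUE(pp$spacing_conserved %||% TRUE)
        for (sp in supp) {
          delta <- if (jit > 0) sample1((-jit):jit) else 0L
          sp_spacing <- if (cons_ok) {
            if (s >= 10) as.integer(round(s * stats::runif(1, 0.87, 1.13))) else s
          } else {
            s + as.integer(ceiling(0.2 * s)) + 3L
          }
          st$writes[[sp]] <- c(st$writes[[sp]], list(
            list(offset = gleft + delta, text = t_left),
            list(offset = gleft + delta + m_left$length + sp_spacing, text = t_right)))
        }
        # scrub every non-planted match of either motif in the region, in
        # every other species and in the reference itself
        keep_ref <- c(gleft, g_right)
        genome_seq <- scrub_seq_matches(genome_seq, ma, ev$strand, reg$start, reg$end,
                                        keep_gstarts = keep_ref)
        genome_seq <- scrub_seq_matches(genome_seq, mb, ev$strand, reg$start, reg$end,
                                        keep_gstarts = keep_ref)
        for (sp in others) {
          st$scrubs[[length(st$scrubs) + 1L]] <- list(
            sp = sp, motif = pp$name_a, strand = ev$strand,
            range_g = c(reg$start, reg$end),
            keep_writes = TRUE)
          st$scrubs[[length(st$scrubs) + 1L]] <- list(
            sp = sp, motif = pp$name_b, strand = ev$strand,
            range_g = c(reg$start, reg$end),
            keep_writes = TRUE)
        }
        off_up <- if (ev$strand == "+") gleft - reg$start else reg$end - g_right - m_right$length
        truth_pairs[[length(truth_pairs) + 1L]] <- data.frame(
          event_id = ev$event_id, gene_id = ev$gene_id,
          motif_a = pp$name_a, motif_b = pp$name_b, label = pp$region,
          spacing = s, order = pp$order %||% "ab",
          gstart_left = gleft, gstart_right = g_right, strand = ev$strand,
          conservation_species = k, spacing_conserved = cons_ok,
          offset_up = off_up, stringsAsFactors = FALSE)
      }
      plant_state[[ev$gene_id]] <- st
    }
  })

  genome <- stats::setNames(c(genome_seq), chrom)

  # ---- junction counts ----------------------------------------------------
  event_keys <- unique(unlist(lapply(catalog, function(ev) {
    j <- rbind(ev$inclusion_junctions, ev$exclusion_junctions)
    paste(j$seq_id, j$donor, j$acceptor, sep = ":")
  })))
  all_introns <- unique(do.call(rbind, lapply(split(models, models$transcript_id),
    function(tm) {
      tm <- tm[order(tm$start), , drop = FALSE]
      n <- nrow(tm)
      if (n < 2) return(NULL)
      data.frame(seq_id = tm$seq_id[-n], donor = tm$end[-n],
                 acceptor = tm$start[-1], strand = tm$strand[-n],
                 stringsAsFactors = FALSE)
    })))
  counts <- list()
  for (smp in cfg$samples) {
    with_substream(cfg$seed, paste0("counts:", smp), {
      rows <- list()
      if (!is.null(all_introns)) {
        bg <- all_introns[!(paste(all_introns$seq_id, all_introns$donor,
                                  all_introns$acceptor, sep = ":") %in% event_keys), ,
                          drop = FALSE]
        if (nrow(bg)) {
          bg$count <- stats::rpois(nrow(bg), cfg$depth)
          rows[[length(rows) + 1L]] <- bg
        }
      }
      for (ev in catalog) {
        cc <- simulate_event_counts(ev, psi[[ev$event_id]][[smp]], cfg$depth)
        cc$strand <- ev$strand
        rows[[length(rows) + 1L]] <- cc[, c("seq_id", "donor", "acceptor", "strand", "count")]
      }
      counts[[smp]] <- junction_counts(do.call(rbind, rows), sample_id = smp)
    })
  }

  # ---- alignments ---------------------------------------------------------
  blocks <- list()
  for (g in genes) {
    st <- plant_state[[g$gene_id]]
    b_start <- max(0L, min(g$starts) - 50L)
    b_end <- min(glen, max(g$ends) + 50L)
    ref_seq <- seq_slice(genome, chrom, b_start, b_end)
    writes_local <- lapply(st$writes, function(ws) {
      lapply(ws, function(w) list(offset = w$offset - b_start, text = w$text))
    })
    blk <- with_substream(cfg$seed, paste0("align:", g$gene_id),
      simulate_alignment_block(ref_seq, cfg$species,
                               substitution_rate = cfg$substitution_rate,
                               indel_rate = cfg$indel_rate,
                               indel_meanlen = cfg$indel_meanlen,
                               protect = unique(st$protect) - b_start,
                               writes = writes_local,
                               chrom = chrom, start = b_start))
    # enforce planted truth: remove accidental matches where they would
    # change a conservation, spacing or ordering call
    if (length(st$scrubs)) {
      cm <- block_colmap(blk)
      keep_cols_for <- function(sp, motif_name) {
        ws <- st$writes[[sp]]
        if (is.null(ws)) return(integer(0))
        offs <- vapply(ws, function(w) w$offset, 0)
        lens <- vapply(ws, function(w) nchar(w$text), 0)
        sel <- lens == motif_objs[[motif_name]]$length
        local <- offs[sel] - b_start
        local <- local[local >= 0 & local < blk$size]
        cm[local + 1L]
      }
      for (sc in st$scrubs) {
        if (!is.null(sc$center_g)) {
          center_local <- sc$center_g - b_start
          blk <- scrub_block_matches(blk, sc$sp, motif_objs[[sc$motif]], sc$strand,
                                     keep_cols = keep_cols_for(sc$sp, sc$motif),
                                     center = cm[center_local + 1L],
                                     window = sc$window + motif_objs[[sc$motif]]$length)
        } else {
          lo_local <- sc$range_g[1] - b_start
          hi_local <- sc$range_g[2] - b_start
          blk <- scrub_block_matches(blk, sc$sp, motif_objs[[sc$motif]], sc$strand,
                                     keep_cols = keep_cols_for(sc$sp, sc$motif),
                                     col_lo = cm[lo_local + 1L],
                                     col_hi = cm[hi_local])
        }
      }
    }
    blocks[[length(blocks) + 1L]] <- blk
  }
  alignments <- structure(list(blocks = blocks, reference = cfg$species[1],
                               species = cfg$species),
                          class = "alignment_set")

  plate <- simulate_fitness_plate(cfg$fitness, seed = substream_seed(cfg$seed, "plate"))
  truth_fitness <- cfg$fitness$epistasis

  truth <- list(
    events = truth_events,
    motifs = if (length(truth_motifs)) do.call(rbind, truth_motifs) else
      data.frame(event_id = character(0)),
    pairs = if (length(truth_pairs)) do.call(rbind, truth_pairs) else
      data.frame(event_id = character(0)),
    fitness = truth_fitness)

  study <- list(genome = genome, models = models, catalog = catalog,
                counts = counts, alignments = alignments, plate = plate,
                truth = truth, config = cfg, paths = NULL)
  class(study) <- "sim_study"
  if (!is.null(dir)) study <- write_study(study, dir)
  study
}

#' Write a simulated study bundle to disk
#' @param study a `sim_study`.
#' @param dir output directory.
#' @return the study with `paths` filled in.
#' @export
write_study <- function(study, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  cfg <- study$config
  meta <- list(seed = cfg$seed, n_genes = cfg$n_genes, depth = cfg$depth,
               samples = paste(cfg$samples, collapse = ","),
               species = paste(cfg$species, collapse = ","))
  paths <- list(
    genome = file.path(dir, "genome.fa"),
    annotation = file.path(dir, "annotation.gff3"),
    alignments = file.path(dir, "alignments.maf"),
    fitness = file.path(dir, "fitness.tsv"),
    truth_events = file.path(dir, "truth_events.tsv"),
    truth_motifs = file.path(dir, "truth_motifs.tsv"),
    truth_pairs = file.path(dir, "truth_pairs.tsv"),
    truth_fitness = file.path(dir, "truth_fitness.tsv"))
  write_genome(study$genome, paths$genome)
  write_gene_models(study$models, paths$annotation)
  src_sizes <- stats::setNames(rep(nchar(study$genome), length(cfg$species)),
                               paste0(cfg$species, ".", names(study$genome)))
  write_alignments(study$alignments, paths$alignments, src_sizes = src_sizes)
  write_tsv_commented(as.data.frame(study$plate), paths$fitness, meta = meta)
  for (smp in names(study$counts)) {
    paths[[paste0("junctions_", smp)]] <- file.path(dir, paste0("junctions_", smp, ".tsv"))
    write_junction_counts(study$counts[[smp]], paths[[paste0("junctions_", smp)]],
                          meta = meta["seed"])
  }
  write_tsv_commented(study$truth$events, paths$truth_events, meta = meta)
  write_tsv_commented(study$truth$motifs, paths$truth_motifs, meta = meta)
  write_tsv_commented(study$truth$pairs, paths$truth_pairs, meta = meta)
  write_tsv_commented(study$truth$fitness, paths$truth_fitness, meta = meta)
  study$paths <- paths
  study
}
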