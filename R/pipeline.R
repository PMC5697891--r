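# cli_pipeline: configuration and end-to-end orchestration of the stages
# (catalog -> psi -> differential -> scan -> conservation -> enrichment ->
# co-occurrence -> geometry -> fitness), each stage writing its table so
# runs can be resumed from cached intermediates.

#' Pipeline run configuration
#'
#' Thresholds default to the study's printed values: alpha 0.05, minimum
#' |PSI change| 15, 300 nt splice-site windows, conservation in >= 2 other
#' species within 25 nt, +/-20% spacing tolerance, 100 (motif) and 1000
#' (term) control randomisations, interaction-score hit threshold 0.7.
#'
#' @param out_dir output directory.
#' @param seed master seed, recorded in every output header.
#' @param simulate generate the input bundle with [simulate_study()]
#'   (default TRUE); otherwise the file paths below must be given.
#' @param sim a [sim_config()] used when `simulate = TRUE`.
#' @param annotation,genome,alignments,fitness input file paths.
#' @param junctions named character vector of junction-table paths
#'   (first = wild type, second = mutant).
#' @param motifs character vector of motif patterns (named or not).
#' @param alpha,min_delta differential-call thresholds.
#' @param window splice-site window (nt).
#' @param conservation_species,conservation_window conservation rule.
#' @param spacing_tolerance relative spacing-conservation tolerance.
#' @param n_randomizations motif-enrichment control sets.
#' @param interaction_threshold screen hit threshold.
#' @return a `run_config` list.
#' @export
run_config <- function(out_dir, seed = 1, simulate = TRUE,
                       sim = sim_config(seed = seed),
                       annotation = NULL, genome = NULL, junctions = NULL,
                       alignments = NULL, fitness = NULL,
                       motifs = c("GCAUG", "GCACA", "U(A|G|U)(A|G)GUU"),
                       alpha = 0.05, min_delta = 15, window = 300,
                       conservation_species = 2, conservation_window = 25,
                       spacing_tolerance = 0.20, n_randomizations = 100,
                       interaction_threshold = 0.7) {
  cfg <- as.list(environment())
  class(cfg) <- "run_config"
  cfg
}

pipeline_stages <- c("catalog", "psi", "diff", "scan", "conserve", "enrich",
                     "cooccur", "geometry", "fitness")

#' Run the full analysis pipeline
#'
#' Executes every stage in order on the configured inputs (or a freshly
#' simulated study), writing one tab-separated table per stage plus a
#' manifest with md5 checksums. Stages before `resume_from` are reloaded
#' from their cached tables instead of recomputed.
#'
#' @param config a [run_config()].
#' @param resume_from stage name to resume from (`NULL` = run everything).
#' @return list of stage results (invisible file paths in `manifest`).
#' @export
run_pipeline <- function(config, resume_from = NULL) {
  cfg <- config
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  meta <- list(seed = cfg$seed, alpha = cfg$alpha, min_delta = cfg$min_delta,
               window = cfg$window,
               conservation = paste0(">=", cfg$conservation_species,
                                     " species within ", cfg$conservation_window, "nt"))
  out <- function(name) file.path(cfg$out_dir, paste0(name, ".tsv"))
  skip_before <- if (is.null(resume_from)) 0L else match(resume_from, pipeline_stages)
  if (is.na(skip_before)) stop("unknown stage: ", resume_from)
  run_stage <- function(idx) is.null(resume_from) || idx >= skip_before
  res <- list()

  # inputs
  if (cfg$simulate) {
    study <- simulate_study(cfg$sim, dir = file.path(cfg$out_dir, "data"))
    genome <- study$genome
    models <- study$models
    counts <- study$counts
    alignments <- study$alignments
    plate <- study$plate
    res$study <- study
  } else {
    genome <- read_genome(cfg$genome)
    models <- read_gene_models(cfg$annotation)
    counts <- lapply(cfg$junctions, read_junction_counts)
    if (is.null(names(counts))) names(counts) <- basename(cfg$junctions)
    alignments <- read_alignments(cfg$alignments)
    plate <- if (!is.null(cfg$fitness)) read_fitness_plate(cfg$fitness) else NULL
  }
  motifs <- lapply(cfg$motifs, parse_motif)
  names(motifs) <- vapply(motifs, function(m) m$name, "")

  stage_fail <- function(stage, e) {
    stop("pipeline stage '", stage, "' failed: ", conditionMessage(e), call. = FALSE)
  }

  # catalog
  if (run_stage(1L)) {
    res$catalog <- tryCatch(build_catalog(models), error = function(e) stage_fail("catalog", e))
    write_catalog(res$catalog, out("catalog"), meta = meta)
    catalog_gff3(res$catalog, file.path(cfg$out_dir, "events.gff3"))
  } else {
    res$catalog <- read_catalog(out("catalog"))
  }

  # psi
  if (run_stage(2L)) {
    res$psi <- tryCatch(
      do.call(rbind, lapply(counts, function(cc) psi_table(res$catalog, cc))),
      error = function(e) stage_fail("psi", e))
    write_tsv_commented(res$psi, out("psi"), meta = meta)
  } else {
    res$psi <- read_tsv_commented(out("psi"))
  }

  # differential (first sample vs second)
  if (run_stage(3L)) {
    if (length(counts) < 2) stop("differential stage needs two samples")
    res$diff <- tryCatch(
      differential_table(res$catalog, counts[[1]], counts[[2]],
                         alpha = cfg$alpha, min_delta = cfg$min_delta),
      error = function(e) stage_fail("diff", e))
    write_tsv_commented(res$diff, out("differential"), meta = meta)
  } else {
    res$diff <- read_tsv_commented(out("differential"))
  }

  # scan
  if (run_stage(4L)) {
    res$hits <- tryCatch(
      scan_event_motifs(res$catalog, genome, motifs, window = cfg$window),
      error = function(e) stage_fail("scan", e))
  } else {
    res$hits <- read_tsv_commented(out("hits"))
  }

  # conservation
  if (run_stage(5L)) {
    res$hits <- tryCatch(
      assess_conservation(res$hits, alignments, motifs,
                          min_species = cfg$conservation_species,
                          window = cfg$conservation_window),
      error = function(e) stage_fail("conserve", e))
    write_tsv_commented(res$hits, out("hits"), meta = meta)
    write_hits_bed(res$hits, file.path(cfg$out_dir, "hits.bed"))
  } else {
    res$hits <- read_tsv_commented(out("hits"))
  }

  # background universe: alternatively spliced events (5..95 PSI in sample 1)
  psi_wt <- res$psi[res$psi$sample_id == names(counts)[1] |
                      is.na(res$psi$sample_id), , drop = FALSE]
  psi_wt_v <- stats::setNames(psi_wt$psi, psi_wt$event_id)
  background <- names(psi_wt_v)[!is.na(psi_wt_v) & psi_wt_v >= 5 & psi_wt_v <= 95]

  # enrichment
  if (run_stage(6L)) {
    res$enrichment <- do.call(rbind, lapply(names(motifs), function(mn) {
      tryCatch(
        motif_enrichment(res$diff, psi_wt_v[background], res$hits, mn,
                         n = cfg$n_randomizations,
                         seed = substream_seed(cfg$seed, paste0("enrich:", mn))),
        error = function(e) NULL)
    }))
    if (is.null(res$enrichment)) res$enrichment <- data.frame(note = "no testable case set")
    write_tsv_commented(res$enrichment, out("enrichment"), meta = meta)
    res$positional <- do.call(rbind, lapply(names(motifs), function(mn) {
      pb <- positional_bias(res$hits, mn)
      if (nrow(pb)) cbind(motif = mn, pb) else NULL
    }))
    if (!is.null(res$positional)) {
      write_tsv_commented(res$positional, out("positional_bias"), meta = meta)
    }
  }

  # co-occurrence
  if (run_stage(7L)) {
    res$cooccurrence <- tryCatch(
      cooccurrence_table(res$hits, background, names(motifs)),
      error = function(e) stage_fail("cooccur", e))
    write_tsv_commented(res$cooccurrence, out("cooccurrence"), meta = meta)
  }

  # geometry
  if (run_stage(8L)) {
    regions <- event_regions_table(res$catalog, genome = NULL, window = cfg$window)
    res$ordering <- tryCatch(
      ordering_screen(res$hits, regions, alignments, motifs,
                      window = cfg$conservation_window),
      error = function(e) stage_fail("geometry", e))
    write_tsv_commented(res$ordering, out("ordering"), meta = meta)
    pairs <- utils::combn(names(motifs), 2)
    sp_rows <- list()
    for (i in seq_len(ncol(pairs))) {
      st <- spacing_table(res$hits, regions, pairs[1, i], pairs[2, i])
      if (is.null(st)) next
      st$spacing_conserved <- vapply(seq_len(nrow(st)), function(r) {
        spacing_conservation(st[r, ], alignments, motifs,
                             tolerance = cfg$spacing_tolerance)$conserved
      }, TRUE)
      sp_rows[[length(sp_rows) + 1L]] <- st
    }
    res$spacing <- if (length(sp_rows)) do.call(rbind, sp_rows) else
      data.frame(event_id = character(0))
    write_tsv_commented(res$spacing, out("spacing"), meta = meta)
  }

  # fitness
  if (run_stage(9L) && !is.null(plate)) {
    res$interactions <- tryCatch(interaction_table(plate),
                                 error = function(e) stage_fail("fitness", e))
    res$screen <- screen_summary(res$interactions,
                                 threshold = cfg$interaction_threshold)
    write_tsv_commented(res$interactions, out("interactions"), meta = meta)
    write_tsv_commented(res$screen$summary, out("screen"), meta = meta)
  }

  # manifest
  files <- list.files(cfg$out_dir, pattern = "\\.(tsv|gff3|bed|fa|maf)$",
                      recursive = TRUE, full.names = TRUE)
  manifest <- data.frame(file = sub(paste0("^", cfg$out_dir, "/?"), "", files),
                         md5 = unname(tools::md5sum(files)),
                         stringsAsFactors = FALSE)
  manifest <- manifest[manifest$file != "manifest.tsv", , drop = FALSE]
  manifest <- manifest[order(manifest$file), , drop = FALSE]
  write_tsv_commented(manifest, file.path(cfg$out_dir, "manifest.tsv"), meta = meta)
  res$manifest <- manifest
  invisible(res)
}

#' Export motif hits as BED6
#' @param hits `motif_hits` with conservation columns.
#' @param path output path.
#' @export
write_hits_bed <- function(hits, path) {
  lines <- vapply(seq_len(nrow(hits)), function(i) {
    paste(hits$seq_id[i], hits$gstart[i], hits$gstart[i] + hits$length[i],
          paste0(hits$motif[i], ":", hits$label[i]),
          hits$species_support[i] %||% 0, hits$strand[i], sep = "\t")
  }, "")
  writeLines(lines, path)
  invisible(path)
}
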