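# Synthetic-study generator: determinism, planted-signal recovery, and the
# binomial read model.

test_that("a fixed seed gives byte-identical study bundles", {
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  simulate_study(sim_config(n_genes = 10, seed = 1), dir = d1)
  simulate_study(sim_config(n_genes = 10, seed = 1), dir = d2)
  f1 <- sort(list.files(d1)); f2 <- sort(list.files(d2))
  expect_equal(f1, f2)
  for (f in f1) {
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)),
                     info = f)
  }
})

test_that("event fractions of zero produce no events of that class", {
  st <- simulate_study(sim_config(n_genes = 15, seed = 2, cassette_fraction = 0,
                                  multi_fraction = 0, alt5_fraction = 0,
                                  alt3_fraction = 0, mxe_fraction = 0))
  expect_length(st$catalog, 0L)
  st2 <- simulate_study(sim_config(n_genes = 15, seed = 2, cassette_fraction = 0,
                                   multi_fraction = 0.3, alt5_fraction = 0.2,
                                   alt3_fraction = 0.2, mxe_fraction = 0.3))
  types <- vapply(st2$catalog, function(e) e$type, "")
  expect_false("cassette" %in% types)
  expect_true(all(c("multi_cassette", "mutually_exclusive") %in% types))
})

test_that("junction counts hit the degenerate PSI boundaries exactly", {
  set.seed(4)
  for (i in 1:20) {
    full <- simulate_junction_counts(100, 50)
    expect_equal(full[["C1C2"]], 0L)
    none <- simulate_junction_counts(0, 50)
    expect_equal(unname(none[c("C1A", "AC2")]), c(0L, 0L))
  }
})

test_that("the read model makes the PSI estimator consistent (p = 50)", {
  set.seed(6)
  psis <- replicate(1000, {
    x <- simulate_junction_counts(50, 10000)
    incl <- x[["C1A"]] + x[["AC2"]]
    100 * (incl / 2) / (incl / 2 + x[["C1C2"]])
  })
  expect_gt(mean(psis), 49)
  expect_lt(mean(psis), 51)
})

test_that("observed PSI errors stay within binomial sampling error at depth 100", {
  st <- simulate_study(sim_config(n_genes = 60, seed = 10, depth = 100,
                                  diff_fraction = 0))
  p <- psi_table(st$catalog, st$counts$wt)
  truth <- st$truth$events
  err <- abs(p$psi - truth$wt[match(p$event_id, truth$event_id)])
  # crude binomial SE of the PSI estimator at depth 100 is < ~7 points
  expect_lt(mean(err, na.rm = TRUE), 3 * 7)
  expect_gt(stats::cor(p$psi, truth$wt[match(p$event_id, truth$event_id)],
                       use = "complete"), 0.9)
})

test_that("planted alignment conservation equals brute-force species support", {
  set.seed(12)
  for (i in 1:40) {
    ref <- paste(sample(c("A", "C", "G", "T"), 90, replace = TRUE), collapse = "")
    pos <- sample(30:50, 1)
    substr(ref, pos + 1, pos + 5) <- "GCATG"
    k <- sample(0:4, 1)
    sp <- c("ref", paste0("s", 2:5))
    supp <- if (k > 0) sample(sp[-1], k) else character(0)
    writes <- stats::setNames(lapply(sp[-1], function(s) {
      if (s %in% supp) list(list(offset = pos + sample(-3:3, 1), text = "GCATG"))
    }), sp[-1])
    blk <- simulate_alignment_block(ref, sp, substitution_rate = 0.15,
                                    indel_rate = 0.02,
                                    protect = (pos - 5):(pos + 10),
                                    writes = writes, start = 0L)
    # ablate the motif region in non-supporting species, then remove any
    # accidental matches the mutation process left nearby
    aln <- structure(list(blocks = list(blk), reference = "ref", species = sp),
                     class = "alignment_set")
    for (s in setdiff(sp[-1], supp)) {
      blk <- splicecomb:::scrub_block_matches(blk, s, parse_motif("GCAUG"), "+",
                                              center = block_colmap(blk)[pos + 1],
                                              window = 31)
    }
    aln$blocks[[1]] <- blk
    hit <- h_hit("E1", "GCAUG", "alt_exon", pos, pos)
    got <- assess_conservation(hit, aln, h_motifs("GCAUG"))
    expect_equal(got$species_support,
                 oracle_block_support(blk, "ref", "GCAUG", pos, "+"))
    expect_equal(got$species_support >= 2, got$conserved)
    expect_gte(got$species_support, k)  # planted support is a lower bound
  }
})

test_that("study-level planted motifs are recovered with exact species support", {
  motifs <- h_motifs()
  st <- simulate_study(sim_config(n_genes = 50, seed = 14))
  hits <- assess_conservation(scan_event_motifs(st$catalog, st$genome, motifs),
                              st$alignments, motifs)
  tm <- st$truth$motifs
  m <- merge(tm, hits, by = c("event_id", "motif", "gstart"))
  expect_equal(nrow(m), nrow(tm))
  expect_equal(m$species_support, m$conservation_species)
  # planting with k = 1 is never called conserved
  st1 <- simulate_study(sim_config(n_genes = 40, seed = 15,
    planted_motifs = list(list(pattern = "GCAUG", name = "GCAUG",
      region = "downstream_intron_5p", prob_case = 0.8, prob_background = 0.5,
      conservation_species = 1, jitter = 3)),
    planted_pairs = list()))
  h1 <- assess_conservation(scan_event_motifs(st1$catalog, st1$genome, motifs),
                            st1$alignments, motifs)
  m1 <- merge(st1$truth$motifs, h1, by = c("event_id", "motif", "gstart"))
  expect_true(nrow(m1) > 0)
  expect_false(any(m1$conserved))
})

test_that("noise-free fitness plates give exact interaction identities", {
  fit0 <- list(strains = c(WT = 1, mutA = 0.8), rnais = c(GFP = 1, r1 = 0.7),
               epistasis = data.frame(strain = character(0), rnai = character(0),
                                      factor = numeric(0)),
               baseline = 100, noise_sd = 0, experiments = 3, replicates = 2,
               exp_effect_sd = 0)
  plate <- simulate_fitness_plate(fit0, seed = 1)
  expect_equal(interaction_score(plate, "mutA", "r1")$score, 1, tolerance = 1e-12)
  fit5 <- fit0
  fit5$epistasis <- data.frame(strain = "mutA", rnai = "r1", factor = 0.5)
  plate5 <- simulate_fitness_plate(fit5, seed = 1)
  expect_equal(interaction_score(plate5, "mutA", "r1")$score, 0.5, tolerance = 1e-12)
})

test_that("infeasible planting geometry raises rather than silently misplacing", {
  expect_error(sim_config(planted_motifs = list(
    list(pattern = "GCAUG", name = "GCAUG", region = "alt_exon",
         prob_case = 1, conservation_species = 9, jitter = 5))),
    "other species")
  expect_error(sim_config(planted_motifs = list(
    list(pattern = "GCAUG", name = "GCAUG", region = "alt_exon",
         prob_case = 1, conservation_species = 2, jitter = 40))),
    "jitter")
})
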