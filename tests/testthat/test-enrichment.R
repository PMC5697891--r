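# PSI-matched controls, motif enrichment, co-occurrence, dinucleotides,
# term enrichment.

test_that("matched control sets reproduce the case PSI histogram", {
  set.seed(23)
  case_psi <- stats::setNames(runif(30, 10, 90), paste0("C", 1:30))
  bg_psi <- stats::setNames(runif(600, 0, 100), paste0("B", 1:600))
  sets <- sample_matched_controls(case_psi, bg_psi, n = 20, seed = 7)
  expect_length(sets, 20)
  bin <- function(x) floor(x / 5)
  case_hist <- table(bin(case_psi))
  for (s in sets[1:5]) {
    expect_length(s, length(case_psi))
    expect_equal(table(bin(bg_psi[s]))[names(case_hist)], case_hist,
                 ignore_attr = TRUE)
    expect_false(any(duplicated(s)))
  }
  # determinism
  sets2 <- sample_matched_controls(case_psi, bg_psi, n = 20, seed = 7)
  expect_identical(sets, sets2)
  # single-bin case set draws only from that bin when populated
  one <- stats::setNames(rep(52, 5), paste0("C", 1:5))
  s1 <- sample_matched_controls(one, bg_psi, n = 3, seed = 1)
  expect_true(all(bin(bg_psi[unlist(s1)]) == bin(52)))
  expect_error(sample_matched_controls(case_psi, bg_psi[1:10]), "smaller")
})

test_that("motif enrichment flags case-specific planting", {
  set.seed(29)
  calls <- data.frame(event_id = paste0("E", 1:200),
                      psi_wt = runif(200, 10, 90),
                      called = rep(c(TRUE, FALSE), c(30, 170)),
                      direction = rep(c("increased_inclusion", NA), c(30, 170)),
                      stringsAsFactors = FALSE)
  bg_psi <- stats::setNames(calls$psi_wt, calls$event_id)
  hits <- do.call(rbind, lapply(calls$event_id[calls$called], function(e) {
    h_hit(e, "GCAUG", "upstream_intron_5p", 10, 1000)
  }))
  r <- motif_enrichment(calls, bg_psi[!calls$called], hits, "GCAUG",
                        n = 30, seed = 3)
  expect_equal(r$case_proportion, 1)
  expect_equal(r$control_proportion, 0)
  expect_lt(r$p_value, 0.05)
  rd <- motif_enrichment(calls, bg_psi[!calls$called], hits, "GCAUG",
                         direction = "increased_inclusion", n = 10, seed = 3)
  expect_equal(rd$n_cases, 30L)
  expect_error(motif_enrichment(calls, bg_psi, hits, "GCAUG",
                                direction = "increased_skipping"),
               "empty case set")
})

test_that("enrichment p-values are calibrated when planting is uniform", {
  set.seed(37)
  ps <- replicate(60, {
    calls <- data.frame(event_id = paste0("E", 1:150),
                        psi_wt = runif(150, 5, 95),
                        called = rep(c(TRUE, FALSE), c(25, 125)),
                        direction = NA_character_, stringsAsFactors = FALSE)
    with_motif <- calls$event_id[runif(150) < 0.4]
    hits <- do.call(rbind, lapply(with_motif, function(e) {
      h_hit(e, "GCAUG", "upstream_intron_5p", 10, 1000)
    }))
    motif_enrichment(calls, stats::setNames(calls$psi_wt, calls$event_id)[!calls$called],
                     hits, "GCAUG", n = 20, seed = sample.int(1e6, 1))$p_value
  })
  expect_lte(mean(ps < 0.05), 0.05 + 3 * sqrt(0.05 * 0.95 / 60))
})

test_that("positional bias counts events per region class", {
  hits <- rbind(h_hit("E1", "GCAUG", "upstream_intron_5p", 1, 1),
                h_hit("E1", "GCAUG", "alt_exon", 1, 1),
                h_hit("E2", "GCAUG", "downstream_intron_3p", 1, 1),
                h_hit("E3", "GCAUG", "constitutive_up", 1, 1, conserved = FALSE))
  pb <- positional_bias(hits, "GCAUG")
  get <- function(r) pb$proportion[pb$region == r]
  expect_equal(get("alt_exon"), 0.5)
  expect_equal(get("upstream_intron"), 0.5)
  expect_equal(get("downstream_intron"), 0.5)
  expect_equal(get("constitutive_exon"), 0)  # non-conserved hit ignored
  expect_equal(nrow(positional_bias(hits[0, ], "GCAUG")), 0L)
})

test_that("co-occurrence follows the multiplicative model and hypergeometric tail", {
  ev <- sprintf("E%03d", 1:100)
  mk <- function(ids, motif) do.call(rbind, lapply(ids, function(e) {
    h_hit(e, motif, "upstream_intron_5p", 5, 500)
  }))
  hits <- rbind(mk(ev[1:40], "A"), mk(ev[21:70], "B"))
  r <- cooccurrence(hits, ev, "A", "B")
  expect_equal(r$expected, 100 * 0.4 * 0.5)
  expect_equal(r$observed, 20L)
  expect_equal(r$p_value, oracle_cum_hyper(20, 100, 40, 50), tolerance = 1e-12)

  ev10 <- ev[1:10]
  h5 <- rbind(mk(ev10[1:5], "A"), mk(ev10[1:5], "B"))
  expect_equal(cooccurrence(h5, ev10, "A", "B")$p_value, 1 / 252, tolerance = 1e-12)
  h3 <- rbind(mk(ev10[1:5], "A"), mk(ev10[c(1, 2, 3, 6, 7)], "B"))
  expect_equal(cooccurrence(h3, ev10, "A", "B")$p_value, 0.5, tolerance = 1e-12)
  expect_error(cooccurrence(hits, character(0), "A", "B"), "empty")
})

test_that("cumulative hypergeometric agrees with enumeration for all N <= 12", {
  for (N in 1:12) for (K in 0:N) for (n in 0:N) for (q in 0:(n + 1)) {
    expect_equal(splicecomb:::cum_hyper_upper(q, N, K, n),
                 oracle_cum_hyper(q, N, K, n), tolerance = 1e-12,
                 info = paste(q, N, K, n))
  }
})

test_that("dinucleotide frequencies and comparisons behave", {
  d <- dinucleotide_comparison("AUGC", c("AUGC", "AUGC"))
  expect_equal(d$mean_a[d$dinucleotide == "AU"], 1 / 3)
  expect_equal(d$mean_a[d$dinucleotide == "UG"], 1 / 3)
  expect_equal(d$mean_a[d$dinucleotide == "GC"], 1 / 3)
  expect_equal(sum(d$mean_a), 1)
  set.seed(41)
  seqs <- replicate(20, paste(sample(c("A", "C", "G", "T"), 100, replace = TRUE),
                              collapse = ""))
  same <- dinucleotide_comparison(seqs, seqs)
  expect_true(all(same$p_value[!is.na(same$p_value)] > 0.99))
  expect_true(all(abs(same$fold[!is.na(same$fold)] - 1) < 1e-12))
  # AT-rich vs GC-rich sets are detected
  at <- replicate(20, paste(sample(c("A", "T"), 60, replace = TRUE), collapse = ""))
  gc <- replicate(20, paste(sample(c("G", "C"), 60, replace = TRUE), collapse = ""))
  diffd <- dinucleotide_comparison(at, gc)
  expect_lt(diffd$p_value[diffd$dinucleotide == "AA"], 0.01)
  expect_error(dinucleotide_comparison(character(0), "AU"), "non-empty")
})

test_that("Mann-Whitney oracle agrees with the U statistic used internally", {
  set.seed(43)
  for (i in 1:50) {
    x <- runif(sample(5:15, 1)); y <- runif(sample(5:15, 1))
    w <- suppressWarnings(stats::wilcox.test(x, y, exact = FALSE))
    expect_equal(unname(w$statistic), oracle_u_stat(x, y))
  }
})

test_that("length-matched term enrichment separates flagged terms from controls", {
  set.seed(47)
  genes <- sprintf("g%03d", 1:120)
  lens <- stats::setNames(round(stats::rlnorm(120, log(500), 0.6)), genes)
  flags <- stats::setNames(runif(120) < 0.2, genes)
  term_genes <- sample(genes, 10)
  flags[term_genes] <- TRUE
  tm <- rbind(data.frame(gene = term_genes, term = "muscle"),
              data.frame(gene = sample(genes, 2), term = "tiny"))
  r <- term_enrichment_length_matched(tm, flags, lens, n = 100, seed = 5)
  expect_equal(attr(r, "skipped"), "tiny")   # < 3 genes
  row <- r[r$term == "muscle", ]
  expect_equal(row$prop_flagged, 1)
  expect_lt(row$control_prop, 0.6)
  expect_lt(row$p_hyper, 0.01)
})

test_that("term-enrichment controls are calibrated when flags are independent", {
  set.seed(53)
  genes <- sprintf("g%03d", 1:200)
  lens <- stats::setNames(round(stats::rlnorm(200, log(500), 0.5)), genes)
  flags <- stats::setNames(runif(200) < 0.3, genes)
  tm <- data.frame(gene = sample(genes, 25), term = "any")
  r <- term_enrichment_length_matched(tm, flags, lens, n = 200, seed = 9)
  expect_lt(abs(r$control_prop - mean(flags)), 0.1)
})
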