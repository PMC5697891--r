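# Inter-motif spacing, spacing conservation, ordering, relative positions.

test_that("closest-pair spacing picks the minimal non-overlapping pair", {
  # upstream motif ends at 100, downstream starts at 150 -> spacing 50
  ps <- pair_spacing(95, 5, 150, 6)
  expect_equal(ps$spacing, 50)
  expect_equal(ps$upstream, "a")
  # multiple instances: the closest one is used
  ps2 <- pair_spacing(c(10, 80), 5, 90, 5)
  expect_equal(ps2$start_up, 80)
  expect_equal(ps2$spacing, 5)
  # adjacent motifs give spacing 0; overlapping pairs are not eligible
  expect_equal(pair_spacing(10, 5, 15, 5)$spacing, 0)
  expect_null(pair_spacing(10, 5, 12, 5))
  # order can run either way
  ps3 <- pair_spacing(100, 5, 20, 5)
  expect_equal(ps3$upstream, "b")
  expect_equal(ps3$spacing, 75)
})

test_that("spacing conservation applies the +/-20% rule per species", {
  # reference: two motifs GCACA ... TAGGTT with spacing 50 inside one region
  mk <- function(spacing_s2, spacing_s3) {
    row <- function(sp) {
      x <- strrep("A", 200)
      substr(x, 21, 25) <- "GCACA"
      start_b <- 25 + sp
      substr(x, start_b + 1, start_b + 6) <- "TAGGTT"
      x
    }
    h_alignment(list(ref = row(50), s2 = row(spacing_s2), s3 = row(spacing_s3)))
  }
  motifs <- h_motifs(c("GCACA", "U(A|G|U)(A|G)GUU"))
  rec <- data.frame(event_id = "E1", label = "upstream_intron_5p",
                    seq_id = "chrI", region_start = 0L, region_end = 200L,
                    strand = "+", motif_a = "GCACA",
                    motif_b = "U(A|G|U)(A|G)GUU", len_a = 5L, len_b = 6L,
                    spacing = 50, upstream_motif = "GCACA",
                    offset_up = 20, offset_down = 75, stringsAsFactors = FALSE)
  # 55 and 58 both inside [40, 60] -> conserved
  expect_true(spacing_conservation(mk(55, 58), rec = rec,
                                   motifs = motifs)$conserved)
  # 61 and 45: only one inside -> not conserved
  expect_false(spacing_conservation(mk(61, 45), rec = rec,
                                    motifs = motifs)$conserved)
  # unaligned region
  rec2 <- rec; rec2$region_start <- 5000L; rec2$region_end <- 5100L
  sc <- spacing_conservation(rec2, mk(50, 50), motifs)
  expect_false(sc$conserved)
  expect_equal(sc$note, "unaligned")
})

test_that("zero reference spacing requires exactly zero in other species", {
  row0 <- function(sp) {
    x <- strrep("A", 100)
    substr(x, 11, 15) <- "GCACA"
    substr(x, 16 + sp, 21 + sp) <- "TAGGTT"
    x
  }
  motifs <- h_motifs(c("GCACA", "U(A|G|U)(A|G)GUU"))
  rec <- data.frame(event_id = "E1", label = "upstream_intron_5p",
                    seq_id = "chrI", region_start = 0L, region_end = 100L,
                    strand = "+", motif_a = "GCACA",
                    motif_b = "U(A|G|U)(A|G)GUU", len_a = 5L, len_b = 6L,
                    spacing = 0, stringsAsFactors = FALSE)
  expect_true(spacing_conservation(
    h_alignment(list(ref = row0(0), s2 = row0(0), s3 = row0(0))), rec = rec,
    motifs = motifs)$conserved)
  expect_false(spacing_conservation(
    h_alignment(list(ref = row0(0), s2 = row0(1), s3 = row0(0))), rec = rec,
    motifs = motifs)$conserved)
})

test_that("the cumulative conservation-by-distance curve ends at the overall rate", {
  rec <- data.frame(spacing = c(5, 10, 20, 40, 80),
                    both_conserved = c(TRUE, TRUE, FALSE, TRUE, FALSE))
  curve <- conservation_by_distance(rec)
  expect_equal(curve$prop_conserved[curve$threshold == 80],
               attr(curve, "overall"))
  flat <- conservation_by_distance(data.frame(spacing = 1:4,
                                              both_conserved = TRUE))
  expect_true(all(flat$prop_conserved == 1))
})


test_that("9-of-10 consistent ordering is unidirectional with the exact binomial p", {
  fx <- h_ordering_fixture(10, 9)
  motifs <- h_motifs(c("GCACA", "U(A|G|U)(A|G)GUU"))
  oc <- ordering_conservation(fx$hits, fx$regions, fx$aln, motifs,
                              "GCACA", "U(A|G|U)(A|G)GUU")
  expect_equal(oc$n_events, 10L)
  expect_equal(oc$n_reversed, 0L)
  expect_lt(oc$chi_p, 0.05)
  expect_equal(oc$direction_p, 22 / 1024, tolerance = 1e-12)
  expect_equal(oc$classification, "unidirectional")
})

test_that("balanced directions with preserved order are bidirectional", {
  fx <- h_ordering_fixture(10, 5)
  motifs <- h_motifs(c("GCACA", "U(A|G|U)(A|G)GUU"))
  oc <- ordering_conservation(fx$hits, fx$regions, fx$aln, motifs,
                              "GCACA", "U(A|G|U)(A|G)GUU")
  expect_equal(oc$classification, "bidirectional")
  expect_gt(oc$direction_p, 0.05)
})

test_that("too few qualifying events yields not_conserved with a note", {
  fx <- h_ordering_fixture(2, 2)
  motifs <- h_motifs(c("GCACA", "U(A|G|U)(A|G)GUU"))
  oc <- ordering_conservation(fx$hits, fx$regions, fx$aln, motifs,
                              "GCACA", "U(A|G|U)(A|G)GUU")
  expect_equal(oc$classification, "not_conserved")
  expect_equal(oc$note, "insufficient_events")
})

test_that("ordering screen emits one record per motif pair (13 -> 78)", {
  nm <- sprintf("M%02d", 1:13)
  motifs <- stats::setNames(lapply(nm, function(x) parse_motif("GCAUG", x)), nm)
  fx <- h_ordering_fixture(1, 1)
  os <- ordering_screen(fx$hits[0, ], fx$regions, fx$aln, motifs)
  expect_equal(nrow(os), choose(13, 2))
  expect_equal(nrow(os), 78L)
  expect_true(all(os$classification == "not_conserved"))
})

test_that("relative positions report signed offsets and a sign-bias test", {
  fx <- h_ordering_fixture(10, 9)
  rp <- relative_positions(fx$hits, fx$regions, "GCACA", "U(A|G|U)(A|G)GUU")
  expect_length(rp$offsets, 10)
  expect_equal(unname(rp$offsets[1]), 60)   # anchor at 20, other at 80
  expect_equal(sum(rp$offsets < 0), 1)
  expect_equal(rp$p_bias, 22 / 1024, tolerance = 1e-12)
  expect_equal(rp$n_zero, 0)
})

test_that("spacing is invariant under shifting the coordinate frame", {
  set.seed(59)
  for (i in 1:20) {
    sa <- sort(sample(0:150, 2)); sb <- sort(sample(0:150, 2))
    shift <- sample(1000, 1)
    p1 <- pair_spacing(sa, 5, sb, 6)
    p2 <- pair_spacing(sa + shift, 5, sb + shift, 6)
    expect_equal(is.null(p1), is.null(p2))
    if (!is.null(p1)) expect_equal(p1$spacing, p2$spacing)
  }
})


test_that("random per-species orders are classified conserved at most at rate alpha", {
  set.seed(61)
  motifs <- h_motifs(c("GCACA", "U(A|G|U)(A|G)GUU"))
  n_tot <- 80
  n_sig <- 0
  for (sim in seq_len(n_tot)) {
    fx <- h_ordering_fixture_random(10)
    oc <- ordering_conservation(fx$hits, fx$regions, fx$aln, motifs,
                                "GCACA", "U(A|G|U)(A|G)GUU")
    if (oc$classification != "not_conserved") n_sig <- n_sig + 1
  }
  expect_lte(n_sig / n_tot, 0.05 + 3 * sqrt(0.05 * 0.95 / n_tot))
})
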