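---
title: "Methods: junction-based splicing analysis and combinatorial motif statistics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: junction-based splicing analysis and combinatorial motif statistics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(splicecomb)
```

This vignette is the package's account of its models and of the design
choices made where the methodology left room: what is estimated, under what
assumptions, which defaults matter, and what the synthetic-study generator
does and does not emulate.

## PSI from junction reads

For a cassette exon with constitutive flanks C1 and C2 and alternative exon
A, inclusion is supported by reads across the two adjacent junctions (C1A,
AC2) and skipping by reads across the skip junction (C1C2). An included
transcript spans *two* inclusion junctions while a skipped transcript spans
one skip junction, so the inclusion read sum double-counts molecules;
halving it makes the estimator a consistent molecule-fraction estimate:

$$\mathrm{PSI} = 100\cdot\frac{\tfrac12(C1A + AC2)}{\tfrac12(C1A + AC2) + C1C2}.$$

Events with alternative donors/acceptors at the flanking exons use the same
form with sums over all adjacent-junction combinations
($\sum C_iA$, $\sum AC_j$, $\sum C_iC_j$). Two conventions needed fixing:

* **Mutually exclusive exons.** Here each *excluding* molecule also spans
  two junctions (C1A', A'C2), so `compute_psi()` halves the exclusion sum
  as well for this event class; otherwise PSI would be biased toward
  inclusion by a factor of two in the denominator. PSI is defined as
  inclusion of the genomically 5' exon (a fixed orientation makes
  cross-sample comparison possible).
* **Alternative-site events.** Their PSI measures inclusion of the middle
  exon through *any* donor/acceptor variant against the direct C1→C2 skip;
  the skip junction is a queryable key even when no annotated isoform uses
  it.

The Fisher 2×2 test uses the *unhalved* integer read sums
(`[[incl_wt, excl_wt], [incl_mut, excl_mut]]`): an exact test needs integer
cells, and halving both entries of a row changes no odds ratio. Defaults
follow the study design the package implements: two-sided test, α = 0.05,
|ΔPSI| ≥ 15 percentage points (a change of exactly 15 counts), a combined
10 reads across both splice forms — enforced *per sample*, the stricter of
the two possible readings — and, for cassette and mutually-exclusive
events, exclusion when the two adjacent inclusion junctions differ by more
than 30-fold in either sample (exactly 30-fold passes; one junction at zero
with the other positive fails). No multiple-testing correction is applied
by default, matching the raw p-value rule; `p.adjust` can be applied
downstream by the caller.

## Splice-proximal regions and conserved motifs

Seven region labels are scanned per event, each clipped at 300 nt from its
anchoring splice site: the alternative exon, the 5'- and 3'-proximal
sub-regions of both flanking introns, and the event-facing ends of the
constitutive flanks. Introns shorter than 600 nt split at the midpoint so
the two sub-regions never overlap. All sequences are reported on the
pre-mRNA sense strand. Two small conventions: an alternative exon longer
than 300 nt keeps its sense-5' 300 nt (the data model carries one interval
per label; internal exons of this size are rare in nematode genomes), and a
motif must match fully inside a region to count — matches straddling the
window edge are not reported.

Motifs are degenerate RNA patterns (IUPAC codes plus parenthesised
alternations, e.g. `U(A|G|U)(A|G)GUU`); internally all sequence is DNA with
T≡U on input. A motif occurrence is **conserved** when at least 2 other
species of the alignment carry a match within 25 alignment columns of the
reference start. Column space is used as the shared coordinate system
(reference-anchored); matches are sought within the same alignment block
only, since blocks delimit orthology. Both thresholds are arguments
(`min_species`, `window`).

## Enrichment, co-occurrence and geometry

*Enrichment* compares differentially spliced events against control sets
drawn from the alternatively-spliced background (5–95 PSI) with a matched
wild-type PSI histogram. Bins are 5 percentage points wide — fine enough to
match the distribution, coarse enough to leave candidates per bin — and the
reported control value averages 100 randomisations. The Fisher test is
one-sided toward enrichment; the default compares cases against the rounded
mean control count (`mode = "averaged"`), with a pooled mode available,
since the source procedure does not state which was used.

*Co-occurrence* counts events with at least one (conserved) hit of each
motif in either flanking intron — presence/absence, multiple instances
count once. The expectation is multiplicative,
$E = N \cdot (n_a/N)(n_b/N)$, and significance is the upper cumulative
hypergeometric tail $P(X \ge \mathrm{obs})$. Being a discrete upper-tail
probability, this p-value is *super-uniform* under the null; the test suite
therefore checks calibration via the randomised tail transform
$P(X > \mathrm{obs}) + U\,P(X = \mathrm{obs})$, which is exactly
Uniform(0,1) when the hypergeometric computation is correct, alongside a
bound on the raw rejection rate.

*Spacing* is measured within single intronic sub-regions as the gap from
the end of the upstream motif to the start of the downstream motif, using
the instance pair closest together when a motif occurs multiple times;
overlapping instances yield no record. A spacing is conserved when ≥2 other
species contain both motifs with a spacing within ±20% of the reference
value (each species contributes its cross-pair spacing most similar to the
reference; a reference spacing of zero demands exactly zero). Species
spacings are measured in that species' own nucleotides.

*Ordering* considers events with both motifs anywhere in the flanking
introns, excluded from spacing when they sit in different sub-regions. The
pair-level statistic is a construction of this package (the source analyses
cite a chi-squared test and a binomial test without specifying the
aggregation): order preservation is tested by chi-squared of
preserved:reversed against 50:50 over all (event, species) observations;
when significant and preservation dominates, the pair is *unidirectional*
if one reference order dominates across events (two-sided binomial
p < 0.05), else *bidirectional*; otherwise *not conserved*. Pairs with
fewer than three qualifying events are not classified. Species matches
qualify within 25 nt of the reference instance in region-local sense
coordinates; ties in start coordinate drop an event from ordering.

## Fitness interactions

Within a strain, relative fitness is the population under a target RNAi
divided by the population under the non-targeting control (GFP), technical
replicates averaged first. The expected double-perturbation fitness is
multiplicative, and the score reduces algebraically to
$w(\mathrm{mut}, r) / w(\mathrm{WT}, r)$ — 1 means no interaction, 0 a
maximal negative one; screen hits fall strictly below 0.7, with allele
classes (e.g. two alleles of one gene) averaged first. Significance
compares per-experiment log scores against per-experiment log
control-ratios. Computing the control ratio from the same control means
makes it identically 1, so the two-sample t-test degenerates; the
implementation detects this structural zero-variance case and applies the
one-sample t-test against the constant control value, which is the Welch
limit of the stated comparison. A paired mode is available; Welch is the
default since the pairing structure across experiments is not specified.

## The synthetic-study generator

`simulate_study()` emulates the full input bundle of a splicing-factor
study: a single-chromosome genome (GC 0.36), 3–6 exons of 80–250 nt per
gene, log-normal introns (median 200 nt, σ = 0.5 on the log scale, minimum
60 nt — on the long side of nematode introns so that 300 nt windows and
planted motif pairs have room), both strands equally, cassette exons as the
dominant event class (40% of genes, with 5% each multi-cassette,
alternative 5', alternative 3', mutually exclusive), two samples with 30%
of events differential at |ΔPSI| = 40, and 200 junction reads per event.

Junction counts follow the molecule model above: with true inclusion
fraction $f$, an inclusion-junction read occurs with probability
$q = 2f/(1+f)$ (included molecules emit two junction reads' worth of
support, skipped ones one), inclusion reads split evenly between C1A and
AC2 — symmetry is the neutral choice — and mutually-exclusive events draw
the exon choice directly at $f$ since both isoforms span two junctions.
This read-level probability is what makes the PSI estimator consistent
(mean PSI ≈ 50 at a planted 50), and it is the model under which the
acceptance checks enumerate exact test power.

Alignments are generated per gene: non-reference rows mutate the reference
at 15% substitutions and 2% indels of geometric mean length 2. Planted
motifs are written into the reference and into exactly *k* other species
within a small column jitter (≤ 25); indels are excluded from planted
windows so the conservation level is exactly controllable, species that
must not support a motif have orthologous and nearby accidental matches
ablated by single substitutions (never inside a kept planted copy), and
pair-planting regions are scrubbed of accidental matches in every row so
closest-pair spacing and ordering recover the planted truth exactly.
Fitness plates multiply baseline, strain, RNAi, epistasis, experiment and
log-normal noise factors; populations stay continuous so the noise-free
multiplicativity identities hold exactly. All randomness runs through named
substreams of one master seed, giving byte-identical bundles per seed.

What the generator does **not** emulate — and hence what green tests do not
establish about real data: read-level artefacts (mapping bias, positional
coverage, sequencing error), expression variation between genes beyond a
flat per-event depth, intron-length and GC heterogeneity between regions,
correlated evolution among species (rows mutate independently from the
reference, there is no phylogeny), motif clustering beyond what is planted,
and biological covariation between splicing change and motif presence other
than the planted associations.

## Problem sizes and numerical conventions

The test suite and acceptance script run at deliberate desk scale: 500
simulated events for calibration/power (against exact enumeration over the
201×201 inclusion-count grid at depth 200), 1,000 random alignment blocks
for the scanner oracle, 500 simulated catalogs of 200 events for
co-occurrence calibration, two 60-gene studies for spacing-truth recovery,
80 shuffled fixtures for ordering calibration, and 500 noisy plates for
interaction recovery. Internally all coordinates are 0-based half-open and
junction keys store intron boundaries in genomic order with donor <
acceptor, so counts match events regardless of strand or annotation
dialect; conversion to 1-based conventions happens only at file boundaries.
MAF blocks on the reference minus strand are normalised to forward
orientation on reading. Ties in closest-pair selection resolve to the first
pair in scan order, deterministically.

## Known limitations

Intron retention and alternative first/last exons are outside the event
model; novel junctions are not discovered from reads (counts are the input
unit); motif scoring is consensus-based, not PWM-based; GO-style term
enrichment uses a flat term map and plain hypergeometric test without DAG
propagation; and the ordering classification, while documented and
swappable, is one of several defensible aggregations of per-species order
observations.
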