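---
title: "Methods: design, simulation and scoring of systemic MPRA screens"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: design, simulation and scoring of systemic MPRA screens}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mprakit)
```

`mprakit` analyses barcoded enhancer screens in which a pooled reporter
library is delivered across many tissues of the same animal and enhancer
activity is read out as the RNA:DNA ratio of per-construct barcodes. This
vignette is the package's account of its methods: the models, the tunable
parameters and their defaults, what the synthetic-data generator does and
does not emulate, and the numerical and design choices made where more than
one reasonable option existed.

## Library anatomy

Each library member is an oligo

```
adapter5 (20 nt) | enhancer (120 nt) | linker (27 nt) | barcode (16 nt) | adapter3 (20 nt)
```

with fixed part lengths, so the decomposition is unique. The linker carries
a restriction-enzyme site (`GGCGCGCC`) used as the *anchor* during barcode
extraction. The default design holds 461 enhancers × 20 barcodes = 9,220
barcodes: cross-tissue viral controls (3), tissue positive controls (30:
brain/liver/immune), published negative controls (10), GC-stratified random
negatives (30: 10 each at 30/50/70% GC), cortical candidates (144),
MEF2-motif enhancers in three versions each — baseline, motif shuffled,
motif plus 5-nt flanks shuffled — (28 × 3), SNP loci as ref/alt pairs with
a region-disrupt version for a subset (27 loci, 64 sequences), and labelled
placeholder candidates filling the remainder. The full member list of the
original screen is not public at the sequence level, so placeholders are
synthetic random sequences; their only role is to give the library its
stated size and a realistic inactive majority.

### Coordinates

All interval arguments (`shuffle_interval()`, `make_allele_pair()`) are
**1-based and inclusive**, the R/Bioconductor convention (IRanges,
Biostrings). Motif-disruption variants shuffle the motif window, optionally
widened by `flank = 5` bases per side; an identity permutation of a
polymorphic window is re-drawn (at most 10 attempts) because the intent of
the variant is disruption. Shuffling preserves the window's base multiset,
so disrupted variants are GC-matched to their baselines by construction.

### Barcode constraints

The original screen does not state barcode design rules; `assign_barcodes()`
enforces three engineering constraints chosen to make extraction
unambiguous: global uniqueness, pairwise Hamming distance ≥ 3 (so
one-mismatch whitelist rescue can never be ambiguous), and exclusion of the
anchor sequence from barcodes. The distance constraint is screened with a
pigeonhole chunk index (a 16-mer pair at distance < 3 must agree on one of
three chunks), keeping assignment near-linear; tests verify the constraint
with brute-force all-pairs comparison.

## The synthetic experiment generator

The generator is first-class, tested code: it defines the study conditions
every downstream module is validated against.

- **Cloning dropout** (`simulate_cloning`): each barcode survives
  independently with probability 0.43, the complement of the 57% dropout
  the original plasmid library showed. At k = 20 this gives 8.6 expected
  barcodes per enhancer and essentially certain (1 − 0.57²⁰) enhancer
  coverage — both properties the acceptance checks measure.
- **Transduction**: per animal-tissue pair, a barcode is deliverable with a
  tissue-specific probability (default 0.93–0.99; muscle and heart 0.45,
  mimicking the poor transduction of those tissues by brain-penetrant AAV).
  The paired DNA and RNA samples of an animal-tissue share the transduced
  set.
- **Counts** (`simulate_counts`): negative binomial. DNA mean is
  `dna_depth / n_transduced` per transduced barcode; RNA mean is
  `mu_DNA × alpha_true × (rna_depth / dna_depth)`. RNA depends on DNA only
  through its mean (conditional independence), the standard MPRA generative
  assumption. We deliberately do **not** renormalise RNA means across
  barcodes: that keeps "doubling an enhancer's activity doubles its
  expected RNA count" exactly true, at the price that realised RNA totals
  track the nominal depth only when mean activity is near 1. Dispersion
  (NB `size`) defaults to 10, a moderately overdispersed regime; no noise
  model is stated for the original data.
- **Activity classes**: matched enhancer–tissue pairs (brain-class
  candidates in brain regions, liver positives in liver, immune positives
  and MEF2/SNP loci in the cultured microglia-like cells, cross-tissue
  controls everywhere) are boosted `active_fold`-fold (default 10) over the
  negative-control baseline; motif-shuffled, flank-shuffled and
  region-disrupt variants fall back to baseline; SNP alternative alleles
  gain `snp_alt_fold` (default 4) over reference in responsive tissues,
  modelling a gain-of-binding allele.
- **Reads** (`emit_amplicon_reads`): reads start at the linker, cover
  anchor, flanks and barcode, and acquire independent per-base
  substitutions (default rate 0.002). Indels, PCR jackpotting, UMI
  structure and quality-score variation are *not* modelled. Passing tests
  therefore demonstrate correctness of the pipeline's logic and
  calibration under a clean substitution channel — not robustness to every
  artefact of real sequencing chemistry.

Per-tissue sequencing depths are not published; the default 2×10⁵
reads/sample is chosen as a desk-scale value at which activity ranks
recover well. The test suite runs on scaled-down libraries (120–140
enhancers, 4–8 barcodes each, 1–5×10⁴ reads/sample) chosen so the full
suite completes in about a minute; the acceptance checks that concern
library geometry use the full 461 × 20 design, which is cheap because no
reads are needed.

## Barcode quantification

A read is accepted iff (i) the anchor matches at its designed offset within
`max_anchor_mismatches`, (ii) the bases adjacent to the barcode (default
3 nt each side) match within the same tolerance, and (iii) the extracted
16-mer matches exactly one whitelist barcode within
`max_barcode_mismatches`. Defaults are all-exact (0 mismatches) — the
strictest reading of a "high-quality barcode read" filter; tolerances are
exposed because relaxed matching is common practice. Rejections are tallied
by reason (`too_short`, `anchor_fail`, `flank_fail`, `barcode_unmatched`,
`barcode_ambiguous`), and per-sample `accepted + rejected = total` is an
enforced invariant. Reads are taken on the designed strand; a
reverse-complement rescue pass is intentionally not applied by default.

`complexity_metrics()` reports detected barcodes per sample (proportions
relative to the global detected union), library complexity (union /
designed barcodes), per-enhancer barcode counts, enhancer coverage, and a
transduction rate defined as `union / (n_enhancers ×
effective_barcodes_per_enhancer)`. The divisor defaults to the rounded
observed mean barcodes per enhancer — the normalisation the original
analysis used (with 9 as its rounded mean). Because the divisor is a
rounded mean, the metric can exceed 100% for a sample that detects nearly
everything; it is reported together with the divisor used. The detection
threshold defaults to 1 read; no count cutoff is part of the published
"high-quality" definition.

## Activity estimation and scoring

The published analysis used MPRAnalyze's GLM for its transcription-rate
estimate; that model is not reproduced here. Instead `mprakit` uses an
explicit closed-form estimator with the same semantics (activity relative
to a negative-control null):

- **alpha**: library-size-normalised RNA:DNA ratio over the enhancer's
  barcodes, with barcodes below a DNA floor (default 1 read) excluded from
  both sums and a pseudocount ε = 10⁻⁶ (in normalised units) guarding empty
  numerators. Scale invariance — multiplying a sample's RNA counts by a
  constant leaves alpha unchanged — holds by construction up to ε.
- **MAD score**: `(log alpha − median(neg)) / (1.4826 × MAD(neg))`,
  computed within each scoring unit (sample, tissue, or tissue type)
  against that unit's negative controls; 1.4826 makes the MAD consistent
  with a standard deviation under normality. Negative controls are scored
  against the full negative set, themselves included. A zero MAD of the
  null is a hard error, not a silent fallback.
- **Empirical p**: add-one one-sided rank `p = (1 + #{neg ≥ s}) / (1 +
  N_neg)`, so p ∈ (0, 1] and is exactly 1/(N+1)-grained; with the default
  40 negatives the smallest attainable p is 1/41 ≈ 0.024. A warning is
  emitted below 20 negatives.
- **Aggregation**: log-alphas are averaged across animals within tissue or
  tissue type, then rescored. Enhancers whose per-sample MAD scores
  disagree in sign are flagged (`consistent = FALSE`) but never silently
  filtered — the consistency rule of the original analysis is surfaced as
  a flag so the user decides.

The MAD-score operating point of 1.3 used in the original disruption
analysis reflects that pipeline's internal scaling; `mpra_config()` carries
it as a default flag level without claiming equivalence between the two
scores.

## Differential tests

- **Motif disruption**: per baseline enhancer, each sample contributes a
  pair (baseline score, mean score of its shuffled versions); a paired t
  across samples, BH-adjusted across baselines. The reported effect is the
  mean paired difference of MAD scores — the "fold difference" axis of the
  original figures is a score difference, and it is labelled operationally
  here. Units with fewer than two complete pairs are kept with
  `skipped = TRUE`.
- **Allelic tests**: paired t of reference vs alternative allele (and
  reference vs region-disrupt where present), BH within each family —
  matching the per-analysis framing of the original work rather than one
  global correction. Effects are signed (ref − alt) so gain-of-binding
  alleles are visible as negative effects. Degenerate all-zero differences
  return t = 0, p = 1 rather than an error.
- **Group tests**: one-sided two-sample t with Welch's unequal-variance
  form; the original description says only "t-test", and Welch is the
  safer default. The test unit is the per-sample value, with aggregation
  to animal means available upstream via `aggregate_activity()`; which
  unit the original analysis pooled is ambiguous, so both are reachable.
- **Correlation structure**: Spearman's rho over paired enhancer alphas
  per group pair, pairwise-complete, cells with fewer than 10 shared
  enhancers set to NA; p-values from the large-sample approximation
  (`cor.test`).
- **Prediction interface**: sequences are N-padded to a predictor's input
  length with the enhancer centred (a 120-nt enhancer padded to 500 nt
  gets 190 Ns per side); when the padding is odd the extra N goes on the
  5' side — an arbitrary, documented tie-break. Forward and
  reverse-complement predictions are averaged before correlating with
  alpha. Running or training the open-chromatin CNN itself is out of
  scope; scores arrive as a TSV.

## Determinism and seeds

Every stochastic function takes a `seed`; the pipeline derives per-stage
seeds from one master seed via a fixed affine map modulo 2³¹ − 1, so a
config plus seed reproduces byte-identical outputs (asserted by test).
`--threads` on the CLI is a scheduling hint only and never changes results.

## Known limitations

- The alpha estimator is a ratio of sums, not a barcode-level random-effects
  model; with very few surviving barcodes its variance grows, and the
  `n_barcodes_used` column should be consulted before trusting extreme
  scores.
- The generator's clean substitution channel means acceptance-rate
  arithmetic ((1 − e)^span) is exact in a way real data, with indels and
  quality-dependent errors, is not.
- Empirical p-values are bounded below by 1/(N_neg + 1); genome-scale
  significance claims need more negatives than the default design carries.
- The transduction-rate normalisation (rounded mean barcodes per enhancer)
  follows the original analysis but is unusual; the divisor is configurable
  and always reported.
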