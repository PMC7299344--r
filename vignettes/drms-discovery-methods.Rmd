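---
title: "Methods: discovering damage-responsive, maturity-silenced enhancers"
author: "drmscan"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: discovering damage-responsive, maturity-silenced enhancers}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(drmscan)
```

## The problem

Drosophila imaginal discs regenerate well early in the third larval instar
(L3) and lose that capacity by late L3. One mechanism behind this loss is a
class of enhancers that are *damage-responsive* — they open upon injury,
largely downstream of JNK/AP-1 — and *maturity-silenced* — Polycomb-mediated
silencing shuts them off as the disc matures. `drmscan` implements the
computational side of screening for such DRMS enhancers from chromatin
accessibility (ATAC-seq style) data: a four-condition design crossing
developmental stage (early vs late L3) with tissue state (damaged vs
undamaged), three biological replicates each.

The package starts from *called, scored peak sets* (one per condition) and
a source of per-sample fragment counts; read trimming, alignment and peak
calling are upstream of its input boundary.

## Pipeline and model

1. **Union atlas** (`select_top_peaks`, `merge_overlapping`,
   `build_atlas`). The top `n_top = 11,500` peaks per condition (ranked by
   the caller's score) are pooled and every group of peaks overlapping by
   ≥ 1 bp is merged, transitively, into one atlas peak. Coordinates are
   0-based half-open everywhere inside the package; *bookended* peaks
   (`end == start`) overlap by zero bases and stay separate. Ties at the
   selection boundary are broken by (chrom, start) so runs are
   reproducible.

2. **Counting** (`count_in_atlas`). Entry (i, j) is the number of sample-j
   fragments overlapping atlas peak i by ≥ 1 bp; a fragment spanning
   several peaks increments all of them (multi-overlap counting).

3. **Differential accessibility** (`size_factors`, `estimate_dispersion`,
   `nb_wald_test`, `bh_adjust`). The engine is a deliberately transparent
   negative-binomial workflow with closed-form estimators:

   - median-of-ratios size factors;
   - per-peak dispersion by method of moments within condition groups,
     pooled by degrees of freedom, clamped at zero, then shrunk 50/50
     toward a fitted mean–dispersion trend `alpha(mu) = a0 + a1/mu`;
   - log2 fold change as the log-ratio of normalized group means, with a
     pseudo-mean of 0.5 added to each group mean to stabilize zeros;
   - delta-method standard error
     `SE = sqrt((1/m_A + alpha)/n_A + (1/m_B + alpha)/n_B) / log(2)`,
     Wald z against the standard normal, two-sided p, BH adjustment.

   This is *not* a re-implementation of a specific published framework:
   no Cox–Reid dispersion likelihood, no posterior fold-change shrinkage,
   no independent filtering, no outlier replacement. Consequences: peak
   counts from a full-scale published analysis are not expected to be
   reproduced number-for-number, and the engine is validated instead by
   calibration (null type-I error at nominal level) and parameter
   recovery (planted fold changes, planted depth factors), which the test
   suite checks.

4. **Classification** (`call_set`, `classify_drms`). Three contrasts are
   fixed: early damaged vs early undamaged (`dr_early`), late damaged vs
   late undamaged (`dr_late`), and late damaged vs early damaged with the
   *late* condition as numerator, called *down* (`ms`, maturity
   silencing). Calls use strict inequalities `padj < cut` and
   `|log2FC| > 0.5`, with both a standard (`0.1`) and a strict (`0.05`)
   adjusted-p cutoff carried through the pipeline. The DRMS set is
   `dr_early ∩ ms`; `dr_both = dr_early ∩ dr_late`. Set-algebra
   invariants are asserted after every construction, and relaxing the
   padj cutoff can only grow each set.

5. **Annotation** (`nearest_two_genes`, `categorize_peak`,
   `category_enrichment`). Candidate targets are the two nearest genes
   regardless of strand or side, distance measured peak edge to gene-body
   edge (a TSS mode and a one-per-side mode are available as flags —
   gene-body/any-side is the default because enhancers most often act on
   immediately flanking genes). Feature categories are assigned at the
   peak midpoint under the precedence promoter > exon > intron > other
   open chromatin > other; enrichment of a subset (e.g. the DRMS set)
   against the atlas background uses two-sided Fisher tests, BH-adjusted
   across categories.

6. **Sequence screens** (`find_conserved_blocks`, `scan_iupac`,
   `exact_motif_search`, `site_map_report`). Conserved blocks are maximal
   runs of *byte-identical* sequence ≥ 50 bp shared by all input species —
   exact identity, no alignment, matching how short ultraconserved
   enhancer elements are screened; identity must hold across all species
   simultaneously (a pairwise mode is not provided). Detection anchors on
   `min_len`-mers of the first sequence, verifies them in all others, and
   extends maximally; `min_len < 8` is refused as uninformative. Motif
   scanning takes IUPAC consensus strings on both strands; the default set
   (AP-1 `TGASTCA`, Pho core `GCCAT`, Sp1 `GGGCGG`) is literature
   consensus and fully overridable. The exact k-mer search (e.g. for a
   17 bp conserved motif) takes the query as user input; palindromic
   queries are reported once per strand at identical coordinates, so
   consumers can deduplicate if they count sites single-strandedly.

7. **Tracks** (`signal_track`, `subtract_tracks`). Pooled per-condition
   coverage is binned (default 10 bp), standardized to z-scores
   genome-wide, and subtracted bin-wise to display damage-responsiveness
   (early damaged − early undamaged) and maturity silencing (early
   damaged − late damaged). Exactly constant coverage standardizes to an
   all-zero track; a degenerate track whose standard deviation is not
   finite (e.g. a single bin) is an error.

## The synthetic-data generator

`sim_design()` / `simulate_truth()` / `simulate_counts()` /
`simulate_scored_peaks()` emulate the study design so that every stage of
the pipeline can be exercised and verified with planted ground truth and
no external data.

Counts for peak *i*, sample *j* in condition *c* are negative binomial
with mean

```
m_ij = s_j * mu_i * ((1 - f_c) + f_c * 2^delta_ic) * 2^(-sigma_ic)
```

and variance `m + alpha * m^2`, where

- `mu_i` is the peak's expected accessibility, log-normal around
  `base_mean = 200` (sdlog 1) for a realistic dynamic range;
- `f_c` is the **responding-tissue fraction**: damage happens in a small
  zone of the disc, so in damaged conditions only a fraction `f = 0.15`
  of the profiled cells carry the response and the bulk fold change is
  the mixture `(1 - f) + f * 2^delta`, not `2^delta`. Undamaged
  conditions have no responding compartment (the damage effect is zero
  there anyway).
- `delta_ic` is the planted damage effect (`effect_lfc = 4`, i.e.
  16-fold within responding cells — a strong silent-to-open enhancer
  transition; after dilution the bulk log2 fold change is
  `log2(0.85 + 0.15·16) ≈ 1.70`, comfortably but not trivially above the
  0.5 calling threshold);
- `sigma_ic` is tissue-wide late-stage silencing (`silence_lfc = 2`) for
  maturity-silenced and DRMS peaks. Silencing is applied tissue-wide, not
  through the dilution mixture, because developmental silencing affects
  the whole disc while dilution models the regenerating fraction;
- `s_j` is a log-normal(0, 0.15) per-sample depth factor, so
  normalization is never trivial;
- `alpha = 0.05` is the NB dispersion.

The truth table partitions peaks into `null` (90%),
`damage_responsive_early` (2%), `damage_responsive_late` (1%),
`damage_responsive_both` (1%), `maturity_silenced` (4%) and `drms` (2%).
A `drms` peak carries both the early damage response and late silencing.
Note that a peak planted as `damage_responsive_early` *also* satisfies
the operational DRMS definition — its damage response is absent in late
discs, so the late-damaged vs early-damaged contrast calls it down.
That mirrors the real screen, where the DRMS set is *defined* by that
intersection; recovery tests therefore assert recall of planted `drms`
peaks and the null false-call rate rather than label exclusivity.

Scored peak sets report every truth peak whose expected bulk mean clears
an accessibility floor (default 5 expected fragments), score it by that
mean (the stand-in for a caller's quality score), jitter boundaries by
±25 bp so condition sets overlap without being identical, and pad with
condition-specific low-scoring noise peaks to the requested pool size.

`make_genome()` and `make_orthologs()` provide deterministic sequence
fixtures: a random ACGT chromosome with non-overlapping gene models
(each gene gets a ≥ 5 kb slot), and orthologs derived by independent
per-base substitution outside exactly-copied conserved blocks (no
indels, so block coordinates are shared across species).

**What the generator does not emulate** — and hence what passing tests do
not show about real data: Tn5 insertion bias, fragment-length structure,
GC effects, correlated (batch) noise across peaks, peak-caller boundary
error beyond uniform jitter, and real genome sequence composition
(repeats, indels between species). Conclusions about *statistical
behavior* (calibration, recovery, monotonicity in `f` and `delta`)
transfer; conclusions about absolute peak counts at a given threshold do
not.

## Numerical choices and degenerate inputs

- All randomness flows from explicit seeds; the pipeline derives one
  sub-seed per stage from a single root seed (kept below 2^31).
- Size factors fall back to total-count ratios (with a warning) when no
  peak is positive in all samples; all-zero peaks are excluded from
  testing and reported with `NA` statistics; BH propagates `NA`s without
  letting them count toward the number of tests.
- Strict inequalities at thresholds: a peak with `padj` exactly at the
  cutoff is not called.
- Problem sizes in the test suite (a few hundred to 10,000 peaks,
  sequences of 0.1–100 kb) were chosen to make every Monte-Carlo check
  stable at fixed seeds while keeping the default suite fast.

## A worked run

```{r example, eval = FALSE}
design <- sim_design(seed = 7)
sim <- simulate_counts(design)
sf <- size_factors(sim$counts)
de <- nb_wald_test(sim$counts, sim$design_table,
                   list(numerator = c("earlyL3", "damaged"),
                        denominator = c("earlyL3", "undamaged")), sf = sf)
dl <- nb_wald_test(sim$counts, sim$design_table,
                   list(numerator = c("lateL3", "damaged"),
                        denominator = c("lateL3", "undamaged")), sf = sf)
dm <- nb_wald_test(sim$counts, sim$design_table,
                   list(numerator = c("lateL3", "damaged"),
                        denominator = c("earlyL3", "damaged")), sf = sf)
classify_drms(call_set(de, "up", 0.1, 0.5),
              call_set(dl, "up", 0.1, 0.5),
              call_set(dm, "down", 0.1, 0.5))
```

The test suite runs this exact configuration and checks that every
planted DRMS peak is recovered and that unplanted nulls enter the DRMS
set at an FDR-consistent rate.

## Known limitations

- The NB Wald engine's normal approximation degrades for very low counts
  (group means of a few fragments); there is no independent filtering, so
  such peaks simply contribute weak tests.
- Conserved-block detection assumes collinear, indel-free identity; an
  insertion inside an otherwise conserved run splits it, as it would in
  the underlying biology of the screen, but diverged spacing between
  blocks is invisible to it.
- Manual curation of browser traces — part of any real enhancer screen —
  is out of scope by nature; the classifier output is a guide, not a
  final call set.
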