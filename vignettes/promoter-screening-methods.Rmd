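---
title: "Methods: screening for strong constitutive promoters from read counts"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: screening for strong constitutive promoters from read counts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(promscreen)
```

## The screening model

`promscreen` operationalises "strong constitutive promoter" as a purely
rank-based definition: a gene drives a strong constitutive promoter if it
sits in the top fraction of expression in *every* sampled condition. No
distributional model is fitted to the counts; the screen is a composition of
order statistics and set intersection, which makes it robust to the
between-sample normalisation problems that plague magnitude-based
definitions (only within-sample ranks matter).

Three choices deserve justification.

**Raw counts, not TPM/CPM.** Within a sample, ranking by raw read counts is
the screen's default. Because the intersection only compares ranks within a
sample, library size cancels; what does *not* cancel is gene length — long
genes accumulate more reads at equal molarity. The screen targets promoter
*output* in aggregate, and the length bias is accepted rather than
corrected; a CPM mode (`normalize = "cpm"`) exists for users who want
library-size-normalised values (note CPM does not remove length bias
either).

**Cutoff size k = ⌈f·n⌉.** The ceiling guarantees a non-empty top set for
any positive fraction and any non-empty gene universe. For the motivating
genome size (4427 annotated genes) this gives k = 133 at f = 0.03.

**Boundary ties.** With discrete counts, the gene at rank k may tie with
genes below it. The default (`boundary_mode = "truncate"`) sorts by
(descending count, ascending gene id) and cuts at exactly k — deterministic
and reproducible. The alternative (`boundary_mode = "ties"`) keeps the whole
tie class at the boundary, so the top set is the superset
\{g : count(g) ≥ count at rank k\}. Both conventions are defensible; the
flag exists because published gene tallies can depend on which one an
analysis used, and reproducing a specific tally may require toggling it.

With replicate columns, replicates of a condition are summed before ranking
(`aggregation = "sum"`), reflecting designs where replicate cultures are
pooled before sequencing; means are an option, and `min_samples` relaxes
"every sample" to "at least m samples".

## Upstream intergenic regions

The promoter candidate for a gene is its upstream intergenic region: from
the gene's 5′ boundary to the nearest annotated feature boundary on the 5′
side, *irrespective of the neighbour's strand*. The phrase "the intergenic
region between the gene and its upstream gene" does not distinguish
co-directional from divergent or convergent neighbours, so the purely
positional reading is implemented, and the neighbour's identity and strand
are recorded for auditing. Feature classes counted as neighbours are gene,
CDS, rRNA, tRNA and tmRNA — non-coding features bound intergenic regions
too (one of the strongest candidate promoters in the motivating study
belongs to a tmRNA).

Conventions:

- Internal coordinates are 0-based half-open; GFF3 and GenBank (1-based
  inclusive) are converted at the I/O boundary, BED is emitted natively.
- On circular replicons the upstream walk wraps the origin; an interval
  stored with `start > end` encodes the wrap. Rotating all coordinates of a
  circular annotation leaves every region length unchanged (tested).
- An overlapping upstream neighbour gives length 0, never negative.
- On a linear replicon with no 5′ feature, the region truncates at the
  replicon edge and is flagged `truncated`.
- `−` strand sequences are reverse-complemented so every exported promoter
  reads 5′→3′ toward its gene.

The length filter retains regions with length ≥ `min_length` (default
100 bp): the exclusion rule is "shorter than 100 bp", so a 100 bp region
survives. Very short intergenic gaps usually mean the candidate is inside
an operon — its transcription is driven from a promoter further upstream,
and the gap alone is unlikely to contain a complete promoter. The threshold
is measured on the intergenic gap itself, not on any larger cloned
fragment.

## Assay quantitation

- **Reporter strength**: percentages are blank-subtracted by default
  (`100·(L̄_p − L̄_blank)/(L̄_ref − L̄_blank)`), with a flag to disable,
  because reported percentages are meaningless unless the blank convention
  is explicit. Negative blank-subtracted signals clamp to 0 with a warning.
  Strength is scale-invariant in the readings. Replicates aggregate by
  arithmetic mean; the sd of the percentage uses the ratio-of-means
  approximation (sd_p/net_ref), documented as approximate.
- **Nitrogenase activity**: the acetylene-reduction formula
  `(A_exp/A_1nmol · V)/(m · t)` with defaults V = 100 mL, t = 4 h. The
  function is linear in peak area and inverse-linear in protein and time
  (tested as invariants).
- **Ammonium standard curve**: ordinary least squares with a fitted
  intercept (not forced through the origin — the colorimetric blank is
  rarely exactly zero); inversion is `(response − intercept)/slope`;
  r² < 0.98 warns; inversions outside the standard range are flagged
  extrapolated rather than refused.
- **qPCR**: `2^−ΔΔCt` with amplification efficiency fixed at 2; no
  efficiency calibration is modelled.
- **Fold ratios**: reported "n-times" values round half away from zero
  (359.1/20.3 = 17.69 → 18), matching how such statements are printed.
  Whether "increased by x fold" means ratio = x or ratio = x + 1 is
  ambiguous in prose; the package computes plain ratios and leaves the
  convention to the caller.
- **ANOVA/Tukey**: `stats::aov` + `stats::TukeyHSD`, stars at
  0.05/0.01/0.001. When every group has exactly zero within-group variance
  but means differ, F is ill-defined; the result is flagged `degenerate`
  with p reported at the machine floor instead of a numerically meaningless
  finite value.

## What the synthetic generator emulates — and what it does not

`synthetic_spec()` defaults define the simulated study conditions:

- **4 samples**, mirroring a two-media × two-time-point design, one pooled
  count column per condition (replicates were pooled before sequencing in
  the motivating design; `n_replicates > 1` exercises the aggregation path
  instead).
- **200 genes** on a 300 kb circular replicon, gene lengths uniform
  300–1500 bp — genome-scale behaviour at test-friendly size. Intergenic
  gaps are a two-component mixture: uniform(10, 99) with probability
  `frac_short_gap` (default 0.2), uniform(100, 600) otherwise, placing a
  known fraction of planted genes below the length filter.
- **Counts**: negative binomial with background mean 50 and overdispersion
  α = 0.1 (variance = μ + αμ²), the order of magnitude typical of bulk
  RNA-seq count noise. Planted constitutive genes get 1000× the background
  mean in every sample; decoys get 100× in a random strict non-empty subset
  of samples. The 1000×/100×/1× ladder was chosen by a separability
  calculation: with α = 0.1 the probability that a constitutive draw falls
  below a decoy draw is ≈ 10⁻⁶ (Beta tail of the gamma-ratio), so exact
  recovery over 20 seeds is expected by design, while decoys still dominate
  every background gene in their active samples. Note the recovery
  guarantee needs `n_constitutive ≤ ⌈f·n⌉` (5 ≤ 6 at the defaults).
- Per-sample sequencing depth is not varied; defaults are chosen for
  separability, not depth realism.

What it does **not** emulate: operon structure (counts are independent
across genes, whereas real neighbours are correlated), length-dependent
read accumulation, ambiguous multi-mapping, overlapping genes, plasmids, or
condition-correlated library composition. Passing the planted-truth tests
therefore demonstrates the pipeline's *logic* — ranking, intersection,
geometry, filtering — not robustness to those real-data artefacts.

Assay tables are generated by inverting each quantitation formula at known
ground truth, with optional multiplicative noise (additive for Ct values);
zero-noise tables invert exactly, which is the basis of the end-to-end
assay tests. Ground-truth magnitudes (strengths 17–959 %, activities
70–287 nmol h⁻¹ mg⁻¹, ammonium up to 359.1 µM, folds 25–127) sit at the
scales the formulas are used on in practice.

## Numerical and degenerate-input choices

- Tie-break everywhere is (primary key, then ascending gene id) under C
  collation — byte-deterministic across platforms and locales.
- A slope is treated as zero (and rejected) when |slope| <
  10⁻¹² · max(|response|)/max(|concentration|), catching constant-response
  series that floating-point OLS reports as ~10⁻¹⁶ instead of 0.
- Empty inputs: an empty count table errors (a screen over nothing is a
  user mistake); an empty retained set exports valid empty files with a
  warning (a legitimate outcome).
- `generate_genome` refuses infeasible packings (genes + gaps exceeding the
  replicon) rather than silently rescaling.
- Reproducibility: every stochastic function takes or derives from a single
  integer seed; identical config and inputs give byte-identical run
  reports.

## Problem sizes used in the tests

The suite runs genome-scale logic at reduced size, chosen so the whole
suite completes in well under a minute while every code path is exercised:
toy annotations of 2–30 genes against a base-by-base oracle, random count
matrices up to 60 × 4 against a full-sort oracle, and 20 independent
200-gene genomes for planted-truth recovery. The 4427-gene cutoff
arithmetic is checked directly on a 4427-row matrix.

## Package shape

The screen is exposed in the classic modelling idiom — `promoter_screen()`
returns a classed object with `print()` and `summary()` methods, and
`fit_standard_curve()` returns a classed fit with `print()` and
`predict()` — while generators and file-level pipeline steps remain plain
functions, which matches how users script such screens. `run_screen()` /
`run_assays()` plus the `inst/scripts/promscreen.R` wrapper provide the
file-in/file-out interface.

## Known limitations

- The positional "nearest upstream feature" rule does not model operons:
  a gene internal to an operon with a long upstream gap still yields a
  candidate region even though its true promoter lies further upstream.
- Raw-count ranking favours long genes (see above).
- The screen is only as good as the annotation: missing features lengthen
  regions; spurious ones shorten them.
- GenBank parsing covers simple and `complement()` locations only;
  `join()` (compound) locations are rejected — convert such annotations to
  GFF3 first.
- The ANOVA path assumes exchangeable replicates and homoscedastic groups;
  it is the figure-legend statistic, not a general mixed-model framework.
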