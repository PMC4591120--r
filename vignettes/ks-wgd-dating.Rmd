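---
title: "Detecting and dating whole-genome duplications from Ks distributions"
author: "ksdater"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting and dating whole-genome duplications from Ks distributions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ksdater)
```

# The scientific problem

A whole-genome duplication (WGD) doubles every gene at one instant. Each
surviving duplicate pair then accumulates synonymous substitutions at a
roughly clock-like rate, so the synonymous distance Ks between the two
copies grows with time since the duplication. A transcriptome sampled
today therefore carries a *Ks age distribution*: many paralog pairs born
in one WGD share a similar Ks and form a peak, while continuous
small-scale duplication contributes a broad background. Finding peaks in
this distribution detects ancient WGDs; converting a peak's median Ks
through a synonymous molecular clock dates them.

`ksdater` implements this analysis end to end for a de novo assembled
transcriptome: assembly QC, hit-guided CDS extraction, paralog-family
construction, pairwise and node-wise Ks estimation, mixture modeling of
the age distribution, and clock dating — plus a mechanistic simulator that
generates every input with known ground truth.

# Core model

## Ks and Ka estimation

Two estimators operate on protein-guided codon alignments
(`alignProteins()` + `backTranslate()`, global alignment, BLOSUM62,
gap open 10 / extend 0.5):

* **NG86** (`ksNG86()`): synonymous sites per codon are the per-position
  fractions of single-nucleotide changes that are synonymous, with
  stop-codon targets excluded from the denominator. Differences between
  codons are averaged over all shortest substitution pathways that avoid
  stop codons, equally weighted. Proportions are corrected with the
  Jukes–Cantor formula $d = -\tfrac{3}{4}\ln(1-\tfrac{4}{3}p)$;
  $p \ge 3/4$ is reported as a saturation flag, never clamped.
* **YN00** (`ksYN00()`, the production estimator): codon frequencies from
  the F3×4 model pooled over both sequences; the transition/transversion
  ratio kappa is estimated iteratively from approximate
  fourfold-degenerate versus nondegenerate site comparisons (two K80
  distances combined by site weight, kappa = 2A/B); site counts are
  weighted by kappa and codon frequencies with S + N = 3L preserved;
  pathway weights are proportional to the product of target-codon
  frequency and $\kappa^{\#\text{transitions}}$; synonymous and
  nonsynonymous transition/transversion splits each get a two-parameter
  (K80-style) correction. Iteration stops when kappa moves < 1e-6 or
  after 100 rounds (non-convergence is flagged, the last iterate kept).

With kappa fixed at 1 and uniform codon frequencies, YN00's site counts
reduce exactly to NG86's — the limiting case the test suite checks. Under
transition bias (kappa > 1) NG86 systematically undercounts synonymous
sites, so the two estimators differ by a few percent; this is expected
behaviour, not a bug, and the simulator's calibration is therefore
estimator-aware (below).

## Families and node Ks

Paralogous pairs come from an all-by-all nucleotide hit table filtered at
E-value ≤ 1e-5, identity ≥ 40% and alignment length ≥ 150 bp (inclusive
thresholds, self-hits dropped, reciprocal hits merged keeping the best
E-value). Gene families are the connected components of the pair graph
(single linkage). A family of m genes would contribute m(m−1)/2 pairwise
Ks values and swamp the age distribution, so each family is reduced to
**node Ks** values: agglomerative single-linkage clustering on the
family's Ks matrix yields m−1 internal nodes, and each node contributes
one value — by default the *median* of all cross-cluster pairwise Ks at
that merge (`min`, the linkage height, and `mean` are switchable). Nodes
with Ks = 0 are removed; values outside (0, 2) are flagged out of the
age-distribution universe. Pairs whose estimation fails inside a family
get distance +∞ so family membership (a similarity-graph property) is
preserved without inventing a finite height.

## Mixture model on ln(Ks)

Node-Ks values in (0, 2) are modeled as a K-component normal mixture on
the natural-log scale (lognormal components on the Ks scale). `fitKsMixture()`
runs multi-start EM — 100 random starts (component means at jittered
sample quantiles) plus 10 k-means (Lloyd) starts, each start seeded as
`seed + start index` — and keeps the best converged, non-degenerate
start. The E-step uses log-sum-exp; variances are floored at 1e-4 and
weights at 1e-8 to rule out the unbounded-likelihood degeneracy of
Gaussian mixtures. The free-parameter count is p = 3K − 1, and
`ksMixtureScan()` selects K by BIC (AIC also reported), ties toward the
smaller K. Components with ln-scale sigma above 0.4 are labeled
*background* (continuous small-scale duplication); the rest are
*discrete-event* candidates.

## Dating

For a discrete-event component with ln-scale mean mu, the median Ks is
exp(mu) (the median, not the mean, of a lognormal — the back-transform is
exact for the location parameter). The divergence time is
$T = K_s^{med} / (2r)$ with the default synonymous rate
$r = 6.1\times10^{-9}$ substitutions per synonymous site per year; the
divisor 2 accounts for both lineages accumulating substitutions since
the split. Reports round to 0.1 Mya; the unrounded value is kept.

# Synthetic data generator

Simulations are *mechanistic*, not draws from the fitted model: a codon
sequence evolves by proposal–acceptance. Proposals pick a nucleotide
site uniformly and a target base with transition:transversion weight
kappa:1; a proposal creating a stop codon is rejected; a nonsynonymous
change is accepted with probability omega and a synonymous one always.
Multiple hits and back-substitutions happen naturally, so the multiple-hit
corrections in both estimators are genuinely exercised rather than
assumed.

The expected number of *accepted synonymous changes per synonymous site*
is not available in closed form under this process (site counting is
itself estimator-dependent), so the proposal count per branch is
calibrated by a pilot simulation: two rounds of 500 replicates on a
fixed internal seed estimate the multiplier that makes the expected
*estimated* Ks equal the target, and the constant is cached per
(length, target, omega, kappa, estimator) configuration. Calibration is
estimator-aware (`calibrate_to = "NG86"` or `"YN00"`) because of the
systematic NG86/YN00 site-count difference described above; recovery
studies should calibrate to the estimator they evaluate.

`evolveFamily()` plants duplications at given node depths (a caterpillar
topology whose true single-linkage node heights are the given depths).
`simulateTranscriptome()` builds every pipeline input — unigene FASTA
with random UTRs flanking each CDS, a best-protein hit table, an
all-by-all nucleotide hit table and a protein FASTA — and writes the
ground truth as JSON. Its defaults represent the conditions this package
is aimed at: two events at Ks 0.25 and 1.33, 300 + 180 two-member
families plus 25 three-member families (≈ 530 node values, matching the
scale of a real transcriptome analysis with n = 529 paralogs), ln-scale
scatter 0.08 between family depths, 300 codons per gene, omega 0.2,
kappa 2.

# Numerical and design choices

* **Codon machinery**: codons are indexed 1..64 in A,C,G,T order;
  neighbor tables, per-codon synonymous-site fractions and pathway
  decompositions are cached in a package environment. If *every*
  pathway between two codons passes through a stop, NG86 falls back to
  splitting the raw differences proportionally to the mean synonymous
  fraction and flags the pair.
* **Histogram**: half-open bins of width 0.05 over [0, 2) via
  `findInterval()` on canonical breaks, so floating-point boundary
  values land deterministically.
* **EM**: relative log-likelihood tolerance 1e-8, 1000-iteration cap per
  start; fits sort the input values first so results are invariant to
  input order.
* **Determinism**: one global seed; the pipeline derives per-stage seeds
  by a stable hash of (seed, stage name). Two runs with the same config
  and seed produce byte-identical stage outputs (timestamps live in a
  separate manifest field), and a matching manifest fingerprint lets
  `runKsPipeline(resume = TRUE)` reuse the expensive CDS and Ks stages.
* **Problem sizes** (package's own choice, sized to run in minutes on one
  core): acceptance-level checks use 1,000 random codon pairs against the
  exhaustive pathway oracle, 200 replicates × 3 targets for estimator
  recovery at 500 codons, 20 seeds × n = 529 for mixture model selection,
  and one full synthetic transcriptome (~1,060 genes) for end-to-end
  recovery.

# Worked example

```{r example, eval = FALSE}
library(ksdater)

## simulate a transcriptome with two planted WGDs (defaults: Ks 0.25, 1.33)
sim <- simulateTranscriptome(dir = "simtx", seed = 1)

cfg <- pipelineConfig(
  fasta = sim$unigenes,
  protein_hits = sim$protein_hits,
  allbyall_hits = sim$allbyall,
  protein_fasta = sim$proteins,
  kmax = 3, seed = 17)
res <- runKsPipeline(cfg, "out")

res$scan                 # mixture scan table, K selected by BIC
subset(res$dates, label == "discrete-event")
```

# Limitations

* YN00 is reimplemented from the published method; minor implementation
  variants exist between programs, and this package pins its own choices
  (pooled F3×4 frequencies, kappa initialized at 2, flag-never-clamp on
  saturation). Bit-for-bit agreement with other implementations is not a
  goal; limiting-case equivalence with NG86 and parameter recovery on
  simulations are the correctness anchors.
* The caterpillar family topology in the simulator is a simplification;
  real families have arbitrary shapes. Node-Ks decomposition does not
  depend on the topology assumption, but recovery numbers do.
* Dating inherits every caveat of a strict synonymous clock: rate
  variation across lineages and genes propagates directly into the
  divergence times, and the default rate is an angiosperm average.
* The similarity searches themselves (BLAST-like all-by-all and
  protein hits) are external inputs; the package consumes their standard
  12-column tabular output but never runs them.
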