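---
title: "Inferring transcriptional burst kinetics from single-cell count histograms"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Inferring transcriptional burst kinetics from single-cell count histograms}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(burstfit)
```

## The model and its assumptions

`burstfit` fits the two-state telegraph model of transcription to per-gene
mRNA count histograms from single-cell RNA-seq. A promoter switches
between an inactive and an active state at rates `k_on` (activation; the
burst frequency) and `k_off` (inactivation); mRNA is produced at rate
`k_eject` only while active and decays at `k_decay` per molecule. All
rates are per minute. The stationary copy-number law of one gene copy is
Beta-Poisson: Poisson with intensity `lam * p`, where
`p ~ Beta(a, b)` and `a = k_on/k_decay`, `b = k_off/k_decay`,
`lam = k_eject/k_decay`. Burst size is `k_eject/k_off`, the mean number of
transcripts per active period.

Assumptions the fit inherits from this model:

- **Stationarity.** Histograms are snapshots of cells at steady state; the
  model has no time-dependent rates.
- **Independent identical alleles.** A cell's count is the sum of
  `n_alleles` independent copies (distribution self-convolution). No
  inter-allele coupling is modeled; ploidy enters only through the
  convolution order, which is what the ploidy-sensitivity refits vary.
- **Known decay.** `k_decay` is fixed per gene from a measured mRNA
  half-life (`k_decay = ln 2 / t_half`), anchoring the timescale so the
  other rates are identified in absolute units. Genes missing from the
  half-life table receive the cohort median, with a warning.
- **No technical-noise layer.** The likelihood is the bare model: no
  dropout, capture-efficiency or amplification term. Inferred rates are
  therefore rates of the *observed* count process; see "Known
  limitations".

## Inference

`telegraph_fit()` samples the posterior of `(k_on, k_off, k_eject)` on the
log10 scale under independent uniform priors on `[-4, 2]` (per-minute
units; wide enough that tested regimes sit far from the bounds), with the
likelihood evaluated from the truncated chemical-master-equation (CME)
stationary solve convolved over alleles.

The sampler is an affine-invariant ensemble (24 walkers, stretch moves,
stretch range 2), pooled after burn-in, rather than a single random-walk
chain. The reason is structural: a count histogram constrains the mean and
overdispersion strongly but the third parameter direction only weakly, so
the log-likelihood is nearly flat along a long curved ridge in rate space.
A single random-walk chain — even with adaptive covariance — equilibrates
to the basin nearest its start and reports a falsely tight posterior
there. That failure is not cosmetic: the quality-control filter keys on
posterior spread (MAD/median), so an under-mixed chain lets structurally
unidentifiable estimates through. Stretch moves are invariant to affine
distortions of the target, so the ensemble expands along such ridges
without tuning, and walkers are initialized uniformly over the prior box
so the pooled summaries are initialization-free. Identifiable histograms
collapse every walker to the single mode; unidentifiable ones show their
honest spread and fail QC. `n_steps` (default 10,000) and `burn_in`
(default 2,000) count pooled draws across the ensemble, keeping them
comparable cost knobs to single-chain step counts; burn-in is floored at
100 ensemble iterations. All randomness flows through R's RNG, so a fixed
seed reproduces a fit exactly.

Summaries are posterior medians and **raw** median absolute deviations
(MAD with constant 1, not R's 1.4826-scaled default), because the QC
filter is defined on median and MAD and the plain definition is the one
whose 0.75 threshold reads directly as "spread below three quarters of
the estimate". QC passes iff `MAD/median < 0.75` for both `k_on` and
burst size (strict) and mean expression `> 0.01` (strict); a zero median
fails. "Expression" here is the observed mean raw count per fitted cell —
the simplest quantity consistent with fitting raw histograms. All-zero
histograms yield a flagged degenerate fit (`qc_pass = FALSE`), never an
error.

`predict()` returns the posterior-predictive distribution (stationary pmf
averaged over thinned posterior draws) rather than a plug-in at the
componentwise posterior medians: the medians of correlated marginals need
not form a representative joint rate set. For the same reason the
recovery suite checks the observed mean against the posterior *median* of
the stationary-mean functional, which is robust to the heavy upper tail
that the mean functional acquires for weakly expressed genes.

## Numerical choices

- **Stationary distribution, two routes.** The production route solves the
  truncated CME (states {OFF, ON} x {0..n}) by backward block elimination
  with 2x2 blocks, O(n) per evaluation, with a forward sweep that rescales
  to avoid underflow when P(0) sits hundreds of decades below the mode.
  The closed-form route evaluates the classical confluent-hypergeometric
  solution in log space (Kummer-transformed so the series has positive
  terms). The two agree to ~1e-14 and serve as mutual oracles; the CME
  route backs the likelihood because hypergeometric evaluation is the more
  delicate of the two at extreme rates.
- **Truncation.** The support is cut at the analytic mean + 10 standard
  deviations (doubled until the closed-form tail mass is below 1e-8; in
  practice this lands near 1e-15). Requesting a smaller `n_max` whose tail
  exceeds 1e-8 raises an error naming the required truncation point.
  Observed counts beyond the moment-based cut extend the solve; they are
  never clipped.
- **Allele convolution inside the likelihood** is truncated at the largest
  observed count plus one (entries below the cut are exact) and uses
  binary powering for high ploidies.
- **Absurd-mean guard.** Proposals implying a stationary mean above 1e4
  counts/cell return a smoothly decreasing penalty instead of paying for
  an enormous solve; the penalty is monotone in the implied mean so a
  walker that lands there is pushed straight back.
- **Hierarchical clustering** of correlation matrices uses Euclidean
  distance between matrix rows with complete linkage (the default
  behavior of the base-R heatmap toolchain); `hclust` breaks merge-height
  ties deterministically by original index, so orderings are reproducible.
  Zero-variance genes yield `NA` correlations, are flagged, and must be
  dropped before ordering — never silently zeroed.

## The synthetic study generator

`generate_study()` emulates the two-condition, one-cluster design the
package targets: a background gene panel with condition-shared kinetics, a
12-gene interferon-related signature whose ejection rate (hence burst
size, with `k_off` fixed) is multiplied by 3 in the treated condition, a
per-cell log-normal extrinsic factor (sdlog = `coupling_strength`, mean
1) multiplying the signature genes' ejection rates in the treated
condition only (creating the treated-only co-expression block), mito
decoy genes so the mitochondrial fraction is computable, planted aberrant
cells violating exactly one cell-QC threshold each, and a per-gene
half-life table (log-normal, median 300 min). Counts are drawn per allele
from the stationary Beta-Poisson law; the Gillespie simulator
cross-validates that sampler in the test suite.

Rate draws: burst size log-uniform on [1, 20]; `k_off/k_on` log-uniform on
[3, 30] — OFF-dominated promoters, the regime live-cell imaging and
transcriptome-wide kinetic fits consistently report for mammalian genes,
and the regime in which "burst size" is a meaningful, identifiable
quantity; `k_on` is then set by a log-uniform target mean on [0.5, 50]
counts/cell and clamped into [0.003, 0.3]/min. An earlier design solved
`k_off` directly from the target mean; it was replaced because it placed
most promoters in a near-always-ON regime with hour-long active periods —
biologically odd and structurally unidentifiable from stationary
histograms.

Because the panel is a few hundred genes, the per-cell QC covariates
(`nFeature`, `nCount`, `percent_mito`) are carried as full-transcriptome
metadata of the kind upstream QC produces before gene subsetting (a
325-gene panel cannot physically realize 12,000 detected genes); the
package recomputes them from the matrix only when metadata are absent.
Mito-violating cells also get their panel mito counts inflated so the
panel signal points the same way.

What the generator does **not** emulate: UMI/read-level sequencing noise,
doublets and ambient RNA, the low-complexity bimodal profiles of
senescent cells, or cell-cycle structure within the cluster. Passing
tests therefore demonstrate that the pipeline recovers known telegraph
kinetics and planted condition effects from clean stationary counts —
not that real droplet data are free of the biases those processes add.
The optional `dropout_rate` (binomial thinning) exists precisely to
document the first of those biases: with thinning the observed means
scale by `1 - dropout_rate` while the likelihood still fits the bare
model.

## Design choices where the design was open

- **Two-sided** Wilcoxon rank-sum for the signature-vs-background
  comparisons; exact null for combined n <= 25 without ties, normal
  approximation with tie correction otherwise. The background is all
  QC-passing non-signature genes.
- **Expression fold change** uses observed mean counts, not the
  model-implied mean — assumption-free and directly comparable between
  conditions.
- **Fold-change records** exist only for genes passing QC in both
  conditions; nonpositive control medians skip the gene with a message.
- **Cells are filtered before genes** (detection counts are taken over
  retained cells), and the pipeline fixes this order.
- **Correlations** are computed on log-normalized values (per-cell scaling
  to 10,000, then log1p) across the cells of one condition at a time;
  the treated-condition leaf order is transferred to the control matrix.
- **Simulator RNG**: both samplers draw from R's single seeded stream
  rather than per-cell counter-based streams; determinism (same seed,
  same output) is the tested contract, order-independence across cells is
  not.

## Problem sizes

The standard validation workloads, chosen to exercise every stage at
desk scale: the default study is 312 genes (300 background + 12
signature) plus 13 mito decoys at 3,000 cells per condition, fitted with
3,000 pooled draws after 1,000 burn-in per gene; the recovery suite is 30
genes spanning means 0.5–50 at 2,000 cells with 10,000 pooled draws; the
ploidy refits use a 60-background-gene panel at 1,000 cells across allele
counts {2, 4, 8, 16}. The full test suite and the acceptance script each
run in a few minutes on one CPU.

## Known limitations

- **Extrinsic noise is attributed to bursting.** The treated-condition
  extrinsic factor that couples the signature genes also inflates each
  gene's marginal overdispersion, and the bare likelihood can only explain
  extra overdispersion as larger, rarer bursts. On the default study the
  signature's burst-size fold change therefore overshoots the planted
  log2(3) and its frequency fold change undershoots zero by the
  complementary amount (their sum, fixed by the expression fold change,
  is recovered accurately); with `coupling_strength = 0` both land on
  truth. This trade-off is intrinsic to any cell-shared factor: the
  pairwise correlation it creates and the per-gene variance it adds scale
  with the same quantity. Interpreting burst-size changes for gene sets
  suspected of shared extrinsic regulation requires this caveat on real
  data too.
- **Weakly identified genes are filtered, not rescued.** For histograms
  close to Poisson the burst-size posterior is ridge-shaped and its
  median reflects prior volume as much as data; the QC filter exists to
  remove these, and the honest posterior spread the ensemble sampler
  produces is what makes it effective.
- **No technical-noise layer** in the likelihood (see above): rates are
  in observed-count units, and capture losses bias `k_eject`-derived
  quantities downward on real data.
- **Single cluster, two conditions.** Cluster assignment is taken from
  metadata; de novo clustering, integration and doublet handling are out
  of scope.
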