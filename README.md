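# burstfit

Per-gene inference of transcriptional bursting kinetics from single-cell
RNA-seq count histograms, built around the two-state telegraph model of
transcription, with tools for comparing burst kinetics between two
experimental conditions and for analyzing gene–gene co-expression
remodeling.

## Who this is for

Analysts of single-cell RNA-seq experiments who want to know *how* a gene's
expression changed between conditions — more frequent bursts, or bigger
ones — rather than just *whether* it changed. The package was designed
around a chemoresistance study design: two conditions (untreated vs.
drug-treated), a proliferative cell cluster analyzed in each, and a small
interferon-related gene signature whose upregulation is driven by burst
size. Everything runs equally on user-supplied count matrices or on the
package's own synthetic studies with known ground truth.

## The model

A gene's promoter switches between an inactive and an active state; mRNA is
produced only while active and degrades continuously:

    OFF --k_on-->  ON          (activation: burst frequency, per minute)
    ON  --k_off--> OFF         (inactivation)
    ON  --k_eject--> ON + mRNA (production while active)
    mRNA --k_decay--> 0        (first-order decay per molecule)

Its stationary mRNA copy-number distribution is Beta-Poisson: Poisson with
intensity `(k_eject/k_decay)·p` where `p ~ Beta(k_on/k_decay,
k_off/k_decay)`. Two derived quantities summarize the kinetics:

- **burst size** `= k_eject / k_off` — mean mRNA made per active period;
- **burst frequency** `= k_on` — how often bursts initiate.

Per gene, the package fixes `k_decay = ln 2 / t_half` from a measured mRNA
half-life (so all rates come out in per-minute units) and samples the
posterior of `(k_on, k_off, k_eject)` from the raw count histogram by
Metropolis–Hastings MCMC (an affine-invariant walker ensemble on the log10
rates, with uniform log10 priors). Multi-allele genes are modeled as
independent identical copies (distribution convolution). Fits are
summarized by posterior medians and MADs and pass quality control iff
`MAD/median < 0.75` for both `k_on` and burst size and the gene's mean
expression exceeds 0.01 — estimates whose histogram does not pin them down
are discarded rather than reported.

Two independent implementations of the stationary law (a closed-form
confluent-hypergeometric evaluation and a truncated chemical-master-
equation linear solve) plus two independent samplers (exact Gillespie
simulation and the Beta-Poisson draw) serve as mutual oracles throughout
the test suite.

## Worked example

Simulate one gene at known rates (burst size `2.5/0.5 = 5`, frequency
`0.05/min`), then fit its histogram:

```r
library(burstfit)

rates  <- telegraph_rates(k_on = 0.05, k_off = 0.5, k_eject = 2.5, k_decay = 0.02)
counts <- betapoisson_counts(rates, n_cells = 2000, n_alleles = 1, seed = 11)
fit    <- telegraph_fit(counts, k_decay = 0.02, n_alleles = 1, seed = 5)
fit
#> Telegraph-model fit: 2000 cells, 1 alleles, k_decay = 0.02 /min
#>   burst size 6.17 (MAD 0.736), frequency 0.0481 /min (MAD 0.00379)
#>   mean expression 11.5 counts/cell; QC pass; acceptance 0.35
round(coef(fit), 4)
#>       k_on      k_off    k_eject    k_decay burst_size  frequency
#>     0.0481     0.1930     1.3502     0.0200     6.1691     0.0481
```

The posterior median burst size (6.17) and frequency (0.048/min) recover
the simulation truth (5 and 0.05/min) within the factor-1.5 window the
recovery suite enforces; `qc_filter(fit)` is `TRUE` because both relative
MADs are small and the gene is expressed. `summary()`, `predict()`
(posterior-predictive distribution), `plot()` (histogram vs. fit),
`residuals()` and `simulate()` are available on the fit object.

A complete two-condition study — synthetic data generation, cell/gene
filtering, per-gene fits in both conditions, burst-size/frequency/expression
log2 fold changes, signature-vs-background Wilcoxon tests, and the
co-expression analysis with ordering transfer — is one call:

```r
res <- run_bursting_study(study_config(seed = 1), seed = 2)
res$comparisons$burst_size   # rank-sum test of signature vs background
res$block_scores             # within-signature correlation per condition
```

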