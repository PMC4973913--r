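---
title: "Label-free quantification and surfaceome analysis: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Label-free quantification and surfaceome analysis: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(surfaceome)
```

This vignette is the package's own account of the statistical machinery it
implements: what each model assumes, which tunable parameters matter, what
the synthetic benchmark generators emulate (and what they do not), and where
the design was genuinely open and a choice had to be made.

## Scope and data model

The package operates downstream of peptide-spectrum identification and
MaxLFQ normalization: its input is a protein-group table in the MaxQuant
`proteinGroups.txt` dialect (or a simplified internal TSV), carrying per
protein group an accession, sequence length, identified-peptide count (PN),
summed MS/MS spectral count (SC), and per-experiment raw (MQ) and
normalized (LFQ) intensities. Two conventions hold everywhere:

* an intensity of 0 means *not detected*, never "measured as zero";
* a protein group with several accessions is keyed by its leading (razor)
  accession.

Rows flagged *only identified by site*, *reverse* or *contaminant* mark
unreliable matches and are removed (`filter_categorical()`) before any
statistics.

## Quantification indices

For protein $p$ with length $L_p$, identified peptides $PN_p$, spectral
count $SC_p$, raw intensity $MQ_p$ and $PO_p$ theoretically observable
tryptic peptides:

$$\mathrm{emPAI}_p = 10^{PN_p/PO_p}, \qquad
  \mathrm{NSAF}_p = \frac{SC_p/L_p}{\sum_i SC_i/L_i}, \qquad
  \mathrm{iBAQ}_p = \log_{10}\!\left(\frac{MQ_p}{PO_p}\right).$$

Two conventions deserve a note. First, the emPAI is implemented without the
"$-1$" of the classical definition, because this form is what the rest of
the toolchain expects; the classical variant ($10^{x}-1$) is available via
`classical = TRUE`. Second, iBAQ values are logarithmized in base 10 by
default, following the absolute-quantification literature; base 2 is a
parameter. NSAF values always sum to one over a table, which the test suite
asserts to $10^{-9}$.

Mean log2 LFQ intensities are mapped to five abundance classes,
`-` / `+` / `++` / `+++` / `++++`, cut at 18, 23, 28 and 33 on the log2
scale. The interval rule had to be chosen (the class bounds are quoted as
"18 to 23" etc. without an endpoint convention): intervals are lower-closed,
$[18,23), [23,28), [28,33)$, with $\ge 33$ in the top class, and
not-detected proteins fall in `-`, treating them as sub-detection-limit
rather than as a separate category. "Mean LFQ" is computed as log2 of the
arithmetic mean of the raw LFQ values across replicates (matching the idea
of averaging intensities, not their logarithms); the alternative
mean-of-log2 is a parameter of `mean_log2_lfq()`.

## Observable peptides

`digest()` performs in-silico tryptic digestion: cleavage after K or R, by
default suppressed before proline, with up to `max_missed_cleavages`
(default 2, the search-engine setting used for this kind of data) internal
missed sites. `count_observable()` counts the *distinct* digest products
passing every enabled observability filter:

| filter | default | rationale |
|---|---|---|
| peptide length | 6–35 aa | MaxQuant's preset window |
| missed cleavages | ≤ 2 | matches the search settings |
| GRAVY (mean Kyte–Doolittle hydropathy) | off | "extreme hydrophobicity/hydrophilicity" window, scale choice ours |
| charge proxy = 1 + #(K,R,H) | off | named without a formula in the sources; this proxy is declared, not derived |
| predicted retention time | off | needs a calibration run |

The proline rule is configurable because search-engine conventions vary
between versions. Distinct-sequence counting (a peptide occurring twice in
one protein counts once) was chosen because observability is a property of
the peptide species. The retention-time filter is deliberately simple: a
linear model of retention time on GRAVY fitted to an observed peptide table
(`estimate_rt_limits()`), whose 1st–99th percentile prediction interval
becomes the admissible window. This is not a serious retention-time
predictor; it reproduces the *limit-setting* step, not chromatography.

## Intensity-binned enrichment

Proteins are ranked by decreasing summed intensity and cut into bins of 50
(`rank_and_bin()`; ties break by accession so results are deterministic).
For each bin and GO term, `bin_term_test()` computes the one-sided
upper-tail hypergeometric probability
$P(X \ge k),\; X \sim \mathrm{Hypergeom}(N, K, n_\text{bin})$ — a Fisher's
exact test for enrichment of the term among the bin members relative to the
universe. The $-\log_{10} p$ profile over bins shows *where in the
abundance ranking* a category concentrates, which frequency-based Venn or
pie summaries cannot.

Defaults mirror the AmiGO-style settings used in this workflow: a term
needs at least 2 members in a bin to be tested (otherwise $p = 1$), and
Bonferroni correction multiplies across the terms tested within a bin, not
across bins (each bin's bar is its own test family).

The universe question is the method's crux. Without knowing the true
abundance distribution of a category over the whole database, a
whole-database universe amounts to assuming a uniform distribution, which
is unrealistic. The default universe is therefore the identified proteins
of the same sample, and the two-sample form (`compare_profiles()`) —
enriched-sample profile minus total-proteome profile, aligned per bin —
is the recommended way to claim enrichment *caused by the preparation*.
Tests are one-sided (enrichment only); annotations are consumed as given,
with no GO-graph ancestor propagation.

## The Boolean surface classifier

A protein is accepted as a cell-surface protein iff

$$\big((GA \lor TM) \land PM\big) \;\lor\; \big(SP \land (ECS \lor ECR \lor ECM)\big)$$

over the feature flags GPI-anchor, transmembrane, signal peptide, plasma
membrane, extracellular space/region/matrix. The expression uses positive
evidence only: conflicting extra annotations (say TM ∧ PM ∧ cytosol) do not
veto a call, making the classifier monotone — a property the tests exercise.
Feature flags come from the annotation file; the package deliberately does
not predict transmembrane segments or signal peptides from sequence.

## Differential testing

`run_differential()` chains three stages.

**Filtering.** LFQ values are log2-transformed with 0 → missing; a protein
is kept if it has at least `min_valid` detected values in *at least one*
group (default: the full size of the smaller group; the four-replicate
benchmarks use 3 of 4). Keeping one-group-only proteins is intentional:
presence/absence differences are exactly what an enrichment experiment
seeks.

**Imputation.** Missing values are drawn per sample column from
$\mathcal N(\mu_s - 1.8\,\sigma_s,\ (0.3\,\sigma_s)^2)$, i.e. a narrow
distribution 1.8 column-SDs below the observed mean — the de-facto standard
for left-censored label-free data. Width and shift are exposed because the
right values depend on the instrument's detection behavior; per-column
(rather than whole-matrix) statistics were chosen so that samples with
different depths are shifted relative to their own distribution.

**Test.** The modified statistic is
$d_p = (\bar x_{1p} - \bar x_{2p}) / (s_p + s_0)$ with $s_p$ the pooled
two-sample standard error and $s_0 \ge 0$ a slope constant that damps
low-variance artifacts (at $s_0 = 0$, $d$ is exactly the classical
equal-variance t statistic, asserted to $10^{-10}$ in the tests). Group
labels are permuted — all distinct relabelings up to group swap, excluding
the observed one, when there are at most 1000; otherwise 250 seeded random
relabelings — and the FDR at cutoff $c$ is estimated by the add-one pooled
estimator

$$\widehat{\mathrm{FDR}}(c) = \frac{\big(1 + \sum_r \#\{|d^{(r)}| \ge c\}\big) / (R + 1)}
      {\#\{|d| \ge c\}}.$$

The cutoff $c^*$ is the smallest observed $|d|$ with
$\widehat{\mathrm{FDR}} \le$ the target. The add-one form (rather than a
median over permutations) is a deliberate design decision: with 3 vs 3
replicates only 10 distinct relabelings exist, and tail-count estimators
without the add-one correction call the single largest $|d|$ "significant"
in roughly half of all pure-noise datasets, at *any* nominal FDR. The
add-one estimator bounds the estimate below by $1/(R+1)$ per observed
exceedance, which restores calibration (realized null FDR ≤ nominal within
Monte-Carlo error at 0.01, 0.05 and 0.25 in the 200-repeat null simulation
of the test suite) while losing essentially no power in the 4-vs-4 spike-in
benchmark (sensitivity ≈ 1 at FDR 0.01). A corollary worth knowing: at
3 vs 3, FDR targets below $1/10$ of the smallest observed tail count are
unattainable, so very small designs need either more replicates or a looser
threshold — which is also why raising the threshold from 0.01 toward 0.25
does not flood the results with false positives.

The significance boundary is exported as a volcano threshold curve: in
$(\Delta, -\log_{10} p)$ coordinates the set
$|\Delta| = c^* (s_0 + |\Delta|/t)$, i.e.
$|\Delta| = c^* s_0 t/(t - c^*)$ for $t > c^*$, with $t$ the t statistic
matching the plotted p-value. A point is significant iff it lies beyond the
curve; the tests assert this equivalence exactly.

## Synthetic benchmarks

Because the real biological counts of any given study depend on the
annotation releases and raw spectra of that study, validation here is
property-based on synthetic data whose generators state their assumptions
explicitly.

`simulate_spike_in()` emulates the classic UPS1-in-yeast differential
standard: 48 equimolar spike proteins at 20 / 6.7 / 2.2 / 0.74 / 0.24 fmol
in quadruplicate over ~1500 background proteins. Intensities are
`amount × per-protein response factor × log-normal noise` with CV 0.2;
response factors are log-normal (SD 0.25 decades) to emulate peptide
response heterogeneity; detection is left-censored by a logistic model on
log2 intensity with midpoint $2^{22.5}$ and slope 0.5, placed below the
0.74 fmol response level so that the 0.24 fmol condition is largely
unquantifiable (< 3 of 4 valid values for most spikes) while 2.2 fmol and
above are essentially complete — the quantifiability boundary the benchmark
is designed to probe. The background abundance spread (mean $10^{7.4}$,
SD 1.2 decades) and count (1500) are declared parameters of the generator,
chosen as realistic for a single-shot yeast background, not measured facts.

`simulate_dilution_series()` spans 500 amol – 500 pmol in decade steps and
additionally generates SC and PN as saturating count processes
(Poisson/binomial with Michaelis–Menten-type rates), so count-based indices
saturate at high input while intensity-based ones remain linear.
`evaluate_accuracy()` then reports, per index, the pooled log-log Pearson
and Spearman correlation, fitted slope, the maximum deviation from the free
regression line in orders of magnitude (`max_outlier`), and the linear
dynamic range — defined against a *unit-slope* line so that a saturating
index is charged for its flattening even when its own regression fits its
points well. Comparing against mass input instead of molar input multiplies
the abscissa by protein length; when all proteins share a length the two
are identical, which the tests use as a degeneracy check.

What these generators do **not** model: spectrum-level sampling,
chromatographic drift, shared/razor peptide ambiguity, inter-sample
normalization error in LFQ values, and annotation noise. Passing the
synthetic benchmarks therefore demonstrates the correctness and calibration
of the statistical machinery under the stated noise model, not performance
on any particular instrument.

## Numerical and reproducibility choices

* Every stochastic operation (imputation, permutation sampling, all
  generators) takes an explicit integer seed; equal seeds give bit-identical
  results, and the workflow runner (`run_workflow()`) derives stage seeds
  from the single config seed.
* Ranking ties break by accession; profiles and bins are invariant to input
  row order and to positive rescaling of intensities.
* Degenerate inputs fail loudly: all-zero spectral counts (NSAF), empty
  sequences, imputation columns with fewer than two observed values, and
  groups with fewer than two samples are errors, not warnings.
* The problem sizes of the shipped simulations (1000-protein null matrices,
  200 null repeats, 1548-protein spike-in tables, 500-sequence digestion
  sweeps) were chosen so the whole validation suite runs in well under a
  minute on a laptop while keeping Monte-Carlo errors small relative to the
  margins being asserted.

## Known limitations

* The permutation FDR is granular at very small replicate numbers
  (see above); q-values below $1/(R+1)$ divided by the tail count cannot
  occur.
* emPAI and PN are implemented faithfully but are poor quantifiers by
  construction (bounded, saturating); the accuracy harness exists partly to
  demonstrate this.
* The surface classifier is only as good as its feature flags; no sequence
  based prediction is attempted.
* `preprocess()` supports exactly two groups; multi-group designs are out
  of scope.
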