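---
title: "Paired tumor-normal D-type cyclin deregulation: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Paired tumor-normal D-type cyclin deregulation: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cyclinpair)
```

## The statistic

HNSCC tumors both amplify and, less famously, silence cyclin D1, and the
sign of the change is invisible to absolute-expression dichotomization.
With a matched normal mucosa sample per patient, the package works on the
per-patient log2 fold change

$$\mathrm{LFC}(p, g) = x^{\text{tumor}}_{p,g} - x^{\text{normal}}_{p,g},
  \qquad \mathrm{FC} = 2^{\mathrm{LFC}},$$

computed by subtraction on the log2 scale (never by dividing linearized
intensities, which would be sensitive to background offsets). Patients are
classified per gene as **up** (FC > 2), **not** (0.5 < FC < 2) or **down**
(FC < 0.5). The inequalities are strict on both sides; a fold change
sitting exactly on a boundary belongs to neither open set and is absorbed
by the middle class. The thresholds are configurable in every entry point
but default-locked to (2, 0.5), and each report echoes the thresholds that
produced it.

Pairing is validated before any fold change is computed: a patient enters
the paired subcohort only with exactly one tumor and one normal sample;
single-tissue patients are counted and excluded, and two samples of the
same tissue for one patient are a hard error rather than a silent choice.

## Preprocessing

The microarray path assumes background-corrected log2 intensities and
applies, in order: quantile normalization (`limma`, with ties receiving
the mean of the quantile targets they span), technical-replicate
averaging at the probe level, probe-to-gene collapsing by the arithmetic
mean of log2 values (a geometric mean of intensities), and a detection
filter that removes genes whose mean log2 intensity over *all* samples is
strictly below 5 — a gene at exactly 5 is kept, matching the strict
wording of the rule. Averaging over all samples (rather than per analysis
group) was chosen so that the expressed-gene set is a property of the
cohort, not of the contrast.

Batch correction is reduced to an optional per-gene, per-batch mean
centering, off by default: deposited expression sets of this kind arrive
already batch-corrected, and a full empirical-Bayes correction is a
published method outside this package's scope.

The count path (for RNA-seq validation cohorts) computes median-of-ratios
size factors over the genes with a nonzero geometric mean and returns
`log2(count / size_factor + 1)`. This log transform stands in for a full
variance-stabilizing transform; the downstream statistic is a paired fold
change, which at moderate counts is essentially indifferent to the choice
among monotone variance transforms.

## Compensation

For two genes the package cross-tabulates the 3×3 call table and reports
the two reciprocal fractions: among patients with gene A down, the
fraction with gene B up, and vice versa. A zero denominator is reported
as undefined (`NA`), never as 0. The formal test uses the statistic
"number of opposite-direction patients" (A-up∧B-down plus A-down∧B-up),
a null built by permuting B's calls across patients, and the add-one
estimator $p = (1 + \#\{T^* \ge T\})/(1 + n_{\text{perm}})$, which cannot
return 0. The test is one-sided because compensation is a directional
hypothesis; the statistic itself is symmetric in the two directions. When
either gene's calls are constant the statistic is permutation-invariant
and the test degenerates to $p = 1$, with a warning. Patient order does
not affect the p-value: patients are put in a canonical order before the
permutation stream is drawn.

## The co-amplification surrogate

Amplification of the 11q13 locus raises the expression of the amplified
block, not of *CCND1* alone. Lacking copy-number data, the package scores
the fold-change profile of the genes within a fixed flank (default 1 Mb)
of the anchor gene. Window membership is by interval overlap, not
containment, so genes straddling the window edge count. "Downstream"
means higher chromosomal coordinate than the anchor's end, independent of
strand — the amplicon is a DNA-level feature, and the layout of the locus
(with *ANO1* and *CTTN* at higher chr11 positions) motivates reading the
window positionally. Genes failing the intensity filter remain listed but
masked, so the report distinguishes "not upregulated" from "not
measurable".

The per-patient flag — at least `min_genes = 2` expressed downstream
genes with LFC ≥ 1.0 — formalizes a qualitative observation that has no
canonical numeric rule; both knobs are configurable, and counts of
qualifying genes are reported alongside the flag so the rule's
sensitivity is visible rather than hidden.

## Survival analysis

The survival stage delegates the estimators to the `survival` package and
fixes the conventions:

* Kaplan–Meier with Greenwood variance and pointwise 95% CIs on the
  complementary log-log scale, which keeps the interval inside [0, 1];
* five-year survival read off the step function at exactly 60 months
  (flagged when 60 months exceeds follow-up);
* the standard unweighted log-rank test with $df = k - 1$;
* univariate Cox regression with the Efron approximation for ties — ties
  are guaranteed because follow-up is recorded in whole months — a tight
  Newton convergence tolerance (1e-9, up to 50 iterations), Wald CIs
  $\exp(\hat\beta \pm 1.96\,\mathrm{SE})$, and the no-deregulation group
  as the reference level.

Zero follow-up times occur in real recruitment data and are kept: an
event at time 0 is shifted to a tiny epsilon and a censoring at 0 to
twice that, so zero-time events precede zero-time censorings. A group
with no events has a divergent partial likelihood; such cells are flagged
non-estimable and reported as `NA` rather than as an enormous hazard
ratio. Groups smaller than `min_group = 3` patients are summarized
descriptively but excluded from the Cox fit.

The tests check these estimators against independent oracles written from
the definitions: a hand product-limit computation, a hand
observed-minus-expected log-rank, and a brute-force grid search of the
Efron partial likelihood (step 1e-4). One classical identity — the
two-group log-rank equals the squared Cox score statistic at $\beta = 0$
— is exact only for untied data: with ties, the log-rank's hypergeometric
variance carries a multiplicity factor $(n-d)/(n-1)$ that the
partial-likelihood information does not. The identity is therefore
asserted on untied fixtures, while tied fixtures are covered by the other
two oracles.

## The synthetic cohort generator

`simulate_cohort()` emits the statistical structure the analysis assumes,
plus ground truth. Its defaults are the study conditions the package was
designed around, chosen once:

* 82 paired patients, 25/82 HPV-positive;
* anchor-gene class probabilities per HPV stratum of (0.04, 0.44, 0.52)
  for HPV(+) and (0.246, 0.631, 0.123) for HPV(−) over (up, not, down) —
  the observed stratum fractions;
* partner-gene marginal class probabilities (0.317, 0.598, 0.085), and a
  directional coupling: with probability `kappa = 0.35` a class-deregulated
  patient's partner gene takes the *opposite* class. This is the simplest
  generative mechanism reproducing the observed reciprocal pattern, and it
  makes the estimand exact: P(B up | A down) = κ + (1 − κ)·P_B(up);
* tumor shifts N(±1.8, 0.3) in log2 units for deregulated classes. With
  σ = 0.3 the thresholds at ±1 sit 2.7σ from the class means, so ~0.4% of
  draws cross a threshold — truth recovery is near-exact but not trivially
  so;
* a probe model (2 probes per gene, 20% duplicated as technical
  replicates, probe affinities shared between a replicate pair) in which
  the tumor value is the normal value *plus* the drawn shift, so
  measurement noise cancels in the paired fold change by construction;
* 8 window genes per side of the anchor on a synthetic chromosome, 30%
  of them seeded below the detection threshold; downstream genes of
  amplified patients (93% of anchor-up patients) gain `amp_mu = 1.5`;
* 300 background genes, enough that quantile normalization of a simulated
  cohort is near-neutral;
* exponential survival with monthly baseline hazards 0.005 (HPV+) and
  0.02 (HPV−) — five-year survival $e^{-60\lambda}$ of ~74% and ~30%,
  matching the observed stratum prognosis — group log hazard ratios of 0
  by default (deregulation carried no survival signal), and uniform
  censoring on [0, 139] months with times rounded to whole months, which
  produces the tied event times the Efron handling exists for.

Sampling uses separate deterministic sub-streams for truth, layout,
expression and survival, so a change in one component's draw count cannot
reshuffle the others, and the session's RNG state is restored afterwards.

What the generator does *not* emulate: spatial microarray artifacts,
background noise, batch effects (beyond optional additive offsets),
DNA-level copy-number structure, or non-proportional hazards. Passing
recovery tests therefore demonstrates the correctness of the pipeline's
logic under its stated model, not robustness to real-array pathology.

### A note on recovery tests and normalization

Because the simulator's samples are already distribution-comparable,
quantile normalization is statistically a no-op there in expectation —
but with a finite gene list it slightly compresses the extreme tail of
tumor samples whose shifted genes change rank. Classification-recovery
tests therefore classify from the collapsed matrix directly; the
normalization stage remains in the standard pipeline, where it belongs,
for real raw data whose samples genuinely differ in distribution.

## Problem sizes used by the test-suite

The operating-characteristic tests run at: 1000 cohorts of n = 82
(classification recovery, per-class accuracy > 0.99); 500 cohorts of
n = 5000 at κ = 0.35 (compensation recovery, against both the truth-label
expectation within 3 per-cohort binomial SEs and the exact closed-form
expectation of the call-based estimator within 3 SEs of the mean); 2000
replicates of n = 200 per group (log-rank type-I error, 0.05 ± 0.02); 200
replicates of n = 500 (HR = 3 recovery within 20%); 500 replicates of
n = 300 (null CI coverage ≈ 95%). These sizes put the Monte-Carlo error
well below each acceptance band while keeping the default suite around
one to two minutes of simulation time.

## Known limitations

* The expression-based co-amplification surrogate cannot distinguish
  coordinated transcriptional co-regulation from true DNA amplification.
* The count path's `log2(x + 1)` is not a variance-stabilizing transform;
  at very low counts fold changes are compressed toward 0, which biases
  calls toward "not".
* The Cox fit is univariate by design; confounding between HPV status and
  deregulation class is addressed by stratified reporting, not by
  adjustment.
* Wald intervals for the Cox hazard ratio run slightly below the nominal
  95% coverage at moderate event counts — a property of the interval
  rather than of the implementation; the coverage test bounds it with
  that in mind.
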