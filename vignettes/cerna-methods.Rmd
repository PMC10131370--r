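---
title: "Models and design choices in cernaflow"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and design choices in cernaflow}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`cernaflow` implements a tumour/normal ceRNA discovery workflow for paired
bulk RNA-seq counts together with a generator of synthetic datasets with
planted ground truth. This vignette explains the statistical models, the
parameters that matter, and the choices made where the design was genuinely
open. It states no empirical result that the test suite and
`scripts/acceptance.R` do not themselves compute.

## Differential expression without replicates

Each tumour sample is compared only with its own adjacent normal sample.
With one observation per condition, no dispersion is estimable, so the test
fixes the negative-binomial dispersion at `phi = 0.16` (a biological
coefficient of variation of 0.4, the conventional assumption for human
tissue when replicates are unavailable). `phi` is an explicit parameter of
`de_params()`.

**Normalization.** `tmm_factors()` implements trimmed-mean-of-M-values
scaling: reference sample by the 75th-percentile count fraction closest to
the mean, double trimming (30% on log-ratios M, 5% on average intensities
A), inverse approximate-binomial variance weights, factors rescaled to
geometric mean 1. The test suite checks it against an independently coded
step-by-step oracle and against `edgeR::calcNormFactors` (agreement to
machine precision on random matrices); neither stands in for the
implementation.

**The per-pair exact test.** `pair_exact_test()` rescales the two counts to
the common effective library size S (geometric mean of the two effective
sizes, rounded to integers) and conditions on the total T. Under two
independent NB(mu, phi) with equal means, the tumour count given T follows
a symmetric beta-binomial BB(T, 1/phi, 1/phi) — the mean cancels — and the
two-sided p-value sums the probability of all outcomes no more probable
than the observed split. By symmetry and unimodality (1/phi >= 1) this is
`P(X <= m) + P(X >= T - m)` with `m = min(y_t, y_n)`; `phi = 0` reduces to
the conditional binomial(T, 1/2). A zero total gives p = 1 by convention.
The implementation is validated against full enumeration of the conditional
law for every total up to 200.

A consequence worth knowing: for `phi = 0.16` the two-sided 5% critical
split is about 0.76/0.24 regardless of depth (the beta-binomial tends to a
Beta(6.25, 6.25), whose 97.5% quantile is 0.761), so a single pair can only
ever flag per-pair fold changes beyond roughly 1.7–1.8 log2 units. Effects
between the reporting cut-off (|log2FC| > 1) and that detection threshold
are structurally invisible to a fixed-dispersion 1-vs-1 test.

**Consensus across pairs.** "Differential in all groups" is read strictly:
cut-offs (`p <= 0.05`, `|log2FC| > 1`) met in every pair with one
consistent sign. `de_params(consensus = "majority" | "any")` relaxes this.
p-values are raw by default — the paired screen is deliberately permissive
and BH adjustment (`adjust = TRUE`) is off unless requested. Fold changes
are computed on the TMM-normalized CPM scale with a pseudo-count of 0.5 so
zeros stay finite; the consensus log2FC is the arithmetic mean of per-pair
values (the per-feature summary has no canonical definition; the mean is
symmetric and transparent).

## ceRNA triad filters

`assemble_triads()` joins lncRNA–miRNA records with miRNA–mRNA records on
the shared miRNA and audits each candidate in a fixed order, recording the
first failing rule:

1. `not_differential` — all three members must be DE;
2. `single_database_only` — the miRNA–mRNA pair must appear under both
   target-database tags; the retained MRE count is the minimum of the two
   databases' counts (conservative; the sources disagree and neither is
   privileged);
3. `direction_discordant` — lncRNA and mRNA same direction, miRNA opposite;
4. `correlation_below_threshold` — Pearson r of the two log2(CPM+1)
   profiles must strictly exceed 0.8 ("greater than" is read as strict);
   an undefined correlation (zero variance) excludes the candidate with its
   own reason;
5. `mre_below_min` — at least 3 MREs on both edges.

First-failure reporting makes exclusion reasons unambiguous (a
direction-discordant candidate usually also has negative correlation; it is
still reported as discordant), which is what makes the decoy audit in the
tests exact. The correlation is computed across all samples
(tumour + normal) by default: the filter is about co-expression of the
sponge and its target, and the tumour/normal contrast is part of that
signal. `cerna_params(corr_samples = "tumor")` restricts to tumour samples,
where only the latent coupling (not the group separation) can carry the
correlation.

For lncRNA–miRNA records appearing under several source tags the maximum
MRE count is kept (a single miRcode-style source is treated as sufficient
evidence for that edge type).

## The synthetic-data generator

`simulate_dataset()` emulates the study conditions: 6 tumour/normal pairs,
three layers (2000 lncRNA / 300 miRNA / 5000 mRNA), library sizes
0.8–1.2 million, 20 planted triads, 20 decoys per violated filter, and
additional planted DE features per layer (25/40/150).

**Count model.** Relative abundances are log-normal; planted features are
given baselines of 200–1500 CPM (they emulate robustly expressed
transcripts — the ones such screens validate). For each gene and patient a
gamma biological factor with CV^2 = phi is shared between the tumour and
the normal sample of that patient, and counts are Poisson around the
resulting mean. Marginally every sample is NB(phi); within a pair the
tumour/normal ratio carries only Poisson noise. This pairing of the
biological factor is the substantive modelling decision: tissue pairs from
one patient share a biological state, which is exactly why paired designs
are powerful. Had the factors been drawn independently per sample, per-pair
log-ratios would have sd ≈ 0.8 log2 and no effect near the cut-off would
ever replicate across six pairs — the generator's own detectability
contract (planted signs recovered in every pair) would be unsatisfiable.

**Effect sizes.** Extra DE features draw |log2FC| uniformly from [1.5, 6].
Given the ~1.7–1.8 detection threshold above, features below ~2 are not
reliably detectable by construction; the planted range deliberately spans
this transition so sensitivity estimates are honest rather than saturated.
Triad and decoy members draw from [3.5, 6] (`triad_lfc_range`): a surviving
ceRNA triad must clear four filters including r > 0.8, and triads are by
definition the strongly, consistently dysregulated configurations; weaker
triads would fail the DE stage stochastically and make the decoy audit
ambiguous.

**Latent coupling.** Each triad has a per-patient standard-normal factor
z_i; tumour means of its lncRNA and mRNA are multiplied by `2^(0.35 * z_i)`
and the miRNA by the attenuated reciprocal `2^(-0.5 * 0.35 * z_i)`.
The default 0.35 log2 keeps the tumour-only lncRNA–mRNA correlation above
0.8 while leaving per-pair fold changes dominated by the planted effect
(at 0.5 the factor occasionally erased enough detection margin to make a
decoy fail the wrong filter).

**Decoys.** Each decoy violates exactly one filter: MRE decoys carry a
count of 0–2 on one edge (alternating edges); single-database decoys lack
one of the two miRNA–mRNA records; direction decoys flip the mRNA's sign;
`not_differential` decoys null one member's effect (rotating which).
Correlation decoys are the delicate case: with 12 samples the sampling sd
of r is ~1/3 on the Fisher scale, so a decoy whose true correlation were
merely "moderate" would cross 0.8 by chance far too often. They are
therefore built with anti-correlated patient-shared factors — lncRNA
multiplied by `2^(sigma * a_i)` and mRNA by `2^(-sigma * a_i)` in all
samples, with balanced ±1 assignments a_i and
`sigma^2 = lfc_l * lfc_m / 4 + 1` — which makes the true correlation
slightly negative while cancelling exactly within pairs, so DE is
unaffected. Their effect sizes are bounded ([3.5, 4], up-regulated) so the
factors never push counts into the low-count regime.

**What the generator does not emulate.** Real library composition, gene
length and GC effects, count over-dispersion heterogeneity, correlated
background genes, annotation bias, or any sequence-level structure; MRE
counts are labels, not predicted binding sites. Passing recovery tests
shows the pipeline correctly implements its own filters under its stated
noise model — not that the filters find true biology in real tissue.

## qPCR model and diagnostics

`simulate_ct_table()` inverts the `2^(-ddCt)` computation: for planted fold
F, tumour delta-Ct is the normal delta-Ct minus log2(F), and target Ct
values receive Gaussian measurement noise (default sd 0.2 cycles, the only
stochastic term by default). With zero noise folds are recovered exactly
(the test plants a 346-fold lncRNA, echoing the scale of the strongest
validated up-regulation such studies report). An optional per-patient
baseline shift (`ct_patient_sd`, default 0) is available to probe
robustness: it cancels in ddCt but adds correlated cross-sample noise that
degrades ROC separation — useful for sensitivity analyses, off by default.

Per-pair folds are aggregated by geometric mean (folds are ratios; the
geometric mean is unbiased on the log scale and matches the ddCt average).

`loocv_scores()` fits a binomial GLM (logit link) on the log2 relative
expression (`-dCt`; the transform is unstated in common practice, and the
log scale is the one on which qPCR noise is additive), predicting each
held-out sample. Perfect separation in a training fold — common with
strong markers — diverges under maximum likelihood; those folds fall back
to a ridge-stabilized fit (penalty 1e-4 on the slope) and are logged.
`roc_auc()` computes the Mann–Whitney AUC from average ranks (ties 1/2),
which equals the trapezoidal area under the tied ROC curve. The default
diagnostic score is the LOOCV probability; `diagnostic_roc(score =
"expression")` ranks by raw relative expression instead. Note that under
label permutation LOOCV probabilities are slightly anti-predictive (the
held-out sample's class is under-represented in its training fold), a known
cross-validation artefact; null calibration checks therefore use the raw
score.

## Enrichment

`hypergeom_enrich()` is the standard one-sided over-representation test.
The background defaults to the genes carrying at least one annotation in
the term's category — not the whole transcriptome — because unannotatable
genes carry no information about term membership; a custom background may
be supplied, and query genes missing from it raise an error rather than
being dropped silently. BH adjustment is applied within category. Ties in
the top-N report are broken by larger overlap, then term id, making the
report deterministic.

## Orchestration and reproducibility

`run_pipeline()` executes simulate → DE → ceRNA → enrichment → diagnostics,
writes each stage's tables plus a `manifest.json` (seed, configuration,
input digests, per-stage counts in total/up/down form), and aborts with a
stage-named error on any failure. All randomness flows from the single
config seed through a pinned RNG (Mersenne-Twister / Inversion), so a rerun
with the same config is bit-identical — this is asserted by the test suite.
The package deliberately exposes functions rather than a shell interface;
the orchestrator plus `scripts/acceptance.R` cover scripted use.

Problem sizes used by the shipped checks: full study-scale datasets
(7300 features × 12 samples) for recovery runs across multiple seeds, and
reduced configurations (550 features) for unit-level properties; both are
the package's own choice of scale for routine verification.

## Known limitations

* The fixed-dispersion 1-vs-1 exact test cannot detect per-pair effects
  below ~1.7–1.8 log2 units at any sequencing depth; sensitivity claims
  must always be read against that floor.
* The all-pairs consensus is strict: one aberrant patient vetoes a feature.
  The `majority` option trades specificity for robustness.
* Pearson correlation over 12 samples has high sampling variance; the 0.8
  threshold is a coarse instrument, and triads near it will flicker between
  seeds. Exclusion logs make this visible.
* The generator's planted structure is idealized (block-independent genes,
  exact filter violations); it validates implementation, not biology.
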