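---
title: "Methods: PHBR scoring and TMB-stratified outcome analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: PHBR scoring and TMB-stratified outcome analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of its methods: the scoring
model and its assumptions, the parameters that matter, what the synthetic
cohort generator emulates, the numerical choices, and the limitations a
user should keep in mind. Nothing here states an empirical result beyond
what the test suite and `scripts/acceptance.R` themselves compute.

## From variants to peptides

Mutant peptide construction works on transcript coding sequences (CDS)
with 1-based, inclusive coordinates throughout.

* **Translation** uses the standard genetic code, stops at (and excludes)
  the first stop codon, and ignores a trailing partial codon. Ambiguity
  codes and selenocysteine are rejected rather than guessed: a panel
  variant mapped onto an ambiguous CDS signals an upstream problem we do
  not want to paper over.
* **Missense** mutations substitute exactly one residue, after checking
  that the stated reference residue matches the translation — a mismatch
  raises a `reference_mismatch` error, the signature of a stale
  transcript mapping.
* **In-frame indels** edit the nucleotide sequence and re-translate. Any
  edit whose net length change is not a multiple of 3 is rejected as
  `unsupported_variant`, as are frameshift, splice and stop-gain classes
  in the variant table reader: the scoring model is defined for missense
  and in-frame events only, and unsupported rows are counted, reported,
  and set aside rather than silently dropped.
* **Window enumeration** returns every 8–11-mer fully inside the mutant
  protein that covers a mutated position: 8 + 9 + 10 + 11 = 38 windows
  for an interior site with at least 10 flanking residues on each side.
  Near the termini fewer windows exist and all valid ones are returned;
  padding would fabricate sequence, so none is applied. The closed form
  `min(p, N-L+1) - max(1, p-L+1) + 1` per length L is verified
  exhaustively in the tests for all protein lengths up to 30.
* **Novelty for indels.** The mutated span is located by stripping the
  longest common prefix and suffix between wild-type and mutant protein;
  candidate windows covering that span are kept only if their sequence
  does not occur anywhere in the same transcript's wild-type protein.
  Proteome-wide uniqueness is deliberately out of scope — "novel" is a
  per-transcript notion here, and the choice is flagged because windows
  merely required to be novel (rather than to overlap the edit) would
  differ only through that filter. Missense windows are retained without
  the novelty filter, since they cover the substituted residue by
  construction.

## PHBR

For one mutation and one patient, each of the six HLA class-I genotype
slots takes its **best rank**: the minimum predictor rank percentile over
the mutation's unique peptide sequences (duplicated sequences at
different starts are scored once). The six best ranks are aggregated by
harmonic mean:

$$\mathrm{PHBR} = \frac{6}{\sum_{i=1}^{6} 1/\mathrm{BR}_i}$$

The harmonic mean is dominated by its smallest term, encoding the
biological reading that a single well-presented window suffices.
Consequences that the tests pin down as invariants: PHBR lies between
`min(BR)` and `max(BR)`, is bounded by `6 * min(BR)`, and decreasing any
single best rank can only decrease it.

**Homozygosity.** Homozygous loci occupy two slots and count twice —
six slots always. A patient homozygous at every locus therefore has the
PHBR of the three-locus genotype; the aggregation does not reward
homozygosity, it simply does not model allele diversity beyond the six
slots. This convention is assumed rather than derivable from first
principles, and is stated here because the alternative (collapsing
duplicated alleles) changes scores for homozygotes.

**Patient summary.** The patient's score is the *minimum* PHBR across
scored mutations — neoantigen quality over quantity. Ties take the first
mutation in input order (documented, deterministic). Patients with no
scoreable missense mutation are not evaluable and are excluded upstream,
because a minimum over an empty set is meaningless, not zero.

**Thresholds.** PHBR is dichotomized at 0.5 by default (configurable):
`< 0.5` strong presentation, `>= 0.5` poor presentation, matching the
conventional strong-binder rank threshold. Rank percentiles below 2 are
labelled weak binders and below 0.5 strong binders in reporting.

**Rank floor.** Oracle ranks are clamped to `>= 1e-6` before reciprocals
are taken, so a pathological rank table containing a zero (or denormal)
rank cannot blow up the harmonic mean. The floor is far below any rank a
real predictor emits and never binds in normal use.

## The rank oracle contract

The binding predictor is deliberately *not* part of the package. Anything
mapping (allele, peptide) to a percentile rank in (0, 100] can stand
behind the `rank_oracle` contract:

* `load_rank_table()` adapts a normalized three-column table
  (`allele`, `peptide`, `rank_percentile`). Native predictor output
  formats are version-dependent and are not parsed; ambiguous duplicate
  pairs are rejected, absent pairs raise `missing_prediction` instead of
  returning a default.
* `synthetic_rank_oracle(seed, strong_binder_fraction)` is a
  deterministic stand-in: an FNV-1a hash of (seed, allele, peptide) is
  mapped so that a configurable fraction of pairs rank below 0.5 and the
  rest spread uniformly over [0.5, 100]. Determinism makes every
  downstream result reproducible without storing predictions.

## TMB and strata

TMB is the panel mutation count divided by the interrogated footprint
(default 1.2 Mb), with drivers and germline polymorphisms excluded by the
caller. Dichotomization uses `>=` on the high side at 10, 20 or 50
mutations/Mb; **missing TMB goes to the low class** (the conservative
assignment for a biomarker whose high class predicts benefit). The 0.001
pseudocount is applied only to continuous analyses (correlations,
log-scale regressions) — never before threshold dichotomization, and it
does not impute missingness. The joint TMB × PHBR label gives the four
strata driving the stratified analyses; overall benefit is CR/PR or
stable disease lasting at least six months, with ongoing stable disease
short of six months excluded from the denominator.

## Statistics layer

* **Risk ratio**: `(a/(a+b)) / (c/(c+d))` with the Wald log-scale CI
  `exp(log RR ± z·sqrt(1/a − 1/(a+b) + 1/c − 1/(c+d)))`, no continuity
  correction. A zero numerator cell is an error, not a silent adjustment.
* **Fisher exact** (`stats::fisher.test`), two-sided by summation of
  hypergeometric probabilities; verified against exhaustive enumeration
  in the tests.
* **Kaplan-Meier / log-rank / Cox** via the `survival` package. The
  median is the smallest time with S(t) ≤ 0.5; when not reached, median
  follow-up is reported via the reverse Kaplan-Meier (event flags
  flipped). Cox models use **Efron's** tie handling — the data are in
  months with frequent ties, and Efron is the better approximation (the
  choice is a package decision; nothing in the contract depends on it).
  Stratified Cox gives each stratum its own baseline hazard, which is
  exactly the right tool for "the PHBR effect within TMB classes":
  proportionality is assumed for PHBR within stratum but never across
  strata. Two-group hazard ratios accompanying log-rank tests come from
  unadjusted Cox fits (a univariable-Cox convention; Mantel-Haenszel
  variants would differ slightly).
* **Backward-AIC logistic selection**: single-term removals, accepting
  the best removal whenever it does not increase the AIC, until no
  acceptable removal remains; forced terms (TMB, then PHBR) are then
  added sequentially with the AIC recorded at each step and the AUROC of
  every model. The retention rule as usually phrased ("keep what helps")
  is ambiguous about ties and direction; this package implements the
  standard minimize-AIC backward elimination, treating "does not
  increase" as `<=` so an exactly AIC-neutral removal simplifies the
  model. Complete or quasi-complete separation is flagged with a warning
  and the model still reported.
* **AUROC** is the midrank Mann-Whitney statistic — ties counted half —
  computed directly from ranks, and verified against exhaustive pair
  counting.
* **Spearman** uses midranks with the t-approximation p value (exact
  enumeration is unavailable under ties); **Mann-Whitney** defers to
  `stats::wilcox.test` (exact for small untied samples).
* Significance is read at 0.05, univariable-to-multivariable inclusion
  at 0.10; both are conventions, both configurable at call sites. No
  multiple-testing correction is applied anywhere — by design, matching
  the descriptive character of the stratified analyses.

## The synthetic cohort generator

`generate_cohort()` emulates the statistical structure the analysis
assumes, not the biology of any real cohort:

* **HLA genotypes**: two draws per locus from a small allele pool, with
  per-locus homozygosity probability (defaults 0.15/0.10/0.15). Pool
  frequencies are plausible but not population-realistic — a stated
  non-goal.
* **TMB**: latent log-normal (meanlog 2.3, sdlog 1.6 mutations/Mb),
  chosen once so that roughly half of measured patients sit at or above
  10 mutations/Mb and about one in six at or above 50, with a 6/83
  missingness rate. The panel count is Poisson(TMB × 1.2 Mb) and the
  reported TMB is count/1.2, so the generator and the estimator agree by
  construction.
* **Mutations**: each patient's panel count is emitted, but only a small
  subset (one guaranteed missense plus Poisson(2) further scoreable
  events, ~5% of them in-frame indels) maps to peptides; the remainder
  are frameshift/splice/synonymous rows that exercise the exclusion
  accounting. This keeps the rank table at desk scale while the TMB
  arithmetic still sees the full count. A zero-count patient has no
  missense mutation and is excluded, mirroring the cohort rule; the
  generator redraws until the configured number of patients is retained.
* **PHBR classes**: each patient is latently assigned min-PHBR < 0.5
  with probability `phbr_low_prevalence` (default 32/83). The emitted
  rank table realises the class: for a low patient, one mutation
  receives a strong rank (uniform 0.1–0.45) under each genotype allele;
  every other pair ranks at or above 0.5, which caps the harmonic mean
  at or above 0.5. Scoring the emitted inputs end-to-end therefore
  reproduces the latent classes exactly, up to the (rare, untreated)
  possibility of two patients sharing an identical mutant peptide.
* **Outcomes**: benefit is Bernoulli per stratum (defaults 0.18, 0.33,
  0.78, 0.43 across the four strata), progression and survival times are
  exponential with per-stratum medians (4.2, 3.5, 26.8, 5.8 and 12.0,
  10.1, 40.0, 17.2 months; the best stratum's overall-survival median is
  a choice, since "not reached" has no median to copy), and censoring is
  administrative, uniform on 12–36 months. Benefit and survival are
  coupled through the stratum only.
* **RNG**: one R stream per generator call, seeded from the config;
  byte-identical outputs per seed are tested. Per-patient sub-streams
  were considered and dropped — the package has no parallel path, and a
  single stream keeps the generator auditable.

Because PHBR class and TMB are drawn independently, the generator does
*not* emulate the positive TMB–presentation correlation real cohorts
show, nor tumor-type-specific mutation spectra, panel artefacts, or
informative censoring. Passing tests therefore demonstrate that the
*machinery* is correct and calibrated — not that real-data effect sizes
are recoverable from synthetic data.

A faster path, `simulate_stratified_survival()`, skips the molecular
layer entirely and draws stratum labels and exponential times with a
configurable within-stratum hazard ratio. The acceptance checks use it
at n = 500 over 200 replicates to show that the stratified Cox interval
covers a true hazard ratio of 0.39 at its nominal rate, and over 500
null replicates (n = 120) to show the log-rank test holds its 5% size.
These problem sizes keep the whole suite to a couple of minutes on one
CPU while leaving the Monte-Carlo error comfortably inside the asserted
bounds.

## Degenerate inputs and error taxonomy

Errors are classed conditions, not message strings: `invalid_sequence`,
`reference_mismatch`, `unsupported_variant`, `arity_error`,
`domain_error`, `empty_input`, `missing_prediction`, `parse_error`,
`schema_error`, `row_error`, `conflict_error`, `config_error`,
`undefined_estimate`, `degenerate_model`, `patient_not_evaluable`.
Contracts worth restating: a Cox fit with no events is degenerate rather
than silently infinite; an AUROC with one class is undefined; a constant
vector has no Spearman correlation; a genotype has exactly six slots;
a rank oracle never returns a non-positive rank.

## Known limitations

* The substring-novelty rule for indel peptides is per-transcript; a
  peptide novel here may occur elsewhere in the proteome.
* The driver/passenger distinction for "which missense mutations are
  scored" is left to the caller (every scoreable panel missense is
  eligible by default; an allowlist can be applied upstream).
* Median survival arithmetic reports `NA` for "not reached"; downstream
  tables carry median follow-up alongside, but comparisons of
  not-reached medians remain qualitative.
* The synthetic generator's independence assumptions (above) bound what
  any simulation-based check can claim about real cohorts; cohort-scale
  summary statistics from real patient-level data (medians, correlation
  coefficients, AUROCs) are outside what this repository can recompute.
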