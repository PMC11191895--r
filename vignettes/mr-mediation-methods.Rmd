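---
title: "Methods: two-sample MR mediation analysis with mrmediate"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: two-sample MR mediation analysis with mrmediate}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mrmediate)
```

## The question and the causal model

`mrmediate` addresses exposure–mediator–outcome questions with GWAS summary
statistics only: for instance, whether a gut microbial genus alters the risk
of Crohn disease or ulcerative colitis, and what share of that effect is
transmitted through a circulating inflammatory protein.  The structural
model has three paths: exposure → mediator (β1), mediator → outcome adjusted
for the exposure (β4), and exposure → outcome adjusted for the mediator
(β5).  The indirect effect is β1·β4, the total effect β1·β4 + β5, and the
proportion mediated their ratio.

All estimators rest on the three instrumental-variable assumptions: each
instrument is associated with its exposure (relevance), shares no common
cause with the outcome (exchangeability), and affects the outcome only
through the exposure (exclusion).  The sensitivity estimators and MR-PRESSO
exist because exclusion fails in practice (horizontal pleiotropy); the
synthetic generator plants such violations deliberately.

## Pipeline structure

Phase 1 screens every exposure–outcome and mediator–outcome pair:
instrument selection, harmonization, IVW (with the heterogeneity-driven
fixed/random rule), MR-Egger and weighted median as sensitivity analyses,
MR-PRESSO, and a replication meta-analysis over at least two outcome
datasets.  A pair survives only if the IVW estimate is nominally
significant, the three estimators agree in direction, the MR-PRESSO global
test finds no pleiotropy, and the pooled replication estimate is
significant; the audit trail names the first failing rule for every
excluded pair.  MR-PRESSO runs per dataset, before pooling, so the
meta-analysis only ever combines estimates that passed (or were corrected
by) the outlier stage; when outliers are flagged, the outlier-corrected IVW
estimate feeds the screen.  Phase 2 takes the surviving
exposure–mediator–outcome triples whose exposure→mediator link is itself
significant, builds a joint instrument set, runs MVMR, and decomposes the
mediation.

Screening uses nominal p-values without multiple-testing correction.  That
mirrors discovery practice in this workflow and is a deliberate,
documented choice, not a statistical endorsement: with 131 genera and 91
proteins a nominal 0.05 screen passes false positives, which is why the
replication meta-analysis and the direction-agreement rule are part of the
conjunction.

## Parameters that matter

| Parameter | Default | Why |
|---|---|---|
| exposure p-threshold | 1e-5 | conventional relaxed threshold for microbiome GWAS, where genome-wide hits are scarce |
| mediator p-threshold | 5e-6 | typical for protein QTL instruments |
| clump window | ±10,000 kb | effectively whole-arm independence for retained instruments |
| clump r² | 0.001 | near-zero correlation between instruments, as IVW assumes |
| F minimum | 10 | the conventional weak-instrument boundary; weak instruments are excluded, not merely flagged, because every downstream estimator assumes relevance |
| palindrome ambiguity window | eaf ∈ [0.42, 0.58] | frequencies this close to 0.5 cannot identify the strand; the bound matches widespread MR tooling practice and is configurable |
| screening α | 0.05 | nominal, see above |
| weighted-median bootstrap | 1,000 draws, mandatory seed | reproducibility of the only resampling-based SE |
| MR-PRESSO simulations | 1,000 | resolves the Bonferroni-corrected outlier threshold (0.05/k) with room to spare; add-one correction keeps all Monte-Carlo p-values positive |

The per-SNP F statistic defaults to (β/se)², computable without sample size
or trait variance and asymptotically equivalent to the classical form; an
n-based variant is available when `n` and `eaf` are present.

## Numerical and procedural choices

- **Wald ratio SE** is first-order (se_y/|β_x|) by default; the
  second-order delta expansion is available.  Exposure-side uncertainty
  otherwise enters through the sensitivity estimators.
- **Random-effects IVW** is multiplicative (SE inflation by √(Q/(k−1)),
  floored at 1) rather than additive-τ², matching the dominant two-sample
  MR convention and the binary "heterogeneity → random effects" rule.
- **P-values**: standard normal for IVW, weighted median and MVMR; t on
  k−2 df for the Egger slope and intercept.  The Egger overdispersion
  factor max(1, √(RSS_w/(k−2))) makes the intercept test mildly
  conservative (measured empirical level ≈ 0.04 at k = 30, inside the
  0.03–0.07 calibration band the tests enforce).
- **Clumping** is greedy by ascending p-value with lexicographic snp_id
  tie-breaks, so results are deterministic and input-order invariant.
  Pairs beyond the window or absent from the LD reference count as r² = 0.
- **Harmonization** is a normal form: harmonizing an already-harmonized
  set changes nothing, and flipping every outcome record's allele labels
  beforehand changes nothing either.  Records missing eaf are dropped only
  when palindromic (where the ambiguity is real).  SNPs missing from any
  study are dropped; LD-proxy substitution is out of scope.
- **Joint MVMR instruments** are the union of the two per-trait selections,
  re-clumped jointly (ranking by the smaller of the two p-values) to
  prevent double-counting LD, then re-extracted from the full summary
  statistics.  The MVMR regression has no intercept, mirroring IVW through
  the origin.  An all-zero effect column is reported as NA and the fit
  reduces to the nested model.  Conditional F diagnostics are reported but
  never used as a filter.
- **MR-PRESSO** follows the leave-one-out formulation: observed RSS uses
  the leave-one-out IVW prediction per SNP; the null distribution redraws
  both effect columns from their sampling distributions and recomputes
  leave-one-out estimates on each simulated dataset.  The distortion
  p-value compares the observed raw-vs-corrected IVW difference with the
  same difference across the simulated (pleiotropy-free) datasets.  Exact
  replication of any external implementation's RNG stream is a non-goal.
- **Meta-analysis** delegates to `metafor::rma.uni` (FE, or
  DerSimonian–Laird when the cross-study Q p-value is below 0.05); the DL
  formulas are retained as an independent oracle in the test suite.
- **Mediation establishment** requires sign agreement of indirect and
  total effects plus significance of the mediator-path links β1 and β4
  only.  The direct path's significance is deliberately not gated on:
  complete mediation (a null direct effect) is not evidence against
  mediation.  Proportions print with one decimal below 10% and as integer
  percent otherwise; the raw fraction is always stored, and the unrounded
  computation path is canonical.

## The synthetic generator

`synthetic_scenario()` draws per-SNP true exposure effects γ_j ~ N(0,
gamma_sd) for the instrument subset, mediator effects θ1·γ_j + κ_j (κ_j
the mediator's own pQTL-like instruments, disjoint from the exposure's),
and outcome effects (θ5 + θ4·θ1)·γ_j + θ4·κ_j + δ_j, with δ_j planted
pleiotropy — balanced N(0, sd) or directional half-normal.  Observed
effects add normal sampling noise at the configured per-study SEs; p-values
are two-sided normal (floored at 1e-300 so extreme associations stay
representable).  Alleles, shared frequencies, LD blocks with a common
within-block r², palindromic SNPs (drawn with decisive frequencies), and
single-SNP outcome outliers (shifted by 10 outcome SEs, planted on the
strongest instrument so they are influential as well as detectable) are all
generated from one seed through fixed per-component sub-streams, so adding
a table never shifts another table's draws.

Default study conditions: 30–150 SNPs per scenario, sampling SEs of
0.005–0.03 (GWAS-scale for cohorts of 15,000–25,000), binary-outcome
effects on the log-odds scale so OR = exp(β).  The mediation-recovery
scenarios use gamma_sd = kappa_sd ≈ 0.1 with se = 0.005 on the exposure
and mediator sides — a strong-instrument regime (mean F in the hundreds,
as real pQTLs often show).  That choice is what makes multivariable MR
recoverable without material regression-dilution bias; with weaker
instruments the mediator column's measurement error attenuates β4 and
inflates β5, a known MVMR phenomenon the package measures but does not
correct.

One interaction deserves note.  When the exposure→mediator path is very
strong (the `strong_mediation` scenario, θ1 = 0.5), exposure instruments
cross-select into the mediator's own instrument set, and their Wald ratios
against the outcome differ systematically from the pQTL instruments' —
horizontal pleiotropy from the mediator's univariable standpoint.  The
phase-1 MR-PRESSO screen then correctly rejects the mediator trait.  This
is a designed property of the screen, not a defect: the end-to-end pipeline
test therefore uses the `weak_mediation` scenario (θ1 = −0.11, per-SNP
exposure effects small enough that the mediator's instruments stay clean),
which is also the regime the applied workflow operates in, while the
strong-mediation recovery checks estimate β1, β4 and β5 directly.

What the generator does *not* emulate: microbiome compositionality, sample
overlap between studies, winner's curse in instrument selection, fine-scale
LD, and population stratification.  Passing tests therefore demonstrate
correctness of the estimators and pipeline logic under the stated model,
not robustness to those real-data complications.

## Validation scales

The acceptance checks run at desk scale on one CPU: 2,000 replicates of the
30-instrument null scenario for type-I-error and Cochran-Q calibration
(IVW and Egger-intercept levels within [0.03, 0.07], mean Q within 5% of
k−1); 500 replicates of the strong-mediation scenario (mean estimated
proportion and MVMR paths within two Monte-Carlo SEs of truth); 100 seeded
MR-PRESSO runs with a planted outlier (≥95% flagged, ≥90% improved by
correction); exact agreement with brute-force oracles for IVW, Egger, the
weighted median, clumping and the screening rules; and exact reproduction
of the worked mediation decompositions.  The whole suite completes in about
half a minute.

## Known limitations

- No reverse-direction MR, Steiger filtering, or LD-proxy lookup.
- No MVMR-Egger or weak-instrument-robust MVMR; conditional F is a
  diagnostic only.
- The proportion-mediated CI is a delta-method extension assuming
  independent inputs and should be read as indicative.
- β2 (mediator → outcome, univariable) and β3 (exposure → outcome,
  univariable) are computed and reported for context but do not enter the
  decomposition, whose inputs are β1, β4 and β5.
- Screening uses nominal significance by design; interpret candidate lists
  as hypotheses for replication, not discoveries.
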