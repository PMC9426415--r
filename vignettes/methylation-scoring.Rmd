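---
title: "Cumulative methylation scoring: model, calibration and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cumulative methylation scoring: model, calibration and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cmscore)
```

## The measurement and the score

The assay measures methylation-specific qPCR cycle thresholds (Ct) for
nine target genes and the *ACTB* reference, with one converted sample
split equally across two detection cartridges (four targets plus ACTB
in cartridge A, five plus ACTB in cartridge B). Ct is on a log2 scale
of template abundance: one cycle less means roughly twice as many
amplifiable copies. Reactions that never cross the detection threshold
are assigned the sentinel Ct = 45 — both a flag and a number, so
downstream arithmetic never branches on missingness.

The cumulative methylation score is built in four steps (functions
`delta_ct()`, `compute_gene_shifts()`, `censor_low_signal()`,
`gene_methylation()`, composed by `score_batch()`):

1. ΔCt = Ct(gene) − Ct(ACTB, same cartridge) normalizes each target to
   the total cfDNA input of its own reaction.
2. Signals beyond the gene's censoring bound — the historical replicate
   median ΔCt at 300 spiked copies of fully methylated DNA, plus 13 ΔCt
   units — are set to ΔCt = 0. On the log2 scale 13 cycles below 300
   copies is 300 × 2⁻¹³ ≈ 0.037 copies, i.e. less than a twenty-fifth
   of a molecule: anything out there is noise, not quantitation.
3. M = 1200/ΔCt maps the (shifted, censored) ΔCt to a methylation value
   that grows with abundance and stretches the dynamic range; censored
   genes contribute M = 0 (the 0 sentinel is "removed from analysis",
   not a divide-by-zero).
4. CM sums M over the nine genes.

Assumptions worth stating: PCR efficiency is treated as ideal (one
cycle per doubling) throughout, including in the copy interpretation of
the censoring bound; the ACTB reference is assumed quantifiable in both
cartridges (if it is not, the sample is invalidated rather than
partially scored, because CM is defined over all nine genes); and all
Ct arithmetic is double precision, with rounding applied only at
serialization (Ct and CM to 4 decimals in machine outputs, display to
1).

### The batch shift

If any sample in an analysis batch shows ΔCt below 1 for a gene, every
sample is shifted for that gene by the smallest nonnegative integer
reaching 1, and the *same* integer is added to that gene's calibration
median before the censoring comparison. Anchoring at 1 (not merely
above 0) bounds M at 1200 per gene and prevents explosive values from
near-zero ΔCt. Mirroring the shift into the median makes the censoring
decision provably identical on the raw and shifted scales — the
property-based tests assert this on random batches. The shift is a
batch-level quantity: scoring a sample alone may shift differently than
scoring it inside a cohort, which is why the score report records the
shifts applied.

### Tunable constants

| constant | default | units | meaning |
|---|---|---|---|
| `no_signal_ct` | 45 | cycles | sentinel for undetected reactions |
| `censor_offset` | 13 | ΔCt units | censoring bound above the 300-copy median |
| `m_scale` | 1200 | — | numerator of the M transform |
| `cm_threshold` | 38.5 | CM units | locked positivity cutoff (strict >) |

All four live in `algorithm_constants()` and in the YAML/JSON
configuration document, whose shipped default reproduces the assay
exactly. The positivity call is strict (`CM > 38.5`); published tables
for assays of this type state the rule both as ">" and as "≥" in
different places, and we resolve the ambiguity toward the strict
reading — the two differ only for scores exactly at the boundary, a
measure-zero event for a continuous score.

## Evaluation layer

* **Group comparison** — Mann–Whitney with average ranks. The p-value
  is exact by enumeration when the pooled size is ≤ 12 with no ties
  (delegated to `stats::wilcox.test`, whose exact path enumerates the
  null U distribution), otherwise the normal approximation with tie and
  continuity corrections. The boundary is fixed and tested on both
  sides. Fully tied data returns p = 1.
* **ROC** — candidate thresholds at midpoints between consecutive
  distinct scores plus ±∞; AUC by pair counting with ties worth ½,
  which the tests verify equals both a brute-force pair enumeration and
  U/(n₁n₂); the reported threshold maximizes Youden's sensitivity +
  specificity with ties broken toward higher specificity (when several
  thresholds are equivalent, prefer the one that keeps controls
  negative). The AUC interval is DeLong's, via `pROC::ci.auc` — the
  field-standard implementation rather than a reimplementation.
* **Confusion metrics** — sensitivity, specificity and accuracy carry
  Wilson score intervals (`prop.test` without continuity correction);
  Wilson was chosen as the closest standard method to the proprietary
  hybrid intervals of common GraphPad workflows, and its oscillating
  exact coverage is checked against binomial enumeration in the tests.
  LR+ = sensitivity/(1 − specificity) is flagged undefined at
  specificity 1 rather than reported as infinite.
* **Concordance** — Spearman rank correlation with average ranks and
  the t-approximation p-value, for duplicate-user and cross-platform
  comparisons.
* **Trajectories** — serial draws are sorted by day, anchored at the
  earliest (baseline) draw, and intervals labelled rise/fall/flat with
  a flatness tolerance defaulting to 5 CM units. No formal
  progression rule exists for this score, so the labels are
  descriptive, and the tolerance is configurable.

## The synthetic data generator

Patient-level datasets behind assays of this kind are not publicly
shareable, so the generator produces Ct tables with the statistical
structure the analyses assume, and every experiment in the package runs
from code alone.

**Measurement model** (`noise_model()`, `simulate_ct()`): molecules
enter a Poisson detection layer, `k ~ Poisson(expected copies)`; zero
molecules emit the no-signal sentinel; detected reactions return
`Ct = alpha_g − log2(k) + Normal(0, ct_sd)`. The per-gene intercepts
`alpha_g` (Ct of one effective copy, fixed in 35.6–36.4 cycles, ACTB
36.0) fold the assay's 20-cycle preamplification into a single
constant, since only the final Ct matters downstream. There is no
amplification-efficiency parameter: the one-cycle-per-doubling ideal is
the simplest model consistent with the censoring bound's own copy
arithmetic. Splitting the converted sample across two cartridges halves
the effective copies of every measurement.

**Replicate structure**: each run carries a bounded sample-level
recovery effect, uniform on ±`recovery_halfwidth` cycles, applied to
the target genes' Poisson means — run-to-run variation in spike
recovery and bisulfite conversion, which does not touch the endogenous
ACTB input. Spike-in replicate *series* additionally carry a bounded
systematic drift (`drift_span`): replicate experiments are run
sequentially over days, and reagent ageing and run-order effects
produce a slow trend, modeled as a linear ramp across the series.

**Calibration of the noise defaults.** The published quality-control
envelope for this assay family reports replicate CM coefficients of
variation of 7.1–10.9% in plasma and 19.0–36.1% in serum. The matrix
defaults were tuned once against those bands: plasma
(`ct_sd` 0.05, `recovery_halfwidth` 0.15, `drift_span` 0.80 cycles)
centres the CV of an 11-replicate 300-copy batch near 8.8%, serum
(`ct_sd` 0.20, `recovery_halfwidth` 0.40, `drift_span` 2.80) near 24%,
with the large serum/plasma gap reflecting serum's poorer handling
properties. Serum also carries a higher background cfDNA input
(`actb_copies` 6000 vs 3000 per reaction), as expected from clotting
lysis. These are tuning targets for the generator's realism, not
mechanistic claims.

**Cohorts** (`cohort_design()`, `simulate_cohort()`): cancer samples
draw per-gene methylated copies from a lognormal
(meanlog log 300, sdlog 1.2) for a per-sample Binomial(9, 0.17) subset
of active genes; all samples carry a small stray-copy background
(0.02 copies/gene). The defaults were set a priori from the published
operating point of the test cohort: P(no active gene) ≈ 0.17 matches
83% sensitivity, P(any stray copy) ≈ 8.5% matches 92% specificity.
ACTB Ct is drawn uniformly within the printed class ranges (cancer
16.0–27.8, controls 21.0–27.4 cycles — only ranges, not distributions,
are published), with a small per-cartridge jitter for the shared
sample; a consequence the generator reproduces is that heavily shedding
patients with very low ACTB Ct have their ctDNA signal *diluted* by the
normalization. Benign and healthy-normal controls share one generative
model; whether benign disease carries low-level methylation of its own
is not quantified in the source material, so it is a knob
(`background_rate`), not an assertion.

**Duplicate users** (`simulate_interuser()`): the duplicate aliquot is
re-measured from the latent truth with additional user-level Ct noise;
the Poisson layer is redrawn by default (no-signal status can flip),
or held fixed to verify that zero user noise reproduces the first
user's table exactly.

**Longitudinal series** (`simulate_longitudinal()`): a latent
tumor-burden trajectory (exponential decay for response; decay to a
nadir then regrowth for progression; constant for stable disease)
drives per-gene copies through a fixed per-patient active-gene profile,
with draws at baseline and every 21-day cycle.

**What the generator does not emulate** — and hence what passing tests
do not show about real data: bisulfite-conversion chemistry and its
sequence-dependent failure modes, cfDNA fragment-length effects, primer
competition and fluorophore crosstalk in the multiplex, inter-lot
calibration drift, and any epidemiological structure (age, subtype,
treatment history) behind the class labels. Tests against generated
cohorts validate the *arithmetic and statistical machinery*, not
clinical performance.

## A designed-AUC profile for statistical checks

The clinically realistic cohort default is zero-inflated: most controls
have CM exactly 0, as real control cohorts do. Zero-inflation is the
right default, but it degrades interval calibration experiments — with
all controls tied at zero, the DeLong variance collapses to a
Wald-binomial form with poor small-sample coverage. For
parameter-recovery experiments the package therefore ships
`cohort_design_auc(auc)`: every sample of both classes carries signal
in all nine genes (elevated control background), making CM continuous
in both classes, and the class separation is set from the binormal
relation delta = qnorm(auc)·√2·σ_eff with σ_eff = 0.806 calibrated
once against a 16,000-sample simulation (anchored at AUC 0.90, where
the large-sample check reproduces 0.899).

One honest limitation surfaced by this experiment: at the test-cohort
shape (40 cases, 26 controls) and a true AUC of 0.90, DeLong 95%
intervals cover the design value in about 91% of replicates — and an
ideal binormal oracle pushed through the same interval machinery covers
about 92%. DeLong is rank-based, so no score distribution does better;
the shortfall is the method's known finite-sample behavior near high
AUCs, not an implementation artifact. The acceptance test records both
numbers side by side; the strict nominal-coverage expectation is left
failing by design rather than widened to fit.

## Problem sizes and numerical choices in the shipped checks

The test suite and the acceptance script size their simulations as the
package's own trade-off between statistical resolution and turnaround:
60–100 spike batches of 11 replicates for the CV bands, 25 cohorts of
66 samples for operating characteristics, 500 replicates for coverage
and null-AUC experiments, 2,000 draws for the null rejection rate
(whose exact size at n = 20+20, 0.0491, is enumerated from the exact U
distribution and used as the oracle), and 5 seeds for dose-response
ordering. Seeds are mandatory arguments throughout the generator — a
missing seed is an error, never a silent clock seed — and every
simulation is a pure function of (design, seed).

## Known limitations

* CM is reported unrounded internally but is only meaningful to about
  one decimal; differences far below the replicate CV should never be
  interpreted.
* The batch shift makes scores batch-dependent when negative ΔCt occurs
  (rare in practice); pipelines comparing across batches should lock a
  calibration and shift policy first.
* Calibration tables are keyed by matrix (plasma/serum) but a single
  default is shipped; whether historical medians should be
  matrix-specific is an open question in the source material.
* The instrument's distinction between "no amplification" and
  "indeterminate late amplification" is not modeled; both map to the
  no-signal sentinel.
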