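---
title: "Methods: gating strategy, positivity indices and the synthetic cohort"
author: "myeloFlow"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: gating strategy, positivity indices and the synthetic cohort}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(myeloFlow)
```

## The measurement problem

The Ki-67 positive fraction of a bone-marrow cell population (its
*proliferation index*) and the Bcl-2 positive fraction (its
*anti-apoptotic index*) are informative markers in myelodysplastic
syndrome (MDS) and acute myeloid leukemia (AML), but they are only as
reproducible as the gates that define (a) the cell populations and (b)
"positive". Both gates are traditionally placed by hand. This package
implements a deterministic, parameterized surrogate of that manual
procedure so the whole measurement chain — event file, compensation,
hierarchical gating, positivity strategy, QC, cohort statistics — can be
exercised, audited, and validated against simulated ground truth.

Four positivity strategies are compared throughout:

* **polygon** — control-anchored adaptive boundary: the population's SSC
  range is split into 8 equal-count bins and the cutoff in each bin is
  the 99.5th percentile of the control distribution in that bin, closed
  into a simple polygon. This reproduces, deterministically, what a
  manually drawn polygon achieves: following the negative cloud across
  SSC. The exact vertex placement of a human operator is unknowable, so
  a per-bin percentile is the package's design choice; with a flat
  control it reduces exactly to the rectangle gate.
* **rectangle** — the global 99.5th control percentile × the full SSC
  range.
* **fixed40 / fixed100** — predefined thresholds at exactly 40 and 100
  fluorescence units (FU), ignoring controls.

Controls are either the IgG1 isotype channels (preferred after tube
merging, because merging injects imputation noise) or the
marker-negative population as an internal biological control. For
isotype controls after merging, events jointly high on *both* isotype
channels are excluded before the percentile is taken: these are
autofluorescent (chiefly eosinophil-derived) events that a human
operator would likewise keep the gate below, and after nearest-neighbour
imputation their values can otherwise leak into any population's
control.

## The intensity scale

The instrument scale on which "40 FU" lives is not part of the package's
inputs, so the package fixes a documented calibration: intensities are
stored and gated on a linear FU scale on which unstained/negative clouds
centre at roughly 10–30 FU and bright positives at 200–1000 FU. On this
scale the fixed thresholds are meaningful: 40 FU sits in the upper tail
of a typical negative cloud (so it approximates an average manual
threshold), and 100 FU only admits strongly positive cells. All gating
constants (`gatingConfig()`) are expressed in these units.

## Gating surrogates for manual steps

* **Density valleys.** Wherever the manual procedure separates
  negative/dim/bright clouds by eye, the package uses the minimum of a
  kernel-smoothed density (Silverman's rule-of-thumb bandwidth, on a
  log10(x+1) axis) between the two dominant modes. The CD45 dim band is
  bounded by the valley above the negative mode and the valley below
  the bright mode; fixed fallback bounds (45–550 FU on the calibrated
  scale) take over when a sample lacks one of the clouds — e.g. an
  AML marrow with almost no CD45-negative events. A unimodal marker
  distribution falls back to a robust fence (median + 3.5·MAD on the
  log scale), which is how rare-positive markers such as CD34 in
  non-malignant marrow are thresholded.
* **Doublets.** The singlet band is the integral/peak scatter ratio
  within median ± 3·MAD; doublets (ratio ≈ 2) fall far outside.
* **Relevant events** are all events above the FSC debris valley —
  doublets and erythroid cells retained — matching the acquisition-count
  definition used for QC (minimum 100,000; ideally 500,000).
* **Eosinophils** are excluded from the myeloid gate by a joint
  FITC/PE upper-tail gate: per-channel 99.5th percentiles computed after
  removing jointly-high events, then exclusion of events above both.
  The joint condition is essential: single-channel tails contain genuine
  Ki-67 or Bcl-2 positives, while eosinophil autofluorescence is
  correlated across both channels.
* **Monocyte backgating.** Mature monocytes (CD14+, intermediate SSC)
  seed a robust bounding box (0.5–99.5% quantiles, expanded by 10% of
  the log-range per side) in SSC vs CD45 that captures the total
  monocyte population including CD14− HLA-DR+ immature forms; high-SSC
  CD13+ myeloid and CD10+CD11b− lymphoid events are then excluded.
  Fewer than 50 seed events raises a degenerate-seed warning and a
  fixed fallback box is used, so monocyte-free samples report ≈ 0%
  rather than noise.
* **Exclusivity.** The four final masks are made pairwise disjoint by
  priority (blast > erythroid > myeloid > monocytic). The erythroid
  chain prefers CD13 and uses CD33 only when CD13 is absent from the
  active tube set.

Changing `gatingConfig()` constants cannot break the containment or
exclusivity invariants; they only move boundaries.

## Tube merging

Tubes of one sample share backbone markers (tubes 1/2/5: FSC, SSC, CD13,
CD34, CD45, CD117, HLA-DR; tubes 3/4/6/7: FSC, SSC, CD33, CD45, CD117,
HLA-DR). Merging standardizes the backbone channels per tube
(median/MAD — robust to population skew), then gives each reference-tube
event the mean of its k nearest donor-tube neighbours (k = 1 by default;
the commercial implementation's internals are proprietary, and nearest
neighbour is the minimal faithful surrogate) for each marker the
reference tube lacks. Populations below 1000 events are ineligible.
Imputation noise is quantified by hiding a marker measured in two tubes
and scoring median absolute error (acceptance default ≤ 15 FU) and
empirical-CDF distance against the measured values. Ties in neighbour
distance resolve to the lowest donor index, so imputed values are
invariant to donor event order.

## Statistics

Cohort comparisons follow the normality-dependent rule: Student's
two-sample t-test (equal variance — the conventional reading of
"independent t-test"; Welch is a config option) when both groups pass
Shapiro-Wilk at α = 0.05, otherwise the two-sided Mann-Whitney U test,
exact by enumeration for group sizes ≤ 8 without ties and by normal
approximation with tie and continuity correction otherwise. Stars are
\* p < 0.05, \*\* p < 0.01, \*\*\* p < 0.001, strict inequalities. No
multiple-testing correction is applied, and the exported p-value table
says so in its header. Missing indices (flagged insufficient
populations) are excluded, never imputed.

## The synthetic cohort generator

The generator emulates the study conditions: 50 non-malignant, 25 MDS
and 27 AML cases — one per row of the packaged per-case fraction tables
— with the published demographics (median ages 70/75/72 within ranges
45–89 / 58–94 / 50–87; 25/16/13 males). Ages are drawn uniformly over
the range and then post-adjusted so the cohort median is exactly the
published median, making a printed number an exact target. The cohort
counts follow the per-cohort sizes (summing to 102 cases).

Per case, events are drawn log-normally around population- and
positivity-specific means on the calibrated FU scale: blasts CD45-dim
CD34+ CD117+ HLA-DR+, erythroid CD45− CD36+ CD71+ CD235a+, granulocytes
SSC-high CD45-dim CD13+, mature monocytes CD14+ HLA-DR+ (immature forms
CD14− HLA-DR+, 30% of the monocytic compartment), lymphocytes
CD45-bright, eosinophils SSC-very-high with strong correlated FITC/PE
autofluorescence, platelets CD36+CD71− at low scatter, debris at low
scatter; doublets are sums of two singlets with a singlet-like peak
channel. Spreads are chosen so adjacent populations overlap mildly —
realistic gating difficulty while keeping recovery within the stated
tolerances. Ki-67/Bcl-2 channels are bimodal (negatives ~20 FU, sdlog
0.40; positives ~350 FU, sdlog 0.45) with latent per-event positivity at
configurable true fractions; the per-cohort defaults are implementation
choices for exercising the pipeline, **not** estimates of the study's
measured indices, which are out of the package's scope. Tubes of one
case share the same latent cells; each physical tube adds small
multiplicative measurement noise (sdlog 0.04) emulating separately
stained aliquots, while the `"full"` pseudo-tube carries noise-free
latent values.

Default nuisance fills are debris 5% of total events and, of relevant
events, 2% doublets, 2% platelets, 1.5% eosinophils, with lymphocytes
absorbing the remainder. A few printed rows sum above 100%; for those
the nuisance fills are shrunk first and the populations rescaled onto
100% only if still necessary, so printed values are preserved wherever
arithmetic allows.

What the generator does **not** emulate: real spillover spreading,
acquisition drift, staining batch effects, nucleated-red-cell lysis
variability, aberrant/maturation-shifted immunophenotypes of dysplastic
clones, or the measured index values of the underlying study. Passing
recovery tests therefore demonstrates the internal consistency and
calibration of the pipeline on idealized marrow, not clinical accuracy
on instrument data.

## Numerical choices and degenerate inputs

* Control percentiles are inverse-ECDF order statistics (`type = 1`), so
  a degenerate control (all values equal) yields that value exactly.
* Fractions are exact integer ratios; no smoothing anywhere.
* Empty populations report missing fractions (never 0) with an
  `insufficient_population` flag; < 100 positives flags
  `insufficient_positives`; controls under 500 events flag
  `control_insufficient` inside the index table, while the standalone
  `controlThreshold()` enforces the 500-event precondition as an error.
* Per-case seeds fan out from the master seed by a stable polynomial
  string hash of the case id, so any case regenerates independently and
  all tabular outputs are byte-identical under a fixed seed.
* The FCS writer emits little-endian float32 (`$DATATYPE/F`, `$PnE/0,0`),
  making read/write round-trips value-preserving at float32 precision;
  the reader converts `$PnE`/`$PnG` encoded integer data to linear FU
  and follows `$NEXTDATA` chains to the FCS 3.x dataset of LMD files.

## Validation problem sizes

The shipped suite validates population-fraction recovery on a 10-case
mixed cohort at 100,000 events/case (mean absolute error bounds
1.5 / 2 / 3 / 3 percentage points for blast / erythroid / myeloid /
monocytic) and control-anchored index recovery within ±0.02 of latent
truth; the strategy-bias experiment uses two 5-case cohorts at 30,000
events with identical true indices and a +60 FU myeloid
autofluorescence shift, expecting fixed40 to show a spurious
between-cohort difference (|Δ| > 0.10) that control-anchored strategies
absorb (|Δ| < 0.03). Unit tests use 1,000–60,000 events; these sizes
were chosen to make the full suite comfortably reproducible on a single
CPU while keeping binomial noise far below the stated tolerances.

## Known limitations

* Manual-gate surrogates are calibrated to the generator's FU scale; on
  instrument data the `gatingConfig()` fallback constants and the
  40/100 FU thresholds must be interpreted on that instrument's linear
  scale, which the package cannot verify.
* The backgated monocyte box is axis-aligned; strongly atypical
  monocytic phenotypes (e.g. CD45-bright monoblasts) may fall outside.
* Gating-ML support covers the package's own gate kinds (rectangle,
  threshold, polygon, adaptive boundary exported as polygon), not the
  full standard.
* The Mann-Whitney exact path requires tie-free data; tied small samples
  use the corrected normal approximation.
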