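---
title: "Methods: perfusion mapping, lesion volumetry and mitochondrial assays in mouse stroke cohorts"
author: "strokeIR"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: perfusion mapping, lesion volumetry and mitochondrial assays}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(strokeIR)
```

# Scope

strokeIR implements the quantitative chain of a preclinical
ischemia-reperfusion study in the mouse middle cerebral artery occlusion
(MCAO) model: per-occlusion contrast-enhanced ultrasound (CEUS) perfusion
mapping with automatic area-at-risk (AAR) segmentation, edema-corrected
MRI lesion volumetry normalized to the AAR, calcium-retention-capacity
(CRC) and oxidative-phosphorylation (OXPHOS) trace analysis on isolated
cortical mitochondria, and the nonparametric cohort statistics. A
synthetic-data module generates every input with known ground truth; all
validation below rests on it.

# Burst-replenishment perfusion mapping

## Model

After a high-power burst destroys the microbubbles in the imaging plane,
the contrast intensity of each voxel refills as

$$I(t) = I_0 + A\,\bigl(1 - e^{-\beta (t - t_{burst})}\bigr), \qquad t \ge t_{burst},$$

where $I_0$ (a.u.) is the post-burst floor, $A$ (a.u.) the plateau
amplitude (proportional to local blood volume) and $\beta$ (1/s) the
refill rate (proportional to blood velocity). The perfusion index is the
flow proxy $PI = A\beta$ (a.u./s), the standard choice of
destruction-replenishment theory; `computePerfusionMap(quantity =)` can
map $A$ or $\beta$ alone for sensitivity analyses, since acquisition
reports do not always state which quantity their maps encode.

## Fitting: variable projection

The model is linear in $(I_0, A)$ given $\beta$, so the per-voxel
least-squares problem is solved by a 1-D minimization of the projected
residual over $\beta \in (0, \beta_{max}]$ (`optimize()`, interval
tolerance $10^{-10}$) with a closed-form linear solve, constrained
$A \ge 0$, at each candidate. Compared with a general nonlinear
optimizer this cannot diverge, needs no starting values, is exact on
noiseless curves (parameter recovery to $10^{-6}$ is asserted per voxel on
a full 4 x 64 x 64, 120-frame phantom) and on noisy curves it matched or
slightly beat `nls()` in accuracy in our checks. A fit is flagged
non-converged when $\beta$ collapses to the zero bound while $A > 0$;
constant curves are valid fits with $A = 0$, $PI = 0$. Non-converged or
non-finite voxels are excluded from every downstream statistic — never set
to zero, which would bias both the contralateral median and the AAR count.

## Normalization and AAR segmentation

Perfusion maps are divided voxel-by-voxel by the median $PI$ over the
converged contralateral-hemisphere voxels, making the contralateral median
exactly 1 (idempotent by construction). The AAR is the set of converged
ipsilateral voxels with relative perfusion strictly below the threshold
(default 0.26, i.e. hypoperfusion < 26% of the contralateral hemisphere;
the strict inequality follows the "< 26%" convention). The AAR volume is
reported as a percentage of the ipsilateral hemisphere, each voxel
weighted by its volume, with a per-slice breakdown. No spatial smoothing
is applied by default; a 3 x 3 in-plane median filter is available behind
`medianFilter = TRUE`. The hemisphere partition is an input label volume
(1 ipsilateral — the occluded right side — 2 contralateral, 0 background),
not a computed midline: automatic midline detection is out of scope.

## Phantom design

The CEUS phantom defaults emulate a 4-slice-level, 64 x 64, 120-frame
acquisition at 0.5 s per frame with the burst at frame 11. Healthy tissue
uses $A = 50$ a.u. and $\beta = 0.15$/s: with a ~6.7 s time constant the
replenishment occupies most of the 55 s post-burst window (~8 time
constants), which is how a practitioner sizes a burst-replenishment
acquisition; a much faster rate would leave the kinetics resolved by only
a handful of frames and make the rate estimate noise-dominated. The
lesion is the deterministic set of ipsilateral voxels nearest the
hemisphere centroid covering `lesionFraction` of the hemisphere; lesion
voxels scale $A$ so that $A\beta$ equals `lesionRelativePerfusion` times
the contralateral product. Noise is additive Gaussian on intensity —
sufficient to exercise fitting robustness; speckle statistics,
attenuation, probe physics and motion are deliberately not modelled, so
passing tests say nothing about those artifacts in real data.

Under these conditions, noise at 5% of $A$ leaves the median relative
$PI$ error below 5% (asserted across > 1000 voxels), and with noiseless
data the segmented AAR mask equals the ground-truth lesion mask exactly.

# Lesion volumetry

Vasogenic edema inflates the ipsilateral hemisphere at 24 h, so the raw
contoured lesion volume $LV$ overestimates infarcted tissue. The
edema-corrected burden is

$$\%HLVc = 100\,\frac{HV_c - (HV_i - LV)}{HV_c},$$

i.e. the contralateral hemisphere volume minus the unlesioned ipsilateral
tissue, as a percentage of the contralateral hemisphere. When
$HV_i = HV_c$ this reduces exactly to $100\,LV/HV_c$. Negative values
(possible when contouring noise makes the unlesioned ipsilateral tissue
exceed $HV_c$) are reported with a warning, never clipped. The per-animal
primary endpoint divides the lesion by each animal's own AAR,
$100\,\%HLVc/\%AAR$, using the initial hypoperfused territory as an
internal control for collateral variability; values above 100% mean the
infarct outgrew the territory at risk, and a zero AAR leaves the endpoint
undefined (NA) with the animal flagged.

The protocol exclusion filter is evaluated in protocol order — no Doppler
occlusion, no CEUS perfusion defect (exclusion from study), incomplete
follow-up, infarct outside the MCA territory, lesion exceeding the AAR
(exclusion from analysis) — and reports the first failing criterion.
"Lesion exceeding the AAR" is supplied as a per-animal flag rather than
computed from the scalars: reported endpoint ratios above 100% show that a
scalar rule cannot be what excluded animals, so the flag supports either a
spatial or a scalar interpretation without guessing.

# Mitochondrial assays

## Calcium retention capacity

The assay adds a CaCl2 bolus (default 10 uL of 500 uM) to 0.5 mg of
isolated mitochondria every 60 s; extramitochondrial Ca2+ (Calcium Green
fluorescence) jumps at each bolus and decays as mitochondria sequester it,
until the mitochondrial permeability transition pore (mPTP) opens and the
accumulated Ca2+ is released in a terminal, non-recovering rise. For each
pulse $k$ the detector forms the recovery ratio

$$r_k = \frac{F(\text{end of window}) - F_{pre}}{F_{peak} - F_{pre}}$$

with the window defaulting to 0.9 of the inter-pulse interval and both
endpoints averaged over short sub-windows for noise robustness. Opening is
the first pulse with $r_k$ above the threshold (default 0.5), with a
sustained-monotone-rise fallback for openings between boluses; a trace that
ends first is censored (no opening, all usable pulses retained). A bolus
with no detectable fluorescence jump is flagged unusable. The triggering
pulse is *not* counted: CRC is the Ca2+ fully sequestered before opening,
`nRetained * pulseVolumeUl * pulseConcUM * 1e-3 / proteinMg` — 10 nmol/mg
per pulse under the default constants, so CRC values are multiples of 10.
An optional linear detrend of the pre-pulse baseline is available but off
by default, since whether device traces were drift-corrected is generally
unknown. With noise at 2% of the trace range the retained-pulse count is
recovered exactly in at least 99% of 500 simulated traces (asserted).

## Respirometry

Stage OCRs come from the least-squares slope of the O2 concentration
within each titration stage: a stage spans from its addition event plus a
settling period (default 25% of the stage, skipping injection artifacts)
to the next event, and

$$OCR = -\,\text{slope}\ [\text{nmol/mL/min}] \times \frac{\text{chamber [mL]}}{\text{protein [mg]}}.$$

Complex-wise rates are stimulated-minus-inhibited differences
(CI: GM+ADP − rotenone; CII: succinate − TTFA; CIV: TMPD/ascorbate −
azide); "inhibitor-sensitive rate" has no universal formula, and the
difference convention is the standard one. Missing stages leave the
corresponding rate NA and flagged rather than erroring. The generator's
piecewise-linear traces are recovered exactly ($10^{-9}$) when noiseless;
a plan that would drive the chamber O2 negative is rejected with a
diagnostic.

# Synthetic cohorts

Endpoint distributions are log-normal — endpoints are positive and
right-skewed, as their asymmetric interquartile ranges show. Each
group-by-endpoint target (median, q25, q75) is converted by
$\mu = \ln(\text{median})$ and the over-determined quartile constraints
$\ln(q_{75}/\text{median}) = 0.6745\,\sigma$,
$\ln(\text{median}/q_{25}) = 0.6745\,\sigma$, averaging the two implied
$\sigma$. Sampling $10^5$ draws reproduces the target median within 1%
(asserted). Defaults calibrate the four arms (12 Sham, 14 tMCAO,
12 tMCAO+CsA, 14 pMCAO) to the study's reported group summaries; Sham
imaging endpoints and the CsA complex-II rate are not reported anywhere
and use plausible values (near-zero AAR/lesion for Sham; CsA CII between
the tMCAO and Sham values).

Endpoints within an animal are coupled through a latent ischemic-severity
factor: the log-scale draw is
$\mu + \sigma(\rho s z + \sqrt{1-\rho^2}\,e)$ with a shared per-animal
$z \sim N(0,1)$, independent $e$, loading sign $s = +1$ for AAR and
lesion burden, $-1$ for ipsilateral CRC/OCR and $0$ for contralateral
endpoints ($\rho$ = `severityCoupling`, default 0.6). This leaves every
calibrated marginal exactly log-normal while making severely ischemic
animals carry larger lesions and weaker mitochondria — the within-cohort
structure behind the observed negative lesion-vs-CRC correlation, which
independent draws cannot produce. Neuroscores are drawn from explicit
per-group category probabilities (scores are ordinal; no latent
continuous model is assumed) matched to the group score medians; exclusion
flags are drawn at a per-group rate near the realized exclusion rate of
such studies (~20%, against the 30% anticipated at design). Block
randomization is not emulated: a fixed block size across four arms with
three animals per day is arithmetically ambiguous, and nothing downstream
depends on allocation order.

# Statistics

Quartiles use inclusive linear interpolation of order statistics
(`quantile` type 7); the convention is stated because reports rarely do.
The Mann-Whitney test uses the exact null distribution when the combined
sample is at most 20 without ties, otherwise the normal approximation with
tie and continuity correction; the exact branch is verified against full
enumeration of all labelings for every group-size pair up to 6 x 6, and
the approximate branch holds a 5% +/- 1% type-I error over 10,000 null
simulations at n = 12 per group (both asserted). Kruskal-Wallis uses the
tie-corrected H against $\chi^2_{k-1}$. Outcome-category comparisons use
Pearson chi-square without continuity correction, with a low-expected-count
note below 5. The lesion-CRC correlation defaults to Spearman (consistent
with the nonparametric framework; Pearson selectable), exact for small
tie-free samples and verified against permutation enumeration at n = 5.
The "for a given AAR" group comparison is a common-slope ANCOVA (OLS of
lesion burden on AAR plus a group indicator, two-sided t on the group
coefficient) — the simplest model matching that phrasing. No
multiple-testing correction is applied anywhere, matching the analysis
convention of such study reports.

The a-priori sample size uses the noncentral-t power of the two-sample
t-test (smallest n reaching the target power), inflated by the 0.955
asymptotic relative efficiency of the Mann-Whitney test and then by the
anticipated attrition. At d = 1.21, two-sided alpha 0.05, power 0.8 this
gives 12 (t-test), 13 per group, 75 randomized over four arms at 30%
attrition. Published designs built with other software sometimes print
smaller numbers (e.g. 10 per group, 52 randomized); those are not exactly
reproducible from the stated inputs under any standard two-sided ARE
convention, so the package documents its own convention rather than
forcing agreement.

# Pipeline, determinism and problem sizes

`runPipeline()` draws per-animal ground-truth endpoints from the cohort
spec, simulates the raw data for each animal (CEUS phantom with the
animal's AAR as lesion fraction, a label volume realizing its lesion
burden at 10% swelling, CRC traces with `round(CRC/10)` retained pulses,
titration traces with the animal's complex rates on fixed inhibited
floors), runs the measurement chain on those raw data, applies the
exclusion filter, and computes summaries and tests on the measured
endpoints of included animals. All randomness derives from a single seed
(sub-seeds per animal and stage); reports are byte-identical across
re-runs and reproducible from the provenance block (seed + config hash).
A stage failure for one animal records an exclusion instead of aborting.

The full-cohort pipeline uses a reduced per-animal phantom
(2 x 24 x 24 voxels, 60 frames) so that a 52-animal run completes in
tens of seconds; unit and acceptance tests exercise the full
4 x 64 x 64 x 120 geometry directly where per-voxel exactness is the
claim. These sizes are the package's validation design choices: they keep
the whole suite fast while covering the full-scale case where it matters.

# Limitations

Synthetic cohorts inherit every simplification above: log-normal
marginals, a single severity factor, independent assay noise, no speckle
or motion, no inter-slice lesion irregularity, no drift in assay traces
unless requested. Passing the suite demonstrates the correctness of the
computations and their robustness to the modelled noise — not performance
on artifacts the generator does not contain. The 26% hypoperfusion
threshold is a calibrated constant from prior pMCAO work and may not
transfer to other models or to maps encoding $A$ or $\beta$ alone; it is
configurable for that reason.
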