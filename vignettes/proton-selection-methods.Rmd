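---
title: "Model-based photon/proton selection: methods and design notes"
author: "protonSelect"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Model-based photon/proton selection: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(protonSelect)
```

## The problem

Proton therapy (PT) can spare healthy tissue better than state-of-the-art
photon radiotherapy (XT, here volumetric modulated arc therapy), but it is
scarce and expensive, so it should go to the patients who stand to benefit
most. The model-based selection approach used in the Netherlands (the
National Indication Protocol Proton therapy, NIPP) quantifies that benefit
for head-and-neck patients as a reduction in normal tissue complication
probability (NTCP): plan both modalities, reduce each dose distribution to
organ-at-risk (OAR) mean doses, evaluate logistic NTCP models for
xerostomia and dysphagia under both plans, and refer the patient to protons
when the risk reduction ΔNTCP = NTCP~XT~ − NTCP~PT~ clears a threshold.

`protonSelect` implements this pipeline end to end: volumetric reductions
(mean dose, DVH queries, distance-to-target maps), the four NIPP logistic
NTCP models, the ΔNTCP decision tree with auditable traces, and the
decision-performance metrics. Because clinical dose data cannot be shipped,
the package also contains a parametric head-and-neck dose phantom and an
analytic dose-prediction surrogate, so the full pipeline — and all of its
tests — run on synthetic cohorts generated in code.

## NTCP models

Each endpoint (grade ≥2 / ≥3 xerostomia `Xer2+`/`Xer3+`, grade ≥2 / ≥3
dysphagia `Dys2+`/`Dys3+`, all at 6 months) is a logistic model in OAR mean
doses:

$$\mathrm{NTCP} = \frac{1}{1 + e^{-S}}, \qquad
S = \beta_0 + \sum_i \beta_i\, \bar D_i + \beta_\mathrm{base}.$$

The xerostomia models use the *summed* parotid mean dose
$\bar D_{PL} + \bar D_{PR}$ as one predictor plus the submandibular gland;
the dysphagia models use the oral cavity and the upper/middle/inferior
pharyngeal constrictor muscles (PCM), plus a fixed baseline-complaint
offset. The shipped coefficient set (NIPP v2.2) lives in
`inst/extdata/nipp_coefficients_v2.2.json` — coefficients are data, not
code, so an updated protocol release can be swapped in via
`nippCoefficients(path)`.

```{r}
zero <- OarDoseSummary(setNames(rep(0, 7), ntcpOars()))
round(ntcpValues(evaluateNTCP(zero, "XT")), 4) # logistic of the constants
```

Two points where the source description of these models required a
decision:

* The NTCP link is printed in some descriptions as $1/(1 - e^{-S})$, which
  is not a probability. We implement the standard logistic $1/(1+e^{-S})$,
  which is what a "logistic model" means and what the protocol uses.
* The trailing constants of the dysphagia models (−0.6281 for `Dys2+`,
  +0.0387 for `Dys3+`) are the baseline-complaint terms with the baseline
  category fixed; they are exposed as a `baseline_offset` field in the
  coefficient registry rather than folded silently into the intercept.
* One mean dose feeds the submandibular predictor. Whether that is the
  ipsilateral, contralateral or combined gland is not recoverable from the
  protocol description; the package accepts a single `submandibular`
  structure (the phantom models one combined gland).

Probabilities are stored as fractions throughout; they are rendered as
percent only in reports. Over a physiological 0–80 Gy grid the grade-3
probability stays below the grade-2 probability for both toxicities (this
is checked empirically in the test suite, not assumed: with extreme
loading of only the middle/inferior PCM the `Dys3+` linear predictor could
in principle overtake `Dys2+`, but not in any dose pattern the falloff
geometry can produce).

## The decision tree

`decide()` evaluates, in fixed order, with all comparisons inclusive (≥):

0. **Gate** (optional, default on): if neither grade-2 photon NTCP reaches
   10%, the absolute risk is too low for the comparison to matter and the
   patient stays with photons.
1. **single2**: ΔXer2+ ≥ 10% or ΔDys2+ ≥ 10% → protons.
2. **sum2**: ΔXer2+ + ΔDys2+ ≥ 15% → protons.
3. **single3**: ΔXer3+ ≥ 5% or ΔDys3+ ≥ 5% → protons.
4. **sum3**: ΔXer3+ + ΔDys3+ ≥ 7.5% → protons.
5. otherwise photons.

The single-endpoint thresholds (10% grade 2, 5% grade 3) are the published
NIPP values. The combined-sum cut-offs are *not* printed in the protocol
summaries this package follows; 15% and 7.5% follow the Dutch convention
(1.5× the single threshold) and are configurable in
`decisionThresholds()`. The first accepting rule wins and is recorded, and
the full rule-by-rule trace is kept on every `DecisionResult`, so
cohort-level attribution ("which rule sent each patient to protons") is
reproducible from the outputs alone.

```{r}
dp <- DeltaProfile(
  delta = c("Xer2+" = 0.01, "Xer3+" = 0.005, "Dys2+" = 0.12, "Dys3+" = 0.03),
  xtLevels = c("Xer2+" = 0.99, "Xer3+" = 0.9, "Dys2+" = 0.18, "Dys3+" = 0.04))
decide(dp)
```

For ROC analysis the binary tree needs a continuous score;
`benefitScore()` uses the threshold-normalised maximum rule margin (each
rule's quantity divided by its threshold, maximised over rules), which
crosses 1 exactly where the ungated tree accepts. Any AUC computed from it
characterises *this* score, not the (unstated) score behind any clinical
ROC, so such AUCs are not comparable across implementations.

## Dose surrogate

The deep-learning dose predictor that motivates this pipeline maps CT,
contours and a distance-to-target map (DPTV) to a 3D dose distribution.
Training such a model requires a patient cohort; its value is the trained
weights, not the architecture. The package therefore defines a *predictor
interface* — any function `(structures, modality, params, ...) → dose
grid` — and ships an analytic surrogate on exactly the geometric feature
the learned model consumes, the DPTV map:

$$D(v) = \begin{cases}
 P & v \in \mathrm{PTV} \\
 \max\{b_m,\; P e^{-d(v)/\lambda_m}\} & v \in \mathrm{body}
   \setminus \mathrm{PTV}\\
 0 & \text{outside body,}
\end{cases}$$

with prescription $P$ (default 73.92 Gy, the high-dose target level; 69.96
and 60.06 Gy are the other standard levels), falloff length $\lambda_m$
and dose bath $b_m$ per modality $m$. Defaults: $\lambda_{XT} = 22$ mm
with a 6 Gy bath (the gradual falloff plus low-dose wash of two full
photon arcs) and $\lambda_{PT} = 11.5$ mm with a 1 Gy bath (the sharper
distal gradient of pencil-beam scanning). $\lambda_{PT} < \lambda_{XT}$ is
enforced as a validity condition — it *is* the proton-sparing premise.
DPTV is computed with an exact anisotropic Euclidean distance transform
(separable squared-distance algorithm in C++), measured voxel-centre to
voxel-centre: distances to the nearest target *voxel centre* rather than
to a polygonal surface differ by at most half a voxel diagonal, which is
the tolerance used in the tests.

Prediction error is modelled as an additive, seeded Gaussian random field
outside the target, clipped at 0 Gy. The field is spatially correlated
(white noise smoothed to a correlation length, then rescaled), because
real dose-prediction errors are coherent over centimetres; uncorrelated
voxel noise would average out of every structure mean dose and could never
flip a decision. Defaults — `noiseSd` 3.2 Gy, `noiseCorrMm` 6 mm — put the
voxel-level mean absolute error inside the swallowing OARs at about 3–4%
of prescription (the magnitude reported for trained head-and-neck dose
predictors) while perturbing structure mean doses by a fraction of a Gray.

## The phantom cohort

`hnPhantomSpec()` defines a template anatomy of ellipsoids on a 40×44×36
lattice at 4 mm spacing (≈16×18×14 cm field of view): an elliptic body, a
central PTV, both parotids *partially inside* the PTV, the oral cavity
anterior, one combined submandibular gland inferior-lateral, and the three
PCMs stacked posterior-centrally about 10–15 mm from the target surface.
Per-case variability is mild Gaussian jitter of structure centres (SD
3.5 mm) and uniform ±18% jitter of semi-axes — enough to spread the cohort
across the decision boundary while keeping the decision drivers
interpretable. A structure that voxelises empty is regenerated with
halved jitter (logged, never silent).

This geometry is chosen to reproduce the *mechanism* reported for
bilateral head-and-neck disease, not any cohort statistic:

* because the parotids overlap the target, neither modality can spare
  them: both xerostomia NTCPs saturate and ΔXer ≈ 0, so xerostomia never
  drives selection (the photon-level gate passes trivially);
* the swallowing structures are central but clear of the target, so the
  shorter proton falloff spares them strongly: ΔDys2+ is the operative
  quantity, and with the default falloff its cohort distribution spans
  roughly 5–17%, straddling the 10% threshold.

The falloff and geometry defaults were calibrated once, on scratch sweeps
of the noise-free generator, to produce exactly that regime (a mixed
cohort with the grade-2 dysphagia rule as the modal accepting rule), and
then frozen; they are not adjusted per analysis.

Each case's **reference label** is produced by running the full noise-free
pipeline (mean doses → NTCP → decision tree) — the stand-in for decisions
from dosimetrist-made plans. The *predicted* doses are the same falloff
plus the seeded noise field; evaluation compares decisions on noisy doses
against the noise-free labels, so every disagreement is attributable to
dose-prediction error. Quality control (`qcCase()`) checks
V~prescription~ ≥ 95% target coverage and zero dose outside the body on
the reference plans; failures are reported, not fatal.

What the phantom deliberately does **not** emulate: CT texture and
heterogeneity corrections, deformable or asymmetric anatomy, beam-model
physics (beam angles, spot placement, range uncertainty), plan
optimisation trade-offs, and inter-planner variability. Passing tests on
the phantom therefore demonstrate the correctness and the qualitative
behaviour of the *selection machinery*, not clinical performance on real
patients.

## Evaluation layer

Dose-prediction accuracy is summarised per OAR as mean absolute error and
mean (signed) error, voxel-averaged within a structure, case-averaged
across the cohort, and normalised by prescription (in percent). The two
published error formulas are printed identically (both as MAE); the signed
version is the only reading under which the accompanying "not biased
towards one direction" interpretation makes sense, so ME drops the
absolute value. MAE ≥ |ME| always, with equality exactly for single-signed
errors — an invariant the tests exercise.

Decision performance uses the positive-means-protons convention:
accuracy (TP+TN)/total, sensitivity TP/(TP+FN), specificity TN/(TN+FP),
F-score 2TP/(2TP+FN+FP), all computed in exact rational arithmetic with
rounding left to the report layer, and zero-denominator metrics returned
as `NA` with a flag. AUC is the rank-based (Mann–Whitney) form with
midrank tie handling, cross-checked in the tests against an independent
ROC package and a pairwise-counting oracle. The paired two-sided t-test
wraps `stats::t.test` and converts its "essentially constant data" error
into a flagged degenerate result.

One arithmetic note a user of the reported-metrics literature should know:
a 48-case cohort with 33 proton referrals and 3 errors (one wrong proton
recommendation, two wrong photon recommendations) gives tp=33, fp=1, fn=2,
tn=12 — accuracy 45/48 = 93.8% (93.7% truncated), specificity 12/13 =
92.3%, F-score 66/69 = 95.7%, and sensitivity 33/35 = **94.3%**. A
sensitivity of 97.1% sometimes quoted alongside those numbers is not
consistent with any tp/fn split of that cohort; the package reproduces the
self-consistent subset and computes sensitivity from the counts.

## Numerical and interface choices

* Voxel values refer to voxel centres; all reductions are deterministic
  for fixed input, and every random draw flows from an explicit seed
  (per-case seeds are derived from the master seed once, by one `sample`
  call).
* The distance transform is exact (no approximation error); the only
  convention tolerance is voxel-centre vs surface, bounded by half a voxel
  diagonal.
* DVHs are cumulative, start at 100%, and are non-increasing; exact
  V~D~/D~max~ queries bypass binning.
* Volumes are exchanged as NIfTI (spacing in `pixdim`, spacing+origin in
  the sform; masks as {0,1} volumes), tables as comma/UTF-8/header CSV,
  traces and metrics as JSON. Tabular round-trips are lossless; grids
  round-trip at 32-bit float precision.
* Pipeline configs are validated against a schema before any compute;
  unknown keys are rejected rather than ignored.
* `runPipeline()` writes a plain-text run log (stage timings, warnings,
  the full config and all case seeds), so any single stage can be re-run
  in isolation.

## Problem sizes

The default end-to-end run is 48 cases on the 40×44×36 lattice (~63k
voxels per volume), which completes in well under a minute on one CPU.
The test suite uses the same lattice for acceptance-level checks and a
coarser 30×32×26 lattice at 5.5 mm for unit-level cohort tests;
brute-force distance oracles run on ≤10³-voxel toys.

## Known limitations

* NTCP models are taken as given (NIPP v2.2 coefficients); no refitting,
  no EQD2 conversion — mean doses feed the models directly, matching how
  the selection protocol is applied in practice.
* The baseline-complaint offsets are fixed constants; per-patient baseline
  grades would modulate them, but that mapping is not recoverable from the
  published description.
* The grade-3 combined-sum cut-off (7.5%) extends the published tree by
  convention; a deployment should confirm the local protocol value.
* Absolute cohort statistics (mean NTCP levels, accuracy on real
  patients, clinical AUC) are not reproducible without patient data; the
  synthetic cohort reproduces mechanisms and arithmetic, not those
  numbers.
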