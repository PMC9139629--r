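---
title: "Modelling secondary malignancy risk from dose-volume histograms"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling secondary malignancy risk from dose-volume histograms}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(smrisk)
```

## The problem

Radiotherapy cures tumours at the price of irradiating the surrounding
normal tissue, and one of the long-term prices is a radiation-induced
second cancer. For tumours of the anterior mediastinum — thymoma and thymic
carcinoma — the patients are often young and long survivorship is the rule,
so the choice between 3-D conformal X-ray therapy (3DCRT),
intensity-modulated X-ray therapy (IMRT) and pencil-beam-scanned proton
therapy (PBS) turns in part on how much carcinogenic dose each technique
deposits in the lungs, breasts, esophagus and thyroid. Since observed
second cancers take decades to accumulate, risk is instead *modelled* from
the dose-volume histogram (DVH) of each organ under each candidate plan.

`smrisk` implements two established mechanistic models of that risk, a
seeded generator of synthetic paired cohorts to exercise them on, and the
paired nonparametric comparison that turns per-patient risks into
per-organ modality verdicts.

## The two risk models

Both models consume a *differential* DVH: bin doses $D_i$ (Gy), volume
fractions $v_i$ with $\sum_i v_i = 1$, and the fraction count $n$ of the
plan. Unirradiated organ volume is kept as an explicit zero-dose bin —
both models normalise by total organ volume, and dropping spared volume
would silently inflate risk.

### Competition model (linear-quadratic)

The competition model balances induction of carcinogenic mutations against
killing of the mutated cells:

$$
R \;=\; \sum_i v_i\,\bigl(\alpha_1 D_i + \beta_1 D_i^2/n\bigr)\,
\exp\!\bigl(-(\alpha_2 D_i + \beta_2 D_i^2/n)\bigr),
$$

reported in percent. The quadratic terms are the per-fraction
linear-quadratic correction $D_i d_i = D_i^2/n$ with $d_i = D_i/n$ the dose
per fraction; $\beta_k = \alpha_k/(\alpha/\beta)$ with a single
$\alpha/\beta = 3$ Gy for organs at risk, applied to both the induction and
the kill term. The induction coefficient $\alpha_1$ is organ-specific and
comes in a *total* (any second cancer) and a *fatal* variant, from ICRP 103
risk coefficients; since the fatal coefficient never exceeds the total one
and the kill term is shared, fatal risk never exceeds total risk.

The kill coefficient $\alpha_2$ is not organ-specific in the shipped
registry: 0.25 Gy$^{-1}$, the value used in the competition-model
literature, applies to every organ. It is a named column of the registry
and is copied into every emitted run manifest, never a buried constant,
because the reported risks are sensitive to it: the uniform-dose response
rises roughly linearly, peaks near $1/\alpha_2$ (a few Gy), and decays as
cell kill wins — which is why low-dose bath volume, not the high-dose
target region, dominates modelled second-cancer risk.

### Organ equivalent dose

The OED model declares two dose distributions equivalent when they predict
the same second-cancer incidence, and with a linear-exponential response
the equivalent uniform dose of a DVH is

$$
\mathrm{OED} \;=\; \sum_i v_i\, D_i\, e^{-\alpha_{org} D_i},
$$

the volume-fraction form of the equal-volume dose-point sum ($v_i = 1/N$
over $N$ calculation points); DVH bins are the discretisation available
here. OED is bounded by the mean dose and, for uniform dose, maximised at
$D = 1/\alpha_{org}$ (7.75 Gy for lung, $\alpha_{org} = 0.129$;
30.3 Gy for thyroid, $\alpha_{org} = 0.033$ — small $\alpha_{org}$ means
weak sterilisation, hence the larger OED on identical DVHs). Incidence is
then

$$
I \;=\; I_0 \cdot \mathrm{OED} \cdot e^{-\alpha_{org}\,\mathrm{OED}},
$$

with $I_0$ the organ-specific incidence rate (per 10,000 patients per year
per Gy). The second exponential — sterilisation applied *again*, to the
OED itself — is how the source formulation prints the incidence equation,
and `smrisk` implements it exactly that way; other OED formulations in the
literature use $I = I_0 \cdot \mathrm{OED}$ alone. The switch
`incidence_form = "linear_in_oed"` selects the plain form; the default
`"as_printed"` keeps the double exponential, so the discrepancy is
surfaced as an option rather than silently resolved. No
repair/repopulation correction is applied in the OED stage: the
formulation implemented here has none, and the fuller mechanistic variants
that do were out of scope.

```{r}
d <- dvh("lung", bin_dose = c(0, 5, 20, 50),
         bin_volume_fraction = c(0.4, 0.3, 0.2, 0.1), n_fractions = 27)
dasu_risk(d, dasu_default_params(), "total")
schneider_risk(d, schneider_default_params())[c("oed", "incidence")]
```

## DVH handling

The canonical internal form is the differential DVH with relative volumes;
both models are volume-weighted sums over dose bins, so cumulative input
is converted at load by successive differences, with the differential bin
dose at the interval midpoint (second-order accurate; the source data's
export convention is unknown, so both dialects are supported). Absolute
volumes are normalised by their total. Doses are fixed to Gy — a
`dose_scale` argument converts explicitly (e.g. `0.01` for cGy); there is
no unit autodetection, which is a known corruption source. The interchange
format is a two-column delimited table with a `#`-commented metadata
header; DICOM-RT is deliberately not parsed.

`rebin()` splits every bin into equal-volume sub-bins at the same dose.
It exists to *test* discretisation invariance: both models depend only on
the dose distribution, so any metric must be identical (to 1e-12) before
and after refinement.

## The synthetic cohort generator

The patient DVHs behind the clinical analysis this package is patterned on
are not publicly available, so the generator produces cohorts with the
qualitative structure that analysis assumes, and is first-class, tested
code. Each (modality, organ) profile is a three-component mixture on a
0.5 Gy grid from 0 to 1.1 times the prescription:

* a **spared** zero-dose bin (volume the beams miss entirely), drawn
  uniformly from the profile's `spared` range;
* a **low/intermediate-dose bath**, a beta-distributed plateau whose mean
  level (as a fraction of prescription) is drawn from `bath`, with
  concentration `concentration`;
* a **near-prescription** component of volume drawn from `high`,
  tightly concentrated (beta concentration 60) just below the
  prescription.

Prescriptions are sampled per patient from the tabulated empirical support
(45–66 Gy in 25–33 fractions, median 54 Gy, 17 patients) and shared across
that patient's three modality plans. A per-patient anatomy random effect
(SD 0.5) is also shared across modalities: it shifts the spared fraction
on the logit scale and scales the bath level, creating the within-patient
pairing that a signed-rank comparison needs. For edge organs whose
`spared` range extends above 1 (thyroid in the defaults), the effect is
applied to the drawn value *before* clamping at 1, and a clamped draw
means complete sparing — all volume at zero dose, risk exactly zero. This
makes "organ wholly outside the field" a patient-correlated event, which
is the anatomically sensible behaviour: whether a thyroid sits in an
anterior mediastinal field is a property of the patient, not of the
delivery technique.

The default profiles are **synthetic calibration, not measured data**.
They encode, once, the qualitative pattern the modalities are known for:
anterior proton beams spare posterior organs (lungs, esophagus) and
lateral breast tissue far more than either photon technique; IMRT trades a
larger low-dose bath (at a lower level) for conformality relative to
3DCRT; and the thyroid profile is *identical across modalities*, so any
apparent thyroid difference in a generated cohort is noise — mirroring the
null finding for that organ. Photon bath levels sit near the
competition-model peak (a few Gy to ~12 Gy), where modelled risk is most
sensitive. What the generator does **not** emulate: real anatomical
correlation between neighbouring organs, beam-arrangement-specific DVH
shapes, inter-institutional planning differences, or the absolute risk
magnitudes of any real cohort. Passing tests therefore demonstrate that
the pipeline recovers a known injected structure — not that any specific
clinical risk estimate is correct.

All randomness flows from one integer seed through named substreams keyed
by patient, modality and organ, so regenerating with the same seed is
bit-identical and adding an organ does not perturb the other organs'
draws.

## Paired comparison

Per organ and metric (competition total %, competition fatal %, OED-based
incidence), the cohort report gives each modality's median and range over
patients plus three pairwise two-tailed Wilcoxon signed-rank p-values
(PBS vs 3DCRT, PBS vs IMRT, IMRT vs 3DCRT), flagged at $\alpha = 0.05$.
Design choices, each surfaced as an option:

* **Zero differences are dropped** before ranking (classical convention;
  `zero_method = "pratt"` available). With every difference zero the test
  is undefined and the implementation returns $p = 1$ with a flag rather
  than an error, so degenerate cells (e.g. an organ fully spared by every
  plan) stay reportable.
* **Exact null distribution** of the rank sum for post-drop $n \le 25$
  without ties — so the 17-patient design is always exact — and a
  tie-corrected normal approximation otherwise (`exact_threshold`
  configurable; which variant the original SPSS analysis used at $n = 17$
  is not recoverable, so both are available).
* **No multiple-testing correction** across organs, metrics or pairs:
  every cell is a raw p-value, reproducing the reporting convention of the
  analysis this package is patterned on. Readers combining many cells
  should apply their own correction.

## Numerical choices and degenerate inputs

* Bin doses must be strictly increasing on input; `rebin()` output is the
  one sanctioned exception (repeated doses, equal sub-volumes).
* Volume fractions are renormalised at construction and validated to sum
  to 1 within 1e-9 at model entry.
* A cumulative curve's residual volume beyond the last tabulated dose is
  assigned to that dose; re-accumulating the differential output
  reproduces the input.
* The generator's bath/high beta masses are computed from the distribution
  function on the bin edges, so bin contents are exact up to the
  bin-centre approximation (0.5 Gy bins keep its effect on all metrics
  below ~1e-3 relative).
* Fully spared organs produce a single zero-dose bin; both models return
  exactly 0 on it.

## Problem sizes used by the test-suite

The suite verifies closed-form single-bin cases exactly; Monte-Carlo
voxel-sampling oracles (20 random DVHs, $10^6$ draws each, 3-SE
agreement); bin-refinement invariance at factors 2–10 (1e-12); grid-scan
maximiser locations; signed-rank exactness against full $2^n$ enumeration
for $n \le 12$; type-I calibration at $\alpha = 0.05$ over 2,000 null
cohorts ($n = 17$ each, all modalities sharing one profile); and recovery
of the qualitative modality pattern on full 17-patient cohorts at seeds
1–10. These sizes keep the whole suite around a minute of CPU while
leaving each statistical check enough resolution to fail informatively.

## Known limitations

* $\alpha_2$ is a literature default, not fitted: absolute competition-model
  risks scale with it and should be read comparatively, not as lifetime
  probabilities.
* The incidence unit string ("per 10,000 patients per year per Gy") is
  carried from the coefficient source as a label; the printed incidence
  equation's algebra suggests "per 10,000 per year". The number reported
  is exactly the equation's output; the label is metadata.
* Synthetic cohorts support method verification and power exploration
  only; no generated DVH corresponds to a real patient, and absolute
  medians from the default profiles are not clinical estimates.
* No neutron/secondary-particle dose, no age or sex modifiers of the risk
  coefficients, no repair/repopulation terms.
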