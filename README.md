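# smrisk

Secondary-malignancy risk modelling from dose–volume histograms, for
radiotherapy plan comparison.

When the same tumour can be treated with 3-D conformal X-rays (3DCRT),
intensity-modulated X-rays (IMRT) or pencil-beam-scanned protons (PBS), the
techniques differ mostly in how much dose they scatter through the healthy
organs around the target — and for young, long-surviving patients (thymic
tumours are the motivating case) that difference translates into the risk
of a radiation-induced second cancer decades later. `smrisk` estimates that
risk per organ from each plan's dose–volume histogram (DVH) with two
established mechanistic models, and compares treatment modalities across a
paired patient cohort.

## Models

For a differential DVH with bin doses $D_i$ (Gy), volume fractions $v_i$
($\sum v_i = 1$, spared volume kept as a zero-dose bin) and $n$ fractions:

**Competition model** (linear-quadratic induction vs cell kill), reported
in percent, with $\beta_k = \alpha_k/(\alpha/\beta)$, $\alpha/\beta = 3$ Gy:

$$R = 100 \sum_i v_i (\alpha_1 D_i + \beta_1 D_i^2/n)\, e^{-(\alpha_2 D_i + \beta_2 D_i^2/n)}$$

$\alpha_1$ is organ-specific (ICRP 103; separate *total* and *fatal*
coefficients); $\alpha_2 = 0.25\ \mathrm{Gy}^{-1}$ by default, explicit in
every run manifest.

**Organ equivalent dose (OED)** with organ-specific sterilisation
$\alpha_{org}$, and the incidence rate it implies ($I_0$ per 10,000
patients per year per Gy):

$$\mathrm{OED} = \sum_i v_i D_i e^{-\alpha_{org} D_i}, \qquad
I = I_0\,\mathrm{OED}\,e^{-\alpha_{org}\mathrm{OED}}$$

Cohort comparison uses exact two-tailed Wilcoxon signed-rank tests on the
within-patient differences, per organ and metric, with no multiplicity
correction (each cell is a raw p-value).

Because the patient DVHs behind the motivating clinical analysis are not
shareable, the package ships a seeded synthetic cohort generator
(17 patients × 3 modalities × 5 thoracic organs by default, prescriptions
45–66 Gy in 25–33 fractions) whose profiles encode the qualitative
modality structure: proton sparing of posterior/lateral organs, photon
low-dose baths, and a modality-invariant thyroid. See the methods
vignette (`vignettes/secondary-malignancy-risk.Rmd`) for what the
generator does and does not emulate.

## Worked example

```r
library(smrisk)

# one organ, one plan: 27-fraction plan, lung mostly spared
d <- dvh("lung", bin_dose = c(0, 5, 20, 50),
         bin_volume_fraction = c(0.4, 0.3, 0.2, 0.1), n_fractions = 27)
dasu_risk(d, dasu_default_params(), "total")
#> [1] 0.6223398
schneider_risk(d, schneider_default_params())[c("oed", "incidence")]
#> $oed
#> [1] 1.097992
#> $incidence
#> [1] 1.601012
```

So this DVH carries a 0.62 % modelled probability of inducing any second
lung cancer, and is equivalent to a uniform 1.10 Gy lung dose, implying
1.60 second cancers per 10,000 patients per year per Gy.

The full cohort workflow lives in `analysis/` as numbered drivers over the
package functions:

```sh
Rscript analysis/01_simulate_cohort.R    # 17-patient paired cohort -> results/cohort/
Rscript analysis/02_evaluate_risk.R      # both models per (patient, modality, organ)
Rscript analysis/03_compare_modalities.R # medians, ranges, signed-rank p-values
Rscript analysis/04_dose_response.R      # uniform-dose response curves
```

Step 3 prints the comparison table; at seed 1 the lung row reads

```
| lung | dasu_total | 0.579 (0.321-0.732) | 0.633 (0.369-0.898) | 0.236 (0.106-0.552) | p < 0.001 | p < 0.001 | p = 0.027 |
```

i.e. median modelled total lung risk 0.58 % (3DCRT), 0.63 % (IMRT) and
0.24 % (PBS), with proton sparing significant against both photon
techniques — while the thyroid rows, whose generator profile is identical
across modalities, stay non-significant in expectation. The same pipeline
runs on measured DVHs via a cohort manifest (`read_cohort()` /
`run_pipeline()`) in the documented two-column table format.

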