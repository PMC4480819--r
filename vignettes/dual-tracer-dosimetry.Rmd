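---
title: "Physiological partition dosimetry from dual-tracer SPECT"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Physiological partition dosimetry from dual-tracer SPECT}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dualspect)
```

## The problem and the model

Treatment planning for Y-90 hepatic radioembolization needs two numbers that
anatomical imaging struggles to provide in diffuse or multifocal disease: the
absorbed dose that will reach the tumour, and the absorbed dose that will
reach the liver tissue the patient still depends on. `dualspect` implements a
purely physiological answer. Before treatment the patient receives a small
intraarterial dose of Tc-99m macroaggregated albumin (TcMAA), which lodges in
the same vascular territory the Y-90 microspheres will later occupy, and is
imaged by SPECT. Without moving the patient, an excess of intravenous Tc-99m
sulphur colloid (TcSC) is given — colloid is cleared by Kupffer cells, so it
marks functional liver parenchyma — and the scan is repeated. The second
acquisition therefore images *both* tracers; subtracting the first scan
recovers the colloid signal.

Thresholding each map at 10 % of its maximum voxel count and fusing the two
binary maps partitions the liver into four compartments:

| compartment | MAA | SC | meaning |
|---|---|---|---|
| tumour (`V_T`) | + | − | microsphere-avid tumour |
| irradiated functional liver (`V_FL-IR`) | + | + | marginal zone, hypervascular rims |
| unirradiated functional liver (`V_FL-UN`) | − | + | spared parenchyma |
| null (`V_NULL`) | − | − | necrosis, vessels, cysts |

`V_FL-TOT = V_FL-IR + V_FL-UN` and `V_TOTAL_LIVER = V_T + V_FL-TOT`; the null
compartment is not liver tissue and is excluded from the total.

Each compartment's mean absorbed dose follows the MIRD activity-per-mass
conversion for Y-90,

$$D_c = \frac{C_c}{C_{\mathrm{liver}}} \cdot A \cdot
  \frac{1}{1.029\ \mathrm{kg/L}} \cdot \frac{1}{V_c\ \mathrm{[L]}} \cdot 50,$$

where $C_c$ is the TcMAA count in the compartment, $C_{\mathrm{liver}}$ the
count over *all* hepatic voxels (including sub-threshold ones — thresholding
affects numerators only), $A$ the administered activity in GBq, 1.029 kg/L
the density of hepatic tissue, and 50 the Gy·kg/GBq conversion factor for
Y-90. One GBq spread uniformly through one litre of liver therefore delivers
$50/1.029 = 48.59$ Gy. Two conventions follow the published method: the dose
to sub-threshold functional liver is set to zero (`D_FL_UN = 0`), and
`D_FL_TOT` spreads the FL-IR activity over the whole functional liver volume,
so `D_FL_TOT · V_FL_TOT = D_FL_IR · V_FL_IR` exactly.

Two prescription rules are provided: the body-surface-area method for resin
microspheres, `A = BSA − 0.2 + LI` (GBq, with LI the fractional tumour
involvement), and the glass-microsphere MIRD inversion
`A = D_target · m_target / 50` for a desired territory dose of 90–120 Gy.
`planning_recommendation()` classifies a dose report against the empirical
thresholds: tumour dose above 32.7 Gy (the level above which a 50 % objective
response rate was observed), and cumulative functional-liver dose — current
`D_FL_TOT` plus any prior mean liver dose from earlier radiotherapy — banded
at <30 Gy (no REILD observed), 30–60 Gy (well tolerated) and >60 Gy (38.5 %
REILD risk). The boundaries 30 and 60 Gy fall in the middle band; the
efficacy floor is strict.

## Parameters that matter

* `threshold_maa`, `threshold_sc` (fraction of maximum, default 0.10 each):
  the working point of the published method, chosen there from a 5–30 %
  comparison. The boundary is inclusive ("10 % or more"). The maximum is the
  global maximum of the volume; an optional liver envelope restricts it when
  a phantom or acquisition has a hot background.
* `maa_scale` (default 1): the factor applied to the MAA image before
  subtraction. Plain subtraction is the published behaviour; whether any
  cross-scan normalisation or decay correction was applied is not stated, so
  the factor is exposed. Negative differences clip to zero.
* The SC threshold is taken on the corrected image's own maximum (the
  alternative — the pre-subtraction maximum — is not what the corrected map
  represents physically).
* Activity (GBq) enters linearly; every dose scales proportionally.
* `prior_liver_dose` (Gy) is a scalar mean liver dose from DVH analysis of a
  previous plan; the package adds it, it does not compute DVHs.

## The digital phantom

No public dataset pairs TcMAA and TcSC volumes, so the package ships a
generative phantom with analytic ground truth. The liver is an ellipsoid of
uniform SC-avid parenchyma (default semi-axes 80 × 60 × 50 mm, about 1 L);
tumours are spheres with uniform MAA avidity, an optional MAA+/SC+ rim
emulating hypervascular margins, and an optional cold necrotic core. Normal
parenchyma also receives a low, sub-threshold MAA density (default 2 % of
tumour avidity) so that the hepatic normalisation denominator — which
includes sub-threshold counts — is genuinely exercised. The simulated TcSC
acquisition is the sum of the colloid distribution and the still-present MAA
counts, exactly the superposition the subtraction step exists to remove.

Ground-truth labels are defined from the geometry, before blur and noise.
On a noise-free, unblurred phantom the default segmentation recovers them
*exactly* (the rim avidity, 30 % of tumour, sits above the 10 % MAA
threshold; parenchymal MAA, 2 %, sits below it; subtraction is exact), and
the pipeline dose report matches the closed-form `analytic_dose()` to
floating-point accuracy. Under degradation — isotropic Gaussian blur as a
resolution surrogate, then Poisson counting noise — recovery is reported as
a Dice score, not required exact.

The default grid is a 64-cube at 4.42 mm isotropic spacing (a ~283 mm field
of view). The acquisition hardware this emulates used a 64 × 64 matrix; the
voxel size printed alongside it is not internally consistent with an
abdominal field of view, so spacing is simply a configurable parameter here.
The phantom deliberately omits projection-domain physics: no attenuation,
scatter, partial-volume or reconstruction artefacts. Passing tests on the
phantom therefore validates the segmentation arithmetic and dose algebra,
not robustness to clinical image degradation beyond blur and Poisson noise.

## The synthetic cohort

`generate_cohort()` draws patient records for validating the statistics
layer, emulating a heterogeneous 122-patient cohort (five cell-type groups:
HCC, cholangiocarcinoma, neuroendocrine, colorectal, other). Choices, made
once from the published summary statistics:

* Doses are log-normal per cell type, medians at the published per-type
  values (e.g. HCC `D_T` 109.7 Gy, `D_FL_TOT` 55.1 Gy) with dispersions
  (`sdlog` 0.7 and 0.6) wide enough to reproduce the reported activity and
  dose ranges.
* Response is logistic in `log(D_T)` with 50 % probability at 45 Gy and
  slope 1.4, which places the responders' median tumour dose near 60 Gy and
  the pooled objective response rate near 41–48 %. Response is dose-driven
  only; real cell-type-specific biology (e.g. high response in
  neuroendocrine tumours at low doses) is not modelled.
* REILD risk is 0 below a cumulative functional-liver dose of 30 Gy, 0 in
  30–60 Gy, and 38.5 % above 60 Gy; 12 % of patients carry a prior liver
  dose (log-normal, median 20 Gy).
* Survival is exponential — the published medians constrain one parameter
  per group, so a richer shape is unidentifiable — with per-cell-type
  medians scaled by the responder/nonresponder contrast. The *pooled*
  survival medians of such a mixture do not reproduce all published pooled
  medians simultaneously; the generator is calibrated to the dose-response
  structure, and survival output is used to exercise the Kaplan-Meier and
  log-rank machinery, not to reproduce cohort survival.
* Censoring is applied with probability 0.28 per patient, uniformly over the
  realised survival time. Toxicity grade change is an ordinal latent model
  monotone in `log(D_FL_TOT)` over a three-lab panel (bilirubin, AST, ALT —
  the labs named in the clinical toxicity description; the panel is
  configurable in the grade-change utility, which takes any matched pair of
  grade vectors).

## Numerical and statistical choices

* Thresholding on an all-zero volume is an error (the maximum is undefined),
  not an empty mask.
* Without a liver envelope, the null compartment is restricted to the
  morphological closure (3×3×3 box) of the union of the two tracer maps, so
  enclosed cold structures are null while the exterior stays background. No
  connected-component filtering or smoothing is applied anywhere — the
  partition is purely voxelwise.
* `ratio_T_FL` is reported missing (not infinite) when `D_FL_TOT` is zero;
  doses are serialized to 0.1 Gy in JSON reports, full precision internally.
* Chi-squared tests use no continuity correction (the convention under which
  the packaged outcome tables reproduce their printed p-values, 0.098 and
  0.022). Mann-Whitney is exact for combined n ≤ 10 without ties, normal
  approximation without continuity correction otherwise; Kruskal-Wallis
  applies the standard tie correction. Kaplan-Meier confidence bands use the
  complementary log-log transform; the median is the first time the survivor
  function reaches 0.5 or below, `NA` when never. The stratified log-rank
  pools observed-minus-expected and variance terms across strata
  (Mantel-Haenszel weighting).
* Seeded generators restore the caller's RNG state; identical spec + seed
  gives bit-identical output.

## Worked example

```{r}
spec <- phantom_spec(
  tumours = list(phantom_tumour(centre = rep(64 * 4.42 / 2, 3), radius = 35,
                                rim_width = 8, necrotic_core_radius = 10)))
ph <- generate_phantom(spec)
seg <- segment_dual_tracer(ph$maa, ph$sc)
report <- dose_report(seg$labels, ph$maa, administered_gbq = 1.73)
report
planning_recommendation(report, prior_liver_dose = 0)
```

## Problem sizes and limitations

The test suite runs phantoms on 32-cubes (5 mm voxels) and cohorts of up to
5 000 patients; the acceptance script regenerates a 5 000-patient cohort.
These sizes give sub-voxel-exact geometry checks and standard errors a few
percent wide while keeping a full run in seconds.

Known limitations: absolute SPECT quantification error, attenuation and
scatter are outside the model; the hepatopulmonary shunt adjustment is
accepted as an already-adjusted activity input; response labels enter as
given (no image-based response assessment); and multivariate survival
modelling is intentionally out of scope — records export cleanly to CSV for
external proportional-hazards fits.
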