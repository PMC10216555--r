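# gliomaDKI

Quantitative MRI analysis of high-grade glioma invasion borders in R.

High-grade gliomas infiltrate brain tissue far beyond the
contrast-enhancing tumor core; radiologically "normal-appearing" white
matter around the edema often already contains tumor cells. Diffusion
kurtosis imaging (DKI) and arterial-spin-labelling perfusion (CBF) can
reveal these subtle microstructural changes. `gliomaDKI` implements the
full quantitative pipeline such a study needs:

* **Tensor estimation** — voxel-wise linear least squares of the
  diffusion-kurtosis signal model
  `ln S = ln S0 − b nᵢnⱼDᵢⱼ + (b²/6) MD² nᵢnⱼnₖnₗWᵢⱼₖₗ`
  from multi-shell DWI (default: b = 0, 1000, 2500 s/mm², 60 directions
  per shell), with an optional two-pass signal-weighted fit.
* **Scalar maps** — MD, FA, MK, AK, RK, KA, with the standard QC rule that
  deletes voxels with MK < 0 or MK > 3 from all kurtosis-family maps.
* **White-matter tract integrity (WMTI)** — the two-compartment inversion
  giving the axonal water fraction `AWF = K_max/(K_max+3)`, intra-/extra-
  axonal axial and radial diffusivities, and tortuosity
  `TORT = AxEAD/RadEAD`.
* **Four-zone ROI statistics** — per-ROI means (enhancing core, perifocal
  infiltrative edema, ipsilateral normal-appearing white matter,
  contralateral white matter), Mann-Whitney comparisons (alpha 0.001),
  empirical ROC with Youden cutoffs and percentile-bootstrap CIs, and
  Spearman correlations with immunohistochemical markers (Ki-67 LI,
  Bcl-2 EA) at alpha 0.05, assembled into a ranked biomarker report.
* **Synthetic phantom + cohort generators** — seeded multi-shell image
  phantoms with Rician noise and closed-form ground truth, and a
  Gaussian-copula cohort simulator whose zone calibration mirrors the
  clinical discrimination profile. These make every stage of the pipeline
  testable against exact oracles.

Everything is deterministic under explicit seeds; all file exchange uses
NIfTI-1 and FSL-style `.bval`/`.bvec`.

## Worked example

A single white-matter voxel with 30% axonal water, intra-axonal axial
diffusivity 0.8 µm²/ms and extra-axonal diffusivities 2.0/0.8 µm²/ms:

```r
library(gliomaDKI)
p  <- tissueParams(f = 0.3, daAx = 0.8, deAx = 2.0, deRad = 0.8)
tp <- wmtiForward(p)                 # exact mixture-cumulant tensors
round(apparentValues(tp, c(1, 0, 0)), 4)
#>      D      K
#> 1.6400 0.3373
```

Along the fiber the apparent diffusivity is `0.3*0.8 + 0.7*2.0 = 1.64`
and the apparent kurtosis `3·0.3·0.7·(0.8−2.0)²/1.64² ≈ 0.337`. Fitting
noise-free signals on the reference 121-volume protocol recovers
everything exactly:

```r
scheme <- makeScheme(60, c(0, 1000, 2500))
fit <- fitVoxel(forwardSignal(tp, scheme, 1000), buildDesign(scheme))
round(gliomaDKI:::wmtiVoxel(fit, sphereDirections(250))$values, 4)
#>    AWF  AxEAD RadEAD  AxIAD RadIAD   TORT
#>    0.3    2.0    0.8    0.8    0.0    2.5
```

A simulated 250-case cohort ranks biomarkers for the invasion-border
contrast (infiltrative edema vs normal-appearing white matter); mean,
radial kurtosis and axonal water fraction lead, as expected for tissue
whose non-Gaussian structure is being eroded by infiltration:

```r
tab <- simulateCohort(cohortSpec(nCases = 250, seed = 7))
roc <- rocAnalysis(tab, 2, 3, nBoot = 200, seed = 7)
head(roc[, c("parameter", "auc", "cutoff", "sensitivity", "specificity")], 5)
#>   parameter   auc cutoff sensitivity specificity
#> 5        RK 0.935  1.337       0.876       0.872
#> 3        MK 0.932  0.777       0.880       0.844
#> 7       AWF 0.923  0.289       0.820       0.888
#> 1        MD 0.917  1.120       0.852       0.852
#> 2        FA 0.854  0.510       0.812       0.764
```

The image-level route is `buildPhantom()` / your own co-registered NIfTI
inputs → `runPipeline()`, which writes tensor fields, all parameter maps,
the per-case ROI table and the ranked report; a thin CLI wrapper lives in
`inst/cli/gliomadki.R` (subcommands `simulate-image`, `simulate-cohort`,
`fit`, `run`, `roistats`).

## Vignette

`vignettes/invasion-border-analysis.Rmd` describes the signal model and
its assumptions, the two-compartment inversion, the phantom and cohort
calibration (and what passing tests do and do not show about real
patient data), numerical choices, and known limitations.
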