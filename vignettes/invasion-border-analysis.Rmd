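---
title: "Diffusion-kurtosis analysis of glioma invasion borders: models, calibration and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Diffusion-kurtosis analysis of glioma invasion borders}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gliomaDKI)
```

## The signal model

`gliomaDKI` fits, voxel by voxel, the truncated cumulant expansion of the
diffusion-weighted signal:

$$\ln S(b, \mathbf n) = \ln S_0 - b \sum_{ij} n_i n_j D_{ij}
  + \frac{b^2}{6} \, \mathrm{MD}^2 \sum_{ijkl} n_i n_j n_k n_l W_{ijkl},$$

where $D$ is the symmetric diffusion tensor (6 unique components,
µm²/ms), $W$ the fully symmetric order-4 kurtosis tensor (15 unique
components, dimensionless under the usual MD²-normalisation), $b$ the
diffusion weighting (converted internally from s/mm² to ms/µm²), and
$\mathbf n$ the gradient direction. The model is linear in
$(\ln S_0, D, V)$ with $V = \mathrm{MD}^2 W$ recovered after the solve.
Identifying $W$ on top of $D$ requires at least two distinct nonzero
shells and 21 nonzero-b measurements; the reference protocol uses
b = 0, 1000, 2500 s/mm² with 60 directions per shell (121 volumes).

Two least-squares variants are provided. The default is a two-pass
signal-weighted fit: an ordinary pass predicts noise-free signals whose
squares weight the second pass, the standard correction for the
heteroscedasticity the log transform induces. Both variants are exact on
noise-free model signals, which the test suite enforces to solver
precision; the unweighted variant is retained for oracle tests. Signals
at or below `minSignal` (default `1e-6` of the volume maximum) are clamped
before the log and effectively removed in the weighted pass; a voxel with
no usable signal is marked invalid rather than raising an error. No
positivity or kurtosis-range constraints are imposed in the fit itself:
out-of-range voxels are handled afterwards by the QC rule below, which
mirrors common practice.

## Scalar maps and the QC rule

From the fitted pair the package derives MD and FA (diffusion-tensor
eigenvalues), MK (spherical average of the apparent kurtosis
$K(\mathbf n) = \mathrm{MD}^2 W(\mathbf n)/D(\mathbf n)^2$), AK (along
the principal eigenvector), RK (average over 64 equispaced directions
perpendicular to it) and KA. Voxels whose MK falls strictly below 0 or
strictly above 3 are deleted from the validity mask of *all*
kurtosis-family maps — MK, AK, RK, KA and the tract-integrity maps
downstream — while MD and FA keep their own tensor-validity mask;
boundary values (exactly 0 or 3) are retained. Whether MD/FA should also
be masked is genuinely ambiguous in the field; restricting the rule to
kurtosis maps is the narrower reading and the one adopted here.

Two numerical choices deserve mention:

* **MK quadrature.** MK is computed by numerical spherical averaging, not
  by the closed-form elliptic-integral expression: a 250-node product
  rule (12 Gauss-Legendre nodes in the polar cosine × 21 uniform azimuth
  angles), evaluated *in the diffusion eigenframe* so that the node set
  co-rotates with the tensor. The eigenframe evaluation makes MK exactly
  rotation invariant (the tests require 1e-6), and the Gauss-Legendre
  weights bring the quadrature within 1e-3 of a 10⁴-direction
  Monte-Carlo average on the tissue-parameter family the phantom
  generates. A plain uniform average over the same node count misses that
  tolerance on strongly anisotropic voxels, which is why a weighted rule
  is used. For extreme tensors outside the tissue family (eigenvalue
  ratios above ~10) the quadrature error can exceed 1e-3.
* **KA.** The literature defines kurtosis anisotropy in several
  incompatible ways. The default here is an FA-analogue over the
  eigenvector-projected kurtoses,
  $KA = \sqrt{3/2}\,\sqrt{\sum_i (K_i - \bar K)^2 / \sum_i K_i^2}$ with
  $K_i = K(e_i)$; the alternative (weighted standard deviation of
  $K(\mathbf n)$ over the sphere) is available via
  `scalarMaps(..., kaVariant = "sphere")`. Results using KA should state
  the variant.

Eigenvalues are sorted descending; each eigenvector's sign is fixed
deterministically (largest-magnitude component positive), so AK/RK are
reproducible on isotropic voxels where the eigenbasis is arbitrary.

## The two-compartment (WMTI) inversion

White-matter voxels are modelled as two non-exchanging Gaussian
compartments sharing one fiber axis: an intra-axonal compartment
(fraction $f$, cylinders, radial diffusivity ≈ 0) and an extra-axonal
compartment. The forward map uses the exact mixture cumulants, so for any
direction $K(\mathbf n) = 3 f (1-f) (D_a(\mathbf n) - D_e(\mathbf
n))^2/D(\mathbf n)^2$; because the truth is closed-form, every derived
metric has an exact oracle.

The inversion takes $f = K_{\max}/(K_{\max}+3)$, with $K_{\max}$ located
by discrete search over the 250-direction set augmented with the three
diffusion eigenvectors — deterministic and oracle-checkable, with error
bounded by the set resolution (doubling the set moves AWF by less than
1e-3). Per direction the compartment diffusivities follow

$$D_e(\mathbf n) = D(\mathbf n)\left[1 + \sqrt{K(\mathbf n) f/(3(1-f))}\right],
\qquad
D_a(\mathbf n) = D(\mathbf n)\left[1 - \sqrt{K(\mathbf n)(1-f)/(3f)}\right],$$

the conventional branch that assigns the larger diffusivity to the
extra-axonal space. Apparent kurtosis is clamped at zero before the
square roots. Each compartment tensor is then recovered by linear least
squares of its directional values against the quadratic design and
summarised as axial (largest eigenvalue) and radial (mean of the two
smaller) diffusivities; TORT = AxEAD/RadEAD. With ideal cylinders and the
exact radial direction in the search set the round trip is exact, which
is why the search set is augmented with the eigenvectors. The radial
intra-axonal diffusivity is reported even though the idealised model
expects it near zero, because clinical tables do tabulate it. Voxels with
$f < 10^{-3}$ have no detectable restricted compartment: their
intra-axonal maps and TORT are invalidated (guarding the division and the
$1/f$ factor) and the extra-axonal tensor equals $D$.

## What the phantom emulates — and what it does not

`buildPhantom()` lays out four disjoint tissue bands — enhancing core,
infiltrative edema, ipsilateral normal-appearing white matter,
contralateral white matter — inside a background margin, generates
per-voxel multi-shell signals from each zone's two-compartment tensors
through the *same* cumulant model the fitter inverts, adds Rician noise
(magnitude of a complex Gaussian perturbation, $\sigma = S_0/\mathrm{SNR}$,
default SNR 30; a Gaussian mode exists for analytic checks), draws a
per-voxel CBF map from zone-level normal distributions, and embeds a
square ROI patch per zone. The requested patch area is 44 mm²; at the
default 2.5 mm in-plane voxels the closest achievable square is 3×3
voxels (56.25 mm²), and the achieved area is recorded on the returned
mask. All randomness is governed by the spec seed; identical specs give
bit-identical images.

The zone presets were chosen once so that FA, MK, RK and AWF increase
monotonically from core to contralateral white matter while MD decreases,
and CBF is high only in the core (zone means 60 vs 25/20/18 mL/100 g/min,
bracketing the published core-vs-edema discrimination cutoff of ~50).
The intra-axonal axial diffusivity is held constant across zones, so
AxIAD and RadIAD carry no diagnostic signal in the default phantom — a
deliberate simplification; the clinical data show modest signal there.

Because signals are generated from the truncated cumulant model, the
noise-free fit is *exactly* specified: round-trip tests isolate estimator
correctness from model mismatch. This also means passing tests say
nothing about b-value truncation bias in real tissue, where the true
signal is not a finite cumulant expansion. The phantom likewise omits
realistic anatomy, partial-volume mixing, fiber dispersion and crossing,
eddy/susceptibility artifacts and motion; co-registration is assumed
perfect. Conclusions from the phantom therefore validate the *pipeline*,
not the biology.

## The cohort simulator and its calibration

`simulateCohort()` skips the image level: for each case and zone it draws
the 13 parameters (12 DKI + CBF) from zone-level normal distributions,
parameters mutually independent given the zone. The default zone means
are the closed-form phantom truths. The per-zone standard deviations were
calibrated once, analytically, through the binormal relation
$\mathrm{AUC} = \Phi(\Delta/\sqrt{\sigma_a^2+\sigma_b^2})$ against the
published combined-group discrimination profile, so that the *expected*
ranking mirrors the clinical one: CBF dominates core-vs-edema, while MK,
RK and AWF dominate the two invasion-border contrasts. Tumor zones are
the most variable, the contralateral zone the tightest. The high-variance
tumor zones can produce physically implausible negative draws in heavy
tails; these are tolerated because every downstream statistic is
rank-based.

Immunohistochemical markers are generated by a Gaussian copula: each
marker's latent normal score blends the standardised scores of its target
parameters with loadings $r_j = 2\sin(\pi\rho_j/6)$, which makes the
*Spearman* correlation equal $\rho_j$ in expectation; a strictly monotone
transform (logistic to percent for Ki-67 LI, exponential for expression
activities) maps the latent score to marker units without touching any
rank correlation. The default links are the reported significant
combined-group correlations (Ki-67 with CBF 0.363, AWF 0.343, RK 0.324 in
the core; Bcl-2 with MK −0.444, RK −0.427 in the edema); markers exist
for zones 1–3 only, mirroring the biopsy protocol. Loading vectors with
summed squares above 1 are rejected as infeasible.

A consequence of the published profile worth stating plainly: at the
clinical cohort size (n = 50) several of the published AUC margins (e.g.
0.90 vs 0.93 for the edema-vs-NAWM contrast) are *smaller than the
sampling error of an AUC*, so the expected ranking is frequently violated
by chance. The end-to-end ranking check therefore simulates 250 cases —
enough for the Monte-Carlo error of each AUC to sit well inside the
calibrated margins — while the cohort default remains n = 50. This is a
measurement-precision choice, not a recalibration.

## The statistical battery

Only per-ROI means enter the statistics. Zone comparisons use the
two-sided Mann-Whitney test between ROIs across the cohort, each case
contributing one mean per ROI, *treated as independent samples*. This
mirrors the reference analysis but is statistically debatable — the ROIs
are intra-patient and a paired test would be more powerful; the package
reproduces the stated procedure. Exact p-values come from full
enumeration of the permutation distribution (valid under ties) when both
groups have at most 8 cases, otherwise from the tie-corrected normal
approximation. Significance is declared at alpha 0.001 for comparisons
and 0.05 for correlations, with no multiple-testing correction, matching
the fixed published thresholds; `p.adjust`-style correction can be
applied by the user to the returned p columns.

ROC analysis is empirical: AUC equals the normalised concordant-pair
count (ties half-weighted), orientation chosen so AUC ≥ 0.5 with the
direction recorded; the cutoff maximises Youden's J over midpoint
thresholds, ties broken toward higher specificity (the published cutoff
criterion is unstated; Youden is the usual default). Confidence intervals
are percentile bootstrap (default 2000 replications, cases resampled
within each group, seeded); the replication count and CI method of the
reference analysis are likewise unstated, so the defaults are package
choices. Spearman correlations use the tie-corrected asymptotic p-value
and percentile-bootstrap CIs. Degenerate inputs (all values tied,
constant columns) are flagged rather than dropped silently.

## Limitations

* The fit is unconstrained linear least squares: no REKINDLE-style
  outlier rejection, denoising, or Gibbs/eddy correction; inputs are
  assumed co-registered and artifact-free.
* The WMTI interpretation assumes a single coherent fiber population with
  no exchange; it is not meaningful in gray matter, crossing-fiber
  regions, or (with reservations) heavily infiltrated tissue — precisely
  the tissue of interest, which is why the clinical literature treats
  WMTI values there as empirical markers rather than literal
  microstructure.
* CBF maps are consumed, not computed: ASL quantification, as well as
  image registration, DICOM handling and interactive ROI drawing, are out
  of scope.
* The cohort simulator draws parameters independently within a zone; real
  DKI parameters are strongly cross-correlated, so simulated joint
  statistics (beyond the explicitly calibrated marker links) should not
  be over-interpreted.
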