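---
title: "Modelling lesion conspicuity in spherical versus linear tensor encoding DWI"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling lesion conspicuity in spherical versus linear tensor encoding DWI}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(steDWI)
```

## The forward model and its assumptions

Every voxel is a mixture of axially symmetric Gaussian diffusion
compartments. Compartment $i$ has axial and radial diffusivities
$d_\parallel \ge d_\perp$ (mm²/s), an orientation $\mathbf{u}_i$, a T2
relaxation time (ms) and a signal fraction $f_i$ summing to one. Under a
b-tensor $\mathbf{B}$ (s/mm²) the noise-free signal at echo time TE is

$$S = S_0 \sum_i f_i \, e^{-\mathrm{TE}/T_{2,i}} \, e^{-\langle \mathbf{B},
\mathbf{D}_i\rangle},$$

with the Frobenius inner product $\langle\mathbf{B},\mathbf{D}\rangle$.
Linear encoding (LTE, $\mathbf{B} = b\,\mathbf{n}\mathbf{n}^\top$) gives
$e^{-b\,\mathbf{n}^\top\mathbf{D}\mathbf{n}}$; spherical encoding (STE,
$\mathbf{B} = (b/3)\mathbf{I}$) gives $e^{-b\,\mathrm{MD}}$ for every
compartment, independent of orientation. Two consequences carry the whole
analysis:

* **Jensen dominance.** The direction-averaged LTE signal of any mixture is
  $\ge$ its STE signal at the same $b$ and TE, with equality exactly when
  every compartment is isotropic, for any direction scheme whose second
  moment is isotropic ($\sum_k \mathbf{n}_k\mathbf{n}_k^\top \propto
  \mathbf{I}$ — true for the 3-axis and icosahedral 6-direction sets used
  here). Dispersed white matter therefore stays bright on LTE-DWI and dark
  on STE-DWI.
* **STE rotation invariance.** The STE signal is unchanged by any rotation
  of the tissue, already at acquisition.

The model is purely Gaussian: no kurtosis terms, no exchange, no restricted
geometry. Orientation dispersion is realized at model-construction time by
expanding each anisotropic compartment into `n_disp = 64` sub-compartments
whose orientations are Watson samples about the nominal axis (fixed seed),
which keeps the forward model a Gaussian mixture and makes dispersion exact
to the sampling resolution. The Watson sampler uses a truncated-exponential
envelope on $\cos^2\theta$ with order-one acceptance at every concentration,
so near-parallel fibers ($\kappa \to \infty$) need no special casing.

## The acquisition protocol

`study_protocol()` encodes the clinical protocol the package models:
b-values 100/700/1400/2000 s/mm², LTE in 3/3/6/6 directions, STE repeated
6/6/11/16 times (57 volumes), TR 5,000 ms, TE 84 ms, 2.3 mm isotropic
voxels. The scanner's direction tables are not published; the package uses
the coordinate axes for the 3-direction set and the antipodally reduced
icosahedron for the 6-direction set — the standard rotationally efficient
6-set. Any uniformly spread antipodal scheme would serve; the choice is
recorded in the protocol table written next to every simulated dataset.
Scan-time arithmetic is one TR per volume: the b = 2,000 s/mm² subsets take
6 × 5 s = 30 s (LTE) and 16 × 5 s = 80 s (STE).

## Rotational variance of the 6-direction scheme

A finite direction scheme only approximates the ideal uniform powder
average. `rotational_variance()` quantifies this as the relative standard
deviation (percent) of the 6-direction powder mean across uniformly random
rotations of the tissue — the standard rotational-invariance measure for
direction sets; the closed-form uniform average
$e^{-b d_\perp}\sqrt{\pi/(4b\Delta d)}\,\mathrm{erf}(\sqrt{b\Delta d})$
serves as the independent oracle. For an FA = 0.6, MD = 0.8e-3 mm²/s tensor
at b = 2,000 s/mm² the icosahedral 6-set gives ≈ 1.0%, and below 1% for all
FA below 0.6; the worst-case single-rotation deviation from the uniform
average is larger (≈ 2.5% at FA 0.6) and is available via
`statistic = "max"`. We report the relative-SD statistic because it is the
quantity for which the 1%-at-FA-0.6 boundary holds; the worst-case
statistic answers a stricter question than rotational *variance*.

## The digital phantom

`build_phantom()` rasterizes geometric regions (winner-take-all by voxel
center, precedence lesion > CSF > GM > WM) on a default 32 × 32 × 16 grid of
2.3 mm voxels: a white-matter slab, a gray-matter shell around it, a
mid-line CSF pocket and a spherical lesion in one hemisphere of the slab.
The analysis ROIs are the lesion (`hyperintensity`) and the white matter of
the opposite hemisphere (`nawm`). Default tissue parameters (all
config-overridable; only the white-matter T2 of 80 ms is anchored by the
protocol being modelled):

| tissue | $d_\parallel$ | $d_\perp$ | MD (mm²/s) | T2 (ms) | $\kappa$ |
|---|---|---|---|---|---|
| white matter | 1.7e-3 | 0.35e-3 | 0.8e-3 | 80 | 9 |
| lesion | — | — | 0.5e-3 (isotropic) | 110 | — |
| cortical GM | — | — | 0.9e-3 (isotropic) | 90 | — |
| CSF | — | — | 3.0e-3 (isotropic) | 500 | — |

Two of these deserve justification. White-matter $d_\perp$ is set to
0.35e-3 so the voxel-scale MD is 0.8e-3 mm²/s — the same MD used in the
rotational-variance analysis — and the lesion MD (0.5e-3) lies firmly below
it, the regime in which high-b STE outperforms LTE. The lesion MD is at the
low end of reported hyperintensity ADCs deliberately: the directional
average of the white-matter signal decays with an effective diffusivity
that *falls* with b (the low-$d_\perp$ directions dominate at high b,
reaching ≈ 0.44e-3 mm²/s at b = 2,000), so a lesion MD near 0.7e-3 would
make the LTE SIR peak inside the protocol's b-range and then decrease —
contrary to the monotone rise in b that the phantom is designed to emulate.
With MD 0.5e-3 both modalities' SIR rise monotonically across
100–2,000 s/mm², and the lesion's longer T2 keeps its contrast positive
already at b = 100 (the T2 shine-through behavior).

Noise is Rician: each volume is $\sqrt{(S + \sigma g_1)^2 + (\sigma
g_2)^2}$ with independent standard normal $g_1, g_2$, one master seed
spawning an independent substream per volume. The default $\sigma$ is
calibrated so the white-matter SNR at b = 0 is 30 — a deliberate
calibration choice (no SNR is published for the protocol), exposed in the
config. At the resulting NAWM SNR of ≈ 6 at b = 2,000 the Rician bias of
the noise estimator is still small; `estimate_sigma_n()` warns below
SNR 5 rather than hiding the bias.

What the phantom does **not** emulate: real anatomy, partial-volume mixing
at tissue borders, susceptibility/EPI distortion, motion, eddy currents and
bias fields (all removed by preprocessing in clinical practice), non-Gaussian
diffusion, and lesion heterogeneity. Passing tests therefore demonstrate the
contrast *mechanism* and the correctness of the estimators on
mechanism-faithful data — not clinical effect sizes. The synthetic cohort's
SIR values (medians ≈ 1.8 LTE / 2.4 STE) sit above the clinical range
precisely because the phantom lesion is a homogeneous isotropic sphere.

## Conspicuity statistics and conventions

* LTE-DWI / STE-DWI maps are **arithmetic** means of magnitude volumes
  (what scanners produce); a geometric mean is available behind a flag. For
  arithmetic means, ROI-averaging and volume-averaging commute (asserted by
  test).
* $\sigma_N$ is the NAWM mean of the voxel-wise sample SD (n − 1
  denominator) across the STE repeats at the highest b-value; it is shared
  between modalities because LTE repeats vary with direction as well as
  noise.
* On noise-free data $\sigma_N = 0$ and CNR columns are `NA`;
  `compute_cnr_eff()` itself treats a non-positive $\sigma_N$ as an error.
* MD/S0 maps use weighted log-linear least squares (weights = squared
  signal), the standard fast estimator; non-positive signals flag the fit
  invalid instead of entering the log.

## Cohort statistics

`paired_wilcoxon()` drops zero differences, midranks ties, enumerates all
$2^n$ sign assignments exactly for $n \le 12$ (two-sided p as twice the
smaller tail, capped at 1) and otherwise uses the tie-corrected normal
approximation without continuity correction; the exact branch is tested
against exhaustive enumeration and the reference implementation, and the
test's type-I error at n = 25 is verified to sit near the nominal 5%.
`ks_normality()` follows the common (uncorrected) practice of testing
against a normal with sample-estimated mean/SD — conservative, and flagged
as such in its output — with the Lilliefors-corrected variant behind a
flag. Quantiles use the linear-interpolation convention (type 7).
Improvement fractions use strict inequalities; ties count as not improved.
Because the STE-vs-LTE mean change is reported ambiguously in practice
(mean of per-case percent changes vs percent change of medians), the
per-case records contain everything needed to compute either; neither is
asserted.

## Problem sizes and runtime

Defaults were chosen for desk-scale runs: the 32 × 32 × 16 phantom with the
57-volume protocol simulates in well under a second (per-tissue signals are
computed once and broadcast over masks), a 25-case cohort in ≈ 10 s, and
the full test suite in ≈ 20 s. The rotational-variance analysis uses 1,000
rotations; the Monte-Carlo powder oracle uses 10⁵ directions.

## Known limitations

* Winner-take-all voxel assignment means no partial-volume fading at ROI
  borders; contrasts are sharper than in resampled clinical data.
* The per-case lesion MD randomization range (0.40–0.55e-3 mm²/s) keeps the
  monotone-SIR regime; lesions near the white-matter MD would weaken or
  invert the low-b contrast, which the cohort simulator deliberately does
  not explore.
* ROI statistics run in native dataset space; up-sampling to a structural
  space changes absolute ROI means on real data.
* The σ_N estimator inherits the Rician floor: at very low SNR it
  underestimates the channel SD (documented and warned, not corrected).
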