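# steDWI

Simulation and analysis of glioma lesion conspicuity in high b-value
diffusion-weighted imaging (DWI) with **spherical tensor encoding (STE)**
versus conventional **linear tensor encoding (LTE)**.

## The problem

Tumor-related hyperintensities on high b-value DWI are radiologically
important in glioma workup, but white matter can be just as bright:
conventional DWI encodes diffusion along one direction at a time, so
dispersed anisotropic axon bundles retain signal in every direction even
after averaging. The direction-averaged LTE image (LTE-DWI) therefore mixes
two tissue properties — low isotropic diffusivity (dense tumor) and high
anisotropy (white matter). Spherical encoding weights diffusion in all
directions simultaneously: every tissue compartment is attenuated by
`exp(-b · MD)` regardless of its orientation, so anisotropic white matter is
suppressed and only low-isotropic-diffusivity tissue stays bright. This
package implements that contrast mechanism as a forward model, a digital
glioma phantom, and the ROI statistics used to quantify conspicuity, so the
whole analysis chain runs without patient data.

## The statistics

For a modality `X` (LTE-DWI or STE-DWI) and ROIs over the hyperintensity and
contralateral normal-appearing white matter (NAWM):

    SIR(X)     = <S_hyper(X)> / <S_NAWM(X)>
    CNR_eff(X) = (<S_hyper(X)> - <S_NAWM(X)>) / sigma_N
    CNR        = CNR_eff * sqrt(n)

where `<.>` is the ROI mean, `n` the number of averaged directions or
repeats, and `sigma_N` the per-acquisition noise SD, estimated as the NAWM
mean of the voxel-wise SD across the STE repeats at the highest b-value
(STE repeats differ only through noise; LTE volumes also differ through
direction). Under the multi-compartment Gaussian model the direction-averaged
LTE signal dominates the STE signal in every voxel (Jensen's inequality),
with equality only for isotropic tissue — so an isotropic lesion embedded in
anisotropic white matter always has `SIR(STE) >= SIR(LTE)`.

## Worked example

```r
library(steDWI)

sp  <- study_phantom(seed = 1)   # digital glioma phantom + 57-volume acquisition
res <- conspicuity(sp$dataset, sp$phantom$masks$hyperintensity, sp$phantom$masks$nawm)
res
#>   modality b_value n_averages mean_hyper mean_nawm   sir sigma_n cnr_eff   cnr
#> 1 LTE         2000          6       17.2      9.31  1.85    1.14    6.94  17.0
#> 2 STE         2000         16       17.2      7.16  2.40    1.14    8.79  35.2
```

The isotropic lesion has the same signal in both modalities (17.2), but STE
attenuates the dispersed white matter more (7.16 vs 9.31), raising the SIR
from 1.85 to 2.40 at b = 2,000 s/mm². A 25-case synthetic cohort replicates
the direction of the clinical effect:

```r
records <- simulate_cohort(n_cases = 25, seed = 2024)
glance(cohort_summary(records))
#>   n_cases     p_sir p_cnr_eff frac_sir_improved frac_cnr_improved frac_sir_ste_above_2 ...
#> 1      25 0.0000123 0.0000123                 1                 1                    1
```

Every case shows higher SIR with STE than LTE (paired Wilcoxon signed-rank
p ≈ 1e-5). `conspicuity_vs_b()` produces the SIR/CNR_eff-versus-b curves
(`autoplot()` plots them), `difference_map()` the voxel-wise LTE − STE map
that highlights white-matter tracts, and `run_pipeline()` drives the whole
simulate → analyze → summarize chain from a YAML config, writing NIfTI, CSV
and JSON outputs reproducibly from one master seed.

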