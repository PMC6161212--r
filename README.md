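# meltrheo

Model-based melt viscosity for hot-melt extrusion of amorphous solid
dispersions (ASDs).

## The problem

Hot-melt extrusion (HME) disperses a poorly soluble drug (API) molecularly in
an amorphous polymer. Process simulation of HME needs the melt viscosity of
every candidate formulation — normally a full small-amplitude oscillatory
shear (SAOS) characterisation per blend, which is slow and API-hungry in
early development. `meltrheo` implements an experimental short-cut: once the
pure polymer has been characterised rheologically, the flow curve of any
API/polymer blend is predicted from a single additional measurement, the
blend's glass-transition temperature *T*g.

The package is aimed at formulation scientists and process modellers working
on ASDs (e.g. drug/copovidone systems), and covers the supporting analyses
around the central prediction: glass-transition mixing models, API-in-polymer
solubility phase diagrams from annealing DSC, time–temperature superposition
(TTS), Carreau–Yasuda and WLF fitting, and specific-mechanical-energy
bookkeeping for twin-screw extrusion.

## The model

The melt's flow curve is the reduced Carreau–Yasuda (CY) model

  η(γ̇) = η₀ · [1 + (λγ̇)ᵃ]^((n−1)/a),

with temperature handled by WLF shift factors
log₁₀ *a*_T = −C₁(T−T₀)/(C₂+(T−T₀)). The blend prediction rests on an
exponential correlation between *T*g and zero-shear viscosity at a reference
temperature,

  η₀ = a·exp(b·*T*g),

calibrated by log-linear least squares. Given the polymer's CY/WLF
description and the blend's *T*g, the blend flow curve keeps the polymer's
shape parameters *n* and *a* and its WLF constants, sets η₀ from the
correlation, and scales the relaxation time by the same ratio,

  r = η₀,blend/η₀,polymer = λ_blend/λ_polymer,

which is equivalent to the exact scaling identity
η_blend(γ̇) = r·η_polymer(r·γ̇).

Supporting models: the Couchman–Karasz (CK) mixing rule
*T*g = (w₁*T*g,1 + k_CK(1−w₁)*T*g,2)/(w₁ + k_CK(1−w₁)) with
k_CK = ΔC_p,2/ΔC_p,1 (evaluated in kelvin); the BCKV polynomial extension
that captures positive/negative deviations from linear mixing; the
exponential solubility phase boundary T_annealing = y₀ + A·exp(R₀·x); and
SME = 2πnτ/(60·ṁ) for extrusion energy.

## Worked example

```r
library(meltrheo)

fx <- load_paper_fixtures()   # packaged reference materials and blends

# How strongly do the blends deviate from Couchman-Karasz mixing?
round(sapply(c("CXB 30%","LOR 30%","NAP 30%","PZQ 30%"),
             function(l) ck_deviation(fx$blends[[l]])), 1)
#> CXB 30% LOR 30% NAP 30% PZQ 30%
#>     8.8   -14.5   -16.2   -14.8

# Tg -> eta0 correlation calibrated on the packaged blends (150 degC)
corr <- default_tg_eta0_correlation()
corr
#> <tg_eta0_correlation> eta0 = 0.0006895 * exp(0.1748 * Tg[degC]) Pa s at 150 degC
#>   calibrated on 5 points; log-linear r^2 = 0.9994

# Predict a blend flow curve from its Tg alone (92 degC, a 10% naproxen
# blend) given a polymer characterisation at the same reference temperature
poly_cy  <- flow_curve_fit(1e4, 0.5, 2, 0.3, t_ref = 150)
poly_wlf <- wlf_params(8, 120, t0 = 150)
blend <- generate_model_flow_curve(poly_cy, poly_wlf, corr, tg_blend = 92)
blend
#> <flow_curve_fit> at 150.0 degC: eta0 = 6642 Pa s, lambda = 0.3321 s, a = 2.000, n = 0.300
tabulate_flow_curve(blend, gamma_dot = c(0.1, 1, 10, 100))
#>   gamma_dot       eta
#> 1       0.1 6639.6457
#> 2       1.0 6403.3718
#> 3      10.0 2781.1402
#> 4     100.0  571.8432
```

The positive CK deviation of celecoxib (+8.8 °C) against the negative
deviations of the other three APIs (−14 to −16 °C), and the near-perfect
log-linearity of the *T*g–η₀ correlation (r² = 0.999), are the two
diagnostics that motivate the single-measurement prediction. The predicted
blend curve has the polymer's shear-thinning shape with its plateau set by
the correlation — 6.6 kPa·s here, close to the 7.1–7.2 kPa·s zero-shear
viscosity such a blend shows when measured directly.

A command-line interface wrapping the same functions (subcommands `synth`,
`fit-tg`, `solubility`, `fit-rheology`, `predict-viscosity`, `sme`,
`simulate`, `run-all`) is installed at `inst/cli/meltrheo.R`.

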