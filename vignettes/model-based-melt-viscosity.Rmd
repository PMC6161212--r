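---
title: "Model-based melt viscosity for amorphous solid dispersions: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Model-based melt viscosity: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(meltrheo)
```

# Scope and workflow

`meltrheo` predicts the melt-viscosity flow curve of an amorphous solid
dispersion (ASD) from one measurement — the blend's glass-transition
temperature $T_g$ — plus a one-off rheological characterisation of the pure
polymer matrix. The workflow has four stages, each an exported module:

1. **Glass-transition mixing** (`ck_tg`, `fit_bckv`, `ck_deviation`):
   predict and diagnose blend $T_g$ behaviour.
2. **Solubility phase diagram** (`solubility_from_annealing`): locate the
   API-in-polymer phase boundary from annealing DSC and extrapolate the
   ambient-temperature solubility.
3. **Polymer rheology** (`build_master_curve`, `fit_carreau_yasuda`,
   `fit_wlf`): SAOS sweeps to a master curve, Carreau–Yasuda and WLF
   parameters.
4. **Model-based prediction and energy** (`calibrate_correlation`,
   `generate_model_flow_curve`, `compute_sme`, `simulate_energy_1d`).

`run_workflow()` binds stages 3–4 behind a flat configuration.

# Models and assumptions

## Glass-transition mixing

The Couchman–Karasz (CK) rule is evaluated **on the kelvin scale**:

$$T_g = \frac{w_1 T_{g,1} + k_{CK}(1-w_1)T_{g,2}}{w_1 + k_{CK}(1-w_1)},
\qquad k_{CK} = \frac{\Delta C_{p,2}}{\Delta C_{p,1}},$$

with subscript 1 the API, 2 the polymer. The entropy-continuity derivation
behind the rule demands an absolute temperature scale; a Celsius evaluation
happens to give nearly identical numbers for pharmaceutical temperature
ranges, but kelvin is canonical here. All temperatures are **stored in °C**
and converted at the point of use — this keeps the data model aligned with
how thermal analysts record values.

The BCKV (Brostow–Chiu–Kalogeras–Vassilikou-Dova) curve adds a
composition-weighted polynomial to linear mixing:

$$T_g(w_1) = w_1 T_{g,1} + (1-w_1)T_{g,2}
 + w_1(1-w_1)\left[a_0 + a_1(2w_1-1) + a_2(2w_1-1)^2\right].$$

Because the correction vanishes at $w_1 \in \{0,1\}$, the pure-component
$T_g$s are **pinned, not fitted** — fitting them would add redundant
parameters the functional form already fixes. The fit is then *linear* least
squares in $(a_0,a_1,a_2)$ on interior points, which is exact, deterministic
and gives closed-form standard errors. With fewer than three interior
points, the polynomial order drops (two points: $a_2=0$; one: $a_0$ only).

Two deviation diagnostics are available, because "deviation from CK" is
ambiguous: `ck_deviation()` evaluates at the *measured* compositions, while
`bckv_ck_extremum()` reports the largest gap between the two fitted curves
over $w \in [0,1]$ on a 0.001 grid. Both are legitimate summaries; the
extremum is scan-based rather than analytic because the gap's derivative has
no convenient closed form.

## Solubility phase diagram

An annealed sample equilibrates the dissolved API fraction at the annealing
temperature; its subsequently measured $T_g$ is an indicator of that
dissolved fraction through the BCKV curve of the amorphous system. The
phase boundary is

$$T_{annealing} = y_0 + A\,e^{R_0 x},$$

with $x$ the soluble API weight fraction. Three numerical choices matter:

* **Inversion** of the BCKV curve uses bracketed root-finding (`uniroot`,
  tolerance $10^{-9}$ in weight fraction) over sign changes located on a
  2001-point grid. BCKV curves with large coefficients can be non-monotone,
  so several roots may exist; the root nearest the sample's nominal
  composition is returned and the multiplicity flagged.
* **Which residuals?** The annealing temperatures are *set* by the
  instrument; the noise lives in the measured $T_g$ and therefore in the
  inverted fraction $x$. `solubility_from_annealing()` accordingly fits with
  residuals in the fraction direction ($x$-space). For generic
  $(x, T)$ point sets with temperature noise, `fit_solubility_curve()`
  defaults to temperature-direction residuals.
* **Anchoring $y_0$.** Annealing can only probe a narrow window above the
  blend $T_g$; over such a window $y_0$ is weakly identified, and an
  unconstrained fit extrapolates erratically to 25 °C. Physically the
  boundary terminates near the API melting point, so when a melting point is
  supplied, $y_0$ is constrained to a ±2 °C window around it — about the
  accuracy of a DSC melting point. Without a melting point the parameter is
  free (and ambient extrapolations should be treated with caution).

Saturation matters: a sample whose nominal load is *below* the boundary
dissolves completely, and its inverted fraction merely echoes the load —
it carries no boundary information and would bias the fit if included. With
replicates available, a condition is classified saturated when its mean
deficit (nominal − dissolved) exceeds three standard errors of the pooled
replicate scatter; without replicates a fixed margin is used. In the
laboratory this classification is done by XRPD or microscopy of crystalline
residues; the statistical test is the in-silico analogue.

Both sign branches of the exponential are supported. For an API partly
soluble at ambient temperature the physical branch has $A<0$, $R_0<0$ with
$y_0$ the upper asymptote; $(T-y_0)/A \le 0$ then means full miscibility
(returns 1), whereas on the $A>0$ branch it means insolubility (returns 0
with an `insoluble` flag) — the loratadine/praziquantel-like case.

## Rheology and time–temperature superposition

Sweeps are ingested in Hz or rad/s ($\omega = 2\pi f$) or as $G'/G''$ moduli
($|\eta^*| = \sqrt{G'^2+G''^2}/\omega$); all internal rates are rad/s. The
**Cox–Merz rule** is applied explicitly whenever SAOS data feed a flow-curve
fit: $|\eta^*|(\omega)$ is read as $\eta(\dot\gamma)$ with
$\dot\gamma \equiv \omega$.

Master curves use **horizontal-only shifting**: each isothermal sweep is
translated in $\log\omega$ onto the growing master curve, no vertical
(density) correction is applied, and the shifted viscosity magnitudes are
merged as they are. The same convention is used consistently by the
synthetic generator, by `eval_viscosity(temperature=)`, and by the model's
$\lambda$-scaling, so the package is internally coherent; users combining
these results with vertically-shifted literature master curves should be
aware of the convention.

Shifting is **pairwise sequential** outward from the reference temperature
(not a global optimisation): deterministic, order-independent for a fixed
reference, and each step is a one-dimensional minimisation that is easy to
test. The overlap objective interpolates the master curve with a cubic
spline in log–log space — linear interpolation leaves curvature bias of
order $10^{-2}$ in $\log a_T$ on realistic flow curves, spline interpolation
reduces it to below $10^{-5}$. Each step's variance is estimated from the
curvature of the overlap objective and **accumulated along the chain**;
`fit_wlf()` given a master curve uses these accumulated, correlated
uncertainties in a generalised-least-squares sense, which is what makes its
confidence intervals honest (a naive residual fit on four shift factors
underestimates them severely).

The Carreau–Yasuda fit minimises residuals in $\log\eta$ (multiplicative
errors are rheometer-typical) with Levenberg–Marquardt
(`minpack.lm::nls.lm`, `ftol = ptol = 1e-15`) on
$(\ln\eta_0, \ln\lambda, \ln a, n)$, bounding $a \in [0.05, 50]$ and
$n \in (0, 1]$. The reduced model has **no infinite-shear viscosity term**
$\eta_\infty$ — none is added. With fewer than 5 points, or data too flat to
resolve the transition (dynamic range < 1.2), the transition breadth is
fixed at $a = 2$ and the fit is flagged `reduced`. WLF fitting is
initialised by the exact linearisation $(T-T_0)/\log a_T$ vs $(T-T_0)$ and
polished under positivity bounds.

Whether $\lambda$'s temperature dependence is carried by the shift factor or
refit per temperature is a genuine ambiguity in practice; the package applies
$a_T$ to the rate (standard TTS semantics), which is equivalent to scaling
$\lambda$.

## The $T_g$–$\eta_0$ correlation and blend prediction

$\eta_0 = a\,e^{b\,T_g}$ is calibrated by ordinary least squares on
$\ln\eta_0$ with $T_g$ in °C. The prefactor $a$ is **reference-temperature
specific** (it carries the correlation's temperature dependence); $b$ is
treated as temperature-independent. A default calibration at 150 °C, fitted
to the five packaged blends with model-estimated $\eta_0$, ships with the
package (`default_tg_eta0_correlation()`); it should be re-calibrated for
other polymers or reference temperatures — the workflow refuses to apply it
elsewhere.

`generate_model_flow_curve()` copies $n$, $a$ and the WLF constants from
the polymer unchanged, sets $\eta_0$ from the correlation and scales
$\lambda$ by $r = \eta_{0,blend}/\eta_{0,polymer}$. The polymer's $\eta_0$
enters only through this ratio and is always taken from the supplied polymer
fit, never hard-coded. The prediction degrades for high loadings of APIs
with strong specific interactions: when the caller declares the API soluble
and $w_{API} \ge 0.30$, a warning is emitted rather than a refusal —
capturing solubility effects in the correlation itself is beyond this
package's scope.

## Extrusion energy

`compute_sme()` is the telemetry identity
$SME = 2\pi n(\tau - \tau_{idle})/(60\,\dot m)$ in kWh/t (numerically
W·h/kg), with the idle torque defaulting to 1.2 N·m and negative net torque
clamped to zero with a flag.

`simulate_energy_1d()` is a deliberately simplified **demonstrator**, not a
process simulator: fully filled channels, melt isothermal at the barrel
temperature, per-element mean shear rate $\pi D N / h$, viscous dissipation
$\eta\dot\gamma^2 V_{channel}$, a conduction term equal to the enthalpy to
heat the feed to barrel temperature ($c_p\,\Delta T$), and zero melting
energy (the softening input is represented by the blend $T_g$). No die or
pressure coupling, no backward iteration from the die. Every simplification
is embedded in the returned object's `assumptions` field so downstream
reports carry the caveats. Only *orderings* between formulations (higher
$\eta_0$ → more dissipation; lower API load → higher SME) are meaningful
outputs; absolute kWh/t values are not claimed. Defaults mirror a
small-scale pharmaceutical setup: 12 mm screws, 25:1 L/D, 300 mm
functional length, channel depth 2.4 mm (0.2 D, a documented assumption),
100 rpm, 0.12 kg/h, thermal conductivity 0.18 W/(m·K).

# Synthetic ground truth and what the tests show

Every fitting stage is exercised against generators with known parameters
(`make_saos_dataset`, `make_tg_dataset`, `make_annealing_dataset`), pure
functions of their arguments and a seed. Noise models: multiplicative
log-normal for viscosities (default σ = 2 %), additive Gaussian in K for
temperatures (default 0.5 K) — both rheometer/DSC-typical magnitudes.

Problem sizes in the test suite match a realistic campaign: SAOS at 5
temperatures (130–170 °C, 10 K steps) × 9 frequencies (10 → 0.1 Hz);
$T_g$-composition sets at $w \in \{0.1,\dots,0.9\}$; annealing at 9
compositions (0.50–0.90) × 3 replicates, each annealed 60 °C above its
predicted blend $T_g$. The copovidone-like truth is
$\eta_0 = 10^4$ Pa·s, $\lambda = 0.5$ s, $a = 2$, $n = 0.3$,
$C_1 = 8$, $C_2 = 120$ K at 150 °C; the celecoxib-like solubility truth
($y_0 = 160.9$, $A = -1368.6$, $R_0 = -7$) dissolves 33 % API at 25 °C and
terminates at the melting point.

What passing these tests does **not** show: the generators emulate idealised
instruments. Real SAOS data can be thermorheologically complex (TTS then
fails structurally, not statistically); real annealed samples may
recrystallise during the $T_g$ scan; densities and heat capacities of real
blends drift slightly with composition (the packaged records carry them as
data, but no model consumes them). The ambient-temperature solubility
extrapolation deserves particular caution: it extends an exponential fitted
over a ~25 °C annealing window roughly 100 °C downward, so its
noise-amplification is large — the pipeline test verifies 2-percentage-point
recovery at the default design and 1 K Tg noise, which should be read as
"achievable under the stated conditions", not as a general accuracy claim.

# Degenerate inputs and tie-breaks

* `fit_carreau_yasuda` on flat (Newtonian) data returns a curve with
  $\eta \equiv \eta_0$; the unidentifiable breadth is fixed at 2.
* `soluble_fraction_from_tg` at a tangential extremum returns the grid
  minimiser; multiple roots break ties toward the nominal composition.
* `compute_sme` clamps sub-idle torque to zero rather than reporting
  negative energy.
* `flow_curve_fit` accepts $\eta_0 = 0$ as the inviscid limit so that the
  energy demonstrator's zero-viscosity bookkeeping is exact; fits always
  return $\eta_0 > 0$.
* Workflow reports embed the fully resolved configuration and an
  assumptions log, so every default that filled a gap is visible in the
  output.

# Known limitations

* The $T_g$–$\eta_0$ correlation ignores specific API–polymer interactions;
  at $w_{API} \ge 30\%$ for APIs soluble in the matrix the predicted
  $\eta_0$ can be off by factors of 2–3 (the packaged celecoxib/loratadine
  records illustrate both directions). The package warns; it does not
  correct.
* Horizontal-only TTS is a convention choice; master curves built here are
  not interchangeable with vertically-corrected ones.
* The 1-D energy model is qualitative by design; no residence-time,
  pressure or scale-up quantities are produced.
* Long-term physical stability of ASDs is out of scope entirely — the
  solubility module describes equilibrium at temperature, not kinetics.
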