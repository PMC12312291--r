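# photoloop

Kinetic simulation and frequency-domain analysis of chlorophyll
fluorescence under harmonically oscillating light.

When a leaf is forced with sinusoidal light and its PAM chlorophyll
fluorescence yield ChlF(t) = F′(t)/F_M is plotted against the
instantaneous irradiance, the trajectory encloses a hysteresis loop.
Fast oscillations (periods of seconds) produce **counter-clockwise**
loops in every genotype: the intrinsic turnover of the primary reactions
— chiefly the plastoquinone (PQ) pool between PSII and PSI — lags the
stimulus (*constitutive* hysteresis). Slow oscillations (≥ ~30 s) flip
the loops **clockwise**: the delayed buildup of energy-dependent
non-photochemical quenching (qE, via PsbS protonation and the
violaxanthin→zeaxanthin cycle) keeps rising after the light peak, so the
fluorescence maximum precedes the light maximum (*regulatory*
hysteresis). The package is aimed at photosynthesis researchers who want
to simulate, analyse, or test hypotheses about these regimes.

## The model

Six ODE state variables: PQ_ox (oxidized PQ per PSII, molecules),
PI_ox (oxidized PSI-donor fraction), H_L (lumen free H⁺, µM), ATP
(per PSII), Zea and PsbS_act (quencher fractions). PSII closure is
algebraic (quasi-steady),

    B = (kL + k1⁻·R) / (kL + k1⁻·R + k1⁺·P),   kL = σ_II·q·u,

with P/R the oxidized/reduced PQ pools in molecules and
q = (1 − Zea_max·Zea)(1 − PsbS_max·PsbS_act) the quench factor acting on
both excitation and emission. Electron flux J2 = k1⁺·P·B − k1⁻·R·(1−B)
feeds protons into the lumen; the ATP synthase removes 14/3 H⁺ per ATP
(c₁₄ ring) at rate v5 = k5·[(A_tot − ATP) − a·ATP/H_L^(14/3)]; the
quenchers follow Hill-type lumen-pH activation (Hill coefficients 6 for
VDE, 4 for PsbS, half-activation 1 µM) with first-order decay. The
observable is

    ChlF = q(1−B) / (1 + q·Φ/(1−Φ)) + q·B,     Φ = F_V/F_M,

equivalent to the Oxborough–Baker F₀′ construction, and
NPQ = 1/q − 1. Genotype presets: `WT`, `npq1` (VDE inactive, k3/1000),
`npq4` (no PsbS, k9/1000). Transport constants without printed values
are fixed by `calibrate_parameters()` against two literature anchors at
1000 µmol photons m⁻² s⁻¹: ≈60 O₂ PSII⁻¹ s⁻¹ and ≈93 ATP synthase⁻¹ s⁻¹.
See the methods vignette (`vignettes/oscillating-light-model.Rmd`) for
the full account.

## Worked example

```r
library(photoloop)

params <- genotype_preset("WT")

# steady state under constant saturating light
ss <- steady_state(1000, params)
o2_rate(ss, 1000, params)          # 60.00  O2 PSII^-1 s^-1
atp_rate_per_synthase(ss, params)  # 93.00  ATP synthase^-1 s^-1
ss
#>    PQ_ox    PI_ox      H_L      ATP      Zea PsbS_act
#> 4.000000 0.700000 4.000000 5.812500 0.909071 0.925658

# oscillating light: one slow and one fast segment, 100-800 umol m-2 s-1
prot <- light_protocol(100, 800,
                       data.frame(period = c(60, 1), cycles = c(5, 12)),
                       pre_illum = c(60, 450), quantization = NULL)
trace <- simulate_protocol(prot, params,
                           initial = steady_state(450, params))
res <- analyze_trace(trace)
res$loops[, c("segment", "orientation", "area_index",
              "classification", "chlf_mean")]
#>  segment orientation area_index classification chlf_mean
#>    T=60s          CW    -0.0542     regulatory     0.292
#>     T=1s         CCW     0.0955   constitutive     0.291
```

The T = 60 s loop is clockwise (area index −0.054): quenching lags the
light, so ChlF peaks *before* the light does — regulatory hysteresis.
The T = 1 s loop is counter-clockwise (+0.096): the quenchers are frozen
over one cycle (their per-cycle excursion is < 10⁻³) and the PQ-pool lag
makes ChlF trail the light — constitutive hysteresis. `res$fits` holds
the offset-plus-four-harmonic decomposition of each steady-state cycle
(e.g. T = 60 s: A0 = 0.292, A1 = 0.085, τ1/T = 0.24, residual RMS
1.2e-4).

The full experimental sequence (10-min pre-illumination, periods 8 min →
1 s with DAC-quantized sine steps) is `standard_schedule(100, 800)`, and
`cmd_simulate()` / `cmd_analyze()` (or `inst/cli/photoloop.R`) run the
pipeline from a shell with CSV/JSON outputs. Noisy ground-truth fixtures
for the fitting machinery come from `generate_synthetic()`.

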