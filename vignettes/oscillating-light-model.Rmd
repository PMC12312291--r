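---
title: "A kinetic model of chlorophyll fluorescence under oscillating light"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A kinetic model of chlorophyll fluorescence under oscillating light}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

When a leaf is driven by sinusoidally oscillating light and its
chlorophyll fluorescence yield is plotted against the instantaneous
irradiance, the trajectory encloses a loop: the same light intensity
produces two different fluorescence values depending on whether the light
is rising or falling. Two distinct mechanisms generate such hysteresis.
At short oscillation periods (seconds) the intrinsic turnover of the
primary photosynthetic reactions — chiefly the filling and emptying of
the plastoquinone (PQ) pool between PSII and PSI — delays the response
behind the stimulus, producing **counter-clockwise** loops that appear in
any genotype ("constitutive" hysteresis). At long periods (tens of
seconds to minutes) the pH-driven regulatory machinery of
energy-dependent non-photochemical quenching (qE) engages, but with its
own delay: quenching keeps building after the light has peaked, so the
fluorescence maximum precedes the light maximum and the loop runs
**clockwise** ("regulatory" hysteresis). `photoloop` implements a
six-variable kinetic model that reproduces both regimes, together with
the frequency-domain analysis used to quantify them.

## The model

The state comprises six variables: the oxidized PQ pool per PSII
(`PQ_ox`, molecules, 0..`PQ_tot`), the oxidized fraction of the PSI donor
side (`PI_ox`), the lumen free proton concentration (`H_L`, µM), the
adenylate pool in ATP form (`ATP`, molecules per PSII), and the two
quencher activities: the zeaxanthin fraction of the xanthophyll pool
(`Zea`) and the protonated, active PsbS fraction (`PsbS_act`).

PSII closure is treated as an algebraic (quasi-steady) variable because
primary charge stabilization relaxes in milliseconds, far faster than
every tracked pool:

$$B = \frac{k_L + k_1^- R}{k_L + k_1^- R + k_1^+ P},$$

with $P$ = `PQ_ox`, $R$ = `PQ_tot` − $P$, and
$k_L = \sigma_{II}\, q\, u$ the quencher-attenuated PSII excitation rate
at irradiance $u$. The lumped PSII↔PQ mass action acts **per PQ
molecule**, so the transfer ceiling is $k_1^+ \cdot \mathrm{PQ_{tot}}$
(1750 e⁻ s⁻¹ with the defaults) rather than $k_1^+$ itself. This
convention matters: a per-fraction reading would cap net electron flux at
250 e⁻ s⁻¹, forcing near-complete light saturation at the calibration
anchor of 240 e⁻ s⁻¹; every electron pool would then relax within
milliseconds and no counter-clockwise loop could survive at a 1-s period.
The per-molecule reading yields an unsaturated operating point
($B \approx 0.42$ in saturating light) and a PQ relaxation time of tens
of milliseconds, which is precisely the reservoir lag that generates the
constitutive loops.

The net fluxes are

* $J_2 = k_1^+ P B - k_1^- R (1-B)$ — PSII → PQ electron flux
  (e⁻ PSII⁻¹ s⁻¹); at the quasi-steady $B$ this equals
  $k_L k_1^+ P / (k_L + k_1^- R + k_1^+ P)$, the excitation rate times
  the photochemical yield,
* $J_{bf} = k_2 R \cdot \mathrm{PI_{ox}}$ — PQH₂ re-oxidation towards
  the PSI donor side,
* $v_5 = k_5\!\left[(A_{tot} - \mathrm{ATP}) - a\,\mathrm{ATP}/H_L^{14/3}\right]$
  — net ATP synthase rate; the 14/3 exponent is the H⁺/ATP
  stoichiometry of a c₁₄-ring ATP synthase and $a$ an empirical
  back-pressure constant,
* Hill-type quencher activation
  $v_3 = k_3 (1-\mathrm{Zea})\,/\,(1 + (K_Q/H_L)^{n_{VDE}})$ and
  $v_9 = k_9 (1-\mathrm{PsbS_{act}})\,/\,(1 + (K_Q/H_L)^{n_{PsbS}})$,
  opposed by first-order decay ($k_4$, $k_{10}$) — the parsimonious
  reading of "effective rate constants" for the back reactions.

Protons enter the lumen with the electron flux ($n_H$ H⁺/e⁻, default 1),
leave through the ATP synthase (14/3 H⁺ per ATP; reverse proton pumping
by ATP hydrolysis is excluded by default, switchable with
`allow_atpase_reversal`) and through a passive leak
$k_{leak}(H_L - H_0)$. The conversion $\beta_H$ from per-PSII proton
fluxes to µM of *free* lumen H⁺ absorbs the lumen's large buffering
capacity; with the default $\beta_H = 10^{-3}$ µM per H⁺ PSII⁻¹ the
lumen responds with an effective relaxation time of roughly a second,
consistent with measured proton-motive-force relaxation and with the
~15-s lag of qE onset reported for oscillating-light experiments. A fast,
weakly buffered lumen would let PsbS-driven quenching imprint clockwise
loops already at a 10-s period, contrary to the observed regime
structure; this choice is therefore a structural property of the model,
not a tuning knob (it leaves every steady state untouched).

Quenching acts multiplicatively on both excitation and fluorescence
through $q = (1 - \mathrm{Zea_{max}}\,\mathrm{Zea})
(1 - \mathrm{PsbS_{max}}\,\mathrm{PsbS_{act}})$ — quenchers are
photoprotective, so they must reduce closure as well as emission. The
observable is the normalized yield

$$\mathrm{ChlF} = \frac{q\,(1-B)}{1 + q\,\Phi/(1-\Phi)} + qB,
\qquad \Phi = \Phi_{II\max} = F_V/F_M,$$

which is algebraically identical to computing $F_M' = qF_M$, estimating
$F_0'$ with the Oxborough–Baker correction and interpolating
$F' = F_0' + B(F_M' - F_0')$. The NPQ parameter is
$(F_M - F_M')/F_M' = 1/q - 1$.

## Parameters

Fixed kinetic constants (s⁻¹ unless noted): $k_1^+ = 250$,
$k_1^- = 100$, $k_3 = 0.01$, $k_4 = 0.001$, $k_9 = 0.05$,
$k_{10} = 0.004$, $k_6 = 8$ (ATP consumption), quencher half-activation
$K_Q = 1$ µM with Hill coefficients $n_{VDE} = 6$ (steeper) and
$n_{PsbS} = 4$, maximal quenching depths
$\mathrm{Zea_{max}} = \mathrm{PsbS_{max}} = 0.3$, back-pressure
$a = 9.202\times10^{-2}$. Genotype presets: `npq1` (no violaxanthin
de-epoxidase) divides $k_3$ by 1000; `npq4` (no PsbS) divides $k_9$ by
1000; the affected quencher then simply never forms.

Structural constants with documented defaults: $\Phi_{II\max} = 0.83$
(canonical dark-adapted $F_V/F_M$ of a healthy leaf),
$\mathrm{PQ_{tot}} = 7$ PQ/PSII, $\nu_e = 2$ e⁻/PQ, $A_{tot} = 10$ ATP
per PSII, $n_H = 1$, $H_0 = 0.1$ µM (≈ pH 7 resting lumen),
$\beta_H = 10^{-3}$ µM per H⁺ PSII⁻¹ (above).

The remaining transport constants are not experimentally printed
anywhere; they are fixed by `calibrate_parameters()` against two
literature steady-state anchors at 1000 µmol photons m⁻² s⁻¹:
≈ 60 O₂ PSII⁻¹ s⁻¹ of water splitting ($J_2 = 240$ e⁻ s⁻¹) and ≈ 93 ATP
ATP-synthase⁻¹ s⁻¹ ($v_5 = 46.5$ per PSII with the ½ synthase/PSII
stoichiometry). With a designed operating point — $H_L^* = 4$ µM (well
above $K_Q$, so both quenchers are engaged in saturating light),
$P^* = 4$ oxidized PQ, $\mathrm{PI_{ox}}^* = 0.7$ — the fixed-point
equations solve in closed form for $\sigma_{II}$, $\sigma_I$, $k_2$,
$k_5$ and $k_{leak}$; a deterministic bounded minimizer then polishes the
solution through the actual steady-state solver (a no-op at the closed
form, kept as a safeguard for user-modified parameter sets). The solve is
seed-free and idempotent, and the shipped YAML presets are its output.
$\mathrm{PI_{ox}}^* = 0.7$ was chosen because flatter PSI excitation
(smaller $\sigma_I$) makes the PSI-donor channel of the PQ response so
steep at low light that the quasi-static PQ response can invert for the
`npq4` preset, producing a spurious clockwise loop at a 1-s period; the
steeper PSI drive keeps the PQ pool's light response monotone across all
genotypes and amplitude ranges. At the calibrated defaults the lumen sits
near $K_Q$ at 100 µmol photons m⁻² s⁻¹ (≈ 0.4 µM) and quencher activity
rises steeply across the 100–800 range, which is what makes the
regulatory loops amplitude-dependent.

## Light protocol

`standard_schedule(u_min, u_max)` reproduces the experimental sequence:
10 min of constant pre-illumination at the oscillation mean, then sine
segments of periods 8, 4, 2, 1 min, 30, 10 s (3, 5, 5, 5, 5, 5 cycles)
and 5, 1 s (10 cycles each). Each segment starts at the minimum
($u_0 - u_1\cos(2\pi t/T)$), so segment boundaries are continuous. The
8-bit DAC of the light source is emulated by rounding the ideal sine to
equally spaced levels — 8, 22 and 49 levels for the 100–200, 100–400 and
100–800 ranges. The printed level counts are not consistent with one
uniform global step size, so the emulation takes the level *count* per
range directly rather than guessing the instrument's DAC mapping.
Spectral properties and the weak actinic effect of the measuring beam are
not modeled.

## Numerics

Integration uses `deSolve::lsoda` with `rtol = 1e-8`, `atol = 1e-10` and
forced output on the 0.1-s sampling grid. Quantized waveforms are
integrated exactly: the solver is restarted at every DAC level switch
with constant light in between, so no discontinuity is smoothed over;
ideal sines are integrated per segment with the analytic forcing.
`steady_state()` combines long stiff integration with a clamped Newton
polish (finite-difference Jacobian) down to a units-scaled residual norm
of 1e-8; no monotone line search is imposed because the first Newton step
from an integrated start can be transiently uphill while convergence
remains quadratic. The dark-adapted initial state is the dark fixed point
with both quenchers set to zero and a fully oxidized PQ pool.

`periodic_steady()` reports the RMS change of ChlF between consecutive
cycles; the default threshold of 1e-4 (ChlF units, well below
experimental noise) is met by single-period runs started from the
mean-light steady state — the configuration used for all per-segment
analyses. Across the *full* multi-period schedule the xanthophyll pool
relaxes with a ~600-s time constant at the schedule's mean irradiance, so
long-period segments retain a slow monotone drift of order 1e-3 per cycle
for any protocol of finite length; the analysis pipeline handles this
exactly as the experimental protocol does, by discarding the first cycle
(8-min period) or first two cycles (all others) and phase-averaging the
rest.

## Harmonic decomposition and loops

Steady-state cycles are fitted with
$A_0 + \sum_{k=1}^{4} A_k \sin(k\,2\pi(t-\tau_k)/T)$ via the linear
reparameterization $a_k\sin(k\omega t) + b_k\cos(k\omega t)$ — an exact
linear least-squares problem, hence deterministic and global, with
$A_k = \sqrt{a_k^2+b_k^2} \ge 0$ and $\tau_k$ from `atan2` (identified
modulo $T/k$, reported as $\tau_k/T$ modulo 1). Replicate parameters are
aggregated as mean ± SE with SE = SD/√n; phases are averaged on the
circle (mean resultant direction) to avoid wrap-around artifacts, with
the circular SD/√n as their SE.

Loops are quantified by the shoelace signed area of the (PAR, ChlF)
polygon, normalized by the bounding-box area to a dimensionless index in
[−1, 1]: positive = counter-clockwise (lagging response, constitutive),
negative = clockwise (leading/regulatory). The index is this package's
own construction — no numeric loop-magnitude metric exists in the
oscillating-light literature — and |index| < 0.02 (below the plotting
resolution of typical published figures) is classified as "negligible".
Branches are split by the sign of the light change, with extrema assigned
to the branch they terminate; plateau samples of quantized waveforms
inherit the preceding direction.

## Synthetic data

`generate_synthetic()` produces replicate traces of a known
offset-plus-harmonics waveform with additive i.i.d. Gaussian noise on the
0.1-s grid (the instrument averages 20 raw points per output sample,
which Gaussianizes the noise) — the fixture against which the fitting
machinery is validated by sampling theory (the analytic SE of each linear
coefficient is $\sigma\sqrt{2/N}$). It deliberately does not emulate
heteroscedasticity, saturation-pulse artifacts or instrument drift, so
passing recovery tests certify the estimator, not robustness to such
structure in real data.

## Problem sizes and scope

The test-suite simulations use single-period protocols of 4–12 cycles
started from the mean-light steady state (seconds each) plus one full
100–800 standard schedule (≈ 4400 s simulated); these sizes resolve every
regime the model exhibits, and larger runs only extend the slow
xanthophyll drift documented above. Out of scope by design: cyclic
electron flow, the Calvin–Benson cycle, photoinhibition, state
transitions, stomatal or chloroplast-movement responses, P700/NIR
observables, and any numerical fitting of the kinetic constants to
experimental fluorescence traces — the model is calibrated only to the
two steady-state anchors, and comparisons with data are qualitative by
construction.
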