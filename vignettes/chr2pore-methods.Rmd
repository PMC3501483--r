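---
title: "From photocurrent sweeps to a pore diameter: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From photocurrent sweeps to a pore diameter: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(chr2pore)
```

Channelrhodopsin-2 (ChR2) is a light-gated, inwardly rectifying cation
channel. Two-electrode voltage clamp (TEVC) on *Xenopus* oocytes
expressing ChR2 constructs yields light-evoked current sweeps whose
shape (rise, inactivation, off-decay), current–voltage relation and
ion-substitution behaviour together determine three progressively more
abstract quantities: apparent kinetic time constants, relative
permeability ratios, and finally an excluded-volume estimate of the
minimum pore diameter. `chr2pore` implements that analysis chain, plus
a simulator with known ground truth so that every stage can be tested
quantitatively without experimental recordings.

This vignette explains the models, the conventions, the tunable
parameters, and the numerical choices, in the order in which data flow
through the pipeline.

## The four-state photocycle simulator

The generator's kinetic core is the standard four-state photocycle:
dark-adapted closed `C1`, early high-conductance open `O1`, late
low-conductance open `O2`, and desensitized closed `C2`. Light drives
`C1 -> O1` (rate `ka1`) and `C2 -> O2` (`ka2`), both linear in a scalar
light-intensity factor; the open states interconvert (`e12`, `e21`);
channels close via `O1 -> C1` (`Gd1`) and `O2 -> C2` (`Gd2`); and `C2`
recovers to `C1` in the dark at the much slower `Gr`. Occupancies obey
a linear ODE with a piecewise-constant generator matrix (light on or
off), integrated by `deSolve::lsoda` with `rtol = 1e-8`, restarted at
the two light transitions so the discontinuity never sits inside a
solver step. Because the system is linear, a matrix-exponential
propagator gives exact solutions; the test suite uses `Matrix::expm`
as an independent oracle against the ODE path.

The observable is the conducting occupancy `O1 + gamma * O2` with
`gamma < 1`, which produces the canonical phenotype: a fast rise to a
peak, partial inactivation to a stationary level under sustained light
(`I_ss/I_p < 1`), and a biexponential off-decay whose two rate
constants are exactly the eigenvalues of the dark `(O1, O2)` submatrix
— the analytic reference the kinetics stage is tested against.

Default rates were calibrated once, by a Nelder–Mead search on
log-rates, so that a simulated wild-type sweep *analysed with the
package's own fitters* reproduces typical wild-type apparent constants:
`tau_on` 4.6 ms, `tau_decay` 122 ms, amplitude-weighted `tau_off`
12.1 ms, and `I_ss/I_p` 0.35 at −120 mV in Na⁺. The calibrated values
(`ka1` 77.95, `ka2` 42.08, `Gd1` 105.5, `Gd2` 57.8, `e12` 16.8, `e21`
3.65, `Gr` 0.4 s⁻¹, `gamma` 0.111) are the `photocycle_params()`
defaults and are not *per-construct* claims: the simulator uses one
photocycle for all constructs, since mutant-specific kinetics are not
its target.

```{r}
p <- photocycle_params()
tr <- simulate_photocycle(p, protocol_spec())
range(rowSums(tr[, c("C1", "O1", "O2", "C2")]))   # conservation
1000 / dark_decay_rates(p)                        # off-decay taus, ms
```

## Voltage dependence and the simulated study

Rate constants are voltage-independent by design (no voltage-dependent
photocycle, no spectral intermediates). Voltage enters through the
driving force. Two forms are used:

* `photocycle_current()` is the plain ohmic form
  `I = g_max (V − E_rev)(O1 + gamma O2)`, useful for state-level
  reasoning and sign contracts.
* The study generator instead multiplies the normalized conducting
  envelope by the *constant-field* (GHK) steady-state current at each
  holding potential, summed over permeant monovalent cations. This
  gives simulated families their inward rectification and places the
  stationary I–V zero crossing exactly at the multi-ion GHK reversal
  potential recorded in the ground-truth sidecar.

A simulated study (`study_config()`, `generate_study()`) assigns each
construct a true pore radius `R_c`; its true permeability ratios follow
the excluded-volume forward model below, so every downstream stage has
an exact target. The default bath series is the five 115 mM alkali
chloride solutions (pH 9, so proton current is negligible; the 2 mM
Ba²⁺ / 1 mM Mg²⁺ blockers are treated as non-permeant and never enter
GHK sums). The internal compartment is fixed at 10 mM Na⁺ + 110 mM K⁺
(textbook oocyte cytosol). Because the internal term of the GHK voltage
equation is identical across bath substitutions, the shift between an
X⁺ bath and the Na⁺ bath is exactly `(RT/F) ln(P_x/P_Na)` whatever the
internal composition; the choice merely keeps reversal potentials near
0 mV, inside the −120…+60 mV protocol, where the experiment can
actually bracket them. Per-cell expression scatter is log-normal
(CV 0.2 by default), and recording noise is i.i.d. Gaussian on current
samples — the simplest model that exercises the fitters; line-frequency
artefacts, drift, series-resistance and capacitance transients are
deliberately absent, so passing tests validate the estimators, not
robustness to every instrumental pathology.

## Sweep segmentation and kinetic fitting

`segment_trace()` splits a sweep into baseline (pre-light), rise (light
onset to peak), decay (peak to light-off) and off (light-off to end).
The peak is the signed extremum of the baseline-subtracted current in
the light window — matching the driving-force sign, i.e. a minimum for
inward currents — after a ~0.5 ms running-median prefilter so a single
noise spike cannot claim the peak. A missing peak is an error naming
the sweep, not a silent guess.

`fit_exp_series()` fits `sum_i A_i exp(−t/tau_i) + C` by
Levenberg–Marquardt (`minpack.lm::nlsLM`, taus bounded positive) with a
fixed initial-guess policy — offset from the segment tail mean,
amplitude from the first-sample residual, `tau` from duration/5 and
duration/50 — so fits are exactly reproducible. Components are reported
sorted by `|A|`, and each phase is summarized by the amplitude-weighted
`tau_w = sum |A_i| tau_i / sum |A_i|`, the single "apparent tau" used
for comparisons: the off-decay is genuinely biphasic, and `tau_w`
collapses it into one comparable number. The off segment is always fit
with two components; rise and light-decay use one, refitting with two
when r² < 0.95. Constant segments return an offset-only result with
`converged = FALSE`. `I_ss` is the mean over the final 50 ms
(default) before light-off; `I_ss/I_p` is scale- and baseline-invariant,
and ratios above 1 are flagged rather than rejected. Mutant peak
currents are normalized to the same-day wild-type peak at −120 mV in
Na⁺, with day matching enforced through metadata.

## Reversal potentials and GHK permeability ratios

`build_iv()` collects one current per holding potential (replicates
averaged) on the *stationary* basis by default — reversal shifts are
measured under continuous illumination — with the peak basis available
by flag and the choice recorded in the output. `estimate_erev()` takes
the zero crossing of the piecewise-linear interpolation through the
I–V points: robust and assumption-free at 20 mV spacing, preferred over
polynomial fits that can oscillate. With no sign change the two points
nearest zero current are extrapolated and the estimate flagged;
multiple sign changes (a non-monotone I–V) are an error reporting every
crossing. Holding potentials are used as commanded, with no
junction-potential correction.

Interpolation error at 20 mV spacing is below 0.5 mV for curves
crossing inside the protocol (the test suite asserts this, and 0.05 mV
at 2 mV spacing); errors partially cancel in the difference
`dErev = E_rev,X − E_rev,Na`. That sign convention makes a less
permeant test cation give a negative shift. The GHK conversion is

```
P_x / P_Na = exp( z F dErev / (R T) )
```

valid for equal-concentration substitution, which `ghk_ratio()` checks
when concentrations are supplied; unequal substitutions are an error
directing the user to the full GHK voltage equation
(`ghk_reversal()`). Temperature defaults to 293.15 K — the oocyte
room-temperature norm — and is configurable; the pore-size quantities
downstream start from the regression coefficients and do not depend on
T. The SEM of a shift propagates to the ratio scale by the delta
method.

```{r}
ghk_ratio(-29.2)$ratio   # a typical wild-type Rb+ shift -> P_Rb/P_Na
```

## Excluded-volume pore estimation

Excluded-volume theory treats permeation through a cylindrical pore of
radius `R_c` as proportional to the cross-sectional area the ion of
radius `R_x` leaves free, giving, relative to sodium,

```
P_x / P_Na = ((R_c - R_x) / (R_c - R_Na))^2
```

so `sqrt(P_x/P_Na)` is linear in `R_x` with intercept
`a = R_c/(R_c − R_Na)` and slope `b = −1/(R_c − R_Na)`. Ordinary least
squares (unweighted — the conventional plain regression; SEM weighting
is available by flag) yields

* minimum pore diameter `d_min = 2a/|b|` (the line's x-intercept,
  doubled); the magnitude of `b` is used so the diameter is a positive
  length, with `b < 0` and `a > 0` required explicitly;
* apparent permeating sodium radius `(1 − a)/b` (where the line crosses
  1), a self-consistency check against the crystal radius 0.98 Å.

Sodium anchors the regression at ratio exactly 1, since both derived
quantities presume the line passes through the reference ion. The
default radius table (Li 0.60, Na 0.98, K 1.33, Rb 1.48, Cs 1.69 Å) is
a standard crystal-radius set and fully user-overridable, as published
tables differ at the 0.1 Å level. A non-negative slope leaves `d_min`
undefined with an explicit diagnostic — no size cutoff is observable —
rather than a nonsense negative diameter.

```{r}
fit <- fit_excluded_volume(predict_ratio(3.11, ion_radii(), 0.98))
fit
```

The forward model and the fit are exact inverses on noiseless input for
any `R_c > R_Na > 0`; the suite verifies recovery to 1e−10 over random
geometries. Under 10% multiplicative noise on ratios, a five-point OLS
propagates roughly 10% uncertainty into `d_min`, so recovery within 10%
of truth holds in most but not all replicates; the suite asserts a
conservative ≥80% rate over 500 seeded draws.

## Aggregation and reporting

`aggregate_stat()` reports mean, SEM (= sd/√n) and n; comparisons
against the wild-type group use Welch's two-sided two-sample t-test,
uncorrected for multiple testing (mirroring common practice in small
mutant panels), with both choices recorded in the report metadata.
Groups of n = 1 flag the p-value as undefined instead of fabricating
one. `run_pipeline()` chains everything — summaries, kinetics at the
analysis voltage (parameterized per segment, since off-rates are
conventionally read at a different potential than on/decay rates),
per-cell reversal potentials, shifts, ratios, pore fits — and is
deterministic given (dataset, config).

## Numerical choices, degenerate inputs, tie-breaks

* ODE: `lsoda`, `rtol 1e-8`, `atol 1e-10`; occupancy conservation is
  asserted to 1e-8 in tests.
* GHK current at V = 0: removable singularity evaluated by its analytic
  limit `P z F (c_in − c_out)` for `|zFV/RT| < 1e-8`.
* Exponential fits: bounded LM, max 500 iterations; failures and
  constant segments surface as `converged = FALSE`.
* Equal-|amplitude| components: ordering falls back to the fitter's
  stable order; `tau_w` is permutation-invariant either way.
* Zero current exactly on a grid point: taken as the crossing without
  interpolation.
* All-zero permeabilities, empty solutions, non-normalized initial
  occupancies, negative rates, non-positive taus, unequal substitution
  concentrations: all rejected with messages naming the offending
  quantity.

## Problem sizes used by the tests

The suite favours closed-form oracles at small n: sweeps are simulated
at 2–20 kHz for ≤1 s; studies used in pipeline tests span 1–3
constructs × 2–5 solutions × 10 voltages × 1–2 cells; Monte-Carlo
checks use 100 fit-recovery seeds, 500 pore-noise replicates, and
50 × 10-sweep coverage experiments for the noisy GHK round trip. These
sizes make the full suite run in well under a minute while keeping
every statistical assertion calibrated.

## Known limitations

* One photocycle serves all constructs; mutant-specific kinetics are
  out of the generator's scope (the analysis stages, of course, fit
  whatever they are given).
* No voltage-dependent rates, so the simulator cannot reproduce the
  empirical voltage dependence of the off-rate; the analysis side
  parameterizes fitting voltage instead.
* Excluded-volume theory yields an *effective minimum* diameter under
  idealized cylindrical-pore assumptions; hydration-shell effects,
  surface charge and activity corrections are deliberately excluded.
* Published coefficient-level reproduction is limited to quantities
  derivable from printed regression coefficients; per-mutant ratios
  were never published numerically and are exercised only through
  simulation round trips.
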