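---
title: "Modeling cold acclimation of chloroplast gene expression"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling cold acclimation of chloroplast gene expression}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(coldshift)
```

## The question and the model

Shift a plant into the cold and every reaction in its chloroplast slows
down, yet quantified immunoblots of thylakoid-complex core subunits show
essentially constant protein levels over the following days. `coldshift`
implements the minimal model with which that observation can be dissected:
four lumped mass-action reactions,

$$\frac{d[\mathrm{mRNA}]}{dt} = k_1 - k_2\,[\mathrm{mRNA}], \qquad
  \frac{d[\mathrm{Protein}]}{dt} = k_3\,[\mathrm{mRNA}] - k_4\,[\mathrm{Protein}],$$

with exact steady states $\mathrm{mRNA}^{SS} = k_1/k_2$ and
$\mathrm{Protein}^{SS} = k_1 k_3/(k_2 k_4)$. Each reaction is a stand-in for
a far more complex composite process; the model's purpose is the *relative*
sensitivity of those processes to temperature, not mechanistic realism. All
concentrations and times are in arbitrary units (`reference_rates()` never
claims absolute calibration), and the system is deterministic, linear and
single-gene by design — no stochastic simulation, no ribosome or polymerase
species, no multi-gene competition.

## Why temperature hits production harder than degradation

For an elementary reaction the Arrhenius law
($k = A e^{-\Delta G / RT}$, `arrhenius_rate()`) would quantify the
temperature effect, but activation parameters for composite processes like
transcription are not tabulated. The package therefore follows an
encounter-rate argument. Diffusion obeys the Stokes–Einstein relation
($D = k_b T / 6\pi\eta R_0$, `stokes_einstein_D()`), so at fixed viscosity a
10 K drop near room temperature slows diffusion by only
`r sprintf("%.1f%%", 100 * (1 - 287.15/297.15))` — per encounter the effect
is tiny. What differs between the processes is *how many* successful
encounters each needs: `encounter_estimate(350)` shows that making the mRNA
for a 350-residue protein takes on the order of 1000 nucleotide encounters
and translating it roughly one loaded-tRNA encounter per residue, whereas a
protease or ribonuclease needs a single encounter with its target. Composite
production reactions therefore multiply the per-encounter slowdown a
thousandfold; degradation hardly at all.

Because the absolute scaling is unknowable at this level, the simulation
interface is driven by explicit per-reaction factors (`shift_factors`,
`apply_shift`) rather than by the Arrhenius form. Two empirical anchors are
exposed and deliberately *not* reconciled: the reference cold rate set slows
production 10-fold per 10 °C, while the Van't Hoff utility
(`q10_factor(2.5, -10)` = `r q10_factor(2.5, -10)`) reflects the ~2.5-fold
per 10 K measured for translation elongation. Users can build factor sets
from either; the canned scenarios use the former.

## Scenarios and defaults

`scenario_factors()` provides four presets applied to the warm reference
rates (2.5, 1, 2.5, 1):

| scenario | factors (f1, f2, f3, f4) | behaviour after the shift |
|---|---|---|
| `uniform` | 0.1, 0.1, 0.1, 0.1 | steady states unchanged; concentrations constant |
| `degradation_spared` | 0.1, 0.5, 0.1, 0.5 | mRNA 5-fold down, protein 25-fold down |
| `protein_degradation_spared` | 0.1, 0.1, 0.1, 0.5 | mRNA constant, protein 5-fold down |
| `mrna_degradation_spared` | 0.1, 0.5, 0.1, 0.1 | mRNA 5-fold down, protein 5-fold down |

`uniform` shows that equal slowdown reproduces the constant blot signal
trivially; `degradation_spared` is the encounter-argument expectation and
the default everywhere. Simulations start with neither species present
(`system_state(0, 0)`), run to steady state, and shift instantaneously at
`shift_time = 400` within a `duration = 1200` window — long enough for both
segments to settle at the reference rates (the slowest relaxation rate is
0.5, so 400 units is 200 e-folding times). Rates are piecewise-constant; no
temperature ramp is modelled.

## Numerics

The cascade is linear, so `closed_form()` gives the exact solution (the
two-exponential protein response; the degenerate $k_2 = k_4$ case switches
to the $t\,e^{-kt}$ limit when $|k_2-k_4| < 10^{-12}\max(k_2,k_4)$). The
numerical integrator `simulate_piecewise()`/`simulate_shift()` uses lsoda
with `rtol = 1e-8`, `atol = 1e-10`; the system is non-stiff and
well-conditioned, and these tolerances keep integration error far below any
quantity of interest — the test suite holds integrator and closed form to
within 1e-6 relative error across 100 random rate sets. Round-off can push
concentrations to tiny negative values; the integrator output clips these
to zero. `is_steady()` declares steadiness when both species vary by less
than `rel_tol` (default 1e-4, relative to the species' mean level) over the
final 10% of the time window.

## Control-point analysis

With the cold rates in place, restoring the warm protein steady state by a
single intervention requires, by inversion of the steady-state formulas:
25-fold up-regulation of transcription or translation, or 25-fold
down-regulation of either degradation (`required_fold_change()`; the
inversion is closed-form, never a numeric search, so compensation is exact
to machine precision). Stabilizing only the mRNA pool is cheaper: a
fivefold slower mRNA degradation suffices. Working through the mRNA side
has a cost the blots could in principle detect: transcription-only (or
mRNA-degradation-only) compensation drives the mRNA pool to five times its
warm level (`mrna_side_effect()`). Joint control relaxes the individual
factors — only the product is constrained (25 for the reference shift), and
`combined_control()` supports the equal split (fivefold each) or any
user-stated split that multiplies out correctly.

`response_simulation()` contrasts an `immediate` intervention (applied at
the moment of the shift, starting from the warm steady state) with a
`settled` one (applied after the system has relaxed into the cold state).
In immediate mode the protein-side interventions (translation up, protein
degradation down) transiently overshoot the restored level, the mRNA-side
ones transiently dip below it. Trajectories are evaluated with the closed
form over a default window of 18/min(k2, k4) of the adjusted rates, which
brings even the slowest solution (k4 reduced to 0.02) within ~1e-5 relative
of its steady state. A temporary complete stop of degradation — faster than
any steady-state-compatible down-regulation, at the price of overshooting —
can be expressed as a three-segment `simulate_piecewise()` schedule
(normal, k4 ≈ 0, restored).

### Transition times

Speed is scored with the model's transition-time measure,
$\tau_{\mathrm{mRNA}} = 1/(k_1+k_2)$ and
$\tau_{\mathrm{Protein}} = 1/(k_1+k_2+k_3+k_4)$, implemented verbatim in
`transition_time(method = "rate_sum")`. Note the dimensional tension: $k_1$
is a zeroth-order rate (concentration/time) summed with first-order
constants (1/time). The formulas are retained as stated because they define
the speed measure used throughout the analysis; as an honest cross-check,
`method = "relaxation"` provides the textbook relaxation times of the
linear cascade ($1/k_2$ for mRNA; the slowest eigenvalue $1/\min(k_2,k_4)$
for protein). Both appear in the JSON control reports. The qualitative
ranking — production-side compensation fast, degradation-side slow — is the
same under either measure.

### The Pareto front

When an up-regulated production rate and a down-regulated degradation rate
share the compensation, up_factor × down_factor is pinned at the required
total (25). `pareto_front()` sweeps the up-factor over a log-spaced grid
(default `n_grid = 50`; the trade-off is multiplicative, so a log grid
samples it evenly) from 1 (pure degradation control, slowest, cheapest) to
25 (pure production control, fastest, most expensive — the up-factor is the
proxy for extra ATP demand). τ decreases strictly along the front: no
strategy is dominated in both objectives.

## The synthetic blot generator

`generate_blots()` emulates the quantified western-blot experiment, not the
images: a control condition resting at the warm steady state and a shifted
condition that starts there and follows the cold rates from time zero,
sampled at 0, 0.5 min, 5 min, 20 min, 1 h, 5 h, 1 day and 2 days with three
replicates for PetA, PsbA and AtpA. One model time unit is mapped to one
hour (`hours_per_unit = 1`) — an arbitrary but fixed convention, since the
model itself never ties its time axis to the clock. Two noise terms act on
the latent kinetic signal:

* a slow shared sinusoid (default amplitude 0.15 of the signal, period
  24 h, one random phase per protein) standing in for the
  circadian/developmental drift visible early in real time courses; it is
  identical in the control and shifted series of a protein, so it cancels
  in expectation from their difference;
* per-blot multiplicative lognormal noise (default CV 0.1; densitometry is
  positive and roughly CV-stable), mean-corrected so the noise factor has
  expectation 1.

Quantification then mirrors the laboratory procedure exactly
(`quantify_relative()`): each replicate is divided by its own 0-min sample
and replicates are averaged — which makes the averaged 0-min value exactly
1 and destroys absolute scale. Everything is reproducible from the seed,
and `run_synth()` writes a provenance JSON sufficient to regenerate the
files byte-identically.

What passing tests on these data do **not** show about real blots: no
loading-control error structure, no blot-to-blot transfer artefacts, no
image saturation, no developmental trends beyond a sinusoid, and noise
parameters that are plausible defaults rather than estimates (no noise
model is published for the real data). The generator's role is to give the
pipeline a truth-known target, not to certify performance on wet-lab data.

## Rate recovery

`fit_rates()` is a recovery harness: least squares on the closed-form
solution via Levenberg–Marquardt, parameters on the log scale (positivity
for free), five starts (log-midpoint of the bounds plus four log-uniform
draws under the seed) to shake off initialization sensitivity, and a
convergence *flag* rather than an exception on failure. From an absolute
noiseless trajectory all four rates are identifiable and recovered to
better than 1%; at 5% multiplicative noise the degradation constants come
back with under 10% median error across 20 seeds (both checked in the test
suite; times 0.25–20 a.u. in steps of 0.5, i.e. 40 points per species —
small enough that the whole suite runs in seconds, large enough that the
estimates are stable). Normalized (relative) series carry no scale
information, so k1 is gauge-fixed at 1 unless supplied, the initial
relative mRNA level becomes an extra parameter, and the result is flagged
`scale_identifiable = FALSE` with the identifiable ratio structure
reported.

## Design choices that were genuinely open

* **Uniform scenario factor.** Only the relative factors matter for the
  scenario comparisons; 0.1 was fixed for the uniform case so that the
  production rates match the other scenarios' post-shift values, keeping
  the four scenarios comparable rate-by-rate.
* **Viscosity.** The temperature dependence of cytosolic viscosity is not
  modelled; η is a user input to `stokes_einstein_D()`. The diffusion
  argument is used qualitatively (D ∝ T at fixed η), and any η(T) model
  would add parameters the analysis never consumes.
* **Fold-change convention.** Fold-changes act on rate constants: a 25-fold
  decrease means k → k/25. Solutions report the multiplicative factor
  (< 1 for down-regulation); reports derive the "fold-decrease" as its
  reciprocal.
* **Transition-time formula.** Implemented as stated (see above) with the
  relaxation-time alternative clearly labelled, rather than silently
  "correcting" the measure.
* **Exactness over generality.** Steady states, compensations and response
  trajectories use closed forms wherever the model permits; the numerical
  integrator exists for piecewise protocols and as the object of the
  oracle-equivalence test, not as the primary computational path.

## Limitations

The model is linear and single-gene: no saturation of ribosomes or
proteases, no resource competition, no feedback, no stochasticity — so
"required fold-change" means required at the level of effective rate
constants, and says nothing about whether the machinery could deliver it in
the cold. The transition-time measure is a heuristic (see the dimensional
caveat). Rates are relative; mapping to wall-clock time or absolute
concentrations needs data the model deliberately does not assume.
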