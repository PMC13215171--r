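---
title: "Modeling calcium-dependent open-channel block of NMDA receptors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling calcium-dependent open-channel block of NMDA receptors}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(blockstate)
```

## The scientific problem

Memantine is an open-channel blocker of NMDA receptors whose potency on
GluN1/2A receptors increases with the intracellular free calcium
concentration [Ca²⁺]ᵢ.  The working hypothesis implemented here is that
this calcium dependence arises because memantine, bound in the channel,
stabilizes a calcium-dependent desensitized (CDD) receptor state.
`blockstate` provides the quantitative machinery for examining that
hypothesis: a kinetic model of gating, trapping block, and CDD; protocol
simulation; a staged fitting pipeline; thermodynamic post-analysis;
the dose-response formulas used for concentration-inhibition, calcium
dependence, recovery from desensitization (RfD), and neuroprotection
curves; and the ligand-optimization-method (LOM) math used to calibrate
the calcium buffers that clamp [Ca²⁺]ᵢ in the first place.

## The kinetic scheme

`build_scheme()` constructs a 22-state continuous-time Markov model laid
out on two planes.  The upper plane holds Ca²⁺-free receptors, the lower
plane Ca²⁺-bound receptors; each plane splits into an unblocked (left)
and a memantine-blocked (right) arm.  Each arm carries a minimal
activation chain — two sequential glutamate bindings (R ⇌ RA ⇌ RA₂), one
gating step (RA₂ ⇌ RA₂\*), and a Ca²⁺-independent desensitized state
(dRA₂).  The Ca²⁺-bound plane additionally carries the CDD state
(cddRA₂), attached to the fully agonist-bound closed state: CDD is
accessible only after ligand binding, which is what makes desensitization
deepen as pipette calcium rises.

Structural contracts, all enforced by tests:

* **Trapping block.**  Memantine binds only to open channels (RA₂\* ⇌
  MRA₂\*); once the channel closes around the blocker, the blocked
  receptor can traverse every state the unblocked receptor can, but the
  blocker cannot leave.  Conducting states are the two *unblocked* open
  states only.
* **Single-site calcium association.**  Every Ca²⁺-free state exchanges
  with its Ca²⁺-bound twin with common rates whose ratio is the 82-nM
  calcium dissociation constant; the individual rates are set arbitrarily
  fast because calcium exchange is not rate limiting.
* **Plane-symmetric in-plane rates** (except the deliberately free
  blocked-arm desensitization entries), so that every plane-crossing
  four-cycle satisfies detailed balance.

The two identical agonist sites carry the standard statistical factors
(2·k₊ for the first binding, 2·k₋ for the second unbinding); a switch
(`statistical_factors = FALSE`) disables them.  At the saturating 1 mM
glutamate used throughout, the choice is kinetically minor.

Default rate constants are the package's calibrated GluN1/2A values at
−65 mV (see `rate_set()`); voltage dependence of block is not modeled
because all protocols are at a single holding potential.

## Simulation: stiff generators and exact propagators

With calcium binding at 10⁶ μM⁻¹s⁻¹ against desensitization rates below
1 s⁻¹ the generator spans eight orders of magnitude, so explicit ODE
stepping on the working grid would be unstable.  Because every protocol
is piecewise-constant in ligand concentrations, the package instead
steps occupancy with the exact matrix-exponential propagator
`expm(Q dt)` of each segment (computed once per segment, applied per
grid step, in compiled code).  This is unconditionally stable and exact
at the grid points; the test suite cross-checks it against a
fine-tolerance `deSolve::lsoda` integration.  Each step re-projects the
occupancy onto the probability simplex, which removes the slow
accumulation of rounding mass (the exact flow conserves it).

Steady states come from the Grassmann–Taksar–Heyman elimination
algorithm, which contains no subtractions and therefore keeps full
accuracy on stiff generators where an SVD null-space solve loses six or
seven digits.  `steady_state()` restricts the solve to the component
reachable from the initial support; under ligand contexts that
disconnect the graph (e.g. ca = 0 makes the lower plane unreachable) the
unreachable part correctly carries zero weight, and in degenerate
multi-class contexts the limit is taken by long-time propagation.

Simulated current is `I = N · P_open · γ(V_m − V_rev)` with γ = 50 pS,
V_m = −65 mV, V_rev = 0 by default, in pA.  The default simulation grid
is 1 ms: the kinetics of interest are on the scale of seconds, so the
experimental 20-kHz sampling is unnecessary.  Solution exchange is
treated as instantaneous; real fast-perfusion exchange is on the
millisecond scale, three orders faster than the kinetics being fit.
Nominally calcium-free ("< 1 nM") pipette solutions are simulated as
ca = 0; with an 82-nM dissociation constant the occupancy error is
about 1%.

## Protocols and trace measurements

* `make_ic50_protocol()` — baseline, agonist to steady state, sequential
  blocker concentrations applied back-to-back in constant agonist, then
  agonist-only recovery.  Blocker applications default to 15 s, inside
  the 10–30 s range used experimentally.
* `make_rfd_protocol()` — conditioning agonist application, then
  alternating agonist-free intervals (default 200, 100, …, 1 s,
  decreasing) and test applications; blocker, when present, is in every
  segment.

Initial occupancy is the steady state of the first (agonist-free)
segment, reflecting the experimental wait after break-in during which
receptors equilibrate with pipette calcium.

Trace measurements mirror the experimental analysis conventions: peaks
are means over a 30-ms window centered on the extremum (searched within
the first 2 s of an application, to avoid chasing plateau noise); steady
states are means over the final 1 s of a segment with the agonist-free
baseline subtracted; `inhibition_table()` forms I_Blocker/I_Glu with
I_Glu the average of pre-blocker and post-recovery steady states, and
rejects traces recovering to less than 85% of the pre-blocker current;
`rfd_peak_series()` normalizes peaks to the 200-s-interval peak and
excludes traces with any normalized peak above 1.2.

## The staged multistart fitting pipeline

Freeing all rate constants at once would leave the model badly
constrained, so fitting proceeds in four steps, each freeing at most two
kinetic rates (plus the amplitude scale N, free in every fit):

1. Ca²⁺-independent desensitization (k_d₊, k_d₋) against a calcium-free
   agonist step.
2. Memantine unbinding and blocked-arm desensitization entry
   (k_M₋, k_dM₊) against a calcium-free concentration-inhibition
   protocol; k_M₊ stays fixed at 30 μM⁻¹s⁻¹ and k_dM₋ is tied to k_d₋.
   Freeing k_dM₊ is what makes the model "asymmetric"; the symmetric
   variant (k_dM₊ forced to k_d₊) fits strictly worse — a nested-model
   inequality the tests assert.
3. CDD entry/exit (k_cdd₊, k_cdd₋) against a high-calcium agonist step.
4. Memantine-bound CDD rates (k_cddM₊, k_cddM₋) against a high-calcium
   concentration-inhibition protocol.

Each step's optimized means are fixed before the next step runs.

Within a step, `multistart_fit()` runs independent trials.  Each trial
multiplies the starting values by lognormal jitter exp N(0, σ²) with
σ = 1.2 — a deliberately wild spread (5th–95th percentile roughly
0.14–7-fold) probing a broad but positive parameter space — and then
chains several runs of a derivative-free local minimizer, each
warm-started from the best parameters so far.  The minimizer operates on
log-rates (positivity without constraints) and combines a
principal-axis-style stage — on the first run a profile search (coarse
grid on one coordinate, Brent line minimization of the other at each
point), on later runs Brent searches along each coordinate — with a
Nelder–Mead simplex polish.  The profile stage exists because the SSE
surface has a flat "pathway-off" plateau (a wild jitter can effectively
disable a desensitization pathway, e.g. by making its exit rate huge),
and a plain simplex started there stalls or wanders; a profile search
sees across the plateau into the true basin.

The amplitude N is profiled analytically (SSE is quadratic in N), which
is exactly equivalent to keeping it free in the optimizer but removes a
search dimension; it is excluded from ensemble intervals.

The objective is the sum of squared differences between the simulated
current and the averaged data trace, each experimental (synthetic) trace
having first been normalized to its own steady state and traces within a
condition averaged.  Ensemble summaries are the across-trial mean and a
two-sided 95% t-based interval, mean ± t₀.₉₇₅,df · SE with df = trials − 1.
Per-trial seeds are `seed + trial_index`, and each pipeline step offsets
the base seed by 100·step, so every ensemble is reproducible.

Thermodynamic post-analysis: `equilibrium_constant()` forms
K = k₊/k₋ for CDD entry with and without memantine bound,
`free_energy()` converts to ΔG = −RT ln K (R = 1.9872×10⁻³ kcal/mol/K),
and `stabilization_energy()` gives the difference.  The temperature
default is 298.15 K — the recordings were at room temperature and the
electrode calibration at 25 °C — which reproduces the −1.04 kcal/mol
free energy of memantine-bound CDD entry from the default rates.  Note
that averaging ΔG per trial and taking ΔG of the mean K differ slightly
for the near-unity K without memantine; the package computes whichever
the caller asks for and treats neither as privileged.

## Dose-response formulas

Four fitters, all plain least squares (no weighting by default; the
experimental analysis is silent on weights, and SEM weighting is easy to
add upstream):

* `fit_hill()` — I_Blocker/I_Glu = 1/(1 + ([B]/IC₅₀)^nH), free IC₅₀ and
  nH.  Bounds keep nH in (0, 6] and IC₅₀ within the data span ×
  [0.01, 100] to prevent runaway fits on degenerate data.
* `fit_ca_dependence()` — Y = min + (max − min)/(1 + ([Ca²⁺]ᵢ/CaEC₅₀)^nH).
  The "< 1 nM" condition enters at ca = 0, where the curve equals max
  exactly.  The upper plateau can be fit (`anchor_max = "free"`, the
  default) or pinned to the lowest-calcium observation
  (`anchor_max = "lowest"`); with a ca = 0 point present the two differ
  negligibly.
* `fit_rfd()` — recovery fit with 1 − A·e^(−t/τ) or the two-component
  analogue; the double exponential is kept only when it improves the
  corrected AIC, since the experimental convention ("single or double")
  names no criterion.  Double fits are summarized by the
  amplitude-weighted τ_w for comparability with single-exponential fits.
  The asymptote is fixed at 1 because the series is self-normalized to
  the 200-s-interval peak.
* `fit_ldh()` — normalized LDH = min + (1 − min)/(1 + ([B]/IC₅₀)^nH)
  after `normalize_ldh()` scales raw LDH release between the vehicle
  (0) and full-insult (1) controls.

## Synthetic data: what it emulates and what it does not

`generate_traces()` emulates whole-cell recordings as
amplitude × clean simulation + iid Gaussian noise + linear drift.
Cell-to-cell variability is confined to a lognormal amplitude factor
(SD 0.3, a typical whole-cell current spread; configurable) because the
fitting convention averages normalized traces within a condition, which
removes amplitude information anyway.  Noise is iid on the working grid
rather than 5-kHz-filtered: SSE fitting of second-scale features is
insensitive to noise color.  The generators are pure functions of
(spec, seed).

What passing tests on these data do show: the pipeline's estimator
machinery is consistent — it recovers generating parameters from data
whose model class it knows.  What they do not show: robustness to model
misspecification (real receptors have more closed states than the
single gating step here), series-resistance or space-clamp artifacts,
or non-stationary noise.  The four-dataset recovery suite uses
single-cell noiseless traces at a 1-ms grid with 3 trials × 3 restarts
— problem sizes chosen to exercise every pipeline stage while keeping
the whole suite desk-scale; the full 10 × 5 configuration is the
package default for real use.

`generate_electrode_series()` emulates the LOM solution design: seven
buffer-free calibration solutions (0.5–10 mM total calcium) and ten
buffered solutions whose free calcium spans 10⁻⁹–10⁻⁶ M around the
buffer's dissociation constant, with Gaussian potential noise
(0.1 mV is a realistic meter resolution).

## LOM calibration

The electrode response is Nikolsky–Eisenman:
ΔE = E⁰ + s·log₁₀([Ca²⁺]_F + Σ), with all potentials referenced to a
fixed calibration solution (E⁰ is fit in that referenced frame).  Buffer
equilibrium is single-site: [Ca²⁺]_T = [Ca²⁺]_F([B]_T + [Ca²⁺]_F + K_d)/
([Ca²⁺]_F + K_d), inverted in closed form by the cancellation-free root
of the binding quadratic.  `fit_lom()` fits E⁰, s, Σ, [B]_T, K_d jointly
by Levenberg–Marquardt with Σ, [B]_T, K_d log-parameterized; buffer-free
rows constrain E⁰ and s, buffered rows the rest.  Joint fitting was
chosen over alternating block iteration because the five-parameter
problem is small and well conditioned under the standard solution
design; the purpose of the method — correcting weighed-in buffer totals
biased by hydration — is exercised by a test that starts [B]_T 10% high
and recovers the true value.  `recipe()` picks the buffer by the
standard ranges (BAPTA below 1 μM free calcium, HEDTA 1–10 μM, NTA
above) and computes the total calcium to add.  This module works in
molar units, as electrode work conventionally does; the kinetic modules
use μM.

## Numerical choices and degenerate inputs

* Grid steps are rounded to whole numbers of `dt_s`; durations that are
  not multiples of the grid are rounded, never truncated to zero.
* Peak windows truncated at segment bounds are flagged (`truncated`
  attribute) rather than silently shortened.
* `free_from_potential()` clamps negative inversions (possible at the
  interference floor under noise) to zero with a `clamped` flag.
* Occupancy vectors are validated to sum to 1 within 10⁻⁹.
* Degenerate dose-response inputs (all fractions near 0 or 1, flat LDH
  curves, non-recovering RfD series) raise errors rather than returning
  unstable estimates; non-monotone calcium-dependence data produce a
  message and proceed, since noise commonly produces small upticks.

## Known limitations

* The single gating step understates peak currents and the speed of
  inhibition onset relative to real receptors; multi-closed-state
  refinements are deliberately out of scope.
* Magnesium competition, voltage-dependent block, and GluN2B/C/D- or
  triheteromer-specific schemes are not modeled.
* The multistart optimizer is local-with-exploration, not a global
  optimizer; with very small trial counts a contaminated trial can
  shift ensemble means, which is why ensembles report intervals.
* Confidence statements are across-trial optimization intervals, not
  sampling-theoretic confidence intervals for the biological parameters.
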