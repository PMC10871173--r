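---
title: "Empirical mean-field modeling with Refractory SoftPlus transfer functions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Empirical mean-field modeling with Refractory SoftPlus transfer functions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rsoftplus)
```

## The problem

Spiking neurons are nonlinear dynamical systems, and a recurrently
connected population of them is far too high-dimensional to analyze
directly. The mean-field route collapses the population to a single
representative neuron: if all neurons and their inputs are
statistically identical and independent, the population is described
by one firing rate $r$, and the only thing one needs to know about the
neuron is its *transfer function* $F(R)$ — the mean firing rate it
produces when bombarded by Poisson synaptic input at total rate $R$.
Analytical transfer functions exist only for special cases (and only
in the diffusion limit of infinitely many, infinitely small synaptic
inputs), so this package takes the empirical route: simulate the
neuron, measure $F$, and fit a cheap parametric form that is accurate
enough to do bifurcation analysis and dynamics with.

## The input model

Synaptic input is a merged pair of Poisson streams: a fraction $\eta$
of events are excitatory, each depositing a postsynaptic potential
(PSP) of $+q_e$ mV, and the rest inhibitory at $-q_i$ mV. We work in
*loose excitatory–inhibitory balance*: $q_i$ is chosen so the mean
synaptic drift is exactly zero and firing is driven by fluctuations
alone, the asynchronous–irregular regime of cortical activity. Writing
the pair in terms of a single effective PSP size $q$,

$$ q_e = q\sqrt{\tfrac{1-\eta}{\eta}}, \qquad
   q_i = q\sqrt{\tfrac{\eta}{1-\eta}}, \qquad
   D = q^2 R, $$

where $D$ (mV²/ms) is the diffusion coefficient of the input. With
$\eta = 0.8$ and $q = 1$ mV this gives $q_e = 0.5$ mV and $q_i = 2$
mV. Transfer curves are sampled on a grid of $S$ rates chosen so $D$
is evenly spaced on $[0, d_{\max}]$; the default $d_{\max} = 100$
mV²/ms drives all three stock neuron models into the tens of hertz,
which is the physiologically interesting part of the curve. (The
$D$-grid convention keeps curves at different $q$ comparable; note
that with $q = 1$ mV it corresponds to input rates up to 100 kHz —
large, but entirely plausible as the summed rate of thousands of
presynaptic neurons.)

For neuron models integrated with current-based synapses the delta PSP
is replaced by an alpha-shaped postsynaptic current whose peak $w =
C_m q / (e\,\tau_{\mathrm{syn}})$ deposits the same total charge, so
results remain comparable across models.

## Measuring transfer curves

Three stock models are simulated in compiled code:

* **LIF** — leaky integrate-and-fire with delta PSPs. Between events
  the membrane decays exponentially, so the event-driven integrator is
  *exact*; it is also the fast path (a 100-point curve at 100 s per
  point takes a few seconds to a few tens of seconds depending on
  $q$). A clock-driven variant exists for cross-checks against
  grid-based simulators.
* **Izhikevich** — the quadratic two-variable model with the canonical
  regular-spiking parameters, alpha PSCs, clock-driven at 0.1 ms.
* **Hodgkin–Huxley** — the standard Na/K/leak scheme (squid-axon rate
  functions shifted to rest near −65 mV, textbook defaults:
  $C_m = 100$ pF, $g_{Na} = 12\,\mu S$, $g_K = 3.6\,\mu S$), alpha
  PSCs with separate excitatory/inhibitory time constants,
  clock-driven at 0.025 ms (the gating dynamics are stiff), spikes
  detected as upward crossings of 0 mV with a 2 ms lockout.

All randomness — Poisson streams included, even inside the C++ loops —
comes from R's RNG, so a single `set.seed()` (or the `seed` arguments)
makes every measurement reproducible.

## The Refractory SoftPlus transfer function

The fitted form is built from the SoftPlus ramp
$\mathrm{sp}(x;\beta) = \beta^{-1}\log(1+e^{\beta x})$ (evaluated as
$x$ exactly once $\beta x > 20$, where the relative error of the
switch is $\approx 10^{-10}$). Because the LIF rate in the diffusion
limit scales with $\sqrt D = q\sqrt R$ rather than $R$, the input is
taken through a square root, and a refractory period is added at the
level of the interspike interval:

$$ F(R) \;=\;
  \Big( T_{\mathrm{ref}} +
  \big[\alpha\,\mathrm{sp}(q\sqrt R - \sigma_0;\,\beta)\big]^{-1}
  \Big)^{-1}. $$

Four parameters: gain $\alpha$, sharpness $\beta$, offset $\sigma_0$,
and refractory period $T_{\mathrm{ref}}$, which imposes the rate
ceiling $1/T_{\mathrm{ref}}$. The function is positive, strictly
increasing in $R$, and has a closed-form derivative (used later for
stability and tangency conditions).

`fit_rsp()` fits the quadruple by bounded Levenberg–Marquardt least
squares on the Hz scale, unweighted. Initial values are read off the
curve (ceiling for $T_{\mathrm{ref}}$, upper-third slope for $\alpha$,
the 1%-of-max crossing for $\sigma_0$); because LM can "converge" in
a degenerate basin (typically $\beta$ collapsing against its bound,
predicting a constant), the optimizer always tries a small
deterministic family of starts and adds jittered restarts while the
best fit is still poor. Fit error is reported as RMS residual divided
by the maximum observed rate (NRMSE). Sigmoid (scaled tanh) and ReLU
baselines are provided for comparison only; the sigmoid saturates and
extrapolates badly, which is much of the motivation for the SoftPlus
form.

```{r example, eval = FALSE}
curve <- measure_transfer_curve(lif_params(), q = 5, eta = 0.8,
                                S = 100, duration = 100, seed = 1)
fit <- fit_rsp(curve)
fit
```

## Mean-field equilibria and bifurcations

A population of neurons, each receiving background Poisson input at
total rate $R_{\mathrm{bg}}$ plus recurrent input from $N$ others
firing at rate $r$, is self-consistent when

$$ r = F(R_{\mathrm{bg}} + N r). $$

`fixed_points()` finds all roots by a dense bracketing scan (2000
points up to 1.2× the refractory ceiling) refined by bisection to
$10^{-6}$ Hz, and classifies each by the feedback gain
$N F'(R_{\mathrm{bg}} + N r^*)$: below 1 stable, above 1 unstable.
For this model family there are 1, 2, or 3 roots, and stability
alternates.

As $N$ grows the consistency curve steepens until a saddle-node
bifurcation creates a bistable pair. `find_bifurcation()` scans
integer $N$ (bisection on the fixed-point count) for the smallest
bistable in-degree, and also solves the continuous tangency system
$F(u) = r$, $(u - R_{\mathrm{bg}})F'(u) = F(u)$ for the exact
tangency. Two caveats shaped this design:

* $N$ is an integer in any actual network, so the primary report is
  at integer resolution: `n_critical` and `r_half`, the member of the
  pair born at `n_critical` whose gain is nearest 1 (the operational
  "half-stable" point of a bifurcation diagram drawn at integer $N$).
* The continuous tangency rate is *hypersensitive*: the pair
  separates as $\sqrt{N - N_c}$, so a half-unit change in $N_c$ —
  well within the run-to-run variation of the fitted parameters —
  moves the tangency rate by several Hz. `r_tangent` is returned, but
  comparisons across refits should expect this sensitivity.

For the stock LIF neuron at $q = 5$ mV and
$R_{\mathrm{bg}} = 0.1$ kHz the pipeline lands the bifurcation at
$N = 51$ with the half-stable point near 34 Hz, and at $N = 55$ the
unstable "watershed" between the two basins sits near 16 Hz; these
numbers are recomputed from scratch by `scripts/acceptance.R` and
asserted (with tolerances reflecting fit stochasticity) in the test
suite. `recurrent_fraction()` reports how much of a neuron's input is
recurrent at a fixed point — useful because the mean-field assumptions
degrade as this fraction approaches 1.

## First-order rate dynamics

`integrate_dynamics()` integrates
$T\,\dot r = F(N r + R_{\mathrm{bg}}(t)) - r$ with a fixed-step RK4
scheme (default step $\min(T/10, 0.1)$ ms). Stationary points coincide
with `fixed_points()` under constant input, and perturbations decay
with the linearized timescale $T/(1 - \mathrm{gain})$. The timescale
$T$ only enters the dynamics — it does not limit the firing rate, one
of the advantages of this transfer-function form — and $T = 1$ ms is
the default for stimulus-following runs, since population rates
respond to input changes much faster than individual membranes.
Stimuli can be constant, steps, or sinusoids of the background rate.
Only first-order (single-population, mean-only) dynamics are
implemented; covariance dynamics and adaptation variables are out of
scope.

## Network validation

`simulate_network()` runs the full recurrent population in compiled
code: static wiring (every neuron draws exactly $N$ distinct
presynaptic partners, never itself; per-edge axonal delays uniform on
1–15 ms) or annealed-average wiring (all-to-all with per-spike
transmission probability $N/M$, which matches the mean input while
destroying temporal correlations). Background input is an independent
Poisson pair per neuron, realized as population-total Poisson counts
multinomially assigned — distributionally identical and much faster.
Warm-up protocols (extra excitatory drive ramping linearly to zero,
default amplitude $R_{\mathrm{bg}}$) let bistable networks reach the
upper basin before recording; warm-up spikes are discarded.

Population traces (1 ms bins, spikes / $M$ / bin width) are
summarized by `fit_ou()` as an Ornstein–Uhlenbeck process: mean,
stationary sd $\sigma$, and a lag-1-autoregression timescale
$\Delta/(1-\hat\rho)$ (which matches $-\Delta/\log\hat\rho$ for
smooth traces and degrades gracefully to the bin width for white
noise). Across population sizes the fluctuation amplitude scales
close to $M^{-1/2}$, as the central limit theorem suggests;
`fluctuation_scaling()` fits $\sigma = k M^{-1/2}$ and reports the
unconstrained log-log slope as a diagnostic. `practical_stability()`
estimates the probability that a warmed-up bistable network keeps its
100 ms trailing-mean rate above the watershed for a whole recording.

## What the simulations do and do not show

The synthetic data here *is* the study system — there is no external
data — and the generator's defaults are the study conditions: LIF
with a 15 mV threshold distance, 10 ms membrane time constant, 2 ms
refractory period; $\eta = 0.8$ except where symmetric input
($\eta = 0.5$) is used for fit-convergence and generalization runs;
$S = 100$–500 rates at 100 s per point. Randomized-parameter sweeps
draw $T_{\mathrm{ref}} \sim \mathrm{Exp}(2\,\mathrm{ms})$ for LIF
(membrane capacitance does not enter delta-PSP dynamics and is not
varied), uniform ranges over the original published intervals for
Izhikevich, and exponential/normal draws for the HH time constants
and capacitance.

Problem sizes in the tests and the acceptance script are chosen for a
desk-scale run: transfer curves at $S = 100$, $T = 100$ s (reference
curves up to 1000 s), networks at $M \le 10^4$ with a handful of
repetitions, sweeps at tens rather than thousands of draws. These
sizes make the stochastic tolerances in the tests what they are; the
pipeline itself runs unchanged at larger sizes.

Known limitations found while validating:

* Clock-driven integration at 0.1 ms underestimates event-driven
  rates by 1–2% at the top of the grid (events within a step are
  aggregated before the threshold check). The mean-field fits use the
  exact event-driven path; network simulations are clock-driven, so
  network equilibria inherit a small downward bias relative to the
  fitted model, partially offset by correlation effects.
* Static-wiring networks at small $M$ (shared presynaptic pools) run
  measurably hot relative to the mean-field fixed point (~10% at
  $M = 10^3$ for the monostable condition, <1% at $M = 5000$), and in
  the strongly recurrent bistable condition (97–99% recurrent input)
  the static network settles into a strongly heterogeneous
  frozen-rate state whose population mean sits well above the
  mean-field upper branch. Replaying a neuron's actual presynaptic
  spikes through the standalone integrator reproduces its in-network
  rate, so this is a property of the system, not of the delivery
  machinery; annealed wiring removes it. Mean-field conclusions in
  the high-recurrence regime should therefore be validated with
  annealed controls.
* The OU timescale estimator carries an $O(\Delta/\tau)$
  discretization bias (~5% at $\tau = 10$ ms with 1 ms bins); mean
  and $\sigma$ are unbiased.

## Numerical choices

Degenerate inputs are handled explicitly: all-zero transfer curves
yield a flagged non-converged fit; constant population traces yield
$\sigma = 0$ with an undefined timescale; $\eta \in \{0, 1\}$ is
rejected for balanced sizing (the balance equations are degenerate)
but allowed for raw stream generation; $q = 0$ makes the rate grid
undefined and is an error. Root scans use 2000 points before
bisection; near-tangent pairs closer than the scan resolution are
reported as the tangency they numerically are. The SoftPlus cutoff
$\beta x = 20$ is configurable but matches the accuracy analysis
above. Blow-ups in the stiff integrators (Izhikevich under extreme
weights) raise diagnostic errors rather than returning garbage.
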