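---
title: "Methods: closed-loop identification of tracking behavior"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: closed-loop identification of tracking behavior}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(loopid)
```

## The identification problem

A tracking task presents two exogenous inputs per movement axis — a target
reference $r(t)$ and a cursor disturbance $d(t)$ — and records one output,
the displayed cursor $y(t)$. The subject's hand motion is modeled as the sum
of a feedforward pathway $PF$ (controller cascaded with the motor plant,
driven only by the target) and a feedback pathway $PB$ (driven by the
perceived cursor–target error). Closing the loop,

$$Y = \underbrace{\frac{PF + PB}{1 + PB}}_{H_{YR}} R +
      \underbrace{\frac{1}{1 + PB}}_{H_{YD}} D,$$

so two measured closed-loop responses determine both open-loop pathways:
$PB = H_{YD}^{-1} - 1$ and $PF = H_{YD}^{-1} H_{YR} - H_{YD}^{-1} + 1$. The
identification is per axis and scalar: the two movement axes are analyzed
separately (off-axis responses are negligible in this task design), so the
identity matrix of the multivariable formula reduces to 1.

Everything rests on three assumptions: (i) the subject behaves linearly and
time-invariantly at the stimulus frequencies over a trial; (ii) the
reference and disturbance excite disjoint frequency sets, so their
contributions to $y$ separate exactly in the frequency domain; and (iii)
any response power not linearly related to the stimuli (the *remnant*)
averages out across trials.

## Stimulus design

The frequency grid is the first 20 prime multiples of a 0.04 Hz base
(0.08–2.84 Hz). Primality guarantees no grid frequency is an integer
multiple of another, so harmonics produced by mild nonlinearities never land
on another probe frequency, and assumption (ii) is enforced by construction.

Component amplitudes follow
$M(f) = \min(v/f,\; M_{\max})$ with $(v, M_{\max}) = (1.3\ \mathrm{cm\,s^{-1}},
2.3\ \mathrm{cm})$ for the reference and $(0.7, 1.5)$ for the disturbance.
The *min* form is deliberate: it is the unique reading under which both the
positional cap ($M \le M_{\max}$) and the peak-velocity cap
($2\pi f M \le 2\pi v$) hold simultaneously across the grid, which is the
stated contract of the design. Phases are drawn uniformly on $[0, 2\pi)$
from a seeded generator, per trial.

The 20 frequencies are partitioned into four groups of five by round-robin
over ascending frequency (index mod 4), so every group spans the band. A
session is 16 trials: a 4-row rotation of (reference, disturbance) group
assignments to the x and y axes — in which each group visits each axis and
a reference group never shares an axis with the same-index disturbance
group — crossed with the two preview conditions (0/500 ms) and repeated
twice, in seeded pseudo-random order. Pooled over a session, every grid
frequency is measured in both channel roles on both axes in both
conditions. The exact frequency-to-group assignment of the original
experiment is not recoverable from the published material; round-robin is
the package's choice and is isolated in `frequency_groups()` so an
alternative partition is a one-line change.

Trial duration defaults to 75 s with the first 25 s (one base period)
discarded before estimation. The duration is not stated in the source
experiment's text; three base periods keeps every single-frequency DFT
leakage-free after the discard while holding the simulated session to a
few seconds of compute.

## The synthetic-subject generator

Because the stimuli are finite sums of sinusoids and the subject model is
linear, the steady-state response is available in closed form: each
stimulus component appears in $y$ scaled by $|H|$ and shifted by
$\arg H$. `simulate_trial()` therefore performs frequency-domain
superposition rather than time-stepping a delay-differential equation —
the simulated record is the exact steady state, with no integration error
and no transient, which makes the simulator usable as a machine-precision
oracle for the estimation code. The 25 s discard window still applies
whenever remnant noise is enabled.

Generator defaults are the study conditions: group parameter sets
(feedforward gain 0.6 with 185/245 ms delays; feedback leaky integrator
with gains 1.3/1.0, delays 123/144 ms for control/ataxia), pole
$a = 0.5$ rad/s (the pole's value was never reported; 0.5 is the package's
fixed choice, and every counterfactual conclusion is conditioned on it),
80 Hz sampling, and the 16-trial session. Remnant is modeled, when enabled,
as white Gaussian noise added to the displayed cursor; real remnant is
colored and partly multiplicative, so remnant-on tests demonstrate
robustness to *a* noise model, not to physiological noise in full. The
preview filter of a synthetic subject defaults to a pure time advance with
a first-order roll-off (stronger advance and later roll-off in the control
group), which reproduces the qualitative preview phenomenology — phase
lead at low frequency, gain attenuation at high frequency, reduced
tracking error — without claiming the true filter's parametric form.

What passing tests on synthetic data do **not** show: that a human's
pathways are well described by these structures, that the remnant is
white, or that the preview filter is first order. They show the *pipeline*
is exact on data that satisfies its assumptions and unbiased under the
modeled noise.

## Estimation and fitting

FRFs are estimated per frequency as the ratio of single-frequency DFT
coefficients of output and input, using a sine-phasor convention in which
the coefficient $c$ means $|c|\sin(2\pi f t + \arg c)$. Repeated
measurements are pooled by the complex mean — phasor averaging, which is
unbiased under additive remnant, unlike averaging magnitudes and phases
separately. A missing (frequency × channel × axis) cell is a hard coverage
error, not an NA.

Candidate structures are fitted by minimizing the squared complex residual
summed over the grid (unweighted), using Nelder–Mead from 100 random
restarts drawn uniformly in the parameter box $k \in (0, 5]$,
$\tau \in [0, 0.6]$ s, $a \in (0, 20]$ rad/s (bounds are the package's
choice; none were published). The delay enters through the complex
exponential, so no phase unwrapping is involved in fitting. Restarts guard
against the residual's delay-induced local minima; the winning restart is
re-polished at tighter tolerance. Structure selection uses
leave-one-subject-out cross-validation: fit on the complex mean of the
remaining subjects, score on the held-out subject, average. Among
structures within 5% of the smallest CVE the fewest-parameter one wins
(the 5% parsimony band is configurable; "as simple as possible" is
inherently qualitative).

Two numerical tie-break rules matter. First, FD errors are compared with
the same 5% relative tolerance plus an absolute floor of $10^{-10}$
(squared-norm units): the generic first-order lag family mathematically
contains the leaky integrator, so on leaky-generated data both drive CVE
and FD error to numerical zero and only the declared candidate order can
(deterministically) separate them — the McRuer-style structure is declared
first for the feedback pathway. Second, isolation refuses near-singular
inversions ($|H_{YD}| \le 10^{-8}$) with an error rather than
regularizing, because silent regularization would bias the fitted delays.

## Preview-filter extraction

The two-channel form $PH_B = H_{YD}^{-1} - 1$, $PH_R = H_{YD}^{-1} H_{YR}$
(satisfying $PH_R = PF + PB$) is computed in both preview conditions; the
preview filter is the nonparametric per-frequency ratio
$M = PH_P / PH_R$. The assumption that preview leaves the feedback loop
unchanged is *checked*, never imposed: the ratio $PH_{BP}/PH_B$ is stored
with every estimate and a deviation beyond 20% anywhere on the grid raises
a warning. An optional 3-point complex moving average for $M$ exists but
is off by default. Applying $M$ componentwise to a sum-of-sines reference
reconstructs the filtered (smoothed, time-advanced) trajectory subjects
effectively track under preview.

## Stability margins and counterfactuals

Margins are computed from the open feedback loop $PB$. Measured FRFs are
first smoothed by window-averaging magnitude and *unwrapped* phase
(endpoints untouched; window default 3, the source description gives only
"a specified window size"); unwrapping is essential because a pure delay
drives the wrapped phase across −180° spuriously. Crossovers are located
by linear interpolation of log-magnitude and of phase against
log-frequency; parametric models are evaluated on a 1000-point log grid
over 0.01–20 Hz, wider than the stimulus band because short-delay loops
cross −180° above 2.84 Hz and the interpolation needs the crossing
bracketed. Absent crossings yield sentinels (gain margin `Inf`, phase
margin `NA`), not errors. The interpolation path is validated against a
closed-form/root-finding oracle to within 0.1° and 0.01 across random
loops.

The gain-swap counterfactual replaces only the feedback gain $k$ and
re-simulates identical stimuli. The phase margin exists only when the loop
reaches unit gain, which for the leaky integrator requires $k > a$; the
default pole sweep for the directional claim (both margins shrink when the
ataxia-parameterized loop receives the control-level gain) is therefore
$a \in \{0.1, 0.25, 0.5, 0.75\}$ rad/s, below the smaller gain. The
tracking-error side of the counterfactual is reported as simulated MSE;
only the direction of effects is meaningful, since the true pole and
remnant spectrum are unknown.

## Problem sizes

The shipped tests and the acceptance script use: 16-trial sessions at
80 Hz × 75 s; cohorts of 2–4 identical noise-free subjects per group for
cross-validation checks; 100 optimizer restarts for headline fits and
25–40 for Monte-Carlo and selection sweeps (the noise-free recovery tests
confirm the smaller restart counts reach the same optima for these 2–3
parameter structures); 20 Monte-Carlo seeds at remnant SD 0.1 cm for the
delay-bias check; and 100 random loops for the margin-oracle sweep.

## Known limitations

* The plant and the individual controllers are not identifiable from this
  experiment; only the cascades $PF$ and $PB$ are estimated, and all
  structural claims are claims about cascades.
* The integrator pole is unreported in the source material; counterfactual
  margins are conditioned on the configured value.
* The generator is linear and stationary by construction; adaptation,
  direction-dependent limb dynamics, and proprioceptive feedback are out
  of scope.
* Preview is modeled as a reference-side filter only; how preview duration
  (other than the 500 ms design value) shapes $M$ is not modeled.
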