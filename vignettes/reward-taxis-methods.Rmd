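---
title: "Methods: dopamine fold-change detection and reward-taxis"
author: "rewardtaxis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: dopamine fold-change detection and reward-taxis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rewardtaxis)
```

# The circuit model

Phasic dopamine is modelled as the output of a two-variable circuit driven
by the logarithm of expected reward $R(t) > 0$:

$$\dot d = \omega_d\,(C + \mu \log R - \alpha g - d), \qquad
  \dot g = \omega\,(d/d_0 - 1).$$

$d$ is dopaminergic and $g$ GABAergic population activity (spikes/s).
The second equation is integral feedback: $g$ accumulates whenever $d$
deviates from the homeostatic level $d_0$, so the only steady state has
$d = d_0$ regardless of the input level (*exact adaptation*), while
$g_{st} = \alpha^{-1}(C - d_0 + \mu\log R_0)$ tracks the log input.
Because the input enters only through $\mu \log R$, rescaling the input
$R \to \lambda R$ can be absorbed into $g' = g + \alpha^{-1}\mu\log\lambda$,
leaving the $d$-dynamics unchanged: the circuit is a *fold-change detector*
(FCD). All response properties therefore depend on relative, not absolute,
reward changes — the mechanism behind scale-invariant responses to rewards
delivered after probabilistic cues, where delivery is always a $1/p$-fold
input step whatever the magnitude.

Default constants (`circuit_preset()`): $\omega_d = 50$ /s,
$\omega = 15$ /s (mouse; 100 and 30 for the primate set), $C = 15$,
$\mu = 6$, $d_0 = 5$ spikes/s, $\alpha = 0.7$. The intended regime is
$\omega_d \gg \omega$; the constructor warns (but does not fail) outside
it.

Four variants are provided:

* `feedback` — the two-ODE system above (default).
* `feedforward` — an incoherent feed-forward loop,
  $\dot g = \omega((C + \mu\log R)/\alpha - g)$ with
  $\dot d = \omega_d(d_0 + C + \mu\log R - \alpha g - d)$; same exact
  adaptation and FCD properties, used to show the conclusions do not hinge
  on the feedback wiring.
* `quasi_static` — the fast-dopamine limit $d = C + \mu\log R - \alpha g$
  with only $g$ integrated. This is the same elimination used in the
  model's analytical treatment; the separation of timescales is a
  convenience, not a load-bearing assumption.
* `rectified` — a non-negative variant with drive
  $\max(0, C + \mu\log R - \alpha g - k_d)$. The published description of
  this variant is typographically ambiguous; we implement the reading in
  which the implicit relation $d = (C + \mu\log R - \alpha g)\,d/(d+k_d)$
  is resolved at its non-negative fixed point $d = \max(0, f - k_d)$.
  This keeps $d \ge 0$ along all trajectories and, from adapted starts,
  the adapted $g$ absorbs $k_d$ exactly, so it reproduces the linear
  model whenever no clipping occurs. This is documented as an
  interpretation, not asserted as the original intent.

The linear variants are allowed to go negative on strong omissions; this
is a known limitation of the log-linear description and the reason the
rectified variant exists.

## Numerics

`simulate_circuit()` integrates with `deSolve::lsoda` (adaptive, default
`rtol = atol = 1e-10`) piecewise between the discontinuities declared by
the input signal, restarting the integrator at each break so steps are
exact discontinuities rather than smoothed ramps. Cue/reward protocols are
therefore resolved without artificial rise times. The response-amplitude
convention is the signed extremum of $d - d_0$ in a window (peak firing
change). The step response of the linearised system is a difference of two
exponentials with rates given by
$\lambda^2 + \omega_d\lambda + \omega_d\omega\alpha/d_0 = 0$; the test
suite uses this closed form as an independent oracle for the simulated
peak amplitude.

# Inputs: signals and fields

Temporal inputs are strictly positive `reward_signal` objects carrying
their discontinuity times: unit steps $R_0 + \lambda\theta(t-t_0)$,
cue–reward schedules ($R_{pre} \to p(b+\lambda u) \to b+\lambda u$, with
omission modelled as a drop back to the pre-cue baseline — the published
protocol does not specify the post-omission level further), and
alternating $X \pm Y$ schedules. Trial orders are generated with a seeded
RNG.

Spatial inputs are `reward_field` objects with analytic log-gradients
(validated against central differences at $10^{-6}$ relative tolerance in
the tests): a two-Gaussian field
$R(x) = R_1 e^{-(x-x_1)^2/2b_1^2} + R_2 e^{-(x-x_2)^2/2b_2^2}$ and an
exponential-decay approach field $R(x) = e^{-\gamma x^h}$
($\gamma = 0.04$, $h = 1.5$ by default). The published two-Gaussian form
prints the first peak with width $2b$; since the exact shape is
immaterial for matching, the package defaults to symmetric widths and
keeps the asymmetric form as an option (`widths = "asymmetric"`).

# The reward-taxis agent

`simulate_taxis()` closes the loop: the circuit is driven by $R(x(t))$
along the path (state carried continuously, never reset at tumbles) and
dopamine modulates locomotion, either through speed,
$v = v_0 (d/d_0)^h$ clipped at zero (default, $h = 1$), or through the
tumble rate $\tau^{-1} d_0/d$ at fixed speed. Tumbling is a per-step
Bernoulli realisation of a Poisson process with mean run duration $\tau$;
fresh headings are uniform ($\pm 1$ in 1D), with an optional correlation
with the previous heading. Default step $dt = 5$ ms, i.e. $\tau/dt = 20$
sub-steps per run; the fast $d$-equation uses an exact exponential update
per step and the integral feedback a trapezoidal one, so the circuit
remains stable and exactly adapted for any $\omega_d$.

Simulations on Gaussian fields run in a reflecting box four times the
peak separation across (well beyond the stated minimum of three), which
leaves statistics near the peaks unaffected; unbounded motion is
available with `box = "none"`.

## Coarse-graining and the matching exponent

Over many runs the agent's motion approximates the Langevin dynamics

$$dx = \chi \nabla \log R\, dt + \sqrt{2D}\, dW, \qquad
  D \approx m^{-1} v_0^2 \tau, \quad \chi \approx D\, h\mu/d_0,$$

whose stationary law is $P(x) \propto R(x)^{\beta}$ with
$\beta = \chi/D = h\mu/d_0$. Between two reward peaks this is exactly the
generalized matching law $P_1/P_2 = k (R_1/R_2)^\beta$ with $k = 1$; a
multiplicative preference bias on one option moves $k$, not $\beta$.

The mapping holds when dopamine relaxation is fast compared with runs and
runs are short compared with adaptation
($\omega_d^{-1} \ll \tau \ll d_0/\omega\alpha$). This matters
quantitatively: outside the regime the emergent sensitivity is attenuated,
to linear order by
$\omega_d\lambda / (\lambda^2 + \omega_d\lambda + \omega_d\omega\alpha/d_0)$
with $\lambda = 1/\tau$, the finite-run-time and finite-relaxation
correction. With the measured mouse rates
($\omega_d = 50$, $\omega = 15$ /s, so adaptation time $\approx 0.48$ s
against $\tau = 0.1$ s) the run-and-tumble experiment yields
$\hat\beta \approx 0.55$ rather than $\mu/d_0 = 0.8$ — mild undermatching,
the direction most commonly observed empirically, and consistent with the
prediction that longer runs reduce $\beta$ proportionally. Conversely,
pushing adaptation much slower than the field-traversal time lets a
quasi-static speed profile build up and over-concentrates the agent
(overmatching).

`matching_default_circuit()` therefore fixes the matching experiment's
circuit once, in the regime the theory assumes: the quasi-static variant
with adaptation rate $\omega\alpha/d_0 = 1$ /s, a ten-fold separation on
either side of the run rate ($10$ /s) and of the well dynamics. With
$\mu = 4$, $d_0 = 5$ this recovers $\hat\beta \approx 0.75$–$0.78$ with a
95% CI that covers $0.8$ at the default budget; the residual percent-level
shortfall is the remaining $O(\omega\alpha\tau/d_0)$ correction, which we
report rather than hide. The Langevin engine, which implements the
coarse-grained equation directly, recovers $\beta = 0.8$ without this
bias.

## Experiment design and estimator

`run_matching_experiment()` sweeps reward ratios
$\{1/8, 1/4, 1/2, 1, 2, 4, 8\}$ with 10 seeded replicates of
$2\times10^4$ s each (the durations give hundreds of visits to the rarer
window at the most extreme ratio). Replicates start alternately at either
peak, adapted to the local input; the first 20% of each path is discarded
from the occupancy accumulators as equilibration (doubling the burn-in
does not move the estimates). Residence times are accumulated at full
resolution within $\pm 2.5$ cm of each peak. $\hat\beta$ and
$\log\hat k$ come from unweighted OLS of per-replicate
$\log(P_1/P_2)$ on $\log(R_1/R_2)$ — nothing in the protocol fixes a
weighting, and the log-log relation is linear — with weighted options
exposed.

`simulate_langevin()` is plain Euler–Maruyama with fixed step
(default 10 ms; halving the step moves the fitted exponent by well under
its standard error) and seed-deterministic Gaussian increments. Its
`drift_mode = "gradR"` control replaces $\nabla\log R$ by $\nabla R$,
which destroys the power law (the log-occupancy slope then varies several
fold across reward ratios) — logarithmic sensing is what produces
matching.

# Temporal-difference learning of log-values

The learner is tabular. The logarithmic value table is updated with

$$\log V(s) \leftarrow \log V(s) + \alpha\,(e^{\delta_{\log}} - 1),
\qquad \delta_{\log} = \log(r + \gamma V(s')) - \log V(s),$$

implemented in the algebraically identical ratio form
$\alpha((r + \gamma V(s'))/V(s) - 1)$, which remains defined when
$r + \gamma V(s') = 0$ (an unrewarded Bernoulli trial at the terminal
transition: $e^{\delta_{\log}} = 0$); negative targets are a domain
error. The expected update vanishes exactly at the classic TD fixed point
$V(s) = E[r + \gamma V(s')]$, and for small errors the rule linearises to
classic TD on the log scale. Multiplying all rewards by $\lambda$ maps the
entire learning trajectory to itself shifted by $\log\lambda$ — the
learning-side face of fold-change detection — and the converged values
feed the circuit's response formula
$\Delta d = \mu(\log(r + V(s')) - \log V(s))$.

Chain-task conventions: states $S_1 \ldots S_N$ ($N = 5$), reward drawn
only at the terminal transition with $V(\text{terminal}) = 0$;
$\log V$ initialised at 0 ($V = 1$; convergence is insensitive to the
initialisation); learning rate $\alpha = 0.02$; reward models
deterministic, normal with CV 0.3, and Bernoulli. The discount factor is
not pinned by the chain protocol itself, so the analytic convergence
target $\log(\gamma^{N-1} E[r])$ is used with the configurable default
$\gamma = 0.9$.

# Dose–response calibration

`fit_log_response()` fits $\Delta d = \mu\log(a u + b)$ to
reward-magnitude/response tables by Levenberg–Marquardt nonlinear least
squares (`minpack.lm::nlsLM`) with five jittered starts; when cued rows
are present a single subtractive constant is fitted jointly. The
logarithm is natural — the base is not identified and only rescales
$\mu$. The three-parameter form is identifiable on four or more distinct
magnitudes; the generator's default seven-magnitude grid
(0.1–20, roughly geometric) emulates the published design. Synthetic
recovery from the published best-fit constants
($a = 0.5$, $b = 1.5$, $\mu = 4.9$, subtraction 3.2, noise SD 0.2
spikes/s) is unbiased to within 2 standard errors of the Monte-Carlo mean
over 500 replicates (relative bias under 5% for every parameter). Real
recordings are not bundled; only synthetic recovery is claimed.
Power-law and Hill alternatives are out of scope (they are not
distinguishable on data of this kind).

# What the synthetic experiments do and do not show

The generators emulate the *structure* of the source experiments —
step and cue/reward inputs, two-option reward fields, fixed-mean reward
draws, log-curve response tables with Gaussian noise — under exactly the
printed parameter values where available. They do not emulate neuronal
heterogeneity, learning of the field inside the navigation loop (fields
are given, as in the matching analysis), spiking noise, or behavioural
confounds; passing tests therefore validate the implementation and the
internal consistency of the theory, not its fit to any new biological
data.

# Problem sizes

Defaults were chosen so a full check runs on a laptop-class single core:
matching experiments use $7 \times 10$ replicates of $2\times10^4$ s
(4 million agent steps each, compiled loop); the stationary-law
comparison pools 16 Langevin paths of $10^5$ s; drift validation uses
1500 short paths; the TD chain runs 8000 episodes; dose–response
recovery uses 500 Monte-Carlo replicates. The acceptance script doubles
the matching replicate counts to halve the slope standard error.

# Known limitations

* $d$ and $g$ are population rates; no spiking or network structure.
* The linear variants admit negative $d$ on strong omissions (use the
  rectified variant where positivity matters).
* The run-and-tumble exponent carries the finite-run-time correction
  discussed above; with measured adaptation rates the model predicts
  systematic undermatching relative to $\mu/d_0$.
* Matching experiments are one-dimensional as in the source protocol;
  the simulators accept $m \le 3$ but the stationary-density helper is
  1D.
* $\omega_d$, $\omega$ are taken as given; no fitting to recordings.
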