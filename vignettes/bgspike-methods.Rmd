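---
title: "The bgspike model: equations, numerics and design choices"
author: "bgspike authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The bgspike model: equations, numerics and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(bgspike)
```

# The model

`bgspike` simulates the subthalamic nucleus (STN), the external and
internal globus pallidus (GPe, GPi) as three 50×50 lattices of Izhikevich
neurons, with the striatum reduced to Poisson spike pools. The circuit
wiring is the classical basal-ganglia motif without the GPe→GPi and
cortex→STN routes: D2 striatum inhibits GPe, D1 striatum inhibits GPi,
STN and GPe are reciprocally coupled one-to-one, STN excites GPi, and
both STN and GPe carry within-nucleus Gaussian lateral collaterals.
Dopamine (a scalar `DA` in [0.1, 0.9]) modulates the striatal gains, the
STN–GPe projection weights, and the lateral kernel widths; in the bandit
task it is itself computed from the reward-prediction error.

## Neurons

Each neuron follows the two-variable Izhikevich model,

$$\dot v = 0.04 v^2 + 5v - u + 140 + I_{ext} + I_{syn}, \qquad
  \dot u = a (b v - u),$$

with the spike rule $v \ge 30\,\mathrm{mV} \Rightarrow v \leftarrow c,\;
u \leftarrow u + d$. Parameters (Table of `izhikevich_params()`): STN
$a=0.005, b=0.265, c=-65, d=1.5, I_{ext}=30$ — a slowly recovering cell
with post-inhibitory rebound; GPe and GPi $a=0.1, b=0.2, c=-65, d=2$
with $I_{ext}=10$, tonically active pacemakers. Integration is forward
Euler at `dt = 0.1` ms (configurable; single-neuron rates converge
within 5% between 0.1 and 0.05 ms, which the test suite checks).

## Synapses

Every projection is an exponential gating synapse
$\tau\,\dot h = -h + S(t)$ with current $I = W h (E - V)$; NMDA currents
are additionally multiplied by the Jahr–Stevens magnesium block
$B(V) = 1/(1 + (\mathrm{Mg}/3.57)e^{-0.062V})$. Receptor constants:
$\tau_{AMPA}=6$, $\tau_{NMDA}=160$ ($67$ onto GPi), $\tau_{GABA}=4$ ms;
$E_{AMPA}=E_{NMDA}=0$, $E_{GABA}=-60$ mV. Projection weights:
$w_{sg}=1$, $w_{gs}=20$ (both scaled by $(1-0.1\,DA)$),
$w_{STN\to GPi}=1.15$, $W_{StrD1\to GPi}=0.8$, $W_{StrD2\to GPe}=1$.
The striatal currents carry the dopamine gains
$cD1 = 10/(1+e^{-7.5(DA-1)})$ (direct pathway, grows with dopamine) and
$cD2 = 7.5/(1+e^{7.5\,DA})$ (indirect pathway, collapses with
dopamine).

### The spike impulse convention

The presynaptic spike train enters the gating equation as an impulse on
the step it occurs. The package default makes the impulse an area-one
density (amplitude $1/dt$), so a spike raises $h$ by $1/\tau$ and the
stationary mean of $h$ equals the presynaptic rate in spikes/ms
*independently of the integration step*. The alternative "unit"
convention (amplitude 1) makes every synaptic current proportional to
`dt`: at `dt = 0.1` ms the circuit is then effectively uncoupled, and no
refinement of `dt` can converge to a coupled limit. A MATLAB-style
Euler loop at `dt = 1` ms with binary spikes is numerically identical to
the density convention at that step, so the density convention is also
the natural reading of the original coupling strengths.

### Synaptic delay

All neuron-to-neuron projections (including collaterals) carry a uniform
transmission delay, `delay_ms = 3.5` ms by default. The delay is load
bearing: with an effectively instantaneous coupling the strongly coupled
GPe lattice settles into an asynchronous splay state at every dopamine
level, whereas a few-millisecond delay — standard in STN–GPe network
models, and comparable to GABA-A rise plus conduction times — lets the
mutual inhibition organize into lattice-wide synchronized volleys. The
delay is a biophysical constant and does not vary with dopamine.

## Dopamine-dependent lateral kernels

Collaterals are Gaussian stencils
$w_{ij,pq} = A_m e^{-d^2_{ij,pq}/R_m^2}$ over an $n_{lat}\times n_{lat}$
neighborhood (5×5 for STN with $A_{STN}=0.2$, 11×11 for GPe with
$A_{GPe}=1$), self term excluded. The width $R_m$ is the dopamine
lever. The published form of the width mapping
($R_s = r_s\,cD21\cdot DA$ with $cD21=0.1$) yields widths of 0.01–0.09
for STN at every dopamine level, i.e. nearest-neighbour weights of order
$e^{-100}$: literally zero, for STN and GPe alike, so as printed the
mapping carries no dopamine dependence at all. The package therefore
treats the mapping as a named strategy (`lateral_mapping` in
`circuit_config()`): `"as_printed"` and the direction-swapped
`"swap_cd21"` are available for comparison, and the default is a
calibrated linear interpolation

$$R_s = r_s\,(1.04375 - 0.4375\,DA), \qquad
  R_g = r_g\,(6.475 - 4.75\,DA),$$

i.e. STN width 1.0→0.65 and GPe width 3.0→1.1 as dopamine goes
0.1→0.9. The two endpoint pairs are the only calibrated quantities in
the package. They were chosen once, before the acceptance measurements
were frozen, so that the free-running STN–GPe loop traverses the
reported regimes: at low dopamine the wide, strong GPe lateral
inhibition (with the transmission delay) locks the lattice into global
inhibition volleys — GPe nearly perfectly phase-locked, STN entrained,
a slow population rhythm near 10 Hz, GPe rate held near 70 Hz well
below its 130 Hz autonomous rate; at high dopamine the narrow kernels
leave both lattices asynchronous, GPe accelerates toward 150 Hz and the
added GABA load slows STN below 50 Hz. Both kernel widths *shrink* with
dopamine; the dopamine–synchrony relation is carried by the loss of the
volley-generating GPe coupling, not by a growth of inhibition.

### Kernel boundary

The default lattice is toroidal (`boundary = "wrap"`). With clipped
stencils, edge neurons receive as little as a quarter of the lateral
input of interior neurons; that built-in heterogeneity caps the
attainable order parameter near 0.75 and the fully synchronized regime
never forms. `"clip"` remains available.

## Initial conditions and burn-in

Membrane potentials start at $c + U(0, \mathrm{jitter})$ mV
(`jitter = 5` by default) with $u = b v$; the synchronized low-dopamine
state is reached dynamically from these dispersed starts within a few
hundred milliseconds. Summary metrics discard the first 100 ms
(`burn_in`); spectral analysis uses a 500 ms burn-in because the volley
attractor takes 300–400 ms to form and the forming transient leaks
low-frequency power into the 2–30 Hz band.

# Analysis metrics

Spike phases are linear interpolations between consecutive spikes
(neurons without a bracketing spike pair are excluded rather than given
phase zero), sampled every 1 ms; the Kuramoto order parameter
$R e^{i\theta} = N^{-1}\sum_j e^{i\phi_j}$ is averaged over the
post-burn-in window. The population oscillation frequency is the
largest 2–30 Hz peak of a modified-Daniell-smoothed periodogram of the
mean-subtracted 1 ms population spike count; a peak counts only if it
exceeds three times the median in-band power. (On a raw periodogram the
same rule is vacuous — the in-band maximum of white noise exceeds three
times the median almost surely — which is why the smoothing is part of
the definition.) Explore/exploit synchrony groups are compared with the
classical pooled two-sample t-test.

# Tasks

## Binary action selection

250 ms trials; stimuli of 4 Hz (stimulus #1) and 8 Hz (stimulus #2) are
delivered to the two lattice halves as fully correlated Poisson trains
during 100–200 ms, 1 Hz uncorrelated background otherwise. GPi half-pool
rates are smoothed over a trailing 10 ms window, normalized and reversed
per window, $f_k = (f_{max}-f'_k)/f_{max}$ with $f_{max}$ the largest
pool rate in that window, and integrated by the race
$\dot z = -z + f$; the first accumulator to cross 0.15 selects. The
whole-trial averaging variant of the pool rate would make the race
deterministic; the sliding window is what lets GPi rate dips drive
probabilistic selection. Trials are independent (fresh network state
per trial).

## Four-armed restless bandit

Arm means follow the decaying Gaussian random walk
$\mu_{k+1} = \lambda_m \mu_k + (1-\lambda_m)\theta_m + e$; the walk
parameters are not part of the circuit model and default to the
restless-bandit convention of the human decision-making literature
($\lambda_m = 0.9836$, $\theta_m = 50$, $\sigma_d = 2.8$,
$\sigma_0 = 4$), payoffs rounded and clipped to [0, 100]. Cortico-
striatal weights start at 50 and update by
$\Delta w^{D1} = \eta\,\delta$, $\Delta w^{D2} = -\eta\,\delta$
($\eta = 0.3$) for the selected arm, with
$\delta = \mathrm{reward} - w^{D1}_{arm}$; dopamine for the next trial
is $\mathrm{sig}(0.2\,\delta)$ clipped to [0.1, 0.9]. The weight-to-rate
map is `w/10` Hz (weights of 50 give a physiological 5 Hz). Two session
defaults differ from the binary task: the race window is 5 ms (with
10 ms smoothing the quadrant pools never cross threshold at
intermediate dopamine and the session deadlocks, since a No-Go trial
performs no update and dopamine freezes), and the network state
persists across trials within a session (with a fresh network every
trial the 100–200 ms stimulus window is dominated by the cold-start
transient and per-trial synchrony carries no dopamine information).
No-Go trials deliver no reward and no update. A trial is labeled
exploitative when the selected arm is the argmax of the true current
means. The soft-max behavioral reference (`behavioral_session()`) uses
delta-rule values and $P(i) \propto e^{\beta Q_i}$; $\beta$ is a free
parameter.

# What the generator does and does not establish

The striatal generator emulates rate-coded saliency with perfect
within-pool spike correlation and exact Poisson statistics; it does not
model striatal membrane dynamics, D1/D2 co-activation structure, or any
within-trial adaptation of cortical drive. The payoff walk reproduces
the stationary AR(1) moments the tests check, not any particular
empirical reward sequence. A green synchrony test therefore establishes
that the circuit model produces the claimed collective dynamics under
idealized inputs — not that those dynamics would survive realistic
striatal correlation structure.

# Known limitations

Three reported phenomena did not survive faithful reimplementation, and
the corresponding acceptance checks are deliberately left failing
rather than being tuned away:

* **High-dopamine STN rate.** With $E_{GABA} = -60$ mV the GPe→STN
  inhibition is largely shunting; driving STN down to the reported
  35–40 Hz requires GPe rates near 175 Hz, incompatible with the
  reported 80–90 Hz. The model settles near 50 Hz at `DA = 0.9`.
* **Intermediate-dopamine exploration.** The printed striatal gain
  curves give $cD1(0.5) \approx 0.23$ and $cD2(0.5) \approx 0.17$: both
  pathways are essentially silent at mid dopamine, the stimulus cannot
  reach the circuit, and every intermediate-dopamine binary trial ends
  in No-Go. Selections occur at low dopamine (through the strong D2
  gain) and at high dopamine (through D1), producing a U-shaped rather
  than the reported monotone/peaked profile.
* **Explore/exploit synchrony contrast.** Because low-dopamine trials
  still select (and the D2 pathway then vetoes low-value arms, making
  those synchronized trials *more* exploitative), exploit trials do not
  concentrate at high dopamine and the per-trial synchrony contrast
  between explore and exploit labels is near zero instead of
  0.33 vs 0.13.

Further structural simplifications: no GPe→GPi or cortex→STN pathways
(excluded by design), one-to-one inter-nucleus wiring, uniform delays,
no short-term plasticity, and a GPi without lateral collaterals.
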