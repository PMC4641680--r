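---
title: "Methods: stochastic rate dynamics, event detection, and fatigue-timescale inference"
author: "netevents"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: stochastic rate dynamics, event detection, and fatigue-timescale inference}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

Cultured cortical networks spontaneously produce a whole spectrum of
collective events: large, quasi-synchronous *network spikes* (NS), smaller
noise-driven transient excursions we call *quasi-orbits*, and *avalanches* —
cascades of spikes bracketed by near-silence, with power-law distributed
sizes.  `netevents` implements, in one package, (i) a stochastic
two-population rate model that produces all three phenomena, (ii) a unified
hidden-Markov detector for them, (iii) the statistical laws of their sizes
and intervals, and (iv) a procedure that infers the timescale of an
*unobserved* activity-dependent fatigue process from the observable firing
history alone.

# The model

## Rate dynamics

Two homogeneous populations (excitatory and inhibitory, `n_E = 160` and
`n_I = 40` neurons by default) evolve as Wilson–Cowan-type rate equations

$$\tau_E\,\dot\nu_E = \Phi(\mu_E, \sigma^2_E) - \nu_E,\qquad
  \tau_I\,\dot\nu_I = \Phi(\mu_I, \sigma^2_I) - \nu_I,$$

where $\Phi$ is the first-passage-time transfer function of the leaky
integrate-and-fire neuron driven by white-noise current with mean $\mu$ and
infinitesimal variance $\sigma^2$:

$$\Phi(\mu,\sigma^2) = \left[\sqrt{\pi}\,\tau_V
  \int_{u(V^{reset})}^{u(V^{thresh})} e^{s^2}(1+\operatorname{erf} s)\,ds
  + \tau_{refract}\right]^{-1},
  \qquad u(V) = \frac{V - V^{rest} - \mu\tau_V}{\sqrt{\sigma^2\tau_V}}.$$

Membrane resistance is 1, so currents carry mV/ms.  Internally all rates
are kHz (1/ms), times ms and potentials mV, which makes the two equations
above dimensionally exact; user-facing summaries convert to Hz and
seconds.

Synaptic transmission is low-pass filtered with AMPA/GABA-like constants
($\tilde\tau_E = 10$ ms, $\tilde\tau_I = 2$ ms; slow NMDA components are
deliberately not modelled), and the input moments are the usual sparse
random-network expressions, e.g. for the excitatory population

$$\mu_E = c\,n_E\,\tilde\nu_E\,w_{exc} J_{EE}\,r_E
        + c\,n_I\,\tilde\nu_I\,w_{inh} J_{EI} + \nu_{ext} J_{ext},$$

with the variance analogue built from $J^2 + \sigma_J^2$ and $r_E^2$.  The
dimensionless factors `w_exc` and `w_inh` rescale all excitatory
($J_{EE}, J_{IE}$) and inhibitory ($J_{EI}, J_{II}$) efficacies and span
the excitation–inhibition plane that organises every analysis in the
package.

## Short-term depression and adaptation

All excitatory synapses deplete: the available resource fraction follows
the Tsodyks–Markram equation

$$\tau_{STD}\,\dot r_E = (1 - r_E) - u_{STD}\, r_E\, \tau_{STD}\,\tilde\nu_E,$$

with recovery time `tau_STD = 800` ms and utilisation `u_STD = 0.2`.
Optionally a spike-frequency-adaptation current is enabled
(`g_SFA > 0`): an adaptation variable integrates the noisy excitatory rate
with timescale `tau_SFA` and subtracts `g_SFA * c_E` from $\mu_E$,
mimicking a Ca²⁺-dependent K⁺ after-hyperpolarisation current.  No value
of `g_SFA` is claimed as a reference; it must be chosen explicitly when
adaptation is wanted.

## Finite-size noise

For a population of $n$ neurons at rate $\nu$, the spike count in a step
$dt$ is Poisson with mean $n\nu\,dt$; the synaptic filters integrate the
empirical rate $\nu_n = \text{count}/(n\,dt)$, which has mean $\nu$ and
variance $\nu/(n\,dt)$.  This multiplicative finite-size noise is the only
stochasticity in the model; rescaling the network at fixed connections per
neuron (`scale_network()`) changes the noise amplitude while leaving the
deterministic mean field invariant.

## Integration

The stochastic system is integrated by explicit Euler at `dt = 0.25` ms
with freshly drawn Poisson counts per step — the noise is a point-process
count, not a diffusion, so a higher-order scheme would buy nothing.
After-update guards clip `r_E` to $[0,1]$ and rates to $\ge 0$ (Euler
overshoot events are far rarer than $10^{-6}$ per step at this `dt`).
Simulations start at the deterministic fixed point and discard a 10 s
burn-in so that event statistics carry no transient bias.  Halving `dt`
changes deterministic trajectories by under $10^{-3}$ in relative L2 norm
over 10 s (tested).

The transfer-function integrand $e^{s^2}(1+\operatorname{erf} s) =
\operatorname{erfcx}(-s)$ is evaluated through the scaled complementary
error function (asymptotic series beyond $|s| = 26$), so integration
bounds up to $\pm 30$ neither overflow nor lose the result; when the lower
barrier is effectively unreachable the rate is computed on the log scale.
Quadrature is an adaptive 7/15-point Gauss pair with relative tolerance
$10^{-10}$ for stability analyses (downstream eigenvalues are sensitive to
$\Phi$'s slope) and $10^{-8}$ inside the simulator.

# Stability analysis

`find_fixed_point()` solves the noise-free self-consistency with
depression at its activity-dependent steady state
$r_E = 1/(1 + u_{STD}\nu_E\tau_{STD})$, using a damped-Newton multistart
over $\nu_E \in \{0.1, 1, 5, 20, 100\}$ Hz and returning the low-activity
root; the residual of the full drift at the returned point is required to
be below $10^{-10}$.  The Jacobian is central finite differences with
Richardson extrapolation (relative step $10^{-5}$); a symbolic derivative
chain through $\Phi$ would be error-prone, and two independent checks
guard the numerics — a one-sided difference scheme at a different step,
and the decay rate of a simulated small perturbation, which must match
$\Re\lambda$ within 5%.  Eigenvalues are reported in Hz (1/s; internal
time is ms, so the conversion factor is 1000), sorted by descending real
part with ties broken by larger $|\Im\lambda|$.

At the default parameters and `w_exc = w_inh = 1` the model has a
low-activity fixed point at $\nu_E \approx 2.25$ Hz whose dominant
eigenvalue is complex with $\Re\lambda \approx 0.03$ Hz — essentially *on*
the Hopf bifurcation.  `plane_sweep()` maps $\Re\lambda$, $\Im\lambda$
and the fixed-point rate over a `(w_exc, w_inh)` grid (default
$[0.4,1.4]\times[0.3,1.5]$, a design choice) and extracts iso-lines at
$\Re\lambda \in \{-3.5, 0, +3.5\}$ Hz; failed cells are marked rather than
aborting the sweep.  The upper-left (weakly excited, strongly inhibited)
corner of the plane has a real dominant eigenvalue — no oscillatory
component — which matters for the inference grid below.

# Event detection

Detection operates on a `count_series`: pooled spike counts per fixed bin
(0-based, half-open bins; bin widths of 0.25–8 ms are the validated
range).  A two-state hidden Markov chain with Poisson emissions (the
emission family is a modelling choice natural for counts) is fitted by
Baum–Welch: low state = quiescence, high state = network event.
Initialisation breaks the EM symmetry toward that meaning — low rate =
mean of counts below the median (floored away from zero, which would be an
absorbing initialisation), high rate = mean above the 90th percentile,
sticky transitions (0.99).  The most probable state path is found by
log-space Viterbi; events are maximal runs of the high state.

**Minimum-duration calibration.**  The same decoding applied to a
bin-shuffled *surrogate* series produces events with no temporal
structure.  The upper tail of their durations is close to exponential:
above the 75th percentile $q_{75}$ the exceedances are fitted by maximum
likelihood (mean exceedance $\hat\tau$), and the threshold is the duration
whose unconditional tail probability is $P = 10^{-3}$:
$d^* = q_{75} + \hat\tau\,\ln(0.25/P)$.  (Reading the probability as
conditional on exceeding $q_{75}$ is available as a config switch; with
fewer than 20 surrogate events the longest surrogate duration is used,
with a warning.)  Only runs at least $d^*$ long are kept as
NS/quasi-orbit candidates.

**Avalanche variant.**  The low state's emission table is clamped for the
whole re-estimation to $p(1) = 10^{-6}\langle n\rangle$, $p(0) = 1 - p(1)$
and $p(n\ge 2) = 0$ (zero mass on two or more counts is the simplest
completion of "essentially silent"); only its transitions and the high
state update.  No duration or size threshold is applied.  Detected
avalanche sets are insensitive to the clamp factor across
$[10^{-8}, 10^{-4}]$ (tested).

Event size is the total spike count in the half-open interval, with no
baseline subtraction; ties at the classification threshold go to NS.

A caveat the permutation machinery must respect: a pointwise 5% surrogate
bound cannot calibrate the *minimum* of a whole scan curve (or the event
count of a whole recording) — scanning inflates the family-wise error.
Where the package reports "significant" optima it therefore gates them on
the null distribution of the curve minimum, while still reporting the
pointwise bound as the familiar reference line.

# Event statistics

**Intervals.**  `insi_stats()` summarises onset-to-onset intervals between
network spikes by their mean (seconds) and coefficient of variation
(population standard deviation over mean): CV ≈ 0 for quasi-periodic
bursting at high net excitation, CV ≈ 1 for the Poisson-like rare-event
regime at weak excitability.  Across the plane, both statistics organise
along iso-$\Re\lambda$ lines: the distance to the instability is the
effective one-dimensional control parameter.  The duration threshold
removes the shortest events and depression suppresses immediate
re-ignition, so measured CVs at weakly excitable points saturate slightly
below 1 (0.85–0.95 at the problem sizes used here).

**Quasi-orbit sizes.**  Near a stable focus close to the Hopf line
($\Re\lambda < 0$, $|\Re\lambda| \ll \Im\lambda$), linearising and
averaging over the fast rotation gives a Rayleigh law for the excursion
radius,

$$p(l) = \frac{4|\Re\lambda|}{\sigma'^2}\,l\,
  e^{-2|\Re\lambda| l^2 / \sigma'^2},$$

hence an exponential law for the size ($\propto l^2$) with mean
$\sigma'^2/(2|\Re\lambda|)$ — small events proliferate as $1/|\Re\lambda|$
away from the line.  The package validates the phase-averaging step by
simulating the planar linear system with a single shared noise source
(`simulate_quasiorbit_sde()`).  The integrator propagates the rotation
and decay exactly over each step and adds the noise increment Euler-wise:
a naive forward-Euler drift at $\Im\lambda \gg |\Re\lambda|$ weakens the
effective damping by $\Im\lambda^2 dt/2$ (a 20% moment bias at
$\Re\lambda = -1$ s⁻¹, $\Im\lambda = 40$ s⁻¹, $dt = 2.5\times10^{-4}$ s),
which the distributional tests at $n = 10^5$ would rightly reject; the
exponential scheme leaves the phase-averaging approximation as the only
thing under test.

**Mixture classification.**  The overall NS + quasi-orbit size
distribution is fitted by maximum likelihood with

$$p(x) = p_0\,\frac{e^{-(x - x_0)/\tau_0}}{\tau_0}
       + (1 - p_0)\,\mathcal N(x;\, m_1, \sigma_1),$$

both components truncated below the shift $x_0 \in [0, \min(x)]$, which
models the soft size threshold the detector imposes (an event shorter than
the minimum credible duration cannot be arbitrarily small).  Optimisation
is bounded L-BFGS-B from a multistart that includes near-pure-component
starts, so the mixture optimum provably nests either pure fit.  The
NS/quasi-orbit threshold is the smallest size in $(x_0, m_1)$ where the
two weighted component densities cross; when no crossing below the
Gaussian peak exists, no threshold is set and every event is labelled NS.

**Avalanche power laws.**  `fit_power_law()` is the standard
continuous-approximation MLE $\hat\alpha = 1 + n/\sum\ln(x_i/x_{min})$
with $x_{min}$ selected by Kolmogorov–Smirnov minimisation over candidate
cutoffs (sizes span $10^2$–$10^4$ where discreteness is negligible; a
discretised estimator is available).  At the reference simulation scale
used here (20 simulated minutes, 200 neurons) the KS-optimal tail spans
about 1.7 orders of magnitude with exponents around 1.9 at
`(w_exc, w_inh) = (0.9, 1.0)`; longer recordings extend the tail but the
finite network caps the largest avalanches, and crossing the Hopf line
grows a large-size bump of network spikes on top of the power law.

# Inferring the fatigue timescale

The driver of event extinction (depression here; adaptation in general)
is not experimentally observable.  The package therefore treats the
fatigue variable as a *generic* linear integrator of the observable
population rate,

$$\dot f = -f/\tau^* + \nu(t),$$

integrated exactly per bin, and asks which candidate $\tau^*$ makes $f$
just before an event onset the best (most negative) Pearson predictor of
the event's size.  "Just before" is the state of the integrator at the
start of the onset bin, so the event itself never contaminates its own
predictor.  Both NS and quasi-orbits enter the scan — both are ignited
near the fixed point, and the extra events sharpen the correlation.  The
scan grid is log-spaced (50 points by default); each significant local
minimum is refined off-grid by a parabola through its three surrounding
points in (log τ, correlation), because the raw grid quantises $\tau^*$
by ~14% steps, comparable to the whole effect being measured.
Significance is permutation-based as described above (B = 1000 by
default; one-sided at 5%); minima closer than a factor 2 in $\tau^*$ are
merged, keeping the deepest.

For Tsodyks–Markram depression the linearisation around the stationary
resource level predicts

$$\tau^*_{opt} = \frac{\tau_{STD}}{1 + u_{STD}\,\langle\nu\rangle\,\tau_{STD}}
             = \tau_{STD}\,\langle r\rangle,$$

so repeating the scan at working points with different mean rates and
fitting this relation (bounded nonlinear least squares,
`fit_std_params()`) recovers both depression parameters from firing
history alone.  `run_timescale_study()` packages the whole loop.  Two
design choices matter:

* **The study grid spans both sides of the Hopf line.**  The default nine
  points cover mean observed rates of roughly 2–12 Hz.  Restricting to
  subcritical points compresses the rate span to below a factor of 2.5,
  over which the predicted $\tau^*$ change (~25%) is smaller than the
  argmin noise of the (very flat) correlation curves at half-hour
  recordings — the utilisation fraction then becomes unidentifiable.
  Points with a real dominant eigenvalue are excluded: the quasi-orbit
  picture behind the analysis assumes an oscillatory approach to
  instability, and at such points the scan optimum scatters by ±20% at
  identical mean rate.
* **$\langle\nu\rangle$ is the mean of the same pooled per-neuron rate
  that drives the integrator** — the only rate an experimenter has.

At desk scale the recovered recovery time is accurate
($\hat\tau_{STD} \approx 0.8{-}0.93$ s against a configured 0.8 s across
seeds) while the utilisation fraction is systematically low
($\hat u_{STD} \approx 0.10{-}0.15$ against 0.2).  The diagnosis is
instructive: the scan finds the timescale of the best *linear
reconstruction* of the actual resource process (the correlation between
$f$ and $r_E$ at the optimum exceeds 0.99 in simulation), and at bursty
working points that optimum sits 10–25% above the linearised prediction
evaluated at the overall mean rate, because most of the reconstruction
weight lies in the quiescent stretches between events where the effective
rate is lower.  The compressed decline of $\tau^*_{opt}$ with
$\langle\nu\rangle$ maps into an underestimated $u_{STD}$.  Hour-scale
recordings per point sharpen each optimum but do not remove this bias;
it is a property of the inference procedure, reported as measured.

When two fatigue mechanisms coexist (depression plus slow adaptation),
the scan can show two significant minima.  Two caveats, both consequences
of Pearson bilinearity, are worth knowing: with a drive whose variance
lives on a single timescale, two mechanisms even a factor 10 apart
produce a *single* merged bowl (the integrator kernels decorrelate too
slowly in log-τ); and when two minima do appear, they attract each other,
so the recovered ratio understates the true one.  The bursty,
slowly-modulated structure of real recordings is what makes the two-peak
phenomenology observable at all.

`precursor_correlation()` closes the loop on model data, where the true
resource level *is* observable: $r_E$ just before onset is a significant
*positive* predictor of NS size (more resources, bigger event; the
negative sign belongs to $f$, which anti-tracks $r$), while avalanche
sizes show weak or no such correlation — avalanches amplify fluctuations
of every size rather than discharging an accumulated resource.

# Synthetic data

`make_planted_count_series()` produces Poisson counts with
piecewise-constant rate — quiescent background punctuated by bursts with
known onsets — emulating pooled multielectrode activity for detector
validation.  `make_mixture_sample()` draws i.i.d. sizes from the mixture
law by inverse-CDF sampling.  What these fixtures deliberately do *not*
emulate: refractory structure inside bursts, inter-event correlations,
per-electrode heterogeneity, non-stationary excitability drift, and spike
sorting artefacts.  Tests passing on them therefore validate the
*detector and estimators*, not the claim that real recordings satisfy
the model's assumptions; the stochastic rate model itself is the bridge
to realistic temporal structure.

# Problem sizes used by the tests and the acceptance script

All headline computations are sized to run on one CPU core in minutes,
as the package's own reference scale: the depression-recovery study uses
9 working points × 30 simulated minutes (events per point ~900–2100);
the avalanche fit uses 20 simulated minutes at `(0.9, 1.0)`
(~60,000 avalanches); the Poisson-limit interval check uses 40 simulated
minutes at `(0.8, 1.4)`; the quasi-orbit law uses $10^5$ radius samples
spaced one relaxation time apart.  Seeds are fixed in the tests; the
acceptance script takes its seed on the command line.

# Known limitations

* The mean-field model has no spatial topology, no leader neurons, no
  facilitation, and no NMDA kinetics — by design, to isolate what balance,
  depression and finite-size noise alone explain.
* The Gaussian description of NS sizes is empirical, not derived; heavy
  event-count runs can fail strict goodness-of-fit on mild skewness.
* The utilisation fraction recovered by the timescale study is biased
  low at desk scale (see above); the recovery time is accurate.
* The avalanche tail at 200 neurons spans just under two decades above
  the KS-selected cutoff; the exponent is insensitive to this.
* Experimental recordings enter only as pooled spike-time tables
  (`read_spike_table()`); proprietary acquisition formats are out of
  scope.
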