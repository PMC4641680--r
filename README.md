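# netevents

Collective events in neural population activity: simulation, detection,
statistics, and fatigue-timescale inference.

Cultured cortical networks (and many in-vivo preparations) spontaneously
alternate between near-quiescence and collective events — large
quasi-synchronous **network spikes** (NS), smaller noise-driven
**quasi-orbits**, and **avalanches** whose sizes follow power laws.
`netevents` provides a single, tested toolchain for studying how these
coexisting phenomena are organised by the balance of excitation and
inhibition:

* a **stochastic two-population rate model** (Wilson–Cowan-type) with the
  leaky integrate-and-fire transfer function
  Φ(μ, σ²) = [√π τ_V ∫ e^{s²}(1+erf s) ds + τ_ref]⁻¹,
  Tsodyks–Markram short-term depression
  (τ_STD ṙ = (1−r) − u_STD r τ_STD ν̃), optional spike-frequency
  adaptation, and finite-size Poisson noise (per-step counts with mean
  n ν dt), integrated in compiled code;
* **linear stability analysis**: fixed points, Jacobians, dominant
  eigenvalues, and Hopf-bifurcation maps over the (w_exc, w_inh) plane —
  the real part ℜλ of the dominant eigenvalue is the effective control
  parameter of the event statistics;
* a **unified two-state hidden-Markov detector** (Baum–Welch + Viterbi)
  for binned spike counts, with a surrogate-calibrated minimum event
  duration for NS/quasi-orbits and a clamped near-silent state for
  avalanches;
* **event statistics**: interval regularity (CV of inter-NS intervals),
  the Rayleigh/exponential quasi-orbit size law
  p(l) = (4|ℜλ|/σ′²) l exp(−2|ℜλ| l²/σ′²), the exponential+Gaussian size
  mixture with an equal-probability NS/quasi-orbit threshold, and
  power-law avalanche fitting (MLE with KS-selected cutoff);
* **fatigue-timescale inference**: reconstruct a generic linear
  integrator f of the observed rate (ḟ = −f/τ* + ν), scan τ* for the
  strongest negative correlation between pre-onset f and event size, and
  recover the depression parameters through
  τ*_opt = τ_STD / (1 + u_STD ⟨ν⟩ τ_STD).

It is aimed at computational neuroscientists studying population bursting
and at experimentalists with multielectrode-array recordings (spike times
per channel are the only required input format).

## Worked example

Simulate a slightly subcritical network, detect and classify its events,
and infer the depression timescale from the firing history alone:

```r
library(netevents)

stability_analysis(network_params())   # reference point, w_exc = w_inh = 1
#> stability_result: nu_E = 2.251 Hz, nu_I = 4.597 Hz, r_E = 0.735
#>   dominant eigenvalue: Re = 0.029 Hz, Im = 4.469 Hz (oscillatory)
```

The reference network sits on the brink of the oscillatory (Hopf)
instability with a 2–4 Hz low-activity fixed point. Reducing excitation
by 6% moves it into the subcritical regime, where finite-size noise
ignites a mixture of network spikes and quasi-orbits:

```r
p <- network_params(w_exc = 0.94)
trace <- simulate_network(p, sim_config(duration = 10 * 60000, seed = 1,
                                        record_stride = 16L))
det <- detect_network_events(trace, dt_bin = 4)
det$mixture
#> mixture_fit: p0 = 0.448, tau0 = 199.9, x0 = 81.0, m1 = 723.1, sigma1 = 165.7
#>   threshold = 452.4, -logLik = 2857.72
table(det$events$label)
#>          NS QUASI_ORBIT
#>         249         168
insi_stats(det$events, labels = "NS")[c("mean_insi", "cv_insi")]
#> $mean_insi [1] 2.412097
#> $cv_insi   [1] 0.4987298
```

About 45% of detected events are exponential-tail quasi-orbits (mean size
≈ 200 spikes) and the rest Gaussian-bulk network spikes (≈ 723 ± 166
spikes); the equal-probability threshold lands at 452 spikes. Network
spikes recur every 2.4 s with CV ≈ 0.5 — the weakly synchronised regime
typical of cultures. The fatigue variable behind the events is
recoverable from the observable rate:

```r
rate_Hz <- det$series$counts / (200 * 0.004)   # pooled per-neuron rate
scan <- correlation_scan(rate_Hz, 0.004, det$events, B = 400, seed = 2)
scan
#> correlation_scan: 50 timescales in [0.05, 100] s
#>   optimum: tau* = 0.827 s (r = -0.535)
effective_timescale(0.8, 0.2, mean(rate_Hz))
#> [1] 0.5218267
```

A single significant negative peak marks the effective depression
timescale; repeating the scan across working points and fitting
τ*_opt(⟨ν⟩) (see `run_timescale_study()`) recovers the configured
recovery time τ_STD = 0.8 s from firing history alone.

A thin command-line front end (`exec/netevents`) exposes the same
pipeline as `simulate`, `stability-map`, `detect`, `classify-sizes`,
`avalanches`, `infer-tau` and `fixtures` subcommands over TSV files.

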