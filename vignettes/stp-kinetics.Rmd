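---
title: "Kinetic models and train analysis of short-term plasticity"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Kinetic models and train analysis of short-term plasticity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(stpkit)
```

## The models

High-frequency transmission at large glutamatergic terminals is shaped by
three quantities: the size of the readily releasable pool (RRP), the
probability `P_r` that a release-ready vesicle fuses upon an action potential
(AP), and the rate at which vacated release sites are refilled. `stpkit`
implements two kinetic schemes for this machinery.

**Single-pool model.** `N_total` release sites are either empty (`N_e`) or
occupied by a primed, fusion-competent vesicle (`N_o`), with

```
dN_o/dt = k_f(Ca) * N_e - k_b * N_o
```

The unpriming rate `k_b` is constant; the priming rate saturates with the
spatially averaged ("effective") calcium concentration,

```
k_f(Ca) = (k_f,rest + sigma * dCa) / (1 + dCa / K_0.5),   dCa = Ca - Ca_rest
```

so `k_f` equals `k_f,rest` at rest (`Ca_rest` = 50 nM) and approaches
`sigma * K_0.5` at saturation. Effective calcium jumps by `delta_ca_ap` at
each AP and relaxes mono-exponentially with rate `k_ca`; both the jump and
the decay have closed forms, which the simulator uses directly.

**Sequential two-step scheme.** Vesicles first dock loosely (ES → LS, rates
`k_1`/`b_1`) and then mature into a tightly docked state (LS → TS, rates
`k_2`/`b_2`) from which — and only from which — they fuse. Both forward rates
carry the same Michaelis–Menten-type calcium dependence as `k_f` above. The
resting distribution over ES/LS/TS is the analytic steady state of the linear
chain (`resting_state()`).

**Release probability dynamics.** The per-AP release probability is

```
P_r,j = P_r,1 * y_j^4.5 * z_j
```

where `y >= 1` captures facilitation of release (local calcium accumulation
and buffer saturation near the sensor) and `z <= 1` a mild
activity-dependent reduction. Both start at 1, receive per-AP increments
(`y += y_inc1 * (y_max - y)`, `z -= z_dec1 * (z - z_min)`) and relax
exponentially back to 1 between stimuli. The exponent 4.5 reflects the
cooperative dependence of fusion on local calcium and is fixed unless
overridden. If the product form exceeds 1 it is clipped with a warning.

**Event loop.** At each AP the simulator (i) evaluates `P_r,j` from the
current `(y, z)`, (ii) computes the quantal content from the
fusion-competent pool just before the AP — as a real number in deterministic
(mean-field) mode, or as a binomial draw in stochastic mode, (iii) returns
the released vesicles' sites to the empty pool, (iv) applies the calcium jump
and the `y`/`z` increments, and (v) integrates the occupancy ODEs to the next
AP. The calcium increment is applied *after* release: its effect is on
priming during the following interval, while the facilitation of `P_r` itself
is carried entirely by the `y`/`z` machinery. EPSC amplitudes are
`m_j * q` with `q` the quantal amplitude (nA per vesicle).

## Numerical choices

* The occupancy equations are integrated with deSolve's adaptive
  Runge–Kutta–Fehlberg 4(5) stepper (`rk45f`), relative tolerance 1e-8,
  absolute 1e-10, segment by segment between APs; AP events are therefore
  handled exactly rather than through event detection. The redundant full
  system (all occupancy states) is integrated so that site-count
  conservation is a genuine numerical check, verified to 1e-6 · `N_total` in
  the tests.
* Internal units are seconds, nM and 1/s. The user-facing Michaelis
  parameters (`sigma`, `k_half`) are per µM and converted once at the
  boundary.
* Calcium and the `y`/`z` relaxations use their closed forms; only pool
  occupancies are integrated numerically.
* In stochastic mode the binomial draw uses `round(pool)` trials; inter-AP
  kinetics stay mean-field. Because every state update is linear in the
  occupancies, the stochastic mean equals the deterministic train up to that
  rounding (asserted within 3 SE over 1000 repetitions in the tests).

## Estimators

* **EQ**: regression of EPSC amplitude on the cumulative amplitude released
  before it over the first 4 stimuli (configurable 3–6; the method is valid
  only on the near-linear initial depletion segment). The x-intercept is the
  pool in amplitude units and `P_r = EPSC_1 / RRP`. The estimator refuses
  non-depressing trains; with active replenishment it is biased upward, a
  property the tests assert rather than hide.
* **SMN**: a line through the last 10 points of the cumulative amplitude
  curve, back-extrapolated to stimulus 0. The corrected variant removes the
  replenishment accumulated before steady state by subtracting, from each
  cumulative point, the steady-state refill rate weighted by the vacated
  pool fraction before each stimulus (refill scales with empty sites),
  refitting and iterating to convergence (tol 1e-6, ≤ 10 iterations). Both
  variants are exposed; on simulated trains the corrected estimate lands
  closer to the true resting pool.
* **NpRf**: least-squares fit of the recursion `a_j = p·n_j`,
  `n_{j+1} = n_j − a_j + R·(N − (n_j − a_j))` over a deterministic grid of
  starts. With `R = 0` it reduces to geometric depletion and agrees with EQ.
* **Onset delay**: a Boltzmann sigmoid is fitted to the rising flank and the
  onset taken at the extremum of its second *time* derivative,
  `t50 − k·ln(2 + sqrt(3))`. Geometric curvature of a current-vs-time plot
  depends on the axis units, so the time-derivative definition is used; it
  makes the delay invariant under amplitude scaling.
* **Recovery fits**: mono- and bi-exponential saturating forms fitted by
  Levenberg–Marquardt from a deterministic multi-start grid
  (τ₁ ∈ {10, 50, 200} ms, τ₂ ∈ {0.5, 2, 5} s, f ∈ {0.2, 0.5, 0.8}; the
  surface is multimodal); nested-model F-test
  `F = ((RSS_mono − RSS_bi)/2)/(RSS_bi/(n−4))` with α = 0.05. When the mono
  fit is already exact to numerical precision the mono model is kept
  (parsimony), avoiding a 0/0 F statistic on noiseless data.
  `τ_w = (1 − f_slow)·τ_fast + f_slow·τ_slow` is the amplitude-weighted
  summary; the weighting is monotone and bounded by the two time constants.

## Event analysis

mEPSC detection thresholds the baseline-subtracted trace at `threshold_sd`
(default 5, middle of the conventional 4–6 range) times the baseline SD,
estimated from a user-specified, event-free window. Before thresholding the
trace is smoothed with a 0.5 ms moving average so baseline noise cannot split
one event into several crossings; segments separated by noise-scale gaps are
merged, and within a segment a second peak is only accepted if the valley
between peaks is at least half the detection threshold deep. Peaks closer
than `min_separation_ms` count as overlapping events and *all* members of the
overlapping group are excluded (matching the exclusion convention of manual
curation, replaced here by a deterministic rule). Rise time is measured
between the interpolated 10% and 90% crossings, width at half maximum
likewise by interpolation.

Spike-timing analysis matches each stimulus to the earliest unconsumed AP
within a 2 ms window (calyceal delays are ~0.1–0.7 ms; 2 ms still separates
adjacent 500 Hz stimuli). Jitter is the SD of the matched latencies.
Preceding activity is the exponential-kernel weighted count of earlier spikes
(τ = 30 ms by default, with 10 and 100 ms as robustness settings; the measure
is monotone in τ). Binned summaries use half-open `[left, right)` bins so
results are bit-for-bit reproducible.

## Synthetic data

Every generator requires a seed and attaches its generating parameters as a
`ground_truth` sidecar. The generators emulate the study conditions the
analyses assume: 50-AP regular trains at 50 and 500 Hz; paired
conditioning/test protocols with log-spaced recovery intervals between 20 ms
and 16 s (12 points by default); Poisson mEPSC traces built from
bi-exponential kernels plus Gaussian noise; sinusoidally amplitude-modulated
(SAM) spike patterns as inhomogeneous Poisson processes
(`rate·(1 + depth·sin(2πf t))`, thinning, 1 ms refractory period) spanning
modulation frequencies 20–2000 Hz; and AP response records whose latency can
be made to grow with kernel-weighted preceding activity. The SAM surrogate is
parametric — it reproduces the alternation of high- and low-activity epochs
that the timing analyses exploit, not the spectro-temporal detail of sound-
evoked firing. What passing tests show is therefore that the analysis chain
recovers known generating parameters under the assumed statistical structure
(Poissonian events, Gaussian noise, binomial release); they cannot certify
behaviour under recording artefacts such as drift, seal instability or
overlapping multiquantal events.

## Calibration

`calibration_problem()`/`fit_stp()` replace by-eye tuning with an explicit
objective: the weighted mean of squared *relative* errors between simulated
and target EPSC amplitudes (both train frequencies) and fractional-recovery
points. Relative errors keep the 50 and 500 Hz trains comparable despite
~4-fold amplitude differences; weights are exposed per dataset. Parameters
named in `free_shared` are fitted jointly across conditions — mirroring the
constraint that `P_r` and `N_total` be identical across genotypes in the
two-step scheme — so the fitted values are bitwise identical across
conditions by construction. Optimisation is bounded local search (`nlminb`)
from Latin-hypercube starts; a derivative-free search would also serve, but
the objective is smooth in practice and the quasi-Newton iteration converges
in far fewer simulator calls. Solutions within 1e-6 of a bound are flagged
(`at_bounds`) rather than silently accepted.

The tests recover shared `(P_r, N_total)` to well under 5% and
condition-specific priming rates to under 10% from noiseless two-condition
train data (20 APs per train at 50 and 500 Hz, 8 starts) — problem sizes
chosen so the whole experiment stays a few minutes on one core while leaving
the parameters clearly identifiable.

## Shipped calibrations

`rac1_calibration()` returns parameter sets for both schemes describing the
control and Rac1-deleted conditions. Hard anchors are enforced by
construction: the single-pool resting occupied pool is exactly 2150 (control)
or 2532 (knockout) vesicles with `P_r` 0.08/0.165, and the two-step resting
tight-docked pool exactly 691/1666 with shared `P_r` (0.25) and `N_total`
(3000). The resting priming equilibration rates were set so the slow
component of recovery sits on the seconds scale (1/2.7 and 1/2.3 s⁻¹ for the
single-pool genotypes). The remaining calcium-dependence parameters are
calibration products of this package, tuned by grid search until the
qualitative genotype contrasts hold with margin: larger first EPSC and loss
of 500 Hz paired-pulse facilitation after Rac1 deletion, a larger 50 Hz
steady state, and a similar 500 Hz steady state. In both schemes the
genotype difference is carried by the calcium dependence of the vesicle
supply step (σ = 10 vs 28 /s/µM with `K_0.5` 4 vs 0.7 µM), while the
effective-calcium parameters (`delta_ca_ap` = 150 nM, `k_ca` = 20 /s — an
effective calcium plateau of ≈3.9 µM during 500 Hz trains and ≈0.45 µM at
50 Hz) and the `P_r` dynamics are shared between genotypes. The per-AP
calcium increment is a free constant: only the qualitative build-up of
effective calcium during trains is constrained by the biology, not its
functional form, and constant increments (linear summation) are the simplest
scheme consistent with it.

## Limitations

* No spatial calcium diffusion, channel-coupling geometry, AP waveform or
  endocytosis/site-clearance model; "effective calcium" is a lumped driving
  variable.
* Facilitation/depression (`y`, `z`) are phenomenological, not mechanistic.
* The SMN correction implements the *intent* of occupancy-dependent refill
  subtraction; published implementations differ in detail, so corrected and
  uncorrected modes are both exposed.
* The paired-train machinery carries `y`/`z` and calcium through the
  recovery interval (continuity at short intervals requires it); with
  intervals ≥ 20 ms and the default relaxation rates this differs negligibly
  from re-initialising at the test-train onset.
* Estimator behaviour is characterised on synthetic data; biases on real
  recordings (series-resistance error, receptor saturation/desensitisation)
  are out of scope.
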