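---
title: "Methods: mean-field thalamocortical dynamics, chaos, and spectral information transfer"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: mean-field thalamocortical dynamics, chaos, and spectral information transfer}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

# Scope

`neurocrit` studies one question: how does the proximity of slow
thalamocortical electrodynamics to edge-of-chaos criticality (the phase
transition between convergent and exponentially divergent dynamics, largest
Lyapunov exponent $\Lambda = 0$) shape directed cross-frequency
communication between the cortex and thalamus? The package provides four
things: a mean-field model of the basal ganglia-thalamo-cortical system
that can be moved continuously between waking, anesthetized, and
seizure-like regimes; two chaos quantifiers (a twin-run stochastic largest
Lyapunov exponent for simulations, and the modified 0-1 test K-statistic
for recorded or simulated series); a spectrally resolved transfer-entropy
estimator that localizes which frequency bands carry directed information;
and the preprocessing, statistics, benchmark generators, and orchestration
needed to run the full analysis end to end.

# The mean-field model

## Populations and rates

Nine neural populations are modeled: cortical excitatory and inhibitory
populations, striatal D1 and D2 populations, the combined GPi/SNr output
nucleus of the basal ganglia, GPe, STN, thalamic relay nuclei, and the
thalamic reticular nucleus (TRN). GPi and SNr are treated as a single
population because both are GABAergic basal-ganglia output structures with
shared targets. Each population converts its mean somatic potential $V_a$
(V) into a mean firing rate through a sigmoid

$$Q_a = \frac{Q_a^{\max}}{1 + \exp[-(V_a - \theta_a)/\sigma']}$$

with maximum rate $Q^{\max}$ (s$^{-1}$), threshold $\theta$ (V), and
potential spread $\sigma'$ (V). Defaults ($Q^{\max}$ 65-500 s$^{-1}$,
$\theta$ 9-19 mV, $\sigma'$ 3.8 mV) are standard mean-field values for
these structures.

## Synaptic dynamics with a rate-invariant peak

Each projection (target $a$ from source $b$) carries its own dendritic
potential $V_{ab}$, driven by the delayed afferent field through a
second-order operator with rise rate $\beta$ and decay rate $\alpha$
(s$^{-1}$). The bi-exponential impulse response is rescaled so that its
*peak* equals $H = 31.5$ s$^{-1}$ for every $(\alpha, \beta)$: slowing the
rates then prolongs the postsynaptic response without changing its maximum,
which is how GABAergic anesthetics prolong inhibition without altering peak
chloride current. The confluent limit $\alpha = \beta$ uses the analytic
$\alpha^2 t e^{-\alpha t}$ form. `synaptic_response()` exposes the kernel;
the peak-invariance contract (`max_t h = 31.5` to $10^{-6}$) is enforced in
the test suite over a grid of rate ratios from 1.01 to 100.

Receptor rates are per-target-population constants, overridable per
projection. Axonal fields obey the damped wave equation reduced to its
spatially uniform mode (the Laplacian dropped): with no spatial structure
analyzed, each projection's field is then a second-order ODE with damping
$\gamma_{ab}$, driven by the source rate and read out after the axonal
delay $\tau_{ab}$. Synaptic strength $\nu_{ab}$ (V s) and conduction
velocity enter as separate quantities; $\gamma$ and $\tau$ are stored per
projection and held fixed across states (anatomy does not change with
brain state; only sigmoid parameters, receptor rates, couplings, and
drives are dose-interpolated).

## Connectivity

The projection set is the classical basal-ganglia-thalamo-cortical circuit
(cortico-cortical, cortico-striatal, cortico-subthalamic, cortico-thalamic;
direct D1 to GPi/SNr and indirect D2 to GPe to STN pathways; pallidal and
thalamic loops) plus pallidal efferents supported by newer tracing and
diffusion-imaging work: GPe to cortical interneurons, to thalamic relay, to
TRN, and to both striatal populations. Signs are fixed by source
neurochemistry (glutamatergic cortex-excitatory, STN, and relay positive;
GABAergic striatum, pallidum, TRN, and cortical interneurons negative) and
validated at configuration time.

## Integration

A fixed-step classical Runge-Kutta (4th-order) scheme advances all
projection states, with ring-buffer delay lines read by linear
interpolation at stage times; configuration validation enforces
$dt \le \min \tau / 4$ so stage lookups never require future samples. The
default step is $10^{-4}$ s with output decimated to 1000 Hz. White noise
enters the external drive (relay nuclei by default, configurable per
population) and is held constant within each step; twin runs can share a
pre-generated noise matrix, which makes unperturbed twins bit-identical —
the property the stochastic Lyapunov procedure relies on. Halving $dt$
changes the 5 s mean cortical rate by well under 1% (tested). Non-finite
states abort with the first diverging population named.

The local field potential of a region is the superposition of its synaptic
currents, computed as the sum of the *absolute* dendritic potentials of its
afferents, so excitatory and inhibitory currents add rather than cancel.

## Dose interpolation

Given waking parameters $P_0$ and altered-state parameters $P_1$ of
identical layout, the state at dose $D$ is the element-wise geometric path
$P = P_0 (P_1 / P_0)^D$: endpoints are exact, no parameter changes sign,
and the increments saturate as $D$ grows, mirroring pharmacological
saturation. Entries that are zero in both endpoints stay zero; a zero
waking entry with a nonzero altered entry is rejected.

## The three shipped states

The shipped configurations were designed with the package's own tools in
two steps. First, `pin_fixed_point()` inverts the sigmoid and sets each
population's constant external drive so that a target rate vector is an
exact equilibrium; the waking targets are the mid-range physiological
rates of `rate_targets()` (cortex 7.7, striatum 5.19, GPi/SNr 75.7, GPe
30.9, STN 13.6, relay 16.4, TRN 15.4 s$^{-1}$). Pinning decouples *where*
the system sits from *how it moves*: stability is then governed entirely
by loop gains, delays, and synaptic rates, which were located by scanning
the corticothalamic loop gain for the oscillation onset. The genetic
optimizer (`genetic_search()` with `fitness()`) can refine these further;
the shipped sets use the scan directly.

* **Waking** sits just past the Hopf point of the corticothalamic loop
  ($\alpha = 50$, $\beta = 200$ s$^{-1}$, 80 ms round trip): a
  low-amplitude, weakly chaotic 8 Hz (alpha-band) oscillation with median
  twin-run $\Lambda \approx +0.04$ s$^{-1}$ — near-critical on the chaotic
  side — and firing rates at the pinned physiological values.
* **Anesthesia** pushes the corticothalamic gain further past the Hopf
  point (with stronger relay noise drive): the alpha oscillation gives way
  to high-amplitude, delta-dominant (peak at or below 1 Hz), strongly and
  *robustly* chaotic dynamics (median $\Lambda \approx +1$ s$^{-1}$,
  positive in essentially every seed). Endpoints with slowed synaptic
  rates reach stronger chaos but sit near a boundary between coexisting
  regimes, making the twin-run exponent bimodal across noise seeds; the
  shipped endpoint trades some anesthetic realism (its cortical rate
  rises rather than falls with dose - see Limitations) for a
  reproducible chaotic arm.
* **Seizure** combines moderately slowed synaptic rates
  ($\alpha = 35$ s$^{-1}$) with a corticothalamic gain *below* onset: a
  strongly contracting spiral with a sharp 6-8 Hz resonance, driven by
  relay noise into a stereotyped spike-like oscillation. Its twin-run
  exponent is genuinely negative ($\Lambda \approx -0.7$ to $-3$
  s$^{-1}$ with dose). This choice is
  deliberate: an autonomous limit cycle has a neutral phase direction, so
  a random perturbation leaves a permanent phase offset and the measured
  stochastic exponent of a self-sustained cycle is pinned near zero. A
  noise-driven subcritical resonance has no neutral direction, so the
  periodic arm's hyper-stability is measurable. The cost is that the
  seizure amplitude is set by the noise gain rather than by a
  self-sustained cycle, and is more modest than empirical spike-and-wave
  discharges — a known limitation.

Along the interpolated dose paths the anesthetic arm's median exponent
rises from $\approx 0$ into clearly positive values while cross-frequency
transfer strength falls, and the seizure arm's exponent falls below zero
with the strength falling as well — the inverted-U around criticality that
`run_insilico()` reproduces at desk scale (3 doses per arm, 3 runs per
dose; the full-scale experiment would use 50 doses and 10 runs).

# Chaos quantification

## Stochastic largest Lyapunov exponent (simulations)

`stochastic_lle()` runs the model twice with identical noise and initial
conditions, adds a tiny random perturbation to every dendritic potential at
the midpoint (uniform, scaled per potential to $10^{-6}$ of its baseline
standard deviation), and measures the normalized squared divergence
$\epsilon(t)$ of the cortical and relay LFPs over the final window, each
normalized by its maximal attainable squared difference. $\Lambda$ is the
least-squares slope of $\ln \epsilon$ versus $t$. Because $\epsilon$ is a
squared distance, $\Lambda$ is twice the state-space exponent; the
uncoupled-relaxation test recovers $\Lambda = -2\alpha$ analytically.

Two windowing guards keep the fit on the exponential segment: growth is
fit only up to the first crossing of $\epsilon = 0.1$ (saturation), and
decay only down to the divergence plateau (the phase-offset/numerical
floor), in both cases with a 0.5 s minimum window so that strongly
chaotic runs that saturate almost immediately still yield a (conservative)
estimate rather than a rejected run.

## Modified 0-1 chaos test (recordings and simulations)

The K-statistic drives a planar walk with the input sequence and
correlates the time-averaged mean square displacement (plus a noise term
$\sigma \eta_n$, $\eta_n$ uniform on $[-1/2, 1/2]$, $\sigma = 0.5$) with
time, for 100 random angles $c$ drawn uniformly from $(0, 2\pi)$; K is the
median Pearson correlation. Chaotic (diffusive) dynamics give K near 1,
periodic (bounded) dynamics near 0. The input is standardized first, which
fixes the relative scale of the $\sigma$ term and makes K exactly
invariant to affine rescaling under a fixed seed. The displacement cap is
$n \le N/10$ and the noise term is redrawn per $(c, n)$ from a seeded
stream. Drawing $c$ from the full $(0, 2\pi)$ follows the method's
published form; a `c_range` argument allows the restricted range some
implementations prefer. The mean-square displacements are computed by an
FFT autocorrelation identity, which keeps 100-angle evaluation of a
5000-point series near a second.

Before the test, neural series are band-passed to 1-13 Hz with a two-pass
(zero-phase) FIR filter whose order follows the $f_s/f_{hi} \cdot A/22$
rule for $A = 85$ dB stop-band attenuation, then time-discretized to their
prominent local extrema (prominence at least 10% of the maximal absolute
amplitude), which removes oversampling of the band-limited waveform.
Recordings above 500 Hz are resampled to 500 Hz first (flag-controlled).
Fewer than ten qualifying extrema is an error ("insufficient extrema") —
by design: a signal without prominent slow extrema has no meaningful slow
chaoticity estimate.

# Spectrally resolved transfer entropy

## Estimator

Transfer entropy from $X$ to $Y$ is the conditional mutual information
$I(Y_t ; X^{(\ell)}_{t-u} \mid Y^{(k)}_{t-1})$, estimated with the
Kraskov-Stögbauer-Grassberger nearest-neighbour method ($K = 4$ neighbours,
Chebyshev balls, Kozachenko-Leonenko log-probabilities), reported in nats
(`nats_to_bits()` converts). A seeded jitter of $10^{-10}$ standard
deviations breaks ties deterministically. History lengths $k$ and $\ell$
(candidates 1-5) are chosen by the Ragwitz criterion — the embedding
minimizing a zeroth-order kNN predictor's mean squared error — and the
interaction delay $u$ by scanning 1-20 samples for maximal transfer
entropy. On smooth band-limited signals the criterion selects $k = \ell =
1$. An optional `max_centers` argument averages the log-probability terms
over an evenly spaced subset of embedding vectors (neighbour counting
always uses all points), trading a little estimator variance for
substantial speed in surrogate loops; all defaults outside the sweep and
pipeline wrappers use the full estimator.

## Band localization

The maximal overlap discrete wavelet transform (LA8 least-asymmetric
filter, 8 levels) decomposes each series into dyadic bands — level $j$
spans $(f_s/2^{j+1}, f_s/2^j]$ — and is exactly invertible (round-trip
error below $10^{-8}$, tested). All information-transfer analyses run at
416 Hz, where level 2 is 52-104 Hz (high gamma) and levels 5-8 jointly
span 0.8125-13 Hz ("~1-13 Hz", the delta/theta/alpha range). The MODWT is
implemented in the package because no installed R package provides it; the
LA8 filter pair is the standard choice of the source surrogate method.

Band-restricted surrogates replace the detail-coefficient series of each
selected level with an IAAFT-randomized version (exact amplitude multiset,
spectrum matched within tolerance, phases randomized) and
inverse-transform; out-of-band content passes through untouched. Because
MODWT level filters leak, content that coherently straddles level
boundaries loses some cross-level covariance under randomization, so the
surrogate's variance matches the original's closely only when in-band
components sit within their levels; a joint time-domain variant was
evaluated and rejected because it destroyed so much within-band structure
that transfer strength no longer discriminated coupled from uncoupled
signals. The swap-out-swap-out test then compares
the original transfer entropy against `n_surr` surrogates in which the
sender's sending band and the receiver's receiving band are randomized
jointly; the embedding is selected once on the original pair and held
fixed so the surrogate contrast isolates band content. The staged
(sender-sweep then receiver-refinement) variant of the source method is
intentionally out of scope; the joint swap is the documented contract.
Strength is the mean transfer-entropy loss; significance is the add-one
corrected $p = (1 + \#\{TE_i \ge TE_0\})/(1 + n_{surr})$, whose floor with
100 surrogates is $1/101 = 0.0099$. The add-one (original-inclusive)
convention was chosen deliberately so that the attainable floor is
well-defined and conservative.

# Preprocessing and statistics

Recordings are segmented into non-overlapping 10 s trials (remainder
dropped), demeaned, linearly detrended, band-stop filtered at the mains
frequency and harmonics (zero-phase, 2 Hz half-width), and resampled to
the working rate by Fourier-domain band-limited resampling (spectral
truncation: exact passband gain and brick-wall anti-aliasing; chosen over
the available polyphase implementation, whose passband ripple and weak
stop-band attenuation failed the resampling contracts). Welch spectra use
2 s Hann segments at 50% overlap (configurable; the convention is a
package default since no single standard exists). Artifact handling is an
`artifact_flag` honored downstream plus an optional amplitude-threshold
flagger; visual rejection is out of scope.

Group statistics: exact one-tailed Wilcoxon signed-rank tests via the
exact signed-rank null (`psignrank`; mid-ranks with a normal approximation
and a warning under ties), with `present_p()` rendering p-values at
4-decimal round-half-even (0.03125 prints 0.0312); a one-sided binomial
test across subjects; the Tort Modulation Index with 18 phase bins; LZ76
Lempel-Ziv complexity binarized at the median and normalized by
$n/\log_2 n$; the bi-symmetric log transform with $C = 1$ (both constants
are package defaults where the literature is silent); and a
permutation ANCOVA using the Freedman-Lane residual-permutation scheme —
chosen as the standard residual-permutation construction, since the
analysis this mirrors does not spell out its scheme. No multiple-comparison
correction is applied anywhere, by design.

# Synthetic benchmarks: what they do and do not show

Every estimator has a generator with known ground truth:
`gen_coupled_pair()` builds a directed low-to-high cross-frequency channel
(a stochastic narrowband 1-13 Hz drive in the sender amplitude-modulates a
52-104 Hz carrier in the receiver at a fixed delay) — amplitude modulation
is one plausible cross-frequency code among several, chosen here as a test
harness, not a physiological claim; `gen_chaos_suite()` provides canonical
periodic/chaotic/stochastic series; `gen_var_pair()` provides
linear-Gaussian autoregressive pairs whose transfer entropy has a closed
form computed by an internal regression oracle, independent of the kNN
path. Passing these tests shows the estimators recover constructed ground
truth at realistic lengths (10 s at 416 Hz) and noise levels; it does not
show that real thalamocortical recordings satisfy the estimators'
assumptions (stationarity within trials, adequate sampling of the
attractor, artifact-free channels), and the 0-1 test in particular can be
inflated by stochasticity unrelated to deterministic chaos.

# Numerical choices and degenerate inputs

Fixed seeds thread through every stochastic step (noise streams,
perturbations, surrogates, angle draws, jitters), making pipelines
bit-reproducible. Degenerate inputs take flagged paths rather than
failures where a value is still meaningful: constant series give K = 0 and
zero Lempel-Ziv with `degenerate` flags, an identically-zero envelope
gives Modulation Index 0, an empty band set is an identity surrogate.
Errors are reserved for contracts: insufficient extrema, upsampling
requests, all-zero paired differences, perturbations below numerical
resolution, unstable autoregressive coefficients, rank-deficient designs.

Problem sizes in the tests and reproduction script are deliberately
desk-scale (12-24 surrogates, 3 runs per dose, 3 doses per arm, 20 s
simulations, 10 s analysis trials); all contracts are written so the
full-scale experiment (e.g. 50 doses per arm, 10 runs per dose, 100-250
surrogates) is a parameter change, not a code change.

# Known limitations

* The seizure regime is a noise-driven subcritical resonance rather than a
  self-sustained spike-and-wave limit cycle (see above); amplitudes are
  correspondingly modest, and because the resonance is noise-driven its
  slow component is less stereotyped than empirical spike-and-wave, so the
  0-1 test reads intermediate K values deep in the periodic arm.
* The anesthetic arm's cortical firing rate rises with dose in the shipped
  configuration, opposite to the empirical dose-response decline; the
  fitness module encodes the empirically correct criterion (low cortical
  rate is rewarded) and endpoint configurations that satisfy it exist, but
  those found so far sit near regime boundaries that make the twin-run
  exponent irreproducible across noise seeds, and reproducibility was
  prioritized.
* The waking state's weak chaos is sensitive to its gain parameters;
  per-seed Lyapunov estimates near criticality scatter, and medians across
  runs are the meaningful quantity.
* The Bayesian stage of the Bayesian-genetic optimization that motivated
  the tuning module is omitted; `genetic_search()` is a pure genetic stage
  over the same stated fitness criteria.
* The shipped waking state does not reproduce a positive correlation
  between cortical firing rate and the high-gamma (60-200 Hz) LFP envelope
  (measured near zero): its high-gamma content is largely noise-driven.
  The waking fitness function rewards that correlation, so configurations
  tuned at larger budgets can recover it.
* Transfer-entropy history is capped at the Ragwitz-selected $k$; with
  $k = 1$ information storage in deep target history can be
  underestimated, inflating apparent transfer.
* Empirical file readers cover delimited text; EDF ingestion is left to
  the user's conversion tooling.
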