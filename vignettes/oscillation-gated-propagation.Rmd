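---
title: "Oscillation-gated synchrony propagation: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Oscillation-gated synchrony propagation: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The question the package addresses

Cortical and hippocampal circuits are thought to transmit signals as
synchronous pulse packets hopping along layered feed-forward subnetworks
(synfire chains). Stable propagation classically requires feed-forward
anatomy far more prominent than what is observed anatomically. This package
implements a spiking-network model in which two ingredients relax that
requirement: fast dendritic sodium spikes, which amplify *synchronous*
excitatory input supralinearly, and background oscillations, which
rhythmically bring the network's nonlinear dendrites close to threshold. The
central phenomenon is resonance: balanced oscillatory input fosters
propagation only when the stimulation frequency is rationally related to the
chain's natural layer-hop rate, and it does so without changing the mean
input — a timing effect, not a gain effect. The same machinery yields
frequency-gated routing: two chains with different conduction delays have
different resonance frequencies, so the oscillation frequency selects which
chain transmits.

## Model

Neurons are conductance-based leaky integrate-and-fire units,

$$C_m \dot V_i = g_L (E_L - V_i) + g_{ex,i}(t)(E_{ex} - V_i) +
  g_{in,i}(t)(E_{in} - V_i) + I_{ds,i}(t) + I_{0,i},$$

with threshold `V_theta`, reset `V_reset` and absolute refractoriness
`t_ref` (the membrane is clamped at `V_reset` for its duration). Each
synaptic input of strength $\varepsilon$ (always quoted as *peak
conductance*, nS) adds a double-exponential conductance transient normalized
to peak $\varepsilon$.

**Additive (linear) mode.** Conductances superpose linearly; spikes arise
only from summed somatic depolarization. No saturation is modeled.

**Non-additive (nonlinear-dendrite) mode.** Every excitatory input — feed
forward, recurrent, background and oscillatory alike — additionally lands on
a single nonlinear dendrite. If the summed peak conductance of the inputs in
the trailing window $\Delta$ reaches the dendritic threshold $\Theta_b$, a
stereotyped current pulse (sum of three positive-prefactor exponentials) is
injected into the soma after a fixed latency, the dendrite becomes
refractory for `t_ref_d`, and the window buffer is cleared. The conductance
counted within one window is capped, which, together with dendritic
refractoriness, reproduces the experimentally observed saturation of the
somatic depolarization. Inhibition never enters the window sum (dendritic
sodium spikes resist inhibition) but still shunts the soma and can prevent
the dendritic spike from triggering a somatic one. The assignment of *all*
excitatory input to the single nonlinear dendrite resolves an underdetermined
modeling choice; it is the simplest reading consistent with oscillatory input
"effectively lowering" the dendritic threshold, and it is what the
predecessor models of this family do.

## Standard parameters and why

The numerical parameter set targets hippocampal CA1/CA3 pyramidal neurons
and is the package's own calibration (see *Provenance* below): membrane
`C_m` = 400 pF, `g_L` = 25 nS (so the membrane time constant is 16 ms),
`E_L` = `V_reset` = −65 mV, `V_theta` = −50 mV, `t_ref` = 3 ms. AMPA-like
excitatory and GABA_A-like inhibitory kernels share rise/decay constants
0.5/2.0 ms with reversal potentials 0 and −75 mV. The excitation/inhibition
balance ratio $\alpha \approx 6.63$ is *computed* (once per parameter set)
so that single EPSP and IPSP peaks from rest are equal; "balanced" always
means this condition.

Dendritic compartment: window $\Delta$ = 2 ms, threshold $\Theta_b$ = 8.65 nS
(roughly nine 1-nS synchronous inputs), conductance cap 1.5 $\Theta_b$,
dendritic-spike latency 2.7 ms, current prefactors (6, 4, 1) nA with decay
constants (0.5, 1.5, 4) ms — a brief ~11 nA pulse whose free somatic
depolarization (~25–30 mV) reliably triggers a somatic spike with
sub-millisecond jitter, as in single-neuron experiments on fast dendritic
spikes — and dendritic refractoriness 5 ms. These values make the spike
latency after suprathreshold input *constant* (~3.3 ms), versus the strongly
strength-dependent latency of the additive mode; this dichotomy is what
makes the non-additive propagation frequency well-defined and resonance
possible.

Background: independent excitatory and inhibitory Poisson trains per neuron
at 0.6 kHz each, strengths 1 nS and $\alpha$ nS. At this working point the
ground state is balanced, fluctuation-driven and very sparse (≲0.05 Hz);
the asynchronous-irregular character of background-driven firing (ISI CV ≈ 1,
negligible pairwise correlation) is verified in the test suite at a 1.2 kHz
background, where ground firing (~2 Hz) yields enough spikes for the
statistics. The sparse standard working point is deliberate: the dendritic
threshold must sit several window-noise standard deviations above the mean
background window sum, otherwise oscillatory support tips the network into
pathological mass synchrony before it can support propagation.

Oscillation: a virtual population of `n_osc` sources fires once per cycle,
Gaussian-jittered (σ = 1 ms, tails untruncated) around cycle centers
`t_k = phase + k/nu_stim`; each source spike reaches each neuron
independently with probability 0.5 per sign, at 0.1 nS excitatory strength
and its balanced inhibitory partner scaled by the unbalance factor `g`. Many
weak quanta rather than few strong ones keep the per-cycle delivered drive
tight around its mean — with coarse quanta the delivery variance triggers
spontaneous dendritic crossings long before the mean drive is useful.
Amplitude is controlled by `n_osc` (mean per-cycle excitatory drive =
`0.05 * n_osc` nS): supportive around 100–140, pathological beyond ~160 at
standard parameters.

Network: directed Erdős–Rényi graph, standard connection probability 0.1
for both signs (a pair may carry both an excitatory and an inhibitory edge;
no self-loops), FFN layers assigned as disjoint random groups, existing
consecutive-layer edges upgraded to `eps_ff` (never added). The scaled-down
standard chain is 10 layers × 150 neurons, so each neuron receives ~15
feed-forward inputs. Connectivity 0.1 rather than a sparser value is a
deliberate scale compensation: at desk scale the binomial sender-count
variance must stay small relative to its mean or the layer-to-layer map
loses its stable high fixed point.

Delays: homogeneous 2 ms standard; uniform, fixed-mode log-normal
($\mu = \ln d_{mode} + \sigma^2$, sd $= d_{mode} e^{3\sigma^2/2}
\sqrt{e^{\sigma^2}-1}$) and hippocampal distance-based variants
(uniform neuron positions on a square patch, axonal delay = pairwise
distance / 300 µm/ms, plus dendritic delay uniform on [0.5, 1.5] ms).
With a 2 ms delay and ~3.3 ms latency the natural layer-hop rate is
~180–190 Hz — ripple range, as appropriate for the hippocampal analogy.

## The analysis layer

**Detector.** A pulse initiated at `t0` (forcing 80% of layer 1 by default)
is traced layer by layer: the layer count $\chi_k$ maximizes the spike count
in a 3 ms window centered at $t_{k-1} + \delta$ over shifts
$\delta \in [0, 10]$ ms (ties to the smallest shift); the chance level
$\lambda_k$ is the smallest count whose sliding-window exceedance
probability in a non-initiated control run (identical stimulation) is ≤
0.05; a layer succeeds iff $\chi_k / \lambda_k \ge 2$ and all previous
layers succeeded. The published form of the chance-level inequality was not
recoverable from the available text; the upper-count-quantile reading
implemented here is stated in the detector documentation and fixed
throughout.

**Iterated map.** From the measured single-neuron response probability
$\hat p(g)$, the expected synchronous group size follows the binomial
mixture $G(\xi) = w \sum_k B(k;\xi,p)\, \hat p(k \varepsilon_{ff})$,
evaluated continuously in $\xi$ through the gamma-function interpolation of
the binomial weights, with $G(0) = w\hat p(0)$ as the continuum limit.
Fixed points come from sign changes of $G(\xi)-\xi$ polished by root
finding; stability from the numerical slope. The propagating regime is born
in a tangent bifurcation (1 → 3 fixed points) as `eps_ff` grows; the
package's bisection for the critical coupling is validated against a dense
grid scan on a closed-form step-response family, and $G$ itself against a
direct Monte-Carlo simulation of the binomial layer model.

**Critical coupling from simulation.** Bisection on `eps_ff` with success
defined as ≥ 50% of trials detected to the final layer. At strong
oscillation amplitudes propagation exists only on an interval
(`eps_crit`, `eps_patho`): beyond the pathological bound the control run
itself carries spontaneous synchronous waves and detection fails. The
search therefore probes the interior for a working coupling when the upper
bracket end fails, and reports the pathological bound separately (flagged
when the control FFN rate exceeds 60 Hz — mass synchrony recruits most
neurons every cycle, an order of magnitude above the supported regime's
cycle-locked activity).

**Headline experiment.** `oscillation_coupling_reduction()` measures the
no-oscillation critical coupling, the propagation frequency at the onset of
propagation, and the minimum oscillation-supported critical coupling over an
amplitude grid (mirroring the coupling-versus-amplitude phase diagram).
With standard parameters the reduction factor computed by
`scripts/acceptance.R` falls in the factor two-to-three range.

## What the generators emulate — and what a green test does not establish

All data are synthetic: topologies, delays, Poisson background and
oscillatory drive are generated from seeds (one master seed, independent
named streams per component, engine noise from dedicated deterministic
generators). The generator's defaults *are* the model world described
above. Green tests therefore establish that the implementation reproduces
the stated regimes of that world — the latency dichotomy, the response
discontinuity at $\Theta_b$, suppression vs. facilitation by balanced
oscillations, resonance bands with rational locking, gating, broad-delay
compensation — at desk scale. They do not establish parameter-free
quantitative predictions for biological tissue: real circuits have
heterogeneous cell parameters, structured (non-ER) connectivity, conductance
states far richer than two exponential kernels, and oscillations generated
within the network rather than delivered by a virtual population.

## Numerical choices

Fixed-step exponential-Euler integration (default dt = 0.1 ms, configurable;
convergence is tested by halving dt), conductances held per step via exact
rise/decay accumulators, threshold crossings resolved to the step, delays
rounded to the nearest step (minimum one step), delivery scheduled so a
spike at `t` arrives at exactly `t + round(d/dt)·dt`. Initial potentials are
drawn uniformly between reset and threshold; propagation trials use a
300 ms settling period before initiation. The initiating pulse is forced
spikes in a random 80% of layer 1, placed in phase with the oscillation by
putting a cycle center at the layer-2 arrival time (`t0` + mean delay). The
response window for single-neuron response probabilities is 10 ms.
Bisection tolerances: 0.05 nS (simulation), 10⁻³ nS (map family, tested at
10⁻⁴). Locking ratios use integers ≤ 4 and a 2% relative tolerance. The
additive unbalance-versus-constant-current equivalence is judged as depths
within two layers at matched amplitudes with a shared monotone trend —
"equal up to trial noise" made concrete.

## Provenance of the standard parameters

The parameter values above reconstruct a standard hippocampal-type
configuration from the modeling literature on dendritic-spike-supported
synchrony propagation; where a value could not be pinned down it was chosen
once, on biophysical plausibility, and calibrated only against the
qualitative regime structure (sparse balanced ground state; ripple-range
natural frequency; a supported oscillation wedge below the pathological
bound). All of them are configuration, not constants: every constructor
accepts replacements, and the experiment layer passes them through.

## Known limitations

- Single nonlinear dendrite per neuron; no NMDA/calcium plateaus, no
  multi-compartment cable, no plasticity.
- Inhibition is a direct fast feedback caricature (no interneuron
  population).
- The pathological-state flag is a rate heuristic, deliberately coarse.
- Event delivery is step-quantized; sub-dt delay structure is not resolved.
- The recurrent embedding is kept weak; prominent recurrence with nonlinear
  dendrites and strong oscillatory drive readily produces epileptic-like
  mass synchrony, which the gating default avoids by construction.
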