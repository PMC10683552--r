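---
title: "Modelling status-dependent modulation of the Mauthner-cell escape circuit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling status-dependent modulation of the Mauthner-cell escape circuit}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

```{r setup}
library(mcescape)
```

## The circuit and its model

Zebrafish escape from threatening stimuli with a fast C-start initiated by a
single spike of the Mauthner cell (M-cell), a paired hindbrain command
neuron. Social status reshapes this behavior: dominant fish are less
startle-sensitive than subordinates, and pharmacology implicates three
interacting neuromodulatory inputs — dopaminergic (D1), GABAergic, and
glycinergic. `mcescape` implements a minimal conductance-based circuit that
reproduces this logic with four cells:

* an **excitatory sensory cell (E)** standing in for the auditory afferent
  drive; it is the only cell receiving the external stimulus;
* a **GABAergic interneuron (GA)** driven by E, inhibiting the glycinergic
  cell and the M-cell;
* a **glycinergic interneuron (GL)** driven by E (with a D1-dependent gain)
  and inhibited by GA, providing feed-forward inhibition of the M-cell;
* the **M-cell (M)**, receiving all three inputs plus a small constant drive
  from its contralateral partner.

Each cell is a modified Morris–Lecar membrane: an instantaneous calcium
current, a potassium current with gating variable $n$, a leak, and a
calcium-gated potassium current fed by a slow intracellular calcium balance,

$$C \frac{dv}{dt} = -I_{Ca} - I_K - I_L - I_{KCa} - I_{syn} + I_{app}(t),
\qquad \frac{d[Ca]}{dt} = \varepsilon(-\mu I_{Ca} - k_{Ca} [Ca]).$$

Chemical synapses follow first-order channel-activation kinetics
$ds/dt = \alpha s_\infty(v_{pre})(1-s) - \beta s$. Two neuromodulatory
mechanisms sit on top:

* **D1 gain**: excitatory input to GL is scaled by $(1 + D1_{GL})$ and to M
  by $(1 + D1_M)$, modelling dopamine receptor activation as a multiplicative
  enhancement of the input a cell receives.
* **Retrograde gain $g_I$**: all presynaptic inputs to the M-cell are scaled
  by a slow gain that decreases with the M-cell's intracellular calcium,
  $dg_I/dt = (g_{I,max}/([Ca]+k_2) - g_I)/\rho$ with $\rho = 10^4$ ms,
  modelling calcium-dependent retrograde suppression of release.

Voltages are in mV and time in ms; conductances, currents and calcium follow
the dimensionless Morris–Lecar convention, so no unit conversions are
performed. All default parameter values are exposed through
`cell_params()`, `synapse_kinetics()`, `connection_params()`,
`modulation_params()` and `network_config()`.

Social status enters as two presets differing in exactly three numbers
(`mcell_preset()`): the dominant-like circuit has a strong D1 gain on the
glycinergic cell ($D1_{GL} = 0.65$) and a weak GABA→glycine conductance
($g_{GA \to GL} = 0.2$); the subordinate-like circuit has $D1_{GL} = 0.25$
and $g_{GA \to GL} = 0.4$. A third status-specific parameter, the glycinergic
decay rate $\beta_{GL}$ (0.024 dominant, 0.0072 subordinate, versus 0.08 at
baseline), applies only under GABA-receptor blockade, where slowed decay
prolongs glycinergic inhibition of the M-cell. We read the source model this
way because the lowered $\beta$ values are introduced specifically to
simulate GABA-receptor blockage; making them baseline status parameters is
the main alternative reading, and `apply_condition(..., beta_GL = )` lets a
user explore it.

### What a "response" is

The in-silico experiment delivers 2-ms square current pulses of strength
$W_E \in \{10, 15, \ldots, 60\}$ to the E cell at 1-s intervals, ten pulses
per strength, each strength starting from a freshly settled state
(`response_curve()`). The published curves plot a "simulated response"
without defining the readout, so the readout is a design decision here: a
pulse counts as a response when the M-cell fires at least one spike (upward
crossing of 0 mV, 5-ms refractory) before the next pulse. We use the full
interstimulus interval rather than a short post-pulse window because the
E cell, with its large capacitance ($C = 20$) sitting just below a
saddle-node threshold, answers a brief pulse with a first-spike latency that
ranges from roughly 20 ms at $W_E = 60$ to several hundred ms near
threshold; a short window would score E-cell latency rather than M-cell
recruitment. The per-pulse spike counts are retained as a secondary readout
(attribute `spike_counts`).

The grading of the response fraction between 0 and 1 at intermediate $W_E$
is deterministic history dependence, not noise: residual slow variables
(intracellular calcium, the retrograde gain) carried from one pulse's
network volley to the next flip marginal pulses.

### Initial conditions and settling

The source material does not state initial conditions or a settling
procedure, so we choose a deterministic, attractor-respecting start: every
cell at its leak reversal with $n = n_\infty(v_L)$, zero calcium, silent
synapses, and the retrograde gain at its zero-calcium fixed point
$g_{I,max}/k_2 = 1.5$ (`initial_state()`). Simulations then settle
stimulus-free for 30 s by default — three time constants of $g_I$, the
slowest variable — so protocols start from the circuit's converged quiescent
equilibrium. Both choices matter: $g_I$ multiplies every synaptic input to
the M-cell, and the response curves are sensitive to its value at stimulus
onset. A 5-s settle from an arbitrary $g_I$ leaves the gain several percent
from its attractor and visibly distorts the curves (for example, the
dominant-like control circuit then fails to fire even at $W_E = 60$).

### Numerics

Integration is classical fixed-step RK4 at $dt = 0.01$ ms, the printed step
size; the source text also mentions adaptive stepping, and we chose the
fixed step for bit-reproducibility, substituting step-halving convergence
checks (spike counts preserved and spike times shifted by well under 0.1 ms
at $dt = 0.005$) for adaptivity. The multi-step integrator is compiled
(Rcpp) for speed; the exported `derivatives()` and `rk4_step()` form a pure-R
reference path, the test suite ties the two paths together to $10^{-10}$,
and an independent literal transcription of the model equations serves as an
equation oracle at $10^{-12}$ relative tolerance. Two further guards:
integration aborts with an error if any $|v| > 500$ mV or any state variable
becomes non-finite (rather than propagating NaN), and every simulation
tracks the extrema of the bounded state variables ($n, s \in [0,1]$,
$[Ca] \ge 0$, $g_I \ge 0$) at every step, exposed as a `bounds` attribute.

The printed equation for $g_I$ is typographically garbled in the source; we
integrate $dg_I/dt = (g_{I,max}/([Ca]+k_2) - g_I)/\rho$, which gives an
order-one gain with $\rho$ acting as its time constant, consistent with the
surrounding text. The alternative reading
$dg_I/dt = g_{I,max}/([Ca]+k_2) - g_I/\rho$ (fixed point $\approx 1.4 \times
10^4$, which would saturate the M-cell) is available behind
`network_config(gI_law = "linear_decay")` but is not the default. Similarly,
the printed synaptic activation is parenthesized ambiguously; we use the
standard sigmoid $s_\infty(v) = 1/(1+\exp(-(v-\theta_s)/\sigma_s))$.

### What the pharmacology experiments show

`apply_condition()` implements the three blockades exactly as parameter
overrides: D1 antagonism ($D1_M = D1_{GL} = 0$), GABA-A antagonism
($g_{GA \to M} = g_{GA \to GL} = 0$ plus the status-specific $\beta_{GL}$),
and glycine-receptor antagonism ($g_{GL \to M} = 0$). On the full grid the
model reproduces the qualitative status logic: the dominant-like control
curve sits well below the subordinate-like one (grid-summed response 4.9
versus 8.3 on the default protocol), D1 or glycine blockade disinhibits the
dominant-like circuit strongly (+3.4 grid-summed response each) while
leaving the subordinate-like circuit unchanged, and GABA blockade suppresses
the subordinate-like circuit (−0.9). The mechanism is a race: the
glycinergic cell, pre-depolarized during the E cell's slow approach to
threshold in proportion to $(1+D1_{GL})$, can veto the M-cell's response to
the E spike; blockades shift who wins.

One effect is only partially reproduced: GABA blockade in the dominant-like
circuit, reported as leaving the startle curve unaltered, here produces a
mild disinhibition (+1.4 grid-summed, the smallest of the non-null effects).
Decomposing the three overrides shows why: zeroing $g_{GA \to GL}$ chronically
disinhibits the glycinergic cell, whose accumulated calcium then recruits its
calcium-gated potassium current and weakens its veto (+1.9), outweighing the
prolonged inhibition from the lowered $\beta_{GL}$ (−1.0). Under the printed
equations these contributions do not cancel; the corresponding acceptance
test asserts the "unchanged" band and fails honestly rather than being
loosened.

## Behavioral analysis

`detect_swim_bursts()` implements the published burst criteria — at least
8 mV peak-to-peak and 30–200 ms duration — on top of an explicit detection
rule, since the original analysis used a commercial threshold tool without
an algorithmic description. Deviations from the trace median are enveloped
with a 25-ms running maximum (bridging carrier zero-crossings), segmented
with 4 mV enter / 2 mV exit hysteresis to prevent chatter, merged across
gaps under 10 ms, trimmed to the raw-deviation extent, and only then tested
against the printed amplitude and duration thresholds. A brute-force
segment-scan oracle in the test suite reproduces the event set exactly on
random synthetic traces.

`filter_mauthner_trials()` applies the 5–15 ms latency window that separates
Mauthner-initiated startles from slower responses; `startle_probability()`
tabulates per-animal response fractions on the 70–100 dB grid and averages
across animals; and `fit_boltzmann()` fits
$Y = Bottom + (Top - Bottom)/(1 + \exp((V_{50} - X)/Slope))$
by Levenberg–Marquardt least squares with a fixed initial-guess rule
(Bottom = min, Top = max, $V_{50}$ at the mid-range point, Slope = 5 dB) so
fits are deterministic. Constant data yield a flagged degenerate fit with a
warning instead of an error.

## qPCR quantification

`analyze_qpcr()` chains the comparative ΔΔCt procedure: technical replicates
averaged per sample, ΔCt against the reference gene *actb2*, ΔΔCt against
the social-isolate control group (arithmetic means within groups), and
conversion to fold change with primer-efficiency correction, reported on a
log2 scale. Efficiencies are the shipped standard-curve panel
(`primer_efficiencies()`), interpreted as amplification factors
$E = 1 + \text{efficiency}/100$; values above 100% are retained as the
common standard-curve artifact they are, with a warning above $E = 2$. The
exact correction formula is not printed in the source, so the default is the
Pfaffl ratio $E_t^{-\Delta Ct_t} / E_{ref}^{-\Delta Ct_{ref}}$ (exponents
are group-minus-control differences of raw Ct means), which collapses to
$E^{-\Delta\Delta Ct}$ for equal efficiencies and to the textbook
$2^{-\Delta\Delta Ct}$ at 100%; the single-power variant is available as
`method = "ddct"`.

## Synthetic data and what passing tests mean

The generators in `gen_swim_trace()`, `gen_startle_trials()` and
`gen_ct_table()` are pure functions of their arguments and seed, and carry
their ground truth so every analysis stage has an end-to-end recovery test:

* swim traces are Tukey-enveloped 30-Hz sinusoid packets on Gaussian
  baseline noise (0.5 mV sd by default, matching a clean chamber recording);
* startle outcomes are Bernoulli draws from a known Boltzmann curve
  ($V_{50} = 85$ dB, Slope = 3 dB by default, mid-grid values a real fish
  would plausibly show), with uniform 6–14 ms latencies and an optional
  fraction of >15 ms contaminants to exercise the latency filter;
* Ct tables encode known log2 fold changes through the same efficiency model
  the analysis inverts, with 0.2-cycle biological noise and technical
  duplicates, n = 10 per group as in the assay design.

These generators emulate the statistical structure the analyses assume —
they do not emulate electrode physics, movement artifacts, amplifier drift,
multi-burst swim rhythms, or pipetting covariance between wells. Passing
recovery tests therefore demonstrates that the pipeline correctly inverts
its own declared data model at realistic noise levels (V50 within ±1 dB
from 40 animals × 5 trials; log2 fold within ±0.3 at n = 10), not that it
is robust to every artifact of real recordings.

## Problem sizes and limitations

The full in-silico pharmacology (2 presets × 4 conditions × 11 stimulus
strengths × 10 pulses at $dt = 0.01$ ms with 30-s settling) integrates about
$10^8$ RK4 steps and completes in roughly two minutes on one core; the
remaining analyses are sub-second. Known limitations: a single explicit
M-cell (the contralateral partner is a constant drive, following the source
model); no channel noise or adaptive stepping; the response readout and the
settling protocol are package design choices where the source is silent; and
the dominant-like GABA-blockade direction is only partially reproduced, as
discussed above.
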