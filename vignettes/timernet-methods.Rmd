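---
title: "Modelling interval timing and its optogenetic perturbation with timernet"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling interval timing and its optogenetic perturbation with timernet}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(timernet)
```

## The model

`timernet` simulates a modular cortical circuit in which recurrently
connected excitatory **Timer (T)** cells learn to span a temporal interval,
inhibitory interneurons gate a population of **Messenger (M)** cells, and
the time at which the population-average M firing rate peaks is the
network's *report* of the stored interval.  Each functional column holds
400 conductance-based leaky integrate-and-fire neurons, split 160 T / 80
I~T~ / 80 M / 80 I~M~, where the two inhibitory subsets are associated with
the Timer and Messenger populations respectively.  Multiple columns, each
driven by its own feed-forward input channel bank, are chained by plastic M
&rarr; next-column-T projections into a sequence representation.

Membrane dynamics follow the standard conductance-based form

$$C\,\dot V_i = g_L (E_L - V_i)\,\sigma_L(t) + g_{E,i}(E_E - V_i) +
  g_{I,i}(E_I - V_i) + I_{opto},$$

integrated with Euler's method at `dt = 0.1` ms.  A spiking neuron is reset
to &minus;61 mV and held there for a 2 ms refractory period.
$\sigma_L(t)$ is a multiplicative leak-noise factor drawn each step from a
normal distribution with mean 1 (default sd 0.1).  Synaptic conductances
are products of a weight and a per-neuron activation $s$ that jumps by
$\rho(1 - s)$ on presynaptic spikes and decays exponentially; all weights
are non-negative, with inhibition acting through the reversal potential
$E_I$.  Per-neuron spike thresholds are spread uniformly (7 mV by default)
to give populations a graded recruitment curve rather than an all-or-none
cliff; this population heterogeneity is what lets the Timer pool decay
smoothly.

### How a column times an interval

Numerical experiments with a purely recurrent Timer pool showed an almost
binary behaviour: activity either collapsed within a few hundred
milliseconds or locked into a saturated persistent state, with essentially
no intermediate durations.  The package therefore shapes the Timer envelope
with two auxiliary synaptic components, both conventional biophysics:

* the ignition — the feed-forward pulse, or a learned launch from the
  previous column — drives a **saturating slow envelope trace**
  (`tau_envelope` = 600 ms, amplitude `g_envelope`) on the Timer cells.
  Because the trace saturates, the envelope is stereotyped no matter how
  strongly the column was ignited, so a column launched internally behaves
  like one stimulated externally.  The recurrent T&rarr;T weights amplify
  the fading drive; stronger recurrence stretches the envelope, which is
  exactly the knob the plasticity rule tunes;
* the I~T~ subset reads the instantaneous Timer rate through a fast
  AMPA-like pathway (`tau_gate = 10` ms) and strongly inhibits M.  Its
  raised, narrowly spread threshold makes it cut out sharply when the
  Timer rate falls below a fixed readout level, releasing the Messenger
  burst — the disinhibition window that reports the stored time;
* the burst recruits I~M~ through both a fast synapse and a slow one
  (`w_M_IM_slow`); the slow component arms a **persistent hold** that
  clamps the column after its report so the fading input trace cannot
  re-ignite it.  Without this hold the columns re-ignite raggedly and
  sequences lose their order.

The M burst of column *k* launches column *k*+1 through the learned
feed-forward projections: they ignite the downstream Timer pool, charge
its envelope trace (in proportion to the learned weight, saturating at the
class ceiling), and — through a static M&rarr;next-I~T~ projection —
close the downstream Messenger gate the same way external input does.

### Learning rule

Each plastic synapse (T&rarr;T recurrent, T&rarr;M, M&rarr;next-T) carries
two eligibility traces obeying

$$\tau^x \dot T^x_{ij} = -T^x_{ij} + \eta^x H_{ij}
  \frac{T^x_{max} - T^x_{ij}}{T^x_{max}}, \qquad x \in \{p, d\},$$

with $H_{ij}$ the product of exponentially filtered pre- and post-synaptic
rates (filter 25 ms).  The LTP trace is fast-activating, slower-decaying
($\eta^p = 4\times10^{-4}$, $\tau^p = 350$ ms) and saturates at 1; the LTD
trace activates more slowly, decays quickly ($\eta^d = 6\times10^{-5}$,
$\tau^d = 150$ ms) and saturates at 2.  A reinforcement delta at each
element-transition time converts the trace difference into a weight step
$\Delta W = \eta\,(T^p - T^d)$, clipped at zero and at a per-class
ceiling, and *consumes* the traces it converts (they are zeroed after the
event, as in standard eligibility-trace reinforcement learning; without
consumption a column that finished early would receive pure potentiation
at every later sequence transition, because its LTD trace decays faster by
construction).  Traces are zeroed at trial start; networks train for 100
trials with the reward step annealed over the last 40% of trials (floor
0.3x) so the weights settle at the equilibrium instead of orbiting it;
afterwards the weights are frozen.

The combination is self-stabilising: while a column is still active at the
reinforcement time the saturated LTD trace exceeds the LTP trace and
recurrent weights shrink; when activity has terminated well before the
reinforcement the LTD trace has collapsed while the LTP trace persists, and
weights grow.  The stable fixed point puts the Messenger burst (which
terminates the column via the I~M~ hold) slightly before the
reinforcement.  Because the equilibrium tracks the *burst* time, any
manipulation that shifts the burst — such as an optogenetic current in the
inhibitory cells — is compensated by the recurrent weights during
training, which is the origin of the train/test interaction analysed in
the crossing experiment.

The T&rarr;M and M&rarr;T classes are given saturating ceilings
(`w_TM_max`, `w_MT_max`).  A brief-burst Hebbian product combined with a
delta reward is unconditionally potentiating for these classes (the LTD
trace never catches up during a ~50 ms burst), so without a physiological
saturation they would grow without bound; with the ceiling they act as
learned, saturated couplings while the timing equilibrium lives entirely
in the recurrent class.

### Simulated optogenetics

The current $I_{opto} = L_I(t)\,g_{opsin}\,N_{eff}\,\sigma_r(t)$ is
injected into every inhibitory cell (both subsets, all columns) while the
simulated laser is on.  Following the figure-label convention of the
optogenetics literature on this circuit, positive $g_{opsin}$ denotes an
inhibitory opsin (hyperpolarizing the interneurons: network
*disinhibition*) and negative $g_{opsin}$ an excitatory opsin (*excess
inhibition*).  $\sigma_r(t)$ is per-neuron, per-step noise with mean 1
(sd 0.1), so the expected magnitude while on is $|g_{opsin}| N_{eff}$.
$N_{eff}$ was calibrated once so that the printed manipulation levels
($g_{opsin} = +1.5$ and $-1.0$) produce clear, monotone report shifts while
leaving at least ~80% of trials interpretable, and is fixed at 0.03 for
every experiment.  The current is an additive current, not a conductance,
and deliberately ignores opsin photocycle kinetics.

Mechanistically, hyperpolarizing I~T~ raises the Timer-rate level at which
the gate releases, so the burst comes earlier and taller; depolarizing I~T~
holds the gate longer, so the burst comes later and smaller.  Because the
Timer envelope itself is paced by the input trace rather than by
inhibition, these shifts are monotone in $g_{opsin}$ across the functional
range.  At strong disinhibition the hold fails and recurrent excitation
runs away (the epileptic regime, max average M rate above 180 Hz); at
strong excess inhibition the gate never opens (flat trials, M rate range
under 5 Hz).

## Readout and statistics

Population rates are spike histograms (5 ms bins) normalised to Hz per
neuron and smoothed with a 20 ms Gaussian.  A trial is classified, in fixed
precedence, *epileptic* (any column's average M rate above 180 Hz), *flat*
(any column's M rate range below 5 Hz), *misordered* (column M peak times
not strictly increasing in the trained order, or a peak failing to rise one
standard deviation above its trace baseline — an automated stand-in for
visual inspection), else *valid*.  Reports are only read from valid trials,
as the earliest argmax of the M trace relative to stimulus onset.

The *functional range* is the maximal contiguous set of tested
$g_{opsin}$ levels containing 0 whose valid-trial fraction is at least
0.8.  Sweep summaries report medians, type-7 quartiles and the SEM.  The
train-by-test crossing is analysed with a fixed-effects two-way ANOVA
(type-II sums of squares, so invalid-trial exclusion that unbalances cells
is handled) with Bonferroni-corrected pairwise post-hoc comparisons; the
implementation is `stats::lm` + `car::Anova` behind the package interface,
and the test suite checks it against a hand-computed sums-of-squares
decomposition on balanced designs.

## Synthetic fixtures

`generate_fixture()` emulates per-column Messenger rate traces with
controllable peak time, height, noise and pathology (`normal`,
`epileptic`, `flat`, `misordered`), each satisfying its classification
criterion by construction.  These close the loop on the readout stage
without running the simulator, but they share none of the simulator's
dynamics: passing fixture tests validates the readout arithmetic, not the
circuit model.

## What the simulations do and do not show

All data in this package are simulated; the generator's default parameters
are the study conditions (400 neurons per column, 100 training trials, a
100 ms / 500 Hz Poisson pulse per element, full-trial laser schedules, the
printed thresholds 180 Hz / 5 Hz / 0.8, and manipulation levels bracketing
$-1.0$ and $+1.5$).  Trial-to-trial variability comes from Poisson input
realisations, leak noise and opto noise; because the timing envelope is
drift- rather than fluctuation-dominated, report distributions are
narrower than those of a biological circuit would be.  Numeric membrane
and synaptic constants not fixed by the architecture were chosen once as
conventional cortical LIF values and calibrated so that a trained single
column reports 0.5–2 s targets within tolerance; they live in
`inst/extdata/default_config.yaml`, never in code.

Problem sizes in the tests and the acceptance script are scaled to desk
hardware: 50–100 recall trials per condition instead of 1,000, sweeps over
seven-level grids, and sequence recall at the four printed element times.
The directional and distributional conclusions are unchanged by the
scaling; only the standard errors widen.

## Known limitations

* Timer rates sit high (hundreds of Hz) compared with cortical neurons;
  the readout thresholds apply to Messenger rates, which stay in a
  physiological range.
* The report equilibrium carries a small systematic bias (reports settle
  within about ±10% of the trained target rather than exactly on it), the
  residue of the finite gap between the eligibility-trace crossing and the
  reinforcement instant.
* Only the two inhibitory subsets of the circuit are modelled; no
  PV/SOM/VIP distinction, no conduction delays, no short-term plasticity,
  and the optogenetic current has no photocycle kinetics.
* The fourth column of a sequence inherits timing errors of the upstream
  columns, so its report distribution is wider than a single trained
  column's.
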