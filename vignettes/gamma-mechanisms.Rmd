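---
title: "Modeling cortical gamma: mechanisms, LFP synthesis, and burst statistics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling cortical gamma: mechanisms, LFP synthesis, and burst statistics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(gammanet)
```

`gammanet` simulates conductance-based spiking networks that generate cortical
gamma oscillations (30-90 Hz) by three classical mechanisms, synthesizes a
local field potential (LFP) from their spike trains, and provides the
statistical chain used to characterize single-unit behavior during gamma
bursts. This vignette explains the models, the parameter choices the package
makes where the design was genuinely open, and what its synthetic benchmarks
do and do not show.

## The neuron model

Every cell is an adaptive exponential integrate-and-fire (Adex) neuron with
conductance-based synapses:

$$C \dot V = -g_L (V - E_L) + g_L \Delta\, e^{(V - V_T)/\Delta} - w
  - g_E (V - E_E) - g_I (V - E_I) + I_{ext},$$
$$\tau_w \dot w = a (V - E_L) - w,$$

with exponential conductance decay (time constants $\tau_E$, $\tau_I$) and a
discrete jump $Q$ per presynaptic spike. A spike is emitted when $V$ crosses
the numerical cutoff `v_cut`; then $V \to V_{rest}$, $w \to w + b$, and both
$V$ and $w$ are held for the refractory period $T_{ref}$ while the synaptic
conductances keep decaying and accumulating input (they are synapse-side
quantities). Integration is forward Euler at `dt = 0.1` ms; conductance decay
uses the exact exponential factor by default (`"euler"` is available for
bit-parity experiments). Halving `dt` changes single-neuron spike counts by
at most one spike per second, and this is asserted in the test suite.

Units are the natural ones for this model family -- pF, nS, mV, ms, pA --
under which $\mathrm{pA}/\mathrm{pF} = \mathrm{mV}/\mathrm{ms}$, so the
equations integrate without any conversion layer. Currents at the user
interface (`I_ext`, current traces) are in nA.

Three cell types are provided (`adex_params`): regular-spiking pyramidal
cells (RS; adapting, $a = 4$ nS, $b = 20$ pA), fast-spiking interneurons
(FS; non-adapting, $a = b = 0$) and chattering cells (Ch; strong subthreshold
adaptation $a = 80$ nS, short $T_{ref} = 1$ ms, depolarized $E_L = -58$ mV,
which together produce burst firing).

### The threshold interpretation

The tabulated cell thresholds (RS $-40$ mV, FS/Ch $-47.5$ mV) admit two
readings: as the exponential take-off threshold $V_T$ itself, or as the
numerical detection cutoff $V_{cut} = V_T + 5\Delta$ above a common take-off
threshold $V_T = -50$ mV -- each printed value equals $-50 + 5\Delta$
exactly, and $V_T + 5\Delta$ is the standard detection convention for the
Adex model. The two readings produce very different network excitability.
Under the literal reading the networks fall far from every published
operating point (the interneuron Gamma Network oscillates near 90 Hz instead
of 70 Hz and pyramidal cells are essentially silent in the PING and CHING
architectures); under the shifted reading all architectures reproduce their
published frequencies and per-type firing rates. The package therefore
builds networks with the shifted reading by default (`threshold = "shifted"`
in `build_network()`), keeps the literal one available for comparison, and
leaves `adex_params()` presets literal so the published table round-trips
exactly.

## The network architectures

All architectures use random (Erdos-Renyi, autapse-free) connectivity with a
uniform 1.5 ms synaptic delay, and are driven by 20000 external Poisson
trains each connected to every neuron with probability 2% (so every neuron
receives 400 trains on average, and pairs of neurons share 2% of their drive
-- a weak common-input correlation). The drive rate per train,
$\mu_{Ext}$, switches the network between an asynchronous-irregular-like
("AI-like") state and a gamma state.

* **PING** (pyramidal-interneuron gamma): 20000 RS + 5000 FS at $p = 2\%$,
  $Q_E = 5$ nS, $Q_I = 3.34$ nS, $\tau_E = 1$ ms, $\tau_I = 7.5$ ms.
  The two sources that report the excitatory time constant disagree (1.5 ms
  versus 1 ms at the parameter-search location); the package uses 1 ms, the
  value consistent with the synaptic-gain normalization
  $Q = Q^{ref}\tau^{ref}/\tau$ that the other synapse and the drive obey
  ($5\,\mathrm{nS} \times 1\,\mathrm{ms} = 1\,\mathrm{nS} \times 5\,\mathrm{ms}$).
  At 1.5 ms the recurrent excitatory charge is 50% above the normalized gain
  and the network is runaway-unstable (population rates above 100 Hz at any
  size), which is incompatible with the published regime. Gamma at
  $\mu_{Ext} = 3$ Hz ($\approx$ 37-45 Hz rhythm, RS $\approx$ 1 Hz,
  FS $\approx$ 6 Hz), AI-like at 2 Hz.
* **AI**: same sizes at $Q_E = 1$ nS, $Q_I = 5$ nS, $\tau_E = \tau_I = 5$ ms.
  Asynchronous and irregular at any drive; serves as the no-oscillation
  control for the responsiveness protocols. (Its drive strength is not
  printed; the package uses $Q_{Ext} = 1$ nS, whose drive charge
  $Q_{Ext}\tau_E = 5$ nS ms matches the other architectures': PING
  $4 \times 1$, ING $0.9 \times 5$, CHING $1 \times 5$.)
* **GAMMA**: 1000 FS at $p = 60\%$, $Q_I = 5$ nS, $\tau_I = 5$ ms. An
  interneuron-only generator oscillating near 70 Hz under 400 trains/neuron
  at 5 Hz.
* **ING**: the AI core (20000 RS + 4000 FS) plus the GAMMA network embedded
  as a second interneuron population (FS2, identical FS parameters,
  different wiring: FS2$\leftrightarrow$RS 15%, FS2$\to$FS 15%,
  FS$\to$FS2 3%, FS2$\leftrightarrow$FS2 60%). Drive $Q_{Ext} = 0.9$ nS;
  gamma at 3 Hz ($\approx$ 55-65 Hz broad rhythm), AI-like at 2 Hz.
* **CHING**: the AI structure with 5% of RS replaced by Ch cells
  (19000 RS + 1000 Ch + 5000 FS), $Q_I = 7$ nS onto excitatory cells and
  5 nS onto FS; drive 1 nS (RS/Ch) and 0.75 nS (FS); gamma at 2 Hz
  ($\approx$ 35-40 Hz), AI-like at 1 Hz.

Initial conditions are $V \sim$ uniform$[E_L, V_T)$, $w = 0$, $g = 0$. The
slow adaptation current ($\tau_w = 500$ ms) equilibrates over roughly two
seconds; analyses therefore discard a default burn-in of 1000 ms (the
stimulation protocols, whose comparisons are paired, use 600 ms).

### Desk-scale runs

`scale_network()` shrinks populations while preserving every expected
in-degree exactly: probabilities are raised by the inverse source-size
ratio, and a source population is only shrunk until its largest outgoing
probability reaches 1 (FS2, at 60%, never goes below 600 cells). The
external drive ensemble is never scaled -- drive in-degree does not depend
on network size, and scaling the ensemble would inflate the shared-drive
correlation between neurons. Frequencies are stable within roughly 15% down
to factor 0.1; finite-size fluctuations grow as networks shrink, so the
package runs the headline frequency measurements at full size (25000
neurons, roughly half a minute per simulated 5 s on one CPU including wiring) and the repetition-heavy
protocols at factor 0.1.

## LFP synthesis

Each spike contributes a Gaussian pulse to the LFP whose amplitude decays
exponentially with the neuron-electrode distance and whose peak is delayed
by a constant plus axonal propagation:
$A_0 e^{-|x - x_p|/\lambda} \exp[-(t - t_{peak})^2/2\sigma^2]$,
$t_{peak} = t_0 + d + |x - x_p|/v_a$, summed over all spikes with separate
excitatory and inhibitory parameter sets. Because the simulated networks
have no intrinsic geometry, neurons are placed uniformly at random in a
square arena (side 0.4 mm by default, an arbitrary scale matched to typical
electrode spacing) with the electrode at the center.

The numeric kernel constants are configuration entries, not results: the
package ships synthetic defaults on the scale reported for measured unitary
LFPs (sub-microvolt amplitudes, $\lambda = 0.2$ mm, millisecond widths,
$d = 10.4$ ms, $v_a = 0.2$ mm/ms, inhibitory amplitude three times the
excitatory and of opposite sign). Everything downstream thresholds the LFP
envelope in SD units, so burst detection and the phase statistics are
insensitive to these values; tests assert the closed-form single-spike
pulse, exact superposition, and scale invariance of detection instead.

## Gamma-burst detection and spike phases

The LFP (1 kHz) is band-passed at 30-50 Hz with a Kaiser-window FIR filter
designed for 60 dB stop-band attenuation and a 5 Hz transition; the filter
is applied causally and the constant group delay is then removed so that
filtered samples, and hence phases, align with the spike clock (a causal
mode retains the raw delay for parity). The analytic signal supplies the
envelope and the instantaneous phase in $(-\pi, \pi]$; phase 0 is the
oscillation peak, and more negative phases are earlier in the cycle.

A gamma burst is a maximal interval where the envelope exceeds its segment
mean by $k$ SD ($k = 1$ for simulated signals, 2 for recordings) for at
least 3 cycles of the band's center frequency (75 ms for 30-50 Hz). Burst
edges are the threshold crossings themselves -- the stricter reading -- with
an optional mode extending them down to the envelope mean. The 3-cycle rule
uses the band center because instantaneous cycle counting is not defined for
a noisy envelope. Spikes are assigned phases only inside bursts of their own
electrode.

### Phase-axis convention

`analytic_signal()` returns the standard analytic-signal argument: phase
advances with time, phase 0 at the oscillation peak, so *smaller* phase
means *earlier* in the cycle. Polar displays of preferred phases in this
field are traditionally read clockwise with time, which is the mirror of
this axis; when the package compares excitatory and inhibitory preferred
phases against published orderings (the inhibition-leads signature of
interneuron-driven rhythms) it evaluates the difference on that clockwise
axis. On the time axis itself, the locked regular-spiking cells in the ING
and CHING models fire fractionally (about 1 ms) before the fast-spiking
cells, and after them in PING — the same pattern, stated in the standard
convention. Spike-level cross-correlations between the population rates
confirm the sub-millisecond lead/lag independently of any LFP processing.

## Unit statistics

Phase-locking uses the Rayleigh test with the standard large-sample p
approximation $p = \exp[\sqrt{1 + 4n + 4(n^2 - nZ)} - (1 + 2n)]$,
$Z = n\bar R^2$, validated in the tests against Monte-Carlo nulls (within a
factor of two across $p \in [10^{-4}, 0.1]$). The Bonferroni family is the
set of neurons tested in the segment (the natural reading; configurable),
and a neuron is locked when $p < 0.01/n_{tested}$. Neurons with fewer than
5 spikes inside bursts, or whose electrode saw less than 1 s of gamma, are
*inconclusive*. Preferred phases come from a von Mises fit (maximum
likelihood: circular mean plus Bessel-ratio inversion of $\bar R$, capped at
$\kappa = 10^3$ for degenerate samples).

Firing-rate change compares the observed in-burst count with the Poisson law
implied by the outside rate: increase above the 95% quantile ("percent point
function") of Poisson($f_{out} T_\gamma$), decrease below the symmetric 5%
quantile (the lower tail is included because decreases are reported alongside
increases in the source analyses; only the increase rule is spelled out
there). Cells with $f_{out} < 0.1$ Hz or under 1 s of gamma are
inconclusive. Consistency analysis counts, per neuron across $K$ segments,
how often each label recurs; inconclusive segments form their own stratum
rather than counting as "never".

## Stimulation protocols

*Responsiveness* (integration mode): $R = (N^S - N)/(T N_n)$, the excess
spike count per neuron per second in a $T = 500$ ms window, for Gaussian
drive-rate stimuli (SD 50 ms). The design is exactly paired: baseline and
stimulated runs share wiring, initial conditions and the baseline drive
realization, and the stimulus is an independent superposed Poisson stream --
so at amplitude 0 the two runs are identical and $R \equiv 0$. Gamma states
are induced by a stereotyped drive fluctuation (100 ms linear ramp from the
AI-like to the gamma rate, plateau covering the window), with the stimulus
centered in the window.

*Phase-dependent responsiveness* (coincidence mode): a 1 ms-SD, 50 Hz
Gaussian stimulus at many times across a few gamma cycles; $R$ is measured
in a one-cycle window centered on the stimulus and binned by the phase read
from the paired baseline run's filtered LFP at the stimulus peak
(delay-compensated). Stimuli falling outside detected bursts are discarded
and counted. The control condition injects a sinusoidal current (0-0.1 nA at
the network's gamma frequency) into the AI-like state and reads the phase of
that current. All values are normalized by the mean AI-like response.

*Resonance*: drive rate $\mu \pm \Delta\sin(2\pi f t)$ over a frequency
grid; spikes of the target cell type are accumulated in 25 equal phase bins
of the drive sinusoid, averaged per neuron and time bin, and the map is
normalized to unit grand mean, removing state-dependent rate levels.

Supporting metrics: the synchrony index is the zero-lag value of a damped
cosine $A e^{-\lambda_d t}\cos(2\pi\nu t)$ fitted to the normalized
population-rate autocorrelation (lag 0 excluded: it carries the shot-noise
peak). "No oscillation" is declared when the fit fails, the decay rate
exceeds 100 s$^{-1}$ (the source threshold, read as s$^{-1}$; the unit is
not printed there), or the fitted amplitude is below 0.05 -- purely
stochastic rates fit $A \approx 0$ with an arbitrary decay, which must not
count as a rhythm. Membrane synchrony is
$\chi = \sqrt{\mathrm{Var}_t(\bar V)/\overline{\mathrm{Var}_t(V_i)}}$, and
balance is the time average of the ratio of population-mean synaptic
current magnitudes, $\langle |\langle I_{exc}\rangle_N| / |\langle
I_{inh}\rangle_N| \rangle_t$. Whether the external drive counts as part of
$I_{exc}$ is ambiguous in the source definition; the engine integrates the
drive conductance separately so both variants are available
(`include_drive` in `network_balance()`). The drive-inclusive ratio is the
default — the interneuron-only network has no other excitation — while the
recurrent-only ratio (about 0.3 in the AI state, versus about 1.6
drive-inclusive) is what expresses inhibition dominance of the recurrent
loop.

## Frequency estimation

The dominant network frequency is the argmax of the Welch-averaged power
spectrum of the population rate (1 ms bins; 1024-sample Hann segments, 50%
overlap, light 3-bin smoothing) within 20-100 Hz. The rhythms of these
fluctuation-driven networks are broadband -- the ING spectrum spans roughly
48-70 Hz -- so the raw periodogram argmax wanders by +/-10 Hz between
realizations; Welch averaging is the standard remedy and stabilizes the
peak to a few Hz. Headline numbers average the peak over two or three
independent simulations of 4-5 stationary seconds each.

## The synthetic fixture generator

`generate_fixture()` emulates the *structure* of a multielectrode unit
recording: $K$ segments, each with a known set of burst intervals (an
amplitude-modulated 40 Hz carrier in white noise), and neurons with planted
ground truth -- von Mises phase concentration inside bursts and separate
in/out-burst Poisson rates. It exists to calibrate the statistics chain:
with $\kappa = 0$ the locked fraction must respect the Bonferroni bound;
with equal in/out rates the false-increase rate must sit at the one-sided 5%
level; with strong concentration the planted phases must be recovered.

What it does *not* emulate: spike-sorting errors, electrode drift,
non-stationary burst amplitudes, 1/f LFP background, or correlations between
neurons beyond the shared burst times. Passing these calibrations therefore
demonstrates the correctness of the statistical machinery on its stated
assumptions, not performance on real recordings.

## Numerical choices and degenerate inputs

* Synaptic delays must be integer multiples of `dt`; anything else is a
  configuration error, never silently rounded. Delivery lands exactly one
  delay after the spike time on the step grid, matching the scheduling of
  the standard simulator for this model family.
* The exponential term is capped at $e^{30}$ to avoid overflow when a high
  `v_cut` lets the upstroke develop; the cap is unreachable under the
  default cutoffs.
* Non-finite membrane state aborts the simulation with the neuron id and
  time.
* `detect_bursts` on a segment shorter than 3 cycles returns an empty table;
  `rayleigh_test` requires at least one phase, `fit_von_mises` at least two;
  antipodal pairs give $\kappa = 0$, identical phases the $\kappa$ cap.
* Drive rates are clipped at 0 Hz when a fluctuation would go negative.
* Every random component (initialization, wiring, drive, stimulus, geometry)
  draws from a stream derived from the master seed by a labeled hash, so any
  stage can be reproduced in isolation and paired designs share exactly the
  streams they should.

## Problem sizes used by the shipped checks

The test suite and the acceptance script run: full-size (25000-neuron)
simulations of 5-6 s for the four oscillation-frequency checks, averaged
over 2-3 seeds; the AI control at factor 0.1 for 4 s; the responsiveness
ordering at factor 0.2 with 14 repetitions and three amplitudes per state;
the phase-relationship check at factor 0.1 over 2-3 minutes of slowly
modulated drive (1 Hz alternation between the AI-like and gamma rates,
which produces the long gamma bursts the 3-cycle rule requires, with burst
edges extended to the envelope mean and the filter band centered on the
measured network peak); and the statistical
calibrations on fixtures of 100 neurons with 13 s of gamma per 60 s
segment. These sizes are the package's desk-scale defaults; the full
protocol grids of the source analyses (100 repetitions, 50 amplitudes,
120 stimulus positions) are available through the same functions by passing
the corresponding arguments.

## Known limitations

* The kernel LFP parameters are synthetic defaults (see above); absolute LFP
  amplitudes are not meaningful, only SD-relative structure.
* Visual confirmation of detected bursts, used alongside the automatic
  criterion in the source analyses, has no algorithmic counterpart; the
  thresholds here are used as-is, which may admit bursts a human would
  reject.
* The PING architecture is close to a runaway instability (see the
  time-constant discussion); parameter changes that increase recurrent
  excitatory charge by tens of percent destabilize it.
* Connectivity is homogeneous Erdos-Renyi; no topography, distance-dependent
  delays, or plasticity.
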