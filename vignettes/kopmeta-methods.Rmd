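---
title: "Measuring TMS-induced changes in brain metastability: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring TMS-induced changes in brain metastability}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(kopmeta)
```

## The scientific problem

A single pulse of transcranial magnetic stimulation (TMS) phase-resets the
stimulated cortical region. From a dynamical-systems standpoint a forced
phase alignment pushes a high-dimensional, flexibly switching system into a
transiently low-dimensional coordinated state, which should register as a
drop in *metastability* — the tendency of the system to move in and out of
coordination states — followed by a recovery whose duration indexes how
long information processing is perturbed. `kopmeta` implements the full
measurement chain for this phenomenon on multichannel EEG, together with a
mechanistic "digital twin": a 90-node Kuramoto network on a structural
connectome with conduction delays, in which the TMS pulse is a phase reset
that propagates through the network.

## Measures

### Kuramoto order parameter and its windowed standard deviation

For channel (or oscillator) phases $\theta_j(t)$, the order parameter is

$$ r(t)\,e^{i\psi(t)} = \frac{1}{N}\sum_{j=1}^{N} e^{i\theta_j(t)}, $$

with $r = 1$ for full synchrony and $r \to 0$ for uniform desynchronization.
Channel phases come from a zero-phase band-pass (default bands: delta 1–4,
theta 4–8, alpha 8–12, beta 12–30, gamma 30–45 Hz) followed by the
analytic-signal angle. Metastability is operationalized as the standard
deviation of $r(t)$ in a sliding window (50 ms for EEG, 500 ms for the
slower twin dynamics). We use the *population* standard deviation
throughout (including GFP); the choice is a fixed convention, not a fitted
parameter. Windows are centered and dense (stride one sample); positions
without full support are `NaN`. Traces can be normalized to percent of a
baseline interval (default 525–1525 ms epoch time, i.e. the interval quoted
with the empirical figures; note it *follows* the pulse at 500 ms — it is a
post-recovery plateau. A pre-pulse baseline can be configured instead.)

Two ambiguities of the published procedure are resolved as follows: the
windowed standard deviation is computed per epoch and then averaged (not
std-of-average), and averaging ignores `NaN` window margins while recording
per-point counts.

### Filtering

No FIR-design library is assumed, and a classical windowed-sinc band-pass
with a transition width of 25 % of the band edge is *infeasible* on 2 s
epochs at low bands (a 1 Hz edge would need more taps than the epoch has
samples). The band-pass is therefore applied in the frequency domain:
unit gain in the band, raised-cosine transitions of 25 % of each edge,
mirror padding by half the epoch. This is zero-phase by construction and
equivalent to a symmetric kernel as long as the epoch. A transient margin
of one cycle of the low band edge (capped at a third of the epoch) is
flagged on the phase tensor.

### Channel grouping from the evoked potential

The TMS-evoked potential is grand-averaged, the sample of maximal global
field power (GFP, the spatial population std) is located inside a
post-pulse search window (default 10–300 ms, so the pulse-sample
discontinuity itself can never be selected), each channel's deviation from
the instantaneous grand mean is computed there, and the top and bottom
$\lfloor n/3 \rfloor$ channels form the two groups. Ties in the deviations
resolve by channel order; tied GFP maxima take the earliest sample. The
"mean of all channels" includes the channel under evaluation (plain grand
mean). Because a TMS-evoked topography is dipolar, the two groups straddle
the stimulated site — channels of a *single* group share polarity, which is
what makes their phase-locking visible to the order parameter (a
mixed-polarity set cancels).

### Microstates and Lempel–Ziv complexity

Microstates are fit per subject on alpha-filtered resting data: maps at
GFP peaks (strict local maxima, plateau-first), clustered by TAAHC —
starting from singletons, the cluster with the lowest Correlation Sum
(sum of members' absolute spatial correlation with the cluster template)
is dissolved and its members reassigned to the best remaining cluster;
templates are the first principal axis of the member maps. Correlation is
polarity-invariant (absolute value), the standard convention. The number
of states is chosen by the Krzanowski–Lai criterion applied to the
dispersion $D_k = n_\text{maps} - \text{CS}_k$, with
$\mathrm{DIFF}(k) = (k-1)^{2/p} D_{k-1} - k^{2/p} D_k$ and
$k^* = \arg\max |\mathrm{DIFF}(k)/\mathrm{DIFF}(k+1)|$ over interior $k$
in a preset range [2, 10] (reported optima fall between 4 and 8). A flat
index warns and returns the earliest maximum.

Backfitting labels every sample with the template of highest absolute
correlation; global explained variance is
$\mathrm{GEV} = \sum_t (\mathrm{GFP}_t\, c_t)^2 / \sum_t \mathrm{GFP}_t^2$.
Zero-variance samples take label 1 by convention and are excluded from the
GEV. Complexity of the label sequence uses LZ76 exhaustive-history
parsing (phrase count, copy-extension allowed), computed in 100 ms
windows. Whether those windows slide or tile is ambiguous in the source
material (both "sliding window" and "bins" appear); both modes are
provided and tiling is the default for bin-style output. Transition
matrices count label *changes* (self-transitions excluded), row-normalized;
rows without exits are zeroed and flagged.

### Pre/post statistics

Per subject, the epoch-averaged trace is averaged in 250 ms windows
immediately before and after the pulse. Differences are tested with a
one-tailed Wilcoxon signed-rank test: zero differences dropped (Wilcoxon's
original treatment), ties midranked, exact null distribution by the shift
algorithm over doubled midranks for $n \le 25$, normal approximation with
tie-corrected variance and continuity correction above. The Shapiro–Wilk
test is computed only as an annotation — the pipeline always proceeds
non-parametrically. Raw p-values are reported per cell (as in the
empirical effect tables) with a Holm-corrected column alongside. The
"increase before the pulse" effect needs a comparator the source text
never defines; we use the earliest 250 ms of the trace's support, and
document this as a package choice.

## The digital twin

The network is
$\dot\theta_i = \omega_i + \frac{K}{N}\sum_j c_{ij}
 \sin(\theta_j(t-\tau_{ij}) - \theta_i) + d\,\zeta(t)$,
integrated by Euler–Maruyama at `dt` = 0.1–0.2 ms with delays rounded to
integer steps and a ring-buffer history backfilled at the intrinsic
frequencies. The noise term's discretization is genuinely ambiguous in
the source description, and the two readings give qualitatively different
dynamics, so both are implemented (`noise_model`). The default,
`"diffusion"`, is Euler–Maruyama: $\sqrt{dt}\, d\, \zeta$ with $d = 3$ per
square-root second — phase diffusion then limits coherence lifetimes to a
few hundred ms, matching the sub-second post-pulse recovery the empirical
results report. The alternative `"drift"` reading integrates the noise
inside the derivative ($dt\, d\, \zeta$, $d$ in rad/s) — numerically
near-deterministic; post-reset locked states then persist for seconds.
Frequencies are assigned from anatomical node strength (hubs slowest):
$f_i = f_\text{max} - \Delta f (s_i - s_\text{min})/(s_\text{max} -
s_\text{min})$ with $\Delta f = 3$ Hz, so sweeping
$f_\text{max} \in \{5, 15, 25, 35\}$ Hz translates the distribution
without changing its dispersion. The exact strength-to-frequency rule in
the cited literature is not reproduced in the source; the linear hub-slow
map is a documented choice.

$K$ and the conduction velocity are chosen by grid search for maximal
metastability (time-averaged 500 ms windowed std of the network KOP). On
the default synthetic connectome (90 nodes in a 70 mm sphere, weights
$e^{-d/30\,\text{mm}}$) the argmax is $K = 0.15$, $v = 7$ m/s, giving mean
$r \approx 0.3$ with large slow fluctuations; these are the package
defaults.

The pulse is delivered at a low-coherence state (local minima of the 25 ms
smoothed KOP after a 2000 ms burn-in, prominence at least half the trace
std). Nodes within 20 mm of the site (a geometric stand-in for the
simulated electric-field region, which is out of scope) reset to $\pi/2$
instantly; every other node resets at the pulse time plus its conduction
delay to the site. Because the noise stream depends only on the seed, the
perturbed run is identical to the unperturbed one up to the pulse. A
subgroup of oscillators within 1 Hz of the site's intrinsic frequency is
the readout, mirroring the empirical channel groups.

### The pulse discontinuity and what "post-pulse metastability" means

The reset makes the subgroup KOP jump from a low-coherence value to near 1
within the reset-propagation time (about 20 ms). Any std window containing
that jump, or the subsequent relaxation ramp, is dominated by it: in the
first 250 ms after the pulse the windowed std is *elevated* in this model
under every window alignment we examined, for exactly the reason the
original figures "removed the discontinuity at the pulse". The genuine
metastability *reduction* — the flat, locked coordination state — appears
once the window clears the jump, roughly 250–1000 ms post-pulse, and then
recovers; the seed-averaged traces produced by `run_experiment()` show
this dip (`dip_ms`, `dip_depth`), and recovery is measured as the first
return into a $\pm 1$ SD band of the pre-pulse baseline *after* the
post-pulse trace minimum (band width: the mean single-run baseline SD,
which unlike the SD of the seed average does not shrink with the seed
count). We deliberately keep the package's pre/post comparison windows
adjacent to the pulse (matching the empirical procedure) rather than
moving them to where the model looks best; the consequence — that the
immediate-window comparison shows the ramp, not the dip — is reported
honestly by the tests rather than hidden by a shifted window.

At desk scale (10 seeds) the *timing* of the dip and recovery on the
seed-averaged trace carries hundreds of ms of uncertainty, and the strict
frequency ordering of recovery times is not resolvable — across base
seeds the ordering fluctuates and can even reverse. The
frequency-dependent decoherence itself is robust in the subgroup KOP:
the decay of the post-reset coherence elevation is consistently faster at
higher maximum frequencies. Tests assert the ordering on the
metastability trace as specified and report the outcome as is.

## The synthetic cohort: what it emulates and what it does not

`generate_resting_eeg()` / `generate_tms_epochs()` produce cohorts
(default 20 subjects × 60 epochs × 32 channels, 2 s epochs at 1 kHz, pulse
at 500 ms — the shape of a single-pulse TMS-EEG study at reduced trial
count) from a small Kuramoto source network (8 sources, 8–12 Hz, all-to-all
coupling 0.015 rad/ms, noise scale 3 per √s) run at a working point chosen
once for clear metastable switching (mean source KOP ≈ 0.5, strongly
fluctuating). Each source projects to the sensors through a localized
dipolar topography; four planted states alternately boost one source
(Markov dwell ≈ 100 ms), creating microstate-like quasi-stable maps. A
500 ms burn-in guarantees stationarity inside the epoch, so a
`reset_strength = 0` "TMS" cohort is distribution-identical to resting — a
clean null for type-I checks. Epochs are statistically independent
(independent source runs), unlike consecutive real epochs.

The pulse effect plants: a phase reset of the local source cluster to a
common value, a coherence hold decaying with `recovery_tau_ms` (100 ms), a
transient amplitude dominance of the coherent cluster with the same time
constant, and a biphasic evoked deflection (difference of Gaussians, peak
30 ms post-pulse, default 15 µV — a realistic TEP amplitude against the
10 µV RMS background). Evoked amplitude and cluster dominance scale with
`reset_strength`, making stimulation intensity a single knob and the null
exact. The generator does not model volume-conduction lead fields, TMS
coil artifacts, line noise, or inter-epoch dependence; preprocessing is
assumed done. A green end-to-end test therefore establishes that the
pipeline recovers planted effects of realistic size and direction — not
that it would survive raw-data artifacts.

## Numerical choices

* EDF export quantizes to 16 bits with per-channel physical scaling
  written at 6 significant digits (header fields are 8 ASCII characters);
  round-trips are exact to half a quantization step.
* The internal canonical container is HDF5 (lossless round-trip);
  BrainVision/EDF are import/export paths. Event markers do not survive
  plain EDF.
* Exact Wilcoxon null distributions use doubled midranks so tied ranks
  stay integral; p-values at n > 25 switch to the tie-corrected normal
  approximation.
* TAAHC cost is bounded by capping the clustered GFP-peak maps
  (`max_maps`, default 1000, evenly subsampled).
* All stochastic stages consume R's RNG only, so a single `set.seed`
  (or the `--seed` CLI flag, logged in every JSON sidecar) makes runs
  bit-reproducible; the integrator draws its normals from the same stream.

## Known limitations

* The twin's immediate-post-window metastability comparison is dominated
  by the reset ramp (see above); the model reproduces the dip-and-recovery
  phenomenology, not a literal sub-250 ms reduction.
* The Krzanowski–Lai criterion needs at least 4 consecutive k values and
  can be flat on structureless data; it warns rather than guessing
  silently.
* The frequency-domain filter assumes the epoch is long relative to the
  band's lowest period; delta-band phases on 2 s epochs carry a large
  flagged margin.
* EDF support targets the package's own round-trip (one data record,
  16-bit); it is not a general-purpose EDF+ reader.
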