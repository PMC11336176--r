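---
title: "Hyperbrain network analysis: models, estimators, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Hyperbrain network analysis: models, estimators, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hyperbrain)
```

## The analysis in one paragraph

Two people tap in alternation while each wears a 29-channel EEG cap. From
the two synchronized recordings, the pipeline estimates how strongly
channels synchronize *within* each brain (weighted phase lag index, wPLI)
and *between* the brains (phase locking value, PLV) in the theta (4–7 Hz),
alpha (8–12 Hz), and beta (13–30 Hz) bands. Every channel pair is then
tested against spectrum-preserving phase-randomization surrogates; pairs
whose synchrony exceeds their surrogate null become edges of a binary
58-node "hyperbrain" graph (29 nodes per participant). Graph topology —
edge number, global efficiency, local efficiency, and the modularity of
the fixed two-brain partition — summarizes how densely and how efficiently
the two brains are wired together. Tapping itself is summarized by the
dyadic mean inter-tap interval and the circular spread of the relative
phase between partners.

## Estimators

**Relative phase and SDRP.** For each interval of participant 1, the first
participant-2 tap inside it is matched and scored as
`RP = (t_p2 - t_p1) / interval * 360` degrees; 180° is perfect
anti-phase. With the unit phasors of all RP values averaged to resultant
length `R`, the circular standard deviation `SDRP = sqrt(-2 log R)`
measures coordination instability; `R = 1` gives `SDRP = 0`, and an exactly
antipodal RP distribution (`R = 0`) is reported as an infinite SDRP with a
degeneracy flag. The matching rule (first onset in the half-open interval,
extra onsets logged but unused, empty intervals skipped and counted) is a
package decision; the source analysis did not specify one. It reproduces
the ideal alternating structure exactly and degrades gracefully.

**wPLI.** With per-sample cross-spectra `C_t = x_t * Conj(y_t)` of the two
Hilbert analytic signals,
`wPLI = |sum |Im C_t| sgn(Im C_t)| / sum |Im C_t|`. Weighting by
`|Im C_t|` makes the index insensitive to zero-lag synchrony, the
signature of volume conduction, which is why it is used *within* a scalp.
When every `Im C_t` is zero (identical or exactly anti-phase signals) the
estimator is 0/0; the package returns 0 with a `degenerate` attribute,
consistent with the estimator's purpose of discounting zero-lag coupling.
The cross-spectrum is computed per sample from the analytic signals over
the whole trimmed recording — no Welch segmentation — matching the
Hilbert-based phase definition used throughout.

**PLV.** `PLV = |mean exp(i(phi - psi))|` over the trimmed samples. It is
invariant to a constant phase offset, which matters twice below: it makes
PLV blind to a pure relabeling of phase zero, and it is the reason
Fourier surrogates cannot lower the PLV of an exactly monochromatic pair.

## Preprocessing and numerical choices

* **Filtering** is forward–backward (two-pass) Butterworth, order 4 per
  pass for band selection and order 8 for the anti-alias low-pass before
  integer decimation. Two-pass filtering has exactly zero phase in the
  passband, so no spurious lag is introduced between channels — a
  precondition for every phase metric downstream. Filter family and order
  are analysis parameters the source analysis did not report; they are
  configuration defaults here, not hard-coded.
* **Edge trimming**: `max(1 s, 3 / low_edge)` seconds at each end
  (`hilbert_phase(trim_seconds =)`) are excluded from every synchrony sum,
  covering both filter transients and the Hilbert transform's edge bias.
  The same trim is applied to original and surrogate data.
* **Bad channels** are interpolated from the three nearest good channels,
  weighted by inverse great-circle distance on the unit sphere of the
  standard 10/20 template montage (shipped as a CSV). The local
  neighborhood keeps gradient fields from being shrunk toward the scalp
  mean; on smooth simulated fields this estimator beats a
  nearest-neighbor copy at every montage site probed. The weighting
  function is one isolated routine so a spherical-spline scheme can be
  swapped in. Independent-component artifact removal is deliberately
  **not** part of the pipeline: it requires manual component selection,
  so the pipeline takes already-clean (or synthetic) data and a
  bad-channel list as input.
* **Hilbert phases** come from the standard FFT analytic-signal
  construction. Broadband input is refused (`band_tag` must name a band):
  an instantaneous phase is only meaningful for narrow-band signals.

## The surrogate test and its calibration

Each channel is independently phase-randomized in the frequency domain:
the phase values of the positive-frequency bins are randomly permuted
while every bin keeps its amplitude, conjugate symmetry is enforced, and
the series is inverse-transformed. Per-bin power is conserved to floating
point; all phase relations, within and between brains, are destroyed.
With `n` surrogates per channel (default 100), each pair's original
synchrony is compared against its surrogate distribution by a one-sample
t-test, one-sided (surrogate mean below the original), Bonferroni-corrected
over all tested pairs — `alpha / 1653` for two 29-channel participants,
recomputed from the actual montage. Edges require both significance and
an original value above the surrogate mean.

Two properties of this procedure deserve loud documentation:

1. **The t-test is anti-conservative under the null.** The original value
   is statistically exchangeable with a single surrogate draw, yet the
   t-test compares it against the *standard error of the surrogate mean*,
   which is `sqrt(n)` times smaller than the surrogate spread. Under zero
   coupling the effective criterion is roughly
   `z > z_crit / sqrt(n + 1)`, so even extreme Bonferroni levels admit a
   substantial false-edge fraction (measured here: ~0.1–0.2 on
   zero-coupling synthetic dyads with 50 surrogates). The procedure is
   implemented as specified because it is the study's procedure; the
   package also exposes `significance_mask(method = "percentile")`, an
   exact rank test that is properly calibrated — but which, with 100
   surrogates, can never reject below `1/101` and therefore cannot pass a
   `0.05/1653` Bonferroni bar at all. That tension (extrapolate the tail
   and lose calibration, or stay exact and lose all power under heavy
   correction) is inherent to surrogate-count-limited thresholding, and
   readers comparing groups should rely on the *contrast* of edge counts
   between conditions, not on their absolute level.
2. **Fourier surrogates cannot break the locking of a pure tone.** Phase
   randomization of a monochromatic signal only shifts its constant
   phase, to which PLV is invariant. Destruction of coupling requires the
   shared fluctuations to occupy many frequency bins, which real (and
   simulated, via phase diffusion) EEG satisfies.

## Graph metrics

All metrics operate on the binary, undirected, zero-diagonal 58-node
adjacency. Edge number counts unordered connected pairs once (the
double-sum formulation double-counts; reported edge counts in the
hundreds out of a 1653 maximum confirm single counting). Global
efficiency is the mean inverse shortest-path length over ordered pairs
with `1/Inf = 0`; the "inverse adjacency" reading of its printed formula
contradicts the accompanying prose and the standard definition, and the
prose wins. Local efficiency averages, over all nodes, the efficiency of
each node's neighborhood subgraph normalized by `d(d-1)`, with
degree-<2 nodes contributing 0. Modularity is Newman's Q evaluated at the
fixed two-brain partition — no community detection. Characteristic path
length averages over reachable ordered pairs and reports the unreachable
fraction alongside; efficiencies treat unreachable pairs as zero
contribution. Metrics are computed on the full 58-node graph including
isolates, which depress both efficiencies — intentional, since one
combined network per dyad is the unit of analysis.

One property worth knowing: global efficiency is monotone non-decreasing
under edge addition (and is property-tested as such), but local
efficiency is **not** — attaching a leaf to a node whose neighborhood was
complete dilutes that neighborhood's efficiency (triangle `u,a,b` plus
isolate `c`: adding `u–c` lowers LE from 3/4 to 7/12). Shortest paths use
igraph's unweighted BFS; an independent Floyd–Warshall oracle verifies
every metric to 1e-12 in the test suite.

## The synthetic-data generator

The generator exists so that every stage has ground truth. Each channel
is a Kuramoto phase oscillator: natural frequency drawn uniformly inside
the carrier band (with a 10%-of-bandwidth interior margin so the
diffusion-broadened line sits inside the band), Euler-integrated sine
coupling to its own participant's mean field (`k_intra_*`) and to the
partner's (`k_inter`), white frequency jitter (`phase_diffusion`, default
0.5 rad/sqrt(s)), observed as `cos(phase)` plus 1/f-shaped noise
(`noise_sd`, default 0.5). The first second is discarded as burn-in. One
root seed spawns per-channel substreams, so enlarging the montage leaves
existing channels' draws untouched; equal configurations are
bit-identical. Tap sequences follow the task design: participant 1 at the
requested interval (0.5 s slow / 0.25 s fast) plus Gaussian jitter
(default 0.02 s, a typical human motor-timing spread at these tempi),
participant 2 at a fixed fraction (default 0.5, anti-phase) of each
interval, 150 taps per participant.

Defaults the source does not pin down are the package's own: coupling
strengths are in rad/s and should be read against the band's frequency
dispersion (~25 rad/s for alpha) — `k_inter` around 10 gives partial
locking, 50 and above near-complete locking; `phase_diffusion = 0.5`
keeps >95% of noiseless signal power inside the carrier band (heavier
diffusion leaks power through Lorentzian tails) while still decorrelating
uncoupled channels over tens of seconds.

What the generator does **not** emulate: volume conduction and a forward
head model (channels are spatially exchangeable within a participant),
non-stationary artifacts (blinks, muscle), heterogeneous per-channel
spectra, and any behavioral-neural coupling between the tap generator and
the oscillators. Passing tests therefore demonstrate correctness of the
estimators and the pipeline's logic under a controlled generative model —
not that real recordings satisfy that model.

## Problem sizes used in the shipped tests

Unit tests run on 2–6 channels per participant and 4–20 s of signal at
125–500 Hz. The acceptance suite uses the full 29+29-channel montage for
pair bookkeeping (short recordings), 100 random 10–20-node graphs against
the brute-force oracles, 20 zero-coupling dyads of 6+6 channels with 50
surrogates for the calibration measurement, and 20 seeded replicates of a
high- versus zero-coupling dyad (6+6 channels, 30 surrogates) for
end-to-end effect recovery. These sizes were chosen as the smallest at
which the tested properties are decidable with comfortable margins.

## Known limitations

* Whole-trimmed-session synchrony only; no sliding-window or
  per-segment-then-average variant, which the source leaves ambiguous.
* The dyad-level mean ITI is defined on the merged tap stream (both
  participants interleaved); per-participant means are also exposed since
  the defining text is ambiguous about the stream.
* No debiased wPLI-squared estimator, no FDR or cluster-based
  alternatives to Bonferroni, no circular time-shift surrogates.
* EDF input is not supported; recordings travel as plain TSV matrices
  (samples x channels, header of labels) plus a sampling rate.
* Group-level mixed-effects modeling is out of scope; the tidy results
  table is exported for external modeling tools. Welch, paired-t with
  Holm, and Bonferroni helpers are included because the post-hoc
  contrasts depend on them.
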