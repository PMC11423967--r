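---
title: "Measuring multimodal synchrony in dyadic conversation with dyadsync"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring multimodal synchrony in dyadic conversation with dyadsync}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dyadsync)
```

## The problem

Two people in face-to-face conversation coordinate continuously: head and
hand gestures entrain to the speaker's own voice (intrapersonal synchrony)
and to the partner's voice and movements (interpersonal synchrony), and
this coordination lives simultaneously on many timescales — the ~0.2 s
syllable scale, the 0.5–2 s gesture scale, and the tens-of-seconds turn
scale. `dyadsync` implements a complete pipeline for quantifying this
multiscale coupling from motion-capture and audio recordings of dyads:

1. **Signal extraction** — head speed, summed left+right wrist speed and
   the speech amplitude envelope per participant, on a common 90 Hz clock.
2. **Turn-taking segmentation** — speech units, pauses, gaps, turns,
   overlaps and turn switches from speaking-time annotation tiers.
3. **Cross-wavelet synchrony** — Morlet wavelet coherence (degree of
   synchronization, 0–1) and relative phase (pattern of synchronization,
   in degrees) between every pair of signals, aggregated over 23
   conversational timescale bands from 0.125 s to 30 s.
4. **Surrogate null models** — pseudo-dyads (between-session reshuffling)
   for interpersonal pairs and 200 ms segment shuffling for intrapersonal
   pairs, with per-band permutation tests and Bonferroni correction.
5. **A synthetic dyad generator** with exact ground truth, so that every
   stage is testable without any external dataset.

## Signal model and preprocessing

Motion arrives as BVH files; `read_bvh()` parses the skeleton and
`world_positions()` runs forward kinematics (translations composed with
per-joint Euler rotations applied in the CHANNELS order, right-handed,
degrees — the de-facto BVH convention; the source format does not state
one). Marker selection is by configurable case-insensitive substring
(`"Head"`, `"LeftHand"`, `"RightHand"` by default) because marker naming
is dataset-specific.

Positions are lowpassed with a **second-order Butterworth** filter before
differentiation. Two choices here are deliberate:

* **Cutoff 10 Hz** (configurable). Gross head and hand movement energy in
  conversation lies well below 10 Hz; the cutoff mainly suppresses marker
  jitter before differentiation amplifies it.
* **Zero-phase (forward–backward) application.** Relative phase is the
  scientific target of the package; a causal filter would inject a
  frequency-dependent lag into every derived phase estimate.

Speed is the Euclidean norm of the central-difference derivative of the
filtered 3-D position — a non-negative magnitude, which is the only
reading under which "summing the left and right wrist velocities" is
meaningful. The voice signal is the **amplitude envelope**: magnitude of
the Hilbert analytic signal, smoothed at 12 Hz (keeps the ~5 Hz syllabic
modulation, removes the carrier) and resampled to the common 90 Hz clock.

## Turn-taking segmentation

The segmentation follows the standard inter-pausal-unit logic with a
200 ms threshold:

* same-speaker annotation intervals separated by silence **shorter than
  200 ms** merge into one *speech unit*;
* remaining silences (≥ 200 ms) are *pauses* (same flanking speaker) or
  *gaps* (different speakers);
* a *turn* accretes one speaker's units across pauses and ends at the
  first unit onset by the other speaker — including a short contained
  backchannel, since backchannels and interruptions are deliberately not
  distinguished;
* *overlaps* are all pairwise intersections of the two speakers' units;
  *turn switches* are the union of overlap onsets and speaker-change turn
  onsets (a time that is both counts once, as an overlap onset).

Boundary conventions that the definitions leave open are fixed as
follows: a silence of exactly 200 ms separates (does not merge); a 1 ns
guard band absorbs binary floating-point artefacts at that threshold
(0.2 s differences computed from decimal annotation times can fall an ulp
short); simultaneous onsets are broken by speaker label order and
flagged. `turn_statistics()` reports the turn-duration histogram over
(0,10], (10,20], (20,30], >30 s, and the share of switches that are
overlap onsets; with zero turns the proportions are `NA`, never 0.

## Wavelet coherence and relative phase

The Morlet continuous wavelet transform uses center frequency
$\omega_0 = 6$ (the field-standard choice; Fourier period
$\approx 1.033\,s$ per unit scale), 16 voices per octave over periods
0.125–32 s (at least two scale bins inside the narrowest band,
0.25–0.375 s), mean removal and zero-padding to a power of two. The cone
of influence (COI) is the e-folding time $\sqrt{2}\,s$ of the wavelet.

For signals $x, y$ with transforms $W^x, W^y$, coherence is

$$ R^2(t,s) = \frac{|S(W^{xy}/s)|^2}{S(|W^x|^2/s)\; S(|W^y|^2/s)},
   \qquad W^{xy} = W^x \overline{W^y}, $$

with $S$ a smoothing operator: a Gaussian in time whose standard
deviation equals the scale, then a boxcar across 0.6 decades of
log-scale. Without smoothing, wavelet coherence is identically 1 and
carries no information; the kernel widths are exposed as configuration
because the literature's toolboxes differ in this choice, and per-band
*differences* between experimental and surrogate conditions (the
inferential target) are robust to it. Relative phase is the argument of
the smoothed cross spectrum, wrapped to $[-180°, 180°)$, with the sign
convention **positive = the first-named series leads**.

Band aggregation pools all (time, scale) bins whose wavelet period falls
in the half-open band $(lo, hi]$ and which lie outside the COI (edge
artefacts otherwise inflate long-period coherence; the exclusion is
switchable via `use_coi`). Coherence is averaged arithmetically; phase by
the circular mean (resultant-vector method), pooling bins across time and
scale within the band. Bands with no valid bins are reported missing, not
zero.

Circular histograms use 20 bins of 18° **centered on multiples of 18°**
(0°, ±18°, ±36°, …). Peaks of phase distributions are conventionally
reported on this lattice (e.g. 342° ≡ −18°); centering the bins on it is
the only convention under which such peaks are representable, and ties
are broken toward 0° and flagged.

## Surrogate null models and inference

* **Interpersonal (pseudo-dyads).** Participant 1 of each take is paired
  with participant 2 of every other take from a different real dyad — all
  ordered pairings; the longer series is truncated to the shorter (both
  series taken from their start). The count is $n(n-1)$ for $n$ takes
  from distinct dyads.
* **Intrapersonal (segment shuffling).** The second-named series of the
  pair is cut into 0.2 s segments which are permuted uniformly (seeded);
  the final shorter remainder is kept and shuffled with the rest
  (droppable via a flag). Shuffling one member of the pair, not both,
  preserves the subject's own structure while destroying the pairwise
  alignment; 200 surrogates per pair per dyad stabilize the null mean.

Surrogate summaries are averaged at the dyad level (coherence
arithmetically, phase circularly; pseudo-dyad pairings are assigned to
the dyad contributing participant 1). Per band, the dyad-level paired
difference (experimental − surrogate) is tested with a **two-sided
sign-flip permutation test** — exact enumeration up to 12 dyads, seeded
resamples beyond — and Bonferroni-corrected across the 23 bands
($p_{adj} = \min(1, 23\,p_{raw})$). This replaces the repeated-measures
ANOVA machinery sometimes used for the same contrast: the scientific
claim (experimental synchrony exceeds chance per band) is identical, the
permutation test is exact at small dyad counts, and it needs no
sphericity adjustments. Phase is contrasted analogously on wrapped
circular differences of the dyad-level circular means. Voice×voice phase
is computed but not interpreted: with identical modalities the sign only
encodes which participant leads, which is arbitrary across dyads.

## The synthetic dyad generator

`generate_session()` produces a complete session with known ground truth:

* **Turn structure.** Alternating speakers; turn durations lognormal
  with `meanlog = 1.75`, `sdlog = 0.9`, chosen analytically so that
  ~72% of turns are ≤ 10 s, ~22% in 10–20 s and ~5% in 20–30 s — the
  canonical unstructured-conversation profile. Switches are overlaps
  with probability 0.7 (the reported share of overlap-attributed
  switches), otherwise gaps; occasional contained backchannels
  (probability 0.05 per turn) exercise the turn-splitting convention.
  Intra-turn pauses and gaps are kept ≥ 0.25 s, safely above the merge
  threshold, and emitted annotation intervals are randomly split by
  sub-200 ms silences so the merging rule is exercised. All times are
  rounded to 1 ms. The generator derives the expected conversational
  structure from its own unit list by a definition-based sweep that
  shares no code with the analysis implementation.
* **Envelopes.** Raised-cosine syllable bumps of 0.2 s (the stable
  cross-language syllable scale) at ~4 Hz with jittered amplitudes inside
  speech, a small positive noise floor outside. Energy inside annotated
  speech exceeds outside by far more than the 5× the tests require.
* **Movements.** Non-negative speed series = baseline 1.0 + 0.25 × a
  zero-mean fluctuation; the fluctuation mixes 1/f background noise
  (0.05–10 Hz — realistic low-frequency content, unlike white noise)
  with band-limited components phase-locked to a configured driver.
  Coupling strength $c \in [0,1]$ enters as
  $\sqrt{1-c^2}\,\text{noise} + c\,\text{component}$, and the phase lag
  is imposed exactly by rotating the analytic signal of the band-passed
  driver — so configured lags are exact ground truth for phase-recovery
  tests. Values are clipped at zero; the baseline keeps clipping rare.

What the generator does **not** emulate: articulated full-body
kinematics, real speech acoustics, annotation errors, and any
dataset-specific marker naming. A green parameter-recovery test therefore
establishes that the analysis chain is correct and calibrated on data
with the stated statistical structure — not that any particular empirical
dataset shows these effects.

## Numerical choices and scaled-down test design

* Wavelet kernels are memoized per (padded length, rate, scale grid);
  all surrogate loops reuse each series' transform and smoothed
  auto-spectrum.
* The type-I calibration of the per-band permutation test runs 500
  replicates of a deliberately scaled-down world: 8 zero-coupling dyads
  of 24 s, three of the printed bands (0.5–1, 1–2, 2–3 s), a 0.5–3 s
  grid at 5 voices/octave, and a pseudo-dyad null subsampled to 3
  partners per dyad. Eight dyads is a deliberate choice: the exact
  two-sided sign-flip test has attainable levels $k/256$, and rejection
  at $\alpha = 0.05$ occurs with probability $12/256 \approx 0.047$
  under the null — inside the 0.05 ± 0.02 acceptance window — whereas 6
  or 7 dyads would make the test unavoidably conservative
  (0.031 / 0.016).
* Phase-lag recovery is verified at module level over 5 seeds per lag
  (8 lags across the circle) and end-to-end over 3 full synthetic dyads
  per lag; both check the ±5° target on the circular-mean error.
* Degenerate inputs: all-zero signals yield missing (`NA`) coherence
  maps, not zeros; bands without grid support are missing; circular
  means with resultant length < 1e-12 are flagged undefined.

## Known limitations

* Coherence magnitudes depend on the smoothing kernel; absolute values
  are comparable only within one configuration (condition contrasts are
  the supported inference).
* The BVH reader covers the mainstream dialect (no scale/endsite
  channels); ELAN EAF annotation files are out of scope — tiers are
  plain TSV.
* Segment shuffling whitens the shuffled series above the segment scale;
  its null coherence matches the independent-noise floor closely but not
  exactly at periods near the segment length.
* With fewer than 6 dyads the sign-flip test cannot reach $p < 0.05$;
  such comparisons are flagged `underpowered`.
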