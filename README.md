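# dyadsync

Multimodal synchrony analysis for dyadic conversation.

When two people talk face to face, their co-speech gestures and voices
coordinate — within each speaker (head and wrist movements entrain to the
speaker's own speech envelope) and between speakers (movements and voices
entrain across the dyad), on timescales from the ~0.2 s syllable up to the
tens-of-seconds turn cycle. `dyadsync` is an R package for researchers in
movement science, psycholinguistics and social interaction who want to
quantify that coordination from motion-capture (BVH), audio (WAV) and
speaking-time annotations:

* **Signal extraction** — zero-phase Butterworth filtering, marker speeds
  (head, summed left+right wrist), Hilbert amplitude envelopes, all on a
  common 90 Hz clock (`build_dyad_recording()`).
* **Turn-taking segmentation** — speech units (merging silences < 200 ms),
  pauses vs gaps, turns, overlaps, turn switches and their summary
  statistics (`conversation_structure()`, `turn_statistics()`).
* **Cross-wavelet synchrony** — Morlet wavelet coherence
  `R²(t,s) = |S(WᵃᵇF/s)|² / (S(|Wᵃ|²/s)·S(|Wᵇ|²/s))` and relative phase
  (positive = first-named series leads), band-averaged over the 23
  conversational timescale bands spanning 0.125–30 s
  (`cwt_morlet()`, `xwt_maps()`, `band_average()`, `default_bands()`).
* **Surrogate inference** — pseudo-dyad reshuffling across sessions
  (interpersonal null) and seeded 200 ms segment shuffling (intrapersonal
  null), with per-band sign-flip permutation tests and Bonferroni
  correction (`plan_pseudo_dyads()`, `segment_shuffle()`,
  `compare_conditions()`, `run_analysis()`).
* **A synthetic dyad generator** with exact ground truth — turn-structured
  envelopes and movement series with configurable per-band coupling
  strength and phase lag (`dyad_sim_config()`, `generate_session()`).

## Worked example

Generate six synthetic dyads in which participant A's head movements are
driven by participant B's voice in the 4–8 s band (coupling 0.9, phase lag
−18°, i.e. the voice leading the head), then test experimental coherence
against the pseudo-dyad null:

```r
library(dyadsync)

coupling <- data.frame(target = "A.head", driver = "B.voice",
                       lo_s = 4, hi_s = 8, strength = 0.9, phase_deg = -18)
sessions <- lapply(1:6, function(k)
  dyad_sim_config(duration = 180, seed = k, couplings = coupling))

cfg <- analysis_config(sessions,
                       bands = timescale_bands(c(2, 4, 8), c(4, 8, 16)),
                       min_period = 2, max_period = 16,
                       voices_per_octave = 8, n_shuffle = 20, seed = 42,
                       roster = default_pair_roster()[8, ])  # inter head x voice
res <- run_analysis(cfg)
res$comparisons[["inter.head_voice"]][
  , c("band_lo_s", "band_hi_s", "exp_mean_coherence",
      "sur_mean_coherence", "p_adjusted", "significant",
      "phase_diff_deg")]
```

```
  band_lo_s band_hi_s exp_mean_coherence sur_mean_coherence p_adjusted
1         2         4          0.3887611          0.1685004    0.09375
2         4         8          0.4349444          0.1427236    0.09375
3         8        16          0.2872403          0.1449912    0.09375
  significant phase_diff_deg
1       FALSE      -1.302013
2       FALSE     -13.187671
3       FALSE     -12.922010
```

The coupled 4–8 s band shows experimental coherence 0.43 against a
pseudo-dyad chance floor of 0.14, and the per-dyad recovered band phases
(`res$experimental[["inter.head_voice"]]`, 4–8 s rows) are −20.2, −14.2,
−20.1, −19.5, −21.8, −26.2° — a circular mean within a few degrees of the
configured −18°. The exact two-sided sign-flip test with 6 dyads bottoms
out at p = 2/2⁶ = 0.03125, and Bonferroni across the 3 analysed bands
gives 0.094: honestly "underpowered at n = 6", which is how the
permutation machinery should behave (at realistic dyad counts the same
pipeline resolves the effect; the full default run uses all 23 bands).
Turn statistics of the generated sessions (`res$turn_stats`) average 74%
of turns ≤ 10 s and a 61% overlap share of switches in these six short
sessions (the configured targets, 72%/70%, are hit in expectation over
longer sessions).

`report(res, "out/")` writes the comparison table, per-dyad band
summaries, turn statistics, phase histograms of significant bands and a
JSON manifest that reproduces the run bit-identically.

## Command line

A thin CLI wrapper ships in `inst/cli/dyadsync.R`:

```sh
Rscript inst/cli/dyadsync.R turns --tiers session.tsv --out structure.json
Rscript inst/cli/dyadsync.R simulate --seed 1 --duration 600 --out session/
Rscript inst/cli/dyadsync.R xwt --a A_head.tsv --b B_voice.tsv --rate 90 --out bands.tsv
```

See `vignettes/dyadsync-methods.Rmd` for the model, parameter rationale,
surrogate design, and what the synthetic generator does and does not
emulate.
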