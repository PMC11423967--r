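Package: dyadsync
Title: Multimodal Synchrony Analysis for Dyadic Conversation
Version: 0.1.0
Authors@R:
    person("Dyadsync", "Developers", email = "dyadsync@example.org",
           role = c("aut", "cre"))
Description: Tools to quantify intrapersonal and interpersonal synchrony of
    speech and co-speech gesture in dyadic conversation. Reads Biovision
    Hierarchy (BVH) motion capture, WAV audio and speaking-time annotation
    tiers; derives head speed, summed wrist speed and the speech amplitude
    envelope on a common 90 Hz clock; segments conversations into speech
    units, pauses, gaps, turns, overlaps and turn switches; measures
    time-scale resolved coupling with Morlet cross-wavelet coherence and
    relative phase aggregated over 23 conversational timescale bands
    (0.125-30 s); and tests observed synchrony against pseudo-dyad and
    segment-shuffle surrogate null models with per-band permutation tests.
    Includes a fully seeded synthetic dyad generator with known turn
    structure and per-band coupling ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
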