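test_that("generate_session is seed-deterministic with aligned series", {
  cfg <- dyad_sim_config(duration = 90, seed = 5)
  s1 <- generate_session(cfg)
  s2 <- generate_session(cfg)
  expect_identical(s1$recording$A$head_speed$values,
                   s2$recording$A$head_speed$values)
  expect_identical(s1$tiers, s2$tiers)
  rec <- s1$recording
  expect_equal(rec$rate, 90)
  expect_equal(rec$n, 90 * 90)
  for (p in c("A", "B")) for (m in c("head", "wrist", "voice")) {
    v <- get_series(rec, p, m)$values
    expect_true(all(is.finite(v)) && all(v >= 0))
    expect_equal(length(v), rec$n)
  }
  # a different seed gives different data
  s3 <- generate_session(dyad_sim_config(duration = 90, seed = 6))
  expect_false(identical(s1$recording$A$head_speed$values,
                         s3$recording$A$head_speed$values))
})

test_that("the analysis reproduces the generator's own structure exactly", {
  for (sd in 1:8) {
    ts <- generate_turn_sequence(dyad_sim_config(duration = 240, seed = sd))
    cs <- conversation_structure(ts$tiers, 0.2)
    gt <- ts$structure
    expect_equal(cs$units$start, gt$units$start)
    expect_equal(cs$units$end, gt$units$end)
    expect_identical(cs$units$speaker, gt$units$speaker)
    expect_equal(cs$turns$start, gt$turns$start)
    expect_equal(cs$turns$end, gt$turns$end)
    expect_equal(cs$overlaps$start, gt$overlaps$start)
    expect_equal(cs$switches$time, gt$switches$time)
    expect_identical(cs$switches$kind, gt$switches$kind)
    expect_identical(cs$silences$kind, gt$silences$kind)
  }
})

test_that("zero overlap probability yields zero overlap switches", {
  ts <- generate_turn_sequence(
    dyad_sim_config(duration = 300, seed = 9, overlap_prob = 0,
                    backchannel_prob = 0))
  expect_equal(nrow(ts$structure$overlaps), 0)
  expect_true(all(ts$structure$switches$kind == "turn_onset"))
})

test_that("turn statistics hit their configured targets on average", {
  shares <- c(); p10 <- c()
  for (sd in 1:25) {
    st <- turn_statistics(conversation_structure(
      generate_turn_sequence(dyad_sim_config(duration = 600,
                                             seed = sd))$tiers))
    shares <- c(shares, st$overlap_switch_share)
    p10 <- c(p10, st$duration_bins[[1]])
  }
  expect_lt(abs(mean(shares) - 0.70), 0.05)
  expect_lt(abs(mean(p10) - 0.72), 0.05)
})

test_that("envelopes concentrate energy inside annotated speech", {
  cfg <- dyad_sim_config(duration = 120, seed = 12)
  ts <- generate_turn_sequence(cfg)
  envs <- generate_envelopes(ts$tiers, cfg)
  for (sp in c("A", "B")) {
    env <- envs[[sp]]
    expect_identical(env$label, "voice_env")
    tt <- sample_times(env)
    inside <- rep(FALSE, length(tt))
    iv <- ts$units[ts$units$speaker == sp, ]
    for (k in seq_len(nrow(iv)))
      inside[tt >= iv$start[k] & tt < iv$end[k]] <- TRUE
    expect_gt(mean(env$values[inside]), 5 * mean(env$values[!inside]))
  }
  # empty tiers: noise floor only
  silent <- generate_envelopes(
    speech_intervals(data.frame(speaker = "A", start = 1, end = 2))[0, ],
    cfg)
  expect_lt(max(silent$A$values), 0.1)
})

test_that("periodic envelope events put the CWT power peak at 0.5 Hz", {
  # one syllable burst every 2 s: dominant timescale 2 s
  cfg <- dyad_sim_config(duration = 60, seed = 13, noise_floor = 0.01)
  iv <- speech_intervals(data.frame(
    speaker = "A", start = seq(0.5, 57.5, 2), end = seq(0.7, 57.7, 2)))
  n <- round(cfg$duration * cfg$rate)
  env <- numeric(n)
  for (t0 in iv$start) {
    i0 <- floor(t0 * cfg$rate) + 1
    i1 <- min(n, ceiling((t0 + 0.2) * cfg$rate))
    tt <- ((i0:i1) - 1) / cfg$rate
    env[i0:i1] <- env[i0:i1] +
      0.5 * (1 - cos(2 * pi * pmin(pmax((tt - t0) / 0.2, 0), 1)))
  }
  s <- uniform_series(env, cfg$rate, label = "voice_env")
  w <- cwt_morlet(s, scale_grid(0.25, 8, 16))
  pow <- Mod(w$coeffs)^2
  pow[!outer(w$coi, w$periods, `>`)] <- NA
  prof <- colMeans(pow, na.rm = TRUE)
  expect_equal(1 / w$periods[which.max(prof)], 0.5, tolerance = 0.03)
})

test_that("configured coupling strength and lag are recovered", {
  g <- scale_grid(2, 16, 8)
  bands <- timescale_bands(4, 8)
  rec_coh <- function(strength, seed = 21) {
    cps <- if (strength > 0)
      data.frame(target = "A.head", driver = "B.voice", lo_s = 4, hi_s = 8,
                 strength = strength, phase_deg = -18) else NULL
    ss <- generate_session(dyad_sim_config(duration = 180, seed = seed,
                                           couplings = cps))
    wa <- cwt_morlet(get_series(ss$recording, "A", "head"), g)
    wb <- cwt_morlet(get_series(ss$recording, "B", "voice"), g)
    m <- xwt_maps(wa, wb)
    band_average(m$coherence, m$phase, bands)
  }
  sweep <- lapply(c(0, 0.3, 0.6, 0.9), rec_coh)
  coh <- vapply(sweep, function(b) b$mean_coherence, numeric(1))
  expect_true(all(diff(coh) > 0))        # monotone in strength
  strong <- sweep[[4]]
  expect_lt(abs(wrap_deg(strong$circ_mean_phase_deg - (-18))), 5)
  # coupling band beyond duration/4 is rejected up front
  expect_error(
    dyad_sim_config(duration = 100, couplings = data.frame(
      target = "A.head", driver = "B.voice", lo_s = 20, hi_s = 30,
      strength = 0.5, phase_deg = 0)),
    "analyzable")
})
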