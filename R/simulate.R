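# Synthetic dyadic sessions with known ground truth: turn-structured speech
# envelopes and coupled movement series, plus matching annotation tiers, so
# every pipeline stage is testable without external data.
#
# The generator's defaults state the world the analysis expects: ~70% of
# turns at most 10 s (lognormal durations), 70% of turn switches arising
# from overlaps, ~0.2 s syllable-scale envelope events, and a common 90 Hz
# clock. Coupling is imposed by phase-locking band-limited components of a
# driver signal, so the configured phase lag is exact ground truth.

#' Configuration for a synthetic dyad session
#'
#' @param duration session length in seconds (default 600; at least 60 for
#'   stable turn statistics).
#' @param rate common sampling rate in Hz (default 90).
#' @param seed integer seed; the session is fully determined by it.
#' @param turn_meanlog,turn_sdlog lognormal parameters of turn duration in
#'   seconds (defaults 1.75 / 0.9: ~72% of turns at most 10 s, ~22% in
#'   10-20 s, ~5% in 20-30 s).
#' @param overlap_prob probability that a turn switch happens through an
#'   overlap rather than after a gap (default 0.7).
#' @param backchannel_prob probability of inserting a short contained
#'   backchannel by the listener into a turn (default 0.05).
#' @param unit_meanlog,unit_sdlog lognormal parameters of within-turn
#'   speech-unit duration (defaults log(1.8) / 0.55).
#' @param pause_min,pause_mean_extra intra-turn pauses are
#'   `pause_min + Exp(mean = pause_mean_extra)` seconds (defaults 0.25 and
#'   0.3, safely above the 0.2 s merge threshold).
#' @param gap_min,gap_mean_extra silences at non-overlap switches,
#'   analogous (defaults 0.25 and 0.4).
#' @param split_prob probability that an emitted annotation interval is
#'   split in two with a sub-threshold (< 0.2 s) silence, to exercise unit
#'   merging (default 0.3).
#' @param syllable_rate syllable event rate inside speech, Hz (default 4).
#' @param syllable_s syllable bump duration in seconds (default 0.2,
#'   raised-cosine).
#' @param amplitude_jitter relative jitter of syllable amplitudes
#'   (default 0.25).
#' @param noise_floor envelope noise level outside speech (default 0.02).
#' @param couplings data.frame with columns `target`, `driver` (series ids
#'   `"A.head"`, `"B.voice"`, ...), `lo_s`, `hi_s` (band, seconds),
#'   `strength` in `[0, 1]` and `phase_deg` (the ground-truth relative
#'   phase of the pair (target, driver); positive = target leads). Default
#'   none.
#' @param movement_baseline,movement_spread mean level and fluctuation SD
#'   of the non-negative synthetic speed series (defaults 1.0 and 0.25).
#' @return a `dyad_sim_config` list.
#' @export
dyad_sim_config <- function(duration = 600, rate = 90, seed = 1L,
                            turn_meanlog = 1.75, turn_sdlog = 0.9,
                            overlap_prob = 0.7, backchannel_prob = 0.05,
                            unit_meanlog = log(1.8), unit_sdlog = 0.55,
                            pause_min = 0.25, pause_mean_extra = 0.3,
                            gap_min = 0.25, gap_mean_extra = 0.4,
                            split_prob = 0.3,
                            syllable_rate = 4, syllable_s = 0.2,
                            amplitude_jitter = 0.25, noise_floor = 0.02,
                            couplings = NULL,
                            movement_baseline = 1.0,
                            movement_spread = 0.25) {
  if (duration < 60)
    stop("`duration` must be at least 60 s for stable statistics",
         call. = FALSE)
  for (p in c(overlap_prob, backchannel_prob, split_prob))
    if (p < 0 || p > 1) stop("probabilities must lie in [0, 1]",
                             call. = FALSE)
  if (is.null(couplings)) {
    couplings <- data.frame(target = character(0), driver = character(0),
                            lo_s = numeric(0), hi_s = numeric(0),
                            strength = numeric(0), phase_deg = numeric(0))
  } else {
    couplings <- as.data.frame(couplings)
    stopifnot(all(c("target", "driver", "lo_s", "hi_s", "strength",
                    "phase_deg") %in% names(couplings)))
    if (any(couplings$strength < 0 | couplings$strength > 1))
      stop("coupling strengths must lie in [0, 1]", call. = FALSE)
    if (any(couplings$hi_s > duration / 4))
      stop(sprintf(
        "coupling band up to %.3g s exceeds the analyzable range (duration/4 = %.3g s)",
        max(couplings$hi_s), duration / 4), call. = FALSE)
  }
  cfg <- list(duration = duration, rate = rate, seed = as.integer(seed),
              turn_meanlog = turn_meanlog, turn_sdlog = turn_sdlog,
              overlap_prob = overlap_prob,
              backchannel_prob = backchannel_prob,
              unit_meanlog = unit_meanlog, unit_sdlog = unit_sdlog,
              pause_min = pause_min, pause_mean_extra = pause_mean_extra,
              gap_min = gap_min, gap_mean_extra = gap_mean_extra,
              split_prob = split_prob,
              syllable_rate = syllable_rate, syllable_s = syllable_s,
              amplitude_jitter = amplitude_jitter,
              noise_floor = noise_floor, couplings = couplings,
              movement_baseline = movement_baseline,
              movement_spread = movement_spread)
  class(cfg) <- "dyad_sim_config"
  cfg
}

r3 <- function(x) round(x, 3)

#' Generate an alternating turn sequence with ground truth
#'
#' Samples alternating speaker turns (lognormal durations), fills each with
#' speech units separated by supra-threshold pauses, realizes switches as
#' overlaps with the configured probability and gaps otherwise, and
#' occasionally inserts contained listener backchannels. Emits both the
#' annotation tiers (some units split by sub-threshold silences) and the
#' expected conversational structure, derived from the unit list by a
#' definition-based sweep that is independent of the analysis code.
#'
#' All emitted times are rounded to 1 ms.
#'
#' @param cfg a [dyad_sim_config()].
#' @param seed integer seed (default derived from `cfg$seed`).
#' @return list with `tiers` (a [speech_intervals()] data.frame), `units`
#'   (the true merged units) and `structure` (the expected
#'   [conversation_structure()]).
#' @export
generate_turn_sequence <- function(cfg,
                                   seed = derive_seed(cfg$seed, "turns")) {
  stopifnot(inherits(cfg, "dyad_sim_config"))
  with_seed(seed, {
    units <- data.frame(speaker = character(0), start = numeric(0),
                        end = numeric(0))
    speaker <- "A"
    t_cur <- r3(stats::runif(1, 0, 0.5))
    last_unit_of_turn <- NULL
    while (t_cur < cfg$duration - 2) {
      turn_d <- min(max(stats::rlnorm(1, cfg$turn_meanlog, cfg$turn_sdlog),
                        0.8), 45, cfg$duration - t_cur - 0.5)
      turn_end <- t_cur + turn_d
      # fill the turn with units and supra-threshold pauses
      u_start <- t_cur
      turn_units <- NULL
      repeat {
        u_d <- min(max(stats::rlnorm(1, cfg$unit_meanlog, cfg$unit_sdlog),
                       0.35), turn_end - u_start)
        u_end <- u_start + u_d
        turn_units <- rbind(turn_units,
                            data.frame(speaker = speaker,
                                       start = r3(u_start), end = r3(u_end)))
        pause_d <- cfg$pause_min + stats::rexp(1, 1 / cfg$pause_mean_extra)
        if (u_end + pause_d + 0.35 > turn_end) break
        u_start <- u_end + pause_d
      }
      units <- rbind(units, turn_units)
      last <- turn_units[nrow(turn_units), ]
      other <- setdiff(c("A", "B"), speaker)
      # occasional contained backchannel by the listener, hosted by an
      # interior unit so it cannot collide with the listener's own turns
      nu <- nrow(turn_units)
      interior <- if (nu >= 3L) 2:(nu - 1L) else integer(0)
      long_units <- interior[turn_units$end[interior] -
                               turn_units$start[interior] >= 1.6]
      if (length(long_units) > 0 &&
          stats::runif(1) < cfg$backchannel_prob) {
        host <- turn_units[long_units[sample.int(length(long_units), 1)], ]
        bc_d <- stats::runif(1, 0.15, 0.4)
        bc_start <- stats::runif(1, host$start + 0.3,
                                 host$end - 0.3 - bc_d)
        units <- rbind(units,
                       data.frame(speaker = other,
                                  start = r3(bc_start),
                                  end = r3(bc_start + bc_d)))
      }
      # switch to the other speaker; the incoming onset must stay clear of
      # the incoming speaker's own previous speech
      other_end <- units$end[units$speaker == other]
      other_last <- if (length(other_end) > 0) max(other_end) else -Inf
      ov_lo <- max(last$start + 0.15, other_last + 0.25)
      if (stats::runif(1) < cfg$overlap_prob && last$end - 0.1 > ov_lo) {
        t_cur <- stats::runif(1, max(ov_lo, last$end - 0.5),
                              last$end - 0.1)
      } else {
        t_cur <- max(last$end, other_last + 0.25) + cfg$gap_min +
          stats::rexp(1, 1 / cfg$gap_mean_extra)
      }
      t_cur <- r3(t_cur)
      speaker <- other
    }
    units <- units[units$end <= cfg$duration, , drop = FALSE]
    units <- units[order(units$start, units$speaker), , drop = FALSE]
    rownames(units) <- NULL
    # annotation tiers: some units split by sub-threshold silences
    tier_rows <- lapply(seq_len(nrow(units)), function(k) {
      u <- units[k, ]
      d <- u$end - u$start
      if (d > 1.0 && stats::runif(1) < cfg$split_prob) {
        cut <- r3(stats::runif(1, u$start + 0.25, u$end - 0.25))
        sil <- r3(stats::runif(1, 0.03, min(0.15, u$end - cut - 0.05)))
        data.frame(speaker = u$speaker, start = c(u$start, cut + sil),
                   end = c(cut, u$end))
      } else u
    })
    tiers <- speech_intervals(do.call(rbind, tier_rows))
    list(tiers = tiers, units = units,
         structure = sweep_structure(units, min_silence = 0.2))
  })
}

# Definition-based derivation of the conversational structure from a
# merged-unit list; intentionally written from the definitions (pairwise
# checks) rather than sharing code with the analysis implementation, so it
# can serve as ground truth for it.
sweep_structure <- function(units, min_silence = 0.2) {
  u <- units[order(units$start, units$speaker), , drop = FALSE]
  rownames(u) <- NULL
  n <- nrow(u)
  # turns: consecutive same-speaker units stay together iff no
  # other-speaker unit onset falls strictly between their onsets
  turn_id <- integer(n)
  tid <- 1L
  turn_id[1] <- tid
  for (k in seq_len(n)[-1]) {
    same <- u$speaker[k] == u$speaker[k - 1]
    if (!same) tid <- tid + 1L
    turn_id[k] <- tid
  }
  turns <- do.call(rbind, lapply(split(seq_len(n), turn_id), function(ii)
    data.frame(speaker = u$speaker[ii[1]], start = min(u$start[ii]),
               end = max(u$end[ii]))))
  rownames(turns) <- NULL
  # overlaps: all pairwise A x B unit intersections
  ov <- NULL
  ia <- which(u$speaker == "A"); ib <- which(u$speaker == "B")
  for (i in ia) for (j in ib) {
    s <- max(u$start[i], u$start[j]); e <- min(u$end[i], u$end[j])
    if (e > s)
      ov <- rbind(ov, data.frame(
        start = s, end = e,
        incoming_speaker = if (u$start[i] >= u$start[j]) "A" else "B"))
  }
  if (is.null(ov)) ov <- data.frame(start = numeric(0), end = numeric(0),
                                    incoming_speaker = character(0))
  ov <- ov[order(ov$start), , drop = FALSE]
  rownames(ov) <- NULL
  # switches: overlap onsets plus onsets of turns after a speaker change
  sw_t <- c()
  sw_kind <- c()
  sw_in <- c()
  if (nrow(turns) >= 2) for (k in 2:nrow(turns)) {
    if (turns$speaker[k] != turns$speaker[k - 1]) {
      sw_t <- c(sw_t, turns$start[k])
      sw_kind <- c(sw_kind,
                   if (turns$start[k] %in% ov$start) "overlap_onset"
                   else "turn_onset")
      sw_in <- c(sw_in, turns$speaker[k])
    }
  }
  extra <- setdiff(ov$start, sw_t)
  if (length(extra) > 0) {
    kk <- match(extra, ov$start)
    sw_t <- c(sw_t, ov$start[kk])
    sw_kind <- c(sw_kind, rep("overlap_onset", length(kk)))
    sw_in <- c(sw_in, ov$incoming_speaker[kk])
  }
  ordsw <- order(sw_t)
  switches <- data.frame(kind = sw_kind[ordsw], time = sw_t[ordsw],
                         incoming_speaker = sw_in[ordsw])
  # silences: maximal no-speech intervals >= min_silence
  cov_end <- cummax(u$end)
  sil <- NULL
  for (k in seq_len(n - 1)) {
    s0 <- cov_end[k]; s1 <- u$start[k + 1]
    if (s1 - s0 >= min_silence - 1e-9) {
      enders <- which(u$end[1:k] == s0)
      before <- u$speaker[enders[which.max(u$start[enders])]]
      after <- u$speaker[k + 1]
      sil <- rbind(sil, data.frame(
        kind = if (before == after) "pause" else "gap",
        start = s0, end = s1, before_speaker = before,
        after_speaker = after))
    }
  }
  if (is.null(sil))
    sil <- data.frame(kind = character(0), start = numeric(0),
                      end = numeric(0), before_speaker = character(0),
                      after_speaker = character(0))
  list(units = u, silences = sil, turns = turns, overlaps = ov,
       switches = switches, min_silence = min_silence)
}

#' Generate syllable-structured voice envelopes from tiers
#'
#' Inside each annotated speech interval, a train of raised-cosine syllable
#' bumps (duration `syllable_s`, rate about `syllable_rate`) with jittered
#' amplitudes; a small positive noise floor elsewhere.
#'
#' @param tiers a [speech_intervals()] data.frame for both speakers.
#' @param cfg a [dyad_sim_config()].
#' @param seed integer seed.
#' @return named list of [uniform_series()] (label `voice_env`), one per
#'   speaker, each `round(duration * rate)` samples.
#' @export
generate_envelopes <- function(tiers, cfg,
                               seed = derive_seed(cfg$seed, "env")) {
  stopifnot(inherits(cfg, "dyad_sim_config"))
  n <- round(cfg$duration * cfg$rate)
  with_seed(seed, {
    out <- list()
    for (sp in c("A", "B")) {
      env <- cfg$noise_floor * (0.5 + abs(stats::rnorm(n)) / 2)
      iv <- tiers[tiers$speaker == sp, , drop = FALSE]
      for (k in seq_len(nrow(iv))) {
        t0 <- iv$start[k]
        while (t0 < iv$end[k]) {
          amp <- max(0.2, 1 + cfg$amplitude_jitter * stats::rnorm(1))
          i0 <- floor(t0 * cfg$rate) + 1
          i1 <- min(n, ceiling((t0 + cfg$syllable_s) * cfg$rate))
          if (i0 <= n && i1 >= i0) {
            tt <- ((i0:i1) - 1) / cfg$rate
            bump <- amp * 0.5 *
              (1 - cos(2 * pi * pmin(pmax((tt - t0) / cfg$syllable_s, 0), 1)))
            env[i0:i1] <- env[i0:i1] + bump
          }
          t0 <- t0 + stats::runif(1, 0.7, 1.3) / cfg$syllable_rate
        }
      }
      out[[sp]] <- uniform_series(env, cfg$rate, label = "voice_env")
    }
    out
  })
}

# 1/f-ish background noise between f_lo and f_hi Hz, unit variance.
pink_noise <- function(n, rate, f_lo = 0.05, f_hi = 10) {
  m <- next_pow2(2 * n)
  f <- (0:(m - 1)) * rate / m
  amp <- numeric(m)
  pos <- f > 0 & f <= f_hi
  amp[pos] <- 1 / sqrt(pmax(f[pos], f_lo))
  z <- amp * (stats::rnorm(m) + 1i * stats::rnorm(m))
  x <- Re(stats::fft(z, inverse = TRUE))[seq_len(n)]
  (x - mean(x)) / stats::sd(x)
}

# Band-limited, phase-rotated component of a driver signal; unit variance.
# phase_deg is the desired relative phase of (target, driver).
coupled_component <- function(driver, rate, lo_s, hi_s, phase_deg) {
  n <- length(driver)
  m <- next_pow2(2 * n)
  xf <- stats::fft(c(driver - mean(driver), numeric(m - n)))
  f <- (0:(m - 1)) * rate / m
  keep <- f >= 1 / hi_s & f <= 1 / lo_s   # positive-frequency band only
  keep[f > rate / 2] <- FALSE
  h <- numeric(m)
  h[keep] <- 2
  z <- stats::fft(xf * h * exp(1i * phase_deg * pi / 180),
                  inverse = TRUE)[seq_len(n)] / m
  x <- Re(z)
  s <- stats::sd(x)
  if (s < 1e-12) stop("driver has no power in the coupling band",
                      call. = FALSE)
  x / s
}

#' Generate head and wrist speed series with configured coupling
#'
#' Each movement series is a positive-mean mixture of 1/f background noise
#' and, per configured coupling row targeting it, a band-limited component
#' phase-locked to its driver (own voice, partner voice or partner
#' movement) with the configured strength and exact phase lag. Zero
#' coupling gives independent noise. Values are clipped at zero (speeds
#' are non-negative); the baseline keeps clipping rare.
#'
#' @param tiers unused directly (envelopes already encode speech activity),
#'   accepted for signature symmetry.
#' @param voice_envs named list (`A`, `B`) of envelope [uniform_series()].
#' @param cfg a [dyad_sim_config()].
#' @param seed integer seed.
#' @return nested list `out[[participant]][[modality]]` with participants
#'   `A`, `B` and modalities `head`, `wrist` ([uniform_series()]).
#' @export
generate_coupled_movements <- function(tiers, voice_envs, cfg,
                                       seed = derive_seed(cfg$seed, "mov")) {
  stopifnot(inherits(cfg, "dyad_sim_config"))
  n <- length(voice_envs$A$values)
  ids <- c("A.head", "A.wrist", "B.head", "B.wrist")
  with_seed(seed, {
    base <- lapply(stats::setNames(ids, ids), function(id)
      pink_noise(n, cfg$rate))
    series_pool <- list(A.voice = voice_envs$A$values,
                        B.voice = voice_envs$B$values)
    out <- list(A = list(), B = list())
    for (id in ids) {
      cps <- cfg$couplings[cfg$couplings$target == id, , drop = FALSE]
      if (sum(cps$strength^2) > 1)
        stop(sprintf("summed squared coupling strengths for %s exceed 1",
                     id), call. = FALSE)
      fluct <- sqrt(1 - sum(cps$strength^2)) * base[[id]]
      for (k in seq_len(nrow(cps))) {
        drv <- cps$driver[k]
        drv_vals <- if (drv %in% names(series_pool)) series_pool[[drv]]
          else base[[drv]]
        fluct <- fluct + cps$strength[k] *
          coupled_component(drv_vals, cfg$rate, cps$lo_s[k], cps$hi_s[k],
                            cps$phase_deg[k])
      }
      part <- substr(id, 1, 1)
      mod <- substr(id, 3, nchar(id))
      vals <- pmax(cfg$movement_baseline + cfg$movement_spread * fluct, 0)
      out[[part]][[mod]] <- uniform_series(
        vals, cfg$rate,
        label = if (mod == "head") "head_speed" else "wrist_speed")
    }
    out
  })
}

#' Generate a complete synthetic session
#'
#' Composes turn sequence, envelopes and coupled movements; fully
#' determined by `cfg$seed`.
#'
#' @param cfg a [dyad_sim_config()].
#' @return a `synthetic_session`: list with `recording`
#'   (a [dyad_recording()]), `tiers`, `units`, `structure` (ground-truth
#'   conversational structure), `couplings`, `cfg`.
#' @export
generate_session <- function(cfg) {
  stopifnot(inherits(cfg, "dyad_sim_config"))
  ts <- generate_turn_sequence(cfg)
  envs <- generate_envelopes(ts$tiers, cfg)
  mov <- generate_coupled_movements(ts$tiers, envs, cfg)
  rec <- dyad_recording(
    session = sprintf("sim-%d", cfg$seed),
    A = list(head_speed = mov$A$head, wrist_speed = mov$A$wrist,
             voice_env = envs$A),
    B = list(head_speed = mov$B$head, wrist_speed = mov$B$wrist,
             voice_env = envs$B))
  structure(list(recording = rec, tiers = ts$tiers, units = ts$units,
                 structure = ts$structure, couplings = cfg$couplings,
                 cfg = cfg, seed = cfg$seed),
            class = "synthetic_session")
}

#' @export
print.synthetic_session <- function(x, ...) {
  cat(sprintf(
    "<synthetic_session seed %d> %.0f s @ %g Hz, %d units, %d couplings\n",
    x$seed, x$cfg$duration, x$cfg$rate, nrow(x$units),
    nrow(x$couplings)))
  invisible(x)
}
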