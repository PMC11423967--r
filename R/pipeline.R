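# Orchestration: the full analysis over a set of dyad sessions -- the
# standard pair roster, experimental band summaries, matched surrogate
# ensembles (segment shuffling for intrapersonal pairs, pseudo-dyads for
# interpersonal pairs), and per-band condition comparisons with Bonferroni
# correction across bands.

#' The standard roster of signal pairs
#'
#' Nine pair types: intrapersonal unimodal wrist x head; intrapersonal
#' multimodal head x voice and wrist x voice; interpersonal unimodal
#' voice x voice, head x head, wrist x wrist and wrist x head; and
#' interpersonal multimodal head x voice and wrist x voice. For
#' interpersonal pairs the first-named modality is participant A's and the
#' second participant B's; intrapersonal pairs are computed per participant
#' and averaged at the dyad level.
#'
#' @return data.frame with columns `pair`, `level`, `modality_class`,
#'   `mod1`, `mod2`.
#' @export
default_pair_roster <- function() {
  data.frame(
    pair = c("intra.wrist_head", "intra.head_voice", "intra.wrist_voice",
             "inter.voice_voice", "inter.head_head", "inter.wrist_wrist",
             "inter.wrist_head", "inter.head_voice", "inter.wrist_voice"),
    level = c("intra", "intra", "intra",
              "inter", "inter", "inter", "inter", "inter", "inter"),
    modality_class = c("unimodal", "multimodal", "multimodal",
                       "unimodal", "unimodal", "unimodal", "unimodal",
                       "multimodal", "multimodal"),
    mod1 = c("wrist", "head", "wrist", "voice", "head", "wrist", "wrist",
             "head", "wrist"),
    mod2 = c("head", "voice", "voice", "voice", "head", "wrist", "head",
             "voice", "voice"))
}

#' Analysis configuration
#'
#' @param sessions list of sessions; each element either a
#'   [dyad_sim_config()] (generated on the fly), a `synthetic_session`, or
#'   a list with elements `recording` (a [dyad_recording()]), `dyad` and
#'   `take` ids.
#' @param bands a `timescale_bands` (default [default_bands()]).
#' @param min_period,max_period,voices_per_octave wavelet grid
#'   (defaults 0.125 s, 32 s, 16).
#' @param omega0 Morlet center frequency (default 6).
#' @param smoothing_decades coherence smoothing span (default 0.6).
#' @param use_coi exclude cone-of-influence bins (default TRUE).
#' @param n_shuffle segment-shuffle surrogates per participant pair per
#'   dyad (default 200).
#' @param segment_s shuffle segment length in seconds (default 0.2).
#' @param n_perm sign-flip resamples for the permutation test when exact
#'   enumeration is infeasible (default 2000).
#' @param alpha significance level before Bonferroni (default 0.05).
#' @param seed master seed; all surrogate and permutation seeds derive
#'   from it.
#' @param roster pair roster (default [default_pair_roster()]).
#' @return an `analysis_config` list.
#' @export
analysis_config <- function(sessions, bands = default_bands(),
                            min_period = 0.125, max_period = 32,
                            voices_per_octave = 16L, omega0 = 6,
                            smoothing_decades = 0.6, use_coi = TRUE,
                            n_shuffle = 200L, segment_s = 0.2,
                            n_perm = 2000L, alpha = 0.05, seed = 1L,
                            roster = default_pair_roster()) {
  structure(list(sessions = sessions, bands = bands,
                 min_period = min_period, max_period = max_period,
                 voices_per_octave = as.integer(voices_per_octave),
                 omega0 = omega0, smoothing_decades = smoothing_decades,
                 use_coi = use_coi, n_shuffle = as.integer(n_shuffle),
                 segment_s = segment_s, n_perm = as.integer(n_perm),
                 alpha = alpha, seed = as.integer(seed), roster = roster),
            class = "analysis_config")
}

# Normalize a session entry to list(recording, dyad, take, tiers?).
resolve_session <- function(entry, k) {
  if (inherits(entry, "dyad_sim_config")) entry <- generate_session(entry)
  if (inherits(entry, "synthetic_session")) {
    return(list(recording = entry$recording,
                dyad = entry$recording$session,
                take = paste0(entry$recording$session, ".t1"),
                tiers = entry$tiers))
  }
  if (is.list(entry) && inherits(entry$recording, "dyad_recording")) {
    if (is.null(entry$dyad)) entry$dyad <- entry$recording$session
    if (is.null(entry$take)) entry$take <- paste0(entry$dyad, ".t", k)
    return(entry)
  }
  stop(sprintf("session %d is neither a sim config nor a recording", k),
       call. = FALSE)
}

# Cached per-series smoothed wavelet machinery for one analysis run.
sync_engine <- function(cfg) {
  grid <- scale_grid(cfg$min_period, cfg$max_period, cfg$voices_per_octave)
  cache <- new.env(parent = emptyenv())
  spectrum_of <- function(series, key = NULL) {
    if (!is.null(key) && !is.null(cache[[key]])) return(cache[[key]])
    w <- cwt_morlet(series, grid, cfg$omega0)
    sa <- Re(smooth_field(Mod(w$coeffs)^2 * rep(1 / w$scales, each = w$n),
                          w$scales, w$rate, cfg$voices_per_octave,
                          cfg$smoothing_decades))
    val <- list(w = w, sa = sa)
    if (!is.null(key)) cache[[key]] <- val
    val
  }
  pair_summary <- function(pa, pb) {
    inv_s <- rep(1 / pa$w$scales, each = pa$w$n)
    sab <- smooth_field(pa$w$coeffs * Conj(pb$w$coeffs) * inv_s,
                        pa$w$scales, pa$w$rate, cfg$voices_per_octave,
                        cfg$smoothing_decades)
    sm <- list(sa = pa$sa, sb = pb$sa, sab = sab,
               periods = pa$w$periods, rate = pa$w$rate,
               coi = pmin(pa$w$coi, pb$w$coi), n = pa$w$n)
    band_average(coherence_from_smoothed(sm), phase_from_smoothed(sm),
                 cfg$bands, cfg$use_coi)
  }
  list(grid = grid, spectrum_of = spectrum_of, pair_summary = pair_summary)
}

#' Run the full synchrony analysis
#'
#' For every pair type in the roster and every session: the experimental
#' per-band summary; a matched surrogate ensemble (segment shuffling of the
#' second-named series for intrapersonal pairs, all pseudo-dyad pairings
#' for interpersonal pairs); and per-band experimental-vs-surrogate
#' comparisons with a paired sign-flip permutation test, Bonferroni
#' corrected across bands. Sessions missing a modality are skipped with a
#' warning.
#'
#' @param cfg an [analysis_config()].
#' @return a `sync_results` bundle: list with `experimental` (per-pair
#'   per-dyad band summaries), `surrogates` (per-pair ensembles),
#'   `comparisons` (per-pair data.frames), `turn_stats` (per session where
#'   tiers are available), `roster`, `config`, `log`.
#' @export
run_analysis <- function(cfg) {
  stopifnot(inherits(cfg, "analysis_config"))
  log <- character(0)
  note <- function(fmt, ...) log <<- c(log, sprintf(fmt, ...))
  sessions <- lapply(seq_along(cfg$sessions), function(k)
    tryCatch(resolve_session(cfg$sessions[[k]], k), error = function(e) {
      warning(sprintf("session %d skipped: %s", k, conditionMessage(e)),
              call. = FALSE)
      NULL
    }))
  sessions <- Filter(Negate(is.null), sessions)
  if (length(sessions) == 0) stop("all sessions skipped", call. = FALSE)
  note("run_analysis: %d sessions, seed %d", length(sessions), cfg$seed)
  eng <- sync_engine(cfg)
  roster <- cfg$roster
  n_bands <- nrow(cfg$bands)

  skey <- function(take, part, mod) paste(take, part, mod, sep = "|")
  get_spec <- function(sess, part, mod) {
    eng$spectrum_of(get_series(sess$recording, part, mod),
                    skey(sess$take, part, mod))
  }

  experimental <- list(); surrogates <- list(); comparisons <- list()
  for (r in seq_len(nrow(roster))) {
    pr <- roster[r, ]
    note("pair %s (%s, %s)", pr$pair, pr$level, pr$modality_class)
    # experimental: per-dyad summaries
    exp_rows <- lapply(sessions, function(sess) {
      if (pr$level == "intra") {
        per_part <- lapply(c("A", "B"), function(p) {
          bs <- eng$pair_summary(get_spec(sess, p, pr$mod1),
                                 get_spec(sess, p, pr$mod2))
          bs$dyad <- sess$dyad; bs
        })
        ag <- aggregate_band_summaries(do.call(rbind, per_part), "dyad")
      } else {
        ag <- eng$pair_summary(get_spec(sess, "A", pr$mod1),
                               get_spec(sess, "B", pr$mod2))
        ag$dyad <- sess$dyad
      }
      ag
    })
    exp_df <- do.call(rbind, exp_rows)
    # surrogate ensemble
    if (pr$level == "intra") {
      per <- list()
      for (sess in sessions) for (p in c("A", "B")) {
        pa <- get_spec(sess, p, pr$mod1)
        b_series <- get_series(sess$recording, p, pr$mod2)
        for (k in seq_len(cfg$n_shuffle)) {
          sh <- segment_shuffle(b_series, cfg$segment_s,
                                derive_seed(cfg$seed, pr$pair, sess$take,
                                            p, k))
          pb <- eng$spectrum_of(sh)
          bs <- eng$pair_summary(pa, pb)
          bs$dyad <- sess$dyad
          bs$surrogate <- paste(p, k, sep = ".")
          per[[length(per) + 1]] <- bs
        }
      }
      per_surrogate <- do.call(rbind, per)
      ens <- structure(
        list(condition = "segment_shuffle", per_surrogate = per_surrogate,
             per_dyad = aggregate_band_summaries(per_surrogate, "dyad"),
             n = length(per)),
        class = "surrogate_ensemble")
    } else {
      takes <- data.frame(
        take = vapply(sessions, `[[`, character(1), "take"),
        dyad = vapply(sessions, `[[`, character(1), "dyad"),
        n_samples = vapply(sessions, function(s) s$recording$n, numeric(1)))
      plan <- tryCatch(plan_pseudo_dyads(takes), error = function(e) NULL)
      if (is.null(plan) || nrow(plan) == 0) {
        warning(sprintf(
          "pair %s: no valid pseudo-dyad pairings; comparison skipped",
          pr$pair), call. = FALSE)
        exp_df$pair <- pr$pair
        experimental[[pr$pair]] <- exp_df
        next
      }
      per <- lapply(seq_len(nrow(plan)), function(k) {
        i <- match(plan$p1_take[k], takes$take)
        j <- match(plan$p2_take[k], takes$take)
        ntr <- plan$truncate_to[k]
        spec_trunc <- function(sess, part, mod) {
          s <- get_series(sess$recording, part, mod)
          if (length(s$values) == ntr)
            get_spec(sess, part, mod)
          else
            eng$spectrum_of(uniform_series(s$values[seq_len(ntr)], s$rate,
                                           s$start, s$label))
        }
        bs <- eng$pair_summary(spec_trunc(sessions[[i]], "A", pr$mod1),
                               spec_trunc(sessions[[j]], "B", pr$mod2))
        bs$dyad <- plan$p1_dyad[k]
        bs$surrogate <- k
        bs
      })
      per_surrogate <- do.call(rbind, per)
      ens <- structure(
        list(condition = "pseudo_dyad", per_surrogate = per_surrogate,
             per_dyad = aggregate_band_summaries(per_surrogate, "dyad"),
             n = length(per), plan = plan),
        class = "surrogate_ensemble")
    }
    cmp <- compare_conditions(exp_df, ens,
                              n_perm = cfg$n_perm, alpha = cfg$alpha,
                              seed = derive_seed(cfg$seed, pr$pair, "perm"))
    cmp$pair <- pr$pair; cmp$level <- pr$level
    cmp$modality_class <- pr$modality_class
    experimental[[pr$pair]] <- exp_df
    surrogates[[pr$pair]] <- ens
    comparisons[[pr$pair]] <- cmp
  }
  turn_stats <- lapply(sessions, function(sess) {
    if (is.null(sess$tiers)) return(NULL)
    st <- turn_statistics(conversation_structure(sess$tiers))
    c(list(session = sess$dyad), st)
  })
  turn_stats <- Filter(Negate(is.null), turn_stats)
  structure(list(experimental = experimental, surrogates = surrogates,
                 comparisons = comparisons, turn_stats = turn_stats,
                 roster = roster, config = cfg, log = log,
                 n_bands = n_bands),
            class = "sync_results")
}

# Paired sign-flip permutation test on the mean of differences; exact
# enumeration for up to 12 pairs, seeded random flips otherwise.
perm_sign_test <- function(d, n_perm = 2000L, seed = 1L) {
  d <- d[!is.na(d)]
  n <- length(d)
  if (n == 0L) return(list(p = NA_real_, obs = NA_real_, n = 0L))
  obs <- mean(d)
  eps <- 1e-12 * (1 + abs(obs))
  if (n <= 12L) {
    signs <- as.matrix(expand.grid(rep(list(c(-1, 1)), n)))
    stats <- as.numeric(signs %*% d) / n
    p <- mean(abs(stats) >= abs(obs) - eps)
  } else {
    stats <- with_seed(seed, {
      flips <- matrix(sample(c(-1, 1), n * n_perm, replace = TRUE), n_perm)
      as.numeric(flips %*% d) / n
    })
    p <- (1 + sum(abs(stats) >= abs(obs) - eps)) / (n_perm + 1)
  }
  list(p = p, obs = obs, n = n)
}

#' Per-band comparison of experimental vs surrogate synchrony
#'
#' For each timescale band, the dyad-level paired difference of mean
#' coherence (experimental minus surrogate) is tested with a two-sided
#' sign-flip permutation test, Bonferroni corrected across bands
#' (`p_adjusted = min(1, p_raw * n_bands)`). Phase is contrasted
#' analogously on the wrapped circular difference of the dyad-level
#' circular means. With fewer than 3 dyads the comparison is flagged
#' underpowered (p is still reported).
#'
#' @param experimental data.frame of per-dyad band summaries (columns
#'   `dyad`, `band_lo_s`, `band_hi_s`, `mean_coherence`,
#'   `circ_mean_phase_deg`).
#' @param surrogate a `surrogate_ensemble`.
#' @param n_perm resamples when exact enumeration is infeasible.
#' @param alpha significance level (default 0.05).
#' @param seed integer seed for the permutation draws.
#' @return data.frame, one row per band: experimental and surrogate means,
#'   difference, `p_raw`, `p_adjusted`, `significant`, the phase contrast
#'   columns, `n_dyads`, `underpowered`.
#' @export
compare_conditions <- function(experimental, surrogate, n_perm = 2000L,
                               alpha = 0.05, seed = 1L) {
  stopifnot(inherits(surrogate, "surrogate_ensemble"))
  sur <- surrogate$per_dyad
  dyads <- intersect(unique(experimental$dyad), unique(sur$dyad))
  if (length(dyads) == 0)
    stop("no common dyads between conditions", call. = FALSE)
  bands <- unique(experimental[, c("band_lo_s", "band_hi_s")])
  bands <- bands[order(bands$band_lo_s), , drop = FALSE]
  n_bands <- nrow(bands)
  rows <- lapply(seq_len(n_bands), function(k) {
    lo <- bands$band_lo_s[k]
    e <- experimental[experimental$band_lo_s == lo &
                        experimental$dyad %in% dyads, ]
    s <- sur[sur$band_lo_s == lo & sur$dyad %in% dyads, ]
    e <- e[match(dyads, e$dyad), ]
    s <- s[match(dyads, s$dyad), ]
    d_coh <- e$mean_coherence - s$mean_coherence
    tc <- perm_sign_test(d_coh, n_perm, derive_seed(seed, "coh", lo))
    d_ph <- wrap_deg(e$circ_mean_phase_deg - s$circ_mean_phase_deg)
    d_ph[is.na(e$circ_mean_phase_deg) | is.na(s$circ_mean_phase_deg)] <- NA
    tp <- perm_sign_test(d_ph, n_perm, derive_seed(seed, "ph", lo))
    data.frame(
      band_lo_s = lo, band_hi_s = bands$band_hi_s[k],
      exp_mean_coherence = mean(e$mean_coherence, na.rm = TRUE),
      sur_mean_coherence = mean(s$mean_coherence, na.rm = TRUE),
      diff_coherence = tc$obs,
      p_raw = tc$p, p_adjusted = min(1, tc$p * n_bands),
      significant = !is.na(tc$p) && min(1, tc$p * n_bands) < alpha,
      phase_diff_deg = tp$obs, p_raw_phase = tp$p,
      p_adjusted_phase = min(1, tp$p * n_bands),
      n_dyads = tc$n, underpowered = tc$n < 3L)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Write the result bundle to disk
#'
#' Emits the band-comparison table, per-dyad experimental band summaries,
#' turn statistics, circular-histogram tables of dyad-level phase means for
#' significant bands, and a JSON run manifest (configuration, seeds,
#' versions) sufficient to reproduce the run bit-identically.
#'
#' @param results a `sync_results` from [run_analysis()].
#' @param dir output directory (created if needed).
#' @return invisibly, the manifest path.
#' @export
report <- function(results, dir) {
  stopifnot(inherits(results, "sync_results"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  roster <- results$roster
  cmp <- do.call(rbind, results$comparisons)
  utils::write.table(cmp, file.path(dir, "band_comparison.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  summaries <- lapply(seq_len(nrow(roster)), function(r) {
    pr <- roster[r, ]
    df <- results$experimental[[pr$pair]]
    df$pair <- pr$pair; df$level <- pr$level
    df$modality_class <- pr$modality_class
    df
  })
  write_band_table(summaries, file.path(dir, "experimental_bands.tsv"))
  if (length(results$turn_stats) > 0) {
    ts <- do.call(rbind, lapply(results$turn_stats, function(s)
      data.frame(session = s$session, n_turns = s$n_turns,
                 n_switches = s$n_switches, n_overlaps = s$n_overlaps,
                 p_turn_le_10s = s$duration_bins[1],
                 p_turn_10_20s = s$duration_bins[2],
                 p_turn_20_30s = s$duration_bins[3],
                 p_turn_gt_30s = s$duration_bins[4],
                 overlap_switch_share = s$overlap_switch_share,
                 mean_turn_s = s$mean_turn_s,
                 median_turn_s = s$median_turn_s)))
    utils::write.table(ts, file.path(dir, "turn_statistics.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  for (pair in names(results$comparisons)) {
    c_p <- results$comparisons[[pair]]
    sig <- c_p$band_lo_s[c_p$significant]
    if (length(sig) == 0) next
    ph <- results$experimental[[pair]]
    ph <- ph$circ_mean_phase_deg[ph$band_lo_s %in% sig &
                                   !is.na(ph$circ_mean_phase_deg)]
    if (length(ph) == 0) next
    write_phase_histogram(
      phase_histogram(ph),
      file.path(dir, sprintf("phase_hist_%s.tsv", pair)))
  }
  manifest <- list(
    package = "dyadsync",
    package_version = as.character(utils::packageVersion("dyadsync")),
    r_version = R.version.string,
    seed = results$config$seed,
    n_sessions = length(results$config$sessions),
    parameters = results$config[c("min_period", "max_period",
                                  "voices_per_octave", "omega0",
                                  "smoothing_decades", "use_coi",
                                  "n_shuffle", "segment_s", "n_perm",
                                  "alpha")],
    bands = as.data.frame(results$config$bands),
    roster = roster,
    log = results$log)
  mp <- file.path(dir, "manifest.json")
  jsonlite::write_json(manifest, mp, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows")
  invisible(mp)
}
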