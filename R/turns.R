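# Conversational structure: speech units, pauses, gaps, turns, overlaps and
# turn switches from speaking-time annotation tiers.
#
# Conventions (documented because the boundary cases matter):
# * silences strictly shorter than `min_silence` between consecutive
#   same-speaker intervals are merged into one speech unit; a silence of
#   exactly `min_silence` separates.
# * a unit onset by the other speaker -- whether it overlaps the current
#   speaker or starts a contained backchannel -- terminates turn accretion,
#   so a backchannel splits the surrounding turn.
# * an overlap's onset is the later-starting unit's onset; simultaneous
#   onsets are broken by speaker label order and flagged.

#' Merge annotated speech intervals into speech units
#'
#' Per speaker, consecutive intervals separated by silence strictly shorter
#' than `min_silence` are merged (transitively) into speech units.
#'
#' @param intervals a [speech_intervals()] data.frame.
#' @param min_silence merge threshold in seconds (default 0.2).
#' @return data.frame of class `speech_units` with columns `speaker`,
#'   `start`, `end` and list-column `source_intervals` (row indices of the
#'   merged input intervals), sorted by start.
#' @export
merge_speech_units <- function(intervals, min_silence = 0.2) {
  if (!inherits(intervals, "speech_intervals"))
    intervals <- speech_intervals(intervals)
  if (min_silence <= 0) stop("`min_silence` must be positive", call. = FALSE)
  out <- list()
  for (sp in unique(intervals$speaker)) {
    rows <- which(intervals$speaker == sp)
    iv <- intervals[rows, , drop = FALSE]
    ov <- which(iv$start[-1] < iv$end[-nrow(iv)])
    if (length(ov) > 0)
      stop(sprintf(
        "speaker '%s' has overlapping annotation intervals near t=%.3f s",
        sp, iv$start[ov[1] + 1]), call. = FALSE)
    cur_start <- iv$start[1]; cur_end <- iv$end[1]; cur_src <- rows[1]
    for (k in seq_len(nrow(iv))[-1]) {
      if (iv$start[k] - cur_end < min_silence - 1e-9) {
        cur_end <- iv$end[k]
        cur_src <- c(cur_src, rows[k])
      } else {
        out[[length(out) + 1]] <- list(speaker = sp, start = cur_start,
                                       end = cur_end, src = cur_src)
        cur_start <- iv$start[k]; cur_end <- iv$end[k]; cur_src <- rows[k]
      }
    }
    out[[length(out) + 1]] <- list(speaker = sp, start = cur_start,
                                   end = cur_end, src = cur_src)
  }
  units <- data.frame(
    speaker = vapply(out, `[[`, character(1), "speaker"),
    start = vapply(out, `[[`, numeric(1), "start"),
    end = vapply(out, `[[`, numeric(1), "end"))
  units$source_intervals <- I(lapply(out, `[[`, "src"))
  ord <- order(units$start, units$speaker)
  units <- units[ord, , drop = FALSE]
  rownames(units) <- NULL
  class(units) <- c("speech_units", "data.frame")
  units
}

#' Classify between-unit silences as pauses or gaps
#'
#' A maximal interval during which neither speaker produces any speech, of
#' duration at least `min_silence`, is a pause if the flanking units belong
#' to the same speaker and a gap otherwise.
#'
#' @param units a `speech_units` data.frame (all speakers, merged).
#' @param min_silence classification threshold in seconds (default 0.2).
#' @return data.frame with columns `kind` ("pause"/"gap"), `start`, `end`,
#'   `before_speaker`, `after_speaker`.
#' @export
classify_silences <- function(units, min_silence = 0.2) {
  empty <- data.frame(kind = character(0), start = numeric(0),
                      end = numeric(0), before_speaker = character(0),
                      after_speaker = character(0))
  if (nrow(units) < 2L) return(empty)
  u <- units[order(units$start), , drop = FALSE]
  cov_end <- cummax(u$end)
  res <- list()
  for (k in seq_len(nrow(u) - 1L)) {
    s0 <- cov_end[k]; s1 <- u$start[k + 1L]
    if (s1 - s0 >= min_silence - 1e-9) {
      enders <- which(u$end[1:k] == s0)
      before <- u$speaker[enders[which.max(u$start[enders])]]
      starters <- which(u$start == s1)
      after <- sort(u$speaker[starters])[1]
      res[[length(res) + 1]] <- data.frame(
        kind = if (identical(before, after)) "pause" else "gap",
        start = s0, end = s1, before_speaker = before,
        after_speaker = after)
    }
  }
  if (length(res) == 0) empty else do.call(rbind, res)
}

#' Group speech units into turns
#'
#' A turn is a maximal run of consecutive same-speaker units in unit-onset
#' order: accretion of a speaker's units continues across pauses and stops
#' at the first unit onset by the other speaker.
#'
#' @param units a `speech_units` data.frame.
#' @return data.frame with columns `speaker`, `start`, `end` and
#'   list-column `unit_indices` (row indices into the onset-sorted units).
#' @export
build_turns <- function(units) {
  if (nrow(units) == 0L)
    return(data.frame(speaker = character(0), start = numeric(0),
                      end = numeric(0)))
  u <- units[order(units$start, units$speaker), , drop = FALSE]
  run <- cumsum(c(TRUE, u$speaker[-1] != u$speaker[-nrow(u)]))
  idx <- split(seq_len(nrow(u)), run)
  turns <- data.frame(
    speaker = vapply(idx, function(ii) u$speaker[ii[1]], character(1)),
    start = vapply(idx, function(ii) u$start[ii[1]], numeric(1)),
    end = vapply(idx, function(ii) max(u$end[ii]), numeric(1)))
  turns$unit_indices <- I(unname(idx))
  rownames(turns) <- NULL
  turns
}

#' Detect overlaps and turn switches
#'
#' Overlaps are the non-empty pairwise intersections of the two speakers'
#' units (backchannels and interruptions are not distinguished). Turn
#' switches are the union of overlap onsets and onsets of turns that follow
#' a turn by the other speaker; a time that is both counts once, as an
#' overlap onset.
#'
#' @param units a `speech_units` data.frame (exactly 2 speakers expected
#'   for overlaps; more are allowed but overlaps are computed pairwise
#'   between the first two by label order).
#' @param turns output of [build_turns()].
#' @return list with `overlaps` (data.frame `start`, `end`,
#'   `incoming_speaker`, `tie` flag) and `switches` (data.frame `kind`,
#'   `time`, `incoming_speaker`).
#' @export
detect_overlaps_and_switches <- function(units, turns) {
  speakers <- sort(unique(units$speaker))
  ov <- data.frame(start = numeric(0), end = numeric(0),
                   incoming_speaker = character(0), tie = logical(0))
  if (length(speakers) >= 2L) {
    a <- units[units$speaker == speakers[1], , drop = FALSE]
    b <- units[units$speaker == speakers[2], , drop = FALSE]
    for (i in seq_len(nrow(a))) {
      js <- which(b$start < a$end[i] & b$end > a$start[i])
      for (j in js) {
        s <- max(a$start[i], b$start[j])
        e <- min(a$end[i], b$end[j])
        tie <- a$start[i] == b$start[j]
        incoming <- if (tie) speakers[1] else
          if (a$start[i] > b$start[j]) speakers[1] else speakers[2]
        ov <- rbind(ov, data.frame(start = s, end = e,
                                   incoming_speaker = incoming, tie = tie))
      }
    }
    ov <- ov[order(ov$start), , drop = FALSE]
    rownames(ov) <- NULL
  }
  sw <- data.frame(kind = character(0), time = numeric(0),
                   incoming_speaker = character(0))
  if (nrow(turns) >= 2L) {
    chg <- which(turns$speaker[-1] != turns$speaker[-nrow(turns)]) + 1L
    sw <- data.frame(kind = "turn_onset", time = turns$start[chg],
                     incoming_speaker = turns$speaker[chg])
  }
  if (nrow(ov) > 0) {
    extra <- !(ov$start %in% sw$time)
    sw$kind[sw$time %in% ov$start] <- "overlap_onset"
    if (any(extra))
      sw <- rbind(sw, data.frame(kind = "overlap_onset",
                                 time = ov$start[extra],
                                 incoming_speaker = ov$incoming_speaker[extra]))
  }
  sw <- sw[order(sw$time), , drop = FALSE]
  rownames(sw) <- NULL
  list(overlaps = ov, switches = sw)
}

#' Full conversational structure of a dyadic session
#'
#' Runs the whole segmentation chain on annotated speech intervals: merge
#' into speech units, classify silences, build turns, detect overlaps and
#' turn switches.
#'
#' @param intervals a [speech_intervals()] data.frame (or coercible).
#' @param min_silence merge/classification threshold in seconds
#'   (default 0.2).
#' @return a `conversation_structure`: list with `units`, `silences`,
#'   `turns`, `overlaps`, `switches`, `min_silence`.
#' @export
conversation_structure <- function(intervals, min_silence = 0.2) {
  units <- merge_speech_units(intervals, min_silence)
  silences <- classify_silences(units, min_silence)
  turns <- build_turns(units)
  os <- detect_overlaps_and_switches(units, turns)
  structure(list(units = units, silences = silences, turns = turns,
                 overlaps = os$overlaps, switches = os$switches,
                 min_silence = min_silence),
            class = "conversation_structure")
}

#' @export
print.conversation_structure <- function(x, ...) {
  cat(sprintf(paste0("<conversation_structure> %d units, %d turns, ",
                     "%d overlaps, %d switches, %d silences\n"),
              nrow(x$units), nrow(x$turns), nrow(x$overlaps),
              nrow(x$switches), nrow(x$silences)))
  invisible(x)
}

#' Summary statistics of the turn-taking structure
#'
#' Turn-duration histogram over the conventional bins (0,10], (10,20],
#' (20,30] and >30 s, the share of turn switches that are overlap onsets,
#' plus counts and mean/median turn duration. With zero turns the
#' proportions are reported as missing (`NA`), not 0.
#'
#' @param structure a [conversation_structure()].
#' @return list with `n_turns`, `n_switches`, `n_overlaps`,
#'   `duration_bins` (named proportions), `overlap_switch_share`,
#'   `mean_turn_s`, `median_turn_s`, `empty` flag.
#' @export
turn_statistics <- function(structure) {
  stopifnot(inherits(structure, "conversation_structure"))
  turns <- structure$turns
  n_turns <- nrow(turns)
  bins <- c("(0,10]" = NA_real_, "(10,20]" = NA_real_,
            "(20,30]" = NA_real_, ">30" = NA_real_)
  if (n_turns == 0L) {
    return(list(n_turns = 0L, n_switches = nrow(structure$switches),
                n_overlaps = nrow(structure$overlaps),
                duration_bins = bins, overlap_switch_share = NA_real_,
                mean_turn_s = NA_real_, median_turn_s = NA_real_,
                empty = TRUE))
  }
  d <- turns$end - turns$start
  bins[] <- c(mean(d <= 10), mean(d > 10 & d <= 20),
              mean(d > 20 & d <= 30), mean(d > 30))
  nsw <- nrow(structure$switches)
  share <- if (nsw == 0L) NA_real_ else
    mean(structure$switches$kind == "overlap_onset")
  list(n_turns = n_turns, n_switches = nsw,
       n_overlaps = nrow(structure$overlaps),
       duration_bins = bins, overlap_switch_share = share,
       mean_turn_s = mean(d), median_turn_s = stats::median(d),
       empty = FALSE)
}

#' Serialize a conversation structure to JSON
#'
#' Times are written in seconds with 3 decimals.
#'
#' @param structure a [conversation_structure()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_structure_json <- function(structure, path) {
  stopifnot(inherits(structure, "conversation_structure"))
  r3 <- function(x) round(x, 3)
  obj <- list(
    min_silence = structure$min_silence,
    units = data.frame(speaker = structure$units$speaker,
                       start = r3(structure$units$start),
                       end = r3(structure$units$end)),
    silences = within(as.data.frame(structure$silences), {
      start <- r3(start); end <- r3(end)
    }),
    turns = data.frame(speaker = structure$turns$speaker,
                       start = r3(structure$turns$start),
                       end = r3(structure$turns$end)),
    overlaps = within(as.data.frame(structure$overlaps), {
      start <- r3(start); end <- r3(end)
    }),
    switches = within(as.data.frame(structure$switches), {
      time <- r3(time)
    })
  )
  jsonlite::write_json(obj, path, dataframe = "rows", auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}
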