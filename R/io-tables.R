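# Tabular I/O: speaking-time annotation tiers and result tables. Tiers are
# a plain TSV dialect (`speaker<TAB>start<TAB>end`, seconds), diff-able and
# trivially writable by the synthetic generator; ELAN EAF import is out of
# scope.

#' Read speaking-time annotation tiers
#'
#' @param path TSV file with header `speaker`, `start`, `end`; times in
#'   seconds.
#' @return a `speech_intervals` data.frame with columns `speaker` (character),
#'   `start`, `end`, sorted by start within speaker.
#' @export
read_tiers <- function(path) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          colClasses = c("character", "numeric", "numeric"))
  if (!identical(names(df)[1:3], c("speaker", "start", "end")))
    stop("tier file must have columns speaker, start, end", call. = FALSE)
  speech_intervals(df)
}

#' Validate a table of speech intervals
#'
#' @param df data.frame with columns `speaker`, `start`, `end` (seconds).
#' @return the validated data.frame, sorted by start within speaker, with
#'   class `speech_intervals`.
#' @export
speech_intervals <- function(df) {
  df <- as.data.frame(df)[, c("speaker", "start", "end")]
  df$speaker <- as.character(df$speaker)
  bad <- which(!is.finite(df$start) | !is.finite(df$end) |
                 df$start < 0 | df$end <= df$start)
  if (length(bad) > 0)
    stop(sprintf("invalid interval at row %d: need 0 <= start < end",
                 bad[1]), call. = FALSE)
  df <- df[order(df$speaker, df$start), , drop = FALSE]
  rownames(df) <- NULL
  class(df) <- c("speech_intervals", "data.frame")
  df
}

#' Write speech intervals as a tier TSV
#' @param intervals a `speech_intervals` data.frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_tiers <- function(intervals, path) {
  utils::write.table(as.data.frame(intervals)[, c("speaker", "start", "end")],
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

band_table_cols <- c("pair", "level", "modality_class", "band_lo_s",
                     "band_hi_s", "mean_coherence", "circ_mean_phase_deg",
                     "resultant_length", "n_valid_bins")

#' Write per-band synchrony summaries as TSV
#'
#' One row per (pair, band) with the band edges, mean coherence, circular
#' mean phase, resultant length and the number of valid (out-of-COI) bins.
#' Numeric columns round-trip losslessly at 6 significant digits.
#'
#' @param summaries a data.frame with the band-summary columns (see
#'   [band_average()]), or a list of such data.frames.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_band_table <- function(summaries, path) {
  if (is.data.frame(summaries)) summaries <- list(summaries)
  df <- if (length(summaries) == 0) {
    stats::setNames(as.data.frame(matrix(nrow = 0, ncol =
      length(band_table_cols))), band_table_cols)
  } else do.call(rbind, lapply(summaries, function(s) {
    miss <- setdiff(band_table_cols, names(s))
    if (length(miss) > 0)
      stop(sprintf("band summary lacks column '%s'", miss[1]), call. = FALSE)
    as.data.frame(s)[, band_table_cols]
  }))
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], signif, digits = 6)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a band-summary TSV written by [write_band_table()]
#' @param path input path.
#' @return a data.frame with the band-summary columns.
#' @export
read_band_table <- function(path) {
  utils::read.delim(path, header = TRUE, sep = "\t",
                    colClasses = c("character", "character", "character",
                                   rep("numeric", 6)))
}
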