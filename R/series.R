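#' Uniformly sampled scalar signal
#'
#' The common currency of the pipeline: a numeric vector sampled at a fixed
#' rate, with a start time and a modality label. Envelope and speed series
#' are constrained to be non-negative.
#'
#' @param values numeric vector of samples; must be finite.
#' @param rate sampling rate in Hz (> 0).
#' @param start time of the first sample in seconds.
#' @param label modality label, one of `"head_speed"`, `"wrist_speed"`,
#'   `"voice_env"`, `"raw_audio"`, or any other descriptive string.
#' @return An object of class `uniform_series`: a list with elements
#'   `values`, `rate`, `start`, `label`.
#' @examples
#' s <- uniform_series(sin(seq(0, 2 * pi, length.out = 90)), rate = 90)
#' duration(s)
#' @export
uniform_series <- function(values, rate, start = 0, label = "signal") {
  values <- as.numeric(values)
  if (!is.numeric(rate) || length(rate) != 1L || !is.finite(rate) || rate <= 0)
    stop("`rate` must be a single positive number", call. = FALSE)
  if (anyNA(values) || any(!is.finite(values)))
    stop("`values` must be finite and non-missing", call. = FALSE)
  if (label %in% c("head_speed", "wrist_speed", "voice_env") &&
      any(values < 0))
    stop(sprintf("series labelled '%s' must be non-negative", label),
         call. = FALSE)
  structure(
    list(values = values, rate = as.numeric(rate),
         start = as.numeric(start), label = as.character(label)),
    class = "uniform_series"
  )
}

#' @export
length.uniform_series <- function(x) length(x$values)

#' Duration of a uniform series in seconds
#' @param s a [uniform_series()].
#' @return length(s) / rate, in seconds.
#' @export
duration <- function(s) {
  stopifnot(inherits(s, "uniform_series"))
  length(s$values) / s$rate
}

#' Sample times of a uniform series
#' @param s a [uniform_series()].
#' @return numeric vector of sample times in seconds.
#' @export
sample_times <- function(s) {
  stopifnot(inherits(s, "uniform_series"))
  s$start + (seq_along(s$values) - 1) / s$rate
}

#' @export
print.uniform_series <- function(x, ...) {
  cat(sprintf("<uniform_series '%s'> %d samples @ %g Hz (%.3f s from t=%g)\n",
              x$label, length(x$values), x$rate,
              length(x$values) / x$rate, x$start))
  invisible(x)
}

#' Paired three-modality recording for one dyadic session
#'
#' Bundles the six analysis series of one session -- head speed, summed
#' wrist speed and voice amplitude envelope for participants A and B --
#' sharing a common rate and sample count.
#'
#' @param session id string for the session.
#' @param A,B named lists with elements `head_speed`, `wrist_speed`,
#'   `voice_env`, each a [uniform_series()].
#' @return An object of class `dyad_recording`.
#' @export
dyad_recording <- function(session, A, B) {
  need <- c("head_speed", "wrist_speed", "voice_env")
  for (p in list(A = A, B = B)) {
    if (!all(need %in% names(p)))
      stop("each participant needs head_speed, wrist_speed, voice_env",
           call. = FALSE)
  }
  all6 <- c(A[need], B[need])
  rates <- vapply(all6, function(s) s$rate, numeric(1))
  lens <- vapply(all6, function(s) length(s$values), integer(1))
  if (length(unique(rates)) != 1L)
    stop("all six series must share one rate", call. = FALSE)
  if (length(unique(lens)) != 1L)
    stop("all six series must share one length", call. = FALSE)
  for (nm in need) {
    if (A[[nm]]$label != nm || B[[nm]]$label != nm)
      stop(sprintf("series '%s' carries label '%s'", nm, A[[nm]]$label),
           call. = FALSE)
  }
  structure(
    list(session = as.character(session), A = A[need], B = B[need],
         rate = rates[[1]], n = lens[[1]]),
    class = "dyad_recording"
  )
}

#' @export
print.dyad_recording <- function(x, ...) {
  cat(sprintf("<dyad_recording '%s'> 2 x 3 series, %d samples @ %g Hz (%.1f s)\n",
              x$session, x$n, x$rate, x$n / x$rate))
  invisible(x)
}

#' Fetch one modality series from a dyad recording
#'
#' @param rec a [dyad_recording()].
#' @param participant `"A"` or `"B"`.
#' @param modality `"head"`, `"wrist"` or `"voice"`.
#' @return the corresponding [uniform_series()].
#' @export
get_series <- function(rec, participant, modality) {
  stopifnot(inherits(rec, "dyad_recording"))
  participant <- match.arg(participant, c("A", "B"))
  modality <- match.arg(modality, c("head", "wrist", "voice"))
  slot <- switch(modality, head = "head_speed", wrist = "wrist_speed",
                 voice = "voice_env")
  rec[[participant]][[slot]]
}
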