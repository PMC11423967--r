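# Signal preparation: filtering, differentiation, envelope extraction and
# resampling that turn raw positions and audio into the three analysis
# series per participant on a common clock.

# Digital Butterworth lowpass coefficients via the bilinear transform.
# Returns list(b, a) with a[1] = 1. Textbook design; no filter-design
# package is available in the target environment.
butter_lowpass_coef <- function(order, cutoff, rate) {
  if (order < 1L) stop("`order` must be >= 1", call. = FALSE)
  if (cutoff <= 0 || cutoff >= rate / 2)
    stop("`cutoff` must lie strictly between 0 and rate/2 (Nyquist)",
         call. = FALSE)
  fs2 <- 2 * rate
  wc <- fs2 * tan(pi * cutoff / rate)        # prewarped analog cutoff
  k <- seq_len(order)
  p <- wc * exp(1i * pi * (2 * k + order - 1) / (2 * order))  # analog poles
  pd <- (fs2 + p) / (fs2 - p)                # bilinear-mapped poles
  gain <- Re(wc^order / prod(fs2 - p))
  poly_from_roots <- function(r) {
    coefs <- 1
    for (ri in r) coefs <- c(coefs, 0) - c(0, coefs * ri)
    coefs
  }
  a <- Re(poly_from_roots(pd))
  b <- gain * Re(poly_from_roots(rep(-1, order)))  # order zeros at z = -1
  list(b = b, a = a)
}

# Causal IIR filtering, direct form, using the C-level recursions in
# stats::filter (FIR pass then AR pass). Zero initial conditions.
iir_filter <- function(x, b, a) {
  nb <- length(b)
  xp <- c(rep(0, nb - 1), x)
  v <- stats::filter(xp, b, method = "convolution", sides = 1)
  v <- as.numeric(v)[nb:length(xp)]
  if (length(a) > 1L)
    v <- as.numeric(stats::filter(v, -a[-1], method = "recursive"))
  v
}

# Forward-backward (zero-phase) filtering with odd-reflection padding to
# suppress edge transients, as in the conventional filtfilt.
filtfilt_zerophase <- function(x, b, a) {
  n <- length(x)
  padlen <- min(n - 1L, 3L * (max(length(a), length(b)) - 1L) * 4L)
  if (padlen > 0) {
    pre <- 2 * x[1] - x[seq(padlen + 1, 2)]
    post <- 2 * x[n] - x[seq(n - 1, n - padlen)]
    xp <- c(pre, x, post)
  } else xp <- x
  # offsetting by the first sample makes the start-up transient vanish for
  # constant inputs (DC gain of the design is 1)
  dc <- sum(b) / sum(a)
  run <- function(v) {
    v0 <- v[1]
    iir_filter(v - v0, b, a) + v0 * dc
  }
  y <- run(xp)
  y <- rev(run(rev(y)))
  if (padlen > 0) y <- y[(padlen + 1):(padlen + n)]
  y
}

#' Zero-phase Butterworth lowpass filter
#'
#' Applies a Butterworth lowpass of the given order forward and backward
#' (zero phase), so that filtering introduces no lag -- essential when the
#' filtered series feed a phase analysis. The effective magnitude response
#' is the squared one-pass response.
#'
#' @param s a [uniform_series()].
#' @param cutoff cutoff frequency in Hz, strictly below Nyquist.
#' @param order filter order (>= 1); default 2.
#' @return a filtered [uniform_series()] with the same rate and length.
#' @export
butterworth_lowpass <- function(s, cutoff, order = 2L) {
  stopifnot(inherits(s, "uniform_series"))
  coef <- butter_lowpass_coef(order, cutoff, s$rate)
  y <- filtfilt_zerophase(s$values, coef$b, coef$a)
  out <- s
  out$values <- y
  out
}

#' Scalar speed of a 3D marker trajectory
#'
#' Per-frame speed as the Euclidean norm of the time derivative of the 3D
#' position, computed by central differences (one-sided at the endpoints).
#'
#' @param traj a [marker_trajectory()] (at least 3 frames).
#' @param label label for the resulting series (default `"head_speed"`).
#' @return a non-negative [uniform_series()] at the trajectory's rate.
#' @export
speed <- function(traj, label = "head_speed") {
  stopifnot(inherits(traj, "marker_trajectory"))
  pos <- traj$positions
  n <- nrow(pos)
  if (n < 3L) stop("need at least 3 frames to differentiate", call. = FALSE)
  d <- matrix(0, n, 3)
  d[2:(n - 1), ] <- (pos[3:n, ] - pos[1:(n - 2), ]) * (traj$rate / 2)
  d[1, ] <- (pos[2, ] - pos[1, ]) * traj$rate
  d[n, ] <- (pos[n, ] - pos[n - 1, ]) * traj$rate
  uniform_series(sqrt(rowSums(d^2)), rate = traj$rate, label = label)
}

#' Sum of left and right wrist speed series
#'
#' @param left,right [uniform_series()] of equal rate and length.
#' @return their elementwise sum, labelled `"wrist_speed"`.
#' @export
sum_wrist_speeds <- function(left, right) {
  stopifnot(inherits(left, "uniform_series"), inherits(right, "uniform_series"))
  if (left$rate != right$rate)
    stop("wrist series rates differ", call. = FALSE)
  if (length(left$values) != length(right$values))
    stop("wrist series lengths differ", call. = FALSE)
  uniform_series(left$values + right$values, rate = left$rate,
                 start = left$start, label = "wrist_speed")
}

# Analytic signal via the frequency-domain Hilbert transform.
analytic_signal <- function(x) {
  n <- length(x)
  X <- stats::fft(x)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[1] <- 1; h[n / 2 + 1] <- 1; h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1; h[2:((n + 1) / 2)] <- 2
  }
  stats::fft(X * h, inverse = TRUE) / n
}

#' Speech amplitude envelope
#'
#' Magnitude of the analytic signal (Hilbert transform) of the audio,
#' smoothed with a zero-phase second-order Butterworth lowpass, then
#' resampled to the common analysis rate. Tiny negative ringing introduced
#' by the smoothing is clipped to zero.
#'
#' @param audio a [uniform_series()] of raw audio samples.
#' @param smooth_cutoff lowpass cutoff in Hz for envelope smoothing
#'   (default 12 Hz: preserves syllabic ~5 Hz structure, removes the
#'   carrier).
#' @param target_rate output rate in Hz (default 90, the common clock).
#' @return a non-negative [uniform_series()] labelled `"voice_env"`.
#' @export
amplitude_envelope <- function(audio, smooth_cutoff = 12, target_rate = 90) {
  stopifnot(inherits(audio, "uniform_series"))
  if (audio$rate <= 2 * smooth_cutoff)
    stop("audio rate must exceed twice the smoothing cutoff", call. = FALSE)
  if (target_rate > audio$rate)
    stop("`target_rate` must not exceed the audio rate", call. = FALSE)
  env <- Mod(analytic_signal(audio$values))
  coef <- butter_lowpass_coef(2L, smooth_cutoff, audio$rate)
  env <- filtfilt_zerophase(env, coef$b, coef$a)
  s <- uniform_series(pmax(env, 0), rate = audio$rate, start = audio$start,
                      label = "voice_env")
  resample(s, target_rate)
}

#' Resample a uniform series to a new rate
#'
#' Downsampling first applies an anti-alias lowpass at `0.45 * target_rate`
#' (zero-phase Butterworth, order 8), then interpolates linearly on the new
#' time grid.
#' Duration is preserved to within one sample period. An identical target
#' rate returns the input unchanged.
#'
#' @param s a [uniform_series()].
#' @param target_rate new rate in Hz (> 0).
#' @return a [uniform_series()] at `target_rate`.
#' @export
resample <- function(s, target_rate) {
  stopifnot(inherits(s, "uniform_series"))
  if (target_rate <= 0) stop("`target_rate` must be positive", call. = FALSE)
  if (target_rate == s$rate) return(s)
  x <- s$values
  if (target_rate < s$rate) {
    coef <- butter_lowpass_coef(8L, 0.45 * target_rate, s$rate)
    x <- filtfilt_zerophase(x, coef$b, coef$a)
  }
  n_out <- max(2L, as.integer(round(length(x) * target_rate / s$rate)))
  t_old <- (seq_along(x) - 1) / s$rate
  t_new <- (seq_len(n_out) - 1) / target_rate
  y <- stats::approx(t_old, x, xout = pmin(t_new, t_old[length(t_old)]),
                     rule = 2)$y
  if (s$label %in% c("voice_env", "head_speed", "wrist_speed"))
    y <- pmax(y, 0)
  uniform_series(y, rate = target_rate, start = s$start, label = s$label)
}

#' Assemble the six analysis series of one session
#'
#' Applies the canonical chain -- position lowpass then differentiation for
#' movement, Hilbert envelope for audio -- and trims all six series to the
#' common overlapping window so they share the analysis rate and length.
#'
#' @param session session id string.
#' @param A,B per-participant named lists with elements `head`,
#'   `wrist_left`, `wrist_right` (each a [marker_trajectory()]) and `audio`
#'   (a [uniform_series()]).
#' @param filter_cutoff_hz position lowpass cutoff (default 10 Hz).
#' @param filter_order position lowpass order (default 2, zero-phase).
#' @param envelope_smooth_cutoff_hz envelope smoothing cutoff (default 12).
#' @param common_rate_hz common clock for all six series (default 90).
#' @return a [dyad_recording()].
#' @export
build_dyad_recording <- function(session, A, B,
                                 filter_cutoff_hz = 10,
                                 filter_order = 2L,
                                 envelope_smooth_cutoff_hz = 12,
                                 common_rate_hz = 90) {
  prep_one <- function(p) {
    stopifnot(all(c("head", "wrist_left", "wrist_right", "audio") %in%
                    names(p)))
    filt_traj <- function(traj) {
      pos <- traj$positions
      coef <- butter_lowpass_coef(filter_order, filter_cutoff_hz, traj$rate)
      for (j in 1:3) pos[, j] <- filtfilt_zerophase(pos[, j], coef$b, coef$a)
      marker_trajectory(traj$joint, pos, traj$rate)
    }
    head_sp <- resample(speed(filt_traj(p$head), "head_speed"), common_rate_hz)
    wl <- resample(speed(filt_traj(p$wrist_left), "head_speed"), common_rate_hz)
    wr <- resample(speed(filt_traj(p$wrist_right), "head_speed"), common_rate_hz)
    n <- min(length(wl$values), length(wr$values))
    wrist_sp <- sum_wrist_speeds(
      uniform_series(wl$values[seq_len(n)], common_rate_hz, label = "head_speed"),
      uniform_series(wr$values[seq_len(n)], common_rate_hz, label = "head_speed"))
    env <- amplitude_envelope(p$audio, envelope_smooth_cutoff_hz, common_rate_hz)
    list(head_speed = head_sp, wrist_speed = wrist_sp, voice_env = env)
  }
  pa <- prep_one(A)
  pb <- prep_one(B)
  n <- min(vapply(c(pa, pb), function(s) length(s$values), integer(1)))
  if (n < 2L) stop("no common overlapping window across series", call. = FALSE)
  trim <- function(s, lab) uniform_series(s$values[seq_len(n)],
                                          common_rate_hz, label = lab)
  dyad_recording(
    session,
    A = list(head_speed = trim(pa$head_speed, "head_speed"),
             wrist_speed = trim(pa$wrist_speed, "wrist_speed"),
             voice_env = trim(pa$voice_env, "voice_env")),
    B = list(head_speed = trim(pb$head_speed, "head_speed"),
             wrist_speed = trim(pb$wrist_speed, "wrist_speed"),
             voice_env = trim(pb$voice_env, "voice_env"))
  )
}
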