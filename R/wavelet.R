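# Morlet continuous wavelet transform, cross-wavelet coherence and relative
# phase, and aggregation over conversational timescale bands.
#
# Numerical conventions: the analytic Morlet mother wavelet with center
# frequency omega0 (default 6, Fourier period ~ 1.033 x scale); transforms
# computed by FFT with the series mean removed and zero-padding to a power
# of two; cone of influence from the e-folding time sqrt(2) * scale;
# coherence smoothing with a scale-matched Gaussian in time and a boxcar
# across a fixed span of log-scale, after which coherence of independent
# signals falls to a chance floor well below 1 (unsmoothed wavelet
# coherence is identically 1 and carries no information).

#' Geometric grid of wavelet timescales
#'
#' @param min_period smallest period in seconds (default 0.125).
#' @param max_period largest period in seconds (default 32).
#' @param voices_per_octave scale resolution (default 16: at least two
#'   scale bins inside the narrowest conversational band, 0.25-0.375 s).
#' @return a `scale_grid`: list with `periods` (strictly increasing,
#'   geometric) and `voices_per_octave`.
#' @export
scale_grid <- function(min_period = 0.125, max_period = 32,
                       voices_per_octave = 16L) {
  if (min_period <= 0 || max_period <= min_period)
    stop("need 0 < min_period < max_period", call. = FALSE)
  n_oct <- log2(max_period / min_period)
  k <- 0:floor(n_oct * voices_per_octave + 1e-9)
  structure(list(periods = min_period * 2^(k / voices_per_octave),
                 voices_per_octave = as.integer(voices_per_octave)),
            class = "scale_grid")
}

morlet_fourier_factor <- function(omega0) {
  4 * pi / (omega0 + sqrt(2 + omega0^2))
}

next_pow2 <- function(n) 2^ceiling(log2(n))

# memo cache for frequency-domain kernel matrices, which depend only on
# (padded length, rate, scales, omega0) and are rebuilt many times in
# surrogate loops
.kernel_cache <- new.env(parent = emptyenv())

cached_kernel <- function(tag, m, rate, scales, extra, build) {
  key <- paste(tag, m, rate, length(scales), scales[1],
               scales[length(scales)], extra, sep = "|")
  val <- .kernel_cache[[key]]
  if (is.null(val)) {
    if (length(ls(.kernel_cache)) > 32) rm(list = ls(.kernel_cache),
                                           envir = .kernel_cache)
    val <- build()
    .kernel_cache[[key]] <- val
  }
  val
}

fft_omega <- function(m, rate) {
  2 * pi * rate * c(0:(m %/% 2), -((m - m %/% 2 - 1):1)) / m
}

#' Morlet continuous wavelet transform
#'
#' @param s a [uniform_series()]; must be at least twice as long as the
#'   largest requested period.
#' @param grid a [scale_grid()].
#' @param omega0 Morlet center frequency (>= 5 for the admissibility
#'   approximation; default 6).
#' @return a `wavelet_spectrum`: list with `coeffs` (time x period complex
#'   matrix), `periods`, `scales`, `rate`, `coi` (per-time maximum
#'   trustworthy period, s), `omega0`, `n`.
#' @export
cwt_morlet <- function(s, grid, omega0 = 6) {
  stopifnot(inherits(s, "uniform_series"), inherits(grid, "scale_grid"))
  if (omega0 < 5) stop("`omega0` must be >= 5", call. = FALSE)
  n <- length(s$values)
  dt <- 1 / s$rate
  dur <- n * dt
  ff <- morlet_fourier_factor(omega0)
  too_long <- grid$periods[2 * grid$periods > dur]
  if (length(too_long) > 0)
    stop(sprintf(
      "series of %.2f s is too short for the %.3f s period (needs >= %.2f s)",
      dur, too_long[1], 2 * too_long[1]), call. = FALSE)
  if (min(grid$periods) < 2 * dt)
    stop("smallest period is below two sample intervals", call. = FALSE)
  x <- s$values - mean(s$values)
  m <- next_pow2(n)
  if (m == n) m <- 2L * n
  xf <- stats::fft(c(x, numeric(m - n)))
  scales <- grid$periods / ff
  # analytic Morlet: support on positive frequencies only
  h <- cached_kernel("morlet", m, s$rate, scales, omega0, function() {
    omega <- fft_omega(m, s$rate)
    vapply(scales, function(sc) {
      psi <- numeric(m)
      pos <- omega > 0
      psi[pos] <- sqrt(2 * pi * sc * s$rate) * pi^(-0.25) *
        exp(-0.5 * (sc * omega[pos] - omega0)^2)
      psi
    }, numeric(m))
  })
  w <- stats::mvfft(xf * h, inverse = TRUE)[seq_len(n), , drop = FALSE] / m
  edge <- pmin(seq_len(n) - 1L, n - seq_len(n)) * dt
  structure(list(coeffs = w, periods = grid$periods, scales = scales,
                 rate = s$rate, coi = ff * edge / sqrt(2),
                 omega0 = omega0, n = n),
            class = "wavelet_spectrum")
}

check_same_grid <- function(a, b) {
  if (a$n != b$n || a$rate != b$rate ||
      length(a$periods) != length(b$periods) ||
      max(abs(a$periods - b$periods)) > 1e-9 * max(a$periods))
    stop("wavelet spectra must share grid, rate and length", call. = FALSE)
}

#' Cross-wavelet spectrum
#'
#' Elementwise `Wa * Conj(Wb)`. The combined cone of influence is the
#' bin-wise minimum of the two inputs'.
#'
#' @param a,b `wavelet_spectrum` objects on identical grids.
#' @return a `cross_spectrum`: list with `cross` (complex matrix),
#'   `periods`, `rate`, `coi`.
#' @export
cross_wavelet <- function(a, b) {
  stopifnot(inherits(a, "wavelet_spectrum"), inherits(b, "wavelet_spectrum"))
  check_same_grid(a, b)
  structure(list(cross = a$coeffs * Conj(b$coeffs), periods = a$periods,
                 scales = a$scales, rate = a$rate,
                 coi = pmin(a$coi, b$coi), n = a$n),
            class = "cross_spectrum")
}

# Smoothing operator S: Gaussian in time with sd equal to the wavelet scale
# (applied per scale, via FFT with zero padding), then a boxcar across
# `smoothing_decades` of log10-scale.
smooth_field <- function(z, scales, rate, voices_per_octave,
                         smoothing_decades = 0.6) {
  n <- nrow(z); ns <- ncol(z)
  pad <- ceiling(6 * max(scales) * rate)
  m <- next_pow2(n + pad)
  zp <- rbind(z, matrix(0, m - n, ns))
  gauss <- cached_kernel("gauss", m, rate, scales, "", function() {
    omega <- fft_omega(m, rate)
    exp(-0.5 * outer(omega^2, scales^2))
  })
  zs <- stats::mvfft(stats::mvfft(zp) * gauss,
                     inverse = TRUE)[seq_len(n), , drop = FALSE] / m
  # boxcar across scales, renormalized at the edges
  dj_dec <- log10(2) / voices_per_octave
  half <- max(0L, round(smoothing_decades / dj_dec / 2))
  if (half == 0L || ns == 1L) return(zs)
  lo <- pmax(seq_len(ns) - half, 1L)
  hi <- pmin(seq_len(ns) + half, ns)
  # running mean along scales as a sparse-band matrix product
  box <- cached_kernel("box", half, ns, c(1, 1), "", function() {
    b <- matrix(0, ns, ns)
    for (j in seq_len(ns)) b[lo[j]:hi[j], j] <- 1 / (hi[j] - lo[j] + 1)
    b
  })
  zs %*% box
}

# Shared worker: smoothed auto- and cross-spectra for one signal pair.
xwt_smoothed <- function(a, b, smoothing_decades = 0.6) {
  check_same_grid(a, b)
  inv_s <- rep(1 / a$scales, each = a$n)
  vpo <- round(1 / log2(a$periods[2] / a$periods[1]))
  sa <- Re(smooth_field(Mod(a$coeffs)^2 * inv_s, a$scales, a$rate, vpo,
                        smoothing_decades))
  sb <- Re(smooth_field(Mod(b$coeffs)^2 * inv_s, b$scales, b$rate, vpo,
                        smoothing_decades))
  sab <- smooth_field(a$coeffs * Conj(b$coeffs) * inv_s, a$scales, a$rate,
                      vpo, smoothing_decades)
  list(sa = sa, sb = sb, sab = sab,
       periods = a$periods, rate = a$rate, coi = pmin(a$coi, b$coi),
       n = a$n)
}

sync_map <- function(values, periods, rate, coi, kind) {
  structure(list(values = values, periods = periods, rate = rate,
                 coi = coi, kind = kind),
            class = "sync_map")
}

#' @export
print.sync_map <- function(x, ...) {
  cat(sprintf("<sync_map '%s'> %d times x %d periods (%.3g-%.3g s)\n",
              x$kind, nrow(x$values), length(x$periods),
              min(x$periods), max(x$periods)))
  invisible(x)
}

#' Wavelet coherence map
#'
#' `|S(Wab/s)|^2 / (S(|Wa|^2/s) S(|Wb|^2/s))` with `S` the smoothing
#' operator described in [scale_grid()]'s module notes; values clipped to
#' `[0, 1]`. Coherence of a degenerate (all-zero after mean removal) input
#' is undefined and returned as `NA`.
#'
#' @param a,b `wavelet_spectrum` objects on identical grids.
#' @param smoothing_decades span of the boxcar scale smoothing in decades
#'   of timescale (default 0.6).
#' @return a `sync_map` with `values` in `[0, 1]` (or `NA`), `periods`,
#'   `rate`, `coi`.
#' @export
wavelet_coherence <- function(a, b, smoothing_decades = 0.6) {
  sm <- xwt_smoothed(a, b, smoothing_decades)
  coherence_from_smoothed(sm)
}

coherence_from_smoothed <- function(sm) {
  den <- sm$sa * sm$sb
  coh <- Mod(sm$sab)^2 / den
  coh[!is.finite(coh) | den <= 0] <- NA_real_
  coh[coh < 0] <- 0
  coh[coh > 1] <- 1
  sync_map(coh, sm$periods, sm$rate, sm$coi, "coherence")
}

#' Relative phase map
#'
#' Argument of the smoothed cross-wavelet spectrum, in degrees wrapped to
#' `[-180, 180)`. Sign convention: positive phase means the first-named
#' series leads (its features occur earlier in time) at that timescale.
#' Zero-cross-power bins are flagged missing.
#'
#' @inheritParams wavelet_coherence
#' @return a `sync_map` with `values` in degrees.
#' @export
relative_phase <- function(a, b, smoothing_decades = 0.6) {
  sm <- xwt_smoothed(a, b, smoothing_decades)
  phase_from_smoothed(sm)
}

phase_from_smoothed <- function(sm) {
  ph <- wrap_deg(Arg(sm$sab) * 180 / pi)
  ph[Mod(sm$sab) == 0] <- NA_real_
  sync_map(ph, sm$periods, sm$rate, sm$coi, "phase")
}

#' Coherence and phase maps in one pass
#'
#' Computes the smoothed spectra once and derives both maps; the pipeline's
#' workhorse.
#'
#' @inheritParams wavelet_coherence
#' @return list with elements `coherence` and `phase` (both `sync_map`s).
#' @export
xwt_maps <- function(a, b, smoothing_decades = 0.6) {
  sm <- xwt_smoothed(a, b, smoothing_decades)
  list(coherence = coherence_from_smoothed(sm),
       phase = phase_from_smoothed(sm))
}

#' The 23 conversational timescale bands
#'
#' The standard partition of conversational timescales from 0.125 s
#' (syllable scale) to 30 s (turn scale), half-open `(lo, hi]` so the
#' printed contiguous list is a partition.
#'
#' @return a `timescale_bands` data.frame with columns `lo_s`, `hi_s`.
#' @export
default_bands <- function() {
  lo <- c(0.125, 0.25, 0.375, 0.5, 1, 2, 3, 4, 5, 6, 7, 8, 9, 10, 12, 14,
          16, 18, 20, 22, 24, 26, 28)
  hi <- c(0.25, 0.375, 0.5, 1, 2, 3, 4, 5, 6, 7, 8, 9, 10, 12, 14, 16, 18,
          20, 22, 24, 26, 28, 30)
  timescale_bands(lo, hi)
}

#' Construct a set of timescale bands
#' @param lo_s,hi_s band edges in seconds; bands are `(lo, hi]`, must be
#'   non-overlapping and increasing.
#' @return a `timescale_bands` data.frame.
#' @export
timescale_bands <- function(lo_s, hi_s) {
  stopifnot(length(lo_s) == length(hi_s))
  if (any(hi_s <= lo_s)) stop("need lo < hi per band", call. = FALSE)
  if (is.unsorted(lo_s) || any(lo_s[-1] < hi_s[-length(hi_s)] - 1e-12))
    stop("bands must be increasing and non-overlapping", call. = FALSE)
  structure(data.frame(lo_s = lo_s, hi_s = hi_s),
            class = c("timescale_bands", "data.frame"))
}

#' Band-averaged coherence and circular-mean phase
#'
#' Per band `(lo, hi]`: the arithmetic mean of coherence over all
#' (time, period) bins whose wavelet period falls in the band and which lie
#' outside the cone of influence (period strictly below the per-time COI
#' limit), and the circular mean of the relative phase over the same bins
#' (resultant-vector method). Bands with zero valid bins are reported as
#' missing, not zero.
#'
#' @param coh coherence `sync_map`.
#' @param ph phase `sync_map` on the same grid.
#' @param bands a `timescale_bands` data.frame (default [default_bands()]).
#' @param use_coi exclude bins inside the cone of influence (default TRUE).
#' @return a `band_summary` data.frame with columns `band_lo_s`,
#'   `band_hi_s`, `mean_coherence`, `circ_mean_phase_deg`,
#'   `resultant_length`, `n_valid_bins`.
#' @export
band_average <- function(coh, ph, bands = default_bands(), use_coi = TRUE) {
  stopifnot(inherits(coh, "sync_map"), inherits(ph, "sync_map"))
  if (length(coh$periods) != length(ph$periods) ||
      max(abs(coh$periods - ph$periods)) > 1e-9)
    stop("maps must share the scale grid", call. = FALSE)
  n <- nrow(coh$values)
  valid_time <- if (use_coi) {
    outer(coh$coi, coh$periods, `>`)    # TRUE where period < coi(t)
  } else matrix(TRUE, n, length(coh$periods))
  res <- lapply(seq_len(nrow(bands)), function(k) {
    in_band <- coh$periods > bands$lo_s[k] & coh$periods <= bands$hi_s[k]
    if (!any(in_band)) {
      return(data.frame(band_lo_s = bands$lo_s[k], band_hi_s = bands$hi_s[k],
                        mean_coherence = NA_real_,
                        circ_mean_phase_deg = NA_real_,
                        resultant_length = NA_real_, n_valid_bins = 0L))
    }
    cvals <- coh$values[, in_band, drop = FALSE]
    pvals <- ph$values[, in_band, drop = FALSE]
    ok <- valid_time[, in_band, drop = FALSE] & !is.na(cvals) & !is.na(pvals)
    nb <- sum(ok)
    if (nb == 0L) {
      data.frame(band_lo_s = bands$lo_s[k], band_hi_s = bands$hi_s[k],
                 mean_coherence = NA_real_, circ_mean_phase_deg = NA_real_,
                 resultant_length = NA_real_, n_valid_bins = 0L)
    } else {
      cm <- circular_mean(pvals[ok])
      data.frame(band_lo_s = bands$lo_s[k], band_hi_s = bands$hi_s[k],
                 mean_coherence = mean(cvals[ok]),
                 circ_mean_phase_deg = cm$mean_deg,
                 resultant_length = cm$resultant_length,
                 n_valid_bins = nb)
    }
  })
  out <- do.call(rbind, res)
  class(out) <- c("band_summary", "data.frame")
  out
}
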