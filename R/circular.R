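#' Wrap angles into [-180, 180) degrees
#'
#' Angles reported on a 0-360 scale (e.g. 342 degrees) map to their signed
#' equivalent (-18 degrees). The boundary +180 maps to -180 so the range is
#' half-open.
#'
#' @param x numeric vector of angles in degrees (finite).
#' @return angles in `[-180, 180)`.
#' @examples
#' wrap_deg(342) # -18
#' wrap_deg(c(324, 540, -180))
#' @export
wrap_deg <- function(x) {
  if (any(!is.finite(x))) stop("angles must be finite", call. = FALSE)
  w <- x - 360 * round(x / 360)
  w[w >= 180] <- w[w >= 180] - 360
  w[w < -180] <- w[w < -180] + 360
  w
}

#' Weighted sample of angles
#'
#' @param angles numeric, degrees.
#' @param weights optional non-negative weights (same length, not all zero).
#'   Equal weighting is the default; coherence weighting of phase samples is
#'   possible but off by default.
#' @return an `angle_sample` object.
#' @export
angle_sample <- function(angles, weights = NULL) {
  angles <- as.numeric(angles)
  if (length(angles) == 0L) stop("empty angle sample", call. = FALSE)
  if (any(!is.finite(angles))) stop("angles must be finite", call. = FALSE)
  if (!is.null(weights)) {
    weights <- as.numeric(weights)
    if (length(weights) != length(angles))
      stop("weights must match angles in length", call. = FALSE)
    if (any(weights < 0) || all(weights == 0))
      stop("weights must be non-negative and not all zero", call. = FALSE)
  }
  structure(list(angles = wrap_deg(angles), weights = weights),
            class = "angle_sample")
}

as_angle_sample <- function(x) {
  if (inherits(x, "angle_sample")) x else angle_sample(x)
}

#' Circular mean and resultant length
#'
#' Resultant-vector method: the mean direction is
#' `atan2(sum(w sin), sum(w cos))` and the mean resultant length
#' `R = |sum(w exp(i theta))| / sum(w)` measures concentration (1 = all
#' angles identical, 0 = perfectly dispersed). When `R` is numerically zero
#' (e.g. four angles at 0/90/180/270) the mean direction is undefined and
#' returned as `NA` with `defined = FALSE`.
#'
#' @param s an [angle_sample()] or numeric vector of degrees.
#' @return list with `mean_deg` (in `[-180, 180)`, or `NA`),
#'   `resultant_length` in `[0, 1]`, and `defined`.
#' @examples
#' circular_mean(c(10, -10)) # mean 0, R = cos(10 * pi / 180)
#' @export
circular_mean <- function(s) {
  s <- as_angle_sample(s)
  w <- if (is.null(s$weights)) rep(1, length(s$angles)) else s$weights
  th <- s$angles * pi / 180
  cbar <- sum(w * cos(th)) / sum(w)
  sbar <- sum(w * sin(th)) / sum(w)
  r <- sqrt(cbar^2 + sbar^2)
  if (r < 1e-12) {
    list(mean_deg = NA_real_, resultant_length = r, defined = FALSE)
  } else {
    list(mean_deg = wrap_deg(atan2(sbar, cbar) * 180 / pi),
         resultant_length = min(r, 1), defined = TRUE)
  }
}

#' Circular histogram of phase angles
#'
#' Probabilities over `n_bins` equal bins covering the circle. Bins are
#' centered on multiples of `360 / n_bins` (for the default 20 bins:
#' centers at 0, +-18, +-36, ... degrees), so that distribution peaks are
#' reported on the same 18-degree lattice as the field's circular-plot
#' conventions; the bin centered at -180 wraps around the antiphase point.
#'
#' @param s an [angle_sample()] or numeric vector of degrees.
#' @param n_bins number of bins; at least 4 and must divide 360. The default
#'   20 gives 18-degree bins, the granularity at which phase-distribution
#'   peaks are conventionally reported.
#' @return a `phase_histogram`: list with `bin_center_deg` (in
#'   `[-180, 180)`), `probability` (sums to 1), `n_bins`, `n`.
#' @export
phase_histogram <- function(s, n_bins = 20L) {
  s <- as_angle_sample(s)
  n_bins <- as.integer(n_bins)
  if (n_bins < 4L || 360L %% n_bins != 0L)
    stop("`n_bins` must be >= 4 and divide 360", call. = FALSE)
  w <- if (is.null(s$weights)) rep(1, length(s$angles)) else s$weights
  width <- 360 / n_bins
  idx <- (floor((s$angles + 180 + width / 2) / width) %% n_bins) + 1
  p <- as.numeric(tapply(w, factor(idx, levels = seq_len(n_bins)), sum))
  p[is.na(p)] <- 0
  p <- p / sum(p)
  structure(list(bin_center_deg = (seq_len(n_bins) - 1) * width - 180,
                 probability = p, n_bins = n_bins, n = length(s$angles)),
            class = "phase_histogram")
}

#' Peak angle of a circular histogram
#'
#' Center of the maximal-probability bin. Exact ties are broken towards the
#' bin whose center is nearest 0 degrees, then towards the smaller angle,
#' and flagged.
#'
#' @param hist a [phase_histogram()].
#' @return list with `peak_deg`, `tie` (logical flag).
#' @export
peak_angle <- function(hist) {
  stopifnot(inherits(hist, "phase_histogram"))
  pmax_ <- max(hist$probability)
  cand <- which(hist$probability >= pmax_ - 1e-15)
  tie <- length(cand) > 1L
  if (tie) {
    centers <- hist$bin_center_deg[cand]
    ord <- order(abs(centers), centers)
    cand <- cand[ord[1]]
  }
  list(peak_deg = hist$bin_center_deg[cand[1]], tie = tie)
}

#' Write a circular histogram as TSV
#' @param hist a [phase_histogram()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_phase_histogram <- function(hist, path) {
  stopifnot(inherits(hist, "phase_histogram"))
  df <- data.frame(bin_center_deg = hist$bin_center_deg,
                   probability = hist$probability)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
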