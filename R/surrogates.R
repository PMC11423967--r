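# Surrogate null models: interpersonal pseudo-dyads (between-subject
# shuffling across sessions) and intrapersonal segment shuffling.

#' Enumerate pseudo-dyad pairings
#'
#' All ordered pairings of participant-1 of one take with participant-2 of
#' another take, excluding pairings whose members come from the same real
#' dyad. For each pairing the common analysis length is the minimum of the
#' two recording lengths (the longer series is truncated, from the start).
#'
#' @param takes data.frame with one row per take: columns `take` (id),
#'   `dyad` (real-dyad id) and `n_samples` (recording length).
#' @return a `pseudo_dyad_plan` data.frame with columns `p1_take`,
#'   `p2_take`, `p1_dyad`, `p2_dyad`, `truncate_to` (samples).
#' @export
plan_pseudo_dyads <- function(takes) {
  takes <- as.data.frame(takes)
  stopifnot(all(c("take", "dyad", "n_samples") %in% names(takes)))
  if (nrow(takes) < 2L)
    stop("need at least 2 takes to form pseudo-dyads", call. = FALSE)
  idx <- expand.grid(i = seq_len(nrow(takes)), j = seq_len(nrow(takes)))
  idx <- idx[idx$i != idx$j & takes$dyad[idx$i] != takes$dyad[idx$j], ,
             drop = FALSE]
  plan <- data.frame(
    p1_take = takes$take[idx$i], p2_take = takes$take[idx$j],
    p1_dyad = takes$dyad[idx$i], p2_dyad = takes$dyad[idx$j],
    truncate_to = pmin(takes$n_samples[idx$i], takes$n_samples[idx$j]))
  plan <- plan[order(plan$p1_take, plan$p2_take), , drop = FALSE]
  rownames(plan) <- NULL
  class(plan) <- c("pseudo_dyad_plan", "data.frame")
  plan
}

#' Segment-shuffle surrogate of a series
#'
#' Cuts the series into consecutive segments of `round(segment_s * rate)`
#' samples and permutes their order uniformly with a seeded generator,
#' preserving the sample multiset exactly. The default 0.2 s segment
#' destroys temporal structure above the segment scale while keeping the
#' subject's value distribution intact. The final shorter remainder is
#' kept and shuffled with the rest by default; set `drop_remainder` to
#' discard it instead.
#'
#' @param s a [uniform_series()] longer than one segment.
#' @param segment_s segment length in seconds (default 0.2).
#' @param rng_seed integer seed for the permutation.
#' @param drop_remainder discard a final partial segment (default FALSE).
#' @return a shuffled [uniform_series()].
#' @export
segment_shuffle <- function(s, segment_s = 0.2, rng_seed = 1L,
                            drop_remainder = FALSE) {
  stopifnot(inherits(s, "uniform_series"))
  if (segment_s <= 0) stop("`segment_s` must be positive", call. = FALSE)
  n <- length(s$values)
  seg <- max(1L, as.integer(round(segment_s * s$rate)))
  if (n <= seg) {
    if (n < seg) stop("series shorter than one segment", call. = FALSE)
    return(s)
  }
  starts <- seq(1L, n, by = seg)
  pieces <- lapply(starts, function(st) s$values[st:min(st + seg - 1L, n)])
  if (drop_remainder && length(pieces[[length(pieces)]]) < seg)
    pieces <- pieces[-length(pieces)]
  perm <- with_seed(rng_seed, sample.int(length(pieces)))
  out <- s
  out$values <- unlist(pieces[perm], use.names = FALSE)
  out
}

# Evaluate an expression under a temporary RNG state.
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# Derive a reproducible child seed below 2^31 from a parent seed and tags.
derive_seed <- function(seed, ...) {
  tags <- paste(c(seed, ...), collapse = "/")
  h <- 0
  for (ch in utf8ToInt(tags)) h <- (h * 31 + ch) %% 2147483629
  as.integer(h + 1)
}

#' Surrogate distribution of band summaries
#'
#' Runs the identical coherence/phase band analysis over an ensemble of
#' surrogate signal pairs and aggregates to one summary per real dyad
#' (mean coherence arithmetically, phase by circular mean across
#' surrogates).
#'
#' @param pairs list of surrogate pairs; each element a list with `dyad`
#'   (id the surrogate is assigned to) and `a`, `b` (two
#'   [uniform_series()]).
#' @param condition `"pseudo_dyad"` or `"segment_shuffle"` (recorded).
#' @param grid a [scale_grid()].
#' @param bands a `timescale_bands` data.frame.
#' @param omega0,smoothing_decades analysis parameters; must equal the
#'   experimental run's.
#' @param use_coi exclude COI bins (default TRUE).
#' @return a `surrogate_ensemble`: list with `condition`, `per_surrogate`
#'   (data.frame of band summaries with `dyad` and `surrogate` columns) and
#'   `per_dyad` (one aggregated band summary per dyad).
#' @export
surrogate_band_distribution <- function(pairs, condition, grid,
                                        bands = default_bands(),
                                        omega0 = 6, smoothing_decades = 0.6,
                                        use_coi = TRUE) {
  if (length(pairs) == 0) stop("empty surrogate plan", call. = FALSE)
  condition <- match.arg(condition, c("pseudo_dyad", "segment_shuffle"))
  per <- lapply(seq_along(pairs), function(k) {
    p <- pairs[[k]]
    wa <- cwt_morlet(p$a, grid, omega0)
    wb <- cwt_morlet(p$b, grid, omega0)
    maps <- xwt_maps(wa, wb, smoothing_decades)
    bs <- band_average(maps$coherence, maps$phase, bands, use_coi)
    bs$dyad <- p$dyad
    bs$surrogate <- k
    bs
  })
  per_surrogate <- do.call(rbind, per)
  per_dyad <- aggregate_band_summaries(per_surrogate, "dyad")
  structure(list(condition = condition, per_surrogate = per_surrogate,
                 per_dyad = per_dyad, n = length(pairs)),
            class = "surrogate_ensemble")
}

# Aggregate band summaries over a grouping column: arithmetic mean of
# coherence, circular mean of phase, summed bin counts.
aggregate_band_summaries <- function(df, group_col) {
  key <- interaction(df[[group_col]], df$band_lo_s, drop = TRUE)
  rows <- lapply(split(seq_len(nrow(df)), key), function(ii) {
    d <- df[ii, , drop = FALSE]
    ok <- !is.na(d$mean_coherence)
    ph_ok <- !is.na(d$circ_mean_phase_deg)
    cm <- if (any(ph_ok)) circular_mean(d$circ_mean_phase_deg[ph_ok]) else
      list(mean_deg = NA_real_, resultant_length = NA_real_)
    out <- data.frame(
      band_lo_s = d$band_lo_s[1], band_hi_s = d$band_hi_s[1],
      mean_coherence = if (any(ok)) mean(d$mean_coherence[ok]) else NA_real_,
      circ_mean_phase_deg = cm$mean_deg,
      resultant_length = cm$resultant_length,
      n_valid_bins = sum(d$n_valid_bins))
    out[[group_col]] <- d[[group_col]][1]
    out
  })
  out <- do.call(rbind, rows)
  out <- out[order(out[[group_col]], out$band_lo_s), , drop = FALSE]
  rownames(out) <- NULL
  out
}
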