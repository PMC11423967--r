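# Independent brute-force oracles used across the suite. These deliberately
# re-derive results by different means than the package code (homogeneous
# matrix products, millisecond boolean masks, literal loops).

# --- forward kinematics: homogeneous 4x4 matrix-product oracle -----------

oracle_rot4 <- function(axis, deg) {
  th <- deg * pi / 180
  m <- diag(4)
  i <- switch(axis, X = c(2, 3), Y = c(3, 1), Z = c(1, 2))
  m[i[1], i[1]] <- cos(th); m[i[2], i[2]] <- cos(th)
  m[i[1], i[2]] <- -sin(th); m[i[2], i[1]] <- sin(th)
  m
}

oracle_trans4 <- function(v) {
  m <- diag(4); m[1:3, 4] <- v; m
}

oracle_world_position <- function(anim, joint, frame) {
  chain <- joint
  while (!is.na(anim$parent[[chain[1]]]))
    chain <- c(anim$parent[[chain[1]]], chain)
  M <- diag(4)
  for (j in chain) {
    M <- M %*% oracle_trans4(anim$offsets[j, ])
    vals <- anim$frames[frame, anim$channel_index[[j]]]
    for (k in seq_along(anim$channels[[j]])) {
      lab <- anim$channels[[j]][k]
      ax <- substr(lab, 1, 1)
      if (endsWith(lab, "position")) {
        v <- c(0, 0, 0)
        v[match(ax, c("X", "Y", "Z"))] <- vals[k]
        M <- M %*% oracle_trans4(v)
      } else {
        M <- M %*% oracle_rot4(ax, vals[k])
      }
    }
  }
  as.numeric((M %*% c(0, 0, 0, 1))[1:3])
}

# random small chain skeleton, all frames/channels randomized
random_chain_skeleton <- function(n_joints, n_frames) {
  joints <- paste0("J", seq_len(n_joints))
  parent <- stats::setNames(c(NA_character_, joints[-n_joints]), joints)
  offsets <- matrix(stats::runif(3 * n_joints, -5, 5), n_joints, 3,
                    dimnames = list(joints, c("x", "y", "z")))
  channels <- list()
  channels[[joints[1]]] <- c("Xposition", "Yposition", "Zposition",
                             "Zrotation", "Xrotation", "Yrotation")
  for (j in joints[-1])
    channels[[j]] <- sample(c("Zrotation", "Xrotation", "Yrotation"))
  idx <- list(); pos <- 0L
  for (j in joints) {
    idx[[j]] <- pos + seq_along(channels[[j]])
    pos <- pos + length(channels[[j]])
  }
  frames <- matrix(stats::runif(n_frames * pos, -170, 170), n_frames, pos)
  structure(list(joints = joints, parent = parent, offsets = offsets,
                 channels = channels, channel_index = idx,
                 frame_time = 1 / 90, frames = frames),
            class = "skeleton_animation")
}

# --- turn-taking: millisecond boolean-mask oracle ------------------------

oracle_conversation <- function(iv, min_silence = 0.2) {
  min_ms <- round(min_silence * 1000)
  n_ms <- max(round(iv$end * 1000)) + 10L
  speakers <- c("A", "B")
  unit_list <- list()
  for (sp in speakers) {
    m <- logical(n_ms)
    for (k in which(iv$speaker == sp)) {
      s <- round(iv$start[k] * 1000); e <- round(iv$end[k] * 1000)
      if (e > s) m[(s + 1):e] <- TRUE
    }
    r <- rle(m)
    short <- which(!r$values & r$lengths < min_ms)
    short <- short[short > 1 & short < length(r$lengths)]
    r$values[short] <- TRUE
    m <- inverse.rle(r)
    r2 <- rle(m)
    ends <- cumsum(r2$lengths)
    starts <- ends - r2$lengths + 1L
    on <- which(r2$values)
    unit_list[[sp]] <- data.frame(
      speaker = sp, start = (starts[on] - 1) / 1000, end = ends[on] / 1000)
    assign(paste0("mask", sp), m)
  }
  units <- do.call(rbind, unit_list)
  units <- units[order(units$start, units$speaker), , drop = FALSE]
  rownames(units) <- NULL
  # turns: maximal same-speaker runs in onset order
  run <- cumsum(c(TRUE, units$speaker[-1] != units$speaker[-nrow(units)]))
  turns <- do.call(rbind, lapply(split(seq_len(nrow(units)), run),
    function(ii) data.frame(speaker = units$speaker[ii[1]],
                            start = units$start[ii[1]],
                            end = max(units$end[ii]))))
  rownames(turns) <- NULL
  # overlaps from the mask intersection
  both <- maskA & maskB
  r <- rle(both)
  ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
  on <- which(r$values)
  ov <- data.frame(start = (starts[on] - 1) / 1000, end = ends[on] / 1000)
  ov$incoming_speaker <- vapply(starts[on], function(s) {
    if (s == 1L) return("A")                      # simultaneous onset tie
    a_new <- !maskA[s - 1L]; b_new <- !maskB[s - 1L]
    if (a_new && b_new) "A" else if (a_new) "A" else "B"
  }, character(1))
  # silences >= threshold between covered stretches
  any_sp <- maskA | maskB
  first_on <- match(TRUE, any_sp)
  last_on <- n_ms + 1L - match(TRUE, rev(any_sp))
  sil <- NULL
  if (!is.na(first_on)) {
    r <- rle(any_sp[first_on:last_on])
    ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
    off <- which(!r$values & r$lengths >= min_ms)
    for (k in off) {
      s0 <- (first_on - 1 + starts[k] - 1) / 1000
      s1 <- (first_on - 1 + ends[k]) / 1000
      ender <- units[units$end == s0, ]
      before <- ender$speaker[which.max(ender$start)]
      starter <- units[units$start == s1, ]
      after <- sort(starter$speaker)[1]
      sil <- rbind(sil, data.frame(
        kind = if (before == after) "pause" else "gap",
        start = s0, end = s1,
        before_speaker = before, after_speaker = after))
    }
  }
  if (is.null(sil))
    sil <- data.frame(kind = character(0), start = numeric(0),
                      end = numeric(0), before_speaker = character(0),
                      after_speaker = character(0))
  # switches: overlap onsets + speaker-change turn onsets, deduplicated
  sw_t <- c(); sw_kind <- c()
  if (nrow(turns) >= 2) for (k in 2:nrow(turns))
    if (turns$speaker[k] != turns$speaker[k - 1]) {
      sw_t <- c(sw_t, turns$start[k])
      sw_kind <- c(sw_kind, if (turns$start[k] %in% ov$start)
        "overlap_onset" else "turn_onset")
    }
  extra <- setdiff(ov$start, sw_t)
  sw_t <- c(sw_t, extra)
  sw_kind <- c(sw_kind, rep("overlap_onset", length(extra)))
  o <- order(sw_t)
  switches <- data.frame(kind = sw_kind[o], time = sw_t[o])
  list(units = units, turns = turns, overlaps = ov, silences = sil,
       switches = switches)
}

# random two-speaker annotation set on a 10 ms grid
random_interval_set <- function(total_s = 60) {
  rows <- NULL
  for (sp in c("A", "B")) {
    t <- stats::runif(1, 0, 2)
    while (t < total_s - 1) {
      d <- stats::runif(1, 0.25, 4)
      e <- min(t + d, total_s)
      rows <- rbind(rows, data.frame(speaker = sp,
                                     start = round(t, 2),
                                     end = round(e, 2)))
      t <- e + stats::runif(1, 0.05, 3)   # silences straddle the 0.2 s rule
    }
  }
  rows <- rows[rows$end > rows$start, , drop = FALSE]
  rows
}

# --- wavelet band averaging: literal-loop recount ------------------------

oracle_band_average <- function(coh, ph, bands, use_coi = TRUE) {
  out <- NULL
  for (k in seq_len(nrow(bands))) {
    cvals <- c(); pvals <- c()
    for (j in seq_along(coh$periods)) {
      if (coh$periods[j] <= bands$lo_s[k] ||
          coh$periods[j] > bands$hi_s[k]) next
      for (i in seq_len(nrow(coh$values))) {
        if (use_coi && coh$periods[j] >= coh$coi[i]) next
        if (is.na(coh$values[i, j]) || is.na(ph$values[i, j])) next
        cvals <- c(cvals, coh$values[i, j])
        pvals <- c(pvals, ph$values[i, j])
      }
    }
    if (length(cvals) == 0) {
      out <- rbind(out, data.frame(mean_coherence = NA_real_,
                                   circ_mean_phase_deg = NA_real_,
                                   n_valid_bins = 0L))
    } else {
      th <- pvals * pi / 180
      mu <- atan2(mean(sin(th)), mean(cos(th))) * 180 / pi
      if (mu >= 180) mu <- mu - 360
      out <- rbind(out, data.frame(mean_coherence = mean(cvals),
                                   circ_mean_phase_deg = mu,
                                   n_valid_bins = length(cvals)))
    }
  }
  out
}

# --- small shared fixtures ----------------------------------------------

two_joint_bvh_text <- function(n_frames = 3, frame_time = 0.0111111,
                               frame_rows = NULL) {
  if (is.null(frame_rows))
    frame_rows <- rep(paste(rep("0", 9), collapse = " "), n_frames)
  c("HIERARCHY",
    "ROOT root",
    "{",
    "  OFFSET 0 0 0",
    "  CHANNELS 6 Xposition Yposition Zposition Zrotation Xrotation Yrotation",
    "  JOINT child",
    "  {",
    "    OFFSET 0 10 0",
    "    CHANNELS 3 Zrotation Xrotation Yrotation",
    "    End Site",
    "    {",
    "      OFFSET 0 1 0",
    "    }",
    "  }",
    "}",
    "MOTION",
    sprintf("Frames: %d", n_frames),
    sprintf("Frame Time: %.7f", frame_time),
    frame_rows)
}
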