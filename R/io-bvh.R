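# Biovision Hierarchy (BVH) motion files: parser, writer and forward
# kinematics. The dialect covered is the common one: a HIERARCHY section of
# nested ROOT/JOINT blocks with OFFSET / CHANNELS / End Site, then a MOTION
# section with "Frames:" and "Frame Time:" followed by whitespace-separated
# rows of channel values. Euler rotations are applied in the per-joint
# CHANNELS order, right-handed, in degrees.

#' World-space marker trajectory
#'
#' @param joint joint name.
#' @param positions n x 3 numeric matrix of world coordinates per frame.
#' @param rate frame rate in Hz.
#' @return a `marker_trajectory` object.
#' @export
marker_trajectory <- function(joint, positions, rate) {
  positions <- as.matrix(positions)
  if (ncol(positions) != 3L) stop("`positions` must be n x 3", call. = FALSE)
  if (any(!is.finite(positions)))
    stop("positions must be finite", call. = FALSE)
  if (rate <= 0) stop("`rate` must be positive", call. = FALSE)
  structure(list(joint = joint, positions = positions, rate = rate),
            class = "marker_trajectory")
}

bvh_error <- function(line, msg) {
  stop(sprintf("BVH parse error at line %d: %s", line, msg), call. = FALSE)
}

#' Read a BVH motion-capture file
#'
#' @param path path to a BVH file.
#' @return a `skeleton_animation`: list with `joints` (names in file
#'   order), `parent` (named character, `NA` for the root), `offsets`
#'   (joints x 3 matrix), `channels` (named list of channel-label vectors),
#'   `channel_index` (named list of column index vectors into `frames`),
#'   `frame_time` (s), `frames` (frame x channel matrix).
#' @export
read_bvh <- function(path) {
  lines <- readLines(path, warn = FALSE)
  toks <- lapply(lines, function(l) strsplit(trimws(l), "[ \t]+")[[1]])
  nline <- length(lines)
  i <- 1L
  skip_blank <- function() {
    while (i <= nline && (length(toks[[i]]) == 0L || toks[[i]][1] == ""))
      i <<- i + 1L
  }
  expect <- function(word) {
    skip_blank()
    if (i > nline || !identical(toupper(toks[[i]][1]), word))
      bvh_error(min(i, nline), sprintf("expected '%s'", word))
  }
  joints <- character(0); parent <- character(0)
  offsets <- NULL; channels <- list()
  valid_channels <- c("Xposition", "Yposition", "Zposition",
                      "Xrotation", "Yrotation", "Zrotation")

  parse_joint <- function(parent_name) {
    # current token line: ROOT/JOINT <name>
    tk <- toks[[i]]
    if (length(tk) < 2L) bvh_error(i, "joint declaration without a name")
    name <- paste(tk[-1], collapse = "_")
    if (name %in% joints) bvh_error(i, sprintf("duplicate joint '%s'", name))
    i <<- i + 1L
    expect("{"); i <<- i + 1L
    expect("OFFSET")
    off <- suppressWarnings(as.numeric(toks[[i]][2:4]))
    if (length(toks[[i]]) < 4L || anyNA(off))
      bvh_error(i, "OFFSET needs three numbers")
    i <<- i + 1L
    expect("CHANNELS")
    nch <- suppressWarnings(as.integer(toks[[i]][2]))
    ch <- toks[[i]][-(1:2)]
    if (is.na(nch) || length(ch) != nch)
      bvh_error(i, "CHANNELS count does not match the labels given")
    if (!all(ch %in% valid_channels))
      bvh_error(i, sprintf("unknown channel label '%s'",
                           setdiff(ch, valid_channels)[1]))
    i <<- i + 1L
    joints <<- c(joints, name)
    parent <<- c(parent, stats::setNames(parent_name, name))
    offsets <<- rbind(offsets, off)
    channels[[name]] <<- ch
    repeat {
      skip_blank()
      if (i > nline) bvh_error(nline, "unterminated joint block")
      head_tok <- toupper(toks[[i]][1])
      if (head_tok == "JOINT") {
        parse_joint(name)
      } else if (head_tok == "END") {           # End Site
        i <<- i + 1L; expect("{"); i <<- i + 1L
        expect("OFFSET"); i <<- i + 1L
        expect("}"); i <<- i + 1L
      } else if (head_tok == "}") {
        i <<- i + 1L
        break
      } else bvh_error(i, sprintf("unexpected token '%s'", toks[[i]][1]))
    }
  }

  expect("HIERARCHY"); i <- i + 1L
  skip_blank()
  if (i > nline || toupper(toks[[i]][1]) != "ROOT")
    bvh_error(min(i, nline), "expected 'ROOT'")
  parse_joint(NA_character_)

  expect("MOTION"); i <- i + 1L
  expect("FRAMES:")
  nframes <- suppressWarnings(as.integer(toks[[i]][2]))
  if (is.na(nframes) || nframes < 0) bvh_error(i, "bad 'Frames:' count")
  i <- i + 1L
  skip_blank()
  if (toupper(paste(toks[[i]][1:2], collapse = " ")) != "FRAME TIME:")
    bvh_error(i, "expected 'Frame Time:'")
  frame_time <- suppressWarnings(as.numeric(toks[[i]][3]))
  if (is.na(frame_time) || frame_time <= 0)
    bvh_error(i, "'Frame Time:' must be a positive number")
  i <- i + 1L

  total_ch <- sum(lengths(channels))
  rows <- vector("list", nframes)
  row <- 0L
  while (row < nframes) {
    skip_blank()
    if (i > nline)
      bvh_error(nline, sprintf("declared %d frames but found %d data rows",
                               nframes, row))
    vals <- suppressWarnings(as.numeric(toks[[i]]))
    if (anyNA(vals)) bvh_error(i, "non-numeric motion data")
    if (length(vals) != total_ch)
      bvh_error(i, sprintf("frame has %d values but %d channels declared",
                           length(vals), total_ch))
    row <- row + 1L
    rows[[row]] <- vals
    i <- i + 1L
  }
  frames <- if (nframes > 0) do.call(rbind, rows) else
    matrix(numeric(0), 0, total_ch)

  idx <- list(); pos <- 0L
  for (j in joints) {
    idx[[j]] <- pos + seq_along(channels[[j]])
    pos <- pos + length(channels[[j]])
  }
  rownames(offsets) <- joints
  colnames(offsets) <- c("x", "y", "z")
  dimnames(frames) <- NULL
  structure(list(joints = joints, parent = parent, offsets = offsets,
                 channels = channels, channel_index = idx,
                 frame_time = frame_time, frames = frames),
            class = "skeleton_animation")
}

#' @export
print.skeleton_animation <- function(x, ...) {
  cat(sprintf("<skeleton_animation> %d joints, %d frames @ %.4g fps\n",
              length(x$joints), nrow(x$frames), 1 / x$frame_time))
  invisible(x)
}

#' Write a skeleton animation as a BVH file
#'
#' Inverse of [read_bvh()] for the dialect it parses; useful to exercise the
#' motion pipeline end-to-end on generated skeletons.
#'
#' @param anim a `skeleton_animation`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_bvh <- function(anim, path) {
  stopifnot(inherits(anim, "skeleton_animation"))
  con <- file(path, "w")
  on.exit(close(con))
  out <- function(depth, fmt, ...)
    writeLines(paste0(strrep("  ", depth), sprintf(fmt, ...)), con)
  children <- function(j) anim$joints[!is.na(anim$parent) & anim$parent == j]
  emit <- function(j, depth, kw) {
    out(depth, "%s %s", kw, j)
    out(depth, "{")
    off <- anim$offsets[j, ]
    out(depth + 1, "OFFSET %.6f %.6f %.6f", off[1], off[2], off[3])
    ch <- anim$channels[[j]]
    out(depth + 1, "CHANNELS %d %s", length(ch), paste(ch, collapse = " "))
    kids <- children(j)
    if (length(kids) == 0L) {
      out(depth + 1, "End Site")
      out(depth + 1, "{")
      out(depth + 2, "OFFSET 0.000000 0.000000 0.000000")
      out(depth + 1, "}")
    } else {
      for (k in kids) emit(k, depth + 1, "JOINT")
    }
    out(depth, "}")
  }
  writeLines("HIERARCHY", con)
  root <- anim$joints[is.na(anim$parent)]
  emit(root, 0L, "ROOT")
  writeLines("MOTION", con)
  writeLines(sprintf("Frames: %d", nrow(anim$frames)), con)
  writeLines(sprintf("Frame Time: %.8f", anim$frame_time), con)
  apply(anim$frames, 1, function(r)
    writeLines(paste(sprintf("%.6f", r), collapse = " "), con))
  invisible(path)
}

rot_mat <- function(axis, deg) {
  th <- deg * pi / 180
  c_ <- cos(th); s_ <- sin(th)
  switch(axis,
         X = matrix(c(1, 0, 0, 0, c_, s_, 0, -s_, c_), 3, 3),
         Y = matrix(c(c_, 0, -s_, 0, 1, 0, s_, 0, c_), 3, 3),
         Z = matrix(c(c_, s_, 0, -s_, c_, 0, 0, 0, 1), 3, 3))
}

#' World positions of one joint by forward kinematics
#'
#' Composes, from the root down to the joint, each ancestor's translation
#' (constant offset plus any position channels) and Euler rotations in the
#' joint's declared channel order (right-handed, degrees).
#'
#' @param anim a `skeleton_animation` from [read_bvh()].
#' @param joint joint name; must exist in `anim`.
#' @return a [marker_trajectory()] at `1 / frame_time` Hz.
#' @export
world_positions <- function(anim, joint) {
  stopifnot(inherits(anim, "skeleton_animation"))
  if (!joint %in% anim$joints)
    stop(sprintf("unknown joint '%s'; available: %s", joint,
                 paste(anim$joints, collapse = ", ")), call. = FALSE)
  chain <- joint
  while (!is.na(anim$parent[[chain[1]]]))
    chain <- c(anim$parent[[chain[1]]], chain)
  nfr <- nrow(anim$frames)
  out <- matrix(0, nfr, 3)
  for (f in seq_len(nfr)) {
    p <- c(0, 0, 0)
    R <- diag(3)
    for (j in chain) {
      vals <- anim$frames[f, anim$channel_index[[j]]]
      ch <- anim$channels[[j]]
      tr <- anim$offsets[j, ]
      Rj <- diag(3)
      for (k in seq_along(ch)) {
        lab <- ch[k]
        if (endsWith(lab, "position")) {
          ax <- match(substr(lab, 1, 1), c("X", "Y", "Z"))
          tr[ax] <- tr[ax] + vals[k]
        } else {
          Rj <- Rj %*% rot_mat(substr(lab, 1, 1), vals[k])
        }
      }
      p <- p + R %*% tr
      R <- R %*% Rj
    }
    out[f, ] <- p
  }
  marker_trajectory(joint, out, 1 / anim$frame_time)
}

#' Select a joint name by case-insensitive substring match
#'
#' Dataset-specific joint naming is not hard-coded anywhere: the analysis
#' selects markers by configurable patterns (defaults `"Head"`,
#' `"LeftHand"`, `"RightHand"`).
#'
#' @param anim a `skeleton_animation`.
#' @param pattern substring to match (case-insensitive, fixed).
#' @return the first matching joint name.
#' @export
find_joint <- function(anim, pattern) {
  hit <- grep(tolower(pattern), tolower(anim$joints), fixed = TRUE)
  if (length(hit) == 0L)
    stop(sprintf("no joint matching '%s'; available: %s", pattern,
                 paste(anim$joints, collapse = ", ")), call. = FALSE)
  anim$joints[hit[1]]
}
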