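#' Interpolate and smooth a keypoint track
#'
#' Fills missing coordinates by linear interpolation (edge values held) and
#' smooths every coordinate with a centered moving mean.
#'
#' @param track a `keypoint_track` (possibly with NaN coordinates).
#' @param window_frames moving-mean window in frames; 1 disables smoothing.
#' @return A `keypoint_track` with no missing values.
#' @export
preprocess_keypoints <- function(track, window_frames = 5L) {
  stopifnot(inherits(track, "keypoint_track"))
  stopifnot_scalar(window_frames, "window_frames")
  coords <- track$coords
  n <- dim(coords)[1]
  for (node in seq_len(dim(coords)[2])) {
    for (d in 1:2) {
      x <- coords[, node, d]
      if (all(is.na(x))) {
        stop(sprintf("node '%s' has no observed coordinates",
                     track$node_names[node]), call. = FALSE)
      }
      if (anyNA(x)) {
        x <- approx(seq_len(n), x, xout = seq_len(n), rule = 2)$y
      }
      coords[, node, d] <- moving_mean(x, window_frames)
    }
  }
  track$coords <- coords
  track
}

# trailing-window tortuosity: path length / net displacement over the last
# `w` frames. Stationary windows -> 1; near-zero net displacement with real
# path length is capped so downstream z-scoring stays finite.
trailing_tortuosity <- function(xy, w, cap = 50) {
  n <- nrow(xy)
  d <- sqrt(rowSums((xy[-1, , drop = FALSE] - xy[-n, , drop = FALSE])^2))
  cum <- c(0, cumsum(d))
  out <- rep(1, n)
  idx <- (w + 1):n
  if (length(idx) == 0 || n <= w) return(out)
  path <- cum[idx] - cum[idx - w]
  net <- sqrt(rowSums((xy[idx, , drop = FALSE] - xy[idx - w, , drop = FALSE])^2))
  tor <- ifelse(path < 1e-9, 1, pmin(path / pmax(net, 1e-9), cap))
  out[idx] <- pmax(tor, 1)
  out
}

#' Compute per-frame behavioral features from a preprocessed track
#'
#' Continuous features: distance of nose to port, unsigned angle of head to
#' port, body velocity and acceleration (torso displacement, px/s and
#' px/s^2), orientation of head to body, orientation of head to tail,
#' turning angle, 1-s and 5-s trailing tortuosity, nose-tail distance and
#' its first difference. Discrete features: zone of the excluded mouse
#' (1-3), oriented_to_port, touching_barrier, oriented_and_touching, and
#' huddle_quality (constant 0 when no cagemate tracks are supplied).
#'
#' @param track preprocessed `keypoint_track` (no missing values).
#' @param arena an [arena_config()].
#' @return A `feature_matrix`: list with `values` (frames x features),
#'   `feature_names`, `kinds` ("continuous"/"discrete"), `fps`, `zscored`.
#' @export
compute_features <- function(track, arena) {
  stopifnot(inherits(track, "keypoint_track"), inherits(arena, "arena_config"))
  coords <- track$coords
  if (anyNA(coords)) stop("track must be preprocessed (no missing values)")
  if (any(coords[, , 1] > arena$image_size[1]) ||
      any(coords[, , 2] > arena$image_size[2])) {
    stop("arena image_size inconsistent with track coordinates")
  }
  fps <- track$fps
  n <- dim(coords)[1]
  nose <- coords[, "nose", ]
  torso <- coords[, "torso", ]
  tail <- coords[, "tail_base", ]
  ears_mid <- (coords[, "ear_left", ] + coords[, "ear_right", ]) / 2

  head_dir <- nose - ears_mid
  to_port <- matrix(arena$port_xy, n, 2, byrow = TRUE) - nose
  dist_port <- sqrt(rowSums(to_port^2))
  angle_port <- angle_between(head_dir, to_port)

  disp <- torso[-1, , drop = FALSE] - torso[-n, , drop = FALSE]
  speed <- c(0, sqrt(rowSums(disp^2))) * fps
  speed[1] <- speed[2]
  accel <- c(0, diff(speed)) * fps

  body_axis <- torso - tail
  head_body <- angle_between(head_dir, body_axis)
  head_tail <- angle_between(head_dir, tail - torso)

  # turning angle: change in movement direction between consecutive steps
  turn <- rep(0, n)
  if (n >= 3) {
    turn[3:n] <- angle_between(disp[-1, , drop = FALSE],
                               disp[-(n - 1), , drop = FALSE])
    turn[!is.finite(turn)] <- 0
  }

  tor1 <- trailing_tortuosity(torso, max(1L, round(fps)))
  tor5 <- trailing_tortuosity(torso, max(1L, round(5 * fps)))

  nose_tail <- sqrt(rowSums((nose - tail)^2))
  d_nose_tail <- c(0, diff(nose_tail))

  zone <- findInterval(torso[, 1], arena$zone_edges) + 1L
  zone <- pmin(zone, 3L)
  oriented <- as.numeric(angle_port <= arena$orient_angle_max)
  touching <- as.numeric(abs(nose[, 1] - arena$barrier_x) <=
                           arena$barrier_contact_dist)
  huddle <- rep(0, n)

  values <- cbind(dist_to_port = dist_port, angle_to_port = angle_port,
                  velocity = speed, acceleration = accel,
                  head_body_angle = head_body, head_tail_angle = head_tail,
                  turning_angle = turn, tortuosity_1s = tor1,
                  tortuosity_5s = tor5, nose_tail_dist = nose_tail,
                  d_nose_tail_dist = d_nose_tail,
                  zone = zone, oriented_to_port = oriented,
                  touching_barrier = touching,
                  oriented_and_touching = oriented * touching,
                  huddle_quality = huddle)
  kinds <- c(rep("continuous", 11), rep("discrete", 5))
  structure(list(values = values, feature_names = colnames(values),
                 kinds = kinds, fps = fps, zscored = FALSE),
            class = "feature_matrix")
}

#' Z-score the continuous features over the full session
#'
#' Discrete columns are untouched. Constant continuous columns are an
#' error (they carry no information and break standardization).
#'
#' @param fm a `feature_matrix`.
#' @return The `feature_matrix` with continuous columns standardized.
#' @export
zscore_features <- function(fm) {
  stopifnot(inherits(fm, "feature_matrix"))
  cont <- which(fm$kinds == "continuous")
  for (j in cont) {
    s <- sd(fm$values[, j])
    if (!is.finite(s) || s == 0) {
      stop(sprintf("continuous feature '%s' has zero variance",
                   fm$feature_names[j]), call. = FALSE)
    }
    fm$values[, j] <- (fm$values[, j] - mean(fm$values[, j])) / s
  }
  fm$zscored <- TRUE
  fm
}

#' Per-trial analysis windows
#'
#' Frame index ranges for the 5-s pre-cue baseline and the three 5-s bins
#' partitioning the 15 s after each cue onset.
#'
#' @param sched trial schedule.
#' @param fps sampling rate of the aligned signal, Hz.
#' @param n_frames total frames available.
#' @return data.frame with one row per trial x window (`window` in
#'   "baseline","bin1","bin2","bin3"), columns `start`,`end` (1-based,
#'   inclusive frame indices).
#' @export
trial_windows <- function(sched, fps, n_frames) {
  per <- round(5 * fps)
  res <- do.call(rbind, lapply(seq_len(nrow(sched)), function(i) {
    onset <- round(sched$onset_s[i] * fps) + 1L   # first frame at/after cue
    data.frame(trial = i,
               window = c("baseline", "bin1", "bin2", "bin3"),
               start = c(onset - per, onset, onset + per, onset + 2L * per),
               end = c(onset - 1L, onset + per - 1L, onset + 2L * per - 1L,
                       onset + 3L * per - 1L))
  }))
  if (any(res$start < 1L) || any(res$end > n_frames)) {
    stop("trial windows exceed recording bounds", call. = FALSE)
  }
  res
}

#' Freezing / dashing scoring
#'
#' A frame is freezing when velocity and |acceleration| are both below their
#' thresholds, dashing when velocity exceeds the dash threshold. The
#' dash/freeze ratio is computed over the 0-15 s post-cue windows when a
#' schedule is supplied, else over the whole session; zero freezing frames
#' yield an NA ratio flagged `undefined`.
#'
#' @param fm `feature_matrix` with unstandardized velocity/acceleration.
#' @param v_thresh,a_thresh freezing thresholds (px/s, px/s^2).
#' @param dash_thresh dashing velocity threshold (px/s).
#' @param sched optional trial schedule restricting the ratio window.
#' @return list `labels` (per-frame "freeze"/"dash"/"other"), `ratio`,
#'   `undefined`, `n_freeze`, `n_dash`.
#' @export
freeze_dash_score <- function(fm, v_thresh, a_thresh, dash_thresh,
                              sched = NULL) {
  stopifnot(inherits(fm, "feature_matrix"))
  if (fm$zscored) stop("freeze/dash thresholds apply to raw features")
  v <- fm$values[, "velocity"]
  a <- abs(fm$values[, "acceleration"])
  freeze <- v < v_thresh & a < a_thresh
  dash <- v > dash_thresh
  labels <- ifelse(freeze, "freeze", ifelse(dash, "dash", "other"))
  keep <- rep(TRUE, length(v))
  if (!is.null(sched)) {
    tw <- trial_windows(sched, fm$fps, length(v))
    tw <- tw[tw$window != "baseline", ]
    keep <- rep(FALSE, length(v))
    for (i in seq_len(nrow(tw))) keep[tw$start[i]:tw$end[i]] <- TRUE
  }
  nf <- sum(freeze & keep)
  nd <- sum(dash & keep)
  list(labels = labels, ratio = if (nf == 0) NA_real_ else nd / nf,
       undefined = nf == 0, n_freeze = nf, n_dash = nd)
}

#' Reward-seeking quantification
#'
#' Percent of frames with nose-to-port distance strictly below a threshold,
#' per trial window (0-15 s post cue) or over the whole session.
#'
#' @param fm `feature_matrix` with unstandardized distance.
#' @param dist_thresh distance threshold, px.
#' @param sched optional trial schedule.
#' @return If `sched` is given, a data.frame `trial`,`percent`; else a
#'   single percentage.
#' @export
reward_seeking <- function(fm, dist_thresh, sched = NULL) {
  stopifnot(inherits(fm, "feature_matrix"))
  d <- fm$values[, "dist_to_port"]
  if (is.null(sched)) return(100 * mean(d < dist_thresh))
  tw <- trial_windows(sched, fm$fps, length(d))
  tw <- tw[tw$window != "baseline", ]
  out <- vapply(split(tw, tw$trial), function(w) {
    idx <- unlist(mapply(seq, w$start, w$end, SIMPLIFY = FALSE))
    100 * mean(d[idx] < dist_thresh)
  }, numeric(1))
  data.frame(trial = as.integer(names(out)), percent = unname(out))
}

#' Hot-plate lick scores
#'
#' Normalized score = paradigm / baseline; difference score =
#' paradigm - baseline. A zero baseline leaves the normalized score
#' undefined (NA) while the difference is still returned.
#'
#' @param paradigm_value,baseline_value lick durations (s).
#' @return list `normalized`, `difference`.
#' @export
hotplate_scores <- function(paradigm_value, baseline_value) {
  stopifnot(is.numeric(paradigm_value), is.numeric(baseline_value))
  norm <- ifelse(baseline_value > 0, paradigm_value / baseline_value, NA_real_)
  list(normalized = norm, difference = paradigm_value - baseline_value)
}
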