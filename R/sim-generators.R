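#' Generate a trial schedule
#'
#' Draws cue onsets for one session: the first onset follows the habituation
#' delay; consecutive onsets are separated by the transparent-wall window
#' plus a uniform inter-trial interval.
#'
#' @param cfg a [sim_config()].
#' @return A `trial_schedule`: data.frame with columns `trial`, `onset_s`,
#'   plus attributes `cue_s`, `wall_s` and `duration_s` (session length
#'   including a tail pad for peri-event windows).
#' @export
gen_schedule <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  with_seed(stage_seed(cfg, "schedule"), {
    itis <- runif(cfg$n_trials - 1L, cfg$iti_range[1], cfg$iti_range[2])
    onsets <- cfg$habituation_s + c(0, cumsum(cfg$wall_s + itis))
  })
  sched <- data.frame(trial = seq_len(cfg$n_trials), onset_s = onsets)
  attr(sched, "cue_s") <- cfg$cue_s
  attr(sched, "wall_s") <- cfg$wall_s
  attr(sched, "duration_s") <- onsets[length(onsets)] + cfg$wall_s + 25
  class(sched) <- c("trial_schedule", "data.frame")
  sched
}

# Per-frame flag: inside a cue/wall window [onset, onset + wall_s).
in_trial_window <- function(t_s, sched) {
  flag <- logical(length(t_s))
  wall <- attr(sched, "wall_s")
  for (on in sched$onset_s) {
    flag <- flag | (t_s >= on & t_s < on + wall)
  }
  flag
}

# Attending geometry predicate used as generator-side ground truth: the nose
# is within contact distance of the barrier AND the head (ear-midpoint to
# nose) points at the port within the angle threshold.
attending_geometry <- function(nose, ears_mid, arena) {
  head_dir <- nose - ears_mid
  to_port <- matrix(arena$port_xy, nrow(nose), 2, byrow = TRUE) - nose
  ang <- angle_between(head_dir, to_port)
  touching <- abs(nose[, 1] - arena$barrier_x) <= arena$barrier_contact_dist
  touching & (ang <= arena$orient_angle_max)
}

#' Node names of the 9-point skeleton
#' @export
skeleton_nodes <- function() {
  c("nose", "ear_left", "ear_right", "torso", "forepaw_left",
    "forepaw_right", "hindpaw_left", "hindpaw_right", "tail_base")
}

#' Generate a synthetic keypoint track with planted attending bouts
#'
#' Simulates a 9-node pose track at the video frame rate. A sticky two-state
#' bout process (attending vs other) runs over frames; its stationary
#' occupancy is `attend_p_cue` inside cue/wall windows and `attend_p_iti`
#' outside. Attending frames place the nose at the barrier, head oriented to
#' the port within the arena's angle threshold; other frames are a bounded
#' random walk kept clear of the barrier contact zone, so the geometric
#' attending predicate holds exactly on the planted attending frames.
#' A configurable fraction of coordinates is then dropped to NaN.
#'
#' @param cfg a [sim_config()].
#' @param sched a schedule from [gen_schedule()].
#' @return list with `track` (a `keypoint_track`: `coords`
#'   frames x 9 x 2 array, `node_names`, `fps`) and `truth` (per-frame
#'   `state` 1/0, `attending_frame` logical from the geometry predicate,
#'   `detections` data.frame of nose points on attending frames, and the
#'   noise-free coordinates).
#' @export
gen_keypoints <- function(cfg, sched) {
  stopifnot(inherits(cfg, "sim_config"), inherits(sched, "trial_schedule"))
  arena <- cfg$arena
  fps <- cfg$fps_video
  n_frames <- ceiling(attr(sched, "duration_s") * fps)
  t_s <- (seq_len(n_frames) - 1L) / fps
  in_win <- in_trial_window(t_s, sched)
  p_t <- ifelse(in_win, cfg$attend_p_cue, cfg$attend_p_iti)

  nodes <- skeleton_nodes()
  body_len <- 25; ear_back <- 8; ear_side <- 6; tail_back <- 20; paw_side <- 10
  # keep the non-attending nose strictly outside the contact zone
  x_max_other <- arena$barrier_x - arena$barrier_contact_dist - body_len - 5

  with_seed(stage_seed(cfg, "keypoints"), {
    state <- integer(n_frames)
    state[1] <- rbinom(1, 1, p_t[1])
    stick <- cfg$attend_stick
    resample <- runif(n_frames) > stick
    draws <- runif(n_frames)
    for (i in 2:n_frames) {
      state[i] <- if (resample[i]) as.integer(draws[i] < p_t[i]) else state[i - 1]
    }

    # other-state torso random walk (reflected into bounds)
    step <- matrix(rnorm(n_frames * 2, sd = 3), ncol = 2)
    walk <- apply(step, 2, cumsum)
    reflect <- function(x, lo, hi) {
      rng <- hi - lo
      y <- (x - lo) %% (2 * rng)
      lo + ifelse(y > rng, 2 * rng - y, y)
    }
    torso_other <- cbind(reflect(walk[, 1] + 60, 20, x_max_other - 20),
                         reflect(walk[, 2] + arena$image_size[2] / 2,
                                 30, arena$image_size[2] - 30))
    heading_other <- cumsum(rnorm(n_frames, sd = 0.3))

    # attending pose: nose at the barrier, head to port with margin
    u <- runif(n_frames, 2, 0.6 * arena$barrier_contact_dist)
    nose_att <- cbind(arena$barrier_x - u,
                      pmin(pmax(arena$port_xy[2] + rnorm(n_frames, sd = 20),
                                30), arena$image_size[2] - 30))
    ang_err <- runif(n_frames, -0.3, 0.3) * arena$orient_angle_max

    noise <- array(rnorm(n_frames * length(nodes) * 2,
                         sd = cfg$keypoint_noise_sd),
                   dim = c(n_frames, length(nodes), 2))
    drop <- array(runif(n_frames * length(nodes) * 2) < cfg$missing_frac,
                  dim = c(n_frames, length(nodes), 2))
  })

  # assemble skeleton per frame
  att <- state == 1L
  nose <- matrix(NA_real_, n_frames, 2)
  heading <- matrix(NA_real_, n_frames, 2)
  to_port_att <- cbind(arena$port_xy[1] - nose_att[, 1],
                       arena$port_xy[2] - nose_att[, 2])
  base_ang <- atan2(to_port_att[, 2], to_port_att[, 1]) + ang_err
  heading_att <- cbind(cos(base_ang), sin(base_ang))
  nose[att, ] <- nose_att[att, ]
  heading[att, ] <- heading_att[att, ]
  h_oth <- cbind(cos(heading_other), sin(heading_other))
  nose[!att, ] <- torso_other[!att, ] + body_len * h_oth[!att, ]
  heading[!att, ] <- h_oth[!att, ]

  perp <- cbind(-heading[, 2], heading[, 1])
  torso <- nose - body_len * heading
  coords <- array(NA_real_, dim = c(n_frames, length(nodes), 2),
                  dimnames = list(NULL, nodes, c("x", "y")))
  coords[, "nose", ] <- nose
  coords[, "ear_left", ] <- nose - ear_back * heading + ear_side * perp
  coords[, "ear_right", ] <- nose - ear_back * heading - ear_side * perp
  coords[, "torso", ] <- torso
  coords[, "forepaw_left", ] <- torso + 8 * heading + paw_side * perp
  coords[, "forepaw_right", ] <- torso + 8 * heading - paw_side * perp
  coords[, "hindpaw_left", ] <- torso - 8 * heading + paw_side * perp
  coords[, "hindpaw_right", ] <- torso - 8 * heading - paw_side * perp
  coords[, "tail_base", ] <- torso - tail_back * heading
  coords <- coords + noise
  # clamp into image
  coords[, , 1] <- pmin(pmax(coords[, , 1], 1), arena$image_size[1] - 1)
  coords[, , 2] <- pmin(pmax(coords[, , 2], 1), arena$image_size[2] - 1)

  ears_mid <- (coords[, "ear_left", ] + coords[, "ear_right", ]) / 2
  attending_frame <- attending_geometry(coords[, "nose", ], ears_mid, arena)

  clean <- coords
  coords[drop] <- NA_real_

  det <- data.frame(frame = which(attending_frame),
                    class = rep("attending", sum(attending_frame)),
                    x = clean[attending_frame, "nose", 1],
                    y = clean[attending_frame, "nose", 2])
  track <- structure(list(coords = coords, node_names = nodes, fps = fps),
                     class = "keypoint_track")
  truth <- list(state = state, attending_frame = attending_frame,
                detections = det, clean_coords = clean, t_s = t_s)
  list(track = track, truth = truth)
}

#' Render synthetic grayscale frames from a keypoint track
#'
#' Draws each mouse keypoint as a Gaussian blob (nose at amplitude 1, other
#' nodes at 0.7) over a faint vertical barrier line, combining everything by
#' elementwise max so the global maximum of an attending frame sits at the
#' nose. Emits one "attending" point label per true attending frame.
#'
#' @param track a `keypoint_track` (noise-free coordinates are taken from
#'   `truth` when given, else from the track).
#' @param cfg a [sim_config()].
#' @param truth ground-truth list from [gen_keypoints()]; needed for the
#'   attending labels.
#' @param scale image downscale factor relative to arena coordinates.
#' @param frames optional integer subset of frames to render.
#' @param blob_sigma Gaussian blob SD in rendered pixels.
#' @return list with `frames` (array n x H x W in [0,1]), `labels`
#'   (data.frame `frame,class,x,y` in rendered coordinates; `frame` indexes
#'   into the rendered subset), `scale`, and `frame_index` (original frame
#'   numbers).
#' @export
gen_frames <- function(track, cfg, truth, scale = 0.25, frames = NULL,
                       blob_sigma = 1.5) {
  arena <- cfg$arena
  coords <- truth$clean_coords %||% track$coords
  if (anyNA(coords)) stop("track must be finite; render from clean coordinates")
  n_all <- dim(coords)[1]
  frames <- frames %||% seq_len(n_all)
  w <- round(arena$image_size[1] * scale)
  h <- round(arena$image_size[2] * scale)
  bx <- arena$barrier_x * scale

  base <- matrix(0, h, w)
  # barrier: 1-px soft vertical line
  xs <- seq_len(w)
  line <- 0.4 * exp(-((xs - bx)^2) / 2)
  base <- matrix(rep(line, each = h), h, w)

  amp <- ifelse(skeleton_nodes() == "nose", 1, 0.7)
  half <- ceiling(3 * blob_sigma)
  out <- array(0, dim = c(length(frames), h, w))
  for (fi in seq_along(frames)) {
    f <- frames[fi]
    img <- base
    for (n in seq_along(skeleton_nodes())) {
      cx <- coords[f, n, 1] * scale
      cy <- coords[f, n, 2] * scale
      x0 <- max(1, floor(cx - half)); x1 <- min(w, ceiling(cx + half))
      y0 <- max(1, floor(cy - half)); y1 <- min(h, ceiling(cy + half))
      if (x0 > x1 || y0 > y1) next
      gx <- exp(-((x0:x1) - cx)^2 / (2 * blob_sigma^2))
      gy <- exp(-((y0:y1) - cy)^2 / (2 * blob_sigma^2))
      blob <- amp[n] * outer(gy, gx)
      img[y0:y1, x0:x1] <- pmax(img[y0:y1, x0:x1], blob)
    }
    out[fi, , ] <- img
  }
  lab <- truth$detections
  lab <- lab[lab$frame %in% frames, , drop = FALSE]
  labels <- data.frame(frame = match(lab$frame, frames), class = lab$class,
                       x = pmin(pmax(lab$x * scale, 1), w),
                       y = pmin(pmax(lab$y * scale, 1), h))
  list(frames = out, labels = labels, scale = scale, frame_index = frames)
}

# Peri-event response templates over [0, post_s] at fs Hz, peak height 1.
response_templates <- function(fs, post_s = 15) {
  t <- seq(0, post_s, by = 1 / fs)
  fast <- t / 1 * exp(1 - t / 1)          # gamma-like, peaks at 1 s
  sustained <- pmin(t / 2, 1) * exp(-t / 12)
  list(excited_fast = fast, excited_sustained = sustained,
       inhibited = -fast, flat = 0 * t)
}

#' Generate a synthetic calcium-imaging session
#'
#' Builds a neurons x time dF/F matrix at the imaging rate. Each neuron is
#' assigned one of four planted response profiles (fast excited, sustained
#' excited, inhibited, flat); its template, scaled by a per-trial-type gain,
#' is added at every cue onset on top of white Gaussian noise.
#'
#' @param cfg a [sim_config()].
#' @param sched trial schedule.
#' @param trial_gain optional numeric vector (length `n_trials`) multiplying
#'   the template per trial (e.g. to plant attending/not differences);
#'   default 1 for all trials.
#' @param animal_id animal identifier stored on the session.
#' @return list with `session` (a `neural_session`: `dff` neurons x time,
#'   `t_s`, `fs`, `events` = cue onsets, `coreg_id`, `animal`) and `truth`
#'   (`cluster` id per neuron, `sign` in -1/0/1).
#' @export
gen_neural <- function(cfg, sched, trial_gain = NULL, animal_id = "m1") {
  fs <- cfg$fs_imaging
  n_t <- ceiling(attr(sched, "duration_s") * fs)
  t_s <- (seq_len(n_t) - 1L) / fs
  tmpl <- response_templates(fs)
  trial_gain <- trial_gain %||% rep(1, nrow(sched))
  with_seed(stage_seed(cfg, "neural"), {
    cl <- sample(seq_along(tmpl), cfg$n_neurons, replace = TRUE,
                 prob = cfg$neuron_cluster_probs)
    dff <- matrix(rnorm(cfg$n_neurons * n_t, sd = cfg$neural_noise_sd),
                  cfg$n_neurons, n_t)
  })
  onset_idx <- round(sched$onset_s * fs) + 1L
  for (i in seq_len(cfg$n_neurons)) {
    kern <- tmpl[[cl[i]]] * cfg$template_amplitude
    if (all(kern == 0)) next
    for (k in seq_along(onset_idx)) {
      j <- onset_idx[k]:min(n_t, onset_idx[k] + length(kern) - 1L)
      dff[i, j] <- dff[i, j] + trial_gain[k] * kern[seq_along(j)]
    }
  }
  sign <- c(1, 1, -1, 0)[cl]
  session <- structure(list(dff = dff, t_s = t_s, fs = fs,
                            events = list(cue = sched$onset_s),
                            coreg_id = seq_len(cfg$n_neurons),
                            animal = animal_id),
                       class = "neural_session")
  list(session = session, truth = list(cluster = cl, sign = sign,
                                       template_names = names(tmpl)))
}

#' Generate a synthetic two-channel photometry session
#'
#' The signal channel carries planted neuromodulator transients at each cue
#' onset, a slow bleaching trend, a smooth shared motion artifact, and white
#' noise; the reference channel carries the same artifact scaled by
#' `photometry_artifact_gain`, its own bleach and noise, but no transients —
#' the generative model the reference-regression correction assumes.
#'
#' @param cfg a [sim_config()].
#' @param sched trial schedule.
#' @param transient_amp overrides `cfg$photometry_transient_amp` when given.
#' @param sensor sensor tag stored on the session ("DA", "OXT" or "eCB").
#' @return list with `session` (a `photometry_session`: `t_s`, `signal`,
#'   `reference`, `events`, `fs`, `sensor`) and `truth` (`transients`,
#'   `artifact` traces).
#' @export
gen_photometry <- function(cfg, sched, transient_amp = NULL, sensor = "DA") {
  fs <- cfg$fs_photometry
  n_t <- ceiling(attr(sched, "duration_s") * fs)
  t_s <- (seq_len(n_t) - 1L) / fs
  amp <- transient_amp %||% cfg$photometry_transient_amp
  with_seed(stage_seed(cfg, "photometry"), {
    innov <- rnorm(n_t)
    artifact <- as.numeric(stats::filter(innov, 0.9, method = "recursive"))
    artifact <- artifact / sd(artifact)
    noise_s <- rnorm(n_t, sd = cfg$photometry_noise_sd)
    noise_r <- rnorm(n_t, sd = cfg$photometry_noise_sd)
    amp_jit <- 1 + 0.2 * runif(nrow(sched))
  })
  # transient kernel: fast rise, 2-s decay
  kt <- seq(0, 10, by = 1 / fs)
  kern <- (1 - exp(-kt / 0.2)) * exp(-kt / 2)
  kern <- kern / max(kern)
  transients <- numeric(n_t)
  onset_idx <- round(sched$onset_s * fs) + 1L
  for (k in seq_along(onset_idx)) {
    j <- onset_idx[k]:min(n_t, onset_idx[k] + length(kern) - 1L)
    transients[j] <- transients[j] + amp * amp_jit[k] * kern[seq_along(j)]
  }
  bleach_s <- 0.3 * exp(-t_s / 2000)
  bleach_r <- 0.2 * exp(-t_s / 2500)
  signal <- transients + artifact + bleach_s + noise_s
  reference <- cfg$photometry_artifact_gain * artifact + bleach_r + noise_r
  session <- structure(list(t_s = t_s, signal = signal, reference = reference,
                            events = sched$onset_s, fs = fs, sensor = sensor),
                       class = "photometry_session")
  list(session = session,
       truth = list(transients = transients, artifact = artifact))
}

#' Generate a per-frame syllable sequence from the true bout states
#'
#' Each behavioral state emits syllables from its own categorical
#' distribution over an alphabet of `n_syllables` ids (0-based). The
#' default distributions give each state a preferred block of syllables with
#' nine-fold enrichment over the rest.
#'
#' @param cfg a [sim_config()].
#' @param states integer per-frame state vector (values in 0..K-1 or 1..K).
#' @param emission optional K x n_syllables row-stochastic matrix.
#' @return integer vector of syllable ids in `[0, n_syllables)`, plus the
#'   emission matrix as attribute `emission`.
#' @export
gen_syllables <- function(cfg, states, emission = NULL) {
  states <- as.integer(states)
  states <- states - min(states) + 1L     # 1-based
  K <- max(states)
  A <- cfg$n_syllables
  if (is.null(emission)) {
    emission <- matrix(1, K, A)
    block <- split(seq_len(A), cut(seq_len(A), K, labels = FALSE))
    for (k in seq_len(K)) emission[k, block[[k]]] <- 10
    emission <- emission / rowSums(emission)
  }
  stopifnot(nrow(emission) >= K, ncol(emission) == A,
            all(abs(rowSums(emission) - 1) < 1e-8))
  syl <- with_seed(stage_seed(cfg, "syllables"), {
    vapply(states, function(s) {
      sample.int(A, 1L, prob = emission[s, ]) - 1L
    }, integer(1))
  })
  attr(syl, "emission") <- emission
  syl
}

#' Simulate observation sequences from a Gaussian-emission HMM
#'
#' Ground-truth generator for the state-segmentation stage: K hidden states
#' with sticky transitions and spherical Gaussian emissions whose means are
#' separated by `sep` within-state standard deviations.
#'
#' @param K number of states.
#' @param n_frames sequence length.
#' @param dim observation dimensionality.
#' @param sep between-state mean separation in within-state SD units.
#' @param self_p self-transition probability.
#' @param seed integer seed.
#' @return list `obs` (matrix n x dim), `states` (1..K), `means`, `transmat`.
#' @export
gen_hmm_session <- function(K = 4, n_frames = 10000, dim = 3, sep = 5,
                            self_p = 0.95, seed = 1) {
  stopifnot(K >= 1, n_frames >= 2)
  # place means at maximally simple separated points: scaled unit directions
  means <- matrix(0, K, dim)
  for (k in seq_len(K)) {
    means[k, ((k - 1) %% dim) + 1] <- sep * ceiling(k / dim)
  }
  A <- matrix((1 - self_p) / max(K - 1, 1), K, K)
  diag(A) <- if (K == 1) 1 else self_p
  with_seed(seed, {
    states <- integer(n_frames)
    states[1] <- sample.int(K, 1)
    u <- runif(n_frames)
    for (i in 2:n_frames) {
      states[i] <- sample.int(K, 1, prob = A[states[i - 1], ])
    }
    obs <- means[states, , drop = FALSE] +
      matrix(rnorm(n_frames * dim), n_frames, dim)
  })
  list(obs = obs, states = states, means = means, transmat = A)
}
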