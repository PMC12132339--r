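#' Arena geometry configuration
#'
#' Describes the behavioral arena as seen by the overhead camera: image size,
#' the reward-port location, the x-position of the switchable barrier that
#' separates the excluded mouse from its cagemates, the zone partition of the
#' excluded-mouse half, and the two thresholds that define the attending
#' geometry (nose-to-barrier contact distance and maximum head-to-port angle).
#'
#' @param image_size integer vector (width, height) in pixels.
#' @param port_xy reward-port location (x, y) in pixels, on the far side of
#'   the barrier.
#' @param barrier_x x-coordinate of the barrier line in pixels.
#' @param zone_edges two strictly increasing x-coordinates partitioning the
#'   excluded-mouse half into 3 zones.
#' @param barrier_contact_dist maximum nose-to-barrier distance (px) for a
#'   frame to count as touching the barrier.
#' @param orient_angle_max maximum unsigned head-to-port angle (radians) for
#'   a frame to count as oriented to the port.
#' @return An object of class `arena_config`.
#' @export
arena_config <- function(image_size = c(256L, 256L),
                         port_xy = c(250, 128),
                         barrier_x = 128,
                         zone_edges = c(43, 86),
                         barrier_contact_dist = 20,
                         orient_angle_max = pi / 4) {
  stopifnot(length(image_size) == 2L, all(image_size > 0),
            length(port_xy) == 2L, length(zone_edges) == 2L)
  if (!(zone_edges[1] < zone_edges[2])) {
    stop("zone_edges must be strictly increasing", call. = FALSE)
  }
  if (any(zone_edges <= 0) || any(zone_edges >= image_size[1])) {
    stop("zone_edges must lie inside the image", call. = FALSE)
  }
  stopifnot_scalar(barrier_contact_dist, "barrier_contact_dist")
  stopifnot_scalar(orient_angle_max, "orient_angle_max")
  structure(list(image_size = as.numeric(image_size),
                 port_xy = as.numeric(port_xy),
                 barrier_x = as.numeric(barrier_x),
                 zone_edges = as.numeric(zone_edges),
                 barrier_contact_dist = as.numeric(barrier_contact_dist),
                 orient_angle_max = as.numeric(orient_angle_max)),
            class = "arena_config")
}

#' Simulation configuration for a synthetic social-exclusion session
#'
#' Bundles every parameter of the synthetic session generators. The defaults
#' encode the task structure the pipeline is designed for: 60 trials per
#' session, a 10-s tone cue, a 15-s transparent-wall window, inter-trial
#' intervals drawn uniformly from 40-60 s, an initial 245-s habituation
#' delay, 30-fps video, 10-Hz calcium imaging and 20-Hz two-channel
#' photometry.
#'
#' @param seed integer seed; a fixed seed makes every generator output
#'   byte-identical across runs.
#' @param n_trials number of trials per session.
#' @param cue_s tone-cue duration, seconds.
#' @param wall_s transparent-wall window duration, seconds (the cue ends at
#'   `cue_s`, the wall reverts at `wall_s`).
#' @param iti_range two-element range (s) of the uniform inter-trial draw.
#' @param habituation_s delay before the first cue onset, seconds.
#' @param fps_video video frame rate, Hz.
#' @param fs_imaging calcium imaging sampling rate, Hz.
#' @param fs_photometry per-channel photometry sampling rate, Hz.
#' @param arena an [arena_config()].
#' @param attend_p_cue,attend_p_iti stationary probability that the bout
#'   process is in the attending state during the cue/wall window and during
#'   the ITI, respectively.
#' @param attend_stick per-frame probability of persisting in the current
#'   bout state (controls bout durations).
#' @param missing_frac i.i.d. per-coordinate probability that a keypoint
#'   coordinate is dropped (NaN) before interpolation.
#' @param keypoint_noise_sd isotropic Gaussian jitter (px) added to keypoints.
#' @param n_neurons neurons in the synthetic calcium session.
#' @param neuron_cluster_probs mixing proportions over the four planted
#'   response profiles (fast excited, sustained excited, inhibited, flat).
#' @param template_amplitude peak template amplitude in dF/F units.
#' @param neural_noise_sd per-sample Gaussian noise of the dF/F traces.
#' @param photometry_artifact_gain gain of the shared motion artifact in the
#'   reference channel relative to the signal channel.
#' @param photometry_transient_amp amplitude of the planted neuromodulator
#'   transients (a.u.).
#' @param photometry_noise_sd per-channel measurement noise (a.u.).
#' @param n_syllables behavioral syllable alphabet size.
#' @param n_mice number of simulated animals (used by cohort-level helpers).
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(seed = 1L,
                       n_trials = 60L,
                       cue_s = 10,
                       wall_s = 15,
                       iti_range = c(40, 60),
                       habituation_s = 245,
                       fps_video = 30,
                       fs_imaging = 10,
                       fs_photometry = 20,
                       arena = arena_config(),
                       attend_p_cue = 0.7,
                       attend_p_iti = 0.05,
                       attend_stick = 0.9,
                       missing_frac = 0.05,
                       keypoint_noise_sd = 0.5,
                       n_neurons = 60L,
                       neuron_cluster_probs = c(0.3, 0.2, 0.2, 0.3),
                       template_amplitude = 3,
                       neural_noise_sd = 1,
                       photometry_artifact_gain = 1,
                       photometry_transient_amp = 2,
                       photometry_noise_sd = 0.02,
                       n_syllables = 87L,
                       n_mice = 1L) {
  stopifnot_scalar(n_trials, "n_trials")
  stopifnot_scalar(cue_s, "cue_s")
  stopifnot_scalar(wall_s, "wall_s")
  stopifnot_scalar(fps_video, "fps_video")
  stopifnot_scalar(fs_imaging, "fs_imaging")
  stopifnot_scalar(fs_photometry, "fs_photometry")
  stopifnot(length(iti_range) == 2L, iti_range[1] <= iti_range[2],
            iti_range[1] >= 0, inherits(arena, "arena_config"))
  if (attend_p_cue < 0 || attend_p_cue > 1 || attend_p_iti < 0 || attend_p_iti > 1) {
    stop("attending probabilities must lie in [0, 1]", call. = FALSE)
  }
  if (missing_frac < 0 || missing_frac >= 1) {
    stop("missing_frac must lie in [0, 1)", call. = FALSE)
  }
  stopifnot(abs(sum(neuron_cluster_probs) - 1) < 1e-8)
  structure(list(seed = as.integer(seed), n_trials = as.integer(n_trials),
                 cue_s = cue_s, wall_s = wall_s, iti_range = iti_range,
                 habituation_s = habituation_s, fps_video = fps_video,
                 fs_imaging = fs_imaging, fs_photometry = fs_photometry,
                 arena = arena, attend_p_cue = attend_p_cue,
                 attend_p_iti = attend_p_iti, attend_stick = attend_stick,
                 missing_frac = missing_frac,
                 keypoint_noise_sd = keypoint_noise_sd,
                 n_neurons = as.integer(n_neurons),
                 neuron_cluster_probs = neuron_cluster_probs,
                 template_amplitude = template_amplitude,
                 neural_noise_sd = neural_noise_sd,
                 photometry_artifact_gain = photometry_artifact_gain,
                 photometry_transient_amp = photometry_transient_amp,
                 photometry_noise_sd = photometry_noise_sd,
                 n_syllables = as.integer(n_syllables),
                 n_mice = as.integer(n_mice)),
            class = "sim_config")
}

# Stage-specific RNG offsets; each generator gets its own reproducible
# stream derived from the config seed.
.seed_offset <- c(schedule = 101L, keypoints = 202L, frames = 303L,
                  neural = 404L, photometry = 505L, syllables = 606L)

stage_seed <- function(cfg, stage) {
  (cfg$seed * 7L + .seed_offset[[stage]]) %% .Machine$integer.max
}
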