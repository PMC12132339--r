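#' Default pipeline configuration
#'
#' Nested list of per-stage parameter blocks; unknown keys passed to
#' [run_pipeline()] are rejected. The configuration can be stored as YAML
#' and the fully resolved version is written next to the outputs.
#'
#' @return named list of stage blocks.
#' @export
default_pipeline_config <- function() {
  list(
    seed = 1L,
    condition = "SE",
    stages = c("simulate", "features", "detect", "label_trials",
               "photometry"),
    simulate = list(n_trials = 60L, missing_frac = 0.05),
    features = list(smooth_window = 5L),
    detect = list(epochs = 15L, conf_thresh = 0.5, radius_px = 16,
                  sigma = 2, max_train_frames = 300L),
    label_trials = list(mode = "local", k = 15L),
    photometry = list(auc_window = c(0, 20), decode = FALSE)
  )
}

merge_config <- function(user, defaults) {
  unknown <- setdiff(names(user), names(defaults))
  if (length(unknown)) {
    stop("unknown config keys: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  for (nm in names(user)) {
    if (is.list(defaults[[nm]]) && is.list(user[[nm]])) {
      allowed <- names(defaults[[nm]])
      if (nm == "simulate") {
        allowed <- setdiff(names(formals(sim_config)), "seed")
      }
      sub_unknown <- setdiff(names(user[[nm]]), allowed)
      if (length(sub_unknown)) {
        stop("unknown config keys in `", nm, "`: ",
             paste(sub_unknown, collapse = ", "), call. = FALSE)
      }
      defaults[[nm]] <- modifyList(defaults[[nm]], user[[nm]])
    } else {
      defaults[[nm]] <- user[[nm]]
    }
  }
  defaults
}

#' Run the synthetic end-to-end pipeline
#'
#' Executes the requested stages in dependency order on a synthetic
#' session: simulate (schedule, keypoints, photometry), features
#' (preprocess + feature extraction + z-scoring), detect (render frames,
#' train the heatmap detector, classify), label_trials (attending
#' quantification, median labels, extreme trials) and photometry
#' (reference regression + AUC). Every stage writes plain-text outputs
#' under `out_dir`; a JSON manifest records stage order, output file
#' hashes, wall time and warnings. No stage mutates its inputs.
#'
#' @param config list overriding [default_pipeline_config()] entries, or a
#'   YAML file path.
#' @param out_dir output directory (created).
#' @return A `run_manifest` list (also written to `manifest.json`).
#' @export
run_pipeline <- function(config = list(), out_dir = tempfile("fomopipe_run_")) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  cfg <- merge_config(config, default_pipeline_config())
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  jsonlite::write_json(cfg, file.path(out_dir, "config.resolved.json"),
                       auto_unbox = TRUE, digits = NA)
  manifest <- list(stages = list())
  warns <- character(0)
  state <- new.env(parent = emptyenv())

  stage_run <- function(name, outputs, fn) {
    t0 <- proc.time()[["elapsed"]]
    res <- withCallingHandlers(fn(), warning = function(w) {
      warns <<- c(warns, sprintf("%s: %s", name, conditionMessage(w)))
      invokeRestart("muffleWarning")
    })
    files <- file.path(out_dir, outputs)
    manifest$stages[[name]] <<- list(
      outputs = outputs,
      md5 = unname(tools::md5sum(files[file.exists(files)])),
      wall_s = proc.time()[["elapsed"]] - t0)
    res
  }

  stages <- cfg$stages
  need <- function(s, dep) {
    if (s %in% stages && !dep %in% stages) {
      stop(sprintf("stage '%s' requires stage '%s'", s, dep), call. = FALSE)
    }
  }
  need("features", "simulate"); need("detect", "simulate")
  need("label_trials", "detect"); need("photometry", "simulate")

  if ("simulate" %in% stages) {
    stage_run("simulate", c("schedule.csv", "keypoints.csv"), function() {
      sim <- do.call(sim_config, c(list(seed = cfg$seed), cfg$simulate))
      state$sim <- sim
      state$sched <- gen_schedule(sim)
      kp <- gen_keypoints(sim, state$sched)
      state$track <- kp$track; state$truth <- kp$truth
      write_schedule_csv(state$sched, file.path(out_dir, "schedule.csv"))
      write_keypoints_csv(kp$track, file.path(out_dir, "keypoints.csv"))
    })
  }
  if ("features" %in% stages) {
    stage_run("features", "features.csv", function() {
      pre <- preprocess_keypoints(state$track, cfg$features$smooth_window)
      fm <- compute_features(pre, state$sim$arena)
      state$fm_raw <- fm
      state$fm <- zscore_features(fm)
      write_features_csv(state$fm, file.path(out_dir, "features.csv"))
    })
  }
  if ("detect" %in% stages) {
    stage_run("detect", c("detections.csv", "ethogram.csv"), function() {
      n_frames <- dim(state$track$coords)[1]
      n_train <- min(cfg$detect$max_train_frames, n_frames)
      train_idx <- with_seed(cfg$seed + 11L, sort(sample.int(n_frames, n_train)))
      fr <- gen_frames(state$track, state$sim, state$truth,
                       frames = train_idx)
      dcfg <- detector_config(input_size = dim(fr$frames)[2:3],
                              epochs = cfg$detect$epochs, seed = cfg$seed)
      tg <- make_heatmap_targets(fr$labels, dim(fr$frames)[1],
                                 dim(fr$frames)[2:3],
                                 sigma = cfg$detect$sigma,
                                 stride = detector_stride(dcfg))
      model <- train_detector(fr$frames, tg, dcfg)
      state$detector <- model
      # only frames inside the per-trial analysis windows feed the trial
      # quantification; render and classify just those
      tw <- trial_windows(state$sched, state$sim$fps_video, n_frames)
      need <- sort(unique(unlist(mapply(seq, tw$start, tw$end,
                                        SIMPLIFY = FALSE))))
      win_fr <- gen_frames(state$track, state$sim, state$truth,
                           frames = need)
      cls <- classify_frames(model, win_fr$frames,
                             conf_thresh = cfg$detect$conf_thresh,
                             radius_px = cfg$detect$radius_px)
      state$ethogram <- rep(FALSE, n_frames)
      state$ethogram[need] <- cls$ethogram[, 1]
      cls$detections$frame <- need[cls$detections$frame]
      write.csv(cls$detections, file.path(out_dir, "detections.csv"),
                row.names = FALSE)
      write.csv(data.frame(frame = seq_along(state$ethogram),
                           attending = as.integer(state$ethogram)),
                file.path(out_dir, "ethogram.csv"), row.names = FALSE)
    })
  }
  if ("label_trials" %in% stages) {
    stage_run("label_trials", "trial_labels.csv", function() {
      att <- quantify_attending(state$ethogram, state$sched,
                                state$sim$fps_video)
      lab <- label_trials(att$total_delta, mode = cfg$label_trials$mode)
      ext <- select_extreme_trials(att$total_count, cfg$label_trials$k)
      out <- cbind(att, label = lab$label, threshold = lab$threshold,
                   in_top = att$trial %in% ext$top,
                   in_bottom = att$trial %in% ext$bottom)
      state$attendance <- out
      write.csv(out, file.path(out_dir, "trial_labels.csv"),
                row.names = FALSE)
    })
  }
  if ("photometry" %in% stages) {
    stage_run("photometry", "photometry_auc.csv", function() {
      pm <- gen_photometry(state$sim, state$sched)
      ct <- regress_reference(pm$session, state$sched)
      auc <- trial_auc(ct, window = cfg$photometry$auc_window)
      write.csv(data.frame(trial = seq_along(auc$auc), auc = auc$auc),
                file.path(out_dir, "photometry_auc.csv"), row.names = FALSE)
      state$photometry_auc <- auc
    })
  }
  manifest$warnings <- warns
  manifest$out_dir <- out_dir
  manifest$config <- cfg
  class(manifest) <- "run_manifest"
  jsonlite::write_json(
    list(stages = manifest$stages, warnings = warns),
    file.path(out_dir, "manifest.json"), auto_unbox = TRUE, digits = NA)
  manifest$state <- state
  manifest
}
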