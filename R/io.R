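# Plain-text file adapters: keypoints and features as CSV with JSON
# sidecars, schedules/events as CSV, models and manifests as JSON,
# configuration as YAML.

#' Write / read a keypoint track as long-form CSV
#'
#' Layout: columns `frame`, `node`, `x`, `y`; a JSON sidecar
#' (`<path>.meta.json`) stores `fps` and node order.
#'
#' @param track a `keypoint_track`.
#' @param path CSV path.
#' @return `path`, invisibly.
#' @export
write_keypoints_csv <- function(track, path) {
  d <- dim(track$coords)
  df <- data.frame(
    frame = rep(seq_len(d[1]), times = d[2]),
    node = rep(track$node_names, each = d[1]),
    x = as.vector(track$coords[, , 1]),
    y = as.vector(track$coords[, , 2]))
  write.csv(df, path, row.names = FALSE)
  jsonlite::write_json(list(fps = track$fps, node_names = track$node_names),
                       paste0(path, ".meta.json"), auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_keypoints_csv
#' @param path CSV path written by [write_keypoints_csv()].
#' @export
read_keypoints_csv <- function(path) {
  meta <- jsonlite::read_json(paste0(path, ".meta.json"),
                              simplifyVector = TRUE)
  df <- read.csv(path)
  nodes <- meta$node_names
  n <- max(df$frame)
  coords <- array(NA_real_, dim = c(n, length(nodes), 2),
                  dimnames = list(NULL, nodes, c("x", "y")))
  for (nd in nodes) {
    sub <- df[df$node == nd, ]
    coords[sub$frame, nd, 1] <- sub$x
    coords[sub$frame, nd, 2] <- sub$y
  }
  structure(list(coords = coords, node_names = nodes, fps = meta$fps),
            class = "keypoint_track")
}

#' Write / read a trial schedule as CSV
#' @param sched a `trial_schedule`.
#' @param path CSV path.
#' @export
write_schedule_csv <- function(sched, path) {
  write.csv(as.data.frame(sched)[, c("trial", "onset_s")], path,
            row.names = FALSE)
  jsonlite::write_json(list(cue_s = attr(sched, "cue_s"),
                            wall_s = attr(sched, "wall_s"),
                            duration_s = attr(sched, "duration_s")),
                       paste0(path, ".meta.json"), auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_schedule_csv
#' @export
read_schedule_csv <- function(path) {
  df <- read.csv(path)
  meta <- jsonlite::read_json(paste0(path, ".meta.json"),
                              simplifyVector = TRUE)
  attr(df, "cue_s") <- meta$cue_s
  attr(df, "wall_s") <- meta$wall_s
  attr(df, "duration_s") <- meta$duration_s
  class(df) <- c("trial_schedule", "data.frame")
  df
}

#' Write / read a feature matrix as CSV with a JSON kind sidecar
#' @param fm a `feature_matrix`.
#' @param path CSV path.
#' @export
write_features_csv <- function(fm, path) {
  write.csv(as.data.frame(fm$values), path, row.names = FALSE)
  jsonlite::write_json(list(kinds = as.list(stats::setNames(fm$kinds,
                                                            fm$feature_names)),
                            fps = fm$fps, zscored = fm$zscored),
                       paste0(path, ".meta.json"), auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_features_csv
#' @export
read_features_csv <- function(path) {
  vals <- as.matrix(read.csv(path))
  meta <- jsonlite::read_json(paste0(path, ".meta.json"),
                              simplifyVector = TRUE)
  structure(list(values = vals, feature_names = colnames(vals),
                 kinds = unname(unlist(meta$kinds)[colnames(vals)]),
                 fps = meta$fps, zscored = meta$zscored),
            class = "feature_matrix")
}

#' Validate pipeline input files against their expected schemas
#'
#' Report-only check of events CSVs (required columns, strictly increasing
#' onsets) and keypoint CSVs (9-node skeleton, finite frame index).
#'
#' @param paths named list/vector; recognized names: `events`, `keypoints`.
#' @return data.frame of violations (`file`, `problem`); zero rows when
#'   everything is well-formed.
#' @export
validate_inputs <- function(paths) {
  viol <- list()
  note <- function(f, p) viol[[length(viol) + 1L]] <<- data.frame(
    file = f, problem = p)
  if (!is.null(paths$events)) {
    f <- paths$events
    if (!file.exists(f)) {
      note(f, "file does not exist")
    } else {
      df <- tryCatch(read.csv(f), error = function(e) NULL)
      if (is.null(df) || !all(c("trial", "onset_s") %in% names(df))) {
        note(f, "missing required columns trial, onset_s")
      } else if (is.unsorted(df$onset_s, strictly = TRUE)) {
        note(f, "onset_s not strictly increasing")
      }
    }
  }
  if (!is.null(paths$keypoints)) {
    f <- paths$keypoints
    if (!file.exists(f)) {
      note(f, "file does not exist")
    } else {
      tr <- tryCatch(read_keypoints_csv(f), error = function(e) NULL)
      if (is.null(tr)) {
        note(f, "unreadable keypoint CSV (or missing .meta.json sidecar)")
      } else if (length(tr$node_names) != 9L) {
        note(f, sprintf("expected 9 skeleton nodes, found %d",
                        length(tr$node_names)))
      }
    }
  }
  if (length(viol) == 0) {
    return(data.frame(file = character(0), problem = character(0)))
  }
  do.call(rbind, viol)
}
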