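# Shared fixtures, built once per test run.

fixture_env <- new.env(parent = emptyenv())

# short session with keypoints + schedule (no missing coords, no smoothing
# distortion) used across feature / detector tests
short_session <- function() {
  if (is.null(fixture_env$short)) {
    cfg <- sim_config(seed = 3, n_trials = 6, habituation_s = 10,
                      missing_frac = 0)
    sched <- gen_schedule(cfg)
    kp <- gen_keypoints(cfg, sched)
    fixture_env$short <- list(cfg = cfg, sched = sched, track = kp$track,
                              truth = kp$truth)
  }
  fixture_env$short
}

# hand-built feature_matrix wrapper
make_fm <- function(values, kinds, fps = 30, zscored = FALSE) {
  structure(list(values = values, feature_names = colnames(values),
                 kinds = kinds, fps = fps, zscored = zscored),
            class = "feature_matrix")
}

# hand-built corrected_trace wrapper (trials x samples at fs Hz over
# [t0, t1))
make_ct <- function(z, fs = 20, t0 = -5) {
  structure(list(z = z, time = t0 + (seq_len(ncol(z)) - 1) / fs,
                 corrected = as.vector(t(z)), slope = 0, intercept = 0,
                 onsets = seq_len(nrow(z)), fs = fs, sensor = "DA"),
            class = "corrected_trace")
}

# exhaustive NMS oracle: strict 8-neighborhood local maxima >= threshold,
# greedy suppression by descending confidence (ties by row then column),
# Euclidean radius, inclusive
nms_oracle <- function(map, conf_thresh, radius) {
  h <- nrow(map); w <- ncol(map)
  peaks <- list()
  for (r in seq_len(h)) for (cc in seq_len(w)) {
    v <- map[r, cc]
    if (v < conf_thresh) next
    ok <- TRUE
    for (dr in -1:1) for (dc in -1:1) {
      if (dr == 0 && dc == 0) next
      rr <- r + dr; ccc <- cc + dc
      if (rr >= 1 && rr <= h && ccc >= 1 && ccc <= w &&
          map[rr, ccc] >= v) ok <- FALSE
    }
    if (ok) peaks[[length(peaks) + 1L]] <- c(r, cc, v)
  }
  if (length(peaks) == 0) {
    return(data.frame(x = numeric(0), y = numeric(0), conf = numeric(0)))
  }
  pk <- do.call(rbind, peaks)
  ord <- order(-pk[, 3], pk[, 1], pk[, 2])
  pk <- pk[ord, , drop = FALSE]
  keep <- logical(nrow(pk))
  for (i in seq_len(nrow(pk))) {
    if (!any(keep)) { keep[i] <- TRUE; next }
    ki <- which(keep)
    d <- sqrt((pk[ki, 1] - pk[i, 1])^2 + (pk[ki, 2] - pk[i, 2])^2)
    keep[i] <- all(d > radius)
  }
  data.frame(x = pk[keep, 2], y = pk[keep, 1], conf = pk[keep, 3])
}

# permutation-matched accuracy of a decoded state sequence
perm_match_acc <- function(truth, decoded, K) {
  perms <- function(v) {
    if (length(v) <= 1) return(list(v))
    out <- list()
    for (i in seq_along(v)) {
      for (p in perms(v[-i])) out[[length(out) + 1L]] <- c(v[i], p)
    }
    out
  }
  max(vapply(perms(seq_len(K)), function(p) {
    mean(p[truth] == decoded)
  }, numeric(1)))
}

# adjusted Rand index between two labelings
adjusted_rand <- function(a, b) {
  tab <- table(a, b)
  comb2 <- function(x) x * (x - 1) / 2
  sij <- sum(comb2(tab))
  si <- sum(comb2(rowSums(tab)))
  sj <- sum(comb2(colSums(tab)))
  n2 <- comb2(sum(tab))
  exp_idx <- si * sj / n2
  (sij - exp_idx) / ((si + sj) / 2 - exp_idx)
}
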