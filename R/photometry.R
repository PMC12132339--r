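# Two-channel biosensor photometry: forward median filtering, reference
# regression on trial-averaged baseline windows, per-trial z-transform,
# trial AUC metrics, and random-forest decoding of trial labels.

#' Forward-only (trailing) median filter
#'
#' Causal median over the trailing `span_s` seconds; the first samples use
#' the available partial window.
#'
#' @param x numeric trace.
#' @param fs sampling rate, Hz.
#' @param span_s filter span, seconds (default 200 ms).
#' @return filtered trace, same length.
#' @export
pm_median_filter <- function(x, fs, span_s = 0.2) {
  width <- max(1L, round(span_s * fs))
  if (width == 1L) return(x)
  zoo::rollapplyr(x, width = width, FUN = median, partial = TRUE)
}

#' Reference-channel regression and per-trial z-transform
#'
#' Both channels are median-filtered, then the regression coefficients
#' (reference -> signal) are estimated by ordinary least squares on the
#' trial-averaged baseline segments (-1 to 0 s from each cue onset) to keep
#' stimulus-evoked transients out of the fit. The fitted reference
#' projection is subtracted from the signal over the whole session, the
#' corrected trace is cut into per-trial windows and each trial is
#' z-transformed on its own -1 to 0 s baseline.
#'
#' @param sess a `photometry_session`.
#' @param sched trial schedule (or numeric onset times).
#' @param fit_win regression window relative to onset, seconds.
#' @param trial_win per-trial extraction window, seconds.
#' @param base_win per-trial z-scoring baseline, seconds.
#' @param filter_span_s median-filter span; 0 disables filtering.
#' @return A `corrected_trace`: list `z` (trials x samples), `time`
#'   (relative seconds), `corrected` (full-session trace), `slope`,
#'   `intercept`, `onsets`, `fs`.
#' @export
regress_reference <- function(sess, sched, fit_win = c(-1, 0),
                              trial_win = c(-5, 20), base_win = c(-1, 0),
                              filter_span_s = 0.2) {
  stopifnot(inherits(sess, "photometry_session"))
  onsets <- if (inherits(sched, "trial_schedule")) sched$onset_s else sched
  if (length(onsets) < 2) stop("need at least 2 trials", call. = FALSE)
  fs <- sess$fs
  sig <- sess$signal; ref <- sess$reference
  if (filter_span_s > 0) {
    sig <- pm_median_filter(sig, fs, filter_span_s)
    ref <- pm_median_filter(ref, fs, filter_span_s)
  }
  n <- length(sig)
  rel_fit <- seq(round(fit_win[1] * fs), round(fit_win[2] * fs) - 1L)
  onset_idx <- round(onsets * fs) + 1L
  ok <- onset_idx + min(rel_fit) >= 1L & onset_idx + max(rel_fit) <= n
  if (!all(ok)) stop("fit windows exceed the recording", call. = FALSE)
  seg_sig <- vapply(onset_idx, function(o) sig[o + rel_fit],
                    numeric(length(rel_fit)))
  seg_ref <- vapply(onset_idx, function(o) ref[o + rel_fit],
                    numeric(length(rel_fit)))
  avg_sig <- rowMeans(seg_sig)
  avg_ref <- rowMeans(seg_ref)
  if (var(avg_ref) <= .Machine$double.eps) {
    warning("reference has no variance in the fit window; slope set to 0")
    slope <- 0
    intercept <- mean(avg_sig)
  } else {
    cf <- stats::coef(stats::lm(avg_sig ~ avg_ref))
    intercept <- cf[[1]]; slope <- cf[[2]]
  }
  corrected <- sig - (slope * ref + intercept)

  rel <- seq(round(trial_win[1] * fs), round(trial_win[2] * fs))
  time <- rel / fs
  if (any(onset_idx + min(rel) < 1L) || any(onset_idx + max(rel) > n)) {
    stop("trial windows exceed the recording", call. = FALSE)
  }
  zmat <- t(vapply(onset_idx, function(o) corrected[o + rel],
                   numeric(length(rel))))
  bmask <- time >= base_win[1] & time < base_win[2]
  bm <- rowMeans(zmat[, bmask, drop = FALSE])
  bs <- apply(zmat[, bmask, drop = FALSE], 1, sd)
  if (any(bs == 0)) warning("zero baseline SD in ", sum(bs == 0), " trial(s)")
  z <- (zmat - bm) / bs
  structure(list(z = z, time = time, corrected = corrected, slope = slope,
                 intercept = intercept, onsets = onsets, fs = fs,
                 sensor = sess$sensor),
            class = "corrected_trace")
}

#' Trial AUC of the corrected z-trace
#'
#' Trapezoidal area under each trial's z-trace over a sensor-specific
#' window (0-20 s for dopamine and oxytocin sensors, 0-15 s for the
#' endocannabinoid sensor). When labels are supplied, also returns the
#' label-averaged trace and AUC.
#'
#' @param ct a `corrected_trace`.
#' @param window AUC window (start, end), seconds post cue.
#' @param labels optional per-trial labels (e.g. attending/not_attending).
#' @return list `auc` (per trial), `window`, and when labeled, `by_label`
#'   (data.frame label/mean_auc/n) and `mean_trace` per label.
#' @export
trial_auc <- function(ct, window = c(0, 20), labels = NULL) {
  stopifnot(inherits(ct, "corrected_trace"))
  if (window[1] < min(ct$time) || window[2] > max(ct$time) + 1 / ct$fs) {
    stop("AUC window exceeds the extracted trace", call. = FALSE)
  }
  mask <- ct$time >= window[1] & ct$time <= window[2]
  tt <- ct$time[mask]
  auc <- apply(ct$z[, mask, drop = FALSE], 1, function(v) {
    pracma::trapz(tt, v)
  })
  out <- list(auc = auc, window = window)
  if (!is.null(labels)) {
    stopifnot(length(labels) == nrow(ct$z))
    out$by_label <- do.call(rbind, lapply(unique(labels), function(l) {
      data.frame(label = l, mean_auc = mean(auc[labels == l]),
                 n = sum(labels == l))
    }))
    out$mean_trace <- lapply(split(seq_along(labels), labels), function(ii) {
      colMeans(ct$z[ii, , drop = FALSE])
    })
  }
  out
}

#' Random-forest decoding of trial labels from photometry z-traces
#'
#' Samples are (trial, timepoint) pairs within the decoding window, with
#' the z-value and the timepoint as predictors. Cross-validation folds are
#' stratified at the trial level so no trial's timepoints leak between
#' training and testing; pooled held-out class votes yield a single ROC.
#' The shuffled control permutes training-trial labels within the same
#' folds.
#'
#' @param ct a `corrected_trace`.
#' @param labels per-trial labels, exactly two classes.
#' @param window decoding window, seconds post cue.
#' @param folds cross-validation folds.
#' @param seed integer seed (folds, forest, shuffle).
#' @param ntree trees per forest.
#' @param shuffle_control run the shuffled-label twin.
#' @return A `decoding_result` list: `auroc`, `fold` assignment per trial,
#'   `shuffled` (auroc under shuffled training labels).
#' @export
rf_decode <- function(ct, labels, window = c(0, 15), folds = 5L, seed = 1L,
                      ntree = 500L, shuffle_control = TRUE) {
  stopifnot(inherits(ct, "corrected_trace"))
  labels <- as.character(labels)
  stopifnot(length(labels) == nrow(ct$z))
  classes <- sort(unique(labels))
  if (length(classes) != 2) stop("need exactly two classes", call. = FALSE)
  mask <- ct$time >= window[1] & ct$time <= window[2]
  tt <- ct$time[mask]
  fold <- stratified_folds(labels, folds, seed)
  run <- function(shuffle) {
    votes <- rep(NA_real_, length(labels) * length(tt))
    resp <- rep(NA_character_, length(labels) * length(tt))
    pos <- 0L
    for (f in seq_len(folds)) {
      tr <- which(fold != f); te <- which(fold == f)
      ytr <- labels[tr]
      if (shuffle) ytr <- with_seed(seed + 91L * f, sample(ytr))
      xtr <- data.frame(
        z = as.vector(t(ct$z[tr, mask, drop = FALSE])),
        t = rep(tt, times = length(tr)))
      yy <- factor(rep(ytr, each = length(tt)), levels = classes)
      xte <- data.frame(
        z = as.vector(t(ct$z[te, mask, drop = FALSE])),
        t = rep(tt, times = length(te)))
      fit <- with_seed(seed + f, {
        randomForest::randomForest(xtr, yy, ntree = ntree)
      })
      pr <- predict(fit, xte, type = "prob")[, classes[2]]
      ii <- pos + seq_along(pr)
      votes[ii] <- pr
      resp[ii] <- rep(labels[te], each = length(tt))
      pos <- pos + length(pr)
    }
    auc_value(resp[seq_len(pos)], votes[seq_len(pos)], classes[2])
  }
  out <- list(auroc = run(FALSE), fold = fold, classes = classes,
              window = window)
  if (shuffle_control) out$shuffled <- list(auroc = run(TRUE))
  class(out) <- "rf_decoding_result"
  out
}
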