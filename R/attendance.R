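#' Per-trial attending-frame quantification
#'
#' Counts positive ethogram frames in the 5-s pre-cue baseline and in each
#' of the three 5-s bins covering 0-15 s post cue, normalizes each bin to
#' baseline (delta = bin count - baseline count) and sums the three deltas
#' into the trial's total delta attending frames.
#'
#' @param ethogram logical per-frame vector (one behavior class).
#' @param sched trial schedule.
#' @param fps ethogram frame rate, Hz.
#' @return A `trial_attendance` data.frame: `trial`, `baseline`, `bin1-3`
#'   raw counts, `dbin1-3`, `total_delta`, `total_count` (0-15 s raw count).
#' @export
quantify_attending <- function(ethogram, sched, fps) {
  ethogram <- as.logical(ethogram)
  tw <- trial_windows(sched, fps, length(ethogram))
  count_win <- function(s, e) sum(ethogram[s:e])
  res <- do.call(rbind, lapply(split(tw, tw$trial), function(w) {
    w <- w[order(match(w$window, c("baseline", "bin1", "bin2", "bin3"))), ]
    cnt <- mapply(count_win, w$start, w$end)
    data.frame(trial = w$trial[1], baseline = cnt[1], bin1 = cnt[2],
               bin2 = cnt[3], bin3 = cnt[4],
               dbin1 = cnt[2] - cnt[1], dbin2 = cnt[3] - cnt[1],
               dbin3 = cnt[4] - cnt[1])
  }))
  res$total_delta <- res$dbin1 + res$dbin2 + res$dbin3
  res$total_count <- res$bin1 + res$bin2 + res$bin3
  res <- res[order(res$trial), ]
  rownames(res) <- NULL
  class(res) <- c("trial_attendance", "data.frame")
  res
}

#' Label trials attending / not-attending by a median threshold
#'
#' Global mode pools every trial of every animal and condition and takes
#' the median as a single threshold; local mode takes the median per animal
#' (across that animal's conditions). A trial is labeled attending iff its
#' value is strictly greater than the applicable threshold.
#'
#' @param values numeric attending-frame values per trial (typically the
#'   total delta from [quantify_attending()]).
#' @param animal animal id per trial (required for local mode; a single
#'   animal may be omitted).
#' @param mode "global" or "local".
#' @return data.frame `animal`, `value`, `label` ("attending"/
#'   "not_attending"), `threshold`, `mode`.
#' @export
label_trials <- function(values, animal = NULL, mode = c("global", "local")) {
  mode <- match.arg(mode)
  if (length(values) == 0) stop("no trials to label", call. = FALSE)
  animal <- animal %||% rep("a1", length(values))
  stopifnot(length(animal) == length(values))
  if (mode == "global") {
    thr <- rep(median(values), length(values))
  } else {
    med <- tapply(values, animal, median)
    thr <- as.numeric(med[as.character(animal)])
  }
  data.frame(animal = animal, value = values,
             label = ifelse(values > thr, "attending", "not_attending"),
             threshold = thr, mode = mode)
}

#' Select the top-k and bottom-k trials by attending count
#'
#' Top trials are taken by descending count (ties broken by earlier trial
#' index); bottom trials by ascending count among the remaining trials
#' (ties again by earlier index), so the two sets are always disjoint.
#'
#' @param counts per-trial attending counts.
#' @param k trials per extreme (default 15).
#' @return list `top`, `bottom`: integer index vectors of length `k`.
#' @export
select_extreme_trials <- function(counts, k = 15L) {
  n <- length(counts)
  if (n < 2L * k) {
    stop(sprintf("need at least %d trials, got %d", 2L * k, n), call. = FALSE)
  }
  ord_desc <- order(-counts, seq_len(n))
  top <- ord_desc[seq_len(k)]
  ord_asc <- order(counts, seq_len(n))
  bottom <- setdiff(ord_asc, top)[seq_len(k)]
  list(top = top, bottom = bottom)
}

#' Lick-bout quantification from a binary ethogram
#'
#' Bouts are maximal runs of positive frames; consecutive runs separated by
#' fewer than `gap_frames` negative frames merge into one bout. Duration is
#' total positive frames divided by the frame rate.
#'
#' @param ethogram logical per-frame lick vector.
#' @param fps frame rate, Hz.
#' @param gap_frames minimum negative gap separating bouts.
#' @return list `n_bouts`, `duration_s`, `bouts` (data.frame start/end).
#' @export
quantify_licks <- function(ethogram, fps = 30, gap_frames = 10L) {
  ethogram <- as.logical(ethogram)
  r <- rle(ethogram)
  if (!any(ethogram)) {
    return(list(n_bouts = 0L, duration_s = 0,
                bouts = data.frame(start = integer(0), end = integer(0))))
  }
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  pos <- which(r$values)
  b_start <- starts[pos]; b_end <- ends[pos]
  # merge across short gaps
  merged_s <- b_start[1]; merged_e <- b_end[1]
  for (i in seq_along(b_start)[-1]) {
    if (b_start[i] - merged_e[length(merged_e)] - 1L < gap_frames) {
      merged_e[length(merged_e)] <- b_end[i]
    } else {
      merged_s <- c(merged_s, b_start[i]); merged_e <- c(merged_e, b_end[i])
    }
  }
  list(n_bouts = length(merged_s), duration_s = sum(ethogram) / fps,
       bouts = data.frame(start = merged_s, end = merged_e))
}
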