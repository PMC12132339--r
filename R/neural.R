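# Peri-event calcium analysis: z-scored PSTHs, Wilcoxon responsiveness,
# Ward/correlation ensemble clustering, train-set-only PCA decoding with
# ROC-over-time, and trajectory geometry in component space.

#' Peri-event z-scored PSTH
#'
#' Extracts per neuron-trial windows of `pre` s before to `post` s after
#' each event at the imaging rate and z-scores each trace as
#' (F(t) - Fm) / SD with Fm and SD taken from the baseline window
#' (default -1 to 0 s). Neuron-trials with zero baseline SD are flagged and
#' excluded (their z is NA).
#'
#' @param sess a `neural_session`.
#' @param events event times in seconds (default the session's cue onsets).
#' @param pre,post window extent, seconds.
#' @param base baseline window (start, end) relative to onset, seconds;
#'   samples in `[start, end)` are used.
#' @return A `psth`: list `z` and `raw` arrays (neurons x trials x bins),
#'   `time` (bin times relative to onset), `fs`, `degenerate`
#'   (neuron x trial logical).
#' @export
compute_psth <- function(sess, events = NULL, pre = 5, post = 15,
                         base = c(-1, 0)) {
  stopifnot(inherits(sess, "neural_session"))
  events <- events %||% sess$events[[1]]
  fs <- sess$fs
  rel <- seq(-round(pre * fs), round(post * fs) - 1L)
  time <- rel / fs
  onset_idx <- round(events * fs) + 1L
  n_t <- ncol(sess$dff)
  if (any(onset_idx + min(rel) < 1L) || any(onset_idx + max(rel) > n_t)) {
    stop("event windows exceed the recording", call. = FALSE)
  }
  nn <- nrow(sess$dff); ntr <- length(events); nb <- length(rel)
  raw <- array(NA_real_, dim = c(nn, ntr, nb))
  for (k in seq_len(ntr)) {
    raw[, k, ] <- sess$dff[, onset_idx[k] + rel, drop = FALSE]
  }
  bmask <- time >= base[1] & time < base[2]
  z <- raw
  degenerate <- matrix(FALSE, nn, ntr)
  for (k in seq_len(ntr)) {
    bm <- raw[, k, bmask, drop = FALSE]
    fm <- apply(bm, 1, mean)
    sdv <- apply(bm, 1, sd)
    bad <- !is.finite(sdv) | sdv == 0
    degenerate[, k] <- bad
    sdv[bad] <- NA_real_
    z[, k, ] <- (raw[, k, ] - fm) / sdv
  }
  structure(list(z = z, raw = raw, time = time, fs = fs,
                 degenerate = degenerate),
            class = "psth")
}

#' Wilcoxon responsiveness calls
#'
#' Paired Wilcoxon signed-rank test of per-trial mean activity in a 5-s
#' baseline window against a 5-s event window, per neuron; significant
#' neurons are called excited or inhibited by the sign of their mean
#' z-score over the 0-15 s response window.
#'
#' @param psth a `psth`.
#' @param alpha significance level (raw, uncorrected by default).
#' @param base_win,event_win 5-s comparison windows, seconds.
#' @param sign_win window whose mean z sets the call sign.
#' @param adjust optional p-value adjustment method (e.g. "BH"); "none"
#'   keeps raw p-values.
#' @return A `responsiveness` data.frame: `neuron`, `p`, `mean_z`, `call`.
#' @export
call_responsive <- function(psth, alpha = 0.05, base_win = c(-5, 0),
                            event_win = c(0, 5), sign_win = c(0, 15),
                            adjust = "none") {
  stopifnot(inherits(psth, "psth"))
  ntr <- dim(psth$raw)[2]
  if (ntr < 6) stop("too few trials for the signed-rank test", call. = FALSE)
  bm <- psth$time >= base_win[1] & psth$time < base_win[2]
  em <- psth$time >= event_win[1] & psth$time < event_win[2]
  sm <- psth$time >= sign_win[1] & psth$time < sign_win[2]
  nn <- dim(psth$raw)[1]
  p <- numeric(nn); mz <- numeric(nn)
  for (i in seq_len(nn)) {
    b <- apply(psth$raw[i, , bm, drop = FALSE], 2, mean)
    e <- apply(psth$raw[i, , em, drop = FALSE], 2, mean)
    p[i] <- tryCatch(
      suppressWarnings(wilcox.test(e, b, paired = TRUE)$p.value),
      error = function(err) NA_real_)
    mz[i] <- mean(psth$z[i, , sm], na.rm = TRUE)
  }
  padj <- stats::p.adjust(p, method = adjust)
  call <- ifelse(!is.na(padj) & padj < alpha,
                 ifelse(mz > 0, "excited", "inhibited"), "none")
  structure(data.frame(neuron = seq_len(nn), p = padj, mean_z = mz,
                       call = call),
            class = c("responsiveness", "data.frame"))
}

#' Hierarchical ensemble clustering of mean response profiles
#'
#' Ward linkage on correlation distance (1 - Pearson correlation between
#' neuron mean-response vectors, concatenated across conditions), cut at
#' 30% of the maximum linkage height. Constant profiles have undefined
#' correlation and are excluded with a warning.
#'
#' @param profiles neurons x timebins matrix of mean z-score profiles.
#' @param cutoff_frac cut height as a fraction of the maximum linkage
#'   height.
#' @return A `cluster_tree`: list `hclust`, `cutoff`, `cluster` (id per
#'   neuron, NA for excluded), `excluded`.
#' @export
cluster_ensembles <- function(profiles, cutoff_frac = 0.3) {
  profiles <- as.matrix(profiles)
  if (nrow(profiles) < 2) stop("need at least 2 neurons", call. = FALSE)
  sds <- apply(profiles, 1, sd)
  excluded <- which(!is.finite(sds) | sds == 0)
  if (length(excluded)) {
    warning(length(excluded), " constant profile(s) excluded from clustering")
  }
  keep <- setdiff(seq_len(nrow(profiles)), excluded)
  d <- stats::as.dist(1 - cor(t(profiles[keep, , drop = FALSE])))
  hc <- hclust(d, method = "ward.D2")
  cutoff <- cutoff_frac * max(hc$height)
  cl_keep <- cutree(hc, h = cutoff)
  cluster <- rep(NA_integer_, nrow(profiles))
  cluster[keep] <- cl_keep
  structure(list(hclust = hc, cutoff = cutoff, cluster = cluster,
                 excluded = excluded),
            class = "cluster_tree")
}

#' Per-condition cluster percentages
#'
#' @param cluster integer cluster id per neuron (NA allowed).
#' @param condition condition label per neuron.
#' @return data.frame `condition`, `cluster`, `percent` (percentages sum to
#'   100 within condition).
#' @export
cluster_percentages <- function(cluster, condition) {
  keep <- !is.na(cluster)
  tab <- table(condition[keep], cluster[keep])
  pct <- 100 * prop.table(tab, margin = 1)
  df <- as.data.frame(pct, stringsAsFactors = FALSE)
  names(df) <- c("condition", "cluster", "percent")
  df
}

#' Overlap of responsiveness calls across event types
#'
#' Counts neurons jointly responsive to two event types (same co-registered
#' neurons), broken down by excitation/inhibition pattern, and compares
#' overlap proportions across conditions with a chi-squared test.
#'
#' @param resp_a,resp_b `responsiveness` tables over the same neurons.
#' @return list `pattern_table` (calls A x calls B), `overlap` (responsive
#'   to both), `both_excited`, `both_inhibited`.
#' @export
overlap_stats <- function(resp_a, resp_b) {
  stopifnot(nrow(resp_a) == nrow(resp_b))
  tab <- table(A = resp_a$call, B = resp_b$call)
  ra <- resp_a$call != "none"; rb <- resp_b$call != "none"
  list(pattern_table = tab, overlap = sum(ra & rb),
       both_excited = sum(resp_a$call == "excited" & resp_b$call == "excited"),
       both_inhibited = sum(resp_a$call == "inhibited" &
                              resp_b$call == "inhibited"))
}

#' Chi-squared comparison of overlap counts across conditions
#'
#' @param counts matrix of counts (conditions x outcome categories), e.g.
#'   overlapping vs non-overlapping neurons per social condition.
#' @param correct continuity correction (passed to [chisq.test()]).
#' @return the `htest` result.
#' @export
compare_conditions_chisq <- function(counts, correct = FALSE) {
  chisq.test(as.matrix(counts), correct = correct)
}

#' Global PCA on training-set trial averages
#'
#' Fits principal components on trial-averaged activity from the training
#' folds only (timepoints x neurons, animals pooled) and retains the
#' smallest number of components whose cumulative explained variance
#' reaches the target (default 90%).
#'
#' @param train_avg timepoints x neurons matrix of training-fold
#'   trial-averaged activity.
#' @param var_target cumulative explained-variance target.
#' @return A `pca_basis`: `rotation` (neurons x PCs), `center`,
#'   `var_ratio`, `n_components`.
#' @export
fit_global_pca <- function(train_avg, var_target = 0.9) {
  train_avg <- as.matrix(train_avg)
  pc <- prcomp(train_avg, center = TRUE, scale. = FALSE)
  vr <- pc$sdev^2 / sum(pc$sdev^2)
  ncomp <- which(cumsum(vr) >= var_target)[1]
  structure(list(rotation = pc$rotation, center = pc$center, var_ratio = vr,
                 n_components = ncomp, var_target = var_target),
            class = "pca_basis")
}

#' Project activity onto a fitted PCA basis
#'
#' @param basis a `pca_basis`.
#' @param x timepoints x neurons matrix, or trials x timepoints x neurons
#'   array, over the same neurons the basis was fit on.
#' @param n_components components to keep (default: the basis' 90% count).
#' @return matrix timepoints x PCs, or array trials x timepoints x PCs.
#' @export
project_activity <- function(basis, x, n_components = NULL) {
  nc <- n_components %||% basis$n_components
  R <- basis$rotation[, seq_len(nc), drop = FALSE]
  if (length(dim(x)) == 2) {
    return(sweep(as.matrix(x), 2, basis$center) %*% R)
  }
  d <- dim(x)
  out <- array(NA_real_, dim = c(d[1], d[2], nc))
  for (i in seq_len(d[1])) {
    out[i, , ] <- sweep(x[i, , , drop = TRUE], 2, basis$center) %*% R
  }
  out
}

# fit one binary classifier and return held-out decision values
fit_decision <- function(xtr, ytr, xte, classifier) {
  xtr <- as.matrix(xtr); xte <- as.matrix(xte)
  if (classifier == "glm") {
    std <- TRUE
    if (ncol(xtr) == 1) {  # glmnet needs >= 2 columns
      xtr <- cbind(xtr, 0); xte <- cbind(xte, 0); std <- FALSE
    }
    fit <- glmnet::glmnet(xtr, ytr, family = "binomial", alpha = 0,
                          lambda = 0.01, standardize = std)
    as.numeric(predict(fit, xte, type = "link"))
  } else {
    fit <- e1071::svm(xtr, factor(ytr), kernel = "linear", scale = TRUE)
    dv <- attr(predict(fit, xte, decision.values = TRUE), "decision.values")
    # libsvm orients the margin towards whichever class it saw first in the
    # training data; the column name ("A/B") records that orientation
    sgn <- if (startsWith(colnames(dv)[1], "TRUE")) 1 else -1
    sgn * as.numeric(dv)
  }
}

auc_value <- function(labels, scores, positive) {
  if (length(unique(labels)) < 2 || length(unique(scores)) < 2) return(0.5)
  r <- pROC::roc(response = factor(labels == positive,
                                   levels = c(FALSE, TRUE)),
                 predictor = scores, quiet = TRUE, direction = "<")
  as.numeric(pROC::auc(r))
}

stratified_folds <- function(labels, folds, seed) {
  with_seed(seed, {
    fold <- integer(length(labels))
    for (lv in unique(labels)) {
      idx <- sample(which(labels == lv))
      fold[idx] <- rep_len(seq_len(folds), length(idx))
    }
    fold
  })
}

decode_binary <- function(x, labels, positive, folds, seed, classifier,
                          balance, window_idx, shuffle_train = FALSE) {
  ntr <- dim(x)[1]; ntime <- dim(x)[2]
  fold <- stratified_folds(labels, folds, seed)
  scores <- matrix(NA_real_, ntr, ntime)
  fold_window_auc <- numeric(folds)
  for (f in seq_len(folds)) {
    tr <- which(fold != f); te <- which(fold == f)
    ytr <- labels[tr]
    if (shuffle_train) {
      ytr <- with_seed(seed + 77L * f, sample(ytr))
    }
    if (balance) {
      n_min <- min(table(ytr))
      tr_bal <- with_seed(seed + 13L * f, {
        unlist(lapply(unique(ytr), function(lv) {
          sample(tr[ytr == lv], n_min)
        }))
      })
      ytr <- labels[tr_bal]
      if (shuffle_train) ytr <- with_seed(seed + 78L * f, sample(ytr))
      tr <- tr_bal
    }
    p <- dim(x)[3]
    for (t in seq_len(ntime)) {
      xtr <- matrix(x[tr, t, , drop = FALSE], length(tr), p)
      xte <- matrix(x[te, t, , drop = FALSE], length(te), p)
      scores[te, t] <- fit_decision(xtr, ytr == positive, xte, classifier)
    }
    fold_window_auc[f] <- mean(vapply(window_idx, function(t) {
      auc_value(labels[te], scores[te, t], positive)
    }, numeric(1)))
  }
  auroc_t <- vapply(seq_len(ntime), function(t) {
    auc_value(labels, scores[, t], positive)
  }, numeric(1))
  list(auroc_t = auroc_t, fold_window_auroc = fold_window_auc,
       window_auroc = mean(fold_window_auc), scores = scores)
}

#' Population decoding with ROC over time
#'
#' Trains a linear classifier (L2-logistic "GLM" or linear SVM) per
#' timepoint on projected single-trial activity under trial-level
#' stratified k-fold cross-validation, with balanced subsampling of the
#' majority class in each training fold. Reports the held-out auROC as a
#' function of time, the window-averaged auROC per fold, and a
#' shuffled-training-label control run with the same folds. Multi-class
#' label sets use a one-vs-all scheme where each class is tested against a
#' trial-matched subsample of the others, repeated `n_repeats` times.
#'
#' @param x trials x timepoints x features array (PCA-projected activity).
#' @param labels per-trial labels (2 or more classes).
#' @param classifier "glm" or "svm".
#' @param folds cross-validation folds (5 default; 10 for rank-style runs).
#' @param seed integer seed driving folds, subsampling and shuffles.
#' @param window timepoint indices averaged into the window auROC
#'   (default: all).
#' @param balance balanced subsampling of training trials.
#' @param n_repeats repeats of the trial-matched subsample in one-vs-all.
#' @param shuffle_control also run the shuffled-label twin.
#' @return A `decoding_result`: for binary labels, list `auroc_t`,
#'   `window_auroc`, `fold_window_auroc`, `shuffled` (same fields);
#'   for multi-class, a named list per class of such results.
#' @export
decode_trials <- function(x, labels, classifier = c("glm", "svm"), folds = 5L,
                          seed = 1L, window = NULL, balance = TRUE,
                          n_repeats = 3L, shuffle_control = TRUE) {
  classifier <- match.arg(classifier)
  labels <- as.character(labels)
  stopifnot(length(labels) == dim(x)[1])
  classes <- sort(unique(labels))
  if (min(table(labels)) < folds) {
    stop("each class needs at least `folds` trials", call. = FALSE)
  }
  window_idx <- window %||% seq_len(dim(x)[2])
  run_binary <- function(xx, ll, pos, sd_off) {
    res <- decode_binary(xx, ll, pos, folds, seed + sd_off, classifier,
                         balance, window_idx, FALSE)
    if (shuffle_control) {
      res$shuffled <- decode_binary(xx, ll, pos, folds, seed + sd_off,
                                    classifier, balance, window_idx, TRUE)
    }
    res
  }
  if (length(classes) == 2) {
    out <- run_binary(x, labels, classes[2], 0L)
    out$positive <- classes[2]
    class(out) <- "decoding_result"
    return(out)
  }
  # one-vs-all with trial-matched pools
  out <- lapply(seq_along(classes), function(ci) {
    cls <- classes[ci]
    pos_idx <- which(labels == cls)
    reps <- lapply(seq_len(n_repeats), function(r) {
      oth_idx <- with_seed(seed + 100L * ci + r, {
        idx <- which(labels != cls)
        sample(idx, min(length(pos_idx), length(idx)))
      })
      sel <- c(pos_idx, oth_idx)
      ll <- ifelse(labels[sel] == cls, cls, "rest")
      run_binary(x[sel, , , drop = FALSE], ll, cls, 100L * ci + r)
    })
    agg <- list(
      auroc_t = rowMeans(vapply(reps, `[[`, numeric(dim(x)[2]), "auroc_t")),
      window_auroc = mean(vapply(reps, `[[`, numeric(1), "window_auroc")),
      fold_window_auroc = rowMeans(vapply(reps, `[[`, numeric(folds),
                                          "fold_window_auroc")))
    if (shuffle_control) {
      agg$shuffled <- list(
        window_auroc = mean(vapply(reps, function(r) {
          r$shuffled$window_auroc
        }, numeric(1))))
    }
    agg
  })
  names(out) <- classes
  class(out) <- "decoding_result_ova"
  out
}

# ---- trajectory geometry -------------------------------------------------

resample_trajectory <- function(mat, n_bins) {
  n <- nrow(mat)
  if (n == n_bins) return(mat)
  xout <- seq(1, n, length.out = n_bins)
  apply(mat, 2, function(v) approx(seq_len(n), v, xout = xout)$y)
}

traj_length <- function(mat) {
  if (nrow(mat) < 2) return(0)
  sum(sqrt(rowSums((mat[-1, , drop = FALSE] -
                      mat[-nrow(mat), , drop = FALSE])^2)))
}

#' Trajectory geometry in component space
#'
#' Projects per-group trial-averaged activity onto a fixed PCA basis,
#' resamples each trajectory to `n_bins` bins, and computes the geodesic
#' length (sum of Euclidean distances between adjacent bins) and pairwise
#' bin-by-bin distance series in the 90%-variance subspace. Leave-one-
#' animal-out replicates drop all of one animal's neurons per iteration
#' while reusing the same per-neuron PCA coefficients.
#'
#' @param basis a `pca_basis` fit on the pooled trial averages.
#' @param group_avgs named list of timepoints x neurons matrices (one per
#'   group, same co-registered neuron order).
#' @param animals character/integer animal id per neuron (for LOO).
#' @param n_bins trajectory resampling resolution.
#' @param n_components subspace dimension (default: the basis' 90% count).
#' @param loo compute leave-one-animal-out replicates.
#' @return A `trajectory_set`: `trajectories` (list of n_bins x PCs),
#'   `geodesic` (named vector), `pairwise` (list of bin-distance series per
#'   group pair), `loo` (data.frame group/animal/geodesic, plus pairwise
#'   LOO mean distances), `n_components`.
#' @export
trajectory_geometry <- function(basis, group_avgs, animals = NULL,
                                n_bins = 100L, n_components = NULL,
                                loo = !is.null(animals)) {
  nc <- n_components %||% basis$n_components
  proj <- lapply(group_avgs, function(g) {
    resample_trajectory(project_activity(basis, g, nc), n_bins)
  })
  geod <- vapply(proj, traj_length, numeric(1))
  pairwise <- list()
  if (length(proj) >= 2) {
    pairs <- utils::combn(names(proj), 2, simplify = FALSE)
    pairwise <- lapply(pairs, function(p) {
      sqrt(rowSums((proj[[p[1]]] - proj[[p[2]]])^2))
    })
    names(pairwise) <- vapply(pairs, paste, character(1), collapse = "_vs_")
  }
  loo_df <- NULL
  if (loo) {
    if (is.null(animals)) stop("animals required for LOO", call. = FALSE)
    ua <- unique(animals)
    if (length(ua) < 2) {
      warning("LOO degenerate with a single animal")
    }
    rows <- list()
    for (g in names(group_avgs)) {
      for (a in ua) {
        keep <- which(animals != a)
        sub_basis <- list(rotation = basis$rotation[keep, , drop = FALSE],
                          center = basis$center[keep],
                          n_components = basis$n_components)
        class(sub_basis) <- "pca_basis"
        tr <- resample_trajectory(
          project_activity(sub_basis, group_avgs[[g]][, keep, drop = FALSE],
                           nc), n_bins)
        rows[[length(rows) + 1L]] <- data.frame(
          group = g, animal = as.character(a), geodesic = traj_length(tr))
      }
    }
    loo_df <- do.call(rbind, rows)
  }
  structure(list(trajectories = proj, geodesic = geod, pairwise = pairwise,
                 loo = loo_df, n_components = nc),
            class = "trajectory_set")
}
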