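# Low-dimensional embedding of trial-window behavioral features and
# density-based clustering. The embedding backend is pluggable; the default
# is a linear 2-D principal-component embedding with a deterministic sign
# convention. Clustering is density-based (DBSCAN) with a grid-accelerated
# 2-D neighbor search; cluster id -1 marks noise points.

# DBSCAN on 2-D points. minPts counts the point itself. Returns integer
# cluster ids (1..k) with -1 for noise. Neighbor queries use an eps-sized
# cell grid; neighbor lists are computed once up front.
dbscan_2d <- function(pts, eps, min_pts) {
  n <- nrow(pts)
  cx <- floor(pts[, 1] / eps); cy <- floor(pts[, 2] / eps)
  key <- paste(cx, cy, sep = "_")
  cell_of <- split(seq_len(n), key)
  nbrs <- vector("list", n)
  for (i in seq_len(n)) {
    ks <- paste(rep(cx[i] + (-1:1), 3), rep(cy[i] + (-1:1), each = 3),
                sep = "_")
    cand <- unlist(cell_of[ks], use.names = FALSE)
    d2 <- (pts[cand, 1] - pts[i, 1])^2 + (pts[cand, 2] - pts[i, 2])^2
    nbrs[[i]] <- cand[d2 <= eps^2]
  }
  core <- lengths(nbrs) >= min_pts
  labels <- rep(NA_integer_, n)   # NA = unvisited, -1 = noise
  cl <- 0L
  queue <- integer(n)
  for (i in seq_len(n)) {
    if (!is.na(labels[i]) || !core[i]) next
    cl <- cl + 1L
    labels[i] <- cl
    queue[1L] <- i; qhead <- 1L; qtail <- 1L
    while (qhead <= qtail) {
      j <- queue[qhead]; qhead <- qhead + 1L
      for (k in nbrs[[j]]) {
        if (is.na(labels[k]) || labels[k] == -1L) {
          unvisited <- is.na(labels[k])
          labels[k] <- cl
          if (unvisited && core[k]) {
            qtail <- qtail + 1L
            if (qtail > length(queue)) queue <- c(queue, integer(n))
            queue[qtail] <- k
          }
        }
      }
    }
  }
  labels[is.na(labels)] <- -1L
  labels
}

#' Embed trial-window features and find density clusters
#'
#' Restricts the feature matrix to the 0-15 s post-cue windows (when a
#' schedule is given), embeds the frames in 2-D and clusters the embedding
#' with DBSCAN. The default embedding backend is the first two principal
#' components with a deterministic sign convention (largest-magnitude
#' loading positive), so repeated runs are identical.
#'
#' @param fm a z-scored `feature_matrix`.
#' @param sched optional trial schedule restricting frames to post-cue
#'   windows.
#' @param eps DBSCAN radius in embedding units; default 5% of the larger
#'   embedding span.
#' @param min_pts DBSCAN core-point threshold (self included).
#' @param exclude_constant drop zero-variance columns before embedding.
#' @return An `embedding_result`: data.frame `frame`, `x`, `y`, `cluster`
#'   (-1 = noise), with the PCA loadings as attribute `rotation`.
#' @export
embed_and_cluster <- function(fm, sched = NULL, eps = NULL, min_pts = 10L,
                              exclude_constant = TRUE) {
  stopifnot(inherits(fm, "feature_matrix"))
  frames <- seq_len(nrow(fm$values))
  if (!is.null(sched)) {
    tw <- trial_windows(sched, fm$fps, nrow(fm$values))
    tw <- tw[tw$window != "baseline", ]
    frames <- sort(unique(unlist(mapply(seq, tw$start, tw$end,
                                        SIMPLIFY = FALSE))))
  }
  X <- fm$values[frames, , drop = FALSE]
  if (exclude_constant) {
    keep <- apply(X, 2, function(v) sd(v) > 0)
    X <- X[, keep, drop = FALSE]
  }
  if (nrow(X) < min_pts) stop("fewer frames than min_pts", call. = FALSE)
  pc <- prcomp(X, center = TRUE, scale. = FALSE, rank. = 2)
  rot <- pc$rotation
  for (j in 1:2) {
    if (rot[which.max(abs(rot[, j])), j] < 0) {
      rot[, j] <- -rot[, j]
      pc$x[, j] <- -pc$x[, j]
    }
  }
  pts <- pc$x[, 1:2, drop = FALSE]
  if (is.null(eps)) {
    span <- max(apply(pts, 2, function(v) diff(range(v))))
    eps <- 0.05 * span
  }
  cl <- dbscan_2d(pts, eps, min_pts)
  er <- data.frame(frame = frames, x = pts[, 1], y = pts[, 2], cluster = cl)
  attr(er, "rotation") <- rot
  attr(er, "eps") <- eps
  class(er) <- c("embedding_result", "data.frame")
  er
}

#' Annotate clusters as attending / not-attending
#'
#' Either from a user-supplied map (replicating manual video-based
#' annotation) or heuristically: a cluster is attending when the mean of
#' its frames' `oriented_and_touching` feature exceeds 0.5.
#'
#' @param er an `embedding_result`.
#' @param fm the `feature_matrix` the embedding was built from.
#' @param map optional named vector/list cluster-id -> "attending" /
#'   "not_attending" overriding the heuristic.
#' @return named character vector over cluster ids (noise excluded).
#' @export
annotate_clusters <- function(er, fm = NULL, map = NULL) {
  ids <- sort(setdiff(unique(er$cluster), -1L))
  if (!is.null(map)) {
    out <- unlist(map)[as.character(ids)]
    if (anyNA(out)) stop("annotation map must cover every cluster")
    return(stats::setNames(out, ids))
  }
  stopifnot(inherits(fm, "feature_matrix"))
  oat <- fm$values[, "oriented_and_touching"]
  out <- vapply(ids, function(k) {
    fr <- er$frame[er$cluster == k]
    if (mean(oat[fr]) > 0.5) "attending" else "not_attending"
  }, character(1))
  stats::setNames(out, ids)
}

#' Per-cluster enrichment of flagged frames
#'
#' With one flag vector: percentage of each cluster's frames that are
#' flagged. With two (condition A and B): percentage of each condition's
#' frames falling in the cluster, and their percentage-point difference
#' (A minus B).
#'
#' @param er `embedding_result`.
#' @param flags logical per embedded frame (aligned with `er` rows).
#' @param flags2 optional second condition.
#' @return data.frame per cluster: `cluster` plus `pct_flagged`, or
#'   `pct_a`, `pct_b`, `diff_pp`.
#' @export
overlay_on_embedding <- function(er, flags, flags2 = NULL) {
  if (length(flags) != nrow(er)) stop("flags length mismatch", call. = FALSE)
  ids <- sort(unique(er$cluster))
  if (is.null(flags2)) {
    pct <- vapply(ids, function(k) {
      100 * mean(flags[er$cluster == k])
    }, numeric(1))
    return(data.frame(cluster = ids, pct_flagged = pct))
  }
  if (length(flags2) != nrow(er)) stop("flags2 length mismatch", call. = FALSE)
  na <- sum(flags); nb <- sum(flags2)
  pa <- vapply(ids, function(k) {
    100 * sum(flags & er$cluster == k) / max(na, 1)
  }, numeric(1))
  pb <- vapply(ids, function(k) {
    100 * sum(flags2 & er$cluster == k) / max(nb, 1)
  }, numeric(1))
  data.frame(cluster = ids, pct_a = pa, pct_b = pb, diff_pp = pa - pb)
}
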