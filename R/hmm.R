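# Gaussian-emission hidden Markov model over syllables + features.
#
# EM with scaled forward-backward (Rcpp core), multiple seeded restarts,
# BIC or held-out log-likelihood model selection over a candidate state
# range, and Viterbi decoding.

#' Build the HMM observation matrix
#'
#' Concatenates a one-hot encoding of the per-frame syllable ids with the
#' selected (z-scored continuous plus discrete) feature columns.
#'
#' @param syllables integer per-frame syllable ids in `[0, alphabet)`.
#' @param fm a `feature_matrix` aligned frame-for-frame with `syllables`.
#' @param features character vector of feature columns to append; default is
#'   the five continuous features used for state modeling plus the two
#'   discrete ones (zone, oriented_to_port).
#' @param alphabet syllable alphabet size (default: max id + 1).
#' @return numeric matrix frames x (alphabet + length(features)).
#' @export
build_observations <- function(syllables, fm,
                               features = c("dist_to_port", "angle_to_port",
                                            "velocity", "turning_angle",
                                            "acceleration", "zone",
                                            "oriented_to_port"),
                               alphabet = NULL) {
  stopifnot(inherits(fm, "feature_matrix"))
  if (length(syllables) != nrow(fm$values)) {
    stop("syllables and features have different frame counts", call. = FALSE)
  }
  alphabet <- alphabet %||% (max(syllables) + 1L)
  onehot <- matrix(0, length(syllables), alphabet)
  onehot[cbind(seq_along(syllables), syllables + 1L)] <- 1
  colnames(onehot) <- paste0("syl", seq_len(alphabet) - 1L)
  miss <- setdiff(features, fm$feature_names)
  if (length(miss)) stop("unknown features: ", paste(miss, collapse = ", "))
  cbind(onehot, fm$values[, features, drop = FALSE])
}

# per-state multivariate normal log-density, chol-based
mvn_logdens <- function(x, mean, cov) {
  d <- ncol(x)
  U <- chol(cov)
  xc <- sweep(x, 2, mean)
  y <- xc %*% backsolve(U, diag(d))
  -0.5 * (d * log(2 * pi) + 2 * sum(log(diag(U))) + rowSums(y^2))
}

safe_chol_cov <- function(cov, reg) {
  cov <- (cov + t(cov)) / 2
  r <- reg
  repeat {
    covr <- cov + diag(r, ncol(cov))
    ok <- tryCatch({ chol(covr); TRUE }, error = function(e) FALSE)
    if (ok) return(covr)
    r <- r * 10
    if (r > 1e6) stop("covariance irreparably degenerate")
    warning("degenerate covariance; increasing regularization to ", r,
            call. = FALSE)
  }
}

#' Fit a Gaussian-emission HMM by EM
#'
#' Full-covariance Gaussian emissions over the observation vector; best of
#' `n_init` seeded restarts by training log-likelihood (the first restart
#' is k-means-initialized, the rest use random responsibilities). The EM
#' log-likelihood trace is non-decreasing up to numerical tolerance.
#'
#' @param obs numeric matrix frames x dims.
#' @param K number of hidden states (>= 2 for a meaningful model; 1 allowed).
#' @param seed integer seed for initialization.
#' @param n_init number of EM restarts.
#' @param max_iter maximum EM iterations per restart.
#' @param tol relative log-likelihood convergence tolerance.
#' @param reg covariance diagonal regularization.
#' @return A `state_model`: `K`, `pi`, `transmat`, `means` (K x D), `covs`
#'   (list), `loglik`, `loglik_trace`, `n_obs`.
#' @export
fit_hmm <- function(obs, K, seed = 1L, n_init = 5L, max_iter = 500L,
                    tol = 1e-4, reg = 1e-6) {
  obs <- as.matrix(obs)
  Tn <- nrow(obs); D <- ncol(obs)
  stopifnot(K >= 1, Tn > K)
  best <- NULL
  for (init in seq_len(n_init)) {
    par <- with_seed(seed * 1000L + init, {
      if (init == 1L) {
        km <- tryCatch(
          suppressWarnings(kmeans(obs, centers = K, nstart = 1L,
                                  iter.max = 30L)),
          error = function(e) NULL)
        means <- if (is.null(km)) {
          obs[sample.int(Tn, K), , drop = FALSE]
        } else {
          km$centers
        }
      } else {
        means <- obs[sample.int(Tn, K), , drop = FALSE]
      }
      list(means = means)
    })
    gcov <- stats::cov(obs)
    covs <- replicate(K, safe_chol_cov(gcov, reg), simplify = FALSE)
    pi0 <- rep(1 / K, K)
    A <- matrix(0.1 / max(K - 1, 1), K, K); diag(A) <- if (K > 1) 0.9 else 1
    means <- par$means
    ll_prev <- -Inf; trace <- numeric(0)
    for (iter in seq_len(max_iter)) {
      logB <- vapply(seq_len(K), function(k) {
        mvn_logdens(obs, means[k, ], covs[[k]])
      }, numeric(Tn))
      fb <- hmm_forward_backward(logB, pi0, A)
      ll <- fb$loglik
      trace <- c(trace, ll)
      if (is.finite(ll_prev) &&
          abs(ll - ll_prev) < tol * (abs(ll_prev) + 1e-3)) break
      ll_prev <- ll
      g <- fb$gamma
      Ng <- colSums(g)
      pi0 <- g[1, ] / sum(g[1, ])
      xi <- fb$xi
      rs <- rowSums(xi)
      A <- xi / ifelse(rs > 0, rs, 1)
      A[rs == 0, ] <- 1 / K
      means <- crossprod(g, obs) / Ng
      for (k in seq_len(K)) {
        xc <- sweep(obs, 2, means[k, ])
        ck <- crossprod(xc * g[, k], xc) / Ng[k]
        covs[[k]] <- safe_chol_cov(ck, reg)
      }
    }
    if (is.null(best) || trace[length(trace)] > best$loglik) {
      best <- list(K = K, pi = pi0, transmat = A, means = means, covs = covs,
                   loglik = trace[length(trace)], loglik_trace = trace,
                   n_obs = Tn)
    }
  }
  structure(best, class = "state_model")
}

hmm_n_params <- function(K, D) {
  (K - 1) + K * (K - 1) + K * D + K * D * (D + 1) / 2
}

#' Log-likelihood of observations under a fitted state model
#' @param model a `state_model`.
#' @param obs observation matrix.
#' @return scalar log-likelihood.
#' @export
logLik_hmm <- function(model, obs) {
  obs <- as.matrix(obs)
  logB <- vapply(seq_len(model$K), function(k) {
    mvn_logdens(obs, model$means[k, ], model$covs[[k]])
  }, numeric(nrow(obs)))
  hmm_forward_backward(logB, model$pi, model$transmat)$loglik
}

#' Select the number of hidden states
#'
#' Fits the HMM for every candidate K and returns the model optimizing the
#' selection criterion: minimum BIC (default) or maximum held-out
#' log-likelihood on a 20% tail split. The raw log-likelihood is monotone
#' in K, so a penalized or held-out criterion is required to make the scan
#' well-posed; all per-K scores are recorded on the returned model.
#'
#' @param obs observation matrix.
#' @param K_range candidate state counts (default 2:12).
#' @param criterion "bic" or "holdout".
#' @param seed,n_init,... passed to [fit_hmm()].
#' @return The selected `state_model` with a `selection` data.frame
#'   attribute column set (`K`, `loglik`, `score`) and `criterion`.
#' @export
select_states <- function(obs, K_range = 2:12, criterion = c("bic", "holdout"),
                          seed = 1L, n_init = 5L, ...) {
  criterion <- match.arg(criterion)
  obs <- as.matrix(obs)
  Tn <- nrow(obs); D <- ncol(obs)
  if (criterion == "holdout") {
    n_tr <- floor(0.8 * Tn)
    tr <- obs[seq_len(n_tr), , drop = FALSE]
    te <- obs[(n_tr + 1):Tn, , drop = FALSE]
  }
  fits <- list(); scores <- numeric(length(K_range)); lls <- numeric(length(K_range))
  for (i in seq_along(K_range)) {
    K <- K_range[i]
    if (criterion == "bic") {
      fit <- fit_hmm(obs, K, seed = seed, n_init = n_init, ...)
      lls[i] <- fit$loglik
      scores[i] <- -2 * fit$loglik + hmm_n_params(K, D) * log(Tn)
    } else {
      fit <- fit_hmm(tr, K, seed = seed, n_init = n_init, ...)
      lls[i] <- fit$loglik
      scores[i] <- -logLik_hmm(fit, te)   # lower = better, like BIC
    }
    fits[[i]] <- fit
  }
  sel <- which.min(scores)
  model <- fits[[sel]]
  model$selection <- data.frame(K = K_range, loglik = lls, score = scores)
  model$criterion <- criterion
  model
}

#' Viterbi state sequence
#'
#' @param model a `state_model`.
#' @param obs observation matrix.
#' @return integer per-frame state ids in 1..K.
#' @export
decode_states <- function(model, obs) {
  obs <- as.matrix(obs)
  logB <- vapply(seq_len(model$K), function(k) {
    mvn_logdens(obs, model$means[k, ], model$covs[[k]])
  }, numeric(nrow(obs)))
  as.integer(hmm_viterbi(logB, model$pi, model$transmat))
}

#' Per-state occupancy, dwell time, stickiness and transition matrices
#'
#' Time in state is occupancy divided by the frame rate; dwell time is the
#' mean consecutive run length in seconds; stickiness is the empirical
#' self-transition probability (self transitions over all outgoing
#' transitions of the state). The transition count matrix is returned both
#' normalized over the entire matrix (all entries sum to 1) and as a
#' row-stochastic variant.
#'
#' @param states integer per-frame state sequence (1..K).
#' @param fps frame rate, Hz.
#' @param K state count (default: max observed).
#' @return list `time_s`, `dwell_s`, `stickiness`, `counts`,
#'   `matrix_normalized`, `row_stochastic`.
#' @export
state_metrics <- function(states, fps, K = max(states)) {
  states <- as.integer(states)
  n <- length(states)
  time_s <- vapply(seq_len(K), function(k) sum(states == k), numeric(1)) / fps
  r <- rle(states)
  dwell_s <- vapply(seq_len(K), function(k) {
    runs <- r$lengths[r$values == k]
    if (length(runs) == 0) NA_real_ else mean(runs) / fps
  }, numeric(1))
  counts <- matrix(0, K, K)
  if (n > 1) {
    for (t in seq_len(n - 1L)) {
      counts[states[t], states[t + 1L]] <- counts[states[t], states[t + 1L]] + 1
    }
  }
  out <- rowSums(counts)
  stickiness <- ifelse(out > 0, diag(counts) / out, NA_real_)
  list(time_s = time_s, dwell_s = dwell_s, stickiness = stickiness,
       counts = counts,
       matrix_normalized = counts / max(sum(counts), 1),
       row_stochastic = counts / ifelse(out > 0, out, 1))
}
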