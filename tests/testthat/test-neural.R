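make_session <- function(dff, fs = 10, events = c(10, 40)) {
  structure(list(dff = dff, t_s = (seq_len(ncol(dff)) - 1) / fs, fs = fs,
                 events = list(cue = events),
                 coreg_id = seq_len(nrow(dff)), animal = "m1"),
            class = "neural_session")
}

test_that("PSTH z-scoring is anchored to the -1..0 s baseline", {
  fs <- 10
  n_t <- 700
  set.seed(51)
  base_noise <- rnorm(n_t)
  # neuron 1: noise with a +3 step after each onset
  events <- c(20, 40)
  d1 <- base_noise
  for (on in events) d1[(on * fs + 1):(on * fs + 150)] <-
      d1[(on * fs + 1):(on * fs + 150)] + 3
  # neuron 2: constant -> degenerate
  sess <- make_session(rbind(d1, rep(1, n_t)), fs = fs, events = events)
  ps <- compute_psth(sess, events = events)
  expect_equal(dim(ps$z)[3], 200)
  # baseline-window mean of z is 0 by construction
  bmask <- ps$time >= -1 & ps$time < 0
  expect_lt(max(abs(apply(ps$z[1, , bmask], 1, mean))), 1e-10)
  post <- ps$time >= 0 & ps$time < 15
  expect_equal(mean(ps$z[1, , post]), 3, tolerance = 3 * 0.35)
  expect_true(all(ps$degenerate[2, ]))
  expect_true(all(is.na(ps$z[2, , ])))

  # z is zero wherever the trace equals its baseline mean
  d3 <- rep(c(0, 2), length.out = n_t)  # baseline mean 1
  d3[(20 * fs + 1):n_t] <- 1
  sess3 <- make_session(matrix(d3, 1), fs = fs, events = 20)
  ps3 <- compute_psth(sess3, events = 20)
  expect_true(all(ps3$z[1, 1, ps3$time >= 0] == 0))

  expect_error(compute_psth(sess, events = 1), "exceed")
})

test_that("responsiveness calls recover planted response signs", {
  cfg <- sim_config(seed = 9, n_neurons = 60, template_amplitude = 3,
                    n_trials = 30)
  sched <- gen_schedule(cfg)
  ns <- gen_neural(cfg, sched)
  ps <- compute_psth(ns$session)
  rp <- call_responsive(ps)
  exc <- ns$truth$sign == 1
  inh <- ns$truth$sign == -1
  expect_gte(mean(rp$call[exc] == "excited"), 0.95)
  expect_gte(mean(rp$call[inh] == "inhibited"), 0.95)

  small <- compute_psth(make_session(matrix(rnorm(2 * 700), 2), events = 30))
  expect_error(call_responsive(small), "few trials")
})

test_that("ensemble clustering recovers planted templates at the 30% cutoff", {
  set.seed(61)
  t1 <- c(rep(1, 20), rep(0, 20))
  t2 <- c(rep(0, 20), rep(1, 20))
  prof <- rbind(t(replicate(25, t1)), t(replicate(25, t2))) +
    matrix(rnorm(50 * 40, sd = 0.05), 50)
  ct <- cluster_ensembles(prof, cutoff_frac = 0.3)
  truth <- rep(1:2, each = 25)
  expect_equal(adjusted_rand(ct$cluster, truth), 1)

  # permutation invariance up to relabeling
  perm <- sample(50)
  ct2 <- cluster_ensembles(prof[perm, ], cutoff_frac = 0.3)
  expect_equal(adjusted_rand(ct2$cluster, ct$cluster[perm]), 1)

  # dendrogram extremes
  expect_equal(length(unique(cluster_ensembles(prof, 1)$cluster)), 1)
  expect_equal(length(unique(cluster_ensembles(prof, 1e-9)$cluster)), 50)

  prof_bad <- rbind(prof, rep(1, 40))
  expect_warning(ct_bad <- cluster_ensembles(prof_bad), "constant")
  expect_true(is.na(ct_bad$cluster[51]))
})

test_that("overlap counts and chi-squared match direct computation", {
  resp <- function(calls) {
    structure(data.frame(neuron = seq_along(calls), p = 0.01, mean_z = 1,
                         call = calls),
              class = c("responsiveness", "data.frame"))
  }
  a <- resp(c(rep("excited", 10), rep("none", 10)))
  b <- resp(c(rep("none", 10), rep("excited", 10)))
  expect_equal(overlap_stats(a, b)$overlap, 0)
  expect_equal(overlap_stats(a, a)$overlap, 10)
  expect_equal(overlap_stats(a, a)$both_excited, 10)

  tab <- matrix(c(12, 8, 5, 15), 2, byrow = TRUE)
  got <- compare_conditions_chisq(tab)
  # textbook formula
  expected <- sum((tab - outer(rowSums(tab), colSums(tab)) / sum(tab))^2 /
                    (outer(rowSums(tab), colSums(tab)) / sum(tab)))
  expect_equal(unname(got$statistic), expected)
})

test_that("the PCA basis honors the 90% cumulative-variance rule", {
  # rank-1 data
  set.seed(71)
  u <- rnorm(100); v <- rnorm(15)
  b1 <- fit_global_pca(outer(u, v) + matrix(rnorm(1500, sd = 1e-6), 100))
  expect_equal(b1$n_components, 1)

  # isotropic noise: compare against the sample-covariance eigenvalue oracle
  X <- matrix(rnorm(4000), 200, 20)
  b <- fit_global_pca(X)
  ev <- eigen(stats::cov(X), symmetric = TRUE)$values
  oracle <- which(cumsum(ev) / sum(ev) >= 0.9)[1]
  expect_equal(b$n_components, oracle)
  expect_gte(sum(b$var_ratio[seq_len(b$n_components)]), 0.9)
  # components are orthonormal
  R <- b$rotation
  expect_equal(unname(crossprod(R)), diag(ncol(R)), tolerance = 1e-8)
})

test_that("linear decoding separates planted classes and not shuffled ones", {
  set.seed(81)
  n <- 40; nt <- 10; p <- 4
  lab <- rep(c("A", "B"), each = n / 2)
  x <- array(rnorm(n * nt * p), dim = c(n, nt, p))
  x[lab == "B", , 1] <- x[lab == "B", , 1] + 3
  r <- decode_trials(x, lab, classifier = "glm", folds = 5, seed = 1)
  expect_gte(r$window_auroc, 0.95)
  expect_true(all(r$auroc_t >= 0 & r$auroc_t <= 1))

  r_svm <- decode_trials(x, lab, classifier = "svm", folds = 5, seed = 1,
                         shuffle_control = FALSE)
  expect_gte(r_svm$window_auroc, 0.95)

  expect_error(decode_trials(x[1:6, , ], lab[c(1:3, 21:23)], folds = 5),
               "at least")
})

test_that("one-vs-all decoding orders classes by planted separability", {
  set.seed(91)
  n_per <- 20; nt <- 6; p <- 3
  lab <- rep(c("high", "mid", "none"), each = n_per)
  x <- array(rnorm(3 * n_per * nt * p), dim = c(3 * n_per, nt, p))
  x[lab == "high", , 1] <- x[lab == "high", , 1] + 4
  x[lab == "mid", , 2] <- x[lab == "mid", , 2] + 1
  r <- decode_trials(x, lab, classifier = "glm", folds = 10, seed = 2,
                     n_repeats = 3, shuffle_control = FALSE)
  expect_named(r, c("high", "mid", "none"))
  expect_gt(r$high$window_auroc, r$mid$window_auroc)
  expect_gte(r$high$window_auroc, 0.95)
})

test_that("trajectory geometry matches closed forms", {
  basis <- structure(list(rotation = diag(2), center = c(0, 0),
                          var_ratio = c(0.9, 0.1), n_components = 2),
                     class = "pca_basis")
  seg <- list(g = rbind(c(0, 0), c(3, 4)))
  ts <- trajectory_geometry(basis, seg, n_bins = 2, loo = FALSE)
  expect_equal(unname(ts$geodesic), 5)

  two <- list(a = rbind(c(0, 0), c(3, 4)), b = rbind(c(0, 0), c(3, 4)))
  ts2 <- trajectory_geometry(basis, two, n_bins = 50, loo = FALSE)
  expect_true(all(ts2$pairwise$a_vs_b == 0))

  # unit circle sampled at 100 points: chord sum within 0.2% of 2*pi
  th <- seq(0, 2 * pi, length.out = 101)
  circ <- list(c = cbind(cos(th), sin(th)))
  ts3 <- trajectory_geometry(basis, circ, n_bins = 101, loo = FALSE)
  expect_equal(unname(ts3$geodesic), 2 * pi, tolerance = 0.002)

  # rigid rotation leaves the geodesic length unchanged
  ang <- 0.7
  R <- matrix(c(cos(ang), sin(ang), -sin(ang), cos(ang)), 2)
  ts4 <- trajectory_geometry(basis, list(c = cbind(cos(th), sin(th)) %*% R),
                             n_bins = 101, loo = FALSE)
  expect_equal(unname(ts4$geodesic), unname(ts3$geodesic), tolerance = 1e-10)

  # LOO drops one animal's neurons per replicate, reusing coefficients
  set.seed(99)
  b <- fit_global_pca(matrix(rnorm(100 * 12), 100, 12))
  ga <- list(g1 = matrix(rnorm(100 * 12), 100, 12))
  ts5 <- trajectory_geometry(b, ga, animals = rep(1:3, each = 4))
  expect_equal(nrow(ts5$loo), 3)
  expect_true(all(ts5$loo$geodesic > 0))
})
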