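test_that("well-separated feature blobs yield two density clusters", {
  set.seed(31)
  n <- 300
  a <- cbind(rnorm(n, 0, 0.3), rnorm(n, 0, 0.3))
  b <- cbind(rnorm(n, 20, 0.3), rnorm(n, 0, 0.3))
  vals <- rbind(a, b)
  colnames(vals) <- c("f1", "f2")
  fm <- make_fm(vals, kinds = c("continuous", "continuous"))
  er <- embed_and_cluster(fm, eps = 1, min_pts = 5)
  ids <- setdiff(unique(er$cluster), -1)
  expect_length(ids, 2)
  # blob membership is pure
  expect_equal(length(unique(er$cluster[1:n])), 1)
  expect_equal(length(unique(er$cluster[(n + 1):(2 * n)])), 1)

  # duplicated rows land at identical embedding coordinates
  fm2 <- make_fm(rbind(vals, vals[1, , drop = FALSE]),
                 kinds = c("continuous", "continuous"))
  er2 <- embed_and_cluster(fm2, eps = 1, min_pts = 5)
  span <- max(diff(range(er2$x)), diff(range(er2$y)))
  d <- sqrt((er2$x[1] - er2$x[2 * n + 1])^2 + (er2$y[1] - er2$y[2 * n + 1])^2)
  expect_lt(d, 0.01 * span)

  # repeated runs are identical
  er3 <- embed_and_cluster(fm, eps = 1, min_pts = 5)
  expect_identical(er$cluster, er3$cluster)
})

test_that("cluster enrichment overlays count flagged frames per cluster", {
  er <- data.frame(frame = 1:100, x = 0, y = 0,
                   cluster = rep(c(1, 2, 3, -1), 25))
  class(er) <- c("embedding_result", "data.frame")
  ov0 <- overlay_on_embedding(er, rep(FALSE, 100))
  expect_true(all(ov0$pct_flagged == 0))

  fl <- er$cluster == 3
  ov <- overlay_on_embedding(er, fl)
  expect_equal(ov$pct_flagged[ov$cluster == 3], 100)
  expect_true(all(ov$pct_flagged[ov$cluster != 3] == 0))

  ovd <- overlay_on_embedding(er, fl, fl)
  expect_true(all(ovd$diff_pp == 0))
  expect_error(overlay_on_embedding(er, rep(TRUE, 99)), "mismatch")
})

test_that("observation matrices concatenate one-hot syllables and features", {
  n <- 50
  vals <- cbind(dist_to_port = rnorm(n), angle_to_port = rnorm(n),
                velocity = rnorm(n), turning_angle = rnorm(n),
                acceleration = rnorm(n), zone = rep(1, n),
                oriented_to_port = rep(0, n))
  fm <- make_fm(vals, kinds = c(rep("continuous", 5), "discrete", "discrete"))
  syl <- sample(0:86, n, replace = TRUE)
  obs <- build_observations(syl, fm, alphabet = 87)
  expect_equal(ncol(obs), 94)
  expect_true(all(rowSums(obs[, 1:87]) == 1))

  obs_const <- build_observations(rep(0L, n), fm, alphabet = 87)
  expect_equal(sum(colSums(obs_const[, 1:87]) > 0), 1)
  expect_error(build_observations(syl[-1], fm), "frame counts")
})

test_that("EM fits recover moments and planted state sequences", {
  set.seed(41)
  # single Gaussian split over K=2: stationary mixture keeps the mean
  x1 <- matrix(rnorm(2000, mean = 3), ncol = 2)
  m1 <- fit_hmm(x1, K = 2, seed = 1, n_init = 2, max_iter = 100)
  statdist <- abs(Re(eigen(t(m1$transmat))$vectors[, 1]))
  statdist <- statdist / sum(statdist)
  mix_mean <- colSums(statdist * m1$means)
  expect_equal(unname(mix_mean), unname(colMeans(x1)), tolerance = 0.1)
  expect_true(all(diff(m1$loglik_trace) > -1e-6 * abs(m1$loglik)))

  g <- gen_hmm_session(K = 4, n_frames = 3000, dim = 3, sep = 5,
                       self_p = 0.95, seed = 5)
  m4 <- fit_hmm(g$obs, 4, seed = 1, n_init = 3)
  vit <- decode_states(m4, g$obs)
  expect_gte(perm_match_acc(g$states, vit, 4), 0.9)
})

test_that("state-count selection recovers planted K", {
  g2 <- gen_hmm_session(K = 2, n_frames = 3000, dim = 3, sep = 5, seed = 9)
  sel2 <- select_states(g2$obs, K_range = 2:5, seed = 1, n_init = 2)
  expect_equal(sel2$K, 2)
  expect_equal(nrow(sel2$selection), 4)

  sel3 <- select_states(g2$obs[1:500, ], K_range = 3, seed = 1, n_init = 1)
  expect_equal(sel3$K, 3)
})

test_that("state metrics match a run-length-encoding oracle", {
  const <- rep(2L, 100)
  mc <- state_metrics(const, fps = 10, K = 2)
  expect_equal(mc$stickiness[2], 1)
  expect_equal(mc$dwell_s[2], 10)
  expect_equal(sum(mc$time_s), 10)

  alt <- rep(1:2, 50)
  ma <- state_metrics(alt, fps = 10)
  expect_equal(unname(ma$stickiness), c(0, 0))
  expect_equal(unname(ma$dwell_s), c(0.1, 0.1))

  seq12 <- c(1, 1, 2, 2, 2, 1, 3, 3, 1, 1, 2, 3)
  m <- state_metrics(seq12, fps = 1)
  # RLE oracle: state 1 runs (2,1,2), state 2 runs (3,1), state 3 runs (2,1)
  expect_equal(unname(m$time_s), c(5, 4, 3))
  expect_equal(unname(m$dwell_s), c(mean(c(2, 1, 2)), mean(c(3, 1)),
                                    mean(c(2, 1))))
  # transitions sum to n-1; whole-matrix normalization sums to 1
  expect_equal(sum(m$counts), 11)
  expect_equal(sum(m$matrix_normalized), 1)
  expect_true(all(abs(rowSums(m$row_stochastic) - 1) < 1e-12))
})

test_that("the attending-dominant hidden state captures the planted bouts", {
  cfg <- sim_config(seed = 4, n_trials = 8, habituation_s = 10,
                    attend_p_cue = 0.7)
  sched <- gen_schedule(cfg)
  kp <- gen_keypoints(cfg, sched)
  fm <- zscore_features(compute_features(preprocess_keypoints(kp$track, 5),
                                         cfg$arena))
  syl <- gen_syllables(cfg, kp$truth$state)
  obs <- build_observations(syl, fm, alphabet = 87)
  m <- fit_hmm(obs, 2, seed = 1, n_init = 2, max_iter = 100)
  vit <- decode_states(m, obs)
  att <- kp$truth$attending_frame
  capture <- max(vapply(1:2, function(k) sum(vit == k & att), numeric(1)))
  expect_gte(capture / sum(att), 0.8)
})
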