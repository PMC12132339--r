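make_track <- function(coords, fps = 30) {
  structure(list(coords = coords, node_names = skeleton_nodes(), fps = fps),
            class = "keypoint_track")
}

# straight-line track moving right at `step` px/frame, heading at the port
straight_track <- function(n, step = 10, y = 128, x0 = 10) {
  coords <- array(NA_real_, dim = c(n, 9, 2),
                  dimnames = list(NULL, skeleton_nodes(), c("x", "y")))
  x <- x0 + step * (seq_len(n) - 1)
  for (nd in skeleton_nodes()) {
    coords[, nd, 1] <- x
    coords[, nd, 2] <- y
  }
  coords[, "nose", 1] <- x + 20
  coords[, "ear_left", ] <- cbind(x + 12, y + 5)
  coords[, "ear_right", ] <- cbind(x + 12, y - 5)
  coords[, "tail_base", 1] <- x - 20
  make_track(coords)
}

test_that("interpolation fills gaps linearly and smoothing is benign", {
  tr <- straight_track(10, step = 1)
  expect_identical(preprocess_keypoints(tr, 1)$coords, tr$coords)

  tr2 <- tr
  tr2$coords[5, "nose", 1] <- NA   # neighbors are 33 and 35 -> midpoint 34
  out <- preprocess_keypoints(tr2, 1)
  expect_equal(out$coords[5, "nose", 1], 34)

  # constant track unchanged by any window
  trc <- straight_track(10, step = 0)
  expect_equal(preprocess_keypoints(trc, 7)$coords, trc$coords)

  tr3 <- tr
  tr3$coords[, "torso", 1] <- NA
  expect_error(preprocess_keypoints(tr3, 1), "torso")
})

test_that("kinematic features match closed-form values", {
  arena <- arena_config()
  tr <- straight_track(20, step = 10, y = 128)   # port at (250, 128)
  fm <- compute_features(tr, arena)
  expect_equal(unname(fm$values[5, "velocity"]), 300)
  # heading along +x towards the port on its line
  expect_equal(unname(fm$values[5, "angle_to_port"]), 0)
  expect_equal(unname(fm$values[5, "oriented_to_port"]), 1)
  # zones partition every frame
  expect_true(all(fm$values[, "zone"] %in% 1:3))
  # straight monotone path: trailing 1-s tortuosity is exactly 1
  tr2 <- straight_track(40, step = 2)
  fm2 <- compute_features(tr2, arena)
  expect_equal(unname(fm2$values[35, "tortuosity_1s"]), 1)
})

test_that("tortuosity equals path/net ratio on a 3-4-5 right angle", {
  # fps 2 -> 1-s trailing window spans 2 steps: legs 3 then 4
  coords <- array(0, dim = c(3, 9, 2),
                  dimnames = list(NULL, skeleton_nodes(), c("x", "y")))
  pos <- rbind(c(10, 10), c(13, 10), c(13, 14))
  for (nd in skeleton_nodes()) coords[, nd, ] <- pos
  tr <- make_track(coords, fps = 2)
  fm <- compute_features(tr, arena_config())
  expect_equal(unname(fm$values[3, "tortuosity_1s"]), 7 / 5)
})

test_that("tortuosity is >= 1 and velocity is reversal-invariant", {
  fx <- short_session()
  pre <- preprocess_keypoints(fx$track, 1)
  fm <- compute_features(pre, fx$cfg$arena)
  expect_true(all(fm$values[, c("tortuosity_1s", "tortuosity_5s")] >= 1))

  rev_track <- pre
  rev_track$coords <- pre$coords[rev(seq_len(dim(pre$coords)[1])), , ]
  fmr <- compute_features(rev_track, fx$cfg$arena)
  v <- fm$values[, "velocity"]; vr <- rev(fmr$values[, "velocity"])
  # reversal maps step t->t+1 onto step t+1->t: one-frame shift; the ends
  # carry the first-frame copy and are excluded
  n <- length(v)
  expect_equal(unname(vr[3:(n - 2)]), unname(v[4:(n - 1)]))
})

test_that("z-scoring standardizes continuous and preserves discrete columns", {
  fx <- short_session()
  fm <- compute_features(preprocess_keypoints(fx$track, 5), fx$cfg$arena)
  fz <- zscore_features(fm)
  cont <- which(fz$kinds == "continuous")
  expect_true(all(abs(colMeans(fz$values[, cont])) < 1e-6))
  expect_true(all(abs(apply(fz$values[, cont], 2, sd) - 1) < 1e-6))
  expect_true(all(fz$values[, "zone"] %in% 1:3))
  # re-standardizing a standardized column is the identity
  fz2 <- fz; fz2$zscored <- FALSE
  expect_equal(zscore_features(fz2)$values[, cont], fz$values[, cont],
               tolerance = 1e-12)

  fm_bad <- fm
  fm_bad$values[, "velocity"] <- 1
  expect_error(zscore_features(fm_bad), "velocity")
})

test_that("geometric features reproduce the generator ground truth", {
  cfg <- sim_config(seed = 21, n_trials = 5, habituation_s = 10,
                    missing_frac = 0)
  sched <- gen_schedule(cfg)
  kp <- gen_keypoints(cfg, sched)
  fm <- compute_features(preprocess_keypoints(kp$track, 1), cfg$arena)
  expect_identical(as.logical(fm$values[, "oriented_and_touching"]),
                   kp$truth$attending_frame)
})

test_that("freeze/dash scoring counts sub-threshold frames", {
  v <- c(0, 0, 5, 20, 1, 30, 4, 2, 50, 9)   # 4 frames below v_thresh = 3
  a <- rep(0, 10)
  vals <- cbind(velocity = v, acceleration = a)
  fm <- make_fm(vals, kinds = c("continuous", "continuous"))
  r <- freeze_dash_score(fm, v_thresh = 3, a_thresh = 1, dash_thresh = 25)
  expect_equal(r$n_freeze, 4)
  expect_equal(r$n_dash, 2)
  expect_equal(r$ratio, 0.5)

  r0 <- freeze_dash_score(make_fm(cbind(velocity = rep(0, 5),
                                        acceleration = rep(0, 5)),
                                  c("continuous", "continuous")),
                          3, 1, 25)
  expect_equal(r0$n_freeze, 5)

  rd <- freeze_dash_score(make_fm(cbind(velocity = rep(100, 5),
                                        acceleration = rep(0, 5)),
                                  c("continuous", "continuous")),
                          3, 1, 25)
  expect_true(rd$undefined)
  expect_true(is.na(rd$ratio))
})

test_that("reward seeking percentage counts frames below threshold", {
  d <- c(rep(1, 50), rep(100, 50))
  fm <- make_fm(cbind(dist_to_port = d), "continuous")
  expect_equal(reward_seeking(fm, 10), 50)
  expect_equal(reward_seeking(make_fm(cbind(dist_to_port = rep(0.5, 10)),
                                      "continuous"), 10), 100)
  expect_equal(reward_seeking(fm, 0), 0)
})

test_that("hot-plate scores follow the ratio and difference definitions", {
  s <- hotplate_scores(6, 3)
  expect_equal(s$normalized, 2)
  expect_equal(s$difference, 3)
  s2 <- hotplate_scores(4, 4)
  expect_equal(s2$normalized, 1)
  expect_equal(s2$difference, 0)
  s3 <- hotplate_scores(0, 3)
  expect_equal(s3$normalized, 0)
  expect_equal(s3$difference, -3)
  s4 <- hotplate_scores(5, 0)
  expect_true(is.na(s4$normalized))
  expect_equal(s4$difference, 5)
})
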