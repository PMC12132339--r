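test_that("heatmap targets place unit Gaussians at scaled labels", {
  empty <- make_heatmap_targets(data.frame(frame = integer(0),
                                           class = character(0),
                                           x = numeric(0), y = numeric(0)),
                                2, c(32, 32))
  expect_true(all(empty == 0))

  lab <- data.frame(frame = 1, class = "attending", x = 20, y = 12)
  tg <- make_heatmap_targets(lab, 1, c(32, 32), sigma = 2)
  am <- which(tg[1, , , 1] == max(tg[1, , , 1]), arr.ind = TRUE)
  expect_equal(unname(am[1, ]), c(12, 20))
  expect_equal(max(tg), 1)

  lab2 <- rbind(lab, data.frame(frame = 1, class = "attending", x = 21,
                                y = 12))
  tg2 <- make_heatmap_targets(lab2, 1, c(32, 32), sigma = 2)
  expect_true(all(tg2 <= 1))
  expect_error(make_heatmap_targets(lab, 1, c(32, 32), sigma = 0), "sigma")
})

test_that("NMS retains strict local maxima and suppresses within radius", {
  expect_equal(nrow(nms_peaks(matrix(0, 20, 20), 0.5, 3)), 0)

  m <- matrix(0, 20, 20); m[5, 5] <- 1
  pk <- nms_peaks(m, 0.5, 3)
  expect_equal(pk$x, 5); expect_equal(pk$y, 5); expect_equal(pk$conf, 1)

  # peaks closer than the radius: only the stronger survives
  m2 <- matrix(0, 20, 20); m2[10, 5] <- 0.9; m2[10, 9] <- 0.8
  pk2 <- nms_peaks(m2, 0.5, 5)
  expect_equal(nrow(pk2), 1)
  expect_equal(pk2$conf, 0.9)

  # sub-threshold noise does not change the output
  set.seed(1)
  noise <- matrix(runif(400, 0, 0.2), 20, 20)
  noise[10, 5] <- 0; noise[10, 9] <- 0
  pk3 <- nms_peaks(m2 + noise, 0.5, 5)
  expect_equal(pk3[, c("x", "y", "conf")], pk2[, c("x", "y", "conf")])
})

test_that("training reduces the heatmap loss; zero epochs is a no-op init", {
  fx <- short_session()
  att <- fx$truth$detections$frame
  oth <- setdiff(seq_len(dim(fx$track$coords)[1]), att)
  set.seed(4)
  idx <- sort(c(sample(att, 40), sample(oth, 40)))
  fr <- gen_frames(fx$track, fx$cfg, fx$truth, frames = idx)
  cfg <- detector_config(epochs = 3, seed = 1)
  tg <- make_heatmap_targets(fr$labels, dim(fr$frames)[1],
                             dim(fr$frames)[2:3], sigma = 1, stride = 4)
  m0 <- train_detector(fr$frames, tg, detector_config(epochs = 0, seed = 1))
  expect_length(m0$loss_history, 0)
  expect_identical(m0$layers, fomopipe:::init_detector(cfg))

  m <- train_detector(fr$frames, tg, cfg)
  expect_lt(m$loss_history[3], m$loss_history[1])
  # outputs live in (0, 1)
  p <- predict_heatmaps(m, fr$frames[1:2, , , drop = FALSE])
  expect_true(all(p > 0 & p < 1))
})

test_that("an impossible confidence threshold yields an empty ethogram", {
  fx <- short_session()
  fr <- gen_frames(fx$track, fx$cfg, fx$truth, frames = 1:4)
  m <- train_detector(fr$frames,
                      make_heatmap_targets(fr$labels, 4, dim(fr$frames)[2:3],
                                           sigma = 1, stride = 4),
                      detector_config(epochs = 0, seed = 2))
  cls <- classify_frames(m, fr$frames, conf_thresh = 1 + 1e-9)
  expect_false(any(cls$ethogram))
  expect_equal(nrow(cls$detections), 0)
})

test_that("attending counts are baseline-normalized per 5-s bin", {
  fps <- 2
  sched <- data.frame(trial = 1, onset_s = 10)
  attr(sched, "cue_s") <- 10; attr(sched, "wall_s") <- 15
  class(sched) <- c("trial_schedule", "data.frame")
  # 2 fps: baseline frames 11-20, bins 21-30, 31-40, 41-50
  etho <- rep(FALSE, 60)
  etho[c(12, 15)] <- TRUE                      # baseline count 2
  etho[21:30] <- TRUE                          # bin1 count 10
  etho[c(31:35)] <- TRUE                       # bin2 count 5
  etho[c(41, 42, 43)] <- TRUE                  # bin3 count 3
  att <- quantify_attending(etho, sched, fps)
  expect_equal(att$baseline, 2)
  expect_equal(c(att$dbin1, att$dbin2, att$dbin3), c(8, 3, 1))
  expect_equal(att$total_delta, 12)

  att0 <- quantify_attending(rep(FALSE, 60), sched, fps)
  expect_equal(att0$total_delta, 0)
})

test_that("median thresholds label trials with a strict inequality", {
  lab <- label_trials(c(0, 1, 2, 3, 10, 20), mode = "global")
  expect_equal(lab$threshold[1], 2.5)
  expect_equal(sum(lab$label == "attending"), 3)

  lab_eq <- label_trials(rep(4, 10), mode = "global")
  expect_equal(sum(lab_eq$label == "attending"), 0)

  v <- c(5, 1, 9, 2, 8, 0)
  g <- label_trials(v, mode = "global")
  l <- label_trials(v, animal = rep("m1", 6), mode = "local")
  expect_identical(g$label, l$label)

  # monotonicity: a higher threshold can only shrink the attending set
  n_att <- function(thr) sum(v > thr)
  thrs <- sort(unique(v))
  expect_true(all(diff(vapply(thrs, n_att, numeric(1))) <= 0))
})

test_that("extreme-trial selection is disjoint with stable tie-breaks", {
  counts <- sample(1:60)
  sel <- select_extreme_trials(counts, 15)
  expect_length(sel$top, 15); expect_length(sel$bottom, 15)
  expect_length(intersect(sel$top, sel$bottom), 0)
  expect_setequal(sel$top, order(-counts)[1:15])

  sel2 <- select_extreme_trials(1:60, 15)
  expect_setequal(sel2$top, 46:60)
  expect_setequal(sel2$bottom, 1:15)

  # all tied: stable order oracle -> first 15 go to top, next 15 to bottom
  sel3 <- select_extreme_trials(rep(7, 60), 15)
  expect_equal(sel3$top, 1:15)
  expect_equal(sel3$bottom, 16:30)
  expect_length(intersect(sel3$top, sel3$bottom), 0)

  expect_error(select_extreme_trials(1:20, 15), "at least 30")
})

test_that("lick bouts merge across short gaps", {
  none <- quantify_licks(rep(FALSE, 100), fps = 30)
  expect_equal(none$n_bouts, 0); expect_equal(none$duration_s, 0)

  one <- quantify_licks(c(rep(FALSE, 10), rep(TRUE, 30), rep(FALSE, 10)),
                        fps = 30)
  expect_equal(one$n_bouts, 1)
  expect_equal(one$duration_s, 1)

  # two runs separated by less than gap_frames merge into one bout
  e <- c(rep(TRUE, 10), rep(FALSE, 5), rep(TRUE, 10),
         rep(FALSE, 20), rep(TRUE, 10))
  q <- quantify_licks(e, fps = 30, gap_frames = 10)
  expect_equal(q$n_bouts, 2)
  expect_equal(q$duration_s, 30 / 30)
})
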