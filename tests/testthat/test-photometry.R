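test_that("the forward median filter matches a brute-force trailing oracle", {
  x <- rep(2, 50)
  expect_equal(pm_median_filter(x, fs = 20), x)

  sp <- rep(1, 50); sp[25] <- 10
  expect_true(all(pm_median_filter(sp, fs = 20, span_s = 0.2) == 1))

  set.seed(101)
  y <- rnorm(10)
  got <- pm_median_filter(y, fs = 20, span_s = 0.2)  # width 4
  oracle <- vapply(seq_along(y), function(i) {
    median(y[max(1, i - 3):i])
  }, numeric(1))
  expect_equal(got, oracle)
})

test_that("reference regression removes a perfectly shared component", {
  fs <- 20
  n <- fs * 200
  t_s <- (seq_len(n) - 1) / fs
  set.seed(103)
  ref <- as.numeric(stats::filter(rnorm(n), 0.9, method = "recursive"))
  sess <- structure(list(t_s = t_s, signal = 2 * ref, reference = ref,
                         events = NULL, fs = fs, sensor = "DA"),
                    class = "photometry_session")
  onsets <- seq(20, 160, by = 30)
  # a perfect fit leaves ~zero baseline variance; that warning is expected
  ct <- suppressWarnings(regress_reference(sess, onsets, filter_span_s = 0))
  expect_equal(ct$slope, 2, tolerance = 1e-6)
  expect_lt(max(abs(ct$corrected)), 1e-8)

  # zero reference: slope forced to 0 with a warning
  sess0 <- sess; sess0$reference <- rep(0, n)
  expect_warning(ct0 <- regress_reference(sess0, onsets, filter_span_s = 0),
                 "no variance")
  expect_equal(ct0$slope, 0)
})

test_that("correction is invariant to a common channel gain", {
  cfg <- sim_config(seed = 15, n_trials = 20)
  sched <- gen_schedule(cfg)
  pm <- gen_photometry(cfg, sched)
  ct1 <- regress_reference(pm$session, sched)
  sess_scaled <- pm$session
  sess_scaled$signal <- 3.7 * sess_scaled$signal
  sess_scaled$reference <- 3.7 * sess_scaled$reference
  ct2 <- regress_reference(sess_scaled, sched)
  expect_equal(ct1$z, ct2$z, tolerance = 1e-8)
})

test_that("per-trial baselines of the corrected z-trace are standardized", {
  cfg <- sim_config(seed = 16, n_trials = 30)
  sched <- gen_schedule(cfg)
  pm <- gen_photometry(cfg, sched)
  ct <- regress_reference(pm$session, sched)
  bmask <- ct$time >= -1 & ct$time < 0
  expect_lt(max(abs(rowMeans(ct$z[, bmask]))), 1e-10)
  expect_lt(max(abs(apply(ct$z[, bmask], 1, sd) - 1)), 1e-10)
})

test_that("trial AUC follows the trapezoid rule", {
  fs <- 20
  nsmp <- fs * 25 + 1          # samples spanning -5..20 s inclusive
  z0 <- matrix(0, 3, nsmp)
  ct0 <- make_ct(z0, fs = fs)
  expect_true(all(trial_auc(ct0, c(0, 20))$auc == 0))

  z1 <- matrix(1, 2, nsmp)
  expect_equal(unname(trial_auc(make_ct(z1, fs = fs), c(0, 20))$auc),
               rep(20, 2))

  # triangle of height 2 over 0..10 s then 0
  tt <- -5 + (seq_len(nsmp) - 1) / fs
  tri <- ifelse(tt >= 0 & tt <= 5, 2 * tt / 5,
                ifelse(tt > 5 & tt <= 10, 2 * (10 - tt) / 5, 0))
  ctt <- make_ct(matrix(tri, 1, byrow = TRUE), fs = fs)
  expect_equal(unname(trial_auc(ctt, c(0, 15))$auc), 10, tolerance = 1e-2)

  lab <- c("att", "att", "not")
  withl <- trial_auc(make_ct(rbind(z1, z0[1, , drop = FALSE]), fs = fs),
                     c(0, 20), labels = lab)
  expect_equal(withl$by_label$mean_auc[withl$by_label$label == "att"], 20)
  expect_equal(withl$by_label$mean_auc[withl$by_label$label == "not"], 0)
  expect_error(trial_auc(ct0, c(0, 30)), "exceeds")
})

test_that("random-forest decoding separates offset traces, not shuffles", {
  set.seed(107)
  n <- 40; fs <- 20
  z <- matrix(rnorm(n * (fs * 25 + 1)), n)
  lab <- rep(c("att", "not"), n / 2)
  ct <- make_ct(z, fs = fs)
  ct$z[lab == "att", ct$time >= 0] <- ct$z[lab == "att", ct$time >= 0] + 3
  r <- rf_decode(ct, lab, window = c(0, 5), folds = 5, seed = 1, ntree = 100)
  expect_gte(r$auroc, 0.95)
  # trial-level folds: every trial is assigned exactly one fold
  expect_length(r$fold, n)
  expect_true(all(r$fold %in% 1:5))
  # stratification keeps both classes in every fold
  expect_true(all(table(r$fold, lab) > 0))
  expect_error(rf_decode(ct, rep("att", n)), "two classes")
})
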