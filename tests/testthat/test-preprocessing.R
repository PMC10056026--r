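make_recording <- function(trial_lens, values = seq_along(trial_lens),
                           labels = paste0("m", seq_along(trial_lens)),
                           kinds = rep("target", length(trial_lens)),
                           rate = 200) {
  n <- sum(trial_lens)
  samples <- matrix(rep(values, trial_lens), n, 8)
  ends <- cumsum(trial_lens)
  emg_recording(samples, rate,
                data.frame(start = ends - trial_lens, end = ends,
                           label = labels, kind = kinds))
}

test_that("window counts follow floor((n - L)/S) + 1 and never cross trials", {
  expect_equal(window_count(1000, 50, 20), 48)
  expect_equal(window_count(50, 50, 20), 1)
  expect_equal(window_count(49, 50, 20), 0)

  brute <- function(n, L, S) {
    k <- 0; s <- 0
    while (s + L <= n) { k <- k + 1; s <- s + S }
    k
  }
  set.seed(42)
  for (i in 1:200) {
    n <- sample(0:400, 1); L <- sample(1:60, 1); S <- sample(1:30, 1)
    expect_identical(window_count(n, L, S), as.integer(brute(n, L, S)))
  }

  rec <- make_recording(c(100, 100), values = c(1, 2), labels = c("a", "b"))
  w <- segment_windows(rec, 250, 100)           # L = 50, S = 20
  expect_equal(dim(w$samples), c(50, 8, 6))     # 3 windows per 100-sample trial
  expect_equal(w$info$label, rep(c("a", "b"), each = 3))
  for (k in 1:6)                                # constant within each trial
    expect_equal(length(unique(as.vector(w$samples[, , k]))), 1)

  short <- make_recording(c(49, 100), labels = c("a", "b"))
  expect_equal(segment_windows(short)$info$label, rep("b", 3))
  expect_error(segment_windows(rec, 251, 100), "whole sample counts")
})

test_that("the activity threshold is mu + 3 sigma of the rectified neutral signal", {
  th <- fit_activity_threshold(c(-1, 1))
  expect_equal(th$mu_neutral, 1)
  expect_equal(th$sigma_neutral, 0)
  expect_equal(th$threshold, 1)

  th2 <- fit_activity_threshold(c(0.4, -0.6))    # |x|: mean .5, pop sd .1
  expect_equal(th2$threshold, 0.8)

  expect_equal(fit_activity_threshold(c(0, 0, 0))$threshold, 0)
  expect_error(fit_activity_threshold(numeric(0)), "at least 2")
  expect_error(fit_activity_threshold(1), "at least 2")
})

test_that("activity detection compares mean rectified amplitude strictly to the threshold", {
  th <- fit_activity_threshold(c(1, -1))         # threshold exactly 1
  expect_true(is_active(matrix(1.25, 50, 8), th))
  expect_false(is_active(matrix(1, 50, 8), th))     # boundary is inactive
  expect_false(is_active(matrix(0, 50, 8), fit_activity_threshold(c(0, 0))))
})

test_that("RMS, MAV, WL match their definitions and scale linearly", {
  x <- c(3, 4)
  expect_equal(rms(x), sqrt(12.5))
  expect_equal(mav(x), 3.5)
  expect_equal(wl(x), 1)
  expect_equal(mav(c(1, -1)), 1)
  expect_equal(wl(c(1, -1)), 2)
  expect_equal(rms(rep(-2.5, 10)), 2.5)
  expect_equal(wl(rep(-2.5, 10)), 0)
  expect_error(rms(numeric(0)), "at least 1")
  expect_error(wl(3), "at least 2")

  set.seed(7)
  for (i in 1:20) {
    v <- rnorm(50)
    expect_equal(rms(v), sqrt(mean(v^2)), tolerance = 1e-14)
    expect_equal(mav(v), mean(abs(v)), tolerance = 1e-14)
    expect_equal(wl(v), sum(abs(diff(v))), tolerance = 1e-14)
    k <- runif(1, 0, 3)
    expect_equal(c(rms(k * v), mav(k * v), wl(k * v)),
                 k * c(rms(v), mav(v), wl(v)), tolerance = 1e-12)
  }
})

test_that("feature images stack consecutive window rows with stride 1", {
  # exactly 53 windows: n = 50 + 52 * 20
  rec <- make_recording(1090, values = 2, labels = "a")
  w <- segment_windows(rec)
  imgs <- encode_feature_images(w, stack = 53)
  expect_length(imgs, 1)
  expect_equal(dim(imgs$planes[[1]]), c(3, 53, 8))
  expect_equal(imgs$pad, 0L)
  expect_true(all(imgs$planes[[1]][1, , ] == 2))   # RMS of constant 2
  expect_true(all(imgs$planes[[1]][2, , ] == 2))   # MAV
  expect_true(all(imgs$planes[[1]][3, , ] == 0))   # WL

  # 5 windows, stack 2 -> 4 stride-1 images
  rec5 <- make_recording(130, labels = "a")
  expect_length(encode_feature_images(segment_windows(rec5), stack = 2), 4)

  # 3 windows, stack 5 -> one image padded by repeating the last row
  rec3 <- make_recording(90, labels = "a")
  imgs3 <- encode_feature_images(segment_windows(rec3), stack = 5)
  expect_length(imgs3, 1)
  expect_equal(imgs3$pad, 2L)
  expect_equal(imgs3$planes[[1]][, 4, ], imgs3$planes[[1]][, 3, ])
  expect_equal(imgs3$planes[[1]][, 5, ], imgs3$planes[[1]][, 3, ])

  empty <- encode_feature_images(segment_windows(make_recording(10, labels = "a")))
  expect_length(empty, 0)
})

test_that("per-window features equal the per-channel RMS/MAV/WL", {
  set.seed(3)
  w <- matrix(rnorm(50 * 8), 50, 8)
  f <- osemg:::window_feature_rows(w)
  for (ch in 1:8) {
    expect_equal(unname(f[1, ch]), rms(w[, ch]), tolerance = 1e-14)
    expect_equal(unname(f[2, ch]), mav(w[, ch]), tolerance = 1e-14)
    expect_equal(unname(f[3, ch]), wl(w[, ch]), tolerance = 1e-14)
  }
})

test_that("preprocess_recording keeps active windows and represents neutral", {
  cfg <- simulation_config(repetitions = 1, seed = 9)
  rec <- generate_recording(cfg)
  pp <- preprocess_recording(rec)
  expect_setequal(unique(pp$images$label),
                  vapply(cfg$movements, `[[`, "", "name"))
  expect_equal(pp$threshold$threshold,
               fit_activity_threshold(neutral_samples(rec))$threshold)
  # non-neutral trials are detected as active nearly everywhere
  act <- pp$windows$info$active
  expect_gt(mean(act[pp$windows$info$kind == "target"]), 0.9)
  expect_equal(mean(act[pp$windows$info$kind == "neutral"]), 0, tolerance = 0.05)

  p <- withr::local_tempfile(fileext = ".rds")
  save_feature_images(pp$images, p)
  expect_equal(load_feature_images(p), pp$images)
})
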