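test_that("autoencoder specs must be mirror-symmetric", {
  expect_error(autoencoder_spec(c(512, 256, 512, 256)), "palindromic")
  expect_error(autoencoder_spec(c(8, 8)), "at least 3")
  expect_equal(autoencoder_spec()$widths,
               c(512L, 256L, 128L, 64L, 128L, 256L, 512L))
})

test_that("autoencoder training is seeded, validated, and reduces the MSE", {
  set.seed(10)
  feats <- matrix(rnorm(20 * 8), 20)
  spec <- autoencoder_spec(c(8, 4, 8))
  ae1 <- train_autoencoder(feats, spec, epochs = 30, seed = 4)
  ae2 <- train_autoencoder(feats, spec, epochs = 30, seed = 4)
  expect_identical(ae1$params, ae2$params)
  expect_length(ae1$history, 30)

  expect_error(train_autoencoder(matrix(0, 0, 8), spec), "at least one sample")
  expect_error(train_autoencoder(matrix(0, 5, 9), spec), "9-wide|expects")

  # on deep features of the trained network, the 50-epoch moving average of
  # the training MSE never increases
  ex <- extract_features(fifty_epoch_cnn(), default_images(0L))
  ae <- train_autoencoder(ex$features[1:30, ], epochs = 300, seed = 0)
  ma <- stats::filter(ae$history, rep(1 / 50, 50), sides = 1)
  expect_true(all(diff(ma[!is.na(ma)]) <= 1e-9))
})

test_that("reconstruction error is 1 minus the Pearson correlation", {
  ident <- manual_ae(4)
  expect_equal(reconstruction_error(ident, c(1, 2, 3, 4)), 0)

  anti <- manual_ae(4, negate = TRUE)
  expect_equal(reconstruction_error(anti, c(1, 2, 3, 4)), 2)

  shifted <- manual_ae(4, shift = c(0, 0, 0, 1))   # y = (1,2,3,5)
  expect_equal(reconstruction_error(shifted, c(1, 2, 3, 4)),
               1 - 6.5 / sqrt(43.75), tolerance = 1e-12)

  expect_warning(e <- reconstruction_error(ident, c(1, 1, 1, 1)), "undefined")
  expect_equal(e, 2)

  # agrees with stats::cor on arbitrary inputs through an untrained model
  ae <- random_ae(c(16L, 8L, 16L), seed = 2)
  set.seed(11)
  for (i in 1:20) {
    x <- rnorm(16)
    expect_equal(reconstruction_error(ae, x),
                 1 - cor(x, as.vector(reconstruct(ae, x))),
                 tolerance = 1e-12)
  }
})

test_that("thresholds are the smallest error covering the recall fraction", {
  errs <- (1:10) / 100
  ae <- constant_ae()
  X <- features_with_errors(errs)
  labs <- rep("wrist_flexion", 10)
  m <- calibrate_thresholds(ae, X, labs, recall_factor = 0.9)
  expect_equal(unname(m$thresholds["wrist_flexion"]), 0.09, tolerance = 1e-9)
  expect_equal(m$global_threshold, 0.09, tolerance = 1e-9)

  expect_equal(unname(calibrate_thresholds(ae, X, labs, 1.0)$thresholds[1]),
               0.10, tolerance = 1e-9)
  expect_equal(unname(calibrate_thresholds(ae, X[3, , drop = FALSE],
                                           "solo", 0.5)$thresholds[1]),
               0.03, tolerance = 1e-9)
  expect_error(calibrate_thresholds(ae, X, labs, 0), "recall_factor")
  expect_error(calibrate_thresholds(ae, X, labs[-1], 0.9), "one entry per")
})

test_that("decisions accept at or below the class threshold, including the boundary", {
  ae <- constant_ae()
  errs <- (1:10) / 100
  X <- features_with_errors(errs)
  m <- calibrate_thresholds(ae, X, rep("g", 10), recall_factor = 0.9)  # tau 0.09

  # the second probe is bit-identical to the calibration sample that set the
  # threshold, so it sits exactly on the boundary and must be accepted
  probe <- features_with_errors(c(0.0001, 9 / 100, 0.0901, 1.5))
  d <- decide(m, probe, rep("g", 4))
  expect_equal(d$verdict, c("accept", "accept", "reject", "reject"))
  expect_equal(d$label, c("g", "g", NA, NA))
  expect_equal(d$error, c(0.0001, 0.09, 0.0901, 1.5), tolerance = 1e-9)
  expect_error(decide(m, probe, rep("unknown", 4)), "no calibrated threshold")

  # global mode applies one pooled threshold
  mg <- calibrate_thresholds(ae, X, rep(c("a", "b"), 5), 0.9, mode = "global")
  dg <- decide(mg, probe, c("a", "b", "a", "b"))
  expect_equal(dg$verdict, c("accept", "accept", "reject", "reject"))
})

test_that("a rejection model refuses to run against a different feature network", {
  rej <- structure(list(cnn_fingerprint = "aaa"), class = "rejection_model")
  cnn <- structure(list(fingerprint = "bbb"), class = "cnn_model")
  expect_error(classify_open_set(cnn, rej, NULL), "different feature network")
})

test_that("rejection models round-trip through their file format", {
  m <- calibrate_thresholds(constant_ae(),
                            features_with_errors(c(0.02, 0.05)),
                            c("a", "a"), 0.9)
  p <- withr::local_tempfile(fileext = ".rds")
  save_rejection_model(m, p)
  expect_equal(load_rejection_model(p)$thresholds, m$thresholds)
  expect_error(load_rejection_model({
    q <- withr::local_tempfile(fileext = ".rds"); saveRDS(1, q); q
  }), "rejection model")
})
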