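test_that("convolution arithmetic and deep-feature width match the design", {
  arch <- cnn_architecture()
  shp <- conv_output_shape(arch)
  expect_equal(shp[[1]], c(3, 53, 8))
  expect_equal(shp[[2]], c(32, 19, 4))    # floor((53-16)/2)+1, floor((8-2)/2)+1
  expect_equal(shp[[3]], c(64, 8, 4))
  expect_equal(shp[[4]], c(64, 8, 4))
  expect_equal(arch$feature_width, 512)
  expect_error(cnn_architecture(input_dim = c(3, 10, 8)), "too small")
})

test_that("softmax cross-entropy matches direct evaluation and validates labels", {
  expect_equal(softmax_cross_entropy(matrix(c(0, 0), 1), 1), log(2))
  expect_equal(softmax_cross_entropy(matrix(c(2, 0, 0), 1), 1),
               -log(exp(2) / (exp(2) + 2)))
  expect_lt(softmax_cross_entropy(matrix(c(200, 0, 0), 1), 1), 1e-12)
  expect_error(softmax_cross_entropy(matrix(0, 1, 3), 4), "labels")
  # mean over the batch
  l <- matrix(rnorm(10 * 4), 10)
  y <- sample(4, 10, replace = TRUE)
  direct <- -mean(log(exp(l[cbind(1:10, y)]) / rowSums(exp(l))))
  expect_equal(softmax_cross_entropy(l, y), direct, tolerance = 1e-12)
})

test_that("center loss is half the mean squared distance to the class center", {
  cc <- class_centers(matrix(0, 2, 3), alpha = 0.5)
  x <- matrix(c(1, 0, 0), 1)
  expect_equal(center_loss(x, 1, cc), 0.5)
  expect_equal(center_loss(cc$centers[c(1, 2), ], c(1, 2), cc), 0)
  # duplicating the batch leaves the mean form unchanged
  set.seed(1)
  f <- matrix(rnorm(6 * 3), 6)
  y <- c(1, 2, 1, 2, 1, 2)
  expect_equal(center_loss(f, y, cc), center_loss(rbind(f, f), c(y, y), cc))
  expect_error(class_centers(matrix(0, 2, 3), alpha = 1), "alpha")
})

test_that("center updates follow the damped rule and leave absent classes alone", {
  cc <- class_centers(matrix(0, 2, 2), alpha = 0.5)
  up <- update_centers(cc, matrix(c(2, 2), 1), 1)
  expect_equal(up$centers[1, ], c(0.5, 0.5))    # delta = -1, c <- 0 - 0.5*(-1)
  expect_equal(up$centers[2, ], c(0, 0))        # class 2 absent

  # features already at the center are a fixed point
  cc2 <- class_centers(matrix(5, 1, 2), alpha = 0.9)
  up2 <- update_centers(cc2, matrix(5, 3, 2), c(1, 1, 1))
  expect_equal(up2$centers, cc2$centers)
})

test_that("joint loss reduces to cross-entropy at lambda 0 and adds the weighted term", {
  set.seed(2)
  l <- matrix(rnorm(8 * 3), 8); f <- matrix(rnorm(8 * 4), 8)
  y <- sample(3, 8, replace = TRUE)
  cc <- class_centers(matrix(rnorm(12), 3), alpha = 0.5)
  expect_identical(joint_loss(l, f, y, cc, 0), softmax_cross_entropy(l, y))
  lam <- 0.00025
  expect_equal(joint_loss(l, f, y, cc, lam),
               softmax_cross_entropy(l, y) + lam * center_loss(f, y, cc),
               tolerance = 1e-15)
})

test_that("inference is deterministic, shape-checked, and yields 512-wide simplex outputs", {
  arch <- cnn_architecture()
  model <- structure(list(arch = arch,
                          params = withr::with_seed(5, osemg:::init_cnn_params(arch)),
                          maps = osemg:::build_conv_maps(arch),
                          stats = NULL, classes = paste0("c", 1:7)),
                     class = "cnn_model")
  img <- withr::with_seed(6, array(rnorm(3 * 53 * 8), c(3L, 53L, 8L)))
  ex <- extract_features(model, list(img))
  expect_length(ex$features, 512)
  expect_equal(sum(ex$probs), 1, tolerance = 1e-9)
  expect_true(all(ex$probs >= 0))
  ex2 <- extract_features(model, list(img))
  expect_identical(ex$features, ex2$features)

  img2 <- withr::with_seed(7, array(rnorm(3 * 53 * 8), c(3L, 53L, 8L)))
  both <- extract_features(model, list(img, img2))
  swapped <- extract_features(model, list(img2, img))
  expect_equal(both$features[1, ], swapped$features[2, ])

  bad <- array(0, c(3L, 40L, 8L))
  expect_error(extract_features(model, list(bad)), "3x40x8.*3x53x8")
})

test_that("training on default synthetic data separates the 7 target classes", {
  cnn <- fifty_epoch_cnn()
  expect_gte(cnn$final_train_accuracy, 0.95)
  expect_equal(nrow(cnn$history), 50)
  expect_named(cnn$history, c("epoch", "ce", "center", "joint", "accuracy"))
  expect_length(cnn$classes, 7)

  # checkpoint round trip preserves weights and predictions
  p <- withr::local_tempfile(fileext = ".rds")
  save_cnn(cnn, p)
  back <- load_cnn(p)
  expect_identical(back$params, cnn$params)
  expect_identical(back$fingerprint, cnn$fingerprint)

  lg <- withr::local_tempfile(fileext = ".jsonl")
  write_training_log(cnn, lg)
  expect_length(readLines(lg), 50)
})

test_that("training refuses single-class data", {
  fake <- structure(list(planes = replicate(6, array(0, c(3L, 22L, 8L)),
                                            simplify = FALSE),
                         label = rep("only", 6), kind = rep("target", 6),
                         trial = 1:6, pad = integer(6)),
                    class = "feature_images")
  expect_error(train_cnn(fake, train_config(epochs = 1)), "at least 2 classes")
})
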