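#' CNN architecture for sEMG feature images
#'
#' Describes the small convolutional network used to extract discriminative
#' deep features from 3-plane time-domain feature images. The network has
#' three convolutional layers (kernels 16x2 stride (2,2) pad (0,0),
#' 8x3 stride (2,1) pad (2,1), 3x3 stride (1,1) pad (1,1)), two fully
#' connected layers, and a softmax output over the target classes. All
#' activations are leaky rectifiers; dropout acts between the two fully
#' connected layers during training only.
#'
#' @param input_dim integer triple `c(planes, T, channels)`; defaults to the
#'   canonical 3 x 53 x 8 feature image.
#' @param conv_channels output channels of the three convolutional layers.
#' @param fc_width width of the first fully connected layer.
#' @param feature_width width of the deep-feature layer (512 in the canonical
#'   architecture; the rejector consumes these features).
#' @param n_classes number of target movement classes.
#' @param dropout dropout rate applied between the two fully connected
#'   layers while training.
#' @param leaky_slope negative-side slope of the leaky rectifier.
#' @return an object of class `cnn_architecture`.
#' @export
cnn_architecture <- function(input_dim = c(3L, 53L, 8L),
                             conv_channels = c(32L, 64L, 64L),
                             fc_width = 1024L,
                             feature_width = 512L,
                             n_classes = 7L,
                             dropout = 0.2,
                             leaky_slope = 0.01) {
  if (length(input_dim) != 3L) abort_input("`input_dim` must be c(planes, T, channels)")
  if (length(conv_channels) != 3L) abort_input("`conv_channels` must have length 3")
  check_number(dropout, "dropout", 0, 1)
  check_number(n_classes, "n_classes", 2, integerish = TRUE)
  conv <- list(
    list(kh = 16L, kw = 2L, sh = 2L, sw = 2L, ph = 0L, pw = 0L, oc = conv_channels[1]),
    list(kh = 8L,  kw = 3L, sh = 2L, sw = 1L, ph = 2L, pw = 1L, oc = conv_channels[2]),
    list(kh = 3L,  kw = 3L, sh = 1L, sw = 1L, ph = 1L, pw = 1L, oc = conv_channels[3])
  )
  arch <- structure(list(
    input_dim = as.integer(input_dim), conv = conv,
    fc_width = as.integer(fc_width), feature_width = as.integer(feature_width),
    n_classes = as.integer(n_classes), dropout = dropout,
    leaky_slope = leaky_slope
  ), class = "cnn_architecture")
  # fail early if the input is too small for the convolution stack
  conv_output_shape(arch)
  arch
}

#' Spatial shapes along the convolution stack
#'
#' Returns the `c(channels, height, width)` of the input and of each
#' convolutional layer's output under the usual convolution arithmetic
#' `floor((n + 2 pad - kernel) / stride) + 1`.
#'
#' @param arch a [cnn_architecture()].
#' @return list of integer triples, one per stage starting at the input.
#' @export
conv_output_shape <- function(arch) {
  shp <- list(c(arch$input_dim[1], arch$input_dim[2], arch$input_dim[3]))
  cur <- shp[[1]]
  for (cl in arch$conv) {
    H <- (cur[2] + 2L * cl$ph - cl$kh) %/% cl$sh + 1L
    W <- (cur[3] + 2L * cl$pw - cl$kw) %/% cl$sw + 1L
    if (H < 1L || W < 1L)
      abort_input(sprintf("input %dx%d too small for %dx%d convolution",
                          cur[2], cur[3], cl$kh, cl$kw))
    cur <- c(cl$oc, H, W)
    shp[[length(shp) + 1L]] <- cur
  }
  shp
}

build_conv_maps <- function(arch) {
  shapes <- conv_output_shape(arch)
  lapply(seq_along(arch$conv), function(i) {
    s <- shapes[[i]]
    cl <- arch$conv[[i]]
    conv_map(s[1], s[2], s[3], cl$kh, cl$kw, cl$sh, cl$sw, cl$ph, cl$pw)
  })
}

init_cnn_params <- function(arch) {
  shapes <- conv_output_shape(arch)
  p <- list()
  for (i in seq_along(arch$conv)) {
    cl <- arch$conv[[i]]
    K <- shapes[[i]][1] * cl$kh * cl$kw
    p[[paste0("W", i)]] <- he_init(cl$oc, K, K)
    p[[paste0("b", i)]] <- numeric(cl$oc)
  }
  flat <- prod(shapes[[4]])
  p$W4 <- he_init(flat, arch$fc_width, flat)
  p$b4 <- numeric(arch$fc_width)
  p$W5 <- he_init(arch$fc_width, arch$feature_width, arch$fc_width)
  p$b5 <- numeric(arch$feature_width)
  p$W6 <- he_init(arch$feature_width, arch$n_classes, arch$feature_width)
  p$b6 <- numeric(arch$n_classes)
  p
}

# Convert a feature-image set to the flat [n x D] batch matrix the network
# consumes, checking shapes and applying optional per-plane standardization.
images_matrix <- function(images, arch, stats = NULL) {
  planes <- if (inherits(images, "feature_images")) images$planes else images
  if (!is.list(planes)) planes <- list(planes)
  want <- arch$input_dim
  X <- matrix(0, length(planes), prod(want))
  for (i in seq_along(planes)) {
    a <- planes[[i]]
    if (!identical(dim(a), as.integer(want)))
      abort_input(sprintf("image %d has shape %s but the network expects %s",
                          i, paste(dim(a), collapse = "x"),
                          paste(want, collapse = "x")))
    if (!is.null(stats))
      a <- (a - stats$mean[slice.index(a, 1L)]) / stats$sd[slice.index(a, 1L)]
    X[i, ] <- flatten_chw(a)
  }
  X
}

cnn_forward_pass <- function(params, maps, arch, X, training = FALSE) {
  sl <- arch$leaky_slope
  n <- nrow(X)
  c1 <- conv_forward(X, params$W1, params$b1, maps[[1]])
  a1 <- leaky_relu(c1$out, sl)
  c2 <- conv_forward(a1, params$W2, params$b2, maps[[2]])
  a2 <- leaky_relu(c2$out, sl)
  c3 <- conv_forward(a2, params$W3, params$b3, maps[[3]])
  a3 <- leaky_relu(c3$out, sl)
  z4 <- dense_forward(a3, params$W4, params$b4)
  a4 <- leaky_relu(z4, sl)
  dr <- if (training) dropout_forward(a4, arch$dropout) else list(out = a4, mask = NULL)
  z5 <- dense_forward(dr$out, params$W5, params$b5)
  a5 <- leaky_relu(z5, sl)
  z6 <- dense_forward(a5, params$W6, params$b6)
  list(logits = z6, probs = row_softmax(z6), features = a5,
       cache = list(X = X, c1 = c1, a1 = a1, c2 = c2, a2 = a2, c3 = c3,
                    a3 = a3, z4 = z4, d4 = dr$out, mask = dr$mask,
                    z5 = z5, a5 = a5, n = n))
}

# dlogits: gradient of the loss w.r.t. logits; dfeatures: extra gradient
# arriving directly at the deep-feature layer (the center-loss term).
cnn_backward_pass <- function(params, maps, arch, cache, dlogits, dfeatures = NULL) {
  sl <- arch$leaky_slope
  g <- list()
  b6 <- dense_backward(dlogits, cache$a5, params$W6)
  g$W6 <- b6$dW; g$b6 <- b6$db
  da5 <- b6$dX
  if (!is.null(dfeatures)) da5 <- da5 + dfeatures
  dz5 <- da5 * leaky_relu_grad(cache$z5, sl)
  b5 <- dense_backward(dz5, cache$d4, params$W5)
  g$W5 <- b5$dW; g$b5 <- b5$db
  da4 <- b5$dX
  if (!is.null(cache$mask)) da4 <- da4 * cache$mask
  dz4 <- da4 * leaky_relu_grad(cache$z4, sl)
  b4 <- dense_backward(dz4, cache$a3, params$W4)
  g$W4 <- b4$dW; g$b4 <- b4$db
  dz3 <- b4$dX * leaky_relu_grad(cache$c3$out, sl)
  b3 <- conv_backward(dz3, cache$c3$cols, params$W3, maps[[3]], cache$n)
  g$W3 <- b3$dW; g$b3 <- b3$db
  dz2 <- b3$dX * leaky_relu_grad(cache$c2$out, sl)
  b2 <- conv_backward(dz2, cache$c2$cols, params$W2, maps[[2]], cache$n)
  g$W2 <- b2$dW; g$b2 <- b2$db
  dz1 <- b2$dX * leaky_relu_grad(cache$c1$out, sl)
  b1 <- conv_backward(dz1, cache$c1$cols, params$W1, maps[[1]], cache$n)
  g$W1 <- b1$dW; g$b1 <- b1$db
  g
}

#' Mean softmax cross-entropy loss
#'
#' Mean over the batch of the negative log softmax probability of the true
#' class, computed with a numerically stable log-sum-exp.
#'
#' @param logits numeric matrix `[n x M]` of unnormalized class scores.
#' @param labels integer vector in `1..M` (or a factor).
#' @return scalar loss.
#' @export
softmax_cross_entropy <- function(logits, labels) {
  logits <- rbind(logits)
  labels <- as_label_index(labels, ncol(logits))
  lse <- row_logsumexp(logits)
  mean(lse - logits[cbind(seq_len(nrow(logits)), labels)])
}

as_label_index <- function(labels, M) {
  if (is.factor(labels)) labels <- as.integer(labels)
  if (!is.numeric(labels) || any(labels < 1 | labels > M | labels != round(labels)))
    abort_input(sprintf("labels must be integers in 1..%d", M))
  as.integer(labels)
}

#' Per-class deep-feature centers
#'
#' Container for the running class centroids of the deep features together
#' with their update rate.
#'
#' @param centers numeric matrix `[M x d]`, one row per class.
#' @param alpha center learning rate, strictly inside (0, 1).
#' @return an object of class `class_centers`.
#' @export
class_centers <- function(centers, alpha = 0.5) {
  centers <- rbind(centers)
  if (!all(is.finite(centers))) abort_input("class centers must be finite")
  check_number(alpha, "alpha")
  if (alpha <= 0 || alpha >= 1) abort_input("`alpha` must lie strictly in (0, 1)")
  structure(list(centers = centers, alpha = alpha), class = "class_centers")
}

center_matrix <- function(centers) {
  if (inherits(centers, "class_centers")) centers$centers else rbind(centers)
}

#' Center loss
#'
#' Half the mean squared Euclidean distance between each deep feature and
#' its class center: `(1/2n) * sum_i ||x_i - c_{y_i}||^2`.
#'
#' @param features numeric matrix `[n x d]` of deep features.
#' @param labels class indices in `1..M`.
#' @param centers a [class_centers()] or bare `[M x d]` matrix.
#' @return scalar, non-negative.
#' @export
center_loss <- function(features, labels, centers) {
  cm <- center_matrix(centers)
  features <- rbind(features)
  labels <- as_label_index(labels, nrow(cm))
  d <- features - cm[labels, , drop = FALSE]
  sum(d * d) / (2 * nrow(features))
}

#' Analytic gradient of the center loss w.r.t. the features
#'
#' `(x_i - c_{y_i}) / n`, the exact derivative of [center_loss()].
#'
#' @inheritParams center_loss
#' @return matrix of the same shape as `features`.
#' @export
center_loss_grad <- function(features, labels, centers) {
  cm <- center_matrix(centers)
  features <- rbind(features)
  labels <- as_label_index(labels, nrow(cm))
  (features - cm[labels, , drop = FALSE]) / nrow(features)
}

#' Mini-batch update of the class centers
#'
#' For every class `j` present in the batch, the center moves toward the
#' batch mean of its features with a damped step:
#' `delta_j = sum_i 1(y_i = j) (c_j - x_i) / (1 + sum_i 1(y_i = j))` and
#' `c_j <- c_j - alpha * delta_j`. Classes absent from the batch are left
#' unchanged.
#'
#' @inheritParams center_loss
#' @return the updated [class_centers()].
#' @export
update_centers <- function(centers, features, labels) {
  if (!inherits(centers, "class_centers"))
    abort_input("`centers` must be a class_centers object")
  cm <- centers$centers
  features <- rbind(features)
  labels <- as_label_index(labels, nrow(cm))
  for (j in unique(labels)) {
    rows <- which(labels == j)
    nj <- length(rows)
    delta <- (nj * cm[j, ] - colSums(features[rows, , drop = FALSE])) / (1 + nj)
    cm[j, ] <- cm[j, ] - centers$alpha * delta
  }
  centers$centers <- cm
  centers
}

#' Joint softmax + center loss
#'
#' The training objective: softmax cross-entropy plus `lambda` times the
#' center loss. `lambda = 0` reduces exactly to [softmax_cross_entropy()].
#'
#' @inheritParams center_loss
#' @param logits numeric matrix `[n x M]`.
#' @param lambda non-negative weight of the center-loss term.
#' @return scalar loss.
#' @export
joint_loss <- function(logits, features, labels, centers, lambda) {
  check_number(lambda, "lambda", lower = 0)
  ce <- softmax_cross_entropy(logits, labels)
  if (lambda == 0) return(ce)
  ce + lambda * center_loss(features, labels, centers)
}

#' Training configuration for the feature network
#'
#' @param lambda center-loss weight (default 0.00025).
#' @param alpha center update rate in (0, 1).
#' @param learning_rate Adam learning rate.
#' @param batch_size mini-batch size.
#' @param epochs training epochs.
#' @param seed integer seed driving initialization, shuffling and dropout.
#' @param standardize if `TRUE`, standardize each feature plane (RMS, MAV,
#'   WL) to zero mean and unit variance using training-set statistics before
#'   feeding the network. Off by default: raw features are passed through.
#' @return an object of class `train_config`.
#' @export
train_config <- function(lambda = 0.00025, alpha = 0.5, learning_rate = 1e-4,
                         batch_size = 32L, epochs = 200L, seed = 1L,
                         standardize = FALSE) {
  check_number(lambda, "lambda", lower = 0)
  check_number(batch_size, "batch_size", lower = 1, integerish = TRUE)
  check_number(epochs, "epochs", lower = 1, integerish = TRUE)
  structure(list(lambda = lambda, alpha = alpha, learning_rate = learning_rate,
                 batch_size = as.integer(batch_size), epochs = as.integer(epochs),
                 seed = as.integer(seed), standardize = isTRUE(standardize)),
            class = "train_config")
}

#' Train the discriminative feature network
#'
#' Runs mini-batch Adam on the joint softmax + center loss. After each
#' optimizer step the class centers are updated from the same batch's
#' features via [update_centers()]. All randomness (weight initialization,
#' shuffling, dropout) derives from `cfg$seed`.
#'
#' @param images a `feature_images` set (see [encode_feature_images()]) or a
#'   list with elements `planes` (list of 3 x T x 8 arrays) and `label`.
#' @param cfg a [train_config()].
#' @param arch a [cnn_architecture()]; by default one matching the images'
#'   shape and number of classes.
#' @return an object of class `cnn_model` with elements `arch`, `params`,
#'   `centers` ([class_centers()]), `classes` (label levels), `history`
#'   (per-epoch data frame of losses and training accuracy),
#'   `final_train_accuracy` (inference-mode), and a weight `fingerprint`.
#' @export
train_cnn <- function(images, cfg = train_config(), arch = NULL) {
  labf <- factor(images$label)
  if (nlevels(labf) < 2L)
    abort_input("training data must contain at least 2 classes")
  if (is.null(arch)) {
    d <- dim(images$planes[[1]])
    arch <- cnn_architecture(input_dim = d, n_classes = nlevels(labf))
  }
  if (arch$n_classes != nlevels(labf))
    abort_input("`arch$n_classes` does not match the number of label levels")
  labels <- as.integer(labf)
  withr::local_seed(cfg$seed)

  stats <- NULL
  if (cfg$standardize) {
    raw <- images_matrix(images, arch)
    C <- arch$input_dim[1]
    plane_of <- rep.int(seq_len(C), prod(arch$input_dim[2:3]))
    mu <- vapply(seq_len(C), function(k) mean(raw[, plane_of == k]), 0)
    sd_ <- vapply(seq_len(C), function(k) stats::sd(as.vector(raw[, plane_of == k])), 0)
    sd_[sd_ == 0] <- 1
    stats <- list(mean = mu, sd = sd_)
  }
  X <- images_matrix(images, arch, stats)
  n <- nrow(X)
  maps <- build_conv_maps(arch)
  params <- init_cnn_params(arch)
  centers <- class_centers(matrix(0, arch$n_classes, arch$feature_width),
                           alpha = cfg$alpha)
  opt <- adam_init(params)
  hist <- vector("list", cfg$epochs)

  for (ep in seq_len(cfg$epochs)) {
    ord <- sample.int(n)
    starts <- seq(1L, n, by = cfg$batch_size)
    ce_s <- cl_s <- acc_s <- 0
    for (st in starts) {
      bi <- ord[st:min(st + cfg$batch_size - 1L, n)]
      nb <- length(bi)
      fw <- cnn_forward_pass(params, maps, arch, X[bi, , drop = FALSE], training = TRUE)
      yb <- labels[bi]
      ce <- softmax_cross_entropy(fw$logits, yb)
      cl <- center_loss(fw$features, yb, centers)
      dlogits <- fw$probs
      dlogits[cbind(seq_len(nb), yb)] <- dlogits[cbind(seq_len(nb), yb)] - 1
      dlogits <- dlogits / nb
      dfeat <- if (cfg$lambda > 0)
        cfg$lambda * center_loss_grad(fw$features, yb, centers) else NULL
      grads <- cnn_backward_pass(params, maps, arch, fw$cache, dlogits, dfeat)
      stp <- adam_step(params, grads, opt, cfg$learning_rate)
      params <- stp$params; opt <- stp$state
      centers <- update_centers(centers, fw$features, yb)
      ce_s <- ce_s + ce * nb
      cl_s <- cl_s + cl * nb
      acc_s <- acc_s + sum(max.col(fw$probs) == yb)
    }
    hist[[ep]] <- data.frame(epoch = ep, ce = ce_s / n, center = cl_s / n,
                             joint = (ce_s + cfg$lambda * cl_s) / n,
                             accuracy = acc_s / n)
  }

  model <- structure(list(arch = arch, params = params, maps = maps,
                          centers = centers, classes = levels(labf),
                          stats = stats, cfg = cfg,
                          history = do.call(rbind, hist)),
                     class = "cnn_model")
  fin <- cnn_forward_pass(params, maps, arch, X, training = FALSE)
  model$final_train_accuracy <- mean(max.col(fin$probs) == labels)
  model$fingerprint <- object_md5(params)
  model
}

#' Extract deep features and class predictions
#'
#' Inference-mode forward pass (dropout disabled, hence deterministic):
#' returns the deep-feature layer output, softmax probabilities, and the
#' predicted class for each image.
#'
#' @param model a trained [train_cnn()] model.
#' @param images a `feature_images` set or list of 3 x T x 8 arrays.
#' @return list with `features` (`[n x feature_width]` matrix), `probs`
#'   (`[n x M]`), and `pred` (factor of predicted class labels).
#' @export
extract_features <- function(model, images) {
  X <- images_matrix(images, model$arch, model$stats)
  fw <- cnn_forward_pass(model$params, model$maps, model$arch, X, training = FALSE)
  list(features = fw$features, probs = fw$probs,
       pred = factor(model$classes[max.col(fw$probs)], levels = model$classes))
}

#' @export
predict.cnn_model <- function(object, images, ...) {
  extract_features(object, images)$pred
}

#' @export
print.cnn_model <- function(x, ...) {
  shp <- conv_output_shape(x$arch)
  cat("CNN feature network:", length(x$classes), "classes,",
      x$arch$feature_width, "deep features\n")
  cat("  input ", paste(x$arch$input_dim, collapse = "x"),
      " -> conv ", paste(vapply(shp[-1], paste, "", collapse = "x"), collapse = " -> "),
      " -> fc ", x$arch$fc_width, " -> ", x$arch$feature_width, "\n", sep = "")
  cat("  trained", nrow(x$history), "epochs; final training accuracy",
      sprintf("%.3f", x$final_train_accuracy), "\n")
  invisible(x)
}

#' Save / load a feature-network checkpoint
#'
#' The checkpoint bundles the architecture, weights, class centers, label
#' levels, training configuration and the weight fingerprint.
#'
#' @param model a trained [train_cnn()] model.
#' @param path checkpoint path (`.rds`).
#' @return `path` invisibly, or the loaded `cnn_model`.
#' @export
save_cnn <- function(model, path) {
  if (!inherits(model, "cnn_model")) abort_input("not a cnn_model")
  saveRDS(model, path)
  invisible(path)
}

#' @rdname save_cnn
#' @export
load_cnn <- function(path) {
  x <- readRDS(path)
  if (!inherits(x, "cnn_model")) abort_input("file does not contain a CNN checkpoint")
  x
}

#' Write a JSON-lines training log
#'
#' One JSON object per epoch with the cross-entropy, center, and joint
#' losses and the training accuracy.
#'
#' @param model a trained [train_cnn()] model.
#' @param path file to write.
#' @return `path`, invisibly.
#' @export
write_training_log <- function(model, path) {
  h <- model$history
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_len(nrow(h)))
    writeLines(jsonlite::toJSON(as.list(h[i, ]), auto_unbox = TRUE, digits = NA), con)
  invisible(path)
}
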