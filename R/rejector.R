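#' Autoencoder specification
#'
#' Mirror-symmetric fully connected autoencoder: leaky-rectifier hidden
#' layers, linear output, trained by mean squared reconstruction error.
#'
#' @param widths layer widths from input to output; must be palindromic
#'   with equal first and last entries (default 512-256-128-64-128-256-512,
#'   a bottleneck at 1/8 of the input width).
#' @param leaky_slope negative-side slope of the hidden activations.
#' @return an object of class `ae_spec`.
#' @export
autoencoder_spec <- function(widths = c(512L, 256L, 128L, 64L, 128L, 256L, 512L),
                             leaky_slope = 0.01) {
  widths <- as.integer(widths)
  if (length(widths) < 3L || any(widths < 1L))
    abort_input("`widths` must list at least 3 positive layer widths")
  if (!identical(widths, rev(widths)))
    abort_input("`widths` must be palindromic (mirror architecture)")
  structure(list(widths = widths, leaky_slope = leaky_slope), class = "ae_spec")
}

ae_forward_pass <- function(params, spec, X, cache = FALSE) {
  L <- length(spec$widths) - 1L
  zs <- vector("list", L)
  a <- X
  acts <- vector("list", L + 1L)
  acts[[1]] <- a
  for (l in seq_len(L)) {
    z <- dense_forward(a, params[[paste0("W", l)]], params[[paste0("b", l)]])
    zs[[l]] <- z
    a <- if (l < L) leaky_relu(z, spec$leaky_slope) else z
    acts[[l + 1L]] <- a
  }
  if (cache) list(out = a, zs = zs, acts = acts) else list(out = a)
}

#' Train the rejection autoencoder
#'
#' Seeded mini-batch Adam minimization of the mean squared reconstruction
#' error on target-class deep features. The feature network that produced
#' the inputs is not touched.
#'
#' @param features numeric matrix `[n x d]` of deep features (target
#'   classes only); `d` must equal the spec's input width.
#' @param spec an [autoencoder_spec()].
#' @param epochs training epochs (default 1000).
#' @param learning_rate Adam learning rate.
#' @param batch_size mini-batch size.
#' @param seed integer seed.
#' @param cnn_fingerprint optional fingerprint of the feature network the
#'   features came from, stored for the calibration safety check.
#' @return an object of class `ae_model` with `spec`, `params`, `history`
#'   (per-epoch MSE), and `cnn_fingerprint`.
#' @export
train_autoencoder <- function(features, spec = autoencoder_spec(),
                              epochs = 1000L, learning_rate = 1e-4,
                              batch_size = 32L, seed = 1L,
                              cnn_fingerprint = NULL) {
  features <- rbind(features)
  if (nrow(features) < 1L) abort_input("`features` must contain at least one sample")
  d <- ncol(features)
  if (d != spec$widths[1])
    abort_input(sprintf("features are %d-wide but the autoencoder expects %d", d, spec$widths[1]))
  check_number(epochs, "epochs", lower = 1, integerish = TRUE)
  check_number(batch_size, "batch_size", lower = 1, integerish = TRUE)
  withr::local_seed(seed)

  L <- length(spec$widths) - 1L
  params <- list()
  for (l in seq_len(L)) {
    params[[paste0("W", l)]] <- he_init(spec$widths[l], spec$widths[l + 1L], spec$widths[l])
    params[[paste0("b", l)]] <- numeric(spec$widths[l + 1L])
  }
  opt <- adam_init(params)
  n <- nrow(features)
  history <- numeric(epochs)

  for (ep in seq_len(epochs)) {
    ord <- sample.int(n)
    mse_s <- 0
    for (st in seq(1L, n, by = batch_size)) {
      bi <- ord[st:min(st + batch_size - 1L, n)]
      X <- features[bi, , drop = FALSE]
      fw <- ae_forward_pass(params, spec, X, cache = TRUE)
      err <- fw$out - X
      mse_s <- mse_s + mean(err * err) * length(bi)
      dA <- 2 * err / length(err)
      grads <- list()
      for (l in rev(seq_len(L))) {
        dZ <- if (l < L) dA * leaky_relu_grad(fw$zs[[l]], spec$leaky_slope) else dA
        bk <- dense_backward(dZ, fw$acts[[l]], params[[paste0("W", l)]])
        grads[[paste0("W", l)]] <- bk$dW
        grads[[paste0("b", l)]] <- bk$db
        dA <- bk$dX
      }
      stp <- adam_step(params, grads, opt, learning_rate)
      params <- stp$params; opt <- stp$state
    }
    history[ep] <- mse_s / n
  }
  structure(list(spec = spec, params = params, history = history,
                 cnn_fingerprint = cnn_fingerprint),
            class = "ae_model")
}

#' Reconstruct features through the autoencoder
#'
#' @param ae a trained [train_autoencoder()] model.
#' @param features numeric vector or `[n x d]` matrix.
#' @return matrix of reconstructions with the shape of `features`.
#' @export
reconstruct <- function(ae, features) {
  ae_forward_pass(ae$params, ae$spec, rbind(features))$out
}

#' Pearson-correlation reconstruction error
#'
#' The rejection score of a feature vector `x` with reconstruction
#' `y = ae(x)` is `1 - rho(x, y)` where `rho` is the Pearson correlation, so
#' it lies in `[0, 2]`: 0 for a perfect reconstruction, 2 for perfect
#' anticorrelation. If either the input or its reconstruction is constant
#' the correlation is undefined and the maximal error 2 is returned with a
#' warning.
#'
#' @param ae a trained [train_autoencoder()] model.
#' @param features numeric vector or `[n x d]` matrix of deep features.
#' @return numeric vector of errors, one per row.
#' @export
reconstruction_error <- function(ae, features) {
  X <- rbind(features)
  Y <- reconstruct(ae, X)
  rho <- row_pearson(X, Y)
  if (anyNA(rho)) {
    warning("constant input or reconstruction: Pearson correlation undefined, ",
            "returning maximal error 2", call. = FALSE)
    rho[is.na(rho)] <- -1
  }
  unname(1 - rho)
}

#' Calibrate per-class rejection thresholds at a recall factor
#'
#' For each target class `c` with `n_c` validation reconstruction errors,
#' the threshold is the `ceiling(r * n_c)`-th order statistic: the smallest
#' error covering at least a fraction `r` of the class's validation samples.
#' A pooled global threshold is recorded the same way. Since boundary errors
#' are accepted by [decide()], the accepted fraction of each class on the
#' calibration set itself is guaranteed to be at least `r`.
#'
#' @param ae a trained [train_autoencoder()] model.
#' @param features `[n x d]` matrix of validation deep features (target
#'   classes only).
#' @param labels class label per row.
#' @param recall_factor preset recall `r` in (0, 1].
#' @param mode `"per_class"` (default) or `"global"`: which threshold
#'   [decide()] applies.
#' @return an object of class `rejection_model` bundling the autoencoder,
#'   the recall factor, per-class `thresholds`, the `global_threshold`, and
#'   the fingerprint of the feature network it was calibrated against.
#' @export
calibrate_thresholds <- function(ae, features, labels, recall_factor = 0.9,
                                 mode = c("per_class", "global")) {
  mode <- match.arg(mode)
  check_number(recall_factor, "recall_factor", lower = 0, upper = 1, strict_lower = TRUE)
  features <- rbind(features)
  labels <- as.character(labels)
  if (length(labels) != nrow(features))
    abort_input("`labels` must have one entry per feature row")
  errors <- reconstruction_error(ae, features)
  classes <- sort(unique(labels))
  thr <- vapply(classes, function(cl) {
    e <- sort(errors[labels == cl])
    if (!length(e)) abort_input(sprintf("class '%s' has no validation samples", cl))
    e[ceiling(recall_factor * length(e))]
  }, 0)
  pooled <- sort(errors)
  structure(list(ae = ae, recall_factor = recall_factor,
                 thresholds = thr,
                 global_threshold = pooled[ceiling(recall_factor * length(pooled))],
                 mode = mode, cnn_fingerprint = ae$cnn_fingerprint),
            class = "rejection_model")
}

#' @export
print.rejection_model <- function(x, ...) {
  cat(sprintf("rejection model: recall factor %.2f, %s thresholds\n",
              x$recall_factor, x$mode))
  print(round(x$thresholds, 5))
  cat(sprintf("global threshold: %.5f\n", x$global_threshold))
  invisible(x)
}

#' Accept-or-reject decisions for deep features
#'
#' Computes each sample's reconstruction error and accepts it with its
#' CNN-predicted label iff the error does not exceed the threshold of that
#' class (or the global threshold in `"global"` mode). A boundary error
#' exactly equal to the threshold accepts, which preserves the calibration
#' recall guarantee on the calibration set itself.
#'
#' @param model a [calibrate_thresholds()] rejection model.
#' @param features `[n x d]` matrix of deep features.
#' @param pred CNN-predicted class label per row.
#' @return data frame with columns `verdict` (`"accept"`/`"reject"`),
#'   `label` (the accepted class label, `NA` when rejected), and `error`.
#' @export
decide <- function(model, features, pred) {
  if (!inherits(model, "rejection_model"))
    abort_input("`model` must be a calibrated rejection_model")
  features <- rbind(features)
  pred <- as.character(pred)
  e <- reconstruction_error(model$ae, features)
  tau <- if (model$mode == "global") rep(model$global_threshold, length(e))
         else {
           unknown <- setdiff(unique(pred), names(model$thresholds))
           if (length(unknown))
             abort_input(sprintf("no calibrated threshold for predicted class '%s'", unknown[1]))
           model$thresholds[pred]
         }
  accept <- e <= tau
  data.frame(verdict = ifelse(accept, "accept", "reject"),
             label = ifelse(accept, pred, NA_character_),
             error = e, row.names = NULL)
}

#' End-to-end open-set classification
#'
#' Runs the feature network and the rejection gate on a set of feature
#' images. Refuses to combine a rejection model with a feature network other
#' than the one it was calibrated against unless `force = TRUE`.
#'
#' @param cnn a trained [train_cnn()] model.
#' @param model a [calibrate_thresholds()] rejection model.
#' @param images a `feature_images` set.
#' @param force bypass the fingerprint check.
#' @return data frame with `pred` (closed-set CNN label), `verdict`,
#'   `label`, `error`.
#' @export
classify_open_set <- function(cnn, model, images, force = FALSE) {
  if (!force && !is.null(model$cnn_fingerprint) &&
      !identical(model$cnn_fingerprint, cnn$fingerprint))
    abort_input("rejection model was calibrated against a different feature network ",
                "(use force = TRUE to override)")
  ex <- extract_features(cnn, images)
  d <- decide(model, ex$features, ex$pred)
  cbind(data.frame(pred = as.character(ex$pred)), d)
}

#' Save / load a rejection model
#'
#' @param model a `rejection_model`.
#' @param path file path (`.rds`).
#' @return `path` invisibly, or the loaded model.
#' @export
save_rejection_model <- function(model, path) {
  if (!inherits(model, "rejection_model")) abort_input("not a rejection_model")
  saveRDS(model, path)
  invisible(path)
}

#' @rdname save_rejection_model
#' @export
load_rejection_model <- function(path) {
  x <- readRDS(path)
  if (!inherits(x, "rejection_model")) abort_input("file does not contain a rejection model")
  x
}
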