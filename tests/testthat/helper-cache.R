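# Memoized pipeline runs and fixtures shared across test files. Training is
# the expensive step, so identical configurations are computed once per
# session and reused wherever a trained model is needed.

.osemg_test_cache <- new.env(parent = emptyenv())

cache_get <- function(key, compute) {
  if (is.null(.osemg_test_cache[[key]]))
    assign(key, compute(), envir = .osemg_test_cache)
  .osemg_test_cache[[key]]
}

cached_pipeline <- function(config) {
  cache_get(osemg:::object_md5(unclass(config)), function() run_pipeline(config))
}

# A full run under the canonical study conditions (defaults), keyed by seed,
# center-loss weight, and similarity band.
default_run <- function(seed = 1L, lambda = 0.00025, similarity = c(0.5, 0.95)) {
  cached_pipeline(pipeline_config(seed = seed,
                                  simulation = list(similarity = similarity),
                                  cnn = list(lambda = lambda)))
}

# A fast, small pipeline (short repetitions, shallow stack, few epochs) for
# plumbing tests where statistical performance is irrelevant.
tiny_config <- function(seed = 1L) {
  pipeline_config(seed = seed,
                  simulation = list(repetition_s = 3, rest_s = 1, repetitions = 5L),
                  preprocess = list(stack = 22L),
                  cnn = list(epochs = 8L),
                  ae = list(epochs = 40L))
}

tiny_run <- function(seed = 1L) cached_pipeline(tiny_config(seed))

# Default synthetic feature images (all 12 movements) and a 50-epoch
# feature network trained on their target classes.
default_images <- function(seed = 0L) {
  cache_get(paste0("images", seed), function() {
    rec <- generate_recording(simulation_config(default_movement_set(), seed = seed))
    preprocess_recording(rec)$images
  })
}

fifty_epoch_cnn <- function() {
  cache_get("cnn50", function() {
    imgs <- default_images(0L)
    train_cnn(imgs[imgs$kind != "unrelated"], train_config(epochs = 50L, seed = 0L))
  })
}

# Hand-built autoencoders with controlled behavior -------------------------

# Identity-like AE on positive inputs: y = x + shift (optionally negated).
manual_ae <- function(d = 4L, shift = rep(0, d), negate = FALSE) {
  spec <- autoencoder_spec(c(d, d, d))
  sgn <- if (negate) -1 else 1
  structure(list(spec = spec,
                 params = list(W1 = diag(d), b1 = numeric(d),
                               W2 = sgn * diag(d), b2 = shift),
                 history = numeric(0), cnn_fingerprint = NULL),
            class = "ae_model")
}

# AE whose output is the constant vector v regardless of the input, so the
# reconstruction error of a sample is fully determined by its correlation
# with v. `features_with_errors()` builds inputs achieving exact errors.
constant_ae <- function(v = c(1, 2, 3, 4)) {
  d <- length(v)
  structure(list(spec = autoencoder_spec(c(d, d, d)),
                 params = list(W1 = matrix(0, d, d), b1 = v,
                               W2 = diag(d), b2 = numeric(d)),
                 history = numeric(0), cnn_fingerprint = NULL),
            class = "ae_model")
}

features_with_errors <- function(errors, v = c(1, 2, 3, 4)) {
  vc <- v - mean(v)
  uc <- c(1, -1, -1, 1)             # mean-zero, orthogonal to 1:4 centered
  stopifnot(abs(sum(vc * uc)) < 1e-12)
  vh <- vc / sqrt(sum(vc^2)); uh <- uc / sqrt(sum(uc^2))
  t(vapply(errors, function(e) {
    rho <- 1 - e
    rho * vh + sqrt(max(0, 1 - rho^2)) * uh + 5
  }, numeric(length(v))))
}

# Small randomly initialized (untrained) AE for properties that must hold
# for any model.
random_ae <- function(widths = c(32L, 16L, 32L), seed = 1L) {
  feats <- withr::with_seed(seed, matrix(stats::rnorm(2L * widths[1]), 2L))
  train_autoencoder(feats, autoencoder_spec(widths), epochs = 1L, seed = seed)
}

# Brute-force pairwise concordance AUC: P(target error < unrelated error)
# plus half the ties.
brute_force_auc <- function(scores, is_unrelated) {
  et <- scores[!is_unrelated]; eu <- scores[is_unrelated]
  tot <- 0
  for (a in et) for (b in eu) tot <- tot + (a < b) + 0.5 * (a == b)
  tot / (length(et) * length(eu))
}
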