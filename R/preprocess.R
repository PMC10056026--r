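#' Number of sliding windows that fit in a trial
#'
#' `floor((n - L) / S) + 1` for a trial of `n` samples, window length `L`
#' and step `S` (all in samples); 0 if the trial is shorter than one window.
#'
#' @param n trial length in samples.
#' @param window_len window length in samples.
#' @param step window step in samples.
#' @return integer window count.
#' @export
window_count <- function(n, window_len, step) {
  if (n < window_len) return(0L)
  as.integer((n - window_len) %/% step + 1L)
}

#' Segment a recording into sliding analysis windows
#'
#' Cuts overlapping windows of `window_ms` every `step_ms` within each trial
#' (never across trial boundaries). Trials shorter than one window
#' contribute no windows.
#'
#' @param recording an [emg_recording()].
#' @param window_ms window length in milliseconds (default 250, i.e. 50
#'   samples at 200 Hz).
#' @param step_ms window step in milliseconds (default 100).
#' @return an object of class `emg_windows`: list with `samples` (array
#'   `[window_len x 8 x n_windows]`), `info` (data frame with `trial`,
#'   `label`, `kind`, `start`), `window_len`, `step`, `sampling_rate`.
#' @export
segment_windows <- function(recording, window_ms = 250, step_ms = 100) {
  rate <- recording$sampling_rate
  L <- window_ms * rate / 1000
  S <- step_ms * rate / 1000
  for (v in c(L = L, S = S))
    if (abs(v - round(v)) > 1e-8 || round(v) < 1)
      abort_input("window length and step must map to whole sample counts >= 1")
  L <- as.integer(round(L)); S <- as.integer(round(S))

  tr <- recording$trials
  counts <- vapply(seq_len(nrow(tr)), function(i)
    window_count(tr$end[i] - tr$start[i], L, S), 0L)
  total <- sum(counts)
  samples <- array(0, dim = c(L, 8L, total))
  info <- data.frame(trial = integer(total), label = character(total),
                     kind = character(total), start = integer(total))
  k <- 0L
  for (i in seq_len(nrow(tr))) {
    if (counts[i] == 0L) next
    starts <- tr$start[i] + (seq_len(counts[i]) - 1L) * S
    for (s in starts) {
      k <- k + 1L
      samples[, , k] <- recording$samples[(s + 1L):(s + L), ]
      info$trial[k] <- i; info$label[k] <- tr$label[i]
      info$kind[k] <- tr$kind[i]; info$start[k] <- s
    }
  }
  structure(list(samples = samples, info = info, window_len = L, step = S,
                 sampling_rate = rate),
            class = "emg_windows")
}

subset_windows <- function(windows, idx) {
  structure(list(samples = windows$samples[, , idx, drop = FALSE],
                 info = windows$info[idx, , drop = FALSE],
                 window_len = windows$window_len, step = windows$step,
                 sampling_rate = windows$sampling_rate),
            class = "emg_windows")
}

#' Muscle-activity threshold from the neutral signal
#'
#' The boundary between rest and muscle activity is the mean plus three
#' standard deviations of the rectified (absolute-value) neutral signal.
#' The standard deviation is the population (1/N) form.
#'
#' @param neutral_samples numeric vector or matrix of neutral-state signal
#'   amplitudes (rectification is applied internally).
#' @return an object of class `activity_threshold` with `mu_neutral`,
#'   `sigma_neutral`, and `threshold = mu_neutral + 3 * sigma_neutral`.
#' @export
fit_activity_threshold <- function(neutral_samples) {
  x <- as.numeric(neutral_samples)
  if (length(x) < 2L) abort_input("`neutral_samples` needs at least 2 samples")
  if (any(!is.finite(x))) abort_input("`neutral_samples` must be finite")
  r <- abs(x)
  mu <- mean(r)
  sigma <- sqrt(mean((r - mu)^2))
  structure(list(mu_neutral = mu, sigma_neutral = sigma,
                 threshold = mu + 3 * sigma),
            class = "activity_threshold")
}

#' Is a window in the muscle-activity state?
#'
#' A window counts as active when its mean rectified amplitude over all
#' samples and channels is strictly greater than the threshold.
#'
#' @param window numeric matrix `[window_len x channels]`.
#' @param threshold an [fit_activity_threshold()] object.
#' @return logical.
#' @export
is_active <- function(window, threshold) {
  mean(abs(window)) > threshold$threshold
}

#' Activity flags for every window in a set
#'
#' @param windows an [segment_windows()] result.
#' @param threshold an [fit_activity_threshold()] object.
#' @return logical vector, one flag per window.
#' @export
active_windows <- function(windows, threshold) {
  n <- dim(windows$samples)[3]
  if (n == 0L) return(logical(0))
  m <- colMeans(abs(matrix(windows$samples, ncol = n)))
  m > threshold$threshold
}

#' Time-domain features: RMS, MAV, WL
#'
#' Root mean square `sqrt(mean(x^2))`, mean absolute value `mean(|x|)`, and
#' waveform length `sum(|x_n - x_(n-1)|)` of a single-channel sample
#' sequence.
#'
#' @param x numeric vector (length >= 1; `wl` needs length >= 2).
#' @return scalar feature value.
#' @export
rms <- function(x) {
  if (length(x) < 1L) abort_input("`x` must contain at least 1 sample")
  sqrt(mean(x^2))
}

#' @rdname rms
#' @export
mav <- function(x) {
  if (length(x) < 1L) abort_input("`x` must contain at least 1 sample")
  mean(abs(x))
}

#' @rdname rms
#' @export
wl <- function(x) {
  if (length(x) < 2L) abort_input("`wl` needs at least 2 samples")
  sum(abs(diff(x)))
}

# Per-channel features of one window: 3 x channels matrix (RMS, MAV, WL rows).
window_feature_rows <- function(w) {
  rbind(rms = sqrt(colMeans(w^2)),
        mav = colMeans(abs(w)),
        wl = colSums(abs(diff(w))))
}

#' Encode windows into CNN-ready feature images
#'
#' Each window yields a 3 x 8 feature row (per-channel RMS, MAV, WL);
#' `stack` consecutive windows of one trial are stacked into a
#' `3 x stack x 8` image, sliding with stride 1 over the trial's window
#' sequence. Trials with fewer than `stack` windows yield a single image
#' padded by repeating the final feature row (the pad count is recorded);
#' trials with no windows yield nothing.
#'
#' @param windows an `emg_windows` set (typically already restricted to
#'   muscle-active windows).
#' @param stack number of stacked window rows `T` per image (default 53).
#' @return an object of class `feature_images`: list with `planes` (list of
#'   `3 x stack x 8` arrays), `label`, `kind`, `trial`, `pad` vectors.
#' @export
encode_feature_images <- function(windows, stack = 53L) {
  check_number(stack, "stack", lower = 1, integerish = TRUE)
  stack <- as.integer(stack)
  n <- dim(windows$samples)[3]
  planes <- list(); label <- kind <- character(0); trial <- pad <- integer(0)
  for (tr in unique(windows$info$trial)) {
    idx <- which(windows$info$trial == tr)
    k <- length(idx)
    feat <- array(0, dim = c(3L, k, 8L))   # rows RMS/MAV/WL, time, channel
    for (j in seq_len(k))
      feat[, j, ] <- window_feature_rows(windows$samples[, , idx[j]])
    starts <- if (k >= stack) seq_len(k - stack + 1L) else 1L
    for (s in starts) {
      take <- if (k >= stack) s:(s + stack - 1L) else c(seq_len(k), rep(k, stack - k))
      planes[[length(planes) + 1L]] <- feat[, take, , drop = FALSE]
      label <- c(label, windows$info$label[idx[1]])
      kind <- c(kind, windows$info$kind[idx[1]])
      trial <- c(trial, tr)
      pad <- c(pad, max(0L, stack - k))
    }
  }
  structure(list(planes = planes, label = label, kind = kind,
                 trial = trial, pad = pad),
            class = "feature_images")
}

#' @export
print.feature_images <- function(x, ...) {
  d <- if (length(x$planes)) paste(dim(x$planes[[1]]), collapse = "x") else "none"
  cat(sprintf("%d feature images (%s) over %d classes\n",
              length(x$planes), d, length(unique(x$label))))
  invisible(x)
}

#' Subset a feature-image set
#'
#' @param x a `feature_images` object.
#' @param i index vector.
#' @param ... unused.
#' @export
`[.feature_images` <- function(x, i, ...) {
  structure(list(planes = x$planes[i], label = x$label[i], kind = x$kind[i],
                 trial = x$trial[i], pad = x$pad[i]),
            class = "feature_images")
}

#' @export
length.feature_images <- function(x) length(x$planes)

#' Full preprocessing of a recording
#'
#' Fits the activity threshold on the recording's neutral-kind trials,
#' segments all trials into windows, flags muscle-active windows, and
#' encodes feature images. Non-neutral trials use their active windows;
#' trials with no active window (the neutral class by construction) fall
#' back to all of their windows, so the neutral/rest class is represented.
#'
#' @param recording an [emg_recording()].
#' @param window_ms,step_ms window length and step in milliseconds.
#' @param stack image stack depth `T`.
#' @return list with `images` (a `feature_images` set), `threshold`, and
#'   `windows` (the segmented `emg_windows` with an `active` flag column).
#' @export
preprocess_recording <- function(recording, window_ms = 250, step_ms = 100,
                                 stack = 53L) {
  threshold <- fit_activity_threshold(neutral_samples(recording))
  windows <- segment_windows(recording, window_ms, step_ms)
  act <- active_windows(windows, threshold)
  windows$info$active <- act
  keep <- logical(length(act))
  for (tr in unique(windows$info$trial)) {
    idx <- which(windows$info$trial == tr)
    sel <- idx[act[idx]]
    if (!length(sel)) sel <- idx
    keep[sel] <- TRUE
  }
  images <- encode_feature_images(subset_windows(windows, which(keep)), stack)
  list(images = images, threshold = threshold, windows = windows)
}

#' Save / load a feature-image archive
#'
#' Feature images round-trip losslessly through R's native serialization.
#'
#' @param images a `feature_images` set.
#' @param path archive path (`.rds`).
#' @return `path` invisibly, or the loaded `feature_images`.
#' @export
save_feature_images <- function(images, path) {
  if (!inherits(images, "feature_images")) abort_input("not a feature_images set")
  saveRDS(images, path)
  invisible(path)
}

#' @rdname save_feature_images
#' @export
load_feature_images <- function(path) {
  x <- readRDS(path)
  if (!inherits(x, "feature_images")) abort_input("archive does not contain feature images")
  x
}
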