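#' Movement specification
#'
#' Describes one movement class by its per-channel activation pattern: the
#' standard deviation of the sEMG-like signal on channel `ch` during an
#' active repetition is `base_amplitude * activation[ch] + noise_sd`.
#'
#' @param name label string.
#' @param kind one of `"target"`, `"unrelated"`, `"neutral"`.
#' @param activation numeric vector of exactly 8 non-negative per-channel
#'   gains.
#' @param base_amplitude overall amplitude scale (arbitrary units).
#' @return an object of class `movement_spec`.
#' @export
movement_spec <- function(name, kind = c("target", "unrelated", "neutral"),
                          activation, base_amplitude = 1) {
  kind <- match.arg(kind)
  if (!is.character(name) || length(name) != 1L || !nzchar(name))
    abort_input("`name` must be a non-empty string")
  if (length(activation) != 8L || any(!is.finite(activation)) || any(activation < 0))
    abort_input(sprintf("`activation` for '%s' must be 8 non-negative finite gains", name))
  check_number(base_amplitude, "base_amplitude", lower = 0)
  structure(list(name = name, kind = kind,
                 activation = as.numeric(activation),
                 base_amplitude = base_amplitude),
            class = "movement_spec")
}

cos_sim <- function(a, b) {
  na <- sqrt(sum(a * a)); nb <- sqrt(sum(b * b))
  if (na == 0 || nb == 0) return(0)
  sum(a * b) / (na * nb)
}

#' Default movement set: 7 target classes and 5 unrelated classes
#'
#' Builds the canonical simulated repertoire: six wrist movements with
#' near-orthogonal activation patterns (each drives one primary and one
#' secondary forearm channel, with equal total gain so classes are not
#' separable by overall amplitude), a neutral class whose gains are at most
#' 5% of the largest target gain, and five unrelated movements. Each
#' unrelated movement is a convex mixture of two target activations plus a
#' small deterministic perturbation, with the mixing weight solved
#' numerically so that its largest cosine similarity to any target lands at
#' a prescribed level inside `similarity`; the five levels are spread evenly
#' across the band (levels below the geometrically attainable minimum are
#' raised to it). Widening the band's upper bound therefore makes the
#' unrelated movements more confusable with the targets.
#'
#' @param similarity length-2 numeric band `c(lower, upper)` for the maximum
#'   cosine similarity between an unrelated activation and the closest
#'   target activation.
#' @return list of 12 [movement_spec()] objects (7 target-side, of which one
#'   neutral, then 5 unrelated).
#' @export
default_movement_set <- function(similarity = c(0.5, 0.95)) {
  if (length(similarity) != 2L || similarity[1] >= similarity[2] ||
      similarity[1] < 0 || similarity[2] > 1)
    abort_input("`similarity` must be an increasing band inside [0, 1]")
  tnames <- c("pronation", "supination", "extension", "flexion",
              "radial_deviation", "ulnar_deviation")
  tpat <- lapply(1:6, function(i) {
    a <- numeric(8); a[i] <- 1; a[i + 2L] <- 0.5; a
  })
  specs <- lapply(seq_along(tnames), function(i)
    movement_spec(tnames[i], "target", tpat[[i]]))
  specs <- c(specs, list(movement_spec("neutral", "neutral", rep(0.03, 8))))

  unames <- c("finger_abduction", "fist", "pronation_alt", "supination_alt",
              "extension_closed")
  pairs <- list(c(1L, 2L), c(2L, 3L), c(3L, 4L), c(4L, 5L), c(5L, 6L))
  tnorm <- mean(vapply(tpat, function(p) sqrt(sum(p * p)), 0))
  lo <- similarity[1]; hi <- similarity[2]
  for (i in seq_along(unames)) {
    pa <- tpat[[pairs[[i]][1]]]
    pb <- tpat[[pairs[[i]][2]]]
    pert <- numeric(8); pert[(i * 3L) %% 8L + 1L] <- 0.08
    maxcos <- function(w) {
      u <- w * pa + (1 - w) * pb + pert
      max(vapply(tpat, cos_sim, 0, a = u))
    }
    level <- lo + i * (hi - lo) / (length(unames) + 1)
    wmin <- stats::optimize(maxcos, c(0, 1))$minimum
    floor_sim <- maxcos(wmin)
    if (floor_sim > hi)
      abort_input(sprintf(
        "similarity band upper bound %.2f is below the attainable minimum %.2f for the default patterns",
        hi, floor_sim))
    w <- if (floor_sim >= level) wmin else
      stats::uniroot(function(w) maxcos(w) - level, c(wmin, 1), tol = 1e-10)$root
    u <- w * pa + (1 - w) * pb + pert
    u <- u * tnorm / sqrt(sum(u * u))
    specs <- c(specs, list(movement_spec(unames[i], "unrelated", u)))
  }
  validate_movement_set(specs, similarity)
  specs
}

# Checks the movement-set invariants; returns the specs invisibly.
validate_movement_set <- function(movements, similarity = c(0.5, 0.95)) {
  if (!all(vapply(movements, inherits, TRUE, "movement_spec")))
    abort_input("`movements` must be a list of movement_spec objects")
  kinds <- vapply(movements, `[[`, "", "kind")
  tpat <- lapply(movements[kinds == "target"], `[[`, "activation")
  if (length(tpat)) {
    gmax <- max(vapply(tpat, max, 0))
    for (m in movements[kinds == "neutral"])
      if (any(m$activation > 0.05 * gmax))
        abort_input(sprintf("neutral '%s' has gains above 5%% of the maximum target gain", m$name))
    for (m in movements[kinds == "unrelated"]) {
      cs <- max(vapply(tpat, cos_sim, 0, a = m$activation))
      if (cs < similarity[1] - 1e-8 || cs > similarity[2] + 1e-8)
        abort_input(sprintf("unrelated '%s' has max target cosine %.3f outside [%.2f, %.2f]",
                            m$name, cs, similarity[1], similarity[2]))
    }
  }
  invisible(movements)
}

#' Simulation configuration
#'
#' @param movements list of [movement_spec()] objects; defaults to
#'   [default_movement_set()].
#' @param sampling_rate sampling rate in Hz.
#' @param repetition_s duration of each active repetition in seconds.
#' @param rest_s rest duration after each repetition in seconds.
#' @param repetitions repetitions per movement.
#' @param noise_sd standard deviation of the baseline noise floor present on
#'   every channel at all times (arbitrary units).
#' @param seed integer seed; the generated recording is a deterministic
#'   function of the configuration.
#' @return an object of class `simulation_config`.
#' @export
simulation_config <- function(movements = default_movement_set(),
                              sampling_rate = 200, repetition_s = 5,
                              rest_s = 3, repetitions = 6,
                              noise_sd = 0.02, seed = 1L) {
  check_number(sampling_rate, "sampling_rate", lower = 0, strict_lower = TRUE)
  check_number(repetition_s, "repetition_s", lower = 0)
  check_number(rest_s, "rest_s", lower = 0)
  check_number(repetitions, "repetitions", lower = 1, integerish = TRUE)
  check_number(noise_sd, "noise_sd", lower = 0)
  check_number(seed, "seed", integerish = TRUE)
  if (!length(movements)) abort_input("`movements` must contain at least one movement_spec")
  validate_movement_set(movements, c(0, 1))
  structure(list(movements = movements, sampling_rate = sampling_rate,
                 repetition_s = repetition_s, rest_s = rest_s,
                 repetitions = as.integer(repetitions), noise_sd = noise_sd,
                 seed = as.integer(seed)),
            class = "simulation_config")
}

#' Multichannel sEMG recording
#'
#' @param samples numeric matrix `[time x 8]` in arbitrary amplitude units.
#' @param sampling_rate sampling rate in Hz.
#' @param trials data frame with columns `start`, `end` (0-based, half-open
#'   sample indices), `label`, `kind`; intervals must lie inside the sample
#'   range and must not overlap.
#' @param subject_id subject identifier string.
#' @return an object of class `emg_recording`.
#' @export
emg_recording <- function(samples, sampling_rate, trials, subject_id = "S1") {
  samples <- as.matrix(samples)
  if (ncol(samples) != 8L) abort_input("`samples` must have exactly 8 channels")
  check_number(sampling_rate, "sampling_rate", lower = 0, strict_lower = TRUE)
  need <- c("start", "end", "label", "kind")
  if (!all(need %in% names(trials))) abort_input("`trials` needs columns start, end, label, kind")
  trials <- trials[order(trials$start), , drop = FALSE]
  if (nrow(trials)) {
    if (any(trials$start < 0) || any(trials$end > nrow(samples)) ||
        any(trials$end < trials$start))
      abort_input("trial intervals must lie within the sample range")
    if (any(trials$start[-1] < trials$end[-nrow(trials)]))
      abort_input("trial intervals must not overlap")
  }
  rownames(trials) <- NULL
  colnames(samples) <- paste0("ch", 1:8)
  structure(list(samples = samples, sampling_rate = sampling_rate,
                 trials = trials, subject_id = subject_id),
            class = "emg_recording")
}

#' @export
print.emg_recording <- function(x, ...) {
  cat(sprintf("sEMG recording: %d samples x 8 channels at %g Hz, %d trials, subject %s\n",
              nrow(x$samples), x$sampling_rate, nrow(x$trials), x$subject_id))
  invisible(x)
}

# Band-shaped (20-95 Hz at 200 Hz) unit-variance noise, one column per channel.
shaped_noise <- function(n, n_ch, sampling_rate) {
  x <- matrix(stats::rnorm(n * n_ch), n, n_ch)
  nyq <- sampling_rate / 2
  lo <- 20; hi <- min(95, 0.95 * nyq)
  if (hi > lo && n > 24) {
    bf <- signal::butter(4, c(lo, hi) / nyq, type = "pass")
    for (j in seq_len(n_ch)) x[, j] <- signal::filtfilt(bf, x[, j])
  }
  for (j in seq_len(n_ch)) {
    s <- stats::sd(x[, j])
    if (s > 0) x[, j] <- x[, j] / s
  }
  x
}

# Trapezoidal on/off envelope with `ramp_n`-sample linear ramps.
trapezoid_envelope <- function(n, ramp_n) {
  if (n <= 0) return(numeric(0))
  if (ramp_n <= 0) return(rep(1, n))
  i <- seq_len(n)
  pmin(1, i / ramp_n, (n - i + 1) / ramp_n)
}

#' Generate a synthetic sEMG recording
#'
#' Emits, for every repetition round and movement, `repetition_s` seconds of
#' zero-mean band-shaped noise whose per-channel standard deviation is
#' `base_amplitude * activation[ch] + noise_sd` (modulated by a trapezoidal
#' onset/offset envelope with 200 ms ramps), followed by `rest_s` seconds of
#' noise at the `noise_sd` floor. Trials are labeled with their movement and
#' kind; the output is a deterministic function of `config` (including its
#' seed).
#'
#' @param config a [simulation_config()].
#' @param subject_id subject identifier stored in the recording.
#' @return an [emg_recording()].
#' @export
generate_recording <- function(config, subject_id = "S1") {
  if (!inherits(config, "simulation_config"))
    abort_input("`config` must be a simulation_config")
  rate <- config$sampling_rate
  rep_n <- round(config$repetition_s * rate)
  rest_n <- round(config$rest_s * rate)
  movs <- config$movements
  nm <- length(movs)
  total <- config$repetitions * nm * (rep_n + rest_n)
  if (total < 1) abort_input("configuration produces an empty recording")

  withr::local_seed(config$seed)
  noise <- shaped_noise(total, 8L, rate)
  amp <- matrix(config$noise_sd, total, 8L)
  env <- trapezoid_envelope(rep_n, round(0.2 * rate))

  trials <- vector("list", config$repetitions * nm)
  pos <- 0L
  k <- 0L
  for (r in seq_len(config$repetitions)) {
    for (m in movs) {
      if (rep_n > 0) {
        seg <- (pos + 1L):(pos + rep_n)
        amp[seg, ] <- amp[seg, ] + outer(env, m$base_amplitude * m$activation)
      }
      k <- k + 1L
      trials[[k]] <- data.frame(start = pos, end = pos + rep_n,
                                label = m$name, kind = m$kind)
      pos <- pos + rep_n + rest_n
    }
  }
  emg_recording(noise * amp, rate, do.call(rbind, trials), subject_id)
}

#' Samples belonging to neutral-kind trials
#'
#' Convenience accessor used to fit the muscle-activity threshold.
#'
#' @param recording an [emg_recording()].
#' @return numeric matrix of the concatenated neutral-trial samples.
#' @export
neutral_samples <- function(recording) {
  tr <- recording$trials[recording$trials$kind == "neutral", , drop = FALSE]
  if (!nrow(tr)) abort_input("recording contains no neutral-kind trials")
  idx <- unlist(lapply(seq_len(nrow(tr)), function(i)
    seq.int(tr$start[i] + 1L, length.out = tr$end[i] - tr$start[i])))
  recording$samples[idx, , drop = FALSE]
}

#' Write / read a recording as a CSV pair
#'
#' The signal file has header `t,ch1..ch8` (`t` in seconds); the sidecar
#' trial table has columns `trial_id,start,end,label,kind,subject` with
#' 0-based, half-open `[start, end)` sample indices.
#'
#' @param recording an [emg_recording()].
#' @param signal_path,trials_path output CSV paths.
#' @return `signal_path`, invisibly.
#' @export
write_recording_csv <- function(recording, signal_path, trials_path) {
  n <- nrow(recording$samples)
  sig <- data.frame(t = (seq_len(n) - 1L) / recording$sampling_rate,
                    recording$samples, check.names = FALSE)
  utils::write.csv(sig, signal_path, row.names = FALSE)
  tr <- recording$trials
  out <- data.frame(trial_id = seq_len(nrow(tr)), start = tr$start, end = tr$end,
                    label = tr$label, kind = tr$kind,
                    subject = recording$subject_id)
  utils::write.csv(out, trials_path, row.names = FALSE)
  invisible(signal_path)
}

#' @rdname write_recording_csv
#' @export
read_recording_csv <- function(signal_path, trials_path) {
  sig <- utils::read.csv(signal_path, check.names = FALSE)
  tr <- utils::read.csv(trials_path)
  rate <- if (nrow(sig) > 1) 1 / stats::median(diff(sig$t)) else 1
  emg_recording(as.matrix(sig[, paste0("ch", 1:8)]), round(rate, 6),
                tr[, c("start", "end", "label", "kind")],
                subject_id = as.character(tr$subject[1] %||% "S1"))
}

#' Write / read a simulation configuration as JSON
#'
#' @param config a [simulation_config()].
#' @param path JSON file path.
#' @return `path` invisibly, or the parsed [simulation_config()].
#' @export
write_simulation_config <- function(config, path) {
  x <- list(sampling_rate = config$sampling_rate,
            repetition_s = config$repetition_s, rest_s = config$rest_s,
            repetitions = config$repetitions, noise_sd = config$noise_sd,
            seed = config$seed,
            movements = lapply(config$movements, function(m)
              list(name = m$name, kind = m$kind, activation = m$activation,
                   base_amplitude = m$base_amplitude)))
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname write_simulation_config
#' @export
read_simulation_config <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE, simplifyDataFrame = FALSE)
  movs <- lapply(x$movements, function(m)
    movement_spec(m$name, m$kind, unlist(m$activation), m$base_amplitude))
  simulation_config(movs, x$sampling_rate, x$repetition_s, x$rest_s,
                    x$repetitions, x$noise_sd, x$seed)
}
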