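test_that("generated recordings have the configured geometry and are seeded", {
  movs <- list(movement_spec("a", "target", c(1, rep(0, 7))),
               movement_spec("b", "target", c(0, 1, rep(0, 6))))
  cfg <- simulation_config(movs, sampling_rate = 200, repetition_s = 5,
                           rest_s = 3, repetitions = 1, seed = 11)
  rec <- generate_recording(cfg)
  expect_equal(nrow(rec$samples), 2 * (1000 + 600))
  expect_equal(ncol(rec$samples), 8)
  expect_equal(nrow(rec$trials), 2)
  expect_equal(rec$trials$end - rec$trials$start, c(1000, 1000))

  rec2 <- generate_recording(cfg)
  expect_identical(rec$samples, rec2$samples)
  expect_identical(rec$trials, rec2$trials)

  # no signal sources -> silent recording
  silent <- simulation_config(list(movement_spec("z", "target", rep(0, 8))),
                              repetitions = 1, noise_sd = 0, seed = 1)
  expect_true(all(generate_recording(silent)$samples == 0))
})

test_that("active-trial channel power follows base_amplitude * activation + noise_sd", {
  cfg <- simulation_config(seed = 3)
  rec <- generate_recording(cfg)
  act <- vapply(cfg$movements, function(m) m$base_amplitude, 0)
  specs <- setNames(cfg$movements, vapply(cfg$movements, `[[`, "", "name"))
  tr <- rec$trials[rec$trials$kind == "target", ][1:6, ]
  for (i in seq_len(nrow(tr))) {
    m <- specs[[tr$label[i]]]
    want <- m$base_amplitude * m$activation + cfg$noise_sd
    got <- apply(rec$samples[(tr$start[i] + 1):tr$end[i], ], 2, sd)
    expect_lt(max(abs(got - want) / want), 0.10)
  }
})

test_that("invalid simulation configurations fail naming the offending field", {
  expect_error(simulation_config(repetitions = 0), "repetitions")
  expect_error(simulation_config(sampling_rate = 0), "sampling_rate")
  expect_error(simulation_config(repetition_s = -1), "repetition_s")
  expect_error(movement_spec("x", "target", rep(1, 7)), "activation")
})

test_that("the default movement set has 7 target-side and 5 unrelated classes", {
  specs <- default_movement_set()
  expect_length(specs, 12)
  kinds <- vapply(specs, `[[`, "", "kind")
  expect_equal(sum(kinds != "unrelated"), 7)
  expect_equal(sum(kinds == "neutral"), 1)
  expect_equal(sum(kinds == "unrelated"), 5)

  tpat <- lapply(specs[kinds == "target"], `[[`, "activation")
  gmax <- max(unlist(tpat))
  neutral <- specs[[which(kinds == "neutral")]]
  expect_true(all(neutral$activation <= 0.05 * gmax))

  maxcos <- function(u) max(vapply(tpat, osemg:::cos_sim, 0, a = u))
  for (m in specs[kinds == "unrelated"]) {
    cs <- maxcos(m$activation)
    expect_gte(cs, 0.5 - 1e-8)
    expect_lte(cs, 0.95 + 1e-8)
  }

  # a narrower band constrains the similarity levels accordingly
  easy <- default_movement_set(c(0.5, 0.8))
  for (m in easy[vapply(easy, `[[`, "", "kind") == "unrelated"])
    expect_lte(maxcos(m$activation), 0.8 + 1e-8)
  expect_error(default_movement_set(c(0.3, 0.5)), "attainable")
})

test_that("recordings and configurations round-trip through CSV and JSON", {
  cfg <- simulation_config(default_movement_set()[c(1, 2, 7)],
                           repetition_s = 1, rest_s = 0.5, repetitions = 2,
                           seed = 5)
  rec <- generate_recording(cfg, subject_id = "S9")
  sp <- withr::local_tempfile(fileext = ".csv")
  tp <- withr::local_tempfile(fileext = ".csv")
  write_recording_csv(rec, sp, tp)
  back <- read_recording_csv(sp, tp)
  expect_equal(back$samples, rec$samples, tolerance = 1e-8, ignore_attr = TRUE)
  expect_equal(back$trials$start, rec$trials$start)
  expect_equal(back$trials$label, rec$trials$label)
  expect_equal(back$sampling_rate, 200)
  expect_equal(back$subject_id, "S9")

  jp <- withr::local_tempfile(fileext = ".json")
  write_simulation_config(cfg, jp)
  cfg2 <- read_simulation_config(jp)
  expect_equal(cfg2$repetitions, cfg$repetitions)
  expect_equal(cfg2$movements[[1]]$activation, cfg$movements[[1]]$activation)
  expect_identical(generate_recording(cfg2)$samples, rec$samples)
})

test_that("trial intervals must be disjoint and inside the sample range", {
  s <- matrix(0, 100, 8)
  bad <- data.frame(start = c(0, 40), end = c(50, 90),
                    label = "a", kind = "target")
  expect_error(emg_recording(s, 200, bad), "overlap")
  out <- data.frame(start = 0, end = 200, label = "a", kind = "target")
  expect_error(emg_recording(s, 200, out), "within the sample range")
})

test_that("more similar unrelated movements are harder to reject downstream", {
  # seed-averaged rejection AUC drops when the similarity band moves up
  auc_for <- function(band, s)
    cached_pipeline(pipeline_config(seed = s,
      simulation = list(similarity = band, repetitions = 5L),
      cnn = list(epochs = 40L), ae = list(epochs = 150L)))$report$auc
  easy <- vapply(1:5, function(s) auc_for(c(0.5, 0.75), s), 0)
  hard <- vapply(1:5, function(s) auc_for(c(0.85, 0.98), s), 0)
  expect_gt(mean(easy), mean(hard))
})
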