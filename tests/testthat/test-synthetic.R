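test_that("generation is a pure function of spec and seed", {
  spec <- motion_spec(duration = 5, rate = 50, seed = 17,
                      components = list(list(channel = "yaw", freq = 0.4,
                                             amplitude = 10, phase = 0)))
  g1 <- generate_recording(spec)
  g2 <- generate_recording(spec)
  expect_identical(g1$recording$t, g2$recording$t)
  expect_identical(g1$recording$q, g2$recording$q)
  p1 <- file.path(tempdir(), "det1.csv"); p2 <- file.path(tempdir(), "det2.csv")
  write_recording(g1$recording, p1); write_recording(g2$recording, p2)
  expect_identical(readLines(p1), readLines(p2))
})

test_that("a zero-motion spec yields a constant-orientation recording", {
  spec <- motion_spec(duration = 3, rate = 50, drift_sd = 0, jitter_sd = 0, seed = 1)
  rec <- generate_recording(spec)$recording
  expect_lt(max(apply(rec$q, 2, function(c) diff(range(c)))), 1e-12)
})

test_that("nyquist-violating components are rejected", {
  expect_error(motion_spec(components = list(list(channel = "yaw", freq = 30,
                                                  amplitude = 1, phase = 0))),
               "Nyquist")
})

test_that("the pipeline recovers injected components and band powers", {
  spec <- motion_spec(duration = 80, rate = 50, drift_sd = 0, jitter_sd = 0.002,
                      components = list(list(channel = "yaw", freq = 0.4,
                                             amplitude = 10, phase = 0.4)),
                      seed = 23)
  gen <- generate_recording(spec)
  tr <- to_euler_trace(gen$recording)
  sp <- power_spectrum(tr$yaw, tr$rate)
  expect_lte(abs(sp$freqs[which.max(sp$power)] - 0.4), tr$rate / sp$n)
  expect_equal(band_power(sp, 0.3, 0.5), gen$truth$band_power$power[1],
               tolerance = 0.02)
})

test_that("amplitudes survive the full generate-analyze chain within 5%", {
  spec <- motion_spec(duration = 40, rate = 50, drift_sd = 0, jitter_sd = 0.002,
                      components = list(
                        list(channel = "yaw", freq = 0.25, amplitude = 12, phase = 0),
                        list(channel = "roll", freq = 0.45, amplitude = 6, phase = 1)),
                      seed = 29)
  tr <- to_euler_trace(generate_recording(spec)$recording)
  cond <- condition_trace(tr, filter_spec(2, 4))
  r <- motion_range(cond$trace)
  expect_equal(unname(r["yaw"]), 24, tolerance = 0.05 * 24)
  expect_equal(unname(r["roll"]), 12, tolerance = 0.05 * 12)
})

test_that("tracking resets inserted by the generator are seen mod 360", {
  spec <- motion_spec(duration = 20, rate = 50, drift_sd = 0, jitter_sd = 0,
                      components = list(list(channel = "yaw", freq = 0.2,
                                             amplitude = 5, phase = 0)),
                      wrap_artifacts = c(10), seed = 31)
  gen <- generate_recording(spec)
  expect_length(gen$truth$discontinuity_indices, 1)
  tr <- to_euler_trace(gen$recording)
  rep1 <- detect_discontinuities(tr$yaw, tr$rate)
  expect_length(rep1$indices, 1)
  expect_lte(abs(rep1$indices - gen$truth$discontinuity_indices), 2)
  # +350 in yaw appears as its wrapped residual, -10 degrees
  expect_equal(rep1$magnitudes, -10, tolerance = 1)
})

test_that("wrap-step recovery over 100 seeded fixtures is >=95% with 0 FP", {
  hits <- 0L; total <- 0L; fp <- 0L
  for (seed in 1:100) {
    x <- smooth_channel(seed, n = 600)
    set.seed(seed + 5000)
    k <- sample(2:5, 1)
    ats <- sort(sample(seq(30, 570, by = 12), k))
    steps <- sample(c(-360, 350, 360), k, replace = TRUE)
    xx <- x
    for (i in seq_len(k)) xx <- inject_wrap_step(xx, ats[i], steps[i])
    rep1 <- detect_discontinuities(xx, rate = 50)
    total <- total + k
    for (at in ats) hits <- hits + any(abs(rep1$indices - at) <= 1)
    fp <- fp + sum(apply(abs(outer(rep1$indices, ats, "-")) > 1, 1, all))
  }
  expect_gte(hits / total, 0.95)
  expect_identical(fp, 0L)
})

test_that("scale item generation hits the target scores", {
  expect_identical(generate_scale_items("SWLS", 35, seed = 1), rep(7L, 5))
  it16 <- generate_scale_items("SWLS", 16, seed = 2)
  expect_length(it16, 5)
  expect_true(all(it16 >= 1 & it16 <= 7))
  expect_equal(sum(it16), 16)
  maas <- generate_scale_items("MAAS", 4.3, seed = 3)
  expect_length(maas, 15)
  expect_true(all(maas >= 1 & maas <= 6))
  expect_equal(score_maas(maas)$value, 4.3)
  expect_identical(generate_scale_items("MMSE", 19, seed = 4), 19L)
  expect_error(generate_scale_items("SWLS", 36, seed = 1), "range")
  expect_error(generate_scale_items("MAAS", 6.5, seed = 1), "reachable|range")
  # seeded: same seed, same items; different seed may differ
  expect_identical(generate_scale_items("MAAS", 3.3, seed = 9),
                   generate_scale_items("MAAS", 3.3, seed = 9))
})

test_that("the study fixture reproduces every reference group statistic", {
  run <- cached_fixture_run()
  rep <- longitudinal_report(run$fixture$responses)
  ref <- reference_scores()
  manual <- dplyr::summarise(
    dplyr::group_by(ref, group, scale, timepoint),
    m = round_half_away_oracle(mean(score), 1),
    s = if (dplyr::n() > 1) round_half_away_oracle(sd(score), 1) else NA_real_,
    .groups = "drop")
  for (i in seq_len(nrow(manual))) {
    row <- rep[rep$group == manual$group[i] & rep$scale == manual$scale[i] &
               rep$timepoint == manual$timepoint[i], ]
    expect_equal(row$mean_rounded, manual$m[i],
                 info = paste(manual$group[i], manual$scale[i], manual$timepoint[i]))
    if (!is.na(manual$s[i])) expect_equal(row$sd_rounded, manual$s[i])
  }
})
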