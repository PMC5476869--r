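test_that("quaternion normalization scales, fixes sign, and rejects zeros", {
  expect_equal(normalize_quaternion(c(0, 0, 0, 2)), c(qx = 0, qy = 0, qz = 0, qw = 1))
  expect_equal(normalize_quaternion(c(0, 0, 0, -1)), c(qx = 0, qy = 0, qz = 0, qw = 1))
  expect_equal(normalize_quaternion(c(1, 1, 1, 1)),
               c(qx = 0.5, qy = 0.5, qz = 0.5, qw = 0.5))
  set.seed(7)
  m <- matrix(rnorm(400), ncol = 4)
  nm <- normalize_quaternion(m)
  expect_true(all(abs(sqrt(rowSums(nm^2)) - 1) < 1e-12))
  expect_true(all(nm[, 4] >= 0))
  expect_error(normalize_quaternion(rbind(c(1, 0, 0, 0), c(0, 0, 0, 0))),
               "sample 2")
})

test_that("elementary rotations map to the expected Euler angles", {
  expect_equal(unname(quat_to_euler_yzx(c(0, 0, 0, 1))), c(0, 0, 0))
  e <- quat_to_euler_yzx(c(0, sin(pi / 4), 0, cos(pi / 4)))
  expect_equal(unname(e), c(90, 0, 0), tolerance = 1e-9)
  # independent check via the rotation action: yaw 180 flips the horizontal
  # direction of the forward axis
  v <- quat_rotate_vector(euler_yzx_to_quat(180, 0, 0), c(0, 0, 1))
  expect_equal(v[1:3], c(0, 0, -1), tolerance = 1e-12)
  expect_equal(unname(quat_to_euler_yzx(euler_yzx_to_quat(30, 20, 10))),
               c(30, 20, 10), tolerance = 1e-9)
  expect_equal(unname(euler_yzx_to_quat(0, 0, 0)), c(0, 0, 0, 1))
})

test_that("non-unit quaternions are rejected with advice to normalize", {
  expect_error(quat_to_euler_yzx(c(0, 0, 0, 1.01)), "normalize_quaternion")
})

test_that("quat -> euler -> quat round trip reproduces the rotation", {
  set.seed(11)
  q <- random_unit_quat(1500)
  e <- quat_to_euler_yzx(q)
  expect_true(all(e[, "yaw"] > -180 & e[, "yaw"] <= 180))
  expect_true(all(e[, "pitch"] >= -90 & e[, "pitch"] <= 90))
  expect_true(all(e[, "roll"] > -180 & e[, "roll"] <= 180))
  q2 <- euler_yzx_to_quat(e)
  err <- pmin(sqrt(rowSums((q - q2)^2)), sqrt(rowSums((q + q2)^2)))
  expect_lt(max(err), 1e-6)
})

test_that("factorization matches a brute-force rotation-matrix oracle", {
  set.seed(13)
  qs <- random_unit_quat(400)
  e_all <- quat_to_euler_yzx(qs)
  keep <- which(abs(e_all[, "pitch"]) < 80)[1:100]
  for (i in keep) {
    R <- oracle_quat_rotmat(qs[i, ])
    ref <- oracle_factor_yzx(R)
    got <- e_all[i, ]
    expect_equal(unname(got), unname(ref), tolerance = 1e-3)
  }
})

test_that("gimbal lock convention is deterministic: roll 0, residual in yaw", {
  q <- euler_yzx_to_quat(35, 90, 25)
  e <- quat_to_euler_yzx(q)
  expect_equal(unname(e["roll"]), 0)
  expect_equal(unname(e["pitch"]), 90, tolerance = 1e-6)
  # at pitch +90 the yaw and roll rotations compound
  expect_equal(unname(e["yaw"]), 60, tolerance = 1e-6)
  # the reconstructed rotation still matches
  R1 <- oracle_quat_rotmat(as.numeric(q))
  R2 <- oracle_quat_rotmat(as.numeric(euler_yzx_to_quat(e)))
  expect_lt(max(abs(R1 - R2)), 1e-6)
})

test_that("constant-orientation recordings give flat traces", {
  q <- euler_yzx_to_quat(12, -5, 3)
  n <- 100
  rec <- orientation_recording((0:(n - 1)) / 50, rep(q[1], n), rep(q[2], n),
                               rep(q[3], n), rep(q[4], n))
  tr <- to_euler_trace(rec)
  expect_lt(diff(range(tr$yaw)), 1e-9)
  expect_lt(diff(range(tr$pitch)), 1e-9)
  expect_lt(diff(range(tr$roll)), 1e-9)
  expect_equal(mean(tr$yaw), 12, tolerance = 1e-6)
})

test_that("unwrapping takes the shortest arc across the +/-180 boundary", {
  qa <- euler_yzx_to_quat(0, 0, 0)
  qb <- euler_yzx_to_quat(350, 0, 0)  # same rotation as -10
  rec <- orientation_recording(c(0, 0.04), c(qa[1], qb[1]), c(qa[2], qb[2]),
                               c(qa[3], qb[3]), c(qa[4], qb[4]))
  tr <- to_euler_trace(rec)
  expect_equal(tr$yaw[1], 0, tolerance = 1e-9)
  expect_equal(tr$yaw[length(tr$yaw)], -10, tolerance = 1e-6)
})

test_that("a synthetic sinusoid recording is recovered through conversion", {
  spec <- motion_spec(duration = 20, rate = 50, drift_sd = 0, jitter_sd = 0.002,
                      components = list(list(channel = "yaw", freq = 0.4,
                                             amplitude = 10, phase = 0)),
                      seed = 3)
  gen <- generate_recording(spec)
  tr <- to_euler_trace(gen$recording)
  tg <- (seq_along(tr$yaw) - 1) / tr$rate + tr$t0
  expect_lt(max(abs(tr$yaw - 10 * sin(2 * pi * 0.4 * tg))), 0.1)
})

test_that("resampled trace length tracks duration times rate", {
  for (dur in c(2.0, 5.5, 13.37)) {
    spec <- motion_spec(duration = dur, rate = 50, drift_sd = 0.01, seed = 5)
    tr <- to_euler_trace(generate_recording(spec)$recording)
    expect_lte(abs(length(tr$yaw) - round(dur * 50)), 1)
  }
})

test_that("degenerate recordings are rejected", {
  q <- euler_yzx_to_quat(0, 0, 0)
  expect_error(orientation_recording(c(0, 0), rep(q[1], 2), rep(q[2], 2),
                                     rep(q[3], 2), rep(q[4], 2)),
               "strictly increasing")
  rec <- orientation_recording(c(0, 0.01), rep(q[1], 2), rep(q[2], 2),
                               rep(q[3], 2), rep(q[4], 2))
  expect_error(to_euler_trace(rec), "too short")
})

test_that("recordings round-trip through the CSV + sidecar format", {
  spec <- motion_spec(duration = 3, rate = 50, seed = 9,
                      components = list(list(channel = "roll", freq = 0.5,
                                             amplitude = 4, phase = 1)))
  rec <- generate_recording(spec, participant = "p1", session = 2L,
                            segment = "sitting-fireplace")$recording
  path <- file.path(tempdir(), "rec-roundtrip.csv")
  write_recording(rec, path)
  back <- read_recording(path)
  expect_equal(back$t, rec$t, tolerance = 1e-6)
  expect_equal(back$q, rec$q, tolerance = 1e-8)
  expect_equal(back$participant, "p1")
  expect_equal(back$session, 2L)
  expect_equal(back$rate_hz, 50)
  writeLines(c("t,qx,qy,qz,qw", "0,0,0,0,1", "bad,0,0,0,1"),
             file.path(tempdir(), "rec-bad.csv"))
  expect_error(read_recording(file.path(tempdir(), "rec-bad.csv")), "line")
})
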