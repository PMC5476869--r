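# Independent oracles used across tests. These deliberately avoid the package
# implementation paths they check.

# full 3x3 rotation matrix from a scalar-last unit quaternion
oracle_quat_rotmat <- function(q) {
  qx <- q[1]; qy <- q[2]; qz <- q[3]; qw <- q[4]
  matrix(c(
    1 - 2 * (qy^2 + qz^2), 2 * (qx * qy - qz * qw), 2 * (qx * qz + qy * qw),
    2 * (qx * qy + qz * qw), 1 - 2 * (qx^2 + qz^2), 2 * (qy * qz - qx * qw),
    2 * (qx * qz - qy * qw), 2 * (qy * qz + qx * qw), 1 - 2 * (qx^2 + qy^2)
  ), nrow = 3, byrow = TRUE)
}

# elemental rotation matrices (degrees)
rot_x <- function(a) { a <- a * pi / 180
  matrix(c(1, 0, 0, 0, cos(a), -sin(a), 0, sin(a), cos(a)), 3, byrow = TRUE) }
rot_y <- function(a) { a <- a * pi / 180
  matrix(c(cos(a), 0, sin(a), 0, 1, 0, -sin(a), 0, cos(a)), 3, byrow = TRUE) }
rot_z <- function(a) { a <- a * pi / 180
  matrix(c(cos(a), -sin(a), 0, sin(a), cos(a), 0, 0, 0, 1), 3, byrow = TRUE) }

oracle_yzx_matrix <- function(yaw, pitch, roll) rot_y(yaw) %*% rot_z(pitch) %*% rot_x(roll)

# brute-force Y-Z-X factorization: coarse vectorized grid search over
# (yaw, pitch, roll), then Nelder-Mead refinement of the Frobenius distance
oracle_factor_yzx <- function(R, coarse_deg = 10) {
  yy <- seq(-175, 180, by = coarse_deg)
  pp <- seq(-85, 85, by = coarse_deg)
  rr <- seq(-175, 180, by = coarse_deg)
  g <- expand.grid(yaw = yy, pitch = pp, roll = rr)
  cy <- cospi(g$yaw / 180); sy <- sinpi(g$yaw / 180)
  cp <- cospi(g$pitch / 180); sp <- sinpi(g$pitch / 180)
  cr <- cospi(g$roll / 180); sr <- sinpi(g$roll / 180)
  # closed forms of the nine entries of Ry %*% Rz %*% Rx
  d2 <- (R[1, 1] - cy * cp)^2 +
    (R[1, 2] - (-cy * sp * cr + sy * sr))^2 +
    (R[1, 3] - (cy * sp * sr + sy * cr))^2 +
    (R[2, 1] - sp)^2 + (R[2, 2] - cp * cr)^2 + (R[2, 3] - (-cp * sr))^2 +
    (R[3, 1] - (-sy * cp))^2 +
    (R[3, 2] - (sy * sp * cr + cy * sr))^2 +
    (R[3, 3] - (-sy * sp * sr + cy * cr))^2
  best <- as.numeric(g[which.min(d2), ])
  obj <- function(a) sum((R - oracle_yzx_matrix(a[1], a[2], a[3]))^2)
  fit <- optim(best, obj, method = "Nelder-Mead",
               control = list(maxit = 2000, reltol = 1e-14))
  fit$par
}

# reporting-convention rounding, written independently of the package helper
round_half_away_oracle <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

# shoelace area of a polygon in vertex order
oracle_shoelace <- function(x, y) {
  j <- c(seq_along(x)[-1], 1)
  abs(sum(x * y[j] - x[j] * y)) / 2
}

random_unit_quat <- function(n) {
  m <- matrix(rnorm(4 * n), ncol = 4)
  m / sqrt(rowSums(m^2))
}

# smooth seeded trace used by detector property tests
smooth_channel <- function(seed, n = 600, rate = 50) {
  set.seed(seed)
  t <- (0:(n - 1)) / rate
  nc <- sample(1:3, 1)
  x <- numeric(n)
  for (i in seq_len(nc)) {
    x <- x + runif(1, 2, 20) * sin(2 * pi * runif(1, 0.1, 0.8) * t + runif(1, 0, 2 * pi))
  }
  x + cumsum(rnorm(n, 0, 0.05))
}

# one shared fixture + analysis run per test session (generation is seeded,
# so sharing does not couple the tests' outcomes)
fixture_cache <- new.env(parent = emptyenv())
cached_fixture_run <- function(seed = 101) {
  key <- paste0("s", seed)
  if (is.null(fixture_cache[[key]])) {
    dir <- file.path(tempdir(), paste0("mm-fixture-", seed))
    fx <- make_study_fixture(seed = seed, dir = dir)
    report <- suppressMessages(
      run_study(file.path(dir, "config.yaml"),
                out_dir = file.path(dir, "out"), quiet = TRUE))
    fixture_cache[[key]] <- list(dir = dir, fixture = fx, report = report)
  }
  fixture_cache[[key]]
}
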