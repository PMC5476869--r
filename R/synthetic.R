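#' Synthetic headset data with known ground truth
#'
#' The study's headset recordings were never deposited, so validation runs on
#' generated data that emulates their statistical structure: slow gaze drift
#' (Gaussian random walk), low-amplitude oscillation in the 0.3-1 Hz band,
#' saccade-like smooth steps, occasional tracking-reset discontinuities and
#' timestamp jitter. Generation is a pure function of (spec, seed).
#'
#' @name synthetic
NULL

with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(as.integer(seed %% .Machine$integer.max))
  force(code)
}

#' Specification for one synthetic recording
#'
#' @param duration recording length in seconds.
#' @param rate sampling rate in Hz (default 50, the headset's nominal rate).
#' @param drift_sd per-sample standard deviation (degrees) of the random-walk
#'   gaze drift added to every channel (default 0.02).
#' @param components list of sinusoidal components, each
#'   `list(channel, freq, amplitude, phase)` with `freq` in Hz (< rate/2),
#'   `amplitude` in degrees, `phase` in radians.
#' @param saccades list of saccade-like steps, each
#'   `list(time, channel, step)`: a smooth sigmoid transition of `step`
#'   degrees centered at `time`, rise time ~0.3 s.
#' @param wrap_artifacts numeric vector of times (s) at which a tracking-reset
#'   discontinuity is injected: from that sample on, reported yaw carries an
#'   extra +350 degree offset. Orientation is serialized as quaternions, so
#'   the offset is observable after conversion as its mod-360 residual
#'   (a -10 degree step).
#' @param jitter_sd timestamp jitter standard deviation in seconds
#'   (default 0.002).
#' @param seed integer seed making generation deterministic.
#' @return Object of class `motion_spec`.
#' @export
motion_spec <- function(duration = 60, rate = 50, drift_sd = 0.02,
                        components = list(), saccades = list(),
                        wrap_artifacts = numeric(0), jitter_sd = 0.002,
                        seed = 1L) {
  if (duration <= 0) stop("duration must be positive")
  if (rate <= 0) stop("rate must be positive")
  for (cmp in components) {
    if (cmp$freq >= rate / 2) {
      stop("component frequency ", cmp$freq, " Hz is at or above Nyquist (", rate / 2, " Hz)")
    }
    if (!cmp$channel %in% trace_channels) stop("unknown channel '", cmp$channel, "'")
  }
  structure(
    list(duration = duration, rate = rate, drift_sd = drift_sd,
         components = components, saccades = saccades,
         wrap_artifacts = wrap_artifacts, jitter_sd = jitter_sd,
         seed = as.integer(seed)),
    class = "motion_spec"
  )
}

# deterministic part (components + saccades) of a channel at times t
synth_channel <- function(spec, channel, t) {
  x <- numeric(length(t))
  for (cmp in spec$components) {
    if (cmp$channel == channel) {
      ph <- if (is.null(cmp$phase)) 0 else cmp$phase
      x <- x + cmp$amplitude * sin(2 * pi * cmp$freq * t + ph)
    }
  }
  for (sc in spec$saccades) {
    if (sc$channel == channel) {
      x <- x + sc$step * stats::plogis((t - sc$time) / 0.075)
    }
  }
  x
}

#' Generate a synthetic orientation recording
#'
#' Builds noiseless Euler channels from the spec's components and saccades,
#' adds seeded random-walk drift and timestamp jitter, injects tracking-reset
#' artifacts into yaw, and encodes the result as unit quaternions via
#' [euler_yzx_to_quat()].
#'
#' @param spec a [motion_spec()].
#' @param participant,session,segment metadata for the recording.
#' @return List with `recording` (an `orientation_recording`) and `truth`
#'   (ground truth: `euler_truth` — the noiseless deterministic trace on the
#'   uniform grid, `discontinuity_indices` — uniform-grid samples at which
#'   resets were injected, `band_power` — tibble of per-component analytic
#'   powers `amplitude^2 / 2`).
#' @export
generate_recording <- function(spec, participant = NA_character_,
                               session = NA_integer_, segment = NA_character_) {
  stopifnot(inherits(spec, "motion_spec"))
  n <- floor(spec$duration * spec$rate) + 1L
  tg <- (0:(n - 1L)) / spec$rate
  with_seed(spec$seed, {
    t <- tg + c(0, rnorm(n - 1L, 0, spec$jitter_sd))
    t <- sort(t)
    t[t < 0] <- 0
    # enforce strict monotonicity under extreme jitter draws
    eps <- 1e-6
    for (i in 2:n) if (t[i] <= t[i - 1L]) t[i] <- t[i - 1L] + eps
    chans <- lapply(trace_channels, function(ch) {
      det <- synth_channel(spec, ch, t)
      if (spec$drift_sd > 0) det <- det + cumsum(rnorm(n, 0, spec$drift_sd)) else det
    })
    names(chans) <- trace_channels
    disc_idx <- integer(0)
    for (tw in spec$wrap_artifacts) {
      k <- which.min(abs(t - tw))
      if (k >= 2L && k <= n - 1L) {
        chans$yaw[k:n] <- chans$yaw[k:n] + 350
        disc_idx <- c(disc_idx, k)
      }
    }
    q <- euler_yzx_to_quat(cbind(chans$yaw, chans$pitch, chans$roll))
    rec <- orientation_recording(t, q[, 1L], q[, 2L], q[, 3L], q[, 4L],
                                 rate_hz = spec$rate, participant = participant,
                                 session = session, segment = segment)
    truth_ch <- lapply(trace_channels, function(ch) synth_channel(spec, ch, tg))
    bp <- bind_rows(lapply(spec$components, function(cmp) {
      tibble(channel = cmp$channel, freq = cmp$freq,
             power = cmp$amplitude^2 / 2)
    }))
    list(
      recording = rec,
      truth = list(
        euler_truth = euler_trace(truth_ch[[1L]], truth_ch[[2L]], truth_ch[[3L]],
                                  rate = spec$rate, t0 = 0),
        discontinuity_indices = sort(disc_idx),
        band_power = bp
      )
    )
  })
}

#' Inject a wrap/reset step into an angle channel
#'
#' Channel-level fixture helper: adds `step` degrees to all samples from `at`
#' onward, emulating an angle-wrap or tracking-reset discontinuity as seen by
#' the conditioning module.
#'
#' @param channel numeric vector of degrees.
#' @param at sample index (first sample after the jump), `2 <= at <= length`.
#' @param step jump magnitude in degrees (default 360).
#' @return Modified channel.
#' @export
inject_wrap_step <- function(channel, at, step = 360) {
  n <- length(channel)
  if (at < 2L || at > n) stop("injection index out of range")
  channel[at:n] <- channel[at:n] + step
  channel
}

#' Generate item responses achieving a target scale score
#'
#' Draws a seeded-random valid item vector whose score equals the target:
#' exactly for SWLS (sum), and within rounding for MAAS (an item sum is chosen
#' whose mean rounds to the target at one decimal). MMSE targets are returned
#' as the single total.
#'
#' @param scale `"SWLS"`, `"MAAS"` or `"MMSE"`.
#' @param target_score target score (SWLS: integer 5-35; MAAS: multiple of
#'   0.1 reachable from a mean of 15 items in 1-6; MMSE: integer 0-30).
#' @param seed integer seed.
#' @return Integer item vector (length 5, 15 or 1).
#' @export
generate_scale_items <- function(scale, target_score, seed = 1L) {
  if (scale == "MMSE") {
    if (target_score != round(target_score) || target_score < 0 || target_score > 30) {
      stop("MMSE target must be an integer in 0-30")
    }
    return(as.integer(target_score))
  }
  par <- switch(scale,
    SWLS = list(n = 5L, lo = 1L, hi = 7L),
    MAAS = list(n = 15L, lo = 1L, hi = 6L),
    stop("unknown scale '", scale, "'")
  )
  total <- if (scale == "SWLS") {
    if (target_score != round(target_score)) stop("SWLS target must be an integer")
    as.integer(target_score)
  } else {
    cand <- round_half_away(15 * target_score) + (-1L:1L)
    ok <- cand[round_half_away(cand / 15, 1L) == round_half_away(target_score, 1L)]
    if (length(ok) == 0L) stop("MAAS target ", target_score, " not reachable as a 15-item mean")
    as.integer(ok[which.min(abs(ok / 15 - target_score))])
  }
  if (total < par$n * par$lo || total > par$n * par$hi) {
    stop(scale, " target ", target_score, " is outside the achievable range")
  }
  with_seed(seed, {
    items <- rep(par$lo, par$n)
    need <- total - par$n * par$lo
    while (need > 0L) {
      room <- which(items < par$hi)
      pick <- room[sample.int(length(room), 1L)]
      items[pick] <- items[pick] + 1L
      need <- need - 1L
    }
    as.integer(items)
  })
}
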