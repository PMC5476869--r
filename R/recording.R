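#' Orientation recordings and Euler traces
#'
#' An `orientation_recording` holds the raw timestamped quaternion stream for
#' one session segment plus metadata; an `euler_trace` is the derived
#' uniform-rate yaw/pitch/roll time series all downstream analysis operates on.
#'
#' @name recording
NULL

#' Construct an orientation recording
#'
#' @param t sample times in seconds, strictly increasing, non-negative.
#' @param qx,qy,qz,qw quaternion components (scalar-last), one per sample.
#' @param rate_hz nominal sensor rate in Hz (default 50).
#' @param participant,session,segment optional metadata.
#' @return An object of class `orientation_recording`.
#' @export
orientation_recording <- function(t, qx, qy, qz, qw, rate_hz = 50,
                                  participant = NA_character_,
                                  session = NA_integer_,
                                  segment = NA_character_) {
  n <- length(t)
  if (length(qx) != n || length(qy) != n || length(qz) != n || length(qw) != n) {
    stop("t, qx, qy, qz, qw must have equal length")
  }
  if (!all(is.finite(t)) || any(t < 0)) stop("timestamps must be finite and non-negative")
  if (n >= 2L && any(diff(t) <= 0)) {
    i <- which(diff(t) <= 0)[1L]
    stop("timestamps must be strictly increasing (violation at sample ", i + 1L, ")")
  }
  if (!is.numeric(rate_hz) || rate_hz <= 0) stop("rate_hz must be positive")
  structure(
    list(
      t = as.numeric(t),
      q = as_quat_matrix(cbind(qx, qy, qz, qw)),
      rate_hz = as.numeric(rate_hz),
      participant = participant,
      session = session,
      segment = segment
    ),
    class = "orientation_recording"
  )
}

#' @export
print.orientation_recording <- function(x, ...) {
  cat(sprintf(
    "<orientation_recording> %d samples, %.1f s @ %g Hz nominal (%s / session %s / %s)\n",
    length(x$t), diff(range(x$t)), x$rate_hz,
    x$participant, x$session, x$segment
  ))
  invisible(x)
}

#' Read / write a recording as CSV with JSON sidecar
#'
#' The on-disk format is a CSV with the exact header `t,qx,qy,qz,qw`
#' (seconds; dimensionless quaternion components, scalar-last), one row per
#' sample, plus an optional JSON sidecar `<stem>.json` with fields
#' `participant`, `session`, `segment`, `rate_hz`.
#'
#' @param path CSV file path.
#' @return [read_recording()] returns an `orientation_recording`.
#' @export
read_recording <- function(path) {
  if (!file.exists(path)) stop("recording file not found: ", path)
  df <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("t", "qx", "qy", "qz", "qw")
  if (!identical(names(df), need)) {
    stop("malformed recording CSV ", path, ": header must be exactly 't,qx,qy,qz,qw' (line 1)")
  }
  df[] <- lapply(df, function(col) suppressWarnings(as.numeric(col)))
  bad <- which(!stats::complete.cases(df))
  if (length(bad) > 0L) {
    stop("malformed recording CSV ", path, ": non-numeric or missing value at line ", bad[1L] + 1L)
  }
  meta <- list(participant = NA_character_, session = NA_integer_,
               segment = NA_character_, rate_hz = 50)
  sidecar <- sub("\\.csv$", ".json", path)
  if (sidecar != path && file.exists(sidecar)) {
    got <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
    meta[names(got)[names(got) %in% names(meta)]] <- got[names(got) %in% names(meta)]
  }
  orientation_recording(df$t, df$qx, df$qy, df$qz, df$qw,
                        rate_hz = as.numeric(meta$rate_hz),
                        participant = as.character(meta$participant),
                        session = as.integer(meta$session),
                        segment = as.character(meta$segment))
}

#' @rdname read_recording
#' @param rec an `orientation_recording`.
#' @param sidecar write the JSON metadata sidecar too (default TRUE).
#' @export
write_recording <- function(rec, path, sidecar = TRUE) {
  stopifnot(inherits(rec, "orientation_recording"))
  # fixed-format numbers so identical recordings serialize byte-identically
  lines <- c(
    "t,qx,qy,qz,qw",
    sprintf("%.6f,%.9f,%.9f,%.9f,%.9f",
            rec$t, rec$q[, 1L], rec$q[, 2L], rec$q[, 3L], rec$q[, 4L])
  )
  writeLines(lines, path)
  if (sidecar) {
    meta <- list(participant = rec$participant, session = rec$session,
                 segment = rec$segment, rate_hz = rec$rate_hz)
    jsonlite::write_json(meta, sub("\\.csv$", ".json", path),
                         auto_unbox = TRUE, digits = NA)
  }
  invisible(path)
}

#' Construct a uniform-rate Euler trace
#'
#' @param yaw,pitch,roll equal-length channels in degrees.
#' @param rate sampling rate in Hz.
#' @param t0 start time in seconds.
#' @return An object of class `euler_trace`.
#' @export
euler_trace <- function(yaw, pitch, roll, rate, t0 = 0) {
  n <- length(yaw)
  if (length(pitch) != n || length(roll) != n) stop("channels must have equal length")
  if (n < 2L) stop("an euler_trace needs at least 2 samples")
  if (rate <= 0) stop("rate must be positive")
  structure(
    list(t0 = t0, rate = rate,
         yaw = as.numeric(yaw), pitch = as.numeric(pitch), roll = as.numeric(roll)),
    class = "euler_trace"
  )
}

#' @export
print.euler_trace <- function(x, ...) {
  cat(sprintf("<euler_trace> %d samples @ %g Hz (%.1f s), yaw range %.1f deg\n",
              length(x$yaw), x$rate, length(x$yaw) / x$rate,
              diff(range(x$yaw))))
  invisible(x)
}

trace_times <- function(trace) trace$t0 + (seq_along(trace$yaw) - 1L) / trace$rate

trace_channels <- c("yaw", "pitch", "roll")

#' Convert a quaternion recording to a uniform Euler trace
#'
#' Converts each sample with [quat_to_euler_yzx()], unwraps each channel so no
#' consecutive pair jumps by more than 180 degrees, and resamples onto a
#' uniform grid at the nominal rate by linear interpolation (headset
#' timestamps carry jitter). Residual artifacts such as tracking resets remain
#' in the trace and are handled by the conditioning step.
#'
#' @param rec an `orientation_recording` with at least 2 samples spanning at
#'   least `2 / rate_hz` seconds.
#' @param normalize normalize quaternions before conversion (default TRUE).
#' @return An `euler_trace` at `rec$rate_hz`.
#' @export
to_euler_trace <- function(rec, normalize = TRUE) {
  stopifnot(inherits(rec, "orientation_recording"))
  n <- length(rec$t)
  if (n < 2L) stop("recording must contain at least 2 samples")
  dur <- rec$t[n] - rec$t[1L]
  if (dur < 2 / rec$rate_hz) {
    stop("recording too short: ", format(dur), " s < ", format(2 / rec$rate_hz), " s")
  }
  q <- if (normalize) normalize_quaternion(rec$q) else rec$q
  ang <- quat_to_euler_yzx(q)
  tg <- rec$t[1L] + (0:floor(dur * rec$rate_hz + 1e-9)) / rec$rate_hz
  ch <- lapply(trace_channels, function(nm) {
    u <- unwrap_deg(ang[, nm])
    approx(rec$t, u, xout = tg, method = "linear", rule = 2)$y
  })
  euler_trace(ch[[1L]], ch[[2L]], ch[[3L]], rate = rec$rate_hz, t0 = rec$t[1L])
}
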