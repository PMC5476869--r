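#' Trace conditioning: low-pass filtering and discontinuity elimination
#'
#' Raw Euler traces carry sensor noise and occasional discontinuities
#' (tracking resets, residual angle-wrap artifacts). Conditioning removes
#' discontinuities by step subtraction with local re-interpolation, then
#' applies a zero-phase Butterworth low-pass filter. Discontinuities are
#' eliminated before filtering: a low cutoff smears a sharp step over many
#' samples, after which its magnitude can no longer be measured or subtracted.
#'
#' @name conditioning
NULL

#' Butterworth low-pass filter specification
#'
#' @param cutoff_hz cutoff frequency in Hz; must stay below the Nyquist
#'   frequency of the trace it is applied to. Default 2 Hz: well above the
#'   0.3-1 Hz oscillations of interest in seated head motion, well below
#'   sensor noise.
#' @param order filter order (default 4).
#' @param zero_phase if TRUE (default) the filter runs forward and backward so
#'   the output has no phase lag.
#' @return An object of class `filter_spec`.
#' @export
filter_spec <- function(cutoff_hz = 2, order = 4, zero_phase = TRUE) {
  if (!is.numeric(cutoff_hz) || cutoff_hz <= 0) stop("cutoff_hz must be positive")
  if (order < 1 || order != round(order)) stop("order must be a positive integer")
  structure(list(kind = "butterworth-lowpass", cutoff_hz = cutoff_hz,
                 order = as.integer(order), zero_phase = isTRUE(zero_phase)),
            class = "filter_spec")
}

# steady-state-initialized single pass of an IIR filter: a constant input
# passes through without a start-up transient
iir_pass <- function(bf, x, m) {
  dc <- sum(bf$b) / sum(bf$a)
  as.numeric(signal::filter(bf, x, init.x = rep(x[1L], m), init.y = rep(x[1L] * dc, m)))
}

butter_apply <- function(x, cutoff_hz, order, rate, zero_phase) {
  bf <- signal::butter(order, cutoff_hz / (rate / 2), type = "low")
  m <- max(length(bf$a), length(bf$b)) - 1L
  n <- length(x)
  if (!zero_phase) return(iir_pass(bf, x, m))
  # odd-reflection padding plus steady-state initial conditions keeps edge
  # transients at rounding level (filtfilt-style zero-phase application)
  npad <- min(n - 1L, 30L * m)
  xpad <- c(2 * x[1L] - x[(npad + 1L):2L], x, 2 * x[n] - x[(n - 1L):(n - npad)])
  y <- iir_pass(bf, xpad, m)
  y <- rev(iir_pass(bf, rev(y), m))
  y[(npad + 1L):(npad + n)]
}

#' Low-pass filter all channels of an Euler trace
#'
#' @param trace an `euler_trace`.
#' @param spec a [filter_spec()].
#' @return Filtered `euler_trace` of identical length.
#' @export
lowpass_filter <- function(trace, spec = filter_spec()) {
  stopifnot(inherits(trace, "euler_trace"), inherits(spec, "filter_spec"))
  nyq <- trace$rate / 2
  if (spec$cutoff_hz >= nyq) {
    stop("filter cutoff ", spec$cutoff_hz, " Hz is at or above the Nyquist frequency ",
         nyq, " Hz of this trace; choose a cutoff strictly below rate/2")
  }
  out <- trace
  for (ch in trace_channels) {
    out[[ch]] <- butter_apply(trace[[ch]], spec$cutoff_hz, spec$order,
                              trace$rate, spec$zero_phase)
  }
  out
}

#' Detect discontinuities in an angle channel
#'
#' Computes level-1 Haar detail coefficients in stationary (undecimated) form,
#' `d[i] = (x[i+1] - x[i]) / sqrt(2)`, and reports local maxima of their
#' absolute deviation from the median detail that exceed
#' `threshold_mult * MAD(d)`. The stationary transform is used because the
#' decimated Haar transform is blind to steps falling on a coefficient-pair
#' boundary. Reported indices point at the first sample after each jump.
#'
#' @param channel numeric vector of angles in degrees, length >= 8.
#' @param rate sampling rate in Hz (recorded in the report; detection itself
#'   is rate-free).
#' @param threshold_mult detection threshold as a multiple of the MAD of the
#'   detail coefficients (default 8).
#' @return An object of class `discontinuity_report` with fields `indices`,
#'   `magnitudes` (signed jump in degrees) and `method`.
#' @export
detect_discontinuities <- function(channel, rate = 50, threshold_mult = 8) {
  if (length(channel) < 8L) stop("channel must contain at least 8 samples")
  bad <- which(!is.finite(channel))
  if (length(bad) > 0L) stop("non-finite sample at index ", bad[1L])
  if (threshold_mult <= 0) stop("threshold_mult must be positive")
  d <- diff(channel) / sqrt(2)
  dev <- abs(d - median(d))
  thr <- threshold_mult * max(mad(d), .Machine$double.eps)
  cand <- which(dev > thr)
  if (length(cand) > 0L) {
    nd <- length(dev)
    keep <- vapply(cand, function(i) {
      (i == 1L || dev[i] >= dev[i - 1L]) && (i == nd || dev[i] >= dev[i + 1L])
    }, logical(1L))
    cand <- cand[keep]
  }
  structure(
    list(indices = cand + 1L,
         magnitudes = d[cand] * sqrt(2),
         method = "haar1-stationary-mad",
         threshold_mult = threshold_mult,
         rate = rate),
    class = "discontinuity_report"
  )
}

#' @export
print.discontinuity_report <- function(x, ...) {
  cat(sprintf("<discontinuity_report> %d flagged (%s, %g x MAD)\n",
              length(x$indices), x$method, x$threshold_mult))
  if (length(x$indices) > 0L) {
    cat(sprintf("  index %d: %+.1f deg\n", x$indices, x$magnitudes), sep = "")
  }
  invisible(x)
}

#' Eliminate flagged discontinuities from a channel
#'
#' For each flagged index the local jump (in excess of the channel's median
#' one-sample difference, so genuine slope is preserved) is subtracted from
#' all subsequent samples; a 3-sample window around each flagged position is
#' then linearly re-interpolated from its neighbors. Overlapping correction
#' windows are merged (with a message).
#'
#' @param channel numeric vector of angles in degrees.
#' @param report a `discontinuity_report` for this channel.
#' @return Corrected channel, same length.
#' @export
remove_discontinuities <- function(channel, report) {
  stopifnot(inherits(report, "discontinuity_report"))
  idx <- report$indices
  if (length(idx) == 0L) return(channel)
  n <- length(channel)
  if (any(idx < 2L) || any(idx > n)) stop("report indices out of channel bounds")
  x <- channel
  med <- median(diff(channel))
  for (k in sort(idx)) {
    jump <- (x[k] - x[k - 1L]) - med
    x[k:n] <- x[k:n] - jump
  }
  # merge correction windows [k-1, k+1] and re-interpolate each from outside
  lo <- pmax(sort(idx) - 1L, 1L)
  hi <- pmin(sort(idx) + 1L, n)
  merged <- list()
  cl <- lo[1L]; ch <- hi[1L]
  if (length(lo) > 1L) {
    for (j in 2:length(lo)) {
      if (lo[j] <= ch + 1L) {
        ch <- max(ch, hi[j])
        message("overlapping discontinuity correction windows merged at index ", lo[j])
      } else {
        merged[[length(merged) + 1L]] <- c(cl, ch)
        cl <- lo[j]; ch <- hi[j]
      }
    }
  }
  merged[[length(merged) + 1L]] <- c(cl, ch)
  for (w in merged) {
    a <- w[1L] - 1L; b <- w[2L] + 1L
    if (a >= 1L && b <= n) {
      x[w[1L]:w[2L]] <- approx(c(a, b), x[c(a, b)], xout = w[1L]:w[2L])$y
    }
  }
  x
}

#' Trim filter edge effects from a trace
#'
#' Drops `n_edge` samples from each end; downstream metrics exclude filter
#' start-up regions this way. Default policy: `max(order, 10)` samples.
#'
#' @param trace an `euler_trace`.
#' @param n_edge samples to drop at each end.
#' @return Shortened `euler_trace` (start time advanced accordingly).
#' @export
trim_edges <- function(trace, n_edge = 10L) {
  stopifnot(inherits(trace, "euler_trace"))
  n <- length(trace$yaw)
  if (2L * n_edge >= n - 1L) stop("trace too short to trim ", n_edge, " samples per edge")
  keep <- (n_edge + 1L):(n - n_edge)
  euler_trace(trace$yaw[keep], trace$pitch[keep], trace$roll[keep],
              rate = trace$rate, t0 = trace$t0 + n_edge / trace$rate)
}

#' Full conditioning chain for one trace
#'
#' Per channel: detect discontinuities, eliminate them, then low-pass filter;
#' finally trim `max(order, 10)` samples from each edge (unless `trim = FALSE`).
#'
#' @param trace an `euler_trace`.
#' @param spec a [filter_spec()].
#' @param threshold_mult detector threshold multiplier (default 8).
#' @param trim drop filter edge samples (default TRUE).
#' @return A list with `trace` (conditioned `euler_trace`) and `reports`
#'   (named list of per-channel `discontinuity_report`s).
#' @export
condition_trace <- function(trace, spec = filter_spec(), threshold_mult = 8, trim = TRUE) {
  stopifnot(inherits(trace, "euler_trace"))
  reports <- list()
  cleaned <- trace
  for (ch in trace_channels) {
    rep_ch <- detect_discontinuities(trace[[ch]], rate = trace$rate,
                                     threshold_mult = threshold_mult)
    reports[[ch]] <- rep_ch
    cleaned[[ch]] <- remove_discontinuities(trace[[ch]], rep_ch)
  }
  out <- lowpass_filter(cleaned, spec)
  if (trim) out <- trim_edges(out, n_edge = max(spec$order, 10L))
  list(trace = out, reports = reports)
}
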