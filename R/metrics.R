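#' Time-domain motion metrics
#'
#' Per-segment summaries of head excursion: per-axis amplitude ranges and the
#' "motion curve area" — the area of the head trajectory projected onto the
#' yaw-roll plane. The area is defined as the convex-hull area of the
#' (yaw, roll) point cloud: deterministic, parameter-free and monotone under
#' added excursions. A 95% covariance-ellipse alternative is available for
#' sensitivity checks.
#'
#' @name metrics
NULL

#' Per-axis motion range of a trace
#'
#' @param trace an `euler_trace`.
#' @return Named numeric vector `c(yaw=, pitch=, roll=)` of max - min in degrees.
#' @export
motion_range <- function(trace) {
  stopifnot(inherits(trace, "euler_trace"))
  vapply(trace_channels, function(ch) diff(range(trace[[ch]])), numeric(1L))
}

# shoelace area of a polygon given vertex coordinates in order
shoelace_area <- function(x, y) {
  j <- c(seq_along(x)[-1L], 1L)
  abs(sum(x * y[j] - x[j] * y)) / 2
}

#' Motion-curve area in the yaw-roll plane
#'
#' @param trace an `euler_trace` with at least 3 samples.
#' @param method `"hull"` (default): convex-hull area of the (yaw, roll)
#'   points, 0 for degenerate/collinear clouds. `"ellipse"`: area of the 95%
#'   covariance ellipse.
#' @return Area in deg^2.
#' @export
yaw_roll_curve_area <- function(trace, method = c("hull", "ellipse")) {
  stopifnot(inherits(trace, "euler_trace"))
  method <- match.arg(method)
  x <- trace$yaw; y <- trace$roll
  if (length(x) < 3L) stop("curve area needs at least 3 samples")
  if (method == "hull") {
    h <- chull(x, y)
    if (length(h) < 3L) return(0)
    return(shoelace_area(x[h], y[h]))
  }
  S <- cov(cbind(x, y))
  d <- det(S)
  if (!is.finite(d) || d <= 0) return(0)
  pi * sqrt(d) * qchisq(0.95, df = 2)
}

#' Percent change of motion-curve area between matched segments
#'
#' Signed percent, negative for a reduction:
#' `(area_after - area_before) / area_before * 100`.
#'
#' @param area_before,area_after areas in deg^2; `area_before` must be > 0.
#' @return Signed percent change.
#' @examples
#' percent_area_change(100, 77)   # -23
#' percent_area_change(100, 117)  # +17
#' @export
percent_area_change <- function(area_before, area_after) {
  if (!is.numeric(area_before) || area_before <= 0) {
    stop("area_before must be positive (percent change is undefined for a zero baseline)")
  }
  (area_after - area_before) / area_before * 100
}

#' Summarize a conditioned segment trace
#'
#' @param trace an `euler_trace` (normally conditioned and edge-trimmed).
#' @param segment,session,participant optional labels carried into the row.
#' @param area_method passed to [yaw_roll_curve_area()].
#' @return One-row tibble: labels, per-axis ranges, `curve_area`, `duration`.
#' @export
motion_summary <- function(trace, segment = NA_character_, session = NA_integer_,
                           participant = NA_character_, area_method = "hull") {
  r <- motion_range(trace)
  tibble(
    participant = participant, session = as.integer(session), segment = segment,
    range_yaw = unname(r["yaw"]), range_pitch = unname(r["pitch"]),
    range_roll = unname(r["roll"]),
    curve_area = yaw_roll_curve_area(trace, method = area_method),
    duration = length(trace$yaw) / trace$rate
  )
}
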