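#' Spectral analysis of head-motion channels
#'
#' One-sided FFT power spectra of angle channels (plain periodogram, no
#' taper), normalized so that the summed power equals the variance of the
#' mean-removed signal (Parseval; variance with divisor n). High-frequency
#' band power above an analyst-chosen cutoff — 0.34 Hz and 0.44 Hz are the
#' conventional cutoffs for "turbulent" head movement in seated VR sessions —
#' is compared between sessions with matched content.
#'
#' @name spectral
NULL

#' One-sided power spectrum of a channel
#'
#' The channel mean is removed, the FFT taken without tapering, and the
#' squared magnitudes folded onto the one-sided frequency grid
#' `0, rate/n, ..., rate/2`. Power units are deg^2; summing all bins
#' reproduces `mean((x - mean(x))^2)` to rounding precision.
#'
#' @param channel numeric vector (degrees), length >= 16, finite.
#' @param rate sampling rate in Hz.
#' @return Object of class `power_spectrum` with fields `freqs`, `power`,
#'   `n`, `rate`.
#' @export
power_spectrum <- function(channel, rate) {
  n <- length(channel)
  if (n < 16L) stop("channel must contain at least 16 samples for spectral analysis")
  if (!all(is.finite(channel))) stop("channel contains non-finite samples")
  if (rate <= 0) stop("rate must be positive")
  x <- channel - mean(channel)
  P <- Mod(fft(x))^2 / n^2
  nh <- floor(n / 2)
  pw <- P[1:(nh + 1L)]
  # double the interior bins; the Nyquist bin is unpaired only when n is even
  if (nh >= 2L) {
    top <- if (n %% 2L == 0L) nh else nh + 1L
    pw[2:top] <- 2 * pw[2:top]
  }
  structure(
    list(freqs = (0:nh) * rate / n, power = pw, n = n, rate = rate),
    class = "power_spectrum"
  )
}

#' @export
print.power_spectrum <- function(x, ...) {
  cat(sprintf("<power_spectrum> n=%d @ %g Hz, df=%.4f Hz, total power %.4g deg^2\n",
              x$n, x$rate, x$rate / x$n, sum(x$power)))
  invisible(x)
}

#' Export a spectrum as a data frame (`freq_hz`, `power`)
#' @param spec a `power_spectrum`.
#' @export
spectrum_to_df <- function(spec) {
  stopifnot(inherits(spec, "power_spectrum"))
  tibble(freq_hz = spec$freqs, power = spec$power)
}

#' Band power of a spectrum
#'
#' Sums power over bins with `f_lo < f <= f_hi` (half-open on the left, so
#' adjacent bands partition the axis and `band_power(spec, 0, rate/2)` is the
#' total power — the DC bin is zero after mean removal).
#'
#' @param spec a `power_spectrum`.
#' @param f_lo,f_hi band edges in Hz, `0 <= f_lo < f_hi <= rate/2`.
#' @return Band power in deg^2.
#' @export
band_power <- function(spec, f_lo, f_hi) {
  stopifnot(inherits(spec, "power_spectrum"))
  tol <- 1e-9 * spec$rate
  if (f_lo < 0 || f_lo >= f_hi || f_hi > spec$rate / 2 + tol) {
    stop("band edges must satisfy 0 <= f_lo < f_hi <= rate/2")
  }
  sum(spec$power[spec$freqs > f_lo + tol & spec$freqs <= f_hi + tol])
}

#' Compare high-frequency band power between two sessions
#'
#' Computes the band power above `f_cut` in both spectra and classifies the
#' change: `reduced` if the later session's power falls below
#' `(1 - negligible_frac)` times the earlier one, `increased` above
#' `(1 + negligible_frac)`, otherwise `negligible`.
#'
#' @param a,b `power_spectrum` objects for the earlier and later session
#'   (must share the sampling rate). Compare spectra computed from
#'   equal-length channels; [run_study()] truncates matched segments to the
#'   shorter length before this step.
#' @param f_cut high-frequency cutoff in Hz (e.g. 0.34 or 0.44).
#' @param negligible_frac width of the "no change" band (default 0.2).
#' @return Object of class `spectral_comparison` with `f_cut`, `power_a`,
#'   `power_b`, `ratio` (`Inf` when `power_a` is 0 and `power_b` positive) and
#'   `verdict`.
#' @export
compare_sessions_spectra <- function(a, b, f_cut, negligible_frac = 0.2) {
  stopifnot(inherits(a, "power_spectrum"), inherits(b, "power_spectrum"))
  if (a$rate != b$rate) stop("spectra must share the sampling rate")
  pa <- band_power(a, f_cut, a$rate / 2)
  pb <- band_power(b, f_cut, b$rate / 2)
  ratio <- if (pa > 0) pb / pa else if (pb > 0) Inf else 1
  verdict <- if (pb < (1 - negligible_frac) * pa) {
    "reduced"
  } else if (pb > (1 + negligible_frac) * pa) {
    "increased"
  } else {
    "negligible"
  }
  structure(
    list(f_cut = f_cut, power_a = pa, power_b = pb, ratio = ratio, verdict = verdict),
    class = "spectral_comparison"
  )
}

#' @export
print.spectral_comparison <- function(x, ...) {
  cat(sprintf("<spectral_comparison> >%g Hz: %.4g -> %.4g deg^2 (ratio %.3g) => %s\n",
              x$f_cut, x$power_a, x$power_b, x$ratio, x$verdict))
  invisible(x)
}
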