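#' Butterworth bandpass filter design
#'
#' Designs a digital Butterworth bandpass filter by the classical analog
#' prototype -> lowpass-to-bandpass transform -> bilinear transform route,
#' returning transfer-function coefficients suitable for [iir_filter()] and
#' [filtfilt()].
#'
#' @param low_hz Lower band edge in Hz.
#' @param high_hz Upper band edge in Hz.
#' @param fs Sampling rate in Hz.
#' @param order Order of the analog lowpass prototype; the resulting digital
#'   bandpass filter has `2 * order` poles. Default 4, the conventional choice
#'   for EEG band decomposition.
#' @return A list with numerator `b` and denominator `a` coefficient vectors
#'   (`a[1] == 1`).
#' @examples
#' bf <- butter_bandpass(8, 14, fs = 128)
#' length(bf$a) # 9 coefficients for order 4
#' @export
butter_bandpass <- function(low_hz, high_hz, fs, order = 4L) {
  if (!is.numeric(low_hz) || !is.numeric(high_hz) || low_hz <= 0)
    stop("band edges must be positive numbers")
  if (high_hz <= low_hz)
    stop("high_hz must exceed low_hz")
  if (high_hz >= fs / 2)
    stop(sprintf("band edge %.3g Hz is at or above the Nyquist frequency %.3g Hz",
                 high_hz, fs / 2))
  order <- as.integer(order)
  if (order < 1L) stop("order must be >= 1")

  # pre-warped analog edge frequencies (rad/s)
  fs2 <- 2 * fs
  w1 <- fs2 * tan(pi * low_hz / fs)
  w2 <- fs2 * tan(pi * high_hz / fs)
  bw <- w2 - w1
  w0 <- sqrt(w1 * w2)

  # analog Butterworth lowpass prototype: poles on the unit circle, no zeros
  k <- seq_len(order)
  p_lp <- exp(1i * pi * (2 * k + order - 1) / (2 * order))

  # lowpass -> bandpass: each pole splits in two; order zeros appear at s = 0
  p_sc <- p_lp * bw / 2
  rt <- sqrt(p_sc^2 - w0^2)
  p_bp <- c(p_sc + rt, p_sc - rt)
  z_bp <- rep(0 + 0i, order)
  k_bp <- bw^order

  # bilinear transform s -> (2/T)(z-1)/(z+1)
  p_z <- (fs2 + p_bp) / (fs2 - p_bp)
  z_z <- (fs2 + z_bp) / (fs2 - z_bp)
  k_z <- k_bp * Re(prod(fs2 - z_bp) / prod(fs2 - p_bp))
  # degree deficit becomes zeros at z = -1
  z_z <- c(z_z, rep(-1 + 0i, length(p_bp) - length(z_bp)))

  b <- Re(k_z * poly_from_roots(z_z))
  a <- Re(poly_from_roots(p_z))
  list(b = b / a[1], a = a / a[1])
}

# expand prod (x - r_i) into descending-power coefficients
poly_from_roots <- function(r) {
  coefs <- 1 + 0i
  for (ri in r) coefs <- c(coefs, 0) - c(0, coefs * ri)
  coefs
}

#' Apply an IIR filter (direct form, zero initial state)
#'
#' @param bf Filter as returned by [butter_bandpass()] (list with `b`, `a`).
#' @param x Numeric vector.
#' @return Filtered vector of the same length.
#' @export
iir_filter <- function(bf, x) {
  b <- bf$b; a <- bf$a
  nb <- length(b)
  # FIR part with zero initial conditions
  z <- stats::filter(c(rep(0, nb - 1), x), b, method = "convolution", sides = 1)
  z <- as.numeric(z[nb:(nb + length(x) - 1)])
  if (length(a) > 1) {
    z <- as.numeric(stats::filter(z, -a[-1], method = "recursive"))
  }
  z
}

#' Zero-phase (forward-backward) filtering
#'
#' Filters the signal forwards and backwards so the net phase response is zero,
#' using odd-symmetric edge extension to suppress startup transients (the same
#' convention scipy's `filtfilt` uses).
#'
#' @inheritParams iir_filter
#' @return Filtered vector of the same length as `x`.
#' @export
filtfilt <- function(bf, x) {
  n <- length(x)
  pad <- 3L * (max(length(bf$a), length(bf$b)) - 1L)
  if (n <= pad)
    stop(sprintf("signal too short for zero-phase filtering: %d samples, need > %d", n, pad))
  # odd extension about the end points
  pre <- 2 * x[1] - x[(pad + 1):2]
  post <- 2 * x[n] - x[(n - 1):(n - pad)]
  y <- iir_filter(bf, c(pre, x, post))
  y <- rev(iir_filter(bf, rev(y)))
  y[(pad + 1):(pad + n)]
}

#' Default EEG frequency bands
#'
#' The four canonical bands used throughout: theta (4-8 Hz), alpha (8-14 Hz),
#' beta (14-31 Hz) and gamma (31-45 Hz).
#'
#' @param filter_order Butterworth prototype order used when the bands are
#'   turned into filters. Default 4.
#' @return A data.frame with columns `name`, `low_hz`, `high_hz`, `filter_order`.
#' @export
default_bands <- function(filter_order = 4L) {
  data.frame(
    name = c("theta", "alpha", "beta", "gamma"),
    low_hz = c(4, 8, 14, 31),
    high_hz = c(8, 14, 31, 45),
    filter_order = as.integer(filter_order),
    stringsAsFactors = FALSE
  )
}

validate_bands <- function(bands, fs) {
  stopifnot(is.data.frame(bands),
            all(c("name", "low_hz", "high_hz", "filter_order") %in% names(bands)))
  if (any(bands$low_hz <= 0) || any(bands$high_hz <= bands$low_hz))
    stop("invalid band edges: need 0 < low_hz < high_hz")
  if (any(bands$high_hz >= fs / 2))
    stop(sprintf("band edge above Nyquist (%g Hz) for sampling rate %g Hz",
                 fs / 2, fs))
  invisible(bands)
}
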