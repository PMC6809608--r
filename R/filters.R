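# Zero-phase FIR filtering.
#
# Kernels are designed with signal::fir1 (Hamming window); application is
# forward-backward ("filtfilt") so the net response is zero-phase with the
# squared magnitude of the kernel. Convolution runs through one FFT per
# direction, which is what makes the 0.1 Hz high-pass (a ~17k-tap kernel at
# 512 Hz) affordable on minutes-long recordings.

fir_order <- function(rate, trans_hz) {
  # Hamming-window transition width ~ 3.3 / N (normalized); force even order
  n <- ceiling(3.3 * rate / trans_hz)
  n + (n %% 2L)
}

fir_highpass <- function(rate, corner_hz, trans_hz = 0.1) {
  check_corner(corner_hz, rate)
  signal::fir1(fir_order(rate, trans_hz), corner_hz / (rate / 2),
               type = "high")
}

fir_lowpass <- function(rate, corner_hz, trans_hz = max(1, corner_hz / 4)) {
  check_corner(corner_hz, rate)
  signal::fir1(fir_order(rate, trans_hz), corner_hz / (rate / 2),
               type = "low")
}

fir_bandstop <- function(rate, band_hz, trans_hz = 1) {
  check_corner(band_hz, rate)
  signal::fir1(fir_order(rate, trans_hz), band_hz / (rate / 2),
               type = "stop")
}

fir_bandpass <- function(rate, band_hz, trans_hz = 5) {
  check_corner(band_hz, rate)
  signal::fir1(fir_order(rate, trans_hz), band_hz / (rate / 2),
               type = "pass")
}

check_corner <- function(hz, rate) {
  if (any(!is.finite(hz)) || any(hz <= 0) || any(hz >= rate / 2))
    stop("filter corner frequencies must lie strictly inside (0, Nyquist)")
  invisible(hz)
}

# Causal FIR filtering y = conv(x, b), truncated to length(x), via FFT.
# B may hold the precomputed kernel FFT at length nfft.
fft_conv_causal <- function(x, b, nfft = NULL, B = NULL) {
  n <- length(x); m <- length(b)
  if (is.null(nfft)) nfft <- stats::nextn(n + m - 1L, 2L)
  if (is.null(B)) B <- stats::fft(c(b, numeric(nfft - m)))
  y <- Re(stats::fft(stats::fft(c(x, numeric(nfft - n))) * B,
                     inverse = TRUE)) / nfft
  y[seq_len(n)]
}

# Zero-phase filtering of every row of a matrix with one kernel; the kernel
# FFT is computed once.
filtfilt_rows <- function(X, b) {
  n <- ncol(X); m <- length(b)
  p <- min(m, n - 1L)
  nfft <- stats::nextn(n + 2L * p + m - 1L, 2L)
  B <- stats::fft(c(b, numeric(nfft - m)))
  for (ch in seq_len(nrow(X))) {
    x <- X[ch, ]
    xx <- c(2 * x[1L] - x[seq(p + 1L, 2L)], x,
            2 * x[n] - x[seq(n - 1L, n - p)])
    y <- fft_conv_causal(xx, b, nfft, B)
    z <- rev(fft_conv_causal(rev(y), b, nfft, B))
    X[ch, ] <- z[seq(p + 1L, p + n)]
  }
  X
}

#' Zero-phase FIR filtering of a signal
#'
#' Applies an FIR kernel forward and backward (via FFT convolution), giving
#' zero phase distortion and twice the kernel's stopband attenuation. The
#' signal is extended at both ends by odd reflection (up to one kernel
#' length) before filtering to suppress edge transients, then trimmed.
#'
#' @param x numeric signal.
#' @param b FIR kernel coefficients.
#' @return filtered signal, same length as \code{x}.
#' @export
filtfilt_fir <- function(x, b) {
  n <- length(x); m <- length(b)
  p <- min(m, n - 1L)
  xx <- c(2 * x[1L] - x[seq(p + 1L, 2L)], x,
          2 * x[n] - x[seq(n - 1L, n - p)])
  y <- fft_conv_causal(xx, b)
  z <- rev(fft_conv_causal(rev(y), b))
  z[seq(p + 1L, p + n)]
}
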