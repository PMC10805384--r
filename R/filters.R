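# Shared signal-processing helpers: zero-phase FIR band-pass, FFT-mask
# notch, band-limited resampling, FFT analytic signal.

# FIR band-pass order by the fs/df * atten/22 rule of thumb, rounded to even
fir_bandpass_coef <- function(fs, lo, hi, atten = 85) {
  stopifnot(hi < fs / 2, lo > 0, lo < hi)
  n <- ceiling(fs / hi * atten / 22)
  n <- n + n %% 2
  as.numeric(signal::fir1(n, c(lo, hi) / (fs / 2), type = "pass"))
}

# two-pass (zero-phase) FIR band-pass
bandpass_zero_phase <- function(x, fs, lo, hi, atten = 85) {
  b <- fir_bandpass_coef(fs, lo, hi, atten)
  as.numeric(signal::filtfilt(b, 1, x))
}

# zero-phase band-stop at f0 +/- width Hz via a Fourier-domain mask
# (exactly zero-phase and idempotent; appropriate for narrow line notches)
bandstop_zero_phase <- function(x, fs, f0, width = 2) {
  stopifnot(f0 + width < fs / 2)
  n <- length(x)
  fr <- (seq_len(n) - 1) / n * fs
  fr <- pmin(fr, fs - fr)  # fold to [0, fs/2]
  mask <- as.numeric(abs(fr - f0) > width)
  Re(stats::fft(stats::fft(x) * mask, inverse = TRUE)) / n
}

#' Band-limited (Fourier-domain) resampling of a numeric series
#'
#' Resamples by spectral truncation: the Fourier transform is cut at the
#' new Nyquist frequency and inverted at the target length, giving exact
#' passband gain and brick-wall anti-aliasing (circular edge effects are
#' negligible for demeaned trial-length series).
#'
#' @param x numeric series.
#' @param fs_from,fs_to original and target sample rates (Hz).
#' @return resampled series of length \code{round(length(x) * fs_to/fs_from)}.
#' @export
resample_series <- function(x, fs_from, fs_to) {
  if (fs_to == fs_from) return(x)
  n <- length(x)
  m <- round(n * fs_to / fs_from)
  X <- stats::fft(x)
  Y <- complex(m)
  h <- floor((min(n, m) - 1) / 2)  # positive frequencies kept
  Y[1:(h + 1)] <- X[1:(h + 1)]
  if (h > 0) Y[(m - h + 1):m] <- X[(n - h + 1):n]
  if (m < n && m %% 2 == 0) {
    # fold energy at the new Nyquist bin to keep the series real
    Y[m / 2 + 1] <- Re(X[m / 2 + 1]) * 0  # brick wall just below Nyquist
  }
  Re(stats::fft(Y, inverse = TRUE)) / n
}

# analytic signal via FFT (phase/envelope extraction)
analytic_signal <- function(x) {
  n <- length(x)
  X <- stats::fft(x)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[c(1, n / 2 + 1)] <- 1
    h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1
    h[2:((n + 1) / 2)] <- 2
  }
  stats::fft(X * h, inverse = TRUE) / n
}
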