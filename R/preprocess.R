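# Turn raw paired recordings into analysis-ready 10 s trials and compute
# descriptive spectra.

#' Construct a multichannel recording
#'
#' @param x numeric matrix (samples x channels) or vector.
#' @param fs sample rate (Hz).
#' @param region character vector per channel, values in
#'   \code{c("cortex", "thalamus")}.
#' @param line_freq mains frequency (50 or 60 Hz).
#' @param state state label (waking / anesthesia / seizure / psychedelic).
#' @param channel_id optional channel identifiers.
#' @return object of class \code{nc_recording}.
#' @export
recording <- function(x, fs, region, line_freq = 60, state = "waking",
                      channel_id = NULL) {
  x <- as.matrix(x)
  stopifnot(length(region) == ncol(x),
            all(region %in% c("cortex", "thalamus")),
            line_freq %in% c(50, 60))
  if (is.null(channel_id)) channel_id <- paste0(region, seq_len(ncol(x)))
  colnames(x) <- channel_id
  structure(list(x = x, fs = fs, region = region, line_freq = line_freq,
                 state = state, channel_id = channel_id),
            class = "nc_recording")
}

#' Split a recording into fixed-length trials
#'
#' Non-overlapping consecutive windows; any remainder shorter than
#' \code{length_s} is dropped.
#'
#' @param rec an \code{nc_recording}.
#' @param length_s trial length (s); default 10.
#' @return list of \code{nc_trial} objects (empty, with a warning, if the
#'   recording is shorter than one trial).
#' @export
segment_trials <- function(rec, length_s = 10) {
  n <- nrow(rec$x)
  nper <- round(length_s * rec$fs)
  k <- n %/% nper
  if (k == 0) {
    warning("recording shorter than one trial; returning no trials")
    return(list())
  }
  lapply(seq_len(k), function(i) {
    idx <- ((i - 1) * nper + 1):(i * nper)
    structure(list(x = rec$x[idx, , drop = FALSE], fs = rec$fs,
                   region = rec$region, line_freq = rec$line_freq,
                   state = rec$state, index = i, artifact_flag = FALSE),
              class = "nc_trial")
  })
}

#' Demean, detrend and notch-filter a trial
#'
#' Removes each channel's mean and linear trend, then applies zero-phase
#' band-stop filters (2 Hz half-width) at the mains frequency and every
#' harmonic below Nyquist.
#'
#' @param trial an \code{nc_trial}.
#' @param line_freq override of the trial's mains frequency.
#' @return cleaned \code{nc_trial}.
#' @export
clean_trial <- function(trial, line_freq = NULL) {
  if (is.null(line_freq)) line_freq <- trial$line_freq
  fs <- trial$fs
  stopifnot(fs > 2 * line_freq)
  tt <- seq_len(nrow(trial$x))
  harmonics <- line_freq * seq_len(floor((fs / 2 - 3) / line_freq))
  trial$x <- apply(trial$x, 2, function(ch) {
    # detrending and notching interact weakly (a trend leaks into every
    # Fourier bin); two passes make the composite a fixed point
    for (pass in 1:2) {
      ch <- residuals(lm(ch ~ tt))
      for (f0 in harmonics) ch <- bandstop_zero_phase(ch, fs, f0, width = 2)
    }
    ch
  })
  trial
}

#' Resample a trial to a lower working rate
#'
#' Band-limited (Fourier-domain) resampling of every channel; duration
#' preserved, passband gain exact, brick-wall anti-aliasing.
#'
#' @param trial an \code{nc_trial}.
#' @param target_fs target rate (Hz), at most the trial's rate.
#' @return resampled \code{nc_trial}.
#' @export
resample_trial <- function(trial, target_fs = 416) {
  if (target_fs > trial$fs) stop("upsampling not supported")
  trial$x <- apply(trial$x, 2, resample_series, fs_from = trial$fs,
                   fs_to = target_fs)
  trial$fs <- target_fs
  trial
}

#' Welch power spectral density
#'
#' Segment-averaged one-sided PSD with Hann-tapered overlapping segments.
#'
#' @param x numeric series or \code{nc_trial} (first channel).
#' @param fs sample rate (ignored for trials).
#' @param seg_s segment length (s); default 2.
#' @param overlap fractional overlap; default 0.5.
#' @return data.frame with \code{freq} (Hz) and \code{power} (units^2/Hz);
#'   satisfies Parseval: \code{sum(power) * df} approximates the variance.
#' @export
welch_psd <- function(x, fs, seg_s = 2, overlap = 0.5) {
  if (inherits(x, "nc_trial")) { fs <- x$fs; x <- x$x[, 1] }
  n <- length(x)
  nper <- min(n, round(seg_s * fs))
  step <- max(1, round(nper * (1 - overlap)))
  starts <- seq(1, n - nper + 1, by = step)
  w <- 0.5 - 0.5 * cos(2 * pi * seq_len(nper) / (nper + 1))
  U <- sum(w^2)
  nf <- nper %/% 2 + 1
  acc <- numeric(nf)
  for (s in starts) {
    seg <- x[s:(s + nper - 1)]
    seg <- (seg - mean(seg)) * w
    sp <- Mod(stats::fft(seg))^2 / (U * fs)
    acc <- acc + sp[seq_len(nf)]
  }
  pw <- acc / length(starts)
  # one-sided: double everything except DC (and Nyquist for even lengths)
  if (nper %% 2 == 0) pw[2:(nf - 1)] <- 2 * pw[2:(nf - 1)]
  else pw[2:nf] <- 2 * pw[2:nf]
  data.frame(freq = (seq_len(nf) - 1) * fs / nper, power = pw)
}

# fraction of total power within a band
band_power_fraction <- function(x, fs, lo, hi, ...) {
  psd <- welch_psd(x, fs, ...)
  tot <- sum(psd$power)
  if (tot == 0) return(0)
  sum(psd$power[psd$freq >= lo & psd$freq <= hi]) / tot
}
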