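# Maximal overlap discrete wavelet transform (pyramid algorithm) with the
# least-asymmetric 8-tap (LA8) filter pair. Shift-invariant, non-decimated,
# exactly invertible; level j details span (fs/2^(j+1), fs/2^j].

# LA8 scaling (low-pass) filter, sum = sqrt(2)
LA8_G <- c(-0.07576571478927333, -0.02963552764599851, 0.49761866763201545,
            0.80373875180591614,  0.29785779560527736, -0.09921954357684722,
           -0.01260396726203783,  0.03222310060404270)
# quadrature mirror wavelet (high-pass) filter
LA8_H <- rev(LA8_G) * c(1, -1, 1, -1, 1, -1, 1, -1)

# one MODWT filtering stage: circular convolution with filter upsampled by
# 2^(j-1)
circ_shift <- function(v, shift) {
  # right-shift by `shift` samples, circular
  n <- length(v)
  shift <- shift %% n
  if (shift == 0) v else c(v[(n - shift + 1):n], v[seq_len(n - shift)])
}

modwt_stage <- function(v, filt, j) {
  n <- length(v)
  out <- numeric(n)
  step <- 2^(j - 1)
  for (l in seq_along(filt)) {
    out <- out + filt[l] * circ_shift(v, (l - 1) * step)
  }
  out
}

imodwt_stage <- function(w, filt, j) {
  n <- length(w)
  out <- numeric(n)
  step <- 2^(j - 1)
  for (l in seq_along(filt)) {
    out <- out + filt[l] * circ_shift(w, -(l - 1) * step)
  }
  out
}

#' Maximal overlap discrete wavelet transform
#'
#' Decomposes a series into \code{J} detail-coefficient series plus a
#' level-J smooth, all of the original length, using the LA8 filter pair
#' rescaled for the non-decimated transform. The decomposition is exactly
#' invertible with [imodwt()]. At sample rate fs, detail level j nominally
#' spans the dyadic band (fs/2^(j+1), fs/2^j].
#'
#' @param x numeric series, length >= 2^J.
#' @param J number of levels; default 8.
#' @return list of class \code{nc_modwt}: \code{W} (n x J detail matrix),
#'   \code{V} (smooth), \code{J}, \code{n}.
#' @export
modwt <- function(x, J = 8) {
  n <- length(x)
  if (n < 2^J) stop("series shorter than 2^J; reduce the level count")
  g <- LA8_G / sqrt(2)
  h <- LA8_H / sqrt(2)
  W <- matrix(0, n, J)
  v <- x
  for (j in seq_len(J)) {
    W[, j] <- modwt_stage(v, h, j)
    v <- modwt_stage(v, g, j)
  }
  structure(list(W = W, V = v, J = J, n = n), class = "nc_modwt")
}

#' Inverse maximal overlap discrete wavelet transform
#'
#' @param d an \code{nc_modwt} decomposition (possibly with modified
#'   coefficients).
#' @return reconstructed series.
#' @export
imodwt <- function(d) {
  g <- LA8_G / sqrt(2)
  h <- LA8_H / sqrt(2)
  v <- d$V
  for (j in rev(seq_len(d$J))) {
    v <- imodwt_stage(d$W[, j], h, j) + imodwt_stage(v, g, j)
  }
  v
}

#' Dyadic frequency span of a MODWT detail level
#'
#' @param level detail level j.
#' @param fs sample rate (Hz).
#' @return c(f_lo, f_hi): the band (fs/2^(j+1), fs/2^j].
#' @export
modwt_band_hz <- function(level, fs = 416) {
  c(fs / 2^(level + 1), fs / 2^level)
}

#' Band-pair specification for spectrally resolved information transfer
#'
#' @param send_levels MODWT detail levels randomized on the sender side.
#' @param recv_levels detail levels randomized on the receiver side.
#' @param fs working sample rate (Hz); default 416, at which level 2 spans
#'   52-104 Hz and levels 5-8 jointly span 0.8125-13 Hz.
#' @param J decomposition depth; default 8.
#' @return list of class \code{nc_band_pair} with nominal Hz spans.
#' @export
band_pair <- function(send_levels, recv_levels, fs = 416, J = 8) {
  stopifnot(all(send_levels %in% seq_len(J)) || !length(send_levels),
            all(recv_levels %in% seq_len(J)) || !length(recv_levels))
  span <- function(lv) if (!length(lv)) c(NA, NA) else
    c(min(fs / 2^(max(lv) + 1)), max(fs / 2^(min(lv))))
  structure(list(send_levels = send_levels, recv_levels = recv_levels,
                 fs = fs, J = J,
                 send_hz = span(send_levels), recv_hz = span(recv_levels)),
            class = "nc_band_pair")
}

#' Iterative amplitude-adjusted Fourier transform surrogate
#'
#' Produces a surrogate sharing the exact amplitude multiset of the input
#' (a permutation of its values) and matching its amplitude spectrum within
#' tolerance, with randomized phase structure.
#'
#' @param x numeric series, length >= 64 recommended.
#' @param seed seed for the initial shuffle.
#' @param max_iter maximum iterations; default 60.
#' @param tol relative spectrum RMS error target; default 1e-4.
#' @return surrogate series; attribute \code{converged} FALSE if
#'   \code{max_iter} was exhausted.
#' @export
iaaft_surrogate <- function(x, seed = NULL, max_iter = 60, tol = 1e-4) {
  if (!is.null(seed)) set.seed(seed)
  n <- length(x)
  amp <- Mod(stats::fft(x))
  xs <- sort(x)
  s <- sample(x)
  prev_rank <- integer(0)
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    z <- stats::fft(s)
    ph <- Arg(z)
    s2 <- Re(stats::fft(amp * exp(1i * ph), inverse = TRUE) / n)
    rk <- rank(s2, ties.method = "first")
    s <- xs[rk]
    sp_err <- sqrt(mean((Mod(stats::fft(s)) - amp)^2)) / sqrt(mean(amp^2))
    if (identical(rk, prev_rank) || sp_err < tol) { converged <- TRUE; break }
    prev_rank <- rk
  }
  structure(s, converged = converged)
}

#' Randomize selected wavelet bands of a series
#'
#' MODWT-decomposes the series, replaces the detail-coefficient series of
#' each selected level with an IAAFT-randomized version, and
#' inverse-transforms. Content outside the selected bands passes through
#' untouched. Each level's coefficient series keeps its exact amplitude
#' distribution and approximate spectrum; the reconstruction's variance is
#' preserved to the extent that in-band content does not straddle level
#' boundaries coherently (wavelet leakage; see the methods vignette).
#'
#' @param x numeric series.
#' @param levels detail levels to randomize (empty = identity).
#' @param seed seed; per-level streams are derived deterministically.
#' @param J decomposition depth; default 8.
#' @param max_iter,tol passed to [iaaft_surrogate()].
#' @return surrogate series.
#' @export
band_swap_surrogate <- function(x, levels, seed = NULL, J = 8,
                                max_iter = 60, tol = 1e-4) {
  if (!length(levels)) return(x)
  d <- modwt(x, J)
  for (i in seq_along(levels)) {
    j <- levels[i]
    sj <- if (is.null(seed)) NULL else seed + 1000L * i
    d$W[, j] <- as.numeric(iaaft_surrogate(d$W[, j], seed = sj,
                                           max_iter = max_iter, tol = tol))
  }
  imodwt(d)
}
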