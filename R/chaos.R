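# Chaoticity estimation: extrema discretization + modified 0-1 chaos test
# for recorded/simulated series, and twin-run stochastic largest Lyapunov
# exponents for the mean-field model.

#' Time-discretize a series by its prominent local extrema
#'
#' Returns the values of all local minima and maxima whose topographic
#' prominence is at least \code{prominence_fraction} of the maximum absolute
#' amplitude of the series, in temporal order. This removes oversampling of
#' smooth band-limited signals before the 0-1 chaos test.
#'
#' @param x numeric series (length > 2).
#' @param prominence_fraction prominence threshold as a fraction of
#'   \code{max(abs(x))}; default 0.10.
#' @return numeric vector of extremum values (temporal order).
#' @export
discretize_extrema <- function(x, prominence_fraction = 0.10) {
  stopifnot(length(x) > 2)
  thr <- prominence_fraction * max(abs(x))
  keep_max <- prominent_peaks(x, thr)
  keep_min <- prominent_peaks(-x, thr)
  idx <- sort(c(keep_max, keep_min))
  if (length(idx) < 10) {
    stop("insufficient extrema: fewer than 10 local extrema pass the prominence threshold")
  }
  x[idx]
}

# indices of local maxima of x with prominence >= thr
prominent_peaks <- function(x, thr) {
  n <- length(x)
  d <- diff(x)
  peaks <- which(d[-(n - 1)] > 0 & d[-1] <= 0) + 1L
  if (!length(peaks)) return(integer(0))
  keep <- logical(length(peaks))
  for (i in seq_along(peaks)) {
    p <- peaks[i]; h <- x[p]
    # walk out to the nearest higher ground on each side; base = min en route
    lb <- h
    j <- p - 1L
    lmin <- h
    while (j >= 1L && x[j] <= h) { if (x[j] < lmin) lmin <- x[j]; j <- j - 1L }
    lb <- if (j >= 1L) lmin else min(x[1:p])
    j <- p + 1L
    rmin <- h
    while (j <= n && x[j] <= h) { if (x[j] < rmin) rmin <- x[j]; j <- j + 1L }
    rb <- if (j <= n) rmin else min(x[p:n])
    keep[i] <- (h - max(lb, rb)) >= thr
  }
  peaks[keep]
}

#' Modified 0-1 chaos test K-statistic
#'
#' Drives a planar walk with the input sequence, \code{p(n+1) = p(n) +
#' phi(n) cos(cn)}, \code{q(n+1) = q(n) + phi(n) sin(cn)}, and measures the
#' growth of the time-averaged mean square displacement plus a noise term
#' \code{sigma * eta_n} (eta uniform on [-1/2, 1/2]). For each of \code{n_c}
#' random angles c drawn from \code{c_range}, \code{K_c} is the Pearson
#' correlation between n and \code{M_c(n)} for n up to a tenth of the series
#' length; the statistic is the median over c. K approaches 1 for chaotic
#' and 0 for periodic dynamics.
#'
#' @param x discretized sequence (e.g. from [discretize_extrema()]).
#' @param sigma noise level of the displacement noise term; default 0.5.
#' @param n_c number of random angles; default 100.
#' @param seed seed for the angle and noise draws.
#' @param c_range interval for c; default \code{c(0, 2*pi)}. Set e.g.
#'   \code{c(pi/5, 4*pi/5)} to avoid resonant angles.
#' @return list of class \code{nc_k01}: \code{K} (median), \code{K_c},
#'   \code{c_values}, \code{sigma}, \code{degenerate} flag.
#' @export
k_statistic <- function(x, sigma = 0.5, n_c = 100, seed = NULL,
                        c_range = c(0, 2 * pi)) {
  if (!is.null(seed)) set.seed(seed)
  N <- length(x)
  if (sd(x) == 0) {
    return(structure(list(K = 0, K_c = rep(0, n_c), c_values = numeric(n_c),
                          sigma = sigma, degenerate = TRUE),
                     class = "nc_k01"))
  }
  # standardize so the sigma = 0.5 noise term has a fixed relative scale;
  # makes K exactly invariant to affine rescaling of the input
  x <- (x - mean(x)) / sd(x)
  ncut <- max(2L, floor(N / 10))
  cs <- runif(n_c, c_range[1], c_range[2])
  Kc <- numeric(n_c)
  j <- seq_len(N)
  ns <- seq_len(ncut)
  # mean over j of (p_{j+n}-p_j)^2 for all n at once, via the FFT-based
  # cross-sum ac(n) = sum_j p_j p_{j+n}
  nfft <- stats::nextn(2 * N)
  msd <- function(p) {
    S2 <- cumsum(p * p)
    pf <- stats::fft(c(p, numeric(nfft - N)))
    ac <- Re(stats::fft(pf * Conj(pf), inverse = TRUE))[ns + 1] / nfft
    (S2[N - ns] + S2[N] - S2[ns] - 2 * ac) / (N - ns)
  }
  for (ic in seq_len(n_c)) {
    cc <- cs[ic]
    p <- cumsum(x * cos(j * cc))
    q <- cumsum(x * sin(j * cc))
    eta <- runif(ncut, -0.5, 0.5)
    M <- msd(p) + msd(q) + sigma * eta
    Kc[ic] <- suppressWarnings(cor(ns, M))
  }
  Kc[is.na(Kc)] <- 0
  structure(list(K = median(Kc), K_c = Kc, c_values = cs, sigma = sigma,
                 degenerate = FALSE),
            class = "nc_k01")
}

#' @export
print.nc_k01 <- function(x, ...) {
  cat(sprintf("<nc_k01> K = %.3f (sigma = %g%s)\n", x$K, x$sigma,
              if (x$degenerate) ", degenerate input" else ""))
  invisible(x)
}

#' Band-pass and discretize a series for the 0-1 chaos test
#'
#' Zero-phase FIR band-pass between \code{lo} and \code{hi} Hz (filter order
#' chosen by the \code{fs/f_hi * atten/22} rule for the stated stop-band
#' attenuation, applied forward and backward), optionally preceded by
#' resampling to 500 Hz, followed by prominent-extrema discretization.
#'
#' @param x numeric series or an \code{nc_trial} (first channel used).
#' @param fs sample rate (Hz; ignored when \code{x} is a trial). Must be at
#'   least 200 Hz.
#' @param lo,hi pass band (Hz); default 1-13.
#' @param atten stop-band attenuation target (dB); default 85.
#' @param resample_to working rate applied before filtering when \code{fs}
#'   exceeds it; default 500 Hz (set NULL to skip).
#' @param prominence_fraction passed to [discretize_extrema()].
#' @return discretized extremum sequence.
#' @export
preprocess_for_chaos <- function(x, fs, lo = 1, hi = 13, atten = 85,
                                 resample_to = 500,
                                 prominence_fraction = 0.10) {
  if (inherits(x, "nc_trial")) { fs <- x$fs; x <- x$x[, 1] }
  if (fs < 200) stop("sample rate too low for the 1-13 Hz chaos band")
  if (!is.null(resample_to) && fs > resample_to) {
    x <- resample_series(x, fs, resample_to)
    fs <- resample_to
  }
  y <- bandpass_zero_phase(x - mean(x), fs, lo, hi, atten)
  discretize_extrema(y, prominence_fraction)
}

#' Median chaoticity across channels
#'
#' Median of per-channel K-statistics for one analysis window.
#'
#' @param channels list of numeric series (already preprocessed/discretized
#'   if \code{preprocess = FALSE}).
#' @param fs sample rate, required when \code{preprocess = TRUE}.
#' @param preprocess apply [preprocess_for_chaos()] per channel.
#' @param seed base seed; channel seeds are derived deterministically.
#' @param ... passed to [k_statistic()].
#' @return median K (attribute \code{degenerate} TRUE if every channel was).
#' @export
median_chaoticity <- function(channels, fs = NULL, preprocess = TRUE,
                              seed = 1, ...) {
  stopifnot(length(channels) >= 1)
  res <- lapply(seq_along(channels), function(i) {
    x <- channels[[i]]
    if (preprocess) x <- preprocess_for_chaos(x, fs)
    k_statistic(x, seed = seed + i - 1, ...)
  })
  deg <- vapply(res, `[[`, logical(1), "degenerate")
  Ks <- vapply(res, `[[`, numeric(1), "K")
  if (all(deg)) {
    return(structure(0, degenerate = TRUE))
  }
  structure(median(Ks[!deg]), degenerate = FALSE)
}

#' Least-squares Lyapunov-exponent fit to a divergence curve
#'
#' Fits the slope of \code{ln epsilon(t)} versus t from the perturbation
#' time to the first saturation crossing (epsilon > \code{saturation}).
#'
#' @param times times (s).
#' @param epsilon normalized squared divergence.
#' @param perturb_time time of the perturbation (s).
#' @param saturation saturation guard on epsilon; default 0.1.
#' @param min_window minimum usable fit window (s); default 0.5.
#' @return list: \code{Lambda} (s^-1), \code{fit_window}, \code{fit_r2}.
#' @export
fit_lle <- function(times, epsilon, perturb_time = 0, saturation = 0.1,
                    min_window = 0.5) {
  sel <- times >= perturb_time
  t <- times[sel]; e <- epsilon[sel]
  if (all(e == 0)) stop("perturbation below resolution: divergence is numerically zero")
  hit <- which(e > saturation)
  if (length(hit)) {
    # saturation guard, floored at min_window so strongly chaotic runs
    # (saturating almost immediately) still yield a conservative estimate
    end <- max(3, hit[1], which(t - t[1] >= min_window)[1])
    if (is.na(end)) end <- length(e)
    t <- t[seq_len(end)]; e <- e[seq_len(end)]
  } else {
    # decaying/neutral curves settle onto a plateau (phase-shift floor);
    # fit only the initial exponential segment
    nn <- length(e)
    plateau <- median(e[ceiling(0.8 * nn):nn])
    first <- e[seq_len(max(3, ceiling(0.05 * nn)))]
    if (median(first) > 4 * plateau) {
      reach <- which(e <= 2 * plateau)
      reach <- reach[reach > 3]
      if (length(reach)) {
        end <- max(reach[1], which(t - t[1] >= min_window)[1], na.rm = TRUE)
        t <- t[seq_len(end)]; e <- e[seq_len(end)]
      }
    }
  }
  pos <- e > 0
  if (sum(pos) < 3) stop("perturbation below resolution: divergence is numerically zero")
  t <- t[pos]; e <- e[pos]
  if (diff(range(t)) < min_window) {
    stop("usable divergence window shorter than ", min_window, " s")
  }
  fit <- lm(log(e) ~ t)
  r2 <- suppressWarnings(summary(fit)$r.squared)  # exact fits warn
  list(Lambda = unname(coef(fit)[2]),
       fit_window = range(t),
       fit_r2 = r2)
}

#' Stochastic largest Lyapunov exponent of the mean-field model
#'
#' Twin-run divergence estimate: the model is integrated twice with
#' identical noise streams and initial conditions; in the second run a tiny
#' random perturbation (uniform, scaled per potential by
#' \code{perturb_scale} times that potential's baseline standard deviation)
#' is added to every dendritic potential at \code{perturb_time}. The
#' normalized squared divergence of the cortical and thalamic relay LFPs
#' over the final window gives \code{Lambda} as the slope of
#' \code{ln epsilon} versus t (squared-distance convention: twice the
#' state-space exponent).
#'
#' @param config an \code{nc_config}.
#' @param perturb_time perturbation time (s); default \code{duration/2 - dt}.
#' @param duration total run length (s); default 20.
#' @param perturb_scale relative perturbation size; default 1e-6.
#' @param seed seed for noise, initial conditions, and the perturbation.
#' @param regions LFP pair over which divergence is measured.
#' @param ... passed to [fit_lle()].
#' @return list of class \code{nc_lle}: \code{Lambda}, \code{fit_window},
#'   \code{fit_r2}, divergence curve \code{epsilon}/\code{times}, and the
#'   unperturbed run as \code{sim}.
#' @export
stochastic_lle <- function(config, perturb_time = NULL, duration = 20,
                           perturb_scale = 1e-6, seed = 1,
                           regions = c("cortex_excitatory", "relay_nuclei"),
                           ...) {
  dt <- config$dt
  if (is.null(perturb_time)) perturb_time <- duration / 2 - dt
  nsteps <- round(duration / dt)
  P <- nrow(config$populations)
  set.seed(seed)
  noise <- matrix(rnorm((nsteps + 1) * P), nsteps + 1, P)

  run1 <- integrate_model(config, seed = seed, duration = duration,
                          noise = noise, init = "random")
  pre <- run1$t < perturb_time & run1$t > perturb_time / 2
  sd_V <- apply(run1$Vab[pre, , drop = FALSE], 2, sd)
  sd_Ve <- apply(run1$Vext[pre, , drop = FALSE], 2, sd)
  sd_V[sd_V == 0] <- mean(c(sd_V[sd_V > 0], 1e-9))
  sd_Ve[sd_Ve == 0] <- mean(c(sd_Ve[sd_Ve > 0], 1e-9))
  set.seed(seed + 31L)
  dV <- runif(ncol(run1$Vab), -1, 1) * perturb_scale * sd_V
  dVe <- runif(P, -1, 1) * perturb_scale * sd_Ve

  run2 <- integrate_model(config, seed = seed, duration = duration,
                          noise = noise, init = "random",
                          perturb = list(time = perturb_time, dV = dV,
                                         dVext = dVe))

  post <- run1$t >= perturb_time
  eps <- rep(0, sum(post))
  for (rg in regions) {
    l1 <- lfp(run1, rg)[post]
    l2 <- lfp(run2, rg)[post]
    emax <- (max(l1) - min(l2))^2
    if (emax == 0) emax <- 1
    eps <- eps + (l1 - l2)^2 / emax
  }
  eps <- eps / length(regions)
  if (all(eps == 0)) stop("perturbation below resolution: runs are identical")
  fit <- fit_lle(run1$t[post], eps, perturb_time = perturb_time, ...)
  structure(c(fit, list(epsilon = eps, times = run1$t[post],
                        perturb_time = perturb_time, sim = run1)),
            class = "nc_lle")
}

#' @export
print.nc_lle <- function(x, ...) {
  cat(sprintf("<nc_lle> Lambda = %.3f s^-1 (fit r2 = %.2f, window %.2f-%.2f s)\n",
              x$Lambda, x$fit_r2, x$fit_window[1], x$fit_window[2]))
  invisible(x)
}
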