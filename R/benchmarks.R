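# Synthetic generators with known ground truth for every estimator in the
# package: cross-frequency coupled pairs (for the spectral transfer-entropy
# path), canonical chaotic/periodic series (for the 0-1 test), and
# linear-Gaussian autoregressive pairs with closed-form transfer entropy.

#' Specification of a cross-frequency coupled pair
#'
#' @param fs sample rate (Hz); default 416.
#' @param duration length (s); default 10.
#' @param carrier_hz high-band carrier frequency (must lie in the level-2
#'   dyadic band, 52-104 Hz at 416 Hz); default 78.
#' @param slow_hz centre of the low-frequency drive band (1-13 Hz);
#'   default 6.
#' @param depth amplitude-modulation depth in [0, 1]; default 0.8.
#' @param delay sender-to-receiver delay (samples); default 10.
#' @param noise_sd additive broadband noise SD; default 0.2.
#' @param seed seed.
#' @return list of class \code{nc_coupled_spec}.
#' @export
coupled_band_spec <- function(fs = 416, duration = 10, carrier_hz = 78,
                              slow_hz = 6, depth = 0.8, delay = 10,
                              noise_sd = 0.2, seed = 1) {
  stopifnot(depth >= 0, depth <= 1,
            carrier_hz > fs / 8, carrier_hz <= fs / 4,  # level 2 band
            slow_hz >= 1, slow_hz <= 13)
  structure(list(fs = fs, duration = duration, carrier_hz = carrier_hz,
                 slow_hz = slow_hz, depth = depth, delay = delay,
                 noise_sd = noise_sd, seed = seed),
            class = "nc_coupled_spec")
}

#' Generate a pair with directed low-to-high cross-frequency coupling
#'
#' The sender X carries a narrowband stochastic low-frequency drive plus
#' broadband noise. The receiver Y carries a high-band carrier whose
#' amplitude is modulated by the delayed drive, plus an independent
#' low-frequency component and noise. Ground truth: directed X -> Y coupling
#' only, from the low band into the high band, at the given delay.
#'
#' @param spec a [coupled_band_spec()].
#' @return list: \code{X}, \code{Y}, and \code{ground_truth} (sidecar with
#'   direction, bands and delay).
#' @export
gen_coupled_pair <- function(spec) {
  set.seed(spec$seed)
  n <- round(spec$fs * spec$duration)
  pad <- spec$delay
  # narrowband stochastic slow drive (so the past of X is informative)
  slow_raw <- rnorm(n + pad)
  bw <- c(max(1, spec$slow_hz - 3), min(13, spec$slow_hz + 3))
  slow <- bandpass_zero_phase(slow_raw, spec$fs, bw[1], bw[2])
  slow <- slow / sd(slow)
  slow_x <- slow[(pad + 1):(pad + n)]
  slow_lag <- slow[(pad + 1 - spec$delay):(pad + n - spec$delay)]
  tt <- seq_len(n) / spec$fs
  carrier <- sin(2 * pi * spec$carrier_hz * tt + runif(1, 0, 2 * pi))
  slow2 <- bandpass_zero_phase(rnorm(n), spec$fs, bw[1], bw[2])
  slow2 <- slow2 / sd(slow2)
  X <- slow_x + spec$noise_sd * rnorm(n)
  Y <- (1 + spec$depth * slow_lag) * carrier + 0.5 * slow2 +
    spec$noise_sd * rnorm(n)
  list(X = X, Y = Y,
       ground_truth = list(direction = "X->Y",
                           send_band_hz = bw,
                           recv_band_hz = modwt_band_hz(2, spec$fs),
                           send_levels = 5:8, recv_levels = 2,
                           delay = spec$delay, depth = spec$depth,
                           seed = spec$seed))
}

#' Labeled series suite for chaos-test validation
#'
#' Logistic maps in the periodic (r = 3.2) and chaotic (r = 3.99, 4.0)
#' regimes, a noisy sine, and Gaussian white noise, each with its
#' ground-truth dynamical class.
#'
#' @param seed seed.
#' @param n points per series; default 5000.
#' @return named list of lists \code{(x, label)} with labels in
#'   \code{c("periodic", "chaotic", "stochastic")}.
#' @export
gen_chaos_suite <- function(seed = 1, n = 5000) {
  set.seed(seed)
  logistic <- function(r, x0 = 0.391) {
    x <- numeric(n + 100)
    x[1] <- x0
    for (i in seq_len(n + 99)) x[i + 1] <- r * x[i] * (1 - x[i])
    x[101:(n + 100)]
  }
  tt <- seq_len(n)
  list(
    logistic_r3.2 = list(x = logistic(3.2), label = "periodic"),
    logistic_r3.99 = list(x = logistic(3.99), label = "chaotic"),
    logistic_r4.0 = list(x = logistic(4.0), label = "chaotic"),
    noisy_sine = list(x = sin(2 * pi * tt / 40) + 0.1 * rnorm(n),
                      label = "periodic"),
    white_noise = list(x = rnorm(n), label = "stochastic"))
}

#' Bivariate linear-Gaussian autoregressive pair with closed-form TE
#'
#' \code{X_t = a X_{t-1} + e_x}, \code{Y_t = b Y_{t-1} + c X_{t-1} + e_y}
#' with unit-variance Gaussian innovations. The analytic transfer entropy
#' (k = l = u = 1) equals half the log ratio of restricted to full
#' prediction-residual variance; it is computed here by an internal
#' regression oracle on the generated sample, independent of the kNN path.
#'
#' @param coeffs list with \code{a}, \code{b}, \code{c}; spectral radius of
#'   the implied system must be < 1.
#' @param n series length; default 5000.
#' @param seed seed.
#' @return list: \code{X}, \code{Y}, \code{te_xy}, \code{te_yx} (nats, from
#'   the regression oracle), \code{ground_truth} sidecar.
#' @export
gen_var_pair <- function(coeffs = list(a = 0.5, b = 0.5, c = 0.4), n = 5000,
                         seed = 1) {
  A <- matrix(c(coeffs$a, coeffs$c, 0, coeffs$b), 2, 2)
  if (max(abs(eigen(A, only.values = TRUE)$values)) >= 1) {
    stop("unstable coefficients: spectral radius >= 1")
  }
  set.seed(seed)
  burn <- 200
  X <- numeric(n + burn); Y <- numeric(n + burn)
  ex <- rnorm(n + burn); ey <- rnorm(n + burn)
  for (t in 2:(n + burn)) {
    X[t] <- coeffs$a * X[t - 1] + ex[t]
    Y[t] <- coeffs$b * Y[t - 1] + coeffs$c * X[t - 1] + ey[t]
  }
  X <- X[(burn + 1):(burn + n)]; Y <- Y[(burn + 1):(burn + n)]
  gaussian_te <- function(src, tgt) {
    t2 <- 2:length(tgt)
    full <- lm(tgt[t2] ~ tgt[t2 - 1] + src[t2 - 1])
    restr <- lm(tgt[t2] ~ tgt[t2 - 1])
    0.5 * log(mean(residuals(restr)^2) / mean(residuals(full)^2))
  }
  list(X = X, Y = Y,
       te_xy = gaussian_te(X, Y), te_yx = gaussian_te(Y, X),
       ground_truth = list(coeffs = coeffs, n = n, seed = seed,
                           coupled_direction = if (coeffs$c != 0) "X->Y" else "none"))
}
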