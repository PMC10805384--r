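# Group-level statistics and control analyses: exact one-tailed signed-rank
# tests, subject-level binomial tests, phase-amplitude Modulation Index,
# Lempel-Ziv complexity, bi-symmetric log transform, permutation ANCOVA,
# baseline normalization.

#' Exact one-tailed Wilcoxon signed-rank test for paired samples
#'
#' Exact enumeration of the signed-rank null (via the \code{psignrank}
#' distribution) for n up to 25 without ties; mid-ranks with a normal
#' approximation (and a warning) when absolute differences tie. Zero
#' differences are dropped; all-zero input is an error.
#'
#' @param baseline,condition paired numeric vectors (by subject).
#' @param alternative \code{"less"}: condition < baseline;
#'   \code{"greater"}: condition > baseline.
#' @return list: \code{p}, \code{statistic} (rank sum of positive
#'   differences), \code{n} (non-zero pairs), \code{exact}.
#' @export
wilcoxon_one_tailed <- function(baseline, condition,
                                alternative = c("less", "greater")) {
  alternative <- match.arg(alternative)
  stopifnot(length(baseline) == length(condition))
  d <- condition - baseline
  d <- d[d != 0]
  n <- length(d)
  if (n == 0) stop("all paired differences are zero")
  if (n < 5) warning("fewer than 5 non-zero pairs; test has little power")
  r <- rank(abs(d))
  V <- sum(r[d > 0])
  ties <- anyDuplicated(abs(d)) > 0
  exact <- !ties && n <= 25
  if (exact) {
    p <- if (alternative == "less") stats::psignrank(V, n)
         else stats::psignrank(V - 1, n, lower.tail = FALSE)
  } else {
    warning("ties in |differences|: using mid-ranks with a normal approximation")
    mu <- n * (n + 1) / 4
    tie_tab <- table(r)
    sig2 <- n * (n + 1) * (2 * n + 1) / 24 -
      sum(tie_tab^3 - tie_tab) / 48
    z <- (V - mu + if (alternative == "less") 0.5 else -0.5) / sqrt(sig2)
    p <- if (alternative == "less") stats::pnorm(z)
         else stats::pnorm(z, lower.tail = FALSE)
  }
  list(p = p, statistic = V, n = n, exact = exact)
}

#' Presentation rounding of a p-value
#'
#' Round-half-even at 4 decimals (so 0.03125 prints as 0.0312 and 0.00195
#' as 0.002).
#'
#' @param p p-value.
#' @param digits decimals; default 4.
#' @return rounded p.
#' @export
present_p <- function(p, digits = 4) round(p, digits)

#' One-sided binomial test across subjects
#'
#' Probability of observing at least \code{successes} significant subjects
#' out of \code{n} when each is significant with probability \code{p0}.
#'
#' @param successes number of significant subjects.
#' @param n subjects.
#' @param p0 null per-subject success probability; default 0.05.
#' @return one-sided p-value P(X >= successes).
#' @export
binomial_subjects <- function(successes, n, p0 = 0.05) {
  stopifnot(successes >= 0, successes <= n)
  if (successes == 0) return(1)
  stats::pbinom(successes - 1, n, p0, lower.tail = FALSE)
}

#' Phase-amplitude Modulation Index
#'
#' Entropy-based (Tort) coupling between the phase of a slow band in one
#' series and the amplitude envelope of a fast band in another: both series
#' are zero-phase band-pass filtered, phase and envelope extracted from the
#' analytic signal, mean envelope computed per phase bin, and the Modulation
#' Index taken as the normalized Kullback-Leibler divergence of that
#' distribution from uniform: \code{(ln n_bins - H) / ln n_bins} in [0, 1].
#'
#' @param phase_src series providing the low-frequency phase.
#' @param amp_src series providing the high-frequency amplitude.
#' @param fs sample rate (Hz).
#' @param phase_band low band (Hz); default c(1, 13).
#' @param amp_band high band (Hz); default c(52, 104).
#' @param n_bins phase bins; default 18.
#' @return Modulation Index; attribute \code{degenerate} TRUE when the
#'   envelope is identically zero.
#' @export
modulation_index <- function(phase_src, amp_src, fs,
                             phase_band = c(1, 13), amp_band = c(52, 104),
                             n_bins = 18) {
  stopifnot(length(phase_src) == length(amp_src), fs > 2 * amp_band[2])
  ph <- Arg(analytic_signal(
    bandpass_zero_phase(phase_src - mean(phase_src), fs,
                        phase_band[1], phase_band[2])))
  am <- Mod(analytic_signal(
    bandpass_zero_phase(amp_src - mean(amp_src), fs,
                        amp_band[1], amp_band[2])))
  if (all(am == 0)) return(structure(0, degenerate = TRUE))
  bins <- cut(ph, breaks = seq(-pi, pi, length.out = n_bins + 1),
              include.lowest = TRUE)
  m <- tapply(am, bins, mean)
  m[is.na(m)] <- 0
  P <- m / sum(m)
  H <- -sum(P[P > 0] * log(P[P > 0]))
  structure((log(n_bins) - H) / log(n_bins), degenerate = FALSE)
}

#' Normalized Lempel-Ziv complexity
#'
#' Binarizes the series at its median and counts LZ76 phrases, normalized
#' by \code{n / log2(n)} so white noise scores near 1.
#'
#' @param x numeric series (length >= 100) or a logical/0-1 vector.
#' @return normalized complexity; attribute \code{degenerate} TRUE for
#'   constant input.
#' @export
lempel_ziv <- function(x) {
  if (is.numeric(x) && !all(x %in% c(0, 1))) {
    if (sd(x) == 0) return(structure(0, degenerate = TRUE))
    x <- as.integer(x > median(x))
  }
  s <- as.integer(x)
  n <- length(s)
  if (length(unique(s)) == 1) return(structure(0, degenerate = TRUE))
  # LZ76 phrase counting (Kaspar & Schuster)
  c_n <- 1L
  l <- 1L; i <- 0L; k <- 1L; kmax <- 1L
  repeat {
    if (s[i + k] == s[l + k]) {
      k <- k + 1L
      if (l + k > n) { c_n <- c_n + 1L; break }
    } else {
      if (k > kmax) kmax <- k
      i <- i + 1L
      if (i == l) {
        c_n <- c_n + 1L
        l <- l + kmax
        if (l + 1 > n) break
        i <- 0L; k <- 1L; kmax <- 1L
      } else {
        k <- 1L
      }
    }
  }
  structure(c_n * log2(n) / n, degenerate = FALSE)
}

#' Bi-symmetric log transform
#'
#' \code{sign(x) * log10(1 + |x|/C)}: odd, monotone, linear near zero and
#' logarithmic in both tails; useful for visualizing signed quantities that
#' span orders of magnitude.
#'
#' @param x numeric.
#' @param C scale constant (> 0); default 1.
#' @return transformed values.
#' @export
bisymlog <- function(x, C = 1) {
  stopifnot(C > 0)
  sign(x) * log10(1 + abs(x) / C)
}

#' Permutation ANCOVA (Freedman-Lane)
#'
#' Tests a state (group) effect on \code{values} controlling for numeric
#' covariates. The observed F-statistic for the state factor comes from the
#' linear model \code{values ~ covariates + state}; the null distribution is
#' built by permuting residuals of the covariates-only model and adding them
#' back to its fitted values (Freedman-Lane scheme).
#'
#' @param values numeric response.
#' @param state_labels factor of state labels (>= 2 levels).
#' @param covariates numeric vector, matrix or data.frame of covariates.
#' @param n_perm permutations; default 10000.
#' @param seed seed.
#' @return list: \code{p}, \code{F_obs}, \code{n_perm}.
#' @export
perm_ancova <- function(values, state_labels, covariates, n_perm = 10000,
                        seed = 1) {
  state_labels <- factor(state_labels)
  stopifnot(nlevels(state_labels) >= 2)
  X0 <- cbind(1, as.matrix(covariates))
  Xs <- stats::model.matrix(~state_labels)[, -1, drop = FALSE]
  X1 <- cbind(X0, Xs)
  if (qr(X1)$rank < ncol(X1)) stop("rank-deficient design")
  n <- length(values)
  f_state <- function(y) {
    rss0 <- sum(stats::lm.fit(X0, y)$residuals^2)
    fit1 <- stats::lm.fit(X1, y)
    rss1 <- sum(fit1$residuals^2)
    df1 <- ncol(Xs)
    df2 <- n - ncol(X1)
    ((rss0 - rss1) / df1) / (rss1 / df2)
  }
  F_obs <- f_state(values)
  fit0 <- stats::lm.fit(X0, values)
  res0 <- fit0$residuals
  yhat0 <- fit0$fitted.values
  set.seed(seed)
  exceed <- 0L
  for (b in seq_len(n_perm)) {
    ystar <- yhat0 + res0[sample.int(n)]
    if (f_state(ystar) >= F_obs) exceed <- exceed + 1L
  }
  list(p = (1 + exceed) / (1 + n_perm), F_obs = F_obs, n_perm = n_perm)
}

#' Normalize per-subject values to a waking baseline
#'
#' @param values numeric values for one subject.
#' @param baseline that subject's waking-state median (nonzero).
#' @return values / baseline.
#' @export
normalize_to_baseline <- function(values, baseline) {
  if (baseline == 0) stop("zero baseline")
  values / baseline
}
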