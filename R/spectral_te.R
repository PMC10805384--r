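# Spectrally resolved directed information transfer: Kraskov kNN transfer
# entropy combined with MODWT band decomposition and IAAFT band-restricted
# surrogates (swap-out-swap-out testing).

#' Embedding specification for transfer entropy
#'
#' @param k target history length (>= 1).
#' @param l source history length (>= 1).
#' @param u source-target delay in samples (>= 1).
#' @return list of class \code{nc_embedding}.
#' @export
embedding_spec <- function(k = 1, l = 1, u = 1) {
  stopifnot(k >= 1, l >= 1, u >= 1)
  structure(list(k = k, l = l, u = u), class = "nc_embedding")
}

# build (Y_t, X_{t-u}^{(l)}, Y_{t-1}^{(k)}) design for the CMI form
te_design <- function(x, y, emb) {
  n <- length(y)
  t0 <- max(emb$k + 1, emb$u + emb$l)
  tt <- t0:n
  yt <- y[tt]
  yp <- vapply(seq_len(emb$k), function(i) y[tt - i], numeric(length(tt)))
  xp <- vapply(seq_len(emb$l), function(i) x[tt - emb$u - (i - 1)],
               numeric(length(tt)))
  list(y = yt, xp = matrix(xp, ncol = emb$l), yp = matrix(yp, ncol = emb$k))
}

#' Kraskov nearest-neighbour transfer entropy
#'
#' Transfer entropy from X to Y as the conditional mutual information
#' I(Y_t ; X_{t-u}^{(l)} | Y_{t-1}^{(k)}), estimated with the
#' Kraskov-Stoegbauer-Grassberger nearest-neighbour method (Chebyshev-ball
#' neighbour counting with Kozachenko-Leonenko log-probability estimates).
#' Inputs are standardized and a tiny seeded jitter (1e-10 of the standard
#' deviation) breaks kNN ties deterministically.
#'
#' @param x source series.
#' @param y target series (same length).
#' @param emb an [embedding_spec()].
#' @param knn number of nearest neighbours K; default 4.
#' @param seed seed for the tie-breaking jitter.
#' @param max_centers cap on the number of embedding vectors over which the
#'   log-probability average runs (evenly spaced subset; neighbour counting
#'   always uses every point). Inf gives the full estimator.
#' @return transfer entropy in nats (may be slightly negative at the
#'   estimator's noise floor).
#' @export
kraskov_te <- function(x, y, emb = embedding_spec(), knn = 4, seed = 1,
                       max_centers = Inf) {
  stopifnot(length(x) == length(y), all(is.finite(x)), all(is.finite(y)))
  if (length(y) < emb$k + emb$u + 10) stop("series too short for embedding")
  sx <- sd(x); sy <- sd(y)
  x <- if (sx > 0) (x - mean(x)) / sx else x - mean(x)
  y <- if (sy > 0) (y - mean(y)) / sy else y - mean(y)
  if (!is.null(seed)) set.seed(seed)
  x <- x + rnorm(length(x)) * 1e-10
  y <- y + rnorm(length(y)) * 1e-10
  d <- te_design(x, y, emb)
  n <- length(d$y)
  centers <- if (is.finite(max_centers) && n > max_centers) {
    as.integer(round(seq(1, n, length.out = max_centers))) - 1L
  } else {
    seq_len(n) - 1L
  }
  knn_cmi_cpp(d$y, d$xp, d$yp, as.integer(knn), centers)
}

#' Convert nats to bits
#' @param nats value in nats.
#' @return value in bits.
#' @export
nats_to_bits <- function(nats) nats / log(2)

#' Select a transfer-entropy embedding
#'
#' History lengths are chosen by the Ragwitz criterion: the candidate
#' (1..\code{max_hist}) minimizing the mean squared error of a zeroth-order
#' (kNN-average) local predictor of the next value from the embedded past,
#' per series. The interaction delay u is then chosen in
#' 1..\code{max_delay} samples to maximize the estimated transfer entropy.
#'
#' @param x source series.
#' @param y target series.
#' @param max_hist largest history length considered; default 5.
#' @param max_delay largest delay considered (samples); default 20.
#' @param knn neighbours for prediction and TE; default 4.
#' @param seed jitter seed.
#' @param n_max cap on points used during selection (subsampled head);
#'   default 2000.
#' @param max_centers passed to [kraskov_te()].
#' @return an [embedding_spec()].
#' @export
select_embedding <- function(x, y, max_hist = 5, max_delay = 20, knn = 4,
                             seed = 1, n_max = 2000, max_centers = Inf) {
  nx <- min(length(x), n_max)
  xs <- x[seq_len(nx)]; ys <- y[seq_len(nx)]
  std <- function(v) if (sd(v) > 0) (v - mean(v)) / sd(v) else v - mean(v)
  xs <- std(xs); ys <- std(ys)
  ragwitz <- function(v) {
    mse <- vapply(seq_len(max_hist), function(m) {
      tt <- (m + 1):length(v)
      z <- vapply(seq_len(m), function(i) v[tt - i], numeric(length(tt)))
      knn_predict_mse_cpp(v[tt], matrix(z, ncol = m), as.integer(knn))
    }, numeric(1))
    which.min(mse)
  }
  k <- ragwitz(ys)
  l <- ragwitz(xs)
  te_u <- vapply(seq_len(max_delay), function(u) {
    kraskov_te(xs, ys, embedding_spec(k, l, u), knn = knn, seed = seed,
               max_centers = max_centers)
  }, numeric(1))
  embedding_spec(k, l, which.max(te_u))
}

#' Swap-out-swap-out band-pair significance test
#'
#' Estimates how much transfer entropy from X to Y is carried by a specific
#' (sending band, receiving band) pair. The original transfer entropy is
#' compared with surrogates in which the sender's send-band and the
#' receiver's receive-band wavelet coefficients are simultaneously
#' IAAFT-randomized; the strength is the mean transfer-entropy loss and the
#' p-value the add-one-corrected fraction of surrogates at or above the
#' original.
#'
#' @param x sender series at the working rate.
#' @param y receiver series at the working rate.
#' @param bp a [band_pair()].
#' @param n_surr surrogate count; default 100 (values below 20 warn:
#'   exploratory mode).
#' @param max_centers passed to [kraskov_te()].
#' @param seed seed; the embedding jitter and all surrogate streams derive
#'   from it.
#' @param emb optional [embedding_spec()]; selected on the original pair
#'   when NULL and then held fixed across surrogates.
#' @param knn neighbours; default 4.
#' @return list of class \code{nc_ste}: \code{te_original} (nats),
#'   \code{te_surrogates}, \code{strength} (nats), \code{p}, \code{n_surr},
#'   \code{embedding}, \code{band_pair}, \code{seed}.
#' @export
soso_test <- function(x, y, bp, n_surr = 100, seed = 1, emb = NULL,
                      knn = 4, max_centers = Inf) {
  stopifnot(length(x) == length(y))
  if (n_surr < 20) warning("fewer than 20 surrogates: exploratory mode")
  if (is.null(emb)) emb <- select_embedding(x, y, knn = knn, seed = seed,
                                            max_centers = max_centers)
  te0 <- kraskov_te(x, y, emb, knn = knn, seed = seed,
                    max_centers = max_centers)
  tes <- vapply(seq_len(n_surr), function(i) {
    xs <- band_swap_surrogate(x, bp$send_levels, seed = seed + 13L * i,
                              J = bp$J)
    ys <- band_swap_surrogate(y, bp$recv_levels, seed = seed + 13L * i + 7L,
                              J = bp$J)
    kraskov_te(xs, ys, emb, knn = knn, seed = seed,
               max_centers = max_centers)
  }, numeric(1))
  p <- (1 + sum(tes >= te0)) / (1 + n_surr)
  structure(list(te_original = te0, te_surrogates = tes,
                 strength = te0 - mean(tes), p = p, n_surr = n_surr,
                 embedding = emb, band_pair = bp, seed = seed),
            class = "nc_ste")
}

#' @export
print.nc_ste <- function(x, ...) {
  cat(sprintf(
    "<nc_ste> TE = %.4f nats (%.4f bits), strength = %.4f nats, p = %.4f (%d surrogates)\n",
    x$te_original, nats_to_bits(x$te_original), x$strength, x$p, x$n_surr))
  invisible(x)
}

#' Exploratory sweep over all band pairs
#'
#' Information-transfer strength for every (send level, receive level) pair
#' with a reduced surrogate count, z-scored across the matrix.
#'
#' @param x sender series.
#' @param y receiver series.
#' @param n_surr surrogates per pair; default 5 (exploratory).
#' @param J decomposition depth; default 8.
#' @param seed seed.
#' @param emb optional fixed embedding (selected once on the original pair
#'   when NULL).
#' @param fs working rate for band labels; default 416.
#' @return J x J matrix (rows = send level, cols = receive level) of
#'   z-scored strengths; raw strengths in attribute \code{raw}.
#' @export
spectral_sweep <- function(x, y, n_surr = 5, J = 8, seed = 1, emb = NULL,
                           fs = 416) {
  if (is.null(emb)) emb <- select_embedding(x, y, seed = seed)
  raw <- matrix(NA_real_, J, J,
                dimnames = list(send = paste0("L", seq_len(J)),
                                recv = paste0("L", seq_len(J))))
  for (s in seq_len(J)) {
    for (r in seq_len(J)) {
      bp <- band_pair(s, r, fs = fs, J = J)
      res <- suppressWarnings(
        soso_test(x, y, bp, n_surr = n_surr,
                  seed = seed + 101L * s + 977L * r, emb = emb))
      raw[s, r] <- res$strength
    }
  }
  z <- (raw - mean(raw)) / sd(raw)
  attr(z, "raw") <- raw
  z
}

#' Harmonic mean of dependent p-values
#'
#' \code{p = n / sum(1/p_i)}; lies between the minimum and maximum of the
#' inputs and is valid under dependence.
#'
#' @param ps p-values in (0, 1].
#' @return harmonic mean p-value.
#' @export
harmonic_mean_p <- function(ps) {
  if (any(ps <= 0)) stop("p-values must be strictly positive")
  stopifnot(all(ps <= 1))
  length(ps) / sum(1 / ps)
}
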