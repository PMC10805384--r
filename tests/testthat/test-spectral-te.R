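test_that("MODWT is exactly invertible and places dyadic bands", {
  set.seed(1)
  x <- rnorm(4160)
  d <- modwt(x, J = 8)
  expect_lt(max(abs(imodwt(d) - x)), 1e-8 * diff(range(x)))
  expect_equal(modwt_band_hz(2, 416), c(52, 104))
  expect_equal(modwt_band_hz(5, 416)[2], 13)
  expect_equal(modwt_band_hz(8, 416)[1], 0.8125)
  # a 78 Hz tone concentrates in level 2; a 5 Hz tone in levels 5-8
  tt <- seq_len(4160) / 416
  en <- colSums(modwt(sin(2 * pi * 78 * tt), 8)$W^2)
  expect_equal(unname(which.max(en)), 2)
  expect_gt(en[2] / sum(en), 0.7)
  d5 <- modwt(sin(2 * pi * 5 * tt), 8)
  en5 <- colSums(d5$W^2)
  expect_gt(sum(en5[5:8]) / (sum(en5) + sum(d5$V^2)), 0.95)
  expect_error(modwt(rnorm(100), 8), "shorter")
})

test_that("IAAFT surrogates keep the amplitude multiset and spectrum", {
  set.seed(2)
  x <- as.numeric(stats::arima.sim(list(ar = 0.9), 4160))
  s <- iaaft_surrogate(x, seed = 7)
  expect_identical(sort(as.numeric(s)), sort(x))
  amp <- Mod(stats::fft(x))
  amps <- Mod(stats::fft(as.numeric(s)))
  expect_lt(sqrt(mean((amps - amp)^2)) / sqrt(mean(amp^2)), 0.02)
  expect_identical(as.numeric(iaaft_surrogate(x, seed = 7)), as.numeric(s))
  expect_false(identical(as.numeric(iaaft_surrogate(x, seed = 8)),
                         as.numeric(s)))
})

test_that("band-swap surrogates randomize only the chosen levels", {
  set.seed(3)
  tt <- seq_len(4160) / 416
  # broadband high component (a pure tone would only admit a phase shift)
  hi_noise <- neurocrit:::bandpass_zero_phase(rnorm(4160), 416, 55, 100)
  x <- 2 * hi_noise / sd(hi_noise) + sin(2 * pi * 5 * tt) + 0.1 * rnorm(4160)
  expect_identical(band_swap_surrogate(x, integer(0), seed = 1), x)
  s <- band_swap_surrogate(x, 2, seed = 1)
  # slow content untouched
  lo <- function(v) neurocrit:::bandpass_zero_phase(v, 416, 2, 10)
  expect_gt(cor(lo(x), lo(s)), 0.99)
  # high band decorrelated
  hi <- function(v) neurocrit:::bandpass_zero_phase(v, 416, 55, 100)
  expect_lt(abs(cor(hi(x), hi(s))), 0.3)
  # energy preservation: tonal components centred within single levels keep
  # the series variance within 5% (coherent straddling of level boundaries
  # can shed more - a documented wavelet-leakage property)
  xt <- sin(2 * pi * 78 * tt) + sin(2 * pi * 5 * tt) + 0.1 * rnorm(4160)
  st <- band_swap_surrogate(xt, 2, seed = 2)
  expect_lt(abs(var(st) / var(xt) - 1), 0.05)
})

test_that("Kraskov TE is near zero for independent series", {
  set.seed(9)
  x <- rnorm(10000); y <- rnorm(10000)
  expect_lt(abs(kraskov_te(x, y, embedding_spec(1, 1, 1))), 0.01)
  # estimator bias bounded in expectation over seeds
  tes <- vapply(1:20, function(s) {
    set.seed(s)
    kraskov_te(rnorm(1500), rnorm(1500), embedding_spec(1, 1, 1), seed = s)
  }, numeric(1))
  expect_gt(mean(tes), -0.005)
  expect_lt(mean(tes), 0.02)
})

test_that("Kraskov TE detects delayed coupling at the right lag", {
  set.seed(4)
  n <- 4000
  x <- as.numeric(stats::arima.sim(list(ar = 0.8), n + 5))
  y <- x[1:n] + 0.1 * rnorm(n)
  x5 <- x[6:(n + 5)]  # y leads by 5 in x5 time: TE x->y max at u = 5
  te5 <- kraskov_te(x5, y, embedding_spec(1, 1, 5))
  te1 <- kraskov_te(x5, y, embedding_spec(1, 1, 1))
  expect_gt(te5, 0.5)
  expect_gt(te5, te1)
})

test_that("Kraskov TE matches the linear-Gaussian closed form", {
  tes <- numeric(10); ana <- numeric(10)
  for (s in 1:10) {
    vp <- gen_var_pair(n = 2000, seed = s)
    tes[s] <- kraskov_te(vp$X, vp$Y, embedding_spec(1, 1, 1), seed = s)
    ana[s] <- vp$te_xy
  }
  expect_lt(abs(mean(tes) - mean(ana)), 3 * sd(tes))
  # uncoupled direction stays at the noise floor
  vp <- gen_var_pair(n = 3000, seed = 99)
  expect_lt(abs(kraskov_te(vp$Y, vp$X, embedding_spec(1, 1, 1))), 0.02)
  expect_lt(abs(vp$te_yx), 0.005)
})

test_that("embedding selection recovers a known delay and short histories", {
  set.seed(5)
  n <- 2000
  x <- as.numeric(stats::arima.sim(list(ar = 0.9), n + 7))
  y <- c(rep(0, 7), x[1:(n - 7)]) + 0.05 * rnorm(n)
  emb <- select_embedding(x[1:n], y)
  expect_equal(emb$u, 7, tolerance = 0)
  expect_lte(emb$k, 3)
  expect_lte(emb$l, 3)
})

test_that("SOSO surrogate test honors its p-value floor and identity swap", {
  set.seed(6)
  cp <- gen_coupled_pair(coupled_band_spec(duration = 5, seed = 6))
  bp0 <- band_pair(integer(0), integer(0))
  r0 <- suppressWarnings(soso_test(cp$X, cp$Y, bp0, n_surr = 5, seed = 1,
                                   emb = embedding_spec(1, 1, 1)))
  expect_equal(r0$strength, 0)
  expect_equal(r0$p, 1)
  # independent signals: p bounded below by the add-one floor
  xi <- rnorm(2080); yi <- rnorm(2080)
  ri <- suppressWarnings(soso_test(xi, yi, band_pair(5:8, 2), n_surr = 10,
                                   seed = 2, emb = embedding_spec(1, 1, 1)))
  expect_gte(ri$p, 1 / 11)
  expect_warning(soso_test(xi[1:512], yi[1:512], bp0, n_surr = 5, seed = 1,
                           emb = embedding_spec(1, 1, 1)),
                 "exploratory")
})

test_that("SOSO recovers ground-truth cross-frequency coupling", {
  hits <- 0; controls_ok <- 0
  nseed <- 4
  for (s in seq_len(nseed)) {
    cp <- gen_coupled_pair(coupled_band_spec(duration = 8, depth = 0.9,
                                             seed = 100 + s))
    emb <- embedding_spec(1, 1, cp$ground_truth$delay)
    r_true <- suppressWarnings(
      soso_test(cp$X, cp$Y, band_pair(5:8, 2), n_surr = 24,
                seed = s, emb = emb, max_centers = 1200))
    r_ctrl <- suppressWarnings(
      soso_test(cp$X, cp$Y, band_pair(2, 5:8), n_surr = 24,
                seed = s, emb = emb, max_centers = 1200))
    if (r_true$p < 0.05) hits <- hits + 1
    if (r_ctrl$p > 0.05) controls_ok <- controls_ok + 1
  }
  expect_gte(hits, nseed - 1)
  expect_gte(controls_ok, nseed - 1)
})

test_that("exploratory sweep is z-scored with the true cell prominent", {
  cp <- gen_coupled_pair(coupled_band_spec(duration = 5, depth = 0.9,
                                           seed = 11))
  z <- spectral_sweep(cp$X, cp$Y, n_surr = 2, J = 8, seed = 3,
                      emb = embedding_spec(1, 1, cp$ground_truth$delay))
  expect_equal(dim(z), c(8, 8))
  expect_equal(mean(z), 0, tolerance = 1e-10)
  expect_equal(sd(z), 1, tolerance = 1e-10)
  # the ground-truth receive band (level 2) carries a top-quartile cell
  best <- which(z == max(z), arr.ind = TRUE)
  expect_equal(unname(best[1, "recv"]), 2)
})

test_that("harmonic mean p-value is bounded, idempotent, and exact", {
  expect_equal(harmonic_mean_p(rep(0.0099, 5)), 0.0099)
  expect_equal(harmonic_mean_p(c(0.01, 0.1)), 2 / 110)
  expect_equal(round(harmonic_mean_p(c(0.01, 0.1)), 4), 0.0182)
  ps <- c(0.2, 0.03, 0.5)
  expect_equal(harmonic_mean_p(ps), harmonic_mean_p(rev(ps)))
  expect_gte(harmonic_mean_p(ps), min(ps))
  expect_lte(harmonic_mean_p(ps), max(ps))
  expect_error(harmonic_mean_p(c(0.1, 0)), "positive")
})
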