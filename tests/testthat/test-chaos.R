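test_that("extrema discretization keeps prominent alternating extrema", {
  tt <- seq(0, 12, by = 1 / 200)
  x <- sin(2 * pi * tt)
  e <- discretize_extrema(x)
  expect_true(all(abs(abs(e) - 1) < 1e-3))
  # strict alternation of maxima and minima
  expect_true(all(abs(diff(sign(e))) == 2))
  expect_error(discretize_extrema(seq_len(100) / 100), "insufficient extrema")
  # small ripple rides on the carrier: its extrema fail the 10% rule
  ripple <- sin(2 * pi * tt) + 0.05 * sin(2 * pi * 13 * tt)
  er <- discretize_extrema(ripple)
  expect_equal(length(er), length(e))
})

test_that("K-statistic separates chaotic from periodic dynamics", {
  suite <- gen_chaos_suite(seed = 1)
  K <- vapply(suite, function(s) k_statistic(s$x, seed = 42)$K, numeric(1))
  expect_gt(K[["logistic_r4.0"]], 0.9)
  expect_lt(K[["logistic_r3.2"]], 0.1)
  expect_gt(K[["logistic_r4.0"]] - K[["logistic_r3.2"]], 0.5)
  # chaotic > noisy periodic > pure periodic
  expect_gt(K[["logistic_r4.0"]], K[["noisy_sine"]])
  expect_gt(K[["noisy_sine"]], K[["logistic_r3.2"]])
})

test_that("K-statistic handles degenerate input and is affine invariant", {
  r <- k_statistic(rep(0, 500), seed = 1)
  expect_equal(r$K, 0)
  expect_true(r$degenerate)
  x <- gen_chaos_suite(seed = 2, n = 2000)$logistic_r3.99$x
  expect_identical(k_statistic(x, seed = 5)$K,
                   k_statistic(3 * x - 7, seed = 5)$K)
  expect_equal(length(k_statistic(x, seed = 1)$K_c), 100)
})

test_that("chaos preprocessing band-passes 1-13 Hz before discretizing", {
  fs <- 500
  tt <- seq_len(10 * fs) / fs
  # 8 Hz passband content survives with amplitude >= 0.9
  e8 <- preprocess_for_chaos(sin(2 * pi * 8 * tt), fs)
  expect_gte(median(abs(e8)), 0.9)
  # 60 Hz content is strongly attenuated; too few prominent extrema remain
  expect_error(preprocess_for_chaos(sin(2 * pi * 60 * tt), fs),
               "insufficient extrema")
  expect_error(preprocess_for_chaos(rnorm(1000), 100), "too low")
  # band-pass confines white noise to the analysis band
  set.seed(3)
  y <- neurocrit:::bandpass_zero_phase(rnorm(10 * fs), fs, 1, 13)
  psd <- welch_psd(y, fs)
  inband <- sum(psd$power[psd$freq >= 1 & psd$freq <= 13])
  expect_gt(inband / sum(psd$power), 0.95)
})

test_that("median chaoticity reduces across channels", {
  ks <- list(0.2, 0.5, 0.9)
  # use raw discrete sequences; preprocess = FALSE exercises the reduction
  xs <- gen_chaos_suite(seed = 4, n = 1000)
  chans <- list(xs$logistic_r3.2$x, xs$logistic_r3.99$x)
  m <- median_chaoticity(chans, preprocess = FALSE, seed = 9)
  k1 <- k_statistic(chans[[1]], seed = 9)$K
  k2 <- k_statistic(chans[[2]], seed = 10)$K
  expect_equal(as.numeric(m), median(c(k1, k2)))
  single <- median_chaoticity(chans[1], preprocess = FALSE, seed = 9)
  expect_equal(as.numeric(single), k1)
  deg <- median_chaoticity(list(rep(1, 300), rep(2, 300)),
                           preprocess = FALSE)
  expect_true(attr(deg, "degenerate"))
})

test_that("divergence-curve fitting recovers a known exponent", {
  lam <- 1.7
  tt <- seq(0, 10, by = 1e-3)
  eps <- 1e-10 * exp(lam * tt)
  fit <- fit_lle(tt, pmin(eps, 1), perturb_time = 0)
  expect_equal(fit$Lambda, lam, tolerance = 0.02)
  expect_gt(fit$fit_r2, 0.99)
  # decaying curve with plateau: slope taken from the initial segment
  eps2 <- 1e-10 * exp(-2 * tt) + 1e-22
  fit2 <- fit_lle(tt, eps2, perturb_time = 0)
  expect_equal(fit2$Lambda, -2, tolerance = 0.15)
  expect_error(fit_lle(tt, rep(0, length(tt))), "below resolution")
})

test_that("twin-run divergence of an uncoupled relaxation matches -2*alpha", {
  cfg <- uncoupled_config(alpha = 3, beta = 12, noise_sd = 1e-4,
                          duration = 10)
  est <- stochastic_lle(cfg, duration = 20, seed = 5)
  # squared-distance convention: epsilon decays at twice the slowest
  # membrane eigenvalue
  expect_lt(est$Lambda, 0)
  expect_equal(est$Lambda, -2 * 3, tolerance = 0.25)
})

test_that("zero perturbation is rejected as below resolution", {
  cfg <- uncoupled_config(duration = 2)
  expect_error(stochastic_lle(cfg, duration = 4, perturb_scale = 0, seed = 1),
               "below resolution|identical")
})

test_that("LLE sign is recovered on systems of known stability", {
  stable <- uncoupled_config(alpha = 3, beta = 12, noise_sd = 1e-4,
                             duration = 10)
  signs_stable <- vapply(1:3, function(s)
    sign(stochastic_lle(stable, duration = 16, seed = s)$Lambda), numeric(1))
  expect_true(all(signs_stable == -1))
  chaotic <- shipped_config("anesthesia")
  signs_chaotic <- vapply(1:3, function(s)
    sign(stochastic_lle(chaotic, duration = 16, seed = s)$Lambda), numeric(1))
  expect_gte(sum(signs_chaotic == 1), 2)
})
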