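test_that("benchmark generators are seed-deterministic with sidecars", {
  a <- gen_coupled_pair(coupled_band_spec(seed = 3, duration = 3))
  b <- gen_coupled_pair(coupled_band_spec(seed = 3, duration = 3))
  expect_identical(a, b)
  expect_equal(a$ground_truth$direction, "X->Y")
  expect_equal(a$ground_truth$recv_band_hz, c(52, 104))
  expect_identical(gen_chaos_suite(seed = 2, n = 500),
                   gen_chaos_suite(seed = 2, n = 500))
  v1 <- gen_var_pair(n = 500, seed = 4)
  expect_identical(v1$X, gen_var_pair(n = 500, seed = 4)$X)
})

test_that("coupled-pair spec validates its band placement", {
  expect_error(coupled_band_spec(carrier_hz = 30), "carrier")
  expect_error(coupled_band_spec(slow_hz = 20), "slow_hz")
  expect_error(coupled_band_spec(depth = 1.5), "depth")
})

test_that("zero-depth pairs carry no detectable coupling", {
  misses <- 0
  for (s in 1:3) {
    cp <- gen_coupled_pair(coupled_band_spec(depth = 0, duration = 8,
                                             seed = 200 + s))
    r <- suppressWarnings(soso_test(cp$X, cp$Y, band_pair(5:8, 2),
                                    n_surr = 24, seed = s,
                                    emb = embedding_spec(1, 1, 10),
                                    max_centers = 1200))
    if (r$p > 0.05) misses <- misses + 1
  }
  expect_gte(misses, 2)
})

test_that("modulation depth scales recovered transfer strength", {
  depths <- c(0.1, 0.5, 0.9)
  med_strength <- vapply(depths, function(d) {
    ss <- vapply(1:3, function(s) {
      cp <- gen_coupled_pair(coupled_band_spec(depth = d, duration = 8,
                                               seed = 300 + s))
      suppressWarnings(soso_test(cp$X, cp$Y, band_pair(5:8, 2), n_surr = 12,
                                 seed = s, emb = embedding_spec(1, 1, 10),
                                 max_centers = 1200))$strength
    }, numeric(1))
    median(ss)
  }, numeric(1))
  expect_true(all(diff(med_strength) > 0))
})

test_that("VAR pair has the advertised analytic transfer entropy", {
  v0 <- gen_var_pair(list(a = 0.5, b = 0.5, c = 0), n = 4000, seed = 9)
  expect_lt(abs(v0$te_xy), 0.005)
  v <- gen_var_pair(list(a = 0.5, b = 0.5, c = 0.4), n = 4000, seed = 9)
  expect_gt(v$te_xy, 0.05)
  expect_lt(abs(v$te_yx), 0.005)
  # swapping roles swaps the coupled direction
  vr <- gen_var_pair(list(a = 0.5, b = 0.5, c = 0.4), n = 4000, seed = 10)
  expect_gt(kraskov_te(vr$X, vr$Y, embedding_spec(1, 1, 1)),
            kraskov_te(vr$Y, vr$X, embedding_spec(1, 1, 1)))
  expect_error(gen_var_pair(list(a = 1.1, b = 0.5, c = 0), n = 100),
               "unstable")
})

test_that("chaos suite carries correct canonical labels", {
  s <- gen_chaos_suite(seed = 1, n = 300)
  expect_equal(s$logistic_r4.0$label, "chaotic")
  expect_equal(s$logistic_r3.2$label, "periodic")
  expect_equal(s$white_noise$label, "stochastic")
  # period-2 orbit visits exactly two values after transients
  expect_lte(length(unique(round(s$logistic_r3.2$x, 8))), 2)
})
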