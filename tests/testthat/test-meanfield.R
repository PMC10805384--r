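test_that("firing-rate sigmoid hits its midpoint, saturates, and inverts", {
  expect_equal(firing_rate(0.013, 100, 0.013, 0.005), 50)
  expect_equal(firing_rate(-10, 100, 0.013, 0.005), 0, tolerance = 1e-12)
  expect_equal(firing_rate(10, 100, 0.013, 0.005), 100)
  # V = theta + sigma' ln 9 puts the rate at 90% of maximum
  expect_equal(firing_rate(0.013 + 0.005 * log(9), 100, 0.013, 0.005), 90)
  V <- seq(-0.05, 0.05, length.out = 200)
  expect_true(all(diff(firing_rate(V, 100, 0.013, 0.005)) > 0))
})

test_that("synaptic response peaks at H for any rate pair", {
  tg <- seq(0, 2, by = 1e-5)
  expect_equal(max(synaptic_response(50, 200, tg)), 31.5, tolerance = 1e-6)
  expect_equal(max(synaptic_response(20, 80, tg)), 31.5, tolerance = 1e-6)
  # peak invariance across a grid of rate ratios, including the confluent limit
  for (a in c(10, 45, 120)) {
    for (r in c(1.01, 1.5, 4, 20, 100)) {
      tt <- seq(0, 20 / a, length.out = 4e4)
      expect_equal(max(synaptic_response(a, a * r, tt)), 31.5,
                   tolerance = 1e-6)
    }
  }
  expect_equal(max(synaptic_response(40, 40, seq(0, 1, 1e-5))), 31.5,
               tolerance = 1e-5)
})

test_that("synaptic peak time follows the calculus solution and rescales", {
  a <- 20; b <- 80
  tp <- synaptic_peak_time(a, b)
  expect_equal(tp, log(b / a) / (b - a))
  # numeric argmax agrees
  tt <- seq(0, 0.5, by = 1e-6)
  h <- synaptic_response(a, b, tt)
  expect_equal(tt[which.max(h)], tp, tolerance = 1e-4)
  # doubling both rates halves the time to peak, peak unchanged
  expect_equal(synaptic_peak_time(2 * a, 2 * b), tp / 2)
  expect_equal(max(synaptic_response(2 * a, 2 * b, tt)), 31.5,
               tolerance = 1e-6)
})

test_that("dose interpolation is geometric, sign-preserving, and guarded", {
  P0 <- c(1, 2, -2, 0.5, 0)
  P1 <- c(2, 2, -8, 0.25, 0)
  expect_equal(interpolate_dose(P0, P1, 0), P0)
  expect_equal(interpolate_dose(P0, P1, 1), P1)
  expect_equal(interpolate_dose(P0, P1, 0.5),
               sign(P0) * sqrt(abs(P0 * P1)))
  expect_equal(interpolate_dose(-2, -8, 2), -32)
  expect_error(interpolate_dose(c(0, 1), c(1, 1), 0.5), "undefined")
  expect_error(interpolate_dose(c(-1, 1), c(1, 1), 0.5), "sign")
  # monotone in D componentwise
  d <- seq(0, 2, length.out = 9)
  path <- vapply(d, function(D) interpolate_dose(2, 8, D), numeric(1))
  expect_true(all(diff(path) > 0))
})

test_that("uncoupled integration settles on the closed-form fixed point", {
  cfg <- uncoupled_config(alpha = 30, beta = 120, drive = 0.013,
                          noise_sd = 0, duration = 3)
  sim <- integrate_model(cfg, seed = 1)
  n <- nrow(sim$Q)
  pop <- cfg$populations
  expect_equal(unname(sim$Vext[n, ]), rep(0.013, 9), tolerance = 1e-8)
  expect_equal(unname(sim$Q[n, ]),
               unname(firing_rate(0.013, pop$Q_max, pop$theta,
                                  pop$sigma_prime)),
               tolerance = 1e-6)
})

test_that("integration is deterministic and rate-bounded", {
  cfg <- shipped_config("waking")
  s1 <- integrate_model(cfg, seed = 42, duration = 2)
  s2 <- integrate_model(cfg, seed = 42, duration = 2)
  expect_identical(s1$Q, s2$Q)
  expect_true(all(s1$Q >= 0))
  expect_true(all(sweep(s1$Q, 2, cfg$populations$Q_max, `<=`)))
})

test_that("delay buffers are causal", {
  # single active projection relay -> cortex with a 40 ms delay: an impulse
  # in the relay drive must not reach cortex before that delay
  cfg <- shipped_config("waking")
  cfg$external$noise_sd[] <- 0
  only <- with(cfg$projections,
               source == "relay_nuclei" & target == "cortex_excitatory")
  cfg$projections$nu[!only] <- 0
  tau <- cfg$projections$tau[only]
  base <- integrate_model(cfg, seed = 1, duration = 0.5)
  t0 <- 0.2
  i_rel <- which(cfg$populations$label == "relay_nuclei")
  nsteps <- round(0.5 / cfg$dt)
  noise <- matrix(0, nsteps + 1, 9)
  noise[round(t0 / cfg$dt) + 1, i_rel] <- 1
  kick <- cfg
  kick$external$noise_sd[i_rel] <- 0.01
  pert <- integrate_model(kick, seed = 1, duration = 0.5, noise = noise)
  lc_b <- lfp(base, "cortex_excitatory")
  lc_p <- lfp(pert, "cortex_excitatory")
  before <- base$t < t0 + tau - 2 / base$fs
  after <- base$t > t0 + tau + 0.05
  expect_equal(lc_p[before], lc_b[before], tolerance = 1e-12)
  expect_gt(max(abs(lc_p[after] - lc_b[after])), 0)
})

test_that("dose-zero interpolation reproduces the waking run bit-exactly", {
  w <- shipped_config("waking")
  a <- shipped_config("anesthesia")
  plain <- integrate_model(w, seed = 3, duration = 1)
  dosed <- integrate_model(w, dose = list(altered = a, D = 0), seed = 3,
                           duration = 1)
  expect_identical(plain$Q, dosed$Q)
})

test_that("LFP is an absolute-value superposition", {
  s <- fake_sim(c(-1, 2, -3), rates = setNames(rep(10, 9),
                                               neurocrit:::BGTC_LABELS))
  expect_equal(lfp(s, "cortex_excitatory", include_external = FALSE),
               c(1, 2, 3))
  # opposite-sign afferents add, never cancel
  s$Vab <- cbind(c(1, 2), c(-1, -2))
  s$projections <- rbind(s$projections, s$projections)
  s$Vext <- s$Vext[1:2, ]
  s$Q <- s$Q[1:2, ]
  expect_equal(lfp(s, "cortex_excitatory", include_external = FALSE),
               c(2, 4))
  expect_error(lfp(s, "GPe", include_external = FALSE), "afferent")
})

test_that("halving the step leaves the mean cortical rate within 1%", {
  cfg <- shipped_config("waking")
  cfg$external$noise_sd[] <- 0  # deterministic convergence check
  r <- sapply(c(1e-4, 5e-5), function(dt) {
    cfg$dt <- dt
    sim <- integrate_model(cfg, seed = 1, duration = 5)
    mean(sim$Q[sim$t >= 1, "cortex_excitatory"])
  })
  expect_lt(abs(r[1] - r[2]) / r[2], 0.01)
})
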