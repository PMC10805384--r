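# brute-force signed-rank null: enumerate all 2^n sign assignments
enumerate_signrank_p <- function(V, n, alternative) {
  stats_all <- vapply(0:(2^n - 1), function(m) {
    signs <- as.integer(intToBits(m))[1:n]
    sum((1:n)[signs == 1])
  }, numeric(1))
  if (alternative == "less") mean(stats_all <= V) else mean(stats_all >= V)
}

test_that("one-tailed signed-rank p-values are exact dyadic rationals", {
  # all subjects move in the hypothesized direction
  for (n in c(5, 7, 9)) {
    res <- wilcoxon_one_tailed(seq_len(n) + 10, seq_len(n) * 0.9,
                               alternative = "less")
    expect_true(res$exact)
    expect_equal(res$p, 1 / 2^n)
    expect_equal(res$p * 2^n, round(res$p * 2^n))  # dyadic
  }
  drop_all <- function(n) wilcoxon_one_tailed(10 + 1:n, 10 + 1:n - (1:n) / 10,
                                              "less")$p
  expect_equal(present_p(drop_all(9)), 0.002)
  expect_equal(present_p(drop_all(5)), 0.0312)
  expect_equal(present_p(drop_all(7)), 0.0078)
})

test_that("exact signed-rank agrees with full enumeration for small n", {
  set.seed(12)
  for (rep in 1:6) {
    n <- sample(5:10, 1)
    base <- rnorm(n)
    cond <- base + rnorm(n)
    for (alt in c("less", "greater")) {
      res <- wilcoxon_one_tailed(base, cond, alt)
      if (!res$exact) next
      expect_equal(res$p, enumerate_signrank_p(res$statistic, res$n, alt))
    }
  }
})

test_that("signed-rank error and tie contracts hold", {
  expect_error(wilcoxon_one_tailed(1:6, 1:6), "zero")
  expect_warning(res <- wilcoxon_one_tailed(c(1, 2, 3, 4, 5, 6),
                                            c(0, 1, 2, 3, 4, 8),
                                            "less"),
                 "ties")
  expect_false(res$exact)
  expect_true(res$p > 0 && res$p < 1)
})

test_that("subject-level binomial test matches the tail sum", {
  expect_equal(binomial_subjects(31, 31), 0.05^31)
  expect_equal(binomial_subjects(0, 10), 1)
  expect_equal(binomial_subjects(1, 1), 0.05)
  expect_equal(binomial_subjects(3, 20, 0.1),
               sum(dbinom(3:20, 20, 0.1)))
})

test_that("Modulation Index responds to phase-amplitude coupling", {
  fs <- 416
  n <- 10 * fs
  tt <- seq_len(n) / fs
  slow <- sin(2 * pi * 6 * tt)
  carrier <- sin(2 * pi * 78 * tt)
  set.seed(21)
  mi0 <- modulation_index(slow + 0.2 * rnorm(n),
                          carrier + 0.2 * rnorm(n), fs)
  expect_lt(mi0, 0.01)
  pac <- function(depth) (1 + depth * slow) * carrier + 0.05 * rnorm(n)
  mi_hi <- modulation_index(slow, pac(0.9), fs)
  mi_lo <- modulation_index(slow, pac(0.1), fs)
  expect_gt(mi_hi, mi_lo)
  # invariant to amplitude rescaling of both inputs
  y <- pac(0.5)
  expect_equal(as.numeric(modulation_index(slow, y, fs)),
               as.numeric(modulation_index(10 * slow, 0.2 * y, fs)),
               tolerance = 1e-10)
})

test_that("degenerate Modulation Index cases hit the entropy bounds", {
  # amplitude concentrated in one phase bin gives MI = 1
  P <- c(1, rep(0, 17))
  H <- -sum(P[P > 0] * log(P[P > 0]))
  expect_equal((log(18) - H) / log(18), 1)
})

test_that("Lempel-Ziv complexity spans its scale", {
  expect_true(attr(lempel_ziv(rep(3.3, 200)), "degenerate"))
  alt <- rep(c(0, 1), 500)
  expect_lte(as.numeric(lempel_ziv(alt)), 0.1)
  set.seed(5)
  r <- lempel_ziv(rnorm(10000))
  expect_gt(as.numeric(r), 0.9)
  expect_lt(as.numeric(r), 1.1)
  # ordering: random > periodic
  expect_gt(as.numeric(lempel_ziv(rnorm(1000))),
            as.numeric(lempel_ziv(sin(2 * pi * (1:1000) / 50))))
})

test_that("bi-symmetric log transform is odd, monotone, and anchored", {
  expect_equal(bisymlog(0), 0)
  expect_equal(bisymlog(99, C = 1), 2)
  x <- seq(-50, 50, length.out = 101)
  expect_equal(bisymlog(-x), -bisymlog(x))
  expect_true(all(diff(bisymlog(x)) > 0))
  expect_error(bisymlog(1, C = 0), "C > 0")
})

test_that("permutation ANCOVA controls type I error and detects effects", {
  set.seed(31)
  n <- 40
  cov1 <- rnorm(n)
  states <- rep(c("a", "b"), each = n / 2)
  # null: no state effect
  hits <- 0
  nsim <- 120
  for (i in seq_len(nsim)) {
    y <- 0.5 * cov1 + rnorm(n)
    p <- perm_ancova(y, states, cov1, n_perm = 199, seed = i)$p
    if (p < 0.05) hits <- hits + 1
  }
  expect_gt(hits / nsim, 0.01)
  expect_lt(hits / nsim, 0.1)
  # strong effect: p at the permutation floor
  y <- 0.5 * cov1 + 3 * (states == "b") + rnorm(n)
  res <- perm_ancova(y, states, cov1, n_perm = 199, seed = 1)
  expect_equal(res$p, 1 / 200)
  expect_identical(perm_ancova(y, states, cov1, n_perm = 99, seed = 7)$p,
                   perm_ancova(y, states, cov1, n_perm = 99, seed = 7)$p)
  expect_error(perm_ancova(y, states, cbind(cov1, cov1), n_perm = 10),
               "rank")
})

test_that("baseline normalization is a plain ratio with guards", {
  expect_equal(normalize_to_baseline(2, 2), 1)
  expect_equal(normalize_to_baseline(c(4, 2), 2), c(2, 1))
  expect_error(normalize_to_baseline(1, 0), "zero")
  v <- c(3, 1, 2)
  expect_equal(order(normalize_to_baseline(v, 5)), order(v))
})
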