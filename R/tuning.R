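# State-specific fitness functions and a seeded genetic optimizer for
# tuning the mean-field model's couplings and drives against physiological
# firing-rate ranges and the qualitative electrodynamic signatures of
# waking, anesthesia, and spike-and-wave seizure states.

#' Physiological firing-rate targets per population
#'
#' Default per-population target ranges (spikes/s) drawn from published
#' single-unit recordings across mammalian species (primate values where a
#' single range covers them, the cross-species span otherwise): cortex 5-20,
#' striatum 4-7, GPi/SNr 60-90, GPe 16-70, STN 8-30, thalamic relay 5-25,
#' TRN 4-64.
#'
#' @return data.frame with columns label, lo, hi.
#' @export
rate_targets <- function() {
  data.frame(
    label = BGTC_LABELS,
    lo = c(5, 5, 4, 4, 60, 16, 8, 5, 4),
    hi = c(20, 20, 7, 7, 90, 70, 30, 25, 64),
    stringsAsFactors = FALSE)
}

#' Fitness specification for one brain state
#'
#' @param state one of \code{"waking"}, \code{"anesthesia"},
#'   \code{"seizure"}.
#' @param targets rate-target data.frame; default [rate_targets()].
#' @param weights named non-negative weights per criterion (merged over the
#'   state's defaults).
#' @return list of class \code{nc_fitness_spec}.
#' @export
fitness_spec <- function(state = c("waking", "anesthesia", "seizure"),
                         targets = rate_targets(), weights = NULL) {
  state <- match.arg(state)
  w <- switch(state,
    waking = c(rates = 1, alpha_peak = 2, chaos = 2, amplitude = 0.5,
               rate_gamma_cor = 0.5),
    anesthesia = c(cortex_rate = 1, chaos = 2, complexity = 1, delta = 2,
                   high_freq = 1),
    seizure = c(osc_2_8 = 2, periodic = 2, complexity = 1))
  if (!is.null(weights)) {
    stopifnot(all(weights >= 0))
    w[names(weights)] <- weights
  }
  structure(list(state = state, targets = targets, weights = w),
            class = "nc_fitness_spec")
}

#' Fitness of a simulation under a state specification
#'
#' Scores a simulation against the qualitative criteria of its state.
#' Waking rewards firing rates inside physiological ranges, an alpha-band
#' (8-13 Hz) spectral peak, weak chaoticity (K-statistic of the 1-13 Hz LFP
#' component near the edge of chaos), low LFP amplitude, and a positive
#' correlation between the cortical rate and the high-gamma LFP envelope.
#' Anesthesia rewards a low cortical rate, strong chaoticity, low
#' Lempel-Ziv complexity, delta (< 4 Hz) dominance, and little power above
#' 60 Hz. Seizure rewards large periodic (low-K) 2-8 Hz oscillations with
#' low complexity. Deterministic given the simulation (internal seeds are
#' fixed).
#'
#' @param sim an \code{nc_sim} (>= 10 s after burn-in recommended).
#' @param spec an [fitness_spec()].
#' @param burn_in seconds discarded before scoring; default 5.
#' @return scalar score (larger is better).
#' @export
fitness <- function(sim, spec, burn_in = 5) {
  keep <- sim$t >= burn_in
  if (sum(keep) < 2 * sim$fs) stop("simulation too short after burn-in")
  Q <- sim$Q[keep, , drop = FALSE]
  lfp_c <- lfp(sim, "cortex_excitatory")[keep]
  fs <- sim$fs
  w <- spec$weights
  score <- 0

  k_of <- function(x) {
    k <- tryCatch(
      k_statistic(preprocess_for_chaos(x, fs), seed = 1)$K,
      error = function(e) NA_real_)
    if (is.na(k)) 0 else k
  }

  if (spec$state == "waking") {
    tg <- spec$targets
    mr <- colMeans(Q)[tg$label]
    viol <- pmax(0, log(tg$lo / pmax(mr, 1e-6)), log(mr / tg$hi))
    score <- score - w["rates"] * sum(viol^2)
    score <- score + w["alpha_peak"] * band_power_fraction(lfp_c, fs, 8, 13)
    K <- k_of(lfp_c)
    score <- score - w["chaos"] * abs(K - 0.35)
    score <- score - w["amplitude"] * min(sd(lfp_c) / 0.01, 2)
    env <- Mod(analytic_signal(bandpass_zero_phase(
      lfp_c - mean(lfp_c), fs, 60, min(200, fs / 2 - 10))))
    rc <- suppressWarnings(cor(Q[, "cortex_excitatory"], env))
    if (!is.na(rc)) score <- score + w["rate_gamma_cor"] * rc
  } else if (spec$state == "anesthesia") {
    score <- score - w["cortex_rate"] * mean(Q[, "cortex_excitatory"]) / 10
    K <- k_of(lfp_c)
    score <- score + w["chaos"] * K
    lz <- as.numeric(lempel_ziv(lfp_c))
    score <- score - w["complexity"] * lz
    score <- score + w["delta"] * band_power_fraction(lfp_c, fs, 0.5, 4)
    score <- score - w["high_freq"] *
      band_power_fraction(lfp_c, fs, 60, fs / 2 - 1)
  } else {  # seizure
    score <- score + w["osc_2_8"] * band_power_fraction(lfp_c, fs, 2, 8)
    K <- k_of(lfp_c)
    score <- score + w["periodic"] * (1 - K)
    lz <- as.numeric(lempel_ziv(lfp_c))
    score <- score - w["complexity"] * lz
    score <- score + min(sd(lfp_c) / 0.005, 1)  # seizures are high-amplitude
  }
  unname(score)
}

#' Pin the model's fixed point at target firing rates
#'
#' Sets each population's constant external drive so that the supplied
#' firing rates are an exact equilibrium of the deterministic system: the
#' sigmoid is inverted to the required somatic potential and the external
#' drive absorbs the difference between that potential and the summed
#' steady-state synaptic afferents. Whether the equilibrium is stable (a
#' fixed point) or unstable (the germ of an oscillation) is then governed
#' entirely by the coupling gains and delays.
#'
#' @param config an \code{nc_config} with couplings set.
#' @param rates named vector of target rates (s^-1) per population label.
#' @return the config with \code{external$mean} replaced.
#' @export
pin_fixed_point <- function(config, rates) {
  pop <- config$populations
  stopifnot(setequal(names(rates), pop$label))
  rates <- rates[pop$label]
  stopifnot(all(rates > 0), all(rates < pop$Q_max))
  # invert the sigmoid: potential required for each target rate
  Vstar <- pop$theta + pop$sigma_prime * log(rates / (pop$Q_max - rates))
  rt <- proj_rates(config)
  hscale <- config$H / mapply(synaptic_peak, rt$alpha, rt$beta)
  pr <- config$projections
  syn <- numeric(nrow(pop))
  for (j in seq_len(nrow(pr))) {
    a <- match(pr$target[j], pop$label)
    b <- match(pr$source[j], pop$label)
    syn[a] <- syn[a] + hscale[j] * pr$nu[j] * rates[b]
  }
  config$external$mean <- unname(Vstar - syn)
  config
}

#' Seeded genetic search over a bounded parameter box
#'
#' Real-coded genetic algorithm with tournament selection, uniform
#' crossover, Gaussian mutation and elitism; the best-so-far fitness is
#' non-decreasing across generations by construction.
#'
#' @param objective function(par) -> scalar score (maximized). Non-finite
#'   scores are treated as -Inf.
#' @param lower,upper bound vectors.
#' @param pop_size population size; default 24.
#' @param generations generations; default 30.
#' @param seed seed.
#' @param elite elites copied unchanged; default 2.
#' @param tournament tournament size; default 3.
#' @param mut_sd mutation SD as a fraction of the box width; default 0.1.
#' @param mut_prob per-gene mutation probability; default 0.25.
#' @return list: \code{par}, \code{value}, \code{history} (best-so-far per
#'   generation).
#' @export
genetic_search <- function(objective, lower, upper, pop_size = 24,
                           generations = 30, seed = 1, elite = 2,
                           tournament = 3, mut_sd = 0.1, mut_prob = 0.25) {
  stopifnot(length(lower) == length(upper), all(is.finite(lower)),
            all(is.finite(upper)), all(upper >= lower))
  d <- length(lower)
  width <- upper - lower
  set.seed(seed)
  pop <- matrix(runif(pop_size * d, rep(lower, each = pop_size),
                      rep(upper, each = pop_size)), pop_size, d)
  evals <- apply(pop, 1, function(p) {
    v <- tryCatch(objective(p), error = function(e) -Inf)
    if (!is.finite(v)) -Inf else v
  })
  history <- numeric(generations)
  for (g in seq_len(generations)) {
    ord <- order(evals, decreasing = TRUE)
    pop <- pop[ord, , drop = FALSE]
    evals <- evals[ord]
    history[g] <- evals[1]
    newpop <- pop[seq_len(elite), , drop = FALSE]
    while (nrow(newpop) < pop_size) {
      pick <- function() {
        cand <- sample.int(pop_size, tournament)
        pop[cand[which.max(evals[cand])], ]
      }
      p1 <- pick(); p2 <- pick()
      mask <- runif(d) < 0.5
      child <- ifelse(mask, p1, p2)
      mut <- runif(d) < mut_prob
      child[mut] <- child[mut] + rnorm(sum(mut)) * mut_sd * width[mut]
      child <- pmin(pmax(child, lower), upper)
      newpop <- rbind(newpop, child)
    }
    keep_evals <- evals[seq_len(elite)]
    new_evals <- apply(newpop[(elite + 1):pop_size, , drop = FALSE], 1,
                       function(p) {
                         v <- tryCatch(objective(p), error = function(e) -Inf)
                         if (!is.finite(v)) -Inf else v
                       })
    pop <- newpop
    evals <- c(keep_evals, new_evals)
  }
  best <- which.max(evals)
  list(par = pop[best, ], value = evals[best],
       history = cummax(history))
}

#' Tune model couplings and drives toward a state's fitness
#'
#' Genetic search over the projection coupling magnitudes and external
#' drives of a configuration (signs held fixed by source neurochemistry),
#' maximizing [fitness()] of a short simulation. A simplified stand-in for
#' full Bayesian-genetic optimization: genetic stage only, same stated
#' fitness criteria.
#'
#' @param base_config starting \code{nc_config}.
#' @param spec an [fitness_spec()].
#' @param scale multiplicative search range around the starting values;
#'   default 4 (each magnitude searched in [x/scale, x*scale]).
#' @param duration simulation length per evaluation (s); default 12.
#' @param sim_seed fixed seed for evaluation simulations.
#' @param ... passed to [genetic_search()].
#' @return list: tuned \code{config}, \code{value}, \code{history}.
#' @export
tune_couplings <- function(base_config, spec, scale = 4, duration = 12,
                           sim_seed = 1, ...) {
  nu0 <- base_config$projections$nu
  ext0 <- base_config$external$mean
  stopifnot(all(nu0 != 0))
  th <- c(abs(nu0), abs(ext0) + 1e-4)
  lower <- th / scale
  upper <- th * scale
  sgn <- c(sign(nu0), rep(1, length(ext0)))
  J <- length(nu0)
  build <- function(par) {
    cfg <- base_config
    cfg$projections$nu <- sgn[seq_len(J)] * par[seq_len(J)]
    cfg$external$mean <- par[(J + 1):length(par)]
    cfg
  }
  obj <- function(par) {
    cfg <- build(par)
    sim <- integrate_model(cfg, seed = sim_seed, duration = duration)
    fitness(sim, spec)
  }
  res <- genetic_search(obj, lower, upper, ...)
  list(config = build(res$par), value = res$value, history = res$history)
}
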