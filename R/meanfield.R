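#' @useDynLib neurocrit, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @importFrom stats rnorm runif median sd cor lm coef residuals fitted
#'   quantile
NULL

# canonical population labels of the basal ganglia-thalamo-cortical system
BGTC_LABELS <- c("cortex_excitatory", "cortex_inhibitory", "striatum_D1",
                 "striatum_D2", "GPi_SNr", "GPe", "STN", "relay_nuclei",
                 "TRN")

# sources releasing glutamate carry positive coupling; GABAergic sources
# (cortical interneurons, striatum, pallidum, TRN) negative
EXCITATORY_SOURCES <- c("cortex_excitatory", "STN", "relay_nuclei")

#' Population firing-rate sigmoid
#'
#' Mean population firing rate as a sigmoidal function of the mean somatic
#' potential: \code{Q_max / (1 + exp(-(V - theta) / sigma_prime))}.
#'
#' @param V mean membrane potential (V); vectorized.
#' @param Q_max maximum firing rate (s^-1).
#' @param theta mean firing threshold (V).
#' @param sigma_prime spread of cell-body potentials about threshold (V).
#' @return firing rate (s^-1), strictly increasing in \code{V}, bounded in
#'   \code{[0, Q_max]}.
#' @export
firing_rate <- function(V, Q_max, theta, sigma_prime) {
  stopifnot(Q_max > 0, sigma_prime > 0)
  Q_max / (1 + exp(-(V - theta) / sigma_prime))
}

#' Unscaled peak of the bi-exponential synaptic response
#'
#' Peak value of the impulse response of the second-order synaptic operator
#' with decay rate \code{alpha} and rise rate \code{beta}, i.e. of
#' \code{hbar(t) = alpha*beta/(beta-alpha) * (exp(-alpha t) - exp(-beta t))}.
#' Handles the confluent limit \code{alpha == beta} analytically
#' (\code{hbar(t) = alpha^2 t exp(-alpha t)}, peak \code{alpha/e}).
#'
#' @param alpha synaptic decay rate (s^-1).
#' @param beta synaptic rise rate (s^-1).
#' @return peak response (s^-1).
#' @export
synaptic_peak <- function(alpha, beta) {
  stopifnot(alpha > 0, beta > 0)
  if (abs(alpha - beta) < 1e-9 * alpha) return(alpha / exp(1))
  tp <- log(beta / alpha) / (beta - alpha)
  alpha * beta / (beta - alpha) * (exp(-alpha * tp) - exp(-beta * tp))
}

#' Peak-normalized synaptic response
#'
#' Bi-exponential synaptic impulse response rescaled so that its maximum over
#' time equals \code{H} regardless of \code{(alpha, beta)}. Changing the rates
#' then alters the duration of the postsynaptic response but not its peak,
#' which is how GABAergic anesthetics prolong inhibition without changing the
#' maximal postsynaptic current.
#'
#' @inheritParams synaptic_peak
#' @param t time since the impulse (s); vectorized, \code{t >= 0}.
#' @param H peak response (s^-1), default 31.5.
#' @return response amplitude at \code{t} (s^-1); \code{max_t} equals \code{H}.
#' @export
synaptic_response <- function(alpha, beta, t, H = 31.5) {
  stopifnot(all(t >= 0))
  if (abs(alpha - beta) < 1e-9 * alpha) {
    hbar <- alpha^2 * t * exp(-alpha * t)
  } else {
    hbar <- alpha * beta / (beta - alpha) * (exp(-alpha * t) - exp(-beta * t))
  }
  H * hbar / synaptic_peak(alpha, beta)
}

#' Time of the synaptic response peak
#' @inheritParams synaptic_peak
#' @return time to peak (s).
#' @export
synaptic_peak_time <- function(alpha, beta) {
  if (abs(alpha - beta) < 1e-9 * alpha) return(1 / alpha)
  log(beta / alpha) / (beta - alpha)
}

#' Population table for the basal ganglia-thalamo-cortical model
#'
#' @param Q_max,theta,sigma_prime,alpha,beta per-population values, recycled
#'   to length 9 and matched to \code{BGTC_LABELS} order (cortex excitatory,
#'   cortex inhibitory, striatal D1, striatal D2, GPi/SNr, GPe, STN, thalamic
#'   relay, TRN).
#' @return data.frame with one row per population.
#' @export
bgtc_populations <- function(Q_max = 340, theta = 0.013,
                             sigma_prime = 0.0038,
                             alpha = 80, beta = 500) {
  df <- data.frame(
    label = BGTC_LABELS,
    Q_max = rep_len(Q_max, 9),
    theta = rep_len(theta, 9),
    sigma_prime = rep_len(sigma_prime, 9),
    alpha = rep_len(alpha, 9),
    beta = rep_len(beta, 9),
    stringsAsFactors = FALSE)
  df
}

#' Projection table of the basal ganglia-thalamo-cortical circuit
#'
#' The anatomical skeleton: cortico-cortical, cortico-striatal,
#' cortico-subthalamic and cortico-thalamic projections, the direct
#' (striatum D1 -> GPi/SNr) and indirect (D2 -> GPe -> STN -> GPi/SNr)
#' pathways, pallido-pallidal and thalamo-cortical loops, plus pallidal
#' (GPe) projections to cortical interneurons, thalamic relay, TRN and both
#' striatal populations. GPi and SNr are treated as a single output
#' population. Coupling strengths \code{nu} (V s) are placeholders (0 sign
#' carriers) to be filled from a tuned state configuration.
#'
#' @return data.frame with columns source, target, nu, tau (s), gamma (s^-1).
#' @export
bgtc_projections <- function() {
  p <- function(src, tgt, tau, gamma = 400) {
    data.frame(source = src, target = tgt, nu = 0, tau = tau, gamma = gamma,
               stringsAsFactors = FALSE)
  }
  ce <- "cortex_excitatory"; ci <- "cortex_inhibitory"
  d1 <- "striatum_D1"; d2 <- "striatum_D2"
  gpi <- "GPi_SNr"; gpe <- "GPe"; stn <- "STN"
  rel <- "relay_nuclei"; trn <- "TRN"
  out <- rbind(
    p(ce, ce, 0.002, 125), p(ce, ci, 0.002, 125),
    p(ce, d1, 0.002, 125), p(ce, d2, 0.002, 125),
    p(ce, stn, 0.002, 125), p(ce, rel, 0.040, 125), p(ce, trn, 0.040, 125),
    p(ci, ce, 0.001), p(ci, ci, 0.001),
    p(d1, d1, 0.001), p(d1, gpi, 0.001),
    p(d2, d2, 0.001), p(d2, gpe, 0.001),
    p(gpi, rel, 0.002),
    p(gpe, gpi, 0.001), p(gpe, stn, 0.001), p(gpe, gpe, 0.001),
    p(gpe, ci, 0.002), p(gpe, rel, 0.002), p(gpe, trn, 0.002),
    p(gpe, d1, 0.002), p(gpe, d2, 0.002),
    p(stn, gpi, 0.001), p(stn, gpe, 0.001),
    p(rel, ce, 0.040), p(rel, ci, 0.040),
    p(rel, d1, 0.002), p(rel, d2, 0.002), p(rel, trn, 0.002),
    p(trn, rel, 0.002))
  rownames(out) <- NULL
  out
}

#' Assemble a mean-field model configuration
#'
#' @param populations data.frame as from [bgtc_populations()].
#' @param projections data.frame as from [bgtc_projections()] with coupling
#'   strengths \code{nu} filled in (V s; sign fixed by source neurochemistry).
#'   Optional columns \code{alpha}, \code{beta} override the target
#'   population's receptor rates for that projection.
#' @param external data.frame with columns \code{label}, \code{mean} (V) and
#'   \code{noise_sd} (V): constant drive plus white-noise amplitude entering
#'   each population through an unscaled synaptic filter.
#' @param dt integration step (s).
#' @param record_rate output sample rate (Hz).
#' @param duration simulated time (s).
#' @param H synaptic peak constant (s^-1).
#' @return object of class \code{nc_config}.
#' @export
model_config <- function(populations, projections, external = NULL,
                         dt = 1e-4, record_rate = 1000, duration = 10,
                         H = 31.5) {
  stopifnot(all(projections$source %in% populations$label),
            all(projections$target %in% populations$label))
  if (is.null(external)) {
    external <- data.frame(label = populations$label, mean = 0,
                           noise_sd = 0, stringsAsFactors = FALSE)
  }
  stopifnot(setequal(external$label, populations$label))
  external <- external[match(populations$label, external$label), ]
  # sign convention check
  exc <- projections$source %in% EXCITATORY_SOURCES
  bad <- (exc & projections$nu < 0) | (!exc & projections$nu > 0)
  if (any(bad)) {
    stop("projection sign violates source neurochemistry: ",
         paste(projections$source[bad], "->", projections$target[bad],
               collapse = ", "))
  }
  pos_tau <- projections$tau[projections$tau > 0]
  if (length(pos_tau) && dt > min(pos_tau) / 4) {
    stop("dt must be <= min positive delay / 4 for resolvable delay lines")
  }
  if (record_rate > 1 / dt) stop("record_rate cannot exceed 1/dt")
  structure(list(populations = populations, projections = projections,
                 external = external, dt = dt, record_rate = record_rate,
                 duration = duration, H = H),
            class = "nc_config")
}

# receptor rates per projection: target population's alpha/beta unless a
# per-projection override column is present and non-NA
proj_rates <- function(config) {
  pr <- config$projections
  pop <- config$populations
  ti <- match(pr$target, pop$label)
  a <- pop$alpha[ti]
  b <- pop$beta[ti]
  if ("alpha" %in% names(pr)) a <- ifelse(is.na(pr$alpha), a, pr$alpha)
  if ("beta" %in% names(pr)) b <- ifelse(is.na(pr$beta), b, pr$beta)
  list(alpha = a, beta = b)
}

#' Integrate the mean-field model
#'
#' Advances the coupled population system with a fixed-step classical
#' Runge-Kutta scheme and ring-buffer delay lines. Per projection
#' (target a <- source b) the dendritic potential obeys the second-order
#' synaptic operator driven by the delayed axonal field, whose amplitude is
#' rescaled so the peak synaptic response is rate-independent; the field
#' obeys the spatially uniform mode of the damped wave equation. White noise
#' in the external drive is held constant within each integration step.
#'
#' @param config an \code{nc_config}.
#' @param dose optional list with \code{altered} (a second \code{nc_config}
#'   with identical layout) and \code{D} (dose, >= 0): parameters are
#'   geometrically interpolated with [interpolate_dose()] before integration.
#' @param seed integer seed for the noise stream and random initial
#'   conditions. Identical seed + config gives bit-identical output.
#' @param duration override of \code{config$duration} (s).
#' @param noise optional pre-generated standard-normal matrix
#'   \code{(nsteps+1) x 9} (for twin runs with shared noise).
#' @param init \code{"rest"} (all potentials at 0) or \code{"random"} (small
#'   seeded uniform perturbation of initial dendritic potentials).
#' @param perturb optional list \code{(time, dV, dVext)}: at \code{time} the
#'   given offsets are added to every dendritic potential (twin-run
#'   divergence probe).
#' @return object of class \code{nc_sim}: per-population firing rates
#'   \code{Q} (s^-1), per-projection dendritic potentials \code{Vab} (V),
#'   external-afferent potentials \code{Vext} (V), times \code{t}, sample
#'   rate \code{fs}, and metadata.
#' @export
integrate_model <- function(config, dose = NULL, seed = NULL, duration = NULL,
                            noise = NULL, init = c("rest", "random"),
                            perturb = NULL) {
  init <- match.arg(init)
  if (!is.null(dose)) {
    config <- interpolate_config(config, dose$altered, dose$D)
  }
  if (!is.null(seed)) set.seed(seed)
  pop <- config$populations
  pr <- config$projections
  ext <- config$external
  if (is.null(duration)) duration <- config$duration
  dt <- config$dt
  nsteps <- round(duration / dt)
  record_every <- round(1 / (config$record_rate * dt))
  fs <- 1 / (dt * record_every)

  P <- nrow(pop); J <- nrow(pr)
  if (is.null(noise)) {
    noise <- matrix(rnorm((nsteps + 1) * P), nsteps + 1, P)
  } else {
    stopifnot(nrow(noise) >= nsteps + 1, ncol(noise) == P)
  }
  drive <- sweep(noise, 2, ext$noise_sd, `*`)
  drive <- sweep(drive, 2, ext$mean, `+`)

  rates <- proj_rates(config)
  hscale <- config$H / mapply(synaptic_peak, rates$alpha, rates$beta)

  si <- match(pr$source, pop$label) - 1L
  ti <- match(pr$target, pop$label) - 1L

  init_V <- numeric(J); init_Ve <- numeric(P)
  if (init == "random") {
    init_V <- runif(J, -1, 1) * 1e-4
    init_Ve <- runif(P, -1, 1) * 1e-4
  }
  # start fields consistent with the initial firing rates
  Va0 <- init_Ve
  for (j in seq_len(J)) Va0[ti[j] + 1] <- Va0[ti[j] + 1] + init_V[j]
  Q0 <- firing_rate(Va0, pop$Q_max, pop$theta, pop$sigma_prime)
  init_P <- Q0[si + 1]

  pstep <- -1L; pV <- numeric(J); pVe <- numeric(P)
  if (!is.null(perturb)) {
    pstep <- as.integer(round(perturb$time / dt))
    pV <- rep_len(perturb$dV, J)
    pVe <- rep_len(perturb$dVext, P)
  }

  res <- mf_integrate_cpp(pop$Q_max, pop$theta, pop$sigma_prime,
                          ti, si, pr$nu, pr$tau, pr$gamma,
                          rates$alpha, rates$beta, hscale,
                          pop$alpha, pop$beta,
                          drive, dt, nsteps, record_every,
                          init_V, numeric(J), init_P, numeric(J),
                          init_Ve, numeric(P),
                          pstep, pV, pVe)
  if (!isTRUE(res$ok)) {
    stop(sprintf("mean-field integration diverged at t = %.4f s (population %s)",
                 res$t, pop$label[res$bad_target]))
  }
  Q <- res$Q; colnames(Q) <- pop$label
  Vext <- res$Vext; colnames(Vext) <- pop$label
  structure(list(t = res$t, Q = Q, Vab = res$Vab, Vext = Vext,
                 projections = pr, fs = fs, dt = dt, seed = seed,
                 dose = if (is.null(dose)) 0 else dose$D,
                 config = config),
            class = "nc_sim")
}

#' @export
print.nc_sim <- function(x, ...) {
  cat(sprintf("<nc_sim> %d populations, %d projections, %.1f s @ %g Hz (dose %g)\n",
              ncol(x$Q), nrow(x$projections), max(x$t), x$fs, x$dose))
  invisible(x)
}

#' Local field potential of a region
#'
#' The LFP of a population is the superposition of its synaptic currents,
#' estimated as the sum of the absolute values of its afferent dendritic
#' potentials (no cancellation between excitatory and inhibitory afferents).
#'
#' @param sim an \code{nc_sim}.
#' @param region population label.
#' @param include_external include the external-drive afferent (default TRUE).
#' @return nonnegative numeric series (V) at \code{sim$fs}.
#' @export
lfp <- function(sim, region, include_external = TRUE) {
  stopifnot(region %in% colnames(sim$Q))
  jj <- which(sim$projections$target == region)
  if (!length(jj) && !include_external) {
    stop("region '", region, "' has no afferent projections")
  }
  out <- if (length(jj) == 1L) abs(sim$Vab[, jj]) else
    rowSums(abs(sim$Vab[, jj, drop = FALSE]))
  if (!length(jj)) out <- 0
  if (include_external) out <- out + abs(sim$Vext[, region])
  out
}

#' Geometric dose interpolation between two parameter vectors
#'
#' \code{P = P0 * (P1/P0)^D}: at D = 0 the waking parameters, at D = 1 the
#' altered-state parameters, with saturating change and preserved sign for
#' D > 1.
#'
#' @param P0 waking parameter vector.
#' @param P1 altered-state parameter vector (same layout and signs).
#' @param D dose, >= 0.
#' @return interpolated parameter vector.
#' @export
interpolate_dose <- function(P0, P1, D) {
  stopifnot(length(P0) == length(P1), D >= 0)
  both_zero <- P0 == 0 & P1 == 0
  if (any(P0 == 0 & !both_zero)) {
    stop("dose interpolation undefined where the waking parameter is 0 and the altered one is not")
  }
  if (any(sign(P0) * sign(P1) < 0)) {
    stop("dose interpolation requires matching signs")
  }
  out <- P0
  i <- !both_zero
  out[i] <- sign(P0[i]) * abs(P0[i]) * (abs(P1[i]) / abs(P0[i]))^D
  out
}

# flatten the dose-interpolated parameters of a config to one vector
config_to_vector <- function(config) {
  c(config$populations$Q_max, config$populations$theta,
    config$populations$sigma_prime, config$populations$alpha,
    config$populations$beta, config$projections$nu,
    config$external$mean, config$external$noise_sd)
}

vector_to_config <- function(v, template) {
  P <- nrow(template$populations); J <- nrow(template$projections)
  k <- 0
  take <- function(n) { i <- v[(k + 1):(k + n)]; k <<- k + n; i }
  template$populations$Q_max <- take(P)
  template$populations$theta <- take(P)
  template$populations$sigma_prime <- take(P)
  template$populations$alpha <- take(P)
  template$populations$beta <- take(P)
  template$projections$nu <- take(J)
  template$external$mean <- take(P)
  template$external$noise_sd <- take(P)
  template
}

#' Interpolate a waking and an altered-state configuration at a dose
#'
#' Applies [interpolate_dose()] element-wise to the shared parameter layout
#' (population sigmoid and receptor rates, projection couplings, external
#' drives). Delays and damping are taken from the waking configuration.
#'
#' @param waking,altered \code{nc_config} objects with identical structure.
#' @param D dose, >= 0.
#' @return an \code{nc_config}.
#' @export
interpolate_config <- function(waking, altered, D) {
  stopifnot(identical(waking$populations$label, altered$populations$label),
            identical(waking$projections$source, altered$projections$source),
            identical(waking$projections$target, altered$projections$target))
  v <- interpolate_dose(config_to_vector(waking), config_to_vector(altered), D)
  vector_to_config(v, waking)
}

#' Dose sweep of chaoticity and cross-frequency information transfer
#'
#' For each dose, runs the model \code{n_runs} times, estimating per run the
#' stochastic largest Lyapunov exponent (twin-run divergence of the cortical
#' and thalamic LFPs), the 0-1 test K-statistic of the 1-13 Hz LFP
#' component, and (optionally) the low-to-high-frequency information
#' transfer strength between the cortical and relay LFPs in both directions.
#'
#' @param waking,altered \code{nc_config} endpoint states.
#' @param doses numeric vector of doses.
#' @param n_runs runs (seeds) per dose.
#' @param seed base seed; run seeds are derived deterministically.
#' @param te compute spectral TE strengths (slow; default TRUE).
#' @param n_surr surrogates per TE direction.
#' @param max_centers passed to [kraskov_te()]; the sweep default trades a
#'   little estimator variance for speed.
#' @param duration simulation length per run (s; the first half is the
#'   twin-run baseline, the final 10 s carry the divergence estimate).
#' @return data.frame with one row per dose: median LLE, median K, median
#'   strengths cortex->thalamus and thalamus->cortex, and a \code{flagged}
#'   count of diverged runs.
#' @export
dose_sweep <- function(waking, altered, doses = seq(0, 1, length.out = 5),
                       n_runs = 3, seed = 1, te = TRUE, n_surr = 16,
                       max_centers = 1600, duration = 20) {
  rows <- lapply(seq_along(doses), function(di) {
    D <- doses[di]
    cfg <- interpolate_config(waking, altered, D)
    lle <- numeric(0); K <- numeric(0)
    s_ct <- numeric(0); s_tc <- numeric(0)
    flagged <- 0L
    for (r in seq_len(n_runs)) {
      run_seed <- (seed + 7919L * di + 104729L * r) %% .Machine$integer.max
      est <- tryCatch(
        stochastic_lle(cfg, seed = run_seed, duration = duration),
        error = function(e) NULL)
      if (is.null(est)) { flagged <- flagged + 1L; next }
      lle <- c(lle, est$Lambda)
      sim <- est$sim
      lx <- lfp(sim, "cortex_excitatory")
      ly <- lfp(sim, "relay_nuclei")
      keep <- sim$t >= max(sim$t) - 10 + 1e-9
      # chaoticity on the trial-length window; burst-like regimes can carry
      # too few prominent slow extrema in 10 s, in which case the window is
      # extended to the whole post-transient run
      k_of <- function(l, ks) {
        tryCatch(
          k_statistic(preprocess_for_chaos(l[keep], sim$fs), seed = ks)$K,
          error = function(e) tryCatch(
            k_statistic(preprocess_for_chaos(l[sim$t >= 2], sim$fs),
                        seed = ks)$K,
            error = function(e) NA_real_))
      }
      kx <- k_of(lx, run_seed)
      ky <- k_of(ly, run_seed + 1)
      K <- c(K, median(c(kx, ky), na.rm = TRUE))
      # transfer entropy on the trial-length final window
      lx <- lx[keep]; ly <- ly[keep]
      if (te) {
        x4 <- resample_series(lx, sim$fs, 416)
        y4 <- resample_series(ly, sim$fs, 416)
        bp <- band_pair(send_levels = 5:8, recv_levels = 2)
        r1 <- suppressWarnings(
          soso_test(x4, y4, bp, n_surr = n_surr, seed = run_seed + 2,
                    max_centers = max_centers))
        r2 <- suppressWarnings(
          soso_test(y4, x4, bp, n_surr = n_surr, seed = run_seed + 3,
                    max_centers = max_centers))
        s_ct <- c(s_ct, r1$strength)
        s_tc <- c(s_tc, r2$strength)
      }
    }
    data.frame(dose = D,
               lle = if (length(lle)) median(lle) else NA_real_,
               K = if (length(K)) median(K, na.rm = TRUE) else NA_real_,
               strength_ct = if (length(s_ct)) median(s_ct) else NA_real_,
               strength_tc = if (length(s_tc)) median(s_tc) else NA_real_,
               flagged = flagged)
  })
  do.call(rbind, rows)
}
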