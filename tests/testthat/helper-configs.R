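# shared fixtures: small model configurations and synthetic simulations

# near-zero couplings with valid signs (for fixed-point / decay tests)
null_projections <- function(nu_mag = 1e-12) {
  prj <- bgtc_projections()
  exc <- prj$source %in% c("cortex_excitatory", "STN", "relay_nuclei")
  prj$nu <- ifelse(exc, nu_mag, -nu_mag)
  prj
}

# uncoupled config: every population relaxes toward its external drive
uncoupled_config <- function(alpha = 3, beta = 12, drive = 0.013,
                             noise_sd = 1e-4, duration = 10) {
  pop <- bgtc_populations(alpha = alpha, beta = beta)
  ext <- data.frame(label = pop$label, mean = drive, noise_sd = noise_sd)
  model_config(pop, null_projections(), ext, duration = duration)
}

# a fabricated nc_sim whose cortical LFP equals a supplied series
fake_sim <- function(lfp_series, rates, fs = 1000) {
  n <- length(lfp_series)
  labels <- neurocrit:::BGTC_LABELS
  Q <- matrix(rep(rates[labels], each = n), n, 9,
              dimnames = list(NULL, labels))
  prj <- data.frame(source = "relay_nuclei", target = "cortex_excitatory",
                    nu = 1e-3, tau = 0.04, gamma = 125,
                    stringsAsFactors = FALSE)
  Vext <- matrix(0, n, 9, dimnames = list(NULL, labels))
  structure(list(t = seq_len(n) / fs - 1 / fs,
                 Q = Q, Vab = matrix(lfp_series, ncol = 1), Vext = Vext,
                 projections = prj, fs = fs, dt = 1e-4, seed = 1, dose = 0,
                 config = NULL),
            class = "nc_sim")
}

# the shipped waking/altered states (loaded once per test file as needed)
shipped_config <- function(state) load_state_config(state)
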