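# End-to-end orchestration: the empirical analysis (trials -> spectral TE +
# chaoticity -> group statistics) and the in-silico dose-sweep experiment.

#' Empirical cross-frequency information-transfer pipeline
#'
#' For every subject: cleans and resamples each trial to the working rate,
#' runs the band-pair surrogate test in both directions (low-frequency send
#' levels into the high-gamma receive level) over every cortical-thalamic
#' channel pair (medianed within trial), and estimates trial chaoticity as
#' the median 0-1 test K across channels. Per subject and state it reports
#' cross-trial median strengths and the harmonic-mean p-value; across
#' subjects it runs one-tailed signed-rank tests (altered state versus
#' waking) and a binomial test counting significant subjects.
#'
#' @param subjects named list; each element a list of \code{nc_recording}
#'   objects (one per state) for one subject, each with a \code{state}
#'   label. A waking recording is required; subjects without one are
#'   skipped with a message.
#' @param n_surr surrogates per trial and direction; default 100.
#' @param seed base seed.
#' @param working_fs working rate; default 416.
#' @param send_levels,recv_levels band pair; defaults 5:8 and 2.
#' @param direction alternative hypothesis for altered states relative to
#'   waking: named character vector by state (defaults: anesthesia/seizure
#'   "less", psychedelic "greater").
#' @param max_trials cap on trials per recording (NULL = all).
#' @param max_centers passed to [kraskov_te()].
#' @param emb optional fixed [embedding_spec()] reused for every trial and
#'   direction (skips per-pair selection; keeps the embedding comparable
#'   across trials).
#' @return list of class \code{nc_empirical}: \code{trials} (per-trial
#'   table), \code{subjects} (per subject x state summary), \code{group}
#'   (signed-rank and binomial results).
#' @export
run_empirical <- function(subjects, n_surr = 100, seed = 1,
                          working_fs = 416, send_levels = 5:8,
                          recv_levels = 2,
                          direction = c(anesthesia = "less",
                                        seizure = "less",
                                        psychedelic = "greater"),
                          max_trials = NULL, max_centers = 1600,
                          emb = NULL) {
  if (!length(subjects)) stop("empty recording set")
  if (is.null(names(subjects))) names(subjects) <- paste0("S", seq_along(subjects))
  bp <- band_pair(send_levels, recv_levels, fs = working_fs)
  trial_rows <- list()
  for (si in seq_along(subjects)) {
    subj <- names(subjects)[si]
    recs <- subjects[[si]]
    states <- vapply(recs, `[[`, character(1), "state")
    if (!"waking" %in% states) {
      message("subject ", subj, " lacks a waking baseline; skipped")
      next
    }
    for (rec in recs) {
      trials <- segment_trials(rec)
      if (!is.null(max_trials)) trials <- utils::head(trials, max_trials)
      for (tr in trials) {
        if (isTRUE(tr$artifact_flag)) next
        tr <- clean_trial(tr)
        K <- as.numeric(median_chaoticity(
          lapply(seq_len(ncol(tr$x)), function(j) tr$x[, j]),
          fs = tr$fs, seed = seed + tr$index))
        tr4 <- resample_trial(tr, working_fs)
        ci <- which(tr$region == "cortex")
        ti <- which(tr$region == "thalamus")
        res_ct <- list(); res_tc <- list()
        for (a in ci) for (b in ti) {
          s1 <- suppressWarnings(soso_test(
            tr4$x[, a], tr4$x[, b], bp, n_surr = n_surr,
            seed = seed + 1000L * tr$index + 10L * a + b,
            max_centers = max_centers, emb = emb))
          s2 <- suppressWarnings(soso_test(
            tr4$x[, b], tr4$x[, a], bp, n_surr = n_surr,
            seed = seed + 1000L * tr$index + 10L * b + a + 5L,
            max_centers = max_centers, emb = emb))
          res_ct <- c(res_ct, list(s1)); res_tc <- c(res_tc, list(s2))
        }
        med <- function(rs, f) median(vapply(rs, `[[`, numeric(1), f))
        trial_rows[[length(trial_rows) + 1]] <- data.frame(
          subject = subj, state = rec$state, trial = tr$index,
          strength_ct = med(res_ct, "strength"),
          p_ct = med(res_ct, "p"),
          strength_tc = med(res_tc, "strength"),
          p_tc = med(res_tc, "p"),
          K = K, n_surr = n_surr, seed = seed,
          stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(trial_rows)) stop("no analyzable trials")
  trials_df <- do.call(rbind, trial_rows)

  agg <- function(df) {
    data.frame(subject = df$subject[1], state = df$state[1],
               n_trials = nrow(df),
               median_strength_ct = median(df$strength_ct),
               median_strength_tc = median(df$strength_tc),
               hmp_ct = harmonic_mean_p(df$p_ct),
               hmp_tc = harmonic_mean_p(df$p_tc),
               median_K = median(df$K),
               stringsAsFactors = FALSE)
  }
  subj_df <- do.call(rbind, by(trials_df, list(trials_df$subject, trials_df$state),
                               agg))
  rownames(subj_df) <- NULL
  # baseline-normalized strengths
  base <- subj_df[subj_df$state == "waking", ]
  subj_df$rel_strength_ct <- NA_real_
  subj_df$rel_strength_tc <- NA_real_
  for (i in seq_len(nrow(subj_df))) {
    b <- base[base$subject == subj_df$subject[i], ]
    if (nrow(b) == 1 && b$median_strength_ct != 0) {
      subj_df$rel_strength_ct[i] <-
        normalize_to_baseline(subj_df$median_strength_ct[i],
                              b$median_strength_ct)
    }
    if (nrow(b) == 1 && b$median_strength_tc != 0) {
      subj_df$rel_strength_tc[i] <-
        normalize_to_baseline(subj_df$median_strength_tc[i],
                              b$median_strength_tc)
    }
  }

  group <- list()
  for (st in setdiff(unique(subj_df$state), "waking")) {
    alt <- if (st %in% names(direction)) direction[[st]] else "less"
    sd_ <- subj_df[subj_df$state == st, ]
    common <- intersect(sd_$subject, base$subject)
    if (length(common) >= 5) {
      bw <- base[match(common, base$subject), ]
      sw <- sd_[match(common, sd_$subject), ]
      group[[st]] <- list(
        wilcoxon_ct = wilcoxon_one_tailed(bw$median_strength_ct,
                                          sw$median_strength_ct, alt),
        wilcoxon_tc = wilcoxon_one_tailed(bw$median_strength_tc,
                                          sw$median_strength_tc, alt))
    }
  }
  wk <- subj_df[subj_df$state == "waking", ]
  group$binomial_ct <- binomial_subjects(sum(wk$hmp_ct < 0.05), nrow(wk))
  group$binomial_tc <- binomial_subjects(sum(wk$hmp_tc < 0.05), nrow(wk))

  structure(list(trials = trials_df, subjects = subj_df, group = group),
            class = "nc_empirical")
}

#' In-silico dose-sweep experiment
#'
#' Sweeps anesthetic and seizure 'doses' from the waking configuration,
#' collecting per dose the median stochastic largest Lyapunov exponent, the
#' median 0-1 test K of the 1-13 Hz LFP component, and the median
#' bidirectional cross-frequency information-transfer strengths between the
#' cortical and thalamic relay LFPs.
#'
#' @param waking_cfg,anesthesia_cfg,seizure_cfg \code{nc_config} endpoints.
#' @param doses dose grid per arm; default 5 points on [0, 1].
#' @param n_runs runs per dose; default 3.
#' @param seed base seed.
#' @param ... passed to [dose_sweep()].
#' @return data.frame with an \code{arm} column (\code{"anesthetic"} /
#'   \code{"seizure"}); attribute \code{k_lle_spearman} holds the pooled
#'   Spearman correlation between per-dose median K and median LLE.
#' @export
run_insilico <- function(waking_cfg, anesthesia_cfg, seizure_cfg,
                         doses = seq(0, 1, length.out = 5), n_runs = 3,
                         seed = 1, ...) {
  an <- dose_sweep(waking_cfg, anesthesia_cfg, doses = doses,
                   n_runs = n_runs, seed = seed, ...)
  an$arm <- "anesthetic"
  sz <- dose_sweep(waking_cfg, seizure_cfg, doses = doses[doses > 0],
                   n_runs = n_runs, seed = seed + 5000L, ...)
  sz$arm <- "seizure"
  out <- rbind(an, sz)
  ok <- stats::complete.cases(out[, c("K", "lle")])
  rho <- if (sum(ok) >= 3) {
    suppressWarnings(stats::cor(out$K[ok], out$lle[ok], method = "spearman"))
  } else NA_real_
  attr(out, "k_lle_spearman") <- rho
  out
}
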