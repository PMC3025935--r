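# Cohort-level simulation.
#
# Two generators at different fidelities: `simulate_stage_cohort()` draws
# subject-by-stage summary tables directly (model truth plus instrument
# noise) for fast statistical validation, and `simulate_lbnp_cohort()` runs
# the full waveform loop (synthesize -> extract) for closed-loop parameter
# recovery.

#' Simulate a subject-by-stage summary cohort
#'
#' Emulates the measurement situation of an LBNP study at the stage-table
#' level.  Per subject, baseline diastole and heart rate are drawn from the
#' cohort distributions (systole fixed at the baseline value since it does
#' not change appreciably under LBNP); stage shifts are scaled by
#' per-subject responsiveness multipliers.  Three instruments observe every
#' stage:
#' \itemize{
#'   \item `T13_mean`: the model's T13 at the stage pressure state plus a
#'     small stage-mean extraction error (default sd 0.3 ms -- the
#'     beat-level jitter averaged over a stage's worth of beats);
#'   \item `PP_cuff`: the mean of `cuff_readings` automatic-cuff readings
#'     (default 4 per stage) each with sd `cuff_sd` (default 20 mmHg for
#'     the derived pulse pressure: systolic and diastolic cuff errors plus
#'     between-reading physiological variability compound, which is why
#'     cuffs cannot resolve few-mmHg pulse-pressure changes -- the
#'     stage-mean sd of 10 mmHg is on the scale implied by the reported
#'     cohort standard errors);
#'   \item `PP_finapres`: a continuous finger-cuff monitor stage mean with
#'     sd `finapres_sd` (default 8 mmHg; finger pulse pressure is dominated
#'     by peripheral vasomotor drift, so it tracks central pulse pressure
#'     poorly).
#' }
#'
#' @param n_subjects number of subjects.
#' @param stages stage schedule (see [default_lbnp_stages()]).
#' @param segments,coeffs forward-model parameters.
#' @param t13_se,cuff_sd,cuff_readings,finapres_sd,hr_se instrument noise.
#' @param diastole_base_sd,hr_base_sd between-subject sd of baseline
#'   diastole (mmHg) and heart rate (bpm).
#' @param null if TRUE, remove all stage effects (for type-I error
#'   calibration).
#' @param seed integer seed.
#' @return a `stage_table`-compatible data.frame with columns `subject`,
#'   `lbnp`, `missing`, `T13_mean`, `PP_cuff`, `PP_finapres`, `HR_mean`,
#'   `PP_true`.
#' @export
simulate_stage_cohort <- function(n_subjects = 15,
                                  stages = default_lbnp_stages(),
                                  segments = default_segments(),
                                  coeffs = reflection_coefficients(),
                                  t13_se = 0.3, cuff_sd = 20,
                                  cuff_readings = 4, finapres_sd = 8,
                                  hr_se = 1, diastole_base_sd = 4,
                                  hr_base_sd = 7, null = FALSE, seed = 1) {
  ## memoize the forward model: many subjects share (rounded) diastole
  memo <- new.env(parent = emptyenv())
  t13_of <- function(state) {
    key <- sprintf("%.4f", state$Pdiast)
    got <- get0(key, envir = memo)
    if (is.null(got)) {
      got <- arrival_times(state, segments, coeffs)$T13
      assign(key, got, envir = memo)
    }
    got
  }
  with_seed(seed, {
    k <- nrow(stages)
    n <- n_subjects * k
    subject <- character(n); lbnp <- numeric(n); t13v <- numeric(n)
    cuff <- numeric(n); fin <- numeric(n); hr <- numeric(n); ppt <- numeric(n)
    r <- 0L
    for (i in seq_len(n_subjects)) {
      d0 <- min(88, max(72, stats::rnorm(1, 80, diastole_base_sd)))
      hr0 <- stats::rnorm(1, 65, hr_base_sd)
      mult_d <- stats::runif(1, 0.7, 1.3)
      mult_h <- stats::runif(1, 0.3, 1.5)
      for (s in seq_len(k)) {
        dshift <- if (null) 0 else stages$diastole_shift[s] * mult_d
        hshift <- if (null) 0 else stages$hr_shift[s] * mult_h
        state <- pressure_state(120, d0 + dshift)
        r <- r + 1L
        subject[r] <- sprintf("s%02d", i)
        lbnp[r] <- stages$lbnp[s]
        t13v[r] <- t13_of(state) + stats::rnorm(1, 0, t13_se)
        cuff[r] <- state$PPulse + mean(stats::rnorm(cuff_readings, 0, cuff_sd))
        fin[r] <- state$PPulse + stats::rnorm(1, 0, finapres_sd)
        hr[r] <- hr0 + hshift + stats::rnorm(1, 0, hr_se)
        ppt[r] <- state$PPulse
      }
    }
    structure(data.frame(subject = subject, lbnp = lbnp, missing = FALSE,
                         T13_mean = t13v, PP_cuff = cuff, PP_finapres = fin,
                         HR_mean = hr, PP_true = ppt),
              class = c("stage_table", "data.frame"))
  })
}

#' Full closed-loop LBNP cohort: synthesize, extract, aggregate
#'
#' For each subject, builds a model-linked [session_spec()] with
#' subject-specific baseline diastole/heart rate and stage responsiveness,
#' synthesizes the 512 Hz derivative stream, runs [extract_beats()] and
#' aggregates per-stage means of both the extracted and the ground-truth
#' T13.
#'
#' @param n_subjects number of subjects.
#' @param stage_duration_s seconds per stage (scaled down from the
#'   ~12-minute chamber stages; 30 s gives ~30 beats per stage).
#' @param noise_sd derivative-stream noise (fraction of primary amplitude).
#' @param seed master seed; per-subject seeds are derived from it.
#' @param sample_rate sampling rate in Hz.
#' @param segments,coeffs forward-model parameters.
#' @param opts extractor options.
#' @return data.frame with one row per subject x stage: `subject`, `lbnp`,
#'   `n_beats`, `true_T13`, `extracted_T13`, `true_P2P1`,
#'   `extracted_P2P1`, plus attribute `quality` (per-subject quality
#'   reports).
#' @export
simulate_lbnp_cohort <- function(n_subjects = 15, stage_duration_s = 30,
                                 noise_sd = 0.02, seed = 1,
                                 sample_rate = 512,
                                 segments = default_segments(),
                                 coeffs = reflection_coefficients(),
                                 opts = extract_opts()) {
  rows <- list()
  quality <- list()
  for (i in seq_len(n_subjects)) {
    subj_seed <- derive_seed(seed, i)
    draws <- with_seed(subj_seed, list(
      d0 = min(88, max(72, stats::rnorm(1, 80, 4))),
      hr0 = min(85, max(50, stats::rnorm(1, 65, 7))),
      mult_d = stats::runif(1, 0.7, 1.3),
      mult_h = stats::runif(1, 0.3, 1.5)))
    stages <- default_lbnp_stages(duration_s = stage_duration_s)
    stages$diastole_shift <- stages$diastole_shift * draws$mult_d
    stages$hr_shift <- stages$hr_shift * draws$mult_h
    spec <- session_spec(stages = stages, sample_rate = sample_rate,
                         noise_sd = noise_sd, seed = derive_seed(subj_seed, 7),
                         base_state = pressure_state(120, draws$d0),
                         base_hr = draws$hr0)
    ses <- synthesize_session(spec, segments, coeffs)
    ex <- extract_beats(ses, opts)
    subj <- sprintf("s%02d", i)
    agg <- stage_aggregate(stats::setNames(list(ex$beats), subj),
                           schedule = stages)
    truth_mean <- stats::aggregate(
      ses$truth[c("t13_ms", "p2p1")], by = list(lbnp = ses$truth$lbnp), mean)
    merged <- merge(agg, truth_mean, by = "lbnp")
    rows[[i]] <- data.frame(subject = subj, lbnp = merged$lbnp,
                            n_beats = merged$n_beats,
                            true_T13 = merged$t13_ms,
                            extracted_T13 = merged$T13_mean,
                            true_P2P1 = merged$p2p1,
                            extracted_P2P1 = merged$P2P1_mean)
    quality[[subj]] <- ex$quality
  }
  structure(do.call(rbind, rows), quality = quality)
}

#' Closed-loop recovery summary
#'
#' Regresses extracted per-stage mean T13 on the synthesizer ground truth
#' and reports the recovery slope and RMSE (ms).
#'
#' @param cohort output of [simulate_lbnp_cohort()].
#' @return list with `slope`, `intercept`, `rmse_ms`, `bias_ms`, `n`.
#' @export
closed_loop_recovery <- function(cohort) {
  ok <- stats::complete.cases(cohort$true_T13, cohort$extracted_T13)
  x <- cohort$true_T13[ok]
  y <- cohort$extracted_T13[ok]
  fit <- stats::lm(y ~ x)
  list(slope = unname(stats::coef(fit)[2]),
       intercept = unname(stats::coef(fit)[1]),
       rmse_ms = sqrt(mean((y - x)^2)),
       bias_ms = mean(y - x), n = length(x))
}
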