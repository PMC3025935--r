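# Cohort statistics: aggregation, OLS fits, repeated-measures ANOVA, ROC.

make_beats <- function(t13, onset_s, p2p1 = 0.3) {
  data.frame(onset_s = onset_s, T13 = t13, P2P1 = p2p1, valid = TRUE)
}

test_that("stage_aggregate: constant input, known delta, missing stages", {
  sch <- data.frame(lbnp = c(0, -15), duration_s = c(30, 30))
  beats <- make_beats(t13 = c(rep(240, 20), rep(220, 20)),
                      onset_s = c(seq(0, 29, length = 20),
                                  seq(30, 59, length = 20)))
  st <- stage_aggregate(beats, sch)
  expect_equal(st$T13_mean, c(240, 220))
  expect_equal(st$T13_se, c(0, 0))
  expect_equal(diff(st$T13_mean), -20, tolerance = 3)
  expect_false(any(st$missing))

  # a stage without valid beats is flagged, not fabricated
  beats2 <- beats
  beats2$valid[21:40] <- FALSE
  st2 <- stage_aggregate(beats2, sch)
  expect_true(st2$missing[st2$lbnp == -15])
  expect_true(is.na(st2$T13_mean[st2$lbnp == -15]))
})

test_that("closed-loop stage delta is recovered within 3 ms", {
  st <- data.frame(lbnp = c(0, -60), duration_s = 20,
                   diastole_shift = c(0, 8), hr_shift = c(0, 0))
  ses <- synthesize_session(session_spec(stages = st, seed = 31))
  ex <- extract_beats(ses)
  agg <- stage_aggregate(ex$beats, st)
  true_delta <- diff(tapply(ses$truth$t13_ms, ses$truth$lbnp, mean)[
    as.character(c(0, -60))])
  est_delta <- diff(agg$T13_mean[match(c(0, -60), agg$lbnp)])
  expect_lt(abs(est_delta - true_delta), 3)
})

test_that("OLS fits recover the printed calibration line exactly", {
  x <- seq(150, 260, by = 5)
  y <- 0.19 * x + 2.58
  f <- fit_linear(x, y)
  expect_equal(unname(f$coefficients), c(2.58, 0.19), tolerance = 1e-10)
  expect_equal(f$r_squared, 1, tolerance = 1e-10)

  # constant response: zero slope, zero R^2
  f0 <- fit_linear(x, rep(5, length(x)))
  expect_equal(unname(f0$coefficients[2]), 0, tolerance = 1e-12)
  expect_equal(f0$r_squared, 0)

  # pure quadratic on symmetric x: linear slope 0, quadratic exact
  xs <- -5:5
  fq_lin <- fit_linear(xs, xs^2)
  expect_equal(unname(fq_lin$coefficients[2]), 0, tolerance = 1e-12)
  fq <- fit_quadratic(xs, xs^2)
  expect_equal(unname(fq$coefficients), c(0, 0, 1), tolerance = 1e-10)
  expect_equal(fq$r_squared, 1, tolerance = 1e-12)

  expect_error(fit_linear(rep(1, 5), 1:5), "degenerate")
  expect_error(fit_linear(1:2, 1:2), "3")
})

test_that("rm_anova: null, strong effect, and degenerate inputs", {
  # identical subjects across stages: no effect, p = 1
  flat <- data.frame(subject = rep(paste0("s", 1:6), each = 3),
                     lbnp = rep(c(0, -15, -30), 6), missing = FALSE,
                     T13_mean = rep(c(240, 250, 260), each = 3))
  expect_equal(rm_anova(flat, stages = c(0, -15, -30))$p_value, 1)

  # stage effect 10x the noise sd resolves at p < 0.01
  set.seed(77)
  eff <- data.frame(subject = rep(paste0("s", 1:15), each = 3),
                    lbnp = rep(c(0, -15, -30), 15), missing = FALSE,
                    T13_mean = rep(c(0, -10, -20), 15) +
                      rnorm(45, sd = 1) + rep(rnorm(15, 240, 8), each = 3))
  expect_lt(rm_anova(eff, stages = c(0, -15, -30))$p_value, 0.01)

  # pooled mode collapses the non-baseline stages
  a <- rm_anova(eff, stages = c(0, -15, -30), mode = "pooled")
  expect_equal(a$df[1], 1)
  expect_lt(a$p_value, 0.01)

  expect_error(rm_anova(flat[flat$subject == "s1", ]), "2 subjects")
})

test_that("rm_anova p-values are uniform under the null (KS)", {
  ps <- vapply(1:200, function(k) {
    st <- simulate_stage_cohort(n_subjects = 10, null = TRUE,
                                seed = 5000 + k)
    rm_anova(st, "T13_mean", stages = c(0, -15, -30))$p_value
  }, numeric(1))
  expect_gt(stats::ks.test(ps, "punif")$p.value, 0.01)
})

test_that("roc_stage: perfect separation, null, and input validation", {
  mk <- function(d15, d30) {
    data.frame(subject = rep(paste0("s", seq_along(d15)), each = 3),
               lbnp = rep(c(0, -15, -30), length(d15)), missing = FALSE,
               T13_mean = as.vector(rbind(240, 240 + d15, 240 + d30)))
  }
  # -30 deltas all below -15 deltas: AUC 1
  sep <- mk(d15 = c(-1, -2, -1.5, -1.2, -0.8), d30 = c(-8, -9, -7, -10, -8.5))
  r <- roc_stage(sep, "T13_mean", -15, -30)
  expect_equal(r$auc, 1)
  expect_true(all(diff(r$curve$sensitivity) >= 0))

  # identical delta distributions: AUC near 1/2
  set.seed(3)
  aucs <- vapply(1:50, function(i) {
    d <- rnorm(8); e <- rnorm(8)
    roc_stage(mk(d, e), "T13_mean", -15, -30)$auc
  }, numeric(1))
  expect_lt(abs(mean(aucs) - 0.5), 0.08)

  expect_error(roc_stage(mk(c(-1, -2), c(-3, -4)), "T13_mean", -15, -30),
               "4 paired")
})

test_that("listwise deletion mirrors the incomplete -60 mmHg design", {
  st <- simulate_stage_cohort(n_subjects = 8, seed = 41)
  # four presyncopal subjects lose their deepest stage
  drop <- st$subject %in% paste0("s0", 1:4) & st$lbnp == -60
  st$missing[drop] <- TRUE
  expect_warning(a <- rm_anova(st, "T13_mean"), "listwise")
  expect_equal(a$n_subjects, 4)
})
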