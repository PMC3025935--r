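# Cohort statistics: stage aggregation, regressions, repeated-measures
# ANOVA and ROC stage discrimination -- the machinery used to evaluate T13
# as a pulse-pressure surrogate against reference instruments.

#' Aggregate beat tables into a subject-by-stage table
#'
#' Maps each beat to its LBNP stage through the stage schedule (cumulative
#' stage durations over the session clock) and reports per subject x stage
#' means and standard errors of the beat metrics.  Invalid beats are
#' excluded; a stage with no valid beats is flagged missing.
#'
#' @param beat_tables named list of beat data.frames (one per subject, as
#'   returned in `extract_beats()$beats`), or a single data.frame for a
#'   one-subject session.
#' @param schedule stage schedule data.frame with columns `lbnp` and
#'   `duration_s` (a single schedule shared by all subjects, or a named
#'   list of per-subject schedules).
#' @return data.frame of class `stage_table`: one row per subject x stage
#'   with columns `subject`, `lbnp`, `n_beats`, `T13_mean`, `T13_se`,
#'   `P2P1_mean`, `P2P1_se`, `HR_mean`, `missing`.
#' @export
stage_aggregate <- function(beat_tables, schedule) {
  if (is.data.frame(beat_tables)) beat_tables <- list(s1 = beat_tables)
  if (is.null(names(beat_tables)) || any(names(beat_tables) == ""))
    names(beat_tables) <- paste0("s", seq_along(beat_tables))
  per_subject_schedule <- is.list(schedule) && !is.data.frame(schedule)
  out <- list()
  for (subj in names(beat_tables)) {
    beats <- beat_tables[[subj]]
    sch <- if (per_subject_schedule) schedule[[subj]] else schedule
    if (!all(c("lbnp", "duration_s") %in% names(sch)))
      stop_invalid("schedule needs columns lbnp and duration_s")
    edges <- c(0, cumsum(sch$duration_s))
    stage_of <- cut(beats$onset_s, breaks = edges, labels = FALSE,
                    include.lowest = TRUE, right = FALSE)
    for (s in seq_len(nrow(sch))) {
      sel <- which(stage_of == s)
      valid <- sel[beats$valid[sel] & !is.na(beats$T13[sel])]
      hr <- if (length(sel) >= 3L)
        60 / mean(diff(beats$onset_s[sel])) else NA_real_
      if (!length(valid)) {
        out[[length(out) + 1L]] <- data.frame(
          subject = subj, lbnp = sch$lbnp[s], n_beats = 0L,
          T13_mean = NA_real_, T13_se = NA_real_, P2P1_mean = NA_real_,
          P2P1_se = NA_real_, HR_mean = hr, missing = TRUE)
        next
      }
      t13 <- beats$T13[valid]
      p2p1 <- beats$P2P1[valid]
      se <- function(v) if (length(v) > 1L) stats::sd(v) / sqrt(length(v)) else 0
      out[[length(out) + 1L]] <- data.frame(
        subject = subj, lbnp = sch$lbnp[s], n_beats = length(valid),
        T13_mean = mean(t13), T13_se = se(t13),
        P2P1_mean = mean(p2p1, na.rm = TRUE),
        P2P1_se = se(p2p1[!is.na(p2p1)]), HR_mean = hr, missing = FALSE)
    }
  }
  structure(do.call(rbind, out), class = c("stage_table", "data.frame"))
}

fit_result <- function(fit, n) {
  s <- suppressWarnings(summary(fit))  # exact fits are legitimate here
  co <- stats::coef(s)
  ## R^2 computed directly so a constant response gives 0, not 0/0
  y <- stats::fitted(fit) + stats::resid(fit)
  tss <- sum((y - mean(y))^2)
  r2 <- if (tss <= .Machine$double.eps * max(1, sum(y^2))) 0
        else 1 - sum(stats::resid(fit)^2) / tss
  structure(list(coefficients = co[, "Estimate"],
                 se = co[, "Std. Error"],
                 r_squared = r2,
                 p_value = if (nrow(co) > 1L)
                   co[2L, "Pr(>|t|)"] else NA_real_,
                 n = n, fit = fit),
            class = "pda_fit")
}

#' Ordinary least squares fits of stage-level summaries
#'
#' `fit_linear` regresses y on x (e.g. pulse pressure on T13, the
#' calibration relation of the pulse-pressure surrogate); `fit_quadratic`
#' adds a squared term (needed, for example, to relate T13 to heart rate).
#'
#' @param x,y numeric vectors of equal length (at least 3 points for
#'   linear, 4 for quadratic; x must have positive variance).
#' @return object of class `pda_fit` with `coefficients`, `se`,
#'   `r_squared`, `p_value` (slope t-test) and the underlying `lm` fit.
#' @export
fit_linear <- function(x, y) {
  ok <- stats::complete.cases(x, y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3L) stop_invalid("need at least 3 complete points")
  if (stats::var(x) == 0) stop_invalid("x is degenerate (zero variance)")
  fit_result(stats::lm(y ~ x), length(x))
}

#' @rdname fit_linear
#' @export
fit_quadratic <- function(x, y) {
  ok <- stats::complete.cases(x, y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 4L) stop_invalid("need at least 4 complete points")
  if (stats::var(x) == 0) stop_invalid("x is degenerate (zero variance)")
  fit_result(stats::lm(y ~ x + I(x^2)), length(x))
}

#' @export
print.pda_fit <- function(x, ...) {
  cat("<pda_fit R^2 =", signif(x$r_squared, 4),
      " p =", signif(x$p_value, 3), ">\n  coefficients:",
      paste(signif(x$coefficients, 6), collapse = ", "), "\n")
  invisible(x)
}

## Wide subject x stage matrix for a value column, listwise-deleted.
stage_matrix <- function(stage_table, value, stages) {
  st <- stage_table[stage_table$lbnp %in% stages & !stage_table$missing, ]
  subjects <- unique(st$subject)
  m <- matrix(NA_real_, length(subjects), length(stages),
              dimnames = list(subjects, as.character(stages)))
  for (i in seq_len(nrow(st)))
    m[as.character(st$subject[i]), as.character(st$lbnp[i])] <- st[[value]][i]
  complete <- stats::complete.cases(m)
  if (any(!complete))
    warning(sum(!complete), " subject(s) without complete stage data ",
            "dropped (listwise deletion)")
  m[complete, , drop = FALSE]
}

#' Repeated-measures ANOVA for a stage effect
#'
#' One-way within-subject ANOVA of a stage-table column over a subset of
#' LBNP stages.  `mode = "joint"` tests the stage factor across all chosen
#' stages; `mode = "pooled"` averages the non-baseline stages per subject
#' and tests that pool against the baseline (two-level within design),
#' matching the reading of a "stages versus atmospheric" comparison.
#' An optional Greenhouse-Geisser correction adjusts the degrees of freedom
#' for sphericity violations (off by default).
#'
#' @param stage_table a `stage_table` (see [stage_aggregate()]), or any
#'   data.frame with `subject`, `lbnp`, `missing` and the value column.
#' @param value name of the column to analyze (default `"T13_mean"`).
#' @param stages LBNP stages to include (default: all present).
#' @param mode `"joint"` or `"pooled"`.
#' @param baseline LBNP value of the baseline stage (used by `"pooled"`).
#' @param gg_correction apply the Greenhouse-Geisser epsilon.
#' @return list with `F`, `df`, `p_value`, `n_subjects`, `epsilon`.
#' @export
rm_anova <- function(stage_table, value = "T13_mean", stages = NULL,
                     mode = c("joint", "pooled"), baseline = 0,
                     gg_correction = FALSE) {
  mode <- match.arg(mode)
  stages <- stages %||% sort(unique(stage_table$lbnp), decreasing = TRUE)
  m <- stage_matrix(stage_table, value, stages)
  if (mode == "pooled") {
    if (!as.character(baseline) %in% colnames(m))
      stop_invalid("baseline stage ", baseline, " not present")
    others <- setdiff(colnames(m), as.character(baseline))
    m <- cbind(baseline = m[, as.character(baseline)],
               pooled = rowMeans(m[, others, drop = FALSE]))
  }
  n <- nrow(m)
  k <- ncol(m)
  if (n < 2L) stop_invalid("need at least 2 subjects with complete rows")
  grand <- mean(m)
  row_m <- rowMeans(m)
  col_m <- colMeans(m)
  ss_subj <- k * sum((row_m - grand)^2)
  ss_stage <- n * sum((col_m - grand)^2)
  ss_tot <- sum((m - grand)^2)
  ss_err <- max(0, ss_tot - ss_subj - ss_stage)
  df1 <- k - 1
  df2 <- (k - 1) * (n - 1)
  eps <- 1
  if (gg_correction && k > 2L) {
    S <- stats::cov(m)
    C <- S - outer(rowMeans(S), rep(1, k)) - outer(rep(1, k), colMeans(S)) +
      mean(S)
    eps <- sum(diag(C))^2 / ((k - 1) * sum(C^2))
    eps <- max(1 / (k - 1), min(1, eps))
  }
  if (ss_stage <= .Machine$double.eps * max(1, ss_tot)) {
    f <- 0
    p <- 1
  } else if (ss_err <= .Machine$double.eps * max(1, ss_tot)) {
    f <- Inf
    p <- .Machine$double.xmin
  } else {
    f <- (ss_stage / df1) / (ss_err / df2)
    p <- stats::pf(f, df1 * eps, df2 * eps, lower.tail = FALSE)
    p <- max(p, .Machine$double.xmin)
  }
  list(F = f, df = c(df1, df2), p_value = p, n_subjects = n,
       stages = stages, mode = mode, epsilon = eps)
}

#' ROC discrimination of two LBNP stages from baseline deltas
#'
#' Per subject, the intra-subject change from atmospheric baseline is
#' computed for both stages; the ROC then measures how well these paired
#' delta distributions separate, i.e. whether the instrument resolves the
#' difference between the two stages relative to atmospheric pressure.  The
#' AUC is the rank (Mann-Whitney) statistic `P(delta_b < delta_a)` under the
#' default orientation `direction = "less"` (the deeper stage shifts the
#' value downward, as for T13 and pulse pressure); use `"greater"` for
#' values that rise with LBNP depth (heart rate).
#'
#' @param stage_table a `stage_table`.
#' @param value column to analyze.
#' @param stage_a,stage_b the two LBNP stages to discriminate.
#' @param baseline LBNP value of the atmospheric stage.
#' @param direction `"less"` or `"greater"`: expected direction of the
#'   deeper stage `stage_b` relative to `stage_a`.
#' @return list with `auc`, `n` (subjects contributing), and `curve`
#'   (data.frame `threshold`, `sensitivity`, `specificity`).
#' @export
roc_stage <- function(stage_table, value = "T13_mean", stage_a = -15,
                      stage_b = -30, baseline = 0,
                      direction = c("less", "greater")) {
  direction <- match.arg(direction)
  m <- stage_matrix(stage_table, value, c(baseline, stage_a, stage_b))
  if (nrow(m) < 4L)
    stop_invalid("fewer than 4 paired observations")
  da <- m[, as.character(stage_a)] - m[, as.character(baseline)]
  db <- m[, as.character(stage_b)] - m[, as.character(baseline)]
  if (direction == "greater") {
    da <- -da
    db <- -db
  }
  cmp <- outer(db, da, `<`) + 0.5 * outer(db, da, `==`)
  auc <- mean(cmp)
  thr <- sort(unique(c(da, db, -Inf, Inf)))
  curve <- data.frame(
    threshold = thr,
    sensitivity = vapply(thr, function(t) mean(db <= t), numeric(1)),
    specificity = vapply(thr, function(t) mean(da > t), numeric(1)))
  list(auc = auc, n = nrow(m), curve = curve, direction = direction)
}
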