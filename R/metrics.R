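# Evaluation metrics for competing-risk waitlist models.
#
# Prediction containers used throughout:
#   * mass array  — n x K x T joint probability mass (competing-risk model),
#   * risk matrix — n x T per-month risk curve for one event (CIF for the
#     competing-risk model, 1 - S(t) for single-risk models, a constant
#     column for score-based rankings such as MELD).
# Outcomes are a data.frame with integer event_type (0/1/2) and
# event_month (bins, 0-based).

check_outcomes <- function(outcomes, n = NULL) {
  stopifnot(is.data.frame(outcomes),
            all(c("event_type", "event_month") %in% names(outcomes)))
  if (!is.null(n) && nrow(outcomes) != n) {
    stopf("predictions and outcomes disagree on patient count (%d vs %d)",
          n, nrow(outcomes))
  }
  outcomes
}

#' Competing event coherence (CEC, mu-score) for a competing-risk model
#'
#' For every patient with an actual event (death or transplant) in a bin at
#' or before the horizon, the prediction is coherent (`mu = 1`) when the
#' strictly largest predicted event mass at the patient's own event month
#' belongs to the event that occurred; ties count as incoherent. The score
#' is the mean of `mu` over those M patients; censored patients and events
#' after the horizon are excluded.
#'
#' @param mass n x K x T array of per-patient event-month mass (K = 2,
#'   ordered death then transplant).
#' @param outcomes outcome data.frame (`event_type`, `event_month`).
#' @param horizon month bin (0-based) closing the evaluation window.
#' @return the mu-score in `[0, 1]`.
#' @export
cec_score <- function(mass, outcomes, horizon) {
  stopifnot(length(dim(mass)) == 3, dim(mass)[2] == 2)
  outcomes <- check_outcomes(outcomes, dim(mass)[1])
  if (horizon < 0 || horizon >= dim(mass)[3]) {
    stopf("horizon must lie in 0..%d", dim(mass)[3] - 1L)
  }
  sel <- which(outcomes$event_type %in% c(EVENT_DEATH, EVENT_TRANSPLANT) &
                 outcomes$event_month <= horizon)
  if (length(sel) == 0) {
    stopf("CEC undefined: no patient has an event at or before bin %d",
          horizon)
  }
  l <- outcomes$event_month[sel] + 1L
  r_death <- mass[cbind(sel, 1L, l)]
  r_tx <- mass[cbind(sel, 2L, l)]
  mu <- ifelse(outcomes$event_type[sel] == EVENT_DEATH,
               r_death > r_tx, r_tx > r_death)
  mean(mu)
}

#' CEC for a pair of cause-specific single-risk models
#'
#' Single-risk models cannot emit a joint event-month mass, so coherence
#' compares the two models' cumulative event probabilities at the
#' patient's event month: `mu = 1` iff the model for the event that
#' occurred assigns the strictly larger probability. With two identical
#' models every comparison ties and the score is 0.
#'
#' @param models named list (`death`, `transplant`); each element either a
#'   fitted single-risk model (see [fit_cause_specific()]) or an n x T
#'   risk matrix.
#' @param cohort a `wl_cohort` (only outcomes and covariates are used;
#'   covariates are needed when `models` holds fitted models).
#' @param horizon month bin closing the evaluation window.
#' @return the mu-score in `[0, 1]`.
#' @export
cec_score_single_risk <- function(models, cohort, horizon) {
  stopifnot(all(c("death", "transplant") %in% names(models)))
  outcomes <- cohort$outcomes
  n <- nrow(outcomes)
  as_matrix <- function(m) {
    if (is.matrix(m)) return(m)
    predict_event_probability(m, cohort$covariates,
                              t = seq_len(cohort$horizon) - 1L)
  }
  p_death <- as_matrix(models$death)
  p_tx <- as_matrix(models$transplant)
  stopifnot(nrow(p_death) == n, nrow(p_tx) == n)
  if (horizon < 0 || horizon >= ncol(p_death)) {
    stopf("horizon must lie in 0..%d", ncol(p_death) - 1L)
  }
  sel <- which(outcomes$event_type %in% c(EVENT_DEATH, EVENT_TRANSPLANT) &
                 outcomes$event_month <= horizon)
  if (length(sel) == 0) {
    stopf("CEC undefined: no patient has an event at or before bin %d",
          horizon)
  }
  l <- outcomes$event_month[sel] + 1L
  pd <- p_death[cbind(sel, l)]
  pt <- p_tx[cbind(sel, l)]
  mu <- ifelse(outcomes$event_type[sel] == EVENT_DEATH, pd > pt, pt > pd)
  mean(mu)
}

#' Relabel the competing event as censoring
#'
#' @param outcomes outcome data.frame.
#' @param event the event of interest (1/"death" or 2/"transplant").
#' @return outcomes with the competing event's type set to 0; months kept.
#' @export
censor_competing <- function(outcomes, event) {
  ev <- resolve_event(event)
  competing <- setdiff(c(EVENT_DEATH, EVENT_TRANSPLANT), ev)
  outcomes$event_type[outcomes$event_type == competing] <- EVENT_CENSORED
  outcomes
}

#' Time-dependent concordance index
#'
#' Antolini-style time-dependent C-index restricted to events at or before
#' the horizon, with the competing event treated as censoring. A pair
#' (i, j) is comparable when i has the event of interest in bin `l_i <=
#' horizon` and j is still under observation strictly after `l_i`;
#' it is concordant when i's predicted risk at `l_i` exceeds j's predicted
#' risk at the same bin, with predictor ties counting 1/2.
#'
#' @param predictions n x T risk matrix for the event of interest.
#' @param outcomes outcome data.frame (competing event is relabelled
#'   internally, so pre-relabelled input is accepted unchanged).
#' @param event event of interest.
#' @param horizon month bin closing the evaluation window.
#' @return the concordance in `[0, 1]`.
#' @export
td_concordance <- function(predictions, outcomes, event, horizon) {
  ev <- resolve_event(event)
  predictions <- as.matrix(predictions)
  outcomes <- check_outcomes(outcomes, nrow(predictions))
  outcomes <- censor_competing(outcomes, ev)
  time <- outcomes$event_month
  is_event <- outcomes$event_type == ev
  cases <- which(is_event & time <= horizon)
  num <- 0
  den <- 0
  for (i in cases) {
    at_risk <- which(time > time[i])
    if (length(at_risk) == 0) next
    pi <- predictions[i, time[i] + 1L]
    pj <- predictions[at_risk, time[i] + 1L]
    num <- num + sum(pi > pj) + 0.5 * sum(pi == pj)
    den <- den + length(at_risk)
  }
  if (den == 0) {
    stopf("C-index undefined: no comparable pairs at horizon bin %d", horizon)
  }
  num / den
}

# Kaplan-Meier of the censoring distribution; returns a step-function pair
# (times, surv) with the convention that at tied bins events precede
# censorings, so G(t-) is the product over censoring bins strictly < t.
censoring_km <- function(outcomes, event) {
  outcomes <- censor_competing(outcomes, event)
  cens <- as.integer(outcomes$event_type == EVENT_CENSORED)
  fit <- survival::survfit(
    survival::Surv(outcomes$event_month, cens) ~ 1)
  list(times = fit$time, surv = fit$surv)
}

km_eval <- function(km, t, left = FALSE) {
  # step-function evaluation; left = TRUE gives G(t-)
  vapply(t, function(tt) {
    keep <- if (left) km$times < tt else km$times <= tt
    if (!any(keep)) 1 else km$surv[max(which(keep))]
  }, numeric(1))
}

#' IPCW Brier score at a horizon
#'
#' Graf-style inverse-probability-of-censoring-weighted Brier score with
#' the competing event treated as censoring. With `G` the Kaplan-Meier
#' estimate of the censoring survival function,
#' `(1/n) * sum[ (1 - p_i)^2 / G(l_i-)` for patients with the event by the
#' horizon `+ p_i^2 / G(horizon)` for patients observed event-free past
#' the horizon `]`; patients censored at or before the horizon get weight
#' zero but stay in the denominator n.
#'
#' @param predictions n-vector of predicted event probabilities at the
#'   horizon, or an n x T risk matrix (its horizon column is used).
#' @param outcomes outcome data.frame.
#' @param event event of interest.
#' @param horizon month bin.
#' @return the Brier score (non-negative).
#' @export
brier_score <- function(predictions, outcomes, event, horizon) {
  ev <- resolve_event(event)
  if (is.matrix(predictions)) predictions <- predictions[, horizon + 1L]
  outcomes <- check_outcomes(outcomes, length(predictions))
  relab <- censor_competing(outcomes, ev)
  time <- relab$event_month
  is_event <- relab$event_type == ev
  km <- censoring_km(outcomes, ev)
  n <- length(predictions)
  had_event <- is_event & time <= horizon
  event_free <- time > horizon
  g_event <- km_eval(km, time[had_event], left = TRUE)
  g_free <- km_eval(km, horizon)
  if (any(g_event <= 0) || (any(event_free) && g_free <= 0)) {
    bad <- which(had_event)[g_event <= 0]
    stopf("censoring weight G = 0 for patient(s) %s",
          paste(utils::head(bad, 5), collapse = ", "))
  }
  total <- sum((1 - predictions[had_event])^2 / g_event) +
    sum(predictions[event_free]^2 / g_free)
  total / n
}

metric_undefined <- function(e) {
  grepl("undefined", conditionMessage(e))
}

compute_metric <- function(metric, preds, outcomes, horizon, event = NULL) {
  switch(metric,
    cec = cec_score(preds, outcomes, horizon),
    cindex = td_concordance(preds, outcomes, event, horizon),
    brier = brier_score(preds, outcomes, event, horizon),
    stopf("unknown metric '%s'", metric)
  )
}

#' Paired bootstrap comparison of two models under one metric
#'
#' Draws `n_boot` bootstrap resamples of the patient set (with
#' replacement, identical indices for both models), recomputes the metric
#' for each model on each resample, and tests the paired replicate
#' differences with a two-sided Wilcoxon signed-rank test (exact
#' distribution for 25 or fewer informative pairs, normal approximation
#' above; all-zero differences give p = 1).
#'
#' @param metric `"cec"`, `"cindex"` or `"brier"`.
#' @param predsA,predsB predictions for the two models on the identical
#'   patient set: n x K x T mass arrays for `"cec"`, n x T risk matrices
#'   otherwise.
#' @param outcomes outcome data.frame.
#' @param horizon month bin.
#' @param n_boot number of bootstrap resamples (>= 100).
#' @param seed integer seed; same seed, same resamples.
#' @param event event of interest (ignored for `"cec"`).
#' @return object of class `wl_metric_comparison`: point estimates,
#'   replicate vectors, percentile 95% CIs, and the p-value.
#' @export
bootstrap_compare <- function(metric, predsA, predsB, outcomes, horizon,
                              n_boot = 200L, seed = 1L, event = NULL) {
  if (n_boot < 100) stopf("n_boot must be >= 100 (got %d)", n_boot)
  outcomes <- check_outcomes(outcomes)
  n <- nrow(outcomes)
  take <- function(preds, idx) {
    if (length(dim(preds)) == 3) preds[idx, , , drop = FALSE]
    else as.matrix(preds)[idx, , drop = FALSE]
  }
  est_a <- compute_metric(metric, predsA, outcomes, horizon, event)
  est_b <- compute_metric(metric, predsB, outcomes, horizon, event)
  reps <- with_seed(seed, {
    vapply(seq_len(n_boot), function(b) {
      idx <- sample.int(n, n, replace = TRUE)
      oo <- outcomes[idx, , drop = FALSE]
      a <- tryCatch(compute_metric(metric, take(predsA, idx), oo, horizon,
                                   event),
                    error = function(e) if (metric_undefined(e)) NA_real_
                            else stop(e))
      bb <- tryCatch(compute_metric(metric, take(predsB, idx), oo, horizon,
                                    event),
                     error = function(e) if (metric_undefined(e)) NA_real_
                             else stop(e))
      c(a, bb)
    }, numeric(2))
  })
  ok <- stats::complete.cases(t(reps))
  if (mean(!ok) > 0.10) {
    stopf("metric '%s' undefined on %d of %d bootstrap resamples",
          metric, sum(!ok), n_boot)
  }
  ra <- reps[1, ok]
  rb <- reps[2, ok]
  d <- ra - rb
  p <- if (all(d == 0)) 1 else {
    nz <- sum(d != 0)
    suppressWarnings(
      stats::wilcox.test(ra, rb, paired = TRUE, exact = nz <= 25)$p.value)
  }
  structure(
    list(metric = metric, event = event, horizon = horizon,
         estimate_a = est_a, estimate_b = est_b,
         replicates_a = ra, replicates_b = rb,
         ci_a = stats::quantile(ra, c(0.025, 0.975), names = FALSE),
         ci_b = stats::quantile(rb, c(0.025, 0.975), names = FALSE),
         p_value = p, n_boot = n_boot, n_used = sum(ok)),
    class = "wl_metric_comparison"
  )
}

#' @export
print.wl_metric_comparison <- function(x, ...) {
  cat(sprintf(
    "<%s comparison, horizon bin %d>\n  A: %.4f [%.4f, %.4f]\n  B: %.4f [%.4f, %.4f]\n  Wilcoxon signed-rank p = %.3g (%d resamples)\n",
    x$metric, x$horizon, x$estimate_a, x$ci_a[1], x$ci_a[2],
    x$estimate_b, x$ci_b[1], x$ci_b[2], x$p_value, x$n_used))
  invisible(x)
}

#' Export a metric table to CSV and JSON
#'
#' @param table data.frame in long format (model, metric, event, horizon,
#'   estimate, ci_lower, ci_upper, p_vs_reference).
#' @param path_csv,path_json output paths; either may be `NULL` to skip.
#' @return the table, invisibly.
#' @export
write_metric_report <- function(table, path_csv = NULL, path_json = NULL) {
  num <- vapply(table, is.numeric, logical(1)) &
    !vapply(table, is.integer, logical(1))
  out <- table
  for (f in names(out)[num]) {
    out[[f]] <- formatC(signif(out[[f]], 6), format = "g", digits = 6)
  }
  if (!is.null(path_csv)) {
    utils::write.csv(out, path_csv, row.names = FALSE, quote = FALSE)
  }
  if (!is.null(path_json)) {
    jsonlite::write_json(table, path_json, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE, na = "null")
  }
  invisible(table)
}
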