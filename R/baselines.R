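# Cause-specific single-risk baselines. Each model targets one event and
# treats the competing event as censoring at its event month (the
# standard cause-specific formulation). Cox proportional hazards fits go
# through survival::coxph with Kalbfleisch-Prentice survival curves
# (product-limit; reduces exactly to Kaplan-Meier under a null design);
# random survival forests go through ranger with a fixed seed and a
# single thread so refits are reproducible.
#
# Times on the survival scale are event_month + 1 (bin m-1 holds events
# during calendar month m, and Surv() wants positive times).

#' Fit a cause-specific single-risk model
#'
#' @param train a `wl_cohort`.
#' @param event the event of interest (1/"death" or 2/"transplant"); the
#'   competing event is relabelled as censored at its month before fitting.
#' @param kind `"coxph"` or `"rsf"`.
#' @param seed integer seed (used by the forest; Cox fits are
#'   deterministic).
#' @param num_trees forest size for `kind = "rsf"`.
#' @return object of class `wl_single_risk`.
#' @export
fit_cause_specific <- function(train, event, kind = c("coxph", "rsf"),
                               seed = 1L, num_trees = 300L) {
  kind <- match.arg(kind)
  ev <- resolve_event(event)
  stopifnot(inherits(train, "wl_cohort"))
  outcomes <- censor_competing(train$outcomes, ev)
  if (!any(outcomes$event_type == ev)) {
    stopf("cannot fit: no record of event '%s' in the training cohort",
          EVENT_NAMES[ev])
  }
  encoder <- make_encoder(train$covariates)
  X <- encode_covariates(encoder, train$covariates)
  keep <- apply(X, 2, function(col) stats::sd(col) > 0)
  df <- as.data.frame(X[, keep, drop = FALSE])
  df$.time <- outcomes$event_month + 1
  df$.status <- as.integer(outcomes$event_type == ev)
  fit <- if (kind == "coxph") {
    form <- if (any(keep)) {
      stats::as.formula(paste("survival::Surv(.time, .status) ~",
                              paste(sprintf("`%s`", colnames(X)[keep]),
                                    collapse = " + ")))
    } else {
      stats::as.formula("survival::Surv(.time, .status) ~ 1")
    }
    m <- survival::coxph(form, data = df, x = FALSE, model = TRUE)
    bad <- names(stats::coef(m))[is.na(stats::coef(m))]
    if (length(bad) > 0) {
      stopf("degenerate design matrix: collinear column(s) %s",
            paste(gsub("`", "", bad), collapse = ", "))
    }
    m
  } else {
    ranger::ranger(
      formula = survival::Surv(.time, .status) ~ .,
      data = df, num.trees = num_trees, seed = as.integer(seed),
      num.threads = 1, respect.unordered.factors = "order")
  }
  structure(
    list(event = ev, kind = kind, fit = fit, encoder = encoder,
         horizon = train$horizon, dropped = names(which(!keep)),
         seed = as.integer(seed)),
    class = "wl_single_risk"
  )
}

#' @export
print.wl_single_risk <- function(x, ...) {
  cat(sprintf("<wl_single_risk> %s model for event '%s' (horizon %d months)\n",
              x$kind, EVENT_NAMES[x$event], x$horizon))
  invisible(x)
}

#' Single-risk event probability by a given month
#'
#' Returns `1 - S_k(t | x)`, the model's probability that its event of
#' interest has occurred by the end of month bin `t` (competing event
#' censored, so this is a net, not crude, probability).
#'
#' @param model a `wl_single_risk`.
#' @param newdata covariate data.frame.
#' @param t month bin(s) in `0..horizon-1`.
#' @return n x length(t) matrix of probabilities.
#' @export
predict_event_probability <- function(model, newdata, t) {
  stopifnot(inherits(model, "wl_single_risk"))
  if (any(t < 0 | t >= model$horizon)) {
    stopf("t must lie in 0..%d", model$horizon - 1L)
  }
  X <- encode_covariates(model$encoder, newdata)
  keep <- setdiff(colnames(X), model$dropped)
  df <- as.data.frame(X[, keep, drop = FALSE])
  times <- t + 1
  if (model$kind == "coxph") {
    null_design <- ncol(df) == 0
    sf <- if (null_design) {
      survival::survfit(model$fit, stype = 1, se.fit = FALSE)
    } else {
      survival::survfit(model$fit, newdata = df, stype = 1, se.fit = FALSE)
    }
    surv <- sf$surv
    if (is.null(dim(surv))) {
      # one curve: a null design (shared for all patients) or one patient
      reps <- if (null_design) nrow(X) else 1
      surv <- matrix(rep(surv, reps), ncol = reps)
    }
    idx <- findInterval(times, sf$time)
    out <- t(vapply(seq_len(ncol(surv)), function(j) {
      s <- c(1, surv[, j])[idx + 1L]
      1 - s
    }, numeric(length(times))))
    if (length(times) == 1) out <- matrix(out, ncol = 1)
    out
  } else {
    pr <- stats::predict(model$fit, data = df, num.threads = 1)
    grid <- pr$unique.death.times
    idx <- findInterval(times, grid)
    surv <- pr$survival  # n x length(grid)
    out <- vapply(seq_along(times), function(j) {
      if (idx[j] == 0) rep(0, nrow(surv)) else 1 - surv[, idx[j]]
    }, numeric(nrow(surv)))
    matrix(out, nrow = nrow(surv))
  }
}

#' Per-month risk matrix for a single-risk model
#'
#' Convenience wrapper evaluating [predict_event_probability()] on the
#' full month grid, the prediction container the evaluation metrics use.
#'
#' @param model a `wl_single_risk`.
#' @param newdata covariate data.frame.
#' @return n x horizon matrix of `1 - S(t|x)`.
#' @export
risk_matrix_single <- function(model, newdata) {
  predict_event_probability(model, newdata, seq_len(model$horizon) - 1L)
}
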