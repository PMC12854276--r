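# Experiment orchestration: stratified split, cross-validated
# hyperparameter selection, refit, paired bootstrap evaluation at fixed
# horizons, permutation importance and per-patient trajectory forecasts.
# One master seed fans out into per-stage seeds, so an identical
# configuration reproduces every output byte for byte.

#' Stratified train/test split
#'
#' Allocates `round(n_class * test_fraction)` patients of each event
#' class (censored/death/transplant) to the test set, so both parts
#' preserve the cohort's event mix to within one patient per class.
#'
#' @param cohort a `wl_cohort`.
#' @param test_fraction fraction held out (default 0.10).
#' @param seed integer seed.
#' @return list with `wl_cohort`s `train` and `test` and the integer
#'   `test_idx` into the original cohort.
#' @export
stratified_split <- function(cohort, test_fraction = 0.10, seed = 1L) {
  stopifnot(inherits(cohort, "wl_cohort"),
            test_fraction > 0, test_fraction < 1)
  types <- cohort$outcomes$event_type
  counts <- table(types)
  if (any(counts < 2)) {
    stopf("stratification impossible: event class %s has fewer than 2 members",
          names(counts)[which(counts < 2)[1]])
  }
  test_idx <- with_seed(seed, {
    sort(unlist(lapply(unique(types), function(k) {
      members <- which(types == k)
      n_test <- max(1L, round(length(members) * test_fraction))
      sample(members, n_test)
    })))
  })
  list(train = cohort_subset(cohort, -test_idx),
       test = cohort_subset(cohort, test_idx),
       test_idx = test_idx)
}

stratified_folds <- function(types, n_folds, seed) {
  fold <- integer(length(types))
  with_seed(seed, {
    for (k in unique(types)) {
      members <- sample(which(types == k))
      fold[members] <- rep_len(seq_len(n_folds), length(members))
    }
  })
  for (f in seq_len(n_folds)) {
    ok <- all(unique(types) %in% types[fold != f]) &&
      all(unique(types) %in% types[fold == f])
    if (!ok) {
      stopf("fold %d would lose an event class; use fewer folds or more data", f)
    }
  }
  fold
}

#' Cross-validated hyperparameter selection
#'
#' For every grid point, fits the competing-risk network on each of
#' `n_folds` stratified training folds and scores the held-out fold by
#' the time-dependent C-index for the chosen event and horizon. Returns
#' the grid point with the highest mean validation C-index (ties go to
#' the earlier grid position) and the full fold-by-grid metric table.
#'
#' @param train training `wl_cohort`.
#' @param grid non-empty list of [hyperparams()] objects.
#' @param n_folds stratified folds (default 5).
#' @param seed integer seed (fold assignment and per-fold fit seeds).
#' @param event selection event (default death).
#' @param horizon_bin selection horizon bin (default 11 = month 12, or
#'   the last bin when the horizon is shorter).
#' @return list: `best_hp`, `best_index`, `metrics` (data.frame
#'   grid_point x fold x cindex).
#' @export
cross_validate <- function(train, grid, n_folds = 5L, seed = 1L,
                           event = "death", horizon_bin = NULL) {
  stopifnot(inherits(train, "wl_cohort"), length(grid) >= 1)
  ev <- resolve_event(event)
  if (is.null(horizon_bin)) horizon_bin <- min(11L, train$horizon - 1L)
  types <- train$outcomes$event_type
  fold <- stratified_folds(types, n_folds, seed)
  fold_seeds <- derive_seeds(seed, n_folds)
  rows <- list()
  for (gi in seq_along(grid)) {
    hp <- grid[[gi]]
    stopifnot(inherits(hp, "wl_hyperparams"))
    for (f in seq_len(n_folds)) {
      hp_f <- hp
      hp_f$seed <- fold_seeds[f]
      fit <- fit_deephit(cohort_subset(train, fold != f), hp_f)
      hold <- cohort_subset(train, fold == f)
      cif <- risk_cif(predict_risk(fit, hold$covariates))
      ci <- td_concordance(cif[, ev, ], hold$outcomes, ev, horizon_bin)
      rows[[length(rows) + 1]] <- data.frame(grid_point = gi, fold = f,
                                             cindex = ci)
    }
  }
  metrics <- do.call(rbind, rows)
  means <- tapply(metrics$cindex, metrics$grid_point, mean)
  best <- as.integer(names(means)[which.max(means)])
  list(best_hp = grid[[best]], best_index = best, metrics = metrics,
       mean_cindex = as.numeric(means))
}

#' Experiment configuration
#'
#' @param cohort the data source: a `wl_cohort`, a [cohort_config()] (the
#'   cohort is generated), or a path to a cohort CSV.
#' @param test_fraction held-out fraction (default 0.10).
#' @param n_folds outer cross-validation folds (default 5).
#' @param grid list of [hyperparams()] candidates (default: one point,
#'   the package defaults).
#' @param horizons evaluation horizons in months (default 1, 3, 6, 12;
#'   mapped internally to month bins 0, 2, 5, 11).
#' @param n_boot bootstrap resamples per metric (default 200).
#' @param models character subset of
#'   `c("deephit", "coxph", "rsf", "meld_na", "meld_30")`.
#' @param importance_repeats permutation repeats (default 20); 0 skips
#'   the importance stage.
#' @param trajectory_patients test-set row indices to forecast and plot;
#'   `NULL` picks the first death and first transplant in the test set.
#' @param seed master seed; every stage seed derives from it.
#' @param out_dir output directory (created if missing).
#' @param csv_horizon horizon used when `cohort` is a CSV path.
#' @return object of class `wl_experiment_config`.
#' @export
experiment_config <- function(cohort, test_fraction = 0.10, n_folds = 5L,
                              grid = list(hyperparams()),
                              horizons = c(1, 3, 6, 12), n_boot = 200L,
                              models = c("deephit", "coxph", "rsf",
                                         "meld_na", "meld_30"),
                              importance_repeats = 20L,
                              trajectory_patients = NULL, seed = 1L,
                              out_dir = tempfile("waitlistcr-run-"),
                              csv_horizon = 120L) {
  models <- match.arg(models, several.ok = TRUE)
  stopifnot(test_fraction > 0, test_fraction < 1, length(grid) >= 1,
            all(horizons >= 1), n_boot >= 100)
  if (!"deephit" %in% models) {
    stopf("the competing-risk model is the reference and must be included")
  }
  structure(
    list(cohort = cohort, test_fraction = test_fraction,
         n_folds = as.integer(n_folds), grid = grid,
         horizons = as.integer(horizons), n_boot = as.integer(n_boot),
         models = models, importance_repeats = as.integer(importance_repeats),
         trajectory_patients = trajectory_patients,
         seed = as.integer(seed), out_dir = out_dir,
         csv_horizon = as.integer(csv_horizon)),
    class = "wl_experiment_config"
  )
}

resolve_cohort <- function(config) {
  src <- config$cohort
  if (inherits(src, "wl_cohort")) src
  else if (inherits(src, "wl_cohort_config")) generate_cohort(src)
  else if (is.character(src)) read_cohort_csv(src, config$csv_horizon)
  else stopf("cohort source must be a wl_cohort, a cohort_config, or a CSV path")
}

# Paired bootstrap evaluation of all requested models against the
# competing-risk reference. Returns the long metric table.
evaluate_models <- function(preds, outcomes, horizons_bins, n_boot, seed) {
  ref <- "deephit"
  rows <- list()
  add <- function(model, metric, event, horizon_bin, cmp, side) {
    est <- if (side == "a") cmp$estimate_a else cmp$estimate_b
    ci <- if (side == "a") cmp$ci_a else cmp$ci_b
    rows[[length(rows) + 1]] <<- data.frame(
      model = model, metric = metric,
      event = if (is.null(event)) "both" else EVENT_NAMES[event],
      horizon_month = horizon_bin + 1L, estimate = est,
      ci_lower = ci[1], ci_upper = ci[2],
      p_vs_reference = if (model == ref) NA_real_ else cmp$p_value)
  }
  for (hb in horizons_bins) {
    # CEC across events: competing model vs single-risk pairs
    ref_cec_added <- FALSE
    for (m in intersect(c("coxph", "rsf"), names(preds$pairs))) {
      cmp <- bootstrap_compare_mixed(
        preds$mass, preds$pairs[[m]], outcomes, hb, n_boot, seed)
      if (!ref_cec_added) {
        add(ref, "cec", NULL, hb, cmp, "a")
        ref_cec_added <- TRUE
      }
      add(m, "cec", NULL, hb, cmp, "b")
    }
    if (!ref_cec_added) {
      cmp <- bootstrap_compare("cec", preds$mass, preds$mass, outcomes, hb,
                               n_boot, seed)
      add(ref, "cec", NULL, hb, cmp, "a")
    }
    for (ev in 1:2) {
      ref_mat <- preds$risk[[ref]][[ev]]
      for (m in names(preds$risk)) {
        mat <- preds$risk[[m]][[ev]]
        if (is.null(mat)) next
        for (metric in c("cindex", "brier")) {
          if (metric == "brier" && m %in% c("meld_na", "meld_30")) next
          cmp <- bootstrap_compare(metric, ref_mat, mat, outcomes, hb,
                                   n_boot, seed, event = ev)
          if (m == ref) add(ref, metric, ev, hb, cmp, "a")
          else add(m, metric, ev, hb, cmp, "b")
        }
      }
    }
  }
  do.call(rbind, rows)
}

# CEC comparison between a mass array (competing-risk model) and a
# single-risk pair (list(death =, transplant =) of risk matrices).
bootstrap_compare_mixed <- function(mass, pair, outcomes, horizon, n_boot,
                                    seed) {
  n <- nrow(outcomes)
  cec_pair <- function(pair_sub, oo, hb) {
    sel_cohort <- list(outcomes = oo, horizon = ncol(pair_sub$death))
    cec_score_single_risk(pair_sub, sel_cohort, hb)
  }
  est_a <- cec_score(mass, outcomes, horizon)
  est_b <- cec_pair(pair, outcomes, horizon)
  reps <- with_seed(seed, {
    vapply(seq_len(n_boot), function(b) {
      idx <- sample.int(n, n, replace = TRUE)
      oo <- outcomes[idx, , drop = FALSE]
      a <- tryCatch(cec_score(mass[idx, , , drop = FALSE], oo, horizon),
                    error = function(e) if (metric_undefined(e)) NA_real_
                            else stop(e))
      bb <- tryCatch(
        cec_pair(list(death = pair$death[idx, , drop = FALSE],
                      transplant = pair$transplant[idx, , drop = FALSE]),
                 oo, horizon),
        error = function(e) if (metric_undefined(e)) NA_real_ else stop(e))
      c(a, bb)
    }, numeric(2))
  })
  ok <- stats::complete.cases(t(reps))
  if (mean(!ok) > 0.10) {
    stopf("CEC undefined on %d of %d bootstrap resamples", sum(!ok), n_boot)
  }
  ra <- reps[1, ok]; rb <- reps[2, ok]
  d <- ra - rb
  p <- if (all(d == 0)) 1 else {
    suppressWarnings(
      stats::wilcox.test(ra, rb, paired = TRUE,
                         exact = sum(d != 0) <= 25)$p.value)
  }
  structure(
    list(metric = "cec", event = NULL, horizon = horizon,
         estimate_a = est_a, estimate_b = est_b,
         replicates_a = ra, replicates_b = rb,
         ci_a = stats::quantile(ra, c(0.025, 0.975), names = FALSE),
         ci_b = stats::quantile(rb, c(0.025, 0.975), names = FALSE),
         p_value = p, n_boot = n_boot, n_used = sum(ok)),
    class = "wl_metric_comparison")
}

#' Run the full experiment
#'
#' split -> cross-validated tuning -> refit on the full training set ->
#' fit single-risk baselines -> paired bootstrap evaluation on the test
#' set at every horizon -> permutation importance -> trajectory
#' forecasts. Writes `metrics.csv` / `metrics.json`, `importance.csv`,
#' `cv_metrics.csv`, trajectory plots, a run log and the resolved
#' configuration into `config$out_dir`; on any stage failure, partial
#' outputs are removed and the error is tagged with the stage name.
#'
#' @param config an [experiment_config()].
#' @return invisible list: fitted models, prediction containers, the
#'   metric table, importance tables and output paths.
#' @export
run_experiment <- function(config) {
  stopifnot(inherits(config, "wl_experiment_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  written <- character(0)
  note <- function(path) { written <<- c(written, path); path }
  log_path <- file.path(config$out_dir, "run.log")
  log_con <- file(log_path, open = "wt")
  on.exit(close(log_con), add = TRUE)
  logmsg <- function(fmt, ...) {
    line <- sprintf("[%s] %s", format(Sys.time(), "%Y-%m-%d %H:%M:%S"),
                    sprintf(fmt, ...))
    writeLines(line, log_con)
    message(line)
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      unlink(written)
      unlink(log_path)
      stopf("stage '%s': %s", name, conditionMessage(e))
    })
  }
  seeds <- derive_seeds(config$seed, 8)
  logmsg("master seed %d; stage seeds %s", config$seed,
         paste(seeds, collapse = " "))

  cohort <- stage("data", resolve_cohort(config))
  horizons_bins <- config$horizons - 1L
  if (any(horizons_bins >= cohort$horizon)) {
    stopf("stage 'data': evaluation horizon beyond the cohort's %d months",
          cohort$horizon)
  }
  logmsg("cohort: %d patients, %d-month horizon", nrow(cohort$covariates),
         cohort$horizon)

  parts <- stage("split",
                 stratified_split(cohort, config$test_fraction, seeds[1]))
  train <- parts$train
  test <- parts$test
  logmsg("split: %d train / %d test", nrow(train$covariates),
         nrow(test$covariates))

  cv <- stage("cross_validation",
              cross_validate(train, config$grid, config$n_folds, seeds[2]))
  logmsg("cross-validation selected grid point %d (mean C-index %s)",
         cv$best_index,
         paste(sprintf("%.3f", cv$mean_cindex), collapse = " / "))

  models <- list()
  best_hp <- cv$best_hp
  best_hp$seed <- seeds[3]
  models$deephit <- stage("refit", fit_deephit(train, best_hp))
  # leakage guard: the frozen standardization stats must equal statistics
  # recomputed from the training covariates alone
  stage("leakage_guard", {
    fresh <- make_encoder(train$covariates)
    stopifnot(isTRUE(all.equal(fresh$center, models$deephit$encoder$center)),
              isTRUE(all.equal(fresh$scale, models$deephit$encoder$scale)))
  })
  for (kind in intersect(c("coxph", "rsf"), config$models)) {
    models[[kind]] <- stage(kind, list(
      death = fit_cause_specific(train, 1, kind, seed = seeds[4]),
      transplant = fit_cause_specific(train, 2, kind, seed = seeds[4])))
  }

  preds <- stage("predictions", {
    mass <- predict_risk(models$deephit, test$covariates)
    cif <- risk_cif(mass)
    risk <- list(deephit = list(cif[, 1, ], cif[, 2, ]))
    pairs <- list()
    for (kind in intersect(c("coxph", "rsf"), config$models)) {
      pd <- risk_matrix_single(models[[kind]]$death, test$covariates)
      pt <- risk_matrix_single(models[[kind]]$transplant, test$covariates)
      risk[[kind]] <- list(pd, pt)
      pairs[[kind]] <- list(death = pd, transplant = pt)
    }
    for (v in intersect(c("meld_na", "meld_30"), config$models)) {
      score <- cohort_meld(test, v)
      # death-only risk ranking, constant over months
      risk[[v]] <- list(matrix(score, nrow(test$covariates), test$horizon),
                        NULL)
    }
    list(mass = mass, risk = risk, pairs = pairs)
  })

  metric_table <- stage("evaluation",
                        evaluate_models(preds, test$outcomes, horizons_bins,
                                        config$n_boot, seeds[5]))
  write_metric_report(metric_table,
                      note(file.path(config$out_dir, "metrics.csv")),
                      note(file.path(config$out_dir, "metrics.json")))
  logmsg("evaluation: %d metric rows at horizons %s months",
         nrow(metric_table), paste(config$horizons, collapse = ", "))

  importance <- NULL
  if (config$importance_repeats > 0) {
    importance <- stage("importance", {
      lapply(1:2, function(ev) {
        permutation_importance(models$deephit, test, ev,
                               horizon = max(horizons_bins),
                               n_repeats = config$importance_repeats,
                               seed = seeds[6])
      })
    })
    imp_tab <- do.call(rbind, lapply(importance, as.data.frame))
    utils::write.csv(imp_tab,
                     note(file.path(config$out_dir, "importance.csv")),
                     row.names = FALSE, quote = FALSE)
  }

  utils::write.csv(cv$metrics,
                   note(file.path(config$out_dir, "cv_metrics.csv")),
                   row.names = FALSE, quote = FALSE)

  traj_paths <- stage("trajectories", {
    idx <- config$trajectory_patients
    if (is.null(idx)) {
      idx <- c(match(EVENT_DEATH, test$outcomes$event_type),
               match(EVENT_TRANSPLANT, test$outcomes$event_type))
      idx <- idx[!is.na(idx)]
    }
    vapply(idx, function(i) {
      traj <- forecast_trajectory(models$deephit,
                                  test$covariates[i, , drop = FALSE],
                                  actual = test$outcomes[i, ])
      p <- plot_trajectory(traj)
      path <- note(file.path(config$out_dir,
                             sprintf("trajectory_patient%03d.png", i)))
      save_plot_safely(p, path)
      path
    }, character(1))
  })

  cfg_snapshot <- config
  cfg_snapshot$cohort <- if (is.character(config$cohort)) config$cohort
                         else class(config$cohort)[1]
  cfg_snapshot$grid <- lapply(config$grid, unclass)
  jsonlite::write_json(unclass(cfg_snapshot),
                       note(file.path(config$out_dir, "config.json")),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       force = TRUE)
  logmsg("done; outputs in %s", config$out_dir)
  invisible(list(models = models, predictions = preds,
                 metrics = metric_table, importance = importance,
                 cv = cv, split = parts, trajectories = traj_paths,
                 out_dir = config$out_dir, written = written))
}

save_plot_safely <- function(p, path) {
  if (!capabilities("png")) path <- sub("\\.png$", ".pdf", path)
  suppressMessages(ggplot2::ggsave(path, p, width = 9, height = 4, dpi = 120))
  path
}

#' Forecast one patient's waitlist trajectory
#'
#' Monthly risk mass and cumulative incidence for death and transplant
#' over the model's full horizon, optionally annotated with the actual
#' outcome.
#'
#' @param model a fitted `wl_deephit`.
#' @param x one-row covariate data.frame.
#' @param actual optional one-row outcome data.frame (`event_type`,
#'   `event_month`).
#' @return object of class `wl_trajectory`: `mass` and `cif` (2 x T
#'   matrices, rows death/transplant), `actual`.
#' @export
forecast_trajectory <- function(model, x, actual = NULL) {
  stopifnot(nrow(x) == 1)
  mass <- predict_risk(model, x)
  cif <- risk_cif(mass)
  m <- rbind(mass[1, 1, ], mass[1, 2, ])
  ci <- rbind(cif[1, 1, ], cif[1, 2, ])
  rownames(m) <- rownames(ci) <- EVENT_NAMES
  structure(list(mass = m, cif = ci, actual = actual,
                 horizon = model$horizon),
            class = "wl_trajectory")
}

#' Plot a waitlist trajectory forecast
#'
#' Cumulative incidence curves for both events over the horizon; the
#' actual event month, when known, is marked with a vertical line
#' coloured by event, and a zoom panel magnifies the months around it.
#'
#' @param traj a `wl_trajectory`.
#' @param zoom_halfwidth months shown either side of the actual event in
#'   the zoom panel.
#' @return a ggplot object (patchwork-combined panels when an actual
#'   event is annotated).
#' @export
plot_trajectory <- function(traj, zoom_halfwidth = 3) {
  Tm <- traj$horizon
  df <- data.frame(
    month = rep(seq_len(Tm) - 1L, 2),
    cif = c(traj$cif[1, ], traj$cif[2, ]),
    event = rep(EVENT_NAMES, each = Tm)
  )
  cols <- c(death = "firebrick", transplant = "forestgreen")
  base <- ggplot2::ggplot(df, ggplot2::aes(month, cif, colour = event)) +
    ggplot2::geom_step(linewidth = 0.7) +
    ggplot2::scale_colour_manual(values = cols) +
    ggplot2::labs(x = "months since listing", y = "cumulative incidence") +
    ggplot2::ylim(0, 1) +
    ggplot2::theme_minimal()
  act <- traj$actual
  if (!is.null(act) && act$event_type %in% 1:2) {
    ev_name <- EVENT_NAMES[act$event_type]
    base <- base +
      ggplot2::geom_vline(xintercept = act$event_month,
                          colour = cols[[ev_name]], linetype = 2)
    lo <- max(0, act$event_month - zoom_halfwidth)
    hi <- min(Tm - 1, act$event_month + zoom_halfwidth)
    zoom <- base + ggplot2::coord_cartesian(xlim = c(lo, hi)) +
      ggplot2::labs(subtitle = sprintf("zoom: months %d-%d (actual %s at month %d)",
                                       lo, hi, ev_name, act$event_month))
    if (requireNamespace("patchwork", quietly = TRUE)) {
      return(base + zoom)
    }
    return(zoom)
  }
  base
}
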