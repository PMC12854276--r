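test_that("with zero competing events the cause-specific fit is the plain fit", {
  cfg <- default_cohort_config(n_patients = 400, horizon = 12, seed = 8)
  cfg$baseline_logit$transplant <- rep(-50, 12)  # no transplants occur
  cohort <- generate_cohort(cfg)
  expect_false(any(cohort$outcomes$event_type == 2))
  m <- fit_cause_specific(cohort, "death", "coxph")
  # plain single-event fit on the same design, no relabelling involved
  enc <- make_encoder(cohort$covariates)
  X <- encode_covariates(enc, cohort$covariates)
  df <- as.data.frame(X[, apply(X, 2, stats::sd) > 0, drop = FALSE])
  df$.time <- cohort$outcomes$event_month + 1
  df$.status <- as.integer(cohort$outcomes$event_type == 1)
  plain <- survival::coxph(
    stats::as.formula(paste("survival::Surv(.time, .status) ~",
                            paste(sprintf("`%s`", setdiff(names(df),
                                                          c(".time", ".status"))),
                                  collapse = " + "))), data = df,
    model = TRUE)
  expect_equal(stats::coef(m$fit), stats::coef(plain), tolerance = 1e-10)
})

test_that("Cox coefficient signs recover a dominant generator effect", {
  hits <- 0
  for (s in 1:20) {
    cfg <- dominant_feature_config(800, 12, seed = 200 + s)
    cohort <- generate_cohort(cfg)
    m <- fit_cause_specific(cohort, "death", "coxph")
    hits <- hits + (stats::coef(m$fit)[["meld_listing"]] > 0)
  }
  expect_gte(hits, 19)  # >= 95% of 20 seeds
})

test_that("forests are reproducible under a fixed seed", {
  cohort <- generate_cohort(default_cohort_config(300, 12, seed = 14))
  m1 <- fit_cause_specific(cohort, "transplant", "rsf", seed = 5,
                           num_trees = 50)
  m2 <- fit_cause_specific(cohort, "transplant", "rsf", seed = 5,
                           num_trees = 50)
  x <- cohort$covariates[1:20, ]
  expect_identical(predict_event_probability(m1, x, c(0, 5, 11)),
                   predict_event_probability(m2, x, c(0, 5, 11)))
  # out-of-bag survival stored with the fit is identical too
  expect_identical(m1$fit$survival, m2$fit$survival)
})

test_that("single-risk event probability is monotone and anchored at zero", {
  cohort <- generate_cohort(default_cohort_config(300, 12, seed = 15))
  for (kind in c("coxph", "rsf")) {
    # sparse dummy levels at this size can leave a Cox coefficient
    # unbounded (survival warns); irrelevant to monotonicity in t
    m <- suppressWarnings(
      fit_cause_specific(cohort, "death", kind, seed = 3, num_trees = 50))
    p <- predict_event_probability(m, cohort$covariates[1:15, ], 0:11)
    expect_true(all(diff(t(p)) >= -1e-12))
    expect_true(all(p >= 0 & p <= 1))
  }
  # near-zero baseline hazard at month 0 gives near-zero probability
  cfg <- default_cohort_config(n_patients = 600, horizon = 12, seed = 16)
  cfg$baseline_logit$death[1] <- -12
  co2 <- generate_cohort(cfg)
  # rare dummy levels among the few early deaths can leave a coefficient
  # unbounded; irrelevant to the month-0 anchor being tested
  m2 <- suppressWarnings(fit_cause_specific(co2, "death", "coxph"))
  p0 <- predict_event_probability(m2, co2$covariates[1:10, ], 0)
  expect_true(all(p0 < 0.05))
})

test_that("a null design reduces to the Kaplan-Meier product-limit curve", {
  # ten identical patients; deaths in bins 1,1,3,5,7, censorings in bins
  # 2,4,6,8,9. Hand-computed product-limit survival (times = bin + 1):
  #   S(2) = 8/10, S(4) = 24/35, S(6) = 96/175, S(8) = 64/175
  cohort <- generate_cohort(default_cohort_config(10, 12, seed = 30))
  cohort$covariates[] <- cohort$covariates[rep(1, 10), ]
  cohort$outcomes <- data.frame(
    event_type = c(1L, 1L, 1L, 1L, 1L, 0L, 0L, 0L, 0L, 0L),
    event_month = c(1L, 1L, 3L, 5L, 7L, 2L, 4L, 6L, 8L, 9L))
  m <- fit_cause_specific(cohort, "death", "coxph")
  p <- predict_event_probability(m, cohort$covariates[1, , drop = FALSE],
                                 c(1, 3, 5, 7))
  expect_equal(as.numeric(p),
               1 - c(8 / 10, 24 / 35, 96 / 175, 64 / 175),
               tolerance = 1e-10)
})

test_that("collinear designs fail loudly naming the offending column", {
  cohort <- generate_cohort(default_cohort_config(250, 12, seed = 31))
  # make the male dummy coincide with the dialysis flag
  cohort$covariates$sex <- ifelse(cohort$covariates$dialysis_last_week == 1,
                                  "male", "female")
  expect_error(fit_cause_specific(cohort, "death", "coxph"),
               "collinear.*(sex_male|dialysis_last_week)")
})

test_that("fitting demands at least one record of the target event", {
  cohort <- generate_cohort(default_cohort_config(100, 12, seed = 32))
  cohort$outcomes$event_type[cohort$outcomes$event_type == 1L] <- 0L
  expect_error(fit_cause_specific(cohort, "death", "coxph"), "no record")
})
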