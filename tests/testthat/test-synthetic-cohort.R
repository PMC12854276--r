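test_that("identical configurations reproduce the cohort exactly", {
  cfg <- default_cohort_config(n_patients = 400, horizon = 24, seed = 7)
  a <- generate_cohort(cfg)
  b <- generate_cohort(cfg)
  expect_identical(a, b)
  cfg2 <- default_cohort_config(n_patients = 400, horizon = 24, seed = 8)
  expect_false(identical(generate_cohort(cfg2)$outcomes, a$outcomes))
})

test_that("waitlist removal reasons map to the event taxonomy", {
  expect_identical(classify_waitlist_outcome("deteriorated"), 1L)
  expect_identical(classify_waitlist_outcome("died"), 1L)
  expect_identical(classify_waitlist_outcome("improved"), 0L)
  expect_identical(classify_waitlist_outcome("other"), 0L)
  expect_identical(classify_waitlist_outcome("transplanted"), 2L)
  expect_identical(
    classify_waitlist_outcome(c("died", "improved", "transplanted")),
    c(1L, 0L, 2L))
  expect_error(classify_waitlist_outcome("withdrawn"), "unknown removal")
})

test_that("disabling censoring with high hazards leaves only events", {
  cfg <- default_cohort_config(n_patients = 300, horizon = 12, seed = 3)
  cfg$censoring_rate <- 0
  cfg$baseline_logit <- list(death = rep(5, 12), transplant = rep(5, 12))
  cohort <- generate_cohort(cfg)
  expect_true(all(cohort$outcomes$event_type %in% 1:2))
})

test_that("zero coefficients and equal baselines give a symmetric event mix", {
  cfg <- default_cohort_config(n_patients = 10000, horizon = 12, seed = 5)
  cfg$beta <- lapply(cfg$beta, function(b) b * 0)
  cfg$baseline_logit <- list(death = rep(-2.5, 12), transplant = rep(-2.5, 12))
  cfg$censoring_rate <- 0
  cohort <- generate_cohort(cfg)
  deaths <- sum(cohort$outcomes$event_type == 1)
  tx <- sum(cohort$outcomes$event_type == 2)
  # conditional on an event, death is Binomial(n_events, 1/2)
  se <- sqrt((deaths + tx) * 0.25)
  expect_lt(abs(deaths - tx) / 2, 3 * se)
})

test_that("the one-month toy matches the hand-computed CIF", {
  cfg <- one_month_config()
  x <- generate_cohort(cfg)$covariates[1, , drop = FALSE]
  expect_equal(true_cif(cfg, x, "death", 0), 0.3, tolerance = 1e-12)
  expect_equal(true_cif(cfg, x, "transplant", 0), 0.2, tolerance = 1e-12)
  expect_error(true_cif(cfg, x, 3, 0), "unknown event")
  expect_error(true_cif(cfg, x, "death", 1), "must lie in")
})

test_that("oracle CIF is monotone, mass-conserving, and null for null hazards", {
  cfg <- default_cohort_config(n_patients = 20, horizon = 36, seed = 9)
  cohort <- generate_cohort(cfg)
  grid <- waitlistcr:::true_cif_grid(cfg, cohort$covariates)
  for (k in 1:2) {
    diffs <- grid[, k, -1] - grid[, k, -36]
    expect_true(all(diffs >= -1e-12))
  }
  expect_true(all(grid[, 1, ] + grid[, 2, ] <= 1 + 1e-12))
  cfg$baseline_logit <- list(death = rep(-50, 36), transplant = rep(-50, 36))
  grid0 <- waitlistcr:::true_cif_grid(cfg, cohort$covariates)
  expect_true(all(grid0 < 1e-12))
})

test_that("empirical cumulative incidence agrees with the analytic oracle", {
  cfg <- default_cohort_config(n_patients = 10000, seed = 1)
  cohort <- generate_cohort(cfg)
  # Aalen-Johansen estimate (independent route, cmprsk) at month 12
  ci <- cmprsk::cuminc(cohort$outcomes$event_month + 1,
                       cohort$outcomes$event_type, cencode = 0)
  est <- cmprsk::timepoints(ci, 12)
  truth <- mean(true_cif(cfg, cohort$covariates, "death", 11))
  aj <- est$est["1 1", 1]
  se <- sqrt(est$var["1 1", 1])
  expect_lt(abs(aj - truth), 3 * se)
  # and the shipped config reproduces the waitlist composition
  mix <- table(factor(cohort$outcomes$event_type, levels = 0:2)) / 10000
  expect_gt(mix[["2"]], 0.50); expect_lt(mix[["2"]], 0.60)
  expect_gt(mix[["1"]], 0.20); expect_lt(mix[["1"]], 0.30)
  expect_gt(mix[["0"]], 0.15); expect_lt(mix[["0"]], 0.25)
})

test_that("observed per-month event counts fit the generative law", {
  # chi-square GOF of observed (event, month) cells against closed-form
  # expectations (censoring included); alpha = 0.01, 20 seeds
  rejections <- 0
  for (s in 1:20) {
    cfg <- default_cohort_config(n_patients = 10000, horizon = 12, seed = s)
    cohort <- generate_cohort(cfg)
    h <- waitlistcr:::config_hazards(cfg, cohort$covariates)
    cr <- cfg$censoring_rate
    n <- cfg$n_patients
    atrisk <- cbind(rep(1, n),
                    t(apply((1 - h$death - h$transplant) * (1 - cr), 1,
                            cumprod))[, -12])
    expected <- c(colSums(h$death * atrisk), colSums(h$transplant * atrisk))
    oo <- cohort$outcomes
    observed <- c(
      vapply(0:11, function(t) sum(oo$event_type == 1 & oo$event_month == t),
             numeric(1)),
      vapply(0:11, function(t) sum(oo$event_type == 2 & oo$event_month == t),
             numeric(1)))
    # remainder cell: censored or surviving
    expected <- c(expected, n - sum(expected))
    observed <- c(observed, n - sum(observed))
    stat <- sum((observed - expected)^2 / expected)
    if (stat > stats::qchisq(0.99, df = length(expected) - 1)) {
      rejections <- rejections + 1
    }
  }
  expect_lte(rejections, 2)
})

test_that("invalid configurations fail with a month-level diagnostic", {
  cfg <- default_cohort_config(n_patients = 10, horizon = 12, seed = 1)
  cfg$baseline_logit$death[4] <- NaN
  expect_error(waitlistcr:::validate_cohort_config(cfg), "month bin 3")
  expect_error(
    cohort_config(n_patients = 5, horizon = 12,
                  beta = default_cohort_config(5, 12)$beta,
                  baseline_logit = list(death = rep(0, 5),
                                        transplant = rep(0, 12)),
                  seed = 1),
    "length horizon")
  cfg2 <- default_cohort_config(n_patients = 5, horizon = 6, seed = 1)
  cfg2$censoring_rate <- 1.2
  expect_error(waitlistcr:::validate_cohort_config(cfg2), "censoring_rate")
})

test_that("covariate validation enforces domains and rejects missing data", {
  cohort <- generate_cohort(default_cohort_config(20, 6, seed = 2))
  cv <- cohort$covariates
  bad <- cv; bad$bilirubin[3] <- NA
  expect_error(validate_covariates(bad), "bilirubin")
  bad <- cv; bad$blood_type[1] <- "Z"
  expect_error(validate_covariates(bad), "blood_type")
  bad <- cv; bad$albumin[2] <- -1
  expect_error(validate_covariates(bad), "albumin")
  bad <- cv[, -1]
  expect_error(validate_covariates(bad), "meld_listing")
})
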