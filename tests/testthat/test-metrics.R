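test_that("coherence is 1 for an oracle predictor and 0 for an adversary", {
  withr::local_seed(11)
  n <- 40; Tm <- 12
  outcomes <- random_outcomes(n, Tm, p_event = c(0.2, 0.4, 0.4))
  outcomes$event_type[1] <- 1L  # guarantee a defined score
  k <- pmax(outcomes$event_type, 1)
  oracle <- oracle_mass(n, Tm, k, outcomes$event_month)
  expect_equal(cec_score(oracle, outcomes, Tm - 1), 1.0)
  adversary <- oracle_mass(n, Tm, 3L - k, outcomes$event_month)
  expect_equal(cec_score(adversary, outcomes, Tm - 1), 0.0)
})

test_that("the three-patient toy scores exactly 2/3", {
  outcomes <- data.frame(event_type = c(1L, 2L, 1L),
                         event_month = c(2L, 5L, 7L))
  mass <- array(0, c(3, 2, 12))
  mass[1, , 3] <- c(0.04, 0.01)
  mass[2, , 6] <- c(0.02, 0.03)
  mass[3, , 8] <- c(0.01, 0.03)
  expect_equal(cec_score(mass, outcomes, 11), 2 / 3)
})

test_that("coherence excludes late events, breaks ties to 0, and is argmax-invariant", {
  outcomes <- data.frame(event_type = c(1L, 2L, 1L, 0L),
                         event_month = c(1L, 3L, 9L, 2L))
  mass <- array(1 / 24, c(4, 2, 12))
  mass[1, 1, 2] <- 0.2; mass[2, 2, 4] <- 0.2; mass[3, 2, 10] <- 0.2
  # horizon 5: only patients 1 and 2 count (censored and late excluded)
  expect_equal(cec_score(mass, outcomes, 5), 1.0)
  # adding a patient whose event falls after the horizon changes nothing
  expect_equal(cec_score(mass[1:2, , , drop = FALSE], outcomes[1:2, ], 5),
               cec_score(mass, outcomes, 5))
  # monotone rescaling applied to both events preserves the argmax
  expect_equal(cec_score(mass^2 * 7, outcomes, 5), cec_score(mass, outcomes, 5))
  # exact tie counts as incoherent
  tied <- mass
  tied[1, 2, 2] <- tied[1, 1, 2]
  expect_equal(cec_score(tied, outcomes, 1), 0.0)
  # no qualifying patient: undefined, not zero
  expect_error(cec_score(mass, outcomes, 0), "undefined")
})

test_that("single-risk coherence ties to zero and matches the oracle-grid score", {
  cfg <- default_cohort_config(300, 12, seed = 13)
  cohort <- generate_cohort(cfg)
  # identical models for both events: every comparison ties
  p <- matrix(runif(300 * 12), 300, 12)
  expect_equal(
    cec_score_single_risk(list(death = p, transplant = p), cohort, 11), 0)
  # exact per-event CIF oracles: the pairwise single-risk rule and the
  # argmax rule applied to the same oracle risk grid must agree exactly
  grid <- waitlistcr:::true_cif_grid(cfg, cohort$covariates)
  mu_single <- cec_score_single_risk(
    list(death = grid[, 1, ], transplant = grid[, 2, ]), cohort, 11)
  mu_grid <- cec_score(grid, cohort$outcomes, 11)
  sel <- cohort$outcomes$event_type %in% 1:2 & cohort$outcomes$event_month <= 11
  expect_gt(sum(sel), 0)
  expect_identical(mu_single, mu_grid)
  p1 <- matrix(runif(12), 1, 12)
  expect_error(
    cec_score_single_risk(list(death = p1, transplant = p1),
                          list(outcomes = data.frame(event_type = 0L,
                                                     event_month = 5L),
                               horizon = 12), 11),
    "undefined")
})

test_that("time-dependent concordance equals brute force on random toys", {
  withr::local_seed(77)
  for (trial in 1:100) {
    n <- sample(5:50, 1)
    Tm <- sample(4:10, 1)
    outcomes <- random_outcomes(n, Tm)
    preds <- matrix(runif(n * Tm), n, Tm)
    # make predictor ties common enough to exercise the 0.5 rule
    preds[] <- round(preds, 1)
    ev <- sample(1:2, 1)
    hb <- sample(seq_len(Tm) - 1, 1)
    expected <- cindex_brute(preds, outcomes, ev, hb)
    if (is.na(expected)) {
      expect_error(td_concordance(preds, outcomes, ev, hb), "undefined")
    } else {
      expect_identical(td_concordance(preds, outcomes, ev, hb), expected)
    }
  }
})

test_that("concordance is 1 for a separated oracle and 1/2 for a constant", {
  outcomes <- data.frame(event_type = rep(1L, 6),
                         event_month = c(0L, 1L, 2L, 3L, 4L, 5L))
  # risk curves perfectly ordered by event time
  preds <- outer(6:1, rep(1, 6)) / 10
  expect_equal(td_concordance(preds, outcomes, 1, 5), 1.0)
  expect_equal(td_concordance(matrix(0.4, 6, 6), outcomes, 1, 5), 0.5)
})

test_that("Brier score reproduces the uncensored closed forms", {
  outcomes <- data.frame(event_type = c(1L, 1L, 0L, 0L),
                         event_month = c(1L, 3L, 11L, 11L))
  # no censoring before the horizon; perfect forecasts
  perfect <- c(1, 1, 0, 0)
  expect_equal(brier_score(perfect, outcomes, 1, 5), 0.0)
  expect_equal(brier_score(rep(0.5, 4), outcomes, 1, 5), 0.25)
  # without censoring the IPCW sum is exactly the mean squared error
  withr::local_seed(5)
  p <- runif(4)
  y <- c(1, 1, 0, 0)
  expect_equal(brier_score(p, outcomes, 1, 5), mean((y - p)^2))
})

test_that("Brier score equals the hand-computed IPCW sum on the 8-patient toy", {
  outcomes <- data.frame(
    event_type = c(1L, 0L, 2L, 1L, 0L, 1L, 0L, 1L),
    event_month = c(2L, 1L, 3L, 6L, 7L, 0L, 4L, 5L))
  preds <- c(0.9, 0.3, 0.4, 0.6, 0.2, 0.8, 0.5, 0.7)
  expect_equal(brier_score(preds, outcomes, 1, 5), 113 / 900,
               tolerance = 1e-12)
})

test_that("paired bootstrap comparison is seeded, guarded, and degenerate-safe", {
  withr::local_seed(31)
  n <- 120; Tm <- 12
  outcomes <- random_outcomes(n, Tm)
  preds <- matrix(runif(n * Tm), n, Tm)
  cmp <- bootstrap_compare("cindex", preds, preds, outcomes, 11,
                           n_boot = 100, seed = 9, event = 1)
  expect_equal(cmp$p_value, 1)
  expect_identical(cmp$replicates_a, cmp$replicates_b)
  cmp2 <- bootstrap_compare("cindex", preds, preds, outcomes, 11,
                            n_boot = 100, seed = 9, event = 1)
  expect_identical(cmp$replicates_a, cmp2$replicates_a)
  expect_error(bootstrap_compare("cindex", preds, preds, outcomes, 11,
                                 n_boot = 0, seed = 1, event = 1), "n_boot")
  expect_true(all(cmp$replicates_a >= 0 & cmp$replicates_a <= 1))
})

test_that("the bootstrap separates an oracle from a shuffled predictor", {
  detections <- 0
  for (s in 1:3) {
    withr::local_seed(s)
    cfg <- default_cohort_config(400, 12, seed = 50 + s)
    cohort <- generate_cohort(cfg)
    grid <- waitlistcr:::true_cif_grid(cfg, cohort$covariates)
    oracle <- grid[, 1, ]
    shuffled <- oracle[sample.int(400), ]
    cmp <- bootstrap_compare("cindex", oracle, shuffled, cohort$outcomes,
                             11, n_boot = 200, seed = s, event = 1)
    if (cmp$p_value < 0.01 && cmp$estimate_a > cmp$estimate_b) {
      detections <- detections + 1
    }
  }
  expect_gte(detections, 2)
})

test_that("metric reports serialize to CSV and JSON", {
  tab <- data.frame(model = c("a", "b"), metric = "cindex", event = "death",
                    horizon_month = 12L, estimate = c(0.81234567, 0.7),
                    ci_lower = c(0.7, 0.6), ci_upper = c(0.9, 0.8),
                    p_vs_reference = c(NA, 0.02))
  pc <- withr::local_tempfile(fileext = ".csv")
  pj <- withr::local_tempfile(fileext = ".json")
  write_metric_report(tab, pc, pj)
  back <- utils::read.csv(pc)
  expect_equal(back$estimate[1], 0.812346, tolerance = 1e-9)
  expect_equal(jsonlite::read_json(pj, simplifyVector = TRUE)$estimate[2], 0.7)
})
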