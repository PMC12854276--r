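# Shared fixtures and independent oracles for the test suite. Everything
# is generated in code; heavyweight fits are cached per session.

.fixture_env <- new.env(parent = emptyenv())

# A moderately sized synthetic cohort and a fitted competing-risk model,
# shared across tests that only need "some reasonable fitted model".
shared_fit <- function() {
  if (is.null(.fixture_env$fit)) {
    # horizon 24 keeps the month-12 evaluations away from the final bin,
    # which by the likelihood convention absorbs residual survivor mass
    cfg <- default_cohort_config(n_patients = 1500, horizon = 24, seed = 42)
    cohort <- generate_cohort(cfg)
    hp <- hyperparams(max_epochs = 60, early_stop_patience = 8, seed = 42)
    .fixture_env$cfg <- cfg
    .fixture_env$cohort <- cohort
    .fixture_env$fit <- fit_deephit(cohort, hp)
  }
  list(cfg = .fixture_env$cfg, cohort = .fixture_env$cohort,
       fit = .fixture_env$fit)
}

# Random outcome table for metric toys.
random_outcomes <- function(n, horizon, p_event = c(0.3, 0.35, 0.35)) {
  data.frame(
    event_type = sample(0:2, n, replace = TRUE, prob = p_event),
    event_month = sample.int(horizon, n, replace = TRUE) - 1L
  )
}

# Brute-force O(n^2) time-dependent concordance oracle: explicit loop
# over every ordered pair, independent of the package implementation.
cindex_brute <- function(predictions, outcomes, event, horizon) {
  competing <- setdiff(1:2, event)
  type <- outcomes$event_type
  type[type == competing] <- 0L
  time <- outcomes$event_month
  num <- 0; den <- 0
  n <- nrow(outcomes)
  for (i in seq_len(n)) {
    if (type[i] != event || time[i] > horizon) next
    for (j in seq_len(n)) {
      if (j == i || time[j] <= time[i]) next
      den <- den + 1
      pi <- predictions[i, time[i] + 1]
      pj <- predictions[j, time[i] + 1]
      num <- num + (pi > pj) + 0.5 * (pi == pj)
    }
  }
  if (den == 0) return(NA_real_)
  num / den
}

# Mass array with each patient's largest cell at (event k_i, month l_i);
# the rest of the mass is spread uniformly.
oracle_mass <- function(n, horizon, k, l, peak = 0.5) {
  mass <- array((1 - peak) / (2 * horizon - 1), c(n, 2, horizon))
  for (i in seq_len(n)) mass[i, k[i], l[i] + 1] <- peak
  mass
}

# Mass array from the generator's exact CIF increments (the oracle
# predictor used in coherence tests).
true_mass_array <- function(config, covariates) {
  cif <- waitlistcr:::true_cif_grid(config, covariates)
  mass <- cif
  Tm <- dim(cif)[3]
  if (Tm > 1) mass[, , 2:Tm] <- cif[, , 2:Tm] - cif[, , 1:(Tm - 1)]
  mass
}

# One-month toy config: beta = 0, baseline logits chosen so that
# h_death = 0.3 and h_transplant = 0.2 exactly.
one_month_config <- function(n = 5L) {
  cohort_config(
    n_patients = n, horizon = 1L,
    beta = list(death = c(meld_listing = 0), transplant = c(meld_listing = 0)),
    baseline_logit = list(death = log(0.6), transplant = log(0.4)),
    censoring_rate = 0, seed = 1L
  )
}

# Config with one dominant encoded feature (5x every other coefficient
# magnitude) for the given event; used by importance and coefficient
# direction tests.
dominant_feature_config <- function(n, horizon, seed,
                                    feature = "meld_listing",
                                    event = "death") {
  base <- 0.12
  beta_small <- stats::setNames(rep(base, length(waitlistcr:::encoded_feature_names())),
                                waitlistcr:::encoded_feature_names())
  beta_small["blood_type_B"] <- 0  # a truly uninformative feature
  beta_dom <- beta_small
  beta_dom[feature] <- 5 * base
  cohort_config(
    n_patients = n, horizon = horizon,
    beta = if (event == "death") {
      list(death = beta_dom, transplant = beta_small)
    } else {
      list(death = beta_small, transplant = beta_dom)
    },
    baseline_logit = list(
      death = baseline_logit_curve(-3.6, -0.1, horizon),
      transplant = baseline_logit_curve(-2.6, -0.3, horizon)
    ),
    censoring_rate = 0.005, seed = seed
  )
}
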