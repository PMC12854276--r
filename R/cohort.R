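# Synthetic waitlist cohorts from a known discrete-time cause-specific
# hazard law. Two mutually exclusive terminal events (death, transplant)
# compete on a monthly grid; the per-month cause-specific hazards follow a
# multinomial-logistic model
#   h_k(t | x) = exp(eta_k) / (1 + exp(eta_1) + exp(eta_2)),
#   eta_k = baseline_logit[k][t] + beta_k . x_enc (+ optional interactions),
# which guarantees h_death + h_transplant < 1 in every month and makes the
# cumulative incidence function available in closed form.

#' Construct a synthetic-cohort configuration
#'
#' @param n_patients number of patients to generate.
#' @param horizon number of monthly bins `T` (events land in bins
#'   `0..T-1`; an event during calendar month m is stored in bin m-1).
#' @param covariate_distributions per-feature sampling specs; see
#'   [default_cohort_config()] for the shipped example.
#' @param beta named list with elements `death` and `transplant`, each a
#'   named coefficient vector over the encoded feature names
#'   (z-scored continuous covariates, treatment-coded dummies).
#' @param baseline_logit named list with elements `death` and `transplant`,
#'   each a numeric vector of length `horizon` of per-month intercepts on
#'   the multinomial-logit scale.
#' @param censoring_rate per-month probability of independent (drop-out)
#'   censoring, applied after the event draw in each month; patients who
#'   survive all `horizon` months are administratively censored in the
#'   final bin.
#' @param interactions optional named list (`death`, `transplant`) of
#'   second-order terms, each a list of `list(a =, b =, coef =)` acting on
#'   the encoded (standardized) columns `a * b`.
#' @param seed integer; the same config (seed included) always yields a
#'   byte-identical cohort.
#' @return object of class `wl_cohort_config`.
#' @export
cohort_config <- function(n_patients, horizon = 120L,
                          covariate_distributions = default_covariate_distributions(),
                          beta, baseline_logit, censoring_rate = 0.002,
                          interactions = NULL, seed = 1L) {
  cfg <- structure(
    list(n_patients = as.integer(n_patients), horizon = as.integer(horizon),
         covariate_distributions = covariate_distributions,
         beta = beta, baseline_logit = baseline_logit,
         censoring_rate = censoring_rate, interactions = interactions,
         seed = as.integer(seed)),
    class = "wl_cohort_config"
  )
  validate_cohort_config(cfg)
  cfg
}

validate_cohort_config <- function(cfg) {
  stopifnot(inherits(cfg, "wl_cohort_config"))
  if (cfg$n_patients < 1) stopf("n_patients must be >= 1")
  if (cfg$horizon < 1) stopf("horizon must be >= 1")
  if (!is.finite(cfg$censoring_rate) ||
      cfg$censoring_rate < 0 || cfg$censoring_rate >= 1) {
    stopf("censoring_rate must lie in [0, 1)")
  }
  enc <- encoded_feature_names()
  for (ev in EVENT_NAMES) {
    b <- cfg$beta[[ev]]
    if (is.null(b) || !all(names(b) %in% enc)) {
      stopf("beta$%s must be a named vector over encoded feature names", ev)
    }
    bl <- cfg$baseline_logit[[ev]]
    if (length(bl) != cfg$horizon) {
      stopf("baseline_logit$%s must have length horizon = %d", ev, cfg$horizon)
    }
    bad <- which(!is.finite(bl))
    if (length(bad) > 0) {
      stopf("baseline_logit$%s is non-finite at month bin %d", ev, bad[1] - 1L)
    }
  }
  invisible(cfg)
}

#' Shipped covariate sampling distributions
#'
#' Marginals chosen to mirror a MASH-cirrhosis waitlist population: MELD at
#' listing ~ N(19.4, 8.1) truncated to 6..40, right-skewed labs
#' (log-normal bilirubin/INR/creatinine), hyponatremia-shifted sodium, BMI
#' centred in the obese range, ~50% female, US blood-type frequencies, and
#' an 8% dialysis rate. Covariates are sampled independently.
#'
#' @return named list of per-feature sampling specs.
#' @export
default_covariate_distributions <- function() {
  list(
    meld_listing = list(kind = "normal", mean = 19.4, sd = 8.1, min = 6, max = 40),
    bilirubin = list(kind = "lognormal", meanlog = log(3.0), sdlog = 0.8, max = 60),
    inr = list(kind = "lognormal", meanlog = log(1.5), sdlog = 0.30, max = 12),
    creatinine = list(kind = "lognormal", meanlog = log(1.2), sdlog = 0.50, max = 12),
    sodium = list(kind = "normal", mean = 135, sd = 5, min = 110, max = 155),
    albumin = list(kind = "normal", mean = 3.0, sd = 0.6, min = 0.8, max = 5.5),
    age_listing = list(kind = "normal", mean = 58, sd = 9, min = 18, max = 85),
    sex = list(kind = "categorical", levels = c("female", "male"),
               probs = c(0.50, 0.50)),
    blood_type = list(kind = "categorical", levels = c("A", "B", "AB", "O"),
                      probs = c(0.40, 0.12, 0.04, 0.44)),
    functional_status = list(kind = "ordinal", values = 1:5,
                             probs = c(0.15, 0.30, 0.30, 0.17, 0.08)),
    bmi = list(kind = "normal", mean = 34, sd = 4.5, min = 20, max = 60),
    dialysis_last_week = list(kind = "binary", prob = 0.08)
  )
}

# Moments implied by a sampling spec (truncation ignored for normals; the
# clamp bounds sit several SDs out so the approximation is immaterial).
# These generator-known statistics standardize covariates inside the
# generator itself; fitted models recompute their own training-fold stats.
dist_moments <- function(spec) {
  switch(spec$kind,
    normal = c(mean = spec$mean, sd = spec$sd),
    lognormal = {
      m <- exp(spec$meanlog + spec$sdlog^2 / 2)
      s <- sqrt((exp(spec$sdlog^2) - 1) * exp(2 * spec$meanlog + spec$sdlog^2))
      c(mean = m, sd = s)
    },
    ordinal = {
      m <- sum(spec$values * spec$probs)
      c(mean = m, sd = sqrt(sum(spec$probs * (spec$values - m)^2)))
    },
    stopf("no moments for distribution kind '%s'", spec$kind)
  )
}

encoder_from_config <- function(config) {
  dists <- config$covariate_distributions
  mom <- vapply(FEATURES_CONTINUOUS, function(f) dist_moments(dists[[f]]),
                numeric(2))
  new_encoder(center = mom["mean", ], scale = mom["sd", ])
}

sample_feature <- function(spec, n) {
  switch(spec$kind,
    normal = pmin(pmax(stats::rnorm(n, spec$mean, spec$sd), spec$min), spec$max),
    lognormal = pmin(stats::rlnorm(n, spec$meanlog, spec$sdlog), spec$max),
    categorical = sample(spec$levels, n, replace = TRUE, prob = spec$probs),
    ordinal = sample(spec$values, n, replace = TRUE, prob = spec$probs),
    binary = as.integer(stats::runif(n) < spec$prob),
    stopf("unknown distribution kind '%s'", spec$kind)
  )
}

sample_covariates <- function(config, n) {
  dists <- config$covariate_distributions
  out <- lapply(covariate_names(), function(f) sample_feature(dists[[f]], n))
  names(out) <- covariate_names()
  as.data.frame(out, stringsAsFactors = FALSE)
}

# Linear predictors eta_k for all patients x months; X is the encoded matrix.
config_eta <- function(config, X, event_name) {
  beta <- config$beta[[event_name]]
  lp <- as.vector(X[, names(beta), drop = FALSE] %*% beta)
  inter <- config$interactions[[event_name]]
  if (!is.null(inter)) {
    for (term in inter) {
      lp <- lp + term$coef * X[, term$a] * X[, term$b]
    }
  }
  outer(lp, config$baseline_logit[[event_name]], "+")
}

# Per-month cause-specific hazards, n x T per event.
config_hazards <- function(config, covariates) {
  enc <- encoder_from_config(config)
  X <- encode_covariates(enc, covariates)
  e1 <- exp(config_eta(config, X, "death"))
  e2 <- exp(config_eta(config, X, "transplant"))
  denom <- 1 + e1 + e2
  h <- list(death = e1 / denom, transplant = e2 / denom)
  for (ev in EVENT_NAMES) {
    bad <- which(!is.finite(h[[ev]]) | h[[ev]] < 0 | h[[ev]] >= 1,
                 arr.ind = TRUE)
    if (nrow(bad) > 0) {
      stopf("configuration yields invalid %s hazard at month bin %d",
            ev, bad[1, 2] - 1L)
    }
  }
  h
}

#' Generate a synthetic waitlist cohort
#'
#' Samples covariates, evaluates the cause-specific monthly hazards for
#' every patient, and walks each patient month by month: event draw first
#' (multinomial over no-event / death / transplant), then an independent
#' censoring draw among event-free patients. Survivors of all `horizon`
#' months are administratively censored in the final bin.
#'
#' @param config a [cohort_config()].
#' @return object of class `wl_cohort`: list with `covariates` (data.frame),
#'   `outcomes` (data.frame with integer `event_type` 0/1/2 and
#'   `event_month` in `0..horizon-1`), `feature_names`, `horizon`.
#' @export
generate_cohort <- function(config) {
  validate_cohort_config(config)
  with_seed(config$seed, {
    n <- config$n_patients
    Tm <- config$horizon
    covariates <- sample_covariates(config, n)
    h <- config_hazards(config, covariates)
    U <- matrix(stats::runif(n * Tm), n, Tm)
    V <- matrix(stats::runif(n * Tm), n, Tm)
    event_here <- U < (h$death + h$transplant)
    censor_here <- !event_here & (V < config$censoring_rate)
    any_here <- event_here | censor_here
    has_any <- rowSums(any_here) > 0
    first <- max.col(any_here, ties.method = "first")  # 1-based month column
    event_type <- integer(n)
    event_month <- rep.int(Tm - 1L, n)
    idx <- which(has_any)
    if (length(idx) > 0) {
      j <- first[idx]
      flat <- cbind(idx, j)
      is_event <- event_here[flat]
      is_death <- U[flat] < h$death[flat]
      event_type[idx] <- ifelse(is_event, ifelse(is_death, EVENT_DEATH,
                                                 EVENT_TRANSPLANT),
                                EVENT_CENSORED)
      event_month[idx] <- j - 1L
    }
    new_cohort(covariates,
               data.frame(event_type = as.integer(event_type),
                          event_month = as.integer(event_month)),
               horizon = Tm)
  })
}

new_cohort <- function(covariates, outcomes, horizon) {
  stopifnot(nrow(covariates) == nrow(outcomes))
  if (anyNA(outcomes$event_type) || anyNA(outcomes$event_month)) {
    stopf("outcomes contain missing values")
  }
  if (any(outcomes$event_month < 0 | outcomes$event_month >= horizon)) {
    stopf("event_month outside 0..%d", horizon - 1L)
  }
  if (!all(outcomes$event_type %in% 0:2)) {
    stopf("event_type must be 0 (censored), 1 (death) or 2 (transplant)")
  }
  structure(list(covariates = covariates, outcomes = outcomes,
                 feature_names = covariate_names(),
                 horizon = as.integer(horizon)),
            class = "wl_cohort")
}

#' @export
print.wl_cohort <- function(x, ...) {
  tab <- table(factor(x$outcomes$event_type, levels = 0:2,
                      labels = c("censored", "death", "transplant")))
  cat(sprintf("<wl_cohort> %d patients, %d-month horizon\n",
              nrow(x$covariates), x$horizon))
  cat(sprintf("  events: %s\n",
              paste(sprintf("%s %d (%.1f%%)", names(tab), tab,
                            100 * tab / nrow(x$covariates)),
                    collapse = ", ")))
  invisible(x)
}

#' Subset a cohort by patient index
#' @param cohort a `wl_cohort`.
#' @param idx integer or logical index vector.
#' @return a `wl_cohort` with the selected patients.
#' @export
cohort_subset <- function(cohort, idx) {
  new_cohort(cohort$covariates[idx, , drop = FALSE],
             cohort$outcomes[idx, , drop = FALSE],
             cohort$horizon)
}

#' Closed-form cumulative incidence under a cohort configuration
#'
#' The generator's exact CIF oracle:
#' `CIF_k(t|x) = sum_{tau<=t} h_k(tau|x) * prod_{s<tau} (1 - h_death - h_transplant)`.
#' Independent censoring is excluded: the CIF is a net quantity of the
#' event process.
#'
#' @param config a [cohort_config()].
#' @param x covariate data.frame (one or more rows).
#' @param event event id (1/"death" or 2/"transplant").
#' @param t month bin in `0..horizon-1`.
#' @return numeric vector, CIF per row of `x`.
#' @export
true_cif <- function(config, x, event, t) {
  ev <- resolve_event(event)
  if (t < 0 || t >= config$horizon) stopf("t must lie in 0..%d", config$horizon - 1L)
  grid <- true_cif_grid(config, x)
  unname(grid[, ev, t + 1L])
}

# Full oracle CIF surface: n x K x T array of CIF_k(t | x_i).
true_cif_grid <- function(config, covariates) {
  h <- config_hazards(config, covariates)
  n <- nrow(h$death)
  Tm <- ncol(h$death)
  surv <- t(apply(1 - h$death - h$transplant, 1, cumprod))
  if (n == 1) surv <- matrix(surv, 1, Tm)
  # probability of still being event-free entering month tau (tau 1-based)
  atrisk <- cbind(rep(1, n), surv[, -Tm, drop = FALSE])
  out <- array(0, dim = c(n, 2, Tm),
               dimnames = list(NULL, EVENT_NAMES, NULL))
  out[, 1, ] <- t(apply(h$death * atrisk, 1, cumsum))
  out[, 2, ] <- t(apply(h$transplant * atrisk, 1, cumsum))
  out
}

#' Map a waitlist removal reason to an event id
#'
#' Deterioration-driven removals count as death; removals for improvement
#' or other administrative reasons are censored.
#'
#' @param removal_reason character vector over
#'   `{died, deteriorated, transplanted, improved, other}`.
#' @return integer vector: 0 censored, 1 death, 2 transplant.
#' @export
classify_waitlist_outcome <- function(removal_reason) {
  map <- c(died = EVENT_DEATH, deteriorated = EVENT_DEATH,
           transplanted = EVENT_TRANSPLANT,
           improved = EVENT_CENSORED, other = EVENT_CENSORED)
  bad <- setdiff(unique(removal_reason), names(map))
  if (length(bad) > 0) {
    stopf("unknown removal reason(s): %s", paste(bad, collapse = ", "))
  }
  unname(map[removal_reason])
}
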