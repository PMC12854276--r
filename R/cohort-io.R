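# Cohort CSV template: one row per patient, the 12 covariate columns in
# canonical order plus event_type (0/1/2) and event_month (0..T-1).
# Numeric values are written at 6 significant digits so that a
# read -> write cycle is byte-stable. Empty cells mean missing and are
# rejected on read; the package performs no imputation.

#' Write a cohort to the CSV template
#'
#' @param cohort a `wl_cohort`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_cohort_csv <- function(cohort, path) {
  stopifnot(inherits(cohort, "wl_cohort"))
  df <- cbind(cohort$covariates, cohort$outcomes)
  for (f in names(df)) {
    if (is.numeric(df[[f]]) && !is.integer(df[[f]])) {
      df[[f]] <- formatC(signif(df[[f]], 6), format = "g", digits = 6)
    }
  }
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE,
                   fileEncoding = "UTF-8")
  invisible(path)
}

#' Read a cohort from the CSV template
#'
#' @param path CSV file path.
#' @param horizon monthly horizon `T` the event months must respect.
#' @return a `wl_cohort`.
#' @export
read_cohort_csv <- function(path, horizon = 120L) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        fileEncoding = "UTF-8", na.strings = "")
  need <- c(covariate_names(), "event_type", "event_month")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols) > 0) {
    stopf("cohort CSV lacks columns: %s", paste(missing_cols, collapse = ", "))
  }
  if (anyNA(df)) {
    stopf("cohort CSV contains missing values (empty cells); rows: %s",
          paste(utils::head(which(rowSums(is.na(df)) > 0), 5), collapse = ", "))
  }
  covariates <- validate_covariates(df[covariate_names()])
  new_cohort(covariates,
             data.frame(event_type = as.integer(df$event_type),
                        event_month = as.integer(df$event_month)),
             horizon = horizon)
}

#' Read a cohort configuration from YAML or JSON
#'
#' The file must carry an explicit `seed`. `baseline_logit` entries may be
#' either full per-month vectors or `list(intercept =, slope =)` curve
#' parameters expanded via [baseline_logit_curve()].
#'
#' @param path file path ending in .yaml/.yml or .json.
#' @return a [cohort_config()].
#' @export
read_cohort_config <- function(path) {
  raw <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    yaml::read_yaml(path)
  } else if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    stopf("config file must be .yaml/.yml or .json: %s", path)
  }
  if (is.null(raw$seed)) stopf("cohort config must state an explicit seed")
  horizon <- as.integer(raw$horizon %||% 120L)
  bl <- lapply(raw$baseline_logit, function(b) {
    if (!is.null(names(b)) && all(c("intercept", "slope") %in% names(b))) {
      baseline_logit_curve(b$intercept, b$slope, horizon)
    } else {
      as.numeric(unlist(b))
    }
  })
  beta <- lapply(raw$beta, function(b) unlist(b))
  dists <- raw$covariate_distributions %||% default_covariate_distributions()
  cohort_config(
    n_patients = raw$n_patients, horizon = horizon,
    covariate_distributions = dists,
    beta = beta, baseline_logit = bl,
    censoring_rate = raw$censoring_rate %||% 0.002,
    interactions = raw$interactions,
    seed = raw$seed
  )
}

#' Write a cohort configuration to YAML or JSON
#'
#' @param config a [cohort_config()].
#' @param path file path ending in .yaml/.yml or .json.
#' @return `path`, invisibly.
#' @export
write_cohort_config <- function(config, path) {
  validate_cohort_config(config)
  raw <- unclass(config)
  raw$beta <- lapply(raw$beta, as.list)
  if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    yaml::write_yaml(raw, path, precision = 17)
  } else if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(raw, path, auto_unbox = TRUE, digits = I(17),
                         pretty = TRUE)
  } else {
    stopf("config file must be .yaml/.yml or .json: %s", path)
  }
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
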