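# Feature schema shared by the generator and every model: nine numeric
# covariates (functional status enters as an ordinal score), two categorical
# covariates expanded to treatment-coded dummies (reference = first level),
# and one binary flag. Continuous/ordinal columns are z-scored; dummies and
# the flag are left on the 0/1 scale.

FEATURES_CONTINUOUS <- c("meld_listing", "bilirubin", "inr", "creatinine",
                         "sodium", "albumin", "age_listing",
                         "functional_status", "bmi")
FEATURES_CATEGORICAL <- list(
  sex = c("female", "male"),
  blood_type = c("A", "B", "AB", "O")
)
FEATURES_BINARY <- "dialysis_last_week"

#' Raw covariate column names, in canonical order
#' @return character vector of the 12 covariate names.
#' @export
covariate_names <- function() {
  c("meld_listing", "bilirubin", "inr", "creatinine", "sodium", "albumin",
    "age_listing", "sex", "blood_type", "functional_status", "bmi",
    "dialysis_last_week")
}

encoded_feature_names <- function() {
  dummies <- unlist(lapply(names(FEATURES_CATEGORICAL), function(f) {
    paste(f, FEATURES_CATEGORICAL[[f]][-1], sep = "_")
  }))
  c(FEATURES_CONTINUOUS, dummies, FEATURES_BINARY)
}

#' Validate a covariate table
#'
#' Checks column presence, finiteness of numeric fields, categorical domains
#' and clinical ranges. Missing values are rejected (no imputation is done
#' anywhere in the package).
#'
#' @param covariates data.frame with the columns of [covariate_names()].
#' @return the validated data.frame, with categorical columns as character.
#' @export
validate_covariates <- function(covariates) {
  covariates <- as.data.frame(covariates)
  missing_cols <- setdiff(covariate_names(), names(covariates))
  if (length(missing_cols) > 0) {
    stopf("covariate table lacks columns: %s",
          paste(missing_cols, collapse = ", "))
  }
  covariates <- covariates[, covariate_names(), drop = FALSE]
  for (f in c(FEATURES_CONTINUOUS, FEATURES_BINARY)) {
    v <- covariates[[f]]
    if (!is.numeric(v) && !is.logical(v)) {
      stopf("covariate '%s' must be numeric", f)
    }
    if (anyNA(v) || any(!is.finite(as.numeric(v)))) {
      stopf("covariate '%s' contains missing or non-finite values", f)
    }
  }
  for (f in names(FEATURES_CATEGORICAL)) {
    v <- as.character(covariates[[f]])
    bad <- setdiff(unique(v), FEATURES_CATEGORICAL[[f]])
    if (anyNA(covariates[[f]]) || length(bad) > 0) {
      stopf("covariate '%s' has values outside {%s}", f,
            paste(FEATURES_CATEGORICAL[[f]], collapse = ", "))
    }
    covariates[[f]] <- v
  }
  positive <- c("bilirubin", "inr", "creatinine", "albumin", "bmi")
  for (f in positive) {
    if (any(covariates[[f]] <= 0)) stopf("covariate '%s' must be > 0", f)
  }
  if (any(covariates$functional_status < 1 | covariates$functional_status > 5)) {
    stopf("functional_status must lie in 1..5")
  }
  if (any(covariates$age_listing < 18)) stopf("age_listing must be >= 18")
  covariates$dialysis_last_week <- as.integer(covariates$dialysis_last_week != 0)
  covariates
}

#' Build a covariate encoder from training data
#'
#' Computes z-scoring statistics for continuous/ordinal covariates on the
#' supplied (training) data and freezes them, together with the one-hot
#' layout, into an encoder object. Models store this encoder so that test
#' or forecast inputs are standardized with training-only statistics.
#'
#' @param covariates training covariate data.frame.
#' @return an object of class `wl_encoder`.
#' @export
make_encoder <- function(covariates) {
  covariates <- validate_covariates(covariates)
  center <- vapply(covariates[FEATURES_CONTINUOUS], mean, numeric(1))
  scale <- vapply(covariates[FEATURES_CONTINUOUS], stats::sd, numeric(1))
  scale[!is.finite(scale) | scale < 1e-12] <- 1
  new_encoder(center, scale)
}

new_encoder <- function(center, scale) {
  structure(
    list(center = center, scale = scale,
         feature_names = covariate_names(),
         encoded_names = encoded_feature_names(),
         schema = schema_hash(covariate_names())),
    class = "wl_encoder"
  )
}

#' Encode covariates to the model design matrix
#'
#' @param encoder a `wl_encoder`.
#' @param covariates covariate data.frame (any number of rows).
#' @return numeric matrix, one row per patient, columns named as
#'   `encoder$encoded_names`.
#' @export
encode_covariates <- function(encoder, covariates) {
  stopifnot(inherits(encoder, "wl_encoder"))
  covariates <- validate_covariates(covariates)
  n <- nrow(covariates)
  cont <- as.matrix(covariates[FEATURES_CONTINUOUS])
  cont <- sweep(sweep(cont, 2, encoder$center), 2, encoder$scale, "/")
  dummies <- lapply(names(FEATURES_CATEGORICAL), function(f) {
    lv <- FEATURES_CATEGORICAL[[f]]
    m <- vapply(lv[-1], function(l) as.numeric(covariates[[f]] == l),
                numeric(n))
    if (n == 1) m <- matrix(m, nrow = 1, dimnames = list(NULL, lv[-1]))
    colnames(m) <- paste(f, lv[-1], sep = "_")
    m
  })
  out <- cbind(cont, do.call(cbind, dummies),
               dialysis_last_week = covariates$dialysis_last_week)
  colnames(out) <- encoder$encoded_names
  out
}
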