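# MELD score calculators following the published OPTN definitions.
# All inputs are vectorized; rounding to an integer score happens only at
# the clinically reported stages (the initial MELD before the sodium
# correction gate, and the final score), and the final score is clamped
# to the allocation range 6..40.

check_labs <- function(...) {
  labs <- list(...)
  for (nm in names(labs)) {
    v <- labs[[nm]]
    if (anyNA(v) || any(!is.finite(v)) || any(v <= 0)) {
      stopf("%s must be positive and finite", nm)
    }
  }
}

#' MELD-Na score
#'
#' `MELD = round(10 * (0.957 ln Cr + 0.378 ln Bili + 1.120 ln INR + 0.643))`
#' with labs floored at 1.0 and creatinine capped at 4.0 (forced to 4.0
#' under dialysis). If the score exceeds 11, the sodium correction
#' `1.32 (137 - Na) - 0.033 MELD (137 - Na)` is added with sodium clamped
#' to 125..137 mEq/L. The final score is rounded and clamped to 6..40.
#'
#' @param bilirubin serum bilirubin, mg/dL.
#' @param inr international normalized ratio.
#' @param creatinine serum creatinine, mg/dL.
#' @param sodium serum sodium, mEq/L.
#' @param dialysis_last_week logical; at least two dialysis sessions (or
#'   24h CVVHD) in the prior week.
#' @return integer score in 6..40 (vectorized).
#' @export
meld_na <- function(bilirubin, inr, creatinine, sodium,
                    dialysis_last_week = FALSE) {
  check_labs(bilirubin = bilirubin, inr = inr, creatinine = creatinine,
             sodium = sodium)
  bili <- pmax(bilirubin, 1)
  inr <- pmax(inr, 1)
  cr <- pmax(creatinine, 1)
  cr <- ifelse(dialysis_last_week, 4, pmin(cr, 4))
  meld <- round(10 * (0.957 * log(cr) + 0.378 * log(bili) +
                        1.120 * log(inr) + 0.643))
  na <- pmin(pmax(sodium, 125), 137)
  corrected <- meld + 1.32 * (137 - na) - 0.033 * meld * (137 - na)
  score <- ifelse(meld > 11, corrected, meld)
  as.integer(pmin(pmax(round(score), 6), 40))
}

#' MELD 3.0 score
#'
#' The sex-adjusted successor to MELD-Na:
#' `1.33 [female] + 4.56 ln Bili + 0.82 (137 - Na)
#'  - 0.24 (137 - Na) ln Bili + 9.09 ln INR + 11.14 ln Cr
#'  + 1.85 (3.5 - Alb) - 1.83 (3.5 - Alb) ln Cr + 6`
#' with bilirubin/INR/creatinine floored at 1.0, creatinine capped at 3.0
#' (forced to 3.0 under dialysis), sodium clamped to 125..137 and albumin
#' to 1.5..3.5. Rounded and clamped to 6..40.
#'
#' @inheritParams meld_na
#' @param albumin serum albumin, g/dL.
#' @param sex `"female"` or `"male"` (vectorized).
#' @return integer score in 6..40 (vectorized).
#' @export
meld_30 <- function(bilirubin, inr, creatinine, sodium, albumin, sex,
                    dialysis_last_week = FALSE) {
  check_labs(bilirubin = bilirubin, inr = inr, creatinine = creatinine,
             sodium = sodium, albumin = albumin)
  if (!all(sex %in% c("female", "male"))) {
    stopf("sex must be 'female' or 'male'")
  }
  bili <- pmax(bilirubin, 1)
  inr <- pmax(inr, 1)
  cr <- pmax(creatinine, 1)
  cr <- ifelse(dialysis_last_week, 3, pmin(cr, 3))
  na <- pmin(pmax(sodium, 125), 137)
  alb <- pmin(pmax(albumin, 1.5), 3.5)
  female <- as.numeric(sex == "female")
  score <- 1.33 * female + 4.56 * log(bili) + 0.82 * (137 - na) -
    0.24 * (137 - na) * log(bili) + 9.09 * log(inr) + 11.14 * log(cr) +
    1.85 * (3.5 - alb) - 1.83 * (3.5 - alb) * log(cr) + 6
  as.integer(pmin(pmax(round(score), 6), 40))
}

#' MELD scores for every patient of a cohort
#'
#' @param cohort a `wl_cohort`.
#' @param version `"meld_na"` or `"meld_30"`.
#' @return integer vector of scores.
#' @export
cohort_meld <- function(cohort, version = c("meld_na", "meld_30")) {
  version <- match.arg(version)
  cv <- cohort$covariates
  if (version == "meld_na") {
    meld_na(cv$bilirubin, cv$inr, cv$creatinine, cv$sodium,
            cv$dialysis_last_week == 1)
  } else {
    meld_30(cv$bilirubin, cv$inr, cv$creatinine, cv$sodium, cv$albumin,
            cv$sex, cv$dialysis_last_week == 1)
  }
}
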