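#' Estimated glomerular filtration rate (CKD-EPI creatinine, 2009)
#'
#' eGFR = 141 * min(Scr/kappa, 1)^alpha * max(Scr/kappa, 1)^-1.209 *
#' 0.993^Age * 1.018[if female] * 1.159[if black], with kappa = 0.7
#' (female) / 0.9 (male) and alpha = -0.329 (female) / -0.411 (male).
#' Continuous at Scr = kappa and strictly decreasing in both Scr and
#' age. Ancestry arrives as a pre-resolved boolean; no code-table or
#' ancestry inference is attempted.
#'
#' @param scr_mg_dl serum creatinine in mg/dL (> 0); see
#'   \code{\link{convertCreatinine}}.
#' @param age_years age in years (>= 0).
#' @param female logical/0-1.
#' @param black logical/0-1 (default 0).
#' @return eGFR in ml/min/1.73 m^2. Vectorised.
#' @examples
#' egfrCkdEpi(0.7, 0, female = TRUE)    # 143.538
#' egfrCkdEpi(0.7, 60, female = TRUE)   # about 94.2
#' @export
egfrCkdEpi <- function(scr_mg_dl, age_years, female, black = FALSE) {
    if (any(scr_mg_dl <= 0)) stop("creatinine must be positive")
    if (any(age_years < 0)) stop("age must be >= 0")
    female <- as.logical(female); black <- as.logical(black)
    kappa <- ifelse(female, 0.7, 0.9)
    alpha <- ifelse(female, -0.329, -0.411)
    r <- scr_mg_dl / kappa
    141 * pmin(r, 1)^alpha * pmax(r, 1)^-1.209 * 0.993^age_years *
        ifelse(female, 1.018, 1) * ifelse(black, 1.159, 1)
}

#' Convert serum creatinine to mg/dL
#'
#' Laboratory creatinine is commonly reported in umol/L; the CKD-EPI
#' equation needs mg/dL (division by 88.42). The unit tag is explicit
#' and never guessed: a silent unit error would shift eGFR by three
#' orders of magnitude.
#'
#' @param value creatinine value(s).
#' @param unit \code{"umol_L"} or \code{"mg_dL"}.
#' @return creatinine in mg/dL.
#' @export
convertCreatinine <- function(value, unit = c("umol_L", "mg_dL")) {
    unit <- match.arg(unit)
    switch(unit, umol_L = value / 88.42, mg_dL = value)
}

#' Chronic kidney disease flag
#'
#' CKD is defined as eGFR below 60 ml/min/1.73 m^2 (strict inequality)
#' OR a pre-resolved diagnosis/procedure code flag (chronic kidney
#' disease, dialysis, transplantation).
#'
#' @param egfr eGFR in ml/min/1.73 m^2.
#' @param diagnosis_code_flag logical/0-1.
#' @return integer 0/1 flag. Vectorised.
#' @export
classifyCKD <- function(egfr, diagnosis_code_flag) {
    as.integer(egfr < 60 | as.logical(diagnosis_code_flag))
}

#' Hypertension flag
#'
#' Hypertensive medication, or prior diagnosis, or blood pressure at
#' or above 140/90 mmHg (OR across the systolic and diastolic
#' thresholds).
#'
#' @param medication_flag,diagnosis_flag logical/0-1.
#' @param sbp,dbp systolic/diastolic blood pressure (mmHg).
#' @return integer 0/1 flag. Vectorised.
#' @export
classifyHypertension <- function(medication_flag, diagnosis_flag,
                                 sbp, dbp) {
    as.integer(as.logical(medication_flag) |
               as.logical(diagnosis_flag) |
               sbp >= 140 | dbp >= 90)
}

#' Recode raw questionnaire covariates
#'
#' Alcohol intake frequency maps to 1 only for "Daily or almost
#' daily"; smoking status to 1 only for "Current" ("Previous" and
#' "Never" are 0); ethnicity to 0 for "White" and 1 otherwise; the
#' waist-to-hip ratio is waist / hip circumference.
#'
#' @param raw data.frame with any of the columns
#'   \code{alcohol_frequency}, \code{smoking_status},
#'   \code{ethnic_background} (character), \code{waist}, \code{hip}
#'   (cm).
#' @return the data.frame with coded columns \code{alcohol_daily},
#'   \code{smoker_current}, \code{ethnicity_nonwhite}, \code{whr}
#'   appended where derivable.
#' @export
codeCovariates <- function(raw) {
    if (!is.null(raw$alcohol_frequency))
        raw$alcohol_daily <-
            as.integer(raw$alcohol_frequency == "Daily or almost daily")
    if (!is.null(raw$smoking_status))
        raw$smoker_current <- as.integer(raw$smoking_status == "Current")
    if (!is.null(raw$ethnic_background))
        raw$ethnicity_nonwhite <-
            as.integer(raw$ethnic_background != "White")
    if (!is.null(raw$waist) && !is.null(raw$hip))
        raw$whr <- raw$waist / raw$hip
    raw
}

#' Cohort quality-control filter cascade
#'
#' Exclusion order: (1) subjects missing any required covariate; (2)
#' among the remainder, subjects with either kidney volume below the
#' lower limit (30 ml) - a subject is excluded even when the other
#' kidney has full coverage. The function is idempotent and
#' kept + excluded always equals the input count. Extreme S2S values
#' are flagged (not excluded) separately via
#' \code{\link{flagS2SOutliers}}.
#'
#' @param cohort data.frame, one row per subject.
#' @param covariate_cols columns required to be non-missing.
#' @param volume_cols per-kidney volume columns (ml).
#' @param min_volume lower volume limit in ml (default 30).
#' @return list with \code{kept} (data.frame), \code{tally} (named
#'   counts: missing_covariates, low_volume, kept),
#'   \code{exclusion_reason} (per input row:
#'   \code{"missing_covariates"}, \code{"low_volume"}, \code{"none"}).
#' @export
qcFilter <- function(cohort,
                     covariate_cols = setdiff(names(cohort),
                                              c("subject_id")),
                     volume_cols = intersect(
                         c("kidney_volume_left", "kidney_volume_right"),
                         names(cohort)),
                     min_volume = 30) {
    reason <- rep("none", nrow(cohort))
    miss <- rep(FALSE, nrow(cohort))
    for (cn in covariate_cols) miss <- miss | is.na(cohort[[cn]])
    reason[miss] <- "missing_covariates"
    low <- rep(FALSE, nrow(cohort))
    for (cn in volume_cols)
        low <- low | (!is.na(cohort[[cn]]) & cohort[[cn]] < min_volume)
    reason[!miss & low] <- "low_volume"
    kept <- cohort[reason == "none", , drop = FALSE]
    tally <- c(missing_covariates = sum(reason == "missing_covariates"),
               low_volume = sum(reason == "low_volume"),
               kept = nrow(kept))
    list(kept = kept, tally = tally, exclusion_reason = reason)
}

#' Flag extreme S2S values without excluding subjects
#'
#' Marks values outside the lower/upper quantiles (defaults 0.1\% and
#' 99.9\%) of the pooled S2S distribution, for visual review.
#'
#' @param s2s subjects x vertices matrix or
#'   \linkS4class{S2SExperiment}.
#' @param quantiles length-2 probabilities.
#' @return logical matrix of the same shape as the S2S matrix.
#' @export
flagS2SOutliers <- function(s2s, quantiles = c(0.001, 0.999)) {
    m <- if (is(s2s, "S2SExperiment")) s2sMatrix(s2s) else as.matrix(s2s)
    q <- stats::quantile(m, quantiles)
    m < q[1] | m > q[2]
}

#' Derive the engineered phenotype table
#'
#' Adds eGFR (from creatinine in umol/L unless \code{creatinine_unit}
#' says otherwise) and the CKD and hypertension flags to a raw
#' phenotype table from the synthetic generator or a real cohort.
#'
#' @param raw data.frame with columns \code{serum_creatinine},
#'   \code{age}, \code{sex} (1 = male), optional \code{black},
#'   \code{ckd} (diagnosis codes), \code{htn_medication},
#'   \code{htn_diagnosis}, \code{sbp}, \code{dbp}.
#' @param creatinine_unit unit of \code{serum_creatinine}.
#' @return the table with \code{egfr}, \code{ckd_flag},
#'   \code{htn_flag} columns appended where derivable.
#' @export
derivePhenotypes <- function(raw, creatinine_unit = "umol_L") {
    scr <- convertCreatinine(raw$serum_creatinine, creatinine_unit)
    raw$egfr <- egfrCkdEpi(scr, raw$age, female = raw$sex == 0,
                           black = if (is.null(raw$black)) FALSE
                                   else raw$black)
    code <- if (!is.null(raw$ckd)) raw$ckd else 0
    raw$ckd_flag <- classifyCKD(raw$egfr, code)
    if (!is.null(raw$sbp) && !is.null(raw$dbp)) {
        med <- if (is.null(raw$htn_medication)) 0 else raw$htn_medication
        dia <- if (is.null(raw$htn_diagnosis)) 0 else raw$htn_diagnosis
        raw$htn_flag <- classifyHypertension(med, dia, raw$sbp, raw$dbp)
    }
    raw
}
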