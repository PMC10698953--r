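#' Assemble censored time-to-event records
#'
#' Time is censored at the first event, death, or the administrative
#' end of follow-up, whichever comes first after baseline; the event
#' indicator is 1 only when the event itself comes first. Dates may be
#' \code{Date}s (converted to years via 365.25) or numeric years.
#'
#' @param event_dates per-subject event date or NA when no event.
#' @param baseline_dates per-subject baseline (imaging visit) date.
#' @param end_of_followup single administrative end date.
#' @param death_dates per-subject death date or NA.
#' @param subject_ids optional ids.
#' @return data.frame with \code{subject_id}, \code{time} (years > 0),
#'   \code{event} (0/1). Subjects with events on or before baseline
#'   are dropped (prevalent cases).
#' @export
censorAndAssemble <- function(event_dates, baseline_dates,
                              end_of_followup, death_dates = NULL,
                              subject_ids = NULL) {
    to_years <- function(x) {
        if (inherits(x, "Date")) as.numeric(x) / 365.25 else as.numeric(x)
    }
    ev <- to_years(event_dates)
    bl <- to_years(baseline_dates)
    eof <- to_years(end_of_followup)
    dd <- if (is.null(death_dates)) rep(NA_real_, length(bl))
          else to_years(death_dates)
    if (is.null(subject_ids)) subject_ids <- seq_along(bl)

    prevalent <- !is.na(ev) & ev <= bl
    stop_t <- pmin(ifelse(is.na(ev), Inf, ev),
                   ifelse(is.na(dd), Inf, dd), eof)
    event <- as.integer(!is.na(ev) & ev <= stop_t)
    out <- data.frame(subject_id = subject_ids,
                      time = stop_t - bl, event = event)
    out <- out[!prevalent & out$time > 0, , drop = FALSE]
    rownames(out) <- NULL
    out
}

#' Cox proportional hazards model on shape scores and covariates
#'
#' Partial-likelihood fit with Efron handling of tied event times,
#' reported as hazard ratios with Wald 95\% confidence intervals
#' exp(beta +/- 1.96 SE). Continuous predictors are standardised to
#' unit SD by default so hazard ratios are per-SD (recorded in the
#' output); separation (runaway coefficients) is flagged rather than
#' silently reported.
#'
#' @param records data.frame with \code{time}, \code{event} and the
#'   predictor columns.
#' @param predictor_set character vector of predictor column names.
#' @param standardise standardise continuous predictors (default
#'   TRUE).
#' @return data.frame of hazard estimates: \code{predictor},
#'   \code{beta}, \code{se}, \code{hr}, \code{ci_low}, \code{ci_high},
#'   \code{p}, \code{flagged}, plus attribute
#'   \code{"standardised"}.
#' @export
fitCoxModel <- function(records, predictor_set, standardise = TRUE) {
    if (sum(records$event) < 1) stop("need at least one event")
    missing_p <- setdiff(predictor_set, names(records))
    if (length(missing_p))
        stop("predictors absent: ", paste(missing_p, collapse = ", "))
    X <- records[predictor_set]
    const <- vapply(X, function(v) stats::sd(v) < 1e-12, logical(1))
    if (any(const))
        stop("constant predictor(s): ",
             paste(predictor_set[const], collapse = ", "))
    if (standardise) {
        cont <- vapply(X, function(v) length(unique(v)) > 2L, logical(1))
        if (any(cont))
            X[cont] <- standardiseColumns(X[cont])$x
    }
    d <- cbind(records[c("time", "event")], X)
    fml <- stats::as.formula(paste("survival::Surv(time, event) ~",
        paste(sprintf("`%s`", predictor_set), collapse = " + ")))
    fit <- tryCatch(
        survival::coxph(fml, data = d, ties = "efron"),
        warning = function(w) {
            f <- suppressWarnings(survival::coxph(fml, data = d,
                                                  ties = "efron"))
            attr(f, "warned") <- conditionMessage(w)
            f
        })
    beta <- stats::coef(fit)
    se <- sqrt(diag(stats::vcov(fit)))
    flagged <- abs(beta) > 15 | se > 100
    if (any(flagged))
        warning("possible separation for: ",
                paste(names(beta)[flagged], collapse = ", "))
    out <- data.frame(
        predictor = predictor_set,
        beta = as.numeric(beta), se = as.numeric(se),
        hr = exp(as.numeric(beta)),
        ci_low = exp(as.numeric(beta) - 1.96 * as.numeric(se)),
        ci_high = exp(as.numeric(beta) + 1.96 * as.numeric(se)),
        p = 2 * stats::pnorm(-abs(as.numeric(beta) / as.numeric(se))),
        flagged = as.logical(flagged))
    rownames(out) <- NULL
    attr(out, "standardised") <- standardise
    out
}

#' BH-FDR across a family of survival tests
#'
#' Adjusts the collected p-values of hazard estimates across
#' outcomes, kidneys and predictors within one run (the correction
#' family is whatever is passed in, and is recorded in the result).
#'
#' @param estimates data.frame as returned by
#'   \code{\link{fitCoxModel}}, possibly row-bound across models; may
#'   carry \code{outcome} / \code{kidney} annotation columns.
#' @param alpha significance threshold on the adjusted values.
#' @return the data.frame with \code{p_fdr} and \code{significant}
#'   columns appended.
#' @export
fdrAcrossTests <- function(estimates, alpha = 0.05) {
    estimates$p_fdr <- bhFdr(estimates$p)
    estimates$significant <- estimates$p_fdr < alpha
    attr(estimates, "fdr_family_size") <- nrow(estimates)
    estimates
}

#' Format a hazard estimate row in report style
#'
#' @param est one row of a hazard-estimate data.frame.
#' @return string like \code{"HR: 0.74, 95\% CI: 0.61-0.90"}.
#' @export
formatHazard <- function(est) {
    sprintf("HR: %.2f, 95%% CI: %.2f-%.2f", est$hr, est$ci_low,
            est$ci_high)
}
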