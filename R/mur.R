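#' Standardise columns to zero mean and unit (population) SD
#'
#' Continuous model variables enter the vertex-wise regressions with
#' units of one SD; the population SD (denominator n) is used so the
#' operation is exactly idempotent.
#'
#' @param x numeric matrix or data.frame.
#' @param columns column names (or indices) to standardise; default all.
#' @return list with \code{x} (standardised), \code{record}
#'   (data.frame of column, mean, sd used).
#' @export
standardiseColumns <- function(x, columns = NULL) {
    df <- as.data.frame(x)
    if (is.null(columns)) columns <- names(df)
    if (is.numeric(columns)) columns <- names(df)[columns]
    rec <- data.frame(column = character(), mean = numeric(),
                      sd = numeric())
    for (cn in columns) {
        v <- df[[cn]]
        mu <- mean(v)
        s <- sqrt(mean((v - mu)^2))
        if (s < 1e-12)
            stop("constant column cannot be standardised: '", cn, "'")
        df[[cn]] <- (v - mu) / s
        rec <- rbind(rec, data.frame(column = cn, mean = mu, sd = s))
    }
    out <- if (is.matrix(x)) as.matrix(df) else df
    list(x = out, record = rec)
}

#' Build the design matrix of the mass univariate regression model
#'
#' Continuous covariates (more than two distinct values, unless listed
#' in \code{keep_raw}) are standardised to unit SD; binary flags pass
#' through; an intercept is prepended; interaction product columns are
#' formed after standardisation of their parents.
#'
#' @param phenotypes per-subject data.frame.
#' @param covariates character vector of column names to include.
#' @param interactions list of length-2 character vectors, e.g.
#'   \code{list(c("age", "ckd"))}.
#' @param intercept include an intercept column (default TRUE).
#' @param keep_raw covariate names exempt from standardisation.
#' @return list with \code{X} (n_s x p named matrix), \code{record}
#'   (standardisation record), \code{targets} (non-intercept columns).
#' @export
murDesign <- function(phenotypes, covariates, interactions = list(),
                      intercept = TRUE, keep_raw = character()) {
    missing_cov <- setdiff(covariates, names(phenotypes))
    if (length(missing_cov))
        stop("covariates not in phenotypes: ",
             paste(missing_cov, collapse = ", "))
    sub <- phenotypes[covariates]
    continuous <- vapply(sub, function(v)
        length(unique(v)) > 2L, logical(1))
    to_std <- setdiff(covariates[continuous], keep_raw)
    rec <- data.frame(column = character(), mean = numeric(),
                      sd = numeric())
    if (length(to_std)) {
        st <- standardiseColumns(sub, to_std)
        sub <- st$x
        rec <- st$record
    }
    X <- as.matrix(sub)
    X <- addInteractions(X, interactions)
    if (intercept) X <- cbind(`(intercept)` = 1, X)
    r <- qr(X)
    if (r$rank < ncol(X)) {
        bad <- colnames(X)[r$pivot[(r$rank + 1):ncol(X)]]
        stop("design matrix is rank deficient; collinear columns: ",
             paste(bad, collapse = ", "))
    }
    list(X = X, record = rec, targets = setdiff(colnames(X),
                                                "(intercept)"))
}

#' Append interaction product columns to a design matrix
#'
#' Products are formed from the columns as present, i.e. after any
#' standardisation of the continuous parents.
#'
#' @param X named numeric matrix.
#' @param pairs list of length-2 character vectors of column names.
#' @return the augmented matrix; interaction columns are named
#'   \code{"a:b"}.
#' @export
addInteractions <- function(X, pairs) {
    for (pr in pairs) {
        if (length(pr) != 2L) stop("each interaction needs two columns")
        missing_col <- setdiff(pr, colnames(X))
        if (length(missing_col))
            stop("interaction refers to unknown column: ",
                 paste(missing_col, collapse = ", "))
        nm <- paste(pr, collapse = ":")
        if (nm %in% colnames(X))
            stop("duplicate interaction: ", nm)
        X <- cbind(X, X[, pr[1]] * X[, pr[2]])
        colnames(X)[ncol(X)] <- nm
    }
    X
}

#' Vertex-wise ordinary least squares (mass univariate regression)
#'
#' Fits the same linear model Y = X beta + eps independently at every
#' vertex: one shared design, \code{n_v} responses. Returns the OLS
#' coefficient and t-statistic matrices and the residuals. Perfect-fit
#' vertices (zero residual variance) get their t capped at 1000 with a
#' warning, keeping downstream enhancement finite on degenerate
#' synthetic inputs.
#'
#' @param Y subjects x vertices response matrix (signed S2S, mm or
#'   SD units), or an \linkS4class{S2SExperiment}.
#' @param X n_s x p design matrix (see \code{\link{murDesign}}).
#' @param standardise_y standardise each vertex's response to unit SD
#'   (the convention for reporting standardised coefficients). Default
#'   FALSE.
#' @return list with \code{beta}, \code{tstat}, \code{se} (all
#'   p x n_v), \code{residuals} (n_s x n_v), \code{df}, \code{sigma2}.
#' @export
fitMUR <- function(Y, X, standardise_y = FALSE) {
    if (is(Y, "S2SExperiment")) Y <- s2sMatrix(Y)
    Y <- as.matrix(Y)
    n <- nrow(Y); p <- ncol(X)
    if (nrow(X) != n) stop("X and Y disagree on subject count")
    if (n <= p) stop("need more subjects than design columns")
    if (standardise_y) {
        sds <- sqrt(colMeans(sweep(Y, 2, colMeans(Y))^2))
        sds[sds < 1e-12] <- 1
        Y <- sweep(Y, 2, sds, "/")
    }
    XtX <- crossprod(X)
    ch <- tryCatch(chol(XtX), error = function(e) NULL)
    if (is.null(ch)) {
        r <- qr(X)
        bad <- colnames(X)[r$pivot[seq(r$rank + 1, ncol(X))]]
        stop("singular design (X'X not invertible); collinear columns: ",
             paste(bad, collapse = ", "))
    }
    XtXinv <- chol2inv(ch)
    beta <- XtXinv %*% crossprod(X, Y)           # p x n_v
    res <- Y - X %*% beta
    df <- n - p
    sigma2 <- colSums(res^2) / df
    se <- sqrt(outer(diag(XtXinv), sigma2))
    tstat <- beta / se
    bad <- !is.finite(tstat) | abs(tstat) > 1e3
    if (any(bad)) {
        warning(sum(bad), " vertex coefficient(s) with (near-)perfect ",
                "fit; t capped at 1000")
        tstat[bad] <- sign(beta[bad]) * 1e3
        tstat[!is.finite(tstat)] <- 0
    }
    rownames(beta) <- rownames(tstat) <- colnames(X)
    list(beta = beta, tstat = tstat, se = se, residuals = res,
         df = df, sigma2 = sigma2)
}
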