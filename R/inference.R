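#' Benjamini-Hochberg false discovery rate adjustment
#'
#' Step-up adjusted p-values (monotone non-decreasing in raw-p rank),
#' as applied across vertices for each covariate and model, and across
#' survival tests. Thin validated wrapper over
#' \code{stats::p.adjust(method = "BH")}.
#'
#' @param pvals numeric vector in [0, 1].
#' @return adjusted p-values, same length.
#' @export
bhFdr <- function(pvals) {
    if (any(!is.finite(pvals)) || any(pvals < 0) || any(pvals > 1))
        stop("p-values must lie in [0, 1]")
    stats::p.adjust(pvals, method = "BH")
}

#' Permutation p-values for TFCE-enhanced vertex statistics
#'
#' Builds the null distribution of each target coefficient's
#' TFCE-enhanced t-map by permutation and returns vertex-wise add-one
#' p-values, \eqn{p(v) = (1 + \#\{|TFCE_{perm}(v)| \ge
#' |TFCE_{obs}(v)|\}) / (1 + n_{perm})}. The default scheme is
#' Freedman-Lane: the reduced model (all columns but the target) is
#' fitted, its residuals are permuted and re-added to the reduced
#' fit, and the full model is refitted on the reconstructed responses,
#' preserving nuisance structure. \code{scheme = "label"} permutes the
#' target column instead.
#'
#' The TFCE quadrature step is fixed from the observed field and
#' shared across permutations, so enhanced values are comparable.
#'
#' @param Y subjects x vertices response matrix or
#'   \linkS4class{S2SExperiment}.
#' @param X design matrix with named columns.
#' @param targets character vector of target column names.
#' @param geometry \code{\link{tfceGeometry}} bundle or
#'   \linkS4class{TriangleMesh}.
#' @param params \code{\link{tfceParams}}.
#' @param n_perm number of permutations (>= 100).
#' @param seed integer seed; fixed seed gives identical p maps.
#' @param scheme \code{"freedman_lane"} (default) or \code{"label"}.
#' @param standardise_y standardise each vertex response to unit SD
#'   before fitting.
#' @return list with \code{p_perm}, \code{tfce_obs}, \code{tstat_obs},
#'   \code{beta_obs} (targets x n_v matrices), \code{n_perm}.
#' @export
permutationPvalues <- function(Y, X, targets, geometry,
                               params = tfceParams(), n_perm = 1000L,
                               seed = 1L,
                               scheme = c("freedman_lane", "label"),
                               standardise_y = FALSE) {
    scheme <- match.arg(scheme)
    if (n_perm < 100) stop("n_perm must be >= 100")
    if (is(Y, "S2SExperiment")) Y <- s2sMatrix(Y)
    Y <- as.matrix(Y)
    if (is(geometry, "TriangleMesh")) geometry <- tfceGeometry(geometry)
    missing_t <- setdiff(targets, colnames(X))
    if (length(missing_t))
        stop("target column absent from design: ",
             paste(missing_t, collapse = ", "))
    if (standardise_y) {
        sds <- sqrt(colMeans(sweep(Y, 2, colMeans(Y))^2))
        sds[sds < 1e-12] <- 1
        Y <- sweep(Y, 2, sds, "/")
    }

    n <- nrow(Y); nv <- ncol(Y)
    fit <- fitMUR(Y, X)
    nt <- length(targets)
    p_perm <- tfce_obs <- matrix(NA_real_, nt, nv,
                                 dimnames = list(targets, NULL))

    set.seed(seed)
    perms <- replicate(n_perm, sample.int(n))

    for (ti in seq_len(nt)) {
        tgt <- targets[ti]
        j <- match(tgt, colnames(X))
        t_obs <- fit$tstat[j, ]
        dh <- if (is.null(params$dh)) max(abs(t_obs)) / 100 else params$dh
        if (dh <= 0) dh <- 1e-8
        pfix <- tfceParams(params$E, params$H, dh, params$two_sided)
        obs_enh <- tfceEnhance(t_obs, geometry, pfix)
        tfce_obs[ti, ] <- obs_enh
        athr <- abs(obs_enh)

        if (scheme == "freedman_lane") {
            Z <- X[, -j, drop = FALSE]
            bz <- qr(Z)
            Ez <- qr.resid(bz, Y)
            Fz <- Y - Ez
        }
        count <- numeric(nv)
        for (b in seq_len(n_perm)) {
            pr <- perms[, b]
            if (scheme == "freedman_lane") {
                Ystar <- Fz + Ez[pr, , drop = FALSE]
                fb <- fitMUR(Ystar, X)
            } else {
                Xp <- X
                Xp[, j] <- X[pr, j]
                fb <- fitMUR(Y, Xp)
            }
            enh <- tfceEnhance(fb$tstat[j, ], geometry, pfix)
            count <- count + (abs(enh) >= athr)
        }
        p_perm[ti, ] <- (1 + count) / (1 + n_perm)
    }
    list(p_perm = p_perm, tfce_obs = tfce_obs,
         tstat_obs = fit$tstat[targets, , drop = FALSE],
         beta_obs = fit$beta[targets, , drop = FALSE],
         n_perm = as.integer(n_perm))
}

#' Full vertex-wise statistical parametric mapping analysis
#'
#' Convenience wrapper chaining the mass univariate regression fit,
#' TFCE enhancement, permutation inference and BH-FDR correction
#' (applied across vertices, per covariate) into a
#' \linkS4class{VertexStats} object.
#'
#' @param s2s an \linkS4class{S2SExperiment}, or a subjects x vertices
#'   matrix (then supply \code{phenotypes} and \code{template}).
#' @param covariates covariate column names for \code{\link{murDesign}}.
#' @param interactions interaction pairs (see \code{\link{murDesign}}).
#' @param targets columns to test; default all non-intercept columns.
#' @param phenotypes,template used when \code{s2s} is a bare matrix.
#' @param params \code{\link{tfceParams}}.
#' @param n_perm permutations (default 1000).
#' @param alpha significance level for the FDR mask (default 0.05).
#' @param seed RNG seed.
#' @param scheme permutation scheme, see
#'   \code{\link{permutationPvalues}}.
#' @param standardise_y standardise vertex responses to unit SD so
#'   coefficients are fully standardised (default TRUE, the reporting
#'   convention).
#' @return a \linkS4class{VertexStats}.
#' @export
murAnalysis <- function(s2s, covariates, interactions = list(),
                        targets = NULL, phenotypes = NULL,
                        template = NULL, params = tfceParams(),
                        n_perm = 1000L, alpha = 0.05, seed = 1L,
                        scheme = "freedman_lane",
                        standardise_y = TRUE) {
    if (is(s2s, "S2SExperiment")) {
        if (is.null(phenotypes))
            phenotypes <- as.data.frame(SummarizedExperiment::colData(s2s))
        if (is.null(template)) template <- templateMesh(s2s)
        Y <- s2sMatrix(s2s)
    } else Y <- as.matrix(s2s)
    if (is.null(template))
        stop("a template mesh is required for TFCE geometry")
    des <- murDesign(phenotypes, covariates, interactions)
    if (is.null(targets)) targets <- des$targets
    geometry <- tfceGeometry(template)
    pp <- permutationPvalues(Y, des$X, targets, geometry, params,
                             n_perm = n_perm, seed = seed,
                             scheme = scheme,
                             standardise_y = standardise_y)
    p_fdr <- t(apply(pp$p_perm, 1, bhFdr))
    dimnames(p_fdr) <- dimnames(pp$p_perm)
    mask <- if (alpha >= 1) matrix(TRUE, nrow(p_fdr), ncol(p_fdr),
                                   dimnames = dimnames(p_fdr))
            else p_fdr < alpha
    new("VertexStats", beta = pp$beta_obs, tstat = pp$tstat_obs,
        tfce = pp$tfce_obs, pPerm = pp$p_perm, pFdr = p_fdr,
        sigMask = mask, alpha = alpha, nPerm = pp$n_perm,
        nVertices = ncol(pp$p_perm))
}

setMethod("show", "VertexStats", function(object) {
    cat(sprintf("VertexStats: %d target(s) x %d vertices, %d permutations, alpha = %g\n",
                nrow(object@beta), object@nVertices, object@nPerm,
                object@alpha))
    cat("  significance area (% of vertices):\n")
    for (nm in rownames(object@beta))
        cat(sprintf("    %-20s %5.1f%%\n", nm,
                    100 * mean(object@sigMask[nm, ])))
})

#' Cohort-level summary of a statistical parametric map
#'
#' Per covariate: median and IQR of the coefficients split by sign,
#' and significance areas as percentages of vertices whose
#' FDR-adjusted p-value falls below alpha, split into negative,
#' positive and total associations. Because it is ambiguous whether
#' published medians are taken over all vertices or the significant
#' ones only, both scopes are computed and labelled.
#'
#' @param stats a \linkS4class{VertexStats}.
#' @param alpha significance level (default the one stored).
#' @param scope \code{"significant"} (medians over significant
#'   vertices of that sign), \code{"all"} (medians over all vertices
#'   of that sign), or \code{"both"}.
#' @return data.frame, one row per covariate and scope: medians and
#'   IQRs by sign (NA where no vertex qualifies, a blank cell), and
#'   the three significance-area percentages.
#' @export
summariseSPM <- function(stats, alpha = stats@alpha,
                         scope = c("both", "significant", "all")) {
    scope <- match.arg(scope)
    scopes <- if (scope == "both") c("significant", "all") else scope
    nv <- stats@nVertices
    mask <- if (alpha >= 1) matrix(TRUE, nrow(stats@pFdr), nv)
            else stats@pFdr < alpha
    rows <- list()
    for (nm in rownames(stats@beta)) {
        b <- stats@beta[nm, ]
        sig <- mask[match(nm, rownames(stats@beta)), ]
        a_neg <- 100 * sum(sig & b < 0) / nv
        a_pos <- 100 * sum(sig & b > 0) / nv
        for (sc in scopes) {
            neg <- if (sc == "significant") b[sig & b < 0] else b[b < 0]
            pos <- if (sc == "significant") b[sig & b > 0] else b[b > 0]
            med <- function(v) if (length(v)) stats::median(v) else NA_real_
            iqr <- function(v) if (length(v) > 1) stats::IQR(v) else NA_real_
            rows[[length(rows) + 1L]] <- data.frame(
                covariate = nm, scope = sc,
                beta_neg_median = med(neg), beta_neg_iqr = iqr(neg),
                area_neg_pct = a_neg,
                beta_pos_median = med(pos), beta_pos_iqr = iqr(pos),
                area_pos_pct = a_pos,
                area_total_pct = a_neg + a_pos)
        }
    }
    do.call(rbind, rows)
}

#' Combined main-effect + interaction coefficient map
#'
#' The local rate of change within a subgroup: elementwise sum of the
#' main-effect and interaction coefficient maps (e.g. age plus
#' age-by-disease), returned as a displayable per-vertex field.
#'
#' @param stats a \linkS4class{VertexStats}, or a named coefficient
#'   matrix (targets x vertices).
#' @param main_term,interaction_term row names.
#' @return numeric per-vertex vector.
#' @export
interactionRateMap <- function(stats, main_term, interaction_term) {
    beta <- if (is(stats, "VertexStats")) stats@beta else as.matrix(stats)
    for (nm in c(main_term, interaction_term))
        if (!nm %in% rownames(beta)) stop("term not present: ", nm)
    beta[main_term, ] + beta[interaction_term, ]
}

#' Convert a standardised coefficient to millimetres
#'
#' Standardised vertex-wise coefficients (response in SD units) are
#' rescaled to mm by the cohort's median vertex-wise S2S SD.
#'
#' @param beta_std standardised coefficient(s).
#' @param sd_s2s_mm median vertex-wise S2S SD in mm (> 0).
#' @return coefficient(s) in mm per covariate SD.
#' @examples
#' unstandardise(-0.33, 3.02)   # about -1.0 mm
#' @export
unstandardise <- function(beta_std, sd_s2s_mm) {
    if (any(sd_s2s_mm <= 0)) stop("sd_s2s_mm must be > 0")
    beta_std * sd_s2s_mm
}
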