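#' Assemble the shape data matrix of a cohort
#'
#' The shape representation fed to PCA: flattened xyz vertex
#' coordinates (d = 3 n_v), signed S2S distances (d = n_v), or their
#' concatenation.
#'
#' @param x a \linkS4class{CorrespondedCohort} or
#'   \linkS4class{S2SExperiment}.
#' @param data_kind \code{"s2s"} (default), \code{"coordinates"}, or
#'   \code{"coordinates+s2s"}.
#' @return numeric matrix, subjects x d.
#' @export
shapeData <- function(x, data_kind = c("s2s", "coordinates",
                                       "coordinates+s2s")) {
    data_kind <- match.arg(data_kind)
    coords <- function(cohort) {
        n_s <- dim(cohort@vertices)[3]
        t(vapply(seq_len(n_s),
                 function(s) as.vector(cohort@vertices[, , s]),
                 numeric(3 * nVertices(cohort@template))))
    }
    if (is(x, "S2SExperiment")) {
        if (data_kind != "s2s")
            stop("coordinate data requires a CorrespondedCohort")
        return(s2sMatrix(x))
    }
    switch(data_kind,
        s2s = s2sMatrix(cohortS2S(x)),
        coordinates = coords(x),
        `coordinates+s2s` = cbind(coords(x), s2sMatrix(cohortS2S(x))))
}

#' Fit a PCA statistical shape model
#'
#' Centred principal component analysis of the cohort shape matrix by
#' exact singular value decomposition. The first mode carries the
#' greatest variance; eigenvalues use the sample (n-1) divisor so
#' training-score variances equal the eigenvalues. Mode signs are
#' fixed so each mode's largest-magnitude loading is positive (PCA
#' signs are otherwise arbitrary).
#'
#' @param data subjects x d matrix (or an object accepted by
#'   \code{\link{shapeData}}).
#' @param n_modes number of modes to retain; clipped with a warning at
#'   \code{min(n_s - 1, d)}.
#' @param data_kind recorded provenance label (see
#'   \code{\link{shapeData}}).
#' @return a \linkS4class{ShapeModel}; degenerate (zero-variance)
#'   models carry attribute-free zero eigenvalues.
#' @export
fitShapeModel <- function(data, n_modes = NULL, data_kind = "s2s") {
    if (is(data, "CorrespondedCohort") || is(data, "S2SExperiment"))
        data <- shapeData(data, data_kind)
    data <- as.matrix(data)
    n_s <- nrow(data); d <- ncol(data)
    if (n_s < 2) stop("need at least two subjects")
    kmax <- min(n_s - 1L, d)
    if (is.null(n_modes)) n_modes <- kmax
    if (n_modes > kmax) {
        warning("n_modes clipped to ", kmax)
        n_modes <- kmax
    }
    ctr <- colMeans(data)
    Xc <- sweep(data, 2, ctr)
    sv <- svd(Xc, nu = 0, nv = kmax)
    lambda <- sv$d[seq_len(kmax)]^2 / (n_s - 1)
    modes <- sv$v[, seq_len(n_modes), drop = FALSE]
    for (k in seq_len(ncol(modes))) {
        i <- which.max(abs(modes[, k]))
        if (modes[i, k] < 0) modes[, k] <- -modes[, k]
    }
    new("ShapeModel", center = ctr, modes = modes,
        variances = pmax(lambda, 0), dataKind = data_kind,
        nSubjects = as.integer(n_s))
}

#' @rdname ShapeModel-class
#' @export
setMethod("shapeModes", "ShapeModel", function(object) object@modes)

#' @rdname ShapeModel-class
#' @export
setMethod("shapeVariances", "ShapeModel",
          function(object) object@variances)

#' @rdname ShapeModel-class
#' @export
setMethod("shapeCenter", "ShapeModel", function(object) object@center)

setMethod("show", "ShapeModel", function(object) {
    tot <- sum(object@variances)
    cat(sprintf("ShapeModel (%s): %d mode(s), d = %d, n = %d\n",
                object@dataKind, ncol(object@modes),
                length(object@center), object@nSubjects))
    if (tot <= 1e-12) {
        cat("  degenerate: zero total variance\n")
    } else {
        k <- min(4L, ncol(object@modes))
        pct <- 100 * object@variances[seq_len(k)] / tot
        cat("  variance explained:",
            paste(sprintf("PC%d %.1f%%", seq_len(k), pct),
                  collapse = ", "), "\n")
    }
})

#' Reconstruct the shape at c SD along one mode
#'
#' The mean shape displaced along eigenmode k by c standard
#' deviations: center + c * sqrt(lambda_k) * e_k. The +/-3 SD
#' reconstructions are the conventional mode visualisation.
#'
#' @param model a \linkS4class{ShapeModel}.
#' @param mode_index which mode (1-based, within fitted modes).
#' @param c displacement in SD units (0 returns the mean exactly).
#' @return shape vector of length d.
#' @export
modeReconstruction <- function(model, mode_index, c = 0) {
    if (mode_index < 1 || mode_index > ncol(model@modes))
        stop("mode_index outside fitted modes")
    model@center + c * sqrt(model@variances[mode_index]) *
        model@modes[, mode_index]
}

#' Project shape vectors onto the model modes
#'
#' PC scores: modes' (x - mean). With the full mode set,
#' reconstruction from the scores returns x to numerical precision.
#'
#' @param model a \linkS4class{ShapeModel}.
#' @param x shape vector (length d) or subjects x d matrix.
#' @return score vector or matrix (columns \code{PC1..PCk}).
#' @export
projectScores <- function(model, x) {
    if (is.null(dim(x))) x <- matrix(x, nrow = 1)
    if (ncol(x) != length(model@center))
        stop("dimension mismatch with the shape model")
    s <- sweep(x, 2, model@center) %*% model@modes
    colnames(s) <- paste0("PC", seq_len(ncol(s)))
    if (nrow(s) == 1L) drop(s) else s
}

#' Reconstruct shape vectors from PC scores
#'
#' @param model a \linkS4class{ShapeModel}.
#' @param scores score vector or matrix as from
#'   \code{\link{projectScores}}.
#' @return shape vector or subjects x d matrix.
#' @export
reconstructShape <- function(model, scores) {
    if (is.null(dim(scores))) scores <- matrix(scores, nrow = 1)
    out <- sweep(scores %*% t(model@modes), 2, model@center, "+")
    if (nrow(out) == 1L) drop(out) else out
}

#' Percentage of variance explained by the first k modes
#'
#' @param model a \linkS4class{ShapeModel}.
#' @param first_k how many leading modes (default: all fitted).
#' @return percentage in [0, 100].
#' @export
varianceExplained <- function(model, first_k = ncol(model@modes)) {
    tot <- sum(model@variances)
    if (tot <= 0) return(0)
    100 * sum(model@variances[seq_len(first_k)]) / tot
}

#' Scree table for the first k modes
#'
#' @param model a \linkS4class{ShapeModel}.
#' @param k number of modes (default 10).
#' @return data.frame with mode, eigenvalue, pct_variance.
#' @export
screeTable <- function(model, k = 10L) {
    k <- min(k, length(model@variances))
    tot <- sum(model@variances)
    data.frame(mode = seq_len(k),
               eigenvalue = model@variances[seq_len(k)],
               pct_variance = if (tot > 0)
                   100 * model@variances[seq_len(k)] / tot else 0)
}
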