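#' @import methods
#' @importFrom Rcpp sourceCpp
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @useDynLib nephroShape, .registration = TRUE
NULL

#' Triangle surface mesh
#'
#' Carrier of all geometry in the package: an organ surface represented by
#' vertex coordinates in world millimetres and triangular faces indexing
#' into the vertex table. Valid meshes have in-range 1-based face indices
#' and no degenerate (zero-area) faces; consistently wound closed meshes
#' have positive enclosed volume (outward-facing normals).
#'
#' @slot vertices numeric matrix, \code{n_v x 3}, world coordinates (mm).
#' @slot faces integer matrix, \code{n_f x 3}, 1-based vertex indices.
#' @export
setClass("TriangleMesh",
    representation(vertices = "matrix", faces = "matrix"),
    validity = function(object) {
        msg <- character()
        if (ncol(object@vertices) != 3L)
            msg <- c(msg, "vertices must have 3 columns")
        if (ncol(object@faces) != 3L)
            msg <- c(msg, "faces must have 3 columns")
        if (nrow(object@faces) > 0) {
            f <- object@faces
            if (any(f < 1L) || any(f > nrow(object@vertices)))
                msg <- c(msg, "face indices out of range")
        }
        if (any(!is.finite(object@vertices)))
            msg <- c(msg, "vertex coordinates must be finite")
        if (length(msg)) msg else TRUE
    })

#' Construct a TriangleMesh
#'
#' @param vertices numeric \code{n_v x 3} matrix of coordinates (mm).
#' @param faces integer \code{n_f x 3} matrix of 1-based vertex indices.
#' @return A \linkS4class{TriangleMesh}.
#' @examples
#' m <- TriangleMesh(diag(3), matrix(1:3, 1))
#' nVertices(m)
#' @export
TriangleMesh <- function(vertices, faces) {
    vertices <- as.matrix(vertices)
    storage.mode(vertices) <- "double"
    faces <- as.matrix(faces)
    storage.mode(faces) <- "integer"
    dimnames(vertices) <- NULL
    dimnames(faces) <- NULL
    new("TriangleMesh", vertices = vertices, faces = faces)
}

#' Binary voxel mask with a voxel-to-world affine
#'
#' @slot data 3D array of \{0,1\} voxels.
#' @slot affine 4x4 voxel-to-world transform (mm); voxel indices 0-based.
#' @export
setClass("VoxelMask",
    representation(data = "array", affine = "matrix"),
    validity = function(object) {
        msg <- character()
        if (length(dim(object@data)) != 3L)
            msg <- c(msg, "mask data must be a 3D array")
        if (!all(dim(object@affine) == c(4L, 4L)))
            msg <- c(msg, "affine must be 4x4")
        else if (abs(det(object@affine)) < 1e-12)
            msg <- c(msg, "affine must be invertible")
        if (length(msg)) msg else TRUE
    })

#' Construct a VoxelMask
#'
#' @param data 3D array; values above 0.5 are foreground.
#' @param affine 4x4 voxel-to-world matrix (default: identity, 1 mm
#'   isotropic, 0-based voxel indices).
#' @return A \linkS4class{VoxelMask}.
#' @export
VoxelMask <- function(data, affine = diag(4)) {
    storage.mode(data) <- "double"
    new("VoxelMask", data = data, affine = affine)
}

#' Cohort of surfaces in dense template correspondence
#'
#' All subjects share the template topology: subject vertex array
#' \code{v} of subject \code{i} corresponds anatomically to template
#' vertex \code{v}. This is the \code{n_s x n_v x 3} correspondence on
#' which signed surface-to-surface distances are defined.
#'
#' @slot template a \linkS4class{TriangleMesh}.
#' @slot vertices numeric array \code{n_v x 3 x n_s} of subject vertices.
#' @slot subjectIds character vector of length \code{n_s}.
#' @export
setClass("CorrespondedCohort",
    representation(template = "TriangleMesh", vertices = "array",
                   subjectIds = "character"),
    validity = function(object) {
        msg <- character()
        d <- dim(object@vertices)
        if (length(d) != 3L || d[2] != 3L)
            msg <- c(msg, "vertices must be an n_v x 3 x n_s array")
        else {
            if (d[1] != nrow(object@template@vertices))
                msg <- c(msg, "subject arrays must match template vertex count")
            if (d[3] != length(object@subjectIds))
                msg <- c(msg, "subjectIds length must equal n_s")
        }
        if (anyDuplicated(object@subjectIds))
            msg <- c(msg, "duplicate subject ids")
        if (length(msg)) msg else TRUE
    })

#' Construct a CorrespondedCohort
#'
#' @param template a \linkS4class{TriangleMesh}.
#' @param vertices \code{n_v x 3 x n_s} array of subject vertex positions.
#' @param subjectIds subject identifiers (default \code{S1..Sn}).
#' @return A \linkS4class{CorrespondedCohort}.
#' @export
CorrespondedCohort <- function(template, vertices,
                               subjectIds = NULL) {
    if (is.null(subjectIds))
        subjectIds <- paste0("S", seq_len(dim(vertices)[3]))
    new("CorrespondedCohort", template = template, vertices = vertices,
        subjectIds = as.character(subjectIds))
}

#' Signed surface-to-surface distance container
#'
#' Extends \link[SummarizedExperiment]{SummarizedExperiment}: rows are
#' template vertices, columns are subjects, the \code{"s2s"} assay holds
#' signed distances in mm (positive = outward expansion relative to the
#' template), and \code{colData} carries per-subject phenotypes. The
#' template mesh travels in \code{metadata(x)$template}.
#'
#' @export
setClass("S2SExperiment", contains = "SummarizedExperiment")

#' Construct an S2SExperiment
#'
#' @param s2s numeric matrix of signed distances, subjects x vertices
#'   (mm); it is stored transposed, vertices x subjects.
#' @param phenotypes optional per-subject data.frame (one row per subject).
#' @param template the \linkS4class{TriangleMesh} the distances refer to.
#' @param subjectIds subject identifiers; default rownames of \code{s2s}
#'   or \code{S1..Sn}.
#' @return An \linkS4class{S2SExperiment}.
#' @export
S2SExperiment <- function(s2s, phenotypes = NULL, template = NULL,
                          subjectIds = NULL) {
    s2s <- as.matrix(s2s)
    if (any(!is.finite(s2s)))
        stop("S2S distances must be finite everywhere")
    if (is.null(subjectIds))
        subjectIds <- if (!is.null(rownames(s2s))) rownames(s2s)
                      else paste0("S", seq_len(nrow(s2s)))
    if (anyDuplicated(subjectIds)) stop("duplicate subject ids")
    if (!is.null(template) && ncol(s2s) != nrow(template@vertices))
        stop("column count must equal template vertex count")
    a <- t(s2s)
    dimnames(a) <- list(NULL, subjectIds)
    cd <- if (is.null(phenotypes)) S4Vectors::DataFrame(row.names = subjectIds)
          else {
              if (nrow(phenotypes) != length(subjectIds))
                  stop("phenotypes must have one row per subject")
              S4Vectors::DataFrame(phenotypes, row.names = subjectIds)
          }
    se <- SummarizedExperiment::SummarizedExperiment(
        assays = list(s2s = a), colData = cd,
        metadata = list(template = template))
    new("S2SExperiment", se)
}

#' Ground truth of a synthetic cohort
#'
#' Everything the generator needs to plant a known signal: per-covariate
#' displacement effect maps (mm per covariate SD, along the template
#' outward normal), the spatially smoothed noise model, and the survival
#' data-generating parameters.
#'
#' @slot effectMaps named list of numeric vectors, each of length
#'   \code{n_v}, in mm per covariate SD.
#' @slot noiseSd target per-vertex noise SD in mm.
#' @slot noiseSmoothPasses integer; adjacency-smoothing passes giving the
#'   noise its spatial correlation.
#' @slot trueLogHr named numeric; per-predictor log hazard ratios.
#' @slot baselineHazard baseline hazard rate (1/years).
#' @slot censorTime administrative follow-up window (years); entry is
#'   uniform over the window, so median follow-up is about half of it.
#' @slot seed integer root seed; all generator randomness derives from it.
#' @export
setClass("SyntheticTruth",
    representation(effectMaps = "list", noiseSd = "numeric",
                   noiseSmoothPasses = "integer", trueLogHr = "numeric",
                   baselineHazard = "numeric", censorTime = "numeric",
                   seed = "integer"),
    validity = function(object) {
        msg <- character()
        if (object@noiseSd <= 0) msg <- c(msg, "noiseSd must be > 0")
        if (object@baselineHazard <= 0)
            msg <- c(msg, "baselineHazard must be > 0")
        if (length(object@effectMaps) &&
            is.null(names(object@effectMaps)))
            msg <- c(msg, "effectMaps must be named by covariate")
        if (length(msg)) msg else TRUE
    })

#' PCA statistical shape model
#'
#' @slot center mean vector (length d).
#' @slot modes d x k matrix of orthonormal eigenvectors, one column per
#'   mode of variation, sign-fixed so each mode's largest-magnitude
#'   loading is positive.
#' @slot variances full eigenvalue spectrum (non-increasing, >= 0);
#'   only the first \code{ncol(modes)} modes are retained as vectors.
#' @slot dataKind one of \code{"coordinates"}, \code{"s2s"},
#'   \code{"coordinates+s2s"}.
#' @slot nSubjects training-set size.
#' @export
setClass("ShapeModel",
    representation(center = "numeric", modes = "matrix",
                   variances = "numeric", dataKind = "character",
                   nSubjects = "integer"),
    validity = function(object) {
        msg <- character()
        if (length(object@variances) &&
            any(diff(object@variances) > 1e-8))
            msg <- c(msg, "eigenvalues must be non-increasing")
        if (any(object@variances < -1e-8))
            msg <- c(msg, "eigenvalues must be non-negative")
        if (nrow(object@modes) != length(object@center))
            msg <- c(msg, "modes rows must match center length")
        if (length(msg)) msg else TRUE
    })

#' Vertex-wise statistical parametric map results
#'
#' Per target covariate: OLS coefficients, t statistics, TFCE-enhanced
#' statistics, permutation p-values, BH-adjusted p-values, and the
#' significance mask at \code{alpha}. Matrices are targets x vertices.
#'
#' @slot beta,tstat,tfce,pPerm,pFdr numeric matrices, targets x n_v.
#' @slot sigMask logical matrix, targets x n_v; \code{pFdr < alpha}.
#' @slot alpha significance level used for the mask.
#' @slot nPerm number of permutations behind \code{pPerm}.
#' @slot nVertices number of vertices.
#' @export
setClass("VertexStats",
    representation(beta = "matrix", tstat = "matrix", tfce = "matrix",
                   pPerm = "matrix", pFdr = "matrix", sigMask = "matrix",
                   alpha = "numeric", nPerm = "integer",
                   nVertices = "integer"),
    validity = function(object) {
        msg <- character()
        if (any(object@pPerm < 0 | object@pPerm > 1))
            msg <- c(msg, "pPerm must lie in [0,1]")
        if (any(object@pFdr < 0 | object@pFdr > 1))
            msg <- c(msg, "pFdr must lie in [0,1]")
        if (any(object@pFdr + 1e-12 < object@pPerm))
            msg <- c(msg, "pFdr must be >= pPerm elementwise")
        if (length(msg)) msg else TRUE
    })
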