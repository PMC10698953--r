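#' Signed surface-to-surface (S2S) distance
#'
#' The mesh-derived phenotype at the heart of the pipeline: for each
#' template vertex, the Euclidean distance to the corresponding subject
#' vertex, signed by the projection of the displacement onto the
#' template outward normal. Positive distances signify outward
#' expansion of the subject relative to the template, negative inward
#' shrinkage.
#'
#' @param template the template \linkS4class{TriangleMesh}.
#' @param subject_vertices \code{n_v x 3} matrix of corresponding
#'   subject vertex positions (or a \linkS4class{TriangleMesh} sharing
#'   the template topology).
#' @param normals optional precomputed template vertex normals.
#' @return numeric vector of signed distances (mm), length \code{n_v}.
#' @examples
#' tpl <- sphereMesh(200, radius = 10)
#' s <- s2sDistance(tpl, meshVertices(tpl) * 1.1)
#' summary(s)   # all close to +1
#' @export
s2sDistance <- function(template, subject_vertices, normals = NULL) {
    if (is(subject_vertices, "TriangleMesh"))
        subject_vertices <- subject_vertices@vertices
    if (nrow(subject_vertices) != nVertices(template))
        stop("vertex count mismatch: subject has ", nrow(subject_vertices),
             " vertices, template has ", nVertices(template))
    if (is.null(normals)) normals <- vertexGeometry(template)$normals
    d <- subject_vertices - template@vertices
    sgn <- sign(rowSums(d * normals))
    sgn[sgn == 0] <- 1
    sgn * sqrt(rowSums(d^2))
}

#' Stack per-subject S2S fields into an S2SExperiment
#'
#' @param fields named list of equal-length signed distance vectors,
#'   names are subject ids; rows of the result are ordered by id.
#' @param template optional \linkS4class{TriangleMesh}.
#' @param phenotypes optional data.frame, one row per subject, matched
#'   by position after ordering.
#' @return an \linkS4class{S2SExperiment}.
#' @export
stackCohort <- function(fields, template = NULL, phenotypes = NULL) {
    if (anyDuplicated(names(fields)))
        stop("duplicate subject ids in fields")
    len <- lengths(fields)
    if (length(unique(len)) != 1L)
        stop("all fields must have equal length")
    ord <- order(names(fields))
    m <- do.call(rbind, fields[ord])
    if (!is.null(phenotypes)) phenotypes <- phenotypes[ord, , drop = FALSE]
    S2SExperiment(m, phenotypes = phenotypes, template = template,
                  subjectIds = names(fields)[ord])
}

#' Compute the S2S matrix of a corresponded cohort
#'
#' @param cohort a \linkS4class{CorrespondedCohort}.
#' @param phenotypes optional per-subject data.frame (cohort order).
#' @return an \linkS4class{S2SExperiment} (rows vertices, columns
#'   subjects).
#' @export
cohortS2S <- function(cohort, phenotypes = NULL) {
    tpl <- cohort@template
    normals <- vertexGeometry(tpl)$normals
    n_s <- dim(cohort@vertices)[3]
    m <- t(vapply(seq_len(n_s), function(s)
        s2sDistance(tpl, cohort@vertices[, , s], normals = normals),
        numeric(nVertices(tpl))))
    rownames(m) <- cohort@subjectIds
    S2SExperiment(m, phenotypes = phenotypes, template = tpl,
                  subjectIds = cohort@subjectIds)
}

#' @rdname S2SExperiment-class
#' @export
setMethod("s2sMatrix", "S2SExperiment", function(x)
    t(SummarizedExperiment::assay(x, "s2s")))

#' @rdname S2SExperiment-class
#' @export
setMethod("templateMesh", "S2SExperiment", function(x)
    S4Vectors::metadata(x)$template)

#' @rdname S2SExperiment-class
#' @export
setMethod("subjectIds", "S2SExperiment", function(x) colnames(x))

#' Median vertex-wise SD of an S2S matrix
#'
#' The cohort-level scale used to convert standardised regression
#' coefficients back to millimetres.
#' @param x an \linkS4class{S2SExperiment} or subjects x vertices
#'   matrix.
#' @return median across vertices of the per-vertex SD (mm).
#' @export
medianVertexSd <- function(x) {
    m <- if (is(x, "S2SExperiment")) s2sMatrix(x) else as.matrix(x)
    stats::median(apply(m, 2, stats::sd))
}
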