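#' @rdname TriangleMesh-class
#' @param x,object a \linkS4class{TriangleMesh}.
#' @export
setGeneric("meshVertices", function(x) standardGeneric("meshVertices"))

#' @rdname TriangleMesh-class
#' @export
setGeneric("meshFaces", function(x) standardGeneric("meshFaces"))

#' @rdname TriangleMesh-class
#' @export
setGeneric("nVertices", function(x) standardGeneric("nVertices"))

#' @rdname TriangleMesh-class
#' @export
setGeneric("nFaces", function(x) standardGeneric("nFaces"))

#' @rdname S2SExperiment-class
#' @param x an \linkS4class{S2SExperiment}.
#' @export
setGeneric("s2sMatrix", function(x) standardGeneric("s2sMatrix"))

#' @rdname S2SExperiment-class
#' @export
setGeneric("templateMesh", function(x) standardGeneric("templateMesh"))

#' @rdname CorrespondedCohort-class
#' @param x a \linkS4class{CorrespondedCohort} or
#'   \linkS4class{S2SExperiment}.
#' @export
setGeneric("subjectIds", function(x) standardGeneric("subjectIds"))

#' @rdname CorrespondedCohort-class
#' @param i subject index or id.
#' @export
setGeneric("subjectMesh", function(x, i) standardGeneric("subjectMesh"))

#' @rdname ShapeModel-class
#' @param object,model a \linkS4class{ShapeModel}.
#' @export
setGeneric("shapeModes", function(object) standardGeneric("shapeModes"))

#' @rdname ShapeModel-class
#' @export
setGeneric("shapeVariances",
           function(object) standardGeneric("shapeVariances"))

#' @rdname ShapeModel-class
#' @export
setGeneric("shapeCenter", function(object) standardGeneric("shapeCenter"))
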