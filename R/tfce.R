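#' TFCE parameters
#'
#' Threshold-free cluster enhancement integrates, over statistic
#' heights h, (cluster surface area)^E * h^H * dh, where the cluster
#' is the connected supra-threshold component containing the vertex.
#' Defaults follow standard surface-TFCE practice: E = 1 with
#' area-based extent (mm^2), H = 2, and an integration step of
#' max|t|/100 when \code{dh} is left NULL.
#'
#' @param E extent exponent (>= 0).
#' @param H height exponent (>= 0).
#' @param dh integration step in statistic units, or NULL for
#'   max|t|/100 per field.
#' @param two_sided enhance positive and negative excursions
#'   separately (the signed result keeps the field's sign).
#' @return a list of class \code{"TFCEParams"}.
#' @export
tfceParams <- function(E = 1, H = 2, dh = NULL, two_sided = TRUE) {
    if (E < 0 || H < 0) stop("E and H must be >= 0")
    if (!is.null(dh) && dh <= 0) stop("dh must be > 0")
    structure(list(E = E, H = H, dh = dh, two_sided = two_sided),
              class = "TFCEParams")
}

#' Mesh geometry bundle for TFCE
#'
#' Precomputes what enhancement needs: the vertex-edge graph and
#' per-vertex areas of a mesh.
#' @param mesh a \linkS4class{TriangleMesh}.
#' @return list with \code{edges} (m x 2, 1-based), \code{areas}
#'   (mm^2), \code{n_vertices}.
#' @export
tfceGeometry <- function(mesh) {
    g <- vertexGeometry(mesh)
    list(edges = g$edges, areas = g$areas, n_vertices = nVertices(mesh))
}

#' Threshold-free cluster enhancement over a triangle mesh
#'
#' @param stat numeric per-vertex statistic field (finite).
#' @param geometry a \code{\link{tfceGeometry}} bundle (or a
#'   \linkS4class{TriangleMesh}).
#' @param params a \code{\link{tfceParams}} list.
#' @return the enhanced field; with \code{two_sided}, negative
#'   excursions are enhanced on the negated field and re-negated.
#' @examples
#' tpl <- sphereMesh(200, radius = 10)
#' g <- tfceGeometry(tpl)
#' enh <- tfceEnhance(rep(2, nVertices(tpl)), g, tfceParams())
#' # constant field t=2, E=1, H=2: every vertex near area * 8/3
#' @export
tfceEnhance <- function(stat, geometry, params = tfceParams()) {
    if (is(geometry, "TriangleMesh")) geometry <- tfceGeometry(geometry)
    if (length(geometry$areas) == 0L || geometry$n_vertices == 0L)
        stop("empty mesh geometry")
    if (any(!is.finite(stat))) stop("statistic field must be finite")
    if (length(stat) != geometry$n_vertices)
        stop("field length does not match vertex count")
    mx <- max(abs(stat))
    if (mx == 0) return(numeric(length(stat)))
    dh <- if (is.null(params$dh)) mx / 100 else params$dh
    e0 <- geometry$edges - 1L
    pos <- tfce_onesided_cpp(pmax(stat, 0), e0, geometry$areas,
                             params$E, params$H, dh)
    if (!params$two_sided) return(pos)
    neg <- tfce_onesided_cpp(pmax(-stat, 0), e0, geometry$areas,
                             params$E, params$H, dh)
    pos - neg
}
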