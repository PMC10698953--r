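#' @rdname TriangleMesh-class
#' @export
setMethod("meshVertices", "TriangleMesh", function(x) x@vertices)

#' @rdname TriangleMesh-class
#' @export
setMethod("meshFaces", "TriangleMesh", function(x) x@faces)

#' @rdname TriangleMesh-class
#' @export
setMethod("nVertices", "TriangleMesh", function(x) nrow(x@vertices))

#' @rdname TriangleMesh-class
#' @export
setMethod("nFaces", "TriangleMesh", function(x) nrow(x@faces))

setMethod("show", "TriangleMesh", function(object) {
    cat(sprintf("TriangleMesh: %d vertices, %d faces\n",
                nVertices(object), nFaces(object)))
    bb <- apply(object@vertices, 2, range)
    cat(sprintf("  bounding box (mm): [%.2f, %.2f] x [%.2f, %.2f] x [%.2f, %.2f]\n",
                bb[1, 1], bb[2, 1], bb[1, 2], bb[2, 2], bb[1, 3], bb[2, 3]))
})

#' @rdname CorrespondedCohort-class
#' @export
setMethod("subjectIds", "CorrespondedCohort", function(x) x@subjectIds)

#' @rdname CorrespondedCohort-class
#' @export
setMethod("subjectMesh", "CorrespondedCohort", function(x, i) {
    if (is.character(i)) i <- match(i, x@subjectIds)
    TriangleMesh(x@vertices[, , i], x@template@faces)
})

#' @rdname CorrespondedCohort-class
#' @export
setMethod("templateMesh", "CorrespondedCohort", function(x) x@template)

setMethod("show", "CorrespondedCohort", function(object) {
    cat(sprintf("CorrespondedCohort: %d subjects on a %d-vertex template\n",
                dim(object@vertices)[3], nVertices(object@template)))
})

.face_cross <- function(mesh) {
    v <- mesh@vertices; f <- mesh@faces
    a <- v[f[, 1], , drop = FALSE]
    e1 <- v[f[, 2], , drop = FALSE] - a
    e2 <- v[f[, 3], , drop = FALSE] - a
    cbind(e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2],
          e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3],
          e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1])
}

#' Triangle areas of a mesh
#' @param mesh a \linkS4class{TriangleMesh}.
#' @return numeric vector of per-face areas (mm^2).
#' @export
faceAreas <- function(mesh) {
    cr <- .face_cross(mesh)
    0.5 * sqrt(rowSums(cr^2))
}

#' Total surface area
#' @param mesh a \linkS4class{TriangleMesh}.
#' @return total area in mm^2.
#' @export
surfaceArea <- function(mesh) sum(faceAreas(mesh))

#' Enclosed (signed) volume of a closed mesh
#'
#' Sum of signed tetrahedron volumes against the origin; positive for a
#' closed surface with consistent outward winding.
#' @param mesh a \linkS4class{TriangleMesh}.
#' @return signed volume in mm^3.
#' @export
meshVolume <- function(mesh) {
    v <- mesh@vertices; f <- mesh@faces
    a <- v[f[, 1], , drop = FALSE]
    b <- v[f[, 2], , drop = FALSE]
    c_ <- v[f[, 3], , drop = FALSE]
    cr <- cbind(b[, 2] * c_[, 3] - b[, 3] * c_[, 2],
                b[, 3] * c_[, 1] - b[, 1] * c_[, 3],
                b[, 1] * c_[, 2] - b[, 2] * c_[, 1])
    sum(rowSums(a * cr)) / 6
}

#' Per-vertex geometry: areas, outward normals, adjacency
#'
#' Per-vertex area is one third of the incident triangle areas, so vertex
#' areas sum exactly to the total surface area (the TFCE cluster-extent
#' measure). Normals are area-weighted averages of incident face normals;
#' for a consistently wound closed surface they point outward. Adjacency
#' is the unique vertex-edge graph, also returned as neighbour lists.
#'
#' @param mesh a \linkS4class{TriangleMesh}.
#' @return list with \code{areas} (n_v, mm^2), \code{normals} (n_v x 3,
#'   unit length), \code{edges} (m x 2, 1-based), \code{neighbors}
#'   (list of integer vectors).
#' @export
vertexGeometry <- function(mesh) {
    f <- mesh@faces
    nv <- nVertices(mesh)
    cr <- .face_cross(mesh)              # 2 * area * unit normal
    fa <- 0.5 * sqrt(rowSums(cr^2))
    if (any(fa < 1e-14))
        stop("mesh has degenerate (zero-area) faces; clean it first")

    idx <- as.vector(f)
    areas <- as.vector(tapply(rep(fa / 3, 3), idx, sum))
    touched <- sort(unique(idx))
    if (length(touched) != nv)
        stop("mesh has isolated vertices not referenced by any face")

    normals <- matrix(0, nv, 3)
    for (j in 1:3) {
        normals[, j] <- as.vector(tapply(rep(cr[, j] / 2, 3), idx, sum))
    }
    nrm <- sqrt(rowSums(normals^2))
    nrm[nrm < 1e-300] <- 1
    normals <- normals / nrm

    e <- rbind(f[, c(1, 2)], f[, c(2, 3)], f[, c(3, 1)])
    e <- cbind(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
    e <- unique(e)
    nb <- split(c(e[, 2], e[, 1]), c(e[, 1], e[, 2]))
    neighbors <- vector("list", nv)
    neighbors[as.integer(names(nb))] <- lapply(nb, function(v) sort(unique(v)))

    list(areas = areas, normals = normals, edges = e, neighbors = neighbors)
}

#' Laplacian (umbrella-operator) smoothing
#'
#' Each pass moves every vertex toward the centroid of its edge
#' neighbours by the relaxation fraction: uniform-weight umbrella
#' smoothing. Topology is unchanged.
#'
#' @param mesh a \linkS4class{TriangleMesh}.
#' @param iterations number of passes (>= 0).
#' @param relaxation step fraction in (0, 1].
#' @return the smoothed \linkS4class{TriangleMesh}.
#' @export
laplacianSmooth <- function(mesh, iterations = 10L, relaxation = 0.5) {
    if (iterations < 0) stop("iterations must be >= 0")
    if (relaxation <= 0 || relaxation > 1)
        stop("relaxation must lie in (0, 1]")
    if (iterations == 0) return(mesh)
    A <- adjacencyOperator(mesh)
    v <- mesh@vertices
    for (i in seq_len(iterations))
        v <- v + relaxation * (as.matrix(A %*% v) - v)
    TriangleMesh(v, mesh@faces)
}

#' Row-stochastic neighbour-averaging operator of a mesh
#'
#' Sparse matrix \code{A} with \code{A v} = per-vertex neighbour centroid.
#' @param mesh a \linkS4class{TriangleMesh}.
#' @return a sparse \code{dgCMatrix}.
#' @export
adjacencyOperator <- function(mesh) {
    g <- vertexGeometry(mesh)
    e <- g$edges
    i <- c(e[, 1], e[, 2]); j <- c(e[, 2], e[, 1])
    A <- Matrix::sparseMatrix(i = i, j = j, x = 1,
                              dims = c(nVertices(mesh), nVertices(mesh)))
    deg <- Matrix::rowSums(A)
    Matrix::Diagonal(x = 1 / deg) %*% A
}

#' Connected components of a mesh
#' @param mesh a \linkS4class{TriangleMesh}.
#' @return integer vector of 1-based component labels per vertex.
#' @export
meshComponents <- function(mesh) {
    g <- vertexGeometry(mesh)
    graph_components_cpp(nVertices(mesh),
                         g$edges - 1L) + 1L
}

# Drop unreferenced vertices and reindex faces.
.compact_mesh <- function(vertices, faces) {
    used <- sort(unique(as.vector(faces)))
    remap <- integer(nrow(vertices))
    remap[used] <- seq_along(used)
    TriangleMesh(vertices[used, , drop = FALSE],
                 matrix(remap[faces], ncol = 3))
}

#' Keep the largest connected component, drop degenerate faces, and make
#' the winding consistently outward (positive signed volume)
#'
#' @param mesh a \linkS4class{TriangleMesh}.
#' @param warn warn when more than one component is discarded.
#' @return the cleaned \linkS4class{TriangleMesh}.
#' @export
cleanMesh <- function(mesh, warn = TRUE) {
    fa <- faceAreas(mesh)
    if (any(fa < 1e-12)) {
        mesh <- .compact_mesh(mesh@vertices,
                              mesh@faces[fa >= 1e-12, , drop = FALSE])
    }
    # duplicate vertex merge (exact coordinates)
    key <- paste(mesh@vertices[, 1], mesh@vertices[, 2], mesh@vertices[, 3])
    if (anyDuplicated(key)) {
        first <- match(key, key)
        mesh <- .compact_mesh(mesh@vertices,
                              matrix(first[mesh@faces], ncol = 3))
    }
    comp <- meshComponents(mesh)
    if (max(comp) > 1L) {
        if (warn)
            warning(sprintf("mesh has %d components; keeping the largest",
                            max(comp)))
        keep <- which.max(tabulate(comp))
        inkeep <- comp == keep
        fkeep <- inkeep[mesh@faces[, 1]]
        mesh <- .compact_mesh(mesh@vertices,
                              mesh@faces[fkeep, , drop = FALSE])
    }
    if (meshVolume(mesh) < 0)
        mesh <- TriangleMesh(mesh@vertices, mesh@faces[, c(1, 3, 2)])
    mesh
}

#' Check whether a mesh is closed (every edge shared by exactly two faces)
#' @param mesh a \linkS4class{TriangleMesh}.
#' @return logical.
#' @export
isClosedMesh <- function(mesh) {
    f <- mesh@faces
    e <- rbind(f[, c(1, 2)], f[, c(2, 3)], f[, c(3, 1)])
    key <- paste(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
    all(table(key) == 2L)
}
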