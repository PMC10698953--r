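.kabsch <- function(moving, fixed) {
    # least-squares rotation + translation (no scaling)
    mc <- colMeans(moving); fc <- colMeans(fixed)
    A <- crossprod(sweep(moving, 2, mc), sweep(fixed, 2, fc))
    s <- svd(A)
    d <- sign(det(s$v %*% t(s$u)))
    R <- s$v %*% diag(c(1, 1, d)) %*% t(s$u)
    t <- fc - as.vector(R %*% mc)
    list(R = R, t = t)
}

.apply_rigid <- function(v, tr) sweep(v %*% t(tr$R), 2, tr$t, "+")

.check_nondegenerate <- function(v, what = "mesh") {
    sv <- svd(sweep(v, 2, colMeans(v)))$d
    if (sv[2] < 1e-9 * max(sv[1], 1))
        stop("degenerate (collinear) geometry in ", what)
}

.closest_points <- function(points, mesh) {
    closest_point_mesh_cpp(points, mesh@vertices, mesh@faces - 1L)$points
}

#' Rigid (Procrustes/ICP) alignment of one mesh onto another
#'
#' When the two meshes share a topology the optimal rotation and
#' translation come from one Kabsch solve on the corresponding
#' vertices; otherwise iterative closest point (ICP) alternates
#' closest-surface-point matching with Kabsch solves. No scaling is
#' applied: size is preserved.
#'
#' @param moving,fixed \linkS4class{TriangleMesh} objects.
#' @param max_iterations ICP iteration cap (unmatched topologies).
#' @param tol RMSD convergence tolerance in mm.
#' @return list with \code{transform} (\code{kind}, rotation \code{R},
#'   translation \code{t}), \code{mesh} (moved mesh), \code{rmsd}.
#' @export
rigidAlign <- function(moving, fixed, max_iterations = 50L, tol = 1e-6) {
    .check_nondegenerate(moving@vertices, "moving mesh")
    .check_nondegenerate(fixed@vertices, "fixed mesh")
    mv <- moving@vertices
    if (nVertices(moving) == nVertices(fixed)) {
        tr <- .kabsch(mv, fixed@vertices)
        out <- .apply_rigid(mv, tr)
        rmsd <- sqrt(mean(rowSums((out - fixed@vertices)^2)))
    } else {
        tr <- list(R = diag(3),
                   t = colMeans(fixed@vertices) - colMeans(mv))
        out <- .apply_rigid(mv, tr)
        rmsd <- Inf
        for (it in seq_len(max_iterations)) {
            target <- .closest_points(out, fixed)
            step <- .kabsch(out, target)
            out <- .apply_rigid(out, step)
            tr <- list(R = step$R %*% tr$R,
                       t = as.vector(step$R %*% tr$t) + step$t)
            new_rmsd <- sqrt(mean(rowSums((out - target)^2)))
            if (abs(rmsd - new_rmsd) < tol) { rmsd <- new_rmsd; break }
            rmsd <- new_rmsd
        }
    }
    list(transform = list(kind = "rigid", R = tr$R, t = tr$t),
         mesh = TriangleMesh(out, moving@faces), rmsd = rmsd)
}

#' Affine (12-dof) alignment of one mesh onto another
#'
#' Least-squares 3x4 affine on matched vertex pairs (same topology or
#' an explicit correspondence), or on closest-point pairs after a rigid
#' initialisation. Exactly recovers the transform when \code{moving}
#' is an affine image of \code{fixed}.
#'
#' @param moving,fixed \linkS4class{TriangleMesh} objects.
#' @param correspondence optional integer vector mapping moving vertex
#'   \code{i} to fixed vertex \code{correspondence[i]}.
#' @return list with \code{transform} (\code{kind}, matrix \code{A}
#'   3x4), \code{mesh} (moved mesh), \code{rmsd}.
#' @export
affineAlign <- function(moving, fixed, correspondence = NULL) {
    mv <- moving@vertices
    if (!is.null(correspondence)) {
        target <- fixed@vertices[correspondence, , drop = FALSE]
    } else if (nVertices(moving) == nVertices(fixed)) {
        target <- fixed@vertices
    } else {
        target <- .closest_points(rigidAlign(moving, fixed)$mesh@vertices,
                                  fixed)
        # pairs are between the rigidly moved vertices and the surface;
        # solve the affine on the original coordinates against them
    }
    X <- cbind(mv, 1)
    if (qr(X)$rank < 4L)
        stop("rank-deficient point configuration; affine underdetermined")
    B <- qr.solve(X, target)              # 4 x 3
    out <- X %*% B
    list(transform = list(kind = "affine", A = t(B)),
         mesh = TriangleMesh(out, moving@faces),
         rmsd = sqrt(mean(rowSums((out - target)^2))))
}

#' Propagate the template topology onto a subject surface
#'
#' Dense template-to-subject map: a Gaussian-style regularised
#' closest-point deformation (smoothed displacement-field iterations
#' over the template adjacency) followed by exact projection onto the
#' subject surface, so every propagated vertex lies on the subject to
#' numerical precision while neighbouring template vertices map to
#' nearby subject points. The subject is assumed rigidly and affinely
#' pre-aligned to the template.
#'
#' @param template the template \linkS4class{TriangleMesh}.
#' @param subject the subject \linkS4class{TriangleMesh}.
#' @param iterations smoothed-deformation iterations before the final
#'   projection.
#' @param smooth_passes adjacency-smoothing passes per iteration
#'   applied to the displacement field.
#' @param step fraction of the smoothed displacement taken per
#'   iteration.
#' @param epsilon maximum tolerated distance (mm) from propagated
#'   vertices to the subject surface.
#' @param flag_folds warn when the propagated mesh has fold-over
#'   (locally inverted faces).
#' @return \code{n_v x 3} matrix of subject-space vertex positions in
#'   template topology, with attribute \code{"flagged"} TRUE if
#'   fold-over was detected.
#' @export
nonrigidPropagate <- function(template, subject, iterations = 10L,
                              smooth_passes = 3L, step = 0.7,
                              epsilon = 0.5, flag_folds = TRUE) {
    A <- adjacencyOperator(template)
    cur <- template@vertices
    for (it in seq_len(iterations)) {
        delta <- .closest_points(cur, subject) - cur
        for (s in seq_len(smooth_passes))
            delta <- as.matrix(A %*% delta)
        cur <- cur + step * delta
    }
    cur <- .closest_points(cur, subject)

    resid <- sqrt(rowSums((.closest_points(cur, subject) - cur)^2))
    if (max(resid) > epsilon)
        warning(sprintf("propagation residual %.3f mm exceeds epsilon %.3f",
                        max(resid), epsilon))

    flagged <- FALSE
    if (flag_folds) {
        before <- .face_cross(template)
        after <- .face_cross(TriangleMesh(cur, template@faces))
        flips <- rowSums(before * after) < 0
        if (mean(flips) > 0.02) {
            flagged <- TRUE
            warning(sprintf("fold-over on %.1f%% of faces; subject flagged",
                            100 * mean(flips)))
        }
    }
    structure(cur, flagged = flagged)
}

#' Build a population template by iterative averaging
#'
#' Starting from a reference mesh, every input mesh is rigidly aligned
#' to the current template, the template is propagated onto it, and
#' the propagated vertex positions are averaged; repeated until the
#' mean vertex shift falls under \code{tol} or \code{max_iterations}
#' is reached (then the last iterate is returned with a warning). The
#' output carries the reference topology.
#'
#' @param meshes list of \linkS4class{TriangleMesh} (>= 2, or 1 which
#'   is returned unchanged).
#' @param reference_index which mesh seeds the topology (default 1).
#' @param max_iterations mean-update iterations (default 3).
#' @param tol convergence tolerance on the mean vertex shift (mm).
#' @param ... passed to \code{\link{nonrigidPropagate}}.
#' @return the template \linkS4class{TriangleMesh}.
#' @export
buildTemplate <- function(meshes, reference_index = 1L,
                          max_iterations = 3L, tol = 1e-3, ...) {
    if (length(meshes) < 1L) stop("need at least one mesh")
    if (length(meshes) == 1L) return(meshes[[1L]])
    ref <- meshes[[reference_index]]
    converged <- FALSE
    for (it in seq_len(max_iterations)) {
        acc <- matrix(0, nVertices(ref), 3)
        for (m in meshes) {
            aligned <- rigidAlign(m, ref)$mesh
            acc <- acc + nonrigidPropagate(ref, aligned, ...)
        }
        newv <- acc / length(meshes)
        shift <- mean(sqrt(rowSums((newv - ref@vertices)^2)))
        ref <- TriangleMesh(newv, ref@faces)
        if (shift < tol) { converged <- TRUE; break }
    }
    if (!converged && max_iterations > 1L)
        warning("template averaging did not converge; returning last iterate")
    ref
}
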