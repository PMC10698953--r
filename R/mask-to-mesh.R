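#' Extract a surface mesh from a binary segmentation mask
#'
#' Isosurface extraction at \code{iso_level} (default 0.5, the midpoint
#' of a binary mask) on the voxel grid, by marching tetrahedra on the
#' zero-padded volume so the surface is always closed. Vertex
#' coordinates are mapped to world millimetres through the mask affine
#' (0-based voxel indices). When the foreground is fragmented, the
#' largest connected surface component is kept with a warning.
#'
#' @param mask a \linkS4class{VoxelMask}, or a 3D array (then
#'   \code{affine} supplies the voxel-to-world map).
#' @param iso_level iso value in (0, 1); default 0.5.
#' @param affine 4x4 voxel-to-world matrix used when \code{mask} is an
#'   array; default identity (1 mm isotropic).
#' @return a closed, consistently wound \linkS4class{TriangleMesh}.
#' @examples
#' a <- array(0, c(12, 12, 12)); a[2:11, 2:11, 2:11] <- 1
#' m <- maskToMesh(a)
#' meshVolume(m)  # close to 1000 mm^3
#' @export
maskToMesh <- function(mask, iso_level = 0.5, affine = diag(4)) {
    if (is(mask, "VoxelMask")) {
        affine <- mask@affine
        mask <- mask@data
    }
    if (length(dim(mask)) != 3L) stop("mask must be a 3D array")
    if (!any(mask > iso_level)) stop("mask is empty (no foreground voxels)")

    d <- dim(mask)
    padded <- array(0, d + 2L)
    padded[2:(d[1] + 1), 2:(d[2] + 1), 2:(d[3] + 1)] <- mask
    res <- marching_tetrahedra_cpp(as.double(padded), dim(padded),
                                   iso_level)
    v <- res$vertices - 1           # back to original 0-based voxel indices
    f <- res$faces + 1L             # to 1-based
    if (nrow(v) == 0) stop("isosurface extraction produced no vertices")

    vw <- cbind(v, 1) %*% t(affine)
    mesh <- TriangleMesh(vw[, 1:3, drop = FALSE], f)
    mesh <- cleanMesh(mesh)
    if (!isClosedMesh(mesh))
        stop("non-manifold isosurface: extracted mesh is not closed")
    mesh
}

#' Read a NIfTI segmentation mask
#'
#' @param path path to a NIfTI-1 file (.nii or .nii.gz).
#' @param threshold values above this are foreground (default 0.5).
#' @return a \linkS4class{VoxelMask} with the NIfTI voxel-to-world affine.
#' @export
readMask <- function(path, threshold = 0.5) {
    img <- RNifti::readNifti(path)
    aff <- RNifti::xform(img)
    arr <- array(as.numeric(img > threshold), dim = dim(img))
    VoxelMask(arr, matrix(as.numeric(aff), 4, 4))
}

#' Voxelize a mesh-independent sphere (testing utility)
#'
#' Builds a binary mask of a sphere of radius \code{r} (in voxels)
#' centred in a cubic grid; used to exercise the mask-to-mesh round trip.
#' @param r radius in voxel units.
#' @param pad grid margin in voxels.
#' @return a \linkS4class{VoxelMask} with identity affine.
#' @export
sphereMask <- function(r, pad = 3L) {
    n <- as.integer(ceiling(2 * r) + 2L * pad)
    ctr <- (n - 1) / 2
    g <- (seq_len(n) - 1) - ctr
    dxy2 <- outer(g^2, g^2, "+")
    arr <- array(0, c(n, n, n))
    for (k in seq_len(n))
        arr[, , k] <- as.numeric(sqrt(dxy2 + g[k]^2) <= r)
    VoxelMask(arr)
}
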