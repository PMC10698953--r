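test_that("rigid alignment inverts a constructed rotation + translation", {
    sph <- smallSphere()
    v <- meshVertices(sph)
    th <- pi / 2
    R <- matrix(c(cos(th), -sin(th), 0, sin(th), cos(th), 0, 0, 0, 1),
                3, 3, byrow = TRUE)
    moved <- TriangleMesh(v %*% t(R) +
                          matrix(c(5, 0, 0), nrow(v), 3, byrow = TRUE),
                          meshFaces(sph))
    out <- rigidAlign(moved, sph)
    expect_lt(out$rmsd, 1e-6)
    expect_equal(det(out$transform$R), 1, tolerance = 1e-10)
    # inter-vertex distances preserved
    i <- c(1, 10, 50); j <- c(5, 60, 120)
    d0 <- sqrt(rowSums((meshVertices(moved)[i, ] -
                        meshVertices(moved)[j, ])^2))
    d1 <- sqrt(rowSums((meshVertices(out$mesh)[i, ] -
                        meshVertices(out$mesh)[j, ])^2))
    expect_equal(d1, d0, tolerance = 1e-9)
})

test_that("rigid alignment is identity on identical meshes and keeps scale", {
    sph <- smallSphere()
    out <- rigidAlign(sph, sph)
    expect_lt(out$rmsd, 1e-10)
    expect_equal(out$transform$R, diag(3), tolerance = 1e-8)
    scaled <- TriangleMesh(meshVertices(sph) * 1.2, meshFaces(sph))
    out2 <- rigidAlign(scaled, sph)
    expect_gt(out2$rmsd, 0.5)   # scale is NOT removed
    # collinear geometry rejected
    line <- TriangleMesh(cbind(1:9, 0, 0),
                         matrix(c(1, 2, 3), 1, 3))
    expect_error(rigidAlign(line, line), "degenerate")
})

test_that("affine alignment exactly recovers constructed affines", {
    sph <- smallSphere()
    v <- meshVertices(sph)
    S <- diag(3); S[1, 2] <- 0.3                  # shear
    sheared <- TriangleMesh(v %*% t(S), meshFaces(sph))
    out <- affineAlign(sheared, sph)
    expect_lt(out$rmsd, 1e-8)
    rec <- out$transform$A %*% rbind(t(v %*% t(S)), 1)
    expect_equal(max(abs(rec - t(v))), 0, tolerance = 1e-8)

    A <- diag(c(1.1, 0.9, 1.0))                   # anisotropic scale
    an <- affineAlign(TriangleMesh(v %*% A, meshFaces(sph)), sph)
    expect_lt(an$rmsd, 1e-8)
    expect_equal(an$transform$A[, 1:3], solve(A), tolerance = 1e-8)

    idm <- affineAlign(sph, sph)
    expect_equal(idm$transform$A, cbind(diag(3), 0), tolerance = 1e-8)
})

test_that("propagation maps the template onto identity, inflation and bumps", {
    sph <- smallSphere()
    v <- meshVertices(sph)
    expect_equal(max(abs(nonrigidPropagate(sph, sph) - v)), 0,
                 tolerance = 1e-6)

    g <- vertexGeometry(sph)
    infl <- TriangleMesh(v + 0.05 * 10 * g$normals, meshFaces(sph))
    p <- nonrigidPropagate(sph, infl)
    err <- sqrt(rowSums((p - meshVertices(infl))^2))
    expect_lt(max(err), 0.2)

    # localized 4 mm bump: all propagated vertices end on the surface
    bump <- 4 * exp(-rowSums(sweep(v, 2, v[1, ])^2) / 20)
    subject <- TriangleMesh(v + bump * g$normals, meshFaces(sph))
    pb <- nonrigidPropagate(sph, subject)
    resid <- sqrt(rowSums((
        nephroShape:::.closest_points(pb, subject) - pb)^2))
    expect_lt(max(resid), 0.5)
    # the bump is reached: some propagated vertices moved ~4 mm outward
    expect_gt(max(sqrt(rowSums((pb - v)^2))), 3)
})

test_that("template averaging recovers symmetric and noisy means", {
    s1 <- sphereMesh(300, 1)
    s3 <- TriangleMesh(meshVertices(s1) * 3, meshFaces(s1))
    expect_identical(buildTemplate(list(s1)), s1)
    tp <- suppressWarnings(buildTemplate(list(s1, s3)))
    r <- sqrt(rowSums(meshVertices(tp)^2))
    expect_equal(mean(r), 2, tolerance = 0.05)

    # template + symmetric noise cohort: recovered within noise/sqrt(n)
    set.seed(8)
    sph <- smallSphere()
    g <- vertexGeometry(sph)
    n <- 12
    meshes <- lapply(seq_len(n), function(i)
        TriangleMesh(meshVertices(sph) +
                     rnorm(nVertices(sph), sd = 0.3) * g$normals,
                     meshFaces(sph)))
    tpl <- suppressWarnings(buildTemplate(meshes, max_iterations = 2))
    err <- sqrt(rowSums((meshVertices(tpl) - meshVertices(sph))^2))
    expect_lt(mean(err), 3 * 0.3 / sqrt(n) + 0.05)

    # order insensitivity given a fixed reference topology
    tpl2 <- suppressWarnings(buildTemplate(rev(meshes),
                                           reference_index = n,
                                           max_iterations = 2))
    expect_lt(mean(sqrt(rowSums((meshVertices(tpl2) -
                                 meshVertices(tpl))^2))), 1e-3)
})
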