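test_that("rank-1 data is explained entirely by the first mode", {
    set.seed(70)
    dirv <- rnorm(20); dirv <- dirv / sqrt(sum(dirv^2))
    X <- outer(rnorm(40), dirv)
    m <- fitShapeModel(X, n_modes = 3)
    expect_equal(varianceExplained(m, 1), 100, tolerance = 1e-8)
    expect_equal(abs(sum(shapeModes(m)[, 1] * dirv)), 1,
                 tolerance = 1e-8)
    # identical rows: degenerate, all eigenvalues zero
    d <- fitShapeModel(matrix(1, 10, 5), n_modes = 2)
    expect_true(all(shapeVariances(d) < 1e-20))
})

test_that("a planted 3-mode subspace is recovered within 5 degrees", {
    set.seed(71)
    d <- 60; n <- 500
    Q <- qr.Q(qr(matrix(rnorm(d * 3), d, 3)))
    scores <- cbind(rnorm(n, sd = 5), rnorm(n, sd = 3), rnorm(n, sd = 2))
    X <- scores %*% t(Q) + matrix(rnorm(n * d, sd = 0.3), n, d)
    m <- fitShapeModel(X, n_modes = 3)
    angles <- acos(pmin(svd(t(shapeModes(m)) %*% Q)$d, 1)) * 180 / pi
    expect_lt(max(angles), 5)
    # modes orthonormal
    expect_equal(crossprod(shapeModes(m)), diag(3), tolerance = 1e-8)
    expect_true(all(diff(shapeVariances(m)) <= 1e-8))
})

test_that("mode reconstructions are symmetric displacements about the mean", {
    set.seed(72)
    X <- matrix(rnorm(200), 20, 10)
    m <- fitShapeModel(X)
    expect_equal(modeReconstruction(m, 1, 0), shapeCenter(m))
    up <- modeReconstruction(m, 2, 3)
    dn <- modeReconstruction(m, 2, -3)
    expect_equal(up - shapeCenter(m), -(dn - shapeCenter(m)),
                 tolerance = 1e-12)
    expect_error(modeReconstruction(m, 99, 1), "mode_index")
})

test_that("a planted size mode changes enclosed volume monotonically", {
    sph <- smallSphere()
    v <- as.vector(meshVertices(sph))
    set.seed(73)
    scal <- rnorm(80, sd = 0.05)
    X <- t(vapply(scal, function(s) (1 + s) * v, numeric(length(v))))
    m <- fitShapeModel(X, n_modes = 1, data_kind = "coordinates")
    vol <- function(c_) meshVolume(TriangleMesh(
        matrix(modeReconstruction(m, 1, c_), ncol = 3), meshFaces(sph)))
    # mode signs are convention-fixed, not size-oriented: orient the
    # mode along growth first
    sgn <- sign(sum(shapeModes(m)[, 1] * v))
    expect_gt(vol(3 * sgn), vol(0))
    expect_gt(vol(0), vol(-3 * sgn))
})

test_that("projection and reconstruction are exact inverses", {
    set.seed(74)
    X <- matrix(rnorm(30 * 12), 30, 12)
    m <- fitShapeModel(X)    # full mode set
    expect_equal(unname(projectScores(m, shapeCenter(m))),
                 rep(0, ncol(shapeModes(m))), tolerance = 1e-10)
    l1 <- shapeVariances(m)[1]
    x <- shapeCenter(m) + 2 * sqrt(l1) * shapeModes(m)[, 1]
    sc <- projectScores(m, x)
    expect_equal(unname(sc[1]), 2 * sqrt(l1), tolerance = 1e-8)
    expect_lt(max(abs(sc[-1])), 1e-8)
    rt <- reconstructShape(m, projectScores(m, X))
    expect_lt(max(abs(rt - X)), 1e-8)
})

test_that("training scores have zero mean and variances equal to eigenvalues", {
    set.seed(75)
    X <- matrix(rnorm(50 * 8), 50, 8) %*% diag(c(4, 3, 2, 2, 1, 1, 1, 1))
    m <- fitShapeModel(X)
    sc <- projectScores(m, X)
    expect_lt(max(abs(colMeans(sc))), 1e-10)
    expect_equal(unname(apply(sc, 2, var)),
                 shapeVariances(m)[seq_len(ncol(sc))], tolerance = 1e-10)
})

test_that("eigenvalues are invariant to rigid rotation of coordinates", {
    tpl <- smallTemplate()
    gen <- generateCohort(tpl, syntheticTruth(seed = 76), n_s = 40)
    X <- shapeData(gen$cohort, "coordinates")
    th <- 0.7
    R <- matrix(c(cos(th), -sin(th), 0, sin(th), cos(th), 0, 0, 0, 1),
                3, 3, byrow = TRUE)
    n_v <- nVertices(tpl)
    Xr <- t(apply(X, 1, function(row)
        as.vector(matrix(row, n_v, 3) %*% t(R))))
    m1 <- fitShapeModel(X, n_modes = 5, data_kind = "coordinates")
    m2 <- fitShapeModel(Xr, n_modes = 5, data_kind = "coordinates")
    expect_equal(shapeVariances(m1), shapeVariances(m2),
                 tolerance = 1e-8)
})

test_that("equal-variance isotropic data spreads variance evenly", {
    set.seed(77)
    X <- matrix(rnorm(5000 * 10), 5000, 10)
    m <- fitShapeModel(X)
    pct <- screeTable(m, 10)$pct_variance
    expect_true(all(pct > 8 & pct < 12))
    expect_equal(sum(pct), 100, tolerance = 1e-8)
    expect_equal(varianceExplained(m), 100, tolerance = 1e-10)
})

test_that("excess mode requests are clipped with a warning", {
    X <- matrix(rnorm(5 * 8), 5, 8)
    expect_warning(m <- fitShapeModel(X, n_modes = 7), "clipped")
    expect_equal(ncol(shapeModes(m)), 4L)
    expect_error(fitShapeModel(X[1, , drop = FALSE]), "two subjects")
})
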