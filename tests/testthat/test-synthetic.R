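test_that("template generator hits the vertex budget on a closed genus-0 surface", {
    tpl <- generateTemplateShape(4000, bend = 0.4)
    expect_lt(abs(nVertices(tpl) - 4000) / 4000, 0.10)
    expect_true(isClosedMesh(tpl))
    # Euler characteristic 2 for genus 0
    f <- meshFaces(tpl)
    edges <- unique(t(apply(rbind(f[, c(1, 2)], f[, c(2, 3)],
                                  f[, c(3, 1)]), 1, sort)))
    expect_equal(nVertices(tpl) - nrow(edges) + nFaces(tpl), 2L)
    expect_gt(meshVolume(tpl), 0)
    expect_error(generateTemplateShape(50), "n_vertices")
})

test_that("zero bend gives a bilaterally symmetric superellipsoid", {
    tpl <- generateTemplateShape(300, bend = 0)
    bb <- apply(meshVertices(tpl), 2, range)
    expect_lt(abs(bb[1, 1] + bb[2, 1]), 1e-9)
    expect_lt(abs(bb[1, 2] + bb[2, 2]), 1e-9)
    expect_lt(abs(mean(meshVertices(tpl)[, 1])), 1e-9)
})

test_that("identical seeds give byte-identical cohorts", {
    tpl <- smallTemplate()
    tr <- syntheticTruth(effectMaps = defaultEffectMaps(tpl), seed = 11)
    g1 <- generateCohort(tpl, tr, n_s = 25)
    g2 <- generateCohort(tpl, tr, n_s = 25)
    expect_identical(g1$cohort@vertices, g2$cohort@vertices)
    expect_identical(g1$phenotypes, g2$phenotypes)
    expect_identical(g1$truth_s2s, g2$truth_s2s)
    g3 <- generateCohort(tpl, syntheticTruth(seed = 12), n_s = 25)
    expect_false(identical(g1$truth_s2s, g3$truth_s2s))
})

test_that("null cohorts have per-vertex means shrinking as 3 sd / sqrt(n)", {
    tpl <- smallTemplate()
    tr <- syntheticTruth(noiseSd = 3, seed = 21)
    gen <- generateCohort(tpl, tr, n_s = 200)
    cm <- colMeans(gen$truth_s2s)
    bound <- 3 * 3 / sqrt(200)
    expect_gt(mean(abs(cm) < bound), 0.99)
    expect_lt(abs(mean(cm)), 0.15)
})

test_that("doubling an effect map doubles the fitted coefficients", {
    tpl <- smallTemplate()
    nv <- nVertices(tpl)
    base <- defaultEffectMaps(tpl)["bmi"]
    double <- list(bmi = 2 * base$bmi)
    g0 <- generateCohort(tpl, syntheticTruth(seed = 5), n_s = 500)
    g1 <- generateCohort(tpl, syntheticTruth(effectMaps = base,
                                             seed = 5), n_s = 500)
    g2 <- generateCohort(tpl, syntheticTruth(effectMaps = double,
                                             seed = 5), n_s = 500)
    des <- murDesign(g1$phenotypes, c("age", "sex", "bmi"))
    b0 <- fitMUR(g0$truth_s2s, des$X)$beta["bmi", ]
    b1 <- fitMUR(g1$truth_s2s, des$X)$beta["bmi", ]
    b2 <- fitMUR(g2$truth_s2s, des$X)$beta["bmi", ]
    # same seed, so noise cancels: the effect increment is exact
    expect_equal(b2 - b1, b1 - b0, tolerance = 1e-8)
    expect_gt(mean(b1 - b0), 0.4)   # planted +0.6 mm per SD (sample-SD scale)
})

test_that("default noise gives a median vertex-wise SD near 3 mm", {
    tpl <- smallTemplate()
    gen <- generateCohort(tpl, syntheticTruth(seed = 31), n_s = 400)
    expect_equal(medianVertexSd(gen$truth_s2s), 3.0, tolerance = 0.1)
})

test_that("S2S recomputation reproduces the stored truth to 1e-6 mm", {
    tpl <- smallTemplate()
    tr <- syntheticTruth(effectMaps = defaultEffectMaps(tpl), seed = 41)
    gen <- generateCohort(tpl, tr, n_s = 30)
    s2s <- cohortS2S(gen$cohort)
    expect_lt(max(abs(s2sMatrix(s2s) - gen$truth_s2s)), 1e-6)
})

test_that("effect map validation names the offending covariate", {
    tpl <- smallTemplate()
    bad <- syntheticTruth(effectMaps = list(bmi = c(1, 2, 3)), seed = 1)
    expect_error(generateCohort(tpl, bad, n_s = 10),
                 "length mismatch for covariate 'bmi'")
    unk <- syntheticTruth(effectMaps =
        list(nope = numeric(nVertices(tpl))), seed = 1)
    expect_error(generateCohort(tpl, unk, n_s = 10), "unknown covariate")
})

test_that("survival generator honours its boundary and recovery contracts", {
    set.seed(2)
    pred <- data.frame(x = rnorm(2000))
    # censor window collapsed to zero: everything censored
    tr0 <- syntheticTruth(trueLogHr = c(x = 0.5), censorTime = 0,
                          seed = 3)
    rec0 <- generateSurvivalOutcomes(pred, tr0)
    expect_true(all(rec0$event == 0))

    expect_error(generateSurvivalOutcomes(pred,
        syntheticTruth(trueLogHr = c(y = 1), seed = 1)), "missing")

    # planted log-HR 0.5 recovered within 3 SE at n = 2000
    tr <- syntheticTruth(trueLogHr = c(x = 0.5), baselineHazard = 0.2,
                         seed = 7)
    rec <- generateSurvivalOutcomes(pred, tr)
    est <- fitCoxModel(rec, "x", standardise = FALSE)
    expect_lt(abs(est$beta - 0.5) / est$se, 3)
})

test_that("median follow-up at generator defaults is near 3.7 years", {
    tr <- syntheticTruth(seed = 9)
    rec <- generateSurvivalOutcomes(data.frame(x = rnorm(10000)), tr)
    expect_equal(median(rec$time), 3.7, tolerance = 0.05)
})
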