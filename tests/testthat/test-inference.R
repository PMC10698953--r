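test_that("BH adjustment reproduces the hand-computed step-up values", {
    expect_equal(bhFdr(c(0.01, 0.02, 0.5, 1.0)),
                 c(0.04, 0.04, 2 / 3, 1.0), tolerance = 1e-10)
    expect_equal(bhFdr(rep(1, 5)), rep(1, 5))
    expect_equal(bhFdr(0.37), 0.37)
    expect_error(bhFdr(c(0.5, 1.2)), "\\[0, 1\\]")
    # monotone non-decreasing in raw-p rank
    set.seed(30)
    p <- runif(50)
    adj <- bhFdr(p)
    expect_true(all(diff(adj[order(p)]) > -1e-12))
    expect_true(all(adj >= p - 1e-12))
})

test_that("permutation p-values respect the add-one bound and are reproducible", {
    tpl <- smallTemplate()
    em <- list(bmi = ifelse(meshVertices(tpl)[, 3] > 30, 6, 0))
    tr <- syntheticTruth(effectMaps = em, noiseSd = 3, seed = 51)
    gen <- generateCohort(tpl, tr, n_s = 300)
    des <- murDesign(gen$phenotypes, c("age", "sex", "bmi"))
    geom <- tfceGeometry(tpl)
    pp <- permutationPvalues(gen$truth_s2s, des$X, "bmi", geom,
                             n_perm = 100, seed = 99)
    expect_gte(min(pp$p_perm), 1 / 101)
    expect_lte(max(pp$p_perm), 1)
    # amplitude 2x noise SD: affected vertices at the attainable minimum
    hit <- em$bmi != 0
    expect_true(all(pp$p_perm[1, hit] == 1 / 101))

    pp2 <- permutationPvalues(gen$truth_s2s, des$X, "bmi", geom,
                              n_perm = 100, seed = 99)
    expect_identical(pp$p_perm, pp2$p_perm)
    pp3 <- permutationPvalues(gen$truth_s2s, des$X, "bmi", geom,
                              n_perm = 100, seed = 100)
    expect_false(identical(pp$p_perm, pp3$p_perm))

    expect_error(permutationPvalues(gen$truth_s2s, des$X, "nope", geom,
                                    n_perm = 100), "absent")
    expect_error(permutationPvalues(gen$truth_s2s, des$X, "bmi", geom,
                                    n_perm = 10), "n_perm")
})

test_that("the label-permutation scheme also detects a planted effect", {
    tpl <- smallTemplate()
    em <- list(bmi = ifelse(meshVertices(tpl)[, 3] > 30, 6, 0))
    gen <- generateCohort(tpl, syntheticTruth(effectMaps = em,
                                              seed = 52), n_s = 300)
    des <- murDesign(gen$phenotypes, c("age", "sex", "bmi"))
    pp <- permutationPvalues(gen$truth_s2s, des$X, "bmi",
                             tfceGeometry(tpl), n_perm = 100,
                             seed = 1, scheme = "label")
    expect_true(all(pp$p_perm[1, em$bmi != 0] == 1 / 101))
})

test_that("murAnalysis assembles consistent vertex statistics", {
    tpl <- smallTemplate()
    em <- list(ckd = -defaultEffectMaps(tpl)$ckd * 3)  # strong outward patch
    cfg <- syntheticCovariateConfig(); cfg$ckd$p <- 0.4
    gen <- generateCohort(tpl, syntheticTruth(effectMaps = em, seed = 53),
                          covariate_config = cfg, n_s = 300)
    s2s <- stackCohort(setNames(
        lapply(seq_len(300), function(i) gen$truth_s2s[i, ]),
        gen$phenotypes$subject_id), template = tpl,
        phenotypes = gen$phenotypes)
    st <- murAnalysis(s2s, covariates = c("age", "sex", "ckd"),
                      targets = "ckd", n_perm = 200, seed = 5)
    expect_s4_class(st, "VertexStats")
    expect_true(all(st@pFdr >= st@pPerm - 1e-12))
    expect_identical(st@sigMask, st@pFdr < 0.05)
    expect_gt(mean(st@sigMask["ckd", em$ckd > 0.5]), 0.9)
})

test_that("SPM summaries split by sign and honour the alpha contract", {
    tpl <- smallTemplate()
    em <- list(bmi = pmin(0, -6 * (meshVertices(tpl)[, 3] > 30)))
    gen <- generateCohort(tpl, syntheticTruth(effectMaps = em, seed = 54),
                          n_s = 300)
    s2s <- S2SExperiment(gen$truth_s2s, phenotypes = gen$phenotypes,
                         template = tpl,
                         subjectIds = gen$phenotypes$subject_id)
    st <- murAnalysis(s2s, covariates = c("age", "sex", "bmi"),
                      targets = "bmi", n_perm = 200, seed = 6)
    sm <- summariseSPM(st, scope = "significant")
    # the planted inward patch dominates the detected area
    expect_gt(sm$area_neg_pct, 10)
    expect_gt(sm$area_neg_pct, sm$area_pos_pct)
    expect_equal(sm$area_total_pct, sm$area_neg_pct + sm$area_pos_pct)
    expect_lt(sm$beta_neg_median, 0)

    both <- summariseSPM(st, scope = "both")
    expect_equal(nrow(both), 2L)
    expect_setequal(both$scope, c("significant", "all"))

    all_sig <- summariseSPM(st, alpha = 1, scope = "significant")
    expect_equal(all_sig$area_total_pct, 100)

    # a sign with no significant vertices yields blank (NA) cells
    vs <- new("VertexStats",
              beta = rbind(x = c(-1, -0.5, 0.2, 0.4)),
              tstat = rbind(x = c(-5, -3, 1, 1.2)),
              tfce = rbind(x = c(-9, -4, 1, 1.5)),
              pPerm = rbind(x = c(0.001, 0.002, 0.4, 0.3)),
              pFdr = rbind(x = c(0.004, 0.004, 0.4, 0.4)),
              sigMask = rbind(x = c(TRUE, TRUE, FALSE, FALSE)),
              alpha = 0.05, nPerm = 999L, nVertices = 4L)
    blank <- summariseSPM(vs, scope = "significant")
    expect_true(is.na(blank$beta_pos_median))
    expect_equal(blank$area_pos_pct, 0)
    expect_equal(blank$area_neg_pct, 50)
})

test_that("interaction rate maps are elementwise coefficient sums", {
    beta <- rbind(age = rep(-0.10, 6), `age:ckd` = rep(-0.06, 6),
                  zero = rep(0, 6))
    expect_equal(interactionRateMap(beta, "age", "age:ckd"),
                 rep(-0.16, 6))
    expect_equal(interactionRateMap(beta, "age", "zero"), beta["age", ])
    expect_error(interactionRateMap(beta, "age", "nope"), "not present")
})

test_that("a planted age-by-disease interaction is recovered end to end", {
    set.seed(60)
    n <- 500; nv <- 60
    age <- rnorm(n); ckd <- rbinom(n, 1, 0.3)
    zs <- function(v) (v - mean(v)) / sqrt(mean((v - mean(v))^2))
    # response in SD units: age slope -0.10 everywhere, extra -0.06 in
    # the disease group
    Y <- outer(zs(age), rep(-0.10, nv)) +
         outer(zs(age) * ckd, rep(-0.06, nv)) +
         matrix(rnorm(n * nv, sd = 0.5), n, nv)
    des <- murDesign(data.frame(age = age, ckd = ckd), c("age", "ckd"),
                     interactions = list(c("age", "ckd")))
    fit <- fitMUR(Y, des$X)
    combined <- interactionRateMap(fit$beta, "age", "age:ckd")
    expect_lt(abs(median(combined) - (-0.16)), 0.03)
    expect_lt(abs(median(fit$beta["age", ]) - (-0.10)), 0.03)
})

test_that("standardised coefficients rescale to published millimetres", {
    expect_equal(unstandardise(-0.33, 3.02), -1.0, tolerance = 0.005)
    expect_equal(unstandardise(0.20, 2.95), 0.59, tolerance = 0.005)
    expect_identical(unstandardise(0, 5), 0)
    expect_error(unstandardise(0.1, 0), "sd_s2s_mm")
})
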