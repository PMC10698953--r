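test_that("eGFR evaluates the CKD-EPI 2009 equation exactly", {
    # all multiplicative pieces at unity except the female factor
    expect_equal(egfrCkdEpi(0.7, 0, female = TRUE), 143.538,
                 tolerance = 1e-10)
    # independent high-precision evaluation: 141 * 0.993^60 * 1.018
    expect_equal(egfrCkdEpi(0.7, 60, female = TRUE),
                 141 * 0.993^60 * 1.018, tolerance = 1e-12)
    expect_equal(egfrCkdEpi(0.7, 60, female = TRUE), 94.17,
                 tolerance = 0.01)
    # male kappa/alpha branch and the ancestry factor
    expect_equal(egfrCkdEpi(0.9, 0, female = FALSE), 141,
                 tolerance = 1e-10)
    expect_equal(egfrCkdEpi(0.9, 0, female = FALSE, black = TRUE),
                 141 * 1.159, tolerance = 1e-10)
    expect_error(egfrCkdEpi(0, 50, TRUE), "positive")
    expect_error(egfrCkdEpi(1, -5, TRUE), "age")
})

test_that("eGFR is continuous at Scr = kappa and strictly monotone", {
    for (fem in c(TRUE, FALSE)) {
        kap <- if (fem) 0.7 else 0.9
        lo <- egfrCkdEpi(kap - 1e-9, 55, fem)
        hi <- egfrCkdEpi(kap + 1e-9, 55, fem)
        expect_lt(abs(lo - hi), 1e-4)
    }
    scr <- seq(0.3, 3, by = 0.05)
    e <- egfrCkdEpi(scr, 60, female = TRUE)
    expect_true(all(diff(e) < 0))
    ages <- seq(20, 90, by = 1)
    ea <- egfrCkdEpi(1.1, ages, female = FALSE)
    expect_true(all(diff(ea) < 0))
})

test_that("creatinine units convert explicitly", {
    expect_equal(convertCreatinine(88.42, "umol_L"), 1.0)
    expect_equal(convertCreatinine(61.894, "umol_L"), 0.7,
                 tolerance = 1e-10)
    expect_identical(convertCreatinine(1.3, "mg_dL"), 1.3)
    expect_error(convertCreatinine(80, "mmol_L"))
})

test_that("disease flags follow the published OR rules and boundaries", {
    expect_equal(classifyCKD(53.8, 0), 1L)
    expect_equal(classifyCKD(90, 1), 1L)
    expect_equal(classifyCKD(60.0, 0), 0L)   # strict inequality
    expect_equal(classifyCKD(59.999, 0), 1L)

    expect_equal(classifyHypertension(0, 0, 145, 85), 1L)
    expect_equal(classifyHypertension(0, 0, 130, 92), 1L)
    expect_equal(classifyHypertension(0, 0, 139, 89), 0L)
    expect_equal(classifyHypertension(1, 0, 110, 70), 1L)
    expect_equal(classifyHypertension(0, 1, 110, 70), 1L)
    expect_equal(classifyHypertension(0, 0, 140, 90), 1L)  # >= boundary
})

test_that("questionnaire covariates are coded by the stated rules", {
    raw <- data.frame(
        alcohol_frequency = c("Daily or almost daily",
                              "Once or twice a week", "Never"),
        smoking_status = c("Current", "Previous", "Never"),
        ethnic_background = c("White", "Asian", "White"),
        waist = c(80, 90, 100), hip = c(100, 100, 100))
    out <- codeCovariates(raw)
    expect_equal(out$alcohol_daily, c(1L, 0L, 0L))
    expect_equal(out$smoker_current, c(1L, 0L, 0L))
    expect_equal(out$ethnicity_nonwhite, c(0L, 1L, 0L))
    expect_equal(out$whr, c(0.8, 0.9, 1.0))
})

test_that("QC cascade excludes in order and reproduces a toy roster", {
    roster <- data.frame(
        subject_id = paste0("S", 1:10),
        age = c(NA, 50:57, NA),
        kidney_volume_left = c(100, 25, rep(120, 8)),
        kidney_volume_right = c(100, 180, rep(130, 8)))
    out <- qcFilter(roster, covariate_cols = "age")
    expect_equal(unname(out$tally),
                 c(2L, 1L, 7L))
    expect_equal(names(out$tally),
                 c("missing_covariates", "low_volume", "kept"))
    # one kidney 29 ml, other with full coverage: still excluded
    r2 <- data.frame(subject_id = "X", age = 55,
                     kidney_volume_left = 29, kidney_volume_right = 200)
    expect_equal(qcFilter(r2, covariate_cols = "age")$tally[["kept"]], 0L)
    # missing data takes precedence over volume in the tally
    r3 <- data.frame(subject_id = "Y", age = NA,
                     kidney_volume_left = 10, kidney_volume_right = 10)
    expect_equal(qcFilter(r3, covariate_cols = "age")$exclusion_reason,
                 "missing_covariates")
    # idempotence and conservation
    again <- qcFilter(out$kept, covariate_cols = "age")
    expect_identical(again$kept, out$kept)
    expect_equal(sum(out$tally), nrow(roster))   # kept + excluded = input
})

test_that("a roster with the published exclusion structure leaves 38,868", {
    n <- 44445L
    roster <- data.frame(subject_id = seq_len(n), age = 60,
                         kidney_volume_left = 150,
                         kidney_volume_right = 150)
    roster$age[1:5272] <- NA
    roster$kidney_volume_left[5273:5577] <- 20
    out <- qcFilter(roster, covariate_cols = "age")
    expect_equal(out$tally[["missing_covariates"]], 5272L)
    expect_equal(out$tally[["low_volume"]], 305L)
    expect_equal(out$tally[["kept"]], 38868L)
})

test_that("outlier flagging marks extreme quantiles without excluding", {
    set.seed(80)
    m <- matrix(rnorm(5000), 50, 100)
    m[1, 1] <- 50
    fl <- flagS2SOutliers(m)
    expect_true(fl[1, 1])
    expect_lt(mean(fl), 0.005)
})

test_that("derived phenotypes chain eGFR into the CKD flag", {
    raw <- data.frame(serum_creatinine = c(70, 200), age = c(60, 60),
                      sex = c(0, 0), ckd = c(0, 0),
                      sbp = c(150, 120), dbp = c(80, 80))
    out <- derivePhenotypes(raw)
    expect_gt(out$egfr[1], 60)
    expect_lt(out$egfr[2], 60)
    expect_equal(out$ckd_flag, c(0L, 1L))
    expect_equal(out$htn_flag, c(1L, 0L))
})
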