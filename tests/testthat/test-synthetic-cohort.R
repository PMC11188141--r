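test_that("disorder sizes honor the count constraints and forced cases", {
    expect_equal(unname(sampleDisorderSizes(2, 2, 1.2, seed = 1)), c(1L, 1L))
    for (seed in c(1, 7, 99)) {
        counts <- sampleDisorderSizes(50, 500, 1.2, seed = seed)
        expect_equal(sum(counts), 500L)
        expect_true(all(counts >= 1L))
    }
    expect_error(sampleDisorderSizes(50, 49, 1.2, seed = 1),
                 "invalid parameter")
    expect_identical(sampleDisorderSizes(50, 500, 1.2, seed = 7),
                     sampleDisorderSizes(50, 500, 1.2, seed = 7))
})

test_that("mean disorder sizes follow the Zipf-like law across replicates", {
    nD <- 20L; nP <- 400L; s <- 1.2
    probs <- seq_len(nD)^(-s); probs <- probs / sum(probs)
    expected <- 1 + (nP - nD) * probs           # closed-form oracle
    sims <- vapply(seq_len(200), function(seed)
        as.numeric(sampleDisorderSizes(nD, nP, s, seed = seed)),
        numeric(nD))
    meanCounts <- rowMeans(sims)
    ## compare log-log slopes over ranks where the +1 floor is negligible
    keep <- expected >= 8
    slopeFit <- function(y) unname(coef(lm(log(y[keep]) ~
                                           log(seq_len(nD)[keep])))[2])
    expect_lt(abs(slopeFit(meanCounts) - slopeFit(expected)), 0.05)
    ## and pointwise agreement within Monte-Carlo tolerance
    se <- apply(sims, 1, sd) / sqrt(ncol(sims))
    expect_true(all(abs(meanCounts - expected) < 4 * se + 0.5))
})

test_that("ancestry mixture fractions match the configured probabilities", {
    params <- simulationParams(nPatients = 10000L, nDisorders = 40L,
                               rawDim = 4L, seed = 5L)
    cohort <- sampleCohort(params)
    pat <- patientTable(cohort)
    obs <- table(factor(pat$ancestry_group,
                        c("Unknown", "European", "Asian", "African",
                          "Others"))) / nrow(pat)
    expected <- c(Unknown = 0.16, European = 0.67 * 0.84,
                  Asian = 0.19 * 0.84, African = 0.07 * 0.84,
                  Others = 0.07 * 0.84)
    se <- sqrt(expected * (1 - expected) / nrow(pat))
    expect_true(all(abs(as.numeric(obs) - expected) < 3 * se))
    ## sex roughly balanced
    sexTab <- table(pat$sex) / nrow(pat)
    expect_lt(abs(sexTab[["male"]] - sexTab[["female"]]), 0.05)
    ## age skew below 10 years among known ages
    ages <- pat$age_years[!is.na(pat$age_years)]
    expect_gt(mean(ages < 10), 0.5)
})

test_that("degenerate noise collapses a disorder onto its archetype", {
    params <- simulationParams(nPatients = 60L, nDisorders = 5L,
                               rawDim = 8L, sigmaAncestry = 0,
                               sigmaInteraction = 0, sigmaPatient = 0,
                               sigmaImage = 0, seed = 2L)
    cohort <- sampleCohort(params)
    feats <- rawFeatures(cohort)
    meta <- cohortMeta(cohort)
    for (d in unique(meta$disorder_id)) {
        rows <- feats[meta$disorder_id == d, , drop = FALSE]
        expect_equal(max(apply(rows, 2, function(x) diff(range(x)))), 0)
    }
})

test_that("identical params and seed give identical cohorts", {
    params <- simulationParams(nPatients = 120L, nDisorders = 8L,
                               rawDim = 8L, seed = 42L)
    a <- sampleCohort(params)
    b <- sampleCohort(params)
    expect_identical(cohortMeta(a), cohortMeta(b))
    expect_identical(rawFeatures(a), rawFeatures(b))
})

test_that("splits are patient-disjoint and infeasibility is detected", {
    onePer <- sampleCohort(simulationParams(nPatients = 12L,
                                            nDisorders = 12L,
                                            tailExponent = 0.01,
                                            rawDim = 4L, seed = 1L))
    expect_error(splitCohort(onePer, 0.7, 0.1, seed = 1),
                 "infeasible split")

    cohort <- smallCohort(seed = 3)
    for (seed in 1:5) {
        sp <- splitCohort(cohort, 0.7, 0.1, seed = seed)
        meta <- cohortMeta(sp)
        fitPat <- meta$patient_id[meta$split %in% c("train", "val")]
        testPat <- meta$patient_id[meta$split == "test"]
        expect_length(intersect(fitPat, testPat), 0)
        expect_true(all(meta$split %in% c("train", "val", "test")))
    }
    expect_error(splitCohort(cohort, 0.7, 0.4, seed = 1),
                 "invalid parameter")
})

test_that("without ancestry effects, disorder means do not separate by ancestry", {
    params <- simulationParams(nPatients = 600L, nDisorders = 5L,
                               tailExponent = 0.01, rawDim = 8L,
                               sigmaAncestry = 0, sigmaInteraction = 0,
                               seed = 9L)
    cohort <- sampleCohort(params)
    meta <- cohortMeta(cohort)
    feats <- rawFeatures(cohort)
    ## largest disorder, known groups: one-way ANOVA on the first feature
    d <- names(sort(table(meta$disorder_id), decreasing = TRUE))[1]
    idx <- meta$disorder_id == d & meta$ancestry_group != "Unknown"
    fit <- stats::aov(feats[idx, 1] ~ factor(meta$ancestry_group[idx]))
    p <- summary(fit)[[1]][["Pr(>F)"]][1]
    expect_gt(p, 0.001)
})
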