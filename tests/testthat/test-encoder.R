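test_that("training-disorder selection applies the at-least-seven rule", {
    cohort <- cohortFromCounts(c(A = 7L, B = 6L, C = 10L))
    expect_identical(selectTrainingDisorders(cohort), c("A", "C"))
    expect_identical(selectTrainingDisorders(cohortFromCounts(
        c(A = 1L, B = 1L, C = 1L))), character(0))
    ## independent tally oracle on a simulated cohort
    cohort <- splitCohort(smallCohort(seed = 4), 0.7, 0.1, seed = 2)
    meta <- cohortMeta(cohort)
    tr <- unique(meta[meta$split == "train",
                      c("patient_id", "disorder_id")])
    oracle <- sort(names(which(table(tr$disorder_id) >= 7)))
    expect_identical(selectTrainingDisorders(cohort), oracle)
})

test_that("class weights are inverse-frequency with mean one", {
    w <- computeClassWeights(c(rep("A", 10), rep("B", 30)))
    expect_equal(w[["A"]], 1.5)
    expect_equal(w[["B"]], 0.5)
    expect_equal(computeClassWeights(rep("A", 5))[["A"]], 1.0)
    w <- computeClassWeights(c("A", "B", "B", "C", "C", "C", "C"))
    expect_equal(unname(w[c("A", "B", "C")]), c(12, 6, 3) / 7)
    expect_equal(mean(w), 1)
    expect_error(computeClassWeights(character(0)), "invalid input")
})

test_that("a separable toy problem is learned to 100% validation top-1", {
    params <- simulationParams(nPatients = 60L, nDisorders = 3L,
                               tailExponent = 0.01, rawDim = 8L,
                               sigmaDisorder = 3, sigmaAncestry = 0,
                               sigmaInteraction = 0, sigmaPatient = 0,
                               sigmaImage = 0.01, seed = 7L)
    cohort <- splitCohort(sampleCohort(params), 0.6, 0.2, seed = 1)
    enc <- trainEncoder(cohort, smallConfig(epochs = 30L),
                        minPatients = 2L)
    expect_equal(enc@history$val_top1[nrow(enc@history)], 100)
})

test_that("training is deterministic and fails cleanly on <2 classes", {
    cohort <- splitCohort(smallCohort(seed = 5), 0.7, 0.1, seed = 1)
    a <- trainEncoder(cohort, smallConfig(seed = 3))
    b <- trainEncoder(cohort, smallConfig(seed = 3))
    expect_identical(a@weights, b@weights)
    expect_identical(a@history, b@history)
    expect_error(trainEncoder(cohort, smallConfig(),
                              disorders = "D001"),
                 "invalid training set")
})

test_that("embeddings have unit norm and collapse under zero image noise", {
    params <- simulationParams(nPatients = 200L, nDisorders = 8L,
                               rawDim = 16L, sigmaImage = 0,
                               imagesPerPatientMean = 2, seed = 6L)
    cohort <- splitCohort(sampleCohort(params), 0.7, 0.1, seed = 1)
    enc <- trainEncoder(cohort, smallConfig(), minPatients = 3L)
    emb <- embedImages(enc, cohort)
    expect_equal(unname(sqrt(rowSums(emb^2))),
                 rep(1, nrow(emb)), tolerance = 1e-9)
    expect_identical(emb, embedImages(enc, cohort))
    ## two images of one patient are identical raw vectors here
    meta <- cohortMeta(cohort)
    multi <- names(which(table(meta$patient_id) >= 2))[1]
    rows <- emb[meta$image_id[meta$patient_id == multi], ]
    expect_equal(rows[1, ], rows[2, ], tolerance = 1e-12)
    expect_error(embedImages(enc, matrix(0, 2, 5)), "dimension mismatch")
})

test_that("ensembles behave as contracts require", {
    cohort <- splitCohort(smallCohort(seed = 8), 0.7, 0.1, seed = 1)
    cfg <- smallConfig()
    ens1 <- trainEnsemble(cohort, cfg, nModels = 1L, seeds = 4L)
    single <- trainEncoder(cohort, { c <- cfg; c@seed <- 4L; c })
    expect_identical(embedImages(ens1, cohort)[[1]],
                     embedImages(single, cohort))
    ens3 <- trainEnsemble(cohort, cfg, nModels = 3L, seeds = 1:3)
    hashes <- vapply(ens3@members, function(m)
        digest_params(m@weights), character(1))
    expect_length(unique(hashes), 3L)
    expect_warning(ensDup <- trainEnsemble(cohort, cfg, nModels = 2L,
                                           seeds = c(9L, 9L)),
                   "duplicate")
    expect_identical(ensDup@members[[1]]@weights,
                     ensDup@members[[2]]@weights)
})

test_that("training loss decreases from the first epoch (smoothed)", {
    cohort <- splitCohort(smallCohort(seed = 10), 0.7, 0.1, seed = 1)
    enc <- trainEncoder(cohort, smallConfig(epochs = 25L))
    loss <- enc@history$loss
    ma <- function(i) mean(loss[i:(i + 4)])
    expect_lt(ma(length(loss) - 4), ma(1))
})

test_that("held-out disorders cluster in embedding space", {
    ## strong disorder signal, no ancestry effect: unseen disorders must
    ## still form clusters (the premise of gallery matching)
    params <- simulationParams(nPatients = 400L, nDisorders = 20L,
                               rawDim = 16L, sigmaAncestry = 0,
                               sigmaInteraction = 0,
                               imagesPerPatientMean = 2, seed = 11L)
    cohort <- splitCohort(sampleCohort(params), 0.7, 0.1, seed = 2)
    enc <- trainEncoder(cohort, smallConfig(epochs = 30L))
    meta <- cohortMeta(cohort)
    unseen <- setdiff(unique(meta$disorder_id), trainingDisorders(enc))
    idx <- meta$disorder_id %in% unseen
    emb <- embedImages(enc, rawFeatures(cohort)[meta$image_id[idx], ])
    lab <- meta$disorder_id[idx]
    D <- 1 - tcrossprod(emb)
    same <- outer(lab, lab, "==") & upper.tri(D)
    diff <- outer(lab, lab, "!=") & upper.tri(D)
    expect_lt(mean(D[same]), mean(D[diff]))
})
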