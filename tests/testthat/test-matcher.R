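test_that("cosine distance matches the closed form", {
    expect_equal(cosineDistance(c(1, 0), c(1, 0)), 0)
    expect_equal(cosineDistance(c(1, 0), c(0, 1)), 1)
    expect_equal(cosineDistance(c(1, 0), c(-1, 0)), 2)
    expect_equal(cosineDistance(c(1, 1), c(1, 0)), 1 - 1 / sqrt(2))
    expect_error(cosineDistance(c(0, 0), c(1, 0)), "zero norm")
    expect_error(cosineDistance(c(1, 0, 0), c(1, 0)), "unequal dimension")
})

test_that("disorder ranking uses nearest-image semantics", {
    gal <- galleryFromCoords(list(D1 = rbind(c(1, 0)),
                                  D2 = rbind(c(0, 1), c(0.6, 0.8))))
    rk <- rankDisorders(c(0.8, 0.6), gal)
    expect_identical(rk$disorder_id, c("D2", "D1"))
    expect_equal(rk$distance, c(0.04, 0.2), tolerance = 1e-12)
    ## trivial single-image gallery
    rk1 <- rankDisorders(c(1, 0), galleryFromCoords(list(D1 = rbind(c(1, 0)))))
    expect_identical(rk1$disorder_id, "D1")
    expect_equal(rk1$distance, 0)
})

test_that("rankings agree with the brute-force oracle on random instances", {
    for (trial in 1:30) {
        withr::with_seed(trial, {
            dim <- sample(2:8, 1)
            nDis <- sample(2:10, 1)
            nGal <- sample(nDis:50, 1)
            nMem <- sample(1:3, 1)
            disorders <- sprintf("D%02d", sample(nDis))
            galDis <- c(disorders,
                        sample(disorders, nGal - nDis, replace = TRUE))
            mats <- replicate(nMem, matrix(rnorm(nGal * dim), nGal, dim),
                              simplify = FALSE)
            testRows <- replicate(nMem, rnorm(dim), simplify = FALSE)
        })
        ids <- sprintf("G%03d", seq_along(galDis))
        mats <- lapply(mats, function(m) { rownames(m) <- ids; m })
        gal <- galleryFromMeta(
            data.frame(image_id = ids, patient_id = ids,
                       disorder_id = galDis, ancestry_group = "European"),
            mats)
        test <- lapply(testRows, function(v)
            matrix(v, 1, dimnames = list("T001", NULL)))
        got <- rankDisorders(test, gal)[[1]]
        want <- oracleRankDisorders(testRows, mats, galDis)
        expect_identical(got$disorder_id, want$disorder_id)
        expect_equal(got$distance, want$distance, tolerance = 1e-9)
        expect_true(all(got$distance >= 0 & got$distance <= 2))
        expect_setequal(got$disorder_id, unique(galDis))
    }
})

test_that("rankings are invariant to gallery row order and ensemble copies", {
    withr::with_seed(99, {
        X <- matrix(rnorm(30 * 4), 30, 4)
        dis <- sample(sprintf("D%d", 1:6), 30, replace = TRUE)
        v <- rnorm(4)
    })
    ids <- sprintf("G%03d", 1:30)
    rownames(X) <- ids
    meta <- data.frame(image_id = ids, patient_id = ids,
                       disorder_id = dis, ancestry_group = "European")
    base <- rankDisorders(v, galleryFromMeta(meta, X))
    perm <- withr::with_seed(1, sample(30))
    shuffled <- rankDisorders(v, galleryFromMeta(meta[perm, ],
                                                 X[perm, ]))
    expect_equal(base, shuffled)
    tripled <- rankDisorders(v, galleryFromMeta(meta, list(X, X, X)))
    expect_equal(base, tripled)
})

test_that("top-k hits follow support semantics", {
    rk <- data.frame(disorder_id = c("A", "B", "C"),
                     distance = c(0.1, 0.2, 0.3))
    expect_true(topKHit(rk, "A", 1))
    expect_false(topKHit(rk, "C", 2))
    expect_true(topKHit(rk, "C", 3))
    expect_true(topKHit(rk, "C", 30))  # k beyond list length
    expect_message(res <- topKHit(rk, "Z", 5), "not supported")
    expect_false(res)
    expect_error(topKHit(rk, "A", 0), "invalid parameter")
})

test_that("gallery construction filters, subsamples whole patients, and tallies", {
    cohort <- splitCohort(smallCohort(seed = 12), 0.7, 0.1, seed = 3)
    meta <- cohortMeta(cohort)
    emb <- rawFeatures(cohort)  # any image-keyed matrix works here
    gal <- buildGallery(cohort, emb, ancestry = "European")
    expect_true(all(gal@meta$ancestry_group == "European"))
    ## tally: default gallery = all train + val images
    galAll <- buildGallery(cohort, emb)
    expect_equal(nrow(galAll@meta),
                 sum(meta$split %in% c("train", "val")))
    ## patient-level subsampling never splits a patient
    galSub <- buildGallery(cohort, emb,
                           subsample = list(groups = c("Asian", "African",
                                                       "Others"),
                                            fraction = 0.5), seed = 4)
    fitMeta <- meta[meta$split %in% c("train", "val"), ]
    for (p in unique(fitMeta$patient_id)) {
        nIn <- sum(galSub@meta$patient_id == p)
        nAll <- sum(fitMeta$patient_id == p)
        expect_true(nIn == 0 || nIn == nAll)
    }
    expect_error(buildGallery(cohort, emb, ancestry = "Martian"),
                 "invalid gallery")
    ## a test image may not be ranked against a gallery containing it
    testId <- meta$image_id[meta$split == "test"][1]
    tm <- emb[testId, , drop = FALSE]
    galLeak <- galleryFromMeta(meta, emb)
    expect_error(rankDisorders(tm, galLeak), "present in the gallery")
})
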