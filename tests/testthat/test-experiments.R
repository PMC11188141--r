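# Fast experiment settings: small cohort, short training.
expCohort <- function(seed = 21L)
    sampleCohort(simulationParams(nPatients = 400L, nDisorders = 15L,
                                  rawDim = 16L, seed = seed))

test_that("composition subsets are patient-disjoint, ancestry-pure and reproducible", {
    cohort <- expCohort()
    spec <- trainingCompositionSpec(sizeEU = 120L, sizeExt = 60L,
                                    evalSize = 60L, masterSeed = 5L)
    subs <- suppressWarnings(
        buildTrainingCompositionSubsets(cohort, spec, repeatSeed = 3L))
    pats <- subs$patients
    combos <- combn(names(pats), 2)
    for (j in seq_len(ncol(combos)))
        expect_length(intersect(pats[[combos[1, j]]],
                                pats[[combos[2, j]]]), 0)
    meta <- cohortMeta(cohort)
    anc <- function(ids) unique(meta$ancestry_group[meta$image_id %in% ids])
    expect_identical(anc(subs$EU), "European")
    expect_identical(anc(subs$EUstar), "European")
    expect_false("European" %in% anc(subs$nonEU))
    expect_false("Unknown" %in% anc(subs$nonEU))
    expect_gt(length(anc(subs$evalSet)), 1)   # eval spans ancestries
    ## determinism
    subs2 <- suppressWarnings(
        buildTrainingCompositionSubsets(cohort, spec, repeatSeed = 3L))
    expect_identical(subs[c("EU", "EUstar", "nonEU", "evalSet")],
                     subs2[c("EU", "EUstar", "nonEU", "evalSet")])
    ## realized-vs-requested accounting is reported
    expect_identical(subs$realized$set, c("EU", "EUstar", "nonEU", "evalSet"))
    expect_true(all(subs$realized$realized > 0))
})

test_that("infeasible non-EU quotas warn and redistribute", {
    ## tiny non-EU pool: quotas cannot be met disorder by disorder
    cohort <- sampleCohort(simulationParams(
        nPatients = 300L, nDisorders = 10L, rawDim = 8L,
        ancestryKnownProps = c(European = 0.94, Asian = 0.02,
                               African = 0.02, Others = 0.02),
        unknownAncestryFrac = 0.05, seed = 8L))
    spec <- trainingCompositionSpec(sizeEU = 150L, sizeExt = 75L,
                                    evalSize = 40L, masterSeed = 2L)
    expect_warning(
        subs <- buildTrainingCompositionSubsets(cohort, spec,
                                                repeatSeed = 1L),
        "non-EU subset")
    nonEU <- subs$realized$realized[subs$realized$set == "nonEU"]
    expect_lt(nonEU, 75L)   # pool exhausted, realized < requested
})

test_that("the training-composition experiment is reproducible and well-shaped", {
    cohort <- expCohort()
    spec <- trainingCompositionSpec(sizeEU = 120L, sizeExt = 60L,
                                    evalSize = 60L, nRepeats = 1L,
                                    masterSeed = 7L)
    cfg <- smallConfig(epochs = 10L)
    a <- suppressWarnings(
        runTrainingCompositionExperiment(cohort, spec, cfg,
                                         minPatients = 4L))
    b <- suppressWarnings(
        runTrainingCompositionExperiment(cohort, spec, cfg,
                                         minPatients = 4L))
    expect_identical(a$perRepeat, b$perRepeat)
    expect_setequal(unique(a$perRepeat$condition), c("eu_only", "diverse"))
    expect_true("Averaged" %in% a$perRepeat$group)
    expect_true(all(a$perRepeat$top_1 >= 0 & a$perRepeat$top_1 <= 100))
    expect_true(all(a$perRepeat$top_1 <= a$perRepeat$top_5))
})

test_that("gallery sweep nests samples and is deterministic at the endpoints", {
    cohort <- splitCohort(expCohort(seed = 22L), 0.7, 0.1, seed = 2)
    enc <- trainEncoder(cohort, smallConfig(epochs = 10L), minPatients = 5L)
    spec <- gallerySweepSpec(proportions = c(0, 0.3, 0.6, 1),
                             nRepeats = 3L, masterSeed = 4L)
    sw <- runGallerySweep(cohort, enc, spec)
    pr <- sw$perRepeat
    ## gallery size grows with p within each repeat
    for (r in unique(pr$rep)) {
        sizes <- unique(pr[pr$rep == r, c("proportion", "gallery_size")])
        sizes <- sizes[order(sizes$proportion), ]
        expect_true(all(diff(sizes$gallery_size) >= 0))
    }
    ## p=0 and p=1 carry no sampling randomness
    for (p in c(0, 1)) {
        acc <- pr[pr$proportion == p, ]
        spread <- tapply(acc$accuracy, acc$group, function(x)
            diff(range(x)))
        expect_equal(max(spread), 0)
    }
    ## p=1 gallery equals the full EU + non-EU train/val set
    meta <- cohortMeta(cohort)
    fit <- meta[meta$split %in% c("train", "val") &
                meta$ancestry_group != "Unknown", ]
    expect_equal(unique(pr$gallery_size[pr$proportion == 1]), nrow(fit))
    ## whole experiment reproducible from the master seed
    sw2 <- runGallerySweep(cohort, enc, spec)
    expect_identical(sw$perRepeat, sw2$perRepeat)
})
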