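test_that("age binning uses half-open intervals with Unknown for missing", {
    expect_identical(ageBin(c(0, 0.99, 1, 4.99, 5, 9.99, 10, 80, NA)),
                     c("[0,1)", "[0,1)", "[1,5)", "[1,5)", "[5,10)",
                       "[5,10)", "[10,Inf)", "[10,Inf)", "Unknown"))
    expect_error(ageBin(-1), "invalid input")
})

makeResults <- function(hits, groups,
                        sex = "female", age = NA_real_) {
    n <- length(hits)
    data.frame(image_id = sprintf("I%03d", seq_len(n)),
               disorder_id = "D001",
               ancestry_group = rep_len(groups, n),
               sex = rep_len(sex, n),
               age_bin = ageBin(rep_len(age, n)),
               rank_true = ifelse(hits, 1L, 99L),
               hit_1 = hits, hit_5 = hits, hit_10 = hits, hit_30 = hits)
}

test_that("the stratified table conserves counts and is monotone in k", {
    res <- makeResults(c(TRUE, FALSE, FALSE, TRUE), "European")
    tab <- topKTable(res)
    expect_equal(tab$top_1[tab$stratum == "Overall"], 50)
    expect_equal(tab$n[tab$stratum == "Overall"], 4)
    ## counts conserve within each category; empty strata have n=0, NA acc
    for (cat in c("Ancestry", "Sex", "Age"))
        expect_equal(sum(tab$n[tab$category == cat]), 4)
    expect_true(all(is.na(tab$top_1[tab$n == 0])))
    ## monotonicity on a real evaluation
    cohort <- splitCohort(smallCohort(seed = 13), 0.7, 0.1, seed = 1)
    enc <- trainEncoder(cohort, smallConfig())
    ev <- evaluateTestSplit(enc, cohort,
                            buildGallery(cohort, embedImages(enc, cohort)))
    tab <- topKTable(ev$results)
    ok <- !is.na(tab$top_1)
    expect_true(all(tab$top_1[ok] <= tab$top_5[ok] &
                    tab$top_5[ok] <= tab$top_10[ok] &
                    tab$top_10[ok] <= tab$top_30[ok]))
    ## recount oracle from the raw rankings
    hits1 <- vapply(seq_len(nrow(ev$results)), function(i) {
        rk <- ev$rankings[[ev$results$image_id[i]]]
        identical(rk$disorder_id[1], ev$results$disorder_id[i])
    }, logical(1))
    expect_equal(tab$top_1[1], 100 * mean(hits1))
})

test_that("ancestry-averaged accuracy weights groups, not images", {
    res <- makeResults(c(rep(c(TRUE, FALSE), 50), rep(TRUE, 10)),
                       c(rep("European", 100), rep("Asian", 10)))
    ## definitional: (50 + 100) / 2 = 75, not the image-weighted 54.5
    expect_equal(ancestryAveragedTopK(res, 1), 75)
    ## duplicating every image of one group changes nothing
    dup <- rbind(res, res[res$ancestry_group == "Asian", ])
    expect_equal(ancestryAveragedTopK(dup, 1), 75)
    ## single group equals its own accuracy
    one <- makeResults(c(TRUE, TRUE, FALSE), "African")
    expect_equal(ancestryAveragedTopK(one, 1), 100 * 2 / 3)
    ## Unknown excluded by default, included on request
    res$ancestry_group[1:100] <- "Unknown"
    expect_equal(ancestryAveragedTopK(res, 1), 100)
    expect_equal(ancestryAveragedTopK(res, 1, includeUnknown = TRUE), 75)
    none <- makeResults(TRUE, "Unknown")
    expect_error(ancestryAveragedTopK(none, 1), "invalid input")
})

test_that("overlapping-disorder comparison restricts to shared disorders", {
    res <- makeResults(rep(TRUE, 6), c(rep("European", 3), rep("Asian", 3)))
    res$disorder_id <- c("D1", "D2", "D2", "D2", "D3", "D3")
    cmp <- overlappingDisorderComparison(res, "European", "Asian")
    expect_equal(cmp$nDisorders, 1L)   # only D2 shared
    expect_equal(cmp$table$n, c(2L, 1L))
    ## identical disorder sets: restriction is the identity
    res2 <- makeResults(rep(TRUE, 4), c("European", "European",
                                        "Asian", "Asian"))
    res2$disorder_id <- c("D1", "D2", "D1", "D2")
    cmp2 <- overlappingDisorderComparison(res2, "European", "Asian")
    expect_equal(cmp2$nDisorders, 2L)
    expect_equal(sum(cmp2$table$n), 4L)
    ## zero overlap flagged, not an error
    res3 <- res2
    res3$disorder_id <- c("D1", "D1", "D2", "D2")
    cmp3 <- overlappingDisorderComparison(res3, "European", "Asian")
    expect_true(cmp3$empty)
    expect_equal(cmp3$nDisorders, 0L)
    expect_error(overlappingDisorderComparison(res3, "European", "Martian"),
                 "not present")
})

test_that("restriction counts match a brute-force filter on a seeded cohort", {
    cohort <- splitCohort(smallCohort(seed = 14), 0.7, 0.1, seed = 2)
    enc <- trainEncoder(cohort, smallConfig())
    ev <- evaluateTestSplit(enc, cohort,
                            buildGallery(cohort, embedImages(enc, cohort)))
    res <- ev$results
    groups <- names(which(table(res$ancestry_group) > 0))
    if (all(c("European", "Asian") %in% groups)) {
        cmp <- overlappingDisorderComparison(res, "European", "Asian")
        dEU <- unique(res$disorder_id[res$ancestry_group == "European"])
        dAS <- unique(res$disorder_id[res$ancestry_group == "Asian"])
        shared <- intersect(dEU, dAS)
        expect_equal(cmp$nDisorders, length(shared))
        if (!cmp$empty)
            expect_equal(cmp$table$n[1],
                         sum(res$ancestry_group == "European" &
                             res$disorder_id %in% shared))
    }
})
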