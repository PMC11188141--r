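.AGE_BINS <- c("[0,1)", "[1,5)", "[5,10)", "[10,Inf)", "Unknown")

#' Bin an age in years into the standard half-open intervals
#'
#' Bins are `[0,1)`, `[1,5)`, `[5,10)`, `[10,Inf)` -- half-open, so an
#' exact boundary age belongs to the upper bin -- and `Unknown` for
#' missing ages.  Negative ages are an error.
#'
#' @param age numeric vector of ages in years, `NA` for missing.
#' @return character vector of bin labels.
#' @examples
#' ageBin(c(0.99, 1, 10, NA))
#' @export
ageBin <- function(age) {
    if (any(!is.na(age) & age < 0))
        stop("invalid input: negative age")
    out <- rep("Unknown", length(age))
    ok <- !is.na(age)
    out[ok] <- as.character(cut(age[ok], c(0, 1, 5, 10, Inf),
                                labels = .AGE_BINS[1:4], right = FALSE,
                                include.lowest = TRUE))
    out
}

#' Evaluate rankings of a test set against its metadata
#'
#' Produces the per-image evaluation record underlying every accuracy
#' table: one row per test image with its stratification variables and a
#' `hit_k` indicator for each cutoff in `kList`.  Images whose true
#' disorder is not supported by the gallery count as misses at every k.
#'
#' @param meta data.frame of test-image metadata (columns `image_id`,
#'   `disorder_id`, `ancestry_group`, `sex`, `age_years`).
#' @param rankings named list of ranking data.frames (names = image ids),
#'   as returned by [rankDisorders()].
#' @param kList integer cutoffs (default `c(1, 5, 10, 30)`).
#' @return data.frame with columns `image_id`, `disorder_id`,
#'   `ancestry_group`, `sex`, `age_bin`, `rank_true` (NA when
#'   unsupported) and logical `hit_<k>` columns.
#' @export
evaluateRankings <- function(meta, rankings, kList = c(1L, 5L, 10L, 30L)) {
    stopifnot(all(meta$image_id %in% names(rankings)))
    kList <- sort(unique(as.integer(kList)))
    rankTrue <- vapply(seq_len(nrow(meta)), function(i) {
        r <- rankings[[meta$image_id[i]]]
        pos <- match(meta$disorder_id[i], r$disorder_id)
        if (is.na(pos)) NA_integer_ else pos
    }, integer(1))
    out <- data.frame(image_id = meta$image_id,
                      disorder_id = meta$disorder_id,
                      ancestry_group = meta$ancestry_group,
                      sex = meta$sex,
                      age_bin = ageBin(meta$age_years),
                      rank_true = rankTrue,
                      stringsAsFactors = FALSE)
    for (k in kList)
        out[[sprintf("hit_%d", k)]] <- !is.na(rankTrue) & rankTrue <= k
    out
}

.strataSpec <- function(results) {
    list(Ancestry = factor(results$ancestry_group,
                           levels = .ANCESTRY_LEVELS),
         Sex = factor(results$sex, levels = .SEX_LEVELS),
         Age = factor(results$age_bin, levels = .AGE_BINS))
}

#' Stratified top-k accuracy table
#'
#' The standard performance readout: top-k accuracy (percent) overall and
#' per stratum of ancestry, sex and age bin.  Strata with no test images
#' are reported with count 0 and blank (NA) accuracy.  Within each
#' category, stratum counts sum to the overall test-set size.
#'
#' @param results a per-image evaluation data.frame from
#'   [evaluateRankings()].
#' @param kList cutoffs; must match the `hit_` columns present.
#' @return data.frame with columns `category`, `stratum`, `n` and one
#'   `top_<k>` column per cutoff (accuracy in percent).
#' @export
topKTable <- function(results, kList = c(1L, 5L, 10L, 30L)) {
    if (!nrow(results)) stop("invalid input: empty results")
    kList <- sort(unique(as.integer(kList)))
    hitCols <- sprintf("hit_%d", kList)
    stopifnot(all(hitCols %in% colnames(results)))
    rows <- list(data.frame(category = "Overall", stratum = "Overall",
                            n = nrow(results),
                            t(vapply(hitCols, function(h)
                                100 * mean(results[[h]]), numeric(1)))))
    for (cat in names(.strataSpec(results))) {
        f <- .strataSpec(results)[[cat]]
        for (lev in levels(f)) {
            idx <- which(f == lev)
            acc <- if (length(idx))
                vapply(hitCols, function(h)
                    100 * mean(results[[h]][idx]), numeric(1))
            else setNames(rep(NA_real_, length(hitCols)), hitCols)
            rows[[length(rows) + 1L]] <-
                data.frame(category = cat, stratum = lev, n = length(idx),
                           t(acc))
        }
    }
    out <- do.call(rbind, rows)
    colnames(out) <- c("category", "stratum", "n",
                       sprintf("top_%d", kList))
    rownames(out) <- NULL
    out
}

#' Ancestry-averaged top-k accuracy
#'
#' The unweighted mean of per-ancestry-group accuracies over groups with
#' at least one test image, so an infrequent group weighs equally with the
#' frequent ones.  The `Unknown` group is excluded by default because the
#' composition experiments define their subsets by known ancestry.
#'
#' @param results per-image evaluation data.frame.
#' @param k cutoff; `hit_<k>` must be present.
#' @param includeUnknown include the `Unknown` group (default `FALSE`).
#' @return accuracy in percent.
#' @examples
#' ## group accuracies 50% (100 images) and 100% (10 images) average to 75
#' @export
ancestryAveragedTopK <- function(results, k, includeUnknown = FALSE) {
    hitCol <- sprintf("hit_%d", as.integer(k))
    stopifnot(hitCol %in% colnames(results))
    groups <- if (includeUnknown) .ANCESTRY_LEVELS else .ANCESTRY_GROUPS
    accs <- vapply(groups, function(g) {
        idx <- results$ancestry_group == g
        if (!any(idx)) NA_real_ else 100 * mean(results[[hitCol]][idx])
    }, numeric(1))
    if (all(is.na(accs)))
        stop("invalid input: no non-empty ancestry group")
    mean(accs, na.rm = TRUE)
}

#' Compare two ancestry groups on their overlapping disorders
#'
#' Frequent and infrequent groups may be evaluated on different disorder
#' sets, so raw per-group accuracies are not directly comparable.  This
#' restricts each group's test images to the disorders present in both
#' groups' test sets and reports per-group top-k accuracy on the
#' restriction together with the number of shared disorders.
#'
#' @param results per-image evaluation data.frame.
#' @param groupA,groupB ancestry group labels present in `results`.
#' @param kList cutoffs.
#' @return list with elements `table` (per-group accuracy data.frame on
#'   the restriction; empty when there is no overlap), `nDisorders`
#'   (shared disorder count) and `empty` (flag).
#' @export
overlappingDisorderComparison <- function(results, groupA, groupB,
                                          kList = c(1L, 5L, 10L, 30L)) {
    for (g in c(groupA, groupB))
        if (!any(results$ancestry_group == g))
            stop(sprintf("group %s not present in results", g))
    kList <- sort(unique(as.integer(kList)))
    hitCols <- sprintf("hit_%d", kList)
    dA <- unique(results$disorder_id[results$ancestry_group == groupA])
    dB <- unique(results$disorder_id[results$ancestry_group == groupB])
    shared <- intersect(dA, dB)
    if (!length(shared))
        return(list(table = data.frame(), nDisorders = 0L, empty = TRUE))
    rows <- lapply(c(groupA, groupB), function(g) {
        idx <- results$ancestry_group == g & results$disorder_id %in% shared
        acc <- vapply(hitCols, function(h)
            100 * mean(results[[h]][idx]), numeric(1))
        data.frame(group = g, n = sum(idx), t(acc))
    })
    tab <- do.call(rbind, rows)
    colnames(tab) <- c("group", "n", sprintf("top_%d", kList))
    list(table = tab, nDisorders = length(shared), empty = FALSE)
}

#' End-to-end evaluation of a cohort's test split
#'
#' Convenience wrapper running the standard pipeline tail: embed the test
#' images with each ensemble member, rank disorders against the gallery
#' and tabulate hits.
#'
#' @param ensemble a [GestaltEnsemble-class] (or single
#'   [GestaltEncoder-class]).
#' @param cohort a split [FaceCohort-class].
#' @param gallery a [GallerySet-class].
#' @param kList cutoffs.
#' @param restrictTo optional character vector of disorders: evaluate only
#'   test images with these true disorders (e.g. training-seen disorders).
#' @param aggregate disorder-score aggregation, see [rankDisorders()].
#' @return list with `results` (per-image data.frame) and `rankings`.
#' @export
evaluateTestSplit <- function(ensemble, cohort, gallery,
                              kList = c(1L, 5L, 10L, 30L),
                              restrictTo = NULL,
                              aggregate = "min") {
    if (is(ensemble, "GestaltEncoder"))
        ensemble <- new("GestaltEnsemble", members = list(ensemble))
    meta <- cohortMeta(cohort)
    testMeta <- meta[meta$split == "test", , drop = FALSE]
    if (!is.null(restrictTo))
        testMeta <- testMeta[testMeta$disorder_id %in% restrictTo, ,
                             drop = FALSE]
    if (!nrow(testMeta)) stop("no test images to evaluate")
    feats <- rawFeatures(cohort)[testMeta$image_id, , drop = FALSE]
    testEmb <- embedImages(ensemble, feats)
    rankings <- rankDisorders(testEmb, gallery, aggregate = aggregate)
    list(results = evaluateRankings(testMeta, rankings, kList),
         rankings = rankings)
}
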