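# Builders for hand-crafted cohorts and galleries used across the suite.

# Assemble a FaceCohort from a metadata data.frame (missing standard
# columns are filled with defaults) and an images x dim feature matrix.
buildCohort <- function(meta, X) {
    defaults <- list(disorder_id = "D001", ancestry_group = "European",
                     sub_ancestry = "", sex = "female",
                     age_years = NA_real_, hpo_terms = "",
                     distinctiveness = NA_integer_, split = "train")
    for (col in names(defaults))
        if (is.null(meta[[col]])) meta[[col]] <- defaults[[col]]
    if (is.null(rownames(X))) rownames(X) <- meta$image_id
    if (is.null(colnames(X))) colnames(X) <- sprintf("F%02d", seq_len(ncol(X)))
    cd <- S4Vectors::DataFrame(meta, row.names = meta$image_id)
    se <- SummarizedExperiment::SummarizedExperiment(
        assays = list(raw = t(X)), colData = cd)
    colnames(se) <- meta$image_id
    rownames(se) <- colnames(X)
    new("FaceCohort", se)
}

# Cohort with a given number of patients per disorder, one image each,
# random features.
cohortFromCounts <- function(counts, dim = 4L, split = "train", seed = 1L) {
    patients <- unlist(lapply(names(counts), function(d)
        rep(d, counts[[d]])))
    n <- length(patients)
    meta <- data.frame(
        patient_id = sprintf("P%03d", seq_len(n)),
        image_id = sprintf("I%03d", seq_len(n)),
        disorder_id = patients,
        split = split)
    X <- withr::with_seed(seed, matrix(rnorm(n * dim), n, dim))
    buildCohort(meta, X)
}

# A small simulated cohort for pipeline-level tests (fast settings).
smallCohort <- function(seed = 1L, ...) {
    sampleCohort(simulationParams(nPatients = 250L, nDisorders = 12L,
                                  rawDim = 16L, seed = seed, ...))
}

smallConfig <- function(seed = 1L, epochs = 15L, ...) {
    encoderConfig(embedDim = 16L, epochs = epochs, seed = seed, ...)
}

# Gallery built straight from coordinates: `images` is a named list
# disorder -> matrix of image coordinates (rows).
galleryFromCoords <- function(images, nMembers = 1L) {
    mats <- do.call(rbind, unname(images))
    ids <- sprintf("G%03d", seq_len(nrow(mats)))
    rownames(mats) <- ids
    meta <- data.frame(
        image_id = ids,
        patient_id = ids,
        disorder_id = rep(names(images),
                          vapply(images, nrow, integer(1))),
        ancestry_group = "European")
    galleryFromMeta(meta, rep(list(mats), nMembers))
}

# Cheap content fingerprint for parameter lists.
digest_params <- function(w) {
    paste(vapply(w, function(m)
        sprintf("%.10e|%.10e", sum(m), sum(m^2)), character(1)),
        collapse = ";")
}

# Brute-force ranking oracle: enumerates every (test, gallery image,
# member) cosine distance with scalar arithmetic, averages over members,
# aggregates per disorder with min, sorts with lexicographic tie-break.
oracleRankDisorders <- function(testRows, galleryMats, galleryDisorders) {
    nG <- nrow(galleryMats[[1]])
    dist <- numeric(nG)
    for (j in seq_len(nG)) {
        per <- vapply(seq_along(galleryMats), function(m)
            cosineDistance(testRows[[m]], galleryMats[[m]][j, ]), numeric(1))
        dist[j] <- mean(per)
    }
    disorders <- sort(unique(galleryDisorders))
    score <- vapply(disorders, function(d)
        min(dist[galleryDisorders == d]), numeric(1))
    ord <- order(score, disorders)
    data.frame(disorder_id = disorders[ord], distance = unname(score[ord]),
               stringsAsFactors = FALSE)
}
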