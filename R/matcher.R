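#' Cosine distance between two vectors
#'
#' `1 - u.v / (|u| |v|)`, in `[0, 2]`; lower distance means higher
#' similarity.  Zero-norm inputs are an error.
#'
#' @param u,v numeric vectors of equal length with positive norm.
#' @return the cosine distance.
#' @examples
#' cosineDistance(c(1, 0), c(0, 1))  # 1
#' @export
cosineDistance <- function(u, v) {
    if (length(u) != length(v))
        stop("invalid vectors: unequal dimension")
    nu <- sqrt(sum(u^2)); nv <- sqrt(sum(v^2))
    if (nu < 1e-12 || nv < 1e-12)
        stop("invalid vector: zero norm")
    d <- 1 - sum(u * v) / (nu * nv)
    min(max(d, 0), 2)
}

#' Build a gallery of embeddings with known diagnoses
#'
#' Selects the images of the requested splits (conventionally train and
#' val, so the gallery covers both seen and unseen disorders while
#' remaining disjoint from the test split), optionally restricted to
#' ancestry groups and optionally subsampled at the patient level: a
#' selected patient contributes all of their images, never a subset.
#'
#' @param cohort a split [FaceCohort-class].
#' @param embeddings a single embedding matrix (images x dim, rownames =
#'   image ids, covering at least the gallery images) or a list of such
#'   matrices, one per ensemble member.
#' @param include character vector of split labels to include
#'   (default `c("train", "val")`).
#' @param ancestry optional character vector of ancestry groups to keep.
#' @param subsample optional list `list(groups =, fraction =)`: among
#'   patients whose ancestry group is in `groups`, keep a random
#'   `fraction` of patients (all their images); patients outside `groups`
#'   are always kept.
#' @param seed seed for the patient-level subsample.
#' @return a [GallerySet-class].
#' @export
buildGallery <- function(cohort, embeddings, include = c("train", "val"),
                         ancestry = NULL, subsample = NULL, seed = 1L) {
    stopifnot(is(cohort, "FaceCohort"))
    if (is.matrix(embeddings)) embeddings <- list(embeddings)
    meta <- cohortMeta(cohort)
    if (!any(meta$split %in% include))
        stop(sprintf("invalid gallery: no images in requested splits (%s)",
                     paste(include, collapse = ",")))
    keep <- meta$split %in% include
    if (!is.null(ancestry))
        keep <- keep & meta$ancestry_group %in% ancestry
    sel <- meta[keep, , drop = FALSE]
    if (!is.null(subsample)) {
        stopifnot(is.list(subsample),
                  all(c("groups", "fraction") %in% names(subsample)))
        inGrp <- unique(sel$patient_id[
            sel$ancestry_group %in% subsample$groups])
        nKeep <- round(subsample$fraction * length(inGrp))
        kept <- withr::with_seed(as.integer(seed),
                                 sample(inGrp, nKeep))
        drop <- sel$patient_id %in% setdiff(inGrp, kept)
        sel <- sel[!drop, , drop = FALSE]
    }
    if (!nrow(sel))
        stop("invalid gallery: selection is empty")
    galleryFromMeta(sel, embeddings)
}

#' Assemble a gallery directly from metadata rows and embeddings
#'
#' Lower-level companion of [buildGallery()] for callers that have already
#' chosen the gallery images (e.g. the composition experiments).
#'
#' @param meta data.frame with at least `image_id`, `patient_id`,
#'   `disorder_id`, `ancestry_group`.
#' @param embeddings matrix or list of matrices keyed by image-id rownames.
#' @return a [GallerySet-class].
#' @export
galleryFromMeta <- function(meta, embeddings) {
    if (is.matrix(embeddings)) embeddings <- list(embeddings)
    ids <- meta$image_id
    emb <- lapply(embeddings, function(m) {
        miss <- setdiff(ids, rownames(m))
        if (length(miss))
            stop(sprintf("invalid gallery: no embedding for image %s",
                         miss[1L]))
        m[ids, , drop = FALSE]
    })
    gmeta <- data.frame(image_id = ids,
                        patient_id = meta$patient_id,
                        disorder_id = meta$disorder_id,
                        ancestry_group = meta$ancestry_group,
                        stringsAsFactors = FALSE)
    new("GallerySet", embeddings = emb, meta = gmeta)
}

#' Rank candidate disorders for test embeddings
#'
#' For each test image: the distance to every gallery image is the mean
#' over ensemble members of the cosine distance between the corresponding
#' embeddings; the score of a disorder aggregates the distances of its
#' gallery images (minimum by default -- nearest-image semantics -- or
#' mean); disorders are sorted by ascending score with lexicographic
#' tie-breaking on disorder id.  Every gallery disorder appears exactly
#' once in each ranking.
#'
#' @param test a numeric vector (one image), a matrix (images x dim), or a
#'   list of matrices, one per ensemble member aligned with the gallery's
#'   members.
#' @param gallery a [GallerySet-class]; the test images must not be part
#'   of it.
#' @param aggregate `"min"` (default) or `"mean"` aggregation from gallery
#'   images to a disorder score.
#' @return for a single test image, a data.frame with columns
#'   `disorder_id`, `distance` (ascending); for several, a named list of
#'   such data.frames.
#' @export
rankDisorders <- function(test, gallery, aggregate = c("min", "mean")) {
    aggregate <- match.arg(aggregate)
    stopifnot(is(gallery, "GallerySet"))
    single <- FALSE
    if (is.numeric(test) && is.null(dim(test))) {
        test <- matrix(test, nrow = 1L)
        single <- TRUE
    }
    if (is.matrix(test))
        test <- rep(list(test), length(gallery@embeddings))
    if (length(test) != length(gallery@embeddings))
        stop("test embeddings and gallery must have the same ensemble size")
    if (!nrow(gallery@meta))
        stop("invalid gallery: empty")
    overlap <- intersect(rownames(test[[1L]]), gallery@meta$image_id)
    if (length(overlap))
        stop(sprintf("test image %s is present in the gallery", overlap[1L]))

    D <- Reduce(`+`, Map(function(tm, gm) .cosineDistanceMatrix(tm, gm),
                         test, gallery@embeddings)) / length(test)
    disorders <- sort(unique(gallery@meta$disorder_id))
    scores <- matrix(NA_real_, nrow(D), length(disorders),
                     dimnames = list(rownames(test[[1L]]), disorders))
    for (j in seq_along(disorders)) {
        cols <- which(gallery@meta$disorder_id == disorders[j])
        block <- D[, cols, drop = FALSE]
        scores[, j] <- if (aggregate == "min")
            do.call(pmin, as.data.frame(block))
        else rowMeans(block)
    }
    rankings <- lapply(seq_len(nrow(scores)), function(i) {
        ord <- order(scores[i, ], disorders)
        data.frame(disorder_id = disorders[ord],
                   distance = unname(scores[i, ord]),
                   stringsAsFactors = FALSE)
    })
    names(rankings) <- rownames(test[[1L]])
    if (single) rankings[[1L]] else rankings
}

#' Is the true disorder within the first k guesses?
#'
#' @param ranking a ranking data.frame from [rankDisorders()].
#' @param trueDisorder the diagnosed disorder id.
#' @param k cutoff (>= 1).
#' @param quiet suppress the log message when the disorder is unsupported
#'   (absent from the gallery).
#' @return `TRUE` iff `trueDisorder` is among the first
#'   `min(k, nrow(ranking))` entries; an unsupported disorder yields
#'   `FALSE` (with a message), not an error.
#' @export
topKHit <- function(ranking, trueDisorder, k, quiet = FALSE) {
    if (k < 1L) stop("invalid parameter: k must be >= 1")
    if (!trueDisorder %in% ranking$disorder_id) {
        if (!quiet)
            message(sprintf("disorder %s is not supported by the gallery",
                            trueDisorder))
        return(FALSE)
    }
    trueDisorder %in% ranking$disorder_id[seq_len(min(k, nrow(ranking)))]
}

#' @export
setMethod("show", "GallerySet", function(object) {
    cat(sprintf(
        "GallerySet: %d images, %d disorders, %d ensemble member(s), dim %d\n",
        nrow(object@meta), length(unique(object@meta$disorder_id)),
        length(object@embeddings), ncol(object@embeddings[[1L]])))
})

#' @describeIn embedDim embedding width of a gallery
#' @export
setMethod("embedDim", "GallerySet", function(x)
    as.integer(ncol(x@embeddings[[1L]])))
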