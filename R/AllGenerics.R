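#' @rdname embedImages
#' @export
setGeneric("embedImages", function(encoder, x, ...)
    standardGeneric("embedImages"))

#' Embedding dimension of an encoder or ensemble
#'
#' @param x a [GestaltEncoder-class], [GestaltEnsemble-class] or
#'   [GallerySet-class].
#' @return integer embedding dimension.
#' @export
setGeneric("embedDim", function(x) standardGeneric("embedDim"))

#' Disorders covered by the classification head
#'
#' @param x a [GestaltEncoder-class] or [GestaltEnsemble-class].
#' @return sorted character vector of disorder ids the classifier was
#'   trained on.
#' @export
setGeneric("trainingDisorders", function(x)
    standardGeneric("trainingDisorders"))

#' Per-image cohort metadata as a base data.frame
#'
#' @param x a [FaceCohort-class].
#' @return data.frame with one row per image (standard cohort columns).
#' @export
setGeneric("cohortMeta", function(x) standardGeneric("cohortMeta"))

#' Raw feature matrix of a cohort
#'
#' @param x a [FaceCohort-class].
#' @param ... unused.
#' @return numeric matrix with images in rows (image ids as rownames) and
#'   raw feature dimensions in columns.
#' @export
setGeneric("rawFeatures", function(x, ...) standardGeneric("rawFeatures"))

#' Per-patient metadata table
#'
#' @param x a [FaceCohort-class].
#' @return data.frame with one row per patient.
#' @export
setGeneric("patientTable", function(x) standardGeneric("patientTable"))
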