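#' @import methods
#' @importFrom S4Vectors DataFrame metadata metadata<-
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @importFrom SummarizedExperiment SummarizedExperiment assay colData colData<-
NULL

.ANCESTRY_GROUPS <- c("European", "Asian", "African", "Others")
.ANCESTRY_LEVELS <- c(.ANCESTRY_GROUPS, "Unknown")
.SPLIT_LEVELS <- c("train", "val", "test", "none")
.SEX_LEVELS <- c("male", "female", "unknown")
.COHORT_COLUMNS <- c("patient_id", "image_id", "disorder_id", "ancestry_group",
                     "sub_ancestry", "sex", "age_years", "hpo_terms",
                     "distinctiveness", "split")

#' Parameters of the synthetic cohort simulator
#'
#' `SimulationParams` bundles every knob of the generative model for a
#' synthetic patient cohort: cohort size, the Zipf-like long tail of
#' disorder sizes, the continental ancestry mixture, demographic
#' distributions, the variance components of the raw feature model and the
#' HPO annotation process.  Construct instances with [simulationParams()].
#'
#' @slot nPatients number of patients.
#' @slot nDisorders number of distinct disorders.
#' @slot tailExponent exponent of the Zipf-like disorder size law.
#' @slot ancestryKnownProps named probabilities over the four continental
#'   groups, conditional on ancestry being known; must sum to one.
#' @slot unknownAncestryFrac probability that a patient's ancestry is
#'   recorded as `Unknown` (a true group is still drawn and drives the
#'   feature model; only the label is masked).
#' @slot imagesPerPatientMean mean number of images per patient; counts are
#'   `1 + Poisson(mean - 1)`.
#' @slot rawDim dimension of the raw per-image feature vectors.
#' @slot sigmaDisorder,sigmaAncestry,sigmaInteraction,sigmaPatient,sigmaImage
#'   standard deviations of the additive Gaussian components of the raw
#'   feature model (disorder archetype, ancestry main effect,
#'   ancestry-by-disorder interaction, patient effect, image noise).
#' @slot ageMissingFrac fraction of patients with missing age.
#' @slot hpoTermsPerDisorder number of characteristic HPO terms per disorder.
#' @slot hpoPenetrance probability that a patient carries each term of the
#'   disorder's characteristic set.
#' @slot seed integer seed making the whole simulation deterministic.
#'
#' @seealso [simulationParams()], [sampleCohort()]
#' @export
setClass("SimulationParams",
    representation(
        nPatients = "integer",
        nDisorders = "integer",
        tailExponent = "numeric",
        ancestryKnownProps = "numeric",
        unknownAncestryFrac = "numeric",
        imagesPerPatientMean = "numeric",
        rawDim = "integer",
        sigmaDisorder = "numeric",
        sigmaAncestry = "numeric",
        sigmaInteraction = "numeric",
        sigmaPatient = "numeric",
        sigmaImage = "numeric",
        ageMissingFrac = "numeric",
        hpoTermsPerDisorder = "integer",
        hpoPenetrance = "numeric",
        seed = "integer"
    ))

setValidity("SimulationParams", function(object) {
    msg <- character()
    if (object@nPatients < object@nDisorders)
        msg <- c(msg, "nPatients must be >= nDisorders")
    if (object@nDisorders < 2L)
        msg <- c(msg, "nDisorders must be >= 2")
    if (abs(sum(object@ancestryKnownProps) - 1) > 1e-9)
        msg <- c(msg, "ancestryKnownProps must sum to 1 (tolerance 1e-9)")
    if (!identical(sort(names(object@ancestryKnownProps)),
                   sort(.ANCESTRY_GROUPS)))
        msg <- c(msg, sprintf("ancestryKnownProps must be named by: %s",
                              paste(.ANCESTRY_GROUPS, collapse = ", ")))
    if (object@unknownAncestryFrac < 0 || object@unknownAncestryFrac > 1)
        msg <- c(msg, "unknownAncestryFrac must lie in [0, 1]")
    sig <- c(object@sigmaDisorder, object@sigmaAncestry,
             object@sigmaInteraction, object@sigmaPatient, object@sigmaImage)
    if (any(sig < 0))
        msg <- c(msg, "all sigma components must be >= 0")
    if (object@imagesPerPatientMean < 1)
        msg <- c(msg, "imagesPerPatientMean must be >= 1")
    if (object@ageMissingFrac < 0 || object@ageMissingFrac > 1)
        msg <- c(msg, "ageMissingFrac must lie in [0, 1]")
    if (object@hpoPenetrance < 0 || object@hpoPenetrance > 1)
        msg <- c(msg, "hpoPenetrance must lie in [0, 1]")
    if (object@rawDim < 2L)
        msg <- c(msg, "rawDim must be >= 2")
    if (length(msg)) msg else TRUE
})

#' A synthetic (or imported) patient/image cohort with raw features
#'
#' `FaceCohort` extends [SummarizedExperiment::SummarizedExperiment]: the
#' `"raw"` assay holds the per-image feature matrix (feature dimensions in
#' rows, images in columns) and `colData` holds one row per image with the
#' patient-level metadata repeated across a patient's images.  Per-image
#' columns are `image_id` and `split`; patient-level columns are
#' `patient_id`, `disorder_id`, `ancestry_group`, `sub_ancestry`, `sex`,
#' `age_years`, `hpo_terms` (semicolon-joined) and `distinctiveness`.
#'
#' The validity method enforces the cohort contract: all metadata columns
#' present, consistent patient-level attributes across a patient's images,
#' legal split labels, and patient-disjoint evaluation (no patient with
#' images in both \{train, val\} and \{test\}).
#'
#' @seealso [sampleCohort()], [splitCohort()], [readCohort()]
#' @export
setClass("FaceCohort", contains = "SummarizedExperiment")

setValidity("FaceCohort", function(object) {
    msg <- character()
    cd <- colData(object)
    missing <- setdiff(.COHORT_COLUMNS, colnames(cd))
    if (length(missing))
        return(sprintf("missing cohort columns: %s",
                       paste(missing, collapse = ", ")))
    if (!"raw" %in% names(object@assays))
        msg <- c(msg, "assay 'raw' is required")
    if (anyDuplicated(cd$image_id))
        msg <- c(msg, sprintf("duplicate image_id: %s",
                              cd$image_id[duplicated(cd$image_id)][1L]))
    if (!all(cd$split %in% .SPLIT_LEVELS))
        msg <- c(msg, "split labels must be one of train/val/test/none")
    if (!all(cd$ancestry_group %in% .ANCESTRY_LEVELS))
        msg <- c(msg, "unrecognized ancestry_group label")
    ## patient-level attributes must not vary within a patient
    for (col in c("disorder_id", "ancestry_group", "sex")) {
        nval <- tapply(as.character(cd[[col]]), cd$patient_id,
                       function(v) length(unique(v)))
        if (any(nval > 1L))
            msg <- c(msg, sprintf("column %s varies within patient %s", col,
                                  names(nval)[which(nval > 1L)][1L]))
    }
    ## patient-disjoint evaluation
    inFit <- unique(cd$patient_id[cd$split %in% c("train", "val")])
    inTest <- unique(cd$patient_id[cd$split == "test"])
    both <- intersect(inFit, inTest)
    if (length(both))
        msg <- c(msg, sprintf(
            "patient %s has images in both train/val and test", both[1L]))
    if (length(msg)) msg else TRUE
})

#' Configuration of the classifier-encoder
#'
#' Hyperparameters of the multilayer-perceptron softmax classifier whose
#' final hidden layer (of width `embedDim`) is used as the embedding
#' encoder.  Construct with [encoderConfig()].
#'
#' @slot embedDim width of the embedding (penultimate) layer.
#' @slot hiddenWidths integer vector of additional hidden layer widths
#'   before the embedding layer; may be empty.
#' @slot epochs number of training epochs (no early stopping; the
#'   validation split is used for monitoring only).
#' @slot learningRate Adam step size.
#' @slot batchSize minibatch size.
#' @slot weightDecay L2 penalty coefficient added to the gradients.
#' @slot seed seed controlling initialization and batch order.
#' @export
setClass("EncoderConfig",
    representation(
        embedDim = "integer",
        hiddenWidths = "integer",
        epochs = "integer",
        learningRate = "numeric",
        batchSize = "integer",
        weightDecay = "numeric",
        seed = "integer"
    ))

setValidity("EncoderConfig", function(object) {
    msg <- character()
    if (object@embedDim < 2L) msg <- c(msg, "embedDim must be >= 2")
    if (object@epochs < 1L) msg <- c(msg, "epochs must be >= 1")
    if (object@learningRate <= 0) msg <- c(msg, "learningRate must be > 0")
    if (object@batchSize < 1L) msg <- c(msg, "batchSize must be >= 1")
    if (object@weightDecay < 0) msg <- c(msg, "weightDecay must be >= 0")
    if (length(msg)) msg else TRUE
})

#' A trained classifier-encoder
#'
#' Holds the learned parameters of the softmax classifier, the list of
#' disorders it was trained on, its configuration and the per-epoch
#' training history.  Everything up to the penultimate (embedding) layer is
#' applied by [embedImages()]; the classification head is retained so the
#' classifier remains inspectable.
#'
#' @slot weights list of weight matrices, one per layer (hidden layers,
#'   embedding layer, classification head).
#' @slot biases list of bias vectors aligned with `weights`.
#' @slot rawDim input feature dimension.
#' @slot config the [EncoderConfig-class] used for training.
#' @slot trainingDisorders sorted character vector of disorder ids covered
#'   by the classification head.
#' @slot history data.frame with one row per epoch: `epoch`, `loss`
#'   (mean minibatch loss), `val_top1` (validation top-1 in percent, `NA`
#'   when no validation images exist).
#' @export
setClass("GestaltEncoder",
    representation(
        weights = "list",
        biases = "list",
        rawDim = "integer",
        config = "EncoderConfig",
        trainingDisorders = "character",
        history = "data.frame"
    ))

setValidity("GestaltEncoder", function(object) {
    msg <- character()
    if (length(object@weights) != length(object@biases))
        msg <- c(msg, "weights and biases must have the same length")
    if (length(object@weights) < 2L)
        msg <- c(msg, "encoder needs at least an embedding layer and a head")
    nclass <- ncol(object@weights[[length(object@weights)]])
    if (nclass != length(object@trainingDisorders))
        msg <- c(msg, "classification head must cover exactly the training disorders")
    if (length(msg)) msg else TRUE
})

#' An ensemble of classifier-encoders
#'
#' One or more [GestaltEncoder-class] objects sharing the same embedding
#' dimension.  Galleries and rankings aggregate cosine distances by
#' averaging over members.
#'
#' @slot members non-empty list of `GestaltEncoder` objects.
#' @export
setClass("GestaltEnsemble", representation(members = "list"))

setValidity("GestaltEnsemble", function(object) {
    if (!length(object@members))
        return("ensemble must contain at least one encoder")
    if (!all(vapply(object@members, is, logical(1), "GestaltEncoder")))
        return("all members must be GestaltEncoder objects")
    dims <- vapply(object@members, embedDim, integer(1))
    if (length(unique(dims)) != 1L)
        return("all members must share the same embedding dimension")
    TRUE
})

#' A gallery of embeddings with known diagnoses
#'
#' The gallery is the set of images a test embedding is matched against;
#' it defines which disorders are supported.  One embedding matrix per
#' ensemble member (rows = images, identically ordered across members)
#' plus per-image metadata.
#'
#' @slot embeddings list of numeric matrices (images x embedDim), one per
#'   ensemble member, with identical rownames (image ids).
#' @slot meta data.frame with columns `image_id`, `patient_id`,
#'   `disorder_id`, `ancestry_group` aligned with the embedding rows.
#' @export
setClass("GallerySet",
    representation(embeddings = "list", meta = "data.frame"))

setValidity("GallerySet", function(object) {
    if (!length(object@embeddings))
        return("gallery must contain at least one embedding matrix")
    ids <- rownames(object@embeddings[[1L]])
    if (is.null(ids) || !nrow(object@meta))
        return("gallery embeddings must have image-id rownames and metadata")
    for (m in object@embeddings)
        if (!identical(rownames(m), ids))
            return("all ensemble members must index the identical image set")
    if (!identical(object@meta$image_id, ids))
        return("gallery metadata must align with embedding rows")
    if (any(is.na(object@meta$disorder_id)))
        return("every gallery image needs a disorder label")
    TRUE
})

#' Expert-defined symptom groups over HPO terms
#'
#' An ordered set of symptom-group labels, each with a set of HPO term
#' identifiers.  Term sets must be pairwise disjoint.  One label is the
#' designated fallback (conventionally `"Others"`); it may have an empty
#' term set and is only ever the leading group when no other group matches.
#'
#' @slot groups ordered character vector of group labels (the order breaks
#'   ties in [leadingGroup()]).
#' @slot terms named list mapping each group label to a character vector of
#'   HPO term ids.
#' @slot fallback the fallback group label.
#' @seealso [symptomGroupDefinition()], [defaultSymptomGroups()]
#' @export
setClass("SymptomGroupDefinition",
    representation(groups = "character", terms = "list",
                   fallback = "character"))

setValidity("SymptomGroupDefinition", function(object) {
    msg <- character()
    if (!identical(sort(names(object@terms)), sort(object@groups)))
        msg <- c(msg, "terms must be named by exactly the group labels")
    if (!(object@fallback %in% object@groups))
        msg <- c(msg, "fallback label must be one of the groups")
    all_terms <- unlist(object@terms, use.names = FALSE)
    if (anyDuplicated(all_terms)) {
        dup <- all_terms[duplicated(all_terms)][1L]
        msg <- c(msg, sprintf(
            "group term sets must be pairwise disjoint (term %s appears in more than one group)",
            dup))
    }
    if (length(msg)) msg else TRUE
})
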