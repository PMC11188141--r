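#' Construct simulation parameters
#'
#' Defaults describe the study conditions of the synthetic cohort
#' generator: a long-tailed collection of disorders, the continental
#' ancestry mixture observed in large dysmorphology image collections
#' (67/19/7/7 percent European/Asian/African/Others among patients with
#' known ancestry, 16 percent unknown), roughly balanced sex, an age
#' distribution skewed below ten years with a large missing fraction, and
#' about 1.3 images per patient.  The feature model and the choice of the
#' variance-component defaults are documented in the package vignette.
#'
#' @param nPatients number of patients (default 800).
#' @param nDisorders number of disorders (default 40).
#' @param tailExponent Zipf-like exponent of the disorder size law
#'   (default 1.2).
#' @param ancestryKnownProps named probabilities for
#'   European/Asian/African/Others among known-ancestry patients.
#' @param unknownAncestryFrac fraction of patients with masked ancestry.
#' @param imagesPerPatientMean mean images per patient (default 1.3).
#' @param rawDim raw feature dimension (default 32).
#' @param sigmaDisorder,sigmaAncestry,sigmaInteraction,sigmaPatient,sigmaImage
#'   standard deviations of the additive Gaussian feature components.
#' @param ageMissingFrac fraction of patients with missing age.
#' @param hpoTermsPerDisorder characteristic HPO terms per disorder.
#' @param hpoPenetrance per-term carry probability per patient.
#' @param seed simulation seed.
#' @return a validated [SimulationParams-class] object.
#' @examples
#' params <- simulationParams(nPatients = 200, nDisorders = 10, seed = 1)
#' @export
simulationParams <- function(nPatients = 800L,
                             nDisorders = 40L,
                             tailExponent = 1.2,
                             ancestryKnownProps = c(European = 0.67,
                                                    Asian = 0.19,
                                                    African = 0.07,
                                                    Others = 0.07),
                             unknownAncestryFrac = 0.16,
                             imagesPerPatientMean = 1.3,
                             rawDim = 32L,
                             sigmaDisorder = 1.0,
                             sigmaAncestry = 1.0,
                             sigmaInteraction = 1.25,
                             sigmaPatient = 1.25,
                             sigmaImage = 0.75,
                             ageMissingFrac = 0.45,
                             hpoTermsPerDisorder = 8L,
                             hpoPenetrance = 0.7,
                             seed = 1L) {
    ancestryKnownProps <- unlist(ancestryKnownProps)  # tolerate JSON round trips
    new("SimulationParams",
        nPatients = as.integer(nPatients),
        nDisorders = as.integer(nDisorders),
        tailExponent = as.numeric(tailExponent),
        ancestryKnownProps = ancestryKnownProps,
        unknownAncestryFrac = as.numeric(unknownAncestryFrac),
        imagesPerPatientMean = as.numeric(imagesPerPatientMean),
        rawDim = as.integer(rawDim),
        sigmaDisorder = as.numeric(sigmaDisorder),
        sigmaAncestry = as.numeric(sigmaAncestry),
        sigmaInteraction = as.numeric(sigmaInteraction),
        sigmaPatient = as.numeric(sigmaPatient),
        sigmaImage = as.numeric(sigmaImage),
        ageMissingFrac = as.numeric(ageMissingFrac),
        hpoTermsPerDisorder = as.integer(hpoTermsPerDisorder),
        hpoPenetrance = as.numeric(hpoPenetrance),
        seed = as.integer(seed))
}

#' Sample long-tailed disorder sizes
#'
#' Patient counts per disorder follow a Zipf-like law: rank-`r` disorders
#' receive probability proportional to `r^-tailExponent`, every disorder is
#' guaranteed at least one patient, and counts sum to `nPatients`.  The
#' long tail makes the frequent/ultra-rare partition used by
#' [selectTrainingDisorders()] non-trivial: some disorders have many
#' patients, many have one or two.
#'
#' @param nDisorders number of disorders (>= 2).
#' @param nPatients number of patients (>= `nDisorders`).
#' @param tailExponent positive Zipf exponent.
#' @param seed integer seed; results are deterministic given the seed.
#' @return named integer vector of patient counts (names `D001`, ...).
#' @examples
#' sampleDisorderSizes(10, 100, 1.2, seed = 7)
#' @export
sampleDisorderSizes <- function(nDisorders, nPatients, tailExponent, seed) {
    nDisorders <- as.integer(nDisorders)
    nPatients <- as.integer(nPatients)
    if (nDisorders < 2L)
        stop("invalid parameter: nDisorders must be >= 2")
    if (nPatients < nDisorders)
        stop("invalid parameter: nPatients must be >= nDisorders")
    if (tailExponent <= 0)
        stop("invalid parameter: tailExponent must be > 0")
    probs <- seq_len(nDisorders)^(-tailExponent)
    probs <- probs / sum(probs)
    extra <- withr::with_seed(as.integer(seed),
        as.vector(stats::rmultinom(1L, nPatients - nDisorders, probs)))
    counts <- extra + 1L
    names(counts) <- sprintf("D%03d", seq_len(nDisorders))
    counts
}

.SUB_ANCESTRY <- list(
    European = c("Western European", "Eastern European", "Southern European"),
    Asian = c("East Asian", "South Asian", "South-East Asian",
              "Middle-East/West Asian"),
    African = c("Sub-Saharan", "North African"),
    Others = c("Latin American", "Native American", "Mixed"))

#' Simulate a synthetic patient cohort with raw image features
#'
#' Draws a full cohort under the additive Gaussian feature model.  The raw
#' feature of image `i` of patient `p` with disorder `d` and (true)
#' ancestry group `g` is
#' \deqn{x = \mu_d + a_g + b_{d,g} + u_p + \epsilon_i,}
#' where the five components are independent spherical Gaussians in
#' `rawDim` dimensions with standard deviations `sigmaDisorder`,
#' `sigmaAncestry`, `sigmaInteraction`, `sigmaPatient` and `sigmaImage`.
#' Patients whose observed ancestry is `Unknown` still draw a true known
#' group that drives their `a` and `b` components; only the label is
#' masked, mirroring missing metadata rather than a distinct population.
#'
#' Ages are drawn from a child-skewed mixture (most patients below ten
#' years, an adult tail) with a configurable missing fraction.  Each
#' disorder has a characteristic set of HPO terms, concentrated in one
#' primary symptom group; a patient carries each term independently with
#' probability `hpoPenetrance`.  All images start with split label
#' `"none"`; see [splitCohort()].
#'
#' @param params a [SimulationParams-class] object.
#' @return a [FaceCohort-class] with assay `"raw"` and full metadata.
#' @examples
#' cohort <- sampleCohort(simulationParams(nPatients = 100,
#'                                         nDisorders = 6, seed = 3))
#' cohort
#' @export
sampleCohort <- function(params) {
    stopifnot(is(params, "SimulationParams"))
    validObject(params)
    defs <- defaultSymptomGroups()
    withr::with_seed(params@seed, {
        nP <- params@nPatients
        dim <- params@rawDim
        sizes <- {
            probs <- seq_len(params@nDisorders)^(-params@tailExponent)
            probs <- probs / sum(probs)
            as.vector(stats::rmultinom(1L, nP - params@nDisorders, probs)) + 1L
        }
        disorderIds <- sprintf("D%03d", seq_len(params@nDisorders))
        patientDisorder <- rep(disorderIds, times = sizes)
        patientId <- sprintf("P%04d", seq_len(nP))

        known <- names(params@ancestryKnownProps)
        trueGroup <- sample(known, nP, replace = TRUE,
                            prob = params@ancestryKnownProps)
        masked <- stats::runif(nP) < params@unknownAncestryFrac
        obsGroup <- ifelse(masked, "Unknown", trueGroup)
        subAnc <- vapply(seq_len(nP), function(i) {
            if (masked[i]) "" else sample(.SUB_ANCESTRY[[trueGroup[i]]], 1L)
        }, character(1))

        sex <- sample(.SEX_LEVELS, nP, replace = TRUE,
                      prob = c(0.46, 0.46, 0.08))
        child <- stats::runif(nP) < 0.75
        age <- ifelse(child,
                      stats::rgamma(nP, shape = 2, scale = 2),
                      10 + stats::rexp(nP, rate = 1 / 15))
        age[stats::runif(nP) < params@ageMissingFrac] <- NA_real_
        distinct <- sample(1:3, nP, replace = TRUE, prob = c(0.25, 0.45, 0.3))

        ## characteristic HPO term sets: concentrated in a primary group
        universe <- unlist(defs@terms, use.names = FALSE)
        nonFallback <- setdiff(defs@groups, defs@fallback)
        disorderTerms <- lapply(seq_len(params@nDisorders), function(d) {
            primary <- sample(nonFallback, 1L)
            k <- params@hpoTermsPerDisorder
            kPrim <- min(ceiling(0.6 * k), length(defs@terms[[primary]]))
            prim <- sample(defs@terms[[primary]], kPrim)
            rest <- sample(setdiff(universe, prim), k - kPrim)
            c(prim, rest)
        })
        patientTerms <- vapply(seq_len(nP), function(i) {
            terms <- disorderTerms[[match(patientDisorder[i], disorderIds)]]
            keep <- terms[stats::runif(length(terms)) < params@hpoPenetrance]
            paste(sort(keep), collapse = ";")
        }, character(1))

        nImages <- 1L + stats::rpois(nP, params@imagesPerPatientMean - 1)
        imgPatientIdx <- rep(seq_len(nP), times = nImages)
        nImg <- length(imgPatientIdx)
        imageId <- sprintf("I%05d", seq_len(nImg))

        ## feature model components
        mu <- matrix(stats::rnorm(params@nDisorders * dim,
                                  sd = params@sigmaDisorder),
                     params@nDisorders, dim)
        aG <- matrix(stats::rnorm(length(known) * dim,
                                  sd = params@sigmaAncestry),
                     length(known), dim, dimnames = list(known, NULL))
        bDG <- array(stats::rnorm(params@nDisorders * length(known) * dim,
                                  sd = params@sigmaInteraction),
                     c(params@nDisorders, length(known), dim))
        uP <- matrix(stats::rnorm(nP * dim, sd = params@sigmaPatient), nP, dim)
        eps <- matrix(stats::rnorm(nImg * dim, sd = params@sigmaImage),
                      nImg, dim)

        dIdx <- match(patientDisorder, disorderIds)
        gIdx <- match(trueGroup, known)
        X <- mu[dIdx[imgPatientIdx], , drop = FALSE] +
            aG[gIdx[imgPatientIdx], , drop = FALSE] +
            matrix(bDG[cbind(rep(dIdx[imgPatientIdx], each = dim),
                             rep(gIdx[imgPatientIdx], each = dim),
                             rep(seq_len(dim), times = nImg))],
                   nImg, dim, byrow = TRUE) +
            uP[imgPatientIdx, , drop = FALSE] + eps
        dimnames(X) <- list(imageId, sprintf("F%02d", seq_len(dim)))

        meta <- DataFrame(
            patient_id = patientId[imgPatientIdx],
            image_id = imageId,
            disorder_id = patientDisorder[imgPatientIdx],
            ancestry_group = obsGroup[imgPatientIdx],
            sub_ancestry = subAnc[imgPatientIdx],
            sex = sex[imgPatientIdx],
            age_years = age[imgPatientIdx],
            hpo_terms = patientTerms[imgPatientIdx],
            distinctiveness = distinct[imgPatientIdx],
            split = rep("none", nImg),
            row.names = imageId)
        se <- SummarizedExperiment(
            assays = list(raw = t(X)),
            colData = meta)
        colnames(se) <- imageId
        rownames(se) <- sprintf("F%02d", seq_len(dim))
        new("FaceCohort", se)
    })
}

#' Assign train/val/test split labels
#'
#' Patients are partitioned so that evaluation is patient-disjoint: a
#' fraction `1 - trainFrac - valFrac` of patients (all their images) goes
#' to the test split; the remaining patients' images are divided between
#' train and val at the image level (a patient may contribute to both,
#' since the validation split is used for monitoring only).  Fails with an
#' infeasible-split error if, after splitting, no disorder retains at
#' least `minPatients` distinct patients with training images, because
#' then no classifier can be trained.
#'
#' @param cohort a [FaceCohort-class].
#' @param trainFrac,valFrac fractions in (0, 1) with
#'   `trainFrac + valFrac < 1`.
#' @param seed integer seed.
#' @param minPatients feasibility threshold (default 7, the classical
#'   "at least seven patients" rule for trainable disorders).
#' @return the cohort with updated `split` labels.
#' @export
splitCohort <- function(cohort, trainFrac = 0.7, valFrac = 0.1, seed = 1L,
                        minPatients = 7L) {
    stopifnot(is(cohort, "FaceCohort"))
    if (trainFrac <= 0 || valFrac <= 0 || trainFrac + valFrac >= 1)
        stop("invalid parameter: need trainFrac, valFrac in (0,1) with trainFrac + valFrac < 1")
    meta <- cohortMeta(cohort)
    patients <- unique(meta$patient_id)
    withr::with_seed(as.integer(seed), {
        nTest <- floor((1 - trainFrac - valFrac) * length(patients))
        testPatients <- sample(patients, nTest)
        split <- rep(NA_character_, nrow(meta))
        isTest <- meta$patient_id %in% testPatients
        split[isTest] <- "test"
        nFit <- sum(!isTest)
        pVal <- valFrac / (trainFrac + valFrac)
        split[!isTest] <- ifelse(stats::runif(nFit) < pVal, "val", "train")
    })
    trainPat <- unique(meta$patient_id[split == "train"])
    perDis <- table(unique(data.frame(
        p = meta$patient_id[split == "train"],
        d = meta$disorder_id[split == "train"]))$d)
    if (!length(perDis) || max(perDis) < minPatients)
        stop(sprintf(paste0(
            "infeasible split: no disorder retains >= %d distinct patients ",
            "in the train split (constraint: trainable disorders need at ",
            "least %d patients)"), minPatients, minPatients))
    colData(cohort)$split <- split
    validObject(cohort)
    cohort
}

## ---- FaceCohort accessors ----

#' @describeIn cohortMeta method for FaceCohort
#' @export
setMethod("cohortMeta", "FaceCohort", function(x) {
    df <- as.data.frame(colData(x))
    rownames(df) <- NULL
    df[, .COHORT_COLUMNS]
})

#' @describeIn rawFeatures method for FaceCohort
#' @export
setMethod("rawFeatures", "FaceCohort", function(x, ...) {
    t(assay(x, "raw"))
})

#' @describeIn patientTable method for FaceCohort
#' @export
setMethod("patientTable", "FaceCohort", function(x) {
    meta <- cohortMeta(x)
    first <- !duplicated(meta$patient_id)
    out <- meta[first, setdiff(.COHORT_COLUMNS, c("image_id", "split"))]
    out$n_images <- as.vector(table(meta$patient_id)[out$patient_id])
    rownames(out) <- NULL
    out
})

#' @export
setMethod("show", "FaceCohort", function(object) {
    meta <- cohortMeta(object)
    cat(sprintf("FaceCohort: %d images / %d patients / %d disorders\n",
                nrow(meta), length(unique(meta$patient_id)),
                length(unique(meta$disorder_id))))
    anc <- table(factor(meta$ancestry_group[!duplicated(meta$patient_id)],
                        levels = .ANCESTRY_LEVELS))
    cat("  ancestry (patients):",
        paste(sprintf("%s=%d", names(anc), anc), collapse = " "), "\n")
    spl <- table(factor(meta$split, levels = .SPLIT_LEVELS))
    cat("  splits (images):",
        paste(sprintf("%s=%d", names(spl), spl), collapse = " "), "\n")
    cat(sprintf("  raw feature dim: %d\n", nrow(object)))
})

#' @export
setMethod("show", "SimulationParams", function(object) {
    cat(sprintf("SimulationParams: %d patients, %d disorders, rawDim=%d, seed=%d\n",
                object@nPatients, object@nDisorders, object@rawDim,
                object@seed))
    cat(sprintf("  sigmas (disorder/ancestry/interaction/patient/image): %s\n",
                paste(c(object@sigmaDisorder, object@sigmaAncestry,
                        object@sigmaInteraction, object@sigmaPatient,
                        object@sigmaImage), collapse = "/")))
})
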