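#' Specification of the training-composition experiment
#'
#' A base subset of European images (EU) is extended either by more
#' European images (EU*) or by an equally sized subset of non-European
#' images (non-EU); one encoder is trained per condition and both are
#' evaluated on a shared multi-ancestry evaluation set via each
#' condition's own gallery.  Default sizes scale the full-cohort protocol
#' down by roughly a factor of ten while preserving the size ratios
#' (EU about twice the extension subsets); the ratios, the matched
#' extension sizes and the disorder-distribution matching are what the
#' protocol fixes.
#'
#' @param sizeEU target image count of the EU base subset (default 320).
#' @param sizeExt target image count of EU* and of non-EU (matched;
#'   default 160).
#' @param evalSize target image count of the shared evaluation set
#'   (default 160).
#' @param nRepeats number of independent subset samplings (default 5).
#' @param masterSeed master seed for the experiment.
#' @return a list with class `"TrainingCompositionSpec"`.
#' @export
trainingCompositionSpec <- function(sizeEU = 320L, sizeExt = 160L,
                                    evalSize = 160L, nRepeats = 5L,
                                    masterSeed = 1L) {
    stopifnot(sizeEU > 0, sizeExt > 0, evalSize > 0, nRepeats >= 1)
    structure(list(sizeEU = as.integer(sizeEU),
                   sizeExt = as.integer(sizeExt),
                   evalSize = as.integer(evalSize),
                   nRepeats = as.integer(nRepeats),
                   masterSeed = as.integer(masterSeed)),
              class = "TrainingCompositionSpec")
}

## largest-remainder apportionment of `total` over quotas `props`
.largestRemainder <- function(props, total) {
    raw <- props / sum(props) * total
    base <- floor(raw)
    rem <- raw - base
    short <- total - sum(base)
    if (short > 0) {
        ord <- order(rem, decreasing = TRUE)
        base[ord[seq_len(short)]] <- base[ord[seq_len(short)]] + 1
    }
    as.integer(base)
}

## greedily add whole patients of one disorder until the image quota is met
.fillQuota <- function(pool, quota) {
    sel <- character(0)
    got <- 0L
    for (i in seq_len(nrow(pool))) {
        if (got >= quota) break
        sel <- c(sel, pool$patient_id[i])
        got <- got + pool$n_images[i]
    }
    list(patients = sel, images = got)
}

#' Build the four patient-disjoint subsets of one repeat
#'
#' Draws EU, EU*, non-EU and the evaluation set as mutually
#' patient-disjoint image sets.  EU* and non-EU match the disorder
#' distribution of EU as closely as availability permits: per-disorder
#' image quotas are computed by largest-remainder apportionment of the EU
#' distribution and filled with whole patients; a disorder with no
#' available patients gets quota zero and the shortfall is redistributed
#' over disorders that still have patients (reported via a warning).
#' The evaluation set spans multiple ancestries and only disorders
#' present in EU (so both conditions' galleries support them).
#'
#' @param cohort a [FaceCohort-class] (split labels are ignored: the
#'   experiment defines its own partitions).
#' @param spec a [trainingCompositionSpec()].
#' @param repeatSeed seed for this repeat's sampling.
#' @return list with character vectors of image ids (`EU`, `EUstar`,
#'   `nonEU`, `evalSet`), the per-set patient ids, and a
#'   `realized` data.frame of requested vs realized image counts.
#' @export
buildTrainingCompositionSubsets <- function(cohort, spec, repeatSeed = 1L) {
    stopifnot(inherits(spec, "TrainingCompositionSpec"))
    meta <- cohortMeta(cohort)
    pat <- patientTable(cohort)
    withr::with_seed(as.integer(repeatSeed), {
        euPool <- pat[pat$ancestry_group == "European", , drop = FALSE]
        nonEuPool <- pat[pat$ancestry_group %in%
                         c("Asian", "African", "Others"), , drop = FALSE]
        if (!nrow(euPool) || !nrow(nonEuPool))
            stop("cohort lacks European or non-European patients")
        euPool <- euPool[sample.int(nrow(euPool)), , drop = FALSE]

        ## EU base: whole patients until the image target is reached
        cum <- cumsum(euPool$n_images)
        nEU <- which(cum >= spec$sizeEU)[1L]
        if (is.na(nEU)) nEU <- nrow(euPool)
        euPat <- euPool$patient_id[seq_len(nEU)]
        euDis <- euPool$disorder_id[seq_len(nEU)]
        euImgCount <- tapply(euPool$n_images[seq_len(nEU)], euDis, sum)
        disorders <- names(euImgCount)

        quotas <- .largestRemainder(as.numeric(euImgCount), spec$sizeExt)
        names(quotas) <- disorders

        drawExt <- function(pool, label) {
            pool <- pool[pool$disorder_id %in% disorders, , drop = FALSE]
            pool <- pool[sample.int(max(nrow(pool), 1L))[seq_len(nrow(pool))],
                         , drop = FALSE]
            selected <- character(0)
            realized <- setNames(integer(length(disorders)), disorders)
            for (d in disorders) {
                sub <- pool[pool$disorder_id == d, , drop = FALSE]
                got <- .fillQuota(sub, quotas[[d]])
                selected <- c(selected, got$patients)
                realized[d] <- got$images
            }
            shortfall <- spec$sizeExt - sum(realized)
            if (shortfall > 0) {
                left <- pool[!pool$patient_id %in% selected, , drop = FALSE]
                got <- .fillQuota(left, shortfall)
                selected <- c(selected, got$patients)
                if (got$images < shortfall)
                    warning(sprintf(
                        "%s subset: realized %d of %d requested images (pool exhausted)",
                        label, sum(realized) + got$images, spec$sizeExt))
                else
                    warning(sprintf(
                        "%s subset: per-disorder quotas infeasible, %d images redistributed",
                        label, shortfall))
            }
            selected
        }
        euStarPat <- drawExt(
            euPool[!euPool$patient_id %in% euPat, , drop = FALSE], "EU*")
        nonEuPat <- drawExt(nonEuPool, "non-EU")

        used <- c(euPat, euStarPat, nonEuPat)
        evalPool <- pat[!pat$patient_id %in% used &
                        pat$ancestry_group != "Unknown" &
                        pat$disorder_id %in% disorders, , drop = FALSE]
        if (!nrow(evalPool))
            stop("evaluation set would be empty")
        evalPool <- evalPool[sample.int(nrow(evalPool)), , drop = FALSE]
        cumE <- cumsum(evalPool$n_images)
        nEv <- which(cumE >= spec$evalSize)[1L]
        if (is.na(nEv)) nEv <- nrow(evalPool)
        evalPat <- evalPool$patient_id[seq_len(nEv)]

        imgsOf <- function(p) meta$image_id[meta$patient_id %in% p]
        sets <- list(EU = imgsOf(euPat), EUstar = imgsOf(euStarPat),
                     nonEU = imgsOf(nonEuPat), evalSet = imgsOf(evalPat))
        realized <- data.frame(
            set = names(sets),
            requested = c(spec$sizeEU, spec$sizeExt, spec$sizeExt,
                          spec$evalSize),
            realized = vapply(sets, length, integer(1)))
        rownames(realized) <- NULL
        c(sets, list(patients = list(EU = euPat, EUstar = euStarPat,
                                     nonEU = nonEuPat, evalSet = evalPat),
                     realized = realized))
    })
}

## subset the cohort to given image ids and mark them all as "train"
.asTrainingCohort <- function(cohort, imageIds) {
    sub <- cohort[, imageIds]
    colData(sub)$split <- rep("train", length(imageIds))
    sub
}

#' Run the training-composition experiment
#'
#' For each repeat: draw the four subsets, train one encoder on EU + EU*
#' and one on EU + non-EU (same configuration, seeds drawn from the same
#' master-seed stream), then evaluate both on the shared evaluation set.
#' Each condition is matched against its own training images as gallery,
#' so both the encoder and the gallery reflect the condition's ancestry
#' composition.  Reports per-ancestry and ancestry-averaged top-1/top-5
#' per repeat, plus across-repeat mean and SD.
#'
#' @param cohort a [FaceCohort-class].
#' @param spec a [trainingCompositionSpec()].
#' @param config an [EncoderConfig-class] shared by both conditions.
#' @param minPatients trainable-disorder threshold within a condition
#'   subset; default 7.
#' @param kList cutoffs (top-1 and top-5 by default).
#' @return list with `perRepeat` (long data.frame: repeat, condition,
#'   group, n, top_k columns) and `summary` (mean and sd across repeats).
#' @export
runTrainingCompositionExperiment <- function(cohort, spec,
                                             config = encoderConfig(
                                                 embedDim = 32L),
                                             minPatients = 7L,
                                             kList = c(1L, 5L)) {
    stopifnot(inherits(spec, "TrainingCompositionSpec"))
    meta <- cohortMeta(cohort)
    kCols <- sprintf("top_%d", sort(kList))
    perRepeat <- list()
    for (r in seq_len(spec$nRepeats)) {
        subs <- buildTrainingCompositionSubsets(
            cohort, spec, deriveSeed(spec$masterSeed, sprintf("subset:%d", r)))
        conditions <- list(eu_only = c(subs$EU, subs$EUstar),
                           diverse = c(subs$EU, subs$nonEU))
        evalMeta <- meta[match(subs$evalSet, meta$image_id), , drop = FALSE]
        for (cond in names(conditions)) {
            condCohort <- .asTrainingCohort(cohort, conditions[[cond]])
            cfg <- config
            cfg@seed <- deriveSeed(spec$masterSeed,
                                   sprintf("train:%d:%s", r, cond))
            enc <- trainEncoder(condCohort, cfg, minPatients = minPatients)
            gal <- galleryFromMeta(cohortMeta(condCohort),
                                   embedImages(enc, condCohort))
            evalFeats <- rawFeatures(cohort)[subs$evalSet, , drop = FALSE]
            rk <- rankDisorders(embedImages(enc, evalFeats), gal)
            res <- evaluateRankings(evalMeta, rk, kList)
            groups <- intersect(.ANCESTRY_GROUPS,
                                unique(res$ancestry_group))
            rows <- lapply(groups, function(g) {
                idx <- res$ancestry_group == g
                acc <- vapply(sort(kList), function(k)
                    100 * mean(res[[sprintf("hit_%d", k)]][idx]), numeric(1))
                data.frame(rep = r, condition = cond, group = g,
                           n = sum(idx), t(acc))
            })
            avg <- vapply(sort(kList), function(k)
                ancestryAveragedTopK(res, k), numeric(1))
            rows[[length(rows) + 1L]] <-
                data.frame(rep = r, condition = cond, group = "Averaged",
                           n = nrow(res), t(avg))
            block <- do.call(rbind, rows)
            colnames(block) <- c("rep", "condition", "group", "n", kCols)
            perRepeat[[length(perRepeat) + 1L]] <- block
        }
    }
    perRepeat <- do.call(rbind, perRepeat)
    agg <- function(fun, suffix) {
        out <- stats::aggregate(perRepeat[, kCols, drop = FALSE],
                                by = perRepeat[, c("condition", "group")],
                                FUN = fun)
        colnames(out) <- c("condition", "group",
                           paste0(kCols, suffix))
        out
    }
    summ <- merge(agg(mean, "_mean"),
                  agg(stats::sd, "_sd"), by = c("condition", "group"))
    list(perRepeat = perRepeat, summary = summ)
}

#' Specification of the gallery-composition sweep
#'
#' @param proportions sorted proportions of non-European train/val
#'   patients to include in the gallery (default 0 to 1 in steps of 0.1).
#' @param nRepeats number of repeats of the random patient sampling
#'   (default 10).
#' @param masterSeed master seed.
#' @return a list with class `"GallerySweepSpec"`.
#' @export
gallerySweepSpec <- function(proportions = seq(0, 1, by = 0.1),
                             nRepeats = 10L, masterSeed = 1L) {
    stopifnot(all(proportions >= 0), all(proportions <= 1),
              !is.unsorted(proportions), nRepeats >= 1)
    structure(list(proportions = proportions,
                   nRepeats = as.integer(nRepeats),
                   masterSeed = as.integer(masterSeed)),
              class = "GallerySweepSpec")
}

#' Run the gallery-composition sweep
#'
#' With a fixed trained encoder (ensemble), the gallery starts from all
#' European train/val images and is extended by a growing random fraction
#' of non-European train/val patients (a selected patient contributes all
#' of their images).  Sampling is nested within a repeat: the patients
#' included at proportion p are a subset of those included at any larger
#' proportion, giving smooth curves.  Evaluation is restricted to test
#' images of disorders the encoder saw during training.  Per-ancestry
#' top-1 accuracy is accumulated as mean and SD across repeats.
#'
#' @param cohort a split [FaceCohort-class].
#' @param ensemble a trained [GestaltEnsemble-class] (or single encoder).
#' @param spec a [gallerySweepSpec()].
#' @param k cutoff for the reported accuracy (default 1).
#' @return list with `perRepeat` (data.frame: rep, proportion, group, n,
#'   accuracy, gallery_size) and `summary` (mean and sd by group and
#'   proportion).
#' @export
runGallerySweep <- function(cohort, ensemble, spec = gallerySweepSpec(),
                            k = 1L) {
    stopifnot(inherits(spec, "GallerySweepSpec"))
    if (is(ensemble, "GestaltEncoder"))
        ensemble <- new("GestaltEnsemble", members = list(ensemble))
    meta <- cohortMeta(cohort)
    seen <- trainingDisorders(ensemble)
    testMeta <- meta[meta$split == "test" & meta$disorder_id %in% seen, ,
                     drop = FALSE]
    if (!nrow(testMeta)) stop("no test images of training-seen disorders")
    fitMeta <- meta[meta$split %in% c("train", "val"), , drop = FALSE]
    euMeta <- fitMeta[fitMeta$ancestry_group == "European", , drop = FALSE]
    nonEuMeta <- fitMeta[fitMeta$ancestry_group %in%
                         c("Asian", "African", "Others"), , drop = FALSE]
    nonEuPatients <- unique(nonEuMeta$patient_id)

    feats <- rawFeatures(cohort)
    fitEmb <- embedImages(ensemble, feats[fitMeta$image_id, , drop = FALSE])
    testEmb <- embedImages(ensemble,
                           feats[testMeta$image_id, , drop = FALSE])
    hitCol <- sprintf("hit_%d", k)
    perRepeat <- list()
    for (r in seq_len(spec$nRepeats)) {
        perm <- withr::with_seed(
            deriveSeed(spec$masterSeed, sprintf("sweep:%d", r)),
            sample(nonEuPatients))
        for (p in spec$proportions) {
            selPat <- perm[seq_len(round(p * length(perm)))]
            galMeta <- rbind(euMeta,
                             nonEuMeta[nonEuMeta$patient_id %in% selPat, ,
                                       drop = FALSE])
            gal <- galleryFromMeta(galMeta, fitEmb)
            rk <- rankDisorders(testEmb, gal)
            res <- evaluateRankings(testMeta, rk, k)
            groups <- intersect(.ANCESTRY_LEVELS,
                                unique(res$ancestry_group))
            rows <- lapply(groups, function(g) {
                idx <- res$ancestry_group == g
                data.frame(rep = r, proportion = p, group = g,
                           n = sum(idx),
                           accuracy = 100 * mean(res[[hitCol]][idx]),
                           gallery_size = nrow(galMeta))
            })
            perRepeat[[length(perRepeat) + 1L]] <- do.call(rbind, rows)
        }
    }
    perRepeat <- do.call(rbind, perRepeat)
    summ <- merge(
        stats::aggregate(accuracy ~ group + proportion, perRepeat, mean),
        stats::aggregate(accuracy ~ group + proportion, perRepeat,
                         stats::sd),
        by = c("group", "proportion"),
        suffixes = c("_mean", "_sd"))
    list(perRepeat = perRepeat, summary = summ)
}
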