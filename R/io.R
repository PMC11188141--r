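#' Write / read a cohort as tab-separated text
#'
#' The cohort travels as two diff-able files: a metadata table with one
#' row per image (columns exactly `patient_id, image_id, disorder_id,
#' ancestry_group, sub_ancestry, sex, age_years, hpo_terms,
#' distinctiveness, split`; missing values as empty fields; `hpo_terms`
#' semicolon-joined) and a numeric feature table whose first column is
#' `image_id`.  Numbers are written with 9 significant digits, so a
#' write/read round trip is the identity up to that precision.
#'
#' @param cohort a [FaceCohort-class].
#' @param metaPath,featuresPath output file paths.
#' @return the two paths, invisibly.
#' @export
writeCohort <- function(cohort, metaPath, featuresPath) {
    .writeTSV(cohortMeta(cohort), metaPath)
    writeFeatureMatrix(rawFeatures(cohort), featuresPath)
    invisible(c(metaPath, featuresPath))
}

#' @rdname writeCohort
#' @export
readCohort <- function(metaPath, featuresPath) {
    meta <- .readTSV(metaPath)
    missing <- setdiff(.COHORT_COLUMNS, colnames(meta))
    if (length(missing))
        stop(sprintf("schema error in %s: missing column(s) %s",
                     metaPath, paste(missing, collapse = ", ")))
    dup <- meta$image_id[duplicated(meta$image_id)]
    if (length(dup))
        stop(sprintf("schema error in %s: duplicate image_id %s",
                     metaPath, dup[1L]))
    feats <- readFeatureMatrix(featuresPath)
    dangling <- setdiff(meta$image_id, rownames(feats))
    if (length(dangling))
        stop(sprintf(
            "referential-integrity error: image %s has no feature row",
            dangling[1L]))
    orphan <- setdiff(rownames(feats), meta$image_id)
    if (length(orphan))
        stop(sprintf(
            "referential-integrity error: feature row %s has no metadata",
            orphan[1L]))
    feats <- feats[meta$image_id, , drop = FALSE]
    meta$age_years <- suppressWarnings(as.numeric(
        ifelse(nzchar(meta$age_years), meta$age_years, NA)))
    meta$distinctiveness <- suppressWarnings(as.integer(
        ifelse(nzchar(meta$distinctiveness), meta$distinctiveness, NA)))
    cd <- DataFrame(meta, row.names = meta$image_id)
    se <- SummarizedExperiment(assays = list(raw = t(feats)),
                               colData = cd)
    colnames(se) <- meta$image_id
    rownames(se) <- colnames(feats)
    new("FaceCohort", se)
}

#' Write / read a numeric matrix keyed by image id
#'
#' Tab-separated with a header; first column `image_id`, remaining
#' columns the numeric dimensions.  Used for raw features and embeddings.
#'
#' @param mat numeric matrix with image ids as rownames.
#' @param path file path.
#' @return the path (writer) or the matrix (reader).
#' @export
writeFeatureMatrix <- function(mat, path) {
    df <- data.frame(image_id = rownames(mat), mat, check.names = FALSE)
    colnames(df) <- c("image_id",
                      if (!is.null(colnames(mat))) colnames(mat)
                      else sprintf("F%02d", seq_len(ncol(mat))))
    .writeTSV(df, path)
}

#' @rdname writeFeatureMatrix
#' @export
readFeatureMatrix <- function(path) {
    df <- .readTSV(path)
    if (colnames(df)[1L] != "image_id")
        stop(sprintf("schema error in %s: first column must be image_id",
                     path))
    dup <- df$image_id[duplicated(df$image_id)]
    if (length(dup))
        stop(sprintf("schema error in %s: duplicate image_id %s",
                     path, dup[1L]))
    mat <- as.matrix(df[, -1L, drop = FALSE])
    storage.mode(mat) <- "double"
    rownames(mat) <- df$image_id
    mat
}

#' Persist / restore a trained encoder
#'
#' Structured JSON bundling the parameter arrays, configuration,
#' training-disorder list and training history.
#'
#' @param encoder a [GestaltEncoder-class].
#' @param path file path.
#' @return the path (writer) or the encoder (reader).
#' @export
writeEncoder <- function(encoder, path) {
    cfg <- encoder@config
    obj <- list(
        raw_dim = encoder@rawDim,
        config = list(embed_dim = cfg@embedDim,
                      hidden_widths = cfg@hiddenWidths,
                      epochs = cfg@epochs,
                      learning_rate = cfg@learningRate,
                      batch_size = cfg@batchSize,
                      weight_decay = cfg@weightDecay,
                      seed = cfg@seed),
        training_disorders = encoder@trainingDisorders,
        history = encoder@history,
        weights = lapply(encoder@weights, function(w)
            list(dim = dim(w), values = as.vector(w))),
        biases = encoder@biases)
    writeLines(jsonlite::toJSON(obj, digits = NA, auto_unbox = TRUE), path)
    invisible(path)
}

#' @rdname writeEncoder
#' @export
readEncoder <- function(path) {
    obj <- jsonlite::fromJSON(path, simplifyVector = TRUE)
    cfg <- encoderConfig(embedDim = obj$config$embed_dim,
                         hiddenWidths = obj$config$hidden_widths,
                         epochs = obj$config$epochs,
                         learningRate = obj$config$learning_rate,
                         batchSize = obj$config$batch_size,
                         weightDecay = obj$config$weight_decay,
                         seed = obj$config$seed)
    weights <- lapply(seq_len(nrow(obj$weights)), function(i)
        matrix(obj$weights$values[[i]], obj$weights$dim[[i]][1L],
               obj$weights$dim[[i]][2L]))
    new("GestaltEncoder",
        weights = weights,
        biases = lapply(obj$biases, as.numeric),
        rawDim = as.integer(obj$raw_dim),
        config = cfg,
        trainingDisorders = as.character(obj$training_disorders),
        history = as.data.frame(obj$history))
}

.STAGES <- c("simulate", "split", "train", "embed", "match", "evaluate",
             "exp-training", "exp-gallery", "hpo-groups")

.cohortPaths <- function(dir) {
    c(meta = file.path(dir, "cohort.tsv"),
      features = file.path(dir, "features.tsv"))
}

.readStageCohort <- function(dir) {
    p <- .cohortPaths(dir)
    for (f in p)
        if (!file.exists(f))
            stop(sprintf("missing input: %s (run the producing stage first)",
                         f))
    readCohort(p[["meta"]], p[["features"]])
}

.encoderConfigFromList <- function(cfg) {
    do.call(encoderConfig, cfg[intersect(names(cfg),
        c("embedDim", "hiddenWidths", "epochs", "learningRate",
          "batchSize", "weightDecay", "seed"))])
}

.readStageEncoders <- function(dir) {
    files <- sort(list.files(dir, pattern = "^encoder_\\d+\\.json$",
                             full.names = TRUE))
    if (!length(files))
        stop(sprintf("missing input: no encoder_*.json in %s (run train first)",
                     dir))
    new("GestaltEnsemble", members = lapply(files, readEncoder))
}

.readStageEmbeddings <- function(dir) {
    files <- sort(list.files(dir, pattern = "^embeddings_\\d+\\.tsv$",
                             full.names = TRUE))
    if (!length(files))
        stop(sprintf("missing input: no embeddings_*.tsv in %s (run embed first)",
                     dir))
    lapply(files, readFeatureMatrix)
}

#' Run one pipeline stage with a manifest
#'
#' File-level pipeline interface: each stage reads its declared inputs
#' from `inDir`, writes its outputs plus a run manifest into `outDir`, and
#' never mutates its inputs.  The manifest records the stage, a snapshot
#' of the configuration, input file checksums and the package version --
#' enough to reproduce the run bit for bit via [rerunFromManifest()].
#'
#' Stages and their configuration entries:
#' \describe{
#'   \item{simulate}{[simulationParams()] arguments; writes `cohort.tsv`,
#'     `features.tsv`.}
#'   \item{split}{`trainFrac`, `valFrac`, `seed`, `minPatients`; rewrites
#'     the cohort with split labels.}
#'   \item{train}{`encoder` (list of [encoderConfig()] arguments),
#'     `nModels`, `seeds`, `minPatients`; writes `encoder_<i>.json`.}
#'   \item{embed}{writes `embeddings_<i>.tsv` for all cohort images.}
#'   \item{match}{`include` (gallery splits), `aggregate`; writes
#'     `rankings.tsv` (long table image_id, rank, disorder_id, distance).}
#'   \item{evaluate}{`kList`; writes `results.tsv`, `topk_table.tsv`.}
#'   \item{exp-training}{[trainingCompositionSpec()] arguments under
#'     `spec`, plus `encoder`; writes per-repeat and summary tables.}
#'   \item{exp-gallery}{[gallerySweepSpec()] arguments under `spec`;
#'     writes per-repeat and summary tables.}
#'   \item{hpo-groups}{optional `defsPath`; writes `hpo_assignments.tsv`,
#'     `hpo_cooccurrence.tsv`.}
#' }
#'
#' @param stage one of the stage names above.
#' @param config named list of stage configuration (see above).
#' @param inDir directory with the stage's inputs (not needed for
#'   `simulate`).
#' @param outDir output directory (created if necessary).
#' @return the manifest path, invisibly.
#' @export
runStage <- function(stage, config = list(), inDir = NULL, outDir) {
    stage <- match.arg(stage, .STAGES)
    dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
    outputs <- switch(stage,
        "simulate" = {
            params <- do.call(simulationParams, config)
            cohort <- sampleCohort(params)
            p <- .cohortPaths(outDir)
            writeCohort(cohort, p[["meta"]], p[["features"]])
            p
        },
        "split" = {
            cohort <- .readStageCohort(inDir)
            cohort <- splitCohort(cohort,
                trainFrac = config$trainFrac %||% 0.7,
                valFrac = config$valFrac %||% 0.1,
                seed = config$seed %||% 1L,
                minPatients = config$minPatients %||% 7L)
            p <- .cohortPaths(outDir)
            writeCohort(cohort, p[["meta"]], p[["features"]])
            p
        },
        "train" = {
            cohort <- .readStageCohort(inDir)
            cfg <- .encoderConfigFromList(config$encoder %||% list())
            nModels <- config$nModels %||% 1L
            seeds <- config$seeds %||% seq_len(nModels)
            ens <- trainEnsemble(cohort, cfg, nModels = nModels,
                                 seeds = seeds,
                                 minPatients = config$minPatients %||% 7L)
            paths <- vapply(seq_along(ens@members), function(i) {
                f <- file.path(outDir, sprintf("encoder_%d.json", i))
                writeEncoder(ens@members[[i]], f)
                f
            }, character(1))
            paths
        },
        "embed" = {
            cohort <- .readStageCohort(inDir)
            ens <- .readStageEncoders(inDir)
            emb <- embedImages(ens, cohort)
            vapply(seq_along(emb), function(i) {
                f <- file.path(outDir, sprintf("embeddings_%d.tsv", i))
                writeFeatureMatrix(emb[[i]], f)
                f
            }, character(1))
        },
        "match" = {
            cohort <- .readStageCohort(inDir)
            emb <- .readStageEmbeddings(inDir)
            gal <- buildGallery(cohort, emb,
                include = config$include %||% c("train", "val"))
            meta <- cohortMeta(cohort)
            testIds <- meta$image_id[meta$split == "test"]
            if (!length(testIds)) stop("missing input: no test split")
            testEmb <- lapply(emb, function(m)
                m[testIds, , drop = FALSE])
            rk <- rankDisorders(testEmb, gal,
                                aggregate = config$aggregate %||% "min")
            long <- do.call(rbind, lapply(names(rk), function(id)
                data.frame(image_id = id,
                           rank = seq_len(nrow(rk[[id]])),
                           rk[[id]])))
            f <- file.path(outDir, "rankings.tsv")
            .writeTSV(long, f)
            f
        },
        "evaluate" = {
            cohort <- .readStageCohort(inDir)
            rkPath <- file.path(inDir, "rankings.tsv")
            if (!file.exists(rkPath))
                stop(sprintf("missing input: %s (run match first)", rkPath))
            long <- .readTSV(rkPath)
            long$distance <- as.numeric(long$distance)
            rk <- split(long[, c("disorder_id", "distance")],
                        long$image_id)
            meta <- cohortMeta(cohort)
            testMeta <- meta[meta$image_id %in% names(rk), , drop = FALSE]
            kList <- as.integer(config$kList %||% c(1L, 5L, 10L, 30L))
            res <- evaluateRankings(testMeta, rk, kList)
            tab <- topKTable(res, kList)
            f1 <- file.path(outDir, "results.tsv")
            f2 <- file.path(outDir, "topk_table.tsv")
            .writeTSV(res, f1)
            .writeTSV(tab, f2)
            c(f1, f2)
        },
        "exp-training" = {
            cohort <- .readStageCohort(inDir)
            spec <- do.call(trainingCompositionSpec, config$spec %||% list())
            cfg <- .encoderConfigFromList(
                config$encoder %||% list(embedDim = 32L))
            out <- runTrainingCompositionExperiment(cohort, spec, cfg)
            f1 <- file.path(outDir, "training_composition_repeats.tsv")
            f2 <- file.path(outDir, "training_composition_summary.tsv")
            .writeTSV(out$perRepeat, f1)
            .writeTSV(out$summary, f2)
            c(f1, f2)
        },
        "exp-gallery" = {
            cohort <- .readStageCohort(inDir)
            ens <- .readStageEncoders(inDir)
            spec <- do.call(gallerySweepSpec, config$spec %||% list())
            out <- runGallerySweep(cohort, ens, spec)
            f1 <- file.path(outDir, "gallery_sweep_repeats.tsv")
            f2 <- file.path(outDir, "gallery_sweep_summary.tsv")
            .writeTSV(out$perRepeat, f1)
            .writeTSV(out$summary, f2)
            c(f1, f2)
        },
        "hpo-groups" = {
            cohort <- .readStageCohort(inDir)
            defs <- if (!is.null(config$defsPath))
                readSymptomGroupDefinition(config$defsPath)
            else defaultSymptomGroups()
            out <- cohortSymptomGroups(cohort, defs)
            f1 <- file.path(outDir, "hpo_assignments.tsv")
            f2 <- file.path(outDir, "hpo_cooccurrence.tsv")
            .writeTSV(out$assignments, f1)
            co <- data.frame(group = rownames(out$cooccurrence),
                             out$cooccurrence, check.names = FALSE)
            .writeTSV(co, f2)
            c(f1, f2)
        })
    manifest <- list(
        stage = stage,
        timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
        package_version = as.character(utils::packageVersion("gestaltR")),
        config = config,
        in_dir = if (is.null(inDir)) NULL else normalizePath(inDir),
        input_md5 = if (is.null(inDir)) NULL else {
            ins <- list.files(inDir, full.names = TRUE,
                              pattern = "\\.(tsv|json)$")
            ins <- ins[!grepl("^manifest_", basename(ins))]
            as.list(tools::md5sum(ins))
        },
        outputs = as.list(unname(outputs)))
    mf <- file.path(outDir, sprintf("manifest_%s.json", stage))
    writeLines(jsonlite::toJSON(manifest, digits = NA, auto_unbox = TRUE,
                                null = "null", pretty = TRUE), mf)
    invisible(mf)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Re-run a stage from its manifest
#'
#' Reads a manifest written by [runStage()] and re-executes the stage
#' with the recorded configuration and input directory.  Because every
#' stochastic stage derives its randomness from recorded seeds, the
#' regenerated outputs are byte-identical to the originals.
#'
#' @param manifestPath path to a `manifest_<stage>.json` file.
#' @param outDir output directory for the re-run.
#' @return the new manifest path, invisibly.
#' @export
rerunFromManifest <- function(manifestPath, outDir) {
    m <- jsonlite::fromJSON(manifestPath, simplifyVector = TRUE)
    cfg <- m$config
    ## fromJSON turns scalar-lists back into lists/vectors; that is fine
    ## because runStage only indexes by name
    runStage(m$stage, config = as.list(cfg),
             inDir = m$in_dir, outDir = outDir)
}
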