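#' Construct an encoder configuration
#'
#' @param embedDim embedding (penultimate layer) width; default 512, the
#'   conventional clinical-face-phenotype-space dimension.  Desk-scale
#'   analyses typically use a width comparable to the raw feature
#'   dimension.
#' @param hiddenWidths integer vector of hidden layer widths before the
#'   embedding layer; empty for a single affine embedding layer.
#' @param epochs training epochs (default 50; no early stopping).
#' @param learningRate Adam step size (default 1e-3).
#' @param batchSize minibatch size (default 32).
#' @param weightDecay L2 penalty (default 0).
#' @param seed training seed.
#' @return a validated [EncoderConfig-class].
#' @export
encoderConfig <- function(embedDim = 512L, hiddenWidths = integer(0),
                          epochs = 50L, learningRate = 1e-3,
                          batchSize = 32L, weightDecay = 0, seed = 1L) {
    new("EncoderConfig",
        embedDim = as.integer(embedDim),
        hiddenWidths = as.integer(hiddenWidths),
        epochs = as.integer(epochs),
        learningRate = as.numeric(learningRate),
        batchSize = as.integer(batchSize),
        weightDecay = as.numeric(weightDecay),
        seed = as.integer(seed))
}

#' Select the disorders eligible for classifier training
#'
#' A disorder enters classifier training only if it has at least
#' `minPatients` distinct patients with images in the train split -- the
#' "at least seven patients" rule separating frequent (seen) from
#' ultra-rare (unseen) disorders.  Unseen disorders remain reachable
#' through the gallery at matching time.
#'
#' @param cohort a split [FaceCohort-class].
#' @param minPatients patient threshold (default 7).
#' @return sorted character vector of disorder ids (possibly empty).
#' @export
selectTrainingDisorders <- function(cohort, minPatients = 7L) {
    meta <- cohortMeta(cohort)
    if (!nrow(meta)) stop("cohort is empty")
    tr <- meta[meta$split == "train", c("patient_id", "disorder_id")]
    if (!nrow(tr)) return(character(0))
    counts <- table(unique(tr)$disorder_id)
    sort(names(counts)[counts >= minPatients])
}

#' Inverse-frequency class weights
#'
#' Weight of class `c` is proportional to `1 / n_c`, rescaled so the
#' unweighted mean over classes equals one; rare classes thus contribute
#' as much total loss as frequent ones without changing the loss scale.
#'
#' @param labels vector of class labels (one per training sample).
#' @return named numeric vector of weights with mean exactly 1.
#' @examples
#' computeClassWeights(c("A", "A", "B", "B", "B", "B", "B", "B"))
#' @export
computeClassWeights <- function(labels) {
    if (!length(labels)) stop("invalid input: no labels")
    counts <- table(as.character(labels))
    w <- 1 / as.numeric(counts)
    w <- w / mean(w)
    names(w) <- names(counts)
    w
}

## forward pass up to the embedding layer (linear) and the softmax head.
## Hidden layers use ReLU; the embedding layer is linear so cosine
## geometry on the sphere is not distorted by rectification.
.encForward <- function(weights, biases, X, upto = c("head", "embedding")) {
    upto <- match.arg(upto)
    L <- length(weights)
    H <- X
    acts <- vector("list", L)
    for (l in seq_len(L - 2L)) {
        H <- pmax(sweep(H %*% weights[[l]], 2L, biases[[l]], "+"), 0)
        acts[[l]] <- H
    }
    E <- sweep(H %*% weights[[L - 1L]], 2L, biases[[L - 1L]], "+")
    acts[[L - 1L]] <- E
    if (upto == "embedding")
        return(list(embedding = E, acts = acts))
    logits <- sweep(E %*% weights[[L]], 2L, biases[[L]], "+")
    logits <- logits - apply(logits, 1L, max)
    P <- exp(logits)
    P <- P / rowSums(P)
    list(embedding = E, probs = P, acts = acts)
}

#' Train a classifier-encoder
#'
#' Fits a multilayer-perceptron softmax classifier over the training
#' disorders by minimizing class-weighted cross-entropy with Adam, for a
#' fixed number of epochs.  The final hidden layer (width
#' `config@embedDim`) is the embedding layer; [embedImages()] exposes it
#' as the encoder.  Validation top-1 accuracy is recorded per epoch for
#' monitoring only.  Training is fully deterministic given
#' `config@seed`: initialization and the per-epoch batch permutation are
#' drawn from a seeded stream.
#'
#' @param cohort a split [FaceCohort-class].
#' @param config an [EncoderConfig-class].
#' @param disorders disorders to train on; defaults to
#'   [selectTrainingDisorders()] with the 7-patient rule.
#' @param minPatients passed to [selectTrainingDisorders()] when
#'   `disorders` is `NULL`.
#' @return a [GestaltEncoder-class].
#' @export
trainEncoder <- function(cohort, config = encoderConfig(),
                         disorders = NULL, minPatients = 7L) {
    stopifnot(is(cohort, "FaceCohort"), is(config, "EncoderConfig"))
    validObject(config)
    meta <- cohortMeta(cohort)
    if (is.null(disorders))
        disorders <- selectTrainingDisorders(cohort, minPatients)
    disorders <- sort(disorders)
    if (length(disorders) < 2L)
        stop("invalid training set: need at least 2 training disorders")
    feats <- rawFeatures(cohort)
    trIdx <- which(meta$split == "train" & meta$disorder_id %in% disorders)
    if (!length(trIdx))
        stop("invalid training set: train split is empty")
    vaIdx <- which(meta$split == "val" & meta$disorder_id %in% disorders)
    X <- feats[trIdx, , drop = FALSE]
    y <- match(meta$disorder_id[trIdx], disorders)
    Xv <- feats[vaIdx, , drop = FALSE]
    yv <- match(meta$disorder_id[vaIdx], disorders)

    wClass <- computeClassWeights(meta$disorder_id[trIdx])
    wSample <- as.numeric(wClass[meta$disorder_id[trIdx]])

    dims <- c(ncol(X), config@hiddenWidths, config@embedDim,
              length(disorders))
    L <- length(dims) - 1L
    n <- nrow(X)
    b1 <- 0.9; b2 <- 0.999; epsAdam <- 1e-8
    lr <- config@learningRate; wd <- config@weightDecay

    withr::with_seed(config@seed, {
        weights <- lapply(seq_len(L), function(l)
            matrix(stats::rnorm(dims[l] * dims[l + 1L],
                                sd = sqrt(2 / dims[l])),
                   dims[l], dims[l + 1L]))
        biases <- lapply(seq_len(L), function(l) numeric(dims[l + 1L]))
        mW <- lapply(weights, function(w) w * 0)
        vW <- mW
        mB <- lapply(biases, function(b) b * 0)
        vB <- mB
        step <- 0L
        history <- data.frame(epoch = integer(), loss = numeric(),
                              val_top1 = numeric())
        for (epoch in seq_len(config@epochs)) {
            perm <- sample.int(n)
            starts <- seq(1L, n, by = config@batchSize)
            epochLoss <- numeric(length(starts))
            for (bi in seq_along(starts)) {
                idx <- perm[starts[bi]:min(starts[bi] + config@batchSize - 1L, n)]
                Xb <- X[idx, , drop = FALSE]
                yb <- y[idx]
                wb <- wSample[idx]
                nb <- length(idx)
                fw <- .encForward(weights, biases, Xb)
                P <- fw$probs
                ce <- -log(pmax(P[cbind(seq_len(nb), yb)], 1e-300))
                loss <- mean(wb * ce)
                if (!is.finite(loss))
                    stop(sprintf("divergence: non-finite loss at epoch %d",
                                 epoch))
                epochLoss[bi] <- loss
                ## backprop
                G <- P
                G[cbind(seq_len(nb), yb)] <- G[cbind(seq_len(nb), yb)] - 1
                G <- G * (wb / nb)
                gW <- vector("list", L)
                gB <- vector("list", L)
                delta <- G
                for (l in rev(seq_len(L))) {
                    Aprev <- if (l == 1L) Xb else fw$acts[[l - 1L]]
                    gW[[l]] <- crossprod(Aprev, delta) + wd * weights[[l]]
                    gB[[l]] <- colSums(delta)
                    if (l > 1L) {
                        delta <- delta %*% t(weights[[l]])
                        if (l - 1L <= L - 2L)  # ReLU hidden layer
                            delta <- delta * (fw$acts[[l - 1L]] > 0)
                    }
                }
                step <- step + 1L
                c1 <- 1 - b1^step
                c2 <- 1 - b2^step
                for (l in seq_len(L)) {
                    mW[[l]] <- b1 * mW[[l]] + (1 - b1) * gW[[l]]
                    vW[[l]] <- b2 * vW[[l]] + (1 - b2) * gW[[l]]^2
                    weights[[l]] <- weights[[l]] -
                        lr * (mW[[l]] / c1) / (sqrt(vW[[l]] / c2) + epsAdam)
                    mB[[l]] <- b1 * mB[[l]] + (1 - b1) * gB[[l]]
                    vB[[l]] <- b2 * vB[[l]] + (1 - b2) * gB[[l]]^2
                    biases[[l]] <- biases[[l]] -
                        lr * (mB[[l]] / c1) / (sqrt(vB[[l]] / c2) + epsAdam)
                }
            }
            valTop1 <- NA_real_
            if (length(vaIdx)) {
                Pv <- .encForward(weights, biases, Xv)$probs
                valTop1 <- 100 * mean(max.col(Pv) == yv)
            }
            history <- rbind(history,
                             data.frame(epoch = epoch,
                                        loss = mean(epochLoss),
                                        val_top1 = valTop1))
        }
        weights <- lapply(weights, unname)
        biases <- lapply(biases, unname)
        new("GestaltEncoder", weights = weights, biases = biases,
            rawDim = ncol(X), config = config,
            trainingDisorders = disorders, history = history)
    })
}

#' Train an ensemble of encoders
#'
#' Independent trainings differing only in seed; downstream matching
#' averages cosine distances over members to reduce variance.
#'
#' @param cohort a split [FaceCohort-class].
#' @param config base [EncoderConfig-class] (its seed is replaced per
#'   member).
#' @param nModels number of members (>= 1).
#' @param seeds integer vector of length `nModels`; duplicate seeds are
#'   legal but produce identical members and are reported with a warning.
#' @param ... passed to [trainEncoder()].
#' @return a [GestaltEnsemble-class].
#' @export
trainEnsemble <- function(cohort, config = encoderConfig(), nModels = 1L,
                          seeds = seq_len(nModels), ...) {
    if (nModels < 1L) stop("invalid parameter: nModels must be >= 1")
    if (length(seeds) != nModels)
        stop("invalid parameter: length(seeds) must equal nModels")
    if (anyDuplicated(seeds))
        warning("duplicate ensemble seeds: members will be identical")
    members <- lapply(seeds, function(s) {
        cfg <- config
        cfg@seed <- as.integer(s)
        trainEncoder(cohort, cfg, ...)
    })
    new("GestaltEnsemble", members = members)
}

#' Embed images into the clinical face phenotype space
#'
#' Applies everything up to the penultimate (embedding) layer of the
#' trained classifier and L2-normalizes each embedding to unit norm, so
#' cosine distance is well-defined and scale-free.  An all-zero embedding
#' raises an error instead of being silently normalized.
#'
#' For a [GestaltEnsemble-class], returns a list with one embedding
#' matrix per member.
#'
#' @param encoder a [GestaltEncoder-class] or [GestaltEnsemble-class].
#' @param x a [FaceCohort-class] or a numeric matrix with images in rows
#'   (rownames taken as image ids).
#' @param ... unused.
#' @return numeric matrix (images x embedDim) with unit-norm rows, or a
#'   list of such matrices for an ensemble.
#' @export
setMethod("embedImages", "GestaltEncoder", function(encoder, x, ...) {
    X <- if (is(x, "FaceCohort")) rawFeatures(x) else as.matrix(x)
    if (ncol(X) != encoder@rawDim)
        stop(sprintf("dimension mismatch: encoder expects %d features, got %d",
                     encoder@rawDim, ncol(X)))
    E <- .encForward(encoder@weights, encoder@biases, X,
                     upto = "embedding")$embedding
    E <- .rowNormalize(E, strict = TRUE, what = "embedding")
    rownames(E) <- rownames(X)
    E
})

#' @rdname embedImages
#' @export
setMethod("embedImages", "GestaltEnsemble", function(encoder, x, ...) {
    lapply(encoder@members, embedImages, x = x, ...)
})

#' @describeIn embedDim embedding width of a single encoder
#' @export
setMethod("embedDim", "GestaltEncoder", function(x) x@config@embedDim)

#' @describeIn embedDim common embedding width of an ensemble
#' @export
setMethod("embedDim", "GestaltEnsemble", function(x)
    embedDim(x@members[[1L]]))

#' @describeIn trainingDisorders disorders of a single encoder
#' @export
setMethod("trainingDisorders", "GestaltEncoder", function(x)
    x@trainingDisorders)

#' @describeIn trainingDisorders common disorders of an ensemble
#' @export
setMethod("trainingDisorders", "GestaltEnsemble", function(x)
    x@members[[1L]]@trainingDisorders)

#' @export
setMethod("length", "GestaltEnsemble", function(x) length(x@members))

#' @export
setMethod("show", "GestaltEncoder", function(object) {
    cat(sprintf(
        "GestaltEncoder: %d -> %s-> %d classes (embedDim %d), %d epochs\n",
        object@rawDim,
        if (length(object@config@hiddenWidths))
            paste0(paste(object@config@hiddenWidths, collapse = " -> "),
                   " -> ") else "",
        length(object@trainingDisorders), embedDim(object),
        object@config@epochs))
    h <- object@history
    if (nrow(h))
        cat(sprintf("  final loss %.4f, final val top-1 %s\n",
                    h$loss[nrow(h)],
                    ifelse(is.na(h$val_top1[nrow(h)]), "NA",
                           sprintf("%.2f%%", h$val_top1[nrow(h)]))))
})

#' @export
setMethod("show", "GestaltEnsemble", function(object) {
    cat(sprintf("GestaltEnsemble of %d encoder(s), embedDim %d\n",
                length(object@members), embedDim(object)))
})
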