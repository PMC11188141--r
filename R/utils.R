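#' @importFrom stats setNames
#' @importFrom utils write.table read.delim packageVersion
#' @importFrom tools md5sum
NULL

#' Derive a stage seed from a master seed
#'
#' One master seed reproduces an entire study: every stochastic stage draws
#' its own seed deterministically from the master seed and a stage name, so
#' independent stages never share RNG streams and a manifest only needs to
#' record the master seed plus stage names.
#'
#' @param master integer master seed.
#' @param stage character stage name (e.g. `"simulate"`, `"train:2"`).
#' @return an integer seed in `[1, 2^31 - 2]`.
#' @examples
#' deriveSeed(1, "simulate")
#' @export
deriveSeed <- function(master, stage) {
    stopifnot(length(master) == 1L, is.finite(master),
              is.character(stage), length(stage) == 1L)
    m <- 2147483647  # 2^31 - 1, prime
    h <- as.numeric(master) %% m
    for (code in utf8ToInt(stage))
        h <- (h * 131 + code) %% m
    as.integer(h %% (m - 1)) + 1L
}

## L2-normalize matrix rows; errors on (near-)zero rows when strict
.rowNormalize <- function(x, strict = TRUE, what = "vector") {
    nrm <- sqrt(rowSums(x^2))
    if (any(nrm < 1e-12)) {
        if (strict)
            stop(sprintf("cannot L2-normalize all-zero %s (row %s)",
                         what, which(nrm < 1e-12)[1L]))
        nrm[nrm < 1e-12] <- 1
    }
    x / nrm
}

## cosine distance matrix between rows of a and rows of b, in [0, 2]
.cosineDistanceMatrix <- function(a, b) {
    d <- 1 - tcrossprod(.rowNormalize(a), .rowNormalize(b))
    ## clamp floating-point excursions outside [0, 2]
    d[d < 0] <- 0
    d[d > 2] <- 2
    d
}

.formatNum <- function(x) {
    out <- vapply(x, function(v) {
        if (is.na(v)) "" else sprintf("%.9g", v)
    }, character(1))
    out
}

.writeTSV <- function(df, path) {
    ## missing values as empty fields, no quoting: diff-able plain text
    out <- df
    for (j in seq_along(out)) {
        if (is.numeric(out[[j]])) out[[j]] <- .formatNum(out[[j]])
        out[[j]] <- as.character(out[[j]])
        out[[j]][is.na(out[[j]])] <- ""
    }
    utils::write.table(out, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = TRUE, na = "")
    invisible(path)
}

.readTSV <- function(path) {
    utils::read.delim(path, sep = "\t", header = TRUE,
                      colClasses = "character", na.strings = NULL,
                      check.names = FALSE)
}
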