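#' Construct a symptom-group definition
#'
#' @param terms named list mapping group labels to character vectors of
#'   HPO term ids; term sets must be pairwise disjoint.
#' @param fallback the fallback label (default `"Others"`); added with an
#'   empty term set if absent from `terms`.  Group order (used for tie
#'   breaking) is the order of `terms`, fallback last.
#' @return a validated [SymptomGroupDefinition-class].
#' @export
symptomGroupDefinition <- function(terms, fallback = "Others") {
    if (!fallback %in% names(terms))
        terms[[fallback]] <- character(0)
    groups <- c(setdiff(names(terms), fallback), fallback)
    new("SymptomGroupDefinition", groups = groups,
        terms = terms[groups], fallback = fallback)
}

#' Read / write symptom-group definitions
#'
#' Two-column tab-separated file with header `group<TAB>term`; one row per
#' (group, term) pair.  The fallback group may be listed with an empty
#' term field.
#'
#' @param path file path.
#' @param fallback fallback label (default `"Others"`).
#' @return [SymptomGroupDefinition-class] for the reader; the path,
#'   invisibly, for the writer.
#' @export
readSymptomGroupDefinition <- function(path, fallback = "Others") {
    df <- .readTSV(path)
    if (!all(c("group", "term") %in% colnames(df)))
        stop("symptom-group file needs columns: group, term")
    groups <- unique(df$group)
    terms <- lapply(groups, function(g) {
        t <- df$term[df$group == g]
        t[nzchar(t)]
    })
    names(terms) <- groups
    symptomGroupDefinition(terms, fallback = fallback)
}

#' @rdname readSymptomGroupDefinition
#' @param defs a [SymptomGroupDefinition-class] to write.
#' @export
writeSymptomGroupDefinition <- function(defs, path) {
    rows <- do.call(rbind, lapply(defs@groups, function(g) {
        t <- defs@terms[[g]]
        if (!length(t)) t <- ""
        data.frame(group = g, term = t)
    }))
    .writeTSV(rows, path)
}

#' Synthetic default symptom groups
#'
#' Twelve disjoint symptom groups over a synthetic HPO-like term universe
#' (ids `HP:SYNxxxx`), shipped with the package.  The group labels follow
#' the broad organ-system categories used in dysmorphology; the term ids
#' are synthetic stand-ins, since real expert-curated group memberships
#' are not redistributable, and the generator only needs a disjoint
#' partition with realistic shape.
#'
#' @return a [SymptomGroupDefinition-class].
#' @export
defaultSymptomGroups <- function() {
    path <- system.file("extdata", "symptom_groups_synthetic.tsv",
                        package = "gestaltR", mustWork = TRUE)
    readSymptomGroupDefinition(path)
}

#' Assign a case to symptom groups
#'
#' A case is assigned to every group for which at least one of the case's
#' annotated HPO terms belongs to the group's term set.  Matching is by
#' exact term identity -- no ontology ancestor propagation.
#'
#' @param caseTerms character vector of HPO term ids annotated for the
#'   case (or a single semicolon-joined string).
#' @param defs a [SymptomGroupDefinition-class].
#' @return character vector of assigned group labels (possibly empty),
#'   in definition order.
#' @export
assignSymptomGroups <- function(caseTerms, defs) {
    stopifnot(is(defs, "SymptomGroupDefinition"))
    validObject(defs)
    caseTerms <- .splitTerms(caseTerms)
    hits <- vapply(defs@groups, function(g)
        any(caseTerms %in% defs@terms[[g]]), logical(1))
    defs@groups[hits]
}

.splitTerms <- function(caseTerms) {
    if (length(caseTerms) == 1L && grepl(";", caseTerms))
        caseTerms <- strsplit(caseTerms, ";", fixed = TRUE)[[1L]]
    caseTerms[nzchar(caseTerms)]
}

#' Leading symptom group of a case
#'
#' The single group comprising the largest number of the case's annotated
#' terms.  Ties are broken by definition order and flagged.  The fallback
#' group is the leading group only when no other group matches at all.
#'
#' @param caseTerms character vector of HPO term ids (or semicolon-joined
#'   string).
#' @param defs a [SymptomGroupDefinition-class].
#' @return list with `group` (label) and `tie` (logical; `TRUE` iff the
#'   maximal matched-term count is shared by several groups).
#' @export
leadingGroup <- function(caseTerms, defs) {
    stopifnot(is(defs, "SymptomGroupDefinition"))
    caseTerms <- .splitTerms(caseTerms)
    nonFallback <- setdiff(defs@groups, defs@fallback)
    counts <- vapply(nonFallback, function(g)
        sum(caseTerms %in% defs@terms[[g]]), integer(1))
    if (!length(counts) || max(counts) == 0L)
        return(list(group = defs@fallback, tie = FALSE))
    best <- which(counts == max(counts))
    list(group = nonFallback[best[1L]], tie = length(best) > 1L)
}

#' Symptom-group co-occurrence matrix
#'
#' Entry (X, Y) is the proportion of cases assigned to group X that are
#' also assigned to group Y; the diagonal is 1 for every group with at
#' least one case.  Groups with no assigned case are reported as `NA`
#' columns/rows.
#'
#' @param assignments list of character vectors, one per case, each a set
#'   of assigned group labels (e.g. from [assignSymptomGroups()]).
#' @param defs a [SymptomGroupDefinition-class] fixing the group order.
#' @return square numeric matrix (groups x groups) of proportions.
#' @export
groupCooccurrence <- function(assignments, defs) {
    if (!length(assignments)) stop("invalid input: no assignments")
    groups <- defs@groups
    member <- vapply(assignments, function(a) groups %in% a,
                     logical(length(groups)))
    member <- matrix(member, nrow = length(groups))  # groups x cases
    counts <- rowSums(member)
    joint <- member %*% t(member)   # (X, Y) joint counts
    out <- joint / counts           # row-wise division by |X|
    out[counts == 0L, ] <- NA_real_
    out[, counts == 0L] <- NA_real_
    dimnames(out) <- list(groups, groups)
    out
}

#' Symptom-group analysis of a cohort
#'
#' Applies assignment and leading-group rules to every patient of a
#' cohort (one case per patient; a patient's semicolon-joined `hpo_terms`
#' field is the annotation) and tabulates the co-occurrence matrix.
#'
#' @param cohort a [FaceCohort-class].
#' @param defs a [SymptomGroupDefinition-class]; default
#'   [defaultSymptomGroups()].
#' @return list with `assignments` (data.frame: patient_id, groups
#'   (semicolon-joined), leading_group, tie) and `cooccurrence` (matrix).
#' @export
cohortSymptomGroups <- function(cohort, defs = defaultSymptomGroups()) {
    pat <- patientTable(cohort)
    asg <- lapply(pat$hpo_terms, assignSymptomGroups, defs = defs)
    lead <- lapply(pat$hpo_terms, leadingGroup, defs = defs)
    list(assignments = data.frame(
             patient_id = pat$patient_id,
             groups = vapply(asg, paste, character(1), collapse = ";"),
             leading_group = vapply(lead, `[[`, character(1), "group"),
             tie = vapply(lead, `[[`, logical(1), "tie")),
         cooccurrence = groupCooccurrence(asg, defs))
}
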