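#' Construct a MirnaExperiment
#'
#' @param values numeric matrix, miRNAs in rows, samples in columns; row and
#'   column names are the (unique) miRNA and sample identifiers. \code{NA}
#'   marks missing intensities.
#' @param phenotype character, one class label per sample.
#' @param dataset character, one batch / source label per sample.
#' @return a \linkS4class{MirnaExperiment}
#' @examples
#' m <- matrix(rnorm(6), 3, 2,
#'             dimnames = list(paste0("miR-", 1:3), c("s1", "s2")))
#' x <- MirnaExperiment(m, phenotype = c("BrC", "Ctrl"),
#'                      dataset = c("D1", "D1"))
#' @export
MirnaExperiment <- function(values, phenotype, dataset) {
    if (!is.matrix(values) || !is.numeric(values))
        stop("'values' must be a numeric matrix (miRNAs x samples)")
    if (length(phenotype) != ncol(values) || length(dataset) != ncol(values))
        stop("'phenotype' and 'dataset' must have one entry per sample column")
    se <- SummarizedExperiment(
        assays = list(exprs = values),
        colData = DataFrame(phenotype = as.character(phenotype),
                            dataset = as.character(dataset),
                            row.names = colnames(values)))
    new("MirnaExperiment", se)
}

#' @rdname MirnaExperiment
#' @export
setMethod("exprValues", "MirnaExperiment", function(x) assay(x, "exprs"))

#' @rdname MirnaExperiment
#' @export
setMethod("phenotype", "MirnaExperiment", function(x) {
    stats::setNames(colData(x)$phenotype, colnames(x))
})

#' @rdname MirnaExperiment
#' @export
setMethod("datasetLabels", "MirnaExperiment", function(x) {
    stats::setNames(colData(x)$dataset, colnames(x))
})

#' @rdname MirnaExperiment
#' @export
setMethod("mirnaIds", "MirnaExperiment", function(x) rownames(x))

#' @rdname MirnaExperiment
#' @export
setMethod("sampleIds", "MirnaExperiment", function(x) colnames(x))

setMethod("show", "MirnaExperiment", function(object) {
    cat("MirnaExperiment:", nrow(object), "miRNAs x", ncol(object), "samples\n")
    ph <- table(phenotype(object))
    cat("phenotypes:", paste(names(ph), ph, sep = "=", collapse = ", "), "\n")
    cat("datasets:  ", paste(unique(datasetLabels(object)), collapse = ", "), "\n")
    nmiss <- sum(is.na(exprValues(object)))
    if (nmiss > 0) cat("missing cells:", nmiss, "\n")
})

#' @rdname GroundTruth
#' @export
setMethod("plantedPairs", "GroundTruth", function(x) x@plantedPairs)

#' @rdname GroundTruth
#' @export
setMethod("diffMirnas", "GroundTruth", function(x) x@diffMirnas)

#' @rdname GroundTruth
#' @export
setMethod("outlierIds", "GroundTruth", function(x) x@outlierIds)

#' @rdname GroundTruth
#' @export
setMethod("duplicatePairs", "GroundTruth", function(x) x@duplicatePairs)

setMethod("show", "GroundTruth", function(object) {
    cat("GroundTruth:", nrow(object@plantedPairs), "planted pairs,",
        length(object@diffMirnas), "planted miRNAs,",
        length(object@outlierIds), "outliers,",
        nrow(object@duplicatePairs), "duplicates\n")
})

#' @rdname VotingModel
#' @export
setMethod("modelPairs", "VotingModel", function(x) x@pairs)

#' @rdname VotingModel
#' @export
setMethod("objectiveTrace", "VotingModel", function(x) x@objectiveTrace)

setMethod("show", "VotingModel", function(object) {
    cat("VotingModel with", nrow(object@pairs), "pairs",
        sprintf("(seed %s|%s)\n", object@seedPair[1], object@seedPair[2]))
    cat(sprintf("final training sqrt(NPV x PPV): %.4f\n",
                utils::tail(object@objectiveTrace, 1)))
})

#' @rdname GreedyResult
#' @export
setMethod("selectedModel", "GreedyResult", function(x) x@models[[x@selected]])

#' @rdname GreedyResult
#' @export
setMethod("modelPairs", "GreedyResult", function(x) modelPairs(selectedModel(x)))

setMethod("show", "GreedyResult", function(object) {
    cat("GreedyResult:", length(object@models), "seeded models;",
        "selected model", object@selected, "with",
        nrow(modelPairs(object)), "pairs\n")
    cat(sprintf("selection (%s) accuracy: %.4f\n", object@selection,
                object@selectionAccuracy[object@selected]))
    if (max(object@duplicateGroups) < length(object@models))
        cat("note: some seeds grew to identical pair sets (see duplicateGroups)\n")
})
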