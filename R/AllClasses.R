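#' @import methods
#' @importFrom S4Vectors DataFrame metadata
#' @importFrom SummarizedExperiment SummarizedExperiment assay colData
NULL

#' MirnaExperiment: miRNA-by-sample expression container
#'
#' A thin extension of \linkS4class{SummarizedExperiment} holding one assay
#' (\code{"exprs"}, continuous log-scale intensities, \code{NA} = missing)
#' and two mandatory per-sample annotations: \code{phenotype} (class label,
#' e.g. a cancer type) and \code{dataset} (batch / cohort of origin). Row
#' names are miRNA identifiers, column names sample identifiers; both must
#' be unique.
#'
#' @slot .Data inherited SummarizedExperiment internals.
#' @export
setClass("MirnaExperiment", contains = "SummarizedExperiment")

setValidity("MirnaExperiment", function(object) {
    msg <- character()
    if (!"exprs" %in% SummarizedExperiment::assayNames(object))
        msg <- c(msg, "assay 'exprs' is required")
    rn <- rownames(object)
    cn <- colnames(object)
    if (is.null(rn) || anyNA(rn) || anyDuplicated(rn))
        msg <- c(msg, "miRNA ids (rownames) must be present and unique")
    if (is.null(cn) || anyNA(cn) || anyDuplicated(cn))
        msg <- c(msg, "sample ids (colnames) must be present and unique")
    cd <- colData(object)
    for (field in c("phenotype", "dataset")) {
        if (!field %in% colnames(cd))
            msg <- c(msg, sprintf("colData column '%s' is required", field))
        else if (anyNA(cd[[field]]))
            msg <- c(msg, sprintf("colData column '%s' has missing entries", field))
    }
    if (length(msg)) msg else TRUE
})

#' Run configuration for the REO pipeline
#'
#' Holds every tunable threshold of the discovery pipeline. Defaults are the
#' values used in the serum miRNA study this package implements: stable-pair
#' PCT >= 80\%, reversed-pair FDR < 5\%, candidate degree of reversal
#' (delta PCT) >= 0.7, ten greedy seeds, 70/30 train/test split, k = 10
#' imputation neighbours, duplicate Euclidean distance < 1, outlier cut at
#' two standard deviations.
#'
#' @export
setClass("ReoConfig", representation(
    pctThreshold = "numeric",
    fdrThreshold = "numeric",
    deltaPctThreshold = "numeric",
    nSeeds = "integer",
    trainFraction = "numeric",
    knnK = "integer",
    duplicateDistance = "numeric",
    outlierSdMultiplier = "numeric",
    rngSeed = "integer",
    caseLabel = "character"
))

setValidity("ReoConfig", function(object) {
    msg <- character()
    frac_in <- function(x, lo, hi) length(x) == 1L && is.finite(x) && x > lo && x <= hi
    if (!frac_in(object@pctThreshold, 0.5, 1))
        msg <- c(msg, "pctThreshold must be in (0.5, 1]")
    if (!(length(object@fdrThreshold) == 1L && object@fdrThreshold > 0 &&
          object@fdrThreshold < 1))
        msg <- c(msg, "fdrThreshold must be in (0, 1)")
    if (!frac_in(object@deltaPctThreshold, 0, 1))
        msg <- c(msg, "deltaPctThreshold must be in (0, 1]")
    if (object@nSeeds < 1L) msg <- c(msg, "nSeeds must be positive")
    if (!(object@trainFraction > 0 && object@trainFraction < 1))
        msg <- c(msg, "trainFraction must be in (0, 1)")
    if (object@knnK < 1L) msg <- c(msg, "knnK must be positive")
    if (object@duplicateDistance < 0)
        msg <- c(msg, "duplicateDistance must be non-negative")
    if (object@outlierSdMultiplier <= 0)
        msg <- c(msg, "outlierSdMultiplier must be positive")
    if (length(object@caseLabel) != 1L || !nzchar(object@caseLabel))
        msg <- c(msg, "caseLabel must be a non-empty string")
    if (length(msg)) msg else TRUE
})

#' Design of a synthetic multi-batch cohort
#'
#' Describes the cohort the generator emulates: several datasets (batches)
#' with dataset-specific monotone intensity distortions, multiple phenotype
#' classes with one designated case class, disjoint planted pair-order
#' reversals between case and control samples, missing values, outlier
#' samples and near-duplicate samples.
#'
#' @export
setClass("SimulationDesign", representation(
    nMirnas = "integer",
    phenotypes = "data.frame",      # columns: label, n
    nDatasets = "integer",
    caseLabel = "character",
    nPlantedReversals = "integer",
    reversalStrength = "numeric",
    stableStrength = "numeric",
    missingRate = "numeric",
    nOutliers = "integer",
    nDuplicates = "integer",
    batchMonotone = "logical",
    noiseSd = "numeric",
    rngSeed = "integer"
))

setValidity("SimulationDesign", function(object) {
    msg <- character()
    ph <- object@phenotypes
    if (!all(c("label", "n") %in% colnames(ph)) || nrow(ph) < 2L)
        msg <- c(msg, "phenotypes needs columns label, n and >= 2 classes")
    else {
        if (anyDuplicated(ph$label)) msg <- c(msg, "phenotype labels must be unique")
        if (!object@caseLabel %in% ph$label)
            msg <- c(msg, "caseLabel must be one of the phenotype labels")
        if (any(ph$n < 1)) msg <- c(msg, "every phenotype needs >= 1 sample")
    }
    if (object@nPlantedReversals * 2L > object@nMirnas)
        msg <- c(msg, "planted pairs are disjoint: need nPlantedReversals <= nMirnas/2")
    if (object@nPlantedReversals > 0L) {
        if (object@reversalStrength <= 0.5 || object@reversalStrength > 1)
            msg <- c(msg, "reversalStrength must be in (0.5, 1]")
        if (object@stableStrength <= 0.5 || object@stableStrength > 1)
            msg <- c(msg, "stableStrength must be in (0.5, 1]")
    }
    if (object@missingRate < 0 || object@missingRate >= 1)
        msg <- c(msg, "missingRate must be in [0, 1)")
    if (object@noiseSd <= 0) msg <- c(msg, "noiseSd must be positive")
    if (object@nDatasets < 1L) msg <- c(msg, "nDatasets must be >= 1")
    if (object@nOutliers < 0L || object@nDuplicates < 0L)
        msg <- c(msg, "nOutliers and nDuplicates must be non-negative")
    if (length(msg)) msg else TRUE
})

#' Ground truth of a simulated cohort
#'
#' @slot plantedPairs data.frame with columns \code{mirna_a}, \code{mirna_b},
#'   \code{control_direction}, \code{case_direction} (the REO characteristic
#'   of case samples).
#' @slot diffMirnas character, miRNAs participating in planted pairs.
#' @slot outlierIds character, sample ids replaced by shuffled profiles.
#' @slot duplicatePairs data.frame with columns \code{source_id}, \code{dup_id}.
#' @export
setClass("GroundTruth", representation(
    plantedPairs = "data.frame",
    diffMirnas = "character",
    outlierIds = "character",
    duplicatePairs = "data.frame"
))

setValidity("GroundTruth", function(object) {
    pp <- object@plantedPairs
    if (nrow(pp) > 0 &&
        !all(c(pp$mirna_a, pp$mirna_b) %in% object@diffMirnas))
        return("every planted pair member must be listed in diffMirnas")
    TRUE
})

#' Majority-voting miRNA-pair classifier
#'
#' An ordered set of miRNA pairs, each carrying the REO direction
#' characteristic of the case class. A sample is scored by the fraction of
#' pairs whose observed within-sample ordering matches the case direction
#' and labelled case when that fraction exceeds 1/2. Classification uses
#' only orderings, so no normalisation of new samples is required.
#'
#' @slot pairs data.frame with columns \code{pair_a}, \code{pair_b},
#'   \code{case_direction} (\code{">"} or \code{"<="}, read as
#'   E_a (direction) E_b in case samples).
#' @slot objectiveTrace numeric, sqrt(NPV x PPV) after each greedy addition.
#' @slot seedPair character(2), the seed pair.
#' @export
setClass("VotingModel", representation(
    pairs = "data.frame",
    objectiveTrace = "numeric",
    seedPair = "character"
))

setValidity("VotingModel", function(object) {
    p <- object@pairs
    msg <- character()
    if (!all(c("pair_a", "pair_b", "case_direction") %in% colnames(p)))
        msg <- c(msg, "pairs needs columns pair_a, pair_b, case_direction")
    else {
        if (nrow(p) < 1L) msg <- c(msg, "a voting model needs >= 1 pair")
        if (anyDuplicated(paste(p$pair_a, p$pair_b)))
            msg <- c(msg, "pairs must be distinct")
        if (!all(p$case_direction %in% c(">", "<=")))
            msg <- c(msg, "case_direction must be '>' or '<='")
    }
    if (length(msg)) msg else TRUE
})

#' Result of the seeded greedy search
#'
#' One \linkS4class{VotingModel} per seed (seeds are the top candidates by
#' absolute degree of reversal), ranked by their training sqrt(NPV x PPV);
#' the final model is the one with the highest accuracy on the selection
#' set. Seeds that grew to identical pair sets are recorded as duplicate
#' groups.
#'
#' @export
setClass("GreedyResult", representation(
    models = "list",
    selected = "integer",
    trainingObjective = "numeric",
    selectionAccuracy = "numeric",
    selection = "character",
    duplicateGroups = "integer"
))

setValidity("GreedyResult", function(object) {
    msg <- character()
    if (!all(vapply(object@models, is, logical(1), "VotingModel")))
        msg <- c(msg, "models must all be VotingModel objects")
    n <- length(object@models)
    if (length(object@selected) != 1L || object@selected < 1L || object@selected > n)
        msg <- c(msg, "selected must index one model")
    if (length(object@trainingObjective) != n || length(object@selectionAccuracy) != n)
        msg <- c(msg, "one objective and one selection accuracy per model required")
    if (length(msg)) msg else TRUE
})
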