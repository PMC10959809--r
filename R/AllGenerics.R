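#' @rdname MirnaExperiment
#' @param x a \linkS4class{MirnaExperiment}
#' @export
setGeneric("exprValues", function(x) standardGeneric("exprValues"))

#' @rdname MirnaExperiment
#' @export
setGeneric("phenotype", function(x) standardGeneric("phenotype"))

#' @rdname MirnaExperiment
#' @export
setGeneric("datasetLabels", function(x) standardGeneric("datasetLabels"))

#' @rdname MirnaExperiment
#' @export
setGeneric("mirnaIds", function(x) standardGeneric("mirnaIds"))

#' @rdname MirnaExperiment
#' @export
setGeneric("sampleIds", function(x) standardGeneric("sampleIds"))

#' @rdname GroundTruth
#' @param x a \linkS4class{GroundTruth}
#' @export
setGeneric("plantedPairs", function(x) standardGeneric("plantedPairs"))

#' @rdname GroundTruth
#' @export
setGeneric("diffMirnas", function(x) standardGeneric("diffMirnas"))

#' @rdname GroundTruth
#' @export
setGeneric("outlierIds", function(x) standardGeneric("outlierIds"))

#' @rdname GroundTruth
#' @export
setGeneric("duplicatePairs", function(x) standardGeneric("duplicatePairs"))

#' @rdname VotingModel
#' @param x a \linkS4class{VotingModel} or \linkS4class{GreedyResult}
#' @export
setGeneric("modelPairs", function(x) standardGeneric("modelPairs"))

#' @rdname VotingModel
#' @export
setGeneric("objectiveTrace", function(x) standardGeneric("objectiveTrace"))

#' @rdname GreedyResult
#' @param x a \linkS4class{GreedyResult}
#' @export
setGeneric("selectedModel", function(x) standardGeneric("selectedModel"))
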