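#' Run the full REO biomarker discovery pipeline
#'
#' Convenience wrapper chaining the discovery stages on an imputed cohort:
#' stable pairs in the training controls, reversed pairs (Fisher + BH),
#' candidate pairs by degree of reversal, the seeded greedy majority-voting
#' search, and evaluation of the selected model on the training and test
#' sets.
#'
#' @param x an imputed \linkS4class{MirnaExperiment}
#' @param config a \linkS4class{ReoConfig}
#' @param split optional list with \code{train_ids}, \code{test_ids};
#'   by default drawn with \code{splitTrainTest} under the config seed.
#' @param mirnaSubset optionally restrict pair screening to these miRNAs
#'   (e.g. a differential set).
#' @param selection greedy model selection set, \code{"holdout"} or
#'   \code{"test"} (see \code{runGreedy}).
#' @return list: \code{split}, \code{stable}, \code{reversed},
#'   \code{candidates}, \code{greedy}, \code{model},
#'   \code{train_metrics}, \code{test_metrics}, \code{config}
#' @export
runReoPipeline <- function(x, config = reoConfig(), split = NULL,
                           mirnaSubset = NULL,
                           selection = c("holdout", "test")) {
    selection <- match.arg(selection)
    case <- config@caseLabel
    if (is.null(split))
        split <- splitTrainTest(x, case, config@trainFraction,
                                seed = config@rngSeed)
    ph <- phenotype(x)
    train_ctrl <- split$train_ids[ph[split$train_ids] != case]
    train_case <- split$train_ids[ph[split$train_ids] == case]
    stable <- findStablePairs(x, train_ctrl, config@pctThreshold,
                              mirnaSubset = mirnaSubset)
    reversed <- findReversedPairs(x, stable, train_case,
                                  config@fdrThreshold)
    candidates <- selectCandidates(reversed, config@deltaPctThreshold)
    if (nrow(candidates) == 0L)
        stop("no candidate pairs at delta PCT >= ",
             config@deltaPctThreshold)
    greedy <- runGreedy(x, candidates, split, case,
                        nSeeds = config@nSeeds, selection = selection,
                        seed = config@rngSeed)
    model <- selectedModel(greedy)
    metrics_on <- function(ids) {
        pred <- voteClassify(model, x, ids)
        evalMetrics(as.integer(ph[ids] == case),
                    as.integer(pred$label == "case"), pred$score)
    }
    list(split = split, stable = stable, reversed = reversed,
         candidates = candidates, greedy = greedy, model = model,
         train_metrics = metrics_on(split$train_ids),
         test_metrics = metrics_on(split$test_ids),
         config = config)
}
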