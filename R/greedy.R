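# binary match matrix: rows = candidate pairs, columns = samples,
# 1 iff the sample's observed REO equals the pair's case direction.
.matchMatrix <- function(x, pairsDf, sampleIdsUse, caseDirection) {
    X <- exprValues(x)
    ia <- match(pairsDf$pair_a, rownames(X))
    ib <- match(pairsDf$pair_b, rownames(X))
    bad <- c(pairsDf$pair_a[is.na(ia)], pairsDf$pair_b[is.na(ib)])
    if (length(bad))
        stop("miRNA(s) not present: ", paste(unique(bad), collapse = ", "))
    Xa <- X[ia, sampleIdsUse, drop = FALSE]
    Xb <- X[ib, sampleIdsUse, drop = FALSE]
    .checkComplete(Xa); .checkComplete(Xb)
    gt <- Xa > Xb
    mm <- ifelse(matrix(caseDirection == ">", nrow(gt), ncol(gt)), gt, !gt)
    storage.mode(mm) <- "integer"
    rownames(mm) <- paste(pairsDf$pair_a, pairsDf$pair_b, sep = "|")
    colnames(mm) <- sampleIdsUse
    mm
}

.caseDirection <- function(candidates) {
    # the case-characteristic REO is the reversal of the stable direction
    ifelse(candidates$direction == ">", "<=", ">")
}

.objective <- function(pred, is_case) {
    tp <- sum(pred & is_case); fp <- sum(pred & !is_case)
    tn <- sum(!pred & !is_case); fn <- sum(!pred & is_case)
    ppv <- if (tp + fp > 0) tp / (tp + fp) else 0
    npv <- if (tn + fn > 0) tn / (tn + fn) else 0
    sqrt(npv * ppv)
}

#' Classify samples by majority vote of pair REOs
#'
#' A sample's score is the fraction of model pairs whose observed
#' within-sample REO equals the case-characteristic direction; the label
#' is case when the score exceeds 1/2 (an exact tie votes control). Only
#' orderings are consulted, so samples need no normalisation.
#'
#' @param model a \linkS4class{VotingModel}
#' @param x a \linkS4class{MirnaExperiment}
#' @param sampleIdsUse samples to classify (default: all).
#' @return data.frame: \code{sample_id}, \code{score}, \code{label}
#'   (\code{"case"} / \code{"control"})
#' @export
voteClassify <- function(model, x, sampleIdsUse = sampleIds(x)) {
    p <- modelPairs(model)
    mm <- .matchMatrix(x, p, sampleIdsUse, p$case_direction)
    score <- colMeans(mm)
    data.frame(sample_id = sampleIdsUse, score = unname(score),
               label = ifelse(score > 0.5, "case", "control"))
}

#' Grow one voting model from a seed pair
#'
#' Starting from the seed alone, repeatedly adds the candidate pair whose
#' inclusion most increases the training sqrt(NPV x PPV) of the
#' majority-vote classifier (steepest ascent, first-index tie-break on the
#' candidate ordering) and stops at the first step with no strict
#' improvement.
#'
#' @param x a \linkS4class{MirnaExperiment}
#' @param candidates candidate pairs from \code{selectCandidates}
#'   (ordered by |delta PCT| decreasing).
#' @param trainIds training samples.
#' @param caseLabel case phenotype label.
#' @param seedIndex row of \code{candidates} used as seed.
#' @return a \linkS4class{VotingModel}
#' @export
greedyGrow <- function(x, candidates, trainIds, caseLabel, seedIndex = 1L) {
    if (nrow(candidates) < 1L) stop("no candidate pairs")
    is_case <- phenotype(x)[trainIds] == caseLabel
    if (all(is_case) || !any(is_case))
        stop("training samples must contain both classes")
    cdir <- .caseDirection(candidates)
    mm <- .matchMatrix(x, candidates, trainIds, cdir)
    nC <- nrow(candidates)
    current <- seedIndex
    votes <- mm[seedIndex, ]
    obj <- .objective(votes > 0.5, is_case)
    trace <- obj
    repeat {
        remaining <- setdiff(seq_len(nC), current)
        if (length(remaining) == 0L) break
        size <- length(current) + 1L
        best <- -Inf; best_j <- NA_integer_
        for (j in remaining) {
            o <- .objective((votes + mm[j, ]) / size > 0.5, is_case)
            if (o > best + 1e-12) { best <- o; best_j <- j }
        }
        if (best <= obj + 1e-12) break
        current <- c(current, best_j)
        votes <- votes + mm[best_j, ]
        obj <- best
        trace <- c(trace, obj)
    }
    sel <- candidates[current, , drop = FALSE]
    new("VotingModel",
        pairs = data.frame(pair_a = sel$pair_a, pair_b = sel$pair_b,
                           case_direction = cdir[current]),
        objectiveTrace = trace,
        seedPair = c(candidates$pair_a[seedIndex],
                     candidates$pair_b[seedIndex]))
}

#' Seeded greedy search for the final pair combination
#'
#' Grows one voting model from each of the top \code{nSeeds} candidates by
#' absolute degree of reversal, ranks the models by training
#' sqrt(NPV x PPV), and selects the model with the highest accuracy on the
#' selection set. By default the selection set is an internal 70/30
#' holdout carved out of the training samples, which keeps the test set
#' untouched; \code{selection = "test"} reproduces the original protocol
#' of selecting on the test set. Ties go to the smaller model, then to the
#' better-ranked seed. Seeds growing to identical pair sets are recorded
#' in \code{duplicateGroups}.
#'
#' @param x a \linkS4class{MirnaExperiment}
#' @param candidates ordered candidates from \code{selectCandidates}.
#' @param split list with \code{train_ids}, \code{test_ids}
#'   (see \code{splitTrainTest}).
#' @param caseLabel case phenotype label.
#' @param nSeeds number of seeds (default 10; capped at the candidate count).
#' @param selection \code{"holdout"} (default) or \code{"test"}.
#' @param seed integer seed for the internal holdout.
#' @return a \linkS4class{GreedyResult}
#' @export
runGreedy <- function(x, candidates, split, caseLabel, nSeeds = 10L,
                      selection = c("holdout", "test"), seed = 1L) {
    selection <- match.arg(selection)
    nSeeds <- min(nSeeds, nrow(candidates))
    if (nSeeds < 1L) stop("no candidate pairs to seed from")
    if (selection == "holdout") {
        xt <- x[, split$train_ids]
        inner <- splitTrainTest(xt, caseLabel, trainFraction = 0.7,
                                seed = seed)
        grow_ids <- inner$train_ids
        select_ids <- inner$test_ids
    } else {
        grow_ids <- split$train_ids
        select_ids <- split$test_ids
    }
    models <- lapply(seq_len(nSeeds), function(s)
        greedyGrow(x, candidates, grow_ids, caseLabel, seedIndex = s))
    train_obj <- vapply(models, function(m)
        utils::tail(objectiveTrace(m), 1), numeric(1))
    is_case_sel <- phenotype(x)[select_ids] == caseLabel
    sel_acc <- vapply(models, function(m) {
        pred <- voteClassify(m, x, select_ids)$label == "case"
        mean(pred == is_case_sel)
    }, numeric(1))
    sizes <- vapply(models, function(m) nrow(modelPairs(m)), numeric(1))
    rank_by_obj <- order(-train_obj, sizes, seq_len(nSeeds))
    pick <- rank_by_obj[order(-sel_acc[rank_by_obj],
                              sizes[rank_by_obj],
                              seq_along(rank_by_obj))][1L]
    sig <- vapply(models, function(m) {
        p <- modelPairs(m)
        paste(sort(paste(p$pair_a, p$pair_b, p$case_direction)),
              collapse = ";")
    }, character(1))
    new("GreedyResult", models = models, selected = as.integer(pick),
        trainingObjective = train_obj, selectionAccuracy = sel_acc,
        selection = selection,
        duplicateGroups = as.integer(match(sig, unique(sig))))
}
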