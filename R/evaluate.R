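#' Confusion-matrix classification metrics
#'
#' Accuracy, specificity, sensitivity, NPV and PPV (case = positive) with
#' the convention that a zero-denominator NPV or PPV is 0, plus their
#' geometric mean sqrt(NPV x PPV) used as the greedy objective.
#'
#' @param labels true 0/1 labels (1 = case); both classes must occur.
#' @param predictions predicted 0/1 labels.
#' @return one-row data.frame: \code{acc}, \code{spe}, \code{sen},
#'   \code{npv}, \code{ppv}, \code{gmean_npv_ppv}, \code{tp}, \code{fp},
#'   \code{tn}, \code{fn}
#' @export
confusionMetrics <- function(labels, predictions) {
    if (length(labels) != length(predictions))
        stop("labels and predictions differ in length")
    labels <- as.integer(labels); predictions <- as.integer(predictions)
    if (!all(c(0L, 1L) %in% labels))
        stop("both classes must be present in labels")
    tp <- sum(predictions == 1L & labels == 1L)
    fp <- sum(predictions == 1L & labels == 0L)
    tn <- sum(predictions == 0L & labels == 0L)
    fn <- sum(predictions == 0L & labels == 1L)
    ratio <- function(num, den) if (den > 0) num / den else 0
    ppv <- ratio(tp, tp + fp); npv <- ratio(tn, tn + fn)
    data.frame(acc = (tp + tn) / length(labels),
               spe = ratio(tn, tn + fp), sen = ratio(tp, tp + fn),
               npv = npv, ppv = ppv, gmean_npv_ppv = sqrt(npv * ppv),
               tp = tp, fp = fp, tn = tn, fn = fn)
}

#' Rank-based AUC
#'
#' The probability that a randomly chosen case outscores a randomly chosen
#' control, with ties counted one half (the Mann-Whitney form of the area
#' under the ROC curve). Invariant to strictly increasing transforms of
#' the scores.
#'
#' @param labels true 0/1 labels (1 = case); both classes must occur.
#' @param scores continuous scores, larger = more case-like.
#' @return the AUC; constant scores give 0.5 with a warning
#' @export
aucFromScores <- function(labels, scores) {
    if (length(labels) != length(scores))
        stop("labels and scores differ in length")
    labels <- as.integer(labels)
    if (!all(c(0L, 1L) %in% labels))
        stop("both classes must be present in labels")
    if (length(unique(scores)) == 1L) {
        warning("scores are constant; AUC undefined, returning 0.5")
        return(0.5)
    }
    r <- rank(scores)
    n1 <- sum(labels == 1L); n0 <- sum(labels == 0L)
    (sum(r[labels == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' All performance metrics for a prediction set
#'
#' Combines \code{confusionMetrics} with the rank-based AUC when scores
#' are supplied.
#'
#' @param labels true 0/1 labels (1 = case).
#' @param predictions predicted 0/1 labels.
#' @param scores optional continuous scores for the AUC.
#' @return one-row data.frame; \code{auc} is \code{NA} without scores
#' @export
evalMetrics <- function(labels, predictions, scores = NULL) {
    out <- confusionMetrics(labels, predictions)
    out$auc <- if (is.null(scores)) NA_real_ else aucFromScores(labels, scores)
    out[, c("auc", setdiff(colnames(out), "auc"))]
}
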