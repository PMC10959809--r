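#' Binary REO feature encoding of candidate pairs
#'
#' Encodes each sample by one binary indicator per candidate pair: 1 iff
#' the sample's observed REO equals the pair's case-characteristic
#' direction. The encoding consults only within-sample orderings, so every
#' model fitted on it inherits the monotone-distortion invariance of the
#' pair statistics.
#'
#' @param x a \linkS4class{MirnaExperiment}
#' @param candidates candidate pairs from \code{selectCandidates}.
#' @param sampleIdsUse samples to encode.
#' @param caseLabel case phenotype label.
#' @return list with \code{features} (samples x pairs 0/1 matrix) and
#'   \code{labels} (1 = case)
#' @export
buildPairFeatures <- function(x, candidates, sampleIdsUse, caseLabel) {
    mm <- .matchMatrix(x, candidates, sampleIdsUse,
                       .caseDirection(candidates))
    list(features = t(mm),
         labels = as.integer(phenotype(x)[sampleIdsUse] == caseLabel))
}

#' LASSO-screened multiple linear regression
#'
#' Three-stage model reduction on the binary pair features: (1) an
#' L1-penalised linear-model path with five-fold cross-validation selects
#' the penalty, either at the minimal mean CV error (\code{"min"}) or by
#' the one-standard-error rule (\code{"1se"}); (2) the pairs with nonzero
#' coefficients enter an ordinary least-squares fit; (3) backward
#' single-term deletion (AIC-based \code{drop1} steps) repeats while it
#' lowers the AIC. Prediction thresholds the fitted value at
#' \code{classificationThreshold}.
#'
#' @param features samples x pairs binary matrix.
#' @param labels 0/1 labels (1 = case).
#' @param lambdaChoice \code{"min"} or \code{"1se"}.
#' @param nfolds cross-validation folds (default 5).
#' @param classificationThreshold fitted-value cut (default 0.5).
#' @param seed integer seed (controls the CV fold assignment).
#' @return list with \code{selected_pairs}, \code{coefficients},
#'   \code{lambda}, \code{aic}, \code{threshold} and the fitted \code{lm}
#' @export
fitLassoMlr <- function(features, labels, lambdaChoice = c("min", "1se"),
                        nfolds = 5L, classificationThreshold = 0.5,
                        seed = 1L) {
    lambdaChoice <- match.arg(lambdaChoice)
    if (min(table(labels)) < 2L) stop("need >= 2 samples per class")
    set.seed(seed)
    cvfit <- glmnet::cv.glmnet(features, labels, family = "gaussian",
                               nfolds = nfolds)
    lambda <- if (lambdaChoice == "min") cvfit$lambda.min else cvfit$lambda.1se
    beta <- as.matrix(stats::coef(cvfit, s = lambda))[-1L, 1L]
    keep <- names(beta)[beta != 0]
    if (length(keep) == 0L)
        stop("no nonzero coefficients at lambda.", lambdaChoice,
             "; try lambdaChoice = \"min\"")
    df <- data.frame(y = labels, features[, keep, drop = FALSE],
                     check.names = FALSE)
    fit <- stats::lm(y ~ ., data = df)
    fit <- stats::step(fit, direction = "backward", trace = 0)
    kept <- setdiff(names(stats::coef(fit)), "(Intercept)")
    kept <- gsub("^`|`$", "", kept)
    list(selected_pairs = kept,
         coefficients = stats::coef(fit),
         lambda = lambda, lambda_choice = lambdaChoice,
         aic = stats::AIC(fit),
         threshold = classificationThreshold,
         fit = fit)
}

#' Predict from a LASSO-screened linear model
#'
#' @param model output of \code{fitLassoMlr}.
#' @param features samples x pairs binary matrix (same column naming as in
#'   fitting).
#' @return data.frame: \code{score} (fitted value) and \code{label}
#'   (1 = case, score above the model's threshold)
#' @export
predictLinearModel <- function(model, features) {
    df <- as.data.frame(features, check.names = FALSE)
    score <- unname(stats::predict(model$fit, newdata = df))
    data.frame(score = score,
               label = as.integer(score > model$threshold))
}

#' Random forest on binary pair features
#'
#' Grows \code{nTrees} classification trees (default 500) on bootstrap
#' samples with random feature subsetting of size floor(sqrt(p)); reports
#' the out-of-bag error and the mean-decrease-in-Gini importance per pair.
#'
#' @param features samples x pairs binary matrix.
#' @param labels 0/1 labels (1 = case).
#' @param nTrees number of trees (default 500).
#' @param seed integer seed.
#' @return list with the fitted \code{forest}, \code{oobError} and
#'   \code{importance} (named, decreasing)
#' @export
fitRandomForest <- function(features, labels, nTrees = 500L, seed = 1L) {
    if (min(table(labels)) < 2L) stop("need >= 2 samples per class")
    set.seed(seed)
    forest <- randomForest::randomForest(x = features,
                                         y = factor(labels, levels = c(0, 1)),
                                         ntree = nTrees)
    imp <- forest$importance[, "MeanDecreaseGini"]
    list(forest = forest,
         oobError = unname(forest$err.rate[nTrees, "OOB"]),
         importance = sort(imp, decreasing = TRUE))
}

#' Predict from a fitted random forest
#'
#' @param model output of \code{fitRandomForest}.
#' @param features samples x pairs binary matrix.
#' @return data.frame: \code{score} (case vote fraction) and \code{label}
#' @export
predictForest <- function(model, features) {
    votes <- stats::predict(model$forest, features, type = "vote")[, "1"]
    data.frame(score = unname(votes),
               label = as.integer(stats::predict(model$forest,
                                                 features) == "1"))
}
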