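#' K-nearest-neighbour imputation of missing intensities
#'
#' Each missing cell is replaced by the plain mean of that miRNA's values
#' over the k nearest samples, where sample-to-sample distances are
#' root-mean-square Euclidean distances over the miRNAs both samples have
#' observed (the RMS form keeps distances comparable when the number of
#' shared miRNAs varies). Only samples in which the miRNA is observed are
#' eligible as neighbours. Non-missing cells are never changed.
#'
#' @param x a \linkS4class{MirnaExperiment}
#' @param k number of neighbours (default 10).
#' @return list with \code{experiment} (no missing values left) and
#'   \code{imputedCells} (count)
#' @export
imputeKnn <- function(x, k = 10L) {
    X <- exprValues(x)
    miss <- is.na(X)
    if (!any(miss))
        return(list(experiment = x, imputedCells = 0L))
    if (ncol(X) < k + 1L)
        stop("need at least k + 1 = ", k + 1L, " samples")
    dead <- rowSums(!miss) == 0L
    if (any(dead))
        stop("miRNA(s) missing in every sample: ",
             paste(rownames(X)[dead], collapse = ", "))

    # pairwise RMS distance over shared non-missing miRNAs
    W <- 1 - miss                       # observation indicator
    X0 <- X; X0[miss] <- 0
    P <- X0^2
    shared <- crossprod(W)              # t(W) %*% W
    ssq <- crossprod(W, P)              # sum over shared of x_t^2 (rows = s)
    cross <- crossprod(X0)
    d2 <- (ssq + t(ssq) - 2 * cross) / pmax(shared, 1L)
    d2[shared == 0L] <- Inf
    d2 <- pmax(d2, 0)
    diag(d2) <- Inf

    imputed <- 0L
    for (s in which(colSums(miss) > 0L)) {
        ord <- order(d2[, s])
        for (g in which(miss[, s])) {
            nb <- ord[!miss[g, ord]]
            if (length(nb) == 0L)
                stop("no donor sample observes miRNA ", rownames(X)[g])
            use <- nb[seq_len(min(k, length(nb)))]
            X[g, s] <- mean(X[g, use])
            imputed <- imputed + 1L
        }
    }
    list(experiment = MirnaExperiment(X, phenotype = unname(phenotype(x)),
                                      dataset = unname(datasetLabels(x))),
         imputedCells = imputed)
}

#' Correlation-based outlier removal within (dataset, phenotype) strata
#'
#' For every stratum with at least three samples, computes each sample's
#' mean Pearson correlation with the other stratum samples and removes, in
#' a single pass, samples whose mean correlation lies outside the stratum
#' mean plus/minus \code{sdMultiplier} stratum standard deviations.
#' Strata with fewer than three samples are skipped with a warning.
#'
#' @param x an imputed \linkS4class{MirnaExperiment}
#' @param sdMultiplier standard-deviation multiplier (default 2).
#' @return list with \code{experiment} and \code{report} (data.frame:
#'   removed sample, stratum, mean correlation, stratum bounds)
#' @export
removeOutliers <- function(x, sdMultiplier = 2) {
    X <- exprValues(x)
    if (anyNA(X)) stop("impute missing values first (see imputeKnn)")
    ph <- phenotype(x); ds <- datasetLabels(x)
    strata <- split(sampleIds(x), list(ds, ph), drop = TRUE)
    report <- data.frame(sample_id = character(), dataset = character(),
                         phenotype = character(), mean_correlation = double(),
                         lower = double(), upper = double())
    drop_ids <- character()
    for (ids in strata) {
        if (length(ids) < 3L) {
            warning("stratum '", ds[ids[1L]], "/", ph[ids[1L]],
                    "' has fewer than 3 samples; outlier filter skipped")
            next
        }
        cc <- stats::cor(X[, ids, drop = FALSE])
        mc <- (rowSums(cc) - 1) / (length(ids) - 1)   # mean cor, self excluded
        mu <- mean(mc); s <- stats::sd(mc)
        tol <- 1e-8 * max(1, abs(mu))
        lo <- mu - sdMultiplier * s - tol
        hi <- mu + sdMultiplier * s + tol
        bad <- ids[mc < lo | mc > hi]
        if (length(bad)) {
            drop_ids <- c(drop_ids, bad)
            report <- rbind(report, data.frame(
                sample_id = bad, dataset = unname(ds[bad]),
                phenotype = unname(ph[bad]),
                mean_correlation = unname(mc[match(bad, ids)]),
                lower = lo, upper = hi))
        }
    }
    keep <- setdiff(sampleIds(x), drop_ids)
    list(experiment = x[, keep], report = report)
}

#' Euclidean-distance duplicate removal
#'
#' Scans samples in input order and removes every sample whose Euclidean
#' distance to an already-kept sample is below \code{distanceThreshold}
#' (the first-encountered member of a duplicate group is kept). With
#' threshold 0 nothing is removed.
#'
#' @param x an imputed \linkS4class{MirnaExperiment}
#' @param distanceThreshold distance below which samples count as
#'   duplicates (default 1).
#' @return list with \code{experiment} and \code{report} (data.frame:
#'   removed sample, the kept sample it duplicates, their distance)
#' @export
removeDuplicates <- function(x, distanceThreshold = 1) {
    X <- exprValues(x)
    if (anyNA(X)) stop("impute missing values first (see imputeKnn)")
    n <- ncol(X)
    report <- data.frame(kept_id = character(), removed_id = character(),
                         distance = double())
    if (n < 2L || distanceThreshold <= 0)
        return(list(experiment = x, report = report))
    D <- as.matrix(stats::dist(t(X)))
    keep <- logical(n); keep[1L] <- TRUE
    for (j in seq_len(n)[-1L]) {
        dk <- D[j, keep]
        if (any(dk < distanceThreshold)) {
            w <- which.min(dk)
            report <- rbind(report, data.frame(
                kept_id = colnames(X)[keep][w],
                removed_id = colnames(X)[j],
                distance = unname(dk[w])))
        } else keep[j] <- TRUE
    }
    list(experiment = x[, keep], report = report)
}

#' Stratified train/test split
#'
#' Randomly assigns samples to training and test sets, stratified by case
#' versus non-case so both sets preserve the class balance.
#'
#' @param x a \linkS4class{MirnaExperiment}
#' @param caseLabel phenotype label of the case class.
#' @param trainFraction fraction assigned to training (default 0.7).
#' @param seed optional integer seed.
#' @param perPhenotype stratify by every phenotype label instead of the
#'   case/non-case dichotomy.
#' @return list with \code{train_ids} and \code{test_ids}
#' @export
splitTrainTest <- function(x, caseLabel, trainFraction = 0.7, seed = NULL,
                           perPhenotype = FALSE) {
    if (!is.null(seed)) set.seed(seed)
    ph <- phenotype(x)
    if (!any(ph == caseLabel) || !any(ph != caseLabel))
        stop("both case and non-case samples are required")
    strata <- if (perPhenotype) ph else ifelse(ph == caseLabel, "case", "control")
    groups <- split(sampleIds(x), strata)
    train <- character()
    for (ids in groups) {
        if (length(ids) < 2L)
            stop("a stratum with fewer than 2 samples cannot be split")
        ntr <- round(trainFraction * length(ids))
        if (ntr >= length(ids) || ntr < 1L)
            stop("trainFraction ", trainFraction, " leaves an empty ",
                 "train or test set in a stratum of ", length(ids))
        train <- c(train, sample(ids, ntr))
    }
    all_ids <- sampleIds(x)
    list(train_ids = all_ids[all_ids %in% train],
         test_ids = setdiff(all_ids, train))
}
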