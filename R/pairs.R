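#' All unordered miRNA pairs
#'
#' Enumerates the C(n, 2) unordered pairs of miRNA identifiers in canonical
#' form (\code{pair_a} lexicographically before \code{pair_b}),
#' deterministically ordered.
#'
#' @param mirnaIds character vector of unique identifiers (n >= 2).
#' @return data.frame with columns \code{pair_a}, \code{pair_b}
#' @examples
#' enumeratePairs(c("miR-21", "miR-155", "miR-10b"))
#' @export
enumeratePairs <- function(mirnaIds) {
    if (anyDuplicated(mirnaIds)) stop("miRNA ids must be unique")
    n <- length(mirnaIds)
    if (n < 2L) stop("need at least 2 miRNAs to form a pair")
    ids <- sort(mirnaIds)
    i <- rep.int(seq_len(n - 1L), times = (n - 1L):1L)
    j <- sequence((n - 1L):1L) + i
    data.frame(pair_a = ids[i], pair_b = ids[j])
}

# counts K[i, j] = number of samples with X[i, s] > X[j, s] (strict;
# ties count towards <=). X must have no missing values.
.pairGtCounts <- function(X) {
    m <- nrow(X)
    K <- matrix(0L, m, m, dimnames = list(rownames(X), rownames(X)))
    tX <- t(X)
    for (i in seq_len(m - 1L)) {
        rest <- (i + 1L):m
        cmp <- tX[, rest, drop = FALSE] < X[i, ]   # sample-major comparison
        gt <- colSums(cmp)
        K[i, rest] <- gt
        K[rest, i] <- colSums(tX[, rest, drop = FALSE] > X[i, ])
    }
    K
}

.checkComplete <- function(X) {
    if (anyNA(X))
        stop("expression values contain missing entries; run imputeKnn first")
}

#' Within-group PCT of a pair
#'
#' Fraction of the given samples with strictly E_a > E_b (PCT = k/m); ties
#' count towards E_a <= E_b.
#'
#' @param x a \linkS4class{MirnaExperiment}
#' @param pairA,pairB miRNA identifiers.
#' @param sampleIdsUse samples forming the group.
#' @return a fraction in [0, 1]
#' @export
computePct <- function(x, pairA, pairB, sampleIdsUse) {
    if (length(sampleIdsUse) == 0L) stop("empty sample list")
    X <- exprValues(x)[, sampleIdsUse, drop = FALSE]
    if (!all(c(pairA, pairB) %in% rownames(X)))
        stop("miRNA(s) not present: ",
             paste(setdiff(c(pairA, pairB), rownames(X)), collapse = ", "))
    .checkComplete(X[c(pairA, pairB), , drop = FALSE])
    mean(X[pairA, ] > X[pairB, ])
}

#' Stable pairs in a control group
#'
#' A pair is stable when the PCT of its majority REO direction in the
#' control group meets the threshold; both directions are screened. The
#' returned \code{direction} is the stable (control) REO read as
#' E_a (direction) E_b, and \code{pct_control} is always PCT(E_a > E_b).
#'
#' @param x a \linkS4class{MirnaExperiment}
#' @param controlIds control-group samples.
#' @param pctThreshold stable-PCT threshold (default 0.80).
#' @param mirnaSubset restrict screening to these miRNAs.
#' @return data.frame: \code{pair_a}, \code{pair_b}, \code{direction},
#'   \code{n1}, \code{n2}, \code{pct_control}
#' @export
findStablePairs <- function(x, controlIds, pctThreshold = 0.80,
                            mirnaSubset = NULL) {
    if (length(controlIds) == 0L) stop("control group is empty")
    ids <- if (is.null(mirnaSubset)) mirnaIds(x) else mirnaSubset
    X <- exprValues(x)[sort(ids), controlIds, drop = FALSE]
    .checkComplete(X)
    K <- .pairGtCounts(X)
    m <- length(controlIds)
    ut <- which(upper.tri(K))
    n1 <- K[ut]
    pct <- n1 / m
    keep <- pct >= pctThreshold | (1 - pct) >= pctThreshold
    ut <- ut[keep]; n1 <- n1[keep]; pct <- pct[keep]
    ii <- ((ut - 1L) %% nrow(K)) + 1L
    jj <- ((ut - 1L) %/% nrow(K)) + 1L
    data.frame(pair_a = rownames(K)[ii], pair_b = rownames(K)[jj],
               direction = ifelse(pct >= pctThreshold, ">", "<="),
               n1 = n1, n2 = m - n1, pct_control = pct)
}

#' Two-sided Fisher exact test for REO reversal
#'
#' Exact two-sided p for the 2x2 table [[n1, n2], [m1, m2]] of REO counts
#' (rows: control/case; columns: E_a > E_b / E_a <= E_b), computed by
#' summing hypergeometric point probabilities not exceeding the observed
#' one (the classic two-sided convention). Vectorised over tables.
#'
#' @param n1,n2 control counts for the two REO directions.
#' @param m1,m2 case counts for the two REO directions.
#' @return p-values, one per table
#' @export
fisherReversalTest <- function(n1, n2, m1, m2) {
    len <- length(n1)
    if (!all(lengths(list(n2, m1, m2)) == len))
        stop("n1, n2, m1, m2 must have equal length")
    if (any(c(n1, n2, m1, m2) < 0)) stop("counts must be non-negative")
    tot <- n1 + n2 + m1 + m2
    if (any(tot == 0L)) stop("all-zero table")
    r1 <- n1 + n2; r2 <- m1 + m2; c1 <- n1 + m1
    p <- numeric(len)
    key <- paste(r1, r2, c1)
    for (k in unique(key)) {
        sel <- which(key == k)
        R1 <- r1[sel[1L]]; R2 <- r2[sel[1L]]; C1 <- c1[sel[1L]]
        lo <- max(0L, C1 - R2); hi <- min(C1, R1)
        dh <- stats::dhyper(lo:hi, R1, R2, C1)
        pobs <- dh[n1[sel] - lo + 1L]
        p[sel] <- vapply(pobs, function(po)
            sum(dh[dh <= po * (1 + 1e-7)]), numeric(1))
    }
    pmin(p, 1)
}

#' Benjamini-Hochberg adjustment
#'
#' Standard step-up false-discovery-rate adjustment; order-preserving,
#' monotone, capped at 1.
#'
#' @param p p-values in [0, 1].
#' @return adjusted p-values in input order
#' @export
bhAdjust <- function(p) {
    if (any(p < 0 | p > 1, na.rm = TRUE) || anyNA(p))
        stop("p-values must lie in [0, 1]")
    stats::p.adjust(p, method = "BH")
}

#' Reversed pairs among stable pairs
#'
#' Completes the pair statistics of the stable pairs with case-group REO
#' counts, the two-sided Fisher exact p, its BH adjustment across all
#' stable pairs tested, and the degree of reversal
#' delta PCT = PCT_control(E_a > E_b) - PCT_case(E_a > E_b).
#' Pairs with adjusted p below \code{fdrThreshold} are returned as
#' reversed.
#'
#' @param x the \linkS4class{MirnaExperiment} the stable pairs came from.
#' @param stable output of \code{findStablePairs}.
#' @param caseIds case-group samples.
#' @param fdrThreshold BH-adjusted significance cut (default 0.05).
#' @param allStats return all tested pairs instead of the significant ones.
#' @return data.frame of pair statistics: \code{pair_a}, \code{pair_b},
#'   \code{direction}, \code{n1}, \code{n2}, \code{m1}, \code{m2},
#'   \code{pct_control}, \code{pct_case}, \code{delta_pct}, \code{p_value},
#'   \code{p_adjusted}
#' @export
findReversedPairs <- function(x, stable, caseIds, fdrThreshold = 0.05,
                              allStats = FALSE) {
    out <- stable[0, ]
    if (nrow(stable) == 0L) {
        cols <- c("m1", "m2", "pct_case", "delta_pct", "p_value", "p_adjusted")
        for (cc in cols) out[[cc]] <- numeric()
        return(out)
    }
    if (length(caseIds) == 0L) stop("case group is empty")
    X <- exprValues(x)
    ia <- match(stable$pair_a, rownames(X))
    ib <- match(stable$pair_b, rownames(X))
    if (anyNA(ia) || anyNA(ib)) stop("stable pairs reference unknown miRNAs")
    Xa <- X[ia, caseIds, drop = FALSE]
    Xb <- X[ib, caseIds, drop = FALSE]
    .checkComplete(Xa); .checkComplete(Xb)
    m1 <- as.integer(rowSums(Xa > Xb))
    mC <- length(caseIds)
    res <- stable
    res$m1 <- m1
    res$m2 <- mC - m1
    res$pct_case <- m1 / mC
    res$delta_pct <- res$pct_control - res$pct_case
    res$p_value <- fisherReversalTest(res$n1, res$n2, res$m1, res$m2)
    res$p_adjusted <- bhAdjust(res$p_value)
    if (allStats) res else res[res$p_adjusted < fdrThreshold, , drop = FALSE]
}

#' Candidate pairs by degree of reversal
#'
#' Keeps reversed pairs whose degree of reversal meets the threshold:
#' delta PCT >= threshold for pairs stable in the E_a > E_b direction and
#' delta PCT <= -threshold for the mirrored direction. Sorted by
#' |delta PCT| decreasing (ties by pair id for determinism).
#'
#' @param reversed output of \code{findReversedPairs}.
#' @param deltaPctThreshold candidacy threshold (default 0.7).
#' @return the qualifying rows of \code{reversed}, sorted
#' @export
selectCandidates <- function(reversed, deltaPctThreshold = 0.7) {
    if (nrow(reversed) == 0L) return(reversed)
    keep <- (reversed$direction == ">" &
                 reversed$delta_pct >= deltaPctThreshold) |
            (reversed$direction == "<=" &
                 reversed$delta_pct <= -deltaPctThreshold)
    out <- reversed[keep, , drop = FALSE]
    out[order(-abs(out$delta_pct), out$pair_a, out$pair_b), , drop = FALSE]
}
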