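#' Hypergeometric upper tail P(X >= k)
#'
#' Survival-function form of the enrichment probability
#' P = 1 - sum_{i=0}^{k-1} C(n, i) C(M - n, N - i) / C(M, N)
#' for X hypergeometric with population size M, n successes and N draws,
#' evaluated via \code{phyper(..., lower.tail = FALSE)} so tiny tails are
#' not lost to cancellation. Vectorised; k = 0 gives 1.
#'
#' @param M population size (stable pairs).
#' @param N draws (reversed pairs).
#' @param n successes (stable pairs involving the miRNA in one direction).
#' @param k observed count (reversed pairs involving the miRNA).
#' @return P(X >= k)
#' @export
hypergeomUpperTail <- function(M, N, n, k) {
    len <- max(lengths(list(M, N, n, k)))
    M <- rep_len(M, len); N <- rep_len(N, len)
    n <- rep_len(n, len); k <- rep_len(k, len)
    if (any(k < 0 | k > N | N > M | n > M | n < 0))
        stop("need 0 <= k <= N <= M and 0 <= n <= M")
    stats::phyper(k - 1, n, M - n, N, lower.tail = FALSE)
}

#' Directional pair memberships of one miRNA
#'
#' Counts, for a given miRNA, the stable and reversed pairs containing it
#' in each orientation, expressed relative to the named miRNA: the
#' "down" orientation has the miRNA on the larger side of the control REO
#' (its reversal means loss of expression in cases), the "up" orientation
#' on the smaller side.
#'
#' @param stable data.frame from \code{findStablePairs} (or the stable
#'   columns of \code{findReversedPairs} output).
#' @param reversed data.frame of reversed pairs (subset of \code{stable}).
#' @param mirnaId the miRNA.
#' @return named integer vector: \code{n_up}, \code{n_down}, \code{k_up},
#'   \code{k_down}
#' @export
countPairMemberships <- function(stable, reversed, mirnaId) {
    larger <- function(df, g)
        (df$pair_a == g & df$direction == ">") |
        (df$pair_b == g & df$direction == "<=")
    smaller <- function(df, g)
        (df$pair_a == g & df$direction == "<=") |
        (df$pair_b == g & df$direction == ">")
    c(n_up = sum(smaller(stable, mirnaId)),
      n_down = sum(larger(stable, mirnaId)),
      k_up = sum(smaller(reversed, mirnaId)),
      k_down = sum(larger(reversed, mirnaId)))
}

#' Differential miRNAs from stable and reversed pair sets
#'
#' For every miRNA appearing in at least one stable pair, tests whether it
#' is enriched among the reversed pairs, separately for the two
#' orientations: with M stable pairs overall, N reversed pairs, n stable
#' pairs carrying the miRNA in one orientation and k of them reversed,
#' P = P(X >= k) under the hypergeometric model. The smaller of P_down and
#' P_up sets the significance level and the regulation direction; BH
#' adjustment is applied across miRNAs and miRNAs with adjusted p below
#' \code{fdrThreshold} are flagged differential.
#'
#' @param stable data.frame of stable pairs.
#' @param reversed data.frame of reversed pairs (subset of \code{stable}).
#' @param fdrThreshold BH-adjusted cut (default 0.05).
#' @return data.frame: \code{mirna_id}, \code{n_up}, \code{n_down},
#'   \code{k_up}, \code{k_down}, \code{p_up}, \code{p_down}, \code{p_min},
#'   \code{direction}, \code{p_adjusted}, \code{differential}; ordered by
#'   \code{p_adjusted} then id
#' @export
identifyDiffMirnas <- function(stable, reversed, fdrThreshold = 0.05) {
    if (nrow(stable) == 0L) stop("no stable pairs supplied")
    M <- nrow(stable); N <- nrow(reversed)
    tally <- function(df) {
        lg <- c(df$pair_a[df$direction == ">"], df$pair_b[df$direction == "<="])
        sm <- c(df$pair_a[df$direction == "<="], df$pair_b[df$direction == ">"])
        list(larger = table(lg), smaller = table(sm))
    }
    ts <- tally(stable); tr <- tally(reversed)
    ids <- sort(unique(c(stable$pair_a, stable$pair_b)))
    pick <- function(tb, ids) {
        v <- as.integer(tb[ids]); v[is.na(v)] <- 0L; v
    }
    n_down <- pick(ts$larger, ids); n_up <- pick(ts$smaller, ids)
    k_down <- pick(tr$larger, ids); k_up <- pick(tr$smaller, ids)
    p_down <- ifelse(k_down == 0L, 1,
                     hypergeomUpperTail(M, N, n_down, k_down))
    p_up <- ifelse(k_up == 0L, 1, hypergeomUpperTail(M, N, n_up, k_up))
    p_min <- pmin(p_down, p_up)
    res <- data.frame(mirna_id = ids, n_up = n_up, n_down = n_down,
                      k_up = k_up, k_down = k_down, p_up = p_up,
                      p_down = p_down, p_min = p_min,
                      direction = ifelse(p_down <= p_up, "down", "up"),
                      p_adjusted = bhAdjust(p_min))
    res$differential <- res$p_adjusted < fdrThreshold
    res[order(res$p_adjusted, res$mirna_id), , drop = FALSE]
}

#' tSNE embedding over a miRNA subset
#'
#' Embeds samples in 2-D with exact t-distributed stochastic neighbour
#' embedding computed on within-sample ranks of the selected miRNAs, so
#' the input carries exactly the ordering information the pair statistics
#' use and the embedding is invariant to monotone per-sample distortions.
#' Reports the silhouette score of the case versus non-case grouping on
#' the embedded coordinates.
#'
#' @param x an imputed \linkS4class{MirnaExperiment}
#' @param mirnaSubset miRNAs to embed over (e.g. the differential set).
#' @param caseLabel case phenotype label for the silhouette.
#' @param seed integer seed (tSNE is stochastic).
#' @param perplexity tSNE perplexity; capped at (n_samples - 1) / 3.
#' @return list with \code{coordinates} (data.frame \code{sample_id},
#'   \code{tsne1}, \code{tsne2}, \code{phenotype}) and \code{silhouette}
#' @export
embedTsne <- function(x, mirnaSubset, caseLabel, seed = 1L,
                      perplexity = 30) {
    if (length(mirnaSubset) == 0L) stop("mirnaSubset is empty")
    missing_ids <- setdiff(mirnaSubset, mirnaIds(x))
    if (length(missing_ids))
        stop("miRNA(s) not present: ", paste(missing_ids, collapse = ", "))
    if (ncol(x) < 10L) stop("need at least 10 samples to embed")
    X <- exprValues(x)[mirnaSubset, , drop = FALSE]
    .checkComplete(X)
    R <- apply(X, 2L, rank)                      # within-sample ranks
    perp <- min(perplexity, floor((ncol(X) - 1) / 3))
    set.seed(seed)
    fit <- Rtsne::Rtsne(t(R), dims = 2, perplexity = perp, theta = 0,
                        check_duplicates = FALSE, pca = TRUE,
                        max_iter = 500, verbose = FALSE)
    coords <- data.frame(sample_id = sampleIds(x),
                         tsne1 = fit$Y[, 1L], tsne2 = fit$Y[, 2L],
                         phenotype = unname(phenotype(x)))
    grp <- as.integer(phenotype(x) == caseLabel) + 1L
    sil <- cluster::silhouette(grp, stats::dist(fit$Y))
    list(coordinates = coords, silhouette = mean(sil[, "sil_width"]))
}
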