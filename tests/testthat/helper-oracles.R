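# Independent brute-force oracles used to check the package's statistics.
# These deliberately share no code with the implementation.

# PCT by an explicit per-sample loop
brutePct <- function(X, a, b, samples) {
    k <- 0L
    for (s in samples) if (X[a, s] > X[b, s]) k <- k + 1L
    k / length(samples)
}

# two-sided Fisher exact p by enumeration over all tables with the
# observed margins, summing probabilities <= the observed one
bruteFisher <- function(n1, n2, m1, m2) {
    r1 <- n1 + n2; r2 <- m1 + m2; c1 <- n1 + m1
    lo <- max(0L, c1 - r2); hi <- min(c1, r1)
    probs <- vapply(lo:hi, function(a) {
        b <- r1 - a; cc <- c1 - a; d <- r2 - cc
        exp(lchoose(r1, a) + lchoose(r2, cc) - lchoose(r1 + r2, c1))
    }, numeric(1))
    pobs <- probs[n1 - lo + 1L]
    min(1, sum(probs[probs <= pobs * (1 + 1e-7)]))
}

# P(X >= k) for a hypergeometric by direct summation of choose() terms
bruteHyperUpper <- function(M, N, n, k) {
    if (k == 0L) return(1)
    i <- k:min(n, N)
    if (length(i) == 0L || min(n, N) < k) return(0)
    sum(exp(lchoose(n, i) + lchoose(M - n, N - i) - lchoose(M, N)))
}

# AUC by comparing every case/control score pair, ties counted half
bruteAuc <- function(labels, scores) {
    cs <- scores[labels == 1L]; ct <- scores[labels == 0L]
    tot <- 0
    for (a in cs) for (b in ct)
        tot <- tot + (a > b) + 0.5 * (a == b)
    tot / (length(cs) * length(ct))
}

# a random strictly increasing transform, applied per sample (column)
applyMonotone <- function(x, seed) {
    set.seed(seed)
    X <- exprValues(x)
    for (j in seq_len(ncol(X))) {
        a <- runif(1, -5, 5); b <- runif(1, 0.1, 3); cc <- runif(1, 0.01, 1)
        X[, j] <- a + b * X[, j] + cc * X[, j]^3
    }
    MirnaExperiment(X, phenotype = unname(phenotype(x)),
                    dataset = unname(datasetLabels(x)))
}

# small labelled experiment with iid noise around per-miRNA means
makeToyExperiment <- function(nMirnas = 12L, nCase = 15L, nCtrl = 15L,
                              seed = 1L, sd = 1) {
    set.seed(seed)
    mu <- runif(nMirnas, 4, 8)
    n <- nCase + nCtrl
    X <- matrix(mu, nMirnas, n) + matrix(rnorm(nMirnas * n, sd = sd),
                                         nMirnas, n)
    dimnames(X) <- list(sprintf("miR-%03d", seq_len(nMirnas)),
                        sprintf("S%03d", seq_len(n)))
    MirnaExperiment(X, phenotype = rep(c("BrC", "Ctrl"), c(nCase, nCtrl)),
                    dataset = rep("D1", n))
}

caseControlIds <- function(x, caseLabel = "BrC") {
    ph <- phenotype(x)
    list(case = names(ph)[ph == caseLabel],
         control = names(ph)[ph != caseLabel])
}
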