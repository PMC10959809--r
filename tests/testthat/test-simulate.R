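nullDesign <- function(seed, nMirnas = 40L) {
    simulationDesign(nMirnas = nMirnas,
                     phenotypes = data.frame(label = c("BrC", "Ctrl"),
                                             n = c(200L, 200L)),
                     nDatasets = 2L, nPlantedReversals = 0L,
                     missingRate = 0, batchMonotone = FALSE,
                     rngSeed = seed)
}

pairDeltas <- function(x, caseLabel = "BrC") {
    g <- caseControlIds(x, caseLabel)
    stable <- findStablePairs(x, g$control, pctThreshold = 0)  # all pairs
    all_stats <- findReversedPairs(x, stable, g$case, allStats = TRUE)
    all_stats
}

test_that("a design without planted reversals yields no reversal signal", {
    sim <- simulateCohort(nullDesign(11L))
    st <- pairDeltas(sim$experiment)
    expect_identical(nrow(plantedPairs(sim$truth)), 0L)
    expect_lt(max(abs(st$delta_pct)), 0.15)
})

test_that("strengths 1.0 give planted pairs a degree of reversal of exactly 1", {
    d <- simulationDesign(nMirnas = 60L,
                          phenotypes = data.frame(label = c("BrC", "Ctrl"),
                                                  n = c(80L, 120L)),
                          nDatasets = 2L, nPlantedReversals = 5L,
                          reversalStrength = 1, stableStrength = 1,
                          missingRate = 0, rngSeed = 5L)
    sim <- simulateCohort(d)
    st <- pairDeltas(sim$experiment)
    pp <- plantedPairs(sim$truth)
    key <- paste(st$pair_a, st$pair_b)
    for (r in seq_len(nrow(pp))) {
        row <- st[key == paste(pp$mirna_a[r], pp$mirna_b[r]), ]
        expect_identical(abs(row$delta_pct), 1)
        # sign matches the planted control direction
        expect_identical(row$delta_pct, if (pp$control_direction[r] == ">") 1 else -1)
    }
})

test_that("per-dataset monotone distortion changes no REO statistic", {
    base <- simulationDesign(nMirnas = 30L,
                             phenotypes = data.frame(label = c("BrC", "Ctrl"),
                                                     n = c(60L, 60L)),
                             nDatasets = 3L, nPlantedReversals = 3L,
                             missingRate = 0, rngSeed = 21L,
                             batchMonotone = TRUE)
    off <- base; off@batchMonotone <- FALSE
    son <- simulateCohort(base); soff <- simulateCohort(off)
    a <- pairDeltas(son$experiment); b <- pairDeltas(soff$experiment)
    expect_identical(a$n1, b$n1)
    expect_identical(a$m1, b$m1)
    expect_equal(a$delta_pct, b$delta_pct)
    # but the intensities themselves did change
    expect_false(isTRUE(all.equal(exprValues(son$experiment),
                                  exprValues(soff$experiment))))
})

test_that("swapping case and control labels negates every planted delta PCT", {
    d <- simulationDesign(nMirnas = 30L,
                          phenotypes = data.frame(label = c("BrC", "Ctrl"),
                                                  n = c(70L, 70L)),
                          nDatasets = 2L, nPlantedReversals = 4L,
                          missingRate = 0, rngSeed = 9L)
    sim <- simulateCohort(d)
    x <- sim$experiment
    g <- caseControlIds(x)
    pp <- plantedPairs(sim$truth)
    for (r in seq_len(nrow(pp))) {
        fwd <- computePct(x, pp$mirna_a[r], pp$mirna_b[r], g$control) -
            computePct(x, pp$mirna_a[r], pp$mirna_b[r], g$case)
        rev <- computePct(x, pp$mirna_a[r], pp$mirna_b[r], g$case) -
            computePct(x, pp$mirna_a[r], pp$mirna_b[r], g$control)
        expect_equal(rev, -fwd)
        expect_gt(abs(fwd), 0.7)
    }
})

test_that("injected outliers are the least-correlated group members", {
    x <- makeToyExperiment(nMirnas = 40L, nCase = 0L, nCtrl = 50L,
                           seed = 2L, sd = 0.3)
    inj <- injectOutliers(x, 2L, seed = 4L)
    cc <- cor(exprValues(inj$experiment))
    mean_cor <- (rowSums(cc) - 1) / (ncol(cc) - 1)
    worst2 <- names(sort(mean_cor))[1:2]
    expect_setequal(worst2, inj$outlierIds)

    expect_identical(injectOutliers(x, 0L)$experiment, x)

    X <- exprValues(x); X[3, 7] <- NA
    xm <- MirnaExperiment(X, unname(phenotype(x)), unname(datasetLabels(x)))
    injm <- injectOutliers(xm, 5L, seed = 1L)
    expect_identical(is.na(exprValues(injm$experiment)), is.na(X))

    expect_error(injectOutliers(x, 100L), "pool")
})

test_that("injected duplicates sit within epsilon of their source", {
    x <- makeToyExperiment(nMirnas = 25L, nCase = 10L, nCtrl = 10L, seed = 6L)
    exact <- injectDuplicates(x, 3L, epsilon = 0, seed = 8L)
    for (r in seq_len(3L)) {
        src <- exact$duplicatePairs$source_id[r]
        dup <- exact$duplicatePairs$dup_id[r]
        expect_identical(unname(exprValues(exact$experiment)[, dup]),
                         unname(exprValues(exact$experiment)[, src]))
    }
    noisy <- injectDuplicates(x, 4L, epsilon = 0.5, seed = 8L)
    X <- exprValues(noisy$experiment)
    d <- sqrt(colSums((X[, noisy$duplicatePairs$dup_id, drop = FALSE] -
                           X[, noisy$duplicatePairs$source_id, drop = FALSE])^2))
    expect_true(all(d < 1))
    expect_identical(injectDuplicates(x, 0L)$experiment, x)
})

test_that("infeasible designs are rejected", {
    expect_error(simulationDesign(nMirnas = 10L, nPlantedReversals = 6L),
                 "disjoint")
    expect_error(simulationDesign(reversalStrength = 0.4), "reversalStrength")
    d <- simulationDesign(nMirnas = 20L,
                          phenotypes = data.frame(label = c("BrC", "Ctrl"),
                                                  n = c(3L, 3L)),
                          nPlantedReversals = 0L, nOutliers = 10L)
    expect_error(simulateCohort(d), "outliers")
})
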