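test_that("pair enumeration is canonical, complete and guarded", {
    p <- enumeratePairs(c("miR-21", "miR-155", "miR-10b"))
    expect_identical(nrow(p), 3L)
    expect_true(all(p$pair_a < p$pair_b))
    expect_identical(nrow(enumeratePairs(c("a", "b"))), 1L)
    expect_error(enumeratePairs("a"), "at least 2")
    expect_error(enumeratePairs(c("a", "a")), "unique")
    n <- 100L
    expect_identical(nrow(enumeratePairs(sprintf("m%03d", 1:n))),
                     as.integer(choose(n, 2L)))
})

test_that("PCT equals the brute-force per-sample count, ties towards <=", {
    x <- makeToyExperiment(nMirnas = 4L, nCase = 3L, nCtrl = 2L, seed = 1L)
    X <- exprValues(x)
    X[1, ] <- X[2, ] + c(1, 1, 1, 1, -1)   # 4 of 5 samples a > b
    x <- MirnaExperiment(X, unname(phenotype(x)), unname(datasetLabels(x)))
    expect_equal(computePct(x, rownames(X)[1], rownames(X)[2],
                            sampleIds(x)), 0.8)
    X[1, ] <- X[2, ]                       # all ties -> PCT 0
    x <- MirnaExperiment(X, unname(phenotype(x)), unname(datasetLabels(x)))
    expect_equal(computePct(x, rownames(X)[1], rownames(X)[2],
                            sampleIds(x)), 0)

    for (seed in 1:5) {
        set.seed(seed)
        Y <- matrix(round(rnorm(20 * 30), 1), 20, 30,
                    dimnames = list(sprintf("g%02d", 1:20),
                                    sprintf("s%02d", 1:30)))
        y <- MirnaExperiment(Y, rep(c("BrC", "C"), 15), rep("D", 30))
        pick <- expand.grid(a = 1:6, b = 7:12)
        for (r in sample(nrow(pick), 10)) {
            a <- rownames(Y)[pick$a[r]]; b <- rownames(Y)[pick$b[r]]
            expect_identical(computePct(y, a, b, sampleIds(y)),
                             brutePct(Y, a, b, colnames(Y)))
        }
    }
    expect_error(computePct(x, "miR-001", "miR-002", character()), "empty")
})

test_that("stable-pair screening finds planted pairs in their control direction", {
    d <- simulationDesign(nMirnas = 40L,
                          phenotypes = data.frame(label = c("BrC", "Ctrl"),
                                                  n = c(40L, 60L)),
                          nDatasets = 2L, nPlantedReversals = 4L,
                          reversalStrength = 1, stableStrength = 1,
                          missingRate = 0, rngSeed = 17L)
    sim <- simulateCohort(d)
    g <- caseControlIds(sim$experiment)
    st <- findStablePairs(sim$experiment, g$control, 0.8)
    pp <- plantedPairs(sim$truth)
    key <- paste(st$pair_a, st$pair_b, st$direction)
    expect_true(all(paste(pp$mirna_a, pp$mirna_b,
                          pp$control_direction) %in% key))

    # a threshold of 1 with one discordant sample per pair finds nothing
    X <- matrix(c(2, 1, 1, 2), 2, 2,
                dimnames = list(c("a", "b"), c("s1", "s2")))
    y <- MirnaExperiment(X, c("A", "A"), c("D", "D"))
    expect_identical(nrow(findStablePairs(y, c("s1", "s2"), 1)), 0L)
    expect_identical(nrow(findStablePairs(y, c("s1", "s2"), 0.6)), 0L)
})

test_that("the reversal test matches fisher.test and exact enumeration", {
    expect_equal(fisherReversalTest(10, 0, 0, 10), 2 / choose(20, 10),
                 tolerance = 1e-12)
    expect_equal(fisherReversalTest(10, 0, 0, 10), 1.0825e-5,
                 tolerance = 1e-4)
    expect_equal(fisherReversalTest(5, 5, 5, 5), 1)

    set.seed(3)
    for (i in 1:40) {
        n1 <- sample(0:12, 1); n2 <- sample(0:12, 1)
        m1 <- sample(0:12, 1); m2 <- sample(0:12, 1)
        if (n1 + n2 + m1 + m2 == 0) next
        expect_equal(fisherReversalTest(n1, n2, m1, m2),
                     bruteFisher(n1, n2, m1, m2), tolerance = 1e-12)
        if (n1 + n2 > 0 && m1 + m2 > 0 && n1 + m1 > 0 && n2 + m2 > 0)
            expect_equal(fisherReversalTest(n1, n2, m1, m2),
                         fisher.test(matrix(c(n1, n2, m1, m2), 2,
                                            byrow = TRUE))$p.value,
                         tolerance = 1e-9)
    }
    # larger tables against fisher.test
    for (i in 1:10) {
        t <- sample(0:200, 4, replace = TRUE)
        if (sum(t[1:2]) == 0 || sum(t[3:4]) == 0 ||
            sum(t[c(1, 3)]) == 0 || sum(t[c(2, 4)]) == 0) next
        expect_equal(fisherReversalTest(t[1], t[2], t[3], t[4]),
                     fisher.test(matrix(t, 2, byrow = TRUE))$p.value,
                     tolerance = 1e-8)
    }
    expect_error(fisherReversalTest(0, 0, 0, 0), "all-zero")
})

test_that("BH adjustment is the textbook step-up", {
    expect_identical(bhAdjust(0.03), 0.03)
    expect_equal(bhAdjust(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
    expect_equal(bhAdjust(rep(0.2, 5)), rep(0.2, 5))
    # hand step-up for a scrambled vector
    p <- c(0.04, 0.001, 0.9, 0.02)
    o <- order(p)
    stepup <- p[o] * length(p) / seq_along(p)
    stepup <- rev(cummin(rev(stepup)))
    expect_equal(bhAdjust(p)[o], pmin(stepup, 1))
    expect_error(bhAdjust(c(0.1, 1.2)), "\\[0, 1\\]")
})

test_that("reversed-pair discovery controls the false positive rate on null data", {
    d <- simulationDesign(nMirnas = 46L,   # 1035 pairs
                          phenotypes = data.frame(label = c("BrC", "Ctrl"),
                                                  n = c(100L, 100L)),
                          nDatasets = 2L, nPlantedReversals = 0L,
                          missingRate = 0, rngSeed = 23L)
    sim <- simulateCohort(d)
    g <- caseControlIds(sim$experiment)
    st <- findStablePairs(sim$experiment, g$control, 0.8)
    rev <- findReversedPairs(sim$experiment, st, g$case, 0.05)
    expect_lte(nrow(rev) / max(nrow(st), 1L), 0.05 + 0.02)

    empty <- findReversedPairs(sim$experiment, st[0, ], g$case)
    expect_identical(nrow(empty), 0L)
})

test_that("candidate selection applies the delta-PCT rule symmetrically", {
    rev <- data.frame(pair_a = c("a", "b", "c", "d"),
                      pair_b = c("x", "y", "z", "w"),
                      direction = c(">", "<=", ">", "<="),
                      delta_pct = c(1, -0.85, 0.4, 0.75),
                      pct_control = 0, pct_case = 0,
                      n1 = 0, n2 = 0, m1 = 0, m2 = 0,
                      p_value = 0, p_adjusted = 0)
    got <- selectCandidates(rev, 0.7)
    # 'd' is <=-stable with positive delta: not a reversal in its direction
    expect_identical(got$pair_a, c("a", "b"))
    expect_identical(got$delta_pct, c(1, -0.85))      # |delta| descending
    expect_identical(nrow(selectCandidates(rev, 1.01)), 0L)
    expect_identical(
        order(-abs(got$delta_pct)), seq_len(nrow(got)))
})

test_that("every pair statistic is invariant to monotone per-sample distortion", {
    x <- makeToyExperiment(nMirnas = 15L, nCase = 20L, nCtrl = 20L,
                           seed = 19L)
    g <- caseControlIds(x)
    st <- findStablePairs(x, g$control, 0.6)
    all1 <- findReversedPairs(x, st, g$case, allStats = TRUE)
    for (trial in 1:5) {
        y <- applyMonotone(x, seed = 100 + trial)
        st2 <- findStablePairs(y, g$control, 0.6)
        all2 <- findReversedPairs(y, st2, g$case, allStats = TRUE)
        expect_identical(all1, all2)
    }
})
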