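test_that("hypergeometric upper tail matches direct summation", {
    expect_identical(hypergeomUpperTail(10, 4, 5, 0), 1)
    expect_equal(hypergeomUpperTail(10, 4, 5, 3), 55 / 210,
                 tolerance = 1e-12)
    for (M in c(5L, 9L, 14L)) {
        for (N in seq(0L, M, by = 2L)) for (n in seq(0L, M, by = 3L)) {
            k <- 0:N
            got <- hypergeomUpperTail(M, N, n, k)
            want <- vapply(k, function(kk) bruteHyperUpper(M, N, n, kk),
                           numeric(1))
            expect_equal(got, want, tolerance = 1e-10)
            expect_true(all(diff(got) <= 1e-12))  # non-increasing in k
        }
    }
    expect_error(hypergeomUpperTail(10, 11, 5, 0), "<=")
    expect_error(hypergeomUpperTail(10, 4, 5, 5), "<=")
})

test_that("pair memberships are counted relative to the named miRNA", {
    stable <- data.frame(
        pair_a = c("g", "g", "g", "a", "b"),
        pair_b = c("p", "q", "r", "g", "g"),
        direction = c(">", ">", ">", "<=", "<="))
    # g is on the larger side in all five pairs
    reversed <- stable[c(1, 2, 4), ]
    got <- countPairMemberships(stable, reversed, "g")
    expect_identical(got, c(n_up = 0L, n_down = 5L, k_up = 0L, k_down = 3L))

    # relabelling a pair's slots (and flipping its direction) changes nothing
    stable2 <- stable
    stable2[1, ] <- list("p", "g", "<=")
    got2 <- countPairMemberships(stable2, reversed, "g")
    expect_identical(got2, got)

    none <- countPairMemberships(stable, stable[0, ], "g")
    expect_identical(none[c("k_up", "k_down")], c(k_up = 0L, k_down = 0L))
    absent <- countPairMemberships(stable, reversed, "zz")
    expect_identical(unname(absent), rep(0L, 4L))
})

test_that("differential calling recovers constructed enrichment exactly", {
    # two enriched miRNAs: every one of their stable pairs is reversed;
    # 40 background miRNAs contribute stable pairs, none reversed
    bg <- sprintf("bg%02d", 1:40)
    enr_pairs <- data.frame(
        pair_a = rep(c("hit1", "hit2"), each = 10),
        pair_b = rep(bg[1:10], 2),
        direction = rep(c(">", "<="), each = 10))
    bg_pairs <- data.frame(pair_a = rep(bg[1:39], 8),
                           pair_b = rep(bg[2:40], 8),
                           direction = ">")
    bg_pairs <- bg_pairs[bg_pairs$pair_a < bg_pairs$pair_b, ]
    stable <- rbind(enr_pairs, bg_pairs)
    reversed <- enr_pairs
    res <- identifyDiffMirnas(stable, reversed, 0.05)
    expect_setequal(res$mirna_id[res$differential], c("hit1", "hit2"))
    expect_identical(res$direction[res$mirna_id == "hit1"], "down")
    expect_identical(res$direction[res$mirna_id == "hit2"], "up")

    # invariant to the input ordering of pairs
    perm <- identifyDiffMirnas(stable[rev(seq_len(nrow(stable))), ],
                               reversed[sample(nrow(reversed)), ], 0.05)
    expect_identical(perm, res)

    # flagged count grows monotonically with the threshold
    counts <- vapply(c(0.01, 0.05, 0.2, 0.5),
                     function(q) sum(identifyDiffMirnas(stable, reversed,
                                                        q)$differential),
                     numeric(1))
    expect_true(all(diff(counts) >= 0))

    # untouched miRNAs have p_min 1 and are never flagged
    quiet <- res[res$k_up == 0L & res$k_down == 0L, ]
    expect_true(all(quiet$p_min == 1))
    expect_false(any(quiet$differential))

    expect_error(identifyDiffMirnas(stable[0, ], reversed), "no stable")
})

test_that("no differential miRNAs are invented on null cohorts", {
    d <- simulationDesign(nMirnas = 100L,
                          phenotypes = data.frame(label = c("BrC", "Ctrl"),
                                                  n = c(100L, 100L)),
                          nDatasets = 2L, nPlantedReversals = 0L,
                          missingRate = 0, rngSeed = 29L)
    sim <- simulateCohort(d)
    g <- caseControlIds(sim$experiment)
    st <- findStablePairs(sim$experiment, g$control, 0.8)
    rev <- findReversedPairs(sim$experiment, st, g$case, 0.05)
    res <- identifyDiffMirnas(st, rev, 0.05)
    expect_lte(mean(res$differential), 0.05 + 0.02)
})

test_that("the rank-tSNE embedding is reproducible and separates planted signal", {
    d <- simulationDesign(nMirnas = 60L,
                          phenotypes = data.frame(label = c("BrC", "Ctrl"),
                                                  n = c(60L, 90L)),
                          nDatasets = 2L, nPlantedReversals = 6L,
                          reversalStrength = 0.95, stableStrength = 0.95,
                          missingRate = 0, rngSeed = 33L)
    sim <- simulateCohort(d)
    x <- sim$experiment
    sub <- diffMirnas(sim$truth)
    e1 <- embedTsne(x, sub, "BrC", seed = 5L)
    e2 <- embedTsne(x, sub, "BrC", seed = 5L)
    expect_identical(e1$coordinates, e2$coordinates)
    expect_gt(e1$silhouette, 0.25)

    # identical duplicated samples land together
    dup <- injectDuplicates(x, 2L, epsilon = 0, seed = 6L)
    ed <- embedTsne(dup$experiment, sub, "BrC", seed = 7L)
    co <- ed$coordinates
    for (r in 1:2) {
        p1 <- co[co$sample_id == dup$duplicatePairs$source_id[r],
                 c("tsne1", "tsne2")]
        p2 <- co[co$sample_id == dup$duplicatePairs$dup_id[r],
                 c("tsne1", "tsne2")]
        d12 <- sqrt(sum((p1 - p2)^2))
        span <- max(dist(co[, c("tsne1", "tsne2")]))
        expect_lt(d12 / span, 0.05)
    }
    expect_error(embedTsne(x, character(), "BrC"), "empty")
    expect_error(embedTsne(x, "nope", "BrC"), "nope")
})
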