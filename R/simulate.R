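#' Describe a synthetic serum-miRNA cohort
#'
#' The generator emulates the structure of multi-cohort serum miRNA
#' microarray collections: several datasets (batches) with batch-specific
#' strictly increasing intensity distortions, 10--20 phenotype classes with
#' one designated case class, disjoint planted pair-order reversals between
#' case and control samples, missing values, outlier samples (shuffled
#' profiles) and near-duplicate samples.
#'
#' Defaults give 300 miRNAs and 800 samples: 200 cases plus twelve control
#' classes of 50, spread over 4 datasets, with 10 planted reversals of
#' strength 0.95 on both sides.
#'
#' @param nMirnas number of miRNAs.
#' @param phenotypes data.frame with columns \code{label}, \code{n}.
#' @param nDatasets number of batches.
#' @param caseLabel the case class.
#' @param nPlantedReversals number of disjoint planted pair reversals.
#' @param reversalStrength probability that a case sample shows the planted
#'   case-direction REO; must exceed 0.5.
#' @param stableStrength probability that a control sample shows the
#'   control-direction REO.
#' @param missingRate fraction of cells set missing at random.
#' @param nOutliers samples replaced by within-sample shuffled profiles.
#' @param nDuplicates near-duplicate samples appended.
#' @param batchMonotone apply a per-dataset strictly increasing distortion.
#' @param noiseSd per-cell Gaussian noise SD on the natural-log scale.
#' @param rngSeed integer seed; the generator consumes no other randomness.
#' @return a \linkS4class{SimulationDesign}
#' @export
simulationDesign <- function(nMirnas = 300L,
                             phenotypes = NULL,
                             nDatasets = 4L,
                             caseLabel = "BrC",
                             nPlantedReversals = 10L,
                             reversalStrength = 0.95,
                             stableStrength = 0.95,
                             missingRate = 0.01,
                             nOutliers = 0L,
                             nDuplicates = 0L,
                             batchMonotone = TRUE,
                             noiseSd = 0.3,
                             rngSeed = 1L) {
    if (is.null(phenotypes)) {
        ctrl <- c("BlC", "BTC", "CRC", "EsC", "GaC", "Gli",
                  "HCC", "LuC", "OvC", "PaC", "PrC", "Sar")
        phenotypes <- data.frame(label = c(caseLabel, ctrl),
                                 n = c(200L, rep(50L, length(ctrl))))
    }
    new("SimulationDesign", nMirnas = as.integer(nMirnas),
        phenotypes = phenotypes, nDatasets = as.integer(nDatasets),
        caseLabel = caseLabel,
        nPlantedReversals = as.integer(nPlantedReversals),
        reversalStrength = reversalStrength,
        stableStrength = stableStrength, missingRate = missingRate,
        nOutliers = as.integer(nOutliers),
        nDuplicates = as.integer(nDuplicates),
        batchMonotone = batchMonotone, noiseSd = noiseSd,
        rngSeed = as.integer(rngSeed))
}

#' Simulate a cohort with planted REO structure
#'
#' Each miRNA has a latent mean spread over roughly four natural-log units;
#' per-sample values are mean plus Gaussian noise. Planted pairs are chosen
#' as adjacent order statistics of the latent means (so no third miRNA sits
#' between a pair's means and planted reversals do not leak into other
#' pairs). For every planted pair and sample, a Bernoulli draw decides
#' whether the sample must show the group-characteristic REO (probability
#' \code{stableStrength} in controls, \code{reversalStrength} for the
#' reversed direction in cases); the ordering is then enforced by swapping
#' the pair's two observed values when they disagree. At strengths 1.0 the
#' planted degree of reversal is therefore exactly 1. Missing values,
#' shuffled-profile outliers and near-duplicates are injected afterwards;
#' the batch distortion (strictly increasing per dataset) is applied last,
#' so it alters intensities but no within-sample ordering.
#'
#' @param design a \linkS4class{SimulationDesign}
#' @return list with elements \code{experiment}
#'   (\linkS4class{MirnaExperiment}) and \code{truth}
#'   (\linkS4class{GroundTruth})
#' @export
simulateCohort <- function(design) {
    validObject(design)
    set.seed(design@rngSeed)
    m <- design@nMirnas
    ph <- design@phenotypes
    nS <- sum(ph$n)
    if (design@nOutliers > nS)
        stop("infeasible design: more outliers than samples")

    mirna_ids <- sprintf("miR-%04d", seq_len(m))
    sample_ids <- sprintf("S%05d", seq_len(nS))
    pheno <- rep(ph$label, ph$n)
    # datasets balanced within each phenotype, order shuffled
    dataset <- unlist(lapply(ph$n, function(n)
        sample(rep_len(seq_len(design@nDatasets), n))))
    dataset <- paste0("D", dataset)

    mu <- stats::runif(m, 4, 8)
    X <- matrix(mu, m, nS) + matrix(stats::rnorm(m * nS, sd = design@noiseSd),
                                    m, nS)
    dimnames(X) <- list(mirna_ids, sample_ids)

    # planted pairs: disjoint adjacent order-statistic pairs of the means
    planted <- data.frame(mirna_a = character(), mirna_b = character(),
                          control_direction = character(),
                          case_direction = character())
    is_case <- pheno == design@caseLabel
    if (design@nPlantedReversals > 0L) {
        ord <- order(mu)
        step <- max(2L, (m - 1L) %/% design@nPlantedReversals)
        starts <- seq(1L, by = step, length.out = design@nPlantedReversals)
        for (r in starts) {
            lo <- ord[r]; hi <- ord[r + 1L]       # mu[hi] >= mu[lo]
            a <- min(mirna_ids[c(lo, hi)]); b <- max(mirna_ids[c(lo, hi)])
            # control REO follows the latent means, expressed for (a, b)
            ctrl_dir <- if (mu[match(a, mirna_ids)] >= mu[match(b, mirna_ids)])
                ">" else "<="
            case_dir <- if (ctrl_dir == ">") "<=" else ">"
            ia <- match(a, mirna_ids); ib <- match(b, mirna_ids)
            hold <- ifelse(is_case,
                           stats::rbinom(nS, 1L, design@reversalStrength),
                           stats::rbinom(nS, 1L, design@stableStrength)) == 1L
            # TRUE when the sample must show E_a > E_b
            want_gt <- ifelse(is_case, xor(hold, case_dir == "<="),
                              xor(hold, ctrl_dir == "<="))
            cur_gt <- X[ia, ] > X[ib, ]
            sw <- want_gt != cur_gt
            tmp <- X[ia, sw]; X[ia, sw] <- X[ib, sw]; X[ib, sw] <- tmp
            planted <- rbind(planted, data.frame(
                mirna_a = a, mirna_b = b,
                control_direction = ctrl_dir, case_direction = case_dir))
        }
    }

    x <- MirnaExperiment(X, phenotype = pheno, dataset = dataset)

    if (design@missingRate > 0) {
        X <- exprValues(x)
        mask <- matrix(stats::runif(length(X)) < design@missingRate,
                       nrow(X), ncol(X))
        # never blank out a whole miRNA
        full <- rowSums(!mask) == 0L
        mask[full, 1L] <- FALSE
        X[mask] <- NA_real_
        x <- MirnaExperiment(X, phenotype = pheno, dataset = dataset)
    }

    out_ids <- character()
    if (design@nOutliers > 0L) {
        inj <- injectOutliers(x, design@nOutliers)
        x <- inj$experiment
        out_ids <- inj$outlierIds
    }

    if (design@batchMonotone) {
        X <- exprValues(x)
        ds <- datasetLabels(x)
        for (d in unique(ds)) {
            alpha <- stats::runif(1, -0.5, 0.5)
            beta <- stats::runif(1, 0.8, 1.25)
            gamma <- stats::runif(1, 0.005, 0.05)
            cols <- which(ds == d)
            v <- X[, cols, drop = FALSE]
            X[, cols] <- alpha + beta * v + gamma * v^3
        }
        x <- MirnaExperiment(X, phenotype = phenotype(x),
                             dataset = unname(ds))
    }

    # duplicates last so their distance bound survives the batch distortion
    dup_pairs <- data.frame(source_id = character(), dup_id = character())
    if (design@nDuplicates > 0L) {
        inj <- injectDuplicates(x, design@nDuplicates, epsilon = 0.5)
        x <- inj$experiment
        dup_pairs <- inj$duplicatePairs
    }

    truth <- new("GroundTruth", plantedPairs = planted,
                 diffMirnas = unique(c(planted$mirna_a, planted$mirna_b)),
                 outlierIds = out_ids, duplicatePairs = dup_pairs)
    list(experiment = x, truth = truth)
}

#' Replace samples with shuffled-profile outliers
#'
#' Each selected sample's non-missing values are permuted across miRNAs,
#' driving its correlation with every other sample towards zero while
#' preserving its value distribution and missing-value mask.
#'
#' @param x a \linkS4class{MirnaExperiment}
#' @param n number of samples to replace.
#' @param phenotypeGroup restrict selection to this phenotype
#'   (default: any sample).
#' @param seed optional integer seed.
#' @return list with \code{experiment} and \code{outlierIds}
#' @export
injectOutliers <- function(x, n, phenotypeGroup = NULL, seed = NULL) {
    if (!is.null(seed)) set.seed(seed)
    pool <- sampleIds(x)
    if (!is.null(phenotypeGroup))
        pool <- pool[phenotype(x) == phenotypeGroup]
    if (n > length(pool))
        stop("cannot inject ", n, " outliers into a pool of ", length(pool),
             " samples")
    if (n == 0L)
        return(list(experiment = x, outlierIds = character()))
    chosen <- sample(pool, n)
    X <- exprValues(x)
    for (s in chosen) {
        ok <- !is.na(X[, s])
        X[ok, s] <- sample(X[ok, s])
    }
    list(experiment = MirnaExperiment(X, phenotype = unname(phenotype(x)),
                                      dataset = unname(datasetLabels(x))),
         outlierIds = chosen)
}

#' Append near-duplicate samples
#'
#' Each duplicate copies a randomly chosen existing sample (including its
#' missing-value mask, phenotype and dataset) and adds a noise vector whose
#' Euclidean norm over non-missing cells is strictly below \code{epsilon}.
#'
#' @param x a \linkS4class{MirnaExperiment}
#' @param n number of duplicates to append.
#' @param epsilon noise-norm bound (>= 0); 0 appends exact copies.
#' @param seed optional integer seed.
#' @return list with \code{experiment} and \code{duplicatePairs}
#'   (data.frame \code{source_id}, \code{dup_id})
#' @export
injectDuplicates <- function(x, n, epsilon = 0.5, seed = NULL) {
    if (epsilon < 0) stop("epsilon must be non-negative")
    if (!is.null(seed)) set.seed(seed)
    if (n == 0L)
        return(list(experiment = x,
                    duplicatePairs = data.frame(source_id = character(),
                                                dup_id = character())))
    X <- exprValues(x)
    src <- sample(sampleIds(x), n, replace = TRUE)
    newX <- matrix(NA_real_, nrow(X), n)
    dup_ids <- sprintf("%s-dup%02d", src, seq_len(n))
    for (j in seq_len(n)) {
        v <- X[, src[j]]
        ok <- !is.na(v)
        if (epsilon > 0) {
            z <- stats::rnorm(sum(ok))
            z <- z / sqrt(sum(z^2)) * stats::runif(1, 0, 0.98 * epsilon)
            v[ok] <- v[ok] + z
        }
        newX[, j] <- v
    }
    colnames(newX) <- dup_ids
    rownames(newX) <- mirnaIds(x)
    ph <- unname(phenotype(x)); ds <- unname(datasetLabels(x))
    si <- match(src, sampleIds(x))
    list(experiment = MirnaExperiment(cbind(X, newX),
                                      phenotype = c(ph, ph[si]),
                                      dataset = c(ds, ds[si])),
         duplicatePairs = data.frame(source_id = src, dup_id = dup_ids))
}
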