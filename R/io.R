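#' Read an expression matrix with its sample annotation
#'
#' Reads a tab-delimited miRNA-by-sample matrix (first column miRNA id,
#' header row of sample ids) together with an annotation table carrying one
#' row per sample with columns \code{sample_id}, \code{phenotype},
#' \code{dataset}. The matrix is never transposed: rows are miRNAs, columns
#' samples (the GEO series-matrix convention). The tokens \code{""},
#' \code{"NA"} and \code{"NaN"} (case-insensitive) are read as missing.
#'
#' @param path matrix file
#' @param annotationPath annotation file
#' @return a \linkS4class{MirnaExperiment}
#' @export
readMirnaMatrix <- function(path, annotationPath) {
    raw <- utils::read.table(path, sep = "\t", header = TRUE,
                             check.names = FALSE, colClasses = "character",
                             quote = "", comment.char = "")
    ids <- raw[[1L]]
    if (anyDuplicated(ids))
        stop("duplicate miRNA ids: ",
             paste(unique(ids[duplicated(ids)]), collapse = ", "))
    cells <- as.matrix(raw[, -1L, drop = FALSE])
    if (anyDuplicated(colnames(cells)))
        stop("duplicate sample ids: ",
             paste(unique(colnames(cells)[duplicated(colnames(cells))]),
                   collapse = ", "))
    missing_tok <- trimws(cells) == "" | tolower(trimws(cells)) %in% c("na", "nan")
    values <- suppressWarnings(as.numeric(cells))
    bad <- which(is.na(values) & !missing_tok)
    if (length(bad)) {
        i <- ((bad[1L] - 1L) %% nrow(cells)) + 1L
        j <- ((bad[1L] - 1L) %/% nrow(cells)) + 1L
        stop(sprintf("non-numeric value '%s' at miRNA '%s', sample '%s'",
                     cells[bad[1L]], ids[i], colnames(cells)[j]))
    }
    values <- matrix(values, nrow = nrow(cells),
                     dimnames = list(ids, colnames(cells)))
    ann <- utils::read.table(annotationPath, sep = "\t", header = TRUE,
                             check.names = FALSE, colClasses = "character",
                             quote = "", comment.char = "")
    need <- c("sample_id", "phenotype", "dataset")
    if (!all(need %in% colnames(ann)))
        stop("annotation must have columns: ", paste(need, collapse = ", "))
    idx <- match(colnames(values), ann$sample_id)
    if (anyNA(idx))
        stop("samples missing from annotation: ",
             paste(colnames(values)[is.na(idx)], collapse = ", "))
    MirnaExperiment(values, phenotype = ann$phenotype[idx],
                    dataset = ann$dataset[idx])
}

#' Write an expression matrix and its annotation
#'
#' Deterministic tab-delimited serialisation; \code{readMirnaMatrix} on the
#' two files reproduces the object.
#'
#' @param x a \linkS4class{MirnaExperiment}
#' @param path matrix file to write
#' @param annotationPath annotation file to write
#' @export
writeMirnaMatrix <- function(x, path, annotationPath) {
    df <- data.frame(mirna_id = mirnaIds(x), exprValues(x),
                     check.names = FALSE)
    writeResultsTsv(df, path)
    ann <- data.frame(sample_id = sampleIds(x),
                      phenotype = unname(phenotype(x)),
                      dataset = unname(datasetLabels(x)))
    writeResultsTsv(ann, annotationPath)
    invisible(NULL)
}

#' Write / read a result table as TSV
#'
#' Plain deterministic tab-delimited output (no quoting, no row names,
#' 15 significant digits) so that a write/read round trip is an identity
#' up to numeric precision.
#'
#' @param df a data.frame
#' @param path file path
#' @export
writeResultsTsv <- function(df, path) {
    num <- vapply(df, is.numeric, logical(1))
    out <- df
    out[num] <- lapply(df[num], function(v) formatC(v, digits = 15,
                                                    format = "g"))
    con <- tryCatch(file(path, "w"),
                    error = function(e) stop("cannot write to ", path,
                                             ": ", conditionMessage(e)))
    on.exit(close(con))
    utils::write.table(out, con, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = TRUE)
    invisible(NULL)
}

#' @rdname writeResultsTsv
#' @export
readResultsTsv <- function(path) {
    utils::read.table(path, sep = "\t", header = TRUE, check.names = FALSE,
                      quote = "", comment.char = "", stringsAsFactors = FALSE)
}

#' Serialise / restore a voting model
#'
#' One row per pair with its case-characteristic REO direction, in voting
#' order, plus the objective trace.
#'
#' @param model a \linkS4class{VotingModel}
#' @param path file path
#' @export
writeVotingModel <- function(model, path) {
    df <- modelPairs(model)
    df$objective <- objectiveTrace(model)
    df$is_seed <- df$pair_a == model@seedPair[1] &
        df$pair_b == model@seedPair[2]
    writeResultsTsv(df, path)
    invisible(NULL)
}

#' @rdname writeVotingModel
#' @export
readVotingModel <- function(path) {
    df <- readResultsTsv(path)
    df$is_seed <- as.logical(df$is_seed)
    seed <- df[df$is_seed, , drop = FALSE][1L, ]
    new("VotingModel",
        pairs = df[, c("pair_a", "pair_b", "case_direction")],
        objectiveTrace = df$objective,
        seedPair = c(seed$pair_a, seed$pair_b))
}

#' Pipeline configuration
#'
#' @param pctThreshold stable-pair PCT threshold, fraction in (0.5, 1].
#' @param fdrThreshold BH-adjusted significance cut for reversed pairs and
#'   differential miRNAs.
#' @param deltaPctThreshold candidate degree-of-reversal threshold.
#' @param nSeeds number of greedy seeds (top candidates by |delta PCT|).
#' @param trainFraction fraction of samples assigned to training.
#' @param knnK neighbours used by \code{imputeKnn}.
#' @param duplicateDistance Euclidean distance below which samples are
#'   treated as duplicates.
#' @param outlierSdMultiplier standard-deviation multiplier of the
#'   correlation-based outlier filter.
#' @param rngSeed integer seed recorded with every run.
#' @param caseLabel phenotype label of the case (positive) class.
#' @return a \linkS4class{ReoConfig}
#' @export
reoConfig <- function(pctThreshold = 0.80, fdrThreshold = 0.05,
                      deltaPctThreshold = 0.70, nSeeds = 10L,
                      trainFraction = 0.70, knnK = 10L,
                      duplicateDistance = 1.0, outlierSdMultiplier = 2.0,
                      rngSeed = 1L, caseLabel = "BrC") {
    new("ReoConfig", pctThreshold = pctThreshold,
        fdrThreshold = fdrThreshold, deltaPctThreshold = deltaPctThreshold,
        nSeeds = as.integer(nSeeds), trainFraction = trainFraction,
        knnK = as.integer(knnK), duplicateDistance = duplicateDistance,
        outlierSdMultiplier = outlierSdMultiplier,
        rngSeed = as.integer(rngSeed), caseLabel = caseLabel)
}

setMethod("show", "ReoConfig", function(object) {
    cat("ReoConfig:\n")
    for (s in slotNames(object))
        cat(sprintf("  %-20s %s\n", s, format(slot(object, s))))
})

#' Read / write a ReoConfig as YAML
#'
#' Field-for-field YAML mirror of \linkS4class{ReoConfig}.
#'
#' @param path YAML file
#' @export
readReoConfig <- function(path) {
    vals <- yaml::read_yaml(path)
    do.call(reoConfig, vals)
}

#' @rdname readReoConfig
#' @param config a \linkS4class{ReoConfig}
#' @export
writeReoConfig <- function(config, path) {
    vals <- lapply(slotNames(config), function(s) slot(config, s))
    names(vals) <- slotNames(config)
    yaml::write_yaml(vals, path)
    invisible(NULL)
}
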