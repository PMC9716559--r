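## End-to-end validation: metrics -> classifier scores -> CMO register
## analysis -> filtered calls -> per-residue report.

#' The classifier shipped with the package
#'
#' A linear SVM trained on the default synthetic labelled dataset
#' (\code{\link{generateLabelledDataset}}); override by passing your own
#' classifier to \code{\link{validateChain}}.
#'
#' @return A \linkS4class{TrainedClassifier}.
#' @export
defaultClassifier <- function() {
    readClassifier(system.file("extdata", "default_classifier.json",
                               package = "registercheck", mustWork = TRUE))
}

#' Validate a chain against a distogram
#'
#' Runs the full pipeline on in-memory objects: per-residue metric table,
#' classifier scores and error-run calls, contact-map-overlap alignment,
#' register-shift extraction and the three false-positive filters.
#'
#' @param chain the model \linkS4class{StructureChain} (reference-numbered).
#' @param distogram the matching \linkS4class{Distogram}.
#' @param classifier a \linkS4class{TrainedClassifier}; the shipped default
#'   when NULL.
#' @param predictedChain optional predicted-model chain (enables the pLDDT
#'   and Q-score filters).
#' @param minRun,scoreThreshold error-run calling defaults (6 residues at
#'   score >= 0.9).
#' @param minShiftLen minimum register-shift call length.
#' @param cutoff,minSep contact definition.
#' @param filters logical; when FALSE the filters are not run (verdicts stay
#'   "not_run"); filters never remove calls from the report.
#' @param seed recorded in the provenance block (the pipeline itself is
#'   deterministic).
#' @return A \linkS4class{ValidationReport}.
#' @export
validateChain <- function(chain, distogram, classifier = NULL,
                          predictedChain = NULL, minRun = 6L,
                          scoreThreshold = 0.9, minShiftLen = 5L,
                          cutoff = 8.0, minSep = 5L, filters = TRUE,
                          seed = 0L) {
    if (is.null(classifier)) classifier <- defaultClassifier()
    L <- chain@L
    if (chainLength(distogram) != L)
        stop("[structures] chain/distogram length mismatch")
    stage <- function(name, expr)
        tryCatch(expr, error = function(e)
            stop("[", name, "] ", conditionMessage(e), call. = FALSE))

    if (all(is.na(chain@residues$ss)))
        chain <- stage("structures", assignSsAcc(chain))
    mt <- stage("metrics", buildMetricTable(chain, distogram,
                                            cutoff = cutoff,
                                            minSep = minSep))
    X <- stage("classifier", buildFeatureMatrix(mt, chain))
    scores <- stage("classifier", scoreResidues(classifier, X))
    errorCalls <- flagErrorRuns(scores, minRun = minRun,
                                threshold = scoreThreshold)

    obsCM <- stage("structures", observedContactMap(chain, cutoff = cutoff,
                                                    minSep = minSep))
    P <- stage("predictions", distogramContactProbabilities(distogram,
                                                            cutoff = cutoff))
    predCM <- stage("predictions", selectTopContacts(P, L = L,
                                                     minSep = minSep))
    cmoCM <- stage("predictions", thresholdContacts(P, minSep = minSep))
    aln <- stage("cmo", alignContactMaps(obsCM, cmoCM))
    shiftCalls <- stage("cmo", extractRegisterShifts(aln,
                                                     minLen = minShiftLen))
    if (filters)
        shiftCalls <- lapply(shiftCalls, applyFilters, predCM = predCM,
                             modelChain = chain,
                             predictedChain = predictedChain)

    cmoStatus <- rep("native", L)
    shift <- integer(L)
    for (sc in shiftCalls) {
        cmoStatus[sc@start:sc@end] <- "alternative"
        shift[sc@start:sc@end] <- sc@shift
    }
    smooth <- smoothProfile(scores, window = 5L)$values
    res <- data.frame(seqIndex = seq_len(L), aa = chain@residues$aa,
                      score = scores, scoreSmooth = smooth,
                      above05 = scores > 0.5, cmoStatus = cmoStatus,
                      shift = shift, stringsAsFactors = FALSE)
    new("ValidationReport", residues = res, errorCalls = errorCalls,
        shiftCalls = shiftCalls,
        provenance = list(
            version = as.character(utils::packageVersion("registercheck")),
            minRun = minRun, scoreThreshold = scoreThreshold,
            minShiftLen = minShiftLen, cutoff = cutoff, minSep = minSep,
            filters = filters, seed = seed))
}

#' Validate a model file against a distogram file
#'
#' File-level wrapper around \code{\link{validateChain}}: reads the model
#' chain (PDB/mmCIF), the distogram (JSON/TSV), optionally a DSSP
#' annotation, a predicted model (pLDDT in its B-factor column) and a
#' classifier JSON, renumbers the chain onto the distogram's reference
#' sequence and runs the pipeline.
#'
#' @param modelPath path to the model (PDB or mmCIF).
#' @param chainId chain to validate.
#' @param distogramPath path to the distogram.
#' @param predictedModelPath optional predicted-model file (same chain id
#'   unless \code{predictedChainId} is given).
#' @param predictedChainId chain id in the predicted model.
#' @param dsspPath optional DSSP annotation for the model chain.
#' @param classifierPath optional classifier JSON
#'   (\code{\link{writeClassifier}} format).
#' @param ... further arguments to \code{\link{validateChain}}.
#' @return A \linkS4class{ValidationReport}.
#' @export
runValidate <- function(modelPath, chainId, distogramPath,
                        predictedModelPath = NULL, predictedChainId = chainId,
                        dsspPath = NULL, classifierPath = NULL, ...) {
    chain <- readModel(modelPath, chainId)
    distogram <- loadDistogram(distogramPath)
    refSeq <- chainSequence(distogram)
    if (!grepl("^X+$", refSeq))
        chain <- renumberToReference(chain, refSeq)
    chain <- assignSsAcc(chain, annotationPath = dsspPath)
    predictedChain <- NULL
    if (!is.null(predictedModelPath)) {
        predictedChain <- readModel(predictedModelPath, predictedChainId)
        if (!grepl("^X+$", refSeq))
            predictedChain <- renumberToReference(predictedChain, refSeq)
    }
    classifier <- if (is.null(classifierPath)) NULL else
        readClassifier(classifierPath)
    validateChain(chain, distogram, classifier = classifier,
                  predictedChain = predictedChain, ...)
}

.call_df <- function(report) {
    list(error_calls = lapply(report@errorCalls, function(e)
             list(start = e@start, end = e@end, mean_score = e@meanScore,
                  n_residues = e@nResidues)),
         register_shifts = lapply(report@shiftCalls, function(s)
             list(start = s@start, end = s@end, shift = s@shift,
                  filters = as.list(s@filterVerdicts))))
}

#' Write a validation report as TSV and JSON
#'
#' TSV: one row per reference position with the raw and display-smoothed
#' classifier score, the 0.5 flag, the CMO register status and the proposed
#' shift. JSON: the same table plus the full call records and provenance.
#'
#' @param report a \linkS4class{ValidationReport}.
#' @param tsvPath,jsonPath output paths (either may be NULL to skip).
#' @export
writeReport <- function(report, tsvPath = NULL, jsonPath = NULL) {
    if (!is.null(tsvPath))
        write.table(report@residues, tsvPath, sep = "\t", quote = FALSE,
                    row.names = FALSE)
    if (!is.null(jsonPath)) {
        calls <- .call_df(report)
        jsonlite::write_json(
            list(residues = report@residues,
                 error_calls = calls$error_calls,
                 register_shifts = calls$register_shifts,
                 provenance = report@provenance),
            jsonPath, auto_unbox = TRUE, digits = NA, na = "null")
    }
    invisible(report)
}

#' Read back a JSON validation report
#'
#' @param jsonPath path written by \code{\link{writeReport}}.
#' @return A \linkS4class{ValidationReport}.
#' @export
readReport <- function(jsonPath) {
    d <- jsonlite::fromJSON(jsonPath, simplifyDataFrame = TRUE,
                            simplifyVector = TRUE)
    ec <- lapply(seq_len(NROW(d$error_calls)), function(k) {
        e <- d$error_calls[k, ]
        new("ErrorCall", start = as.integer(e$start),
            end = as.integer(e$end), meanScore = as.numeric(e$mean_score),
            nResidues = as.integer(e$n_residues))
    })
    rs <- lapply(seq_len(NROW(d$register_shifts)), function(k) {
        s <- d$register_shifts[k, ]
        new("RegisterShiftCall", start = as.integer(s$start),
            end = as.integer(s$end), shift = as.integer(s$shift),
            filterVerdicts = unlist(s$filters))
    })
    new("ValidationReport", residues = d$residues, errorCalls = ec,
        shiftCalls = rs, provenance = as.list(d$provenance))
}
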