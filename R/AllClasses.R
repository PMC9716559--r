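#' @import methods
#' @importFrom stats cor median pnorm predict quantile runif sd setNames glm
#'   binomial coef
#' @importFrom utils read.table write.table head tail
#' @useDynLib registercheck, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

## Central containers. Residue-level information is kept in a single
## data.frame slot rather than a list of residue objects: all per-residue
## operations in the package are vectorised over the chain.

#' StructureChain: a single protein chain with representative-atom coordinates
#'
#' Holds one chain of a coordinate model, indexed by position in the
#' reference sequence (1-based). Each residue carries a representative-atom
#' coordinate (C-beta; C-alpha for glycine), an optional pLDDT confidence
#' read from the B-factor column, a secondary-structure class and a relative
#' solvent accessibility. Reference positions that are not modelled are kept
#' as rows with \code{modelled = FALSE} and \code{NA} coordinates so that
#' the chain always covers positions \code{1..L}.
#'
#' @slot residues data.frame with columns \code{seqIndex}, \code{aa},
#'   \code{x}, \code{y}, \code{z}, \code{plddt}, \code{ss}, \code{acc},
#'   \code{modelled}; one row per reference position, strictly increasing
#'   \code{seqIndex}.
#' @slot L integer, reference sequence length.
#' @slot chainId character, chain identifier.
#' @export
setClass("StructureChain",
    representation(residues = "data.frame", L = "integer",
                   chainId = "character"))

setValidity("StructureChain", function(object) {
    r <- object@residues
    need <- c("seqIndex", "aa", "x", "y", "z", "plddt", "ss", "acc",
              "modelled")
    if (!all(need %in% names(r)))
        return(paste("residues must have columns:",
                     paste(need, collapse = ", ")))
    if (nrow(r) > 1 && any(diff(r$seqIndex) <= 0))
        return("seqIndex must be strictly increasing")
    if (any(duplicated(r$seqIndex)))
        return("duplicate seqIndex")
    if (object@L < sum(r$modelled))
        return("L smaller than number of modelled residues")
    mod <- r$modelled
    if (any(mod) && !all(is.finite(as.matrix(r[mod, c("x", "y", "z")]))))
        return("modelled residues must have finite coordinates")
    pl <- r$plddt[!is.na(r$plddt)]
    if (length(pl) && (any(pl < 0) || any(pl > 100)))
        return("plddt must lie in [0, 100]")
    if (!all(r$ss %in% c("helix", "sheet", "coil", NA)))
        return("ss must be helix/sheet/coil or NA")
    TRUE
})

#' DistanceMatrix: observed inter-residue distances with a validity mask
#'
#' @slot values L x L symmetric matrix of representative-atom distances in
#'   Angstrom; entries involving unmodelled residues are NA.
#' @slot mask L x L logical matrix, TRUE where both residues are modelled.
#' @export
setClass("DistanceMatrix",
    representation(values = "matrix", mask = "matrix"))

setValidity("DistanceMatrix", function(object) {
    v <- object@values
    m <- object@mask
    if (!identical(dim(v), dim(m))) return("values/mask dimension mismatch")
    if (nrow(v) != ncol(v)) return("matrix must be square")
    vv <- v
    vv[!m] <- 0
    if (max(abs(vv - t(vv))) > 1e-9) return("masked values must be symmetric")
    if (any(abs(diag(vv)) > 1e-9)) return("diagonal must be zero")
    TRUE
})

#' ContactMap: a weighted set of residue-residue contacts
#'
#' Contacts are stored as pairs \code{(i, j, weight)} with \code{i < j} and
#' weight in (0, 1]. Observed maps use weight 1; predicted maps carry the
#' contact probability.
#'
#' @slot pairs data.frame with columns \code{i}, \code{j}, \code{weight}.
#' @slot L integer, sequence length the map refers to.
#' @export
setClass("ContactMap",
    representation(pairs = "data.frame", L = "integer"))

setValidity("ContactMap", function(object) {
    p <- object@pairs
    if (!all(c("i", "j", "weight") %in% names(p)))
        return("pairs must have columns i, j, weight")
    if (nrow(p)) {
        if (any(p$i >= p$j)) return("pairs must satisfy i < j")
        if (any(p$i < 1) || any(p$j > object@L))
            return("pair indices out of 1..L")
        if (any(duplicated(p[, c("i", "j")]))) return("duplicate pairs")
        if (any(p$weight <= 0) || any(p$weight > 1))
            return("weights must lie in (0, 1]")
    }
    TRUE
})

#' PredictedContactMap: a top-L/2 predicted contact map
#'
#' A \linkS4class{ContactMap} whose weights are contact probabilities, plus
#' the per-residue count of selected predicted contacts (used by the
#' contact-density false-positive filter).
#'
#' @slot counts numeric vector of length L, predicted contacts per residue.
#' @export
setClass("PredictedContactMap", contains = "ContactMap",
    representation(counts = "numeric"))

setValidity("PredictedContactMap", function(object) {
    if (length(object@counts) != object@L)
        return("counts must have length L")
    TRUE
})

#' Distogram: per-pair probability distributions over distance bins
#'
#' \code{binEdges} holds the B finite lower bin boundaries; bin b covers
#' \code{[binEdges[b], binEdges[b+1])} for b < B and the final bin is
#' open-ended above \code{binEdges[B]}.
#'
#' @slot sequence character, the reference amino-acid sequence (length L).
#' @slot binEdges strictly increasing numeric vector of B finite edges.
#' @slot probs L x L x B array; \code{probs[i, j, ]} sums to 1 and equals
#'   \code{probs[j, i, ]}.
#' @export
setClass("Distogram",
    representation(sequence = "character", binEdges = "numeric",
                   probs = "array"))

setValidity("Distogram", function(object) {
    e <- object@binEdges
    if (length(e) < 2 || any(diff(e) <= 0) || any(!is.finite(e)))
        return("binEdges must be >= 2 strictly increasing finite values")
    d <- dim(object@probs)
    L <- nchar(object@sequence)
    if (length(d) != 3 || d[1] != L || d[2] != L || d[3] != length(e))
        return("probs must be L x L x B with B = length(binEdges)")
    s <- apply(object@probs, c(1, 2), sum)
    if (max(abs(s - 1)) > 1e-6) return("per-pair probabilities must sum to 1")
    for (b in seq_len(d[3])) {
        sl <- object@probs[, , b]
        if (max(abs(sl - t(sl))) > 1e-9) return("probs must be symmetric")
    }
    TRUE
})

#' DistancePrediction: mode distances and confidences from a distogram
#'
#' @slot predDist L x L matrix of predicted distances (argmax bin midpoints).
#' @slot confidence L x L matrix in [0, 1], the argmax bin's probability.
#' @slot farBin L x L logical matrix, TRUE where the argmax bin is the
#'   open-ended final bin: the prediction then says "far apart" without a
#'   usable distance estimate, and such pairs are excluded from wRMSD.
#' @export
setClass("DistancePrediction",
    representation(predDist = "matrix", confidence = "matrix",
                   farBin = "matrix"),
    prototype(farBin = matrix(FALSE, 0, 0)))

setValidity("DistancePrediction", function(object) {
    if (!identical(dim(object@predDist), dim(object@confidence)))
        return("predDist/confidence dimension mismatch")
    if (max(abs(object@predDist - t(object@predDist))) > 1e-9)
        return("predDist must be symmetric")
    cf <- object@confidence
    if (any(cf < -1e-9) || any(cf > 1 + 1e-9))
        return("confidence must lie in [0, 1]")
    TRUE
})

#' MetricTable: the 24 per-residue validation metrics
#'
#' Eight base metrics (wRMSD, Accuracy, Precision, Sensitivity, Specificity,
#' FPrate, FNcount, FPcount), their five-point smoothed variants
#' (\code{smooth_*}) and their 10-Angstrom spatial Z-score variants
#' (\code{Z_*}). Degenerate values (zero denominators, unmodelled residues)
#' are stored as 0 with the corresponding flag set.
#'
#' @slot metrics L x 24 numeric matrix, named columns.
#' @slot flags L x 24 logical matrix, TRUE where the value is a degenerate
#'   placeholder rather than a measurement.
#' @slot modelled logical vector of length L.
#' @export
setClass("MetricTable",
    representation(metrics = "matrix", flags = "matrix",
                   modelled = "logical"))

setValidity("MetricTable", function(object) {
    if (ncol(object@metrics) != 24) return("metric table must have 24 columns")
    if (!identical(dim(object@metrics), dim(object@flags)))
        return("metrics/flags dimension mismatch")
    if (length(object@modelled) != nrow(object@metrics))
        return("modelled length mismatch")
    rates <- c("Accuracy", "Precision", "Sensitivity", "Specificity",
               "FPrate")
    rv <- object@metrics[, rates, drop = FALSE]
    if (any(rv < -1e-9) || any(rv > 1 + 1e-9))
        return("rate metrics must lie in [0, 1]")
    TRUE
})

#' LabelledDataset: per-residue features with binary error labels
#'
#' @slot features numeric matrix, one row per residue.
#' @slot labels integer vector, 1 = within modelling error, 0 = correct.
#' @slot groups character vector, source chain/segment id per residue, used
#'   for leakage-aware (group-wise) splitting.
#' @export
setClass("LabelledDataset",
    representation(features = "matrix", labels = "integer",
                   groups = "character"))

setValidity("LabelledDataset", function(object) {
    n <- nrow(object@features)
    if (length(object@labels) != n || length(object@groups) != n)
        return("labels/groups must align with feature rows")
    if (!all(object@labels %in% c(0L, 1L))) return("labels must be 0/1")
    TRUE
})

#' TrainedClassifier: a calibrated linear SVM for per-residue error scoring
#'
#' Stores the standardiser (fitted on training rows only), the linear SVM
#' decision function (weights and bias in standardised feature space) and
#' the Platt sigmoid calibration mapping decision values to probabilities.
#'
#' @slot featureNames character, expected feature order.
#' @slot center,scale numeric, per-feature standardisation parameters.
#' @slot weights numeric, linear SVM weight vector.
#' @slot bias numeric(1), SVM intercept (decision = x.w + bias).
#' @slot calibration numeric(2), Platt parameters (a, b):
#'   p = 1 / (1 + exp(a * decision + b)).
#' @slot metadata list: seed, hyperparameters, search score, version.
#' @export
setClass("TrainedClassifier",
    representation(featureNames = "character", center = "numeric",
                   scale = "numeric", weights = "numeric", bias = "numeric",
                   calibration = "numeric", metadata = "list"))

setValidity("TrainedClassifier", function(object) {
    k <- length(object@featureNames)
    if (length(object@center) != k || length(object@scale) != k ||
        length(object@weights) != k)
        return("scaler/weight lengths must match featureNames")
    if (length(object@bias) != 1) return("bias must be scalar")
    if (length(object@calibration) != 2)
        return("calibration must be (a, b)")
    TRUE
})

#' ErrorCall: a run of consecutive residues flagged by the classifier
#'
#' @slot start,end integer, inclusive residue range.
#' @slot meanScore numeric(1), mean classifier score over the run.
#' @slot nResidues integer(1), run length.
#' @export
setClass("ErrorCall",
    representation(start = "integer", end = "integer", meanScore = "numeric",
                   nResidues = "integer"))

#' CMOAlignment: a monotone alignment between two contact maps
#'
#' @slot mapping integer matrix with columns \code{model}, \code{predicted};
#'   strictly increasing in both columns.
#' @slot matchedContacts integer(1), contact pairs present in both maps
#'   under the mapping.
#' @slot matchedWeight numeric(1), summed min-weight of matched contacts.
#' @slot score numeric(1), matched weight minus gap penalties.
#' @slot supported logical, one entry per mapping row: TRUE where the
#'   aligned pair participates in at least one matched contact (only such
#'   positions carry evidence for their assigned register).
#' @export
setClass("CMOAlignment",
    representation(mapping = "matrix", matchedContacts = "integer",
                   matchedWeight = "numeric", score = "numeric",
                   supported = "logical"),
    prototype(supported = logical(0)))

setValidity("CMOAlignment", function(object) {
    m <- object@mapping
    if (ncol(m) != 2) return("mapping must have two columns")
    if (nrow(m) > 1 && (any(diff(m[, 1]) <= 0) || any(diff(m[, 2]) <= 0)))
        return("mapping must be strictly increasing in both coordinates")
    TRUE
})

#' RegisterShiftCall: a proposed sequence-register correction
#'
#' @slot start,end integer, inclusive model residue range affected.
#' @slot shift integer(1), proposed register shift
#'   (predicted index - model index), nonzero.
#' @slot filterVerdicts named character, verdicts of the
#'   contact-density, pLDDT and Q-score false-positive filters
#'   ("pass", "fail", "skipped" or "not_run").
#' @export
setClass("RegisterShiftCall",
    representation(start = "integer", end = "integer", shift = "integer",
                   filterVerdicts = "character"))

setValidity("RegisterShiftCall", function(object) {
    if (object@shift == 0L) return("shift must be nonzero")
    if (object@end < object@start) return("end must be >= start")
    TRUE
})

#' SuperpositionResult: least-squares rigid-body superposition
#'
#' @slot rotation 3 x 3 proper rotation matrix.
#' @slot translation numeric(3).
#' @slot rmsd numeric(1), RMSD over the aligned pairs after superposition.
#' @slot nAlign integer(1), number of aligned pairs.
#' @slot qScore numeric(1), superposition Q-score in [0, 1]
#'   (1 iff rmsd = 0 and the alignment is complete).
#' @export
setClass("SuperpositionResult",
    representation(rotation = "matrix", translation = "numeric",
                   rmsd = "numeric", nAlign = "integer", qScore = "numeric"))

#' ValidationReport: the combined per-residue validation result
#'
#' @slot residues data.frame, one row per reference position: \code{seqIndex},
#'   \code{aa}, \code{score} (raw classifier score), \code{scoreSmooth}
#'   (5-residue rolling average, display only), \code{above05},
#'   \code{cmoStatus} ("native" or "alternative"), \code{shift}.
#' @slot errorCalls list of \linkS4class{ErrorCall}.
#' @slot shiftCalls list of \linkS4class{RegisterShiftCall}.
#' @slot provenance list: thresholds, seed, package version.
#' @export
setClass("ValidationReport",
    representation(residues = "data.frame", errorCalls = "list",
                   shiftCalls = "list", provenance = "list"))

## ---- show methods -------------------------------------------------------

setMethod("show", "StructureChain", function(object) {
    cat(sprintf("StructureChain '%s': %d/%d residues modelled\n",
                object@chainId, sum(object@residues$modelled), object@L))
})

setMethod("show", "ContactMap", function(object) {
    cat(sprintf("%s: L = %d, %d contacts\n", class(object), object@L,
                nrow(object@pairs)))
})

setMethod("show", "Distogram", function(object) {
    cat(sprintf("Distogram: L = %d, %d bins [%.1f, %.1f+) A\n",
                nchar(object@sequence), length(object@binEdges),
                min(object@binEdges), max(object@binEdges)))
})

setMethod("show", "MetricTable", function(object) {
    cat(sprintf("MetricTable: %d residues x %d metrics (%d modelled)\n",
                nrow(object@metrics), ncol(object@metrics),
                sum(object@modelled)))
})

setMethod("show", "TrainedClassifier", function(object) {
    cat(sprintf(
        "TrainedClassifier: %d features, C = %.4g, CV accuracy = %.3f\n",
        length(object@featureNames),
        object@metadata$cost %||% NA_real_,
        object@metadata$searchScore %||% NA_real_))
})

setMethod("show", "CMOAlignment", function(object) {
    cat(sprintf(
        "CMOAlignment: %d aligned positions, %d matched contacts, score %.2f\n",
        nrow(object@mapping), object@matchedContacts, object@score))
})

setMethod("show", "RegisterShiftCall", function(object) {
    cat(sprintf("RegisterShiftCall: residues %d-%d, shift %+d [%s]\n",
                object@start, object@end, object@shift,
                paste(names(object@filterVerdicts), object@filterVerdicts,
                      sep = "=", collapse = ", ")))
})

setMethod("show", "ValidationReport", function(object) {
    cat(sprintf(
        "ValidationReport: %d residues, %d error call(s), %d register-shift call(s)\n",
        nrow(object@residues), length(object@errorCalls),
        length(object@shiftCalls)))
})

`%||%` <- function(a, b) if (is.null(a)) b else a
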