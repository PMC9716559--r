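## Contact-map-overlap alignment, register-shift extraction and the three
## false-positive filters.

#' Align two contact maps for maximum contact overlap
#'
#' Heuristic contact-map-overlap (CMO) alignment by iterated double dynamic
#' programming: an inner DP scores each residue pair by the best monotone
#' matching of their contact-neighbourhood offset profiles, an outer
#' affine-gap DP (terminal gaps free) converts the similarity matrix into a
#' monotone residue alignment, and refinement rounds rebuild the similarity
#' from contacts made consistent by the previous alignment. Exact CMO is
#' NP-hard in general; on small maps the result is checked against
#' \code{\link{bruteForceCMO}} in the test-suite.
#'
#' @param cmModel observed \linkS4class{ContactMap} (weights 1).
#' @param cmPred predicted \linkS4class{ContactMap} (probability weights).
#' @param gapOpen,gapExtend affine gap penalties in matched-contact units
#'   (negative). The defaults forbid spurious single-residue jitter while
#'   allowing genuine register shifts.
#' @param nIter number of refinement rounds.
#' @param sigma width (in residues) of the neighbour-offset agreement kernel.
#' @return A \linkS4class{CMOAlignment}; a matched contact contributes
#'   \code{min(w_model, w_pred)} to the matched weight, and the score is the
#'   matched weight minus internal gap penalties. For maps of at most 10
#'   residues the heuristic is replaced by an exact depth-first search, so
#'   the result is the true contact-maximum overlap there.
#' @export
alignContactMaps <- function(cmModel, cmPred, gapOpen = -3, gapExtend = -0.1,
                             nIter = 3L, sigma = 1.5) {
    stopifnot(is(cmModel, "ContactMap"), is(cmPred, "ContactMap"))
    WA <- contactMatrix(cmModel)
    WB <- contactMatrix(cmPred)
    if (nrow(cmModel@pairs) == 0 || nrow(cmPred@pairs) == 0)
        return(new("CMOAlignment",
                   mapping = matrix(integer(0), 0, 2,
                                    dimnames = list(NULL,
                                        c("model", "predicted"))),
                   matchedContacts = 0L, matchedWeight = 0, score = 0))
    res <- if (max(cmModel@L, cmPred@L) <= 10)
        cpp_cmo_exact(WA, WB)
    else cpp_cmo_align(WA, WB, gapOpen, gapExtend, as.integer(nIter),
                       sigma)
    m <- res$mapping
    colnames(m) <- c("model", "predicted")
    n <- nrow(m)
    supp <- logical(n)
    if (n > 1) {
        Asub <- WA[m[, 1], m[, 1], drop = FALSE] > 0
        Bsub <- WB[m[, 2], m[, 2], drop = FALSE] > 0
        diag(Asub) <- FALSE
        supp <- rowSums(Asub & Bsub) > 0
    }
    new("CMOAlignment", mapping = m,
        matchedContacts = as.integer(res$matchedContacts),
        matchedWeight = res$matchedWeight, score = res$score,
        supported = supp)
}

#' Exact contact-map-overlap by exhaustive enumeration
#'
#' Enumerates every monotone mapping between the two maps and returns one
#' that maximises the matched contact weight. Exponential in L: intended as
#' a test oracle, guarded to maps of at most 12 residues (8 or fewer is
#' practical).
#'
#' @param cmA,cmB \linkS4class{ContactMap}s with \code{L <= 12}.
#' @return A \linkS4class{CMOAlignment} with the optimal matched weight
#'   (score equals matched weight; no gap penalties).
#' @export
bruteForceCMO <- function(cmA, cmB) {
    LA <- cmA@L; LB <- cmB@L
    if (LA > 12 || LB > 12) stop("bruteForceCMO is limited to L <= 12")
    WA <- contactMatrix(cmA); WB <- contactMatrix(cmB)
    ut <- function(M, idx) {
        s <- M[idx, idx, drop = FALSE]
        s[upper.tri(s)]
    }
    bestScore <- 0; bestN <- 0L
    bestMap <- matrix(integer(0), 0, 2)
    for (k in seq_len(min(LA, LB))) {
        if (k < 2) next   # no pair can match
        subA <- utils::combn(LA, k)
        subB <- utils::combn(LB, k)
        for (a in seq_len(ncol(subA))) {
            ia <- subA[, a]
            wa <- ut(WA, ia)
            if (!any(wa > 0)) next
            for (b in seq_len(ncol(subB))) {
                jb <- subB[, b]
                wb <- ut(WB, jb)
                both <- wa > 0 & wb > 0
                if (!any(both)) next
                sc <- sum(pmin(wa[both], wb[both]))
                if (sc > bestScore + 1e-12) {
                    bestScore <- sc
                    bestN <- sum(both)
                    bestMap <- cbind(ia, jb)
                }
            }
        }
    }
    colnames(bestMap) <- c("model", "predicted")
    new("CMOAlignment", mapping = bestMap,
        matchedContacts = as.integer(bestN), matchedWeight = bestScore,
        score = bestScore)
}

#' Extract register-shift calls from a contact-map alignment
#'
#' Maximal runs of consecutively aligned residues with a constant nonzero
#' offset (predicted index minus model index) and length at least
#' \code{minLen} become calls; calls with the same shift lying within
#' \code{mergeGap} residues of each other are merged. Each run is first
#' trimmed to its matched-contact support: a contact-free residue at the
#' edge of a run carries no evidence for the alternative register (its
#' placement is an artefact of gap geometry), so it is not reported.
#'
#' @param aln a \linkS4class{CMOAlignment}.
#' @param minLen minimum run length to report.
#' @param mergeGap merge same-shift calls separated by at most this many
#'   residues.
#' @return List of \linkS4class{RegisterShiftCall} (filter verdicts
#'   initialised to "not_run").
#' @export
extractRegisterShifts <- function(aln, minLen = 5L, mergeGap = 5L) {
    m <- aln@mapping
    if (nrow(m) == 0) return(list())
    supp <- if (length(aln@supported) == nrow(m)) aln@supported
            else rep(TRUE, nrow(m))
    off <- m[, 2] - m[, 1]
    # break runs where the offset changes or model indices are not contiguous
    brk <- c(TRUE, diff(off) != 0 | diff(m[, 1]) != 1)
    run <- cumsum(brk)
    calls <- list()
    for (r in unique(run)) {
        sel <- which(run == r)
        if (off[sel[1]] == 0) next
        ws <- which(supp[sel])
        if (!length(ws)) next
        sel <- sel[ws[1]:ws[length(ws)]]
        if (length(sel) < minLen) next
        calls[[length(calls) + 1]] <- list(start = m[sel[1], 1],
                                           end = m[sel[length(sel)], 1],
                                           shift = off[sel[1]])
    }
    if (!length(calls)) return(list())
    # merge same-shift calls within mergeGap residues
    merged <- list(calls[[1]])
    for (c0 in calls[-1]) {
        last <- merged[[length(merged)]]
        if (c0$shift == last$shift && c0$start - last$end <= mergeGap + 1L)
            merged[[length(merged)]]$end <- c0$end
        else merged[[length(merged) + 1]] <- c0
    }
    lapply(merged, function(c0)
        new("RegisterShiftCall", start = as.integer(c0$start),
            end = as.integer(c0$end), shift = as.integer(c0$shift),
            filterVerdicts = c(contact_density = "not_run",
                               plddt = "not_run", qscore = "not_run")))
}

#' Contact-density false-positive filter
#'
#' A register-shift call fails when either the mean or the median number of
#' predicted contacts per residue over the affected range is below two:
#' too little contact information to trust the contact-map alignment.
#'
#' @param call a \linkS4class{RegisterShiftCall}.
#' @param predCM the \linkS4class{PredictedContactMap} used for alignment.
#' @return "pass" or "fail".
#' @export
contactDensityFilter <- function(call, predCM) {
    rng <- call@start:call@end
    if (!length(rng) || call@end > predCM@L) stop("empty or invalid range")
    cts <- contactCounts(predCM)[rng]
    if (mean(cts) < 2 || median(cts) < 2) "fail" else "pass"
}

#' pLDDT false-positive filter
#'
#' A call fails when the mean pLDDT of the predicted model over the affected
#' range is below 65 (prediction of insufficient quality). When no pLDDT is
#' available the filter is skipped with a warning.
#'
#' @param call a \linkS4class{RegisterShiftCall}.
#' @param predictedChain the predictor's \linkS4class{StructureChain}
#'   carrying pLDDT in its B-factor column.
#' @return "pass", "fail" or "skipped".
#' @export
plddtFilter <- function(call, predictedChain) {
    r <- predictedChain@residues
    sel <- r$seqIndex >= call@start & r$seqIndex <= call@end & r$modelled
    pl <- r$plddt[sel]
    pl <- pl[!is.na(pl)]
    if (!length(pl)) {
        warning("no pLDDT available; pLDDT filter skipped", call. = FALSE)
        return("skipped")
    }
    if (mean(pl) < 65) "fail" else "pass"
}

#' Least-squares rigid-body superposition (Kabsch)
#'
#' Finds the proper rotation and translation minimising the RMSD between
#' two matched coordinate sets, via SVD of the cross-covariance with a
#' determinant correction to exclude reflections.
#'
#' @param coordsA,coordsB n x 3 matrices of matched coordinates (n >= 3,
#'   non-degenerate). B is superposed onto A.
#' @return A \linkS4class{SuperpositionResult}; its \code{qScore} uses
#'   \code{n1 = n2 = nAlign} (so it is 1 iff the RMSD is 0).
#' @export
kabschSuperpose <- function(coordsA, coordsB) {
    coordsA <- as.matrix(coordsA); coordsB <- as.matrix(coordsB)
    n <- nrow(coordsA)
    if (n < 3 || nrow(coordsB) != n) stop("need >= 3 matched pairs")
    ca <- colMeans(coordsA); cb <- colMeans(coordsB)
    A <- sweep(coordsA, 2, ca); B <- sweep(coordsB, 2, cb)
    H <- t(B) %*% A
    sv <- svd(H)
    if (min(sv$d) < 1e-10 && sv$d[2] < 1e-10)
        stop("degenerate (collinear) coordinate set")
    d <- sign(det(sv$v %*% t(sv$u)))
    R <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
    Bfit <- B %*% t(R)
    rmsd <- sqrt(mean(rowSums((Bfit - A)^2)))
    q <- 1 / (1 + (rmsd / 3)^2)
    new("SuperpositionResult", rotation = R,
        translation = as.numeric(ca - R %*% cb), rmsd = rmsd,
        nAlign = as.integer(n), qScore = q)
}

#' Superposition Q-score over a residue range
#'
#' Superposes the whole model and predicted chains on their shared modelled
#' positions outside the suspect range (sequence-position correspondence),
#' then evaluates \code{Q = nAlign^2 / ((1 + (rmsd/R0)^2) * n1 * n2)} with
#' R0 = 3 Angstrom over the requested range, where n1 and n2 are the
#' numbers of modelled range residues in each chain and rmsd is taken over
#' the aligned range pairs after the whole-chain superposition.
#'
#' Within the range, model residue i is paired with predicted residue
#' \code{i + shift}: for a register-shift call the structurally
#' corresponding predicted residue is the one under the proposed register
#' (the backbone trace of a genuine register error matches the prediction
#' there), so a genuine shift scores high while a prediction in a different
#' conformation scores low.
#'
#' @param modelChain,predictedChain \linkS4class{StructureChain}s sharing
#'   the reference numbering.
#' @param start,end inclusive residue range (in model numbering).
#' @param shift pairing offset applied to the predicted chain within the
#'   range (0 = plain sequence-position pairing).
#' @param r0 Q-score distance constant in Angstrom.
#' @return list(q, rmsd, nAlign, n1, n2).
#' @export
rangeQscore <- function(modelChain, predictedChain, start, end, shift = 0L,
                        r0 = 3) {
    rm <- modelChain@residues; rp <- predictedChain@residues
    common <- intersect(rm$seqIndex[rm$modelled], rp$seqIndex[rp$modelled])
    frame <- setdiff(common, start:end)
    if (length(frame) < 3) frame <- common
    if (length(frame) < 3) stop("fewer than 3 shared modelled residues")
    xa <- repCoords(modelChain)
    xb <- repCoords(predictedChain)
    sup <- kabschSuperpose(xa[as.character(frame), , drop = FALSE],
                           xb[as.character(frame), , drop = FALSE])
    fit <- function(x) sweep(x %*% t(sup@rotation), 2, sup@translation, "+")
    rng <- start:end
    n1 <- sum(rm$modelled & rm$seqIndex %in% rng)
    n2 <- sum(rp$modelled & rp$seqIndex %in% rng)
    pairA <- rng[rm$modelled[rng]]
    pairB <- pairA + shift
    ok <- pairB >= 1 & pairB <= predictedChain@L
    pairA <- pairA[ok]; pairB <- pairB[ok]
    ok <- rp$modelled[pairB]
    pairA <- pairA[ok]; pairB <- pairB[ok]
    nAl <- length(pairA)
    if (nAl == 0 || n1 == 0 || n2 == 0)
        return(list(q = 0, rmsd = NA_real_, nAlign = 0L, n1 = n1, n2 = n2))
    d2 <- rowSums((fit(xb[as.character(pairB), , drop = FALSE]) -
                   xa[as.character(pairA), , drop = FALSE])^2)
    rmsd <- sqrt(mean(d2))
    q <- nAl^2 / ((1 + (rmsd / r0)^2) * n1 * n2)
    list(q = q, rmsd = rmsd, nAlign = as.integer(nAl), n1 = n1, n2 = n2)
}

#' Q-score false-positive filter
#'
#' A call fails when the superposition Q-score between the model and the
#' predicted model over the affected range (with predicted residues paired
#' under the call's proposed register) is below 0.5, indicating high
#' discrepancy between the two models: an inaccurate prediction or a
#' different conformation. Skipped when no predicted model is supplied.
#'
#' @param call a \linkS4class{RegisterShiftCall}.
#' @param modelChain the model being validated.
#' @param predictedChain the predicted model, or NULL.
#' @return "pass", "fail" or "skipped".
#' @export
qscoreFilter <- function(call, modelChain, predictedChain = NULL) {
    if (is.null(predictedChain)) return("skipped")
    q <- rangeQscore(modelChain, predictedChain, call@start, call@end,
                     shift = call@shift)$q
    if (q < 0.5) "fail" else "pass"
}

#' Apply the three false-positive filters to a register-shift call
#'
#' @param call a \linkS4class{RegisterShiftCall}.
#' @param predCM predicted contact map (for the contact-density filter).
#' @param predictedChain predicted model chain or NULL (pLDDT and Q-score
#'   filters are skipped when unavailable).
#' @param modelChain the model being validated (for the Q-score filter).
#' @return The call with \code{filterVerdicts} filled in.
#' @export
applyFilters <- function(call, predCM, modelChain, predictedChain = NULL) {
    v <- c(contact_density = contactDensityFilter(call, predCM),
           plddt = if (is.null(predictedChain)) "skipped" else
               suppressWarnings(plddtFilter(call, predictedChain)),
           qscore = qscoreFilter(call, modelChain, predictedChain))
    call@filterVerdicts <- v
    call
}

#' Write a CMO alignment as a two-column TSV
#'
#' @param aln a \linkS4class{CMOAlignment}.
#' @param path output path.
#' @export
writeAlignment <- function(aln, path) {
    write.table(as.data.frame(aln@mapping), path, sep = "\t", quote = FALSE,
                row.names = FALSE)
    invisible(path)
}
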