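## Predicted inter-residue distance distributions and derived quantities.

#' Construct a Distogram
#'
#' @param sequence reference amino-acid sequence (length L).
#' @param binEdges strictly increasing finite lower bin boundaries; bin b
#'   covers \code{[binEdges[b], binEdges[b+1])} and the last bin is
#'   open-ended above \code{binEdges[B]}.
#' @param probs L x L x B array of per-pair bin probabilities.
#' @return A \linkS4class{Distogram}.
#' @export
Distogram <- function(sequence, binEdges, probs) {
    new("Distogram", sequence = sequence, binEdges = as.numeric(binEdges),
        probs = probs)
}

# Default bin layout used by the synthetic generator: 2 to 22 A in 0.5 A
# steps, plus the open-ended bin above 22 A (41 bins).
defaultBinEdges <- function() seq(2, 22, by = 0.5)

.normalize_probs <- function(probs, tol = 1e-3) {
    L <- dim(probs)[1]; B <- dim(probs)[3]
    flat <- matrix(probs, L * L, B)
    s <- rowSums(flat)
    if (any(s <= 0) || any(abs(s - 1) > tol))
        stop("probability rows do not sum to 1 within ", tol)
    flat <- flat / s
    array(flat, dim = c(L, L, B))
}

#' Read a distogram from its JSON or TSV interchange form
#'
#' JSON dialect: an object with keys \code{sequence}, \code{bin_edges} and
#' \code{probs} (row-major flattened L x L x B, bin index fastest). TSV
#' dialect: a header line \code{#bin_edges: e1,e2,...} (and optionally
#' \code{#sequence: ...}), then rows \code{i<TAB>j<TAB>p1..pB}; missing
#' \code{(j, i)} rows are completed by symmetry.
#'
#' Rows are renormalised when their sum is within 1e-3 of 1 and rejected
#' otherwise; the distogram is symmetrised by averaging.
#'
#' @param path path to the distogram file (.json, or TSV otherwise).
#' @return A \linkS4class{Distogram}.
#' @export
loadDistogram <- function(path) {
    if (!file.exists(path)) stop("file not found: ", path)
    if (tolower(tools::file_ext(path)) == "json") {
        d <- jsonlite::fromJSON(path)
        if (!all(c("sequence", "bin_edges", "probs") %in% names(d)))
            stop("malformed distogram JSON: need sequence, bin_edges, probs")
        L <- nchar(d$sequence)
        B <- length(d$bin_edges)
        v <- as.numeric(unlist(d$probs))
        if (length(v) != L * L * B)
            stop("probs length does not match L^2 * B")
        probs <- aperm(array(v, dim = c(B, L, L)), c(3, 2, 1))
        sequence <- d$sequence
        edges <- as.numeric(d$bin_edges)
    } else {
        lines <- readLines(path)
        eh <- grep("^#bin_edges:", lines, value = TRUE)
        if (!length(eh)) stop("TSV distogram lacks a #bin_edges header")
        edges <- as.numeric(strsplit(sub("^#bin_edges:\\s*", "", eh[1]),
                                     ",")[[1]])
        sh <- grep("^#sequence:", lines, value = TRUE)
        body <- lines[!grepl("^#", lines) & nzchar(lines)]
        parts <- strsplit(body, "\t")
        B <- length(edges)
        mat <- t(vapply(parts, function(p) as.numeric(p), numeric(2 + B)))
        L <- max(mat[, 1:2])
        sequence <- if (length(sh))
            sub("^#sequence:\\s*", "", sh[1]) else strrep("X", L)
        if (nchar(sequence) != L) stop("sequence length mismatch")
        probs <- array(0, dim = c(L, L, B))
        seen <- matrix(FALSE, L, L)
        for (r in seq_len(nrow(mat))) {
            i <- mat[r, 1]; j <- mat[r, 2]
            probs[i, j, ] <- mat[r, -(1:2)]
            seen[i, j] <- TRUE
        }
        for (i in seq_len(L)) for (j in seq_len(L))
            if (seen[i, j] && !seen[j, i]) probs[j, i, ] <- probs[i, j, ]
        for (i in seq_len(L)) probs[i, i, ] <- c(1, rep(0, B - 1))
    }
    probs <- (probs + aperm(probs, c(2, 1, 3))) / 2
    probs <- .normalize_probs(probs)
    Distogram(sequence, edges, probs)
}

#' Write a distogram in the JSON interchange form
#'
#' @param d a \linkS4class{Distogram}.
#' @param path output path.
#' @export
writeDistogram <- function(d, path) {
    L <- chainLength(d)
    flat <- as.numeric(aperm(d@probs, c(3, 2, 1)))
    jsonlite::write_json(list(sequence = d@sequence,
                              bin_edges = d@binEdges, probs = flat),
                         path, auto_unbox = TRUE, digits = NA)
    invisible(path)
}

# Bin midpoints; the open-ended final bin uses its lower edge plus half the
# previous bin's width, since "midpoint" is undefined for an unbounded bin.
.bin_midpoints <- function(edges) {
    B <- length(edges)
    c((edges[-B] + edges[-1]) / 2, edges[B] + (edges[B] - edges[B - 1]) / 2)
}

#' Predicted distances and confidences from a distogram
#'
#' The predicted distance for a pair is the midpoint of its
#' highest-probability bin, and the confidence is that bin's probability.
#' Ties go to the lower-distance bin.
#'
#' @param d a \linkS4class{Distogram}.
#' @return A \linkS4class{DistancePrediction}.
#' @export
distogramToDistance <- function(d) {
    L <- chainLength(d)
    B <- length(d@binEdges)
    flat <- matrix(d@probs, L * L, B)
    best <- max.col(flat, ties.method = "first")
    mids <- .bin_midpoints(d@binEdges)
    pred <- matrix(mids[best], L, L)
    conf <- matrix(flat[cbind(seq_len(L * L), best)], L, L)
    new("DistancePrediction", predDist = pred, confidence = conf,
        farBin = matrix(best == B, L, L))
}

#' Contact probabilities from a distogram
#'
#' The contact probability of a pair is the total probability mass of the
#' bins whose upper edge is at or below the cutoff. The cutoff must coincide
#' with a bin edge so that no bin's mass is silently split.
#'
#' @param d a \linkS4class{Distogram}.
#' @param cutoff contact cutoff in Angstrom (default 8).
#' @return An L x L matrix of contact probabilities in [0, 1].
#' @export
distogramContactProbabilities <- function(d, cutoff = 8.0) {
    edges <- d@binEdges
    k <- which(abs(edges - cutoff) < 1e-9)
    if (!length(k))
        stop("cutoff ", cutoff, " does not coincide with a bin edge")
    nb <- k[1] - 1L   # bins fully below the cutoff
    if (nb == 0L) return(matrix(0, chainLength(d), chainLength(d)))
    apply(d@probs[, , seq_len(nb), drop = FALSE], c(1, 2), sum)
}

#' Select the top-L/2 predicted contacts
#'
#' Keeps the \code{floor(L * fraction)} pairs with the highest contact
#' probability among candidates with \code{|i - j| >= minSep}; ties are
#' broken by probability (descending), then i, then j (ascending). Pairs
#' with zero probability are never selected.
#'
#' @param P symmetric L x L contact-probability matrix.
#' @param L sequence length.
#' @param fraction fraction of L to keep (default 0.5, the standard top-L/2).
#' @param minSep minimum sequence separation.
#' @return A \linkS4class{PredictedContactMap}.
#' @export
selectTopContacts <- function(P, L = nrow(P), fraction = 0.5, minSep = 5L) {
    stopifnot(nrow(P) == ncol(P))
    ut <- which(upper.tri(P) & abs(row(P) - col(P)) >= minSep & P > 0,
                arr.ind = TRUE)
    p <- P[ut]
    ord <- order(-p, ut[, 1], ut[, 2])
    nKeep <- min(floor(L * fraction), length(ord))
    sel <- ord[seq_len(nKeep)]
    pairs <- data.frame(i = as.integer(ut[sel, 1]),
                        j = as.integer(ut[sel, 2]),
                        weight = pmin(1, p[sel]))
    pairs <- pairs[order(pairs$i, pairs$j), , drop = FALSE]
    rownames(pairs) <- NULL
    counts <- tabulate(c(pairs$i, pairs$j), nbins = L)
    new("PredictedContactMap", pairs = pairs, L = as.integer(L),
        counts = as.numeric(counts))
}

#' All predicted contacts above a probability threshold
#'
#' Returns every pair whose contact probability is at least \code{minProb}
#' (the binarised predicted contact map). The contact-map-overlap alignment
#' consumes this map: register assignment needs every confident contact,
#' and capping the list at L/2 leaves holes that make shifted alignments
#' spuriously competitive. The top-L/2 map remains the basis of the
#' confusion metrics and of the contact-density filter.
#'
#' @param P symmetric L x L contact-probability matrix.
#' @param minProb probability threshold (default 0.5: pairs more likely
#'   than not to be in contact).
#' @param minSep minimum sequence separation.
#' @return A \linkS4class{PredictedContactMap}.
#' @export
thresholdContacts <- function(P, minProb = 0.5, minSep = 5L) {
    L <- nrow(P)
    ut <- which(upper.tri(P) & abs(row(P) - col(P)) >= minSep &
                P >= minProb, arr.ind = TRUE)
    pairs <- data.frame(i = as.integer(ut[, 1]), j = as.integer(ut[, 2]),
                        weight = pmin(1, P[ut]))
    pairs <- pairs[order(pairs$i, pairs$j), , drop = FALSE]
    rownames(pairs) <- NULL
    counts <- tabulate(c(pairs$i, pairs$j), nbins = L)
    new("PredictedContactMap", pairs = pairs, L = as.integer(L),
        counts = as.numeric(counts))
}

#' Read a CASP-RR contact file
#'
#' Parses records \code{i j d1 d2 prob}; header/footer keywords (PFRMAT,
#' TARGET, MODEL, END, and a sequence block) are ignored. Used for
#' contact-only validation when no full distogram is available (wRMSD cannot
#' be computed in that mode).
#'
#' @param path path to the RR file.
#' @param L sequence length; inferred from the largest index if omitted.
#' @return A \linkS4class{PredictedContactMap} containing all listed pairs
#'   (apply \code{\link{selectTopContacts}} to its matrix form for top-L/2
#'   selection).
#' @export
readCaspRR <- function(path, L = NULL) {
    lines <- readLines(path)
    lines <- trimws(lines)
    keep <- grepl("^[0-9]+\\s+[0-9]+\\s", lines)
    parts <- strsplit(lines[keep], "\\s+")
    mat <- t(vapply(parts, function(p) as.numeric(p[1:5]), numeric(5)))
    if (!nrow(mat)) stop("no contact records in ", path)
    ii <- pmin(mat[, 1], mat[, 2]); jj <- pmax(mat[, 1], mat[, 2])
    if (is.null(L)) L <- max(jj)
    pairs <- data.frame(i = as.integer(ii), j = as.integer(jj),
                        weight = pmin(1, pmax(mat[, 5], 1e-6)))
    pairs <- pairs[!duplicated(pairs[, c("i", "j")]), , drop = FALSE]
    pairs <- pairs[order(pairs$i, pairs$j), , drop = FALSE]
    rownames(pairs) <- NULL
    counts <- tabulate(c(pairs$i, pairs$j), nbins = L)
    new("PredictedContactMap", pairs = pairs, L = as.integer(L),
        counts = as.numeric(counts))
}

#' Contact map as a dense weight matrix
#'
#' @param cm a \linkS4class{ContactMap}.
#' @return Symmetric L x L matrix with the pair weights (0 where no contact).
#' @export
contactMatrix <- function(cm) {
    m <- matrix(0, cm@L, cm@L)
    if (nrow(cm@pairs)) {
        m[cbind(cm@pairs$i, cm@pairs$j)] <- cm@pairs$weight
        m[cbind(cm@pairs$j, cm@pairs$i)] <- cm@pairs$weight
    }
    m
}
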