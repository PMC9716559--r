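## Reading coordinate models and deriving observed geometry.

# Theoretical maximum accessible surface areas (A^2) per residue type,
# used to turn raw DSSP accessibilities into relative values.
.MAX_ACC <- c(A = 129, R = 274, N = 195, D = 193, C = 167, E = 223, Q = 225,
              G = 104, H = 224, I = 197, L = 201, K = 236, M = 224, F = 240,
              P = 159, S = 155, T = 172, W = 285, Y = 263, V = 174, X = 200)

#' Construct a StructureChain
#'
#' Builds a chain covering reference positions \code{1..L}; positions not in
#' \code{seqIndex} are recorded as unmodelled.
#'
#' @param seqIndex integer vector of 1-based reference positions of the
#'   modelled residues (strictly increasing).
#' @param aa one-letter amino-acid codes of the modelled residues.
#' @param coords numeric matrix (n x 3) of representative-atom coordinates
#'   in Angstrom (C-beta convention; C-alpha for glycine).
#' @param plddt optional numeric vector of per-residue confidences (0-100).
#' @param L reference sequence length (default \code{max(seqIndex)}).
#' @param chainId chain identifier.
#' @return A \linkS4class{StructureChain}.
#' @export
StructureChain <- function(seqIndex, aa, coords, plddt = NULL,
                           L = max(seqIndex), chainId = "A") {
    seqIndex <- as.integer(seqIndex)
    coords <- as.matrix(coords)
    stopifnot(length(seqIndex) == length(aa),
              nrow(coords) == length(seqIndex), ncol(coords) == 3)
    if (is.null(plddt)) plddt <- rep(NA_real_, length(seqIndex))
    res <- data.frame(seqIndex = seq_len(L), aa = NA_character_,
                      x = NA_real_, y = NA_real_, z = NA_real_,
                      plddt = NA_real_, ss = NA_character_, acc = NA_real_,
                      modelled = FALSE, stringsAsFactors = FALSE)
    res$aa[seqIndex] <- aa
    res$x[seqIndex] <- coords[, 1]
    res$y[seqIndex] <- coords[, 2]
    res$z[seqIndex] <- coords[, 3]
    res$plddt[seqIndex] <- plddt
    res$modelled[seqIndex] <- TRUE
    new("StructureChain", residues = res, L = as.integer(L),
        chainId = chainId)
}

#' Read a single chain from a PDB or mmCIF file
#'
#' Extracts one chain and reduces each residue to its representative atom:
#' C-beta, or C-alpha for glycine and for residues whose C-beta is missing
#' (with a warning). Per-residue confidence (pLDDT for predicted models) is
#' read from the B-factor column.
#'
#' @param path path to a PDB (.pdb/.ent) or mmCIF (.cif) file.
#' @param chainId chain identifier to extract.
#' @return A \linkS4class{StructureChain}; unmodelled reference positions up
#'   to the largest residue number are present with empty coordinates.
#' @export
readModel <- function(path, chainId) {
    if (!file.exists(path)) stop("file not found: ", path)
    ext <- tolower(tools::file_ext(path))
    pdb <- if (ext == "cif") bio3d::read.cif(path) else bio3d::read.pdb(path)
    at <- pdb$atom
    at <- at[at$chain == chainId & at$type == "ATOM", , drop = FALSE]
    if (!nrow(at)) stop("unknown chain: ", chainId)
    # first alternate conformation only
    if ("alt" %in% names(at))
        at <- at[is.na(at$alt) | at$alt %in% c("", "A"), , drop = FALSE]
    resno <- unique(at$resno)
    if (length(resno) < 3) stop("chain has fewer than 3 modelled residues")
    if (min(resno) < 1)
        stop("non-positive residue numbers; renumber to the reference first")
    rows <- lapply(resno, function(rn) {
        a <- at[at$resno == rn, , drop = FALSE]
        aa3 <- a$resid[1]
        aa1 <- suppressWarnings(bio3d::aa321(aa3))
        if (is.na(aa1)) aa1 <- "X"
        elety <- if (aa1 == "G") "CA" else "CB"
        hit <- a[a$elety == elety, , drop = FALSE]
        if (!nrow(hit)) {
            hit <- a[a$elety == "CA", , drop = FALSE]
            if (!nrow(hit)) return(NULL)
            if (aa1 != "G")
                warning("residue ", rn, " (", aa3,
                        ") lacks a C-beta; using C-alpha", call. = FALSE)
        }
        c(rn, hit$x[1], hit$y[1], hit$z[1], hit$b[1], aa = aa1)
    })
    keep <- !vapply(rows, is.null, logical(1))
    rows <- rows[keep]
    if (length(rows) < 3) stop("chain has fewer than 3 modelled residues")
    num <- t(vapply(rows, function(r) as.numeric(r[1:5]), numeric(5)))
    aa <- vapply(rows, function(r) r[["aa"]], character(1))
    pl <- num[, 5]
    if (any(!is.na(pl)) && (min(pl, na.rm = TRUE) < 0 ||
                            max(pl, na.rm = TRUE) > 100))
        pl <- rep(NA_real_, length(pl))   # B-factors, not pLDDT
    StructureChain(seqIndex = num[, 1], aa = aa, coords = num[, 2:4],
                   plddt = pl, L = max(num[, 1]), chainId = chainId)
}

#' Observed inter-residue distance matrix
#'
#' Euclidean distances between representative-atom coordinates; entries
#' involving unmodelled residues are masked.
#'
#' @param chain a \linkS4class{StructureChain} with >= 2 modelled residues.
#' @return A \linkS4class{DistanceMatrix}.
#' @export
observedDistanceMatrix <- function(chain) {
    stopifnot(is(chain, "StructureChain"))
    if (sum(chain@residues$modelled) < 2)
        stop("need at least 2 modelled residues")
    xyz <- repCoords(chain)
    L <- chain@L
    mod <- chain@residues$modelled
    v <- matrix(NA_real_, L, L)
    d <- as.matrix(stats::dist(xyz[mod, , drop = FALSE]))
    v[mod, mod] <- d
    mask <- outer(mod, mod, "&")
    new("DistanceMatrix", values = v, mask = mask)
}

#' Observed contact map
#'
#' Two residues are in contact when their representative atoms (C-beta;
#' C-alpha for glycine) lie within \code{cutoff} of each other. Pairs closer
#' than \code{minSep} in sequence are excluded, as in standard
#' contact-prediction evaluation.
#'
#' @param chain a \linkS4class{StructureChain}.
#' @param cutoff contact distance cutoff in Angstrom.
#' @param minSep minimum sequence separation \code{|i - j|}.
#' @return A \linkS4class{ContactMap} with unit weights.
#' @export
observedContactMap <- function(chain, cutoff = 8.0, minSep = 5L) {
    dm <- observedDistanceMatrix(chain)
    L <- nrow(dm@values)
    idx <- which(upper.tri(dm@values) & dm@mask &
                 abs(row(dm@values) - col(dm@values)) >= minSep &
                 dm@values < cutoff, arr.ind = TRUE)
    p <- data.frame(i = as.integer(idx[, 1]), j = as.integer(idx[, 2]),
                    weight = rep(1, nrow(idx)))
    p <- p[order(p$i, p$j), , drop = FALSE]
    rownames(p) <- NULL
    new("ContactMap", pairs = p, L = as.integer(L))
}

# Virtual dihedral over four points, degrees in (-180, 180].
.dihedral <- function(p1, p2, p3, p4) {
    b1 <- p2 - p1; b2 <- p3 - p2; b3 <- p4 - p3
    n1 <- c(b1[2] * b2[3] - b1[3] * b2[2], b1[3] * b2[1] - b1[1] * b2[3],
            b1[1] * b2[2] - b1[2] * b2[1])
    n2 <- c(b2[2] * b3[3] - b2[3] * b3[2], b2[3] * b3[1] - b2[1] * b3[3],
            b2[1] * b3[2] - b2[2] * b3[1])
    m1 <- c(n1[2] * b2[3] - n1[3] * b2[2], n1[3] * b2[1] - n1[1] * b2[3],
            n1[1] * b2[2] - n1[2] * b2[1])
    bn <- sqrt(sum(b2^2))
    # sign convention: a right-handed alpha-helix trace scores about +50
    -atan2(sum(m1 * n2) / bn, sum(n1 * n2)) * 180 / pi
}

.parse_dssp <- function(path) {
    lines <- readLines(path)
    hdr <- grep("^  #  RESIDUE", lines)
    if (!length(hdr)) stop("not a DSSP file: ", path)
    body <- lines[(hdr[1] + 1):length(lines)]
    body <- body[nchar(body) >= 38]
    resno <- suppressWarnings(as.integer(substr(body, 6, 10)))
    keep <- !is.na(resno)
    data.frame(resno = resno[keep],
               chain = trimws(substr(body[keep], 12, 12)),
               aa = trimws(substr(body[keep], 14, 14)),
               ss = substr(body[keep], 17, 17),
               acc = suppressWarnings(as.numeric(substr(body[keep], 35, 38))),
               stringsAsFactors = FALSE)
}

#' Annotate secondary structure and solvent accessibility
#'
#' With a DSSP-format annotation file, secondary-structure codes are
#' collapsed to three classes (H/G/I to helix, E/B to sheet, the rest to
#' coil) and raw accessibilities are divided by the residue-type maximum and
#' clamped to [0, 1]. Without a file, a geometric fallback assigns secondary
#' structure from C-alpha virtual dihedrals and the i,i+3 distance, and
#' accessibility from a neighbour-count burial approximation (crude but
#' ordinal; accessibility is a minor feature of the classifier).
#'
#' @param chain a \linkS4class{StructureChain}.
#' @param annotationPath optional path to a DSSP file covering the chain.
#' @return The chain with \code{ss} and \code{acc} filled for modelled
#'   residues.
#' @export
assignSsAcc <- function(chain, annotationPath = NULL) {
    stopifnot(is(chain, "StructureChain"))
    r <- chain@residues
    if (!is.null(annotationPath)) {
        d <- .parse_dssp(annotationPath)
        d <- d[d$chain == chain@chainId | d$chain == "", , drop = FALSE]
        if (!nrow(d)) stop("annotation does not cover chain ", chain@chainId)
        m <- match(r$seqIndex, d$resno)
        found <- r$modelled & !is.na(m)
        if (!any(found)) stop("annotation/chain mismatch")
        code <- d$ss[m[found]]
        r$ss[found] <- ifelse(code %in% c("H", "G", "I"), "helix",
                       ifelse(code %in% c("E", "B"), "sheet", "coil"))
        mx <- .MAX_ACC[ifelse(r$aa[found] %in% names(.MAX_ACC),
                              r$aa[found], "X")]
        r$acc[found] <- pmin(1, pmax(0, d$acc[m[found]] / mx))
        r$ss[r$modelled & is.na(r$ss)] <- "coil"
        r$acc[r$modelled & is.na(r$acc)] <- 0.5
    } else {
        xyz <- as.matrix(r[, c("x", "y", "z")])
        mod <- which(r$modelled)
        ss <- rep("coil", nrow(r))
        for (k in seq_along(mod)) {
            i <- mod[k]
            # need i-1 .. i+2 and i+3 modelled and consecutive in sequence
            if (all(c(i - 1, i + 1, i + 2, i + 3) %in% mod)) {
                dih <- .dihedral(xyz[i - 1, ], xyz[i, ], xyz[i + 1, ],
                                 xyz[i + 2, ])
                d13 <- sqrt(sum((xyz[i, ] - xyz[i + 3, ])^2))
                if (abs(dih - 50) <= 30 && d13 < 6) ss[i] <- "helix"
                else if (abs(dih) > 120 && d13 > 9) ss[i] <- "sheet"
            }
        }
        r$ss[r$modelled] <- ss[r$modelled]
        dm <- as.matrix(stats::dist(xyz[mod, , drop = FALSE]))
        nb <- rowSums(dm <= 10) - 1
        r$acc[mod] <- 1 - nb / max(1, max(nb))
    }
    chain@residues <- r
    validObject(chain)
    chain
}

# Diagonal substitution matrix over the one-letter alphabet (match 2,
# mismatch -1); enough for near-identical model-vs-reference alignment.
.aa_submat <- function() {
    alpha <- c(LETTERS, "*")
    m <- matrix(-1, length(alpha), length(alpha),
                dimnames = list(alpha, alpha))
    diag(m) <- 2
    m
}

#' Renumber a chain onto its reference sequence
#'
#' Globally aligns the modelled residues' sequence to the reference sequence
#' and replaces residue numbers by the aligned reference positions. Refuses
#' if the alignment identity over modelled residues is below 90%, which
#' indicates the chain does not correspond to the reference.
#'
#' @param chain a \linkS4class{StructureChain}.
#' @param refSeq reference amino-acid sequence (one-letter string).
#' @return The renumbered chain, with \code{L = nchar(refSeq)}; residues that
#'   cannot be aligned are dropped with a warning.
#' @export
renumberToReference <- function(chain, refSeq) {
    stopifnot(is(chain, "StructureChain"), nchar(refSeq) >= 3)
    r <- chain@residues[chain@residues$modelled, , drop = FALSE]
    seqModel <- paste(r$aa, collapse = "")
    aln <- Biostrings::pairwiseAlignment(
        Biostrings::AAString(seqModel), Biostrings::AAString(refSeq),
        type = "global", substitutionMatrix = .aa_submat(),
        gapOpening = 8, gapExtension = 0.5)
    pat <- strsplit(as.character(Biostrings::alignedPattern(aln)), "")[[1]]
    sub <- strsplit(as.character(Biostrings::alignedSubject(aln)), "")[[1]]
    ip <- 0L; is_ <- 0L
    mapTo <- rep(NA_integer_, nrow(r))
    nid <- 0L
    for (k in seq_along(pat)) {
        if (pat[k] != "-") ip <- ip + 1L
        if (sub[k] != "-") is_ <- is_ + 1L
        if (pat[k] != "-" && sub[k] != "-") {
            mapTo[ip] <- is_
            if (pat[k] == sub[k]) nid <- nid + 1L
        }
    }
    identity <- nid / nrow(r)
    if (identity < 0.9)
        stop(sprintf(
            "alignment identity %.2f below 0.9; manual inspection required",
            identity))
    drop <- is.na(mapTo)
    if (any(drop))
        warning(sum(drop), " residue(s) could not be aligned and were dropped",
                call. = FALSE)
    keep <- !drop
    StructureChain(seqIndex = mapTo[keep], aa = r$aa[keep],
                   coords = as.matrix(r[keep, c("x", "y", "z")]),
                   plddt = r$plddt[keep], L = nchar(refSeq),
                   chainId = chain@chainId)
}
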