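## Synthetic structures, distograms and register-error corruptions.
## These define the test-bed conditions for the whole package: toy folds
## with realistic contact density, sharply peaked distograms with
## controllable corruption, and register shifts that move coordinates (not
## sequence letters), so downstream modules see exactly the signature of a
## real register error: the observed geometry of position i matches the
## prediction for position i + k.

# Ideal alpha-helix C-alpha trace along +/- z.
.helix_seg <- function(n, phase = 0, dirz = 1) {
    t <- seq_len(n) - 1
    th <- phase + dirz * t * 100 * pi / 180
    cbind(2.3 * cos(th), 2.3 * sin(th), dirz * 1.5 * t)
}

# Extended beta-strand trace along +/- z; the pleat is perpendicular to the
# sheet plane (strands stack along x), so it does not modulate the
# strand-to-strand spacing. Each strand gets its own small rise, tilt and
# z-offset perturbations: real strands are never exact lattice repeats, and
# an exactly periodic sheet would make the contact map invariant under
# register shifts of one pleat, which no real fold is.
.strand_seg <- function(n, dirz = 1) {
    t <- seq_len(n) - 1
    rise <- 3.3 + stats::runif(1, -0.25, 0.25)
    tiltx <- stats::runif(1, -0.2, 0.2)
    tilty <- stats::runif(1, -0.2, 0.2)
    z0 <- stats::runif(1, -0.5, 0.5)
    cbind(tiltx * t, 0.9 * (-1)^t + tilty * t, dirz * (z0 + rise * t))
}

# Bridge between two anchor points (turn residues); an optional arc bulge
# (along `bulge`, typically +/- z beyond the strand tips) keeps longer
# turns from piling onto the straight line between the anchors.
.bridge <- function(from, to, n, bulge = c(0, 0, 0)) {
    if (n < 1) return(NULL)
    f <- seq_len(n) / (n + 1)
    out <- outer(f, to - from) + matrix(from, n, 3, byrow = TRUE)
    out + outer(sin(pi * f), bulge)
}

.self_avoid <- function(xyz, minDist = 2.2, maxTries = 200) {
    for (t in seq_len(maxTries)) {
        d <- as.matrix(stats::dist(xyz))
        diag(d) <- Inf
        bad <- which(apply(d, 1, min) < minDist)
        if (!length(bad)) return(xyz)
        xyz[bad, ] <- xyz[bad, ] +
            matrix(stats::rnorm(3 * length(bad), 0, 0.3), ncol = 3)
    }
    xyz
}

#' Generate a toy protein fold
#'
#' Builds a self-avoiding representative-atom trace from parametric
#' secondary-structure segments joined by short turns: either a bundle of
#' antiparallel helices (axis spacing 9 Angstrom) or a mixed sheet
#' (strand spacing 4.8 Angstrom) with coil insertions. Residue identities
#' are drawn uniformly from the 20 standard amino acids and pLDDT is set to
#' 90. Deterministic under the seed.
#'
#' @param L chain length (>= 10).
#' @param topology "helix_bundle" or "sheet_coil_mix".
#' @param seed integer seed.
#' @return A \linkS4class{StructureChain} with every residue modelled.
#' @export
makeToyFold <- function(L, topology = c("helix_bundle", "sheet_coil_mix"),
                        seed = 1L) {
    topology <- match.arg(topology)
    if (L < 10) stop("L must be at least 10")
    set.seed(seed)
    if (topology == "helix_bundle") {
        # antiparallel helices, uniform 9 A axis spacing
        segType <- function(s) "helix"
        spacing <- function(s) 9
    } else {
        # one tightly packed sheet unit (five short strands, 4.7 A spacing)
        # followed by a helical periphery: the tight unit's cross-strand
        # distances (4.7-5.8 A) outrank everything else, so the most
        # confident predicted contacts concentrate there, as they do in the
        # well-packed core of a real fold. Strand lengths vary so the unit
        # is aperiodic (a register shift by one strand repeat must not
        # reproduce the contact map, as it would in an idealised lattice).
        # spacing widens from the first interface outwards, so the most
        # confident predicted contacts concentrate at the sheet edge (a
        # packing gradient, as in real mixed sheets with one tight core)
        segType <- function(s) if (s <= 4) "strand" else "helix"
        spacing <- function(s) if (s < 4) c(4.5, 4.7, 6.6)[s] +
                                   stats::runif(1, -0.1, 0.1)
                               else 11
    }
    coords <- NULL
    ss <- character(0)
    s <- 0L
    x <- 0
    strandLen <- sample(9:11, 1)   # constant within a chain, so every
                                   # strand is fully paired with its
                                   # neighbours in the antiparallel ladder
    while (is.null(coords) || nrow(coords) < L) {
        s <- s + 1L
        dirz <- if (s %% 2 == 1) 1 else -1
        if (segType(s) == "strand") {
            seg <- .strand_seg(strandLen, dirz = dirz)
            segSS <- "sheet"
            # five-residue arced turns keep the strand-to-strand hairpin
            # connections longer than the contact minimum separation, so
            # rungs near the turns still count as (long-range) contacts
            turnLen <- 5L
            turnBulge <- c(0, 0, -dirz * 3.5)
        } else {
            seg <- .helix_seg(sample(18:26, 1), dirz = dirz)
            segSS <- "helix"
            turnLen <- sample(2:4, 1)
            turnBulge <- c(0, 0, 0)
        }
        if (s > 1) x <- x + spacing(s - 1)
        seg[, 1] <- seg[, 1] + x
        if (s > 1) {
            # start near where the previous segment ended
            prevEnd <- coords[nrow(coords), ]
            seg[, 3] <- seg[, 3] + prevEnd[3] - seg[1, 3]
            br <- .bridge(prevEnd, seg[1, ], turnLen, turnBulge)
            coords <- rbind(coords, br)
            ss <- c(ss, rep("coil", nrow(br)))
        }
        coords <- rbind(coords, seg)
        ss <- c(ss, rep(segSS, nrow(seg)))
    }
    coords <- coords[seq_len(L), , drop = FALSE]
    ss <- ss[seq_len(L)]
    coords <- coords + matrix(stats::rnorm(3 * L, 0, 0.15), ncol = 3)
    coords <- .self_avoid(coords)
    aa <- sample(setdiff(names(.MAX_ACC), "X"), L, replace = TRUE)
    chain <- StructureChain(seqIndex = seq_len(L), aa = aa, coords = coords,
                            plddt = rep(90, L), L = L, chainId = "A")
    chain@residues$ss <- ss   # generating topology is known exactly
    chain
}

#' Simulate a distogram for a chain
#'
#' For each residue pair the probability mass is a discretised Gaussian
#' centred on the true representative-atom distance with standard deviation
#' \code{sharpness}; with probability \code{noise} a pair's centre is
#' displaced by a random offset of at least 4 Angstrom (emulating a
#' confidently wrong prediction). Mass below the first bin edge is folded
#' into the first bin; the final open-ended bin absorbs the upper tail, so
#' every row sums to exactly 1.
#'
#' @param chain a fully modelled \linkS4class{StructureChain}.
#' @param sharpness Gaussian standard deviation in Angstrom (> 0).
#' @param noise fraction of pairs with a corrupted centre, in [0, 1].
#' @param seed integer seed.
#' @param binEdges finite lower bin boundaries (default 2 to 22 Angstrom in
#'   0.5 steps plus the open bin above 22).
#' @return A \linkS4class{Distogram}.
#' @export
simulateDistogram <- function(chain, sharpness = 1.0, noise = 0.0,
                              seed = 1L, binEdges = defaultBinEdges()) {
    stopifnot(sharpness > 0, noise >= 0, noise <= 1)
    set.seed(seed)
    dm <- observedDistanceMatrix(chain)
    L <- nrow(dm@values)
    C <- dm@values
    if (noise > 0) {
        ut <- which(upper.tri(C), arr.ind = TRUE)
        hit <- which(runif(nrow(ut)) < noise)
        if (length(hit)) {
            off <- runif(length(hit), 4, 10) *
                   sample(c(-1, 1), length(hit), replace = TRUE)
            idx <- ut[hit, , drop = FALSE]
            C[idx] <- pmax(0.5, C[idx] + off)
            C[idx[, c(2, 1), drop = FALSE]] <- C[idx]
        }
    }
    B <- length(binEdges)
    probs <- array(0, dim = c(L, L, B))
    cum <- lapply(binEdges, function(e) pnorm(e, mean = C, sd = sharpness))
    probs[, , 1] <- cum[[2]]
    for (b in 2:(B - 1)) probs[, , b] <- cum[[b + 1]] - cum[[b]]
    probs[, , B] <- 1 - cum[[B]]
    for (i in seq_len(L)) probs[i, i, ] <- c(1, rep(0, B - 1))
    Distogram(chainSequence(chain), binEdges, probs)
}

#' Inject a sequence-register shift into a chain
#'
#' Residues in \code{[start, end]} take the coordinates of residues
#' \code{[start + shift, end + shift]} of the input chain: the backbone
#' trace is kept but the sequence register is wrong over the segment, which
#' is the geometric signature of a register error. The \code{|shift|}
#' residues flanking the segment whose true positions are consumed by the
#' misassigned stretch (\code{end+1 .. end+shift} for a positive shift,
#' \code{start+shift .. start-1} for a negative one) become unmodelled: a
#' single physical backbone cannot occupy those positions twice, and in
#' real register-shifted models the corresponding stretch is compressed
#' into or missing near the error. All other coordinates are untouched.
#'
#' @param chain a \linkS4class{StructureChain}.
#' @param start,end inclusive segment, with
#'   \code{[start + shift, end + shift]} inside \code{[1, L]}.
#' @param shift nonzero integer register offset.
#' @return list(chain = corrupted \linkS4class{StructureChain},
#'   labels = integer vector, 1 inside the segment and 0 outside).
#' @export
injectRegisterShift <- function(chain, start, end, shift) {
    shift <- as.integer(shift)
    if (shift == 0L) stop("shift must be nonzero")
    L <- chain@L
    if (start < 1 || end > L || end < start ||
        start + shift < 1 || end + shift > L)
        stop("shifted range out of bounds")
    r <- chain@residues
    src <- (start:end) + shift
    if (!all(r$modelled[c(start:end, src)]))
        stop("segment and its shifted source must be fully modelled")
    r[start:end, c("x", "y", "z")] <- r[src, c("x", "y", "z")]
    # positions whose density is consumed by the shifted segment
    dup <- if (shift > 0) (end + 1L):(end + shift)
           else (start + shift):(start - 1L)
    dup <- setdiff(dup, start:end)
    r$modelled[dup] <- FALSE
    r[dup, c("x", "y", "z")] <- NA_real_
    chain@residues <- r
    labels <- integer(L)
    labels[start:end] <- 1L
    list(chain = chain, labels = labels)
}

# Sample up to nSeg non-overlapping register-error segments for a chain.
.sample_segments <- function(L, nSeg, lenRange = c(6L, 40L),
                             shiftRange = 1:5) {
    segs <- list()
    occupied <- rep(FALSE, L)
    tries <- 0
    while (length(segs) < nSeg && tries < 50) {
        tries <- tries + 1
        len <- sample(lenRange[1]:lenRange[2], 1)
        shift <- sample(shiftRange, 1) * sample(c(-1L, 1L), 1)
        lo <- max(1L, 1L - shift)
        hi <- min(L, L - shift) - len + 1L
        if (hi < lo) next
        start <- sample(lo:hi, 1)
        end <- start + len - 1L
        # reserve the segment, its shifted source and the flank residues
        # that the corruption unmodels, so later segments cannot collide
        span <- max(1L, min(start, start + shift) - 5L):
                min(L, max(end, end + shift) + 5L)
        if (any(occupied[span])) next
        occupied[span] <- TRUE
        segs[[length(segs) + 1]] <- list(start = start, end = end,
                                         shift = shift)
    }
    segs
}

#' Generate a labelled per-residue error dataset
#'
#' Builds \code{nChains} toy folds, injects 0-2 register-shift segments per
#' chain (lengths 6-40 residues, shifts 1-5 in either direction, so both
#' easily detectable and hard short errors are represented), simulates a
#' distogram for each clean chain, and computes the classifier feature
#' matrix for the corrupted chains. Labels are 1 inside injected segments
#' and 0 outside; group ids record the source chain for leakage-aware
#' splitting.
#'
#' @param nChains number of chains.
#' @param L chain length.
#' @param sharpness,noise distogram simulation parameters (see
#'   \code{\link{simulateDistogram}}).
#' @param seed integer seed.
#' @return A \linkS4class{LabelledDataset}.
#' @export
generateLabelledDataset <- function(nChains = 40L, L = 100L,
                                    sharpness = 1.0, noise = 0.1,
                                    seed = 1L) {
    set.seed(seed)
    chainSeeds <- sample.int(2^30, nChains * 3)
    feats <- list(); labs <- list(); grps <- list()
    for (c0 in seq_len(nChains)) {
        topo <- if (c0 %% 2 == 1) "helix_bundle" else "sheet_coil_mix"
        chain <- makeToyFold(L, topo, seed = chainSeeds[3 * c0 - 2])
        dg <- simulateDistogram(chain, sharpness = sharpness, noise = noise,
                                seed = chainSeeds[3 * c0 - 1])
        set.seed(chainSeeds[3 * c0])
        nSeg <- sample(0:2, 1, prob = c(0.15, 0.45, 0.4))
        segs <- .sample_segments(L, nSeg)
        corrupted <- chain
        labels <- integer(L)
        for (s in segs) {
            res <- injectRegisterShift(corrupted, s$start, s$end, s$shift)
            corrupted <- res$chain
            labels <- pmax(labels, res$labels)
        }
        corrupted <- assignSsAcc(corrupted)
        mt <- buildMetricTable(corrupted, dg)
        feats[[c0]] <- buildFeatureMatrix(mt, corrupted)
        labs[[c0]] <- labels
        grps[[c0]] <- rep(sprintf("chain%03d", c0), L)
    }
    new("LabelledDataset", features = do.call(rbind, feats),
        labels = as.integer(unlist(labs)), groups = unlist(grps))
}

#' Run one seeded register-shift recovery trial
#'
#' Builds a mixed-sheet toy fold, simulates a sharp distogram, picks a
#' segment of \code{lenRange} residues whose top-L/2 predicted-contact
#' density is at least \code{minDensity} contacts per residue (register
#' reassignment needs sufficient contact information; contact-poor segments
#' are exactly where the method is expected to miss), injects a register
#' shift of \code{shift} over it, runs the contact-map alignment and reports
#' whether the shift was recovered.
#'
#' @param seed integer seed.
#' @param shift register shift to inject (nonzero).
#' @param L chain length.
#' @param lenRange segment length range (inclusive).
#' @param sharpness distogram sharpness in Angstrom.
#' @param minDensity minimum predicted contacts per residue over the segment.
#' @param tol endpoint tolerance (residues) for calling a recovery exact.
#' @return list(start, end, shift, calls, recovered, startError, endError);
#'   \code{recovered} is TRUE when some call has the exact shift and both
#'   endpoints within \code{tol}.
#' @export
registerShiftTrial <- function(seed, shift, L = 100L, lenRange = c(20L, 30L),
                               sharpness = 1.0, minDensity = 2, tol = 2L) {
    set.seed(seed)
    subSeeds <- sample.int(2^30, 40)
    for (attempt in seq_along(subSeeds)) {
        trial <- .one_shift_trial(subSeeds[attempt], shift, L, lenRange,
                                  sharpness, minDensity, tol)
        if (!is.null(trial)) return(trial)
    }
    stop("no fold admitting a qualifying segment was found")
}

# A single candidate fold; NULL when it admits no qualifying segment for
# this shift (the caller then draws a fresh fold).
.one_shift_trial <- function(seed, shift, L, lenRange, sharpness,
                             minDensity, tol) {
    chain <- makeToyFold(L, "sheet_coil_mix", seed = seed)
    dg <- simulateDistogram(chain, sharpness = sharpness, noise = 0,
                            seed = seed + 10^6)
    P <- distogramContactProbabilities(dg)
    predCM <- selectTopContacts(P, L)          # defines the density condition
    cmoCM <- thresholdContacts(P)              # alignment input
    cnt <- contactCounts(predCM)
    set.seed(seed + 2 * 10^6)
    # candidate segments span whole strands, with boundaries at the
    # midpoints of the flanking turns: register errors occupy complete
    # secondary-structure units delimited by loops, and only there is the
    # error boundary defined by the contact data to within a couple of
    # residues
    ssr <- chain@residues$ss
    rl <- rle(ssr)
    segEnd <- cumsum(rl$lengths)
    segStart <- segEnd - rl$lengths + 1L
    str <- which(rl$values == "sheet")
    pp <- contactPairs(cmoCM)
    cand <- list()
    for (a in 1L) for (b in seq_len(max(0, length(str) - 2))) {
        if (b < a) next
        # the segment spans whole strands starting at the sheet edge, with
        # its boundaries one residue into the flanking turns: register
        # errors occupy complete secondary-structure units delimited by
        # loops, and the strands left outside the segment must themselves
        # stay contact-anchored (each still pairs with a further strand),
        # otherwise their register - and hence the segment boundary - is
        # undetermined
        lo <- max(1L, segStart[str[a]] - 1L)
        hi <- min(L, segEnd[str[b]] + 1L)
        len <- hi - lo + 1L
        if (len < lenRange[1] || len > lenRange[2]) next
        if (lo + shift < 1 || hi + shift > L) next
        if (mean(cnt[lo:hi]) < minDensity) next
        # detectability: the shifted segment's observed geometry is that of
        # the true window [lo + shift, hi + shift], so its register is only
        # determined where that window has internal predicted contacts;
        # require the support to reach both window ends to within two
        # residues, otherwise no contact-based method can place the
        # boundaries
        internal <- pp$i >= lo + shift & pp$j <= hi + shift
        if (!any(internal)) next
        if (min(pp$i[internal]) > lo + shift + 2L ||
            max(pp$j[internal]) < hi + shift - 2L) next
        cand[[length(cand) + 1]] <- c(lo, hi)
    }
    if (!length(cand)) return(NULL)
    pick <- cand[[sample.int(length(cand), 1)]]
    start <- pick[1]; end <- pick[2]
    corrupted <- injectRegisterShift(chain, start, end, shift)$chain
    aln <- alignContactMaps(observedContactMap(corrupted), cmoCM)
    calls <- extractRegisterShifts(aln)
    recovered <- FALSE; se <- NA_integer_; ee <- NA_integer_
    for (c0 in calls)
        if (c0@shift == shift) {
            se <- c0@start - start; ee <- c0@end - end
            if (abs(se) <= tol && abs(ee) <= tol) recovered <- TRUE
        }
    list(start = start, end = end, shift = shift, calls = calls,
         recovered = recovered, startError = se, endError = ee)
}
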