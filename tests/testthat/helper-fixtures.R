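# Fixture builders shared across the suite. Everything is generated in
# code; no binary fixtures.

# Minimal PDB writer: one representative atom per residue is enough for
# readModel (CB, CA for glycine), plus optional extra CA records.
write_mini_pdb <- function(path, resno, aa3, elety, xyz, bfac = 0,
                           chain = "A") {
    bfac <- rep_len(bfac, length(resno))
    lines <- vapply(seq_along(resno), function(k) {
        sprintf("ATOM  %5d  %-3s%4s %s%4d    %8.3f%8.3f%8.3f  1.00%6.2f",
                k, elety[k], aa3[k], chain, resno[k],
                xyz[k, 1], xyz[k, 2], xyz[k, 3], bfac[k])
    }, character(1))
    writeLines(c(lines, "END"), path)
    path
}

# ALA-GLY-ALA three-residue chain with CB/CA/CB representative atoms.
mini_chain_pdb <- function(path, bfac = 90) {
    write_mini_pdb(path,
                   resno = c(1L, 1L, 2L, 3L, 3L),
                   aa3 = c("ALA", "ALA", "GLY", "ALA", "ALA"),
                   elety = c("CA", "CB", "CA", "CA", "CB"),
                   xyz = rbind(c(0, 0, 0), c(0, 1.5, 0),
                               c(3.8, 0, 0),
                               c(7.6, 0, 0), c(7.6, 1.5, 0)),
                   bfac = bfac)
}

# StructureChain straight line along x with given spacing.
line_chain <- function(L, spacing = 3.8, aa = NULL) {
    if (is.null(aa)) aa <- rep("A", L)
    StructureChain(seqIndex = seq_len(L), aa = aa,
                   coords = cbind((seq_len(L) - 1) * spacing, 0, 0),
                   plddt = rep(90, L), L = L)
}

# Distogram with an exact one-hot bin per pair, from a distance matrix.
onehot_distogram <- function(D, binEdges = defaultBinEdges(),
                             sequence = NULL) {
    L <- nrow(D)
    if (is.null(sequence)) sequence <- strrep("A", L)
    B <- length(binEdges)
    probs <- array(0, dim = c(L, L, B))
    for (i in seq_len(L)) for (j in seq_len(L)) {
        b <- if (i == j) 1L else max(1L, findInterval(D[i, j], binEdges))
        probs[i, j, b] <- 1
    }
    Distogram(sequence, binEdges, probs)
}

# ContactMap from an explicit pair list.
contact_map <- function(pairs_ij, L, weight = 1) {
    p <- data.frame(i = as.integer(pairs_ij[, 1]),
                    j = as.integer(pairs_ij[, 2]),
                    weight = rep_len(weight, nrow(pairs_ij)))
    p <- p[order(p$i, p$j), , drop = FALSE]
    rownames(p) <- NULL
    new("ContactMap", pairs = p, L = as.integer(L))
}

# Seeded random contact map (density ~0.3, separation >= 2).
random_contact_map <- function(L, seed, weighted = FALSE) {
    set.seed(seed)
    m0 <- matrix(0, L, L)
    ut <- which(upper.tri(m0) & abs(row(m0) - col(m0)) >= 2,
                arr.ind = TRUE)
    keep <- runif(nrow(ut)) < 0.3
    w <- if (weighted) round(runif(sum(keep), 0.4, 1), 3)
         else rep(1, sum(keep))
    contact_map(ut[keep, , drop = FALSE], L, w)
}

# Manually assembled CMOAlignment (all positions supported).
manual_alignment <- function(model, predicted) {
    m <- cbind(model = as.integer(model), predicted = as.integer(predicted))
    new("CMOAlignment", mapping = m, matchedContacts = 0L,
        matchedWeight = 0, score = 0, supported = rep(TRUE, nrow(m)))
}

# Register-shift call helper.
shift_call <- function(start, end, shift) {
    new("RegisterShiftCall", start = as.integer(start),
        end = as.integer(end), shift = as.integer(shift),
        filterVerdicts = c(contact_density = "not_run", plddt = "not_run",
                           qscore = "not_run"))
}
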