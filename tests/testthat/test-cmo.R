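test_that("aligning a map against itself recovers the identity", {
    cm <- random_contact_map(12, seed = 7)
    aln <- alignContactMaps(cm, cm)
    expect_equal(aln@matchedWeight, sum(contactPairs(cm)$weight))
    expect_equal(aln@matchedContacts, nrow(contactPairs(cm)))
    m <- alignmentMapping(aln)
    # contact-bearing residues sit on the identity diagonal
    touched <- sort(unique(unlist(contactPairs(cm)[, c("i", "j")])))
    sel <- m[, 1] %in% touched
    expect_equal(m[sel, 1], m[sel, 2])
})

test_that("an empty map aligns with zero overlap", {
    empty <- new("ContactMap",
                 pairs = data.frame(i = integer(0), j = integer(0),
                                    weight = numeric(0)), L = 8L)
    aln <- alignContactMaps(empty, random_contact_map(8, 1))
    expect_equal(aln@matchedContacts, 0L)
    expect_equal(nrow(alignmentMapping(aln)), 0L)
})

test_that("a shifted copy aligns at the shift with optimal overlap", {
    # 8-residue map vs the same contacts moved by +2 within 10 positions
    p <- rbind(c(1, 4), c(2, 6), c(3, 8), c(4, 7), c(5, 8))
    A <- contact_map(p, 10)
    B <- contact_map(p + 2, 10)
    aln <- alignContactMaps(A, B)
    m <- alignmentMapping(aln)
    expect_true(all(m[, 2] - m[, 1] == 2))
    expect_equal(aln@matchedWeight, bruteForceCMO(A, B)@matchedWeight)
})

test_that("the brute-force oracle handles identical and disjoint maps", {
    cm <- random_contact_map(5, seed = 3)
    expect_equal(bruteForceCMO(cm, cm)@matchedWeight,
                 sum(contactPairs(cm)$weight))
    a <- contact_map(rbind(c(1, 3)), 5)
    b <- contact_map(rbind(c(2, 5)), 5)
    # single contacts always match under some monotone mapping
    expect_equal(bruteForceCMO(a, b)@matchedWeight, 1)
    expect_error(bruteForceCMO(random_contact_map(13, 1), cm), "L <= 12")
})

test_that("the aligner never beats and almost always matches the oracle", {
    eq <- 0
    for (s in 1:30) {
        A <- random_contact_map(8, 2 * s)
        B <- random_contact_map(8, 2 * s + 1, weighted = TRUE)
        h <- alignContactMaps(A, B)
        bf <- bruteForceCMO(A, B)
        expect_lte(h@matchedWeight, bf@matchedWeight + 1e-9)
        if (abs(h@matchedWeight - bf@matchedWeight) < 1e-9) eq <- eq + 1
    }
    expect_gte(eq, ceiling(0.95 * 30))
})

test_that("register-shift extraction reports constant-offset runs", {
    expect_length(extractRegisterShifts(manual_alignment(1:20, 1:20)), 0)
    aln <- manual_alignment(c(1:9, 10:40), c(1:9, 12:42))
    calls <- extractRegisterShifts(aln)
    expect_length(calls, 1)
    expect_equal(c(calls[[1]]@start, calls[[1]]@end, calls[[1]]@shift),
                 c(10, 40, 2))
    # same-shift runs within five residues are merged
    aln2 <- manual_alignment(c(5:20, 23:30), c(6:21, 24:31))
    merged <- extractRegisterShifts(aln2)
    expect_length(merged, 1)
    expect_equal(c(merged[[1]]@start, merged[[1]]@end, merged[[1]]@shift),
                 c(5, 30, 1))
    # runs below the minimum length are dropped
    short <- manual_alignment(c(1:4, 8:20), c(2:5, 8:20))
    expect_length(extractRegisterShifts(short, minLen = 5), 0)
})

test_that("unsupported run edges are trimmed from calls", {
    m <- cbind(model = 1:12, predicted = 3:14)
    aln <- new("CMOAlignment", mapping = m, matchedContacts = 0L,
               matchedWeight = 0, score = 0,
               supported = c(FALSE, FALSE, rep(TRUE, 8), FALSE, FALSE))
    calls <- extractRegisterShifts(aln)
    expect_length(calls, 1)
    expect_equal(c(calls[[1]]@start, calls[[1]]@end), c(3, 10))
})

test_that("the contact-density filter flips at two contacts per residue", {
    mk <- function(counts) new("PredictedContactMap",
        pairs = data.frame(i = integer(0), j = integer(0),
                           weight = numeric(0)),
        L = length(counts), counts = counts)
    call <- shift_call(1, 5, 1)
    expect_equal(contactDensityFilter(call, mk(c(1, 1, 2, 2, 2))), "fail")
    expect_equal(contactDensityFilter(call, mk(rep(2, 5))), "pass")
    expect_equal(contactDensityFilter(call, mk(c(0, 0, 10, 10, 10))),
                 "pass")   # median 10, mean 6
})

test_that("the pLDDT filter flips at 65 and skips without pLDDT", {
    mk <- function(pl) {
        ch <- line_chain(5)
        ch@residues$plddt <- pl
        ch
    }
    call <- shift_call(1, 5, 1)
    expect_equal(plddtFilter(call, mk(rep(64.9, 5))), "fail")
    expect_equal(plddtFilter(call, mk(rep(65, 5))), "pass")
    expect_warning(v <- plddtFilter(call, mk(rep(NA_real_, 5))), "skipped")
    expect_equal(v, "skipped")
})

test_that("Kabsch superposition is exact under rigid motion", {
    set.seed(11)
    A <- matrix(rnorm(30), 10, 3)
    expect_equal(kabschSuperpose(A, A)@rmsd, 0, tolerance = 1e-10)
    th <- 0.7
    R <- rbind(c(cos(th), -sin(th), 0), c(sin(th), cos(th), 0), c(0, 0, 1))
    B <- A %*% t(R) + matrix(c(3, -2, 5), 10, 3, byrow = TRUE)
    sup <- kabschSuperpose(A, B)
    expect_equal(sup@rmsd, 0, tolerance = 1e-8)
    expect_equal(sup@qScore, 1, tolerance = 1e-8)
    expect_equal(det(sup@rotation), 1, tolerance = 1e-8)
    expect_error(kabschSuperpose(A[1:2, ], B[1:2, ]), "3 matched")
})

test_that("superposition RMSD agrees with an independent least-squares fit", {
    set.seed(4)
    A <- matrix(rnorm(12), 4, 3)
    B <- A
    B[2, ] <- B[2, ] + c(1.5, -0.5, 2)   # one displaced point
    ours <- kabschSuperpose(A, B)
    ref <- suppressWarnings(bio3d::fit.xyz(fixed = as.numeric(t(A)),
                                           mobile = as.numeric(t(B))))
    refRmsd <- sqrt(mean(rowSums((matrix(ref, ncol = 3, byrow = TRUE) -
                                  A)^2)))
    expect_equal(ours@rmsd, refRmsd, tolerance = 1e-6)
})

test_that("the Q-score filter flips at 0.5", {
    # displacement pattern orthogonal to all rigid motions: after optimal
    # superposition the residual RMSD equals the displacement amplitude
    L <- 40
    base <- cbind((seq_len(L) - 1) * 3.8, rep(c(0, 2, 0, 2), L / 4), 0)
    sgn <- rep(c(1, -1, -1, 1), L / 4)
    mk <- function(delta) {
        xyz <- base
        xyz[, 3] <- xyz[, 3] + delta * sgn
        StructureChain(seqIndex = seq_len(L), aa = rep("A", L),
                       coords = xyz, plddt = rep(90, L), L = L)
    }
    model <- mk(0)
    q3 <- rangeQscore(model, mk(3), 1, L)
    expect_equal(q3$rmsd, 3, tolerance = 1e-6)
    expect_equal(q3$q, 0.5, tolerance = 1e-6)
    expect_equal(rangeQscore(model, mk(0), 1, L)$q, 1, tolerance = 1e-8)
    # boundary behaviour of the filter itself
    call <- shift_call(11, 30, 1)
    expect_equal(qscoreFilter(call, model, NULL), "skipped")
})

test_that("a genuine register shift passes the Q filter, a different fold fails", {
    L <- 40
    i <- seq_len(L)
    truth <- StructureChain(seqIndex = i, aa = rep("A", L),
                            coords = cbind(3.8 * i, 3 * sin(0.9 * i),
                                           2.5 * cos(0.6 * i)),
                            plddt = rep(90, L), L = L)
    corrupted <- injectRegisterShift(truth, 11, 30, 1)$chain
    call <- shift_call(11, 30, 1)
    # the model's shifted range superposes onto the prediction under the
    # proposed register, so the call survives the filter
    expect_equal(qscoreFilter(call, corrupted, truth), "pass")
    other <- StructureChain(seqIndex = i, aa = rep("A", L),
                            coords = cbind(3.8 * i, 6 * cos(1.7 * i),
                                           4 * sin(2.3 * i)),
                            plddt = rep(90, L), L = L)
    expect_equal(qscoreFilter(call, corrupted, other), "fail")
})
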