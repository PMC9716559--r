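# End-to-end validation pipeline on synthetic chains.

# Deterministically find a fold admitting a qualifying shifted segment and
# return the pieces validateChain needs.
qualifying_case <- function(seed, shift) {
    set.seed(seed)
    subSeeds <- sample.int(2^30, 40)
    for (ss in subSeeds) {
        tr <- tryCatch(
            registercheck:::.one_shift_trial(ss, as.integer(shift), 100L,
                                             c(20L, 30L), 1.0, 2, 2L),
            error = function(e) NULL)
        if (!is.null(tr))
            return(list(foldSeed = ss, start = tr$start, end = tr$end))
    }
    stop("no qualifying fold")
}

test_that("clean chains produce no calls at default thresholds", {
    for (s in 1:5) {
        topo <- if (s %% 2) "helix_bundle" else "sheet_coil_mix"
        ch <- assignSsAcc(makeToyFold(100, topo, seed = s))
        dg <- simulateDistogram(ch, sharpness = 1, noise = 0,
                                seed = s + 3000)
        rep <- validateChain(ch, dg)
        expect_length(rep@errorCalls, 0)
        expect_length(rep@shiftCalls, 0)
        expect_equal(nrow(reportTable(rep)), 100L)
    }
})

test_that("an injected +3 shift yields one filtered register-shift call", {
    cs <- qualifying_case(seed = 5, shift = 3)
    chain <- makeToyFold(100, "sheet_coil_mix", seed = cs$foldSeed)
    dg <- simulateDistogram(chain, sharpness = 1, noise = 0,
                            seed = cs$foldSeed + 10^6)
    corrupted <- injectRegisterShift(chain, cs$start, cs$end, 3)$chain
    rep <- validateChain(corrupted, dg, predictedChain = chain)
    expect_length(rep@shiftCalls, 1)
    call <- rep@shiftCalls[[1]]
    expect_equal(call@shift, 3L)
    expect_lte(abs(call@start - cs$start), 2)
    expect_lte(abs(call@end - cs$end), 2)
    expect_equal(unname(filterVerdicts(call)), rep("pass", 3))
    # per-residue CMO status reflects the call
    tab <- reportTable(rep)
    expect_true(all(tab$cmoStatus[call@start:call@end] == "alternative"))
    expect_true(all(tab$shift[call@start:call@end] == 3))
})

test_that("disabling filters keeps calls but leaves verdicts unset", {
    cs <- qualifying_case(seed = 7, shift = 2)
    chain <- makeToyFold(100, "sheet_coil_mix", seed = cs$foldSeed)
    dg <- simulateDistogram(chain, sharpness = 1, noise = 0,
                            seed = cs$foldSeed + 10^6)
    corrupted <- injectRegisterShift(chain, cs$start, cs$end, 2)$chain
    with_f <- validateChain(corrupted, dg, predictedChain = chain)
    no_f <- validateChain(corrupted, dg, predictedChain = chain,
                          filters = FALSE)
    expect_equal(length(no_f@shiftCalls), length(with_f@shiftCalls))
    expect_true(all(unlist(lapply(no_f@shiftCalls, filterVerdicts)) ==
                    "not_run"))
})

test_that("the same inputs give a byte-identical JSON report", {
    ch <- assignSsAcc(makeToyFold(60, "sheet_coil_mix", seed = 21))
    dg <- simulateDistogram(ch, sharpness = 1, noise = 0, seed = 22)
    f1 <- withr::local_tempfile(fileext = ".json")
    f2 <- withr::local_tempfile(fileext = ".json")
    writeReport(validateChain(ch, dg), jsonPath = f1)
    writeReport(validateChain(ch, dg), jsonPath = f2)
    expect_identical(readLines(f1), readLines(f2))
})

test_that("reports round-trip through TSV and JSON", {
    cs <- qualifying_case(seed = 9, shift = 2)
    chain <- makeToyFold(100, "sheet_coil_mix", seed = cs$foldSeed)
    dg <- simulateDistogram(chain, sharpness = 1, noise = 0,
                            seed = cs$foldSeed + 10^6)
    corrupted <- injectRegisterShift(chain, cs$start, cs$end, 2)$chain
    rep <- validateChain(corrupted, dg, predictedChain = chain)
    tsv <- withr::local_tempfile(fileext = ".tsv")
    json <- withr::local_tempfile(fileext = ".json")
    writeReport(rep, tsvPath = tsv, jsonPath = json)
    tab <- read.table(tsv, sep = "\t", header = TRUE)
    expect_equal(nrow(tab), 100L)      # one row per reference position
    back <- readReport(json)
    expect_equal(length(back@shiftCalls), length(rep@shiftCalls))
    expect_equal(back@shiftCalls[[1]]@shift, rep@shiftCalls[[1]]@shift)
    expect_equal(back@residues$score, rep@residues$score)
    # display smoothing never alters the stored raw scores
    expect_equal(back@residues$score, reportTable(rep)$score)
})

test_that("file-level validation runs from a PDB and a distogram JSON", {
    ch <- makeToyFold(40, "sheet_coil_mix", seed = 31)
    r <- residueTable(ch)
    pdb <- withr::local_tempfile(fileext = ".pdb")
    aa3 <- vapply(r$aa, function(a) bio3d::aa123(a), character(1))
    write_mini_pdb(pdb, resno = r$seqIndex, aa3 = aa3,
                   elety = ifelse(r$aa == "G", "CA", "CB"),
                   xyz = as.matrix(r[, c("x", "y", "z")]), bfac = 90)
    dg <- simulateDistogram(ch, sharpness = 1, noise = 0, seed = 32)
    json <- withr::local_tempfile(fileext = ".json")
    writeDistogram(dg, json)
    rep <- runValidate(pdb, "A", json)
    expect_s4_class(rep, "ValidationReport")
    expect_equal(nrow(reportTable(rep)), 40L)
    expect_length(rep@shiftCalls, 0)
})
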