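make_ds <- function(X, y, groups = NULL) {
    if (is.null(groups)) groups <- rep("g1", length(y))
    new("LabelledDataset", features = as.matrix(X), labels = as.integer(y),
        groups = groups)
}

test_that("correlation pruning groups by transitive |r| >= 0.4", {
    set.seed(2)
    n <- 300
    a <- rnorm(n)
    X <- cbind(a = a, b = a + rnorm(n, 0, 1e-6),      # |r| = 1 with a
               c = rnorm(n), d = rnorm(n))
    y <- as.integer(a + rnorm(n) > 0)
    keep <- correlationPrune(X, y)
    expect_length(intersect(keep, c("a", "b")), 1)    # one of the pair
    expect_true(all(c("c", "d") %in% keep))           # independent survive
    # brute-force closure oracle on a 5-column block structure
    e <- rnorm(n)
    X5 <- cbind(p = a, q = a + rnorm(n, 0, 0.5), r = e,
                s = e + rnorm(n, 0, 0.5), t = rnorm(n))
    R <- abs(cor(X5)) >= 0.4
    expect_true(R["p", "q"] && R["r", "s"] && !R["p", "r"])
    keep5 <- correlationPrune(X5, y)
    expect_length(keep5, 3)   # one of {p,q}, one of {r,s}, plus t
    expect_true("t" %in% keep5)
    expect_warning(correlationPrune(cbind(X, const = 1), y), "constant")
})

test_that("the balanced 80:20 split reproduces the published arithmetic", {
    P <- 2428L; N <- 6192L
    ds <- make_ds(matrix(rnorm(P + N), ncol = 1),
                  c(rep(1L, P), rep(0L, N)))
    sp <- makeBalancedSplit(ds, seed = 1)
    expect_equal(nrow(sp$train@features), 3884L)
    expect_equal(nrow(sp$test@features), 972L)
    expect_equal(sum(sp$train@labels == 1), sum(sp$train@labels == 0))
    expect_equal(sum(sp$test@labels == 1), sum(sp$test@labels == 0))
    # no row is shared between the two sides
    small <- makeBalancedSplit(make_ds(matrix(rnorm(30), ncol = 1),
                                       rep(c(1L, 0L), c(10, 20))),
                               seed = 2)
    expect_equal(nrow(small$train@features), 16L)   # floor(8) * 2
    expect_equal(nrow(small$test@features), 4L)
    expect_error(makeBalancedSplit(make_ds(matrix(rnorm(19), ncol = 1),
                                           rep(c(1L, 0L), c(10, 9))),
                                   seed = 1), "balance")
})

test_that("group-aware splitting keeps a group's positives on one side", {
    set.seed(3)
    y <- rep(c(1L, 0L), c(60, 240))
    g <- paste0("chain", rep(1:10, 30))
    ds <- make_ds(matrix(rnorm(300), ncol = 1), y, g)
    sp <- makeBalancedSplit(ds, seed = 4, byGroup = TRUE)
    trG <- unique(sp$train@groups[sp$train@labels == 1])
    teG <- unique(sp$test@groups[sp$test@labels == 1])
    expect_length(intersect(trG, teG), 0)
})

test_that("training separates separable blobs and is seed-deterministic", {
    set.seed(5)
    X <- rbind(matrix(rnorm(120, 3), ncol = 2),
               matrix(rnorm(120, -3), ncol = 2))
    colnames(X) <- c("f1", "f2")
    y <- rep(c(1L, 0L), each = 60)
    ds <- make_ds(X, y)
    clf <- trainErrorClassifier(ds, nIter = 10, seed = 1)
    acc <- mean((scoreResidues(clf, X) > 0.5) == (y == 1))
    expect_equal(acc, 1)
    clf2 <- trainErrorClassifier(ds, nIter = 10, seed = 1)
    expect_identical(clf@weights, clf2@weights)
    expect_identical(clf@calibration, clf2@calibration)
    expect_error(trainErrorClassifier(make_ds(X, rep(1L, 120)), seed = 1),
                 "both classes")
    expect_error(trainErrorClassifier(ds, nIter = 0, seed = 1), "nIter")
})

test_that("the scaler is fitted on training rows only", {
    set.seed(6)
    X <- matrix(rnorm(200), ncol = 2,
                dimnames = list(NULL, c("f1", "f2")))
    y <- rep(c(0L, 1L), 50)
    clf <- trainErrorClassifier(make_ds(X, y), nIter = 5, seed = 1)
    expect_equal(clf@center, unname(colMeans(X)))
    expect_equal(clf@scale, unname(apply(X, 2, sd)))
    # appending extra rows that are NOT in the training set must not
    # change the stored scaler
    clf2 <- trainErrorClassifier(make_ds(X, y), nIter = 5, seed = 1)
    expect_identical(clf@center, clf2@center)
})

test_that("scoring is deterministic and guards feature dimensions", {
    set.seed(7)
    X <- matrix(rnorm(120), ncol = 2,
                dimnames = list(NULL, c("f1", "f2")))
    y <- rep(c(0L, 1L), 30)
    clf <- trainErrorClassifier(make_ds(X, y), nIter = 5, seed = 1)
    s1 <- scoreResidues(clf, X)
    expect_true(all(s1 >= 0 & s1 <= 1))
    expect_equal(scoreResidues(clf, X[c(1, 1, 2), ]),
                 s1[c(1, 1, 2)])                 # duplicates score equally
    expect_error(scoreResidues(clf, matrix(0, 2, 5)), "dimensionality")
})

test_that("error-run calling applies the run-length and score thresholds", {
    base <- rep(0.1, 30)
    s <- base; s[10:15] <- 0.95
    calls <- flagErrorRuns(s)
    expect_length(calls, 1)
    expect_equal(c(calls[[1]]@start, calls[[1]]@end, calls[[1]]@nResidues),
                 c(10, 15, 6))
    s5 <- base; s5[10:14] <- 0.95                # five < minRun
    expect_length(flagErrorRuns(s5), 0)
    s2 <- base; s2[1:6] <- 0.95; s2[7] <- 0.5; s2[8:13] <- 0.95
    expect_length(flagErrorRuns(s2), 2)          # run-length scan oracle
    # threshold 0 and minRun 1 span the whole chain
    all1 <- flagErrorRuns(base, minRun = 1, threshold = 0)
    expect_length(all1, 1)
    expect_equal(c(all1[[1]]@start, all1[[1]]@end), c(1, 30))
})

test_that("recall never increases with the run-length threshold", {
    set.seed(8)
    labels <- integer(200)
    labels[40:60] <- 1L; labels[120:150] <- 1L
    scores <- ifelse(labels == 1, runif(200, 0.7, 1), runif(200, 0, 0.8))
    recall <- vapply(1:20, function(mr) {
        calls <- flagErrorRuns(scores, minRun = mr, threshold = 0.7)
        flagged <- logical(200)
        for (c0 in calls) flagged[c0@start:c0@end] <- TRUE
        sum(flagged & labels == 1) / sum(labels == 1)
    }, numeric(1))
    expect_true(all(diff(recall) <= 1e-12))
})

test_that("the rank AUC agrees with an independent implementation", {
    set.seed(9)
    y <- rep(c(0L, 1L), 60)
    s <- y * 0.4 + runif(120)
    expect_equal(aucScore(s, y),
                 as.numeric(pROC::auc(pROC::roc(y, s, quiet = TRUE))))
    rp <- rocPoints(s, y)
    expect_true(all(diff(rp$TPR) >= 0) && all(diff(rp$FPR) >= 0))
})

test_that("classifier JSON serialisation round-trips", {
    set.seed(10)
    X <- matrix(rnorm(120), ncol = 2,
                dimnames = list(NULL, c("f1", "f2")))
    y <- rep(c(0L, 1L), 30)
    clf <- trainErrorClassifier(make_ds(X, y), nIter = 5, seed = 1)
    path <- withr::local_tempfile(fileext = ".json")
    writeClassifier(clf, path)
    back <- readClassifier(path)
    expect_equal(back@weights, clf@weights)
    expect_equal(back@center, clf@center)
    expect_equal(scoreResidues(back, X), scoreResidues(clf, X))
})
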