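make_pred <- function(predDist, confidence) {
    new("DistancePrediction", predDist = predDist, confidence = confidence)
}

test_that("wRMSD reproduces the hand-evaluated 3-residue case", {
    x <- matrix(c(0, 5, 9,
                  5, 0, 5,
                  9, 5, 0), 3, 3, byrow = TRUE)
    xhat <- matrix(c(0, 6, 9,
                     6, 0, 5,
                     9, 5, 0), 3, 3, byrow = TRUE)
    obs <- new("DistanceMatrix", values = x, mask = matrix(TRUE, 3, 3))
    pred <- make_pred(xhat, matrix(1, 3, 3))
    wr <- wrmsdProfile(obs, pred, minSep = 1)
    expect_equal(wr$values, c(sqrt(1 / 2), sqrt(1 / 2), 0))
    expect_false(any(wr$flags))
})

test_that("wRMSD is zero for a perfect prediction and flags zero weight", {
    x <- matrix(c(0, 5, 9, 5, 0, 5, 9, 5, 0), 3, 3)
    obs <- new("DistanceMatrix", values = x, mask = matrix(TRUE, 3, 3))
    perfect <- wrmsdProfile(obs, make_pred(x, matrix(1, 3, 3)), minSep = 1)
    expect_equal(perfect$values, rep(0, 3))
    zero_w <- wrmsdProfile(obs, make_pred(x + 1, matrix(0, 3, 3)),
                           minSep = 1)
    expect_equal(zero_w$values, rep(0, 3))
    expect_true(all(zero_w$flags))
})

test_that("wRMSD grows when one residue's deviations are inflated", {
    set.seed(1)
    ch <- makeToyFold(30, "helix_bundle", seed = 1)
    obs <- observedDistanceMatrix(ch)
    base <- obs@values
    for (eps in c(0.5, 1, 2)) {
        xhat <- base
        xhat[3, ] <- xhat[3, ] + eps
        xhat[, 3] <- xhat[, 3] + eps
        diag(xhat) <- 0
        w <- wrmsdProfile(obs, make_pred(xhat, matrix(1, 30, 30)),
                          minSep = 5)$values
        if (eps > 0.5) expect_gt(w[3], prev)
        prev <- w[3]
    }
})

test_that("confusion counts partition the pair universe", {
    obsCM <- contact_map(rbind(c(1, 6), c(2, 8), c(3, 8)), 10)
    predCM <- new("PredictedContactMap",
                  pairs = contact_map(rbind(c(1, 6), c(4, 10)), 10)@pairs,
                  L = 10L, counts = tabulate(c(1, 6, 4, 10), 10))
    cc <- contactConfusionProfile(predCM, obsCM, minSep = 5)
    expect_true(all(with(cc, TP + FP + TN + FN == universe)))
    # brute-force oracle over every pair
    U <- abs(outer(1:10, 1:10, "-")) >= 5
    P <- contactMatrix(predCM) > 0
    O <- contactMatrix(obsCM) > 0
    expect_equal(cc$TP, as.integer(rowSums(P & O & U)))
    expect_equal(cc$FN, as.integer(rowSums(!P & O & U)))
    expect_equal(cc$FP, as.integer(rowSums(P & !O & U)))
    # identical maps: no FP/FN, TP = degree
    cc2 <- contactConfusionProfile(
        new("PredictedContactMap", pairs = obsCM@pairs, L = 10L,
            counts = tabulate(c(obsCM@pairs$i, obsCM@pairs$j), 10)),
        obsCM, minSep = 5)
    expect_true(all(cc2$FP == 0 & cc2$FN == 0))
    expect_equal(cc2$TP, as.integer(rowSums(contactMatrix(obsCM) > 0 & U)))
})

test_that("confusion metrics match the direct formulas", {
    counts <- data.frame(TP = 2L, FP = 1L, TN = 90L, FN = 3L,
                         universe = 96L)
    m <- confusionMetrics(counts)
    expect_equal(m$values[, "Accuracy"], 92 / 96, ignore_attr = TRUE)
    expect_equal(m$values[, "Sensitivity"], 0.4, ignore_attr = TRUE)
    expect_equal(m$values[, "FPrate"], 1 / 91, ignore_attr = TRUE)
    expect_equal(m$values[, "Precision"], 2 / 3, ignore_attr = TRUE)
    # zero denominators flagged, not NaN
    z <- confusionMetrics(data.frame(TP = 0L, FP = 0L, TN = 5L, FN = 0L,
                                     universe = 5L))
    expect_equal(z$values[, "Sensitivity"], 0, ignore_attr = TRUE)
    expect_true(z$flags[, "Sensitivity"])
    expect_true(all(is.finite(z$values)))
})

test_that("five-point smoothing shrinks at the edges and honours flags", {
    expect_equal(smoothProfile(rep(3, 9))$values, rep(3, 9))
    spike <- c(0, 0, 0, 0, 10, 0, 0, 0, 0)
    sm <- smoothProfile(spike)$values
    expect_equal(sm[5], 2)                     # five-point mean
    expect_equal(sm[c(1, 2, 8, 9)], rep(0, 4)) # >= 3 away untouched
    edge <- smoothProfile(c(10, rep(0, 9)))$values
    expect_equal(edge[1], 10 / 3)              # shrunk 3-point window
    # flagged values are excluded from window means
    fl <- smoothProfile(c(10, 0, 0, 0, 0), flags = c(TRUE, rep(FALSE, 4)))
    expect_equal(fl$values[2], 0)
    # commutes with constant shifts
    v <- rnorm(20)
    expect_equal(smoothProfile(v + 7)$values, smoothProfile(v)$values + 7)
})

test_that("spatial Z-scores standardise within the 10 A neighbourhood", {
    ch <- StructureChain(seqIndex = 1:4, aa = rep("A", 4),
                        coords = cbind((0:3) * 4, 0, 0), L = 4)
    v <- c(1, 2, 3, 10)
    z <- spatialZscoreProfile(v, ch)$values
    # oracle: explicit neighbourhood means and population SDs
    xyz <- cbind((0:3) * 4, 0, 0)
    want <- vapply(1:4, function(i) {
        nb <- which(sqrt(rowSums((xyz - matrix(xyz[i, ], 4, 3,
                                               byrow = TRUE))^2)) <= 10)
        s <- v[nb]
        sdev <- sqrt(mean((s - mean(s))^2))
        if (sdev > 0) (v[i] - mean(s)) / sdev else 0
    }, numeric(1))
    expect_equal(z, want)
    # uniform values and affine invariance
    expect_equal(spatialZscoreProfile(rep(4, 4), ch)$values, rep(0, 4))
    expect_equal(spatialZscoreProfile(3 * v + 2, ch)$values, z)
})

test_that("the metric table has exactly 24 named columns", {
    ch <- makeToyFold(40, "sheet_coil_mix", seed = 5)
    dg <- simulateDistogram(ch, sharpness = 1, noise = 0, seed = 6)
    mt <- buildMetricTable(ch, dg)
    expect_equal(ncol(metricValues(mt)), 24L)
    expect_equal(colnames(metricValues(mt)), metricNames())
    expect_true(all(metricValues(mt)[, c("Accuracy", "Precision",
                                         "Sensitivity", "Specificity",
                                         "FPrate")] >= 0))
    # FP rate and specificity are complementary where defined
    ok <- !metricFlags(mt)[, "FPrate"] & !metricFlags(mt)[, "Specificity"]
    expect_equal(metricValues(mt)[ok, "FPrate"] +
                 metricValues(mt)[ok, "Specificity"], rep(1, sum(ok)))
    # deterministic recomputation
    expect_equal(metricValues(buildMetricTable(ch, dg)), metricValues(mt))
})

test_that("a faithful sparse prediction yields perfect contact metrics", {
    # two clusters; the only long-separation contacts are (1,6) and (7,12),
    # and a very sharp distogram has zero mass below 8 A for all far pairs
    xyz <- rbind(cbind(seq(0, 7.5, length.out = 6), 0, 0),
                 cbind(seq(0, 7.5, length.out = 6), 100, 0))
    ch <- StructureChain(seqIndex = 1:12, aa = rep("A", 12), coords = xyz,
                        L = 12)
    dg <- simulateDistogram(ch, sharpness = 0.05, noise = 0, seed = 1)
    mt <- buildMetricTable(ch, dg)
    expect_true(all(metricValues(mt)[, "wRMSD"] < 0.3))
    expect_equal(metricValues(mt)[, "Accuracy"], rep(1, 12),
                 ignore_attr = TRUE)
})
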