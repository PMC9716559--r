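## Feature engineering, balanced splitting, linear-SVM training with random
## hyperparameter search, Platt-calibrated scoring and run-based error calls.

# The seven metrics surviving correlation pruning, in canonical order.
.selected_metrics <- c("Accuracy", "FPrate", "smooth_Sensitivity",
                       "smooth_wRMSD", "Z_Accuracy", "Z_Sensitivity",
                       "Z_wRMSD")

#' Names of the classifier features
#'
#' The seven selected covariance metrics plus solvent accessibility and the
#' secondary-structure one-hot encoding (11 features).
#'
#' @return Character vector of length 11.
#' @export
featureNames <- function() {
    c(.selected_metrics, "acc", "ss_helix", "ss_sheet", "ss_coil")
}

#' Build the per-residue feature matrix
#'
#' Extracts the seven selected metrics from a \linkS4class{MetricTable} and
#' appends the residue solvent accessibility and the three-class
#' secondary-structure one-hot encoding. Residues without an annotation are
#' encoded as coil with accessibility 0.
#'
#' @param mt a \linkS4class{MetricTable}.
#' @param chain the matching \linkS4class{StructureChain} (provides ss/acc).
#' @return Numeric matrix, one row per residue, 11 named columns.
#' @export
buildFeatureMatrix <- function(mt, chain) {
    r <- chain@residues
    stopifnot(nrow(mt@metrics) == nrow(r))
    ss <- ifelse(is.na(r$ss), "coil", r$ss)
    X <- cbind(mt@metrics[, .selected_metrics, drop = FALSE],
               acc = ifelse(is.na(r$acc), 0, r$acc),
               ss_helix = as.numeric(ss == "helix"),
               ss_sheet = as.numeric(ss == "sheet"),
               ss_coil = as.numeric(ss == "coil"))
    colnames(X) <- featureNames()
    X
}

#' Prune mutually correlated metric columns
#'
#' Groups columns by the transitive closure of pairwise Pearson
#' \code{|r| >= threshold} and keeps one representative per group: the
#' column with the largest absolute linear-discriminant coefficient against
#' the labels (falling back to the univariate standardised mean difference
#' when the joint discriminant is singular). Constant columns are dropped
#' with a warning since their correlation is undefined. Shipped as a
#' reusable utility: the default feature set is fixed, so this is not rerun
#' at inference time.
#'
#' @param X numeric matrix (>= 2 columns).
#' @param labels binary vector aligned with rows.
#' @param threshold absolute correlation threshold (default 0.4).
#' @return Character vector of surviving column names.
#' @export
correlationPrune <- function(X, labels, threshold = 0.4) {
    stopifnot(ncol(X) >= 2, length(labels) == nrow(X))
    sds <- apply(X, 2, sd)
    if (any(sds == 0)) {
        warning("dropping constant column(s): ",
                paste(colnames(X)[sds == 0], collapse = ", "),
                call. = FALSE)
        X <- X[, sds > 0, drop = FALSE]
    }
    if (ncol(X) < 2) return(colnames(X))
    R <- abs(cor(X)) >= threshold
    # connected components of the correlation graph
    comp <- rep(NA_integer_, ncol(X))
    cid <- 0L
    for (s in seq_len(ncol(X))) {
        if (!is.na(comp[s])) next
        cid <- cid + 1L
        queue <- s
        while (length(queue)) {
            v <- queue[1]; queue <- queue[-1]
            if (!is.na(comp[v])) next
            comp[v] <- cid
            queue <- c(queue, which(R[v, ] & is.na(comp)))
        }
    }
    disc <- function(cols) {
        Z <- scale(X[, cols, drop = FALSE])
        co <- tryCatch({
            # collinear columns are exactly what this utility prunes, so
            # lda's collinearity warning is expected noise here
            fit <- suppressWarnings(MASS::lda(Z, grouping = factor(labels)))
            abs(fit$scaling[, 1])
        }, error = function(e) {
            vapply(seq_along(cols), function(k) {
                z <- Z[, k]
                abs(mean(z[labels == 1]) - mean(z[labels == 0]))
            }, numeric(1))
        })
        cols[which.max(co)]
    }
    keep <- vapply(seq_len(cid), function(g) {
        cols <- colnames(X)[comp == g]
        if (length(cols) == 1) cols else disc(cols)
    }, character(1))
    keep[order(match(keep, colnames(X)))]
}

.subset_ds <- function(ds, idx) {
    new("LabelledDataset", features = ds@features[idx, , drop = FALSE],
        labels = ds@labels[idx], groups = ds@groups[idx])
}

#' Balanced 80:20 train/test split
#'
#' Positives are split \code{floor(trainFraction * P)} into training and the
#' rest into test; an equal number of negatives is then randomly sampled
#' into each side, so both sides are exactly class-balanced. With
#' \code{byGroup = TRUE}, whole groups (source chains) of positives are
#' assigned to one side, preventing residues of the same error from
#' straddling the split (residue-level splitting risks redundancy between
#' train and test); the 80:20 ratio then holds approximately.
#'
#' @param ds a \linkS4class{LabelledDataset} with at least as many negatives
#'   as positives.
#' @param trainFraction fraction of positives assigned to training.
#' @param seed integer seed.
#' @param byGroup logical; split positives by group rather than by residue.
#' @return list(train, test) of \linkS4class{LabelledDataset}s.
#' @export
makeBalancedSplit <- function(ds, trainFraction = 0.8, seed = 1L,
                              byGroup = FALSE) {
    set.seed(seed)
    pos <- which(ds@labels == 1L)
    neg <- which(ds@labels == 0L)
    P <- length(pos)
    if (length(neg) < P) stop("fewer negatives than positives; cannot balance")
    if (byGroup) {
        gs <- unique(ds@groups[pos])
        gs <- sample(gs)
        cum <- cumsum(vapply(gs, function(g)
            sum(ds@groups[pos] == g), numeric(1)))
        nTrainG <- max(1, which.min(abs(cum - trainFraction * P)))
        trainPos <- pos[ds@groups[pos] %in% gs[seq_len(nTrainG)]]
        testPos <- setdiff(pos, trainPos)
    } else {
        trainPos <- sort(sample(pos, floor(trainFraction * P)))
        testPos <- setdiff(pos, trainPos)
    }
    negPool <- sample(neg)
    trainNeg <- negPool[seq_along(trainPos)]
    testNeg <- negPool[length(trainPos) + seq_along(testPos)]
    list(train = .subset_ds(ds, sort(c(trainPos, trainNeg))),
         test = .subset_ds(ds, sort(c(testPos, testNeg))))
}

# Linear SVM weight vector in input space; oriented so that higher decision
# values mean the positive class.
.svm_linear_weights <- function(fit, X, y) {
    w <- as.numeric(t(fit$coefs) %*% fit$SV)
    b <- -fit$rho
    dv <- as.numeric(X %*% w) + b
    if (mean(dv[y == 1]) < mean(dv[y == 0])) { w <- -w; b <- -b }
    list(w = w, b = b)
}

.stratified_folds <- function(y, k) {
    fold <- integer(length(y))
    for (cls in unique(y)) {
        idx <- sample(which(y == cls))
        fold[idx] <- rep_len(seq_len(k), length(idx))
    }
    fold
}

#' Train the per-residue error classifier
#'
#' Standardises the features (fit on the training rows only), then runs a
#' seeded random search over the linear-SVM hyperparameters: regularisation
#' strength C log-uniform in 1e-3..1e2 and class weighting in {balanced,
#' none}, scored by 5-fold cross-validated mean accuracy. A linear SVM's
#' decision boundary saturates well below C = 100 on standardised features,
#' while SMO solve times grow roughly linearly in C, so the search caps C
#' there. The best configuration is refit on the full training set and its
#' decision values from the cross-validation folds are used to fit a Platt
#' sigmoid, so the classifier outputs calibrated error probabilities.
#'
#' @param train a balanced \linkS4class{LabelledDataset} with both classes.
#' @param nIter number of random-search iterations (>= 1).
#' @param seed integer seed.
#' @param cvFolds number of cross-validation folds.
#' @return A \linkS4class{TrainedClassifier}.
#' @export
trainErrorClassifier <- function(train, nIter = 200L, seed = 1L,
                                 cvFolds = 5L) {
    y <- train@labels
    if (length(unique(y)) < 2) stop("training set must contain both classes")
    if (nIter < 1) stop("nIter must be >= 1")
    set.seed(seed)
    ctr <- colMeans(train@features)
    scl <- apply(train@features, 2, sd)
    scl[scl == 0] <- 1
    X <- scale(train@features, center = ctr, scale = scl)
    fold <- .stratified_folds(y, cvFolds)
    cand <- data.frame(cost = 10^runif(nIter, -3, 2),
                       balanced = sample(c(TRUE, FALSE), nIter,
                                         replace = TRUE))
    yf <- factor(y, levels = c(0, 1))
    cw <- function(balanced) {
        if (!balanced) return(NULL)
        tb <- table(yf)
        setNames(as.numeric(sum(tb) / (2 * tb)), names(tb))
    }
    cvAccuracy <- function(cost, balanced, collectDV = FALSE) {
        dv <- numeric(length(y))
        acc <- numeric(cvFolds)
        for (f in seq_len(cvFolds)) {
            tr <- fold != f
            fit <- e1071::svm(X[tr, , drop = FALSE], yf[tr],
                              kernel = "linear", cost = cost,
                              class.weights = cw(balanced), scale = FALSE,
                              tolerance = 0.01)
            wb <- .svm_linear_weights(fit, X[tr, , drop = FALSE], y[tr])
            dvf <- as.numeric(X[!tr, , drop = FALSE] %*% wb$w) + wb$b
            acc[f] <- mean((dvf > 0) == (y[!tr] == 1))
            if (collectDV) dv[!tr] <- dvf
        }
        list(acc = mean(acc), dv = dv)
    }
    bestScore <- -Inf; best <- NULL
    for (k in seq_len(nIter)) {
        sc <- cvAccuracy(cand$cost[k], cand$balanced[k])$acc
        if (sc > bestScore + 1e-12) { bestScore <- sc; best <- cand[k, ] }
    }
    # calibration decision values from CV under the winning hyperparameters
    cv <- cvAccuracy(best$cost, best$balanced, collectDV = TRUE)
    # separable decision values saturate the sigmoid; glm's perfect-fit
    # warning is expected then and the calibrated scores remain valid
    cal <- suppressWarnings(glm(y ~ dv, data = data.frame(y = y, dv = cv$dv),
                                family = binomial()))
    fit <- e1071::svm(X, yf, kernel = "linear", cost = best$cost,
                      class.weights = cw(best$balanced), scale = FALSE)
    wb <- .svm_linear_weights(fit, X, y)
    # Platt convention p = 1 / (1 + exp(a * d + b))
    a <- -as.numeric(coef(cal)[2]); b <- -as.numeric(coef(cal)[1])
    new("TrainedClassifier", featureNames = colnames(train@features),
        center = as.numeric(ctr), scale = as.numeric(scl),
        weights = wb$w, bias = wb$b, calibration = c(a = a, b = b),
        metadata = list(seed = seed, cost = best$cost,
                        balanced = best$balanced, nIter = nIter,
                        cvFolds = cvFolds, searchScore = bestScore,
                        nSupport = fit$tot.nSV,
                        version = as.character(
                            utils::packageVersion("registercheck"))))
}

#' Score residues with a trained classifier
#'
#' @param clf a \linkS4class{TrainedClassifier}.
#' @param features numeric matrix whose columns match the classifier's
#'   feature names (order is fixed up automatically when names are present).
#' @return Numeric vector of calibrated error probabilities in [0, 1].
#' @export
scoreResidues <- function(clf, features) {
    features <- as.matrix(features)
    if (!is.null(colnames(features))) {
        if (!all(clf@featureNames %in% colnames(features)))
            stop("feature columns do not match the classifier")
        features <- features[, clf@featureNames, drop = FALSE]
    } else if (ncol(features) != length(clf@featureNames))
        stop("feature dimensionality does not match the classifier")
    Z <- scale(features, center = clf@center, scale = clf@scale)
    dv <- as.numeric(Z %*% clf@weights) + clf@bias
    1 / (1 + exp(clf@calibration[["a"]] * dv + clf@calibration[["b"]]))
}

#' Call maximal runs of high-scoring residues
#'
#' @param scores numeric vector of per-residue probabilities in [0, 1].
#' @param minRun minimum run length (default 6 consecutive residues).
#' @param threshold minimum score (default 0.9).
#' @return List of \linkS4class{ErrorCall}: maximal runs of consecutive
#'   residues with \code{score >= threshold} and length \code{>= minRun}.
#' @export
flagErrorRuns <- function(scores, minRun = 6L, threshold = 0.9) {
    stopifnot(all(scores >= 0 & scores <= 1))
    r <- rle(scores >= threshold)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    keep <- which(r$values & r$lengths >= minRun)
    lapply(keep, function(k)
        new("ErrorCall", start = as.integer(starts[k]),
            end = as.integer(ends[k]),
            meanScore = mean(scores[starts[k]:ends[k]]),
            nResidues = as.integer(r$lengths[k])))
}

#' Area under the ROC curve
#'
#' Rank-based (Mann-Whitney) AUC of scores against binary labels.
#'
#' @param scores numeric vector.
#' @param labels binary vector (1 = positive).
#' @return AUC in [0, 1].
#' @export
aucScore <- function(scores, labels) {
    pos <- scores[labels == 1]; neg <- scores[labels == 0]
    if (!length(pos) || !length(neg)) stop("need both classes")
    r <- rank(c(pos, neg))
    (sum(r[seq_along(pos)]) - length(pos) * (length(pos) + 1) / 2) /
        (length(pos) * length(neg))
}

#' ROC curve points
#'
#' @param scores,labels as in \code{\link{aucScore}}.
#' @return data.frame(threshold, TPR, FPR), one row per distinct score.
#' @export
rocPoints <- function(scores, labels) {
    th <- sort(unique(scores), decreasing = TRUE)
    P <- sum(labels == 1); N <- sum(labels == 0)
    data.frame(threshold = th,
               TPR = vapply(th, function(t)
                   sum(scores >= t & labels == 1) / P, numeric(1)),
               FPR = vapply(th, function(t)
                   sum(scores >= t & labels == 0) / N, numeric(1)))
}

#' Permutation feature importance
#'
#' Mean AUC drop over \code{nRep} seeded permutations of each feature
#' column, evaluated on the given data.
#'
#' @param clf a \linkS4class{TrainedClassifier}.
#' @param features numeric matrix.
#' @param labels binary labels.
#' @param nRep permutations per feature.
#' @param seed integer seed.
#' @return Named numeric vector of importances, sorted decreasing.
#' @export
permutationImportance <- function(clf, features, labels, nRep = 5L,
                                  seed = 1L) {
    set.seed(seed)
    base <- aucScore(scoreResidues(clf, features), labels)
    imp <- vapply(clf@featureNames, function(fn) {
        drops <- vapply(seq_len(nRep), function(r) {
            Xp <- features
            Xp[, fn] <- sample(Xp[, fn])
            base - aucScore(scoreResidues(clf, Xp), labels)
        }, numeric(1))
        mean(drops)
    }, numeric(1))
    sort(imp, decreasing = TRUE)
}

#' Serialize a trained classifier to JSON
#'
#' A single versioned, human-readable JSON file (no opaque binary formats).
#'
#' @param clf a \linkS4class{TrainedClassifier}.
#' @param path output path.
#' @export
writeClassifier <- function(clf, path) {
    jsonlite::write_json(list(format = "registercheck-classifier",
                              formatVersion = 1L,
                              featureNames = clf@featureNames,
                              center = clf@center, scale = clf@scale,
                              weights = clf@weights, bias = clf@bias,
                              calibration = as.list(clf@calibration),
                              metadata = clf@metadata),
                         path, auto_unbox = TRUE, digits = NA)
    invisible(path)
}

#' Read a trained classifier from JSON
#'
#' @param path path written by \code{\link{writeClassifier}}.
#' @return A \linkS4class{TrainedClassifier}.
#' @export
readClassifier <- function(path) {
    d <- jsonlite::fromJSON(path)
    if (!identical(d$format, "registercheck-classifier"))
        stop("not a registercheck classifier file")
    new("TrainedClassifier", featureNames = d$featureNames,
        center = as.numeric(d$center), scale = as.numeric(d$scale),
        weights = as.numeric(d$weights), bias = as.numeric(d$bias),
        calibration = c(a = d$calibration$a, b = d$calibration$b),
        metadata = as.list(d$metadata))
}
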