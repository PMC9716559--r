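## Per-residue validation metrics comparing observed and predicted
## inter-residue geometry. Each profile is returned as list(values, flags):
## degenerate values (empty universe, zero denominator/weight) are stored as
## 0 with the flag set, so downstream feature matrices stay finite.

.metric_base_names <- c("wRMSD", "Accuracy", "Precision", "Sensitivity",
                        "Specificity", "FPrate", "FNcount", "FPcount")

#' Names of the 24 validation metrics
#'
#' Eight base metrics, their five-point smoothed variants and their spatial
#' Z-score variants.
#'
#' @return Character vector of 24 column names.
#' @export
metricNames <- function() {
    c(.metric_base_names,
      paste0("smooth_", .metric_base_names),
      paste0("Z_", .metric_base_names))
}

# Pair universe U(i): |i - j| >= minSep and both residues modelled.
.pair_universe <- function(L, modelled, minSep) {
    sep <- abs(outer(seq_len(L), seq_len(L), "-")) >= minSep
    sep & outer(modelled, modelled, "&")
}

#' Per-residue weighted RMSD between observed and predicted distances
#'
#' For residue i, over all partners j with \code{|i - j| >= minSep} and both
#' residues modelled:
#' \code{wRMSD(i) = sqrt(sum_j w_ij (x_ij - xhat_ij)^2 / sum_j w_ij)},
#' where x is the observed distance, xhat the predicted distance and w the
#' prediction confidence. The normalisation by the summed confidence reduces
#' to a plain RMSD when all confidences are 1 and is invariant to rescaling
#' the confidences; dividing by the partner count instead is available via
#' \code{normalize = "n"}.
#'
#' @param obs a \linkS4class{DistanceMatrix}.
#' @param pred a \linkS4class{DistancePrediction} of matching size.
#' @param minSep minimum sequence separation.
#' @param normalize "weight" (divide by sum of w) or "n" (divide by count).
#' @return list(values, flags); residues with zero total weight get 0 with
#'   the flag set.
#' @export
wrmsdProfile <- function(obs, pred, minSep = 5L,
                         normalize = c("weight", "n")) {
    normalize <- match.arg(normalize)
    L <- nrow(obs@values)
    if (!identical(dim(obs@values), dim(pred@predDist)))
        stop("observed/predicted shape mismatch")
    modelled <- diag(obs@mask)
    U <- .pair_universe(L, modelled, minSep)
    if (length(pred@farBin) == length(U)) U <- U & !pred@farBin
    w <- pred@confidence * U
    d2 <- (obs@values - pred@predDist)^2
    d2[!U] <- 0
    num <- rowSums(w * d2)
    den <- if (normalize == "weight") rowSums(w) else rowSums(U)
    flags <- den <= 0
    vals <- ifelse(flags, 0, sqrt(num / ifelse(flags, 1, den)))
    list(values = vals, flags = flags)
}

#' Per-residue contact confusion counts
#'
#' For each residue i and every partner j in the universe
#' \code{|i - j| >= minSep} (both modelled): TP if the pair is a contact in
#' both maps, FP if predicted only, FN if observed only, TN otherwise.
#'
#' @param predCM predicted \linkS4class{ContactMap} (typically top-L/2).
#' @param obsCM observed \linkS4class{ContactMap}.
#' @param modelled logical vector of length L (default: all modelled).
#' @param minSep minimum sequence separation.
#' @return data.frame with columns TP, FP, TN, FN, universe; one row per
#'   residue. \code{TP + FP + TN + FN == universe} always holds.
#' @export
contactConfusionProfile <- function(predCM, obsCM, modelled = NULL,
                                    minSep = 5L) {
    if (predCM@L != obsCM@L) stop("contact maps have different L")
    L <- predCM@L
    if (is.null(modelled)) modelled <- rep(TRUE, L)
    U <- .pair_universe(L, modelled, minSep)
    P <- contactMatrix(predCM) > 0 & U
    O <- contactMatrix(obsCM) > 0 & U
    data.frame(TP = as.integer(rowSums(P & O)),
               FP = as.integer(rowSums(P & !O)),
               TN = as.integer(rowSums(!P & !O & U)),
               FN = as.integer(rowSums(!P & O)),
               universe = as.integer(rowSums(U)))
}

#' The seven contact-based metrics from confusion counts
#'
#' Accuracy, Precision, Sensitivity, Specificity and FP rate follow the
#' standard confusion-matrix definitions; the raw FN and FP counts are kept
#' as two additional features. Zero denominators yield 0 with the flag set.
#'
#' @param counts data.frame from \code{\link{contactConfusionProfile}}.
#' @return list(values = matrix with 7 named columns, flags = logical matrix).
#' @export
confusionMetrics <- function(counts) {
    safe <- function(num, den) {
        flag <- den <= 0
        list(v = ifelse(flag, 0, num / ifelse(flag, 1, den)), f = flag)
    }
    with(counts, {
        acc <- safe(TP + TN, TP + TN + FP + FN)
        pre <- safe(TP, TP + FP)
        sen <- safe(TP, TP + FN)
        spe <- safe(TN, TN + FP)
        fpr <- safe(FP, FP + TN)
        vals <- cbind(Accuracy = acc$v, Precision = pre$v,
                      Sensitivity = sen$v, Specificity = spe$v,
                      FPrate = fpr$v, FNcount = as.numeric(FN),
                      FPcount = as.numeric(FP))
        flg <- cbind(Accuracy = acc$f, Precision = pre$f,
                     Sensitivity = sen$f, Specificity = spe$f,
                     FPrate = fpr$f, FNcount = universe <= 0,
                     FPcount = universe <= 0)
        list(values = vals, flags = flg)
    })
}

#' Five-point moving-average smoothing with edge shrinkage
#'
#' Each position is replaced by the unweighted mean of the values in a
#' window of \code{window} positions centred on it, intersected with the
#' chain, so no data are lost at the edges (the window simply shrinks).
#' Flagged positions are excluded from every window mean; a window with no
#' usable values yields 0 with the flag set.
#'
#' @param values numeric vector.
#' @param window odd window size (default 5).
#' @param flags logical vector marking degenerate values to exclude.
#' @return list(values, flags).
#' @export
smoothProfile <- function(values, window = 5L, flags = NULL) {
    stopifnot(window %% 2 == 1)
    L <- length(values)
    if (is.null(flags)) flags <- rep(FALSE, L)
    h <- (window - 1L) %/% 2L
    out <- numeric(L)
    outf <- logical(L)
    for (i in seq_len(L)) {
        w <- max(1L, i - h):min(L, i + h)
        w <- w[!flags[w]]
        if (!length(w)) { out[i] <- 0; outf[i] <- TRUE }
        else out[i] <- mean(values[w])
    }
    list(values = out, flags = outf)
}

#' Spatial Z-score profile
#'
#' Standardises each residue's value against the values of all residues
#' whose representative atoms lie within \code{radius} of it (the residue
#' itself included), using the population standard deviation. A
#' zero-variance neighbourhood yields z = 0. Flagged or unmodelled residues
#' are excluded from every sample and get 0 with the flag set.
#'
#' @param values numeric vector of length L.
#' @param chain the \linkS4class{StructureChain} providing coordinates.
#' @param radius neighbourhood radius in Angstrom (default 10).
#' @param flags logical vector marking degenerate values.
#' @return list(values, flags).
#' @export
spatialZscoreProfile <- function(values, chain, radius = 10, flags = NULL) {
    L <- chain@L
    stopifnot(length(values) == L)
    if (is.null(flags)) flags <- rep(FALSE, L)
    modelled <- chain@residues$modelled
    usable <- modelled & !flags
    xyz <- repCoords(chain)
    out <- numeric(L)
    outf <- !usable
    midx <- which(modelled)
    if (length(midx)) {
        dm <- as.matrix(stats::dist(xyz[midx, , drop = FALSE]))
        for (k in seq_along(midx)) {
            i <- midx[k]
            if (!usable[i]) next
            nb <- midx[dm[k, ] <= radius]
            nb <- nb[usable[nb]]
            s <- values[nb]
            mu <- mean(s)
            sdev <- sqrt(mean((s - mu)^2))   # population SD
            out[i] <- if (sdev > 0) (values[i] - mu) / sdev else 0
        }
    }
    list(values = out, flags = outf)
}

#' Build the 24-column per-residue metric table
#'
#' Computes the eight base metrics (wRMSD plus the seven contact confusion
#' metrics over the top-L/2 predicted contacts), their five-point smoothed
#' variants and their spatial Z-score variants (Z-scores are taken over the
#' unsmoothed values).
#'
#' @param chain a \linkS4class{StructureChain}.
#' @param distogram the matching \linkS4class{Distogram}.
#' @param cutoff contact cutoff in Angstrom.
#' @param minSep minimum sequence separation.
#' @param fraction contact-list size as a fraction of L (default top-L/2).
#' @param window smoothing window.
#' @param radius spatial Z-score radius in Angstrom.
#' @param normalize wRMSD normalisation, see \code{\link{wrmsdProfile}}.
#' @return A \linkS4class{MetricTable}.
#' @export
buildMetricTable <- function(chain, distogram, cutoff = 8.0, minSep = 5L,
                             fraction = 0.5, window = 5L, radius = 10,
                             normalize = "weight") {
    L <- chain@L
    if (chainLength(distogram) != L)
        stop("chain/distogram length mismatch (", L, " vs ",
             chainLength(distogram), ")")
    obs <- observedDistanceMatrix(chain)
    obsCM <- observedContactMap(chain, cutoff = cutoff, minSep = minSep)
    pred <- distogramToDistance(distogram)
    P <- distogramContactProbabilities(distogram, cutoff = cutoff)
    predCM <- selectTopContacts(P, L = L, fraction = fraction,
                                minSep = minSep)
    modelled <- chain@residues$modelled

    wr <- wrmsdProfile(obs, pred, minSep = minSep, normalize = normalize)
    cc <- contactConfusionProfile(predCM, obsCM, modelled = modelled,
                                  minSep = minSep)
    cm <- confusionMetrics(cc)

    base_vals <- cbind(wRMSD = wr$values, cm$values)
    base_flgs <- cbind(wRMSD = wr$flags, cm$flags)
    base_flgs <- base_flgs | !modelled

    sm_vals <- matrix(0, L, 8); sm_flgs <- matrix(FALSE, L, 8)
    z_vals <- matrix(0, L, 8); z_flgs <- matrix(FALSE, L, 8)
    for (k in 1:8) {
        s <- smoothProfile(base_vals[, k], window = window,
                           flags = base_flgs[, k])
        sm_vals[, k] <- s$values; sm_flgs[, k] <- s$flags
        z <- spatialZscoreProfile(base_vals[, k], chain, radius = radius,
                                  flags = base_flgs[, k])
        z_vals[, k] <- z$values; z_flgs[, k] <- z$flags
    }
    metrics <- cbind(base_vals, sm_vals, z_vals)
    flags <- cbind(base_flgs, sm_flgs, z_flgs)
    colnames(metrics) <- colnames(flags) <- metricNames()
    rownames(metrics) <- rownames(flags) <- NULL
    new("MetricTable", metrics = metrics, flags = flags,
        modelled = modelled)
}

#' Write a metric table as TSV or JSON
#'
#' TSV: one row per residue with the 24 metric columns plus a
#' \code{modelled} mask column. JSON: an object with \code{metrics},
#' \code{flags} and \code{modelled}.
#'
#' @param mt a \linkS4class{MetricTable}.
#' @param path output path; format chosen by extension (.json for JSON).
#' @export
writeMetricTable <- function(mt, path) {
    if (tolower(tools::file_ext(path)) == "json") {
        jsonlite::write_json(list(metrics = as.data.frame(mt@metrics),
                                  flags = as.data.frame(mt@flags),
                                  modelled = mt@modelled),
                             path, digits = NA)
    } else {
        df <- data.frame(residue = seq_len(nrow(mt@metrics)), mt@metrics,
                         modelled = mt@modelled, check.names = FALSE)
        write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
    }
    invisible(path)
}
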