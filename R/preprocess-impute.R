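## Feature-wise K-nearest-neighbor imputation and its masking validation.

## Standardize columns on their observed values; returns list(z, mu, sd).
.colStandardize <- function(x) {
    mu <- colMeans(x, na.rm = TRUE)
    sd <- apply(x, 2, stats::sd, na.rm = TRUE)
    sd[!is.finite(sd) | sd == 0] <- 1
    z <- sweep(sweep(x, 2, mu), 2, sd, "/")
    list(z = z, mu = mu, sd = sd)
}

#' K-nearest-neighbor imputation (feature-wise)
#'
#' Fills each missing cell of a feature from the `k` features nearest to it
#' in Euclidean distance (root-mean-square difference on standardized,
#' co-observed values; at least 3 co-observed animals required for a
#' distance to be defined).  Neighbor values are standardized to the target
#' feature's observed mean and SD before averaging (unweighted), so
#' differing abundance scales across features do not leak into the imputed
#' values.  Suited to missing-at-random patterns.
#'
#' @param x animals x features numeric matrix with `NA` for missing cells.
#' @param k neighbor count (default 10).
#' @return Complete matrix of the same shape.  If `x` has no missing cells
#'   it is returned unchanged.
#' @export
knnImpute <- function(x, k = 10L) {
    stopifnot(is.matrix(x), k >= 1L)
    if (!anyNA(x)) return(x)
    std <- .colStandardize(x)
    z <- std$z
    out <- x
    targets <- which(colSums(is.na(x)) > 0L)
    for (j in targets) {
        d2 <- colMeans((z - z[, j])^2, na.rm = TRUE)
        co <- colSums(!is.na(z) & !is.na(z[, j]))
        d2[co < 3L] <- Inf
        d2[j] <- Inf
        miss <- which(is.na(x[, j]))
        for (i in miss) {
            cand <- which(!is.na(z[i, ]) & is.finite(d2))
            if (length(cand) < k)
                stop("knnNeighborPool: only ", length(cand),
                     " usable neighbors (< k = ", k, ") for feature ",
                     j, ", animal ", i)
            nb <- cand[order(d2[cand], cand)][seq_len(k)]
            out[i, j] <- std$mu[j] + std$sd[j] * mean(z[i, nb])
        }
    }
    out
}

#' Masking-based validation of KNN imputation
#'
#' Repeatedly holds out half of the observed cells of randomly selected
#' features - one feature at a time, the rest of the matrix untouched -
#' re-imputes with [knnImpute()], and records the Pearson correlation
#' between the held-out originals and the imputed values per feature.
#' Features whose mean correlation over repeats exceeds `threshold` are
#' retained.  Features never selected across repeats get `NA` mean accuracy
#' and are kept (no evidence against them).
#'
#' @param x complete or near-complete animals x features matrix.
#' @param nMaskedFeatures features masked per repeat (default 100; if the
#'   matrix has fewer features, all are masked, with a warning).
#' @param nRepeats repeats (default 100).
#' @param k neighbors for [knnImpute()].
#' @param threshold retention threshold on mean correlation (default 0.4).
#' @param holdoutFraction fraction of a selected feature's observed cells
#'   masked per repeat (default 0.5).
#' @param seed optional seed.
#' @return list: `meanCor` (named per-feature mean correlation, `NA` if
#'   never evaluated), `nEvaluated` (repeats per feature), `retained`
#'   (feature names kept).
#' @export
validateImputation <- function(x, nMaskedFeatures = 100L, nRepeats = 100L,
                               k = 10L, threshold = 0.4,
                               holdoutFraction = 0.5, seed = NULL) {
    stopifnot(is.matrix(x), nRepeats >= 1L)
    if (!is.null(seed)) set.seed(seed)
    q <- ncol(x)
    if (is.null(colnames(x))) colnames(x) <- paste0("f", seq_len(q))
    if (q < nMaskedFeatures) {
        warning("fewer features (", q, ") than nMaskedFeatures (",
                nMaskedFeatures, "); masking all features each repeat")
        nMaskedFeatures <- q
    }
    corSum <- setNames(rep(0, q), colnames(x))
    corN <- setNames(rep(0L, q), colnames(x))
    for (r in seq_len(nRepeats)) {
        sel <- sample.int(q, nMaskedFeatures)
        for (j in sel) {
            obs <- which(!is.na(x[, j]))
            h <- sample(obs, max(1L, floor(holdoutFraction * length(obs))))
            masked <- x
            masked[h, j] <- NA_real_
            imp <- knnImpute(masked, k = k)
            if (length(h) >= 3L && stats::sd(x[h, j]) > 0 &&
                stats::sd(imp[h, j]) > 0) {
                corSum[j] <- corSum[j] + stats::cor(x[h, j], imp[h, j])
                corN[j] <- corN[j] + 1L
            }
        }
    }
    meanCor <- ifelse(corN > 0, corSum / pmax(corN, 1L), NA_real_)
    names(meanCor) <- colnames(x)
    retained <- colnames(x)[is.na(meanCor) | meanCor > threshold]
    list(meanCor = meanCor, nEvaluated = corN, retained = retained)
}
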