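## Per-feature mixed-model residualization: for every molecular feature, fit
##   y = X b + Z_pen p + e,   p ~ N(0, I s2_p),  e ~ N(0, I s2_e)
## by REML, take the conditional residuals e-hat and divide by the feature's
## residual SD, yielding the residual-standardized matrix from which the
## layer kernel is computed.
##
## All features of a layer share X and Z_pen, so the pen cross-product is
## eigendecomposed once and each feature reduces to a 1-D profiled REML
## search over the ratio lambda = s2_p / s2_e.

#' Per-layer feature adjustment model
#'
#' Holds the fixed-effect terms and the random-pen flag used to residualize
#' one omics layer.  Layer defaults follow the standard blood-omics
#' adjustment sets: transcriptome - batch, enrichment-toy status, entry age,
#' RNA integrity number; proteome and metabolome - batch and entry age.
#' Pen (nested in batch) is always fitted as a random effect.
#'
#' @slot fixedTerms character vector of design-table column names.
#' @slot randomPen logical, fit pen as a random effect.
#' @slot layer layer tag.
#' @export
setClass("FeatureModelSpec",
    slots = c(fixedTerms = "character", randomPen = "logical",
              layer = "character"))

#' @rdname FeatureModelSpec-class
#' @param layer one of `"transcriptome"`, `"proteome"`, `"metabolome"` (other
#'   tags allowed; they default to batch + entry age).
#' @param fixedTerms override the layer default.
#' @param randomPen fit pen within batch as a random effect (default TRUE).
#' @export
featureModelSpec <- function(layer, fixedTerms = NULL, randomPen = TRUE) {
    if (is.null(fixedTerms))
        fixedTerms <- switch(layer,
            transcriptome = c("batch", "toyStatus", "entryAge", "rin"),
            c("batch", "entryAge"))
    new("FeatureModelSpec", fixedTerms = fixedTerms, randomPen = randomPen,
        layer = layer)
}

## Build a fixed-effect design matrix from design-table columns; character
## columns become factors.  Returns the matrix with intercept.
.fixedDesign <- function(design, terms, levelsFrom = NULL) {
    if (length(terms) == 0L)
        return(matrix(1, nrow(design), 1, dimnames = list(NULL, "(Intercept)")))
    df <- design[, terms, drop = FALSE]
    for (nm in terms) {
        if (is.character(df[[nm]]) || is.factor(df[[nm]])) {
            lev <- if (!is.null(levelsFrom)) {
                unique(as.character(levelsFrom[[nm]]))
            } else unique(as.character(df[[nm]]))
            df[[nm]] <- factor(df[[nm]], levels = lev)
        }
    }
    stats::model.matrix(stats::reformulate(terms), data = df)
}

## Profiled restricted log-likelihood at ratio lambda, in the basis where
## Z_pen Z_pen' = U diag(d) U'.  Returns -ll (for minimization) or fit pieces.
.profileREML <- function(lambda, d, Xt, yt, pieces = FALSE) {
    w <- 1 / (1 + lambda * d)
    XtW <- Xt * w
    XtWX <- crossprod(Xt, XtW)
    ch <- tryCatch(chol(XtWX), error = function(e) NULL)
    if (is.null(ch)) return(if (pieces) NULL else Inf)
    b <- backsolve(ch, forwardsolve(t(ch), crossprod(XtW, yt)))
    r <- yt - Xt %*% b
    np <- length(yt) - ncol(Xt)
    rss <- sum(w * r^2)
    if (rss <= 0) return(if (pieces) NULL else Inf)
    s2e <- rss / np
    nll <- 0.5 * (sum(log(1 + lambda * d)) + 2 * sum(log(diag(ch))) +
                  np * log(s2e))
    if (!pieces) return(nll)
    list(nll = nll, b = b, r = r, w = w, s2e = s2e, lambda = lambda)
}

#' Residualize omics features and assemble the standardized matrix
#'
#' Fits, per feature, a one-random-effect (pen within batch) linear mixed
#' model by profiled REML over the variance ratio `s2_pen / s2_e` (bounded
#' search on \[0, 1e6\]), computes conditional residuals, divides each
#' feature by its residual standard deviation, and assembles the
#' animals x features matrix with column mean 0 and unit variance.
#' Features with (numerically) zero residual variance are flagged degenerate
#' and dropped; features whose ratio search fails fall back to
#' fixed-effects-only (OLS) residuals and are flagged.
#'
#' @param x animals x features complete numeric matrix (log scale).
#' @param spec a [FeatureModelSpec-class].
#' @param design cohort design table covering all rows of `x` (matched by
#'   row name against `design$animal` when both are present).
#' @return An [OmicsMatrix-class]; `provenance` records per-feature ratio
#'   estimates, OLS fallbacks, and dropped features.
#' @export
residualizeFeatures <- function(x, spec, design) {
    stopifnot(is.matrix(x), is(spec, "FeatureModelSpec"))
    if (anyNA(x)) stop("feature matrix must be complete before residualization")
    if (!is.null(rownames(x)) && "animal" %in% names(design)) {
        if (!all(rownames(x) %in% design$animal))
            stop("design does not cover all animals in the feature matrix")
        design <- design[match(rownames(x), design$animal), , drop = FALSE]
    } else if (nrow(design) != nrow(x)) {
        stop("design rows do not match the feature matrix")
    }

    X <- .fixedDesign(design, spec@fixedTerms)
    qrX <- qr(X)
    if (qrX$rank < ncol(X))
        X <- X[, qrX$pivot[seq_len(qrX$rank)], drop = FALSE]
    n <- nrow(X); p <- ncol(X)
    if (n - p < 2L) stop("not enough residual degrees of freedom")

    if (spec@randomPen) {
        Zp <- stats::model.matrix(~ 0 + factor(design$pen))
        eg <- eigen(tcrossprod(Zp), symmetric = TRUE)
        U <- eg$vectors
        d <- pmax(eg$values, 0)
    } else {
        U <- diag(n)
        d <- rep(0, n)
    }
    Xt <- crossprod(U, X)
    Yt <- crossprod(U, x)

    vals <- matrix(NA_real_, n, ncol(x), dimnames = dimnames(x))
    lambdaHat <- setNames(rep(NA_real_, ncol(x)), colnames(x))
    olsFallback <- setNames(rep(FALSE, ncol(x)), colnames(x))
    degenerate <- setNames(rep(FALSE, ncol(x)), colnames(x))

    for (j in seq_len(ncol(x))) {
        yt <- Yt[, j]
        fit0 <- .profileREML(0, d, Xt, yt, pieces = TRUE)
        fit <- fit0
        if (spec@randomPen && !is.null(fit0)) {
            opt <- tryCatch(
                stats::optimize(function(lg) .profileREML(exp(lg), d, Xt, yt),
                                interval = c(log(1e-6), log(1e6))),
                error = function(e) NULL)
            if (is.null(opt) || !is.finite(opt$objective)) {
                olsFallback[j] <- TRUE        # ratio search failed: OLS residuals
            } else if (opt$objective < fit0$nll - 1e-10) {
                mixed <- .profileREML(exp(opt$minimum), d, Xt, yt,
                                      pieces = TRUE)
                if (is.null(mixed)) olsFallback[j] <- TRUE else fit <- mixed
            }
        }
        if (is.null(fit)) {          # degenerate even at lambda = 0
            degenerate[j] <- TRUE
            next
        }
        lambdaHat[j] <- fit$lambda
        ehat <- as.vector(U %*% (fit$w * fit$r))
        s <- stats::sd(ehat)
        sy <- stats::sd(x[, j])
        if (!is.finite(s) || s < 1e-8 * max(sy, 1e-300)) {
            degenerate[j] <- TRUE
            next
        }
        vals[, j] <- ehat / s
    }

    keep <- !degenerate
    OmicsMatrix(vals[, keep, drop = FALSE], layer = spec@layer,
                provenance = list(
                    fixedTerms = spec@fixedTerms,
                    lambda = lambdaHat[keep],
                    olsFallback = olsFallback[keep],
                    dropped = colnames(x)[degenerate],
                    droppedReason = if (any(degenerate))
                        setNames(rep("degenerate: zero residual variance",
                                     sum(degenerate)),
                                 colnames(x)[degenerate]) else character()))
}
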