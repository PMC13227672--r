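## Count normalization and metabolite filtering.

#' TMM-normalized log2 counts per million
#'
#' Computes trimmed-mean-of-M-values scaling factors (via edgeR, with the
#' canonical trims: log-ratio trim 0.30, absolute-intensity trim 0.05,
#' reference sample chosen by the upper-quartile rule), converts counts to
#' counts per million on the effective library sizes, and returns
#' `log2(CPM + 1)`.
#'
#' @param counts animals x genes matrix of non-negative integers.
#' @return animals x genes matrix of log2(CPM + 1); attribute `normFactors`
#'   holds the per-animal TMM factors.
#' @export
normalizeCounts <- function(counts) {
    stopifnot(is.matrix(counts))
    if (nrow(counts) < 2L)
        stop("normalizeCounts requires at least 2 animals")
    if (any(counts < 0))
        stop("counts must be non-negative")
    lib <- rowSums(counts)
    if (any(lib == 0))
        stop("zeroLibrarySize: animal(s) with zero library size: ",
             paste(rownames(counts)[lib == 0], collapse = ", "))
    if (ncol(counts) >= 2L) {
        f <- edgeR::calcNormFactors(t(counts), method = "TMM")
    } else {
        ## a single gene carries no relative information; factors collapse to 1
        f <- rep(1, nrow(counts))
    }
    eff <- lib * f
    out <- log2(counts / eff * 1e6 + 1)
    dimnames(out) <- dimnames(counts)
    attr(out, "normFactors") <- setNames(f, rownames(counts))
    out
}

#' Filter and impute a metabolite matrix
#'
#' Drops metabolites that are below the limit of detection in more than 20%
#' of samples, or missing in 20% or more of samples (note the different
#' comparators: sub-LOD is strict `>`, generic missingness is `>=`; the two
#' rules are evaluated independently).  Remaining missing cells (of either
#' kind) are replaced by the metabolite-specific median of observed values,
#' and the matrix is log2-transformed.
#'
#' @param x animals x metabolites matrix of positive concentrations with
#'   `NA` for unobserved cells.
#' @param subLOD logical matrix of the same shape flagging which `NA` cells
#'   are below the detection limit (default: the `"subLOD"` attribute of
#'   `x`; if absent, all `NA`s count as generic missingness).
#' @param lodRate,missRate the two thresholds (defaults 0.20).
#' @param log2Transform apply log2 after imputation (default `TRUE`).  The
#'   filter + imputation stage is idempotent; the log transform, applied
#'   once at the end of preprocessing, is not.
#' @return Filtered (and by default log2-transformed) matrix; attribute
#'   `dropped` is a named character vector of dropped features and reasons.
#' @export
filterMetabolites <- function(x, subLOD = attr(x, "subLOD"),
                              lodRate = 0.20, missRate = 0.20,
                              log2Transform = TRUE) {
    stopifnot(is.matrix(x))
    if (is.null(subLOD))
        subLOD <- matrix(FALSE, nrow(x), ncol(x), dimnames = dimnames(x))
    stopifnot(identical(dim(subLOD), dim(x)))
    isMissing <- is.na(x) & !subLOD
    isSub <- is.na(x) & subLOD

    fracMiss <- colMeans(isMissing)
    fracSub <- colMeans(isSub)
    dropReason <- character(0)
    drop <- rep(FALSE, ncol(x))
    for (j in seq_len(ncol(x))) {
        nm <- colnames(x)[j]
        if (is.null(nm)) nm <- as.character(j)
        if (fracMiss[j] + fracSub[j] >= 1) {
            drop[j] <- TRUE
            dropReason[nm] <- "entirely missing"
        } else if (fracSub[j] > lodRate) {
            drop[j] <- TRUE
            dropReason[nm] <- sprintf("sub-LOD in %.0f%% of samples (> %.0f%%)",
                                      100 * fracSub[j], 100 * lodRate)
        } else if (fracMiss[j] >= missRate) {
            drop[j] <- TRUE
            dropReason[nm] <- sprintf("missing in %.0f%% of samples (>= %.0f%%)",
                                      100 * fracMiss[j], 100 * missRate)
        }
    }
    out <- x[, !drop, drop = FALSE]
    for (j in seq_len(ncol(out))) {
        na <- is.na(out[, j])
        if (any(na))
            out[na, j] <- stats::median(out[!na, j])
    }
    if (log2Transform) out <- log2(out)
    attr(out, "dropped") <- dropReason
    out
}

#' Genotype quality control
#'
#' Applies, in one pass and in this order: SNP call rate > `snpCallRate`,
#' individual call rate > `indCallRate`, then minor allele frequency >
#' `maf`.  Both call-rate criteria are evaluated on the input matrix (no
#' recursive re-filtering); the MAF is computed on the surviving animals.
#' All comparators are strict, matching the stated rules (a SNP at MAF
#' exactly 0.05 is removed).  Remaining missing dosages are mean-imputed per
#' SNP (2 x allele frequency).
#'
#' @param dosages animals x SNPs matrix with entries in \{0, 1, 2, NA\}.
#' @param maf,snpCallRate,indCallRate thresholds.
#' @return list with `dosages` (filtered, complete), `removedSnps`,
#'   `removedAnimals`.
#' @export
qcGenotypes <- function(dosages, maf = 0.05, snpCallRate = 0.90,
                        indCallRate = 0.90) {
    stopifnot(is.matrix(dosages))
    rng <- range(dosages, na.rm = TRUE)
    ## fractional values are allowed so that mean-imputed output re-passes QC
    if (rng[1] < 0 || rng[2] > 2)
        stop("dosages must lie in [0, 2] (or NA)")

    snpRate <- colMeans(!is.na(dosages))
    keepSnp <- snpRate > snpCallRate
    indRate <- rowMeans(!is.na(dosages))
    keepInd <- indRate > indCallRate
    x <- dosages[keepInd, keepSnp, drop = FALSE]

    p <- colMeans(x, na.rm = TRUE) / 2
    mafObs <- pmin(p, 1 - p)
    keepMaf <- mafObs > maf
    x <- x[, keepMaf, drop = FALSE]
    p <- p[keepMaf]

    if (ncol(x) == 0L)
        stop("allSnpsRemoved: no SNP passed quality control")

    for (j in seq_len(ncol(x))) {
        na <- is.na(x[, j])
        if (any(na)) x[na, j] <- 2 * p[j]
    }
    removedSnps <- c(colnames(dosages)[!keepSnp],
                     colnames(dosages)[keepSnp][!keepMaf])
    list(dosages = x,
         removedSnps = removedSnps,
         removedAnimals = rownames(dosages)[!keepInd])
}
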