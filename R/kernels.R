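## Relationship-kernel construction: block-diagonal within-company genomic G
## (VanRaden method 1), per-layer omics kernels K = M M' / p, equal-weight
## combined kernels, and diagonal stabilization.

#' Block-diagonal within-company genomic relationship matrix
#'
#' Computes a VanRaden method-1 genomic relationship matrix separately for
#' the animals of each source company, using within-company allele
#' frequencies, and assembles the blocks on the diagonal; every
#' cross-company entry is exactly zero, restricting relationships to
#' within-company comparisons.  SNPs monomorphic within a company are
#' excluded from that company's centering and denominator.
#'
#' @param dosages animals x SNPs matrix in \{0, 1, 2\}, complete (run
#'   [qcGenotypes()] first).
#' @param companies character vector of company labels, one per animal.
#' @return A [RelationshipKernel-class] with layer `"G"`, in the input
#'   animal order.
#' @export
buildGenomicKernel <- function(dosages, companies) {
    stopifnot(is.matrix(dosages), length(companies) == nrow(dosages))
    if (anyNA(dosages)) stop("dosages must be complete")
    n <- nrow(dosages)
    ids <- rownames(dosages)
    if (is.null(ids)) ids <- sprintf("A%04d", seq_len(n))
    K <- matrix(0, n, n, dimnames = list(ids, ids))
    for (co in unique(companies)) {
        idx <- which(companies == co)
        if (length(idx) == 1L)
            warning("company '", co, "' has a single animal; 1x1 block")
        W <- dosages[idx, , drop = FALSE]
        p <- colMeans(W) / 2
        poly <- p > 0 & p < 1
        if (!any(poly))
            stop("company '", co, "' has no polymorphic SNPs")
        Wc <- sweep(W[, poly, drop = FALSE], 2, 2 * p[poly])
        denom <- 2 * sum(p[poly] * (1 - p[poly]))
        K[idx, idx] <- tcrossprod(Wc) / denom
    }
    RelationshipKernel(K, layer = "G")
}

#' Omics similarity kernel K = M M' / p
#'
#' @param M an [OmicsMatrix-class] (residual-standardized, complete) or a
#'   plain animals x features matrix.
#' @param layer kernel tag; defaults to the uppercase initial of the layer
#'   of `M` when `M` is an [OmicsMatrix-class].
#' @return A [RelationshipKernel-class].
#' @export
buildOmicsKernel <- function(M, layer = NULL) {
    if (is(M, "OmicsMatrix")) {
        if (is.null(layer)) layer <- toupper(substr(layerName(M), 1, 1))
        M <- as.matrix(M)
    }
    stopifnot(is.matrix(M))
    if (is.null(layer)) layer <- "K"
    p <- ncol(M)
    if (p == 0L) stop("cannot build a kernel from zero features")
    if (anyNA(M)) stop("feature matrix must be complete")
    RelationshipKernel(tcrossprod(M) / p, layer = layer)
}

#' Equal-weight mean of relationship kernels
#'
#' `C = (1/n_K) sum_k K_k`, elementwise, over kernels sharing the same
#' animal order.  No cross-layer rescaling is applied before averaging: the
#' layers are taken as comparable because their kernels are built from
#' residual-standardized features.
#'
#' @param kernels list of [RelationshipKernel-class] objects (>= 1) with
#'   identical animal order; an order mismatch is an error, never silently
#'   realigned.
#' @param label optional label; default concatenates the layer tags plus
#'   `"(mean)"`.
#' @return A [RelationshipKernel-class].
#' @export
combineKernels <- function(kernels, label = NULL) {
    stopifnot(is.list(kernels), length(kernels) >= 1L)
    ids <- animalIds(kernels[[1]])
    for (k in kernels) {
        stopifnot(is(k, "RelationshipKernel"))
        if (!identical(animalIds(k), ids))
            stop("animalOrderMismatch: kernels must share an identical animal order")
    }
    if (length(kernels) == 1L) return(kernels[[1]])
    V <- Reduce(`+`, lapply(kernels, as.matrix)) / length(kernels)
    if (is.null(label))
        label <- paste0(paste(vapply(kernels, layerName, ""), collapse = ""),
                        "(mean)")
    RelationshipKernel(V, layer = label)
}

#' Stabilize a kernel for mixed-model solving
#'
#' If the minimum eigenvalue is below `epsilon`, adds `epsilon - min(eig)`
#' to the diagonal and records it in `ridgeApplied`; otherwise the kernel is
#' returned unchanged.
#'
#' @param K a [RelationshipKernel-class] or symmetric matrix.
#' @param epsilon target minimum eigenvalue (default 1e-8, the smallest
#'   value that reliably permits Cholesky factorization at n around 1000 in
#'   double precision).
#' @return A [RelationshipKernel-class].
#' @export
stabilizeKernel <- function(K, epsilon = 1e-8) {
    if (!is(K, "RelationshipKernel")) {
        stopifnot(is.matrix(K))
        if (max(abs(K - t(K))) > 1e-8 * max(1, max(abs(K))))
            stop("asymmetric input")
        K <- RelationshipKernel(K, layer = "K")
    }
    v <- as.matrix(K)
    minEig <- min(eigen(v, symmetric = TRUE, only.values = TRUE)$values)
    if (minEig >= epsilon) return(K)
    ridge <- epsilon - minEig
    RelationshipKernel(v + diag(ridge, nrow(v)), layer = layerName(K),
                       ridgeApplied = ridgeApplied(K) + ridge)
}
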