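## Variance-share summaries and the model grid.

#' Variance-proportion summary of a converged fit
#'
#' The share of phenotypic variance attributed to each kernel effect is its
#' component divided by the total `s2_pen + s2_litter + sum_k s2_k + s2_e`;
#' the total omics share is the analogous sum over all kernel components.
#'
#' @param fit a converged [VarCompFit-class].
#' @return A [VarianceReport-class].
#' @export
varianceReport <- function(fit) {
    stopifnot(is(fit, "VarCompFit"))
    if (!isConverged(fit))
        stop("varianceReport requires a converged fit")
    s2 <- sigma2(fit)
    tot <- sum(s2)
    if (tot <= 0)
        stop("allComponentsZero: variance shares are undefined")
    kn <- setdiff(names(s2), c("pen", "litter", "residual"))
    per <- s2[kn] / tot
    new("VarianceReport",
        perKernelShare = per,
        totalOmicsShare = sum(per),
        penShare = if ("pen" %in% names(s2)) unname(s2["pen"]) / tot else 0,
        litterShare = if ("litter" %in% names(s2))
            unname(s2["litter"]) / tot else 0,
        residualShare = unname(s2["residual"]) / tot)
}

#' Enumerate all model specifications over the available kernel layers
#'
#' All nonempty subsets of the layers, fitted with one random animal effect
#' per kernel, plus - when `combinedVariants` - one additional spec per
#' subset of size >= 2 using the equal-weight mean kernel as a single
#' effect.  With the four layers G, T, P, M this yields 15 + 11 = 26
#' specifications, in a deterministic order (subsets by size, then in the
#' given layer order; combined variants appended in the same order).
#'
#' @param layers available kernel tags (1 to 4 of `"G","T","P","M"` or
#'   custom tags).
#' @param combinedVariants include combined-mean variants (default TRUE).
#' @param trait,fixedTerms,includePen,includeLitter passed to every
#'   [ModelSpec()].
#' @return list of [ModelSpec-class], named by [modelLabel()].
#' @export
enumerateModelSpecs <- function(layers = c("G", "T", "P", "M"),
                                combinedVariants = TRUE, trait = "trait",
                                fixedTerms = character(), includePen = TRUE,
                                includeLitter = TRUE) {
    if (length(layers) == 0L) stop("layer set must be nonempty")
    if (anyDuplicated(layers)) stop("layers must be unique")
    subsets <- list()
    for (sz in seq_along(layers))
        subsets <- c(subsets,
                     utils::combn(layers, sz, simplify = FALSE))
    specs <- lapply(subsets, function(s)
        ModelSpec(trait = trait, kernelSet = s, fixedTerms = fixedTerms,
                  combined = FALSE, includePen = includePen,
                  includeLitter = includeLitter))
    if (combinedVariants) {
        multi <- Filter(function(s) length(s) >= 2L, subsets)
        specs <- c(specs, lapply(multi, function(s)
            ModelSpec(trait = trait, kernelSet = s, fixedTerms = fixedTerms,
                      combined = TRUE, includePen = includePen,
                      includeLitter = includeLitter)))
    }
    names(specs) <- vapply(specs, modelLabel, "")
    specs
}
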