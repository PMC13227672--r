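## Accessors, coercions and show methods.

#' @rdname accessors
#' @export
setMethod("animalIds", "RelationshipKernel", function(x, ...)
    rownames(x@values))

#' @rdname accessors
#' @export
setMethod("animalIds", "OmicsMatrix", function(x, ...) rownames(x@values))

#' @rdname accessors
#' @export
setMethod("featureIds", "OmicsMatrix", function(x, ...) colnames(x@values))

#' @rdname accessors
#' @export
setMethod("layerName", "RelationshipKernel", function(x, ...) x@layer)

#' @rdname accessors
#' @export
setMethod("layerName", "OmicsMatrix", function(x, ...) x@layer)

#' @rdname accessors
#' @export
setMethod("ridgeApplied", "RelationshipKernel", function(x, ...)
    x@ridgeApplied)

#' @rdname accessors
#' @export
setMethod("sigma2", "VarCompFit", function(x, ...) x@sigma2)

#' @rdname accessors
#' @export
setMethod("blupEffects", "VarCompFit", function(x, ...) x@blup)

#' @rdname accessors
#' @export
setMethod("isConverged", "VarCompFit", function(x, ...) x@converged)

#' @rdname accessors
#' @export
setMethod("weightedAccuracy", "CVResult", function(x, ...)
    x@weightedAccuracy)

#' @rdname accessors
#' @export
setMethod("pooledAUCValue", "CVResult", function(x, ...) x@pooledAUC)

#' @rdname accessors
#' @export
setMethod("perFold", "CVResult", function(x, ...) x@perFold)

#' Model label such as "GTM" or "GTM(mean)"
#' @rdname accessors
#' @export
setMethod("modelLabel", "ModelSpec", function(x, ...) {
    lab <- paste(x@kernelSet, collapse = "")
    if (isTRUE(x@combined)) lab <- paste0(lab, "(mean)")
    lab
})

#' @export
#' @method as.matrix RelationshipKernel
as.matrix.RelationshipKernel <- function(x, ...) x@values

#' @export
#' @method as.matrix OmicsMatrix
as.matrix.OmicsMatrix <- function(x, ...) x@values

setMethod("show", "RelationshipKernel", function(object) {
    v <- object@values
    cat(sprintf("RelationshipKernel '%s': %d animals\n", object@layer,
                nrow(v)))
    cat(sprintf("  mean diagonal %.4f; ridge applied %.3g\n",
                mean(diag(v)), object@ridgeApplied))
})

setMethod("show", "OmicsMatrix", function(object) {
    v <- object@values
    cat(sprintf("OmicsMatrix '%s': %d animals x %d features\n",
                object@layer, nrow(v), ncol(v)))
    dropped <- object@provenance$dropped
    if (length(dropped))
        cat(sprintf("  %d features dropped during preprocessing\n",
                    length(dropped)))
})

setMethod("show", "ModelSpec", function(object) {
    cat(sprintf("ModelSpec: trait '%s', model %s\n", object@trait,
                modelLabel(object)))
})

setMethod("show", "VarCompFit", function(object) {
    lab <- if (is(object@spec, "ModelSpec")) modelLabel(object@spec) else ""
    cat(sprintf("VarCompFit %s(n = %d): %s after %d iterations\n",
                if (nzchar(lab)) paste0("[", lab, "] ") else "", object@n,
                if (object@converged) "converged" else "NOT converged",
                object@nIterations))
    print(round(object@sigma2, 6))
    cat(sprintf("  restricted logLik: %.6f\n", object@loglik))
})

setMethod("show", "VarianceReport", function(object) {
    cat("VarianceReport\n")
    for (nm in names(object@perKernelShare))
        cat(sprintf("  %-8s %.4f\n", nm, object@perKernelShare[nm]))
    cat(sprintf("  total omics share %.4f | pen %.4f | litter %.4f | residual %.4f\n",
                object@totalOmicsShare, object@penShare, object@litterShare,
                object@residualShare))
})

setMethod("show", "FoldPlan", function(object) {
    cat(sprintf("FoldPlan: company %s, validation batch %s (%d train / %d validation)\n",
                object@company, object@validationBatch,
                length(object@trainingAnimals),
                length(object@validationAnimals)))
})

setMethod("show", "CVResult", function(object) {
    cat(sprintf("CVResult: trait '%s', model %s\n", object@trait,
                object@model))
    cat(sprintf("  %d/%d folds converged; weighted accuracy %.4f",
                object@nFoldsConverged, nrow(object@perFold),
                object@weightedAccuracy))
    if (!is.na(object@pooledAUC))
        cat(sprintf("; pooled AUC %.4f", object@pooledAUC))
    cat("\n")
})

setMethod("show", "SimulationConfig", function(object) {
    cat(sprintf("SimulationConfig: %d companies, %d batches, %d animals, %d SNPs\n",
                object@nCompanies, sum(object@batchesPerCompany),
                sum(object@batchesPerCompany) * object@animalsPerBatch,
                object@nSnps))
    cat(sprintf("  layers: %s\n",
                paste(sprintf("%s (%d)", names(object@nFeatures),
                              as.integer(object@nFeatures)), collapse = ", ")))
    cat(sprintf("  traits: %s | seed %d\n",
                paste(names(object@trueVarcomps), collapse = ", "),
                object@seed))
})

setMethod("show", "SyntheticCohort", function(object) {
    cat(sprintf("SyntheticCohort: %d animals, %d SNPs, layers: %s\n",
                nrow(object@design), ncol(object@genotypes),
                paste(names(object@rawLayers), collapse = ", ")))
    cat(sprintf("  traits: %s\n",
                paste(colnames(object@phenotypes), collapse = ", ")))
})
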