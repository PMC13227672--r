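#' @import methods
NULL

## ---------------------------------------------------------------------------
## RelationshipKernel
## ---------------------------------------------------------------------------

#' Relationship kernel among animals
#'
#' An n x n symmetric similarity matrix on the relationship scale, tagged with
#' the omics layer it was built from (`"G"`, `"T"`, `"P"`, `"M"`, or a
#' combination label such as `"GTM(mean)"`).  `ridgeApplied` records any value
#' added to the diagonal for numerical stabilization (0 if none).
#'
#' @slot values n x n numeric matrix with identical row/column animal IDs.
#' @slot layer single character tag.
#' @slot ridgeApplied non-negative scalar added to the diagonal.
#'
#' @seealso [buildGenomicKernel()], [buildOmicsKernel()], [combineKernels()],
#'   [stabilizeKernel()]
#' @export
setClass("RelationshipKernel",
    slots = c(values = "matrix", layer = "character",
              ridgeApplied = "numeric"))

setValidity("RelationshipKernel", function(object) {
    v <- object@values
    msg <- character()
    if (nrow(v) != ncol(v))
        msg <- c(msg, "kernel matrix must be square")
    if (is.null(rownames(v)) || is.null(colnames(v)) ||
        !identical(rownames(v), colnames(v)))
        msg <- c(msg, "row and column animal IDs must be present and identical")
    if (nrow(v) > 0L && max(abs(v - t(v))) > 0)
        msg <- c(msg, "kernel must be exactly symmetric")
    if (nrow(v) > 0L && any(diag(v) <= 0))
        msg <- c(msg, "diagonal entries must be > 0")
    if (length(object@layer) != 1L)
        msg <- c(msg, "layer must be a single string")
    if (length(object@ridgeApplied) != 1L || object@ridgeApplied < 0)
        msg <- c(msg, "ridgeApplied must be a single non-negative number")
    if (length(msg)) msg else TRUE
})

#' Construct a RelationshipKernel
#'
#' Symmetrizes `values` exactly (average with its transpose) before
#' validation, so kernels assembled by floating-point matrix products are
#' accepted.
#'
#' @param values square numeric matrix with animal IDs as dimnames.
#' @param layer layer tag.
#' @param ridgeApplied diagonal ridge already applied (default 0).
#' @return A [RelationshipKernel-class] object.
#' @export
RelationshipKernel <- function(values, layer, ridgeApplied = 0) {
    stopifnot(is.matrix(values), is.numeric(values))
    values <- (values + t(values)) / 2
    new("RelationshipKernel", values = values, layer = as.character(layer),
        ridgeApplied = as.numeric(ridgeApplied))
}

## ---------------------------------------------------------------------------
## OmicsMatrix
## ---------------------------------------------------------------------------

#' Residual-standardized omics feature matrix
#'
#' Animals x features matrix M of mixed-model residuals divided by the
#' feature-specific residual standard deviation, so that each column has mean
#' zero and unit variance across the animals used in fitting.  This is the
#' matrix from which per-layer similarity kernels K = M M' / p are computed.
#'
#' @slot values animals x features numeric matrix, no missing entries.
#' @slot layer layer tag, e.g. `"transcriptome"`.
#' @slot provenance list recording filters applied, features dropped and why,
#'   and per-feature convergence flags from the residualization fits.
#' @export
setClass("OmicsMatrix",
    slots = c(values = "matrix", layer = "character", provenance = "list"))

setValidity("OmicsMatrix", function(object) {
    v <- object@values
    msg <- character()
    if (anyNA(v))
        msg <- c(msg, "OmicsMatrix must not contain missing values")
    if (is.null(rownames(v)) || is.null(colnames(v)))
        msg <- c(msg, "animal and feature IDs must be present as dimnames")
    if (length(object@layer) != 1L)
        msg <- c(msg, "layer must be a single string")
    if (length(msg)) msg else TRUE
})

#' @rdname OmicsMatrix-class
#' @param values,layer,provenance see slots.
#' @export
OmicsMatrix <- function(values, layer, provenance = list()) {
    new("OmicsMatrix", values = values, layer = as.character(layer),
        provenance = provenance)
}

## ---------------------------------------------------------------------------
## ModelSpec
## ---------------------------------------------------------------------------

#' Specification of one trait/model combination
#'
#' Which kernels enter the mixed model for a trait, whether they are fitted
#' as separate random animal effects or collapsed into a single effect with
#' the equal-weight mean kernel, and whether pen and litter effects are
#' included.
#'
#' @slot trait trait name.
#' @slot fixedTerms character vector of fixed-effect column names in the
#'   cohort design table.
#' @slot kernelSet ordered subset of kernel tags, e.g. `c("G","T")`.
#' @slot combined if `TRUE`, one random effect with the mean kernel.
#' @slot includePen,includeLitter random pen / litter effects.
#' @export
setClass("ModelSpec",
    slots = c(trait = "character", fixedTerms = "character",
              kernelSet = "character", combined = "logical",
              includePen = "logical", includeLitter = "logical"))

setValidity("ModelSpec", function(object) {
    msg <- character()
    if (length(object@kernelSet) < 1L)
        msg <- c(msg, "kernelSet must be nonempty")
    if (anyDuplicated(object@kernelSet))
        msg <- c(msg, "kernelSet must not contain duplicates")
    if (isTRUE(object@combined) && length(object@kernelSet) < 2L)
        msg <- c(msg, "combined = TRUE requires at least 2 kernels")
    if (length(msg)) msg else TRUE
})

#' @rdname ModelSpec-class
#' @param trait,fixedTerms,kernelSet,combined,includePen,includeLitter see
#'   slots.
#' @export
ModelSpec <- function(trait, kernelSet, fixedTerms = character(),
                      combined = FALSE, includePen = TRUE,
                      includeLitter = TRUE) {
    new("ModelSpec", trait = trait, fixedTerms = fixedTerms,
        kernelSet = kernelSet, combined = combined,
        includePen = includePen, includeLitter = includeLitter)
}

## ---------------------------------------------------------------------------
## VarCompFit
## ---------------------------------------------------------------------------

#' REML fit of a multi-kernel mixed model
#'
#' Holds the estimated variance components (one per kernel effect plus pen,
#' litter and residual), the restricted log-likelihood, convergence
#' diagnostics, BLUPs of every random effect mapped to the animal level, and
#' fixed-effect estimates.
#'
#' @slot sigma2 named variance components.
#' @slot loglik restricted log-likelihood at the final accepted iterate.
#' @slot converged did the fit meet the tolerance within `maxit`?
#' @slot nIterations accepted iterations used.
#' @slot blup named list of per-animal random-effect predictions.
#' @slot fixedEstimates named fixed-effect coefficients.
#' @slot spec the [ModelSpec-class] fitted (may be `NULL` for internal fits).
#' @slot n number of records.
#' @slot trace restricted log-likelihood at each accepted iterate.
#' @slot notes character log (aliased columns dropped, pinned components...).
#' @export
setClass("VarCompFit",
    slots = c(sigma2 = "numeric", loglik = "numeric", converged = "logical",
              nIterations = "integer", blup = "list",
              fixedEstimates = "numeric", spec = "ANY", n = "integer",
              trace = "numeric", notes = "character"))

setValidity("VarCompFit", function(object) {
    msg <- character()
    if (any(object@sigma2 < 0))
        msg <- c(msg, "variance components must be >= 0")
    if (length(object@trace) > 1L &&
        any(diff(object@trace) < -1e-6))
        msg <- c(msg, "restricted log-likelihood must be non-decreasing over accepted iterates")
    if (length(msg)) msg else TRUE
})

## ---------------------------------------------------------------------------
## VarianceReport
## ---------------------------------------------------------------------------

#' Variance-share summary of a fit
#'
#' Phenotypic-variance proportions: one share per kernel, their total, and
#' the pen, litter and residual shares.  Per-kernel shares sum to the total
#' omics share; all shares sum to one.
#'
#' @slot perKernelShare named fractions, one per fitted kernel effect.
#' @slot totalOmicsShare,penShare,litterShare,residualShare fractions.
#' @export
setClass("VarianceReport",
    slots = c(perKernelShare = "numeric", totalOmicsShare = "numeric",
              penShare = "numeric", litterShare = "numeric",
              residualShare = "numeric"))

setValidity("VarianceReport", function(object) {
    sh <- c(object@perKernelShare, object@penShare, object@litterShare,
            object@residualShare, object@totalOmicsShare)
    msg <- character()
    if (any(sh < -1e-12) || any(sh > 1 + 1e-12))
        msg <- c(msg, "all shares must lie in [0, 1]")
    if (abs(sum(object@perKernelShare) - object@totalOmicsShare) > 1e-10)
        msg <- c(msg, "per-kernel shares must sum to the total omics share")
    tot <- object@totalOmicsShare + object@penShare + object@litterShare +
        object@residualShare
    if (abs(tot - 1) > 1e-10)
        msg <- c(msg, "shares must sum to 1")
    if (length(msg)) msg else TRUE
})

## ---------------------------------------------------------------------------
## FoldPlan / CVResult
## ---------------------------------------------------------------------------

#' One leave-one-batch-out fold
#'
#' @slot company company ID the fold belongs to.
#' @slot validationBatch the held-out batch.
#' @slot trainingAnimals,validationAnimals disjoint animal ID vectors, all
#'   from `company`.
#' @export
setClass("FoldPlan",
    slots = c(company = "character", validationBatch = "character",
              trainingAnimals = "character", validationAnimals = "character"))

setValidity("FoldPlan", function(object) {
    msg <- character()
    if (length(object@trainingAnimals) == 0L ||
        length(object@validationAnimals) == 0L)
        msg <- c(msg, "training and validation sets must be nonempty")
    if (length(intersect(object@trainingAnimals, object@validationAnimals)))
        msg <- c(msg, "training and validation sets must be disjoint")
    if (length(msg)) msg else TRUE
})

#' Cross-validation result for one trait/model
#'
#' @slot trait,model identifiers.
#' @slot perFold data.frame with one row per fold: batch, n, correlation,
#'   converged flag.
#' @slot weightedAccuracy sample-size-weighted mean of fold correlations over
#'   converged folds with defined correlations.
#' @slot pooledAUC pooled out-of-sample AUC (binary traits; `NA` otherwise).
#' @slot nFoldsConverged count of folds whose REML fit converged.
#' @slot scores pooled out-of-sample scores, named by animal.
#' @slot log character messages (dropped folds, confounded terms...).
#' @export
setClass("CVResult",
    slots = c(trait = "character", model = "character",
              perFold = "data.frame", weightedAccuracy = "numeric",
              pooledAUC = "numeric", nFoldsConverged = "integer",
              scores = "numeric", log = "character"))

## ---------------------------------------------------------------------------
## SimulationConfig / SyntheticCohort
## ---------------------------------------------------------------------------

#' Configuration of a synthetic multi-omics cohort
#'
#' Defines the cohort layout (companies, batches, pens, litters), the
#' genotype panel, the omics layers with their genetic anchoring, the
#' ground-truth variance components per trait, liability thresholds for
#' binary traits, and per-layer missingness rates.
#'
#' @slot nCompanies number of source companies.
#' @slot batchesPerCompany integer vector, one entry per company.
#' @slot animalsPerBatch animals entering per batch.
#' @slot pensPerBatch,littersPerBatch pens / litters nested in each batch.
#' @slot nSnps SNP panel size.
#' @slot mafRange minor-allele-frequency range, within (0, 0.5].
#' @slot nFeatures named counts per omics layer.
#' @slot geneticAnchor named fractions in \[0,1\]: share of each feature's
#'   variance driven by genotype.
#' @slot trueVarcomps named list, one entry per trait: named variance
#'   components over kernels (`G` and/or layer initials), `pen`, `litter`,
#'   `residual`.
#' @slot binaryTraits named liability thresholds; listed traits are emitted
#'   as 0/1 by thresholding the latent liability.
#' @slot missingness named per-layer missing rates in \[0, 1).
#' @slot seed integer master seed.
#' @export
setClass("SimulationConfig",
    slots = c(nCompanies = "integer", batchesPerCompany = "integer",
              animalsPerBatch = "integer", pensPerBatch = "integer",
              littersPerBatch = "integer", nSnps = "integer",
              mafRange = "numeric", nFeatures = "numeric",
              geneticAnchor = "numeric", trueVarcomps = "list",
              binaryTraits = "numeric", missingness = "numeric",
              seed = "integer"))

setValidity("SimulationConfig", function(object) {
    msg <- character()
    if (length(object@batchesPerCompany) != object@nCompanies)
        msg <- c(msg, "batchesPerCompany must have one entry per company")
    if (any(c(object@batchesPerCompany, object@animalsPerBatch,
              object@pensPerBatch, object@littersPerBatch,
              object@nSnps) <= 0))
        msg <- c(msg, "all counts must be positive")
    if (length(object@mafRange) != 2L || object@mafRange[1] <= 0 ||
        object@mafRange[2] > 0.5 || diff(object@mafRange) < 0)
        msg <- c(msg, "mafRange must be an increasing pair within (0, 0.5]")
    if (any(object@geneticAnchor < 0 | object@geneticAnchor > 1))
        msg <- c(msg, "geneticAnchor entries must lie in [0, 1]")
    if (!setequal(names(object@geneticAnchor), names(object@nFeatures)))
        msg <- c(msg, "geneticAnchor and nFeatures must name the same layers")
    layerInitials <- toupper(substr(names(object@nFeatures), 1, 1))
    for (tr in names(object@trueVarcomps)) {
        vc <- object@trueVarcomps[[tr]]
        if (any(vc < 0))
            msg <- c(msg, sprintf("variance components for '%s' must be >= 0", tr))
        if (!all(c("pen", "litter", "residual") %in% names(vc)))
            msg <- c(msg, sprintf("'%s' needs pen, litter and residual components", tr))
        kn <- setdiff(names(vc), c("pen", "litter", "residual"))
        bad <- setdiff(kn, c("G", layerInitials))
        if (length(bad))
            msg <- c(msg, sprintf("'%s' references unsimulated kernel(s): %s",
                                  tr, paste(bad, collapse = ", ")))
        if (!is.finite(sum(vc)))
            msg <- c(msg, sprintf("'%s' components must sum to a finite variance", tr))
    }
    if (any(object@missingness < 0 | object@missingness >= 1))
        msg <- c(msg, "missingness rates must lie in [0, 1)")
    if (length(msg)) msg else TRUE
})

#' Synthetic cohort with known ground truth
#'
#' @slot genotypes animals x SNP dosage matrix in \{0, 1, 2\}.
#' @slot design data.frame: animal, company, batch, pen, litter, entryAge,
#'   rin, toyStatus.
#' @slot rawLayers named list of animals x features raw matrices (counts for
#'   the transcriptome, abundances with injected missingness for the
#'   proteome, concentrations with sub-LOD masking for the metabolome).
#' @slot phenotypes animals x traits matrix; binary traits are 0/1.
#' @slot truth list: realized random effects per trait, the truth kernels,
#'   and the [SimulationConfig-class] used.
#' @export
setClass("SyntheticCohort",
    slots = c(genotypes = "matrix", design = "data.frame",
              rawLayers = "list", phenotypes = "matrix", truth = "list"))

setValidity("SyntheticCohort", function(object) {
    n <- nrow(object@design)
    msg <- character()
    if (nrow(object@genotypes) != n || nrow(object@phenotypes) != n)
        msg <- c(msg, "row counts must be identical across components")
    for (nm in names(object@rawLayers))
        if (nrow(object@rawLayers[[nm]]) != n)
            msg <- c(msg, sprintf("layer '%s' row count differs from design", nm))
    cfg <- object@truth$config
    if (is(cfg, "SimulationConfig")) {
        for (tr in names(cfg@binaryTraits)) {
            v <- object@phenotypes[, tr]
            if (!all(v %in% c(0, 1)))
                msg <- c(msg, sprintf("binary trait '%s' must be 0/1", tr))
        }
    }
    if (length(msg)) msg else TRUE
})
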