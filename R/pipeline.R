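## End-to-end orchestration: simulate -> preprocess -> kernels -> variance
## fits -> leave-one-batch-out CV -> delimited tables, plots and a
## reproducibility manifest.  One YAML config governs everything.

.defaultPipelineConfig <- function() {
    list(simulation = list(seed = 1L),
         analysis = list(layers = c("transcriptome", "proteome", "metabolome"),
                         models = "all", combinedVariants = TRUE,
                         traits = "all", fixedTerms = c("entryAge", "batch"),
                         minBatches = 3L, knnK = 10L, adjustMode = "fold",
                         epsilon = 1e-8,
                         validateProteomeImputation = FALSE))
}

.mergeConfig <- function(base, user) {
    for (nm in names(user)) {
        base[[nm]] <- if (is.list(base[[nm]]) && is.list(user[[nm]]))
            .mergeConfig(base[[nm]], user[[nm]]) else user[[nm]]
    }
    base
}

## Preprocess one raw layer into an OmicsMatrix.
.preprocessLayer <- function(layer, raw, design, knnK = 10L,
                             validateProteome = FALSE, logLines = NULL) {
    spec <- featureModelSpec(layer)
    mat <- switch(layer,
        transcriptome = normalizeCounts(raw),
        proteome = {
            m <- log2(raw)
            if (validateProteome && anyNA(m)) {
                val <- validateImputation(m, nMaskedFeatures = min(100L, ncol(m)),
                                          nRepeats = 20L, k = knnK)
                m <- m[, colnames(m) %in% val$retained, drop = FALSE]
            }
            if (anyNA(m)) knnImpute(m, k = knnK) else m
        },
        metabolome = filterMetabolites(raw),
        { if (anyNA(raw)) knnImpute(raw, k = knnK) else raw })
    residualizeFeatures(mat, spec, design)
}

#' Run the full analysis pipeline from one config
#'
#' Stages: simulate the cohort, preprocess each omics layer (TMM/log-CPM for
#' counts, metabolite filtering + median imputation, KNN imputation for the
#' proteome, per-feature mixed-model residualization), QC genotypes and
#' build the block-diagonal genomic kernel plus one kernel per layer
#' (stabilized), fit every requested trait x model combination on the full
#' cohort (variance-component table), and run leave-one-batch-out CV
#' (accuracy table, pooled AUC for binary traits).  Writes delimited tables,
#' summary barplots and a JSON manifest (config hash, seed, package version,
#' per-file digests, non-convergence log) to `outDir`; reruns with the same
#' config are byte-identical.
#'
#' @param config path to a YAML config, or an equivalent nested list.  Keys:
#'   `simulation` (arguments of [simulationConfig()]) and `analysis`
#'   (`layers`, `models` = `"all"` or labels like `"GT"` / `"GT(mean)"`,
#'   `traits`, `fixedTerms`, `minBatches`, `knnK`, `adjustMode`,
#'   `epsilon`).
#' @param outDir output directory.
#' @return invisible list with the cohort, kernels, fit table and CV table.
#' @export
runPipeline <- function(config = list(), outDir) {
    if (is.character(config) && length(config) == 1L)
        config <- yaml::read_yaml(config)
    cfg <- .mergeConfig(.defaultPipelineConfig(), config)
    dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
    logLines <- character()
    note <- function(stage, msg)
        logLines <<- c(logLines, paste0("[", stage, "] ", msg))

    ## ---- simulate --------------------------------------------------------
    simArgs <- cfg$simulation
    simCfg <- tryCatch(do.call(simulationConfig, simArgs),
                       error = function(e)
                           stop("stage simulate: ", conditionMessage(e)))
    cohort <- simulateCohort(simCfg)
    writeCohort(cohort, file.path(outDir, "cohort"))

    layers <- intersect(cfg$analysis$layers, names(cohort@rawLayers))

    ## ---- preprocess ------------------------------------------------------
    omics <- list()
    for (layer in layers) {
        omics[[layer]] <- tryCatch(
            .preprocessLayer(layer, cohort@rawLayers[[layer]],
                             cohort@design, knnK = cfg$analysis$knnK,
                             validateProteome =
                                 isTRUE(cfg$analysis$validateProteomeImputation)),
            error = function(e)
                stop("stage preprocess/", layer, ": ", conditionMessage(e)))
        writeOmicsMatrix(omics[[layer]],
                         file.path(outDir, sprintf("omics_%s.tsv", layer)))
        nd <- length(omics[[layer]]@provenance$dropped)
        if (nd) note("preprocess", sprintf("%s: %d features dropped", layer, nd))
    }

    ## ---- kernels ---------------------------------------------------------
    qc <- qcGenotypes(cohort@genotypes)
    if (length(qc$removedSnps))
        note("kernels", sprintf("genotype QC removed %d SNPs, %d animals",
                                length(qc$removedSnps),
                                length(qc$removedAnimals)))
    keptAnimals <- rownames(qc$dosages)
    design <- cohort@design[cohort@design$animal %in% keptAnimals, ,
                            drop = FALSE]
    eps <- cfg$analysis$epsilon
    kernels <- list(G = stabilizeKernel(
        buildGenomicKernel(qc$dosages, design$company), epsilon = eps))
    for (layer in layers) {
        M <- omics[[layer]]
        idx <- match(design$animal, animalIds(M))
        Msub <- OmicsMatrix(as.matrix(M)[idx, , drop = FALSE],
                            layer = layerName(M), provenance = M@provenance)
        tag <- toupper(substr(layer, 1, 1))
        kernels[[tag]] <- stabilizeKernel(buildOmicsKernel(Msub, layer = tag),
                                          epsilon = eps)
    }
    for (tag in names(kernels))
        writeKernel(kernels[[tag]],
                    file.path(outDir, sprintf("kernel_%s.tsv", tag)))

    ## ---- model grid ------------------------------------------------------
    traits <- cfg$analysis$traits
    if (identical(traits, "all")) traits <- colnames(cohort@phenotypes)
    specsAll <- enumerateModelSpecs(names(kernels),
                                    combinedVariants =
                                        isTRUE(cfg$analysis$combinedVariants),
                                    fixedTerms = cfg$analysis$fixedTerms)
    if (!identical(cfg$analysis$models, "all"))
        specsAll <- specsAll[names(specsAll) %in% cfg$analysis$models]
    if (length(specsAll) == 0L) stop("stage fit: no model selected")

    ## ---- variance-component fits ----------------------------------------
    idx <- match(design$animal, cohort@design$animal)
    fitRows <- list()
    cvRows <- list()
    foldRows <- list()
    for (tr in traits) {
        y <- cohort@phenotypes[idx, tr]
        for (lab in names(specsAll)) {
            spec <- specsAll[[lab]]
            spec@trait <- tr
            fit <- tryCatch(fitREML(y, design, spec, kernels),
                            error = function(e)
                                stop("stage fit (", tr, "/", lab, "): ",
                                     conditionMessage(e)))
            s2 <- sigma2(fit)
            row <- data.frame(trait = tr, model = lab,
                              converged = isConverged(fit),
                              iterations = fit@nIterations)
            ## uniform component columns across models so rows bind cleanly
            for (nm in c(names(kernels), "C", "pen", "litter", "residual"))
                row[[paste0("s2_", nm)]] <-
                    if (nm %in% names(s2)) unname(s2[nm]) else NA_real_
            if (isConverged(fit) && sum(s2) > 0) {
                vr <- varianceReport(fit)
                row$totalOmicsShare <- vr@totalOmicsShare
                row$penShare <- vr@penShare
                row$litterShare <- vr@litterShare
                row$residualShare <- vr@residualShare
            } else {
                note("fit", sprintf("%s/%s did not converge", tr, lab))
                row$totalOmicsShare <- NA_real_
                row$penShare <- NA_real_
                row$litterShare <- NA_real_
                row$residualShare <- NA_real_
            }
            fitRows[[paste(tr, lab)]] <- row

            cv <- tryCatch(
                runCV(tr, spec, design, kernels, y,
                      adjustMode = cfg$analysis$adjustMode,
                      minBatches = cfg$analysis$minBatches),
                error = function(e)
                    stop("stage cv (", tr, "/", lab, "): ",
                         conditionMessage(e)))
            for (msg in cv@log) note("cv", sprintf("%s/%s: %s", tr, lab, msg))
            cvRows[[paste(tr, lab)]] <- data.frame(
                trait = tr, model = lab,
                weightedAccuracy = weightedAccuracy(cv),
                pooledAUC = pooledAUCValue(cv),
                nFoldsConverged = cv@nFoldsConverged,
                nFolds = nrow(perFold(cv)))
            pf <- perFold(cv)
            pf$trait <- tr; pf$model <- lab
            foldRows[[paste(tr, lab)]] <- pf
        }
    }
    fitTable <- do.call(rbind, c(fitRows, list(make.row.names = FALSE)))
    cvTable <- do.call(rbind, c(cvRows, list(make.row.names = FALSE)))
    foldTable <- do.call(rbind, c(foldRows, list(make.row.names = FALSE)))
    .writeTSV(fitTable, file.path(outDir, "variance_components.tsv"))
    .writeTSV(cvTable, file.path(outDir, "cv_results.tsv"))
    .writeTSV(foldTable, file.path(outDir, "cv_folds.tsv"))

    ## ---- plots -----------------------------------------------------------
    grDevices::pdf(file.path(outDir, "variance_shares.pdf"), width = 9,
                   height = 4 * length(traits))
    graphics::par(mfrow = c(length(traits), 1), mar = c(7, 4, 2, 1))
    for (tr in traits) {
        d <- fitTable[fitTable$trait == tr, ]
        graphics::barplot(d$totalOmicsShare, names.arg = d$model, las = 2,
                          ylab = "total omics share", main = tr,
                          cex.names = 0.7)
    }
    grDevices::dev.off()
    grDevices::pdf(file.path(outDir, "cv_accuracy.pdf"), width = 9,
                   height = 4 * length(traits))
    graphics::par(mfrow = c(length(traits), 1), mar = c(7, 4, 2, 1))
    for (tr in traits) {
        d <- cvTable[cvTable$trait == tr, ]
        graphics::barplot(d$weightedAccuracy, names.arg = d$model, las = 2,
                          ylab = "weighted accuracy", main = tr,
                          cex.names = 0.7)
    }
    grDevices::dev.off()

    ## ---- manifest --------------------------------------------------------
    writeLines(logLines, file.path(outDir, "run_log.txt"))
    tables <- c("variance_components.tsv", "cv_results.tsv", "cv_folds.tsv")
    manifest <- list(
        configHash = unname(tools::md5sum(.writeConfigCanonical(cfg, outDir))),
        seed = simCfg@seed,
        packageVersion = as.character(utils::packageVersion("omicBLUP")),
        files = as.list(tools::md5sum(file.path(outDir, tables))),
        nonConvergence = logLines[grepl("did not converge", logLines)])
    jsonlite::write_json(manifest, file.path(outDir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
    invisible(list(cohort = cohort, omics = omics, kernels = kernels,
                   fitTable = fitTable, cvTable = cvTable,
                   foldTable = foldTable, manifest = manifest))
}

## Serialize the merged config deterministically so its digest is stable.
.writeConfigCanonical <- function(cfg, outDir) {
    path <- file.path(outDir, "config_resolved.yaml")
    sortRec <- function(x) {
        if (!is.list(x)) return(x)
        x <- x[order(names(x))]
        lapply(x, sortRec)
    }
    yaml::write_yaml(sortRec(cfg), path)
    path
}
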