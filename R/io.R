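## Delimited readers and writers.  All tables are TSV with headers; square
## kernels carry the animal IDs as header row and first column, plus a YAML
## sidecar (layer, ridge, dimensions).

.writeTSV <- function(x, path, rowNames = FALSE) {
    utils::write.table(x, path, sep = "\t", quote = FALSE,
                       row.names = rowNames, col.names = TRUE)
}

#' Write a synthetic cohort to a directory
#'
#' Emits `design.tsv`, `phenotypes.tsv`, `dosages.tsv` (delimited 0/1/2
#' dosage matrix, animals in rows), one `layer_<name>.tsv` per omics layer
#' (`NA` for missing cells; sub-LOD flags for the metabolome in
#' `layer_<name>_subLOD.tsv`), and `truth.yaml` with the configured
#' variance components and seed.
#'
#' @param cohort a [SyntheticCohort-class].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
writeCohort <- function(cohort, dir) {
    stopifnot(is(cohort, "SyntheticCohort"))
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    .writeTSV(cohort@design, file.path(dir, "design.tsv"))
    .writeTSV(data.frame(animal = rownames(cohort@phenotypes),
                         cohort@phenotypes, check.names = FALSE),
              file.path(dir, "phenotypes.tsv"))
    .writeTSV(data.frame(animal = rownames(cohort@genotypes),
                         cohort@genotypes, check.names = FALSE),
              file.path(dir, "dosages.tsv"))
    for (nm in names(cohort@rawLayers)) {
        m <- cohort@rawLayers[[nm]]
        .writeTSV(data.frame(animal = rownames(m), m, check.names = FALSE),
                  file.path(dir, sprintf("layer_%s.tsv", nm)))
        sub <- attr(m, "subLOD")
        if (!is.null(sub))
            .writeTSV(data.frame(animal = rownames(m), sub * 1L,
                                 check.names = FALSE),
                      file.path(dir, sprintf("layer_%s_subLOD.tsv", nm)))
    }
    cfg <- cohort@truth$config
    yaml::write_yaml(list(seed = cfg@seed,
                          trueVarcomps = lapply(cfg@trueVarcomps, as.list),
                          binaryTraits = as.list(cfg@binaryTraits)),
                     file.path(dir, "truth.yaml"))
    invisible(dir)
}

#' Read a delimited feature (or dosage) matrix
#'
#' First column is the animal ID; remaining columns are features.
#'
#' @param path TSV path.
#' @return numeric matrix with animal row names.
#' @export
readFeatureMatrix <- function(path) {
    d <- utils::read.delim(path, check.names = FALSE,
                           stringsAsFactors = FALSE)
    m <- as.matrix(d[, -1, drop = FALSE])
    rownames(m) <- d[[1]]
    storage.mode(m) <- "double"
    m
}

#' Read a cohort design table
#' @param path TSV path.
#' @return data.frame.
#' @export
readDesign <- function(path) {
    utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE,
                      colClasses = NA)
}

#' Write / read a relationship kernel
#'
#' The kernel is a TSV square matrix with the animal IDs as header and
#' first column; `<path>.meta.yaml` records layer, ridge and dimensions.
#'
#' @param kernel a [RelationshipKernel-class].
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
writeKernel <- function(kernel, path) {
    stopifnot(is(kernel, "RelationshipKernel"))
    v <- as.matrix(kernel)
    .writeTSV(data.frame(animal = rownames(v), v, check.names = FALSE), path)
    yaml::write_yaml(list(layer = layerName(kernel),
                          ridgeApplied = ridgeApplied(kernel),
                          n = nrow(v)),
                     paste0(path, ".meta.yaml"))
    invisible(path)
}

#' @rdname writeKernel
#' @export
readKernel <- function(path) {
    v <- readFeatureMatrix(path)
    colnames(v) <- rownames(v)
    meta <- if (file.exists(paste0(path, ".meta.yaml")))
        yaml::read_yaml(paste0(path, ".meta.yaml")) else list()
    RelationshipKernel(v, layer = meta$layer %||% "K",
                       ridgeApplied = meta$ridgeApplied %||% 0)
}

#' Write an OmicsMatrix with its provenance sidecar
#'
#' @param M an [OmicsMatrix-class].
#' @param path output TSV path; provenance goes to `<path>.meta.yaml`.
#' @return `path`, invisibly.
#' @export
writeOmicsMatrix <- function(M, path) {
    stopifnot(is(M, "OmicsMatrix"))
    v <- as.matrix(M)
    .writeTSV(data.frame(animal = rownames(v), v, check.names = FALSE), path)
    prov <- M@provenance
    yaml::write_yaml(list(layer = layerName(M),
                          nFeatures = ncol(v),
                          fixedTerms = prov$fixedTerms,
                          dropped = as.list(prov$droppedReason),
                          nOlsFallback = sum(prov$olsFallback %||% FALSE)),
                     paste0(path, ".meta.yaml"))
    invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
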