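## Leave-one-batch-out validation: fold planning within companies that have
## at least three batches, phenotype pre-adjustment, training-fold REML,
## out-of-fold kernel BLUP, batch-weighted accuracy and pooled AUC.

#' Plan leave-one-batch-out folds
#'
#' One fold per (company, batch) for every company with at least
#' `minBatches` batches: the batch is held out for validation and the
#' company's remaining batches form the training set.  Deterministic order:
#' companies sorted, batches sorted within company.
#'
#' @param design cohort design table with `animal`, `company`, `batch`.
#' @param minBatches eligibility threshold (default 3).
#' @return list of [FoldPlan-class].
#' @export
planFolds <- function(design, minBatches = 3L) {
    stopifnot(all(c("animal", "company", "batch") %in% names(design)))
    byCompany <- split(design, design$company)
    eligible <- names(byCompany)[vapply(byCompany, function(d)
        length(unique(d$batch)) >= minBatches, NA)]
    if (length(eligible) == 0L)
        stop("noEligibleCompany: no company has at least ", minBatches,
             " batches")
    folds <- list()
    for (co in sort(eligible)) {
        d <- byCompany[[co]]
        for (b in sort(unique(d$batch))) {
            folds[[length(folds) + 1L]] <-
                new("FoldPlan", company = co, validationBatch = b,
                    trainingAnimals = d$animal[d$batch != b],
                    validationAnimals = d$animal[d$batch == b])
        }
    }
    folds
}

## Baseline (kernel-free) mixed model: fixed effects + pen + litter + e.
## Returns the conditional residuals and the fixed-effect solve pieces.
.baselineFit <- function(y, design, fixedTerms, includePen = TRUE,
                         includeLitter = TRUE, X = NULL, maxit = 200L) {
    if (is.null(X)) X <- .fixedDesign(design, fixedTerms)
    keep <- .fullRankColumns(X)
    X <- X[, keep, drop = FALSE]
    covs <- list()
    if (includePen)
        covs$pen <- tcrossprod(stats::model.matrix(~ 0 + factor(design$pen)))
    if (includeLitter)
        covs$litter <- tcrossprod(stats::model.matrix(~ 0 + factor(design$litter)))
    fit <- .remlCore(y, X, covs, maxit = maxit)
    corrected <- fit$theta[["residual"]] * fit$Py   # e-hat: y - Xb - pen - litter
    list(corrected = as.vector(corrected), fixed = fit$fixed, keep = keep,
         converged = fit$converged, theta = fit$theta)
}

#' Pre-adjust phenotypes with the kernel-free baseline model
#'
#' Fits fixed effects plus random pen and litter (no omics or genomic
#' animal effects) by REML and returns the conditional residuals
#' `y - X b-hat - pen BLUP - litter BLUP`.  These corrected phenotypes are
#' what out-of-fold predictions are evaluated against.
#'
#' @param y phenotype vector aligned to `design`.
#' @param design cohort design table.
#' @param fixedTerms fixed-effect columns of `design`.
#' @param includePen,includeLitter random terms of the baseline (default
#'   both TRUE).
#' @return named numeric vector of corrected phenotypes.
#' @export
adjustPhenotypes <- function(y, design, fixedTerms, includePen = TRUE,
                             includeLitter = TRUE) {
    stopifnot(length(y) == nrow(design))
    bl <- .baselineFit(y, design, fixedTerms, includePen, includeLitter)
    if (!bl$converged)
        stop("baselineNonConvergence: kernel-free adjustment model did not converge")
    setNames(bl$corrected, design$animal)
}

#' Predict validation animals from a training fit
#'
#' For each fitted kernel effect, projects the training BLUPs onto the
#' validation animals through the kernel:
#' `u-hat_val = K_val,train (K_train,train + ridge I)^-1 u-hat_train`
#' (the conditional mean, equivalent to solving the mixed-model equations
#' with validation phenotypes absent).  The prediction score is the sum
#' over fitted kernel effects; pen and litter effects are not projected
#' (validation batches house new pens and litters).
#'
#' @param fit [VarCompFit-class] from the training animals.
#' @param kernels named list of [RelationshipKernel-class] over training
#'   and validation animals, one per kernel effect in `fit` (for a
#'   combined fit: one kernel named `"C"`).
#' @param fold a [FoldPlan-class].
#' @param ridge added to the training block diagonal before solving
#'   (default 1e-8).
#' @return named numeric score per validation animal.
#' @export
predictValidation <- function(fit, kernels, fold, ridge = 1e-8) {
    stopifnot(is(fit, "VarCompFit"), is(fold, "FoldPlan"))
    effectNames <- setdiff(names(sigma2(fit)), c("pen", "litter", "residual"))
    scores <- setNames(rep(0, length(fold@validationAnimals)),
                       fold@validationAnimals)
    for (k in effectNames) {
        kern <- kernels[[k]]
        if (is.null(kern))
            stop("no kernel supplied for effect '", k, "'")
        K <- as.matrix(kern)
        itr <- match(fold@trainingAnimals, animalIds(kern))
        ival <- match(fold@validationAnimals, animalIds(kern))
        if (anyNA(itr) || anyNA(ival))
            stop("animalMissingFromKernel: fold animals absent from kernel '",
                 k, "'")
        uTrain <- blupEffects(fit)[[k]][fold@trainingAnimals]
        Ktt <- K[itr, itr] + diag(ridge, length(itr))
        scores <- scores +
            as.vector(K[ival, itr, drop = FALSE] %*% solve(Ktt, uTrain))
    }
    scores
}

#' Correlation between scores and corrected phenotypes in one fold
#'
#' @param scores predicted scores for the validation animals.
#' @param corrected adjusted phenotypes for the same animals, same order.
#' @return list with `correlation` (`NA` with `flagged = TRUE` when
#'   undefined, e.g. zero-variance scores) and `n`.
#' @export
evaluateFold <- function(scores, corrected) {
    stopifnot(length(scores) == length(corrected))
    n <- length(scores)
    if (n < 3L)
        stop("at least 3 validation animals required")
    if (stats::sd(scores) == 0 || stats::sd(corrected) == 0)
        return(list(correlation = NA_real_, n = n, flagged = TRUE))
    list(correlation = stats::cor(scores, corrected), n = n, flagged = FALSE)
}

#' Pooled AUC over concatenated out-of-fold scores
#'
#' Rank-based area under the ROC curve with ties counted one half
#' (equivalent to the Mann-Whitney statistic).  Pooling the out-of-sample
#' scores of all folds - each animal contributing exactly once - keeps the
#' AUC defined even when single batches contain only cases or only
#' controls.
#'
#' @param scores numeric prediction scores.
#' @param labels 0/1 outcomes, same length.
#' @return AUC in \[0, 1\].
#' @export
pooledAUC <- function(scores, labels) {
    stopifnot(length(scores) == length(labels))
    labels <- as.integer(labels)
    if (!all(labels %in% c(0L, 1L))) stop("labels must be 0/1")
    n1 <- sum(labels == 1L)
    n0 <- sum(labels == 0L)
    if (n1 == 0L || n0 == 0L)
        stop("singleClass: pooled set contains only cases or only controls")
    r <- rank(scores)          # midranks: ties count 1/2
    (sum(r[labels == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

## Factor terms whose validation levels are all seen in training; numeric
## terms are always kept.  Returns list(kept, dropped).
.foldSafeTerms <- function(terms, designTrain, designVal) {
    kept <- character(); dropped <- character()
    for (tm in terms) {
        v <- designTrain[[tm]]
        if (is.numeric(v)) { kept <- c(kept, tm); next }
        if (all(unique(as.character(designVal[[tm]])) %in%
                unique(as.character(v))))
            kept <- c(kept, tm)
        else dropped <- c(dropped, tm)
    }
    list(kept = kept, dropped = dropped)
}

#' Run leave-one-batch-out cross-validation for one trait and model
#'
#' Per fold: (i) fit the kernel-free baseline on the training batches and
#' correct the phenotypes (validation animals corrected with the
#' training-fold fixed-effect estimates; `adjustMode = "global"` instead
#' adjusts once on all data before splitting), (ii) fit the full model on
#' the raw training phenotypes, (iii) project kernel BLUPs onto the
#' validation batch, (iv) correlate scores with corrected phenotypes.
#' Fixed factors whose validation levels are unseen in training (always the
#' batch factor) are excluded from the fold-level model; their adjustment
#' falls to the intercept.  Folds whose REML fit does not converge are
#' excluded from the weighted mean and logged.  For binary traits the
#' pooled out-of-fold scores additionally give a pooled AUC.
#'
#' @param trait trait name (used for labeling).
#' @param spec a [ModelSpec-class].
#' @param design cohort design table.
#' @param kernels named list of stabilized [RelationshipKernel-class] over
#'   all animals, covering `spec@kernelSet`.
#' @param y phenotype vector aligned to `design` rows.
#' @param adjustMode `"fold"` (default; adjustment estimated on the
#'   training batches only) or `"global"`.
#' @param minBatches fold-eligibility threshold (default 3).
#' @param binary treat the trait as binary for AUC; default: auto-detect
#'   0/1 phenotypes.
#' @param ridge ridge for the validation projection.
#' @param maxit REML iteration cap per fold.
#' @return A [CVResult-class].
#' @export
runCV <- function(trait, spec, design, kernels, y,
                  adjustMode = c("fold", "global"), minBatches = 3L,
                  binary = NULL, ridge = 1e-8, maxit = 200L) {
    adjustMode <- match.arg(adjustMode)
    stopifnot(length(y) == nrow(design))
    if (is.null(binary)) binary <- all(y %in% c(0, 1))
    folds <- planFolds(design, minBatches)
    log <- character()

    globalCorrected <- NULL
    if (adjustMode == "global")
        globalCorrected <- adjustPhenotypes(y, design, spec@fixedTerms,
                                            spec@includePen,
                                            spec@includeLitter)

    perFold <- data.frame(company = character(), batch = character(),
                          n = integer(), correlation = numeric(),
                          converged = logical())
    allScores <- numeric()
    allLabels <- integer()

    for (fold in folds) {
        itr <- match(fold@trainingAnimals, design$animal)
        ival <- match(fold@validationAnimals, design$animal)
        dTrain <- design[itr, , drop = FALSE]
        dVal <- design[ival, , drop = FALSE]
        safe <- .foldSafeTerms(spec@fixedTerms, dTrain, dVal)
        if (length(safe$dropped))
            log <- c(log, sprintf(
                "fold %s/%s: fixed term(s) %s confounded with the split; dropped",
                fold@company, fold@validationBatch,
                paste(safe$dropped, collapse = ",")))

        dAll <- rbind(dTrain, dVal)
        Xall <- .fixedDesign(dAll, safe$kept)
        tIdx <- seq_len(nrow(dTrain))
        vIdx <- nrow(dTrain) + seq_len(nrow(dVal))

        ## corrected validation phenotypes
        if (adjustMode == "global") {
            corrVal <- globalCorrected[fold@validationAnimals]
        } else {
            keep <- .fullRankColumns(Xall[tIdx, , drop = FALSE])
            bl <- tryCatch(
                .remlCore(y[itr], Xall[tIdx, keep, drop = FALSE],
                          c(if (spec@includePen) list(pen = tcrossprod(
                                stats::model.matrix(~ 0 + factor(dTrain$pen)))),
                            if (spec@includeLitter) list(litter = tcrossprod(
                                stats::model.matrix(~ 0 + factor(dTrain$litter))))),
                          maxit = maxit),
                error = function(e) NULL)
            if (is.null(bl) || !bl$converged) {
                log <- c(log, sprintf("fold %s/%s: baseline adjustment failed; fold dropped",
                                      fold@company, fold@validationBatch))
                perFold <- rbind(perFold, data.frame(
                    company = fold@company, batch = fold@validationBatch,
                    n = length(ival), correlation = NA_real_,
                    converged = FALSE))
                next
            }
            corrVal <- as.vector(y[ival] -
                Xall[vIdx, keep, drop = FALSE] %*% bl$fixed)
        }

        ## full model on the training batches (raw phenotypes)
        foldSpec <- ModelSpec(trait = spec@trait, kernelSet = spec@kernelSet,
                              fixedTerms = safe$kept,
                              combined = spec@combined,
                              includePen = spec@includePen,
                              includeLitter = spec@includeLitter)
        kTrain <- lapply(kernels[spec@kernelSet], function(k) {
            idx <- match(fold@trainingAnimals, animalIds(k))
            RelationshipKernel(as.matrix(k)[idx, idx, drop = FALSE],
                               layer = layerName(k),
                               ridgeApplied = ridgeApplied(k))
        })
        fit <- tryCatch(
            fitREML(y[itr], dTrain, foldSpec, kTrain, maxit = maxit),
            error = function(e) NULL)
        if (is.null(fit) || !isConverged(fit)) {
            log <- c(log, sprintf("fold %s/%s: REML did not converge; fold excluded",
                                  fold@company, fold@validationBatch))
            perFold <- rbind(perFold, data.frame(
                company = fold@company, batch = fold@validationBatch,
                n = length(ival), correlation = NA_real_, converged = FALSE))
            next
        }

        predKernels <- if (isTRUE(spec@combined)) {
            list(C = combineKernels(kernels[spec@kernelSet]))
        } else kernels[spec@kernelSet]
        scores <- predictValidation(fit, predKernels, fold, ridge = ridge)
        ev <- evaluateFold(scores, corrVal)
        if (isTRUE(ev$flagged))
            log <- c(log, sprintf("fold %s/%s: zero-variance scores; correlation undefined",
                                  fold@company, fold@validationBatch))
        perFold <- rbind(perFold, data.frame(
            company = fold@company, batch = fold@validationBatch,
            n = ev$n, correlation = ev$correlation, converged = TRUE))
        allScores <- c(allScores, scores)
        allLabels <- c(allLabels, as.integer(y[ival]))
    }

    use <- perFold$converged & !is.na(perFold$correlation)
    wacc <- if (any(use))
        sum(perFold$n[use] * perFold$correlation[use]) / sum(perFold$n[use])
    else NA_real_
    auc <- NA_real_
    if (binary && length(allScores)) {
        auc <- tryCatch(pooledAUC(allScores, allLabels),
                        error = function(e) {
                            log <<- c(log, paste("pooled AUC undefined:",
                                                 conditionMessage(e)))
                            NA_real_
                        })
    }
    new("CVResult", trait = trait, model = modelLabel(spec),
        perFold = perFold, weightedAccuracy = wacc, pooledAUC = auc,
        nFoldsConverged = sum(perFold$converged),
        scores = allScores, log = log)
}
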