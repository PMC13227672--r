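## Shared fixtures: all built in code at test time.

## Small single-company cohort config; override any field.
smallConfig <- function(..., seed = 1L) {
    defaults <- list(
        nCompanies = 1L, batchesPerCompany = 3L, animalsPerBatch = 30L,
        pensPerBatch = 3L, littersPerBatch = 8L, nSnps = 200L,
        nFeatures = c(transcriptome = 100),
        geneticAnchor = c(transcriptome = 0.3),
        missingness = c(transcriptome = 0),
        trueVarcomps = list(y = c(G = 0.3, T = 0.2, pen = 0.05,
                                  litter = 0.05, residual = 0.4)),
        binaryTraits = numeric(), seed = seed)
    args <- utils::modifyList(defaults, list(...))
    do.call(simulationConfig, args)
}

## Random PSD kernel with animal IDs.
randomKernel <- function(n, layer = "K", seed = 1L, rank = n) {
    set.seed(seed)
    ids <- sprintf("A%03d", seq_len(n))
    M <- matrix(rnorm(n * rank), n, rank)
    v <- tcrossprod(scale(M)) / rank
    dimnames(v) <- list(ids, ids)
    stabilizeKernel(RelationshipKernel(v, layer = layer))
}

## Brute-force pairwise AUC oracle: concordant pairs + half ties.
bruteAUC <- function(scores, labels) {
    cases <- scores[labels == 1]
    ctrls <- scores[labels == 0]
    tot <- 0
    for (a in cases) for (b in ctrls)
        tot <- tot + (a > b) + 0.5 * (a == b)
    tot / (length(cases) * length(ctrls))
}

## Independent feature-wise KNN oracle: plain loops, same contract.
bruteKnnImpute <- function(x, k) {
    mu <- colMeans(x, na.rm = TRUE)
    sdv <- apply(x, 2, sd, na.rm = TRUE)
    sdv[!is.finite(sdv) | sdv == 0] <- 1
    z <- sweep(sweep(x, 2, mu), 2, sdv, "/")
    out <- x
    q <- ncol(x)
    for (j in seq_len(q)) {
        miss <- which(is.na(x[, j]))
        if (!length(miss)) next
        d <- rep(Inf, q)
        for (jj in seq_len(q)) {
            if (jj == j) next
            co <- which(!is.na(z[, j]) & !is.na(z[, jj]))
            if (length(co) >= 3)
                d[jj] <- mean((z[co, j] - z[co, jj])^2)
        }
        for (i in miss) {
            cand <- which(!is.na(z[i, ]) & is.finite(d))
            nb <- cand[order(d[cand], cand)][seq_len(k)]
            out[i, j] <- mu[j] + sdv[j] * mean(z[i, nb])
        }
    }
    out
}
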