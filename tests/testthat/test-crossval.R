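## Leave-one-batch-out protocol.

test_that("fold planning honors the three-batch eligibility rule", {
    ## layout with companies holding 3, 4, 4 batches among smaller ones
    mk <- function(co, nb, size = 10) {
        do.call(rbind, lapply(seq_len(nb), function(b)
            data.frame(animal = sprintf("%s_b%d_%02d", co, b, 1:size),
                       company = co, batch = sprintf("%s_b%d", co, b))))
    }
    design <- rbind(mk("A", 2), mk("B", 3), mk("C", 1), mk("D", 4),
                    mk("E", 4))
    folds <- planFolds(design)
    expect_length(folds, 11)            # 3 + 4 + 4
    expect_setequal(unique(vapply(folds, function(f) f@company, "")),
                    c("B", "D", "E"))

    ## all companies below threshold: named error
    expect_error(planFolds(rbind(mk("A", 2), mk("B", 2))),
                 "noEligibleCompany")

    ## validation sizes follow batch sizes
    d3 <- mk("Z", 3, 5)
    f3 <- planFolds(d3)
    expect_identical(vapply(f3, function(f) length(f@validationAnimals), 0L),
                     rep(5L, 3))
})

test_that("phenotype adjustment collapses to OLS residuals without random variance", {
    set.seed(51)
    n <- 60
    des <- data.frame(animal = sprintf("a%02d", 1:n),
                      batch = rep(c("b1", "b2", "b3"), each = 20),
                      pen = rep(sprintf("p%d", 1:6), each = 10),
                      litter = rep(sprintf("l%d", 1:12), 5),
                      entryAge = sample(19:25, n, TRUE))
    y <- 1 + 0.3 * des$entryAge + rnorm(n)   # no pen/litter signal
    corr <- adjustPhenotypes(y, des, c("batch", "entryAge"))
    X <- model.matrix(~ batch + entryAge, des)
    ols <- residuals(lm.fit(X, y))
    ## pen/litter variances estimate near zero -> near-OLS residuals
    expect_gt(cor(corr, ols), 0.999)

    ## corrected phenotypes are orthogonal to every fixed design column
    for (k in 2:ncol(X))
        expect_lt(abs(cor(corr, X[, k])), 1e-6)
})

test_that("adjustment strips nuisance variation and gets closer to the true signal", {
    better <- 0
    for (r in 1:20) {
        coh <- simulateCohort(smallConfig(seed = 6000L + r))
        y <- coh@phenotypes[, "y"]
        uSum <- Reduce(`+`, coh@truth$effects$y$u)
        corr <- adjustPhenotypes(y, coh@design, c("entryAge", "batch"))
        if (cor(corr, uSum) > cor(y, uSum)) better <- better + 1
    }
    expect_gte(better, 18)
})

test_that("validation scores follow kernel relationships to the training set", {
    set.seed(52)
    n <- 30
    K <- randomKernel(n, "G", seed = 11)
    ids <- animalIds(K)
    des <- data.frame(animal = ids, pen = "p1", litter = "l1")
    u <- as.vector(t(chol(as.matrix(K))) %*% rnorm(n))
    y <- 1 + u + rnorm(n, 0, 0.5)
    tr <- 1:24; va <- 25:30
    spec <- ModelSpec("y", "G", includePen = FALSE, includeLitter = FALSE)
    Ktr <- RelationshipKernel(as.matrix(K)[tr, tr], "G", ridgeApplied(K))
    fit <- fitREML(y[tr], des[tr, ], spec, list(G = Ktr))
    fold <- new("FoldPlan", company = "X", validationBatch = "b",
                trainingAnimals = ids[tr], validationAnimals = ids[va])

    ## zero kernel rows to training -> zero score
    K0 <- as.matrix(K)
    K0[va, tr] <- 0; K0[tr, va] <- 0
    sc0 <- predictValidation(fit, list(G = RelationshipKernel(K0, "G")), fold)
    expect_equal(unname(sc0), rep(0, 6), tolerance = 1e-12)

    ## clone of a training animal scores as that animal's u-hat
    Kc <- as.matrix(K)
    Kc[25, ] <- Kc[1, ]; Kc[, 25] <- Kc[, 1]; Kc[25, 25] <- Kc[1, 1]
    scc <- predictValidation(fit, list(G = RelationshipKernel(Kc, "G")),
                             fold, ridge = 1e-12)
    expect_equal(unname(scc[1]), unname(blupEffects(fit)$G[1]),
                 tolerance = 1e-8)

    ## full-MME oracle with the validation phenotypes absent
    sc <- predictValidation(fit, list(G = K), fold)
    s2 <- sigma2(fit)
    lam <- s2[["residual"]] / s2[["G"]]
    X <- matrix(1, 24); Z <- diag(n)[tr, ]
    Ki <- solve(as.matrix(K))
    C <- rbind(cbind(crossprod(X), crossprod(X, Z)),
               cbind(crossprod(Z, X), crossprod(Z) + lam * Ki))
    sol <- solve(C, c(crossprod(X, y[tr]), crossprod(Z, y[tr])))
    expect_lt(max(abs(sc - sol[1 + va])), 1e-6)

    ## validation animal absent from the kernel is an error
    Ksmall <- RelationshipKernel(as.matrix(K)[1:28, 1:28], "G")
    expect_error(predictValidation(fit, list(G = Ksmall), fold),
                 "animalMissingFromKernel")
})

test_that("fold evaluation is the plain product-moment correlation", {
    expect_equal(evaluateFold(1:5, (1:5) * 2)$correlation, 1)
    expect_equal(evaluateFold(1:5, -(1:5))$correlation, -1)
    s <- c(1.2, -0.5, 3.1, 0.4, -2.2)
    yv <- c(0.3, 0.1, 2.5, -1.0, -0.8)
    ev <- evaluateFold(s, yv)
    expect_equal(ev$correlation,
                 sum((s - mean(s)) * (yv - mean(yv))) /
                     sqrt(sum((s - mean(s))^2) * sum((yv - mean(yv))^2)))
    expect_identical(ev$n, 5L)
    expect_true(is.na(evaluateFold(rep(1, 4), rnorm(4))$correlation))
    expect_error(evaluateFold(1:2, 1:2), "at least 3")
})

test_that("pooled AUC equals the pairwise Mann-Whitney oracle", {
    expect_equal(pooledAUC(c(1, 2, 3, 10, 11, 12), c(0, 0, 0, 1, 1, 1)), 1)
    expect_error(pooledAUC(1:4, rep(1, 4)), "singleClass")

    ## hand-set scores with a tie
    s <- c(0.9, 0.8, 0.8, 0.7, 0.4, 0.3, 0.2, 0.1)
    l <- c(1, 1, 0, 0, 1, 0, 0, 1)
    expect_equal(pooledAUC(s, l), bruteAUC(s, l))

    set.seed(53)
    for (r in 1:10) {
        n <- sample(10:200, 1)
        s <- sample(round(rnorm(n), 1))  # rounded -> ties
        l <- rbinom(n, 1, 0.4)
        if (length(unique(l)) < 2) next
        expect_equal(pooledAUC(s, l), bruteAUC(s, l), tolerance = 1e-12)
    }

    ## null case: labels independent of scores
    set.seed(54)
    s <- rnorm(500); l <- rbinom(500, 1, 0.5)
    se <- sqrt((sum(l == 1) + sum(l == 0) + 1) /
               (12 * sum(l == 1) * sum(l == 0)))
    expect_lt(abs(pooledAUC(s, l) - 0.5), 3 * se)
})

test_that("cross-validation is deterministic and leak-free", {
    coh <- simulateCohort(smallConfig(seed = 61L, batchesPerCompany = 4L))
    k <- lapply(coh@truth$kernels, stabilizeKernel)
    spec <- ModelSpec("y", c("G", "T"), fixedTerms = c("entryAge", "batch"))
    y <- coh@phenotypes[, "y"]
    cv1 <- runCV("y", spec, coh@design, k, y)
    cv2 <- runCV("y", spec, coh@design, k, y)
    expect_identical(perFold(cv1), perFold(cv2))
    expect_identical(weightedAccuracy(cv1), weightedAccuracy(cv2))

    ## out-of-fold purity: perturbing a validation phenotype leaves that
    ## fold's training fit (and hence its correlation) bitwise unchanged
    folds <- planFolds(coh@design)
    vIds <- folds[[1]]@validationAnimals
    y2 <- y
    y2[match(vIds[1], coh@design$animal)] <- 999
    cv3 <- runCV("y", spec, coh@design, k, y2)
    ## other folds see the perturbed animal in training; fold 1 must not:
    ## its out-of-fold scores are bitwise unchanged
    expect_identical(cv1@scores[vIds], cv3@scores[vIds])

    ## weighted accuracy recomputes exactly from the per-fold table
    pf <- perFold(cv1)
    use <- pf$converged & !is.na(pf$correlation)
    expect_identical(weightedAccuracy(cv1),
                     sum(pf$n[use] * pf$correlation[use]) / sum(pf$n[use]))
})

test_that("combined-kernel models predict through the mean kernel", {
    coh <- simulateCohort(smallConfig(seed = 62L, batchesPerCompany = 3L))
    k <- lapply(coh@truth$kernels, stabilizeKernel)
    spec <- ModelSpec("y", c("G", "T"), fixedTerms = c("entryAge", "batch"),
                      combined = TRUE)
    cv <- runCV("y", spec, coh@design, k, coh@phenotypes[, "y"])
    expect_identical(cv@model, "GT(mean)")
    expect_true(cv@nFoldsConverged >= 1)
    expect_true(all(perFold(cv)$n > 0))
})

test_that("binary traits produce a pooled AUC on out-of-fold scores", {
    cfg <- smallConfig(seed = 63L, batchesPerCompany = 4L,
                       animalsPerBatch = 40L,
                       binaryTraits = c(m = qnorm(0.7)),
                       trueVarcomps = list(
                           m = c(G = 0.3, T = 0.2, pen = 0.05,
                                 litter = 0.05, residual = 0.4)))
    coh <- simulateCohort(cfg)
    k <- lapply(coh@truth$kernels, stabilizeKernel)
    spec <- ModelSpec("m", c("G", "T"), fixedTerms = c("entryAge", "batch"))
    cv <- runCV("m", spec, coh@design, k, coh@phenotypes[, "m"])
    expect_false(is.na(pooledAUCValue(cv)))
    expect_gte(pooledAUCValue(cv), 0)
    expect_lte(pooledAUCValue(cv), 1)
    ## each validation animal of a converged fold contributes exactly once
    if (cv@nFoldsConverged == nrow(perFold(cv)))
        expect_identical(sort(names(cv@scores)), sort(coh@design$animal))
    expect_false(anyDuplicated(names(cv@scores)) > 0)
})
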