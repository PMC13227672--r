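## Multi-kernel REML, variance shares, model grid.

test_that("single-kernel REML matches a 1-D grid/profile search oracle", {
    set.seed(41)
    n <- 40
    K <- randomKernel(n, "G", seed = 5, rank = 30)
    des <- data.frame(animal = animalIds(K), age = rnorm(n),
                      pen = "p1", litter = "l1")
    u <- as.vector(t(chol(as.matrix(K))) %*% rnorm(n)) * sqrt(1.5)
    y <- 2 + 0.5 * des$age + u + rnorm(n, 0, sqrt(2))
    spec <- ModelSpec("y", "G", fixedTerms = "age", includePen = FALSE,
                      includeLitter = FALSE)
    fit <- fitREML(y, des, spec, list(G = K))
    expect_true(isConverged(fit))

    ## oracle: profile the restricted likelihood over the variance ratio
    X <- cbind(1, des$age)
    Km <- as.matrix(K)
    profLL <- function(lam) {
        V0 <- lam * Km + diag(n)
        ch <- chol(V0); Vi <- chol2inv(ch)
        XtViX <- crossprod(X, Vi %*% X)
        b <- solve(XtViX, crossprod(X, Vi %*% y))
        r <- y - X %*% b
        s2e <- sum(r * (Vi %*% r)) / (n - 2)
        -0.5 * (2 * sum(log(diag(ch))) +
                as.numeric(determinant(XtViX)$modulus) + (n - 2) * log(s2e))
    }
    opt <- optimize(function(lg) -profLL(exp(lg)), c(-12, 12))
    lam <- exp(opt$minimum)
    Vi <- chol2inv(chol(lam * Km + diag(n)))
    b <- solve(crossprod(X, Vi %*% X), crossprod(X, Vi %*% y))
    r <- y - X %*% b
    s2e <- sum(r * (Vi %*% r)) / (n - 2)
    expect_equal(unname(sigma2(fit)[["G"]]), lam * s2e, tolerance = 1e-3)
    expect_equal(unname(sigma2(fit)[["residual"]]), s2e, tolerance = 1e-3)
})

test_that("zero-variance phenotypes are rejected", {
    K <- randomKernel(10, "G", seed = 6)
    des <- data.frame(animal = animalIds(K), pen = "p1", litter = "l1")
    spec <- ModelSpec("y", "G", includePen = FALSE, includeLitter = FALSE)
    expect_error(fitREML(rep(3, 10), des, spec, list(G = K)),
                 "degenerateResponse")
})

test_that("variance estimates are scale equivariant", {
    set.seed(42)
    n <- 60
    K <- randomKernel(n, "G", seed = 7)
    des <- data.frame(animal = animalIds(K),
                      pen = rep(paste0("p", 1:6), each = 10),
                      litter = rep(paste0("l", 1:12), 5))
    u <- as.vector(t(chol(as.matrix(K))) %*% rnorm(n))
    y <- 1 + u + rnorm(n)
    spec <- ModelSpec("y", "G")
    f1 <- fitREML(y, des, spec, list(G = K))
    f3 <- fitREML(3 * y, des, spec, list(G = K))
    expect_equal(sigma2(f3), 9 * sigma2(f1), tolerance = 1e-3)
})

test_that("with identity kernels only the component total is identified", {
    set.seed(43)
    n <- 50
    ids <- sprintf("a%03d", 1:n)
    I1 <- RelationshipKernel(diag(n) |> `dimnames<-`(list(ids, ids)), "G")
    I2 <- RelationshipKernel(diag(n) |> `dimnames<-`(list(ids, ids)), "T")
    des <- data.frame(animal = ids, age = rnorm(n), pen = "p1",
                      litter = "l1")
    y <- 2 + 0.3 * des$age + rnorm(n, 0, 2)
    spec <- ModelSpec("y", c("G", "T"), fixedTerms = "age",
                      includePen = FALSE, includeLitter = FALSE)
    fit <- fitREML(y, des, spec, list(G = I1, T = I2))
    X <- cbind(1, des$age)
    s2ref <- sum(residuals(lm.fit(X, y))^2) / (n - 2)
    expect_equal(unname(sum(sigma2(fit))), s2ref, tolerance = 1e-6)
})

test_that("restricted log-likelihood is non-decreasing along accepted steps", {
    set.seed(44)
    n <- 60
    K <- randomKernel(n, "G", seed = 8)
    des <- data.frame(animal = animalIds(K),
                      pen = rep(paste0("p", 1:6), each = 10),
                      litter = rep(paste0("l", 1:12), 5))
    u <- as.vector(t(chol(as.matrix(K))) %*% rnorm(n)) * 0.8
    y <- u + rnorm(n)
    fit <- fitREML(y, des, ModelSpec("y", "G"), list(G = K))
    expect_true(all(diff(fit@trace) > -1e-8))
    expect_identical(fit@loglik, fit@trace[length(fit@trace)])
})

test_that("single-kernel parameter recovery at moderate n", {
    ## y simulated under the model with s2_G = 3, s2_e = 7; mean estimate
    ## over replicates within 2 empirical SD of the truth
    K <- randomKernel(120, "G", seed = 9, rank = 60)
    des <- data.frame(animal = animalIds(K), pen = "p1", litter = "l1")
    spec <- ModelSpec("y", "G", includePen = FALSE, includeLitter = FALSE)
    R <- chol(as.matrix(K))
    set.seed(45)
    est <- vapply(1:25, function(r) {
        u <- as.vector(t(R) %*% rnorm(120)) * sqrt(3)
        y <- 5 + u + rnorm(120, 0, sqrt(7))
        sigma2(fitREML(y, des, spec, list(G = K)))[["G"]]
    }, 0)
    expect_lt(abs(mean(est) - 3), 2 * sd(est))
})

test_that("variance shares follow the component-ratio definition", {
    mkFit <- function(s2) new("VarCompFit", sigma2 = s2, loglik = 0,
                              converged = TRUE, nIterations = 1L,
                              blup = list(), fixedEstimates = numeric(),
                              spec = NULL, n = 10L, trace = 0,
                              notes = character())
    vr <- varianceReport(mkFit(c(G = 3, pen = 1, litter = 1, residual = 5)))
    expect_equal(vr@totalOmicsShare, 0.3)
    expect_equal(unname(vr@perKernelShare["G"]), 0.3)
    expect_equal(vr@penShare, 0.1)

    vr0 <- varianceReport(mkFit(c(G = 0, T = 0, pen = 1, litter = 1,
                                  residual = 2)))
    expect_equal(vr0@totalOmicsShare, 0)

    vr2 <- varianceReport(mkFit(c(G = 2, T = 1, pen = 0, litter = 0,
                                  residual = 7)))
    expect_equal(unname(vr2@perKernelShare), c(0.2, 0.1))
    expect_equal(vr2@totalOmicsShare, 0.3)
    expect_equal(vr2@residualShare, 0.7)

    expect_error(varianceReport(mkFit(c(G = 0, pen = 0, litter = 0,
                                        residual = 0))),
                 "allComponentsZero")
    nc <- mkFit(c(G = 1, pen = 0, litter = 0, residual = 1))
    nc@converged <- FALSE
    expect_error(varianceReport(nc), "converged")
})

test_that("model grid enumerates the documented combination counts", {
    specs4 <- enumerateModelSpecs(c("G", "T", "P", "M"),
                                  combinedVariants = TRUE)
    expect_length(specs4, 26)
    expect_identical(names(specs4)[1:4], c("G", "T", "P", "M"))
    expect_identical(names(specs4)[15], "GTPM")
    expect_identical(names(specs4)[16], "GT(mean)")
    expect_identical(names(specs4)[26], "GTPM(mean)")
    expect_false(anyDuplicated(names(specs4)) > 0)

    expect_length(enumerateModelSpecs("G"), 1)
    expect_length(enumerateModelSpecs(c("G", "T"), combinedVariants = TRUE),
                  4)
    expect_length(enumerateModelSpecs(c("G", "T", "P", "M"),
                                      combinedVariants = FALSE), 15)
    expect_error(enumerateModelSpecs(character()), "nonempty")
})

test_that("aliased fixed columns are dropped and reported", {
    set.seed(46)
    n <- 40
    K <- randomKernel(n, "G", seed = 10)
    des <- data.frame(animal = animalIds(K),
                      batch = rep(c("b1", "b2"), each = 20),
                      company = rep(c("c1", "c2"), each = 20),  # aliased
                      pen = "p1", litter = "l1")
    y <- rnorm(n)
    spec <- ModelSpec("y", "G", fixedTerms = c("batch", "company"),
                      includePen = FALSE, includeLitter = FALSE)
    fit <- fitREML(y, des, spec, list(G = K))
    expect_true(any(grepl("aliased", fit@notes)))
})
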