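## Relationship-kernel construction.

test_that("single-company genomic kernel equals plain VanRaden method 1", {
    set.seed(31)
    n <- 12
    W <- matrix(rbinom(n * 40, 2, runif(40, 0.1, 0.5)), n, byrow = TRUE,
                dimnames = list(sprintf("a%02d", 1:n), paste0("s", 1:40)))
    K <- buildGenomicKernel(W, rep("X", n))
    p <- colMeans(W) / 2
    poly <- p > 0 & p < 1
    Wc <- sweep(W[, poly], 2, 2 * p[poly])
    ref <- tcrossprod(Wc) / (2 * sum(p[poly] * (1 - p[poly])))
    expect_equal(unname(as.matrix(K)), unname(ref), tolerance = 1e-12)
    expect_identical(layerName(K), "G")
})

test_that("cross-company entries are exactly zero", {
    set.seed(32)
    n <- 14
    W <- matrix(rbinom(n * 30, 2, 0.3), n,
                dimnames = list(sprintf("a%02d", 1:n), paste0("s", 1:30)))
    co <- rep(c("A", "B"), c(6, 8))
    K <- as.matrix(buildGenomicKernel(W, co))
    expect_true(all(K[1:6, 7:14] == 0))
    expect_true(all(K[7:14, 1:6] == 0))
})

test_that("6x20 hand-set dosages match the element-wise VanRaden oracle", {
    set.seed(33)
    W <- matrix(rbinom(6 * 20, 2, rep(c(0.2, 0.4), 10)), 6, byrow = TRUE,
                dimnames = list(paste0("a", 1:6), paste0("s", 1:20)))
    K <- as.matrix(buildGenomicKernel(W, rep("X", 6)))
    p <- colMeans(W) / 2
    poly <- which(p > 0 & p < 1)
    denom <- 2 * sum(p[poly] * (1 - p[poly]))
    for (i in 1:6) for (j in 1:6) {
        kij <- sum((W[i, poly] - 2 * p[poly]) * (W[j, poly] - 2 * p[poly])) /
            denom
        expect_equal(K[i, j], kij, tolerance = 1e-12)
    }
})

test_that("within-company permutation permutes the block identically", {
    set.seed(34)
    n <- 10
    W <- matrix(rbinom(n * 25, 2, 0.3), n,
                dimnames = list(sprintf("a%02d", 1:n), paste0("s", 1:25)))
    co <- rep(c("A", "B"), each = 5)
    K1 <- as.matrix(buildGenomicKernel(W, co))
    perm <- c(3, 1, 2, 5, 4, 6:10)      # permute within company A only
    K2 <- as.matrix(buildGenomicKernel(W[perm, ], co[perm]))
    expect_equal(unname(K2), unname(K1[perm, perm]), tolerance = 1e-12)
})

test_that("omics kernel matches its definition and handles clones", {
    ## orthogonal columns scaled so M M' = p I
    M <- diag(3) * sqrt(3)
    dimnames(M) <- list(paste0("a", 1:3), paste0("f", 1:3))
    K <- as.matrix(buildOmicsKernel(M, layer = "T"))
    expect_equal(unname(K), diag(3), tolerance = 1e-12)

    ## duplicate animal rows: off-diagonal equals both diagonals
    set.seed(35)
    M2 <- matrix(rnorm(4 * 6), 4, 6,
                 dimnames = list(paste0("a", 1:4), paste0("f", 1:6)))
    M2[2, ] <- M2[1, ]
    K2 <- as.matrix(buildOmicsKernel(M2, layer = "P"))
    expect_equal(K2[1, 2], K2[1, 1], tolerance = 1e-12)
    expect_equal(K2[1, 2], K2[2, 2], tolerance = 1e-12)

    ## 4x3 hand computation
    M3 <- matrix(c(1, 2, 0, -1,
                   0, 1, 1, 2,
                   2, 0, -1, 1), 4, 3,
                 dimnames = list(paste0("a", 1:4), paste0("f", 1:3)))
    K3 <- as.matrix(buildOmicsKernel(M3))
    for (i in 1:4) for (j in 1:4)
        expect_equal(K3[i, j], sum(M3[i, ] * M3[j, ]) / 3,
                     tolerance = 1e-12)

    expect_error(buildOmicsKernel(M3[, 0, drop = FALSE]), "zero features")
})

test_that("omics kernel equals the brute-force double loop on random instances", {
    set.seed(36)
    for (rep in 1:5) {
        n <- sample(5:50, 1)
        p <- sample(3:30, 1)
        M <- matrix(rnorm(n * p), n, p,
                    dimnames = list(sprintf("a%03d", 1:n), paste0("f", 1:p)))
        K <- as.matrix(buildOmicsKernel(M))
        ref <- matrix(0, n, n)
        for (i in 1:n) for (j in 1:n)
            ref[i, j] <- sum(M[i, ] * M[j, ]) / p
        expect_lt(max(abs(K - unname(ref))), 1e-10)
        expect_identical(K, t(K))      # exact symmetry
    }
})

test_that("kernel combination is the unweighted elementwise mean", {
    k1 <- randomKernel(8, "G", seed = 1)
    k2 <- randomKernel(8, "T", seed = 2)
    k3 <- randomKernel(8, "M", seed = 3)

    expect_identical(combineKernels(list(k1)), k1)
    expect_equal(as.matrix(combineKernels(list(k1, k1))), as.matrix(k1),
                 tolerance = 1e-15)

    C <- combineKernels(list(k1, k2))
    expect_equal(as.matrix(C), (as.matrix(k1) + as.matrix(k2)) / 2,
                 tolerance = 1e-15)
    expect_identical(layerName(C), "GT(mean)")

    ## direct n_K definition for three kernels, asserted entrywise
    C3 <- as.matrix(combineKernels(list(k1, k2, k3)))
    ref <- (as.matrix(k1) + as.matrix(k2) + as.matrix(k3)) / 3
    for (i in 1:8) expect_equal(C3[i, ], ref[i, ], tolerance = 1e-14)

    ## animal-order mismatch is an error, never silently realigned
    v <- as.matrix(k2)[8:1, 8:1]
    k2r <- RelationshipKernel(v, "T")
    expect_error(combineKernels(list(k1, k2r)), "animalOrderMismatch")
})

test_that("stabilizeKernel adds the minimal ridge and records it", {
    k <- randomKernel(6, seed = 4)
    expect_identical(ridgeApplied(stabilizeKernel(k, 1e-10)),
                     ridgeApplied(k))

    ## rank-deficient kernel gains a factorizable diagonal
    set.seed(37)
    M <- matrix(rnorm(10 * 3), 10, 3)
    v <- tcrossprod(M)                 # rank 3, singular
    dimnames(v) <- list(paste0("a", 1:10), paste0("a", 1:10))
    raw <- RelationshipKernel(v + diag(1e-12, 10), "K")
    expect_lt(min(eigen(as.matrix(raw), symmetric = TRUE,
                        only.values = TRUE)$values), 1e-8)
    st <- stabilizeKernel(raw, 1e-8)
    expect_silent(chol(as.matrix(st)))
    expect_gt(ridgeApplied(st), 0)
    minEig <- min(eigen(as.matrix(st), symmetric = TRUE,
                        only.values = TRUE)$values)
    expect_gte(minEig, 1e-8 - 1e-12)

    expect_error(stabilizeKernel(matrix(c(1, 2, 0, 1), 2)), "asymmetric")
})
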