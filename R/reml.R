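## Average-information REML for linear covariance structures
##   V(theta) = sum_k theta_k V_k + theta_e I
## with V_k an n x n PSD matrix per random term (omics kernels; pen and
## litter incidence cross-products).  AI steps with step-halving, an
## EM-type multiplicative fallback, and active-set pinning of components at
## zero.  Only accepted (likelihood-improving) iterates enter the trace, so
## the restricted log-likelihood is non-decreasing by construction.
##
## Per-iteration cost is one Cholesky + one inverse of V; traces tr(P V_k)
## are elementwise sums sum(P * V_k) and the AI matrix needs only
## matrix-vector products, so n around 1000 is comfortable.

## Restricted log-likelihood and derivative ingredients at theta.
.remlEval <- function(theta, y, X, covs) {
    n <- length(y)
    V <- diag(theta[length(theta)], n)
    for (k in seq_along(covs))
        V <- V + theta[k] * covs[[k]]
    ch <- tryCatch(chol(V), error = function(e) NULL)
    if (is.null(ch)) return(NULL)
    Vi <- chol2inv(ch)
    W <- Vi %*% X
    XtViX <- crossprod(X, W)
    cx <- tryCatch(chol(XtViX), error = function(e) NULL)
    if (is.null(cx)) return(NULL)
    XtViXi <- chol2inv(cx)
    P <- Vi - W %*% XtViXi %*% t(W)
    Py <- as.vector(P %*% y)
    ll <- -0.5 * (2 * sum(log(diag(ch))) + 2 * sum(log(diag(cx))) +
                  sum(y * Py))
    list(ll = ll, P = P, Py = Py, Vi = Vi, XtViXi = XtViXi, W = W)
}

## Core solver.  X must already be full rank.
.remlCore <- function(y, X, covs, init = NULL, tolLL = 1e-6, tolPar = 1e-4,
                      maxit = 200L) {
    n <- length(y)
    m <- length(covs) + 1L              # + residual
    termNames <- c(names(covs), "residual")

    ols <- stats::lm.fit(X, y)
    v0 <- sum(ols$residuals^2) / max(1L, n - ncol(X))
    if (v0 <= 0 || stats::var(y) == 0)
        stop("degenerateResponse: phenotype has zero residual variance")
    theta <- if (is.null(init)) rep(v0 / m, m) else init
    floorTheta <- 1e-8 * v0

    ev <- .remlEval(theta, y, X, covs)
    if (is.null(ev)) stop("initial variance structure is not positive definite")
    pinned <- rep(FALSE, m)
    trace <- ev$ll
    converged <- FALSE
    iter <- 0L

    quadTrace <- function(ev) {
        ## per term: q_k = V_k Py, yPVPy_k = Py' q_k, tr_k = sum(P * V_k)
        Q <- matrix(0, n, m)
        trP <- numeric(m)
        for (k in seq_along(covs)) {
            Q[, k] <- covs[[k]] %*% ev$Py
            trP[k] <- sum(ev$P * covs[[k]])
        }
        Q[, m] <- ev$Py
        trP[m] <- sum(diag(ev$P))
        list(Q = Q, trP = trP, yPVPy = as.vector(crossprod(Q, ev$Py)))
    }

    repeat {
        iter <- iter + 1L
        qt <- quadTrace(ev)
        score <- 0.5 * (qt$yPVPy - qt$trP)
        ## release pinned components pushed upward by the gradient
        pinned[pinned & score > 1e-8] <- FALSE
        free <- which(!pinned)

        proposals <- list()
        PQ <- ev$P %*% qt$Q[, free, drop = FALSE]
        AI <- 0.5 * crossprod(qt$Q[, free, drop = FALSE], PQ)
        delta <- tryCatch(solve(AI, score[free]), error = function(e) NULL)
        if (!is.null(delta) && all(is.finite(delta))) {
            step <- 1
            for (h in seq_len(12L)) {
                cand <- theta
                cand[free] <- pmax(theta[free] + step * delta, 0)
                proposals[[length(proposals) + 1L]] <- cand
                step <- step / 2
            }
        }
        ## EM-type multiplicative fallback (positive, fixed point at score=0)
        emTheta <- theta
        okEm <- free[qt$trP[free] > 0 & qt$yPVPy[free] >= 0]
        emTheta[okEm] <- theta[okEm] * qt$yPVPy[okEm] / qt$trP[okEm]
        step <- 1
        for (h in seq_len(6L)) {
            proposals[[length(proposals) + 1L]] <-
                theta + step * (emTheta - theta)
            step <- step / 2
        }

        accepted <- FALSE
        for (cand in proposals) {
            cand[length(cand)] <- max(cand[length(cand)], floorTheta)
            evNew <- .remlEval(cand, y, X, covs)
            if (is.null(evNew) || !is.finite(evNew$ll)) next
            if (evNew$ll > ev$ll - 1e-12) {
                dLL <- evNew$ll - ev$ll
                relPar <- max(abs(cand - theta) /
                              pmax(pmax(theta, cand), floorTheta))
                ## pin tiny components driven to the boundary
                pin <- cand < floorTheta & seq_len(m) < m
                cand[pin] <- 0
                pinned[pin] <- TRUE
                theta <- cand
                ev <- if (any(pin)) .remlEval(theta, y, X, covs) else evNew
                if (is.null(ev)) { ev <- evNew; theta[pin] <- floorTheta }
                trace <- c(trace, ev$ll)
                accepted <- TRUE
                if (dLL < tolLL && relPar < tolPar) converged <- TRUE
                break
            }
        }
        if (!accepted) {
            ## no improving direction left: at a (numerical) maximum
            converged <- TRUE
            break
        }
        if (converged || iter >= maxit) break
    }

    names(theta) <- termNames
    blup <- lapply(seq_along(covs), function(k)
        theta[k] * as.vector(covs[[k]] %*% ev$Py))
    names(blup) <- names(covs)
    blup$residual <- theta[m] * ev$Py
    bhat <- as.vector(ev$XtViXi %*% crossprod(ev$W, y))
    names(bhat) <- colnames(X)

    list(theta = theta, loglik = ev$ll, converged = converged,
         iterations = iter, trace = trace, blup = blup, fixed = bhat,
         Py = ev$Py, pinned = pinned)
}

## Drop aliased columns of X by pivoted QR; returns kept column indices.
.fullRankColumns <- function(X, tol = 1e-7) {
    qrX <- qr(X, tol = tol)
    sort(qrX$pivot[seq_len(qrX$rank)])
}

#' Fit the multi-kernel mixed model by REML
#'
#' Fits `y = X b + sum_k u_k + pen + litter + e` with
#' `u_k ~ N(0, K_k s2_k)`, pen and litter as i.i.d. random effects, and
#' `e ~ N(0, I s2_e)`, using average-information REML with EM fallback
#' steps and active-set constraints keeping every component non-negative.
#' When `spec@combined` is set, the kernels in `spec@kernelSet` are replaced
#' by their equal-weight mean and a single component `C` is fitted.
#' Non-convergence within `maxit` returns `converged = FALSE` rather than
#' an error, mirroring how such fits are reported (and then skipped) in
#' downstream tables.
#'
#' @param y numeric phenotype vector aligned to `design` rows (binary 0/1
#'   traits are fitted with the same linear model).
#' @param design cohort design table with at least the columns named in
#'   `spec@fixedTerms` plus `pen` and `litter` as required.
#' @param spec a [ModelSpec-class].
#' @param kernels named list of [RelationshipKernel-class] objects covering
#'   `spec@kernelSet`; animal order must equal `design$animal`.
#' @param init optional initial variance components (default: equal split
#'   of the fixed-effects-residual variance).
#' @param tolLL,tolPar,maxit convergence controls: change in restricted
#'   log-likelihood < `tolLL` and max relative component change < `tolPar`,
#'   at most `maxit` iterations.
#' @return A [VarCompFit-class].
#' @export
fitREML <- function(y, design, spec, kernels, init = NULL, tolLL = 1e-6,
                    tolPar = 1e-4, maxit = 200L) {
    stopifnot(is(spec, "ModelSpec"))
    validObject(spec)
    n <- nrow(design)
    stopifnot(length(y) == n)
    missingK <- setdiff(spec@kernelSet, names(kernels))
    if (length(missingK))
        stop("kernels missing for: ", paste(missingK, collapse = ", "))
    ids <- design$animal
    for (tag in spec@kernelSet)
        if (!identical(animalIds(kernels[[tag]]), ids))
            stop("kernel '", tag, "' animal order does not match the design")

    X <- .fixedDesign(design, spec@fixedTerms)
    keep <- .fullRankColumns(X)
    notes <- character()
    if (length(keep) < ncol(X)) {
        droppedCols <- colnames(X)[-keep]
        notes <- c(notes, paste0("aliased fixed columns dropped: ",
                                 paste(droppedCols, collapse = ", ")))
        X <- X[, keep, drop = FALSE]
    }

    covs <- list()
    if (isTRUE(spec@combined)) {
        covs[["C"]] <- as.matrix(combineKernels(kernels[spec@kernelSet]))
    } else {
        for (tag in spec@kernelSet)
            covs[[tag]] <- as.matrix(kernels[[tag]])
    }
    if (isTRUE(spec@includePen))
        covs[["pen"]] <- tcrossprod(stats::model.matrix(~ 0 + factor(design$pen)))
    if (isTRUE(spec@includeLitter))
        covs[["litter"]] <- tcrossprod(stats::model.matrix(~ 0 + factor(design$litter)))

    fit <- .remlCore(y, X, covs, init = init, tolLL = tolLL, tolPar = tolPar,
                     maxit = maxit)
    if (any(fit$pinned))
        notes <- c(notes, paste0("components pinned at zero: ",
                                 paste(names(fit$theta)[fit$pinned],
                                       collapse = ", ")))
    blup <- lapply(fit$blup, function(v) setNames(as.vector(v), ids))
    new("VarCompFit", sigma2 = fit$theta, loglik = fit$loglik,
        converged = fit$converged, nIterations = as.integer(fit$iterations),
        blup = blup, fixedEstimates = fit$fixed, spec = spec,
        n = as.integer(n), trace = fit$trace, notes = notes)
}
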