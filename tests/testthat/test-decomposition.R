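mkTable <- function(values, intact = NULL) {
    p <- genericParcellation(dim(values)[1])
    metrics <- c("lambda", "localEfficiency")
    dimnames(values) <- list(parcelLabels(p),
                             sprintf("s%d", seq_len(dim(values)[2])), metrics)
    if (is.null(intact))
        intact <- matrix(1, dim(values)[2], 2,
                         dimnames = list(dimnames(values)[[2]], metrics))
    new("NodeLesionTable", values = values, intact = intact,
        lesioned = seq_len(dim(values)[1]), metrics = metrics,
        parcellation = p, missingCount = sum(is.na(values)))
}

test_that("lesion correlation matrix equals element-wise Pearson correlations", {
    set.seed(90)
    values <- array(rnorm(5 * 8 * 2), dim = c(5, 8, 2))
    nlt <- mkTable(values)
    R <- lesionCorrelationMatrix(nlt, "lambda")
    expect_equal(dim(R), c(5, 5))
    expect_equal(unname(diag(R)), rep(1, 5))
    expect_identical(unname(R), unname(t(R)))
    for (i in 1:5) for (j in 1:5) {
        if (i == j) next
        expect_equal(unname(R[i, j]),
                     cor(values[i, , 1], values[j, , 1]), tolerance = 1e-12)
    }
    # identical effect vectors across parcels: R is all ones
    same <- array(rep(rnorm(8), each = 5), dim = c(5, 8, 2))
    Rsame <- lesionCorrelationMatrix(mkTable(same), "lambda")
    expect_equal(unname(Rsame), matrix(1, 5, 5), ignore_attr = TRUE)
    # a zero-variance lesion column flags its entries missing
    degen <- values
    degen[2, , 1] <- 3
    Rd <- lesionCorrelationMatrix(mkTable(degen), "lambda")
    expect_true(all(is.na(Rd[2, -2])))
    expect_equal(unname(Rd[2, 2]), 1)
})

test_that("PCA matches an independent eigendecomposition oracle up to sign", {
    set.seed(91)
    X <- matrix(rnorm(48), 8, 6)
    res <- pcaLoadings(X, nComponents = 6)
    # oracle: svd of the column-centered matrix
    Xc <- scale(X, center = TRUE, scale = FALSE)
    sv <- svd(Xc)
    varExp <- sv$d^2 / sum(sv$d^2)
    expect_equal(res@varianceFraction, varExp, tolerance = 1e-10)
    for (k in 1:6)
        expect_equal(abs(sum(res@loadings[, k] * sv$v[, k])), 1,
                     tolerance = 1e-8)
    # loadings are orthonormal, fractions nonincreasing and sum to 1
    expect_equal(crossprod(res@loadings), diag(6), tolerance = 1e-10,
                 ignore_attr = TRUE)
    expect_true(all(diff(res@varianceFraction) <= 1e-12))
    expect_equal(sum(res@varianceFraction), 1, tolerance = 1e-10)
    # sign convention: largest-magnitude entry of each column positive
    for (k in 1:6)
        expect_gt(res@loadings[which.max(abs(res@loadings[, k])), k], 0)
})

test_that("PCA handles rank-1, isotropic and rank-deficient inputs", {
    u <- c(1, 2, 3, 4); v <- c(2, -1, 0.5, 1)
    rank1 <- outer(u, v)
    res <- pcaLoadings(rank1, nComponents = 1)
    expect_equal(res@varianceFraction[1], 1, tolerance = 1e-12)
    # isotropic covariance: equal variance fractions
    set.seed(92)
    Z <- matrix(rnorm(4000), 1000, 4)
    resI <- pcaLoadings(Z, nComponents = 4)
    expect_true(all(abs(resI@varianceFraction - 0.25) < 0.05))
    # asking beyond the rank truncates with a warning
    expect_warning(pcaLoadings(rank1, nComponents = 3), "truncating")
})

test_that("intact-metric PCA composes metric, correlation and PCA", {
    co <- Cohort(lapply(1:6, function(n) {
        con <- normalizeConnectome(randomConnectome(7, p = 0.6, seed = 900 + n))
        con@subjectID <- sprintf("s%d", n)
        con
    }))
    res <- intactMetricPCA(co, "betweenness", nComponents = 2)
    expect_equal(nrow(res@loadings), 7)      # all parcels cortical here
    vals <- sapply(connectomes(co), function(x) betweennessCentrality(x))
    R <- suppressWarnings(cor(t(vals)))
    R[!is.finite(R)] <- 0; diag(R) <- 1
    ref <- pcaLoadings(R, 2, metric = "betweenness")
    expect_equal(res@loadings, ref@loadings)
    expect_equal(res@varianceFraction, ref@varianceFraction)
    # identical subjects are degenerate
    co2 <- Cohort(lapply(1:3, function(n) {
        con <- randomConnectome(6, p = 0.7, seed = 1)
        con@subjectID <- sprintf("s%d", n)
        con
    }))
    expect_error(intactMetricPCA(co2, "betweenness"), "zero variance")
})

test_that("lesion-vs-intact comparison is the plain Pearson correlation", {
    set.seed(93)
    L <- new("PCAResult", loadings = .colOrtho <- qr.Q(qr(matrix(rnorm(30), 10, 3))),
             varianceFraction = c(0.5, 0.3, 0.2), metric = "lambda")
    I1 <- new("PCAResult", loadings = qr.Q(qr(matrix(rnorm(30), 10, 3))),
              varianceFraction = c(0.6, 0.3, 0.1), metric = "betweenness")
    cmp <- compareLesionVsIntact(L, list(I1))
    expect_equal(nrow(cmp), 9)
    for (r in seq_len(nrow(cmp)))
        expect_equal(cmp$r[r], cor(L@loadings[, cmp$lesion_pc[r]],
                                   I1@loadings[, cmp$intact_pc[r]]),
                     tolerance = 1e-12)
    expect_equal(attr(cmp, "maxAbs"), max(abs(cmp$r)))
    # identical loadings give r = 1; orthogonal loadings give r ~ 0
    Lid <- new("PCAResult", loadings = cbind(c(1, 2, 3, 4) - 2.5),
               varianceFraction = 1, metric = "x")
    expect_equal(compareLesionVsIntact(Lid, list(Lid))$r, 1)
    A <- cbind(c(1, -1, 1, -1) / 2)
    B <- cbind(c(1, 1, -1, -1) / 2)
    expect_equal(compareLesionVsIntact(
        new("PCAResult", loadings = A, varianceFraction = 1, metric = "a"),
        list(new("PCAResult", loadings = B, varianceFraction = 1,
                 metric = "b")))$r, 0)
    # mismatched parcel sets are an error
    expect_error(compareLesionVsIntact(L, list(Lid)), "parcel sets")
})

test_that("edge-effect tensor is symmetric and matches brute-force entries", {
    co <- Cohort(lapply(1:5, function(n) {
        con <- normalizeConnectome(randomConnectome(6, p = 0.7, seed = 950 + n))
        con@subjectID <- sprintf("s%d", n)
        con
    }))
    C <- edgeEffectTensor(co, "eccentricity")
    expect_equal(dim(C), c(6, 6, 6))
    # symmetry in the first two modes
    for (k in 1:6) expect_equal(C[, , k], t(C[, , k]))
    # brute-force a few entries
    ecc <- function(w) nodeEccentricity(distanceMatrix(w))
    lam <- function(w) as.numeric(characteristicPathLength(distanceMatrix(w)))
    for (pair in list(c(1, 2), c(2, 5), c(3, 6))) {
        i <- pair[1]; j <- pair[2]
        dn <- matrix(0, 6, 5); dl <- numeric(5)
        for (n in 1:5) {
            w <- weights(co[[n]])
            if (w[i, j] == 0) next
            wl <- w; wl[i, j] <- wl[j, i] <- 0
            dn[, n] <- ecc(wl) - ecc(w)
            dl[n] <- lam(wl) - lam(w)
        }
        if (sd(dl) > 0) {
            for (k in 1:6) {
                expected <- suppressWarnings(cor(dn[k, ], dl))
                if (is.finite(expected))
                    expect_equal(C[i, j, k], expected, tolerance = 1e-12)
                else expect_true(is.na(C[i, j, k]))
            }
        }
    }
    # removing an edge in a tree far from k'' leaves eccentricity unchanged
    w <- matrix(0, 5, 5)
    w[1, 2] <- w[2, 1] <- 1; w[2, 3] <- w[3, 2] <- 1
    w[3, 4] <- w[4, 3] <- 1; w[4, 5] <- w[5, 4] <- 1
    con <- Connectome(w, genericParcellation(5))
    e0 <- ecc(w)
    wl <- w; wl[4, 5] <- wl[5, 4] <- 0
    # node 1's eccentricity to the surviving component only grows via
    # disconnection handling; removing a leaf edge not on 1's longest path
    # in the truncated component leaves finite eccentricities of 1..4 intact
    expect_equal(nodeEccentricity(distanceMatrix(wl))[1:3],
                 c(3, 2, 2), ignore_attr = TRUE)
})

test_that("MPCA recovers rank-1 structure exactly and improves on HOSVD", {
    a <- c(1, 2, -1, 0.5); b <- c(2, 1, 1, -1); cc <- c(1, -2, 3, 0.5)
    C <- array(0, dim = c(4, 4, 4))
    for (k in 1:4) C[, , k] <- outer(a, b) * cc[k]
    res <- mpca(C, c(1, 1))
    expect_equal(res@capturedVariation, 1, tolerance = 1e-10)
    expect_true(res@converged)
    # loadings proportional to the generating vector
    expect_equal(abs(cor(res@mpc1Loadings, a)), 1, tolerance = 1e-10)

    set.seed(94)
    for (s in 1:5) {
        C <- array(rnorm(125), dim = c(5, 5, 5))
        res <- mpca(C, c(1, 1))
        # alternating refinement never does worse than its HOSVD initializer
        expect_gte(res@capturedVariation, hosvdCaptured(C, c(1, 1)) - 1e-10)
        # captured variation is nondecreasing across iterations
        expect_true(all(diff(res@variationTrace) >= -1e-10))
        # monotone in the number of components
        res2 <- mpca(C, c(2, 2))
        expect_gte(res2@capturedVariation, res@capturedVariation - 1e-10)
        # projections orthonormal
        expect_equal(crossprod(res2@projections$mode1), diag(2),
                     tolerance = 1e-10, ignore_attr = TRUE)
    }
    # missing entries are imputed and counted
    C[1, 2, 3] <- NA
    expect_equal(mpca(C)@imputedCount, 1L)
})

test_that("decompositions are invariant under subject reordering", {
    set.seed(95)
    values <- array(rnorm(5 * 7 * 2), dim = c(5, 7, 2))
    nlt1 <- mkTable(values)
    nlt2 <- mkTable(values[, 7:1, ])
    expect_equal(unname(lesionCorrelationMatrix(nlt1)),
                 unname(lesionCorrelationMatrix(nlt2)), tolerance = 1e-12)
})
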