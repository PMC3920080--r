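test_that("distances follow the inverse-weight rule on toy graphs", {
    # path A-B-C with unit weights: d(A,C) = 2
    w <- matrix(0, 3, 3)
    w[1, 2] <- w[2, 1] <- 1; w[2, 3] <- w[3, 2] <- 1
    d <- distanceMatrix(w)
    expect_equal(d[1, 3], 2)

    # strong relay beats a weak direct edge: lengths 0.5 + 0.5 < 4
    w2 <- matrix(0, 3, 3)
    w2[1, 2] <- w2[2, 1] <- 2
    w2[2, 3] <- w2[3, 2] <- 2
    w2[1, 3] <- w2[3, 1] <- 0.25
    d2 <- distanceMatrix(w2)
    expect_equal(d2[1, 3], 1.0)

    # edgeless graph: all off-diagonal infinite
    d0 <- distanceMatrix(matrix(0, 4, 4))
    expect_true(all(is.infinite(d0[upper.tri(d0)])))
    expect_equal(diag(d0), rep(0, 4))
})

test_that("distances equal exhaustive simple-path enumeration on random graphs", {
    for (s in 1:8) {
        w <- randomWeights(7, p = 0.45, seed = 100 + s)
        expect_equal(unname(distanceMatrix(w)), enumDistances(w),
                     tolerance = 1e-12)
    }
})

test_that("characteristic path length follows the finite-pairs convention", {
    # 4-cycle, unit weights: distances per node are 1, 1, 2
    w <- matrix(0, 4, 4)
    for (i in 1:4) { j <- i %% 4 + 1; w[i, j] <- w[j, i] <- 1 }
    expect_equal(as.numeric(characteristicPathLength(distanceMatrix(w))), 4 / 3)

    # complete K4
    k4 <- matrix(1, 4, 4); diag(k4) <- 0
    expect_equal(as.numeric(characteristicPathLength(distanceMatrix(k4))), 1)

    # two disconnected unit edges: finite pairs only, flagged
    w2 <- matrix(0, 4, 4)
    w2[1, 2] <- w2[2, 1] <- 1; w2[3, 4] <- w2[4, 3] <- 1
    lam <- characteristicPathLength(distanceMatrix(w2))
    expect_equal(as.numeric(lam), 1)
    expect_true(attr(lam, "disconnected"))

    # fully disconnected: explicit error
    expect_error(characteristicPathLength(distanceMatrix(matrix(0, 3, 3))),
                 "no finite")
})

test_that("local efficiency matches its definition on canonical graphs", {
    tri <- matrix(1, 3, 3); diag(tri) <- 0
    expect_equal(unname(localEfficiency(tri)), rep(1, 3))
    star <- matrix(0, 4, 4)
    star[1, 2:4] <- star[2:4, 1] <- 1
    expect_equal(unname(localEfficiency(star)), rep(0, 4))
    for (s in 1:6) {
        w <- randomWeights(8, p = 0.5, seed = 200 + s)
        expect_equal(unname(localEfficiency(w)), oracleLocalEff(w),
                     tolerance = 1e-12)
    }
})

test_that("assortativity equals Newman's closed form and flags degeneracy", {
    star <- matrix(0, 4, 4)
    star[1, 2:4] <- star[2:4, 1] <- 1
    expect_equal(degreeAssortativity(star), -1)
    # 6-cycle: all endpoint degrees equal -> typed undefined, not NaN
    cyc <- matrix(0, 6, 6)
    for (i in 1:6) { j <- i %% 6 + 1; cyc[i, j] <- cyc[j, i] <- 1 }
    expect_true(isUndefined(degreeAssortativity(cyc)))
    for (s in 1:6) {
        w <- randomWeights(10, p = 0.35, seed = 300 + s)
        a <- degreeAssortativity(w)
        if (!isUndefined(a))
            expect_equal(a, oracleAssortativity(w), tolerance = 1e-12)
    }
})

test_that("transitivity, clustering, density and distance summaries match brute force", {
    tri <- matrix(1, 3, 3); diag(tri) <- 0
    expect_equal(graphTransitivity(tri), 1)
    star <- matrix(0, 4, 4)
    star[1, 2:4] <- star[2:4, 1] <- 1
    expect_equal(graphTransitivity(star), 0)
    expect_true(isUndefined(graphTransitivity(matrix(0, 3, 3))))

    k4 <- matrix(1, 4, 4); diag(k4) <- 0
    expect_equal(edgeDensity(k4), 1)

    # path P3: diameter 2, radius 1, middle betweenness 1 (unnormalized)
    p3 <- matrix(0, 3, 3)
    p3[1, 2] <- p3[2, 1] <- 1; p3[2, 3] <- p3[3, 2] <- 1
    d <- distanceMatrix(p3)
    expect_equal(as.numeric(graphDiameter(d)), 2)
    expect_equal(as.numeric(graphRadius(d)), 1)
    expect_equal(unname(betweennessCentrality(p3)), c(0, 1, 0))

    for (s in 1:6) {
        w <- randomWeights(9, p = 0.45, seed = 400 + s)
        d <- distanceMatrix(w)
        expect_equal(graphTransitivity(w), oracleTransitivity(w),
                     tolerance = 1e-12)
        expect_equal(unname(clusteringCoefficient(w)), oracleClustering(w),
                     tolerance = 1e-12)
        fwd <- fwDistances(w)
        expect_equal(unname(d), fwd, tolerance = 1e-12)
        eccOracle <- sapply(seq_len(9), function(i) {
            r <- fwd[i, -i]
            if (any(is.finite(r))) max(r[is.finite(r)]) else NA_real_
        })
        expect_equal(unname(nodeEccentricity(d)), eccOracle,
                     tolerance = 1e-12)
        expect_equal(unname(betweennessCentrality(w)), oracleBetweenness(w),
                     tolerance = 1e-9)
    }
})

test_that("metrics are invariant under node permutation", {
    w <- randomWeights(9, p = 0.5, seed = 77)
    set.seed(7)
    perm <- sample(9)
    wp <- w[perm, perm]
    expect_equal(as.numeric(characteristicPathLength(distanceMatrix(wp))),
                 as.numeric(characteristicPathLength(distanceMatrix(w))))
    expect_equal(sort(localEfficiency(wp)), sort(localEfficiency(w)),
                 tolerance = 1e-12)
    expect_equal(degreeAssortativity(wp), degreeAssortativity(w),
                 tolerance = 1e-12)
    expect_equal(graphTransitivity(wp), graphTransitivity(w),
                 tolerance = 1e-12)
    expect_equal(edgeDensity(wp), edgeDensity(w))
})

test_that("feature vector is the composition of its four metrics", {
    k5 <- matrix(1, 5, 5); diag(k5) <- 0
    fv <- featureVector(k5)
    expect_equal(length(fv), 4)
    expect_true(is.na(fv["assortativity"]))       # regular graph
    expect_equal(attr(fv, "undefined"), "assortativity")
    expect_equal(unname(fv["lambda"]), 1)
    expect_equal(unname(fv["density"]), 1)
    expect_equal(unname(fv["transitivity"]), 1)

    w <- randomWeights(10, p = 0.4, seed = 55)
    fv <- featureVector(w)
    expect_equal(unname(fv["assortativity"]), as.numeric(degreeAssortativity(w)))
    expect_equal(unname(fv["lambda"]),
                 as.numeric(characteristicPathLength(distanceMatrix(w))))
    expect_equal(unname(fv["density"]), edgeDensity(w))
    expect_equal(unname(fv["transitivity"]), as.numeric(graphTransitivity(w)))
})

test_that("connectome methods agree with matrix methods", {
    con <- randomConnectome(8, p = 0.5, seed = 5)
    expect_equal(featureVector(con), featureVector(weights(con)))
    expect_equal(localEfficiency(con), localEfficiency(weights(con)))
    expect_equal(nodeDegree(con), rowSums(weights(con) > 0))
})
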