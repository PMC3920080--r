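test_that("Bonferroni thresholds reproduce the edge-test constants", {
    expect_equal(bonferroniThreshold(0.05, 13530), 3.7e-6, tolerance = 0.005)
    expect_equal(bonferroniThreshold(0.0001, 13530), 7.4e-9, tolerance = 0.005)
    expect_equal(bonferroniThreshold(0.05, 1), 0.05)
    expect_error(bonferroniThreshold(0.05, 0), "at least 1")
})

mkNodeTable <- function(values, intact, metrics = c("lambda", "localEfficiency")) {
    # values: lesions x subjects x metrics
    p <- genericParcellation(dim(values)[1])
    dimnames(values) <- list(parcelLabels(p),
                             sprintf("s%d", seq_len(dim(values)[2])), metrics)
    dimnames(intact) <- list(sprintf("s%d", seq_len(nrow(intact))), metrics)
    new("NodeLesionTable", values = values, intact = intact,
        lesioned = seq_len(dim(values)[1]), metrics = metrics,
        parcellation = p, missingCount = sum(is.na(values)))
}

test_that("paired node t tests match the textbook formula and flag degeneracy", {
    set.seed(42)
    nles <- 4; N <- 10
    values <- array(rnorm(nles * N * 2, mean = 2), dim = c(nles, N, 2))
    intact <- matrix(rnorm(N * 2, mean = 2), N, 2)
    # lesion 1, metric 1: identical to intact -> t = 0, p = 1
    values[1, , 1] <- intact[, 1]
    # lesion 2, metric 1: constant shift -> zero-variance degenerate
    values[2, , 1] <- intact[, 1] + 0.5
    nlt <- mkNodeTable(values, intact)
    res <- pairedTNode(nlt, alpha = 0.05)
    expect_equal(attr(res, "m"), 8)

    r11 <- res[res$parcel == "n001" & res$metric == "lambda", ]
    expect_equal(r11$t, 0)
    expect_equal(r11$p, 1)
    r21 <- res[res$parcel == "n002" & res$metric == "lambda", ]
    expect_true(r21$degenerate)
    expect_true(is.na(r21$p))

    # the rest match mean/sd/sqrt(N) and the t distribution directly
    for (k in 3:4) for (m in 1:2) {
        d <- intact[, m] - values[k, , m]
        tExp <- mean(d) / (sd(d) / sqrt(N))
        pExp <- 2 * pt(-abs(tExp), N - 1)
        row <- res[res$parcel == sprintf("n%03d", k) &
                   res$metric == c("lambda", "localEfficiency")[m], ]
        expect_equal(row$t, tExp, tolerance = 1e-12)
        expect_equal(row$p, pExp, tolerance = 1e-12)
        expect_equal(row$mean_healthy, mean(intact[, m]))
        expect_equal(row$sd_lesioned, sd(values[k, , m]))
        # cross-check against stats::t.test
        tt <- t.test(intact[, m], values[k, , m], paired = TRUE)
        expect_equal(row$t, unname(tt$statistic), tolerance = 1e-12)
        expect_equal(row$p, tt$p.value, tolerance = 1e-12)
    }
})

test_that("paired Hotelling test matches an independent implementation", {
    # all-zero differences
    X <- matrix(rnorm(40), 10, 4)
    z <- hotellingPaired(X, X)
    expect_equal(z$T2, 0)
    expect_equal(z$F, 0)
    expect_equal(z$p, 1)

    # N = 12, p = 4 random paired data vs mahalanobis-based closed form
    for (s in 1:10) {
        set.seed(600 + s)
        intact <- matrix(rnorm(48), 12, 4)
        lesioned <- intact + matrix(rnorm(48, sd = 0.7), 12, 4)
        got <- hotellingPaired(lesioned, intact)
        exp <- oracleHotelling(lesioned, intact)
        expect_equal(got$T2, exp$T2, tolerance = 1e-10)
        expect_equal(got$F, exp$F, tolerance = 1e-10)
        expect_equal(got$p, exp$p, tolerance = 1e-10)
        expect_false(got$rankDeficient)
        expect_equal(got$pDim, 4L)
    }
    expect_error(hotellingPaired(matrix(rnorm(8), 2, 4),
                                 matrix(rnorm(8), 2, 4)), "N >")
})

test_that("with p = 1 the Hotelling F equals the squared paired t", {
    for (s in 1:100) {
        set.seed(700 + s)
        N <- sample(5:20, 1)
        intact <- matrix(rnorm(N), N, 1)
        lesioned <- intact + matrix(rnorm(N, mean = 0.3), N, 1)
        got <- hotellingPaired(lesioned, intact)
        d <- lesioned - intact
        tstat <- mean(d) / (sd(d) / sqrt(N))
        expect_equal(got$F, tstat^2, tolerance = 1e-10)
        expect_equal(got$T2, tstat^2, tolerance = 1e-10)
    }
})

test_that("Hotelling T2 is invariant under affine rescaling of a feature", {
    set.seed(81)
    intact <- matrix(rnorm(60), 15, 4)
    lesioned <- intact + matrix(rnorm(60, sd = 0.5), 15, 4)
    base <- hotellingPaired(lesioned, intact)
    for (scale in c(10, 1e-4)) {
        li <- intact; ll <- lesioned
        li[, 2] <- li[, 2] * scale + 7
        ll[, 2] <- ll[, 2] * scale + 7
        got <- hotellingPaired(ll, li)
        expect_equal(got$T2, base$T2, tolerance = 1e-8)
    }
})

test_that("singular covariance falls back to pseudoinverse with reduced rank", {
    set.seed(5)
    intact <- matrix(rnorm(40), 10, 4)
    lesioned <- intact
    lesioned[, 1] <- intact[, 1] + rnorm(10, mean = 1)   # only one component moves
    lesioned[, 2] <- intact[, 2] + 0.25                  # constant shift: no variance
    got <- hotellingPaired(lesioned, intact)
    expect_true(got$rankDeficient)
    expect_lt(got$pDim, 4)
})

test_that("edge significance uses m = G(G-1)/2 and reports non-testable pairs", {
    co <- Cohort(lapply(1:8, function(n) {
        con <- normalizeConnectome(randomConnectome(7, p = 0.6, seed = 800 + n))
        con@subjectID <- sprintf("s%d", n)
        con
    }))
    elt <- edgeLesionSweep(co)
    res <- edgeSignificance(elt, alpha = 0.05)
    expect_equal(attr(res, "m"), 21)
    expect_equal(nrow(res), 21)
    # a pair absent in every subject is non-testable and never significant
    absent <- which(elt@edgePresence == 0)
    if (length(absent) > 0) {
        expect_false(any(res$testable[absent]))
        expect_false(any(res$significant[absent]))
        expect_equal(res$T2[absent], rep(0, length(absent)))
        expect_equal(res$p[absent], rep(1, length(absent)))
    }
    # pairs with too few affected subjects are also non-testable
    few <- which(elt@edgePresence > 0 & elt@edgePresence < 6)
    if (length(few) > 0) expect_false(any(res$testable[few]))
})

test_that("a strongly planted bridge attains the maximum F", {
    planted <- matrix(c(3, 13), ncol = 2)
    spec <- cohortSpec(G = 20, nSubjects = 40, nModules = 2,
                       pWithin = 0.9, pBetween = 0, weightLogSD = 0.25,
                       subjectNoiseSD = 1.0, plantedEdges = planted,
                       plantedBoost = 5, seed = 41)
    co <- generateCohort(spec)
    elt <- edgeLesionSweep(co)
    res <- edgeSignificance(elt, alpha = 0.05)
    best <- res[which.max(res$F), ]
    expect_equal(c(best$i, best$j), c(3, 13))
})

test_that("scaffold extraction ranks by F and nests across alpha levels", {
    spec <- recoverySpec(seed = 3)
    co <- generateCohort(spec)
    elt <- edgeLesionSweep(co)
    res <- edgeSignificance(elt, alpha = 0.05)
    lenient <- extractScaffold(res, 0.05)
    stringent <- extractScaffold(res, 0.0001)
    expect_true(all(diff(lenient$F) <= 0))
    keyL <- paste(lenient$i, lenient$j)
    keyS <- paste(stringent$i, stringent$j)
    expect_true(all(keyS %in% keyL))
    # shrinking alpha never adds edges
    expect_lte(nrow(stringent), nrow(lenient))
    # an impossible alpha empties the scaffold
    none <- extractScaffold(res, 1e-300)
    expect_equal(nrow(none), 0)
})
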