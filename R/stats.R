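#' Bonferroni-corrected significance threshold
#'
#' @param alpha family-wise significance level in (0, 1).
#' @param mComparisons number of comparisons (for edge tests,
#'   m = G(G-1)/2).
#' @return the per-comparison threshold alpha / m.
#' @examples
#' bonferroniThreshold(0.05, 13530)    # ~3.7e-06
#' bonferroniThreshold(0.0001, 13530)  # ~7.4e-09
#' @export
bonferroniThreshold <- function(alpha, mComparisons) {
    stopifnot(alpha > 0, alpha < 1)
    if (mComparisons < 1) stop("mComparisons must be at least 1")
    alpha / mComparisons
}

#' Paired t tests for node removals
#'
#' For each lesioned cortical parcel and each metric (characteristic path
#' length and mean local efficiency), tests whether the across-subject
#' distribution of the lesioned-network metric differs from the intact one
#' with a two-sided paired t test on healthy-minus-lesioned differences.
#' Reports the healthy and lesioned means and standard deviations, the t
#' score per parcel (the quantity mapped over the cortex in reports), and
#' Bonferroni-corrected significance. The comparison family defaults to
#' (number of lesioned parcels) x (number of metrics), each (parcel, metric)
#' pair being one hypothesis.
#'
#' Degenerate cases are flagged, not crashed: all-zero differences give
#' t = 0, p = 1; a constant nonzero difference (zero variance) is reported
#' as `degenerate` with NA statistics; subjects with a missing lesioned
#' value are dropped pairwise and counted in `nMissing`.
#'
#' @param nlt a [NodeLesionTable-class] from [nodeLesionSweep()].
#' @param alpha family-wise significance level (default 0.05).
#' @param mComparisons Bonferroni family size; default
#'   `nLesions * nMetrics`.
#' @return data.frame, one row per (parcel, metric): `parcel`, `metric`,
#'   `mean_healthy`, `sd_healthy`, `mean_lesioned`, `sd_lesioned`, `t`, `p`,
#'   `significant`, `degenerate`, `nMissing`. Attributes `alpha`, `m`, `N`.
#' @export
pairedTNode <- function(nlt, alpha = 0.05, mComparisons = NULL) {
    stopifnot(is(nlt, "NodeLesionTable"))
    nles <- dim(nlt@values)[1]
    nm <- length(nlt@metrics)
    if (is.null(mComparisons)) mComparisons <- nles * nm
    thr <- bonferroniThreshold(alpha, mComparisons)
    rows <- vector("list", nles * nm)
    r <- 0L
    for (m in seq_len(nm)) {
        h <- nlt@intact[, m]
        for (k in seq_len(nles)) {
            x <- nlt@values[k, , m]
            ok <- !is.na(x) & !is.na(h)
            d <- h[ok] - x[ok]
            N <- sum(ok)
            tstat <- p <- NA_real_
            degenerate <- FALSE
            if (N >= 3) {
                if (all(d == 0)) {
                    tstat <- 0; p <- 1
                } else if (stats::sd(d) == 0) {
                    degenerate <- TRUE
                } else {
                    tstat <- mean(d) / (stats::sd(d) / sqrt(N))
                    p <- 2 * stats::pt(-abs(tstat), df = N - 1)
                }
            } else degenerate <- TRUE
            r <- r + 1L
            rows[[r]] <- data.frame(
                parcel = dimnames(nlt@values)[[1]][k],
                metric = nlt@metrics[m],
                mean_healthy = mean(h[ok]), sd_healthy = stats::sd(h[ok]),
                mean_lesioned = mean(x[ok]), sd_lesioned = stats::sd(x[ok]),
                t = tstat, p = p,
                significant = !is.na(p) && p < thr,
                degenerate = degenerate, nMissing = sum(!ok),
                stringsAsFactors = FALSE)
        }
    }
    out <- do.call(rbind, rows)
    attr(out, "alpha") <- alpha
    attr(out, "m") <- mComparisons
    attr(out, "N") <- dim(nlt@values)[2]
    out
}

#' Paired Hotelling T-squared test
#'
#' The multivariate generalization of the paired t test: given N paired
#' p-dimensional observations, forms the differences D = lesioned - intact,
#' computes T2 = N * dbar' S^-1 dbar (dbar the mean difference, S the sample
#' covariance of D with divisor N-1), converts it to
#' F = (N - p) T2 / [p (N - 1)], and takes the upper tail probability of
#' F_{p, N-p}. Two-sided by construction.
#'
#' A singular S is handled with the Moore-Penrose pseudoinverse, using the
#' effective rank of S as p in the F conversion and flagging the result
#' (`rankDeficient`); difference components with no variance at all are
#' thereby ignored. All-zero differences give T2 = 0, F = 0, p = 1. Rows
#' containing NA are dropped pairwise (`nDropped`); N must stay above the
#' effective p.
#'
#' @param lesioned,intact N x p numeric matrices, rows paired by subject.
#' @return list with `T2`, `F`, `p`, `pDim` (effective rank used), `N`,
#'   `rankDeficient`, `nDropped`.
#' @examples
#' set.seed(1)
#' intact <- matrix(rnorm(40), 10, 4)
#' lesioned <- intact + matrix(rnorm(40, sd = 0.1), 10, 4)
#' hotellingPaired(lesioned, intact)$p
#' @export
hotellingPaired <- function(lesioned, intact) {
    lesioned <- as.matrix(lesioned)
    intact <- as.matrix(intact)
    stopifnot(identical(dim(lesioned), dim(intact)))
    D <- lesioned - intact
    ok <- stats::complete.cases(D)
    nDropped <- sum(!ok)
    D <- D[ok, , drop = FALSE]
    N <- nrow(D)
    p <- ncol(D)
    if (N < 2) stop("need at least two complete paired observations")
    if (N <= p)
        stop("need N > p: more paired observations than feature dimensions")
    if (all(D == 0))
        return(list(T2 = 0, F = 0, p = 1, pDim = 0L, N = N,
                    rankDeficient = FALSE, nDropped = nDropped))
    dbar <- colMeans(D)
    S <- stats::cov(D)
    ev <- eigen(S, symmetric = TRUE, only.values = TRUE)$values
    tol <- max(ev) * p * .Machine$double.eps
    rank <- sum(ev > tol)
    rankDeficient <- rank < p
    if (rank == 0)
        stop("difference covariance has rank zero with nonzero mean; ",
             "constant nonzero differences are untestable")
    if (N <= rank)
        stop("need N > effective dimension p for the F conversion")
    Sinv <- if (rankDeficient) MASS::ginv(S) else solve(S)
    T2 <- as.numeric(N * crossprod(dbar, Sinv %*% dbar))
    pe <- rank
    Fstat <- (N - pe) * T2 / (pe * (N - 1))
    pval <- stats::pf(Fstat, pe, N - pe, lower.tail = FALSE)
    list(T2 = T2, F = Fstat, p = pval, pDim = as.integer(pe), N = N,
         rankDeficient = rankDeficient, nDropped = nDropped)
}

#' Edge-removal significance tests
#'
#' Runs the paired Hotelling test of [hotellingPaired()] for every unordered
#' parcel pair of an edge-lesion sweep, testing whether removing that
#' connection shifts the global feature vector across subjects. The
#' Bonferroni family is always m = G(G-1)/2 — every possible connection,
#' present or not. Pairs whose difference vectors are all-zero in every
#' subject (the edge exists nowhere in the cohort), or with fewer than
#' p + 2 subjects showing a nonzero difference vector, are reported
#' non-testable: T2 = 0, p = 1, never significant.
#'
#' @param elt an [EdgeLesionTable-class] from [edgeLesionSweep()].
#' @param alpha family-wise significance level (default 0.05).
#' @return data.frame, one row per pair: `i`, `j`, `label_a`, `label_b`,
#'   `T2`, `F`, `p`, `pDim`, `nNonzero`, `testable`, `rankDeficient`,
#'   `significant`. Attributes `alpha`, `m`, `N`, `G`.
#' @export
edgeSignificance <- function(elt, alpha = 0.05) {
    stopifnot(is(elt, "EdgeLesionTable"))
    G <- nParcels(elt@parcellation)
    m <- G * (G - 1) / 2
    thr <- bonferroniThreshold(alpha, m)
    labels <- parcelLabels(elt@parcellation)
    nPairs <- nrow(elt@pairs)
    N <- dim(elt@values)[2]
    pDimNominal <- dim(elt@values)[3]
    out <- data.frame(
        i = elt@pairs[, 1], j = elt@pairs[, 2],
        label_a = labels[elt@pairs[, 1]], label_b = labels[elt@pairs[, 2]],
        T2 = 0, F = 0, p = 1, pDim = 0L, nNonzero = 0L,
        testable = FALSE, rankDeficient = FALSE, significant = FALSE,
        stringsAsFactors = FALSE)
    for (q in seq_len(nPairs)) {
        L <- elt@values[q, , , drop = TRUE]
        if (N == 1) L <- matrix(L, nrow = 1)
        D <- L - elt@intact
        nz <- rowSums(D != 0, na.rm = TRUE) > 0
        out$nNonzero[q] <- sum(nz)
        if (sum(nz) < pDimNominal + 2) next
        res <- tryCatch(hotellingPaired(L, elt@intact), error = function(e) NULL)
        if (is.null(res)) next
        out$T2[q] <- res$T2
        out$F[q] <- res$F
        out$p[q] <- res$p
        out$pDim[q] <- res$pDim
        out$testable[q] <- TRUE
        out$rankDeficient[q] <- res$rankDeficient
        out$significant[q] <- res$p < thr
    }
    attr(out, "alpha") <- alpha
    attr(out, "m") <- m
    attr(out, "N") <- N
    attr(out, "G") <- G
    out
}

#' Extract the core scaffold of significant edges
#'
#' The core scaffold is the set of connections whose individual removal
#' produces a Bonferroni-significant change in the global feature vector:
#' edges with p < alpha / m, ranked by descending F so the strongest core
#' connections (largest F) come first. Two conventional levels: alpha = 0.05
#' for the full scaffold, alpha = 0.0001 for the stringent core.
#'
#' @param edgeResults data.frame from [edgeSignificance()].
#' @param alpha family-wise level; defaults to the level the tests were run
#'   at. Shrinking alpha can only remove edges (nested rejection regions).
#' @return data.frame of scaffold edges sorted by decreasing F, with the
#'   pair labels and statistics.
#' @export
extractScaffold <- function(edgeResults, alpha = attr(edgeResults, "alpha")) {
    m <- attr(edgeResults, "m")
    if (is.null(m)) stop("edgeResults must come from edgeSignificance()")
    thr <- bonferroniThreshold(alpha, m)
    sel <- edgeResults$testable & edgeResults$p < thr
    out <- edgeResults[sel, , drop = FALSE]
    out <- out[order(-out$F), , drop = FALSE]
    rownames(out) <- NULL
    attr(out, "alpha") <- alpha
    attr(out, "m") <- m
    out
}
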