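## Spatial decomposition of lesion effects: the across-subject lesion-effect
## correlation matrix R and its PCA; PCA of intact nodal metrics for the
## lesioned-vs-intact comparison; the rank-3 edge-effect tensor and its
## multilinear PCA (alternating partial projections).

#' Lesion-effect correlation matrix R
#'
#' Entry R[i, j] is the Pearson correlation, across subjects, between a
#' global network measure computed after removing parcel i and the same
#' measure after removing parcel j (post-lesion values, not differences).
#' Rows/columns follow the parcellation's ordering convention
#' (right-hemisphere parcels first, antero-posterior within lobe), so R can
#' be inspected for anatomical block structure. Pairs involving a
#' zero-variance lesion column are flagged missing (NA), with the count in
#' attribute `nMissing`; the diagonal is exactly 1.
#'
#' @param nlt a [NodeLesionTable-class] over at least 3 subjects.
#' @param metric `"lambda"` (integration, default) or `"localEfficiency"`
#'   (segregation).
#' @return symmetric correlation matrix over the lesioned parcels.
#' @export
lesionCorrelationMatrix <- function(nlt, metric = c("lambda", "localEfficiency")) {
    stopifnot(is(nlt, "NodeLesionTable"))
    metric <- match.arg(metric)
    M <- nlt@values[, , metric]     # lesions x subjects
    if (ncol(M) < 3) stop("need at least 3 subjects for correlations")
    R <- suppressWarnings(stats::cor(t(M), use = "pairwise.complete.obs"))
    R[!is.finite(R)] <- NA_real_
    diag(R) <- 1
    attr(R, "metric") <- metric
    attr(R, "nMissing") <- sum(is.na(R))
    R
}

.fixSigns <- function(loadings) {
    for (c in seq_len(ncol(loadings))) {
        peak <- which.max(abs(loadings[, c]))
        if (loadings[peak, c] < 0) loadings[, c] <- -loadings[, c]
    }
    loadings
}

#' Principal component analysis by eigendecomposition
#'
#' Components are the eigenvectors of the covariance matrix of the input's
#' columns (each column one variable); variance fractions are the
#' corresponding eigenvalue shares of the total. Applies equally to the
#' symmetric lesion-effect correlation matrix R (columns = parcels) and to a
#' samples x variables matrix of intact metrics. Loadings columns are
#' orthonormal and sign-fixed so each column's largest-magnitude entry is
#' positive; with all components retained the variance fractions sum to 1.
#'
#' @param x numeric matrix.
#' @param nComponents number of components to keep; truncated with a warning
#'   if it exceeds the matrix rank.
#' @param metric label stored in the result.
#' @return a [PCAResult-class].
#' @export
pcaLoadings <- function(x, nComponents = 3, metric = "") {
    x <- as.matrix(x)
    if (any(is.na(x))) x[is.na(x)] <- 0
    cv <- stats::cov(x)
    e <- eigen(cv, symmetric = TRUE)
    vals <- pmax(e$values, 0)
    total <- sum(vals)
    if (total <= 0) stop("degenerate input: zero total variance")
    rank <- sum(vals > max(vals) * ncol(x) * .Machine$double.eps)
    if (nComponents > rank) {
        warning("nComponents exceeds rank ", rank, "; truncating")
        nComponents <- rank
    }
    new("PCAResult",
        loadings = .fixSigns(e$vectors[, seq_len(nComponents), drop = FALSE]),
        varianceFraction = vals / total,
        metric = metric)
}

setMethod("show", "PCAResult", function(object) {
    k <- ncol(object@loadings)
    cat(sprintf("PCAResult (%s): %d components kept\n",
                if (nzchar(object@metric)) object@metric else "unlabeled", k))
    vf <- object@varianceFraction[seq_len(min(k, length(object@varianceFraction)))]
    cat("  variance fractions:", paste(sprintf("%.3f", vf), collapse = ", "), "\n")
})

#' PCA of intact-network nodal metrics
#'
#' Computes a nodal metric (betweenness centrality, clustering coefficient or
#' eccentricity) on every subject's intact network over the cortical parcels,
#' forms the across-subject correlation matrix of per-parcel values in the
#' same manner as [lesionCorrelationMatrix()], and applies [pcaLoadings()].
#' Used to check that the lesion analysis is not reproducible from intact
#' metrics alone (see [compareLesionVsIntact()]).
#'
#' @param cohort a [Cohort-class].
#' @param metric one of `"betweenness"`, `"clustering"`, `"eccentricity"`.
#' @param nComponents components to keep.
#' @return a [PCAResult-class] with loadings over the cortical parcels.
#' @export
intactMetricPCA <- function(cohort,
                            metric = c("betweenness", "clustering",
                                       "eccentricity"),
                            nComponents = 3) {
    stopifnot(is(cohort, "Cohort"))
    metric <- match.arg(metric)
    ci <- corticalIndices(parcellation(cohort))
    vals <- vapply(connectomes(cohort), function(con) {
        w <- weights(con)
        v <- switch(metric,
            betweenness = .betweenness(w),
            clustering = .clustering(w),
            eccentricity = nodeEccentricity(.spDistances(w)))
        v[ci]
    }, numeric(length(ci)))          # parcels x subjects
    if (all(apply(vals, 1, stats::sd) == 0))
        stop("degenerate cohort: intact ", metric,
             " has zero variance everywhere")
    R <- suppressWarnings(stats::cor(t(vals)))
    R[!is.finite(R)] <- 0
    diag(R) <- 1
    pcaLoadings(R, nComponents, metric = metric)
}

#' Correlate lesion-PCA loadings with intact-metric PCA loadings
#'
#' Pearson correlation between each leading lesion-PCA loading vector and
#' each leading intact-metric loading vector, over the shared parcel set.
#' The summary of interest is the maximum absolute correlation: values below
#' about 0.3 indicate the lesioning analysis captures structure that intact
#' network metrics do not.
#'
#' @param lesionPCA a [PCAResult-class] from the lesion analysis.
#' @param intactPCAs one [PCAResult-class] or a named list of them.
#' @return data.frame with columns `intact_metric`, `lesion_pc`,
#'   `intact_pc`, `r`; attribute `maxAbs` holds max |r|.
#' @export
compareLesionVsIntact <- function(lesionPCA, intactPCAs) {
    if (is(intactPCAs, "PCAResult")) intactPCAs <- list(intactPCAs)
    rows <- list()
    for (ip in intactPCAs) {
        if (nrow(ip@loadings) != nrow(lesionPCA@loadings))
            stop("loading vectors are defined on different parcel sets")
        for (a in seq_len(ncol(lesionPCA@loadings)))
            for (b in seq_len(ncol(ip@loadings)))
                rows[[length(rows) + 1L]] <- data.frame(
                    intact_metric = ip@metric, lesion_pc = a, intact_pc = b,
                    r = stats::cor(lesionPCA@loadings[, a], ip@loadings[, b]),
                    stringsAsFactors = FALSE)
    }
    out <- do.call(rbind, rows)
    attr(out, "maxAbs") <- max(abs(out$r))
    out
}

#' Rank-3 edge-effect tensor
#'
#' For every unordered pair \{k, k'\} and every subject, removes that edge
#' from the subject's network and records the change in a nodal metric at
#' each node k'' together with the change in global characteristic path
#' length. The subject dimension is collapsed by correlating, across
#' subjects, the nodal effect at k'' with the global path-length effect of
#' the same edge removal, giving the G x G x G tensor
#' C[k, k', k''], symmetric in its first two indices. Pairs absent in a
#' subject contribute exact-zero effects; entries whose series have zero
#' variance are NA (imputed to 0 by [mpca()], which counts them).
#'
#' This collapse is one of several defensible rules (the two series to
#' correlate in a 4-way edge-effect array are not canonical); it is the
#' package default and is isolated here so alternatives can be swapped in.
#'
#' @param cohort a [Cohort-class] (intended for modest G; the tensor has G^3
#'   entries).
#' @param nodalMetric `"eccentricity"` (default; distance-based and
#'   sensitive to edge removal), `"betweenness"`, `"clustering"` or
#'   `"localEfficiency"`.
#' @return numeric G x G x G array with attribute `metric`.
#' @export
edgeEffectTensor <- function(cohort,
                             nodalMetric = c("eccentricity", "betweenness",
                                             "clustering", "localEfficiency")) {
    stopifnot(is(cohort, "Cohort"))
    nodalMetric <- match.arg(nodalMetric)
    G <- nParcels(cohort)
    N <- nSubjects(cohort)
    nodal <- function(w) switch(nodalMetric,
        eccentricity = nodeEccentricity(.spDistances(w)),
        betweenness = .betweenness(w),
        clustering = .clustering(w),
        localEfficiency = .localEfficiency(w))
    pairs <- which(upper.tri(matrix(0, G, G)), arr.ind = TRUE)
    pairs <- pairs[order(pairs[, 1], pairs[, 2]), , drop = FALSE]
    dNodal <- array(0, dim = c(nrow(pairs), G, N))
    dLambda <- matrix(0, nrow(pairs), N)
    for (n in seq_len(N)) {
        w <- weights(cohort[[n]])
        base <- nodal(w)
        baseLam <- tryCatch(as.numeric(.lambda(.spDistances(w))),
                            error = function(e) NA_real_)
        for (q in seq_len(nrow(pairs))) {
            i <- pairs[q, 1]; j <- pairs[q, 2]
            if (w[i, j] == 0) next
            wl <- w
            wl[i, j] <- wl[j, i] <- 0
            dNodal[q, , n] <- nodal(wl) - base
            lam <- tryCatch(as.numeric(.lambda(.spDistances(wl))),
                            error = function(e) NA_real_)
            dLambda[q, n] <- lam - baseLam
        }
    }
    C <- array(NA_real_, dim = c(G, G, G))
    for (q in seq_len(nrow(pairs))) {
        i <- pairs[q, 1]; j <- pairs[q, 2]
        gl <- dLambda[q, ]
        r <- rep(NA_real_, G)
        if (isTRUE(stats::sd(gl, na.rm = TRUE) > 0)) {
            r <- suppressWarnings(
                apply(dNodal[q, , , drop = FALSE], 2, function(v)
                    tryCatch(stats::cor(as.numeric(v), gl,
                                        use = "complete.obs"),
                             error = function(e) NA_real_)))
            r[!is.finite(r)] <- NA_real_
        }
        C[i, j, ] <- C[j, i, ] <- r
    }
    attr(C, "metric") <- nodalMetric
    C
}

.mode3Unfoldings <- function(C) {
    # samples are mode-3 slices: one G x G effect matrix per target region
    lapply(seq_len(dim(C)[3]), function(s) C[, , s])
}

#' Multilinear PCA of a rank-3 tensor
#'
#' Treats the tensor's mode-3 slices as the sample set (one matrix sample
#' per target region), centers them by the sample mean, and finds one
#' orthonormal projection matrix per remaining mode maximizing the captured
#' variation — the fraction of total centered squared norm retained by the
#' projected samples. Projections are initialized by full-projection
#' truncation (the leading eigenvectors of each mode's total scatter) and
#' refined by alternating partial-projection eigendecompositions until the
#' captured variation changes by less than `tol` or `maxIter` is reached;
#' the refinement never decreases the captured variation, so it can only
#' improve on plain multilinear SVD truncation. Missing entries are imputed
#' to zero (no effect) and counted.
#'
#' @param C numeric 3-way array (e.g. from [edgeEffectTensor()]).
#' @param nComponentsPerMode integer 2-vector: components kept in modes 1
#'   and 2.
#' @param tol convergence tolerance on captured variation (default 1e-8).
#' @param maxIter maximum alternating iterations (default 100).
#' @return an [MPCAResult-class]; `mpc1Loadings` (first column of the mode-1
#'   projection) is the per-region vector mapped over the cortex.
#' @export
mpca <- function(C, nComponentsPerMode = c(1, 1), tol = 1e-8, maxIter = 100) {
    stopifnot(length(dim(C)) == 3)
    imputed <- sum(is.na(C))
    C[is.na(C)] <- 0
    P <- as.integer(nComponentsPerMode)
    stopifnot(length(P) == 2, all(P >= 1))
    slices <- .mode3Unfoldings(C)
    meanSlice <- Reduce(`+`, slices) / length(slices)
    Xs <- lapply(slices, function(x) x - meanSlice)
    total <- sum(vapply(Xs, function(x) sum(x^2), numeric(1)))
    if (total == 0)
        stop("tensor has zero centered variation")

    topEig <- function(M, k) {
        e <- eigen((M + t(M)) / 2, symmetric = TRUE)
        e$vectors[, seq_len(k), drop = FALSE]
    }
    # full-projection initialization (multilinear SVD truncation)
    U1 <- topEig(Reduce(`+`, lapply(Xs, function(x) x %*% t(x))), P[1])
    U2 <- topEig(Reduce(`+`, lapply(Xs, function(x) t(x) %*% x)), P[2])
    captured <- function(U1, U2)
        sum(vapply(Xs, function(x) sum((t(U1) %*% x %*% U2)^2),
                   numeric(1))) / total
    trace <- captured(U1, U2)
    iter <- 0L
    converged <- FALSE
    while (iter < maxIter) {
        iter <- iter + 1L
        U1 <- topEig(Reduce(`+`, lapply(Xs, function(x)
            x %*% U2 %*% t(U2) %*% t(x))), P[1])
        U2 <- topEig(Reduce(`+`, lapply(Xs, function(x)
            t(x) %*% U1 %*% t(U1) %*% x)), P[2])
        trace <- c(trace, captured(U1, U2))
        if (abs(trace[iter + 1] - trace[iter]) < tol) {
            converged <- TRUE
            break
        }
    }
    U1 <- .fixSigns(U1)
    U2 <- .fixSigns(U2)
    new("MPCAResult",
        projections = list(mode1 = U1, mode2 = U2),
        capturedVariation = trace[length(trace)],
        mpc1Loadings = as.numeric(U1[, 1]),
        iterations = iter, converged = converged,
        variationTrace = trace, imputedCount = as.integer(imputed))
}

setMethod("show", "MPCAResult", function(object) {
    cat(sprintf("MPCAResult: captured variation %.4f after %d iteration(s)%s\n",
                object@capturedVariation, object@iterations,
                if (object@converged) "" else " (not converged)"))
    if (object@imputedCount > 0)
        cat(sprintf("  %d missing entries imputed to 0\n", object@imputedCount))
})
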