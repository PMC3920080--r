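# Independent brute-force oracles used to cross-check the package's metric
# implementations. Deliberately naive: Floyd-Warshall, exhaustive path /
# triple enumeration, closed-form statistics. None of them share code with
# the package internals.

# all-pairs shortest paths on lengths 1/w via Floyd-Warshall
fwDistances <- function(w) {
    G <- nrow(w)
    d <- matrix(Inf, G, G)
    diag(d) <- 0
    d[w > 0] <- 1 / w[w > 0]
    for (k in seq_len(G))
        for (i in seq_len(G))
            for (j in seq_len(G))
                if (d[i, k] + d[k, j] < d[i, j])
                    d[i, j] <- d[i, k] + d[k, j]
    d
}

# exhaustive enumeration of all simple paths (tiny graphs only)
enumDistances <- function(w) {
    G <- nrow(w)
    best <- matrix(Inf, G, G)
    diag(best) <- 0
    recurse <- function(path, len) {
        i <- path[1]; j <- path[length(path)]
        if (len < best[i, j]) best[i, j] <<- len
        for (k in seq_len(G)) {
            if (w[j, k] > 0 && !(k %in% path))
                recurse(c(path, k), len + 1 / w[j, k])
        }
    }
    for (s in seq_len(G)) recurse(s, 0)
    pmin(best, t(best))
}

oracleLambda <- function(d) {
    off <- d[row(d) != col(d)]
    mean(off[is.finite(off)])
}

oracleLocalEff <- function(w) {
    G <- nrow(w)
    sapply(seq_len(G), function(i) {
        nb <- which(w[i, ] > 0)
        if (length(nb) < 2) return(0)
        d <- fwDistances(w[nb, nb, drop = FALSE])
        vals <- 1 / d[row(d) != col(d)]
        mean(ifelse(is.finite(vals), vals, 0))
    })
}

# Newman's closed-form degree assortativity over the edge list
oracleAssortativity <- function(w) {
    A <- w > 0
    deg <- rowSums(A)
    e <- which(A & upper.tri(A), arr.ind = TRUE)
    ji <- deg[e[, 1]]; ki <- deg[e[, 2]]
    M1 <- 1 / nrow(e)
    num <- M1 * sum(ji * ki) - (M1 * sum((ji + ki) / 2))^2
    den <- M1 * sum((ji^2 + ki^2) / 2) - (M1 * sum((ji + ki) / 2))^2
    num / den
}

oracleTransitivity <- function(w) {
    A <- w > 0
    G <- nrow(A)
    tri <- 0; triples <- 0
    for (i in seq_len(G)) for (j in seq_len(G)) for (k in seq_len(G)) {
        if (i == j || j == k || i == k) next
        if (A[i, j] && A[j, k]) {
            triples <- triples + 1
            if (A[i, k]) tri <- tri + 1
        }
    }
    # ordered counts: triangles appear 6x, 2-paths 2x, so the ordered ratio
    # tri/triples equals 3 * triangles / (number of 2-paths)
    tri / triples
}

oracleClustering <- function(w) {
    A <- w > 0
    G <- nrow(A)
    sapply(seq_len(G), function(i) {
        nb <- which(A[i, ])
        if (length(nb) < 2) return(0)
        links <- 0
        for (a in nb) for (b in nb) if (a < b && A[a, b]) links <- links + 1
        links / choose(length(nb), 2)
    })
}

# betweenness via shortest-path counting on Floyd-Warshall distances
oracleBetweenness <- function(w, tol = 1e-9) {
    G <- nrow(w)
    d <- fwDistances(w)
    len <- matrix(Inf, G, G)
    len[w > 0] <- 1 / w[w > 0]
    sigma <- matrix(0, G, G)   # number of shortest paths s -> t
    for (s in seq_len(G)) {
        ord <- order(d[s, ])
        sigma[s, s] <- 1
        for (t in ord) {
            if (t == s || !is.finite(d[s, t])) next
            for (v in seq_len(G)) {
                if (v != t && is.finite(len[v, t]) &&
                    abs(d[s, v] + len[v, t] - d[s, t]) < tol)
                    sigma[s, t] <- sigma[s, t] + sigma[s, v]
            }
        }
    }
    b <- numeric(G)
    for (s in seq_len(G)) for (t in seq_len(G)) {
        if (s >= t || !is.finite(d[s, t]) || sigma[s, t] == 0) next
        for (v in seq_len(G)) {
            if (v == s || v == t) next
            if (abs(d[s, v] + d[v, t] - d[s, t]) < tol)
                b[v] <- b[v] + sigma[s, v] * sigma[v, t] / sigma[s, t]
        }
    }
    b
}

# random symmetric weight matrix; weights in (0.5, 1.5) to keep shortest-path
# ties measure-zero
randomWeights <- function(G, p = 0.4, seed = 1) {
    set.seed(seed)
    w <- matrix(0, G, G)
    for (i in seq_len(G - 1)) for (j in (i + 1):G) {
        if (runif(1) < p) w[i, j] <- w[j, i] <- runif(1, 0.5, 1.5)
    }
    w
}

randomConnectome <- function(G, p = 0.4, seed = 1) {
    Connectome(randomWeights(G, p, seed), genericParcellation(G),
               subjectID = sprintf("rnd%d", seed))
}

# paired Hotelling T2 via an independent route (stats::mahalanobis + pf)
oracleHotelling <- function(lesioned, intact) {
    D <- lesioned - intact
    N <- nrow(D); p <- ncol(D)
    T2 <- N * stats::mahalanobis(colMeans(D), rep(0, p), stats::cov(D))
    Fs <- (N - p) * T2 / (p * (N - 1))
    list(T2 = T2, F = Fs, p = stats::pf(Fs, p, N - p, lower.tail = FALSE))
}

# plain multilinear SVD truncation: captured variation without alternating
# refinement (mode-3 slices as centered samples)
hosvdCaptured <- function(C, P = c(1, 1)) {
    slices <- lapply(seq_len(dim(C)[3]), function(s) C[, , s])
    meanSlice <- Reduce(`+`, slices) / length(slices)
    Xs <- lapply(slices, function(x) x - meanSlice)
    U1 <- eigen(Reduce(`+`, lapply(Xs, function(x) x %*% t(x))),
                symmetric = TRUE)$vectors[, seq_len(P[1]), drop = FALSE]
    U2 <- eigen(Reduce(`+`, lapply(Xs, function(x) t(x) %*% x)),
                symmetric = TRUE)$vectors[, seq_len(P[2]), drop = FALSE]
    sum(vapply(Xs, function(x) sum((t(U1) %*% x %*% U2)^2), numeric(1))) /
        sum(vapply(Xs, function(x) sum(x^2), numeric(1)))
}

# the ten planted inter-module bridges of the standard recovery experiment
# (modules are contiguous blocks of ten nodes at G = 40)
recoveryPlantedEdges <- function() {
    rbind(c(1, 11), c(2, 21), c(3, 31), c(12, 22), c(13, 32), c(23, 33),
          c(4, 14), c(5, 24), c(15, 35), c(6, 36))
}

recoverySpec <- function(seed = 3) {
    cohortSpec(G = 40, nSubjects = 30, nModules = 4,
               pWithin = 0.9, pBetween = 0, weightLogSD = 0.25,
               subjectNoiseSD = 1.0, plantedEdges = recoveryPlantedEdges(),
               plantedBoost = 5, seed = seed)
}
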