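## Graph metrics. Exported surface dispatches on Connectome or plain matrix;
## the .dot internal functions work on weight matrices and are what the
## lesion sweeps call. Shortest paths, betweenness and per-node clustering are
## delegated to igraph; everything else is computed directly. Edge lengths
## follow the inverse-weight rule (length = 1/weight) unless stated otherwise.

.undefined <- function(reason) structure(NA_real_, undefined = reason)

#' Test for an undefined metric value
#'
#' Degenerate metric values (e.g. assortativity on a regular graph,
#' transitivity with no connected triple) are returned as a typed undefined
#' value — an NA carrying the reason — rather than silent NaN. Downstream
#' statistics treat them as missing and report how many were missing.
#'
#' @param x a scalar metric value.
#' @return TRUE if `x` is an undefined-metric signal.
#' @export
isUndefined <- function(x) {
    length(x) == 1 && is.na(x) && !is.null(attr(x, "undefined"))
}

.asWeights <- function(x) if (is(x, "Connectome")) weights(x) else as.matrix(x)

.graphFromWeights <- function(w, rule = "inverse") {
    g <- igraph::graph_from_adjacency_matrix(w, mode = "undirected",
                                             weighted = TRUE, diag = FALSE)
    len <- if (rule == "binary") rep(1, igraph::ecount(g))
           else 1 / igraph::E(g)$weight
    list(g = g, len = len)
}

.spDistances <- function(w, rule = "inverse") {
    G <- nrow(w)
    if (all(w == 0)) {
        d <- matrix(Inf, G, G)
        diag(d) <- 0
        return(d)
    }
    gl <- .graphFromWeights(w, rule)
    d <- igraph::distances(gl$g, weights = gl$len)
    dimnames(d) <- dimnames(w)
    d
}

#' Shortest-path distance matrix
#'
#' All-pairs shortest-path lengths under a weight-to-length rule. The default
#' rule, `"inverse"`, maps each edge to length 1/weight, so strong
#' connections are short; `"binary"` gives every edge unit length.
#' Disconnected pairs get `Inf`. An edgeless network returns an all-infinite
#' off-diagonal.
#'
#' @param x a [Connectome-class] or weight matrix.
#' @param rule weight-to-length rule, `"inverse"` (default) or `"binary"`.
#' @return G x G numeric matrix with zero diagonal.
#' @rdname distanceMatrix
#' @export
setMethod("distanceMatrix", "Connectome", function(x, rule = c("inverse", "binary")) {
    .spDistances(weights(x), match.arg(rule))
})

#' @rdname distanceMatrix
#' @export
setMethod("distanceMatrix", "matrix", function(x, rule = c("inverse", "binary")) {
    .spDistances(x, match.arg(rule))
})

.lambda <- function(d) {
    off <- d[upper.tri(d) | lower.tri(d)]
    fin <- off[is.finite(off)]
    if (length(fin) == 0)
        stop("characteristic path length undefined: no finite off-diagonal ",
             "distances (fully disconnected network)")
    structure(mean(fin), disconnected = any(!is.finite(off)))
}

#' Characteristic path length
#'
#' The mean of the finite off-diagonal entries of the distance matrix (the
#' network's integration measure: lower values mean cheaper average routes).
#' Disconnected pairs are excluded from the average — the finite-pairs
#' convention — and the result then carries attribute `disconnected = TRUE`.
#' A fully disconnected network is an error.
#'
#' @param x a distance matrix from [distanceMatrix()], or a
#'   [Connectome-class] (computed with the inverse-weight rule).
#' @param ... passed on (unused).
#' @return scalar; attribute `disconnected` flags excluded pairs.
#' @rdname characteristicPathLength
#' @export
setMethod("characteristicPathLength", "matrix", function(x, ...) .lambda(x))

#' @rdname characteristicPathLength
#' @export
setMethod("characteristicPathLength", "Connectome", function(x, ...) {
    .lambda(.spDistances(weights(x)))
})

.localEfficiency <- function(w, rule = "inverse") {
    G <- nrow(w)
    eff <- numeric(G)
    for (i in seq_len(G)) {
        nb <- which(w[i, ] > 0)
        k <- length(nb)
        if (k < 2) next
        d <- .spDistances(w[nb, nb, drop = FALSE], rule)
        inv <- 1 / d          # 1/Inf = 0 for unreachable neighbor pairs
        diag(inv) <- 0
        eff[i] <- sum(inv) / (k * (k - 1))
    }
    names(eff) <- rownames(w)
    eff
}

#' Nodal local efficiency
#'
#' For each node, the subgraph induced by its neighbors is extracted,
#' shortest-path distances are computed within that subgraph (inverse-weight
#' lengths), and the inverse distances are averaged over ordered neighbor
#' pairs (an unreachable pair contributes 0). Nodes with fewer than two
#' neighbors have local efficiency 0. The network's segregation measure is
#' the mean of this vector.
#'
#' @param x a [Connectome-class] or weight matrix.
#' @return per-node numeric vector; take `mean()` for the network value.
#' @rdname localEfficiency
#' @export
setMethod("localEfficiency", "Connectome", function(x) .localEfficiency(weights(x)))

#' @rdname localEfficiency
#' @export
setMethod("localEfficiency", "matrix", function(x) .localEfficiency(x))

.assortativity <- function(w) {
    A <- w > 0
    deg <- rowSums(A)
    e <- which(A & upper.tri(A), arr.ind = TRUE)
    if (nrow(e) < 2)
        return(.undefined("fewer than two edges"))
    dx <- c(deg[e[, 1]], deg[e[, 2]])
    dy <- c(deg[e[, 2]], deg[e[, 1]])
    if (stats::var(dx) == 0)
        return(.undefined("zero degree variance over edge endpoints"))
    stats::cor(dx, dy)
}

#' Degree assortativity
#'
#' Pearson correlation of endpoint degrees over the symmetrized edge list
#' (Newman's r), on the binary topology. Degenerate inputs — fewer than two
#' edges, or all endpoint degrees equal (e.g. a cycle) — return a typed
#' undefined value, see [isUndefined()].
#'
#' @param x a [Connectome-class] or weight matrix.
#' @return scalar in [-1, 1], or an undefined signal.
#' @rdname degreeAssortativity
#' @export
setMethod("degreeAssortativity", "Connectome", function(x) .assortativity(weights(x)))

#' @rdname degreeAssortativity
#' @export
setMethod("degreeAssortativity", "matrix", function(x) .assortativity(x))

.transitivity <- function(w) {
    A <- (w > 0) + 0
    deg <- rowSums(A)
    triples <- sum(deg * (deg - 1) / 2)
    if (triples == 0)
        return(.undefined("no connected triples"))
    triangles <- sum(diag(A %*% A %*% A)) / 6
    3 * triangles / triples
}

#' Transitivity
#'
#' 3 x triangles / connected triples on the binary topology: a global
#' clustering measure without low-degree bias. Undefined (see
#' [isUndefined()]) when no connected triple exists.
#'
#' @param x a [Connectome-class] or weight matrix.
#' @return scalar in [0, 1], or an undefined signal.
#' @rdname graphTransitivity
#' @export
setMethod("graphTransitivity", "Connectome", function(x) .transitivity(weights(x)))

#' @rdname graphTransitivity
#' @export
setMethod("graphTransitivity", "matrix", function(x) .transitivity(x))

.density <- function(w) {
    G <- nrow(w)
    sum(w[upper.tri(w)] > 0) / (G * (G - 1) / 2)
}

#' Edge density
#'
#' Fraction of the G(G-1)/2 possible edges present (binary topology).
#'
#' @param x a [Connectome-class] or weight matrix.
#' @return scalar in [0, 1].
#' @rdname edgeDensity
#' @export
setMethod("edgeDensity", "Connectome", function(x) .density(weights(x)))

#' @rdname edgeDensity
#' @export
setMethod("edgeDensity", "matrix", function(x) .density(x))

#' @rdname nodeDegree
#' @export
setMethod("nodeDegree", "Connectome", function(x) rowSums(weights(x) > 0))

#' Node degree
#'
#' Number of edges at each node (binary topology).
#'
#' @param x a [Connectome-class] or weight matrix.
#' @return per-node integer-valued vector.
#' @rdname nodeDegree
#' @export
setMethod("nodeDegree", "matrix", function(x) rowSums(x > 0))

.betweenness <- function(w) {
    if (all(w == 0)) return(stats::setNames(numeric(nrow(w)), rownames(w)))
    gl <- .graphFromWeights(w)
    b <- igraph::betweenness(gl$g, weights = gl$len, normalized = FALSE)
    stats::setNames(as.numeric(b), rownames(w))
}

#' Betweenness centrality
#'
#' Unnormalized shortest-path betweenness on inverse-weight edge lengths
#' (each unordered pair counted once).
#'
#' @param x a [Connectome-class] or weight matrix.
#' @return per-node nonnegative vector.
#' @rdname betweennessCentrality
#' @export
setMethod("betweennessCentrality", "Connectome", function(x) .betweenness(weights(x)))

#' @rdname betweennessCentrality
#' @export
setMethod("betweennessCentrality", "matrix", function(x) .betweenness(x))

.clustering <- function(w) {
    A <- (w > 0) + 0
    G <- nrow(A)
    cc <- numeric(G)
    deg <- rowSums(A)
    for (i in seq_len(G)) {
        if (deg[i] < 2) next
        nb <- which(A[i, ] > 0)
        cc[i] <- sum(A[nb, nb]) / 2 / (deg[i] * (deg[i] - 1) / 2)
    }
    names(cc) <- rownames(w)
    cc
}

#' Per-node clustering coefficient
#'
#' Fraction of a node's neighbor pairs that are themselves connected (binary
#' topology); 0 for nodes of degree below 2.
#'
#' @param x a [Connectome-class] or weight matrix.
#' @return per-node vector in [0, 1].
#' @rdname clusteringCoefficient
#' @export
setMethod("clusteringCoefficient", "Connectome", function(x) .clustering(weights(x)))

#' @rdname clusteringCoefficient
#' @export
setMethod("clusteringCoefficient", "matrix", function(x) .clustering(x))

#' Eccentricity, radius and diameter
#'
#' `nodeEccentricity()` is each node's greatest finite distance to any other
#' node (NA for isolated nodes); `graphRadius()` and `graphDiameter()` are
#' its minimum and maximum. On a disconnected network only finite distances
#' enter, and radius/diameter carry attribute `disconnected = TRUE`.
#'
#' @param d a distance matrix from [distanceMatrix()].
#' @return per-node vector (`nodeEccentricity`) or flagged scalar.
#' @export
nodeEccentricity <- function(d) {
    diag(d) <- NA
    apply(d, 1, function(r) {
        fin <- r[is.finite(r)]
        if (length(fin) == 0) NA_real_ else max(fin)
    })
}

#' @rdname nodeEccentricity
#' @export
graphDiameter <- function(d) {
    ecc <- nodeEccentricity(d)
    if (all(is.na(ecc))) stop("diameter undefined: no connected node pair")
    off <- d[upper.tri(d)]
    structure(max(ecc, na.rm = TRUE),
              disconnected = any(!is.finite(off)) || any(is.na(ecc)))
}

#' @rdname nodeEccentricity
#' @export
graphRadius <- function(d) {
    ecc <- nodeEccentricity(d)
    if (all(is.na(ecc))) stop("radius undefined: no connected node pair")
    off <- d[upper.tri(d)]
    structure(min(ecc, na.rm = TRUE),
              disconnected = any(!is.finite(off)) || any(is.na(ecc)))
}

.featureVector <- function(w) {
    fv <- c(assortativity = NA_real_, lambda = NA_real_,
            density = NA_real_, transitivity = NA_real_)
    und <- character()
    a <- .assortativity(w)
    if (isUndefined(a)) und <- c(und, "assortativity") else fv["assortativity"] <- a
    lam <- tryCatch(as.numeric(.lambda(.spDistances(w))), error = function(e) NA_real_)
    if (is.na(lam)) und <- c(und, "lambda") else fv["lambda"] <- lam
    fv["density"] <- .density(w)
    tr <- .transitivity(w)
    if (isUndefined(tr)) und <- c(und, "transitivity") else fv["transitivity"] <- tr
    attr(fv, "undefined") <- und
    fv
}

#' Global feature vector for edge-removal tests
#'
#' The ordered 4-vector (assortativity, characteristic path length, density,
#' transitivity) summarizing global topology; the dependent variables (p = 4)
#' of the paired multivariate edge test. Undefined components are NA, with
#' the offending metric named in attribute `undefined`.
#'
#' @param x a [Connectome-class] or weight matrix.
#' @return named numeric vector of length 4.
#' @seealso [edgeLesionSweep()], [hotellingPaired()]
#' @rdname featureVector
#' @export
setMethod("featureVector", "Connectome", function(x) .featureVector(weights(x)))

#' @rdname featureVector
#' @export
setMethod("featureVector", "matrix", function(x) .featureVector(x))
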