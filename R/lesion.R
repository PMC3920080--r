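## Lesion simulation: node deletion (parcel plus incident connections) and
## single-edge deletion, plus cohort-wide sweeps over every possible lesion.
## Post-lesion networks are never renormalized: the lesion removes tissue from
## the measured network, it does not rescale the surviving connections.

.subsetParcellation <- function(p, keep) {
    Parcellation(p@parcels[keep, , drop = FALSE])
}

#' Delete one node and its connections
#'
#' Returns the (G-1)-node connectome obtained by removing the given parcel
#' and every edge incident to it; surviving weights are untouched. The
#' original parcel identity survives through the labels of the reduced
#' parcellation.
#'
#' @param x a [Connectome-class].
#' @param parcel parcel index (1-based) or label.
#' @return a [Connectome-class] on G-1 parcels.
#' @rdname removeNode
#' @export
setMethod("removeNode", "Connectome", function(x, parcel) {
    G <- nParcels(x)
    if (is.character(parcel)) parcel <- match(parcel, parcelLabels(x))
    if (is.na(parcel) || parcel < 1 || parcel > G)
        stop("invalid parcel")
    keep <- setdiff(seq_len(G), parcel)
    sub <- function(m) if (is.null(m)) NULL else m[keep, keep, drop = FALSE]
    Connectome(weights(x)[keep, keep, drop = FALSE],
               .subsetParcellation(parcellation(x), keep),
               subjectID = subjectID(x), lengths = sub(x@lengths),
               fa = sub(x@fa))
})

#' Delete one edge
#'
#' Sets the weight of the unordered pair \{i, j\} to zero (both triangle
#' entries), leaving everything else identical; companion entries become NA.
#' Removing an already-absent edge is the identity.
#'
#' @param x a [Connectome-class].
#' @param i,j distinct parcel indices (1-based) or labels.
#' @return a [Connectome-class] on the same parcellation.
#' @rdname removeEdge
#' @export
setMethod("removeEdge", "Connectome", function(x, i, j) {
    if (is.character(i)) i <- match(i, parcelLabels(x))
    if (is.character(j)) j <- match(j, parcelLabels(x))
    G <- nParcels(x)
    if (is.na(i) || is.na(j) || i < 1 || j < 1 || i > G || j > G)
        stop("invalid parcel index")
    if (i == j) stop("cannot remove a self-edge: i must differ from j")
    if (weights(x)[i, j] == 0) return(x)
    w <- weights(x)
    w[i, j] <- w[j, i] <- 0
    blank <- function(m) {
        if (is.null(m)) return(NULL)
        m[i, j] <- m[j, i] <- NA_real_
        m
    }
    Connectome(w, parcellation(x), subjectID = subjectID(x),
               lengths = blank(x@lengths), fa = blank(x@fa))
})

.NODE_METRICS <- c("lambda", "localEfficiency")

.nodeMetrics <- function(w) {
    lam <- tryCatch(as.numeric(.lambda(.spDistances(w))),
                    error = function(e) NA_real_)
    c(lambda = lam, localEfficiency = mean(.localEfficiency(w)))
}

#' Sweep all single-node lesions over a cohort
#'
#' For every cortical parcel and every subject, removes that parcel from the
#' subject's network and computes the two global metrics of the node-removal
#' analysis — characteristic path length (integration) and mean local
#' efficiency (segregation) — alongside the intact-network values. Under the
#' default 165-parcel scheme this is 148 lesions per subject; subcortical
#' structures, cerebellum and brainstem stay in the network but are never
#' lesioned. Metrics undefined on a lesioned network (e.g. a fully
#' disconnected remainder) become NA cells, counted in `missingCount`.
#'
#' @param cohort a [Cohort-class].
#' @return a [NodeLesionTable-class].
#' @export
nodeLesionSweep <- function(cohort) {
    stopifnot(is(cohort, "Cohort"))
    p <- parcellation(cohort)
    lesioned <- corticalIndices(p)
    N <- nSubjects(cohort)
    values <- array(NA_real_, dim = c(length(lesioned), N, 2),
                    dimnames = list(parcelLabels(p)[lesioned],
                                    subjectID(cohort), .NODE_METRICS))
    intact <- matrix(NA_real_, N, 2,
                     dimnames = list(subjectID(cohort), .NODE_METRICS))
    for (n in seq_len(N)) {
        w <- weights(cohort[[n]])
        intact[n, ] <- .nodeMetrics(w)
        for (q in seq_along(lesioned)) {
            k <- lesioned[q]
            values[q, n, ] <- .nodeMetrics(w[-k, -k, drop = FALSE])
        }
    }
    new("NodeLesionTable", values = values, intact = intact,
        lesioned = as.integer(lesioned), metrics = .NODE_METRICS,
        parcellation = p, missingCount = sum(is.na(values)))
}

setMethod("show", "NodeLesionTable", function(object) {
    cat(sprintf("NodeLesionTable: %d lesions x %d subjects x %d metrics (%d missing)\n",
                dim(object@values)[1], dim(object@values)[2],
                dim(object@values)[3], object@missingCount))
})

#' Sweep all single-edge lesions over a cohort
#'
#' For every unordered parcel pair — all G(G-1)/2 of them, present or not —
#' and every subject, removes that connection from the subject's intact
#' network and evaluates the global [featureVector()]. Pairs absent in a
#' subject reproduce the intact vector exactly (no recomputation), so the
#' statistics module can recognize all-zero difference vectors.
#'
#' @param cohort a [Cohort-class].
#' @return an [EdgeLesionTable-class].
#' @export
edgeLesionSweep <- function(cohort) {
    stopifnot(is(cohort, "Cohort"))
    p <- parcellation(cohort)
    G <- nParcels(p)
    pairs <- which(upper.tri(matrix(0, G, G)), arr.ind = TRUE)
    pairs <- pairs[order(pairs[, 1], pairs[, 2]), , drop = FALSE]
    colnames(pairs) <- c("i", "j")
    N <- nSubjects(cohort)
    fvNames <- c("assortativity", "lambda", "density", "transitivity")
    values <- array(NA_real_, dim = c(nrow(pairs), N, 4),
                    dimnames = list(NULL, subjectID(cohort), fvNames))
    intact <- matrix(NA_real_, N, 4,
                     dimnames = list(subjectID(cohort), fvNames))
    presence <- integer(nrow(pairs))
    for (n in seq_len(N)) {
        w <- weights(cohort[[n]])
        iv <- .featureVector(w)
        intact[n, ] <- iv
        for (q in seq_len(nrow(pairs))) {
            i <- pairs[q, 1]; j <- pairs[q, 2]
            if (w[i, j] > 0) {
                presence[q] <- presence[q] + 1L
                wl <- w
                wl[i, j] <- wl[j, i] <- 0
                values[q, n, ] <- .featureVector(wl)
            } else {
                values[q, n, ] <- iv
            }
        }
    }
    new("EdgeLesionTable", values = values, intact = intact,
        pairs = pairs, edgePresence = presence, metrics = fvNames,
        parcellation = p, missingCount = sum(is.na(values)))
}

setMethod("show", "EdgeLesionTable", function(object) {
    cat(sprintf("EdgeLesionTable: %d pairs x %d subjects x %d features (%d missing)\n",
                dim(object@values)[1], dim(object@values)[2],
                dim(object@values)[3], object@missingCount))
    cat(sprintf("  pairs present in >=1 subject: %d\n",
                sum(object@edgePresence > 0)))
})

#' Long-format export of lesion sweep tables
#'
#' @param x a [NodeLesionTable-class] or [EdgeLesionTable-class].
#' @param path optional TSV path; when given the table is also written.
#' @return data.frame with columns lesion, subject, metric, value.
#' @export
lesionTableLong <- function(x, path = NULL) {
    labels <- parcelLabels(x@parcellation)
    if (is(x, "NodeLesionTable")) {
        lesion <- labels[x@lesioned]
    } else if (is(x, "EdgeLesionTable")) {
        lesion <- paste(labels[x@pairs[, 1]], labels[x@pairs[, 2]], sep = "|")
    } else stop("unsupported table type")
    # expand.grid keeps the first factor fastest, matching array layout
    grid <- expand.grid(lesion = lesion,
                        subject = dimnames(x@values)[[2]],
                        metric = x@metrics, stringsAsFactors = FALSE)
    grid$value <- as.vector(x@values)
    if (!is.null(path))
        utils::write.table(grid, path, sep = "\t", quote = FALSE,
                           row.names = FALSE)
    grid
}
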