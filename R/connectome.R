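#' Construct a Connectome
#'
#' Validates and wraps a weight matrix (with optional mean-length and mean-FA
#' companions) over a parcellation. Asymmetric input is rejected, never
#' silently symmetrized.
#'
#' @param weights G x G symmetric nonnegative matrix with zero diagonal.
#' @param parcellation a [Parcellation-class] with G parcels.
#' @param subjectID subject identifier string.
#' @param lengths optional G x G matrix of mean fiber length in cm, NA where
#'   `weights` is zero.
#' @param fa optional G x G matrix of mean fractional anisotropy in [0, 1].
#' @return a [Connectome-class].
#' @examples
#' p <- genericParcellation(3)
#' w <- matrix(0, 3, 3); w[1, 2] <- w[2, 1] <- 1
#' con <- Connectome(w, p, subjectID = "s1")
#' @export
Connectome <- function(weights, parcellation, subjectID = "subject",
                       lengths = NULL, fa = NULL) {
    weights <- as.matrix(weights)
    dimnames(weights) <- list(parcelLabels(parcellation),
                              parcelLabels(parcellation))
    if (!is.null(lengths)) dimnames(lengths) <- dimnames(weights)
    if (!is.null(fa)) dimnames(fa) <- dimnames(weights)
    new("Connectome", subjectID = as.character(subjectID), weights = weights,
        lengths = lengths, fa = fa, parcellation = parcellation)
}

#' @rdname accessors
#' @export
setMethod("weights", "Connectome", function(object, ...) object@weights)

#' @rdname accessors
#' @export
setMethod("fiberLengths", "Connectome", function(object) object@lengths)

#' @rdname accessors
#' @export
setMethod("fiberFA", "Connectome", function(object) object@fa)

#' @rdname accessors
#' @export
setMethod("parcellation", "Connectome", function(object) object@parcellation)

#' @rdname accessors
#' @export
setMethod("subjectID", "Connectome", function(object) object@subjectID)

setMethod("show", "Connectome", function(object) {
    w <- object@weights
    ne <- sum(w[upper.tri(w)] > 0)
    cat(sprintf("Connectome '%s': %d parcels, %d edges, density %.3f\n",
                object@subjectID, nrow(w), ne,
                ne / (nrow(w) * (nrow(w) - 1) / 2)))
    cat(sprintf("  companions: lengths=%s, fa=%s\n",
                !is.null(object@lengths), !is.null(object@fa)))
})

#' Construct a Cohort
#'
#' @param connectomes list of [Connectome-class] objects sharing one
#'   parcellation.
#' @return a [Cohort-class].
#' @export
Cohort <- function(connectomes) {
    if (length(connectomes) == 0)
        stop("a Cohort needs at least one connectome")
    new("Cohort", connectomes = connectomes,
        parcellation = connectomes[[1]]@parcellation)
}

#' @rdname accessors
#' @export
setMethod("nSubjects", "Cohort", function(object) length(object@connectomes))

#' @rdname accessors
#' @export
setMethod("connectomes", "Cohort", function(object) object@connectomes)

#' @rdname accessors
#' @export
setMethod("parcellation", "Cohort", function(object) object@parcellation)

#' @rdname accessors
#' @export
setMethod("nParcels", "Cohort", function(object) nParcels(object@parcellation))

#' @rdname accessors
#' @export
setMethod("subjectID", "Cohort", function(object)
    vapply(object@connectomes, subjectID, character(1)))

#' @export
setMethod("[[", "Cohort", function(x, i) x@connectomes[[i]])

#' @export
setMethod("length", "Cohort", function(x) length(x@connectomes))

setMethod("show", "Cohort", function(object) {
    cat(sprintf("Cohort: %d subjects over %d parcels\n",
                nSubjects(object), nParcels(object)))
})

#' Average a cohort into a group-level connectome
#'
#' Entrywise arithmetic mean of the subjects' weight matrices (probabilistic
#' group connectivity when subjects are individually normalized). Companion
#' matrices are not averaged.
#'
#' @param cohort a [Cohort-class] with at least one subject.
#' @return a [Connectome-class] with subjectID `"cohort-average"`.
#' @export
cohortAverage <- function(cohort) {
    stopifnot(is(cohort, "Cohort"))
    if (nSubjects(cohort) == 0) stop("empty cohort")
    w <- Reduce(`+`, lapply(cohort@connectomes, weights)) / nSubjects(cohort)
    Connectome(w, cohort@parcellation, subjectID = "cohort-average")
}
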