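#' @importFrom stats weights
NULL

#' Accessors for connectome containers
#'
#' `weights()`, `fiberLengths()` and `fiberFA()` return the weight and
#' companion matrices of a [Connectome-class]; `parcellation()` returns the
#' underlying [Parcellation-class]; `subjectID()` the subject identifier;
#' `nParcels()` the node count G; `parcelLabels()` the ordered label vector;
#' `corticalIndices()` the indices of cortical (lesionable) parcels;
#' `nSubjects()` and `connectomes()` the size and members of a
#' [Cohort-class].
#'
#' @param object a [Parcellation-class], [Connectome-class] or
#'   [Cohort-class], as appropriate.
#' @param ... ignored.
#' @return the accessed component (see above).
#' @name accessors
#' @aliases weights
NULL

#' @rdname accessors
#' @export
setGeneric("weights")

#' @rdname accessors
#' @export
setGeneric("fiberLengths", function(object) standardGeneric("fiberLengths"))

#' @rdname accessors
#' @export
setGeneric("fiberFA", function(object) standardGeneric("fiberFA"))

#' @rdname accessors
#' @export
setGeneric("parcellation", function(object) standardGeneric("parcellation"))

#' @rdname accessors
#' @export
setGeneric("subjectID", function(object) standardGeneric("subjectID"))

#' @rdname accessors
#' @export
setGeneric("nParcels", function(object) standardGeneric("nParcels"))

#' @rdname accessors
#' @export
setGeneric("parcelLabels", function(object) standardGeneric("parcelLabels"))

#' @rdname accessors
#' @export
setGeneric("corticalIndices", function(object) standardGeneric("corticalIndices"))

#' @rdname accessors
#' @export
setGeneric("nSubjects", function(object) standardGeneric("nSubjects"))

#' @rdname accessors
#' @export
setGeneric("connectomes", function(object) standardGeneric("connectomes"))

#' @rdname distanceMatrix
#' @export
setGeneric("distanceMatrix",
    function(x, rule = c("inverse", "binary")) standardGeneric("distanceMatrix"))

#' @rdname characteristicPathLength
#' @export
setGeneric("characteristicPathLength",
    function(x, ...) standardGeneric("characteristicPathLength"))

#' @rdname localEfficiency
#' @export
setGeneric("localEfficiency", function(x) standardGeneric("localEfficiency"))

#' @rdname degreeAssortativity
#' @export
setGeneric("degreeAssortativity", function(x) standardGeneric("degreeAssortativity"))

#' @rdname graphTransitivity
#' @export
setGeneric("graphTransitivity", function(x) standardGeneric("graphTransitivity"))

#' @rdname edgeDensity
#' @export
setGeneric("edgeDensity", function(x) standardGeneric("edgeDensity"))

#' @rdname nodeDegree
#' @export
setGeneric("nodeDegree", function(x) standardGeneric("nodeDegree"))

#' @rdname betweennessCentrality
#' @export
setGeneric("betweennessCentrality",
    function(x) standardGeneric("betweennessCentrality"))

#' @rdname clusteringCoefficient
#' @export
setGeneric("clusteringCoefficient",
    function(x) standardGeneric("clusteringCoefficient"))

#' @rdname featureVector
#' @export
setGeneric("featureVector", function(x) standardGeneric("featureVector"))

#' @rdname removeNode
#' @export
setGeneric("removeNode", function(x, parcel) standardGeneric("removeNode"))

#' @rdname removeEdge
#' @export
setGeneric("removeEdge", function(x, i, j) standardGeneric("removeEdge"))
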