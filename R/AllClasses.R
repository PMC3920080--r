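#' @import methods
NULL

setClassUnion("matrixOrNULL", c("matrix", "NULL"))

.CORTICAL_LOBES <- c("frontal", "insula", "limbic", "temporal", "parietal",
                     "occipital")
.ALL_LOBES <- c(.CORTICAL_LOBES, "subcortical", "cerebellum", "brainstem")
.HEMISPHERES <- c("left", "right", "midline")

#' Parcellation of the brain into network nodes
#'
#' An ordered catalogue of brain parcels. Each parcel has a unique label, a
#' hemisphere, a lobe, and an antero-posterior rank within its lobe. The row
#' order of the catalogue fixes the row/column order of every connectivity
#' matrix defined on it.
#'
#' The `parcels` slot is a data.frame with columns `label` (unique character),
#' `hemisphere` (one of left/right/midline), `lobe` (one of the six cortical
#' lobes, subcortical, cerebellum or brainstem) and `ap_rank` (integer
#' antero-posterior order within the lobe). Parcels with a cortical lobe are
#' the lesionable nodes of the node-removal analysis.
#'
#' @slot parcels data.frame of parcel metadata, one row per network node.
#' @seealso [defaultParcellation()], [genericParcellation()]
#' @export
setClass("Parcellation", representation(parcels = "data.frame"))

setValidity("Parcellation", function(object) {
    p <- object@parcels
    msg <- character()
    need <- c("label", "hemisphere", "lobe", "ap_rank")
    if (!all(need %in% names(p)))
        return(paste("parcels must have columns:", paste(need, collapse = ", ")))
    if (nrow(p) < 1)
        msg <- c(msg, "parcellation must contain at least one parcel")
    if (anyDuplicated(p$label))
        msg <- c(msg, "parcel labels must be unique")
    if (!all(p$hemisphere %in% .HEMISPHERES))
        msg <- c(msg, "hemisphere must be one of left/right/midline")
    if (!all(p$lobe %in% .ALL_LOBES))
        msg <- c(msg, paste("lobe must be one of:", paste(.ALL_LOBES, collapse = ", ")))
    if (length(msg)) msg else TRUE
})

#' A single subject's structural connectome
#'
#' Holds a symmetric, nonnegative, zero-diagonal weight matrix over a
#' [Parcellation-class], with optional companion matrices of mean fiber
#' length (cm) and mean fractional anisotropy. Companion entries are defined
#' (non-NA) only where the corresponding weight is positive.
#'
#' @slot subjectID character subject identifier.
#' @slot weights G x G numeric matrix; normalized fiber-count fractions or raw
#'   counts. Symmetric, finite, nonnegative, zero diagonal.
#' @slot lengths optional G x G matrix of mean fiber length in cm (NA where no
#'   connection exists).
#' @slot fa optional G x G matrix of mean fractional anisotropy in [0, 1].
#' @slot parcellation the [Parcellation-class] defining node identity/order.
#' @seealso [Connectome()], [readConnectome()], [buildConnectome()]
#' @export
setClass("Connectome",
    representation(subjectID = "character", weights = "matrix",
                   lengths = "matrixOrNULL", fa = "matrixOrNULL",
                   parcellation = "Parcellation"))

.checkCompanion <- function(m, w, name, lo = -Inf, hi = Inf) {
    msg <- character()
    if (!is.null(m)) {
        if (!identical(dim(m), dim(w)))
            msg <- c(msg, paste(name, "matrix dimensions must match weights"))
        else {
            if (any(!is.na(m[w == 0])))
                msg <- c(msg, paste(name, "must be NA where weight is zero"))
            vals <- m[w > 0]
            vals <- vals[!is.na(vals)]
            if (any(vals < lo | vals > hi))
                msg <- c(msg, paste(name, "values out of range"))
        }
    }
    msg
}

setValidity("Connectome", function(object) {
    w <- object@weights
    msg <- character()
    G <- nrow(object@parcellation@parcels)
    if (nrow(w) != ncol(w))
        return("weights must be a square matrix")
    if (nrow(w) != G)
        msg <- c(msg, sprintf("weights are %d x %d but parcellation has %d parcels",
                              nrow(w), ncol(w), G))
    if (!is.numeric(w) || any(!is.finite(w)))
        msg <- c(msg, "weights must be finite numeric")
    else {
        if (any(w < 0))
            msg <- c(msg, "weights must be nonnegative")
        if (any(diag(w) != 0))
            msg <- c(msg, "weights must have an exactly zero diagonal")
        if (!identical(w, t(w)))
            msg <- c(msg, "weights must be exactly symmetric")
        msg <- c(msg, .checkCompanion(object@lengths, w, "lengths", lo = 0))
        msg <- c(msg, .checkCompanion(object@fa, w, "fa", lo = 0, hi = 1))
    }
    if (length(msg)) msg else TRUE
})

#' A cohort of connectomes sharing one parcellation
#'
#' The unit of all statistics in the lesion analysis: N subjects' connectomes
#' over one shared [Parcellation-class].
#'
#' @slot connectomes list of [Connectome-class] objects.
#' @slot parcellation the shared [Parcellation-class].
#' @seealso [generateCohort()], [cohortAverage()], [readCohort()]
#' @export
setClass("Cohort",
    representation(connectomes = "list", parcellation = "Parcellation"))

setValidity("Cohort", function(object) {
    msg <- character()
    if (!all(vapply(object@connectomes, is, logical(1), class2 = "Connectome")))
        return("all cohort members must be Connectome objects")
    ref <- object@parcellation@parcels
    same <- vapply(object@connectomes,
                   function(x) identical(x@parcellation@parcels, ref), logical(1))
    if (!all(same))
        msg <- c(msg, "all connectomes must share the cohort's parcellation")
    ids <- vapply(object@connectomes, function(x) x@subjectID, character(1))
    if (anyDuplicated(ids))
        msg <- c(msg, "subject IDs must be unique")
    if (length(msg)) msg else TRUE
})

#' Specification of a synthetic connectome cohort
#'
#' Parameters of the seeded generator in [generateCohort()]: a
#' planted-partition modular base topology with log-normal base weights, per
#' subject multiplicative log-normal noise, optional per-subject edge dropout,
#' optional homotopic (left/right) weight coupling, and optional planted
#' inter-module bridge edges used as ground truth for scaffold recovery.
#'
#' @slot parcellation [Parcellation-class] defining G and node metadata.
#' @slot nSubjects number of subjects to generate.
#' @slot nModules number of modules in the planted-partition base graph.
#' @slot pWithin,pBetween within-/between-module edge probabilities.
#' @slot weightLogMean,weightLogSD log-normal base-weight parameters.
#' @slot subjectNoiseSD sd (log scale) of multiplicative inter-subject noise.
#' @slot plantedEdges integer matrix with two columns (1-based node indices);
#'   edges forced present in every subject.
#' @slot plantedBoost multiplier (>= 1) applied to planted base weights.
#' @slot edgeDropout per-subject probability of dropping a non-planted edge.
#' @slot symmetryRho correlation of homotopic left/right log-weights.
#' @slot seed master integer seed; same seed, same cohort.
#' @slot enforceConnectivity add deterministic bridges if the base graph is
#'   disconnected (disable only to exercise degenerate topologies).
#' @seealso [cohortSpec()], [generateCohort()], [plantedTruth()]
#' @export
setClass("CohortSpec",
    representation(parcellation = "Parcellation", nSubjects = "integer",
                   nModules = "integer", pWithin = "numeric",
                   pBetween = "numeric", weightLogMean = "numeric",
                   weightLogSD = "numeric", subjectNoiseSD = "numeric",
                   plantedEdges = "matrix", plantedBoost = "numeric",
                   edgeDropout = "numeric", symmetryRho = "numeric",
                   seed = "integer", enforceConnectivity = "logical"))

setValidity("CohortSpec", function(object) {
    msg <- character()
    G <- nrow(object@parcellation@parcels)
    if (G < 4) msg <- c(msg, "G must be at least 4")
    if (object@nSubjects < 1) msg <- c(msg, "nSubjects must be positive")
    if (object@nModules < 2) msg <- c(msg, "nModules must be >= 2")
    if (object@pWithin <= 0 || object@pWithin > 1)
        msg <- c(msg, "pWithin must lie in (0, 1]")
    if (object@pBetween < 0 || object@pBetween >= 1)
        msg <- c(msg, "pBetween must lie in [0, 1)")
    if (object@subjectNoiseSD < 0) msg <- c(msg, "subjectNoiseSD must be >= 0")
    if (object@plantedBoost < 1) msg <- c(msg, "plantedBoost must be >= 1")
    if (object@edgeDropout < 0 || object@edgeDropout >= 1)
        msg <- c(msg, "edgeDropout must lie in [0, 1)")
    if (object@symmetryRho < 0 || object@symmetryRho > 1)
        msg <- c(msg, "symmetryRho must lie in [0, 1]")
    pe <- object@plantedEdges
    if (nrow(pe) > 0) {
        if (ncol(pe) != 2) msg <- c(msg, "plantedEdges must have two columns")
        else if (any(pe < 1) || any(pe > G) || any(pe[, 1] == pe[, 2]))
            msg <- c(msg, "plantedEdges must be pairs of distinct node indices in 1..G")
    }
    if (length(msg)) msg else TRUE
})

#' Node-lesion sweep results
#'
#' Global metric values for every (lesioned cortical parcel, subject) pair and
#' the intact per-subject values. Produced by [nodeLesionSweep()].
#'
#' @slot values numeric array lesions x subjects x metrics; NA marks a metric
#'   undefined on the lesioned network (e.g. fully disconnected remainder).
#' @slot intact subjects x metrics matrix of intact-network values.
#' @slot lesioned integer indices (into the parcellation) of lesioned parcels.
#' @slot metrics metric names, in array order.
#' @slot parcellation shared [Parcellation-class].
#' @slot missingCount number of NA cells in `values`.
#' @export
setClass("NodeLesionTable",
    representation(values = "array", intact = "matrix", lesioned = "integer",
                   metrics = "character", parcellation = "Parcellation",
                   missingCount = "integer"))

#' Edge-lesion sweep results
#'
#' Post-lesion global feature vectors (assortativity, characteristic path
#' length, density, transitivity) for every unordered node pair and subject,
#' plus the intact vectors. Produced by [edgeLesionSweep()]. Lesioning a pair
#' absent in a subject reproduces that subject's intact vector exactly.
#'
#' @slot values numeric array pairs x subjects x 4.
#' @slot intact subjects x 4 matrix of intact feature vectors.
#' @slot pairs integer matrix (G(G-1)/2 rows, 2 columns) of node indices, i < j.
#' @slot edgePresence per-pair count of subjects with positive weight.
#' @slot metrics feature names.
#' @slot parcellation shared [Parcellation-class].
#' @slot missingCount number of NA cells in `values`.
#' @export
setClass("EdgeLesionTable",
    representation(values = "array", intact = "matrix", pairs = "matrix",
                   edgePresence = "integer", metrics = "character",
                   parcellation = "Parcellation", missingCount = "integer"))

#' Principal component analysis result
#'
#' @slot loadings variables x components matrix with orthonormal columns; each
#'   column is oriented so its largest-magnitude entry is positive.
#' @slot varianceFraction per-component fraction of total variance,
#'   nonincreasing.
#' @slot metric name of the metric the analysed matrix was built from.
#' @seealso [pcaLoadings()], [intactMetricPCA()]
#' @export
setClass("PCAResult",
    representation(loadings = "matrix", varianceFraction = "numeric",
                   metric = "character"))

#' Multilinear PCA result
#'
#' Result of [mpca()] on a rank-3 edge-effect tensor: one orthonormal
#' projection matrix per non-sample tensor mode, the fraction of total
#' (centered) variation captured by the multilinear projection, and the first
#' multilinear component's per-region loadings.
#'
#' @slot projections list of mode projection matrices (orthonormal columns).
#' @slot capturedVariation fraction in [0, 1] of total variation captured.
#' @slot mpc1Loadings first column of the mode-1 (region) projection matrix.
#' @slot iterations number of alternating refinement iterations performed.
#' @slot converged logical; FALSE if maxIter was reached first.
#' @slot variationTrace captured variation after each iteration (nondecreasing).
#' @slot imputedCount number of missing tensor entries imputed to zero.
#' @export
setClass("MPCAResult",
    representation(projections = "list", capturedVariation = "numeric",
                   mpc1Loadings = "numeric", iterations = "integer",
                   converged = "logical", variationTrace = "numeric",
                   imputedCount = "integer"))
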