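#' Specify a synthetic cohort
#'
#' Builds a [CohortSpec-class] describing a seeded synthetic cohort of
#' weighted connectomes with the statistical structure the lesion analysis
#' assumes: a modular (planted-partition) base topology shared by all
#' subjects, log-normal base weights, independent multiplicative log-normal
#' inter-subject noise per edge, and optional planted inter-module bridge
#' edges boosted in weight — the ground truth for scaffold recovery
#' experiments. Defaults emulate a resting healthy-adult DTI cohort: the
#' 165-parcel default parcellation, 110 subjects, six modules, within-module
#' edge probability 0.6, between-module 0.05, and inter-subject noise of
#' sd 0.5 on the log scale (weight CV about 50%, typical of streamline
#' counts).
#'
#' @param G reduced parcel count; builds a [genericParcellation()] when
#'   `parcellation` is not given.
#' @param parcellation explicit [Parcellation-class] (default: the 165-parcel
#'   scheme when `G` is also NULL).
#' @param nSubjects number of subjects (default 110).
#' @param nModules number of modules (default 6).
#' @param pWithin,pBetween within-/between-module edge probabilities.
#' @param weightLogMean,weightLogSD base-weight log-normal parameters.
#' @param subjectNoiseSD sd of the multiplicative log-normal subject noise.
#' @param plantedEdges two-column matrix of node index pairs (1-based) forced
#'   present in every subject.
#' @param plantedBoost weight multiplier (>= 1) for planted edges.
#' @param edgeDropout per-subject probability of dropping a non-planted edge.
#' @param symmetryRho correlation between homotopic left/right log-weights
#'   (applies only when the parcellation has matching `r*`/`l*` labels).
#' @param seed master integer seed.
#' @param enforceConnectivity deterministically bridge disconnected base
#'   components (default TRUE).
#' @return a validated [CohortSpec-class].
#' @seealso [generateCohort()], [plantedTruth()]
#' @export
cohortSpec <- function(G = NULL, parcellation = NULL, nSubjects = 110,
                       nModules = 6, pWithin = 0.6, pBetween = 0.05,
                       weightLogMean = 0, weightLogSD = 1,
                       subjectNoiseSD = 0.5,
                       plantedEdges = matrix(integer(0), ncol = 2),
                       plantedBoost = 1, edgeDropout = 0, symmetryRho = 0,
                       seed = 1, enforceConnectivity = TRUE) {
    if (is.null(parcellation))
        parcellation <- if (is.null(G)) defaultParcellation()
                        else genericParcellation(G)
    plantedEdges <- matrix(as.integer(plantedEdges),
                           ncol = max(2, ncol(plantedEdges)))
    new("CohortSpec", parcellation = parcellation,
        nSubjects = as.integer(nSubjects), nModules = as.integer(nModules),
        pWithin = pWithin, pBetween = pBetween, weightLogMean = weightLogMean,
        weightLogSD = weightLogSD, subjectNoiseSD = subjectNoiseSD,
        plantedEdges = plantedEdges, plantedBoost = plantedBoost,
        edgeDropout = edgeDropout, symmetryRho = symmetryRho,
        seed = as.integer(seed), enforceConnectivity = enforceConnectivity)
}

#' Ground-truth planted bridge edges of a cohort spec
#'
#' @param spec a [CohortSpec-class].
#' @return the cohort spec's planted edges as a two-column integer matrix (possibly
#'   zero rows), with i < j per row.
#' @export
plantedTruth <- function(spec) {
    stopifnot(is(spec, "CohortSpec"))
    pe <- spec@plantedEdges
    if (nrow(pe) > 0)
        pe <- cbind(pmin(pe[, 1], pe[, 2]), pmax(pe[, 1], pe[, 2]))
    colnames(pe) <- c("i", "j")
    pe
}

#' Module assignment: contiguous near-equal blocks
#' @noRd
.moduleAssignment <- function(G, nModules) {
    sort(rep_len(seq_len(nModules), G))
}

#' Homotopic partner index per parcel (NA when none), via r*/l* label swap
#' @noRd
.mirrorIndex <- function(parcellation) {
    labels <- parcelLabels(parcellation)
    swapped <- ifelse(grepl("^r", labels), sub("^r", "l", labels),
                      ifelse(grepl("^l", labels), sub("^l", "r", labels), NA))
    match(swapped, labels)
}

#' Generate a synthetic cohort
#'
#' Draws the base topology and base weights once from the master seed, then
#' gives every subject its own random substream (drawn from the master
#' stream), so the cohort is reproducible and independent of subject
#' iteration order. Subjects share the base topology and differ by
#' multiplicative log-normal weight noise, plus optional per-subject edge
#' dropout; every subject is normalized to unit upper-triangle sum. If the
#' base graph is disconnected and `enforceConnectivity` is set, the
#' lowest-index node of each extra component is joined to the lowest-index
#' node of the first component (the added edge draws its weight like any
#' other base edge).
#'
#' @param spec a [CohortSpec-class].
#' @return a [Cohort-class] of `nSubjects` normalized connectomes.
#' @examples
#' spec <- cohortSpec(G = 20, nSubjects = 5, nModules = 2, seed = 7)
#' cohort <- generateCohort(spec)
#' nSubjects(cohort)
#' @export
generateCohort <- function(spec) {
    stopifnot(is(spec, "CohortSpec"))
    validObject(spec)
    G <- nParcels(spec@parcellation)
    mod <- .moduleAssignment(G, spec@nModules)
    pairs <- which(upper.tri(matrix(0, G, G)), arr.ind = TRUE)
    pairs <- pairs[order(pairs[, 1], pairs[, 2]), , drop = FALSE]
    pWire <- ifelse(mod[pairs[, 1]] == mod[pairs[, 2]], spec@pWithin,
                    spec@pBetween)

    set.seed(spec@seed)
    present <- stats::runif(nrow(pairs)) < pWire
    planted <- rep(FALSE, nrow(pairs))
    pt <- plantedTruth(spec)
    if (nrow(pt) > 0) {
        key <- (pairs[, 1] - 1L) * G + pairs[, 2]
        pkey <- (pt[, 1] - 1L) * G + pt[, 2]
        planted <- key %in% pkey
        present <- present | planted
    }

    if (spec@enforceConnectivity) {
        repeat {
            A <- matrix(0L, G, G)
            A[pairs[present, , drop = FALSE]] <- 1L
            A <- A + t(A)
            comp <- igraph::components(igraph::graph_from_adjacency_matrix(
                A, mode = "undirected"))
            if (comp$no == 1L) break
            first <- which(comp$membership == 1L)[1]
            other <- which(comp$membership == 2L)[1]
            i <- min(first, other); j <- max(first, other)
            present[pairs[, 1] == i & pairs[, 2] == j] <- TRUE
        }
    }

    logW <- rep(NA_real_, nrow(pairs))
    logW[present] <- stats::rnorm(sum(present), spec@weightLogMean,
                                  spec@weightLogSD)
    if (spec@symmetryRho > 0) {
        mir <- .mirrorIndex(spec@parcellation)
        if (any(!is.na(mir))) {
            mi <- mir[pairs[, 1]]; mj <- mir[pairs[, 2]]
            ok <- !is.na(mi) & !is.na(mj) & mi != mj
            a <- pmin(mi, mj); b <- pmax(mi, mj)
            key <- (pairs[, 1] - 1L) * G + pairs[, 2]
            mkey <- ifelse(ok, (a - 1L) * G + b, NA)
            partner <- match(mkey, key)
            # blend each edge with its already-drawn homotopic partner once
            doBlend <- which(!is.na(partner) & partner < seq_along(key) &
                             present & present[ifelse(is.na(partner), 1L, partner)])
            rho <- spec@symmetryRho
            mu <- spec@weightLogMean
            logW[doBlend] <- mu + rho * (logW[partner[doBlend]] - mu) +
                sqrt(1 - rho^2) * (logW[doBlend] - mu)
        }
    }
    boost <- ifelse(planted, log(spec@plantedBoost), 0)
    baseW <- exp(logW + boost)

    subjectSeeds <- sample.int(.Machine$integer.max - 1L, spec@nSubjects)
    presentIdx <- which(present)
    cons <- lapply(seq_len(spec@nSubjects), function(n) {
        set.seed(subjectSeeds[n])
        noise <- exp(stats::rnorm(length(presentIdx), 0, spec@subjectNoiseSD))
        keep <- rep(TRUE, length(presentIdx))
        if (spec@edgeDropout > 0)
            keep <- planted[presentIdx] |
                (stats::runif(length(presentIdx)) >= spec@edgeDropout)
        w <- matrix(0, G, G)
        sel <- presentIdx[keep]
        w[pairs[sel, , drop = FALSE]] <- baseW[sel] * noise[keep]
        w <- w + t(w)
        normalizeConnectome(Connectome(w, spec@parcellation,
                                       subjectID = sprintf("S%03d", n)))
    })
    Cohort(cons)
}

#' Write / read a cohort spec as a plain-text key-value file
#'
#' The parcellation is recorded as `default` (the 165-parcel scheme) or
#' `generic:<G>`; custom parcellations should be saved separately with
#' [writeParcellation()].
#'
#' @param spec a [CohortSpec-class].
#' @param path file path.
#' @return `readCohortSpec()` returns a [CohortSpec-class].
#' @export
writeCohortSpec <- function(spec, path) {
    stopifnot(is(spec, "CohortSpec"))
    p <- spec@parcellation@parcels
    parc <- if (identical(p, defaultParcellation()@parcels)) "default"
            else if (identical(p, genericParcellation(nrow(p))@parcels))
                sprintf("generic:%d", nrow(p))
            else stop("custom parcellations are not serializable here; ",
                      "use writeParcellation()")
    pe <- spec@plantedEdges
    lines <- c(
        sprintf("parcellation=%s", parc),
        sprintf("nSubjects=%d", spec@nSubjects),
        sprintf("nModules=%d", spec@nModules),
        sprintf("pWithin=%.17g", spec@pWithin),
        sprintf("pBetween=%.17g", spec@pBetween),
        sprintf("weightLogMean=%.17g", spec@weightLogMean),
        sprintf("weightLogSD=%.17g", spec@weightLogSD),
        sprintf("subjectNoiseSD=%.17g", spec@subjectNoiseSD),
        sprintf("plantedEdges=%s",
                paste(sprintf("%d:%d", pe[, 1], pe[, 2]), collapse = ",")),
        sprintf("plantedBoost=%.17g", spec@plantedBoost),
        sprintf("edgeDropout=%.17g", spec@edgeDropout),
        sprintf("symmetryRho=%.17g", spec@symmetryRho),
        sprintf("seed=%d", spec@seed),
        sprintf("enforceConnectivity=%s", spec@enforceConnectivity))
    writeLines(lines, path)
    invisible(path)
}

#' @rdname writeCohortSpec
#' @export
readCohortSpec <- function(path) {
    lines <- readLines(path)
    lines <- lines[nzchar(lines) & !grepl("^#", lines)]
    kv <- strsplit(lines, "=", fixed = TRUE)
    vals <- stats::setNames(vapply(kv, function(x)
        paste(x[-1], collapse = "="), character(1)),
        vapply(kv, `[[`, character(1), 1))
    parc <- if (identical(vals[["parcellation"]], "default"))
        defaultParcellation()
    else genericParcellation(as.integer(sub("^generic:", "",
                                            vals[["parcellation"]])))
    pe <- matrix(integer(0), ncol = 2)
    if (nzchar(vals[["plantedEdges"]])) {
        parts <- strsplit(strsplit(vals[["plantedEdges"]], ",")[[1]], ":")
        pe <- do.call(rbind, lapply(parts, as.integer))
    }
    cohortSpec(parcellation = parc,
               nSubjects = as.integer(vals[["nSubjects"]]),
               nModules = as.integer(vals[["nModules"]]),
               pWithin = as.numeric(vals[["pWithin"]]),
               pBetween = as.numeric(vals[["pBetween"]]),
               weightLogMean = as.numeric(vals[["weightLogMean"]]),
               weightLogSD = as.numeric(vals[["weightLogSD"]]),
               subjectNoiseSD = as.numeric(vals[["subjectNoiseSD"]]),
               plantedEdges = pe,
               plantedBoost = as.numeric(vals[["plantedBoost"]]),
               edgeDropout = as.numeric(vals[["edgeDropout"]]),
               symmetryRho = as.numeric(vals[["symmetryRho"]]),
               seed = as.integer(vals[["seed"]]),
               enforceConnectivity = as.logical(vals[["enforceConnectivity"]]))
}
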