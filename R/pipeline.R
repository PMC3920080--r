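#' Configuration for a full lesion-analysis run
#'
#' @param cohortSpec a [CohortSpec-class] to generate a synthetic cohort, or
#'   NULL when `cohortDir` is given.
#' @param cohortDir directory bundle readable by [readCohort()].
#' @param alpha lenient family-wise level (full scaffold; default 0.05).
#' @param alphaStringent stringent level (core scaffold; default 0.0001).
#' @param nodalMetric nodal metric for the edge-effect tensor.
#' @param nComponents PCA components to keep.
#' @param runTensor run the edge-effect tensor + MPCA stage (cubic in G;
#'   intended for modest parcel counts).
#' @param seed integer seed recorded with the run; overrides the cohort
#'   spec's seed so one number reproduces the whole pipeline.
#' @return a `list` of class `lesionRunConfig`.
#' @seealso [runPipeline()]
#' @export
lesionRunConfig <- function(cohortSpec = NULL, cohortDir = NULL,
                            alpha = 0.05, alphaStringent = 1e-4,
                            nodalMetric = "eccentricity", nComponents = 3,
                            runTensor = TRUE, seed = 1) {
    if (is.null(cohortSpec) && is.null(cohortDir))
        stop("provide either a cohortSpec or a cohortDir")
    structure(list(cohortSpec = cohortSpec, cohortDir = cohortDir,
                   alpha = alpha, alphaStringent = alphaStringent,
                   nodalMetric = nodalMetric, nComponents = nComponents,
                   runTensor = runTensor, seed = as.integer(seed)),
              class = "lesionRunConfig")
}

.stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
        stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
             call. = FALSE))
}

#' Run the full lesion-analysis pipeline
#'
#' Executes cohort acquisition (generation or loading), the node- and
#' edge-lesion sweeps, the paired univariate and multivariate tests at both
#' alpha levels, scaffold extraction, and the decompositions (lesion-effect
#' correlation matrix + PCA, intact-metric PCAs + comparison, and optionally
#' the edge-effect tensor + MPCA). When `outDir` is given, writes TSV tables
#' for every stage, a Circos-compatible link file for the scaffold, the
#' resolved configuration, and a JSON run summary recording alpha, the
#' Bonferroni m, N, G, significance counts, variance fractions and
#' degeneracy counts. Rerunning with the same config reproduces all outputs
#' bit-exactly.
#'
#' @param config a config from [lesionRunConfig()].
#' @param outDir optional output directory.
#' @return (invisibly) a list with the cohort, sweep tables, test tables,
#'   scaffolds, decomposition results and the `summary` list.
#' @examples
#' cfg <- lesionRunConfig(cohortSpec = cohortSpec(G = 12, nSubjects = 6,
#'                                                nModules = 2, seed = 5),
#'                        runTensor = FALSE, seed = 5)
#' res <- runPipeline(cfg)
#' res$summary$nSignificantEdges
#' @export
runPipeline <- function(config, outDir = NULL) {
    stopifnot(inherits(config, "lesionRunConfig"))
    cohort <- .stage("cohort", {
        if (!is.null(config$cohortSpec)) {
            spec <- config$cohortSpec
            spec@seed <- config$seed
            generateCohort(spec)
        } else readCohort(config$cohortDir)
    })
    G <- nParcels(cohort)
    N <- nSubjects(cohort)

    nlt <- .stage("nodeSweep", nodeLesionSweep(cohort))
    elt <- .stage("edgeSweep", edgeLesionSweep(cohort))

    nodeTests <- .stage("nodeTests", pairedTNode(nlt, alpha = config$alpha))
    edgeTests <- .stage("edgeTests", edgeSignificance(elt, alpha = config$alpha))
    scaffold <- .stage("scaffold", extractScaffold(edgeTests, config$alpha))
    scaffoldStringent <- .stage("scaffoldStringent",
                                extractScaffold(edgeTests,
                                                config$alphaStringent))

    R <- .stage("correlation", lesionCorrelationMatrix(nlt, "lambda"))
    lesionPCA <- .stage("pca",
        pcaLoadings(R, config$nComponents, metric = "lambda"))
    # intact metrics with zero variance everywhere (e.g. binary-topology
    # metrics in a cohort sharing one topology) are skipped, not fatal
    intactMetrics <- c("betweenness", "clustering", "eccentricity")
    intactPCAs <- .stage("intactPCA", lapply(intactMetrics, function(m)
        tryCatch(intactMetricPCA(cohort, m, config$nComponents),
                 error = function(e) NULL)))
    skippedIntact <- intactMetrics[vapply(intactPCAs, is.null, logical(1))]
    intactPCAs <- intactPCAs[!vapply(intactPCAs, is.null, logical(1))]
    comparison <- if (length(intactPCAs) > 0)
        .stage("comparison", compareLesionVsIntact(lesionPCA, intactPCAs))
    else NULL

    tensor <- mp <- NULL
    if (isTRUE(config$runTensor)) {
        tensor <- .stage("tensor", edgeEffectTensor(cohort, config$nodalMetric))
        mp <- .stage("mpca", mpca(tensor))
    }

    summary <- list(
        G = G, N = N, seed = config$seed,
        alpha = config$alpha, alphaStringent = config$alphaStringent,
        mEdgeComparisons = attr(edgeTests, "m"),
        mNodeComparisons = attr(nodeTests, "m"),
        bonferroniEdge = bonferroniThreshold(config$alpha,
                                             attr(edgeTests, "m")),
        bonferroniEdgeStringent = bonferroniThreshold(config$alphaStringent,
                                                      attr(edgeTests, "m")),
        nLesionedParcels = length(nlt@lesioned),
        nSignificantNodes = sum(nodeTests$significant),
        nDegenerateNodeTests = sum(nodeTests$degenerate),
        nTestableEdges = sum(edgeTests$testable),
        nSignificantEdges = nrow(scaffold),
        nSignificantEdgesStringent = nrow(scaffoldStringent),
        nodeSweepMissing = nlt@missingCount,
        edgeSweepMissing = elt@missingCount,
        pcaVarianceFractions = lesionPCA@varianceFraction[
            seq_len(min(config$nComponents,
                        length(lesionPCA@varianceFraction)))],
        skippedIntactMetrics = skippedIntact,
        maxLesionIntactCorrelation = if (!is.null(comparison))
            attr(comparison, "maxAbs") else NA,
        mpc1CapturedVariation = if (!is.null(mp)) mp@capturedVariation else NA,
        mpcaImputed = if (!is.null(mp)) mp@imputedCount else NA)

    if (!is.null(outDir)) {
        dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
        wtsv <- function(x, f) utils::write.table(
            x, file.path(outDir, f), sep = "\t", quote = FALSE,
            row.names = FALSE)
        writeParcellation(parcellation(cohort),
                          file.path(outDir, "parcels.tsv"))
        wtsv(nodeTests, "node_tests.tsv")
        wtsv(edgeTests, "edge_tests.tsv")
        wtsv(scaffold, "scaffold.tsv")
        wtsv(scaffoldStringent, "scaffold_stringent.tsv")
        writeCircosLinks(scaffold, file.path(outDir, "circos_links.tsv"))
        ld <- data.frame(parcel = rownames(R), lesionPCA@loadings)
        colnames(ld) <- c("parcel",
                          paste0("PC", seq_len(ncol(lesionPCA@loadings))))
        wtsv(ld, "pca_loadings.tsv")
        utils::write.table(round(R, 10), file.path(outDir, "R_matrix.tsv"),
                           sep = "\t", quote = FALSE)
        if (!is.null(mp))
            wtsv(data.frame(parcel = parcelLabels(cohort@parcellation),
                            mpc1 = mp@mpc1Loadings), "mpc1_loadings.tsv")
        if (!is.null(config$cohortSpec))
            writeCohortSpec({s <- config$cohortSpec; s@seed <- config$seed; s},
                            file.path(outDir, "cohort_spec.txt"))
        jsonlite::write_json(summary, file.path(outDir, "summary.json"),
                             auto_unbox = TRUE, digits = NA, pretty = TRUE)
    }
    invisible(list(cohort = cohort, nodeTable = nlt, edgeTable = elt,
                   nodeTests = nodeTests, edgeTests = edgeTests,
                   scaffold = scaffold, scaffoldStringent = scaffoldStringent,
                   R = R, lesionPCA = lesionPCA, intactPCAs = intactPCAs,
                   comparison = comparison, tensor = tensor, mpca = mp,
                   summary = summary))
}
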