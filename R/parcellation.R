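.LOBE_ABBR <- c(frontal = "Fro", insula = "Ins", limbic = "Lim",
                temporal = "Tem", parietal = "Par", occipital = "Occ",
                subcortical = "Sub", cerebellum = "Cer")
.DEFAULT_LOBE_COUNTS <- c(frontal = 21, insula = 8, limbic = 8, temporal = 11,
                          parietal = 11, occipital = 15, subcortical = 7,
                          cerebellum = 1)

#' Construct a Parcellation
#'
#' @param parcels data.frame with columns `label`, `hemisphere`, `lobe`,
#'   `ap_rank`. Row order defines matrix ordering.
#' @return a [Parcellation-class].
#' @export
Parcellation <- function(parcels) {
    parcels$label <- as.character(parcels$label)
    parcels$hemisphere <- as.character(parcels$hemisphere)
    parcels$lobe <- as.character(parcels$lobe)
    parcels$ap_rank <- as.integer(parcels$ap_rank)
    rownames(parcels) <- NULL
    new("Parcellation", parcels = parcels[, c("label", "hemisphere", "lobe",
                                              "ap_rank")])
}

.hemisphereBlock <- function(hemi) {
    prefix <- substr(hemi, 1, 1)
    blocks <- lapply(names(.DEFAULT_LOBE_COUNTS), function(lobe) {
        n <- .DEFAULT_LOBE_COUNTS[[lobe]]
        data.frame(label = sprintf("%s%s%02d", prefix, .LOBE_ABBR[[lobe]],
                                   seq_len(n)),
                   hemisphere = hemi, lobe = lobe, ap_rank = seq_len(n),
                   stringsAsFactors = FALSE)
    })
    do.call(rbind, blocks)
}

#' The default 165-parcel whole-brain parcellation
#'
#' Per hemisphere: 74 cortical parcels (frontal 21, insula 8, limbic 8,
#' temporal 11, parietal 11, occipital 15), 7 subcortical parcels and the
#' cerebellum; plus one midline brainstem parcel, for 165 parcels in total and
#' 148 cortical parcels across hemispheres. Right-hemisphere parcels come
#' first, then left, each lobe ordered by antero-posterior rank; the brainstem
#' is last. Labels are systematic placeholders (e.g. `rFro01`): the anatomical
#' abbreviation catalogue belongs to the atlas the user works with and can be
#' supplied via [Parcellation()] or [readParcellation()].
#'
#' @return a [Parcellation-class] with 165 parcels.
#' @examples
#' p <- defaultParcellation()
#' nParcels(p)                 # 165
#' length(corticalIndices(p))  # 148
#' @export
defaultParcellation <- function() {
    Parcellation(rbind(.hemisphereBlock("right"), .hemisphereBlock("left"),
                       data.frame(label = "bstem", hemisphere = "midline",
                                  lobe = "brainstem", ap_rank = 1L,
                                  stringsAsFactors = FALSE)))
}

#' A minimal G-node parcellation for reduced-size analyses
#'
#' All parcels are marked cortical (right frontal) so that every node is
#' lesionable; intended for synthetic cohorts and tests at small G.
#'
#' @param G number of parcels (>= 1).
#' @return a [Parcellation-class].
#' @export
genericParcellation <- function(G) {
    stopifnot(G >= 1)
    Parcellation(data.frame(label = sprintf("n%03d", seq_len(G)),
                            hemisphere = "right", lobe = "frontal",
                            ap_rank = seq_len(G), stringsAsFactors = FALSE))
}

#' @rdname accessors
#' @export
setMethod("nParcels", "Parcellation", function(object) nrow(object@parcels))

#' @rdname accessors
#' @export
setMethod("parcelLabels", "Parcellation", function(object) object@parcels$label)

#' @rdname accessors
#' @export
setMethod("corticalIndices", "Parcellation",
    function(object) which(object@parcels$lobe %in% .CORTICAL_LOBES))

#' @rdname accessors
#' @export
setMethod("nParcels", "Connectome", function(object) nParcels(object@parcellation))

#' @rdname accessors
#' @export
setMethod("parcelLabels", "Connectome",
    function(object) parcelLabels(object@parcellation))

#' @rdname accessors
#' @export
setMethod("corticalIndices", "Connectome",
    function(object) corticalIndices(object@parcellation))

setMethod("show", "Parcellation", function(object) {
    p <- object@parcels
    cat(sprintf("Parcellation with %d parcels (%d cortical)\n", nrow(p),
                sum(p$lobe %in% .CORTICAL_LOBES)))
    tab <- table(p$hemisphere)
    cat("  hemispheres:", paste(sprintf("%s=%d", names(tab), tab),
                                collapse = ", "), "\n")
})

#' Read / write a parcel metadata table
#'
#' Tab-separated with columns `id` (0-based position, the on-disk contract),
#' `label`, `hemisphere`, `lobe`, `ap_rank`. The in-memory API is 1-based; the
#' `id` column is only used to check that the file rows are in matrix order.
#'
#' @param path file path.
#' @param x a [Parcellation-class] (for writing).
#' @return `readParcellation()` returns a [Parcellation-class];
#'   `writeParcellation()` returns `path` invisibly.
#' @export
readParcellation <- function(path) {
    tab <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE)
    need <- c("id", "label", "hemisphere", "lobe", "ap_rank")
    if (!all(need %in% names(tab)))
        stop("parcel table must have columns: ", paste(need, collapse = ", "))
    if (!identical(as.integer(tab$id), seq_len(nrow(tab)) - 1L))
        stop("parcel table ids must be the contiguous 0-based sequence 0..G-1 ",
             "in row order")
    Parcellation(tab)
}

#' @rdname readParcellation
#' @export
writeParcellation <- function(x, path) {
    stopifnot(is(x, "Parcellation"))
    tab <- cbind(id = seq_len(nParcels(x)) - 1L, x@parcels)
    utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(path)
}
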