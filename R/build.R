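#' Build a connectome from a streamline-endpoint table
#'
#' Converts a per-fiber table (endpoint parcels, length in cm, FA) into a
#' subject's weight, mean-length and mean-FA matrices. Fibers shorter than
#' `minLengthCM` are discarded (strictly shorter: a fiber of exactly the
#' cutoff length is kept), as are fibers whose two endpoints fall in the same
#' parcel — only fibers joining two distinct parcels count. The weight entry
#' for a pair is the surviving fiber count; length/FA entries are the mean
#' over surviving fibers of that pair.
#'
#' @param fiberTable data.frame with columns `parcel_a`, `parcel_b` (labels,
#'   or integer 0-based ids matching the on-disk parcel-table contract),
#'   `length_cm` (> 0) and `fa` (in [0, 1]). An empty table yields the valid
#'   all-zero connectome.
#' @param parcellation a [Parcellation-class].
#' @param minLengthCM minimum fiber length retained, in cm (default 1.5).
#' @param subjectID subject identifier.
#' @return a [Connectome-class] with raw fiber counts as weights (see
#'   [normalizeConnectome()]).
#' @export
buildConnectome <- function(fiberTable, parcellation, minLengthCM = 1.5,
                            subjectID = "subject") {
    stopifnot(is(parcellation, "Parcellation"))
    G <- nParcels(parcellation)
    labels <- parcelLabels(parcellation)
    ft <- as.data.frame(fiberTable)
    need <- c("parcel_a", "parcel_b", "length_cm", "fa")
    if (!all(need %in% names(ft)))
        stop("fiber table must have columns: ", paste(need, collapse = ", "))
    toIndex <- function(v) {
        if (is.numeric(v)) {
            idx <- as.integer(v) + 1L   # 0-based file contract
        } else {
            idx <- match(as.character(v), labels)
        }
        if (any(is.na(idx)) || any(idx < 1L) || any(idx > G))
            stop("fiber table refers to unknown parcels")
        idx
    }
    w <- matrix(0, G, G)
    len <- matrix(NA_real_, G, G)
    fam <- matrix(NA_real_, G, G)
    if (nrow(ft) > 0) {
        if (any(ft$length_cm <= 0)) stop("fiber lengths must be positive")
        if (any(ft$fa < 0 | ft$fa > 1)) stop("FA values must lie in [0, 1]")
        a <- toIndex(ft$parcel_a)
        b <- toIndex(ft$parcel_b)
        keep <- ft$length_cm >= minLengthCM & a != b
        a <- a[keep]; b <- b[keep]
        l <- ft$length_cm[keep]; f <- ft$fa[keep]
        if (length(a) > 0) {
            i <- pmin(a, b); j <- pmax(a, b)
            key <- (i - 1L) * G + j
            cnt <- tapply(rep(1, length(key)), key, sum)
            ml <- tapply(l, key, mean)
            mf <- tapply(f, key, mean)
            kk <- as.integer(names(cnt))
            ii <- (kk - 1L) %/% G + 1L
            jj <- (kk - 1L) %% G + 1L
            for (q in seq_along(kk)) {
                w[ii[q], jj[q]] <- w[jj[q], ii[q]] <- cnt[q]
                len[ii[q], jj[q]] <- len[jj[q], ii[q]] <- ml[q]
                fam[ii[q], jj[q]] <- fam[jj[q], ii[q]] <- mf[q]
            }
        }
    }
    Connectome(w, parcellation, subjectID = subjectID, lengths = len, fa = fam)
}

#' Normalize a connectome's weights to within-subject fractions
#'
#' Divides every weight by the total over unordered pairs (equal to the
#' subject's total surviving fiber count when weights are raw counts), so the
#' upper-triangle sum becomes exactly 1. Length and FA companions are
#' unchanged. Idempotent up to floating point. An all-zero matrix (no fibers)
#' is an error.
#'
#' @param x a [Connectome-class].
#' @return a normalized [Connectome-class].
#' @export
normalizeConnectome <- function(x) {
    stopifnot(is(x, "Connectome"))
    w <- weights(x)
    total <- sum(w[upper.tri(w)])
    if (total <= 0)
        stop("cannot normalize a connectome with no positive weights")
    Connectome(w / total, parcellation(x), subjectID = subjectID(x),
               lengths = x@lengths, fa = x@fa)
}

#' Read a fiber table from TSV
#'
#' Columns `parcel_a`, `parcel_b`, `length_cm`, `fa`; endpoint parcels as
#' labels or 0-based ids (the on-disk contract).
#'
#' @param path file path.
#' @return a data.frame.
#' @export
readFiberTable <- function(path) {
    utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE)
}
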