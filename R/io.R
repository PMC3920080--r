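#' Read / write a connectome weight matrix
#'
#' Connectome matrices are stored as tab-separated full square matrices with a
#' header row of parcel labels, written with 17 significant digits so a
#' write/read round trip reproduces the weights bit-exactly. On read, the
#' matrix must match the parcel table's dimension and label order; asymmetry,
#' negative entries and NaN/NA entries are rejected (never repaired).
#'
#' @param matrixFile path to the weight matrix TSV.
#' @param parcellation a [Parcellation-class] (or path to a parcel table,
#'   see [readParcellation()]).
#' @param subjectID subject identifier for the returned object.
#' @param lengthsFile,faFile optional paths to companion matrices in the same
#'   format (empty entries are NA).
#' @return `readConnectome()` returns a [Connectome-class].
#' @export
readConnectome <- function(matrixFile, parcellation, subjectID = NULL,
                           lengthsFile = NULL, faFile = NULL) {
    if (is.character(parcellation))
        parcellation <- readParcellation(parcellation)
    labels <- parcelLabels(parcellation)
    w <- .readSquareMatrix(matrixFile, labels)
    if (any(is.na(w))) stop("weight matrix contains NA/NaN entries")
    if (any(w < 0)) stop("weight matrix contains negative entries")
    if (!identical(w, t(w)))
        stop("weight matrix is asymmetric; refusing to symmetrize")
    if (any(diag(w) != 0)) stop("weight matrix diagonal must be zero")
    if (is.null(subjectID))
        subjectID <- sub("\\.[^.]*$", "", basename(matrixFile))
    lengths <- if (!is.null(lengthsFile)) .readSquareMatrix(lengthsFile, labels)
    fa <- if (!is.null(faFile)) .readSquareMatrix(faFile, labels)
    Connectome(w, parcellation, subjectID = subjectID, lengths = lengths,
               fa = fa)
}

.readSquareMatrix <- function(path, labels) {
    tab <- utils::read.delim(path, sep = "\t", check.names = FALSE,
                             stringsAsFactors = FALSE)
    m <- as.matrix(tab)
    if (nrow(m) != ncol(m))
        stop("matrix in ", path, " is not square: ", nrow(m), " x ", ncol(m))
    if (nrow(m) != length(labels))
        stop("matrix dimension ", nrow(m), " does not match parcel table (",
             length(labels), " parcels)")
    if (!identical(colnames(m), labels))
        stop("matrix header labels do not match the parcel table order")
    storage.mode(m) <- "double"
    dimnames(m) <- list(labels, labels)
    m
}

.writeSquareMatrix <- function(m, path) {
    txt <- matrix(sprintf("%.17g", m), nrow = nrow(m))
    txt[is.na(m)] <- "NA"
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(paste(colnames(m), collapse = "\t"), con)
    writeLines(apply(txt, 1, paste, collapse = "\t"), con)
    invisible(path)
}

#' @rdname readConnectome
#' @param x a [Connectome-class] to write.
#' @param path output path for the weight matrix.
#' @export
writeConnectome <- function(x, path, lengthsFile = NULL, faFile = NULL) {
    stopifnot(is(x, "Connectome"))
    .writeSquareMatrix(weights(x), path)
    if (!is.null(lengthsFile) && !is.null(x@lengths))
        .writeSquareMatrix(x@lengths, lengthsFile)
    if (!is.null(faFile) && !is.null(x@fa))
        .writeSquareMatrix(x@fa, faFile)
    invisible(path)
}

#' Read / write a cohort bundle
#'
#' A cohort is bundled as a directory holding `parcels.tsv` (the parcel
#' metadata table), one `<subjectID>.tsv` weight matrix per subject, and a
#' `subjects.txt` manifest fixing subject order.
#'
#' @param dir bundle directory.
#' @param cohort a [Cohort-class] (for writing).
#' @return `readCohort()` returns a [Cohort-class]; `writeCohort()` returns
#'   `dir` invisibly.
#' @export
readCohort <- function(dir) {
    p <- readParcellation(file.path(dir, "parcels.tsv"))
    ids <- readLines(file.path(dir, "subjects.txt"))
    cons <- lapply(ids, function(id)
        readConnectome(file.path(dir, paste0(id, ".tsv")), p, subjectID = id))
    Cohort(cons)
}

#' @rdname readCohort
#' @export
writeCohort <- function(cohort, dir) {
    stopifnot(is(cohort, "Cohort"))
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    writeParcellation(parcellation(cohort), file.path(dir, "parcels.tsv"))
    ids <- subjectID(cohort)
    writeLines(ids, file.path(dir, "subjects.txt"))
    for (con in connectomes(cohort))
        writeConnectome(con, file.path(dir, paste0(subjectID(con), ".tsv")))
    invisible(dir)
}

#' Export scaffold edges as a Circos-compatible link file
#'
#' One line per edge: the two parcel labels and the edge's F statistic
#' (usable as link weight/opacity in a connectogram).
#'
#' @param scaffold data.frame from [extractScaffold()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeCircosLinks <- function(scaffold, path) {
    utils::write.table(scaffold[, c("label_a", "label_b", "F")], path,
                       sep = "\t", quote = FALSE, row.names = FALSE,
                       col.names = c("parcel_a", "parcel_b", "F"))
    invisible(path)
}
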