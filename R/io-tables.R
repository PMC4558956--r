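#' Write / read a count table
#'
#' Tab-separated matrix with a header row and row keys (gene ids or
#' "G1|G2" MMG serialisations) in the first column.  Integer counts
#' round-trip exactly.
#'
#' @param m matrix with rownames (row keys) and colnames (sample names).
#' @param path file path.
#' @return \code{writeCountTable} returns the path invisibly;
#'   \code{readCountTable} returns the matrix.
#' @export
writeCountTable <- function(m, path) {
    if (is.null(rownames(m)) && nrow(m) > 0)
        stop("matrix must have row keys")
    if (anyDuplicated(rownames(m)))
        stop("duplicate row keys")
    dt <- data.table(id = rownames(m))
    for (j in seq_len(ncol(m))) dt[[colnames(m)[j]]] <- m[, j]
    fwrite(dt, path, sep = "\t", quote = FALSE)
    invisible(path)
}

#' @rdname writeCountTable
#' @export
readCountTable <- function(path) {
    dt <- fread(path, sep = "\t", header = TRUE)
    if (anyDuplicated(dt[[1]])) stop("duplicate row keys in ", path)
    m <- as.matrix(dt[, -1, drop = FALSE])
    rownames(m) <- as.character(dt[[1]])
    m
}

#' Write sequences as FASTA / perfect-read FASTQ
#'
#' FASTA is wrapped at 60 columns.  FASTQ writes Phred+33 qualities, all
#' \code{I} (Q40), matching the zero-error read contract of the simulator.
#'
#' @param seqs a named DNAStringSet.
#' @param path output path.
#' @return the path, invisibly.
#' @export
writeFasta <- function(seqs, path) {
    Biostrings::writeXStringSet(seqs, path, width = 60L)
    invisible(path)
}

#' @rdname writeFasta
#' @export
writeFastq <- function(seqs, path) {
    q <- Biostrings::PhredQuality(strrep("I", Biostrings::width(seqs)))
    Biostrings::writeXStringSet(seqs, path, format = "fastq", qualities = q)
    invisible(path)
}
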