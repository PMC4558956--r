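#' Read a GTF annotation
#'
#' Parses gene/transcript/exon records from a tab-separated GTF file with
#' Ensembl-style attributes (\code{gene_id "G"; transcript_id "T";}).
#' Comment lines (\code{#}) are skipped and unknown feature types are
#' ignored.  Coordinates are kept 1-based inclusive, as on disk.
#'
#' @param path path to a GTF file.
#' @param featureTypes feature types to retain.
#' @return a \link[GenomicRanges]{GRanges} with metadata columns
#'   \code{type}, \code{gene_id}, \code{transcript_id} and \code{biotype}
#'   (NA where absent).
#' @examples
#' gtf <- tempfile(fileext = ".gtf")
#' writeLines(paste("chr1\tsim\texon\t1\t100\t.\t+\t.",
#'                  'gene_id "G1"; transcript_id "T1";', sep = "\t"), gtf)
#' readGtf(gtf)
#' @export
readGtf <- function(path, featureTypes = c("gene", "transcript", "exon")) {
    if (!file.exists(path)) stop("GTF file not found: ", path)
    # line-by-line split so parse errors can name the offending line
    raw <- readLines(path)
    keepLine <- !startsWith(raw, "#") & nzchar(raw)
    lineNo <- which(keepLine)
    fields <- strsplit(raw[keepLine], "\t", fixed = TRUE)
    nf <- lengths(fields)
    if (any(nf != 9))
        stop("malformed GTF (expected 9 tab-separated columns) at line ",
             lineNo[which(nf != 9)[1]])
    dt <- data.table(
        seqname = vapply(fields, `[`, "", 1L),
        type    = vapply(fields, `[`, "", 3L),
        start   = as.integer(vapply(fields, `[`, "", 4L)),
        end     = as.integer(vapply(fields, `[`, "", 5L)),
        strand  = vapply(fields, `[`, "", 7L),
        attributes = vapply(fields, `[`, "", 9L),
        line = lineNo
    )
    dt <- dt[type %in% featureTypes]
    if (!nrow(dt))
        return(GenomicRanges::GRanges(
            type = character(), gene_id = character(),
            transcript_id = character(), biotype = character()))
    getAttr <- function(attr, key) {
        out <- rep(NA_character_, length(attr))
        ok <- regexpr(paste0(key, '\\s+"([^"]*)"'), attr, perl = TRUE) > 0
        out[ok] <- sub(paste0('.*', key, '\\s+"([^"]*)".*'), "\\1",
                       attr[ok], perl = TRUE)
        out
    }
    dt[, gene_id := getAttr(attributes, "gene_id")]
    dt[, transcript_id := getAttr(attributes, "transcript_id")]
    dt[, biotype := getAttr(attributes, "gene_biotype")]
    bad <- dt[type == "exon" & (is.na(gene_id) | !nzchar(gene_id))]
    if (nrow(bad))
        stop("malformed attribute column (exon without gene_id) at line ",
             bad$line[1])
    if (any(dt$start > dt$end))
        stop("start > end at line ", dt$line[dt$start > dt$end][1])
    gr <- GenomicRanges::GRanges(
        seqnames = dt$seqname,
        ranges = IRanges::IRanges(dt$start, dt$end),
        strand = ifelse(dt$strand %in% c("+", "-"), dt$strand, "*"))
    mcols(gr)$type <- dt$type
    mcols(gr)$gene_id <- dt$gene_id
    mcols(gr)$transcript_id <- dt$transcript_id
    mcols(gr)$biotype <- dt$biotype
    gr
}

#' Write GTF annotation records
#'
#' Inverse of \code{\link{readGtf}} for the record types this package
#' produces; coordinates are written 1-based inclusive.
#'
#' @param annotation GRanges with \code{type}, \code{gene_id},
#'   \code{transcript_id} (and optionally \code{biotype}) metadata columns.
#' @param path output path.
#' @return the path, invisibly.
#' @export
writeGtf <- function(annotation, path) {
    md <- mcols(annotation)
    attrs <- paste0('gene_id "', md$gene_id, '";')
    hasTx <- !is.na(md$transcript_id)
    attrs[hasTx] <- paste0(attrs[hasTx], ' transcript_id "',
                           md$transcript_id[hasTx], '";')
    if (!is.null(md$biotype)) {
        hasBt <- !is.na(md$biotype)
        attrs[hasBt] <- paste0(attrs[hasBt], ' gene_biotype "',
                               md$biotype[hasBt], '";')
    }
    lines <- paste(as.character(GenomicRanges::seqnames(annotation)),
                   "MMGcount", md$type,
                   GenomicRanges::start(annotation),
                   GenomicRanges::end(annotation),
                   ".", as.character(GenomicRanges::strand(annotation)),
                   ".", attrs, sep = "\t")
    writeLines(lines, path)
    invisible(path)
}
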