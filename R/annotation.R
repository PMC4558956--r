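#' Build a queryable exon-union index
#'
#' Collapses all exon records of each gene (over all its transcripts)
#' into disjoint sorted intervals and wraps them for overlap queries.
#' Intronic and intergenic positions belong to no feature.
#'
#' @param annotation GRanges from \code{\link{readGtf}} (exon records must
#'   carry \code{gene_id}).
#' @return a \linkS4class{FeatureIndex}.
#' @examples
#' gr <- GenomicRanges::GRanges("chr1", IRanges::IRanges(c(1, 51), c(60, 100)),
#'         strand = "+", type = "exon", gene_id = "G1",
#'         transcript_id = "T1", biotype = NA_character_)
#' idx <- buildFeatureIndex(gr)
#' queryOverlaps(idx, GenomicRanges::GRanges("chr1", IRanges::IRanges(10, 10)))
#' @export
buildFeatureIndex <- function(annotation) {
    ex <- annotation[mcols(annotation)$type == "exon"]
    if (!length(ex)) stop("annotation contains no exon records")
    byGene <- GenomicRanges::split(ex, mcols(ex)$gene_id)
    red <- GenomicRanges::reduce(byGene)
    flat <- unlist(red, use.names = FALSE)
    mcols(flat)$gene_id <- rep(names(red), S4Vectors::elementNROWS(red))
    gdt <- unique(data.table(
        gene_id = mcols(ex)$gene_id,
        seqnames = as.character(GenomicRanges::seqnames(ex)),
        strand = as.character(GenomicRanges::strand(ex)),
        biotype = if (is.null(mcols(ex)$biotype)) NA_character_
                  else mcols(ex)$biotype))
    if (anyDuplicated(gdt$gene_id))
        stop("duplicate gene_id with conflicting metadata")
    new("FeatureIndex", exons = flat,
        genes = DataFrame(gdt[order(gene_id)]))
}

#' Query genes overlapping ranges
#'
#' @param index a \linkS4class{FeatureIndex}.
#' @param ranges GRanges to query (1-based inclusive, as everywhere in
#'   Bioconductor).
#' @return list (one element per query range) of character vectors of
#'   gene ids whose exon union overlaps the range.
#' @export
queryOverlaps <- function(index, ranges) {
    hits <- GenomicRanges::findOverlaps(ranges, index@exons,
                                        ignore.strand = TRUE)
    ids <- split(mcols(index@exons)$gene_id[S4Vectors::subjectHits(hits)],
                 factor(S4Vectors::queryHits(hits),
                        levels = seq_along(ranges)))
    lapply(ids, function(x) sort(unique(x)))
}

#' Select the reference (longest) transcript of each gene
#'
#' Picks, per gene, the transcript maximising summed exon length; ties go
#' to the lexicographically smallest transcript id.  Simulation and the
#' per-gene characterisation statistics are defined on this transcript.
#'
#' @param annotation GRanges with exon records carrying \code{gene_id}
#'   and \code{transcript_id}.
#' @return data.table with columns gene_id, transcript_id, length_bp.
#' @export
selectReferenceTranscript <- function(annotation) {
    ex <- annotation[mcols(annotation)$type == "exon"]
    dt <- data.table(gene_id = mcols(ex)$gene_id,
                     transcript_id = mcols(ex)$transcript_id,
                     w = GenomicRanges::width(ex))
    tx <- dt[, .(length_bp = sum(w)), by = .(gene_id, transcript_id)]
    setorder(tx, gene_id, -length_bp, transcript_id)
    tx[, .SD[1], by = gene_id]
}

#' Per-gene characteristic statistics
#'
#' Computes, for each gene, exon-length statistics, exon count,
#' transcript length and percentage GC of the reference (longest)
#' transcript, plus -- when alignments are supplied -- the number of
#' distinct fragments with at least one locus overlapping the gene's exon
#' union (each fragment counted once however many of its loci overlap).
#'
#' @param annotation GRanges annotation (exon records).
#' @param txSeqs named DNAStringSet of transcript sequences (names are
#'   transcript ids); GC is NA for transcripts without sequence.
#' @param frags optional \linkS4class{AlignedFragments}.
#' @return DataFrame with one row per gene: gene_id, min_exon_len,
#'   max_exon_len, mean_exon_len, n_exons, transcript_len, gc_percent,
#'   overlapping_fragments.
#' @export
characterizeGenes <- function(annotation, txSeqs = NULL, frags = NULL) {
    ref <- selectReferenceTranscript(annotation)
    ex <- annotation[mcols(annotation)$type == "exon"]
    dt <- data.table(gene_id = mcols(ex)$gene_id,
                     transcript_id = mcols(ex)$transcript_id,
                     w = GenomicRanges::width(ex))
    dt <- merge(dt, ref, by = c("gene_id", "transcript_id"))
    st <- dt[, .(min_exon_len = min(w), max_exon_len = max(w),
                 mean_exon_len = mean(w), n_exons = .N,
                 transcript_len = sum(w)), by = gene_id]
    st[, gc_percent := NA_real_]
    if (!is.null(txSeqs)) {
        ref2 <- ref[transcript_id %in% names(txSeqs)]
        af <- Biostrings::alphabetFrequency(txSeqs[ref2$transcript_id],
                                            baseOnly = TRUE)
        gc <- 100 * rowSums(af[, c("C", "G"), drop = FALSE]) /
            rowSums(af[, c("A", "C", "G", "T"), drop = FALSE])
        st[match(ref2$gene_id, gene_id), gc_percent := gc]
    }
    st[, overlapping_fragments := NA_integer_]
    if (!is.null(frags)) {
        idx <- buildFeatureIndex(annotation)
        ov <- .recordGeneOverlaps(frags@records, idx)
        cnt <- unique(ov[, .(fragment_id, gene_id)])[, .N, by = gene_id]
        st[, overlapping_fragments := 0L]
        st[match(cnt$gene_id, gene_id), overlapping_fragments := cnt$N]
    }
    setorder(st, gene_id)
    DataFrame(st)
}

#' Filter genes the way the simulation design does
#'
#' Keeps protein-coding genes (when biotypes are annotated) whose
#' reference transcript is longer than a minimum length.
#'
#' @param annotation GRanges annotation.
#' @param minLen minimum reference-transcript length in bp (exclusive).
#' @return character vector of surviving gene ids.
#' @export
filterGenes <- function(annotation, minLen = 400L) {
    ref <- selectReferenceTranscript(annotation)
    keep <- ref[length_bp > minLen]
    ex <- annotation[mcols(annotation)$type == "exon"]
    if (!is.null(mcols(ex)$biotype) && any(!is.na(mcols(ex)$biotype))) {
        bt <- unique(data.table(gene_id = mcols(ex)$gene_id,
                                biotype = mcols(ex)$biotype))
        pc <- bt[is.na(biotype) | biotype == "protein_coding", gene_id]
        keep <- keep[gene_id %in% pc]
    }
    sort(keep$gene_id)
}
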