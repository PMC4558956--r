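#' @import methods
#' @importFrom S4Vectors DataFrame metadata metadata<- mcols mcols<-
#' @importClassesFrom S4Vectors DataFrame
#' @importClassesFrom GenomicRanges GRanges
#' @importClassesFrom Biostrings DNAStringSet
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @importFrom data.table data.table as.data.table setkey setkeyv := .N .SD
#'   setorder setorderv rbindlist fread fwrite shift setnames copy
#' @importFrom stats cor runif setNames sd
#' @importFrom utils head tail modifyList
NULL

setOldClass("data.table")

#' Simulation design
#'
#' Parameters of a synthetic transcriptome / read-simulation experiment:
#' perfect paired-end reads of fixed length and insert size, simulated from
#' one transcript per gene, with optional groups of near-identical gene
#' copies (gene families).
#'
#' The defaults describe the global benchmark design: 100-bp paired-end
#' reads, 250-bp insert, zero sequencing errors, 1000 read pairs per gene,
#' transcripts at least 400 bp long.  A "targeted" design instead draws the
#' number of pairs per gene uniformly from a closed integer range (100 to
#' 100,000 by convention); set \code{pairsPerGene} to a length-2 vector for
#' that behaviour.
#'
#' @slot nGenes number of unique (non-family) genes.
#' @slot minTranscriptLen,maxTranscriptLen transcript length bounds (bp);
#'   lengths are drawn uniformly between them.
#' @slot readLen read length in bp.
#' @slot insertLen insert (fragment) length in bp.
#' @slot pairsPerGene either a single fixed depth or a length-2 integer
#'   range \code{c(lo, hi)} sampled uniformly per gene.
#' @slot familySpec data.frame with columns \code{size} and
#'   \code{divergence}: each row adds one gene family of \code{size}
#'   near-identical copies, each copy mutated from a common ancestral
#'   sequence by independent per-base substitution at rate
#'   \code{divergence} (0 gives identical copies).
#' @slot intronLen intron length in bp; 0 embeds transcripts contiguously
#'   in the genome, > 0 splits each transcript into exons separated by
#'   introns of this length.
#' @slot exonsPerTranscript number of exons per transcript when
#'   \code{intronLen > 0}.
#' @slot spacerLen intergenic spacer between embedded genes (bp).
#' @slot seed integer RNG seed; identical seeds give byte-identical output.
#' @export
setClass("SimDesign", representation(
    nGenes = "integer",
    minTranscriptLen = "integer",
    maxTranscriptLen = "integer",
    readLen = "integer",
    insertLen = "integer",
    pairsPerGene = "integer",
    familySpec = "data.frame",
    intronLen = "integer",
    exonsPerTranscript = "integer",
    spacerLen = "integer",
    seed = "integer"
))

setValidity("SimDesign", function(object) {
    msg <- character()
    if (object@insertLen < object@readLen)
        msg <- c(msg, "insertLen must be >= readLen")
    if (object@minTranscriptLen < object@insertLen)
        msg <- c(msg, "minTranscriptLen must be >= insertLen")
    if (object@maxTranscriptLen < object@minTranscriptLen)
        msg <- c(msg, "maxTranscriptLen must be >= minTranscriptLen")
    if (!length(object@pairsPerGene) %in% 1:2 || any(object@pairsPerGene < 0))
        msg <- c(msg, "pairsPerGene must be a non-negative scalar or range")
    fs <- object@familySpec
    if (nrow(fs)) {
        if (!all(c("size", "divergence") %in% names(fs)))
            msg <- c(msg, "familySpec needs columns 'size' and 'divergence'")
        else if (any(fs$divergence < 0 | fs$divergence > 1))
            msg <- c(msg, "divergence must lie in [0, 1]")
        else if (any(fs$size < 2))
            msg <- c(msg, "family size must be >= 2")
    }
    if (object@nGenes < 0) msg <- c(msg, "nGenes must be >= 0")
    if (length(msg)) msg else TRUE
})

#' Queryable exon-union index over gene models
#'
#' Maps genomic intervals to the genes whose exon unions they overlap.
#' Built once from annotation, then queried by stage-1 counting, the MMG
#' machinery and the characterisation utilities.  Overlap is always against
#' the union of exons over all transcripts of a gene; intronic bases are
#' not part of any feature.
#'
#' @slot exons GRanges of disjoint per-gene exon-union intervals with a
#'   \code{gene_id} metadata column.
#' @slot genes DataFrame with one row per gene: \code{gene_id},
#'   \code{seqnames}, \code{strand}, and \code{biotype} (NA when the
#'   annotation carries none).
#' @export
setClass("FeatureIndex", representation(
    exons = "GRanges",
    genes = "DataFrame"
))

setValidity("FeatureIndex", function(object) {
    msg <- character()
    if (is.null(object@exons$gene_id))
        msg <- c(msg, "exons must carry a gene_id metadata column")
    if (anyDuplicated(object@genes$gene_id))
        msg <- c(msg, "duplicate gene_id in gene table")
    if (length(msg)) msg else TRUE
})

#' Aligned fragments
#'
#' All reported alignment loci for a set of sequenced fragments (read
#' pairs).  One fragment is one template: both mates and every reported
#' locus are grouped under a single \code{fragment_id}, so that a pair
#' counts once everywhere downstream.
#'
#' @slot records data.table with one row per mate-locus alignment record:
#'   \code{fragment_id}, \code{qname}, \code{mate} (1/2), \code{rname},
#'   \code{pos} (1-based leftmost), \code{strand}, \code{cigar}, \code{nh}
#'   (NA when the aligner reported no NH tag), \code{nloci} (maximum
#'   reported loci over the fragment's mates; fallback multi-mapping signal).
#' @slot nFragments number of distinct mapped fragments.
#' @slot nNotAligned fragments whose records were all unmapped (flag 0x4).
#' @slot nSingletons mapped fragments observed with only one mate.
#' @export
setClass("AlignedFragments", representation(
    records = "data.table",
    nFragments = "integer",
    nNotAligned = "integer",
    nSingletons = "integer"
))

setValidity("AlignedFragments", function(object) {
    need <- c("fragment_id", "qname", "mate", "rname", "pos", "strand",
              "cigar", "nh", "nloci")
    if (!all(need %in% names(object@records)))
        return(paste("records must have columns:", paste(need, collapse = ", ")))
    TRUE
})

#' Stage-1 counting results
#'
#' Per-gene fragment counts under one overlap-resolution mode together
#' with the fate of every fragment.  Fates partition the input: assigned,
#' no_feature, ambiguous, alignment_not_unique, not_aligned.  Fragments
#' not assigned in stage 1 carry their overlap gene sets forward so that
#' stage 2 can place them into multi-map groups.
#'
#' @slot counts named integer vector, one entry per gene in the index.
#' @slot fates DataFrame with one row per fragment: \code{fragment_id},
#'   \code{qname}, \code{verdict}, \code{gene_id} (non-NA iff assigned),
#'   \code{mmg} ("|"-joined sorted gene set over all loci; "" when no
#'   locus overlaps any gene).
#' @slot tallies named integer vector over the five verdicts.
#' @slot mode the counting mode used.
#' @export
setClass("Stage1Results", representation(
    counts = "integer",
    fates = "DataFrame",
    tallies = "integer",
    mode = "character"
))

.VERDICTS <- c("assigned", "no_feature", "ambiguous",
               "alignment_not_unique", "not_aligned")

setValidity("Stage1Results", function(object) {
    msg <- character()
    if (!identical(names(object@tallies), .VERDICTS))
        msg <- c(msg, "tallies must be named by the five verdicts")
    f <- object@fates
    if (nrow(f)) {
        bad <- xor(f$verdict == "assigned", !is.na(f$gene_id))
        if (any(bad))
            msg <- c(msg, "gene_id must be present iff verdict == 'assigned'")
    }
    if (length(msg)) msg else TRUE
})

#' Multi-map-group count matrix
#'
#' A \linkS4class{SummarizedExperiment} whose rows are multi-map groups
#' (MMGs): sets of genes to which stage-1-unassigned fragments map
#' consistently.  Each rescuable fragment increments exactly one
#' (group, sample) cell.  Row names are the canonical group serialisation
#' (gene ids sorted lexicographically, joined with "|"); \code{rowData}
#' holds the gene sets and group sizes; \code{colData} holds per-sample
#' library sizes and stage-1 unassigned totals.
#'
#' @export
setClass("MmgExperiment", contains = "SummarizedExperiment")

setValidity("MmgExperiment", function(object) {
    a <- SummarizedExperiment::assay(object, "counts")
    if (any(a < 0)) return("counts must be non-negative")
    rd <- SummarizedExperiment::rowData(object)
    if (!all(c("gene_ids", "size") %in% names(rd)))
        return("rowData must carry gene_ids and size")
    TRUE
})

#' Simulated dataset
#'
#' The full output of the synthetic-data generator: genome and transcript
#' sequences, annotation, the genome layout of every embedded exon, and
#' the per-gene simulation truth (true fragment counts and expected FPKM).
#' Reads and their origins are attached when reads were simulated.
#'
#' @slot design the \linkS4class{SimDesign} used.
#' @slot genome DNAStringSet of chromosome sequences.
#' @slot transcripts DNAStringSet of transcript sequences (one per gene),
#'   named by transcript id.
#' @slot annotation GRanges with gene/transcript/exon records (GTF-style).
#' @slot layout data.table mapping transcript coordinates to genome
#'   coordinates, one row per exon.
#' @slot truth DataFrame: gene_id, transcript_id, length_bp, true_count,
#'   expected_fpkm.
#' @slot reads list with DNAStringSet elements \code{mate1}, \code{mate2}
#'   and a data.table \code{origins} (fragment qname, gene, start offset);
#'   empty for count-only simulations.
#' @export
setClass("SimulatedDataset", representation(
    design = "SimDesign",
    genome = "DNAStringSet",
    transcripts = "DNAStringSet",
    annotation = "GRanges",
    layout = "data.table",
    truth = "DataFrame",
    reads = "list"
))

setValidity("SimulatedDataset", function(object) {
    tr <- object@truth
    if (nrow(tr) && !all(c("gene_id", "true_count", "expected_fpkm") %in%
                         colnames(tr)))
        return("truth needs gene_id, true_count, expected_fpkm")
    TRUE
})
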