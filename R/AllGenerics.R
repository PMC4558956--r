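#' @rdname FeatureIndex-class
#' @param x a FeatureIndex
#' @export
setGeneric("geneIds", function(x) standardGeneric("geneIds"))

#' @rdname FeatureIndex-class
#' @export
setGeneric("exonUnion", function(x) standardGeneric("exonUnion"))

#' @rdname AlignedFragments-class
#' @param x an object holding fragments
#' @export
setGeneric("nFragments", function(x) standardGeneric("nFragments"))

#' @rdname Stage1Results-class
#' @param x a Stage1Results
#' @export
setGeneric("fragmentFates", function(x) standardGeneric("fragmentFates"))

#' @rdname Stage1Results-class
#' @export
setGeneric("fateTallies", function(x) standardGeneric("fateTallies"))

#' @rdname Stage1Results-class
#' @export
setGeneric("geneCounts", function(x) standardGeneric("geneCounts"))

#' @rdname MmgExperiment-class
#' @param x an MmgExperiment
#' @export
setGeneric("mmgIds", function(x) standardGeneric("mmgIds"))

#' @rdname MmgExperiment-class
#' @export
setGeneric("mmgGeneSets", function(x) standardGeneric("mmgGeneSets"))

#' @rdname SimulatedDataset-class
#' @param x a SimulatedDataset
#' @export
setGeneric("simTruth", function(x) standardGeneric("simTruth"))

setMethod("geneIds", "FeatureIndex", function(x) x@genes$gene_id)
setMethod("exonUnion", "FeatureIndex", function(x) x@exons)
setMethod("nFragments", "AlignedFragments", function(x) x@nFragments)
setMethod("fragmentFates", "Stage1Results", function(x) x@fates)
setMethod("fateTallies", "Stage1Results", function(x) x@tallies)
setMethod("geneCounts", "Stage1Results", function(x) x@counts)
setMethod("mmgIds", "MmgExperiment", function(x) rownames(x))
setMethod("mmgGeneSets", "MmgExperiment",
          function(x) SummarizedExperiment::rowData(x)$gene_ids)
setMethod("simTruth", "SimulatedDataset", function(x) x@truth)

setMethod("show", "SimDesign", function(object) {
    ppg <- object@pairsPerGene
    cat("SimDesign:", object@nGenes, "unique genes")
    if (nrow(object@familySpec))
        cat(" +", nrow(object@familySpec), "families (sizes",
            paste(object@familySpec$size, collapse = ","), ")")
    cat("\n  reads:", object@readLen, "bp paired-end, insert",
        object@insertLen, "bp, zero errors\n")
    cat("  pairs/gene:", if (length(ppg) == 1) ppg else
        paste0("U[", ppg[1], ",", ppg[2], "]"),
        " transcript length:", object@minTranscriptLen, "-",
        object@maxTranscriptLen, "bp  seed:", object@seed, "\n")
})

setMethod("show", "FeatureIndex", function(object) {
    cat("FeatureIndex:", nrow(object@genes), "genes,",
        length(object@exons), "exon-union intervals on",
        length(unique(object@genes$seqnames)), "sequence(s)\n")
})

setMethod("show", "AlignedFragments", function(object) {
    cat("AlignedFragments:", object@nFragments, "mapped fragments (",
        nrow(object@records), "mate-locus records );",
        object@nNotAligned, "not aligned;",
        object@nSingletons, "singleton mates\n")
})

setMethod("show", "Stage1Results", function(object) {
    cat("Stage1Results (mode =", object@mode, "):\n")
    print(object@tallies)
})

setMethod("show", "SimulatedDataset", function(object) {
    cat("SimulatedDataset:", nrow(object@truth), "genes,",
        sum(object@truth$true_count), "simulated pairs",
        if (length(object@reads)) "(reads attached)" else "(count-only)",
        "\n")
})
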