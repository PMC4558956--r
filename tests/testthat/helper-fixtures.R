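suppressPackageStartupMessages({
    library(data.table)
    library(GenomicRanges)
    library(Biostrings)
    library(SummarizedExperiment)
})

# annotation GRanges from a compact spec: list(gene = list(tx = list(c(s,e), ...)))
makeAnnotation <- function(genes, seqname = "chr1", strand = "+",
                           biotype = NA_character_) {
    rows <- list()
    for (g in names(genes)) {
        for (tx in names(genes[[g]])) {
            for (ex in genes[[g]][[tx]]) {
                rows[[length(rows) + 1L]] <-
                    data.table::data.table(start = ex[1], end = ex[2], gene_id = g,
                               transcript_id = tx)
            }
        }
    }
    dt <- data.table::rbindlist(rows)
    gr <- GenomicRanges::GRanges(seqname,
        IRanges::IRanges(dt$start, dt$end), strand = strand)
    S4Vectors::mcols(gr)$type <- "exon"
    S4Vectors::mcols(gr)$gene_id <- dt$gene_id
    S4Vectors::mcols(gr)$transcript_id <- dt$transcript_id
    S4Vectors::mcols(gr)$biotype <- biotype
    gr
}

# AlignedFragments straight from a loci table (qname, mate, rname, pos,
# cigar, nh); strand defaults to +/- by mate
makeFragments <- function(dt) {
    dt <- data.table::as.data.table(dt)
    if (is.null(dt$strand)) dt[, strand := ifelse(mate == 1L, "+", "-")]
    if (is.null(dt$nh)) dt[, nh := NA_integer_]
    dt[, fragment_id := as.integer(factor(qname, levels = unique(qname)))]
    dt[, nloci := 0L]
    if (nrow(dt)) {
        dt[, nperm := .N, by = .(fragment_id, mate)]
        dt[, nloci := max(nperm), by = fragment_id]
        dt[, nperm := NULL]
    }
    new("AlignedFragments",
        records = dt[, .(fragment_id, qname, mate, rname, pos, strand,
                         cigar, nh, nloci)],
        nFragments = length(unique(dt$fragment_id)),
        nNotAligned = 0L, nSingletons = 0L)
}

# independent oracle: all exact-match loci of a pattern in a genome
# (forward and reverse complement), by naive all-positions comparison
naiveLoci <- function(pattern, genomeChar) {
    w <- nchar(pattern)
    n <- nchar(genomeChar) - w + 1L
    subs <- substring(genomeChar, seq_len(n), seq_len(n) + w - 1L)
    rcp <- as.character(Biostrings::reverseComplement(
        Biostrings::DNAString(pattern)))
    list(fw = which(subs == pattern), rv = which(subs == rcp))
}

# independent re-implementation of the MMG filter rule
naiveFilterMmgs <- function(m, minReads, minSamples) {
    keep <- apply(m, 1L, function(r) sum(r >= minReads) >= minSamples)
    m[keep, , drop = FALSE]
}

# independent re-implementation of the deterministic collapse fixed point:
# smallest eligible contained group first, merged into its smallest strict
# superset, repeated until stable
naiveCollapseMmgs <- function(m, minSize = 5L) {
    sets <- lapply(strsplit(rownames(m), "|", fixed = TRUE), sort)
    repeat {
        sz <- lengths(sets)
        ids <- vapply(sets, paste, "", collapse = "|")
        done <- TRUE
        for (i in order(sz, ids)) {
            if (sz[i] < minSize) next
            sup <- which(vapply(seq_along(sets), function(j)
                sz[j] > sz[i] && all(sets[[i]] %in% sets[[j]]), logical(1)))
            if (!length(sup)) next
            j <- sup[order(sz[sup], ids[sup])][1]
            m[j, ] <- m[j, ] + m[i, ]
            m <- m[-i, , drop = FALSE]
            sets <- sets[-i]
            done <- FALSE
            break
        }
        if (done) break
    }
    rownames(m) <- vapply(sets, paste, "", collapse = "|")
    m
}

# random MMG count matrix for property tests
randomMmgMatrix <- function(nGroups, nSamples, genePool = LETTERS[1:10],
                            maxCount = 200L) {
    ids <- character(0)
    while (length(unique(ids)) < nGroups) {
        sz <- sample(1:7, nGroups, replace = TRUE)
        ids <- vapply(sz, function(k)
            paste(sort(sample(genePool, k)), collapse = "|"), "")
        ids <- unique(ids)
    }
    ids <- ids[seq_len(nGroups)]
    m <- matrix(sample(0:maxCount, nGroups * nSamples, replace = TRUE),
                nrow = nGroups,
                dimnames = list(ids, paste0("s", seq_len(nSamples))))
    m
}

mmgFromMatrix <- function(m) MMGcount:::.newMmgExperiment(m)
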