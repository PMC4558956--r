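.MODES <- c("union", "intersection_strict", "intersection_nonempty")

# Reference-space blocks of each record (M/D consume and participate,
# N skips, I/S consume nothing), as a data.table keyed by record row.
.recordBlocks <- function(rec) {
    rng <- GenomicAlignments::cigarRangesAlongReferenceSpace(
        rec$cigar, pos = rec$pos, ops = c("M", "D", "=", "X"),
        reduce.ranges = TRUE)
    n <- S4Vectors::elementNROWS(rng)
    flat <- unlist(rng, use.names = FALSE)
    data.table(rec = rep(seq_len(nrow(rec)), n),
               rname = rep(rec$rname, n),
               start = IRanges::start(flat), end = IRanges::end(flat))
}

# Per (record, gene) overlap widths plus per-record aligned width (W) and
# covered width (C = bases under >=1 feature), honouring strandedness.
.recordGeneSets <- function(rec, index, stranded = "no") {
    blocks <- .recordBlocks(rec)
    bgr <- GenomicRanges::GRanges(blocks$rname,
                                  IRanges::IRanges(blocks$start, blocks$end))
    hits <- GenomicRanges::findOverlaps(bgr, index@exons, ignore.strand = TRUE)
    qh <- S4Vectors::queryHits(hits); sh <- S4Vectors::subjectHits(hits)
    ov <- data.table(
        rec = blocks$rec[qh],
        gene_id = mcols(index@exons)$gene_id[sh],
        s = pmax(blocks$start[qh], GenomicRanges::start(index@exons)[sh]),
        e = pmin(blocks$end[qh], GenomicRanges::end(index@exons)[sh]))
    if (stranded != "no" && nrow(ov)) {
        gstrand <- setNames(as.character(index@genes$strand),
                            index@genes$gene_id)
        # effective fragment strand: mate1 reports it, mate2 is flipped
        eff <- ifelse(rec$mate == 2L,
                      ifelse(rec$strand == "+", "-", "+"), rec$strand)
        if (stranded == "reverse") eff <- ifelse(eff == "+", "-", "+")
        gs <- gstrand[ov$gene_id]
        ov <- ov[is.na(gs) | gs == "*" | gs == eff[ov$rec]]
    }
    W <- blocks[, .(W = sum(end - start + 1L)), by = rec]
    list(ov = ov, W = W)
}

# any-overlap (fragment_id, gene_id) pairs -- stage-2 / characterisation use
.recordGeneOverlaps <- function(rec, index) {
    if (!nrow(rec))
        return(data.table(fragment_id = integer(), rec = integer(),
                          gene_id = character()))
    gs <- .recordGeneSets(rec, index)
    ov <- unique(gs$ov[, .(rec, gene_id)])
    fid <- rec$fragment_id
    ov[, fragment_id := fid[rec]]
    ov
}

#' Per-base gene sets for one aligned mate
#'
#' The three htseq-style per-mate decision sets: \code{union} is the
#' union of overlapping-gene sets over all aligned bases; under
#' \code{intersection_strict} a gene must cover every aligned base (bases
#' over no feature contribute the empty set, so any overhang empties the
#' set); under \code{intersection_nonempty} a gene must cover every
#' aligned base that overlaps at least one feature.
#'
#' @param index a \linkS4class{FeatureIndex}.
#' @param rname,pos,cigar the mate's reference name, 1-based leftmost
#'   position and CIGAR (M/=/X/D consume reference and participate in the
#'   per-base sets, N skips reference, I/S consume none).
#' @return list with sorted character vectors \code{union},
#'   \code{intersection_strict}, \code{intersection_nonempty}.
#' @examples
#' gr <- GenomicRanges::GRanges("chr1", IRanges::IRanges(101, 200),
#'         strand = "+", type = "exon", gene_id = "A",
#'         transcript_id = "T", biotype = NA_character_)
#' idx <- buildFeatureIndex(gr)
#' # half in the exon, half intronic: strict loses the gene, nonempty keeps it
#' mateGeneSets(idx, "chr1", 151L, "100M")
#' @export
mateGeneSets <- function(index, rname, pos, cigar) {
    rec <- data.table(rname = rname, pos = as.integer(pos), cigar = cigar,
                      mate = 1L, strand = "+", fragment_id = 1L)
    sets <- .modeSets(rec, index, stranded = "no")$sets
    pick <- function(col) sort(sets[get(col) == TRUE, unique(gene_id)])
    list(union = pick("inUnion"),
         intersection_strict = pick("inStrict"),
         intersection_nonempty = pick("inNonempty"))
}

# mode membership per (record, gene): inUnion, inStrict, inNonempty,
# plus per-record coverage info (covered = any base under a feature)
.modeSets <- function(rec, index, stranded = "no") {
    gs <- .recordGeneSets(rec, index, stranded)
    ov <- gs$ov
    empty <- data.table(rec = integer(), gene_id = character(),
                        inUnion = logical(), inStrict = logical(),
                        inNonempty = logical())
    if (!nrow(ov))
        return(list(sets = empty,
                    recCov = data.table(rec = integer(), covered = logical())))
    ov[, w := e - s + 1L]
    wg <- ov[, .(w = sum(w)), by = .(rec, gene_id)]
    # covered width per record: union of all (block x exon) intersections
    setorder(ov, rec, s, e)
    ov[, cmax := shift(cummax(e), 1L, fill = 0L), by = rec]
    ov[, contrib := pmax(0L, e - pmax(s, cmax + 1L) + 1L)]
    C <- ov[, .(C = sum(contrib)), by = rec]
    wg <- merge(wg, C, by = "rec")
    wg <- merge(wg, gs$W, by = "rec")
    wg[, inUnion := w > 0L]
    wg[, inStrict := w == W]
    wg[, inNonempty := w == C]
    list(sets = wg[, .(rec, gene_id, inUnion, inStrict, inNonempty)],
         recCov = C[, .(rec, covered = C > 0L)])
}

#' Resolve fragment fates under a counting mode
#'
#' Stage-1 decision for every fragment.  Multi-mapped fragments (NH > 1,
#' or more than one reported locus when NH is absent) are
#' \code{alignment_not_unique} regardless of overlap.  For uniquely
#' mapped fragments the decision set is computed over the pooled aligned
#' bases of both mates, htseq-style: under \code{union} a gene qualifies
#' by overlapping any base of either mate; under
#' \code{intersection_strict} it must cover every aligned base of both
#' mates; under \code{intersection_nonempty} it must cover every aligned
#' base that lies under at least one feature.  One gene in the decision
#' set means \code{assigned}, none \code{no_feature}, several
#' \code{ambiguous}.  Every fragment not assigned keeps the union of
#' genes overlapped by any of its loci (its candidate multi-map group)
#' for stage 2.
#'
#' @param frags an \linkS4class{AlignedFragments}.
#' @param index a \linkS4class{FeatureIndex}.
#' @param mode one of \code{"union"}, \code{"intersection_strict"},
#'   \code{"intersection_nonempty"} (dashes accepted).
#' @param stranded \code{"no"} (default), \code{"yes"} or
#'   \code{"reverse"}.
#' @return a \linkS4class{Stage1Results}.
#' @export
resolveFragments <- function(frags, index,
                             mode = c("union", "intersection_strict",
                                      "intersection_nonempty"),
                             stranded = c("no", "yes", "reverse")) {
    mode <- gsub("-", "_", mode[1])
    mode <- match.arg(mode, .MODES)
    stranded <- match.arg(stranded)
    rec <- frags@records
    col <- c(union = "inUnion", intersection_strict = "inStrict",
             intersection_nonempty = "inNonempty")[[mode]]

    if (nrow(rec)) {
        ms <- .modeSets(rec, index, stranded)
        sets <- ms$sets
        fid <- rec$fragment_id
        sets[, fragment_id := fid[rec]]
        multi <- rec[, .(multi = if (any(!is.na(nh)))
                             max(nh, na.rm = TRUE) > 1L else nloci[1] > 1L),
                     by = .(fragment_id, qname = qname)]
        # candidate MMG: union of any-overlap genes over all loci
        mmg <- unique(sets[inUnion == TRUE, .(fragment_id, gene_id)])
        mmg <- mmg[order(fragment_id, gene_id),
                   .(mmg = paste(gene_id, collapse = "|")), by = fragment_id]
        # decision set over the pooled bases of both mates: a gene must
        # qualify on every record (strict), on every feature-covered
        # record (nonempty), or on any record (union)
        nRec <- data.table(fragment_id = fid)[, .(nRec = .N), by = fragment_id]
        covFlag <- ms$recCov[covered == TRUE, rec]
        nCov <- data.table(fragment_id = fid[covFlag])[
            , .(nCov = .N), by = fragment_id]
        dec <- switch(mode,
            union = unique(sets[inUnion == TRUE, .(fragment_id, gene_id)]),
            intersection_strict = merge(
                sets[inStrict == TRUE, .(k = .N), by = .(fragment_id, gene_id)],
                nRec, by = "fragment_id")[k == nRec, .(fragment_id, gene_id)],
            intersection_nonempty = merge(
                sets[inNonempty == TRUE, .(k = .N),
                     by = .(fragment_id, gene_id)],
                nCov, by = "fragment_id")[k == nCov, .(fragment_id, gene_id)])
        ndec <- dec[, .(n = .N, gene1 = gene_id[1L]), by = fragment_id]
        fates <- multi
        fates <- merge(fates, ndec, by = "fragment_id", all.x = TRUE)
        fates <- merge(fates, mmg, by = "fragment_id", all.x = TRUE)
        fates[is.na(n), n := 0L]
        fates[is.na(mmg), mmg := ""]
        fates[, verdict := ifelse(multi, "alignment_not_unique",
                           ifelse(n == 0L, "no_feature",
                           ifelse(n == 1L, "assigned", "ambiguous")))]
        fates[, gene_id := ifelse(verdict == "assigned", gene1, NA_character_)]
        setorder(fates, fragment_id)
        fates <- fates[, .(fragment_id, qname, verdict, gene_id, mmg)]
    } else {
        fates <- data.table(fragment_id = integer(), qname = character(),
                            verdict = character(), gene_id = character(),
                            mmg = character())
    }
    gids <- geneIds(index)
    counts <- setNames(integer(length(gids)), gids)
    asg <- fates[verdict == "assigned", .N, by = gene_id]
    counts[asg$gene_id] <- asg$N
    tal <- setNames(integer(5L), .VERDICTS)
    tv <- table(fates$verdict)
    tal[names(tv)] <- as.integer(tv)
    tal["not_aligned"] <- frags@nNotAligned
    fates$verdict <- factor(fates$verdict, levels = .VERDICTS)
    new("Stage1Results", counts = counts, fates = DataFrame(as.data.frame(fates)),
        tallies = tal, mode = mode)
}

#' Stage-1 gene counting
#'
#' Counts uniquely mapped fragments against genes under one
#' overlap-resolution mode; a read pair counts once.  Convenience wrapper
#' returning the same \linkS4class{Stage1Results} as
#' \code{\link{resolveFragments}}.
#'
#' @inheritParams resolveFragments
#' @return a \linkS4class{Stage1Results}; \code{geneCounts()} gives the
#'   per-gene counts, \code{fateTallies()} the verdict totals.
#' @export
countStage1 <- function(frags, index, mode = "union", stranded = "no") {
    resolveFragments(frags, index, mode = mode, stranded = stranded)
}

#' Write stage-1 outputs
#'
#' @param res a \linkS4class{Stage1Results}.
#' @param countsPath,fatesPath output TSV paths (either may be NULL).
#' @return invisibly, NULL.
#' @export
writeStage1 <- function(res, countsPath = NULL, fatesPath = NULL) {
    if (!is.null(countsPath)) {
        m <- matrix(res@counts, ncol = 1,
                    dimnames = list(names(res@counts), "count"))
        writeCountTable(m, countsPath)
    }
    if (!is.null(fatesPath))
        fwrite(as.data.frame(res@fates), fatesPath, sep = "\t", quote = FALSE)
    invisible(NULL)
}
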