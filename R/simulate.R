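#' Construct a simulation design
#'
#' @param nGenes number of unique (single-copy) genes.
#' @param pairsPerGene fixed read-pair depth per gene, or a length-2
#'   integer range \code{c(lo, hi)} sampled uniformly per gene (the
#'   targeted design uses \code{c(100, 100000)}).
#' @param familySpec data.frame with columns \code{size},
#'   \code{divergence}: extra gene families of near-identical copies.
#' @param minTranscriptLen,maxTranscriptLen transcript length bounds (bp).
#' @param readLen,insertLen read and insert length (bp).
#' @param intronLen 0 for contiguous embedding (default), else intron
#'   size separating exons in the genome.
#' @param exonsPerTranscript exons per transcript when introns are used.
#' @param spacerLen intergenic spacer (bp).
#' @param seed RNG seed.
#' @return a \linkS4class{SimDesign}.
#' @export
simDesign <- function(nGenes, pairsPerGene = 1000L,
                      familySpec = data.frame(size = integer(),
                                              divergence = numeric()),
                      minTranscriptLen = 400L, maxTranscriptLen = 2500L,
                      readLen = 100L, insertLen = 250L,
                      intronLen = 0L, exonsPerTranscript = 1L,
                      spacerLen = 300L, seed = 1L) {
    new("SimDesign", nGenes = as.integer(nGenes),
        minTranscriptLen = as.integer(minTranscriptLen),
        maxTranscriptLen = as.integer(maxTranscriptLen),
        readLen = as.integer(readLen), insertLen = as.integer(insertLen),
        pairsPerGene = as.integer(pairsPerGene),
        familySpec = as.data.frame(familySpec),
        intronLen = as.integer(intronLen),
        exonsPerTranscript = as.integer(exonsPerTranscript),
        spacerLen = as.integer(spacerLen), seed = as.integer(seed))
}

.randomDna <- function(n) {
    paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

.mutate <- function(seqChar, rate) {
    if (rate <= 0) return(seqChar)
    v <- strsplit(seqChar, "")[[1]]
    hit <- runif(length(v)) < rate
    if (any(hit)) {
        alt <- list(A = c("C", "G", "T"), C = c("A", "G", "T"),
                    G = c("A", "C", "T"), T = c("A", "C", "G"))
        v[hit] <- vapply(v[hit], function(b) sample(alt[[b]], 1L), "")
    }
    paste(v, collapse = "")
}

#' Generate a synthetic transcriptome and genome
#'
#' Unique genes receive i.i.d. uniform-random A/C/G/T sequence; each
#' family is one ancestral sequence copied \code{size} times with
#' independent per-base substitution at its divergence rate (divergence 0
#' gives identical copies).  Transcripts are embedded on one synthetic
#' chromosome, separated by random intergenic spacers, either
#' contiguously (default) or split into exons with introns; the
#' annotation records the embedding exactly.  Deterministic under the
#' design seed.
#'
#' @param design a \linkS4class{SimDesign}.
#' @param sequences generate genome/transcript sequences (TRUE); FALSE
#'   gives the layout, annotation and truth skeleton only (count-only
#'   work at scale).  Transcript lengths and ids are identical either
#'   way under the same seed.
#' @return a \linkS4class{SimulatedDataset} (truth counts not yet drawn).
#' @export
generateTranscriptome <- function(design, sequences = TRUE) {
    validObject(design)
    set.seed(design@seed)
    fs <- design@familySpec
    nFam <- nrow(fs)
    lens <- sample(seq(design@minTranscriptLen, design@maxTranscriptLen),
                   design@nGenes + max(1L, nFam), replace = TRUE)
    gids <- c(if (design@nGenes) sprintf("GENE%04d", seq_len(design@nGenes)),
              if (nFam) unlist(lapply(seq_len(nFam), function(f)
                  sprintf("FAM%d_%d", f, seq_len(fs$size[f])))))
    if (!length(gids)) stop("design yields no genes")
    glens <- c(lens[seq_len(design@nGenes)],
               if (nFam) rep(lens[design@nGenes + seq_len(nFam)], fs$size))
    seqs <- NULL
    if (sequences) {
        seqs <- character(length(gids))
        for (i in seq_len(design@nGenes)) seqs[i] <- .randomDna(lens[i])
        at <- design@nGenes
        for (f in seq_len(nFam)) {
            anc <- .randomDna(lens[design@nGenes + f])
            for (k in seq_len(fs$size[f])) {
                at <- at + 1L
                seqs[at] <- .mutate(anc, fs$divergence[f])
            }
        }
    }
    txIds <- sub("^GENE", "TX", sub("^FAM", "TXF", gids))
    nex <- if (design@intronLen > 0) design@exonsPerTranscript else 1L

    # layout first (pure arithmetic), then stitch the genome in one pass
    layout <- vector("list", length(gids))
    cursor <- 0L
    for (i in seq_along(gids)) {
        cursor <- cursor + design@spacerLen
        L <- glens[i]
        bnd <- unique(round(seq(0, L, length.out = nex + 1L)))
        exw <- as.integer(diff(bnd))
        txStarts <- as.integer(cumsum(c(1L, head(exw, -1L))))
        gStarts <- integer(length(exw))
        for (e in seq_along(exw)) {
            if (e > 1L) cursor <- cursor + design@intronLen
            gStarts[e] <- cursor + 1L
            cursor <- cursor + exw[e]
        }
        layout[[i]] <- data.table(gene_id = gids[i], transcript_id = txIds[i],
                                  exon = seq_along(exw), tx_start = txStarts,
                                  width = exw, g_start = gStarts,
                                  rname = "chr1")
    }
    layout <- rbindlist(layout)
    genome <- Biostrings::DNAStringSet()
    transcripts <- Biostrings::DNAStringSet()
    if (sequences) {
        genomeLen <- cursor
        # exon blocks come from the transcripts; everything else is spacer
        spacers <- .randomDna(genomeLen)  # then overwrite exon intervals
        gseq <- strsplit(spacers, "")[[1]]
        for (i in seq_along(gids)) {
            lay <- layout[gene_id == gids[i]]
            for (e in seq_len(nrow(lay))) {
                piece <- substring(seqs[i], lay$tx_start[e],
                                   lay$tx_start[e] + lay$width[e] - 1L)
                idx <- lay$g_start[e]:(lay$g_start[e] + lay$width[e] - 1L)
                gseq[idx] <- strsplit(piece, "")[[1]]
            }
        }
        genome <- Biostrings::DNAStringSet(paste(gseq, collapse = ""))
        names(genome) <- "chr1"
        transcripts <- Biostrings::DNAStringSet(seqs)
        names(transcripts) <- txIds
    }

    ann <- layout[, {
        gs <- min(g_start); ge <- max(g_start + width - 1L)
        .(type = c("gene", "transcript", rep("exon", .N)),
          start = c(gs, gs, g_start), end = c(ge, ge, g_start + width - 1L),
          transcript_id = c(NA_character_, transcript_id[1],
                            rep(transcript_id[1], .N)))
    }, by = gene_id]
    gr <- GenomicRanges::GRanges("chr1", IRanges::IRanges(ann$start, ann$end),
                                 strand = "+")
    mcols(gr)$type <- ann$type
    mcols(gr)$gene_id <- ann$gene_id
    mcols(gr)$transcript_id <- ann$transcript_id
    mcols(gr)$biotype <- "protein_coding"

    truth <- DataFrame(gene_id = gids, transcript_id = txIds,
                       length_bp = glens, true_count = NA_integer_,
                       expected_fpkm = NA_real_)
    new("SimulatedDataset", design = design, genome = genome,
        transcripts = transcripts, annotation = gr, layout = layout,
        truth = truth, reads = list())
}

#' Draw per-gene read-pair counts
#'
#' Fixed-depth designs give every gene the same count; targeted designs
#' draw uniformly from the closed integer range.  Uses a dedicated RNG
#' stream (seed + 1) so the transcriptome is unaffected.
#'
#' @param dataset a \linkS4class{SimulatedDataset}.
#' @return the dataset with \code{true_count} and \code{expected_fpkm}
#'   filled in.
#' @export
simulateCounts <- function(dataset) {
    d <- dataset@design
    set.seed(d@seed + 1L)
    n <- nrow(dataset@truth)
    ppg <- d@pairsPerGene
    cnt <- if (length(ppg) == 1L) rep(ppg, n)
           else as.integer(sample(seq(ppg[1], ppg[2]), n, replace = TRUE))
    dataset@truth$true_count <- cnt
    rm <- sum(cnt) / 1e6
    dataset@truth$expected_fpkm <-
        (cnt / (dataset@truth$length_bp / 1000)) / rm
    dataset
}

#' Simulate perfect read pairs from one transcript
#'
#' Fragment starts are uniform on the feasible range; mate 1 is the
#' first \code{readLen} bases of the fragment, mate 2 the reverse
#' complement of its last \code{readLen} bases; zero errors.
#'
#' @param transcriptSeq a DNAString (or character) transcript sequence.
#' @param nPairs number of pairs.
#' @param readLen,insertLen read and insert length in bp.
#' @return list with DNAStringSet \code{mate1}, \code{mate2} and integer
#'   \code{start} (1-based fragment start on the transcript).
#' @export
simulatePairs <- function(transcriptSeq, nPairs, readLen = 100L,
                          insertLen = 250L) {
    s <- Biostrings::DNAString(as.character(transcriptSeq))
    L <- length(s)
    if (L < insertLen)
        stop("transcript (", L, " bp) shorter than insert (", insertLen,
             " bp); such transcripts must be filtered out before simulation")
    if (nPairs == 0)
        return(list(mate1 = Biostrings::DNAStringSet(),
                    mate2 = Biostrings::DNAStringSet(), start = integer()))
    start <- sample(seq_len(L - insertLen + 1L), nPairs, replace = TRUE)
    m1 <- Biostrings::extractAt(s, IRanges::IRanges(start, width = readLen))
    m2 <- Biostrings::reverseComplement(Biostrings::extractAt(
        s, IRanges::IRanges(start + insertLen - readLen, width = readLen)))
    list(mate1 = m1, mate2 = m2, start = start)
}

#' Simulate reads for a whole dataset
#'
#' Draws truth counts if absent, then simulates perfect pairs from every
#' gene's transcript (RNG stream seed + 2).  Read names encode nothing
#' about their origin; origins are recorded in the returned dataset.
#'
#' @param dataset a \linkS4class{SimulatedDataset}.
#' @return the dataset with \code{reads} attached (\code{mate1},
#'   \code{mate2} DNAStringSets named by fragment qname, and an
#'   \code{origins} data.table: qname, gene_id, start).
#' @export
simulateReads <- function(dataset) {
    if (all(is.na(dataset@truth$true_count)))
        dataset <- simulateCounts(dataset)
    d <- dataset@design
    set.seed(d@seed + 2L)
    tr <- dataset@truth
    m1 <- vector("list", nrow(tr)); m2 <- vector("list", nrow(tr))
    org <- vector("list", nrow(tr))
    for (i in seq_len(nrow(tr))) {
        p <- simulatePairs(dataset@transcripts[[tr$transcript_id[i]]],
                           tr$true_count[i], d@readLen, d@insertLen)
        m1[[i]] <- p$mate1; m2[[i]] <- p$mate2
        org[[i]] <- data.table(gene_id = tr$gene_id[i], start = p$start)
    }
    org <- rbindlist(org)
    qn <- sprintf("frag%07d", seq_len(nrow(org)))
    org[, qname := qn]
    mate1 <- do.call(c, m1); mate2 <- do.call(c, m2)
    names(mate1) <- qn; names(mate2) <- qn
    dataset@reads <- list(mate1 = mate1, mate2 = mate2,
                          origins = org[, .(qname, gene_id, start)])
    dataset
}

#' Simulate a complete dataset
#'
#' @param design a \linkS4class{SimDesign}.
#' @param countOnly if TRUE, draw per-gene truth counts without
#'   generating read sequences (for scale checks and expected-FPKM
#'   work).
#' @return a \linkS4class{SimulatedDataset}.
#' @export
simulateDataset <- function(design, countOnly = FALSE) {
    ds <- simulateCounts(generateTranscriptome(design,
                                               sequences = !countOnly))
    if (countOnly) ds else simulateReads(ds)
}

#' k-mers shared between different sequences
#'
#' Brute-force check that sequences are mutually unique at the read
#' scale: returns the number of k-mers occurring in more than one
#' sequence (forward strand on both, plus reverse complements).
#'
#' @param seqs a DNAStringSet.
#' @param k k-mer size (the read length, by default).
#' @return integer count of distinct shared k-mers.
#' @export
sharedKmers <- function(seqs, k = 100L) {
    ch <- as.character(seqs)
    rc <- as.character(Biostrings::reverseComplement(seqs))
    grab <- function(x, id) {
        n <- nchar(x) - k + 1L
        if (n < 1L) return(NULL)
        data.table(kmer = substring(x, seq_len(n), seq_len(n) + k - 1L),
                   id = id)
    }
    dt <- rbindlist(c(mapply(grab, ch, seq_along(ch), SIMPLIFY = FALSE),
                      mapply(grab, rc, seq_along(rc), SIMPLIFY = FALSE)))
    dt <- unique(dt)
    dt[, .(nseq = length(unique(id))), by = kmer][nseq > 1L, .N]
}

# lift transcript-space intervals to genome space; returns pos + cigar
.liftToGenome <- function(layout, txId, offset, len) {
    lay <- layout[transcript_id %in% unique(txId)]
    q <- data.table(hit = seq_along(txId), transcript_id = txId,
                    s = offset, e = offset + len - 1L)
    j <- merge(q, lay, by = "transcript_id", allow.cartesian = TRUE)
    j <- j[s <= tx_start + width - 1L & e >= tx_start]
    j[, ps := pmax(s, tx_start)]
    j[, pe := pmin(e, tx_start + width - 1L)]
    j[, gs := g_start + (ps - tx_start)]
    j[, ge := g_start + (pe - tx_start)]
    setorder(j, hit, ps)
    out <- j[, {
        gaps <- if (.N > 1L) gs[-1L] - ge[-.N] - 1L else integer()
        cig <- paste0(pe - ps + 1L, "M")
        if (.N > 1L)
            cig <- c(cig[1L], paste0(gaps, "N", cig[-1L]))
        .(pos = gs[1L], cigar = paste(cig, collapse = ""),
          rname = rname[1L])
    }, by = hit]
    if (nrow(out) != length(txId))
        stop("lift failed: interval outside its transcript's exons")
    out[order(hit)]
}

#' Exhaustive exact-match truth alignment
#'
#' Reports, for every simulated mate, every exact-match locus of its
#' sequence (either orientation) in the embedded transcript space,
#' lifted to genome coordinates; loci are paired across mates by
#' compatible orientation and insert, NH is set to the number of locus
#' pairs, and the lowest-coordinate locus is primary.  Perfect reads
#' from a k-member identical family therefore get exactly k loci.  A
#' read with no exact locus is an error -- it would violate the
#' perfect-read contract.
#'
#' @param dataset a \linkS4class{SimulatedDataset} with reads attached.
#' @return an \linkS4class{AlignedFragments}.
#' @export
truthAlign <- function(dataset) {
    if (!length(dataset@reads)) stop("dataset has no reads; run simulateReads()")
    d <- dataset@design
    m1 <- dataset@reads$mate1; m2 <- dataset@reads$mate2
    qn <- names(m1)
    allCh <- c(as.character(m1), as.character(m2))
    u <- unique(allCh)
    pu <- Biostrings::DNAStringSet(u)
    pd <- Biostrings::PDict(pu)
    tx <- dataset@transcripts
    hits <- vector("list", 2L * length(tx)); hi <- 0L
    for (t in seq_along(tx)) {
        fw <- Biostrings::matchPDict(pd, tx[[t]])
        n <- S4Vectors::elementNROWS(fw)
        if (any(n > 0)) {
            st <- IRanges::start(unlist(fw, use.names = FALSE))
            hi <- hi + 1L
            hits[[hi]] <- data.table(pat = rep(seq_along(n), n),
                                     transcript_id = names(tx)[t],
                                     o = st, strand = "+")
        }
        rv <- Biostrings::matchPDict(pd, Biostrings::reverseComplement(tx[[t]]))
        n <- S4Vectors::elementNROWS(rv)
        if (any(n > 0)) {
            st <- IRanges::start(unlist(rv, use.names = FALSE))
            L <- length(tx[[t]])
            hi <- hi + 1L
            hits[[hi]] <- data.table(pat = rep(seq_along(n), n),
                                     transcript_id = names(tx)[t],
                                     o = L - (st + d@readLen - 1L) + 1L,
                                     strand = "-")
        }
    }
    H <- rbindlist(hits[seq_len(hi)])
    p1 <- match(as.character(m1), u)
    p2 <- match(as.character(m2), u)
    if (anyNA(p1) || anyNA(p2)) stop("internal error: read not in pattern set")
    noHit <- setdiff(c(p1, p2), H$pat)
    if (length(noHit))
        stop("read(s) with zero exact-match loci violate the perfect-read ",
             "contract (first pattern index: ", noHit[1], ")")
    gap <- d@insertLen - d@readLen
    F <- data.table(frag = seq_along(qn), qname = qn, p1 = p1, p2 = p2)
    # plus orientation: mate1 forward at o, mate2 reverse at o + gap
    Hfw <- H[strand == "+"]; Hrv <- H[strand == "-"]
    j1 <- merge(F, Hfw, by.x = "p1", by.y = "pat", allow.cartesian = TRUE)
    j2 <- Hrv[, .(pat, transcript_id, o1 = o - gap)]
    plus <- merge(j1, j2, by.x = c("p2", "transcript_id", "o"),
                  by.y = c("pat", "transcript_id", "o1"))
    plus <- plus[, .(frag, qname, transcript_id, o1 = o, o2 = o + gap,
                     orient = "+")]
    # minus orientation: mate1 reverse at o2 + gap, mate2 forward at o2
    j3 <- merge(F, Hfw, by.x = "p2", by.y = "pat", allow.cartesian = TRUE)
    j4 <- Hrv[, .(pat, transcript_id, o2 = o - gap)]
    minus <- merge(j3, j4, by.x = c("p1", "transcript_id", "o"),
                   by.y = c("pat", "transcript_id", "o2"))
    minus <- minus[, .(frag, qname, transcript_id, o1 = o + gap, o2 = o,
                       orient = "-")]
    loci <- unique(rbindlist(list(plus, minus)))
    if (!nrow(loci)) stop("no pairable loci found")
    l1 <- .liftToGenome(dataset@layout, loci$transcript_id, loci$o1, d@readLen)
    l2 <- .liftToGenome(dataset@layout, loci$transcript_id, loci$o2, d@readLen)
    loci[, `:=`(pos1 = l1$pos, cigar1 = l1$cigar, rname = l1$rname,
                pos2 = l2$pos, cigar2 = l2$cigar)]
    setorder(loci, frag, rname, pos1, pos2)
    loci[, nh := .N, by = frag]
    rec <- rbindlist(list(
        loci[, .(fragment_id = frag, qname, mate = 1L, rname, pos = pos1,
                 strand = ifelse(orient == "+", "+", "-"), cigar = cigar1, nh)],
        loci[, .(fragment_id = frag, qname, mate = 2L, rname, pos = pos2,
                 strand = ifelse(orient == "+", "-", "+"), cigar = cigar2, nh)]))
    rec[, nloci := nh]
    setorder(rec, fragment_id, mate, rname, pos)
    new("AlignedFragments", records = rec,
        nFragments = length(unique(rec$fragment_id)),
        nNotAligned = 0L, nSingletons = 0L)
}
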