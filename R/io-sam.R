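.FLAG_PAIRED <- 0x1L
.FLAG_UNMAPPED <- 0x4L
.FLAG_REVERSE <- 0x10L
.FLAG_MATE_REVERSE <- 0x20L
.FLAG_MATE1 <- 0x40L
.FLAG_MATE2 <- 0x80L
.FLAG_SECONDARY <- 0x100L

#' Read SAM alignments as fragments
#'
#' Groups all records sharing a query name -- both mates and every
#' reported locus -- into single fragments, the unit of counting.  The
#' multi-mapping signal is the NH tag where present, with the per-mate
#' record count as fallback.  Unmapped records (flag 0x4) are tallied as
#' \code{not_aligned} fragments, never turned into alignment records; a
#' mapped mate with no partner is kept as a single-end fragment and
#' counted in the singleton tally.
#'
#' @param path path to a SAM (or BAM) file with \code{@SQ} headers.
#' @return an \linkS4class{AlignedFragments} object.
#' @export
readSamFragments <- function(path) {
    if (!file.exists(path)) stop("SAM file not found: ", path)
    bam <- path
    if (!grepl("\\.bam$", path, ignore.case = TRUE)) {
        dest <- tempfile(fileext = "")
        bam <- Rsamtools::asBam(path, dest, overwrite = TRUE,
                                indexDestination = FALSE)
    }
    p <- Rsamtools::ScanBamParam(
        what = c("qname", "flag", "rname", "pos", "cigar"), tag = "NH")
    res <- Rsamtools::scanBam(bam, param = p)[[1]]
    nh <- res$tag$NH
    if (is.null(nh)) nh <- rep(NA_integer_, length(res$qname))
    dt <- data.table(qname = res$qname, flag = res$flag,
                     rname = as.character(res$rname), pos = res$pos,
                     cigar = res$cigar, nh = as.integer(nh))
    alignedFragmentsFromRecords(dt)
}

#' Build AlignedFragments from raw SAM-like records
#'
#' @param dt data.table with columns qname, flag, rname, pos, cigar, nh.
#' @return an \linkS4class{AlignedFragments} object.
#' @keywords internal
alignedFragmentsFromRecords <- function(dt) {
    unmapped <- bitwAnd(dt$flag, .FLAG_UNMAPPED) > 0L
    mappedQ <- unique(dt$qname[!unmapped])
    nNotAligned <- length(setdiff(unique(dt$qname[unmapped]), mappedQ))
    dt <- dt[!unmapped]
    if (!nrow(dt)) {
        return(new("AlignedFragments",
                   records = data.table(fragment_id = integer(),
                                        qname = character(), mate = integer(),
                                        rname = character(), pos = integer(),
                                        strand = character(),
                                        cigar = character(), nh = integer(),
                                        nloci = integer()),
                   nFragments = 0L, nNotAligned = as.integer(nNotAligned),
                   nSingletons = 0L))
    }
    dt[, mate := ifelse(bitwAnd(flag, .FLAG_MATE2) > 0L, 2L, 1L)]
    dt[, strand := ifelse(bitwAnd(flag, .FLAG_REVERSE) > 0L, "-", "+")]
    dt[, fragment_id := as.integer(factor(qname, levels = unique(qname)))]
    dt[, lociMate := .N, by = .(fragment_id, mate)]
    dt[, nloci := max(lociMate), by = fragment_id]
    dt[, lociMate := NULL]
    nmate <- dt[, .(nm = length(unique(mate)),
                    paired = any(bitwAnd(flag, .FLAG_PAIRED) > 0L)),
                by = fragment_id]
    nSingle <- nmate[, sum(nm == 1L & paired)]
    rec <- dt[, .(fragment_id, qname, mate, rname, pos, strand, cigar,
                  nh, nloci)]
    new("AlignedFragments", records = rec,
        nFragments = length(unique(rec$fragment_id)),
        nNotAligned = as.integer(nNotAligned),
        nSingletons = as.integer(nSingle))
}

#' Write alignments as SAM
#'
#' Serialises an \linkS4class{AlignedFragments} object (or the alignment
#' table of the truth aligner) to SAM with \code{@SQ} header lines and
#' \code{NH:i} tags.  The lowest-coordinate locus of each fragment is
#' primary; other loci are flagged secondary (0x100).
#'
#' @param frags an AlignedFragments object.
#' @param path output path.
#' @param seqlengths named integer vector of reference lengths for the
#'   \code{@SQ} header.
#' @param seqs optional named list with DNAStringSet \code{mate1},
#'   \code{mate2} holding read sequences by qname; written as \code{*}
#'   when absent.
#' @return the path, invisibly.
#' @export
writeSam <- function(frags, path, seqlengths, seqs = NULL) {
    rec <- copy(frags@records)
    hdr <- c("@HD\tVN:1.6\tSO:unknown",
             paste0("@SQ\tSN:", names(seqlengths), "\tLN:", seqlengths))
    if (!nrow(rec)) { writeLines(hdr, path); return(invisible(path)) }
    rec[, insert := insertLenOf(cigar)]
    setorder(rec, fragment_id, mate, rname, pos)
    rec[, locus := seq_len(.N), by = .(fragment_id, mate)]
    # pair mates locus-by-locus (truth aligner emits matching locus order)
    mate2 <- rec[mate == 2L, .(fragment_id, locus, mpos = pos, mrname = rname,
                               mstrand = strand)]
    mate1 <- rec[mate == 1L, .(fragment_id, locus, mpos = pos, mrname = rname,
                               mstrand = strand)]
    setkey(mate2, fragment_id, locus); setkey(mate1, fragment_id, locus)
    rec1 <- merge(rec[mate == 1L], mate2, by = c("fragment_id", "locus"),
                  all.x = TRUE)
    rec2 <- merge(rec[mate == 2L], mate1, by = c("fragment_id", "locus"),
                  all.x = TRUE)
    rec <- rbindlist(list(rec1, rec2))
    rec[, paired := !is.na(mpos)]
    rec[, flag := ifelse(paired, .FLAG_PAIRED + 2L, 0L) +
            ifelse(strand == "-", .FLAG_REVERSE, 0L) +
            ifelse(paired & mstrand == "-", .FLAG_MATE_REVERSE, 0L) +
            ifelse(paired & mate == 1L, .FLAG_MATE1,
                   ifelse(paired, .FLAG_MATE2, 0L)) +
            ifelse(locus > 1L, .FLAG_SECONDARY, 0L)]
    rec[, tlen := 0L]
    rec[paired == TRUE, tlen := {
        lo <- pmin(pos, mpos)
        hi <- pmax(pos + insert, mpos + insert)
        sign <- ifelse(pos <= mpos, 1L, -1L)
        as.integer(sign * (hi - lo))
    }]
    seqStr <- rep("*", nrow(rec)); qualStr <- rep("*", nrow(rec))
    if (!is.null(seqs)) {
        for (m in 1:2) {
            idx <- which(rec$mate == m)
            ss <- as.character(seqs[[paste0("mate", m)]][rec$qname[idx]])
            rev <- rec$strand[idx] == "-"
            ss[rev] <- as.character(Biostrings::reverseComplement(
                Biostrings::DNAStringSet(ss[rev])))
            seqStr[idx] <- ss
            qualStr[idx] <- strrep("I", nchar(ss))
        }
    }
    setorder(rec, fragment_id, locus, mate)
    lines <- paste(rec$qname, rec$flag, rec$rname, rec$pos, 255L, rec$cigar,
                   ifelse(rec$paired, "=", "*"),
                   ifelse(rec$paired, rec$mpos, 0L),
                   rec$tlen, seqStr, qualStr,
                   ifelse(is.na(rec$nh), "", paste0("NH:i:", rec$nh)),
                   sep = "\t")
    lines <- sub("\t$", "", lines)
    writeLines(c(hdr, lines), path)
    invisible(path)
}

# reference-consumed length of a cigar string (M/D/N/=/X)
insertLenOf <- function(cigar) {
    GenomicAlignments::cigarWidthAlongReferenceSpace(cigar)
}
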