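#' Canonical multi-map-group id
#'
#' Gene ids are deduplicated, sorted lexicographically and joined with
#' \code{"|"}; group equality is set equality.
#'
#' @param geneIds character vector of gene ids.
#' @return a single group id string ("" for an empty set).
#' @export
mmgId <- function(geneIds) paste(sort(unique(geneIds)), collapse = "|")

#' Multi-map group of each stage-1-unassigned fragment
#'
#' For every fragment not assigned in stage 1 (ambiguous, multi-mapped,
#' or no_feature with at least one locus overlapping a gene), the group
#' is the sorted union of all genes overlapped by any of its loci.
#' Fragments whose loci overlap no gene at all remain discarded.
#'
#' @param res a \linkS4class{Stage1Results}.
#' @return data.table with columns fragment_id, qname, group (the "|"
#'   serialisation), one row per rescuable fragment.
#' @export
fragmentGroups <- function(res) {
    f <- as.data.table(as.data.frame(res@fates))
    f[verdict != "assigned" & nzchar(mmg),
      .(fragment_id, qname, group = mmg)]
}

#' Compile the MMG count matrix across samples
#'
#' Discovers multi-map groups from the data only (no family or paralogue
#' annotation is consulted) and counts each rescuable fragment into
#' exactly one (group, sample) cell.  Distinct gene sets stay distinct
#' rows here; merging of contained sets is a separate, explicit step
#' (\code{\link{collapseMmgs}}).
#'
#' @param fatesBySample named list of \linkS4class{Stage1Results}, one
#'   per sample.
#' @return an \linkS4class{MmgExperiment} with assay \code{counts},
#'   rowData \code{gene_ids} (CharacterList) and \code{size}, colData
#'   \code{librarySize} (total fragments entering stage 1) and
#'   \code{unassigned} (stage-1 unassigned fragments).
#' @export
countMmgs <- function(fatesBySample) {
    stopifnot(is.list(fatesBySample), length(fatesBySample) > 0)
    if (is.null(names(fatesBySample)))
        names(fatesBySample) <- paste0("sample", seq_along(fatesBySample))
    tabs <- lapply(names(fatesBySample), function(s) {
        g <- fragmentGroups(fatesBySample[[s]])
        if (nrow(g)) g[, .(n = .N), by = group][, sample := s] else
            data.table(group = character(), n = integer(), sample = character())
    })
    long <- rbindlist(tabs)
    groups <- sort(unique(long$group))
    m <- matrix(0L, nrow = length(groups), ncol = length(fatesBySample),
                dimnames = list(groups, names(fatesBySample)))
    if (nrow(long))
        m[cbind(match(long$group, groups), match(long$sample, colnames(m)))] <-
            long$n
    .newMmgExperiment(m, fatesBySample)
}

.newMmgExperiment <- function(m, fatesBySample = NULL) {
    rn <- rownames(m)
    if (is.null(rn)) rn <- character(nrow(m))   # R drops empty dimnames
    sets <- strsplit(rn, "|", fixed = TRUE)
    rd <- DataFrame(gene_ids = IRanges::CharacterList(sets),
                    size = lengths(sets))
    cd <- DataFrame(row.names = colnames(m))
    if (!is.null(fatesBySample)) {
        tal <- vapply(fatesBySample, fateTallies, setNames(integer(5), .VERDICTS))
        cd$librarySize <- as.integer(colSums(tal))
        cd$unassigned <- as.integer(colSums(
            tal[c("no_feature", "ambiguous", "alignment_not_unique"), ,
                drop = FALSE]))
    }
    se <- SummarizedExperiment::SummarizedExperiment(
        assays = list(counts = m), rowData = rd, colData = cd)
    new("MmgExperiment", se)
}

#' Filter MMGs by read support
#'
#' Keeps a group iff it has at least \code{minReads} fragments in at
#' least \code{minSamples} samples (the reference configuration on the
#' 27-sample dataset the method was developed on is 100 reads in 13
#' datasets).
#'
#' @param x an \linkS4class{MmgExperiment}.
#' @param minReads minimum per-sample fragment count (inclusive).
#' @param minSamples minimum number of samples meeting \code{minReads}
#'   (inclusive).
#' @return the filtered \linkS4class{MmgExperiment}.
#' @export
filterMmgs <- function(x, minReads = 100L, minSamples = 13L) {
    stopifnot(minReads >= 1, minSamples >= 1)
    if (minSamples > ncol(x))
        stop("minSamples (", minSamples, ") exceeds number of samples (",
             ncol(x), ")")
    a <- SummarizedExperiment::assay(x, "counts")
    keep <- rowSums(a >= minReads) >= minSamples
    x[keep, ]
}

#' Collapse contained MMGs into their supersets
#'
#' Large groups (size >= \code{minSize}) whose gene set is wholly
#' contained in a larger surviving group are merged into that superset,
#' counts summed per sample.  The procedure is deterministic: candidates
#' are visited in increasing size (ties by group id); a contained group
#' merges into its smallest strict superset (ties by group id); merging
#' repeats until a fixed point.  Groups smaller than \code{minSize} are
#' never merged away.
#'
#' @param x an \linkS4class{MmgExperiment}.
#' @param minSize smallest group size eligible for merging (inclusive).
#' @return the collapsed \linkS4class{MmgExperiment}; total counts per
#'   sample are conserved.
#' @export
collapseMmgs <- function(x, minSize = 5L) {
    a <- SummarizedExperiment::assay(x, "counts")
    rn <- rownames(a)
    if (is.null(rn)) rn <- character(nrow(a))
    sets <- lapply(strsplit(rn, "|", fixed = TRUE), sort)
    names(sets) <- rn
    repeat {
        sizes <- lengths(sets)
        ids <- names(sets)
        ord <- order(sizes, ids)
        merged <- FALSE
        for (i in ord) {
            if (sizes[i] < minSize) next
            gi <- sets[[i]]
            cand <- which(sizes > sizes[i])
            cand <- cand[vapply(cand, function(j) all(gi %in% sets[[j]]),
                                logical(1))]
            if (!length(cand)) next
            j <- cand[order(sizes[cand], ids[cand])][1]
            a[j, ] <- a[j, ] + a[i, ]
            a <- a[-i, , drop = FALSE]
            sets <- sets[-i]
            merged <- TRUE
            break
        }
        if (!merged) break
    }
    out <- .newMmgExperiment(a)
    SummarizedExperiment::colData(out) <- SummarizedExperiment::colData(x)
    out
}

#' Rescue statistics
#'
#' Per-sample fraction of stage-1 discarded (unassigned) fragments that
#' were recovered into the kept multi-map groups.
#'
#' @param fatesBySample named list of \linkS4class{Stage1Results} (must
#'   be the ones the matrix was compiled from).
#' @param x the filtered/collapsed \linkS4class{MmgExperiment}.
#' @return data.table: sample, total, unassigned, rescued, rescued_pct
#'   (NA when nothing was unassigned), unassigned_pct.
#' @export
rescueStats <- function(fatesBySample, x) {
    a <- SummarizedExperiment::assay(x, "counts")
    tal <- vapply(fatesBySample, fateTallies, setNames(integer(5), .VERDICTS))
    total <- colSums(tal)
    unassigned <- colSums(tal[c("no_feature", "ambiguous",
                                "alignment_not_unique"), , drop = FALSE])
    rescued <- colSums(a)[names(fatesBySample)]
    data.table(sample = names(fatesBySample),
               total = as.integer(total),
               unassigned = as.integer(unassigned),
               rescued = as.integer(rescued),
               rescued_pct = ifelse(unassigned > 0,
                                    100 * rescued / unassigned, NA_real_),
               unassigned_pct = ifelse(total > 0,
                                       100 * unassigned / total, NA_real_))
}

#' Size-1 MMGs
#'
#' Groups whose every multi-mapped locus overlaps the same single gene
#' (or only one of the loci overlaps any gene); these can be folded back
#' into the single-gene analysis.
#'
#' @param x an \linkS4class{MmgExperiment}.
#' @return the subset with group size 1.
#' @export
singletonMmgs <- function(x) x[SummarizedExperiment::rowData(x)$size == 1L, ]
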