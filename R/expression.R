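#' FPKM / FPM / count conversions
#'
#' Fragments per kilobase of transcript per million fragments:
#' \code{FPKM = (Rc / T) / Rm}, with the exact inverse
#' \code{Rc = FPKM * Rm * T}, where \code{Rc} is the fragment count
#' assigned to a gene, \code{T} the transcript length in kilobases and
#' \code{Rm} the library size in millions of fragments (a read pair
#' counts once).  No effective-length or bias correction is applied.
#' FPM (\code{Rc / Rm}) is the length-free measure used for multi-map
#' groups, which have no single defensible transcript length.
#'
#' @param rc fragment count(s), >= 0.
#' @param tKb transcript length(s) in kilobases, > 0.
#' @param rmMillions library size in millions of fragments, > 0.
#' @param fpkm,fpm expression values for the inverse/log helpers.
#' @param pseudocount added before log for \code{logFpm}.
#' @return numeric vector.
#' @examples
#' fpkmFromCount(1000, 1.0, 19.654)   # 50.88 for the global design
#' countFromFpkm(fpkmFromCount(1000, 1.0, 19.654), 1.0, 19.654)
#' @export
fpkmFromCount <- function(rc, tKb, rmMillions) {
    .checkPos(tKb, "transcript length")
    .checkPos(rmMillions, "library size")
    if (any(rc < 0)) stop("counts must be >= 0")
    (rc / tKb) / rmMillions
}

#' @rdname fpkmFromCount
#' @export
countFromFpkm <- function(fpkm, tKb, rmMillions) {
    .checkPos(tKb, "transcript length")
    .checkPos(rmMillions, "library size")
    (fpkm * rmMillions) * tKb
}

#' @rdname fpkmFromCount
#' @export
fpmFromCount <- function(rc, rmMillions) {
    .checkPos(rmMillions, "library size")
    if (any(rc < 0)) stop("counts must be >= 0")
    rc / rmMillions
}

#' @rdname fpkmFromCount
#' @export
logFpm <- function(fpm, pseudocount = 1) log(fpm + pseudocount)

.checkPos <- function(x, what) {
    if (any(!is.finite(x)) || any(x <= 0))
        stop(what, " must be > 0")
    invisible(x)
}

#' Expected FPKM of a simulated design
#'
#' Computes, per gene, the FPKM implied by the simulation truth:
#' \code{(true_count / T_kb) / Rm} with \code{Rm} the total number of
#' simulated pairs in millions.
#'
#' @param dataset a \linkS4class{SimulatedDataset} (or its truth
#'   DataFrame with gene_id, length_bp, true_count).
#' @return data.table: gene_id, true_count, length_bp, expected_fpkm.
#' @export
expectedFpkmTable <- function(dataset) {
    tr <- if (is(dataset, "SimulatedDataset")) as.data.frame(simTruth(dataset))
          else as.data.frame(dataset)
    tr <- as.data.table(tr)
    rm <- sum(tr$true_count) / 1e6
    tr[, .(gene_id, true_count, length_bp,
           expected_fpkm = fpkmFromCount(true_count, length_bp / 1000, rm))]
}

#' Expression records for a count vector
#'
#' @param counts named fragment counts (genes or MMG ids).
#' @param lengthsBp named transcript lengths in bp; NA entries (e.g.
#'   MMGs) get FPM only.
#' @param librarySize total fragments in the sample.
#' @return data.table: id, Rc, T_kb, fpm, fpkm (NA where no length).
#' @export
expressionTable <- function(counts, lengthsBp = NULL, librarySize = sum(counts)) {
    .checkPos(librarySize, "library size")
    rm <- librarySize / 1e6
    dt <- data.table(id = names(counts), Rc = as.numeric(counts))
    dt[, T_kb := NA_real_]
    if (!is.null(lengthsBp))
        dt[, T_kb := as.numeric(lengthsBp[id]) / 1000]
    dt[, fpm := fpmFromCount(Rc, rm)]
    dt[, fpkm := ifelse(is.na(T_kb), NA_real_, (Rc / T_kb) / rm)]
    dt[]
}
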