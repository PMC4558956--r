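#' Pearson correlation between observed and expected expression
#'
#' Standard product-moment correlation on raw (untransformed) values,
#' aligned on gene id.  Genes present in the expectation but missing
#' from the observation are treated as 0 with a warning.
#'
#' @param observed named numeric vector (FPKM or counts) by gene id.
#' @param expected named numeric vector by gene id.
#' @return Pearson r; NA when either vector has zero variance.
#' @export
correlateExpression <- function(observed, expected) {
    stopifnot(!is.null(names(observed)), !is.null(names(expected)))
    miss <- setdiff(names(expected), names(observed))
    if (length(miss)) {
        warning(length(miss), " gene(s) missing from observation, treated as 0")
        observed <- c(observed, setNames(numeric(length(miss)), miss))
    }
    obs <- observed[names(expected)]
    if (length(obs) < 2) stop("need >= 2 genes to correlate")
    if (stats::sd(obs) == 0 || stats::sd(expected) == 0) return(NA_real_)
    as.numeric(cor(obs, expected, method = "pearson"))
}

#' Classify genes as grossly under-/over-estimated
#'
#' A gene is underestimated when at least one method assigns it a count
#' strictly below \code{low}, and overestimated when at least one method
#' assigns it a count strictly above \code{high}; the two classes are not
#' mutually exclusive.  The defaults (100 / 1900) are tied to the
#' uniform 1000-pairs-per-gene design; for variable-depth designs pass
#' \code{relativeTo} (named expected counts) and bounds are interpreted
#' as fractions of expectation.
#'
#' @param results named list of per-method named count vectors.
#' @param low,high classification thresholds (strict inequalities).
#' @param relativeTo optional named expected counts; when given, a gene
#'   is under/over when observed/expected < low or > high.
#' @return list with \code{verdicts} (data.table: gene_id, under, over,
#'   zero, plus per-method counts) and \code{summary} (nUnder, nOver,
#'   nProblematic, nZero).
#' @export
classifyGenes <- function(results, low = 100, high = 1900, relativeTo = NULL) {
    stopifnot(is.list(results), length(results) > 0)
    if (is.null(names(results)))
        names(results) <- paste0("method", seq_along(results))
    genes <- sort(unique(unlist(lapply(results, names))))
    m <- matrix(vapply(results, function(v) {
        out <- setNames(numeric(length(genes)), genes)
        out[names(v)] <- v
        out
    }, numeric(length(genes))), nrow = length(genes),
        dimnames = list(genes, names(results)))
    cmp <- m
    if (!is.null(relativeTo)) cmp <- m / relativeTo[genes]
    under <- rowSums(cmp < low) > 0
    over <- rowSums(cmp > high) > 0
    zero <- rowSums(m == 0) > 0
    verdicts <- data.table(gene_id = genes, under = under, over = over,
                           zero = zero)
    verdicts <- cbind(verdicts, as.data.table(m))
    list(verdicts = verdicts,
         summary = list(nUnder = sum(under), nOver = sum(over),
                        nProblematic = sum(under | over), nZero = sum(zero)))
}

#' Count matrix of problematic genes for heatmap export
#'
#' Rows are the genes classified problematic (under- or overestimated by
#' at least one method), ordered by gene id; columns are methods; cells
#' are counts.  Rendering is left to the caller.
#'
#' @param classification result of \code{\link{classifyGenes}}.
#' @return numeric matrix (possibly 0-row).
#' @export
accuracyHeatmapMatrix <- function(classification) {
    v <- classification$verdicts
    prob <- v[under | over]
    setorder(prob, gene_id)
    methodCols <- setdiff(names(v), c("gene_id", "under", "over", "zero"))
    m <- as.matrix(prob[, ..methodCols])
    rownames(m) <- prob$gene_id
    m
}

#' Correlation distance matrices
#'
#' Pearson correlation converted to a distance by subtracting from 1,
#' computed both across rows and across columns of a (log-FPM) matrix.
#' Cells involving a constant vector are NA.
#'
#' @param m numeric matrix (e.g. MMGs x samples of log FPM).
#' @return list with \code{rows} and \code{cols} distance matrices.
#' @export
corrDistance <- function(m) {
    if (nrow(m) < 2 || ncol(m) < 2)
        stop("need a matrix with >= 2 rows and >= 2 columns")
    d <- function(x) suppressWarnings(1 - cor(x, method = "pearson"))
    list(rows = d(t(m)), cols = d(m))
}
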