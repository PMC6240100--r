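#' @include diffphos.R
NULL

#' Enumerate positional phosphosite isoforms of a peptide
#'
#' All ways of placing `nPhospho` phosphate groups on the
#' Ser/Thr/Tyr residues of a peptide sequence — the candidate set over
#' which site-localization scores are compared. For `m` candidate
#' residues there are exactly `choose(m, nPhospho)` isoforms, returned in
#' deterministic lexicographic order.
#'
#' @param sequence amino-acid string.
#' @param nPhospho number of phosphate groups (0 <= nPhospho <= number of
#'   S/T/Y residues).
#' @return list with elements `candidates` (integer positions of S/T/Y
#'   residues) and `isoforms` (list of integer position vectors, one per
#'   isoform; a single empty assignment for `nPhospho = 0`).
#' @examples
#' enumerateSiteIsoforms("SAMSPK", 1)$isoforms   # positions 1 and 4
#' @export
enumerateSiteIsoforms <- function(sequence, nPhospho) {
    cand <- .styPositions(sequence)
    nPhospho <- as.integer(nPhospho)
    if (length(nPhospho) != 1L || is.na(nPhospho) || nPhospho < 0L)
        stop("'nPhospho' must be a single non-negative integer")
    if (nPhospho > length(cand))
        stop("nPhospho (", nPhospho, ") exceeds the ", length(cand),
             " candidate S/T/Y residue(s) of '", sequence, "'")
    isoforms <- if (nPhospho == 0L) list(integer())
                else if (length(cand) == 1L) list(cand)
                else apply(utils::combn(cand, nPhospho), 2L, identity,
                           simplify = FALSE)
    list(candidates = cand, isoforms = isoforms)
}

#' Delta score of a phosphosite assignment
#'
#' Confidence of the best positional isoform: the difference between the
#' best and the second-best assignment score. A peptide with a single
#' possible isoform is unambiguous; by default its delta is its own score
#' (maximal confidence), or `NA` when `singleIsoform = "NA"`. The delta
#' is always >= 0 and depends only on the top two scores.
#'
#' @param scores numeric assignment scores (any order; sorted
#'   internally).
#' @param singleIsoform `"score"` (default) or `"NA"`: what to report
#'   when only one isoform exists.
#' @return single non-negative number (or `NA`).
#' @examples
#' deltaScore(c(72.4, 51.0, 10.0))   # 21.4
#' @export
deltaScore <- function(scores, singleIsoform = c("score", "NA")) {
    singleIsoform <- match.arg(singleIsoform)
    scores <- as.numeric(scores)
    if (!length(scores) || anyNA(scores))
        stop("'scores' must be a non-empty numeric vector without NA")
    s <- sort(scores, decreasing = TRUE)
    if (length(s) == 1L)
        return(if (singleIsoform == "score") s else NA_real_)
    s[1L] - s[2L]
}

#' Annotate an identification table with delta scores
#'
#' Parses the semicolon-separated per-isoform score column of an
#' identification table and appends a `delta_score` column with the
#' best-minus-second-best score per row.
#'
#' @param ids identification data.frame with an isoform-score column.
#' @param column name of the isoform-score column (scores separated by
#'   `";"`).
#' @param singleIsoform passed to [deltaScore()].
#' @return `ids` with an added numeric `delta_score` column.
#' @export
annotateDeltaScores <- function(ids, column = "isoform_scores",
                                singleIsoform = c("score", "NA")) {
    singleIsoform <- match.arg(singleIsoform)
    if (!column %in% names(ids))
        stop("identification table is missing required column(s): ", column)
    ids$delta_score <- vapply(strsplit(as.character(ids[[column]]), ";",
                                       fixed = TRUE),
        function(s) deltaScore(as.numeric(s), singleIsoform), numeric(1L))
    ids
}
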