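#' @include xic.R
NULL

#' Average technical replicate runs into sample-level intensities
#'
#' Collapses the run-level quantification matrix to one column per
#' biological sample by the arithmetic mean of that sample's technical
#' replicate runs. Zero-filled (undetected) run values participate in the
#' mean as true zeros — the zero assigned to an undetectable peptide is a
#' measurement, not a missing value. Output columns are sorted by sample
#' label so the result is deterministic.
#'
#' @param object a [PhosphoQuant-class] at level `"run"`.
#' @param repMap optional data.frame with columns `run_id` and
#'   `sample_id` overriding the run-to-sample mapping in `colData`;
#'   every run must be mapped to exactly one sample.
#' @return a [PhosphoQuant-class] at level `"sample"` with one column per
#'   sample.
#' @export
averageTechnicalReplicates <- function(object, repMap = NULL) {
    stopifnot(is(object, "PhosphoQuant"))
    if (quantLevel(object) != "run")
        stop("expected a run-level matrix, got level '",
             quantLevel(object), "'")
    m <- intensityMatrix(object)
    runIds <- colnames(m)
    if (is.null(repMap)) {
        sampleOf <- SummarizedExperiment::colData(object)$sample_id
        if (is.null(sampleOf))
            stop("no 'sample_id' in colData and no 'repMap' given")
    } else {
        idx <- match(runIds, repMap$run_id)
        if (anyNA(idx))
            stop("run(s) missing from repMap: ",
                 paste(runIds[is.na(idx)], collapse = ", "))
        if (anyDuplicated(repMap$run_id))
            stop("repMap maps some run to more than one sample")
        sampleOf <- repMap$sample_id[idx]
    }
    samples <- sort(unique(sampleOf))
    out <- vapply(samples, function(s)
        rowMeans(m[, sampleOf == s, drop = FALSE]), numeric(nrow(m)))
    out <- matrix(out, nrow = nrow(m),
                  dimnames = list(rownames(m), samples))

    cd <- SummarizedExperiment::colData(object)
    keep <- !duplicated(sampleOf)
    cdS <- cd[keep, setdiff(colnames(cd), c("run_id", "tech_rep")),
              drop = FALSE]
    rownames(cdS) <- sampleOf[keep]
    cdS <- cdS[samples, , drop = FALSE]
    cdS$sample_id <- samples
    PhosphoQuant(out, colData = cdS,
                 rowData = SummarizedExperiment::rowData(object),
                 level = "sample")
}

#' Normalize each sample to total sample intensity
#'
#' Divides every column by its own total intensity, then rescales all
#' columns by the mean of the original column totals so values stay on
#' the familiar intensity scale. After normalization every column sums to
#' the same total; the operation is invariant to per-sample scale factors
#' and maps zeros to zeros.
#'
#' @param object a [PhosphoQuant-class] at level `"sample"`.
#' @return a [PhosphoQuant-class] at level `"normalized"`.
#' @export
normalizeTotalIntensity <- function(object) {
    stopifnot(is(object, "PhosphoQuant"))
    if (quantLevel(object) != "sample")
        stop("expected a sample-level matrix, got level '",
             quantLevel(object), "'; average technical replicates first")
    m <- intensityMatrix(object)
    tot <- colSums(m)
    if (any(tot <= 0))
        stop("all-zero sample column(s): ",
             paste(colnames(m)[tot <= 0], collapse = ", "))
    out <- sweep(m, 2L, tot, "/") * mean(tot)
    PhosphoQuant(out, colData = SummarizedExperiment::colData(object),
                 rowData = SummarizedExperiment::rowData(object),
                 level = "normalized")
}
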