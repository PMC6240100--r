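#' @include siteloc.R
NULL

## Required columns of an identification CSV. 'run_id' is optional: a
## table with one row per peptide species is also accepted.
.ID_REQUIRED <- c("peptide_key", "sequence", "phospho_positions", "charge",
                  "mz", "rt_obs", "score", "fdr")

#' Read and write centroided MS1 runs as mzML
#'
#' `readMzML()` reads the MS1 spectra of an mzML file into a
#' [RunSpectra-class]; retention times are converted from the mzML
#' seconds convention to the minutes used throughout the package.
#' `writeMzML()` writes a run as centroided MS1-only mzML. A write/read
#' round trip reproduces scan times, m/z and intensities to better than
#' 1e-6 relative.
#'
#' @param path mzML file path.
#' @param run a [RunSpectra-class].
#' @param runId,sampleId,techRep run annotation to attach on read
#'   (defaults: file base name, run id, 1).
#' @return `readMzML()` returns a [RunSpectra-class]; `writeMzML()`
#'   returns `path` invisibly.
#' @export
readMzML <- function(path, runId = NULL, sampleId = NULL, techRep = 1L) {
    if (!file.exists(path)) stop("mzML file not found: ", path)
    if (is.null(runId))
        runId <- sub("\\.mzML$", "", basename(path), ignore.case = TRUE)
    if (is.null(sampleId)) sampleId <- runId
    h <- NULL
    f <- mzR::openMSfile(path)
    on.exit(mzR::close(f), add = TRUE)
    n <- length(f)
    if (n == 0L) {
        warning("mzML file '", path, "' contains no spectra")
        return(RunSpectra(runId, sampleId, techRep))
    }
    h <- mzR::header(f)
    ms1 <- which(h$msLevel == 1L)
    pk <- mzR::peaks(f)
    if (!is.list(pk)) pk <- list(pk)
    peaks <- lapply(pk[ms1], function(p) {
        p <- p[order(p[, 1L]), , drop = FALSE]
        dimnames(p) <- list(NULL, c("mz", "intensity"))
        p
    })
    RunSpectra(runId, sampleId, techRep,
               scanTimes = h$retentionTime[ms1] / 60, peaks = peaks)
}

#' @rdname readMzML
#' @export
writeMzML <- function(run, path) {
    stopifnot(is(run, "RunSpectra"))
    n <- nScans(run)
    pk <- lapply(run@peaks, function(p)
        cbind(mz = p[, 1L], intensity = p[, 2L]))
    counts <- vapply(run@peaks, nrow, integer(1L))
    tic <- vapply(run@peaks, function(p) sum(p[, 2L]), numeric(1L))
    bpi <- vapply(run@peaks, function(p)
        if (nrow(p)) max(p[, 2L]) else 0, numeric(1L))
    bpm <- vapply(run@peaks, function(p)
        if (nrow(p)) p[which.max(p[, 2L]), 1L] else 0, numeric(1L))
    lomz <- vapply(run@peaks, function(p)
        if (nrow(p)) min(p[, 1L]) else 0, numeric(1L))
    himz <- vapply(run@peaks, function(p)
        if (nrow(p)) max(p[, 1L]) else 0, numeric(1L))
    hdr <- data.frame(
        seqNum = seq_len(n), acquisitionNum = seq_len(n),
        msLevel = rep(1L, n), polarity = rep(1L, n), peaksCount = counts,
        totIonCurrent = tic, retentionTime = run@scanTimes * 60,
        basePeakMZ = bpm, basePeakIntensity = bpi,
        collisionEnergy = rep(0, n), ionisationEnergy = rep(0, n),
        lowMZ = lomz, highMZ = himz, precursorScanNum = rep(0L, n),
        precursorMZ = rep(0, n), precursorCharge = rep(0L, n),
        precursorIntensity = rep(0, n), mergedScan = rep(0L, n),
        mergedResultScanNum = rep(0L, n),
        mergedResultStartScanNum = rep(0L, n),
        mergedResultEndScanNum = rep(0L, n), injectionTime = rep(0, n),
        filterString = rep(NA_character_, n),
        spectrumId = sprintf("scan=%d", seq_len(n)),
        centroided = rep(TRUE, n),
        ionMobilityDriftTime = rep(NA_real_, n),
        isolationWindowTargetMZ = rep(NA_real_, n),
        isolationWindowLowerOffset = rep(NA_real_, n),
        isolationWindowUpperOffset = rep(NA_real_, n),
        scanWindowLowerLimit = rep(NA_real_, n),
        scanWindowUpperLimit = rep(NA_real_, n))
    mzR::writeMSData(pk, file = path, header = hdr, outformat = "mzml")
    invisible(path)
}

#' Read and write runs as a TSV peak-list dialect
#'
#' A plain-text alternative to mzML for small fixtures: a
#' tab-separated table with columns `scan`, `rt_min`, `mz`, `intensity`,
#' one row per centroid (scans with no centroids are kept through the
#' per-scan `rt_min` values of an accompanying `scans` attribute line;
#' a scan is present in the grid if any row mentions it, and `intensity`
#' may be 0).
#'
#' @param path TSV file path.
#' @param run a [RunSpectra-class].
#' @param runId,sampleId,techRep run annotation to attach on read.
#' @return `readPeakTSV()` returns a [RunSpectra-class]; `writePeakTSV()`
#'   returns `path` invisibly.
#' @export
readPeakTSV <- function(path, runId = NULL, sampleId = NULL, techRep = 1L) {
    if (!file.exists(path)) stop("peak TSV not found: ", path)
    if (is.null(runId))
        runId <- sub("\\.tsv$", "", basename(path), ignore.case = TRUE)
    if (is.null(sampleId)) sampleId <- runId
    d <- utils::read.delim(path, stringsAsFactors = FALSE)
    need <- c("scan", "rt_min", "mz", "intensity")
    miss <- setdiff(need, names(d))
    if (length(miss))
        stop("peak TSV is missing required column(s): ",
             paste(miss, collapse = ", "))
    scans <- sort(unique(d$scan))
    rt <- vapply(scans, function(s) d$rt_min[d$scan == s][1L], numeric(1L))
    peaks <- lapply(scans, function(s) {
        p <- d[d$scan == s & !is.na(d$mz), c("mz", "intensity")]
        p <- p[order(p$mz), , drop = FALSE]
        cbind(mz = p$mz, intensity = p$intensity)
    })
    RunSpectra(runId, sampleId, techRep, scanTimes = rt, peaks = peaks)
}

#' @rdname readPeakTSV
#' @export
writePeakTSV <- function(run, path) {
    stopifnot(is(run, "RunSpectra"))
    rows <- lapply(seq_len(nScans(run)), function(k) {
        p <- run@peaks[[k]]
        if (nrow(p))
            data.frame(scan = k, rt_min = run@scanTimes[k],
                       mz = p[, 1L], intensity = p[, 2L])
        else  # keep empty scans on the grid with an NA centroid row
            data.frame(scan = k, rt_min = run@scanTimes[k],
                       mz = NA_real_, intensity = NA_real_)
    })
    d <- do.call(rbind, rows)
    utils::write.table(d, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    invisible(path)
}

#' Read and write peptide identification tables
#'
#' CSV with one row per identified phosphopeptide (optionally one row per
#' (peptide, run) identification event when a `run_id` column is
#' present). Required columns: `peptide_key`, `sequence`,
#' `phospho_positions`, `charge`, `mz`, `rt_obs`, `score`, `fdr`;
#' optional: `run_id`, `isoform_scores`, `delta_score`.
#'
#' @param path CSV file path.
#' @param ids identification data.frame.
#' @return `readIdTable()` returns the validated data.frame;
#'   `writeIdTable()` returns `path` invisibly.
#' @export
readIdTable <- function(path) {
    if (!file.exists(path)) stop("identification table not found: ", path)
    d <- utils::read.csv(path, stringsAsFactors = FALSE)
    miss <- setdiff(.ID_REQUIRED, names(d))
    if (length(miss))
        stop("identification table is missing required column(s): ",
             paste(miss, collapse = ", "))
    if (any(d$charge < 1)) stop("'charge' must be >= 1")
    if (any(d$mz <= 0)) stop("'mz' must be positive")
    if (any(d$fdr > 0.01))
        warning("identification FDR above 1% for ",
                sum(d$fdr > 0.01), " row(s)")
    d
}

#' @rdname readIdTable
#' @export
writeIdTable <- function(ids, path) {
    miss <- setdiff(.ID_REQUIRED, names(ids))
    if (length(miss))
        stop("identification table is missing required column(s): ",
             paste(miss, collapse = ", "))
    utils::write.csv(ids, path, row.names = FALSE, quote = FALSE)
    invisible(path)
}

#' Read and write quantification matrices as CSV
#'
#' The matrix is written with peptide keys in the first column
#' (`peptide_key`) and one column per run/sample; a sidecar metadata CSV
#' (`<path>.meta.csv` by default) stores the processing `level` and the
#' column annotation.
#'
#' @param object a [PhosphoQuant-class].
#' @param path matrix CSV path.
#' @param metaPath sidecar metadata CSV path.
#' @return `readQuantMatrix()` returns a [PhosphoQuant-class];
#'   `writeQuantMatrix()` returns `path` invisibly.
#' @export
writeQuantMatrix <- function(object, path,
                             metaPath = paste0(path, ".meta.csv")) {
    stopifnot(is(object, "PhosphoQuant"))
    m <- intensityMatrix(object)
    d <- data.frame(peptide_key = rownames(m), m, check.names = FALSE)
    utils::write.csv(d, path, row.names = FALSE, quote = FALSE)
    cd <- as.data.frame(SummarizedExperiment::colData(object))
    meta <- data.frame(column = colnames(m), level = quantLevel(object),
                       cd, row.names = NULL, check.names = FALSE)
    utils::write.csv(meta, metaPath, row.names = FALSE, quote = FALSE)
    invisible(path)
}

#' @rdname writeQuantMatrix
#' @export
readQuantMatrix <- function(path, metaPath = paste0(path, ".meta.csv")) {
    if (!file.exists(path)) stop("matrix CSV not found: ", path)
    d <- utils::read.csv(path, check.names = FALSE,
                         stringsAsFactors = FALSE)
    if (names(d)[1L] != "peptide_key")
        stop("first column of a matrix CSV must be 'peptide_key'")
    m <- as.matrix(d[, -1L, drop = FALSE])
    rownames(m) <- d$peptide_key
    level <- "run"; cd <- NULL
    if (file.exists(metaPath)) {
        meta <- utils::read.csv(metaPath, check.names = FALSE,
                                stringsAsFactors = FALSE)
        if (!all(meta$column == colnames(m)))
            stop("metadata columns disagree with matrix columns")
        level <- meta$level[1L]
        cd <- meta[, setdiff(names(meta), c("column", "level")),
                   drop = FALSE]
        rownames(cd) <- meta$column
    }
    PhosphoQuant(m, colData = cd, level = level)
}

#' Write the ground truth of a synthetic study to CSV
#'
#' Three plain CSV files: `<prefix>_peptides.csv` (regulation truth),
#' `<prefix>_abundance.csv` (true peptide x sample abundance) and
#' `<prefix>_presence.csv` (peptide x run presence flags).
#'
#' @param truth a [GroundTruth-class].
#' @param prefix output path prefix.
#' @return character vector of the three paths, invisibly.
#' @export
writeGroundTruth <- function(truth, prefix) {
    stopifnot(is(truth, "GroundTruth"))
    paths <- paste0(prefix, c("_peptides.csv", "_abundance.csv",
                              "_presence.csv"))
    utils::write.csv(truth@peptides, paths[1L], row.names = FALSE,
                     quote = FALSE)
    utils::write.csv(data.frame(peptide_key = rownames(truth@abundance),
                                truth@abundance, check.names = FALSE),
                     paths[2L], row.names = FALSE, quote = FALSE)
    utils::write.csv(data.frame(peptide_key = rownames(truth@presence),
                                truth@presence, check.names = FALSE),
                     paths[3L], row.names = FALSE, quote = FALSE)
    invisible(paths)
}
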