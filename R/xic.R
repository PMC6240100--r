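#' @include synthetic.R
NULL

#' Symmetric ppm mass window
#'
#' Relative mass window around a target m/z:
#' `lo = mz * (1 - tol * 1e-6)`, `hi = mz * (1 + tol * 1e-6)`. The
#' default tolerance for XIC construction in this package is 7 ppm.
#'
#' @param mz target m/z in Th (> 0); vectorized.
#' @param ppmTol tolerance in parts per million (>= 0).
#' @return a two-column matrix with columns `lo` and `hi`.
#' @examples
#' ppmWindow(1000, 7)   # 999.993 to 1000.007
#' @export
ppmWindow <- function(mz, ppmTol = 7) {
    if (!length(mz) || any(is.na(mz)) || any(mz <= 0))
        stop("'mz' must be positive")
    if (length(ppmTol) != 1L || is.na(ppmTol) || ppmTol < 0)
        stop("'ppmTol' must be a single value >= 0")
    cbind(lo = mz * (1 - ppmTol * 1e-6), hi = mz * (1 + ppmTol * 1e-6))
}

#' Trapezoidal XIC peak area
#'
#' Integrates an intensity-over-retention-time trace by the trapezoidal
#' rule. A trace with fewer than two points has zero width and integrates
#' to 0.
#'
#' @param trace an [XICTrace-class], or a two-column data.frame/matrix of
#'   (rt, intensity) points ordered by rt.
#' @return peak area in intensity x minutes (>= 0).
#' @examples
#' integrateArea(data.frame(rt = c(0, 1, 2), intensity = c(0, 2, 0)))  # 2
#' @export
integrateArea <- function(trace) {
    if (is(trace, "XICTrace")) {
        rt <- trace@rt; y <- trace@intensity
    } else {
        trace <- as.data.frame(trace)
        rt <- trace[[1L]]; y <- trace[[2L]]
    }
    if (length(rt) != length(y)) stop("rt and intensity lengths differ")
    if (length(rt) < 2L) return(0)
    if (any(diff(rt) <= 0)) stop("trace points must be ordered by rt")
    sum(diff(rt) * (utils::head(y, -1L) + utils::tail(y, -1L)) / 2)
}

## Normalise the 'target' argument of extractXIC: a one-row data.frame
## (identification-table row) or a named list/vector with mz, rt_ref
## (or rt_obs) and optionally peptide_key.
.asTarget <- function(target) {
    t <- as.list(target)
    mz <- t$mz
    rt <- if (!is.null(t$rt_ref)) t$rt_ref else t$rt_obs
    if (is.null(mz) || is.null(rt))
        stop("'target' needs 'mz' and 'rt_ref' (or 'rt_obs')")
    key <- if (!is.null(t$peptide_key)) as.character(t$peptide_key)
           else NA_character_
    list(mz = as.numeric(mz)[1L], rt = as.numeric(rt)[1L], key = key[1L])
}

#' Extract an ion chromatogram for one peptide from one run
#'
#' For every MS1 scan within `rtTol` minutes of the peptide's reference
#' retention time, sums the intensities of all centroids inside the
#' `ppmTol` window around the peptide m/z (the sum, not the apex centroid,
#' so that split centroids still contribute linearly). Scans with no
#' matching centroid contribute intensity 0, and a run containing no
#' signal at all yields a valid all-zero trace — absence of signal is not
#' an error, it is the zero that match-between-runs zero-fill propagates.
#'
#' Defaults are the thresholds used throughout the package: +/-7 ppm and
#' +/-2 min.
#'
#' @param run a [RunSpectra-class].
#' @param target peptide target: a one-row identification data.frame or a
#'   named list with `mz`, `rt_ref` (or `rt_obs`) and optionally
#'   `peptide_key`.
#' @param ppmTol m/z tolerance in ppm.
#' @param rtTol retention-time tolerance in minutes.
#' @return an [XICTrace-class] with the per-scan summed intensities and
#'   the trapezoidal `area`.
#' @export
extractXIC <- function(run, target, ppmTol = 7, rtTol = 2) {
    stopifnot(is(run, "RunSpectra"))
    tg <- .asTarget(target)
    w <- ppmWindow(tg$mz, ppmTol)
    sel <- which(abs(run@scanTimes - tg$rt) <= rtTol)
    y <- numeric(length(sel))
    for (k in seq_along(sel)) {
        p <- run@peaks[[sel[k]]]
        if (nrow(p)) {
            lo <- findInterval(w[1L, "lo"], p[, 1L], left.open = TRUE) + 1L
            hi <- findInterval(w[1L, "hi"], p[, 1L])
            if (hi >= lo) y[k] <- sum(p[lo:hi, 2L])
        }
    }
    rt <- run@scanTimes[sel]
    area <- if (length(rt) >= 2L) integrateArea(data.frame(rt, y)) else 0
    new("XICTrace", peptideKey = tg$key, runId = run@runId,
        rt = rt, intensity = y, area = area)
}

## Collapse a per-(peptide, run) identification table to one row per
## peptide species. The cross-run retention-time anchor is the median of
## the observed identification RTs; m/z and annotation are constant per
## key by construction.
.collapseIds <- function(ids) {
    need <- c("peptide_key", "mz", "rt_obs")
    miss <- setdiff(need, names(ids))
    if (length(miss))
        stop("identification table is missing required column(s): ",
             paste(miss, collapse = ", "))
    sp <- split(seq_len(nrow(ids)), ids$peptide_key)
    first <- vapply(sp, `[`, integer(1L), 1L)
    out <- ids[first, setdiff(names(ids), c("rt_obs", "run_id")),
               drop = FALSE]
    out$rt_ref <- vapply(sp, function(i) stats::median(ids$rt_obs[i]),
                         numeric(1L))
    mzSpread <- vapply(sp, function(i) diff(range(ids$mz[i])), numeric(1L))
    if (any(mzSpread > 0))
        stop("inconsistent theoretical m/z within peptide_key: ",
             paste(utils::head(names(sp)[mzSpread > 0], 3L), collapse = ", "))
    rownames(out) <- NULL
    out[order(out$peptide_key), , drop = FALSE]
}

#' Quantify all identified peptides in all runs
#'
#' The label-free quantification core: every identified peptide species
#' is quantified in every run by XIC peak-area integration, whether or
#' not it was identified in that run (match between runs), and peptides
#' with no detectable signal in a run get area 0, so the resulting matrix
#' is complete. With the study design of 6836 phosphopeptides over 24
#' samples acquired in duplicate this yields 6836 x 48 = 328,128 data
#' points.
#'
#' The identification table may carry one row per (peptide, run)
#' identification event; rows are collapsed per `peptide_key` and the
#' cross-run retention-time anchor is the median observed identification
#' RT. If the table is already one row per peptide, its `rt_obs` is used
#' directly.
#'
#' @param runs list of [RunSpectra-class] with unique run ids.
#' @param ids identification table with at least `peptide_key`, `mz`,
#'   `rt_obs` (observed or reference RT, minutes); duplicated
#'   `peptide_key` rows must agree on `mz`.
#' @param ppmTol,rtTol XIC extraction windows (defaults +/-7 ppm,
#'   +/-2 min).
#' @return a [PhosphoQuant-class] at level `"run"`, peptides x runs, with
#'   peptide annotation (including `rt_ref`) in `rowData` and run
#'   annotation (`run_id`, `sample_id`, `tech_rep`) in `colData`.
#' @export
quantifyAll <- function(runs, ids, ppmTol = 7, rtTol = 2) {
    if (is(runs, "RunSpectra")) runs <- list(runs)
    stopifnot(length(runs) > 0, all(vapply(runs, is, logical(1L),
                                           "RunSpectra")))
    runIds <- vapply(runs, runId, character(1L))
    if (anyDuplicated(runIds))
        stop("duplicate run id(s): ",
             paste(unique(runIds[duplicated(runIds)]), collapse = ", "))
    pep <- .collapseIds(ids)
    if (anyDuplicated(pep$peptide_key))
        stop("duplicate peptide_key after collapsing")
    nPep <- nrow(pep)

    m <- matrix(0, nPep, length(runs),
                dimnames = list(pep$peptide_key, runIds))
    w <- ppmWindow(pep$mz, ppmTol)

    for (r in seq_along(runs)) {
        run <- runs[[r]]
        nSc <- length(run@scanTimes)
        if (nSc == 0L) {
            warning("run '", runIds[r], "' has no scans; column is all zero")
            next
        }
        ## flatten the run once, sorted by m/z, for fast window lookup
        counts <- vapply(run@peaks, nrow, integer(1L))
        allScan <- rep.int(seq_len(nSc), counts)
        allMz <- unlist(lapply(run@peaks, function(p) p[, 1L]),
                        use.names = FALSE)
        allInt <- unlist(lapply(run@peaks, function(p) p[, 2L]),
                         use.names = FALSE)
        ord <- order(allMz)
        allScan <- allScan[ord]; allMz <- allMz[ord]; allInt <- allInt[ord]
        scanT <- run@scanTimes

        for (i in seq_len(nPep)) {
            sel <- which(abs(scanT - pep$rt_ref[i]) <= rtTol)
            if (length(sel) < 2L) next
            lo <- findInterval(w[i, "lo"], allMz, left.open = TRUE) + 1L
            hi <- findInterval(w[i, "hi"], allMz)
            y <- numeric(length(sel))
            if (hi >= lo) {
                hitScan <- allScan[lo:hi]
                inWin <- match(hitScan, sel)
                ok <- !is.na(inWin)
                if (any(ok)) {
                    agg <- rowsum(allInt[lo:hi][ok], group = inWin[ok])
                    y[as.integer(rownames(agg))] <- agg[, 1L]
                }
            }
            m[i, r] <- integrateArea(data.frame(scanT[sel], y))
        }
    }

    colData <- DataFrame(
        run_id = runIds,
        sample_id = vapply(runs, sampleId, character(1L)),
        tech_rep = vapply(runs, techRep, integer(1L)),
        row.names = runIds)
    PhosphoQuant(m, colData = colData, rowData = pep, level = "run")
}
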