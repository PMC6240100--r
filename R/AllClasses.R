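#' @import methods
#' @importFrom S4Vectors DataFrame metadata
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
NULL

## ---------------------------------------------------------------------------
## StudyDesign
## ---------------------------------------------------------------------------

#' Study design for a two-genotype, multi-treatment LC-MS experiment
#'
#' Describes the sampling layout of a label-free phosphoproteomics study:
#' genotypes crossed with treatments, a number of biological replicates per
#' condition, and a number of technical (repeat-injection) LC-MS runs per
#' biological sample, plus the instrument geometry of the simulated runs
#' (gradient length, MS1 duty cycle, and survey scan m/z range).
#'
#' The default design is 2 genotypes x 3 treatments x 4 biological
#' replicates = 24 samples, each acquired twice, i.e. 48 runs, with a
#' 2.1 s MS1 duty cycle and survey scans over m/z 375-1500. The default
#' gradient is 20 min so that a full synthetic study simulates in seconds;
#' a 120 min gradient is available by configuration.
#'
#' @slot genotypes character, genotype labels (reference group first).
#' @slot treatments character, treatment-arm labels.
#' @slot nBiological integer, biological replicates per condition (>= 2).
#' @slot nTechnical integer, technical replicate runs per sample (>= 1).
#' @slot gradientMinutes numeric, LC gradient duration in minutes.
#' @slot scanIntervalS numeric, MS1 duty cycle in seconds.
#' @slot mzRange numeric length 2, survey scan m/z range in Th.
#'
#' @aliases StudyDesign-class
#' @exportClass StudyDesign
setClass("StudyDesign",
    representation(
        genotypes = "character",
        treatments = "character",
        nBiological = "integer",
        nTechnical = "integer",
        gradientMinutes = "numeric",
        scanIntervalS = "numeric",
        mzRange = "numeric"
    ),
    prototype(
        genotypes = c("control", "mutant"),
        treatments = c("vehicle_24h", "oht_24h", "oht_96h"),
        nBiological = 4L,
        nTechnical = 2L,
        gradientMinutes = 20,
        scanIntervalS = 2.1,
        mzRange = c(375, 1500)
    )
)

setValidity("StudyDesign", function(object) {
    msg <- character()
    if (length(object@genotypes) < 1L || anyDuplicated(object@genotypes))
        msg <- c(msg, "'genotypes' must be non-empty unique labels")
    if (length(object@treatments) < 1L || anyDuplicated(object@treatments))
        msg <- c(msg, "'treatments' must be non-empty unique labels")
    if (length(object@nBiological) != 1L || object@nBiological < 2L)
        msg <- c(msg, "'nBiological' must be a single integer >= 2")
    if (length(object@nTechnical) != 1L || object@nTechnical < 1L)
        msg <- c(msg, "'nTechnical' must be a single integer >= 1")
    if (length(object@gradientMinutes) != 1L || object@gradientMinutes <= 0)
        msg <- c(msg, "'gradientMinutes' must be a single positive number")
    if (length(object@scanIntervalS) != 1L || object@scanIntervalS <= 0)
        msg <- c(msg, "'scanIntervalS' must be a single positive number")
    if (length(object@mzRange) != 2L || object@mzRange[1] >= object@mzRange[2])
        msg <- c(msg, "'mzRange' must be (low, high) with low < high")
    if (length(msg)) msg else TRUE
})

#' @param genotypes,treatments,nBiological,nTechnical,gradientMinutes,scanIntervalS,mzRange
#'   see the corresponding slots.
#' @return `studyDesign()` returns a validated [StudyDesign-class] object.
#' @examples
#' d <- studyDesign()
#' nSamples(d)   # 24
#' nRuns(d)      # 48
#' @rdname StudyDesign-class
#' @export
studyDesign <- function(genotypes = c("control", "mutant"),
                        treatments = c("vehicle_24h", "oht_24h", "oht_96h"),
                        nBiological = 4, nTechnical = 2,
                        gradientMinutes = 20, scanIntervalS = 2.1,
                        mzRange = c(375, 1500)) {
    new("StudyDesign", genotypes = as.character(genotypes),
        treatments = as.character(treatments),
        nBiological = as.integer(nBiological),
        nTechnical = as.integer(nTechnical),
        gradientMinutes = as.numeric(gradientMinutes),
        scanIntervalS = as.numeric(scanIntervalS),
        mzRange = as.numeric(mzRange))
}

## ---------------------------------------------------------------------------
## TruthParams
## ---------------------------------------------------------------------------

#' Ground-truth parameters of the synthetic LC-MS study
#'
#' Parameters controlling the simulated peptide population and its noise
#' structure: how many phosphopeptides, which fraction carries a true
#' genotype effect and how large it is, multiplicative log-normal
#' biological and technical variation, Bernoulli peptide-run dropout
#' (missingness that the pipeline later zero-fills), chromatographic peak
#' width, per-run mass-measurement and retention-time errors, and an
#' additive uniform background-peak model.
#'
#' @slot nPeptides integer, number of simulated phosphopeptides.
#' @slot fracRegulated numeric in \[0,1\], fraction with a true genotype
#'   effect.
#' @slot effectLog2fc numeric, magnitude of the true log2 fold change for
#'   regulated peptides (sign drawn per peptide).
#' @slot biologicalCV numeric, coefficient of variation of multiplicative
#'   log-normal noise across biological replicates.
#' @slot technicalCV numeric, same across technical replicate runs.
#' @slot dropoutProb numeric in \[0,1), probability a peptide is absent
#'   from any given run.
#' @slot peakBaseWidthS numeric, chromatographic peak width at base in
#'   seconds (base is interpreted as 4 Gaussian sigma).
#' @slot mzErrorPpmSd numeric, SD (ppm) of the per-(peptide, run) m/z
#'   error; the default 1.5 ppm keeps errors well inside a +/-7 ppm
#'   extraction window.
#' @slot rtJitterMinSd numeric, SD (minutes) of the per-(peptide, run)
#'   retention-time error.
#' @slot backgroundPeaksPerScan numeric, expected number of uniform
#'   background centroids added per MS1 scan.
#' @slot backgroundIntensityMax numeric, upper bound of the uniform
#'   background peak intensity.
#' @slot abundanceMeanLog,abundanceSdLog numeric, log-normal parameters of
#'   the base peptide abundance (XIC-area units).
#'
#' @aliases TruthParams-class
#' @exportClass TruthParams
setClass("TruthParams",
    representation(
        nPeptides = "integer",
        fracRegulated = "numeric",
        effectLog2fc = "numeric",
        biologicalCV = "numeric",
        technicalCV = "numeric",
        dropoutProb = "numeric",
        peakBaseWidthS = "numeric",
        mzErrorPpmSd = "numeric",
        rtJitterMinSd = "numeric",
        backgroundPeaksPerScan = "numeric",
        backgroundIntensityMax = "numeric",
        abundanceMeanLog = "numeric",
        abundanceSdLog = "numeric"
    ),
    prototype(
        nPeptides = 500L,
        fracRegulated = 0.1,
        effectLog2fc = 2,
        biologicalCV = 0.2,
        technicalCV = 0.05,
        dropoutProb = 0.05,
        peakBaseWidthS = 30,
        mzErrorPpmSd = 1.5,
        rtJitterMinSd = 0.15,
        backgroundPeaksPerScan = 5,
        backgroundIntensityMax = 1e4,
        abundanceMeanLog = log(1e6),
        abundanceSdLog = 1
    )
)

setValidity("TruthParams", function(object) {
    msg <- character()
    chk1 <- function(x, nm, lo = 0, loOpen = FALSE, hi = Inf, hiOpen = FALSE) {
        if (length(x) != 1L || is.na(x) ||
            (if (loOpen) x <= lo else x < lo) ||
            (if (hiOpen) x >= hi else x > hi))
            sprintf("invalid '%s'", nm) else character()
    }
    msg <- c(msg,
        chk1(object@nPeptides, "nPeptides", lo = 1),
        chk1(object@fracRegulated, "fracRegulated", lo = 0, hi = 1),
        chk1(object@effectLog2fc, "effectLog2fc", lo = -Inf),
        chk1(object@biologicalCV, "biologicalCV"),
        chk1(object@technicalCV, "technicalCV"),
        chk1(object@dropoutProb, "dropoutProb", lo = 0, hi = 1, hiOpen = TRUE),
        chk1(object@peakBaseWidthS, "peakBaseWidthS", lo = 0, loOpen = TRUE),
        chk1(object@mzErrorPpmSd, "mzErrorPpmSd"),
        chk1(object@rtJitterMinSd, "rtJitterMinSd"),
        chk1(object@backgroundPeaksPerScan, "backgroundPeaksPerScan"),
        chk1(object@backgroundIntensityMax, "backgroundIntensityMax"),
        chk1(object@abundanceSdLog, "abundanceSdLog"))
    if (length(msg)) msg else TRUE
})

#' @param nPeptides,fracRegulated,effectLog2fc,biologicalCV,technicalCV,dropoutProb,peakBaseWidthS,mzErrorPpmSd,rtJitterMinSd,backgroundPeaksPerScan,backgroundIntensityMax,abundanceMeanLog,abundanceSdLog
#'   see the corresponding slots.
#' @return `truthParams()` returns a validated [TruthParams-class] object.
#' @rdname TruthParams-class
#' @export
truthParams <- function(nPeptides = 500, fracRegulated = 0.1,
                        effectLog2fc = 2, biologicalCV = 0.2,
                        technicalCV = 0.05, dropoutProb = 0.05,
                        peakBaseWidthS = 30, mzErrorPpmSd = 1.5,
                        rtJitterMinSd = 0.15, backgroundPeaksPerScan = 5,
                        backgroundIntensityMax = 1e4,
                        abundanceMeanLog = log(1e6), abundanceSdLog = 1) {
    new("TruthParams", nPeptides = as.integer(nPeptides),
        fracRegulated = as.numeric(fracRegulated),
        effectLog2fc = as.numeric(effectLog2fc),
        biologicalCV = as.numeric(biologicalCV),
        technicalCV = as.numeric(technicalCV),
        dropoutProb = as.numeric(dropoutProb),
        peakBaseWidthS = as.numeric(peakBaseWidthS),
        mzErrorPpmSd = as.numeric(mzErrorPpmSd),
        rtJitterMinSd = as.numeric(rtJitterMinSd),
        backgroundPeaksPerScan = as.numeric(backgroundPeaksPerScan),
        backgroundIntensityMax = as.numeric(backgroundIntensityMax),
        abundanceMeanLog = as.numeric(abundanceMeanLog),
        abundanceSdLog = as.numeric(abundanceSdLog))
}

## ---------------------------------------------------------------------------
## RunSpectra
## ---------------------------------------------------------------------------

#' One LC-MS run of centroided MS1 spectra
#'
#' An ordered sequence of MS1 survey scans, each a centroided peak list.
#' Retention times are minutes throughout the package; conversion from the
#' seconds convention of mzML happens at the reader boundary.
#'
#' @slot runId character, unique run label.
#' @slot sampleId character, biological sample this run was acquired from.
#' @slot techRep integer, technical replicate index within the sample.
#' @slot scanTimes numeric, strictly increasing scan retention times
#'   (minutes).
#' @slot peaks list of two-column `cbind(mz, intensity)` matrices, one per
#'   scan, each with strictly increasing m/z and non-negative intensities.
#'
#' @aliases RunSpectra-class
#' @exportClass RunSpectra
setClass("RunSpectra",
    representation(
        runId = "character",
        sampleId = "character",
        techRep = "integer",
        scanTimes = "numeric",
        peaks = "list"
    )
)

setValidity("RunSpectra", function(object) {
    msg <- character()
    if (length(object@runId) != 1L) msg <- c(msg, "'runId' must be length 1")
    if (length(object@sampleId) != 1L)
        msg <- c(msg, "'sampleId' must be length 1")
    if (length(object@scanTimes) != length(object@peaks))
        msg <- c(msg, "one peak matrix required per scan")
    if (length(object@scanTimes) > 1L && any(diff(object@scanTimes) <= 0))
        msg <- c(msg, "'scanTimes' must be strictly increasing")
    ok <- vapply(object@peaks, function(p) {
        is.matrix(p) && ncol(p) == 2L &&
            (nrow(p) < 2L || all(diff(p[, 1L]) > 0)) &&
            all(p[, 2L] >= 0)
    }, logical(1))
    if (!all(ok))
        msg <- c(msg, paste("each scan must be a 2-column (mz, intensity)",
                            "matrix with increasing m/z and intensities >= 0"))
    if (length(msg)) msg else TRUE
})

#' @param runId,sampleId,techRep,scanTimes,peaks see the corresponding
#'   slots.
#' @return `RunSpectra()` returns a validated [RunSpectra-class] object.
#' @rdname RunSpectra-class
#' @export
RunSpectra <- function(runId, sampleId = runId, techRep = 1L,
                       scanTimes = numeric(), peaks = list()) {
    peaks <- lapply(peaks, function(p) {
        p <- as.matrix(p)
        colnames(p) <- c("mz", "intensity")
        p
    })
    new("RunSpectra", runId = as.character(runId),
        sampleId = as.character(sampleId), techRep = as.integer(techRep),
        scanTimes = as.numeric(scanTimes), peaks = peaks)
}

## ---------------------------------------------------------------------------
## XICTrace
## ---------------------------------------------------------------------------

#' Extracted ion chromatogram of one peptide in one run
#'
#' The per-scan summed intensity inside a ppm window around the peptide
#' m/z, restricted to scans within the retention-time window, together
#' with its trapezoidal peak area (intensity x minutes).
#'
#' @slot peptideKey character, peptide species label.
#' @slot runId character, source run.
#' @slot rt numeric, retention times (minutes) of the retained scans.
#' @slot intensity numeric, summed window intensity per retained scan.
#' @slot area numeric, trapezoidal integral of intensity over rt.
#'
#' @aliases XICTrace-class
#' @exportClass XICTrace
setClass("XICTrace",
    representation(
        peptideKey = "character",
        runId = "character",
        rt = "numeric",
        intensity = "numeric",
        area = "numeric"
    )
)

setValidity("XICTrace", function(object) {
    msg <- character()
    if (length(object@rt) != length(object@intensity))
        msg <- c(msg, "'rt' and 'intensity' must have equal length")
    if (length(object@rt) > 1L && any(diff(object@rt) <= 0))
        msg <- c(msg, "'rt' must be strictly increasing")
    if (any(object@intensity < 0)) msg <- c(msg, "intensities must be >= 0")
    if (length(object@area) != 1L || object@area < 0)
        msg <- c(msg, "'area' must be a single value >= 0")
    if (length(msg)) msg else TRUE
})

## ---------------------------------------------------------------------------
## PhosphoQuant
## ---------------------------------------------------------------------------

#' Phosphopeptide quantification matrix
#'
#' A [SummarizedExperiment][SummarizedExperiment::SummarizedExperiment-class]
#' holding the complete (zero-filled) phosphopeptide x run intensity
#' matrix in the `"intensity"` assay, with run/sample annotation in
#' `colData` and peptide annotation in `rowData`. The `level` slot records
#' the processing stage: `"run"` (XIC areas per run), `"sample"` (after
#' technical-replicate averaging), or `"normalized"` (after
#' total-intensity normalization).
#'
#' @slot level character, one of `"run"`, `"sample"`, `"normalized"`.
#'
#' @aliases PhosphoQuant-class
#' @exportClass PhosphoQuant
setClass("PhosphoQuant",
    contains = "SummarizedExperiment",
    representation(level = "character"),
    prototype(level = "run")
)

setValidity("PhosphoQuant", function(object) {
    msg <- character()
    if (!(length(object@level) == 1L &&
          object@level %in% c("run", "sample", "normalized")))
        msg <- c(msg, "'level' must be one of 'run', 'sample', 'normalized'")
    if (!"intensity" %in% SummarizedExperiment::assayNames(object))
        msg <- c(msg, "an 'intensity' assay is required")
    else {
        a <- SummarizedExperiment::assay(object, "intensity")
        if (anyNA(a))
            msg <- c(msg, "intensity matrix must be complete (no NA)")
        else if (any(a < 0))
            msg <- c(msg, "intensities must be >= 0")
    }
    if (length(msg)) msg else TRUE
})

#' @param intensity numeric matrix, peptides x runs (or samples),
#'   complete and non-negative, with row and column names.
#' @param colData data.frame or DataFrame of column annotation.
#' @param rowData data.frame or DataFrame of peptide annotation.
#' @param level processing stage, see the `level` slot.
#' @return `PhosphoQuant()` returns a validated [PhosphoQuant-class]
#'   object.
#' @rdname PhosphoQuant-class
#' @export
PhosphoQuant <- function(intensity, colData = NULL, rowData = NULL,
                         level = c("run", "sample", "normalized")) {
    level <- match.arg(level)
    intensity <- as.matrix(intensity)
    if (is.null(colData))
        colData <- DataFrame(row.names = colnames(intensity))
    se <- SummarizedExperiment::SummarizedExperiment(
        assays = list(intensity = intensity),
        colData = colData)
    if (!is.null(rowData))
        SummarizedExperiment::rowData(se) <- rowData
    new("PhosphoQuant", se, level = level)
}

## ---------------------------------------------------------------------------
## GroundTruth
## ---------------------------------------------------------------------------

#' Ground truth of a synthetic study
#'
#' What the simulator actually put into the runs: the true per-sample
#' abundance (expected XIC area) of every peptide, its regulation status
#' and signed true log2 fold change (mutant over control genotype), and
#' the per-(peptide, run) presence flags whose complement the pipeline
#' must recover as zero-filled cells.
#'
#' @slot peptides data.frame with columns `peptide_key`, `regulated`
#'   (logical) and `true_log2fc`; `regulated` is true iff
#'   `true_log2fc != 0`.
#' @slot abundance numeric matrix, peptide x sample true abundance
#'   (positive).
#' @slot presence logical matrix, peptide x run presence flags.
#'
#' @aliases GroundTruth-class
#' @exportClass GroundTruth
setClass("GroundTruth",
    representation(
        peptides = "data.frame",
        abundance = "matrix",
        presence = "matrix"
    )
)

setValidity("GroundTruth", function(object) {
    msg <- character()
    need <- c("peptide_key", "regulated", "true_log2fc")
    if (!all(need %in% names(object@peptides)))
        msg <- c(msg, paste("'peptides' must have columns",
                            paste(need, collapse = ", ")))
    else {
        if (!identical(object@peptides$regulated,
                       object@peptides$true_log2fc != 0))
            msg <- c(msg, "'regulated' must equal 'true_log2fc != 0'")
        n <- nrow(object@peptides)
        if (nrow(object@abundance) != n || nrow(object@presence) != n)
            msg <- c(msg, "matrix row counts must match 'peptides'")
    }
    if (any(object@abundance <= 0))
        msg <- c(msg, "true abundances must be positive")
    if (!is.logical(object@presence))
        msg <- c(msg, "'presence' must be logical")
    if (length(msg)) msg else TRUE
})
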