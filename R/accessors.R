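#' @include AllGenerics.R
NULL

#' Accessors for package classes
#'
#' Small accessor generics: `runId()`, `sampleId()`, `techRep()`,
#' `scanTimes()`, `peakLists()` and `nScans()` for [RunSpectra-class];
#' `peptideKey()`, `runId()`, `xicPoints()` and `xicArea()` for
#' [XICTrace-class]; `quantLevel()` and `intensityMatrix()` for
#' [PhosphoQuant-class]; `nSamples()` and `nRuns()` for
#' [StudyDesign-class]; `truePeptides()`, `trueAbundance()` and
#' `presenceMatrix()` for [GroundTruth-class].
#'
#' @param object an object of the documented class.
#' @return the slot content named by the accessor; `xicPoints()` returns
#'   a two-column data.frame of (rt, intensity); `nSamples()`/`nRuns()`
#'   return counts implied by the design.
#' @name accessors
#' @aliases runId sampleId techRep scanTimes peakLists nScans peptideKey
#'   xicArea xicPoints quantLevel intensityMatrix nSamples nRuns
#'   truePeptides trueAbundance presenceMatrix
NULL

#' @rdname accessors
#' @exportMethod runId
setMethod("runId", "RunSpectra", function(object) object@runId)

#' @rdname accessors
setMethod("runId", "XICTrace", function(object) object@runId)

#' @rdname accessors
#' @exportMethod sampleId
setMethod("sampleId", "RunSpectra", function(object) object@sampleId)

#' @rdname accessors
#' @exportMethod techRep
setMethod("techRep", "RunSpectra", function(object) object@techRep)

#' @rdname accessors
#' @exportMethod scanTimes
setMethod("scanTimes", "RunSpectra", function(object) object@scanTimes)

#' @rdname accessors
#' @exportMethod peakLists
setMethod("peakLists", "RunSpectra", function(object) object@peaks)

#' @rdname accessors
#' @exportMethod nScans
setMethod("nScans", "RunSpectra", function(object) length(object@scanTimes))

#' @rdname accessors
#' @exportMethod peptideKey
setMethod("peptideKey", "XICTrace", function(object) object@peptideKey)

#' @rdname accessors
#' @exportMethod xicArea
setMethod("xicArea", "XICTrace", function(object) object@area)

#' @rdname accessors
#' @exportMethod xicPoints
setMethod("xicPoints", "XICTrace", function(object)
    data.frame(rt = object@rt, intensity = object@intensity))

#' @rdname accessors
#' @exportMethod quantLevel
setMethod("quantLevel", "PhosphoQuant", function(object) object@level)

#' @rdname accessors
#' @exportMethod intensityMatrix
setMethod("intensityMatrix", "PhosphoQuant", function(object)
    SummarizedExperiment::assay(object, "intensity"))

#' @rdname accessors
#' @exportMethod nSamples
setMethod("nSamples", "StudyDesign", function(object)
    length(object@genotypes) * length(object@treatments) * object@nBiological)

#' @rdname accessors
#' @exportMethod nRuns
setMethod("nRuns", "StudyDesign", function(object)
    nSamples(object) * object@nTechnical)

#' @rdname accessors
#' @exportMethod truePeptides
setMethod("truePeptides", "GroundTruth", function(object) object@peptides)

#' @rdname accessors
#' @exportMethod trueAbundance
setMethod("trueAbundance", "GroundTruth", function(object) object@abundance)

#' @rdname accessors
#' @exportMethod presenceMatrix
setMethod("presenceMatrix", "GroundTruth", function(object) object@presence)

## show methods --------------------------------------------------------------

setMethod("show", "StudyDesign", function(object) {
    cat("StudyDesign:", length(object@genotypes), "genotypes x",
        length(object@treatments), "treatments x",
        object@nBiological, "biological replicates\n")
    cat("  ", nSamples(object), "samples x", object@nTechnical,
        "technical runs =", nRuns(object), "runs\n")
    cat("  gradient", object@gradientMinutes, "min, MS1 every",
        object@scanIntervalS, "s, m/z",
        paste(object@mzRange, collapse = "-"), "\n")
})

setMethod("show", "TruthParams", function(object) {
    cat("TruthParams:", object@nPeptides, "peptides,",
        sprintf("%.0f%% regulated at |log2FC| = %g",
                100 * object@fracRegulated, object@effectLog2fc), "\n")
    cat(sprintf("  CV bio %.2f / tech %.2f, dropout %.2f, peak base %g s\n",
        object@biologicalCV, object@technicalCV, object@dropoutProb,
        object@peakBaseWidthS))
})

setMethod("show", "RunSpectra", function(object) {
    cat("RunSpectra", object@runId, "(sample", object@sampleId,
        ", tech rep", object@techRep, "):", nScans(object), "MS1 scans")
    if (nScans(object))
        cat(sprintf(", rt %.2f-%.2f min", min(object@scanTimes),
                    max(object@scanTimes)))
    cat("\n")
})

setMethod("show", "XICTrace", function(object) {
    cat("XICTrace", object@peptideKey, "in", object@runId, ":",
        length(object@rt), "points, area", format(object@area), "\n")
})

setMethod("show", "PhosphoQuant", function(object) {
    cat("PhosphoQuant (level =", object@level, "):",
        nrow(object), "peptides x", ncol(object), "columns\n")
    callNextMethod()
})

setMethod("show", "GroundTruth", function(object) {
    cat("GroundTruth:", nrow(object@peptides), "peptides,",
        sum(object@peptides$regulated), "regulated;",
        ncol(object@abundance), "samples,", ncol(object@presence), "runs\n")
})
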