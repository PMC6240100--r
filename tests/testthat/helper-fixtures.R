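## Shared fixtures: everything is built in code at test time.

## A minimal study design: 2 genotypes x 1 treatment x 2 biological
## replicates x 2 technical runs on a short gradient.
tinyDesign <- function(...) {
    studyDesign(treatments = "vehicle_24h", nBiological = 2,
                gradientMinutes = 5, ...)
}

## Noise-free truth parameters: no dropout, no jitter, no background.
noiselessTruth <- function(nPeptides = 5, dropoutProb = 0, ...) {
    truthParams(nPeptides = nPeptides, fracRegulated = 0,
                biologicalCV = 0, technicalCV = 0,
                dropoutProb = dropoutProb,
                mzErrorPpmSd = 0, rtJitterMinSd = 0,
                backgroundPeaksPerScan = 0, ...)
}

## One run holding a single noiseless Gaussian peak of known area.
gaussianRun <- function(mz = 600, rtCenter = 2.5, area = 1e6,
                        baseWidthS = 30, gradientMinutes = 5,
                        scanIntervalS = 2.1, runId = "run1",
                        sampleId = "s1", techRep = 1L) {
    sigma <- (baseWidthS / 4) / 60
    amp <- area / (sigma * sqrt(2 * pi))
    ts <- seq(0, gradientMinutes, by = scanIntervalS / 60)
    y <- simulatePeak(amp, rtCenter, baseWidthS, ts)
    peaks <- lapply(y, function(v) cbind(mz = mz, intensity = v))
    RunSpectra(runId, sampleId, techRep, scanTimes = ts, peaks = peaks)
}

## A one-row identification target.
idRow <- function(key = "pep1", mz = 600, rt = 2.5, charge = 2L) {
    data.frame(peptide_key = key, sequence = "SAMPLEK",
               phospho_positions = "1", charge = charge, mz = mz,
               rt_obs = rt, run_id = "run1", score = 50, fdr = 0.005,
               isoform_scores = "50.0;30.0", stringsAsFactors = FALSE)
}

## Run-level PhosphoQuant built directly from a matrix.
quantFromMatrix <- function(m, sampleOf, techRep = NULL,
                            level = "run") {
    if (is.null(techRep)) {
        techRep <- stats::ave(seq_along(sampleOf), sampleOf,
                              FUN = seq_along)
    }
    cd <- S4Vectors::DataFrame(run_id = colnames(m), sample_id = sampleOf,
                               tech_rep = as.integer(techRep),
                               row.names = colnames(m))
    PhosphoQuant(m, colData = cd, level = level)
}

## Wrap a study's true run-level intensities as a run-level PhosphoQuant
## (the quantification an ideal XIC extractor would recover).
quantFromTruth <- function(study) {
    quantFromMatrix(study$runIntensity, study$runInfo$sample_id,
                    study$runInfo$tech_rep)
}
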