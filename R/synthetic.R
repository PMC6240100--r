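#' @include accessors.R
NULL

## Monoisotopic residue masses (Da). Cys omitted from the simulated
## alphabet (fixed carbamidomethylation is irrelevant to the simulator).
.AA_MONO <- c(
    G = 57.02146, A = 71.03711, S = 87.03203, P = 97.05276, V = 99.06841,
    T = 101.04768, L = 113.08406, I = 113.08406, N = 114.04293,
    D = 115.02694, Q = 128.05858, K = 128.09496, E = 129.04259,
    M = 131.04049, H = 137.05891, F = 147.06841, R = 156.10111,
    Y = 163.06333, W = 186.07931)
.MASS_H2O <- 18.0105646
.MASS_PROTON <- 1.00727646
.MASS_PHOSPHO <- 79.9663309

#' Theoretical m/z of a phosphopeptide
#'
#' Monoisotopic m/z of a peptide sequence carrying `nPhospho` phosphate
#' groups at charge `charge`.
#'
#' @param sequence amino-acid string (no Cys in the simulated alphabet).
#' @param nPhospho number of phosphate groups.
#' @param charge positive integer charge state.
#' @return m/z in Th.
#' @export
peptideMz <- function(sequence, nPhospho = 1L, charge = 2L) {
    aa <- strsplit(toupper(sequence), "")[[1L]]
    if (!all(aa %in% names(.AA_MONO)))
        stop("unknown residue(s): ",
             paste(unique(aa[!aa %in% names(.AA_MONO)]), collapse = ", "))
    m <- sum(.AA_MONO[aa]) + .MASS_H2O + nPhospho * .MASS_PHOSPHO
    (m + charge * .MASS_PROTON) / charge
}

#' Gaussian elution peak sampled on a scan grid
#'
#' Evaluates a Gaussian chromatographic peak at the given MS1 scan times.
#' The peak base width is interpreted as 4 standard deviations, so the
#' intensity at half the base width from the apex is
#' `amplitude * exp(-2)`, i.e. the peak has visibly returned to baseline
#' at its nominal base. With the instrument's 2.1 s duty cycle a 30 s
#' base is sampled by at least 10 MS1 scans.
#'
#' @param amplitude apex intensity (>= 0).
#' @param rtCenter apex retention time, minutes.
#' @param baseWidthS peak width at base, seconds (> 0).
#' @param scanTimes numeric vector of scan retention times, minutes.
#' @return numeric vector of intensities, one per scan time (empty for an
#'   empty grid).
#' @examples
#' ts <- seq(0, 2, by = 2.1 / 60)
#' y <- simulatePeak(1000, 1, 30, ts)
#' sum(y > 0)
#' @export
simulatePeak <- function(amplitude, rtCenter, baseWidthS, scanTimes) {
    if (length(amplitude) != 1L || is.na(amplitude) || amplitude < 0)
        stop("'amplitude' must be a single value >= 0")
    if (length(baseWidthS) != 1L || is.na(baseWidthS) || baseWidthS <= 0)
        stop("'baseWidthS' must be a single value > 0")
    if (!length(scanTimes)) return(numeric())
    sigma <- (baseWidthS / 4) / 60       # minutes
    amplitude * exp(-((scanTimes - rtCenter)^2) / (2 * sigma^2))
}

## Random tryptic-like phosphopeptide sequences: 7-19 residues ending in
## K/R, at least one S/T/Y so a phosphosite exists.
.randomSequences <- function(n) {
    alphabet <- names(.AA_MONO)
    out <- character(n)
    for (i in seq_len(n)) {
        repeat {
            len <- sample(7:19, 1L)
            body <- sample(alphabet, len - 1L, replace = TRUE)
            seqi <- paste0(paste(body, collapse = ""),
                           sample(c("K", "R"), 1L))
            if (any(strsplit(seqi, "")[[1L]] %in% c("S", "T", "Y"))) {
                out[i] <- seqi
                break
            }
        }
    }
    out
}

.styPositions <- function(sequence)
    which(strsplit(toupper(sequence), "")[[1L]] %in% c("S", "T", "Y"))

## One simulated peptide population: sequence, phospho positions, charge,
## theoretical m/z inside mzRange (with a small margin for ppm error).
.simulatePeptides <- function(n, mzRange) {
    margin <- 1
    seqs <- character(n); nph <- integer(n); pos <- character(n)
    charge <- integer(n); mz <- numeric(n)
    for (i in seq_len(n)) {
        repeat {
            s <- .randomSequences(1L)
            sty <- .styPositions(s)
            k <- if (length(sty) >= 2L && stats::runif(1) < 0.2) 2L else 1L
            p <- sort(sample(sty, k))
            z <- sample(2:3, 2L)          # random preference order
            hit <- FALSE
            for (zi in z) {
                m <- peptideMz(s, k, zi)
                if (m > mzRange[1] + margin && m < mzRange[2] - margin) {
                    charge[i] <- zi; mz[i] <- m; hit <- TRUE
                    break
                }
            }
            if (hit) {
                seqs[i] <- s; nph[i] <- k
                pos[i] <- paste(p, collapse = ";")
                break
            }
        }
    }
    data.frame(
        peptide_key = sprintf("pep%04d_%dp_z%d", seq_len(n), nph, charge),
        sequence = seqs, phospho_positions = pos, n_phospho = nph,
        charge = charge, mz = mz, stringsAsFactors = FALSE)
}

## Mascot-like per-peptide scores and per-isoform score lists for the
## delta-score annotation. Best isoform score equals the peptide score.
.simulateScores <- function(peptides) {
    n <- nrow(peptides)
    score <- round(stats::runif(n, 20, 100), 1)
    iso <- character(n)
    for (i in seq_len(n)) {
        m <- length(.styPositions(peptides$sequence[i]))
        k <- peptides$n_phospho[i]
        nIso <- choose(m, k)
        if (nIso <= 1L) {
            iso[i] <- format(score[i], nsmall = 1)
        } else {
            others <- score[i] - stats::rgamma(nIso - 1L, shape = 2, rate = 0.15)
            s <- sort(c(score[i], pmax(others, 0)), decreasing = TRUE)
            iso[i] <- paste(format(round(s, 1), nsmall = 1, trim = TRUE),
                            collapse = ";")
        }
    }
    data.frame(score = score, fdr = round(stats::runif(n, 0, 0.01), 4),
               isoform_scores = iso, stringsAsFactors = FALSE)
}

.lnormNoise <- function(n, cv) {
    if (cv <= 0) return(rep(1, n))
    s <- sqrt(log(1 + cv^2))
    stats::rlnorm(n, meanlog = -s^2 / 2, sdlog = s)
}

## Sample sheet in deterministic order: genotype (outer), treatment,
## biological replicate.
.sampleSheet <- function(design) {
    g <- rep(design@genotypes,
             each = length(design@treatments) * design@nBiological)
    tr <- rep(rep(design@treatments, each = design@nBiological),
              times = length(design@genotypes))
    b <- rep(seq_len(design@nBiological),
             times = length(design@genotypes) * length(design@treatments))
    data.frame(sample_id = paste(g, tr, sprintf("b%d", b), sep = "."),
               genotype = g, treatment = tr, bio_rep = b,
               stringsAsFactors = FALSE)
}

.runSheet <- function(design) {
    ss <- .sampleSheet(design)
    idx <- rep(seq_len(nrow(ss)), each = design@nTechnical)
    tech <- rep(seq_len(design@nTechnical), times = nrow(ss))
    data.frame(run_id = paste0(ss$sample_id[idx], sprintf(".t%d", tech)),
               sample_id = ss$sample_id[idx], tech_rep = tech,
               genotype = ss$genotype[idx], treatment = ss$treatment[idx],
               stringsAsFactors = FALSE)
}

#' Generate a complete synthetic LC-MS phosphoproteomics study
#'
#' Simulates a full label-free study with known ground truth: a peptide
#' population with tryptic-like sequences, phosphosite assignments and
#' theoretical m/z; per-sample true abundances with a genotype effect
#' injected into a chosen fraction of peptides (sign drawn per peptide,
#' applied in the non-reference genotype across all treatments);
#' log-normal biological and technical noise; Bernoulli peptide-run
#' dropout; per-run m/z (ppm) and retention-time errors; and, when
#' `spectra = TRUE`, the centroided MS1 scans of every run, with
#' Gaussian elution peaks on the design's duty-cycle grid plus uniform
#' background centroids.
#'
#' All randomness flows from `seed`: a master stream draws the peptide
#' population, truth, and one sub-seed per run, and each run's noise is
#' generated from its own sub-stream, so identical seeds give
#' bit-identical studies.
#'
#' @param design a [StudyDesign-class].
#' @param truth a [TruthParams-class].
#' @param seed integer seed fixing all randomness.
#' @param spectra logical; if `FALSE`, MS1 scans are not built and `runs`
#'   is `NULL`, which is much faster when only the true run-level areas
#'   (`runIntensity`) are needed, e.g. for large statistical calibration
#'   studies.
#' @return a list with elements
#'   \describe{
#'     \item{runs}{list of [RunSpectra-class], one per (sample, technical
#'       replicate), or `NULL` when `spectra = FALSE`.}
#'     \item{ids}{identification table: one row per (peptide, run) where
#'       the peptide was detectable, with columns `peptide_key`,
#'       `sequence`, `phospho_positions`, `charge`, `mz`, `rt_obs`,
#'       `run_id`, `score`, `fdr`, `isoform_scores`. Every peptide appears
#'       at least once.}
#'     \item{truth}{a [GroundTruth-class].}
#'     \item{runIntensity}{numeric matrix, peptide x run true XIC area
#'       (0 where absent).}
#'     \item{samples, runInfo}{sample and run annotation tables.}
#'     \item{design, truthParams}{the inputs, echoed.}
#'   }
#' @examples
#' st <- generateStudy(studyDesign(), truthParams(nPeptides = 20), seed = 1,
#'                     spectra = FALSE)
#' nrow(trueAbundance(st$truth))
#' @export
generateStudy <- function(design = studyDesign(), truth = truthParams(),
                          seed, spectra = TRUE) {
    if (missing(seed) || length(seed) != 1L || is.na(seed))
        stop("'seed' must be a single integer")
    validObject(design); validObject(truth)
    set.seed(as.integer(seed))

    ss <- .sampleSheet(design)
    rs <- .runSheet(design)
    n <- truth@nPeptides

    ## master stream: peptide population, truth, per-run sub-seeds
    peptides <- .simulatePeptides(n, design@mzRange)
    scores <- .simulateScores(peptides)
    rtTrue <- stats::runif(n, 0.08, 0.92) * design@gradientMinutes
    baseAbundance <- stats::rlnorm(n, truth@abundanceMeanLog,
                                   truth@abundanceSdLog)
    nReg <- round(truth@fracRegulated * n)
    regIdx <- if (nReg > 0) sort(sample.int(n, nReg)) else integer()
    sign <- numeric(n)
    if (nReg > 0)
        sign[regIdx] <- sample(c(-1, 1), nReg, replace = TRUE)
    trueLog2fc <- sign * truth@effectLog2fc

    mutant <- ss$genotype != design@genotypes[1L]
    abundance <- matrix(0, n, nrow(ss),
                        dimnames = list(peptides$peptide_key, ss$sample_id))
    for (j in seq_len(nrow(ss))) {
        eff <- if (mutant[j]) 2^trueLog2fc else rep(1, n)
        abundance[, j] <- baseAbundance * eff *
            .lnormNoise(n, truth@biologicalCV)
    }

    runSeeds <- sample.int(.Machine$integer.max, nrow(rs))

    presence <- matrix(FALSE, n, nrow(rs),
                       dimnames = list(peptides$peptide_key, rs$run_id))
    runIntensity <- matrix(0, n, nrow(rs),
                           dimnames = list(peptides$peptide_key, rs$run_id))
    runs <- if (spectra) vector("list", nrow(rs)) else NULL
    sigma <- (truth@peakBaseWidthS / 4) / 60
    scanT <- seq(0, design@gradientMinutes, by = design@scanIntervalS / 60)
    ids <- vector("list", nrow(rs))

    for (r in seq_len(nrow(rs))) {
        set.seed(runSeeds[r])
        present <- stats::runif(n) >= truth@dropoutProb
        tech <- .lnormNoise(n, truth@technicalCV)
        mzErr <- stats::rnorm(n, 0, truth@mzErrorPpmSd)
        rtErr <- stats::rnorm(n, 0, truth@rtJitterMinSd)
        sj <- match(rs$sample_id[r], ss$sample_id)
        area <- abundance[, sj] * tech * present
        presence[, r] <- present
        runIntensity[, r] <- area

        mzRun <- peptides$mz * (1 + mzErr * 1e-6)
        rtRun <- pmin(pmax(rtTrue + rtErr, 0), design@gradientMinutes)

        pidx <- which(present)
        ids[[r]] <- data.frame(
            peptide_key = peptides$peptide_key[pidx],
            rt_obs = rtRun[pidx], run_id = rs$run_id[r],
            stringsAsFactors = FALSE)

        if (spectra) {
            runs[[r]] <- .buildRunSpectra(
                runId = rs$run_id[r], sampleId = rs$sample_id[r],
                techRep = rs$tech_rep[r], scanT = scanT, sigma = sigma,
                mz = mzRun[pidx], rt = rtRun[pidx],
                area = area[pidx], truth = truth,
                mzRange = design@mzRange)
        }
    }

    idTab <- do.call(rbind, ids)
    ## contract: every peptide appears in the identification table at
    ## least once; a peptide dropped from every run is reported with its
    ## reference retention time
    missing <- setdiff(peptides$peptide_key, idTab$peptide_key)
    if (length(missing)) {
        mi <- match(missing, peptides$peptide_key)
        idTab <- rbind(idTab, data.frame(
            peptide_key = missing, rt_obs = rtTrue[mi],
            run_id = NA_character_, stringsAsFactors = FALSE))
    }
    pi <- match(idTab$peptide_key, peptides$peptide_key)
    idTab <- data.frame(
        peptide_key = idTab$peptide_key,
        sequence = peptides$sequence[pi],
        phospho_positions = peptides$phospho_positions[pi],
        charge = peptides$charge[pi], mz = peptides$mz[pi],
        rt_obs = idTab$rt_obs, run_id = idTab$run_id,
        score = scores$score[pi], fdr = scores$fdr[pi],
        isoform_scores = scores$isoform_scores[pi],
        stringsAsFactors = FALSE)
    rownames(idTab) <- NULL

    gt <- new("GroundTruth",
        peptides = data.frame(peptide_key = peptides$peptide_key,
                              regulated = trueLog2fc != 0,
                              true_log2fc = trueLog2fc,
                              rt_true = rtTrue,
                              stringsAsFactors = FALSE),
        abundance = abundance, presence = presence)

    list(runs = runs, ids = idTab, truth = gt, runIntensity = runIntensity,
         samples = ss, runInfo = rs, design = design, truthParams = truth)
}

## Build one run's centroided MS1 scans: Gaussian elution peaks for the
## detectable peptides (evaluated out to 4 sigma, i.e. >99.99% of the
## area) plus Poisson-many uniform background centroids per scan.
.buildRunSpectra <- function(runId, sampleId, techRep, scanT, sigma,
                             mz, rt, area, truth, mzRange) {
    nScan <- length(scanT)
    scanIdx <- integer(); pkMz <- numeric(); pkInt <- numeric()

    keep <- which(area > 0)
    for (i in keep) {
        lo <- findInterval(rt[i] - 4 * sigma, scanT) + 1L
        hi <- findInterval(rt[i] + 4 * sigma, scanT)
        if (hi < lo) next
        sel <- lo:hi
        amp <- area[i] / (sigma * sqrt(2 * pi))
        y <- amp * exp(-((scanT[sel] - rt[i])^2) / (2 * sigma^2))
        scanIdx <- c(scanIdx, sel)
        pkMz <- c(pkMz, rep(mz[i], length(sel)))
        pkInt <- c(pkInt, y)
    }

    if (truth@backgroundPeaksPerScan > 0) {
        nBg <- stats::rpois(nScan, truth@backgroundPeaksPerScan)
        tot <- sum(nBg)
        if (tot > 0) {
            scanIdx <- c(scanIdx, rep(seq_len(nScan), nBg))
            pkMz <- c(pkMz, stats::runif(tot, mzRange[1], mzRange[2]))
            pkInt <- c(pkInt, stats::runif(tot, 0,
                                           truth@backgroundIntensityMax))
        }
    }

    peaks <- vector("list", nScan)
    if (length(scanIdx)) {
        ord <- order(scanIdx, pkMz)
        scanIdx <- scanIdx[ord]; pkMz <- pkMz[ord]; pkInt <- pkInt[ord]
        starts <- c(1L, which(diff(scanIdx) > 0) + 1L)
        ends <- c(starts[-1L] - 1L, length(scanIdx))
        bySc <- scanIdx[starts]
        for (k in seq_along(starts)) {
            sel <- starts[k]:ends[k]
            m <- cbind(mz = pkMz[sel], intensity = pkInt[sel])
            ## merge centroids at identical m/z so per-scan m/z stays
            ## strictly increasing
            if (nrow(m) > 1L && any(diff(m[, 1L]) == 0)) {
                agg <- rowsum(m[, 2L], group = m[, 1L])
                m <- cbind(mz = as.numeric(rownames(agg)),
                           intensity = agg[, 1L])
            }
            peaks[[bySc[k]]] <- m
        }
    }
    empty <- cbind(mz = numeric(), intensity = numeric())
    for (k in seq_len(nScan))
        if (is.null(peaks[[k]])) peaks[[k]] <- empty

    new("RunSpectra", runId = runId, sampleId = sampleId,
        techRep = as.integer(techRep), scanTimes = scanT, peaks = peaks)
}
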