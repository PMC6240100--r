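test_that("default design yields 24 samples acquired as 48 runs", {
    d <- studyDesign()
    expect_equal(nSamples(d), 24L)
    expect_equal(nRuns(d), 48L)
    st <- generateStudy(d, truthParams(nPeptides = 3), seed = 1,
                        spectra = FALSE)
    expect_equal(nrow(st$samples), 24L)
    expect_equal(nrow(st$runInfo), 48L)
    expect_equal(ncol(trueAbundance(st$truth)), 24L)
    expect_equal(ncol(presenceMatrix(st$truth)), 24L * 2L)
})

test_that("design and truth parameters are validated by field", {
    expect_error(studyDesign(nBiological = 1), "nBiological")
    expect_error(studyDesign(scanIntervalS = 0), "scanIntervalS")
    expect_error(studyDesign(mzRange = c(1500, 375)), "mzRange")
    expect_error(truthParams(fracRegulated = 1.2), "fracRegulated")
    expect_error(truthParams(dropoutProb = 1), "dropoutProb")
    expect_error(truthParams(peakBaseWidthS = 0), "peakBaseWidthS")
    expect_error(generateStudy(studyDesign(), truthParams()), "seed")
})

test_that("same seed reproduces the study bit-identically", {
    d <- tinyDesign()
    tp <- truthParams(nPeptides = 10)
    a <- generateStudy(d, tp, seed = 99)
    b <- generateStudy(d, tp, seed = 99)
    expect_identical(truePeptides(a$truth), truePeptides(b$truth))
    expect_identical(trueAbundance(a$truth), trueAbundance(b$truth))
    expect_identical(a$ids, b$ids)
    expect_identical(peakLists(a$runs[[3]]), peakLists(b$runs[[3]]))
    c <- generateStudy(d, tp, seed = 100)
    expect_false(identical(trueAbundance(a$truth), trueAbundance(c$truth)))
})

test_that("no dropout means every peptide is present in every run", {
    st <- generateStudy(tinyDesign(), noiselessTruth(nPeptides = 1),
                        seed = 5, spectra = FALSE)
    expect_true(all(presenceMatrix(st$truth)))
    ## and every (peptide, sample) pair is covered with positive abundance
    expect_true(all(trueAbundance(st$truth) > 0))
})

test_that("every simulated peptide appears in the identification table", {
    st <- generateStudy(tinyDesign(), truthParams(nPeptides = 30,
                                                  dropoutProb = 0.9),
                        seed = 3, spectra = FALSE)
    expect_setequal(unique(st$ids$peptide_key),
                    truePeptides(st$truth)$peptide_key)
})

test_that("simulated peptide m/z values fall inside the instrument range", {
    d <- studyDesign()
    st <- generateStudy(d, truthParams(nPeptides = 100), seed = 8,
                        spectra = FALSE)
    mzs <- st$ids$mz
    expect_true(all(mzs > d@mzRange[1] & mzs < d@mzRange[2]))
})

test_that("simulatePeak is a Gaussian with base width = 4 sigma", {
    expect_equal(simulatePeak(1000, 2, 30, 2), 1000)
    expect_equal(simulatePeak(0, 2, 30, seq(1, 3, 0.01)),
                 rep(0, 201))
    expect_identical(simulatePeak(5, 1, 30, numeric()), numeric())
    ## at half the base width from the apex the peak is down to e^-2
    base <- 30 / 60
    y <- simulatePeak(1000, 2, 30, c(2 - base / 2, 2 + base / 2))
    expect_equal(y, rep(1000 * exp(-2), 2))
    expect_error(simulatePeak(-1, 2, 30, 1:3), "amplitude")
})

test_that("a 30 s peak at 2.1 s duty cycle spans at least 10 MS1 scans", {
    ts <- seq(0, 20, by = 2.1 / 60)
    y <- simulatePeak(1000, 10, 30, ts)
    inBase <- sum(abs(ts - 10) <= 15 / 60 & y > 0)
    expect_gte(inBase, 10)
    ## holds wherever the apex falls relative to the scan grid
    for (rt in c(5.013, 7.77, 12.3456)) {
        y <- simulatePeak(1, rt, 30, ts)
        expect_gte(sum(abs(ts - rt) <= 15 / 60 & y > 0), 10)
    }
})

test_that("simulated spectra follow the scan grid and centroid contract", {
    d <- tinyDesign()
    st <- generateStudy(d, truthParams(nPeptides = 10), seed = 2)
    expect_length(st$runs, nRuns(d))
    r <- st$runs[[1]]
    expect_true(all(diff(scanTimes(r)) > 0))
    expect_equal(scanTimes(r)[2] - scanTimes(r)[1], 2.1 / 60)
    for (p in peakLists(r)[1:20]) {
        if (nrow(p) > 1) expect_true(all(diff(p[, "mz"]) > 0))
        expect_true(all(p[, "intensity"] >= 0))
    }
})

test_that("regulation truth is internally consistent", {
    st <- generateStudy(studyDesign(),
                        truthParams(nPeptides = 200, fracRegulated = 0.25),
                        seed = 4, spectra = FALSE)
    tp <- truePeptides(st$truth)
    expect_equal(sum(tp$regulated), 50)
    expect_identical(tp$regulated, tp$true_log2fc != 0)
    expect_true(all(abs(tp$true_log2fc[tp$regulated]) == 2))
    ## effect is applied in the mutant genotype
    ab <- trueAbundance(st$truth)
    ctrl <- grepl("^control", colnames(ab))
    up <- tp$regulated & tp$true_log2fc > 0
    ratio <- rowMeans(ab[up, !ctrl, drop = FALSE]) /
             rowMeans(ab[up, ctrl, drop = FALSE])
    expect_true(all(ratio > 2))  # 2^2 effect with CV 0.2 noise
})
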