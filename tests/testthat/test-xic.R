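test_that("ppmWindow applies the relative tolerance symmetrically", {
    expect_equal(ppmWindow(1000, 7), cbind(lo = 999.993, hi = 1000.007))
    expect_equal(ppmWindow(500, 7), cbind(lo = 499.9965, hi = 500.0035))
    expect_equal(ppmWindow(1000, 0), cbind(lo = 1000, hi = 1000))
    expect_error(ppmWindow(-5, 7), "positive")
    expect_error(ppmWindow(0, 7), "positive")
    ## symmetry property over random targets and tolerances
    set.seed(1)
    mz <- runif(50, 375, 1500)
    tol <- runif(50, 0, 50)
    for (i in 1:50) {
        w <- ppmWindow(mz[i], tol[i])
        expect_equal(w[, "hi"] - mz[i], mz[i] - w[, "lo"],
                     ignore_attr = TRUE)
    }
})

test_that("integrateArea is the trapezoidal rule with zero-width = 0", {
    expect_equal(integrateArea(data.frame(rt = c(0, 1, 2),
                                          intensity = c(0, 2, 0))), 2)
    expect_equal(integrateArea(data.frame(rt = 1, intensity = 5)), 0)
    expect_equal(integrateArea(data.frame(rt = 1:10,
                                          intensity = rep(0, 10))), 0)
    expect_error(integrateArea(data.frame(rt = c(2, 1),
                                          intensity = c(1, 1))),
                 "ordered")
})

test_that("extractXIC of a run with no matching signal has area 0", {
    run <- gaussianRun(mz = 600)
    tr <- extractXIC(run, idRow(mz = 900, rt = 2.5))
    expect_s4_class(tr, "XICTrace")
    expect_equal(xicArea(tr), 0)
    expect_true(all(xicPoints(tr)$intensity == 0))
    ## points restricted to the rt window
    expect_true(all(abs(xicPoints(tr)$rt - 2.5) <= 2))
})

test_that("noiseless Gaussian area matches the closed form within 2%", {
    for (area in c(1e5, 1e6)) {
        run <- gaussianRun(area = area)
        tr <- extractXIC(run, idRow())
        expect_lt(abs(xicArea(tr) - area) / area, 0.02)
    }
    ## off-grid apex position too
    run <- gaussianRun(area = 1e6, rtCenter = 2.5137)
    tr <- extractXIC(run, idRow(rt = 2.5137))
    expect_lt(abs(xicArea(tr) - 1e6) / 1e6, 0.02)
})

test_that("XIC extraction and area are linear in the signal", {
    run <- gaussianRun(area = 1e6)
    doubled <- RunSpectra(runId(run), sampleId(run), techRep(run),
                          scanTimes(run),
                          lapply(peakLists(run), function(p)
                              cbind(mz = p[, 1], intensity = 2 * p[, 2])))
    a1 <- xicArea(extractXIC(run, idRow()))
    a2 <- xicArea(extractXIC(doubled, idRow()))
    expect_equal(a2, 2 * a1)
})

test_that("per-scan window intensity is the sum of matching centroids", {
    ## two centroids inside the window on each of three scans
    ts <- c(1.0, 1.1, 1.2)
    peaks <- lapply(c(10, 20, 10), function(v)
        cbind(mz = c(599.9995, 600.0005), intensity = c(v, v)))
    run <- RunSpectra("r", "s", 1L, ts, peaks)
    tr <- extractXIC(run, idRow(mz = 600, rt = 1.1), ppmTol = 7)
    expect_equal(xicPoints(tr)$intensity, c(20, 40, 20))
})

test_that("quantifyAll produces a complete zero-filled matrix", {
    run <- gaussianRun()
    q <- quantifyAll(list(run), idRow())
    expect_s4_class(q, "PhosphoQuant")
    expect_equal(dim(q), c(1L, 1L))
    expect_gt(intensityMatrix(q)[1, 1], 0)
    expect_equal(quantLevel(q), "run")

    ## a peptide with no signal anywhere still gets a (zero) cell
    ids2 <- rbind(idRow(), idRow(key = "pep2", mz = 1200))
    q2 <- quantifyAll(list(run), ids2)
    expect_equal(dim(q2), c(2L, 1L))
    expect_false(anyNA(intensityMatrix(q2)))
    expect_equal(intensityMatrix(q2)["pep2", 1], 0, ignore_attr = TRUE)
})

test_that("quantifyAll rejects inconsistent input and warns on empty runs", {
    run <- gaussianRun()
    dup <- rbind(idRow(), transform(idRow(), mz = 700))
    expect_error(quantifyAll(list(run), dup), "inconsistent")
    r2 <- RunSpectra("run1b", "s1", 2L)
    expect_warning(q <- quantifyAll(list(run, r2), idRow()), "no scans")
    expect_equal(intensityMatrix(q)[, "run1b"], 0, ignore_attr = TRUE)
    expect_error(quantifyAll(list(run, run), idRow()), "duplicate run")
})

test_that("identification rows collapse per peptide with a median rt anchor", {
    rows <- do.call(rbind, lapply(c(2.4, 2.5, 2.9), function(rt)
        transform(idRow(), rt_obs = rt, run_id = paste0("r", rt))))
    run <- gaussianRun(rtCenter = 2.5)
    q <- quantifyAll(list(run), rows)
    expect_equal(nrow(q), 1L)
    expect_equal(SummarizedExperiment::rowData(q)$rt_ref, 2.5)
})

test_that("widening tolerances never decreases a cell", {
    st <- generateStudy(tinyDesign(), truthParams(nPeptides = 8),
                        seed = 21)
    base <- intensityMatrix(quantifyAll(st$runs, st$ids, ppmTol = 3,
                                        rtTol = 0.5))
    widerPpm <- intensityMatrix(quantifyAll(st$runs, st$ids, ppmTol = 10,
                                            rtTol = 0.5))
    widerRt <- intensityMatrix(quantifyAll(st$runs, st$ids, ppmTol = 3,
                                           rtTol = 2))
    expect_true(all(widerPpm - base >= -1e-9 * base))
    expect_true(all(widerRt - base >= -1e-9 * base))
})

test_that("zeros land exactly where the ground truth marks absence", {
    st <- generateStudy(tinyDesign(),
                        noiselessTruth(nPeptides = 12, dropoutProb = 0.3),
                        seed = 31)
    q <- quantifyAll(st$runs, st$ids)
    m <- intensityMatrix(q)
    pres <- presenceMatrix(st$truth)[rownames(m), colnames(m)]
    expect_identical(m > 0, pres)
})

test_that("recovered areas are proportional to true abundances", {
    st <- generateStudy(tinyDesign(), noiselessTruth(nPeptides = 15),
                        seed = 41)
    q <- quantifyAll(st$runs, st$ids)
    m <- as.vector(intensityMatrix(q))
    truth <- as.vector(st$runIntensity[rownames(intensityMatrix(q)),
                                       colnames(intensityMatrix(q))])
    fit <- stats::lm(m ~ truth)
    expect_gt(summary(fit)$r.squared, 0.999)
})
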