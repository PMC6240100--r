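test_that("technical replicates average arithmetically, zeros included", {
    m <- matrix(c(4, 0, 6, 8), nrow = 2,
                dimnames = list(c("p1", "p2"), c("s1.t1", "s1.t2")))
    q <- quantFromMatrix(m, c("s1", "s1"))
    avg <- averageTechnicalReplicates(q)
    expect_equal(quantLevel(avg), "sample")
    ## 4 and 6 -> 5; 0 (undetected, zero-filled) and 8 -> 4
    expect_equal(intensityMatrix(avg)[, "s1"], c(p1 = 5, p2 = 4))
})

test_that("a single technical replicate leaves values unchanged", {
    m <- matrix(c(1, 2, 3, 4), nrow = 2,
                dimnames = list(c("p1", "p2"), c("sB.t1", "sA.t1")))
    q <- quantFromMatrix(m, c("sB", "sA"))
    avg <- averageTechnicalReplicates(q)
    ## values identical, columns relabelled and sorted by sample
    expect_equal(colnames(intensityMatrix(avg)), c("sA", "sB"))
    expect_equal(intensityMatrix(avg)[, "sA"], m[, "sA.t1"])
    expect_equal(intensityMatrix(avg)[, "sB"], m[, "sB.t1"])
})

test_that("runs missing from an explicit replicate map are an error", {
    m <- matrix(1:4, 2, dimnames = list(c("p1", "p2"), c("r1", "r2")))
    q <- quantFromMatrix(m, c("s1", "s1"))
    repMap <- data.frame(run_id = "r1", sample_id = "s1")
    expect_error(averageTechnicalReplicates(q, repMap), "r2")
})

test_that("normalization equalizes column totals and preserves zeros", {
    m <- matrix(c(2, 3, 5, 0, 8, 12), nrow = 3,
                dimnames = list(paste0("p", 1:3), c("sA", "sB")))
    q <- quantFromMatrix(m, c("sA", "sB"), techRep = c(1, 1),
                         level = "sample")
    n <- normalizeTotalIntensity(q)
    expect_equal(quantLevel(n), "normalized")
    nm <- intensityMatrix(n)
    ## totals 10 and 20 -> both columns sum to their mean, 15
    expect_equal(unname(colSums(nm)), c(15, 15))
    expect_equal(nm["p1", "sB"], 0, ignore_attr = TRUE)
    expect_true(all(nm >= 0))
})

test_that("a single-sample matrix is a fixed point of normalization", {
    m <- matrix(c(2, 3, 5), 3, dimnames = list(paste0("p", 1:3), "sA"))
    q <- quantFromMatrix(m, "sA", techRep = 1, level = "sample")
    expect_equal(intensityMatrix(normalizeTotalIntensity(q)), m)
})

test_that("normalization is invariant to per-sample scale factors", {
    set.seed(7)
    m <- matrix(rexp(30, 1e-5), 10, 3,
                dimnames = list(paste0("p", 1:10), paste0("s", 1:3)))
    q1 <- quantFromMatrix(m, colnames(m), techRep = rep(1, 3),
                          level = "sample")
    m2 <- m; m2[, 2] <- m2[, 2] * 100
    q2 <- quantFromMatrix(m2, colnames(m), techRep = rep(1, 3),
                          level = "sample")
    n1 <- intensityMatrix(normalizeTotalIntensity(q1))
    n2 <- intensityMatrix(normalizeTotalIntensity(q2))
    ## identical up to the overall rescale constant (ratios preserved)
    expect_equal(sweep(n1, 2, colSums(n1), "/"),
                 sweep(n2, 2, colSums(n2), "/"), tolerance = 1e-10)
    ## column-sum equality to within 1e-10 relative
    expect_lt(diff(range(colSums(n2))) / mean(colSums(n2)), 1e-10)
})

test_that("an all-zero sample is rejected by name", {
    m <- matrix(c(1, 2, 0, 0), 2,
                dimnames = list(c("p1", "p2"), c("good", "bad")))
    q <- quantFromMatrix(m, colnames(m), techRep = c(1, 1),
                         level = "sample")
    expect_error(normalizeTotalIntensity(q), "bad")
})

test_that("the pipeline enforces the average-then-normalize order", {
    m <- matrix(1:4, 2, dimnames = list(c("p1", "p2"), c("r1", "r2")))
    q <- quantFromMatrix(m, c("s1", "s2"))
    expect_error(normalizeTotalIntensity(q), "sample-level")
    avg <- averageTechnicalReplicates(q)
    expect_error(averageTechnicalReplicates(avg), "run-level")
})
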