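test_that("pooled t matches the frozen worked example", {
    r <- studentsT(c(1, 2, 3, 4), c(2, 3, 4, 5))
    expect_equal(r$t, -1.0954451150, tolerance = 1e-9)
    expect_equal(r$df, 6)
    expect_equal(r$p, 0.3153335962, tolerance = 1e-9)
})

test_that("pooled t is antisymmetric and handles degenerate groups", {
    a <- c(1.2, 3.4, 2.2); b <- c(0.4, 4.1, 5.0, 2.2)
    r1 <- studentsT(a, b); r2 <- studentsT(b, a)
    expect_equal(r1$t, -r2$t)
    expect_equal(r1$p, r2$p)
    ## identical groups
    r <- studentsT(c(1, 2, 3), c(1, 2, 3))
    expect_equal(r$t, 0); expect_equal(r$p, 1)
    ## zero variance, equal means
    r <- studentsT(c(2, 2), c(2, 2))
    expect_equal(r$p, 1); expect_false(r$degenerate)
    ## zero variance, unequal means: smallest positive p, flagged
    r <- studentsT(c(2, 2), c(3, 3))
    expect_equal(r$p, .Machine$double.xmin)
    expect_true(r$degenerate)
    expect_error(studentsT(1, c(1, 2)), "at least 2")
})

test_that("pooled t agrees with stats::t.test on 100 random instances", {
    set.seed(123)
    for (i in 1:100) {
        na <- sample(2:8, 1); nb <- sample(2:8, 1)
        a <- rnorm(na, sd = runif(1, 0.5, 3))
        b <- rnorm(nb, mean = runif(1, -1, 1), sd = runif(1, 0.5, 3))
        mine <- studentsT(a, b)
        ref <- t.test(a, b, var.equal = TRUE)
        expect_equal(mine$t, unname(ref$statistic), tolerance = 1e-10)
        expect_equal(mine$p, ref$p.value, tolerance = 1e-8)
        expect_equal(mine$df, unname(ref$parameter))
    }
})

test_that("vectorized row-wise t equals the scalar implementation", {
    set.seed(5)
    A <- matrix(rlnorm(40 * 4), 40)
    B <- matrix(rlnorm(40 * 4), 40)
    rr <- phosphoLFQ:::.rowPooledT(A, B)
    for (i in seq_len(40)) {
        s <- studentsT(A[i, ], B[i, ])
        expect_equal(rr$t[i], s$t, tolerance = 1e-12)
        expect_equal(rr$p[i], s$p, tolerance = 1e-12)
    }
})

test_that("log2 fold change follows the epsilon rule", {
    expect_equal(log2FoldChange(c(100, 100), c(400, 400)), 2)
    expect_equal(log2FoldChange(c(5, 5), c(5, 5)), 0)
    expect_warning(z <- log2FoldChange(c(0, 0), c(0, 0)), "zero")
    expect_equal(z, 0)
    ## epsilon keeps zero-filled peptides finite
    expect_true(is.finite(log2FoldChange(c(0, 0), c(4, 4),
                                         epsilon = 0.5)))
    m <- matrix(c(0, 4, 10, 2), 2)
    expect_equal(foldChangeEpsilon(m), 1)  # half of the smallest positive
})

test_that("classification applies both the P tiers and the fc gate", {
    r <- classifyRegulation(c(1.0, 0.5, -0.9, 0.9, 0.9),
                            c(0.005, 0.001, 0.03, 0.04, 0.2))
    expect_equal(as.character(r$sig_class),
                 c("sig_p01", "ns", "sig_p05", "sig_p05", "ns"))
    expect_equal(as.character(r$direction),
                 c("up", "none", "down", "up", "none"))
})

test_that("classification is monotone in p and |log2fc|", {
    set.seed(9)
    rank <- c(ns = 0, sig_p05 = 1, sig_p01 = 2)
    for (i in 1:200) {
        fc <- runif(1, -3, 3); p <- runif(1)
        c1 <- rank[as.character(classifyRegulation(fc, p)$sig_class)]
        ## decreasing p or increasing |fc| never demotes significance
        c2 <- rank[as.character(classifyRegulation(fc, p * runif(1))$sig_class)]
        c3 <- rank[as.character(
            classifyRegulation(fc * (1 + runif(1)), p)$sig_class)]
        expect_gte(c2, c1)
        expect_gte(c3, c1)
    }
})

test_that("volcano coordinates are (log2fc, -log10 p)", {
    expect_equal(volcanoCoords(1.5, 0.01), data.frame(x = 1.5, y = 2))
    expect_equal(volcanoCoords(0, 1), data.frame(x = 0, y = 0))
    expect_equal(volcanoCoords(-0.8, 0.05)$y, 1.3010299957,
                 tolerance = 1e-9)
    expect_error(volcanoCoords(1, 0), "p")
    expect_error(volcanoCoords(1, -0.1), "p")
})

test_that("venn regions enumerate correctly and sum to the union", {
    v <- vennPartition(list(g1 = c("A", "B"), g2 = c("B", "C")))
    expect_equal(v$count[v$region == "g1"], 1L)
    expect_equal(v$count[v$region == "g2"], 1L)
    expect_equal(v$count[v$region == "g1&g2"], 1L)
    expect_equal(sum(v$count), 3L)
    expect_equal(sum(v$percent), 100)

    ## identical sets: all mass in the intersection
    v2 <- vennPartition(list(a = c("x", "y"), b = c("x", "y")))
    expect_equal(v2$count[v2$region == "a&b"], 2L)
    expect_equal(sum(v2$count), 2L)

    ## three disjoint sets
    v3 <- vennPartition(list(a = paste0("a", 1:2), b = paste0("b", 1:3),
                             c = paste0("c", 1:4)))
    expect_equal(v3$count[match(c("a", "b", "c"), v3$region)],
                 c(2L, 3L, 4L))
    expect_equal(sum(v3$count), 9L)
    expect_true(all(v3$count[grepl("&", v3$region)] == 0L))
})

test_that("venn conservation holds on random set systems", {
    set.seed(11)
    for (i in 1:25) {
        n <- sample(2:3, 1)
        sets <- lapply(seq_len(n), function(j)
            sample(letters, sample(0:15, 1)))
        names(sets) <- paste0("S", seq_len(n))
        v <- vennPartition(sets)
        expect_equal(sum(v$count),
                     length(unique(unlist(sets, use.names = FALSE))))
    }
})

test_that("diffPhos ties the statistics together on a known matrix", {
    ## p1 strongly up in group B, p2 unchanged, p3 zero everywhere in A
    m <- rbind(
        p1 = c(10, 11, 9, 10, 41, 39, 40, 42) * 1000,
        p2 = c(20, 21, 19, 20, 20, 21, 19, 20) * 1000,
        p3 = c(0, 0, 0, 0, 5, 6, 5, 5))
    colnames(m) <- paste0("s", 1:8)
    q <- quantFromMatrix(m, colnames(m), techRep = rep(1, 8),
                         level = "normalized")
    r <- diffPhos(q, paste0("s", 1:4), paste0("s", 5:8), name = "cmp")
    expect_equal(as.character(r$sig_class[r$peptide_key == "p1"]),
                 "sig_p01")
    expect_equal(as.character(r$direction[r$peptide_key == "p1"]), "up")
    expect_equal(r$log2fc[r$peptide_key == "p1"], 2, tolerance = 0.05)
    expect_equal(as.character(r$sig_class[r$peptide_key == "p2"]), "ns")
    expect_true(is.finite(r$log2fc[r$peptide_key == "p3"]))
    ## guards
    expect_error(diffPhos(q, paste0("s", 1:4), paste0("s", 4:8)),
                 "disjoint")
    expect_error(diffPhos(q, "s1", paste0("s", 5:8)), "at least 2")
    expect_error(diffPhos(q, paste0("s", 1:4), c("s5", "s6", "nope")),
                 "unknown sample")
})

test_that("heatmap fold changes recover group ratios per comparison", {
    st <- generateStudy(studyDesign(),
                        truthParams(nPeptides = 300, biologicalCV = 0.1,
                                    technicalCV = 0, dropoutProb = 0),
                        seed = 17, spectra = FALSE)
    q <- quantFromTruth(st)
    n <- normalizeTotalIntensity(averageTechnicalReplicates(q))
    cmp <- makeComparisons(st$samples)
    tp <- truePeptides(st$truth)
    reg <- tp$peptide_key[tp$regulated]
    fc <- heatmapFoldChanges(n, cmp, reg, log2 = TRUE)
    expect_equal(dim(fc), c(length(reg), 3L))
    ## injected effect recovered in every treatment arm
    truefc <- tp$true_log2fc[match(reg, tp$peptide_key)]
    for (j in 1:3)
        expect_true(all(abs(fc[, j] - truefc) < 0.5))
    ## unregulated peptides sit near fold change 1
    un <- tp$peptide_key[!tp$regulated][1:10]
    fcu <- heatmapFoldChanges(n, cmp, un)
    expect_true(all(abs(log2(fcu)) < 0.5))
    ## empty subset and unknown keys
    expect_equal(nrow(heatmapFoldChanges(n, cmp, character())), 0L)
    expect_error(heatmapFoldChanges(n, cmp, "nope"), "unknown peptide")
})
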