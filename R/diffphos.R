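#' @include abundance.R
NULL

#' Pooled-variance two-sample Student's t test
#'
#' Classical two-sided Student's t test with pooled variance on
#' `length(a) + length(b) - 2` degrees of freedom, as used for
#' per-phosphopeptide group comparisons. The statistic is
#' `t = (mean(a) - mean(b)) / (sp * sqrt(1/na + 1/nb))`, so swapping the
#' groups negates `t` and leaves `p` unchanged.
#'
#' Degenerate inputs are resolved deterministically rather than erroring:
#' both groups constant and equal gives `t = 0, p = 1`; both groups
#' constant but unequal gives an infinite statistic and the smallest
#' representable positive p, flagged in the `degenerate` field.
#'
#' @param a,b numeric vectors of length >= 2.
#' @return list with elements `t`, `df`, `p` and logical `degenerate`.
#' @examples
#' studentsT(c(1, 2, 3, 4), c(2, 3, 4, 5))
#' @export
studentsT <- function(a, b) {
    if (length(a) < 2L || length(b) < 2L)
        stop("each group needs at least 2 values")
    if (anyNA(a) || anyNA(b)) stop("missing values not allowed")
    na <- length(a); nb <- length(b)
    df <- na + nb - 2
    sp2 <- ((na - 1) * stats::var(a) + (nb - 1) * stats::var(b)) / df
    dm <- mean(a) - mean(b)
    if (sp2 <= 0) {
        if (dm == 0) return(list(t = 0, df = df, p = 1, degenerate = FALSE))
        return(list(t = sign(dm) * Inf, df = df,
                    p = .Machine$double.xmin, degenerate = TRUE))
    }
    t <- dm / sqrt(sp2 * (1 / na + 1 / nb))
    list(t = t, df = df, p = 2 * stats::pt(-abs(t), df), degenerate = FALSE)
}

## Row-wise pooled t over two column-subsets of a matrix (vectorized
## equivalent of studentsT per row; same degenerate-case contracts).
.rowPooledT <- function(A, B) {
    na <- ncol(A); nb <- ncol(B)
    df <- na + nb - 2
    ma <- rowMeans(A); mb <- rowMeans(B)
    va <- rowSums((A - ma)^2) / (na - 1)
    vb <- rowSums((B - mb)^2) / (nb - 1)
    sp2 <- ((na - 1) * va + (nb - 1) * vb) / df
    dm <- ma - mb
    t <- dm / sqrt(sp2 * (1 / na + 1 / nb))
    p <- 2 * stats::pt(-abs(t), df)
    deg <- sp2 <= 0
    if (any(deg)) {
        zeq <- deg & dm == 0
        t[zeq] <- 0; p[zeq] <- 1
        zne <- deg & dm != 0
        t[zne] <- sign(dm[zne]) * Inf
        p[zne] <- .Machine$double.xmin
    }
    list(t = t, df = df, p = p, degenerate = deg & dm != 0)
}

#' Epsilon for log2 fold changes of zero-filled intensities
#'
#' Half the smallest positive value in the matrix: a deterministic,
#' scale-aware pseudo-intensity added to both group means so zero-filled
#' peptides have finite fold changes.
#'
#' @param m non-negative numeric matrix (or [PhosphoQuant-class]).
#' @return single non-negative number (0 when the matrix has no positive
#'   entry).
#' @export
foldChangeEpsilon <- function(m) {
    if (is(m, "PhosphoQuant")) m <- intensityMatrix(m)
    pos <- m[m > 0]
    if (!length(pos)) 0 else min(pos) / 2
}

#' Log2 fold change between group means
#'
#' `log2(mean(b) + epsilon) - log2(mean(a) + epsilon)`, the log2 fold
#' change of group b over group a. With both means zero the fold change
#' is 0 and a warning flags the degenerate peptide.
#'
#' @param a,b non-negative numeric vectors (group a = reference).
#' @param epsilon non-negative pseudo-intensity, see
#'   [foldChangeEpsilon()].
#' @return log2 fold change (single number).
#' @examples
#' log2FoldChange(c(100, 100), c(400, 400))  # 2
#' @export
log2FoldChange <- function(a, b, epsilon = 0) {
    if (any(a < 0) || any(b < 0)) stop("intensities must be non-negative")
    ma <- mean(a); mb <- mean(b)
    if (ma == 0 && mb == 0) {
        warning("both group means are zero; fold change set to 0")
        return(0)
    }
    log2(mb + epsilon) - log2(ma + epsilon)
}

#' Classify differential regulation from fold change and P value
#'
#' The volcano-plot classification rule: a phosphopeptide is significant
#' at the 1% tier (`sig_p01`) when `p < p01` and `|log2fc| > fcThreshold`,
#' at the 5% tier (`sig_p05`) when `p01 <= p < p05` with the same
#' fold-change gate, and not significant (`ns`) otherwise. Direction is
#' `up`/`down` by the sign of the fold change for significant peptides
#' and `none` for `ns`. The fold-change threshold (default 0.8) is taken
#' on the log2 axis.
#'
#' @param log2fc,p numeric vectors (recycled to common length).
#' @param fcThreshold log2 fold-change gate (> 0).
#' @param p05,p01 significance tiers.
#' @return data.frame with factor columns `sig_class`
#'   (`ns`/`sig_p05`/`sig_p01`) and `direction` (`none`/`up`/`down`).
#' @examples
#' classifyRegulation(c(1, 0.5, -0.9), c(0.005, 0.001, 0.03))
#' @export
classifyRegulation <- function(log2fc, p, fcThreshold = 0.8,
                               p05 = 0.05, p01 = 0.01) {
    stopifnot(fcThreshold > 0, p05 > 0, p01 > 0, p01 <= p05)
    n <- max(length(log2fc), length(p))
    log2fc <- rep_len(log2fc, n); p <- rep_len(p, n)
    gate <- abs(log2fc) > fcThreshold
    cls <- ifelse(gate & p < p01, "sig_p01",
           ifelse(gate & p < p05, "sig_p05", "ns"))
    dir <- ifelse(cls == "ns", "none", ifelse(log2fc > 0, "up", "down"))
    data.frame(
        sig_class = factor(cls, levels = c("ns", "sig_p05", "sig_p01")),
        direction = factor(dir, levels = c("none", "up", "down")))
}

#' Volcano plot coordinates
#'
#' `x = log2fc`, `y = -log10(p)`.
#'
#' @param log2fc,p numeric vectors; `p` must lie in (0, 1].
#' @return data.frame with columns `x` and `y`.
#' @export
volcanoCoords <- function(log2fc, p) {
    if (any(is.na(p)) || any(p <= 0) || any(p > 1))
        stop("'p' must lie in (0, 1]")
    data.frame(x = log2fc, y = -log10(p))
}

#' Differential regulation of every phosphopeptide between two groups
#'
#' Runs the per-peptide statistics of one group comparison on a
#' normalized quantification matrix: pooled-variance Student's t test,
#' log2 fold change of the mutant/treated group over the control group
#' (with the matrix-wide epsilon of [foldChangeEpsilon()]), and the
#' two-tier volcano significance classification.
#'
#' @param object a [PhosphoQuant-class] at level `"normalized"` (a
#'   `"sample"`-level matrix is accepted with a warning).
#' @param groupA character, sample ids of the reference (control) group
#'   (>= 2, disjoint from `groupB`).
#' @param groupB character, sample ids of the comparison group (>= 2).
#' @param name comparison label carried into the result.
#' @param fcThreshold,p05,p01 classification thresholds, see
#'   [classifyRegulation()].
#' @return data.frame with one row per peptide: `peptide_key`,
#'   `comparison`, `log2fc`, `t`, `p_value`, `sig_class`, `direction`,
#'   `degenerate`.
#' @export
diffPhos <- function(object, groupA, groupB, name = "comparison",
                     fcThreshold = 0.8, p05 = 0.05, p01 = 0.01) {
    stopifnot(is(object, "PhosphoQuant"))
    if (quantLevel(object) == "run")
        stop("run-level matrix: average technical replicates and ",
             "normalize first")
    if (quantLevel(object) == "sample")
        warning("matrix is not normalized to total sample intensity")
    m <- intensityMatrix(object)
    groupA <- as.character(groupA); groupB <- as.character(groupB)
    if (length(intersect(groupA, groupB)))
        stop("groups must be disjoint")
    if (length(groupA) < 2L || length(groupB) < 2L)
        stop("each group needs at least 2 samples")
    miss <- setdiff(c(groupA, groupB), colnames(m))
    if (length(miss))
        stop("unknown sample id(s): ", paste(miss, collapse = ", "))

    A <- m[, groupA, drop = FALSE]
    B <- m[, groupB, drop = FALSE]
    tt <- .rowPooledT(A, B)
    eps <- foldChangeEpsilon(m)
    ma <- rowMeans(A); mb <- rowMeans(B)
    l2fc <- ifelse(ma == 0 & mb == 0, 0,
                   log2(mb + eps) - log2(ma + eps))
    ## t is computed as mean(A) - mean(B); report it oriented like the
    ## fold change (B over A)
    cls <- classifyRegulation(l2fc, tt$p, fcThreshold, p05, p01)
    data.frame(
        peptide_key = rownames(m), comparison = name,
        log2fc = l2fc, t = -tt$t, p_value = tt$p,
        sig_class = cls$sig_class, direction = cls$direction,
        degenerate = tt$degenerate | (ma == 0 & mb == 0),
        row.names = NULL, stringsAsFactors = FALSE)
}

#' Standard per-treatment genotype comparisons of a study design
#'
#' One comparison per treatment arm: control-genotype samples versus
#' mutant-genotype samples within that treatment.
#'
#' @param samples sample annotation data.frame with columns `sample_id`,
#'   `genotype`, `treatment` (e.g. the `samples` element of
#'   [generateStudy()]).
#' @param reference genotype label of the control group; defaults to the
#'   first genotype in the table.
#' @return named list of comparisons, each a list with `name`, `groupA`
#'   (control sample ids) and `groupB`.
#' @export
makeComparisons <- function(samples, reference = NULL) {
    stopifnot(all(c("sample_id", "genotype", "treatment") %in%
                  names(samples)))
    if (is.null(reference)) reference <- samples$genotype[1L]
    out <- lapply(unique(samples$treatment), function(tr) {
        list(name = tr,
             groupA = samples$sample_id[samples$treatment == tr &
                                        samples$genotype == reference],
             groupB = samples$sample_id[samples$treatment == tr &
                                        samples$genotype != reference])
    })
    names(out) <- unique(samples$treatment)
    out
}

#' Venn partition of significant peptide sets
#'
#' Counts the exclusive regions of a 2- or 3-set Venn diagram over sets
#' of significant peptide keys (up- and downregulated sets are usually
#' partitioned separately). Region counts always sum to the size of the
#' union, and percentages are relative to the union.
#'
#' @param sets named list of 2 or 3 character vectors.
#' @return data.frame with columns `region` (labels like `"A"`,
#'   `"A&B"`), `count` and `percent`.
#' @examples
#' vennPartition(list(A = c("x", "y"), B = c("y", "z")))
#' @export
vennPartition <- function(sets) {
    if (!is.list(sets) || length(sets) < 2L || length(sets) > 3L ||
        is.null(names(sets)) || any(!nzchar(names(sets))))
        stop("'sets' must be a named list of 2 or 3 vectors")
    sets <- lapply(sets, unique)
    universe <- unique(unlist(sets, use.names = FALSE))
    member <- vapply(sets, function(s) universe %in% s,
                     logical(length(universe)))
    if (length(universe) == 1L) member <- matrix(member, nrow = 1L)
    n <- length(sets)
    combos <- expand.grid(rep(list(c(FALSE, TRUE)), n))[-1L, , drop = FALSE]
    region <- apply(combos, 1L, function(z)
        paste(names(sets)[unlist(z)], collapse = "&"))
    count <- apply(combos, 1L, function(z) {
        if (!length(universe)) return(0L)
        sum(apply(member, 1L, function(row) all(row == unlist(z))))
    })
    pct <- if (length(universe)) 100 * count / length(universe) else
        rep(0, length(count))
    data.frame(region = region, count = as.integer(count), percent = pct,
               row.names = NULL, stringsAsFactors = FALSE)
}

#' Fold-change heatmap matrix over several comparisons
#'
#' For a chosen peptide subset, the mean fold change of the mutant group
#' over the control group in every comparison — the quantity displayed in
#' cross-treatment fold-change heatmaps.
#'
#' @param object a normalized [PhosphoQuant-class].
#' @param comparisons list of comparisons as produced by
#'   [makeComparisons()].
#' @param peptides character vector of peptide keys (rows of the result,
#'   in the given order); all must be present in the matrix. An empty
#'   vector yields an empty matrix.
#' @param log2 if `TRUE` return log2 fold changes instead of linear fold
#'   changes.
#' @return numeric matrix, peptides x comparisons; linear fold change
#'   (1 = unchanged) unless `log2 = TRUE`.
#' @export
heatmapFoldChanges <- function(object, comparisons, peptides,
                               log2 = FALSE) {
    stopifnot(is(object, "PhosphoQuant"))
    m <- intensityMatrix(object)
    peptides <- as.character(peptides)
    miss <- setdiff(peptides, rownames(m))
    if (length(miss))
        stop("unknown peptide key(s): ", paste(miss, collapse = ", "))
    eps <- foldChangeEpsilon(m)
    out <- matrix(NA_real_, length(peptides), length(comparisons),
                  dimnames = list(peptides,
                                  vapply(comparisons, `[[`, character(1L),
                                         "name")))
    if (!length(peptides)) return(out)
    for (j in seq_along(comparisons)) {
        cmp <- comparisons[[j]]
        ma <- rowMeans(m[peptides, cmp$groupA, drop = FALSE])
        mb <- rowMeans(m[peptides, cmp$groupB, drop = FALSE])
        l2 <- ifelse(ma == 0 & mb == 0, 0, log2(mb + eps) - log2(ma + eps))
        out[, j] <- if (log2) l2 else 2^l2
    }
    out
}
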