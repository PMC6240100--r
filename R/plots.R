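#' @include io.R
NULL

#' Volcano plot of a differential-regulation result
#'
#' Scatter of log2 fold change against -log10 P value, coloured by the
#' two-tier significance classification (P < 0.01 and P < 0.05 with the
#' fold-change gate), with the classification thresholds drawn as guide
#' lines.
#'
#' @param result data.frame from [diffPhos()].
#' @param fcThreshold,p05,p01 thresholds to draw (should match those used
#'   for classification).
#' @return a ggplot object.
#' @export
plotVolcano <- function(result, fcThreshold = 0.8, p05 = 0.05,
                        p01 = 0.01) {
    xy <- volcanoCoords(result$log2fc, result$p_value)
    d <- cbind(result, xy)
    ggplot2::ggplot(d, ggplot2::aes(x = x, y = y, colour = sig_class)) +
        ggplot2::geom_point(size = 0.8, alpha = 0.7) +
        ggplot2::geom_vline(xintercept = c(-fcThreshold, fcThreshold),
                            linetype = "dashed", linewidth = 0.3) +
        ggplot2::geom_hline(yintercept = -log10(c(p05, p01)),
                            linetype = "dashed", linewidth = 0.3) +
        ggplot2::scale_colour_manual(
            values = c(ns = "grey60", sig_p05 = "#E6B800",
                       sig_p01 = "#CC3311"),
            drop = FALSE, name = NULL,
            labels = c(ns = "ns", sig_p05 = "P < 0.05",
                       sig_p01 = "P < 0.01")) +
        ggplot2::labs(x = expression(log[2] ~ "fold change"),
                      y = expression(-log[10] ~ italic(P)),
                      title = unique(d$comparison)[1L]) +
        ggplot2::theme_bw()
}

#' Fold-change heatmap across comparisons
#'
#' Heatmap of log2 fold changes for a peptide subset over several group
#' comparisons (regulated peptides across treatment arms), drawn with
#' pheatmap on a blue-white-red scale centred at 0.
#'
#' @param fcMatrix matrix from [heatmapFoldChanges()] (linear fold
#'   changes unless `log2 = TRUE` was used).
#' @param log2Input set to `TRUE` if `fcMatrix` is already on the log2
#'   scale.
#' @param filename optional path; when given the heatmap is written
#'   there instead of drawn.
#' @param ... further arguments passed to [pheatmap::pheatmap()].
#' @return the pheatmap object, invisibly.
#' @export
plotFoldChangeHeatmap <- function(fcMatrix, log2Input = FALSE,
                                  filename = NA, ...) {
    m <- if (log2Input) fcMatrix else log2(fcMatrix)
    lim <- max(abs(m[is.finite(m)]), 1e-6)
    brk <- seq(-lim, lim, length.out = 101)
    cols <- grDevices::colorRampPalette(
        c("#2166AC", "white", "#B2182B"))(100)
    ph <- pheatmap::pheatmap(m, color = cols, breaks = brk,
                             cluster_cols = FALSE, filename = filename,
                             silent = !is.na(filename), ...)
    invisible(ph)
}
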