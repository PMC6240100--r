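#' @include plots.R
NULL

utils::globalVariables(c("x", "y", "sig_class"))

.defaultConfig <- function() list(
    mzml_dir = NULL, id_table = NULL, outdir = "phospholfq_out",
    ppm_tol = 7, rt_tol = 2,
    fc_threshold = 0.8, p05 = 0.05, p01 = 0.01,
    simulate = FALSE, design = list(), truth = list(),
    seed = 1L, write_mzml = FALSE, figures = TRUE)

#' Read a pipeline configuration file
#'
#' YAML configuration for [runPipeline()]. Unset fields take the package
#' defaults, which are the standard analysis parameters: +/-7 ppm and
#' +/-2 min XIC windows and the 0.8 / 0.05 / 0.01 classification
#' thresholds. `design:` and `truth:` sub-maps override [studyDesign()]
#' and [truthParams()] arguments when `simulate: true`.
#'
#' @param path YAML file path.
#' @return configuration list with defaults filled in.
#' @export
readPipelineConfig <- function(path) {
    if (!file.exists(path)) stop("config file not found: ", path)
    cfg <- yaml::read_yaml(path)
    out <- .defaultConfig()
    unknown <- setdiff(names(cfg), names(out))
    if (length(unknown))
        stop("unknown config field(s): ", paste(unknown, collapse = ", "))
    out[names(cfg)] <- cfg
    out
}

## sample annotation from run-level colData (genotype/treatment parsed
## from the sample ids produced by the simulator, when present)
.samplesFromColData <- function(cd) {
    s <- unique(as.data.frame(cd)[, "sample_id", drop = FALSE])
    parts <- strsplit(s$sample_id, ".", fixed = TRUE)
    ok <- all(lengths(parts) == 3L)
    data.frame(sample_id = s$sample_id,
               genotype = if (ok) vapply(parts, `[`, "", 1L) else NA,
               treatment = if (ok) vapply(parts, `[`, "", 2L) else NA,
               stringsAsFactors = FALSE)
}

#' Run the full label-free phosphoproteomics pipeline
#'
#' Executes simulate (optional) -> quantify -> average technical
#' replicates -> normalize -> differential statistics (+ delta-score
#' annotation of the identification table), writing every stage's table,
#' the volcano and heatmap figures, and a machine-readable provenance
#' record (`provenance.json` with the configuration, package version and
#' MD5 checksums of all outputs) into the output directory. On failure,
#' files already written in this invocation are removed.
#'
#' @param config configuration list (see [readPipelineConfig()]) or a
#'   path to a YAML config file. With `simulate = TRUE` a synthetic study
#'   is generated from `config$design`/`config$truth`/`config$seed`;
#'   otherwise `mzml_dir` and `id_table` name the inputs.
#' @return invisibly, a list with the result objects (`quant`,
#'   `bySample`, `normalized`, `results`, `venn`, `ids`) and the output
#'   file paths.
#' @export
runPipeline <- function(config = list()) {
    if (is.character(config)) config <- readPipelineConfig(config)
    cfg <- .defaultConfig()
    unknown <- setdiff(names(config), names(cfg))
    if (length(unknown))
        stop("unknown config field(s): ", paste(unknown, collapse = ", "))
    cfg[names(config)] <- config

    outdir <- cfg$outdir
    dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
    written <- character()
    ok <- FALSE
    on.exit(if (!ok && length(written)) unlink(written), add = TRUE)
    reg <- function(p) { written <<- c(written, p); p }

    truthObj <- NULL
    if (isTRUE(cfg$simulate)) {
        design <- do.call(studyDesign, cfg$design)
        truth <- do.call(truthParams, cfg$truth)
        study <- generateStudy(design, truth, seed = cfg$seed)
        runs <- study$runs
        ids <- study$ids
        truthObj <- study$truth
        samples <- study$samples
        reg(writeIdTable(ids, file.path(outdir, "ids.csv")))
        written <- c(written,
                     writeGroundTruth(truthObj, file.path(outdir, "truth")))
        if (isTRUE(cfg$write_mzml)) {
            mzdir <- file.path(outdir, "mzml")
            dir.create(mzdir, showWarnings = FALSE)
            for (r in runs)
                reg(writeMzML(r, file.path(mzdir,
                                           paste0(runId(r), ".mzML"))))
        }
    } else {
        if (is.null(cfg$id_table) || !file.exists(cfg$id_table))
            stop("identification table not found: ",
                 if (is.null(cfg$id_table)) "(unset)" else cfg$id_table)
        if (is.null(cfg$mzml_dir) || !dir.exists(cfg$mzml_dir))
            stop("mzML directory not found: ",
                 if (is.null(cfg$mzml_dir)) "(unset)" else cfg$mzml_dir)
        ids <- readIdTable(cfg$id_table)
        files <- list.files(cfg$mzml_dir, pattern = "\\.mzML$",
                            ignore.case = TRUE, full.names = TRUE)
        if (!length(files))
            stop("no mzML files in ", cfg$mzml_dir)
        runs <- lapply(files, readMzML)
        samples <- NULL
    }

    ids <- annotateDeltaScores(ids)
    quant <- quantifyAll(runs, ids, ppmTol = cfg$ppm_tol,
                         rtTol = cfg$rt_tol)
    reg(writeQuantMatrix(quant, file.path(outdir, "quant_run.csv")))
    written <- c(written, file.path(outdir, "quant_run.csv.meta.csv"))

    bySample <- averageTechnicalReplicates(quant)
    normd <- normalizeTotalIntensity(bySample)
    reg(writeQuantMatrix(normd, file.path(outdir, "quant_normalized.csv")))
    written <- c(written,
                 file.path(outdir, "quant_normalized.csv.meta.csv"))

    if (is.null(samples))
        samples <- .samplesFromColData(SummarizedExperiment::colData(normd))
    results <- venn <- NULL
    if (!anyNA(samples$genotype) &&
        length(unique(samples$genotype)) == 2L) {
        comparisons <- makeComparisons(samples)
        results <- do.call(rbind, lapply(comparisons, function(cmp)
            diffPhos(normd, cmp$groupA, cmp$groupB, name = cmp$name,
                     fcThreshold = cfg$fc_threshold, p05 = cfg$p05,
                     p01 = cfg$p01)))
        rownames(results) <- NULL
        reg(file.path(outdir, "diff_results.csv"))
        utils::write.csv(results, file.path(outdir, "diff_results.csv"),
                         row.names = FALSE, quote = FALSE)

        sig <- results[results$sig_class != "ns", ]
        vennOf <- function(dir) {
            s <- split(sig$peptide_key[sig$direction == dir],
                       sig$comparison[sig$direction == dir])
            s <- s[lengths(s) >= 0]
            if (length(s) >= 2L) vennPartition(s) else NULL
        }
        venn <- list(up = vennOf("up"), down = vennOf("down"))
        for (nm in names(venn)) if (!is.null(venn[[nm]])) {
            p <- file.path(outdir, sprintf("venn_%s.csv", nm))
            reg(p)
            utils::write.csv(venn[[nm]], p, row.names = FALSE,
                             quote = FALSE)
        }

        if (isTRUE(cfg$figures)) {
            for (cmp in comparisons) {
                p <- file.path(outdir,
                               sprintf("volcano_%s.png", cmp$name))
                reg(p)
                g <- plotVolcano(
                    results[results$comparison == cmp$name, ],
                    cfg$fc_threshold, cfg$p05, cfg$p01)
                ggplot2::ggsave(p, g, width = 5, height = 4, dpi = 150)
            }
            sigKeys <- unique(sig$peptide_key)
            if (length(sigKeys) >= 2L) {
                fc <- heatmapFoldChanges(normd, comparisons, sigKeys)
                p <- file.path(outdir, "heatmap_foldchange.png")
                reg(p)
                plotFoldChangeHeatmap(fc, filename = p)
                pcsv <- file.path(outdir, "heatmap_foldchange.csv")
                reg(pcsv)
                utils::write.csv(
                    data.frame(peptide_key = rownames(fc), fc,
                               check.names = FALSE),
                    pcsv, row.names = FALSE, quote = FALSE)
            }
        }
    }

    prov <- list(
        package = "phosphoLFQ",
        version = as.character(utils::packageVersion("phosphoLFQ")),
        timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
        config = cfg[!vapply(cfg, is.null, logical(1L))],
        outputs = as.list(tools::md5sum(sort(written[file.exists(written)]))))
    provPath <- file.path(outdir, "provenance.json")
    jsonlite::write_json(prov, provPath, auto_unbox = TRUE, pretty = TRUE,
                         digits = NA)
    ok <- TRUE
    invisible(list(quant = quant, bySample = bySample, normalized = normd,
                   results = results, venn = venn, ids = ids,
                   truth = truthObj, samples = samples,
                   files = c(written, provPath)))
}
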