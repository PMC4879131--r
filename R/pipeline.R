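.classifierFromList <- function(cf) {
    if (is.null(cf)) return(ClassifierParams())
    args <- list(focalTissue = cf$focal_tissue,
                 referenceTissue = cf$reference_tissue,
                 focalFcThreshold = cf$focal_fc_threshold,
                 referenceFcCeiling = cf$reference_fc_ceiling,
                 enhancedDiffThreshold = cf$enhanced_diff_threshold,
                 enhancedTimepoint = cf$enhanced_timepoint,
                 timepointsConsidered = unlist(cf$timepoints_considered))
    do.call(ClassifierParams, args[!vapply(args, is.null, logical(1))])
}

.simConfigFromList <- function(sc) {
    if (is.null(sc)) return(SimulationConfig())
    props <- sc$category_proportions
    args <- list(nTranscripts = sc$n_transcripts,
                 categoryProportions = if (is.null(props)) NULL else
                     unlist(props),
                 baselineLogMean = sc$baseline_rpkm_log_mean,
                 baselineLogSd = sc$baseline_rpkm_log_sd,
                 nbDispersion = if (identical(sc$nb_dispersion, "Inf")) Inf
                                else sc$nb_dispersion,
                 focalFcRange = unlist(sc$planted_focal_fc_range),
                 referenceFcRange = unlist(sc$planted_reference_fc_range),
                 librarySize = sc$library_size_per_sample,
                 lengthRange = unlist(sc$transcript_length_range),
                 seed = sc$seed)
    do.call(SimulationConfig, args[!vapply(args, is.null, logical(1))])
}

.paramsAsList <- function(p) list(
    focal_tissue = p@focalTissue, reference_tissue = p@referenceTissue,
    focal_fc_threshold = p@focalFcThreshold,
    reference_fc_ceiling = p@referenceFcCeiling,
    enhanced_diff_threshold = p@enhancedDiffThreshold,
    enhanced_timepoint = p@enhancedTimepoint,
    timepoints_considered = p@timepointsConsidered)

#' Run the whole classification pipeline from a configuration
#'
#' Executes simulate (or read counts / read RPKM), RPKM normalization,
#' flooring, gating, fold changes in both direction conventions, the
#' five-way classification, report tables per category, and optionally
#' the delta-delta quantification of an RT-qPCR Ct table, writing all
#' outputs and a JSON run summary into the output directory. Each stage
#' logs its input/output row counts; any stage error aborts with the
#' stage name. Rerunning an identical configuration reproduces an
#' identical summary (no timestamps are recorded).
#'
#' @param config a named list, or the path of a YAML file holding one.
#'   Recognized fields: exactly one of \code{simulation} (generator
#'   settings, see \code{\link{SimulationConfig}}; snake_case keys),
#'   \code{counts} (list with \code{counts}, \code{lengths},
#'   \code{library_sizes} paths) or \code{rpkm} (path of a precomputed
#'   RPKM TSV); optional \code{classifier} (snake_case
#'   \code{\link{ClassifierParams}} fields), \code{floor}, \code{gate},
#'   \code{annotation} (path), \code{qpcr} (list with \code{ct} path,
#'   \code{reference_gene}, optional \code{efficiency},
#'   \code{calibrator_tissue}, \code{calibrator_timepoint}),
#'   \code{seed} (overrides the simulation seed) and \code{output_dir}.
#' @param outputDir overrides \code{config$output_dir}.
#' @param quiet suppress stage logging.
#' @return the run summary (category counts, parameters, seed, input
#'   hashes, per-stage row counts), invisibly; also written as
#'   \code{summary.json}.
#' @export
runPipeline <- function(config, outputDir = NULL, quiet = FALSE) {
    if (is.character(config)) {
        .stopIfNot(file.exists(config), "config file not found: %s", config)
        config <- yaml::read_yaml(config)
    }
    log <- function(...) if (!quiet) message(sprintf(...))
    stage <- function(name, expr) tryCatch(expr, error = function(e)
        stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
             call. = FALSE))

    modes <- c("simulation", "counts", "rpkm")
    sel <- modes[modes %in% names(config)]
    .stopIfNot(length(sel) == 1,
        "config must select exactly one input mode of %s (found: %s)",
        paste(modes, collapse = "/"),
        if (length(sel)) paste(sel, collapse = ", ") else "none")

    outputDir <- if (!is.null(outputDir)) outputDir else config$output_dir
    .stopIfNot(!is.null(outputDir), "config must name an output_dir")
    dir.create(outputDir, recursive = TRUE, showWarnings = FALSE)

    inputHashes <- list()
    seed <- NA_integer_
    if (sel == "simulation") {
        simConfig <- .simConfigFromList(config$simulation)
        if (!is.null(config$seed)) simConfig@seed <- as.integer(config$seed)
        seed <- simConfig@seed
        x <- stage("simulate", simulateTcExperiment(simConfig))
        log("simulate: %d transcripts x %d samples (seed %d)",
            nrow(x), ncol(x), seed)
    } else if (sel == "counts") {
        paths <- config$counts
        for (f in c("counts", "lengths", "library_sizes"))
            .stopIfNot(!is.null(paths[[f]]) && file.exists(paths[[f]]),
                       "counts mode needs existing file '%s'", f)
        inputHashes <- as.list(tools::md5sum(unlist(paths)))
        x <- stage("read_counts",
                   readCountTsv(paths$counts, paths$lengths,
                                paths$library_sizes))
        log("read_counts: %d transcripts x %d samples", nrow(x), ncol(x))
    } else {
        .stopIfNot(file.exists(config$rpkm), "rpkm file not found: %s",
                   config$rpkm)
        inputHashes <- as.list(tools::md5sum(config$rpkm))
        x <- stage("read_rpkm", readRpkmTsv(config$rpkm))
        log("read_rpkm: %d transcripts x %d samples", nrow(x), ncol(x))
    }
    nInput <- nrow(x)

    if ("counts" %in% assayNames(x)) {
        x <- stage("rpkm", computeRpkm(x))
        log("rpkm: computed for %d transcripts", nrow(x))
    }
    floor <- if (is.null(config$floor)) 0.1 else config$floor
    gate <- if (is.null(config$gate)) 0.5 else config$gate
    x <- stage("floor", applyFloor(x, floor))
    x <- stage("gate", gateExpressed(x, gate))
    log("gate: %d of %d transcripts retained (%d removed)",
        nrow(x), nInput, length(removedIds(x)))
    writeRpkmTsv(x, file.path(outputDir, "rpkm.tsv"))

    fcUp <- stage("fold_changes", foldChanges(x, "up_ratio"))
    fcDown <- stage("fold_changes", foldChanges(x, "down_ratio"))
    writeFoldChangeTsv(fcUp, file.path(outputDir, "fold_changes_up.tsv"))
    writeFoldChangeTsv(fcDown, file.path(outputDir, "fold_changes_down.tsv"))

    params <- .classifierFromList(config$classifier)
    result <- stage("classify", classifyAll(x, params, floor, gate))
    log("classify: %s",
        paste(sprintf("%s=%d", names(categoryCounts(result)),
                      as.integer(categoryCounts(result))), collapse = " "))
    writeClassificationTsv(result, file.path(outputDir, "classification.tsv"))

    annotation <- NULL
    if (!is.null(config$annotation)) {
        inputHashes <- c(inputHashes, as.list(tools::md5sum(config$annotation)))
        annotation <- stage("annotation", readAnnotationTsv(config$annotation))
    }
    reportRows <- list()
    for (cat in c("specific_up", "specific_down", "enhanced_up",
                  "enhanced_down")) {
        rep <- stage("report",
                     emitReport(result, fcUp, fcDown, cat, annotation,
                                file.path(outputDir,
                                          sprintf("report_%s.tsv", cat))))
        reportRows[[cat]] <- nrow(rep)
    }

    qpcrSummary <- NULL
    if (!is.null(config$qpcr)) {
        qc <- config$qpcr
        inputHashes <- c(inputHashes, as.list(tools::md5sum(qc$ct)))
        qx <- stage("qpcr", {
            ct <- readCtTsv(qc$ct)
            QpcrExperiment(ct, qc$reference_gene,
                calibratorTissue = if (is.null(qc$calibrator_tissue)) "EP"
                                   else qc$calibrator_tissue,
                calibratorTimepoint = if (is.null(qc$calibrator_timepoint)) 0
                                      else qc$calibrator_timepoint,
                efficiency = if (is.null(qc$efficiency)) 2 else qc$efficiency)
        })
        ne <- stage("qpcr", normalizedExpressionTable(qx))
        utils::write.table(ne, file.path(outputDir, "qpcr_normalized.tsv"),
                           sep = "\t", quote = FALSE, row.names = FALSE)
        qpcrSummary <- list(genes = setdiff(unique(qx@ct$gene),
                                            qx@referenceGene),
                            reference_gene = qx@referenceGene)
        log("qpcr: %d gene(s) normalized", length(qpcrSummary$genes))
    }

    summary <- list(
        input_mode = sel,
        n_input = nInput,
        n_removed = length(removedIds(x)),
        category_counts = as.list(categoryCounts(result)),
        report_rows = reportRows,
        params = .paramsAsList(params),
        floor = floor, gate = gate,
        seed = if (is.na(seed)) NULL else seed,
        input_hashes = inputHashes,
        qpcr = qpcrSummary)
    summary <- summary[!vapply(summary, is.null, logical(1))]
    jsonlite::write_json(summary, file.path(outputDir, "summary.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    invisible(summary)
}
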