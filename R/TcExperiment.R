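#' Construct a two-tissue time-course experiment
#'
#' Bundles a transcripts-by-samples matrix with the sample grid (tissue,
#' timepoint), per-sample library sizes and per-transcript lengths into a
#' validated \linkS4class{TcExperiment}. Exactly one of \code{counts} or
#' \code{rpkm} must be supplied; lengths and library sizes are mandatory
#' with counts (they are the RPKM denominators) and optional with a
#' precomputed RPKM matrix.
#'
#' @param counts,rpkm numeric matrix, transcripts x samples, with
#'   transcript IDs as rownames. Columns must follow the order of
#'   \code{tissue}/\code{timepoint}.
#' @param tissue,timepoint vectors describing each column: tissue labels
#'   (e.g. \code{"EP"}, \code{"SP"}) and timepoints in hours.
#' @param lengthsBp per-transcript length in base pairs.
#' @param librarySizes per-sample total mapped reads.
#' @param rowData optional extra per-transcript columns.
#'
#' @return a \linkS4class{TcExperiment}; sample names are
#'   \code{<tissue>_<timepoint>h}.
#' @examples
#' cts <- matrix(rpois(16, 50), nrow = 2,
#'               dimnames = list(c("tx1", "tx2"), NULL))
#' se <- TcExperiment(counts = cts,
#'                    tissue = rep(c("EP", "SP"), each = 4),
#'                    timepoint = rep(c(0, 3, 9, 24), 2),
#'                    lengthsBp = c(1500, 800),
#'                    librarySizes = rep(45e6, 8))
#' se
#' @export
TcExperiment <- function(counts = NULL, rpkm = NULL, tissue, timepoint,
                         lengthsBp = NULL, librarySizes = NULL,
                         rowData = NULL) {
    if (is.null(counts) == is.null(rpkm))
        stop("supply exactly one of 'counts' or 'rpkm'")
    m <- if (is.null(counts)) rpkm else counts
    storage.mode(m) <- "double"
    if (is.null(rownames(m))) stop("transcript IDs (rownames) are required")
    if (ncol(m) != length(tissue) || ncol(m) != length(timepoint))
        stop("tissue/timepoint must describe every sample column")
    if (is.null(librarySizes)) librarySizes <- rep(NA_real_, ncol(m))
    cd <- DataFrame(tissue = as.character(tissue),
                    timepoint = as.numeric(timepoint),
                    library_size = as.numeric(librarySizes))
    rownames(cd) <- sprintf("%s_%gh", cd$tissue, cd$timepoint)
    colnames(m) <- rownames(cd)
    rd <- if (is.null(rowData)) DataFrame(row.names = rownames(m))
          else DataFrame(rowData, row.names = rownames(m))
    if (!is.null(lengthsBp)) rd$length_bp <- as.numeric(lengthsBp)
    assays <- if (is.null(counts)) list(rpkm = m) else list(counts = m)
    se <- SummarizedExperiment(assays = assays, rowData = rd, colData = cd)
    new("TcExperiment", se)
}

#' Accessors for TcExperiment
#'
#' \code{tissues} and \code{timepoints} return the distinct tissue labels
#' and timepoints (hours) of the sample grid; \code{transcriptLengths}
#' and \code{librarySizes} the RPKM denominators; \code{rpkm} the RPKM
#' assay (\code{prefloor = TRUE} returns the unfloored values kept by
#' \code{\link{applyFloor}}); \code{flooredMask} the logical mask of
#' cells raised to the floor; \code{expressedInTissue} the per-(transcript,
#' tissue) expression calls set by \code{\link{gateExpressed}}.
#'
#' @param x a \linkS4class{TcExperiment}.
#' @param prefloor logical; return pre-floor RPKM values if available.
#' @param ... unused.
#' @return see the per-function description above.
#' @name TcExperiment-accessors
#' @aliases tissues timepoints transcriptLengths librarySizes rpkm
#'   flooredMask expressedInTissue
#' @examples
#' sim <- simulateTcExperiment(SimulationConfig(nTranscripts = 20, seed = 1))
#' tissues(sim); timepoints(sim)
NULL

#' @rdname TcExperiment-accessors
#' @export
setMethod("tissues", "TcExperiment", function(x, ...)
    unique(colData(x)$tissue))

#' @rdname TcExperiment-accessors
#' @export
setMethod("timepoints", "TcExperiment", function(x, ...)
    sort(unique(colData(x)$timepoint)))

#' @rdname TcExperiment-accessors
#' @export
setMethod("transcriptLengths", "TcExperiment", function(x)
    stats::setNames(rowData(x)$length_bp, rownames(x)))

#' @rdname TcExperiment-accessors
#' @export
setMethod("librarySizes", "TcExperiment", function(x)
    stats::setNames(colData(x)$library_size, colnames(x)))

#' @rdname TcExperiment-accessors
#' @export
setMethod("rpkm", "TcExperiment", function(x, prefloor = FALSE, ...) {
    nm <- if (prefloor && "rpkm_prefloor" %in% assayNames(x)) "rpkm_prefloor"
          else "rpkm"
    if (!nm %in% assayNames(x))
        stop("no RPKM assay; run computeRpkm() first")
    assay(x, nm)
})

#' @rdname TcExperiment-accessors
#' @export
setMethod("flooredMask", "TcExperiment", function(x) {
    if (!"floored" %in% assayNames(x))
        stop("no floored mask; run applyFloor() first")
    assay(x, "floored")
})

#' @rdname TcExperiment-accessors
#' @export
setMethod("expressedInTissue", "TcExperiment", function(x) {
    cols <- paste0("expressed_", tissues(x))
    if (!all(cols %in% colnames(rowData(x))))
        stop("no expression calls; run gateExpressed() first")
    m <- as.matrix(rowData(x)[, cols, drop = FALSE])
    colnames(m) <- tissues(x)
    m
})

#' @rdname gateExpressed
#' @export
setMethod("removedIds", "TcExperiment", function(x) {
    ids <- metadata(x)$removed_ids
    if (is.null(ids)) character(0) else ids
})

#' @rdname simulateTcExperiment
#' @export
setMethod("syntheticTruth", "TcExperiment", function(x) {
    rd <- rowData(x)
    if (!"true_category" %in% colnames(rd))
        stop("no planted truth: this experiment was not simulated")
    cols <- c("true_category", grep("^planted_", colnames(rd), value = TRUE))
    out <- rd[, cols, drop = FALSE]
    out <- DataFrame(transcript_id = rownames(x), out)
    rownames(out) <- rownames(x)
    out
})

setMethod("show", "TcExperiment", function(object) {
    cat(sprintf("TcExperiment: %d transcripts x %d samples (%s x %s h)\n",
                nrow(object), ncol(object),
                paste(tissues(object), collapse = "/"),
                paste(timepoints(object), collapse = ",")))
    cat("assays:", paste(assayNames(object), collapse = ", "), "\n")
    if ("true_category" %in% colnames(rowData(object)))
        cat("planted truth: yes\n")
    if (length(removedIds(object)))
        cat(sprintf("gated: %d transcript(s) removed as not expressed\n",
                    length(removedIds(object))))
    invisible(NULL)
})
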