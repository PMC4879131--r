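#' Publication-style report table for one category
#'
#' Renders the transcripts of one category the way the study's summary
#' tables are laid out. For the specific categories, each timepoint
#' column holds the focal-tissue log2 fold change with the reference
#' tissue's log2 fold change in brackets, e.g. \code{"8.9 (-)"} when the
#' reference tissue is silent; log2 values are rounded to one decimal.
#' For the enhanced categories the columns are the linear 3-h (more
#' precisely, \code{enhancedTimepoint}) fold changes of both tissues and
#' their difference, rounded to integers. Rows are sorted by the focal
#' fold change at the earliest considered timepoint, descending, ties by
#' transcript ID; the not-expressed sentinel renders as \code{-}
#' throughout. Annotation columns, when provided, are carried along.
#'
#' @param result a \linkS4class{ClassificationResult}.
#' @param fcUp,fcDown the \linkS4class{FoldChangeTable}s of the same run.
#' @param category one of \code{specific_up}, \code{specific_down},
#'   \code{enhanced_up}, \code{enhanced_down}.
#' @param annotation optional data.frame from
#'   \code{\link{readAnnotationTsv}}.
#' @param path optional output TSV path.
#' @return the report data.frame (header-only when the category is
#'   empty); written to \code{path} when given.
#' @export
emitReport <- function(result, fcUp, fcDown, category, annotation = NULL,
                       path = NULL) {
    stopifnot(is(result, "ClassificationResult"))
    ok <- c("specific_up", "specific_down", "enhanced_up", "enhanced_down")
    .stopIfNot(category %in% ok, "unknown category '%s' (expected one of %s)",
               category, paste(ok, collapse = ", "))
    params <- classifierParams(result)
    tab <- classification(result)
    ids <- tab$transcript_id[tab$category == category]

    up <- grepl("_up$", category)
    tbl <- if (up) fcUp else fcDown
    focal <- foldChangeMatrix(tbl, params@focalTissue)
    ref <- foldChangeMatrix(tbl, params@referenceTissue)

    fmt1 <- function(v) ifelse(is.na(v), "-", sprintf("%.1f", v))
    fmt0 <- function(v) ifelse(is.na(v), "-", sprintf("%d", round(v)))

    if (grepl("^specific", category)) {
        tps <- sprintf("%gh", params@timepointsConsidered)
        out <- data.frame(transcript_id = ids, stringsAsFactors = FALSE)
        for (tp in tps)
            out[[paste0("log2fc_", tp)]] <-
                sprintf("%s (%s)", fmt1(log2(focal[ids, tp])),
                        fmt1(log2(ref[ids, tp])))
        sortKey <- focal[ids, tps[1]]
    } else {
        tp <- sprintf("%gh", params@enhancedTimepoint)
        diffCol <- if (up) "enhanced_diff_up" else "enhanced_diff_down"
        dv <- stats::setNames(tab[[diffCol]], tab$transcript_id)[ids]
        out <- data.frame(transcript_id = ids,
                          focal_fc = fmt0(focal[ids, tp]),
                          reference_fc = fmt0(ref[ids, tp]),
                          fold_difference = fmt0(dv),
                          stringsAsFactors = FALSE)
        colnames(out)[2:3] <- c(sprintf("%s_fc_%s", params@focalTissue, tp),
                                sprintf("%s_fc_%s", params@referenceTissue, tp))
        sortKey <- focal[ids, tp]
    }
    ord <- order(-sortKey, ids, na.last = TRUE)
    out <- out[ord, , drop = FALSE]
    rownames(out) <- NULL

    if (!is.null(annotation) && nrow(out)) {
        ann <- annotation[match(out$transcript_id, annotation$transcript_id),
                          setdiff(colnames(annotation), "transcript_id"),
                          drop = FALSE]
        out <- cbind(out["transcript_id"], ann,
                     out[setdiff(colnames(out), "transcript_id")])
        rownames(out) <- NULL
    } else if (!is.null(annotation)) {
        ann <- annotation[0, setdiff(colnames(annotation), "transcript_id"),
                          drop = FALSE]
        out <- cbind(out["transcript_id"], ann,
                     out[setdiff(colnames(out), "transcript_id")])
    }
    if (!is.null(path)) .writeTsv(out, path, sprintf("category: %s", category))
    out
}
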