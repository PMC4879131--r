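#' Construct classifier parameters
#'
#' @param focalTissue,referenceTissue tissue labels of the contrast
#'   (defaults EP vs SP).
#' @param focalFcThreshold minimum focal-tissue linear fold change (at
#'   one or more considered timepoints) for the specific categories;
#'   default 5.
#' @param referenceFcCeiling reference-tissue elimination bound: a
#'   transcript is dropped from the specific categories when the
#'   reference tissue changes by this factor or more, in either
#'   direction, at any considered timepoint; default 2.
#' @param enhancedDiffThreshold minimum focal-minus-reference linear
#'   fold-change difference for the enhanced categories; default 25.
#' @param enhancedTimepoint timepoint (hours) at which the enhanced
#'   difference is evaluated; default 3 (the early-induction contrast).
#' @param timepointsConsidered post-baseline timepoints entering the
#'   specific filters; default \code{c(3, 9, 24)}.
#' @return a validated \linkS4class{ClassifierParams}.
#' @examples
#' ClassifierParams()                         # stringent screen (5 / 2 / 25)
#' ClassifierParams(focalFcThreshold = 2,
#'                  referenceFcCeiling = 1.2) # exploratory screen
#' @export
ClassifierParams <- function(focalTissue = "EP", referenceTissue = "SP",
                             focalFcThreshold = 5, referenceFcCeiling = 2,
                             enhancedDiffThreshold = 25,
                             enhancedTimepoint = 3,
                             timepointsConsidered = c(3, 9, 24)) {
    new("ClassifierParams", focalTissue = focalTissue,
        referenceTissue = referenceTissue,
        focalFcThreshold = focalFcThreshold,
        referenceFcCeiling = referenceFcCeiling,
        enhancedDiffThreshold = enhancedDiffThreshold,
        enhancedTimepoint = enhancedTimepoint,
        timepointsConsidered = timepointsConsidered)
}

setMethod("show", "ClassifierParams", function(object) {
    cat(sprintf(paste0("ClassifierParams: %s vs %s; specific >= %g-fold focal,",
                       " < %g-fold reference; enhanced diff >= %g at %g h;",
                       " timepoints {%s} h\n"),
                object@focalTissue, object@referenceTissue,
                object@focalFcThreshold, object@referenceFcCeiling,
                object@enhancedDiffThreshold, object@enhancedTimepoint,
                paste(object@timepointsConsidered, collapse = ",")))
    invisible(NULL)
})

.checkTables <- function(fcUp, fcDown, params) {
    validObject(params)
    .stopIfNot(direction(fcUp) == "up_ratio",
               "fcUp must be an up_ratio table")
    .stopIfNot(direction(fcDown) == "down_ratio",
               "fcDown must be a down_ratio table")
    .stopIfNot(identical(rownames(fcUp@fc), rownames(fcDown@fc)),
               "fcUp and fcDown must cover the same transcripts in order")
    for (ti in c(params@focalTissue, params@referenceTissue))
        .stopIfNot(ti %in% tissues(fcUp), "tissue '%s' absent from tables", ti)
    .stopIfNot(all(params@timepointsConsidered %in% timepoints(fcUp)),
               "considered timepoints absent from tables")
}

# reference elimination: >= ceiling change in EITHER direction at ANY
# considered timepoint; a transcript silent in the reference tissue
# trivially passes (sentinel cells are NA)
.referenceEliminated <- function(fcUp, params) {
    m <- foldChangeMatrix(fcUp, params@referenceTissue)
    m <- m[, sprintf("%gh", params@timepointsConsidered), drop = FALSE]
    mag <- pmax(m, 1 / m)
    out <- rowSums(mag >= params@referenceFcCeiling, na.rm = TRUE) > 0
    stats::setNames(out, rownames(m))
}

.passedFocal <- function(fcTable, params) {
    m <- foldChangeMatrix(fcTable, params@focalTissue)
    m <- m[, sprintf("%gh", params@timepointsConsidered), drop = FALSE]
    out <- rowSums(m >= params@focalFcThreshold, na.rm = TRUE) > 0
    stats::setNames(out, rownames(m))
}

#' Tissue-specific up/down classification (two-step filter)
#'
#' Step one selects transcripts whose focal-tissue fold change reaches
#' \code{focalFcThreshold} at one or more considered timepoints (the
#' up-ratio table feeds the up call, the down-ratio table the down
#' call). Step two eliminates, from either list, transcripts whose
#' reference tissue changes by \code{referenceFcCeiling} or more, in
#' either direction, at any considered timepoint; transcripts not
#' expressed in the reference tissue trivially pass the elimination.
#'
#' @param fcUp,fcDown \linkS4class{FoldChangeTable}s in up-ratio and
#'   down-ratio convention, computed from the same gated matrix.
#' @param params a \linkS4class{ClassifierParams}.
#' @return list with \code{up} and \code{down} (character ID vectors)
#'   and \code{decisions}, a \code{DataFrame} of the per-transcript
#'   filter outcomes (\code{passed_focal_up}, \code{passed_focal_down},
#'   \code{eliminated_by_reference}).
#' @seealso \code{\link{classifyEnhanced}}, \code{\link{classifyAll}}
#' @export
classifySpecific <- function(fcUp, fcDown, params = ClassifierParams()) {
    .checkTables(fcUp, fcDown, params)
    ids <- rownames(fcUp@fc)
    focalUp <- .passedFocal(fcUp, params)
    focalDown <- .passedFocal(fcDown, params)
    refElim <- .referenceEliminated(fcUp, params)
    decisions <- DataFrame(transcript_id = ids,
                           passed_focal_up = unname(focalUp),
                           passed_focal_down = unname(focalDown),
                           eliminated_by_reference = unname(refElim))
    list(up = ids[focalUp & !refElim],
         down = ids[focalDown & !refElim],
         decisions = decisions)
}

#' Tissue-enhanced up/down classification (fold-change difference)
#'
#' Evaluated only on transcripts excluded from the specific categories.
#' A transcript is enhanced-up when its focal minus reference linear
#' fold change at \code{enhancedTimepoint} is at least
#' \code{enhancedDiffThreshold} (up-ratio tables); enhanced-down is the
#' analogous comparison on the down-ratio tables. A transcript silent in
#' the reference tissue contributes reference fold change 1 (no change)
#' to the difference; a transcript silent in the focal tissue cannot be
#' enhanced (difference is the sentinel).
#'
#' @inheritParams classifySpecific
#' @param excluded character IDs of the transcripts excluded from the
#'   specific categories; every ID must be present in the tables.
#' @return list with \code{up} and \code{down} ID vectors and
#'   \code{diffs}, a \code{DataFrame} of the per-transcript difference
#'   values (\code{NA} where the focal tissue is silent).
#' @examples
#' fcUp <- FoldChangeTable(matrix(c(378, 1, 1, 1, 1, 1),
#'     nrow = 1, dimnames = list("Unigene11848",
#'     c("EP_3h", "EP_9h", "EP_24h", "SP_3h", "SP_9h", "SP_24h"))))
#' fcDown <- FoldChangeTable(1 / foldChangeMatrix(fcUp),
#'                           direction = "down_ratio")
#' classifyEnhanced(fcUp, fcDown, "Unigene11848")$diffs
#' @export
classifyEnhanced <- function(fcUp, fcDown, excluded,
                             params = ClassifierParams()) {
    .checkTables(fcUp, fcDown, params)
    missing <- setdiff(excluded, rownames(fcUp@fc))
    .stopIfNot(length(missing) == 0,
               "excluded transcript(s) absent from fold-change tables: %s",
               paste(missing, collapse = ", "))
    tp <- sprintf("%gh", params@enhancedTimepoint)
    diffAt <- function(tbl) {
        focal <- foldChangeMatrix(tbl, params@focalTissue)[excluded, tp]
        ref <- foldChangeMatrix(tbl, params@referenceTissue)[excluded, tp]
        ref[is.na(ref)] <- 1
        focal - ref
    }
    dUp <- diffAt(fcUp)
    dDown <- diffAt(fcDown)
    diffs <- DataFrame(transcript_id = excluded,
                       enhanced_diff_up = unname(dUp),
                       enhanced_diff_down = unname(dDown))
    thr <- params@enhancedDiffThreshold
    list(up = excluded[!is.na(dUp) & dUp >= thr],
         down = excluded[!is.na(dDown) & dDown >= thr],
         diffs = diffs)
}

#' Five-way classification from fold-change tables
#'
#' Applies the two-step specific filter, then the enhanced filter on the
#' specific exclusions, labelling the remaining transcripts
#' \code{unclassified} and any \code{removed} IDs \code{not_expressed}.
#' A transcript passing both specific focal filters (possible when it
#' rises at one timepoint and falls at another) is labelled
#' \code{specific_up} (up-before-down precedence); the per-filter
#' booleans in the decisions table expose both outcomes.
#'
#' @inheritParams classifySpecific
#' @param removed IDs removed by the expression gate, reported as
#'   \code{not_expressed}.
#' @return a \linkS4class{ClassificationResult}.
#' @export
classifyFromTables <- function(fcUp, fcDown, params = ClassifierParams(),
                               removed = character(0)) {
    kept <- rownames(fcUp@fc)
    if (length(kept)) {
        spec <- classifySpecific(fcUp, fcDown, params)
        excluded <- setdiff(kept, union(spec$up, spec$down))
        enh <- classifyEnhanced(fcUp, fcDown, excluded, params)
        category <- stats::setNames(rep("unclassified", length(kept)), kept)
        category[enh$down] <- "enhanced_down"
        category[enh$up] <- "enhanced_up"
        category[spec$down] <- "specific_down"
        category[spec$up] <- "specific_up"
        diffUp <- stats::setNames(rep(NA_real_, length(kept)), kept)
        diffDown <- diffUp
        diffUp[excluded] <- enh$diffs$enhanced_diff_up
        diffDown[excluded] <- enh$diffs$enhanced_diff_down
        tab <- DataFrame(transcript_id = kept,
                         category = unname(category),
                         passed_focal_up = spec$decisions$passed_focal_up,
                         passed_focal_down = spec$decisions$passed_focal_down,
                         eliminated_by_reference =
                             spec$decisions$eliminated_by_reference,
                         enhanced_diff_up = unname(diffUp),
                         enhanced_diff_down = unname(diffDown))
    } else {
        tab <- DataFrame(transcript_id = character(0),
                         category = character(0),
                         passed_focal_up = logical(0),
                         passed_focal_down = logical(0),
                         eliminated_by_reference = logical(0),
                         enhanced_diff_up = numeric(0),
                         enhanced_diff_down = numeric(0))
    }
    if (length(removed))
        tab <- rbind(tab, DataFrame(transcript_id = removed,
                                    category = "not_expressed",
                                    passed_focal_up = FALSE,
                                    passed_focal_down = FALSE,
                                    eliminated_by_reference = FALSE,
                                    enhanced_diff_up = NA_real_,
                                    enhanced_diff_down = NA_real_))
    rownames(tab) <- tab$transcript_id
    new("ClassificationResult", table = tab, params = params)
}

#' Run the full five-way classification on an expression matrix
#'
#' Composes the whole procedure: floor, gate, fold-change tables in both
#' direction conventions, then \code{\link{classifyFromTables}} with the
#' gated-out transcripts reported as \code{not_expressed}, so the result
#' covers every input transcript.
#'
#' @param x a \linkS4class{TcExperiment} with an \code{rpkm} assay (or a
#'   \code{counts} assay, in which case RPKM is computed first).
#' @param params a \linkS4class{ClassifierParams}.
#' @param floor,gate the RPKM floor and expression gate applied before
#'   classification (defaults 0.1 and 0.5).
#' @return a \linkS4class{ClassificationResult} covering every input
#'   transcript.
#' @examples
#' sim <- simulateTcExperiment(SimulationConfig(nTranscripts = 200, seed = 11))
#' res <- classifyAll(sim)
#' categoryCounts(res)
#' @export
classifyAll <- function(x, params = ClassifierParams(),
                        floor = 0.1, gate = 0.5) {
    stopifnot(is(x, "TcExperiment"))
    validObject(params)
    if (!"rpkm" %in% assayNames(x)) x <- computeRpkm(x)
    x <- applyFloor(x, floor)
    x <- gateExpressed(x, gate)
    if (nrow(x)) {
        fcUp <- foldChanges(x, "up_ratio")
        fcDown <- foldChanges(x, "down_ratio")
    } else {
        empty <- matrix(NA_real_, 0, 6,
                        dimnames = list(NULL, as.vector(t(outer(tissues(x),
                            setdiff(timepoints(x), 0),
                            function(a, b) sprintf("%s_%gh", a, b))))))
        ex <- matrix(logical(0), 0, length(tissues(x)),
                     dimnames = list(NULL, tissues(x)))
        fcUp <- FoldChangeTable(empty, ex, "up_ratio")
        fcDown <- FoldChangeTable(empty, ex, "down_ratio")
    }
    classifyFromTables(fcUp, fcDown, params, removed = removedIds(x))
}

#' Accessors for ClassificationResult
#'
#' \code{classification} returns the per-transcript table (category plus
#' intermediate filter decisions); \code{categoryCounts} the counts over
#' the six labels in canonical order; \code{classifierParams} the
#' parameters used (provenance).
#'
#' @param x a \linkS4class{ClassificationResult}.
#' @name ClassificationResult-accessors
#' @aliases classification categoryCounts classifierParams
NULL

#' @rdname ClassificationResult-accessors
#' @export
setMethod("classification", "ClassificationResult", function(x) x@table)

#' @rdname ClassificationResult-accessors
#' @export
setMethod("categoryCounts", "ClassificationResult", function(x) {
    f <- factor(x@table$category, levels = .RESULT_CATEGORIES)
    table(f, dnn = NULL)
})

#' @rdname ClassificationResult-accessors
#' @export
setMethod("classifierParams", "ClassificationResult", function(x) x@params)

setMethod("show", "ClassificationResult", function(object) {
    cat(sprintf("ClassificationResult: %d transcripts\n", nrow(object@table)))
    cc <- categoryCounts(object)
    for (nm in names(cc)) cat(sprintf("  %-14s %d\n", nm, cc[[nm]]))
    show(object@params)
    invisible(NULL)
})
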