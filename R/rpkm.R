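#' Compute RPKM from read counts
#'
#' RPKM (reads per kilobase of transcript per million mapped reads) for
#' every cell: \code{counts * 1e9 / (length_bp * library_size)}. No
#' flooring is applied here; the \code{floored} mask is initialized all
#' \code{FALSE}.
#'
#' @param x a \linkS4class{TcExperiment} with a \code{counts} assay,
#'   transcript lengths and library sizes.
#' @return \code{x} with \code{rpkm} and \code{floored} assays added.
#' @examples
#' # 1000 reads on a 2 kb transcript in a 10 M read library -> RPKM 50
#' se <- TcExperiment(counts = matrix(1000, 1, 8,
#'                        dimnames = list("tx1", NULL)),
#'                    tissue = rep(c("EP", "SP"), each = 4),
#'                    timepoint = rep(c(0, 3, 9, 24), 2),
#'                    lengthsBp = 2000, librarySizes = rep(1e7, 8))
#' rpkm(computeRpkm(se))[1, 1]
#' @seealso \code{\link{applyFloor}}, \code{\link{gateExpressed}},
#'   \code{\link{foldChanges}}
#' @export
computeRpkm <- function(x) {
    stopifnot(is(x, "TcExperiment"))
    .stopIfNot("counts" %in% assayNames(x), "no counts assay to normalize")
    len <- transcriptLengths(x)
    lib <- librarySizes(x)
    bad <- names(len)[!is.na(len) & len == 0]
    .stopIfNot(length(bad) == 0, "zero-length transcript(s): %s",
               paste(bad, collapse = ", "))
    bad <- names(lib)[is.na(lib) | lib == 0]
    .stopIfNot(length(bad) == 0, "zero or missing library size for sample(s): %s",
               paste(bad, collapse = ", "))
    cts <- assay(x, "counts")
    r <- cts * 1e9 / outer(len, lib)
    assay(x, "rpkm", withDimnames = FALSE) <- r
    assay(x, "floored", withDimnames = FALSE) <-
        matrix(FALSE, nrow(x), ncol(x), dimnames = dimnames(r))
    x
}

#' Floor low RPKM values
#'
#' Replaces every RPKM value below \code{floor} by \code{floor}, so
#' fold-change denominators are never (near) zero, and flags the replaced
#' cells. The unfloored values are kept in the \code{rpkm_prefloor}
#' assay; flooring is idempotent and re-flooring always starts from the
#' unfloored values. Values exactly at the floor are not flagged (the
#' rule is strictly "less than").
#'
#' @param x a \linkS4class{TcExperiment} with an \code{rpkm} assay.
#' @param floor positive RPKM floor (default 0.1).
#' @return \code{x} with floored \code{rpkm}, updated \code{floored}
#'   mask and an \code{rpkm_prefloor} assay.
#' @export
applyFloor <- function(x, floor = 0.1) {
    stopifnot(is(x, "TcExperiment"))
    .stopIfNot(is.numeric(floor) && floor > 0, "floor must be positive")
    pre <- rpkm(x, prefloor = TRUE)
    assay(x, "rpkm_prefloor", withDimnames = FALSE) <- pre
    assay(x, "rpkm", withDimnames = FALSE) <- pmax(pre, floor)
    assay(x, "floored", withDimnames = FALSE) <- pre < floor
    metadata(x)$floor <- floor
    x
}

#' Gate transcripts on the expression threshold
#'
#' A transcript is expressed in a tissue when its RPKM reaches
#' \code{gate} at one or more timepoints of that tissue; transcripts
#' below \code{gate} in every sample are deemed not expressed and
#' removed. The comparison uses pre-floor RPKM values when flooring has
#' already been applied, keeping the gate rule independent of the floor
#' parameter (with the defaults, floor 0.1 < gate 0.5, the two choices
#' are observationally equivalent).
#'
#' @param x a \linkS4class{TcExperiment} with an \code{rpkm} assay.
#' @param gate positive expression threshold (default 0.5 RPKM).
#' @return the gated \linkS4class{TcExperiment}: removed transcripts are
#'   dropped (their IDs available via \code{removedIds}), and per-tissue
#'   calls are stored in row data (\code{expressedInTissue}).
#' @examples
#' sim <- simulateTcExperiment(SimulationConfig(nTranscripts = 50, seed = 2))
#' g <- gateExpressed(applyFloor(computeRpkm(sim)))
#' length(removedIds(g))
#' @export
gateExpressed <- function(x, gate = 0.5) {
    stopifnot(is(x, "TcExperiment"))
    .stopIfNot(is.numeric(gate) && gate > 0, "gate must be positive")
    r <- rpkm(x, prefloor = TRUE)
    cd <- colData(x)
    for (ti in tissues(x)) {
        cols <- rownames(cd)[cd$tissue == ti]
        rowData(x)[[paste0("expressed_", ti)]] <-
            rowSums(r[, cols, drop = FALSE] >= gate) > 0
    }
    anywhere <- rowSums(r >= gate) > 0
    removed <- rownames(x)[!anywhere]
    x <- x[anywhere, ]
    # accumulate across repeated gating so a re-gated matrix still knows
    # its full not-expressed set
    metadata(x)$removed_ids <- union(metadata(x)$removed_ids, removed)
    metadata(x)$gate <- gate
    x
}

#' Fold changes versus the baseline timepoint
#'
#' For every transcript and tissue, the linear fold change of floored
#' RPKM at each post-baseline timepoint relative to the baseline
#' (0 h) sample of the same tissue. \code{direction = "up_ratio"} is
#' timepoint/baseline; \code{"down_ratio"} is baseline/timepoint, so the
#' same "at least k-fold" comparison expresses down-regulation as a
#' positive ratio. Tissues in which a transcript is not expressed carry
#' the not-expressed sentinel (\code{NA}); flooring must have been
#' applied first (zero baselines are a hard error) and gating must have
#' set the expression calls.
#'
#' @param x a floored, gated \linkS4class{TcExperiment}.
#' @param direction \code{"up_ratio"} (default) or \code{"down_ratio"}.
#' @param baselineTimepoint baseline timepoint in hours (default 0).
#' @return a \linkS4class{FoldChangeTable}.
#' @examples
#' sim <- simulateTcExperiment(SimulationConfig(nTranscripts = 40, seed = 5))
#' m <- gateExpressed(applyFloor(computeRpkm(sim)))
#' fc <- foldChanges(m)
#' head(foldChangeMatrix(fc))
#' @export
foldChanges <- function(x, direction = c("up_ratio", "down_ratio"),
                        baselineTimepoint = 0) {
    stopifnot(is(x, "TcExperiment"))
    direction <- match.arg(direction)
    r <- rpkm(x)
    expressed <- expressedInTissue(x)
    cd <- colData(x)
    tps <- sort(setdiff(timepoints(x), baselineTimepoint))
    .stopIfNot(baselineTimepoint %in% cd$timepoint,
               "baseline timepoint %g h absent from the samples",
               baselineTimepoint)
    tis <- tissues(x)
    fc <- matrix(NA_real_, nrow(x), length(tis) * length(tps),
                 dimnames = list(rownames(x),
                     as.vector(t(outer(tis, tps,
                                       function(a, b) sprintf("%s_%gh", a, b))))))
    for (ti in tis) {
        b <- r[, .sampleLabel(ti, baselineTimepoint)]
        .stopIfNot(all(b > 0),
            "zero baseline RPKM in tissue %s: apply the floor before fold changes",
            ti)
        for (tp in tps) {
            v <- r[, .sampleLabel(ti, tp)]
            .stopIfNot(direction == "up_ratio" || all(v > 0),
                "zero RPKM at %g h in tissue %s: apply the floor before fold changes",
                tp, ti)
            ratio <- if (direction == "up_ratio") v / b else b / v
            ratio[!expressed[, ti]] <- NA_real_
            fc[, sprintf("%s_%gh", ti, tp)] <- ratio
        }
    }
    FoldChangeTable(fc = fc, expressed = expressed, direction = direction,
                    tissues = tis, timepoints = tps,
                    baseline = baselineTimepoint)
}

#' Construct a fold-change table directly
#'
#' Mainly useful for planting literature fold-change patterns (e.g.
#' published table rows) straight into the classifier without a full
#' expression matrix.
#'
#' @param fc numeric matrix, transcripts x \code{<tissue>_<timepoint>h}
#'   columns (tissues varying slowest); \code{NA} marks the not-expressed
#'   sentinel.
#' @param expressed logical transcripts x tissues matrix; defaults to
#'   "expressed wherever any fold change is defined".
#' @param direction \code{"up_ratio"} or \code{"down_ratio"}.
#' @param tissues,timepoints,baseline the grid; defaults are read off
#'   \code{colnames(fc)} when they follow the naming scheme.
#' @return a \linkS4class{FoldChangeTable}.
#' @export
FoldChangeTable <- function(fc, expressed = NULL,
                            direction = c("up_ratio", "down_ratio"),
                            tissues = NULL, timepoints = NULL, baseline = 0) {
    direction <- match.arg(direction)
    parts <- regmatches(colnames(fc),
                        regexec("^(.+)_([0-9.]+)h$", colnames(fc)))
    .stopIfNot(all(lengths(parts) == 3),
               "fc columns must be named <tissue>_<timepoint>h")
    if (is.null(tissues)) tissues <- unique(vapply(parts, `[`, "", 2))
    if (is.null(timepoints))
        timepoints <- sort(unique(as.numeric(vapply(parts, `[`, "", 3))))
    if (is.null(expressed)) {
        expressed <- vapply(tissues, function(ti)
            rowSums(!is.na(fc[, sprintf("%s_%gh", ti, timepoints),
                              drop = FALSE])) > 0,
            logical(nrow(fc)))
        expressed <- matrix(expressed, nrow = nrow(fc),
                            dimnames = list(rownames(fc), tissues))
    }
    new("FoldChangeTable", fc = fc, expressed = expressed,
        direction = direction, tissues = tissues,
        timepoints = timepoints, baseline = baseline)
}

#' Accessors for FoldChangeTable
#'
#' \code{foldChangeMatrix} returns the linear fold changes (optionally
#' one tissue's columns, named by timepoint); \code{foldChangeLog2} the
#' log2 values derived from the linear ratios (same sentinel cells);
#' \code{direction} the direction convention.
#'
#' @param x a \linkS4class{FoldChangeTable}.
#' @param tissue optional tissue label to subset columns.
#' @param ... unused.
#' @name FoldChangeTable-accessors
#' @aliases foldChangeMatrix foldChangeLog2 direction
NULL

#' @rdname FoldChangeTable-accessors
#' @export
setMethod("foldChangeMatrix", "FoldChangeTable", function(x, tissue = NULL, ...) {
    if (is.null(tissue)) return(x@fc)
    .stopIfNot(tissue %in% x@tissues, "unknown tissue '%s'", tissue)
    m <- x@fc[, sprintf("%s_%gh", tissue, x@timepoints), drop = FALSE]
    colnames(m) <- sprintf("%gh", x@timepoints)
    m
})

#' @rdname FoldChangeTable-accessors
#' @export
setMethod("foldChangeLog2", "FoldChangeTable", function(x, tissue = NULL, ...)
    log2(foldChangeMatrix(x, tissue)))

#' @rdname FoldChangeTable-accessors
#' @export
setMethod("direction", "FoldChangeTable", function(x) x@direction)

#' @rdname FoldChangeTable-accessors
#' @export
setMethod("tissues", "FoldChangeTable", function(x, ...) x@tissues)

#' @rdname FoldChangeTable-accessors
#' @export
setMethod("timepoints", "FoldChangeTable", function(x, ...) x@timepoints)

#' @rdname FoldChangeTable-accessors
#' @export
setMethod("expressedInTissue", "FoldChangeTable", function(x) x@expressed)

setMethod("show", "FoldChangeTable", function(object) {
    cat(sprintf("FoldChangeTable (%s): %d transcripts, tissues %s, %s h vs %g h\n",
                object@direction, nrow(object@fc),
                paste(object@tissues, collapse = "/"),
                paste(object@timepoints, collapse = ","), object@baseline))
    invisible(NULL)
})
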