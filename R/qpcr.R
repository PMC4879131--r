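#' Construct an RT-qPCR experiment
#'
#' @param ct data.frame of per-well threshold cycles with columns
#'   \code{gene}, \code{tissue}, \code{timepoint}, \code{replicate},
#'   \code{ct} (see \code{\link{readCtTsv}}).
#' @param referenceGene label of the reference gene (e.g. the elongation
#'   factor used for normalization).
#' @param calibratorTissue,calibratorTimepoint the calibrator sample all
#'   normalized expressions are scaled against (default EP at 0 h, whose
#'   normalized expression is 1 by construction).
#' @param efficiency amplification factor per cycle in (1, 2]; the
#'   default 2 is perfect doubling, giving the \code{2^(-ddCt)} closed
#'   form.
#' @return a validated \linkS4class{QpcrExperiment}.
#' @seealso \code{\link{normalizedExpression}},
#'   \code{\link{concordanceReport}}
#' @export
QpcrExperiment <- function(ct, referenceGene,
                           calibratorTissue = "EP", calibratorTimepoint = 0,
                           efficiency = 2) {
    ct <- as.data.frame(ct)
    new("QpcrExperiment", ct = ct, referenceGene = referenceGene,
        calibrator = list(tissue = calibratorTissue,
                          timepoint = calibratorTimepoint),
        efficiency = efficiency)
}

setMethod("show", "QpcrExperiment", function(object) {
    cat(sprintf(paste0("QpcrExperiment: %d wells, %d gene(s) + reference '%s';",
                       " calibrator %s_%gh; efficiency %g\n"),
                nrow(object@ct),
                length(setdiff(unique(object@ct$gene), object@referenceGene)),
                object@referenceGene, object@calibrator$tissue,
                object@calibrator$timepoint, object@efficiency))
    invisible(NULL)
})

# mean Ct and SEM of one (gene, tissue, timepoint); SEM is NA with a
# single replicate, never zero
.ctStats <- function(x, gene, tissue, timepoint) {
    sel <- x@ct$gene == gene & x@ct$tissue == tissue &
        x@ct$timepoint == timepoint
    .stopIfNot(any(sel), "no Ct measurements for %s in sample %s_%gh",
               gene, tissue, timepoint)
    v <- x@ct$ct[sel]
    list(mean = mean(v),
         sem = if (length(v) > 1) stats::sd(v) / sqrt(length(v)) else NA_real_)
}

.deltaCt <- function(x, gene, tissue, timepoint) {
    tgt <- .ctStats(x, gene, tissue, timepoint)
    ref <- .ctStats(x, x@referenceGene, tissue, timepoint)
    list(dct = tgt$mean - ref$mean, var = tgt$sem^2 + ref$sem^2)
}

#' Delta-delta Ct normalized expression
#'
#' Relative quantification of a target gene in one sample: replicate Ct
#' values are averaged per (gene, sample), dCt = mean Ct(target) - mean
#' Ct(reference), ddCt = dCt(sample) - dCt(calibrator), and the
#' normalized expression is \code{efficiency^(-ddCt)} (with efficiency 2,
#' \code{2^(-ddCt)}). The calibrator sample returns exactly 1 by
#' construction. The replicate standard error is propagated to the
#' expression scale first-order as
#' \code{value * log(efficiency) * SEM(ddCt)}; any group with a single
#' replicate yields an undefined (\code{NA}) SEM, never zero.
#'
#' @param x a \linkS4class{QpcrExperiment}.
#' @param gene a target gene label (not the reference gene; the
#'   reference gene's own normalized expression is identically 1).
#' @param tissue,timepoint the sample.
#' @return list with \code{value} (normalized expression) and \code{sem}.
#' @examples
#' ct <- expand.grid(gene = c("VfWRKY28", "VfEFalpha"),
#'                   tissue = "EP", timepoint = c(0, 3),
#'                   replicate = 1:3, stringsAsFactors = FALSE)
#' ct$ct <- ifelse(ct$gene == "VfEFalpha", 20,
#'                 ifelse(ct$timepoint == 0, 30, 29))  # 1 cycle earlier at 3 h
#' q <- QpcrExperiment(ct, "VfEFalpha")
#' normalizedExpression(q, "VfWRKY28", "EP", 3)$value  # 2: one-cycle doubling
#' @export
normalizedExpression <- function(x, gene, tissue, timepoint) {
    stopifnot(is(x, "QpcrExperiment"))
    validObject(x)
    .stopIfNot(gene != x@referenceGene,
               "gene must differ from the reference gene '%s'", x@referenceGene)
    s <- .deltaCt(x, gene, tissue, timepoint)
    cal <- .deltaCt(x, gene, x@calibrator$tissue, x@calibrator$timepoint)
    ddct <- s$dct - cal$dct
    value <- x@efficiency^(-ddct)
    sem <- value * log(x@efficiency) * sqrt(s$var + cal$var)
    list(value = value, sem = sem)
}

#' Normalized expression across the whole sample grid
#'
#' @param x a \linkS4class{QpcrExperiment}.
#' @param genes target genes (default: every non-reference gene).
#' @return data.frame with columns \code{gene}, \code{tissue},
#'   \code{timepoint}, \code{value}, \code{sem}.
#' @rdname normalizedExpression
#' @export
normalizedExpressionTable <- function(x, genes = NULL) {
    stopifnot(is(x, "QpcrExperiment"))
    validObject(x)
    if (is.null(genes))
        genes <- setdiff(unique(x@ct$gene), x@referenceGene)
    grids <- unique(x@ct[x@ct$gene %in% genes, c("gene", "tissue", "timepoint")])
    grids <- grids[order(grids$gene, grids$tissue, grids$timepoint), ]
    out <- do.call(rbind, lapply(seq_len(nrow(grids)), function(i) {
        g <- grids[i, ]
        ne <- normalizedExpression(x, g$gene, g$tissue, g$timepoint)
        data.frame(gene = g$gene, tissue = g$tissue, timepoint = g$timepoint,
                   value = ne$value, sem = ne$sem)
    }))
    rownames(out) <- NULL
    out
}

#' Platform concordance of qPCR and RNA-seq expression calls
#'
#' Side-by-side comparison of qPCR normalized expression and RNA-seq
#' RPKM over the same gene x (tissue, timepoint) grid, plus, per gene
#' and tissue, whether the two platforms agree on the direction of the
#' baseline-to-induction change (sign of the fold change vs the earliest
#' timepoint). A no-change tie (fold change exactly 1) on either
#' platform counts as agreement: a flat call cannot contradict.
#'
#' @param qpcrValues data.frame with columns \code{gene}, \code{tissue},
#'   \code{timepoint}, \code{value} (e.g. from
#'   \code{\link{normalizedExpressionTable}}).
#' @param rnaseqValues data.frame with the same columns, \code{value}
#'   holding RPKM; must cover exactly the same grid (a mismatch is an
#'   error listing the missing cells).
#' @return list with \code{sideBySide} (the merged grid with both
#'   platforms' values) and \code{agreement} (per gene x tissue:
#'   both fold changes and \code{"agree"}/\code{"disagree"}).
#' @export
concordanceReport <- function(qpcrValues, rnaseqValues) {
    key <- function(d) paste(d$gene, d$tissue, d$timepoint)
    missQ <- setdiff(key(rnaseqValues), key(qpcrValues))
    missR <- setdiff(key(qpcrValues), key(rnaseqValues))
    .stopIfNot(length(missQ) + length(missR) == 0,
               "platform grids differ; missing from qPCR: [%s]; missing from RNA-seq: [%s]",
               paste(missQ, collapse = "; "), paste(missR, collapse = "; "))
    side <- merge(qpcrValues[, c("gene", "tissue", "timepoint", "value")],
                  rnaseqValues[, c("gene", "tissue", "timepoint", "value")],
                  by = c("gene", "tissue", "timepoint"),
                  suffixes = c("_qpcr", "_rpkm"))
    side <- side[order(side$gene, side$tissue, side$timepoint), ]
    rownames(side) <- NULL

    base <- min(side$timepoint)
    induced <- max(side$timepoint)
    agr <- unique(side[, c("gene", "tissue")])
    fold <- function(col, g, ti, tp) {
        side[side$gene == g & side$tissue == ti & side$timepoint == tp, col]
    }
    res <- lapply(seq_len(nrow(agr)), function(i) {
        g <- agr$gene[i]; ti <- agr$tissue[i]
        fq <- fold("value_qpcr", g, ti, induced) / fold("value_qpcr", g, ti, base)
        fr <- fold("value_rpkm", g, ti, induced) / fold("value_rpkm", g, ti, base)
        sq <- sign(fq - 1); sr <- sign(fr - 1)
        data.frame(gene = g, tissue = ti, qpcr_fold = fq, rnaseq_fold = fr,
                   agreement = if (sq == sr || sq == 0 || sr == 0) "agree"
                               else "disagree")
    })
    agreement <- do.call(rbind, res)
    rownames(agreement) <- NULL
    list(sideBySide = side, agreement = agreement)
}
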