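#' @import methods
#' @import SummarizedExperiment
#' @importFrom S4Vectors DataFrame metadata metadata<-
NULL

.CATEGORIES <- c("specific_up", "specific_down", "enhanced_up",
                 "enhanced_down", "unchanged", "not_expressed")

.RESULT_CATEGORIES <- c("specific_up", "specific_down", "enhanced_up",
                        "enhanced_down", "unclassified", "not_expressed")

#' Two-tissue time-course expression experiment
#'
#' A thin wrapper around \linkS4class{SummarizedExperiment} for a
#' transcripts-by-samples experiment in which every sample is one
#' (tissue, timepoint) combination of a two-tissue induction time course.
#' Assays used by the pipeline are \code{counts} (non-negative integers),
#' \code{rpkm}, \code{rpkm_prefloor} (kept by \code{\link{applyFloor}} so
#' the expression gate can always be evaluated on unfloored values) and
#' \code{floored} (logical mask of floored cells). Column data must carry
#' \code{tissue}, \code{timepoint} (hours) and \code{library_size} (total
#' mapped reads); row data carries \code{length_bp} whenever counts are
#' present, plus the planted truth columns for simulated data.
#'
#' @seealso \code{\link{TcExperiment}} for the constructor,
#'   \code{\link{simulateTcExperiment}}, \code{\link{computeRpkm}}.
#' @export
setClass("TcExperiment", contains = "SummarizedExperiment")

setValidity("TcExperiment", function(object) {
    cd <- colData(object)
    need <- c("tissue", "timepoint", "library_size")
    miss <- setdiff(need, colnames(cd))
    if (length(miss))
        return(sprintf("colData is missing column(s): %s",
                       paste(miss, collapse = ", ")))
    combo <- paste(cd$tissue, cd$timepoint)
    if (anyDuplicated(combo))
        return(sprintf("duplicated (tissue, timepoint) sample(s): %s",
                       paste(unique(combo[duplicated(combo)]), collapse = ", ")))
    full <- as.vector(outer(unique(cd$tissue), unique(cd$timepoint), paste))
    miss <- setdiff(full, combo)
    if (length(miss))
        return(sprintf("missing (tissue, timepoint) sample(s): %s",
                       paste(miss, collapse = ", ")))
    if ("counts" %in% assayNames(object)) {
        if (!"length_bp" %in% colnames(rowData(object)))
            return("rowData$length_bp is required when a counts assay is present")
        cts <- assay(object, "counts")
        if (any(cts < 0)) return("counts must be non-negative")
        if (any(abs(cts - round(cts)) > 1e-8)) return("counts must be integral")
    }
    if (is.null(rownames(object)))
        return("transcript IDs (rownames) are required")
    if (anyDuplicated(rownames(object)))
        return(sprintf("duplicated transcript ID(s): %s",
                       paste(unique(rownames(object)[duplicated(rownames(object))]),
                             collapse = ", ")))
    TRUE
})

#' Per-tissue fold-change table versus the baseline timepoint
#'
#' Linear fold changes of floored RPKM at each post-baseline timepoint
#' relative to the baseline, per tissue, under one direction convention:
#' \code{up_ratio} is timepoint/baseline and \code{down_ratio} is its
#' reciprocal, so "k-fold down-regulated" prints as a positive value k in
#' a down table. Cells of a tissue in which the transcript is not
#' expressed hold \code{NA}, the not-expressed sentinel; how thresholds
#' treat the sentinel is defined by the classifier, not here.
#'
#' @slot fc numeric matrix, transcripts x (tissue, timepoint) columns
#'   named \code{<tissue>_<timepoint>h}; \code{NA} = not-expressed sentinel.
#' @slot expressed logical matrix, transcripts x tissues.
#' @slot direction \code{"up_ratio"} or \code{"down_ratio"}.
#' @slot tissues,timepoints,baseline the grid the table was computed on;
#'   \code{timepoints} are the post-baseline timepoints in hours.
#' @seealso \code{\link{foldChanges}}, \code{\link{foldChangeMatrix}}
#' @export
setClass("FoldChangeTable",
    representation(fc = "matrix", expressed = "matrix",
                   direction = "character", tissues = "character",
                   timepoints = "numeric", baseline = "numeric"))

setValidity("FoldChangeTable", function(object) {
    if (!object@direction %in% c("up_ratio", "down_ratio"))
        return("direction must be 'up_ratio' or 'down_ratio'")
    exp_cols <- as.vector(t(outer(object@tissues, object@timepoints,
                                  function(ti, tp) sprintf("%s_%gh", ti, tp))))
    if (!identical(colnames(object@fc), exp_cols))
        return("fc columns must be tissue x timepoint in declared order")
    if (!identical(colnames(object@expressed), object@tissues))
        return("expressed columns must match tissues")
    if (!identical(rownames(object@fc), rownames(object@expressed)))
        return("fc and expressed must share transcript IDs")
    if (any(object@fc[!is.na(object@fc)] <= 0))
        return("defined fold changes must be positive")
    TRUE
})

#' Parameters of the two-stage specific/enhanced classifier
#'
#' Defaults encode the stringent screen: a transcript is focal-tissue
#' specific when its focal fold change reaches \code{focalFcThreshold}
#' (5) at one or more considered timepoints while the reference tissue
#' changes by less than \code{referenceFcCeiling} (2, in either
#' direction) at every considered timepoint; transcripts excluded from
#' the specific categories are focal-enhanced when the focal minus
#' reference linear fold change at \code{enhancedTimepoint} (3 h) is at
#' least \code{enhancedDiffThreshold} (25). The exploratory variant of
#' the same screen is the parameterization \code{focalFcThreshold = 2},
#' \code{referenceFcCeiling = 1.2}.
#'
#' @export
setClass("ClassifierParams",
    representation(focalTissue = "character", referenceTissue = "character",
                   focalFcThreshold = "numeric", referenceFcCeiling = "numeric",
                   enhancedDiffThreshold = "numeric",
                   enhancedTimepoint = "numeric",
                   timepointsConsidered = "numeric"),
    prototype(focalTissue = "EP", referenceTissue = "SP",
              focalFcThreshold = 5, referenceFcCeiling = 2,
              enhancedDiffThreshold = 25, enhancedTimepoint = 3,
              timepointsConsidered = c(3, 9, 24)))

setValidity("ClassifierParams", function(object) {
    if (length(object@focalTissue) != 1 || length(object@referenceTissue) != 1)
        return("focalTissue and referenceTissue must be single labels")
    if (object@focalTissue == object@referenceTissue)
        return("focal and reference tissue must differ")
    if (!(object@focalFcThreshold > object@referenceFcCeiling))
        return("focalFcThreshold must exceed referenceFcCeiling")
    if (!(object@referenceFcCeiling > 1))
        return("referenceFcCeiling must exceed 1")
    if (!(object@enhancedDiffThreshold > 0))
        return("enhancedDiffThreshold must be positive")
    if (!object@enhancedTimepoint %in% object@timepointsConsidered)
        return("enhancedTimepoint must be one of timepointsConsidered")
    TRUE
})

#' Result of the five-way transcript classification
#'
#' One category per input transcript
#' (\code{specific_up}, \code{specific_down}, \code{enhanced_up},
#' \code{enhanced_down}, \code{unclassified}, \code{not_expressed}),
#' together with the intermediate filter decisions that produced it and
#' the parameters used (provenance).
#'
#' @slot table a \code{DataFrame} with columns \code{transcript_id},
#'   \code{category}, \code{passed_focal_up}, \code{passed_focal_down},
#'   \code{eliminated_by_reference}, \code{enhanced_diff_up},
#'   \code{enhanced_diff_down}.
#' @slot params the \linkS4class{ClassifierParams} used.
#' @seealso \code{\link{classifyAll}}, \code{\link{categoryCounts}}
#' @export
setClass("ClassificationResult",
    representation(table = "DataFrame", params = "ClassifierParams"))

setValidity("ClassificationResult", function(object) {
    need <- c("transcript_id", "category", "passed_focal_up",
              "passed_focal_down", "eliminated_by_reference",
              "enhanced_diff_up", "enhanced_diff_down")
    miss <- setdiff(need, colnames(object@table))
    if (length(miss))
        return(sprintf("result table missing column(s): %s",
                       paste(miss, collapse = ", ")))
    if (anyDuplicated(object@table$transcript_id))
        return("each transcript must receive exactly one category")
    if (!all(object@table$category %in% .RESULT_CATEGORIES))
        return("unknown category label in result table")
    TRUE
})

#' Configuration of the synthetic two-tissue time-course generator
#'
#' Defines the simulated study conditions: number of transcripts,
#' category mix, baseline expression distribution, negative-binomial
#' dispersion, planted fold-change ranges, sequencing depth, transcript
#' length range and the seed. See \code{\link{SimulationConfig}} for the
#' constructor and defaults, and the package vignette for the rationale
#' behind each default.
#'
#' @export
setClass("SimulationConfig",
    representation(nTranscripts = "integer", categoryProportions = "numeric",
                   baselineLogMean = "numeric", baselineLogSd = "numeric",
                   nbDispersion = "numeric", focalFcRange = "numeric",
                   referenceFcRange = "numeric", librarySize = "numeric",
                   lengthRange = "numeric", seed = "integer"))

setValidity("SimulationConfig", function(object) {
    p <- object@categoryProportions
    if (!identical(sort(names(p)), sort(.CATEGORIES)))
        return(sprintf("categoryProportions must be named exactly: %s",
                       paste(.CATEGORIES, collapse = ", ")))
    if (any(p < 0)) return("category proportions must be non-negative")
    if (abs(sum(p) - 1) > 1e-9)
        return("category proportions must sum to 1 (tolerance 1e-9)")
    if (object@nTranscripts < 1L) return("nTranscripts must be positive")
    if (object@baselineLogSd < 0) return("baselineLogSd must be non-negative")
    if (!(object@nbDispersion > 0))
        return("nbDispersion must be positive (Inf = noise-free limit)")
    for (nm in c("focalFcRange", "referenceFcRange", "lengthRange")) {
        r <- slot(object, nm)
        if (length(r) != 2 || any(!is.finite(r)) || r[1] > r[2])
            return(sprintf("%s must be a finite interval [lo, hi]", nm))
    }
    if (object@focalFcRange[1] < 5)
        return("planted focal fold-change range must lie at or above the focal threshold 5")
    if (object@referenceFcRange[1] < 2)
        return("planted reference fold-change range must lie at or above the reference ceiling 2")
    if (object@focalFcRange[2] - object@referenceFcRange[2] <= 25)
        return(paste("focalFcRange upper bound must exceed referenceFcRange upper",
                     "bound by more than the enhanced difference threshold 25"))
    if (object@lengthRange[1] < 1) return("transcript lengths must be positive")
    if (object@librarySize <= 0) return("librarySize must be positive")
    TRUE
})

#' Replicated Ct readings of a validation RT-qPCR experiment
#'
#' Holds per-well threshold cycles (Ct) of target and reference genes
#' across (tissue, timepoint) samples, plus the normalization settings of
#' the delta-delta method: the reference gene, the calibrator sample
#' (default focal tissue at 0 h) and the per-cycle amplification
#' efficiency (default 2, perfect doubling).
#'
#' @slot ct data.frame with columns \code{gene}, \code{tissue},
#'   \code{timepoint}, \code{replicate}, \code{ct}.
#' @slot referenceGene label of the reference gene within \code{ct}.
#' @slot calibrator list with elements \code{tissue} and \code{timepoint}.
#' @slot efficiency amplification factor per cycle, in (1, 2].
#' @seealso \code{\link{QpcrExperiment}}, \code{\link{normalizedExpression}}
#' @export
setClass("QpcrExperiment",
    representation(ct = "data.frame", referenceGene = "character",
                   calibrator = "list", efficiency = "numeric"))

setValidity("QpcrExperiment", function(object) {
    need <- c("gene", "tissue", "timepoint", "replicate", "ct")
    miss <- setdiff(need, colnames(object@ct))
    if (length(miss))
        return(sprintf("ct table missing column(s): %s",
                       paste(miss, collapse = ", ")))
    ct <- object@ct
    if (any(!is.finite(ct$ct)) || any(ct$ct <= 0))
        return("Ct values must be finite and positive")
    if (!object@referenceGene %in% ct$gene)
        return(sprintf("reference gene '%s' absent from the Ct table",
                       object@referenceGene))
    if (!(object@efficiency > 1 && object@efficiency <= 2))
        return("efficiency must lie in (1, 2]")
    if (!all(c("tissue", "timepoint") %in% names(object@calibrator)))
        return("calibrator must name a tissue and a timepoint")
    tgt <- ct[ct$gene != object@referenceGene, ]
    ref <- ct[ct$gene == object@referenceGene, ]
    tgt_samples <- unique(paste(tgt$tissue, tgt$timepoint))
    ref_samples <- unique(paste(ref$tissue, ref$timepoint))
    miss <- setdiff(tgt_samples, ref_samples)
    if (length(miss))
        return(sprintf("reference gene not measured in sample(s): %s",
                       paste(miss, collapse = "; ")))
    cal <- paste(object@calibrator$tissue, object@calibrator$timepoint)
    if (!cal %in% ref_samples)
        return(sprintf("calibrator sample (%s) has no measurements", cal))
    TRUE
})
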