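#' @rdname TcExperiment-accessors
#' @export
setGeneric("tissues", function(x, ...) standardGeneric("tissues"))

#' @rdname TcExperiment-accessors
#' @export
setGeneric("timepoints", function(x, ...) standardGeneric("timepoints"))

#' @rdname TcExperiment-accessors
#' @export
setGeneric("transcriptLengths", function(x) standardGeneric("transcriptLengths"))

#' @rdname TcExperiment-accessors
#' @export
setGeneric("librarySizes", function(x) standardGeneric("librarySizes"))

#' @rdname TcExperiment-accessors
#' @export
setGeneric("rpkm", function(x, ...) standardGeneric("rpkm"))

#' @rdname TcExperiment-accessors
#' @export
setGeneric("flooredMask", function(x) standardGeneric("flooredMask"))

#' @rdname TcExperiment-accessors
#' @export
setGeneric("expressedInTissue", function(x) standardGeneric("expressedInTissue"))

#' @rdname gateExpressed
#' @export
setGeneric("removedIds", function(x) standardGeneric("removedIds"))

#' @rdname simulateTcExperiment
#' @export
setGeneric("syntheticTruth", function(x) standardGeneric("syntheticTruth"))

#' @rdname FoldChangeTable-accessors
#' @export
setGeneric("foldChangeMatrix", function(x, ...) standardGeneric("foldChangeMatrix"))

#' @rdname FoldChangeTable-accessors
#' @export
setGeneric("foldChangeLog2", function(x, ...) standardGeneric("foldChangeLog2"))

#' @rdname FoldChangeTable-accessors
#' @export
setGeneric("direction", function(x) standardGeneric("direction"))

#' @rdname ClassificationResult-accessors
#' @export
setGeneric("classification", function(x) standardGeneric("classification"))

#' @rdname ClassificationResult-accessors
#' @export
setGeneric("categoryCounts", function(x) standardGeneric("categoryCounts"))

#' @rdname ClassificationResult-accessors
#' @export
setGeneric("classifierParams", function(x) standardGeneric("classifierParams"))
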