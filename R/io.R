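# TSV I/O. All readers skip "#" comment lines, keep original line numbers
# for diagnostics, reject explicit NA tokens (silent coercion of a
# missing-value token into a number or sentinel is never allowed) and
# validate before constructing typed objects.

.readRawTsv <- function(path) {
    .stopIfNot(file.exists(path), "file not found: %s", path)
    lines <- readLines(path)
    keep <- !grepl("^#", lines) & nzchar(lines)
    .stopIfNot(sum(keep) >= 1, "%s: no header line", path)
    df <- utils::read.delim(text = paste(lines[keep], collapse = "\n"),
                            header = TRUE, sep = "\t", check.names = FALSE,
                            colClasses = "character",
                            na.strings = character(0),
                            stringsAsFactors = FALSE)
    attr(df, "line_numbers") <- which(keep)[-1]
    df
}

.asNumericCol <- function(df, col, path, integer = FALSE) {
    v <- df[[col]]
    ln <- attr(df, "line_numbers")
    bad <- which(v %in% c("NA", "na", "-", "−"))
    .stopIfNot(length(bad) == 0,
               "%s: explicit NA/sentinel token in column '%s' (line %s)",
               path, col, paste(ln[bad], collapse = ", "))
    num <- suppressWarnings(as.numeric(v))
    bad <- which(is.na(num))
    .stopIfNot(length(bad) == 0,
               "%s: non-numeric value '%s' in column '%s' (line %s)",
               path, if (length(bad)) v[bad[1]] else "", col,
               paste(ln[bad], collapse = ", "))
    if (integer) {
        bad <- which(abs(num - round(num)) > 1e-8)
        .stopIfNot(length(bad) == 0,
                   "%s: non-integral value in column '%s' (line %s)",
                   path, col, paste(ln[bad], collapse = ", "))
    }
    num
}

.checkIds <- function(df, path, col = "transcript_id") {
    .stopIfNot(col %in% colnames(df), "%s: missing '%s' column", path, col)
    ids <- df[[col]]
    ln <- attr(df, "line_numbers")
    if (anyDuplicated(ids)) {
        dup <- ids[duplicated(ids)][1]
        at <- ln[ids == dup]
        stop(sprintf("%s: duplicated transcript ID '%s' (lines %s)",
                     path, dup, paste(at, collapse = " and ")),
             call. = FALSE)
    }
    ids
}

.parseSampleColumns <- function(cols, path) {
    parts <- regmatches(cols, regexec("^(.+)_([0-9.]+)h$", cols))
    bad <- cols[lengths(parts) != 3]
    .stopIfNot(length(bad) == 0,
               "%s: column(s) not of the form <tissue>_<timepoint>h: %s",
               path, paste(bad, collapse = ", "))
    tissue <- vapply(parts, `[`, "", 2)
    timepoint <- as.numeric(vapply(parts, `[`, "", 3))
    full <- as.vector(outer(unique(tissue), unique(timepoint),
                            function(a, b) sprintf("%s_%gh", a, b)))
    miss <- setdiff(full, cols)
    .stopIfNot(length(miss) == 0, "%s: missing sample column(s): %s",
               path, paste(miss, collapse = ", "))
    list(tissue = tissue, timepoint = timepoint)
}

.readMatrixTsv <- function(path, integer = FALSE) {
    df <- .readRawTsv(path)
    ids <- .checkIds(df, path)
    samples <- setdiff(colnames(df), "transcript_id")
    .stopIfNot(length(samples) > 0, "%s: no sample columns", path)
    grid <- .parseSampleColumns(samples, path)
    m <- vapply(samples, function(col) .asNumericCol(df, col, path, integer),
                numeric(nrow(df)))
    m <- matrix(m, nrow = nrow(df), dimnames = list(ids, samples))
    list(matrix = m, tissue = grid$tissue, timepoint = grid$timepoint)
}

#' Read a count matrix with its lengths and library sizes
#'
#' Reads the three TSVs emitted by \code{\link{writeSimulatedData}} (or
#' equivalently formatted files): a count matrix whose columns are
#' \code{<tissue>_<timepoint>h} sample labels, a transcript-length table
#' (\code{transcript_id}, \code{length_bp}) and a library-size table
#' (\code{sample}, \code{total_mapped_reads}). Comment lines prefixed
#' \code{#} are skipped; duplicated IDs, missing samples, explicit NA
#' tokens and non-numeric cells are hard errors reported with line
#' numbers.
#'
#' @param countsPath,lengthsPath,librarySizesPath file paths.
#' @return a \linkS4class{TcExperiment} with a \code{counts} assay.
#' @seealso \code{\link{readRpkmTsv}}, \code{\link{computeRpkm}}
#' @export
readCountTsv <- function(countsPath, lengthsPath, librarySizesPath) {
    cm <- .readMatrixTsv(countsPath, integer = TRUE)
    .stopIfNot(all(cm$matrix >= 0), "%s: negative counts", countsPath)

    ldf <- .readRawTsv(lengthsPath)
    lids <- .checkIds(ldf, lengthsPath)
    .stopIfNot("length_bp" %in% colnames(ldf),
               "%s: missing 'length_bp' column", lengthsPath)
    len <- stats::setNames(.asNumericCol(ldf, "length_bp", lengthsPath), lids)
    miss <- setdiff(rownames(cm$matrix), lids)
    .stopIfNot(length(miss) == 0, "%s: no length for transcript(s): %s",
               lengthsPath, paste(utils::head(miss, 5), collapse = ", "))

    sdf <- .readRawTsv(librarySizesPath)
    .stopIfNot(all(c("sample", "total_mapped_reads") %in% colnames(sdf)),
               "%s: needs columns 'sample' and 'total_mapped_reads'",
               librarySizesPath)
    lib <- stats::setNames(
        .asNumericCol(sdf, "total_mapped_reads", librarySizesPath),
        sdf$sample)
    miss <- setdiff(colnames(cm$matrix), names(lib))
    .stopIfNot(length(miss) == 0, "%s: no library size for sample(s): %s",
               librarySizesPath, paste(miss, collapse = ", "))

    TcExperiment(counts = cm$matrix, tissue = cm$tissue,
                 timepoint = cm$timepoint,
                 lengthsBp = unname(len[rownames(cm$matrix)]),
                 librarySizes = unname(lib[colnames(cm$matrix)]))
}

#' Read a precomputed RPKM matrix
#'
#' Same layout as the count matrix TSV; use this to skip
#' \code{\link{computeRpkm}} when normalized values are already
#' available.
#'
#' @param path file path.
#' @return a \linkS4class{TcExperiment} with an \code{rpkm} assay.
#' @export
readRpkmTsv <- function(path) {
    rm <- .readMatrixTsv(path)
    .stopIfNot(all(rm$matrix >= 0), "%s: negative RPKM values", path)
    x <- TcExperiment(rpkm = rm$matrix, tissue = rm$tissue,
                      timepoint = rm$timepoint)
    assay(x, "floored", withDimnames = FALSE) <-
        matrix(FALSE, nrow(x), ncol(x), dimnames = dimnames(rm$matrix))
    x
}

#' Read an RT-qPCR Ct table
#'
#' TSV with columns \code{gene}, \code{tissue}, \code{timepoint},
#' \code{replicate}, \code{ct}.
#'
#' @param path file path.
#' @return a data.frame ready for \code{\link{QpcrExperiment}}.
#' @export
readCtTsv <- function(path) {
    df <- .readRawTsv(path)
    need <- c("gene", "tissue", "timepoint", "replicate", "ct")
    miss <- setdiff(need, colnames(df))
    .stopIfNot(length(miss) == 0, "%s: missing column(s): %s", path,
               paste(miss, collapse = ", "))
    data.frame(gene = df$gene, tissue = df$tissue,
               timepoint = .asNumericCol(df, "timepoint", path),
               replicate = .asNumericCol(df, "replicate", path, integer = TRUE),
               ct = .asNumericCol(df, "ct", path))
}

#' Read a transcript annotation table
#'
#' Optional mapping of transcript IDs to gene-product descriptions for
#' report generation; annotation is consumed, never computed. Recognized
#' columns besides \code{transcript_id}: \code{gene_product},
#' \code{species_accession}, \code{evalue}, \code{ortholog},
#' \code{is_transcription_factor} (TRUE/FALSE or 1/0). All are optional.
#'
#' @param path file path.
#' @return a data.frame keyed by unique \code{transcript_id}.
#' @export
readAnnotationTsv <- function(path) {
    df <- .readRawTsv(path)
    .checkIds(df, path)
    out <- as.data.frame(df, stringsAsFactors = FALSE)
    attr(out, "line_numbers") <- NULL
    if ("is_transcription_factor" %in% colnames(out))
        out$is_transcription_factor <-
            toupper(out$is_transcription_factor) %in% c("TRUE", "T", "1", "YES")
    out
}

.fmtNum <- function(v) {
    out <- vapply(v, function(x) {
        if (is.na(x)) "-" else format(x, scientific = FALSE, trim = TRUE,
                                      digits = 15)
    }, "")
    out
}

.writeTsv <- function(df, path, comments = character(0)) {
    con <- file(path, "w")
    on.exit(close(con))
    if (length(comments)) writeLines(paste0("# ", comments), con)
    utils::write.table(df, con, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = TRUE)
    invisible(path)
}

.matrixToDf <- function(m) {
    df <- data.frame(transcript_id = rownames(m), check.names = FALSE,
                     stringsAsFactors = FALSE)
    for (col in colnames(m)) df[[col]] <- .fmtNum(m[, col])
    df
}

.seedComment <- function(x) {
    sim <- metadata(x)$simulation
    if (is.null(sim)) character(0) else sprintf("seed: %d", sim$seed)
}

#' Write a count or RPKM matrix as TSV
#'
#' Layout read back by \code{\link{readCountTsv}} /
#' \code{\link{readRpkmTsv}}: a \code{transcript_id} column followed by
#' one \code{<tissue>_<timepoint>h} column per sample. For simulated
#' data the generator seed is echoed as a \code{#} comment line.
#'
#' @param x a \linkS4class{TcExperiment}.
#' @param path output file.
#' @return the path, invisibly.
#' @export
writeCountTsv <- function(x, path) {
    .writeTsv(.matrixToDf(assay(x, "counts")), path, .seedComment(x))
}

#' @rdname writeCountTsv
#' @export
writeRpkmTsv <- function(x, path) {
    .writeTsv(.matrixToDf(rpkm(x)), path, .seedComment(x))
}

#' Write every table of a simulated experiment
#'
#' Emits the four TSVs describing a simulated run into \code{dir}:
#' \code{counts.tsv}, \code{lengths.tsv} (\code{transcript_id},
#' \code{length_bp}), \code{library_sizes.tsv} (\code{sample},
#' \code{total_mapped_reads}) and \code{truth.tsv} (planted category and
#' fold-change profile). The generator seed is echoed as a comment line
#' in each file.
#'
#' @param x a simulated \linkS4class{TcExperiment}.
#' @param dir output directory (created if needed).
#' @return named vector of the four paths, invisibly.
#' @export
writeSimulatedData <- function(x, dir) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    cmt <- .seedComment(x)
    paths <- c(counts = file.path(dir, "counts.tsv"),
               lengths = file.path(dir, "lengths.tsv"),
               library_sizes = file.path(dir, "library_sizes.tsv"),
               truth = file.path(dir, "truth.tsv"))
    writeCountTsv(x, paths["counts"])
    .writeTsv(data.frame(transcript_id = rownames(x),
                         length_bp = .fmtNum(transcriptLengths(x))),
              paths["lengths"], cmt)
    .writeTsv(data.frame(sample = colnames(x),
                         total_mapped_reads = .fmtNum(librarySizes(x))),
              paths["library_sizes"], cmt)
    if ("true_category" %in% colnames(rowData(x))) {
        truth <- as.data.frame(syntheticTruth(x))
        num <- vapply(truth, is.numeric, logical(1))
        truth[num] <- lapply(truth[num], .fmtNum)
        .writeTsv(truth, paths["truth"], cmt)
    } else {
        paths <- paths[setdiff(names(paths), "truth")]
    }
    invisible(paths)
}

#' Write a fold-change table as TSV
#'
#' One row per transcript and tissue with linear and log2 fold changes
#' at every post-baseline timepoint plus the expression call; the
#' not-expressed sentinel renders as \code{-}.
#'
#' @param fct a \linkS4class{FoldChangeTable}.
#' @param path output file.
#' @return the path, invisibly.
#' @export
writeFoldChangeTsv <- function(fct, path) {
    rows <- lapply(tissues(fct), function(ti) {
        lin <- foldChangeMatrix(fct, ti)
        l2 <- foldChangeLog2(fct, ti)
        df <- data.frame(transcript_id = rownames(lin), tissue = ti,
                         stringsAsFactors = FALSE)
        for (tp in colnames(lin)) df[[paste0("fc", sub("h$", "", tp))]] <-
            .fmtNum(lin[, tp])
        for (tp in colnames(l2)) df[[paste0("log2fc", sub("h$", "", tp))]] <-
            .fmtNum(l2[, tp])
        df$expressed <- expressedInTissue(fct)[, ti]
        df
    })
    .writeTsv(do.call(rbind, rows), path,
              sprintf("direction: %s", direction(fct)))
}

#' Write a classification table as TSV
#'
#' Per transcript: category, the two focal-filter booleans, the
#' reference-elimination boolean and the enhanced difference values
#' (sentinel \code{-} where undefined).
#'
#' @param result a \linkS4class{ClassificationResult}.
#' @param path output file.
#' @return the path, invisibly.
#' @export
writeClassificationTsv <- function(result, path) {
    tab <- as.data.frame(classification(result))
    tab$enhanced_diff_up <- .fmtNum(tab$enhanced_diff_up)
    tab$enhanced_diff_down <- .fmtNum(tab$enhanced_diff_down)
    .writeTsv(tab, path)
}
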