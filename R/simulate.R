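#' Configure the synthetic two-tissue time-course generator
#'
#' Builds a validated \linkS4class{SimulationConfig}. The defaults are
#' the simulated study conditions: eight pooled samples (two tissues,
#' EP and SP, at 0/3/9/24 h), ~45 million mapped reads each, log-normal
#' baseline expression, negative-binomial counting noise, and planted
#' fold-change profiles that realize each of the six transcript
#' categories of the specific/enhanced classification scheme. See the
#' package vignette for the rationale behind every default.
#'
#' @param nTranscripts number of transcripts to simulate.
#' @param categoryProportions named fractions over the six categories
#'   \code{specific_up}, \code{specific_down}, \code{enhanced_up},
#'   \code{enhanced_down}, \code{unchanged}, \code{not_expressed};
#'   must sum to 1 (tolerance 1e-9). Quotas are allocated exactly by the
#'   largest-remainder method, not sampled.
#' @param baselineLogMean,baselineLogSd natural-log mean and sd of the
#'   log-normal baseline RPKM of expressed transcripts.
#' @param nbDispersion negative-binomial size parameter of the count
#'   noise; \code{Inf} gives the noise-free limit (counts are the rounded
#'   expected values).
#' @param focalFcRange interval of planted focal-tissue linear fold
#'   changes for the specific categories; must lie at or above the focal
#'   threshold 5. Draws are log-uniform.
#' @param referenceFcRange interval of planted reference-tissue fold
#'   changes for the enhanced categories; must lie at or above the
#'   reference ceiling 2 (these transcripts must fail the specific
#'   filter by construction).
#' @param librarySize total mapped reads per sample.
#' @param lengthRange interval of transcript lengths in bp (uniform
#'   integer draws).
#' @param seed integer seed; the generator is deterministic given the
#'   full configuration.
#' @return a \linkS4class{SimulationConfig}.
#' @seealso \code{\link{simulateTcExperiment}}
#' @export
SimulationConfig <- function(nTranscripts = 1000L,
                             categoryProportions = c(specific_up = 0.10,
                                                     specific_down = 0.05,
                                                     enhanced_up = 0.05,
                                                     enhanced_down = 0.01,
                                                     unchanged = 0.69,
                                                     not_expressed = 0.10),
                             baselineLogMean = 3, baselineLogSd = 1,
                             nbDispersion = 50,
                             focalFcRange = c(6, 600),
                             referenceFcRange = c(2.5, 10),
                             librarySize = 45e6,
                             lengthRange = c(500, 3000),
                             seed = 1L) {
    new("SimulationConfig",
        nTranscripts = as.integer(nTranscripts),
        categoryProportions = categoryProportions,
        baselineLogMean = baselineLogMean, baselineLogSd = baselineLogSd,
        nbDispersion = nbDispersion,
        focalFcRange = as.numeric(focalFcRange),
        referenceFcRange = as.numeric(referenceFcRange),
        librarySize = librarySize,
        lengthRange = as.numeric(lengthRange),
        seed = as.integer(seed))
}

setMethod("show", "SimulationConfig", function(object) {
    cat(sprintf("SimulationConfig: %d transcripts, seed %d\n",
                object@nTranscripts, object@seed))
    p <- object@categoryProportions[.CATEGORIES]
    cat("  proportions:", paste(sprintf("%s=%g", names(p), p), collapse = " "), "\n")
    cat(sprintf("  baseline lnRPKM ~ N(%g, %g); NB size %g; library %g reads\n",
                object@baselineLogMean, object@baselineLogSd,
                object@nbDispersion, object@librarySize))
    invisible(NULL)
})

.lograndom <- function(k, lo, hi) exp(stats::runif(k, log(lo), log(hi)))

#' Simulate a two-tissue time course with planted category truth
#'
#' Generates an eight-sample (EP/SP at 0, 3, 9, 24 h) count matrix whose
#' expected RPKM values follow planted per-category fold-change profiles,
#' so the full RPKM/floor/gate/classify pipeline can be exercised and
#' scored against known truth. Counts are drawn negative-binomially with
#' mean \code{planted RPKM x length_kb x library_millions}; with
#' \code{nbDispersion = Inf} the counts are the rounded means (noise-free
#' limit). Category quotas are met exactly (largest-remainder
#' allocation); category placement along the transcript index is a seeded
#' permutation.
#'
#' Planted profiles (linear fold change vs 0 h, up-ratio convention):
#' specific transcripts sustain their focal fold change (or its
#' reciprocal) at all three post-baseline timepoints with an unchanged
#' reference tissue; enhanced transcripts change at 3 h only, with a
#' reference change drawn from \code{referenceFcRange} (so they fail the
#' specific filter) and a focal-minus-reference difference drawn
#' log-uniformly above the enhanced threshold; \code{unchanged} is flat;
#' \code{not_expressed} has baseline RPKM uniform on [0, 0.4] in both
#' tissues, below the 0.5 expression gate. Baselines of down-regulated
#' plantings are raised to 0.12 x the planted down-fold, since a k-fold
#' decrease is only observable when the baseline exceeds k x the 0.1
#' RPKM floor.
#'
#' @param config a \linkS4class{SimulationConfig}.
#' @return a \linkS4class{TcExperiment} with a \code{counts} assay,
#'   \code{length_bp} row data and planted-truth row columns
#'   (\code{true_category}, \code{planted_fc_<tissue>_<t>h},
#'   \code{planted_baseline_<tissue>}); retrieve them with
#'   \code{\link{syntheticTruth}}.
#' @param x a \linkS4class{TcExperiment} (for \code{syntheticTruth}).
#' @examples
#' sim <- simulateTcExperiment(SimulationConfig(nTranscripts = 60, seed = 7))
#' table(syntheticTruth(sim)$true_category)
#' @export
simulateTcExperiment <- function(config) {
    validObject(config)
    set.seed(config@seed)
    n <- config@nTranscripts
    quota <- .largestRemainderQuota(n, config@categoryProportions[.CATEGORIES])
    category <- sample(rep(names(quota), quota))
    ids <- sprintf("tx_%05d", seq_len(n))
    tissues <- c("EP", "SP")
    tps <- c(0, 3, 9, 24)
    len <- sample(seq(config@lengthRange[1], config@lengthRange[2]), n,
                  replace = TRUE)

    base <- matrix(pmax(stats::rlnorm(2 * n, config@baselineLogMean,
                                      config@baselineLogSd), 1),
                   nrow = n, dimnames = list(ids, tissues))
    # fold-change profiles (up-ratio convention), flat by default
    fc <- array(1, dim = c(n, 2, 3),
                dimnames = list(ids, tissues, paste0(tps[-1], "h")))

    idx <- function(cat) which(category == cat)
    flo <- config@focalFcRange[1]; fhi <- config@focalFcRange[2]
    rlo <- config@referenceFcRange[1]; rhi <- config@referenceFcRange[2]
    dhi <- max(27, fhi - rhi)

    i <- idx("specific_up")
    if (length(i)) fc[i, "EP", ] <- .lograndom(length(i), flo, fhi)

    i <- idx("specific_down")
    if (length(i)) {
        f <- .lograndom(length(i), flo, fhi)
        fc[i, "EP", ] <- 1 / f
        base[i, "EP"] <- pmax(base[i, "EP"], 0.12 * f)
    }

    i <- idx("enhanced_up")
    if (length(i)) {
        r <- stats::runif(length(i), rlo, rhi)
        d <- .lograndom(length(i), 27, dhi)
        fc[i, "EP", "3h"] <- r + d
        fc[i, "SP", "3h"] <- r
        base[i, "SP"] <- pmax(base[i, "SP"], 0.12 * r)
    }

    i <- idx("enhanced_down")
    if (length(i)) {
        r <- stats::runif(length(i), rlo, rhi)
        d <- .lograndom(length(i), 27, dhi)
        fc[i, "EP", "3h"] <- 1 / (r + d)
        fc[i, "SP", "3h"] <- 1 / r
        base[i, "EP"] <- pmax(base[i, "EP"], 0.12 * (r + d))
        base[i, "SP"] <- pmax(base[i, "SP"], 0.12 * r)
    }

    i <- idx("not_expressed")
    if (length(i)) base[i, ] <- stats::runif(2 * length(i), 0, 0.4)

    # expected RPKM per sample, then counts
    planted <- matrix(0, n, 8,
                      dimnames = list(ids, .sampleLabel(rep(tissues, each = 4),
                                                        rep(tps, 2))))
    for (ti in tissues) {
        planted[, .sampleLabel(ti, 0)] <- base[, ti]
        for (k in seq_along(tps[-1]))
            planted[, .sampleLabel(ti, tps[-1][k])] <-
                base[, ti] * fc[, ti, k]
    }
    mu <- planted * (len / 1e3) * (config@librarySize / 1e6)
    counts <- if (is.infinite(config@nbDispersion)) round(mu) else
        matrix(stats::rnbinom(length(mu), mu = mu, size = config@nbDispersion),
               nrow = n, dimnames = dimnames(mu))

    truth <- DataFrame(true_category = category)
    for (ti in tissues) for (k in seq_along(tps[-1]))
        truth[[sprintf("planted_fc_%s_%gh", ti, tps[-1][k])]] <- fc[, ti, k]
    truth$planted_baseline_EP <- base[, "EP"]
    truth$planted_baseline_SP <- base[, "SP"]

    se <- TcExperiment(counts = counts,
                       tissue = rep(tissues, each = 4),
                       timepoint = rep(tps, 2),
                       lengthsBp = len,
                       librarySizes = rep(config@librarySize, 8),
                       rowData = truth)
    metadata(se)$simulation <- list(seed = config@seed,
                                    n_transcripts = n,
                                    nb_dispersion = config@nbDispersion,
                                    quota = as.list(quota))
    se
}

#' Score planted-truth recovery of a classification
#'
#' Compares predicted categories with the planted truth, mapping the
#' truth label \code{unchanged} onto the classifier label
#' \code{unclassified} (an unchanged transcript is correctly recovered
#' when the classifier leaves it unclassified).
#'
#' @param result a \linkS4class{ClassificationResult}.
#' @param truth the \code{DataFrame} from \code{\link{syntheticTruth}},
#'   or a named character vector of planted categories.
#' @return list with \code{overall} (fraction of transcripts whose
#'   predicted category equals the planted one) and \code{perCategory}
#'   (named fractions by planted category).
#' @examples
#' sim <- simulateTcExperiment(SimulationConfig(nTranscripts = 120, seed = 3,
#'                                              nbDispersion = Inf))
#' res <- classifyAll(computeRpkm(sim))
#' recoveryRate(res, syntheticTruth(sim))$overall
#' @export
recoveryRate <- function(result, truth) {
    stopifnot(is(result, "ClassificationResult"))
    if (is(truth, "DataFrame") || is.data.frame(truth))
        truth <- stats::setNames(as.character(truth$true_category),
                                 truth$transcript_id)
    tab <- classification(result)
    .stopIfNot(all(tab$transcript_id %in% names(truth)),
               "classified transcripts missing from the truth table")
    planted <- truth[tab$transcript_id]
    expected <- ifelse(planted == "unchanged", "unclassified", planted)
    hit <- tab$category == expected
    per <- vapply(split(hit, planted), mean, numeric(1))
    list(overall = mean(hit), perCategory = per)
}
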