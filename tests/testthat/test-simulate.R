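test_that("generation is deterministic given the seed", {
    cfg <- SimulationConfig(nTranscripts = 80, seed = 42L)
    a <- simulateTcExperiment(cfg)
    b <- simulateTcExperiment(cfg)
    expect_identical(assay(a, "counts"), assay(b, "counts"))
    expect_identical(as.data.frame(syntheticTruth(a)),
                     as.data.frame(syntheticTruth(b)))
})

test_that("category quotas are allocated exactly, not sampled", {
    cfg <- SimulationConfig(nTranscripts = 1000,
                            categoryProportions = c(specific_up = 0.1,
                                                    specific_down = 0.05,
                                                    enhanced_up = 0.05,
                                                    enhanced_down = 0.01,
                                                    unchanged = 0.69,
                                                    not_expressed = 0.1),
                            seed = 7L)
    sim <- simulateTcExperiment(cfg)
    tally <- table(syntheticTruth(sim)$true_category)
    expect_identical(as.integer(tally[c("specific_up", "specific_down",
                                        "enhanced_up", "enhanced_down",
                                        "unchanged", "not_expressed")]),
                     c(100L, 50L, 50L, 10L, 690L, 100L))
    # truth covers every emitted transcript exactly once
    expect_identical(syntheticTruth(sim)$transcript_id, rownames(sim))
    expect_false(anyDuplicated(rownames(sim)) > 0)
})

test_that("noise-free counts reproduce the planted RPKM profile", {
    props <- setNames(rep(1 / 6, 6),
                      c("specific_up", "specific_down", "enhanced_up",
                        "enhanced_down", "unchanged", "not_expressed"))
    cfg <- SimulationConfig(nTranscripts = 6, categoryProportions = props,
                            nbDispersion = Inf, seed = 3L)
    sim <- simulateTcExperiment(cfg)
    truth <- syntheticTruth(sim)
    planted <- cbind(EP_0h = truth$planted_baseline_EP,
                     EP_3h = truth$planted_baseline_EP * truth$planted_fc_EP_3h,
                     EP_9h = truth$planted_baseline_EP * truth$planted_fc_EP_9h,
                     EP_24h = truth$planted_baseline_EP * truth$planted_fc_EP_24h,
                     SP_0h = truth$planted_baseline_SP,
                     SP_3h = truth$planted_baseline_SP * truth$planted_fc_SP_3h,
                     SP_9h = truth$planted_baseline_SP * truth$planted_fc_SP_9h,
                     SP_24h = truth$planted_baseline_SP * truth$planted_fc_SP_24h)
    got <- rpkm(computeRpkm(sim))
    # integer rounding of counts bounds the per-cell RPKM error
    tol <- 0.5 / ((transcriptLengths(sim) / 1e3) %o%
                  (librarySizes(sim) / 1e6))
    expect_true(all(abs(got - planted) <= tol))
})

test_that("not-expressed plantings sit below the gate in every sample", {
    cfg <- SimulationConfig(nTranscripts = 120, nbDispersion = Inf, seed = 5L)
    sim <- simulateTcExperiment(cfg)
    ne <- syntheticTruth(sim)$true_category == "not_expressed"
    r <- rpkm(computeRpkm(sim))
    expect_true(all(r[ne, ] < 0.5))
})

test_that("invalid configurations are rejected", {
    expect_error(SimulationConfig(categoryProportions = c(specific_up = 0.5,
        specific_down = 0.1, enhanced_up = 0.1, enhanced_down = 0.1,
        unchanged = 0.1, not_expressed = 0.2)), "sum to 1")
    expect_error(SimulationConfig(focalFcRange = c(3, 600)),
                 "focal fold-change range")
    expect_error(SimulationConfig(referenceFcRange = c(1.5, 10)),
                 "reference fold-change range")
    expect_error(SimulationConfig(lengthRange = c(3000, 500)), "interval")
    expect_error(SimulationConfig(nbDispersion = 0), "nbDispersion")
})
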