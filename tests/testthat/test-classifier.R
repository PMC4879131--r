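test_that("focal threshold is inclusive at >= 5 and reference at >= 2 either way", {
    up <- rbind(below = c(4.9, 4.9, 4.9, 1, 1, 1),
                at = c(5, 1, 1, 1, 1, 1),
                ref_up = c(512, 128, 64, 2, 1, 1),
                ref_down = c(512, 128, 64, 1, 0.5, 1),
                ref_near = c(512, 128, 64, 1.4, 0.6, 1))
    colnames(up) <- fc_cols
    fc <- make_fc_pair(up)
    spec <- classifySpecific(fc$up, fc$down)
    expect_identical(sort(spec$up), c("at", "ref_near"))
    expect_false("below" %in% spec$up)
    # SP at exactly 2-fold (either direction) eliminates
    d <- spec$decisions
    expect_true(d$eliminated_by_reference[d$transcript_id == "ref_up"])
    expect_true(d$eliminated_by_reference[d$transcript_id == "ref_down"])
    expect_false(d$eliminated_by_reference[d$transcript_id == "ref_near"])
})

test_that("a transcript silent in the reference tissue passes the elimination", {
    up <- rbind(t13378 = c(2^8.9, 2^7.1, 2^6.5, NA, NA, NA))
    colnames(up) <- fc_cols
    fc <- make_fc_pair(up)
    spec <- classifySpecific(fc$up, fc$down)
    expect_identical(spec$up, "t13378")
})

test_that("enhanced difference uses linear 3-h fold changes with silent reference = 1", {
    up <- rbind(strong = c(378, 1, 1, 1, 1, 1),
                boundary = c(27, 1, 1, 2, 1, 1),
                under = c(20, 1, 1, 1, 1, 1),
                silent_ref = c(40, 1, 1, NA, NA, NA))
    colnames(up) <- fc_cols
    fc <- make_fc_pair(up)
    enh <- classifyEnhanced(fc$up, fc$down, rownames(up))
    expect_true(all(c("strong", "boundary", "silent_ref") %in% enh$up))
    expect_false("under" %in% enh$up)
    d <- setNames(enh$diffs$enhanced_diff_up, enh$diffs$transcript_id)
    expect_equal(d[["strong"]], 377)
    expect_equal(d[["boundary"]], 25)     # "25 or greater" includes the tie
    expect_equal(d[["silent_ref"]], 39)
    expect_error(classifyEnhanced(fc$up, fc$down, c("strong", "ghost")),
                 "ghost")
})

test_that("invalid parameters error before any computation", {
    expect_error(ClassifierParams(focalFcThreshold = 2, referenceFcCeiling = 2),
                 "exceed")
    expect_error(ClassifierParams(referenceFcCeiling = 0.9), "exceed 1")
    expect_error(ClassifierParams(enhancedTimepoint = 12),
                 "timepointsConsidered")
})

test_that("classifySpecific agrees with per-transcript rule evaluation", {
    m <- random_rpkm_matrix(200, seed = 31)
    x <- gateExpressed(applyFloor(make_rpkm_tc(m)))
    fcUp <- foldChanges(x, "up_ratio")
    fcDown <- foldChanges(x, "down_ratio")
    spec <- classifySpecific(fcUp, fcDown)
    oracle <- oracle_specific_sets(m)
    expect_setequal(spec$up, oracle$up)
    expect_setequal(spec$down, oracle$down)
})

test_that("classifyAll partitions the input and matches planted truth noise-free", {
    sim <- simulateTcExperiment(SimulationConfig(nTranscripts = 300,
                                                 nbDispersion = Inf,
                                                 seed = 17L))
    res <- classifyAll(sim)
    tab <- classification(res)
    expect_setequal(tab$transcript_id, rownames(sim))
    expect_equal(sum(categoryCounts(res)), nrow(sim))
    expect_equal(recoveryRate(res, syntheticTruth(sim))$overall, 1)
})

test_that("empty input yields an empty result with zero counts everywhere", {
    sim <- simulateTcExperiment(SimulationConfig(nTranscripts = 10, seed = 2L))
    empty <- computeRpkm(sim)[integer(0), ]
    res <- classifyAll(empty)
    expect_equal(nrow(classification(res)), 0)
    expect_true(all(categoryCounts(res) == 0))
})

test_that("specific sets shrink as thresholds tighten (subset monotonicity)", {
    m <- random_rpkm_matrix(250, seed = 53)
    x <- gateExpressed(applyFloor(make_rpkm_tc(m)))
    fcUp <- foldChanges(x, "up_ratio")
    fcDown <- foldChanges(x, "down_ratio")
    base <- classifySpecific(fcUp, fcDown, ClassifierParams())
    higher_focal <- classifySpecific(fcUp, fcDown,
                                     ClassifierParams(focalFcThreshold = 10))
    lower_ceiling <- classifySpecific(fcUp, fcDown,
        ClassifierParams(referenceFcCeiling = 1.5))
    expect_true(all(higher_focal$up %in% base$up))
    expect_true(all(higher_focal$down %in% base$down))
    expect_true(all(lower_ceiling$up %in% base$up))
    excl <- setdiff(rownames(x), union(base$up, base$down))
    enh <- classifyEnhanced(fcUp, fcDown, excl)
    enh_strict <- classifyEnhanced(fcUp, fcDown, excl,
                                   ClassifierParams(enhancedDiffThreshold = 50))
    expect_true(all(enh_strict$up %in% enh$up))
    expect_true(all(enh_strict$down %in% enh$down))
})

test_that("the exploratory parameterization is the same filter, relaxed", {
    m <- random_rpkm_matrix(150, seed = 77)
    x <- gateExpressed(applyFloor(make_rpkm_tc(m)))
    fcUp <- foldChanges(x, "up_ratio")
    fcDown <- foldChanges(x, "down_ratio")
    exploratory <- ClassifierParams(focalFcThreshold = 2,
                                    referenceFcCeiling = 1.2)
    stringent <- ClassifierParams(focalFcThreshold = 5,
                                  referenceFcCeiling = 1.2)
    # with the reference ceiling held, raising only the focal threshold
    # from the exploratory 2 to the stringent 5 can only shrink the sets
    a <- classifySpecific(fcUp, fcDown, exploratory)
    b <- classifySpecific(fcUp, fcDown, stringent)
    expect_true(all(b$up %in% a$up))
    expect_true(all(b$down %in% a$down))
    # and the exploratory screen is a valid parameterization end to end
    res <- classifyFromTables(fcUp, fcDown, exploratory)
    expect_equal(sum(categoryCounts(res)), nrow(x))
})
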