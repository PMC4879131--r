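test_that("one target cycle gained over the reference doubles expression", {
    fc <- list(VfWRKY28 = list(EP_0 = 1, EP_3 = 2, SP_0 = 1, SP_3 = 1))
    q <- QpcrExperiment(make_ct_table(fc), "VfEFalpha")
    expect_equal(normalizedExpression(q, "VfWRKY28", "EP", 3)$value, 2)
    # calibrator sample is exactly 1 by construction
    expect_identical(normalizedExpression(q, "VfWRKY28", "EP", 0)$value, 1)
})

test_that("the reference gene's own normalized expression would be 1 everywhere", {
    # normalizing the reference against itself is rejected as a target,
    # so check the identity through a target with identical Ct profile
    ct <- make_ct_table(list(shadow = list(EP_0 = 1, EP_3 = 1,
                                           SP_0 = 1, SP_3 = 1)))
    q <- QpcrExperiment(ct, "VfEFalpha")
    for (ti in c("EP", "SP")) for (tp in c(0, 3))
        expect_equal(normalizedExpression(q, "shadow", ti, tp)$value, 1)
    expect_error(normalizedExpression(q, "VfEFalpha", "EP", 3),
                 "reference gene")
})

test_that("delta-delta matches brute-force enumeration on random Ct tables", {
    set.seed(19)
    ct <- expand.grid(gene = c("g1", "g2", "ref"),
                      tissue = c("EP", "SP"), timepoint = c(0, 3),
                      replicate = 1:3, stringsAsFactors = FALSE)
    ct$ct <- runif(nrow(ct), 15, 35)
    q <- QpcrExperiment(ct, "ref")
    for (g in c("g1", "g2")) for (ti in c("EP", "SP")) for (tp in c(0, 3))
        expect_equal(normalizedExpression(q, g, ti, tp)$value,
                     oracle_ddct(ct, "ref", g, ti, tp),
                     tolerance = 1e-12)
})

test_that("a uniform additive Ct shift within a sample cancels out", {
    set.seed(23)
    ct <- expand.grid(gene = c("g1", "ref"), tissue = c("EP", "SP"),
                      timepoint = c(0, 3), replicate = 1:3,
                      stringsAsFactors = FALSE)
    ct$ct <- runif(nrow(ct), 18, 30)
    shifted <- ct
    sel <- shifted$tissue == "SP" & shifted$timepoint == 3
    shifted$ct[sel] <- shifted$ct[sel] + 2.7   # e.g. less input cDNA
    a <- normalizedExpression(QpcrExperiment(ct, "ref"), "g1", "SP", 3)
    b <- normalizedExpression(QpcrExperiment(shifted, "ref"), "g1", "SP", 3)
    expect_equal(a$value, b$value, tolerance = 1e-12)
})

test_that("sub-2 efficiency follows efficiency^(-ddCt)", {
    fc <- list(g = list(EP_0 = 1, EP_3 = 4, SP_0 = 1, SP_3 = 1))
    ct <- make_ct_table(fc)
    q <- QpcrExperiment(ct, "VfEFalpha", efficiency = 1.9)
    # planted ddCt is -2 cycles
    expect_equal(normalizedExpression(q, "g", "EP", 3)$value, 1.9^2)
})

test_that("single replicates give an undefined SEM, and missing reference errors", {
    ct <- make_ct_table(list(g = list(EP_0 = 1, EP_3 = 2, SP_0 = 1, SP_3 = 1)),
                        reps = 1)
    q <- QpcrExperiment(ct, "VfEFalpha")
    ne <- normalizedExpression(q, "g", "EP", 3)
    expect_true(is.na(ne$sem))
    expect_equal(ne$value, 2)
    bad <- ct[!(ct$gene == "VfEFalpha" & ct$tissue == "SP" & ct$timepoint == 3), ]
    expect_error(QpcrExperiment(bad, "VfEFalpha"), "SP 3")
})

test_that("replicate scatter propagates to a positive SEM", {
    ct <- make_ct_table(list(g = list(EP_0 = 1, EP_3 = 2, SP_0 = 1, SP_3 = 1)))
    ct$ct <- ct$ct + rep(c(-0.1, 0, 0.1), length.out = nrow(ct))
    q <- QpcrExperiment(ct, "VfEFalpha")
    ne <- normalizedExpression(q, "g", "EP", 3)
    expect_gt(ne$sem, 0)
})

test_that("concordance flags exactly the discordant platform calls", {
    qv <- expand.grid(gene = c("g1", "g2", "g3", "g4"),
                      tissue = c("EP", "SP"), timepoint = c(0, 3),
                      stringsAsFactors = FALSE)
    qv$value <- 1
    rv <- qv
    bump <- function(d, g, ti, tp, v) {
        d$value[d$gene == g & d$tissue == ti & d$timepoint == tp] <- v; d
    }
    # g1: up on both platforms in EP; g2: discordant in SP; g3/g4 flat
    qv <- bump(qv, "g1", "EP", 3, 6);  rv <- bump(rv, "g1", "EP", 3, 8)
    qv <- bump(qv, "g2", "SP", 3, 5);  rv <- bump(rv, "g2", "SP", 3, 0.2)
    rep <- concordanceReport(qv, rv)
    agr <- rep$agreement
    expect_equal(sum(agr$agreement == "disagree"), 1)
    expect_identical(agr$gene[agr$agreement == "disagree"], "g2")
    expect_identical(agr$agreement[agr$gene == "g1" & agr$tissue == "EP"],
                     "agree")
    expect_identical(agr$agreement[agr$gene == "g3" & agr$tissue == "SP"],
                     "agree")   # flat on both platforms counts as agreement
    # grid mismatch is a hard error listing the missing cell
    expect_error(concordanceReport(qv[-1, ], rv), "g1 EP 0")
})
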