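make_count_tc <- function(counts, lengths, libs = rep(1e7, 8)) {
    TcExperiment(counts = counts,
                 tissue = rep(c("EP", "SP"), each = 4),
                 timepoint = rep(c(0, 3, 9, 24), 2),
                 lengthsBp = lengths, librarySizes = libs)
}

test_that("RPKM follows the closed form", {
    cts <- matrix(c(rep(1000, 8), rep(0, 8)), nrow = 2, byrow = TRUE,
                  dimnames = list(c("a", "b"), NULL))
    x <- computeRpkm(make_count_tc(cts, lengths = c(2000, 2000)))
    expect_equal(unname(rpkm(x)["a", ]), rep(50, 8))  # 1000/(2 kb x 10 M/1e6)
    expect_equal(unname(rpkm(x)["b", ]), rep(0, 8))
    expect_false(any(flooredMask(x)))
})

test_that("RPKM agrees with the scalar brute-force oracle", {
    set.seed(101)
    cts <- matrix(rpois(160, 400), nrow = 20,
                  dimnames = list(sprintf("t%02d", 1:20), NULL))
    len <- sample(200:4000, 20)
    lib <- sample(1e6:5e7, 8)
    x <- computeRpkm(make_count_tc(cts, len, lib))
    expect_equal(unname(rpkm(x)), unname(oracle_rpkm(cts, len, lib)),
                 tolerance = 1e-12)
})

test_that("zero denominators are hard errors naming the offender", {
    cts <- matrix(5, 2, 8, dimnames = list(c("a", "b"), NULL))
    expect_error(computeRpkm(make_count_tc(cts, c(2000, 2000),
                                           libs = c(0, rep(1e7, 7)))),
                 "EP_0h")
    x <- make_count_tc(cts, c(2000, 2000))
    rowData(x)$length_bp[2] <- 0
    expect_error(computeRpkm(x), "b")
})

test_that("flooring replaces only sub-floor cells, flags them, and is idempotent", {
    m <- matrix(c(0.05, rep(1, 7),
                  0.1, rep(1, 7),
                  rep(2, 8)), nrow = 3, byrow = TRUE,
                dimnames = list(c("low", "edge", "hi"), SAMPLES))
    x <- applyFloor(make_rpkm_tc(m))
    expect_equal(rpkm(x)["low", "EP_0h"], 0.1)
    expect_true(flooredMask(x)["low", "EP_0h"])
    expect_equal(rpkm(x)["edge", "EP_0h"], 0.1)
    expect_false(flooredMask(x)["edge", "EP_0h"])   # not "less than" the floor
    expect_false(any(flooredMask(x)["hi", ]))
    twice <- applyFloor(x)
    expect_identical(rpkm(twice), rpkm(x))
    expect_identical(flooredMask(twice), flooredMask(x))
    # unfloored values are retained
    expect_equal(rpkm(x, prefloor = TRUE)["low", "EP_0h"], 0.05)
})

test_that("the expression gate removes all-silent transcripts and flags tissues", {
    m <- rbind(silent = rep(0.1, 8),
               ep_only = c(0.6, 12, 40, 33, rep(0.1, 4)),
               boundary = c(0.5, rep(0.1, 7)),
               both = rep(3, 8))
    colnames(m) <- SAMPLES
    x <- gateExpressed(make_rpkm_tc(m))
    expect_identical(removedIds(x), "silent")
    expect_identical(sort(rownames(x)), sort(c("ep_only", "boundary", "both")))
    e <- expressedInTissue(x)
    expect_true(e["ep_only", "EP"]); expect_false(e["ep_only", "SP"])
    expect_true(e["boundary", "EP"])  # 0.5 or above is expressed
    expect_true(all(e["both", ]))
})

test_that("gating reads pre-floor values, so floor and gate commute", {
    m <- random_rpkm_matrix(60, seed = 8)
    a <- gateExpressed(applyFloor(make_rpkm_tc(m)))
    b <- gateExpressed(make_rpkm_tc(m))
    expect_identical(removedIds(a), removedIds(b))
    expect_identical(expressedInTissue(a), expressedInTissue(b))
})

test_that("fold changes follow the direction conventions", {
    m <- rbind(powers = c(0.1, 51.2, 0.1, 0.1, 1, 1, 1, 1),
               flat = c(rep(2, 4), 1, 1, 1, 1),
               down = c(8, 8, 8, 1, 1, 1, 1, 1))
    colnames(m) <- SAMPLES
    x <- gateExpressed(applyFloor(make_rpkm_tc(m)))
    up <- foldChanges(x, "up_ratio")
    down <- foldChanges(x, "down_ratio")
    expect_equal(foldChangeMatrix(up, "EP")["powers", "3h"], 512)
    expect_equal(foldChangeLog2(up, "EP")["powers", "3h"], 9)
    expect_equal(foldChangeMatrix(up, "EP")["flat", "3h"], 1)
    expect_equal(foldChangeLog2(up, "EP")["flat", "3h"], 0)
    expect_equal(foldChangeMatrix(down, "EP")["down", "24h"], 8)
    expect_equal(foldChangeLog2(down, "EP")["down", "24h"], 3)
})

test_that("up and down tables are element-wise reciprocal where defined", {
    m <- random_rpkm_matrix(80, seed = 21)
    x <- gateExpressed(applyFloor(make_rpkm_tc(m)))
    up <- foldChangeMatrix(foldChanges(x, "up_ratio"))
    down <- foldChangeMatrix(foldChanges(x, "down_ratio"))
    expect_identical(is.na(up), is.na(down))
    ok <- !is.na(up)
    expect_equal(up[ok], 1 / down[ok], tolerance = 1e-12)
})

test_that("sentinels appear exactly for silent tissues, and zero baselines error", {
    m <- rbind(ep_only = c(0.6, 12, 40, 33, rep(0.1, 4)))
    colnames(m) <- SAMPLES
    x <- gateExpressed(applyFloor(make_rpkm_tc(m)))
    up <- foldChanges(x, "up_ratio")
    expect_true(all(is.na(foldChangeMatrix(up, "SP"))))
    expect_false(any(is.na(foldChangeMatrix(up, "EP"))))
    # unfloored zero baseline is a hard error
    m2 <- rbind(z = c(0, 5, 5, 5, 1, 1, 1, 1))
    colnames(m2) <- SAMPLES
    expect_error(foldChanges(gateExpressed(make_rpkm_tc(m2))),
                 "floor")
})

test_that("RPKM mass balance holds per sample on synthetic data", {
    sim <- simulateTcExperiment(SimulationConfig(nTranscripts = 150, seed = 9L))
    x <- computeRpkm(sim)
    lhs <- colSums(rpkm(x) * (transcriptLengths(x) / 1e3))
    rhs <- colSums(assay(x, "counts")) / (librarySizes(x) / 1e6)
    expect_equal(lhs, rhs, tolerance = 1e-12)
})
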