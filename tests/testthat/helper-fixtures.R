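# fixtures built in code

# TcExperiment straight from an RPKM matrix with standard sample columns
make_rpkm_tc <- function(m) {
    stopifnot(identical(sort(colnames(m)), sort(SAMPLES)))
    m <- m[, SAMPLES, drop = FALSE]
    TcExperiment(rpkm = m,
                 tissue = rep(c("EP", "SP"), each = 4),
                 timepoint = rep(c(0, 3, 9, 24), 2))
}

# paired up/down FoldChangeTables from a linear up-ratio matrix with
# columns EP_3h, EP_9h, EP_24h, SP_3h, SP_9h, SP_24h (NA = sentinel)
make_fc_pair <- function(up, expressed = NULL) {
    list(up = FoldChangeTable(up, expressed, direction = "up_ratio"),
         down = FoldChangeTable(1 / up, expressed, direction = "down_ratio"))
}

fc_cols <- c("EP_3h", "EP_9h", "EP_24h", "SP_3h", "SP_9h", "SP_24h")

# random raw RPKM matrices exercising sentinels, gate and floor boundaries
random_rpkm_matrix <- function(n, seed) {
    set.seed(seed)
    m <- matrix(2^stats::rnorm(n * 8, mean = 2, sd = 4), nrow = n,
                dimnames = list(sprintf("r_%04d", seq_len(n)), SAMPLES))
    # silence some tissue blocks and depress some rows below the gate
    sil <- stats::runif(n)
    m[sil < 0.1, 1:4] <- stats::runif(sum(sil < 0.1) * 4, 0, 0.45)
    m[sil > 0.9, 5:8] <- stats::runif(sum(sil > 0.9) * 4, 0, 0.45)
    low <- stats::runif(n) < 0.05
    m[low, ] <- stats::runif(sum(low) * 8, 0, 0.45)
    m
}

# published enhanced-table rows: EP and SP linear 3-h fold changes and
# the printed difference column
enhanced_table_rows <- data.frame(
    id = c("11848", "19283", "10055", "12104", "7382", "7356", "2088",
           "10876", "11312", "15437", "3427", "20862", "5690", "2809",
           "10215", "18475", "10039", "1309", "19791", "18219"),
    ep = c(378, 332, 278, 191, 131, 121, 81, 78, 73, 69, 64, 48, 46, 46,
           42, 31, 30, 29, 27, 27),
    sp = c(1, 7, 1, 1, 4, 3, 2, 2, 12, 1, 1, 2, 2, 2, 2, 2, 1, 2, 2, 2),
    diff = c(377, 325, 277, 190, 127, 118, 79, 76, 61, 68, 63, 46, 44, 44,
             40, 29, 29, 27, 25, 25),
    stringsAsFactors = FALSE)

# replicated Ct table over the EP/SP x 0/3 h grid for given true
# normalized expressions (efficiency-2 geometry, reference flat)
make_ct_table <- function(genes_fc, reps = 3, ref_ct = 20, base_ct = 28) {
    grid <- expand.grid(tissue = c("EP", "SP"), timepoint = c(0, 3),
                        stringsAsFactors = FALSE)
    rows <- list()
    for (g in names(genes_fc)) {
        for (i in seq_len(nrow(grid))) {
            ti <- grid$tissue[i]; tp <- grid$timepoint[i]
            expr <- genes_fc[[g]][[paste0(ti, "_", tp)]]
            ct <- base_ct - log2(expr)
            rows[[length(rows) + 1]] <- data.frame(
                gene = g, tissue = ti, timepoint = tp,
                replicate = seq_len(reps), ct = ct)
        }
        for (i in seq_len(nrow(grid)))
            rows[[length(rows) + 1]] <- data.frame(
                gene = "VfEFalpha", tissue = grid$tissue[i],
                timepoint = grid$timepoint[i],
                replicate = seq_len(reps), ct = ref_ct)
    }
    do.call(rbind, rows)
}
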