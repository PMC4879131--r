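# Independent straight-line oracles: scalar loops, no shared code with
# the package implementation.

SAMPLES <- as.vector(outer(c(0, 3, 9, 24), c("EP", "SP"),
                           function(tp, ti) sprintf("%s_%gh", ti, tp)))

# brute-force scalar RPKM
oracle_rpkm <- function(counts, lengths_bp, lib_sizes) {
    out <- counts * NA_real_
    for (i in seq_len(nrow(counts)))
        for (j in seq_len(ncol(counts)))
            out[i, j] <- counts[i, j] * 1e9 /
                (as.numeric(lengths_bp[i]) * as.numeric(lib_sizes[j]))
    out
}

# per-transcript re-evaluation of the whole rule set on a raw RPKM matrix
# (columns named <tissue>_<timepoint>h)
oracle_classify_all <- function(rpkm_raw, floor = 0.1, gate = 0.5,
                                fthr = 5, ceil = 2, dthr = 25, dtp = 3,
                                tps = c(3, 9, 24)) {
    out <- character(nrow(rpkm_raw))
    names(out) <- rownames(rpkm_raw)
    for (id in rownames(rpkm_raw)) {
        raw <- rpkm_raw[id, ]
        if (all(raw < gate)) { out[id] <- "not_expressed"; next }
        ep_exp <- FALSE; sp_exp <- FALSE
        for (tp in c(0, tps)) {
            if (raw[sprintf("EP_%gh", tp)] >= gate) ep_exp <- TRUE
            if (raw[sprintf("SP_%gh", tp)] >= gate) sp_exp <- TRUE
        }
        v <- pmax(raw, floor)
        ratio <- function(ti, tp) v[sprintf("%s_%gh", ti, tp)] /
            v[sprintf("%s_0h", ti)]
        focal_up <- FALSE; focal_down <- FALSE; ref_elim <- FALSE
        for (tp in tps) {
            if (ep_exp && ratio("EP", tp) >= fthr) focal_up <- TRUE
            if (ep_exp && 1 / ratio("EP", tp) >= fthr) focal_down <- TRUE
            if (sp_exp) {
                r <- ratio("SP", tp)
                if (r >= ceil || 1 / r >= ceil) ref_elim <- TRUE
            }
        }
        if (focal_up && !ref_elim) { out[id] <- "specific_up"; next }
        if (focal_down && !ref_elim) { out[id] <- "specific_down"; next }
        if (ep_exp) {
            ref_up <- if (sp_exp) ratio("SP", dtp) else 1
            ref_down <- if (sp_exp) 1 / ratio("SP", dtp) else 1
            if (ratio("EP", dtp) - ref_up >= dthr) {
                out[id] <- "enhanced_up"; next
            }
            if (1 / ratio("EP", dtp) - ref_down >= dthr) {
                out[id] <- "enhanced_down"; next
            }
        }
        out[id] <- "unclassified"
    }
    out
}

# the two specific filter sets without the up-before-down precedence of
# the final labelling (classifySpecific reports both outcomes)
oracle_specific_sets <- function(rpkm_raw, floor = 0.1, gate = 0.5,
                                 fthr = 5, ceil = 2, tps = c(3, 9, 24)) {
    up <- character(0); down <- character(0)
    for (id in rownames(rpkm_raw)) {
        raw <- rpkm_raw[id, ]
        ep_cols <- sprintf("EP_%gh", c(0, tps))
        sp_cols <- sprintf("SP_%gh", c(0, tps))
        ep_exp <- any(raw[ep_cols] >= gate)
        sp_exp <- any(raw[sp_cols] >= gate)
        if (!ep_exp && !sp_exp) next
        v <- pmax(raw, floor)
        f_up <- FALSE; f_down <- FALSE; elim <- FALSE
        for (tp in tps) {
            r_ep <- v[sprintf("EP_%gh", tp)] / v["EP_0h"]
            if (ep_exp && r_ep >= fthr) f_up <- TRUE
            if (ep_exp && 1 / r_ep >= fthr) f_down <- TRUE
            r_sp <- v[sprintf("SP_%gh", tp)] / v["SP_0h"]
            if (sp_exp && (r_sp >= ceil || 1 / r_sp >= ceil)) elim <- TRUE
        }
        if (f_up && !elim) up <- c(up, id)
        if (f_down && !elim) down <- c(down, id)
    }
    list(up = up, down = down)
}

# delta-delta by direct enumeration of replicate means
oracle_ddct <- function(ct, ref_gene, gene, tissue, tp,
                        cal_tissue = "EP", cal_tp = 0, eff = 2) {
    m <- function(g, ti, t)
        mean(ct$ct[ct$gene == g & ct$tissue == ti & ct$timepoint == t])
    dct <- m(gene, tissue, tp) - m(ref_gene, tissue, tp)
    dct_cal <- m(gene, cal_tissue, cal_tp) - m(ref_gene, cal_tissue, cal_tp)
    eff^(-(dct - dct_cal))
}
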