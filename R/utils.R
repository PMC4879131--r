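.sampleLabel <- function(tissue, timepoint) sprintf("%s_%gh", tissue, timepoint)

# Largest-remainder (Hamilton) apportionment: exact integer quotas whose
# sum is n, ties broken by position. Used so planted category counts are
# deterministic rather than multinomial.
.largestRemainderQuota <- function(n, proportions) {
    exact <- proportions * n
    base <- floor(exact)
    short <- n - sum(base)
    if (short > 0) {
        rem <- exact - base
        ord <- order(rem, decreasing = TRUE)
        base[ord[seq_len(short)]] <- base[ord[seq_len(short)]] + 1
    }
    stats::setNames(as.integer(base), names(proportions))
}

.stopIfNot <- function(ok, ...) if (!ok) stop(sprintf(...), call. = FALSE)
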