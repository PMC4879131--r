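# epiTC

Threshold-based classification of tissue-specific and tissue-enhanced
transcript regulation in a two-tissue induction time course, with a
planted-truth synthetic-data generator and ΔΔCt quantification of
validation RT-qPCR data.

## The scientific problem

When *Vicia faba* cotyledons are cultured, their adaxial epidermal (EP)
cells *trans*-differentiate into transfer cells while the adjacent
storage parenchyma (SP) does not. Transcripts whose expression changes
specifically in the epidermis across the induction time course
(0, 3, 9, 24 h) are therefore candidates for regulating transfer-cell
development. This package implements the RPKM-based screen used for
that contrast, for anyone who wants to run, audit or benchmark the same
classification on their own two-condition time-course data.

The procedure, per transcript:

1. **RPKM** from read counts: `rpkm = counts × 10⁹ / (length_bp ×
   library_size)`.
2. **Floor**: RPKM < 0.1 is raised to 0.1 so fold-change denominators
   are never near zero.
3. **Expression gate**: RPKM ≥ 0.5 in at least one timepoint of a
   tissue ⇒ expressed in that tissue; below 0.5 everywhere ⇒
   `not_expressed`, removed.
4. **Fold changes** of floored RPKM at 3, 9, 24 h vs the 0-h baseline,
   per tissue, as up-ratios (t/0 h) and down-ratios (0 h/t).
5. **Specific filter (two steps)**: focal fold change ≥ 5 (log₂ 5 =
   2.3) at ≥ 1 timepoint, then elimination of transcripts whose
   reference tissue changes ≥ 2-fold (log₂ 2 = 1, either direction) at
   any timepoint ⇒ `specific_up` / `specific_down`. The exploratory
   variant of the same filter is the parameterization 2 / 1.2.
6. **Enhanced filter** on everything excluded from step 5: linear
   focal-minus-reference fold-change difference at 3 h ≥ 25 ⇒
   `enhanced_up` / `enhanced_down` (a silent reference tissue counts as
   fold change 1).

Everything else is `unclassified`. The published screen's headline
counts (444 epidermal-specific up, 172 down, 198 epidermal-enhanced up,
13 down) come from the deposited raw reads (SRA SRP071162); this
package reproduces the procedure and validates it structurally on
synthetic data with planted categories.

## Worked example

```r
library(epiTC)

sim <- simulateTcExperiment(SimulationConfig(nTranscripts = 1000, seed = 7))
res <- classifyAll(sim)
res
#> ClassificationResult: 1000 transcripts
#>   specific_up    100
#>   specific_down  50
#>   enhanced_up    49
#>   enhanced_down  9
#>   unclassified   707
#>   not_expressed  85
#> ClassifierParams: EP vs SP; specific >= 5-fold focal, < 2-fold reference;
#>   enhanced diff >= 25 at 3 h; timepoints {3,9,24} h

recoveryRate(res, syntheticTruth(sim))$overall
#> [1] 0.983
```

The generator planted exactly 100/50/50/10/690/100 transcripts in the
six categories (quotas are allocated deterministically); at the default
negative-binomial dispersion the classifier recovers 98.3% of them, the
misses sitting at the gate and threshold boundaries (e.g. weakly
expressed transcripts drifting across the 0.5 RPKM gate). With
`nbDispersion = Inf` (noise-free counts) recovery is exactly 100%.

File-based runs go through the pipeline driver:

```r
runPipeline(list(simulation = list(n_transcripts = 1000, seed = 7),
                 output_dir = "run1"))
```

which writes the RPKM matrix, both fold-change tables, the
classification table, one publication-style report per category (focal
log₂ fold changes with the reference tissue in brackets, `-` for
not-expressed sentinels) and a JSON run summary. `readCountTsv` /
`readRpkmTsv` accept external count or RPKM matrices in the same TSV
layout, and `QpcrExperiment` + `normalizedExpression` implement the
ΔΔCt quantification (reference gene, calibrator sample EP 0 h,
`efficiency^(−ΔΔCt)`) used for RT-qPCR cross-validation, with
`concordanceReport` comparing direction calls across platforms.

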