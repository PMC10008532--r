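# spikeline

Analysis of 16S rRNA amplicon experiments that use an **in-situ mock
community (MC) spike-in** — a defined pair of bacteria added to each
sample *before* DNA extraction — as a positive control and internal
ruler. The package is aimed at microbial ecologists who already have a
denoised sequence-variant (SV) count table and want to (1) find and
remove the spike-in variants, (2) quality-control the spike, (3) turn
relative counts into absolute 16S gene-copy estimates, and (4) run the
standard diversity statistics on the recovered sample communities.

## What it computes

The default spike is the commercial two-taxon pair: gram-negative
*Imtechella halotolerans* (6.0×10⁷ 16S copies per dose) and
gram-positive *Allobacillus halotolerans* (1.4×10⁸ per dose), dosed
copy ratio 6.0×10⁷ / 1.4×10⁸ = 0.43.

* **MC-SV detection** — every SV is aligned to the reference 16S
  sequences; assignments at ≥ 97% identity are split into one
  *primary* SV per taxon (most abundant, 100% identity) and
  *secondary* variants.
* **Spike QC** — per-library MC read fraction checked against the
  recommended 1–10% band, and the gram-negative : gram-positive read
  ratio as a DNA-extraction bias diagnostic (observed/expected ratio =
  the under-extraction factor of the gram-positive taxon).
* **Absolute quantification** — per library *j*,

  ```
  GCN_j = (N_j / r_j) * D_j
  ```

  where `N_j` is the total read count, `r_j` the reads of the
  gram-negative reference taxon, and `D_j` its spiked copy number
  (dose fraction × 6.0×10⁷). Sample-SV counts are rescaled to copy
  scale by `(SV_ij / N_j) * GCN_j * (1 - r_j / N_j)`.
* **Outlier flagging and dose recommendation** — replicate-group
  copy-number outliers (> 2.5-fold from the group median), and the
  dose fraction that puts the spike inside a target read-share band:
  `d = f/(1-f) * S / (C_neg + g * C_pos)`.
* **Diversity stack** — CLR normalization (offset 1), seeded
  rarefaction to 99% of the minimum depth, alpha diversity (S, Shannon
  H, inverse Simpson D₂), Hill-number rarefaction curves with
  bootstrap bands, Euclidean/Bray–Curtis distances, PCoA, and a
  from-first-principles sequential PERMANOVA.
* **Synthetic experiments** — `simulate_experiment()` generates spiked
  communities with known ground truth (log-normal pools, per-dose
  copy inputs, gram-extraction bias, multinomial read sampling,
  low-frequency secondary spike variants), so the whole stack is
  testable without sequencing data.

## Worked example

```r
library(spikeline)

# a simulated spiked experiment: 3 fecal pools x {50, 1.25} mg
# x {no, 0.0125, 0.5} dose, 2 replicates, 30000 reads per library
cfg <- simulation_config(design = bovine_design(n_replicates = 2),
                         seed = 42)
sim <- simulate_experiment(cfg)
sim$table
#> count_table: 36 samples x 307 SVs
#>   total reads per sample: 30000 .. 30000

asg <- assign_mc_svs(sim$sequences, sim$refs, sim$table)
head(asg$assignments)
#>     sv_id                     taxon identity    status reads
#> 1 sv_0301   Imtechella halotolerans    100.0   primary 56772
#> 2 sv_0302   Imtechella halotolerans     99.6 secondary   605
#> 3 sv_0303   Imtechella halotolerans     99.2 secondary   583
#> 4 sv_0304 Allobacillus halotolerans    100.0   primary 43730
#> 5 sv_0305 Allobacillus halotolerans     99.6 secondary   450
#> 6 sv_0306 Allobacillus halotolerans     99.2 secondary   457
```

Each taxon yields one primary SV (identical to its reference) plus
low-frequency secondaries about 100× rarer — the expected spike-in
signature. QC compares the taxon read ratio with the dosed 0.43:

```r
qc <- mc_qc(sim$table, asg, sim$refs, metadata = sim$metadata)
qc$summary[c("expected_ratio", "mean_ratio", "bias_factor")]
#> $expected_ratio
#> [1] 0.4285714
#> $mean_ratio
#> [1] 1.453419
#> $bias_factor
#> [1] 3.391312
```

The observed ratio exceeds 0.43 about 3.4-fold: the gram-positive
taxon was under-extracted (the simulation plants an extraction
efficiency of 0.336, and the diagnostic recovers ≈ 1/0.336). Absolute
copy estimates then follow from the gram-negative spike share:

```r
gcn <- estimate_gcn(sim$table, asg, sim$metadata, sim$refs)
head(subset(gcn, flag == "ok")[, c("sample_id", "ih_reads", "gcn")], 4)
#>                     sample_id ih_reads        gcn
#> BP1_HBM_LMC_r1 BP1_HBM_LMC_r1        7 3214285714
#> BP1_HBM_LMC_r2 BP1_HBM_LMC_r2       13 1730769231
#> BP1_HBM_HMC_r1 BP1_HBM_HMC_r1      439 2050113895
#> BP1_HBM_HMC_r2 BP1_HBM_HMC_r2      469 1918976546
```

A 50 mg sample at 4×10⁷ copies/mg truly carries 2×10⁹ copies: the
high-dose libraries (hundreds of reference reads) land within a few
percent, while the low-dose libraries (7–13 reference reads) scatter —
which is exactly why doses should put the spike at 1–10% of reads:

```r
recommend_dose(5e7, sim$refs, gram_pos_efficiency = 0.336)
#>   sample_copies target_fraction dose_fraction
#> 1         5e+07            0.01   0.004718334
#> 2         5e+07            0.10   0.051901677
```

`run_pipeline()` chains all stages (detect → qc → quantify →
transform → diversity) from a config list or YAML file and writes the
result tables, figures and a log; `strip_mc()`, `clr_normalize()`,
`rarefy_table()`, `distance_matrix()`, `pcoa()`, `permanova()` and
`compare_alpha()` expose the individual steps.

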