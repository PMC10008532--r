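---
title: "Mock-community spike-ins as in-situ controls: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mock-community spike-ins as in-situ controls: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spikeline)
```

## The problem

Amplicon surveys of the 16S rRNA gene report *relative* composition:
library sizes are arbitrary, so two samples with very different
microbial loads can look identical. Adding a defined mock community
(MC) of known cell numbers to each sample *before* DNA extraction
turns the experiment into one with an internal ruler. After denoising,
the spike-in appears as a handful of sequence variants (MC-SVs) whose
read share reflects how many 16S copies the sample itself contributed.
That single number supports several things at once: a per-library
estimate of absolute 16S gene-copy number, a DNA-extraction bias
diagnostic, detection of anomalous libraries, and a rule for choosing
spike doses for new sample types.

`spikeline` implements this workflow downstream of denoising: it
consumes an SV count table, SV sequences and per-sample metadata, and
does not touch fastq files, denoising or general taxonomy assignment.

## The spike-in model

The default reference set is the commercial two-taxon pair:
gram-negative *Imtechella halotolerans* (one dose carries
$6.0\times10^{7}$ 16S copies from $2\times10^{7}$ cells, i.e. 3 copies
per genome) and gram-positive *Allobacillus halotolerans*
($1.4\times10^{8}$ copies from $2\times10^{7}$ cells, 7 per genome).
The dosed copy ratio is therefore $6.0\times10^{7} / 1.4\times10^{8}
= 0.43$.

**MC-SV detection.** Every SV is aligned to every reference sequence
(whole SV against the best-matching reference substring; identity =
matches / aligned columns, reference end gaps free) and assigned to
the best reference at $\geq$ 97% identity. The threshold is a
compromise: observed MC-SV clusters sit at 98--100% identity to their
references, while unrelated sample taxa score far lower; 97% leaves
margin for sequencing error without capturing sample taxa. Within a
taxon, the assigned SV that is both most abundant *and* at 100%
identity is the *primary* MC-SV; all others are *secondary*
(intragenomic 16S variants and/or residual sequencing errors --- the
data cannot distinguish these, and the package does not try).
Abundance ties break by lexicographic SV id; if the most abundant
assigned SV is below 100% identity it is flagged rather than promoted.

We align the whole SV rather than scoring free-end-gap overlap of both
sequences: with both ends free, two unrelated sequences can share a
short perfect overlap and score 100% identity, so requiring the full
SV to take part makes the identity threshold meaningful.

**Copy-number estimation.** With $N_j$ the total quality-filtered
reads of library $j$, $r_j$ the reads assigned to the reference taxon
(primary plus secondary SVs --- all of them originate from the spiked
cells), and $D_j$ the number of reference-taxon copies spiked
($\mathrm{dose\ fraction}_j \times 6.0\times10^{7}$), the total 16S
copy number of the library is estimated as

$$\widehat{GCN}_j = \frac{N_j}{r_j} \, D_j.$$

The *gram-negative* taxon is the reference by default: the estimator
divides by its reads, so its copy input is what makes the units
cancel, and its extraction is unbiased. (Some studies use the
gram-positive taxon instead; `estimate_gcn(reference_taxon = )`
supports that, but no reconciliation rule between the two choices is
defined.) The estimator is undefined for unspiked libraries and
flagged when the dose is positive but no reference reads were
observed.

**Absolute-scale transformation.** Sample-SV counts are rescaled to
copy scale by

$$\mathrm{norm}_{ij} = \frac{SV_{ij}}{N_j}\,\widehat{GCN}_j
  \left(1 - \frac{r_j}{N_j}\right),$$

where $N_j$ is the *pre-stripping* total (the spike reads are part of
the denominator; only the reference-taxon reads are discounted by the
last factor, which acts as the sample microbial-load indicator). The
transform is a per-sample constant, so within-sample proportions among
sample SVs are preserved exactly.

**Extraction-bias diagnostic.** Both taxa are dosed in a fixed copy
ratio, so the observed gram-negative : gram-positive read ratio should
equal 0.43. A systematic excess --- e.g. a mean observed ratio of 1.28
--- implies the gram-positive taxon was under-extracted by a factor
$0.43 / 1.28 \approx 0.336$, the `bias_factor` reported by
[gram_ratio()] and [mc_qc()].

**Dose recommendation.** The expected spike read share at dose $d$ is
$f(d) = E(d) / (E(d) + S)$ with $E(d) = d\,(C_{neg} + g\,C_{pos})$ and
$S$ the sample's copy pool; inverting gives
$d = \frac{f}{1-f}\,\frac{S}{C_{neg} + g\,C_{pos}}$. The default
target band of 1--10% of library reads keeps the spike large enough to
quantify and small enough not to compete with sample taxa for reads.

**Outlier flagging.** Within a replicate group, a library whose
estimated copies deviate from the group median by more than 2.5-fold
(on the $\log_2$ scale, in either direction) is flagged. The 2.5-fold
default is our quantification of what is visually called an outlier in
replicate dot plots; reported outlier magnitudes of roughly 9.8-fold
and 3.8-fold both clear it. The rule is invariant to rescaling all of
a group's estimates. Note the estimator measures *total* (sample +
spike) copies, so a sample-pool outlier's apparent fold shrinks when
the spike is a non-trivial share of the pool.

## The synthetic-data generator

`simulate_experiment()` builds experiments with known ground truth so
that every downstream stage is testable without sequencing data. Per
sample:

1. a **copy pool** is assembled: sample taxa get `biomass_mass`
   $\times$ `copies_per_mg` $\times$ `outlier_fold` copies, split by
   log-normal proportions drawn once per pool (technical replicates
   optionally perturbed by a multiplicative log-normal factor,
   `replicate_sigma`); the MC taxa get `dose_fraction` $\times$
   copies-per-dose, with the gram-positive pool multiplied by
   `gram_pos_efficiency`;
2. **reads** are drawn from a single multinomial over all pools at a
   fixed depth, so per-sample read sums are exact and each pool's
   expected read share equals its effective copy share;
3. each MC taxon's reads are thinned binomially into one primary SV
   (the reference sequence) and a few secondary SVs (the reference
   with 1--3 point substitutions, identity $\geq$ 98.8%), each
   receiving on average `secondary_sv_rate` of the taxon's reads.
   Thinning at read level is agnostic about whether secondary variants
   are biological or error-derived, matching both interpretations.

Defaults are the study conditions the package models: three fecal
pools, 50 / 1.25 mg input masses, dose fractions 0 / 0.0125 / 0.5,
30000 reads per library, four replicates, 300 taxa with
log-normal(0, 2) proportions, secondary variants at $10^{-2}$ of the
primary (about 100-fold lower), and two (for the gram-negative) or
three (for the gram-positive) secondary variants, matching the
reported V4 cluster sizes. Two defaults are our own calibration, set
once:

* `gram_pos_efficiency = 0.336`, the value implied by an observed mean
  read ratio of 1.28 against the expected 0.43 --- with it, the
  simulator's expected read ratio is $0.43/0.336 = 1.28$;
* `copies_per_mg = 4\times10^{7}` (i.e. $4\times10^{10}$ 16S copies
  per gram of feces, a plausible gut-microbiome load), chosen so the
  design's MC read fractions span roughly 0.05--50% from the
  high-biomass/low-dose corner to the low-biomass/high-dose corner,
  the reported dynamic range.

The dose fraction 0.0125 follows the "1/40th of half a dose"
derivation; tables that print it as 0.012 are stored as supplied and
not reconciled.

What the generator does **not** emulate: PCR-cycle kinetics and
primer-bias chimeras, overdispersion beyond multinomial sampling,
taxon-specific amplification efficiency for sample taxa (extraction
bias is modelled only through the MC pair, as only the pair quantifies
it), and read-level errors outside the fixed secondary variants.
Consequences worth knowing: conditional on the post-stripping read
count, sample-taxon composition is exactly multinomial whatever the
spike share --- so after rarefying all libraries to a common depth the
spike leaves *no* compositional trace. Real libraries keep some
distortion through amplification competition. The replicate-distortion
property is therefore checked at a fixed total read budget (the spike
consumes reads), which is the mechanism the generator does model.

## The diversity stack

* **CLR**: $x \mapsto \ln(x + 1) - \overline{\ln(x + 1)}$ per sample
  (offset 1 handles zeros); rows are centred exactly. Euclidean
  distance on CLR matrices is the Aitchison geometry.
* **Rarefaction**: subsampling without replacement, one seeded draw
  per sample; the default depth is 99% of the minimum library size
  rounded down (e.g. a 10,195-read minimum rarefies to 10,093).
* **Alpha diversity**: richness $S$, Shannon $H$ (natural log) and
  inverse Simpson $D_2$; these are Hill numbers of order 0,
  $e^{H}$ = order 1 and $D_2$ = order 2. The pipeline computes alpha
  on rarefied counts (whether to rarefy first is genuinely open in
  practice; `alpha_diversity()` itself accepts any table, so raw-count
  alpha is one call away).
* **Rarefaction curves** (`re_curves()`): Hill numbers on
  hypergeometric subsamples over a size grid, 200 bootstrap replicates
  by default, percentile 95% bands. Draws are nested within a
  replicate (one shuffled read vector, truncated at each grid size) so
  the order-0 curve is non-decreasing replicate by replicate.
  Extrapolation beyond the observed depth is out of scope.
* **PCoA**: eigendecomposition of the Gower-centred matrix
  $-\tfrac12 J D^2 J$; coordinates for positive eigenvalues only;
  negative eigenvalues (possible for Bray--Curtis) are reported
  uncorrected.
* **PERMANOVA** (`permanova()`): sequential (Type-I) partitioning of
  the distance sum of squares in user-given term order --- pool
  identifier before the MC:biomass ratio in the pipeline default ---
  pseudo-$F$ per term, significance by seeded label permutation with
  $p = (1 + \#\{F^* \geq F\}) / (1 + n_{perm})$, 999 permutations by
  default. An explicit permutation matrix can be supplied, which makes
  exact small-sample enumeration possible. Implemented from first
  principles; `vegan::adonis2` serves as an independent cross-check in
  the test suite, not as the implementation.
* **Rank-sum comparisons** (`compare_alpha()`): exact null
  distribution for small tie-free groups, normal approximation with
  tie correction otherwise.
* The **MC:biomass ratio** covariate is computed from metadata as
  (dose / mass) normalized to the high-biomass/high-dose combination,
  so low-biomass/high-dose samples get 40 and high-biomass/low-dose
  samples 0.025. Published tables sometimes print these two values the
  other way round; the package always derives the ratio from the
  metadata arithmetic rather than hard-coding printed values.

## Numerical choices and degenerate inputs

Identity is computed with match +1 / mismatch $-1$, gap open 8, gap
extend 2; a primary call requires identity $\geq 100 - 10^{-6}$ to
absorb floating-point noise. Constant columns are dropped (with a
warning) before the MC-SV PCA; an all-constant matrix returns zero
scores. Zero-read samples yield missing QC fractions; zero
gram-positive reads make the ratio undefined and are flagged rather
than propagated as infinities. PERMANOVA terms that add no model rank
(constant or confounded) raise an error naming the term. All
randomized operations (simulation, rarefaction, bootstrap,
permutation) take explicit seeds and are reproducible; the pipeline
writes byte-identical tables given the same config and seed.

## Test problem sizes

The statistical test suite runs the estimator-recovery check on 200
libraries at depth $10^{5}$ with spike shares spread over the 1--10%
band (median relative error must stay within 5%), the gram-bias
recovery on the same libraries (3 Monte-Carlo standard errors), the
PERMANOVA null calibration on 500 simulated datasets of 12 samples
with 199 permutations each (empirical size 0.05 $\pm$ 0.02 and
uniformity of the p-value distribution), and the replicate-distortion
property with 30 technical replicates per spike share
$\{0.1\%, 5\%, 30\%, 50\%\}$ at depth $2\times10^{4}$. Exhaustive
enumeration (all 720 label permutations; all 20 rank splits) anchors
the small-sample p-values, and the CLR / Hill / PCoA identities are
checked to $10^{-10}$.

## Known limitations

* The identity threshold cannot separate true intragenomic 16S
  variants from systematic sequencing errors; secondary MC-SVs are a
  single bucket.
* Copy estimates are *gene* copies, not cell counts: 16S copy number
  varies within and between taxa.
* Libraries dosed far below the 1--10% band carry only a handful of
  reference reads, so their copy estimates are shot-noise limited;
  outliers in such groups may not be recoverable (the acceptance
  script reports this honestly for the low-dose planted outlier).
* Because pools are drawn independently, simulated between-pool
  differences are larger than real fecal pools would show; PERMANOVA
  pool $R^2$ on simulated data is correspondingly high and should not
  be read as an empirical claim about real communities.
* UniFrac (needs a phylogeny), mixed-effects models of mapped-read
  percentages, ANOVA/Tukey group letters and rarefaction
  *extrapolation* are out of scope.
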