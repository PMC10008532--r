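random_dna <- function(n, length) {
  vapply(seq_len(n), function(i)
    paste(sample(c("A", "C", "G", "T"), length, replace = TRUE),
          collapse = ""),
    character(1))
}

mutate_sequence <- function(seq, n_mut) {
  bases <- strsplit(seq, "")[[1]]
  pos <- sample(length(bases), n_mut)
  for (p in pos) {
    bases[p] <- sample(setdiff(c("A", "C", "G", "T"), bases[p]), 1)
  }
  paste(bases, collapse = "")
}

#' Factorial spiked-sample design
#'
#' Builds a per-sample design table mirroring a pooled-feces spike-in
#' experiment: replicated combinations of sample pool, input biomass
#' (high: 50 mg, low: 1.25 mg) and mock-community dose (none, low:
#' 0.0125 of a dose, high: 0.5 of a dose). Sample ids follow the
#' `<pool>_<biomass>_<dose>_r<k>` convention, e.g. `BP1_HBM_HMC_r1`.
#'
#' @param n_replicates technical replicates per combination.
#' @param pools pool labels.
#' @param biomass named vector of input masses in mg.
#' @param dose named vector of dose fractions (fraction of one
#'   manufacturer dose; 0 = no MC).
#' @return data.frame with columns `sample_id`, `pool_id`,
#'   `biomass_mass`, `mc_dose_fraction`, `replicate_label`, `condition`.
#' @export
bovine_design <- function(n_replicates = 4,
                          pools = c("BP1", "BP2", "BP3"),
                          biomass = c(HBM = 50, LBM = 1.25),
                          dose = c(nMC = 0, LMC = 0.0125, HMC = 0.5)) {
  grid <- expand.grid(replicate = seq_len(n_replicates),
                      dose = names(dose), biomass = names(biomass),
                      pool = pools, stringsAsFactors = FALSE)
  data.frame(
    sample_id = sprintf("%s_%s_%s_r%d", grid$pool, grid$biomass,
                        grid$dose, grid$replicate),
    pool_id = grid$pool,
    biomass_mass = unname(biomass[grid$biomass]),
    mc_dose_fraction = unname(dose[grid$dose]),
    replicate_label = sprintf("r%d", grid$replicate),
    condition = sprintf("%s-%s", grid$biomass, grid$dose),
    stringsAsFactors = FALSE)
}

#' Configure a synthetic spike-in experiment
#'
#' Collects all generator parameters. Defaults emulate the bovine-feces
#' spike-in study design: three fecal pools with log-normal
#' rank-abundance communities, 50 mg / 1.25 mg input masses, dose
#' fractions 0 / 0.0125 / 0.5 of a manufacturer dose carrying 6.0e7
#' (gram-negative) and 1.4e8 (gram-positive) 16S copies, a gram-positive
#' extraction efficiency of 0.336 (the value implied by an observed
#' gram-negative:gram-positive read ratio of 1.28 against an expected
#' copy ratio of 0.43), fixed sequencing depth of 30000 reads, and
#' low-frequency secondary MC variants at about 1/100 of the primary.
#'
#' @param design data.frame as from [bovine_design()] (one row per
#'   sample with `sample_id`, `pool_id`, `biomass_mass`,
#'   `mc_dose_fraction`).
#' @param n_taxa number of sample (non-MC) taxa.
#' @param lognormal_mu,lognormal_sigma parameters of the log-normal
#'   community rank-abundance distribution (per pool).
#' @param replicate_sigma log-normal sd of per-replicate multiplicative
#'   noise on taxon pools (0 = exact technical replicates).
#' @param copies_per_mg 16S gene copies per mg of sample material.
#' @param copies_per_dose_ih,copies_per_dose_ah 16S copies per dose for
#'   the gram-negative and gram-positive spike-in taxon.
#' @param cells_per_dose cells per dose per taxon.
#' @param gram_pos_efficiency relative DNA-extraction efficiency of
#'   gram-positive taxa, in (0, 1].
#' @param depth reads per sample (exact, fixed).
#' @param secondary_sv_rate expected secondary:primary MC read ratio.
#' @param n_secondary_ih,n_secondary_ah number of secondary sequence
#'   variants per MC taxon.
#' @param outlier_fold named per-sample multiplier on the true sample
#'   copy pool (1 = no outlier); see [inject_outlier()].
#' @param amplicon_length length of simulated SV sequences (nt).
#' @param seed integer seed; the whole experiment is reproducible.
#' @return a list of class `simulation_config`.
#' @export
simulation_config <- function(design = bovine_design(),
                              n_taxa = 300,
                              lognormal_mu = 0,
                              lognormal_sigma = 2,
                              replicate_sigma = 0.1,
                              copies_per_mg = 4e7,
                              copies_per_dose_ih = 6.0e7,
                              copies_per_dose_ah = 1.4e8,
                              cells_per_dose = 2e7,
                              gram_pos_efficiency = 0.336,
                              depth = 30000,
                              secondary_sv_rate = 0.01,
                              n_secondary_ih = 2,
                              n_secondary_ah = 3,
                              outlier_fold = NULL,
                              amplicon_length = 250,
                              seed = 1) {
  stopifnot(is.data.frame(design),
            all(c("sample_id", "biomass_mass", "mc_dose_fraction") %in%
                  names(design)))
  if (anyDuplicated(design$sample_id))
    stop("duplicate sample ids in design", call. = FALSE)
  if (n_taxa < 1) stop("n_taxa must be >= 1", call. = FALSE)
  if (depth < 1) stop("depth must be >= 1", call. = FALSE)
  if (!(gram_pos_efficiency > 0 && gram_pos_efficiency <= 1))
    stop("gram_pos_efficiency must be in (0, 1]", call. = FALSE)
  if (secondary_sv_rate < 0 || copies_per_mg < 0 ||
      copies_per_dose_ih < 0 || copies_per_dose_ah < 0)
    stop("rates and copy numbers must be non-negative", call. = FALSE)
  if (any(design$biomass_mass < 0) || any(design$mc_dose_fraction < 0))
    stop("biomass_mass and mc_dose_fraction must be non-negative",
         call. = FALSE)
  if (is.null(outlier_fold))
    outlier_fold <- setNames(rep(1, nrow(design)), design$sample_id)
  if (is.null(names(outlier_fold)) ||
      !all(names(outlier_fold) %in% design$sample_id))
    stop("outlier_fold must be named by sample_id", call. = FALSE)
  fold <- setNames(rep(1, nrow(design)), design$sample_id)
  fold[names(outlier_fold)] <- outlier_fold
  if (any(fold <= 0)) stop("outlier_fold must be > 0", call. = FALSE)
  structure(list(design = design, n_taxa = n_taxa,
                 lognormal_mu = lognormal_mu,
                 lognormal_sigma = lognormal_sigma,
                 replicate_sigma = replicate_sigma,
                 copies_per_mg = copies_per_mg,
                 copies_per_dose_ih = copies_per_dose_ih,
                 copies_per_dose_ah = copies_per_dose_ah,
                 cells_per_dose = cells_per_dose,
                 gram_pos_efficiency = gram_pos_efficiency,
                 depth = depth,
                 secondary_sv_rate = secondary_sv_rate,
                 n_secondary_ih = n_secondary_ih,
                 n_secondary_ah = n_secondary_ah,
                 outlier_fold = fold,
                 amplicon_length = amplicon_length,
                 seed = seed),
            class = "simulation_config")
}

#' Mark a sample as a copy-number outlier
#'
#' Multiplies a sample's true sample-taxon copy pool by `fold` (applied
#' at simulation time), e.g. `fold = 1/9.84` for a library with 9.84
#' times fewer copies than its replicate group, or `fold = 3.78` for one
#' with 3.78 times more.
#'
#' @param config a [simulation_config()].
#' @param sample_id sample to alter.
#' @param fold positive multiplier on the sample copy pool.
#' @return the updated config.
#' @export
inject_outlier <- function(config, sample_id, fold) {
  stopifnot(inherits(config, "simulation_config"))
  if (fold <= 0) stop("fold must be > 0", call. = FALSE)
  if (!sample_id %in% config$design$sample_id)
    stop("unknown sample_id: ", sample_id, call. = FALSE)
  config$outlier_fold[sample_id] <- config$outlier_fold[sample_id] * fold
  config
}

#' Simulate a spiked amplicon experiment with known ground truth
#'
#' For each sample the generator builds an effective 16S copy pool:
#' sample taxa receive `biomass_mass * copies_per_mg * outlier_fold`
#' copies split by (per-pool) log-normal proportions; the two
#' mock-community taxa receive `mc_dose_fraction * copies_per_dose`
#' copies, with the gram-positive pool multiplied by
#' `gram_pos_efficiency` to emulate extraction bias. Reads are drawn
#' once per sample from a multinomial over all pools at the configured
#' depth, so per-sample read sums equal `depth` exactly and the expected
#' read share of any pool equals its effective-copy share. Each MC
#' taxon's reads are then thinned binomially into one primary SV
#' (sequence identical to the reference) and `n_secondary_*` secondary
#' SVs (reference sequence with 1-3 point mutations), each secondary
#' receiving on average `secondary_sv_rate` of the taxon's reads.
#'
#' @param config a [simulation_config()].
#' @return a list of class `spike_sim` with elements `table`
#'   ([count_table]), `sequences` (`DNAStringSet` of SV sequences),
#'   `metadata` (data.frame), `refs` ([mc_references]) and `truth`
#'   (class `ground_truth`: per-sample effective sample copies, per-taxon
#'   effective MC copies, expected MC read fraction, expected
#'   gram-ratio, outlier folds, and the MC SV id map).
#' @export
simulate_experiment <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  cfg <- config
  design <- cfg$design
  n <- nrow(design)

  with_seed(cfg$seed, {
    L <- cfg$amplicon_length
    ref_seq <- setNames(random_dna(2, L),
                        c("Imtechella halotolerans",
                          "Allobacillus halotolerans"))
    refs <- mc_references(
      taxon = names(ref_seq),
      gram = c("negative", "positive"),
      copies_per_dose = c(cfg$copies_per_dose_ih, cfg$copies_per_dose_ah),
      cells_per_dose = rep(cfg$cells_per_dose, 2),
      sequences = ref_seq)

    # SV sequence layout: sample taxa, then Ih primary + secondaries,
    # then Ah primary + secondaries
    taxa_ids <- sprintf("sv_%04d", seq_len(cfg$n_taxa))
    ih_ids <- sprintf("sv_%04d", cfg$n_taxa + seq_len(1 + cfg$n_secondary_ih))
    ah_ids <- sprintf("sv_%04d",
                      cfg$n_taxa + 1 + cfg$n_secondary_ih +
                        seq_len(1 + cfg$n_secondary_ah))
    seqs <- c(setNames(random_dna(cfg$n_taxa, L), taxa_ids),
              setNames(c(ref_seq[1],
                         vapply(seq_len(cfg$n_secondary_ih), function(k)
                           mutate_sequence(ref_seq[[1]], k), character(1))),
                       ih_ids),
              setNames(c(ref_seq[2],
                         vapply(seq_len(cfg$n_secondary_ah), function(k)
                           mutate_sequence(ref_seq[[2]], k), character(1))),
                       ah_ids))

    pools <- design$pool_id %||% rep("P1", n)
    pools[is.na(pools)] <- "P1"
    base_w <- lapply(unique(pools), function(p)
      rlnorm(cfg$n_taxa, cfg$lognormal_mu, cfg$lognormal_sigma))
    names(base_w) <- unique(pools)

    all_ids <- c(taxa_ids, ih_ids, ah_ids)
    m <- matrix(0, n, length(all_ids),
                dimnames = list(design$sample_id, all_ids))
    sample_copies <- setNames(numeric(n), design$sample_id)
    mc_copies <- matrix(0, n, 2,
                        dimnames = list(design$sample_id, refs$taxon))
    g <- cfg$gram_pos_efficiency
    for (j in seq_len(n)) {
      w <- base_w[[pools[j]]]
      if (cfg$replicate_sigma > 0)
        w <- w * rlnorm(cfg$n_taxa, 0, cfg$replicate_sigma)
      s_pool <- design$biomass_mass[j] * cfg$copies_per_mg *
        cfg$outlier_fold[design$sample_id[j]]
      taxa_eff <- s_pool * w / sum(w)
      d <- design$mc_dose_fraction[j]
      ih_eff <- d * cfg$copies_per_dose_ih        # gram-negative
      ah_eff <- d * cfg$copies_per_dose_ah * g    # gram-positive
      total <- sum(taxa_eff) + ih_eff + ah_eff
      if (total <= 0)
        stop("zero total copy pool for sample ", design$sample_id[j],
             call. = FALSE)
      reads <- rmultinom(1, cfg$depth, c(taxa_eff, ih_eff, ah_eff))[, 1]
      n_t <- cfg$n_taxa
      ih_reads <- reads[n_t + 1]
      ah_reads <- reads[n_t + 2]
      split_mc <- function(total_reads, n_sec) {
        sec <- if (n_sec > 0)
          vapply(seq_len(n_sec), function(k)
            rbinom(1, total_reads, cfg$secondary_sv_rate), numeric(1))
        else numeric(0)
        while (sum(sec) > total_reads)  # pathological high rates only
          sec[which.max(sec)] <- sec[which.max(sec)] - 1
        c(total_reads - sum(sec), sec)
      }
      m[j, taxa_ids] <- reads[seq_len(n_t)]
      m[j, ih_ids] <- split_mc(ih_reads, cfg$n_secondary_ih)
      m[j, ah_ids] <- split_mc(ah_reads, cfg$n_secondary_ah)
      sample_copies[j] <- s_pool
      mc_copies[j, ] <- c(ih_eff, ah_eff)
    }
  })

  metadata <- validate_metadata(design)
  truth <- structure(list(
    sample_id = design$sample_id,
    sample_copies = sample_copies,
    mc_copies = mc_copies,
    total_copies = sample_copies + rowSums(mc_copies),
    expected_mc_fraction =
      rowSums(mc_copies) / (sample_copies + rowSums(mc_copies)),
    expected_ih_ah_ratio = ifelse(mc_copies[, 2] > 0,
                                  mc_copies[, 1] / mc_copies[, 2], NA_real_),
    gram_pos_efficiency = config$gram_pos_efficiency,
    outlier_fold = config$outlier_fold,
    outlier = config$outlier_fold != 1,
    mc_sv = data.frame(
      sv_id = c(ih_ids, ah_ids),
      taxon = rep(refs$taxon, c(length(ih_ids), length(ah_ids))),
      role = c("primary", rep("secondary", length(ih_ids) - 1),
               "primary", rep("secondary", length(ah_ids) - 1)),
      stringsAsFactors = FALSE)),
    class = "ground_truth")

  structure(list(table = count_table(m),
                 sequences = Biostrings::DNAStringSet(seqs),
                 metadata = metadata,
                 refs = refs,
                 truth = truth,
                 config = config),
            class = "spike_sim")
}

#' @export
print.spike_sim <- function(x, ...) {
  cat(sprintf("spike_sim: %d samples, %d SVs, depth %d, seed %s\n",
              nrow(counts(x$table)), ncol(counts(x$table)),
              x$config$depth, format(x$config$seed)))
  invisible(x)
}
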