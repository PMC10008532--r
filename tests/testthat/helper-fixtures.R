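# Shared fixtures, built in code. All randomness is seeded.

rand_dna <- function(L, seed = NULL) {
  draw <- function() paste(sample(c("A", "C", "G", "T"), L,
                                  replace = TRUE), collapse = "")
  if (is.null(seed)) draw() else withr::with_seed(seed, draw())
}

substitute_at <- function(seq, pos) {
  b <- strsplit(seq, "")[[1]]
  for (p in pos) b[p] <- setdiff(c("A", "C", "G", "T"), b[p])[1]
  paste(b, collapse = "")
}

# two fixed 250-nt reference sequences + a reference table
REF_SEQ <- c("Imtechella halotolerans" = rand_dna(250, seed = 101),
             "Allobacillus halotolerans" = rand_dna(250, seed = 102))

make_refs <- function() {
  mc_references(taxon = names(REF_SEQ),
                gram = c("negative", "positive"),
                copies_per_dose = c(6.0e7, 1.4e8),
                cells_per_dose = c(2e7, 2e7),
                sequences = REF_SEQ)
}

# count table + sequences with known MC structure:
#   sv_ih  = exact Ih reference          (primary)
#   sv_ih2 = Ih with 2 substitutions     (identity 99.2, secondary)
#   sv_ah  = exact Ah reference          (primary)
#   sv_x, sv_y = unrelated random sample SVs
make_mc_fixture <- function(counts = NULL) {
  seqs <- Biostrings::DNAStringSet(c(
    sv_ih = unname(REF_SEQ[1]),
    sv_ih2 = substitute_at(REF_SEQ[[1]], c(10, 200)),
    sv_ah = unname(REF_SEQ[2]),
    sv_x = rand_dna(250, seed = 103),
    sv_y = rand_dna(250, seed = 104)))
  if (is.null(counts))
    counts <- matrix(c(450, 50, 400, 8000, 1100,
                       300, 20, 250, 7000, 1000),
                     nrow = 2, byrow = TRUE,
                     dimnames = list(c("s1", "s2"), names(seqs)))
  list(table = count_table(counts), seqs = seqs, refs = make_refs())
}

quick_sim <- function(n_replicates = 2, n_taxa = 60, depth = 5000,
                      seed = 11, ...) {
  simulate_experiment(simulation_config(
    design = bovine_design(n_replicates = n_replicates),
    n_taxa = n_taxa, depth = depth, seed = seed, ...))
}

# one moderately sized simulation shared across test files
SIM <- quick_sim()
SIM_ASSIGN <- suppressWarnings(
  assign_mc_svs(SIM$sequences, SIM$refs, SIM$table))

# all permutations of 1..n (for exhaustive enumeration oracles)
all_permutations <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- all_permutations(n - 1)
  out <- matrix(0L, n * nrow(sub), n)
  r <- 0L
  for (k in seq_len(n)) {
    rows <- r + seq_len(nrow(sub))
    out[rows, k] <- n
    out[rows, -k] <- sub
    r <- r + nrow(sub)
  }
  out
}

# brute-force one-factor PERMANOVA pseudo-F straight from distances
brute_force_f <- function(D, groups) {
  n <- nrow(D)
  a <- length(unique(groups))
  ss_tot <- sum(D[lower.tri(D)]^2) / n
  ss_w <- 0
  for (g in unique(groups)) {
    k <- which(groups == g)
    sub <- D[k, k, drop = FALSE]
    ss_w <- ss_w + sum(sub[lower.tri(sub)]^2) / length(k)
  }
  ss_b <- ss_tot - ss_w
  (ss_b / (a - 1)) / (ss_w / (n - a))
}
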