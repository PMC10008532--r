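#' Pairwise percent identity to a reference sequence
#'
#' Aligns each whole SV against the best-matching substring of the
#' reference (pattern-global, subject-local alignment with free end
#' gaps on the reference), so short SVs (e.g. the V4 region) align
#' inside a full-length reference without end-gap penalties, while the
#' full SV must take part in the alignment — short spurious overlaps
#' cannot score as high identity. Identity is matches / aligned
#' columns, reference end gaps excluded.
#'
#' @param query `DNAStringSet` of SV sequences.
#' @param reference single reference sequence (character or
#'   `DNAString`).
#' @return numeric vector of percent identities in `[0, 100]`.
#' @export
pairwise_identity <- function(query, reference) {
  if (!methods::is(query, "DNAStringSet"))
    query <- Biostrings::DNAStringSet(query)
  mat <- Biostrings::nucleotideSubstitutionMatrix(match = 1,
                                                  mismatch = -1)
  aln <- Biostrings::pairwiseAlignment(
    query, Biostrings::DNAString(as.character(reference)),
    type = "global-local", substitutionMatrix = mat,
    gapOpening = 8, gapExtension = 2)
  Biostrings::pid(aln, type = "PID1")
}

#' Assign sequence variants to mock-community taxa
#'
#' Scores every SV against every MC reference by pairwise identity (free
#' end-gap alignment) and assigns it to the best-matching reference when
#' identity is at least `min_identity`. Within each taxon, the assigned
#' SV with the highest total read count *and* 100% reference identity is
#' classified `primary` (abundance ties broken by lexicographic SV id);
#' all other assigned SVs are `secondary`. If the most abundant assigned
#' SV of a taxon is below 100% identity no SV is promoted and the taxon
#' is flagged instead.
#'
#' @param svs `DNAStringSet` of SV representative sequences (names =
#'   SV ids).
#' @param refs an [mc_references] table.
#' @param table a [count_table] sharing SV ids with `svs`.
#' @param min_identity assignment threshold in percent (default 97).
#' @return an object of class `mc_assignment`: list with `assignments`
#'   (data.frame sv_id, taxon, identity, status, reads), `taxon_reads`
#'   (samples x taxa matrix of assigned reads, secondaries included),
#'   `flags` (character) and `min_identity`.
#' @export
assign_mc_svs <- function(svs, refs, table, min_identity = 97) {
  stopifnot(inherits(refs, "mc_references"), inherits(table, "count_table"))
  ids <- sv_ids(table)
  missing <- setdiff(ids, names(svs))
  if (length(missing))
    stop("no sequence for SV id(s): ",
         paste(head(missing, 5), collapse = ", "), call. = FALSE)
  svs <- svs[ids]

  ident <- vapply(seq_len(nrow(refs)), function(k)
    pairwise_identity(svs, refs$sequence[k]), numeric(length(svs)))
  ident <- matrix(ident, ncol = nrow(refs),
                  dimnames = list(ids, refs$taxon))

  best <- max.col(ident, ties.method = "first")
  best_id <- ident[cbind(seq_along(ids), best)]
  assigned <- best_id >= min_identity
  reads_total <- colSums(counts(table))

  assignments <- data.frame(sv_id = ids[assigned],
                            taxon = refs$taxon[best[assigned]],
                            identity = best_id[assigned],
                            status = rep(NA_character_, sum(assigned)),
                            reads = unname(reads_total[ids[assigned]]),
                            stringsAsFactors = FALSE)
  flags <- character(0)
  for (tx in refs$taxon) {
    k <- which(assignments$taxon == tx)
    if (!length(k)) {
      flags <- c(flags, sprintf("no SV assigned to taxon '%s'", tx))
      next
    }
    assignments$status[k] <- "secondary"
    full <- k[assignments$identity[k] >= 100 - 1e-6]
    if (!length(full)) {
      flags <- c(flags, sprintf(
        "most abundant SV for taxon '%s' is below 100%% identity; no primary promoted",
        tx))
      next
    }
    ord <- full[order(-assignments$reads[full], assignments$sv_id[full])]
    assignments$status[ord[1]] <- "primary"
    if (assignments$reads[ord[1]] < max(assignments$reads[k]))
      flags <- c(flags, sprintf(
        "most abundant SV assigned to taxon '%s' is not at 100%% identity", tx))
  }

  taxon_reads <- matrix(0, nrow(counts(table)), nrow(refs),
                        dimnames = list(sample_ids(table), refs$taxon))
  for (tx in refs$taxon) {
    cols <- assignments$sv_id[assignments$taxon == tx]
    if (length(cols))
      taxon_reads[, tx] <-
        rowSums(counts(table)[, cols, drop = FALSE])
  }
  for (f in flags) warning(f, call. = FALSE)

  structure(list(assignments = assignments, taxon_reads = taxon_reads,
                 identity = ident, flags = flags,
                 min_identity = min_identity),
            class = "mc_assignment")
}

#' @export
print.mc_assignment <- function(x, ...) {
  cat(sprintf("mc_assignment: %d MC-SV(s) across %d taxon/taxa\n",
              nrow(x$assignments), length(unique(x$assignments$taxon))))
  print(x$assignments, row.names = FALSE)
  invisible(x)
}

mc_sv_ids <- function(assignment) assignment$assignments$sv_id

#' Per-sample mock-community read fraction
#'
#' Fraction of each library's reads carried by assigned MC-SVs
#' (primary and secondary, all taxa).
#'
#' @param table the [count_table] the assignment was computed on
#'   (pre-stripping).
#' @param assignment an [assign_mc_svs()] result.
#' @return named numeric vector in `[0, 1]`; `NA` for zero-read samples.
#' @export
mc_read_fraction <- function(table, assignment) {
  stopifnot(inherits(table, "count_table"),
            inherits(assignment, "mc_assignment"))
  ids <- intersect(mc_sv_ids(assignment), sv_ids(table))
  mc <- if (length(ids))
    rowSums(counts(table)[, ids, drop = FALSE]) else
      setNames(rep(0, nrow(counts(table))), sample_ids(table))
  out <- ifelse(totals(table) > 0, mc / totals(table), NA_real_)
  setNames(out, sample_ids(table))
}

#' Gram-ratio extraction-bias diagnostic
#'
#' Ratio of gram-negative to gram-positive spike-in reads per sample,
#' compared with the ratio expected from the dosed 16S copy numbers.
#' Since both taxa are added in a fixed copy ratio, a systematic excess
#' of the gram-negative taxon indicates under-extraction of the
#' gram-positive one; the bias factor is observed/expected ratio.
#'
#' @inheritParams mc_read_fraction
#' @param refs the [mc_references] used for assignment (must contain one
#'   gram-negative and one gram-positive taxon).
#' @return list with `per_sample` (data.frame: sample_id, ih_reads,
#'   ah_reads, ratio), `expected_ratio`, `mean_ratio`, `sd_ratio`,
#'   `bias_factor`, and `flags` for samples with zero gram-positive
#'   reads (ratio undefined).
#' @export
gram_ratio <- function(table, assignment, refs) {
  stopifnot(inherits(assignment, "mc_assignment"),
            inherits(refs, "mc_references"))
  neg <- gram_negative_taxon(refs)
  pos <- gram_positive_taxon(refs)
  ih <- setNames(assignment$taxon_reads[, neg],
                 rownames(assignment$taxon_reads))
  ah <- setNames(assignment$taxon_reads[, pos],
                 rownames(assignment$taxon_reads))
  ratio <- ifelse(ah > 0, ih / ah, NA_real_)
  flags <- names(ratio)[ah == 0 & ih > 0]
  expected <- refs[neg, "copies_per_dose"] / refs[pos, "copies_per_dose"]
  ok <- !is.na(ratio) & (ih + ah) > 0
  mean_ratio <- if (any(ok)) mean(ratio[ok]) else NA_real_
  list(per_sample = data.frame(sample_id = names(ratio),
                               ih_reads = unname(ih),
                               ah_reads = unname(ah),
                               ratio = unname(ratio),
                               stringsAsFactors = FALSE),
       expected_ratio = expected,
       mean_ratio = mean_ratio,
       sd_ratio = if (sum(ok) > 1) sd(ratio[ok]) else NA_real_,
       bias_factor = mean_ratio / expected,
       flags = flags)
}

#' Remove mock-community SVs from a count table
#'
#' Drops all assigned MC-SV columns and recomputes per-sample totals.
#' The pre-stripping totals and per-sample MC read counts are retained
#' as attributes (`original_total`, `mc_reads`) because the gene-copy
#' estimator needs the original library sizes.
#'
#' @inheritParams mc_read_fraction
#' @return a [count_table] of sample SVs only.
#' @seealso [original_totals()]
#' @export
strip_mc <- function(table, assignment) {
  stopifnot(inherits(table, "count_table"),
            inherits(assignment, "mc_assignment"))
  drop <- intersect(mc_sv_ids(assignment), sv_ids(table))
  keep <- setdiff(sv_ids(table), drop)
  out <- count_table(counts(table)[, keep, drop = FALSE])
  attr(out, "original_total") <- totals(table)
  attr(out, "mc_reads") <- totals(table) - totals(out)
  out
}

#' Pre-stripping library sizes of a stripped table
#'
#' @param x a [count_table] produced by [strip_mc()] (falls back to the
#'   table's own totals otherwise).
#' @return named numeric vector of original per-sample totals.
#' @export
original_totals <- function(x) {
  attr(x, "original_total") %||% totals(x)
}

#' Spike-in quality-control summary
#'
#' Combines the MC read fraction and gram-ratio diagnostics and checks
#' each sample against the recommended dose band: spike-in reads should
#' make up 1-10% of a library, below that band the spike is too dilute
#' for reliable quantification, above it the spike competes with sample
#' taxa for reads.
#'
#' @inheritParams gram_ratio
#' @param band numeric length 2, the acceptable MC read-fraction band
#'   (default `c(0.01, 0.10)`).
#' @param metadata optional metadata; when given, taxa dosed in some
#'   sample but never detected raise a warning flag.
#' @return list of class `mc_qc` with `per_sample` (data.frame:
#'   sample_id, mc_fraction, ih_ah_ratio, verdict in
#'   below/in_band/above) and `summary` (expected/mean/sd ratio, bias
#'   factor, band, flags).
#' @export
mc_qc <- function(table, assignment, refs, band = c(0.01, 0.10),
                  metadata = NULL) {
  if (length(band) != 2 || band[1] >= band[2] ||
      band[1] <= 0 || band[2] >= 1)
    stop("band must be increasing and inside (0, 1)", call. = FALSE)
  frac <- mc_read_fraction(table, assignment)
  gr <- gram_ratio(table, assignment, refs)
  verdict <- ifelse(is.na(frac), NA_character_,
                    ifelse(frac < band[1], "below",
                           ifelse(frac <= band[2], "in_band", "above")))
  flags <- c(assignment$flags,
             if (length(gr$flags))
               sprintf("gram-positive reads absent in: %s",
                       paste(gr$flags, collapse = ", ")))
  if (!is.null(metadata)) {
    md <- validate_metadata(metadata, table)
    dosed <- any(md$mc_dose_fraction > 0)
    detected <- unique(assignment$assignments$taxon)
    undetected <- setdiff(refs$taxon, detected)
    if (dosed && length(undetected))
      flags <- c(flags, sprintf("dosed taxon not detected: %s",
                                paste(undetected, collapse = ", ")))
  }
  structure(list(
    per_sample = data.frame(sample_id = names(frac),
                            mc_fraction = unname(frac),
                            ih_ah_ratio = gr$per_sample$ratio,
                            verdict = unname(verdict),
                            stringsAsFactors = FALSE),
    summary = list(expected_ratio = gr$expected_ratio,
                   mean_ratio = gr$mean_ratio,
                   sd_ratio = gr$sd_ratio,
                   bias_factor = gr$bias_factor,
                   band = band, flags = flags)),
    class = "mc_qc")
}

#' @export
print.mc_qc <- function(x, ...) {
  cat("mock-community QC\n")
  print(x$per_sample, row.names = FALSE)
  with(x$summary, cat(sprintf(
    "gram ratio: mean %.3f (sd %.3f), expected %.3f, bias factor %.2f\n",
    mean_ratio, sd_ratio, expected_ratio, bias_factor)))
  for (f in x$summary$flags) cat("flag:", f, "\n")
  invisible(x)
}

#' Synthetic-spike (SNA) standard-curve regression
#'
#' Ordinary least squares of log2 template copies on log2(observed SNA
#' read count + 0.1), the standard-curve check for PCR spike-ins of
#' synthetic molecules.
#'
#' @param sna_counts observed SNA-SV read counts, one per molecule.
#' @param template_copies known template copy numbers per molecule (e.g.
#'   375000 / 75000 / 15000 / 3000 for a four-molecule dilution mix).
#' @return list with `slope`, `intercept`, `r_squared`,
#'   `adj_r_squared`, `p_value`, `n`.
#' @export
sna_regression <- function(sna_counts, template_copies) {
  if (length(sna_counts) != length(template_copies))
    stop("counts and copies must have equal length", call. = FALSE)
  ok <- !is.na(sna_counts) & !is.na(template_copies)
  if (sum(ok) < 3)
    stop("at least 3 molecules with counts and copies are required",
         call. = FALSE)
  x <- log2(sna_counts[ok] + 0.1)
  y <- log2(template_copies[ok])
  fit <- lm(y ~ x)
  s <- summary(fit)
  list(slope = unname(coef(fit)[2]), intercept = unname(coef(fit)[1]),
       r_squared = s$r.squared, adj_r_squared = s$adj.r.squared,
       p_value = unname(s$coefficients[2, 4]), n = sum(ok))
}

#' PCA of mock-community SV abundances
#'
#' Ordinates samples by their MC-SV abundance profile: counts are
#' ln(x + 1)-transformed, each SV (variable) is centred and scaled to
#' unit variance, and principal components are computed by singular
#' value decomposition. Clusters in this space separate dose/biomass
#' combinations and expose spike-in processing anomalies.
#'
#' @param mc_counts samples x MC-SVs matrix (or [count_table]) of MC-SV
#'   read counts.
#' @return list with `scores` (samples x components), `loadings`,
#'   `explained_var` (shares summing to 1 over returned components) and
#'   `sdev`.
#' @export
mc_abundance_pca <- function(mc_counts) {
  if (inherits(mc_counts, "count_table")) mc_counts <- counts(mc_counts)
  mc_counts <- as.matrix(mc_counts)
  if (nrow(mc_counts) < 2 || ncol(mc_counts) < 2)
    stop("PCA needs at least 2 samples and 2 MC-SVs", call. = FALSE)
  y <- log(mc_counts + 1)
  sds <- apply(y, 2, sd)
  keep <- sds > 0
  if (!any(keep)) {
    warning("constant MC-SV matrix; returning zero scores")
    scores <- matrix(0, nrow(y), 1,
                     dimnames = list(rownames(y), "PC1"))
    return(list(scores = scores, loadings = NULL,
                explained_var = NA_real_, sdev = 0))
  }
  if (!all(keep))
    warning(sum(!keep), " constant MC-SV column(s) dropped from PCA")
  pr <- stats::prcomp(y[, keep, drop = FALSE], center = TRUE,
                      scale. = TRUE)
  list(scores = pr$x, loadings = pr$rotation,
       explained_var = pr$sdev^2 / sum(pr$sdev^2), sdev = pr$sdev)
}
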