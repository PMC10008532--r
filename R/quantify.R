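#' Estimate absolute 16S gene copies per library from the spike-in
#'
#' For each library j, the total number of 16S gene copies is estimated
#' by scaling the spiked reference-taxon copy input by the inverse of
#' its read share:
#' \deqn{GCN_j = (N_j / r_j) \times D_j}
#' where `N_j` is the total quality-filtered read count (pre-stripping),
#' `r_j` the reads assigned to the reference taxon (primary plus
#' secondary SVs; they all originate from the spiked cells), and `D_j`
#' the number of reference-taxon 16S copies spiked, i.e.
#' `mc_dose_fraction x copies_per_dose` of that taxon. The gram-negative
#' taxon is the default reference because gram-positive extraction is
#' biased.
#'
#' @param table the pre-stripping [count_table] (totals are the
#'   quality-filtered library sizes).
#' @param assignment an [assign_mc_svs()] result.
#' @param metadata per-sample metadata (see [read_metadata()]).
#' @param refs the [mc_references] used.
#' @param reference_taxon taxon used for estimation; default the
#'   gram-negative reference taxon.
#' @return data.frame of class `gcn_estimate` with one row per sample:
#'   `sample_id`, `total_reads`, `ih_reads` (reference-taxon reads),
#'   `dose_copies`, `gcn`, `log2_gcn`, `flag` (`"ok"`, `"no_mc"` for
#'   dose 0, `"qc_fail"` for dose > 0 with zero reference reads).
#' @export
estimate_gcn <- function(table, assignment, metadata, refs,
                         reference_taxon = NULL) {
  stopifnot(inherits(table, "count_table"),
            inherits(assignment, "mc_assignment"),
            inherits(refs, "mc_references"))
  md <- validate_metadata(metadata, table)
  if (is.null(reference_taxon)) reference_taxon <- gram_negative_taxon(refs)
  if (!reference_taxon %in% refs$taxon)
    stop("reference_taxon not in refs: ", reference_taxon, call. = FALSE)
  ih <- assignment$taxon_reads[sample_ids(table), reference_taxon]
  total <- totals(table)
  dose_copies <- md$mc_dose_fraction *
    refs[reference_taxon, "copies_per_dose"]
  gcn <- ifelse(dose_copies > 0 & ih > 0,
                total / ih * dose_copies, NA_real_)
  flag <- ifelse(dose_copies == 0, "no_mc",
                 ifelse(ih == 0, "qc_fail", "ok"))
  if (any(flag == "qc_fail"))
    warning("dose > 0 but no reference-taxon reads in: ",
            paste(sample_ids(table)[flag == "qc_fail"], collapse = ", "),
            call. = FALSE)
  out <- data.frame(sample_id = sample_ids(table),
                    total_reads = unname(total),
                    ih_reads = unname(ih),
                    dose_copies = unname(dose_copies),
                    gcn = unname(gcn),
                    log2_gcn = unname(log2(gcn)),
                    flag = unname(flag),
                    stringsAsFactors = FALSE)
  rownames(out) <- out$sample_id
  class(out) <- c("gcn_estimate", "data.frame")
  attr(out, "reference_taxon") <- reference_taxon
  out
}

#' Rescale sample-SV counts to absolute copy scale
#'
#' Transforms each sample-SV count into an absolute-scale abundance:
#' \deqn{norm_{ij} = (SV_{ij} / N_j) \times GCN_j \times (1 - r_j / N_j)}
#' with `SV_ij` the count of sample SV i, `N_j` the pre-stripping
#' library size, `GCN_j` the estimated total copies, and `r_j` the
#' reference-taxon (gram-negative spike) reads. The last factor is the
#' share of the library left after removing the reference-taxon spike
#' reads, used as the sample microbial-load indicator. Within-sample
#' proportions among sample SVs are preserved exactly (the transform is
#' a per-sample constant).
#'
#' @param stripped a [count_table] of sample SVs only, from
#'   [strip_mc()].
#' @param gcn a [estimate_gcn()] result covering the table's samples.
#' @return samples x sample-SVs numeric matrix of class
#'   `transformed_table`; samples without a copy estimate (no MC dose or
#'   failed QC) are dropped with a warning.
#' @export
transform_counts <- function(stripped, gcn) {
  stopifnot(inherits(stripped, "count_table"),
            inherits(gcn, "gcn_estimate"))
  ids <- sample_ids(stripped)
  missing <- setdiff(ids, gcn$sample_id)
  if (length(missing))
    stop("no copy estimate row for sample(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  g <- gcn[match(ids, gcn$sample_id), ]
  drop <- is.na(g$gcn)
  if (any(drop)) {
    warning("dropping sample(s) without a copy estimate: ",
            paste(ids[drop], collapse = ", "), call. = FALSE)
    ids <- ids[!drop]
    g <- g[!drop, ]
  }
  m <- counts(stripped)[ids, , drop = FALSE]
  factor_j <- g$gcn / g$total_reads * (1 - g$ih_reads / g$total_reads)
  out <- m * factor_j
  class(out) <- c("transformed_table", class(out))
  attr(out, "gcn") <- g
  out
}

#' Flag copy-number outliers within replicate groups
#'
#' A library is an outlier when its estimated gene-copy number deviates
#' from the median of its replicate group by more than `fold_threshold`
#' in either direction, measured as `2^|log2(GCN) - median group
#' log2(GCN)|`. The rule is invariant to global rescaling of a group's
#' estimates. Groups with fewer than 3 members cannot support a median
#' comparison and are skipped with a warning.
#'
#' @param gcn a [estimate_gcn()] result.
#' @param grouping vector (same length/order as `gcn` rows, or named by
#'   sample id) giving the replicate group of each sample, e.g.
#'   pool x condition.
#' @param fold_threshold flag when fold deviation exceeds this (default
#'   2.5).
#' @return data.frame: `sample_id`, `group`, `fold_deviation`,
#'   `flagged`. Samples without an estimate get `NA`.
#' @export
flag_outliers <- function(gcn, grouping, fold_threshold = 2.5) {
  stopifnot(inherits(gcn, "gcn_estimate"))
  if (!is.null(names(grouping)))
    grouping <- grouping[gcn$sample_id]
  if (length(grouping) != nrow(gcn))
    stop("grouping must match the estimate table", call. = FALSE)
  grouping <- as.character(grouping)
  fold_dev <- rep(NA_real_, nrow(gcn))
  flagged <- rep(NA, nrow(gcn))
  for (gr in unique(grouping)) {
    k <- which(grouping == gr & !is.na(gcn$log2_gcn))
    if (length(k) < 3) {
      if (length(k) > 0)
        warning("group '", gr, "' has fewer than 3 estimable members; skipped",
                call. = FALSE)
      next
    }
    med <- median(gcn$log2_gcn[k])
    fold_dev[k] <- 2^abs(gcn$log2_gcn[k] - med)
    flagged[k] <- fold_dev[k] > fold_threshold
  }
  data.frame(sample_id = gcn$sample_id, group = grouping,
             fold_deviation = fold_dev, flagged = flagged,
             stringsAsFactors = FALSE)
}

#' Recommend a mock-community dose for a sample type
#'
#' Inverts the expected spike read fraction
#' `f(d) = E(d) / (E(d) + S)` for the dose `d` at each edge of the
#' target band, where `S` is the sample's 16S copy pool (from a pilot
#' estimate or mass x copies/mg) and
#' `E(d) = d x (C_neg + g x C_pos)` is the effective spiked copy pool
#' (`C` = copies per dose of the gram-negative / gram-positive taxon,
#' `g` = gram-positive extraction efficiency). The closed form is
#' `d = f / (1 - f) x S / (C_neg + g C_pos)`. The default band of
#' 1-10% of library reads keeps the spike quantifiable without letting
#' it compete with sample taxa.
#'
#' @param sample_copies expected 16S copy pool of the sample (> 0).
#' @param refs an [mc_references] table.
#' @param band target MC read-fraction band, inside (0, 1).
#' @param gram_pos_efficiency assumed extraction efficiency of the
#'   gram-positive taxon (1 = unbiased).
#' @param label optional sample-type label.
#' @return data.frame of class `dose_recommendation` with the dose
#'   fractions achieving the band edges.
#' @export
recommend_dose <- function(sample_copies, refs, band = c(0.01, 0.10),
                           gram_pos_efficiency = 1, label = NA_character_) {
  stopifnot(inherits(refs, "mc_references"))
  if (sample_copies <= 0)
    stop("sample_copies must be > 0", call. = FALSE)
  if (length(band) != 2 || any(band <= 0) || any(band >= 1) ||
      band[1] >= band[2])
    stop("band must be increasing and inside (0, 1)", call. = FALSE)
  neg <- gram_negative_taxon(refs)
  pos <- gram_positive_taxon(refs)
  eff_per_dose <- refs[neg, "copies_per_dose"] +
    gram_pos_efficiency * refs[pos, "copies_per_dose"]
  d <- band / (1 - band) * sample_copies / eff_per_dose
  out <- data.frame(label = label,
                    sample_copies = sample_copies,
                    target_fraction = band,
                    dose_fraction = d,
                    stringsAsFactors = FALSE)
  class(out) <- c("dose_recommendation", "data.frame")
  out
}

#' Cross-validate sequencing copy estimates against ddPCR
#'
#' OLS regression of log2 ddPCR-measured copies on log2
#' sequencing-estimated copies across paired libraries; a slope near 1
#' and high adjusted R-squared indicate the spike-based estimator tracks
#' the orthogonal absolute measurement.
#'
#' @param gcn a [estimate_gcn()] result.
#' @param ddpcr data.frame with columns `sample_id` and `copies`.
#' @return list with `slope`, `intercept`, `r_squared`,
#'   `adj_r_squared`, `p_value`, `n`, `excluded` (unmatched sample ids).
#' @export
ddpcr_crossval <- function(gcn, ddpcr) {
  stopifnot(inherits(gcn, "gcn_estimate"),
            all(c("sample_id", "copies") %in% names(ddpcr)))
  est <- gcn[!is.na(gcn$gcn), c("sample_id", "gcn")]
  merged <- merge(est, ddpcr, by = "sample_id")
  excluded <- c(setdiff(ddpcr$sample_id, est$sample_id),
                setdiff(est$sample_id, ddpcr$sample_id))
  if (length(excluded))
    warning("unmatched sample(s) excluded: ",
            paste(excluded, collapse = ", "), call. = FALSE)
  if (nrow(merged) < 3)
    stop("at least 3 paired measurements are required", call. = FALSE)
  fit <- lm(log2(copies) ~ log2(gcn), data = merged)
  s <- summary(fit)
  list(slope = unname(coef(fit)[2]), intercept = unname(coef(fit)[1]),
       r_squared = s$r.squared, adj_r_squared = s$adj.r.squared,
       p_value = unname(s$coefficients[2, 4]), n = nrow(merged),
       excluded = excluded)
}
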