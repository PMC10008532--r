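#' Permutational multivariate ANOVA (PERMANOVA) on a distance matrix
#'
#' Partitions the total sum of squares of a distance matrix over an
#' ordered list of model terms using sequential (Type-I) sums of
#' squares, in the spirit of `vegan::adonis2`. The Gower-centred inner
#' product matrix `G = -0.5 J D^2 J` yields the total SS as `tr(G)`;
#' each term's SS is the increment in `tr(H G)` when the term's columns
#' join the cumulative model matrix (hat matrix `H`). The pseudo-F for
#' term k is `(SS_k / df_k) / (SS_res / df_res)`. Significance is
#' assessed by permuting sample labels: `p = (1 + #(F* >= F)) /
#' (1 + n_perm)`.
#'
#' @param d a [distance_matrix], `dist` or square matrix.
#' @param metadata data.frame of sample covariates; if it has a
#'   `sample_id` column (or row names) matching the distance matrix,
#'   rows are aligned by id.
#' @param terms character vector of metadata columns, in testing order
#'   (order matters: sums of squares are sequential).
#' @param n_perm number of permutations (default 999).
#' @param seed integer seed for the permutation draw.
#' @param permutations optional integer matrix of permutations (one per
#'   row) to use instead of random draws, e.g. an exhaustive
#'   enumeration for exact small-sample p-values.
#' @return data.frame of class `permanova` with one row per term plus
#'   `Residual` and `Total`: `df`, `SS`, `R2`, `F`, `p_value`.
#' @export
permanova <- function(d, metadata, terms, n_perm = 999, seed = NULL,
                      permutations = NULL) {
  D <- dist_to_matrix(d)
  n <- nrow(D)
  ids <- rownames(D)
  md <- as.data.frame(metadata)
  if (!is.null(md$sample_id) && !is.null(ids)) {
    if (!all(ids %in% md$sample_id))
      stop("metadata is missing sample(s) present in the distance matrix",
           call. = FALSE)
    md <- md[match(ids, md$sample_id), , drop = FALSE]
  } else if (nrow(md) != n) {
    stop("metadata rows do not match the distance matrix", call. = FALSE)
  }
  missing <- setdiff(terms, names(md))
  if (length(missing))
    stop("term(s) not in metadata: ", paste(missing, collapse = ", "),
         call. = FALSE)

  G <- gower_center(D)
  ss_total <- sum(diag(G))

  # cumulative hat matrices, one per term prefix
  hats <- vector("list", length(terms) + 1)
  ranks <- integer(length(terms) + 1)
  X <- matrix(1, n, 1)
  qrX <- qr(X)
  hats[[1]] <- tcrossprod(qr.Q(qrX)[, seq_len(qrX$rank), drop = FALSE])
  ranks[1] <- qrX$rank
  for (k in seq_along(terms)) {
    f <- reformulate(terms[seq_len(k)])
    X <- model.matrix(f, data = md)
    qrX <- qr(X)
    hats[[k + 1]] <- tcrossprod(qr.Q(qrX)[, seq_len(qrX$rank),
                                          drop = FALSE])
    ranks[k + 1] <- qrX$rank
    if (ranks[k + 1] == ranks[k])
      stop("term '", terms[k],
           "' is constant or confounded with earlier terms",
           call. = FALSE)
  }
  df_terms <- diff(ranks)
  df_res <- n - ranks[length(ranks)]
  if (df_res < 1)
    stop("no residual degrees of freedom", call. = FALSE)

  stat_fun <- function(Gm) {
    tr <- vapply(hats, function(H) sum(H * Gm), numeric(1))
    ss <- diff(tr)
    ss_res <- sum(diag(Gm)) - tr[length(tr)]
    f <- (ss / df_terms) / (ss_res / df_res)
    list(ss = ss, ss_res = ss_res, f = f)
  }
  obs <- stat_fun(G)

  if (is.null(permutations)) {
    perms <- with_seed(seed, t(replicate(n_perm, sample.int(n))))
  } else {
    perms <- as.matrix(permutations)
    if (ncol(perms) != n)
      stop("permutation matrix must have one column per sample",
           call. = FALSE)
  }
  n_used <- nrow(perms)
  exceed <- numeric(length(terms))
  for (b in seq_len(n_used)) {
    p <- perms[b, ]
    fb <- stat_fun(G[p, p])$f
    exceed <- exceed + (fb >= obs$f - 1e-12)
  }
  pvals <- (1 + exceed) / (1 + n_used)

  out <- data.frame(
    term = c(terms, "Residual", "Total"),
    df = c(df_terms, df_res, n - 1),
    SS = c(obs$ss, obs$ss_res, ss_total),
    R2 = c(obs$ss, obs$ss_res, ss_total) / ss_total,
    F = c(obs$f, NA, NA),
    p_value = c(pvals, NA, NA),
    stringsAsFactors = FALSE)
  class(out) <- c("permanova", "data.frame")
  attr(out, "n_perm") <- n_used
  attr(out, "seed") <- seed
  out
}

#' @export
print.permanova <- function(x, ...) {
  cat(sprintf("PERMANOVA (sequential SS, %d permutations)\n",
              attr(x, "n_perm")))
  df <- as.data.frame(x)
  df$SS <- signif(df$SS, 5)
  df$R2 <- round(df$R2, 3)
  df$F <- round(df$F, 3)
  print(df, row.names = FALSE)
  invisible(x)
}

#' MC:biomass ratio covariate
#'
#' Dose-to-biomass ratio of each sample normalized so that the
#' high-biomass / high-dose reference combination (0.5 dose on 50 mg)
#' equals 1: `ratio = (dose / mass) / (0.5 / 50)`. Samples with equal
#' dose-per-mass share a value regardless of scale; a low-biomass
#' high-dose sample (0.5 dose on 1.25 mg) gets 40, a high-biomass
#' low-dose one (0.0125 dose on 50 mg) gets 0.025, and unspiked samples
#' get 0.
#'
#' @param metadata per-sample metadata with `biomass_mass` and
#'   `mc_dose_fraction`.
#' @param reference_dose,reference_mass the combination mapped to 1.
#' @return named numeric vector.
#' @export
mc_biomass_ratio <- function(metadata, reference_dose = 0.5,
                             reference_mass = 50) {
  md <- validate_metadata(metadata)
  r <- (md$mc_dose_fraction / md$biomass_mass) /
    (reference_dose / reference_mass)
  setNames(r, md$sample_id)
}
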