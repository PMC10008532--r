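#' Centred log-ratio (CLR) normalization
#'
#' Per sample, counts are offset, logged and centred:
#' `clr(x) = ln(x + offset) - mean(ln(x + offset))`, so every row of the
#' output has mean exactly zero. An offset of 1 (default) handles zero
#' counts.
#'
#' @param x a [count_table] or samples x SVs matrix.
#' @param offset pseudocount added to every cell before the log.
#' @return real-valued samples x SVs matrix.
#' @export
clr_normalize <- function(x, offset = 1) {
  if (inherits(x, "count_table")) x <- counts(x)
  x <- as.matrix(x)
  if (any(x < 0)) stop("counts must be non-negative", call. = FALSE)
  if (offset <= 0 && any(x == 0))
    stop("offset must be > 0 when zero counts are present",
         call. = FALSE)
  lx <- log(x + offset)
  lx - rowMeans(lx)
}

#' Rarefy a count table to even depth
#'
#' Subsamples each library without replacement (hypergeometric) to
#' exactly `depth` reads. The default depth is 99% of the minimum
#' library size, rounded down, which keeps all samples while dampening
#' the influence of the shallowest library. Samples below the requested
#' depth are dropped with a warning.
#'
#' @param table a [count_table].
#' @param depth target depth; default `floor(0.99 * min(totals))`.
#' @param seed integer seed for the subsampling draw.
#' @return a rarefied [count_table].
#' @export
rarefy_table <- function(table, depth = NULL, seed = NULL) {
  stopifnot(inherits(table, "count_table"))
  tot <- totals(table)
  if (is.null(depth)) depth <- floor(0.99 * min(tot))
  if (depth < 1) stop("rarefaction depth must be >= 1", call. = FALSE)
  keep <- tot >= depth
  if (!all(keep)) {
    warning("dropping sample(s) below depth ", depth, ": ",
            paste(sample_ids(table)[!keep], collapse = ", "),
            call. = FALSE)
    if (!any(keep)) stop("no sample reaches the rarefaction depth",
                         call. = FALSE)
  }
  m <- counts(table)[keep, , drop = FALSE]
  # vegan warns when a matrix has no singleton counts (suspecting
  # non-count data); our inputs are validated integer counts
  r <- with_seed(seed, withCallingHandlers(
    vegan::rrarefy(m, depth),
    warning = function(w) {
      if (grepl("observed counts", conditionMessage(w)))
        invokeRestart("muffleWarning")
    }))
  count_table(r)
}

hill_number <- function(x, q) {
  x <- x[x > 0]
  if (!length(x)) return(NA_real_)
  p <- x / sum(x)
  if (q == 0) length(p)
  else if (q == 1) exp(-sum(p * log(p)))
  else sum(p^q)^(1 / (1 - q))
}

#' Per-sample alpha diversity
#'
#' Richness `S` (SVs with at least one read), Shannon entropy `H`
#' (natural log) and inverse Simpson `D2 = 1 / sum(p^2)`. These are the
#' Hill numbers of order 0, `exp(H)` = order 1 and `D2` = order 2.
#'
#' @param table a [count_table].
#' @return data.frame: `sample_id`, `richness`, `shannon`,
#'   `inv_simpson`; empty samples yield `NA` rows.
#' @export
alpha_diversity <- function(table) {
  stopifnot(inherits(table, "count_table"))
  m <- counts(table)
  out <- data.frame(
    sample_id = sample_ids(table),
    richness = apply(m, 1, function(x) {
      if (sum(x) == 0) NA_real_ else sum(x > 0)
    }),
    shannon = apply(m, 1, function(x) {
      if (sum(x) == 0) return(NA_real_)
      p <- x[x > 0] / sum(x)
      -sum(p * log(p))
    }),
    inv_simpson = apply(m, 1, function(x) {
      if (sum(x) == 0) NA_real_ else hill_number(x, 2)
    }),
    stringsAsFactors = FALSE)
  rownames(out) <- out$sample_id
  out
}

#' Rarefaction curves of Hill numbers with bootstrap intervals
#'
#' For each sample and each diversity order q, the Hill number is
#' estimated at a grid of sub-sample sizes by repeatedly drawing reads
#' without replacement (hypergeometric interpolation). Draws are nested
#' within a bootstrap replicate (a single shuffled read vector per
#' replicate, truncated at each grid point), so the order-0 curve is
#' non-decreasing in sub-sample size replicate by replicate. The point
#' estimate is the replicate mean and the confidence band the
#' 2.5/97.5 percentiles. Extrapolation beyond the observed depth is not
#' performed; grid points above a sample's total are skipped with a
#' warning.
#'
#' @param table a [count_table].
#' @param q diversity orders, subset of `c(0, 1, 2)`.
#' @param grid sub-sample sizes; default 10 sizes from 10% of each
#'   library to its full depth.
#' @param n_boot bootstrap replicates (default 200).
#' @param seed integer seed.
#' @return data.frame of class `re_curves`: `sample_id`, `q`, `m`
#'   (sub-sample size), `estimate`, `lower`, `upper`.
#' @export
re_curves <- function(table, q = c(0, 1, 2), grid = NULL,
                      n_boot = 200, seed = NULL) {
  stopifnot(inherits(table, "count_table"), all(q %in% c(0, 1, 2)))
  m <- counts(table)
  res <- with_seed(seed, {
    out <- vector("list", nrow(m))
    for (j in seq_len(nrow(m))) {
      x <- m[j, ]
      N <- sum(x)
      gj <- if (is.null(grid))
        unique(round(seq(max(1, N / 10), N, length.out = 10)))
      else sort(unique(round(grid)))
      over <- gj > N
      if (any(over)) {
        warning("grid point(s) above depth of sample ",
                rownames(m)[j], " skipped", call. = FALSE)
        gj <- gj[!over]
      }
      if (!length(gj)) next
      reads <- rep.int(seq_along(x), x)
      vals <- array(NA_real_, c(n_boot, length(gj), length(q)))
      for (b in seq_len(n_boot)) {
        perm <- sample(reads)
        for (gi in seq_along(gj)) {
          tab <- tabulate(perm[seq_len(gj[gi])], nbins = length(x))
          for (qi in seq_along(q))
            vals[b, gi, qi] <- hill_number(tab, q[qi])
        }
      }
      rows <- expand.grid(m = gj, q = q)
      est <- low <- up <- numeric(nrow(rows))
      for (r in seq_len(nrow(rows))) {
        gi <- match(rows$m[r], gj); qi <- match(rows$q[r], q)
        v <- vals[, gi, qi]
        est[r] <- mean(v)
        low[r] <- unname(quantile(v, 0.025))
        up[r] <- unname(quantile(v, 0.975))
      }
      out[[j]] <- data.frame(sample_id = rownames(m)[j],
                             q = rows$q, m = rows$m, estimate = est,
                             lower = low, upper = up,
                             stringsAsFactors = FALSE)
    }
    do.call(rbind, out)
  })
  class(res) <- c("re_curves", "data.frame")
  res
}

#' Sample-by-sample distance matrix
#'
#' Euclidean distance (intended for CLR-normalized matrices; together
#' they form the Aitchison distance) or Bray-Curtis dissimilarity
#' (intended for rarefied counts). Exact symmetry and a zero diagonal
#' are enforced.
#'
#' @param x a samples x features matrix (euclidean) or [count_table] /
#'   count matrix (bray_curtis).
#' @param metric `"euclidean"` or `"bray_curtis"`.
#' @return object of class `distance_matrix`: list with `matrix`
#'   (symmetric, zero diagonal), `metric`, `sample_ids`.
#' @export
distance_matrix <- function(x, metric = c("euclidean", "bray_curtis")) {
  metric <- match.arg(metric)
  is_ct <- inherits(x, "count_table")
  m <- if (is_ct) counts(x) else as.matrix(x)
  if (metric == "euclidean") {
    if (is_ct)
      warning("euclidean distance expects a CLR-normalized matrix, ",
              "got raw counts", call. = FALSE)
    d <- as.matrix(dist(m))
  } else {
    if (any(m < 0))
      warning("Bray-Curtis expects non-negative counts; ",
              "negative values present", call. = FALSE)
    d <- as.matrix(vegan::vegdist(m, method = "bray"))
  }
  d <- (d + t(d)) / 2
  diag(d) <- 0
  structure(list(matrix = d, metric = metric, sample_ids = rownames(m)),
            class = "distance_matrix")
}

#' @export
as.matrix.distance_matrix <- function(x, ...) x$matrix

#' @export
as.dist.distance_matrix <- function(m, diag = FALSE, upper = FALSE)
  as.dist(m$matrix, diag = diag, upper = upper)

#' @export
print.distance_matrix <- function(x, ...) {
  cat(sprintf("distance_matrix (%s): %d samples\n", x$metric,
              nrow(x$matrix)))
  invisible(x)
}

dist_to_matrix <- function(d) {
  if (inherits(d, "distance_matrix")) d$matrix
  else if (inherits(d, "dist")) as.matrix(d)
  else as.matrix(d)
}

gower_center <- function(D) {
  n <- nrow(D)
  J <- diag(n) - 1 / n
  -0.5 * J %*% (D^2) %*% J
}

#' Principal coordinates analysis (classical MDS)
#'
#' Eigendecomposition of the Gower-centred matrix `-0.5 J D^2 J`.
#' Coordinates are returned for positive eigenvalues only; negative
#' eigenvalues (possible for semi-metric dissimilarities such as
#' Bray-Curtis) are reported as-is with no correction.
#'
#' @param d a [distance_matrix], `dist` or square matrix.
#' @return list with `coordinates` (samples x axes, scaled by the
#'   square-rooted eigenvalues), `eigenvalues` (all, sorted
#'   decreasingly), `explained` (shares of the positive eigenvalue sum).
#' @export
pcoa <- function(d) {
  D <- dist_to_matrix(d)
  n <- nrow(D)
  G <- gower_center(D)
  e <- eigen(G, symmetric = TRUE)
  tol <- max(abs(e$values)) * 1e-9
  if (all(abs(e$values) <= .Machine$double.eps * n)) {
    warning("all distances are zero; returning zero coordinates")
    coords <- matrix(0, n, 1, dimnames = list(rownames(D), "Axis.1"))
    return(list(coordinates = coords, eigenvalues = e$values,
                explained = NA_real_))
  }
  pos <- which(e$values > tol)
  coords <- e$vectors[, pos, drop = FALSE] %*%
    diag(sqrt(e$values[pos]), length(pos))
  dimnames(coords) <- list(rownames(D),
                           paste0("Axis.", seq_along(pos)))
  list(coordinates = coords, eigenvalues = e$values,
       explained = e$values[pos] / sum(e$values[pos]))
}

#' Compare alpha diversity between two groups
#'
#' Wilcoxon rank-sum test per diversity index. The exact null
#' distribution is used for small groups (both sizes at most 10, no
#' ties); otherwise the normal approximation with tie correction and
#' continuity correction applies. The p-value depends on the
#' observations only through their ranks, so it is invariant to
#' monotone transformations.
#'
#' @param alpha an [alpha_diversity()] table.
#' @param grouping two-level vector (same order as `alpha` rows, or
#'   named by sample id), each level with at least 2 samples.
#' @return data.frame: `index`, `statistic`, `p_value`, `n1`, `n2`,
#'   `method`.
#' @export
compare_alpha <- function(alpha, grouping) {
  if (!is.null(names(grouping))) grouping <- grouping[alpha$sample_id]
  grouping <- as.factor(as.character(grouping))
  if (nlevels(grouping) != 2)
    stop("exactly two groups are required; compare groups pairwise",
         call. = FALSE)
  if (any(table(grouping) < 2))
    stop("each group needs at least 2 samples", call. = FALSE)
  idx <- intersect(c("richness", "shannon", "inv_simpson"), names(alpha))
  rows <- lapply(idx, function(ix) {
    v <- alpha[[ix]]
    ok <- !is.na(v)
    g <- grouping[ok]; v <- v[ok]
    x <- v[g == levels(g)[1]]; y <- v[g == levels(g)[2]]
    exact <- max(length(x), length(y)) <= 10 &&
      !anyDuplicated(c(x, y))
    wt <- suppressWarnings(wilcox.test(x, y, exact = exact))
    data.frame(index = ix, statistic = unname(wt$statistic),
               p_value = wt$p.value, n1 = length(x), n2 = length(y),
               method = if (exact) "exact" else "normal approximation",
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
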