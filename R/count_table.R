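#' Construct an SV count table
#'
#' A `count_table` holds a samples x SVs matrix of non-negative integer
#' read counts together with per-sample totals (the quality-filtered
#' library sizes). Rows are samples, columns are sequence variants.
#'
#' @param counts numeric matrix (samples as rows) with unique, non-empty
#'   row and column names; all entries must be non-negative integers.
#' @return An object of class `count_table`: a list with elements
#'   `counts` (the matrix) and `total` (named per-sample read sums).
#' @examples
#' m <- matrix(c(4, 6, 12, 8), 2, 2,
#'             dimnames = list(c("s1", "s2"), c("sv1", "sv2")))
#' ct <- count_table(m)
#' totals(ct)
#' @export
count_table <- function(counts) {
  counts <- as.matrix(counts)
  if (nrow(counts) == 0L)
    stop("count table must contain at least one sample", call. = FALSE)
  if (!is.numeric(counts))
    stop("counts must be numeric", call. = FALSE)
  if (anyNA(counts))
    stop("counts must not contain missing values", call. = FALSE)
  if (any(counts < 0))
    stop("counts must be non-negative", call. = FALSE)
  if (any(abs(counts - round(counts)) > 1e-8))
    stop("counts must be integral", call. = FALSE)
  counts <- round(counts)
  if (is.null(rownames(counts)) || anyDuplicated(rownames(counts)))
    stop("sample ids must be present and unique", call. = FALSE)
  if (ncol(counts) > 0L &&
      (is.null(colnames(counts)) || anyDuplicated(colnames(counts))))
    stop("SV ids must be present and unique", call. = FALSE)
  structure(list(counts = counts, total = rowSums(counts)),
            class = "count_table")
}

#' @rdname count_table
#' @param x a `count_table`.
#' @export
counts <- function(x) UseMethod("counts")

#' @export
counts.count_table <- function(x) x$counts

#' @rdname count_table
#' @export
totals <- function(x) UseMethod("totals")

#' @export
totals.count_table <- function(x) x$total

#' @rdname count_table
#' @export
sample_ids <- function(x) UseMethod("sample_ids")

#' @export
sample_ids.count_table <- function(x) rownames(x$counts)

#' @rdname count_table
#' @export
sv_ids <- function(x) UseMethod("sv_ids")

#' @export
sv_ids.count_table <- function(x) colnames(x$counts)

#' @export
dim.count_table <- function(x) dim(x$counts)

#' @export
as.matrix.count_table <- function(x, ...) x$counts

#' @export
print.count_table <- function(x, ...) {
  cat(sprintf("count_table: %d samples x %d SVs\n",
              nrow(x$counts), ncol(x$counts)))
  cat(sprintf("  total reads per sample: %s .. %s\n",
              format(min(x$total)), format(max(x$total))))
  invisible(x)
}

#' Subset a count table
#'
#' @param x a `count_table`.
#' @param samples,svs character, integer or logical indices; `NULL`
#'   keeps everything.
#' @return a `count_table`.
#' @export
subset_table <- function(x, samples = NULL, svs = NULL) {
  m <- x$counts
  if (!is.null(samples)) m <- m[samples, , drop = FALSE]
  if (!is.null(svs)) m <- m[, svs, drop = FALSE]
  count_table(m)
}
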