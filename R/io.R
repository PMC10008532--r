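#' Read an SV count table from TSV or BIOM
#'
#' TSV tables are tab-delimited with `#`-prefixed comment lines allowed
#' before the header. By default samples are rows; many amplicon tools
#' emit the transpose (SVs as rows), selected with
#' `orientation = "svs"`. If the first header field is literally
#' `sample_id` or `sv_id` the orientation is taken from the file itself.
#' BIOM files (JSON or HDF5 dialect) follow the BIOM convention of
#' observations (SVs) as rows and are transposed on read.
#'
#' @param path file path.
#' @param format `"auto"` (by extension), `"tsv"` or `"biom"`.
#' @param orientation orientation of a TSV table: `"samples"` (rows are
#'   samples, default) or `"svs"` (rows are SVs; transposed on read).
#' @return a [count_table].
#' @export
read_count_table <- function(path,
                             format = c("auto", "tsv", "biom"),
                             orientation = c("samples", "svs")) {
  format <- match.arg(format)
  orientation <- match.arg(orientation)
  if (!file.exists(path))
    stop("file not found: ", path, call. = FALSE)
  if (format == "auto")
    format <- if (grepl("\\.biom$", path, ignore.case = TRUE)) "biom" else "tsv"

  if (format == "biom") {
    b <- biomformat::read_biom(path)
    m <- as(biomformat::biom_data(b), "matrix")  # observations x samples
    m <- t(m)
  } else {
    first <- readLines(path, n = 50L)
    first <- first[!startsWith(first, "#")][1]
    lead <- sub("\t.*$", "", first)
    if (identical(lead, "sv_id")) orientation <- "svs"
    if (identical(lead, "sample_id")) orientation <- "samples"
    df <- read.delim(path, comment.char = "#", check.names = FALSE,
                     row.names = 1, sep = "\t")
    m <- as.matrix(df)
    if (orientation == "svs") m <- t(m)
  }
  if (length(m) == 0L || nrow(m) == 0L || ncol(m) == 0L)
    stop("empty count table: ", path, call. = FALSE)
  if (!is.numeric(m))
    stop("count table cells must be numeric: ", path, call. = FALSE)
  if (any(m < 0) || any(abs(m - round(m)) > 1e-8))
    stop("count table must contain non-negative integers: ", path,
         call. = FALSE)
  count_table(m)
}

#' Write an SV count table to TSV or BIOM
#'
#' @param x a [count_table].
#' @param path output path.
#' @param format `"tsv"` or `"biom"` (JSON dialect).
#' @param orientation for TSV output, whether rows are samples or SVs.
#'   The first header field records the orientation (`sample_id` or
#'   `sv_id`) so [read_count_table()] round-trips without flags.
#' @return `path`, invisibly.
#' @export
write_count_table <- function(x, path, format = c("tsv", "biom"),
                              orientation = c("samples", "svs")) {
  stopifnot(inherits(x, "count_table"))
  format <- match.arg(format)
  orientation <- match.arg(orientation)
  if (format == "biom") {
    b <- biomformat::make_biom(t(counts(x)))
    biomformat::write_biom(b, path)
  } else {
    m <- counts(x)
    lead <- "sample_id"
    if (orientation == "svs") {
      m <- t(m)
      lead <- "sv_id"
    }
    df <- data.frame(rownames(m), m, check.names = FALSE)
    colnames(df)[1] <- lead
    write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}

#' Read per-sample metadata
#'
#' Expects a tab-delimited file with at least the columns `sample_id`,
#' `biomass_mass` (mg of sample material) and `mc_dose_fraction`
#' (fraction of one manufacturer mock-community dose; 0 means no MC
#' added). Optional columns `pool_id`, `replicate_label` and `condition`
#' are filled with `NA` when absent.
#'
#' @param path tab-delimited file.
#' @return a `data.frame` with one row per sample.
#' @export
read_metadata <- function(path) {
  if (!file.exists(path))
    stop("file not found: ", path, call. = FALSE)
  df <- read.delim(path, comment.char = "#", check.names = FALSE,
                   sep = "\t", stringsAsFactors = FALSE)
  validate_metadata(df)
}

#' Validate a metadata data frame
#'
#' @param df data.frame of per-sample metadata.
#' @param table optional [count_table]; when given, every sample in the
#'   table must have exactly one metadata row.
#' @return the validated data.frame (optional columns completed), with
#'   rows ordered to match `table` when supplied.
#' @export
validate_metadata <- function(df, table = NULL) {
  required <- c("sample_id", "biomass_mass", "mc_dose_fraction")
  missing <- setdiff(required, names(df))
  if (length(missing))
    stop("metadata is missing required column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  if (anyDuplicated(df$sample_id))
    stop("duplicate sample_id in metadata", call. = FALSE)
  for (col in c("biomass_mass", "mc_dose_fraction")) {
    v <- df[[col]]
    if (!is.numeric(v) || anyNA(v) || any(v < 0))
      stop("metadata column '", col, "' must be non-negative numeric",
           call. = FALSE)
  }
  for (col in c("pool_id", "replicate_label", "condition"))
    if (is.null(df[[col]])) df[[col]] <- NA_character_
  df$no_mc <- df$mc_dose_fraction == 0
  if (!is.null(table)) {
    ids <- sample_ids(table)
    missing <- setdiff(ids, df$sample_id)
    if (length(missing))
      stop("metadata has no row for sample(s): ",
           paste(missing, collapse = ", "), call. = FALSE)
    df <- df[match(ids, df$sample_id), , drop = FALSE]
  }
  rownames(df) <- df$sample_id
  df
}

#' Read and write SV representative sequences (FASTA)
#'
#' Sequences are stored as an uppercase [Biostrings::DNAStringSet] named
#' by SV id.
#'
#' @param path FASTA file.
#' @return a `DNAStringSet`.
#' @export
read_sv_sequences <- function(path) {
  if (!file.exists(path))
    stop("file not found: ", path, call. = FALSE)
  s <- Biostrings::readDNAStringSet(path)
  names(s) <- sub("\\s.*$", "", names(s))
  if (any(Biostrings::width(s) == 0))
    stop("empty sequence in ", path, call. = FALSE)
  if (anyDuplicated(names(s)))
    stop("duplicate sequence ids in ", path, call. = FALSE)
  s
}

#' @rdname read_sv_sequences
#' @param seqs named character vector or `DNAStringSet`.
#' @export
write_sv_sequences <- function(seqs, path) {
  if (!methods::is(seqs, "DNAStringSet"))
    seqs <- Biostrings::DNAStringSet(seqs)
  Biostrings::writeXStringSet(seqs, path)
  invisible(path)
}

#' Read a pipeline configuration file
#'
#' Thin wrapper around [yaml::read_yaml()]; see [run_pipeline()] for the
#' recognised fields.
#' @param path YAML file.
#' @return a nested list.
#' @export
read_config <- function(path) {
  if (!file.exists(path))
    stop("config file not found: ", path, call. = FALSE)
  yaml::read_yaml(path)
}
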