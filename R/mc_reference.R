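#' Define a mock-community reference set
#'
#' Each reference describes one mock-community taxon: its name, gram
#' status, reference 16S sequence, and the number of 16S gene copies and
#' cells contained in one manufacturer dose. The per-taxon ratio
#' copies-per-dose / cells-per-dose is the genomic 16S copy number and
#' must be a positive integer.
#'
#' @param taxon character vector of taxon names.
#' @param gram `"negative"` or `"positive"` per taxon.
#' @param copies_per_dose 16S gene copies contained in one dose.
#' @param cells_per_dose cells contained in one dose.
#' @param sequences named character vector or `DNAStringSet` of
#'   reference 16S sequences; names must match `taxon`.
#' @return a `data.frame` of class `mc_references` with one row per
#'   taxon and a character `sequence` column.
#' @seealso [zymo_spikein_references()] for the default two-taxon set.
#' @export
mc_references <- function(taxon, gram, copies_per_dose, cells_per_dose,
                          sequences) {
  stopifnot(length(taxon) == length(gram),
            length(taxon) == length(copies_per_dose),
            length(taxon) == length(cells_per_dose))
  if (anyDuplicated(taxon))
    stop("duplicate taxon names in MC references", call. = FALSE)
  if (!all(gram %in% c("negative", "positive")))
    stop("gram must be 'negative' or 'positive'", call. = FALSE)
  if (any(copies_per_dose <= 0) || any(cells_per_dose <= 0))
    stop("copies_per_dose and cells_per_dose must be positive",
         call. = FALSE)
  gcn <- copies_per_dose / cells_per_dose
  if (any(abs(gcn - round(gcn)) > 1e-6) || any(round(gcn) < 1))
    stop("copies_per_dose / cells_per_dose must be a positive integer ",
         "(per-genome 16S copy number)", call. = FALSE)
  if (methods::is(sequences, "DNAStringSet"))
    sequences <- as.character(sequences)
  sequences <- toupper(sequences)
  if (is.null(names(sequences)))
    names(sequences) <- taxon
  missing <- setdiff(taxon, names(sequences))
  if (length(missing))
    stop("no reference sequence for taxon: ",
         paste(missing, collapse = ", "), call. = FALSE)
  if (any(nchar(sequences[taxon]) == 0))
    stop("reference sequences must be non-empty", call. = FALSE)
  out <- data.frame(taxon = taxon, gram = gram,
                    copies_per_dose = copies_per_dose,
                    cells_per_dose = cells_per_dose,
                    genome_16s_copies = round(gcn),
                    sequence = unname(sequences[taxon]),
                    stringsAsFactors = FALSE)
  rownames(out) <- taxon
  class(out) <- c("mc_references", "data.frame")
  out
}

#' Default two-taxon spike-in reference set
#'
#' The widely used commercial spike-in pair: gram-negative
#' *Imtechella halotolerans* (6.0e7 16S copies from 2e7 cells per dose;
#' 3 copies per genome) and gram-positive *Allobacillus halotolerans*
#' (1.4e8 copies from 2e7 cells; 7 copies per genome). The expected
#' gram-negative : gram-positive copy ratio is therefore
#' 6.0e7 / 1.4e8 = 0.43. Reference 16S sequences must be supplied by
#' the caller (e.g. downloaded from GenBank, or the synthetic pair from
#' [example_mc_references()]).
#'
#' @param sequences named character vector or `DNAStringSet` with
#'   entries `"Imtechella halotolerans"` and `"Allobacillus
#'   halotolerans"` (extra names are ignored).
#' @return an `mc_references` data frame.
#' @export
zymo_spikein_references <- function(sequences) {
  taxa <- c("Imtechella halotolerans", "Allobacillus halotolerans")
  if (methods::is(sequences, "DNAStringSet"))
    sequences <- as.character(sequences)
  mc_references(taxon = taxa,
                gram = c("negative", "positive"),
                copies_per_dose = c(6.0e7, 1.4e8),
                cells_per_dose = c(2e7, 2e7),
                sequences = sequences[taxa])
}

#' Synthetic example reference sequences
#'
#' Loads a pair of synthetic 16S-like reference sequences shipped with
#' the package (file `mc_refs_synthetic.fasta`). These are
#' randomly generated stand-ins for the public reference accessions of
#' the two spike-in taxa, suitable for examples and for pairing with
#' [simulate_experiment()] outputs, not for analysing real data.
#'
#' @return an `mc_references` data frame with the default dose
#'   constants and synthetic sequences.
#' @export
example_mc_references <- function() {
  path <- system.file("extdata", "mc_refs_synthetic.fasta",
                      package = "spikeline", mustWork = TRUE)
  s <- Biostrings::readDNAStringSet(path)
  # header format: "<id> <Genus> <species> ..." -> name by binomial
  names(s) <- sub("^\\S+\\s+(\\S+\\s+\\S+).*$", "\\1", names(s))
  zymo_spikein_references(s)
}

gram_negative_taxon <- function(refs) {
  i <- which(refs$gram == "negative")
  if (!length(i)) stop("no gram-negative reference taxon", call. = FALSE)
  refs$taxon[i[1]]
}

gram_positive_taxon <- function(refs) {
  i <- which(refs$gram == "positive")
  if (!length(i)) stop("no gram-positive reference taxon", call. = FALSE)
  refs$taxon[i[1]]
}
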