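#' Read a proteome FASTA into a tibble
#'
#' Reads a (possibly line-wrapped) multi-record amino-acid FASTA and returns
#' the tabular form used throughout the package. Record ids are the first
#' whitespace-delimited token of each header.
#'
#' @param path Path to a FASTA file.
#' @return Tibble with columns `protein_id`, `sequence`.
#' @export
read_proteome <- function(path) {
  aa <- Biostrings::readAAStringSet(path)
  if (length(aa) == 0) stop("FASTA contains no records: ", path, call. = FALSE)
  ids <- sub("\\s.*$", "", names(aa))
  tibble::tibble(protein_id = ids, sequence = unname(toupper(as.character(aa))))
}

#' Write a proteome tibble to FASTA
#'
#' @param proteome Tibble with `protein_id` and `sequence` columns (or a
#'   named character vector).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_proteome <- function(proteome, path) {
  proteome <- as_proteome(proteome)
  aa <- Biostrings::AAStringSet(stats::setNames(proteome$sequence, proteome$protein_id))
  Biostrings::writeXStringSet(aa, path)
  invisible(path)
}

# Plain TSV readers/writers; tab-separated, header row, no quoting needed for
# the package's sequence/score tables.
read_tsv_strict <- function(path, ...) {
  tibble::as_tibble(utils::read.delim(path, stringsAsFactors = FALSE, ...))
}

write_tsv_plain <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
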