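#' Extract the T cell exposed motif (TCEM) of an epitope peptide
#'
#' The TCEM is the five-residue stretch of an HLA class I bound peptide that
#' contacts the TCR CDR3 region: positions 4-8 of a 9-mer or positions 5-9
#' of a 10-mer (1-based, fully closed).
#'
#' @param peptide Character vector of 9- or 10-mer peptides over the 20
#'   standard amino-acid letters.
#' @return Character vector of 5-letter motifs, same length as `peptide`.
#' @examples
#' extract_tcem("ACDEFGHIK")   # "EFGHI"
#' extract_tcem("ACDEFGHIKL")  # "FGHIK"
#' @export
extract_tcem <- function(peptide) {
  assert_peptides(peptide)
  start <- ifelse(nchar(peptide) == 9L, 4L, 5L)
  substr(peptide, start, start + 4L)
}

#' Build a TCEM occurrence index from a proteome
#'
#' Decomposes every protein into overlapping 9-mers and records the TCEM
#' (positions 4-8) of each window. A motif occurrence is one 9-mer window:
#' a pentamer within 3 residues of the N terminus or within 1 residue of the
#' C terminus has no complete 9-mer context and does not count. Windows that
#' contain any non-standard letter (X, U, B, Z, ...) are skipped and tallied.
#'
#' @param proteome A named character vector of protein sequences, a
#'   data frame with columns `protein_id` and `sequence`, or a
#'   [Biostrings::AAStringSet].
#' @return An object of class `tcem_index`: a list with
#'   \describe{
#'     \item{occurrences}{tibble with columns `motif`, `protein_id`,
#'       `start` (1-based start of the 9-mer window).}
#'     \item{counts}{tibble with columns `motif`, `n`.}
#'     \item{n_windows}{total number of valid 9-mer windows.}
#'     \item{n_skipped}{windows skipped for non-standard letters.}
#'     \item{proteins}{tibble with `protein_id`, `length`.}
#'   }
#' @examples
#' idx <- build_proteome_index(c(p1 = "ACDEFGHIK", p2 = "AAAAAAAAAA"))
#' tidy(idx)
#' @export
build_proteome_index <- function(proteome) {
  proteome <- as_proteome(proteome)
  if (nrow(proteome) == 0) {
    stop("proteome contains no protein records", call. = FALSE)
  }
  if (anyDuplicated(proteome$protein_id)) {
    stop("duplicate protein ids in proteome", call. = FALSE)
  }

  occ <- purrr::map2(proteome$protein_id, proteome$sequence, function(id, seq) {
    L <- nchar(seq)
    if (L < 9L) return(NULL)
    starts <- seq_len(L - 8L)
    windows <- substring(seq, starts, starts + 8L)
    ok <- is_standard_aa(windows)
    tibble::tibble(
      motif = substring(seq, starts[ok] + 3L, starts[ok] + 7L),
      protein_id = rep(id, sum(ok)),
      start = starts[ok]
    )
  })
  occurrences <- dplyr::bind_rows(occ)
  if (nrow(occurrences) == 0) {
    occurrences <- tibble::tibble(
      motif = character(), protein_id = character(), start = integer()
    )
  }
  total_windows <- sum(pmax(0L, nchar(proteome$sequence) - 8L))
  n_skipped <- total_windows - nrow(occurrences)
  counts <- dplyr::count(occurrences, .data$motif, name = "n")

  structure(
    list(
      occurrences = occurrences,
      counts = counts,
      n_windows = nrow(occurrences),
      n_skipped = n_skipped,
      proteins = tibble::tibble(
        protein_id = proteome$protein_id,
        length = nchar(proteome$sequence)
      )
    ),
    class = "tcem_index"
  )
}

as_proteome <- function(proteome) {
  if (inherits(proteome, "AAStringSet")) {
    proteome <- stats::setNames(as.character(proteome), names(proteome))
  }
  if (is.character(proteome)) {
    if (is.null(names(proteome)) || any(names(proteome) == "")) {
      stop("protein sequences must be named (protein ids)", call. = FALSE)
    }
    proteome <- tibble::tibble(
      protein_id = names(proteome),
      sequence = unname(proteome)
    )
  }
  if (!is.data.frame(proteome) ||
      !all(c("protein_id", "sequence") %in% names(proteome))) {
    stop("proteome must have columns `protein_id` and `sequence`", call. = FALSE)
  }
  tibble::as_tibble(proteome[c("protein_id", "sequence")]) |>
    dplyr::mutate(sequence = toupper(.data$sequence))
}

#' @export
print.tcem_index <- function(x, ...) {
  cat(
    sprintf(
      "<tcem_index> %d proteins, %d windows, %d distinct motifs (%d skipped windows)\n",
      nrow(x$proteins), x$n_windows, nrow(x$counts), x$n_skipped
    )
  )
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @describeIn build_proteome_index `tidy()` returns the per-motif count table.
#' @param x A `tcem_index`.
#' @param ... Unused.
#' @method tidy tcem_index
#' @export
tidy.tcem_index <- function(x, ...) x$counts

#' @describeIn build_proteome_index `glance()` returns a one-row summary
#'   (protein, window, motif counts and pentamer-space coverage).
#' @method glance tcem_index
#' @export
glance.tcem_index <- function(x, ...) {
  tibble::tibble(
    n_proteins = nrow(x$proteins),
    n_windows = x$n_windows,
    n_motifs = nrow(x$counts),
    n_skipped = x$n_skipped,
    coverage = pentamer_space_coverage(x)
  )
}

#' TCEM frequency in an indexed proteome
#'
#' Number of 9-mer windows of the indexed proteome whose TCEM equals the
#' query motif; 0 for motifs absent from the proteome.
#'
#' @param index A `tcem_index` from [build_proteome_index()].
#' @param motif Character vector of 5-letter motifs.
#' @return Integer vector of counts, same length as `motif`.
#' @export
tcem_frequency <- function(index, motif) {
  stopifnot(inherits(index, "tcem_index"))
  if (any(nchar(motif) != 5L) || any(!is_standard_aa(motif))) {
    stop("motifs must be 5 standard amino-acid letters", call. = FALSE)
  }
  n <- index$counts$n[match(motif, index$counts$motif)]
  as.integer(ifelse(is.na(n), 0L, n))
}

#' Classify motif frequency as rare or nonrare
#'
#' Motifs occurring fewer than `threshold` times in the human proteome are
#' unlikely to be presented on the cTEC surface and hence unlikely to have
#' mediated positive selection; the default boundary is 4 (counts 0-3 are
#' "rare").
#'
#' @param count Non-negative integer vector of proteome counts.
#' @param threshold Rare/nonrare boundary; rare iff `count < threshold`.
#' @return Factor with levels `rare`, `nonrare`.
#' @examples
#' classify_frequency(c(0, 3, 4, 100))
#' @export
classify_frequency <- function(count, threshold = 4L) {
  if (any(count < 0)) stop("counts must be non-negative", call. = FALSE)
  factor(
    ifelse(count < threshold, "rare", "nonrare"),
    levels = c("rare", "nonrare")
  )
}

#' Fraction of the pentamer space present in a proteome
#'
#' Fraction of all 20^5 = 3,200,000 possible pentamers that occur at least
#' once as a TCEM in the indexed proteome.
#'
#' @param index A `tcem_index`.
#' @return A fraction in \[0, 1\].
#' @export
pentamer_space_coverage <- function(index) {
  stopifnot(inherits(index, "tcem_index"))
  nrow(index$counts) / tcem_space_size()
}

#' Size of the TCEM motif space
#'
#' Counts the pentamers over the 20-letter standard alphabet by explicit
#' enumeration of the five positions (20^5 = 3,200,000).
#'
#' @param enumerate If `TRUE` (default), the count is obtained by
#'   enumerating position combinations rather than as a power.
#' @return Integer count of possible TCEMs.
#' @export
tcem_space_size <- function(enumerate = TRUE) {
  if (!enumerate) return(as.integer(20L^5))
  n <- 1L
  for (pos in 1:5) n <- n * length(AA_STANDARD)
  n
}

#' Enumerate all pentamer motifs
#'
#' Returns every 5-letter motif over the standard alphabet. The full space
#' has 3.2 million members; `limit` guards against accidental generation.
#'
#' @param limit Safety cap on the number of motifs generated.
#' @return Character vector of all pentamers in lexicographic order.
#' @export
all_tcems <- function(limit = 3.3e6) {
  size <- tcem_space_size(enumerate = FALSE)
  if (size > limit) stop("motif space larger than `limit`", call. = FALSE)
  grid <- expand.grid(
    p5 = AA_STANDARD, p4 = AA_STANDARD, p3 = AA_STANDARD,
    p2 = AA_STANDARD, p1 = AA_STANDARD,
    stringsAsFactors = FALSE
  )
  paste0(grid$p1, grid$p2, grid$p3, grid$p4, grid$p5)
}
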