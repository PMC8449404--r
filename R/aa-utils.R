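#' @keywords internal
#' @importFrom rlang .data
#' @importFrom tibble tibble
"_PACKAGE"

#' The 20 standard amino-acid one-letter codes
#'
#' Alphabetical one-letter codes of the 20 standard proteinogenic amino
#' acids. The TCEM motif space is this alphabet to the fifth power
#' (20^5 = 3,200,000 motifs).
#'
#' @format A character vector of length 20.
#' @export
AA_STANDARD <- c(
  "A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
  "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y"
)

# Kyte-Doolittle hydropathy values, used for TCEM hydrophobicity and for the
# hydrophobic residue set in the synthetic cleavage tables.
KYTE_DOOLITTLE <- c(
  A = 1.8, C = 2.5, D = -3.5, E = -3.5, F = 2.8, G = -0.4, H = -3.2,
  I = 4.5, K = -3.9, L = 3.8, M = 1.9, N = -3.5, P = -1.6, Q = -3.5,
  R = -4.5, S = -0.8, T = -0.7, V = 4.2, W = -0.9, Y = -1.3
)

# Hydrophobic residues (Kyte-Doolittle > 0): A, C, F, I, L, M, V.
AA_HYDROPHOBIC <- names(KYTE_DOOLITTLE)[KYTE_DOOLITTLE > 0]

.tcemr_cache <- new.env(parent = emptyenv())

# BLOSUM62 restricted to the 20 standard letters, row/column order AA_STANDARD.
blosum62_matrix <- function() {
  if (is.null(.tcemr_cache$blosum62)) {
    env <- new.env()
    utils::data("BLOSUM62", package = "Biostrings", envir = env)
    .tcemr_cache$blosum62 <- env$BLOSUM62[AA_STANDARD, AA_STANDARD]
  }
  .tcemr_cache$blosum62
}

is_standard_aa <- function(x) {
  !is.na(x) & !grepl(sprintf("[^%s]", paste(AA_STANDARD, collapse = "")), x)
}

# Integer codes 1..20 per residue; NA for non-standard letters.
aa_codes <- function(seq) {
  match(strsplit(seq, "", fixed = TRUE)[[1]], AA_STANDARD)
}

assert_peptides <- function(peptides, lengths = c(9L, 10L)) {
  if (!is.character(peptides) || length(peptides) == 0) {
    stop("`peptides` must be a non-empty character vector", call. = FALSE)
  }
  bad_len <- !(nchar(peptides) %in% lengths)
  if (any(bad_len)) {
    stop(
      sprintf(
        "peptide length must be in {%s}; offending: %s",
        paste(lengths, collapse = ","),
        paste(utils::head(peptides[bad_len], 3), collapse = ", ")
      ),
      call. = FALSE
    )
  }
  bad_aa <- !is_standard_aa(peptides)
  if (any(bad_aa)) {
    stop(
      sprintf(
        "peptides must contain only the 20 standard amino-acid letters; offending: %s",
        paste(utils::head(peptides[bad_aa], 3), collapse = ", ")
      ),
      call. = FALSE
    )
  }
  invisible(peptides)
}

#' Mean Kyte-Doolittle hydrophobicity of a motif
#'
#' Average per-residue hydropathy over the positions of a motif (typically
#' the 5 TCR-contact residues of a TCEM), on the Kyte-Doolittle scale.
#' Used as a covariate when checking that immunogenicity associations are
#' not explained by the hydrophobicity of TCR contact residues.
#'
#' @param motif Character vector of motifs (standard letters only).
#' @return Numeric vector of mean hydropathy values.
#' @examples
#' tcem_hydrophobicity(c("IIIII", "RRRRR", "AIAIA"))
#' @export
tcem_hydrophobicity <- function(motif) {
  if (any(!is_standard_aa(motif))) {
    stop("motifs must contain only standard amino-acid letters", call. = FALSE)
  }
  vapply(
    strsplit(motif, "", fixed = TRUE),
    function(a) mean(KYTE_DOOLITTLE[a]),
    numeric(1)
  )
}
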