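#' Assemble a per-motif attribute profile
#'
#' Joins the proteome frequency counts with per-motif cTEC expression and
#' thymo-/immunoproteasomal cleavage scores into the single attribute
#' table used by the immunogenicity, repertoire and pathogen analyses.
#' Motifs are the ones occurring in the indexed proteome; missing
#' attributes are `NA`.
#'
#' @param index A `tcem_index` of the reference (human) proteome.
#' @param expression Optional tibble from [tcem_expression()].
#' @param thymo,immuno Optional tibbles from
#'   [proteome_cleavage_scores()] for the two proteasome types.
#' @return Tibble with `motif`, `count` and whichever of `expression`,
#'   `n_values`, `thymo_score`, `immuno_score` were supplied.
#' @export
tcem_profile <- function(index, expression = NULL, thymo = NULL, immuno = NULL) {
  stopifnot(inherits(index, "tcem_index"))
  out <- dplyr::rename(index$counts, count = "n")
  if (!is.null(expression)) {
    out <- dplyr::left_join(out, expression, by = "motif")
  }
  if (!is.null(thymo)) {
    out <- dplyr::left_join(
      out,
      dplyr::select(thymo, "motif", thymo_score = "score"),
      by = "motif"
    )
  }
  if (!is.null(immuno)) {
    out <- dplyr::left_join(
      out,
      dplyr::select(immuno, "motif", immuno_score = "score"),
      by = "motif"
    )
  }
  out
}
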