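#' Position-specific cleavage preference scores
#'
#' Normalizes the amino-acid prevalence observed at the five positions on
#' each side of proteasomal cleavage sites by the amino-acid composition of
#' the digested substrates: `c[i, j] = prevalence[i, j] / background[j]`
#' for positions i in \{-5..-1, 1..5\} and the 20 standard residues j.
#' A uniform experiment (prevalence equal to background everywhere) gives
#' all scores 1.
#'
#' @param prevalence Tibble with columns `position` (integer in -5..-1,
#'   1..5), `amino_acid`, `prevalence` (per-position fractions summing
#'   to 1).
#' @param background Tibble with columns `amino_acid`, `fraction`
#'   (substrate composition, summing to 1).
#' @return Tibble with columns `position`, `amino_acid`, `c`.
#' @export
preference_scores <- function(prevalence, background) {
  positions <- c(-5:-1, 1:5)
  stopifnot(all(prevalence$position %in% positions))
  sums <- dplyr::summarise(
    prevalence,
    s = sum(.data$prevalence), .by = "position"
  )
  if (any(abs(sums$s - 1) > 1e-6)) {
    stop("per-position prevalences must sum to 1", call. = FALSE)
  }
  scores <- dplyr::left_join(prevalence, background, by = "amino_acid")
  bad <- scores$prevalence > 0 & (is.na(scores$fraction) | scores$fraction == 0)
  if (any(bad)) {
    stop(
      sprintf(
        "zero/missing background with nonzero prevalence at (%d, %s)",
        scores$position[bad][1], scores$amino_acid[bad][1]
      ),
      call. = FALSE
    )
  }
  scores |>
    dplyr::mutate(c = ifelse(.data$prevalence == 0 & is.na(.data$fraction),
      0, .data$prevalence / .data$fraction
    )) |>
    dplyr::select("position", "amino_acid", "c")
}

# Dense 10 x 20 matrix form (rows: positions -5..-1,1..5; cols AA_STANDARD)
# for fast per-protein scoring. Missing (position, aa) combinations score 0
# prevalence -> c = 0.
pref_matrix <- function(scores) {
  positions <- c(-5:-1, 1:5)
  m <- matrix(0, nrow = 10, ncol = 20,
    dimnames = list(as.character(positions), AA_STANDARD))
  m[cbind(
    match(scores$position, positions),
    match(scores$amino_acid, AA_STANDARD)
  )] <- scores$c
  m
}

#' Per-site proteasomal cleavage scores of a protein
#'
#' Site s lies between residues s and s+1 (s = 1..L-1). Its score C is the
#' median of the preference scores `c[i, j]` of the residues at offsets
#' -5..-1 (positions s-4..s) and +1..+5 (positions s+1..s+5) that exist
#' within the protein; near a terminus the median runs over the available
#' positions only (at least one per side by construction).
#'
#' @param sequence A single protein sequence (standard letters).
#' @param scores Preference-score tibble from [preference_scores()].
#' @param require_full_context If `TRUE`, sites with fewer than the full 10
#'   flanking positions are `NA` instead of using the available subset.
#' @return Tibble with columns `site`, `score`.
#' @export
site_cleavage_scores <- function(sequence, scores, require_full_context = FALSE) {
  L <- nchar(sequence)
  if (L < 2) stop("protein must have length >= 2", call. = FALSE)
  m <- if (is.matrix(scores)) scores else pref_matrix(scores)
  codes <- aa_codes(sequence)
  if (anyNA(codes)) stop("non-standard letters in sequence", call. = FALSE)
  sites <- seq_len(L - 1L)
  offsets <- c(-5:-1, 1:5)
  # residue position contributing offset i at site s: s + i + (i < 0)
  vals <- matrix(NA_real_, nrow = 10, ncol = L - 1L)
  for (k in seq_along(offsets)) {
    pos <- sites + offsets[k] + as.integer(offsets[k] < 0)
    inside <- pos >= 1L & pos <= L
    vals[k, inside] <- m[k, codes[pos[inside]]]
  }
  score <- apply(vals, 2, function(v) {
    v <- v[!is.na(v)]
    if (length(v) == 0) NA_real_ else stats::median(v)
  })
  if (require_full_context) score[colSums(!is.na(vals)) < 10] <- NA_real_
  tibble::tibble(site = sites, score = score)
}

#' Peptide-formation scores for the 9-mer windows of a protein
#'
#' A 9-mer starting at position p is liberated by cleavage at the site
#' before its N-terminal residue (site p-1) and the site after its
#' C-terminal residue (site p+8); the formation score is the mean of the
#' two site scores. Windows at a protein terminus lack an interior flanking
#' site and are excluded by default (`NA`); set `terminal` to
#' `"cleaved"` to treat the free terminus as an already-cleaved site with
#' C = 1.
#'
#' @param sequence A single protein sequence.
#' @param sites Tibble from [site_cleavage_scores()] for the same protein.
#' @param terminal `"exclude"` (default) or `"cleaved"`.
#' @return Tibble with columns `start`, `motif`, `cbar` (`NA` when
#'   excluded).
#' @export
formation_scores <- function(sequence, sites, terminal = c("exclude", "cleaved")) {
  terminal <- match.arg(terminal)
  L <- nchar(sequence)
  if (L < 9) {
    return(tibble::tibble(start = integer(), motif = character(), cbar = double()))
  }
  starts <- seq_len(L - 8L)
  site_score <- sites$score
  n_side <- ifelse(starts == 1L, NA_real_, site_score[pmax(starts - 1L, 1L)])
  c_side <- ifelse(starts + 8L > L - 1L, NA_real_, site_score[pmin(starts + 8L, L - 1L)])
  if (terminal == "cleaved") {
    n_side[starts == 1L] <- 1
    c_side[starts + 8L > L - 1L] <- 1
  }
  tibble::tibble(
    start = starts,
    motif = substring(sequence, starts + 3L, starts + 7L),
    cbar = (n_side + c_side) / 2
  )
}

#' Per-TCEM proteasomal cleavage scores over a proteome
#'
#' Runs the full cascade (preference scores, per-site medians, per-window
#' formation scores) over every protein and aggregates to motifs: each
#' motif's score is the median formation score of the 9-mer windows whose
#' TCEM it is. Run once per proteasome type (thymo/immuno differ only in
#' the preference table).
#'
#' @param proteome Proteome accepted by [build_proteome_index()].
#' @param prevalence,background Preference inputs, see [preference_scores()].
#' @param terminal Terminal-window rule, see [formation_scores()].
#' @return Tibble with columns `motif`, `score`, `n_windows` (windows with
#'   a defined formation score).
#' @export
proteome_cleavage_scores <- function(proteome, prevalence, background,
                                     terminal = c("exclude", "cleaved")) {
  terminal <- match.arg(terminal)
  proteome <- as_proteome(proteome)
  m <- pref_matrix(preference_scores(prevalence, background))
  per_window <- purrr::map(proteome$sequence, function(seq) {
    if (nchar(seq) < 9 || !is_standard_aa(seq)) return(NULL)
    sites <- site_cleavage_scores(seq, m)
    formation_scores(seq, sites, terminal = terminal)
  })
  dplyr::bind_rows(per_window) |>
    dplyr::filter(!is.na(.data$cbar)) |>
    dplyr::summarise(
      score = stats::median(.data$cbar),
      n_windows = dplyr::n(),
      .by = "motif"
    )
}

#' Stratify cleavage scores at the first quartile
#'
#' Motifs below the first quartile of the score distribution are "low"
#' (unlikely to be liberated by the proteasome type in question); scores
#' equal to the quartile are "normal" (strict-less convention). Quartiles
#' use linear interpolation (type 7).
#'
#' @param scores Numeric vector of per-motif cleavage scores.
#' @param quantile Probability defining the low/normal boundary.
#' @return Factor with levels `low`, `normal`.
#' @export
stratify_cleavage <- function(scores, quantile = 0.25) {
  ok <- !is.na(scores)
  if (sum(ok) < 4) stop("need at least 4 defined scores", call. = FALSE)
  q1 <- stats::quantile(scores[ok], quantile, type = 7, names = FALSE)
  if (q1 == min(scores[ok])) warning("degenerate score distribution: no scores below Q1")
  out <- rep(NA_character_, length(scores))
  out[ok] <- ifelse(scores[ok] < q1, "low", "normal")
  factor(out, levels = c("low", "normal"))
}
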