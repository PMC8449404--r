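#' Eligible allele-peptide pairs for the repertoire analysis
#'
#' An allele-peptide pair enters the naive CD8+ repertoire analysis when
#' the binding prediction indicates strong binding (affinity < 50 nM and
#' rank percentile < 0.5) and specific T cells were found in at least two
#' individuals carrying the allele.
#'
#' @param predictions Tibble with `peptide`, `allele`, `affinity_nm`,
#'   `rank_pct`.
#' @param recognition Tibble with `individual`, `peptide`, `recognized`
#'   (logical).
#' @param genotypes Tibble with `individual`, `allele` (one row per
#'   carried allele).
#' @param affinity_nm,rank_pct,min_carriers Eligibility thresholds.
#' @return Tibble with `peptide`, `allele` for the eligible pairs.
#' @export
eligible_pairs <- function(predictions, recognition, genotypes,
                           affinity_nm = 50, rank_pct = 0.5,
                           min_carriers = 2L) {
  strong <- predictions |>
    dplyr::filter(.data$affinity_nm < !!affinity_nm, .data$rank_pct < !!rank_pct)
  carriers <- recognition |>
    dplyr::filter(.data$recognized) |>
    dplyr::inner_join(genotypes, by = "individual",
      relationship = "many-to-many") |>
    dplyr::summarise(
      n_carriers = dplyr::n_distinct(.data$individual),
      .by = c("peptide", "allele")
    )
  strong |>
    dplyr::inner_join(carriers, by = c("peptide", "allele")) |>
    dplyr::filter(.data$n_carriers >= min_carriers) |>
    dplyr::select("peptide", "allele")
}

#' Per-individual recognized fractions by TCEM attribute group
#'
#' For each individual, the presented peptides are those with at least one
#' eligible allele-peptide pair whose allele the individual carries. Within
#' each TCEM attribute group the fraction of presented peptides recognized
#' by the individual's repertoire is reported. Individuals with fewer than
#' `min_recognized` recognized presented peptides are excluded.
#'
#' @param recognition,genotypes As in [eligible_pairs()].
#' @param eligible Eligible pairs from [eligible_pairs()].
#' @param peptide_groups Tibble with `peptide`, `group` (one row per
#'   peptide per grouping variable value).
#' @param min_recognized Inclusion threshold on recognized presented
#'   peptides per individual.
#' @return Tibble with `individual`, `group`, `n_presented`,
#'   `n_recognized`, `fraction` (`NA` when nothing is presented in a
#'   group).
#' @export
per_individual_fractions <- function(recognition, genotypes, eligible,
                                     peptide_groups, min_recognized = 20L) {
  presented <- genotypes |>
    dplyr::inner_join(eligible, by = "allele", relationship = "many-to-many") |>
    dplyr::distinct(.data$individual, .data$peptide)
  rec <- recognition |>
    dplyr::filter(.data$recognized) |>
    dplyr::distinct(.data$individual, .data$peptide)
  presented <- presented |>
    dplyr::mutate(recognized = paste(.data$individual, .data$peptide) %in%
      paste(rec$individual, rec$peptide))
  included <- presented |>
    dplyr::summarise(n_rec = sum(.data$recognized), .by = "individual") |>
    dplyr::filter(.data$n_rec >= min_recognized)
  presented |>
    dplyr::filter(.data$individual %in% included$individual) |>
    dplyr::inner_join(peptide_groups, by = "peptide",
      relationship = "many-to-many") |>
    dplyr::summarise(
      n_presented = dplyr::n(),
      n_recognized = sum(.data$recognized),
      fraction = mean(.data$recognized),
      .by = c("individual", "group")
    )
}

#' Paired comparison of per-individual fractions between two groups
#'
#' Two-sided paired Wilcoxon signed-rank test on the per-individual
#' recognized fractions of two TCEM attribute groups, over individuals
#' with both fractions defined.
#'
#' @param fractions Tibble from [per_individual_fractions()].
#' @param group_a,group_b The two group labels to compare.
#' @param min_pairs Minimum complete pairs required.
#' @return Tibble with `p_value`, `direction` (sign of median
#'   `group_a - group_b` difference), `n_pairs`.
#' @export
paired_group_comparison <- function(fractions, group_a, group_b,
                                    min_pairs = 6L) {
  wide <- fractions |>
    dplyr::filter(.data$group %in% c(group_a, group_b)) |>
    dplyr::select("individual", "group", "fraction") |>
    tidyr::pivot_wider(names_from = "group", values_from = "fraction") |>
    dplyr::filter(!is.na(.data[[group_a]]), !is.na(.data[[group_b]]))
  if (nrow(wide) < min_pairs) {
    stop(sprintf("only %d complete pairs (need >= %d)", nrow(wide), min_pairs),
      call. = FALSE
    )
  }
  res <- ranksum_test(wide[[group_a]], wide[[group_b]], paired = TRUE)
  dplyr::mutate(res, n_pairs = nrow(wide))
}

#' Cutoffs for the np-TCEM definition from a human motif profile
#'
#' "Low expression" is the bottom-tertile boundary of the defined human
#' TCEM expression values; "low thymoproteasomal cleavage" is the first
#' quartile of the human TCEM thymo scores (the same stratification used
#' for the repertoire analysis).
#'
#' @param profile Tibble with (at least) `expression` and `thymo_score`
#'   columns over human-proteome motifs.
#' @return List with `expression` and `thymo` cutoff values.
#' @export
np_cutoffs <- function(profile) {
  expr <- profile$expression[!is.na(profile$expression)]
  thymo <- profile$thymo_score[!is.na(profile$thymo_score)]
  list(
    expression = stats::quantile(expr, 1 / 3, type = 7, names = FALSE),
    thymo = stats::quantile(thymo, 0.25, type = 7, names = FALSE)
  )
}

#' Flag motifs not expected to mediate positive selection (np-TCEMs)
#'
#' A motif is an np-TCEM when any of three criteria fires: it occurs fewer
#' than `freq_threshold` times in the human proteome, its cTEC expression
#' is below the expression cutoff, or its thymoproteasomal cleavage score
#' is below the thymo cutoff. Motifs with undefined expression (no mapped
#' encoding gene) are treated as low expression by default — they cannot
#' mediate positive selection through expression.
#'
#' @param profile Tibble with `motif`, `count`, `expression`,
#'   `thymo_score`.
#' @param cutoffs List from [np_cutoffs()] (elements `expression`,
#'   `thymo`).
#' @param freq_threshold Rare-frequency boundary.
#' @param missing_expression `"low"` (default) or `"ignore"` for motifs
#'   with `NA` expression.
#' @return `profile` with added logical columns `np_freq`, `np_expr`,
#'   `np_cleav`, `is_np`.
#' @export
np_flag <- function(profile, cutoffs, freq_threshold = 4L,
                    missing_expression = c("low", "ignore")) {
  missing_expression <- match.arg(missing_expression)
  low_expr_na <- missing_expression == "low"
  profile |>
    dplyr::mutate(
      np_freq = .data$count < freq_threshold,
      np_expr = dplyr::coalesce(.data$expression < cutoffs$expression, low_expr_na),
      np_cleav = dplyr::coalesce(.data$thymo_score < cutoffs$thymo, FALSE),
      is_np = .data$np_freq | .data$np_expr | .data$np_cleav
    )
}

#' Fraction of np-TCEMs in a pathogen proteome
#'
#' Decomposes the pathogen proteome into 9-mer windows, takes each
#' window's TCEM, and reports the fraction flagged np. Motifs absent from
#' the human profile have human frequency 0 and count as np. Windows are
#' the default unit ("prevalence in the proteome"); `distinct = TRUE`
#' counts each distinct motif once instead.
#'
#' @param pathogen Proteome accepted by [build_proteome_index()].
#' @param np_profile Tibble with `motif`, `is_np` over human motifs.
#' @param distinct Count distinct motifs instead of windows.
#' @return A fraction in \[0, 1\].
#' @export
pathogen_np_fraction <- function(pathogen, np_profile, distinct = FALSE) {
  idx <- build_proteome_index(pathogen)
  tab <- if (distinct) {
    dplyr::mutate(idx$counts, n = 1L)
  } else {
    idx$counts
  }
  is_np <- np_profile$is_np[match(tab$motif, np_profile$motif)]
  is_np[is.na(is_np)] <- TRUE  # absent from human proteome -> frequency 0 -> np
  sum(tab$n[is_np]) / sum(tab$n)
}

#' Per-allele fraction of np-TCEM peptides among presented peptides
#'
#' A pathogen 9-mer is bound by an allele when the predicted rank
#' percentile is under `rank_pct` and affinity under `affinity_nm`. For
#' alleles with zero predicted binders, the N peptides with the lowest
#' predicted affinity stand in, where N is the median binder count of the
#' other alleles at the same HLA locus (the locus is the letter after
#' `HLA-`). The reported value is the fraction of presented peptides whose
#' TCEM is np.
#'
#' @param predictions Tibble with `peptide`, `allele`, `affinity_nm`,
#'   `rank_pct` covering the pathogen's 9-mers.
#' @param peptide_np Tibble with `peptide`, `is_np` (np status of each
#'   peptide's TCEM).
#' @param affinity_nm,rank_pct Binding thresholds.
#' @return Tibble with `allele`, `n_bound`, `np_fraction`, `fallback`
#'   (logical: fallback-N rule used).
#' @export
allele_presented_np_fraction <- function(predictions, peptide_np,
                                         affinity_nm = 50, rank_pct = 0.5) {
  predictions <- dplyr::mutate(
    predictions,
    locus = sub("^HLA-([A-Z]).*$", "\\1", .data$allele),
    bound = .data$affinity_nm < !!affinity_nm & .data$rank_pct < !!rank_pct
  )
  counts <- predictions |>
    dplyr::summarise(
      n_bound = sum(.data$bound),
      locus = .data$locus[1],
      .by = "allele"
    )
  np_of <- function(peps) {
    flag <- peptide_np$is_np[match(peps, peptide_np$peptide)]
    if (anyNA(flag)) stop("np status missing for some peptides", call. = FALSE)
    mean(flag)
  }
  purrr::pmap(counts, function(allele, n_bound, locus) {
    rows <- predictions[predictions$allele == allele, ]
    if (n_bound > 0) {
      peps <- rows$peptide[rows$bound]
      return(tibble::tibble(
        allele = allele, n_bound = n_bound,
        np_fraction = np_of(peps), fallback = FALSE
      ))
    }
    others <- counts[counts$locus == locus & counts$allele != allele & counts$n_bound > 0, ]
    if (nrow(others) == 0) {
      stop(sprintf("no same-locus allele with binders for fallback at %s", allele),
        call. = FALSE
      )
    }
    n_fallback <- round(stats::median(others$n_bound))
    peps <- rows$peptide[order(rows$affinity_nm)][seq_len(min(n_fallback, nrow(rows)))]
    tibble::tibble(
      allele = allele, n_bound = 0L,
      np_fraction = np_of(peps), fallback = TRUE
    )
  }) |>
    dplyr::bind_rows()
}

#' Across-allele variance of np-presentation vs pathogen proteome size
#'
#' For each species, the variance of the per-allele presented np-TCEM
#' fractions, and the Spearman correlation of that variance with proteome
#' size: small proteomes expose few bindable peptides, so the presented
#' fraction fluctuates strongly between alleles.
#'
#' @param fractions Tibble with `species`, `allele`, `np_fraction`.
#' @param sizes Tibble with `species`, `proteome_size`.
#' @return List with `variances` (tibble `species`, `variance`,
#'   `proteome_size`), `rho`, `p_value`.
#' @export
variance_vs_proteome_size <- function(fractions, sizes) {
  v <- fractions |>
    dplyr::summarise(variance = stats::var(.data$np_fraction), .by = "species") |>
    dplyr::inner_join(sizes, by = "species")
  if (nrow(v) < 3) stop("need at least 3 species", call. = FALSE)
  ct <- suppressWarnings(
    stats::cor.test(v$variance, v$proteome_size, method = "spearman")
  )
  list(variances = v, rho = unname(ct$estimate), p_value = ct$p.value)
}

#' Aggregate HLA association studies by odds-ratio rank percentile
#'
#' Within each study the allele groups are ranked by odds ratio and the
#' rank percentile (rank/n, average ranks for ties) computed. Groups
#' present in at least `coverage` of the studies are averaged across
#' studies; the group with the lowest mean percentile is labelled
#' protective and the one with the highest is labelled risk.
#'
#' @param studies Tibble with `study_id`, `allele_group`, `odds_ratio`.
#' @param coverage Minimum fraction of studies a group must appear in.
#' @return List with `percentiles` (tibble `allele_group`, `n_studies`,
#'   `mean_percentile`), `protective`, `risk`.
#' @export
rank_percentile_aggregation <- function(studies, coverage = 0.75) {
  n_total <- dplyr::n_distinct(studies$study_id)
  if (n_total < 2) stop("need at least 2 studies", call. = FALSE)
  per <- studies |>
    dplyr::mutate(
      percentile = rank(.data$odds_ratio) / dplyr::n(),
      .by = "study_id"
    ) |>
    dplyr::summarise(
      n_studies = dplyr::n_distinct(.data$study_id),
      mean_percentile = mean(.data$percentile),
      .by = "allele_group"
    ) |>
    dplyr::filter(.data$n_studies >= coverage * !!n_total)
  if (nrow(per) == 0) stop("no allele group meets the coverage requirement", call. = FALSE)
  list(
    percentiles = dplyr::arrange(per, .data$mean_percentile),
    protective = per$allele_group[which.min(per$mean_percentile)],
    risk = per$allele_group[which.max(per$mean_percentile)]
  )
}

#' Group-level np-presentation values for serotypes or allele groups
#'
#' Association studies report serotypes or two-digit allele groups, not
#' individual four-digit alleles, so per-allele np fractions are averaged
#' over the group's member alleles — all members for a serotype, or the
#' members classified as common for a two-digit group.
#'
#' @param allele_values Tibble with `allele`, `value`.
#' @param membership Tibble with `group`, `allele` and (optionally)
#'   `is_common`.
#' @param common_only Average only common member alleles (two-digit group
#'   rule).
#' @return Tibble with `group`, `n_alleles`, `value`.
#' @export
group_level_np_fraction <- function(allele_values, membership,
                                    common_only = FALSE) {
  members <- membership
  if (common_only) {
    if (!"is_common" %in% names(members)) {
      stop("`membership` needs an `is_common` column when `common_only`", call. = FALSE)
    }
    members <- dplyr::filter(members, .data$is_common)
  }
  joined <- dplyr::inner_join(members, allele_values, by = "allele")
  empty <- setdiff(unique(membership$group), unique(joined$group))
  if (length(empty)) {
    stop("group(s) with no member allele values: ",
      paste(empty, collapse = ", "),
      call. = FALSE
    )
  }
  joined |>
    dplyr::summarise(
      n_alleles = dplyr::n(),
      value = mean(.data$value),
      .by = "group"
    )
}
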