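#' Filter assay-level records for the immunogenicity analysis
#'
#' Keeps linear 9- and 10-mer peptides over the 20 standard letters, from
#' nonhuman source organisms, tested against HLA class I alleles typed at
#' 4-digit resolution (e.g. `HLA-A*02:01`). Human peptides are removed
#' because tolerance mechanisms would confound the immunogenicity labels.
#' Rejection reasons are attached as the `"rejected"` attribute.
#'
#' @param assays Tibble with columns `peptide`, `allele`, `assay_kind`
#'   (`tcell`/`mhc_binding`), `outcome` (`positive`/`negative`),
#'   `source_taxon` (contains `"human"` for human-source peptides).
#' @return Filtered tibble; `attr(, "rejected")` holds the removed rows
#'   with a `reason` column.
#' @export
filter_assays <- function(assays) {
  allele_ok <- grepl("^HLA-[ABC]\\*\\d{2}:\\d{2}$", assays$allele)
  reason <- dplyr::case_when(
    !(nchar(assays$peptide) %in% c(9L, 10L)) ~ "length",
    !is_standard_aa(assays$peptide) ~ "nonstandard_letter",
    grepl("human", assays$source_taxon, ignore.case = TRUE) ~ "human_source",
    !allele_ok ~ "allele_resolution",
    TRUE ~ NA_character_
  )
  kept <- assays[is.na(reason), , drop = FALSE]
  attr(kept, "rejected") <- dplyr::mutate(
    assays[!is.na(reason), , drop = FALSE],
    reason = reason[!is.na(reason)]
  )
  kept
}

#' Label allele-peptide pairs by aggregated T cell assay outcome
#'
#' Pairs with solely negative T cell assays are nonimmunogenic; pairs with
#' more positive than negative assays are immunogenic; anything in between
#' (ties, minority positives) is excluded. Peptides labelled immunogenic
#' for one allele and nonimmunogenic for another are contradictory and all
#' their pairs are excluded.
#'
#' @param assays Filtered assay tibble (only `assay_kind == "tcell"` rows
#'   are used).
#' @return Tibble with `peptide`, `allele`, `n_pos`, `n_neg`, `label`
#'   (factor `immunogenic`/`nonimmunogenic`); excluded pairs are absent.
#' @export
label_immunogenicity <- function(assays) {
  tc <- dplyr::filter(assays, .data$assay_kind == "tcell")
  pairs <- tc |>
    dplyr::summarise(
      n_pos = sum(.data$outcome == "positive"),
      n_neg = sum(.data$outcome == "negative"),
      .by = c("peptide", "allele")
    ) |>
    dplyr::mutate(label = dplyr::case_when(
      .data$n_pos == 0 & .data$n_neg > 0 ~ "nonimmunogenic",
      .data$n_pos > .data$n_neg ~ "immunogenic",
      TRUE ~ NA_character_
    )) |>
    dplyr::filter(!is.na(.data$label))
  contradictory <- pairs |>
    dplyr::summarise(k = dplyr::n_distinct(.data$label), .by = "peptide") |>
    dplyr::filter(.data$k > 1)
  pairs |>
    dplyr::filter(!.data$peptide %in% contradictory$peptide) |>
    dplyr::mutate(label = factor(.data$label, c("immunogenic", "nonimmunogenic")))
}

#' Dataset-1 binding filter: prediction-confirmed HLA binding
#'
#' Keeps an allele-peptide pair when the binding prediction confirms it:
#' predicted affinity below 500 nM or predicted rank percentile below 2.
#' Pairs without a prediction are dropped (reported via the `"missing"`
#' attribute).
#'
#' @param pairs Tibble with `peptide`, `allele`.
#' @param predictions Tibble with `peptide`, `allele`, `affinity_nm`,
#'   `rank_pct`.
#' @param affinity_nm,rank_pct Filter thresholds.
#' @return `pairs` restricted to prediction-confirmed rows.
#' @export
dataset1_binding_filter <- function(pairs, predictions,
                                    affinity_nm = 500, rank_pct = 2) {
  joined <- dplyr::left_join(
    pairs, predictions,
    by = c("peptide", "allele")
  )
  missing <- joined[is.na(joined$affinity_nm) & is.na(joined$rank_pct), c("peptide", "allele")]
  keep <- !is.na(joined$affinity_nm) & !is.na(joined$rank_pct) &
    (joined$affinity_nm < affinity_nm | joined$rank_pct < rank_pct)
  out <- pairs[keep, , drop = FALSE]
  attr(out, "missing") <- missing
  out
}

#' Dataset-2 binding filter: assay-verified HLA binding
#'
#' Keeps an allele-peptide pair when binding is verified empirically: the
#' pair appears in at least `min_assays` MHC-binding assays and at least
#' `min_assays` T cell assays, and strictly more than `positive_fraction`
#' of its binding assays are positive.
#'
#' @param pairs Tibble with `peptide`, `allele`.
#' @param assays Full assay tibble (both `tcell` and `mhc_binding` rows).
#' @param min_assays Minimum assay count per kind.
#' @param positive_fraction Binding-assay positive fraction that must be
#'   strictly exceeded.
#' @return `pairs` restricted to assay-verified rows.
#' @export
dataset2_binding_filter <- function(pairs, assays, min_assays = 2,
                                    positive_fraction = 0.60) {
  stats_tbl <- assays |>
    dplyr::summarise(
      n_binding = sum(.data$assay_kind == "mhc_binding"),
      n_tcell = sum(.data$assay_kind == "tcell"),
      pos_frac = ifelse(
        sum(.data$assay_kind == "mhc_binding") > 0,
        mean(.data$outcome[.data$assay_kind == "mhc_binding"] == "positive"),
        0
      ),
      .by = c("peptide", "allele")
    )
  ok <- stats_tbl |>
    dplyr::filter(
      .data$n_binding >= min_assays,
      .data$n_tcell >= min_assays,
      .data$pos_frac > positive_fraction
    )
  dplyr::semi_join(pairs, ok, by = c("peptide", "allele"))
}

#' k-tuple distance between two peptide sequences
#'
#' `1 - shared / (min(La, Lb) - k + 1)` where `shared` is the multiset
#' intersection size of the two sequences' length-k subwords. With the
#' protein default k = 1 a distance of 0.5 corresponds to a maximum 50%
#' overlap between the sequences.
#'
#' @param a,b Peptide sequences (single strings).
#' @param k Tuple length.
#' @return Distance in \[0, 1\].
#' @examples
#' ktuple_distance("ACDEF", "ACDEF")  # 0
#' @export
ktuple_distance <- function(a, b, k = 1L) {
  if (nchar(a) < k || nchar(b) < k || nchar(a) == 0 || nchar(b) == 0) {
    stop("sequences must be non-empty and at least k long", call. = FALSE)
  }
  ta <- table(substring(a, seq_len(nchar(a) - k + 1L), seq_len(nchar(a) - k + 1L) + k - 1L))
  tb <- table(substring(b, seq_len(nchar(b) - k + 1L), seq_len(nchar(b) - k + 1L) + k - 1L))
  common <- intersect(names(ta), names(tb))
  shared <- sum(pmin(ta[common], tb[common]))
  1 - shared / (min(nchar(a), nchar(b)) - k + 1L)
}

#' Pairwise k-tuple distance matrix
#'
#' @param peptides Character vector of peptide sequences.
#' @inheritParams ktuple_distance
#' @return Symmetric numeric matrix with `peptides` as dimnames.
#' @export
ktuple_distance_matrix <- function(peptides, k = 1L) {
  n <- length(peptides)
  d <- matrix(0, n, n, dimnames = list(peptides, peptides))
  if (n < 2) return(d)
  # k-mer count matrix; shared multiset size = sum over k-mers of pairwise
  # minima, accumulated one k-mer column at a time
  kmers_of <- function(s) {
    substring(s, seq_len(nchar(s) - k + 1L), seq_len(nchar(s) - k + 1L) + k - 1L)
  }
  kl <- lapply(peptides, kmers_of)
  vocab <- unique(unlist(kl))
  M <- vapply(kl, function(km) {
    tabulate(match(km, vocab), nbins = length(vocab))
  }, integer(length(vocab)))
  M <- matrix(M, nrow = length(vocab))  # vocab x n
  shared <- matrix(0, n, n)
  for (v in seq_len(nrow(M))) {
    shared <- shared + pmin(
      matrix(M[v, ], n, n, byrow = FALSE),
      matrix(M[v, ], n, n, byrow = TRUE)
    )
  }
  denom <- outer(nchar(peptides), nchar(peptides), pmin) - k + 1L
  d[] <- 1 - shared / denom
  diag(d) <- 0
  d
}

#' Iterative redundancy removal by k-tuple distance
#'
#' Repeatedly finds the peptide pair(s) at the minimum pairwise distance
#' and removes, among their members, the peptide with the lowest mean
#' distance to all remaining peptides (ties broken by removing the
#' lexicographically smallest sequence), until every remaining pair is at
#' distance >= `threshold`.
#'
#' @param peptides Character vector of peptide sequences.
#' @param threshold Minimum pairwise distance of the retained set.
#' @inheritParams ktuple_distance
#' @return Character vector of retained peptides (input order preserved).
#' @export
iterative_dedup <- function(peptides, threshold = 0.5, k = 1L) {
  stopifnot(length(peptides) >= 1)
  keep <- unique(peptides)
  if (length(keep) < length(peptides)) {
    # identical sequences are at distance 0; all but one would be removed
    # one per iteration anyway
    keep <- keep[order(match(keep, peptides))]
  }
  d <- ktuple_distance_matrix(keep, k)
  while (length(keep) > 1) {
    off <- d
    diag(off) <- Inf
    dmin <- min(off)
    if (dmin >= threshold) break
    in_min_pair <- apply(off == dmin, 1, any)
    mean_d <- rowSums(d) / (length(keep) - 1)
    cand <- which(in_min_pair)
    cand <- cand[mean_d[cand] == min(mean_d[cand])]
    drop <- cand[order(keep[cand])][1]
    keep <- keep[-drop]
    d <- d[-drop, -drop, drop = FALSE]
  }
  peptides[peptides %in% keep & !duplicated(peptides)]
}

#' Anchor positions of allele-bound peptides by positional entropy
#'
#' A position is an anchoring residue for an allele when the Shannon
#' entropy (natural log) of the amino-acid distribution at that position,
#' over the peptides bound by the allele, is below `entropy_threshold`.
#' Alleles with fewer than `min_peptides` bound peptides are skipped with
#' a warning.
#'
#' @param bound_peptides Tibble with `allele`, `peptide` (equal-length
#'   peptides per allele).
#' @param entropy_threshold Entropy (nats) below which a position anchors.
#' @param min_peptides Minimum bound peptides per allele.
#' @return Tibble with `allele`, `position`, `entropy`, `anchor`.
#' @export
anchor_positions <- function(bound_peptides, entropy_threshold = 0.8,
                             min_peptides = 20L) {
  by_allele <- split(bound_peptides$peptide, bound_peptides$allele)
  out <- purrr::imap(by_allele, function(peps, allele) {
    if (length(peps) < min_peptides) {
      warning(sprintf("allele %s skipped: only %d bound peptides", allele, length(peps)))
      return(NULL)
    }
    len <- unique(nchar(peps))
    if (length(len) > 1) len <- min(len)
    ent <- vapply(seq_len(len), function(p) {
      aa <- substr(peps, p, p)
      f <- table(aa) / length(aa)
      -sum(f * log(f))
    }, numeric(1))
    tibble::tibble(
      allele = allele, position = seq_len(len),
      entropy = ent, anchor = ent < entropy_threshold
    )
  })
  dplyr::bind_rows(out)
}

#' Exclude peptides bound only through secondary anchors in the TCEM region
#'
#' A curated peptide is removed when every allele it is reported bound by
#' has at least one anchor position inside the peptide's TCEM window
#' (positions 4-8 of a 9-mer, 5-9 of a 10-mer). One anchor-free allele
#' retains the peptide.
#'
#' @param curated Tibble with `peptide`, `allele` (one row per reported
#'   pair).
#' @param anchors Tibble from [anchor_positions()].
#' @return `curated` minus the excluded peptides.
#' @export
secondary_anchor_exclusion <- function(curated, anchors) {
  tcem_start <- ifelse(nchar(curated$peptide) == 9L, 4L, 5L)
  anchored <- purrr::map2_lgl(curated$allele, tcem_start, function(al, st) {
    pos <- anchors$position[anchors$allele == al & anchors$anchor]
    any(pos >= st & pos <= st + 4L)
  })
  flags <- tibble::tibble(peptide = curated$peptide, anchored = anchored) |>
    dplyr::summarise(all_anchored = all(.data$anchored), .by = "peptide")
  excluded <- flags$peptide[flags$all_anchored]
  curated[!curated$peptide %in% excluded, , drop = FALSE]
}

#' Run the two-dataset curation pipeline
#'
#' Chains the curation steps into the two benchmark datasets:
#' \enumerate{
#'   \item filter assay records ([filter_assays()]);
#'   \item label allele-peptide pairs ([label_immunogenicity()]);
#'   \item dataset 1 = prediction-confirmed binders
#'     ([dataset1_binding_filter()]);
#'   \item dataset 2 = assay-verified binders
#'     ([dataset2_binding_filter()]) with iterative redundancy removal
#'     ([iterative_dedup()]);
#'   \item overlap resolution: peptides present in both datasets are kept
#'     only in dataset 2.
#' }
#'
#' @param assays Raw assay tibble (see [filter_assays()]).
#' @param predictions Binding-prediction tibble (see
#'   [dataset1_binding_filter()]).
#' @param dedup_threshold,k Redundancy-removal parameters.
#' @return Tibble with `peptide`, `allele`, `label`, `n_pos`, `n_neg`,
#'   `dataset` (1 or 2); no peptide appears in both datasets.
#' @export
curate_datasets <- function(assays, predictions, dedup_threshold = 0.5, k = 1L) {
  kept <- filter_assays(assays)
  labelled <- label_immunogenicity(kept)

  ds1 <- dataset1_binding_filter(
    labelled[c("peptide", "allele")], predictions
  ) |>
    dplyr::left_join(labelled, by = c("peptide", "allele"))

  ds2_pairs <- dataset2_binding_filter(
    labelled[c("peptide", "allele")], kept
  )
  ds2 <- dplyr::left_join(ds2_pairs, labelled, by = c("peptide", "allele"))
  if (nrow(ds2) > 0) {
    retained <- iterative_dedup(unique(ds2$peptide), threshold = dedup_threshold, k = k)
    ds2 <- ds2[ds2$peptide %in% retained, , drop = FALSE]
  }

  ds1 <- ds1[!ds1$peptide %in% ds2$peptide, , drop = FALSE]
  dplyr::bind_rows(
    dplyr::mutate(ds1, dataset = 1L),
    dplyr::mutate(ds2, dataset = 2L)
  ) |> tibble::as_tibble()
}
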