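#' Normalized BLOSUM62 similarity between equal-length sequences
#'
#' The raw score `s(a, b)` is the sum of BLOSUM62 entries over aligned
#' positions; similarity is the geometric-mean normalization
#' `s(a, b) / sqrt(s(a, a) * s(b, b))`. Identical sequences score exactly 1
#' and, because BLOSUM62 diagonal entries are maximal within their rows,
#' no pair scores above 1. Both the 5-mer TCEM comparisons and the full
#' 9-mer self-similarity analyses use this scorer.
#'
#' @param a,b Character vectors of equal-length sequences (recycled
#'   pairwise).
#' @return Numeric vector of similarities (<= 1).
#' @examples
#' blosum_similarity("AAAAA", "AAAAV")  # 0.8
#' @export
blosum_similarity <- function(a, b) {
  if (length(a) != length(b)) {
    n <- max(length(a), length(b))
    a <- rep_len(a, n)
    b <- rep_len(b, n)
  }
  if (any(nchar(a) != nchar(b))) {
    stop("sequences must have equal length pairwise", call. = FALSE)
  }
  if (any(!is_standard_aa(c(a, b)))) {
    stop("sequences must contain only standard amino-acid letters", call. = FALSE)
  }
  B <- blosum62_matrix()
  diag_b <- diag(B)
  purrr::map2_dbl(a, b, function(x, y) {
    cx <- aa_codes(x)
    cy <- aa_codes(y)
    s_xy <- sum(B[cbind(cx, cy)])
    s_xy / sqrt(sum(diag_b[cx]) * sum(diag_b[cy]))
  })
}

#' Most similar human-proteome window of a peptide
#'
#' Exhaustively scans every ungapped window of the peptide's length across
#' all proteins and returns the maximum normalized BLOSUM62 similarity and
#' one attaining location (first protein in input order, then the smallest
#' start). Exhaustive scanning is the definition of "best hit" here; it is
#' at least as sensitive as a heuristic local-alignment search.
#'
#' @param peptide Character vector of query peptides.
#' @param proteome Proteome accepted by [build_proteome_index()].
#' @return Tibble with `peptide`, `similarity`, `protein_id`, `start`.
#' @export
best_human_hit <- function(peptide, proteome) {
  proteome <- as_proteome(proteome)
  B <- blosum62_matrix()
  diag_b <- diag(B)
  codes <- purrr::map(proteome$sequence, aa_codes)
  out <- purrr::map(peptide, function(pep) {
    L <- nchar(pep)
    pc <- aa_codes(pep)
    if (anyNA(pc)) stop("non-standard letters in peptide: ", pep, call. = FALSE)
    s_pp <- sum(diag_b[pc])
    best <- list(sim = -Inf, protein_id = NA_character_, start = NA_integer_)
    for (i in seq_len(nrow(proteome))) {
      prot <- codes[[i]]
      n_win <- length(prot) - L + 1L
      if (n_win < 1) next
      raw <- numeric(n_win)
      self <- numeric(n_win)
      for (k in seq_len(L)) {
        res <- prot[seq_len(n_win) + k - 1L]
        raw <- raw + B[cbind(pc[k], res)]
        self <- self + diag_b[res]
      }
      sims <- raw / sqrt(s_pp * self)
      sims[is.na(sims)] <- -Inf  # windows with non-standard letters
      w <- which.max(sims)
      if (length(w) && sims[w] > best$sim) {
        best <- list(sim = sims[w], protein_id = proteome$protein_id[i], start = w)
      }
    }
    if (!is.finite(best$sim)) {
      stop("proteome has no window of length ", L, call. = FALSE)
    }
    tibble::tibble(
      peptide = pep, similarity = unname(best$sim),
      protein_id = best$protein_id, start = as.integer(best$start)
    )
  })
  dplyr::bind_rows(out)
}

#' Label TCR-scan variants as binders
#'
#' Variants retaining at least `cutoff` (default 10%) of the original
#' epitope's TCR binding strength are binders; below that T cell
#' activation is negligible.
#'
#' @param scan Tibble with a `relative_binding` column.
#' @param cutoff Binding fraction at and above which a variant binds.
#' @return `scan` with an added logical `binder` column.
#' @export
label_binders <- function(scan, cutoff = 0.10) {
  dplyr::mutate(scan, binder = .data$relative_binding >= cutoff)
}

#' ROC curve and AUC for a score-based binary classifier
#'
#' Sweeps every observed score as a cutoff (predict positive when
#' `score >= cutoff`), computing sensitivity and specificity; ties are
#' grouped by using each distinct score once. AUC is the trapezoid area
#' over the (FPR, TPR) points.
#'
#' @param score Numeric classifier scores (higher = more positive).
#' @param label Logical (or two-level) true class.
#' @return Object of class `tcem_roc`: list with `points` (tibble
#'   `cutoff`, `tpr`, `fpr`, `sens`, `spec`), `auc`, `n_pos`, `n_neg`.
#' @export
roc_curve <- function(score, label) {
  if (!is.logical(label)) {
    if (is.numeric(label)) {
      label <- label != 0
    } else {
      f <- factor(label)
      if (nlevels(f) != 2) stop("label must be binary", call. = FALSE)
      label <- f == levels(f)[2]
    }
  }
  ok <- !is.na(score) & !is.na(label)
  score <- score[ok]
  label <- label[ok]
  n_pos <- sum(label)
  n_neg <- sum(!label)
  if (n_pos == 0 || n_neg == 0) {
    stop("both classes must be present", call. = FALSE)
  }
  cutoffs <- sort(unique(score), decreasing = TRUE)
  tpr <- vapply(cutoffs, function(c) mean(score[label] >= c), numeric(1))
  fpr <- vapply(cutoffs, function(c) mean(score[!label] >= c), numeric(1))
  # prepend the (0,0) corner (cutoff above every score)
  pts <- tibble::tibble(
    cutoff = c(Inf, cutoffs),
    tpr = c(0, tpr),
    fpr = c(0, fpr)
  )
  pts$sens <- pts$tpr
  pts$spec <- 1 - pts$fpr
  o <- order(pts$fpr, pts$tpr)
  auc <- sum(diff(pts$fpr[o]) * (utils::head(pts$tpr[o], -1) + utils::tail(pts$tpr[o], -1)) / 2)
  # close the curve at (1,1) if the smallest cutoff does not reach it
  if (max(pts$fpr) < 1 || max(pts$tpr) < 1) {
    auc <- auc + (1 - max(pts$fpr)) * 1
  }
  structure(
    list(points = pts, auc = auc, n_pos = n_pos, n_neg = n_neg),
    class = "tcem_roc"
  )
}

#' @export
print.tcem_roc <- function(x, ...) {
  cat(sprintf(
    "<tcem_roc> AUC = %.4f (%d positive, %d negative)\n",
    x$auc, x$n_pos, x$n_neg
  ))
  invisible(x)
}

#' @describeIn roc_curve `tidy()` returns the per-cutoff points.
#' @param x A `tcem_roc`.
#' @param ... Unused.
#' @method tidy tcem_roc
#' @export
tidy.tcem_roc <- function(x, ...) x$points

#' @describeIn roc_curve `glance()` returns AUC and class sizes.
#' @method glance tcem_roc
#' @export
glance.tcem_roc <- function(x, ...) {
  tibble::tibble(auc = x$auc, n_pos = x$n_pos, n_neg = x$n_neg)
}

#' Cost-benefit optimal ROC cutpoint
#'
#' Chooses the observed cutoff maximizing `Se - m * (1 - Sp)` with slope
#' `m = cost_ratio * (1 - prevalence) / prevalence`. With `cost_ratio = 1`
#' and `prevalence = 0.5` this reduces to Youden's J. Among tied maxima the
#' smallest finite cutoff is returned.
#'
#' @param roc A `tcem_roc` from [roc_curve()].
#' @param cost_ratio Relative cost of a false positive vs a false negative.
#' @param prevalence Positive-class prevalence; defaults to the sample
#'   prevalence of the ROC data.
#' @return The optimal cutoff (a value attained by an observed score).
#' @export
optimal_cutpoint_costbenefit <- function(roc, cost_ratio = 1, prevalence = NULL) {
  stopifnot(inherits(roc, "tcem_roc"))
  if (is.null(prevalence)) prevalence <- roc$n_pos / (roc$n_pos + roc$n_neg)
  m <- cost_ratio * (1 - prevalence) / prevalence
  pts <- roc$points[is.finite(roc$points$cutoff), ]
  crit <- pts$sens - m * (1 - pts$spec)
  best <- which(crit == max(crit))
  min(pts$cutoff[best])
}

#' Cross-reactivity scan between two motif groups
#'
#' Computes all pairwise normalized BLOSUM62 similarities between motifs
#' in group 1 (motifs without expected positively selected T cells) and
#' group 2 (motifs with an expected repertoire) and reports, for each
#' group-1 motif, the fraction of group 2 reaching the cross-reactivity
#' cutoff — i.e. the fraction of the existing repertoire close enough in
#' sequence space to recognise it. Similarities are aggregated motif by
#' motif, so the full pair matrix is never materialized.
#'
#' @param group1,group2 Character vectors of equal-length motifs.
#' @param cutoff Similarity at and above which two motifs are considered
#'   cross-recognizable.
#' @return Object of class `tcem_xreact`: list with `fractions` (tibble
#'   `motif`, `n_above`, `fraction`), `n_pairs`, `cutoff` and `summary`
#'   (min/median/max fraction).
#' @export
crossreactivity_scan <- function(group1, group2, cutoff) {
  stopifnot(length(group1) > 0, length(group2) > 0)
  len <- unique(nchar(c(group1, group2)))
  if (length(len) != 1) stop("all motifs must have equal length", call. = FALSE)
  B <- blosum62_matrix()
  diag_b <- diag(B)
  g2 <- matrix(
    match(unlist(strsplit(group2, "", fixed = TRUE)), AA_STANDARD),
    ncol = len, byrow = TRUE
  )
  if (anyNA(g2)) stop("non-standard letters in group2", call. = FALSE)
  g2_self <- matrix(diag_b[g2], ncol = len)
  g2_self <- rowSums(g2_self)
  n2 <- length(group2)
  res <- purrr::map(group1, function(mot) {
    mc <- aa_codes(mot)
    if (anyNA(mc)) stop("non-standard letters in group1: ", mot, call. = FALSE)
    raw <- numeric(n2)
    for (k in seq_len(len)) raw <- raw + B[cbind(mc[k], g2[, k])]
    sims <- raw / sqrt(sum(diag_b[mc]) * g2_self)
    n_above <- sum(sims >= cutoff)
    tibble::tibble(motif = mot, n_above = n_above, fraction = n_above / n2)
  })
  fractions <- dplyr::bind_rows(res)
  structure(
    list(
      fractions = fractions,
      n_pairs = length(group1) * n2,
      cutoff = cutoff,
      summary = tibble::tibble(
        min = min(fractions$fraction),
        median = stats::median(fractions$fraction),
        max = max(fractions$fraction)
      )
    ),
    class = "tcem_xreact"
  )
}

#' @export
print.tcem_xreact <- function(x, ...) {
  cat(sprintf(
    "<tcem_xreact> %d x %d = %d pairs at cutoff %.3g; fraction above: min %.3g, median %.3g, max %.3g\n",
    nrow(x$fractions), x$n_pairs / max(1, nrow(x$fractions)), x$n_pairs, x$cutoff,
    x$summary$min, x$summary$median, x$summary$max
  ))
  invisible(x)
}

#' Immunogenic:nonimmunogenic ratio across similarity bins
#'
#' Pools labelled peptides, splits them into `n_bins` equal-count groups by
#' best-hit similarity rank, and computes the within-bin ratio of
#' immunogenic to nonimmunogenic peptides plus a cubic smoothing-spline fit
#' of ratio against mean bin similarity. Bins without nonimmunogenic
#' peptides get an `NA` ratio and are excluded from the fit.
#'
#' @param data Tibble with `similarity` and `label`
#'   (`immunogenic`/`nonimmunogenic`).
#' @param n_bins Number of equal-count similarity bins.
#' @return List with `bins` (tibble `bin`, `mean_similarity`, `n`,
#'   `n_immunogenic`, `n_nonimmunogenic`, `ratio`), `spline` (fitted
#'   values at bin means, or `NULL` for < 4 usable bins) and `argmax_bin`.
#' @export
similarity_bins <- function(data, n_bins = 25) {
  stopifnot(nrow(data) >= n_bins)
  data <- dplyr::arrange(data, .data$similarity)
  data$bin <- ceiling(seq_len(nrow(data)) / (nrow(data) / n_bins))
  bins <- data |>
    dplyr::summarise(
      mean_similarity = mean(.data$similarity),
      n = dplyr::n(),
      n_immunogenic = sum(.data$label == "immunogenic"),
      n_nonimmunogenic = sum(.data$label == "nonimmunogenic"),
      .by = "bin"
    ) |>
    dplyr::mutate(ratio = ifelse(
      .data$n_nonimmunogenic == 0, NA_real_,
      .data$n_immunogenic / .data$n_nonimmunogenic
    ))
  usable <- bins[!is.na(bins$ratio), ]
  spline <- NULL
  if (nrow(usable) >= 4) {
    fit <- stats::smooth.spline(usable$mean_similarity, usable$ratio)
    spline <- tibble::tibble(
      mean_similarity = usable$mean_similarity,
      fitted = stats::predict(fit, usable$mean_similarity)$y
    )
  }
  list(
    bins = bins,
    spline = spline,
    argmax_bin = if (any(!is.na(bins$ratio))) bins$bin[which.max(bins$ratio)] else NA_integer_
  )
}
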