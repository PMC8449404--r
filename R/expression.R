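#' TMM normalization factors for a cTEC count matrix
#'
#' Scales the columns of a gene-by-sample count matrix with trimmed-mean-of-
#' M-values factors (edgeR's `calcNormFactors`), the same normalization the
#' cTEC expression data require before RPKM calculation. Factors are
#' geometric-mean-centred, so they multiply to 1.
#'
#' @param counts Gene-by-sample matrix of non-negative integer counts, or a
#'   data frame with a `gene_id` column followed by sample columns.
#' @return A list with `factors` (named per sample), `lib_size` (raw column
#'   sums), `effective_lib_size` (`lib_size * factors`) and `counts`
#'   (the matrix form).
#' @export
normalize_counts <- function(counts) {
  counts <- as_count_matrix(counts)
  if (ncol(counts) < 2) stop("need at least 2 samples", call. = FALSE)
  lib <- colSums(counts)
  if (any(lib == 0)) {
    stop(
      "all-zero sample(s): ",
      paste(colnames(counts)[lib == 0], collapse = ", "),
      call. = FALSE
    )
  }
  f <- edgeR::calcNormFactors(counts, method = "TMM")
  list(
    factors = stats::setNames(f, colnames(counts)),
    lib_size = lib,
    effective_lib_size = lib * f,
    counts = counts
  )
}

as_count_matrix <- function(counts) {
  if (is.data.frame(counts)) {
    idcol <- intersect(c("gene_id", "gene"), names(counts))[1]
    if (!is.na(idcol)) {
      m <- as.matrix(counts[setdiff(names(counts), idcol)])
      rownames(m) <- counts[[idcol]]
      counts <- m
    } else {
      counts <- as.matrix(counts)
    }
  }
  storage.mode(counts) <- "double"
  if (any(counts < 0)) stop("negative counts", call. = FALSE)
  if (is.null(rownames(counts))) stop("counts must have gene ids as rownames", call. = FALSE)
  counts
}

#' RPKM from TMM-normalized counts
#'
#' Reads per kilobase per million mapped reads against the effective
#' (TMM-scaled) library size:
#' `rpkm = count / (exon_length/1e3) / (effective_lib_size/1e6)`.
#'
#' @param normalized Result of [normalize_counts()].
#' @param exon_length Named numeric vector (bases) or tibble with `gene_id`,
#'   `exon_length`; every gene in the count matrix must be covered.
#' @return Tibble with columns `gene_id`, `sample`, `rpkm`.
#' @export
compute_rpkm <- function(normalized, exon_length) {
  counts <- normalized$counts
  if (is.data.frame(exon_length)) {
    exon_length <- stats::setNames(exon_length$exon_length, exon_length$gene_id)
  }
  len <- exon_length[rownames(counts)]
  if (anyNA(len) || any(len <= 0)) {
    stop("exon_length must be positive and cover every gene", call. = FALSE)
  }
  els <- normalized$effective_lib_size
  if (any(els <= 0)) stop("effective library size must be positive", call. = FALSE)
  rpkm <- sweep(counts / (len / 1e3), 2, els / 1e6, "/")
  tibble::as_tibble(rpkm, rownames = "gene_id") |>
    tidyr::pivot_longer(-"gene_id", names_to = "sample", values_to = "rpkm")
}

#' Per-gene median RPKM across cTEC samples
#'
#' @param rpkm Long tibble from [compute_rpkm()] (columns `gene_id`,
#'   `sample`, `rpkm`).
#' @return Tibble with `gene_id`, `median_rpkm`.
#' @export
median_gene_expression <- function(rpkm) {
  rpkm |>
    dplyr::summarise(median_rpkm = stats::median(.data$rpkm), .by = "gene_id")
}

#' Map proteins to genes by shared symbol
#'
#' Joins protein and gene identifier tables on a shared gene symbol (the
#' HUGO-style join used when direct identifier conversion is incomplete).
#' A protein maps to every gene with which it shares at least one symbol;
#' proteins with no shared symbol are reported as unmapped, not errors.
#'
#' @param protein_symbols Tibble with `protein_id`, `symbol`.
#' @param gene_symbols Tibble with `gene_id`, `symbol`.
#' @return A list with `map` (tibble `protein_id`, `gene_id`) and
#'   `unmapped` (character vector of protein ids).
#' @export
map_proteins_to_genes <- function(protein_symbols, gene_symbols) {
  stopifnot(nrow(protein_symbols) > 0, nrow(gene_symbols) > 0)
  map <- dplyr::inner_join(
    protein_symbols, gene_symbols,
    by = "symbol", relationship = "many-to-many"
  ) |>
    dplyr::distinct(.data$protein_id, .data$gene_id)
  list(
    map = map,
    unmapped = setdiff(unique(protein_symbols$protein_id), map$protein_id)
  )
}

#' Per-TCEM cTEC expression
#'
#' For each motif, collects the median cTEC RPKM of the gene(s) encoding
#' every protein occurrence — a motif found k times in one protein
#' contributes that gene's value k times — and returns the median of the
#' collected values. Occurrences in unmapped proteins contribute nothing;
#' motifs with no contributing value have `NA` expression and are excluded
#' from expression-stratified analyses downstream.
#'
#' @param index A `tcem_index`.
#' @param gene_map Result of [map_proteins_to_genes()] (or its `map` tibble).
#' @param expression Tibble from [median_gene_expression()].
#' @return Tibble with `motif`, `expression`, `n_values`.
#' @export
tcem_expression <- function(index, gene_map, expression) {
  stopifnot(inherits(index, "tcem_index"))
  map <- if (is.list(gene_map) && !is.data.frame(gene_map)) gene_map$map else gene_map
  values <- index$occurrences |>
    dplyr::inner_join(map, by = "protein_id", relationship = "many-to-many") |>
    dplyr::inner_join(expression, by = "gene_id") |>
    dplyr::summarise(
      expression = stats::median(.data$median_rpkm),
      n_values = dplyr::n(),
      .by = "motif"
    )
  index$counts |>
    dplyr::select("motif") |>
    dplyr::left_join(values, by = "motif") |>
    dplyr::mutate(n_values = dplyr::coalesce(.data$n_values, 0L))
}

#' Stratify expression values into groups
#'
#' Tertile mode assigns `low`/`medium`/`high` by the tertile boundaries of
#' the defined values; percentile mode returns the percentile rank
#' (`rank/n`, average ranks for ties) in \[0, 1\]. `NA` values stay `NA`.
#'
#' @param values Numeric vector (may contain `NA`).
#' @param mode `"tertile"` or `"percentile"`.
#' @return Factor (`tertile`) or numeric vector (`percentile`).
#' @export
stratify_expression <- function(values, mode = c("tertile", "percentile")) {
  mode <- match.arg(mode)
  ok <- !is.na(values)
  if (mode == "percentile") {
    out <- rep(NA_real_, length(values))
    out[ok] <- rank(values[ok]) / sum(ok)
    return(out)
  }
  if (sum(ok) < 3) stop("need at least 3 defined values for tertiles", call. = FALSE)
  q <- stats::quantile(values[ok], c(1, 2) / 3, type = 7)
  if (q[1] == q[2]) warning("degenerate tertile boundaries: values nearly constant")
  out <- rep(NA_character_, length(values))
  out[ok] <- ifelse(values[ok] <= q[1], "low",
    ifelse(values[ok] <= q[2], "medium", "high")
  )
  factor(out, levels = c("low", "medium", "high"))
}

#' Flag motifs encoded by housekeeping genes
#'
#' A motif is flagged if any of its occurrences lies in a protein encoded by
#' a gene on the housekeeping list (the "any encoding gene" rule; switch to
#' `"all"` to require every mapped gene on the list).
#'
#' @param index A `tcem_index`.
#' @param gene_map Result of [map_proteins_to_genes()] (or its `map` tibble).
#' @param housekeeping_genes Character vector of housekeeping gene ids.
#' @param rule `"any"` (default) or `"all"` over a motif's mapped genes.
#' @return Tibble with `motif`, `housekeeping` (logical).
#' @export
housekeeping_flag <- function(index, gene_map, housekeeping_genes,
                              rule = c("any", "all")) {
  rule <- match.arg(rule)
  stopifnot(length(housekeeping_genes) > 0)
  map <- if (is.list(gene_map) && !is.data.frame(gene_map)) gene_map$map else gene_map
  agg <- if (rule == "any") any else all
  flags <- index$occurrences |>
    dplyr::inner_join(map, by = "protein_id", relationship = "many-to-many") |>
    dplyr::summarise(
      housekeeping = agg(.data$gene_id %in% housekeeping_genes),
      .by = "motif"
    )
  index$counts |>
    dplyr::select("motif") |>
    dplyr::left_join(flags, by = "motif") |>
    dplyr::mutate(housekeeping = dplyr::coalesce(.data$housekeeping, FALSE))
}
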