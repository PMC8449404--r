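# Shared fixtures, built once per test run and cached.

.fixtures <- new.env(parent = emptyenv())

# A structured synthetic "human" proteome with long-tailed TCEM counts,
# plus the full attribute profile (frequency, cTEC expression, thymo and
# immuno cleavage scores with a planted hydrophobic deficit).
human_fixture <- function() {
  if (!is.null(.fixtures$human)) return(.fixtures$human)
  proteome <- sim_structured_proteome(
    n_proteins = 60, protein_length = 360, n_pool = 300, seed = 101
  )
  index <- build_proteome_index(proteome)
  genes <- sprintf("G%03d", seq_len(nrow(proteome)))
  symbols <- sprintf("S%03d", seq_len(nrow(proteome)))
  expr_sim <- sim_expression(genes, n_samples = 4, seed = 102)
  median_expr <- median_gene_expression(
    compute_rpkm(normalize_counts(expr_sim$counts), expr_sim$exon_length)
  )
  gene_map <- map_proteins_to_genes(
    tibble::tibble(protein_id = proteome$protein_id, symbol = symbols),
    tibble::tibble(gene_id = genes, symbol = symbols)
  )
  expression <- tcem_expression(index, gene_map, median_expr)
  tables <- sim_cleavage_tables(theta = 0.2)
  thymo <- proteome_cleavage_scores(
    proteome, tables$thymo$prevalence, tables$thymo$background
  )
  immuno <- proteome_cleavage_scores(
    proteome, tables$immuno$prevalence, tables$immuno$background
  )
  profile <- tcem_profile(index, expression = expression,
    thymo = thymo, immuno = immuno)
  .fixtures$human <- list(
    proteome = proteome, index = index, genes = genes,
    expr_sim = expr_sim, median_expr = median_expr, gene_map = gene_map,
    expression = expression, tables = tables, thymo = thymo,
    immuno = immuno, profile = profile
  )
  .fixtures$human
}

# Brute-force TCEM count oracle: a naive per-position scan counting 5-mer
# starts with >= 3 residues before and >= 1 after, within one protein.
oracle_tcem_counts <- function(proteome) {
  counts <- list()
  for (r in seq_len(nrow(proteome))) {
    s <- strsplit(proteome$sequence[r], "")[[1]]
    L <- length(s)
    if (L < 9) next
    for (p in 4:(L - 5)) {
      win <- s[(p - 3):(p + 5)]
      if (any(!win %in% AA_STANDARD)) next
      m <- paste(s[p:(p + 4)], collapse = "")
      counts[[m]] <- (counts[[m]] %||% 0L) + 1L
    }
  }
  counts
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Brute-force best-hit oracle: double loop over proteins and window starts
# through the public pairwise scorer.
oracle_best_hit <- function(peptide, proteome) {
  L <- nchar(peptide)
  best <- -Inf
  for (r in seq_len(nrow(proteome))) {
    seq <- proteome$sequence[r]
    if (nchar(seq) < L) next
    for (p in seq_len(nchar(seq) - L + 1)) {
      win <- substr(seq, p, p + L - 1)
      s <- blosum_similarity(peptide, win)
      if (s > best) best <- s
    }
  }
  best
}

# Independent re-implementation of the iterative redundancy filter used to
# cross-check iterative_dedup (deliberately simple and quadratic).
oracle_dedup <- function(peptides, threshold = 0.5, k = 1L) {
  keep <- unique(peptides)
  repeat {
    n <- length(keep)
    if (n < 2) break
    d <- matrix(0, n, n)
    for (i in seq_len(n)) {
      for (j in seq_len(n)) {
        if (i != j) d[i, j] <- ktuple_distance(keep[i], keep[j], k)
      }
    }
    off <- d
    diag(off) <- Inf
    if (min(off) >= threshold) break
    members <- which(apply(off == min(off), 1, any))
    meand <- rowSums(d) / (n - 1)
    cand <- members[meand[members] == min(meand[members])]
    drop <- cand[order(keep[cand])][1]
    keep <- keep[-drop]
  }
  keep
}

# Exact two-sided Fisher p by hypergeometric enumeration.
oracle_fisher_p <- function(a, b, c, d) {
  m <- a + b        # row 1 total
  n <- c + d        # row 2 total
  k <- a + c        # column 1 total
  lo <- max(0, k - n)
  hi <- min(k, m)
  probs <- stats::dhyper(lo:hi, m, n, k)
  p_obs <- stats::dhyper(a, m, n, k)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

random_peptides <- function(n, length = 9) {
  vapply(seq_len(n), function(i) {
    paste(sample(AA_STANDARD, length, replace = TRUE), collapse = "")
  }, character(1))
}
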