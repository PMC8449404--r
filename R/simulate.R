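# Synthetic-data generators. Every generator is a pure function of its
# arguments plus `seed`, and emits ground truth alongside the data so that
# parameter-recovery tests can score the pipeline without re-deriving the
# planted effects.

with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

#' Simulate a proteome with optional planted motifs
#'
#' Residues are drawn i.i.d. from `aa_freq` (uniform by default; no
#' homology structure, which keeps TCEM counts analytically controllable).
#' Motifs listed in `planted` are written into full 9-mer contexts at
#' non-overlapping positions so that their TCEM frequency in the output is
#' exactly the requested count; the generator retries if a background
#' collision would distort a planted count.
#'
#' @param n_proteins Number of proteins.
#' @param protein_length Integer vector recycled over proteins.
#' @param aa_freq Named residue sampling weights over [AA_STANDARD].
#' @param planted Optional tibble with `motif`, `n` (exact TCEM counts to
#'   plant).
#' @param seed RNG seed.
#' @return Tibble with `protein_id`, `sequence`; planted positions in
#'   `attr(, "planted_at")`.
#' @export
sim_proteome <- function(n_proteins = 50, protein_length = 400,
                         aa_freq = NULL, planted = NULL, seed = 1) {
  if (n_proteins == 0) {
    warning("zero proteins requested: empty proteome")
    return(tibble::tibble(protein_id = character(), sequence = character()))
  }
  if (is.null(aa_freq)) aa_freq <- stats::setNames(rep(1, 20), AA_STANDARD)
  lens <- rep_len(protein_length, n_proteins)
  with_seed(seed, {
    for (attempt in 1:20) {
      seqs <- vapply(lens, function(L) {
        paste(sample(AA_STANDARD, L, replace = TRUE, prob = aa_freq[AA_STANDARD]),
          collapse = ""
        )
      }, character(1))
      proteome <- tibble::tibble(
        protein_id = sprintf("prot%04d", seq_len(n_proteins)),
        sequence = seqs
      )
      if (is.null(planted)) return(proteome)
      planted_at <- plant_motifs(proteome, planted)
      if (is.null(planted_at)) next  # collision; redraw
      proteome$sequence <- attr(planted_at, "sequences")
      idx <- build_proteome_index(proteome)
      if (all(tcem_frequency(idx, planted$motif) == planted$n)) {
        attr(planted_at, "sequences") <- NULL
        attr(proteome, "planted_at") <- planted_at
        return(proteome)
      }
    }
    stop("could not plant motifs at exact counts in 20 attempts", call. = FALSE)
  })
}

#' Simulate a proteome with a long-tailed TCEM frequency distribution
#'
#' Real proteomes reuse motifs heavily (repeats, paralogous families), so
#' TCEM counts are long-tailed rather than near-uniform. This generator
#' emulates that at desk scale: proteins are built from 9-residue blocks
#' whose TCEM is drawn from a pool of `n_pool` motifs with Zipf weights
#' (`weight ~ rank^-zipf_s`), while block flanks and block-overlap windows
#' contribute background motifs at count ~ 1.
#'
#' @param n_proteins,protein_length Proteome dimensions (length is rounded
#'   down to whole blocks).
#' @param n_pool Number of distinct pooled motifs.
#' @param zipf_s Zipf exponent of the pool weights.
#' @param seed RNG seed.
#' @return Tibble with `protein_id`, `sequence`; the pool motifs in
#'   `attr(, "motif_pool")`.
#' @export
sim_structured_proteome <- function(n_proteins = 60, protein_length = 360,
                                    n_pool = 300, zipf_s = 1, seed = 1) {
  with_seed(seed, {
    pool <- unique(replicate(
      n_pool * 2,
      paste(sample(AA_STANDARD, 5, TRUE), collapse = "")
    ))[seq_len(n_pool)]
    w <- (seq_len(n_pool))^(-zipf_s)
    n_blocks <- protein_length %/% 9L
    seqs <- vapply(seq_len(n_proteins), function(i) {
      motifs <- sample(pool, n_blocks, replace = TRUE, prob = w)
      blocks <- vapply(motifs, function(m) {
        paste0(
          paste(sample(AA_STANDARD, 3, TRUE), collapse = ""),
          m,
          sample(AA_STANDARD, 1)
        )
      }, character(1))
      paste(blocks, collapse = "")
    }, character(1))
    out <- tibble::tibble(
      protein_id = sprintf("prot%04d", seq_len(n_proteins)),
      sequence = seqs
    )
    attr(out, "motif_pool") <- pool
    out
  })
}

# Writes each planted motif into `n` distinct 9-mer slots. Slots are taken
# on a stride-9 grid so planted windows never overlap. Returns NULL when
# there are not enough slots.
plant_motifs <- function(proteome, planted) {
  seqs <- proteome$sequence
  slots <- purrr::imap(seqs, function(s, i) {
    L <- nchar(s)
    if (L < 9) return(NULL)
    starts <- seq(1L, L - 8L, by = 9L)
    tibble::tibble(protein = i, start = starts)
  })
  slots <- dplyr::bind_rows(slots)
  need <- sum(planted$n)
  if (nrow(slots) < need) return(NULL)
  pick <- slots[sample.int(nrow(slots), need), ]
  pick$motif <- rep(planted$motif, planted$n)
  for (r in seq_len(nrow(pick))) {
    i <- pick$protein[r]
    p <- pick$start[r]
    substr(seqs[i], p + 3L, p + 7L) <- pick$motif[r]
  }
  out <- tibble::tibble(
    motif = pick$motif,
    protein_id = proteome$protein_id[pick$protein],
    start = pick$start
  )
  attr(out, "sequences") <- seqs
  out
}

#' Simulate a cTEC count matrix with a planted housekeeping set
#'
#' Negative-binomial counts per gene and sample with a common dispersion;
#' a random `housekeeping_fraction` of genes is expressed at
#' `housekeeping_fold` times the base level. Ground truth carries each
#' gene's expected RPKM.
#'
#' @param gene_ids Character vector of gene ids.
#' @param n_samples Number of cTEC samples.
#' @param base_rpkm Base expected RPKM of non-housekeeping genes.
#' @param housekeeping_fraction,housekeeping_fold Planting parameters.
#' @param dispersion Negative-binomial dispersion (`size = 1/dispersion`).
#' @param lib_size Target library size per sample.
#' @param seed RNG seed.
#' @return List with `counts` (tibble `gene_id` + sample columns),
#'   `exon_length` (tibble), `housekeeping` (character vector) and
#'   `truth` (tibble `gene_id`, `expected_rpkm`, `housekeeping`).
#' @export
sim_expression <- function(gene_ids, n_samples = 4, base_rpkm = 20,
                           housekeeping_fraction = 0.1,
                           housekeeping_fold = 10, dispersion = 0.2,
                           lib_size = 2e6, seed = 1) {
  n <- length(gene_ids)
  with_seed(seed, {
    hk <- sample(gene_ids, max(1, round(housekeeping_fraction * n)))
    exon_length <- tibble::tibble(
      gene_id = gene_ids,
      exon_length = sample(500:5000, n, replace = TRUE)
    )
    expected_rpkm <- ifelse(gene_ids %in% hk,
      base_rpkm * housekeeping_fold, base_rpkm
    )
    mu_raw <- expected_rpkm * exon_length$exon_length / 1e3
    mu <- mu_raw / sum(mu_raw) * lib_size
    counts <- matrix(
      stats::rnbinom(n * n_samples, mu = rep(mu, n_samples), size = 1 / dispersion),
      nrow = n,
      dimnames = list(gene_ids, sprintf("ctec%02d", seq_len(n_samples)))
    )
    list(
      counts = tibble::as_tibble(counts, rownames = "gene_id"),
      exon_length = exon_length,
      housekeeping = hk,
      truth = tibble::tibble(
        gene_id = gene_ids,
        expected_rpkm = expected_rpkm,
        housekeeping = gene_ids %in% hk
      )
    )
  })
}

#' Simulate thymo- and immunoproteasomal cleavage preference tables
#'
#' The immunoproteasome table has prevalence equal to the background at
#' every position (all preference scores 1). The thymoproteasome table
#' additionally carries a hydrophobic deficit on the N-terminal flank of
#' the cleavage site — strongest at position -1 (the residue whose C-side
#' bond is cut, i.e. reduced chymotrypsin-like activity) and decaying
#' toward position -5: the prevalence of hydrophobic residues at position
#' -k is multiplied by `theta^(1/k)` and the position renormalized. The
#' graded flank matters because the per-site score is a median over ten
#' flanking positions, which a single perturbed position cannot move.
#' `theta = 1` makes both tables uniform (all preference scores 1).
#'
#' @param theta Hydrophobic deficit at position -1, in (0, 1].
#' @param background Named amino-acid composition (defaults uniform).
#' @return List with elements `thymo` and `immuno`, each a list of
#'   `prevalence` and `background` tibbles, plus `hydrophobic` (the
#'   affected residue set).
#' @export
sim_cleavage_tables <- function(theta = 0.2, background = NULL) {
  stopifnot(theta > 0, theta <= 1)
  if (is.null(background)) {
    background <- stats::setNames(rep(1 / 20, 20), AA_STANDARD)
  }
  background <- background[AA_STANDARD] / sum(background[AA_STANDARD])
  bg_tbl <- tibble::tibble(
    amino_acid = AA_STANDARD,
    fraction = unname(background)
  )
  positions <- c(-5:-1, 1:5)
  base <- tidyr::expand_grid(position = positions, amino_acid = AA_STANDARD) |>
    dplyr::mutate(prevalence = unname(background[.data$amino_acid]))
  thymo <- base |>
    dplyr::mutate(prevalence = ifelse(
      .data$position < 0L & .data$amino_acid %in% AA_HYDROPHOBIC,
      .data$prevalence * theta^(1 / abs(.data$position)), .data$prevalence
    )) |>
    dplyr::mutate(prevalence = .data$prevalence / sum(.data$prevalence),
      .by = "position")
  list(
    thymo = list(prevalence = thymo, background = bg_tbl),
    immuno = list(prevalence = base, background = bg_tbl),
    hydrophobic = AA_HYDROPHOBIC
  )
}

#' Toy position-weight-matrix HLA binding predictor
#'
#' A deterministic per-allele predictor good enough to create
#' allele-specific presented peptide sets offline: each allele prefers one
#' residue at anchor positions 2 and 9 (drawn from the allele name's
#' hash), and the predicted affinity decreases with anchor matches.
#' Rank percentiles are the within-allele percentile ranks of affinity.
#'
#' @param peptides Character vector of 9-mers.
#' @param alleles Character vector of allele names.
#' @param match_fold Affinity fold-change per anchor match.
#' @param base_nm Affinity (nM) with no anchor match.
#' @param seed RNG seed (controls the anchor preferences only).
#' @return Tibble with `peptide`, `allele`, `affinity_nm`, `rank_pct`.
#' @export
toy_binding_predictor <- function(peptides, alleles, match_fold = 25,
                                  base_nm = 5000, seed = 1) {
  alleles_u <- unique(alleles)
  with_seed(seed, {
    prefs <- tibble::tibble(
      allele = alleles_u,
      p2 = sample(AA_STANDARD, length(alleles_u), replace = TRUE),
      p9 = sample(AA_STANDARD, length(alleles_u), replace = TRUE)
    )
    purrr::pmap(prefs, function(allele, p2, p9) {
      matches <- (substr(peptides, 2, 2) == p2) + (substr(peptides, 9, 9) == p9)
      aff <- base_nm / match_fold^matches
      # deterministic jitter so ranks are unambiguous
      aff <- aff * (1 + 0.01 * (seq_along(peptides) %% 97) / 97)
      tibble::tibble(
        peptide = peptides, allele = allele,
        affinity_nm = aff,
        rank_pct = 100 * rank(aff) / length(aff)
      )
    }) |>
      dplyr::bind_rows()
  })
}

#' Simulate an assay-level immunogenicity dataset with planted effects
#'
#' Each peptide's latent immunogenicity probability follows a logistic
#' model on its TCEM attributes:
#' `logit(p) = beta0 + beta_freq * [count >= 4] + beta_mid * [expression
#' percentile in the middle third] + beta_cleav * [thymo score >= Q1]`
#' (the middle-third term plants the bimodal expression effect). Assay
#' records are drawn so that the labelling rules recover the latent label:
#' immunogenic pairs get `n_assays` majority-positive T cell assays,
#' nonimmunogenic ones all-negative. Binding predictions come from the toy
#' predictor and pass the dataset-1 filter.
#'
#' @param attributes Tibble with `motif`, `count`, `expression`,
#'   `thymo_score` (human-proteome TCEM attributes to sample from).
#' @param n_peptides Number of distinct peptides.
#' @param beta0,beta_freq,beta_mid,beta_cleav Model coefficients.
#' @param n_assays T cell assays per pair.
#' @param binding_assay_fraction Fraction of pairs with additional
#'   positive MHC-binding assays (feeds the dataset-2 branch).
#' @param alleles Allele pool.
#' @param seed RNG seed.
#' @return List with `assays`, `predictions`, `peptides` (tibble
#'   `peptide`, `motif`, attribute columns, `latent_p`, `immunogenic`)
#'   and `truth` (the planted coefficients).
#' @export
sim_assay_dataset <- function(attributes, n_peptides = 2000,
                              beta0 = -1, beta_freq = 1, beta_mid = 1,
                              beta_cleav = 1, n_assays = 3,
                              binding_assay_fraction = 0.15,
                              alleles = c(
                                "HLA-A*02:01", "HLA-A*01:01",
                                "HLA-B*07:02", "HLA-B*08:01"
                              ),
                              seed = 1) {
  with_seed(seed, {
    rows <- attributes[sample.int(nrow(attributes), n_peptides, replace = TRUE), ]
    flank1 <- replicate(n_peptides, paste(sample(AA_STANDARD, 3, TRUE), collapse = ""))
    flank2 <- replicate(n_peptides, sample(AA_STANDARD, 1))
    peptide <- paste0(flank1, rows$motif, flank2)
    # de-duplicate peptides (same motif may be drawn twice)
    dup <- duplicated(peptide)
    while (any(dup)) {
      flank1[dup] <- replicate(sum(dup), paste(sample(AA_STANDARD, 3, TRUE), collapse = ""))
      peptide <- paste0(flank1, rows$motif, flank2)
      dup <- duplicated(peptide)
    }
    expr_pct <- stratify_expression(rows$expression, mode = "percentile")
    mid <- !is.na(expr_pct) & expr_pct > 1 / 3 & expr_pct <= 2 / 3
    thymo_q1 <- stats::quantile(rows$thymo_score, 0.25, na.rm = TRUE, type = 7)
    high_cleav <- !is.na(rows$thymo_score) & rows$thymo_score >= thymo_q1
    eta <- beta0 + beta_freq * (rows$count >= 4) + beta_mid * mid +
      beta_cleav * high_cleav
    p <- stats::plogis(eta)
    imm <- stats::runif(n_peptides) < p
    allele <- sample(alleles, n_peptides, replace = TRUE)

    n_pos <- ifelse(imm, ceiling(n_assays / 2) + 1, 0)
    n_pos <- pmin(n_pos, n_assays)
    assays <- tibble::tibble(
      peptide = rep(peptide, each = n_assays),
      allele = rep(allele, each = n_assays),
      assay_kind = "tcell",
      outcome = unlist(purrr::map2(n_pos, n_assays - n_pos, function(p, n) {
        c(rep("positive", p), rep("negative", n))
      })),
      source_taxon = "synthetic virus"
    )
    # a subset of pairs also has assay-verified binding (3 binding assays,
    # all positive) so the dataset-2 branch is populated
    verified <- stats::runif(n_peptides) < binding_assay_fraction
    if (any(verified)) {
      assays <- dplyr::bind_rows(
        assays,
        tibble::tibble(
          peptide = rep(peptide[verified], each = 3L),
          allele = rep(allele[verified], each = 3L),
          assay_kind = "mhc_binding",
          outcome = "positive",
          source_taxon = "synthetic virus"
        )
      )
    }
    predictions <- tibble::tibble(
      peptide = peptide, allele = allele,
      affinity_nm = stats::runif(n_peptides, 10, 400),
      rank_pct = stats::runif(n_peptides, 0.1, 1.9)
    )
    peptides <- tibble::tibble(
      peptide = peptide, allele = allele, motif = rows$motif,
      count = rows$count, expression = rows$expression,
      thymo_score = rows$thymo_score, latent_p = p, immunogenic = imm
    )
    list(
      assays = assays,
      predictions = predictions,
      peptides = peptides,
      truth = list(
        beta0 = beta0, beta_freq = beta_freq,
        beta_mid = beta_mid, beta_cleav = beta_cleav
      )
    )
  })
}

#' Simulate a single-TCR mutational scan
#'
#' Generates the variants of a 9-mer epitope obtained by substituting each
#' TCEM position (4-8) with every alternative residue, plus the original.
#' Relative TCR binding decays exponentially in motif similarity:
#' `binding = max(0, exp(lambda * (sim - 1)) + N(0, sigma))`; relative
#' activation follows binding through a threshold link (negligible below
#' 10% binding).
#'
#' @param epitope The original 9-mer.
#' @param lambda Similarity decay rate.
#' @param sigma Gaussian noise SD on relative binding.
#' @param seed RNG seed.
#' @return List with `scan` (tibble `variant`, `tcem`, `similarity`,
#'   `relative_binding`, `relative_activation`, `is_original`) and
#'   `truth` (`lambda`, `sigma` and the analytic 10%-binding similarity
#'   cutoff `sim_star`).
#' @export
sim_tcr_scan <- function(epitope, lambda = 8, sigma = 0, seed = 1) {
  assert_peptides(epitope, lengths = 9L)
  orig_tcem <- extract_tcem(epitope)
  variants <- purrr::map(4:8, function(pos) {
    cur <- substr(epitope, pos, pos)
    purrr::map_chr(setdiff(AA_STANDARD, cur), function(aa) {
      v <- epitope
      substr(v, pos, pos) <- aa
      v
    })
  })
  variants <- c(epitope, unlist(variants))
  tcems <- extract_tcem(variants)
  sims <- blosum_similarity(tcems, rep(orig_tcem, length(tcems)))
  with_seed(seed, {
    binding <- exp(lambda * (sims - 1)) + stats::rnorm(length(sims), 0, sigma)
    binding <- pmax(binding, 0)
    binding[1] <- 1
    activation <- ifelse(binding >= 0.1, binding, 0.079 * binding)
    list(
      scan = tibble::tibble(
        variant = variants, tcem = tcems, similarity = sims,
        relative_binding = binding, relative_activation = activation,
        is_original = variants == epitope
      ),
      truth = list(
        lambda = lambda, sigma = sigma,
        sim_star = 1 + log(0.1) / lambda
      )
    )
  })
}

#' Simulate a multi-individual naive CD8+ recognition dataset
#'
#' Builds an allele pool with allele-specific strongly-bound peptide sets
#' (via the toy predictor thresholds), assigns each individual a genotype,
#' and draws recognition of each presented peptide as
#' `Bernoulli(base_rate * np_penalty^[np])`. `np_penalty = 1` is the null
#' configuration.
#'
#' @param peptide_np Tibble with `peptide`, `is_np`.
#' @param n_individuals Number of individuals.
#' @param alleles Allele pool.
#' @param alleles_per_individual Genotype size.
#' @param bound_fraction Fraction of peptides strongly bound per allele.
#' @param base_rate Recognition probability of non-np presented peptides.
#' @param np_penalty Multiplier on the recognition probability of np
#'   peptides.
#' @param seed RNG seed.
#' @return List with `recognition`, `genotypes`, `predictions` and
#'   `truth`.
#' @export
sim_repertoire <- function(peptide_np, n_individuals = 27,
                           alleles = sprintf("HLA-A*%02d:01", 1:10),
                           alleles_per_individual = 6,
                           bound_fraction = 0.35,
                           base_rate = 0.5, np_penalty = 0.5, seed = 1) {
  peptides <- peptide_np$peptide
  with_seed(seed, {
    predictions <- purrr::map(alleles, function(al) {
      bound <- stats::runif(length(peptides)) < bound_fraction
      tibble::tibble(
        peptide = peptides, allele = al,
        affinity_nm = ifelse(bound, stats::runif(length(peptides), 5, 45),
          stats::runif(length(peptides), 100, 5000)
        ),
        rank_pct = ifelse(bound, stats::runif(length(peptides), 0.05, 0.45),
          stats::runif(length(peptides), 1, 50)
        )
      )
    }) |> dplyr::bind_rows()
    genotypes <- purrr::map(seq_len(n_individuals), function(i) {
      tibble::tibble(
        individual = sprintf("ind%02d", i),
        allele = sample(alleles, alleles_per_individual)
      )
    }) |> dplyr::bind_rows()
    strong <- predictions |>
      dplyr::filter(.data$affinity_nm < 50, .data$rank_pct < 0.5)
    presented <- genotypes |>
      dplyr::inner_join(strong, by = "allele", relationship = "many-to-many") |>
      dplyr::distinct(.data$individual, .data$peptide)
    presented <- presented |>
      dplyr::left_join(peptide_np, by = "peptide") |>
      dplyr::mutate(
        p = base_rate * ifelse(.data$is_np, np_penalty, 1),
        recognized = stats::runif(dplyr::n()) < .data$p
      )
    recognition <- dplyr::select(presented, "individual", "peptide", "recognized")
    list(
      recognition = recognition,
      genotypes = genotypes,
      predictions = predictions,
      truth = list(base_rate = base_rate, np_penalty = np_penalty)
    )
  })
}

#' Simulate a pathogen proteome as a mixture of foreign and host-like segments
#'
#' Builds proteins as mixtures of foreign segments (random sequence, whose
#' pentamers are essentially absent from the human proteome and therefore
#' np by the frequency criterion) and host-like segments copied verbatim
#' from random stretches of the human proteome (whose windows inherit the
#' human np rate). Alongside the sequences the generator emits the
#' expected np window fraction, computed from the per-window np status of
#' the source material: 1 for foreign-interior windows, the source
#' stretch's measured np rate for copied windows. Windows spanning a
#' segment boundary (8 per junction) are a small uncontrolled remainder.
#'
#' @param human_proteome Human proteome tibble (source of host-like
#'   segments).
#' @param np_profile Tibble with `motif`, `is_np` over human motifs.
#' @param foreign_fraction Probability that a segment is foreign
#'   (np-rich).
#' @param n_proteins,protein_length Pathogen proteome dimensions.
#' @param segment_length Segment length (residues).
#' @param seed RNG seed.
#' @return Tibble with `protein_id`, `sequence`; the construction-derived
#'   expectation in `attr(, "expected_np_fraction")`.
#' @export
sim_pathogen_proteome <- function(human_proteome, np_profile,
                                  foreign_fraction = 0.3, n_proteins = 8,
                                  protein_length = 360,
                                  segment_length = 60, seed = 1) {
  human_proteome <- as_proteome(human_proteome)
  idx <- build_proteome_index(human_proteome)
  occ <- idx$occurrences |>
    dplyr::left_join(np_profile, by = "motif") |>
    dplyr::mutate(is_np = dplyr::coalesce(.data$is_np, TRUE))
  seqs <- stats::setNames(human_proteome$sequence, human_proteome$protein_id)
  long_enough <- human_proteome[nchar(human_proteome$sequence) >= segment_length, ]
  if (nrow(long_enough) == 0) {
    stop("no human protein at least one segment long", call. = FALSE)
  }
  with_seed(seed, {
    n_segments <- protein_length %/% segment_length
    exp_np <- numeric(0)
    exp_w <- numeric(0)
    proteins <- purrr::map_chr(seq_len(n_proteins), function(i) {
      segs <- purrr::map_chr(seq_len(n_segments), function(s) {
        if (stats::runif(1) < foreign_fraction) {
          seg <- paste(sample(AA_STANDARD, segment_length, TRUE), collapse = "")
          exp_np <<- c(exp_np, 1)
        } else {
          src <- long_enough[sample.int(nrow(long_enough), 1), ]
          st <- sample.int(nchar(src$sequence) - segment_length + 1L, 1)
          seg <- substr(src$sequence, st, st + segment_length - 1L)
          win <- occ[occ$protein_id == src$protein_id &
            occ$start >= st & occ$start <= st + segment_length - 9L, ]
          exp_np <<- c(exp_np, mean(win$is_np))
        }
        exp_w <<- c(exp_w, segment_length - 8L)
        seg
      })
      paste(segs, collapse = "")
    })
    out <- tibble::tibble(
      protein_id = sprintf("path%03d", seq_len(n_proteins)),
      sequence = proteins
    )
    attr(out, "expected_np_fraction") <- sum(exp_np * exp_w) / sum(exp_w)
    out
  })
}

#' Simulate HLA association studies with planted risk/protective groups
#'
#' Constructs allele groups whose member alleles have high (risk) or low
#' (protective) presented np-TCEM fractions, and per-study odds ratios
#' increasing with the group-level np fraction plus noise, mirroring the
#' design in which predisposing allele groups present mainly np-TCEM
#' peptides.
#'
#' @param n_risk,n_protective Numbers of allele groups.
#' @param alleles_per_group Member alleles per group.
#' @param n_studies Number of association studies.
#' @param np_high,np_low Mean member np fractions of risk and protective
#'   groups.
#' @param sd_np SD of member np fractions around the group mean.
#' @param or_noise_sd SD of the per-study log-OR noise.
#' @param seed RNG seed.
#' @return List with `studies` (tibble `study_id`, `allele_group`,
#'   `odds_ratio`), `membership` (tibble `group`, `allele`,
#'   `is_common`), `allele_values` (tibble `allele`, `value`) and
#'   `truth` (group labels).
#' @export
sim_associations <- function(n_risk = 6, n_protective = 7,
                             alleles_per_group = 4, n_studies = 4,
                             np_high = 0.75, np_low = 0.35, sd_np = 0.05,
                             or_noise_sd = 0.2, seed = 1) {
  with_seed(seed, {
    groups <- tibble::tibble(
      group = c(
        sprintf("R%02d", seq_len(n_risk)),
        sprintf("P%02d", seq_len(n_protective))
      ),
      role = c(rep("risk", n_risk), rep("protective", n_protective)),
      mean_np = c(rep(np_high, n_risk), rep(np_low, n_protective))
    )
    membership <- groups |>
      dplyr::reframe(
        allele = sprintf("HLA-%s*%02d:01", .data$group, seq_len(alleles_per_group)),
        is_common = c(TRUE, stats::runif(alleles_per_group - 1) < 0.7),
        mean_np = .data$mean_np,
        .by = "group"
      )
    membership$value <- pmin(pmax(
      stats::rnorm(nrow(membership), membership$mean_np, sd_np), 0
    ), 1)
    studies <- purrr::map(seq_len(n_studies), function(s) {
      g <- groups
      tibble::tibble(
        study_id = sprintf("study%02d", s),
        allele_group = g$group,
        odds_ratio = exp(
          1.5 * (g$mean_np - mean(g$mean_np)) +
            stats::rnorm(nrow(g), 0, or_noise_sd)
        )
      )
    }) |> dplyr::bind_rows()
    list(
      studies = studies,
      membership = dplyr::select(membership, "group", "allele", "is_common"),
      allele_values = dplyr::select(
        dplyr::rename(membership, value2 = "value"), "allele",
        value = "value2"
      ),
      truth = dplyr::select(groups, "group", "role", "mean_np")
    )
  })
}
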