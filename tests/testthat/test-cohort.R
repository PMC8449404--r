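test_that("pair eligibility needs strong binding and two recognizing carriers", {
  predictions <- tibble::tibble(
    peptide = c("P1", "P2", "P3"),
    allele = "HLA-A*02:01",
    affinity_nm = c(40, 40, 60),
    rank_pct = c(0.4, 0.4, 0.4)
  )
  genotypes <- tibble::tibble(
    individual = c("i1", "i2"), allele = "HLA-A*02:01"
  )
  recognition <- tibble::tibble(
    individual = c("i1", "i2", "i1"),
    peptide = c("P1", "P1", "P2"),
    recognized = TRUE
  )
  el <- eligible_pairs(predictions, recognition, genotypes)
  expect_equal(el$peptide, "P1")   # P2: one carrier; P3: affinity fails
})

test_that("per-individual fractions and the 20-recognized inclusion rule", {
  peptides <- sprintf("P%02d", 1:60)
  eligible <- tibble::tibble(peptide = peptides, allele = "HLA-A*02:01")
  genotypes <- tibble::tibble(
    individual = c("rich", "poor"), allele = "HLA-A*02:01"
  )
  # "rich" recognizes 30 peptides, "poor" only 19
  recognition <- dplyr::bind_rows(
    tibble::tibble(individual = "rich", peptide = peptides,
      recognized = rep(c(TRUE, FALSE), c(30, 30))),
    tibble::tibble(individual = "poor", peptide = peptides,
      recognized = rep(c(TRUE, FALSE), c(19, 41)))
  )
  groups <- tibble::tibble(
    peptide = peptides, group = rep(c("g1", "g2"), each = 30)
  )
  fr <- per_individual_fractions(recognition, genotypes, eligible, groups)
  expect_setequal(unique(fr$individual), "rich")  # "poor" excluded at 19
  expect_equal(fr$fraction[fr$group == "g1"], 1)
  expect_equal(fr$fraction[fr$group == "g2"], 0)
  expect_equal(fr$n_presented, c(30, 30))
})

test_that("paired group comparison returns p = 1 for identical fractions", {
  fr <- tibble::tibble(
    individual = rep(sprintf("i%d", 1:8), 2),
    group = rep(c("a", "b"), each = 8),
    fraction = rep(seq(0.1, 0.8, by = 0.1), 2)
  )
  expect_warning(res <- paired_group_comparison(fr, "a", "b"), "zero")
  expect_equal(res$p_value, 1)
  expect_equal(res$direction, 0)
  expect_error(
    paired_group_comparison(fr[c(1:3, 9:11), ], "a", "b"),
    "complete pairs"
  )
})

test_that("np flag is the three-criterion disjunction with provenance", {
  cutoffs <- list(expression = 1.0, thymo = 0.8)
  profile <- tibble::tibble(
    motif = c("M1", "M2", "M3", "M4"),
    count = c(3, 10, 10, 10),
    expression = c(5, 5, 5, NA),
    thymo_score = c(1, 1, 0.5, 1)
  )
  np <- np_flag(profile, cutoffs)
  expect_equal(np$is_np, c(TRUE, FALSE, TRUE, TRUE))
  expect_true(np$np_freq[1])
  expect_true(np$np_cleav[3])
  expect_true(np$np_expr[4])    # undefined expression counts as low
  np2 <- np_flag(profile, cutoffs, missing_expression = "ignore")
  expect_false(np2$is_np[4])
})

test_that("np flag is monotone in every attribute", {
  cutoffs <- list(expression = 1.0, thymo = 0.8)
  set.seed(51)
  profile <- tibble::tibble(
    motif = sprintf("M%d", 1:50),
    count = sample(0:10, 50, TRUE),
    expression = runif(50, 0, 3),
    thymo_score = runif(50, 0, 2)
  )
  base <- np_flag(profile, cutoffs)
  lowered <- dplyr::mutate(profile,
    count = pmax(count - 2, 0),
    expression = expression / 2,
    thymo_score = thymo_score / 2
  )
  after <- np_flag(lowered, cutoffs)
  expect_true(all(after$is_np >= base$is_np))
})

test_that("pathogen np fraction is window-weighted and handles unseen motifs", {
  np_profile <- tibble::tibble(
    motif = c("QWERT", "KLMNP"), is_np = c(FALSE, TRUE)
  )
  # all windows carry motifs absent from the human profile -> 1.0
  expect_equal(
    pathogen_np_fraction(c(p = "CCCYYYYYG"), np_profile), 1
  )
  # all windows carry the non-np motif -> 0
  expect_equal(
    pathogen_np_fraction(c(p = "CCCQWERTG"), np_profile), 0
  )
  # concatenation: window-count-weighted mean of the parts
  pA <- "CCCQWERTG"                 # 1 window, non-np
  pB <- "CCCKLMNPGCCCKLMNPG"        # 10 windows, np where motif = KLMNP
  fA <- pathogen_np_fraction(c(p = pA), np_profile)
  fB <- pathogen_np_fraction(c(p = pB), np_profile)
  fAB <- pathogen_np_fraction(c(a = pA, b = pB), np_profile)
  expect_equal(fAB, (1 * fA + 10 * fB) / 11)
})

test_that("pathogen np composition matches the construction-derived expectation", {
  h <- human_fixture()
  cuts <- np_cutoffs(h$profile)
  np <- np_flag(h$profile, cuts)
  for (ff in c(0.2, 0.6)) {
    pathogen <- sim_pathogen_proteome(
      h$proteome, np[c("motif", "is_np")],
      foreign_fraction = ff, n_proteins = 20, protein_length = 600,
      segment_length = 120, seed = 52
    )
    expected <- attr(pathogen, "expected_np_fraction")
    frac <- pathogen_np_fraction(pathogen, np[c("motif", "is_np")])
    expect_lt(abs(frac - expected), 0.05)
    # more foreign material can only push the fraction up
    expect_gte(frac, 0)
  }
})

test_that("per-allele presented np fraction and the fallback-N rule", {
  peptide_np <- tibble::tibble(
    peptide = sprintf("P%d", 1:12),
    is_np = rep(c(TRUE, FALSE), 6)
  )
  mk_pred <- function(allele, bound_peps, n_bound_target = NULL) {
    tibble::tibble(
      peptide = peptide_np$peptide,
      allele = allele,
      affinity_nm = ifelse(peptide_np$peptide %in% bound_peps, 10,
        100 + seq_len(12)),
      rank_pct = ifelse(peptide_np$peptide %in% bound_peps, 0.1, 5)
    )
  }
  # allele binding 4 peptides, 3 np -> 0.75
  pred <- mk_pred("HLA-A*01:01", c("P1", "P3", "P5", "P2"))
  out <- allele_presented_np_fraction(pred, peptide_np)
  expect_equal(out$np_fraction, 0.75)
  expect_false(out$fallback)

  # zero binders: N = median(5, 7, 9) = 7 lowest-affinity fallback peptides
  preds <- dplyr::bind_rows(
    mk_pred("HLA-B*01:01", sprintf("P%d", 1:5)),
    mk_pred("HLA-B*02:01", sprintf("P%d", 1:7)),
    mk_pred("HLA-B*03:01", sprintf("P%d", 1:9)),
    mk_pred("HLA-B*04:01", character(0))
  )
  out2 <- allele_presented_np_fraction(preds, peptide_np)
  fb <- out2[out2$allele == "HLA-B*04:01", ]
  expect_true(fb$fallback)
  # 7 lowest affinities are P1..P7 -> 4 np of 7
  expect_equal(fb$np_fraction, 4 / 7)

  # single-allele locus with no binders has no defined fallback
  solo <- mk_pred("HLA-C*01:02", character(0))
  expect_error(allele_presented_np_fraction(solo, peptide_np), "fallback")
})

test_that("across-allele variance falls with proteome size", {
  # binomially noisy presentation: small proteomes -> few bound peptides
  set.seed(53)
  sizes <- tibble::tibble(
    species = sprintf("sp%02d", 1:12),
    proteome_size = round(10^seq(2.5, 5, length.out = 12))
  )
  fractions <- purrr::pmap(sizes, function(species, proteome_size) {
    n_bound <- pmax(3, round(proteome_size / 500))
    tibble::tibble(
      species = species,
      allele = sprintf("A%02d", 1:12),
      np_fraction = rbinom(12, n_bound, 0.6) / n_bound
    )
  }) |> dplyr::bind_rows()
  res <- variance_vs_proteome_size(fractions, sizes)
  expect_lt(res$rho, -0.5)
  expect_lt(res$p_value, 0.05)

  # permuted sizes: correlation collapses
  perm <- sizes
  perm$proteome_size <- sample(perm$proteome_size)
  res2 <- variance_vs_proteome_size(fractions, perm)
  expect_gt(res2$p_value, res$p_value)

  const <- dplyr::mutate(fractions, np_fraction = 0.5)
  expect_true(all(variance_vs_proteome_size(const, sizes)$variances$variance == 0))
})

test_that("rank-percentile aggregation labels extremes and enforces coverage", {
  studies <- tibble::tibble(
    study_id = rep(c("s1", "s2"), each = 3),
    allele_group = rep(c("g_low", "g_mid", "g_high"), 2),
    odds_ratio = c(0.5, 1.0, 2.0, 0.6, 1.1, 3.0)
  )
  res <- rank_percentile_aggregation(studies)
  expect_equal(res$protective, "g_low")
  expect_equal(res$risk, "g_high")
  expect_equal(
    res$percentiles$mean_percentile,
    c(1 / 3, 2 / 3, 1)
  )

  # a group in only 1 of 2 studies misses 75% coverage
  studies2 <- dplyr::bind_rows(
    studies,
    tibble::tibble(study_id = "s1", allele_group = "g_once", odds_ratio = 0.1)
  )
  res2 <- rank_percentile_aggregation(studies2)
  expect_false("g_once" %in% res2$percentiles$allele_group)

  # invariance under strictly monotone OR transforms
  studies3 <- dplyr::mutate(studies, odds_ratio = odds_ratio^3)
  res3 <- rank_percentile_aggregation(studies3)
  expect_equal(res3$protective, res$protective)
  expect_equal(res3$risk, res$risk)

  expect_error(
    rank_percentile_aggregation(studies[studies$study_id == "s1", ]),
    "at least 2"
  )
})

test_that("group-level values average members (optionally common only)", {
  values <- tibble::tibble(
    allele = c("a1", "a2", "b1"), value = c(0.4, 0.6, 0.9)
  )
  membership <- tibble::tibble(
    group = c("sero1", "sero1", "twodigit"),
    allele = c("a1", "a2", "b1"),
    is_common = c(TRUE, FALSE, TRUE)
  )
  res <- group_level_np_fraction(values, membership)
  expect_equal(res$value[res$group == "sero1"], 0.5)
  expect_equal(res$value[res$group == "twodigit"], 0.9)

  res2 <- group_level_np_fraction(values, membership, common_only = TRUE)
  expect_equal(res2$value[res2$group == "sero1"], 0.4)

  bad <- tibble::tibble(group = "ghost", allele = "zz", is_common = TRUE)
  expect_error(group_level_np_fraction(values, bad), "no member")
})
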