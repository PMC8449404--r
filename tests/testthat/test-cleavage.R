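uniform_tables <- sim_cleavage_tables(theta = 1)

test_that("preference scores are prevalence/background ratios", {
  pref <- uniform_tables$thymo$prevalence
  bg <- uniform_tables$thymo$background
  sc <- preference_scores(pref, bg)
  expect_true(all(sc$c == 1))

  # one amino acid twice as frequent at position +1
  pref2 <- pref
  pref2$prevalence[pref2$position == 1 & pref2$amino_acid == "L"] <- 0.10
  pref2$prevalence[pref2$position == 1 & pref2$amino_acid == "A"] <- 0.00
  sc2 <- preference_scores(pref2, bg)
  expect_equal(sc2$c[sc2$position == 1 & sc2$amino_acid == "L"], 2)
  expect_equal(sc2$c[sc2$position == 1 & sc2$amino_acid == "A"], 0)
})

test_that("preference scores validate their inputs", {
  pref <- uniform_tables$thymo$prevalence
  bad_bg <- dplyr::mutate(uniform_tables$thymo$background,
    fraction = ifelse(.data$amino_acid == "L", 0, .data$fraction))
  expect_error(preference_scores(pref, bad_bg), "zero/missing background")
  bad_pref <- dplyr::mutate(pref,
    prevalence = ifelse(.data$position == 1, .data$prevalence * 2, .data$prevalence))
  expect_error(preference_scores(bad_pref, uniform_tables$thymo$background),
    "sum to 1")
})

test_that("site scores are medians over available flanking positions", {
  # hand-built table: c depends only on the residue
  cvals <- stats::setNames(seq(0.1, 2, length.out = 20), AA_STANDARD)
  scores <- tidyr::expand_grid(
    position = c(-5:-1, 1:5), amino_acid = AA_STANDARD
  )
  scores$c <- cvals[scores$amino_acid]

  prot <- "ACDEFGHIKLM"  # 11 residues
  ss <- site_cleavage_scores(prot, scores)
  expect_equal(nrow(ss), 10L)
  res <- strsplit(prot, "")[[1]]
  # central site 5 (between E and F): full context, residues 1..10
  expect_equal(ss$score[ss$site == 5], median(cvals[res[1:10]]))
  # site 1: one upstream residue + five downstream -> 6 values
  expect_equal(ss$score[ss$site == 1], median(cvals[res[1:6]]))
  # uniform table gives all-1 site scores
  ss1 <- site_cleavage_scores(prot, preference_scores(
    uniform_tables$thymo$prevalence, uniform_tables$thymo$background))
  expect_true(all(ss1$score == 1))
})

test_that("require_full_context masks short-context sites", {
  cvals <- stats::setNames(rep(1, 20), AA_STANDARD)
  scores <- tidyr::expand_grid(position = c(-5:-1, 1:5), amino_acid = AA_STANDARD)
  scores$c <- cvals[scores$amino_acid]
  ss <- site_cleavage_scores("ACDEFGHIKLMNP", scores, require_full_context = TRUE)
  expect_true(is.na(ss$score[ss$site == 1]))
  expect_false(is.na(ss$score[ss$site == 6]))
})

test_that("formation scores average the two flanking sites and drop termini", {
  prot <- paste(rep("A", 20), collapse = "")
  sites <- tibble::tibble(site = 1:19, score = seq(0.1, 1.9, by = 0.1))
  fs <- formation_scores(prot, sites)
  expect_equal(nrow(fs), 12L)
  # window at start 2: sites 1 and 10 -> (0.1 + 1.0) / 2
  expect_equal(fs$cbar[fs$start == 2], (0.1 + 1.0) / 2)
  # first and last windows excluded
  expect_true(is.na(fs$cbar[fs$start == 1]))
  expect_true(is.na(fs$cbar[fs$start == 12]))

  fs2 <- formation_scores(prot, sites, terminal = "cleaved")
  expect_equal(fs2$cbar[fs2$start == 1], (1 + sites$score[9]) / 2)
  expect_false(any(is.na(fs2$cbar)))
})

test_that("uniform preference tables give every TCEM score exactly 1", {
  proteome <- sim_proteome(n_proteins = 5, protein_length = 120, seed = 21)
  thy <- proteome_cleavage_scores(
    proteome, uniform_tables$thymo$prevalence, uniform_tables$thymo$background
  )
  imm <- proteome_cleavage_scores(
    proteome, uniform_tables$immuno$prevalence, uniform_tables$immuno$background
  )
  expect_true(all(thy$score == 1))
  expect_true(all(imm$score == 1))
  expect_equal(thy, imm)  # same table in, same cascade out
})

test_that("per-TCEM score is the median formation score of its windows", {
  # single protein, deficit table; check one motif against a manual median
  tabs <- sim_cleavage_tables(theta = 0.3)
  proteome <- sim_proteome(n_proteins = 1, protein_length = 80, seed = 22)
  out <- proteome_cleavage_scores(
    proteome, tabs$thymo$prevalence, tabs$thymo$background
  )
  sc <- preference_scores(tabs$thymo$prevalence, tabs$thymo$background)
  ss <- site_cleavage_scores(proteome$sequence, sc)
  fs <- formation_scores(proteome$sequence, ss)
  fs <- fs[!is.na(fs$cbar), ]
  manual <- tapply(fs$cbar, fs$motif, median)
  expect_equal(out$score, as.numeric(manual[out$motif]))
})

test_that("cleavage stratification splits at the type-7 first quartile", {
  g <- stratify_cleavage(1:100)
  expect_equal(as.character(g[10]), "low")     # Q1 = 25.75
  expect_equal(as.character(g[26]), "normal")
  q1 <- quantile(1:100, 0.25, type = 7, names = FALSE)
  expect_equal(as.character(g)[1:100 < q1], rep("low", sum(1:100 < q1)))
  expect_warning(stratify_cleavage(rep(1, 10)), "degenerate")
  expect_error(stratify_cleavage(c(1, 2, 3)), "at least 4")
})

test_that("a planted hydrophobic cleavage deficit lowers thymo scores", {
  h <- human_fixture()
  cmp <- dplyr::inner_join(
    dplyr::select(h$thymo, motif, thymo = score),
    dplyr::select(h$immuno, motif, immuno = score),
    by = "motif"
  )
  # the immuno table equals its background, so the cascade is the identity
  expect_true(all(cmp$immuno == 1))

  # motifs whose windows end in a hydrophobic residue score lower under the
  # thymoproteasome than the others (one-sided rank-sum)
  occ <- h$index$occurrences
  seqs <- stats::setNames(h$proteome$sequence, h$proteome$protein_id)
  last_res <- substr(
    seqs[occ$protein_id],
    occ$start + 8L, occ$start + 8L
  )
  hydro_motifs <- unique(occ$motif[last_res %in% c("A", "C", "F", "I", "L", "M", "V")])
  flagged <- cmp$motif %in% hydro_motifs
  p <- stats::wilcox.test(
    cmp$thymo[flagged], cmp$thymo[!flagged],
    alternative = "less"
  )$p.value
  expect_lt(p, 0.01)
})

test_that("raising one preference score never lowers a site score", {
  cvals <- stats::setNames(runif(20, 0.2, 2), AA_STANDARD)
  scores <- tidyr::expand_grid(position = c(-5:-1, 1:5), amino_acid = AA_STANDARD)
  scores$c <- cvals[scores$amino_acid]
  prot <- paste(sample(AA_STANDARD, 40, TRUE), collapse = "")
  base <- site_cleavage_scores(prot, scores)
  bumped <- scores
  bumped$c[bumped$position == -1 & bumped$amino_acid == "L"] <-
    bumped$c[bumped$position == -1 & bumped$amino_acid == "L"] * 10
  after <- site_cleavage_scores(prot, bumped)
  expect_true(all(after$score >= base$score - 1e-12))
})
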