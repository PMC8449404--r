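mk_assays <- function(peptide, allele = "HLA-A*02:01", kind = "tcell",
                      outcome = "positive", taxon = "vaccinia virus") {
  tibble::tibble(
    peptide = peptide, allele = allele, assay_kind = kind,
    outcome = outcome, source_taxon = taxon
  )
}

test_that("assay filtering enforces length, alphabet, source and allele resolution", {
  assays <- dplyr::bind_rows(
    mk_assays("ACDEFGHIK"),
    mk_assays("ACDEFGHIKLM"),                          # 11-mer
    mk_assays("ACDEFGHIX"),                            # non-standard
    mk_assays("ACDEFGHIK", taxon = "Homo sapiens (human)"),
    mk_assays("ACDEFGHIK", allele = "HLA-A*02"),       # 2-digit
    mk_assays("ACDEFGHIKL")
  )
  kept <- filter_assays(assays)
  expect_equal(kept$peptide, c("ACDEFGHIK", "ACDEFGHIKL"))
  rejected <- attr(kept, "rejected")
  expect_setequal(
    rejected$reason,
    c("length", "nonstandard_letter", "human_source", "allele_resolution")
  )
})

test_that("immunogenicity labels follow the solely-negative / majority-positive rules", {
  assays <- dplyr::bind_rows(
    mk_assays(rep("AAAAAAAAA", 3), outcome = c("negative", "negative", "negative")),
    mk_assays(rep("CCCCCCCCC", 3), outcome = c("positive", "positive", "negative")),
    mk_assays(rep("DDDDDDDDD", 2), outcome = c("positive", "negative"))
  )
  lab <- label_immunogenicity(assays)
  expect_equal(as.character(lab$label[lab$peptide == "AAAAAAAAA"]), "nonimmunogenic")
  expect_equal(as.character(lab$label[lab$peptide == "CCCCCCCCC"]), "immunogenic")
  expect_false("DDDDDDDDD" %in% lab$peptide)  # 1:1 tie excluded
})

test_that("peptides with opposite labels across alleles are excluded entirely", {
  assays <- dplyr::bind_rows(
    mk_assays("AAAAAAAAA", allele = "HLA-A*02:01", outcome = "positive"),
    mk_assays("AAAAAAAAA", allele = "HLA-B*07:02", outcome = "negative")
  )
  lab <- label_immunogenicity(assays)
  expect_equal(nrow(lab), 0L)
})

test_that("dataset-1 filter keeps affinity < 500 nM or rank < 2%", {
  pairs <- tibble::tibble(
    peptide = c("A", "B", "C", "D"), allele = "HLA-A*02:01"
  )
  pred <- tibble::tibble(
    peptide = c("A", "B", "C"), allele = "HLA-A*02:01",
    affinity_nm = c(400, 600, 600), rank_pct = c(3, 1.5, 3)
  )
  kept <- dataset1_binding_filter(pairs, pred)
  expect_setequal(kept$peptide, c("A", "B"))
  expect_equal(attr(kept, "missing")$peptide, "D")
})

test_that("dataset-2 filter needs 2+2 assays and > 60% positive binding", {
  base <- function(pep, n_bind_pos, n_bind_neg, n_tcell) {
    dplyr::bind_rows(
      mk_assays(rep(pep, n_bind_pos + n_bind_neg), kind = "mhc_binding",
        outcome = rep(c("positive", "negative"), c(n_bind_pos, n_bind_neg))),
      mk_assays(rep(pep, n_tcell), outcome = "negative")
    )
  }
  assays <- dplyr::bind_rows(
    base("AAAAAAAAA", 2, 1, 2),  # 66.7% positive -> keep
    base("CCCCCCCCC", 3, 2, 2),  # exactly 60% -> drop
    base("DDDDDDDDD", 1, 0, 2)   # single binding assay -> drop
  )
  pairs <- dplyr::distinct(assays, peptide, allele)
  kept <- dataset2_binding_filter(pairs, assays)
  expect_equal(kept$peptide, "AAAAAAAAA")
})

test_that("k-tuple distance matches its closed form", {
  expect_equal(ktuple_distance("ACDEF", "ACDEF"), 0)
  expect_equal(ktuple_distance("AAAAA", "WWWWW"), 1)
  # 9-mers sharing a 5-letter multiset
  expect_equal(ktuple_distance("AAAAACCCC", "AAAAADDDD"), 1 - 5 / 9)
  # k = 2 counts shared 2-tuples over min-length windows
  expect_equal(ktuple_distance("ACACA", "ACGGG", k = 2), 1 - 1 / 4)
  expect_error(ktuple_distance("", "ACDEF"), "non-empty")
})

test_that("distance matrix equals the scalar distance on every pair", {
  set.seed(31)
  peps <- random_peptides(25)
  D <- ktuple_distance_matrix(peps)
  for (i in sample(25, 5)) {
    for (j in sample(25, 5)) {
      expected <- if (i == j) 0 else ktuple_distance(peps[i], peps[j])
      expect_equal(D[i, j], expected)
    }
  }
})

test_that("iterative dedup removes redundancy deterministically", {
  expect_length(iterative_dedup(c("AAAAAAAAA", "AAAAAAAAA")), 1L)
  far <- c("AAAAAAAAA", "CCCCCCCCC", "DDDDDDDDD")
  expect_equal(iterative_dedup(far), far)

  trio <- c("AAAAAAAAA", "AAAAAAAAW", "WCDEFGHIK")
  expect_equal(iterative_dedup(trio), oracle_dedup(trio))
})

test_that("dedup output matches the brute-force oracle and its post-condition", {
  set.seed(32)
  for (n in c(20, 60)) {
    # low-diversity alphabet so that close pairs actually occur
    peps <- unique(vapply(seq_len(n), function(i) {
      paste(sample(AA_STANDARD[1:6], 9, TRUE), collapse = "")
    }, character(1)))
    kept <- iterative_dedup(peps)
    expect_setequal(kept, oracle_dedup(peps))
    D <- ktuple_distance_matrix(kept)
    diag(D) <- Inf
    expect_true(all(D >= 0.5))
  }
})

test_that("anchor detection uses natural-log entropy below 0.8", {
  peps_const <- paste0("A", strrep("C", 8))
  peps <- c(rep(peps_const, 25))
  anc <- anchor_positions(tibble::tibble(allele = "HLA-A*02:01", peptide = peps))
  expect_true(all(anc$anchor))          # entropy 0 everywhere
  expect_equal(anc$entropy[1], 0)

  set.seed(33)
  unif <- vapply(1:400, function(i) {
    paste(sample(AA_STANDARD, 9, TRUE), collapse = "")
  }, character(1))
  anc2 <- anchor_positions(tibble::tibble(allele = "HLA-A*01:01", peptide = unif))
  expect_true(all(anc2$entropy > 2.5))  # near ln 20 = 3.0
  expect_false(any(anc2$anchor))

  # 50/50 over two residues: entropy ln 2 = 0.693 < 0.8 -> anchor
  half <- c(rep("ACCCCCCCC", 20), rep("CCCCCCCCC", 20))
  anc3 <- anchor_positions(tibble::tibble(allele = "HLA-B*07:02", peptide = half))
  expect_equal(anc3$entropy[anc3$position == 1], log(2), tolerance = 1e-12)
  expect_true(anc3$anchor[anc3$position == 1])

  expect_warning(
    anchor_positions(tibble::tibble(allele = "HLA-C*01:02", peptide = peps[1:5])),
    "skipped"
  )
})

test_that("secondary-anchor exclusion requires anchors in the TCEM of all alleles", {
  anchors <- tibble::tibble(
    allele = c("in_tcem", "outside", "in_tcem2"),
    position = c(5, 2, 6),
    entropy = 0.1,
    anchor = TRUE
  )
  # bound only by an allele anchoring at position 5 (inside 4-8) -> excluded
  cur1 <- tibble::tibble(peptide = "AAAAAAAAA", allele = "in_tcem")
  expect_equal(nrow(secondary_anchor_exclusion(cur1, anchors)), 0L)
  # one anchor-free allele in the TCEM -> retained
  cur2 <- tibble::tibble(
    peptide = c("CCCCCCCCC", "CCCCCCCCC"),
    allele = c("in_tcem", "outside")
  )
  expect_equal(nrow(secondary_anchor_exclusion(cur2, anchors)), 2L)
  # anchors only at positions 2 and 9 -> retained
  anchors2 <- tibble::tibble(
    allele = "edge", position = c(2, 9), entropy = 0.1, anchor = TRUE
  )
  cur3 <- tibble::tibble(peptide = "DDDDDDDDD", allele = "edge")
  expect_equal(nrow(secondary_anchor_exclusion(cur3, anchors2)), 1L)
})

test_that("full curation is deterministic and keeps the datasets disjoint", {
  h <- human_fixture()
  ad <- sim_assay_dataset(h$profile, n_peptides = 400, seed = 34)
  cur1 <- curate_datasets(ad$assays, ad$predictions)
  cur2 <- curate_datasets(ad$assays, ad$predictions)
  expect_identical(cur1, cur2)
  expect_length(
    intersect(cur1$peptide[cur1$dataset == 1], cur1$peptide[cur1$dataset == 2]),
    0L
  )
  expect_true(all(cur1$label %in% c("immunogenic", "nonimmunogenic")))
  expect_true(all((cur1$n_pos == 0) == (cur1$label == "nonimmunogenic")))
})
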