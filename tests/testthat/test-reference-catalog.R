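test_that("packaged catalog loads with the full validated clade structure", {
  cat <- load_catalog()
  expect_s3_class(cat, "phytase_catalog")
  expect_length(cat, 16L)
  fams <- table(vapply(cat, `[[`, "", "family"))
  expect_equal(unname(fams[c("BPP", "HAP", "CP", "PAP")]),
               c(4L, 8L, 2L, 2L), ignore_attr = TRUE)

  abl <- cat[["ABL86758"]]
  expect_equal(abl$motifs$pattern, c("YG", "EGMAAD", "DIEG", "DG"))
  expect_equal(abl$motifs$start, c(159L, 211L, 258L, 314L))
  expect_equal(abl$motifs$end, c(160L, 216L, 261L, 315L))

  awn <- cat[["AWN00236"]]
  expect_equal(awn$family, "CP")
  expect_equal(awn$motifs$pattern, c("YF", "HCTAGKDRT"))
  expect_equal(awn$motifs$start, c(240L, 268L))
  expect_equal(awn$motifs$end, c(241L, 276L))

  # homolog lists preserved
  expect_true("AAC31775.1" %in% abl$homologs)
  expect_length(cat[["ACR23329"]]$homologs, 24L)
})

test_that("catalog loading validates its input", {
  empty <- tempfile(fileext = ".tsv")
  writeLines("accession\tfamily\tclade\torganism\tmotifs", empty)
  expect_warning(cat0 <- load_catalog(empty), "empty")
  expect_length(cat0, 0L)

  bad_family <- tempfile(fileext = ".tsv")
  writeLines(c("accession\tfamily\tclade\torganism\tmotifs",
               "X1\tZZZ\tX\torg\tAB:1-2"), bad_family)
  expect_error(load_catalog(bad_family), "unknown family")

  bad_motif <- tempfile(fileext = ".tsv")
  writeLines(c("accession\tfamily\tclade\torganism\tmotifs",
               "X1\tBPP\tX\torg\tAB_1_2"), bad_motif)
  expect_error(load_catalog(bad_motif), "X1")

  dup <- tempfile(fileext = ".tsv")
  writeLines(c("accession\tfamily\tclade\torganism\tmotifs",
               "X1\tBPP\tX\torg\tAB:1-2",
               "X1\tBPP\tY\torg\tAB:1-2"), dup)
  expect_error(load_catalog(dup), "duplicate")
})

test_that("pairwise identity follows the aligned-column definition", {
  expect_equal(pairwise_identity("ACDEFG", "ACDEFG"), 1.0)
  expect_equal(pairwise_identity("ACDE", "ACDF"), 0.75)
  expect_error(pairwise_identity("", "ACD"), "non-empty")
  expect_error(pairwise_identity("ACD", "AC1D"), "non-amino-acid")

  # construction-based oracle: deleting k internal residues from a sequence
  # leaves an alignment of the original length with (L - k) matches
  set.seed(5)
  full <- paste(sample(c("A","C","D","E","F","G","H","I","K","L"), 30,
                       replace = TRUE), collapse = "")
  gapped <- paste(strsplit(full, "")[[1]][-c(12, 13, 14)], collapse = "")
  expect_equal(pairwise_identity(full, gapped), 27 / 30)
})

test_that("pairwise identity is symmetric on random sequences", {
  seqs <- random_proteome(6, length_mean = 60, length_sd = 5, seed = 31)
  for (i in 1:5) for (j in (i + 1):6) {
    expect_equal(pairwise_identity(seqs[[i]], seqs[[j]]),
                 pairwise_identity(seqs[[j]], seqs[[i]]))
  }
})

test_that("representative-linkage clustering applies the identity threshold", {
  # A and B related (identity ~0.55), C unrelated
  set.seed(9)
  A <- random_proteome(1, length_mean = 100, length_sd = 0, seed = 91)[[1]]
  B <- phytascan:::mutate_sequence(A, integer(0), 0.55)
  C <- random_proteome(1, length_mean = 100, length_sd = 0, seed = 92)[[1]]
  enz <- list(list(accession = "A", family = "BPP", sequence = A),
              list(accession = "B", family = "BPP", sequence = B),
              list(accession = "C", family = "BPP", sequence = C))
  cl <- cluster_into_clades(enz, threshold = 0.28)
  expect_equal(nrow(cl), 2L)
  expect_setequal(unlist(cl$members[cl$n_members == 2]), c("A", "B"))
  expect_equal(unlist(cl$members[cl$n_members == 1]), "C")

  # partition property: every accession in exactly one clade
  expect_setequal(unlist(cl$members), c("A", "B", "C"))

  single <- cluster_into_clades(enz[3], threshold = 0.28)
  expect_equal(single$representative, "C")
  expect_equal(single$n_members, 1L)

  expect_error(cluster_into_clades(enz, threshold = 1.2), "threshold")
  enz[[2]]$sequence <- NA_character_
  expect_error(cluster_into_clades(enz), "B")
})

test_that("lowering the threshold never increases the clade count", {
  seqs <- random_proteome(5, length_mean = 80, length_sd = 0, seed = 77)
  base <- seqs[[1]]
  fam <- lapply(seq_along(seqs), function(i) {
    s <- if (i <= 3) phytascan:::mutate_sequence(base, integer(0),
                                                 c(1, 0.6, 0.45)[i])
         else seqs[[i]]
    list(accession = paste0("S", i), family = "BPP", sequence = s)
  })
  counts <- vapply(c(0.6, 0.4, 0.28, 0.15), function(th)
    nrow(cluster_into_clades(fam, threshold = th)), 0L)
  expect_true(all(diff(counts) <= 0))
})

test_that("clustering the synthetic validated set recovers the catalog clades", {
  # representatives only (full-set clustering is exercised in acceptance)
  cl <- cluster_into_clades(REF_REPS, threshold = 0.28)
  expect_equal(nrow(cl), 16L)
  expect_equal(sum(cl$family == "BPP"), 4L)
  expect_equal(sum(cl$family == "HAP"), 8L)
  # every representative has self-identity 1 and its own clade
  expect_equal(pairwise_identity(ABL$sequence, ABL$sequence), 1.0)
})

test_that("representative selection maximizes score with lexicographic ties", {
  expect_equal(select_representative(c(X = 10, Y = 12)), "Y")
  expect_equal(select_representative(c(Y = 10, X = 10)), "X")
  expect_equal(select_representative(c(Z = 3)), "Z")
  expect_error(select_representative(numeric(0)), "empty")
})
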