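test_that("profiles encode per-column residue preferences", {
  p <- build_profile("ACD", pseudocount_weight = 0)
  expect_equal(p$length, 3L)
  expect_equal(colnames(p$probs)[apply(p$probs, 1, which.max)],
               c("A", "C", "D"))

  # duplication invariance
  p2 <- build_profile(c("ACD", "ACD"), pseudocount_weight = 0)
  expect_equal(p2$probs, p$probs)

  expect_error(build_profile(c("ACD", "ACDE")), "ragged")
})

test_that("profile probabilities match the pseudocount oracle", {
  aln <- c("ACD", "ACD", "AGD", "CCD", "ACE")
  w <- 1
  p <- build_profile(aln, pseudocount_weight = w)
  bg <- p$background
  # hand-computed counts: col1 A=4 C=1; col2 C=4 G=1; col3 D=4 E=1
  for (col in 1:3) {
    counts <- table(factor(substring(aln, col, col),
                           levels = names(bg)))
    expected <- (as.numeric(counts) + w * bg) / (5 + w)
    expect_equal(unname(p$probs[col, ]), unname(expected))
  }
  expect_true(all(abs(rowSums(p$probs) - 1) < 1e-12))
})

test_that("match-column rule drops majority-gap columns", {
  aln <- c("A-CD", "A-CD", "AEC-")  # col2 gap in 2/3 (>50%) -> dropped
  p <- build_profile(aln)
  expect_equal(p$length, 3L)
})

test_that("E-value calibration is deterministic and describes the tail", {
  cal1 <- calibrate_evalues(ABL_PROFILE, n_random = 200, seed = 7)
  cal2 <- calibrate_evalues(ABL_PROFILE, n_random = 200, seed = 7)
  expect_identical(cal1, cal2)
  expect_gt(cal1$lambda, 0)
  expect_gt(cal1$kappa, 0)
  expect_error(calibrate_evalues(ABL_PROFILE, n_random = 50), "100")

  # empirical tail vs fitted tail near the 95th percentile
  scores <- withr::with_seed(13, {
    vapply(1:400, function(i) {
      q <- sample.int(20, 380, replace = TRUE,
                      prob = phytascan:::AA_BACKGROUND)
      phytascan:::pssm_best_placement(q, ABL_PROFILE$pssm, 30)[1]
    }, 0)
  })
  q95 <- stats::quantile(scores, 0.95)
  fitted_tail <- exp(-exp(-(q95 - cal1$mu) / cal1$beta))
  emp_tail <- mean(scores <= q95)
  expect_lt(abs(fitted_tail - emp_tail), 0.06)
})

test_that("profile search retrieves itself and planted homologs, not noise", {
  bench <- make_planted_benchmark(n_background = 300, n_intact = 10,
                                  n_broken = 0, identity = 0.6, seed = 21)
  db <- c(bench$proteins, self = ABL$sequence)
  hits <- search_profiles(list(ABL_PROFILE), db, cutoff = 1e-30,
                          calibrations = list(ABL86758 = ABL_CAL))
  expect_true("self" %in% hits$query_id)
  expect_equal(hits$query_id[1], "self")  # best E-value first
  planted <- grep("planted", names(db), value = TRUE)
  expect_setequal(intersect(hits$query_id, planted), planted)
  expect_equal(sum(grepl("^bg_", hits$query_id)), 0L)
  # sorted by ascending E-value, monotone in score
  expect_true(!is.unsorted(hits$e_value))
  expect_true(all(diff(order(-hits$raw_score)) != 0) ||
                all(hits$e_value[order(-hits$raw_score)] ==
                      sort(hits$e_value)))

  expect_equal(nrow(search_profiles(list(ABL_PROFILE), db, cutoff = 0,
                                    calibrations = list(ABL86758 = ABL_CAL))),
               0L)
  expect_warning(
    search_profiles(list(ABL_PROFILE), character(0), 1e-30,
                    list(ABL86758 = ABL_CAL)), "empty")
  expect_error(search_profiles(list(ABL_PROFILE), db, 1e-30, list()),
               "calibration")
})

test_that("planted-homolog sensitivity is monotone in identity", {
  bg <- random_proteome(100, seed = 41)
  recovered <- vapply(c(0.4, 0.6, 0.8), function(id) {
    pl <- plant_homologs(bg, ABL$sequence, ABL$motifs, 8, id,
                         motif_intact = TRUE, seed = 42)
    hits <- search_profiles(list(ABL_PROFILE), pl$proteins, 1e-30,
                            list(ABL86758 = ABL_CAL))
    sum(grepl("planted", hits$query_id))
  }, 0)
  expect_true(all(diff(recovered) >= 0))
  expect_equal(recovered[3], 8)
})

test_that("null databases produce E-values consistent with their definition", {
  # expected false positives at threshold t is ~ t per scan; with t = 0.5
  # the count over seeds must stay within twice the expectation
  t <- 0.5
  n_fp <- 0
  trials <- 5
  for (s in 1:trials) {
    db <- random_proteome(80, seed = 200 + s)
    hits <- search_profiles(list(ABL_PROFILE), db, cutoff = t,
                            calibrations = list(ABL86758 = ABL_CAL))
    n_fp <- n_fp + nrow(hits)
  }
  expect_lte(n_fp, 2 * t * trials + 3)
})

test_that("candidate-representative alignment yields a faithful column map", {
  s <- random_proteome(1, length_mean = 60, length_sd = 0, seed = 55)[[1]]
  aln <- align_to_representative(s, s)
  expect_equal(aln$map, seq_len(nchar(s)))

  # single internal deletion: exactly the deleted representative positions
  # map to NA
  cand <- paste(strsplit(s, "")[[1]][-(20:24)], collapse = "")
  aln2 <- align_to_representative(cand, s)
  expect_equal(sum(is.na(aln2$map)), 5L)
  expect_equal(which(is.na(aln2$map)), 20:24)
  expect_equal(aln2$map[25:60], 20:55)

  expect_error(align_to_representative("AC1", s), "non-amino-acid")
})

test_that("alignment scores agree with an exhaustive dynamic-programming oracle", {
  for (seed in 1:4) {
    pair <- random_proteome(2, length_mean = 25, length_sd = 0,
                            seed = 300 + seed)
    ours <- align_to_representative(pair[[1]], pair[[2]])$score
    oracle <- gotoh_score(pair[[2]], pair[[1]])
    expect_equal(ours, oracle, tolerance = 1e-8)
  }
})
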