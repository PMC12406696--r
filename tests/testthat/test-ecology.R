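test_that("Bray-Curtis matches its closed form", {
  m <- rbind(a = c(1, 1, 0), b = c(1, 0, 0), c = c(1, 1, 0),
             d = c(0, 0, 5))
  d <- bray_curtis_matrix(m)
  expect_equal(d["a", "b"], 1 / 3)
  expect_equal(d["a", "c"], 0)
  expect_equal(d["a", "d"], 1)
  expect_equal(d, t(d))
  expect_true(all(d >= 0 & d <= 1))
  expect_error(bray_curtis_matrix(rbind(a = c(1, 2), z = c(0, 0))), "z")
})

test_that("PCoA reconstructs Euclidean configurations", {
  pts <- cbind(x = c(0, 3, 3, 0), y = c(0, 0, 4, 4))
  rownames(pts) <- paste0("p", 1:4)
  d <- as.matrix(dist(pts))
  res <- pcoa_ordination(d, n_axes = 3)
  rec <- as.matrix(dist(res$coordinates[, 1:2]))
  expect_lt(max(abs(rec - d)), 1e-8)
  expect_true(all(diff(res$eigenvalues) <= 1e-9))
  expect_equal(sum(res$variance_explained), 1)

  # collinear points: essentially one positive axis (trailing eigenvalues
  # are dropped or negligible)
  d3 <- matrix(c(0, 1, 2, 1, 0, 1, 2, 1, 0), 3)
  res3 <- pcoa_ordination(d3, n_axes = 2)
  expect_gt(res3$eigenvalues[1], 0)
  expect_true(length(res3$eigenvalues) == 1L ||
                abs(res3$eigenvalues[2]) < 1e-8 * res3$eigenvalues[1] + 1e-8)

  # duplicated samples are coincident
  m <- rbind(a = c(5, 1, 0), b = c(5, 1, 0), c = c(0, 2, 8))
  dd <- bray_curtis_matrix(m)
  resd <- pcoa_ordination(dd)
  expect_equal(resd$coordinates["a", ], resd$coordinates["b", ],
               tolerance = 1e-10, ignore_attr = TRUE)

  expect_error(pcoa_ordination(matrix(c(0, 1, 2, 0), 2)), "symmetric")
})

test_that("alpha richness counts occupied taxa and detects group differences", {
  m <- rbind(s1 = c(0.1, 0, 3, 0), s2 = c(0, 0, 0, 0))
  r <- alpha_richness(m)
  expect_equal(unname(r$richness), c(2L, 0L))

  # two groups with true richness 20 vs 60 of 100 taxa
  n_taxa <- 100
  mk_rows <- function(n, rich, seed) {
    withr::with_seed(seed, t(vapply(seq_len(n), function(i) {
      v <- numeric(n_taxa)
      v[sample.int(n_taxa, rich)] <- 1
      v
    }, numeric(n_taxa))))
  }
  mat <- rbind(mk_rows(15, 20, 3), mk_rows(15, 60, 4))
  rownames(mat) <- paste0("s", 1:30)
  groups <- rep(c("low", "high"), each = 15)
  res <- alpha_richness(mat, groups)
  expect_lt(res$pairwise_p$p_value, 0.01)
})

test_that("Hellinger transform and tb-RDA behave as designed", {
  expect_equal(unname(hellinger_transform(matrix(c(1, 1, 2), 1))[1, ]),
               c(0.5, 0.5, sqrt(0.5)), tolerance = 1e-10)

  # two community blocks perfectly separated by a binary factor
  set.seed(8)
  block1 <- matrix(rpois(10 * 6, lambda = rep(c(50, 50, 50, 1, 1, 1),
                                              each = 10)), 10)
  block2 <- matrix(rpois(10 * 6, lambda = rep(c(1, 1, 1, 50, 50, 50),
                                              each = 10)), 10)
  m <- rbind(block1, block2)
  rownames(m) <- paste0("s", 1:20)
  fac <- data.frame(habitat = rep(c("wat", "sedi"), each = 10))
  fit <- tb_rda(m, fac)
  expect_gt(fit$constrained_fraction, 0.9)
  ax1 <- fit$site_scores[, 1]
  expect_true(all(sign(ax1[1:10]) == sign(ax1[1])) &&
                all(sign(ax1[11:20]) == -sign(ax1[1])))

  # constraints orthogonal to community structure explain almost nothing
  noise <- data.frame(z = withr::with_seed(9, rnorm(20)))
  fit0 <- tb_rda(m, noise)
  expect_lt(fit0$constrained_fraction, 0.1)

  dup <- data.frame(a = rep(c(0, 1), each = 10), b = rep(c(0, 2), each = 10))
  expect_error(tb_rda(m, dup), "collinear")
})

test_that("distance decay regresses similarity on log distance", {
  g <- c(10, 100, 1000, 10000, 31, 310)
  flat <- distance_decay(rep(0.4, 6), g)
  expect_equal(flat$slope, 0, tolerance = 1e-12)

  sim <- 1 - 0.2 * log10(g)
  dec <- distance_decay(sim, g)
  expect_equal(dec$slope, -0.2, tolerance = 1e-10)

  # noisy recovery
  withr::with_seed(5, {
    gg <- 10^runif(100, 0.5, 4)
    ss <- 1 - 0.2 * log10(gg) + rnorm(100, 0, 0.05)
  })
  noisy <- distance_decay(ss, gg)
  expect_lt(abs(noisy$slope + 0.2), 0.05)
  expect_true(noisy$slope_ci[1] < noisy$slope &&
                noisy$slope < noisy$slope_ci[2])

  expect_error(distance_decay(c(1, 2, 3), c(0, 1, 2)), "positive")
  expect_error(distance_decay(c(1, 2), c(1, 2)), "3 pairs")
})

test_that("haversine distances are symmetric and match a known separation", {
  lat <- c(36.06, 18.41)  # two coastal sampling regions
  lon <- c(120.31, 110.05)
  d <- haversine_km(lat, lon)
  expect_equal(d[1, 2], d[2, 1])
  expect_gt(d[1, 2], 1900); expect_lt(d[1, 2], 2400)
})

test_that("NST is deterministic, bounded and order-invariant", {
  m <- simulate_community_assembly("neutral", 12, n_taxa = 25, seed = 6)
  r1 <- nst(m, reps = 150, seed = 3)
  r2 <- nst(m, reps = 150, seed = 3)
  expect_identical(r1$nst_percent, r2$nst_percent)
  expect_true(r1$nst_percent >= 0 && r1$nst_percent <= 100)

  perm <- withr::with_seed(4, sample(nrow(m)))
  tperm <- withr::with_seed(5, sample(ncol(m)))
  r3 <- nst(m[perm, tperm], reps = 150, seed = 3)
  expect_equal(r3$nst_percent, r1$nst_percent)

  expect_error(nst(m, reps = 10, seed = 1), "100")
  expect_warning(nst(m, groups = c(rep("a", 10), "b", "b"),
                     reps = 150, seed = 1), "fewer than 3")
})

test_that("communities drawn from the null model score as stochastic", {
  m <- simulate_community_assembly("neutral", 12, n_taxa = 25, seed = 16)
  null_m <- withr::with_seed(17, phytascan:::nst_null_sample(m))
  rownames(null_m) <- rownames(m); colnames(null_m) <- colnames(m)
  res <- nst(null_m, reps = 300, seed = 18)
  expect_gt(res$nst_percent, 50)
  expect_gt(res$nst_percent, 75)  # near the stochastic limit
  expect_equal(res$classification, "stochastic")
})

test_that("PERMANOVA separates clearly distinct groups", {
  m <- rbind(matrix(rep(c(40, 40, 2, 2), each = 6), 6) +
               withr::with_seed(1, matrix(rpois(24, 2), 6)),
             matrix(rep(c(2, 2, 40, 40), each = 6), 6) +
               withr::with_seed(2, matrix(rpois(24, 2), 6)))
  res <- permanova_test(m, rep(c("A", "B"), each = 6), permutations = 199,
                        seed = 9)
  expect_lt(res$`Pr(>F)`[1], 0.05)
})
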