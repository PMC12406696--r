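#' Bray-Curtis dissimilarity matrix
#'
#' `sum|x - y| / sum(x + y)` over taxa, via [vegan::vegdist()].
#'
#' @param m samples x taxa non-negative abundance matrix.
#' @return symmetric `dist`-backed matrix with zero diagonal, entries in
#'   `[0, 1]`.
#' @export
bray_curtis_matrix <- function(m) {
  m <- as.matrix(m)
  if (nrow(m) < 2L) stop("need at least 2 samples")
  if (any(m < 0)) stop("abundances must be non-negative")
  zero <- rowSums(m) == 0
  if (any(zero))
    stop("all-zero sample row(s): ",
         paste(rownames(m)[zero], collapse = ", "))
  as.matrix(vegan::vegdist(m, method = "bray"))
}

#' Principal coordinates analysis with Lingoes correction
#'
#' Double-centred eigendecomposition of a dissimilarity matrix
#' ([ape::pcoa()]); when negative eigenvalues arise the Lingoes correction
#' is applied and variance fractions are reported on the corrected
#' eigenvalues.
#'
#' @param d symmetric dissimilarity matrix with zero diagonal.
#' @param n_axes number of axes to return; default 2.
#' @return list with `coordinates` (samples x n_axes), `eigenvalues`,
#'   `variance_explained` (fractions), `correction` (`"none"` or
#'   `"lingoes"`).
#' @export
pcoa_ordination <- function(d, n_axes = 2L) {
  d <- as.matrix(d)
  if (!isTRUE(all.equal(d, t(d), tolerance = 1e-8)))
    stop("dissimilarity matrix must be symmetric")
  res <- ape::pcoa(stats::as.dist(d))
  correction <- "none"
  if (any(res$values$Eigenvalues < -1e-8)) {
    res <- ape::pcoa(stats::as.dist(d), correction = "lingoes")
    correction <- "lingoes"
  }
  vals <- res$values
  eig <- if ("Corr_eig" %in% names(vals)) vals$Corr_eig
         else vals$Eigenvalues
  pos <- pmax(eig, 0)
  n_axes <- min(n_axes, ncol(res$vectors))
  list(coordinates = res$vectors[, seq_len(n_axes), drop = FALSE],
       eigenvalues = eig,
       variance_explained = pos / sum(pos),
       correction = correction)
}

#' Per-sample taxon richness with pairwise group tests
#'
#' Richness is the count of taxa with abundance > 0. With group labels,
#' two-sided Wilcoxon rank-sum tests compare every pair of groups.
#'
#' @param m samples x taxa abundance matrix.
#' @param groups optional factor/character of group labels per sample.
#' @return list with `richness` (named integer vector) and, when groups are
#'   given, `pairwise_p` (data frame `group_a`, `group_b`, `p_value`).
#' @export
alpha_richness <- function(m, groups = NULL) {
  m <- as.matrix(m)
  rich <- as.integer(rowSums(m > 0))
  names(rich) <- rownames(m)
  out <- list(richness = rich)
  if (!is.null(groups)) {
    groups <- as.character(groups)
    gl <- sort(unique(groups))
    rows <- list()
    for (i in seq_along(gl)) for (j in seq_along(gl)) {
      if (j <= i) next
      p <- suppressWarnings(stats::wilcox.test(
        rich[groups == gl[i]], rich[groups == gl[j]],
        alternative = "two.sided"))$p.value
      rows[[length(rows) + 1L]] <- data.frame(
        group_a = gl[i], group_b = gl[j], p_value = p,
        stringsAsFactors = FALSE)
    }
    out$pairwise_p <- do.call(rbind, rows)
  }
  out
}

#' Transformation-based redundancy analysis
#'
#' Hellinger-transforms the community matrix (square root of row-relative
#' abundances, [vegan::decostand()]) and fits a redundancy analysis
#' constrained by the design ([vegan::rda()]).
#'
#' @param m samples x taxa abundance matrix.
#' @param constraints data frame of explanatory factors/covariates, one row
#'   per sample.
#' @return list with `site_scores`, `constraint_scores` (biplot scores),
#'   `species_scores`, `constrained_fraction` (share of total inertia
#'   explained by the constraints), `axis_variance` (per constrained axis,
#'   as fractions of total inertia), and the underlying `rda` fit.
#' @export
tb_rda <- function(m, constraints) {
  m <- as.matrix(m)
  constraints <- as.data.frame(constraints)
  mm <- stats::model.matrix(~ ., data = constraints)
  if (qr(mm)$rank < ncol(mm)) {
    qr_ <- qr(mm)
    bad <- colnames(mm)[-seq_len(qr_$rank)]
    stop("rank-deficient design; collinear column(s): ",
         paste(bad, collapse = ", "))
  }
  hell <- vegan::decostand(m, method = "hellinger")
  fit <- vegan::rda(hell ~ ., data = constraints)
  total <- fit$tot.chi
  constrained <- if (is.null(fit$CCA)) 0 else fit$CCA$tot.chi
  axis_var <- if (is.null(fit$CCA)) numeric(0) else fit$CCA$eig / total
  list(site_scores = vegan::scores(fit, display = "sites"),
       constraint_scores = vegan::scores(fit, display = "bp"),
       species_scores = vegan::scores(fit, display = "species"),
       constrained_fraction = constrained / total,
       axis_variance = axis_var,
       fit = fit)
}

#' Hellinger transformation
#'
#' Square root of row-relative abundances.
#' @param m samples x taxa matrix.
#' @return transformed matrix.
#' @export
hellinger_transform <- function(m) {
  vegan::decostand(as.matrix(m), method = "hellinger")
}

#' Great-circle distances between sample coordinates
#'
#' Haversine distance in kilometres from decimal lat/lon, for all pairs.
#'
#' @param lat,lon numeric vectors of coordinates.
#' @return symmetric matrix of distances (km).
#' @export
haversine_km <- function(lat, lon) {
  n <- length(lat)
  d <- matrix(0, n, n)
  for (i in seq_len(n - 1L)) for (j in seq.int(i + 1L, n)) {
    d[i, j] <- d[j, i] <-
      geosphere::distHaversine(c(lon[i], lat[i]), c(lon[j], lat[j])) / 1000
  }
  d
}

#' Distance-decay regression of community similarity
#'
#' Ordinary least squares of pairwise similarity on log10 geographic
#' distance, with a 95 percent confidence interval on the slope.
#'
#' @param similarity numeric vector of pairwise community similarities.
#' @param geo_distance numeric vector of matching pairwise distances
#'   (positive; same pair order).
#' @return list with `slope`, `intercept`, `correlation`, `slope_ci`
#'   (length-2), `p_value`, `fit`.
#' @export
distance_decay <- function(similarity, geo_distance) {
  if (length(similarity) != length(geo_distance))
    stop("similarity and distance vectors must align pairwise")
  if (length(similarity) < 3L) stop("need at least 3 pairs")
  if (any(geo_distance <= 0))
    stop("geographic distances must be positive for the log scale")
  x <- log10(geo_distance)
  fit <- stats::lm(similarity ~ x)
  # degenerate (constant) similarity gives a perfect fit and an undefined
  # correlation; both are legitimate outputs here
  ci <- suppressWarnings(stats::confint(fit, "x", level = 0.95))
  list(slope = unname(stats::coef(fit)[2L]),
       intercept = unname(stats::coef(fit)[1L]),
       correlation = suppressWarnings(stats::cor(x, similarity)),
       slope_ci = as.numeric(ci),
       p_value = suppressWarnings(summary(fit)$coefficients[2L, 4L]),
       fit = fit)
}

#' PERMANOVA group test on a community matrix
#'
#' Supporting significance test for ordination groupings
#' ([vegan::adonis2()] on Bray-Curtis dissimilarities).
#'
#' @param m samples x taxa abundance matrix.
#' @param groups group labels per sample.
#' @param permutations number of permutations; default 999.
#' @param seed integer seed.
#' @return the `adonis2` result table.
#' @export
permanova_test <- function(m, groups, permutations = 999, seed = 42) {
  df <- data.frame(group = as.factor(groups))
  withr::with_seed(seed,
    vegan::adonis2(as.matrix(m) ~ group, data = df,
                   permutations = permutations, method = "bray"))
}

# ---- normalized stochasticity ratio ----------------------------------------

nst_dissim <- function(m, variant) {
  method <- "jaccard"
  binary <- identical(variant, "incidence")
  as.matrix(vegan::vegdist(m, method = method, binary = binary))
}

# Richness-preserving, occupancy-proportional taxa shuffle ("PF"-style):
# each null sample keeps its observed richness and its own abundance
# values; occupied taxa are re-drawn with probability proportional to
# regional occurrence frequency and the sample's non-zero abundances are
# assigned to them in random order. Deterministic community structure
# (which taxon carries which abundance, identically across samples) is
# therefore destroyed while alpha diversity and abundance distributions
# are preserved.
nst_null_sample <- function(m) {
  p_occ <- pmax(colMeans(m > 0), 1e-12)
  null <- m * 0
  for (i in seq_len(nrow(m))) {
    vals <- m[i, m[i, ] > 0]
    rich <- length(vals)
    if (rich == 0L) next
    taxa <- sample.int(ncol(m), rich, replace = FALSE, prob = p_occ)
    null[i, taxa] <- sample(vals)
  }
  null
}

#' Normalized stochasticity ratio (NST)
#'
#' Null-model statistic separating stochastic from deterministic community
#' assembly. For each within-group sample pair, the observed dissimilarity
#' `D` is compared with its null expectation `E(D)` under a
#' richness-preserving, occupancy-proportional taxa shuffle; the pairwise
#' normalized stochasticity is `(Dmax - D) / (Dmax - E(D))` when `D > E(D)`
#' and `D / E(D)` otherwise (with `Dmax = 1` for proportional
#' dissimilarities), so a pair at its null expectation scores 1 and extreme
#' determinism scores 0. The group NST is the pairwise mean expressed as a
#' percentage; 50 percent is the conventional boundary between
#' predominantly deterministic (<50) and stochastic (>50) assembly.
#'
#' @param m samples x taxa non-negative abundance matrix.
#' @param groups group labels per sample (single group if `NULL`).
#' @param variant `"abundance"` (Ruzicka, default) or `"incidence"`
#'   (Jaccard) dissimilarity basis.
#' @param reps null-model replicates; default 1000 (>= 100).
#' @param seed integer seed; results are deterministic given the seed.
#' @return data frame with one row per group: `group`, `nst_percent`,
#'   `classification`, `n_pairs`, `reps`, `variant`; per-pair ratios in
#'   `attr(, "pairs")`.
#' @export
nst <- function(m, groups = NULL, variant = c("abundance", "incidence"),
                reps = 1000, seed = 42) {
  variant <- match.arg(variant)
  m <- as.matrix(m)
  if (is.null(groups)) groups <- rep("all", nrow(m))
  groups <- as.character(groups)
  if (reps < 100) stop("reps must be >= 100")
  out <- list()
  pair_list <- list()
  for (g in unique(groups)) {
    idx <- which(groups == g)
    if (length(idx) < 3L) {
      warning("group ", g, " has fewer than 3 samples; skipped")
      next
    }
    sub <- m[idx, , drop = FALSE]
    sub <- sub[, colSums(sub) > 0, drop = FALSE]
    # canonical ordering so results do not depend on input row/column order
    if (!is.null(rownames(sub)))
      sub <- sub[order(rownames(sub)), , drop = FALSE]
    if (!is.null(colnames(sub)))
      sub <- sub[, order(colnames(sub)), drop = FALSE]
    obs <- nst_dissim(sub, variant)
    null_sum <- matrix(0, nrow(sub), nrow(sub))
    withr::with_seed(seed, {
      for (r in seq_len(reps)) {
        null_sum <- null_sum + nst_dissim(nst_null_sample(sub), variant)
      }
    })
    ed <- null_sum / reps
    ut <- upper.tri(obs)
    D <- obs[ut]; E <- pmin(pmax(ed[ut], 1e-12), 1 - 1e-12)
    mst <- ifelse(D > E, (1 - D) / (1 - E), D / E)
    mst <- pmin(pmax(mst, 0), 1)
    pct <- 100 * mean(mst)
    out[[length(out) + 1L]] <- data.frame(
      group = g, nst_percent = pct,
      classification = if (pct > 50) "stochastic" else "deterministic",
      n_pairs = sum(ut), reps = reps, variant = variant,
      stringsAsFactors = FALSE)
    pair_list[[g]] <- data.frame(observed = D, expected = E,
                                 stochasticity = mst)
  }
  res <- do.call(rbind, out)
  attr(res, "pairs") <- pair_list
  res
}
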