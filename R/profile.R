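#' Build a position-specific scoring profile from aligned clade members
#'
#' Columns with more than 50 percent gaps are dropped (match-column rule).
#' Per-column residue probabilities are background-proportional
#' pseudocounted: `(count + pseudocount_weight * background) /
#' (n_residues + pseudocount_weight)`, then converted to log-odds bits
#' against the background composition. Background-proportional pseudocounts
#' keep single-sequence and few-sequence profiles informative enough that
#' genuine homologs separate from the random-score tail by many orders of
#' magnitude, which a flat +1-per-residue smoothing does not.
#'
#' @param aligned_members character vector of aligned sequences (equal
#'   lengths; `-` marks gaps). A single unaligned sequence is allowed.
#' @param pseudocount_weight non-negative pseudocount added to each residue
#'   count per column; default 1 (Laplace).
#' @param clade_label label carried into hits.
#' @return object of class `pssm_profile` with elements `clade_label`,
#'   `pssm` (length x 20 log-odds matrix, bits), `probs` (length x 20
#'   probability matrix), `background`, `length`.
#' @export
build_profile <- function(aligned_members, pseudocount_weight = 1,
                          clade_label = "profile") {
  if (length(aligned_members) < 1L) stop("need at least one sequence")
  if (pseudocount_weight < 0) stop("pseudocount_weight must be >= 0")
  widths <- nchar(aligned_members)
  if (length(unique(widths)) != 1L)
    stop("ragged alignment: sequences have differing lengths")
  chars <- do.call(rbind, strsplit(aligned_members, ""))
  gap_frac <- colMeans(chars == "-")
  keep <- which(gap_frac <= 0.5)
  if (!length(keep)) stop("no match columns after gap filtering")
  n_seq <- nrow(chars)
  probs <- matrix(0, nrow = length(keep), ncol = 20,
                  dimnames = list(NULL, AA_ALPHABET))
  for (j in seq_along(keep)) {
    col <- chars[, keep[j]]
    col <- col[col != "-"]
    bad <- setdiff(unique(col), AA_ALPHABET)
    if (length(bad))
      stop("invalid residue(s) in alignment: ", paste(bad, collapse = ", "))
    cnt <- table(factor(col, levels = AA_ALPHABET))
    p <- (as.numeric(cnt) + pseudocount_weight * AA_BACKGROUND) /
      (length(col) + pseudocount_weight)
    if (pseudocount_weight == 0 && length(col) == 0) p <- rep(1 / 20, 20)
    probs[j, ] <- p
  }
  # zero-pseudocount columns can contain exact zeros; floor for the log
  odds <- log2(pmax(probs, 1e-12) /
                 matrix(AA_BACKGROUND, nrow = nrow(probs), ncol = 20,
                        byrow = TRUE))
  structure(list(clade_label = clade_label, pssm = odds, probs = probs,
                 background = AA_BACKGROUND, length = nrow(probs)),
            class = "pssm_profile")
}

#' Calibrate extreme-value E-value parameters for a profile
#'
#' Scores `n_random` background-composition random sequences with the profile
#' and fits a Gumbel law to the maximal-placement scores by the method of
#' moments. E-values are then computed as
#' `E(s) = database_size * kappa * exp(-lambda * s)` with
#' `kappa = exp(lambda * mu)`, so a uniform shift of all scores is absorbed
#' into `kappa` while `lambda` is unchanged.
#'
#' @param profile a `pssm_profile`.
#' @param n_random number of random sequences (>= 100).
#' @param seed integer seed; calibration is deterministic given the seed.
#' @param length_sampler function(n) returning integer sequence lengths;
#'   default samples around 1.1 times the profile length.
#' @return object of class `evalue_calibration` with `lambda`, `kappa`,
#'   `mu`, `beta`, `n_random`, `seed`.
#' @export
calibrate_evalues <- function(profile, n_random = 200, seed = 42,
                              length_sampler = NULL) {
  stopifnot(inherits(profile, "pssm_profile"))
  if (n_random < 100) stop("n_random must be >= 100")
  if (is.null(length_sampler))
    length_sampler <- function(n)
      pmax(30L, as.integer(round(stats::rnorm(n, 1.1 * profile$length,
                                              0.15 * profile$length))))
  scores <- withr::with_seed(seed, {
    lens <- length_sampler(n_random)
    vapply(lens, function(L) {
      q <- sample.int(20L, L, replace = TRUE, prob = AA_BACKGROUND)
      pssm_best_placement(q, profile$pssm,
                          min_overlap = min(profile$length, 30L))[1L]
    }, 0)
  })
  if (stats::sd(scores) < 1e-9)
    stop("degenerate null score distribution; cannot calibrate")
  beta <- stats::sd(scores) * sqrt(6) / pi
  mu <- mean(scores) - 0.5772156649015329 * beta
  lambda <- 1 / beta
  structure(list(lambda = lambda, kappa = exp(lambda * mu), mu = mu,
                 beta = beta, n_random = n_random, seed = seed),
            class = "evalue_calibration")
}

evalue_from_score <- function(score, calibration, database_size) {
  database_size * calibration$kappa * exp(-calibration$lambda * score)
}

#' Search protein sets with clade profiles
#'
#' Scores every query against every profile (best ungapped placement),
#' converts scores to E-values scaled to the scanned database size, keeps the
#' best clade per family for each query, and returns hits at or below the
#' E-value cutoff, sorted by ascending E-value. The cutoff is applied per
#' profile-query pair.
#'
#' @param profiles list of `pssm_profile` objects, named by clade label.
#' @param proteins named character vector of query protein sequences.
#' @param cutoff E-value cutoff; default `1e-30`.
#' @param calibrations named list of `evalue_calibration`, one per profile.
#' @param family_of optional named character vector clade label -> family;
#'   when given, only the best clade per (query, family) is reported.
#' @return data frame of hits: `query_id`, `clade_label`, `family`,
#'   `raw_score`, `e_value`, `align_start`, `align_end`, `profile_start`,
#'   `profile_end`.
#' @export
search_profiles <- function(profiles, proteins, cutoff = 1e-30,
                            calibrations, family_of = NULL) {
  empty <- data.frame(query_id = character(0), clade_label = character(0),
                      family = character(0), raw_score = numeric(0),
                      e_value = numeric(0), align_start = integer(0),
                      align_end = integer(0), profile_start = integer(0),
                      profile_end = integer(0), stringsAsFactors = FALSE)
  if (length(proteins) == 0L) {
    warning("empty protein database; no hits")
    return(empty)
  }
  labs <- vapply(profiles, `[[`, "", "clade_label")
  missing_cal <- setdiff(labs, names(calibrations))
  if (length(missing_cal))
    stop("missing calibration for profile(s): ",
         paste(missing_cal, collapse = ", "))
  db_size <- length(proteins)
  encoded <- lapply(proteins, aa_encode)
  rows <- vector("list", length(profiles) * length(proteins))
  k <- 0L
  for (p in profiles) {
    cal <- calibrations[[p$clade_label]]
    fam <- if (!is.null(family_of)) unname(family_of[p$clade_label])
           else NA_character_
    minov <- min(p$length, 30L)
    for (qi in seq_along(encoded)) {
      res <- pssm_best_placement(encoded[[qi]], p$pssm, minov)
      if (!is.finite(res[1L])) next
      e <- evalue_from_score(res[1L], cal, db_size)
      k <- k + 1L
      rows[[k]] <- data.frame(
        query_id = names(proteins)[qi], clade_label = p$clade_label,
        family = fam, raw_score = res[1L], e_value = e,
        align_start = as.integer(res[2L]), align_end = as.integer(res[3L]),
        profile_start = as.integer(res[4L]),
        profile_end = as.integer(res[5L]), stringsAsFactors = FALSE)
    }
  }
  if (k == 0L) return(empty)
  hits <- do.call(rbind, rows[seq_len(k)])
  # best clade per (query, family)
  if (!is.null(family_of)) {
    key <- paste(hits$query_id, hits$family)
    hits <- hits[order(key, hits$e_value, hits$clade_label), ]
    hits <- hits[!duplicated(paste(hits$query_id, hits$family)), ]
  }
  hits <- hits[hits$e_value <= cutoff, , drop = FALSE]
  hits <- hits[order(hits$e_value, hits$query_id), , drop = FALSE]
  rownames(hits) <- NULL
  hits
}

#' Globally align a candidate to a clade representative
#'
#' Needleman-Wunsch global alignment (BLOSUM62, gap opening 10, extension
#' 0.5) returning the aligned strings and a 1-based coordinate map from
#' representative positions to candidate positions (`NA` at deletions).
#'
#' @param candidate,representative amino-acid strings.
#' @return list with `map` (integer vector, length `nchar(representative)`),
#'   `aligned_candidate`, `aligned_representative`, `score`.
#' @export
align_to_representative <- function(candidate, representative) {
  assert_aa(candidate, "candidate")
  assert_aa(representative, "representative")
  aln <- Biostrings::pairwiseAlignment(
    representative, candidate, type = "global",
    substitutionMatrix = "BLOSUM62", gapOpening = 10, gapExtension = 0.5)
  rep_aln <- strsplit(as.character(Biostrings::alignedPattern(aln)), "")[[1]]
  cand_aln <- strsplit(as.character(Biostrings::alignedSubject(aln)), "")[[1]]
  map <- integer(nchar(representative))
  ri <- 0L; ci <- 0L
  for (k in seq_along(rep_aln)) {
    if (cand_aln[k] != "-") ci <- ci + 1L
    if (rep_aln[k] != "-") {
      ri <- ri + 1L
      map[ri] <- if (cand_aln[k] != "-") ci else NA_integer_
    }
  }
  list(map = map, aligned_candidate = paste(cand_aln, collapse = ""),
       aligned_representative = paste(rep_aln, collapse = ""),
       score = Biostrings::score(aln))
}
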