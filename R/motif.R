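#' Parse a conserved-motif pattern string
#'
#' Grammar: plain residues match themselves, `X` matches any standard
#' residue (never a gap), `[A/B]` matches either alternative at one
#' position, and `/` between complete motifs (e.g. `"HD/HAE"`) gives
#' whole-motif alternates, any one of which qualifies.
#'
#' @param pattern motif string, e.g. `"EGXXXD"`, `"GNH[D/E]"`, `"HD/HAE"`.
#' @return object of class `motif_pattern`: list with `pattern` (the input)
#'   and `alternates`, a list of token lists; each token is a character
#'   vector of admissible residues (`"X"` stored as all 20).
#' @export
parse_motif_pattern <- function(pattern) {
  if (!is.character(pattern) || length(pattern) != 1L || !nzchar(pattern))
    stop("pattern must be a non-empty string")
  # split whole-motif alternates on '/' outside brackets
  chars <- strsplit(pattern, "")[[1]]
  depth <- 0L; cuts <- integer(0)
  for (i in seq_along(chars)) {
    if (chars[i] == "[") depth <- depth + 1L
    else if (chars[i] == "]") depth <- depth - 1L
    else if (chars[i] == "/" && depth == 0L) cuts <- c(cuts, i)
    if (depth < 0L) stop("unbalanced bracket in motif pattern: ", pattern)
  }
  if (depth != 0L) stop("unbalanced bracket in motif pattern: ", pattern)
  bounds <- c(0L, cuts, length(chars) + 1L)
  alt_strings <- vapply(seq_len(length(bounds) - 1L), function(k) {
    paste(chars[seq.int(bounds[k] + 1L, bounds[k + 1L] - 1L)], collapse = "")
  }, "")
  alternates <- lapply(alt_strings, tokenize_motif)
  structure(list(pattern = pattern, alternates = alternates),
            class = "motif_pattern")
}

tokenize_motif <- function(s) {
  if (!nzchar(s)) stop("empty motif alternate")
  tokens <- list()
  i <- 1L
  chars <- strsplit(s, "")[[1]]
  while (i <= length(chars)) {
    ch <- chars[i]
    if (ch == "[") {
      j <- i
      while (j <= length(chars) && chars[j] != "]") j <- j + 1L
      if (j > length(chars)) stop("unbalanced bracket in motif: ", s)
      inner <- paste(chars[seq.int(i + 1L, j - 1L)], collapse = "")
      alts <- strsplit(inner, "/", fixed = TRUE)[[1]]
      if (!all(nzchar(alts)) || !all(alts %in% AA_ALPHABET))
        stop("invalid bracket alternatives in motif: ", s)
      tokens[[length(tokens) + 1L]] <- alts
      i <- j + 1L
    } else if (ch == "X") {
      tokens[[length(tokens) + 1L]] <- AA_ALPHABET
      i <- i + 1L
    } else if (ch %in% AA_ALPHABET) {
      tokens[[length(tokens) + 1L]] <- ch
      i <- i + 1L
    } else {
      stop("invalid character '", ch, "' in motif: ", s)
    }
  }
  tokens
}

#' @export
print.motif_pattern <- function(x, ...) {
  cat("motif pattern:", x$pattern, "(",
      length(x$alternates), "alternate(s) )\n")
  invisible(x)
}

match_tokens_at <- function(residues, tokens, start) {
  end <- start + length(tokens) - 1L
  if (start < 1L || end > length(residues)) return(FALSE)
  for (k in seq_along(tokens)) {
    if (!(residues[start + k - 1L] %in% tokens[[k]])) return(FALSE)
  }
  TRUE
}

#' Locate a clade's conserved motifs in a candidate sequence
#'
#' Each motif anchor (its printed position in the clade representative) is
#' projected onto the candidate through the alignment column map; the
#' candidate is then searched within `tolerance_window` residues of the
#' projected start for a token-wise match of the motif (any whole-motif
#' alternate counts).
#'
#' @param candidate candidate amino-acid string.
#' @param representative representative amino-acid string.
#' @param motifs data frame with `pattern`, `start`, `end` (anchors in the
#'   representative, 1-based).
#' @param column_map representative -> candidate position map from
#'   [align_to_representative()]; computed when `NULL`.
#' @param tolerance_window residues searched either side of the projected
#'   anchor; default 10.
#' @return data frame: `pattern`, `anchor_start`, `found`,
#'   `candidate_start`, `matched_text`.
#' @export
locate_motifs <- function(candidate, representative, motifs,
                          column_map = NULL, tolerance_window = 10) {
  assert_aa(candidate, "candidate")
  assert_aa(representative, "representative")
  if (any(motifs$end > nchar(representative)))
    stop("motif anchor lies outside the representative sequence ",
         "(catalog inconsistency)")
  if (is.null(column_map))
    column_map <- align_to_representative(candidate, representative)$map
  res <- strsplit(candidate, "")[[1]]
  out <- vector("list", nrow(motifs))
  for (i in seq_len(nrow(motifs))) {
    pat <- parse_motif_pattern(motifs$pattern[i])
    anchor <- motifs$start[i]
    # project through the map; fall back to nearest mapped position
    proj <- column_map[anchor]
    if (is.na(proj)) {
      mapped <- which(!is.na(column_map))
      if (length(mapped)) {
        nb <- mapped[which.min(abs(mapped - anchor))]
        proj <- column_map[nb] + (anchor - nb)
      } else proj <- anchor
    }
    found <- FALSE; cand_start <- NA_integer_; text <- NA_character_
    for (alt in pat$alternates) {
      offsets <- order(abs(seq.int(-tolerance_window, tolerance_window)))
      window <- seq.int(-tolerance_window, tolerance_window)[offsets]
      for (d in window) {
        s <- proj + d
        if (match_tokens_at(res, alt, s)) {
          found <- TRUE
          cand_start <- s
          text <- paste(res[seq.int(s, s + length(alt) - 1L)], collapse = "")
          break
        }
      }
      if (found) break
    }
    out[[i]] <- data.frame(pattern = motifs$pattern[i],
                           anchor_start = anchor, found = found,
                           candidate_start = cand_start,
                           matched_text = text, stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}

#' Screen search hits for conserved catalytic motifs
#'
#' Implements the qualification filter: every hit is aligned to its clade
#' representative and all of the clade's conserved motifs must be located
#' (within the tolerance window) for the sequence to qualify. Unqualified
#' sequences are reported with the missing motif(s) named.
#'
#' @param hits hit data frame from [search_profiles()] (needs `query_id`
#'   and `clade_label`).
#' @param candidates named character vector with every hit's query sequence.
#' @param catalog a `phytase_catalog` whose records carry sequences; hits
#'   are matched to records by clade label (or accession).
#' @param tolerance_window see [locate_motifs()].
#' @param min_motifs minimum number of motifs that must be found; default
#'   `Inf` means all clade motifs are required.
#' @return data frame with one row per hit: `query_id`, `clade_label`,
#'   `qualified`, `n_found`, `n_motifs`, `reason`; per-motif detail in
#'   `attr(, "motif_checks")`.
#' @export
screen_candidates <- function(hits, candidates, catalog,
                              tolerance_window = 10, min_motifs = Inf) {
  if (nrow(hits) == 0L)
    return(data.frame(query_id = character(0), clade_label = character(0),
                      qualified = logical(0), n_found = integer(0),
                      n_motifs = integer(0), reason = character(0),
                      stringsAsFactors = FALSE))
  missing_q <- setdiff(hits$query_id, names(candidates))
  if (length(missing_q))
    stop("hit query sequence(s) not supplied: ",
         paste(missing_q, collapse = ", "))
  by_clade <- stats::setNames(
    vapply(catalog, `[[`, "", "clade"),
    vapply(catalog, `[[`, "", "accession"))
  checks <- vector("list", nrow(hits))
  rows <- vector("list", nrow(hits))
  for (i in seq_len(nrow(hits))) {
    lab <- hits$clade_label[i]
    idx <- if (lab %in% names(catalog)) match(lab, names(catalog))
           else match(lab, by_clade)
    if (is.na(idx)) stop("hit references unknown clade: ", lab)
    rec <- catalog[[idx]]
    cand <- candidates[[hits$query_id[i]]]
    req <- min(nrow(rec$motifs), min_motifs)
    earliest <- min(rec$motifs$start)
    if (nchar(cand) < earliest - tolerance_window) {
      rows[[i]] <- data.frame(
        query_id = hits$query_id[i], clade_label = lab, qualified = FALSE,
        n_found = 0L, n_motifs = nrow(rec$motifs),
        reason = "sequence too short", stringsAsFactors = FALSE)
      next
    }
    mc <- locate_motifs(cand, rec$sequence, rec$motifs,
                        tolerance_window = tolerance_window)
    ok <- sum(mc$found) >= req
    reason <- if (ok) "all motifs found"
              else paste("missing motif(s):",
                         paste(mc$pattern[!mc$found], collapse = ", "))
    checks[[i]] <- mc
    rows[[i]] <- data.frame(
      query_id = hits$query_id[i], clade_label = lab, qualified = ok,
      n_found = sum(mc$found), n_motifs = nrow(mc),
      reason = reason, stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "motif_checks") <- checks
  out
}

#' Neighbor-joining tree from sequences or a distance matrix
#'
#' Builds an unrooted neighbor-joining tree ([ape::nj()]) from either a
#' symmetric distance matrix or a set of sequences (distance = 1 - pairwise
#' identity). Negative branch lengths are clamped to zero. Used as an
#' advisory screen for clades lacking validated structures: candidates
#' falling outside the subtree containing validated members can be flagged.
#'
#' @param x named character vector of >= 3 sequences, or a `dist`/matrix.
#' @return an [ape::phylo] tree.
#' @export
build_nj_tree <- function(x) {
  if (is.character(x)) {
    if (length(x) < 3L) stop("need at least 3 sequences")
    n <- length(x)
    d <- matrix(0, n, n, dimnames = list(names(x), names(x)))
    for (i in seq_len(n - 1L)) for (j in seq.int(i + 1L, n)) {
      d[i, j] <- d[j, i] <- 1 - pairwise_identity(x[[i]], x[[j]])
    }
  } else {
    d <- as.matrix(x)
    if (nrow(d) < 3L) stop("need at least 3 taxa")
  }
  tr <- ape::nj(stats::as.dist(d))
  tr$edge.length[tr$edge.length < 0] <- 0
  tr
}
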