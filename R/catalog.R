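#' Load the validated-phytase reference catalog
#'
#' Reads a columnar catalog of biochemically or structurally characterized
#' phytases: one clade representative per row with its family (BPP, HAP, CP
#' or PAP), clade label, organism, conserved catalytic/substrate-binding
#' motifs with their 1-based anchor positions in the representative, and the
#' accessions of the homologs grouped with it. The packaged default fixture
#' holds the full validated set: 4 BPP, 8 HAP, 2 CP and 2 PAP clade entries.
#'
#' @param path path to a tab-separated catalog file with columns
#'   `accession`, `family`, `clade`, `organism`, `motifs`
#'   (`PATTERN:start-end` entries joined by `;`) and optionally `homologs`
#'   (accessions joined by `;`). Defaults to the packaged catalog.
#' @param sequences optional named character vector of amino-acid sequences
#'   keyed by accession, attached to matching records.
#' @return an object of class `phytase_catalog`: a list of records, each with
#'   `accession`, `family`, `clade`, `organism`, `motifs` (data frame with
#'   `pattern`, `start`, `end`), `homologs`, and `sequence` (`NA` until
#'   supplied).
#' @export
load_catalog <- function(path = system.file("extdata", "table1_catalog.tsv",
                                            package = "phytascan"),
                         sequences = NULL) {
  raw <- utils::read.delim(path, stringsAsFactors = FALSE,
                           colClasses = "character", fill = TRUE)
  if (nrow(raw) == 0L) {
    warning("catalog source is empty")
    return(structure(list(), class = "phytase_catalog"))
  }
  needed <- c("accession", "family", "clade", "motifs")
  missing_cols <- setdiff(needed, names(raw))
  if (length(missing_cols))
    stop("malformed catalog: missing column(s) ",
         paste(missing_cols, collapse = ", "))
  if (anyDuplicated(raw$accession))
    stop("duplicate accession(s) in catalog: ",
         paste(unique(raw$accession[duplicated(raw$accession)]),
               collapse = ", "))
  records <- lapply(seq_len(nrow(raw)), function(i) {
    rec <- raw[i, ]
    if (is.na(rec$accession) || !nzchar(rec$accession))
      stop("malformed catalog record at row ", i, ": empty accession")
    if (!rec$family %in% PHYTASE_FAMILIES)
      stop("unknown family '", rec$family, "' for record ", rec$accession)
    motifs <- parse_motif_field(rec$motifs, rec$accession)
    homologs <- character(0)
    if ("homologs" %in% names(rec) && !is.na(rec$homologs) &&
        nzchar(rec$homologs))
      homologs <- strsplit(rec$homologs, ";", fixed = TRUE)[[1]]
    seq <- NA_character_
    if (!is.null(sequences) && rec$accession %in% names(sequences))
      seq <- unname(sequences[[rec$accession]])
    list(accession = rec$accession,
         family = rec$family,
         clade = rec$clade,
         organism = if ("organism" %in% names(rec)) rec$organism else "",
         motifs = motifs,
         homologs = homologs,
         sequence = seq)
  })
  names(records) <- raw$accession
  structure(records, class = "phytase_catalog")
}

parse_motif_field <- function(field, accession) {
  if (is.na(field) || !nzchar(field))
    stop("malformed catalog record ", accession, ": no motifs")
  parts <- strsplit(field, ";", fixed = TRUE)[[1]]
  m <- regmatches(parts, regexec("^(.+):([0-9]+)-([0-9]+)$", parts))
  bad <- vapply(m, length, 0L) != 4L
  if (any(bad))
    stop("malformed motif entry for ", accession, ": ",
         paste(parts[bad], collapse = ", "))
  out <- data.frame(
    pattern = vapply(m, `[`, "", 2L),
    start = as.integer(vapply(m, `[`, "", 3L)),
    end = as.integer(vapply(m, `[`, "", 4L)),
    stringsAsFactors = FALSE
  )
  if (any(out$start > out$end))
    stop("motif anchor start > end for ", accession)
  out
}

#' @export
print.phytase_catalog <- function(x, ...) {
  fam <- vapply(x, `[[`, "", "family")
  cat("phytase reference catalog:", length(x), "clade entries\n")
  if (length(x)) print(table(factor(fam, levels = PHYTASE_FAMILIES)))
  invisible(x)
}

#' Pairwise amino-acid sequence identity
#'
#' Global (Needleman-Wunsch) alignment with BLOSUM62 scoring, gap opening 10
#' and gap extension 0.5, via [Biostrings::pairwiseAlignment()]. Identity is
#' the fraction of identical residues over aligned columns, counting internal
#' gap columns but excluding terminal overhangs.
#'
#' @param seq_a,seq_b amino-acid strings.
#' @return identity fraction in `[0, 1]`.
#' @export
pairwise_identity <- function(seq_a, seq_b) {
  assert_aa(seq_a, "seq_a"); assert_aa(seq_b, "seq_b")
  # canonical argument order: co-optimal alignments can differ between
  # (a, b) and (b, a), so fix the orientation to guarantee symmetry
  if (seq_a > seq_b) { tmp <- seq_a; seq_a <- seq_b; seq_b <- tmp }
  aln <- Biostrings::pairwiseAlignment(
    seq_a, seq_b, type = "global",
    substitutionMatrix = "BLOSUM62",
    gapOpening = 10, gapExtension = 0.5)
  a <- strsplit(as.character(Biostrings::alignedPattern(aln)), "")[[1]]
  b <- strsplit(as.character(Biostrings::alignedSubject(aln)), "")[[1]]
  aligned_identity(a, b)
}

# Identity over aligned columns excluding terminal gap runs in either row.
aligned_identity <- function(a, b) {
  n <- length(a)
  gap_a <- a == "-"; gap_b <- b == "-"
  lead <- 0L
  while (lead < n && (gap_a[lead + 1L] || gap_b[lead + 1L])) lead <- lead + 1L
  trail <- 0L
  while (trail < n - lead && (gap_a[n - trail] || gap_b[n - trail]))
    trail <- trail + 1L
  keep <- seq.int(lead + 1L, n - trail)
  if (!length(keep)) return(0)
  sum(a[keep] == b[keep]) / length(keep)
}

#' Group reference enzymes into clades by representative-linkage
#'
#' Greedy clustering: sequences are visited in descending length order (ties
#' broken by accession); each sequence joins the first existing clade whose
#' representative it matches with identity strictly above `threshold`,
#' otherwise it seeds a new clade and becomes its representative. Clustering
#' is performed within each enzyme family, so clades never span families, and
#' is deterministic for a given input.
#'
#' @param enzymes a `phytase_catalog` or list of records, each bearing
#'   `accession`, `family` and a non-`NA` `sequence`.
#' @param threshold identity fraction in `(0, 1)`; default `0.28`
#'   (homologs above 28 percent identity are grouped).
#' @return data frame with one row per clade: `family`, `representative`,
#'   `members` (list column of accessions), `n_members`.
#' @export
cluster_into_clades <- function(enzymes, threshold = 0.28) {
  if (!is.numeric(threshold) || threshold <= 0 || threshold >= 1)
    stop("threshold must lie in (0, 1)")
  acc <- vapply(enzymes, `[[`, "", "accession")
  seqs <- vapply(enzymes, function(e) as.character(e$sequence), "")
  fams <- vapply(enzymes, `[[`, "", "family")
  if (anyNA(seqs) || any(!nzchar(seqs)))
    stop("missing sequence for: ",
         paste(acc[is.na(seqs) | !nzchar(seqs)], collapse = ", "))
  out <- list()
  for (fam in unique(fams)) {
    idx <- which(fams == fam)
    ord <- idx[order(-nchar(seqs[idx]), acc[idx])]
    reps <- integer(0)           # indices of clade representatives
    members <- list()
    for (i in ord) {
      placed <- FALSE
      for (k in seq_along(reps)) {
        if (pairwise_identity(seqs[i], seqs[reps[k]]) > threshold) {
          members[[k]] <- c(members[[k]], acc[i])
          placed <- TRUE
          break
        }
      }
      if (!placed) {
        reps <- c(reps, i)
        members[[length(reps)]] <- acc[i]
      }
    }
    for (k in seq_along(reps)) {
      out[[length(out) + 1L]] <- data.frame(
        family = fam, representative = acc[reps[k]],
        n_members = length(members[[k]]), stringsAsFactors = FALSE)
      out[[length(out)]]$members <- list(members[[k]])
    }
  }
  do.call(rbind, out)
}

#' Select a clade representative by score
#'
#' Returns the accession with the maximal score; ties are broken
#' lexicographically by accession.
#'
#' @param scores named numeric vector, one score per clade member.
#' @return the selected accession.
#' @export
select_representative <- function(scores) {
  if (length(scores) == 0L) stop("clade is empty")
  if (is.null(names(scores)) || any(!nzchar(names(scores))))
    stop("scores must be named by accession")
  best <- names(scores)[scores == max(scores)]
  sort(best)[1L]
}
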