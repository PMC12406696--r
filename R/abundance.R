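#' Marker-gene-normalized relative abundances
#'
#' Divides each gene's per-sample count by the mean count of the 10
#' universal single-copy bacterial marker genes in that sample, yielding a
#' per-genome-equivalent relative abundance that is invariant to sequencing
#' depth. Samples whose marker mean is zero are dropped with a warning.
#'
#' @param gene_counts samples x genes numeric matrix (or data frame) of
#'   non-negative counts; counts may be fractional (coverage-based).
#' @param marker_counts samples x markers matrix of non-negative counts;
#'   must have `n_markers` columns and the same rows as `gene_counts`.
#' @param n_markers expected number of marker genes; default 10.
#' @return object of class `abundance_table`: list with `values`
#'   (samples x genes relative abundances), `normalizer` (per-sample marker
#'   mean), `dropped` (samples removed).
#' @export
normalize_to_markers <- function(gene_counts, marker_counts,
                                 n_markers = 10L) {
  gene_counts <- as.matrix(gene_counts)
  marker_counts <- as.matrix(marker_counts)
  if (ncol(marker_counts) != n_markers)
    stop("expected ", n_markers, " marker genes, got ", ncol(marker_counts))
  if (nrow(gene_counts) != nrow(marker_counts))
    stop("gene and marker tables disagree on samples")
  if (any(gene_counts < 0) || any(marker_counts < 0))
    stop("counts must be non-negative")
  normalizer <- rowMeans(marker_counts)
  keep <- normalizer > 0
  if (!all(keep))
    warning("dropping sample(s) with zero marker abundance: ",
            paste(rownames(gene_counts)[!keep], collapse = ", "))
  values <- gene_counts[keep, , drop = FALSE] / normalizer[keep]
  structure(list(values = values, normalizer = normalizer[keep],
                 dropped = rownames(gene_counts)[!keep]),
            class = "abundance_table")
}

#' Assign each homolog its best-hit taxon
#'
#' Keeps, per query, the subject with the maximal bitscore (ties: lowest
#' E-value, then lexicographic subject id) and resolves its taxon to class
#' and kingdom through a lineage map. Unresolvable taxa are retained as
#' `"unclassified"`.
#'
#' @param hit_table data frame with columns `query`, `subject`, `bitscore`,
#'   `e_value`, `subject_taxon`.
#' @param lineage_map data frame with columns `taxon`, `kingdom`, `class`.
#' @return data frame: `query`, `subject`, `taxon`, `class`, `kingdom`.
#' @export
assign_best_hit_taxon <- function(hit_table, lineage_map) {
  needed <- c("query", "subject", "bitscore", "e_value", "subject_taxon")
  miss <- setdiff(needed, names(hit_table))
  if (length(miss))
    stop("hit table lacks column(s): ", paste(miss, collapse = ", "))
  if (nrow(hit_table) == 0L) stop("hit table is empty")
  ord <- order(hit_table$query, -hit_table$bitscore, hit_table$e_value,
               hit_table$subject)
  best <- hit_table[ord, ][!duplicated(hit_table$query[ord]), ]
  m <- match(best$subject_taxon, lineage_map$taxon)
  data.frame(query = best$query, subject = best$subject,
             taxon = best$subject_taxon,
             class = ifelse(is.na(m), "unclassified", lineage_map$class[m]),
             kingdom = ifelse(is.na(m), "unclassified",
                              lineage_map$kingdom[m]),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Class-level taxonomic frequency profiles per sample type
#'
#' For each sample type, class frequencies are normalized to sum to 1 and
#' sorted by descending frequency.
#'
#' @param assignments data frame with `query` and `class` (e.g. from
#'   [assign_best_hit_taxon()]).
#' @param sample_type_of named character vector query -> sample type.
#' @return named list (one element per sample type) of named numeric
#'   frequency vectors, class `tax_profile_set`.
#' @export
class_frequency_profile <- function(assignments, sample_type_of) {
  unmapped <- setdiff(assignments$query, names(sample_type_of))
  if (length(unmapped))
    stop("query with no sample type: ", paste(unmapped, collapse = ", "))
  types <- unique(unname(sample_type_of[assignments$query]))
  out <- list()
  for (ty in types) {
    cls <- assignments$class[sample_type_of[assignments$query] == ty]
    if (!length(cls)) {
      warning("no assignments for sample type ", ty, "; omitted")
      next
    }
    tab <- table(cls)
    freq <- sort(as.numeric(tab) / sum(tab), decreasing = TRUE)
    names(freq) <- names(tab)[order(-as.numeric(tab))]
    out[[ty]] <- freq
  }
  structure(out, class = "tax_profile_set")
}

#' Exclusive-region (Venn) shared-class counts across sample types
#'
#' For every non-empty subset S of sample types, counts the classes present
#' in all members of S and absent from every other type (the exclusive Venn
#' region), so the regions partition the union of all class sets.
#'
#' @param profiles a `tax_profile_set` or named list of class sets
#'   (character vectors or named frequency vectors).
#' @return data frame: `region` (sample types joined by `&`), `n_types`,
#'   `count`, plus a `classes` list column.
#' @export
shared_class_counts <- function(profiles) {
  if (length(profiles) < 2L) stop("need at least 2 profiles")
  if (is.null(names(profiles)) || anyDuplicated(names(profiles)))
    stop("profiles must have unique sample-type labels")
  sets <- lapply(profiles, function(p) {
    if (is.character(p)) unique(p) else names(p)
  })
  types <- names(sets)
  universe <- unique(unlist(sets))
  membership <- vapply(sets, function(s) universe %in% s,
                       logical(length(universe)))
  if (length(universe) == 1L) membership <- matrix(membership, nrow = 1L)
  n <- length(types)
  rows <- list()
  for (mask in seq_len(2^n - 1L)) {
    inset <- as.logical(bitwAnd(mask, 2^(seq_len(n) - 1L)))
    in_region <- apply(membership, 1L, function(r) all(r == inset))
    cls <- universe[in_region]
    rows[[length(rows) + 1L]] <- data.frame(
      region = paste(types[inset], collapse = "&"),
      n_types = sum(inset), count = length(cls),
      stringsAsFactors = FALSE)
    rows[[length(rows)]]$classes <- list(cls)
  }
  do.call(rbind, rows)
}

#' Share of the n most abundant classes
#'
#' @param profile named numeric frequency vector (one sample type).
#' @param n number of top classes; default 10.
#' @return the summed frequency of the `n` largest classes, in `[0, 1]`.
#' @export
top_n_share <- function(profile, n = 10L) {
  if (n < 1L) stop("n must be >= 1")
  if (n >= length(profile)) {
    if (n > length(profile))
      message("n exceeds the number of classes; returning the full total")
    return(sum(profile))
  }
  sum(sort(profile, decreasing = TRUE)[seq_len(n)])
}
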