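PIPELINE_DEFAULTS <- list(
  query_fasta = NULL,          # path to candidate protein FASTA (required)
  out_dir = "phytascan_out",
  evalue_cutoff = 1e-30,
  identity_threshold = 0.28,
  tolerance_window = 10,
  marker_genes = NULL,         # defaults to the 10 universal marker COGs
  reference_accessions = NULL, # restrict profiles to these representatives
  gene_counts = NULL,          # optional TSV paths for the quantify stage
  marker_counts = NULL,
  nst_reps = 1000,
  calibration_n = 200,
  seed = 42
)

#' Validate and normalize a pipeline configuration
#'
#' Accepts a list or a YAML file path; unknown keys are rejected (with a
#' nearest-key suggestion), numeric fields given as strings are coerced,
#' and defaults matching the published analysis parameters (E-value cutoff
#' 1e-30, identity threshold 0.28, 10 marker genes) are injected.
#'
#' @param config named list or path to a YAML config file; `NULL` or an
#'   empty file yields all defaults.
#' @return normalized configuration list of class `pipeline_config`.
#' @export
validate_config <- function(config = NULL) {
  if (is.character(config) && length(config) == 1L) {
    config <- yaml::read_yaml(config)
    if (is.null(config)) config <- list()
  }
  if (is.null(config)) config <- list()
  if (!is.list(config)) stop("config must be a list or a YAML file path")
  unknown <- setdiff(names(config), names(PIPELINE_DEFAULTS))
  if (length(unknown)) {
    hints <- vapply(unknown, function(k) {
      near <- agrep(k, names(PIPELINE_DEFAULTS), max.distance = 2,
                    value = TRUE)
      if (length(near)) paste0(" (did you mean '", near[1L], "'?)") else ""
    }, "")
    stop("unknown config key(s): ",
         paste0(unknown, hints, collapse = ", "))
  }
  out <- utils::modifyList(PIPELINE_DEFAULTS, config)
  for (k in c("evalue_cutoff", "identity_threshold", "tolerance_window",
              "nst_reps", "calibration_n", "seed")) {
    if (is.character(out[[k]])) {
      val <- suppressWarnings(as.numeric(out[[k]]))
      if (is.na(val)) stop("config key '", k, "' is not numeric")
      out[[k]] <- val
    }
    if (!is.numeric(out[[k]]))
      stop("config key '", k, "' must be numeric")
  }
  if (out$evalue_cutoff < 0) stop("evalue_cutoff must be >= 0")
  if (out$identity_threshold <= 0 || out$identity_threshold >= 1)
    stop("identity_threshold must lie in (0, 1)")
  if (is.null(out$marker_genes)) out$marker_genes <- DEFAULT_MARKER_GENES
  structure(out, class = c("pipeline_config", "list"))
}

write_tsv_provenance <- function(df, path, params) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  for (k in names(params))
    writeLines(sprintf("# %s=%s", k, params[[k]]), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

read_tsv_provenance <- function(path) {
  utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
}

#' Run the mining pipeline end to end
#'
#' Executes build-db (reference profiles and E-value calibration), search
#' (profile scan at the configured E-value cutoff), screen (conserved-motif
#' qualification), and, when count tables are configured, quantify
#' (marker-gene normalization). Stage outputs are written as plain TSV
#' files with `# key=value` provenance headers and each stage is re-runnable
#' on its own: with `force = FALSE` an existing stage output is reloaded
#' rather than recomputed.
#'
#' @param config a `pipeline_config` (or anything [validate_config()]
#'   accepts).
#' @param catalog optional `phytase_catalog` with sequences; when `NULL`,
#'   the synthetic stand-in reference set is generated from the packaged
#'   catalog.
#' @param force recompute stages even when their outputs exist.
#' @return summary list: `n_queries`, `n_hits`, `n_qualified`,
#'   `per_family`, `manifest` (paths of all outputs), `config`.
#' @export
run_pipeline <- function(config, catalog = NULL, force = FALSE) {
  config <- validate_config(config)
  if (is.null(config$query_fasta) || !file.exists(config$query_fasta))
    stop("query_fasta is missing or does not exist")
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- character(0)
  prov <- list(evalue_cutoff = format(config$evalue_cutoff),
               identity_threshold = config$identity_threshold,
               tolerance_window = config$tolerance_window,
               seed = config$seed,
               evalue_cutoff_scope = "per profile-query pair",
               package = as.character(utils::packageVersion("phytascan")))

  # ---- build-db ----
  if (is.null(catalog))
    catalog <- synthetic_reference_set(seed = config$seed)
  reps <- Filter(function(r) isFALSE(r$synthetic_member %||% FALSE), catalog)
  if (!is.null(config$reference_accessions))
    reps <- reps[intersect(names(reps), config$reference_accessions)]
  if (!length(reps)) stop("no reference representatives selected")
  family_of <- stats::setNames(vapply(reps, `[[`, "", "family"),
                               vapply(reps, `[[`, "", "accession"))
  profiles <- lapply(reps, function(r)
    build_profile(r$sequence, clade_label = r$accession))
  calibrations <- lapply(profiles, function(p)
    calibrate_evalues(p, n_random = config$calibration_n,
                      seed = config$seed))
  names(calibrations) <- vapply(profiles, `[[`, "", "clade_label")

  queries <- read_protein_fasta(config$query_fasta)

  # ---- search ----
  hits_path <- file.path(config$out_dir, "hits.tsv")
  if (!force && file.exists(hits_path)) {
    hits <- read_tsv_provenance(hits_path)
  } else {
    hits <- search_profiles(profiles, queries, cutoff = config$evalue_cutoff,
                            calibrations = calibrations,
                            family_of = family_of)
    write_tsv_provenance(
      format_hits(hits), hits_path, prov)
  }
  manifest <- c(manifest, hits_path)

  # ---- screen ----
  screen_path <- file.path(config$out_dir, "screen.tsv")
  if (!force && file.exists(screen_path)) {
    screen <- read_tsv_provenance(screen_path)
  } else {
    screen <- screen_candidates(hits, queries, catalog,
                                tolerance_window = config$tolerance_window)
    write_tsv_provenance(screen, screen_path, prov)
  }
  rejected_path <- file.path(config$out_dir, "rejected.tsv")
  if (force || !file.exists(rejected_path))
    write_tsv_provenance(screen[!screen$qualified, , drop = FALSE],
                         rejected_path, prov)
  manifest <- c(manifest, screen_path, rejected_path)

  # ---- quantify (optional) ----
  abundance_path <- NULL
  if (!is.null(config$gene_counts) && !is.null(config$marker_counts)) {
    abundance_path <- file.path(config$out_dir, "abundance.tsv")
    if (force || !file.exists(abundance_path)) {
      gc <- as.matrix(read_tsv_provenance(config$gene_counts)[, -1,
                                                              drop = FALSE])
      mc <- as.matrix(read_tsv_provenance(config$marker_counts)[, -1,
                                                                drop = FALSE])
      ab <- normalize_to_markers(gc, mc,
                                 n_markers = length(config$marker_genes))
      write_tsv_provenance(as.data.frame(ab$values), abundance_path, prov)
    }
    manifest <- c(manifest, abundance_path)
  }

  fam_hits <- table(factor(
    hits$family[hits$query_id %in% screen$query_id[screen$qualified]],
    levels = PHYTASE_FAMILIES))
  list(n_queries = length(queries),
       n_hits = nrow(hits),
       n_qualified = sum(screen$qualified),
       per_family = fam_hits,
       manifest = manifest,
       config = config)
}

format_hits <- function(hits) {
  hits$raw_score <- round(hits$raw_score, 4)
  hits$e_value <- signif(hits$e_value, 6)
  hits
}

`%||%` <- function(a, b) if (is.null(a)) b else a
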