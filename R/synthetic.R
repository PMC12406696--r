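#' Generate a random background proteome
#'
#' Sequences of i.i.d. residues from the background amino-acid composition,
#' with normally distributed lengths (floored at 30 residues).
#'
#' @param n number of sequences (>= 1).
#' @param length_mean,length_sd length distribution in residues; defaults
#'   300 and 50, typical of predicted metagenome proteins.
#' @param seed integer seed; output is deterministic given the seed.
#' @param prefix sequence-name prefix.
#' @return named character vector of sequences.
#' @export
random_proteome <- function(n, length_mean = 300, length_sd = 50,
                            seed = 42, prefix = "bg") {
  if (n < 1) stop("n must be >= 1")
  withr::with_seed(seed, {
    lens <- pmax(30L, as.integer(round(stats::rnorm(n, length_mean,
                                                    length_sd))))
    seqs <- vapply(lens, random_aa, "")
  })
  names(seqs) <- sprintf("%s_%05d", prefix, seq_len(n))
  seqs
}

#' Synthetic stand-in sequences for the validated reference set
#'
#' The validated reference enzymes are distributed by accession only; this
#' generator constructs synthetic stand-in sequences for each clade entry in
#' the catalog: a random background-composition sequence long enough to host
#' the clade's motifs, with every conserved motif written at its printed
#' anchor positions, plus one synthetic homolog per listed homolog accession
#' mutated (outside motif columns) to a controlled identity with the
#' representative. Between-clade sequences are unrelated, so clustering at
#' the catalog threshold recovers the catalog's clade structure.
#'
#' @param catalog a `phytase_catalog`; default the packaged catalog.
#' @param member_identity within-clade identity of generated homologs to
#'   their representative; default 0.7.
#' @param seed integer seed.
#' @param tail_length residues appended after the last motif anchor.
#' @return a `phytase_catalog` whose records carry synthetic sequences; the
#'   generated homolog records are appended as additional entries with
#'   `clade`/`family` inherited and `synthetic_member = TRUE`.
#' @export
synthetic_reference_set <- function(catalog = load_catalog(),
                                    member_identity = 0.7, seed = 101,
                                    tail_length = 40L) {
  out <- list()
  withr::with_seed(seed, {
    for (rec in catalog) {
      L <- max(rec$motifs$end) + tail_length
      seq_chars <- strsplit(random_aa(L), "")[[1]]
      for (i in seq_len(nrow(rec$motifs))) {
        pat <- strsplit(rec$motifs$pattern[i], "")[[1]]
        seq_chars[seq.int(rec$motifs$start[i], rec$motifs$end[i])] <- pat
      }
      rec$sequence <- paste(seq_chars, collapse = "")
      rec$synthetic_member <- FALSE
      out[[rec$accession]] <- rec
      motif_cols <- unlist(lapply(seq_len(nrow(rec$motifs)), function(i)
        seq.int(rec$motifs$start[i], rec$motifs$end[i])))
      for (hom in rec$homologs) {
        hrec <- rec
        hrec$accession <- hom
        hrec$homologs <- character(0)
        hrec$sequence <- mutate_sequence(rec$sequence, motif_cols,
                                         member_identity)
        hrec$synthetic_member <- TRUE
        out[[hom]] <- hrec
      }
    }
  })
  structure(out, class = "phytase_catalog")
}

# Substitute residues outside `protected` columns until the target identity
# is reached (substitutions only, so identity is exact arithmetic).
mutate_sequence <- function(seq, protected, target_identity) {
  chars <- strsplit(seq, "")[[1]]
  L <- length(chars)
  n_mut <- round((1 - target_identity) * L)
  mutable <- setdiff(seq_len(L), protected)
  if (n_mut > length(mutable))
    stop("target identity too low to preserve motifs; minimum is ",
         sprintf("%.2f", 1 - length(mutable) / L))
  pos <- sample(mutable, n_mut)
  for (p in pos) {
    chars[p] <- sample(setdiff(AA_ALPHABET, chars[p]), 1L)
  }
  paste(chars, collapse = "")
}

#' Plant phytase homologs in a background proteome
#'
#' Emits mutated copies of a clade representative at a requested identity.
#' When `motif_intact` is `TRUE` substitutions avoid motif columns, so every
#' planted copy passes motif screening; when `FALSE`, two residues of the
#' longest motif are additionally mutated, so every copy fails it.
#'
#' @param background named character vector (e.g. from [random_proteome()]).
#' @param representative representative amino-acid string.
#' @param motifs data frame of motif anchors (`pattern`, `start`, `end`).
#' @param copies number of planted copies.
#' @param target_identity identity of planted copies to the representative,
#'   in `(0, 1]`.
#' @param motif_intact logical.
#' @param seed integer seed.
#' @param clade_label,taxon_class labels recorded in the truth table.
#' @param prefix name prefix for planted sequences.
#' @return list with `proteins` (background + planted) and `truth`
#'   (data frame: `id`, `clade`, `intact`, `taxon_class`,
#'   `target_identity`, `realized_identity`).
#' @export
plant_homologs <- function(background, representative, motifs, copies,
                           target_identity, motif_intact = TRUE, seed = 42,
                           clade_label = "clade", taxon_class = "unknown",
                           prefix = if (motif_intact) "planted_intact"
                                    else "planted_broken") {
  assert_aa(representative, "representative")
  if (target_identity <= 0 || target_identity > 1)
    stop("target_identity must lie in (0, 1]")
  L <- nchar(representative)
  motif_cols <- unlist(lapply(seq_len(nrow(motifs)), function(i)
    seq.int(motifs$start[i], motifs$end[i])))
  longest <- which.max(motifs$end - motifs$start)
  planted <- character(copies)
  realized <- numeric(copies)
  withr::with_seed(seed, {
    for (k in seq_len(copies)) {
      s <- if (target_identity == 1) representative
           else mutate_sequence(representative, motif_cols, target_identity)
      if (!motif_intact) {
        chars <- strsplit(s, "")[[1]]
        span <- seq.int(motifs$start[longest], motifs$end[longest])
        brk <- span[seq_len(min(2L, length(span)))]
        for (p in brk)
          chars[p] <- sample(setdiff(AA_ALPHABET, chars[p]), 1L)
        s <- paste(chars, collapse = "")
      }
      planted[k] <- s
      rep_chars <- strsplit(representative, "")[[1]]
      realized[k] <- mean(strsplit(s, "")[[1]] == rep_chars)
    }
  })
  names(planted) <- sprintf("%s_%03d", prefix, seq_len(copies))
  truth <- data.frame(id = names(planted),
                      clade = rep(clade_label, copies),
                      intact = rep(motif_intact, copies),
                      taxon_class = rep(taxon_class, copies),
                      target_identity = rep(target_identity, copies),
                      realized_identity = realized,
                      stringsAsFactors = FALSE)
  list(proteins = c(background, planted), truth = truth)
}

#' Simulate per-sample gene and marker-gene count tables
#'
#' Expected marker counts equal a per-sample depth factor; expected gene
#' counts are the true per-genome-equivalent relative abundance times that
#' depth. Counts are Poisson draws, so marker normalization of the output
#' recovers the true relative abundances up to sampling noise, invariant to
#' the depth factors.
#'
#' @param rel_abundance samples x genes matrix of true relative abundances
#'   (per genome equivalent).
#' @param depth per-sample depth factors (positive), recycled.
#' @param n_markers number of marker genes; default 10.
#' @param seed integer seed.
#' @return list with `gene_counts`, `marker_counts`, `truth`
#'   (= `rel_abundance`), `depth`.
#' @export
simulate_sample_counts <- function(rel_abundance, depth = 100,
                                   n_markers = 10L, seed = 42) {
  rel_abundance <- as.matrix(rel_abundance)
  if (any(rel_abundance < 0)) stop("relative abundances must be >= 0")
  ns <- nrow(rel_abundance)
  depth <- rep_len(depth, ns)
  if (any(depth <= 0)) stop("depth factors must be positive")
  withr::with_seed(seed, {
    lambda <- rel_abundance * depth  # depth recycles per row (column-major)
    gene_counts <- matrix(
      stats::rpois(length(lambda), as.vector(lambda)),
      nrow = ns, dimnames = dimnames(rel_abundance))
    marker_counts <- matrix(
      stats::rpois(ns * n_markers, rep(depth, n_markers)),
      nrow = ns,
      dimnames = list(rownames(rel_abundance), DEFAULT_MARKER_GENES[
        seq_len(n_markers)]))
  })
  list(gene_counts = gene_counts, marker_counts = marker_counts,
       truth = rel_abundance, depth = depth)
}

#' Simulate community matrices under neutral or selective assembly
#'
#' Neutral mode emulates stochastic assembly (dispersal and drift): each
#' sample occupies a random subset of taxa drawn with probability
#' proportional to metacommunity abundance, then experiences ecological
#' drift — its composition is a Dirichlet resampling of the metacommunity
#' (concentration `drift_theta`; smaller is stronger drift) — before
#' multinomial sampling. Selection mode emulates strong environmental
#' filtering: every sample is a multinomial draw from one fixed target
#' composition over the same occupied set, making samples far more similar
#' to one another than any null expectation.
#'
#' @param mode `"neutral"` or `"selection"`.
#' @param n_samples number of samples (>= 6).
#' @param n_taxa number of taxa; default 40.
#' @param total individuals per sample; default 2000.
#' @param drift_theta Dirichlet concentration of per-sample drift in
#'   neutral mode; default 10.
#' @param seed integer seed.
#' @return samples x taxa count matrix with row/column names.
#' @export
simulate_community_assembly <- function(mode = c("neutral", "selection"),
                                        n_samples, n_taxa = 40L,
                                        total = 2000L, drift_theta = 10,
                                        seed = 42) {
  mode <- match.arg(mode)
  if (n_samples < 6L) stop("need at least 6 samples")
  m <- matrix(0L, n_samples, n_taxa,
              dimnames = list(sprintf("s%02d", seq_len(n_samples)),
                              sprintf("t%03d", seq_len(n_taxa))))
  withr::with_seed(seed, {
    meta <- stats::rlnorm(n_taxa, 0, 1)
    meta <- meta / sum(meta)
    if (mode == "neutral") {
      for (i in seq_len(n_samples)) {
        rich <- sample(seq.int(round(0.5 * n_taxa), round(0.8 * n_taxa)), 1L)
        taxa <- sample.int(n_taxa, rich, prob = meta)
        p <- meta[taxa] / sum(meta[taxa])
        q <- stats::rgamma(rich, shape = drift_theta * p)
        if (sum(q) <= 0) q <- p
        m[i, taxa] <- stats::rmultinom(1L, total, q / sum(q))[, 1L]
      }
    } else {
      rich <- round(0.65 * n_taxa)
      taxa <- sample.int(n_taxa, rich, prob = meta)
      target <- meta[taxa] / sum(meta[taxa])
      for (i in seq_len(n_samples)) {
        m[i, taxa] <- stats::rmultinom(1L, total, target)[, 1L]
      }
    }
  })
  m
}

#' Simulate Michaelis-Menten rate data
#'
#' `v = Vmax S / (Km + S)` plus Gaussian noise truncated at zero;
#' `noise_sd = 0` yields exact model values. The design is flagged as
#' ill-conditioned when every substrate concentration far exceeds Km (the
#' double-reciprocal intercept is then poorly determined).
#'
#' @param Km,Vmax positive parameters.
#' @param S_grid substrate concentrations (mM), positive.
#' @param noise_sd standard deviation of additive noise (>= 0).
#' @param seed integer seed.
#' @return data frame with `S` and `v`; attribute `ill_conditioned`.
#' @export
simulate_kinetics_data <- function(Km, Vmax, S_grid, noise_sd = 0,
                                   seed = 42) {
  if (Km <= 0 || Vmax <= 0) stop("Km and Vmax must be positive")
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  v <- mm_rate(S_grid, Km, Vmax)
  if (noise_sd > 0)
    v <- withr::with_seed(seed,
      pmax(v + stats::rnorm(length(v), 0, noise_sd), 0))
  out <- data.frame(S = S_grid, v = v)
  attr(out, "ill_conditioned") <- min(S_grid) > 5 * Km
  out
}
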