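#' @useDynLib phytascan, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

# Standard amino-acid alphabet, fixed ordering used throughout (PSSM rows,
# integer encoding in the compiled scanner).
AA_ALPHABET <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                 "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

# Background residue frequencies (UniProt-like composition), used for random
# proteome generation and as the null model in log-odds profile scores.
AA_BACKGROUND <- c(
  A = 0.0826, C = 0.0137, D = 0.0546, E = 0.0672, F = 0.0386,
  G = 0.0708, H = 0.0227, I = 0.0593, K = 0.0581, L = 0.0965,
  M = 0.0241, N = 0.0406, P = 0.0474, Q = 0.0394, R = 0.0553,
  S = 0.0665, T = 0.0536, V = 0.0686, W = 0.0110, Y = 0.0292
)
AA_BACKGROUND <- AA_BACKGROUND / sum(AA_BACKGROUND)

PHYTASE_FAMILIES <- c("BPP", "HAP", "CP", "PAP")

# Family-level motif grammars as printed in the clade table header rows.
FAMILY_MOTIFS <- list(
  BPP = c("YG", "EGXXXD", "DXEG", "DG"),
  HAP = c("RHGXRXP", "HD/HAE"),
  CP  = c("DH", "HCXXGXGRT"),
  PAP = c("GDXG", "GNH[D/E]", "VXXXH", "GHXH")
)

# The 10 universal single-copy bacterial marker genes used for abundance
# normalization (ribosomal-protein / tRNA-synthetase COGs).
DEFAULT_MARKER_GENES <- c(
  "COG0012", "COG0016", "COG0018", "COG0172", "COG0215",
  "COG0495", "COG0525", "COG0533", "COG0541", "COG0552"
)

assert_aa <- function(seq, what = "sequence") {
  if (length(seq) != 1L || !is.character(seq) || is.na(seq) || nchar(seq) == 0L)
    stop(what, " must be a non-empty amino-acid string", call. = FALSE)
  bad <- setdiff(unique(strsplit(seq, "")[[1]]), AA_ALPHABET)
  if (length(bad))
    stop(what, " contains non-amino-acid characters: ",
         paste(bad, collapse = ", "), call. = FALSE)
  invisible(seq)
}

aa_encode <- function(seq) {
  match(strsplit(seq, "")[[1]], AA_ALPHABET)
}

#' Sample a random amino-acid sequence from the background composition
#' @keywords internal
random_aa <- function(n) {
  paste(sample(AA_ALPHABET, n, replace = TRUE, prob = AA_BACKGROUND),
        collapse = "")
}

#' Read a protein FASTA file into a named character vector
#'
#' Thin wrapper over [Biostrings::readAAStringSet()] returning plain
#' character sequences keyed by the first whitespace-delimited token of each
#' header.
#'
#' @param path path to a FASTA file of protein sequences.
#' @return named character vector of sequences.
#' @export
read_protein_fasta <- function(path) {
  x <- Biostrings::readAAStringSet(path)
  out <- as.character(x)
  names(out) <- vapply(strsplit(names(x), "\\s+"), `[`, "", 1L)
  out
}

#' Write protein sequences to a FASTA file
#'
#' @param seqs named character vector of amino-acid sequences.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_protein_fasta <- function(seqs, path) {
  x <- Biostrings::AAStringSet(seqs)
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}
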