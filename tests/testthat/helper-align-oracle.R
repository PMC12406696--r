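# Independent affine-gap global alignment oracle (Gotoh), for checking
# alignment scores on short sequences. Gap of length k costs
# gap_open + k * gap_ext, matching the convention of the aligner under test.
gotoh_score <- function(a, b, gap_open = 10, gap_ext = 0.5) {
  data("BLOSUM62", package = "Biostrings", envir = environment())
  sm <- BLOSUM62
  x <- strsplit(a, "")[[1]]
  y <- strsplit(b, "")[[1]]
  n <- length(x); m <- length(y)
  NEG <- -1e9
  M <- matrix(NEG, n + 1, m + 1)   # ends in match/mismatch
  Ix <- matrix(NEG, n + 1, m + 1)  # gap in y (consumes x)
  Iy <- matrix(NEG, n + 1, m + 1)  # gap in x (consumes y)
  M[1, 1] <- 0
  for (i in seq_len(n))
    Ix[i + 1, 1] <- -(gap_open + gap_ext * i)
  for (j in seq_len(m))
    Iy[1, j + 1] <- -(gap_open + gap_ext * j)
  for (i in seq_len(n)) {
    for (j in seq_len(m)) {
      s <- sm[x[i], y[j]]
      M[i + 1, j + 1] <- max(M[i, j], Ix[i, j], Iy[i, j]) + s
      Ix[i + 1, j + 1] <- max(M[i, j + 1] - gap_open - gap_ext,
                              Ix[i, j + 1] - gap_ext)
      Iy[i + 1, j + 1] <- max(M[i + 1, j] - gap_open - gap_ext,
                              Iy[i + 1, j] - gap_ext)
    }
  }
  max(M[n + 1, m + 1], Ix[n + 1, m + 1], Iy[n + 1, m + 1])
}
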