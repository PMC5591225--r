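# Independent brute-force oracles used to check the package's interval,
# alignment and translation code. Deliberately naive implementations.

# per-base boolean membership vector over [0, n) for one sequence
bits_from_intervals <- function(iv, n) {
  b <- logical(n)
  for (i in seq_len(nrow(iv))) b[(iv$start[i] + 1):iv$end[i]] <- TRUE
  b
}

intervals_from_bits <- function(b, seq_id = "s") {
  r <- rle(b)
  ends <- cumsum(r$lengths); starts <- ends - r$lengths
  keep <- r$values
  data.frame(seq_id = seq_id, start = starts[keep], end = ends[keep])
}

random_raw_intervals <- function(n_iv, n, seq_id = "s") {
  s <- sample.int(n, n_iv, replace = TRUE) - 1L
  w <- sample.int(max(n %/% 10L, 2L), n_iv, replace = TRUE)
  data.frame(seq_id = seq_id, start = s, end = pmin(s + w, n))
}

# naive per-base depth: increment one position at a time
depth_oracle <- function(iv, n) {
  d <- integer(n)
  for (i in seq_len(nrow(iv)))
    for (p in (iv$start[i] + 1):iv$end[i]) d[p] <- d[p] + 1L
  d
}

# Smith-Waterman local alignment score, affine gaps (Gotoh); a gap of
# length L costs gap_open + L * gap_ext, matching Biostrings' convention
sw_score_oracle <- function(a, b, mat, gap_open = 11, gap_ext = 1) {
  a <- strsplit(a, "")[[1]]; b <- strsplit(b, "")[[1]]
  n <- length(a); m <- length(b)
  M <- matrix(0, n + 1, m + 1)   # best ending in a match/mismatch
  E <- matrix(-Inf, n + 1, m + 1) # gap in b (vertical)
  F_ <- matrix(-Inf, n + 1, m + 1)
  best <- 0
  for (i in 2:(n + 1)) {
    for (j in 2:(m + 1)) {
      E[i, j] <- max(M[i - 1, j] - (gap_open + gap_ext), E[i - 1, j] - gap_ext)
      F_[i, j] <- max(M[i, j - 1] - (gap_open + gap_ext), F_[i, j - 1] - gap_ext)
      s <- mat[a[i - 1], b[j - 1]]
      M[i, j] <- max(0, M[i - 1, j - 1] + s, E[i, j], F_[i, j])
      if (M[i, j] > best) best <- M[i, j]
    }
  }
  best
}

# codon-by-codon translation via a literal lookup table
codon_oracle <- function(dna) {
  code <- Biostrings::GENETIC_CODE
  n <- nchar(dna) %/% 3L
  if (n == 0L) return("")
  out <- character(n)
  for (k in seq_len(n)) {
    codon <- substr(dna, 3L * k - 2L, 3L * k)
    out[k] <- if (grepl("N", codon)) "X" else unname(code[codon])
  }
  paste(out, collapse = "")
}

# brute-force sliding-window canonical 4-mer frequencies
tnf_oracle <- function(seq) {
  revcomp <- function(s) chartr("ACGT", "TGCA", paste(rev(strsplit(s, "")[[1]]), collapse = ""))
  counts <- new.env()
  for (i in seq_len(nchar(seq) - 3L)) {
    k <- substr(seq, i, i + 3L)
    if (grepl("[^ACGT]", k)) next
    canon <- min(k, revcomp(k))
    counts[[canon]] <- (if (is.null(counts[[canon]])) 0 else counts[[canon]]) + 1
  }
  v <- unlist(as.list(counts))
  v[order(names(v))] / sum(v)
}
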