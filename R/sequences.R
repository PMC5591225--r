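#' Read a FASTA file into a validated sequence set
#'
#' Sequences are upper-cased and restricted to the DNA alphabet
#' `A,C,G,T,N`. IUPAC ambiguity codes other than `N` are mapped to `N`
#' with a warning; any other character is an error. The id of each record
#' is the header up to the first whitespace.
#'
#' @param path Path to a FASTA file.
#' @return A [Biostrings::DNAStringSet] with unique, non-empty names.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  x <- Biostrings::readBStringSet(path)
  ids <- sub("\\s.*$", "", names(x))
  if (any(ids == "")) stop("empty sequence id in ", path)
  dup <- unique(ids[duplicated(ids)])
  if (length(dup)) stop("duplicate sequence id(s): ", paste(dup, collapse = ", "))
  names(x) <- ids
  as_sequence_set(x)
}

#' Coerce character vectors or string sets to the internal sequence set
#'
#' @param x Named character vector or XStringSet.
#' @return A validated `DNAStringSet` over `A,C,G,T,N`.
#' @export
as_sequence_set <- function(x) {
  if (is(x, "DNAStringSet") || is(x, "BStringSet")) {
    seqs <- toupper(as.character(x))
    names(seqs) <- names(x)
  } else if (is.character(x)) {
    seqs <- toupper(x)
  } else stop("cannot coerce to sequence set: ", class(x)[1])
  if (!length(seqs)) return(Biostrings::DNAStringSet())
  if (is.null(names(seqs)) || any(names(seqs) == ""))
    stop("sequence set requires non-empty names")
  if (any(nchar(seqs) == 0))
    stop("empty sequence: ", paste(names(seqs)[nchar(seqs) == 0], collapse = ", "))
  # IUPAC ambiguity codes (not N) are tolerated but masked
  ambig <- "RYSWKMBDHV"
  has_ambig <- grepl(paste0("[", ambig, "]"), seqs)
  if (any(has_ambig)) {
    warning("IUPAC ambiguity codes mapped to N in: ",
            paste(names(seqs)[has_ambig], collapse = ", "))
    seqs <- chartr(ambig, strrep("N", nchar(ambig)), seqs)
  }
  bad <- grepl("[^ACGTN]", seqs)
  if (any(bad))
    stop("non-IUPAC characters in: ", paste(names(seqs)[bad], collapse = ", "))
  Biostrings::DNAStringSet(seqs)
}

#' Write a sequence set to FASTA
#'
#' @param x A `DNAStringSet` (or named character vector).
#' @param path Output path.
#' @param width Line width for wrapping.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(x, path, width = 70L) {
  x <- as_sequence_set(x)
  Biostrings::writeXStringSet(x, path, width = width)
  invisible(path)
}

#' Read a FASTQ file (qualities parsed then discarded)
#'
#' @param path Path to a FASTQ file.
#' @return A validated `DNAStringSet`.
#' @export
read_fastq <- function(path) {
  x <- Biostrings::readDNAStringSet(path, format = "fastq")
  names(x) <- sub("\\s.*$", "", names(x))
  as_sequence_set(x)
}

#' GC content of sequences
#'
#' @param x Sequence set.
#' @param weighted If `TRUE` (default) return the single length-weighted
#'   fraction over all sequences; otherwise a per-sequence vector.
#'   `N` bases are excluded from the denominator.
#' @return Fraction(s) in `[0,1]`.
#' @export
gc_content <- function(x, weighted = TRUE) {
  x <- as_sequence_set(x)
  f <- Biostrings::alphabetFrequency(x, baseOnly = TRUE)
  gc <- f[, "G"] + f[, "C"]
  acgt <- gc + f[, "A"] + f[, "T"]
  if (weighted) sum(gc) / sum(acgt) else stats::setNames(gc / acgt, names(x))
}

seq_lengths <- function(x) stats::setNames(Biostrings::width(x), names(x))
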