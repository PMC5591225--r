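#' Six-frame translation of a DNA sequence
#'
#' Standard genetic code; codons containing `N` translate to `X`,
#' trailing partial codons are dropped, and frames `-1..-3` translate
#' the reverse complement.
#'
#' @param sequence DNA string over `A,C,G,T,N`.
#' @return Character vector of 6 protein strings named
#'   `+1,+2,+3,-1,-2,-3` (empty strings for sequences shorter than a
#'   codon).
#' @export
six_frame_translate <- function(sequence) {
  s <- Biostrings::DNAString(toupper(as.character(sequence)))
  rc <- Biostrings::reverseComplement(s)
  one <- function(x, off) {
    n <- length(x) - off
    if (n < 3L) return("")
    codons <- Biostrings::subseq(x, off + 1L, off + (n %/% 3L) * 3L)
    as.character(suppressWarnings(
      Biostrings::translate(codons, if.fuzzy.codon = "X", no.init.codon = TRUE)))
  }
  out <- c(one(s, 0L), one(s, 1L), one(s, 2L), one(rc, 0L), one(rc, 1L), one(rc, 2L))
  stats::setNames(out, c("+1", "+2", "+3", "-1", "-2", "-3"))
}

#' Read a phylogenomic marker set from a directory of alignments
#'
#' One multi-FASTA per marker (extension `.fa`, `.faa` or `.fasta`);
#' all sequences within a marker must share the same aligned length.
#' File base names become marker ids.
#'
#' @param dir Directory path.
#' @return Named list of `AAStringSet`s (class `marker_set`).
#' @export
read_marker_set <- function(dir) {
  files <- sort(list.files(dir, pattern = "\\.(fa|faa|fasta)$", full.names = TRUE))
  if (!length(files)) stop("no marker FASTA files in ", dir)
  ms <- lapply(files, Biostrings::readAAStringSet)
  names(ms) <- sub("\\.(fa|faa|fasta)$", "", basename(files))
  marker_set(ms)
}

#' @rdname read_marker_set
#' @param x Named list of `AAStringSet`s (aligned marker proteins).
#' @export
marker_set <- function(x) {
  if (!length(x) || is.null(names(x))) stop("marker set must be a non-empty named list")
  for (m in names(x)) {
    w <- Biostrings::width(x[[m]])
    if (length(unique(w)) != 1L) stop("unequal aligned lengths in marker ", m)
  }
  structure(x, class = "marker_set")
}

marker_representative <- function(aln) {
  gsub("-", "", as.character(aln[[1]]))
}

#' Translated search of phylogenomic markers in nucleotide scaffolds
#'
#' Each marker's representative (its first aligned sequence, ungapped)
#' is locally aligned (affine gaps, BLOSUM62) against all six reading
#' frames of every scaffold; the best hit per marker is kept and the
#' marker counted recovered when the score reaches `min_score`.
#'
#' @param scaffolds Sequence set.
#' @param markers A [marker_set].
#' @param min_score Score threshold for recovery (substitution-matrix
#'   units; calibrated so planted markers pass and shuffled controls do
#'   not).
#' @param gap_open,gap_extend Affine gap penalties.
#' @return Data frame, one row per marker: `marker_id`, `scaffold_id`,
#'   `frame`, `score`, `aligned_columns`, `recovered`, `peptide` (the
#'   matched scaffold peptide, used for supermatrix placement).
#' @export
search_markers <- function(scaffolds, markers, min_score = 60,
                           gap_open = 11, gap_extend = 1) {
  markers <- marker_set(markers)
  scaffolds <- as_sequence_set(scaffolds)
  if (!length(scaffolds)) stop("no scaffolds to search")
  blosum <- get_blosum62()
  frames <- lapply(names(scaffolds), function(sid) six_frame_translate(scaffolds[[sid]]))
  names(frames) <- names(scaffolds)
  rows <- lapply(names(markers), function(m) {
    rep_seq <- marker_representative(markers[[m]])
    best <- list(score = -Inf, scaffold = NA_character_, frame = NA_character_,
                 cols = 0L, pep = "")
    for (sid in names(frames)) for (fr in names(frames[[sid]])) {
      subj <- frames[[sid]][[fr]]
      if (nchar(subj) < 5L) next
      pa <- Biostrings::pairwiseAlignment(
        Biostrings::AAString(rep_seq), Biostrings::AAString(subj),
        type = "local", substitutionMatrix = blosum,
        gapOpening = gap_open, gapExtension = gap_extend)
      sc <- Biostrings::score(pa)
      if (sc > best$score) {
        pat_str <- as.character(Biostrings::pattern(pa))
        best <- list(score = sc, scaffold = sid, frame = fr,
                     cols = nchar(gsub("-", "", pat_str)),
                     pep = gsub("-", "", as.character(Biostrings::subject(pa))))
      }
    }
    data.frame(marker_id = m, scaffold_id = best$scaffold, frame = best$frame,
               score = best$score, aligned_columns = best$cols,
               recovered = best$score >= min_score, peptide = best$pep,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

get_blosum62 <- function() {
  e <- new.env()
  utils::data("BLOSUM62", package = "Biostrings", envir = e)
  e$BLOSUM62
}

#' Concatenate recovered markers into a supermatrix row
#'
#' Recovered marker peptides are re-aligned to their marker
#' representative and their residues placed onto the marker's alignment
#' columns; unrecovered markers contribute all-gap blocks. Duplicate
#' hits for one marker keep the best score.
#'
#' @param hits Data frame from [search_markers].
#' @param markers The [marker_set] searched.
#' @param taxon_name Row label for the emitted sequence.
#' @return List with `row` (named character: the concatenated aligned
#'   sequence), `ungapped_positions`, `total_columns`,
#'   `recovery_pct`, and `occupancy` (per-marker data frame).
#' @export
build_supermatrix <- function(hits, markers, taxon_name) {
  markers <- marker_set(markers)
  blosum <- get_blosum62()
  hits <- hits[order(-hits$score), , drop = FALSE]
  if (any(duplicated(hits$marker_id))) {
    message("duplicate marker hits; keeping best score")
    hits <- hits[!duplicated(hits$marker_id), , drop = FALSE]
  }
  blocks <- character(0); occ <- NULL
  for (m in names(markers)) {
    aln_len <- Biostrings::width(markers[[m]])[1]
    row <- rep("-", aln_len)
    h <- hits[hits$marker_id == m & hits$recovered, , drop = FALSE]
    if (nrow(h) == 1L && nzchar(h$peptide)) {
      rep_aligned <- strsplit(as.character(markers[[m]][[1]]), "")[[1]]
      col_of <- which(rep_aligned != "-")  # ungapped rep position -> column
      pa <- Biostrings::pairwiseAlignment(
        Biostrings::AAString(h$peptide),
        Biostrings::AAString(marker_representative(markers[[m]])),
        type = "local", substitutionMatrix = blosum,
        gapOpening = 11, gapExtension = 1)
      pat <- strsplit(as.character(Biostrings::pattern(pa)), "")[[1]]
      sub <- strsplit(as.character(Biostrings::subject(pa)), "")[[1]]
      rep_pos <- IRanges::start(Biostrings::subject(pa)) - 1L
      for (i in seq_along(sub)) {
        if (sub[i] != "-") rep_pos <- rep_pos + 1L
        if (sub[i] != "-" && pat[i] != "-" && rep_pos <= length(col_of))
          row[col_of[rep_pos]] <- pat[i]
      }
    }
    blocks <- c(blocks, paste(row, collapse = ""))
    occ <- rbind(occ, data.frame(marker_id = m, aligned_length = aln_len,
                                 ungapped = sum(row != "-"),
                                 recovered = nrow(h) == 1L, stringsAsFactors = FALSE))
  }
  full <- paste(blocks, collapse = "")
  list(row = stats::setNames(full, taxon_name),
       ungapped_positions = sum(strsplit(full, "")[[1]] != "-"),
       total_columns = nchar(full),
       recovery_pct = 100 * sum(occ$recovered) / length(markers),
       occupancy = occ)
}

#' Write supermatrix rows as FASTA
#'
#' @param rows Named character vector (taxon -> aligned sequence).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_supermatrix <- function(rows, path) {
  Biostrings::writeXStringSet(Biostrings::AAStringSet(rows), path)
  invisible(path)
}
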