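#' Read-mapping summary against a reference genome
#'
#' A read counts as mapped if it has at least one alignment record.
#' Breadth and the depth histogram are accumulated over all reference
#' sequences; the genic fraction is the share of covered reference
#' positions lying inside merged gene spans.
#'
#' @param read_alignments An [alignment_records] table of read-to-
#'   reference alignments.
#' @param reference Reference sequence set.
#' @param annotation Reference [gene_annotation] (or `NULL` to skip the
#'   genic fraction).
#' @param n_total_reads Total reads in the library (mapped or not).
#' @return List with `n_reads`, `n_mapped`, `pct_mapped`, `breadth_pct`,
#'   `depth_histogram` (named vector, depth -> positions),
#'   `genic_covered_fraction`, and `covered` (the covered
#'   [interval_set], for reuse downstream).
#' @export
mapping_summary <- function(read_alignments, reference, annotation, n_total_reads) {
  aln <- alignment_records(read_alignments)
  reference <- as_sequence_set(reference)
  unknown <- setdiff(unique(aln$target_id), names(reference))
  if (length(unknown)) stop("alignment to unknown reference id: ",
                            paste(unknown, collapse = ", "))
  n_mapped <- length(unique(aln$query_id))
  if (n_total_reads < n_mapped) stop("n_total_reads < number of mapped reads")
  lens <- seq_lengths(reference)
  hist <- integer(0); covered <- NULL
  for (sid in names(reference)) {
    prof <- depth_from_alignments(aln, sid, lens[[sid]])
    tb <- table(unclass(prof))
    all_d <- union(names(hist), names(tb))
    hist <- stats::setNames(
      ifelse(all_d %in% names(hist), hist[all_d], 0L) +
      ifelse(all_d %in% names(tb), as.integer(tb[all_d]), 0L), all_d)
    hist[is.na(hist)] <- 0L
    covered <- rbind(covered, covered_intervals(prof, 1L))
  }
  covered <- merge_intervals(covered)
  hist <- hist[order(as.integer(names(hist)))]
  cov_len <- interval_length(covered)
  genic <- NA_real_
  if (!is.null(annotation)) {
    spans <- merge_intervals(gene_spans(annotation)[c("seq_id", "start", "end")])
    genic <- if (cov_len > 0)
      interval_length(intersect_intervals(covered, spans)) / cov_len else 0
  }
  list(n_reads = n_total_reads, n_mapped = n_mapped,
       pct_mapped = 100 * n_mapped / n_total_reads,
       breadth_pct = 100 * cov_len / sum(lens),
       depth_histogram = hist, genic_covered_fraction = genic,
       covered = covered)
}

#' Random nested downsampling of a read set
#'
#' Reproduces the downsampling design of saturation analysis: random
#' subsets at increasing fractions. With `nested = TRUE` (default) the
#' subsets form a chain under inclusion, so coverage is monotone in the
#' fraction. Paired reads are kept together when `pair_of` is supplied.
#'
#' @param reads A `DNAStringSet` (or any named vector of reads).
#' @param fractions Fractions in `(0, 1]`.
#' @param seed Integer seed.
#' @param nested Chain subsets under inclusion?
#' @param pair_of Optional vector (same length as `reads`) giving a pair
#'   key per read; pairs are sampled as units.
#' @return Named list, one read subset per fraction (names are the
#'   fractions).
#' @export
downsample_reads <- function(reads, fractions = c(0.1, 0.3, 0.5, 0.8, 1.0),
                             seed = 1L, nested = TRUE, pair_of = NULL) {
  if (!length(reads)) stop("no reads to downsample")
  if (any(fractions <= 0 | fractions > 1)) stop("fractions must be in (0,1]")
  fractions <- sort(fractions)
  units <- if (is.null(pair_of)) seq_along(reads) else pair_of
  keys <- unique(units)
  with_seed(seed, {
    out <- list()
    perm <- sample(keys)
    for (f in fractions) {
      take <- if (nested) perm[seq_len(round(f * length(keys)))]
              else sample(keys, round(f * length(keys)))
      out[[as.character(f)]] <- reads[units %in% take]
    }
    out
  })
}

#' Assembly-length saturation curve over read subsets
#'
#' For each subset the assembler is invoked and the total length of
#' contigs of at least `min_contig` bases recorded. The curve is flagged
#' saturated when the relative length gain between the two largest
#' fractions falls below `threshold`.
#'
#' @param subsets Named list of read subsets (names are fractions), as
#'   returned by [downsample_reads]; at least 3 fractions including the
#'   maximum.
#' @param assemble Function taking one read subset and returning a
#'   `DNAStringSet` of contigs (e.g. a closure over
#'   [perfect_assembler]).
#' @param min_contig Minimum contig length counted.
#' @param threshold Relative-gain cutoff for saturation.
#' @return List with `points` (data frame `fraction`, `n_reads`,
#'   `assembly_length`) and `saturated`.
#' @export
saturation_curve <- function(subsets, assemble, min_contig = 500L, threshold = 0.05) {
  f <- as.numeric(names(subsets))
  if (length(f) < 3L) stop("need at least 3 fractions")
  ord <- order(f); f <- f[ord]; subsets <- subsets[ord]
  lens <- vapply(subsets, function(rd) {
    contigs <- assemble(rd)
    w <- Biostrings::width(contigs)
    sum(w[w >= min_contig])
  }, 0)
  k <- length(f)
  gain <- if (lens[k - 1] > 0) (lens[k] - lens[k - 1]) / lens[k - 1] else Inf
  list(points = data.frame(fraction = f, n_reads = vapply(subsets, length, 0L),
                           assembly_length = unname(lens)),
       saturated = is.finite(gain) && gain < threshold)
}
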