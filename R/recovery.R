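#' Scaffold-to-reference recovery metrics
#'
#' Scaffolds shorter than `min_scaffold` are excluded from both the
#' numerator and the denominator. Reports the fraction of assembly bases
#' in at least one alignment, the reference breadth, and the genic share
#' of aligned reference positions.
#'
#' @param scaffold_alignments [alignment_records] of assembly scaffolds
#'   (query) against the reference (target).
#' @param assembly,reference Sequence sets named consistently with the
#'   alignments.
#' @param annotation Reference [gene_annotation] (or `NULL`).
#' @param min_scaffold Scaffold length filter in bases.
#' @return List with `pct_assembly_aligned`, `reference_breadth_pct`,
#'   `genic_share_pct`, `covered` (reference [interval_set]),
#'   `assembly_aligned` ([interval_set] on assembly coordinates), and
#'   `n_scaffolds_used`.
#' @export
assembly_vs_reference <- function(scaffold_alignments, assembly, reference,
                                  annotation = NULL, min_scaffold = 500L) {
  aln <- alignment_records(scaffold_alignments)
  assembly <- as_sequence_set(assembly); reference <- as_sequence_set(reference)
  bad_q <- setdiff(unique(aln$query_id), names(assembly))
  bad_t <- setdiff(unique(aln$target_id), names(reference))
  if (length(bad_q) || length(bad_t))
    stop("alignment names absent from assemblies: ",
         paste(c(bad_q, bad_t), collapse = ", "))
  lens <- seq_lengths(assembly)
  keep <- names(lens)[lens >= min_scaffold]
  aln <- aln[aln$query_id %in% keep, , drop = FALSE]
  covered <- merge_intervals(data.frame(seq_id = aln$target_id,
                                        start = aln$t_start, end = aln$t_end))
  qcov <- merge_intervals(data.frame(seq_id = aln$query_id,
                                     start = aln$q_start, end = aln$q_end))
  ref_len <- sum(seq_lengths(reference))
  asm_len <- sum(lens[keep])
  genic <- NA_real_
  cov_len <- interval_length(covered)
  if (!is.null(annotation) && cov_len > 0) {
    spans <- merge_intervals(gene_spans(annotation)[c("seq_id", "start", "end")])
    genic <- 100 * interval_length(intersect_intervals(covered, spans)) / cov_len
  }
  list(pct_assembly_aligned = if (asm_len > 0) 100 * interval_length(qcov) / asm_len else NA_real_,
       reference_breadth_pct = 100 * cov_len / ref_len,
       genic_share_pct = genic, covered = covered, assembly_aligned = qcov,
       n_scaffolds_used = length(keep))
}

#' Gene completeness at recovery thresholds
#'
#' For each gene, the fraction of its CDS length covered by the aligned
#' reference intervals; `counts_at[t]` is the number of genes with
#' fraction `>= t`. Counts are monotone decreasing in the threshold.
#'
#' @param covered Reference [interval_set] of aligned positions.
#' @param annotation Reference [gene_annotation].
#' @param thresholds Completeness cutoffs in `(0,1]`, descending.
#' @param mode `"cds"` measures the CDS union (default), `"span"` the
#'   whole gene span.
#' @return List with `fractions` (named per-gene vector) and `counts_at`
#'   (named by threshold).
#' @export
gene_completeness <- function(covered, annotation, thresholds = c(0.9, 0.5, 0.2),
                              mode = c("cds", "span")) {
  mode <- match.arg(mode)
  if (any(thresholds <= 0 | thresholds > 1)) stop("thresholds must be in (0,1]")
  thresholds <- sort(thresholds, decreasing = TRUE)
  covered <- merge_intervals(covered)
  ann <- gene_annotation(annotation)
  iv <- if (mode == "cds") ann else {
    sp <- gene_spans(ann); sp$strand <- "+"; sp
  }
  lens <- tapply(iv$end - iv$start, iv$gene_id, sum)
  if (any(lens <= 0)) stop("gene with zero CDS length")
  frac <- vapply(names(lens), function(g) {
    d <- iv[iv$gene_id == g, ]
    gi <- merge_intervals(data.frame(seq_id = d$seq_id, start = d$start, end = d$end))
    interval_length(intersect_intervals(covered, gi)) / lens[[g]]
  }, 0)
  counts <- vapply(thresholds, function(t) sum(frac >= t), 0L)
  list(fractions = frac,
       counts_at = stats::setNames(counts, format(thresholds)))
}

#' Positions shared between individual SAGs and a pooled assembly
#'
#' @param individual_covered List of reference [interval_set]s, one per
#'   individual SAG.
#' @param pooled_covered Reference [interval_set] of the pooled
#'   co-assembly.
#' @return List with `union_length`, `shared_fraction` (share of the
#'   individual union also covered by the pooling), and
#'   `pooled_exclusive_length`.
#' @export
shared_positions <- function(individual_covered, pooled_covered) {
  if (!length(individual_covered)) stop("need at least one individual set")
  u <- merge_intervals(do.call(rbind, lapply(individual_covered, merge_intervals)))
  if (!nrow(u)) stop("empty union of individual sets")
  pooled <- merge_intervals(pooled_covered)
  inter <- interval_length(intersect_intervals(u, pooled))
  list(union_length = interval_length(u),
       shared_fraction = inter / interval_length(u),
       pooled_exclusive_length = interval_length(pooled) - inter)
}

#' Detect segmental inversions from discordant-strand alignments
#'
#' Per scaffold, alignment blocks of at least `min_block` bases are
#' merged by strand; scaffolds aligning to both strands of the same
#' reference sequence yield calls. For each pair of adjacent
#' discordant-strand blocks the breakpoint is the reference interval
#' strictly between their projections, and the affected genes are those
#' whose span overlaps it.
#'
#' @param scaffold_alignments [alignment_records] with strand flags.
#' @param annotation Reference [gene_annotation] (or `NULL`).
#' @param min_block Minimum block length in bases.
#' @return Data frame `scaffold_id`, `seq_id`, `bp_start`, `bp_end`,
#'   `plus_block`, `minus_block`, `affected_gene_ids` (comma-joined);
#'   zero rows when no inversion is found.
#' @export
detect_inversions <- function(scaffold_alignments, annotation = NULL, min_block = 1000L) {
  aln <- alignment_records(scaffold_alignments)
  spans <- if (!is.null(annotation)) gene_spans(annotation) else NULL
  calls <- NULL
  for (sc in unique(aln$query_id)) {
    a <- aln[aln$query_id == sc, , drop = FALSE]
    for (tid in unique(a$target_id)) {
      at <- a[a$target_id == tid, , drop = FALSE]
      blocks <- NULL
      for (st in c("+", "-")) {
        as_ <- at[at$strand == st, , drop = FALSE]
        if (!nrow(as_)) next
        m <- merge_intervals(data.frame(seq_id = tid, start = as_$t_start, end = as_$t_end))
        m <- m[m$end - m$start >= min_block, , drop = FALSE]
        if (nrow(m)) blocks <- rbind(blocks, data.frame(m, strand = st))
      }
      if (is.null(blocks) || length(unique(blocks$strand)) < 2L) next
      blocks <- blocks[order(blocks$start), ]
      for (i in seq_len(nrow(blocks) - 1L)) {
        b1 <- blocks[i, ]; b2 <- blocks[i + 1L, ]
        if (b1$strand == b2$strand) next
        bp_start <- b1$end; bp_end <- max(b2$start, b1$end)
        genes <- ""
        if (!is.null(spans) && bp_end > bp_start) {
          hit <- spans$seq_id == tid & spans$start < bp_end & spans$end > bp_start
          genes <- paste(spans$gene_id[hit], collapse = ",")
        }
        calls <- rbind(calls, data.frame(
          scaffold_id = sc, seq_id = tid, bp_start = bp_start, bp_end = bp_end,
          plus_block = sprintf("%d-%d", as.integer(if (b1$strand == "+") b1$start else b2$start),
                               as.integer(if (b1$strand == "+") b1$end else b2$end)),
          minus_block = sprintf("%d-%d", as.integer(if (b1$strand == "-") b1$start else b2$start),
                                as.integer(if (b1$strand == "-") b1$end else b2$end)),
          affected_gene_ids = genes, stringsAsFactors = FALSE))
      }
    }
  }
  if (is.null(calls))
    calls <- data.frame(scaffold_id = character(), seq_id = character(),
                        bp_start = numeric(), bp_end = numeric(),
                        plus_block = character(), minus_block = character(),
                        affected_gene_ids = character(), stringsAsFactors = FALSE)
  calls
}
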