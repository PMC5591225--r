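#' Average nucleotide identity from local alignments
#'
#' Implements the BLAST-style ANI procedure: discard alignments below
#' `min_identity` percent or above `max_evalue`; independently in each
#' coordinate system, merge overlapping/touching alignment intervals,
#' assign each merged interval the mean identity of its constituent
#' records, and take the length-weighted average over merged intervals.
#' Records lacking e-values (e.g. from [align_collinear]) pass the
#' e-value filter with a notice.
#'
#' @param alignments [alignment_records] between query and target.
#' @param query_genome,target_genome Optional sequence sets, used to
#'   report aligned fractions.
#' @param min_identity Identity floor in percent.
#' @param max_evalue E-value ceiling.
#' @param within_merge `"unweighted"` (default) averages constituent
#'   identities equally inside a merged interval; `"length"` weights
#'   them by record length.
#' @return List of class `ani_result`: `ani_query_pct`,
#'   `ani_target_pct`, `aligned_length_query`, `aligned_length_target`,
#'   `aligned_fraction_query`, `aligned_fraction_target`,
#'   `n_alignments_used`.
#' @export
compute_ani <- function(alignments, query_genome = NULL, target_genome = NULL,
                        min_identity = 70, max_evalue = 1e-5,
                        within_merge = c("unweighted", "length")) {
  within_merge <- match.arg(within_merge)
  aln <- alignment_records(alignments)
  if (all(is.na(aln$e_value)) && nrow(aln))
    message("alignments carry no e-values; e-value filter skipped")
  keep <- aln$identity_pct >= min_identity &
    (is.na(aln$e_value) | aln$e_value <= max_evalue)
  aln <- aln[keep, , drop = FALSE]
  if (!nrow(aln)) stop("ANI undefined: no alignments survive the filters")
  side <- function(ids, ss, se) {
    tot_len <- 0; tot_wid <- 0
    for (sid in unique(ids)) {
      i <- ids == sid
      o <- order(ss[i])
      s <- ss[i][o]; e <- se[i][o]; idp <- aln$identity_pct[i][o]
      len <- e - s
      grp <- cumsum(c(TRUE, s[-1] > cummax(e)[-length(e)]))
      for (g in unique(grp)) {
        m <- grp == g
        mlen <- max(e[m]) - min(s[m])
        mid <- if (within_merge == "unweighted") mean(idp[m])
               else sum(idp[m] * len[m]) / sum(len[m])
        tot_len <- tot_len + mlen
        tot_wid <- tot_wid + mlen * mid
      }
    }
    c(ani = tot_wid / tot_len, len = tot_len)
  }
  q <- side(aln$query_id, aln$q_start, aln$q_end)
  t <- side(aln$target_id, aln$t_start, aln$t_end)
  frac <- function(len, genome) if (is.null(genome)) NA_real_ else
    unname(len) / sum(seq_lengths(as_sequence_set(genome)))
  structure(list(
    ani_query_pct = unname(q["ani"]), ani_target_pct = unname(t["ani"]),
    aligned_length_query = unname(q["len"]), aligned_length_target = unname(t["len"]),
    aligned_fraction_query = frac(q["len"], query_genome),
    aligned_fraction_target = frac(t["len"], target_genome),
    n_alignments_used = nrow(aln)), class = "ani_result")
}

#' Pairwise ANI matrix over a set of genomes
#'
#' All unordered pairs are aligned with `aligner` and scored with
#' [compute_ani]; the headline matrix holds the conservative
#' `min(query-side, target-side)` ANI. Pairs whose ANI is undefined
#' leave `NA` cells.
#'
#' @param genomes Named list of sequence sets (`>= 2`).
#' @param aligner Function `(query, target) -> alignment_records`;
#'   defaults to the internal collinear aligner.
#' @param ... Passed to [compute_ani].
#' @return List with `matrix` (symmetric, 100 on the diagonal) and
#'   `pairs` (named list of `ani_result`s, names `"a|b"`).
#' @export
ani_matrix <- function(genomes, aligner = align_collinear, ...) {
  if (length(genomes) < 2L) stop("need at least 2 genomes")
  nm <- names(genomes)
  if (is.null(nm)) stop("genomes must be named")
  m <- matrix(NA_real_, length(nm), length(nm), dimnames = list(nm, nm))
  diag(m) <- 100
  pairs <- list()
  for (i in seq_along(nm)) for (j in seq_along(nm)) {
    if (j <= i) next
    res <- tryCatch({
      aln <- aligner(genomes[[i]], genomes[[j]])
      compute_ani(aln, genomes[[i]], genomes[[j]], ...)
    }, error = function(e) NULL)
    if (!is.null(res)) {
      m[i, j] <- m[j, i] <- min(res$ani_query_pct, res$ani_target_pct)
      pairs[[paste(nm[i], nm[j], sep = "|")]] <- res
    }
  }
  list(matrix = m, pairs = pairs)
}
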