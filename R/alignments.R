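#' Alignment record tables
#'
#' Local alignments are held as a data frame with columns `query_id`,
#' `q_start`, `q_end`, `target_id`, `t_start`, `t_end` (0-based half-open
#' on the forward strand of both sequences), `strand` (`+`/`-`),
#' `identity_pct`, `aligned_length`, `e_value`, `score` (the last two may
#' be `NA`). Minus-strand records keep forward-strand coordinates with
#' the strand flag retained.
#'
#' @param df Data frame with the columns above.
#' @return Validated data frame with class `alignment_records`.
#' @export
alignment_records <- function(df) {
  need <- c("query_id", "q_start", "q_end", "target_id", "t_start", "t_end",
            "strand", "identity_pct", "aligned_length")
  if (!all(need %in% names(df))) stop("alignments need columns: ", paste(need, collapse = ", "))
  df <- as.data.frame(df)
  if (is.null(df$e_value)) df$e_value <- NA_real_
  if (is.null(df$score)) df$score <- NA_real_
  df <- df[c(need, "e_value", "score")]
  num <- c("q_start", "q_end", "t_start", "t_end", "identity_pct",
           "aligned_length", "e_value", "score")
  for (cn in num) df[[cn]] <- as.numeric(df[[cn]])
  if (any(df$q_start >= df$q_end) || any(df$t_start >= df$t_end))
    stop("alignment with start >= end")
  if (any(df$q_start < 0) || any(df$t_start < 0)) stop("negative alignment coordinates")
  if (any(df$aligned_length < 1)) stop("aligned_length must be >= 1")
  if (any(df$identity_pct < 0 | df$identity_pct > 100))
    stop("identity_pct outside [0,100]")
  if (!all(df$strand %in% c("+", "-"))) stop("strand must be '+' or '-'")
  rownames(df) <- NULL
  class(df) <- c("alignment_records", "data.frame")
  df
}

#' Read local alignments (PAF or 12-column BLAST-style tabular)
#'
#' `tab12` columns are qid, tid, identity%, aln_len, mismatches,
#' gapopens, qstart, qend, tstart, tend, evalue, bitscore with 1-based
#' inclusive coordinates; rows with `tstart > tend` are normalized to
#' forward-strand coordinates with `strand = "-"`. PAF coordinates are
#' already 0-based half-open; identity is computed as
#' `100 * matches / alignment_block_length`.
#'
#' @param path Input file.
#' @param dialect `"paf"` or `"tab12"`.
#' @return An [alignment_records] data frame.
#' @export
read_alignments <- function(path, dialect = c("paf", "tab12")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (!length(lines))
    return(alignment_records(data.frame(query_id = character(), q_start = numeric(),
      q_end = numeric(), target_id = character(), t_start = numeric(),
      t_end = numeric(), strand = character(), identity_pct = numeric(),
      aligned_length = numeric())[0, ]))
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nmin <- if (dialect == "paf") 12L else 12L
  nc <- lengths(fields)
  bad <- which(if (dialect == "paf") nc < nmin else nc != nmin)
  if (length(bad))
    stop(sprintf("line %d: expected %s%d columns, found %d", bad[1],
                 if (dialect == "paf") ">= " else "", nmin, nc[bad[1]]))
  rows <- lapply(seq_along(fields), function(i) {
    f <- fields[[i]]
    if (dialect == "paf") {
      matches <- as.numeric(f[10]); block <- as.numeric(f[11])
      data.frame(query_id = f[1], q_start = as.numeric(f[3]), q_end = as.numeric(f[4]),
                 target_id = f[6], t_start = as.numeric(f[8]), t_end = as.numeric(f[9]),
                 strand = f[5], identity_pct = 100 * matches / block,
                 aligned_length = block, e_value = NA_real_, score = NA_real_,
                 stringsAsFactors = FALSE)
    } else {
      qs <- as.numeric(f[7]); qe <- as.numeric(f[8])
      ts <- as.numeric(f[9]); te <- as.numeric(f[10])
      strand <- "+"
      if (ts > te) { tmp <- ts; ts <- te; te <- tmp; strand <- "-" }
      if (qs > qe) { tmp <- qs; qs <- qe; qe <- tmp; strand <- if (strand == "-") "+" else "-" }
      if (any(c(qs, ts) < 1)) stop(sprintf("line %d: non-positive 1-based coordinate", i))
      data.frame(query_id = f[1], q_start = qs - 1, q_end = qe,
                 target_id = f[2], t_start = ts - 1, t_end = te,
                 strand = strand, identity_pct = as.numeric(f[3]),
                 aligned_length = as.numeric(f[4]), e_value = as.numeric(f[11]),
                 score = as.numeric(f[12]), stringsAsFactors = FALSE)
    }
  })
  alignment_records(do.call(rbind, rows))
}

#' Write alignment records as 12-column tabular
#'
#' Inverse of `read_alignments(dialect = "tab12")`: coordinates go back
#' to 1-based inclusive, minus-strand records get swapped target
#' coordinates. Mismatch and gap-open columns are written as 0.
#'
#' @param aln An [alignment_records] data frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_alignments <- function(aln, path) {
  aln <- alignment_records(aln)
  ts <- aln$t_start + 1; te <- aln$t_end
  minus <- aln$strand == "-"
  tmp <- ts[minus]; ts[minus] <- te[minus]; te[minus] <- tmp
  lines <- sprintf("%s\t%s\t%s\t%d\t0\t0\t%d\t%d\t%d\t%d\t%s\t%s",
                   aln$query_id, aln$target_id, format_float(aln$identity_pct),
                   as.integer(aln$aligned_length),
                   as.integer(aln$q_start + 1), as.integer(aln$q_end),
                   as.integer(ts), as.integer(te),
                   ifelse(is.na(aln$e_value), "0", formatC(aln$e_value, format = "g")),
                   ifelse(is.na(aln$score), "0", formatC(aln$score, format = "g")))
  writeLines(lines, path)
  invisible(path)
}

#' Windowed collinear alignment of two genomes
#'
#' A deliberately simple internal aligner for genomes that are collinear
#' apart from substitutions and segmental inversions (the situation the
#' strain simulator produces). Each fixed-size window of the shared
#' coordinate space is compared base-by-base; maximal runs of windows
#' below the identity floor are retried as a reverse-complement local
#' alignment against the same target region, and reported as a single
#' minus-strand record when that rescues them (an in-place inversion).
#' Real assemblies should be aligned with an external aligner and
#' imported as PAF/tab12.
#'
#' @param query,target Sequence sets sharing sequence ids.
#' @param window Window size in bases.
#' @param min_identity Identity floor (percent) below which a window is
#'   not reported.
#' @return An [alignment_records] data frame (no e-values/scores).
#' @export
align_collinear <- function(query, target, window = 1000L, min_identity = 70) {
  query <- as_sequence_set(query); target <- as_sequence_set(target)
  shared <- intersect(names(query), names(target))
  if (!length(shared)) stop("no shared sequence ids to align")
  out <- list()
  emit <- function(sid, qs, qe, ts, te, strand, id) {
    out[[length(out) + 1L]] <<- data.frame(
      query_id = sid, q_start = qs, q_end = qe, target_id = sid,
      t_start = ts, t_end = te, strand = strand, identity_pct = id,
      aligned_length = te - ts, e_value = NA_real_, score = NA_real_,
      stringsAsFactors = FALSE)
  }
  for (sid in shared) {
    qc <- as.character(query[[sid]]); tc <- as.character(target[[sid]])
    q <- charToRaw(qc); t <- charToRaw(tc)
    n <- min(length(q), length(t))
    if (n < 10L) next
    starts <- seq.int(0L, n - 1L, by = window)
    failed <- logical(length(starts))
    for (k in seq_along(starts)) {
      s <- starts[k]; e <- min(s + window, n)
      if (e - s < 10L) { failed[k] <- FALSE; next }
      idf <- 100 * sum(q[(s + 1):e] == t[(s + 1):e]) / (e - s)
      if (idf >= min_identity) emit(sid, s, e, s, e, "+", idf)
      else failed[k] <- TRUE
    }
    # maximal runs of failed windows: retry as an in-place inversion
    r <- rle(failed)
    hi <- cumsum(r$lengths); lo <- hi - r$lengths + 1L
    for (j in which(r$values)) {
      s <- starts[lo[j]]; e <- min(starts[hi[j]] + window, n)
      rc <- Biostrings::reverseComplement(
        Biostrings::DNAString(substr(qc, s + 1L, e)))
      submat <- Biostrings::nucleotideSubstitutionMatrix(match = 2, mismatch = -3)
      pa <- Biostrings::pairwiseAlignment(rc,
              Biostrings::DNAString(substr(tc, s + 1L, e)), type = "local",
              substitutionMatrix = submat, gapOpening = 5, gapExtension = 2)
      idr <- Biostrings::pid(pa, type = "PID1")
      ss <- IRanges::start(Biostrings::subject(pa))
      se <- IRanges::end(Biostrings::subject(pa))
      if (idr < min_identity || se - ss + 1L < min(window, e - s) / 2) next
      ts <- s + ss - 1L
      te <- s + se
      # pattern range in revcomp coordinates maps back to forward query
      rlen <- e - s
      pe <- s + rlen - (IRanges::start(Biostrings::pattern(pa)) - 1L)
      ps <- s + rlen - IRanges::end(Biostrings::pattern(pa))
      emit(sid, ps, pe, ts, te, "-", idr)
    }
  }
  if (!length(out)) stop("no windows reached the identity floor")
  alignment_records(do.call(rbind, out))
}

format_float <- function(x) formatC(x, format = "f", digits = 4)
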