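#' Disjoint interval sets over named sequences
#'
#' An `interval_set` is a data frame (`seq_id`, `start`, `end`; 0-based
#' half-open) kept in canonical form: sorted, and overlapping or touching
#' intervals merged. All interval arithmetic in the package runs on this
#' representation (backed by IRanges).
#'
#' @param df Data frame with columns `seq_id`, `start`, `end`.
#' @return Canonical interval set (class `interval_set`).
#' @export
interval_set <- function(df) merge_intervals(df)

#' Merge intervals into a minimal disjoint cover
#'
#' Touching intervals (`[0,5)`, `[5,9)`) are merged, matching half-open
#' genome-arithmetic semantics.
#'
#' @param df Data frame with `seq_id`, `start`, `end` (each `start < end`).
#' @return An [interval_set].
#' @export
merge_intervals <- function(df) {
  df <- as.data.frame(df)
  if (!nrow(df)) {
    out <- data.frame(seq_id = character(), start = numeric(), end = numeric())
    class(out) <- c("interval_set", "data.frame")
    return(out)
  }
  if (!all(c("seq_id", "start", "end") %in% names(df)))
    stop("intervals need columns seq_id, start, end")
  if (any(df$start >= df$end)) stop("interval with start >= end")
  if (any(df$start < 0)) stop("negative interval coordinate")
  parts <- lapply(split(df, df$seq_id), function(d) {
    r <- IRanges::reduce(IRanges::IRanges(d$start + 1, d$end), min.gapwidth = 1L)
    data.frame(seq_id = d$seq_id[1], start = IRanges::start(r) - 1,
               end = IRanges::end(r), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, parts[order(names(parts))])
  rownames(out) <- NULL
  class(out) <- c("interval_set", "data.frame")
  out
}

#' Total length of an interval set
#' @param x An [interval_set] (or coercible data frame).
#' @return Summed base count.
#' @export
interval_length <- function(x) { x <- merge_intervals(x); sum(x$end - x$start) }

#' Per-base intersection of two interval sets
#' @param a,b Interval sets.
#' @return An [interval_set]; commutative.
#' @export
intersect_intervals <- function(a, b) {
  a <- merge_intervals(a); b <- merge_intervals(b)
  shared <- intersect(unique(a$seq_id), unique(b$seq_id))
  parts <- lapply(shared, function(sid) {
    ra <- with(a[a$seq_id == sid, ], IRanges::IRanges(start + 1, end))
    rb <- with(b[b$seq_id == sid, ], IRanges::IRanges(start + 1, end))
    r <- IRanges::intersect(ra, rb)
    if (!length(r)) return(NULL)
    data.frame(seq_id = sid, start = IRanges::start(r) - 1, end = IRanges::end(r),
               stringsAsFactors = FALSE)
  })
  merge_intervals(do.call(rbind, parts))
}

#' Jaccard statistic of two interval sets
#'
#' `J = |A intersect B| / |A union B|`, ranging 0 (disjoint) to 1
#' (identical).
#'
#' @param a,b Interval sets, not both empty.
#' @return Numeric in `[0,1]`.
#' @export
interval_jaccard <- function(a, b) {
  a <- merge_intervals(a); b <- merge_intervals(b)
  la <- interval_length(a); lb <- interval_length(b)
  if (la + lb == 0) stop("undefined Jaccard: both interval sets empty")
  li <- interval_length(intersect_intervals(a, b))
  li / (la + lb - li)
}

#' Per-position read depth over one reference sequence
#'
#' @param alignments An [alignment_records] table; every record must
#'   target `seq_id` with `t_end <= seq_length`.
#' @param seq_id Target sequence id.
#' @param seq_length Target length in bases.
#' @return A `depth_profile`: integer vector of length `seq_length` with
#'   attributes `seq_id`.
#' @export
depth_from_alignments <- function(alignments, seq_id, seq_length) {
  aln <- alignment_records(alignments)
  aln <- aln[aln$target_id == seq_id, , drop = FALSE]
  if (nrow(aln) && any(aln$t_end > seq_length))
    stop("alignment beyond end of ", seq_id)
  depth_from_intervals(data.frame(start = aln$t_start, end = aln$t_end),
                       seq_id, seq_length)
}

#' Per-position depth from raw intervals
#'
#' Like [depth_from_alignments] but starting from bare `start`/`end`
#' columns (e.g. simulator truth placements) instead of alignment
#' records.
#'
#' @param iv Data frame with `start`, `end` (0-based half-open).
#' @param seq_id Sequence id recorded on the profile.
#' @param seq_length Sequence length in bases.
#' @return A `depth_profile`.
#' @export
depth_from_intervals <- function(iv, seq_id, seq_length) {
  delta <- numeric(seq_length + 1L)
  if (nrow(iv)) {
    if (any(iv$start < 0) || any(iv$end > seq_length)) stop("interval out of range")
    s <- tabulate(iv$start + 1L, nbins = seq_length)
    e <- tabulate(iv$end + 1L, nbins = seq_length + 1L)
    delta <- c(s, 0) - e
  }
  d <- cumsum(delta)[seq_len(seq_length)]
  structure(as.integer(d), seq_id = seq_id, class = "depth_profile")
}

#' Breadth of coverage at a depth cutoff
#'
#' @param profile A `depth_profile`.
#' @param min_depth Integer `>= 1`.
#' @return Fraction of positions with depth `>= min_depth`.
#' @export
breadth <- function(profile, min_depth = 1L) {
  if (min_depth < 1) stop("min_depth must be >= 1")
  mean(unclass(profile) >= min_depth)
}

#' Covered intervals of a depth profile
#'
#' @param profile A `depth_profile`.
#' @param min_depth Depth cutoff.
#' @return An [interval_set] of maximal runs with depth `>= min_depth`.
#' @export
covered_intervals <- function(profile, min_depth = 1L) {
  d <- unclass(profile) >= min_depth
  r <- rle(d)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths
  keep <- r$values
  if (!any(keep)) return(merge_intervals(data.frame()))
  merge_intervals(data.frame(seq_id = attr(profile, "seq_id"),
                             start = starts[keep], end = ends[keep]))
}

#' BED3 import/export and BedGraph export
#'
#' @param path File path.
#' @param x Interval set or depth profile.
#' @return `read_bed3`: an [interval_set]; writers return `path`
#'   invisibly.
#' @export
read_bed3 <- function(path) {
  tb <- utils::read.table(path, sep = "\t", header = FALSE, stringsAsFactors = FALSE)
  merge_intervals(data.frame(seq_id = tb[[1]], start = tb[[2]], end = tb[[3]]))
}

#' @rdname read_bed3
#' @export
write_bed3 <- function(x, path) {
  x <- merge_intervals(x)
  writeLines(sprintf("%s\t%d\t%d", x$seq_id, as.integer(x$start), as.integer(x$end)), path)
  invisible(path)
}

#' @rdname read_bed3
#' @export
write_bedgraph <- function(x, path) {
  stopifnot(inherits(x, "depth_profile"))
  r <- rle(as.integer(unclass(x)))
  ends <- cumsum(r$lengths); starts <- ends - r$lengths
  writeLines(sprintf("%s\t%d\t%d\t%d", attr(x, "seq_id"),
                     as.integer(starts), as.integer(ends), r$values), path)
  invisible(path)
}
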