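#' Gene annotation tables
#'
#' A gene annotation is a data frame with one row per CDS interval and
#' columns `gene_id`, `seq_id`, `strand` (`+`/`-`), `start`, `end`
#' (0-based half-open). Within a gene, intervals are sorted and
#' non-overlapping. `gene_annotation()` validates and normalizes.
#'
#' @param df Data frame with the columns above.
#' @return The validated data frame with class `gene_annotation`.
#' @export
gene_annotation <- function(df) {
  need <- c("gene_id", "seq_id", "strand", "start", "end")
  if (!all(need %in% names(df))) stop("annotation needs columns: ", paste(need, collapse = ", "))
  df <- as.data.frame(df)[need]
  df$start <- as.numeric(df$start); df$end <- as.numeric(df$end)
  if (any(df$end <= df$start)) stop("annotation has end <= start intervals")
  if (any(df$start < 0)) stop("annotation has negative coordinates")
  if (!all(df$strand %in% c("+", "-"))) stop("strand must be '+' or '-'")
  df <- df[order(df$gene_id, df$start), , drop = FALSE]
  for (g in unique(df$gene_id)) {
    iv <- df[df$gene_id == g, ]
    if (length(unique(iv$seq_id)) > 1L) stop("gene on multiple sequences: ", g)
    if (nrow(iv) > 1L && any(iv$start[-1] < iv$end[-nrow(iv)]))
      stop("overlapping CDS intervals within gene: ", g)
  }
  rownames(df) <- NULL
  class(df) <- c("gene_annotation", "data.frame")
  df
}

#' Read a gene annotation (GFF3 or BED12)
#'
#' GFF3 `CDS` features are grouped into genes by following `Parent`
#' chains (CDS -> mRNA -> gene); 1-based closed coordinates are converted
#' to 0-based half-open. For BED12 the blocks are taken as CDS intervals.
#'
#' @param path Input file.
#' @param dialect `"gff3"` or `"bed12"`.
#' @return A [gene_annotation] data frame.
#' @export
read_annotation <- function(path, dialect = c("gff3", "bed12")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file not found: ", path)
  if (dialect == "gff3") read_annotation_gff3(path) else read_annotation_bed12(path)
}

read_annotation_gff3 <- function(path) {
  gr <- rtracklayer::import(path, format = "gff3")
  meta <- as.data.frame(gr)
  id_of <- function(x) ifelse(is.na(x) | x == "", NA_character_, x)
  ids <- id_of(as.character(meta$ID))
  parent <- vapply(meta$Parent, function(p) if (length(p)) as.character(p[[1]]) else NA_character_, "")
  type <- as.character(meta$type)
  # map any feature id to its top-level gene ancestor
  parent_of <- stats::setNames(parent, ids)
  type_of <- stats::setNames(type, ids)
  gene_of <- function(feat_parent) {
    p <- feat_parent
    for (i in 1:10) {
      if (is.na(p)) return(NA_character_)
      if (identical(unname(type_of[p]), "gene")) return(p)
      nxt <- if (p %in% names(parent_of)) unname(parent_of[p]) else NA_character_
      if (is.na(nxt)) return(p)  # topmost known ancestor stands for the gene
      p <- nxt
    }
    p
  }
  is_cds <- type == "CDS"
  if (!any(is_cds)) stop("no CDS features in ", path)
  g <- vapply(parent[is_cds], gene_of, "")
  if (any(is.na(g))) stop("CDS without resolvable gene parent in ", path)
  gene_annotation(data.frame(
    gene_id = g,
    seq_id = as.character(meta$seqnames)[is_cds],
    strand = as.character(meta$strand)[is_cds],
    start = meta$start[is_cds] - 1L,   # 1-based closed -> 0-based half-open
    end = meta$end[is_cds],
    stringsAsFactors = FALSE))
}

read_annotation_bed12 <- function(path) {
  tb <- utils::read.table(path, sep = "\t", header = FALSE, comment.char = "#",
                          stringsAsFactors = FALSE)
  if (ncol(tb) < 12L) stop("BED12 requires 12 columns, found ", ncol(tb))
  rows <- lapply(seq_len(nrow(tb)), function(i) {
    n <- tb[i, 10]
    sizes <- as.numeric(strsplit(as.character(tb[i, 11]), ",")[[1]])[seq_len(n)]
    starts <- as.numeric(strsplit(as.character(tb[i, 12]), ",")[[1]])[seq_len(n)]
    data.frame(gene_id = tb[i, 4], seq_id = tb[i, 1], strand = tb[i, 6],
               start = tb[i, 2] + starts, end = tb[i, 2] + starts + sizes,
               stringsAsFactors = FALSE)
  })
  gene_annotation(do.call(rbind, rows))
}

#' Write a gene annotation as GFF3
#'
#' Emits gene/mRNA/CDS feature triples, converting back to 1-based
#' closed coordinates.
#'
#' @param ann A [gene_annotation].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_annotation <- function(ann, path) {
  ann <- gene_annotation(ann)
  con <- file(path, "w"); on.exit(close(con))
  writeLines("##gff-version 3", con)
  for (g in unique(ann$gene_id)) {
    iv <- ann[ann$gene_id == g, ]
    sp <- c(min(iv$start), max(iv$end))
    line <- function(type, s, e, attrs)
      sprintf("%s\tsagqc\t%s\t%d\t%d\t.\t%s\t.\t%s",
              iv$seq_id[1], type, s + 1L, e, iv$strand[1], attrs)
    writeLines(line("gene", sp[1], sp[2], sprintf("ID=%s", g)), con)
    writeLines(line("mRNA", sp[1], sp[2], sprintf("ID=%s.t1;Parent=%s", g, g)), con)
    for (i in seq_len(nrow(iv)))
      writeLines(line("CDS", iv$start[i], iv$end[i],
                      sprintf("ID=%s.cds;Parent=%s.t1", g, g)), con)
  }
  invisible(path)
}

#' Per-gene spans and CDS interval sets
#'
#' `gene_spans` returns one `[min,max)` interval per gene;
#' `gene_cds_length` the summed CDS length per gene.
#'
#' @param ann A [gene_annotation].
#' @return `gene_spans`: data frame (`gene_id`, `seq_id`, `start`, `end`);
#'   `gene_cds_length`: named numeric vector.
#' @export
gene_spans <- function(ann) {
  ann <- gene_annotation(ann)
  sp <- do.call(rbind, lapply(split(ann, ann$gene_id), function(iv)
    data.frame(gene_id = iv$gene_id[1], seq_id = iv$seq_id[1],
               start = min(iv$start), end = max(iv$end), stringsAsFactors = FALSE)))
  rownames(sp) <- NULL
  sp[order(sp$gene_id), ]
}

#' @rdname gene_spans
#' @export
gene_cds_length <- function(ann) {
  ann <- gene_annotation(ann)
  len <- tapply(ann$end - ann$start, ann$gene_id, sum)
  if (any(len <= 0)) stop("gene with zero CDS length")
  stats::setNames(as.numeric(len), names(len))
}
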