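#' Jaccard overlap between a predicted and a reference annotation
#'
#' Both annotations must live on the same (reference) coordinate
#' system; projecting SAG annotations through scaffold-to-reference
#' alignments is the caller's responsibility. The statistic is computed
#' on merged gene bodies by default.
#'
#' @param predicted,reference [gene_annotation]s on shared coordinates.
#' @param mode `"span"` (merged gene bodies, default) or `"cds"`.
#' @return Jaccard statistic in `[0,1]`.
#' @export
annotation_jaccard <- function(predicted, reference, mode = c("span", "cds")) {
  mode <- match.arg(mode)
  predicted <- gene_annotation(predicted); reference <- gene_annotation(reference)
  if (!nrow(predicted)) stop("empty predicted annotation")
  ivs <- function(ann) {
    d <- if (mode == "span") gene_spans(ann) else ann
    merge_intervals(d[c("seq_id", "start", "end")])
  }
  interval_jaccard(ivs(predicted), ivs(reference))
}

#' Unique reference genes recovered via protein best hits
#'
#' BLASTp-style hits are filtered (`e_value < max_evalue`, identity
#' `> min_identity`); each predicted protein keeps its best surviving
#' hit (highest bit score, ties broken by lower e-value, then
#' lexicographic gene id). Fragmented genes split over several predicted
#' proteins collapse onto one reference gene.
#'
#' @param protein_hits Data frame or TSV path with columns
#'   `protein_id`, `gene_id`, `identity_pct`, `e_value`, `bit_score`.
#' @param max_evalue,min_identity Filter thresholds.
#' @return List with `n_unique`, `genes` (sorted id vector) and
#'   `assignments` (protein -> gene).
#' @export
unique_gene_recovery <- function(protein_hits, max_evalue = 1e-5, min_identity = 90) {
  hits <- read_tsv_table(protein_hits,
                         c("protein_id", "gene_id", "identity_pct", "e_value", "bit_score"))
  for (cn in c("identity_pct", "e_value", "bit_score")) {
    hits[[cn]] <- as.numeric(hits[[cn]])
    if (any(is.na(hits[[cn]])))
      stop("malformed row ", which(is.na(hits[[cn]]))[1], " in protein hits")
  }
  hits <- hits[hits$e_value < max_evalue & hits$identity_pct > min_identity, , drop = FALSE]
  if (!nrow(hits))
    return(list(n_unique = 0L, genes = character(0),
                assignments = stats::setNames(character(0), character(0))))
  hits <- hits[order(hits$protein_id, -hits$bit_score, hits$e_value, hits$gene_id), ]
  best <- hits[!duplicated(hits$protein_id), ]
  genes <- sort(unique(best$gene_id))
  list(n_unique = length(genes), genes = genes,
       assignments = stats::setNames(best$gene_id, best$protein_id))
}

#' Protein-domain set comparison across annotations
#'
#' Computes per-annotation distinct domain sets, counts shared/unique
#' domains versus the reference set, and full Venn region counts over
#' all sets (up to 4).
#'
#' @param domain_tables Named list; each element a data frame/TSV path
#'   with columns `protein_id`, `domain_id`, or simply a character
#'   vector of domain ids.
#' @param reference_name Name of the reference entry in the list.
#' @return List with `sets`, `shared_with_reference`,
#'   `unique_vs_reference` (per set: in set, not in reference),
#'   `pct_reference_domains`, and `venn` (named region counts; names
#'   are `+`/`-` membership patterns in list order).
#' @export
domain_overlap <- function(domain_tables, reference_name) {
  if (!reference_name %in% names(domain_tables))
    stop("unknown reference_name: ", reference_name)
  if (length(domain_tables) > 4L) stop("at most 4 domain sets supported")
  sets <- lapply(domain_tables, function(x) {
    if (is.character(x) && (length(x) > 1L || !file.exists(x))) return(sort(unique(x)))
    sort(unique(read_tsv_table(x, c("protein_id", "domain_id"))$domain_id))
  })
  ref <- sets[[reference_name]]
  others <- setdiff(names(sets), reference_name)
  shared <- vapply(sets[others], function(s) length(intersect(s, ref)), 0L)
  uniq <- vapply(sets[others], function(s) length(setdiff(s, ref)), 0L)
  pct <- 100 * shared / length(ref)
  universe <- sort(unique(unlist(sets)))
  memb <- vapply(sets, function(s) universe %in% s, logical(length(universe)))
  if (length(universe) == 1L) memb <- matrix(memb, nrow = 1L, dimnames = list(NULL, names(sets)))
  pat <- apply(memb, 1L, function(r) paste(ifelse(r, "+", "-"), collapse = ""))
  venn <- table(pat)
  list(sets = sets, shared_with_reference = shared, unique_vs_reference = uniq,
       pct_reference_domains = pct,
       venn = stats::setNames(as.integer(venn), names(venn)))
}
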