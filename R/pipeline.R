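#' Assembly contiguity statistics
#'
#' Computed on scaffolds of at least `min_len` bases. N50 is the length
#' of the scaffold at which the cumulative sorted-descending length
#' first exceeds half the total; L75 the number of scaffolds needed to
#' reach 75% of the total.
#'
#' @param scaffolds Sequence set.
#' @param min_len Length filter in bases.
#' @return List `total_length`, `n_scaffolds`, `N50`, `L75`, `GC`.
#' @export
assembly_stats <- function(scaffolds, min_len = 500L) {
  scaffolds <- as_sequence_set(scaffolds)
  w <- seq_lengths(scaffolds)
  keep <- w >= min_len
  if (!any(keep)) stop("no scaffolds of at least ", min_len, " bases")
  scaffolds <- scaffolds[keep]; w <- sort(w[keep], decreasing = TRUE)
  cs <- cumsum(w)
  total <- cs[length(cs)]
  n50 <- w[which(cs > total / 2)[1]]
  l75 <- which(cs >= 0.75 * total)[1]
  list(total_length = unname(total), n_scaffolds = length(w),
       N50 = unname(n50), L75 = unname(l75), GC = gc_content(scaffolds))
}

#' Run the SAG evaluation pipeline over a configuration
#'
#' Stages run in dependency order; contamination screening precedes all
#' reference-facing metrics, so contaminant-labeled scaffolds are
#' excluded from recovery and ANI. Each enabled stage requires its
#' inputs and fails naming the stage and the missing path. Outputs are
#' written under `config$outdir` (TSV/JSON) when set, and the combined
#' summary is returned.
#'
#' @param config Named list, or path to a YAML file with the same
#'   structure. Recognized fields: `reference`, `annotation` (GFF3),
#'   `scaffolds` (FASTA), `read_alignments` + `read_alignment_dialect`,
#'   `scaffold_alignments` + `scaffold_alignment_dialect`,
#'   `n_total_reads`, `taxonomy_hits` (TSV), `host_rule` (regex),
#'   `marker_dir`, `protein_hits` (TSV), `domain_tables` (named list of
#'   TSVs) + `domain_reference`, `outdir`, `seed`, a `stages` list of
#'   toggles (`screen`, `recover`, `ani`, `read_qc`, `annot_eval`,
#'   `markers`), and a `thresholds` list (`min_scaffold`,
#'   `gene_thresholds`, `ani_min_identity`, `ani_max_evalue`,
#'   `tnf_min_scaffold`, `tnf_window`, `marker_min_score`).
#' @return Named list with one section per stage run, plus
#'   `assembly_stats`, `config_digest` and `seed`.
#' @export
run_pipeline <- function(config) {
  if (is.character(config) && length(config) == 1L) config <- yaml::read_yaml(config)
  stopifnot(is.list(config))
  th <- utils::modifyList(list(
    min_scaffold = 500L, gene_thresholds = c(0.9, 0.5, 0.2),
    ani_min_identity = 70, ani_max_evalue = 1e-5,
    tnf_min_scaffold = 10000L, tnf_window = 5000L,
    marker_min_score = 60, saturation = 0.05), config$thresholds %||% list())
  st <- utils::modifyList(list(read_qc = FALSE, screen = TRUE, recover = TRUE,
                               ani = FALSE, annot_eval = FALSE, markers = FALSE),
                          config$stages %||% list())
  seed <- config$seed %||% 1L
  need <- function(stage, field) {
    p <- config[[field]]
    if (is.null(p)) stop("stage '", stage, "' needs config field '", field, "'")
    if (is.character(p) && length(p) == 1L && !file.exists(p))
      stop("stage '", stage, "': missing input ", p)
    p
  }
  load_seq <- function(x) if (is.character(x) && length(x) == 1L) read_fasta(x) else as_sequence_set(x)
  load_ann <- function(x) if (is.character(x) && length(x) == 1L) read_annotation(x, "gff3") else gene_annotation(x)
  load_aln <- function(x, dialect) if (is.character(x) && length(x) == 1L)
    read_alignments(x, dialect) else alignment_records(x)

  out <- list(seed = seed, config_digest = config_digest(config))
  scaffolds <- load_seq(need("stats", "scaffolds"))
  out$assembly_stats <- assembly_stats(scaffolds, th$min_scaffold)

  reference <- if (!is.null(config$reference)) load_seq(config$reference)
  annotation <- if (!is.null(config$annotation)) load_ann(config$annotation)

  if (isTRUE(st$read_qc)) {
    aln <- load_aln(need("read_qc", "read_alignments"),
                    config$read_alignment_dialect %||% "tab12")
    out$read_qc <- mapping_summary(aln, reference, annotation,
                                   need("read_qc", "n_total_reads"))
    out$read_qc$covered <- NULL
  }

  verdicts <- NULL
  if (isTRUE(st$screen)) {
    tnf <- tnf_profile(scaffolds, th$tnf_min_scaffold, th$tnf_window)
    cl <- if (nrow(tnf$matrix) >= 2L) cluster_tnf(tnf, seed = seed) else NULL
    verdicts <- classify_scaffolds(need("screen", "taxonomy_hits"),
                                   names(scaffolds),
                                   config$host_rule %||% "host",
                                   cl$scaffold_labels)
    out$screen <- list(verdicts = verdicts, tnf_k = cl$k %||% NA_integer_,
                       gc = gc_screen(scaffolds, verdicts))
  }
  host_scaffolds <- if (!is.null(verdicts))
    scaffolds[setdiff(names(scaffolds), verdicts$scaffold_id[verdicts$label == "contaminant"])]
  else scaffolds
  out$contamination_screened <- !is.null(verdicts)

  if (isTRUE(st$recover)) {
    aln <- load_aln(need("recover", "scaffold_alignments"),
                    config$scaffold_alignment_dialect %||% "tab12")
    aln <- aln[aln$query_id %in% names(host_scaffolds), , drop = FALSE]
    rec <- assembly_vs_reference(aln, host_scaffolds, reference, annotation,
                                 th$min_scaffold)
    out$recovery <- rec[c("pct_assembly_aligned", "reference_breadth_pct",
                          "genic_share_pct", "n_scaffolds_used")]
    if (!is.null(annotation)) {
      gcm <- gene_completeness(rec$covered, annotation, th$gene_thresholds)
      out$recovery$gene_counts_at <- gcm$counts_at
    }
    out$recovery$inversions <- detect_inversions(aln, annotation)
  }

  if (isTRUE(st$ani)) {
    aln <- load_aln(need("ani", "scaffold_alignments"),
                    config$scaffold_alignment_dialect %||% "tab12")
    aln <- aln[aln$query_id %in% names(host_scaffolds), , drop = FALSE]
    res <- compute_ani(aln, host_scaffolds, reference,
                       th$ani_min_identity, th$ani_max_evalue)
    out$ani <- unclass(res)
  }

  if (isTRUE(st$annot_eval)) {
    pred <- load_ann(need("annot_eval", "predicted_annotation"))
    out$annot_eval <- list(jaccard = annotation_jaccard(pred, annotation))
    if (!is.null(config$protein_hits))
      out$annot_eval$unique_genes <- unique_gene_recovery(config$protein_hits)$n_unique
    if (!is.null(config$domain_tables))
      out$annot_eval$domains <- domain_overlap(config$domain_tables,
                                               need("annot_eval", "domain_reference"))
  }

  if (isTRUE(st$markers)) {
    ms <- read_marker_set(need("markers", "marker_dir"))
    hits <- search_markers(host_scaffolds, ms, th$marker_min_score)
    sm <- build_supermatrix(hits, ms, config$taxon_name %||% "sag")
    out$markers <- list(n_recovered = sum(hits$recovered),
                        recovery_pct = sm$recovery_pct,
                        ungapped_positions = sm$ungapped_positions,
                        total_columns = sm$total_columns)
  }

  if (!is.null(config$outdir)) {
    dir.create(config$outdir, showWarnings = FALSE, recursive = TRUE)
    if (!is.null(verdicts))
      write_report(verdicts, file.path(config$outdir, "scaffold_verdicts.tsv"), "tsv")
    summary_flat <- jsonlite::toJSON(flatten_summary(out), auto_unbox = TRUE,
                                     digits = NA, pretty = TRUE)
    writeLines(summary_flat, file.path(config$outdir, "summary.json"))
  }
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# order-insensitive digest of the configuration (polynomial rolling hash
# over the canonical JSON serialization); ties outputs to their settings
config_digest <- function(config) {
  config$outdir <- NULL  # destination does not affect results
  js <- jsonlite::toJSON(config[order(names(config))], auto_unbox = TRUE, digits = NA)
  bytes <- utf8ToInt(as.character(js))
  h <- 0
  for (b in bytes) h <- (h * 131 + b) %% 2147483647
  sprintf("%08x", as.integer(h))
}

flatten_summary <- function(x) {
  rapply(x, function(v) if (is.data.frame(v)) NULL else v, how = "replace")
}
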