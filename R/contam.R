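#' Tetranucleotide-frequency profile of assembly scaffolds
#'
#' Non-overlapping windows are taken from position 0 of every scaffold
#' at least `min_scaffold` bases long; the final partial window is
#' discarded and windows with more than 10% `N` are skipped. 4-mer
#' counts are pooled with their reverse complements into the 136
#' canonical classes and normalized to frequencies.
#'
#' @param scaffolds Sequence set.
#' @param min_scaffold Minimum scaffold length contributing windows.
#' @param window Window size in bases (`>= 256`).
#' @return List with `matrix` (rows = windows, 136 columns) and `rows`
#'   (data frame `scaffold_id`, `window_start`).
#' @export
tnf_profile <- function(scaffolds, min_scaffold = 10000L, window = 5000L) {
  if (window < 256) stop("window must be >= 256 for stable 4-mer counts")
  scaffolds <- as_sequence_set(scaffolds)
  canon <- canonical_4mer_classes()
  rows <- NULL; mat <- NULL
  for (sid in names(scaffolds)) {
    s <- scaffolds[[sid]]
    L <- length(s)
    if (L < min_scaffold) next
    n_win <- L %/% window
    for (w in seq_len(n_win)) {
      st <- (w - 1L) * window
      win <- Biostrings::subseq(s, st + 1L, st + window)
      af <- Biostrings::alphabetFrequency(win, baseOnly = TRUE)
      if (af[["other"]] / window > 0.10) next
      cnt <- Biostrings::oligonucleotideFrequency(win, width = 4L)
      pooled <- rowsum(as.numeric(cnt), canon[names(cnt)])
      v <- stats::setNames(numeric(length(unique(canon))), sort(unique(canon)))
      v[rownames(pooled)] <- pooled[, 1]
      if (sum(v) == 0) next
      mat <- rbind(mat, v / sum(v))
      rows <- rbind(rows, data.frame(scaffold_id = sid, window_start = st,
                                     stringsAsFactors = FALSE))
    }
  }
  if (is.null(mat)) mat <- matrix(numeric(0), 0, 136)
  rownames(mat) <- if (!is.null(rows)) sprintf("%s:%d", rows$scaffold_id, rows$window_start)
  list(matrix = mat, rows = rows)
}

canonical_4mer_classes <- function() {
  kmers <- Biostrings::mkAllStrings(c("A", "C", "G", "T"), 4L)
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(kmers)))
  stats::setNames(pmin(kmers, rc), kmers)
}

#' Cluster tetranucleotide profiles into composition bins
#'
#' Rows are projected onto their first 10 principal components and
#' k-means is run for each candidate k under a fixed seed; k is chosen
#' by maximal mean silhouette width, falling back to a single cluster
#' when the best silhouette is below 0.25. A deterministic, dependency-
#' light substitute for self-organizing-map binning.
#'
#' @param tnf Result of [tnf_profile].
#' @param k_candidates Candidate cluster counts.
#' @param seed Integer seed.
#' @return List with `k`, `window_labels` (integer per row),
#'   `scaffold_labels` (majority label per scaffold), `silhouette`.
#' @export
cluster_tnf <- function(tnf, k_candidates = 1:4, seed = 1L) {
  mat <- tnf$matrix; rows <- tnf$rows
  if (nrow(mat) < 2L) {
    lab <- rep(0L, nrow(mat))
    return(list(k = 1L, window_labels = lab,
                scaffold_labels = stats::setNames(rep(0L, length(unique(rows$scaffold_id))),
                                                  unique(rows$scaffold_id)),
                silhouette = NA_real_))
  }
  npc <- min(10L, ncol(mat), nrow(mat) - 1L)
  pcs <- stats::prcomp(mat, center = TRUE, scale. = FALSE)$x[, seq_len(npc), drop = FALSE]
  d <- stats::dist(pcs)
  best <- list(k = 1L, sil = -Inf, labels = rep(1L, nrow(mat)))
  for (k in sort(setdiff(k_candidates, 1L))) {
    if (nrow(mat) < 2L * k) next
    km <- with_seed(seed, stats::kmeans(pcs, centers = k, nstart = 10L, iter.max = 50L))
    sil <- mean(cluster::silhouette(km$cluster, d)[, "sil_width"])
    if (sil > best$sil) best <- list(k = k, sil = sil, labels = km$cluster)
  }
  if (!is.finite(best$sil) || best$sil < 0.25)
    best <- list(k = 1L, sil = best$sil, labels = rep(1L, nrow(mat)))
  maj <- vapply(split(best$labels, rows$scaffold_id), function(l)
    as.integer(names(which.max(table(l)))), 0L)
  list(k = best$k, window_labels = best$labels, scaffold_labels = maj,
       silhouette = if (is.finite(best$sil)) best$sil else NA_real_)
}

#' Classify scaffolds as host or contaminant
#'
#' Taxonomy hits (best BLAST-style hit per scaffold) are filtered at
#' `max_evalue`; the best surviving hit (highest bit score, ties broken
#' by lower e-value then lexicographic taxon) decides host vs
#' contaminant via `host_rule`. Scaffolds without usable hits inherit
#' the label of their tetranucleotide cluster when that cluster is
#' anchored by taxonomically labeled scaffolds; otherwise they stay
#' unknown.
#'
#' @param taxonomy_hits Data frame or TSV path with columns
#'   `scaffold_id`, `taxon`, `e_value` and optionally `bit_score`.
#' @param scaffold_ids All scaffold ids under classification.
#' @param host_rule Predicate on the taxon string: a function, or a
#'   regular expression matched case-insensitively.
#' @param tnf_clusters Optional `scaffold_labels` from [cluster_tnf].
#' @param max_evalue E-value cutoff.
#' @return Data frame `scaffold_id`, `label` (host/contaminant/unknown),
#'   `evidence` (comma-joined sources, empty for unknown).
#' @export
classify_scaffolds <- function(taxonomy_hits, scaffold_ids, host_rule,
                               tnf_clusters = NULL, max_evalue = 1e-5) {
  hits <- read_tsv_table(taxonomy_hits, c("scaffold_id", "taxon", "e_value"))
  if (is.null(hits$bit_score)) hits$bit_score <- NA_real_
  hits$e_value <- as.numeric(hits$e_value)
  hits$bit_score <- as.numeric(hits$bit_score)
  is_host <- if (is.function(host_rule)) host_rule else
    function(tx) grepl(host_rule, tx, ignore.case = TRUE)
  hits <- hits[hits$e_value < max_evalue, , drop = FALSE]
  tax_label <- character(0)
  if (nrow(hits)) {
    hits <- hits[order(hits$scaffold_id, -ifelse(is.na(hits$bit_score), -Inf, hits$bit_score),
                       hits$e_value, hits$taxon), ]
    best <- hits[!duplicated(hits$scaffold_id), ]
    tax_label <- stats::setNames(
      ifelse(vapply(best$taxon, is_host, TRUE), "host", "contaminant"), best$scaffold_id)
  }
  label <- stats::setNames(rep("unknown", length(scaffold_ids)), scaffold_ids)
  evidence <- stats::setNames(rep("", length(scaffold_ids)), scaffold_ids)
  known <- intersect(names(tax_label), scaffold_ids)
  label[known] <- tax_label[known]; evidence[known] <- "taxonomy"
  if (!is.null(tnf_clusters)) {
    # anchor each cluster by the majority taxonomy label of its members
    cl <- tnf_clusters[names(tnf_clusters) %in% scaffold_ids]
    for (k in unique(cl)) {
      members <- names(cl)[cl == k]
      anchored <- label[members][evidence[members] == "taxonomy"]
      if (!length(anchored)) next
      maj <- names(which.max(table(anchored)))
      fill <- members[label[members] == "unknown"]
      label[fill] <- maj; evidence[fill] <- "tnf"
    }
  }
  data.frame(scaffold_id = scaffold_ids, label = unname(label[scaffold_ids]),
             evidence = unname(evidence[scaffold_ids]), stringsAsFactors = FALSE)
}

#' GC screen of an assembly before/after contaminant removal
#'
#' Reports length-weighted GC of the whole assembly and of the scaffolds
#' not labeled contaminant, plus a bimodality flag from a two-component
#' Gaussian mixture over per-window GC of the retained scaffolds
#' (bimodal when component means differ by more than `delta` and both
#' weights exceed `min_weight`).
#'
#' @param scaffolds Sequence set.
#' @param verdicts Optional classification from [classify_scaffolds];
#'   contaminant-labeled scaffolds are dropped from the host-side
#'   numbers.
#' @param window Window size for per-window GC.
#' @param delta,min_weight Bimodality thresholds (configurable).
#' @return List `gc_all`, `gc_host_only`, `bimodal_flag`, `component_means`.
#' @export
gc_screen <- function(scaffolds, verdicts = NULL, window = 5000L,
                      delta = 0.05, min_weight = 0.10) {
  scaffolds <- as_sequence_set(scaffolds)
  if (!length(scaffolds)) stop("no scaffolds")
  keep <- names(scaffolds)
  if (!is.null(verdicts))
    keep <- setdiff(keep, verdicts$scaffold_id[verdicts$label == "contaminant"])
  host <- scaffolds[keep]
  gw <- unlist(lapply(names(host), function(sid) {
    L <- length(host[[sid]])
    st <- seq.int(0L, max(L - 1L, 0L), by = window)
    en <- pmin(st + window, L)
    ok <- en - st >= 200L
    vapply(which(ok), function(i)
      gc_content(stats::setNames(as.character(Biostrings::subseq(host[[sid]], st[i] + 1L, en[i])), "w")),
      0)
  }))
  bimodal <- FALSE; means <- NA_real_
  if (length(gw) >= 10L && stats::sd(gw) > 0) {
    fit <- tryCatch(
      suppressWarnings(mclust::Mclust(gw, G = 2, modelNames = "V", verbose = FALSE)),
      error = function(e) NULL)
    if (!is.null(fit)) {
      means <- as.numeric(fit$parameters$mean)
      wts <- as.numeric(fit$parameters$pro)
      bimodal <- abs(diff(means)) > delta && min(wts) > min_weight
    }
  }
  list(gc_all = gc_content(scaffolds),
       gc_host_only = if (length(host)) gc_content(host) else NA_real_,
       bimodal_flag = bimodal, component_means = means)
}

#' 16S rDNA screen with greedy OTU clustering
#'
#' Local alignments of a 16S query against the scaffolds (computed
#' internally, or supplied as imported alignment records) are filtered
#' to hit regions of at least `min_hit_len` bases and `min_identity`;
#' the extracted sequences are sorted longest-first and greedily
#' clustered into OTUs at `otu_threshold` global identity to the
#' centroid.
#'
#' @param scaffolds Sequence set (typically the contaminant scaffolds).
#' @param query_16s 16S rDNA query sequence (character or DNAString).
#' @param min_identity Minimum local identity (fraction).
#' @param otu_threshold OTU membership identity (fraction).
#' @param min_hit_len Minimum hit length in bases.
#' @param alignments Optional [alignment_records] of query-vs-scaffold
#'   hits to use instead of the internal aligner.
#' @param sag_of Optional named vector mapping scaffold id to SAG name.
#' @return Data frame, one row per OTU: `otu_id`, `centroid_id`,
#'   `n_members`, `member_ids` (comma-joined), `sag_ids`, plus attribute
#'   `sequences` (centroid sequences).
#' @export
rdna_screen <- function(scaffolds, query_16s, min_identity = 0.80,
                        otu_threshold = 0.97, min_hit_len = 300L,
                        alignments = NULL, sag_of = NULL) {
  scaffolds <- as_sequence_set(scaffolds)
  q <- Biostrings::DNAString(toupper(as.character(query_16s)))
  if (!length(q)) stop("empty 16S query")
  hits <- list()
  if (is.null(alignments)) {
    submat <- Biostrings::nucleotideSubstitutionMatrix(match = 2, mismatch = -3)
    for (sid in names(scaffolds)) {
      s <- scaffolds[[sid]]
      for (strand in c("+", "-")) {
        subj <- if (strand == "+") s else Biostrings::reverseComplement(s)
        pa <- Biostrings::pairwiseAlignment(q, subj, type = "local",
                substitutionMatrix = submat, gapOpening = 5, gapExtension = 2)
        w <- Biostrings::nchar(pa)
        idf <- Biostrings::pid(pa, type = "PID1") / 100
        if (w >= min_hit_len && idf >= min_identity) {
          r <- Biostrings::subject(pa)
          hits[[length(hits) + 1L]] <- list(
            id = sprintf("%s|%s", sid, strand),
            scaffold_id = sid,
            seq = gsub("-", "", as.character(r)))
        }
      }
    }
  } else {
    aln <- alignment_records(alignments)
    aln <- aln[aln$identity_pct / 100 >= min_identity &
               (aln$t_end - aln$t_start) >= min_hit_len, , drop = FALSE]
    for (i in seq_len(nrow(aln))) {
      sid <- aln$target_id[i]
      if (!sid %in% names(scaffolds)) next
      seg <- as.character(Biostrings::subseq(scaffolds[[sid]], aln$t_start[i] + 1L, aln$t_end[i]))
      if (aln$strand[i] == "-")
        seg <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(seg)))
      hits[[length(hits) + 1L]] <- list(id = sprintf("%s|%d", sid, i),
                                        scaffold_id = sid, seq = seg)
    }
  }
  empty <- data.frame(otu_id = character(), centroid_id = character(),
                      n_members = integer(), member_ids = character(),
                      sag_ids = character(), stringsAsFactors = FALSE)
  if (!length(hits)) return(structure(empty, sequences = character(0)))
  hits <- hits[order(-vapply(hits, function(h) nchar(h$seq), 0L))]
  centroids <- list(); members <- list()
  for (h in hits) {
    placed <- FALSE
    for (k in seq_along(centroids)) {
      pa <- Biostrings::pairwiseAlignment(Biostrings::DNAString(h$seq),
              Biostrings::DNAString(centroids[[k]]$seq), type = "global")
      if (Biostrings::pid(pa, type = "PID1") / 100 >= otu_threshold) {
        members[[k]] <- c(members[[k]], list(h)); placed <- TRUE; break
      }
    }
    if (!placed) {
      centroids[[length(centroids) + 1L]] <- h
      members[[length(members) + 1L]] <- list(h)
    }
  }
  sag_name <- function(sid) if (!is.null(sag_of) && sid %in% names(sag_of))
    sag_of[[sid]] else sid
  out <- do.call(rbind, lapply(seq_along(centroids), function(k) {
    ids <- vapply(members[[k]], `[[`, "", "id")
    sids <- vapply(members[[k]], `[[`, "", "scaffold_id")
    data.frame(otu_id = sprintf("OTU%02d", k), centroid_id = centroids[[k]]$id,
               n_members = length(ids), member_ids = paste(ids, collapse = ","),
               sag_ids = paste(sort(unique(vapply(sids, sag_name, ""))), collapse = ","),
               stringsAsFactors = FALSE)
  }))
  structure(out, sequences = stats::setNames(
    vapply(centroids, `[[`, "", "seq"),
    vapply(centroids, `[[`, "", "id")))
}

read_tsv_table <- function(x, need) {
  if (is.character(x) && length(x) == 1L && file.exists(x)) {
    x <- tryCatch(utils::read.table(x, sep = "\t", header = TRUE,
                                    stringsAsFactors = FALSE, comment.char = ""),
                  error = function(e) stop("malformed table: ", conditionMessage(e)))
  }
  x <- as.data.frame(x)
  miss <- setdiff(need, names(x))
  if (length(miss)) stop("table missing columns: ", paste(miss, collapse = ", "))
  x
}
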