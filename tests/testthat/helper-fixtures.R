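# Shared fixture builders: everything is generated in code at test time.

rand_dna <- function(n, gc = 0.5) paste(
  sample(c("A", "C", "G", "T"), n, replace = TRUE,
         prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)), collapse = "")

# encode a peptide as DNA using one fixed codon per amino acid
peptide_to_dna <- function(pep) {
  code <- Biostrings::GENETIC_CODE
  pick <- tapply(names(code), code, `[`, 1L)
  paste(pick[strsplit(pep, "")[[1]]], collapse = "")
}

rand_peptide <- function(n) paste(
  sample(setdiff(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]], NULL), n, replace = TRUE),
  collapse = "")

aln_df <- function(query_id, q_start, q_end, target_id, t_start, t_end,
                   strand = "+", identity_pct = 100, aligned_length = NULL,
                   e_value = NA_real_, score = NA_real_) {
  if (is.null(aligned_length)) aligned_length <- t_end - t_start
  alignment_records(data.frame(query_id = query_id, q_start = q_start,
    q_end = q_end, target_id = target_id, t_start = t_start, t_end = t_end,
    strand = strand, identity_pct = identity_pct,
    aligned_length = aligned_length, e_value = e_value, score = score,
    stringsAsFactors = FALSE))
}

blosum62 <- function() sagqc:::get_blosum62()
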