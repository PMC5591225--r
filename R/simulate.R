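#' Configuration for the synthetic SAG simulator
#'
#' Defaults emulate the composition of the study system: a ~0.5 Mb
#' reference slice at 54% GC with 66% of its length coding, 240-base
#' reads (the post-trimming read length of typical MiSeq SAG libraries),
#' and per-window lognormal amplification factors whose shape parameter
#' `sigma` is the single MDA-bias knob (`sigma = 0` means unbiased
#' shotgun coverage; values around 1.5-3.5 reproduce hyper-amplified
#' spikes next to zero-coverage deserts).
#'
#' @param genome_length Reference length in bases.
#' @param gc_content GC fraction of the host genome.
#' @param n_genes Number of genes to place.
#' @param coding_fraction Fraction of the genome covered by gene spans.
#' @param read_length Read length in bases.
#' @param target_depth Total fold-coverage of emitted reads.
#' @param window Amplification window size in bases.
#' @param sigma Lognormal shape of per-window amplification factors.
#' @param contaminant_genomes List of `c(length, gc)` pairs.
#' @param contaminant_read_fraction Fraction of reads drawn from
#'   contaminant genomes, in `[0,1)`.
#' @param chimera_rate Fraction of host reads that are two-locus chimeras.
#' @param subst_rate Strain substitution rate used by [mutate_strain].
#' @param inversions List of `c(start, end)` intervals to invert.
#' @param seed Integer seed; every simulator operation is deterministic
#'   under it.
#' @return A `sim_config` list.
#' @export
sim_config <- function(genome_length = 500000L, gc_content = 0.54,
                       n_genes = 300L, coding_fraction = 0.66,
                       read_length = 240L, target_depth = 20,
                       window = 2000L, sigma = 0,
                       contaminant_genomes = list(),
                       contaminant_read_fraction = 0,
                       chimera_rate = 0, subst_rate = 0,
                       inversions = list(), seed = 1L) {
  cfg <- list(genome_length = as.integer(genome_length), gc_content = gc_content,
              n_genes = as.integer(n_genes), coding_fraction = coding_fraction,
              read_length = as.integer(read_length), target_depth = target_depth,
              window = as.integer(window), sigma = sigma,
              contaminant_genomes = contaminant_genomes,
              contaminant_read_fraction = contaminant_read_fraction,
              chimera_rate = chimera_rate, subst_rate = subst_rate,
              inversions = inversions, seed = as.integer(seed))
  frac_in <- function(x, lo, hi) is.numeric(x) && x >= lo && x <= hi
  stopifnot(frac_in(cfg$gc_content, 0, 1), frac_in(cfg$coding_fraction, 0, 1),
            frac_in(cfg$chimera_rate, 0, 1), cfg$contaminant_read_fraction >= 0,
            cfg$contaminant_read_fraction < 1, cfg$window <= cfg$genome_length)
  if (cfg$sigma < 0) stop("sigma must be >= 0")
  class(cfg) <- "sim_config"
  cfg
}

# run expr under a fixed seed, restoring the caller's RNG state
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (is.null(old)) rm(".Random.seed", envir = globalenv())
          else assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  expr
}

random_dna <- function(n, gc) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE,
               prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
        collapse = "")
}

#' Simulate a reference genome and gene annotation
#'
#' Bases are i.i.d. with `P(G) + P(C) = gc_content`. `n_genes`
#' non-overlapping single-CDS genes are placed so that coding length
#' matches `coding_fraction * genome_length` within 2%.
#'
#' @param config A [sim_config].
#' @return List with `genome` (a `DNAStringSet` with one sequence
#'   `ref_1`) and `annotation` (a [gene_annotation]).
#' @export
simulate_reference <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  with_seed(config$seed, {
    L <- config$genome_length
    genome <- Biostrings::DNAStringSet(stats::setNames(random_dna(L, config$gc_content), "ref_1"))
    target <- round(config$coding_fraction * L)
    n <- config$n_genes
    if (target / n < 300) stop("coding_fraction unachievable: mean gene length < 300")
    w <- stats::rgamma(n, shape = 10)
    len <- pmax(300L, round(w / sum(w) * target))
    # rebalance so total coding length hits the target exactly
    over <- sum(len) - target
    i <- 1L
    while (over != 0L) {
      step <- if (over > 0) -min(over, len[i] - 300L) else -over
      len[i] <- len[i] + step; over <- over + step
      i <- i %% n + 1L
      if (i == 1L && over > 0 && all(len == 300L)) stop("coding_fraction unachievable")
    }
    noncoding <- L - sum(len)
    if (noncoding < 0) stop("coding_fraction unachievable: exceeds genome length")
    g <- stats::rgamma(n + 1L, shape = 2)
    gaps <- floor(g / sum(g) * noncoding)
    gaps[n + 1L] <- noncoding - sum(gaps[seq_len(n)])
    starts <- cumsum(c(0, len[-n])) + cumsum(gaps[seq_len(n)])
    ann <- gene_annotation(data.frame(
      gene_id = sprintf("g%04d", seq_len(n)), seq_id = "ref_1",
      strand = sample(c("+", "-"), n, replace = TRUE),
      start = starts, end = starts + len, stringsAsFactors = FALSE))
    list(genome = genome, annotation = ann)
  })
}

#' Derive a diverged strain by substitution and segmental inversion
#'
#' Each base is substituted to a different base with probability
#' `subst_rate`; afterwards the listed intervals are reverse-
#' complemented. Applied to every sequence in the set (inversions refer
#' to the first sequence).
#'
#' @param genome A sequence set.
#' @param subst_rate Substitution probability in `[0, 0.2)`.
#' @param inversions List of disjoint `c(start, end)` intervals.
#' @param seed Integer seed.
#' @return List with `genome` (mutated set), `mutated_positions`
#'   (0-based, per first sequence ordering) and `inversion_intervals`.
#' @export
mutate_strain <- function(genome, subst_rate = 0.01, inversions = list(), seed = 1L) {
  genome <- as_sequence_set(genome)
  if (subst_rate < 0 || subst_rate >= 0.2) stop("subst_rate must be in [0, 0.2)")
  if (length(inversions) > 1L) {
    iv <- do.call(rbind, inversions)
    iv <- iv[order(iv[, 1]), , drop = FALSE]
    if (any(iv[-1, 1] < iv[-nrow(iv), 2])) stop("overlapping inversions")
  }
  with_seed(seed, {
    bases <- c("A", "C", "G", "T")
    out <- character(length(genome)); muts <- list()
    for (k in seq_along(genome)) {
      s <- strsplit(as.character(genome[[k]]), "")[[1]]
      hit <- which(stats::runif(length(s)) < subst_rate & s %in% bases)
      if (length(hit)) {
        cur <- match(s[hit], bases)
        s[hit] <- bases[(cur - 1L + sample.int(3L, length(hit), replace = TRUE)) %% 4L + 1L]
      }
      muts[[k]] <- hit - 1L
      seqc <- paste(s, collapse = "")
      if (k == 1L) for (ivk in inversions) {
        a <- ivk[1]; b <- ivk[2]
        if (a < 0 || b > nchar(seqc) || a >= b) stop("inversion out of range")
        seg <- substr(seqc, a + 1, b)
        rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(seg)))
        seqc <- paste0(substr(seqc, 1, a), rc, substr(seqc, b + 1, nchar(seqc)))
      }
      out[k] <- seqc
    }
    names(out) <- names(genome)
    list(genome = Biostrings::DNAStringSet(out),
         mutated_positions = muts[[1]], inversion_intervals = inversions)
  })
}

#' Simulate an MDA-biased SAG read set with ground truth
#'
#' The host genome is cut into windows of `config$window` bases; each
#' window gets an amplification factor drawn from LogNormal(0, sigma).
#' Host read start positions are drawn with probability proportional to
#' the factor of the containing window. A `contaminant_read_fraction`
#' share of reads is drawn uniformly from the contaminant genomes, and a
#' `chimera_rate` share of host reads joins two uniformly chosen loci.
#'
#' @param genome Host genome to sample reads from (typically a mutated
#'   strain of the reference).
#' @param config A [sim_config].
#' @return List with `reads` (a `DNAStringSet`), `truth` (data frame
#'   `read_id`, `origin` in host/contaminant_k/chimeric, `seq_id`,
#'   `start`, `end` of the true locus), `window_factors`, and
#'   `contaminants` (the contaminant genomes, named `contam_k`).
#' @export
simulate_mda_reads <- function(genome, config) {
  stopifnot(inherits(config, "sim_config"))
  genome <- as_sequence_set(genome)
  if (config$sigma < 0) stop("sigma must be >= 0")
  host_id <- names(genome)[1]
  gseq <- as.character(genome[[1]])
  L <- nchar(gseq); rl <- config$read_length
  with_seed(config$seed + 1L, {
    n_total <- round(config$target_depth * L / rl)
    n_contam <- round(config$contaminant_read_fraction * n_total)
    n_host <- n_total - n_contam
    win_starts <- seq.int(0L, L - 1L, by = config$window)
    win_len <- pmin(win_starts + config$window, L) - win_starts
    factors <- stats::rlnorm(length(win_starts), 0, config$sigma)
    # windows too short to start a full read get zero sampling mass
    eligible <- pmax(pmin(win_starts + win_len, L - rl + 1L) - win_starts, 0)
    p <- factors * eligible
    widx <- sample.int(length(win_starts), n_host, replace = TRUE, prob = p)
    starts <- win_starts[widx] +
      floor(stats::runif(n_host) * eligible[widx])
    n_chim <- round(config$chimera_rate * n_host)
    is_chim <- seq_len(n_host) <= n_chim  # first block; ids shuffled below anyway
    seqs <- substring(gseq, starts + 1, starts + rl)
    origin <- rep("host", n_host)
    if (n_chim > 0) {
      half <- rl %/% 2L
      a <- floor(stats::runif(n_chim) * (L - half + 1))
      b <- floor(stats::runif(n_chim) * (L - (rl - half) + 1))
      seqs[is_chim] <- paste0(substring(gseq, a + 1, a + half),
                              substring(gseq, b + 1, b + (rl - half)))
      starts[is_chim] <- a
      origin[is_chim] <- "chimeric"
    }
    truth <- data.frame(read_id = character(0), origin = character(0),
                        seq_id = character(0), start = numeric(0), end = numeric(0))
    host_truth <- data.frame(
      read_id = NA_character_, origin = origin, seq_id = host_id,
      start = starts, end = pmin(starts + rl, L), stringsAsFactors = FALSE)
    contams <- list(); contam_truth <- NULL
    if (n_contam > 0) {
      if (!length(config$contaminant_genomes))
        stop("contaminant_read_fraction > 0 but no contaminant genomes configured")
      cl <- vapply(config$contaminant_genomes, `[[`, 0, 1)
      cg <- vapply(config$contaminant_genomes, `[[`, 0, 2)
      cseq <- vapply(seq_along(cl), function(k) random_dna(cl[k], cg[k]), "")
      names(cseq) <- sprintf("contam_%d", seq_along(cl))
      contams <- Biostrings::DNAStringSet(cseq)
      ck <- sample.int(length(cl), n_contam, replace = TRUE, prob = cl)
      cs <- floor(stats::runif(n_contam) * pmax(cl[ck] - rl + 1, 1))
      cread <- substring(cseq[ck], cs + 1, pmin(cs + rl, cl[ck]))
      seqs <- c(seqs, cread)
      contam_truth <- data.frame(
        read_id = NA_character_, origin = sprintf("contaminant_%d", ck),
        seq_id = names(cseq)[ck], start = cs, end = cs + nchar(cread),
        stringsAsFactors = FALSE)
    }
    truth <- rbind(host_truth, contam_truth)
    ord <- sample.int(nrow(truth))  # interleave host and contaminant reads
    seqs <- seqs[ord]; truth <- truth[ord, , drop = FALSE]
    ids <- sprintf("read%06d", seq_len(nrow(truth)))
    truth$read_id <- ids; rownames(truth) <- NULL
    names(seqs) <- ids
    list(reads = Biostrings::DNAStringSet(seqs), truth = truth,
         window_factors = stats::setNames(factors, win_starts),
         contaminants = if (length(contams)) contams else Biostrings::DNAStringSet())
  })
}

#' Idealized assembler over true read placements
#'
#' Stands in for an external single-cell assembler in tests: contigs are
#' the maximal intervals of each source sequence covered at depth
#' `>= min_depth` by non-chimeric reads, with sequence copied from the
#' sampled genome. Contig ids encode their source coordinates
#' (`<seq>:<start>-<end>`).
#'
#' @param truth Truth table from [simulate_mda_reads] (possibly
#'   subsetted, e.g. by [downsample_reads]).
#' @param sources Sequence set of all source genomes (host strain plus
#'   contaminants).
#' @param min_depth Minimum read depth, `>= 1`.
#' @return List with `contigs` (a `DNAStringSet`) and `contig_map`
#'   (data frame `contig_id`, `seq_id`, `start`, `end`, `origin`).
#' @export
perfect_assembler <- function(truth, sources, min_depth = 1L) {
  if (min_depth < 1) stop("min_depth must be >= 1")
  sources <- as_sequence_set(sources)
  placed <- truth[truth$origin != "chimeric", , drop = FALSE]
  out_seq <- character(0); map <- NULL
  for (sid in unique(placed$seq_id)) {
    if (!sid %in% names(sources)) stop("truth references unknown source: ", sid)
    L <- nchar(as.character(sources[[sid]]))
    iv <- placed[placed$seq_id == sid, c("start", "end")]
    prof <- depth_from_intervals(iv, sid, L)
    cov <- covered_intervals(prof, min_depth)
    if (!nrow(cov)) next
    org <- if (startsWith(sid, "contam_")) "contaminant" else "host"
    ids <- sprintf("%s:%d-%d", sid, as.integer(cov$start), as.integer(cov$end))
    out_seq <- c(out_seq, stats::setNames(
      substring(as.character(sources[[sid]]), cov$start + 1, cov$end), ids))
    map <- rbind(map, data.frame(contig_id = ids, seq_id = sid,
                                 start = cov$start, end = cov$end,
                                 origin = org, stringsAsFactors = FALSE))
  }
  list(contigs = if (length(out_seq)) Biostrings::DNAStringSet(out_seq)
                 else Biostrings::DNAStringSet(),
       contig_map = map)
}

#' Alignment records implied by simulator ground truth
#'
#' Converts true host read placements into perfect-identity alignment
#' records on the reference, standing in for an external read mapper.
#' Contaminant and chimeric reads yield no records (they would not map).
#'
#' @param truth Truth table from [simulate_mda_reads].
#' @return An [alignment_records] data frame.
#' @export
truth_alignments <- function(truth) {
  h <- truth[truth$origin == "host", , drop = FALSE]
  alignment_records(data.frame(
    query_id = h$read_id, q_start = 0, q_end = h$end - h$start,
    target_id = h$seq_id, t_start = h$start, t_end = h$end,
    strand = "+", identity_pct = 100, aligned_length = h$end - h$start,
    stringsAsFactors = FALSE))
}
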