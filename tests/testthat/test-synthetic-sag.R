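test_that("simulated references hit their GC and coding-fraction targets", {
  cfg <- sim_config(genome_length = 100000L, n_genes = 80L, gc_content = 1.0, seed = 3L)
  ref <- simulate_reference(cfg)
  expect_true(grepl("^[GC]+$", as.character(ref$genome[[1]])))
  cfg <- sim_config(genome_length = 100000L, n_genes = 80L, gc_content = 0.54, seed = 4L)
  ref <- simulate_reference(cfg)
  expect_equal(gc_content(ref$genome), 0.54, tolerance = 0.01 / 0.54)
  coding <- sum(ref$annotation$end - ref$annotation$start) / 100000
  expect_equal(coding, 0.66, tolerance = 0.02 / 0.66)
  # genes non-overlapping by construction (validated by gene_annotation),
  # spans sorted within the sequence
  sp <- gene_spans(ref$annotation)
  sp <- sp[order(sp$start), ]
  expect_true(all(sp$start[-1] >= sp$end[-nrow(sp)]))
})

test_that("reference simulation is deterministic and rejects infeasible configs", {
  cfg <- sim_config(genome_length = 20000L, n_genes = 30L, seed = 9L)
  a <- simulate_reference(cfg); b <- simulate_reference(cfg)
  expect_identical(as.character(a$genome), as.character(b$genome))
  expect_identical(a$annotation, b$annotation)
  bad <- sim_config(genome_length = 20000L, n_genes = 60L, coding_fraction = 0.66)
  expect_error(simulate_reference(bad), "unachievable")
})

test_that("strain mutation matches its binomial substitution model", {
  ref <- simulate_reference(sim_config(genome_length = 100000L, n_genes = 80L, seed = 5L))
  same <- mutate_strain(ref$genome, 0, seed = 2L)
  expect_identical(as.character(same$genome), as.character(ref$genome))
  r <- 0.01
  mut <- mutate_strain(ref$genome, r, seed = 2L)
  a <- strsplit(as.character(ref$genome[[1]]), "")[[1]]
  b <- strsplit(as.character(mut$genome[[1]]), "")[[1]]
  mm <- mean(a != b)
  expect_equal(mm, r, tolerance = 3 * sqrt(r * (1 - r) / 1e5) / r)
  expect_equal(which(a != b) - 1L, mut$mutated_positions)
})

test_that("inversions reverse-complement the chosen segment", {
  ref <- simulate_reference(sim_config(genome_length = 5000L, n_genes = 8L, seed = 6L))
  mut <- mutate_strain(ref$genome, 0, inversions = list(c(100, 200)), seed = 1L)
  src <- substr(as.character(ref$genome[[1]]), 101, 200)
  got <- substr(as.character(mut$genome[[1]]), 101, 200)
  expect_equal(got, as.character(Biostrings::reverseComplement(Biostrings::DNAString(src))))
  expect_error(mutate_strain(ref$genome, 0, inversions = list(c(100, 200), c(150, 300))),
               "overlapping")
})

test_that("read simulation respects depth, labels, and seed determinism", {
  cfg <- sim_config(genome_length = 50000L, n_genes = 40L, target_depth = 10,
                    sigma = 0, contaminant_genomes = list(c(20000, 0.3)),
                    contaminant_read_fraction = 0.5, seed = 21L)
  ref <- simulate_reference(cfg)
  sim <- simulate_mda_reads(ref$genome, cfg)
  n_expected <- round(10 * 50000 / 240)
  expect_equal(length(sim$reads), n_expected)
  # contaminant share exact by construction
  expect_equal(sum(startsWith(sim$truth$origin, "contaminant")),
               round(0.5 * n_expected))
  expect_true(all(sim$window_factors > 0))
  sim2 <- simulate_mda_reads(ref$genome, cfg)
  expect_identical(as.character(sim$reads), as.character(sim2$reads))
  expect_identical(sim$truth, sim2$truth)
  # total emitted sequence approximately target_depth * genome_length
  expect_equal(sum(Biostrings::width(sim$reads)), 10 * 50000,
               tolerance = 2 * 240 / (10 * 50000))
})

test_that("unbiased coverage reaches the Lander-Waterman breadth", {
  cfg <- sim_config(genome_length = 50000L, n_genes = 40L, target_depth = 20,
                    sigma = 0, seed = 31L)
  ref <- simulate_reference(cfg)
  sim <- simulate_mda_reads(ref$genome, cfg)
  prof <- depth_from_intervals(sim$truth[c("start", "end")], "ref_1", 50000L)
  expected <- 1 - exp(-20 * (1 - (240 - 1) / 50000))
  expect_equal(breadth(prof, 1), expected, tolerance = 0.02 / expected)
})

test_that("amplification bias strictly shrinks breadth at equal depth", {
  worse <- 0L
  for (s in 1:20) {
    cfg0 <- sim_config(genome_length = 30000L, n_genes = 30L, target_depth = 8,
                       sigma = 0, seed = 100L + s)
    cfg3 <- sim_config(genome_length = 30000L, n_genes = 30L, target_depth = 8,
                       sigma = 3, seed = 100L + s)
    ref <- simulate_reference(cfg0)
    b0 <- breadth(depth_from_intervals(
      simulate_mda_reads(ref$genome, cfg0)$truth[c("start", "end")], "ref_1", 30000L), 1)
    b3 <- breadth(depth_from_intervals(
      simulate_mda_reads(ref$genome, cfg3)$truth[c("start", "end")], "ref_1", 30000L), 1)
    if (b3 < b0) worse <- worse + 1L
  }
  expect_gte(worse, 19L)
})

test_that("chimeric reads are junction products and labeled as such", {
  cfg <- sim_config(genome_length = 30000L, n_genes = 30L, target_depth = 5,
                    chimera_rate = 0.2, seed = 41L)
  ref <- simulate_reference(cfg)
  sim <- simulate_mda_reads(ref$genome, cfg)
  n_host <- sum(sim$truth$origin != "chimeric")
  n_chim <- sum(sim$truth$origin == "chimeric")
  expect_equal(n_chim, round(0.2 * (n_host + n_chim)))
  # a chimeric read's first half matches its recorded locus, the whole
  # read is absent from the genome
  ch <- sim$truth[sim$truth$origin == "chimeric", ][1, ]
  rd <- as.character(sim$reads[[ch$read_id]])
  g <- as.character(ref$genome[[1]])
  expect_equal(substr(rd, 1, 120), substr(g, ch$start + 1, ch$start + 120))
})

test_that("the idealized assembler reproduces hand-built contig structures", {
  g <- as_sequence_set(c(ref_1 = rand_dna(1000)))
  tile <- data.frame(read_id = sprintf("r%02d", 1:10), origin = "host",
                     seq_id = "ref_1", start = seq(0, 900, 100), end = seq(100, 1000, 100))
  asm <- perfect_assembler(tile, g, 1)
  expect_equal(length(asm$contigs), 1L)
  expect_equal(Biostrings::width(asm$contigs), 1000L)
  expect_equal(as.character(asm$contigs[[1]]), as.character(g[[1]]))
  gap <- tile[!(tile$start >= 500 & tile$start < 600), ]
  asm2 <- perfect_assembler(gap, g, 1)
  expect_equal(asm2$contig_map$start, c(0, 600))
  expect_equal(asm2$contig_map$end, c(500, 1000))
  # single-covered region excluded at min_depth 2
  dbl <- rbind(tile, tile[tile$start < 500, ])
  asm3 <- perfect_assembler(dbl, g, 2)
  expect_equal(asm3$contig_map$start, 0)
  expect_equal(asm3$contig_map$end, 500)
  expect_error(perfect_assembler(tile, g, 0), "min_depth")
})
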