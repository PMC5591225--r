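test_that("six-frame translation follows the standard code", {
  fr <- six_frame_translate("ATGAAA")
  expect_equal(unname(fr["+1"]), "MK")
  # N-containing codons become X, trailing partial codons drop
  fr2 <- six_frame_translate("ATGANAAA")
  expect_equal(unname(fr2["+1"]), "MX")
  expect_equal(nchar(fr2[["+2"]]), 2L)
  expect_equal(unname(six_frame_translate("AT")), rep("", 6))
})

test_that("reverse complement swaps plus and minus frames", {
  set.seed(53)
  s <- rand_dna(300)
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
  a <- six_frame_translate(s); b <- six_frame_translate(rc)
  expect_equal(unname(a[c("+1", "+2", "+3")]), unname(b[c("-1", "-2", "-3")]))
  expect_equal(unname(a[c("-1", "-2", "-3")]), unname(b[c("+1", "+2", "+3")]))
})

test_that("every frame equals the codon-table oracle", {
  set.seed(59)
  s <- rand_dna(300)
  fr <- six_frame_translate(s)
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
  expect_equal(unname(fr["+1"]), codon_oracle(s))
  expect_equal(unname(fr["+2"]), codon_oracle(substr(s, 2, 300)))
  expect_equal(unname(fr["+3"]), codon_oracle(substr(s, 3, 300)))
  expect_equal(unname(fr["-1"]), codon_oracle(rc))
  expect_equal(unname(fr["-2"]), codon_oracle(substr(rc, 2, 300)))
  expect_equal(unname(fr["-3"]), codon_oracle(substr(rc, 3, 300)))
})

test_that("local protein alignment scores match a brute-force Gotoh oracle", {
  set.seed(61)
  mat <- blosum62()
  for (rep in 1:8) {
    a <- rand_peptide(sample(10:40, 1))
    b <- rand_peptide(sample(10:50, 1))
    pa <- Biostrings::pairwiseAlignment(
      Biostrings::AAString(a), Biostrings::AAString(b), type = "local",
      substitutionMatrix = mat, gapOpening = 11, gapExtension = 1)
    expect_equal(Biostrings::score(pa), sw_score_oracle(a, b, mat), info = rep)
  }
})

test_that("planted markers are recovered in every frame at their self-score", {
  set.seed(67)
  mat <- blosum62()
  pep <- rand_peptide(60)
  self <- sw_score_oracle(pep, pep, mat)
  cds <- peptide_to_dna(pep)
  stopf <- strrep("TAA", 20)  # stop-codon flanks prevent local extension
  ms <- marker_set(list(mk = Biostrings::AAStringSet(c(rep = pep))))
  for (off in 0:2) {
    scaf <- as_sequence_set(c(s = paste0(rand_dna(90), strrep("A", off), stopf, cds, stopf, rand_dna(90))))
    hit <- search_markers(scaf, ms, min_score = 60)
    expect_true(hit$recovered)
    expect_equal(hit$frame, sprintf("+%d", off %% 3 + 1))
    expect_equal(hit$score, self)
    rcs <- as_sequence_set(c(s = as.character(Biostrings::reverseComplement(scaf[[1]]))))
    hit_rc <- search_markers(rcs, ms, min_score = 60)
    expect_true(hit_rc$recovered)
    expect_true(hit_rc$frame %in% c("-1", "-2", "-3"))
    expect_equal(hit_rc$score, self)
  }
})

test_that("shuffled scaffolds do not reach the recovery threshold", {
  set.seed(71)
  pep <- rand_peptide(60)
  ms <- marker_set(list(mk = Biostrings::AAStringSet(c(rep = pep))))
  for (rep in 1:5) {
    scaf <- as_sequence_set(c(s = rand_dna(3000)))
    hit <- search_markers(scaf, ms, min_score = 60)
    expect_false(hit$recovered)
  }
})

test_that("supermatrix accounting is exact on constructed marker sets", {
  pepA <- rand_peptide(100); pepB <- rand_peptide(50)
  ms <- marker_set(list(
    m1 = Biostrings::AAStringSet(c(t1 = pepA)),
    m2 = Biostrings::AAStringSet(c(t1 = pepB))))
  scaf <- as_sequence_set(c(s = paste0(strrep("TAA", 10), peptide_to_dna(pepA),
                                       strrep("TAA", 10))))
  hits <- search_markers(scaf, ms, min_score = 60)
  sm <- build_supermatrix(hits, ms, "sag1")
  expect_equal(sm$total_columns, 150L)
  expect_equal(sm$ungapped_positions, 100L)
  expect_equal(sm$recovery_pct, 50)
  expect_equal(nchar(unname(sm$row)), 150L)
  # the recovered block reproduces the marker, the missing block is gaps
  expect_equal(substr(unname(sm$row), 1, 100), pepA)
  expect_equal(substr(unname(sm$row), 101, 150), strrep("-", 50))
  # no recovery at all gives an all-gap row
  none <- hits; none$recovered <- FALSE
  sm0 <- build_supermatrix(none, ms, "sag1")
  expect_equal(sm0$ungapped_positions, 0L)
  expect_equal(unname(sm0$row), strrep("-", 150))
})

test_that("gapped marker alignments place residues on the right columns", {
  # representative has gaps in its own alignment row
  ms <- marker_set(list(m = Biostrings::AAStringSet(c(t1 = "MK--WVTFISLL"))))
  pep <- "MKWVTFISLL"
  scaf <- as_sequence_set(c(s = paste0(strrep("TAA", 10), peptide_to_dna(pep),
                                       strrep("TAA", 10))))
  hits <- search_markers(scaf, ms, min_score = 20)
  sm <- build_supermatrix(hits, ms, "x")
  expect_equal(unname(sm$row), "MK--WVTFISLL")
  expect_equal(sm$ungapped_positions, 10L)
})

test_that("marker recovery rises with simulated assembly breadth", {
  set.seed(73)
  peps <- lapply(1:8, function(i) rand_peptide(60))
  ms <- marker_set(stats::setNames(lapply(peps, function(p)
    Biostrings::AAStringSet(c(rep = p))), sprintf("m%d", 1:8)))
  # plant markers evenly across a 40 kb genome
  cds <- vapply(peps, peptide_to_dna, "")
  spacer <- function(n) rand_dna(n)
  genome <- paste0(vapply(1:8, function(i)
    paste0(spacer(2000), strrep("TAA", 5), cds[i], strrep("TAA", 5), spacer(2500)), ""),
    collapse = "")
  g <- as_sequence_set(c(ref_1 = genome))
  L <- nchar(genome)
  frac_cov <- function(bre) {
    # contigs tiling the first `bre` fraction of the genome
    asm <- as_sequence_set(c(c1 = substr(genome, 1, round(bre * L))))
    hits <- search_markers(asm, ms, min_score = 60)
    sum(hits$recovered)
  }
  rec <- vapply(c(0.25, 0.5, 1.0), frac_cov, 0L)
  expect_true(all(diff(rec) >= 0))
  expect_gt(rec[3], rec[1])
  expect_equal(rec[3], 8L)
})

test_that("marker sets read from a directory and validate aligned lengths", {
  d <- withr::local_tempdir()
  writeLines(c(">a", "MKWV", ">b", "MRWV"), file.path(d, "m1.fa"))
  writeLines(c(">a", "PQRS"), file.path(d, "m2.fa"))
  ms <- read_marker_set(d)
  expect_equal(names(ms), c("m1", "m2"))
  writeLines(c(">a", "MKWV", ">b", "MRW"), file.path(d, "m3.fa"))
  expect_error(read_marker_set(d), "unequal aligned lengths")
  p <- withr::local_tempfile(fileext = ".fa")
  sm <- write_supermatrix(c(sag1 = "MK--WV"), p)
  back <- Biostrings::readAAStringSet(p)
  expect_equal(as.character(back[["sag1"]]), "MK--WV")
})
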