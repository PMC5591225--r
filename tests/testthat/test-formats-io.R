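test_that("read_fasta normalizes case, wrapping, and header descriptions", {
  p <- withr::local_tempfile(fileext = ".fa")
  writeLines(c(">s1 some description", "ac", "gt", ">s2", "ACGT"), p)
  x <- read_fasta(p)
  expect_equal(names(x), c("s1", "s2"))
  expect_equal(as.character(x[["s1"]]), "ACGT")
  expect_equal(Biostrings::width(x), c(4L, 4L))
})

test_that("read_fasta rejects duplicates, empties and junk; masks ambiguity codes", {
  p <- withr::local_tempfile(fileext = ".fa")
  writeLines(c(">a", "ACGT", ">a", "GGGG"), p)
  expect_error(read_fasta(p), "duplicate.*a")
  writeLines(c(">a", "", ">b", "ACGT"), p)
  expect_error(read_fasta(p), "empty sequence")
  writeLines(c(">a", "AC-T"), p)
  expect_error(read_fasta(p), "non-IUPAC")
  writeLines(c(">a", "ACRT"), p)
  expect_warning(x <- read_fasta(p), "ambiguity")
  expect_equal(as.character(x[["a"]]), "ACNT")
})

test_that("FASTA write/read round-trips 100 random records", {
  set.seed(42)
  seqs <- vapply(1:100, function(i) rand_dna(sample(50:300, 1)), "")
  names(seqs) <- sprintf("rec%03d", 1:100)
  p <- withr::local_tempfile(fileext = ".fa")
  write_fasta(seqs, p)
  back <- read_fasta(p)
  expect_equal(as.character(back), seqs)
})

test_that("GFF3 coordinates convert to 0-based half-open and group by gene", {
  p <- withr::local_tempfile(fileext = ".gff3")
  writeLines(c("##gff-version 3",
    "chr1\tsrc\tgene\t1\t150\t.\t+\t.\tID=gA",
    "chr1\tsrc\tmRNA\t1\t150\t.\t+\t.\tID=gA.t1;Parent=gA",
    "chr1\tsrc\tCDS\t1\t50\t.\t+\t0\tID=c1;Parent=gA.t1",
    "chr1\tsrc\tCDS\t101\t150\t.\t+\t0\tID=c2;Parent=gA.t1",
    "chr1\tsrc\tgene\t201\t300\t.\t-\t.\tID=gB",
    "chr1\tsrc\tmRNA\t201\t300\t.\t-\t.\tID=gB.t1;Parent=gB",
    "chr1\tsrc\tCDS\t201\t300\t.\t-\t0\tID=c3;Parent=gB.t1"), p)
  ann <- read_annotation(p, "gff3")
  a <- ann[ann$gene_id == "gA", ]
  expect_equal(a$start, c(0, 100))
  expect_equal(a$end, c(50, 150))
  sp <- gene_spans(ann)
  expect_equal(sp$start[sp$gene_id == "gA"], 0)
  expect_equal(sp$end[sp$gene_id == "gA"], 150)
  expect_equal(unname(gene_cds_length(ann)[c("gA", "gB")]), c(100, 100))
})

test_that("GFF3 single CDS 101..200 becomes [100,200)", {
  p <- withr::local_tempfile(fileext = ".gff3")
  writeLines(c("##gff-version 3",
    "chr1\tsrc\tgene\t101\t200\t.\t+\t.\tID=g1",
    "chr1\tsrc\tmRNA\t101\t200\t.\t+\t.\tID=t1;Parent=g1",
    "chr1\tsrc\tCDS\t101\t200\t.\t+\t0\tID=c1;Parent=t1"), p)
  ann <- read_annotation(p, "gff3")
  expect_equal(ann$start, 100)
  expect_equal(ann$end, 200)
})

test_that("annotation write/read round-trips a synthetic annotation", {
  set.seed(7)
  ann <- gene_annotation(data.frame(
    gene_id = rep(sprintf("g%02d", 1:10), each = 2),
    seq_id = "chr1", strand = rep(sample(c("+", "-"), 10, TRUE), each = 2),
    start = as.numeric(rbind(seq(0, 9000, 1000), seq(400, 9400, 1000))),
    end = as.numeric(rbind(seq(300, 9300, 1000), seq(800, 9800, 1000)))))
  p <- withr::local_tempfile(fileext = ".gff3")
  write_annotation(ann, p)
  back <- read_annotation(p, "gff3")
  expect_equal(back$gene_id, ann$gene_id)
  expect_equal(back$start, ann$start)
  expect_equal(back$end, ann$end)
  expect_equal(back$strand, ann$strand)
})

test_that("BED12 blocks become CDS intervals", {
  p <- withr::local_tempfile(fileext = ".bed")
  writeLines("chr1\t100\t400\tgX\t0\t+\t100\t400\t0\t2\t50,100\t0,200", p)
  ann <- read_annotation(p, "bed12")
  expect_equal(ann$start, c(100, 300))
  expect_equal(ann$end, c(150, 400))
  expect_equal(ann$gene_id, c("gX", "gX"))
})

test_that("tab12 alignments parse with coordinate and strand normalization", {
  p <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("q\tt\t95.0\t100\t5\t0\t1\t100\t1\t100\t1e-20\t180",
               "q2\tt\t88.0\t100\t2\t1\t1\t100\t200\t101\t1e-10\t90"), p)
  aln <- read_alignments(p, "tab12")
  expect_equal(aln$q_start[1], 0); expect_equal(aln$q_end[1], 100)
  expect_equal(aln$t_start[1], 0); expect_equal(aln$t_end[1], 100)
  expect_equal(aln$strand[1], "+")
  expect_equal(aln$identity_pct[1], 95.0)
  # tstart > tend flips to minus strand with forward coordinates
  expect_equal(aln$t_start[2], 100); expect_equal(aln$t_end[2], 200)
  expect_equal(aln$strand[2], "-")
})

test_that("PAF identity is 100*matches/block and column errors carry line numbers", {
  p <- withr::local_tempfile(fileext = ".paf")
  writeLines("q\t500\t0\t100\t+\tt\t900\t10\t110\t90\t100\t60", p)
  aln <- read_alignments(p, "paf")
  expect_equal(aln$identity_pct, 90.0)
  expect_equal(aln$t_start, 10); expect_equal(aln$t_end, 110)
  writeLines(c("q\tt\t95.0\t100", "x\ty\t90\t50"), p)
  expect_error(read_alignments(p, "tab12"), "line 1")
})

test_that("alignment tables round-trip through tab12", {
  set.seed(11)
  n <- 50
  s <- sample(0:900, n); w <- sample(20:100, n)
  ts <- sample(0:900, n); tw <- sample(20:100, n)
  aln <- aln_df(sprintf("q%02d", 1:n), s, s + w, sprintf("t%02d", 1:n),
                ts, ts + tw, strand = sample(c("+", "-"), n, TRUE),
                identity_pct = round(stats::runif(n, 70, 100), 4),
                aligned_length = tw)
  p <- withr::local_tempfile(fileext = ".tsv")
  write_alignments(aln, p)
  back <- read_alignments(p, "tab12")
  for (cn in c("query_id", "q_start", "q_end", "target_id", "t_start", "t_end",
               "strand", "identity_pct", "aligned_length"))
    expect_equal(back[[cn]], aln[[cn]], info = cn)
})

test_that("write_report is deterministic and JSON round-trips", {
  tb <- data.frame(id = c("b", "a"), value = c(1.23456, 2.5))
  p1 <- withr::local_tempfile(fileext = ".tsv")
  p2 <- withr::local_tempfile(fileext = ".tsv")
  write_report(tb, p1, "tsv"); write_report(tb[2:1, ], p2, "tsv")
  expect_identical(readLines(p1), readLines(p2))
  # header-only TSV for an empty table
  p3 <- withr::local_tempfile(fileext = ".tsv")
  write_report(tb[0, ], p3, "tsv")
  expect_equal(readLines(p3), "id\tvalue")
  pj <- withr::local_tempfile(fileext = ".json")
  write_report(tb, pj, "json")
  back <- read_report_json(pj)
  expect_equal(back$id, c("a", "b"))
  expect_equal(back$value, c(2.5, 1.2346), tolerance = 1e-9)
})
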