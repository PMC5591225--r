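---
title: "Evaluating single-cell amplified genomes against a reference: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Evaluating single-cell amplified genomes against a reference}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sagqc)
```

## The problem

Single-cell genomics recovers genomic DNA from one isolated cell via
whole-genome amplification, almost always multiple displacement
amplification (MDA). MDA's phi29 polymerase amplifies unevenly: a few
genomic windows are amplified thousands-fold while large blocks receive
no product at all, so a library can have very high sequencing depth yet
cover a small fraction of the genome. Amplification also admits
contaminant DNA (free bacterial DNA, engulfed or attached prey
bacteria) and produces chimeric junction molecules. When a conspecific
reference genome exists, every one of these pathologies can be
quantified; `sagqc` implements that evaluation as a set of composable
stages plus a synthetic data generator so each stage is testable at
desk scale.

The stages mirror how a practitioner works through a SAG:

1. **Read metrics** — what fraction of reads maps, how deep, how broad
   (`mapping_summary`), and whether more sequencing would help
   (`downsample_reads`, `saturation_curve`).
2. **Contamination screen** — four independent lines of evidence:
   taxonomy best hits, tetranucleotide-frequency (TNF) composition
   clusters, GC bimodality, and 16S rDNA OTU profiling
   (`classify_scaffolds`, `tnf_profile` + `cluster_tnf`, `gc_screen`,
   `rdna_screen`).
3. **Reference recovery** — scaffold-to-reference alignment breadth,
   gene completeness at 90/50/20% thresholds, pooled-versus-individual
   shared positions, inversion detection (`assembly_vs_reference`,
   `gene_completeness`, `shared_positions`, `detect_inversions`).
4. **ANI** — BLAST-style average nucleotide identity with overlap
   merging, in both coordinate systems (`compute_ani`, `ani_matrix`).
5. **Annotation scoring** — Jaccard overlap with the reference
   annotation, unique-gene recovery through protein best hits,
   protein-domain set algebra (`annotation_jaccard`,
   `unique_gene_recovery`, `domain_overlap`).
6. **Marker recovery** — six-frame translated search of single-copy
   protein domains and supermatrix occupancy accounting
   (`six_frame_translate`, `search_markers`, `build_supermatrix`).

`run_pipeline()` orchestrates stages over a configuration list or YAML
file; contamination screening always precedes the reference-facing
metrics so that contaminant scaffolds are excluded from recovery and
ANI, matching how such studies report GC and completeness "after
removal".

## Coordinate and container conventions

All coordinates are 0-based half-open internally. GFF3 (1-based closed)
and BLAST-style 12-column tabular input (1-based inclusive, minus-strand
rows with swapped target coordinates) are converted once at the I/O
boundary; a single convention eliminates a whole class of off-by-one
errors. Minus-strand alignment records always store forward-strand
intervals with a strand flag, because interval arithmetic needs forward
coordinates while inversion detection needs the flag.

Interval sets are kept canonical (sorted, overlapping *and touching*
intervals merged — half-open semantics, as in standard genome
arithmetic). Depth profiles are dense integer vectors; the references
this package targets are at most tens of megabases and the synthetic
tests use &le; 1 Mb, so a sparse representation is deliberately out of
scope.

## The MDA-bias generator

The generator is first-class code, not a fixture. Its model:

* The host genome is i.i.d. sequence at a configurable GC fraction
  (default 0.54) with `n_genes` non-overlapping single-CDS genes whose
  summed length hits `coding_fraction` (default 0.66) exactly. Those
  defaults reproduce the composition of a choanoflagellate-like genome
  — 54% GC, 66% coding. Genes are single-CDS by design: the generator's
  job is to make coding/non-coding shares and gene-completeness
  accounting exact, while multi-exon parsing is exercised through the
  GFF3/BED12 readers.
* Per-window amplification: the genome is cut into `window`-sized bins
  (default 2 kb) and each bin draws a factor from LogNormal(0, `sigma`).
  Read start positions are sampled proportionally to the factor of the
  containing bin. `sigma` is the single bias knob: 0 recovers uniform
  (Lander–Waterman) coverage, values around 1.5–2.5 give visibly ragged
  coverage, and 5 produces the pathological profile of a
  hyper-amplified SAG — the published trios show bins above 1000x next
  to zero-coverage deserts, and a heavy-tailed lognormal is the
  simplest generator of that shape. The published data show the
  phenomenon but no quantitative bias model, so `sigma` values for the
  MB1/MB2/MB4-like test conditions were calibrated once on simulations
  until the breadth ordering reproduced the observed signature (the
  most-biased SAG maps the most reads but covers the least genome);
  the calibrated triple is sigma = 1.5/5.0/2.5 with contaminant read
  fractions 0.35/0.10/0.84.
* Strain divergence: `mutate_strain` substitutes each base to a
  *different* base with probability `subst_rate` and then
  reverse-complements the listed inversion intervals. Because a
  selected base always changes, the expected mismatch fraction equals
  the rate exactly and ANI on a simulated pair is 100·(1−r) in
  expectation — regenerating the 99%/95% intra-SAG versus SAG-vs-
  reference contrast at r = 0.01 and 0.05.
* Contaminant reads are drawn uniformly from separately simulated
  contaminant genomes (default test condition: 30% GC versus the host's
  54%); chimeras join two uniformly chosen loci. Reads are error-free:
  the package evaluates recovery metrics, not base accuracy, and adding
  a sequencing-error model would only blur the ground truth.

Every operation is deterministic under the config seed, and the
emitted read set carries a per-read origin label, true locus, window
factors, mutated positions and inversion intervals as ground truth.

What the generator does **not** emulate: MDA branch structure and
primer bias, quality scores, indels, repeat content, and real k-mer
composition (simulated genomes are i.i.d., which makes TNF clustering
*easier* than on real DNA). Passing tests therefore demonstrate that
the metrics are computed correctly and that the screens work when
composition signal exists — not that the screens would reach the same
accuracy on arbitrary real contaminants.

`perfect_assembler` converts true read placements into contigs (maximal
regions at depth ≥ `min_depth`). It is an idealized stand-in for an
external single-cell assembler so that downsampling and recovery stages
are testable in isolation; real assemblies come from external tools and
enter through FASTA + PAF/tab12.

## Numerical and procedural choices

* **Saturation rule.** Published downsampling curves are read by eye;
  the package needs a rule, so a curve is "saturated" when the relative
  assembly-length gain between the two largest fractions is below 5%
  (configurable). Contigs under 500 bp are excluded wherever scaffolds
  are measured, the same filter applied to assembly statistics.
* **N50.** `assembly_stats` uses the strict-majority reading: the
  length at which the cumulative descending sum first *exceeds* half
  the total (so lengths 1000/500/500 give N50 = 500). Tools differ on
  the boundary case; this choice is deliberate and documented rather
  than load-bearing.
* **TNF screen.** Windows of 5 kb from scaffolds ≥ 10 kb, 4-mers pooled
  with reverse complements into 136 canonical classes (strand
  invariance of contigs; canonicalization is this package's choice),
  rows normalized to frequencies. Clustering is PCA (10 components) +
  k-means with silhouette model selection over k ∈ {1..4}, falling back
  to one cluster below mean silhouette 0.25. This replaces
  self-organizing-map binning: deterministic, dependency-light, and
  adequate for the 2-cluster host/contaminant structure the screen
  targets. The per-row frequency normalization is simpler than the
  robust mean-variance normalization some SOM workflows use; on
  simulated mixtures the separation is driven by composition distance,
  not normalization detail.
* **GC bimodality.** A 2-component Gaussian mixture over per-window GC;
  bimodal when component means differ by > 0.05 and both weights exceed
  0.10. These thresholds are invented and configurable; they replace an
  external GC-partitioning tool.
* **Taxonomy verdicts.** "First BLAST hit" is interpreted as the
  best-scoring hit after the e-value filter (ties: higher bit score,
  then lower e-value, then lexicographic taxon) for determinism.
  Scaffolds without usable hits inherit the majority taxonomy label of
  their TNF cluster when the cluster has taxonomically anchored
  members; otherwise they stay `unknown`.
* **OTU clustering.** Extracted 16S hit regions (≥ 300 bases, ≥ 80%
  local identity) are sorted longest-first and greedily joined to the
  first centroid at ≥ 97% global identity. The 97% threshold is the
  field's convention; the source studies do not state one.
* **ANI.** Records below 70% identity or above e-value 1e−5 are
  dropped; surviving intervals are merged per coordinate system, each
  merged interval takes the *unweighted* mean identity of its
  constituents (the merge-with-mean semantics of the BEDtools-based
  procedure; a length-weighted variant is available behind
  `within_merge = "length"`), and the ANI is the length-weighted mean
  over merged intervals. Query-side and target-side ANI are both
  reported; the headline pairwise value is their minimum, a
  conservative symmetric choice since the published summaries do not
  state how the two directions were combined. Records without e-values
  (the internal aligner emits none) pass the filter with a notice.
* **Collinear toy aligner.** `align_collinear` compares equal
  coordinates window by window and rescues maximal runs of failed
  windows as reverse-complement local alignments (in-place inversions).
  It is only valid for genomes that are collinear up to substitutions
  and inversions — exactly what the strain simulator emits. Real
  assemblies must be aligned externally (LAST, minimap2, BLASTn) and
  imported as PAF or 12-column tabular; the package does not guess how
  external output was tabularized, it accepts both dialects.
* **Inversion calls.** Strand-discordant adjacent block pairs (blocks
  ≥ 1 kb after per-strand merging, suppressing micro-alignment strand
  noise) produce one call per breakpoint; an inversion flanked by
  forward-strand sequence on both sides yields two calls, one per edge.
  Cross-sequence discordance is not called.
* **Gene completeness** is measured on the CDS union by default (the
  published thresholds refer to coding regions); a gene-span mode is
  available because the original description is ambiguous between the
  two. The annotation Jaccard likewise defaults to merged gene bodies
  with a CDS mode behind a flag.
* **Marker search.** The translated ortholog search is re-implemented
  as six-frame translation plus affine-gap local protein alignment
  (BLOSUM62, gap open 11, extend 1). `min_score = 60` is a calibrated
  stand-in for the unstated recovery criterion of the original
  tBLASTn-based tool: planted 60-residue markers score in the hundreds
  while the best shuffled-control scores stay far below 60 (0/50
  replicates recovered in the test suite). Supermatrix placement
  re-aligns the hit peptide to the marker representative and maps
  residues onto the marker's alignment columns; unrecovered markers
  contribute all-gap blocks.

## Problem sizes in tests

The test suite and the acceptance study run entirely on synthetic data:
reference slices of 20–150 kb, 120 genes, depth 20, read length 240 —
large enough that binomial noise sits well inside the asserted
tolerances (e.g. GC of a 100 kb draw at 0.54 has a standard deviation
of ~0.0016 against a ±0.01 band) and small enough that the whole suite
runs in a few minutes on one core. The oracle tests compare every
interval operation against per-base boolean arrays on 1,000 random
instances, alignment scores against a hand-written Gotoh dynamic
program, translations against a literal codon table, and TNF rows
against a naive sliding-window counter.

## Known limitations

* The contamination screen's TNF stage needs scaffolds ≥ 10 kb; short
  fragmented contaminants are only caught by taxonomy or GC evidence.
* `align_collinear` is not a genome aligner; using it on rearranged or
  indel-rich genome pairs silently under-reports aligned length.
* The pipeline consumes externally produced taxonomy and protein-domain
  tables; it does not run BLAST/Pfam searches itself.
* Simulated genomes are compositionally idealized; screen accuracies
  measured on them are upper bounds.
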