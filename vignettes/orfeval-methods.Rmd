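---
title: "Methods: locus-aware evaluation of prokaryotic CDS predictions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: locus-aware evaluation of prokaryotic CDS predictions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(orfeval)
```

# The comparison model

`orfeval` treats a prokaryotic annotation as a set of CDS intervals with
1-based inclusive coordinates, an explicit strand, and identity given by
the tuple (contig, start, end, strand). Both the reference gene set and
every prediction set are held in this one representation (a sorted,
deduplicated `GRanges`), so the same machinery scores a single tool, a
union of tools, or an annotation against itself.

The unit of evaluation is the *locus*, not the nucleotide. A reference
gene counts as detected only when a prediction on the same strand is in
the same reading frame and covers at least 75% of the gene's
nucleotides. The three gates are deliberately separate:

* **Coverage** is frame-agnostic gene-side overlap,
  `|gene ∩ prediction| / |gene|`, so a 74.99%-covering in-frame
  prediction and a 99%-covering out-of-frame prediction both fail
  detection, but for different, reportable reasons.
* **Frame** is start-coordinate congruence modulo 3 on the shared
  strand: `(start(p) − start(g)) mod 3 = 0`. For codon-multiple
  features this is equivalent to anchoring at the 3′ end. We chose the
  genomic-start anchor because it is the only formulation that is
  strand-symmetric in coordinate space and needs no length assumptions;
  its one visible consequence is that trimming a reverse-strand gene's
  genomic end does not break frame (correct: the 3′-anchored codon grid
  is unchanged).
* **Assignment** is one-to-one: each prediction is credited with at
  most one gene. Small genes encompassed by a larger in-frame
  prediction are technically covered, but the prediction does not
  represent their protein product, so only the minimal-deviation gene
  receives credit. A `one_to_one = FALSE` switch provides the
  permissive alternative for sensitivity analysis.

Assignment is computed gene-centrically: genes are processed in
coordinate order, each proposing to its candidates in preference order
(total deviation `|Δstart| + |Δstop|`, then `|Δstart|`, then leftmost
prediction start, then shortest prediction, then input order). When two
genes want the same prediction, the smaller deviation key wins and the
loser falls back to its next-best candidate; a residual tie is broken in
favour of the gene earlier in coordinate order. This is a deferred-
acceptance scheme, so the result is deterministic and independent of
superficial input ordering.

Signed deviations are reported 5′→3′ in gene orientation with positive
values meaning elongation; on the reverse strand the genomic end plays
the biological start. Deviations divide by 3 into codon units; for
in-frame matches the start deviation is always an exact codon multiple.

# Parameters that matter

| Parameter | Default | Meaning |
|---|---|---|
| `threshold` / `min_coverage` | 0.75 | detection (and intersection) coverage gate, fraction of the gene |
| `short_threshold` | 300 nt | "short CDS" bound, strict `length < 300` |
| `min_overlap` | 1 nt | minimum shared length for two features to count as overlapping |
| `overlap_allowance` (`gff_add`) | 50 nt | maximum tolerated overlap of an added CDS with any existing one |
| `m5_all_genes` | `FALSE` | M5 denominator: detected genes (default) or all genes |
| `m89_side` | `"prediction"` | whether M8/M9 count the property on matched predictions or matched genes |

The short-ORF boundary is read strictly: 300 nt is *not* short. The
overlap definition is any-strand and same-contig, with no minimum beyond
a single shared base, because real bacterial gene overlaps span
everything from 1 nt stop/start sharing to long antisense overlaps.

Undefined quantities (precision with zero predictions, M5 with zero
detections, percentage differences with a zero reference count)
propagate as `NA` and serialize as `"NA"`/`null` — never as 0, which
would silently rank a degenerate run as perfect. In rank tables,
undefined values take the worst rank for that metric.

Metric values are kept at full precision internally; the reporting layer
(TSV/JSON writers, print methods) rounds percentages to two decimals.
`gc_content()` and `gene_density()` are reporting-style statistics and
round at the operation level.

# The twelve primary metrics

M1 (genes detected %) and M11 (recall) coincide under one-to-one
assignment, as do M2 (predictions that detected a gene %) and M10
(precision); both pairs are reported because they answer differently
phrased questions and diverge under the permissive assignment switch.
M10 + M12 = 100 whenever defined. M3/M4/M8/M9 use the percentage
difference `100·(predicted − reference)/reference`, whose ideal value is
0 and which is deliberately signed: over- and under-prediction are
different failure modes. M6/M7 are medians of the *absolute* codon
deviation over matched genes whose start (resp. stop) was mispredicted,
and 0 when no such gene exists; signed medians are available among the
secondary outputs. M5's denominator is the detected genes — the
percentage answers "when the tool finds a gene, how often is the locus
exact?" — with the all-genes variant behind a flag.

M8/M9 compare the number of *matched predictions* that are
overlapping/short with the number of *reference genes* that are. The
property could equally be evaluated on the matched genes; both are
implemented (`m89_side`), prediction-side is the default because the
metric names the predicted CDSs.

Cross-genome ranking totals, per tool, the per-metric ranks over all
(genome, metric) pairs, with average ranks for ties. Orientation is per
metric: higher-better (M1, M2, M5, M10, M11), closer-to-zero-better
(M3, M4, M8, M9), lower-better (M6, M7, M12).

# The synthetic benchmark and its truth ledger

`generate_genome()` draws i.i.d. bases at a target GC; for ≥ 100 kb the
realized GC is within about a percentage point of target (binomial
concentration). `plant_annotation()` writes genes into the sequence with
real start and stop codons, exact short-gene and overlapping-pair
fractions by construction, and a configurable start-codon profile. The
defaults — 10% short genes, 10% of genes in overlapping pairs, start
codons 80/12/8% ATG/GTG/TTG, uniform gene lengths of 300–1500 nt, gene
spacing of 30–150 nt — sit inside the ranges observed across sequenced
bacteria (short-gene proportions of roughly 5–14%, ATG usage of roughly
69–91%, median CDS lengths near 1 kb) and are fixed once here rather
than tuned per experiment. Overlapping pairs are planted convergently
(tail-to-tail on opposite strands, 10–48 nt), the commonest real overlap
geometry and one that keeps both planted start codons intact. Under
translation table 11 internal in-frame stops are scrubbed from
non-overlapping genes so every planted gene is a genuine ORF; under
table 4 the stop set is TAA/TAG and at least one gene carries an
internal in-frame TGA — the tryptophan codon a universal-table caller
mistakes for a stop, producing exactly the 3′-truncation failure mode
seen in *Mycoplasma*.

`perturb()` degrades the gold annotation gene by gene: missed with
probability `p_miss`, frame-broken with probability `p_frameshift`
(a +1/+2 nt shift of the genomic start, the anchor of the frame gate),
otherwise copied with 5′/3′ shifts drawn in codons. Spurious features
are added at `p_spurious` expected features per gene. Two guards make
the ledger exact rather than approximate: truncating shifts are capped
at 24% of the gene length (so an intended partial match can never fall
below the 75% coverage gate), and every shifted or spurious feature is
rejection-sampled against the whole gold set so it cannot satisfy the
detection rule for any gene other than its own. Consequently the
intended category of every gene — and therefore every count-based
metric — is derivable from the ledger alone, and `ledger_metrics()`
does exactly that with independent all-pairs interval arithmetic. The
test suite verifies pipeline/ledger agreement over 50 random
perturbation profiles at 200 genes each.

What the generator does *not* emulate: realistic codon usage and
ribosome-binding motifs, operon structure, genome-scale GC skew,
circular-genome wrap-around, and assembly artefacts (chimeras,
fragmented contigs). Passing the ledger-recovery suite therefore
demonstrates that the scoring machinery is correct, not that any
particular gene caller is good; conclusions about real tools still
require real genomes, read through `read_gff3()`/`read_fasta()`.

# Numerical and degenerate-input choices

* Coordinates are GFF3 1-based inclusive everywhere, including
  internally; no half-open conversion exists to get wrong.
* CDS coordinates are compared verbatim; no stop-codon trimming or
  extension is applied, matching how reference records and tool outputs
  are actually distributed.
* Duplicate features (same identity tuple) collapse to one at
  construction; all operations are invariant under duplication and
  reordering of their inputs.
* `gff_intersect()` keeps the a-side coordinates (the first annotation
  is the frame of reference); `--symmetric` evaluates both directions.
  `gff_add()` caps the overlap per existing feature (stricter than
  footprint-total; `footprint = TRUE` gives the other reading).
* Empty inputs are legal everywhere and produce empty outputs or `NA`
  metrics, never errors; malformed records (start > end, unknown
  strand, non-integer coordinates) fail loudly with line numbers.
* All generators restore the caller's RNG state; a fixed seed gives
  bit-identical genomes, annotations, perturbations and output files.

# Problem sizes in the shipped tests

The test suite and the acceptance script run on synthetic instances
sized for quick iteration: genomes of 50–260 kb, 40–200 planted genes,
50 perturbation profiles for the ledger-recovery sweep, and 1000 random
instances for the classifier-vs-oracle comparison. These sizes were
chosen as the smallest at which the binomial rate checks (3 standard
errors at n = 200) and tie-breaking paths are all exercised; every
routine scales linearly or near-linearly (interval queries use
`findOverlaps`) and handles full bacterial genomes (4–6 Mb, ~4000–5000
CDSs) comfortably.

# Known limitations

* Eukaryote-style multi-exon CDS grouping is out of scope; each GFF3
  `CDS` row is an independent feature.
* Circular genomes: features spanning the origin must be split by the
  caller before import.
* The permissive (`one_to_one = FALSE`) mode reports a prediction's
  matched gene as the first of possibly several; its per-prediction
  table is coarser than the default mode's.
* `read_gff3()` validates only the rows whose type is requested;
  malformed rows of other types are rejected by the underlying parser
  without line numbers.
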