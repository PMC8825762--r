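# orfeval

Benchmarking prokaryotic CDS (coding sequence) prediction against a
reference annotation.

Gene callers such as Prodigal, GeneMark or GLIMMER rarely disagree about
whether "something" is coding in a region — they disagree about *which
locus* is coding: where the start codon is, which frame, which strand,
whether a short or overlapping gene exists at all. Headline accuracy
numbers that only count overlapping intervals hide those differences.
`orfeval` scores a prediction set against a reference annotation with an
explicit, locus-aware detection rule and a panel of twelve complementary
metrics, so the strengths and failure modes of a tool (or a union of
tools) are visible individually.

It is aimed at anyone comparing gene callers on bacterial or archaeal
genomes: tool developers, annotation pipeline maintainers, and groups
re-annotating genomes against an existing (e.g. Ensembl) gene set.

## The detection rule and the metrics

A reference gene *g* is **detected** by a prediction *p* iff

* *p* is on the same contig and strand as *g*,
* *p* is **in frame**: `(start(p) − start(g)) mod 3 = 0`, and
* *p* **covers at least 75%** of *g*'s nucleotides
  (`|g ∩ p| / |g| ≥ 0.75`; the threshold is configurable).

A detected gene is a **perfect match** when the coordinates agree
exactly, otherwise a **partial match** with signed 5′/3′ deviations
(positive = elongation, in gene orientation); all other genes are
**missed**. Each prediction is credited with at most one gene — a long
prediction encompassing several small in-frame genes detects only the
gene it deviates least from (deviation = |Δstart| + |Δstop|, with a fully
deterministic tie chain).

From a comparison the package computes twelve primary metrics: the
percentage of genes detected (M1) and of predictions that detected a
gene (M2); percentage differences of prediction count (M3) and median
length (M4), where `percentage difference = 100·(predicted −
reference)/reference` and 0 is ideal; the percentage of perfect matches
among detected genes (M5); median start/stop deviations of mispredicted
matches in codons (M6/M7); percentage differences of matched overlapping
and short (< 300 nt) CDS counts (M8/M9); and precision, recall and false
discovery rate over whole features (M10–M12). Secondary groups (GC
content and length by match category, codon usage of matched
predictions, encompassed-gene counts) refine the picture, and tools can
be ranked across genomes by totalling their per-metric ranks.

The package also provides prediction-set **aggregation** (deduplicated
union of several tools, evaluated with the same rule, with per-gene
provenance), and two GFF utilities: `gff_intersect()` (keep features of
one annotation supported by another at ≥ 75% coverage in frame) and
`gff_add()` (add new CDSs unless they overlap an existing feature by
more than 50 nt).

Because downloading genomes and running fifteen external tools is not
needed to validate any of this, `orfeval` ships a synthetic benchmark
generator: a random genome, a planted gold annotation (controlled GC,
short-gene and overlapping-gene fractions, start-codon usage,
translation table 11 or 4), and perturbed "tool" outputs with a
machine-readable **truth ledger** whose intended categories the
comparator provably recovers.

## Worked example

```r
library(orfeval)

genome  <- generate_genome(150000, gc = 45, seed = 7)
planted <- plant_annotation(genome, 120, frac_short = 0.1,
                            frac_overlapping = 0.1, seed = 8)
profile <- perturbation_profile(p_miss = 0.1, p_spurious = 0.2,
                                start_shift = c("0" = 0.7, "2" = 0.2, "-2" = 0.1),
                                seed = 9, label = "toy_tool")
sim    <- perturb(planted$annotation, profile, genome = planted$genome)
report <- match_annotations(planted$annotation, sim$predictions)
report
#> Comparison of 130 predictions against 120 reference genes  (coverage threshold 0.75)
#>   perfect 65 | partial 44 | missed 11
compute_primary(report, planted$annotation, sim$predictions)
#> M1   Percentage of Genes Detected                                 90.83
#> M2   Percentage of Predicted CDSs that Detected a Gene            83.85
#> M3   Percentage Difference of Number of Predicted CDSs            8.33
#> M4   Percentage Difference of Median Predicted CDS Length         -13.93
#> M5   Percentage of Perfect Matches                                59.63
#> M6   Median Start Difference of Matched Predicted CDSs            2.00
#> M7   Median Stop Difference of Matched Predicted CDSs             0.00
#> M8   Percentage Difference of Matched Overlapping Predicted CDSs  108.33
#> M9   Percentage Difference of Matched Short Predicted CDSs        -50.00
#> M10  Precision                                                    83.85
#> M11  Recall                                                       90.83
#> M12  False Discovery Rate                                         16.15
```

Reading: the simulated tool found 90.83% of the genes (M1) but only
59.63% of those at the exact locus (M5); the median start misprediction
is 2 codons (M6) while stops are called exactly (M7); one in six of its
calls is spurious (M12). M8/M9 show it over-calls overlapping CDSs and
under-detects short genes — exactly the kind of signal the metric panel
is designed to separate.

Real annotations enter through the standard formats: `read_gff3()` /
`read_fasta()` for the reference and genome, and `read_predictions()`
for tool outputs (GFF3 or a simple contig/start/stop/strand TSV, with a
registry for adding per-tool dialects). A command-line front end is
installed at `inst/scripts/orfeval` with subcommands `compare`,
`aggregate`, `intersect`, `add`, `simulate` and `stats`.

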