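---
title: "Finding phage genomes in bacterial assemblies: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Finding phage genomes in bacterial assemblies: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bapscan)
```

## The problem

Bacterial genome assemblies routinely contain complete phage genomes as
separate contigs: DNA from virions or replicating phage that was present in
the sequenced culture and assembled alongside the host chromosome. bapscan
implements a desk-scale version of a pipeline for recovering and
classifying such contigs: a compositional phage-likeness classifier, a
rule-based classification cascade, sketch-based genome networks, and
normalized phage-to-host abundance ratios, together with a synthetic-genome
generator that provides ground truth for testing all of it.

## Gene features and triplets

Contigs are decomposed into genes by a deliberately naive, deterministic
six-frame ORF scanner: an ORF runs from the first start codon (ATG, GTG or
TTG) after the previous in-frame stop to the next in-frame stop (included),
with a 90 nt minimum, and codons containing N cannot be spanned. The
scanner is a pluggable contract — any external caller returning BED-style
0-based half-open coordinates with a strand column can replace it — but the
bundled one needs no external binaries and behaves identically everywhere.
It makes no attempt to resolve overlapping ORFs across frames; because
training and scoring see genes from the same process, the classifier's two
classes are compared on an equal footing.

Each gene yields a fixed, versioned vector of 93 features (see
`feature_schema()`): gene length, GC fraction, GC skew, the 64 codon
frequencies (over all codons, stop included, so they sum to exactly 1), the
20 amino-acid frequencies, the hydrophobic-residue fraction, strand
agreement with the previous/next gene, intergenic distances (floored at 0
for overlaps, clipped at 5,000 bp), and local gene density in a 10 kb
window. First and last genes take sentinel 0 for neighbour features so
vectors stay fixed-length. Three consecutive genes are concatenated into
one 279-value triplet row, sliding one gene at a time, so a contig with *g*
genes yields max(0, *g* − 2) rows. The triplet is the classifier's unit:
it captures short-range organisational context (strand runs, tight
spacing) that single genes cannot.

A contig with fewer than three genes has no triplets; it is scored 0 and
flagged `too_few_genes` rather than silently dropped, so downstream counts
always partition the input.

## The phage-likeness classifier

`train_phager()` fits a gradient-boosted tree ensemble (xgboost, binary
log-loss) on labelled triplet rows. Positives come from phage genomes;
negatives from bacterial genomes with known prophage intervals excised
(`mask_regions()`) and then cut into fragments whose lengths are resampled
from the positive set's length distribution
(`sample_negative_fragments()`), so the classifier cannot learn "long
means bacterial". Defaults: 500 rounds, depth ≤ 8, learning rate 0.05,
early stopping after 30 stagnant rounds on a seeded 10% validation split,
negatives downsampled to at most 3× the positives, one thread. Single
threading is the default because it makes training bit-reproducible: two
runs with the same seed produce byte-identical model archives. The model
file is a JSON archive carrying the serialized ensemble (base64), the
feature-schema hash, the hyperparameters and the seed; scoring refuses
inputs whose schema hash differs from the model's.

A contig's score is the arithmetic mean of its triplet probabilities — the
simplest order-independent aggregate, monotone in every triplet
probability. The cascade gates contigs at score ≥ 0.8, with "below 0.8"
read strictly.

Evaluation (`evaluate_model()`) reports contig-level AUC using a
rank-based Mann–Whitney statistic with midrank ties (a constant classifier
scores exactly 0.5), plus precision/recall at the 0.8 operating point.

## The classification cascade

`run_cascade()` applies, in order:

1. **Length gate.** Contigs over 1,000,000 bp are taken as bona fide
   bacterial chromosomes; under 5,000 bp they are too short to be complete
   phage genomes. The 5 kb–1 Mb interval is closed at both ends
   ("exceeding" read strictly).
2. **Score gate.** Phage-likeness below 0.8 excludes the contig.
3. **Reference hits.** A top nucleotide-database hit with subject length
   > 1,200,000 bp *and* alignment length > 2,100 bp marks the contig
   bacterial; otherwise any hit description containing "plasmid"
   (case-insensitive) marks it a plasmid; otherwise a phage-database hit,
   or a description containing "phage" but not "prophage", is recorded as
   phage evidence. "prophage" always suppresses the phage keyword for that
   hit. Bacterial > plasmid > phage precedence follows the workflow's
   narrative order.
4. **Lifestyle.** Marker screening flags terminase large subunit (terL),
   integrase, transposase and anti-repressor genes. Any cluster containing
   even one integrase-bearing member is temperate as a whole
   (`propagate_temperate()`); a contig is lytic only if it has terL, none
   of the lysogeny/mobility markers, and a clean cluster; everything else
   phage-like but undetermined. Additional marker classes supplied in the
   reference (e.g. excisionases, recombinases, repressors) are treated as
   lysogeny markers, i.e. they behave like integrase.

Marker screening's dependency-free default compares each predicted protein
to each reference marker by amino-acid 5-mer containment (fraction of the
marker's distinct 5-mers found in the protein) with a floor of 0.5 —
deliberately permissive for near-copies and robust to N/C-terminal
extensions from the naive ORF caller — and a precomputed hit table from an
external HMM search can be supplied instead. The bundled marker FASTA is
synthetic (random sense codons): it exercises the rule machinery without
shipping real gene content, and real marker libraries should be
substituted for real analyses.

Every contig receives exactly one label and the name of the rule that
fired, so label counts always sum to the input size.

## Sketches, networks and clouds

`sketch_genome()` implements bottom-s MinHash: every canonical k-mer
(lexicographic minimum of k-mer and reverse complement; k = 21) is hashed
with a fixed 64-bit mixing function (splitmix64, masked to 53 bits so
values are exact in doubles), and the s = 1000 smallest distinct values are
kept. Jaccard similarity is estimated with the merged-sketch estimator —
among the min(s, |union|) smallest hashes of the two sketches' union, the
fraction present in both — and converted to a Mash distance
d = −(1/k)·ln(2j/(1+j)), clamped to [0, 1] with j = 0 mapped to the cap 1.
These are the same distance semantics as the dedicated sketching tools;
the parameters are declared defaults, not recovered ones.

Networks connect genomes at d ≤ 0.1 (the figure convention); ANI clouds
use single-linkage components at ANI = 1 − d ≥ 0.95; reference matching
reports a loose tier (d ≤ 0.2, "closely associated") and a strict tier
(d ≤ 0.05, "strongly associated"), the strict tier nested in the loose by
construction. Component and cluster ids are the lexicographically smallest
member, making clustering order-independent. Microbiome-style hit
summarization (`nonoverlapping_match_length()`) filters alignments at
≥ 90% identity and ≥ 500 bp and returns the interval-union length, so
repeated matches are not double-counted.

## Abundance ratios

`abundance_table()` pools reads and lengths per role (phage/host) within a
sample — host chromosomes are usually fragmented across contigs, and
per-contig ratios would be noise — and computes reads per kilobase per
million mapped reads, the minimal statistic normalized for both contig
length and library size. The phage:host ratio of these abundances equals
the per-base coverage ratio, so ratio 1 is the temperate baseline of about
one phage genome per host genome; the log10 ratio is reported alongside,
and a host with zero reads yields an explicit `host_not_detected` status
rather than an infinite ratio. Pooling before normalization (rather than
averaging per-contig CPMs) is a documented choice.

## The synthetic-genome generator

The generator emulates exactly the signal the classifier is meant to
exploit, and nothing else. Two composition models differ in GC (0.42
phage-like vs 0.52 host-like), codon usage (a GC-calibrated table times a
fixed-seed log-normal perturbation, spread `codon_jitter` = 0.5 by
default; after perturbation the table is recalibrated so expected GC still
hits the target), gene spacing (mean intergenic gap 40 bp vs 150 bp) and
strand coherence (forward-strand probability 0.95 vs 0.75). Genomes
alternate GC-matched random gaps with genes built as ATG + sampled sense
codons + a random stop; true coordinates are returned for
feature-extraction tests. Gene lengths are log-normal (median 800 nt,
sdlog 0.3) for both classes so length is not a shortcut feature.

What the generator does *not* emulate: real protein families, packaging
signals, repeats, assembly artefacts, or the actual compositional distance
between real phages and their hosts. A high AUC on this synthetic suite
shows the pipeline machinery is sound — features carry class signal,
training and aggregation work, gates behave — not that the bundled model
would reach any particular accuracy on real assemblies; for real use the
classifier must be trained on real phage and prophage-masked bacterial
genomes.

The 12-contig fixture suite (`make_fixture_suite()`) covers every cascade
branch — the length gates, the score gate, the bacterial/plasmid hit
rules, the "prophage" keyword trap, lytic, marker-temperate,
cluster-propagated temperate, transposase-excluded, and a `too_few_genes`
contig built from a motif (TTAA repeats) that places a stop codon in every
reading frame on both strands. Marker profiles in the fixture are computed
by actually calling genes and screening the implanted synthetic markers,
closing the loop from sequence to label.

## Numerical and design choices

* Coordinates are 0-based half-open on the forward strand everywhere
  (BED-style); strand is a separate column.
* The initiator codon is translated as M whatever its identity
  (ATG/GTG/TTG), matching common prokaryotic caller conventions.
* Boundary conventions — 5,000 and 1,000,000 bp inclusive candidates,
  "below 0.8" strict — are encoded in `length_gate()` and `phager_gate()`
  and frozen by tests.
* Jaccard of two identical sub-sized sketches must be 1, so the estimator
  divides by min(s, |union|) rather than s.
* Tests run at deliberately small problem sizes (tens to hundreds of
  genomes of 10–20 kb; the full classifier check trains on 200 + 200
  genomes and evaluates on 50 + 50) — large enough for the statistics
  being asserted, small enough to run comfortably on one CPU.
* Determinism is treated as a feature: every stochastic step takes a seed,
  every generator is byte-reproducible, and training at one thread yields
  identical model bytes across runs. Multi-threaded training is possible
  but documented as potentially non-deterministic.

## Known limitations

* The naive ORF caller over-predicts genes (nested ORFs across frames) and
  misses genes with non-standard starts; it is a testing-grade default,
  not a Prodigal replacement.
* The 93-feature schema is a declared reconstruction of the compositional
  and organisational signals the cited feature-based predictors use, not a
  recovered original.
* Sketch parameters (k = 21, s = 1000) and the marker containment floor
  (0.5) are declared defaults; thresholds from the underlying workflow
  (0.8 score gate, 0.1/0.2/0.05 distances, 90%/500 bp floors) are
  preserved exactly.
* The abundance module assumes exactly two roles per sample and ignores
  ambiguous mappings; read alignment itself is out of scope.
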