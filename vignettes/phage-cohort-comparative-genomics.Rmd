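---
title: "Comparative genomics of phage cohorts with phamnet: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Comparative genomics of phage cohorts with phamnet}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phamnet)
```

`phamnet` organizes an annotated phage cohort the way large
actinobacteriophage collections are organized in practice: proteins are
pooled into phamilies, gene content defines clusters and networks,
nucleotide identity defines subclusters, and conserved intergenic
motifs are discovered per cluster. This vignette records the models,
the parameters that matter, and the design decisions behind the
implementation.

## The genome data model

A `phage_genome` is one DNA sequence over `{A,C,G,T,N}` plus an ordered
gene table. Coordinates are 0-based half-open internally and 1-based
inclusive in every human-facing format (GenBank, GFF3); the conversion
is lossless and tested by write/read round trips. A joined
(multi-interval) CDS is flattened to a single gene spanning its
outermost coordinates — phage genomes are overwhelmingly
single-interval, and for intergenic computation only the covered span
matters. Genome termini classes (circularly permuted, cos-type
extensions, direct terminal repeats) are metadata read from the record,
never inferred: termini determination requires raw sequencing reads,
which are out of scope here.

G+C content is `100·(G+C)/(A+C+G+T)` with ambiguous bases excluded from
both numerator and denominator, rounded half away from zero to one
decimal — the convention used in published genometrics tables, and the
reason `round()`'s half-to-even is not used. Coding density is the
union of gene intervals divided by genome length, so overlapping genes
are not double-counted.

## Phams

All non-tRNA gene products are compared all-vs-all by Smith–Waterman
local alignment (BLOSUM62, gap open 11, extend 1, via
`Biostrings::pairwiseAlignment`). Two proteins are linked when

* percent identity over aligned columns ≥ 32.5, and
* aligned residue pairs cover ≥ 50% of the shorter protein,

and phams are the connected components of the link graph
(single-linkage closure). The published cohort analyses state only that
phams were assorted "using similar metrics" to the Phamerator lineage;
the thresholds above are that lineage's published defaults, made
explicit, configurable, and recorded inside every `pham_set` so a
result always carries the rule that produced it. Identity is
`Biostrings::pid(type = "PID1")` — matches over aligned columns
*including* internal gaps — and coverage is
`(nmatch + nmismatch) / min(nchar)`. One subtlety worth recording: with
identity defined over aligned columns, a pair with *m* true matches can
legitimately score `m/(2m−1)` (just above 50% for a half-substituted
pair), because a maximal local alignment can start and end on matched
columns.

Single linkage is deliberate and matches pham practice; it chains, and
that chaining is biologically meaningful (mosaic relationships), but it
means one promiscuous protein can fuse two otherwise distinct phams.
Pham ids are assigned by the lexicographically smallest member gene id,
making the partition invariant to genome and protein input order.

## Pairwise metrics

**Gene-content similarity** follows the averaged shared-pham formula
(`GCS = 100·½(|A∩B|/|A| + |A∩B|/|B|)`) computed on *distinct* pham
sets, so in-genome paralogs count once. `GCD = 1 − GCS/100` exactly.

**ANI** uses the classic fragment method: the query is cut into
non-overlapping 1,020-bp fragments (a trailing fragment is kept if
≥ 100 bp), each is locally aligned to the subject and its reverse
complement (match +1, mismatch −2, gap 5/2), fragments passing 30%
identity and 70% coverage are retained, and the directional ANI is the
mean identity of retained fragments; the reported value symmetrizes the
two directions. The published cohort's ANI tool ("DNA Master with
default settings") is undocumented, so this package uses the standard
reproducible method and records its parameters in the matrix object;
the comparison surface is cluster-level ANI bands (e.g. 71–99% within a
cos-packaged cluster), not tool-exact values. The symmetrization choice
(directional tables were also plausible) is recorded here once.

**Nucleotide distance** is bottom-sketch MinHash over canonical 21-mers
(sketch size 1,000, 64-bit splitmix hash with an explicit seed,
truncated to 53 bits so hashes survive R doubles), with the Mash
transform `d = −(1/k)·ln(2j/(1+j))`, capped at 1 when no hashes are
shared. With `sketch_size = 0` the full k-mer set is kept and the
estimator degenerates to the exact Jaccard distance — the tests exploit
this to check the sketch against an independent pure-R k-mer oracle.

`all_pairs()` computes upper triangles only, mirrors them, and sets
diagonals analytically (GCS 100, GCD 0, ANI 100, distance 0);
self-comparisons are never executed.

## Taxonomy, networks, MaxGCDGap

Clusters are connected components of the GCS ≥ 35% graph — threshold
*inclusive*, per the defining phrase "35% or more", and component-based
rather than clique-based because published cluster memberships include
phages that qualify through a single member. Multi-member components
are named C1, C2, … by decreasing size (ties by smallest member id); an
optional label map supports EA/EB-style display names. Size-1
components are `SINGLETON`.

Subclusters are connected components of the within-cluster ANI graph at
a configurable threshold. No published ANI cut separating subclusters
is stated for the motivating cohort, so the default (75%) is chosen so
that a cluster spanning ANI 71–99% is *not* split by default — the
parameter is surfaced prominently and subcluster recovery on real data
should be treated as qualitative.

Genome networks retain pairs with `gcd < 0.89` **and** nucleotide
distance `< 0.42`. Both inequalities are strict, matching the defining
"less than" phrasing, and the boundary behavior is pinned by tests. The
package emits the edge list and components; layout/rendering
(Cytoscape-style) is out of scope.

MaxGCDGap sorts one phage's gcd values to all others, prepends a
sentinel 0 (the self-comparison), and returns the largest consecutive
gap. No trailing sentinel at 1 is added: the statistic measures
isolation from the nearest sampled relatives, and a phage whose nearest
neighbor is at gcd 0.95 already shows that as its leading gap. The
source description of the statistic leaves this convention implicit, so
it is documented here and fixed by tests.

Heatmap ordering reproduces the published convention: row distances
under the maximum (Chebyshev) metric, single-linkage agglomeration,
dendrogram leaf order (`stats::dist` + `stats::hclust`).

Lifestyle marker flagging greps products for
integrase/immunity-repressor/repressor keywords and reports
"temperate-marker present" or "no markers". It is explicitly not a
lifestyle call: marker-free genomes may still be temperate, and the
bioinformatic prediction in cohort tables carries the same caveat.

## Intergenic motifs

Intergenic regions are the complement of the gene-interval union, with
the nearest downstream gene resolved per strand (plus-strand: next gene
start at/after the region end; minus-strand: next gene whose start
codon, at its right edge, lies at/before the region start).

Matching is Hamming (substitution-only): the motifs of interest are
fixed-length elements whose "departures" are counted positionally, so
indel alignment would only blur the statistic. The scanner supports the
full IUPAC alphabet in the consensus (N matches any base), reports
every window within the mismatch budget including overlaps, and finds
reverse-strand hits by scanning with the reverse-complemented
consensus. A C++ kernel with early exit keeps the scan linear-time in
practice; tests compare it exhaustively against a brute-force R oracle.

Discovery is greedy seed-and-refine: every intergenic L-mer (in genome,
then coordinate order — deterministic, no randomization) is a seed; a
C++ pre-screen counts each seed's matches so only seeds that can reach
the copy-number floor are refined; matching windows are collapsed into
a case-encoded consensus (uppercase = 100% column conservation,
lowercase = ≥ 75%, else N — the 75% encodes "at least 9 of 12
instances") and rescanned to a fixed point (≤ 10 rounds). Phase-shifted
rediscoveries of the same repeat reach their own fixed points with
uninformative flank columns, so final model selection ranks candidates
by total column conservation (the sum over columns of the majority-base
frequency, maximized by the true phase), then copy number, and drops
models whose occurrence windows mostly overlap an already-selected
model. Consensus column ties break alphabetically.

Upstream distance is measured from the motif's 3'-most position to the
first base of the next start codon on the hit's strand, both endpoints
exclusive, capped at 500 bp; published descriptions of the same
elements vary by one base between text and supplementary material, so
the convention is fixed here and used consistently. Inverted repeats
are windows `arm + spacer + revcomp(arm)` with a total arm-mismatch
budget; the default arm 8 / spacer 2 describes the 18-bp
`GATCAACC-NN-GGTTGATC` family of elements.

## The synthetic cohort generator

`generate_cohort()` emulates exactly the structure the pipeline is
meant to detect:

* **Gene families** are uniform random proteins reverse-translated with
  codons biased toward a GC target; each cluster owns a template of
  families (optionally sharing a fraction with a global pool), members
  retain each family with probability 0.9 and mutate retained CDSs at a
  per-cluster substitution rate.
* **Intergenic spacers belong to the template too** and are inherited
  with the same mutation rate — related genomes share diverged
  intergenic sequence rather than independent random DNA, which is what
  makes fragment ANI behave realistically.
* **Divergence is substitution-only** (no indels or rearrangements), so
  ANI and Mash-distance targets stay analytic: members mutated at rate
  *r* from a template sit at pairwise divergence ≈ 2r (ANI ≈ 100·(1−2r));
  gene gain/loss is modeled solely through family retention, which is
  exactly what GCS measures.
* **Subclusters** are planted by deriving subgroup references from the
  template at a higher between-subgroup rate.
* **Motifs** are planted into intergenic spacers with chosen copy
  numbers, mismatch budgets and upstream offsets; successive plantings
  exclude already-used windows so they never overwrite each other.
  Planted coordinates, family assignments, cluster labels and realized
  substitution counts are returned as machine-readable truth and
  round-trip through the GenBank writer/reader.

Default study conditions: 4 clusters × 5 genomes + 2 singletons, 10–14
genes per genome of 80–200 aa, retention 0.9, zero cross-cluster
overlap, substitution rate 0.05, spacers 30–120 bp, GC target 0.63
(mid-range for Microbacterium phages), 20% minus-strand genes. These
sizes keep a full pham build (~250 proteins, ~30k alignments) in the
tens of seconds while leaving within-cluster GCS (~90%) far above the
35% threshold and between-cluster GCS at ~0. Realized genome GC
compresses a few points toward 50% at extreme targets because uniform
random proteins bound the coding GC — a documented limitation, not a
bug.

What the generator does *not* emulate — and what passing tests
therefore cannot show about real data: mosaicism and recombination
(genes move as whole families, never as fragments), indels and
rearrangements, codon-usage structure beyond GC, shared gene content
between "unrelated" clusters (real inter-cluster GCS is small but
nonzero), and database-scale pham context (phams built on a cohort
alone will differ from phams built against a multi-thousand-genome
database; published pham counts are not reproducible cohort-only).

## Pipeline and numerical choices

`run_pipeline()` chains the stages on ≥ 2 genomes and writes every
table with a `#` parameter header; the effective configuration goes to
`provenance.json`. The pham and matrix stages are cached keyed on an
MD5 content hash of the genomes plus parameters, so threshold sweeps
(e.g. cluster cut at 20/35/50) reuse the expensive work. Reruns are
byte-identical; a stage failure aborts with the stage name.

Other numerical conventions: symmetric matrices are written to 3
decimals and round-trip losslessly at that precision; MinHash uses one
fixed hash seed by default so distances are reproducible across runs;
all generator randomness flows from a single mandatory seed; motif
discovery is fully deterministic given the genome and parameters.

## Known limitations

* Pham thresholds are the Phamerator-lineage defaults, not recovered
  from any specific published run; absolute pham counts on real cohorts
  will differ from database-contextualized counts.
* ANI is fragment-based with fixed alignment scoring; tools differ by
  fractions of a percent, which matters only near subcluster cuts.
* Single-linkage clustering chains by construction; a borderline pair
  (GCS barely over 35%) merges whole clusters, which is faithful to the
  published scheme but sensitive to single comparisons.
* The motif finder models fixed-length, substitution-degenerate
  elements only — no PWMs, no indels, no regulatory inference.
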