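---
title: "Methods and design notes for plastcomp"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods and design notes for plastcomp}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(plastcomp)
```

# Scope

plastcomp re-implements, as a self-contained desk-scale library, the
computational core of a comparative chloroplast-genome analysis platform:
feature extraction from annotated genomes, feature-content comparison,
two whole-genome phylogenetic distance pipelines (one alignment-free, one
based on maximal exact matches) feeding neighbor-joining, and annotation
transfer onto draft genomes by seeded local alignment. Everything is
testable offline against synthetic quadripartite plastomes generated by the
package itself. Web serving, genome-map rendering (OGDRAW/Circos figures)
and database harvesting are deliberately out of scope.

# Data model

A `genome_record` holds an accession, organism, upper-cased IUPAC sequence,
topology and an ordered feature table. Eleven feature classes are
recognised (`Gene`, `CDS`, `tRNA`, `rRNA`, `Exon`, `Intron`, `Promoter`,
`RepeatRegion`, `StemLoop`, `Minus10Signal`, `Minus35Signal`), matching the
conventional GenBank keys (`gene` ... `-10_signal`, `-35_signal`).
Coordinates are 1-based and inclusive everywhere, including the CSV
dialects. Three representational choices deserve a note:

* **Origin-spanning and multi-segment features.** `join(...)` locations are
  decomposed into part-segments sharing a name and carrying increasing
  `part_index`, so `1 <= start <= end <= L` is an invariant of every stored
  row. Parts keep the order in which they appear in the location string —
  including inside `complement(join(...))` — which makes the
  GenBank writer/parser round trip exact. The FASTA exporter concatenates
  parts in `part_index` order, reverse-complementing each minus-strand
  part; for the rare complemented join whose parts are listed in genome
  order rather than coding order this differs from strict GenBank
  semantics, a documented simplification.
* **Feature names from GenBank qualifiers.** The source of a feature's name
  is the first available of `/gene`, `/product`, `/note`, else a
  synthesised `class_start_end`. The upstream description annotates
  features "by name" without fixing the qualifier; this priority follows
  common plastome annotation practice (genes carry `/gene`, tRNAs often
  only `/product`).
* **User annotation items carry no strand.** The two-part annotation
  dialect has exactly four fields per item, so all user features default to
  the plus strand. This only affects sequence extraction, never the
  name-based content comparison the dialect feeds.

Malformed GenBank feature locations warn and skip the feature; a missing
sequence block is fatal. The CSV dialect parsers are strict: wrong field
counts, non-enumerated feature types, out-of-range or inverted coordinates
all fail with the offending line number.

# Feature-content comparison

Genome content is compared **by normalised feature name within feature
class**, not by sequence: `normalize_feature_name()` trims and collapses
whitespace and case-folds, reporting names on the bundled canonical plastid
gene list in conventional capitalisation; tRNA anticodon suffixes remain
distinguishing (`trnH-GUG` != `trnH-CAC`). A `Gene` rbcL and a `CDS` rbcL
are tracked as different keys. The alternative — calling two features "the
same" only when their sequences align — would be stricter but is not what
an annotation-driven content comparison does; it is noted here as the
road not taken.

Duplicated names (the inverted-repeat gene copies) collapse to a single
name key for the set logic, but every coordinate instance is retained and
exported by `export_links()`, whose TSV is deterministically ordered
(other label, then status, then name) so identical inputs are
byte-identical. Region filtering uses *any overlap* between the feature and
the window, the most permissive reading of "focused range"; it applies to
the reference side only. Two invariants are enforced by tests: shared and
unique sets partition each side's name set, and `compare_pair(A, B)`
mirrors `compare_pair(B, A)`.

# Alignment-free distances: base-base correlation

For a genome of length $L$ the BBC vector has 16 components indexed by
ordered base pairs $(i, j)$ over $\{A, C, G, T\}$:

$$\mathrm{BBC}_{ij} = \sum_{l=1}^{K} P_{ij}(l)\,
  \log_2 \frac{P_{ij}(l)}{P_i\,P_j}$$

with $P_i$ the base frequencies over unambiguous positions and $P_{ij}(l)$
the frequency of base $i$ at $t$ and base $j$ at $t+l$ over all windows
$t = 1..L-l$ whose two positions are both unambiguous. Zero-probability
terms contribute 0. This is the plain mutual-information form of the
statistic; the source platform cites the BBC literature without printing a
formula, and some published variants normalise by $K$ — the form above was
fixed here because it is directly verifiable against an exhaustive
counting oracle (the test suite checks agreement to 1e-12). The gap depth
defaults to $K = 10$ and is exposed everywhere, since no upstream value is
stated. Sequences are treated as linear even for circular molecules: the
missing wrap-around windows are $O(K/L)$ of the total, negligible at
plastome scale.

Ten vector distance measures are provided (`euclidean`, `sqeuclidean`,
`manhattan`, `chebyshev`, `minkowski` with order 3, `canberra`,
`braycurtis` on absolute values, `cosine`, `pearson` as $1-r$, `spearman`
as $1-\rho$); the platform's ten methods are unnamed upstream, so these
are ten widely used measures valid for signed inputs. Degenerate cases are
defined rather than left undefined: correlation- and cosine-type distances
between two constant (or zero-norm) vectors are 0 when both are
degenerate and 1 when only one is; Canberra and Bray–Curtis terms with
zero denominators contribute 0. All ten are symmetric, non-negative and
zero on identical vectors, which the suite checks on random vectors.

# Alignment-based distances: maximal exact matches

The alignment pipeline scores a genome pair by coverage with **maximal
exact matches** (MEMs): exact substring matches of length at least
`min_len` (default 20, the conventional minimum unique-match length of
whole-genome aligners) on either strand of the second genome, extendable
on neither side. MEMs are found by hashing all `min_len`-mers of B and
merging runs of consecutive seed hits along each diagonal; a maximal run
of consecutive matching $k$-mers is exactly a maximal match, so the finder
is equivalent to the quadratic all-substrings oracle it is tested against.
Ambiguity codes never match.

The pair distance is the published formula

$$D_{AB} = -\log_2 \frac{N_{mat}}{L_{max}}$$

where $L_{max}$ is the maximum genome length in the analysed set
(computed once per matrix) and $N_{mat}$ the matched nucleotide count.
Two details are under-specified upstream and fixed here:

* $N_{mat}$ is the number of A-positions covered by at least one MEM,
  averaged with the covered-position count of B and rounded half up.
  Per-genome coverage differs when lengths differ; averaging keeps the
  matrix exactly symmetric, which neighbor-joining requires.
* An empty match set would make $D$ infinite, so $N_{mat}$ is clamped to
  at least 1, giving the finite ceiling $D = \log_2 L_{max}$.

The formula has one counter-intuitive arithmetic property: any genome
shorter than $L_{max}$ has a nonzero "self-distance"
$-\log_2(L_A/L_{max})$. The matrix diagonal is therefore *defined* as 0,
and an identical pair inside a set with a longer third genome sits at
$-\log_2(N_{mat}/L_{max}) > 0$ — the tests assert this exact behaviour
rather than hiding it. Circularity is ignored (linear scan), as for BBC.

# Neighbor joining and serialisation

`nj_tree()` is the Saitou–Nei agglomeration: join the pair minimising
$Q(i,j) = (n-2)\,d_{ij} - \sum_k d_{ik} - \sum_k d_{jk}$, with the standard
two-point branch lengths and the three-point formulas for the final
triple. Two determinism choices make trees bit-reproducible: ties in $Q$
are broken on the lexicographically smallest pair of node labels (each
active node is identified by the smallest leaf label it contains), and the
Newick writer orders children by smallest contained leaf label. Negative
branch-length estimates are clamped to 0 with the deficit moved to the
sibling edge, standard practice that keeps the format writers'
non-negativity assumption true. On additive matrices the output tree
reproduces the input distances to 1e-9 and the generating topology exactly
(Robinson–Foulds 0), which the suite checks over random 8-leaf trees.

Branch lengths (and all numeric text output) use the shortest decimal
representation that parses back to the identical double, so
write → parse → write is byte-idempotent. Matrix writers target classic
dialects: PHYLIP square (taxon count header; names padded/truncated to 10
characters with `~k` uniqueness suffixes on collisions; 6 decimals), the
`#mega` / `!Title` lower-left MEGA dialect (the exact MEGA version emitted
upstream is unstated; this classic dialect was chosen and is documented),
and Nexus TAXA + DISTANCES blocks with `TRIANGLE=LOWER`. A PHYLIP reader
provides the matrix round trip; trees round trip through `ape`.

# Annotation transfer

`build_feature_library()` collects one entry per feature *instance*
(inverted-repeat duplicates stay separate, distinguished by
`location_id`), stored in coding orientation. `local_align()` replaces an
external BLAST dependency with seed-and-extend: exact 11-mer seeds,
diagonal clustering, then optimal local alignment of the entry within the
seeded query window (Smith–Waterman via Biostrings) under match +1,
mismatch −2, gap of length $k$ costing $5 + 2k$. E-values use
$K m n e^{-\lambda S}$ with the ungapped Karlin–Altschul constants for the
+1/−2 scheme ($\lambda = 1.33$, $K = 0.621$) as a documented approximation
for the gapped scheme. Hits on both strands of the query are reported in
forward coordinates.

Entries carry the eight canonical fields. Two of their published
definitions are reproduced literally or deliberately corrected, and both
choices are explicit:

* **LengthRatio** is computed as the literal $|End-Start|/L$ — one less
  than the inclusive span over the library feature length, so an exact
  full-length hit scores $(L-1)/L \approx 0.999$, not 1. The off-by-one is
  preserved because it is the printed definition; callers wanting the
  inclusive ratio can add $1/L$.
* **Identity** is the standard fraction of matching columns over alignment
  length, in $[0, 1]$. The published field description reads
  "matches/mismatches", which is unbounded and almost certainly a typo;
  the standard fraction is implemented and the literal reading rejected —
  deliberately, not silently.

Non-redundancy keeps, among hits with the same normalised name whose query
intervals overlap by more than `max_overlap` (default 0.5 of the shorter
interval), only the highest-scoring one; ties break on E-value, position
and library identifier, so results are deterministic. The in-memory entry
table carries two extra columns (`strand`, `feature_class`) needed to emit
re-parseable GenBank output; the tabular serialiser emits exactly the
eight canonical columns.

Default thresholds (identity ≥ 0.7, E ≤ 1e-6, length ratio ≥ 0.2) are
package choices — the source platform does not state its BLAST thresholds
— and are exposed in `annotation_thresholds()`.

# The synthetic world, and what green tests establish

`simulate_plastome()` emulates the quadripartite architecture: LSC + IRa +
SSC + IRb with IRb an exact reverse complement of IRa, features planted
without overlap in each region and IRa features mirrored into IRb on the
opposite strand — reproducing duplicated IR gene content, the structural
property the comparison and annotation modules must handle. Real plastomes
are 110–200 kb with 6–76 kb IRs; the test-scale defaults (LSC 8 kb,
SSC 2 kb, IR 1.5 kb, GC 0.37) keep runtimes desk-scale while real-scale
parameters remain legal. Mutation is uniform Jukes–Cantor-like
substitution plus geometric-length (mean 3) indels with coordinate
lift-over; divergence along a tree branch is proportional to branch
length.

What the generator does **not** emulate: codon structure and coding bias,
GC heterogeneity between regions, RNA editing, IR expansion/contraction,
rearrangements. Consequently a green end-to-end test establishes that the
pipelines correctly process plastome-shaped data at controlled divergence
— not that either statistic resolves any particular real phylogeny.

The bundled `clade6_preset()` — three species pairs,
`((A:0.5,B:0.5):2,(C:0.5,D:0.5):2,(E:0.5,F:0.5):2)` at 0.02 substitutions
per site per unit length on ~19.6 kb genomes — was chosen with the
statistics' resolving power in mind. Because the BBC vector has only 16
components, its pairwise distances carry an irreducible sampling noise
floor and saturate at moderate divergence: on this generator BBC reliably
separates closely related pairs from everything else, but cannot rank
already-saturated cross-clade distances. A topology whose every internal
split is a cherry is therefore exactly what the method can recover, and
mirrors the realistic use case of distinguishing genera containing close
species pairs. The end-to-end acceptance test exercises the preset at a
fixed seed; because BBC distances sit close to their noise floor, recovery
under this statistic is reliable but not guaranteed for every seed,
whereas the exact-match pipeline has ample signal at these divergences.

# Numerical choices

* BBC/oracle agreement is asserted to 1e-12 (pure counting, no
  cancellation-prone arithmetic).
* Distance matrices must be symmetric to 1e-8 on input and are
  symmetrised by averaging; diagonals must be exactly 0.
* NJ tie-breaks and writer orderings are lexicographic; all text output is
  deterministic byte-for-byte.
* Negative NJ estimates clamp to 0 (deficit to sibling); intermediate
  node distances clamp at 0 against floating-point dips.
* Degenerate inputs fail fast with informative errors: sequences with
  fewer than two unambiguous bases, K ≥ L, matrices under 3 taxa,
  duplicate genome labels, empty feature-class sets, empty libraries.

# Known limitations

* The GenBank parser covers the flat-file subset the pipelines need
  (LOCUS/ACCESSION/ORGANISM/FEATURES/ORIGIN; `join`, `complement`,
  `order`, partial markers). Exotic location operators (`a^b`, remote
  references) are skipped with a warning.
* MEM finding hashes `min_len`-mers; highly repetitive inputs inflate the
  seed-pair list (quadratic in repeat copy number), acceptable at plastome
  scale.
* The E-value approximation re-uses ungapped constants for the gapped
  scheme; absolute E-values are indicative, ranking is unaffected.
* `apply_modifications()` applies one item's coordinates to every feature
  instance matching the name, collapsing multi-part features to the
  new single interval — the dialect has no way to address one part or one
  IR copy.
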