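---
title: "Discovering AT-specific insertion transposons: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Discovering AT-specific insertion transposons: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(atonscan)
```

## The problem

Nonautonomous DNA transposons — MITEs and their relatives — leave a
characteristic footprint in a genome: many short, near-identical copies
bounded by terminal inverted repeats (TIRs), each sitting in unrelated
flanking sequence. A family whose members include dozens of *byte-identical*
copies at distinct loci has, almost certainly, transposed very recently or
is still doing so, because substitutions accumulate quickly once copies
stop moving. `atonscan` implements this identical-copy activity screen and
the downstream characterization of one particular element class: small
TIR-bearing elements that insert specifically at the dinucleotide `AT`
("ATons"). These elements are always flanked by an `A` on their 5' side and
a `T` on their 3' side, begin with `T` and end with `A`, and leave a plain
`AT` at the orthologous empty site — a target behavior that is
Helitron-like, while the TIRs are MITE-like, which is what makes the class
worth a dedicated toolkit.

Throughout the package, coordinates are 0-based half-open (BED convention),
and the flanking target nucleotides are *not* part of the element: an
element interval covers `T ... A`, with the target `A`/`T` in the flanks.
This convention removes the classic off-by-one ambiguity about whether the
target dinucleotide belongs to the element.

## Pipeline stages and the choices behind them

### Copy retrieval and the identical-copy screen

`map_copies()` is a seed-and-extend homology search: exact 12-mer seeds on
both strands, seed hits clustered by diagonal, each cluster extended by
local alignment with match +1, mismatch −1, gap −2. Identity is defined as
matches divided by alignment columns (gap columns count against identity).
A copy is **complete** when its alignment reaches both query termini within
`end_tolerance` (default 2 bp) and covers ≥ 90% of the query. Defaults of
90% identity over 90% coverage are deliberate: the original family-member
retrieval tools do not document their cut-offs, so both are exposed as
arguments rather than constants.

`group_identical()` partitions complete copies by exact sequence equality.
Two byte-identical copies whose 50 bp flank pairs differ at fewer than 5
positions (over the 100 flanking bases) are collapsed into one: such pairs
are far more likely to be assembly redundancy than independent insertions,
and counting them would inflate the activity signal. `rank_families()`
then emits one row per identical group of at least `min_group_size`
members (default 10), labelled `a`, `b`, `c`, … in descending size — the
layout of a published activity screen, which the test-suite reproduces
from a table fixture.

### TIR and hairpin detection

Thermodynamic folding is replaced by direct combinatorial search.
`detect_tir()` reports the longest prefix length `L` whose reverse
complement matches the 3' suffix exactly (and, alongside, the best `L` at a
relaxed ≤ 10% mismatch fraction, since it is not documented whether
published TIR lengths admit internal mismatches; the relaxed call can only
extend the exact one). TIRs shorter than 10 bp are not called — the same
`> 10 bp` terminal criterion used for the autonomous-partner search.
G·T wobble pairs do not count as matches: this is DNA-level analysis, and
`N` never matches anything. `detect_hairpin()` enumerates all exact
stem-loop configurations (stem ≥ 5 bp, loop 3–10 bp by default) in the 50
bp subterminal windows, preferring the longest stem and breaking ties by
smallest offset — no free-energy model, because the published use of
folding is only to reveal inverted-repeat configuration, which exact
complementarity search reproduces testably.

### Related empty sites and target-site classification

An empty allele of an occupied locus reads `left flank + right flank`
directly, because the target `A` is the last base of the left flank and the
target `T` the first base of the right flank. `retrieve_res()` therefore
anchors on the *outer* 44 bp of each flank — the 5 bp junction pad plus the
target base are excluded from the anchors, so no junction edit can move
them — and requires both anchors in the correct order and orientation at
≥ 80% identity, separated by at most a short junction (`max_gap`, default
20 bp extra). Requiring both flanks with correct spacing is what keeps
paralogous flank hits (flanks that happen to lie inside other repeats) out
of the RES set. Occupied loci are excluded by the junction-length bound,
and the source locus itself is excluded by coordinate overlap.

Classification reads the junction edit script deterministically: the
observed mid-segment between the anchors is decomposed as a prefix of the
left remainder plus a suffix of the right remainder. From which bases are
missing or inserted follows the class: `intact_AT`; `typeI` (target `AT`
absent, flanks intact); `typeII` (one target base absent, possibly with
small flank erosion); `typeIII` (target absent and at least one flank base
deleted); `typeIV` (extra bases inserted between `A` and `T`). When several
decompositions fit, the one with least flank deletion and then the most
balanced split wins — one can show this recovers the generating edit
exactly for every junction the synthetic grammar produces, which is what
the classifier-accuracy test checks. Junctions fitting no decomposition are
flagged `unclassified`, never silently binned.

`infer_scenario()` encodes a genuine ambiguity: for canonical elements
(first base `T`, last base `A`) an insertion between `A` and `T` and a
duplication of `AT` produce byte-identical occupied loci, so the function
returns `"ambiguous"` for them, and resolves the scenario only for
hypothetical non-canonical termini where the occupied junction
distinguishes the two models.

### De novo discovery

`scan_candidates()` enforces the full canonical grammar at scan time —
flank `A`, first base `T`, last base `A`, flank `T`, exact TIR ≥ 10 bp,
length 50–1000 bp. The grammar collapses the search space enough that the
scan reduces to pairing `AT` dinucleotide positions whose flanking 10-mers
are reverse complements, which is done by hashing rather than by the
quadratic enumeration (the test-suite proves the two equivalent on small
genomes). Because `A [T…A] T` is its own reverse-complement layout,
insertions on either strand produce the same plus-strand pattern and are
found once. Overlapping candidates are resolved greedily: maximal-TIR
intervals win, and remaining non-overlapping intervals are kept — a pure
"best per cluster" rule would silently drop a real copy whenever two
insertions sit closer than the length bound and a spanning pseudo-candidate
ties their TIR.

`cluster_candidates()` single-links candidates at ≥ 80% full-length
identity (the clustering threshold of the original automated search is
undocumented; 80% is the conventional family boundary in repeat annotation
and is exposed as an argument). Clusters of ≥ 10 members become candidate
families. The published "subsequent manual inspection" is replaced by three
logged automatic filters: exact consensus TIR ≥ 10 bp, copy-length
coefficient of variation ≤ 10%, and at least one intact RES; rejected
clusters are returned with reasons so the filters can be relaxed
deliberately. `find_flanked_fragments()` retrieves 500 bp – 200 kb
fragments bounded by a family's termini (the autonomous-partner hunt) and
annotates only the longest ORF — no protein-domain scanning, since that
depends on external profile databases and the published search found no
such domains.

### Age profiles, trees, ESTs

`align_family()` is a deterministic star alignment around the modal
sequence — adequate because family members are near-identical by
construction of the problem; a progressive aligner would add dependencies
without changing the downstream statistics. `build_consensus()` takes the
per-column strict majority, drops gap-majority columns, and breaks ties by
the fixed order A < C < G < T (a logged, arbitrary but deterministic
choice). `divergence()` is 100 minus global-alignment percent identity —
divergence as the complement of similarity — binned at 1% by flooring.

Trees are neighbor-joining on p-distances with site-resampling bootstrap
(default 100 replicates at desk scale, configurable to 1000). This is a
deliberate substitution for parsimony tree search: the tree's only role
here is to delineate subclades of identical or near-identical copies, which
NJ reproduces at a fraction of the cost. Subclade extraction uses
cophenetic (tree-path) distance at threshold `eps` with single linkage
rather than literal clade membership, because NJ attaches diverged copies
at arbitrary points along zero-length backbones, making clade membership of
an identical-copy group unstable while path lengths are not.

`search_ests()` keeps the published significance thresholds — alignment
longer than 60 bp, identity above 70%, E ≤ 10⁻⁶ — but computes the
E-value internally from Karlin–Altschul statistics with the ungapped
+1/−1 nucleotide parameters (λ ≈ 1.33, K ≈ 0.621) against the actual
database size. The thresholds, not the alignment engine, are the
scientific content.

### In-silico transposon display

`simulate_td()` predicts the band count a transposon-display (AFLP-style)
assay would show: for each copy, the nearest BfaI site (`CTAG`, cut after
the first base) in the element-side flank within 1 kb defines a fragment,
and the copy survives selective amplification when the genomic base
adjacent to the recognition site — the first base the adaptor primer reads
through the overhang junction, a detail the protocol leaves implicit but
standard AFLP chemistry fixes — equals the selective base. With one
selective base and uniform flanking sequence, retention is Binomial(n,
1/4). Bands are distinct fragment sizes after merging within ±1 bp (a
size-resolution limit); PCR efficiency and intensity are not modeled
because the assay is read as a band count. Whether the TE primer reads from
the element's 5' or 3' end is not documented; it is a flag, default 3'.

## The synthetic genome generator

`sim_genome()` exists so that every stage can be scored against known
ground truth without any download. Its defaults *are* the reference study
conditions used by the test-suite:

* 2 Mb of i.i.d. background at 38% GC (mosquito-like) over 4 contigs;
* three planted families of 150, 80 and 12 copies (112 bp/TIR 15,
  144 bp/TIR 17, 200 bp/TIR 12), inserted between the `A` and `T` of
  background `AT` dinucleotides — the duplicated-`AT` model is
  sequence-indistinguishable for canonical elements, so only one insertion
  model is generated;
* per-copy divergence classes {0, 1%, 5%} allocated deterministically by
  family-specific weights: 0.50/0.40/0.10 for the large family,
  0.25/0.55/0.20 for the middle one, 0.80/0.10/0.10 for the small one.
  The profiles mirror the empirical shape of recently expanded families —
  roughly half of a large active family's copies are identical and most of
  the rest are within 1% — and a 12-copy family that passes an
  identical-copy screen is by construction dominated by identical copies.
  Deterministic allocation (rounded cumulative weights) makes the truth
  table, and hence the acceptance checks, reproducible rather than
  themselves stochastic;
* an empty allele emitted for 50% of insertions (empty sites are found for
  about half of real copies), copied verbatim from the pre-insertion
  background onto a dedicated RES-bank contig; 0.5% of empty alleles carry
  one aberrant junction drawn uniformly from the four-type edit grammar.
  RES flanks are copied exactly because real aberrant junctions are
  typically the only mutation over long stretches of flank;
* 100 ESTs of 500 bp, 10% of which embed an element with 30 bp of its
  genomic flanks (co-transcription), the rest background.

What the generator does **not** emulate — and what passing tests therefore
do not demonstrate about real genomes: a background repeat landscape
(nested insertions, decayed repeat copies; a `decoy_n` option plants
TIR-less repeats for specificity probes, but there is no realistic repeat
ecology), indels within element copies (substitution-only by default),
assembly artifacts other than the exact-duplicate kind that
`group_identical()` collapses, and sequencing error. Recall and
classification accuracy on real assemblies will be lower than on these
simulations; the simulations establish correctness of the machinery, not
field performance.

## Numerical conventions, degenerate inputs, problem sizes

One scoring scheme is used for every alignment in the package (match +1,
mismatch −1, gap open 0, gap extend −2), so identity percentages are
comparable across stages. All tie-breaks are fixed and documented:
consensus ties A < C < G < T; hairpin ties longest stem, then smallest
offset, then smallest loop; overlapping hits by descending score, then
leftmost. Empty FASTA files, duplicate ids, invalid characters,
out-of-range slices, too-short queries, and sub-minimum copy counts are
hard errors, never silent truncation; flank extraction at contig edges
clips and records the clipping instead of erroring.

The shipped tests run the full discovery loop on the 2 Mb default
simulation (a few minutes on one core), oracle-equivalence suites on ≤ 5 kb
genomes where brute-force enumeration is feasible, the junction classifier
on thousands of grammar-generated junctions, and the display simulator on
the 294-copy reference layout. These sizes were chosen so that every
claimed property is re-verified from scratch on installation while staying
desk-scale; the same machinery runs unchanged on larger inputs.

## Known limitations

* Single-linkage clustering at 80% identity can, in principle, chain two
  genuinely distinct families through intermediate copies; the planted
  families here are well separated, and real analyses should inspect the
  per-family length CV that the filters report.
* The RES search requires both flank anchors at ≥ 80% identity; empty
  sites in regions that have diverged further, or whose flanks were
  themselves disrupted by later insertions, are missed (counted as "no
  RES", not as aberrant).
* E-values use ungapped Karlin–Altschul parameters with a gapped aligner,
  the usual pragmatic approximation; at the 10⁻⁶ threshold with > 60 bp
  hits this affects nothing near the decision boundary.
* The scanner's grammar is exact: an element whose terminal base has
  mutated is invisible to de novo discovery (though still found by
  `map_copies()` homology search once the family is known). This is the
  same asymmetry real pipelines have between discovery and annotation.
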