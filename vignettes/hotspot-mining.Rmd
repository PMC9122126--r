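---
title: "Mining anchor-gene diversity hotspots: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mining anchor-gene diversity hotspots: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hotspotr)
```

## The mining model

Prophages and phage satellites concentrate their genetic variability in
short loci flanked by conserved genes. In P4-like satellites the hotspot
sits between the polarity-suppression protein gene (*psu*) and the
integrase; in P2-like phages, between the portal gene *gpQ* and the
replication endonuclease gene *gpA*. Both loci are adjacent to the *cos*
packaging site and are enriched in anti-phage defense systems. `hotspotr`
operationalises the discovery procedure as five composable stages, each a
plain function over tibbles.

### Anchor search

Homologs of the anchor protein are found by **exact affine-gap
Smith–Waterman local alignment**, not a heuristic seed-and-extend search:
at the scale the package targets (one query against 10^3–10^6 proteins)
exactness is affordable, removes a tuning surface, and makes an
independent-oracle test meaningful. The score of a gap of length $k$ is
$\mathrm{open} + k \cdot \mathrm{extend}$ (defaults 11 and 1 under
BLOSUM62, the familiar protein-search convention). The ambiguity letter
`X` scores 0 against everything; any other non-standard letter is an
error naming its position.

Significance uses the Karlin–Altschul form
$E = K \, m \, n \, e^{-\lambda S}$ with the query length $m$, the total
residue count of the corpus $n$, and fixed gapped-BLOSUM62 parameters
$\lambda = 0.267$, $K = 0.041$. The parameters are deliberately *not*
re-fit per query: at the operating threshold $E \le 10^{-10}$ the score
cutoff is so deep in the tail that reasonable parameter refinements do
not change hit sets, and fixed parameters keep the statistic a pure
function of the score. Both are exposed in `mining_config()` for users
who want BLAST-compatible values for other matrices.

### Locus extraction

From each anchor hit the **10 downstream genes** are scanned for a
closing gene whose product annotation contains a keyword
(case-insensitive substring; `"integrase"` by default,
`"replication endonuclease"` for the P2-like scenario). "Downstream" is
interpreted relative to the anchor's strand — increasing gene index for a
`+` anchor, decreasing for `-` — because the anchor and closing genes are
co-oriented in the canonical elements; `scan_both_directions` relaxes
this for exploratory use, preferring the downstream side on ties. Gene
index always means rank by start coordinate within a contig, regardless
of strand.

A hit whose window runs off the contig end before completing is logged
with reason `contig_end`: this is exactly the published rule of
discarding loci that span two contigs, expressed as a per-hit discard.
A complete window without the keyword logs `no_closer`. Loci are
deduplicated on the (anchor, closer) feature pair, so one anchor yields
one locus. The locus span is measured between the proximal boundaries of
the anchor and closing genes (the cargo region only), matching the
intuition that a hotspot is the material *between* the conserved genes.

### Cargo clustering

All cargo proteins are clustered by the canonical greedy incremental
scheme: sequences are processed longest-first (ties by id) and each joins
the *first* existing representative — not the best — that it matches;
otherwise it founds a cluster. A match requires coverage of **both**
sequences at or above `min_coverage` (default 0.6, the published
threshold; bidirectional coverage mirrors the default coverage mode of
the clustering tool the procedure was built on) and identity over aligned
columns (gap columns counted) at or above `min_identity` (default 0.3).
The identity floor is this package's addition: coverage alone would merge
unrelated proteins of similar length, and 30% is the customary twilight
zone boundary. Pairs whose length ratio is below `min_coverage` are
skipped without aligning — an exact pruning, since the local footprint
cannot exceed the shorter sequence. `cluster_oracle()` re-executes the
same policy from an exhaustive all-pairs alignment table and must agree
exactly; it is capped at 200 sequences.

### Arrangements, curation, systems

A locus's **arrangement** is the tuple of its cargo cluster ids in
anchor-to-closer order, so elements integrated in either genomic
orientation yield the same tuple (orientation invariance is tested by
reverse-complementing whole corpora). Order sensitivity is the default
because cassette rearrangements are biologically meaningful; an unordered
mode is available (`ordered = FALSE`). A locus with no cargo is the
*empty arrangement*: it is tallied and reported — an empty hotspot is a
real locus state — but never grouped into a system.

Curation keeps arrangements occurring at least `min_count` times
(5 and 10 are the published choices for the two hotspot families) and,
optionally, whose longest member protein reaches `min_protein_aa`
(120 aa in the published P2 arm); `cumulative_fraction` reports the
retained share of all loci and is non-increasing in `min_count`.

Grouping "highly similar systems sharing a core set of genes" was a
manual step in the original procedure; here it is made deterministic:
arrangements are nodes, with an edge when one cluster set contains the
other or their Jaccard index is at least 0.5, and connected components
are systems. The core is the intersection of member cluster sets and
variant percentages are member counts over the system total. The
threshold is exposed; containment handles the common
core-plus-accessory-gene pattern, Jaccard the sibling-variants pattern.

### Co-localization detection

`detect_systems()` evaluates a declarative `system_model()` against
per-protein domain-profile bit scores: a gene satisfies a component if
*any* accepted profile reaches its threshold, a quorum hit needs every
component on one contig within `max_intervening_genes` (default 2) of
each other, and a fusion profile at threshold satisfies the model as a
single gene anywhere (loner). **Thresholds are inclusive** (score ≥
threshold passes) — the sources state thresholds without strictness, so
inclusivity is fixed and boundary-tested at every threshold of the
built-in PARIS model (AAA_15 ≥ 32, AAA_21 ≥ 27, DUF4435 ≥ 27; fusions
AAA_15+DUF4435 ≥ 80, AAA_21+DUF4435 ≥ 20). Overlapping candidates are
resolved greedily by (contig, leftmost gene, rightmost gene, variant with
fused first), each gene joining at most one hit, which makes output
deterministic; a brute-force enumeration oracle checks this policy.
The default spacing of 2 intervening genes is a documented choice: the
target systems are two-gene cassettes and the original detection tool's
co-localization distance is not recorded. Scoring is decoupled from
detection (a TSV of `feature_id, profile_name, bit_score`), so the module
runs without any profile database; prevalence counts genomes, not
replicons, with at least one hit.

## The synthetic corpus and what it does (not) show

`generate_corpus()` emulates the *annotation-level structure* of a real
corpus: each carrier genome gets one element — a mutated anchor homolog,
0–9 cargo genes instantiated from a template cassette, and a
keyword-annotated closing gene — surrounded by decoy genes, with
intergenic gaps drawn uniformly from 10–200 bp (a realistic span scale
for the size statistics without modelling promoters). Defaults define
the standard study conditions: 200 genomes, 40% prevalence, a 12-system
pool under a Zipf($s = 1.2$) frequency law, 10% per-site divergence on
anchors and cargo, 15 decoys per genome, 10% contig breaks, 50%
orientation flips, 5% empty loci, and a 12 kb locus-size cap reflecting
the packaging capacity of satellite-sized capsids. The Zipf exponent and
the empty-locus rate are modelling choices — the real corpus's frequency
distribution is only published graphically — and the planted-truth
design makes downstream checks independent of them. Decoy proteins are
i.i.d. draws from background amino-acid frequencies, so a chance anchor
hit at $E \le 10^{-10}$ is overwhelmingly improbable and search
specificity is testable without a real database. The anchor and closing
reference proteins shipped with the package are synthetic stand-ins
generated once from the same background model; the mining procedure is
indifferent to the anchor's actual sequence, only to its conservation.

Mutation is i.i.d. per-site substitution to one of the 19 other residues
— no indels, no rate heterogeneity, no codon structure. Consequently a
perfect recovery on synthetic corpora demonstrates the *logic* of every
stage (window scan, discard rule, coverage arithmetic, tuple counting,
quorum resolution) and the aligner's exactness, but does not demonstrate
robustness to real-world annotation noise: miscalled gene boundaries,
missed genes inside loci, product strings lacking the keyword, domain
fusions, or homology too remote for a 60%-coverage cluster. On real
corpora those effects make counts conservative rather than wrong, but
they are outside what the ledger can certify.

## Numerical and degenerate-input choices

* The Smith–Waterman DP floors at the empty alignment, so
  `raw_score = 0` with empty footprint and zero coverages when nothing
  scores positively; identity of an empty alignment is 0.
* Traceback prefers the match state and trims zero-scoring prefixes, so
  the reported footprint is the shortest optimum; scores (which carry
  all decisions) are tie-free by construction, and the equality tests
  against the quadratic oracle compare scores.
* E-values are monotone decreasing in score; hit filtering happens in
  score space using the smallest integer score whose E-value passes,
  avoiding repeated exponentials.
* Empty corpora, genomes without genes, zero planted loci, header-only
  tables and empty score files all flow through and produce empty
  results rather than errors; configuration contradictions (empty
  template pool with positive prevalence, oversized templates) fail fast
  in `corpus_spec()`.
* All generation is a pure function of the spec seed; reruns are
  byte-identical, including GenBank output (fixed LOCUS date).

## Problem sizes used by the test suite

The suite validates the aligner on 500 random pairs (length ≤ 120)
against an independently formulated quadratic DP (closed-form scan for
the gap states), the clusterer on 50 randomized fixtures against the
exhaustive oracle, the detector on 100 random 50-gene genomes against
brute-force enumeration, and the full pipeline on the 200-genome study
corpus, where it must achieve locus precision = recall = 1 over
non-split loci, adjusted Rand index 1 against planted families, and an
exactly matching arrangement table. These sizes were chosen to exercise
every code path many times while keeping a complete run inside a few
minutes on one core.

## Known limitations

* The GenBank writer/parser covers the feature subset the pipeline uses
  (CDS with simple, `join()` and `complement()` locations and the
  locus_tag/product/translation/codon_start qualifiers); it is not a
  general GenBank implementation.
* Clustering is quadratic in the number of representatives; for corpora
  far beyond this package's intended scale, an external clustering run
  can be substituted upstream, and an external homology search can stand
  in for the built-in aligner by constructing the hits table directly.
* System grouping approximates a manual curation step; counts of
  "systems" depend on the Jaccard threshold in ways the planted truth
  cannot arbitrate, which is why recovery is scored at the arrangement
  level.
* The detector implements quorum-of-all-components and fused-loner
  semantics only — enough for two-gene cassette systems; it is not a
  general multi-model detection engine.
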