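---
title: "Methods: comparative genomic signatures with genosig"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: comparative genomic signatures with genosig}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`genosig` compares small sets of annotated bacterial genomes along the
axes that matter for closely related strains under divergent selection:
whole-genome identity (ANI), proteome identity (AAI), shared gene
content (orthologous groups), phylogeny (single-copy supermatrix), and
the functional complements that typically separate ecotypes — multiheme
c-type cytochromes, chemotaxis systems, flagellar machinery and
transposable elements. This vignette documents the models, the
parameters that matter, the numerical choices, and what the synthetic
data generator does and does not emulate.

## Genome representation

Genomes are held as named `DNAStringSet` replicons with a feature table
in 0-based half-open coordinates; GFF3 input/output uses the standard
1-based inclusive dialect, and the conversion happens once at the I/O
boundary so all internal arithmetic is unambiguous. Proteomes are
derived with the bacterial genetic code (table 11); minus-strand CDS
are reverse-complemented before translation; the trailing stop is
removed. Two deliberate conventions:

* start codons are translated *as encoded* (no forced methionine) so a
  proteome derived twice is bit-identical; a `force_start_met` flag
  restores the biological convention;
* GC% excludes `N` from numerator and denominator, which keeps draft
  and complete assemblies comparable (the alternative, counting N in
  the denominator, deflates GC in fragmented assemblies).

A CDS with an internal stop codon is flagged `disrupted` and excluded
from protein-level analyses (similarly for `pseudogene` features, with
a flag to include them); a CDS whose length is not a multiple of three
is flagged `partial` and translated on its longest in-frame prefix.

## ANI: fragment recruitment

`fragment_ani()` follows the ANIb convention: the query genome is cut
into consecutive non-overlapping fragments of 1020 bp (the terminal
short fragment is discarded), each fragment is located on the subject
genome by shared 15-mer seeds (both strands; the modal seed diagonal,
binned at 50 bp, selects a candidate window padded by 60 bp), and is
then aligned to that window with the fragment globally aligned within a
locally chosen subject stretch (match +1, mismatch −2, gap open −4, gap
extend −2). A fragment is retained when its alignment identity is
≥ 30% and its aligned fraction is ≥ 0.7; the directional mean is the
mean identity over retained fragments, and the reported ANI is the mean
of the two directional means, to one decimal. Both directional means
are always reported because published tables rarely state their
directionality; the symmetric mean is our single value.

At ~70% identity, 15-mer seeds are sparse (expected exact-seed density
0.7^15 ≈ 0.5% per position), which is why seeds are sampled every 5
positions along the fragment: the expected seed count per fragment stays
above 1 even at the lowest identities the retention filter accepts.
Fragments with no seed at all are unplaced and count as unretained;
this is logged in the per-direction fragment counts.

## Orthology, OGs, AAI

All-vs-all protein comparison aligns every ordered pair sharing at
least one amino-acid 5-mer, with a BLOSUM62 gapped local alignment
(gap open 11, extend 1) — the classical BLASTP parameterization. A hit
needs identity ≥ 30% (matches over all alignment columns, gap columns
included) and query coverage ≥ 0.5. Reciprocal best hits take the
maximum score per query, with ties broken by higher identity and then
lexicographic subject id so the result is independent of input order.

Orthologous groups are the connected components (size ≥ 2) of the graph
whose edges are all inter-genome RBH pairs plus within-genome
*in-paralog* edges: gene h joins gene g's component when
score(g, h) ≥ g's best inter-genome score. This replaces the
normalized-score + MCL machinery of graph-clustering orthology tools
with a deterministic, oracle-checkable construction; the trade-off is
that absolute OG counts on deeply diverged real genomes are
approximate, which is why the pipeline treats published OG totals as
qualitative context rather than reproduction targets, and why the test
suite validates component structure against an independent union-find
implementation instead.

AAI is the unweighted mean identity over RBH pairs passing identity
≥ 30% and *two-way* coverage ≥ 0.7 — the common two-way AAI convention,
chosen because AAI calculators rarely publish their exact filters; both
thresholds are arguments.

## Phylogenomics

Single-copy OGs (exactly one member per genome; the required fraction
of genomes is tunable) are aligned per gene by progressive alignment:
guide order from 3-mer Jaccard distances (most central sequence first),
each new sequence globally aligned against the running profile
consensus (majority residue per column, ties alphabetical), with
consensus-side gaps opening new all-gap columns. At the divergences
where single-copy orthologs are reliably recovered (≤ ~20% amino-acid
distance) this consensus-based scheme is effectively exact; a
user-supplied `aligner` function can substitute an external aligner's
output for harder cases.

Distances use pairwise gap deletion and the Poisson correction
d = −ln(1 − p); pairs with p ≥ 1 or no comparable columns are hard
errors naming the pair. The tree is Saitou–Nei neighbor joining;
negative estimated branch lengths are clamped to zero with the deficit
moved to the sibling branch, preserving path lengths. Maximum-likelihood
inference is intentionally out of scope: at the clade level the
distance tree is robust for these divergences, NJ on an additive matrix
is provably exact (and tested on constructed additive matrices), and
the stage stays self-contained. Bootstrap support resamples supermatrix
columns with replacement under a caller-supplied seed; the default of
100 replicates keeps the desk-scale suite fast, and the argument raises
it to publication scale (1000) when wanted.

No alignment trimming is applied before concatenation; a gap-fraction
column filter exists as an option but defaults off, since trimming
policies are rarely reported and untrimmed matrices are reproducible.

## Heme motifs and OGCs

The c-type cytochrome heme-binding motif is CXXCH, with the CXXXCH
variant. Published pattern descriptions are sometimes ambiguous between
this canonical pair and a literal C-X-X-[X]-H reading, so both modes
are implemented — `canonical` (default) and `literal` — and every
report states its mode; the literal pattern is strictly more
permissive, which the property suite asserts. Scanning is
left-to-right, shortest match first, non-overlapping, resuming after
the matched histidine: overlapping counting would inflate tandem motif
arrays. "Multiheme" is motif count ≥ 4, the strict reading of "more
than 3"; the threshold is an argument because a ≥ 3 convention is also
widespread. OGCs are the OGs containing at least one multiheme member;
singleton multiheme proteins append as single-member rows so the
profile matrix loses nothing.

## Chemotaxis mapping

Identification is keyword-driven (fusion kinases first, then
methyl-accepting receptors, then `Che<letter>` names) with an optional
user table that overrides keywords; every call carries an evidence tag.
HMM-based signal-transduction databases are not reimplemented, so exact
published chemotaxis gene counts are approximated rather than
reproduced — the recovery guarantees in the test suite apply to the
planted truth, where identification is exact.

Operons are maximal same-strand runs with intergenic gaps ≤ 200 bp (the
published operon predictor's rule is proprietary; 200 bp is the common
heuristic and is an argument). Chemotaxis clusters are windows in which
consecutive che genes are separated by at most 2 non-che genes, kept at
≥ 3 che genes; receptors outside every window are reported as
dispersed. The `min_che = 3` default is a judgment call — the criterion
behind published "major cluster" counts is undefined — and reports flag
it. MCP classes come from the heptad count H = round(L/7) of the
cytoplasmic domain, the sequence C-terminal of the last transmembrane
helix detected by Kyte-Doolittle hydropathy (window 19, mean ≥ 1.6,
overlapping windows merged); the class is the nearest of
{24, 28, 34, 36, 38, 40, 44, 64} when within 2 heptads. Classes 28H and
38H stay in the valid set even where a given genome set lacks them,
because the classing scheme defines them. Proteins with no detected
helix are unclassified with H computed on the full length and flagged;
proteins under 50 aa are unclassified with a reason.

Cluster typing is a pure function of member kinds and receptor classes,
first match wins: CheA-CheY fusion → Frz-like; 44H receptor plus
{cheA, cheC, cheD, cheW, cheY} → Dif-like; {cheA, cheB, cheR, cheW}
with no receptor → β group, and with {cheC, cheD, cheX} → its CDX
variant; ≥ 2 receptors plus ≥ 1 interleaved non-che gene → E. coli-like
type 2; otherwise Unclassified.

## Mobilome

Transposases are CDS whose product contains "transposase"
(case-insensitive); the census reports count and percent of CDS to one
decimal, with a warning on draft assemblies (fragmentation
underestimates element counts). Family assignment is best qualifying
local-alignment hit (identity ≥ 25%, query coverage ≥ 0.6) against a
user-supplied labeled protein library — family databases are services,
not shippable, so the interface takes any FASTA with `family=` header
tags and the package provides a synthetic seed library
(`is_reference_library()`) for tests and demonstrations.

## Bray-Curtis signatures

Every count matrix (OG, OGC, IS family) is clustered by UPGMA on
Bray-Curtis dissimilarities d = Σ|u−v| / Σ(u+v). Average linkage is the
choice where the published method names only the distance; complete and
single linkage are arguments. Items are pre-sorted by label before
clustering so ties resolve identically across platforms, and both axes
can be clustered (genomes by default). Heatmaps are emitted as ordered
matrices plus dendrograms (TSV/Newick); rendering is cosmetic and out
of scope.

## The synthetic data generator

`simulate_genome_set()` builds an ancestor genome — intergenic sequence
i.i.d. at the target GC, genes as stop-free codon sequences — and
evolves independent descendants at a per-branch, per-site substitution
probability p (one hit per site, new base uniform over the three
alternatives), so the realized parent-child mismatch fraction equals p
up to binomial noise and the expected mismatch between two siblings is
p_a + p_b − (4/3) p_a p_b exactly; the truth table records these
expected identities. Substitutions that would create an in-frame stop
codon are reverted — a crude but effective stand-in for purifying
selection that keeps the proteome analyzable at the divergences the
recovery tests target. Indels (length 1–10, geometric) are restricted
to intergenic sequence: every gene carries a planted role (neutral
included), and indel protection is what guarantees role parameters
survive divergence; robustness to coding indels is a separate concern
from recovery and is not conflated with it.

Planted features make the classifiers' assumptions literal:

* cytochromes have exactly k non-overlapping CAACH motifs on a
  C/H-free background, so the scanner's expected count is unambiguous;
* receptors are built as Met + 24 hydrophilic residues + two 20-residue
  transmembrane stretches (alternating Ala/Met, mean hydropathy 1.85 —
  above the 1.6 detection cutoff only for windows fully inside the
  stretch, so detected helix boundaries are exact) separated by a
  10-residue loop, with a hydrophilic cytoplasmic tail of exactly 7·H
  residues;
* chemotaxis operons of the five architectures are laid out with 50-bp
  internal gaps on one strand, and chemotaxis items are separated by at
  least three universal neutral genes so cluster boundaries are
  unambiguous in every genome, including genomes from which
  target-restricted features were excised;
* transposase copies of a family derive from a deterministic family
  seed protein, with copies planted at slight mutual divergence (10%
  per extra copy) so each copy's orthologs remain distinguishable while
  family assignment is unaffected;
* the default plan mirrors a two-block study design: the first two
  genomes carry the flagellar cluster, the Frz-like and β-CDX clusters,
  a 36H receptor and their own cytochrome, the remaining genomes carry
  a transposase expansion and a different cytochrome — so two-block
  cytochrome clustering and differential chemotaxis complements are
  recoverable ground truth. Default conditions: 5 genomes, 70 kb,
  110 genes, GC 0.58, substitution rate 0.05 per branch — a deliberately
  compact genome that preserves the statistical structure (divergence,
  gene families, planted signatures) of a multi-megabase strain panel
  at desk scale.

What the generator does **not** emulate: codon usage bias,
recombination and rearrangement, horizontal transfer, pseudogenization,
assembly fragmentation and sequencing error. Passing recovery tests
therefore demonstrate correctness of the implemented rules under the
stated model, not robustness to every feature of real data; on real
genomes the keyword-driven identification steps in particular inherit
the annotation's quality.

## Problem sizes and numerical choices

The test and acceptance workloads use 20–50-kb genomes with 25–110
genes, 1000-protein scanner comparisons, 60 planted receptors, and
100-replicate bootstraps on 200-column matrices — sizes chosen so the
full suite exercises every stage end to end in about a minute while
keeping every statistical check (binomial tolerances on realized rates,
±1 percentage point on ANI recovery) well-powered. Determinism is
enforced throughout: library code never perturbs the caller's RNG
(private, restorable RNG state keyed by explicit integer seeds),
sorting precedes every tie-prone step, and identical inputs plus seeds
give byte-identical outputs.

Known limitations, beyond the generator's scope: OG counts are
RBH-graph approximations (above); the ANI local-window placement
assumes mostly colinear homology within a fragment (it tolerates
strand flips but not fragment-internal breakpoints); the progressive
aligner is not intended for deep (> 40%) protein divergence; and the
chemotaxis/transposase censuses are exactly as good as the product
annotations they read.
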