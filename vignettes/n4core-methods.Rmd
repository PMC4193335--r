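---
title: "Methods: core-genome delineation and metagenome recruitment for N4-like phages"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: core-genome delineation and metagenome recruitment for N4-like phages}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# Scope

`n4core` re-implements, as a tested desk-scale pipeline, the comparative
analysis that delineates the core genome of a phage genus (here shaped after
the N4-like podoviruses and their *Roseobacter*-infecting members) and
estimates the environmental abundance of its genes from metagenome read
sets.  The pipeline has five computational stages — CDS amalgamation,
ortholog clustering, pan-genome partitioning, concatenated core-gene
phylogeny, and translated fragment recruitment — plus a synthetic-data
generator that produces all inputs with planted ground truth, so that every
stage can be validated against known answers rather than eyeballed.

# CDS amalgamation

Gene callers frequently agree on a gene's stop codon but disagree on its
start (the "discordant start" problem: prokaryotic 5' ends are hard).
`merge_predictions()` therefore keys calls by (stop coordinate, strand) —
the stop codon ends at `end` on the plus strand and begins at `start` on
the minus strand — and, where two predictors share a key but differ in
start, keeps the longer call.  Calls unique to one predictor are retained:
nothing in the merged set has invented coordinates.  The built-in
`find_orfs()` caller reports, per (stop, strand), the longest open reading
frame with an `ATG`/`GTG`/`TTG` initiator; it exists so the pipeline is
self-contained, not as a serious gene finder.  Translation
(`extract_and_translate()`) treats the three alternative initiators as `M`,
strips the trailing stop, and treats an internal stop as a hard error,
since planted and real CDSs alike must be stop-free.

# Protein similarity and ortholog families

`all_vs_all()` computes Smith–Waterman local alignments (BLOSUM62, gap open
11 / extend 1) for every protein pair and converts raw scores to
expectation values with the Karlin–Altschul formula
`E = K m n exp(-lambda S)` using the published gapped BLOSUM62-11/1
constants (`lambda = 0.267`, `K = 0.041`) over a search space of query
length times total database residues.  The default cutoff is `E <= 1e-6`.
Scores are computed once per unordered pair (the score is symmetric) and
reported in both directions with direction-specific `E`; a score-only pass
selects candidate pairs before full alignments are computed, which keeps a
~600-protein all-vs-all around a minute on one core.

`bbh_graph()` keeps, for each gene and each *other* genome, the single best
subject by bit score (ties: lower `E`, longer alignment, lexicographic id)
and draws an undirected edge only where the choice is mutual.  The graph is
strictly between-genome: within-genome ("recent paralog") edges are not
added, which is the one documented deviation from full OrthoMCL behavior
and a caveat when comparing absolute family counts on real proteomes rich
in in-paralogs.  Edge weights are `-log10(max(E, 1e-180))` averaged over
the two directions.

`mcl_cluster()` is a from-scratch Markov clustering: self-loops at each
node's maximum incident weight (1 for isolated nodes), column
normalization, then alternating expansion (matrix squaring) and inflation
(entrywise power, default 1.5, then renormalization) until the maximum
entrywise change drops below `1e-8` or 200 iterations pass, with entries
below `1e-12` pruned each round.  Clusters are connected components of the
attractor structure (rows with positive diagonal claim their positive
columns); isolated nodes become singletons.  Tests verify the
textbook-expected behavior: clusters refine connected components, weakly
bridged cliques split at inflation 1.5, and granularity is monotone in the
inflation on that family.

# Pan-genome partition

All set definitions operate on the cluster-by-genome presence matrix with
"present" meaning at least one member (paralog multiplicity never affects
status): *core* families have a member in every genome; *clade-conserved*
families have a member in every clade genome (outside presence allowed);
*clade-exclusive* families additionally have none outside; *unique* genes
sit in singleton clusters.  The reported core size is a count of clusters,
not genes — the only consistent reading of a "core genome of N genes" over
ortholog families.

# Concatenated core-gene phylogeny

Each core family is aligned with a small progressive aligner: a guide tree
from k-mer (k = 3) count distances and neighbor joining, midpoint-rooted,
then bottom-up profile–profile global alignment under BLOSUM62 with affine
gaps (open 10, extend 0.5).  The aligner is deliberately modest — it is not
a ClustalW re-implementation, and tree-level results are what the package
stands behind.  When a genome has several members in a core family, the
representative is the member with the highest summed bit score against the
family's members in other genomes (ties: longer, then lexicographic id).

The per-family alignments are concatenated (partition boundaries recorded),
and *complete deletion* removes every column containing a gap or `X` before
any distance is computed.  Distances are Poisson-corrected,
`d = -ln(1 - p)` for the proportion `p` of differing columns — the
appropriate correction when substitutions arrive as a Poisson process with
uniform rates, which is exactly the process the generator uses, making the
estimator consistent on synthetic data by construction.  A pair with
`p >= 1` has no defined distance and is a named error rather than a silent
`Inf`.

`nj_tree()` is a from-scratch Saitou–Nei agglomeration with the standard
`Q` criterion and branch-length formulas; negative branch lengths are
clamped to zero with the deficit moved to the sister branch, matching the
desktop phylogeny software whose output this pipeline mirrors.  `ape::nj()`
and `phangorn::RF.dist()` serve as independent oracles in the test suite —
on random additive matrices both implementations must agree with the
generating tree exactly (paths within `1e-9`).

`bootstrap_consensus()` resamples alignment columns with replacement to the
original length, recomputes distance and tree per replicate, and reports
for each internal bipartition of the full-data NJ tree the percentage of
replicates containing it; branches under 50% are collapsed into polytomies
(majority rule, with branch lengths taken from the full-data tree).
Replicates where the Poisson distance is undefined are discarded; more than
10% discarded is an error.  Column resampling depends only on the seed and
the alignment length, so supports are invariant to taxon input order.
Midpoint rooting is delegated to `phangorn::midpoint()` behind a validating
wrapper (the 2-leaf case is handled directly).

# Translated fragment recruitment

`translated_search()` emulates a six-frame translated search (the tBLASTx
setting of the original analysis): all six frames of each query gene
against all six frames of each read, in protein space, Smith–Waterman under
BLOSUM62 with the same Karlin–Altschul statistics, expectation cutoff
`1e-4`, and no cap on reported hits.  Stop codons in translated frames are
aligned as `*` with the standard BLOSUM62 penalties.  For speed, candidate
frame pairs are pre-screened by exact shared amino-acid words (size 4,
at least 2 shared).  This screen is lossless at the stated cutoff: at the
database sizes involved a passing alignment needs a raw score implying at
least ~24 identical aligned residues in at most 7 runs, which forces at
least 3 exact shared 4-words; `word_size = NULL` disables the screen for
exhaustive behavior on tiny inputs.

The reciprocal filter mirrors the original "top four results" rule:
`reciprocal_filter()` searches the aligned read segment (not the whole
read) against a labelled viral protein panel, ranks panel proteins by bit
score (ties: lower `E`, then lexicographic phage name), and keeps the hit
iff the focal phage appears at rank `<= k` (default 4, chosen because a
panel can contain several close relatives of the focal phage).

Counting and normalization follow the published procedure exactly: a read
contributes at most one count per gene per sample (HSP multiplicity would
double-count long genes); each count is divided by the number of sequences
in the sample's database (taken from metadata — the full database size,
not the subset processed) and by the gene-product length in residues; the
whole matrix is then scaled by its grand mean, computed over all
gene-by-sample cells including zeros — the only reading under which a
perfectly uniform design scales to exactly 1 everywhere.  Per-environment
summaries are means of normalized values over each environment's samples.

# The synthetic-data generator

`simulate_genomes()` emulates the genome architecture the comparative
stage expects: a syntenic core (families in a fixed ancestral order),
clade-exclusive and partially shared accessory families inserted at fixed
hotspots between core blocks, orphan genes unique to single genomes, and
intergenic spacers at 49% GC (the GC content of the roseophage genomes this
generator is shaped after).  Protein evolution is a Poisson substitution
process with uniform exchangeabilities along a random rooted binary tree;
branch lengths are drawn uniform on [0.1, 1] before scaling — bounded away
from zero so that every internal edge carries phylogenetic signal — and
scaled so the mean root-to-tip depth equals the requested divergence in
expected substitutions per site.  Codons are inherited along the tree and
redrawn (uniformly among synonymous codons) only at substituted sites, so
zero divergence yields byte-identical core genes and shared-lineage
substitutions share codons.  Site 1 is pinned to `M` so every planted gene
keeps a valid initiator.

`simulate_metagenome()` draws reads as exact substrings: source genome
proportional to abundance weight *times genome length* (weights are genome
copy numbers; a shotgun read samples bases, so a genome's read share scales
with copies times size — this is precisely the length confound the
abundance normalization is designed to invert), position and strand
uniform, plus an i.i.d. background fraction at the genomes' mean GC.
Everything is byte-deterministic per seed.

What the generator does *not* emulate — and hence what green tests do not
establish about real data: within-gene indels (alignments of synthetic
families are gapless, so complete deletion is only lightly exercised),
in-paralogs and gene duplication, recombination and gene gain/loss along
the tree, codon-usage and amino-acid composition bias (uniform synonymous
codons put coding GC near 47%, slightly below the 49% spacers), sequencing
error, and the scale and taxonomic breadth of real metagenome databases.
Results on real proteomes, particularly absolute family counts, can differ
for exactly these reasons.

# Study-shaped conditions and problem sizes

The default validation scenario (`paper_shaped_scenario()`) is 25 genomes,
14 core families, one 5-genome clade with 9 exclusive plus 10 partially
shared families (hence 33 clade-conserved), 2 orphans per genome, and
divergence 0.2 — the shape of the genus analysis this package
re-implements, with gene lengths reduced to 150–300 nt so the all-vs-all
stage (about 590 proteins) runs in about a minute on one core.  The
recruitment scenario uses 3 samples of 10,000 reads (25% background) over
five genomes whose per-copy abundances span a 4:1 extreme ratio in five
distinct levels (4, 2.5, 2, 1.5, 1; two genes per genome).  Distinct
levels, rather than two tied groups, were chosen deliberately: with only
two abundance levels the tie structure caps the Spearman correlation
between planted and recovered abundances at about 0.87 regardless of how
perfect the recovery is, so a two-level design cannot demonstrate rank
recovery.  Bootstrap replicate counts are reduced (50–200) in scripted
runs; the `run_config()` default remains 1000.

# Numerical choices and degenerate inputs

* MCL: convergence at maximum entrywise change `< 1e-8`, pruning floor
  `1e-12`, attractor threshold `1e-6`; non-symmetric input is an error.
* NJ pair selection ties resolve to the first minimum in column-major
  order; best-hit ties resolve by lower `E`, longer alignment, then
  lexicographic subject id — all choices are deterministic and documented
  where they matter.
* Poisson distance refuses `p >= 1`; the bootstrap discards such
  replicates and refuses if more than 10% are lost.
* `gc_content()` excludes `N` from numerator and denominator and refuses
  all-`N` input; FASTA parsing accepts only `{A,C,G,T,N}` and fails fast
  on other ambiguity codes, which the genome records in scope do not use.
* The grand-mean abundance scaling refuses an all-zero count matrix unless
  explicitly told to return zeros (`allow_zero = TRUE`), because a zero
  scaling mean is undefined rather than zero.
* Progressive alignment falls back to sequential merging in input order
  when all k-mer distances are zero (identical sequences), where any guide
  tree is equivalent.

# Limitations

The aligner is profile-based without iterative refinement; trees are
distance-based NJ only (no likelihood or Bayesian alternative); the
similarity backend is exact Smith–Waterman, feasible at desk scale and
importable from external tabular hit files (`read_hits()`) for larger
runs; and the in-paralog simplification above means real-proteome family
counts should be read with that caveat.  Functional annotation of core
genes, tRNA detection, promoter search, and assembly are out of scope.
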