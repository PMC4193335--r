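# n4core

Comparative-genomics and metagenome-recruitment toolkit for phage genera,
shaped after the analysis that delineated the core genome of the N4-like
podoviruses and mapped the ocean-wide distribution of their
*Roseobacter*-infecting members (RN4 phages).  It is written for
phage/virome researchers who want that workflow as tested, reusable R
functions rather than a one-off collection of scripts.

The pipeline covers five stages:

1. **CDS amalgamation** — reconcile two gene predictors' call sets by
   (stop codon, strand); at discordant starts the longer call wins
   (`merge_predictions()`, with a built-in ORF caller `find_orfs()`).
2. **Ortholog families** — all-vs-all Smith–Waterman (BLOSUM62, gap
   11/1) with Karlin–Altschul statistics *E* = *K m n* e^(−λS)
   (λ = 0.267, *K* = 0.041), cutoff *E* ≤ 10⁻⁶; bidirectional best hits;
   Markov clustering at inflation *I* = 1.5
   (`all_vs_all()`, `bbh_graph()`, `mcl_cluster()`).
3. **Pan-genome partition** — core, clade-conserved, clade-exclusive and
   genome-unique gene sets from the presence matrix
   (`core_clusters()`, `conserved_clusters()`, `exclusive_clusters()`,
   `unique_genes()`).
4. **Core-gene phylogeny** — per-family progressive alignment,
   concatenation, complete deletion of gapped columns, Poisson-corrected
   distances *d* = −ln(1 − *p*), Saitou–Nei neighbor joining, bootstrap
   consensus with <50% branches collapsed, midpoint rooting
   (`nj_tree()`, `bootstrap_consensus()`, `midpoint_root()`).
5. **Fragment recruitment** — six-frame translated search of metagenome
   reads (*E* ≤ 10⁻⁴), reciprocal top-*k* filtering against a viral
   panel (*k* = 4), per-read counting, and normalized relative abundance:
   counts divided by database size and gene-product length, scaled by the
   grand mean (`translated_search()`, `reciprocal_filter()`,
   `abundance()`, `group_by_environment()`).

A synthetic-data generator (`simulate_genomes()`,
`simulate_predictor_pair()`, `simulate_metagenome()`) produces genomes
with a syntenic core evolved along a known tree, planted accessory and
orphan genes, imperfect predictor outputs, and read sets with known
per-genome abundances — so every stage is validated against planted truth.

## Worked example

The numbered scripts under `analysis/` run the whole study at desk scale.
Stage 1 simulates the study-shaped genus (25 genomes, 14 planted core
families, a 5-genome clade with 9 exclusive and 10 partially shared
families, divergence 0.2); stages 2–4 analyse it blind to the truth and
then compare:

```text
$ Rscript analysis/01_simulate.R
simulated 25 genomes (7.5 kb mean, 46.8% GC)
planted 591 genes in 83 families (14 core, 9 clade-exclusive, 10 clade-shared, 50 orphan)

$ Rscript analysis/02_core_genome.R
merged 591 + 591 predictions into 591 CDS calls
all-vs-all: 591 proteins, 10974 hits at E <= 1e-6
pan-genome: 83 families total; 14 core in all 25 genomes
clade (G01,G02,G03,G04,G05): 33 conserved, of which 9 exclusive

$ Rscript analysis/03_phylogeny.R
concatenated core alignment: 25 genomes x 961 columns after complete deletion
Robinson-Foulds distance to the generating topology: 0

$ Rscript analysis/04_recruitment.R
recovered extreme abundance ratio: 4.11 (planted 4.00)
rank correlation with planted abundances: 0.985
```

Reading the numbers: the ortholog stage reconstructs exactly the planted
family structure (14 core, 33 clade-conserved, 9 clade-exclusive), the
concatenated core-gene NJ tree is topologically identical to the
generating tree (RF = 0), and recruitment recovers the planted 4:1
abundance gradient within 3% with near-perfect rank agreement.  The same
calls work on real genomes: read FASTA with `read_genome_fasta()`, CDS
GFF3 with `read_gff3()` (or import external tabular hits with
`read_hits()`), and run `run_core_workflow()` / `run_recruit_workflow()`.

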