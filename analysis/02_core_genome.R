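#!/usr/bin/env Rscript

# Stage 2: CDS amalgamation, orthology and the pan-genome partition.
#
# Merges the two predictor call sets per genome (longer call wins at
# discordant starts), runs the all-vs-all protein search (E <= 1e-6),
# builds the bidirectional-best-hit graph, clusters it with MCL at
# inflation 1.5, and partitions the families into core / clade-conserved /
# clade-exclusive / genome-unique sets.

suppressMessages({ library(n4core); library(Biostrings) })

sim_dir <- "results/sim"
out <- "results/core"
dir.create(out, showWarnings = FALSE, recursive = TRUE)

genomes <- read_genome_fasta(file.path(sim_dir, "genomes.fasta"))
predA <- read_gff3(file.path(sim_dir, "predA.gff3"))
predB <- read_gff3(file.path(sim_dir, "predB.gff3"))
clade <- sprintf("G%02d", 1:5)

merged <- do.call(rbind, lapply(names(genomes), function(g) {
  merge_predictions(predA[predA$genome_id == g, ],
                    predB[predB$genome_id == g, ])
}))
cat(sprintf("merged %d + %d predictions into %d CDS calls\n",
            nrow(predA), nrow(predB), nrow(merged)))
write_gff3(merged, file.path(out, "merged_cds.gff3"))

tr <- translate_calls(genomes, merged)
hits <- all_vs_all(tr$proteins, evalue_max = 1e-6)
cat(sprintf("all-vs-all: %d proteins, %d hits at E <= 1e-6\n",
            length(tr$proteins), nrow(hits)))
write_hits(hits, file.path(out, "hits.tsv"))

graph <- bbh_graph(hits, tr$genome_of)
clusters <- mcl_cluster(graph, inflation = 1.5)
write_clusters(clusters, file.path(out, "clusters.tsv"))
m <- presence_matrix(clusters, names(genomes))
write_presence_matrix(m, file.path(out, "presence.tsv"))

core <- core_clusters(m)
conserved <- conserved_clusters(m, clade)
exclusive <- exclusive_clusters(m, clade)
cat(sprintf("pan-genome: %d families total; %d core in all %d genomes\n",
            nrow(m), length(core), ncol(m)))
cat(sprintf("clade (%s): %d conserved, of which %d exclusive\n",
            paste(clade, collapse = ","), length(conserved), length(exclusive)))
for (g in c("G01", "G02")) {
  cat(sprintf("unique genes in %s: %s\n", g,
              paste(unique_genes(clusters, g), collapse = " ")))
}
sets <- rbind(data.frame(set = "core", cluster_id = core),
              data.frame(set = "conserved", cluster_id = conserved),
              data.frame(set = "exclusive", cluster_id = exclusive))
write.table(sets, file.path(out, "gene_sets.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
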