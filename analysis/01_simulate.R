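#!/usr/bin/env Rscript

# Stage 1: generate the study-shaped synthetic phage genus.
#
# 25 genomes evolved along a known tree at 0.2 expected amino-acid
# substitutions per site, carrying 14 core families, a 5-genome clade with
# 9 exclusive and 10 partially shared accessory families, and 2 orphan
# genes per genome — the same shape as the phage genus whose comparative
# analysis this package re-implements.  Writes genomes, planted gene
# models, the generating tree and two imperfect predictor call sets.

suppressMessages({ library(n4core); library(Biostrings) })

seed <- 42L
out <- "results/sim"
dir.create(out, showWarnings = FALSE, recursive = TRUE)

scn <- paper_shaped_scenario(seed = seed)
sim <- do.call(simulate_genomes, scn)

write_fasta(sim$genomes, file.path(out, "genomes.fasta"))
write_gff3(sim$truth$coords[, c("genome_id", "gene_id", "start", "end",
                                "strand", "source")],
           file.path(out, "planted_cds.gff3"))
ape::write.tree(sim$truth$tree, file.path(out, "true_tree.nwk"))
write.table(sim$truth$families, file.path(out, "families.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)

pp <- simulate_predictor_pair(sim$truth, start_error_rate = 0.2, miss_rate = 0,
                              seed = derive_seed(seed, "predictors"))
write_gff3(pp$predA, file.path(out, "predA.gff3"))
write_gff3(pp$predB, file.path(out, "predB.gff3"))

cat(sprintf("simulated %d genomes (%.1f kb mean, %.1f%% GC)\n",
            length(sim$genomes), mean(width(sim$genomes)) / 1000,
            100 * mean(gc_content(sim$genomes))))
cat(sprintf("planted %d genes in %d families (%d core, %d clade-exclusive, %d clade-shared, %d orphan)\n",
            nrow(sim$truth$coords),
            length(unique(sim$truth$families$family_id)),
            sum(table(sim$truth$families$family_id,
                      sim$truth$families$class)[, "core"] > 0),
            length(unique(sim$truth$families$family_id[
              sim$truth$families$class == "clade_exclusive"])),
            length(unique(sim$truth$families$family_id[
              sim$truth$families$class == "clade_shared"])),
            sum(sim$truth$families$class == "orphan")))
cat("outputs in", out, "\n")
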