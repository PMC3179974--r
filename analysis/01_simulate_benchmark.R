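#!/usr/bin/env Rscript
# Step 1: generate the synthetic benchmark bundle used by the rest of the
# analysis — a 40-organism Yule species tree, a consistent taxonomy, 60
# gene-family distance matrices of which 20 pairs co-evolve (rho = 0.9,
# sigma = 0.3, 90% organism retention), and the matching gold standard.
# Everything is written as plain text under results/benchmark/.

suppressMessages(library(coevotree))

cfg <- sim_config(seed = 1)
bm <- simulate_benchmark(cfg)
write_benchmark(bm, "results/benchmark")

# companion hit table so the orthology stage can be exercised on files
ht <- simulate_hit_table(bm, seed = 1)
dir.create("results/benchmark", showWarnings = FALSE, recursive = TRUE)
write_hit_table(ht$hits, "results/benchmark/hits.tsv")
write.table(data.frame(protein = names(ht$genome_of),
                       genome = unname(ht$genome_of),
                       length = unname(ht$seq_lengths[names(ht$genome_of)])),
            "results/benchmark/proteins.tsv",
            sep = "\t", quote = FALSE, row.names = FALSE)

cat(sprintf("benchmark: %d organisms, %d families, %d interacting pairs\n",
            length(bm$species_tree$tip.label), length(bm$family_matrices),
            nrow(bm$interacting)))
cat(sprintf("gold standard: P = %d, N = %d\n", bm$gold$P, bm$gold$N))
cat(sprintf("hit table: %d rows over %d proteins\n", nrow(ht$hits),
            length(ht$genome_of)))
cat("written to results/benchmark/\n")
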