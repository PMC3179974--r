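#!/usr/bin/env Rscript
# Step 2: sample organism subsets from the benchmark taxonomy under the
# two criteria — "nearest" (growing clades around a reference organism)
# and "level" (one largest-proteome genome per group at each taxonomic
# depth) — and write each set as a one-genome-per-line file.

suppressMessages(library(coevotree))

tax <- read_taxonomy("results/benchmark/taxonomy.tsv",
                     genomes_source = "results/benchmark/genomes.tsv")
ref <- "org001"

dir.create("results/organism_sets", showWarnings = FALSE, recursive = TRUE)
near <- sample_nearest(tax, ref)
lev <- sample_level(tax)
for (s in c(near, lev))
  write_organism_set(s, file.path("results/organism_sets",
                                  paste0(s$label, ".txt")))

cat("reference organism:", ref, "\n")
cat("nearest sets:",
    paste(sprintf("%s(%d)", sapply(near, `[[`, "label"),
                  sapply(near, function(s) length(s$genomes))),
          collapse = " "), "\n")
cat("level sets:",
    paste(sprintf("%s(%d)", sapply(lev, `[[`, "label"),
                  sapply(lev, function(s) length(s$genomes))),
          collapse = " "), "\n")
cat("written to results/organism_sets/\n")
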