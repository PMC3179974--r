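#!/usr/bin/env Rscript
# Step 5: the two qualitative scenario experiments.
#
# (a) Strain redundancy: duplicate 10 leaves as epsilon-distant strains
#     and compare how the background (non-interacting) score level moves
#     for mirrortree vs profile-correlation.
# (b) Interaction age: confine the co-evolution signal to a 30% clade
#     ("recent" interactions) and compare mirrortree's AUC on clade-only
#     vs all organisms; repeat with taxonomy-wide signal ("old").

suppressMessages(library(coevotree))
label_pairs <- getFromNamespace("label_pairs", "coevotree")
pick_clade <- getFromNamespace("pick_clade", "coevotree")

rows <- list()

## (a) redundancy -------------------------------------------------------------
for (s in 1:10) {
  for (strains in c(0, 10)) {
    cfg <- sim_config(retention_prob = 1, redundancy_strains = strains,
                      strain_epsilon = 1e-3, seed = 100 + s)
    b <- simulate_benchmark(cfg)
    sm <- build_score_matrix(b$family_matrices)
    mt <- score_matrix_to_table(sm); pc <- pc_score_table(sm)
    rows[[length(rows) + 1L]] <- data.frame(
      experiment = "redundancy", replicate = s, strains = strains,
      mt_background = mean(mt$score[label_pairs(mt, b$gold) == 0],
                           na.rm = TRUE),
      pc_background = mean(pc$score[label_pairs(pc, b$gold) == 0],
                           na.rm = TRUE),
      auc_mt = roc_curve(mt, b$gold)$auc,
      auc_pc = roc_curve(pc, b$gold)$auc)
  }
}

## (b) interaction age --------------------------------------------------------
auc_on <- function(b, orgs) {
  fams <- lapply(b$family_matrices, function(m) {
    k <- intersect(rownames(m), orgs); m[k, k, drop = FALSE]
  })
  t <- mt_score_table(fams)
  if (!nrow(t)) return(NA_real_)
  roc_curve(t, b$gold)$auc
}
for (s in 1:10) {
  for (fraction in c(0.3, 1)) {
    cfg <- sim_config(n_organisms = 60, retention_prob = 1,
                      recent_clade_fraction = fraction, seed = 200 + s)
    b <- simulate_benchmark(cfg)
    clade <- if (fraction < 1) b$clade_organisms
             else pick_clade(b$species_tree, 0.3)
    rows[[length(rows) + 1L]] <- data.frame(
      experiment = ifelse(fraction < 1, "recent", "old"), replicate = s,
      strains = NA, mt_background = NA, pc_background = NA,
      auc_mt = auc_on(b, clade),          # clade-only organism set
      auc_pc = auc_on(b, b$species_tree$tip.label))  # all organisms
  }
}

out <- do.call(rbind, rows)
dir.create("results", showWarnings = FALSE)
write.table(out, "results/properties.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)

red <- out[out$experiment == "redundancy", ]
d_mt <- with(red, mt_background[strains == 10] - mt_background[strains == 0])
d_pc <- with(red, pc_background[strains == 10] - pc_background[strains == 0])
cat(sprintf("redundancy: mean background rise MT %+0.4f vs PC %+0.4f (MT > PC in %d/10)\n",
            mean(d_mt), mean(d_pc), sum(d_mt > d_pc)))
rec <- out[out$experiment == "recent", ]
cat(sprintf("recent interactions: AUC clade-only %.3f vs all organisms %.3f (clade wins %d/10)\n",
            mean(rec$auc_mt), mean(rec$auc_pc), sum(rec$auc_mt > rec$auc_pc)))
old <- out[out$experiment == "old", ]
cat(sprintf("old interactions:    AUC clade-only %.3f vs all organisms %.3f\n",
            mean(old$auc_mt), mean(old$auc_pc)))
cat("table written to results/properties.tsv\n")
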