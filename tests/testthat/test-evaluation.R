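scored_df <- function(a, b, s)
  data.frame(protein_a = a, protein_b = b, score = s,
             stringsAsFactors = FALSE)

test_that("gold-standard files are unordered, de-duplicated and self-pair safe", {
  tmp <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("A\tB", "B\tA", "C\tD"), tmp)
  pos <- read_gold_standard(tmp)
  expect_equal(nrow(pos), 2)
  writeLines(c("A\tB", "C\tC"), tmp)
  expect_error(read_gold_standard(tmp), "format-error.*2")
})

test_that("negative sets are all pairs among involved proteins minus positives", {
  g1 <- generate_negatives(scored_df("A", "B", 1)[1:2])
  expect_equal(g1$N, 0)
  g2 <- generate_negatives(data.frame(protein_a = c("A", "C"),
                                      protein_b = c("B", "D")))
  expect_equal(g2$P, 2)
  expect_equal(g2$N, 4)                       # C(4,2) - 2
  set.seed(3)
  prots <- sprintf("p%02d", 1:12)
  pos <- t(combn(prots, 2))[sample(choose(12, 2), 10), ]
  g3 <- generate_negatives(data.frame(protein_a = pos[, 1],
                                      protein_b = pos[, 2]))
  # brute-force oracle: enumerate all pairs among the involved proteins
  involved <- sort(unique(c(pos)))
  all_keys <- apply(t(combn(involved, 2)), 1, function(p)
    paste(sort(p), collapse = "|"))
  pos_keys <- apply(pos, 1, function(p) paste(sort(p), collapse = "|"))
  expect_equal(g3$N, length(setdiff(all_keys, pos_keys)))
  expect_equal(g3$N, choose(length(involved), 2) - 10)
  expect_length(intersect(paste(g3$positives[[1]], g3$positives[[2]]),
                          paste(g3$negatives[[1]], g3$negatives[[2]])), 0)
})

test_that("gold standards round-trip through TSV", {
  bm <- simulate_benchmark(sim_config(n_organisms = 8, n_families = 8,
                                      n_interacting_pairs = 3, seed = 2))
  tmp <- withr::local_tempfile(fileext = ".tsv")
  write_gold_standard(bm$gold, tmp)
  df <- read.table(tmp, header = TRUE, sep = "\t",
                   stringsAsFactors = FALSE)
  pos <- df[df$label == "positive", c("protein_a", "protein_b")]
  back <- generate_negatives(pos, label = "simulated")
  expect_equal(back$P, bm$gold$P)
  expect_equal(back$N, bm$gold$N)
})

test_that("totals-based ROC: perfect ranking, partial coverage, tie handling", {
  pos <- data.frame(protein_a = paste0("p", 1:10),
                    protein_b = paste0("q", 1:10))
  gold <- generate_negatives(pos)
  # perfect full-coverage ranking -> AUC exactly 1
  all_pairs <- rbind(
    cbind(gold$positives, score = 1 + seq_len(gold$P)),
    cbind(gold$negatives, score = -seq_len(gold$N)))
  expect_equal(roc_curve(all_pairs, gold)$auc, 1.0)
  # scoring only half of each class, still perfectly ranked: the curve
  # terminates at the coverage-scaled endpoint, not (1, 1)
  half <- rbind(
    cbind(gold$positives[1:5, ], score = 100 + 1:5),
    cbind(gold$negatives[seq_len(floor(gold$N / 2)), ], score = -(1:floor(gold$N / 2))))
  roc_half <- roc_curve(half, gold)
  last <- roc_half$points[nrow(roc_half$points), ]
  expect_equal(last$TPR, 5 / gold$P)
  expect_equal(last$FPR, floor(gold$N / 2) / gold$N)
  expect_lt(last$TPR, 1)
  # tied scores move in a single threshold step
  tied <- rbind(cbind(gold$positives[1:2, ], score = 5),
                cbind(gold$negatives[1:2, ], score = 5))
  roc_tied <- roc_curve(tied, gold)
  expect_equal(nrow(roc_tied$points), 1)
  expect_equal(roc_tied$points$Tp, 2)
  expect_equal(roc_tied$points$Fp, 2)
})

test_that("ROC points equal a hand-enumerated sweep on a 20-pair toy list", {
  set.seed(14)
  pos <- data.frame(protein_a = paste0("a", 1:5), protein_b = paste0("b", 1:5))
  gold <- generate_negatives(pos)          # P = 5, N = 40
  scored <- rbind(cbind(gold$positives, score = round(rnorm(5, 1), 2)),
                  cbind(gold$negatives[1:15, ], score = round(rnorm(15), 2)))
  roc <- roc_curve(scored, gold)
  labels <- c(rep(1, 5), rep(0, 15))
  want <- oracle_roc_points(scored$score, labels, gold$P, gold$N)
  expect_equal(roc$points$threshold, want$threshold)
  expect_equal(roc$points$TPR, want$TPR)
  expect_equal(roc$points$FPR, want$FPR)
  # conservation at every threshold: Tp <= P, Fp <= N, monotone
  expect_true(all(diff(roc$points$Tp) >= 0))
  expect_true(all(roc$points$Tp <= gold$P & roc$points$Fp <= gold$N))
})

test_that("full-coverage ROC agrees with a reference implementation", {
  skip_if_not_installed("pROC")
  set.seed(6)
  pos <- data.frame(protein_a = paste0("a", 1:20),
                    protein_b = paste0("b", 1:20))
  gold <- generate_negatives(pos)
  scored <- rbind(
    cbind(gold$positives, score = rnorm(gold$P, 1)),
    cbind(gold$negatives, score = rnorm(gold$N, 0)))
  mine <- roc_curve(scored, gold)$auc
  ref <- suppressMessages(pROC::auc(pROC::roc(
    response = c(rep(1, gold$P), rep(0, gold$N)),
    predictor = scored$score, direction = "<")))
  expect_equal(mine, as.numeric(ref), tolerance = 1e-12)
})

test_that("a random scorer sits on the diagonal for balanced toy gold", {
  set.seed(77)
  pos <- data.frame(protein_a = sprintf("x%03d", 1:500),
                    protein_b = sprintf("y%03d", 1:500))
  neg <- data.frame(protein_a = sprintf("v%03d", 1:500),
                    protein_b = sprintf("w%03d", 1:500))
  gold <- coevotree:::new_gold_standard(pos, neg)
  scored <- rbind(cbind(pos, score = runif(500)),
                  cbind(neg, score = runif(500)))
  expect_gt(roc_curve(scored, gold)$auc, 0.45)
  expect_lt(roc_curve(scored, gold)$auc, 0.55)
})

test_that("precision/recall and max-F behave on canonical cases", {
  pos <- data.frame(protein_a = paste0("a", 1:4), protein_b = paste0("b", 1:4))
  gold <- generate_negatives(pos)
  perfect <- rbind(cbind(gold$positives, score = 10 + 1:4),
                   cbind(gold$negatives, score = -seq_len(gold$N)))
  expect_equal(pr_curve(perfect, gold)$max_f, 1.0)
  # single positive ranked first of 10: at the top-1 threshold
  # precision = recall = F = 1
  g1 <- coevotree:::new_gold_standard(
    data.frame(protein_a = "a", protein_b = "b"),
    data.frame(protein_a = paste0("n", 1:9), protein_b = paste0("m", 1:9)))
  s1 <- rbind(scored_df("a", "b", 10),
              scored_df(paste0("n", 1:9), paste0("m", 1:9), 9:1))
  pr1 <- pr_curve(s1, g1)
  expect_equal(pr1$points$F[1], 1.0)
  expect_equal(pr1$max_f, 1.0)
  # hand-computed table on a small list
  g2 <- coevotree:::new_gold_standard(
    data.frame(protein_a = c("a", "c"), protein_b = c("b", "d")),
    data.frame(protein_a = c("e", "g"), protein_b = c("f", "h")))
  s2 <- rbind(scored_df("a", "b", 4), scored_df("e", "f", 3),
              scored_df("c", "d", 2), scored_df("g", "h", 1))
  pr2 <- pr_curve(s2, g2)
  expect_equal(pr2$points$precision, c(1, 1/2, 2/3, 1/2))
  expect_equal(pr2$points$recall, c(1/2, 1/2, 1, 1))
  expect_equal(pr2$max_f, 2 * (2/3) * 1 / (2/3 + 1))
})

test_that("per-protein ranking uses the in-list Mann-Whitney convention", {
  g <- coevotree:::new_gold_standard(
    data.frame(protein_a = "P", protein_b = "I1"),
    data.frame(protein_a = rep("P", 9), protein_b = paste0("N", 1:9)))
  top <- rbind(scored_df("P", "I1", 10),
               scored_df(rep("P", 9), paste0("N", 1:9), 9:1))
  r_top <- rank_interactors(top, "P", g)
  expect_equal(r_top$auc_local, 1.0)
  expect_equal(r_top$n_candidates, 10)
  expect_equal(r_top$n_positives, 1)
  expect_identical(r_top$top_partner, "I1")
  bottom <- rbind(scored_df("P", "I1", 0),
                  scored_df(rep("P", 9), paste0("N", 1:9), 9:1 + 10))
  expect_equal(rank_interactors(bottom, "P", g)$auc_local, 0.0)
  expect_error(rank_interactors(top, "Q", g), "not-found")
})

test_that("local AUC equals the normalized Mann-Whitney U on random lists", {
  set.seed(55)
  for (rep in 1:10) {
    npos <- sample(2:5, 1); nneg <- sample(5:15, 1)
    g <- coevotree:::new_gold_standard(
      data.frame(protein_a = rep("P", npos), protein_b = paste0("I", 1:npos)),
      data.frame(protein_a = rep("P", nneg), protein_b = paste0("N", 1:nneg)))
    scores <- round(rnorm(npos + nneg), 1)   # ties likely
    s <- rbind(scored_df(rep("P", npos), paste0("I", 1:npos),
                         scores[1:npos]),
               scored_df(rep("P", nneg), paste0("N", 1:nneg),
                         scores[-(1:npos)]))
    got <- rank_interactors(s, "P", g)$auc_local
    w <- wilcox.test(scores[1:npos], scores[-(1:npos)],
                     exact = FALSE, correct = FALSE)
    expect_equal(got, unname(w$statistic) / (npos * nneg), tolerance = 1e-12)
  }
})

test_that("the experiment grid is deterministic and separates a clean benchmark", {
  cfg <- sim_config(n_organisms = 25, n_families = 12,
                    n_interacting_pairs = 4, noise_sd = 0.3,
                    retention_prob = 1, seed = 5)
  bm <- simulate_benchmark(cfg)
  ex1 <- run_experiment(bm, methods = c("mt", "pc"))
  ex2 <- run_experiment(bm, methods = c("mt", "pc"))
  expect_identical(ex1$summary, ex2$summary)
  expect_equal(ex1$summary$auc[ex1$summary$method == "mt"], 1.0)
  expect_true(all(c("coverage", "max_f") %in% names(ex1$summary)))
})
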