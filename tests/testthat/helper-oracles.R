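# Independent oracles used across the suite.  Each deliberately re-derives
# its quantity by the most direct brute-force route (explicit loops,
# residual regressions, path enumeration) so that it shares no code with
# the implementation it checks.

# Pearson correlation between two distance matrices over explicitly
# enumerated common organism pairs, from the raw sum formulas.
oracle_mt_r <- function(dmA, dmB) {
  com <- sort(intersect(rownames(dmA), rownames(dmB)))
  va <- c(); vb <- c()
  for (i in seq_along(com)) {
    for (j in seq_along(com)) {
      if (i < j) {
        va <- c(va, dmA[com[i], com[j]])
        vb <- c(vb, dmB[com[i], com[j]])
      }
    }
  }
  n <- length(va)
  num <- n * sum(va * vb) - sum(va) * sum(vb)
  den <- sqrt(n * sum(va^2) - sum(va)^2) * sqrt(n * sum(vb^2) - sum(vb)^2)
  num / den
}

# Partial correlation of columns 1 and 2 of a data matrix given the
# remaining columns, via explicit least-squares residuals.
oracle_residual_pcor <- function(X) {
  if (ncol(X) == 2) return(cor(X[, 1], X[, 2]))
  ctrl <- X[, -(1:2), drop = FALSE]
  ra <- resid(lm(X[, 1] ~ ctrl))
  rb <- resid(lm(X[, 2] ~ ctrl))
  cor(ra, rb)
}

# Patristic distances by breadth-first path enumeration over the tree's
# edge list (no reuse of cophenetic).
oracle_patristic <- function(tree) {
  n <- length(tree$tip.label)
  nv <- n + tree$Nnode
  adj <- vector("list", nv)
  for (e in seq_len(nrow(tree$edge))) {
    a <- tree$edge[e, 1]; b <- tree$edge[e, 2]; w <- tree$edge.length[e]
    adj[[a]] <- rbind(adj[[a]], c(b, w))
    adj[[b]] <- rbind(adj[[b]], c(a, w))
  }
  d <- matrix(NA_real_, n, n, dimnames = list(tree$tip.label, tree$tip.label))
  for (s in seq_len(n)) {
    dist <- rep(NA_real_, nv)
    dist[s] <- 0
    queue <- s
    while (length(queue)) {
      cur <- queue[1]; queue <- queue[-1]
      for (k in seq_len(NROW(adj[[cur]]))) {
        nb <- adj[[cur]][k, 1]; w <- adj[[cur]][k, 2]
        if (is.na(dist[nb])) {
          dist[nb] <- dist[cur] + w
          queue <- c(queue, nb)
        }
      }
    }
    d[s, ] <- dist[seq_len(n)]
  }
  diag(d) <- 0
  d
}

# Reciprocal best hits by a double loop over proteins, recomputing "best"
# from scratch for every query.
oracle_rbh <- function(hits, genome_a, genome_b) {
  best_of <- function(q, target_genome) {
    rows <- hits[hits$query_id == q & hits$subject_genome == target_genome &
                   hits$subject_id != q, , drop = FALSE]
    if (!nrow(rows)) return(NA_character_)
    rows <- rows[order(rows$e_value, -rows$bit_score, rows$subject_id), ,
                 drop = FALSE]
    rows$subject_id[1]
  }
  qa <- sort(unique(hits$query_id[hits$query_genome == genome_a]))
  out <- character(0)
  pairs <- data.frame(protein_a = character(0), protein_b = character(0))
  for (p in qa) {
    q <- best_of(p, genome_b)
    if (!is.na(q) && identical(best_of(q, genome_a), p))
      pairs <- rbind(pairs, data.frame(protein_a = p, protein_b = q))
  }
  pairs[order(pairs$protein_a), , drop = FALSE]
}

# Random labeled distance matrix (symmetric, zero diagonal, positive).
random_dist_matrix <- function(labels) {
  n <- length(labels)
  m <- matrix(0, n, n, dimnames = list(labels, labels))
  m[upper.tri(m)] <- runif(n * (n - 1) / 2, 0.1, 5)
  m + t(m)
}

# ROC points by naive per-threshold recount (no sorting tricks).
oracle_roc_points <- function(scores, labels, P, N) {
  th <- sort(unique(scores), decreasing = TRUE)
  data.frame(
    threshold = th,
    TPR = vapply(th, function(t) sum(labels == 1 & scores >= t) / P, 0),
    FPR = vapply(th, function(t) sum(labels == 0 & scores >= t) / N, 0))
}
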