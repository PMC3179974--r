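# The three tree-similarity co-evolution scorers.
#
# mirrortree (MT): Pearson correlation between two families' patristic
#   distance matrices over their common organisms.
# profile-correlation (PC): correlation between two proteins' rows of the
#   genome-wide significant-score matrix (co-evolutionary profiles).
# context-mirror (CM): partial correlation of a pair given its strongest
#   third-party co-evolutionary "controllers", at increasing levels of
#   specificity.

new_coevo_score <- function(r, n_common, p_value, significant,
                            reason = NA_character_) {
  structure(list(r = r, n_common = n_common,
                 n_pairs = if (is.na(n_common)) NA_integer_
                           else as.integer(n_common * (n_common - 1) / 2),
                 p_value = p_value, significant = isTRUE(significant),
                 reason = reason),
            class = "coevo_score")
}

#' @export
print.coevo_score <- function(x, ...) {
  cat(sprintf("coevo_score: r = %s, n_common = %s, p = %s, significant = %s\n",
              format(x$r), format(x$n_common), format(x$p_value),
              x$significant))
  invisible(x)
}

# Two-sided P-value for a Pearson correlation from the t approximation
# with df degrees of freedom.  Distance-pair observations are treated as
# independent, as in the original method (a documented caveat: pairs
# sharing a leaf are not independent).
pearson_p_value <- function(r, df) {
  if (is.na(r) || df < 1) return(NA_real_)
  if (abs(r) >= 1) return(0)
  tstat <- r * sqrt(df / (1 - r^2))
  2 * pt(-abs(tstat), df)
}

#' Organisms shared by two distance matrices
#'
#' @param dmA,dmB Labeled distance matrices.
#' @return Sorted character vector of common organism labels.
#' @export
common_organisms <- function(dmA, dmB) {
  sort(intersect(rownames(dmA), rownames(dmB)))
}

#' Mirrortree score of two protein families
#'
#' Computes the linear (Pearson) correlation between the two families'
#' inter-ortholog distance matrices, using only distances among organisms
#' present in both.  The two matrices are reduced to their common
#' organisms and the upper triangles, taken in canonical (lexicographic)
#' organism-pair order, are correlated.  A minimum number of common
#' organisms is required for a pair to be evaluable, and the correlation's
#' two-sided t-test P-value (with `n_pairs - 2` degrees of freedom) must
#' pass `p_max` for the score to be significant.
#'
#' @param dmA,dmB Labeled distance matrices for the two families.
#' @param min_common Minimum number of shared organisms (default 15).
#' @param p_max Significance cutoff on the P-value (default 1e-5).
#' @return A `coevo_score`; `r` is `NA` when the pair is not evaluable
#'   (too few common organisms, or zero variance in either distance
#'   vector).
#' @export
mirrortree_score <- function(dmA, dmB, min_common = 15, p_max = 1e-5) {
  com <- common_organisms(dmA, dmB)
  n <- length(com)
  if (n < min_common)
    return(new_coevo_score(NA_real_, n, NA_real_, FALSE, "too-few-common"))
  a <- upper_vec(dmA[com, com, drop = FALSE])
  b <- upper_vec(dmB[com, com, drop = FALSE])
  if (stats::sd(a) == 0 || stats::sd(b) == 0)
    return(new_coevo_score(NA_real_, n, NA_real_, FALSE, "zero-variance"))
  r <- cor(a, b)
  p <- pearson_p_value(r, length(a) - 2)
  new_coevo_score(r, n, p, n >= min_common && !is.na(p) && p <= p_max)
}

#' Genome-wide significant-score matrix
#'
#' Scores every unordered pair of families with [mirrortree_score()] and
#' assembles the symmetric matrix of significant correlations; entries
#' that are not evaluable or not significant are `NA` (the availability
#' mask).  A row of this matrix is a protein's co-evolutionary profile.
#'
#' @param family_matrices Named list of per-family distance matrices.
#' @param min_common,p_max Passed to [mirrortree_score()].
#' @return A `score_matrix`: list with `r` (masked correlation matrix),
#'   `n_common`, `p_value`, and `proteins`.
#' @export
build_score_matrix <- function(family_matrices, min_common = 15,
                               p_max = 1e-5) {
  if (length(family_matrices) < 2)
    stop("invalid-argument: need at least 2 families")
  prots <- names(family_matrices)
  if (is.null(prots) || anyDuplicated(prots))
    stop("invalid-argument: family matrices must be uniquely named")
  k <- length(prots)
  r <- nc <- pv <- matrix(NA_real_, k, k, dimnames = list(prots, prots))
  for (i in seq_len(k - 1)) {
    for (j in (i + 1):k) {
      s <- mirrortree_score(family_matrices[[i]], family_matrices[[j]],
                            min_common, p_max)
      nc[i, j] <- nc[j, i] <- s$n_common
      pv[i, j] <- pv[j, i] <- s$p_value
      if (s$significant) r[i, j] <- r[j, i] <- s$r
    }
  }
  structure(list(r = r, n_common = nc, p_value = pv, proteins = prots),
            class = "score_matrix")
}

#' @export
print.score_matrix <- function(x, ...) {
  k <- length(x$proteins)
  cat("score_matrix:", k, "proteins,",
      sum(!is.na(x$r[upper.tri(x$r)])), "of", k * (k - 1) / 2,
      "pairs significant\n")
  invisible(x)
}

#' Profile-correlation score of two proteins
#'
#' Re-assesses the co-evolution of proteins A and B as the Pearson
#' correlation between their co-evolutionary profiles (their rows of the
#' significant-score matrix), taken over the profile positions where both
#' are available, excluding A and B themselves (pairwise-complete
#' treatment of the mask; `zero_fill = TRUE` instead substitutes 0 for
#' unavailable entries, a compatibility mode).
#'
#' @param score_matrix A `score_matrix` from [build_score_matrix()].
#' @param A,B Protein names present in the matrix.
#' @param min_joint Minimum number of joint profile positions (default 3).
#' @param zero_fill Treat unavailable profile entries as 0 instead of
#'   excluding them.
#' @return A `coevo_score` over profile positions (`n_common` here counts
#'   joint positions, and the P-value uses `n_joint - 2` degrees of
#'   freedom).
#' @export
profile_correlation <- function(score_matrix, A, B, min_joint = 3,
                                zero_fill = FALSE) {
  prots <- score_matrix$proteins
  if (A == B || !(A %in% prots) || !(B %in% prots))
    stop("invalid-argument: A and B must be distinct proteins in the matrix")
  others <- setdiff(prots, c(A, B))
  pa <- score_matrix$r[A, others]
  pb <- score_matrix$r[B, others]
  if (zero_fill) {
    pa[is.na(pa)] <- 0
    pb[is.na(pb)] <- 0
  }
  joint <- !is.na(pa) & !is.na(pb)
  n <- sum(joint)
  if (n < min_joint)
    return(new_coevo_score(NA_real_, n, NA_real_, FALSE, "too-few-joint"))
  if (stats::sd(pa[joint]) == 0 || stats::sd(pb[joint]) == 0)
    return(new_coevo_score(NA_real_, n, NA_real_, FALSE, "zero-variance"))
  r <- cor(pa[joint], pb[joint])
  p <- pearson_p_value(r, n - 2)
  new_coevo_score(r, n, p, !is.na(p))
}

#' First-order partial correlation
#'
#' Correlation between A and B once the linear effect of a third variable
#' C is removed: `(r_ab - r_ac * r_bc) / sqrt((1 - r_ac^2)(1 - r_bc^2))`.
#'
#' @param r_ab,r_ac,r_bc Pairwise Pearson correlations, all in `[-1, 1]`.
#' @return The partial correlation, or `NA` when the denominator is zero
#'   (|r_ac| or |r_bc| = 1).
#' @export
partial_correlation <- function(r_ab, r_ac, r_bc) {
  stopifnot(abs(r_ab) <= 1 + 1e-12, abs(r_ac) <= 1 + 1e-12,
            abs(r_bc) <= 1 + 1e-12)
  den <- sqrt((1 - r_ac^2) * (1 - r_bc^2))
  if (!is.finite(den) || den == 0) return(NA_real_)
  (r_ab - r_ac * r_bc) / den
}

# Order-k partial correlation of variables 1 and 2 of correlation matrix R
# given the rest, via inversion of R.  Returns NA if R is singular.
pcor_from_submatrix <- function(R) {
  P <- tryCatch(solve(R), error = function(e) NULL)
  if (is.null(P) || P[1, 1] <= 0 || P[2, 2] <= 0) return(NA_real_)
  # numerically near-singular inversions can leak outside [-1, 1]
  p <- -P[1, 2] / sqrt(P[1, 1] * P[2, 2])
  if (!is.finite(p) || abs(p) > 1 + 1e-8) return(NA_real_)
  max(min(p, 1), -1)
}

#' Context-mirror scores at a given specificity level
#'
#' For each pair (A, B) with an available correlation in the score matrix,
#' candidate controller proteins C (those with available r_AC and r_BC)
#' are ranked by `|r_AC * r_BC|` descending, and the strongest
#' `min(level, available)` controllers whose mutual correlations are also
#' available form the control set S.  The score is the order-|S| partial
#' correlation of (A, B) given S, computed by inverting the
#' (|S|+2) x (|S|+2) correlation submatrix; if that submatrix is singular
#' the largest non-singular leading controller subset is used.  Pairs with
#' no usable controller degrade to the raw correlation (order 0) and are
#' flagged.
#'
#' @param score_matrix A `score_matrix`.
#' @param level Number of controllers to remove (specificity level >= 1).
#' @return Data frame with one row per evaluable pair: `protein_a`,
#'   `protein_b`, `score`, `order` (controllers actually used), `flagged`.
#' @export
context_mirror <- function(score_matrix, level) {
  stopifnot(level >= 1)
  r <- score_matrix$r
  prots <- score_matrix$proteins
  k <- length(prots)
  rows <- vector("list", k * (k - 1) / 2)
  nrow_out <- 0L
  for (i in seq_len(k - 1)) {
    for (j in (i + 1):k) {
      r_ab <- r[i, j]
      if (is.na(r_ab)) next
      cand <- setdiff(which(!is.na(r[i, ]) & !is.na(r[j, ])), c(i, j))
      strength <- abs(r[i, cand] * r[j, cand])
      cand <- cand[order(-strength, prots[cand])]
      # greedy selection: each controller must have available correlations
      # with A, B and all previously selected controllers
      S <- integer(0)
      for (c_ in cand) {
        if (length(S) >= level) break
        if (all(!is.na(r[c_, S]))) S <- c(S, c_)
      }
      score <- r_ab
      used <- 0L
      while (length(S) > 0) {
        idx <- c(i, j, S)
        R <- r[idx, idx]
        R[is.na(R)] <- 0   # unreachable by construction; defensive
        diag(R) <- 1
        p <- pcor_from_submatrix(R)
        if (!is.na(p)) { score <- p; used <- length(S); break }
        S <- S[-length(S)]  # drop weakest controller and retry
      }
      nrow_out <- nrow_out + 1L
      rows[[nrow_out]] <- data.frame(
        protein_a = prots[i], protein_b = prots[j], score = score,
        order = used, flagged = used == 0L, stringsAsFactors = FALSE)
    }
  }
  if (!nrow_out)
    return(data.frame(protein_a = character(0), protein_b = character(0),
                      score = numeric(0), order = integer(0),
                      flagged = logical(0)))
  out <- do.call(rbind, rows[seq_len(nrow_out)])
  rownames(out) <- NULL
  out
}

# ---- scored-pair tables for evaluation -------------------------------------

#' Scored pair tables for the three methods
#'
#' Convenience builders returning the sorted-list inputs the evaluation
#' stage consumes: one row per pair the method can score.  For MT the list
#' contains the significant pairs (this is what produces partial-coverage
#' ROC curves); for PC the pairs with a defined profile correlation; for
#' CM the pairs returned by [context_mirror()].
#'
#' @param family_matrices Named list of per-family distance matrices.
#' @param min_common,p_max Mirrortree cutoffs.
#' @return Data frame `protein_a`, `protein_b`, `score` (+ method
#'   specific columns).
#' @export
mt_score_table <- function(family_matrices, min_common = 15, p_max = 1e-5) {
  sm <- build_score_matrix(family_matrices, min_common, p_max)
  score_matrix_to_table(sm)
}

#' @rdname mt_score_table
#' @param score_matrix A prebuilt `score_matrix`.
#' @export
score_matrix_to_table <- function(score_matrix) {
  r <- score_matrix$r
  idx <- which(upper.tri(r) & !is.na(r), arr.ind = TRUE)
  out <- data.frame(
    protein_a = score_matrix$proteins[idx[, 1]],
    protein_b = score_matrix$proteins[idx[, 2]],
    score = r[idx],
    n_common = score_matrix$n_common[idx],
    p_value = score_matrix$p_value[idx],
    stringsAsFactors = FALSE)
  out[order(-out$score, out$protein_a, out$protein_b), , drop = FALSE]
}

#' @rdname mt_score_table
#' @param min_joint Minimum joint profile positions for PC.
#' @export
pc_score_table <- function(score_matrix, min_joint = 3) {
  prots <- score_matrix$proteins
  k <- length(prots)
  rows <- list()
  for (i in seq_len(k - 1)) {
    for (j in (i + 1):k) {
      s <- profile_correlation(score_matrix, prots[i], prots[j], min_joint)
      if (!is.na(s$r))
        rows[[length(rows) + 1L]] <- data.frame(
          protein_a = prots[i], protein_b = prots[j], score = s$r,
          n_joint = s$n_common, p_value = s$p_value,
          stringsAsFactors = FALSE)
    }
  }
  if (!length(rows))
    return(data.frame(protein_a = character(0), protein_b = character(0),
                      score = numeric(0), n_joint = integer(0),
                      p_value = numeric(0)))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out[order(-out$score, out$protein_a, out$protein_b), , drop = FALSE]
}

#' Write a scored-pair table as TSV
#'
#' @param table Scored pair data frame.
#' @param path File path.
#' @param method,level Recorded in the output columns.
#' @export
write_score_table <- function(table, path, method = "mt", level = NA) {
  table$method <- method
  table$level <- level
  write.table(table, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
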