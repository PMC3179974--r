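# Gold-standard handling and coverage-aware ROC / precision-recall
# evaluation.
#
# The key convention: TPR and FPR are computed against the *fixed totals*
# P and N of the original gold standard, irrespective of whether a method
# could score a given pair with a given organism set.  Methods with low
# coverage therefore produce curves that terminate before (1, 1) — curve
# length reflects applicability as well as accuracy.

pair_key <- function(a, b) paste(pmin(a, b), pmax(a, b), sep = "\r")

new_gold_standard <- function(positives, negatives, label = "gold") {
  structure(list(positives = positives, negatives = negatives,
                 P = nrow(positives), N = nrow(negatives), label = label),
            class = "gold_standard")
}

#' @export
print.gold_standard <- function(x, ...) {
  cat(sprintf("gold_standard '%s': P = %d positives, N = %d negatives\n",
              x$label, x$P, x$N))
  invisible(x)
}

#' Read a gold-standard positive pair list
#'
#' TSV with two protein-id columns (header optional, detected) and an
#' optional third label column.  Pairs are unordered and de-duplicated;
#' self-pairs are a format error.
#'
#' @param path File path.
#' @return Data frame with columns `protein_a`, `protein_b` (canonically
#'   ordered within each row).
#' @export
read_gold_standard <- function(path) {
  raw <- read.table(path, sep = "\t", colClasses = "character", quote = "",
                    comment.char = "#", header = FALSE,
                    stringsAsFactors = FALSE)
  if (ncol(raw) < 2)
    stop("format-error: gold-standard TSV needs at least 2 columns")
  offset <- 0L
  if (tolower(raw[1, 1]) %in% c("protein_a", "protein1"))
    { raw <- raw[-1, , drop = FALSE]; offset <- 1L }
  a <- raw[[1]]; b <- raw[[2]]
  selfp <- which(a == b)
  if (length(selfp))
    stop("format-error: self-pair at line(s) ",
         paste(selfp + offset, collapse = ", "), " of ", path)
  pos <- unique(data.frame(protein_a = pmin(a, b), protein_b = pmax(a, b),
                           stringsAsFactors = FALSE))
  rownames(pos) <- NULL
  pos
}

#' Build a gold standard with all-pairs negatives
#'
#' Negatives are constructed as every unordered pair between the proteins
#' involved in the positive set, minus the positives themselves.  The
#' totals P and N are fixed at construction and never rescaled.
#'
#' @param positives Data frame with columns `protein_a`, `protein_b`.
#' @param label Dataset name.
#' @return A `gold_standard`.
#' @export
generate_negatives <- function(positives, label = "gold") {
  a <- pmin(positives$protein_a, positives$protein_b)
  b <- pmax(positives$protein_a, positives$protein_b)
  pos <- unique(data.frame(protein_a = a, protein_b = b,
                           stringsAsFactors = FALSE))
  prots <- sort(unique(c(pos$protein_a, pos$protein_b)))
  if (length(prots) < 2)
    stop("invalid-argument: need at least 2 proteins")
  all_pairs <- t(utils::combn(prots, 2))
  keys <- pair_key(all_pairs[, 1], all_pairs[, 2])
  neg_idx <- !(keys %in% pair_key(pos$protein_a, pos$protein_b))
  neg <- data.frame(protein_a = all_pairs[neg_idx, 1],
                    protein_b = all_pairs[neg_idx, 2],
                    stringsAsFactors = FALSE)
  rownames(pos) <- rownames(neg) <- NULL
  new_gold_standard(pos, neg, label)
}

#' Write / read a gold standard as TSV
#'
#' Writes one row per labelled pair: `protein_a  protein_b  label`
#' (`positive` / `negative`).
#'
#' @param gold A `gold_standard`.
#' @param path File path.
#' @export
write_gold_standard <- function(gold, path) {
  df <- rbind(cbind(gold$positives, label = "positive"),
              cbind(gold$negatives, label = "negative"))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# Label scored pairs against a gold standard: +1 positive, 0 negative,
# NA not in the gold universe (dropped from evaluation).
label_pairs <- function(scored, gold) {
  keys <- pair_key(scored$protein_a, scored$protein_b)
  pos_keys <- pair_key(gold$positives$protein_a, gold$positives$protein_b)
  neg_keys <- pair_key(gold$negatives$protein_a, gold$negatives$protein_b)
  ifelse(keys %in% pos_keys, 1L, ifelse(keys %in% neg_keys, 0L, NA_integer_))
}

#' Totals-based ROC curve
#'
#' Sweeps thresholds over the distinct scores (descending; tied scores
#' move in a single step) and computes `TPR = Tp / P`, `FPR = Fp / N`
#' against the gold standard's fixed totals.  Gold pairs the method did
#' not score count in P and N but can never become Tp or Fp, so partial
#' coverage yields a curve terminating before (1, 1).  AUC is the
#' trapezoidal area under the realized curve.
#'
#' @param scored Data frame with `protein_a`, `protein_b`, `score`.
#' @param gold A `gold_standard` with P > 0 and N > 0.
#' @return A `roc_curve`: list with `points` (threshold, Tp, Fp, TPR,
#'   FPR), `auc`, `coverage` (fraction of gold pairs scored).
#' @export
roc_curve <- function(scored, gold) {
  if (gold$P == 0 || gold$N == 0)
    stop("undefined-curve: gold standard must have positives and negatives")
  lab <- label_pairs(scored, gold)
  keep <- !is.na(lab) & !is.na(scored$score)
  s <- scored$score[keep]
  y <- lab[keep]
  o <- order(-s)
  s <- s[o]; y <- y[o]
  # one step per distinct score value
  last_of_tie <- !duplicated(s, fromLast = TRUE)
  tp <- cumsum(y)[last_of_tie]
  fp <- cumsum(1 - y)[last_of_tie]
  pts <- data.frame(threshold = s[last_of_tie], Tp = tp, Fp = fp,
                    TPR = tp / gold$P, FPR = fp / gold$N)
  fpr <- c(0, pts$FPR); tpr <- c(0, pts$TPR)
  auc <- sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
  structure(list(points = pts, auc = auc,
                 coverage = length(s) / (gold$P + gold$N),
                 P = gold$P, N = gold$N),
            class = "roc_curve")
}

#' @export
print.roc_curve <- function(x, ...) {
  cat(sprintf("roc_curve: AUC = %.4f, coverage = %.3f, %d thresholds\n",
              x$auc, x$coverage, nrow(x$points)))
  invisible(x)
}

#' Precision-recall / F-measure curve
#'
#' Same threshold sweep as [roc_curve()]; at each threshold
#' `precision = Tp / (Tp + Fp)` and `recall = Tp / P` (fixed total), with
#' the F-measure their harmonic mean.  `max_f` is the maximum F over
#' thresholds where F is defined.
#'
#' @inheritParams roc_curve
#' @return A `pr_curve`: list with `points` (threshold, precision,
#'   recall, F) and `max_f`.
#' @export
pr_curve <- function(scored, gold) {
  roc <- roc_curve(scored, gold)
  p <- roc$points
  precision <- ifelse(p$Tp + p$Fp > 0, p$Tp / (p$Tp + p$Fp), NA_real_)
  recall <- p$Tp / gold$P
  f <- ifelse(!is.na(precision) & precision + recall > 0,
              2 * precision * recall / (precision + recall), NA_real_)
  pts <- data.frame(threshold = p$threshold, precision = precision,
                    recall = recall, F = f)
  structure(list(points = pts,
                 max_f = if (all(is.na(f))) NA_real_ else max(f, na.rm = TRUE)),
            class = "pr_curve")
}

# Mann-Whitney AUC (ties count 1/2) of scores for positives vs negatives.
mann_whitney_auc <- function(scores, labels) {
  npos <- sum(labels == 1); nneg <- sum(labels == 0)
  if (npos == 0 || nneg == 0) return(NA_real_)
  rk <- rank(scores)  # average ranks handle ties as 1/2
  (sum(rk[labels == 1]) - npos * (npos + 1) / 2) / (npos * nneg)
}

#' Per-protein interactor ranking report
#'
#' For one protein, collects every scored pair it participates in, sorts
#' the candidate partners by score, and summarises how highly the true
#' interactors rank.  The local AUC follows the in-list convention: it is
#' computed over the positives/negatives present in this candidate list
#' only (the normalized Mann-Whitney U, ties counting 1/2), not against
#' the gold standard's totals.
#'
#' @param scored Data frame with `protein_a`, `protein_b`, `score`.
#' @param protein Protein id.
#' @param gold A `gold_standard`.
#' @return List with `protein`, `n_candidates` (list size),
#'   `n_positives` (positives in the list), `auc_local`, `top_partner`,
#'   `top_score`, and the sorted `candidates` data frame.
#' @export
rank_interactors <- function(scored, protein, gold) {
  inlist <- scored$protein_a == protein | scored$protein_b == protein
  if (!any(inlist))
    stop("not-found: protein '", protein, "' has no scored pairs")
  sub <- scored[inlist, , drop = FALSE]
  partner <- ifelse(sub$protein_a == protein, sub$protein_b, sub$protein_a)
  lab <- label_pairs(sub, gold)
  o <- order(-sub$score)
  cand <- data.frame(partner = partner[o], score = sub$score[o],
                     label = lab[o], stringsAsFactors = FALSE)
  known <- !is.na(cand$label)
  auc <- mann_whitney_auc(cand$score[known], cand$label[known])
  list(protein = protein,
       n_candidates = nrow(cand),
       n_positives = sum(cand$label == 1, na.rm = TRUE),
       auc_local = auc,
       top_partner = cand$partner[1],
       top_score = cand$score[1],
       candidates = cand)
}

# ---- experiment grid -------------------------------------------------------

restrict_family_matrices <- function(family_matrices, organisms) {
  lapply(family_matrices, function(m) {
    keep <- intersect(rownames(m), organisms)
    m[keep, keep, drop = FALSE]
  })
}

#' Run the organism-set x method evaluation grid
#'
#' For every combination of organism set and method, restricts the
#' family distance matrices to that set's organisms, scores all protein
#' pairs, and evaluates the scored list against the benchmark's gold
#' standard with the totals-based ROC and the F-measure curve.
#'
#' @param benchmark A `sim_benchmark` (or any list with
#'   `family_matrices` and `gold`).
#' @param organism_sets List of `organism_set`s (or named character
#'   vectors); `NULL` means a single set with all organisms.
#' @param methods Subset of `c("mt", "pc", "cm")`.
#' @param level Context-mirror specificity level.
#' @param min_common,p_max Mirrortree cutoffs.
#' @param min_joint Profile-correlation minimum joint positions.
#' @return List with `summary` (one row per cell: organism_set, method,
#'   level, n_scored, coverage, auc, max_f) and `cells` (the scored
#'   tables and curves).
#' @export
run_experiment <- function(benchmark, organism_sets = NULL,
                           methods = c("mt", "pc", "cm"), level = 10,
                           min_common = 15, p_max = 1e-5, min_joint = 3) {
  methods <- match.arg(methods, several.ok = TRUE)
  if (is.null(organism_sets)) {
    all_orgs <- sort(unique(unlist(lapply(benchmark$family_matrices,
                                          rownames))))
    organism_sets <- list(new_organism_set("explicit", 1, all_orgs))
  }
  set_label <- function(s) if (inherits(s, "organism_set")) s$label
                           else paste0("set_", seq_along(organism_sets))
  rows <- list()
  cells <- list()
  for (s in organism_sets) {
    orgs <- if (inherits(s, "organism_set")) s$genomes else s
    lbl <- if (inherits(s, "organism_set")) s$label else
      paste0("explicit_", length(orgs))
    fams <- restrict_family_matrices(benchmark$family_matrices, orgs)
    sm <- NULL
    for (m in methods) {
      if (is.null(sm)) sm <- build_score_matrix(fams, min_common, p_max)
      scored <- switch(m,
        mt = score_matrix_to_table(sm),
        pc = pc_score_table(sm, min_joint),
        cm = context_mirror(sm, level))
      cell <- list(organism_set = lbl, method = m, scored = scored)
      if (nrow(scored)) {
        roc <- roc_curve(scored, benchmark$gold)
        pr <- pr_curve(scored, benchmark$gold)
        cell$roc <- roc
        cell$pr <- pr
        rows[[length(rows) + 1L]] <- data.frame(
          organism_set = lbl, method = m,
          level = if (m == "cm") level else NA_integer_,
          n_organisms = length(orgs), n_scored = nrow(scored),
          coverage = roc$coverage, auc = roc$auc, max_f = pr$max_f,
          stringsAsFactors = FALSE)
      } else {
        rows[[length(rows) + 1L]] <- data.frame(
          organism_set = lbl, method = m,
          level = if (m == "cm") level else NA_integer_,
          n_organisms = length(orgs), n_scored = 0L,
          coverage = 0, auc = NA_real_, max_f = NA_real_,
          stringsAsFactors = FALSE)
      }
      cells[[paste(lbl, m, sep = ".")]] <- cell
    }
  }
  summary <- do.call(rbind, rows)
  rownames(summary) <- NULL
  list(summary = summary, cells = cells)
}
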