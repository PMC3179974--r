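#' @importFrom stats cor pt runif rnorm setNames
#' @importFrom utils read.table write.table count.fields
NULL

# ---- distance matrices -----------------------------------------------------

#' Canonicalize and validate a labeled distance matrix
#'
#' Distance matrices throughout the package are plain numeric matrices with
#' row/column names (organism ids), symmetric to 1e-12, zero on the diagonal,
#' and with labels in lexicographic order.  This helper enforces that
#' canonical form.
#'
#' @param m Square numeric matrix with identical row and column names.
#' @return The matrix with rows/columns reordered lexicographically.
#' @export
as_dist_matrix <- function(m) {
  if (!is.matrix(m) || nrow(m) != ncol(m))
    stop("distance matrix must be square")
  labs <- rownames(m)
  if (is.null(labs) || is.null(colnames(m)) || !setequal(labs, colnames(m)))
    stop("distance matrix must carry matching row/column labels")
  m <- m[sort(labs), sort(labs), drop = FALSE]
  if (max(abs(m - t(m))) > 1e-12)
    stop("distance matrix is not symmetric")
  if (any(abs(diag(m)) > 1e-12))
    stop("distance matrix diagonal is not zero")
  diag(m) <- 0
  (m + t(m)) / 2
}

# Upper-triangle vector in canonical organism-pair order (labels sorted).
upper_vec <- function(m) {
  m <- m[sort(rownames(m)), sort(rownames(m)), drop = FALSE]
  m[upper.tri(m)]
}

# ---- p-distances from alignments -------------------------------------------

#' Pairwise sequence distances with pairwise gap deletion
#'
#' Computes the uncorrected p-distance between every pair of aligned
#' sequences: the fraction of mismatching positions among the columns where
#' neither sequence has a gap (`-`).  An optional Kimura correction for
#' multiple substitutions, `d = -ln(1 - p - p^2/5)`, can be applied.
#'
#' @param alignment Named character vector of equal-length aligned sequences,
#'   or a character matrix (rows = sequences).
#' @param correction `"none"` (default) for the raw p-distance or
#'   `"kimura"` for Kimura's protein-distance correction.
#' @return A canonical distance matrix (see [as_dist_matrix()]).
#' @export
pdistance_matrix <- function(alignment, correction = c("none", "kimura")) {
  correction <- match.arg(correction)
  if (is.matrix(alignment)) {
    chars <- alignment
  } else {
    if (length(alignment) < 3) stop("alignment must contain at least 3 sequences")
    lens <- nchar(alignment)
    if (length(unique(lens)) != 1) stop("aligned sequences must have equal length")
    chars <- do.call(rbind, strsplit(toupper(alignment), ""))
    rownames(chars) <- names(alignment)
  }
  ids <- rownames(chars)
  if (is.null(ids) || anyDuplicated(ids)) stop("sequences must carry unique ids")
  n <- nrow(chars)
  gap <- chars == "-"
  d <- matrix(0, n, n, dimnames = list(ids, ids))
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      ok <- !gap[i, ] & !gap[j, ]
      ncomp <- sum(ok)
      if (ncomp == 0)
        stop(sprintf("degenerate pair: '%s' and '%s' share no gap-free columns",
                     ids[i], ids[j]))
      p <- sum(chars[i, ok] != chars[j, ok]) / ncomp
      if (correction == "kimura") {
        arg <- 1 - p - p^2 / 5
        p <- if (arg <= 0) 10 else -log(arg)  # saturated pairs capped
      }
      d[i, j] <- d[j, i] <- p
    }
  }
  as_dist_matrix(d)
}

# ---- neighbor joining ------------------------------------------------------

#' Neighbor-joining tree from a distance matrix
#'
#' Native Saitou-Nei implementation.  On additive input the unrooted tree's
#' path metric reproduces the input distances exactly.  Ties on the
#' Q-criterion are broken deterministically by the lexicographically lowest
#' label pair (merged nodes inherit the smaller of their children's labels),
#' and negative branch-length estimates are clamped to zero.
#'
#' @param d Labeled symmetric distance matrix (>= 3 taxa).
#' @return An unrooted `phylo` tree over all input taxa.
#' @seealso [patristic_distances()] for the inverse direction.
#' @export
neighbor_joining <- function(d) {
  if (!is.matrix(d) || nrow(d) < 3) stop("invalid-argument: need >= 3 taxa")
  if (max(abs(d - t(d))) > 1e-8) stop("invalid-argument: matrix not symmetric")
  d <- as_dist_matrix(d)
  fmt <- function(x) sprintf("%.15g", max(x, 0))
  labels <- rownames(d)           # lexicographic tie-break keys
  subtree <- rownames(d)          # growing Newick fragments
  while (nrow(d) > 3) {
    n <- nrow(d)
    r <- rowSums(d)
    q <- (n - 2) * d - outer(r, r, "+")
    diag(q) <- Inf
    qmin <- min(q)
    cand <- which(q <= qmin + 1e-12, arr.ind = TRUE)
    cand <- cand[cand[, 1] < cand[, 2], , drop = FALSE]
    key <- paste(pmin(labels[cand[, 1]], labels[cand[, 2]]),
                 pmax(labels[cand[, 1]], labels[cand[, 2]]), sep = "\r")
    pick <- cand[order(key)[1], ]
    i <- pick[1]; j <- pick[2]
    li <- d[i, j] / 2 + (r[i] - r[j]) / (2 * (n - 2))
    lj <- d[i, j] - li
    new_sub <- paste0("(", subtree[i], ":", fmt(li), ",",
                      subtree[j], ":", fmt(lj), ")")
    new_lab <- min(labels[i], labels[j])
    du <- (d[i, ] + d[j, ] - d[i, j]) / 2
    keep <- setdiff(seq_len(n), c(i, j))
    d <- rbind(cbind(d[keep, keep, drop = FALSE], du[keep]), c(du[keep], 0))
    subtree <- c(subtree[keep], new_sub)
    labels <- c(labels[keep], new_lab)
    dimnames(d) <- list(labels, labels)
  }
  l1 <- (d[1, 2] + d[1, 3] - d[2, 3]) / 2
  l2 <- (d[1, 2] + d[2, 3] - d[1, 3]) / 2
  l3 <- (d[1, 3] + d[2, 3] - d[1, 2]) / 2
  nwk <- paste0("(", subtree[1], ":", fmt(l1), ",", subtree[2], ":", fmt(l2),
                ",", subtree[3], ":", fmt(l3), ");")
  ape::read.tree(text = nwk)
}

# ---- patristic distances ---------------------------------------------------

#' Patristic distance matrix of a tree
#'
#' Entry (i, j) is the sum of branch lengths along the unique path between
#' leaves i and j.  Root placement is irrelevant; trees are treated as
#' unrooted for path sums.
#'
#' @param tree A `phylo` tree with branch lengths on every edge.
#' @return A canonical distance matrix over the tree's leaf labels.
#' @export
patristic_distances <- function(tree) {
  stopifnot(inherits(tree, "phylo"))
  if (is.null(tree$edge.length) || anyNA(tree$edge.length))
    stop("format-error: tree has missing branch lengths")
  as_dist_matrix(stats::cophenetic(tree))
}

#' Check the four-point condition on a distance matrix
#'
#' A metric is realizable on a tree (additive) iff for every quadruple
#' (i, j, k, l) the two largest of the three pairings
#' d(i,j)+d(k,l), d(i,k)+d(j,l), d(i,l)+d(j,k) are equal.  Used as a
#' structural oracle on simulated trees.
#'
#' @param d Labeled distance matrix.
#' @param tol Numeric tolerance on the equality of the two largest sums.
#' @return `TRUE` if every quadruple satisfies the condition.
#' @export
four_point_condition <- function(d, tol = 1e-9) {
  n <- nrow(d)
  if (n < 4) return(TRUE)
  quads <- utils::combn(n, 4)
  for (c_ in seq_len(ncol(quads))) {
    q <- quads[, c_]
    s <- sort(c(d[q[1], q[2]] + d[q[3], q[4]],
                d[q[1], q[3]] + d[q[2], q[4]],
                d[q[1], q[4]] + d[q[2], q[3]]))
    if (s[3] - s[2] > tol * max(1, s[3])) return(FALSE)
  }
  TRUE
}

# ---- file formats ----------------------------------------------------------

#' Read / write Newick trees
#'
#' Thin wrappers over ape's Newick parser that turn silent failures into
#' explicit format errors (e.g. unbalanced parentheses).
#'
#' @param path File path.
#' @return `read_newick` returns a `phylo`; `write_newick` invisibly
#'   returns `path`.
#' @export
read_newick <- function(path) {
  txt <- paste(readLines(path, warn = FALSE), collapse = "")
  n_open <- lengths(regmatches(txt, gregexpr("(", txt, fixed = TRUE)))
  n_close <- lengths(regmatches(txt, gregexpr(")", txt, fixed = TRUE)))
  if (n_open != n_close)
    stop("format-error: unbalanced parentheses in Newick file ", path)
  tree <- tryCatch(suppressWarnings(ape::read.tree(text = txt)),
                   error = function(e) NULL)
  if (is.null(tree)) stop("format-error: cannot parse Newick file ", path)
  tree
}

#' @rdname read_newick
#' @param tree A `phylo` tree.
#' @export
write_newick <- function(tree, path) {
  ape::write.tree(tree, file = path, digits = 12)
  invisible(path)
}

#' Read / write PHYLIP square distance matrices
#'
#' Standard square layout: a first line with the number of taxa, then one
#' row per taxon (name followed by the whitespace-delimited distances).
#'
#' @param path File path.
#' @return `read_phylip` returns a canonical distance matrix.
#' @export
read_phylip <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  n <- as.integer(trimws(lines[1]))
  if (is.na(n) || length(lines) != n + 1)
    stop("format-error: malformed PHYLIP matrix in ", path)
  labs <- character(n)
  m <- matrix(NA_real_, n, n)
  for (i in seq_len(n)) {
    parts <- strsplit(trimws(lines[i + 1]), "\\s+")[[1]]
    if (length(parts) != n + 1)
      stop("format-error: row ", i, " of ", path, " has wrong field count")
    labs[i] <- parts[1]
    m[i, ] <- as.numeric(parts[-1])
  }
  dimnames(m) <- list(labs, labs)
  as_dist_matrix(m)
}

#' @rdname read_phylip
#' @param m Labeled distance matrix.
#' @export
write_phylip <- function(m, path) {
  m <- as_dist_matrix(m)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("%5d", nrow(m)), con)
  for (i in seq_len(nrow(m)))
    writeLines(paste(c(rownames(m)[i], sprintf("%.10f", m[i, ])),
                     collapse = "  "), con)
  invisible(path)
}

#' Read / write aligned FASTA
#'
#' @param path File path.
#' @return `read_alignment_fasta` returns a named character vector of
#'   equal-length sequences.
#' @export
read_alignment_fasta <- function(path) {
  s <- Biostrings::readBStringSet(path)
  aln <- setNames(as.character(s), names(s))
  if (length(unique(nchar(aln))) > 1)
    stop("format-error: sequences in ", path, " are not aligned")
  aln
}

#' @rdname read_alignment_fasta
#' @param alignment Named character vector of aligned sequences.
#' @export
write_alignment_fasta <- function(alignment, path) {
  Biostrings::writeXStringSet(Biostrings::BStringSet(alignment), path)
  invisible(path)
}
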