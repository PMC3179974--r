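# Taxonomy trees and the two organism-sampling criteria ("nearest", "level").
#
# A taxonomy_tree holds a rooted hierarchy of named, ranked nodes plus the
# attachment of each genome to a node.  It carries no branch lengths: the
# NCBI-style classification is purely topological.

new_taxonomy_tree <- function(nodes, genomes, proteome_sizes = NULL) {
  stopifnot(is.data.frame(nodes), is.data.frame(genomes))
  nodes$node_id <- as.character(nodes$node_id)
  nodes$parent_id <- as.character(nodes$parent_id)
  genomes$genome_id <- as.character(genomes$genome_id)
  genomes$node_id <- as.character(genomes$node_id)

  is_root <- nodes$parent_id == nodes$node_id | is.na(nodes$parent_id) |
    nodes$parent_id == ""
  if (sum(is_root) != 1)
    stop("format-error: taxonomy must have exactly one root, found ",
         sum(is_root))
  root <- nodes$node_id[is_root]
  parent <- setNames(nodes$parent_id, nodes$node_id)
  missing_parent <- setdiff(parent[!is_root], nodes$node_id)
  if (length(missing_parent))
    stop("format-error: unknown parent node(s): ",
         paste(missing_parent, collapse = ", "))
  # cycle check: every node must reach the root in < |nodes| steps
  for (nd in nodes$node_id) {
    cur <- nd
    for (step in seq_len(nrow(nodes) + 1)) {
      if (cur == root) break
      cur <- parent[[cur]]
      if (step > nrow(nodes))
        stop("format-error: cycle detected in taxonomy at node ", nd)
    }
    if (cur != root)
      stop("format-error: cycle detected in taxonomy at node ", nd)
  }
  bad <- setdiff(genomes$node_id, nodes$node_id)
  if (length(bad))
    stop("format-error: genome attached to missing node(s): ",
         paste(bad, collapse = ", "))
  structure(list(nodes = nodes, root = root, genomes = genomes,
                 proteome_sizes = proteome_sizes),
            class = "taxonomy_tree")
}

#' @export
print.taxonomy_tree <- function(x, ...) {
  cat("taxonomy_tree:", nrow(x$nodes), "nodes,", nrow(x$genomes),
      "genomes, root =", x$root, "\n")
  invisible(x)
}

#' Read a taxonomy from NCBI-dump or simplified-TSV sources
#'
#' Two dialects are accepted and auto-detected.  The NCBI dump dialect is
#' the `nodes.dmp`/`names.dmp` field layout (fields separated by
#' `"\t|\t"`, rows terminated by `"\t|"`); `names_source` then supplies
#' scientific names.  The simplified dialect is a single 4-column TSV with
#' header `node_id  parent_id  rank  name` (the root's parent is itself or
#' empty).  Genomes are supplied as a TSV with header
#' `genome_id  node_id  [proteome_size]`.
#'
#' @param nodes_source Path to nodes.dmp or the simplified taxonomy TSV.
#' @param names_source Path to names.dmp (NCBI dialect only).
#' @param genomes_source Path to the genome-attachment TSV.
#' @return A `taxonomy_tree`.
#' @export
read_taxonomy <- function(nodes_source, names_source = NULL, genomes_source) {
  first <- readLines(nodes_source, n = 1, warn = FALSE)
  if (grepl("\t|\t", first, fixed = TRUE)) {
    nodes <- read_ncbi_dump(nodes_source, names_source)
  } else {
    nodes <- read.table(nodes_source, sep = "\t", header = TRUE,
                        colClasses = "character", quote = "",
                        comment.char = "")
    need <- c("node_id", "parent_id", "rank", "name")
    if (!all(need %in% names(nodes)))
      stop("format-error: taxonomy TSV must have header columns ",
           paste(need, collapse = ", "))
    nodes <- nodes[need]
  }
  g <- read.table(genomes_source, sep = "\t", header = TRUE,
                  colClasses = "character", quote = "", comment.char = "")
  if (!all(c("genome_id", "node_id") %in% names(g)))
    stop("format-error: genomes TSV must have columns genome_id, node_id")
  sizes <- NULL
  if ("proteome_size" %in% names(g))
    sizes <- setNames(suppressWarnings(as.numeric(g$proteome_size)),
                      g$genome_id)
  new_taxonomy_tree(nodes, g[c("genome_id", "node_id")], sizes)
}

read_ncbi_dump <- function(nodes_path, names_path) {
  parse_dmp <- function(path) {
    lines <- readLines(path, warn = FALSE)
    lines <- sub("\t\\|$", "", lines)
    strsplit(lines, "\t\\|\t")
  }
  nd <- parse_dmp(nodes_path)
  nodes <- data.frame(
    node_id = vapply(nd, `[`, "", 1),
    parent_id = vapply(nd, `[`, "", 2),
    rank = vapply(nd, `[`, "", 3),
    name = NA_character_, stringsAsFactors = FALSE)
  if (!is.null(names_path)) {
    nm <- parse_dmp(names_path)
    sci <- vapply(nm, function(f)
      length(f) >= 4 && trimws(f[4]) == "scientific name", logical(1))
    name_of <- setNames(vapply(nm[sci], `[`, "", 2),
                        vapply(nm[sci], `[`, "", 1))
    nodes$name <- unname(name_of[nodes$node_id])
  }
  nodes$name[is.na(nodes$name)] <- nodes$node_id[is.na(nodes$name)]
  nodes
}

#' Write a taxonomy in the simplified TSV dialect
#'
#' Produces `taxonomy.tsv` (node_id, parent_id, rank, name) and
#' `genomes.tsv` (genome_id, node_id, proteome_size) under `dir`.
#'
#' @param tax A `taxonomy_tree`.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the two file paths.
#' @export
write_taxonomy <- function(tax, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  np <- file.path(dir, "taxonomy.tsv")
  gp <- file.path(dir, "genomes.tsv")
  write.table(tax$nodes, np, sep = "\t", quote = FALSE, row.names = FALSE)
  g <- tax$genomes
  if (!is.null(tax$proteome_sizes))
    g$proteome_size <- tax$proteome_sizes[g$genome_id]
  write.table(g, gp, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(c(np, gp))
}

# parent lookup vector
tax_parent <- function(tax) setNames(tax$nodes$parent_id, tax$nodes$node_id)

# topological depth of every node (root = 0)
tax_depths <- function(tax) {
  parent <- tax_parent(tax)
  depth <- setNames(rep(NA_real_, nrow(tax$nodes)), tax$nodes$node_id)
  depth[tax$root] <- 0
  pending <- setdiff(names(depth), tax$root)
  while (length(pending)) {
    for (nd in pending)
      if (!is.na(depth[parent[[nd]]])) depth[nd] <- depth[parent[[nd]]] + 1
    pending2 <- names(depth)[is.na(depth)]
    if (length(pending2) == length(pending)) break
    pending <- pending2
  }
  depth
}

#' Lineage of a genome
#'
#' Follows a genome's taxonomy back to the root: returns the node ids from
#' its attachment node up to (and including) the root.
#'
#' @param tax A `taxonomy_tree`.
#' @param genome_id Genome identifier.
#' @return Character vector of node ids, attachment first, root last.
#' @export
lineage <- function(tax, genome_id) {
  i <- match(genome_id, tax$genomes$genome_id)
  if (is.na(i)) stop("not-found: unknown genome '", genome_id, "'")
  parent <- tax_parent(tax)
  path <- character(0)
  cur <- tax$genomes$node_id[i]
  repeat {
    path <- c(path, cur)
    if (cur == tax$root) break
    cur <- parent[[cur]]
  }
  path
}

# genomes attached within the subtree rooted at `node`
subtree_genomes <- function(tax, node) {
  children <- split(tax$nodes$node_id, tax_parent(tax))
  keep <- character(0)
  stack <- node
  while (length(stack)) {
    cur <- stack[[1]]; stack <- stack[-1]
    keep <- c(keep, cur)
    kids <- setdiff(children[[cur]], cur)   # root lists itself as child
    stack <- c(stack, kids)
  }
  sort(tax$genomes$genome_id[tax$genomes$node_id %in% keep])
}

new_organism_set <- function(criterion, index, genomes) {
  structure(list(label = paste0(criterion, "_", index),
                 criterion = criterion, index = index,
                 genomes = genomes),
            class = "organism_set")
}

#' @export
print.organism_set <- function(x, ...) {
  cat(x$label, ": ", length(x$genomes), " genomes\n", sep = "")
  invisible(x)
}

#' "Nearest" organism sampling
#'
#' Starting from a reference genome, its taxonomy is followed back to the
#' root and, at each node visited, all genomes in that node's subtree are
#' taken.  `nearest_1` is the reference's own attachment group (e.g. the
#' strains of its species), `nearest_2` the next node up (e.g. its family),
#' and the last set contains every genome in the taxonomy.  The sets are
#' nested and all contain the reference genome.
#'
#' @param tax A `taxonomy_tree`.
#' @param reference_genome Genome id of the reference organism.
#' @return List of `organism_set`s, labelled `nearest_1`, `nearest_2`, ...
#' @export
sample_nearest <- function(tax, reference_genome) {
  anc <- lineage(tax, reference_genome)
  out <- vector("list", length(anc))
  for (k in seq_along(anc))
    out[[k]] <- new_organism_set("nearest", k, subtree_genomes(tax, anc[k]))
  out
}

#' "Level" organism sampling
#'
#' The taxonomy is cut at each successive depth starting below the root
#' (superkingdom, phylum, ...).  A cut at depth k partitions the genomes
#' into the groups induced by their depth-k ancestors, and one genome is
#' taken from each non-empty group: the one with the largest proteome
#' (ties broken by lexicographic genome id).  Genomes attached above the
#' cut form their own singleton group, and cuts below a genome's
#' attachment node key the genome by itself, so the deepest level always
#' returns every genome.
#'
#' @param tax A `taxonomy_tree` with `proteome_sizes` for every genome
#'   (genomes lacking a size are excluded with a warning).
#' @return List of `organism_set`s, labelled `level_1`, `level_2`, ...
#' @export
sample_level <- function(tax) {
  sizes <- tax$proteome_sizes
  g <- tax$genomes$genome_id
  if (is.null(sizes)) sizes <- setNames(rep(NA_real_, length(g)), g)
  missing <- g[!(g %in% names(sizes)) | is.na(sizes[g])]
  if (length(missing)) {
    warning("configuration-error: no proteome size for ",
            paste(missing, collapse = ", "), "; excluded from level sampling")
    g <- setdiff(g, missing)
  }
  if (!length(g)) return(list())
  lin <- lapply(setNames(g, g), function(x) lineage(tax, x))
  depth_g <- vapply(lin, length, 0L) - 1L    # attachment depth
  max_k <- max(depth_g) + 1L
  out <- vector("list", max_k)
  for (k in seq_len(max_k)) {
    # group key of each genome under a depth-k cut
    key <- vapply(g, function(x) {
      l <- lin[[x]]; dg <- length(l) - 1L
      if (k > dg) paste0("genome:", x)           # cut passes below attachment
      else l[dg - k + 1L]                        # depth-k ancestor node
    }, "")
    chosen <- vapply(split(g, key), function(members) {
      s <- sizes[members]
      members[order(-s, members)][1]
    }, "")
    out[[k]] <- new_organism_set("level", k, sort(unname(chosen)))
  }
  out
}

#' Write / read an organism set as one-genome-per-line text
#'
#' The header comment records the sampling criterion and index.
#'
#' @param set An `organism_set`.
#' @param path File path.
#' @export
write_organism_set <- function(set, path) {
  writeLines(c(sprintf("# criterion=%s index=%d", set$criterion, set$index),
               set$genomes), path)
  invisible(path)
}

#' @rdname write_organism_set
#' @export
read_organism_set <- function(path) {
  lines <- readLines(path, warn = FALSE)
  hdr <- lines[startsWith(lines, "#")][1]
  criterion <- sub(".*criterion=(\\S+).*", "\\1", hdr)
  index <- as.integer(sub(".*index=(\\d+).*", "\\1", hdr))
  new_organism_set(criterion, index,
                   lines[!startsWith(lines, "#") & nzchar(lines)])
}
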