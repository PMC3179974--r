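# Synthetic benchmark generator.
#
# The generative model: a Yule-type species tree gives the true patristic
# distances t(i, j); each gene family f perceives the multiplicative
# log-normal distortion d_f(i, j) = t(i, j) * exp(sigma * z_f(i, j)) with
# z standard normal per organism pair.  Interacting family pairs share a
# component of z with correlation rho ("co-evolution"); if the interaction
# is "recent" the shared component applies only to organism pairs inside a
# designated clade.  Each organism is retained in a family with a fixed
# probability (emulating ortholog absence).  One root seed drives
# per-operation derived substreams (see derive_seed()).

#' Simulation configuration
#'
#' Validates and bundles the parameters of the synthetic benchmark.
#'
#' @param n_organisms Number of species-tree leaves (>= 3).
#' @param n_families Number of gene families.
#' @param n_interacting_pairs Number of interacting family pairs
#'   (<= n_families / 2); these are the gold-standard positives.
#' @param coevolution_strength Correlation rho in `[0, 1]` of the rate
#'   perturbations shared by an interacting pair.
#' @param noise_sd Standard deviation sigma (>= 0) of the log-normal
#'   distance noise.
#' @param retention_prob Per-organism probability in `(0, 1]` that a
#'   family retains the organism (ortholog present).
#' @param redundancy_strains Number of leaves to duplicate as
#'   epsilon-distant strains.
#' @param strain_epsilon Branch length (> 0) of each duplicated strain.
#' @param recent_clade_fraction Fraction in `(0, 1]` of leaves forming
#'   the clade inside which co-evolution acts; 1 = taxonomy-wide ("old"
#'   interactions), < 1 = clade-confined ("recent" interactions).
#' @param seed Integer root seed.
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_organisms = 40, n_families = 60,
                       n_interacting_pairs = 20,
                       coevolution_strength = 0.9, noise_sd = 0.3,
                       retention_prob = 0.9, redundancy_strains = 0,
                       strain_epsilon = 1e-3, recent_clade_fraction = 1,
                       seed = 1) {
  stopifnot(n_organisms >= 3, n_families >= 2,
            n_interacting_pairs >= 0,
            n_interacting_pairs <= n_families / 2,
            coevolution_strength >= 0, coevolution_strength <= 1,
            noise_sd >= 0,
            retention_prob > 0, retention_prob <= 1,
            redundancy_strains >= 0, strain_epsilon > 0,
            recent_clade_fraction > 0, recent_clade_fraction <= 1)
  structure(list(n_organisms = n_organisms, n_families = n_families,
                 n_interacting_pairs = n_interacting_pairs,
                 coevolution_strength = coevolution_strength,
                 noise_sd = noise_sd, retention_prob = retention_prob,
                 redundancy_strains = redundancy_strains,
                 strain_epsilon = strain_epsilon,
                 recent_clade_fraction = recent_clade_fraction,
                 seed = as.integer(seed)),
            class = "sim_config")
}

#' Simulate a species tree under a Yule-type process
#'
#' @param n_organisms Number of leaves (>= 3).
#' @param seed Integer seed.
#' @return A rooted binary `phylo` with leaves `org001`, `org002`, ...
#'   and strictly positive branch lengths.
#' @export
simulate_species_tree <- function(n_organisms, seed) {
  if (n_organisms < 3)
    stop("invalid-argument: need at least 3 organisms")
  tree <- with_seed(derive_seed(seed, "species-tree"),
                    ape::rphylo(n_organisms, birth = 1, death = 0))
  tree$tip.label <- sprintf("org%03d", seq_len(n_organisms))
  tree
}

#' Add strain-level redundancy to a tree
#'
#' Duplicates `k` randomly chosen leaves: each chosen leaf X is replaced
#' by a cherry (X, X_strain1) whose two terminal branches have length
#' `epsilon`, inserted `epsilon` above the original leaf position so that
#' X's distances to all other leaves are unchanged (when its terminal
#' branch is longer than epsilon) and d(X, X_strain1) = 2 * epsilon.
#'
#' @param tree A `phylo`.
#' @param k Number of leaves to duplicate (0 <= k <= leaf count).
#' @param epsilon Strain branch length (> 0).
#' @param seed Integer seed for the leaf choice.
#' @return The augmented `phylo` with `k` extra leaves.
#' @export
add_strain_redundancy <- function(tree, k, epsilon, seed) {
  stopifnot(inherits(tree, "phylo"), epsilon > 0)
  n <- length(tree$tip.label)
  if (k < 0 || k > n)
    stop("invalid-argument: k must be between 0 and the leaf count")
  if (k == 0) return(tree)
  chosen <- sort(with_seed(derive_seed(seed, "strain-choice"),
                           sample.int(n, k)))
  m <- tree$Nnode
  edge <- tree$edge
  # tips keep ids 1..n, strains get n+1..n+k, old internal nodes shift by k
  map_node <- function(v) ifelse(v <= n, v, v + k)
  new_edge <- cbind(map_node(edge[, 1]), map_node(edge[, 2]))
  new_len <- tree$edge.length
  next_node <- n + k + m
  strain_labels <- character(k)
  for (s in seq_along(chosen)) {
    tip <- chosen[s]
    strain_id <- n + s
    next_node <- next_node + 1L
    row <- which(edge[, 2] == tip)
    L <- tree$edge.length[row]
    new_edge[row, ] <- c(new_edge[row, 1], next_node)
    new_len[row] <- max(L - epsilon, 0)
    new_edge <- rbind(new_edge, c(next_node, tip), c(next_node, strain_id))
    new_len <- c(new_len, epsilon, epsilon)
    strain_labels[s] <- paste0(tree$tip.label[tip], "_strain1")
  }
  out <- list(edge = new_edge, edge.length = new_len,
              tip.label = c(tree$tip.label, strain_labels),
              Nnode = m + k)
  class(out) <- "phylo"
  ape::reorder.phylo(out, "cladewise")
}

# symmetric zero-diagonal matrix from an upper-triangle vector
sym_from_upper <- function(v, labels) {
  n <- length(labels)
  m <- matrix(0, n, n, dimnames = list(labels, labels))
  m[upper.tri(m)] <- v
  m + t(m)
}

#' Simulate one gene-family distance matrix
#'
#' Applies the multiplicative log-normal distortion
#' `d(i, j) = t(i, j) * exp(noise_sd * z(i, j))` to the species patristic
#' distances and drops each organism independently with probability
#' `1 - retention_prob`.  Families left with fewer than 3 organisms are
#' kept but flagged degenerate (attribute `degenerate`), exercising
#' downstream minimum-organism filters.
#'
#' @param species_tree A `phylo`, or a precomputed patristic matrix.
#' @param rate_perturbation Optional symmetric standard-normal
#'   perturbation matrix z over the tree's leaves (shared components are
#'   how interacting families are made to co-evolve); drawn i.i.d. when
#'   `NULL`.
#' @param retention_prob Per-organism retention probability.
#' @param noise_sd Log-normal noise standard deviation.
#' @param seed Integer seed (substreams: "retention", "noise").
#' @return A canonical distance matrix over the retained organisms.
#' @export
simulate_family_matrix <- function(species_tree, rate_perturbation = NULL,
                                   retention_prob = 1, noise_sd = 0,
                                   seed = 1) {
  stopifnot(noise_sd >= 0)
  t_mat <- if (inherits(species_tree, "phylo"))
    patristic_distances(species_tree) else as_dist_matrix(species_tree)
  labels <- rownames(t_mat)
  n <- length(labels)
  if (noise_sd > 0) {
    if (is.null(rate_perturbation)) {
      z <- with_seed(derive_seed(seed, "noise"),
                     sym_from_upper(rnorm(n * (n - 1) / 2), labels))
    } else {
      z <- rate_perturbation[labels, labels]
    }
    d <- t_mat * exp(noise_sd * z)
  } else {
    d <- t_mat
  }
  keep <- with_seed(derive_seed(seed, "retention"),
                    runif(n) <= retention_prob)
  d <- d[keep, keep, drop = FALSE]
  attr(d, "degenerate") <- nrow(d) < 3
  d
}

# Deterministically pick the internal node whose clade size is closest to
# fraction * Ntip (ties: smaller clade, then lower node id).
pick_clade <- function(tree, fraction) {
  n <- length(tree$tip.label)
  target <- fraction * n
  internal <- (n + 1):(n + tree$Nnode)
  sizes <- vapply(internal, function(nd)
    length(tip_labels_under(tree, nd)), 0L)
  ok <- internal[sizes < n]           # exclude the root (= everything)
  sz <- sizes[sizes < n]
  pick <- ok[order(abs(sz - target), sz, ok)][1]
  sort(tip_labels_under(tree, pick))
}

tip_labels_under <- function(tree, node) {
  n <- length(tree$tip.label)
  if (node <= n) return(tree$tip.label[node])
  kids <- tree$edge[tree$edge[, 1] == node, 2]
  unlist(lapply(kids, tip_labels_under, tree = tree))
}

#' Derive a taxonomy from a species tree
#'
#' Cuts the rooted species tree at its topological depths into named,
#' ranked groups: every internal node becomes a taxon of rank
#' `rank<depth>`, every leaf becomes a terminal taxon (rank `strain`),
#' and each genome attaches to its leaf taxon.  The resulting taxonomy is
#' consistent with the tree's clade structure by construction.  Proteome
#' sizes (needed by level sampling) are assigned deterministically from
#' the genome label.
#'
#' @param tree A rooted `phylo`.
#' @return A `taxonomy_tree`.
#' @export
taxonomy_from_tree <- function(tree) {
  n <- length(tree$tip.label)
  tree <- ape::reorder.phylo(tree, "cladewise")
  root <- n + 1L
  ids <- function(v) ifelse(v <= n, paste0("tax_leaf_", tree$tip.label[v]),
                            paste0("tax_node_", v))
  parent_of <- setNames(ids(tree$edge[, 1]), ids(tree$edge[, 2]))
  all_nodes <- c(ids(root), names(parent_of))
  depth <- setNames(rep(0L, length(all_nodes)), all_nodes)
  for (nd in ids(tree$edge[, 2]))   # cladewise order: parents first
    depth[nd] <- depth[parent_of[nd]] + 1L
  nodes <- data.frame(
    node_id = all_nodes,
    parent_id = c(ids(root), unname(parent_of)),
    rank = ifelse(startsWith(all_nodes, "tax_leaf_"), "strain",
                  ifelse(all_nodes == ids(root), "root",
                         paste0("rank", depth[all_nodes]))),
    name = sub("^tax_(leaf|node)_", "", all_nodes),
    stringsAsFactors = FALSE)
  genomes <- data.frame(genome_id = tree$tip.label,
                        node_id = paste0("tax_leaf_", tree$tip.label),
                        stringsAsFactors = FALSE)
  sizes <- vapply(tree$tip.label, function(g)
    3000 + sum(utf8ToInt(g) * seq_along(utf8ToInt(g))) %% 2000, 0)
  new_taxonomy_tree(nodes, genomes, sizes)
}

#' Simulate a complete benchmark bundle
#'
#' Produces the species tree (with optional strain redundancy), a
#' consistent taxonomy, per-family distance matrices with pairwise
#' correlated rate perturbations for the designated interacting pairs,
#' and a gold standard whose positives are those pairs (negatives: all
#' other pairs among the involved families).
#'
#' @param config A `sim_config`.
#' @return A `sim_benchmark`: list with `species_tree`, `taxonomy`,
#'   `family_matrices` (named `fam001`, ...), `gold`, `interacting`
#'   (positive pair data frame), `clade_organisms` (the "recent" clade,
#'   or all organisms when `recent_clade_fraction = 1`), and `config`.
#' @export
simulate_benchmark <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  cfg <- config
  tree <- simulate_species_tree(cfg$n_organisms, cfg$seed)
  if (cfg$redundancy_strains > 0)
    tree <- add_strain_redundancy(tree, cfg$redundancy_strains,
                                  cfg$strain_epsilon, cfg$seed)
  t_mat <- patristic_distances(tree)
  labels <- rownames(t_mat)
  n <- length(labels)
  np <- n * (n - 1) / 2

  clade <- if (cfg$recent_clade_fraction < 1)
    pick_clade(tree, cfg$recent_clade_fraction) else labels
  in_clade <- labels %in% clade
  inside <- outer(in_clade, in_clade, "&")
  inside_vec <- inside[upper.tri(inside)]

  fam_names <- sprintf("fam%03d", seq_len(cfg$n_families))
  pairs <- with_seed(derive_seed(cfg$seed, "interacting-pairs"), {
    chosen <- sample(cfg$n_families, 2 * cfg$n_interacting_pairs)
    matrix(chosen, ncol = 2, byrow = TRUE)
  })
  pairmate <- integer(cfg$n_families)
  if (cfg$n_interacting_pairs > 0)
    for (i in seq_len(nrow(pairs)))
      pairmate[pairs[i, ]] <- i

  rho <- cfg$coevolution_strength
  z_list <- with_seed(derive_seed(cfg$seed, "perturbations"), {
    shared <- if (cfg$n_interacting_pairs > 0)
      lapply(seq_len(cfg$n_interacting_pairs), function(i) rnorm(np))
    else list()
    lapply(seq_len(cfg$n_families), function(f) {
      own <- rnorm(np)
      if (pairmate[f] > 0) {
        s <- shared[[pairmate[f]]]
        ifelse(inside_vec, sqrt(rho) * s + sqrt(1 - rho) * own, own)
      } else own
    })
  })

  fams <- setNames(vector("list", cfg$n_families), fam_names)
  for (f in seq_len(cfg$n_families))
    fams[[f]] <- simulate_family_matrix(
      t_mat, sym_from_upper(z_list[[f]], labels),
      retention_prob = cfg$retention_prob, noise_sd = cfg$noise_sd,
      seed = derive_seed(cfg$seed, paste0("family-", f)))

  positives <- if (cfg$n_interacting_pairs > 0) data.frame(
    protein_a = pmin(fam_names[pairs[, 1]], fam_names[pairs[, 2]]),
    protein_b = pmax(fam_names[pairs[, 1]], fam_names[pairs[, 2]]),
    stringsAsFactors = FALSE)
  else data.frame(protein_a = character(0), protein_b = character(0))
  gold <- generate_negatives(positives, label = "simulated")

  structure(list(species_tree = tree, taxonomy = taxonomy_from_tree(tree),
                 family_matrices = fams, gold = gold,
                 interacting = positives, clade_organisms = clade,
                 config = cfg),
            class = "sim_benchmark")
}

#' @export
print.sim_benchmark <- function(x, ...) {
  cat(sprintf(paste0("sim_benchmark: %d organisms, %d families, ",
                     "%d interacting pairs (rho = %.2f, sigma = %.2f)\n"),
              length(x$species_tree$tip.label), length(x$family_matrices),
              nrow(x$interacting), x$config$coevolution_strength,
              x$config$noise_sd))
  invisible(x)
}

#' Simulate aligned sequences along the species tree
#'
#' Evolves one alignment per family under a Jukes-Cantor substitution
#' model, with each family's branch lengths scaled by its rate
#' multiplier.  Provides an end-to-end fixture for the
#' alignment -> distance -> tree stage.
#'
#' @param species_tree A `phylo`.
#' @param family_rates Named numeric vector of per-family rate
#'   multipliers (default: one family, rate 1).
#' @param seq_length Alignment length (>= 50).
#' @param seed Integer seed.
#' @return Named list (per family) of named character vectors of aligned
#'   sequences, one per leaf.
#' @export
emit_sequences <- function(species_tree, family_rates = c(fam001 = 1),
                           seq_length, seed) {
  stopifnot(seq_length >= 50)
  out <- setNames(vector("list", length(family_rates)), names(family_rates))
  for (f in names(family_rates)) {
    tr <- species_tree
    tr$edge.length <- tr$edge.length * family_rates[[f]]
    sim <- with_seed(derive_seed(seed, paste0("seq-", f)),
                     phangorn::simSeq(tr, l = seq_length, type = "DNA"))
    chars <- toupper(as.character(sim))
    out[[f]] <- setNames(apply(chars, 1, paste, collapse = ""),
                         rownames(chars))
  }
  out
}

#' Simulate an all-vs-all hit table with known ortholog truth
#'
#' Emits a synthetic BLAST-tabular hit table over the proteins implied by
#' a benchmark: protein `<org>.<fam>` exists in genome `org` iff the
#' organism is retained in family `fam`'s distance matrix.  True ortholog
#' pairs (same family, different genomes) receive strong reciprocal hits;
#' decoy cross-family hits are weaker and/or under-covered, so filtering
#' and reciprocal-best-hit recovery can be validated against the recorded
#' truth.
#'
#' @param benchmark A `sim_benchmark`.
#' @param seed Integer seed.
#' @param decoys_per_family Number of decoy hit pairs added per family.
#' @return List with `hits` (data frame in outfmt-6 column order),
#'   `genome_of`, `seq_lengths`, and `truth` (data frame
#'   `family`, `genome`, `protein`).
#' @export
simulate_hit_table <- function(benchmark, seed = 1, decoys_per_family = 3) {
  fams <- benchmark$family_matrices
  prot <- function(org, fam) paste0(org, ".", fam)
  truth <- do.call(rbind, lapply(names(fams), function(f) {
    orgs <- rownames(fams[[f]])
    if (!length(orgs)) return(NULL)
    data.frame(family = f, genome = orgs, protein = prot(orgs, f),
               stringsAsFactors = FALSE)
  }))
  genome_of <- setNames(truth$genome, truth$protein)
  # orthologs within a family share a base length, so true reciprocal hits
  # always clear a two-sided coverage filter
  seq_lengths <- with_seed(derive_seed(seed, "hit-lengths"), {
    base <- setNames(round(runif(length(fams), 250, 400)), names(fams))
    setNames(round(base[truth$family] + runif(nrow(truth), -10, 10)),
             truth$protein)
  })
  rows <- list()
  add_row <- function(q, s, pid, alen, ev, bits) {
    rows[[length(rows) + 1L]] <<- data.frame(
      query_id = q, subject_id = s, percent_identity = pid,
      alignment_length = alen, mismatches = round(alen * (1 - pid / 100)),
      gap_opens = 0, query_start = 1, query_end = alen,
      subject_start = 1, subject_end = alen,
      e_value = ev, bit_score = bits, stringsAsFactors = FALSE)
  }
  with_seed(derive_seed(seed, "hit-table"), {
    for (f in names(fams)) {
      orgs <- rownames(fams[[f]])
      if (length(orgs) < 2) next
      for (i in seq_len(length(orgs) - 1)) {
        for (j in (i + 1):length(orgs)) {
          q <- prot(orgs[i], f); s <- prot(orgs[j], f)
          alen <- round(0.9 * min(seq_lengths[q], seq_lengths[s]))
          ev <- 10^-runif(1, 40, 80)
          pid <- runif(1, 55, 90)
          bits <- runif(1, 200, 500)
          add_row(q, s, pid, alen, ev, bits)
          add_row(s, q, pid, alen, ev, bits)
        }
      }
      # decoys: cross-family, weak and/or under-covered
      other <- setdiff(names(fams), f)
      for (d in seq_len(decoys_per_family)) {
        f2 <- sample(other, 1)
        orgs2 <- rownames(fams[[f2]])
        if (length(orgs) < 1 || length(orgs2) < 1) next
        q <- prot(sample(orgs, 1), f)
        s <- prot(sample(orgs2, 1), f2)
        alen <- round(runif(1, 0.3, 0.65) * min(seq_lengths[q],
                                                seq_lengths[s]))
        add_row(q, s, runif(1, 20, 35), alen, 10^-runif(1, 0, 8),
                runif(1, 30, 60))
      }
    }
  })
  hits <- do.call(rbind, rows)
  rownames(hits) <- NULL
  list(hits = hits, genome_of = genome_of, seq_lengths = seq_lengths,
       truth = truth)
}

#' Write a hit table in 12-column tabular layout
#'
#' @param hits Hit data frame (outfmt-6 column order).
#' @param path File path.
#' @export
write_hit_table <- function(hits, path) {
  write.table(hits[HIT_COLS], path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Write a benchmark bundle to disk
#'
#' Emits `species_tree.nwk`, one PHYLIP square matrix per family under
#' `matrices/`, the taxonomy TSV pair, the gold-standard TSV and a JSON
#' provenance file recording the configuration.
#'
#' @param benchmark A `sim_benchmark`.
#' @param dir Output directory (created if needed).
#' @return Invisibly, `dir`.
#' @export
write_benchmark <- function(benchmark, dir) {
  dir.create(file.path(dir, "matrices"), showWarnings = FALSE,
             recursive = TRUE)
  write_newick(benchmark$species_tree, file.path(dir, "species_tree.nwk"))
  for (f in names(benchmark$family_matrices)) {
    m <- benchmark$family_matrices[[f]]
    if (nrow(m) >= 2)
      write_phylip(m, file.path(dir, "matrices", paste0(f, ".phy")))
  }
  write_taxonomy(benchmark$taxonomy, dir)
  write_gold_standard(benchmark$gold, file.path(dir, "gold.tsv"))
  jsonlite::write_json(unclass(benchmark$config),
                       file.path(dir, "provenance.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
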