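# Reciprocal-best-hit orthology from all-vs-all similarity hit tables.
#
# The pipeline never runs BLAST itself: it consumes precomputed hit tables
# in the 12-column tabular (outfmt-6) layout, applies the E-value and
# alignment-coverage filters, and derives one-ortholog-per-genome tables by
# the best-bidirectional-hit criterion.

HIT_COLS <- c("query_id", "subject_id", "percent_identity",
              "alignment_length", "mismatches", "gap_opens",
              "query_start", "query_end", "subject_start", "subject_end",
              "e_value", "bit_score")

#' Read an all-vs-all hit table (BLAST outfmt-6 layout)
#'
#' @param path Path to a 12-column tab-separated hit file.
#' @param genome_of Named character vector mapping protein id -> genome id;
#'   every protein in the table must be mappable.
#' @param seq_lengths Optional named numeric vector of protein sequence
#'   lengths (needed later by [filter_hits()]).
#' @return A data frame of hits with `query_genome`/`subject_genome`
#'   columns and the `seq_lengths` attached as an attribute.
#' @export
read_hits <- function(path, genome_of, seq_lengths = NULL) {
  nf <- count.fields(path, sep = "\t", quote = "", comment.char = "")
  bad <- which(nf != 12)
  if (length(bad))
    stop("format-error: line(s) ", paste(bad, collapse = ", "), " of ",
         path, " do not have 12 tab-separated columns")
  h <- read.table(path, sep = "\t", quote = "", comment.char = "",
                  stringsAsFactors = FALSE,
                  colClasses = c("character", "character", rep("numeric", 10)))
  names(h) <- HIT_COLS
  if (any(h$e_value < 0) || any(h$alignment_length < 1))
    stop("format-error: negative E-value or empty alignment in ", path)
  prots <- unique(c(h$query_id, h$subject_id))
  unmapped <- setdiff(prots, names(genome_of))
  if (length(unmapped))
    stop("configuration-error: no genome assignment for protein(s): ",
         paste(utils::head(unmapped, 5), collapse = ", "))
  h$query_genome <- unname(genome_of[h$query_id])
  h$subject_genome <- unname(genome_of[h$subject_id])
  attr(h, "seq_lengths") <- seq_lengths
  h
}

#' Filter hits by E-value and two-sided alignment coverage
#'
#' Retains rows with `e_value <= e_max` and alignment coverage
#' (`alignment_length / sequence_length`) of at least `coverage_min` on
#' *both* the query and the subject sequence — the symmetric, strictest
#' reading of a one-sided coverage requirement.  Defaults are the standard
#' ortholog-search cutoffs (E <= 1e-5, coverage >= 70%).
#'
#' @param hits Hit data frame from [read_hits()].
#' @param e_max Maximum E-value.
#' @param coverage_min Minimum coverage fraction, applied to query and
#'   subject.
#' @param seq_lengths Named numeric vector of sequence lengths; defaults to
#'   the attribute attached by [read_hits()].
#' @return The filtered hit data frame (attributes preserved).
#' @export
filter_hits <- function(hits, e_max = 1e-5, coverage_min = 0.70,
                        seq_lengths = attr(hits, "seq_lengths")) {
  need <- unique(c(hits$query_id, hits$subject_id))
  if (is.null(seq_lengths) || length(setdiff(need, names(seq_lengths))))
    stop("configuration-error: sequence lengths missing for some proteins")
  cov_q <- hits$alignment_length / seq_lengths[hits$query_id]
  cov_s <- hits$alignment_length / seq_lengths[hits$subject_id]
  keep <- hits$e_value <= e_max & cov_q >= coverage_min & cov_s >= coverage_min
  out <- hits[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "seq_lengths") <- seq_lengths
  out
}

# Collapse multiple HSPs of the same protein pair to the single row with
# the lowest E-value (tie: highest bit score).
dedupe_hsps <- function(hits) {
  o <- order(hits$query_id, hits$subject_id, hits$e_value, -hits$bit_score)
  h <- hits[o, , drop = FALSE]
  h[!duplicated(paste(h$query_id, h$subject_id, sep = "\r")), , drop = FALSE]
}

# Best hit of each genome_a protein among genome_b subjects.
# "Best" = lowest E-value, tie-broken by highest bit score, then
# lexicographic subject id.
best_hits_dir <- function(hits, genome_a, genome_b) {
  h <- hits[hits$query_genome == genome_a & hits$subject_genome == genome_b &
              hits$query_id != hits$subject_id, , drop = FALSE]
  if (!nrow(h)) return(setNames(character(0), character(0)))
  h <- dedupe_hsps(h)
  o <- order(h$query_id, h$e_value, -h$bit_score, h$subject_id)
  h <- h[o, , drop = FALSE]
  h <- h[!duplicated(h$query_id), , drop = FALSE]
  setNames(h$subject_id, h$query_id)
}

#' Reciprocal best hits between two genomes
#'
#' Returns the pairs (p, q), p in `genome_a` and q in `genome_b`, such
#' that q is p's best hit in `genome_b` and p is q's best hit in
#' `genome_a`.
#'
#' @param hits A (filtered) hit data frame.
#' @param genome_a,genome_b Genome ids.
#' @return Data frame with columns `protein_a`, `protein_b`, sorted by
#'   `protein_a`.
#' @export
reciprocal_best_hits <- function(hits, genome_a, genome_b) {
  ab <- best_hits_dir(hits, genome_a, genome_b)
  ba <- best_hits_dir(hits, genome_b, genome_a)
  mutual <- names(ab)[!is.na(ba[ab]) & ba[ab] == names(ab)]
  mutual <- mutual[!is.na(mutual)]
  out <- data.frame(protein_a = mutual, protein_b = unname(ab[mutual]),
                    stringsAsFactors = FALSE)
  out[order(out$protein_a), , drop = FALSE]
}

#' Ortholog table for a reference genome across an organism set
#'
#' Runs the reciprocal-best-hit search between the reference genome and
#' every other genome of the set, recording at most one ortholog per
#' (reference protein, genome).  Reference proteins map to themselves in
#' the reference genome.
#'
#' @param hits A (filtered) hit data frame.
#' @param reference_genome Reference genome id.
#' @param genome_set Character vector of genome ids, including the
#'   reference.
#' @return Data frame with columns `reference_protein`, `genome`,
#'   `ortholog`.
#' @export
build_ortholog_table <- function(hits, reference_genome, genome_set) {
  if (!length(genome_set) || !(reference_genome %in% genome_set))
    stop("invalid-argument: genome_set must contain the reference genome")
  ref_prots <- sort(unique(c(
    hits$query_id[hits$query_genome == reference_genome],
    hits$subject_id[hits$subject_genome == reference_genome])))
  rows <- list(data.frame(reference_protein = ref_prots,
                          genome = reference_genome,
                          ortholog = ref_prots, stringsAsFactors = FALSE))
  for (g in sort(setdiff(genome_set, reference_genome))) {
    rbh <- reciprocal_best_hits(hits, reference_genome, g)
    if (nrow(rbh))
      rows[[length(rows) + 1L]] <- data.frame(
        reference_protein = rbh$protein_a, genome = g,
        ortholog = rbh$protein_b, stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Write an ortholog table as TSV
#'
#' @param table Ortholog table from [build_ortholog_table()].
#' @param path File path.
#' @export
write_ortholog_table <- function(table, path) {
  write.table(table, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
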