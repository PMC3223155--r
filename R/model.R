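#' Train a fixed-order Markov model for one genome
#'
#' Sums (k+1)-mer transition counts over all replicons of a genome
#' (chromosomes and plasmids contribute to a single model) and converts
#' them to negative-log transition costs. For a context m with outgoing
#' count total F(m) = sum_n F(m -> n), an observed transition gets cost
#' -ln(F(m -> n) / F(m)); a transition never observed in the genome gets
#' the constant `missing_cost`. Smaller cost means more probable, so a
#' query's total cost acts as a distance to the genome.
#'
#' With `strand_policy = "both"` (the default) the reverse complement of
#' every replicon is counted too, making downstream classification
#' orientation-invariant.
#'
#' @param sequences Replicon sequences of one genome: character vector,
#'   list, or [Biostrings::DNAStringSet].
#' @param k Model order (1-8). Default 5.
#' @param missing_cost Cost charged per transition absent from the
#'   training counts, in -log units. Default 10.
#' @param strand_policy `"both"` (train on sequence plus reverse
#'   complement) or `"forward"`.
#' @param genome_id Identifier stored in the model.
#' @return A `genome_model`: list with `genome_id`, `k`, `costs` (double
#'   vector of length 4^(k+1), all >= 0), `missing_cost`,
#'   `strand_policy`, `n_transitions_trained`.
#' @examples
#' m <- build_model("AACG", k = 1, missing_cost = 10,
#'                  strand_policy = "forward")
#' m$costs[c("AA", "AC", "CG")]   # -ln(1/2), -ln(1/2), -ln(1)
#' @export
build_model <- function(sequences, k = 5L, missing_cost = 10,
                        strand_policy = c("both", "forward"),
                        genome_id = "genome") {
  k <- check_order(k)
  missing_cost <- check_missing_cost(missing_cost)
  strand_policy <- check_strand_policy(strand_policy)
  seqs <- as_dna_set(sequences)
  if (length(seqs) == 0L) {
    stop("at least one sequence is required to train a model", call. = FALSE)
  }
  counts <- colSums(Biostrings::oligonucleotideFrequency(seqs, width = k + 1L))
  if (strand_policy == "both") {
    rc <- Biostrings::reverseComplement(seqs)
    counts <- counts +
      colSums(Biostrings::oligonucleotideFrequency(rc, width = k + 1L))
  }
  n_trained <- sum(counts)
  if (n_trained == 0) {
    stop("model-degenerate: no countable (k+1)-mer transition in any ",
         "training sequence", call. = FALSE)
  }
  costs <- costs_from_counts(counts, k, missing_cost)
  structure(
    list(genome_id = as.character(genome_id), k = k, costs = costs,
         missing_cost = missing_cost, strand_policy = strand_policy,
         n_transitions_trained = n_trained),
    class = "genome_model"
  )
}

# counts: named vector of length 4^(k+1), successor base fastest-varying.
# Reshaped so each row is one context's 4 successors; row sums give F(m).
costs_from_counts <- function(counts, k, missing_cost) {
  m <- matrix(counts, ncol = 4L, byrow = TRUE)
  ctx_tot <- rowSums(m)
  p <- m / ifelse(ctx_tot > 0, ctx_tot, 1)
  costs <- -log(p)
  costs[m == 0] <- missing_cost
  costs <- as.numeric(t(costs))
  names(costs) <- names(counts)
  costs
}

#' @export
print.genome_model <- function(x, ...) {
  cat(sprintf(
    "genome_model '%s': k=%d, %d cost cells (%d observed), strand=%s, missing_cost=%g\n",
    x$genome_id, x$k, length(x$costs), sum(x$costs != x$missing_cost),
    x$strand_policy, x$missing_cost
  ))
  invisible(x)
}

#' Build a reference database from a set of genomes
#'
#' Trains one Markov model per genome (see [build_model()]) and stacks
#' the cost vectors into an N x 4^(k+1) matrix, one row per genome in
#' input order, against which query reads are scored in a single matrix
#' product. Rows are stored at binary32 precision, the precision of the
#' on-disk container and of single-precision GEMM scoring.
#'
#' @param genomes Named list: `genome_id -> sequences` (each element as
#'   accepted by [build_model()]), or a [Biostrings::DNAStringSet] whose
#'   names are genome ids (one replicon per genome).
#' @param taxonomy A lineage table from [parse_lineage_table()] or
#'   [make_lineage_table()] covering every genome id, or `NULL` with
#'   `allow_missing_taxonomy = TRUE` to assign all-`"NA"` lineages.
#' @param allow_missing_taxonomy If `TRUE`, genomes absent from
#'   `taxonomy` get an all-`"NA"` lineage instead of an error.
#' @inheritParams build_model
#' @return A `reference_db`: list with `k`, `missing_cost`,
#'   `strand_policy`, `matrix` (genomes x 4^(k+1), binary32-valued
#'   doubles, rownames = genome ids), and `genomes` (data.frame:
#'   `genome_id`, `n_transitions_trained`, plus the seven lineage rank
#'   columns).
#' @export
build_database <- function(genomes, k = 5L, missing_cost = 10,
                           strand_policy = c("both", "forward"),
                           taxonomy = NULL,
                           allow_missing_taxonomy = FALSE) {
  k <- check_order(k)
  missing_cost <- check_missing_cost(missing_cost)
  strand_policy <- check_strand_policy(strand_policy)
  if (methods::is(genomes, "DNAStringSet")) {
    genomes <- as.list(as.character(genomes))
  }
  if (!is.list(genomes) || length(genomes) == 0L) {
    stop("`genomes` must be a non-empty named list of genome_id -> sequences",
         call. = FALSE)
  }
  ids <- names(genomes)
  if (is.null(ids) || any(!nzchar(ids))) {
    stop("every genome must be named with a genome_id", call. = FALSE)
  }
  if (anyDuplicated(ids)) {
    stop("duplicate genome_id: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "), call. = FALSE)
  }
  lineages <- resolve_lineages(ids, taxonomy, allow_missing_taxonomy)
  mods <- lapply(ids, function(id) {
    build_model(genomes[[id]], k = k, missing_cost = missing_cost,
                strand_policy = strand_policy, genome_id = id)
  })
  mat <- do.call(rbind, lapply(mods, function(m) quantize_float32(m$costs)))
  rownames(mat) <- ids
  colnames(mat) <- names(mods[[1L]]$costs)
  meta <- cbind(
    data.frame(genome_id = ids,
               n_transitions_trained =
                 vapply(mods, `[[`, numeric(1), "n_transitions_trained"),
               stringsAsFactors = FALSE),
    lineages
  )
  rownames(meta) <- NULL
  new_reference_db(k, missing_cost, strand_policy, mat, meta)
}

new_reference_db <- function(k, missing_cost, strand_policy, mat, meta) {
  stopifnot(nrow(mat) == nrow(meta), identical(rownames(mat), meta$genome_id))
  structure(
    list(k = k, missing_cost = missing_cost, strand_policy = strand_policy,
         matrix = mat, genomes = meta),
    class = "reference_db"
  )
}

resolve_lineages <- function(ids, taxonomy, allow_missing) {
  empty <- as.data.frame(
    setNames(rep(list(rep("NA", length(ids))), length(TAXONOMY_RANKS)),
             TAXONOMY_RANKS),
    stringsAsFactors = FALSE
  )
  if (is.null(taxonomy)) {
    if (!allow_missing) {
      stop("`taxonomy` is required unless allow_missing_taxonomy = TRUE",
           call. = FALSE)
    }
    return(empty)
  }
  taxonomy <- validate_lineage_table(taxonomy)
  hit <- match(ids, taxonomy$genome_id)
  if (anyNA(hit) && !allow_missing) {
    stop("no taxonomy entry for genome_id: ",
         paste(ids[is.na(hit)], collapse = ", "),
         " (set allow_missing_taxonomy = TRUE to assign NA lineages)",
         call. = FALSE)
  }
  out <- empty
  ok <- !is.na(hit)
  out[ok, ] <- taxonomy[hit[ok], TAXONOMY_RANKS]
  out
}

#' @export
print.reference_db <- function(x, ...) {
  cat(sprintf(
    "reference_db: %d genomes x %d transition cells (k=%d), missing_cost=%g, strand=%s\n",
    nrow(x$matrix), ncol(x$matrix), x$k, x$missing_cost, x$strand_policy
  ))
  invisible(x)
}

#' Add one genome to an existing reference database
#'
#' Trains a model for the new genome with the database's own order,
#' missing cost and strand policy, and appends it as the last row. The
#' result is bit-identical to rebuilding the database from scratch with
#' the new genome appended to the input list.
#'
#' @param db A `reference_db`.
#' @param genome_id New genome identifier; must not already be present.
#' @param sequences Replicon sequences of the new genome.
#' @param lineage A one-row lineage (named character vector or one-row
#'   data.frame with the seven rank columns), or `NULL` for all-`"NA"`.
#' @return The extended `reference_db`.
#' @export
add_genome <- function(db, genome_id, sequences, lineage = NULL) {
  stopifnot(inherits(db, "reference_db"))
  genome_id <- as.character(genome_id)
  if (genome_id %in% db$genomes$genome_id) {
    stop("duplicate genome_id: ", genome_id, call. = FALSE)
  }
  mod <- build_model(sequences, k = db$k, missing_cost = db$missing_cost,
                     strand_policy = db$strand_policy, genome_id = genome_id)
  row <- quantize_float32(mod$costs)
  mat <- rbind(db$matrix, row)
  rownames(mat) <- c(rownames(db$matrix), genome_id)
  lin <- lineage_row(lineage)
  meta <- rbind(
    db$genomes,
    cbind(data.frame(genome_id = genome_id,
                     n_transitions_trained = mod$n_transitions_trained,
                     stringsAsFactors = FALSE),
          lin)
  )
  rownames(meta) <- NULL
  new_reference_db(db$k, db$missing_cost, db$strand_policy, mat, meta)
}

lineage_row <- function(lineage) {
  out <- as.data.frame(setNames(as.list(rep("NA", length(TAXONOMY_RANKS))),
                                TAXONOMY_RANKS), stringsAsFactors = FALSE)
  if (is.null(lineage)) return(out)
  if (is.data.frame(lineage)) {
    stopifnot(nrow(lineage) == 1L)
    lineage <- unlist(lineage[1L, , drop = TRUE])
  }
  lineage <- lineage[names(lineage) %in% TAXONOMY_RANKS]
  out[1L, names(lineage)] <- as.character(lineage)
  out
}
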