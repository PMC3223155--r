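#' Simulate a genome as a realization of a random Markov chain
#'
#' Draws each transition row of an order-`order` chain over \{A,C,G,T\}
#' from a symmetric Dirichlet(`concentration`) and then walks the chain
#' from a uniformly chosen start context. Small concentrations give
#' sharply peaked transition rows, hence compositionally well-separated
#' genomes; very large concentrations approach an i.i.d. uniform
#' sequence. Deterministic given `seed`.
#'
#' @param length Genome length in bases.
#' @param order Order of the generating chain (default 3 — deliberately
#'   different from the classifier's default k = 5, so recovering
#'   simulated reads never relies on a model-order match).
#' @param concentration Symmetric Dirichlet concentration for the
#'   transition rows (default 0.1).
#' @param seed Optional integer; when supplied, the global RNG is
#'   seeded with it (two calls with the same seed give identical
#'   genomes).
#' @return A single character string of A/C/G/T of the requested
#'   length.
#' @export
simulate_genome <- function(length, order = 3L, concentration = 0.1,
                            seed = NULL) {
  stopifnot(length > order, order >= 1L, concentration > 0)
  if (!is.null(seed)) set.seed(seed)
  order <- as.integer(order)
  n_ctx <- 4L^order
  # symmetric Dirichlet rows via normalized gammas
  g <- matrix(stats::rgamma(n_ctx * 4L, shape = concentration, rate = 1),
              nrow = n_ctx)
  g[g == 0] <- .Machine$double.xmin  # guard against underflow at tiny shape
  p <- g / rowSums(g)
  cum1 <- p[, 1L]
  cum2 <- cum1 + p[, 2L]
  cum3 <- cum2 + p[, 3L]
  bases <- c("A", "C", "G", "T")
  out <- integer(length)
  start_ctx <- sample.int(n_ctx, 1L) - 1L
  # emit the start context's own bases first
  ctx_digits <- integer(order)
  cc <- start_ctx
  for (i in order:1) { ctx_digits[i] <- cc %% 4L; cc <- cc %/% 4L }
  out[seq_len(order)] <- ctx_digits
  ctx <- start_ctx
  u <- stats::runif(length - order)
  mod <- 4L^(order - 1L)
  for (t in seq_len(length - order)) {
    i <- ctx + 1L
    b <- (u[t] > cum1[i]) + (u[t] > cum2[i]) + (u[t] > cum3[i])
    out[order + t] <- b
    ctx <- (ctx %% mod) * 4L + b
  }
  paste(bases[out + 1L], collapse = "")
}

#' Sample reads from a genome
#'
#' Emulates shotgun sampling used to benchmark the classifier: uniform
#' start positions, uniform strand (a read may be the reverse complement
#' of the sampled window), and optional i.i.d. substitution errors.
#' Deterministic given `seed`.
#'
#' @param genome Genome sequence (character string).
#' @param read_length Read length in bases; must not exceed the genome
#'   length.
#' @param n Number of reads.
#' @param seed Optional integer RNG seed.
#' @param error_rate Per-base substitution probability in \[0, 1).
#'   Default 0 (error-free, the benchmark default).
#' @param genome_id Source genome id recorded in the truth columns.
#' @return data.frame `read_id`, `sequence`, `genome_id`, `strand`
#'   (`"+"`/`"-"`), `start` (1-based window start on the forward
#'   strand).
#' @export
sample_reads <- function(genome, read_length, n, seed = NULL,
                         error_rate = 0, genome_id = "genome") {
  genome <- as.character(genome)
  L <- nchar(genome)
  if (read_length > L) {
    stop("read_length (", read_length, ") exceeds genome length (", L, ")",
         call. = FALSE)
  }
  stopifnot(error_rate >= 0, error_rate < 1, n >= 0)
  if (!is.null(seed)) set.seed(seed)
  if (n == 0L) {
    return(data.frame(read_id = character(0), sequence = character(0),
                      genome_id = character(0), strand = character(0),
                      start = integer(0), stringsAsFactors = FALSE))
  }
  starts <- sample.int(L - read_length + 1L, n, replace = TRUE)
  strands <- sample(c("+", "-"), n, replace = TRUE)
  seqs <- substring(genome, starts, starts + read_length - 1L)
  rc <- strands == "-"
  if (any(rc)) {
    seqs[rc] <- as.character(Biostrings::reverseComplement(
      Biostrings::DNAStringSet(seqs[rc])))
  }
  if (error_rate > 0) {
    seqs <- vapply(seqs, mutate_read, character(1), error_rate)
    names(seqs) <- NULL
  }
  data.frame(
    read_id = sprintf("%s_r%04d", genome_id, seq_len(n)),
    sequence = seqs,
    genome_id = genome_id,
    strand = strands,
    start = starts,
    stringsAsFactors = FALSE
  )
}

mutate_read <- function(seq, error_rate) {
  ch <- strsplit(seq, "")[[1L]]
  hit <- which(stats::runif(length(ch)) < error_rate)
  if (length(hit)) {
    bases <- c("A", "C", "G", "T")
    for (i in hit) {
      ch[i] <- sample(setdiff(bases, ch[i]), 1L)
    }
  }
  paste(ch, collapse = "")
}

#' Build a complete synthetic benchmark
#'
#' Generates `n_genomes` well-separated synthetic genomes, a synthetic
#' lineage table (one genus and species per genome; genera grouped into
#' `n_phyla` phyla round-robin, so every rank of the schema carries
#' signal), and error-free read sets at each requested length with a
#' truth table. All randomness derives from `seed`, so two runs are
#' identical.
#'
#' @param n_genomes Number of genomes (>= 2). Default 20.
#' @param genome_length Length of each genome. Default 1e5.
#' @param order Generating-chain order. Default 3.
#' @param concentration Dirichlet concentration. Default 0.1.
#' @param reads_per_genome Reads sampled per genome per length.
#'   Default 50.
#' @param read_lengths Integer vector of read lengths.
#'   Default `c(100, 500, 1000)`.
#' @param error_rate Per-base substitution rate for the reads.
#'   Default 0.
#' @param n_phyla Number of synthetic phyla. Default 5.
#' @param seed Master seed (default 42); per-genome and per-read-set
#'   sub-seeds are drawn from it.
#' @return List with `genomes` (named character vector), `lineage`
#'   (a `lineage_table`), `reads` (named list, one data.frame per read
#'   length as from [sample_reads()]), and `truth` (data.frame
#'   `read_id`, `genome_id`, plus the seven rank columns).
#' @export
make_benchmark <- function(n_genomes = 20L, genome_length = 1e5,
                           order = 3L, concentration = 0.1,
                           reads_per_genome = 50L,
                           read_lengths = c(100L, 500L, 1000L),
                           error_rate = 0, n_phyla = 5L, seed = 42L) {
  stopifnot(n_genomes >= 2L)
  set.seed(seed)
  sub_seeds <- sample.int(.Machine$integer.max - 1L,
                          n_genomes * (1L + length(read_lengths)))
  sub_seeds <- matrix(sub_seeds, nrow = n_genomes)
  ids <- sprintf("g%02d", seq_len(n_genomes))
  genomes <- setNames(vapply(seq_len(n_genomes), function(i) {
    simulate_genome(genome_length, order = order,
                    concentration = concentration,
                    seed = sub_seeds[i, 1L])
  }, character(1)), ids)
  n_phyla <- min(as.integer(n_phyla), n_genomes)
  lineage <- make_lineage_table(
    genome_id = ids,
    superkingdom = rep("Bacteria_syn", n_genomes),
    phylum = sprintf("Phylum_%02d", ((seq_len(n_genomes) - 1L) %% n_phyla) + 1L),
    class = sprintf("Class_%s", ids),
    order = sprintf("Order_%s", ids),
    family = sprintf("Family_%s", ids),
    genus = sprintf("Genus_%s", ids),
    species = sprintf("Species_%s", ids)
  )
  reads <- lapply(seq_along(read_lengths), function(j) {
    len <- read_lengths[j]
    per_genome <- lapply(seq_len(n_genomes), function(i) {
      sample_reads(genomes[[i]], read_length = len, n = reads_per_genome,
                   seed = sub_seeds[i, 1L + j], error_rate = error_rate,
                   genome_id = ids[i])
    })
    out <- do.call(rbind, per_genome)
    out$read_id <- sprintf("L%d_%s", len, out$read_id)
    rownames(out) <- NULL
    out
  })
  names(reads) <- sprintf("L%d", read_lengths)
  truth <- do.call(rbind, lapply(reads, function(r) {
    r[, c("read_id", "genome_id"), drop = FALSE]
  }))
  truth <- cbind(truth,
                 lineage[match(truth$genome_id, lineage$genome_id),
                         TAXONOMY_RANKS, drop = FALSE])
  rownames(truth) <- NULL
  list(genomes = genomes, lineage = lineage, reads = reads, truth = truth)
}

#' Write a benchmark to fixture files
#'
#' Emits `genomes.fasta` (one record per genome), `lineage.tsv`,
#' `reads_L<len>.fasta` per read length, and `truth.tsv` into `dir`.
#' Writers are deterministic, so identical seeds give byte-identical
#' files.
#'
#' @param bench A benchmark from [make_benchmark()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_benchmark <- function(bench, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_fasta(bench$genomes, file.path(dir, "genomes.fasta"))
  write_lineage_table(bench$lineage, file.path(dir, "lineage.tsv"))
  for (nm in names(bench$reads)) {
    r <- bench$reads[[nm]]
    write_fasta(setNames(r$sequence, r$read_id),
                file.path(dir, sprintf("reads_%s.fasta", nm)))
  }
  utils::write.table(bench$truth, file.path(dir, "truth.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = TRUE)
  invisible(dir)
}
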