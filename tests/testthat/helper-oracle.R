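# Independent brute-force oracles, deliberately built from plain string
# operations (no shared code path with the package internals).

oracle_labels <- function(k) {
  bases <- c("A", "C", "G", "T")
  out <- bases
  for (i in seq_len(k)) out <- as.vector(t(outer(out, bases, paste0)))
  sort(out)
}

# enumerate (k+1)-mer windows of one sequence; windows with any
# non-ACGT character are dropped
oracle_windows <- function(seq, k) {
  seq <- toupper(seq)
  L <- nchar(seq)
  if (L < k + 1) return(character(0))
  w <- substring(seq, seq_len(L - k), seq_len(L - k) + k)
  w[!grepl("[^ACGT]", w)]
}

oracle_count <- function(seq, k) {
  labs <- oracle_labels(k)
  tab <- table(factor(oracle_windows(seq, k), levels = labs))
  setNames(as.integer(tab), labs)
}

oracle_revcomp <- function(seq) {
  comp <- chartr("ACGTacgtRYSWKMBDHVN", "TGCAtgcaYRSWMKVHDBN", seq)
  paste(rev(strsplit(comp, "")[[1]]), collapse = "")
}

# -log conditional probabilities from pooled window counts
oracle_costs <- function(seqs, k, missing_cost = 10,
                         strand_policy = "both") {
  if (strand_policy == "both") {
    seqs <- c(seqs, vapply(seqs, oracle_revcomp, character(1)))
  }
  counts <- Reduce(`+`, lapply(seqs, oracle_count, k = k))
  labs <- names(counts)
  ctx <- substr(labs, 1, k)
  ctx_tot <- tapply(counts, ctx, sum)[ctx]
  costs <- ifelse(counts > 0, -log(counts / ctx_tot), missing_cost)
  setNames(as.numeric(costs), labs)
}

# per-transition score of one read against one cost vector
oracle_score <- function(read, costs, k) {
  sum(costs[oracle_windows(read, k)])
}

# random DNA helpers for property-style cases
random_dna <- function(n, alphabet = c("A", "C", "G", "T")) {
  paste(sample(alphabet, n, replace = TRUE), collapse = "")
}
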