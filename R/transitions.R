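#' (k+1)-mer transition counts of a DNA sequence
#'
#' A k-th order Markov model treats a DNA sequence as a chain of k-mer
#' states; consecutive states overlap by k-1 bases, so one transition is
#' one (k+1)-mer window. `count_transitions()` tallies every window of
#' k+1 consecutive unambiguous bases into a vector of length 4^(k+1),
#' indexed lexicographically (A<C<G<T, first base most significant): the
#' first k bases of the window are the context, the last base the
#' successor. Windows containing any non-ACGT letter are skipped without
#' affecting downstream windows; for a gap-free sequence of length L the
#' total count is L-k.
#'
#' @param sequence A single DNA sequence: a character string or a
#'   [Biostrings::DNAString]. IUPAC ambiguity codes are allowed (their
#'   windows are simply not counted); case is ignored.
#' @param k Markov-model order (number of context bases), an integer
#'   between 1 and 8.
#' @return An object of class `transition_counts`: a list with elements
#'   `k` and `counts` (named non-negative integer vector of length
#'   4^(k+1)).
#' @examples
#' tc <- count_transitions("AACG", k = 1)
#' tc$counts[tc$counts > 0]   # AA, AC, CG each once
#' @export
count_transitions <- function(sequence, k) {
  k <- check_order(k)
  x <- as_dna(sequence)
  counts <- Biostrings::oligonucleotideFrequency(x, width = k + 1L)
  new_transition_counts(k, counts)
}

new_transition_counts <- function(k, counts) {
  structure(list(k = k, counts = counts), class = "transition_counts")
}

#' @export
print.transition_counts <- function(x, ...) {
  nz <- sum(x$counts > 0)
  cat(sprintf(
    "transition_counts: order k=%d, %d cells (%d non-zero), %d transitions\n",
    x$k, length(x$counts), nz, sum(x$counts)
  ))
  invisible(x)
}

# Shared input checks -------------------------------------------------------

check_order <- function(k) {
  if (length(k) != 1L || is.na(k) || k < 1 || k != as.integer(k)) {
    stop("`k` must be a single integer >= 1", call. = FALSE)
  }
  k <- as.integer(k)
  if (k > 8L) {
    stop("`k` must be <= 8 (cost vectors grow as 4^(k+1))", call. = FALSE)
  }
  k
}

as_dna <- function(sequence) {
  if (methods::is(sequence, "DNAString")) return(sequence)
  if (is.character(sequence) && length(sequence) == 1L) {
    return(Biostrings::DNAString(sequence))
  }
  stop("`sequence` must be a single character string or DNAString",
       call. = FALSE)
}

as_dna_set <- function(sequences) {
  if (methods::is(sequences, "DNAStringSet")) return(sequences)
  if (methods::is(sequences, "DNAString")) {
    return(Biostrings::DNAStringSet(list(sequences)))
  }
  if (is.character(sequences)) {
    return(Biostrings::DNAStringSet(sequences))
  }
  if (is.list(sequences)) {
    return(Biostrings::DNAStringSet(vapply(sequences, function(s) {
      as.character(as_dna(s))
    }, character(1))))
  }
  stop("`sequences` must be a character vector, list, or DNAStringSet",
       call. = FALSE)
}

#' Names of all (k+1)-mer transitions in index order
#'
#' @param k Model order.
#' @return Character vector of length 4^(k+1), lexicographic (A<C<G<T).
#' @keywords internal
transition_labels <- function(k) {
  k <- check_order(k)
  Biostrings::mkAllStrings(c("A", "C", "G", "T"), width = k + 1L)
}
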