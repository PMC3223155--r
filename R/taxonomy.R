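#' The fixed seven-rank lineage schema
#'
#' Ranks used throughout the package, from coarsest to finest. Lineage
#' labels are opaque strings compared case-sensitively; `"NA"` marks an
#' unknown rank and never matches anything (including another `"NA"`)
#' when accuracy is scored.
#'
#' @export
TAXONOMY_RANKS <- c("superkingdom", "phylum", "class", "order",
                    "family", "genus", "species")

LINEAGE_COLUMNS <- c("genome_id", TAXONOMY_RANKS)

#' Read a genome lineage table
#'
#' Parses a tab-separated table with header
#' `genome_id superkingdom phylum class order family genus species`
#' mapping each reference genome to its lineage. `"NA"` marks unknown
#' ranks.
#'
#' @param path Path to the TSV file.
#' @return A data.frame with the eight columns above, one row per
#'   genome, class `lineage_table`.
#' @export
parse_lineage_table <- function(path) {
  if (!file.exists(path)) stop("lineage table not found: ", path, call. = FALSE)
  tab <- utils::read.delim(path, header = TRUE, sep = "\t",
                           colClasses = "character", check.names = FALSE,
                           na.strings = NULL, quote = "")
  validate_lineage_table(tab, where = path)
}

validate_lineage_table <- function(tab, where = "lineage table") {
  if (!is.data.frame(tab)) {
    stop(where, ": expected a data.frame", call. = FALSE)
  }
  missing_cols <- setdiff(LINEAGE_COLUMNS, names(tab))
  if (length(missing_cols)) {
    stop(where, ": missing required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  tab <- tab[, LINEAGE_COLUMNS, drop = FALSE]
  for (cn in LINEAGE_COLUMNS) tab[[cn]] <- as.character(tab[[cn]])
  bad <- which(!nzchar(tab$genome_id) | is.na(tab$genome_id))
  if (length(bad)) {
    stop(where, ": empty genome_id at data row ", bad[1L], call. = FALSE)
  }
  dup <- tab$genome_id[duplicated(tab$genome_id)]
  if (length(dup)) {
    stop(where, ": duplicate genome_id: ",
         paste(unique(dup), collapse = ", "), call. = FALSE)
  }
  # short/ragged rows surface as NA or "" fills; unknown ranks must be
  # spelled out as the literal string "NA"
  incomplete <- which(apply(tab[TAXONOMY_RANKS], 1L, function(r) {
    any(is.na(r) | !nzchar(r))
  }))
  if (length(incomplete)) {
    stop(where, ": malformed row ", incomplete[1L],
         " (missing rank field; use the literal string \"NA\")",
         call. = FALSE)
  }
  class(tab) <- c("lineage_table", "data.frame")
  tab
}

#' Construct a lineage table in code
#'
#' @param genome_id Character vector of genome ids.
#' @param ... Named rank vectors (any of the seven ranks); omitted ranks
#'   are filled with `"NA"`.
#' @return A `lineage_table` data.frame.
#' @export
make_lineage_table <- function(genome_id, ...) {
  ranks <- list(...)
  tab <- data.frame(genome_id = as.character(genome_id),
                    stringsAsFactors = FALSE)
  for (r in TAXONOMY_RANKS) {
    tab[[r]] <- if (!is.null(ranks[[r]])) as.character(ranks[[r]]) else "NA"
  }
  validate_lineage_table(tab, where = "make_lineage_table()")
}

#' Write a lineage table as TSV
#'
#' @param tab A `lineage_table`.
#' @param path Output path.
#' @export
write_lineage_table <- function(tab, path) {
  tab <- validate_lineage_table(tab)
  utils::write.table(tab, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' Classification accuracy at one taxonomy rank
#'
#' The fraction of reads whose predicted lineage label at `rank` equals
#' the true label: correctly predicted reads divided by all reads.
#' Unclassified reads and `"NA"` labels (on either side) count as
#' incorrect, so the denominator is always the full read set and
#' accuracies are comparable across parameter settings.
#'
#' @param assignments Classification results carrying lineage columns,
#'   as returned by [classify_reads()]/[classify_stream()] (or any
#'   data.frame with `read_id` and the rank columns).
#' @param truth Truth table: data.frame with `read_id` and the rank
#'   columns (e.g. the `truth` element of [make_benchmark()]), covering
#'   every read in `assignments`. Alternatively, for genome-level
#'   accuracy use `rank = "genome_id"` with a `genome_id` truth column.
#' @param rank One of the seven ranks, or `"genome_id"`.
#' @return A single number in \[0, 1\].
#' @export
accuracy_at_rank <- function(assignments, truth, rank) {
  rank <- as.character(rank)
  if (!rank %in% c(TAXONOMY_RANKS, "genome_id")) {
    stop("unknown rank: '", rank, "' (expected one of ",
         paste(c(TAXONOMY_RANKS, "genome_id"), collapse = ", "), ")",
         call. = FALSE)
  }
  for (need in c("read_id", rank)) {
    if (!need %in% names(assignments)) {
      stop("assignments lack column '", need, "'", call. = FALSE)
    }
    if (!need %in% names(truth)) {
      stop("truth lacks column '", need, "'", call. = FALSE)
    }
  }
  hit <- match(assignments$read_id, truth$read_id)
  if (anyNA(hit)) {
    stop("no truth lineage for read_id: ",
         paste(utils::head(assignments$read_id[is.na(hit)], 3L),
               collapse = ", "), call. = FALSE)
  }
  pred <- as.character(assignments[[rank]])
  true <- as.character(truth[[rank]])[hit]
  ok <- !is.na(pred) & !is.na(true) & pred != "NA" & true != "NA" &
    pred != "UNCLASSIFIED" & pred == true
  sum(ok) / length(ok)
}

#' Community composition profile at one rank
#'
#' Tallies assignments by their lineage label at `rank` (the histogram
#' behind phylum-level community summaries). `UNCLASSIFIED` is kept as
#' its own label; with `top_n`, labels beyond the `top_n` most abundant
#' are pooled into `"OTHER"`. Fractions always sum to 1.
#'
#' @param assignments As in [accuracy_at_rank()].
#' @param rank One of the seven ranks, or `"genome_id"`.
#' @param top_n Optional number of labels to keep before pooling.
#' @return data.frame `label`, `read_count`, `fraction`, sorted by
#'   count descending (ties: label order of first appearance).
#' @export
composition_profile <- function(assignments, rank, top_n = NULL) {
  rank <- as.character(rank)
  if (!rank %in% c(TAXONOMY_RANKS, "genome_id")) {
    stop("unknown rank: '", rank, "'", call. = FALSE)
  }
  if (!rank %in% names(assignments)) {
    stop("assignments lack column '", rank, "'", call. = FALSE)
  }
  lab <- as.character(assignments[[rank]])
  lab[is.na(lab)] <- "UNCLASSIFIED"
  cnt <- table(factor(lab, levels = unique(lab)))
  ord <- order(-as.integer(cnt))
  cnt <- cnt[ord]
  out <- data.frame(label = names(cnt), read_count = as.integer(cnt),
                    stringsAsFactors = FALSE)
  if (!is.null(top_n) && nrow(out) > top_n) {
    keep <- out[seq_len(top_n), , drop = FALSE]
    rest <- out[-seq_len(top_n), , drop = FALSE]
    keep <- rbind(keep, data.frame(label = "OTHER",
                                   read_count = sum(rest$read_count),
                                   stringsAsFactors = FALSE))
    out <- keep
  }
  out$fraction <- out$read_count / max(1L, sum(out$read_count))
  rownames(out) <- NULL
  out
}
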