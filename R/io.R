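#' Read a FASTA file
#'
#' Thin wrapper over [Biostrings::readDNAStringSet()] (plain or gzip,
#' LF or CRLF). The record id is the first whitespace-delimited token of
#' the header; the remainder is kept as the description. Records with
#' empty sequences are dropped with a warning; a file with no usable
#' records is an error.
#'
#' @param path Path to the FASTA file.
#' @return data.frame `id`, `description`, `sequence`, in file order.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("FASTA file not found: ", path, call. = FALSE)
  set <- tryCatch(
    Biostrings::readDNAStringSet(path, format = "fasta"),
    error = function(e) {
      stop("failed to parse FASTA '", path, "': ", conditionMessage(e),
           call. = FALSE)
    }
  )
  headers <- names(set)
  ids <- sub("\\s.*$", "", headers)
  desc <- ifelse(grepl("\\s", headers),
                 sub("^\\S+\\s+", "", headers), "")
  out <- data.frame(id = ids, description = desc,
                    sequence = as.character(set),
                    stringsAsFactors = FALSE)
  empty <- !nzchar(out$sequence)
  if (any(empty)) {
    warning("skipping ", sum(empty), " empty record(s) in ", path,
            call. = FALSE)
    out <- out[!empty, , drop = FALSE]
  }
  if (nrow(out) == 0L) {
    stop("no usable FASTA records in ", path, call. = FALSE)
  }
  rownames(out) <- NULL
  out
}

#' Write sequences as FASTA
#'
#' Deterministic writer (fixed 70-column wrapping, LF line endings).
#'
#' @param sequences Named character vector or data.frame with
#'   `id`/`read_id` and `sequence` columns.
#' @param path Output path.
#' @export
write_fasta <- function(sequences, path) {
  if (is.data.frame(sequences)) {
    ids <- sequences[["id"]] %||% sequences[["read_id"]]
    sequences <- setNames(as.character(sequences$sequence),
                          as.character(ids))
  }
  set <- Biostrings::DNAStringSet(sequences)
  Biostrings::writeXStringSet(set, path, width = 70L)
  invisible(path)
}

DB_MAGIC <- "MARKOVBIN1"

#' Save a reference database to its binary container
#'
#' Container layout: the magic string `"MARKOVBIN1"`, then k, the
#' missing cost, the strand policy and the genome count, a UTF-8
#' tab-delimited genome metadata block, and the genomes x 4^(k+1) cost
#' matrix as little-endian 32-bit floats, row-major. Writing is
#' deterministic and [load_database()] restores the object bit-exactly
#' (the in-memory matrix is already binary32-valued).
#'
#' @param db A `reference_db`.
#' @param path Output path.
#' @export
save_database <- function(db, path) {
  stopifnot(inherits(db, "reference_db"))
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(charToRaw(DB_MAGIC), con)
  writeBin(as.integer(db$k), con, size = 4L, endian = "little")
  writeBin(as.numeric(db$missing_cost), con, size = 8L, endian = "little")
  pol <- charToRaw(db$strand_policy)
  writeBin(length(pol), con, size = 4L, endian = "little")
  writeBin(pol, con)
  writeBin(nrow(db$matrix), con, size = 4L, endian = "little")
  meta_lines <- c(
    paste(names(db$genomes), collapse = "\t"),
    vapply(seq_len(nrow(db$genomes)), function(i) {
      paste(vapply(db$genomes[i, ], as.character, character(1)),
            collapse = "\t")
    }, character(1))
  )
  meta_raw <- charToRaw(enc2utf8(paste(meta_lines, collapse = "\n")))
  writeBin(length(meta_raw), con, size = 4L, endian = "little")
  writeBin(meta_raw, con)
  writeBin(as.numeric(t(db$matrix)), con, size = 4L, endian = "little")
  invisible(path)
}

#' Load a reference database from its binary container
#'
#' @param path Path written by [save_database()].
#' @return A `reference_db`.
#' @export
load_database <- function(path) {
  if (!file.exists(path)) stop("database file not found: ", path,
                               call. = FALSE)
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- rawToChar(readBin(con, "raw", n = nchar(DB_MAGIC)))
  if (!identical(magic, DB_MAGIC)) {
    stop("not a markovbin database: bad magic in ", path, call. = FALSE)
  }
  hdr <- function(what, n, size) {
    v <- readBin(con, what, n = n, size = size, endian = "little")
    if (length(v) < n) stop("truncated markovbin database: ", path,
                            call. = FALSE)
    v
  }
  k <- hdr("integer", 1L, 4L)
  if (k < 1L || k > 8L) {
    stop("unsupported markovbin database version/order (k=", k, ") in ",
         path, call. = FALSE)
  }
  missing_cost <- hdr("numeric", 1L, 8L)
  pol_len <- hdr("integer", 1L, 4L)
  pol_raw <- readBin(con, "raw", n = pol_len)
  if (length(pol_raw) < pol_len) stop("truncated markovbin database: ",
                                      path, call. = FALSE)
  strand_policy <- rawToChar(pol_raw)
  n_genomes <- hdr("integer", 1L, 4L)
  meta_len <- hdr("integer", 1L, 4L)
  meta_raw <- readBin(con, "raw", n = meta_len)
  if (length(meta_raw) < meta_len) stop("truncated markovbin database: ",
                                        path, call. = FALSE)
  meta <- utils::read.delim(text = rawToChar(meta_raw), sep = "\t",
                            colClasses = "character", check.names = FALSE,
                            na.strings = NULL, quote = "")
  meta$n_transitions_trained <- as.numeric(meta$n_transitions_trained)
  ncell <- 4L^(k + 1L)
  vals <- readBin(con, "numeric", n = n_genomes * ncell, size = 4L,
                  endian = "little")
  if (length(vals) < n_genomes * ncell) {
    stop("truncated markovbin database: ", path,
         " (expected ", n_genomes * ncell, " matrix cells, got ",
         length(vals), ")", call. = FALSE)
  }
  mat <- matrix(vals, nrow = n_genomes, ncol = ncell, byrow = TRUE,
                dimnames = list(meta$genome_id, transition_labels(k)))
  new_reference_db(k, missing_cost, strand_policy, mat, meta)
}

#' Write classification results as TSV
#'
#' Column order: `read_id`, `genome_id`, `score`, `n_transitions`, then
#' the seven lineage ranks (plus `hit_rank` when present from
#' `top > 1`). Deterministic: fixed column order, scores printed with
#' `%.6f`, no timestamps.
#'
#' @param assignments Assignment data.frame from [classify_reads()] or
#'   [classify_stream()].
#' @param path Output path.
#' @export
write_results <- function(assignments, path) {
  cols <- c("read_id",
            if ("hit_rank" %in% names(assignments)) "hit_rank",
            "genome_id", "score", "n_transitions", TAXONOMY_RANKS)
  out <- assignments[, cols, drop = FALSE]
  out$score <- ifelse(is.na(out$score), "NA", sprintf("%.6f", out$score))
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' Read a classification results TSV
#'
#' @param path Path written by [write_results()].
#' @return data.frame with the results columns.
#' @export
read_results <- function(path) {
  tab <- utils::read.delim(path, sep = "\t", colClasses = "character",
                           check.names = FALSE, na.strings = "NA",
                           quote = "")
  if (!all(c("read_id", "genome_id", "score") %in% names(tab))) {
    stop("not a markovbin results table: ", path, call. = FALSE)
  }
  tab$score <- as.numeric(tab$score)
  if ("n_transitions" %in% names(tab)) {
    tab$n_transitions <- as.integer(tab$n_transitions)
  }
  for (r in TAXONOMY_RANKS) {
    if (r %in% names(tab)) tab[[r]][is.na(tab[[r]])] <- "NA"
  }
  tab
}
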