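#' Read sequence pairs from the two-line pair format
#'
#' The native dataset format of pairwise-alignment benchmarks: each pair
#' occupies two lines, the pattern prefixed with `>` and the text with
#' `<`.  Ids are assigned by record order (`pair1`, `pair2`, ...).
#'
#' @param path File path.
#' @return `data.frame` with columns `id`, `pattern`, `text`.
#' @export
read_seq_pairs <- function(path) {
  lines <- readLines(path)
  if (length(lines) %% 2L != 0L)
    stop("malformed pair file (odd line count): ", path)
  if (length(lines) == 0L)
    return(data.frame(id = character(0), pattern = character(0),
                      text = character(0), stringsAsFactors = FALSE))
  pi <- seq(1L, length(lines), by = 2L)
  bad <- c(pi[!startsWith(lines[pi], ">")], (pi + 1L)[!startsWith(lines[pi + 1L], "<")])
  if (length(bad))
    stop(sprintf("parse error at line %d: expected '>'/'<' prefix", min(bad)))
  data.frame(id = paste0("pair", seq_along(pi)),
             pattern = substring(lines[pi], 2L),
             text = substring(lines[pi + 1L], 2L), stringsAsFactors = FALSE)
}

#' Write sequence pairs in the two-line pair format
#'
#' @param path File path.
#' @param pairs `data.frame` with columns `pattern` and `text`.
#' @return `path`, invisibly.
#' @export
write_seq_pairs <- function(path, pairs) {
  check_pairs(pairs)
  con <- file(path, "w")
  on.exit(close(con))
  if (nrow(pairs))
    writeLines(rbind(paste0(">", pairs$pattern), paste0("<", pairs$text)),
               con)
  invisible(path)
}

#' Read sequence pairs from two FASTA files
#'
#' Pairs the k-th record of `path_a` (patterns) with the k-th record of
#' `path_b` (texts); record counts must match.  Multi-line sequences are
#' supported; ids come from the pattern file's headers.
#'
#' @param path_a,path_b FASTA file paths.
#' @param normalize_case Uppercase both sequences (by default comparison
#'   is case-sensitive and every byte is a valid symbol; `N` matches
#'   only `N`).
#' @return `data.frame` with columns `id`, `pattern`, `text`.
#' @export
read_fasta_pairs <- function(path_a, path_b, normalize_case = FALSE) {
  if (!requireNamespace("Biostrings", quietly = TRUE))
    stop("read_fasta_pairs() requires the Biostrings package")
  a <- Biostrings::readBStringSet(path_a)
  b <- Biostrings::readBStringSet(path_b)
  if (length(a) != length(b))
    stop(sprintf("record count mismatch: %d vs %d", length(a), length(b)))
  pat <- as.character(a); txt <- as.character(b)
  if (normalize_case) { pat <- toupper(pat); txt <- toupper(txt) }
  ids <- names(a)
  if (is.null(ids) || any(!nzchar(ids))) ids <- paste0("pair", seq_along(pat))
  data.frame(id = make.unique(ids), pattern = unname(pat),
             text = unname(txt), stringsAsFactors = FALSE)
}
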