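#' Generate one synthetic sequence pair
#'
#' Draws a uniform random pattern of length `n` over `alphabet` and
#' derives the text by applying `round(error_rate * n)` edits at
#' uniformly chosen, distinct pattern positions, each edit type drawn
#' from `op_mix` (mismatch, insertion, deletion).  Edits are applied
#' right-to-left at the sorted positions so that insertions never shift
#' later edit positions; a mismatch always substitutes a *different*
#' symbol.  This emulates simulated read pairs with a nominal,
#' uniformly distributed error rate.  Note that independent edits can
#' partially cancel, so the optimal edit distance is at most (typically
#' slightly below) the number of edits applied.
#'
#' @param n Pattern length.
#' @param error_rate Nominal error rate in `[0, 1]`.
#' @param seed Optional integer seed (applied via [set.seed()]); if
#'   `NULL` the current RNG stream is used.
#' @param op_mix Probabilities of (mismatch, insertion, deletion);
#'   must sum to 1.  Default uniform.
#' @param alphabet Symbols to draw from. Default `A,C,G,T`.
#' @param id Record identifier.
#' @return List with `record` (list `id`, `pattern`, `text`) and
#'   `edits_applied`.
#' @examples
#' g <- generate_pair(100, 0.1, seed = 1)
#' g$edits_applied  # 10
#' @export
generate_pair <- function(n, error_rate, seed = NULL,
                          op_mix = c(1, 1, 1) / 3,
                          alphabet = c("A", "C", "G", "T"), id = "pair1") {
  if (!is.numeric(error_rate) || error_rate < 0 || error_rate > 1)
    stop("error_rate must be in [0, 1]")
  if (length(op_mix) != 3L || any(op_mix < 0) ||
      abs(sum(op_mix) - 1) > 1e-8)
    stop("op_mix must be three non-negative probabilities summing to 1")
  if (!is.null(seed)) set.seed(seed)
  pat <- sample(alphabet, n, replace = TRUE)
  k <- round(error_rate * n)
  x <- pat
  if (k > 0) {
    pos <- sort(sample.int(n, k), decreasing = TRUE)
    ops <- sample.int(3L, k, replace = TRUE, prob = op_mix)
    for (z in seq_len(k)) {
      p <- pos[z]
      if (ops[z] == 1L) {             # mismatch
        x[p] <- sample(setdiff(alphabet, x[p]), 1L)
      } else if (ops[z] == 2L) {      # insertion
        x <- append(x, sample(alphabet, 1L), after = p)
      } else {                        # deletion
        x <- x[-p]
      }
    }
  }
  list(record = list(id = id, pattern = paste(pat, collapse = ""),
                     text = paste(x, collapse = "")),
       edits_applied = k)
}

#' Generate a batch of synthetic sequence pairs
#'
#' Repeatedly calls [generate_pair()]; the whole batch is reproducible
#' from `seed`.
#'
#' @inheritParams generate_pair
#' @param num_pairs Number of pairs.
#' @param id_prefix Prefix of the generated ids.
#' @return `data.frame` with columns `id`, `pattern`, `text`,
#'   `edits_applied`.
#' @export
generate_pairs <- function(num_pairs, n, error_rate, seed = NULL,
                           op_mix = c(1, 1, 1) / 3,
                           alphabet = c("A", "C", "G", "T"),
                           id_prefix = "pair") {
  if (!is.null(seed)) set.seed(seed)
  rows <- lapply(seq_len(num_pairs), function(k) {
    g <- generate_pair(n, error_rate, seed = NULL, op_mix = op_mix,
                       alphabet = alphabet,
                       id = paste0(id_prefix, k))
    data.frame(id = g$record$id, pattern = g$record$pattern,
               text = g$record$text, edits_applied = g$edits_applied,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
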