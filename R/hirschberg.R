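#' Score-only boundary pass for divide-and-conquer
#'
#' Runs the score-bounded tile sweep up to `split_col` and returns the
#' `H` values of that column for every pattern row (+`Inf` for rows
#' outside the region the cutoff admits).  The cutoff anticipates the
#' full (sub)problem's corner, so the admitted rows are those that can
#' lie on a path of cost at most `s_hat` from `(0,0)` to `(n,m)`.  The
#' `"backward"` direction computes, for each row `i`, the cost of
#' aligning `pattern[(i+1)..n]` against `text[(split_col+1)..m]` by
#' running the same sweep on the reversed remainder.  No traceback state
#' is retained.
#'
#' @inheritParams edit_dp_oracle
#' @param s_hat Score bound for the cutoff.
#' @param direction `"forward"` or `"backward"`.
#' @param split_col Column at which scores are read, `0..m`.
#' @return Numeric vector of length `nchar(pattern) + 1`; element `i + 1`
#'   is the prefix (or suffix) score at row `i`, or `Inf`.
#' @export
score_column_pass <- function(pattern, text, s_hat,
                              direction = c("forward", "backward"),
                              split_col) {
  check_seq(pattern); check_seq(text)
  direction <- match.arg(direction)
  n <- nchar(pattern); m <- nchar(text)
  if (split_col < 0 || split_col > m) stop("split_col out of range")
  if (direction == "forward") {
    if (split_col == 0L) return(as.numeric(0:n))
    cpp_score_pass(pattern, text, s_hat, split_col)
  } else {
    if (split_col == m) return(as.numeric(n:0))
    rev(cpp_score_pass(cpp_revstr(pattern), cpp_revstr(text), s_hat,
                       m - split_col))
  }
}

#' Optimal meeting point of forward and backward passes
#'
#' Given prefix scores `fwd` and suffix scores `bwd` on the same split
#' column (as returned by [score_column_pass()]), finds the row
#' minimizing their sum.  When the bound used for the passes is at least
#' the optimal score, the minimum equals the (sub)problem's exact optimal
#' score `s*`, and the prefix/suffix scores at the breakpoint are exact
#' bounds for the two subproblems.
#'
#' @param fwd,bwd Numeric vectors of equal length (`Inf` allowed).
#' @return List with `row` (0-based, smallest on ties), `prefix_score`,
#'   `suffix_score`, `s_star`.  If every sum is infinite the bound was
#'   too small; an error is raised so the caller can retry with a larger
#'   bound.
#' @examples
#' find_breakpoint(c(2, 1, 3), c(1, 1, 2))  # row 1, s* = 2
#' @export
find_breakpoint <- function(fwd, bwd) {
  if (length(fwd) != length(bwd)) stop("fwd and bwd must have equal length")
  tot <- fwd + bwd
  if (!any(is.finite(tot)))
    stop("no finite breakpoint: score bound too small")
  i <- which.min(tot)  # first minimum = smallest row
  list(row = i - 1L, prefix_score = fwd[i], suffix_score = bwd[i],
       s_star = tot[i])
}

# Worst-case bytes of retained tile traces for a direct bounded
# alignment: tiles admitted per column are at most 2*ceil(s/64)+3.
worst_case_trace_bytes <- function(n, m, s_hat) {
  ceiling(max(n, m) / 64) * (2 * ceiling(s_hat / 64) + 3) * (80 + 16 * 64)
}

#' Exact alignment in bounded memory (divide-and-conquer)
#'
#' Computes the same exact alignment as [bounded_align()] while keeping
#' traceback memory below a configurable threshold.  When the worst-case
#' trace storage of a direct bounded alignment fits under
#' `mem_limit` (or the text is at most 128 columns), the problem is
#' solved directly.  Otherwise the text is split at the tile-aligned
#' column nearest `m/2`, score-only forward and backward passes meet at
#' the split column, and [find_breakpoint()] yields a row where the two
#' halves meet optimally; the halves are solved recursively with the
#' *exact* sub-scores as bounds (perfect bounds, which tightens every
#' deeper level).  If a supplied bound turns out below the optimum the
#' passes cannot meet within it, and the bound is doubled transparently.
#'
#' @inheritParams bounded_align
#' @param mem_limit Trace-memory threshold in bytes (default 16 MiB,
#'   about a modern last-level cache).
#' @return An `edit_alignment` (see [bounded_align()]) with additional
#'   fields `peak_trace_bytes` (largest trace storage held at any one
#'   time, instrumented), `splits` (breakpoints computed) and `depth`
#'   (maximum recursion depth).
#' @examples
#' a <- hirschberg_align(strrep("AC", 300), strrep("AC", 300), 0,
#'                       mem_limit = 1)
#' a$score  # 0
#' @export
hirschberg_align <- function(pattern, text, s_hat, mem_limit = 16 * 2^20) {
  check_seq(pattern); check_seq(text)
  if (s_hat < 0) stop("s_hat must be non-negative")
  if (mem_limit <= 0) stop("mem_limit must be positive")
  env <- new.env(parent = emptyenv())
  env$peak <- 0; env$tiles <- 0; env$splits <- 0L; env$retries <- 0L
  r <- hb_rec(pattern, text, s_hat, mem_limit, env, 1L)
  structure(list(score = r$score, cigar = r$cigar,
                 tiles_computed = env$tiles, tiles_total = env$tiles,
                 bound_used = s_hat, retries = env$retries,
                 trace_bytes = env$peak, peak_trace_bytes = env$peak,
                 splits = env$splits, depth = env$depth %||% 1L,
                 stage = NULL),
            class = "edit_alignment")
}

hb_rec <- function(p, t, s_hat, mem_limit, env, depth) {
  env$depth <- max(env$depth %||% 1L, depth)
  n <- nchar(p); m <- nchar(t)
  if (n == 0L || m == 0L || m <= 128L ||
      worst_case_trace_bytes(n, m, s_hat) <= mem_limit) {
    r <- cpp_bounded_align(p, t, s_hat)
    env$peak <- max(env$peak, r$trace_bytes)
    env$tiles <- env$tiles + r$total_tiles
    env$retries <- env$retries + r$retries
    return(list(score = r$score, cigar = r$cigar))
  }
  split <- 64 * round(m / 128)
  split <- max(64, min(split, 64 * floor((m - 1) / 64)))
  s <- s_hat
  repeat {
    fwd <- cpp_score_pass(p, t, s, split)
    bwd <- rev(cpp_score_pass(cpp_revstr(p), cpp_revstr(t), s, m - split))
    tot <- fwd + bwd
    if (any(is.finite(tot)) && min(tot) <= s) break
    if (s >= n + m) stop("internal error: no breakpoint at the full bound")
    s <- min(n + m, max(1, 2 * s))
    env$retries <- env$retries + 1L
  }
  bp <- find_breakpoint(fwd, bwd)
  env$splits <- env$splits + 1L
  left <- hb_rec(substr(p, 1L, bp$row), substr(t, 1L, split),
                 bp$prefix_score, mem_limit, env, depth + 1L)
  right <- hb_rec(substr(p, bp$row + 1L, n), substr(t, split + 1L, m),
                  bp$suffix_score, mem_limit, env, depth + 1L)
  stopifnot(left$score + right$score == bp$s_star)
  list(score = bp$s_star,
       cigar = merge_cigar_runs(rbind(parse_cigar(left$cigar),
                                      parse_cigar(right$cigar))))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
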