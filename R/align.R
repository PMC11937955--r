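#' Score-bounded exact alignment with traceback
#'
#' Computes the exact optimal edit distance and its CIGAR, restricting
#' computation to 64 x 64 tiles that can contain a cell of an alignment
#' path of cost at most `s_hat`.  Tile columns are processed left to
#' right with an active tile-row range around the target diagonal
#' `d = m - n`; a tile is computed iff its boundary cell closest to the
#' target diagonal satisfies \eqn{H + d_k \le \hat s}, where
#' \eqn{d_k(i,j) = |(j-i)-(m-n)|} is the remaining distance to the target
#' diagonal (bottom-left cell for tiles above the diagonal, upper-right
#' for tiles below; straddling tiles are always computed, and the active
#' range never drops below 3 tile rows).  Vertical differences of every
#' computed tile are stored (about 2 bits per DP-cell) and the alignment
#' is backtraced through them.
#'
#' Because the cutoff uses an upper bound, the result is exact whenever
#' `s_hat >= optimum`.  If a caller supplies a bound below the optimum,
#' the computed score fails its certificate (`score <= s_hat`) and the
#' function transparently retries with the bound doubled, so the returned
#' score is always the exact optimum.
#'
#' @inheritParams edit_dp_oracle
#' @param s_hat Upper bound on the optimal score (see [edit_bound()]).
#' @return Object of class `edit_alignment`: list with `score`, `cigar`
#'   (run-length encoded over `=`, `X`, `I` (consumes pattern), `D`
#'   (consumes text)), `tiles_computed` (successful attempt),
#'   `tiles_total` (including retries), `bound_used`, `retries`,
#'   `trace_bytes` (bytes of stored tile traces).
#' @examples
#' bounded_align("AAAA", "AATA", 1)$cigar  # "2=1X1="
#' @export
bounded_align <- function(pattern, text, s_hat) {
  check_seq(pattern); check_seq(text)
  if (s_hat < 0) stop("s_hat must be non-negative")
  r <- cpp_bounded_align(pattern, text, s_hat)
  new_edit_alignment(r)
}

new_edit_alignment <- function(r, stage = NULL) {
  structure(list(score = r$score, cigar = r$cigar,
                 tiles_computed = r$tiles, tiles_total = r$total_tiles,
                 bound_used = r$bound_used, retries = r$retries,
                 trace_bytes = r$trace_bytes, stage = stage),
            class = "edit_alignment")
}

#' @export
print.edit_alignment <- function(x, ...) {
  cig <- x$cigar
  if (nchar(cig) > 60) cig <- paste0(substr(cig, 1, 57), "...")
  cat(sprintf("edit alignment: score %g%s\n  cigar: %s\n", x$score,
              if (!is.null(x$stage)) paste0(" (bound stage ", x$stage, ")")
              else "", cig))
  invisible(x)
}

parse_cigar <- function(cigar) {
  if (!is.character(cigar) || length(cigar) != 1L) stop("cigar must be a string")
  if (cigar == "") return(data.frame(len = integer(0), op = character(0)))
  toks <- regmatches(cigar, gregexpr("[0-9]+[=XIDM]", cigar))[[1]]
  if (sum(nchar(toks)) != nchar(cigar)) stop("malformed cigar: ", cigar)
  data.frame(len = as.integer(sub("[=XIDM]$", "", toks)),
             op = sub("^[0-9]+", "", toks), stringsAsFactors = FALSE)
}

#' Validate an alignment against its sequences
#'
#' Checks the structural invariants of an extended-CIGAR alignment: every
#' run length is positive and adjacent runs use distinct operations; the
#' operations consume exactly the pattern (`=`, `X`, `I`) and exactly the
#' text (`=`, `X`, `D`); `=` runs match byte for byte and `X` runs
#' mismatch at every position; and the implied cost (`#X + #I + #D`)
#' equals the reported score.
#'
#' @inheritParams edit_dp_oracle
#' @param alignment An `edit_alignment` object, or a list with elements
#'   `score` and `cigar`.
#' @return `TRUE`, or `FALSE` with the failing check in attribute
#'   `"reason"`.
#' @export
validate_alignment <- function(pattern, text, alignment) {
  check_seq(pattern); check_seq(text)
  fail <- function(reason) structure(FALSE, reason = reason)
  ops <- tryCatch(parse_cigar(alignment$cigar), error = function(e) NULL)
  if (is.null(ops)) return(fail("malformed cigar"))
  if (any(ops$len < 1L)) return(fail("non-positive run length"))
  if (nrow(ops) > 1L && any(ops$op[-1L] == ops$op[-nrow(ops)]))
    return(fail("adjacent runs with identical op"))
  if (any(ops$op == "M")) return(fail("classic 'M' op is not validatable"))
  i <- 0L; j <- 0L; cost <- 0L
  for (k in seq_len(nrow(ops))) {
    L <- ops$len[k]
    switch(ops$op[k],
      "=" = {
        if (substr(pattern, i + 1L, i + L) != substr(text, j + 1L, j + L))
          return(fail("'=' run mismatches"))
        i <- i + L; j <- j + L
      },
      "X" = {
        a <- strsplit(substr(pattern, i + 1L, i + L), "")[[1]]
        b <- strsplit(substr(text, j + 1L, j + L), "")[[1]]
        if (length(a) < L || length(b) < L || any(a == b))
          return(fail("'X' run contains a match"))
        i <- i + L; j <- j + L; cost <- cost + L
      },
      "I" = { i <- i + L; cost <- cost + L },
      "D" = { j <- j + L; cost <- cost + L },
      return(fail("unknown op"))
    )
    if (i > nchar(pattern) || j > nchar(text))
      return(fail("consumption overruns a sequence"))
  }
  if (i != nchar(pattern) || j != nchar(text))
    return(fail("consumption short of sequence ends"))
  if (cost != alignment$score) return(fail("implied cost differs from score"))
  TRUE
}

#' Convert an extended CIGAR to classic ops
#'
#' Collapses `=` and `X` runs into `M` and merges adjacent runs.
#'
#' @param cigar Extended CIGAR string.
#' @return Classic CIGAR string over `M`, `I`, `D`.
#' @export
cigar_classic <- function(cigar) {
  ops <- parse_cigar(cigar)
  if (nrow(ops) == 0L) return("")
  ops$op[ops$op %in% c("=", "X")] <- "M"
  merge_cigar_runs(ops)
}

merge_cigar_runs <- function(ops) {
  keep <- ops$len > 0L
  ops <- ops[keep, , drop = FALSE]
  if (nrow(ops) == 0L) return("")
  grp <- cumsum(c(TRUE, ops$op[-1L] != ops$op[-nrow(ops)]))
  len <- tapply(ops$len, grp, sum)
  op <- tapply(ops$op, grp, function(x) x[[1L]])
  paste0(as.integer(len), op, collapse = "")
}

#' Estimated traceback memory of a bounded alignment
#'
#' The bounded aligner's traceback region spans roughly
#' `max(n, m) * s_hat` DP-cells at 2 bits each, i.e.
#' `ceiling(max(n, m) * s_hat / 4)` bytes.  [hirschberg_align()] switches
#' to divide-and-conquer when this estimate exceeds its memory policy.
#'
#' @param n,m Sequence lengths.
#' @param s_hat Score bound.
#' @return Estimated bytes (numeric).
#' @examples
#' estimate_traceback_bytes(1000, 1000, 100)  # 25000
#' @export
estimate_traceback_bytes <- function(n, m, s_hat) {
  ceiling(max(n, m) * s_hat / 4)
}
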