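#' Full dynamic-programming matrix of edit distances (reference oracle)
#'
#' Fills the complete \eqn{(n+1) \times (m+1)} matrix `H` of edit
#' distances between all prefixes of `pattern` (rows) and `text`
#' (columns) by the classical recurrence
#' \deqn{H_{i,j} = \min(H_{i-1,j} + 1,\; H_{i,j-1} + 1,\; H_{i-1,j-1} +
#'   [p_i \neq t_j])}
#' with border `H[i,0] = i`, `H[0,j] = j`.  `H[n+1, m+1]` (1-based R
#' indexing) is the optimal edit distance.  Quadratic in time and memory;
#' intended as the independent reference that the tile-based aligner is
#' validated against, not for production use.
#'
#' @param pattern,text Single character strings (any bytes; comparison is
#'   exact byte equality, so e.g. `"N"` matches only `"N"` and case
#'   matters).
#' @return Integer matrix of dimensions `(nchar(pattern)+1) x
#'   (nchar(text)+1)`.
#' @examples
#' H <- edit_dp_oracle("kitten", "sitting")
#' H[7, 8]  # 3
#' @export
edit_dp_oracle <- function(pattern, text) {
  check_seq(pattern); check_seq(text)
  cpp_oracle_matrix(pattern, text)
}

#' Edit distance by the reference oracle (score only)
#'
#' As [edit_dp_oracle()] but keeps two rolling rows, so memory is linear.
#'
#' @inheritParams edit_dp_oracle
#' @return Integer scalar, the optimal edit distance.
#' @export
edit_dp_score <- function(pattern, text) {
  check_seq(pattern); check_seq(text)
  cpp_oracle_score(pattern, text)
}

#' Build per-block pattern equality masks
#'
#' Packs the pattern into blocks of 64 rows.  For each block, `masks[[s]]`
#' is a 64-element logical vector whose bit `r` (1-based element `r`) is
#' `TRUE` iff the pattern character at row `64*(k-1)+r` equals symbol `s`.
#' Padding rows of a final partial block are set in no mask, so they can
#' never produce a diagonal match.
#'
#' @param pattern Single character string.
#' @return List of blocks; each block is a list with elements `live`
#'   (number of pattern rows the block covers) and `masks` (named list of
#'   64-element logical vectors, one per distinct symbol in the block).
#'   A symbol absent from `masks` has an all-`FALSE` mask.
#' @examples
#' b <- build_peq_blocks("AAAA")
#' which(b[[1]]$masks[["A"]])  # rows 1..4
#' @export
build_peq_blocks <- function(pattern) {
  check_seq(pattern)
  n <- nchar(pattern)
  if (n == 0L) return(list())
  chars <- strsplit(pattern, "", fixed = TRUE)[[1]]
  lapply(seq_len(ceiling(n / 64)), function(k) {
    rows <- chars[(64 * (k - 1) + 1):min(64 * k, n)]
    masks <- lapply(split(seq_along(rows), rows), function(idx) {
      v <- logical(64); v[idx] <- TRUE; v
    })
    list(live = length(rows), masks = masks)
  })
}

#' Retrieve one symbol's equality mask from a block
#'
#' @param block One element of the list returned by [build_peq_blocks()].
#' @param symbol Single character.
#' @return 64-element logical vector (all `FALSE` if the symbol does not
#'   occur in the block).
#' @export
peq_mask <- function(block, symbol) {
  m <- block$masks[[symbol]]
  if (is.null(m)) logical(64) else m
}

#' One column step of the bit-parallel kernel
#'
#' Advances the vertical-difference state of one 64-row pattern block
#' across a single text character.  `dv` carries the vertical differences
#' \eqn{\Delta v \in \{-1,0,+1\}} of the current column as two disjoint
#' 64-bit masks (`vp` rows with +1, `vn` rows with -1); `h_in` is the
#' horizontal difference entering at the block's top row.  The update is
#' exactly equivalent to the classical recurrence restated in terms of
#' differences: the returned state reproduces, bit for bit, the column
#' differences the full matrix would have.
#'
#' @param peq 64-element logical vector: equality mask of the text
#'   character against the block's pattern rows (see [build_peq_blocks()]).
#' @param dv List with logical elements `vp`, `vn` (length 64,
#'   non-overlapping).
#' @param h_in Integer in `-1, 0, 1`.
#' @return List with `dv` (the new state, same shape) and `h_out`, the
#'   horizontal difference leaving at the block's bottom row.
#' @export
bpm_advance_column <- function(peq, dv, h_in) {
  r <- cpp_advance_column(as.logical(peq), as.logical(dv$vp),
                          as.logical(dv$vn), as.integer(h_in))
  list(dv = list(vp = r$vp, vn = r$vn), h_out = r$h_out)
}

#' Compute one 64 x 64 DP tile
#'
#' Runs the bit-parallel kernel over one tile: a pattern block of up to 64
#' rows against up to 64 text characters, given the tile's entry
#' boundaries (vertical differences of the entering column, horizontal
#' differences along the entering row, and the score at the cell
#' diagonally above-left of the tile interior).  For the first tile row
#' use `top_h = +1` everywhere, for the first tile column use
#' `left_dv = list(vp = rep(TRUE, 64), vn = rep(FALSE, 64))` -- the
#' global DP border.
#'
#' @param pattern_block Character string of 1..64 pattern rows.
#' @param text_block Character string of 1..64 text columns.
#' @param left_dv List with `vp`, `vn` (64 logicals each).
#' @param top_h Integer vector (one value in `-1,0,1` per text column).
#' @param entry_score Integer, `H` at the tile's top-left corner cell.
#' @return List with `right_dv` (exiting vertical differences),
#'   `bottom_h` (exiting horizontal differences at the block's 64th row),
#'   `exit_score` (`H` at the live bottom-right interior cell),
#'   `topright_score`, and `dv_cols` (64 x ncol matrix of per-column
#'   vertical differences in `-1,0,1`; rows beyond `live` are padding).
#' @export
compute_tile <- function(pattern_block, text_block, left_dv, top_h,
                         entry_score) {
  r <- cpp_compute_tile(pattern_block, text_block, as.logical(left_dv$vp),
                        as.logical(left_dv$vn), as.integer(top_h),
                        as.integer(entry_score))
  list(right_dv = list(vp = r$right_vp, vn = r$right_vn),
       bottom_h = r$bottom_h, exit_score = r$exit_score,
       topright_score = r$topright_score, dv_cols = r$dv_cols,
       live = r$live)
}

#' Expand a differential column into absolute scores
#'
#' Cumulatively applies the vertical differences in `dv` starting from
#' `entry_score`, returning the 64 scores down the column.  Inverse of
#' taking adjacent differences.
#'
#' @param entry_score Integer, score of the cell above the column's first
#'   row.
#' @param dv List with logical `vp`, `vn` of length 64.
#' @return Integer vector of 64 scores.
#' @export
expand_boundary_scores <- function(entry_score, dv) {
  vp <- as.logical(dv$vp); vn <- as.logical(dv$vn)
  stopifnot(length(vp) == 64L, length(vn) == 64L)
  if (any(vp & vn)) stop("malformed delta vector: vp and vn overlap")
  as.integer(entry_score) + cumsum(ifelse(vp, 1L, ifelse(vn, -1L, 0L)))
}

check_seq <- function(x) {
  if (!is.character(x) || length(x) != 1L || is.na(x))
    stop("sequences must be single non-NA character strings", call. = FALSE)
  invisible(x)
}
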