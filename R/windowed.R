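#' Windowed score-bounding configuration
#'
#' Parameters of the windowed heuristic: square windows of `W` DP-cells
#' per side are chained from the top-left to the bottom-right corner of
#' the DP-matrix, each new window anchored `O` cells (the overlap) back
#' from the previous window's exit so the local alignment can be
#' reconsidered.  Both must be multiples of the 64-cell tile size.  A
#' window whose local error rate exceeds `hew_error_threshold` counts as
#' a high-error window (HEW); the fraction of HEWs signals that the bound
#' may be loose.
#'
#' @param W Window side in DP-cells (multiple of 64). Default 128.
#' @param O Overlap in DP-cells (multiple of 64, `0 <= O < W`). Default 64.
#' @param hew_error_threshold Local error rate above which a window is
#'   flagged as high-error. Default 0.40.
#' @return Object of class `window_config`.
#' @export
window_config <- function(W = 128L, O = 64L, hew_error_threshold = 0.40) {
  W <- as.integer(W); O <- as.integer(O)
  if (W <= 0L || W %% 64L != 0L) stop("W must be a positive multiple of 64")
  if (O < 0L || O %% 64L != 0L || O >= W)
    stop("O must be a non-negative multiple of 64 smaller than W")
  if (!is.numeric(hew_error_threshold) || hew_error_threshold <= 0)
    stop("hew_error_threshold must be positive")
  structure(list(W = W, O = O, hew_error_threshold = hew_error_threshold),
            class = "window_config")
}

#' Compute a single alignment window
#'
#' Fills one `W x W` window anchored at the DP cell `anchor` (0-based
#' `(row, col)`), with the boundary initialized so that every path enters
#' through the anchor with score `entry_score` (border cells cost +1 per
#' step away from the anchor, i.e. real gap operations).  The exit is the
#' minimum-score cell on the window's bottom row or right column (ties:
#' larger `row+col`, then larger `row`); if the window contains the
#' bottom-right corner of the matrix the exit is forced there.  A
#' within-window traceback locates the next anchor: the first path cell,
#' walking back from the exit, at least `O` cells from the exit in both
#' dimensions (falling back to the exit itself when the path is too
#' short, which keeps the chain progressing).
#'
#' @inheritParams edit_dp_oracle
#' @param anchor Numeric length-2 vector, 0-based `(row, col)`.
#' @param entry_score Score at the anchor.
#' @param config A [window_config()].
#' @return List with `exit`, `exit_score`, `next_anchor`, `next_entry`,
#'   `window_error` (score gained divided by the larger number of rows or
#'   columns advanced), and `is_final`.
#' @export
compute_window <- function(pattern, text, anchor, entry_score = 0,
                           config = window_config()) {
  check_seq(pattern); check_seq(text)
  stopifnot(length(anchor) == 2L)
  cpp_window_single(pattern, text, anchor[1], anchor[2], entry_score,
                    config$W, config$O)
}

#' Windowed upper bound on the edit distance
#'
#' Chains alignment windows (see [compute_window()]) from `(0,0)` until a
#' window contains `(n,m)`.  The concatenated per-window paths form one
#' feasible end-to-end alignment, so the returned `s_hat` is always an
#' upper bound on the optimal edit distance; it equals the optimum
#' whenever each window's optimal sub-path stays inside the window.
#' Cost is linear in the sequence length and memory is one window.
#'
#' A backward run applies the same procedure to both sequences reversed
#' (edit distance is invariant under joint reversal); when a large gap
#' sits near one end, one of the two directions typically recovers a much
#' tighter bound.
#'
#' @inheritParams compute_window
#' @param direction `"forward"` or `"backward"`.
#' @return Object of class `windowed_result`: list with `s_hat`,
#'   `hew_fraction`, `windows_computed`, `direction`.
#' @examples
#' p <- strrep("ACGT", 512)
#' windowed_score(p, p)$s_hat  # 0
#' @export
windowed_score <- function(pattern, text, config = window_config(),
                           direction = c("forward", "backward")) {
  check_seq(pattern); check_seq(text)
  direction <- match.arg(direction)
  if (direction == "backward") {
    pattern <- cpp_revstr(pattern); text <- cpp_revstr(text)
  }
  r <- cpp_windowed(pattern, text, config$W, config$O,
                    config$hew_error_threshold)
  structure(list(s_hat = r$s_hat,
                 hew_fraction = if (r$windows > 0) r$hews / r$windows else 0,
                 windows_computed = r$windows, direction = direction),
            class = "windowed_result")
}

#' Bidirectional windowed bound
#'
#' Runs [windowed_score()] forward and backward and keeps the smaller of
#' the two bounds (the minimum of two upper bounds is an upper bound).
#' The HEW fraction reported is the one of the run that achieved the
#' minimum (forward on ties).
#'
#' @inheritParams windowed_score
#' @return A `windowed_result` with `direction = "bidirectional"`.
#' @export
windowed_bound_bidir <- function(pattern, text, config = window_config()) {
  fwd <- windowed_score(pattern, text, config, "forward")
  bwd <- windowed_score(pattern, text, config, "backward")
  pick <- if (bwd$s_hat < fwd$s_hat) bwd else fwd
  structure(list(s_hat = pick$s_hat, hew_fraction = pick$hew_fraction,
                 windows_computed = fwd$windows_computed + bwd$windows_computed,
                 direction = "bidirectional"),
            class = "windowed_result")
}

#' @export
print.windowed_result <- function(x, ...) {
  cat(sprintf("windowed bound: s_hat = %g (%s, %g windows, %.1f%% high-error)\n",
              x$s_hat, x$direction, x$windows_computed,
              100 * x$hew_fraction))
  invisible(x)
}
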