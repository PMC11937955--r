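#' Banded edit-distance score
#'
#' Computes the DP-matrix restricted to tiles intersecting the diagonal
#' band \eqn{\{d = j - i : |d| \le b \ \mathrm{and}\ |d - (m-n)| \le b\}}
#' -- the intersection of a band around the main diagonal and one around
#' the target diagonal, so that any alignment of cost `s <= b` lies
#' entirely inside the band.  Consequently a finite result is always an
#' upper bound of the true distance, and `score <= b` certifies that it
#' *is* the true distance (`exact = TRUE`).  If the band cannot connect
#' `(0,0)` to `(n,m)` (e.g. `b < |m - n|`) the score is `Inf`.
#'
#' A dynamic cutoff additionally skips in-band tiles whose best possible
#' entry score plus remaining distance to the target diagonal already
#' exceeds `b`; this never affects results with `score <= b`.
#'
#' @inheritParams edit_dp_oracle
#' @param b Band half-width in DP-cells (`>= 0`).
#' @param cutoff Apply the dynamic tile cutoff (default `TRUE`).
#' @return List with `score` (may be `Inf`), `exact`, `tiles_computed`.
#' @examples
#' banded_score("ACGT", "ACGG", 64)   # score 1, exact
#' banded_score(strrep("A", 50), strrep("A", 80), 8)  # Inf: band too narrow
#' @export
banded_score <- function(pattern, text, b, cutoff = TRUE) {
  check_seq(pattern); check_seq(text)
  if (b < 0) stop("band must be non-negative")
  r <- cpp_banded(pattern, text, b, isTRUE(cutoff))
  list(score = r$score, exact = r$exact, tiles_computed = r$tiles)
}

#' Exact edit distance by band doubling
#'
#' Runs [banded_score()] with bands `b0, 2*b0, 4*b0, ...` until the
#' computed score is at most the band, which certifies optimality (a
#' cost-`s` alignment fits in a band of half-width `s`).  The doubling
#' test is non-strict (`score <= band`).
#'
#' @inheritParams banded_score
#' @param b0 Initial band half-width (`>= 1`).  The bound cascade uses
#'   `ceiling(0.15 * max(n, m))`, i.e. it assumes at most a 15% error
#'   rate on the first attempt.
#' @return List with `score` (exact optimum), `final_band`, `rounds`,
#'   `tiles_total`.
#' @examples
#' band_doubling_score(strrep("A", 50), strrep("A", 80), 8)$score  # 30
#' @export
band_doubling_score <- function(pattern, text, b0) {
  check_seq(pattern); check_seq(text)
  if (b0 < 1) stop("b0 must be at least 1")
  r <- cpp_band_doubling(pattern, text, b0)
  list(score = r$score, final_band = r$final_band, rounds = r$rounds,
       tiles_total = r$tiles_total)
}
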