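#' Bound-cascade configuration
#'
#' Defaults of the three-stage score-bounding cascade: a small-window
#' pass (`W = 128, O = 64`, forward only), a large-window bidirectional
#' pass (`W = 640, O = 128`), and band doubling starting at 15% of the
#' longer sequence.  After each windowed stage the fraction of high-error
#' windows (local error rate above `hew_error_threshold`) is compared
#' with `hew_fraction_threshold`: the cascade escalates only when the
#' fraction is strictly above it.
#'
#' @param ws [window_config()] of the small-window stage.
#' @param wl [window_config()] of the large-window stage.
#' @param hew_fraction_threshold Escalate when the HEW fraction exceeds
#'   this value (default 0.15).
#' @param band_start_fraction Initial band of the doubling stage as a
#'   fraction of `max(n, m)` (default 0.15).
#' @return Object of class `cascade_config`.
#' @export
cascade_config <- function(ws = window_config(W = 128L, O = 64L),
                           wl = window_config(W = 640L, O = 128L),
                           hew_fraction_threshold = 0.15,
                           band_start_fraction = 0.15) {
  stopifnot(inherits(ws, "window_config"), inherits(wl, "window_config"),
            hew_fraction_threshold > 0, hew_fraction_threshold < 1,
            band_start_fraction > 0, band_start_fraction < 1)
  structure(list(ws = ws, wl = wl,
                 hew_fraction_threshold = hew_fraction_threshold,
                 band_start_fraction = band_start_fraction),
            class = "cascade_config")
}

#' Upper bound on the edit distance (bounding cascade)
#'
#' Runs the score-bounding cascade: the small-window stage first; if its
#' high-error-window fraction exceeds the threshold, the large-window
#' bidirectional stage; if that is also above the threshold, exact band
#' doubling.  Early stages are fast and accurate for similar sequences;
#' the banded stage is slower but exact, so the returned `s_hat` is
#' always an upper bound and is the exact distance when `stage ==
#' "banded"` (or for degenerate empty inputs).
#'
#' @inheritParams edit_dp_oracle
#' @param config A [cascade_config()].
#' @return Object of class `bound_result`: list with `s_hat`,
#'   `hew_fraction` (of the stage that produced the bound), `stage`
#'   (`"window_s"`, `"window_l"` or `"banded"`), and `is_exact`.
#' @examples
#' p <- strrep("ACGT", 256)
#' edit_bound(p, p)  # s_hat 0, stage window_s
#' @export
edit_bound <- function(pattern, text, config = cascade_config()) {
  check_seq(pattern); check_seq(text)
  n <- nchar(pattern); m <- nchar(text)
  if (n == 0L || m == 0L)
    return(new_bound_result(n + m, 0, "window_s", TRUE))
  ws <- windowed_score(pattern, text, config$ws, "forward")
  if (ws$hew_fraction <= config$hew_fraction_threshold)
    return(new_bound_result(ws$s_hat, ws$hew_fraction, "window_s", FALSE))
  wl <- windowed_bound_bidir(pattern, text, config$wl)
  if (wl$hew_fraction <= config$hew_fraction_threshold)
    return(new_bound_result(wl$s_hat, wl$hew_fraction, "window_l", FALSE))
  b0 <- ceiling(config$band_start_fraction * max(n, m))
  bd <- band_doubling_score(pattern, text, b0)
  new_bound_result(bd$score, wl$hew_fraction, "banded", TRUE)
}

new_bound_result <- function(s_hat, hew_fraction, stage, is_exact) {
  structure(list(s_hat = s_hat, hew_fraction = hew_fraction, stage = stage,
                 is_exact = is_exact), class = "bound_result")
}

#' @export
print.bound_result <- function(x, ...) {
  cat(sprintf("score bound: s_hat = %g (stage %s%s)\n", x$s_hat, x$stage,
              if (x$is_exact) ", exact" else ""))
  invisible(x)
}

#' Normalized score deviation
#'
#' Accuracy metric for approximate score bounds: the mean of
#' \eqn{(\hat s - s_{opt}) / s_{opt}} over pairs, where \eqn{\hat s} is
#' the bound and \eqn{s_{opt}} the optimal score.  Pairs with
#' `optima == 0` are excluded from the mean and reported in `skipped`.
#' For genuine upper bounds the value is non-negative; 0 means every
#' bound was exact.
#'
#' @param bounds Numeric vector of score bounds.
#' @param optima Numeric vector of optimal scores, same length.
#' @return Object of class `nsd_report`: list with `N` (pairs entering
#'   the mean), `nsd`, `skipped`.
#' @examples
#' nsd(c(110, 100), c(100, 100))$nsd  # 0.05
#' @export
nsd <- function(bounds, optima) {
  if (length(bounds) != length(optima))
    stop("bounds and optima must have the same length")
  if (any(optima < 0)) stop("optima must be non-negative")
  keep <- optima > 0
  structure(list(N = sum(keep),
                 nsd = if (any(keep))
                   mean((bounds[keep] - optima[keep]) / optima[keep])
                 else 0,
                 skipped = sum(!keep)),
            class = "nsd_report")
}

#' @export
print.nsd_report <- function(x, ...) {
  cat(sprintf("NSD = %.4g%% over %d pairs (%d with zero optimum skipped)\n",
              100 * x$nsd, x$N, x$skipped))
  invisible(x)
}

#' Cumulative distribution of length-normalized scores
#'
#' For each pair, the normalized score is the score divided by the
#' sequence length; the curve gives, for each observed normalized score,
#' the number of alignments at or below it.  Useful for comparing score
#' estimators against an exact baseline.
#'
#' @param scores Numeric vector of alignment scores.
#' @param lengths Numeric vector of sequence lengths, same length.
#' @return `data.frame` with columns `normalized_score` (sorted) and
#'   `cumulative_count`.
#' @export
cumulative_score_curve <- function(scores, lengths) {
  if (length(scores) != length(lengths))
    stop("scores and lengths must have the same length")
  if (length(scores) == 0L)
    return(data.frame(normalized_score = numeric(0),
                      cumulative_count = integer(0)))
  ns <- sort(scores / lengths)
  data.frame(normalized_score = ns, cumulative_count = seq_along(ns))
}
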