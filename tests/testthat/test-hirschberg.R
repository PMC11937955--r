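test_that("score passes expose prefix scores and closed forms", {
  p <- strrep("AC", 128)  # identical pair, n = m = 256
  f <- score_column_pass(p, p, 10, "forward", 128)
  i <- which(is.finite(f)) - 1
  expect_true(128 %in% i)
  expect_equal(f[i + 1], abs(i - 128))
  # border columns
  expect_equal(score_column_pass("ACGT", "ACGT", 4, "forward", 0), 0:4)
  expect_equal(score_column_pass("ACGT", "ACGT", 4, "backward", 4), 4:0)
  # split_col = m equals the bounded final column
  set.seed(117)
  p <- rand_seq(200); t <- mutate_seq(p, 20)
  so <- edit_dp_score(p, t)
  f <- score_column_pass(p, t, so, "forward", nchar(t))
  expect_equal(f[201], so)
})

test_that("breakpoints recover the exact optimum", {
  bp <- find_breakpoint(c(2, 1, 3), c(1, 1, 2))
  expect_equal(bp$row, 1)
  expect_equal(bp$s_star, 2)
  expect_error(find_breakpoint(c(Inf, Inf), c(Inf, Inf)), "bound too small")
  set.seed(118)
  for (rep in 1:25) {
    n <- sample(150:800, 1)
    p <- rand_seq(n)
    t <- mutate_seq(p, sample(0:(n %/% 4), 1))
    m <- nchar(t)
    so <- edit_dp_score(p, t)
    split <- 64 * max(1, round(m / 128))
    split <- min(split, 64 * floor((m - 1) / 64))
    fwd <- score_column_pass(p, t, so, "forward", split)
    bwd <- score_column_pass(p, t, so, "backward", split)
    bp <- find_breakpoint(fwd, bwd)
    expect_equal(bp$s_star, so)
    expect_equal(bp$prefix_score + bp$suffix_score, so)
  }
})

test_that("divide-and-conquer equals direct alignment at any threshold", {
  set.seed(119)
  for (rep in 1:25) {
    n <- sample(300:2000, 1)
    p <- rand_seq(n)
    t <- mutate_seq(p, sample(0:round(0.25 * n), 1))
    so <- edit_dp_score(p, t)
    sh <- edit_bound(p, t)$s_hat
    direct <- bounded_align(p, t, sh)
    dac <- hirschberg_align(p, t, sh, mem_limit = 1)
    expect_equal(direct$score, so)
    expect_equal(dac$score, so)
    expect_valid_alignment(p, t, dac)
    expect_gte(dac$splits, 1)
  }
})

test_that("a huge threshold delegates to the direct aligner unchanged", {
  set.seed(120)
  p <- rand_seq(1000)
  t <- mutate_seq(p, 50)
  sh <- edit_bound(p, t)$s_hat
  dac <- hirschberg_align(p, t, sh, mem_limit = 1e12)
  direct <- bounded_align(p, t, sh)
  expect_identical(dac$score, direct$score)
  expect_identical(dac$cigar, direct$cigar)
  expect_equal(dac$splits, 0)
})

test_that("retained trace bytes respect the memory policy", {
  # With threshold t, every direct leaf satisfies either the worst-case
  # trace-byte bound <= t or the 128-column floor; the instrumented peak
  # can therefore never exceed max(t, floor-case bound).
  set.seed(121)
  for (rep in 1:10) {
    n <- sample(2000:6000, 1)
    p <- rand_seq(n)
    t <- mutate_seq(p, round(0.15 * n))
    sh <- edit_bound(p, t)$s_hat
    lim <- sample(c(1, 2^12, 2^16, 2^20), 1)
    a <- hirschberg_align(p, t, sh, mem_limit = lim)
    expect_equal(a$score, edit_dp_score(p, t))
    floor_bytes <- ceiling(max(n, nchar(t)) / 64) *
      (2 * ceiling(sh / 64) + 3) * (80 + 16 * 64)  # never reached by leaves
    expect_lte(a$peak_trace_bytes,
               max(lim, 2 * (2 * ceiling(sh / 64) + 3) * (80 + 16 * 64)))
    expect_lt(a$peak_trace_bytes, floor_bytes)
  }
  # tiny threshold on an identical megabase-scale pair stays tiny
  p <- strrep("ACGT", 50000)
  a <- hirschberg_align(p, p, 0, mem_limit = 1)
  expect_equal(a$score, 0)
  expect_equal(a$cigar, "200000=")
})
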