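test_that("single windows behave per contract", {
  cfg <- window_config(W = 128, O = 64)
  # identical 128-mers: one window reaching the corner exactly
  p <- rand_seq(128)
  w <- compute_window(p, p, c(0, 0), 0, cfg)
  expect_equal(w$exit, c(128, 128))
  expect_equal(w$exit_score, 0)
  expect_equal(w$window_error, 0)
  expect_true(w$is_final)
  # one substitution inside the window
  set.seed(106)
  p <- rand_seq(300)
  t <- p
  substr(t, 50, 50) <- if (substr(t, 50, 50) == "A") "C" else "A"
  w <- compute_window(p, t, c(0, 0), 0, cfg)
  expect_equal(w$exit_score, 1)
  expect_equal(w$window_error, 1 / 128)
  expect_false(w$is_final)
  # next anchor backs off at least O from the exit in both dimensions
  expect_true(all(w$exit - w$next_anchor >= 64))
})

test_that("windowed bound is sound and exact on low-error pairs", {
  set.seed(107)
  cfg <- window_config(128, 64)
  for (rep in 1:40) {
    n <- sample(300:3000, 1)
    p <- rand_seq(n)
    t <- mutate_seq(p, sample(0:round(0.3 * n), 1))
    so <- edit_dp_score(p, t)
    w <- windowed_score(p, t, cfg)
    expect_gte(w$s_hat, so)       # always an upper bound
    wb <- windowed_bound_bidir(p, t, cfg)
    expect_gte(wb$s_hat, so)
    expect_lte(wb$s_hat, w$s_hat) # min of two upper bounds
    expect_lte(w$windows_computed, ceiling((n + nchar(t)) / 64) + 2)
  }
  # near-exact on low-error pairs (e <= 2%)
  for (rep in 1:15) {
    n <- sample(1000:4000, 1)
    p <- rand_seq(n)
    t <- mutate_seq(p, round(0.02 * n))
    expect_equal(windowed_score(p, t, cfg)$s_hat, edit_dp_score(p, t))
  }
})

test_that("identical and degenerate inputs give trivial bounds", {
  p <- rand_seq(2048)
  w <- windowed_score(p, p, window_config(128, 64))
  expect_equal(w$s_hat, 0)
  expect_equal(w$hew_fraction, 0)
  w <- windowed_score("", rand_seq(10))
  expect_equal(w$s_hat, 10)
  expect_equal(w$windows_computed, 0)
  expect_equal(w$hew_fraction, 0)
  # single substitution in the middle
  set.seed(108)
  p <- rand_seq(2048); t <- p
  substr(t, 1024, 1024) <- if (substr(t, 1024, 1024) == "G") "T" else "G"
  expect_equal(windowed_score(p, t)$s_hat, 1)
})

test_that("a gap larger than the window may overestimate but never underestimates", {
  set.seed(109)
  p <- rand_seq(3000)
  t <- paste0(substr(p, 1, 1000), substr(p, 1301, 3000))  # 300-base gap
  so <- edit_dp_score(p, t)
  expect_equal(so, 300)
  w <- windowed_score(p, t, window_config(128, 64))
  expect_gte(w$s_hat, so)
  expect_gt(w$hew_fraction, 0)  # the gap produces high-error windows
  # gap near the start: backward run recovers a tighter bound
  t2 <- paste0(substr(p, 1, 100), substr(p, 901, 3000))
  fwd <- windowed_score(p, t2, window_config(640, 128))
  bb <- windowed_bound_bidir(p, t2, window_config(640, 128))
  expect_lte(bb$s_hat, fwd$s_hat)
  expect_gte(bb$s_hat, edit_dp_score(p, t2))
})

test_that("window configuration is validated", {
  expect_error(window_config(100, 64), "multiple of 64")
  expect_error(window_config(128, 128), "smaller than W")
  expect_error(window_config(128, 63), "multiple of 64")
})
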