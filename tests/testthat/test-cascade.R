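test_that("cascade routes by high-error-window fraction and stays sound", {
  set.seed(113)
  # identical long pair: first stage suffices
  p <- rand_seq(10000)
  b <- edit_bound(p, p)
  expect_equal(b$s_hat, 0)
  expect_equal(b$stage, "window_s")
  # low error: first stage, near-exact bound
  p <- rand_seq(10000)
  t <- mutate_seq(p, round(0.02 * 10000))
  so <- edit_dp_score(p, t)
  b <- edit_bound(p, t)
  expect_equal(b$stage, "window_s")
  expect_gte(b$s_hat, so)
  expect_lte((b$s_hat - so) / so, 0.05)
  # heavy noise plus a long gap: escalates to the exact banded stage
  p <- rand_seq(6000)
  t <- paste0(mutate_seq(substr(p, 1, 2000), 600),
              mutate_seq(substr(p, 4000, 6000), 600))
  so <- edit_dp_score(p, t)
  b <- edit_bound(p, t)
  expect_equal(b$stage, "banded")
  expect_true(b$is_exact)
  expect_equal(b$s_hat, so)
})

test_that("degenerate inputs short-circuit the cascade", {
  b <- edit_bound("", "ACGT")
  expect_equal(b$s_hat, 4)
  expect_true(b$is_exact)
  b <- edit_bound("ACGT", "")
  expect_equal(b$s_hat, 4)
})

test_that("cascade is deterministic and the bound is always an upper bound", {
  set.seed(114)
  for (rep in 1:30) {
    n <- sample(500:3000, 1)
    p <- rand_seq(n)
    t <- mutate_seq(p, sample(0:round(0.45 * n), 1))
    so <- edit_dp_score(p, t)
    b1 <- edit_bound(p, t)
    b2 <- edit_bound(p, t)
    expect_identical(b1, b2)
    expect_gte(b1$s_hat, so)
    if (b1$stage == "banded") expect_equal(b1$s_hat, so)
  }
})

test_that("NSD follows its formula and skips zero optima", {
  r <- nsd(c(110, 100), c(100, 100))
  expect_equal(r$nsd, 0.05)
  expect_equal(r$N, 2)
  expect_equal(nsd(c(50, 70), c(50, 70))$nsd, 0)
  r <- nsd(c(0, 110), c(0, 100))
  expect_equal(r$skipped, 1)
  expect_equal(r$nsd, 0.1)
  expect_error(nsd(1:3, 1:2), "length")
})

test_that("cumulative score curve sorts and counts", {
  cc <- cumulative_score_curve(c(1, 2), c(10, 10))
  expect_equal(cc$normalized_score, c(0.1, 0.2))
  expect_equal(cc$cumulative_count, 1:2)
  expect_equal(nrow(cumulative_score_curve(numeric(0), numeric(0))), 0)
  cc <- cumulative_score_curve(rep(5, 4), rep(100, 4))
  expect_true(all(cc$normalized_score == 0.05))
  expect_equal(max(cc$cumulative_count), 4)
})

test_that("long gaps separate the accuracy of the bounding stages", {
  # windows miss paths around gaps longer than W, so the small-window
  # bound overestimates most, the large bidirectional window less, and
  # band doubling not at all
  set.seed(125)
  dev <- matrix(0, 0, 3)
  for (k in 1:8) {
    n <- 6000
    p <- rand_seq(n)
    gpos <- sample(2000:4000, 1); glen <- sample(300:800, 1)
    t <- mutate_seq(paste0(substr(p, 1, gpos), substr(p, gpos + glen + 1, n)),
                    round(0.05 * n))
    so <- edit_dp_score(p, t)
    ws <- windowed_score(p, t, window_config(128, 64))$s_hat
    wl <- windowed_bound_bidir(p, t, window_config(640, 128))$s_hat
    bd <- band_doubling_score(p, t, ceiling(0.15 * n))$score
    expect_gte(ws, so); expect_gte(wl, so)
    expect_equal(bd, so)
    dev <- rbind(dev, c(ws - so, wl - so, bd - so))
  }
  m <- colMeans(dev)
  expect_gt(m[1], m[2])   # small windows overestimate more than large
  expect_gt(m[2], m[3])   # large windows still overestimate; banded exact
  expect_equal(m[3], 0)
})
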