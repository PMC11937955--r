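test_that("bounded alignment returns exact scores and stated CIGARs", {
  a <- bounded_align("ACGT", "", 4)
  expect_equal(a$score, 4)
  expect_equal(a$cigar, "4I")
  a <- bounded_align("", "ACG", 0)
  expect_equal(a$cigar, "3D")
  p <- rand_seq(500)
  a <- bounded_align(p, p, 0)
  expect_equal(a$score, 0)
  expect_equal(a$cigar, "500=")
  a <- bounded_align("AAAA", "AATA", 1)
  expect_equal(a$cigar, "2=1X1=")
  a <- bounded_align("ACGT", "ACT", 1)
  expect_equal(a$cigar, "2=1I1=")  # drop the pattern's G
})

test_that("a bound below the optimum self-heals by doubling", {
  set.seed(115)
  for (rep in 1:30) {
    n <- sample(50:400, 1)
    p <- rand_seq(n)
    t <- mutate_seq(p, sample(1:(n %/% 3), 1))
    so <- edit_dp_score(p, t)
    a <- bounded_align(p, t, sample(0:max(0, so - 1), 1))
    expect_equal(a$score, so)
    expect_gte(a$retries, 1)
    expect_valid_alignment(p, t, a)
  }
})

test_that("work scales with the bound and tightening never changes the score", {
  set.seed(116)
  for (rep in 1:40) {
    n <- sample(200:1200, 1)
    p <- rand_seq(n)
    t <- mutate_seq(p, sample(0:round(0.3 * n), 1))
    m <- nchar(t)
    so <- edit_dp_score(p, t)
    loose <- bounded_align(p, t, min(n + m, 4 * so + 64))
    tight <- bounded_align(p, t, so)
    expect_equal(loose$score, so)
    expect_equal(tight$score, so)
    expect_lte(tight$tiles_computed, loose$tiles_computed)
    for (a in list(loose, tight))
      expect_lte(a$tiles_computed,
                 ceiling(max(n, m) / 64) * (2 * ceiling(a$bound_used / 64) + 3))
    expect_valid_alignment(p, t, loose)
    expect_valid_alignment(p, t, tight)
  }
})

test_that("validate_alignment catches broken CIGARs", {
  expect_false(validate_alignment("AAAA", "AAAT", list(score = 0, cigar = "4=")))
  expect_false(validate_alignment("AAAA", "AAAA", list(score = 0, cigar = "3=")))
  expect_false(validate_alignment("AAAA", "AAAA", list(score = 1, cigar = "4=")))
  expect_false(validate_alignment("AA", "AA", list(score = 2, cigar = "2X")))
  v <- validate_alignment("AAAA", "AAAT", list(score = 0, cigar = "4="))
  expect_match(attr(v, "reason"), "mismatch")
  expect_true(validate_alignment("AAAA", "AAAT", list(score = 1, cigar = "3=1X")))
})

test_that("classic CIGAR conversion collapses matches and mismatches", {
  expect_equal(cigar_classic("2=1X1="), "4M")
  expect_equal(cigar_classic("2=1I3=1D1X"), "2M1I3M1D1M")
  expect_equal(cigar_classic(""), "")
})

test_that("traceback memory estimate follows the 2-bit model", {
  expect_equal(estimate_traceback_bytes(1000, 1000, 100), 25000)
  expect_equal(estimate_traceback_bytes(500, 2000, 0), 0)
  expect_gt(estimate_traceback_bytes(1e6, 1e6, 1e5), 16 * 2^20)
})
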