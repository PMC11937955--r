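test_that("equality-mask blocks cover the pattern and pad with no-match rows", {
  b <- build_peq_blocks("AAAA")
  expect_length(b, 1)
  expect_identical(which(peq_mask(b[[1]], "A")), 1:4)
  expect_identical(peq_mask(b[[1]], "C"), logical(64))
  expect_identical(build_peq_blocks(""), list())
  b <- build_peq_blocks(rand_seq(130))
  expect_length(b, 3)
  expect_equal(b[[3]]$live, 2)
  # every live row set in exactly one mask, padding rows in none
  for (blk in b) {
    hits <- Reduce(`+`, lapply(blk$masks, as.integer))
    expect_identical(hits[seq_len(blk$live)], rep(1L, blk$live))
    if (blk$live < 64) expect_identical(hits[(blk$live + 1):64],
                                        rep(0L, 64 - blk$live))
  }
})

test_that("advance_column reproduces oracle column differences", {
  # frozen examples: 64 identical rows against one matching / one
  # mismatching character, entering from the global border
  border <- list(vp = rep(TRUE, 64), vn = rep(FALSE, 64))
  r <- bpm_advance_column(rep(TRUE, 64), border, 1L)
  expect_true(r$dv$vn[1]); expect_true(all(r$dv$vp[2:64]))
  expect_equal(r$h_out, -1)
  r <- bpm_advance_column(rep(FALSE, 64), border, 1L)
  expect_false(r$dv$vp[1]); expect_false(r$dv$vn[1])
  expect_true(all(r$dv$vp[2:64]))
  expect_equal(r$h_out, 0)

  # fuzz: full columns of random 64-row problems against the oracle
  set.seed(103)
  for (rep in 1:60) {
    p <- rand_seq(64, c("A", "C", "G"))
    t <- rand_seq(sample(5:50, 1), c("A", "C", "G"))
    H <- edit_dp_oracle(p, t)
    pc <- strsplit(p, "")[[1]]
    dv <- list(vp = rep(TRUE, 64), vn = rep(FALSE, 64))
    for (j in seq_len(nchar(t))) {
      r <- bpm_advance_column(pc == substr(t, j, j), dv, 1L)
      dv <- r$dv
      expect_false(any(dv$vp & dv$vn))
      expect_true(r$h_out %in% -1:1)
      expect_identical(ifelse(dv$vp, 1L, ifelse(dv$vn, -1L, 0L)),
                       H[2:65, j + 1] - H[1:64, j + 1])
      expect_equal(r$h_out, H[65, j + 1] - H[65, j])
    }
  }
})

test_that("malformed delta vectors are rejected", {
  both <- list(vp = rep(TRUE, 64), vn = rep(TRUE, 64))
  expect_error(bpm_advance_column(rep(TRUE, 64), both, 1L), "overlap")
  expect_error(expand_boundary_scores(0, both), "overlap")
})

test_that("expand_boundary_scores is the inverse of taking differences", {
  expect_identical(expand_boundary_scores(0, list(vp = rep(TRUE, 64),
                                                  vn = rep(FALSE, 64))),
                   1:64)
  expect_identical(expand_boundary_scores(5, list(vp = logical(64),
                                                  vn = logical(64))),
                   rep(5L, 64))
  set.seed(104)
  for (rep in 1:10) {
    d <- sample(c(-1L, 0L, 1L), 64, replace = TRUE)
    dv <- list(vp = d == 1L, vn = d == -1L)
    s <- expand_boundary_scores(7L, dv)
    expect_identical(diff(c(7L, s)), d)
  }
})
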