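# Shared fixtures: random pair construction and an edlib cross-check
# (used only where the quadratic oracle would be too slow).

DNA <- c("A", "C", "G", "T")

rand_seq <- function(n, alphabet = DNA) {
  paste(sample(alphabet, n, replace = TRUE), collapse = "")
}

# Mutate a sequence with single-base mismatches/insertions/deletions.
mutate_seq <- function(x, n_edits, alphabet = DNA) {
  v <- strsplit(x, "", fixed = TRUE)[[1]]
  for (k in seq_len(n_edits)) {
    op <- sample.int(3L, 1L)
    pos <- sample.int(length(v), 1L)
    if (op == 1L) v[pos] <- sample(alphabet, 1L)
    else if (op == 2L) v <- append(v, sample(alphabet, 1L), after = pos)
    else if (length(v) > 1L) v <- v[-pos]
  }
  paste(v, collapse = "")
}

# Exact edit distances from the edlib library (independent C
# implementation), one python call for the whole batch.
edlib_scores <- function(pairs) {
  f <- tempfile(fileext = ".tsv")
  on.exit(unlink(f))
  writeLines(paste(pairs$pattern, pairs$text, sep = "\t"), f)
  out <- system2("python", c("-c", shQuote(paste0(
    "import edlib,sys\n",
    "for line in open(sys.argv[1]):\n",
    "    p,t = line.rstrip('\\n').split('\\t')\n",
    "    print(edlib.align(p, t)['editDistance'])")), f),
    stdout = TRUE)
  as.integer(out)
}

expect_valid_alignment <- function(pattern, text, alignment) {
  v <- validate_alignment(pattern, text, alignment)
  expect_true(isTRUE(v), info = paste("invalid alignment:", attr(v, "reason")))
}
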