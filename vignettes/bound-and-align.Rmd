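---
title: "Bound-and-align: how boundalign computes exact edit distances"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Bound-and-align: how boundalign computes exact edit distances}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(boundalign)
```

## The problem

Pairwise edit-distance (Levenshtein) alignment underlies read mapping,
assembly polishing and variant calling. The classical dynamic program fills
an $(n{+}1)\times(m{+}1)$ matrix
$$H_{i,j} = \min\big(H_{i-1,j}+1,\; H_{i,j-1}+1,\; H_{i-1,j-1}+[p_i \neq t_j]\big),$$
which is exact but quadratic — prohibitive for the long, noisy reads of
third-generation sequencers. Heuristics (banded, windowed, X-drop) are fast
but can return suboptimal alignments exactly where accuracy matters most,
on noisy or gap-rich pairs.

`boundalign` combines both: a *bound* phase uses aggressive heuristics only
to obtain an **upper bound** $\hat{s}$ on the optimal score, and an *align*
phase uses $\hat{s}$ to prune the exact computation. Because pruning is
driven by an upper bound, the align phase provably returns the optimum:
work becomes $O(n\hat{s})$ instead of $O(nm)$, without sacrificing
exactness.

## The bit-parallel tile kernel

Adjacent cells of $H$ differ by at most 1 along rows and columns, so the
matrix can be stored as vertical differences $\Delta v \in \{-1,0,+1\}$ (2
bits per cell) and advanced one text character at a time with a handful of
64-bit bitwise operations (the bit-parallel formulation of the recurrence;
`bpm_advance_column()`). All higher layers process the matrix in **64×64
tiles** (`compute_tile()`): a tile consumes boundary differences from its
left and top neighbours and emits its right and bottom boundaries. Tiles
give coarse-grained control — cutoff decisions, trace storage and memory
accounting all happen per tile.

The kernel's contract is semantic, not syntactic: the test suite stitches
tiles over full matrices and checks every boundary value against the
quadratic oracle `edit_dp_oracle()` (which is itself cross-checked against
`utils::adist`), and fuzzes more than $10^4$ single columns.

Patterns whose length is not a multiple of 64 pad the final block with rows
whose equality mask is empty; padded rows can never produce a match and sit
*below* the live rows, so they cannot influence live scores (dependencies
flow down-right). Any byte is a valid symbol: comparisons are exact byte
equality, so `N` matches only `N` and case matters unless the reader's
`normalize_case` option is used.

## Bounding stage 1–2: windowed heuristic with high-error detection

`windowed_score()` chains small $W\times W$ windows from $(0,0)$ towards
$(n,m)$. Each window is initialized so every path enters through its anchor
cell (border cells cost +1 per step — genuine gap operations), the exit is
the cheapest cell on the bottom/right edge, and a within-window traceback
backs off $O$ cells to place the next anchor. Three consequences:

* the concatenation of window paths is one feasible alignment, so the
  result is **always** an upper bound;
* cost is linear in sequence length, memory is one window;
* a gap longer than $W$ makes windows miss the optimal path and
  overestimate — detectable, because affected windows show a high local
  error rate. Windows with error above 40% are flagged **high-error
  windows (HEW)**.

Two under-specified details are pinned down as package decisions: the
window error divides the score gained by the larger of rows/columns
advanced (so clipped final windows are judged fairly), and when the
$O$-backoff finds no cell at least $O$ from the exit in both dimensions the
next anchor falls back to the exit itself. The fallback (rather than
re-using the old anchor) guarantees progress — each window advances at
least $W-O$ in some dimension — while preserving the feasible-path
argument; termination is asserted as a window-count bound in the tests.

The cascade (`edit_bound()`) first runs a small forward pass
($W{=}128, O{=}64$). If more than 15% of its windows are HEWs, a large
bidirectional pass ($W{=}640, O{=}128$, both sequences reversed for the
backward run, minimum of the two bounds) is tried; exactly 15% does *not*
escalate. The thresholds (40% window error, 15% HEW fraction) and window
geometries are adopted as fixed constants of the method.

## Bounding stage 3: banded alignment with band doubling

If both windowed passes look unreliable, `band_doubling_score()` computes
the score exactly. `banded_score()` restricts tiles to the diagonal set
$\{|d| \le b\} \cap \{|d-(m-n)| \le b\}$ — the intersection (rather than a
naive $|j-i|\le b$ strip) makes the certificate provable: any alignment of
cost $s$ stays within $s$ of both the main and the target diagonal, so
**score ≤ b implies optimality**. Otherwise the finite result is still an
upper bound, and doubling $b$ (starting at $0.15\cdot\max(n,m)$, i.e.
assuming at most 15% error) terminates with the exact score; the doubling
test is non-strict (`score <= band`). A dynamic cutoff skips in-band tiles
whose entry boundary plus remaining diagonal distance already exceeds $b$;
the test uses the tile corner nearest the target diagonal, which provably
minimizes $H+d_k$ over the tile.

## Align phase: score-bounded exact alignment

`bounded_align()` sweeps tile columns left-to-right keeping an active
tile-row range around the target diagonal. A cell can belong to a path of
cost $\le\hat{s}$ only if $H(i,j) + d_k(i,j) \le \hat{s}$ with
$d_k = |(j-i)-(m-n)|$; per tile this is checked at the bottom-left corner
(tiles above the diagonal) or upper-right corner (below), reading $H$ from
the already-computed entry boundary. Straddling tiles are always computed
and the range never shrinks below 3 tile rows (192 DP-elements) around the
target diagonal.

Boundaries of tiles that were *not* computed are synthesized as +1-growth
from the nearest known corner. Synthesized values are provably upper
bounds, and cells on any optimal path of cost $\le\hat{s}$ retain exact
values (their whole prefix path is admissible), so the final score
certifies itself: if it is $\le\hat{s}$ it is the optimum. When a
user-supplied bound is too small the certificate fails and the aligner
retries with the bound doubled — the API is total, and a bound of $n+m$
always succeeds.

Every computed tile stores its entry score, entering vertical differences,
top-row horizontal differences and per-column vertical differences
(~2 bits per cell plus small per-tile overhead); `traceback` reconstructs
cell values from these and walks predecessors with the deterministic
tie-break *diagonal (match before mismatch), then vertical (I, consumes
pattern), then horizontal (D, consumes text)*. Emitted CIGARs use extended
ops `=`, `X`, `I`, `D` (`cigar_classic()` collapses to `M`);
`validate_alignment()` re-checks every invariant against the raw bytes.

## Linear-memory mode

Direct trace storage is $O(n\hat{s})$ bits — too much for megabase pairs.
`hirschberg_align()` splits the text at the tile-aligned column nearest
$m/2$, runs score-only forward and backward passes (one column of state
each), and `find_breakpoint()` selects the row minimizing
$f(i)+g(i)$, which equals the subproblem's exact score $s^*$ whenever the
bound was sufficient (all sums infinite, or a minimum above the bound,
triggers the doubling retry). The two halves recurse with the *exact*
sub-scores as perfect bounds, so deeper levels do strictly less work, and
CIGARs are concatenated with run merging at the seam.

Two policy decisions: the split is on a column (never a row) and always a
multiple of 64, and subproblems of at most 128 columns are solved directly
regardless of the threshold. The direct/recurse decision uses the
*worst-case* retained-trace bound
$\lceil\max(n,m)/64\rceil\,(2\lceil\hat{s}/64\rceil+3)$ tiles × bytes/tile
rather than the coarser public estimator `estimate_traceback_bytes()`
($\max(n,m)\hat{s}/4$): the admitted region spans up to $2\hat{s}$
diagonals and each stored tile carries boundary overhead, so only the
worst-case form makes the instrumented peak provably respect the
threshold (up to the 128-column floor leaves). The default threshold is
16 MiB, matching last-level cache sizes. The instrumented peak is the sum
of live trace bytes, not an OS measurement.

`edit_align()` wires it together: bound, then memory-aware align. When the
bound stage ended in band doubling the aligner receives an already-exact
score as a perfect bound.

## The synthetic generator — and what passing tests do (not) show

`generate_pair()` draws a uniform random `ACGT` pattern and applies
`round(e·n)` edits at distinct uniform positions, each drawn
mismatch/insertion/deletion with equal probability, right-to-left so
insertion offsets never invalidate later positions. This emulates
simulated benchmark datasets with uniformly distributed error rates; the
default error grid used in tests (0–40%) and the 10 kb/100 kb lengths
match that setting, scaled to a few thousand pairs so the suite runs in
minutes.

Uniform single-base errors are the generator's deliberate limitation:
real long reads contain structural gaps and repeats. On uniform errors
every bounding stage is near-exact (NSD ≈ 0), so the accuracy *ordering*
of the stages is exercised separately with gap-structured pairs (long
deletions plus background noise), where the small-window bound
overestimates most, the large bidirectional window less, and band doubling
not at all. Exactness of the align phase, by contrast, is a theorem for
any input, and is tested on both uniform and gap-structured pairs, with
100 kb pairs cross-checked against an independent exact implementation
(edlib) where the quadratic oracle is impractical.

## Numerical and degenerate-input choices

* Empty sequences: score $n+m$, pure-gap CIGAR, no tiles.
* Exit ties in a window: larger $row+col$, then larger row.
* Breakpoint ties: smallest row.
* Bands that cannot reach the target diagonal return `Inf`, never a
  misleading finite score.
* All scores are integers throughout; `Inf` is the only non-integer value.
* Determinism: identical inputs and configuration produce identical
  results everywhere; the generator is reproducible from its seed.

## Problem sizes used in the shipped checks

The test suite validates ~2000 pairs at $n \le 2000$ plus twenty 100 kb
pairs end-to-end, a 200-pair 10 kb grid for bound accuracy, and $10^4$
fuzzed kernel columns. `scripts/acceptance.R` reruns the pipeline from
scratch (350 mixed pairs, an 80-pair 10 kb grid, 60 divide-and-conquer
comparisons, one 100 kb alignment) and writes the headline numbers as
JSON. These sizes were chosen so each run completes in minutes on one CPU
while every claim is still exercised at multi-tile, multi-split scale.

## Known limitations

* Edit distance only — no affine or weighted scoring, and no semi-global
  or overlap modes.
* The windowed bound's quality degrades on highly repetitive sequences;
  the cascade then falls through to band doubling, which is exact but
  slower.
* Single-threaded by design (`--threads` is accepted for interface
  compatibility and ignored).
* The kernel is scalar 64-bit; no SIMD multi-word variant.
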