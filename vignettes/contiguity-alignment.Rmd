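---
title: "Contiguity-scored alignment: model, parameters and design notes"
author: "contalign"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Contiguity-scored alignment: model, parameters and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(contalign)
```

## The scoring model

An alignment is a monotone path of columns over two nucleotide sequences:
match, mismatch, or a gap in either sequence. Linear schemes value each
match identically, so they cannot distinguish a contiguous motif match from
the same number of matches scattered across diverged flanks. `contalign`
scores a run of $n$ consecutive matches by a non-decreasing *contiguity
function* $f(n)$ with $f(0) = 0$; the score of an alignment is

$$\sum_{\text{match runs}} f(L_r) \;-\; \rho_m \cdot \#\text{mismatches}
  \;-\; \sum_{\text{gap runs}} (\rho_o + L_g \rho_e),$$

with $\rho_o$ dropped under the linear gap model. Because
$f(L) = \sum_{n \le L} \Delta f(n)$ with $\Delta f(n) = f(n) - f(n-1)$, the
optimum is computable cell by cell if the state records how long the
current match run is. That is the third dimension of the edit graph: cell
$(i,j)$ holds depth nodes $S_{i,j,n}$ for $n = 1..d_{i,j}$, where $d_{i,j}$
is the length of the matching suffix ending at $(i,j)$, alongside the two
Gotoh gap states and the zero-contiguity family (mismatch arrival, gap
arrivals, and — in local mode — the restart 0). A match arriving at depth
$n$ adds $\Delta f(n)$ to the diagonal predecessor's node $n-1$; depth node
1 is seeded from the predecessor's zero-contiguity state, so a match can
follow a gap or a mismatch. Depth nodes are allocated on demand, and a
single node suffices when $f$ is linear ($\Delta f$ constant), which is how
the engine degenerates into plain SW/SWGA with no overhead.

Removing the local-restart 0 from the cell maximum, and initialising the
first row and column with boundary gap costs $-(\rho_o + k\rho_e)$ (or
$-k\rho_e$ under linear gaps), yields the global aligner.

One convention is worth stating explicitly: the two gap-state recurrences
are the standard Gotoh ones — the horizontal state at $(i,j)$ extends the
horizontal state at $(i,j-1)$ by $\rho_e$ or opens from the cell best at
$(i,j-1)$ for $\rho_o + \rho_e$, and the vertical state mirrors this with
$(i-1,j)$. Gap openings are anchored at the cell best, not at particular
depth nodes, so a gap may open directly after a match run of any depth.

## Parameters and defaults

* **Contiguity function** — `cubicScoring()` ($f(n) = n^3$) by default: a
  quadratic rewards contiguity only weakly, an exponential overwhelms every
  penalty within a few matches; the cubic sits between. Also available:
  `linearScoring(c)`, `quadraticScoring()`, `exponentialScoring(base)`
  ($f(n) = base^n - 1$, so $f(0)=0$), and `tabulatedScoring(values)` for
  arbitrary user tables, extended past the last entry with the final
  increment.
* **Penalties** (score units): $\rho_m = 8$, $\rho_o = 200$,
  $\rho_e = 20$ for the cubic presets. These are balanced against the
  cubic $f$ so that two consecutive matches equal one mismatch penalty
  ($f(2) = 8$), three consecutive matches outscore one gap extension
  ($f(3) = 27 > 20$), and a gap opening costs between six and seven
  consecutive matches ($f(6) = 216 < 220 \le f(7)$). `minRunReaching()`
  computes such balance points for any scheme.
* **Linear presets** (`sw`, `swga`) use match reward $c = 1$. The cubic
  penalty set would be wildly disproportionate at that scale (a mismatch
  would cost eight matches instead of two), so the linear presets rescale
  the penalties to preserve the same run-length relations under
  $f(n) = n$: $\rho_m = 2$, $\rho_e = 2$, $\rho_o = 5$. With these, SW
  extends through diverged flanks and aligns the most nucleotides of the
  four presets — the qualitative behaviour a practitioner expects of it —
  while remaining bit-compatible with a textbook implementation at the
  same parameters (verified in the test suite against an independent
  gap-affine aligner).
* **Band half-width** (`bandWidth`, positions): cells farther than this
  from the resampled diagonal joining $(0,0)$ and $(N,M)$ are never
  created. Off-band cells are unreachable rather than clamped; in global
  mode a band too narrow to connect the corners raises an error rather
  than silently returning a suboptimal path.
* **Depth cap** (`depthCap`, nodes): beyond the cap $C$,
  $\Delta f(n) = \Delta f(C)$ and deeper nodes merge into node $C$. Off by
  default; it bounds memory against pathological perfect repeats.
* **Checkpoint interval** (`checkpointInterval`, rows): the linear-space
  variant stores one full state row every so many rows (default
  $\lceil\sqrt{N}\rceil$, balancing recomputation passes against retained
  rows) and recomputes the blocks between checkpoints during traceback.
  Checkpoints store the complete per-cell state — all depth nodes and both
  gap states — so block recomputation is exact and the result is
  bit-identical to the full-matrix run.

## Numerical choices

Scores are exact when $f$ and the penalties are integer-valued: all
arithmetic is additions of integers within double precision. State
comparisons during traceback use an absolute tolerance of $10^{-9}$ so
real-valued contiguity functions behave sensibly. Unreachable states are a
large negative sentinel, never infinities, to keep arithmetic finite.

Tie-breaking is deterministic: during traceback, deeper match node >
mismatch > vertical gap > horizontal gap > local restart; among
equal-scoring local maxima the cell with the smallest target index, then
smallest query index, wins; an equal-valued gap extension is preferred to
re-opening. `N` never matches anything, including another `N` (a masking
convention; aligning two `N`s as a "match" would manufacture contiguity
out of missing data), and lowercase input is uppercased. IUPAC ambiguity
codes other than `N` are rejected because partial-match semantics are
undefined under contiguity scoring. All reported intervals are 0-based
half-open, with the target on dynamic-programme rows and the query on
columns; conserved elements are returned as 1-based `IRanges` in keeping
with Bioconductor convention and written as 0-based half-open BED.

## Consistency metrics

Given one local alignment of each genome against a shared reference,
`buildMatchMatrix()` marks per-position coverage (inside the reported
alignment interval) and matches (match columns). Agreement at a position
is the matched fraction over *covered* genomes by default — reading
"matched in 90% of the aligned genomes" literally — with the full genome
count available as an option; positions covered by no genome are undefined
and excluded from histograms. Conserved elements are maximal runs of
positions with agreement at or above `minFrac` (exact threshold values are
inside), reported at length `minLen` or more; the defaults (6, 0.9) match
the length of the poly-adenylation signal. `summarizeMethods()` compares
schemes only on the regions where every method reports alignments, first
intersecting each genome's coverage across methods, and counts matched
cells over genome × position — the per-pairwise-alignment sum, documented
here because a per-reference-position count is the other defensible
reading. k-mer tallies slide windows fully inside elements, overlapping
windows counted, reference strand only.

## The simulator, and what it does not emulate

`simulateFamily()` draws a uniform random reference, overwrites
non-overlapping copies of a motif (starts at least two motif lengths
apart), and derives each ortholog independently: substitutions per
position at `flankSubRate` (motif positions at `motifSubRate`, sampling a
uniformly different base), indels initiated per flank position at
`flankIndelRate` with geometric lengths (mean 2 at the default
$p = 0.5$). Indels never touch motif positions while `motifSubRate` is 0.
Each genome's stream is seeded deterministically from the family seed, so
families are bitwise reproducible. The reference conditions used
throughout the validation suite are 300 bp references, 10 genomes, 3
motifs, 30% flank divergence, 2% indel initiation, 1% motif divergence —
a deliberately hard setting in which flank homology is near the twilight
zone while motifs remain nearly intact.

The simulator is a star topology: orthologs diverge independently from
the reference, with no phylogenetic correlation, no rate variation along
the sequence, no realistic indel length mixture, and no compositional
bias. Passing tests on these families therefore demonstrates the engine's
and the metrics' correctness and the qualitative advantage of contiguity
scoring in recovering planted motifs; they do not calibrate how large that
advantage is on real genomes.

## Validation strategy and problem sizes

Correctness rests on three independent checks, each at sizes chosen to
keep the default suite comfortably fast. First, an exhaustive
path-enumeration oracle (`bruteForceAlign()`, guarded to
$N \times M \le 100$) scores every alignment by the run-length rescoring
semantics; the engine matches it on every sequence pair up to length 4
(all $340^2$ ordered pairs, four presets, both modes) and on 500 seeded
pairs up to length 8. Second, with linear $f$ the engine is
score-identical to an independent textbook SW/gap-affine implementation on
1000 seeded pairs up to length 60. Third, `rescoreAlignment()` re-derives
every reported score from the emitted operations, which ties the traceback
to the forward pass exactly; banding at full width and every checkpoint
interval reproduce the full-matrix result bit for bit on 200 seeded
pairs. The motif-recovery comparison runs 50 seeded families under the
reference conditions above.

## Known limitations

Nucleotide sequences only — no protein or translated alignment, no
substitution matrices (match/mismatch only), no multiple alignment, and no
seed-and-extend heuristics: the engine is the optimal back-end a seeder
would call, not a seeder itself. Memory for the full-traceback engine is
$O(NM)$ cells (times mean contiguity depth for nonlinear $f$); use
`alignLinearSpace()` beyond a few thousand bases. The consistency metrics
assume one alignment per genome per reference and do not assess
statistical significance of motif enrichment.
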