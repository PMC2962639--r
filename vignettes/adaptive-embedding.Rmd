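---
title: "Seed-embedded alignment profiling: model, parameters and design"
author: "agblast"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Seed-embedded alignment profiling: model, parameters and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(agblast)
```

## The model

`agblast` detects remote protein homology by *sequence embedding*. A target
is a scoring profile (PSSM) `X` of length `n` with a consensus sequence; a
query `Y` has length `m`. A seed `S` — the N- or C-terminal
`k = max(1, floor(p/100 * n))` consensus residues, `p = 10` by default — is
inserted at a query position `q` to form the chimera
`C(q) = Y[0,q) | S | Y[q,m)`. The seed aligns exactly to its own profile
terminus, so it acts as a guaranteed anchor from which an affine-gap
extension can reach into flanking low-identity sequence that no unseeded
heuristic would align.

Two search strategies share one alignment substrate:

* **Exhaustive**: seed every position `q = 0..m-1`, both terminals —
  `2m` seeded DP runs per (query, profile) pair. This is the reference
  implementation and the oracle for the tests.
* **Adaptive**: first find unseeded, non-overlapping *partial alignments*
  (word hits of size 3 scoring `> minimum word score`; ungapped extension
  with a drop-off rule and hit consumption into HSPs; affine-gap extension
  from each HSP's *GE starting pair*), then seed only positions from which
  the seeded extension could reach a partial alignment. For a partial with
  query span `[ys, ye)` and target span `[xs, xe)` the candidate positions
  are

  * N-terminal: `q` in `[max(0, ys - G(S) - k), ys + max(0, k - xs)]`
  * C-terminal: `q` in `[ye - max(0, xe - (n - k)), min(m, ye + G(S))]`

  where `G(S) = max(0, floor((Score(S) - GOP) / GEP))` is the longest gap
  whose affine penalty the seed self-score `Score(S)` can pay for. The
  upper/lower correction terms cover the *seamless* insertion: when a
  partial's target span reaches inside the seed's own target block, the
  redundant query residues belong in front of the seed, not in a gap.

The seeded final alignment (one DP per chimera) is anchored at the seed's
inner end and extends toward the region of interest only — rightward/
downward for N-terminal seeds, leftward/upward for C-terminal ones: any
alignment on the other side is discoverable from the unmodified query and
would only duplicate it. Survivors must exceed both filters strictly:
coverage (`100 * aligned target span / n`, > 60 by default) and pairwise
identity computed over non-seed columns only (> 10 by default; a seed-only
alignment has identity 0 and never survives).

Per (query, profile) pair the survivors from both terminals are pooled into
the composite score
`(# survivors) × (mean identity fraction) × (max coverage fraction)` — zero
exactly when nothing survives, bounded by the survivor count. Encoding a
query against M profiles gives its alignment profile; Pearson correlation
between profiles drives top-k ROC fold recognition and average-linkage
dendrograms, and surviving alignment regions drive the per-residue
structural-signal track (Smith–Waterman realignment under BLOSUM62 and
BLOSUM45, identical residues scoring 2, conserved ones 1, averaged across
the two matrices, then normalized, smoothed and baselined).

## Parameters

| parameter | default | units | role |
|---|---|---|---|
| `p` | 10 | % of `n` | seed fraction; `k = max(1, floor(p n / 100))` |
| `wordSize` | 3 | residues | hit width in the unseeded scan |
| `minWordScore` | 11 | score units | strict hit threshold |
| `dropoff` | 7 | score units | ungapped-extension drop-off |
| `minHspScore` | 25 | score units | strict HSP acceptance threshold |
| `gop`, `gep` | 11, 1 | score units | affine gap: length-L gap costs `gop + L*gep` |
| `minPartialFraction` | 0.10 | fraction of `n` | minimum partial-alignment length |
| `minCoverage` | 60 | % | strict survivor coverage gate |
| `minIdentity` | 10 | % | strict seed-excluded identity gate |
| `alpha` | 0.05 | score units/column | length adjustment (below) |
| `window` | 8 | residues | positional-track smoothing width |

The BLAST-protein conventions (word size 3, thresholds 11/25, drop-off 7,
gap 11/1, BLOSUM62) are adopted for every knob whose value the method
itself does not fix; all are arguments on the user-facing functions and
`agb` CLI flags.

## Numerical design choices

**Length adjustment.** Twilight-zone homology often produces a long
alignment with a lower score that is biologically more meaningful than a
short, higher-scoring one. The DP therefore tracks the alignment length
`a` at every cell and selects the final cell by the adjusted comparison
score `raw + alpha * a`, while the recurrence itself maximizes the *raw*
affine score. The adjustment must not enter the recurrence (nor exceed the
score decay rate of random extensions, ~0.15–0.25 per column under
BLOSUM62 with gap 11/1): a per-column bonus at or above that rate makes
arbitrarily long random alignments profitable — the aligner leaves the
local-alignment regime and unrelated sequences acquire full-coverage
"alignments". The default `alpha = 0.05` sits safely below the decay rate;
`alpha = 0` recovers standard anchored extension, and the preference for
longer alignments can be strengthened explicitly where specificity matters
less than boundary recall.

**Seed budget.** The seeded extension prunes any prefix whose cumulative
raw score would exhaust `Score(S)`. This is the DP-side counterpart of the
`G(S)` selection rule — a gap (or mismatch run) the seed cannot pay for
terminates the extension — and it is what makes the adaptive candidate
ranges meaningful. Without it, the full-rectangle DP would happily bridge
from any seed position to any conserved region.

**Determinism.** Traceback ties break in fixed order (diagonal, then gap
consuming the target, then gap consuming the query); gap-state ties prefer
opening over extending; the best cell is the first encountered in scan
order; GE starting pairs take the leftmost maximal length-11 window of the
HSP (whole HSP if shorter) and its central pair. Hits are consumed by every
*constructed* HSP (accepted or not), and per-diagonal occupancy bounds
later extensions, so HSP spans on a diagonal are disjoint. Survivors are
deduplicated on (terminal, q, target span, query span) and sorted by
(terminal, q, target start). A profile matrix is bit-identical across runs.

**Non-overlapping partials.** Gapped extensions are reduced greedily in
decreasing score order, rejecting any alignment whose *query* span overlaps
an accepted one. Query spans partition the conserved query regions that
Step-2 ranges are built from; target spans may repeat, because a repeated
domain legitimately aligns the same profile once per copy.

**Filters and degenerate inputs.** Both filters are strict (`>`).
Seed-only alignments (empty extension) return no result. The identity
denominator counts all non-seed columns including gaps. An all-`X` query
scores negatively everywhere (X falls back to −1 unless the matrix defines
it) and cleanly produces an all-zero profile row. Percentages are exact
ratios; the only tolerance in the package is the 1e-9 mean-zero check on
normalized tracks.

**ROC.** Sensitivity `TP/(TP+FN)` and FPR `FP/(FP+TN)` are averaged per
query (pooled counts are also reported and coincide with the averages for
equal-sized groups); similarity ties break lexicographically by query id;
candidates with undefined Pearson correlation (constant profile rows) are
excluded from rankings; single-member groups contribute no sensitivity
term. Note that under random rankings the expected *sensitivity* at `k = 1`
with groups of 5 among 10 queries is `(4/9)/4 = 1/9` — the top-1 hit
*rate* 4/9 is a different quantity.

**Smoothing and baselining.** The positional track uses a centered moving
average of width `window` (edge-truncated), a linear-phase low-pass filter
chosen so the property suite depends only on that qualitative behavior —
proprietary smoothing implementations differ in detail but share it.
Discontinuous baselining subtracts the piecewise-linear curve through all
strict local minima of the smoothed track (endpoints included), so the
result is exactly zero at each anchor.

## The synthetic benchmark

`generateProfile()` draws a uniform-random consensus and derives PSSM
columns from the BLOSUM62 rows of the consensus (so the consensus
self-score is the diagonal sum and each column peaks at its consensus
residue). `plantHomolog()` embeds a copy of the consensus, mutated i.i.d.
to a controlled identity (substitutions drawn uniformly from the other 19
residues; no indels by default so the ground-truth span stays exact),
between uniform-random flanks. `generateBenchmark()` builds fold groups by
drawing several planted homologs per hidden profile. Defaults — profile
length 60, flanks 30+30 (query 120), planted identities 0.3–0.7 — are the
conditions the test suites run at; the benchmark of 5 groups × 4 members
at identity 0.4 is the desk-scale fold-recognition experiment.

What the generator does *not* emulate: realistic residue composition and
correlation structure, indel-rich divergence (an `indelRate` switch exists
for stress tests), profiles estimated from alignments rather than single
sequences, and realistic profile lengths. The last point matters: with a
60-residue profile, 60% coverage is only ~36 aligned columns, which chains
of chance local matches can reach, so the exhaustive search retains a
background of spurious survivors on unrelated pairs at this scale (the
adaptive search does not — without partial alignments it never seeds).
Passing tests therefore demonstrate the algorithmic contracts
(containment, shift laws, DP optimality, filter behavior, ROC mechanics),
not production-grade specificity, which additionally requires longer
profiles and curated libraries.

## Known limitations

* Alignment-level agreement between adaptive and exhaustive search is
  structurally bounded: the exhaustive DP also survives for seeds placed
  *inside* a conserved region (the extension simply re-registers past the
  redundant residues) and, rarely, for placements bridged by chance
  matches beyond `G(S)`. The adaptive ranges deliberately skip those
  placements — they yield truncated or duplicated variants of alignments
  already found — so adaptive recovery of exhaustive survivor *placements*
  saturates near half, while detection-level agreement (does this query
  match this profile at all?) is essentially complete. Fold-recognition
  results are driven by the latter.
* No e-value statistics: significance is coverage/identity filtering only,
  as in the embedding method itself.
* One seeded DP per chimera; the hit/HSP reuse expressed by the shift laws
  is exploited for candidate selection, not yet for incremental DP.

## Test problem sizes

The suites run on profiles of 20–60 residues (queries up to 120; shift-law
fixtures at 40/80; DP-oracle instances up to 50×50), 200 planted fixtures
for the containment/recovery suites, 50 for the shift laws, 50 decoys and
a 5×4 benchmark — small enough for routine continuous testing, large
enough that every property is exercised across the full identity band.
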