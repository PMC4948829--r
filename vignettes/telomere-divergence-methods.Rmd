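---
title: "Calling telomere sequence divergence: models, rules and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Calling telomere sequence divergence: models, rules and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(telodiverge)
```

## The assay and its model

Yeast telomeres are irregular C₁₋₃A/TG₁₋₃ repeats. Because telomerase
adds *degenerate* repeats, two telomeres that diverged from a common
ancestor carry distinguishable distal sequence: sequencing many clones
of one telomere from a clonal population reveals a shared
centromere-proximal span and clone-specific distal tails. `telodiverge`
turns that qualitative picture into per-clone calls with three
quantities: the *divergence point* (first reference position of the
first intolerable difference, 1-based), the *undiverged length*
(reference span proximal to it), and a *truncation* flag (undiverged
span strictly below 125 nt — a length end-replication attrition of
3–4 bp per generation cannot plausibly produce, so in a
telomerase-positive strain it marks an abrupt truncation that telomerase
later re-extended; in telomerase-null sets the flag is still computed
but has no such reading).

Clone-level divergence incidence connects to a per-generation event rate
through the at-least-one-event form

$$f = 1 - (1 - r)^g, \qquad r = 1 - (1 - f)^{1/g},$$

so an 8.6 % diverged fraction after ~30 population doublings corresponds
to r ≈ 0.3 % per telomere per generation. Observed fractions come with
exact (Clopper–Pearson) 95 % intervals because clone counts are small
(n ≈ 30–40); group comparisons use Fisher's exact test (two-sided, by
summing tables no more probable than the observed one). These fractions
mix in-vivo events with technical artifacts of PCR, cloning and
sequencing; under independence, a control-derived background fraction
can be removed as $f_\mathrm{adj} = 1 - (1-f_\mathrm{obs})/(1-f_\mathrm{bg})$.
The adjustment is reported alongside, never instead of, the raw
fraction, since the independence assumption is not testable within one
experiment.

## Classification procedure

### Reference selection

The reference is *the longest telomere without divergent sequence*.
Candidates are ranked by length (ties broken by clone id); the top
candidate is accepted unless calling every other clone against it shows
that it is itself divergent, in which case it is demoted and the next
candidate tried. Two demotion signals are used:

* **majority divergence** — more than half of the other clones called
  diverged. A clean reference cannot make the majority of its siblings
  look divergent, whereas a reference carrying its own divergent tail
  at mid-length makes almost every longer-spanning sibling appear
  diverged at one shared position.
* **shared gap signature** — most clones gapping within the same ±2 nt
  reference window. This is the footprint of a small technical indel in
  the candidate itself (gap placement jitters inside repeats, hence the
  window). A reference indel is otherwise pernicious: it can fuse with
  a clone's own tolerated indel into an apparent >6 nt event, and it
  shifts the reference coordinate system.

If every candidate is demoted (e.g. a telomerase-positive set in which
most clones genuinely diverge distally), the longest clone is used with
a warning; calls against it remain correct for clones whose own
divergence is proximal of the reference's.

### Alignment

Each clone is aligned to the reference with an affine-gap Gotoh
aligner, both sequences anchored at the proximal end and trailing gaps
of the shorter sequence free, so end-replication shortening aligns as an
exact prefix. Scoring defaults: match +1, mismatch −2, gap open −4, gap
extend −1 (a gap of length L costs 4 + L). Gaps must buy at least three
matches to beat a mismatch, which suppresses spurious gap placement in
the low-complexity repeats. Ties are broken deterministically (diagonal
over gap, reference gap over clone gap; among free end cells, consume
more sequence). The implementation is compiled (Rcpp) and is checked in
the test suite against an independent memoized-recursion oracle.

### Tolerance rules

Scanning alignment columns proximal→distal, the following are
tolerated: isolated point substitutions (runs of length ≤ 1 by default,
with no cap on their number — scattered point mutations are expected
from PCR and sequencing error and from mutation accumulation); gap runs
of ≤ 6 nt on either side (the boundary is inclusive: a 6-nt indel is
tolerated, a 7-nt indel is divergent); and the free trailing gap run of
a shorter clone. Substitution runs of length ≥ 3 are automatic
violations. Runs of exactly 2 are *not* automatic: with per-base
technical substitution rates of order 10⁻³ on both sequences of the
pair, two independent tolerated point errors collide into an adjacent
pair about once per ~2500 clone-reference pairs, so an isolated 2-run in
otherwise matching context is tolerated, while a 2-run inside a
degraded distal segment still terminates the undiverged span through
the changepoint detector below.

### The unalignable-tail detector

Divergent tails of degenerate repeats are the hard case: two unrelated
TG₁₋₃ stretches align at ~77 % column identity under this scoring, so a
recombinant tail rarely produces any single intolerable run — it
produces many isolated mismatches and small gaps. The caller therefore
supplements the explicit rules with a suffix log-likelihood-ratio
changepoint on the aligned columns: substitution columns score
log((1−q₁)/e₀) against matches scoring log(q₁/(1−e₀)), with diverged
identity q₁ = 0.77 (measured on simulated unrelated repeat stretches)
and null mismatch rate e₀ = 0.01 (deliberately conservative against
clustered technical noise). Gap runs contribute at most two columns at
a slightly discounted weight, so a lone tolerated indel cannot
approach the detection threshold of 7 — at these weights at least
three clustered difference columns, distally situated, are required.

A detection is accepted only with *positional corroboration*: in the
coordinate frame fixed by the alignment proximal of the landing, at
least 6 mismatches at ≥ 20 % density over ≥ 15 positions of remaining
overlap must follow the proposed junction. This rejects
aligner-fragmented small indels near the end of the overlap, whose
evidence is dense but short.

### Positional junction refinement

The changepoint localizes the tail in *alignment* coordinates, which the
gap-happy tail alignment blurs (median error ~20 nt). In *positional*
coordinates — comparing clone and reference base-by-base in the frame
established proximal of the junction — the junction is sharp: mismatch
density jumps from ~0 to ~0.44 per position. The refinement walks
proximally across positional mismatches separated by fewer than 16
matching positions, starting near the detected changepoint, under two
candidate frames (taken 40 nt proximal of the candidate and immediately
at it, because artifactual tail gaps can corrupt the near frame while a
real proximal indel invalidates the far frame). A landing must pass two
checks: its proximal flank must be essentially matching (≥ 80 % over 15
positions), and no candidate frame may render the region just distal of
it near-perfectly matching (which would mean the "divergence" is a
frame artifact of a real tolerated indel). The refinement also applies
to substitution-run violations and to long-indel violations, where the
positional mismatch chain starts exactly at the indel, so the spec's
6/7 boundary behaviour is unchanged.

With this refinement, planted breakpoints in simulations are recovered
exactly in ~94 % of detected events and within ±5 nt in ~96 % of
events with ≥ 30 nt of replaced tail. The residual misses are close to
the information-theoretic floor: a stray technical substitution within
~16 nt proximal of a junction is indistinguishable from the tail's
first mismatch, and a freshly written tail occasionally opens with a
long coincidental match.

### Reference-error masking

Columns at which most clones of a set disagree with the reference in
the same way (with clean flanks, runs no longer than a tolerable
indel) are attributed to technical errors in the reference clone and
treated as matches. Flank cleanliness keeps genuinely divergent distal
zones — where many clones disagree broadly — out of the mask. This is
deliberately *not* consensus construction: the comparison target
remains a single real clone; masking only prevents that clone's own
point errors from being charged to every other clone.

## Simulator

The generator emulates the study conditions so that every module is
testable with known ground truth:

* **grammar** — telomeres are concatenations of T·Gₖ units, k ∈ {1,2,3}
  with probabilities 0.2/0.5/0.3. The unit mix is an invented default
  (the real distal repeat statistics are irregular); it reproduces the
  ~56 % positional self-identity that makes divergence calling
  non-trivial.
* **conditions** — founder telomeres of 300 nt (including a fixed 30-nt
  non-telomeric proximal anchor standing in for the subtelomeric
  primer-anchored segment), 30 generations of clonal expansion, 35
  clones per set, shortening of 3 or 4 nt per generation, divergence
  events at 0.003 per telomere per generation (distal-tail replacement
  from a uniform breakpoint — only the breakpoint is identifiable by
  the assay, so the replacement is sampled at the replaced length), and
  optional truncation events. With telomerase active, telomeres
  dropping below 160 nt are re-extended by a geometric-length stretch
  (mean 50 nt) of fresh repeats.
* **clonal structure** — each clone evolves independently from the
  shared founder: the founder supplies the stable proximal sequence,
  the per-clone histories the independent distal events, and per-clone
  event counts are Binomial(g, r) by construction. Real pedigrees
  correlate early events between clones; this simplification
  reproduces the proximal-stable/distal-divergent structure without
  modeling lineage trees, and means simulated divergence fractions
  estimate the per-lineage incidence without pedigree-induced
  overdispersion.
* **technical layer** — each clone independently acquires an
  artifactual distal replacement with probability 0.04 (bracketed by
  the 3.8–4.2 % control re-cloning fractions), plus background isolated
  substitutions at 10⁻³ per base and small indels (1–6 nt) at 2×10⁻⁴
  per base. Substitutions are placed non-adjacent and indels well
  separated, matching their tolerated classification; the background
  split between the artifact probability and the per-base rates is a
  design choice constrained only by the aggregate control fractions.
* **ground truth** — the truth table records the *effective* breakpoint
  of every surviving event: the first base at which the replacement
  actually differs from the founder (fresh repeats reproduce the
  founder for a geometric-tailed number of leading bases, and no caller
  can place a junction proximal of the first differing base). Each
  clone's technical indels are recorded so that founder-coordinate
  truth can be mapped onto the chosen reference's coordinates with
  `reference_coordinate()`.

What passing tests on these simulations do *not* show: robustness to
chromatogram/base-calling artifacts, to pedigree-correlated events, to
non-uniform breakpoint placement, or to subtelomeric polymorphism —
real data can violate all four.

## Senescence quantification

Daily densities after 24 h of growth and dilution to 2×10⁵ cells/ml
convert to per-passage doublings log₂(density/2×10⁵); senescence is
tracked in cumulative PD, not days, because telomere shortening tracks
divisions. Negative increments (shrinking cultures) are retained so
cumulative PD reflects decline honestly. The *point of maximum
senescence* is the passage of minimum density (earliest on ties) — the
natural reading in a daily-dilution design, consistent with survivor
sampling at "the first time point after" it. Genotypes are compared by
Welch's unequal-variance two-tailed t-test on replicate-level PD at
maximum senescence (replicate counts typically differ between
genotypes; the pooled-variance variant is not assumed). Replicates are
aligned by passage number for averaging — each passage is one
measurement event — and both density and cumulative-PD means ± SE are
emitted per passage, since either may be wanted on the y-axis.

## Numerical and interface conventions

* All reported positions and lengths are 1-based nucleotides; the
  undiverged length is measured on the *reference* coordinate, also
  when tolerated indels precede the divergence point.
* Ties are broken lexicographically by clone id everywhere, so repeated
  runs are bit-identical.
* Every emitted simulation artifact derives its own RNG stream from the
  master seed by a fixed integer recurrence, so artifacts can be
  regenerated independently and identical configurations are
  byte-identical.
* Degenerate inputs are hard errors (empty sequences, non-ACGT bases
  after upper-casing, singleton clone groups, non-consecutive assay
  days, non-positive densities), except that singleton clone groups are
  dropped with a warning on FASTA ingest.
* Problem sizes used in the shipped tests and in
  `scripts/acceptance.R` — 10⁵ lineages for incidence, 1000-clone null
  panels, ~1500–3000 clones for detection benchmarks — were chosen to
  give three-sigma headroom on the quantities being checked while
  keeping a full run in the order of a minute.

## Known limitations

* A divergence whose surviving tail is shorter than ~15 nt of reference
  overlap is deliberately not callable (indistinguishable from a
  tolerated end indel); events whose tail was entirely eroded by
  subsequent shortening are invisible in principle.
* The breakpoint of a deletion inside repeats is ambiguous up to the
  repeat phase; calls may slide by up to the indel length.
* The 125-nt truncation threshold and the 6-nt indel tolerance are
  assay conventions, exposed as configuration but not re-derived here.
* Rate estimation treats clones as independent; pedigree correlation in
  real clonal populations widens the true sampling interval relative to
  the binomial one.
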