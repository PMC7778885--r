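---
title: "Rearranging Hi-C contact maps along derivative chromosomes"
author: "derivHiC"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Rearranging Hi-C contact maps along derivative chromosomes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(derivHiC)
```

## The problem

Large structural variations (SVs) — deletions, duplications, inversions and
translocations — rewire the 3D folding of cancer genomes. On a Hi-C contact
map drawn in reference coordinates, an SV junction appears as an ectopic
"bowtie" of enriched contacts between loci that are far apart (or on
different chromosomes) in the reference but adjacent on the tumor's
*derivative chromosome*. Interpreting these signals — TAD fusions,
neo-TADs, enhancer hijacking — is much easier once the contact matrix is
re-drawn in derivative coordinates, so that truly adjacent sequence is
adjacent on the axis.

derivHiC reconstructs those derivative views. It converts WGS breakend
records or free-form fragment orders into an explicit bin-level coordinate
map, remaps binned contact matrices onto it, supports sequential
interactive-style edits with undo, normalizes by distance-expected
background, and quantifies whether a putative junction really behaves like
contiguous chromatin.

## The coordinate model

Everything reduces to two objects:

* A `BinTable` partitions the genome into fixed bins of `binsize` bp
  (`ceiling(length / binsize)` per chromosome, global 0-based ids in input
  chromosome order). 40 kb is the conventional resolution for cancer maps
  with both cis and trans contacts; deeply binned normal maps use 5 kb with
  a 2 Mb cis cap, available as the CLI `--preset normal`.
* A `BinMap` is an ordered list of `(source bin, orientation, fragment
  index)` entries. Derivative chromosomes, breakend records, order-spec
  files and interactive edits are all reduced to BinMaps, and a single
  materialization routine consumes them: `M'[a, b] = M[src(a), src(b)]`.
  Having one canonical reduction is what makes the engine testable against
  a brute-force per-bin-list oracle.

Coordinates are 0-based half-open internally; all user-facing text formats
are 1-based inclusive except BED-convention bin starts in matrix triples
and interaction tables. A breakpoint at position p is a cut coordinate: the
bin holding it is found by floor division `p %/% binsize`, and a fragment
keeps every bin it overlaps, even partially. Consequently, in an
intra-chromosomal deletion the two junction bins both survive — published
recombined maps show breakpoint-spanning bins, and no truncation rule is
standard, so retention is the deterministic choice.

## Breakend orientation semantics

A breakend record `chrom1 pos1 chrom2 pos2 TYPE ORIENT` names which side
(3′ or 5′) of each breakpoint is fused. Writing "side 3 at p" for the
segment `[0, p)` ending at p and "side 5 at p" for `[p, L)` starting at p,
the junction algebra is:

| orientation | derivative |
|---|---|
| 3to5 | `[c1:0-p1 +] [c2:p2-L2 +]` |
| 5to3 | `[c2:0-p2 +] [c1:p1-L1 +]` |
| 3to3 | `[c1:0-p1 +] [c2:0-p2 −]` |
| 5to5 | `[c1:p1-L1 −] [c2:p2-L2 +]` |

The anchor for this table is the deletion convention: a DEL recorded as
`3to5` must produce the deletion-joined map, i.e. `[0, p1)` fused to
`[p2, L)`. The other three rows follow by the same side algebra.
Derivatives are canonicalized to start with a + fragment where the algebra
allows it; fusing two 5′ sides cannot start with a + fragment (its mirror
image starts with − as well), so 5to5 derivatives begin with a reversed
fragment. Intra-chromosomal type/orientation consistency (DEL↔3to5,
DUP↔5to3, INV↔3to3/5to5) is checked; because pan-cancer SV tables carry
heterogeneous annotations, a mismatch warns by default and errors only in
strict mode. TRA accepts any orientation, and a reciprocal translocation is
written as two records, one per junction product.

```{r}
bt <- makeBinTable(c(chr6 = 170805979), 40000)
sv <- parseSVTable("chr6 75343990 chr6 125216780 DEL 3to5")
entries(derivativeToBinMap(bt, svToDerivative(bt, sv)))[1883:1886, ]
```

## Edits, order specs, and materialization

Interactive manipulation is modeled as an edit script over the *current*
derivative axis (what a user looking at the map sees), not reference
coordinates: `delete`, `invert`, `duplicate` (tandem), and `join` between
two derivatives at cut points. `applyEditSequence()` left-folds the edits
and keeps an undo stack. After every edit, fragment indices are recomputed
as maximal same-orientation consecutive-bin runs; this is deterministic,
and its one side effect — two fragments that happen to abut in source
coordinates merge into one run — only affects cosmetic fragment boundaries,
never the matrix.

Complex rearrangements come in as order-spec text
(`name TAB chrom:start-end[+|-];...`), one derivative per line; regions not
mentioned are deleted by construction, since they never enter the axis.

`materialize()` fills the dense rearranged matrix, multiplies entries whose
two source bins lie on different reference chromosomes by the trans weight
w (a display-time enhancement for faint translocation signal; it is never
persisted into counts), and records derivative/fragment boundaries for
rendering. Duplicated source bins replicate their source rows and columns,
including the dup–dup self-block: with a single observed matrix, the
tandem-copy assumption is the only computable fill, though real duplicated
alleles need not fold identically — a stated limitation.

## Normalization

Two normalizers operate on the same sparsity pattern:

* **Coverage** (`coverageNormalize()`): `value(i,j) = counts(i,j) /
  (m_i m_j) · S`, with `m` the symmetric marginals (diagonal once) and `S`
  restoring total mass. This is a deliberately simple marginal-product
  stand-in for regression-based coverage normalizers; a custom function can
  be plugged in via the `normalizer` argument.
* **Distance** (`expectedByDistance()` + `distanceNormalize()`): expected
  contact at bin distance d is the mean over *all* cis pairs at that
  distance — structural zeros included, which keeps the estimate
  deterministic and makes the mean fold change at every distance exactly 1
  before smoothing. Smoothing is a log-space moving average (default
  window 3 bins) floored at 1e-8 to keep ratios finite. Per-chromosome
  profiles are the default (chromosomes differ in decay); a pooled profile
  is always computed as well, since junction scoring and trans baselines
  need a chromosome-agnostic expectation.

## Junction smoothness

`junctionSmoothness()` quantifies the "smooth linkage" criterion: over the
k×k bin pairs flanking an axis cut, it averages observed / expected(d)
where d is the pair distance *on the rearranged axis*. That is precisely
the neo-adjacency hypothesis: if the derivative is real, cross-junction
pairs at axis distance d should carry the same signal as any cis pairs at
distance d, giving S ≈ 1. Scoring the same flanks across an unrearranged
reference gap gives S ≪ 1, because the intervening bins carry no signal in
a genome that lacks them. The expected profile is taken from the rearranged
map itself (via `rearrangedToContactMatrix()`), so the score is internally
calibrated and scale-free. Pairs whose expected value sits at the floor are
excluded and reported.

## The synthetic generator

`simulateReference()` / `simulateRearranged()` produce matrices with known
ground truth: cis mean `A (1 + d)^(-alpha)`, within-TAD boost `beta`, flat
trans mean `t·A`, Poisson counts, mandatory seed. `simulateRearranged()`
first builds the truth derivative genome (reciprocal products for a
translocation; the balanced three-fragment derivative for an inversion,
which has two junctions; identity derivatives for untouched chromosomes),
simulates on derivative coordinates, and projects every pair back to
reference bins. Projection conserves total counts, and bins covered twice
by a duplication accumulate — as sequencing reads from two copies pile onto
one reference bin.

Default parameters, chosen once as a realistic desk-scale operating point:
`A = 100` (deep local coverage at 40 kb), `alpha = 1` (the classic
contact-decay slope), `t = 0.05` (trans background a few percent of the
short-range cis signal), `beta = 1.5` with TADs opt-in (`nTads = 0` by
default so that calibration experiments run on the pure power-law model;
TAD-structured fixtures set `nTads` or explicit boundaries). Poisson
emission keeps exact-mean properties for the recovery experiments;
overdispersed (negative-binomial) emission is a natural extension hook not
currently implemented.

What the generator does *not* emulate: A/B compartments, loops,
copy-number-dependent coverage, mappability artifacts, or overdispersion.
Tests passing on these fixtures therefore validate the coordinate algebra,
the normalization identities and the recovery logic — not robustness to
every artifact of real cancer Hi-C.

## Validation experiments and problem sizes

The test suite and `scripts/acceptance.R` recompute, among others:

* 100 randomized trials (100–300 bins, 1–3 chromosomes, up to 5 random
  edits) where the engine must equal a brute-force per-bin-list editor
  exactly;
* the chr6 deletion worked example, whose junction bins 1883 and 3130 must
  be adjacent on the 40 kb axis;
* decay-exponent recovery within ±0.1 for α ∈ {1.0, 1.5} on 200–250 bin
  maps (`beta = 1`, `t = 0` to isolate the power law);
* the deletion-recovery experiment: 300-bin maps simulated at default
  parameters with an 80-bin deletion; after correct rearrangement the true
  junction scores S ∈ [0.8, 1.25], while the unrearranged gap and a
  20-bin-shifted junction score far outside, in at least 8 of 10 seeded
  replicates.

These sizes were chosen so every experiment is comfortably reproducible on
a laptop in seconds while leaving the stochastic tolerances wide relative
to Monte-Carlo error (the standard error of the mean fold change over 100
junction pairs at `A = 100` is below 0.05).

## Numerical and design choices

* Chromosome order is input order, never sorted — determinism across
  naming dialects.
* Intra-chromosomal records are normalized to `pos1 ≤ pos2` at parse time,
  swapping the orientation sides accordingly.
* The expected-profile floor (1e-8) and the log-space smoothing window are
  exposed; `estimateDecayExponent()` bypasses smoothing entirely, since a
  moving average of an exact power law is no longer an exact power law.
* Zero-coverage bins normalize to zero and are flagged rather than
  dropped, preserving matrix shape.
* All-zero matrices, empty derivatives, out-of-range edits and join cuts
  that would produce an empty side raise immediately with the offending
  index; edit sequences abort at the first invalid edit.
* Rendering ("crop", zoom) is a windowing concern, not a data operation:
  the data model never truncates matrices for display.

## Known limitations

* Copy-number alterations are not modeled: expected profiles and the
  duplication fill assume a single underlying copy, so fold changes around
  amplified regions are biased.
* The smoothness score tests neo-adjacency only; it cannot distinguish a
  deletion junction from any other mechanism producing the same contact
  geometry.
* Only single-resolution matrices in text form are supported (sparse
  triples in, triples/dense TSV out); multi-resolution pyramid formats are
  out of scope.
* The orientation algebra is anchored on the deletion convention; SV
  callers that emit a different side convention must be mapped at import
  (the BEDPE reader's strand mapping is one such adapter).
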