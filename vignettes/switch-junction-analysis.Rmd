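---
title: "Switch-junction and hypermutation analysis: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Switch-junction and hypermutation analysis: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(switchjunction)
```

# Scope

`switchjunction` analyses class-switch-recombination (CSR) junction amplicons:
chimeric Sanger reads whose 5' part derives from the donor switch region (Sμ)
and whose 3' part derives from an acceptor switch region (Sγ1, Sγ3, ...).
The package reconstructs each read as a chain of germline fragments, resolves
every fragment-to-fragment boundary into one of three mutually exclusive
structures (blunt, microhomology, insertion), classifies the overall junction
architecture (simple vs compound, with atypical-event flags and a complexity
score), summarizes junction overlap distributions, profiles somatic
hypermutation (SHM) in clone sets, and supplies the statistical toolbox for
group comparisons. A generator with exact ground truth closes the loop for
validation.

# The model

## Junction structure

A junction read is modeled as an ordered concatenation of gap-free germline
fragments, each an interval of one switch region on one strand, possibly with
novel (non-templated) bases between consecutive fragments. Switch regions are
highly repetitive pentamer-rich sequence, so a read rarely has a unique
base-exact explanation; the package therefore commits to explicit, documented
conventions rather than claiming to recover "the" physical event.

## The overlap (microhomology) definition

The quantity at the heart of the analysis is the boundary overlap `OL`: the
length of the longest window of the read spanning the breakpoint that matches
**both** germline continuations perfectly — the donor sequence read through
its end of the window and the acceptor sequence read back from its start. A
junction with `OL = 0` and no novel bases is *blunt*. A junction carrying
novel bases at the seam that match neither germline continuation is an
*insertion* junction; insertion and microhomology are mutually exclusive by
construction (a seam either has extra unmatched bases or shared matched
bases, never both), and insertion junctions are recorded with `OL = 0` and
are excluded from mean-overlap statistics and overlap histograms (they are
counted separately).

## Breakpoint as a window, not a point

Because the two germline continuations share the microhomology bases, the
breakpoint is not a point but an ambiguity window of width `OL`. The package
reports the window: `leftBreakRef` is the genomic coordinate of the last
donor-matched base and `rightBreakRef` that of the first acceptor-matched
base, and the three-wise render (`renderThreewise()`) displays read, donor
germline and acceptor germline with the window bracketed in all three.

## Boundary resolution

Given two adjacent fragments, `resolveBoundary()`:

1. scans candidate split points `m` in a window around the nominal seam and
   scores each by (matches to donor left of `m`) + (matches to acceptor right
   of `m`), with mismatches penalized 2:1 against matches; the best-scoring,
   leftmost split is the canonical breakpoint;
2. extends maximal perfect match runs leftward into the donor and rightward
   into the acceptor, requiring each run to be connected to the body of its
   fragment (this prevents isolated chance matches inside an insertion from
   masquerading as homology);
3. the intersection of the two perfect extensions is the microhomology
   window; a gap between them is an insertion; abutting extensions are blunt.

The mismatch-penalized split score is needed because, in pentamer-repeat
sequence, a tolerant aligner can over-extend a fragment tens of bases past
the true seam; scoring raw matches alone can then settle inside a spurious
double-match region. The 2:1 penalty mirrors the +1/−2 scoring used in the
seed-and-extend aligner, so the two stages agree about what "supported by the
reference" means.

## Segmentation (the caller)

`scanReference()` is a seed-and-extend, gap-free diagonal aligner: exact
12-mers are hashed, seed hits are grouped by diagonal, and each diagonal's
match/mismatch profile is scanned for maximal scoring runs (+1 match, −2
mismatch), trimmed to match ends. `segmentJunction()` chains candidate
segments across both references with a dynamic program that charges each
additional fragment a fixed penalty and each read-coordinate overlap its
length, preferring fewer fragments, then fewer mismatches, then leftmost
placements. Both orientations of the read are tried; the orientation that
yields a valid donor-then-acceptor architecture wins, so reported junctions
are always donor-forward. Reads explained by a single region only are
returned as uncallable (with their partial matches) rather than as errors.

## Classification

A callable junction is *simple* iff it is exactly two fragments, donor then
acceptor, both forward; anything else is *compound* (extra same-region
fragments are intra-switch recombination events; reverse-strand fragments are
inversions). Atypical flags: `microdeletion` (same-region adjacent fragments
with a reference gap of 1–50 nt), `long_microhomology` (any boundary with
`OL ≥ 15`), `inversion`. Complexity counts intra-switch events + insertions +
inversions + microdeletions.

Two conventions deserve note. First, whether a seam insertion in an
otherwise-simple junction should contribute to complexity is genuinely
ambiguous; the package resolves it by definition: simple junctions have
complexity 0, and insertions contribute to complexity only in compound
junctions. Flags, by contrast, are recorded unconditionally, so no
information is lost. Second, a same-region gap larger than 50 nt is counted
as a plain intra-switch event, not a microdeletion.

## SHM profiling

`profileClones()` aligns each clone globally to its germline reference
(affine gaps; clones identical to, or gaplessly within the identity threshold
of, the reference take a fast path), emits substitutions into the 12-class
spectrum with their 5-mer context and motif class, and emits indels
separately — indels never enter the substitution spectrum, but substitutions
adjacent to an indel column are flagged. Motif classes are the field-standard
AID hotspots RGYW/WRCY (scanned on both strands), the polymerase-η hotspots
WA/TW, and SYC/GRS coldspots; hotspots take priority over coldspots.

Mutation frequency `F` is substitutions per total analyzed bases
(`nSequences × analyzedLen`), not per mutated-sequence bases; this is the
stricter and more reproducible denominator and is used consistently.
Clonally related duplicates (identical mutation sets) can be collapsed on
request; the default keeps all clones.

## Statistics

* `fisherExact2x2()` implements the exact test with the two-tailed
  *point-probability* definition: the p-value sums all hypergeometric tables
  (same margins) whose probability does not exceed the observed table's,
  with a `1 + 1e-7` relative tolerance on the comparison. This is the
  convention of mainstream statistical software; other two-tail conventions
  exist, and small discrepancies against externally reported p-values are
  possible and should be reported, not hidden.
* `chi2Test()` is the plain Pearson statistic without continuity correction.
  Cells with expected counts below 1 are pooled before testing — into the
  adjacent higher bin for ordered histograms (overlap-length binning), into a
  rest column otherwise — with degrees of freedom computed after pooling.
* `ratioWithPropagatedSD()` propagates measurement error through a division
  with relative errors added in quadrature (first-order/delta method); a
  zero numerator falls back to `sd_num / |den|`. This is the standard
  treatment for normalizing qPCR/ChIP quantities to a control, and is
  accurate when relative errors are small; it is not exact for large ones.
* `meanOverlap()` bins overlaps as 0, 1, ..., 14, ≥15, excludes insertion
  junctions, and flags (rather than errors on) the degenerate all-insertion
  case.

# The generator and what validation means

`simulateJunctions()` builds reads by concatenating reference fragments with
a sampled boundary type. The critical correctness trap is that naive
concatenation in repeat-rich sequence frequently creates *accidental*
homology longer than the planted value, or alternative exact registrations
of the seam elsewhere in the region that can absorb a planted insertion.
Every emitted read therefore passes a seam-honesty check: all competitive
registrations of the seam (exact occurrences of the flanking words, plus
shifted near-registrations with mismatches charged 2:1) are enumerated, and
the read is rejected and resampled unless the planted boundary remains the
unique net-positive explanation and the realized maximal perfect homology
equals the planted `OL` exactly. Intra-switch seams of compound reads are
emitted blunt, so the planted event list is unambiguous. Point mutations, if
requested, are applied outside a protected window around each seam so the
planted boundary type remains the ground truth (a flag allows seam mutations
for robustness testing).

Reference sequences are generated as tandem pentamer blocks interleaved with
random sequence at a configurable density; the defaults emulate the
repetitiveness of real switch regions, and density 0 gives easy,
repeat-free cases. All randomness derives from the configuration seed and
the generator is byte-deterministic under a fixed seed.

The test suite validates the package against this generator and against
independent oracles (string-walking seam homology, exhaustive diagonal
scans, `choose()`-based hypergeometric enumeration, the installed
`fisher.test`/`chisq.test`/`pairwiseAlignment` as cross-checks). Passing
these suites shows that the caller inverts the generator's model of junction
formation at study scale and that the statistics match their closed forms.
It does **not** show that the conventions (canonical breakpoint choice,
mismatch tolerances) reproduce any other software's calls on real
chromatogram data, and the generator has no sequencing-error model, so
robustness results with planted point mutations do not cover chromatogram
artifacts such as miscalled peaks or trimming errors.

# Parameter defaults and rationale

| Parameter | Default | Rationale |
|---|---|---|
| `minSegLen` | 20 | shortest fragment accepted; below ~20 nt a match is not meaningfully unique in pentamer repeats |
| `maxMismatchRate` | 0.1 | tolerates SHM-level mutation loads in fragments without admitting junk matches |
| `seedK` | 12 | exact-seed length; long enough to thin the index in repeats, short enough to survive ~1 mutation per 12 nt |
| `maxBoundaryOverlap` | 80 | maximum read-coordinate overlap of adjacent fragments the chainer accepts; generous because tolerant alignment over-extends into repeats |
| `fragmentPenalty` | 25 | score charged per extra fragment; prefers parsimonious architectures |
| `longMhThreshold` | 15 | overlaps of ≥ 15 nt flagged as long microhomology (the top histogram bin) |
| `microdelMin`, `microdelMax` | 1, 50 | same-region gap range called a microdeletion; larger gaps are intra-switch events |
| `mhBinMax` | 15 | overlap histogram bins 0..14 and ≥15 |
| identity threshold (SHM) | 0.9 | clones below 90% global identity are excluded as unalignable |
| alignment scores (SHM) | match 2, mismatch −2, gap open 8, gap extend 2 | standard affine scheme; favors substitution calls over spurious short gaps |

Generator defaults (read length 280–520, reference length 1500, repeat
density 0.35, boundary mix 0.45/0.40/0.15 blunt/microhomology/insertion,
geometric microhomology lengths, compound fraction 0.15) were fixed as the
study conditions for all validation runs; scenario-specific suites override
single dimensions (e.g. all-blunt, uniform 1–30 microhomology) while keeping
everything else at the defaults.

The hypermutation generator normalizes per-position rates so that the
realized genome-wide expectation equals the target frequency `F0` regardless
of the hotspot bias (multipliers are divided by their mean); without this,
raising the bias would silently raise the total mutation load and conflate
two parameters.

# Limitations

* Germline interval boundaries for the switch regions are user input; the
  package does not choose amplicon windows.
* Boundary resolution reports a canonical choice under explicit conventions;
  base-exact breakpoints in repeats are not identifiable in principle.
* The gap-free fragment model means small indels inside a fragment surface
  as extra boundaries or mismatches, not as within-fragment gaps.
* The SHM aligner assumes clones are colinear with the reference
  (no rearrangements) and a user-supplied analysis window.
* No chromatogram-level error model anywhere in the package.
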