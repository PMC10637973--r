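---
title: "Screening and designing loop-insertion crystallization tags"
author: "insertag"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Screening and designing loop-insertion crystallization tags}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(insertag)
```

## Background

Carrier-driven crystallization rescues proteins that do not crystallize on
their own by fusing them to a small domain with an excellent
crystallization track record. The loop-insertion variant of the strategy
replaces an *internal* flexible insertion of the target with the carrier,
so both target halves are held by one rigid domain. Geometrically this is
only possible when the carrier's N- and C-terminal Cα atoms are close
together in space — a few Å, comparable to the Cα–Cα distance of the two
target residues flanking the removed insertion.

`insertag` implements the three computational stages of that workflow:
candidate screening over structure libraries, fusion-construct assembly
with provenance, and the structure/interface comparisons used to validate
the result. This vignette documents the models, the tunable parameters and
the design decisions behind each stage.

## The screening model

A chain passes the hard screen when all six criteria hold
(`screen_criteria()` defaults in parentheses, all configurable):

| criterion | quantity | rule | default |
|---|---|---|---|
| i | residue count | strictly `<` | 400 |
| ii | disulfide bonds | none | — |
| iii | non-water het residues | none | — |
| iv | method + resolution | X-ray, strictly `<` | 1.6 Å |
| v | terminal Cα separation | `<=` (inclusive) | 10 Å |
| vi | globularity ratio | `<=` | 1.25 |

Strictness follows the conventional reading of such thresholds: size and
resolution cutoffs are strict upper bounds, while the termini rule is a
distance bound and therefore inclusive. A missing resolution record fails
criterion (iv) rather than passing by default, because the criterion is
about demonstrated crystallizability at high resolution.

**Globularity** has no standard quantitative definition in this context.
We use the ratio of the observed heavy-atom radius of gyration to the
empirical scaling for globular proteins, `R_ref = 2.2 · N^0.38` Å with `N`
the residue count; compact folded domains score near or below 1, extended
chains score several-fold higher. The 1.25 pass threshold leaves room for
slightly prolate domains while rejecting hairpins and coils; it is exposed
in `screen_criteria()` for users who disagree.

**Disulfides** are CYS SG–SG pairs within 2.5 Å, paired greedily
nearest-first so each cysteine bonds at most once. 2.5 Å is a typical bond
length (2.05 Å) plus refinement slack; it is a parameter of
`detect_disulfides()`.

**Ligands** are counted as non-water het residues. Waters (HOH/DOD/...)
never count. The default reading is strict — any het residue fails — but
`ligand_census(ignore = ...)` accepts a list of tolerated cryo/buffer
additives, since glycerol or sulfate from the cryo solution arguably says
nothing about the domain itself.

**Termini proximity** uses the first and last *resolved* polymer residues
with a Cα. When a terminal residue lacks one, the computation walks inward
and flags `termini_resolved = FALSE` instead of guessing unmodeled
coordinates: a tag candidate whose true termini are disordered should be
inspected, not silently trusted.

### Soft ranking

The published screen also "considered" B-factors, surface charge and
related factors without giving a formula. `rank_candidates()` therefore
uses an explicitly heuristic score over the chains that pass the hard
screen: each badness term — mean polymer B-factor, |net exposed charge|
per residue, globularity — is min–max normalized over the batch and the
score is the weighted sum of `1 − badness` with equal thirds by default.
The weights are parameters; ties break lexicographically by entry id so
reports are reproducible. The score orders candidates within one batch and
has no meaning across batches.

Surface charge counts Arg/Lys/His minus Asp/Glu among residues whose
relative solvent accessibility is at least 0.25, computed against a fixed
table of published per-residue maxima. The same 0.25 exposure threshold
drives `ser_candidates()`, which lists exposed Lys/Glu/Gln grouped into
sequence clusters (gaps ≤ 2 positions) with the conventional
surface-entropy-reduction substitutions (Lys→Ala/Ser, Glu→Ala, Gln→Ala) —
clustered flexible surface residues are the classic SER targets for
engineering crystal contacts.

## Solvent-accessible surface area

SASA uses Shrake–Rupley point sampling: each atom is expanded by the probe
radius (1.4 Å, water) and covered with a deterministic Fibonacci-spiral
point set; points inside any neighbouring expanded sphere are buried, and
the exposed fraction scales the analytic sphere area. Defaults: 960 points
per atom, a van der Waals radius table by element with a 1.8 Å fallback.
At 960 points the total area of test structures is stable to under 1%
against doubling the point count, and an isolated atom reproduces
`4π(r + 1.4)²` to well under 2%. The quadrature is deterministic, so all
SASA-derived quantities are bit-reproducible.

Buried surface area of a complex is the two-sided total
`BSA = SASA(A) + SASA(B) − SASA(A∪B)`; the per-side value (half of it) is
reported alongside, because both conventions circulate in the interface
literature and published numbers are frequently ambiguous between them.

## Interface census

Hydrogen bonds are geometric: a donor atom in one partition within 3.5 Å
of an acceptor atom in the other, with donor/acceptor typing from
per-residue templates (backbone N donates, backbone O accepts; side-chain
N/O/S per residue type; His ring nitrogens and hydroxyls act as both).
When explicit hydrogens are present the donor–H–acceptor angle must exceed
120°; crystal structures usually lack hydrogens, and the criterion then
degrades gracefully to distance-only — the appropriate behaviour for X-ray
models. Salt bridges are unique residue pairs with a basic side-chain
nitrogen (Arg NE/NH1/NH2, Lys NZ, His ND1/NE2) within 4.0 Å of an acidic
side-chain oxygen (Asp OD1/OD2, Glu OE1/OE2); like-charge proximities never
count. These are deliberately simple, fully disclosed criteria — published
interface servers use proprietary variants, so exact counts from other
tools should be compared with the cutoffs in mind, not expected to match
to the unit.

## Superposition and identity

`kabsch()` computes the closed-form least-squares rotation via SVD of the
cross-covariance matrix, with the determinant correction that forbids
reflections; degenerate (collinear) point sets are rejected rather than
silently resolved. `structure_superpose()` matches residues by global
sequence alignment, takes Cα coordinates (or all shared heavy atoms), and
iterates: fit, compute per-pair deviations, discard pairs beyond
`2 SD` of the deviation distribution (never below a 3.5 Å floor), refit,
until a fixed point or 10 rounds. The result reports pairs used out of
pairs total, mirroring how outlier-rejected RMSDs are customarily quoted
("x Å over n of m atoms"). Both the SD multiplier and the floor are
parameters; `outlier_sd = Inf` disables rejection.

Sequence identity is convention-sensitive enough that full-length identity
figures between paralogs can move by several points depending on the
denominator. `sequence_align()` uses global Needleman–Wunsch with affine
gaps (BLOSUM62, open 10, extend 0.5) and defines identity as identical
pairs over aligned non-gap pairs; the parameters are echoed in the result
so reported figures are self-describing. Alignment is computed in a
canonical argument order internally, which makes identity exactly
symmetric even when equally scoring alignments exist.

## Construct assembly

`build_fusion()` concatenates target-N, optional linker, tag (with its
point mutations applied), optional linker, target-C, each segment carrying
its source name and author-numbered range. Length conservation and
segment-concatenation identity are asserted on every build. Two
bookkeeping rules deserve comment:

* **Author numbering is mandatory.** Mutations are written against
  isoform numbering (e.g. `K94A` in a tag trimmed to residues 3–123), so
  `apply_point_mutations()` validates the wild-type letter at the
  author-numbered position and fails loudly on mismatch — the cheapest
  possible guard against off-by-one numbering bugs that would otherwise
  surface only after gene synthesis.
* **Removed-segment length is reported exclusively.** Replacing the
  segment between anchors 489 and 778 removes residues 490–777, i.e. 288
  residues; the construct notes state this exclusive count. (Counts quoted
  elsewhere sometimes include an anchor.)

The geometric pre-check `compatibility()` passes a tag when
`|d_anchor − d_tag| ≤ 4.0 + 3.5 · L` Å, with `L` the total linker residue
count. The 3.5 Å per-residue reach models a near-extended backbone; the
4.0 Å base tolerance absorbs side-chain and backbone relaxation at the
junctions. Neither constant is derived from data — they are stated design
parameters of a feasibility heuristic, not a structural prediction.

Because the real target and tag sequences are not bundled, the package
ships deterministic *synthetic* stand-ins (`synthetic_usp_target()`,
`synthetic_rd_tag()`) that preserve the author numbering, anchor positions
and mutation sites of the motivating design (a 643-residue two-subdomain
core numbered 295–937 with anchors 489/778; a 121-residue tag numbered
3–123 with Lys at 94 and 96). All residue-count arithmetic is therefore
real; the letters between the pinned positions are not. Human ubiquitin
1–76 is included verbatim, and `c_terminal_extension()` builds the
tail-modified substrate variants (e.g. the 79-residue triple-glycine
linear mimic of an isopeptide-linked ubiquitin).

## The synthetic-structure generator

Fixtures are Cα traces plus whatever functional atoms a test plants (SG
for disulfides, charged-group atoms, het ligands). Three generators cover
the geometric regimes:

* `make_ideal_helix()` — canonical α-helix (1.5 Å rise, 100°/residue):
  the extended control.
* `make_compact_bundle()` — a toroidal solenoid with an integer winding
  number, scaled so the chain is globular (ratio ≈ 0.7–0.9) and stopped
  one arc gap short of closure; the final Cα is then placed *exactly* the
  requested distance from the first. This emulates the defining tag
  geometry: compact fold, termini a few Å apart.
* `make_hairpin()` — two long antiparallel strands with adjacent termini:
  fails globularity while passing termini proximity, isolating criterion
  (vi).

`make_screen_library()` composes these into libraries where each chain
passes everything or violates exactly one criterion (oversized chain,
planted disulfide, het ligand, degraded resolution record, 14 Å termini,
hairpin), and writes the planted truth to a manifest that tests treat as
the oracle. All randomness flows from explicit seed arguments through a
scoped RNG (the caller's `.Random.seed` is restored), and equal seeds
reproduce byte-identical PDB files.

What the fixtures deliberately do **not** emulate: real side-chain
packing, hydrogen positions, physically plausible Ramachandran geometry,
crystallographic disorder beyond what a test plants. Consequently, passing
tests demonstrate that the *operators* are correct — detectors equal
brute-force enumeration, quadratures match closed forms, verdicts match
planted truth — not that default thresholds are optimal for real archive
entries. On real structures the same functions apply unchanged; analyses
of specific archive entries require the user to supply the downloaded
files, since the package performs no network access.

## Numerical choices and degenerate inputs

* In-memory models carry full double precision; PDB serialization rounds
  to the format's 3-decimal grid, so file round-trips are exact to 1e-3 Å
  (planted quantities are exact to 1e-6 in memory).
* Altloc resolution keeps the highest-occupancy location, ties broken by
  altloc character order; only the first model of multi-model files is
  kept (crystallographic use case).
* When refinement and REMARK 2 resolutions disagree, the refinement value
  wins (it reflects the data actually used); REMARK 2 is the fallback.
* `kabsch()` errors below 3 pairs or on collinear sets; superposition
  outlier rejection never drops below 3 pairs.
* Screening monotonicity holds by construction: relaxing any threshold
  can only turn failures into passes.

Test problem sizes — 100-seed property suites for each detector,
121-residue bundles, 500 random construct builds, 960-point quadratures —
were chosen so the whole suite exercises every code path in well under a
minute of CPU while keeping Monte-Carlo assertions statistically
comfortable.

## Limitations

* No electrostatics (Poisson–Boltzmann) and no thermodynamic interface
  scores; the census is geometric.
* No secondary-structure assignment, assembly generation or
  crystallographic data handling; inputs are final coordinate models.
* The soft ranking is a labelled heuristic, not a crystallizability
  predictor.
* Literature metadata the original screen inspected by eye
  (crystallization concentration, space-group history) enter only as
  optional user annotations; they are not computable from coordinates.
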