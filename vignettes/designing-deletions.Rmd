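---
title: "Designing seamless CRISPR/Cas9 deletions: models, parameters and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Designing seamless CRISPR/Cas9 deletions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(crisprko)
```

This vignette is the package's own account of what it computes, which knobs
matter, and where design choices were genuinely open. It states no empirical
result that the test suite does not itself compute.

## The editing model

S. pyogenes Cas9 binds a 20-nt spacer-matching protospacer that must be
followed, on the same strand, by a 5'-NGG-3' PAM. It cuts bluntly 3 bp
upstream of the PAM — between spacer positions 17 and 18 counted from the
spacer's 5' end. A cell given a repair template spanning the break repairs it
by homologous recombination; if the template is the fusion of the sequences
flanking a target region, repair deletes the region without leaving a marker
or scar. Cells that fail to repair die, which is the selection.

The design problem is therefore threefold: find spacers that direct Cas9 into
the target region and nowhere else; synthesise the repair template; and
verify the junction afterwards by PCR.

## sgRNA uniqueness and the similarity profile

All PAM-adjacent 20-nt spacers on both strands are collected into an index
(`scan_pams()` + `build_index()`). Two deliberate semantics follow the way
the index is built:

- **Uniqueness is relative to PAM-adjacent spacers**, not all genomic
  20-mers. A 20-mer that recurs without an adjacent NGG cannot recruit Cas9
  and does not disqualify a spacer.
- **Counts include the queried spacer's own occurrence.** "Unique in the
  genome" is `count(k = 20) == 1`. This makes the uniqueness filter and the
  displayed profile one data structure. Whether the original web tool
  displayed self-inclusive counts is not documented; this convention is
  declared, not inferred, and is asserted throughout the tests.

The similarity profile counts, for each PAM-proximal suffix length
k = 20, 18, …, 8, how many indexed spacers share that suffix. Counts are
necessarily non-decreasing as k shrinks (a 12-nt match implies a 10-nt
match), which the property tests verify. Mismatches in the 12-nt PAM-proximal
*seed* suppress Cas9 activity most strongly, so `seed_unique`
(`count(k = 12) == 1`) is the single most informative flag; the full tuple
gives a graded picture for manual choice.

**Ranking.** Candidates are ordered by ascending lexicographic comparison of
(k20, k18, k16, k14, k12, k10, k8), ties broken by ascending position, then
'+' strand first. The comparison order the original tool used internally is
not published; lexicographic-from-k20 was chosen because a long shared suffix
is more dangerous than many short ones, and it yields a total, input-order-
independent order (verified by permutation tests). Two guides per deletion
are recommended — an off-target mutation is unlikely to recur across
independent guides — so reports default to the top 2 and a warning is logged
when fewer exist; this is guidance, never enforcement.

**Containment.** By default both spacer and PAM must lie inside the target
region, since PAM sites are sought "within the input coordinates"; a relaxed
mode (PAM inside, spacer may overhang) exists behind a flag because for
deletion work the overhang case is biologically harmless.

## Coordinates and the cut site

Coordinates are 1-based inclusive on the plus strand everywhere; 0-based
offsets exist only at array access. The stored `cut_position` is the
plus-strand coordinate of spacer base 17 counted from the spacer's own
5' end — for a '+' site with PAM at p..p+2 that is p−4; for a '−' site,
p+6. (For '−' sites this is the base immediately 5' of the cut *on the
site's own strand*; representing the blunt cut by one integer forces a
convention, and this one keeps the "17th spacer base" meaning on both
strands.) The mutable window is the 10 PAM-proximal spacer bases — the
permissive reading of the "8–10 nt upstream of the PAM" rule for where point
mutations can both take effect and block re-cutting — and is labelled as
such in output.

## HR template and its primers

The template is `flank` nt upstream + `flank` nt downstream of the region
(defaults 80 + 80 = 160 nt). The two synthesis primers are the template's
first 100 nt and the reverse complement of its last 100 nt, so with the
defaults they overlap by 2×100 − 160 = 40 nt and the template is produced by
primer extension alone, without genomic DNA. The protocol note that ~20 nt
of overlap suffices sits oddly beside the 100/100/160 arithmetic, which
fixes 40; the package treats 20 as a minimum bound (designs with computed
overlap < 20 are rejected) and always reports the actual overlap rather than
asserting either constant.

## Cloning primers and assembly checking

The spacer is cloned by amplifying the whole plasmid outward from the
insertion point p (between the sgRNA leader and the scaffold), with the
spacer on primer 5' tails:

- *ligation*: forward = spacer + 20 nt of scaffold-side anneal; reverse =
  reverse complement of 20 nt of leader-side anneal. Blunt product,
  phosphorylated and ligated.
- *ligation-free*: both primers additionally carry the spacer (reverse
  primer in opposite orientation), so the linear product ends in a 20-nt
  direct repeat and the bacterium recircularises it.

The published description ("via the 5' ends of the primers", plural) is
ambiguous about splitting the spacer across both ligation-method primers;
the full spacer is placed on the forward primer because the assembled
plasmid is identical either way. `check_assembly()` does not take this on
faith: it locates both primers' 3' anneal ends on the circular template,
simulates the inverse PCR product including tails, performs the
method-appropriate recircularisation, and compares the result —
rotation-invariantly — against leader + spacer + scaffold. Anneal windows
crossing the circular origin wrap around. The real expression plasmid's
sequence is not shipped; the built-in default is a labelled synthetic
stand-in and real use requires the user's plasmid file plus insertion point.
A spacer that already occurs in the plasmid triggers a mispriming warning.
The spec'd lower bound of 15 nt annealing is enforced as a warning rather
than an error because the reference worked examples themselves use shorter
toy windows.

## Melting temperature and checking-primer selection

Tm uses the unified SantaLucia/Allawi nearest-neighbor tables with duplex
initiation penalties, the entropic salt correction 0.368·(N−1)·ln[Na+], and
Tm = 1000·ΔH / (ΔS + R·ln(C_T/4)) − 273.15, at the Primer3 default
conditions (50 mM monovalent cation, C_T = 50 nM). Reference values were
computed with an independent implementation of the same tables *before* this
one was written and are frozen in the tests (e.g. the M13F sequencing primer
at 51.14 °C under these conditions). Tm is strand-symmetric, so candidate
windows are evaluated on the top strand via cumulative range sums — an exact
fast path asserted against the scalar model in the tests.

Checking primers frame the simulated junction (250 + 250 nt by default; the
junction sequence itself is reported for Sanger verification). Candidates of
length 18–25 must satisfy Tm 57–63 °C and GC 20–80 %; the chosen pair
minimises |Tm_fw − 60| + |Tm_rv − 60| + |Tm_fw − Tm_rv| subject to a pair
difference ≤ 3 °C. The "pair penalty" term was not specified; the pair Tm
difference was chosen because it is the dominant pair term in Primer3's own
default weighting. Ties go to the leftmost forward, then the rightmost
reverse primer, making selection deterministic. For speed, pairing considers
the 150 lowest-penalty candidates per side and falls back to the full cross
product if that subset has no feasible pair — the fallback makes the pruning
behaviour-preserving in the only case it could matter. Product sizes follow
by construction: wild-type = deletion product + deleted length, an identity
the tests check on 100 random fixtures.

Failure is a real outcome: a strongly AT-rich flank can contain no window
reaching Tm 57 under this model, and the error names the failing side and
the tightest violated constraint. This is why the shipped demo genome and
the primer-design test fixtures use a GC-balanced (0.5) background, while
the generator's default background GC is 0.36 (fission-yeast-like): the
fixtures for primer feasibility emulate flanks in which Primer3-default
constraints are satisfiable, and the infeasible case is tested separately as
an error path.

## The synthetic world and what green tests establish

`synth_genome()` draws i.i.d. background bases at a configurable GC fraction
(default 0.36), splices in optional N runs, and plants spacer+PAM elements
at exact coordinates, re-drawing the background until no planted 20-mer
occurs anywhere (either strand) except where planted — so truth tables are
exact, at O(genome × planted) re-scan cost per draw. Planted items are one
row per placement; planting the same spacer twice is how a deliberately
non-unique spacer is expressed. The generator emulates only what the
pipeline reads: base composition, PAM density, spacer uniqueness. It does
not emulate chromatin accessibility, repeat structure, or real gene
annotation, so a green suite establishes algorithmic correctness of the
design rules — not wet-lab success rates, which in the published experience
vary widely between loci and guides.

Independent oracles back the main path: a window-by-window PAM scanner and
an `endsWith()`-based profile counter that share no code with the indexed
implementation; the suite requires exact agreement on dozens of seeded
genomes up to 10 kb. All randomness is seed-parameterised; the design
pipeline itself contains none, and byte-identical reports across repeated
runs are asserted.

## Degenerate inputs and edge behaviour

- Spacers or PAMs containing N, and spacers running off a chromosome end,
  are silently skipped (counted in a log summary) — they are not designable.
- Soft-masked (lowercase) FASTA is uppercased; masking carries no meaning
  here.
- `start > end` is swapped with a warning; a region shorter than 23 nt
  yields an empty candidate list with a warning, not an error.
- An empty candidate list is legal; every error family maps to a distinct
  CLI exit code with a single-line machine-parsable message.
- Index caches embed a genome checksum and are refused (and rebuilt by the
  CLI) when stale.

## Known limitations

Exact-suffix counting is not an off-target *score*: no Hamming/bulge search,
no MIT/CFD weighting, no accounting for NAG PAMs. Gene lookup uses the union
CDS span across transcripts (deletion work targets whole loci, and gene
strand never reorders plus-strand coordinates); per-transcript targeting and
UTR/intron helpers are out of scope, as are IUPAC ambiguity codes beyond N
and any web front end.
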