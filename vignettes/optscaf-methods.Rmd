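---
title: "Methods: optical-map-guided assembly improvement in optscaf"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: optical-map-guided assembly improvement in optscaf}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

This vignette is the package's account of its models and of the design
choices that were genuinely open: what is assumed, what each tunable
parameter means, what the simulator does and does not emulate, and the
numerical conventions that keep results deterministic.

## The problem

A whole-genome-shotgun assembly of a large repeat-rich genome arrives
as scaffolds that may be chimeric (joining segments of different loci
through a gap), misplaced, or wrongly oriented.  An optical map — label
positions along long DNA molecules, assembled into consensus contigs —
is constructed independently of the sequence assembly, so discrepancies
between the two localize assembly errors, and concordant alignments
order, orient and connect scaffolds with physically measured gap sizes.
`optscaf` implements the complete loop: digest, align, arbitrate, split,
super-scaffold, anchor.

## Coordinates and containers

Sequences travel as tibbles (`seq_id`, `seq`, `length_bp`; `seq` may be
`NA` for lengths-only accounting).  Label maps are long tibbles in CMAP
convention: 1-based bp positions, strictly increasing, within
`[1, length_bp]`.  All internal intervals (N runs) are 0-based
half-open; the only 1-based formats are CMAP and AGP, and the
conversion happens in one place.  A label's position is the 1-based
start of the motif match on the forward strand; mirroring a map for
reverse-orientation alignment therefore uses the match-aware map
`p -> length - p - footprint + 2` (`label_footprint_bp`, default the
6-bp motif length), which makes flipped coordinates exact rather than
off by one motif length.

## In-silico digestion

`digest_sequences()` reports every motif occurrence on either strand
once (palindromic motifs collapse naturally), refuses to call labels
over unknown bases (N never matches), and merges label clusters closer
than `min_label_distance_bp` to their rounded midpoint.  The default
merge distance of 1000 bp models the imaging resolution limit; the
value is not published for the vendor software and is exposed as
configuration.  Merging has one important consequence discussed under
*Study conditions* below.  The shipped enzyme presets are DLE-1
(`CTTAAG`, direct chemistry) and Nt.BspQI (`GCTCTTC`, nick chemistry,
fragile pairs within 1000 bp); both are overridable, keeping motif
knowledge out of the algorithms.

## The label-map aligner

`align_maps()` runs a banded local dynamic programme over label pairs.
A chain step from pair $(i',j')$ to $(i,j)$ inside the band
(`max_lookback` = 5 labels per side) costs

$$ -\frac{(\Delta q - \Delta r)^2}{2\,c^2\,\Delta r}
   \;-\; p_\mathrm{miss}(l-1) \;-\; p_\mathrm{false}(k-1), $$

with a `match_bonus` (default 3) per pair.  The sizing model takes the
measured length of a true interval $d$ to be Gaussian with sd
$c\sqrt{d}$; the default $c = 1\,\mathrm{bp}^{1/2}$ corresponds to about
300 bp of sizing noise on a 90-kb interval, a plausible optical error
magnitude.  Penalties (`miss_penalty`, `false_penalty`, both 2) charge
unaligned labels inside the span; overhangs outside the span are free
(local alignment).

Two additions matter in practice:

* **Jump steps.**  A single-sided flat-cost transition
  (`jump_penalty` = 10, up to `max_jump` = 50 labels) lets one
  alignment bridge a long discordant stretch — for example a
  repeat-array copy-number disagreement, where the map carries an extra
  ~100-kb block of labels the scaffold lacks.  Without jumps the
  5-label band could never skip the five-plus consecutive labels that
  the internal-discordance detector looks for, and such events would
  surface only as truncated chains.
* **Minimum evidence.**  Retained alignments need `min_pairs` = 5
  aligned labels.  Five labels per side is also the minimum flank the
  chimera-detection completeness property assumes, so the two
  thresholds are deliberately the same number.

Secondary alignments are extracted greedily: report the best chain,
mask its query labels, repeat while chains clear the confidence
threshold.  Greedy masking (rather than full suboptimal traceback) is
sufficient for split-alignment detection and far easier to verify.

### Confidence

Confidence is `max(0, (score - null_mean) / ln 10)` with
`null_mean = n_pairs * null_per_step`.  The per-step null is the
expected best step cost of a random placement.  The naive estimate —
the expected no-skip sizing mismatch of independent uniform intervals,
$\mu_r/(3c^2)$ — is a poor null: it is orders of magnitude above the
skip penalties, so the DP adversary never pays it; among the lookback
candidates the cheapest step of a random placement typically costs
about one label-skip penalty instead.  The package therefore uses
`null_per_step = -(miss_penalty + false_penalty)/2` (default −2).  With
the default scores, one well-matched label then contributes roughly one
confidence unit, so the retention ladder 10 / 11 / 15 (initial
alignment, confirmation, second-round merging — the log10 analogues of
P < 1e-10 / 1e-11 / 1e-15) demands on the order of 10 / 11 / 15
well-matched labels, which is how such cutoffs behave in practice.  The
null excludes the match bonus, so confidence strictly increases with
`match_bonus` and with chain length, and chance 5-pair chains (which
arise surprisingly often in a 100-map all-vs-all comparison) fall below
threshold unless their intervals agree almost perfectly.

## Conflict detection and arbitration

Two signals, with tolerances chosen comfortably above the default
sizing noise (none of them is published; all are configurable via
`conflict_tol()`):

* **Split alignment** — one scaffold with two retained alignments whose
  scaffold spans do not overlap by more than `junction_bp` (50 kb) and
  whose placements are incompatible: different contigs, different
  orientations, or a map-vs-scaffold distance mismatch above
  `distance_bp` (100 kb).  The span condition is an overlap *tolerance*,
  not a required separation: a zero-noise chimera's two spans are
  separated only by the junction gap and sub-interval tails, so
  requiring 50 kb of separation would miss every clean chimera; the
  tolerance instead guards against calling one noisily-duplicated locus
  a split.
* **Internal discordance** — inside one alignment, a run of at least
  `min_unaligned` = 5 consecutive unaligned labels on one side spanning
  more than `span_bp` (100 kb), the copy-number-disagreement signature.

The breakpoint interval is the scaffold interval between the flanking
aligned labels exclusive to each side.  A chain occasionally
appropriates a few stray labels just past a true junction (their
intervals happen to match the continuing contig), so a breakpoint is
localized only to a few label intervals; every consumer of the interval
honors that precision — conflicts carry an extended bracket reaching
`min_unaligned` aligned labels outward, agreement between the two maps
is judged on the extended brackets, and the split planner falls back to
the extended bracket when the strict interval holds no N run.
Arbitration asks the second, chemically independent map: a conflict is a `sequence_error` if the second map also conflicts
over an overlapping interval, a `map_error` if one second-map alignment
crosses the whole interval with at least `min_confirm` = 5 aligned
labels on each side, and `unresolved` otherwise.  Map errors are
reported, never acted on.

Cuts go only where Ns already are: the midpoint of the N run nearest
the conflict-interval center (ties toward the lower coordinate);
overlapping conflict intervals merge before planning so one event never
yields two cuts; a conflict without an N run stays unresolved rather
than forcing a blind cut.  Splitting apportions the N run to the piece
ends, conserves every non-N base, and grows the ledger by exactly one
record per cut.

## Gap estimation and super-scaffolding

A scaffold is placed at its best alignment if every runner-up on a
different locus trails by more than `margin` = 3 confidence units, and
placements on one map may overlap by at most `overlap_tol` = 20 kb
(the lower-confidence overlapper is demoted).  The gap between adjacent
placements is the map distance between the facing aligned labels minus
the unaligned sequence tail and head beyond them, floored at
`min_gap` = 13 bp; gaps of unknown size are written as AGP `U 100`
rows (the 100-N convention of older assemblies), estimated gaps as `N`
rows with their length, so both styles are expressible in one format.
The vendor's per-gap estimator is unpublished; this one is defined
above and validated on simulations only.

The second round re-digests the emitted super-scaffolds (gap Ns carry
no labels), aligns them to the second map at the merge rung of the
confidence ladder, and merges super-scaffolds linked by concordant
placements.  New conflicts are detected and arbitrated, but confirmed
offenders are excluded from merging rather than cut inside the round:
this preserves the invariant that super-scaffold N50 never decreases
through rounds, and leaves actual cutting to an explicit re-run of the
resolve step with the maps' roles swapped.

## Anchoring

A super-scaffold is assigned to the chromosome with the (unique)
plurality of its markers, provided that chromosome supplies at least
two markers — the two-or-more-SNP rule; ties go unassigned and
minority markers are logged as discordant.  Order along the chromosome
is by mean cM of the concordant markers (ties: longer first, then
lexicographic id — the published procedure does not say how equal-cM
scaffolds were ordered, so determinism decided).  Orientation is the
sign of the Spearman correlation between marker cM and bp position,
computed only when two distinct cM values exist; degenerate cases
(plateau markers) are recorded as `+` with an explicit
`orientation_determined = FALSE` flag, mirroring an ambiguity the
procedure cannot avoid.  Anchored members are joined with 1000 Ns
(AGP `U` rows, linkage evidence `map`); with $S$ anchored scaffolds on
$C$ chromosomes the unknown-length joins total $S - C$.  ChrUn is never
concatenated — unplaced scaffolds stay separate records.  Multiple
linkage maps merge by marker union, dropping markers that claim two
chromosomes.

Assembly comparison classifies each scaffold as rescued (previously
unplaced), relocated, reoriented or unchanged.  "Same location" is
judged by membership in the longest increasing subsequence of the
old-versus-new order mapping per chromosome, so a scaffold that merely
lost a moved neighbour is not itself flagged — a plain
neighbour-identity test would cascade one relocation into three.

## The simulator

`simulate_dataset()` generates the complete study:

* **Genome** — i.i.d. uniform bases, optional planted tandem arrays
  (identical unit copies, placed uniformly without overlap).  The motif
  occurrence count is then tuned to the configured `label_density`
  (default 15 labels/100 kb) by mutating surplus occurrences or
  planting extra motifs outside the arrays; without this, density would
  be an accident of motif length rather than a controlled condition.
* **Scaffolds** — Poisson breakpoints (default 3/Mb); at each break a
  gap segment of 500–20,000 bp is dropped (unsequenced) and recorded as
  the true inter-scaffold gap; internal N runs of 100–5,000 bp
  *replace* equal-length sequence at 1 per 500 kb, as real sized gaps
  do, keeping scaffold coordinates congruent with the chromosome; each
  scaffold flips with probability 0.5.  Fragments under
  `min_scaffold_bp` (100 kb, roughly 15 labels) are not emitted:
  sub-resolution slivers are unplaceable by any label-based method, and
  the simulator models the alignable fraction of an assembly (in a
  10-Gb wheat assembly only a few thousand of 150,000 scaffolds are).
* **Errors** — chimeras join scaffolds from different chromosomes
  through a 100-N spacer, so a break-at-N fix exists; a corrupted "old"
  layout (misplacements, misorientations, ChrUn demotions) supports
  testing the comparison ledger, including the rescued class.
* **Optical maps** — true labels from the digestion of each chromosome;
  per-label Bernoulli misses (default 8%), Poisson false labels
  (0.8/100 kb), Gaussian interval sizing noise (sd $c\sqrt{d}$,
  $c = 1$); under the nick chemistry each fragile pair breaks the
  contig with `fragile_break_prob` (0.5), reproducing the fragmentation
  that makes nick-labeled maps an order of magnitude less contiguous
  than direct-labeled maps of the same genome; contigs under
  `min_molecule_kb` (150 kb) are dropped.
* **Genetic map** — Poisson markers; cM is a piecewise-linear monotone
  transform of bp with random plateaus, so single-cM scaffolds (the
  undetermined-orientation case) arise naturally.

Every stage draws from its own sub-seed derived from the master seed,
so adding a stage never perturbs earlier streams and all outputs are
byte-identical under one seed.

What the simulator does **not** emulate: raw molecules (stretch,
per-molecule noise, coverage), diploid haplotypes, chimeric map contigs
(map assembly errors are constructed in the tests by duplicating label
blocks), sequencing error in the scaffolds, and the sub-resolution
scaffold fraction.  Passing tests therefore demonstrate correctness of
the algorithms under the declared observation model, not performance on
any particular real dataset.

## Study conditions and problem sizes

The desk-scale preset is 4 chromosomes × 12.5 Mb (50 Mb), ~120
scaffolds, 8 chimeras, label density 15/100 kb; the full zero-noise
pipeline on it runs in minutes on one CPU.  Module tests use 2-chromosome
genomes of 3–8 Mb.  Two deliberate study-condition choices involve the
label-merge distance:

* `zero_noise()` also sets the merge distance to zero ("perfect
  resolution").  With merging on, a label cluster truncated at a
  scaffold boundary merges to a different midpoint than on the intact
  chromosome — a systematic shift of up to half the merge radius that
  is a property of the resolution model, not of the estimator.  Exact
  zero-noise recovery of layout and gap sizes is only a meaningful
  claim with the resolution model off.
* The noisy gap-accuracy study (error within $3c\sqrt{\mathrm{span}}$
  for ≥ 95% of ~200 gaps) likewise runs with merging off, because that
  band is derived from the Gaussian sizing model alone; with merging on
  the extra displacement would have to be folded into the band.

After chimera splitting, the spacer Ns are apportioned to the piece
edges (the splitting contract conserves bases).  A piece's edge-N
overhang is fictitious sequence, so the ground-truth expectation for
the gap next to a split piece is the true gap minus that overhang; the
recovery scorer (`evaluate_recovery()`) accounts for this, and the
emitted super-scaffold still reconstructs the chromosome length
exactly because gap and overhang compensate.

## Numerical conventions

Deterministic tie-breaks throughout: equidistant N runs cut toward the
lower coordinate; equal-cM scaffolds order longer-first then by id;
equal-scoring DP orientations prefer `+`.  Merged-label positions round
to the nearest integer.  The DP is exact within its transition set
(verified against exhaustive enumeration on small instances); bands
bound runtime at $O(nm(k^2 + 2J))$ for lookback $k$ and jump range $J$.
Degenerate inputs return empty results rather than errors where the
condition is a signal (maps with fewer than two labels), and errors
with context where it is a contract violation (cuts outside the
sequence, non-monotone CMAPs, malformed files).

## Known limitations

The aligner's confidence is a calibrated score, not a P-value; its
absolute scale is meaningful only relative to the configured penalties.
Arbitration trusts the second map's independence; correlated errors
(e.g. a genuine genomic variant absent from both map and reference
expectations) would be mis-verdicted.  Gap estimates inherit the
resolution-merge bias described above (sub-500-bp for the default
radius).  The second round never cuts, so a chimera that only the
second map can see survives round 2 flagged but uncut until the
resolve stage is re-run with the maps swapped.  Orientation of
single-cM scaffolds is unknowable from the linkage map alone and is
reported as such rather than guessed.
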