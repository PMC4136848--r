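---
title: "serscan: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{serscan: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

serscan annotates cysteine-rich, GPI-anchored surface antigen gene
families — the *Ser* (serotype / immobilization antigen) family of
*Tetrahymena thermophila* being the motivating case — in proteomes where
sequence homology is useless because family members are too polymorphic.
This vignette documents the models each module implements, the
parameters that matter, the numerical choices, and what the synthetic
fixtures do and do not establish.

## 1. The cysteine-block motif scan

The scan grammar is `C X(>=f) C X(g..G) C ... C` over `n` cysteines,
where `X` is any residue except cysteine. Defaults encode the family's
published final criterion: `n = 6` cysteines, first inter-cysteine gap
of more than 5 residues (`min_first_gap = 6`), every other gap at least
1 residue (unbounded above), and a motif span (last cysteine − first
cysteine + 1) of at most 120 residues. The exploratory short-gap grammar
is available as `n_cys = 4`, `max_inner_gap = 5`, `window_min = 30`.

Because `X` excludes cysteine, every match is necessarily a run of `n`
*consecutive* cysteines of the sequence, so the scan reduces to testing
each consecutive-cysteine tuple against the gap and span constraints.
The test suite holds the implementation to an independently written
exhaustive tuple oracle on thousands of random sequences at 15% cysteine
content.

Interpretation choices (each a one-line change if a different reading is
wanted):

* "within 120 amino acid residues" is read as the inclusive motif span,
  not the sum of gaps;
* "more than 5" means at least 6 residues strictly between the first
  cysteine pair;
* all overlapping matches are reported; a protein is a *hit* if it has
  at least one.

The hit count is monotone: non-increasing in `min_first_gap`,
`min_inner_gap` and `window_min`, non-decreasing in `window_max` — a
property the tests assert, and the basis of `saturation_scan()` for
choosing a grammar by hit-count saturation.

## 2. The GPI anchor signal classifier

Trained GPI predictors (HMM-based web services) are not reproducible
offline, so serscan implements the signal anatomy itself as a
deterministic rule checklist, keeping the conventional class vocabulary.
For every candidate ω position whose distance to the C-terminus lies in
`omega_search_window` (default 11–34 residues, at least one residue of
mature protein upstream), four hard rules are evaluated:

| rule | default | meaning |
|------|---------|---------|
| ω residue ∈ `omega_residues` | {G, A, S, N, D, C} | transamidase accepts small residues at the attachment site |
| ≥ `min_polar_spacer` of the 6 spacer residues (ω+3..ω+8) polar | 4 | polar spacer region; "polar" = Kyte–Doolittle hydropathy < 0 |
| tail length (ω+9 to C-terminus) ≥ `min_tail_len` | 8 | minimum hydrophobic region for GPI attachment |
| mean tail hydropathy ≥ `min_tail_hydropathy` | 1.0 | hydrophobic tail, Kyte–Doolittle scale |

ω+1 and ω+2 are unconstrained, mirroring the anatomy's silence about
them. The small-residue set extends the three residues typically drawn
in family schematics (Ala, Gly, Ser) to the conventional
transamidase-compatible six; it is a parameter.

The best passing candidate is scored as the mean of three margins
clipped to [0, 1]: spacer polar fraction, tail hydropathy margin
(normalized by the scale maximum 4.5), and tail length margin
(reaching 1 at twice the minimum). Classes: `highly_probable` ≥ 0.5,
`probable` ≥ 0.25, else `weakly_probable`; `none` when no candidate
passes the hard rules. The 0.5/0.25 cut points are calibration choices
of this package, not published values; only the `highly_probable` class
feeds the candidate set, mirroring the published selection gate.
Published candidate *counts* are therefore not expected to be
reproduced, and no acceptance quantity depends on them.

A boundary note: the hard minimum evaluable length is
`min_tail_len + 11 = 19` residues; sequences shorter than that are
classed `none` without error. A 20-residue sequence *can* in principle
host a compliant anatomy (ω at position 1), so "too short" behaviour is
only guaranteed below 19.

## 3. Repeat-block decomposition

The family's subtype signature is the number of cysteines per repeat
block (6, 8 or 10) and the block length (55–100 aa). Published figures
draw the blocks but never define boundaries algorithmically, so the
decomposition is this package's convention:

1. Build the greedy left-to-right chain of non-overlapping motif
   anchors.
2. Treat each distinct chain spacing as a candidate period and score it
   by tiling consistency — the fraction of period-tiled block starts
   (from the first anchor) that coincide with an anchor within
   `tolerance` × period (default 0.25). Highest score wins; ties fall
   back to chain frequency, then the smallest value.
3. Walk blocks anchor-to-anchor: the next boundary is the anchor nearest
   to `current + period` within the tolerance window; when none exists a
   final block of exactly one period is emitted if it fits, and the
   tiling stops (trailing partial blocks are dropped, a leading offset
   stays outside block 1).
4. Count **all** cysteines inside each block interval, so an 8-cysteine
   subtype reports 8 even though the scan motif only requires 6.

The consistency score in step 2 exists because the naive rule — modal
chain spacing — is wrong even on perfectly periodic sequences: a valid
motif can start at the *last* cysteines of a block and reach across the
boundary (its long first gap is the intra-block filler), which injects
alternating short/long spacings into the chain and lets the mode pick
the offset instead of the period for 3-block proteins. On 200 random
planted specs the consistency rule recovers period, block count and
cysteine count exactly; the modal rule failed 14 of 60.

A decomposition needs at least `min_blocks = 2` consistent blocks;
otherwise it is empty (`n_blocks = 0`), which is also the answer for
proteins without motif matches. Decomposition is invariant to prepending
up to period−1 non-cysteine residues (anchors shift together).

## 4. Phylogeny and subtype assignment

**Alignment.** Classification needs clade structure, not a particular
aligner's output (the original analysis even adjusted its alignment
manually), so serscan bundles a plain progressive aligner: pairwise
global alignments (Biostrings, BLOSUM62, gap open 10 / extend 0.2) give
identity-based guide distances; profiles are merged along an NJ guide
tree with an affine-gap (Gotoh) profile–profile DP in C++ whose column
score is the frequency-weighted substitution score f₁ᵀ B f₂. Externally
computed alignments are accepted via `read_msa()`. Sequences longer than
5× the median are excluded with a warning — they cannot be aligned
meaningfully (the motivating case is a 3,751-residue outlier).

**Distances.** p-distance over shared ungapped columns, or the Poisson
correction −ln(1−p) capped at 10; a pair with no shared columns is an
error naming the pair.

**Neighbor joining** is re-implemented (Saitou–Nei Q criterion) rather
than delegated, because determinism is part of the contract: ties in Q
are broken by the lexicographically smallest pair of cluster labels, so
the topology is independent of input order. Negative branch lengths are
clamped to zero. Correctness is held to an oracle: on random additive
matrices from known trees (n ≤ 8), the Robinson–Foulds distance to the
generating topology must be 0 in 100/100 trials, and 3-taxon branch
lengths match the closed form.

**Bootstrap.** Alignment columns are resampled with replacement,
the NJ tree rebuilt, and each internal edge of the original tree
receives the percentage of replicates containing its bipartition.
Replicates are drawn from one seeded index matrix, so supports are
reproducible under a fixed seed and invariant to taxon input order.
The replicate-count default is 1000 (the published methods text);
tests and the acceptance script use 100 (the published figure caption —
the two disagree; both are supported, neither is resolved here).

**Subtype assignment.** The tree is midpoint rooted (the published
cladogram is displayed rooted without a stated rule). For each
candidate leaf, the smallest ancestral clade containing a reference is
located; ancestors are ascended while their references remain a single
subtype, and the subtype is assigned at the first edge with bootstrap
support ≥ `min_support` (default 40 — the weakest clade the original
analysis accepted was 42.2%). The ascent is a deliberate design choice:
requiring support on the *locally* smallest clade would reject
candidates sitting deep inside a well-supported subtype clade merely
because their local attachment is fuzzy, while the published support
values refer to the big subtype clades. If no supported pure edge
exists, the starred sister-group rule applies: when the candidate's
maximal reference-free clade is sister to a clade whose references are
one subtype and whose edge meets `min_support`, the starred subtype
(`H*`, `L*`, `J*`) is assigned with that sister support. Everything else
is `unclassified`. A starred call is never made below `min_support`.

## 5. Tandem arrays

Array detection works in gene rank, not base pairs: on each scaffold,
a tandem array is a maximal run of ≥ 2 candidate genes in which
consecutive candidates are separated by at most `max_intervening`
non-candidate genes (default 1 — published scaffold maps show single
interspersed non-family genes inside arrays). Rank adjacency is robust
to assembly gaps; both knobs are exposed. Detection is
subtype-agnostic; homogeneity (pure/mixed) and orientation consistency
are *reported* properties in `tandem_summary()`, matching the
observation that arrays tend to be same-subtype and same-strand rather
than enforcing it.

## 6. Expression clustering

Profiles are 20-condition log2 expression vectors (growth at three
densities, seven starvation and ten conjugation time points; the
condition labels are fixed and validated on input). The distance is
Pearson, d = 1 − r, so clustering sees shape, not level.

k-means under 1 − r needs care: with value-space mean centroids the
within-cluster distance is *not* guaranteed to decrease at the update
step, yet a non-increasing inertia is part of this package's contract.
serscan therefore iterates spherical k-means on row-standardized
profiles (centered, unit norm), where 1 − r is half the squared
Euclidean distance and the normalized mean direction is the exact
update-step minimizer — every half-step provably lowers the inertia,
and the tests assert the full trace of every restart. The *reported*
`centroids` remain value-space means of the member profiles, which is
what heat-map displays want. Seeding is k-means++ in Pearson-distance
space, with `restarts` (default 10) independent runs under one seed and
the best inertia returned; empty clusters are repaired by seizing the
globally worst-fit point and moving the centroid onto it (also
monotone). Constant profiles, for which r is undefined, are dropped
with a warning before clustering. `k` defaults to 30 (the published
cluster count for the family's expression data); desk-scale tests use
k ≤ 5. Because seeding is this package's choice, cluster numbering will
not match any published figure's ids.

`median_center()` is the display transform (row median subtraction,
idempotent); clustering always runs on raw log2 values.

## 7. Synthetic fixtures: what they emulate and what they don't

The generators emit the *stated world* of the family's anatomy:

* `generate_ser_protein()` — identical-period repeat blocks (length
  55–100, 3–8 blocks), per-block cysteine layout whose first six
  cysteines satisfy the grammar (first gap 6–10, inner gaps 1–3, extra
  cysteine pairs appended with short gaps), non-cysteine fill uniform
  over the other 19 residues, and a compliant 21-residue GPI signal
  (ω ∈ {G,A,S}, 6-residue polar spacer, 12-residue hydrophobic tail).
* decoys violate exactly one criterion: `decoy_no_gpi` keeps the repeat
  body and replaces the tail with acidic residues of equal length (only
  hydropathy changes — and provably fails the tail rule at every ω
  candidate); `decoy_no_pattern` puts a compliant signal on a
  cysteine-free body.
* `background` is random sequence at 2% cysteine (15% in scanner stress
  tests). A background draw that happens to satisfy *both* criteria
  would contradict its own truth label, so it is regenerated — this is
  label enforcement, not tuning; backgrounds that pass only the pattern
  screen are kept, preserving realistic funnel pressure.
* `generate_genome_layout()` plants same-subtype, same-strand arrays
  with configurable intervening-gene and antisense rates and guarantees
  disjoint loci; `generate_expression()` plants k unit-variance
  sinusoidal centroid shapes in anti-correlated pairs, amplitude 2 log2
  units, noise sd 0.5 by default.
* `synthetic_reference_set()` is an explicitly synthetic stand-in for
  the 13-sequence published reference panel (6 H, 1 J, 6 L), built from
  per-subtype centroid bodies with 10% mutation outside the cysteine
  skeleton and signal.

What a green test does **not** establish: real proteomes have biased
residue composition, imperfect repeat periods, degenerate or truncated
signals, and reference sets whose within/between-subtype divergences
are not controlled — so planted-recovery rates (recall 1.0, assignment
accuracy ≥ 95%, ARI ≥ 0.9) are statements about the stated world, not
predictions for a reanalysis of any particular genome. The published
headline counts additionally depend on a historical proteome release
and a trained GPI HMM that is not available, and are out of scope by
design.

## 8. Numerical and degenerate-input choices

* Coordinates are 0-based half-open internally; GFF3 is converted on
  ingest and restored on export. Readers fail loudly (format errors name
  the offending line or pair); nothing is silently dropped.
* Residues outside the 20-letter alphabet plus X are mapped to X with a
  warning; X never counts as cysteine and has hydropathy 0.
* All writers are deterministic: fixed column order, `\n` endings,
  full-precision `%.17g` numerics (expression round-trips are exact),
  no timestamps — pipeline reruns under a fixed config and seed are
  byte-identical, which the tests check by hashing.
* Every stochastic entry point takes an explicit seed and restores the
  caller's RNG state afterwards.
* The pipeline configuration file is JSON rather than YAML (no YAML
  parser in the supported dependency set); the structure is otherwise
  the same.

## Known limitations

* The GPI classifier is a rule-based approximation; its class boundaries
  (0.5/0.25) are internal calibration, and agreement with trained HMM
  predictors on real sequences has not been measured.
* The progressive aligner has no iterative refinement and is not meant
  to reproduce any specific aligner's output; for publication-grade
  trees, supply an external alignment via `read_msa()`.
* Repeat decomposition assumes one dominant period; proteins mixing two
  repeat families will report only the better-tiled one.
* Tandem-array detection needs complete gene annotations per scaffold;
  rank adjacency is meaningless on gene sets filtered upstream.
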