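---
title: "Screening candidate GRL proteins: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Screening candidate GRL proteins: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(grlscreen)
library(dplyr)
```

## The problem

Insect odorant and gustatory receptors (ORs/GRs) and their relatives — the
Gustatory Receptor-Like (GRL) proteins found across animals, and the plant
DUF3537 family — are seven-transmembrane (7-TM) ion channels with a topology
opposite to GPCRs: the N-terminus is intracellular. Searching for remote
homologs of this family in unicellular eukaryotes cannot rely on sequence
identity alone (family members can share as little as ~10% identity), so
candidates are screened on architectural grounds instead. `grlscreen`
implements that screen as a reusable, tested pipeline:

1. **Topology** — hydropathy-based TM segment calling and positive-inside
   orientation.
2. **Screen** — five retention criteria with a configurable "most or all"
   threshold.
3. **Motif** — scanning TM7 for the diagnostic motif
   (T/S)·Y·h·h·h·h·h·(Q/K/E)·(F/L/M), `h` hydrophobic.
4. **Profiles** — pseudocounted family profiles, profile–profile alignment,
   and an all-vs-all similarity matrix with clustering.
5. **Alignment / trees** — percent identity, progressive MSA, and
   neighbor-joining distance trees.
6. **Introns** — intron positions in protein coordinates, projected onto
   alignment columns to assess positional conservation.
7. **Structure** — Kabsch superposition, RMSD, and TM-score with
   fold-classification thresholds.
8. **Synthetic data** — seeded generators for every input class, with
   planted ground truth.

Database searching (PSI/DELTA-BLAST, HHblits over large clusterings), HMM
topology servers, maximum-likelihood inference, and ab initio structure
prediction are out of scope; the package consumes their *outputs* (hit
tables, coordinates) or provides desk-scale stand-ins (simple profiles,
neighbor joining).

## Topology prediction

The predictor is a classical single-sequence hydropathy method. Each residue
gets the mean Kyte–Doolittle value over a centred window (default 19, the
standard choice for membrane helices); positions within half a window of
either end carry the nearest full-window value; `X` contributes 0. TM
segments are maximal runs of windowed hydropathy at or above a threshold
(default 1.5), with runs separated by at most `merge_gap = 3` residues
merged, runs shorter than `min_len = 15` discarded, and runs longer than 30
trimmed symmetrically.

Orientation uses the positive-inside rule: loops (tails included) alternate
sides; for both candidate orientations the K+R count over "inside" loops is
summed and the larger sum wins, with ties assigned an intracellular
N-terminus — the configuration the screen is looking for, and the
biologically expected default for this family.

Two optional curation heuristics mirror the manual curation such predictors
need in practice. `drop_nterm_reentrant` removes the first segment when
eight are found and the first lies within the first 60 residues (membrane
re-entrant helices near the N-terminus are commonly mispredicted as TM
domains). `rescue_tm7` rescans C-terminal of segment six with the threshold
lowered by 0.5 when exactly six segments are found (the final helix often
scores just under threshold). Both are off by default, are recorded in the
output, and make no claim to reproduce any external predictor's posterior
probabilities.

**Numerical choice.** Whether a window sits at the call threshold is decided
after rounding the margin to 6 decimals. Windowed means computed in
different summation orders differ by ~1e-15, and without the rounding a
sequence and its reversal could disagree at exact-tie boundaries; with it,
segment calling is mirror-symmetric.

## The five retention criteria

For a candidate with a topology model and a (precomputed) homology hit
table:

* **c1 reciprocal** — among hits with E-value `< 0.05` and query coverage
  `> 50%` (strict inequalities), the minimum-E-value hit belongs to the
  GRL or DUF3537 family, or no qualifying hit belongs to another family.
  An empty hit table passes: no significant similarity to *other* families.
* **c2 length** — total length within ~350–500 aa; the "~" is an explicit
  `len_slack` (default 30) rather than a silent fudge.
* **c3 seven TM** — predicted segment count equals 7.
* **c4 N-in** — intracellular N-terminus.
* **c5 IL > EL** — summed intracellular loop length exceeds extracellular.

"Most or all" is operationalised as `min_criteria_passed = 4` of 5 by
default: published screens of this kind retained candidates that failed
single criteria (divergent motifs, subthreshold TM7), but no exact count is
ever stated, so the threshold is a parameter. Retention is monotone under
threshold relaxation and nested across `min_criteria_passed` levels — both
are property-tested.

## TM7 motif scanning

The motif is scored on 9-residue windows: four anchor positions (1, 2, 8, 9
= T/S, Y, Q/K/E, F/L/M) and a 5-residue hydrophobic run (positions 3–7).
`anchors_matched` counts anchors only; the hydrophobic run is reported
separately (`h_run_ok`: at least 4 of 5 in class `h`). The hydrophobic class
is the conventional set {A, C, F, I, L, M, V, W, Y} including aromatics —
the motif definition only says "hydrophobic" — and is configurable. The one
conservative substitution recognised by default is Y→F at position 2, the
substitution explicitly seen in some animal GRLs; counting it is controlled
by `count_conservative`.

The scan region is anchored to the *last* predicted TM segment — every
window whose start lies in [segment midpoint − 5, segment end + 10] — since
the motif sits in the C-terminal half of TM7 and the helix extends toward
the extracellular face; the +10 margin absorbs prediction jitter. Ties are
broken toward more hydrophobic-run matches, then the leftmost start. The
scanner is tested for exact equivalence with a brute-force oracle over
1,000 random sequences.

## Profiles and the similarity matrix

Family profiles are plain pseudocounted position-specific probability
tables: columns with more than 50% gaps are dropped, and each retained
column is `(counts + pc·bg) / (n + pc)` with `pc = 1` and uniform background
by default. No insert/delete states: the analysis-level object downstream is
the all-vs-all similarity matrix, which this reproduces structurally; it is
an analogue of, not a replica of, profile-HMM homology probabilities.

Profile pairs are aligned locally (Smith–Waterman, affine gaps, default
open 5 / extend 0.5 bits) over column co-emission scores
`log2 Σ_a p1[i,a]·p2[j,a]/bg[a]`. The raw score maps to [0, 1] through a
logistic in bits per effective aligned column:

* midpoint 1.5 bits/column, scale 0.35 — chosen so that self-alignment of a
  sharp family profile (~3.2 bits/column) exceeds 0.99 while dissimilar
  profiles fall near 0;
* the effective column count is floored at half the shorter profile length,
  so a short spurious local hit between unrelated profiles is diluted
  rather than scored as if it covered the proteins.

These constants are frozen; the two calibration contracts (self ≥ 0.99,
unrelated ≈ 0) and the planted-family separation property (within-family
mean above between-family mean over 20 seeded replicates) are tested.
Clustering of `1 − similarity` uses average linkage.

## Alignment, identity, and trees

Global pairwise alignment is Needleman–Wunsch with affine gaps under
BLOSUM62 (delegated to Biostrings; scores verified against exhaustive
enumeration on short strings). Percent identity is
`100 · identical / both-non-gap columns`. Distances are p-distances
(`1 − id/100`) by default with an optional Poisson correction — simple,
monotone, and sufficient for the clade-recovery properties asserted on
planted data. Trees are neighbor joining (exact on additive matrices,
property-tested on random additive trees of up to 8 taxa), with negative
branch estimates clamped to zero. The progressive MSA merges single-sequence
blocks up an average-linkage guide tree with a linear-gap profile–profile
Needleman–Wunsch; every input is recoverable by degapping. It is a
desk-scale stand-in, not a substitute for a production aligner, and no
claim is made about Fig-quality phylogenies: branch supports, ML inference
and rooting are out of scope.

## Structure comparison

Superposition is the closed-form Kabsch solution via SVD with
determinant-sign correction (no reflections). TM-score is

$$\mathrm{TM} = \frac{1}{L_{ref}} \sum_i \frac{1}{1 + (d_i/d_0)^2},
\qquad d_0 = \max(0.5,\; 1.24\,(L_{ref}-15)^{1/3} - 1.8)$$

maximised over the standard iterative subset refinement: superpose on all
corresponding pairs, re-superpose on pairs with `d < 2·d0` until the subset
is stable (cap 20 iterations), keep the best score seen. `L_ref` must be at
least 16. Classification follows the published bands: ≤ 0.30 random,
≥ 0.5 same fold, otherwise ambiguous. In pairwise matrices the TM-score of
(i, j) is normalised by structure i's length — the reference-length
convention — so both orientations are reported, while RMSD is symmetric.
Which normalisation an external tool used for any given published matrix is
not always stated; reporting both sides makes the choice explicit.

Model-intake filters (`filter_model_intake`) drop predicted models seeded by
alignments of fewer than 15 sequences or with estimated TM-score below 0.17,
the conventional cutoffs for unreliable ab initio models.

## Introns

For each junction between consecutive exons, the cumulative CDS length `c`
gives phase `c mod 3`; phase-0 introns are recorded at the boundary after
residue `c/3`, others inside residue `⌊c/3⌋+1`. Marks are projected onto
alignment columns (monotone in residue index) and grouped as shared when
phases are equal and columns lie within a tolerance (default 0 — the strict
reading; published discussions of "the same position" state no tolerance,
so the knob makes the criterion explicit). Internally all interval
arithmetic is 0-based half-open; everything user-facing is 1-based closed.

## The synthetic-data generator

Generators emit every input class with planted truth, and each one
*self-validates*: a generated "passes-all" protein is re-screened at
generation time and the construction is resampled (deterministically, via
bounded retries under per-attempt substreams) until the planted truth is
recovered exactly. A single integer seed drives per-item substreams so
adding one protein never shifts another; output is bitwise reproducible.

Key construction choices, all fixed a priori from the detection arithmetic
of the topology module rather than tuned to test outcomes:

* **TM length 21–28** (last TM 26–30 when the motif is planted). At window
  19 with charged loops, an above-threshold run has length ≈ `t − 6`, and
  the caller requires 15, so helices must be ≥ 21 residues to be
  recoverable at noise 0. Shorter helices exist in nature; they are simply
  not recoverable by a windowed single-sequence method, so the generator's
  study conditions exclude them.
* **Outside loops ≥ 9 residues**, inside 20–80. Loops of 5–8 residues
  between strong helices do not pull the windowed mean below threshold, so
  adjacent helices would fuse.
* **Positive-inside bias**: inside loops draw K/R at ~40% frequency;
  outside loops draw from a K/R-free polar pool, making orientation
  decisive at noise 0.
* **Motif planting**: the last TM and the first 18 tail residues avoid
  every residue that could form a stray anchor (no T/S/Y/F/L/M/Q/K/E
  outside the planted window; an intracellular C-tail gets its
  positive-inside charge from R only), so the planted anchor count 0–4 is
  the unique maximum over the scanned region and parameter recovery is
  exact. Broken anchors are written as I; the planted F/L/M anchor avoids F
  so no shifted window can pick up a conservative Y→F match.

Decoys violate exactly their named criteria (`short`, `long`, `six_tm`,
`n_out`, `el_gt_il`, and the opposite-topology `gpcr_like` failing both
orientation criteria) and are self-validated against the screen. Families
mutate an ancestor along star or two-clade topologies with
category-preserving substitutions (hydrophobic↔hydrophobic,
polar↔polar) and optional small indels, recording realised identities.
Coordinate bundles are ideal α-helices (1.5 Å rise, 100°/residue twist,
2.3 Å helical radius) on a ring, antiparallel by default, with per-atom
Gaussian noise.

**What the generator does not emulate:** real loop composition, sequence
correlations, lipid-exposed vs buried faces, helix kinks, signal peptides,
or realistic evolutionary processes. Passing tests therefore demonstrate
that the pipeline's logic is correct on data realising its assumptions —
not that the hydropathy predictor matches HMM-based predictors on real
proteins.

## Worked cohort

```{r cohort}
pos <- bind_rows(lapply(1:3, function(s) make_grl_like(seed = s)$record))
dec <- bind_rows(lapply(1:3, function(s) make_decoy("gpcr_like", seed = s)$record))
recs <- bind_rows(pos, dec)
topo <- predict_topology(recs)
res <- screen_collection(recs, topo, make_hit_table(recs$id))
glance(res)
motif_conservation_table(recs, topo)
```

## Problem sizes and reproducibility

The test suite and examples run on deliberately desk-scale problems: single
proteins of 350–500 aa, cohorts of up to 200 synthetic candidates, families
of 4–12 members, profiles of ~200–450 columns, trees of up to 8 taxa for
exactness properties, and 400-residue coordinate bundles. These sizes
exercise every code path while keeping a full run of the suite in minutes;
all randomness flows from explicit integer seeds.

## Known limitations

* The topology module is a single-sequence hydropathy caller; it has no
  posterior probabilities and the curation heuristics are stand-ins for
  manual inspection.
* Profile similarity values are calibrated quantities on an arbitrary but
  fixed logistic scale; they are comparable within a run, not across
  methods.
* The progressive MSA has no iterative refinement and the NJ tree no
  support values; both exist to make positional and clade-level statements
  on planted data.
* Structure comparison assumes a correspondence is supplied (from sequence
  alignment or residue indices); there is no structural alignment search.
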