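---
title: "Template-based mapping of cell-rearrangement motifs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Template-based mapping of cell-rearrangement motifs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(epimotifs)
```

## The problem

Converging–extending epithelia, such as the ventrolateral ectoderm of the
early *Drosophila* embryo during germband extension, remodel themselves
through recurring multicellular "motifs": T1 neighbour exchanges (a quartet
of cells in which one junction contracts to a four-way vertex and the
orthogonal junction grows), abortive or *reversing* T1s (the junction
contracts but recovers without an exchange), multicellular rosettes (five or
more cells converging onto a single vertex) and rosette *hubs* (persistent
core vertices at which members are iteratively exchanged).  Hand-crafted
if–then rules on the cell-adjacency graph detect these events poorly when
their temporal dynamics vary.  `epimotifs` instead treats motif detection as
a time-series subsequence-matching problem: one user-chosen example of the
motif becomes a *template*, and every tracked group of k connected cells in
the movie is scanned for a time-warped occurrence of that template.

## The matching model

A tracked k-cell group is summarised per frame by a feature vector:

* **quartets** (k = 4): the six pairwise minimal Euclidean distances between
  cell boundary polylines (zero for adjacent cells), giving a 6-dimensional
  series;
* **rosettes** (k = 5, 6): the maximal pairwise boundary distance, a
  1-dimensional series that hits zero exactly when all cells meet at one
  vertex.

The template `T = (t_1 … t_m)` is aligned to a candidate series
`C = (c_1 … c_n)` by dynamic time warping with step pattern
{(1,1), (1,0), (0,1)} and unit weights.  The alignment cost is the sum of
Euclidean distances between matched feature vectors, and the reported score
is normalised by the warping-path length, i.e. the *average* distance per
matched pair — without this normalisation shorter matches would be
spuriously favoured.  Subsequence search is open at both ends: entry is free
anywhere along the candidate axis and the score is read out along the final
template row, so the best window `C_i..j` falls out of one dynamic
programme.  Unbounded stretching is prevented by capping the number of times
any single time point may be matched (`max_repeat`, default 3; a slope bound
is accepted and translated into the equivalent cap).  Ties in the dynamic
programme prefer diagonal steps, then template advances, so paths are
reproducible.  Phase labels attached to template frames ("contracting",
"transition", "growing") are transferred to the matched candidate frames
through the warping path; when several template points map to one candidate
frame the earliest phase wins.

## Search space and pruning

Candidates are all connected induced k-subgraphs of the cell-adjacency
graph, enumerated by recursive extension with exclusive neighbourhoods and
tracked over time by their member sets (the only key that is stable across
frames).  Adjacency itself derives from shared junction chains; meeting at a
single tissue vertex does not qualify.  Before any feature is computed,
tracks are pruned by, in order:

1. **topology** — a quartet must visit one of the two T1-relevant topology
   classes: the diamond (K4 minus one edge, the before/after state) and the
   4-cycle (the four-way-vertex state).  Classes are canonical forms obtained
   by minimising the adjacency bit mask over all k! vertex permutations
   (k ≤ 6), which is exhaustive and dependency-free; there are exactly 6
   connected classes on 4 vertices and 2 on 3;
2. **in-group degree** — every rosette member needs at least two in-group
   neighbours;
3. **enclosure** — groups that fully wall in a non-member cell are invalid.
   We test this combinatorially on the whole-frame graph: the group encloses
   someone iff some connected component of the non-member cells contains no
   field-of-view boundary cell.  Counting interior faces of the induced
   subgraph alone cannot work here: a rosette and a ring-around-a-cell both
   induce a plain cycle, and only tissue-vertex information distinguishes
   them.  The complement-component rule is exact and is cross-checked in the
   tests against a geometric flood-fill oracle;
4. **persistence** — tracks lasting under 2.5 minutes are discarded
   (duration counted as frame slots × frame interval);
5. **neighbour exchange** — the in-group adjacency must change at least once.

Each rejected track is charged to the first rule it fails, so the rejection
ledger partitions the rejected set; the retained set itself is independent
of rule order (asserted in the tests).  On simulated tissues these filters
remove ≈ 99 % of quartet tracks.  After matching, T1 candidates whose
contracting junction starts below 2 µm, or whose growing junction ends below
2 µm, are dropped (strict inequalities: exactly 2 µm is kept).

## Classification

Matches are sorted by normalised score and classified by a 1-nearest-
neighbour rule: an unlabelled match inherits the label of the most similar
labelled match, with similarity again the path-length-normalised DTW
distance between the matched feature subsequences (normalisation makes the
distance length-invariant; the raw score is exposed as an option).  Distance
ties resolve conservatively towards "false", then by training order.
Labelling is file-based: the sorted candidate sheet is written as CSV, the
user annotates any subset, later rounds override earlier ones.  A plain
score cutoff is provided as the baseline this replaces.  Overlapping
detections are reduced by non-maximum suppression: ascending score, a match
is suppressed when it shares ≥ k−1 cells with a kept match and their
transition frames differ by ≤ 2 frames.

## The synthetic tissue

Validation uses a vertex model: cells are counter-clockwise vertex cycles
with energy

E = Σ_cells [ K/2 (A − A₀)² + Γ/2 P² ] + Σ_edges λ_e ℓ_e,

relaxed by overdamped gradient descent (adaptive step, capped so that one
frame corresponds to finite viscous motion rather than full equilibration;
energy is non-increasing across accepted steps and the outer boundary is
pinned).  Defaults: 12 × 12 hexagonal cells of edge 3 µm (≈ 6 µm across,
typical of germband cells), K = 0.02, Γ = 0.01, λ_base = 0.05, seeded vertex
jitter of 0.25 µm, 30 s frames, 40 frames.  Scripted events raise the
tension of chosen junctions (λ_high = 0.45; rosette junctions 2.5× that,
since contraction against a high-order vertex meets more elastic
resistance).  An edge shorter than 0.3 µm collapses into a higher-order
vertex; the four-way vertex is held for one emitted frame — so a canonical
T1 visits diamond → 4-cycle → diamond — and then split orthogonally.  New
junctions grow under λ_grow = −0.35 for 8 frames and then keep a reduced
tension λ_stab = −0.3 representing junction maturation; without it the
swapped configuration would relax back to the four-way vertex, because the
unperturbed lattice is the energy minimum.  Reversals release tension at a
fraction of the onset length, well above the swap threshold.  Distractors
are pulsatile contractions, abortive reversals and transient preferred-area
dilations.  Every scripted event is emitted as a ground-truth record whose
consistency with the emitted frames is asserted by replay in the tests.

The simulator emulates the geometry and topology dynamics of an
intercalating epithelium.  It does **not** emulate medial myosin pulsing
noise on junction lengths, cell divisions and delaminations, segmentation
or tracking errors, image registration artefacts, or curved tissue surfaces.
Detection rates measured on it therefore certify the correctness of the
search machinery under clean tracking, not performance on any particular
microscopy dataset.

## Validation protocol and problem sizes

The validation experiment scripts 100 T1 events and 100 distractors spread
over 20 simulations (five per simulation, quartets pairwise disjoint) across
5 seeds; the template comes from one additional held-out simulation, and a
single labelling round on the first simulation (10 true + 10 false labels
taken from its manifest, mimicking a user annotating the sorted sheet)
trains the 1NN classifier.  Sensitivity is TP/(TP+FN) over scripted T1s and
specificity TN/(TN+FP) over distractor candidate groups, both at the
candidate-group level (member-set equality).  These sizes keep the whole
experiment within a few minutes on one CPU while exceeding one hundred
events per class.

## Downstream statistics

* **Frequency**: events per 100 cells per minute with boundary correction —
  each event contributes the fraction of its cells that are non-boundary
  cells, the sum is divided by the non-boundary cell count, by the event
  size k (generalising the quartet 1/4 factor to rosettes) and by the frame
  interval.
* **Junction kinetics**: traces are truncated at the intercalation gap
  (contracting side: first zero; growing side: onset of ≥ 2 consecutive
  positive lengths, our operationalisation of "persistent growth"), smoothed
  by a centred width-3 moving average whose window shrinks symmetrically at
  the ends (width 1 at the extremes, so linear signals pass exactly),
  resampled to 30 s by linear interpolation and differenced; event averages
  use the final 10 minutes and discard shorter traces.
* **Orientation**: junction angles are measured against a tissue midline
  fitted per anchor frame as a polynomial of degree min(points−1, 4), with
  coefficients interpolated across frames by a monotone piecewise cubic
  (Fritsch–Carlson); the nearest midline point is found by dense sampling
  (1000 points) plus one quadratic refinement.  Angles are folded to
  [0°, 90°]; axial data are doubled before the Rayleigh test (z = nR̄², with
  the standard series approximation for p) and duplicated at α+180° for
  rose plots.
* **Rosette structure**: sequentiality is the interval between the first and
  last junction disappearance (and the growth-side analogue); hubs are
  persistent ≥ 4-cell core vertices, tracked by proximity across frames
  (linking radius 2 µm, since a junction collapse moves the core by up to
  half an edge length), at which at least one member leaves and at least one
  new member joins afterwards.

## Design choices that were genuinely open

* **Quartet pair order.**  No fixed correspondence between the six cell
  pairs and the six feature dimensions transfers across quartets, so by
  default the six distances are sorted descending at each frame, making one
  template applicable to every quartet; the raw lexicographic order (over
  sorted member ids) is kept as an option for studies that fix a
  correspondence by hand.
* **Tracking rule.**  A new cell index is assigned whenever no previous cell
  overlaps by more than half of *both* areas; divisions and fusions are
  deliberately not resolved — they surface as fresh indices.
* **Branch points.**  Membrane-skeleton pixels with ≥ 3 membrane neighbours
  (8-connectivity); clusters merge into one vertex at their centroid.  Cell
  polygons are assembled by chaining the incident junction polylines;
  border cells, whose outline is partly the field edge, fall back to their
  pixel-region contour, which is why the render→polygonise round trip
  guarantees interior-cell areas within 5 % but treats border-cell polygons
  as approximate (border cells are excluded from the frequency denominator
  anyway).
* **Thick membranes** are detected by a conservative local test (a deep
  membrane pixel tightly between two distinct labels) and resolved by
  growing the cell regions until a 1–2 px separation remains, with a
  diagnostic warning.
* **One or several matches per track.**  Both are supported: the matcher
  returns the global best window by default and can emit all local minima of
  the end-score profile separated by at least half a template length.

## Known limitations

Topology classification is exhaustive over k! permutations and therefore
limited to k ≤ 6 (the built-in motifs); the enumeration targets sparse
planar adjacency graphs, not dense general graphs.  The vertex model is
quasi-static and purely mechanical; scripted tension programmes stand in
for biochemical dynamics.  Boundary-cell geometry after rasterisation is
approximate, and junction-kinetics truncation assumes a single contraction
episode per junction (wobbly transients are absorbed by extending the
truncation window to the last pre-growth frame).
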