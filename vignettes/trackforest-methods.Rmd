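---
title: "Methods: lineage-tree tracking, repair and class smoothing"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: lineage-tree tracking, repair and class smoothing}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem and the model

`trackforest` is a tracking-by-detection pipeline for 2D timelapse
microscopy: cells are segmented independently in every frame (by an
external CNN or classical method), and the package links those instance
segmentations into lineage trees. A *tree* is one founding cell and all of
its progeny; a *branch* is a maximal run of frames without a division; a
binary branching is a mitosis. The tracker is deliberately rule-based and
deterministic: mammalian cells move a small fraction of their diameter per
frame at usual sampling intervals, divide into exactly two daughters, and
cannot divide again immediately — these biological facts, not a learned
motion model, drive the assignment.

Assignment is hierarchical, most-trusted evidence first. Within a frame,
in order:

1. **Unique mask overlap.** Current instances overlapping exactly one open
   branch tip (rasterized mask IoU > 0, bounding boxes prefiltered) are
   linked. Tips remain in this pool while their cell goes undetected, up
   to `cache_depth` frames — an aged tip is exactly the branch's cached
   segmentation, and a fresh instance still overlapping it is
   high-confidence evidence. This choice matters: if only previous-frame
   tips were eligible, two neighbouring cells dropped in adjacent frames
   can cross-wire (the reappearing cell is captured by its neighbour's
   unmatched tip at stage 3 below before the cache stage could reunite it
   with its own branch); with aged tips in the overlap pool those identity
   swaps disappear without introducing any threshold.
2. **Contested groups** (many-to-many overlaps) are resolved greedily by
   the similarity index, ties by smallest instance id — a total order, so
   runs are reproducible.
3. **Expanded-box search.** An orphan's bounding box is expanded by
   `alpha` times its extent on every side (clipped to the image) and
   unmatched previous-frame tips whose centroid falls inside are
   candidates, best similarity first. Scaling the search range by cell
   size rather than a pixel distance is what keeps the defaults valid
   across magnifications.
4. **Mitosis detection.** A remaining orphan becomes a daughter of a
   previous-frame tip iff the tip's area is at least
   `division_size_ratio` times the orphan's, the tip's lineage has not
   divided within `division_cooldown` frames, the tip centroid lies in
   the orphan's expanded box, and — when class labels are in use — the
   tip is in M phase. The second daughter is the instance already linked
   to that tip this frame; a mother with no linked continuation cannot
   yield two daughters and the division is rejected. Divisions are
   strictly binary.
5. **Cache matching.** Orphans still unassigned search branches that
   stalled 2..`cache_depth` frames ago (centroid-in-expanded-box, best
   similarity); otherwise a new tree is opened. Frame-0 instances always
   root new trees.

### The similarity index

`sm_{i,j} = w · (IoU, Dis, Sps, Sas, Δ)` with all weights `+1` by
default:

* `Dis = 1/(1e-5 + d)` — inverse Euclidean centroid distance, capped at
  `1e5` for coincident centroids;
* `Sps = Σ_{n=1..7} |1/m_n^i − 1/m_n^j|` — reciprocal-difference over the
  seven Hu shape invariants. Raw Hu invariants span ~10 orders of
  magnitude, which would make the reciprocal difference numerically
  meaningless, so by default they are log-transformed
  (`sign(h)·log10|h|`, exact-zero invariants kept at 0 and skipped in the
  sum); the raw variant is a config switch (`hu_transform = "raw"`).
* `Sas = min(A_i, A_j)/max(A_i, A_j)` — area ratio in `(0, 1]`;
* `Δ` — sum of the smaller-over-larger ratios of intensity means and
  variances when intensity data exist on both sides, else 0. The source
  formula gives the two ratios as a set without a combiner; the sum is
  this package's choice, making the identical-cell value 2 and letting
  the term vanish cleanly when absent.

Two tensions are left visible rather than silently fixed: `Sps` is a
*dissimilarity* inside a sum that is otherwise similarity-increasing, and
no component normalization is defined, so `Dis` dominates at short range.
The printed combination is kept as the default; per-component weights are
exposed (`weights = c(iou, dis, sps, sas, delta)`), e.g. a negative `Sps`
weight, for users who want the coherent variant. In practice the
contested groups the index adjudicates involve candidates at comparable
distances, where the geometry terms break the tie.

## Post-tracking repair

Four passes, in a fixed, tested order:

1. `prune_singletons` — one-node trees are false detections (nothing ever
   linked to them).
2. `link_fragments` — a tree ending at `t_e` and a tree starting at
   `t_s`, `0 < t_s − t_e ≤ 3`, with the predecessor's last centroid in
   the successor's first expanded box, are spliced; competition resolved
   one-to-one by terminal-instance similarity, ascending `t_s`.
3. `discard_short_trees` — trees spanning < `min_track_span` (10) frames
   are dropped. Two boundary exemptions are this package's: trees still
   open at the movie's final frame (a cell that entered late would
   otherwise vanish), and frame-0 trees in movies shorter than the
   threshold (else a 9-frame movie would lose every cell). Fragment
   linking runs *before* this filter so two 6-frame halves of a real
   track survive as a 12+-frame track; reversing the order demonstrably
   loses tracks and is guarded by a test.
4. `fill_gaps` — missing frames inside a branch are imputed by copying
   the nearest preceding real node (geometry and class), flagged
   `is_gap_fill`. Copying, not interpolating, is deliberate: the cached
   segmentation is the last observation, and an interpolated contour
   would be an invented one. Gap-fill nodes are excluded from all
   detection-level metric counting.

## Class smoothing (TCS)

Per branch, never across a division: the first node's label is the
running default; at the first node whose raw label `X` differs, the next
`window` (9) raw labels are inspected and the switch to `X` is adopted
iff strictly more than `threshold` (60%) of them equal `X` — so 6 of 9
switches and 5 of 9 (55.6%) does not; otherwise the trigger node is
rewritten to the default. The trigger itself is excluded from the count
(the rule counts the *subsequent* frames), with two consequences worth
stating: a run must be ≥ 7 frames long (trigger + 6 confirmations) to
survive smoothing, and near a branch end the window shrinks to the nodes
remaining — with fewer than 3 remaining no switch is allowed, a guard
against deciding on 1–2 samples. A true 2-frame M run at the very end of
a mother branch is therefore smoothed away; M phase is still recovered on
the daughters, whose branches *start* in M. Smoothing is idempotent and
constant sequences are fixed points (tested as properties). A per-class
threshold map is exposed (`thresholds =`) but not default.

## Evaluation metrics

* **IDF1** `= 2·IDTP/(2·IDTP + IDFP + IDFN)` under the globally optimal
  one-to-one identity assignment between ground-truth and predicted
  branches, solved exactly with an O(n³) rectangular Hungarian solver
  written in-package (no assignment solver exists in the supported
  dependency set); a brute-force permutation oracle validates it in the
  tests.
* **MOTA** `= 1 − Σ_t(FN_t + FP_t + IDsw_t)/Σ_t GT_t`, per-frame greedy
  IoU matching (threshold 0.5, the MOT convention — the source never
  states its matcher), identity switches counted per ground-truth track.
* **CDF1** `= 2·CDTP/(2·CDTP + CDFP + CDFN)`: a predicted division is a
  true positive iff both daughters' first detections correspond to the
  two daughters of one ground-truth division, within a ±1-frame division
  timing tolerance (exposed). No divisions on either side gives an
  undefined score, printed as a dash. A division with one daughter
  correct and one imputed counts as a false negative.
* **Per-class F1**, one-vs-rest, on labels aligned by detection
  correspondence.

Forest inputs correspond detections by mask IoU; lineage-CSV inputs (which
carry no contours) by shared `(frame, instance_id)`, valid when both CSVs
were produced from the same segmentation — the intended use being scoring
a third-party tracker's relabelling of the same masks.

## The synthetic world

The generator emulates exactly the conditions the tracker assumes, so a
green end-to-end test means "the algorithm recovers the truth in its own
stated regime", no more:

* 20 cells (default) as rasterized ellipses, radius ~N(12, 1.5²) px,
  eccentricity 1.02–1.2, mild per-frame shape wobble (±2%) and slow
  rotation, on a 512×512 canvas — a cell covers ~450 px², comparable to
  20× nuclear segmentations.
* Gaussian random-walk motion, σ = 2 px/frame: consecutive-frame IoU of a
  cell with itself stays well above zero, the overlap-first assumption.
  Spawn separation ≥ 70 px and a collision-avoiding step
  (≥ 1.6·(r_i + r_j) + 6 px between centres) keep masks from ever
  overlapping within a frame.
* Divisions: the chosen mothers swell to 1.5× area over their last two
  frames (labelled M), then split into two adjacent daughters of 55% of
  the swollen area each, placed along a random axis — mother/daughter
  ratio ≈ 1.8, comfortably above the 1.3 rule, and the daughters' first
  two frames are also M (M straddles cytokinesis). Non-dividing cells
  cycle G1/G2 (35 frames) and S (25 frames) with a random phase offset;
  all interior runs exceed the 7-frame smoothing survival bound.
* Corruption is separate and truth-preserving: i.i.d. detection dropout
  (optionally capped so no cell is missing more than `max_gap`
  consecutive frames), single-frame false-positive blobs (radius 3–5 px,
  placed ≥ 40 px from any real cell and ≥ 100 px from other blobs in
  nearby frames, so a blob can never legitimately link to anything —
  the margin is a generator choice; the contract only demands
  non-overlap), and i.i.d. class-label flips to a uniformly chosen other
  class.
* All randomness flows through one seed; runs are bit-identical.

What the generator does **not** emulate — and what a green test therefore
does not establish: confluent cultures with touching cells, segmentation
*errors* that distort shape rather than delete detections, cells entering
or leaving the field of view, fluorescence intensity dynamics (the Δ term
is exercised by unit tests only), and photobleaching. The dropout
robustness scenario runs without divisions: i.i.d. dropout of a
daughter's birth frame would corrupt the division topology itself, which
is a different failure mode from the gap repair that scenario measures.

## Numerical and representation choices

* Coordinates are 0-based pixels, `x` = column, `y` = row; areas and IoU
  are computed on rasterized pixel sets (matching the mask input format).
* Contours are traced along *pixel corners* (marching-squares boundary of
  the pixel set), not through boundary pixel centres. Two exact
  identities follow: the shoelace area of a traced contour equals the
  pixel count, and rasterizing a traced contour (pixel-centre-in-polygon,
  even-odd rule with on-edge inclusion) recovers the original pixel set —
  so mask → VIA JSON → mask round-trips are lossless, which the test
  suite asserts.
* Hu invariance under translation and 90° rotation is exact on rasters
  and tested at 1e-6; invariance under uniform *scaling* is only
  asymptotic for discretized moments (a doubled 14-px ellipse agrees to
  ~0.02 in log10 units), so congruence — what the shape term actually
  needs — is what is tested tightly.
* Expanded boxes are clipped to the image; labels above 255 are accepted
  (the 1–255 range of the source data is a property of that data, not a
  format limit); multi-component labels keep the largest 8-connected
  component with a warning.
* The division cooldown is inherited by daughters at the division frame;
  "no division in the previous 50 frames" is strict (`elapsed > 50`).
* TIFF I/O is a minimal baseline codec written in-package (uncompressed
  greyscale, 8/16/32-bit unsigned, both byte orders, multi-page,
  multi-strip) because no TIFF package exists in the supported dependency
  set; it rejects compressed, tiled, float and multi-sample files with
  format errors, and the reader is validated against a frozen reference
  file produced independently by the Python `tifffile` library.
* `cache_depth = 5` (the text's "five preceding frames") and
  `min_track_span = 10` are kept as separate parameters; the source's
  parameter table lists a single `gap_window_len = 10` whose mapping is
  ambiguous, so both knobs are exposed rather than guessing.

## Known limitations

2D only; binary divisions only (no fusion, no multipolar mitoses); the
cascade is deterministic rules, not a probabilistic model — there are no
posterior link probabilities; dense/touching cells degrade the overlap
stage; the class smoother assumes error rates roughly equal across
classes and penalizes true runs shorter than 7 frames (notably terminal
M runs); and the tracker trusts raw M-phase calls for mitosis detection,
so class noise on a mother's division frame can cost a division (the
README example shows exactly this).
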