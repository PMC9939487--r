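---
title: "Bifurcation matching for Circle-of-Willis labeling: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Bifurcation matching for Circle-of-Willis labeling}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cowlabel)
```

## The problem and the model

The Circle of Willis (CoW) redistributes the blood arriving through the two
internal carotid arteries (ICA) and the two vertebral arteries to all brain
territories. `cowlabel` assigns anatomical identities to 14 arteries around
the CoW and to the 6 bifurcations joining them, in centerline graphs derived
from CTA vessel segmentations. Such graphs are artifact-prone: stroke or
segmentation gaps delete segments, and region-growing segmentations create
shortcuts, parallel loops and spurious (often venous) branches. The design
premise is therefore *consistency first*: instead of matching each artery
independently to atlas landmarks, the method searches for the graph node at
which the three arteries of a bifurcation jointly look best, which forces
the labeled arteries to meet where anatomy says they must.

The method assumes:

* the graph is metrically calibrated (millimeters) and centerlines carry
  plausible radii — both are used by the path cost;
* landmarks arrive *roughly* pre-aligned to the patient (in the intended
  deployment an upstream non-rigid atlas-to-volume registration provides
  this); only a residual rigid error plus local jitter remains, which the
  rigid ICP step and the generous 2 cm candidate threshold absorb;
* bifurcations of interest lie within 1.5 cm of their registered end
  landmarks.

## Scores, costs and the recursion

The per-artery candidate graphs use the landmark distance score

$$d_a(e) = \frac{1}{N}\sum_n s_n + \sqrt{\frac{1}{N}\sum_n (s_n - \min_i s_i)^2},
\qquad s_n = \min_m \lVert x_n - x^{(a)}_m \rVert_2 ,$$

over the edge's retained centerline points. Two refinements matter:

* **End-landmark omission.** A point whose nearest landmark is the first or
  last of the ordered set is dropped from both terms. Edges that merely
  extend past the artery's anatomical ends are thus not penalized, and
  edges lying entirely beyond them drop out (score `Inf`).
* **Support requirement.** A score must rest on at least
  `max(2, ceil(0.1 N))` retained points; otherwise it is `Inf`. With a
  single retained point the spread term is identically zero and the score
  degenerates to one (jitter-sensitive) distance; in practice such
  single-point scores arose for points *at a shared bifurcation* whose
  nearest-landmark argmin flipped onto an interior landmark of the
  neighboring artery, handing a 30 mm edge a sub-millimeter score and an
  absurd length/distance ratio. The 10% floor generalizes the same argument
  to very thin support.

Path scoring multiplies three factors: smoothness, extent and caliber. The
cost of an edge inside a path is
$c_a(e,\mathbf w) = \tfrac{1}{2}(w_N + \prod_i w_i)\, \cdot l_e / d_a(e) \cdot (1 + \delta r_e)$,
where the weight sequence $\mathbf w$ starts at 1 and appends, per
transition, the linear map of the direction dot product onto $[0.2, 1]$.
The recursion maximizes the summed cost over all *edge-simple* paths leaving
the candidate node: the current edge is removed from the candidate set along
each branch, so loops cannot be traversed twice, and since all costs are
positive the optimum is attained on a maximal path. Direction at a node is
measured on a chord of `min(3 mm, l_e/2)` arc length rather than the
full-edge chord, which keeps the angle local on curved segments; the paper
trail of this choice is that the transition angle of two anatomically
continuous but curved edges should reflect the junction geometry, not the
segments' far ends.

Configuration enumeration at a candidate node assigns distinct incident
edges to the three adjacent arteries injectively — all $P(\deg,3)$ ordered
choices for degree ≥ 3. Nodes of degree 1 or 2 are deliberately allowed,
with surplus arteries scoring 0: this is what lets a Media bifurcation
survive a complete M1 occlusion. An assigned edge outside the artery's
candidate set scores 0 rather than invalidating the configuration (the
milder reading; it lets two good arteries carry a bifurcation whose third
artery is ambiguous). Ties between configurations and nodes are broken by
smallest node id, then lexicographic edge tuple, making the matcher fully
deterministic.

## Fusion rules

* **Anterior double assignment.** If both anterior bifurcations land on the
  same node, the runner-up node of the *lower-scoring* match is consulted;
  at ≥ 80% of that match's own best score the match moves there (two ACA 2s
  assumed), otherwise the lower bifurcation is reported unmatched (single
  ACA 2). The source formulation is grammatically ambiguous about whether
  the 80% refers to the lower match's own best or the other side's; we
  compare against the lower match's own best score — the alternative only
  rescales the threshold by the ratio of the two sides' scores and behaved
  indistinguishably on phantoms.
* **Inner merging.** Inner arteries are found twice. Overlapping paths are
  merged as the arc-length-shortest path between the two bifurcation nodes
  inside the union of the two edge lists; disjoint paths are bridged by the
  global shortest path between their far endpoints. "Merged according to
  their overlap" admits several operationalizations; the union-shortest-path
  rule is ours, chosen because its result is always a single consistent
  node-to-node path. One-sided recoveries and unbridgeable gaps are kept
  and flagged `interrupted` (the stroke case).
* **Label uniqueness.** Each edge carries at most one artery. Collisions are
  resolved in favor of inner arteries first (they encode the consistency
  core), then outer/incoming arteries in descending order of their
  bifurcation's mean score; the losing path is truncated at the collision.
* **Tracing.** Outer and incoming arteries often extend beyond the
  landmarks, so their free ends are traced across the smoothest unlabeled
  transition as long as its angle exceeds 120° (weight > 0.8); tracing runs
  last so it can stop at labeled edges.

## The phantom generator

`generate_phantom()` builds a schematic CoW — 14 arteries as natural cubic
splines through anatomically placed control points in a ~120 mm cube, ICA
radii ≈ 3.6–4.4 mm tapering, AComm 1.5 mm, the rest 2–3 mm with a ±10%
smooth along-edge variation — plus ground truth and a landmark atlas. The
atlas is always sampled from the *normal* template (≈ 1 landmark per 5 mm),
then rigidly displaced and jittered; the defaults (8° rotation, 6 mm
translation, 1 mm per-landmark jitter, 0.3 mm centerline noise) model the
residual error left by an upstream non-rigid registration and the
sub-voxel noise of CTA centerline extraction. Variants rewire the template
(fetal PCA re-rooted on the ipsilateral ICA; missing AComm; single ACA 2),
occlusions delete arc-length fractions from the bifurcation end, and
artifacts inject shortcuts, parallel loops, spurious branches and edge
splits. All randomness flows through one seeded generator, so a spec is a
complete, reproducible description of a phantom.

What the phantoms do *not* emulate: patient-realistic tortuosity and caliber
distributions, the dense distal branching that surrounds the CoW in real
segmentations, intensity-dependent segmentation dropout, and non-rigid
anatomical deformation between atlas and patient. Passing the phantom
suites therefore demonstrates the algorithmic properties (consistency,
occlusion robustness, artifact tolerance, the fetal failure mode) — it does
not certify clinical-grade accuracy on CTA data, whose published rates were
measured by manual review on real scans.

## Numerical choices and degenerate inputs

* Distances, thresholds and tolerances are millimeters; the published
  constants (20 mm candidate threshold, 15 mm node radius, δ = 0.1, weight
  range [0.2, 1], 120° tracing angle, 80% anterior ratio, 5 mm bifurcation
  tolerance, 20 mm outgoing evaluation extent) live in one `cow_params()`
  object.
* `d_a(e) = 0` is floored at 0.1 mm inside the cost — sub-resolution
  distances are geometrically meaningless and would otherwise divide by
  zero.
* The recursion depth is guarded at 64 edges; exceeding it signals a
  pathological loop graph rather than silently looping.
* Mean radius is the arithmetic mean of the per-point radii; edge length is
  the exact polyline arc length.
* Evaluation operationalizes the manual notions numerically: "main part of
  the vessel" is ≥ 50% arc-length overlap with the truth, clipping for
  outgoing arteries keeps the edges whose upstream path length is below
  2 cm, and bifurcation displacement is geodesic (along the centerlines,
  via the graph), not Euclidean. These thresholds are declared conventions
  of the automatic evaluation, not claims about the original manual one.
* Degenerate inputs fail loudly and early: empty landmark sets, collinear
  point clouds for ICP, zero-length direction chords, dangling edge
  endpoints and radii/point count mismatches are all rejected with specific
  messages; an *empty graph* however labels to an all-empty result with a
  warning, since "no vessels found upstream" is a legitimate pipeline
  state.

## Test-suite problem sizes

The recursion is verified against an exhaustive path-enumeration oracle on
200 random multigraphs of up to 12 edges (the oracle enumerates all maximal
edge-simple paths and folds costs right-to-left, so agreement is exact, not
approximate). Recovery properties run on 20 clean and 20 M1-occlusion
phantoms, the method-versus-baseline comparison on 40 artifact-laden
phantoms, the fetal failure mode on 5, ICP recovery on 6 rigid perturbations
up to 10°/10 mm. These sizes give stable rates while keeping the default
suite fast on one CPU.

## Known limitations

* The fetal-PCA variant is mislabeled by construction: the method's fixed
  consistency template expects the PCA at the basilar tip. This is the
  documented failure mode and is asserted as such in the tests.
* The AComm, being short, is structurally disadvantaged by the
  length-driven cost; on real data it shows the highest failure rates.
* The baseline shares registration and distance scores with the main
  method by construction, so comparisons isolate the matching strategy —
  but on schematic phantoms the baseline is stronger than on real data,
  where its lack of bifurcation consistency is much more damaging.
* Landmark *orientation* (which end is which) is a fixed package
  convention; atlases supplied externally must follow it.
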