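---
title: "knotph: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{knotph: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

A protein backbone can be entangled like an open-ended knot. Two geometric
attributes of such entanglement matter biologically: the *knot core* (the
shortest sub-chain that remains knotted) and the *knot depth* (how far that
core sits from the chain termini; a knot is *deep* when both tails are
long, *shallow* when the core nearly touches an end). Knot-theoretic
characterization of open chains is expensive and brittle under noisy or
incomplete coordinates. `knotph` takes the persistent-homology route: the
backbone becomes a point cloud, the cloud becomes a degree-1 persistence
diagram, and all downstream comparison, statistics and localization operate
on that summary, which is provably stable under coordinate perturbations.

## The pipeline and its model

**Point cloud.** The chain is modelled as the piecewise-linear curve
through its C&alpha; atoms. The analysis cloud contains every C&alpha;
position plus `points_per_gap` equidistant interior points per segment
(default 5, i.e. interior fractions k/6). `points_per_gap = 0` gives the
sparse, bare-C&alpha; variant used in the robustness experiment. Chain
breaks (consecutive C&alpha; distance > 4.5 &Aring;) are interpolated across like
any other segment — the PL-curve model has no gap concept — with a warning.
Units are &Aring;ngstr&ouml;m throughout; coordinates are never rescaled.

**Persistence.** The Vietoris–Rips filtration enters a vertex at scale 0,
an edge at its length, and a triangle at its longest edge. Homology is
computed over Z/2 by column reduction of the triangle boundary matrix, with
simplices ordered by (diameter, dimension, lexicographic vertex tuple) so
that pairings are deterministic under ties. Zero-persistence pairs are
discarded. The default filtration threshold is the *enclosing radius*
min_p max_q d(p, q), at which the Rips complex is a cone and every degree-1
class has died; smaller thresholds are allowed and yield right-censored
pairs flagged as such (refused by the Wasserstein distance with an
instruction to recompute). The reduction keeps the reduced column of every
positive-persistence death triangle: its edge set is the *representative
cycle*, a mod-2 cycle whose edges all have length &le; birth and which
becomes a boundary at the death scale. No post-hoc cycle shortening is
attempted; minimal-cycle search is NP-hard, and for spatial curves the
reduced-column representative is empirically close to minimal.

**Landscapes.** &lambda;_k(t) is the k-th largest value of
max(0, min(t − b_i, d_i − t)). Layers are stored as exact PL knot lists,
never on a grid: the ranking of tents can only change at tent endpoints or
at pairwise side intersections (b_i + d_j)/2, so evaluating on that
candidate set and pruning collinear knots is exact. Averages are computed
on the union of the members' knots (missing layers are zero functions);
distances integrate |&Delta;| segment-wise in closed form, splitting
segments at sign changes. The L1 distance sums all kept layers
(`max_layers` = 10 by default); a layer filter (e.g. `layers = 2`) exposes
the &lambda;2-only comparison used for the knotted/unknotted heat map,
since whether the reference analysis truncates layers is not stated.

**Wasserstein.** W1[L&infin;]: cost exponent 1, ground metric L&infin;,
matching to the diagonal allowed at cost (d − b)/2. Solved exactly as an
assignment problem on the (n + m)-augmented square matrix with an O(N³)
Hungarian solver; diagrams here have tens of points, so exactness is cheap.

**Randomization test.** The statistic is the landscape distance (L1 by
default, optional layer filter) between the two group averages. Labels are
reshuffled Monte-Carlo style preserving group sizes (a "1000-sample" test
corresponds to `n_permutations = 1000`), and the p-value uses the add-one
convention, so p &ge; 1/(N + 1). Two implementation details are worth
noting. First, all pooled landscapes are evaluated once on the union of
their critical abscissae; every permutation statistic is then an exact
closed-form computation on that matrix (the functions are PL with knots
inside the union grid). Second, the pool is put into a canonical
content-derived order before sampling and the smaller group size is the one
drawn, which makes the p-value *exactly* invariant under swapping the two
group arguments — with a naive implementation the Monte-Carlo draws would
differ between `f(A, B)` and `f(B, A)`.

**Isomap.** Union k-NN graph (k = 5 by default; ties broken by id order)
weighted by the input dissimilarity, all-pairs shortest paths, classical
MDS, top two coordinates. A disconnected graph is an error that names the
components and the smallest connecting k; the pipeline wrappers raise k to
that value automatically, because strongly separated classes legitimately
disconnect small neighbourhoods. Sign ambiguity is canonicalized by
requiring non-negative skewness on *both* axes (first item's sign as
tie-break). Fixing axis 2 by the first item alone was considered and
rejected: it breaks the invariant that permuting the inputs permutes the
rows.

**Localization.** Given a knotted and an unknotted group, both average
landscapes are computed and every strict local maximum (t\*, h) of every
knotted-average layer is tested for *absence* in the unknotted average:
value at t\* below `absence_threshold` &times; h (default 0.2, a
visually-clear-peak-vs-flat criterion; configurable). The most prominent
absent peak wins. It is mapped through the tent correspondence
(t\* &minus; h, t\* + h) to a diagram pair of a representative knotted
curve — the curve whose discriminating layer is L1-closest to the group
average — whose representative cycle is resolved through the cloud's
provenance to residue/index ranges and scored as
|cycle vertices inside the annotated core| / |cycle vertices|. Identical
groups have no absent peak and return a `found = FALSE` report rather than
an error.

**Class-separation score.** The robustness sweep needs a number where the
reference analysis assesses separation visually; we use leave-one-out
nearest-centroid accuracy in the 2-D embedding of the W1[L&infin;] matrix.

## The synthetic world

The generator exists so that every stage is testable without structure
downloads; its defaults are the stated world of the test suite.

* **Core.** The standard open trefoil (sin t + 2 sin 2t, cos t − 2 cos 2t,
  −sin 3t) on [&delta;, 2&pi; − &delta;], &delta; = 0.4, resampled
  uniformly in arc length (the raw parametrization has ~2&times; speed
  variation) and rescaled to a mean consecutive spacing of 3.8 &Aring;, the
  C&alpha; virtual bond length. `n_core` defaults to 40 — desk scale; real
  trefoil cores run ~40–80 residues. A seeded Gaussian core jitter
  (0.25 &Aring;, small against the ~5 &Aring; persistence of the core loop) plays the
  role of within-class structural variability: curves with equal parameters
  and different seeds are distinct structures of one fold.
* **Tails and depth.** Straight radial tails were implemented first and
  proved wrong: they contribute *no* degree-1 homology, so deep and shallow
  curves had identical diagrams and depth was invisible to the pipeline —
  the opposite of what the method is supposed to detect on real proteins,
  whose termini pack against the domain. Tails are therefore built as a
  short radial escape followed by an arc on a sphere enclosing the core
  (clearance 2.5 &times; spacing; the two termini arc in opposite senses on
  shells offset by 2.2 &times; spacing, each arc's pole being the other
  tail's ray so the tails provably keep clear of each other; long arcs
  spiral slowly in latitude instead of self-overlapping). A curve confined
  to an enclosing sphere can be pushed radially to infinity without
  crossing the interior core, so shell tails cannot entangle with it. Their
  arcs hug the core at a fixed clearance and generate the large-scale loops
  through which tail length — depth — enters the diagram. Depth labels use
  min(tail)/total length: deep &ge; 0.25, shallow &le; 0.05, else neither;
  the thresholds only need to be consistent and well separated.
* **Unknotted partner.** Opening the parametric trefoil at &delta; = 0.4
  removes the strands of two of the three diagram crossings (verified by
  fine-sampled projection); the open arc retains exactly one, and
  `trefoil_crossings()` reports it with its index window. The partner is
  produced by displacing the window's points along the projection axis with
  a sin&sup2; taper (zero at the window boundaries, so the two boundary
  points are literally unmoved), peak displacement 2 &times; the local
  strand separation — a localized strand passage that converts the closure
  to the unknot. Cosine-family tapering preserves continuity and
  approximate spacing; reflection would not.
* **Noise.** I.i.d. centred Gaussian per coordinate. The sweep grid
  defaults to 8 log-spaced values up to 2 &Aring; (the reference grid is not
  public); the acceptance criterion probes {0, spacing/6, spacing/3},
  spacing/3 being the level at which class recovery is expected to fail.

What a green suite establishes: the persistence core is exactly the naive
reduction on random clouds; landscapes and Wasserstein distances are exact
against independent oracles; the test is calibrated (type-I error within
[0.03, 0.07] at nominal 0.05) and powered on this world; the localization
cycle lands in the annotated core; separation survives the sparse cloud and
degrades monotonically under noise. What it does not establish: behaviour
on real PDB structures (different feature scales, heterogeneous chain
lengths, experimental noise) or the specific published figures, which
require the full knotted-protein corpus.

## Numerical choices, in one place

* Coefficients Z/2; filtration ties broken by (diameter, dimension,
  lexicographic vertex tuple).
* Enclosing radius as default threshold; censored pairs carry
  `death = max_scale` and a flag.
* Zero-persistence pairs discarded (birth and death compare as exact
  doubles: both are the same computed distance when equal).
* Dense bit-packed reduction columns with word-wise XOR up to 60k edges,
  sparse merge fallback above.
* Landscape candidate knots {b_i} &cup; {d_i} &cup; {(b_i + d_j)/2};
  collinear-knot pruning at slope tolerance 1e-12.
* Peak detection: plateaus (possible in averages) located at the plateau
  midpoint; peaks on the window boundary do not count as local maxima.
* Assignment "infinities": off-diagonal point-to-diagonal entries use a
  finite bound larger than any optimal matching, keeping the Hungarian
  arithmetic finite.
* Add-one p-values; permutation draws seeded and reproducible; child seeds
  derived as (7919 s + 104729 k) mod 2147483629 in double arithmetic
  (exact below 2^53, within 32-bit range).
* Isomap: union k-NN, id-order tie-breaks, skewness sign canonicalization,
  residual variance 1 − cor(geodesic, embedded)&sup2;.

## Known limitations

* Only homology degree 1; no cohomology, approximate Rips, or sparse
  filtrations — clouds beyond a few thousand points become expensive.
* Representative cycles are reduced-column representatives, not minimal
  cycles.
* The PDB reader handles ATOM records of standard fixed-column files
  (altloc by highest occupancy, first model by default); mmCIF and
  non-protein polymers are out of scope.
* Synthetic tails are entanglement-free by a radial-pushing argument, but
  knot types are never verified by invariant computation (out of scope);
  the generator's realism is geometric, not energetic.
* Depth labels for synthetic curves are by construction; for real proteins
  the annotations come from the metadata table, not from coordinates.
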