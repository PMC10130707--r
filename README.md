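# knotph

Persistent homology of open knotted protein backbones.

Roughly one protein in a hundred has a backbone that is entangled like an
open-ended knot, and the geometry of that entanglement — how large the
knotted core is and how deeply it is buried between the chain termini —
shapes folding and stability. Classical knot-theoretic tools need clean,
complete coordinates and expensive sub-chain scans. `knotph` implements an
alternative: treat the C&alpha; trace as a point cloud, compute its degree-1
Vietoris–Rips persistent homology, and compare, test and localize
entanglement directly on those topological summaries. It is written for
structural bioinformaticians who want a noise-tolerant, alignment-free
fingerprint of backbone entanglement.

## What it computes

For a point cloud sampled from the backbone (every C&alpha; atom plus, by
default, 5 equidistant interpolated points per virtual bond):

* the **degree-1 persistence diagram** over Z/2 — the multiset of scales
  (b, d) at which each loop in the Rips filtration is born and dies, with a
  mod-2 **representative cycle** for every finite pair, computed by
  boundary-matrix reduction with deterministic (diameter, dimension,
  lexicographic) tie-breaking;
* the exact piecewise-linear **persistence landscape**
  λ1 ≥ λ2 ≥ …, where a diagram point (b, d) contributes a tent of
  height (d − b)/2 supported on [b, d]; landscapes average exactly and
  carry an L1 and a sup metric;
* the **W1\[L∞\] Wasserstein distance** between diagrams (exact
  assignment on the diagonal-augmented cost matrix);
* a **label-randomization test** on the distance between two groups'
  average landscapes, with the add-one p-value
  p = (1 + #{perm ≥ obs}) / (1 + N);
* a 2-D **Isomap** embedding of any distance matrix (k-NN geodesics +
  classical MDS);
* a **localization report**: the landscape peak present in a knotted
  family's average and absent in its unknotted homologues is mapped back to
  a diagram pair, its representative cycle is extracted, and the cycle's
  overlap with the annotated knot core is scored.

A built-in generator produces annotated open trefoil curves with tunable
knot depth, a matched unknotted partner differing by one localized strand
passage, and Gaussian coordinate noise, so the entire pipeline is testable
without downloading structures.

## Worked example

```r
library(knotph)

# a deeply knotted synthetic trefoil: 40-point core, 20-point tails
curve <- make_open_trefoil(n_core = 40, tail_lengths = c(20, 20), seed = 1)
curve
#> <synthetic_curve trefoil_s1: 80 points, knotted, core 21..60, deep>

dgm <- rips_diagram_h1(curve)
dgm
#> <persistence_diagram trefoil_s1: degree 1, 6 pair(s)>
#>   (6.949, 17.724)
#>   (10.587, 13.892)
#>   (9.018, 12.263)
#>   ...
```

The most persistent loop (born 6.9 Å, dead 17.7 Å) is the trefoil's central
cycle; the shorter-lived features come from the curve's packed tails.

```r
diagram_to_landscape(dgm, max_layers = 5)
#> <persistence_landscape trefoil_s1: 4 layer(s)>
#>   lambda_1: sup 5.387 on [6.95, 28.07]
#>   lambda_2: sup 1.653 on [6.95, 28.07]
#>   lambda_3: sup 1.227 on [6.95, 28.07]
#>   ...
```

λ1's sup is (17.724 − 6.949)/2 = 5.387, the half-persistence of the main
loop — the tent formula at work. Now compare ten knotted curves with their
unknotted partners (same geometry up to one strand passage) and localize
what distinguishes them:

```r
knotted   <- lapply(1:10, function(i) make_open_trefoil(40, c(20, 20), seed = i))
unknotted <- lapply(knotted, make_unknotted_partner)
report <- localize_discriminating_feature(knotted, unknotted,
                                          list(max_layers = 5))
report
#> <localization_report: lambda_3 peak at t = 10.65 (h = 1.08) -> pair (9.51, 12.09)
#>   representative trefoil_s6, knot-core overlap 1.00>
report$residue_ranges
#>   [,1] [,2]
#> 1   21   23
#> 2   25   26
#> 3   28   31
#> 4   46   49
```

The λ3 layer of the knotted average has a peak at scale 10.65 Å that the
unknotted average lacks; inverting the tent gives the diagram pair
(9.51, 12.09), whose representative cycle runs through curve indices 21–49
— entirely inside the annotated knot core (21..60), hence the overlap
fraction 1.00. On real structures the same call, fed PDB-derived clouds of
knotted AOTCases and unknotted OTCases, reproduces this analysis with
residue numbers.

Real structures enter through `read_backbone()` / `interpolate_cloud()`:

```r
chain <- read_backbone("3kzk.pdb", chain_id = "A")
cloud <- interpolate_cloud(chain, points_per_gap = 5)
```

A command-line front end drives the same stages
(`Rscript -e 'knotph::knotph_cli()' --help` style usage; subcommands
`cloud`, `ph`, `landscape`, `dist`, `embed`, `rtest`, `synth`, `localize`,
`sweep`, `run-all`).

## Vignette

`vignettes/knotph-methods.Rmd` describes the model and its assumptions, the
synthetic-data world and what a green test does (and does not) establish,
and every numerical design choice.
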