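---
title: "Measuring and testing the fundamental–existing–realized niche chain"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring and testing the fundamental–existing–realized niche chain}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nichebounds)
```

## The model

`nichebounds` works on one (or two) scenopoetic niche axes — environmental
conditions such as temperature that a species experiences but does not
consume. Three nested objects are quantified per species:

* the **fundamental niche** N~F~ = [T~min~, T~max~], a physiological
  tolerance interval between critical/lethal limits, with measure
  |N~F~| = T~max~ − T~min~ (°C). Membership is closed on both ends: the
  limits themselves are survivable conditions.
* the **existing niche** N\*(t, G) = N~F~ ∩ E(t, G), the part of the
  fundamental niche actually present among the environments available in
  region G — here the values of an equal-area climate grid, modelled
  continuously by a kernel density k~E~(T). Its proportional measure is the
  kernel mass inside the interval,
  p\* = ∫~Tmin~^Tmax^ k~E~(x) dx.
* the **realized niche** N~R~(t, G), sampled by the climates at observed
  occurrences and modelled by a second kernel density.

Because the objects are nested as sets, their measures should satisfy
|N~F~| ≥ |N\*| ≥ |N~R~|; the package's statistical machinery asks whether
occurrence data respect the inclusion N~R~ ⊆ N~F~ more strongly than chance
placement would.

### The random-placement null

If a species' records sampled available environments at random, the number
k of n records inside its tolerance interval would be Binomial(n, p\*).
`placement_test()` reports the exact upper tail P(X ≥ k) — no normal
approximation, which keeps every p-value checkable against term-by-term
summation. Across species the tests form one family, corrected by the
sequential (step-down Holm) Bonferroni procedure at a family-wise level of
0.01: sort the p-values, reject the i-th smallest while
p~(i)~ ≤ α/(m − i + 1), stop at the first failure. The mirror family —
are there more records *outside* the interval than chance predicts,
upper tail of Binomial(n, 1 − p\*) — is conventionally reported at a plain
Bonferroni level (0.05 divided by the number of species). The two families
deliberately keep their two different corrections and levels; both are
configurable (`alpha_inside`, `alpha_outside`).

Degenerate corner: if a tolerance interval holds no available climate
(p\* = 0), a random point inside is impossible; the p-value is 1 when
k = 0 and 0 (with a warning) otherwise, avoiding the 0^0 ambiguity.

### The volume null model

To ask whether observed tolerance widths could be random intervals,
`nf_volume_null()` draws 10,000 independent left/right limit pairs
uniformly within the available climate range and keeps the positive
differences. These follow the triangular density 2(W − δ)/W² with mean
W/3 — a property the test-suite verifies by moment and KS checks — and the
observed |N~F~| distribution is compared to it with a two-sample KS test on
log10 volumes.

## Kernel choices

The climate and realized-niche kernels are Gaussian kernel density
estimates with Silverman's rule-of-thumb bandwidth (`stats::bw.nrd0`),
overridable per analysis (`bandwidth`). The estimated density's support is
truncated at 4 bandwidths beyond the sample range; the truncated tail mass
is below 10^-4^, so the density is not renormalized and still integrates to
1 within the 10^-3^ contract the tests enforce. Two-dimensional kernels are
product (diagonal-bandwidth) kernels with one Silverman bandwidth per axis.

Integration over an interval uses adaptive quadrature (absolute tolerance
10^-6^) with a deterministic composite-Simpson fallback; the overlap
integral ∫ min(k~species~, k~E~) is evaluated on a 1024-interval Simpson
grid directly, because the min() kink violates adaptive quadrature's
smoothness assumptions. The grid step (≈0.04 °C for a 40 °C niche) sits
well below the smallest bandwidths that occur, so discretization error is
negligible against the kernels' own smoothing bias. Two-dimensional box
masses use a 256-interval tensor Simpson grid, with the separable structure
of the product kernel exploited so large samples stay fast.

Results near tolerance-interval edges are bandwidth-sensitive; this is
inherent to kernel modelling of E-space, which is why the bandwidth is an
explicit, reported parameter rather than a hidden default.

## Measure conventions (a genuinely open design point)

The kernel gives a *proportional* existing-niche measure p\* ∈ [0, 1];
plotting it in °C needs a conversion, and two conventions are implemented:

* **`"intersection"` (default)**: |N\*| = length of
  [T~min~, T~max~] ∩ [min E, max E]. Under a uniform climate this equals
  p\* × range exactly, and it can never exceed |N~F~|, so the definitional
  inclusion N~F~ ⊇ N\* survives conversion for every climate shape.
* **`"proportion_range"`**: |N\*| = p\* × (max E − min E). This preserves
  |N\*| ≥ |N~R~| for the overlap-based realized measure but can exceed
  |N~F~| whenever the climate concentrates mass inside a narrow interval
  (with a bimodal climate this happens for most realistic tolerance
  intervals), breaking the chain at the top.

The default is the convention under which the measure chain reflects the
set-inclusion chain it is meant to quantify.

Similarly, the realized measure multiplies the overlap integral by "the
observed range of temperatures". With any contamination in the data, a
single stray record stretches the raw occurrence range across most of the
climate range and can push |N~R~| above |N\*|. The default
(`occ_range_within = TRUE`) therefore takes the range of occurrence
climates *inside* the tolerance interval — the measure is of
N~R~ ∩ N~F~ by definition — and the raw-range reading remains available
(`occ_range_within = FALSE`). Realized kernels are fitted only for species
with at least `min_points = 5` annotated records; species below the
threshold stay in the output with an explicit reason code.

## Occurrence handling

Coordinates are validated (longitude ∈ [−180, 180], latitude ∈ [−90, 90];
an optional user-supplied region mask can reject further records), then
spatially thinned: a seeded randomized-greedy pass per species accepts a
record iff it lies at least `thin_radius_km` (default 10 km, great-circle
on a 6371 km sphere) from every accepted record. Thinning is idempotent and
deterministic given the seed; per-species streams are independent. Climate
values are then extracted from the nearest grid-cell centroid; records
outside a configurable coverage radius are excluded and counted, never
silently dropped.

## The virtual-species generator

The simulator is first-class, tested code — its defaults define the study
conditions under which the package validates itself:

* **World**: 16,712 equal-area cells of 10⁴ km² (the scale of a global
  equal-area grid excluding Antarctica), with climate values drawn i.i.d.
  from a two-component normal mixture (weights 0.45/0.55, means −5 °C and
  22 °C, sds 8 and 5 °C) — a bimodal shape qualitatively mimicking the
  global mean-temperature distribution, with a cold high-latitude mode and
  a warm tropical mode. Cell centroids sit on a regular lon/lat lattice so
  thinning and extraction operate on meaningful geometry. Defaults are
  illustrative, not calibrated to any particular dataset.
* **Species**: tolerance midpoints ~ Normal(15, 6) °C and widths ~
  Uniform(20, 40) °C, the scale typical of compiled reptile and amphibian
  thermal-tolerance ranges; occurrence counts ~ NegBin(mean 134,
  size 0.8), emulating the strong skew of public occurrence databases while
  averaging ~134 records/species; contamination 0.05 — each record is,
  with probability 0.05, sampled from the whole world regardless of the
  niche (georeferencing error, coarse-grid microclimate mismatch).
* Occurrence records carry a hidden ground-truth label (niche-directed vs
  background draw) that analysis functions never read; only test code uses
  it as an oracle.

What the simulator deliberately does **not** emulate: spatial
autocorrelation of climate, dispersal limitation, biotic exclusion, niche
evolution, and observation effort gradients. Passing tests therefore
demonstrate the statistical machinery is correct and calibrated under
random sampling — not that real occurrence data meet those assumptions.

## Problem sizes and determinism

The test-suite exercises the pipeline on worlds of 1,500–4,000 cells with
15–300 species, plus one full-scale run (default 16,712-cell world, 200
species) for the measure-ordering check; the acceptance script runs the
complete default world with 105 species (~14,000 records). These sizes give
Monte-Carlo standard errors comfortably inside every asserted band. All
randomness flows from one master seed through per-stage derived streams
(32-bit, multiplicative-hash spacing), so identical configurations
reproduce reports byte for byte; the suite asserts this.

## Known limitations

* One or two climate axes only; no ellipsoidal or non-convex
  fundamental-niche shapes — tolerance boxes are axis-aligned.
* The existing-measure °C conversion is a convention (see above), so
  absolute |N\*| values are comparable within a convention, not across.
* Kernel support truncation makes densities exactly zero beyond 4
  bandwidths; extreme-tail probabilities below ~10^-4^ are not resolved.
* The binomial null treats records as independent; spatial thinning reduces
  but does not remove residual autocorrelation, so significance on real
  data is anti-conservative to an unquantified degree.
* Raster climate layers are not read directly; they must be pre-sampled to
  an equal-area cell table (CSV), optionally in tenths of °C.
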