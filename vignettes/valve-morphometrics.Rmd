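---
title: "Methods: shell volumetrics, disparity rarefaction, and phylogenetically corrected ANOVA"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: shell volumetrics, disparity rarefaction, and phylogenetically corrected ANOVA}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(valvemorph)
```

`valvemorph` quantifies how shell form varies across two clades of
heterodont bivalves that differ in one functionally pivotal trait — the
possession of siphons — and asks how that variation relates to family
membership, substratum use, and shared ancestry. This vignette explains
the models and procedures, the tunable parameters, the numerical choices,
and what the synthetic-data generator does and does not emulate.

## Mesh volumetrics

A valve arrives as an indexed triangle mesh in a fixed, hinge-aligned
frame: x anterior–posterior, y dorso-ventral, z commissure-normal, units
mm. Two surfaces describe one specimen: the closed `shell_solid` bounding
the shell material, and the open `interior_surface` of the shell's inside,
whose single boundary loop traces the commissure.

The volume of a closed, consistently outward-wound mesh is the sum of
signed tetrahedra, $V = \tfrac16\sum_f v_0\cdot(v_1\times v_2)$, exact for
the polyhedron (divergence theorem). On load, duplicate vertices are
merged within $10^{-6}\times$ the bounding-box diagonal (a scale-free
tolerance), triangles with area below $10^{-12}$ mm² are dropped, winding
is made consistent by flood fill across shared edges, and closed meshes
are flipped globally if their signed volume is negative. `validate_mesh()`
reports closedness (every edge in exactly two faces), manifoldness (at
most two), orientation consistency, boundary-loop and component counts;
`compute_metrics()` refuses a shell solid that is not closed + manifold.

The interior surface is open, so its volume depends on how the opening is
treated — a genuinely underdetermined step, resolved here by offering both
readings and defaulting to the interpretable one:

* **capped** (default): the boundary loop is fanned to its own centroid
  and the closed mesh's volume taken. On an open hemisphere of radius $r$
  this converges to $2\pi r^3/3$, the cavity volume below the commissural
  plane.
* **origin_fan**: the surface is translated so its area-weighted centroid
  sits at the origin and the raw signed-tetrahedra sum is taken —
  equivalent to fanning the opening to the surface centroid. On the
  hemisphere this converges to $\pi r^3/2$: the capped volume minus the
  cone from the centroid (at height $r/2$) to the boundary circle,
  $\tfrac13\pi r^2\cdot\tfrac r2 = \pi r^3/6$.

The area-weighted surface centroid is used rather than the vertex
centroid because the two agree only for uniform meshing, and area
weighting is the meshing-invariant choice. Both modes return absolute
values; the mode is recorded in the metrics output, and for real
specimens the two should be compared whenever they differ by more than
about 1%.

From one valve: $\mathrm{TSV} = 2\,V_{\text{shell}}$,
$\mathrm{TIV} = 2\,V_{\text{interior}}$ (the taxa are equivalve, so one
valve is half the animal), and

$$\mathrm{pSV} = \frac{\mathrm{TSV}}{\mathrm{TSV}+\mathrm{TIV}} \in (0,1].$$

SL is the x bounding-box extent, height the y extent, width twice the z
extent, $\mathrm{XS} = \text{width}/\text{height}$, and logSL uses base 10
by default (configurable; the base only shifts and scales the log
variable, so inference is unaffected). pSV and XS are dimensionless and
invariant under uniform scaling and under mirroring
(`mirror_valve()` reflects z and flips winding, the right-to-left-valve
operation); SL scales linearly. These invariances are asserted to a
relative $10^{-9}$ in the tests.

Alignment to the hinge axis is an input contract: meshes must arrive
aligned, because the alignment procedure itself is external to this
package's scope. All bounding-box quantities silently assume it.

## Substratum-use classification

Six categories: infaunal asiphonate, shallow infaunal siphonate, deep
infaunal siphonate, borer, nestler, epifaunal. Precedence, applied by
`classify_substratum()`:

1. a manual override column (for taxa classified on direct observation);
2. habit annotations borer / nestler / epifaunal — these are defined by
   the substrate occupied, not by burial depth, so they outrank the depth
   rules;
3. asiphonate + infaunal → infaunal asiphonate;
4. siphonate with SL < 50 mm → shallow (small shells cannot house siphons
   long enough for deep burial);
5. otherwise the siphon length is estimated as the pallial-sinus depth
   fraction × SL, and an estimate **strictly greater than** 30 mm makes
   the species deep.

Both boundaries are read strictly: SL = 50 mm falls through to the sinus
check, and an estimated depth of exactly 30 mm stays shallow. The general
rule (fraction × SL vs 30 mm) is implemented rather than any worked
numeric shortcut. A siphonate specimen at or above 50 mm without a sinus
fraction is an error naming the row — classification is total and
single-valued on valid input, never silently imputed.

## Disparity rarefaction

Disparity of a group is the sample variance (denominator $n-1$) or the
cumulative range of a trait. Because variance is size-unbiased and range
is strongly size-biased, groups of unequal diversity are compared by
rarefaction: for each subsample size $n$ from `n_min = 5` to the group
size, draw `reps = 1000` subsamples **without replacement** and summarise
the statistic by its median and 2.5/97.5 percentile envelope. Sampling
without replacement is the substantive choice: it makes the curve
terminate exactly at the full-sample statistic at $n = N$ (there is only
one such subsample), which is what the plotted full-sample endpoints
mean. The 95% envelope is a plain percentile interval of the replicate
statistics; nothing distributional is assumed.

`divergence_threshold()` returns the smallest shared $n$ at which two
envelopes are disjoint *and remain disjoint at every larger shared n*.
The persistence requirement guards against sporadic Monte-Carlo crossings
of wobbly envelopes; the first-crossing reading is available via
`persistent = FALSE`. `range_stabilization()` returns the smallest $n$
from which the median range stays within `tol = 1%` of the full-sample
range — the flattening point of the range curve; the tolerance is exposed
because "flat" admits no unique definition.

For groups of at most ~8 values the Monte-Carlo machinery is checked
against `rarefy_exhaustive()`, which enumerates all $\binom{N}{n}$
subsamples. One caveat found while testing: when the subsample statistic
has an atom of probability ≈ 0.5 at one value (e.g. ranges of pairs from
{0,1,2,3}), the Monte-Carlo *median* oscillates between neighbouring
atoms and is not a 2%-stable estimator of the interpolated enumeration
median; comparisons therefore use generic continuous fixtures, where both
estimators agree.

## Phylogenetic comparative statistics

Under Brownian motion on a rooted tree with branch lengths, tip trait
covariance is $\sigma^2 C$ with $C_{ij}$ the root-to-MRCA depth of tips
$i,j$. `phylo_vcv()` accumulates each edge's length over the tip pairs
descended from it (verified against an independent implementation), and
applies Pagel's λ as an off-diagonal multiplier: λ = 0 is a star
phylogeny, λ = 1 full Brownian structure. Since both $C$ and its diagonal
are positive definite, any λ in [0, 1] is valid; the ML search is bounded
there, shrinking with a warning if a requested bound leaves the Cholesky
factorization infeasible.

**Blomberg's K** is the ratio of the observed MSE of tip values about the
phylogenetic (GLS) mean to the $C$-standardized MSE, divided by the
expectation of that ratio under Brownian motion on the same tree, so
K = 1 is the Brownian reference. Its p value shuffles trait values across
tips, counting $(\#\{K^* \ge K\}+1)/(n_{\text{perm}}+1)$. **Pagel's λ**
is fitted by maximising the multivariate normal likelihood with mean and
$\sigma^2$ profiled out analytically, and tested against λ = 0 by a
likelihood ratio on one degree of freedom. Calibration is part of the
test suite: across 500 Brownian simulations on a 64-tip birth–death tree
the mean K lies in [0.9, 1.1] and the mean λ̂ exceeds 0.9, while
tip-shuffled traits give mean λ̂ below 0.1.

**pgls_rrpp()** fits a linear model after premultiplying response and
design by $C^{-1/2}$, computed by eigendecomposition with eigenvalues
floored at $10^{-10}\times$ the largest — near-ultrametric trees with
short terminal branches make $C$ ill-conditioned, and the floor acts as a
minimal ridge rather than a model change. Sums of squares are sequential
(type I) in the written term order; each term's df is the *rank gained*
over the preceding model, so partially aliased factors (a family level
fully determined by preceding substratum levels, a structural feature of
this study design) lose df rather than aborting, while a term adding no
estimable column at all is an error. Significance uses residual
randomization (RRPP): for term $k$, residuals of the reduced model with
terms $1..k-1$ are permuted and added back to the reduced fit, the term's
F is recomputed on each of the `n_perm = 999` permuted datasets, and
$p_k = (\#\{F^*\ge F\}+1)/(n_{\text{perm}}+1)$ — the observed arrangement
counts, so p is floored at 1/(n_perm+1), matching a reported floor of
0.001 at 999 permutations. The effect size Z is the standard deviate of
log F within the permutation distribution (log-transforming F before
standardising keeps the distribution near-symmetric; weak terms then
naturally produce negative Z). With the identity covariance and many
permutations these p values converge to classical parametric ANOVA p
values on balanced normal data, and under a Brownian null with a random
factor the empirical type-I error at α = 0.05 sits within [0.03, 0.07]
over 500 replicates — both asserted in the tests.

All stochastic operations take explicit integer seeds and are bit-wise
reproducible from them. The pipeline keeps one seed per stage
(rarefaction, permutation, simulation) rather than one global stream, so
a stage can be re-run in isolation without disturbing the others.

## What the synthetic generator emulates — and what it does not

`make_valve()` builds the solid between two nested hemi-ellipsoids
(z ≥ 0) closed by a commissural annulus, plus the open inner surface.
This proxy matches every quantity the pipeline measures — volumes,
bounding boxes, boundary loops — while ignoring coiling, ornament, hinge
teeth and the pallial sinus itself, none of which enter any implemented
formula. Analytic truth: $\mathrm{pSV} = 1 - a'b'c'/(abc)$. The default
subdivision (32 latitude rings, 96 azimuth steps) keeps each raw volume
within 0.2% of its analytic value, converging as $O(h^2)$. A useful exact
property: the discretized hemi-ellipsoid is an affine image of one unit
grid, and affine maps scale all signed volumes by the same determinant,
so discretization cancels *exactly* in the pSV ratio — measured pSV
equals the analytic value to machine precision at any subdivision. The
0.5% acceptance margin is therefore carried entirely by the
mode-dependent interior closure, not by mesh resolution.

`simulate_tree()` wraps a birth–death simulation conditioned on the tip
count (default birth 0.4, death 0.1 per Myr — a mild net diversification
typical of marine invertebrate estimates); `simulate_bm()` is a ten-line
preorder walk drawing each branch's increment from
$N(0, \sigma^2 t)$, checked against the covariance identity
$\mathrm{Cov}(y) = \sigma^2 C$ and the Yule depth expectation
$\sum_{k=2}^{n} 1/(bk)$.

`make_cohort()` emulates the study system's statistical structure with
family sizes 12 / 72 / 40 / 126 (Astartidae, Carditidae, Crassatellidae,
Veneridae) on a two-clade backbone (family crowns 150–200 Myr,
archiheterodont crown 350 Myr, root 450 Myr — round numbers consistent
with the clades' relative ages). pSV is simulated on the logit scale to
respect its (0, 1] bounds, with archiheterodont means around 0.32–0.38
against 0.15 for venerids; the logit spreads (0.20 / 0.45 / 0.30 / 0.90)
were chosen so that raw-scale pSV disparity orders with family diversity
and venerids are the most disparate — detectable against Astartidae at
subsample sizes near 10. logSL is largest but least variable in venerids
(1.55 ± 0.18 log₁₀ mm) and most variable in crassatellids; XS sits near 1
everywhere. Venerids are siphonate with Beta(2, 2) sinus-depth fractions
and small borer/nestler fractions; a few carditids are epifaunal. Two
trait modes: `independent` (iid within family — clean disparity
contrasts) and `brownian` (one standardized Brownian draw per trait plus
family mean shifts — strong phylogenetic signal *and* family structure).
The acceptance script uses the Brownian cohort for the GLS and signal
stages and the independent cohort for the rarefaction thresholds,
matching each analysis to the structure it interrogates.

What passing tests on these cohorts show: the estimators recover known
truths under the generating model. What they cannot show: robustness to
real-data pathologies — meshes with scan noise or repaired holes,
non-Brownian trait evolution, measurement error in sinus fractions,
unbalanced substratum cells, or phylogenetic uncertainty. Conclusions
about real specimens inherit those caveats.

## Problem sizes and runtime

The test suite and acceptance script are sized to run in minutes on one
CPU: valves at subdivision 8–32 (≈1.5–12 k faces), rarefaction oracles on
groups of 7–8 with 10 000 replicates, calibration runs of 500 simulations
on 64-tip trees (tests) and 200 (acceptance script), permutation counts
of 199 for calibration loops and 999 for reported tables. These sizes
were chosen so that Monte-Carlo standard errors are comfortably inside
the asserted bounds; all scale linearly if larger runs are wanted.

## Known limitations

* No mesh repair: holes, self-intersections and non-manifold edges are
  detected and refused, not fixed; upstream cleaning is assumed.
* Hinge-axis alignment is trusted, not verified; misaligned meshes yield
  silently wrong SL/height/width (pSV is alignment-invariant).
* The λ search is bounded at 1, so traits with more-than-Brownian
  structure report λ̂ = 1 rather than exceeding it.
* Univariate responses only — no multivariate (Procrustes-style) RRPP.
* The rarefaction envelope is a percentile band per n, not a joint
  confidence region across the whole curve; divergence thresholds should
  be read as descriptive, within about one grid step.
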