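# valvemorph

Morphometric and macroevolutionary analysis of bivalve shell valves in R.

`valvemorph` is aimed at researchers comparing shell form across clades of
equivalve bivalves (e.g. the asiphonate Archiheterodonta — Astartidae,
Carditidae, Crassatellidae — against the siphonate Veneridae). It takes
three kinds of input — watertight triangle meshes of single valves
(micro-CT isosurfaces in STL/OBJ/PLY, hinge-aligned, mm), a specimen trait
table (CSV), and a time-calibrated phylogeny (Newick/NEXUS, branch lengths
in Myr) — and carries them through a complete, reproducible pipeline:

1. **Mesh volumetrics.** The shell-material volume of a valve is the sum of
   signed tetrahedra over its closed surface mesh,
   `V = (1/6) Σ v₀ · (v₁ × v₂)`. The internal (soft tissue + water) volume
   comes from the open interior surface, either by capping its commissural
   boundary loop (`capped`, default) or by the signed-tetrahedra sum about
   the surface centroid (`origin_fan`). Valve volumes are doubled
   (equivalve taxa) to give TSV and TIV, and **proportional shell volume**
   is `pSV = TSV / (TSV + TIV)` — a proxy for skeletal investment.
   **Shell length** SL is the anterior–posterior bounding-box extent;
   **cross-sectional aspect ratio** XS = width / height, with width twice
   the single-valve half-width.
2. **Functional classification.** Specimens are binned into six
   substratum-use groups (infaunal asiphonate, shallow/deep infaunal
   siphonate, borer, nestler, epifaunal) using habit annotations and
   burial-depth rules: siphonate species under 50 mm SL are shallow;
   larger ones are deep when the estimated siphon length
   (pallial-sinus depth fraction × SL) exceeds 30 mm.
3. **Disparity rarefaction.** Variance and cumulative range of pSV, logSL
   and XS per family, rarefied from n = 5 to the family size (1000
   subsamples without replacement per n), with median and 95% percentile
   envelopes; the sample size at which two families' envelopes diverge
   persistently estimates how many species are needed to tell their
   disparity apart, and `range_stabilization()` finds where a range curve
   flattens.
4. **Phylogenetic comparative statistics.** Brownian covariance from the
   tree (`phylo_vcv`), phylogenetic signal by Blomberg's K and ML Pagel's
   λ, Pearson correlations among the variables, and GLS linear models with
   sequential (type I) SS whose term-wise F statistics are tested by
   residual randomization (RRPP): for each term the reduced-model
   residuals are permuted and the ANOVA recomputed, giving permutation p
   values (floor 1/(n_perm+1)) and Z effect sizes on log F.

A synthetic-data module generates every input in code: hemi-ellipsoid
valves with analytically known volumes (`make_valve`), birth–death trees
(`simulate_tree`), Brownian traits (`simulate_bm`), and full cohorts with
study-like family structure (`make_cohort`), so the entire pipeline runs
and is tested without any external files.

## Worked example

```r
library(valvemorph)

# a synthetic valve: outer semi-axes 20 x 12 x 8 mm, shell 1.5 mm thick
sp <- shell_params(axes = c(20, 12, 8), thickness = 1.5)
v  <- make_valve(sp)
validate_mesh(v$shell)
#> mesh validity: closed=TRUE manifold=TRUE oriented=TRUE boundary_loops=0 components=1 area=2061
compute_metrics(v$shell, v$interior)
#>   valve_shell_volume valve_internal_volume      TSV      TIV    pSV SL height width     XS  logSL
#> 1           1374.992              2640.956 2749.983 5281.913 0.3424 40     24    16 0.6667 1.6021
sp$analytic_pSV
#> [1] 0.3424
```

The measured pSV matches the analytic value of the nested hemi-ellipsoid
exactly, SL is the full 40 mm anterior–posterior extent, and XS = 16/24
says the valve pair is two-thirds as wide as tall.

```r
# a 250-species synthetic cohort (12/72/40/126 per family) with Brownian
# traits and family shifts, then the phylogenetic permutation ANOVA
co  <- make_cohort(cohort_config(trait_mode = "brownian", seed = 101))
pgls_rrpp(pSV ~ substratum + logSL + XS + family, co$traits,
          phy = co$tree, n_perm = 999, seed = 1)
#> Permutation ANOVA (residual randomization), sequential SS
#> Model: pSV ~ substratum + logSL + XS + family
#> Permutations: 999
#>
#>             Df     SS    MS    Rsq      F       Z     p Sig
#> substratum   5 0.0004 1e-04 0.0274 1.3663  0.7775 0.221
#> logSL        1 0.0000 0e+00 0.0004 0.1011 -0.4418 0.747
#> XS           1 0.0001 1e-04 0.0094 2.3487  0.9686 0.129
#> family       2 0.0000 0e+00 0.0006 0.0710 -1.5677 0.930
#> Residuals  240 0.0136 1e-04 0.9622     NA      NA    NA
#> Total      249 0.0142    NA     NA     NA      NA    NA
```

Note the degrees of freedom: substratum takes 5, family only 2 of its 3 —
one family contrast is absorbed by the venerid-only substratum levels, and
once shared ancestry is accounted for, the family-level differences built
into this cohort are explained by the phylogeny rather than the factors.
Phylogenetic signal in the same trait is strong, as simulated:

```r
k <- blomberg_K(setNames(co$traits$pSV, co$traits$taxon), co$tree,
                n_perm = 999, seed = 3)
sprintf("Blomberg K = %.3f (p = %.3f)", k$K, k$p)
#> [1] "Blomberg K = 1.269 (p = 0.001)"
```

Disparity rarefaction distinguishes the least and most variable families
at small sample sizes:

```r
ast <- rarefy(subset(co$traits, family == "Astartidae")$pSV, "variance",
              group = "Astartidae", variable = "pSV", seed = 11)
ven <- rarefy(subset(co$traits, family == "Veneridae")$pSV, "variance",
              group = "Veneridae", variable = "pSV", seed = 12)
divergence_threshold(ast, ven)
#> [1] 11
```

`run_pipeline(run_config(...))` chains all stages and writes the
classified table, correlation matrix, rarefaction curves, ANOVA tables and
a JSON manifest to an output directory; see `vignettes/` for the methods
discussion.

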