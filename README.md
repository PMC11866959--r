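# ionsaxs

SAXS-guided Mg²⁺ placement and ensemble selection for RNA atomistic
models, in R.

Predicted RNA structures typically miss two things that solution
small-angle X-ray scattering (SAXS) is sensitive to: the Mg²⁺ ions that
neutralise and compact folded RNA, and the conformational plasticity that
no single rigid model captures. `ionsaxs` scores models against an
experimental profile and repairs both omissions:

1. **Profile calculation & fitting** — Debye-formula intensities
   `I(q) = Σᵢ Σⱼ fᵢ(q) fⱼ(q) sin(q dᵢⱼ)/(q dᵢⱼ)` with per-atom effective
   form factors `fᵢ = f_v − c₁G(q,c₁) f_s + c₂ sᵢ f_w` (excluded-volume
   and hydration-layer adjustments), scored by
   `χ² = S⁻¹ Σ ((I_exp − c·I)/σ)²` with the scale `c` optimised
   analytically and `c₁, c₂` fixed at 1 by default.
2. **Binding-site prediction** — surface probes; each probe's ≤8 Å atomic
   neighborhood becomes a distance-based graph classified by a small
   graph-attention + graph-convolution network (Mg²⁺ shell vs water
   shell); confident predictions are greedily clustered into candidate
   sites.
3. **Ion subset selection** — the Debye intensity of RNA ∪ subset is
   assembled exactly from precomputed subprofiles (RNA, ion self, RNA–ion
   and ion–ion cross terms), and subsets are enumerated by a beam-style
   branch-and-bound that stops when χ² no longer improves.
4. **Multistate models** — when no single decorated conformation fits
   within the noise (χ² ≤ 1.3), conformer subsets are enumerated with the
   same beam machinery and weighted by non-negative least squares.

Guinier, dimensionless-Kratky and model-based P(r) analytics, a
synthetic-data generator (helices, hinge-perturbed ensembles, noisy
profiles with calibrated errors, labelled coordination shells), tidy
(`tidy()`/`glance()`/`augment()`) accessors and ggplot2 `autoplot()`
methods are included. See `vignettes/saxs-ion-modelling.Rmd` for the
methods account.

## Worked example

Plant two Mg²⁺ ions on a synthetic helix, simulate a noisy "experimental"
profile, and let the package find them again:

```r
library(ionsaxs)

rna  <- assign_accessibility(make_helix(10))
q    <- seq(0, 0.5, length.out = 201)
cand <- generate_surface_probes(rna, density = 0.05)[c(40, 80, 120, 160), ]

# ground truth: ions at candidates 1 and 3, 1% noise
target <- simulate_profile(rna, q, ions = cand[c(1, 3), ], seed = 42)

fit_chi2(target, rna)
#> SAXS fit: chi2 = 1.3774  c = 1.072  c1 = 1.000  c2 = 1.000  (S = 201)

guinier_rg(target)
#> Guinier fit: Rg = 11.557 +/- 0.0635 A, I(0) = 8.381e+05 (44 points, qRg_max = 1.27)

cache <- precompute_subprofiles(rna, cand, q = q)
sel   <- branch_and_bound(target, cache, K = 50)
sel
#> Ion subset selection: 2 ion(s) {1,3}, chi2 = 0.9609
tidy(sel)
#> # A tibble: 3 × 3
#>   level  chi2 subset
#>   <int> <dbl> <chr>
#> 1     0 1.38  ""
#> 2     1 1.01  "3"
#> 3     2 0.961 "1,3"
```

Reading the numbers: the bare RNA misfits its own decorated profile
(χ² = 1.38, just outside the noise), the Guinier estimate matches the
helix's actual radius of gyration, and the branch-and-bound trajectory
shows χ² dropping to 0.96 — within the noise — exactly when the two
planted ions are added. A dimensionless Kratky plot
(`autoplot(dimensionless_kratky(target))`) peaks well beyond the
globular reference point (√3, 3/e), as expected for an elongated helix.

For classifier-driven placement, train on labelled shells and run the
whole pipeline:

```r
cl  <- train_site_classifier(make_neighborhoods(500, 500, seed = 1),
                             folds = 4, seed = 1)
res <- run_pipeline(models, experimental_profile, classifier = cl)
```

A thin command-line driver with subcommands `fit`, `place-ions`,
`multistate`, `simulate`, `train-classifier` and `run` is installed under
`exec/ionsaxs`.

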