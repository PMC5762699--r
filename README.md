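# mitonet

Percolation and complexity analysis of mitochondrial network morphology.

Mitochondria form cell-wide networks of tubules remodelled by fission and
fusion, and a body of evidence suggests healthy cells keep that balance
near a percolation transition: oxidative stress fragments the network
(subcritical), fusion-protein over-expression hyperfuses it
(supercritical), and control networks sit near the critical point, where
cluster sizes are maximally heterogeneous. `mitonet` provides the complete
toolchain to quantify this from 2-D fluorescence images and to interpret
the measurements against an explicit kinetic model:

- **Image pipeline** — binarize at a sweep of thresholds *th*, thin to
  one-pixel skeletons (topology-preserving), label 8-connected clusters of
  mass *s*, classify pixel degrees *k* ∈ {1,2,3}, extract 1-1 / 1-3 / 3-3
  segments.
- **Percolation statistics** — cluster-mass CCDF `P(s) = Pr(S ≥ s)` and
  its collapse under `s/⟨s⟩` onto a power law `P(s) ~ s^(1-γ)`; mass
  entropy `H = −Σ p_i log p_i` (with `p_i` the pixel fraction in clusters
  of mass *i*) and the critical threshold *th\** at its maximum;
  box-counting fractal dimension `D_f`; finite-size scaling of `N_g/N`;
  Lempel–Ziv complexity z-score `Z = (K − μ_R)/σ_R` against
  occupancy-preserving randomizations.
- **Fission/fusion simulator** — Gillespie dynamics over `L` dimers whose
  tips fuse tip-to-tip (`2X₁ → X₂`, rate `a₁`) and tip-to-side
  (`X₁ + X₂ → X₃`, rate `a₂`) with fission reversals (`b₁`,
  `b₂ = 3/2·b₁`), controlled by the relative rates `c₁ = a₁/b₁`,
  `c₂ = a₂/b₂`. Observables: mean degree ⟨k⟩, giant-cluster fraction
  ⟨N_g/N⟩, mean cluster size ⟨s⟩ excluding the giant.
- **Phase diagram & matching** — sweep `(c₁, c₂)`, extract the critical
  line from the interior ⟨s⟩ maxima, invert measured (⟨k⟩, N_g/N) pairs
  onto the diagram and classify networks as subcritical / critical /
  supercritical.
- **Synthetic micrographs** — render simulated networks as pseudo-confocal
  frames (curvilinear tubules, additive fluorescence, Gaussian PSF and
  camera noise) so the whole analysis is testable without microscope data.

The methods vignette (`vignettes/mitonet-methods.Rmd`) documents the
model, every tunable parameter, the generator's design and its limits.

## Worked example

Render a balanced (near-critical) synthetic network, sweep thresholds,
and fit the collapsed cluster-mass exponent:

```r
library(mitonet)

ph  <- phenotype_presets(L = 1000)$balanced      # c1 = 0.1, c2 = 3e-4
img <- generate_model_image(ph, render_params(seed = 1))
prof <- threshold_sweep(img, seq(0.06, 0.30, by = 0.03), keep_masses = TRUE)
round(as.data.frame(prof), 3)
#>    th   n_c  mean_s mean_k ng_over_n entropy
#>  0.06  2061 144.377  2.315     0.910   0.680
#>  0.09 12159   9.806  1.900     0.045   3.484
#>  0.12  1265  23.089  2.056     0.094   3.501
#>  0.15    71 248.915  2.119     0.116   3.524
#>  0.18    57 260.404  2.091     0.114   3.528
#>  0.21    71 190.437  2.067     0.114   3.631
#>  0.24    89 142.517  2.045     0.115   3.789
#>  0.27   114 106.518  2.027     0.069   3.956
#>  0.30   129  91.109  2.032     0.064   4.103

fit <- collapse_and_fit_exponent(lapply(attr(prof, "masses"), ccdf))
fit$gamma
#> [1] 1.741
```

At very low thresholds the whole frame is one lacy cluster
(`N_g/N = 0.91`); the cluster count peaks as the background noise band is
cut; above it the network's own clusters dominate and fade gradually. The
fitted exponent γ ≈ 1.7 places the mass distribution in the heavy-tailed
regime expected near criticality. The same simulator that generated the
image provides the reference curve for inversion:

```r
obs <- run_model(model_params(L = 1000, c1 = 0.1, c2 = 3e-4,
                              n_reps = 20, seed = 1))
c(obs$mean_k, obs$ng_over_n)
#> [1] 1.902 0.163
```

The numbered scripts under `analysis/` chain these stages into the full
study: `01` renders phenotype images, `02` analyzes them, `03` builds the
phase diagram and critical line, `04` matches images onto the diagram,
`05` runs the multi-seed study with the phenotype-ordering checks.

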