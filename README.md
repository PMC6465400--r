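# strixsel

Within-home-range resource selection of sympatric forest owls from
airborne-lidar forest-structure metrics.

## The problem

Northern spotted owls (*Strix occidentalis caurina*) and invasive barred
owls (*S. varia*) are ecologically similar forest predators whose
coexistence may hinge on fine-scale partitioning of three-dimensional
forest structure. Testing that requires linking telemetry relocations to
lidar-derived canopy and terrain covariates *within* each bird's seasonal
home range, where availability is individual-specific. `strixsel`
implements that analysis end to end for researchers in movement ecology and
habitat selection:

* **Lidar metrics** — 30 m grids of dominant canopy height (HEIGHT, the
  95th percentile of returns > 2 m), canopy cover (CANCOV), rumple
  (canopy-surface rugosity), strata cover (D4to8, S2to4), slope, solar
  radiation index (SRI), multi-window topographic position (TPI), and
  distance to permanent stream, extracted as 150 m means around points.
* **Home ranges** — 95% fixed-kernel seasonal ranges with
  likelihood-cross-validation bandwidths, joint ranges for breeding pairs,
  a >27-relocation floor, and movement-rate buffers (520 m spotted, 350 m
  barred).
* **Choice sets** — each used location paired with 5 random available
  points from the buffered range, all points ≥ 300 m apart, censored for
  forest harvested between telemetry and lidar dates, with an independent
  post-hoc constraint audit.
* **Inference** — a hierarchical Bayesian conditional multinomial-logit
  model fitted by an adaptive MCMC sampler (Rcpp core), split-chain R-hat
  diagnostics, WAIC ranking of the candidate model set, and 10-fold
  cross-validated predictive scores against the 17% random baseline.
* **Synthetic data** — a landscape/telemetry generator with known selection
  coefficients, so every stage is testable by ground-truth recovery without
  field or lidar downloads.

## The model

A choice set contrasts the used location against its 5 available points.
With standardized covariates `x_j` and coefficients `β`, the likelihood of
the used location (j = 1) is the conditional logit

    P(used | set) = exp(x_1'β) / Σ_{j=1..6} exp(x_j'β)

Individual-by-season coefficient vectors are drawn from species-by-season
normal populations, `β_u[t] ~ N(μ_g[t], σ_g[t])`, with vague priors
`μ ~ N(0, variance 100)` and `σ ~ half-Normal(2)`. Covariates are
standardized over all locations, so `exp(μ)` is the selection ratio per one
SD of a covariate. Convergence requires split-chain R̂ ≤ 1.1 for every
hyper-parameter; 2,000 draws per chain are retained from 3 chains.

## Worked example

Simulate a 4 × 4 km landscape, lidar returns, eight owls with known
selection coefficients (μ = +1 HEIGHT, +0.5 CANCOV, −0.5 SLOPE per grid SD),
then run the full analysis:

```r
library(strixsel)

ls    <- gen_landscape(extent = c(4000, 4000), harvest_fraction = 0.06, seed = 1)
cloud <- gen_returns(ls, density_per_m2 = 0.3, seed = 2)
grid  <- compute_metric_grids(cloud, ls$dem, ls$streams, lat = 44)

owls  <- gen_owls(c(spotted = 4, barred = 4), extent = c(4000, 4000),
                  margin = 1500, seed = 3)
truth <- make_truth(c("HEIGHT", "CANCOV", "SLOPE"), mu = c(1, 0.5, -0.5),
                    sigma = 0.3, owls = owls, seed = 4)
telemetry <- gen_telemetry_all(owls, grid, truth, n_locs = 120, seed = 5)

ranges <- build_home_ranges(telemetry, owls)
cs     <- build_choice_sets(telemetry, ranges, grid, harvest = ls$harvest,
                            lidar_date = ls$lidar_date,
                            layers = c("HEIGHT", "CANCOV", "SLOPE"), seed = 6)
design <- dcm_design(standardize_design(cs, c("HEIGHT", "CANCOV", "SLOPE")))
fit    <- fit_hierarchical(design, chains = 3, seed = 7)
```

The run prints (abridged):

```
<home_range> spotted_1+spotted_2 [spotted, breeding] n=120 h=203 m area=755 ha (buffered 1489 ha)
<dcm_design> 580 sets x 6 alternatives, 16 units, 4 groups
<dcm_fit> 3 terms, 16 units, 3 chains x 2000 draws (warmup 1500)
max split R-hat (hyper-parameters): 1.065 [certified]

   species      season   term  mean     lo    hi    f selection_ratio supported
1   barred    breeding HEIGHT  0.94  0.535  1.37 1.00            2.55      TRUE
3   barred    breeding  SLOPE -1.47 -2.390 -0.55 0.99            0.23      TRUE
7  spotted    breeding HEIGHT  0.91  0.016  1.87 0.98            2.49      TRUE
10 spotted nonbreeding HEIGHT  1.05  0.533  1.57 1.00            2.85      TRUE
...
WAIC 1343.6 (lppd -639.5, p_waic 32.3); null WAIC 2078.4
10-fold CV predictive score: 56.6% (random baseline 16.7%)
```

Every coefficient recovers the sign of its generating value with strong
posterior support (f ≥ 0.9), the joint pair range is built from pooled
breeding relocations, 351 of 1,920 relocations were censored by the
simulated harvest layer, the fitted model beats the null by ~735 WAIC
units, and the predictive score more than triples the random baseline.
`summarize_coefficients()`, `seasonal_overlap()`, `response_curve()`,
`relative_importance()` and `used_vs_available_tests()` produce the
standard reporting tables; see the vignette in `vignettes/` for the model,
its assumptions, and every numerical convention.

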