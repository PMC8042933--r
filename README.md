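# polynest

Spatially explicit analysis of social polygyny in nest-box breeding
populations of territorial birds.

## The problem this package addresses

In facultatively polygynous passerines, a small fraction of males hold two
nest sites and attract a second ("secondary") female. Whether a given
male-female combination turns polygynous depends on the pair's *local*
breeding context — distance between nests, how early each bird breeds
relative to its neighbours, local density, and phenotypes relative to
neighbours — not on population-wide averages. `polynest` is for behavioural
and evolutionary ecologists who have (or want to simulate) multi-season
nest-box data with coordinates, laying dates, phenotypes and mating
statuses, and who want to analyse polygyny and its fitness consequences at
the neighbourhood scale.

The core machinery:

* **Territories and neighbour orders.** Each season's occupied boxes are
  tessellated into Thiessen (Voronoi) polygons; territories sharing a
  boundary segment are 1st-order neighbours, neighbours-of-neighbours
  2nd-order, and so on (shortest path on the adjacency graph).
* **Candidate pairs.** All male × female combinations of a season (minus
  each male's own social mate and the ambiguous "unassisted" females), kept
  to neighbour order ≤ 2, with neighbourhood-relative covariates: local
  asynchrony (focal laying date − neighbourhood mean; positive = later),
  local density, and relative phenotypes.
* **Polygyny model.** For combination *i* of male *m* and female *f*,

  `logit P(y_i = 1) = beta_0 + x_i' beta + u_m + v_f`,

  a binomial GLMM over 15 standardized terms (distance; per-sex asynchrony,
  density, relative tarsus, wing, orthogonal quadratic age; male forehead
  patch and dorsal blackness) with crossed male/female random intercepts,
  where `y_i = 1` only for the realized polygynous male-secondary pairing.
* **Phenology models.** Per sex, a linear mixed model of local asynchrony
  on relative phenotype with individual and year intercepts — does
  phenotype set who breeds locally early?
* **Fitness models.** Zero-inflated count regressions of female fitness on
  mating status (monogamous reference): recruits via a mean-parameterized
  Conway–Maxwell–Poisson kernel, lifetime grand-offspring via a negative
  binomial, each with a year intercept and a breeding-date control, with an
  AICc ladder over {Poisson, CMP, NB} × {zero-inflation} × {year intercept}
  and a simulation-based power module for the status contrasts.

Because such field datasets are rarely public, the package ships a
synthetic-population generator (`sim_config()`, `simulate_population()`)
whose generating effect structure is exactly what the models assume;
parameter-recovery simulation against those generating values is the
package's correctness surface. See the vignette
(`vignettes/spatial-polygyny-methods.Rmd`) for the models, the generator's
assumptions, calibration, and known structural limits.

## Worked example

```r
library(polynest)

cfg <- sim_config()                       # 19 seasons, 180 boxes, ~4% secondary share
pop <- simulate_population(cfg, seed = 1)
pop
#> Synthetic breeding population
#>   seasons: 19   female-nests: 2642
#>   status counts: monogamous 2376, primary 95, secondary 95, unassisted 76

pairs <- build_pair_data(pop)             # order <= 2 candidate combinations
nrow(pairs)
#> [1] 18786

fit <- fit_polygyny_glmm(pairs)
fit$coefficients[c(1, 2, 3, 9), ]
#>        term   estimate        se          z            p
#> 1 intercept -5.7246011 0.1447281 -39.554170 0.000000e+00
#> 2  distance -0.4060353 0.1631852  -2.488188 1.283959e-02
#> 3    f_asyn  0.7743990 0.1236420   6.263238 3.770648e-10
#> 9    m_asyn  0.2030222 0.1166533   1.740389 8.179071e-02

phen <- fit_phenology_lmm(pairs, "male")
phen$ranef
#>      group   variance        sd
#> 1       id 30.6185887 5.5334066
#> 2     year  0.2863828 0.5351474
#> 3 Residual 12.5471008 3.5421887

rec <- reclassify_unassisted(pop$fitness, "exclude")
fit_zi_count_glmm(rec, "recruits", family = "cmp")$coefficients
#>                      term     estimate         se           z            p
#> 1               intercept -0.720108712 0.15952499 -4.51408085 6.359196e-06
#> 2   primary_vs_monogamous -0.003770315 0.17086179 -0.02206646 9.823949e-01
#> 3 secondary_vs_monogamous -0.379072253 0.22313771 -1.69882648 8.935188e-02
#> 4           breeding_date -0.305101635 0.03430718 -8.89322956 5.935801e-19
```

Reading the output: the strongest polygyny term is the female's local
asynchrony — females laying late relative to their neighbourhood are the
ones found as secondary females, an association that partly reflects the
status definition itself (a secondary lays after the primary by
definition; see the vignette). Distance is negative (polygyny is local)
and the phenotype terms are weak. Secondary females do not differ
significantly from monogamous ones in recruits, while later breeding
lowers direct fitness. The phenology model splits laying-date variation
into a large repeatable individual component, a near-zero year component
(local asynchrony cancels season-wide shifts by construction) and a
residual.
`run_pipeline(cfg, "out/", seed = 1)` runs every stage and writes CSV /
GeoJSON / JSON artifacts plus a markdown report.

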