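# polmorph

Analysis toolkit for colour-polymorphic, deceptively pollinated orchid
populations — for pollination ecologists and conservation planners who
need to know whether an insect pollinator can *see* the colour variation
humans classify, whether any colour variant is disadvantaged in natural
fruit set, and whether the variants are genetically differentiated.

The package has three analytical strands plus seeded generators for every
input:

1. **Pollinator colour vision.** Flower reflectance spectra are modelled
   in the hymenopteran hexagon colour space. For receptor class *i* with
   sensitivity *Sᵢ(λ)*, illuminant *I(λ)* and adaptation background
   *R_b(λ)*, the von Kries-adapted quantum catch is

   *Pᵢ = ∫I Sᵢ R dλ / ∫I Sᵢ R_b dλ*,

   excitation *Eᵢ = Pᵢ/(Pᵢ+1)*, and loci are projected to
   *x = (√3/2)(E_G − E_UV)*, *y = E_B − (E_UV+E_G)/2*. Pairwise Euclidean
   distances feed a psychometric discrimination curve
   *P(d) = 0.5 + (A−0.5)/(1+e^−(d−d₀)/s)* calibrated on bundled
   behavioural data; pairs are classified against the strict 70%
   discrimination threshold.

2. **Reproductive success.** Contingency-table χ² tests (Pearson, no
   continuity correction), goodness-of-fit tests, OLS regressions of fruit
   on flower numbers, five association measures verified against
   brute-force oracles, pooled and per-year fruit-set rates,
   Kruskal–Wallis viability tests and capsule-formation summaries.

3. **Genetic diversity.** Dominant-marker (ISSR-style) statistics under
   the Hardy–Weinberg square-root estimator (N_e, H_e, uH_e, Shannon I),
   AMOVA φ_PT with seeded permutation tests, Jukes–Cantor sequence
   distances with pairwise deletion and saturation handling, and
   within/among-group diversities with a bootstrap-SE coefficient of
   differentiation.

See `vignettes/colour-polymorphism-methods.Rmd` for the full model
descriptions, parameter defaults and design decisions.

## Worked example

Calibrate the psychometric curve on the bundled distance–probability pairs
and summarize which flower-part pairs a bee could tell apart:

```r
library(polmorph)

pairs <- discrimination_pairs()
fit <- fit_psychometric(pairs$distance, pairs$probability)
fit
#> <psychometric: A = 0.8415, d0 = 0.0856, s = 0.0071, RMSE = 0.0056 (n = 21)>

dm <- discrimination_matrix()
summarize_comparisons(dm$distance, dm$part, dm$flower, fit)
#>          comparison n_pairs n_above fraction_above
#> 1       sepal-sepal       3       2             67
#> 2 labellum-labellum       6       4             67
#> 3     within-flower       3       2             67
#> 4      cross-flower       9       7             78
```

The fitted curve sits at chance (0.5) for near-identical colours, rises
steeply around 0.07–0.10 hexagon units and saturates near 0.84; 67% of
sepal pairs, 67% of labellum pairs and 78% of cross-part pairs between
flowers lie above the 70% discrimination threshold — the colour
polymorphism is visible to a hymenopteran, not just to humans.

Fruit set from the bundled census, by colour category:

```r
rec <- records_from_counts(fruiting_counts(), "category")
flowers <- rowSums(tabulate_records(rec, "category", "year", "flowers"))
fruits  <- rowSums(tabulate_records(rec, "category", "year", "fruits"))
linreg(flowers, fruits)[c("slope", "intercept", "r_squared")]
#> $slope     0.2119
#> $intercept -1.4783
#> $r_squared 0.9562

success_rates(rec, "overall")
#>     level pooled_pct mean_pct   se_pct pct_2003 pct_2004
#> 1 overall   15.67164 15.73661 1.450893 14.28571  17.1875
```

Fruit number tracks flower number across categories almost perfectly
(R² = 0.956): no colour variant is over- or under-pollinated relative to
its abundance, and overall natural fruit set is 15.7%.

Differentiation recovery on synthetic dominant markers:

```r
m <- gen_marker_matrix(differentiation = 0.085, seed = 42)
a <- amova_phipt(m, n_permutations = 999, seed = 1)
#> phi_PT = 0.100 (p = 0.001), %among = 10.0, %within = 90.0
```

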