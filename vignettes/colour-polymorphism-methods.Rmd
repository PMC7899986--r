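---
title: "Methods: pollinator colour vision, fruiting statistics and diversity for a colour-polymorphic orchid population"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: pollinator colour vision, fruiting statistics and diversity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(polmorph)
```

`polmorph` analyses a colour-polymorphic, deceptively pollinated orchid
population along three strands: (1) whether a hymenopteran pollinator can
*see* the colour differences humans use to classify the flowers, (2) whether
colour category or growing patch affects natural fruiting success, and
(3) whether the colour variants are genetically differentiated. This
vignette explains each model, its assumptions, the tunable parameters, and
the numerical and design choices; it states no empirical result that the
package's tests and acceptance script do not themselves compute.

## 1. Hymenopteran colour vision in the hexagon

### Quantum catch and von Kries adaptation

A trichromatic hymenopteran eye has UV, blue and green photoreceptor
classes. For a flower reflectance $R(\lambda)$ viewed under illuminant
$I(\lambda)$, the quantum catch of receptor class $i$ with spectral
sensitivity $S_i(\lambda)$, adapted to a background $R_b(\lambda)$, is

$$
P_i \;=\; \frac{\int I(\lambda)\, S_i(\lambda)\, R(\lambda)\, d\lambda}
               {\int I(\lambda)\, S_i(\lambda)\, R_b(\lambda)\, d\lambda}.
$$

The denominator is the von Kries normalization: the eye rescales each
channel by its catch from the adaptation background, so the background
itself always yields $P_i = 1$. Integrals are trapezoidal on the 300–650 nm
grid at 10 nm — the resolution of the reflectance measurements the pipeline
is built around; finer grids change catches only at the fourth decimal for
smooth floral spectra.

Photoreceptor excitation follows the usual hyperbolic transduction
$E_i = P_i/(P_i + 1)$, mapping the background to half-maximal excitation
$E = 0.5$ and bounding $E \in [0, 1)$.

### The hexagon projection

The three excitations are projected into a plane:

$$
x = \frac{\sqrt{3}}{2}\,(E_G - E_{UV}), \qquad
y = E_B - \tfrac{1}{2}(E_{UV} + E_G),
$$

with UV at the lower left, green at the lower right, blue at the top, and
the adapted background at the origin. Two derived signals matter
behaviourally:

* **colour contrast** — Euclidean distance of a locus from the origin
  (chromatic signal strength);
* **green contrast** — $|E_G - 0.5|$, the achromatic long-wavelength
  signal hymenopterans use to detect small targets. The bundled contrast
  table is consistent in magnitude with this definition.

Perceptual difference between two stimuli is the Euclidean distance between
their loci.

### Parameters and built-in assets

* **Illuminant** — tabulated CIE D65 (open midday sky), shipped as
  plain-text data. Bee photoreceptors count photons, not energy, so the
  spectral power is multiplied by $\lambda$ (the remaining constants cancel
  in the von Kries ratio) and normalized to 1 at 550 nm.
* **Receptor sensitivities** — built from a standard A1 visual-pigment
  alpha-band absorbance template parameterized only by the peak wavelength,
  with honeybee defaults $\lambda_{max} = 344, 436, 544$ nm (UV/B/G). The
  measured honeybee curves the literature uses are not distributed in
  tabulated form; a pigment nomogram reproduces them closely, is exactly
  reproducible from a formula, and keeps $\lambda_{max}$ configurable. The
  beta (short-wavelength) absorbance band is omitted: within 300–650 nm its
  contribution is small for these peak positions and omitting it keeps the
  template unimodal, which the tests assert. Curves are tabulated on the
  standard grid augmented with the exact $\lambda_{max}$ node and normalized
  to 1 there, so resampling recovers the peak exactly.
* **Adaptation background** — flat 10% reflectance by default, the
  conventional stand-in for vegetation-adapted viewing.
* **Negative reflectance readings** (instrument noise below the dark
  reference) are clipped to 0 with a warning; values above 1 are kept,
  since a petal can out-reflect the white standard.

## 2. The psychometric discrimination function

Behavioural experiments under *absolute conditioning* (a single rewarded
colour, no distractor) yield a probability of correct discrimination as a
function of hexagon distance $d$. The package models it as a
three-parameter logistic with the lower asymptote pinned at chance:

$$
P(d) = 0.5 + \frac{A - 0.5}{1 + e^{-(d - d_0)/s}},
$$

with upper asymptote $A \in (0.5, 1]$, midpoint $d_0$ and slope scale $s$
(hexagon units). The published parameterizations of this curve live in
cited prior behavioural work rather than in a reusable table, so the
package calibrates the curve by least squares on the bundled 21
(distance, probability) pairs; this is a reconstruction, and the fit
quality (RMSE ≤ 0.02 on those pairs) is asserted in the tests rather than
assumed.

Numerical choices: the fit runs Nelder–Mead in an unconstrained
reparameterization ($A$ through a scaled logistic, $d_0$ and $s$ through
logs), started from $A = \max p$, $d_0 = \mathrm{median}(d)$,
$s = \mathrm{range}(d)/10$ and restarted from 5 jittered seeds (seeded,
reproducible); the best RMSE wins. A fit whose asymptote collapses to
chance ($A - 0.5 < 10^{-3}$) is flagged degenerate. The fitted curve is
monotone by construction, which makes threshold classification
order-consistent.

A pair of colours counts as discriminable when $P(d)$ **strictly exceeds**
0.70 — "exceeds" is taken literally, so exactly 0.70 is below threshold.
Class summaries (sepal–sepal, labellum–labellum, within-flower,
cross-flower) report whole-percent fractions, matching the precision such
results are quoted at.

```{r psychometric}
pairs <- discrimination_pairs()
fit <- fit_psychometric(pairs$distance, pairs$probability)
fit
dm <- discrimination_matrix()
summarize_comparisons(dm$distance, dm$part, dm$flower, fit)
```

## 3. Reproductive-success statistics

Tagged-plant records carry a year, a colour category (1–5), a patch (1–5)
and a fruiting flag; the bundled census tables can be expanded into
per-plant records with `records_from_counts()` (the two classifiers are
published as separate margins, so an expanded record carries one of them
and `NA` for the other).

* **Chi-square tests** (`chisq_rxc`, `chisq_gof`) use the Pearson
  statistic with **no continuity correction** — the convention the recorded
  census statistics follow. Expected counts below 5 produce a warning but
  do not block, because real field tables routinely violate that rule of
  thumb.
* **`chisq_on_values`** reproduces a construction sometimes applied to
  percentage-success figures: $\sum (v - \bar v)^2/\bar v$ with the values
  treated as counts. Percentages are not Poisson counts, so this is not a
  valid test; the function exists to reproduce recorded analyses and emits
  a methodological warning on every call.
* **Regression** (`linreg`) is ordinary least squares of fruit numbers on
  flower numbers across strata, reporting slope, intercept and $R^2$.
* **Association measures** between category/patch and fruiting use the
  standard definitions: Cramér's $V^2 = \chi^2/(N(\min(r,c)-1))$, Pearson's
  $r$ on raw codes, Spearman's $\rho$ on midranks, Kendall's $\tau_b$ with
  tie correction, and Goodman–Kruskal's $\tau$ as proportional reduction in
  error predicting the outcome. The tests verify each against brute-force
  pair-counting oracles on exhaustively enumerated small tables; recorded
  association values whose construction could not be reconstructed are not
  used as test anchors.
* **Success rates** report both conventions found in field tables: the
  pooled rate $100\,\Sigma\text{fruits}/\Sigma\text{flowers}$ and the mean
  of yearly percentages with SE $= \mathrm{sd}/\sqrt{n_\text{years}}$ (for
  two years, the half-range).
* **Seed viability** uses the Kruskal–Wallis rank test (the data are
  percentages and not normalizable); all-identical observations return
  $H = 0$ rather than the 0/0 the tie correction would produce.
* **Capsule summaries** exclude grazed, lost and moldy capsules from the
  per-cell denominators, while the overall rate counts capsules over all
  crosses.

```{r repro}
rec <- records_from_counts(fruiting_counts(), "category")
flowers <- rowSums(tabulate_records(rec, "category", "year", "flowers"))
fruits <- rowSums(tabulate_records(rec, "category", "year", "fruits"))
linreg(flowers, fruits)[c("slope", "intercept", "r_squared")]
success_rates(rec, "overall")
```

## 4. Marker and sequence diversity

### Dominant binary markers

ISSR-style fingerprints are dominant: a band is present for both the
homozygote and the heterozygote, so allele frequencies must be inferred.
The package uses the Hardy–Weinberg square-root estimator
$q = \sqrt{1 - \text{band frequency}}$ — the simplest defensible default;
bias-corrected estimators (e.g. Lynch–Milligan) are out of scope. From
$(p, q)$ per locus: $H_e = 2pq$, $N_e = 1/(p^2+q^2)$,
$I = -(p\ln p + q\ln q)$ and $uH_e = H_e \cdot 2N/(2N-1)$, with means and
standard errors over loci.

### AMOVA φ-PT

Differentiation among populations uses a two-level analysis of molecular
variance on squared-Euclidean band distances (for 0/1 data, the number of
band differences). Variance components come from the standard moment
equations with the unequal-size correction
$n_0 = (N - \sum n_g^2/N)/(k-1)$, and
$\varphi_{PT} = \sigma^2_a/(\sigma^2_a + \sigma^2_w)$. Significance is by
permutation of population labels (default 999, seeded) with the add-one
correction $p = (\#\{\varphi^* \ge \varphi\} + 1)/(B + 1)$. Negative
variance components are reported as such in $\varphi_{PT}$ (the estimator
is unbiased around zero under no differentiation) but floored at zero for
the within/among percentage display.

### Sequences

Jukes–Cantor distances use pairwise deletion by default (sites with a gap
or N in either sequence of a pair are dropped; complete deletion is
available by flag), $d = -\frac{3}{4}\ln(1 - \frac{4}{3}\hat p)$, with
saturated pairs ($\hat p \ge 3/4$) and pairs without comparable sites
returned as `NA` with a reason rather than a number. Group diversities
report mean within-group, among-group and total pairwise distance; the
coefficient of differentiation is the Nei-style
$(d_T - d_S)/d_T$ with $d_S$ the unweighted average within-group
diversity (no formula is attached to the recorded value, so the standard
definition is used), undefined when $d_T = 0$. Its standard error comes
from a seeded bootstrap over alignment sites (default 500 replicates),
which `group_diversities()` takes the alignment (not a bare distance
matrix) to support.

## 5. Synthetic-data generators

Every input has a seeded generator, so the full pipeline is testable
without downloads, and the generators' defaults are the study conditions
rather than tuning knobs:

* **`gen_spectrum`** — baseline + sigmoid long-pass edge (the step-up near
  400 nm of yellow-green tepals) + Gaussian red bump (crimson labellum
  pigment) + optional UV bump + Gaussian noise, clipped to $[0, 1.2]$.
* **`gen_plant_records`** — two census years of 70 and 64 plants; category
  mix 21/26/30/15/8%; patch mix (0.261, 0.179, 0.075, 0.119, 0.366) and
  per-patch fruiting probabilities (0.314, 0.250, 0.100, 0.063, 0.041)
  taken from the fruiting census, so patch drives success, category does
  not, and the expected overall fruit set is 15.7%. The patch mix
  deliberately uses the fruiting-census distribution rather than the
  three-year flowering mix: only the former makes the overall rate
  consistent with the per-patch rates.
* **`gen_marker_matrix`** — per locus a mean band frequency
  $\bar p \sim U(0.2, 0.8)$ and population frequencies from a
  Balding–Nichols beta distribution with variance
  $F\bar p(1-\bar p)$, $F$ = the requested differentiation. For a 0/1 band
  indicator the among-population variance is then exactly $F\bar p(1-\bar p)$
  and the expected within-population variance $(1-F)\bar p(1-\bar p)$, so
  the expected φ-PT equals the requested level *analytically* — no
  empirical calibration table is needed, which is why none is shipped.
* **`gen_alignment`** — Jukes–Cantor evolution on a star topology: group
  ancestors at branch length $(d_{between}-d_{within})/2$ from the root,
  tips at $d_{within}/2$, giving expected pairwise distances equal to the
  targets. A star suffices for distance-recovery testing and avoids tree
  I/O.

All generators restore the caller's RNG stream, and identical seeds give
bit-identical output (asserted in tests).

**What the generators do not emulate** — and therefore what passing tests
do not demonstrate about real data: spatial clustering of plants within
patches (records are i.i.d. draws), year-to-year demographic correlation,
linkage among marker loci, rate variation among sites or lineages, and any
pollinator-behaviour feedback (e.g. negative frequency-dependent
selection). Recovery results on synthetic data show estimator correctness
under the stated models, not robustness to these realistic violations.

## 6. Problem sizes and runtime choices

The test suite runs at desk scale: the recovery experiments use 20
replicate marker matrices (5 populations × 6 individuals, 60 loci, 999
permutations each) for φ-PT, alignments of 10,000 sites for Jukes–Cantor
recovery, and exhaustive enumeration of all 2×2 and 2×3 contingency tables
with cell counts ≤ 4 for the association-measure oracles. These sizes were
chosen as the smallest at which the statistical tolerances (±0.03 on φ-PT,
±0.01 on JC distance) are comfortably non-flaky.

## 7. Known limitations

* The hexagon pipeline never claims to regenerate the bundled contrast and
  distance tables from raw spectra — the raw curves behind them are not
  distributed — so those tables are consumed as recorded values, and one
  recorded pair violates the triangle inequality by 0.003 (printed-rounding
  scale), which consistency checks tolerate at 0.005.
* The psychometric calibration is a reconstruction from 21 pairs; its
  asymptote (≈0.84) and steep transition (≈0.07–0.10 hexagon units) are
  data-driven, not taken from the original behavioural fits.
* `chisq_on_values` is intentionally non-standard (see above).
* Bundled category and patch census margins cannot be joined into a
  category × patch table; expanded records carry `NA` for the unobserved
  classifier.
* No receptor-noise (ΔS) colour space, no tetrachromat support, no
  multi-level AMOVA, no tree inference.
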