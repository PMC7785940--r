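---
title: "Methods: modeling and optimizing culture-medium mineral composition"
author: "phytomedia"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: modeling and optimizing culture-medium mineral composition}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The problem

Plant tissue culture media are recipes of mineral salts, and the response of
explants — how many shoots regenerate, how long they grow, how large the
leaves get, and whether disorders such as basal callus or hyperhydricity
appear — depends on the ions those salts release, not on the salts
themselves. Because several salts release the same ion (sulfate arrives with
magnesium, manganese, zinc, copper and iron; potassium with nitrate, iodide
and phosphate), salt-level analyses suffer from *ion confounding*: the
effect of an individual ion cannot be attributed. `phytomedia` implements a
complete analysis pipeline around this problem for hardy-kiwi (kiwiberry,
*Actinidia arguta*) micropropagation:

1. **Stoichiometry** — convert factor-scaled salt recipes (mg/L) into
   18-ion profiles (mM) through a versioned salt registry.
2. **Design generation** — D-optimal sampling of a five-factor design
   space of multipliers applied to salt groups of the Murashige–Skoog (MS)
   medium.
3. **Neurofuzzy modeling** — parsimonious additive tensor B-spline models
   of each response from the ion profiles, selected by a structural-risk
   criterion and read out as fuzzy IF–THEN rules with membership degrees.
4. **Neural-network modeling and optimization** — per-response multilayer
   perceptrons on the 14-salt representation, searched by a
   desirability-weighted genetic algorithm for an improved medium.
5. **Validation statistics** — Welch tests from printed summaries, ANOVA
   with Tukey HSD letters, and Kruskal–Wallis tests for ordinal scores.
6. **Synthetic experiments** — a generator with the vessel/explant
   replicate hierarchy of micropropagation trials, used to benchmark every
   stage without access to raw data.

The bundled study data comprise 34 media: 33 design treatments plus the MS
control, with six responses each — shoot number (SN), shoot length (SL,
cm), leaf area (LA, cm²), and ordinal shoot quality (SQ, 1–5), basal
callus (BC, 1–4) and hyperhydricity (H, 1–3) scores, recorded as
mean ± SD over 45 explants (5 vessels × 3 explants × 3 repetitions).

# Stoichiometry

Each salt contributes `conc / molar_mass` mmol/L, multiplied by integer
stoichiometric yields (e.g. CaCl₂·2H₂O → 1 Ca²⁺ + 2 Cl⁻). Molar masses are
fixed in a versioned registry (`inst/extdata/salt_registry.csv`). Three
conventions matter and are deliberate:

* Sodium molybdate releases one molybdate anion (kept under the label
  `MoO2`, the study's notation) and two Na⁺.
* Boric acid maps to one borate; Na₂EDTA·2H₂O to one EDTA⁻ and two Na⁺.
  No speciation or chelation equilibrium is modeled — Fe²⁺ and EDTA⁻ are
  counted independently, matching how the reference tables were computed.
* Comparisons against printed tables use round-half-away-from-zero at each
  column's printed precision.

The design's factor levels are printed to two decimals while the reference
ion table was evidently computed from unrounded internal levels; the
recomputed table therefore matches the printed one to the last printed
digit for about 90 % of cells, with the rest bounded by the propagation of
a half-unit level rounding through the salt sources of the ion (the test
suite encodes exactly that bound).

# Design generation

The five factors scale salt groups of MS: NH₄NO₃ (0.2–1×), KNO₃ (0.1–1×),
*mesos* (CaCl₂·2H₂O, MgSO₄·7H₂O, KH₂PO₄; 0.25–3×), *micros* (the seven
trace-element salts; 0.1–1.5×) and iron (FeSO₄·7H₂O + Na₂EDTA·2H₂O;
1–5×). `d_optimal()` runs a Fedorov exchange over a uniform candidate
grid, maximizing `det(XᵀX)` of the full quadratic model matrix on coded
[−1, 1] factors, with a first-improvement scan in candidate index order
and a seeded random start — deterministic given the seed, and the
determinant trace is non-decreasing by construction. `augment_design()`
appends exact replicate rows and base-medium controls, mirroring the study
layout of 30 distinct runs + 3 replicate pairs + 3 MS controls.

The study's own 33 runs came from closed-source software and are shipped
as a data fixture, not regenerated; the generator's contract is the
property suite (optimality against random designs, bound preservation,
monotone exchange).

# Neurofuzzy models

## Basis and geometry

Each ion's domain is its empirical min/max over the 34 training media.
A *fuzzy partition* places 2 or 3 triangular membership functions with
apexes uniformly spaced across the domain; these are order-2 B-splines on
uniform knots, so memberships sum to one everywhere and double as the
regression basis. The label dominance boundaries are then closed-form:
`min + range/2` for two sets, `min + range/4` and `min + 3·range/4` for
three. Using *unrounded* recomputed domains is what reproduces the printed
dominance tables (e.g. the ammonium Low/Mid boundary 8.25 mM arises from
the unrounded domain 4.1234–20.6147 mM; the rounded domain would give
8.24).

A submodel over an ion subset uses the row-wise tensor product of the
per-ion bases; the additive model is an intercept plus a sum of submodel
contributions, fitted jointly by ridge least squares (factor 10⁻⁶) on the
[0, 1]-scaled response. Reported MSEs are on that scale, which matches the
magnitudes of the reference fit table.

## Structure search

`asmod_fit()` grows the structure greedily from the intercept-only model.
Candidate moves per step:

* add a univariate submodel, at **each** candidate density (2 and 3) — a
  strongly curved component is nearly invisible to the linear 2-set basis;
* add a bivariate submodel directly — pure interactions with weak marginal
  effects are unreachable through univariate adds;
* expand an existing submodel by tensoring in one new input (up to 4
  inputs per submodel);
* raise one input's density from 2 to 3;
* shrink a submodel by removing one input, or drop it (prune moves).

Each candidate is refitted and scored with the structural-risk criterion
below; the best admissible move is accepted. Determinism comes from
lexicographic enumeration and ties broken toward fewer parameters.

Three guards shape the search, all tunable in `nf_config()`:

* **Admissibility cap**: candidate structures may not exceed
  `(n − 1)/2` effective parameters — at least two observations per
  parameter. At the study's n = 34 this cap is 16, which is exactly the
  largest model degrees of freedom in the reference fit table.
* **Improvement margin** (`improve_tol`, default 3 %): a growth move must
  improve the score by a few percent. The search evaluates on the order of
  a hundred candidates per step, so marginal improvements are
  overwhelmingly selection noise; without the margin the structure
  accretes spurious submodels once the residual is small. Prune moves are
  exempt — removing an input that fails to pay for itself should never be
  blocked. At 8 % the margin starts truncating genuine signal on the study
  data (shoot length drops below the 70 % predictability threshold), so
  3 % leaves a comfortable factor against both failure modes.
* **MSE floor** (`min_mse`, default 10⁻⁶ on the scaled response): once a
  structure reproduces the data to numerical precision, further
  refinements only chase rounding noise.

## The structural-risk criterion

The selection score is
`mse / max(κ, 1 − √ε)` with
`ε = (p(ln(2n/p) + 1) − ln(1 − C1)) / (C2·n)`, κ = 10⁻³, where `p` is the
raw coefficient count (intercept plus every tensor cell), `C1 = 0.868`
(0.8 for shoot number) plays the role of the confidence constant and
`C2 = 4.8` scales down the capacity term. The score is strictly increasing
in both `mse` and `p`, and `p ≥ n` is inadmissible. The exact formula
inside the reference software is not published; this form is a declared
default, isolated behind `srm_score()` so it can be swapped. The common
textbook placement of the scaling constant — multiplying the capacity term
instead of dividing it — makes the square root exceed one for every model
size at n = 34, collapsing the criterion to a constant multiple of the
MSE with no complexity penalty at all; the divided form is the reading
that preserves a working penalty at the sample sizes this analysis
actually uses.

## What the fitted models deliver

On the bundled 34-row table, all six responses fit with train R²
(the `(1 − SSE/SST) × 100` statistic of `train_r2()`) between roughly 82
and 94 %, above the 70 % threshold used in this field for useful
predictability and below the >99 % zone indicative of overfitting. The
selected structures are parsimonious (one or two submodels, ≤ 16 effective
parameters).

One structural caveat is intrinsic to the design, not the method: factors
scale whole salt groups, so ions within a group are *exactly* collinear
across the 34 media (Ca²⁺, Mg²⁺, PO₄³⁻ and virtually Cl⁻ all track the
mesos multiplier; the seven micros-borne ions are mutually
indistinguishable; Fe²⁺, Na⁺ and EDTA⁻ track iron). Which member of a
collinear class the search names is an arbitrary label; interpretation and
the ion-overlap report therefore operate at the level of distinguishable
ion classes.

## Rules and ANOVA conventions

At a tensor cell's apex combination the basis is an indicator, so the
submodel's predicted contribution at that cell is exactly its coefficient.
`extract_rules()` min–max normalizes the cell coefficients within each
submodel to `s ∈ [0, 1]` and emits `High` with membership degree `s` when
`s ≥ 0.5`, else `Low` with `1 − s` — a declared default for how the
reference software derives its printed membership degrees, which it does
not document. Degenerate (constant) submodels yield flagged rules at 0.5.

`model_anova()` uses the reporting convention of the reference fit table:
`df1` = effective model parameters (`1 + Σ(∏densities − 1)`),
`df2 = n − 1`, error df their difference, F-ratio
`(SSR/df1)/(SSE/(df2 − df1))`, and the critical value is the F quantile at
`(df1, df2)`. The table's printed critical values correspond to
α = 0.001 under this convention (its header says 0.05, but the quantiles
match 0.001 exactly, consistent with the significance level quoted in the
surrounding text); `alpha` is therefore an explicit argument.

# Neural networks and optimization

`train_mlp()` trains a 1-hidden-layer perceptron (asymmetric sigmoid
hidden units, linear output) by full-batch RPROP (η⁺ = 1.2, η⁻ = 0.5,
Δ₀ = 0.1, Δ ∈ [10⁻⁶, 50]) on min–max scaled inputs and response, up to
1000 iterations with a target training MSE of 10⁻⁴ and a smart stop: the
blended criterion `0.9·train + 0.1·test` MSE must improve within a
50-iteration patience window (never before iteration 20), and the
returned weights are those of the best blended iteration. With a fixed
seed the whole path is bit-for-bit reproducible.

`select_architecture()` splits the data 80/20 (`floor(0.8·n)` training
rows — 27/7 at n = 34), trains hidden sizes 2–4 over 20 seeded weight
restarts each, and keeps the network with the lowest test MSE. With only
7 test points the test R² of any single network is volatile; selection
over the restart pool is what stabilizes it. Even so, some splits are
simply unpredictable for some output (a test set of seven near-identical
values leaves no variance to explain), which is why the headline
train/test benchmark is reported as the best over five split seeds and
remains the most split-sensitive quantity in the package.

`ga_optimize()` searches the five factor levels (keeping candidates inside
the sampled design space; a free-salt mode exists but is off by default
because the models only ever saw group-scaled compositions) with a
real-coded GA: population 100, 200 generations, tournament selection of
size 3, blend crossover (rate 0.9), bounded Gaussian mutation (rate 0.1,
SD 10 % of each gene's range), elitism 2. Fitness is the Derringer–Suich
weighted geometric mean of one-sided desirability ramps — zero
desirability on any weighted output vetoes a candidate — with the study's
goals and weights: SQ > 4.00 (weight 10), SN > 4.4 (9), SL > 1.6 cm (8),
LA > 28 cm² (7). Lower anchors default to each response's training
minimum, since the reference analysis does not state them. The GA
hyperparameters are likewise package defaults; the reference names the
algorithm but no settings. Agreement is reported as 100·D.

# Validation statistics

Continuous responses are compared by one-way ANOVA with Tukey HSD letters
at the study's unusually strict α = 0.001 (honored, not defaulted to
0.05), ordinal ones by tie-corrected Kruskal–Wallis — both through the
base R implementations (`aov`, `TukeyHSD`, `kruskal.test`), with a
hand-rolled insert-and-absorb compact letter display. For printed
mean ± SD tables, `welch_t_summary()` computes the Welch statistic and
Satterthwaite df directly from the summaries, and
`simulate_from_summary()` reconstructs samples with exactly the printed
moments so letter displays can be reproduced from published tables.
Whether the study's letters derive from raw or vessel-mean data is not
stated; both routes are available (raw values or aggregated means can be
passed equally).

# Synthetic experiments

`sample_ground_truth()` draws a sparse additive tensor-spline surface over
a known ion subset, normalized so every submodel has equal cell spread and
every input demonstrably modulates its submodel (redrawn otherwise) — a
*separable* truth, without which "recovery" is ill-posed. The surface is
rescaled to a realistic response range (shoot number ≈ 1–8 by default).
`simulate_experiment()` adds a vessel-level random effect (SD half the
explant noise by default; the study never separates the two components)
and explant noise under the 5 × 3 × 3 replicate hierarchy, thresholds
ordinal outputs at supplied cutpoints, and aggregates to the mean ± SD
table shape that all downstream modules consume.

`recovery_benchmark()` samples runs *uniformly over the ion domains*
rather than through the factor design: the factor structure leaves ions
within a salt group exactly collinear, so subset identity would be
undefined on it (see above). Recovery is scored as the selected ion set
equaling the truth's active set; requiring the exact submodel partition
would be too strict a currency, because distinct partitions (e.g. one
merged tensor versus two additive submodels) can represent the same
surface and the criterion legitimately picks either within its margin.
At 300 runs and noise of 10 % of the response range, active-ion recovery
exceeds 80 % of replicates, and pure-noise responses are refused any
submodel in essentially all replicates at that size. At the study's own
n = 34 the capacity bound is loose — chance improvements among ~100
candidate moves rival genuine ones — so structure selection there should
be read as descriptive, exactly as the reference analysis treats it.

# Problem sizes and reproducibility

The test-suite and acceptance computations use: the full 34-media study
table for all stoichiometry, fuzzification, neurofuzzy and ANN results;
300-run uniform ion samples × 25 seeds for recovery and noise-rejection
benchmarks; 120-run samples for the smaller reproducibility checks; GA
populations of 60 × 80 generations for the optimization properties (the
package default is 100 × 200). Every stochastic step takes an explicit
integer seed, and all pipeline artifacts embed a 32-bit FNV-1a hash of
their configuration plus the seed.

# Known limitations

* Vitamins, growth regulators and glycine are carried as passthrough
  metadata and never modeled; pH, solubility, chelation and activity
  corrections are out of scope.
* The synthetic generator emulates the replicate hierarchy and smooth
  sparse surfaces, not real physiology: passing recovery benchmarks shows
  the selection machinery works under its own assumptions, not that the
  study's specific ion attributions are correct.
* Ordinal scores are modeled as continuous treatment means, as the
  reference software does; a cumulative-link treatment would be more
  principled but would not be comparable to the published tables.
* Exact reproduction of the closed-source reference software (its SRM
  constant placement, its membership-degree derivation, its RPROP
  internals) is explicitly not attempted; the corresponding package
  defaults are documented above and isolated behind single functions.
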