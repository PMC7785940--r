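# phytomedia

Data-driven design of plant tissue culture mineral media, built around the
micropropagation of hardy kiwi (kiwiberry, *Actinidia arguta*).

Culture media are recipes of mineral salts, but explants respond to the
ions those salts release — and several salts release the same ion, so
salt-level analyses cannot attribute effects to individual nutrients (the
"ion confounding" problem). `phytomedia` implements the full
machine-learning pipeline that addresses this:

* **Stoichiometry** — salt recipes (mg/L) ⇄ 18-ion profiles (mM) through a
  versioned salt registry; the bundled Murashige–Skoog (MS), B5, St, Ha and
  optimized reference media; the 36-run five-factor study design and its
  34-media response table.
* **D-optimal design** — Fedorov exchange over multiplier-scaled salt
  groups (NH₄NO₃, KNO₃, mesos, micros, iron), with replicate and control
  augmentation.
* **Neurofuzzy models** — additive tensor B-spline models of six shoot
  responses (number SN, length SL, leaf area LA, quality SQ, basal callus
  BC, hyperhydricity H) from the ion profiles, selected by a
  structural-risk criterion, read out as fuzzy IF–THEN rules with
  membership degrees and low/mid/high dominance ranges:

  for a fitted response *y* with predictions *y′*,
  `R² = (1 − Σ(yᵢ − y′ᵢ)² / Σ(yᵢ − ȳ)²) × 100`, and model accuracy is
  screened by the F-ratio `(SSR/df₁)/(SSE/(df₂ − df₁))` against the F
  quantile at `(df₁, df₂ = n − 1)`.
* **ANN + GA optimization** — per-response RPROP multilayer perceptrons on
  the 14-salt representation and a genetic algorithm maximizing the
  Derringer–Suich overall desirability
  `D = Π dᵢ^(wᵢ/Σw)` with the study's goals (SQ > 4.00, SN > 4.4,
  SL > 1.6 cm, LA > 28 cm²) and weights (10, 9, 8, 7).
* **Validation statistics** — Welch tests straight from printed
  mean ± SD tables, ANOVA + Tukey HSD letters at α = 0.001,
  Kruskal–Wallis for ordinal scores.
* **Synthetic experiments** — ground-truth surfaces plus the
  5 vessels × 3 explants × 3 repetitions replicate hierarchy, for
  benchmarking recovery of known structure.

See the methods vignette
(`vignettes/media-optimization-methods.Rmd`) for the model details,
conventions and design decisions.

## A worked example

Convert the MS recipe to its ion profile, model shoot quality from the
bundled 34-media study table, and read the rules:

```r
library(phytomedia)

round(recipe_to_ions(ms_recipe()), 3)
#>    NH4    NO3      K     Ca     Mg    PO4    SO4     Cl     Fe    BO3     Mn
#> 20.615 39.408 20.047  2.993  1.501  1.249  1.731  5.986  0.100  0.100  0.100
#>     Zn     Cu   MoO2     Na     Co      I   EDTA
#>  0.030  0.000  0.001  0.202  0.000  0.005  0.100

resp <- kiwi_responses()                 # printed means +/- SD, 34 media
X    <- kiwi_ion_table()                 # recomputed full-precision ions
m    <- asmod_fit(X, resp$SQ_mean, nf_config(), output = "SQ")
m
#> <asmod_model> SQ: 3 submodel(s), p = 15, scaled MSE = 0.004876
#>    EDTA(2) x K(2) x Ca(2)
#>    NH4(3) x NO3(2)
#>    BO3(3)
train_r2(resp$SQ_mean, m$fitted)
#> [1] 93.2
```

Shoot quality is explained by an iron-chelate × potassium × calcium-class
interaction plus nitrogen and borate terms, at 93.2 % train R² — above the
70 % bar for useful predictability, below the > 99 % overfitting zone.
(Ions within one salt group are exactly collinear on this design, so e.g.
`Ca` stands for the whole mesos class and `EDTA` for the iron class.)

```r
head(subset(extract_rules(m), select = -degenerate), 4)
#>   output submodel EDTA    K   Ca  NH4  NO3  BO3 consequent    MD
#> 1     SQ        1  Low  Low  Low <NA> <NA> <NA>       High 0.730
#> 2     SQ        1  Low  Low High <NA> <NA> <NA>        Low 0.760
#> 3     SQ        1  Low High  Low <NA> <NA> <NA>        Low 0.615
#> 4     SQ        1  Low High High <NA> <NA> <NA>       High 1.000

model_anova(resp$SQ_mean, m$fitted, model_df(m), 33, alpha = 0.001)
#> F = 16.53 vs F_crit(15, 33) = 3.621 -> accurate: TRUE
```

Validation straight from a printed summary table — shoot length of the
optimized medium versus the MS control (n = 45 each):

```r
sl <- subset(kiwi_validation(), response == "SL" & medium %in% c("R", "MS"))
welch_t_summary(sl$mean[1], sl$sd[1], sl$n[1], sl$mean[2], sl$sd[2], sl$n[2])
#> Welch t = 9.57, df = 80.4, p = 6.5e-15
```

The improvement is significant far beyond the study's α = 0.001.

A command-line wrapper over the same functions ships in
`inst/cli/phytomedia.R`, with subcommands `design`, `ions`, `fit-rules`,
`fit-ann`, `optimize`, `validate` and `simulate`; every artifact embeds
the configuration hash and seed.

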