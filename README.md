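# nvcoach — an interactive, explanation-based nutrition virtual coach

`nvcoach` is an R implementation of a negotiating food-recommendation
agent for nutrition coaching. It is aimed at researchers in recommender
systems, explainable AI and digital health who need a complete, seeded,
inspectable pipeline: multi-criteria recipe scoring, constraint filtering
through an ingredient-class taxonomy, a turn-taking negotiation protocol
with structured critiques, post-hoc explanations (decision-tree based and
contrastive), and a simulated-user harness for paired experiments.

## The model in brief

Each consumable recipe is scored

```
recipeScore = w_n · nutrientScore/30 + w_a · amrScore/5 + w_u · userScore
```

* **nutrientScore** — each of six nutrients (protein, lipids,
  carbohydrates, cholesterol, sodium, saturated fat) scores 5 inside its
  healthy band [minₙ, maxₙ], 3 below, 1 above; the six sub-scores sum to
  6–30.
* **amrScore** — the user's basal metabolic rate
  `BMR = 10·weight + 6.25·height − 5·age + 5` (men; constant 161 for
  women) is scaled by an activity multiplier (1.2–1.9) to the daily
  requirement, of which one meal gets a configurable fraction ±10%;
  calories score 5/3/1 against that band.
* **userScore** — the mean of the liked-ingredient fraction of the recipe
  and the community rating normalised as rating/5.

The agent offers the argmax, explains it, and renegotiates on critiques
("I ate Y recently", "I'm allergic to Y", "I don't like Y", free text; or
critiques of the explanation itself). Dietary constraints are resolved
through a single-rooted ingredient-class taxonomy in which restrictions
cover entire subtrees. As a round deadline approaches, a time-based
concession policy shifts weight from the health terms toward user
satisfaction. Explanations cycle through item-based and user-based
decision trees (feature importances of a shallow CART fit) and a
contrastive strategy that compares the offer with its most similar
lower-scoring rival (ingredient Jaccard similarity).

See the methods vignette (`vignettes/nvcoach-methods.Rmd`) for the full
account of the model, its parameters and its limitations.

## A worked example

```r
library(nvcoach)

tax     <- default_taxonomy()
recipes <- read_recipes(system.file("extdata", "example_recipes.csv",
                                    package = "nvcoach"), tax)
profile <- read_profile(system.file("extdata", "example_profile.json",
                                    package = "nvcoach"))

bmr(profile)   # 1669.75 kcal/day at rest
amr(profile)   # 2295.91 kcal/day with light activity
calorie_band(profile)  # per-meal band: 688.8 – 841.8 kcal

cmd_recommend(profile, recipes, tax, k = 3)
#>      id                       name nutrient    amr satisfaction  total
#>  r00004         Thai yogurt dish 4   0.1778 0.3333       0.1013 0.6124
#>  r00010  Indian mozzarella dish 10   0.2444 0.2000       0.1143 0.5588
#>  r00002 Italian plum tomato dish 2   0.2222 0.2000       0.1320 0.5542
```

The breakdown columns are the three weighted terms and recombine exactly
to `total`; `r00004` leads because its calories sit inside the user's
band (`amr` term at its maximum, 1/3 · 5/5).

A negotiation session with critiques:

```r
s <- start_session(profile, recipes, tax, nvc_config(), "interactive",
                   seed = 42)
s
#> <nvc_session> mode interactive, round 1/20, state awaiting_user, outcome none_yet
#>   current offer: Thai yogurt dish 4 (r00004)
#>   └ This recipe is low in saturated fats.

s <- step(s, user_action("critique_recipe",
                         critique("dislike", target_class = "yogurt")))
#>   current offer: Indian mozzarella dish 10 (r00010)
#>   └ This recipe provides sufficient protein and is high in carbohydrates.

s <- step(s, user_action("critique_explanation",
                         critique("not_convincing")))
#>   └ This recipe is suggested instead of Italian plum tomato dish 2 that
#>     provides a poorer protein balance and contains a substantially higher
#>     amount of saturated fats; this recipe keeps fats in a healthy range.

s <- step(s, user_action("accept"))
s$outcome      # "agreement" — recipe r00010, reached in round 3
```

The dislike permanently removes yogurt recipes, the explanation critique
keeps the recipe but switches strategy (here to a contrastive
explanation), and `write_transcript()` / `replay_transcript()` make the
whole dialogue replayable.

Paired simulated-user experiments:

```r
m <- run_experiment("both", n_users = 54, seed = 1)
m$interactive
#> <nvc_metrics> interactive: 54 sessions, 100.0% agreement, 2.02 +/- 1.47 rounds
#>   healthiness of agreements: highly_healthy=30, healthy=24, unhealthy=0
```

A command-line front end over the same functions ships with the package
(`system.file("cli", "nvc.R", package = "nvcoach")`):

```sh
Rscript nvc.R recommend --recipes recipes.csv --profile profile.json
Rscript nvc.R simulate --mode both --n-users 54 --seed 1 --out metrics.json
Rscript nvc.R gen-data --dir data/ --n-recipes 1300 --seed 1
```

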