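---
title: "How the nutrition virtual coach scores, negotiates and explains"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{How the nutrition virtual coach scores, negotiates and explains}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nvcoach)
```

`nvcoach` implements an interactive food-recommendation agent: it scores a
recipe catalogue against a user's physiology and preferences, offers the
best candidate, explains the offer, and renegotiates in rounds as the user
critiques either the recipe or the explanation. This vignette is the
package's account of the underlying model — its assumptions, its tunable
parameters, and the design decisions that were genuinely open.

## The multi-criteria recipe score

Every consumable recipe gets a utility in $[0,1]$:

$$\mathrm{recipeScore} \;=\; w_n \frac{\mathrm{nutrientScore}}{30}
 \;+\; w_a \frac{\mathrm{amrScore}}{5} \;+\; w_u\,\mathrm{userScore},
 \qquad w_n + w_a + w_u = 1 .$$

**Nutrient score.** Each of six tracked nutrients (protein, lipids,
carbohydrates, cholesterol, sodium, saturated fat) is scored against a
healthy per-serving band $[\min_n, \max_n]$: 5 inside the band, 3 below it,
1 above it. Under-consumption is deliberately scored better than
over-consumption — for a single meal, eating too little of a nutrient is the
smaller health risk. The six sub-scores sum to a total in
$\{6, 8, \dots, 30\}$.

Two normalisations of that total are defensible: `sum/30` (the default)
keeps the three cases proportionally spaced at 1/3–3/5–1, while
`(sum-6)/24` maps the attainable range onto exactly $[0,1]$. We default to
`sum/30` and expose the alternative as `nutrient_norm = "range"` in
`nvc_config()`; the choice only rescales the nutrient term, it never
reorders recipes ranked by that term alone.

The shipped default bands (`default_nutrient_limits()`) are per-meal
placeholders in recipe-table units (grams; cholesterol and sodium in mg).
Authoritative intake limits vary by jurisdiction and population, so the
bands are plain data, meant to be replaced; every minimum is strictly
positive so that each of the three scoring cases is reachable for every
nutrient.

**Calorie (AMR) score.** The user's basal metabolic rate is the linear
form $\mathrm{BMR} = 10\,w + 6.25\,h - 5\,a + c$ with weight in kg, height
in cm, age in years, and $c = 5$ for men. For women we use $c = +161$ as
our reference source states it; note the classical Mifflin–St Jeor
equation *subtracts* 161, and `bmr(female_constant = -161)` (or the config
field of the same name) restores the textbook form. The daily requirement
(AMR) multiplies BMR by an activity factor (1.2, 1.375, 1.55, 1.725, 1.9
from sedentary to very strong exercise).

A recipe is one meal, but AMR is a daily quantity, and the mapping between
them was an open design point. We allot the meal a configurable fraction
of the day (default `meal_fraction = 1/3`, three equal meals) and widen
the target by a relative `tolerance` (default 10%), giving a band
$[\tfrac{1}{3}\mathrm{AMR} \cdot 0.9,\; \tfrac{1}{3}\mathrm{AMR} \cdot 1.1]$.
Calories are then scored 5/3/1 like a nutrient, again preferring
under-eating to over-eating.

**User-satisfaction score.** The equal-weight mean of (a) the fraction of
the recipe's ingredient classes the user has declared liking, and (b) the
community rating normalised as `rating/5`. The `rating/5` normalisation
(rather than `(rating-1)/4`) is chosen so a rating of 4 maps to 0.8,
matching the reference worked example in which liked classes
$\{i_1,i_2,i_3\}$, recipe $\{i_1,i_2,i_5,i_6\}$ and rating 4 combine to
$(0.5 + 0.8)/2 = 0.65$. A pool-level max-normalisation of the individual
rates is sometimes described alongside this score, but applying it would
break that worked example (the 0.5 is used raw), so it is off by default
and available as `max_normalize = TRUE`.

The default weights are $w_n = w_a = w_u = 1/3$: no published weighting
exists, and equal thirds make no silent priority claim. All three weights
are configurable.

## Constraint filtering through the taxonomy

Ingredient classes form a single-rooted tree; dietary restrictions are a
map from category labels (vegan, kosher, …) to class ids, and a
restriction on a class always covers its whole descendant closure —
forbidding `dairy` forbids every cheese below it. A user's forbidden set
is the union of their categories' entries, their allergies, and their
dislikes, each expanded by `descendants()`. Dislikes are hard filters, not
soft penalties: a recipe containing any forbidden class is never offered.
This is transitive-closure reasoning only; the schema deliberately avoids
any heavier ontology machinery, and `load_taxonomy()` documents the flat
YAML format so real food ontologies can be exported into it.

## The negotiation protocol and concession

A session opens with the top-scoring consumable recipe and proceeds in
rounds. The user may accept (terminating with an agreement), leave,
critique the recipe ("I ate Y recently" — excluded for this session only;
"I'm allergic to Y" / "I don't like Y" — permanent profile updates; or a
free-text remark, which changes no constraints), or critique the
explanation, which keeps the same recipe on the table and produces a
different justification. Every non-terminal action consumes one round;
`deadline` rounds (default 20) bound the session, expressed in rounds
rather than wall-clock time for reproducibility. Offered recipes are never
re-offered within a session, even after constraints change.

As the deadline nears the agent concedes: with progress
$\beta = \min(1, (t/T)^e)$, the satisfaction weight is interpolated toward
1, $w_u(t) = w_u^0 + \beta\,(1 - w_u^0)$, and the two health weights are
shrunk by a common factor so the weights still sum to 1. The exponent
(default $e = 1$, linear) gives Boulware-style late concession for $e > 1$
and early concession for $e < 1$. A consequence worth stating precisely:
the *pool-wide* best recipe under $w(t)$ has a non-increasing health
component as $t$ grows (monotone comparative statics in the
health–taste trade-off). The health component of the *offer sequence* is
usually non-increasing too, but not always — the no-re-offer rule can
force the agent back to healthier leftovers after the tasty candidates are
exhausted — so the package's tests assert the pool-wide statement, which
is the one the mechanism actually guarantees.

Ties in ranking are broken by higher community rating, then lexicographic
recipe id; every component of the agent is deterministic given its inputs.

## Post-hoc explanations

Three strategies are cycled in a fixed order (item-based, user-based,
contrastive), skipping whichever is unavailable, and never repeating an
explanation text for the same recipe within a session.

**Item-based.** The catalogue is labelled from the current user's
viewpoint: recipes removed by constraints or critiques, and consumable
recipes below the 0.33 score quantile, are negative; consumable recipes at
or above the 0.67 quantile are positive; the middle band is neutral. The
quantile cut-offs are implementation choices (no published thresholds
exist) and are configurable (`q_low`, `q_high`). A CART classification
tree (Gini impurity; entropy available via `tree_criterion`) is fitted on
eight features — the six nutrients, calories and rating — with `max_depth
= 4` and `min_leaf = 2`; shallow trees keep the surfaced features
interpretable. The tree is never used to predict: its only output is the
per-feature importance (normalised total impurity decrease over the
realised splits, surrogate and competitor splits disabled), of which the
top `top_k = 3` features are voiced.

**User-based.** The same tree machinery over a history of offers labelled
with *all* users' accept/reject decisions; unavailable when no history has
been supplied.

**Contrastive.** A counter-recipe is chosen from the filtered and
lower-scoring pool: among recipes with strictly lower utility than the
offer, the one with maximal ingredient-set Jaccard similarity (ties: lower
score, then id). Features — the six nutrient sub-scores, the calorie
sub-score and a taste term — are partitioned into the counter-recipe's
weaknesses ($\varepsilon^-$, strictly lower sub-score than the offer) and
the rest ($\varepsilon^+$); the realised sentence dismisses the
counter-recipe by its weaknesses and credits the offer with one
$\varepsilon^+$ strength.

Realisation is slot-filling over a phrase repository (YAML-overridable,
`default_phrases()`): one fragment per (feature, qualitative level), where
levels derive from the sub-scores (in-band → "sufficient", below → "low",
above → "high"). The exact grammar of the original system's templates is
not published; the shipped templates are reconstructions that keep the
item/user sentences short and let contrastive sentences run longer. When
every strategy is exhausted, a plain nutrient-fact sentence is emitted and
logged as a fallback.

## What the synthetic data emulates — and what it does not

The generator reproduces the *statistical shell* of a realistic
deployment: a catalogue of ~1300 recipes with 3–10 ingredient classes
drawn from the taxonomy leaves; nutrient amounts log-normal around each
healthy band with the spread set so that roughly a third of draws fall
below, inside and above the band (so every sub-score value is common, and
"healthy on all seven criteria" is rare — about the proportions a real
catalogue shows); ratings Beta(4, 2) rescaled to $[1,5]$; and a user panel
with ages 19–58, sex-specific anthropometrics, occasional dietary
categories, and persona priorities taste-first/health-first/mixed in
proportions 0.69/0.21/0.10, the split a pre-study survey of food-choice
priorities reported.

Simulated users carry *hidden* preferences: liked classes (~40% of
leaves), of which only half are revealed to the agent as profile likes,
and disliked classes (~15% of leaves). Their hidden utility is
$u = \lambda\,\mathrm{taste} + (1-\lambda)\,\mathrm{health}$ with
$\lambda$ = 0.8 / 0.2 / 0.5 by priority, taste the hidden-liked fraction
of the offer's ingredients, and health the mean of the seven sub-scores
rescaled to $[0,1]$. A dish containing any hidden-disliked ingredient is
vetoed outright ($u = 0$): "I don't like Y" is modelled as a genuine
refusal, not a mild penalty. Acceptance requires $u \ge \theta(t)$ with
$\theta$ falling linearly from 0.75 to 0.45 over the deadline — chosen
once so that default sessions terminate well before the round budget.
When a rejected offer contains a hidden-disliked class the user issues an
exclusion critique against it (kind drawn from propensities 0.6 dislike /
0.3 ate-recently / 0.1 allergic — allergy is rare and irreversible);
otherwise the user sends a custom remark and lets the agent move on. This
split matters: exclusion critiques then only remove recipes the user would
never accept, which is exactly why the interactive dialogue reaches
agreement in no more rounds than the traditional one on the same seed.

The simulated user is an evaluation harness, not a behavioural claim.
It does not model persuasion (explanations never change the acceptance
threshold, because no calibration target for such an effect exists),
fatigue, ordering effects, or free-text feedback content. Passing
simulated-user tests therefore demonstrates protocol safety, determinism
and the structural efficiency of critiques — not that human participants
would behave this way.

## Numerical and degenerate-case choices

* Quantile labelling uses R's default type-7 quantiles; on nine distinct
  scores with the default cut-offs this yields a 3/3/3 label split.
* Single-label datasets refuse to fit a tree (the caller falls back to the
  next strategy); stump trees report all-zero importances and surface no
  features.
* An empty candidate set at any point terminates the session with outcome
  `no_candidates`; an empty eligible contrast pool makes the contrastive
  strategy unavailable rather than erroring.
* Healthiness labels trisect the mean of the seven sub-scores at 4 and
  2.5 (configurable): all-5 recipes are "highly healthy", and the cutoffs
  split the attainable $[1,5]$ range into three comparable slabs.
* Weight vectors must sum to 1 within $10^{-9}$; scores are never
  renormalised downstream.

## Problem sizes in the test-suite

The shipped tests run desk-scale versions of every property: oracle
equivalence (filtering, ranking, root splits, contrast selection) on
catalogues of 100–200 recipes against brute-force reimplementations; a
protocol-safety audit over 1,000 randomized sessions on a 200-recipe
catalogue; and a paired 54-user experiment (one traditional and one
interactive session per user on a 1300-recipe catalogue) checking that
both arms agree in at least 90% of sessions and that the interactive arm
needs no more rounds on average. These sizes were chosen to exercise the
asymptotic behaviour while keeping the default test run short.

## Known limitations

* The taxonomy is illustrative; no published food ontology or recipe
  dataset is reconstructed, and the WHO-style nutrient bands are
  placeholders to be replaced with jurisdiction-appropriate values.
* Negotiation state lives within a session: the agent does not learn user
  preferences across sessions.
* Explanation quality is not evaluated beyond availability, determinism
  and non-repetition; there is no model of how explanations shift
  acceptance.
* The female BMR constant follows its printed source (+161); users wanting
  the Mifflin–St Jeor form must override it. The difference is a constant
  322 kcal/day shift for female profiles, which propagates into the
  calorie band.
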