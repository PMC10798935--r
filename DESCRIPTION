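Package: nvcoach
Title: Interactive Nutrition Virtual Coach with Explainable Recipe
    Recommendations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: A multi-criteria recipe recommender that negotiates with a
    user over rounds toward a healthy meal choice. Recipes are scored by
    combining a nutrient-band score, a calorie score derived from the
    user's basal and active metabolic rate, and a user-satisfaction score
    built from liked ingredients and community ratings. The agent accepts
    structured critiques of both recipes and explanations, filters
    candidates through an ingredient-class taxonomy with dietary
    restrictions, concedes toward user taste as a round deadline
    approaches, and justifies each offer with post-hoc explanations
    generated from decision trees or from contrastive counter-recipes.
    Includes a synthetic-data generator and simulated users for seeded,
    reproducible evaluation of full negotiation dialogues.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    rpart,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
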