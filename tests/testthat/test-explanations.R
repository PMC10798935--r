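# brute-force helpers used as independent oracles ---------------------------

# exhaustive best binary split over all (feature, threshold) pairs by the
# weighted-Gini objective; returns the best achievable child impurity
best_split_gini <- function(features, labels) {
  gini <- function(y) {
    if (length(y) == 0) return(0)
    p <- table(y) / length(y)
    1 - sum(p^2)
  }
  best <- list(impurity = Inf)
  n <- length(labels)
  for (f in names(features)) {
    v <- features[[f]]
    cuts <- sort(unique(v))
    if (length(cuts) < 2) next
    mids <- (cuts[-1] + cuts[-length(cuts)]) / 2
    for (thr in mids) {
      left <- labels[v < thr]
      right <- labels[v >= thr]
      imp <- (length(left) * gini(left) + length(right) * gini(right)) / n
      if (imp < best$impurity - 1e-12) {
        best <- list(impurity = imp, feature = f, threshold = thr)
      }
    }
  }
  best
}

rand_dataset <- function(n, seed) {
  set.seed(seed)
  f <- as.data.frame(matrix(round(stats::runif(n * 8, 0, 100), 1), n, 8))
  names(f) <- c("protein", "lipids", "carbohydrates", "cholesterol",
                "sodium", "saturated_fat", "calories", "rating")
  labels <- sample(c(-1L, 1L), n, replace = TRUE)
  if (length(unique(labels)) < 2) labels[1] <- -labels[1]
  list(features = f, labels = labels)
}

as_nvc_dataset <- function(d) {
  build_user_dataset(cbind(d$features,
                           decision = ifelse(d$labels > 0, "accept",
                                             "reject")))
}

# ---------------------------------------------------------------------------

test_that("item datasets label by exclusion and score quantiles", {
  rec <- bind_recipes(
    make_recipe("a", "rice"), make_recipe("b", "rice"),
    make_recipe("c", "rice"))
  # everything filtered -> all -1
  ds <- build_item_dataset(rec, c(a = "constraint-filtered",
                                  b = "constraint-filtered",
                                  c = "critiqued"),
                           scores = numeric(0))
  expect_true(all(ds$labels == -1))

  # 9 consumable recipes with distinct scores and default quantiles -> 3/3/3
  rec9 <- do.call(bind_recipes, lapply(1:9, function(i)
    make_recipe(sprintf("r%d", i), "rice")))
  scores <- stats::setNames(seq(0.1, 0.9, by = 0.1), rec9$id)
  ds9 <- build_item_dataset(rec9, character(0), scores)
  expect_equal(as.numeric(table(ds9$labels)), c(3, 3, 3))
  expect_equal(ds9$labels[scores[ds9$recipe_id] < 0.35], rep(-1L, 3))
  expect_equal(ds9$labels[scores[ds9$recipe_id] > 0.65], rep(1L, 3))

  # a critiqued recipe is -1 no matter how well it scores
  ds_crit <- build_item_dataset(rec9, c(r9 = "critiqued"),
                                scores[setdiff(names(scores), "r9")])
  expect_equal(ds_crit$labels[ds_crit$recipe_id == "r9"], -1L)
})

test_that("user datasets keep one row per historical offer", {
  h1 <- data.frame(protein = 20, lipids = 15, carbohydrates = 60,
                   cholesterol = 50, sodium = 300, saturated_fat = 5,
                   calories = 700, rating = 4, decision = "accept")
  ds <- build_user_dataset(h1)
  expect_equal(ds$labels, 1L)
  expect_equal(nrow(ds$features), 1)

  # duplicated recipe with conflicting decisions -> two rows, no dedup
  h2 <- rbind(h1, transform(h1, decision = "reject"))
  ds2 <- build_user_dataset(h2)
  expect_equal(ds2$labels, c(1L, -1L))

  expect_error(build_user_dataset(h1[0, ]), "unavailable")

  tx <- default_taxonomy()
  users <- gen_users(6, tx, seed = 2)
  hist <- gen_history(users$profiles, users$personas,
                      gen_catalogue(80, tx, seed = 2), n_offers = 200,
                      seed = 3)
  expect_equal(nrow(build_user_dataset(hist)$features), 200)
})

test_that("tree fitting is deterministic and importances are normalised", {
  # one feature separates the classes perfectly -> importance 1 on it
  d <- rand_dataset(20, seed = 1)
  d$features$sodium <- ifelse(d$labels > 0, 90, 10) + stats::runif(20)
  ds <- as_nvc_dataset(d)
  fit <- fit_tree(ds, max_depth = 3, min_leaf = 2)
  expect_equal(unname(fit$importance["sodium"]), 1)
  expect_equal(sum(fit$importance), 1)

  # constant features -> stump with all-zero importances
  const <- as_nvc_dataset(list(
    features = as.data.frame(matrix(1, 6, 8,
      dimnames = list(NULL, names(d$features)))),
    labels = rep(c(-1L, 1L), 3)))
  stump <- fit_tree(const)
  expect_true(all(stump$importance == 0))
  expect_equal(top_features(stump), character(0))

  # single-class data refuses to fit, naming the class
  one_class <- as_nvc_dataset(list(features = d$features,
                                   labels = rep(1L, 20)))
  expect_error(fit_tree(one_class), "label 1")

  # determinism
  f2 <- fit_tree(ds, max_depth = 3, min_leaf = 2)
  expect_identical(fit$importance, f2$importance)
})

test_that("root split equals exhaustive search on small datasets", {
  for (seed in 1:12) {
    d <- rand_dataset(sample(5:8, 1), seed = seed + 100)
    ds <- as_nvc_dataset(d)
    fit <- fit_tree(ds, max_depth = 1, min_leaf = 1)
    oracle <- best_split_gini(d$features, d$labels)
    rp <- fit$fit
    if (is.null(rp$splits) || nrow(rp$splits) == 0) {
      # no split found: the oracle must not improve on the root impurity
      gini0 <- 1 - sum((table(d$labels) / length(d$labels))^2)
      expect_gte(oracle$impurity, gini0 - 1e-9)
    } else {
      thr <- rp$splits[1, "index"]
      feat <- rownames(rp$splits)[1]
      v <- d$features[[feat]]
      gini <- function(y) if (!length(y)) 0 else
        1 - sum((table(y) / length(y))^2)
      got <- (sum(v < thr) * gini(d$labels[v < thr]) +
                sum(v >= thr) * gini(d$labels[v >= thr])) / length(v)
      expect_equal(got, oracle$impurity, tolerance = 1e-9)
      # depth-1 training accuracy also matches the best achievable stump
      acc <- function(split_v, split_thr) {
        pred <- ifelse(split_v < split_thr,
                       names(which.max(table(d$labels[split_v < split_thr]))),
                       names(which.max(table(d$labels[split_v >= split_thr]))))
        mean(pred == as.character(d$labels))
      }
      vo <- d$features[[oracle$feature]]
      expect_equal(acc(v, thr), acc(vo, oracle$threshold),
                   tolerance = 1e-9)
    }
  }
})

test_that("top_features orders by importance with fixed-order tie-breaks", {
  fake <- structure(list(importance = c(
    protein = 0.7, lipids = 0, carbohydrates = 0, cholesterol = 0,
    sodium = 0.3, saturated_fat = 0, calories = 0, rating = 0)),
    class = "nvc_tree")
  expect_equal(top_features(fake, 3), c("protein", "sodium"))
  expect_equal(top_features(fake, 1), "protein")
  tied <- fake
  tied$importance[c("protein", "sodium")] <- 0.5
  expect_equal(top_features(tied, 2), c("protein", "sodium"))
})

test_that("recipe Jaccard similarity follows the set definition", {
  expect_equal(recipe_jaccard(c("a", "b"), c("a", "b")), 1)
  expect_equal(recipe_jaccard(c("a", "b"), c("c", "d")), 0)
  expect_equal(recipe_jaccard(c("a", "b", "c"), c("b", "c", "d")), 0.5)
  r1 <- make_recipe("r1", c("rice", "beef"))
  r2 <- make_recipe("r2", c("rice", "milk"))
  expect_equal(recipe_jaccard(r1, r2), 1 / 3)
})

test_that("contrast selection is the Jaccard argmax over lower scorers", {
  tx <- default_taxonomy()
  prof <- base_profile(likes = c("rice", "salmon"))
  band <- calorie_band(prof)
  for (seed in c(3, 9, 27)) {
    pool <- gen_catalogue(100, tx, seed = seed)
    scores <- recipe_score(pool, prof, band = band)
    rec_i <- which.max(scores)
    rec <- pool[rec_i, ]
    got <- select_contrast(rec, pool, scores, scores[rec_i])
    # brute force
    elig <- setdiff(which(scores < scores[rec_i]), rec_i)
    sims <- vapply(elig, function(i) recipe_jaccard(rec, pool[i, ]),
                   numeric(1))
    ord <- order(-sims, scores[elig], pool$id[elig], method = "radix")
    expect_equal(got$id, pool$id[elig[ord[1]]])
    expect_lt(scores[pool$id == got$id], scores[rec_i])
  }
  # empty eligible pool -> unavailable
  solo <- make_recipe("s", "rice")
  expect_null(select_contrast(solo, solo, 0.5, 0.5))
})

test_that("contrastive features partition exhaustively and disjointly", {
  band <- test_band()
  prof <- base_profile(likes = "rice")
  r <- make_recipe("r", c("rice", "beef"))

  # identical recipes: nothing is worse
  eps_same <- contrast_features(r, make_recipe("r2", c("rice", "beef")),
                                band = band, profile = prof)
  expect_length(eps_same$eps_minus, 0)
  expect_setequal(eps_same$eps_plus,
                  c("protein", "lipids", "carbohydrates", "cholesterol",
                    "sodium", "saturated_fat", "calories", "taste"))

  # counter worse on sodium only
  salty <- make_recipe("s", c("rice", "beef"), sodium = 5000)
  eps <- contrast_features(r, salty, band = band, profile = prof)
  expect_equal(eps$eps_minus, "sodium")

  # partition property over random recipe pairs
  pool <- gen_catalogue(40, default_taxonomy(), seed = 77)
  for (k in seq(1, 39, by = 2)) {
    e <- contrast_features(pool[k, ], pool[k + 1, ], band = band,
                           profile = prof)
    expect_length(intersect(e$eps_plus, e$eps_minus), 0)
    expect_length(union(e$eps_plus, e$eps_minus), 8)
  }
})

test_that("realisation is deterministic template filling", {
  lv <- c(protein = "sufficient")
  e <- realize(explanation("item_based", features = "protein", levels = lv))
  expect_equal(e$text, "This recipe provides sufficient protein.")
  e2 <- realize(explanation("item_based", features = "protein", levels = lv))
  expect_identical(e$text, e2$text)

  ec <- realize(explanation(
    "contrastive", counter_name = "American Salad",
    eps_minus = "saturated_fat", eps_plus = c("protein", "calories")))
  expect_match(ec$text, "American Salad")
  expect_match(ec$text, "substantially higher amount of saturated fats")
  expect_match(ec$text, "instead of")

  expect_error(
    realize(explanation("item_based", features = "protein",
                        levels = c(protein = "galactic"))),
    "protein, galactic")
})

test_that("strategies cycle and texts never repeat within a session", {
  tx <- default_taxonomy()
  rec <- gen_catalogue(120, tx, seed = 88)
  prof <- base_profile(likes = c("rice", "salmon"))
  users <- gen_users(5, tx, seed = 4)
  hist <- gen_history(users$profiles, users$personas, rec, 150, seed = 5)

  s <- start_session(prof, rec, tx, nvc_config(deadline = 10),
                     "interactive", seed = 1, history = hist)
  first <- current_offer(s)$explanation
  expect_equal(first$strategy, "item_based")
  texts <- first$text
  for (i in 1:3) {
    s <- step(s, user_action("critique_explanation",
                             critique("not_convincing")))
    ex <- current_offer(s)$explanation
    expect_false(ex$text %in% texts)
    texts <- c(texts, ex$text)
  }
  # order: item -> user -> contrastive, then the logged fallback
  expect_equal(s$expl_tried[[current_offer(s)$recipe$id]],
               c("item_based", "user_based", "contrastive"))

  # without history the user-based strategy is skipped
  s2 <- start_session(prof, rec, tx, nvc_config(deadline = 10),
                     "interactive", seed = 1, history = NULL)
  s2 <- step(s2, user_action("critique_explanation",
                             critique("not_my_case")))
  ex2 <- current_offer(s2)$explanation
  expect_true(ex2$strategy %in% c("contrastive", "fallback"))
})
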