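#' Choose and realise the next explanation for an offer
#'
#' Strategies are tried in the fixed order item-based, user-based,
#' contrastive, skipping the ones already used for this recipe in this
#' session and the ones that are unavailable (no offer history for the
#' user-based tree, a single-label dataset, no lower-scoring counter-recipe,
#' a stump tree with no informative feature). When every strategy is
#' exhausted a plain nutrient-fact sentence is emitted as a logged
#' fallback. Within one session the same recipe never receives the same
#' explanation text twice.
#'
#' @param session an `nvc_session` whose last filtering/ranking state is
#'   populated (i.e. an offer is on the table or being prepared).
#' @param recipe one-row recipe table: the recipe to explain.
#' @return an `nvc_explanation` with realised `text`.
#' @export
next_explanation <- function(session, recipe) {
  stopifnot(inherits(session, "nvc_session"))
  recipe <- recipe_table(recipe)
  cfg <- session$config
  rid <- recipe$id[1]
  tried <- session$expl_tried[[rid]]
  used_texts <- session$expl_texts[[rid]]
  order_ <- c("item_based", "user_based", "contrastive")
  for (strategy in setdiff(order_, tried)) {
    expl <- tryCatch(
      build_strategy(session, recipe, strategy),
      error = function(e) NULL
    )
    if (!is.null(expl) && !(expl$text %in% used_texts)) {
      return(expl)
    }
  }
  fallback_explanation(recipe, used_texts)
}

build_strategy <- function(session, recipe, strategy) {
  cfg <- session$config
  if (strategy == "item_based") {
    scores <- stats::setNames(session$last$ranked$score,
                              session$last$ranked$id)
    ds <- build_item_dataset(session$catalogue, session$last$excluded,
                             scores, cfg$q_low, cfg$q_high)
    model <- fit_tree(ds, cfg$tree_max_depth, cfg$tree_min_leaf,
                      cfg$tree_criterion)
    feats <- top_features(model, cfg$top_k)
    if (length(feats) == 0) stop("stump tree: no informative feature")
    lv <- feature_levels(recipe, cfg$limits, session$band)
    return(realize(explanation("item_based", features = feats, levels = lv),
                   session$phrases))
  }
  if (strategy == "user_based") {
    ds <- build_user_dataset(session$history)
    model <- fit_tree(ds, cfg$tree_max_depth, cfg$tree_min_leaf,
                      cfg$tree_criterion)
    feats <- top_features(model, cfg$top_k)
    if (length(feats) == 0) stop("stump tree: no informative feature")
    lv <- feature_levels(recipe, cfg$limits, session$band)
    return(realize(explanation("user_based", features = feats, levels = lv),
                   session$phrases))
  }
  # contrastive
  w <- session$last$weights
  pool_scores <- recipe_score(session$catalogue, session$profile,
                              cfg$limits, session$band, w,
                              nutrient_norm = cfg$nutrient_norm,
                              max_normalize = cfg$max_normalize)
  rec_score <- pool_scores[session$catalogue$id == recipe$id[1]]
  counter <- select_contrast(recipe, session$catalogue, pool_scores,
                             rec_score)
  if (is.null(counter)) stop("no eligible counter-recipe")
  eps <- contrast_features(recipe, counter, cfg$limits, session$band,
                           session$profile)
  realize(explanation("contrastive", counter_recipe = counter$id,
                      counter_name = counter$name,
                      eps_plus = eps$eps_plus, eps_minus = eps$eps_minus),
          session$phrases)
}

fallback_explanation <- function(recipe, used_texts) {
  text <- sprintf(
    paste0("%s provides %.1f g protein, %.1f g fat, %.1f g carbohydrates ",
           "and %.0f kcal per serving."),
    recipe$name[1], recipe$protein[1], recipe$lipids[1],
    recipe$carbohydrates[1], recipe$calories[1])
  n_prior <- sum(startsWith(used_texts %||% character(0), text))
  if (n_prior > 0) text <- paste0(text, " (", n_prior + 1, ")")
  explanation("fallback", text = text)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

generate_explanation <- function(session, recipe) {
  rid <- recipe$id[1]
  expl <- next_explanation(session, recipe)
  if (expl$strategy != "fallback") {
    session$expl_tried[[rid]] <- c(session$expl_tried[[rid]], expl$strategy)
  }
  session$expl_texts[[rid]] <- c(session$expl_texts[[rid]], expl$text)
  session$.last_expl <- expl
  session
}
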