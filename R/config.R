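#' Coach configuration
#'
#' Bundles every tunable of the recommendation pipeline: aggregation
#' weights, nutrient limits, the per-meal calorie band parameters, the
#' time-based concession policy, explanation-tree hyperparameters and the
#' session deadline. All arguments have working defaults; [load_config()]
#' reads the same fields from a YAML file (unknown keys are rejected).
#'
#' @param weights `nvc_weights` or numeric `c(w_n, w_a, w_u)`.
#' @param limits `nvc_limits` or a named list of `c(min, max)` per nutrient.
#' @param meal_fraction fraction of daily calories for the target meal.
#' @param tolerance relative half-width of the calorie band.
#' @param female_constant additive BMR constant for women (see [bmr()]).
#' @param deadline round budget T of a negotiation session.
#' @param concession_exponent exponent e of the concession curve; e = 1 is
#'   linear, e > 1 concedes late (Boulware), e < 1 concedes early.
#' @param q_low,q_high score quantiles used to label recipes for item-based
#'   explanation trees.
#' @param tree_max_depth,tree_min_leaf decision-tree depth and minimum leaf
#'   size for explanation trees.
#' @param tree_criterion `"gini"` or `"information"` split criterion.
#' @param top_k number of features voiced in a tree-based explanation.
#' @param nutrient_norm nutrient-term normalisation, `"max"` or `"range"`.
#' @param max_normalize pool-level max-normalisation of individual
#'   satisfaction (off by default; see [user_satisfaction()]).
#' @param healthiness_thresholds cutoffs for [healthiness_label()].
#' @param phrases path to a phrase-repository YAML, or `NULL` for the
#'   shipped English default.
#' @return an object of class `nvc_config`.
#' @export
nvc_config <- function(weights = score_weights(),
                       limits = default_nutrient_limits(),
                       meal_fraction = 1 / 3,
                       tolerance = 0.10,
                       female_constant = 161,
                       deadline = 20,
                       concession_exponent = 1,
                       q_low = 0.33,
                       q_high = 0.67,
                       tree_max_depth = 4,
                       tree_min_leaf = 2,
                       tree_criterion = "gini",
                       top_k = 3,
                       nutrient_norm = "max",
                       max_normalize = FALSE,
                       healthiness_thresholds = c(4, 2.5),
                       phrases = NULL) {
  if (!inherits(weights, "nvc_weights")) {
    weights <- do.call(score_weights, as.list(stats::setNames(
      as.numeric(weights), c("w_n", "w_a", "w_u"))))
  }
  stopifnot(deadline >= 1, concession_exponent > 0,
            q_low >= 0, q_high <= 1, q_low < q_high,
            tree_max_depth >= 1, tree_min_leaf >= 1, top_k >= 1)
  tree_criterion <- match.arg(tree_criterion, c("gini", "information"))
  nutrient_norm <- match.arg(nutrient_norm, c("max", "range"))
  structure(
    list(weights = weights, limits = nutrient_limits(limits),
         meal_fraction = meal_fraction, tolerance = tolerance,
         female_constant = female_constant,
         deadline = as.integer(deadline),
         concession_exponent = concession_exponent,
         q_low = q_low, q_high = q_high,
         tree_max_depth = as.integer(tree_max_depth),
         tree_min_leaf = as.integer(tree_min_leaf),
         tree_criterion = tree_criterion,
         top_k = as.integer(top_k),
         nutrient_norm = nutrient_norm, max_normalize = max_normalize,
         healthiness_thresholds = as.numeric(healthiness_thresholds),
         phrases = phrases),
    class = "nvc_config"
  )
}

#' @rdname nvc_config
#' @param path YAML file with any subset of the configuration fields;
#'   omitted fields keep their defaults.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  raw <- yaml::read_yaml(path)
  if (is.null(raw)) raw <- list()
  known <- names(formals(nvc_config))
  unknown <- setdiff(names(raw), known)
  if (length(unknown) > 0) {
    stop("unknown config key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  if (!is.null(raw$weights) && !is.null(names(raw$weights))) {
    raw$weights <- unlist(raw$weights)[c("w_n", "w_a", "w_u")]
  }
  do.call(nvc_config, raw)
}

#' @rdname nvc_config
#' @param config an `nvc_config`.
#' @export
config_show <- function(config = nvc_config()) {
  stopifnot(inherits(config, "nvc_config"))
  out <- unclass(config)
  out$weights <- as.list(unclass(out$weights))
  out$limits <- lapply(unclass(out$limits), as.numeric)
  out$phrases <- if (is.null(out$phrases)) "<built-in English phrases>" else out$phrases
  cat(yaml::as.yaml(out))
  invisible(config)
}

#' @export
print.nvc_config <- function(x, ...) {
  cat("<nvc_config>\n")
  config_show(x)
  invisible(x)
}
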