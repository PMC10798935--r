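#' Filter a catalogue against user constraints
#'
#' Removes every recipe the user cannot (or will not) eat — dietary
#' categories, allergies and dislikes, all expanded through the taxonomy —
#' plus any explicitly excluded recipe ids (already offered, critiqued).
#' Every removal is recorded with its reason so explanations can later use
#' the filtered pool.
#'
#' @param recipes recipe table.
#' @param profile an `nvc_profile`.
#' @param tax an `nvc_taxonomy`.
#' @param exclusions named character vector: recipe id -> reason (e.g.
#'   `c(r12 = "already-offered")`).
#' @param excluded_classes extra ingredient-class ids to treat as forbidden
#'   for this call only (session-scoped critiques such as "I ate Y
#'   recently"); expanded by [descendants()].
#' @return list with `candidates` (recipe table rows that survive) and
#'   `excluded` (named character vector id -> reason; constraint removals
#'   get reason `"constraint-filtered"`, class exclusions `"critiqued"`).
#' @export
filter_recipes <- function(recipes, profile, tax,
                           exclusions = character(0),
                           excluded_classes = character(0)) {
  recipes <- recipe_table(recipes)
  ok <- consumable(tax, profile, recipes)
  excluded <- stats::setNames(rep("constraint-filtered", sum(!ok)),
                              recipes$id[!ok])
  if (length(excluded_classes) > 0) {
    closure <- descendants_of_set(tax, excluded_classes)
    hit <- vapply(recipes$ingredient_classes,
                  function(ing) any(ing %in% closure), logical(1))
    crit <- ok & hit
    excluded <- c(excluded, stats::setNames(rep("critiqued", sum(crit)),
                                            recipes$id[crit]))
    ok <- ok & !hit
  }
  if (length(exclusions) > 0) {
    manual <- recipes$id %in% names(exclusions) & ok
    excluded <- c(excluded,
                  stats::setNames(exclusions[recipes$id[manual]],
                                  recipes$id[manual]))
    ok <- ok & !(recipes$id %in% names(exclusions))
  }
  list(candidates = recipes[ok, , drop = FALSE], excluded = excluded)
}

#' Time-based concession policy
#'
#' As the round deadline approaches the agent shifts utility weight from
#' its own goal (healthiness: the nutrient and calorie terms) toward the
#' user's satisfaction term. With progress `beta = min(1, (t/T)^e)` the
#' satisfaction weight is interpolated to 1,
#' `w_u(t) = w_u0 + beta * (1 - w_u0)`, and the two health weights are
#' scaled down by a common factor so the three still sum to 1. `e = 1`
#' concedes linearly; `e > 1` holds firm until late (Boulware); `e < 1`
#' concedes early.
#'
#' @param deadline_rounds round budget T (>= 1).
#' @param exponent concession exponent e (> 0).
#' @param base_weights `nvc_weights` at t = 0.
#' @return an object of class `nvc_concession`.
#' @export
concession_policy <- function(deadline_rounds = 20, exponent = 1,
                              base_weights = score_weights()) {
  stopifnot(deadline_rounds >= 1, exponent > 0,
            inherits(base_weights, "nvc_weights"))
  structure(list(deadline_rounds = as.integer(deadline_rounds),
                 exponent = exponent, base_weights = base_weights),
            class = "nvc_concession")
}

#' @rdname concession_policy
#' @param policy an `nvc_concession`.
#' @param t elapsed rounds, `0 <= t <= deadline_rounds`.
#' @return [concession_weights()]: the `nvc_weights` in force at time t.
#' @export
concession_weights <- function(policy, t) {
  stopifnot(inherits(policy, "nvc_concession"), t >= 0)
  base <- policy$base_weights
  beta <- min(1, (t / policy$deadline_rounds)^policy$exponent)
  w_u <- base[["w_u"]] + beta * (1 - base[["w_u"]])
  health0 <- base[["w_n"]] + base[["w_a"]]
  if (health0 > 0) {
    scale <- (1 - w_u) / health0
    w_n <- base[["w_n"]] * scale
    w_a <- base[["w_a"]] * scale
  } else {
    w_n <- 0
    w_a <- 0
    w_u <- 1
  }
  score_weights(w_n = w_n, w_a = w_a, w_u = w_u)
}

#' Score and rank candidate recipes
#'
#' Attaches the multi-criteria score to each candidate and sorts
#' non-increasingly; ties are broken deterministically by higher community
#' rating, then lexicographic recipe id.
#'
#' @param candidates recipe table of consumable candidates.
#' @param profile an `nvc_profile`.
#' @param limits an `nvc_limits`.
#' @param band an `nvc_band`.
#' @param w an `nvc_weights`.
#' @param ... passed to [recipe_score()] (`nutrient_norm`, `max_normalize`).
#' @return the candidate table with a `score` column, sorted.
#' @export
rank_candidates <- function(candidates, profile,
                            limits = default_nutrient_limits(),
                            band = calorie_band(profile),
                            w = score_weights(), ...) {
  candidates <- recipe_table(candidates)
  if (nrow(candidates) == 0) {
    candidates$score <- numeric(0)
    return(candidates)
  }
  candidates$score <- recipe_score(candidates, profile, limits, band, w, ...)
  ord <- order(-candidates$score, -candidates$rating, candidates$id,
               method = "radix")
  out <- candidates[ord, , drop = FALSE]
  rownames(out) <- NULL
  out
}
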