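#' Phrase repository
#'
#' The explanation realiser is a slot-filling grammar: a subject fragment,
#' one phrase per (feature, qualitative level) pair, and two sentence
#' templates — one for the tree-based (item/user) explanations, one for the
#' contrastive comparison. `default_phrases()` returns the built-in English
#' repository; `load_phrases()` reads the same structure from YAML
#' (`phrases: {feature: {level: text}}`,
#' `templates: {item_user: ..., contrastive: ...}`, `subject: ...`) so the
#' wording, or the language, can be swapped without touching code.
#'
#' Levels used by the realiser: nutrients `sufficient`/`low`/`high` plus
#' the contrastive fragments `worse`/`better`; calories
#' `appropriate`/`low`/`high`/`worse`/`better`; rating
#' `high`/`moderate`/`low`/`worse`/`better`; taste `worse`/`better`.
#'
#' @return a list with elements `subject`, `phrases`, `templates`.
#' @export
default_phrases <- function() {
  list(
    subject = "This recipe",
    templates = list(
      item_user = "{subject} {clauses}.",
      contrastive = paste0(
        "{subject} is suggested instead of {counter} that {neg_clauses}; ",
        "this recipe {pos_clauses}.")
    ),
    phrases = list(
      protein = list(
        sufficient = "provides sufficient protein",
        low = "is light on protein",
        high = "is rather high in protein",
        worse = "provides a poorer protein balance",
        better = "keeps protein at a healthy level"),
      lipids = list(
        sufficient = "has a balanced amount of fats",
        low = "is low in fat",
        high = "is high in fat",
        worse = "contains a substantially higher amount of fats",
        better = "keeps fats in a healthy range"),
      carbohydrates = list(
        sufficient = "provides a balanced amount of carbohydrates",
        low = "is low in carbohydrates",
        high = "is high in carbohydrates",
        worse = "carries a less healthy amount of carbohydrates",
        better = "keeps carbohydrates in a healthy range"),
      cholesterol = list(
        sufficient = "keeps cholesterol within a healthy range",
        low = "is very low in cholesterol",
        high = "is high in cholesterol",
        worse = "contains a substantially higher amount of cholesterol",
        better = "keeps cholesterol in check"),
      sodium = list(
        sufficient = "has a reasonable amount of salt",
        low = "is low in salt",
        high = "is high in salt",
        worse = "contains a substantially higher amount of salt",
        better = "keeps salt at a healthy level"),
      saturated_fat = list(
        sufficient = "keeps saturated fats within a healthy range",
        low = "is low in saturated fats",
        high = "is high in saturated fats",
        worse = "contains a substantially higher amount of saturated fats",
        better = "keeps saturated fats low"),
      calories = list(
        appropriate = "matches your calorie needs for this meal",
        low = "is a little light on calories for you",
        high = "exceeds your calorie needs for this meal",
        worse = "fits your calorie needs less well",
        better = "fits your calorie needs better"),
      rating = list(
        high = "is highly rated by other users",
        moderate = "is decently rated by other users",
        low = "has modest ratings from other users",
        worse = "is rated lower by other users",
        better = "is better appreciated by other users"),
      taste = list(
        worse = "matches your ingredient preferences less",
        better = "matches your ingredient preferences better")
    )
  )
}

#' @rdname default_phrases
#' @param path YAML file with the repository structure above.
#' @export
load_phrases <- function(path) {
  if (!file.exists(path)) stop("phrase file not found: ", path, call. = FALSE)
  raw <- yaml::read_yaml(path)
  base <- default_phrases()
  if (!is.null(raw$subject)) base$subject <- raw$subject
  for (nm in names(raw$templates)) base$templates[[nm]] <- raw$templates[[nm]]
  for (f in names(raw$phrases)) {
    for (lv in names(raw$phrases[[f]])) {
      base$phrases[[f]][[lv]] <- raw$phrases[[f]][[lv]]
    }
  }
  base
}

#' @rdname default_phrases
#' @param phrases a phrase repository list.
#' @export
save_phrases <- function(phrases, path) {
  yaml::write_yaml(phrases, path)
  invisible(path)
}
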