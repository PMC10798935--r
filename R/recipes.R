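NUTRIENTS <- c("protein", "lipids", "carbohydrates", "cholesterol",
               "sodium", "saturated_fat")
RECIPE_FEATURES <- c(NUTRIENTS, "calories", "rating")

#' Recipe tables
#'
#' Recipes are stored as a plain data.frame, one row per recipe, with
#' columns `id`, `name`, `cuisine`, `ingredient_classes` (a list column of
#' character vectors of class ids), the six per-serving nutrient amounts
#' (`protein`, `lipids`, `carbohydrates` in grams; `cholesterol`, `sodium`
#' in milligrams; `saturated_fat` in grams), `calories` (kcal) and `rating`
#' (community rating in \[1, 5\]).
#'
#' `recipe_table()` validates (and normalises) such a data.frame:
#' ingredient sets must be non-empty, all amounts non-negative, ratings in
#' \[1, 5\], ids unique. If `tax` is given, every ingredient class id must
#' resolve in the taxonomy; unknown ids are reported with their row numbers.
#'
#' @param recipes data.frame as described above; `ingredient_classes` may
#'   alternatively be a character column of semicolon-separated ids (the CSV
#'   encoding).
#' @param tax optional `nvc_taxonomy` for ingredient-id validation.
#' @return the validated recipe data.frame (class ids lower-cased).
#' @export
recipe_table <- function(recipes, tax = NULL) {
  stopifnot(is.data.frame(recipes))
  if (inherits(recipes, "nvc_recipes") && is.null(tax)) return(recipes)
  needed <- c("id", "name", "ingredient_classes", RECIPE_FEATURES)
  missing_cols <- setdiff(needed, names(recipes))
  if (length(missing_cols) > 0) {
    stop("recipe table lacks column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  if (!"cuisine" %in% names(recipes)) recipes$cuisine <- NA_character_
  recipes$id <- as.character(recipes$id)
  if (anyDuplicated(recipes$id)) {
    stop("duplicate recipe id(s): ",
         paste(unique(recipes$id[duplicated(recipes$id)]), collapse = ", "),
         call. = FALSE)
  }
  if (!is.list(recipes$ingredient_classes)) {
    recipes$ingredient_classes <- strsplit(
      as.character(recipes$ingredient_classes), ";", fixed = TRUE)
  }
  recipes$ingredient_classes <- lapply(recipes$ingredient_classes, function(x) {
    unique(tolower(trimws(as.character(x))))
  })
  empty <- which(lengths(recipes$ingredient_classes) == 0)
  if (length(empty) > 0) {
    stop("recipe row(s) with empty ingredient set: ",
         paste(empty, collapse = ", "), call. = FALSE)
  }
  for (col in RECIPE_FEATURES) {
    recipes[[col]] <- as.numeric(recipes[[col]])
  }
  amount_cols <- c(NUTRIENTS, "calories")
  neg <- which(Reduce(`|`, lapply(amount_cols, function(cn) {
    !is.na(recipes[[cn]]) & recipes[[cn]] < 0
  })))
  if (length(neg) > 0) {
    stop("negative nutrient amount(s) in row(s): ",
         paste(neg, collapse = ", "), call. = FALSE)
  }
  bad_rating <- which(!is.na(recipes$rating) &
                        (recipes$rating < 1 | recipes$rating > 5))
  if (length(bad_rating) > 0) {
    stop("rating outside [1, 5] in row(s): ",
         paste(bad_rating, collapse = ", "), call. = FALSE)
  }
  if (!is.null(tax)) {
    known <- tax$classes$id
    for (i in seq_len(nrow(recipes))) {
      unknown <- setdiff(recipes$ingredient_classes[[i]], known)
      if (length(unknown) > 0) {
        stop("row ", i, " (recipe '", recipes$id[i],
             "') has unknown ingredient class id(s): ",
             paste(unknown, collapse = ", "), call. = FALSE)
      }
    }
  }
  rownames(recipes) <- NULL
  class(recipes) <- c("nvc_recipes", "data.frame")
  recipes
}

#' Read / write recipe files
#'
#' The CSV layout has columns
#' `id,name,cuisine,ingredient_classes,protein,lipids,carbohydrates,`
#' `cholesterol,sodium,saturated_fat,calories,rating`, with
#' `ingredient_classes` semicolon-separated. A JSON mirror with the same
#' field names (ingredient classes as arrays) is selected by the `.json`
#' extension.
#'
#' Rows with any missing nutrient, calorie or rating value are dropped (the
#' catalogue-cleaning step applied to the source recipe collection); the
#' number of dropped rows is reported via `message()` and attached as
#' attribute `"dropped"`.
#'
#' @param path file path (`.csv` or `.json`).
#' @param tax optional taxonomy; unknown ingredient ids then error with row
#'   numbers.
#' @return [read_recipes()]: a validated recipe table with attribute
#'   `dropped`; [write_recipes()]: `path`, invisibly.
#' @export
read_recipes <- function(path, tax = NULL) {
  if (!file.exists(path)) stop("recipe file not found: ", path, call. = FALSE)
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    raw <- jsonlite::read_json(path, simplifyVector = FALSE)
    rows <- lapply(raw, function(r) {
      data.frame(
        id = as.character(r$id), name = as.character(r$name),
        cuisine = if (is.null(r$cuisine)) NA_character_ else as.character(r$cuisine),
        ingredient_classes = paste(unlist(r$ingredient_classes), collapse = ";"),
        protein = null_na(r$protein), lipids = null_na(r$lipids),
        carbohydrates = null_na(r$carbohydrates),
        cholesterol = null_na(r$cholesterol), sodium = null_na(r$sodium),
        saturated_fat = null_na(r$saturated_fat),
        calories = null_na(r$calories), rating = null_na(r$rating),
        stringsAsFactors = FALSE
      )
    })
    df <- do.call(rbind, rows)
  } else {
    df <- utils::read.csv(path, stringsAsFactors = FALSE,
                          colClasses = c(id = "character"))
    missing_cols <- setdiff(c("id", "name", "ingredient_classes",
                              RECIPE_FEATURES), names(df))
    if (length(missing_cols) > 0) {
      stop("recipe file ", path, " lacks column(s): ",
           paste(missing_cols, collapse = ", "), call. = FALSE)
    }
  }
  complete <- stats::complete.cases(df[, c(RECIPE_FEATURES)])
  n_drop <- sum(!complete)
  if (n_drop > 0) {
    message("read_recipes: dropped ", n_drop,
            " recipe(s) with incomplete nutrient information")
  }
  out <- recipe_table(df[complete, , drop = FALSE], tax = tax)
  attr(out, "dropped") <- n_drop
  out
}

null_na <- function(x) if (is.null(x)) NA_real_ else as.numeric(x)

#' @rdname read_recipes
#' @param recipes a recipe table.
#' @export
write_recipes <- function(recipes, path) {
  recipes <- recipe_table(recipes)
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    out <- lapply(seq_len(nrow(recipes)), function(i) {
      r <- as.list(recipes[i, setdiff(names(recipes), "ingredient_classes")])
      r$ingredient_classes <- recipes$ingredient_classes[[i]]
      r
    })
    jsonlite::write_json(out, path, auto_unbox = TRUE, pretty = TRUE, digits = NA)
  } else {
    flat <- recipes
    flat$ingredient_classes <- vapply(recipes$ingredient_classes,
                                      paste, character(1), collapse = ";")
    utils::write.csv(flat, path, row.names = FALSE)
  }
  invisible(path)
}

#' User profiles
#'
#' A user profile carries the demographics needed for the metabolic-rate
#' calculations plus the dietary constraint set: dietary categories
#' (matched against the taxonomy's `does_not_eat` map), allergies,
#' disliked and liked ingredient classes.
#'
#' @param sex `"male"` or `"female"`.
#' @param age years (> 0).
#' @param height cm (> 0).
#' @param weight kg (> 0).
#' @param activity_level one of `"too_little"`, `"light"`, `"moderate"`,
#'   `"strong"`, `"very_strong"`.
#' @param dietary_categories character vector of category labels (e.g.
#'   `"vegan"`).
#' @param allergies,dislikes,likes character vectors of ingredient-class ids;
#'   `likes` and `dislikes` must be disjoint.
#' @return an object of class `nvc_profile`.
#' @export
user_profile <- function(sex, age, height, weight,
                         activity_level = "moderate",
                         dietary_categories = character(0),
                         allergies = character(0),
                         dislikes = character(0),
                         likes = character(0)) {
  sex <- match.arg(sex, c("male", "female"))
  activity_level <- match.arg(activity_level, names(ACTIVITY_MULTIPLIERS))
  stopifnot(is.numeric(age), age > 0, is.numeric(height), height > 0,
            is.numeric(weight), weight > 0)
  norm <- function(x) unique(tolower(trimws(as.character(x))))
  likes <- norm(likes); dislikes <- norm(dislikes)
  overlap <- intersect(likes, dislikes)
  if (length(overlap) > 0) {
    stop("classes cannot be both liked and disliked: ",
         paste(overlap, collapse = ", "), call. = FALSE)
  }
  structure(
    list(sex = sex, age = as.numeric(age), height = as.numeric(height),
         weight = as.numeric(weight), activity_level = activity_level,
         dietary_categories = norm(dietary_categories),
         allergies = norm(allergies), dislikes = dislikes, likes = likes),
    class = "nvc_profile"
  )
}

#' @export
print.nvc_profile <- function(x, ...) {
  cat("<nvc_profile> ", x$sex, ", ", x$age, " y, ", x$height, " cm, ",
      x$weight, " kg, activity ", x$activity_level, "\n", sep = "")
  if (length(x$dietary_categories) > 0)
    cat("  categories:", paste(x$dietary_categories, collapse = ", "), "\n")
  invisible(x)
}

#' Read / write a user profile (JSON)
#'
#' Field names match [user_profile()] exactly.
#'
#' @param path JSON file path.
#' @return [read_profile()]: an `nvc_profile`; [write_profile()]: `path`,
#'   invisibly.
#' @export
read_profile <- function(path) {
  if (!file.exists(path)) stop("profile file not found: ", path, call. = FALSE)
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  chr0 <- function(x) if (is.null(x)) character(0) else as.character(x)
  user_profile(
    sex = raw$sex, age = raw$age, height = raw$height, weight = raw$weight,
    activity_level = if (is.null(raw$activity_level)) "moderate" else raw$activity_level,
    dietary_categories = chr0(raw$dietary_categories),
    allergies = chr0(raw$allergies),
    dislikes = chr0(raw$dislikes),
    likes = chr0(raw$likes)
  )
}

#' @rdname read_profile
#' @param profile an `nvc_profile`.
#' @export
write_profile <- function(profile, path) {
  stopifnot(inherits(profile, "nvc_profile"))
  jsonlite::write_json(unclass(profile), path, auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)
  invisible(path)
}

RECIPE_CRITIQUES <- c("ate_recently", "allergic", "dislike", "custom")
EXPLANATION_CRITIQUES <- c("not_convincing", "not_my_case", "incomplete",
                           "not_clear", "disagree")

#' Structured critiques
#'
#' A critique is the user's pre-structured objection, either to the offered
#' recipe ("I ate Y recently", "I'm allergic to Y", "I don't like Y", or a
#' free-text custom remark) or to its explanation ("not convincing",
#' "doesn't fit my case", "incomplete", "not clear", "I disagree").
#'
#' @param kind recipe critiques: `ate_recently`, `allergic`, `dislike`,
#'   `custom`; explanation critiques: `not_convincing`, `not_my_case`,
#'   `incomplete`, `not_clear`, `disagree`.
#' @param target_class ingredient-class id; required for (and only allowed
#'   with) `ate_recently`, `allergic` and `dislike`.
#' @param text optional free text (custom critiques).
#' @return an object of class `nvc_critique`.
#' @export
critique <- function(kind, target_class = NULL, text = NULL) {
  kind <- match.arg(kind, c(RECIPE_CRITIQUES, EXPLANATION_CRITIQUES))
  targeted <- kind %in% c("ate_recently", "allergic", "dislike")
  if (targeted && (is.null(target_class) || !nzchar(target_class))) {
    stop("critique '", kind, "' requires a target ingredient class",
         call. = FALSE)
  }
  if (!targeted && !is.null(target_class)) {
    stop("critique '", kind, "' does not take a target class", call. = FALSE)
  }
  structure(
    list(kind = kind,
         target_class = if (targeted) tolower(trimws(target_class)) else NULL,
         text = text,
         scope = if (kind %in% RECIPE_CRITIQUES) "recipe" else "explanation"),
    class = "nvc_critique"
  )
}
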