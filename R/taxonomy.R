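#' Ingredient-class taxonomy
#'
#' An `nvc_taxonomy` holds the ingredient-class tree used for dietary
#' reasoning: every class has an id, a human-readable name, and a parent id
#' (the single root has none). A `does_not_eat` map links dietary-category
#' labels (e.g. `"vegan"`) to the ingredient classes that category excludes;
#' exclusions always apply to a class together with all of its descendants,
#' so listing `"dairy"` is enough to rule out every kind of cheese below it.
#'
#' Class ids are matched case-insensitively and stored lower-case.
#'
#' @param classes data.frame with columns `id`, `name`, `parent`
#'   (`NA` or `""` for the root).
#' @param does_not_eat named list mapping a dietary-category label to a
#'   character vector of class ids.
#' @return An object of class `nvc_taxonomy` with elements `classes`
#'   (data.frame), `does_not_eat` (named list of lower-case ids), and
#'   `children` (precomputed child index used by [descendants()]).
#' @examples
#' tx <- taxonomy(data.frame(
#'   id = c("food", "veg", "tomatoes"),
#'   name = c("Food", "Vegetables", "Tomatoes"),
#'   parent = c(NA, "food", "veg")
#' ))
#' descendants(tx, "veg")
#' @export
taxonomy <- function(classes, does_not_eat = list()) {
  stopifnot(is.data.frame(classes))
  required <- c("id", "name", "parent")
  missing_cols <- setdiff(required, names(classes))
  if (length(missing_cols) > 0) {
    stop("taxonomy classes table lacks column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  classes <- data.frame(
    id = tolower(trimws(as.character(classes$id))),
    name = as.character(classes$name),
    parent = tolower(trimws(as.character(classes$parent))),
    stringsAsFactors = FALSE
  )
  classes$parent[is.na(classes$parent) | classes$parent == "" |
                   classes$parent == "na"] <- NA_character_

  if (anyDuplicated(classes$id)) {
    dup <- unique(classes$id[duplicated(classes$id)])
    stop("duplicate class id(s): ", paste(dup, collapse = ", "), call. = FALSE)
  }
  roots <- classes$id[is.na(classes$parent)]
  if (length(roots) != 1) {
    stop("taxonomy must have exactly one root class, found ",
         length(roots), call. = FALSE)
  }
  unknown_parent <- setdiff(classes$parent[!is.na(classes$parent)], classes$id)
  if (length(unknown_parent) > 0) {
    stop("parent id(s) not defined as classes: ",
         paste(unknown_parent, collapse = ", "), call. = FALSE)
  }

  # walk towards the root from every node; revisiting a node on the same walk
  # is a cycle (includes self-parents)
  parent_of <- stats::setNames(classes$parent, classes$id)
  for (start in classes$id) {
    seen <- character(0)
    node <- start
    while (!is.na(node)) {
      if (node %in% seen) {
        cyc <- c(seen[which(seen == node):length(seen)], node)
        stop("cycle in taxonomy parent links: ",
             paste(cyc, collapse = " -> "), call. = FALSE)
      }
      seen <- c(seen, node)
      node <- parent_of[[node]]
    }
  }

  does_not_eat <- lapply(does_not_eat, function(ids) {
    unique(tolower(trimws(as.character(ids))))
  })
  bad <- setdiff(unique(unlist(does_not_eat)), classes$id)
  if (length(bad) > 0) {
    stop("does_not_eat references unknown class id(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  }

  children <- split(classes$id[!is.na(classes$parent)],
                    classes$parent[!is.na(classes$parent)])
  structure(
    list(classes = classes, does_not_eat = does_not_eat, children = children),
    class = "nvc_taxonomy"
  )
}

#' @export
print.nvc_taxonomy <- function(x, ...) {
  cat("<nvc_taxonomy> ", nrow(x$classes), " classes, ",
      length(x$does_not_eat), " dietary categories, root '",
      x$classes$id[is.na(x$classes$parent)], "'\n", sep = "")
  invisible(x)
}

#' Load / save a taxonomy file
#'
#' Taxonomy files are YAML (or JSON) with the schema
#' `classes: [{id, name, parent}]` and
#' `does_not_eat: {category: [class ids]}`. Saving always writes canonical
#' YAML (classes sorted by id, lower-case ids), so load -> save -> load is
#' idempotent.
#'
#' @param path file path; format chosen by extension (`.json` vs `.yaml`/`.yml`).
#' @return [load_taxonomy()] returns an `nvc_taxonomy`;
#'   [save_taxonomy()] returns `path` invisibly.
#' @export
load_taxonomy <- function(path) {
  if (!file.exists(path)) stop("taxonomy file not found: ", path, call. = FALSE)
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = FALSE)
  } else {
    yaml::read_yaml(path)
  }
  if (is.null(raw$classes)) {
    stop("taxonomy file has no 'classes' section: ", path, call. = FALSE)
  }
  rows <- lapply(seq_along(raw$classes), function(i) {
    cl <- raw$classes[[i]]
    if (is.null(cl$id) || !nzchar(cl$id)) {
      stop("taxonomy class #", i, " has no id", call. = FALSE)
    }
    data.frame(
      id = as.character(cl$id),
      name = if (is.null(cl$name)) as.character(cl$id) else as.character(cl$name),
      parent = if (is.null(cl$parent)) NA_character_ else as.character(cl$parent),
      stringsAsFactors = FALSE
    )
  })
  dne <- raw$does_not_eat
  if (is.null(dne)) dne <- list()
  dne <- lapply(dne, function(v) as.character(unlist(v)))
  taxonomy(do.call(rbind, rows), dne)
}

#' @rdname load_taxonomy
#' @param tax an `nvc_taxonomy`.
#' @export
save_taxonomy <- function(tax, path) {
  stopifnot(inherits(tax, "nvc_taxonomy"))
  cl <- tax$classes[order(tax$classes$id), , drop = FALSE]
  classes <- lapply(seq_len(nrow(cl)), function(i) {
    entry <- list(id = cl$id[i], name = cl$name[i])
    if (!is.na(cl$parent[i])) entry$parent <- cl$parent[i]
    entry
  })
  dne <- tax$does_not_eat[order(names(tax$does_not_eat))]
  dne <- lapply(dne, function(v) as.list(sort(v)))
  out <- list(classes = classes)
  if (length(dne) > 0) out$does_not_eat <- dne
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(out, path, auto_unbox = TRUE, pretty = TRUE)
  } else {
    yaml::write_yaml(out, path)
  }
  invisible(path)
}

#' Transitive descendants of an ingredient class
#'
#' Returns the class itself plus every class reachable through child links,
#' mirroring how a dietary restriction on a broad class (e.g. `dairy`)
#' covers all of its specialisations.
#'
#' @param tax an `nvc_taxonomy`.
#' @param class_id a single class id (case-insensitive).
#' @return character vector of class ids (the class itself always included).
#' @export
descendants <- function(tax, class_id) {
  stopifnot(inherits(tax, "nvc_taxonomy"), length(class_id) == 1)
  class_id <- tolower(trimws(class_id))
  if (!class_id %in% tax$classes$id) {
    stop("unknown ingredient class id: ", class_id, call. = FALSE)
  }
  out <- character(0)
  frontier <- class_id
  while (length(frontier) > 0) {
    out <- c(out, frontier)
    frontier <- unlist(tax$children[frontier], use.names = FALSE)
  }
  unique(out)
}

descendants_of_set <- function(tax, ids) {
  ids <- tolower(trimws(ids))
  unique(unlist(lapply(ids, function(id) descendants(tax, id)), use.names = FALSE))
}

#' Ingredient classes forbidden for a user
#'
#' The union of the `does_not_eat` entries of the user's dietary categories,
#' plus allergies and disliked classes, each expanded to their full
#' descendant closure. Dislikes are treated as hard exclusions, the same as
#' allergies. A dietary category with no `does_not_eat` entry contributes
#' nothing.
#'
#' @param tax an `nvc_taxonomy`.
#' @param profile an `nvc_profile` (see [user_profile()]).
#' @return character vector of forbidden class ids.
#' @export
forbidden_classes <- function(tax, profile) {
  stopifnot(inherits(tax, "nvc_taxonomy"), inherits(profile, "nvc_profile"))
  seeds <- character(0)
  for (cat in profile$dietary_categories) {
    entry <- tax$does_not_eat[[tolower(cat)]]
    if (!is.null(entry)) seeds <- c(seeds, entry)
  }
  seeds <- c(seeds, profile$allergies, profile$dislikes)
  if (length(seeds) == 0) return(character(0))
  descendants_of_set(tax, unique(seeds))
}

#' Can a user eat these recipes?
#'
#' A recipe is consumable when none of its ingredient classes falls in the
#' user's forbidden set ([forbidden_classes()]).
#'
#' @param tax an `nvc_taxonomy`.
#' @param profile an `nvc_profile`.
#' @param recipes a recipe table (see [recipe_table()]); may have any number
#'   of rows.
#' @return logical vector, one element per recipe row.
#' @export
consumable <- function(tax, profile, recipes) {
  recipes <- recipe_table(recipes)
  forb <- forbidden_classes(tax, profile)
  vapply(recipes$ingredient_classes,
         function(ing) !any(ing %in% forb),
         logical(1))
}
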