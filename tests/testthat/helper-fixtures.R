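# Shared fixtures: a tiny hand-built taxonomy and recipe constructors used
# across the module tests. Everything is built in code at test time.

tiny_taxonomy <- function() {
  taxonomy(
    data.frame(
      id = c("food", "plants", "animals", "veg", "zucchini", "tomatoes",
             "cherry_tomato", "dairy", "cheese", "milk", "meat", "beef",
             "grains", "rice", "pasta"),
      name = c("Food", "Plants", "Animals", "Vegetables", "Zucchini",
               "Tomatoes", "Cherry tomato", "Dairy", "Cheese", "Milk",
               "Meat", "Beef", "Grains", "Rice", "Pasta"),
      parent = c(NA, "food", "food", "plants", "veg", "veg", "tomatoes",
                 "animals", "dairy", "dairy", "animals", "meat", "plants",
                 "grains", "grains")
    ),
    does_not_eat = list(vegan = "animals", vegetarian = "meat")
  )
}

# a recipe row with controllable nutrients; defaults sit inside the default
# per-meal bands so the base recipe scores 5 on everything
make_recipe <- function(id, ingredients, protein = 20, lipids = 15,
                        carbohydrates = 60, cholesterol = 50, sodium = 300,
                        saturated_fat = 5, calories = 700, rating = 4,
                        name = id, cuisine = "test") {
  df <- data.frame(id = id, name = name, cuisine = cuisine,
                   protein = protein, lipids = lipids,
                   carbohydrates = carbohydrates, cholesterol = cholesterol,
                   sodium = sodium, saturated_fat = saturated_fat,
                   calories = calories, rating = rating,
                   stringsAsFactors = FALSE)
  df$ingredient_classes <- if (is.list(ingredients)) ingredients else
    list(ingredients)
  recipe_table(df)
}

bind_recipes <- function(...) {
  out <- do.call(rbind, lapply(list(...), as.data.frame))
  recipe_table(out)
}

base_profile <- function(...) {
  user_profile(sex = "male", age = 30, height = 178, weight = 80,
               activity_level = "moderate", ...)
}

# a fixed band independent of any profile: recipes at 700 kcal sit inside
test_band <- function() make_band(600, 800)
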