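#' Built-in ingredient-class taxonomy
#'
#' A five-level, ~55-class illustrative taxonomy (food > plant/animal
#' products > groups > items > varieties) with dietary-restriction entries
#' for vegan, vegetarian, pescatarian, halal, kosher and
#' lactose-intolerant users. It is designed for the synthetic generators
#' and examples, not as a reconstruction of any particular food ontology;
#' the same YAML schema ([load_taxonomy()]) accepts real ones.
#'
#' @return an `nvc_taxonomy`.
#' @export
default_taxonomy <- function() {
  entry <- function(id, name, parent = NA) {
    data.frame(id = id, name = name, parent = parent, stringsAsFactors = FALSE)
  }
  cl <- rbind(
    entry("food", "Food"),
    entry("plant_products", "Plant products", "food"),
    entry("animal_products", "Animal products", "food"),
    # plant side
    entry("vegetables", "Vegetables", "plant_products"),
    entry("tomatoes", "Tomatoes", "vegetables"),
    entry("cherry_tomato", "Cherry tomato", "tomatoes"),
    entry("plum_tomato", "Plum tomato", "tomatoes"),
    entry("leafy_greens", "Leafy greens", "vegetables"),
    entry("spinach", "Spinach", "leafy_greens"),
    entry("kale", "Kale", "leafy_greens"),
    entry("zucchini", "Zucchini", "vegetables"),
    entry("peppers", "Peppers", "vegetables"),
    entry("onions", "Onions", "vegetables"),
    entry("carrots", "Carrots", "vegetables"),
    entry("mushrooms", "Mushrooms", "vegetables"),
    entry("fruits", "Fruits", "plant_products"),
    entry("apples", "Apples", "fruits"),
    entry("bananas", "Bananas", "fruits"),
    entry("berries", "Berries", "fruits"),
    entry("strawberry", "Strawberry", "berries"),
    entry("blueberry", "Blueberry", "berries"),
    entry("citrus", "Citrus", "fruits"),
    entry("lemon", "Lemon", "citrus"),
    entry("orange", "Orange", "citrus"),
    entry("grains", "Grains", "plant_products"),
    entry("rice", "Rice", "grains"),
    entry("wheat", "Wheat", "grains"),
    entry("pasta", "Pasta", "wheat"),
    entry("bread", "Bread", "wheat"),
    entry("oats", "Oats", "grains"),
    entry("corn", "Corn", "grains"),
    entry("legumes", "Legumes", "plant_products"),
    entry("lentils", "Lentils", "legumes"),
    entry("chickpeas", "Chickpeas", "legumes"),
    entry("beans", "Beans", "legumes"),
    entry("soy", "Soy", "legumes"),
    entry("tofu", "Tofu", "soy"),
    entry("nuts_seeds", "Nuts and seeds", "plant_products"),
    entry("peanuts", "Peanuts", "nuts_seeds"),
    entry("almonds", "Almonds", "nuts_seeds"),
    entry("walnuts", "Walnuts", "nuts_seeds"),
    entry("sesame", "Sesame", "nuts_seeds"),
    entry("herbs_spices", "Herbs and spices", "plant_products"),
    entry("basil", "Basil", "herbs_spices"),
    entry("garlic", "Garlic", "herbs_spices"),
    entry("chili", "Chili", "herbs_spices"),
    entry("oils", "Oils", "plant_products"),
    entry("olive_oil", "Olive oil", "oils"),
    # animal side
    entry("meat", "Meat", "animal_products"),
    entry("beef", "Beef", "meat"),
    entry("pork", "Pork", "meat"),
    entry("poultry", "Poultry", "meat"),
    entry("chicken", "Chicken", "poultry"),
    entry("turkey", "Turkey", "poultry"),
    entry("lamb", "Lamb", "meat"),
    entry("seafood", "Seafood", "animal_products"),
    entry("fish", "Fish", "seafood"),
    entry("salmon", "Salmon", "fish"),
    entry("tuna", "Tuna", "fish"),
    entry("shellfish", "Shellfish", "seafood"),
    entry("shrimp", "Shrimp", "shellfish"),
    entry("dairy", "Dairy", "animal_products"),
    entry("milk", "Milk", "dairy"),
    entry("cheese", "Cheese", "dairy"),
    entry("cheddar", "Cheddar", "cheese"),
    entry("mozzarella", "Mozzarella", "cheese"),
    entry("yogurt", "Yogurt", "dairy"),
    entry("butter", "Butter", "dairy"),
    entry("eggs", "Eggs", "animal_products"),
    entry("honey", "Honey", "animal_products")
  )
  taxonomy(cl, does_not_eat = list(
    vegan = "animal_products",
    vegetarian = c("meat", "seafood"),
    pescatarian = "meat",
    halal = "pork",
    kosher = c("pork", "shellfish"),
    lactose_intolerant = "dairy"
  ))
}

#' Leaf classes of a taxonomy
#'
#' @param tax an `nvc_taxonomy`.
#' @return character vector of class ids without children.
#' @export
taxonomy_leaves <- function(tax) {
  stopifnot(inherits(tax, "nvc_taxonomy"))
  sort(setdiff(tax$classes$id, names(tax$children)))
}

#' Generate a synthetic recipe catalogue
#'
#' Each recipe draws 3–10 ingredient classes uniformly from the taxonomy
#' leaves. Nutrient amounts are log-normal, centred (on the log scale) on
#' the midpoint of each nutrient's healthy band with the spread chosen so
#' that roughly one third of draws fall below, inside and above the band —
#' mirroring a realistic catalogue in which most recipes break at least
#' one guideline. Calories follow the same rule around `calorie_range`;
#' ratings are a Beta(4, 2) draw rescaled to \[1, 5\]. Fully deterministic
#' per seed.
#'
#' @param n_recipes catalogue size (the emulated catalogue is ~1300
#'   recipes).
#' @param tax an `nvc_taxonomy`.
#' @param seed integer seed.
#' @param limits an `nvc_limits` giving the per-nutrient bands.
#' @param calorie_range kcal band used to centre the calorie draw.
#' @return a validated recipe table of `n_recipes` rows.
#' @export
gen_catalogue <- function(n_recipes = 1300, tax = default_taxonomy(),
                          seed = 1L, limits = default_nutrient_limits(),
                          calorie_range = c(650, 850)) {
  stopifnot(n_recipes >= 1)
  limits <- nutrient_limits(limits)
  leaves <- taxonomy_leaves(tax)
  cuisines <- c("italian", "turkish", "indian", "mexican", "japanese",
                "french", "levantine", "thai")
  withr_seed(seed, {
    ings <- lapply(seq_len(n_recipes), function(i) {
      sample(leaves, sample(3:10, 1))
    })
    lognorm_band <- function(n, lo, hi) {
      mu <- (log(lo) + log(hi)) / 2
      s <- (log(hi) - log(lo)) / (2 * stats::qnorm(2 / 3))
      stats::rlnorm(n, meanlog = mu, sdlog = s)
    }
    df <- data.frame(
      id = sprintf("r%05d", seq_len(n_recipes)),
      name = NA_character_,
      cuisine = sample(cuisines, n_recipes, replace = TRUE),
      stringsAsFactors = FALSE
    )
    df$ingredient_classes <- ings
    for (n in NUTRIENTS) {
      df[[n]] <- round(lognorm_band(n_recipes, limits[[n]]["min"],
                                    limits[[n]]["max"]), 2)
    }
    df$calories <- round(lognorm_band(n_recipes, calorie_range[1],
                                      calorie_range[2]), 1)
    df$rating <- round(1 + 4 * stats::rbeta(n_recipes, 4, 2), 2)
    main <- vapply(ings, `[`, character(1), 1)
    df$name <- paste0(toupper(substring(df$cuisine, 1, 1)),
                      substring(df$cuisine, 2), " ",
                      gsub("_", " ", main), " dish ", seq_len(n_recipes))
    recipe_table(df, tax = tax)
  })
}

withr_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Simulated-user persona
#'
#' The hidden behavioural model of a simulated participant: a set of truly
#' liked ingredient classes (of which the revealed profile likes are only a
#' subset), a priority blend `lambda` between taste and healthiness in the
#' hidden utility, a non-increasing acceptance-threshold schedule
#' `theta(t)` over the session, and propensities over the three exclusion
#' critique kinds.
#'
#' @param hidden_likes character vector of class ids the user truly likes.
#' @param hidden_dislikes class ids the user truly dislikes; an offer
#'   containing any of them is vetoed (hidden utility 0) and they are the
#'   preferred critique targets (disjoint from `hidden_likes`).
#' @param priority `"taste_first"`, `"health_first"` or `"mixed"`.
#' @param lambda taste weight in \[0, 1\] of the hidden utility
#'   `u = lambda * taste + (1 - lambda) * health`; defaults 0.8 / 0.2 /
#'   0.5 by priority.
#' @param theta_start,theta_end acceptance threshold at the first and last
#'   round (linear in between, non-increasing).
#' @param propensities named probabilities over `dislike`, `ate_recently`,
#'   `allergic`; must sum to 1.
#' @return an object of class `nvc_persona`.
#' @export
persona <- function(hidden_likes, hidden_dislikes = character(0),
                    priority = c("taste_first", "health_first", "mixed"),
                    lambda = NULL,
                    theta_start = 0.75, theta_end = 0.45,
                    propensities = c(dislike = 0.6, ate_recently = 0.3,
                                     allergic = 0.1)) {
  priority <- match.arg(priority)
  if (is.null(lambda)) {
    lambda <- switch(priority, taste_first = 0.8, health_first = 0.2,
                     mixed = 0.5)
  }
  stopifnot(lambda >= 0, lambda <= 1, theta_end <= theta_start,
            abs(sum(propensities) - 1) < 1e-9)
  stopifnot(all(names(propensities) %in%
                  c("dislike", "ate_recently", "allergic")))
  hidden_dislikes <- tolower(hidden_dislikes)
  if (length(intersect(tolower(hidden_likes), hidden_dislikes)) > 0) {
    stop("hidden likes and dislikes must be disjoint", call. = FALSE)
  }
  structure(list(hidden_likes = tolower(hidden_likes),
                 hidden_dislikes = hidden_dislikes, priority = priority,
                 lambda = lambda, theta_start = theta_start,
                 theta_end = theta_end, propensities = propensities),
            class = "nvc_persona")
}

#' @rdname persona
#' @param p an `nvc_persona`.
#' @param t round number (1-based).
#' @param deadline round budget T.
#' @return [persona_theta()]: the acceptance threshold at round t.
#' @export
persona_theta <- function(p, t, deadline) {
  if (deadline <= 1) return(p$theta_end)
  frac <- (min(t, deadline) - 1) / (deadline - 1)
  p$theta_start + frac * (p$theta_end - p$theta_start)
}

#' Generate synthetic users
#'
#' Profiles emulate a small adult study population: ages uniform in 19–58,
#' sex-specific height and weight, all five activity levels represented,
#' and occasional dietary categories drawn from the taxonomy's
#' `does_not_eat` map. Each user also receives a hidden persona: priority
#' taste-first with probability 0.69, health-first with 0.21, mixed
#' otherwise (the proportions observed in the pre-study survey of food
#' priorities). Hidden likes cover ~40% of the taxonomy leaves and hidden
#' dislikes ~15%; the revealed profile likes are a random half of the
#' hidden likes, and a revealed dislike (when any) is one of the hidden
#' dislikes.
#'
#' @param n_users number of users.
#' @param tax an `nvc_taxonomy`.
#' @param seed integer seed.
#' @return list with `profiles` (list of `nvc_profile`) and `personas`
#'   (list of `nvc_persona`).
#' @export
gen_users <- function(n_users = 54, tax = default_taxonomy(), seed = 1L) {
  stopifnot(n_users >= 1)
  leaves <- taxonomy_leaves(tax)
  cats <- names(tax$does_not_eat)
  withr_seed(seed, {
    profiles <- vector("list", n_users)
    personas <- vector("list", n_users)
    for (i in seq_len(n_users)) {
      sex <- sample(c("male", "female"), 1)
      age <- sample(19:58, 1)
      height <- round(stats::rnorm(1, if (sex == "male") 178 else 165, 7), 1)
      weight <- round(max(45, stats::rnorm(1, if (sex == "male") 80 else 65,
                                           11)), 1)
      activity <- sample(names(ACTIVITY_MULTIPLIERS), 1,
                         prob = c(0.15, 0.25, 0.30, 0.20, 0.10))
      dietary <- if (stats::runif(1) < 0.20) sample(cats, 1) else character(0)
      hidden <- sample(leaves, round(0.4 * length(leaves)))
      likes <- sample(hidden, ceiling(length(hidden) / 2))
      dis_pool <- setdiff(leaves, hidden)
      hidden_dis <- sample(dis_pool, round(0.15 * length(leaves)))
      dislikes <- if (stats::runif(1) < 0.8 && length(hidden_dis) > 0)
        sample(hidden_dis, 1) else character(0)
      allergies <- if (stats::runif(1) < 0.05) "peanuts" else character(0)
      pr <- stats::runif(1)
      priority <- if (pr < 0.69) "taste_first" else if (pr < 0.90)
        "health_first" else "mixed"
      profiles[[i]] <- user_profile(
        sex = sex, age = age, height = height, weight = weight,
        activity_level = activity, dietary_categories = dietary,
        allergies = allergies, dislikes = dislikes, likes = likes)
      personas[[i]] <- persona(hidden_likes = hidden,
                               hidden_dislikes = hidden_dis,
                               priority = priority)
    }
    list(profiles = profiles, personas = personas)
  })
}

hidden_utility <- function(p, recipe, limits, band) {
  ing <- recipe$ingredient_classes[[1]]
  # a dish containing a truly disliked ingredient is vetoed outright
  if (any(ing %in% p$hidden_dislikes)) return(0)
  taste <- sum(ing %in% p$hidden_likes) / length(ing)
  subs <- c(nutrient_subscores(recipe, limits)[1, ],
            amr_score(recipe$calories, band))
  health <- mean(subs) / 5
  p$lambda * taste + (1 - p$lambda) * health
}

#' Simulated user response to an offer
#'
#' The hidden utility `u = lambda * taste + (1 - lambda) * health` is
#' compared with the persona's threshold at the current round: at or above
#' it the user accepts. Otherwise an interactive user critiques the
#' recipe: when the offer contains a truly disliked ingredient class, an
#' exclusion critique (kind drawn from the persona's propensities) targets
#' the least-liked such class (deterministic tie-break by id); when it
#' does not, the user sends a custom remark, which asks for a different
#' recipe without excluding an ingredient they might happily eat
#' elsewhere. A traditional user simply requests a new recommendation.
#' Consumes RNG draws; seed the stream per session for reproducibility.
#'
#' @param p an `nvc_persona`.
#' @param profile the user's `nvc_profile` (kept for interface symmetry;
#'   the hidden model does not read it).
#' @param offer one-row recipe table (the current offer).
#' @param round current round.
#' @param deadline session round budget.
#' @param mode `"interactive"` or `"traditional"`.
#' @param limits,band scoring context for the health term.
#' @return an `nvc_action`.
#' @export
simulated_user_respond <- function(p, profile, offer, round, deadline,
                                   mode = "interactive",
                                   limits = default_nutrient_limits(),
                                   band) {
  stopifnot(inherits(p, "nvc_persona"))
  offer <- recipe_table(offer)
  u <- hidden_utility(p, offer, limits, band)
  if (u >= persona_theta(p, round, deadline)) {
    return(user_action("accept"))
  }
  if (mode == "traditional") {
    return(user_action("request_new"))
  }
  ing <- sort(offer$ingredient_classes[[1]])
  disliked <- intersect(ing, sort(p$hidden_dislikes))
  if (length(disliked) > 0) {
    kind <- sample(names(p$propensities), 1, prob = p$propensities)
    return(user_action("critique_recipe",
                       critique(kind, target_class = disliked[1])))
  }
  # nothing in the dish is truly disliked: a custom remark asks to move on
  # without excluding an ingredient the user might actually accept later
  user_action("critique_recipe",
              critique("custom", text = "not to my taste"))
}

#' Generate a multi-user offer history
#'
#' Random (user, recipe) offers labelled by each persona's
#' utility-threshold rule; the threshold defaults to the persona's schedule
#' evaluated at a random round, or to the fixed `theta` when supplied. The
#' output feeds [build_user_dataset()].
#'
#' @param profiles,personas paired lists from [gen_users()].
#' @param recipes recipe table.
#' @param n_offers number of simulated offers.
#' @param seed integer seed.
#' @param limits,band scoring context (band defaults to each profile's own
#'   per-meal band).
#' @param deadline round budget used when sampling the threshold round.
#' @param theta optional fixed acceptance threshold overriding the
#'   schedule.
#' @return data.frame with `id`, the eight feature columns, `user` and
#'   `decision` (`"accept"`/`"reject"`).
#' @export
gen_history <- function(profiles, personas, recipes, n_offers = 200,
                        seed = 1L, limits = default_nutrient_limits(),
                        band = NULL, deadline = 20, theta = NULL) {
  recipes <- recipe_table(recipes)
  if (n_offers == 0) {
    out <- recipes[0, c("id", RECIPE_FEATURES)]
    out$user <- integer(0); out$decision <- character(0)
    return(as.data.frame(out))
  }
  withr_seed(seed, {
    ui <- sample(seq_along(profiles), n_offers, replace = TRUE)
    ri <- sample(seq_len(nrow(recipes)), n_offers, replace = TRUE)
    tt <- sample(seq_len(deadline), n_offers, replace = TRUE)
    decision <- character(n_offers)
    for (k in seq_len(n_offers)) {
      p <- personas[[ui[k]]]
      b <- if (is.null(band)) calorie_band(profiles[[ui[k]]]) else band
      u <- hidden_utility(p, recipes[ri[k], , drop = FALSE], limits, b)
      th <- if (is.null(theta)) persona_theta(p, tt[k], deadline) else theta
      decision[k] <- if (u >= th) "accept" else "reject"
    }
    out <- as.data.frame(recipes[ri, c("id", RECIPE_FEATURES)])
    out$user <- ui
    out$decision <- decision
    rownames(out) <- NULL
    out
  })
}

#' Run a paired simulated-user experiment
#'
#' Generates (or reuses) a catalogue, a user panel and an offer history,
#' then runs one full negotiation session per user in the requested
#' mode(s). With `mode = "both"` the same users, catalogue and per-session
#' seeds are used for the traditional and the interactive arm, giving a
#' paired design. Metrics per arm: agreement rate, mean and SD of the
#' terminal round, and the healthiness-label distribution of the accepted
#' recipes.
#'
#' @param mode `"interactive"`, `"traditional"` or `"both"`.
#' @param n_users number of simulated users (default 54, the emulated
#'   study size).
#' @param seed master seed; every random component derives from it.
#' @param config an `nvc_config`.
#' @param tax an `nvc_taxonomy`.
#' @param recipes optional pre-built catalogue; generated when `NULL`.
#' @param n_recipes catalogue size when generating.
#' @param n_history offers in the simulated global history (enables
#'   user-based explanations).
#' @return for a single mode an `nvc_metrics` list
#'   (`mode`, `n_sessions`, `agreement_rate`, `mean_rounds`, `sd_rounds`,
#'   `healthiness`, `rounds`, `outcomes`); for `"both"` a list with both
#'   arms under `$traditional` and `$interactive`.
#' @export
run_experiment <- function(mode = c("both", "interactive", "traditional"),
                           n_users = 54, seed = 1L, config = nvc_config(),
                           tax = default_taxonomy(), recipes = NULL,
                           n_recipes = 1300, n_history = 200) {
  mode <- match.arg(mode)
  if (is.null(recipes)) {
    recipes <- gen_catalogue(n_recipes, tax, seed = seed,
                             limits = config$limits)
  }
  users <- gen_users(n_users, tax, seed = seed + 1L)
  history <- gen_history(users$profiles, users$personas, recipes,
                         n_offers = n_history, seed = seed + 2L,
                         limits = config$limits,
                         deadline = config$deadline)
  session_seeds <- withr_seed(seed + 3L,
                              sample.int(.Machine$integer.max, n_users))
  modes <- if (mode == "both") c("traditional", "interactive") else mode
  arms <- lapply(modes, function(m) {
    run_arm(m, users, recipes, tax, config, history, session_seeds)
  })
  names(arms) <- modes
  if (mode == "both") arms else arms[[1]]
}

run_arm <- function(mode, users, recipes, tax, config, history,
                    session_seeds) {
  n <- length(users$profiles)
  rounds <- integer(n)
  outcomes <- character(n)
  accepted <- character(n)
  for (i in seq_len(n)) {
    res <- run_session(users$profiles[[i]], users$personas[[i]], recipes,
                       tax, config, mode, session_seeds[i], history)
    rounds[i] <- res$rounds
    outcomes[i] <- res$outcome
    accepted[i] <- if (is.null(res$accepted_id)) NA_character_ else
      res$accepted_id
  }
  agreed <- outcomes == "agreement"
  acc <- recipes[match(accepted[agreed], recipes$id), , drop = FALSE]
  health <- if (nrow(acc) > 0) {
    # healthiness of an agreement is judged against the accepting user's band
    vapply(which(agreed), function(i) {
      healthiness_label(recipes[match(accepted[i], recipes$id), ,
                                drop = FALSE],
                        config$limits,
                        calorie_band(users$profiles[[i]],
                                     config$meal_fraction, config$tolerance,
                                     config$female_constant),
                        config$healthiness_thresholds)
    }, character(1))
  } else character(0)
  dist <- table(factor(health, levels = c("highly_healthy", "healthy",
                                          "unhealthy")))
  structure(list(
    mode = mode, n_sessions = n,
    agreement_rate = mean(agreed),
    mean_rounds = mean(rounds), sd_rounds = stats::sd(rounds),
    healthiness = as.list(dist),
    rounds = rounds, outcomes = outcomes, accepted = accepted
  ), class = "nvc_metrics")
}

run_session <- function(profile, p, recipes, tax, config, mode, seed,
                        history) {
  withr_seed(seed, {
    session <- start_session(profile, recipes, tax, config, mode,
                             seed = seed, history = history)
    band <- session$band
    while (session$state == "awaiting_user") {
      off <- current_offer(session)
      action <- simulated_user_respond(
        p, session$profile, off$recipe, session$round, config$deadline,
        mode = mode, limits = config$limits, band = band)
      session <- step(session, action)
    }
    list(rounds = min(session$round, config$deadline),
         outcome = session$outcome, accepted_id = session$accepted_id,
         session = session)
  })
}

#' @export
print.nvc_metrics <- function(x, ...) {
  cat("<nvc_metrics> ", x$mode, ": ", x$n_sessions, " sessions, ",
      sprintf("%.1f%%", 100 * x$agreement_rate), " agreement, ",
      sprintf("%.2f +/- %.2f", x$mean_rounds, x$sd_rounds), " rounds\n",
      sep = "")
  cat("  healthiness of agreements: ",
      paste(names(x$healthiness), unlist(x$healthiness), sep = "=",
            collapse = ", "), "\n", sep = "")
  invisible(x)
}
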