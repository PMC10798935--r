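#' User actions in a negotiation session
#'
#' At every turn the user may accept the current offer, leave without an
#' agreement, critique the recipe or its explanation (interactive mode), or
#' simply ask for a new recommendation (traditional mode).
#'
#' @param kind one of `accept`, `leave`, `critique_recipe`,
#'   `critique_explanation`, `request_new`.
#' @param crit an `nvc_critique` (required for the two critique kinds; its
#'   scope must match).
#' @return an object of class `nvc_action`.
#' @export
user_action <- function(kind, crit = NULL) {
  kind <- match.arg(kind, c("accept", "leave", "critique_recipe",
                            "critique_explanation", "request_new"))
  if (kind %in% c("critique_recipe", "critique_explanation")) {
    if (is.null(crit) || !inherits(crit, "nvc_critique")) {
      stop("action '", kind, "' requires an nvc_critique", call. = FALSE)
    }
    need <- if (kind == "critique_recipe") "recipe" else "explanation"
    if (crit$scope != need) {
      stop("critique scope '", crit$scope, "' does not match action '",
           kind, "'", call. = FALSE)
    }
  } else if (!is.null(crit)) {
    stop("action '", kind, "' does not take a critique", call. = FALSE)
  }
  structure(list(kind = kind, critique = crit), class = "nvc_action")
}

#' Start a negotiation session
#'
#' Initialises the session state from the user's profile (constraints,
#' calorie band, concession policy) and immediately emits the first offer:
#' the highest-utility consumable recipe, with an explanation attached in
#' interactive mode. If the constraints rule out every recipe the session
#' terminates at once with outcome `no_candidates`.
#'
#' @param profile an `nvc_profile`.
#' @param recipes recipe table (the catalogue).
#' @param tax an `nvc_taxonomy`.
#' @param config an `nvc_config`.
#' @param mode `"interactive"` (offers carry explanations; critiques
#'   allowed) or `"traditional"` (no explanations; accept / request new /
#'   leave only).
#' @param seed integer recorded in the session and transcript; the agent
#'   itself is deterministic, the seed matters for simulated users driving
#'   the session.
#' @param history optional offer history data.frame (see
#'   [build_user_dataset()]) enabling user-based explanations.
#' @return an `nvc_session`; inspect the current offer with
#'   [current_offer()].
#' @export
start_session <- function(profile, recipes, tax, config = nvc_config(),
                          mode = c("interactive", "traditional"), seed = 1L,
                          history = NULL) {
  mode <- match.arg(mode)
  stopifnot(inherits(profile, "nvc_profile"), inherits(tax, "nvc_taxonomy"),
            inherits(config, "nvc_config"))
  recipes <- recipe_table(recipes, tax = tax)
  phrases <- if (is.null(config$phrases)) default_phrases() else
    load_phrases(config$phrases)
  session <- structure(list(
    profile = profile,
    taxonomy = tax,
    catalogue = recipes,
    config = config,
    mode = mode,
    seed = as.integer(seed),
    history = history,
    phrases = phrases,
    policy = concession_policy(config$deadline, config$concession_exponent,
                               config$weights),
    band = calorie_band(profile, config$meal_fraction, config$tolerance,
                        config$female_constant),
    round = 1L,
    state = "awaiting_user",
    outcome = "none_yet",
    accepted_id = NULL,
    offered_ids = character(0),
    session_excluded_classes = character(0),
    offers = list(),
    expl_tried = list(),
    expl_texts = list(),
    last = NULL,
    events = list()
  ), class = "nvc_session")
  session <- log_event(session, "start", "system",
                       list(mode = mode, seed = as.integer(seed)))
  next_offer(session)
}

#' @export
print.nvc_session <- function(x, ...) {
  cat("<nvc_session> mode ", x$mode, ", round ", x$round, "/",
      x$config$deadline, ", state ", x$state, ", outcome ", x$outcome,
      "\n", sep = "")
  off <- current_offer(x)
  if (!is.null(off)) {
    cat("  current offer: ", off$recipe$name, " (", off$recipe$id, ")\n",
        sep = "")
    if (!is.null(off$explanation$text) && nzchar(off$explanation$text))
      cat("  └ ", off$explanation$text, "\n", sep = "")
  }
  invisible(x)
}

#' Current offer of a session
#'
#' @param session an `nvc_session`.
#' @return `NULL` if nothing is on the table, else a list with `recipe`
#'   (one-row recipe table) and `explanation` (`nvc_explanation`).
#' @export
current_offer <- function(session) {
  if (length(session$offers) == 0) return(NULL)
  last <- session$offers[[length(session$offers)]]
  list(recipe = session$catalogue[session$catalogue$id == last$recipe_id, ,
                                  drop = FALSE],
       explanation = last$explanation)
}

log_event <- function(session, event, actor, payload = list()) {
  session$events[[length(session$events) + 1]] <- list(
    event = event, round = session$round, actor = actor, payload = payload,
    timestamp = length(session$events) + 1L
  )
  session
}

terminate <- function(session, outcome, accepted_id = NULL) {
  session$state <- "terminated"
  session$outcome <- outcome
  session$accepted_id <- accepted_id
  log_event(session, "terminate", "system",
            list(outcome = outcome, accepted_id = accepted_id))
}

#' Produce the agent's next offer
#'
#' Filters the catalogue under the current constraints, scores the
#' survivors with the concession weights in force this round, and offers
#' the top-ranked recipe that has not been offered before. In interactive
#' mode an explanation is generated and attached. An empty candidate set
#' terminates the session with outcome `no_candidates`.
#'
#' Normally called through [start_session()] / [step()].
#'
#' @param session an `nvc_session`.
#' @return the updated session.
#' @export
next_offer <- function(session) {
  cfg <- session$config
  excl <- stats::setNames(rep("already-offered", length(session$offered_ids)),
                          session$offered_ids)
  filt <- filter_recipes(session$catalogue, session$profile,
                         session$taxonomy, exclusions = excl,
                         excluded_classes = session$session_excluded_classes)
  t <- min(session$round - 1L, session$policy$deadline_rounds)
  w <- concession_weights(session$policy, t)
  ranked <- rank_candidates(filt$candidates, session$profile, cfg$limits,
                            session$band, w,
                            nutrient_norm = cfg$nutrient_norm,
                            max_normalize = cfg$max_normalize)
  session$last <- list(ranked = ranked, excluded = filt$excluded, weights = w)
  if (nrow(ranked) == 0) {
    return(terminate(session, "no_candidates"))
  }
  top <- ranked[1, , drop = FALSE]
  session$offered_ids <- c(session$offered_ids, top$id)
  expl <- if (session$mode == "interactive") {
    session <- generate_explanation(session, top)
    session$.last_expl
  } else {
    explanation("none", text = "")
  }
  session$.last_expl <- NULL
  session$offers[[length(session$offers) + 1]] <-
    list(round = session$round, recipe_id = top$id, explanation = expl)
  payload <- list(recipe_id = top$id, score = top$score)
  if (session$mode == "interactive") {
    payload$explanation <- expl$text
    payload$strategy <- expl$strategy
  }
  log_event(session, "offer", "agent", payload)
}

#' Apply a recipe critique to the session state
#'
#' "I ate Y recently" excludes recipes containing Y for the rest of this
#' session; "I'm allergic to Y" and "I don't like Y" permanently extend the
#' profile's allergy / dislike sets (and are re-applied on every subsequent
#' filter); custom free-text remarks are logged in the transcript but do
#' not change the candidate set. In all cases [step()] follows the
#' feedback with a fresh offer.
#'
#' @param session an `nvc_session`.
#' @param crit an `nvc_critique` with recipe scope.
#' @return the updated session (no new offer is produced here).
#' @export
apply_recipe_feedback <- function(session, crit) {
  stopifnot(inherits(crit, "nvc_critique"))
  if (crit$scope != "recipe") {
    stop("apply_recipe_feedback expects a recipe critique", call. = FALSE)
  }
  if (crit$kind == "ate_recently") {
    session$session_excluded_classes <-
      unique(c(session$session_excluded_classes, crit$target_class))
  } else if (crit$kind == "allergic") {
    session$profile$allergies <-
      unique(c(session$profile$allergies, crit$target_class))
  } else if (crit$kind == "dislike") {
    session$profile$likes <- setdiff(session$profile$likes,
                                     crit$target_class)
    session$profile$dislikes <-
      unique(c(session$profile$dislikes, crit$target_class))
  }
  # custom: transcript only
  session
}

#' Advance a session by one user action
#'
#' Implements the turn-taking protocol: accept or leave terminate the
#' session; a recipe critique updates the constraints and yields a fresh
#' offer; an explanation critique keeps the recipe on the table but
#' generates a different explanation; request-new (traditional mode) simply
#' moves down the ranking. Every non-terminal action consumes a round, and
#' passing the round deadline terminates the session with outcome
#' `deadline`.
#'
#' @param session an active `nvc_session`.
#' @param action an `nvc_action`.
#' @return the updated session.
#' @export
step <- function(session, action) {
  stopifnot(inherits(session, "nvc_session"), inherits(action, "nvc_action"))
  if (session$state != "awaiting_user") {
    stop("session is terminated (outcome ", session$outcome,
         "); no further actions accepted", call. = FALSE)
  }
  if (action$kind == "request_new" && session$mode != "traditional") {
    stop("request_new is only available in traditional mode", call. = FALSE)
  }
  if (action$kind %in% c("critique_recipe", "critique_explanation") &&
      session$mode != "interactive") {
    stop("critiques are only available in interactive mode", call. = FALSE)
  }
  payload <- list(kind = action$kind)
  if (!is.null(action$critique)) {
    payload$critique_kind <- action$critique$kind
    payload$target_class <- action$critique$target_class
    payload$text <- action$critique$text
  }
  session <- log_event(session, "user_action", "user", payload)

  if (action$kind == "accept") {
    off <- current_offer(session)
    return(terminate(session, "agreement", off$recipe$id))
  }
  if (action$kind == "leave") {
    return(terminate(session, "leave"))
  }

  if (action$kind == "critique_recipe") {
    session <- apply_recipe_feedback(session, action$critique)
  }
  session$round <- session$round + 1L
  if (session$round > session$config$deadline) {
    return(terminate(session, "deadline"))
  }
  if (action$kind == "critique_explanation") {
    off <- current_offer(session)
    session <- generate_explanation(session, off$recipe)
    expl <- session$.last_expl
    session$.last_expl <- NULL
    n <- length(session$offers)
    session$offers[[n]]$explanation <- expl
    return(log_event(session, "explanation", "agent",
                     list(recipe_id = off$recipe$id, explanation = expl$text,
                          strategy = expl$strategy)))
  }
  next_offer(session)
}

#' Session transcript
#'
#' `transcript()` returns the ordered event log as a list;
#' `write_transcript()` serialises it as line-delimited JSON, one event per
#' line with fields `event`, `round`, `actor`, `payload`, `timestamp`
#' (a logical, replay-stable event counter). `replay_transcript()`
#' re-executes the logged user actions against the same inputs and returns
#' the reconstructed session, which reaches the same final state.
#'
#' @param session an `nvc_session`.
#' @return [transcript()]: list of event records.
#' @export
transcript <- function(session) {
  stopifnot(inherits(session, "nvc_session"))
  session$events
}

#' @rdname transcript
#' @param path output / input JSONL path.
#' @export
write_transcript <- function(session, path) {
  lines <- vapply(transcript(session), function(ev) {
    jsonlite::toJSON(ev, auto_unbox = TRUE, null = "null", digits = NA)
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname transcript
#' @inheritParams start_session
#' @export
replay_transcript <- function(path, profile, recipes, tax,
                              config = nvc_config(),
                              mode = c("interactive", "traditional"),
                              seed = 1L, history = NULL) {
  events <- lapply(readLines(path), jsonlite::fromJSON, simplifyVector = TRUE)
  actions <- Filter(function(ev) ev$event == "user_action", events)
  session <- start_session(profile, recipes, tax, config, mode, seed,
                           history)
  for (ev in actions) {
    p <- ev$payload
    crit <- if (!is.null(p$critique_kind)) {
      critique(p$critique_kind,
               target_class = p$target_class,
               text = p$text)
    }
    session <- step(session, user_action(p$kind, crit))
  }
  session
}

#' Comparable session state
#'
#' The part of a session that defines its negotiation outcome — round,
#' state, outcome, accepted recipe, offer sequence and accumulated
#' constraints — without the caches and the event log. Two sessions that
#' followed the same dialogue are identical under this view.
#'
#' @param session an `nvc_session`.
#' @return a list.
#' @export
session_state <- function(session) {
  list(round = session$round, state = session$state,
       outcome = session$outcome, accepted_id = session$accepted_id,
       offered_ids = session$offered_ids,
       session_excluded_classes = sort(session$session_excluded_classes),
       allergies = sort(session$profile$allergies),
       dislikes = sort(session$profile$dislikes))
}
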