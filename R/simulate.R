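# Synthetic living-lab pilot generator.
#
# The default configuration reproduces the deployment conditions of the
# ontology's pilot: 14 elderly players (3 male, 11 female, mean age 73.4
# years), each visiting the lab on 6 days and playing 7 different games
# per visit, with the SideRaises game in the catalog. Game metrics have no
# published distributions; the defaults here (Success ~ Bernoulli(0.7),
# ReactionTime ~ lognormal(log 1.5 s, 0.4), GoalTime ~ normal(4 s, 1 s)
# truncated at zero) are plausibility choices and are overridable per
# metric in the configuration.

#' Default pilot configuration
#'
#' @return A `SimulationConfig` with the pilot cohort settings (14 players,
#'   3 male, mean age 73.4, 6 visits per player, 7 games per visit), a
#'   seven-game catalog containing the SideRaises game, per-metric
#'   distribution models, and `seed = 42`. Deterministic.
#' @examples
#' cfg <- default_pilot_config()
#' cfg$n_players
#' @export
default_pilot_config <- function() {
  cfg <- list(
    n_players = 14L,
    n_male = 3L,
    age_mean = 73.4,
    age_sd = 5,
    visits_per_player = 6L,
    games_per_visit = 7L,
    game_catalog = default_game_catalog(),
    iterations_range = c(6L, 10L),
    metric_models = list(),
    session_gap_minutes = c(2, 8),
    start_date = "2014-09-22",
    utc_offset_minutes = 120L,
    player_iri_base = FFA_RES,
    site = site_record(
      iri = paste0(FFA_RES, "MedicalPhysicsLaboratoryAuth"),
      site_type = paste0(NS_SITETYPE, "ResearchLaboratory")),
    seed = 42L
  )
  cfg$metric_models <- list2env2(list(
    bernoulli_model(paste0(NS_METRIC, "Success"), p = 0.7),
    lognormal_model(paste0(NS_METRIC, "ReactionTime"),
                    meanlog = log(1.5), sdlog = 0.4),
    truncnormal_model(paste0(NS_METRIC, "GoalTime"), mean = 4, sd = 1)
  ))
  structure(cfg, class = "SimulationConfig")
}

# named list keyed by each model's metric IRI
list2env2 <- function(models) {
  setNames(models, vapply(models, function(m) m$metric, character(1)))
}

#' Per-metric distribution models
#'
#' A metric model describes how per-iteration values of one metric are
#' drawn: `bernoulli_model()` yields logical successes, `lognormal_model()`
#' strictly positive times, and `truncnormal_model()` a normal truncated
#' at zero (rejection sampling). Continuous draws are rounded to 3
#' decimals (millisecond resolution for second-valued metrics).
#'
#' @param metric Metric IRI the model applies to.
#' @param p Success probability in `[0, 1]`.
#' @param meanlog,sdlog Log-scale mean and standard deviation.
#' @param mean,sd Mean and standard deviation (natural scale).
#' @param unit Unit IRI attached to the observations (`NULL` for none).
#' @return A model object consumed by [simulate_session()].
#' @name metric_models
NULL

#' @rdname metric_models
#' @export
bernoulli_model <- function(metric, p, unit = NULL) {
  stopifnot(p >= 0, p <= 1)
  list(metric = assert_iri(metric, "metric"), kind = "bernoulli", p = p,
       unit = unit)
}

#' @rdname metric_models
#' @export
lognormal_model <- function(metric, meanlog, sdlog, unit = QUDT_SECOND) {
  stopifnot(sdlog > 0)
  list(metric = assert_iri(metric, "metric"), kind = "lognormal",
       meanlog = meanlog, sdlog = sdlog, unit = unit)
}

#' @rdname metric_models
#' @export
truncnormal_model <- function(metric, mean, sd, unit = QUDT_SECOND) {
  stopifnot(sd > 0)
  list(metric = assert_iri(metric, "metric"), kind = "truncnormal",
       mean = mean, sd = sd, unit = unit)
}

draw_model <- function(model, n) {
  switch(model$kind,
    bernoulli = stats::runif(n) < model$p,
    lognormal = round(stats::rlnorm(n, model$meanlog, model$sdlog), 3),
    truncnormal = {
      v <- stats::rnorm(n, model$mean, model$sd)
      while (any(v <= 0)) {
        v[v <= 0] <- stats::rnorm(sum(v <= 0), model$mean, model$sd)
      }
      round(v, 3)
    },
    stop("unknown metric model kind: ", model$kind, call. = FALSE))
}

#' Default game catalog
#'
#' Seven upper/lower-limb exercise games in the style of the pilot's
#' protocol, each recording success, reaction time and goal time; the
#' first is the published SideRaises game.
#'
#' @return List of `GameDescription`s.
#' @export
default_game_catalog <- function() {
  side <- sideraises_fixture()$game
  others <- c("FrontRaises", "BicepsCurls", "Squats", "LegExtension",
              "ShoulderPress", "TorsoTwists")
  c(list(side), lapply(others, function(nm) {
    game_description(
      iri = paste0(FFA_RES, nm, "Game"),
      label = nm,
      metrics = side$metrics,
      controllers = side$controllers,
      presentation_hardware = side$presentation_hardware
    )
  }))
}

validate_config <- function(config) {
  stopifnot(inherits(config, "SimulationConfig"))
  with(config, {
    if (!is.numeric(n_players) || n_players < 1L) {
      stop("configuration error: n_players must be >= 1", call. = FALSE)
    }
    if (n_male > n_players) {
      stop("configuration error: n_male exceeds n_players", call. = FALSE)
    }
    if (visits_per_player < 1L) {
      stop("configuration error: visits_per_player must be >= 1", call. = FALSE)
    }
    if (games_per_visit < 1L) {
      stop("configuration error: games_per_visit must be >= 1", call. = FALSE)
    }
    if (games_per_visit > length(game_catalog)) {
      stop("configuration error: games_per_visit (", games_per_visit,
           ") exceeds catalog size (", length(game_catalog), ")",
           call. = FALSE)
    }
    if (length(iterations_range) != 2L ||
        iterations_range[1] < 1L ||
        iterations_range[2] < iterations_range[1]) {
      stop("configuration error: iterations_range must be (min, max), min >= 1",
           call. = FALSE)
    }
    for (game in game_catalog) {
      for (m in game$metrics) {
        if (is.null(metric_models[[m$iri]])) {
          stop("configuration error: no metric model for ", m$iri,
               call. = FALSE)
        }
      }
    }
  })
  invisible(config)
}

#' Simulate one game session
#'
#' Draws one observation per game metric from the configured metric
#' models, with a shared iteration count per session (all metrics of a
#' game measure the same physical exercise iterations). The session
#' duration is the summed goal time when a goal-time-like metric is drawn,
#' plus a fixed per-iteration overhead, so `end > start` always.
#'
#' Uses the current RNG state; fix the seed (or call through
#' [simulate_pilot()]) for reproducibility.
#'
#' @param player Player IRI.
#' @param game A `GameDescription`.
#' @param start `POSIXct` session start.
#' @param config A `SimulationConfig` (metric models, iteration range,
#'   site, UTC offset).
#' @param session_id Identifier for the record.
#' @return A `SessionRecord`.
#' @export
simulate_session <- function(player, game, start, config,
                             session_id = "session1") {
  stopifnot(inherits(game, "GameDescription"), inherits(start, "POSIXct"))
  ir <- config$iterations_range
  n_iter <- sample(seq.int(ir[1], ir[2]), 1L)
  obs <- lapply(game$metrics, function(m) {
    model <- config$metric_models[[m$iri]]
    if (is.null(model)) {
      stop("configuration error: no metric model for ", m$iri, call. = FALSE)
    }
    vals <- draw_model(model, n_iter)
    unit <- if (!is.null(model$unit)) model$unit else m$default_unit
    metric_observation(m$iri, vals, unit = unit)
  })
  # duration: per-iteration work plus setup overhead
  per_iter <- vapply(obs, function(o) {
    if (is.numeric(o$values)) mean(o$values) else NA_real_
  }, numeric(1))
  work <- if (all(is.na(per_iter))) 5 else max(per_iter, na.rm = TRUE)
  duration <- ceiling(n_iter * work + 15 + stats::runif(1, 0, 20))
  end <- start + duration
  off <- config$utc_offset_minutes
  session_record(
    session_id = session_id,
    game = game$iri,
    player = player,
    site = if (!is.null(config$site)) config$site$iri else NULL,
    start = format_datetime(start, off),
    end = format_datetime(end, off),
    observations = obs
  )
}

#' Simulate a full pilot
#'
#' Generates players with opaque IRIs (`player001`, ...), their visit
#' days, and one session per (player, visit, game) with ordered
#' start/end times within each visit day; emits the whole pilot as a
#' single RDF graph: game descriptions, site, and all sessions — as the
#' real deployment stored everything in a single graph.
#'
#' @param config A `SimulationConfig`, see [default_pilot_config()].
#' @return A `PilotOutput`: list with `players` (list of `PlayerRecord`),
#'   `sessions` (list of `SessionRecord`, length
#'   `n_players * visits_per_player * games_per_visit`), `graph`
#'   (`TripleGraph`), and `config`. Deterministic given `config$seed`.
#' @examples
#' \donttest{
#' pilot <- simulate_pilot(default_pilot_config())
#' length(pilot$sessions)  # 14 * 6 * 7
#' }
#' @export
simulate_pilot <- function(config = default_pilot_config()) {
  validate_config(config)
  old_seed <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  } else NULL
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv())
  }, add = TRUE)
  set.seed(config$seed)

  n <- config$n_players
  ids <- sprintf("player%03d", seq_len(n))
  genders <- sample(rep(c("male", "female"),
                        c(config$n_male, n - config$n_male)))
  ages <- pmin(pmax(round(stats::rnorm(n, config$age_mean, config$age_sd), 1),
                    60), 95)
  players <- lapply(seq_len(n), function(i) {
    player_record(paste0(config$player_iri_base, ids[i]),
                  age = ages[i], gender = genders[i])
  })

  day0 <- as.Date(config$start_date)
  gap_rng <- config$session_gap_minutes
  sessions <- list()
  for (i in seq_len(n)) {
    # fixed per-player selection: every visit plays the same set of games
    games <- config$game_catalog[seq_len(config$games_per_visit)]
    for (v in seq_len(config$visits_per_player)) {
      day <- day0 + (v - 1L)
      # visits start mid-morning local time
      t <- as.POSIXct(paste0(format(day, "%Y-%m-%d"), " 10:00:00"),
                      tz = "UTC") - config$utc_offset_minutes * 60
      t <- t + round(stats::runif(1, 0, 45)) * 60
      for (k in seq_along(games)) {
        sid <- sprintf("%s_v%d_g%d", ids[i], v, k)
        s <- simulate_session(players[[i]]$iri, games[[k]], t, config,
                              session_id = sid)
        sessions[[length(sessions) + 1L]] <- s
        gap <- stats::runif(1, gap_rng[1], gap_rng[2]) * 60
        t <- parse_datetime(s$end) + round(gap)
      }
    }
  }

  terms <- default_terms()
  graph <- graph_union(c(
    lapply(config$game_catalog, game_to_graph, terms = terms),
    if (!is.null(config$site)) list(site_to_graph(config$site, terms)),
    list(sessions_to_graph(sessions, terms))
  ))
  structure(list(players = players, sessions = sessions, graph = graph,
                 config = config),
            class = "PilotOutput")
}

#' Session log of a pilot as a long-format table
#'
#' One row per (session, metric, iteration), in the schema consumed by the
#' tabular converter ([default_mapping()]), enabling the end-to-end loop
#' simulator CSV -> converter -> RDF.
#'
#' @param sessions List of `SessionRecord`s (e.g. `pilot$sessions`).
#' @return A data.frame with columns session_id, player_id, game_iri,
#'   site_iri, start, end, metric, unit, iteration, value.
#' @export
sessions_to_log <- function(sessions) {
  rows <- lapply(sessions, function(s) {
    do.call(rbind, lapply(s$observations, function(ob) {
      lx <- values_to_lexical(ob$values)
      data.frame(
        session_id = s$session_id,
        player_id = iri_local(s$player),
        game_iri = s$game,
        site_iri = if (is.null(s$site)) "" else s$site,
        start = s$start, end = s$end,
        metric = ob$metric,
        unit = if (is.null(ob$unit)) "" else ob$unit,
        iteration = seq_along(ob$values),
        value = lx$lex,
        stringsAsFactors = FALSE)
    }))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
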