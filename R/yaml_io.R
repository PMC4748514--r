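# Game descriptions as YAML/JSON documents.
#
# The document mirrors the GameDescription fields; a JSON Schema for it is
# shipped under inst/schema/game-description.schema.json. Metrics may be
# given by metric-namespace local name (preferred) or full IRI.

#' Load a game description from YAML
#'
#' @param document Path to a YAML (or JSON) document, or a parsed list.
#' @return A `GameDescription`.
#' @examples
#' path <- system.file("extdata", "sideraises-game.yaml",
#'                     package = "exergraph")
#' game <- game_from_yaml(path)
#' game$label
#' @export
game_from_yaml <- function(document) {
  doc <- if (is.character(document)) yaml::read_yaml(document) else document
  if (!is.list(doc)) stop("game document must be a mapping", call. = FALSE)
  for (k in c("iri", "label", "metrics")) {
    if (is.null(doc[[k]])) {
      stop("game document lacks required field '", k, "'", call. = FALSE)
    }
  }
  metrics <- lapply(doc[["metrics"]], function(m) {
    local <- if (!is.null(m$local_name)) m$local_name else iri_local(m$iri)
    define_metric(local, m$label,
                  concept = m$concept, unit = m$unit)
  })
  controllers <- lapply(doc[["controllers"]], function(ctl) {
    local <- if (!is.null(ctl$local_name)) ctl$local_name else iri_local(ctl$iri)
    controller_definition(local, ctl$label, same_as = ctl$same_as)
  })
  hardware <- lapply(doc[["presentation_hardware"]], function(h) {
    list(iri = normalize_iri(h$iri), label = h$label)
  })
  exercise <- if (!is.null(doc[["exercise"]])) {
    ex <- doc[["exercise"]]
    exercise_definition(
      iri = ex$iri, label = ex$label,
      muscles = lapply(ex$muscles, function(m) muscle_ref(m$iri, m$source)),
      equipment = as.character(unlist(ex$equipment)),
      benefits = as.character(unlist(ex$benefits)))
  }
  goals <- lapply(doc[["goals"]], function(g) list(kind = g$kind, text = g$text))
  game_description(iri = doc[["iri"]], label = doc[["label"]], metrics = metrics,
                   controllers = controllers,
                   presentation_hardware = hardware,
                   exercise = exercise, goals = goals)
}

#' Write a game description to YAML
#'
#' @param game A `GameDescription`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
game_to_yaml <- function(game, path) {
  stopifnot(inherits(game, "GameDescription"))
  drop_null <- function(x) x[!vapply(x, is.null, logical(1))]
  doc <- drop_null(list(
    iri = game$iri,
    label = game$label,
    metrics = lapply(game$metrics, function(m) drop_null(list(
      local_name = iri_local(m$iri), label = m$label,
      concept = m$concept, unit = m$default_unit))),
    controllers = if (length(game$controllers)) {
      lapply(game$controllers, function(ctl) drop_null(list(
        local_name = iri_local(ctl$iri), label = ctl$label,
        same_as = ctl$same_as)))
    },
    presentation_hardware = if (length(game$presentation_hardware)) {
      game$presentation_hardware
    },
    exercise = if (!is.null(game$exercise)) {
      ex <- game$exercise
      drop_null(list(
        iri = ex$iri, label = ex$label,
        muscles = lapply(ex$muscles, function(m) {
          list(iri = m$iri, source = m$source)
        }),
        equipment = if (length(ex$equipment)) as.list(ex$equipment),
        benefits = if (length(ex$benefits)) as.list(ex$benefits)))
    },
    goals = if (length(game$goals)) game$goals
  ))
  yaml::write_yaml(doc, path)
  invisible(path)
}

#' Load a pilot configuration from YAML
#'
#' Scalar fields of [default_pilot_config()] may be overridden
#' (`n_players`, `n_male`, `age_mean`, `age_sd`, `visits_per_player`,
#' `games_per_visit`, `iterations_range`, `session_gap_minutes`,
#' `start_date`, `seed`), metric models through a `metric_models` block
#' (named by metric IRI, each with a `kind` and its parameters), and the
#' game catalog through a list of game-description documents under
#' `games`.
#'
#' @param document Path to YAML, or a parsed list.
#' @return A `SimulationConfig`.
#' @export
pilot_config_from_yaml <- function(document) {
  doc <- if (is.character(document)) yaml::read_yaml(document) else document
  cfg <- default_pilot_config()
  scalars <- c("n_players", "n_male", "age_mean", "age_sd",
               "visits_per_player", "games_per_visit", "iterations_range",
               "session_gap_minutes", "start_date", "seed",
               "utc_offset_minutes", "player_iri_base")
  for (k in intersect(names(doc), scalars)) {
    v <- doc[[k]]
    cfg[[k]] <- if (is.numeric(cfg[[k]]) ||
                    k %in% c("iterations_range", "session_gap_minutes")) {
      if (is.integer(cfg[[k]])) as.integer(unlist(v)) else as.numeric(unlist(v))
    } else v
  }
  if (!is.null(doc[["games"]])) {
    cfg$game_catalog <- lapply(doc[["games"]], game_from_yaml)
  }
  if (!is.null(doc[["metric_models"]])) {
    for (iri in names(doc[["metric_models"]])) {
      m <- doc[["metric_models"]][[iri]]
      iri_n <- normalize_iri(iri)
      cfg$metric_models[[iri_n]] <- switch(
        m$kind,
        bernoulli = bernoulli_model(iri_n, p = m$p),
        lognormal = lognormal_model(iri_n, meanlog = m$meanlog,
                                    sdlog = m$sdlog),
        truncnormal = truncnormal_model(iri_n, mean = m$mean, sd = m$sd),
        stop("unknown metric model kind: ", m$kind, call. = FALSE))
    }
  }
  validate_config(cfg)
}
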