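# The ontology term registry and the typed in-memory records every other
# module consumes.
#
# Classes and properties mirror the published exergame ontology at
# http://purl.org/net/exergame/ns#. The ontology's public description never
# prints the properties that attach a game to its metrics, controllers,
# presentation hardware and exercise, nor the one that attaches a unit to a
# metric relation; those five (gameMetric, gameController,
# presentationHardware, gameExercise, metricUnit) plus the exercise
# annotations (involvesMuscle, equipment, healthBenefit, gameGoal,
# exerciseGoal) are minted by this package in the exergame namespace and
# are remappable through the registry so a corrected official vocabulary
# can be dropped in.

NS_EXERGAME   <- "http://purl.org/net/exergame/ns#"
NS_METRIC     <- "http://purl.org/net/exergame/metric#"
NS_CONTROLLER <- "http://purl.org/net/exergame/controller#"
NS_CONCEPT    <- "http://purl.org/net/exergame/concept#"
NS_SITETYPE   <- "http://purl.org/net/exergame/sitetype#"
NS_FOAF       <- "http://xmlns.com/foaf/0.1/"
NS_SKOS       <- "http://www.w3.org/2004/02/skos/core#"
NS_OPE        <- "http://www.semanticweb.org/ontologies/2013/2/OPE.owl#"
NS_NCI        <- "http://ncicb.nci.nih.gov/xml/owl/EVS/Thesaurus.owl#"
NS_QUDT       <- "http://qudt.org/schema/qudt#"
NS_VCARD      <- "http://www.w3.org/2006/vcard/ns#"

#' The ontology term registry
#'
#' Returns the complete registry of classes, properties and namespace
#' prefixes used by the exergame ontology, including the linkage properties
#' minted by this package (see the package vignette for which those are).
#'
#' @return An `OntologyTerms` object: list with named character vectors
#'   `classes`, `properties` and `prefixes`.
#' @examples
#' t <- default_terms()
#' t$classes[["GameSession"]]
#' @export
default_terms <- function() {
  ex <- function(l) paste0(NS_EXERGAME, l)
  classes <- c(
    Game                 = ex("Game"),
    GameSession          = ex("GameSession"),
    Result               = ex("Result"),
    MetricRelation       = ex("MetricRelation"),
    GoalMetric           = ex("GoalMetric"),
    Unit                 = ex("Unit"),
    GameController       = ex("GameController"),
    PresentationHardware = ex("PresentationHardware"),
    Exercise             = ex("Exercise"),
    SiteType             = ex("SiteType"),
    Player               = ex("Player")
  )
  properties <- c(
    result         = ex("result"),
    site           = ex("site"),
    startDateTime  = ex("startDateTime"),
    endDateTime    = ex("endDateTime"),
    player         = ex("player"),
    game           = ex("game"),
    metricRelation = ex("metricRelation"),
    metricName     = ex("metricName"),
    metricValue    = ex("metricValue"),
    siteAddress    = ex("siteAddress"),
    concept        = ex("concept"),
    # package-minted linkage properties (no official IRIs published)
    gameMetric           = ex("gameMetric"),
    gameController       = ex("gameController"),
    presentationHardware = ex("presentationHardware"),
    gameExercise         = ex("gameExercise"),
    metricUnit           = ex("metricUnit"),
    involvesMuscle       = ex("involvesMuscle"),
    equipment            = ex("equipment"),
    healthBenefit        = ex("healthBenefit"),
    gameGoal             = ex("gameGoal"),
    exerciseGoal         = ex("exerciseGoal")
  )
  prefixes <- c(
    "exergame"            = NS_EXERGAME,
    "exergame-metric"     = NS_METRIC,
    "exergame-controller" = NS_CONTROLLER,
    "exergame-concept"    = NS_CONCEPT,
    "exergame-sitetype"   = NS_SITETYPE,
    rdf   = NS_RDF,
    rdfs  = NS_RDFS,
    owl   = NS_OWL,
    foaf  = NS_FOAF,
    skos  = NS_SKOS,
    ope   = NS_OPE,
    nci   = NS_NCI,
    qudt  = NS_QUDT,
    vcard = NS_VCARD,
    xsd   = NS_XSD
  )
  stopifnot(!anyDuplicated(names(prefixes)), !anyDuplicated(prefixes))
  structure(list(classes = classes, properties = properties,
                 prefixes = prefixes),
            class = "OntologyTerms")
}

term <- function(terms, group, name) {
  v <- terms[[group]][[name]]
  if (is.null(v) || is.na(v)) {
    stop("term registry has no ", group, " entry '", name, "'", call. = FALSE)
  }
  v
}

valid_fragment <- function(x) {
  length(x) == 1L && is.character(x) && !is.na(x) &&
    grepl("^[A-Za-z_][A-Za-z0-9_.-]*$", x)
}

#' Define a game metric
#'
#' Metrics are shared across games as individuals of `exergame:GoalMetric`
#' in the common metric namespace `http://purl.org/net/exergame/metric#`.
#'
#' @param local_name IRI fragment within the metric namespace, e.g. `"Success"`.
#' @param label Human-readable label (non-empty).
#' @param concept Optional IRI of the SKOS concept the metric represents.
#' @param unit Optional IRI of the default unit of measurement (QUDT unit).
#' @return A `MetricDefinition`.
#' @examples
#' define_metric("GoalTime", "goal time",
#'   concept = "http://purl.org/net/exergame/concept#Time")
#' @export
define_metric <- function(local_name, label, concept = NULL, unit = NULL) {
  if (!valid_fragment(local_name)) {
    stop("metric local_name must be a valid IRI fragment, got ",
         deparse(local_name), call. = FALSE)
  }
  if (!is.character(label) || length(label) != 1L || !nzchar(label)) {
    stop("metric label must be a non-empty string", call. = FALSE)
  }
  if (!is.null(concept)) concept <- assert_iri(concept, "concept")
  if (!is.null(unit)) unit <- assert_iri(unit, "unit")
  structure(list(iri = paste0(NS_METRIC, local_name), label = label,
                 concept = concept, default_unit = unit),
            class = "MetricDefinition")
}

#' Define a game controller
#'
#' Controller individuals live in `http://purl.org/net/exergame/controller#`
#' and may be linked to the corresponding DBpedia resource with
#' `owl:sameAs`.
#'
#' @param local_name IRI fragment within the controller namespace.
#' @param label Human-readable label.
#' @param same_as Optional IRI of the equivalent DBpedia resource.
#' @return A `ControllerDefinition`.
#' @export
controller_definition <- function(local_name, label, same_as = NULL) {
  if (!valid_fragment(local_name)) {
    stop("controller local_name must be a valid IRI fragment", call. = FALSE)
  }
  if (!is.null(same_as)) same_as <- assert_iri(same_as, "same_as")
  structure(list(iri = paste0(NS_CONTROLLER, local_name), label = label,
                 same_as = same_as),
            class = "ControllerDefinition")
}

#' Reference a muscle involved in an exercise
#'
#' Muscles named by the physical-exercise ontology (OPE) are referenced by
#' their OPE individual; muscles missing from OPE are declared as
#' subclasses of the NCI Thesaurus `Muscle` class.
#'
#' @param iri Muscle IRI (OPE individual or NCIt-namespace class).
#' @param source Either `"OPE"` or `"NCIt-subclass"`.
#' @return A list with `iri` and `source`.
#' @export
muscle_ref <- function(iri, source = c("OPE", "NCIt-subclass")) {
  source <- match.arg(source)
  list(iri = assert_iri(iri, "muscle iri"), source = source)
}

#' Define the physical exercise behind a game
#'
#' @param iri Exercise IRI.
#' @param label Human-readable label.
#' @param muscles List of [muscle_ref()] entries (may be empty).
#' @param equipment Character vector of auxiliary equipment names.
#' @param benefits Character vector of expected health benefits.
#' @return An `ExerciseDefinition`.
#' @export
exercise_definition <- function(iri, label, muscles = list(),
                                equipment = character(), benefits = character()) {
  iri <- assert_iri(iri, "exercise iri")
  stopifnot(is.list(muscles))
  for (m in muscles) {
    stopifnot(is.list(m), !is.null(m$iri), m$source %in% c("OPE", "NCIt-subclass"))
  }
  structure(list(iri = iri, label = label, muscles = muscles,
                 equipment = as.character(equipment),
                 benefits = as.character(benefits)),
            class = "ExerciseDefinition")
}

#' Describe a game
#'
#' A game is described once, as an individual of `exergame:Game`, and all
#' sessions then refer to it by IRI.
#'
#' @param iri Game IRI.
#' @param label Human-readable game name.
#' @param metrics List of [define_metric()] results; at least one, with
#'   unique IRIs.
#' @param controllers List of [controller_definition()] results.
#' @param presentation_hardware List of `list(iri =, label =)` entries for
#'   the devices on which the game is presented.
#' @param exercise Optional [exercise_definition()].
#' @param goals List of `list(kind =, text =)` entries with kind
#'   `"game_goal"` or `"exercise_goal"`; kept as annotations.
#' @return A `GameDescription`.
#' @export
game_description <- function(iri, label, metrics, controllers = list(),
                             presentation_hardware = list(), exercise = NULL,
                             goals = list()) {
  iri <- assert_iri(iri, "game iri")
  stopifnot(is.list(metrics))
  if (length(metrics) < 1L) {
    stop("a game must declare at least one metric", call. = FALSE)
  }
  miris <- vapply(metrics, function(m) m$iri, character(1))
  if (anyDuplicated(miris)) {
    stop("metric IRIs must be unique within a game", call. = FALSE)
  }
  for (h in presentation_hardware) {
    stopifnot(is.list(h), is_absolute_iri(h$iri), nzchar(h$label))
  }
  for (g in goals) {
    stopifnot(is.list(g), g$kind %in% c("game_goal", "exercise_goal"),
              nzchar(g$text))
  }
  structure(list(iri = iri, label = label, metrics = metrics,
                 controllers = controllers,
                 presentation_hardware = presentation_hardware,
                 exercise = exercise, goals = goals),
            class = "GameDescription")
}

#' An anonymized player
#'
#' Players are identified by opaque IRIs only; the IRI local name must not
#' look like personal data (no `@`, no spaces). Optional demographics are
#' cohort attributes used by the simulator and are never serialized as
#' identifying literals.
#'
#' @param iri Player IRI with an opaque local name.
#' @param age Optional age in years.
#' @param gender Optional, `"male"` or `"female"`.
#' @return A `PlayerRecord`.
#' @export
player_record <- function(iri, age = NULL, gender = NULL) {
  iri <- assert_iri(iri, "player iri")
  local <- iri_local(iri)
  if (grepl("@|%40| ", local)) {
    stop("player IRI local name must be opaque (no email-like identifiers)",
         call. = FALSE)
  }
  if (!is.null(gender)) gender <- match.arg(gender, c("male", "female"))
  if (!is.null(age)) stopifnot(is.numeric(age), age > 0)
  structure(list(iri = iri, age = age, gender = gender),
            class = "PlayerRecord")
}

#' A game-session site
#'
#' @param iri Site IRI.
#' @param site_type IRI of the site category, normally an individual in
#'   `http://purl.org/net/exergame/sitetype#` or a user-minted individual of
#'   `exergame:SiteType`.
#' @param address Optional address literal (the ontology leaves the range
#'   of `exergame:siteAddress` open).
#' @return A `SiteRecord`.
#' @export
site_record <- function(iri, site_type, address = NULL) {
  structure(list(iri = assert_iri(iri, "site iri"),
                 site_type = assert_iri(site_type, "site_type"),
                 address = address),
            class = "SiteRecord")
}

#' One metric's per-iteration values in a session
#'
#' @param metric Metric IRI.
#' @param values Atomic vector of per-iteration values (logical, integer,
#'   double or character), one entry per exercise iteration, length >= 1.
#' @param unit Optional unit IRI.
#' @return A `MetricObservation`.
#' @export
metric_observation <- function(metric, values, unit = NULL) {
  metric <- assert_iri(metric, "metric")
  if (!is.atomic(values) || length(values) < 1L || anyNA(values)) {
    stop("observation values must be a non-empty atomic vector without NA",
         call. = FALSE)
  }
  if (!is.null(unit)) unit <- assert_iri(unit, "unit")
  structure(list(metric = metric, unit = unit, values = values),
            class = "MetricObservation")
}

#' One game session
#'
#' A session is the period in which one player plays one game: it starts
#' with the game and ends when the game ends or stops, and carries the
#' player, the game, the site and the per-metric results.
#'
#' @param session_id Opaque identifier (used to derive node labels; keep to
#'   letters, digits and underscores for lossless round trips).
#' @param game Game IRI.
#' @param player Player IRI.
#' @param start,end ISO-8601 timestamps with UTC offset; `start <= end`
#'   (equality allowed: zero-length sessions occur in the field data).
#' @param observations List of [metric_observation()]; metrics unique.
#' @param site Optional site IRI.
#' @return A `SessionRecord`.
#' @export
session_record <- function(session_id, game, player, start, end,
                           observations, site = NULL) {
  stopifnot(is.character(session_id), length(session_id) == 1L,
            nzchar(session_id))
  game <- assert_iri(game, "game")
  player <- assert_iri(player, "player")
  if (!is.null(site)) site <- assert_iri(site, "site")
  ts <- parse_datetime(start); te <- parse_datetime(end)
  if (is.na(ts) || is.na(te)) {
    stop("start/end must be ISO-8601 timestamps with UTC offset", call. = FALSE)
  }
  if (ts > te) stop("session start must not be after its end", call. = FALSE)
  stopifnot(is.list(observations))
  for (ob in observations) {
    if (!inherits(ob, "MetricObservation")) {
      stop("observations must be MetricObservation objects", call. = FALSE)
    }
  }
  metrics <- vapply(observations, function(o) o$metric, character(1))
  if (anyDuplicated(metrics)) {
    stop("observation metrics must be unique within a session", call. = FALSE)
  }
  structure(list(session_id = session_id, game = game, player = player,
                 site = site, start = start, end = end,
                 observations = observations),
            class = "SessionRecord")
}
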