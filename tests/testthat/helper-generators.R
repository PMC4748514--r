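# Randomized-record generators used by the property-style tests. All
# draws use the session RNG; tests fix a seed with withr::local_seed().

random_values <- function(n, type = c("boolean", "decimal", "integer", "string")) {
  type <- match.arg(type)
  switch(type,
         boolean = stats::runif(n) < 0.5,
         decimal = round(stats::rlnorm(n, 0, 1), 3),
         integer = sample.int(100L, n, replace = TRUE),
         string = replicate(n, paste0("v", paste(
           sample(letters, 4, replace = TRUE), collapse = ""))))
}

random_session <- function(i = 1L) {
  pool <- c("Success", "ReactionTime", "GoalTime", "Score", "TotalTime")
  types <- c("boolean", "decimal", "decimal", "integer", "string")
  k <- sample.int(4L, 1L)
  pick <- sample(seq_along(pool), k)
  obs <- lapply(pick, function(j) {
    n <- sample.int(5L, 1L)  # n = 1 exercises the direct-literal encoding
    metric_observation(
      paste0("http://purl.org/net/exergame/metric#", pool[j]),
      random_values(n, types[j]),
      unit = if (stats::runif(1) < 0.5)
        "http://qudt.org/vocab/unit#SecondTime")
  })
  t0 <- as.POSIXct("2014-09-22 08:00:00", tz = "UTC") +
    sample.int(86400L * 6L, 1L)
  dur <- sample.int(600L, 1L)
  session_record(
    session_id = sprintf("rnd%03d", i),
    game = paste0("http://www.fitforall.gr/resources/",
                  sample(c("SideRaisesGame", "SquatsGame"), 1L)),
    player = sprintf("http://www.fitforall.gr/resources/player%03d",
                     sample.int(20L, 1L)),
    site = if (stats::runif(1) < 0.7)
      "http://www.fitforall.gr/resources/MedicalPhysicsLaboratoryAuth",
    start = exergraph:::format_datetime(t0, 120L),
    end = exergraph:::format_datetime(t0 + dur, 120L),
    observations = obs
  )
}

# a reduced cohort: same structure as the pilot, smaller problem size
small_config <- function(seed = 1L, n_players = 3L, visits = 2L, games = 2L) {
  cfg <- default_pilot_config()
  cfg$n_players <- as.integer(n_players)
  cfg$n_male <- min(1L, n_players)
  cfg$visits_per_player <- as.integer(visits)
  cfg$games_per_visit <- as.integer(games)
  cfg$iterations_range <- c(2L, 4L)
  cfg$seed <- as.integer(seed)
  cfg
}

# delete the i-th matching triple from a graph
drop_triple <- function(graph, s = NULL, p = NULL, o = NULL) {
  df <- graph$triples
  keep <- rep(TRUE, nrow(df))
  if (!is.null(s)) keep <- keep & df$s == s
  if (!is.null(p)) keep <- keep & df$p == p
  if (!is.null(o)) keep <- keep & df$o == o
  stopifnot(any(keep))
  graph$triples <- df[-which(keep)[1], , drop = FALSE]
  graph
}

relabel_blanks <- function(graph, perm_seed = 1L) {
  # consistently rename all blank labels (simulates a foreign serializer)
  df <- graph$triples
  blanks <- unique(c(df$s[df$s_kind == "blank"], df$o[df$o_kind == "blank"]))
  withr::with_seed(perm_seed, {
    new <- paste0("z", sample(seq_along(blanks)))
  })
  map <- stats::setNames(new, blanks)
  sb <- df$s_kind == "blank"; ob <- df$o_kind == "blank"
  df$s[sb] <- map[df$s[sb]]
  df$o[ob] <- map[df$o[ob]]
  graph$triples <- df
  graph
}

EX_NS <- "http://purl.org/net/exergame/ns#"
METRIC_SUCCESS <- "http://purl.org/net/exergame/metric#Success"
RDF_NS <- "http://www.w3.org/1999/02/22-rdf-syntax-ns#"
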