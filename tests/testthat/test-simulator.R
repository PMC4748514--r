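test_that("default configuration mirrors the pilot cohort", {
  cfg <- default_pilot_config()
  expect_identical(cfg$n_players, 14L)
  expect_identical(cfg$n_male, 3L)
  expect_identical(cfg$age_mean, 73.4)
  expect_identical(cfg$visits_per_player, 6L)
  expect_identical(cfg$games_per_visit, 7L)
  expect_identical(length(cfg$game_catalog), 7L)
  expect_identical(cfg$game_catalog[[1]]$iri,
                   "http://www.fitforall.gr/resources/SideRaisesGame")
  expect_identical(default_pilot_config(), cfg)  # deterministic
})

test_that("invalid configurations are rejected with configuration errors", {
  cfg <- small_config()
  cfg$visits_per_player <- 0L
  expect_error(simulate_pilot(cfg), "configuration error")
  cfg <- small_config()
  cfg$n_male <- 99L
  expect_error(simulate_pilot(cfg), "n_male")
  cfg <- small_config()
  cfg$games_per_visit <- 100L
  expect_error(simulate_pilot(cfg), "catalog")
  cfg <- small_config()
  cfg$metric_models[[METRIC_SUCCESS]] <- NULL
  expect_error(simulate_pilot(cfg), "no metric model")
})

test_that("same seed gives byte-identical canonical graphs", {
  cfg <- small_config(seed = 7L)
  c1 <- canonicalize(simulate_pilot(cfg)$graph)
  c2 <- canonicalize(simulate_pilot(cfg)$graph)
  expect_identical(c1, c2)
  c3 <- canonicalize(simulate_pilot(small_config(seed = 8L))$graph)
  expect_false(identical(c1, c3))
})

test_that("session count and cohort structure follow the configuration", {
  cfg <- small_config(seed = 3L, n_players = 4L, visits = 3L, games = 2L)
  pilot <- simulate_pilot(cfg)
  expect_length(pilot$sessions, 4L * 3L * 2L)
  expect_length(pilot$players, 4L)
  # players carry opaque sequential IRIs and cohort demographics only
  expect_identical(
    vapply(pilot$players, function(p) exergraph:::iri_local(p$iri),
           character(1)),
    sprintf("player%03d", 1:4))
  expect_identical(sum(vapply(pilot$players, function(p)
    identical(p$gender, "male"), logical(1))), 1L)
  expect_true(all(vapply(pilot$players, function(p)
    p$age >= 60 && p$age <= 95, logical(1))))

  # per player: distinct visit dates and distinct games per visit
  by_player <- split(pilot$sessions,
                     vapply(pilot$sessions, function(s) s$player, character(1)))
  for (ps in by_player) {
    dates <- unique(substr(vapply(ps, function(s) s$start, character(1)),
                           1, 10))
    expect_length(dates, 3L)
    for (d in dates) {
      day <- Filter(function(s) startsWith(s$start, d), ps)
      games <- vapply(day, function(s) s$game, character(1))
      expect_length(unique(games), 2L)
      # start/end times are ordered within the visit day
      starts <- parse_datetime(vapply(day, function(s) s$start, character(1)))
      ends <- parse_datetime(vapply(day, function(s) s$end, character(1)))
      expect_true(all(diff(order(starts)) == 1L) || length(day) == 1L)
      expect_true(all(ends >= starts))
    }
  }
})

test_that("every simulated graph validates cleanly", {
  for (seed in c(11L, 12L)) {
    pilot <- simulate_pilot(small_config(seed = seed))
    expect_identical(nrow(validate_graph(pilot$graph)), 0L)
  }
})

test_that("a certain success model makes every sequence member true", {
  cfg <- small_config(seed = 5L)
  cfg$metric_models[[METRIC_SUCCESS]] <- bernoulli_model(METRIC_SUCCESS, 1)
  pilot <- simulate_pilot(cfg)
  df <- pilot$graph$triples
  rels <- df$s[df$p == default_terms()$properties[["metricName"]] &
                 df$o == METRIC_SUCCESS]
  vnodes <- df$o[df$s %in% rels &
                   df$p == default_terms()$properties[["metricValue"]]]
  memb <- df[df$s %in% vnodes & grepl(paste0("^", RDF_NS, "_[0-9]+$"), df$p), ]
  expect_gt(nrow(memb), 0L)
  expect_true(all(memb$o == "true"))
})

test_that("metric models have the declared support and location", {
  withr::local_seed(88)
  rt <- exergraph:::draw_model(
    lognormal_model(paste0("http://purl.org/net/exergame/metric#ReactionTime"),
                    meanlog = log(1.5), sdlog = 0.4), 1000L)
  expect_true(all(rt > 0))
  gt <- exergraph:::draw_model(
    truncnormal_model(paste0("http://purl.org/net/exergame/metric#GoalTime"),
                      mean = 4, sd = 1), 4000L)
  expect_true(all(gt > 0))
  # empirical mean within 3 sigma / sqrt(N) of the model mean
  expect_lt(abs(mean(gt) - 4), 3 * 1 / sqrt(length(gt)) + 0.01)
})

test_that("simulate_session observes the game's metric set", {
  fx <- sideraises_fixture()
  cfg <- default_pilot_config()
  withr::local_seed(21)
  s <- simulate_session("http://www.fitforall.gr/resources/player001",
                        fx$game, as.POSIXct("2014-09-22 08:00:00", tz = "UTC"),
                        cfg, session_id = "t1")
  expect_setequal(
    vapply(s$observations, function(o) exergraph:::iri_local(o$metric),
           character(1)),
    c("Success", "ReactionTime", "GoalTime"))
  expect_gt(parse_datetime(s$end), parse_datetime(s$start))
  withr::local_seed(21)
  s2 <- simulate_session("http://www.fitforall.gr/resources/player001",
                         fx$game,
                         as.POSIXct("2014-09-22 08:00:00", tz = "UTC"),
                         cfg, session_id = "t1")
  expect_identical(s, s2)
})

test_that("the session log round-trips through the tabular converter", {
  pilot <- simulate_pilot(small_config(seed = 31L))
  log <- sessions_to_log(pilot$sessions)
  back <- rows_to_sessions(log, default_mapping())
  expect_identical(
    canonicalize(sessions_to_graph(back)),
    canonicalize(sessions_to_graph(pilot$sessions)))
})
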