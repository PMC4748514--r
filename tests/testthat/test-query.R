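EX_PREFIX <- "PREFIX exergame: <http://purl.org/net/exergame/ns#>\n"

test_that("SELECT over an empty graph returns zero rows", {
  r <- run_query(triple_graph(), paste0(
    EX_PREFIX, "SELECT ?s ?p WHERE { ?s exergame:player ?p }"))
  expect_identical(nrow(r), 0L)
  expect_identical(names(r), c("s", "p"))
})

test_that("COUNT DISTINCT on the fixture graph counts its single player", {
  g <- session_to_graph(sideraises_fixture()$session)
  r <- run_query(g, paste0(
    EX_PREFIX,
    "SELECT (COUNT(DISTINCT ?p) AS ?n) WHERE { ?s exergame:player ?p }"))
  expect_identical(r$n, 1L)
})

test_that("engine matches the nested-scan oracle on random patterns", {
  withr::local_seed(321)
  pilot <- simulate_pilot(small_config(seed = 64L, n_players = 2L,
                                       visits = 1L, games = 2L))
  g <- pilot$graph
  P <- default_terms()$properties
  queries <- list(
    list(exergraph:::bgp_pattern("?s", P[["player"]], "?p")),
    list(exergraph:::bgp_pattern("?s", P[["result"]], "?r"),
         exergraph:::bgp_pattern("?r", P[["metricRelation"]], "?rel")),
    list(exergraph:::bgp_pattern("?s", P[["player"]], "?p"),
         exergraph:::bgp_pattern("?s", P[["game"]], "?g"),
         exergraph:::bgp_pattern("?s", P[["startDateTime"]], "?d")),
    list(exergraph:::bgp_pattern("?rel", P[["metricName"]],
                                 paste0("I", METRIC_SUCCESS)),
         exergraph:::bgp_pattern("?rel", P[["metricValue"]], "?v")),
    list(exergraph:::bgp_pattern("?s", "?p", "?o"))
  )
  as_multiset <- function(df) {
    df <- df[, order(names(df)), drop = FALSE]
    sort(do.call(paste, c(df, sep = "\x01")))
  }
  for (q in queries) {
    a <- exergraph:::eval_bgp(g, q)
    b <- exergraph:::oracle_bgp(g, q)
    expect_identical(as_multiset(a), as_multiset(b))
  }
})

test_that("canned per-iteration query reproduces the published lookup", {
  g <- session_to_graph(sideraises_fixture()$session)
  r <- metric_at_iteration(g, METRIC_SUCCESS, 3L)
  expect_identical(nrow(r), 1L)
  expect_identical(r$value, "false")
  expect_identical(r$player, "http://www.fitforall.gr/resources/player162")
  expect_identical(r$startDateTime, "2014-09-22T18:09:39+02:00")

  expect_identical(nrow(metric_at_iteration(g, METRIC_SUCCESS, 99L)), 0L)
  expect_error(metric_at_iteration(g, METRIC_SUCCESS, 0L), "positive")
})

test_that("the shipped query file matches metric_at_iteration", {
  g <- session_to_graph(sideraises_fixture()$session)
  rq <- paste(readLines(system.file("sparql", "metric-at-iteration.rq",
                                    package = "exergraph")), collapse = "\n")
  rq <- gsub("{{metric}}", METRIC_SUCCESS, rq, fixed = TRUE)
  rq <- gsub("{{iteration}}", "3", rq, fixed = TRUE)
  r <- run_query(g, rq)
  expect_identical(r$value, "false")
  expect_identical(r$player, "http://www.fitforall.gr/resources/player162")
})

test_that("iteration 1 covers both the direct-literal and Seq encodings", {
  s_direct <- session_record(
    "direct", "http://g.example/g", "http://p.example/pA",
    start = "2014-09-23T10:00:00+02:00", end = "2014-09-23T10:05:00+02:00",
    observations = list(metric_observation(METRIC_SUCCESS, TRUE)))
  s_seq <- session_record(
    "seq", "http://g.example/g", "http://p.example/pB",
    start = "2014-09-23T11:00:00+02:00", end = "2014-09-23T11:05:00+02:00",
    observations = list(metric_observation(METRIC_SUCCESS, c(FALSE, TRUE))))
  g <- sessions_to_graph(list(s_direct, s_seq))
  r <- metric_at_iteration(g, METRIC_SUCCESS, 1L)
  expect_identical(nrow(r), 2L)
  expect_setequal(r$value, c("true", "false"))
  r2 <- metric_at_iteration(g, METRIC_SUCCESS, 2L)
  expect_identical(r2$player, "http://p.example/pB")
})

test_that("graph query equals the record oracle over seeded pilots", {
  metrics <- paste0("http://purl.org/net/exergame/metric#",
                    c("Success", "ReactionTime", "GoalTime"))
  for (seed in 1:10) {
    pilot <- simulate_pilot(small_config(seed = seed, n_players = 2L,
                                         visits = 1L, games = 2L))
    for (m in metrics) {
      for (it in c(1L, 2L, 3L)) {
        a <- metric_at_iteration(pilot$graph, m, it)
        b <- oracle_metric_at_iteration(pilot$sessions, m, it)
        expect_identical(a, b, info = paste(seed, m, it))
      }
    }
  }
})

test_that("adding sessions never removes per-iteration result rows", {
  withr::local_seed(555)
  sessions <- lapply(1:6, random_session)
  g3 <- sessions_to_graph(sessions[1:3])
  g6 <- sessions_to_graph(sessions)
  for (m in unique(unlist(lapply(sessions, function(s)
    vapply(s$observations, function(o) o$metric, character(1)))))) {
    r3 <- metric_at_iteration(g3, m, 1L)
    r6 <- metric_at_iteration(g6, m, 1L)
    key <- function(df) paste(df$player, df$startDateTime, df$value)
    expect_true(all(key(r3) %in% key(r6)), info = m)
  }
})

test_that("unsupported SPARQL constructs fail with a clear parse error", {
  g <- triple_graph()
  expect_error(run_query(g, paste0(
    EX_PREFIX,
    "SELECT ?s WHERE { ?s exergame:player ?p FILTER(?p > 1) }")),
    "FILTER")
  expect_error(run_query(g, "SELECT ?s WHERE { ?s ex:player ?p }"),
               "undeclared prefix")
  expect_error(run_query(g, "ASK { ?s ?p ?o }"), "SELECT")
})
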