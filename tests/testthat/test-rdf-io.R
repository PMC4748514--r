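terms <- default_terms()
P <- terms$properties

test_that("session emission reproduces the published n-ary structure", {
  fx <- sideraises_fixture()
  g <- session_to_graph(fx$session, terms)
  df <- g$triples

  sess <- df$s[df$p == exergraph:::rdf("type") &
                 df$o == terms$classes[["GameSession"]]]
  res <- df$o[df$s == sess & df$p == P[["result"]]]
  expect_length(sess, 1L)
  expect_length(res, 1L)
  # result node carries exactly 3 metric-relation links
  rels <- df[df$s == res & df$p == P[["metricRelation"]], ]
  expect_identical(nrow(rels), 3L)

  # the Success relation's value node is an rdf:Seq with ordered members
  name_rows <- df[df$p == P[["metricName"]] & df$o == METRIC_SUCCESS, ]
  expect_identical(nrow(name_rows), 1L)
  rel <- name_rows$s
  vnode <- df$o[df$s == rel & df$p == P[["metricValue"]]]
  expect_true(any(df$s == vnode & df$p == exergraph:::rdf("type") &
                    df$o == exergraph:::rdf("Seq")))
  memb <- df[df$s == vnode & grepl(paste0("^", RDF_NS, "_[0-9]+$"), df$p), ]
  idx <- as.integer(sub(paste0("^", RDF_NS, "_"), "", memb$p))
  expect_identical(memb$o[order(idx)],
                   c("true", "true", "false", "true", "false", "true"))
  expect_identical(max(idx), 6L)
})

test_that("single-iteration observations are direct literals, not sequences", {
  s <- session_record(
    "one", "http://g.example/g", "http://p.example/p",
    start = "2014-09-22T10:00:00+02:00", end = "2014-09-22T10:05:00+02:00",
    observations = list(metric_observation(
      "http://purl.org/net/exergame/metric#Score", 42L)))
  g <- session_to_graph(s, terms)
  df <- g$triples
  val <- df[df$p == P[["metricValue"]], ]
  expect_identical(val$o_kind, "literal")
  expect_identical(val$o, "42")
  expect_false(any(df$o == exergraph:::rdf("Seq")))
})

test_that("a session without observations cannot be emitted", {
  s <- session_record("empty", "http://g.example/g", "http://p.example/p",
                      start = "2014-09-22T10:00:00+02:00",
                      end = "2014-09-22T10:00:00+02:00",
                      observations = list())
  expect_error(session_to_graph(s, terms), "no metric observations")
})

test_that("round trip graph_to_sessions . session_to_graph is the identity", {
  fx <- sideraises_fixture()
  back <- graph_to_sessions(session_to_graph(fx$session, terms), terms)
  expect_length(back, 1L)
  expect_identical(back[[1]], fx$session)

  withr::local_seed(4711)
  sessions <- lapply(1:25, random_session)
  back <- graph_to_sessions(sessions_to_graph(sessions, terms), terms)
  key <- function(s) paste(s$start, s$player, s$session_id)
  sessions <- sessions[order(vapply(sessions, key, character(1)))]
  expect_identical(back, sessions)
})

test_that("skolemized emission uses resolvable IRIs and still round-trips", {
  fx <- sideraises_fixture()
  g <- session_to_graph(fx$session, terms,
                        skolem_base = "http://www.fitforall.gr/id/")
  expect_false(any(g$triples$s_kind == "blank"))
  expect_false(any(g$triples$o_kind == "blank"))
  back <- graph_to_sessions(g, terms)
  expect_identical(back[[1]], fx$session)
})

test_that("hand-built graph of the published table yields the session", {
  g <- parse_graph(test_path("table1.nt"), "ntriples")
  # the excerpt elides the other two relations' names/values: complete
  # them minimally so the record is well-formed
  g <- add_triple(g, exergraph:::nd_blank("MetricRelation2"),
                  P[["metricName"]],
                  "http://purl.org/net/exergame/metric#ReactionTime")
  g <- add_triple(g, exergraph:::nd_blank("MetricRelation2"),
                  P[["metricValue"]], 1.5)
  g <- add_triple(g, exergraph:::nd_blank("MetricRelation3"),
                  P[["metricName"]],
                  "http://purl.org/net/exergame/metric#GoalTime")
  g <- add_triple(g, exergraph:::nd_blank("MetricRelation3"),
                  P[["metricValue"]], 4.0)
  sessions <- graph_to_sessions(g, terms)
  expect_length(sessions, 1L)
  s <- sessions[[1]]
  expect_identical(s$player, "http://www.fitforall.gr/resources/player162")
  suc <- Filter(function(o) o$metric == METRIC_SUCCESS, s$observations)[[1]]
  expect_identical(suc$values, c(TRUE, TRUE, FALSE, TRUE, FALSE, TRUE))
})

test_that("missing mandatory links are reported with node and predicate", {
  fx <- sideraises_fixture()
  g <- session_to_graph(fx$session, terms)
  for (role in c("player", "game", "result", "startDateTime")) {
    broken <- drop_triple(g, p = P[[role]])
    expect_error(graph_to_sessions(broken, terms), role)
  }
})

test_that("sequence gaps are detected for every 1- and 2-gap pattern", {
  # enumerate all membership subsets of 1..n (n <= 4) that keep the last
  # index but miss at least one interior one
  for (n in 2:4) {
    full <- seq_len(n)
    drop_sets <- Filter(function(set) length(set) >= 1 && length(set) <= 2,
                        unlist(lapply(1:2, function(k) {
                          utils::combn(seq_len(n - 1L), min(k, n - 1L),
                                       simplify = FALSE)
                        }), recursive = FALSE))
    for (drop in unique(drop_sets)) {
      s <- session_record(
        "gap", "http://g.example/g", "http://p.example/p",
        start = "2014-09-22T10:00:00+02:00",
        end = "2014-09-22T10:05:00+02:00",
        observations = list(metric_observation(METRIC_SUCCESS,
                                               rep(TRUE, n))))
      g <- session_to_graph(s, terms)
      for (d in drop) {
        g <- drop_triple(g, p = exergraph:::rdf(paste0("_", d)))
      }
      expect_error(graph_to_sessions(g, terms), "non-contiguous")
      v <- validate_graph(g, terms)
      expect_true("SEQ_GAP" %in% v$code)
    }
  }
})

test_that("game emission covers controllers, hardware, exercise, goals", {
  fx <- sideraises_fixture()
  g <- game_to_graph(fx$game, terms)
  df <- g$triples
  expect_true(any(
    df$s == "http://purl.org/net/exergame/controller#Kinect" &
      df$p == paste0(exergraph:::NS_OWL, "sameAs") &
      df$o == "http://dbpedia.org/resource/Kinect"))
  goal_metrics <- df$s[df$p == exergraph:::rdf("type") &
                         df$o == terms$classes[["GoalMetric"]]]
  expect_length(unique(goal_metrics), 3L)
  # NCIt muscles are declared subclasses of the thesaurus Muscle class
  sub <- df[df$p == paste0(exergraph:::NS_RDFS, "subClassOf"), ]
  expect_identical(sort(unique(sub$o)),
                   paste0(exergraph:::NS_NCI, "Muscle"))
  expect_identical(nrow(sub), 3L)

  plain <- game_description("http://g.example/g", "g",
                            metrics = list(define_metric("Score", "score")))
  g2 <- game_to_graph(plain, terms)
  expect_false(any(g2$triples$p == P[["gameExercise"]]))
})
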