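# Conversion between in-memory records and RDF graphs.
#
# The emitted structure follows the published dataset: a game session is a
# blank node typed exergame:GameSession holding exergame:{result, site,
# startDateTime, endDateTime, player, game}; its result blank node is typed
# exergame:Result and links one exergame:MetricRelation blank node per
# observation. RDF properties being binary, the metric relation is the
# auxiliary node of the n-ary (result x metric x unit x value)
# association: exergame:metricName points at the metric individual and
# exergame:metricValue at the value — a plain typed literal for a single
# iteration, otherwise a blank rdf:Seq whose numbered membership
# properties rdf:_1..rdf:_n keep the iteration order.

#' Emit one session as RDF
#'
#' @param session A `SessionRecord`.
#' @param terms Term registry, see [default_terms()].
#' @param skolem_base Optional IRI base; when given, session/result/
#'   relation/sequence nodes are minted as resolvable IRIs under it instead
#'   of blank nodes (useful before triplestore upload).
#' @return A `TripleGraph`.
#' @examples
#' g <- session_to_graph(sideraises_fixture()$session, default_terms())
#' graph_size(g)
#' @export
session_to_graph <- function(session, terms = default_terms(),
                             skolem_base = NULL) {
  stopifnot(inherits(session, "SessionRecord"),
            inherits(terms, "OntologyTerms"))
  if (length(session$observations) == 0L) {
    stop("session '", session$session_id,
         "' has no metric observations; nothing to emit", call. = FALSE)
  }
  g <- triple_graph(terms$prefixes)
  g$triples <- session_triples(session, terms, skolem_base)
  new_graph_from_df(g$triples, g$prefixes)
}

# Internal: triples data.frame for one session (used by the bulk emitters).
session_triples <- function(session, terms, skolem_base = NULL) {
  p <- terms$properties; cl <- terms$classes
  sid <- blank_label(session$session_id)
  mk <- if (is.null(skolem_base)) {
    function(label) nd_blank(label)
  } else {
    function(label) nd_iri(paste0(skolem_base, label))
  }
  sess <- mk(paste0("sess_", sid))
  res <- mk(paste0("res_", sid))
  rows <- vector("list", 2L + length(session$observations))

  dt_dt <- xsd("dateTime")
  sess_rows <- triples_df(
    s = sess$value, s_kind = sess$kind,
    p = c(rdf("type"), p[["result"]], p[["startDateTime"]],
          p[["endDateTime"]], p[["player"]], p[["game"]]),
    o = c(cl[["GameSession"]], res$value, session$start, session$end,
          session$player, session$game),
    o_kind = c("iri", res$kind, "literal", "literal", "iri", "iri"),
    o_dt = c(NA, NA, dt_dt, dt_dt, NA, NA)
  )
  if (!is.null(session$site)) {
    sess_rows <- rbind(sess_rows, triples_df(
      sess$value, sess$kind, p[["site"]], session$site, "iri"))
  }
  rows[[1]] <- sess_rows
  rows[[2]] <- triples_df(res$value, res$kind, rdf("type"),
                          cl[["Result"]], "iri")

  for (k in seq_along(session$observations)) {
    ob <- session$observations[[k]]
    rel <- mk(paste0("rel_", sid, "_", k, "_", iri_local(ob$metric)))
    lx <- values_to_lexical(ob$values)
    n <- length(ob$values)
    rel_rows <- triples_df(
      s = c(res$value, rel$value, rel$value),
      s_kind = c(res$kind, rel$kind, rel$kind),
      p = c(p[["metricRelation"]], rdf("type"), p[["metricName"]]),
      o = c(rel$value, cl[["MetricRelation"]], ob$metric),
      o_kind = c(rel$kind, "iri", "iri")
    )
    if (!is.null(ob$unit)) {
      rel_rows <- rbind(rel_rows, triples_df(
        rel$value, rel$kind, p[["metricUnit"]], ob$unit, "iri"))
    }
    if (n == 1L) {
      val_rows <- triples_df(rel$value, rel$kind, p[["metricValue"]],
                             lx$lex, "literal", lx$dt)
    } else {
      sq <- mk(paste0("seq_", sid, "_", k, "_", iri_local(ob$metric)))
      val_rows <- rbind(
        triples_df(rel$value, rel$kind, p[["metricValue"]],
                   sq$value, sq$kind),
        triples_df(sq$value, sq$kind, rdf("type"), rdf("Seq"), "iri"),
        triples_df(sq$value, sq$kind, rdf(paste0("_", seq_len(n))),
                   lx$lex, "literal", lx$dt)
      )
    }
    rows[[2L + k]] <- rbind(rel_rows, val_rows)
  }
  do.call(rbind, rows)
}

#' Emit several sessions into one graph
#'
#' @inheritParams session_to_graph
#' @param sessions List of `SessionRecord`s.
#' @return A `TripleGraph` holding the union of the per-session subgraphs.
#' @export
sessions_to_graph <- function(sessions, terms = default_terms(),
                              skolem_base = NULL) {
  stopifnot(is.list(sessions))
  if (length(sessions) == 0L) return(triple_graph(terms$prefixes))
  dfs <- lapply(sessions, function(s) {
    if (length(s$observations) == 0L) {
      stop("session '", s$session_id, "' has no metric observations",
           call. = FALSE)
    }
    session_triples(s, terms, skolem_base)
  })
  new_graph_from_df(do.call(rbind, dfs), terms$prefixes)
}

#' Emit a game description as RDF
#'
#' The game individual is typed `exergame:Game`; metrics become
#' `exergame:GoalMetric` individuals (with SKOS concept and default unit
#' when given), controllers `exergame:GameController` individuals linked to
#' DBpedia with `owl:sameAs` when known, presentation hardware
#' `exergame:PresentationHardware` individuals, and the exercise an
#' `exergame:Exercise` individual whose muscles are referenced by their OPE
#' IRI or declared as NCIt `Muscle` subclasses.
#'
#' @param game A `GameDescription`.
#' @param terms Term registry.
#' @return A `TripleGraph`.
#' @export
game_to_graph <- function(game, terms = default_terms()) {
  stopifnot(inherits(game, "GameDescription"),
            inherits(terms, "OntologyTerms"))
  p <- terms$properties; cl <- terms$classes
  rows <- list()
  add <- function(s, pred, o, o_kind = "iri", o_dt = NA_character_) {
    rows[[length(rows) + 1L]] <<- triples_df(s, "iri", pred, o, o_kind, o_dt)
  }
  lab <- paste0(NS_RDFS, "label")
  add(game$iri, rdf("type"), cl[["Game"]])
  add(game$iri, lab, game$label, "literal", xsd("string"))
  for (m in game$metrics) {
    add(game$iri, p[["gameMetric"]], m$iri)
    add(m$iri, rdf("type"), cl[["GoalMetric"]])
    add(m$iri, lab, m$label, "literal", xsd("string"))
    if (!is.null(m$concept)) add(m$iri, p[["concept"]], m$concept)
    if (!is.null(m$default_unit)) {
      add(m$iri, p[["metricUnit"]], m$default_unit)
      add(m$default_unit, rdf("type"), cl[["Unit"]])
    }
  }
  for (ctrl in game$controllers) {
    add(game$iri, p[["gameController"]], ctrl$iri)
    add(ctrl$iri, rdf("type"), cl[["GameController"]])
    add(ctrl$iri, lab, ctrl$label, "literal", xsd("string"))
    if (!is.null(ctrl$same_as)) {
      add(ctrl$iri, paste0(NS_OWL, "sameAs"), ctrl$same_as)
    }
  }
  for (h in game$presentation_hardware) {
    add(game$iri, p[["presentationHardware"]], h$iri)
    add(h$iri, rdf("type"), cl[["PresentationHardware"]])
    add(h$iri, lab, h$label, "literal", xsd("string"))
  }
  if (!is.null(game$exercise)) {
    ex <- game$exercise
    add(game$iri, p[["gameExercise"]], ex$iri)
    add(ex$iri, rdf("type"), cl[["Exercise"]])
    add(ex$iri, lab, ex$label, "literal", xsd("string"))
    for (m in ex$muscles) {
      add(ex$iri, p[["involvesMuscle"]], m$iri)
      if (m$source == "NCIt-subclass") {
        add(m$iri, paste0(NS_RDFS, "subClassOf"), paste0(NS_NCI, "Muscle"))
      }
    }
    for (eq in ex$equipment) {
      add(ex$iri, p[["equipment"]], eq, "literal", xsd("string"))
    }
    for (b in ex$benefits) {
      add(ex$iri, p[["healthBenefit"]], b, "literal", xsd("string"))
    }
  }
  for (gl in game$goals) {
    pred <- if (gl$kind == "game_goal") p[["gameGoal"]] else p[["exerciseGoal"]]
    add(game$iri, pred, gl$text, "literal", xsd("string"))
  }
  new_graph_from_df(do.call(rbind, rows), terms$prefixes)
}

#' Emit a site record as RDF
#'
#' @param site A `SiteRecord`.
#' @param terms Term registry.
#' @return A `TripleGraph`: the site typed by its site-type individual,
#'   which is itself typed `exergame:SiteType`; the address, when present,
#'   with `exergame:siteAddress` (range left open by the ontology).
#' @export
site_to_graph <- function(site, terms = default_terms()) {
  stopifnot(inherits(site, "SiteRecord"))
  g <- triple_graph(terms$prefixes)
  g <- add_triple(g, site$iri, rdf("type"), site$site_type)
  g <- add_triple(g, site$site_type, rdf("type"),
                  term(terms, "classes", "SiteType"))
  if (!is.null(site$address)) {
    g <- add_triple(g, site$iri, term(terms, "properties", "siteAddress"),
                    nd_lit(site$address))
  }
  g
}

## ---- graph -> records -------------------------------------------------

subject_key <- function(df) paste0(df$s_kind, "\x01", df$s)

# one object of (node, pred); errors name the node and predicate
need_one <- function(graph, node, pred, what) {
  hits <- graph_match(graph, s = node, p = pred)
  if (nrow(hits) == 0L) {
    stop("structural violation at node '", node, "': missing ", what,
         " (", pred, ")", call. = FALSE)
  }
  if (nrow(hits) > 1L) {
    stop("structural violation at node '", node, "': multiple ", what,
         " (", pred, ")", call. = FALSE)
  }
  hits
}

#' Recover session records from a graph
#'
#' The structural inverse of [session_to_graph()]: every node typed
#' `exergame:GameSession` yields one `SessionRecord`, with rdf:Seq members
#' restored in membership-index order. Blank-node labels of the form
#' `sess_<id>` (as emitted by this package) are stripped back to `<id>`;
#' any other label or IRI local name is used as the session id verbatim.
#'
#' @param graph A `TripleGraph`.
#' @param terms Term registry.
#' @return List of `SessionRecord`s, ordered by (start, player, node).
#' @export
graph_to_sessions <- function(graph, terms = default_terms()) {
  stopifnot(is_triple_graph(graph), inherits(terms, "OntologyTerms"))
  p <- terms$properties; cl <- terms$classes
  sess_rows <- graph_match(graph, p = rdf("type"), o = cl[["GameSession"]])
  if (nrow(sess_rows) == 0L) return(list())

  out <- lapply(seq_len(nrow(sess_rows)), function(i) {
    node <- sess_rows$s[i]
    player <- need_one(graph, node, p[["player"]], "player")$o
    game <- need_one(graph, node, p[["game"]], "game")$o
    start <- need_one(graph, node, p[["startDateTime"]], "startDateTime")$o
    end <- need_one(graph, node, p[["endDateTime"]], "endDateTime")$o
    res <- need_one(graph, node, p[["result"]], "result")$o
    site_rows <- graph_match(graph, s = node, p = p[["site"]])
    site <- if (nrow(site_rows) >= 1L) site_rows$o[1] else NULL

    rel_rows <- graph_match(graph, s = res, p = p[["metricRelation"]])
    rel_rows <- rel_rows[order(rel_rows$o), , drop = FALSE]
    obs <- lapply(rel_rows$o, function(rel) relation_to_observation(
      graph, rel, terms))

    sid <- sess_rows$s[i]
    if (sess_rows$s_kind[i] == "iri") sid <- iri_local(sid)
    sid <- sub("^sess_", "", sid)
    session_record(session_id = sid, game = game, player = player,
                   start = start, end = end, observations = obs, site = site)
  })
  keys <- vapply(out, function(s) paste(s$start, s$player, s$session_id),
                 character(1))
  out[order(keys)]
}

relation_to_observation <- function(graph, rel, terms) {
  p <- terms$properties
  name <- need_one(graph, rel, p[["metricName"]], "metricName")
  if (name$o_kind != "iri") {
    stop("structural violation at node '", rel,
         "': metricName must be an IRI", call. = FALSE)
  }
  val <- need_one(graph, rel, p[["metricValue"]], "metricValue")
  unit_rows <- graph_match(graph, s = rel, p = p[["metricUnit"]])
  unit <- if (nrow(unit_rows) >= 1L) unit_rows$o[1] else NULL

  if (val$o_kind == "literal") {
    values <- lexical_to_values(val$o, val$o_dt)
  } else {
    members <- graph_match(graph, s = val$o)
    members <- members[grepl(paste0("^", NS_RDF, "_[0-9]+$"), members$p), ,
                       drop = FALSE]
    if (nrow(members) == 0L) {
      stop("structural violation at node '", val$o,
           "': value node has no rdf:_n members", call. = FALSE)
    }
    idx <- as.integer(sub(paste0("^", NS_RDF, "_"), "", members$p))
    members <- members[order(idx), , drop = FALSE]
    idx <- sort(idx)
    if (!identical(idx, seq_along(idx))) {
      stop("non-contiguous rdf:Seq indices at node '", val$o, "': found ",
           paste(idx, collapse = ","), call. = FALSE)
    }
    dts <- unique(members$o_dt)
    if (length(dts) > 1L) {
      stop("mixed datatypes in rdf:Seq at node '", val$o, "'", call. = FALSE)
    }
    values <- lexical_to_values(members$o, dts[1])
  }
  metric_observation(name$o, values, unit = unit)
}
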