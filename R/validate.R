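# Structural validation of session graphs, including the anonymization
# rule: information that might reveal a player's identity must not be
# stored, so player nodes carry an opaque identifier and no personal
# predicates (FOAF name/mbox/phone, vCard fn/email/tel by default).

VIOLATION_CODES <- c("MISSING_LINK", "TIME_ORDER", "SEQ_GAP", "SEQ_SINGLETON",
                     "UNKNOWN_METRIC", "UNIT_MISSING", "PII_PRESENT",
                     "NAMESPACE_DRIFT")

#' Default personal-data predicate blocklist
#'
#' FOAF and vCard predicates that would attach identifying information to a
#' player node. The ontology's deployment rule is the principle (no
#' identity-revealing data); the concrete list is a package choice and can
#' be extended via the `pii_predicates` argument of [validate_graph()].
#'
#' @return Character vector of predicate IRIs.
#' @export
default_pii_predicates <- function() {
  c(paste0(NS_FOAF, c("name", "givenName", "familyName", "firstName",
                      "lastName", "mbox", "mbox_sha1sum", "phone")),
    paste0(NS_VCARD, c("fn", "hasEmail", "email", "hasTelephone", "tel")))
}

violation_row <- function(code, node, detail) {
  stopifnot(code %in% VIOLATION_CODES)
  data.frame(code = code, node = node, detail = detail,
             stringsAsFactors = FALSE)
}

no_violations <- function() {
  data.frame(code = character(0), node = character(0), detail = character(0),
             stringsAsFactors = FALSE)
}

#' Validate a session graph against the ontology's structural rules
#'
#' Checks every `exergame:GameSession` node for its mandatory links
#' (exactly one player, game, result, startDateTime, endDateTime), time
#' ordering, every metric relation for metricName/metricValue, rdf:Seq
#' membership contiguity, the anonymization rule on player nodes, and that
#' all terms used from the core exergame namespace resolve in the registry.
#' Violations are data, not exceptions: an empty result means a clean
#' graph.
#'
#' The `strict` profile additionally reports a missing site link, a
#' missing unit of measurement on a metric relation, and single-element
#' sequences (a lone iteration should be a plain literal). The published
#' session excerpt itself shows no unit on its relations, which is why
#' unit presence is a strict-only rule.
#'
#' @param graph A `TripleGraph`.
#' @param terms Term registry.
#' @param profile `"compat"` (default) or `"strict"`.
#' @param pii_predicates Predicate blocklist for the anonymization check.
#' @return A data.frame with columns `code`, `node`, `detail`; zero rows
#'   iff the graph is clean at the selected profile. The graph is never
#'   modified.
#' @examples
#' fx <- sideraises_fixture()
#' g <- session_to_graph(fx$session)
#' nrow(validate_graph(g))  # 0
#' @export
validate_graph <- function(graph, terms = default_terms(),
                           profile = c("compat", "strict"),
                           pii_predicates = default_pii_predicates()) {
  profile <- match.arg(profile)
  stopifnot(is_triple_graph(graph), inherits(terms, "OntologyTerms"))
  p <- terms$properties; cl <- terms$classes
  df <- graph$triples
  out <- list(no_violations())
  push <- function(code, node, detail) {
    out[[length(out) + 1L]] <<- violation_row(code, node, detail)
  }

  sessions <- df$s[df$p == rdf("type") & df$o == cl[["GameSession"]]]
  mandatory <- c("player", "game", "result", "startDateTime", "endDateTime")
  for (sess in sessions) {
    for (role in mandatory) {
      k <- sum(df$s == sess & df$p == p[[role]])
      if (k == 0L) {
        push("MISSING_LINK", sess, paste0("session lacks exergame:", role))
      } else if (k > 1L) {
        push("MISSING_LINK", sess,
             paste0("session has ", k, " exergame:", role, " links; expected 1"))
      }
    }
    if (profile == "strict" && !any(df$s == sess & df$p == p[["site"]])) {
      push("MISSING_LINK", sess,
           "session lacks exergame:site (optional; strict profile)")
    }
    st <- df$o[df$s == sess & df$p == p[["startDateTime"]]]
    en <- df$o[df$s == sess & df$p == p[["endDateTime"]]]
    if (length(st) == 1L && length(en) == 1L) {
      ts <- parse_datetime(st); te <- parse_datetime(en)
      if (!is.na(ts) && !is.na(te) && ts > te) {
        push("TIME_ORDER", sess,
             paste0("startDateTime ", st, " is after endDateTime ", en))
      }
    }
  }

  # metric relations: objects of exergame:metricRelation plus anything
  # typed exergame:MetricRelation
  rels <- unique(c(df$o[df$p == p[["metricRelation"]] & df$o_kind != "literal"],
                   df$s[df$p == rdf("type") & df$o == cl[["MetricRelation"]]]))
  for (rel in rels) {
    names_ <- df[df$s == rel & df$p == p[["metricName"]], , drop = FALSE]
    if (nrow(names_) == 0L) {
      push("MISSING_LINK", rel, "metric relation lacks exergame:metricName")
    } else {
      bad <- names_$o_kind != "iri" | !startsWith(names_$o, NS_METRIC)
      for (i in which(bad)) {
        push("UNKNOWN_METRIC", rel,
             paste0("metricName '", names_$o[i],
                    "' is not an IRI in the metric namespace ", NS_METRIC))
      }
    }
    if (!any(df$s == rel & df$p == p[["metricValue"]])) {
      push("MISSING_LINK", rel, "metric relation lacks exergame:metricValue")
    }
    if (profile == "strict" &&
        !any(df$s == rel & df$p == p[["metricUnit"]])) {
      push("UNIT_MISSING", rel,
           "metric relation lacks a unit of measurement (strict profile)")
    }
  }

  # rdf:Seq membership discipline
  seq_nodes <- unique(c(
    df$s[df$p == rdf("type") & df$o == rdf("Seq")],
    df$s[grepl(paste0("^", NS_RDF, "_[0-9]+$"), df$p)]))
  for (sq in seq_nodes) {
    memb <- df[df$s == sq & grepl(paste0("^", NS_RDF, "_[0-9]+$"), df$p), ,
               drop = FALSE]
    if (nrow(memb) == 0L) next
    idx <- sort(as.integer(sub(paste0("^", NS_RDF, "_"), "", memb$p)))
    if (!identical(idx, seq_along(idx))) {
      push("SEQ_GAP", sq,
           paste0("membership indices not contiguous from 1: ",
                  paste(idx, collapse = ",")))
    }
    if (profile == "strict" && length(idx) == 1L) {
      push("SEQ_SINGLETON", sq,
           "single-iteration value should be a plain literal, not a sequence")
    }
  }

  # anonymization: player nodes must not carry personal predicates
  players <- unique(df$o[df$p == p[["player"]]])
  for (pl in players) {
    hits <- df[df$s == pl & df$p %in% pii_predicates, , drop = FALSE]
    for (i in seq_len(nrow(hits))) {
      push("PII_PRESENT", pl,
           paste0("player node carries identifying predicate <",
                  hits$p[i], ">"))
    }
  }

  # namespace drift: core-namespace terms must resolve in the registry
  known <- c(unname(p), unname(cl))
  core_preds <- unique(df$p[startsWith(df$p, NS_EXERGAME)])
  for (pr in setdiff(core_preds, known)) {
    push("NAMESPACE_DRIFT", pr,
         "predicate in the exergame namespace is not in the term registry")
  }
  core_classes <- unique(df$o[df$p == rdf("type") &
                                startsWith(df$o, NS_EXERGAME)])
  for (clx in setdiff(core_classes, known)) {
    push("NAMESPACE_DRIFT", clx,
         "class in the exergame namespace is not in the term registry")
  }

  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Violations as JSON lines
#'
#' @param violations Result of [validate_graph()].
#' @return Character vector, one JSON object per violation.
#' @export
violations_to_json <- function(violations) {
  if (nrow(violations) == 0L) return(character(0))
  vapply(seq_len(nrow(violations)), function(i) {
    as.character(jsonlite::toJSON(as.list(violations[i, ]),
                                  auto_unbox = TRUE))
  }, character(1))
}
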