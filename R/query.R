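# SPARQL evaluation over in-memory graphs.
#
# The engine covers the SELECT fragment the exergame dataset is queried
# with: PREFIX declarations, SELECT [DISTINCT] with a variable projection
# or a single (COUNT(DISTINCT ?v) AS ?alias) aggregate, and a basic graph
# pattern with '.', ';', ',' and the 'a' keyword. Unsupported syntax
# (FILTER, OPTIONAL, UNION, property paths) raises a parse error naming
# the offending token. The published query text for the dataset is not
# reproduced in the source article, so the canned per-iteration query is a
# reconstruction of the described access path: session -> result ->
# metric relation -> metric name/value -> rdf:_n member.
#
# A deliberately naive oracle (recursive nested triple scan) evaluates
# the same basic graph patterns; tests require engine/oracle agreement.

# encode terms for joining: kind tag + value (+ datatype/lang for literals)
enc_term <- function(value, kind, dt = NA_character_, lang = NA_character_) {
  ifelse(kind == "iri", paste0("I", value),
  ifelse(kind == "blank", paste0("B", value),
         paste0("L", value, "\x01", ifelse(is.na(dt), "", dt),
                "\x01", ifelse(is.na(lang), "", lang))))
}

dec_term <- function(enc) {
  kind <- substr(enc, 1L, 1L)
  rest <- substring(enc, 2L)
  ifelse(kind == "I", rest,
  ifelse(kind == "B", paste0("_:", rest),
         sub("\x01.*$", "", rest)))
}

enc_graph <- function(graph) {
  df <- graph$triples
  df$enc_s <- enc_term(df$s, df$s_kind)
  df$enc_o <- enc_term(df$o, df$o_kind, df$o_dt, df$o_lang)
  df
}

is_var <- function(x) is.character(x) && length(x) == 1L && startsWith(x, "?")

# A pattern is list(s=, p=, o=): each either "?var" or an encoded constant
# ("I<iri>" / "L<lex>\x01<dt>\x01" ...); p may additionally be a plain IRI.
bgp_pattern <- function(s, p, o) list(s = s, p = p, o = o)

match_pattern <- function(edf, pat) {
  keep <- rep(TRUE, nrow(edf))
  if (!is_var(pat$s)) keep <- keep & edf$enc_s == pat$s
  if (!is_var(pat$p)) keep <- keep & edf$p == pat$p
  if (!is_var(pat$o)) keep <- keep & edf$enc_o == pat$o
  rows <- edf[keep, , drop = FALSE]
  cols <- list()
  if (is_var(pat$s)) cols[[substring(pat$s, 2L)]] <- rows$enc_s
  if (is_var(pat$p)) cols[[substring(pat$p, 2L)]] <- paste0("I", rows$p)
  if (is_var(pat$o)) cols[[substring(pat$o, 2L)]] <- rows$enc_o
  # repeated variable within one pattern: positions must agree
  nm <- c(if (is_var(pat$s)) "s", if (is_var(pat$p)) "p", if (is_var(pat$o)) "o")
  if (anyDuplicated(names(cols))) {
    dup <- names(cols)[duplicated(names(cols))][1]
    ix <- which(names(cols) == dup)
    ok <- cols[[ix[1]]] == cols[[ix[2]]]
    cols <- lapply(cols[!duplicated(names(cols))], function(v) v[ok])
  }
  if (length(cols) == 0L) {
    return(data.frame(.n = integer(nrow(rows)))[, 0, drop = FALSE])
  }
  as.data.frame(cols, stringsAsFactors = FALSE, optional = TRUE)
}

join_solutions <- function(a, b) {
  shared <- intersect(names(a), names(b))
  if (nrow(a) == 0L || nrow(b) == 0L) {
    out <- a[integer(0), , drop = FALSE]
    for (nm in setdiff(names(b), names(a))) out[[nm]] <- character(0)
    return(out)
  }
  if (length(shared) == 0L) return(merge(a, b, by = NULL))
  merge(a, b, by = shared)
}

eval_bgp <- function(graph, patterns) {
  edf <- enc_graph(graph)
  sols <- NULL
  for (pat in patterns) {
    m <- match_pattern(edf, pat)
    if (ncol(m) == 0L) {
      # fully ground pattern: acts as an existence filter
      hits <- nrow(match_rows_ground(edf, pat))
      if (hits == 0L) {
        if (is.null(sols)) return(data.frame())
        return(sols[integer(0), , drop = FALSE])
      }
      next
    }
    sols <- if (is.null(sols)) m else join_solutions(sols, m)
    if (nrow(sols) == 0L) return(sols)
  }
  if (is.null(sols)) sols <- data.frame(row.names = 1L)[, 0, drop = FALSE]
  sols
}

match_rows_ground <- function(edf, pat) {
  keep <- edf$enc_s == pat$s & edf$p == pat$p & edf$enc_o == pat$o
  edf[keep, , drop = FALSE]
}

## ---- oracle: exhaustive nested triple scan ---------------------------

oracle_bgp <- function(graph, patterns) {
  edf <- enc_graph(graph)
  results <- list()
  recurse <- function(pi, binding) {
    if (pi > length(patterns)) {
      results[[length(results) + 1L]] <<- binding
      return(invisible(NULL))
    }
    pat <- patterns[[pi]]
    subst <- function(t) {
      if (is_var(t) && substring(t, 2L) %in% names(binding)) {
        binding[[substring(t, 2L)]]
      } else t
    }
    s <- subst(pat$s); p <- subst(pat$p); o <- subst(pat$o)
    for (r in seq_len(nrow(edf))) {
      if (!is_var(s) && edf$enc_s[r] != s) next
      if (!is_var(p)) {
        pp <- if (startsWith(p, "I")) substring(p, 2L) else p
        if (edf$p[r] != pp) next
      }
      if (!is_var(o) && edf$enc_o[r] != o) next
      b2 <- binding
      if (is_var(s)) b2[[substring(s, 2L)]] <- edf$enc_s[r]
      if (is_var(p)) b2[[substring(p, 2L)]] <- paste0("I", edf$p[r])
      if (is_var(o)) b2[[substring(o, 2L)]] <- edf$enc_o[r]
      # consistency for repeated variables within the pattern
      if (is_var(s) && is_var(o) && substring(s, 2L) == substring(o, 2L) &&
          edf$enc_s[r] != edf$enc_o[r]) next
      recurse(pi + 1L, b2)
    }
  }
  recurse(1L, list())
  if (length(results) == 0L) return(data.frame())
  vars <- unique(unlist(lapply(results, names)))
  out <- as.data.frame(do.call(rbind, lapply(results, function(b) {
    unlist(b)[vars]
  })), stringsAsFactors = FALSE, optional = TRUE)
  names(out) <- vars
  out
}

## ---- SPARQL text ------------------------------------------------------

#' Parse a SPARQL SELECT query (supported fragment)
#'
#' @param text Query text.
#' @return A list with `prefixes`, `distinct`, `projection` (variable
#'   names, or an aggregate spec), and `patterns`.
#' @keywords internal
parse_sparql <- function(text) {
  td <- ttl_tokenize_sparql(text)
  toks <- td$tok; lines <- td$line
  n <- length(toks)
  i <- 1L
  px <- character()
  perr <- function(i, msg) {
    where <- if (i <= n) paste0("near '", toks[i], "' (line ", lines[i], ")")
             else "at end of query"
    stop("SPARQL parse error ", where, ": ", msg, call. = FALSE)
  }
  upper <- function(t) toupper(t)

  while (i <= n && upper(toks[i]) == "PREFIX") {
    pn <- sub(":$", "", toks[i + 1L])
    iri_tok <- toks[i + 2L]
    if (!startsWith(iri_tok, "<")) perr(i + 2L, "expected namespace IRI")
    px[pn] <- normalize_iri(substr(iri_tok, 2L, nchar(iri_tok) - 1L))
    i <- i + 3L
  }
  if (i > n || upper(toks[i]) != "SELECT") perr(i, "expected SELECT")
  i <- i + 1L
  distinct <- FALSE
  if (i <= n && upper(toks[i]) == "DISTINCT") { distinct <- TRUE; i <- i + 1L }

  projection <- list(kind = "vars", vars = character(0))
  if (toks[i] == "*") {
    projection <- list(kind = "all")
    i <- i + 1L
  } else if (toks[i] == "(") {
    # (COUNT(DISTINCT ?v) AS ?alias)
    if (upper(toks[i + 1L]) != "COUNT" || toks[i + 2L] != "(") {
      perr(i + 1L, "only COUNT aggregates are supported")
    }
    j <- i + 3L
    agg_distinct <- FALSE
    if (upper(toks[j]) == "DISTINCT") { agg_distinct <- TRUE; j <- j + 1L }
    if (!startsWith(toks[j], "?")) perr(j, "expected variable in COUNT")
    v <- substring(toks[j], 2L)
    j <- j + 1L
    if (toks[j] != ")") perr(j, "expected ')'")
    j <- j + 1L
    if (upper(toks[j]) != "AS" || !startsWith(toks[j + 1L], "?")) {
      perr(j, "expected AS ?alias")
    }
    alias <- substring(toks[j + 1L], 2L)
    j <- j + 2L
    if (toks[j] != ")") perr(j, "expected ')'")
    projection <- list(kind = "count", var = v, distinct = agg_distinct,
                       alias = alias)
    i <- j + 1L
  } else {
    while (i <= n && startsWith(toks[i], "?")) {
      projection$vars <- c(projection$vars, substring(toks[i], 2L))
      i <- i + 1L
    }
    if (length(projection$vars) == 0L) perr(i, "empty projection")
  }

  if (i <= n && upper(toks[i]) == "WHERE") i <- i + 1L
  if (i > n || toks[i] != "{") perr(i, "expected '{'")
  i <- i + 1L

  resolve <- function(tok, at, role) {
    if (startsWith(tok, "?")) return(tok)
    if (startsWith(tok, "<")) {
      v <- normalize_iri(substr(tok, 2L, nchar(tok) - 1L))
      return(if (role == "p") v else paste0("I", v))
    }
    if (tok == "a") {
      return(if (role == "p") rdf("type") else paste0("I", rdf("type")))
    }
    if (startsWith(tok, "\"")) {
      lex <- unescape_lit(substr(tok, 2L, nchar(tok) - 1L))
      dt <- xsd("string")
      # datatype / lang attachment handled by caller via lookahead
      return(paste0("L", lex, "\x01", dt, "\x01"))
    }
    if (tok %in% c("true", "false")) {
      return(paste0("L", tok, "\x01", xsd("boolean"), "\x01"))
    }
    if (grepl("^[-+]?[0-9]", tok)) {
      dt <- if (grepl("\\.", tok)) xsd("decimal") else xsd("integer")
      return(paste0("L", tok, "\x01", dt, "\x01"))
    }
    if (grepl(":", tok)) {
      colon <- regexpr(":", tok, fixed = TRUE)
      pn <- substr(tok, 1L, colon - 1L)
      if (!pn %in% names(px)) perr(at, paste0("undeclared prefix '", pn, ":'"))
      v <- normalize_iri(paste0(px[[pn]], substring(tok, colon + 1L)))
      return(if (role == "p") v else paste0("I", v))
    }
    if (upper(tok) %in% c("FILTER", "OPTIONAL", "UNION", "GRAPH", "MINUS",
                          "BIND", "VALUES", "SERVICE")) {
      perr(at, paste0(upper(tok), " is not supported by this engine"))
    }
    perr(at, "unexpected token in graph pattern")
  }

  patterns <- list()
  repeat {
    if (i > n) perr(i, "unterminated graph pattern")
    if (toks[i] == "}") { i <- i + 1L; break }
    s <- resolve(toks[i], i, "s"); i <- i + 1L
    repeat {
      p <- resolve(toks[i], i, "p"); i <- i + 1L
      repeat {
        o_tok <- toks[i]
        o <- resolve(o_tok, i, "o"); i <- i + 1L
        # typed literal: "lex"^^<dt>
        if (startsWith(o_tok, "\"") && i <= n && toks[i] == "^^") {
          dt_enc <- resolve(toks[i + 1L], i + 1L, "p")
          o <- paste0("L", unescape_lit(substr(o_tok, 2L, nchar(o_tok) - 1L)),
                      "\x01", dt_enc, "\x01")
          i <- i + 2L
        }
        patterns[[length(patterns) + 1L]] <- bgp_pattern(s, p, o)
        if (i <= n && toks[i] == ",") { i <- i + 1L; next }
        break
      }
      if (i <= n && toks[i] == ";") {
        i <- i + 1L
        if (i <= n && toks[i] %in% c(".", "}")) break
        next
      }
      break
    }
    if (i <= n && toks[i] == ".") i <- i + 1L
  }
  list(prefixes = px, distinct = distinct, projection = projection,
       patterns = patterns)
}

# SPARQL shares the Turtle token syntax plus ?vars and bare keywords
ttl_tokenize_sparql <- function(text) {
  pat <- paste0("\\?[A-Za-z_][A-Za-z0-9_]*",
                "|\\*|\\(|\\)|\\{|\\}",
                "|[A-Za-z]+(?![A-Za-z0-9_:-])", # bare keywords
                "|", TTL_TOKEN)
  m <- gregexpr(pat, text, perl = TRUE)[[1]]
  if (m[1] == -1L) return(data.frame(tok = character(0), line = integer(0)))
  toks <- regmatches(text, gregexpr(pat, text, perl = TRUE))[[1]]
  starts <- as.integer(m)
  nl <- gregexpr("\n", text, fixed = TRUE)[[1]]
  nl <- if (nl[1] == -1L) integer(0) else as.integer(nl)
  line <- findInterval(starts, nl) + 1L
  keep <- !startsWith(toks, "#")
  data.frame(tok = toks[keep], line = line[keep], stringsAsFactors = FALSE)
}

#' Run a SPARQL SELECT query over a graph
#'
#' @param graph A `TripleGraph`.
#' @param sparql_text Query text (supported fragment: PREFIX, SELECT
#'   [DISTINCT], a COUNT(DISTINCT ?v) aggregate, basic graph patterns).
#' @return A data.frame (`ResultTable`): one column per projected
#'   variable, one row per solution. IRIs are returned as plain strings,
#'   blank nodes as `_:label`, literals as their lexical form.
#' @examples
#' g <- session_to_graph(sideraises_fixture()$session)
#' run_query(g, "
#'   PREFIX exergame: <http://purl.org/net/exergame/ns#>
#'   SELECT (COUNT(DISTINCT ?p) AS ?n) WHERE { ?s exergame:player ?p }")
#' @export
run_query <- function(graph, sparql_text) {
  stopifnot(is_triple_graph(graph))
  q <- parse_sparql(sparql_text)
  sols <- eval_bgp(graph, q$patterns)
  finish_select(sols, q)
}

finish_select <- function(sols, q) {
  proj <- q$projection
  if (proj$kind == "count") {
    col <- sols[[proj$var]]
    if (is.null(col)) col <- character(0)
    val <- if (isTRUE(proj$distinct)) length(unique(col)) else length(col)
    out <- data.frame(val)
    names(out) <- proj$alias
    return(out)
  }
  vars <- if (proj$kind == "all") names(sols) else proj$vars
  missing_vars <- setdiff(vars, names(sols))
  for (v in missing_vars) sols[[v]] <- character(nrow(sols))
  out <- sols[, vars, drop = FALSE]
  out[] <- lapply(out, dec_term)
  if (isTRUE(q$distinct)) out <- unique(out)
  rownames(out) <- NULL
  out
}

## ---- canned query: metric value at a given iteration ------------------

#' All values of a metric at one iteration, with player and date
#'
#' The dataset's canonical retrieval: for a metric and an iteration
#' index, return one row per session whose relation for that metric has an
#' `rdf:_i` member — or, for `iteration = 1`, a direct literal value (the
#' single-iteration encoding) — together with the session's player and
#' start date.
#'
#' @param graph A `TripleGraph`.
#' @param metric Metric IRI.
#' @param iteration Iteration index, >= 1.
#' @param terms Term registry.
#' @return A data.frame with columns `player`, `startDateTime`, `value`,
#'   ordered by (player, startDateTime, value).
#' @examples
#' g <- session_to_graph(sideraises_fixture()$session)
#' metric_at_iteration(g, "http://purl.org/net/exergame/metric#Success", 3)
#' @export
metric_at_iteration <- function(graph, metric, iteration,
                                terms = default_terms()) {
  stopifnot(is_triple_graph(graph))
  metric <- assert_iri(metric, "metric")
  if (!is.numeric(iteration) || length(iteration) != 1L || iteration < 1 ||
      iteration != as.integer(iteration)) {
    stop("iteration must be a positive integer", call. = FALSE)
  }
  iteration <- as.integer(iteration)
  p <- terms$properties
  base <- list(
    bgp_pattern("?sess", p[["player"]], "?player"),
    bgp_pattern("?sess", p[["startDateTime"]], "?startDateTime"),
    bgp_pattern("?sess", p[["result"]], "?res"),
    bgp_pattern("?res", p[["metricRelation"]], "?rel"),
    bgp_pattern("?rel", p[["metricName"]], paste0("I", metric))
  )
  seq_sols <- eval_bgp(graph, c(base, list(
    bgp_pattern("?rel", p[["metricValue"]], "?vnode"),
    bgp_pattern("?vnode", rdf(paste0("_", iteration)), "?value")
  )))
  rows <- decode_mai(seq_sols)
  if (iteration == 1L) {
    direct <- eval_bgp(graph, c(base, list(
      bgp_pattern("?rel", p[["metricValue"]], "?value")
    )))
    if (nrow(direct) > 0L) {
      direct <- direct[startsWith(direct$value, "L"), , drop = FALSE]
    }
    rows <- rbind(rows, decode_mai(direct))
  }
  rows[order(rows$player, rows$startDateTime, rows$value,
             method = "radix"), , drop = FALSE] -> rows
  rownames(rows) <- NULL
  rows
}

decode_mai <- function(sols) {
  if (is.null(sols) || nrow(sols) == 0L) {
    return(data.frame(player = character(0), startDateTime = character(0),
                      value = character(0), stringsAsFactors = FALSE))
  }
  data.frame(player = dec_term(sols$player),
             startDateTime = dec_term(sols$startDateTime),
             value = dec_term(sols$value), stringsAsFactors = FALSE)
}

#' Record-side oracle for [metric_at_iteration()]
#'
#' Pure scan over `SessionRecord`s, independent of the RDF path: reads
#' `observations[[metric]]$values[[iteration]]` directly.
#'
#' @param sessions List of `SessionRecord`s.
#' @param metric Metric IRI.
#' @param iteration Iteration index, >= 1.
#' @return Same shape and ordering as [metric_at_iteration()].
#' @export
oracle_metric_at_iteration <- function(sessions, metric, iteration) {
  metric <- assert_iri(metric, "metric")
  if (!is.numeric(iteration) || length(iteration) != 1L || iteration < 1) {
    stop("iteration must be a positive integer", call. = FALSE)
  }
  rows <- list(data.frame(player = character(0),
                          startDateTime = character(0),
                          value = character(0), stringsAsFactors = FALSE))
  for (s in sessions) {
    for (ob in s$observations) {
      if (ob$metric == metric && length(ob$values) >= iteration) {
        lx <- values_to_lexical(ob$values)
        rows[[length(rows) + 1L]] <- data.frame(
          player = s$player, startDateTime = s$start,
          value = lx$lex[iteration], stringsAsFactors = FALSE)
      }
    }
  }
  out <- do.call(rbind, rows)
  out <- out[order(out$player, out$startDateTime, out$value,
                   method = "radix"), , drop = FALSE]
  rownames(out) <- NULL
  out
}
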