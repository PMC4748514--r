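# TripleGraph: the universal exchange object.
#
# A graph is a list(triples = data.frame, prefixes = named character).
# The triples data.frame has columns
#   s, s_kind ("iri"|"blank"), p (always an IRI),
#   o, o_kind ("iri"|"blank"|"literal"), o_dt, o_lang
# with NA for absent datatype/language. Duplicate triples are removed on
# construction and on union, so the data.frame behaves as a set.

triple_columns <- c("s", "s_kind", "p", "o", "o_kind", "o_dt", "o_lang")

empty_triples <- function() {
  as.data.frame(
    setNames(rep(list(character(0)), length(triple_columns)), triple_columns),
    stringsAsFactors = FALSE
  )
}

#' Create an RDF triple graph
#'
#' @param prefixes Named character vector mapping prefix to namespace IRI;
#'   defaults to the ontology's full prefix table.
#' @return A `TripleGraph` object (empty).
#' @seealso [add_triple()], [graph_union()], [serialize_graph()]
#' @export
triple_graph <- function(prefixes = default_terms()$prefixes) {
  if (length(prefixes)) {
    stopifnot(!is.null(names(prefixes)), all(is_absolute_iri(prefixes)))
    if (anyDuplicated(names(prefixes)) || anyDuplicated(prefixes)) {
      stop("prefix map must be bijective", call. = FALSE)
    }
  }
  structure(list(triples = empty_triples(), prefixes = prefixes),
            class = "TripleGraph")
}

is_triple_graph <- function(x) inherits(x, "TripleGraph")

new_graph_from_df <- function(df, prefixes) {
  df <- unique(df[triple_columns])
  rownames(df) <- NULL
  structure(list(triples = df, prefixes = prefixes), class = "TripleGraph")
}

# Assemble a triples data.frame from parallel vectors (vector-recycled).
triples_df <- function(s, s_kind, p, o, o_kind,
                       o_dt = NA_character_, o_lang = NA_character_) {
  data.frame(s = s, s_kind = s_kind, p = p, o = o, o_kind = o_kind,
             o_dt = o_dt, o_lang = o_lang, stringsAsFactors = FALSE)
}

node_to_cols <- function(nd) {
  if (is.character(nd)) nd <- nd_iri(nd)
  nd
}

#' Add one triple to a graph
#'
#' Subject and object may be given as node lists built by the internal
#' constructors or, for IRIs, as plain strings. The predicate is always an
#' IRI string.
#'
#' @param graph A `TripleGraph`.
#' @param s Subject: IRI string or node list.
#' @param p Predicate IRI string.
#' @param o Object: IRI string, node list, or an R scalar (logical, numeric,
#'   character) which is converted to a typed literal.
#' @return The graph with the triple added (set semantics).
#' @export
add_triple <- function(graph, s, p, o) {
  stopifnot(is_triple_graph(graph))
  s <- node_to_cols(s)
  if (!is.list(o)) {
    if (is.character(o) && is_absolute_iri(o)) {
      o <- nd_iri(o)
    } else {
      lx <- values_to_lexical(o)
      o <- nd_lit(lx$lex, lx$dt)
    }
  }
  p <- assert_iri(p, "predicate")
  row <- triples_df(s$value, s$kind, p, o$value, o$kind, o$dt, o$lang)
  new_graph_from_df(rbind(graph$triples, row), graph$prefixes)
}

#' Number of triples in a graph
#' @param graph A `TripleGraph`.
#' @return Integer count.
#' @export
graph_size <- function(graph) nrow(graph$triples)

#' Union of triple graphs
#'
#' Set union of the triples; prefix maps are merged (identical mappings
#' collapse, conflicting prefix bindings are an error).
#'
#' @param ... `TripleGraph` objects, or a single list of them.
#' @return A `TripleGraph`.
#' @export
graph_union <- function(...) {
  gs <- list(...)
  if (length(gs) == 1L && !is_triple_graph(gs[[1]])) gs <- gs[[1]]
  stopifnot(length(gs) > 0L, all(vapply(gs, is_triple_graph, logical(1))))
  prefixes <- gs[[1]]$prefixes
  for (g in gs[-1]) {
    for (pn in names(g$prefixes)) {
      if (pn %in% names(prefixes)) {
        if (!identical(unname(prefixes[[pn]]), unname(g$prefixes[[pn]]))) {
          stop("conflicting binding for prefix '", pn, "'", call. = FALSE)
        }
      } else {
        prefixes[pn] <- g$prefixes[[pn]]
      }
    }
  }
  df <- do.call(rbind, lapply(gs, function(g) g$triples))
  new_graph_from_df(df, prefixes)
}

# Subset helper: rows of the triples data.frame matching fixed terms.
graph_match <- function(graph, s = NULL, p = NULL, o = NULL, o_kind = NULL) {
  df <- graph$triples
  keep <- rep(TRUE, nrow(df))
  if (!is.null(s)) keep <- keep & df$s == s
  if (!is.null(p)) keep <- keep & df$p == p
  if (!is.null(o)) keep <- keep & df$o == o
  if (!is.null(o_kind)) keep <- keep & df$o_kind == o_kind
  df[keep, , drop = FALSE]
}

#' @export
print.TripleGraph <- function(x, ...) {
  cat("<TripleGraph> ", graph_size(x), " triples, ",
      length(x$prefixes), " prefixes\n", sep = "")
  invisible(x)
}

#' @export
format.TripleGraph <- function(x, ...) {
  paste0("<TripleGraph: ", graph_size(x), " triples>")
}
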