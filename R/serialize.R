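# RDF serialization: Turtle, RDF/XML, N-Triples.
#
# The writers emit a plain, line-oriented style (one triple per statement
# in Turtle); the Turtle reader accepts the richer subset commonly found
# in hand-written files: ';' and ',' continuation, the 'a' keyword, bare
# numbers and booleans (including the upper-case TRUE/FALSE that appear in
# the published example table), comments, and @prefix/PREFIX directives.
# N-Triples is read through the Turtle reader (it is a syntactic subset).

SUPPORTED_FORMATS <- c("turtle", "rdfxml", "ntriples")

#' Serialize a graph
#'
#' @param graph A `TripleGraph`.
#' @param format One of `"turtle"`, `"rdfxml"`, `"ntriples"`.
#' @return A single character string with the serialized document.
#' @seealso [parse_graph()], [canonicalize()]
#' @export
serialize_graph <- function(graph, format = c("turtle", "rdfxml", "ntriples")) {
  format <- match.arg(format)
  stopifnot(is_triple_graph(graph))
  switch(format,
         turtle = ttl_serialize(graph),
         ntriples = nt_serialize(graph),
         rdfxml = rdfxml_serialize(graph))
}

#' Parse an RDF document
#'
#' @param text Document text (single string) or a file path.
#' @param format One of `"turtle"`, `"rdfxml"`, `"ntriples"`.
#' @param prefixes Extra prefix bindings to seed the parser with.
#' @return A `TripleGraph`. The exergame `purl.com` namespace misprint is
#'   normalized to `purl.org` on input.
#' @export
parse_graph <- function(text, format = c("turtle", "rdfxml", "ntriples"),
                        prefixes = character()) {
  format <- match.arg(format)
  if (length(text) == 1L && !grepl("[\n<@{]", text) && file.exists(text)) {
    text <- paste(readLines(text, warn = FALSE), collapse = "\n")
  }
  switch(format,
         turtle = ttl_parse(text, prefixes),
         ntriples = ttl_parse(text, prefixes),
         rdfxml = rdfxml_parse(text))
}

# Infer a serialization format from a file extension.
format_from_path <- function(path) {
  switch(tolower(sub(".*\\.", "", path)),
         ttl = "turtle", turtle = "turtle",
         rdf = "rdfxml", xml = "rdfxml", owl = "rdfxml",
         nt = "ntriples", ntriples = "ntriples",
         stop("cannot infer RDF format from path: ", path, call. = FALSE))
}

## ---- N-Triples --------------------------------------------------------

escape_lit <- function(x) {
  x <- gsub("\\", "\\\\", x, fixed = TRUE)
  x <- gsub("\"", "\\\"", x, fixed = TRUE)
  x <- gsub("\n", "\\n", x, fixed = TRUE)
  x <- gsub("\r", "\\r", x, fixed = TRUE)
  gsub("\t", "\\t", x, fixed = TRUE)
}

unescape_lit <- function(x) {
  # reverse of escape_lit; processed sequentially over escape pairs
  vapply(x, function(s) {
    out <- character(0)
    parts <- strsplit(s, "", fixed = TRUE)[[1]]
    i <- 1L
    while (i <= length(parts)) {
      ch <- parts[i]
      if (ch == "\\" && i < length(parts)) {
        nxt <- parts[i + 1L]
        out <- c(out, switch(nxt, n = "\n", r = "\r", t = "\t",
                             "\"" = "\"", "\\" = "\\", nxt))
        i <- i + 2L
      } else {
        out <- c(out, ch)
        i <- i + 1L
      }
    }
    paste(out, collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

term_nt <- function(value, kind, dt = NA_character_, lang = NA_character_) {
  ifelse(kind == "iri", paste0("<", value, ">"),
  ifelse(kind == "blank", paste0("_:", value),
         paste0("\"", escape_lit(value), "\"",
                ifelse(!is.na(lang), paste0("@", lang),
                       ifelse(is.na(dt) | dt == xsd("string"), "",
                              paste0("^^<", dt, ">"))))))
}

nt_lines <- function(df) {
  if (nrow(df) == 0L) return(character(0))
  paste(term_nt(df$s, df$s_kind), paste0("<", df$p, ">"),
        term_nt(df$o, df$o_kind, df$o_dt, df$o_lang), ".")
}

nt_serialize <- function(graph) {
  lines <- nt_lines(graph$triples)
  if (length(lines) == 0L) return("")
  paste0(paste(lines, collapse = "\n"), "\n")
}

## ---- Turtle writer ----------------------------------------------------

LOCAL_OK <- "^[A-Za-z_][A-Za-z0-9_-]*$"

pname_or_iri <- function(iris, prefixes) {
  if (length(prefixes) == 0L) return(paste0("<", iris, ">"))
  ns <- unname(prefixes); pn <- names(prefixes)
  ord <- order(nchar(ns), decreasing = TRUE)  # longest namespace wins
  ns <- ns[ord]; pn <- pn[ord]
  out <- paste0("<", iris, ">")
  done <- rep(FALSE, length(iris))
  for (i in seq_along(ns)) {
    hit <- !done & startsWith(iris, ns[i])
    if (!any(hit)) next
    local <- substring(iris[hit], nchar(ns[i]) + 1L)
    ok <- grepl(LOCAL_OK, local)
    idx <- which(hit)[ok]
    out[idx] <- paste0(pn[i], ":", local[ok])
    done[idx] <- TRUE
  }
  out
}

ttl_serialize <- function(graph) {
  px <- graph$prefixes
  header <- if (length(px)) {
    paste0("@prefix ", names(px), ": <", unname(px), "> .",
           collapse = "\n")
  } else ""
  df <- graph$triples
  if (nrow(df) == 0L) return(paste0(header, "\n"))
  s <- ifelse(df$s_kind == "iri", pname_or_iri(df$s, px),
              paste0("_:", df$s))
  p <- ifelse(df$p == rdf("type"), "a", pname_or_iri(df$p, px))
  o <- character(nrow(df))
  is_lit <- df$o_kind == "literal"
  o[!is_lit] <- ifelse(df$o_kind[!is_lit] == "iri",
                       pname_or_iri(df$o[!is_lit], px),
                       paste0("_:", df$o[!is_lit]))
  if (any(is_lit)) {
    dt <- df$o_dt[is_lit]
    suffix <- ifelse(!is.na(df$o_lang[is_lit]),
                     paste0("@", df$o_lang[is_lit]),
                     ifelse(is.na(dt) | dt == xsd("string"), "",
                            paste0("^^", pname_or_iri(ifelse(is.na(dt), "", dt), px))))
    o[is_lit] <- paste0("\"", escape_lit(df$o[is_lit]), "\"", suffix)
  }
  paste0(header, "\n\n", paste(paste(s, p, o, "."), collapse = "\n"), "\n")
}

## ---- Turtle reader ----------------------------------------------------

TTL_TOKEN <- paste0(
  "<[^<>\"{}|^`\\\\[:space:]]*>",
  "|\"(?:[^\"\\\\]|\\\\.)*\"",
  "|#[^\n]*",
  "|@prefix\\b|@base\\b|\\bPREFIX\\b|\\bBASE\\b",
  "|\\^\\^",
  "|@[A-Za-z][A-Za-z0-9-]*",
  "|_:[A-Za-z0-9][A-Za-z0-9_.-]*",
  "|[A-Za-z][A-Za-z0-9_.-]*:[A-Za-z0-9_][A-Za-z0-9_-]*",
  "|[A-Za-z][A-Za-z0-9_.-]*:",
  "|:[A-Za-z0-9_][A-Za-z0-9_-]*",
  "|[-+]?[0-9]+(?:\\.[0-9]+)?",
  "|\\btrue\\b|\\bfalse\\b|\\bTRUE\\b|\\bFALSE\\b|\\ba\\b",
  "|:|[.;,\\[\\]()]"
)

ttl_tokenize <- function(text) {
  m <- gregexpr(TTL_TOKEN, text, perl = TRUE)[[1]]
  if (m[1] == -1L) return(data.frame(tok = character(0), line = integer(0)))
  toks <- regmatches(text, gregexpr(TTL_TOKEN, text, perl = TRUE))[[1]]
  starts <- as.integer(m)
  nl <- gregexpr("\n", text, fixed = TRUE)[[1]]
  nl <- if (nl[1] == -1L) integer(0) else as.integer(nl)
  line <- findInterval(starts, nl) + 1L
  keep <- !startsWith(toks, "#")
  data.frame(tok = toks[keep], line = line[keep], stringsAsFactors = FALSE)
}

ttl_parse <- function(text, prefixes = character()) {
  td <- ttl_tokenize(text)
  toks <- td$tok; lines <- td$line
  n <- length(toks)
  px <- prefixes
  rows <- list()
  i <- 1L

  perr <- function(i, msg) {
    where <- if (i <= n) paste0("near '", toks[i], "' (line ", lines[i], ")")
             else "at end of input"
    stop("RDF parse error ", where, ": ", msg, call. = FALSE)
  }
  expect <- function(i, what) {
    if (i > n || toks[i] != what) perr(i, paste0("expected '", what, "'"))
    i + 1L
  }
  expand_pname <- function(tok, at) {
    colon <- regexpr(":", tok, fixed = TRUE)
    pn <- substr(tok, 1L, colon - 1L)
    local <- substring(tok, colon + 1L)
    if (!pn %in% names(px) && !(pn == "" && "" %in% names(px))) {
      perr(at, paste0("undeclared prefix '", pn, ":'"))
    }
    normalize_iri(paste0(px[[pn]], local))
  }
  # returns list(node, next_index)
  read_term <- function(i, role) {
    if (i > n) perr(i, "unexpected end of input")
    tok <- toks[i]
    if (startsWith(tok, "<")) {
      v <- substr(tok, 2L, nchar(tok) - 1L)
      if (!is_absolute_iri(v)) perr(i, paste0("relative or malformed IRI <", v, ">"))
      return(list(node = nd_iri(v), i = i + 1L))
    }
    if (startsWith(tok, "_:")) {
      return(list(node = nd_blank(blank_label(substring(tok, 3L))), i = i + 1L))
    }
    if (startsWith(tok, "\"")) {
      lex <- unescape_lit(substr(tok, 2L, nchar(tok) - 1L))
      i <- i + 1L
      if (i <= n && toks[i] == "^^") {
        dtm <- read_term(i + 1L, "datatype")
        if (dtm$node$kind != "iri") perr(i + 1L, "datatype must be an IRI")
        return(list(node = nd_lit(lex, dtm$node$value), i = dtm$i))
      }
      if (i <= n && grepl("^@[A-Za-z]", toks[i]) &&
          !toks[i] %in% c("@prefix", "@base")) {
        return(list(node = nd_lit(lex, NA_character_,
                                  substring(toks[i], 2L)), i = i + 1L))
      }
      return(list(node = nd_lit(lex), i = i))
    }
    if (tok == "a" && role == "predicate") {
      return(list(node = nd_iri(rdf("type")), i = i + 1L))
    }
    if (tok %in% c("true", "false", "TRUE", "FALSE")) {
      return(list(node = nd_lit(tolower(tok), xsd("boolean")), i = i + 1L))
    }
    if (grepl("^[-+]?[0-9]", tok)) {
      dt <- if (grepl("\\.", tok)) xsd("decimal") else xsd("integer")
      return(list(node = nd_lit(tok, dt), i = i + 1L))
    }
    if (tok %in% c("[", "]", "(", ")")) {
      perr(i, "blank-node property lists / collections are not supported")
    }
    if (grepl(":", tok, fixed = TRUE) || tok == ":") {
      return(list(node = nd_iri(expand_pname(tok, i)), i = i + 1L))
    }
    perr(i, "unexpected token")
  }

  while (i <= n) {
    tok <- toks[i]
    if (tok %in% c("@prefix", "PREFIX")) {
      pn_tok <- toks[i + 1L]
      if (is.na(pn_tok) || !grepl(":$", pn_tok) && pn_tok != ":") {
        perr(i + 1L, "expected prefix name")
      }
      pn <- sub(":$", "", pn_tok)
      iri_tok <- toks[i + 2L]
      if (is.na(iri_tok) || !startsWith(iri_tok, "<")) {
        perr(i + 2L, "expected namespace IRI")
      }
      px[pn] <- normalize_iri(substr(iri_tok, 2L, nchar(iri_tok) - 1L))
      i <- i + 3L
      if (tok == "@prefix") i <- expect(i, ".")
      next
    }
    if (tok %in% c("@base", "BASE")) {
      perr(i, "@base is not supported; use absolute IRIs")
    }
    subj <- read_term(i, "subject")
    if (subj$node$kind == "literal") perr(i, "literal cannot be a subject")
    i <- subj$i
    repeat {
      pred <- read_term(i, "predicate")
      if (pred$node$kind != "iri") perr(i, "predicate must be an IRI")
      i <- pred$i
      repeat {
        obj <- read_term(i, "object")
        i <- obj$i
        rows[[length(rows) + 1L]] <- triples_df(
          subj$node$value, subj$node$kind, pred$node$value,
          obj$node$value, obj$node$kind, obj$node$dt, obj$node$lang)
        if (i <= n && toks[i] == ",") { i <- i + 1L; next }
        break
      }
      if (i <= n && toks[i] == ";") {
        i <- i + 1L
        # tolerate trailing ';' before '.'
        if (i <= n && toks[i] == ".") break
        next
      }
      break
    }
    i <- expect(i, ".")
  }
  df <- if (length(rows)) do.call(rbind, rows) else empty_triples()
  base_px <- default_terms()$prefixes
  keep <- px[!(names(px) %in% "") ]
  # only bijective prefix subset is retained on the graph
  keep <- keep[!duplicated(unname(keep))]
  new_graph_from_df(df, keep)
}

## ---- RDF/XML ----------------------------------------------------------

split_iri <- function(iri) {
  # split at the last '#' or '/' such that the local part is an XML NCName
  m <- regexpr("[A-Za-z_][A-Za-z0-9_.-]*$", iri)
  if (m == -1L || m == 1L) return(NULL)
  list(ns = substr(iri, 1L, m - 1L), local = substring(iri, m))
}

rdfxml_serialize <- function(graph) {
  df <- graph$triples
  px <- graph$prefixes
  # every predicate namespace must have a prefix; invent for unknowns
  pred_ns <- unique(vapply(unique(df$p), function(p) {
    sp <- split_iri(p)
    if (is.null(sp)) stop("predicate IRI not splittable for RDF/XML: ", p,
                          call. = FALSE)
    sp$ns
  }, character(1)))
  missing_ns <- setdiff(pred_ns, unname(px))
  if (length(missing_ns)) {
    extra <- setNames(missing_ns, paste0("n", seq_along(missing_ns)))
    px <- c(px, extra)
  }
  if (!NS_RDF %in% unname(px)) px <- c(px, rdf = NS_RDF)
  ns_to_prefix <- setNames(names(px), unname(px))
  rdfpn <- ns_to_prefix[[NS_RDF]]

  decls <- paste0("xmlns:", names(px), "=\"", unname(px), "\"",
                  collapse = " ")
  doc <- xml2::read_xml(paste0("<", rdfpn, ":RDF ", decls, "/>"))

  key <- paste0(df$s_kind, "\x01", df$s)
  for (k in unique(key)) {
    rows <- df[key == k, , drop = FALSE]
    desc <- xml2::xml_add_child(doc, paste0(rdfpn, ":Description"))
    if (rows$s_kind[1] == "iri") {
      xml2::xml_set_attr(desc, paste0(rdfpn, ":about"), rows$s[1])
    } else {
      xml2::xml_set_attr(desc, paste0(rdfpn, ":nodeID"), rows$s[1])
    }
    for (j in seq_len(nrow(rows))) {
      sp <- split_iri(rows$p[j])
      el <- xml2::xml_add_child(
        desc, paste0(ns_to_prefix[[sp$ns]], ":", sp$local))
      if (rows$o_kind[j] == "iri") {
        xml2::xml_set_attr(el, paste0(rdfpn, ":resource"), rows$o[j])
      } else if (rows$o_kind[j] == "blank") {
        xml2::xml_set_attr(el, paste0(rdfpn, ":nodeID"), rows$o[j])
      } else {
        xml2::xml_text(el) <- rows$o[j]
        if (!is.na(rows$o_lang[j])) {
          xml2::xml_set_attr(el, "xml:lang", rows$o_lang[j])
        } else if (!is.na(rows$o_dt[j]) && rows$o_dt[j] != xsd("string")) {
          xml2::xml_set_attr(el, paste0(rdfpn, ":datatype"), rows$o_dt[j])
        }
      }
    }
  }
  as.character(doc)
}

rdfxml_parse <- function(text) {
  doc <- tryCatch(xml2::read_xml(text),
                  error = function(e) stop("RDF/XML parse error: ",
                                           conditionMessage(e), call. = FALSE))
  nsmap <- xml2::xml_ns(doc)
  # xml_ns gives prefix -> uri (prefixes may be doc-local, e.g. d1)
  rdf_attr <- function(node, local) {
    # whatever prefix the document binds to the rdf namespace
    v <- NA_character_
    for (pn in names(nsmap)[nsmap == NS_RDF]) {
      v <- xml2::xml_attr(node, paste0(pn, ":", local), ns = nsmap)
      if (!is.na(v)) break
    }
    v
  }
  rows <- list()
  bcount <- 0L
  descs <- xml2::xml_find_all(doc, "./*")
  for (desc in descs) {
    about <- rdf_attr(desc, "about")
    nodeid <- rdf_attr(desc, "nodeID")
    if (!is.na(about)) {
      s <- normalize_iri(about); s_kind <- "iri"
    } else if (!is.na(nodeid)) {
      s <- blank_label(nodeid); s_kind <- "blank"
    } else {
      bcount <- bcount + 1L
      s <- paste0("genx", bcount); s_kind <- "blank"
    }
    # typed node element (e.g. <exergame:Game rdf:about=...>)
    qn <- xml2::xml_name(desc, ns = nsmap)
    if (!qn %in% c("rdf:Description") &&
        !grepl(":Description$", qn)) {
      pn <- sub(":.*", "", qn)
      cls <- paste0(nsmap[[pn]], sub(".*:", "", qn))
      if (cls != paste0(NS_RDF, "RDF")) {
        rows[[length(rows) + 1L]] <- triples_df(
          s, s_kind, rdf("type"), normalize_iri(cls), "iri")
      }
    }
    for (prop in xml2::xml_find_all(desc, "./*")) {
      qn <- xml2::xml_name(prop, ns = nsmap)
      pn <- sub(":.*", "", qn)
      if (!pn %in% names(nsmap)) {
        stop("RDF/XML parse error: unresolvable property element '", qn, "'",
             call. = FALSE)
      }
      p <- normalize_iri(paste0(nsmap[[pn]], sub(".*:", "", qn)))
      res <- rdf_attr(prop, "resource")
      onid <- rdf_attr(prop, "nodeID")
      if (!is.na(res)) {
        rows[[length(rows) + 1L]] <- triples_df(
          s, s_kind, p, normalize_iri(res), "iri")
      } else if (!is.na(onid)) {
        rows[[length(rows) + 1L]] <- triples_df(
          s, s_kind, p, blank_label(onid), "blank")
      } else {
        dt <- rdf_attr(prop, "datatype")
        lang <- xml2::xml_attr(prop, "lang")
        lex <- xml2::xml_text(prop)
        rows[[length(rows) + 1L]] <- triples_df(
          s, s_kind, p, lex, "literal",
          if (is.na(dt)) xsd("string") else normalize_iri(dt),
          if (is.na(lang)) NA_character_ else lang)
      }
    }
  }
  px <- nsmap[!grepl("^d[0-9]+$", names(nsmap))]
  px <- px[names(px) != "xml"]
  px <- setNames(normalize_iri(unname(px)), names(px))
  px <- px[!duplicated(unname(px))]
  df <- if (length(rows)) do.call(rbind, rows) else empty_triples()
  new_graph_from_df(df, px)
}
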