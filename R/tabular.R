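# R2RML-inspired conversion of legacy tabular game logs to session
# records. Full R2RML is out of scope: the dialect implemented here maps a
# single long-format table (one row per session x metric x iteration) to
# the ontology, which covers the relational exports the deployment
# produced. Wide-format logs are a documented non-goal.

MANDATORY_ROLES <- c("session_id", "player_id", "game_iri", "start", "end",
                     "metric", "iteration", "value")
OPTIONAL_ROLES <- c("site_iri", "unit")

#' Default column mapping
#'
#' The mapping for the session-log schema written by [sessions_to_log()],
#' with explicit datatypes for the three standard metrics.
#'
#' @return A `MappingSpec`.
#' @export
default_mapping <- function() {
  mapping_spec(
    columns = setNames(as.list(c(MANDATORY_ROLES, OPTIONAL_ROLES)),
                       c(MANDATORY_ROLES, OPTIONAL_ROLES)),
    iri_bases = list(player = FFA_RES),
    datatypes = list2env3(list(
      list(metric = paste0(NS_METRIC, "Success"), type = "boolean"),
      list(metric = paste0(NS_METRIC, "ReactionTime"), type = "decimal"),
      list(metric = paste0(NS_METRIC, "GoalTime"), type = "decimal")
    ))
  )
}

list2env3 <- function(entries) {
  setNames(lapply(entries, `[[`, "type"),
           vapply(entries, `[[`, character(1), "metric"))
}

#' Construct a tabular-to-RDF mapping
#'
#' @param columns Named list role -> column name. Mandatory roles:
#'   session_id, player_id, game_iri, start, end, metric, iteration,
#'   value. Optional: site_iri, unit.
#' @param iri_bases Named list role -> base IRI; `player` is used to mint
#'   player IRIs from opaque identifiers (anonymity is preserved: the id
#'   is used verbatim, never enriched).
#' @param datatypes Optional named list metric IRI -> one of `"boolean"`,
#'   `"integer"`, `"decimal"`, `"string"`; unmapped metrics are inferred
#'   from the value lexicals.
#' @return A `MappingSpec`.
#' @export
mapping_spec <- function(columns, iri_bases = list(), datatypes = list()) {
  stopifnot(is.list(columns))
  missing_roles <- setdiff(MANDATORY_ROLES, names(columns))
  if (length(missing_roles)) {
    stop("mapping is missing mandatory column binding(s): ",
         paste(missing_roles, collapse = ", "), call. = FALSE)
  }
  for (cn in columns) stopifnot(is.character(cn), nzchar(cn))
  if (!is.null(datatypes) && length(datatypes)) {
    bad <- !unlist(datatypes) %in% c("boolean", "integer", "decimal", "string")
    if (any(bad)) {
      stop("unknown datatype in mapping: ",
           paste(unlist(datatypes)[bad], collapse = ", "), call. = FALSE)
    }
  }
  structure(list(columns = columns, iri_bases = iri_bases,
                 datatypes = datatypes),
            class = "MappingSpec")
}

#' Load a mapping from YAML
#'
#' @param document Path to a YAML document, or an already-parsed list,
#'   with keys `columns`, `iri_bases`, `datatypes` mirroring
#'   [mapping_spec()].
#' @return A validated `MappingSpec`.
#' @export
load_mapping <- function(document) {
  doc <- if (is.character(document)) yaml::read_yaml(document) else document
  if (!is.list(doc) || is.null(doc$columns)) {
    stop("mapping document must contain a 'columns' block", call. = FALSE)
  }
  mapping_spec(columns = doc$columns,
               iri_bases = if (is.null(doc$iri_bases)) list() else doc$iri_bases,
               datatypes = if (is.null(doc$datatypes)) list() else doc$datatypes)
}

#' Write a mapping to YAML
#'
#' @param mapping A `MappingSpec`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_mapping <- function(mapping, path) {
  stopifnot(inherits(mapping, "MappingSpec"))
  yaml::write_yaml(list(columns = mapping$columns,
                        iri_bases = mapping$iri_bases,
                        datatypes = mapping$datatypes), path)
  invisible(path)
}

convert_values <- function(lex, type) {
  switch(type,
         boolean = lexical_to_values(lex, xsd("boolean")),
         integer = as.integer(lex),
         decimal = as.numeric(lex),
         string = as.character(lex),
         stop("unknown datatype: ", type, call. = FALSE))
}

infer_type <- function(lex) {
  if (all(tolower(lex) %in% c("true", "false"))) return("boolean")
  if (suppressWarnings(!anyNA(as.numeric(lex)))) {
    if (all(!grepl("[.eE]", lex))) return("integer")
    return("decimal")
  }
  "string"
}

#' Convert tabular log rows to session records
#'
#' Rows are grouped by session identifier (in first-appearance order);
#' within a session, each metric's values are ordered by the iteration
#' column, which must run 1..n without duplicates or gaps. Player IRIs
#' are minted as `iri_bases$player + player_id` unless the id is already
#' an absolute IRI.
#'
#' @param rows A data.frame (e.g. from `read.csv(..., colClasses =
#'   "character")`) whose columns satisfy the mapping.
#' @param mapping A `MappingSpec`.
#' @return List of `SessionRecord`s.
#' @examples
#' log <- sessions_to_log(list(sideraises_fixture()$session))
#' length(rows_to_sessions(log, default_mapping()))  # 1
#' @export
rows_to_sessions <- function(rows, mapping = default_mapping()) {
  stopifnot(is.data.frame(rows), inherits(mapping, "MappingSpec"))
  cols <- mapping$columns
  need <- unlist(cols[MANDATORY_ROLES])
  absent <- setdiff(need, names(rows))
  if (length(absent)) {
    stop("input rows lack mapped column(s): ", paste(absent, collapse = ", "),
         call. = FALSE)
  }
  if (nrow(rows) == 0L) return(list())
  col <- function(role, df = rows) {
    cn <- cols[[role]]
    if (is.null(cn) || !cn %in% names(df)) return(NULL)
    as.character(df[[cn]])
  }
  sids <- col("session_id")
  groups <- split(seq_len(nrow(rows)), factor(sids, levels = unique(sids)))

  lapply(names(groups), function(sid) {
    g <- rows[groups[[sid]], , drop = FALSE]
    one <- function(role, what = role) {
      v <- unique(col(role, g))
      v <- v[!is.na(v) & nzchar(v)]
      if (length(v) > 1L) {
        stop("session '", sid, "' has conflicting ", what, " values",
             call. = FALSE)
      }
      if (length(v) == 0L) NULL else v
    }
    player_id <- one("player_id")
    player <- if (is_absolute_iri(player_id)) player_id else {
      base <- mapping$iri_bases$player
      if (is.null(base)) {
        stop("mapping has no iri_bases$player to mint player IRIs",
             call. = FALSE)
      }
      paste0(base, player_id)
    }
    site <- one("site_iri")
    metrics_in_order <- unique(col("metric", g))
    obs <- lapply(metrics_in_order, function(m) {
      mg <- g[col("metric", g) == m, , drop = FALSE]
      it <- suppressWarnings(as.integer(col("iteration", mg)))
      if (anyNA(it) || any(it < 1L)) {
        stop("session '", sid, "', metric '", m,
             "': iteration column must hold positive integers",
             call. = FALSE)
      }
      if (anyDuplicated(it)) {
        stop("duplicate (session, metric, iteration): ('", sid, "', '", m,
             "', ", it[duplicated(it)][1], ")", call. = FALSE)
      }
      mg <- mg[order(it), , drop = FALSE]
      it <- sort(it)
      if (!identical(it, seq_along(it))) {
        stop("session '", sid, "', metric '", m,
             "': iterations not contiguous from 1 (found ",
             paste(it, collapse = ","), ")", call. = FALSE)
      }
      lex <- col("value", mg)
      type <- mapping$datatypes[[normalize_iri(m)]]
      if (is.null(type)) type <- infer_type(lex)
      unit <- {
        u <- unique(col("unit", mg))
        u <- u[!is.na(u) & nzchar(u)]
        if (length(u)) u[1] else NULL
      }
      metric_observation(m, convert_values(lex, type), unit = unit)
    })
    session_record(session_id = sid, game = one("game_iri"),
                   player = player, start = one("start"), end = one("end"),
                   observations = obs, site = site)
  })
}

#' Read a session log CSV and convert to records
#'
#' @param path CSV file (RFC-4180, UTF-8, header row).
#' @param mapping A `MappingSpec`.
#' @return List of `SessionRecord`s.
#' @export
sessions_from_csv <- function(path, mapping = default_mapping()) {
  rows <- utils::read.csv(path, colClasses = "character",
                          check.names = FALSE, fileEncoding = "UTF-8")
  rows_to_sessions(rows, mapping)
}

#' Write a session log CSV
#'
#' @param sessions List of `SessionRecord`s.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
sessions_to_csv <- function(sessions, path) {
  utils::write.csv(sessions_to_log(sessions), path, row.names = FALSE,
                   quote = TRUE, fileEncoding = "UTF-8")
  invisible(path)
}
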