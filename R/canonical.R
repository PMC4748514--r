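# Deterministic graph canonicalization.
#
# Blank nodes carry no global identity, so two serializations of the same
# data may differ only in their labels. canonicalize() relabels blank
# nodes by iterative signature refinement: each blank node's signature is
# the sorted multiset of its incident triples with neighbouring blank
# nodes replaced by their previous-round signatures. For the tree-shaped
# blank structures this ontology emits (session -> result -> relation ->
# sequence) refinement separates all nodes in a few rounds; if a
# signature class remains ambiguous (automorphic subgraphs, e.g. two
# byte-identical sessions) one member is individualized deterministically
# and refinement resumes, which yields a stable canonical text in those
# cases too.

# locale-independent (C collation) character sort, so canonical text is
# byte-identical across platforms
csort <- function(x) x[order(x, method = "radix")]
csort_order <- function(x) order(x, method = "radix")

#' Canonical N-Triples form of a graph
#'
#' Produces sorted N-Triples with deterministic blank-node labels
#' (`_:b1`, `_:b2`, ...): identical output for any two graphs that differ
#' only in blank-node labels, and stable across runs. Enables bit-exact
#' graph comparison.
#'
#' @param graph A `TripleGraph`.
#' @return A single string: sorted canonical N-Triples, `""` for an empty
#'   graph.
#' @seealso [graphs_isomorphic()]
#' @export
canonicalize <- function(graph) {
  stopifnot(is_triple_graph(graph))
  df <- graph$triples
  if (nrow(df) == 0L) return("")
  blanks <- unique(c(df$s[df$s_kind == "blank"], df$o[df$o_kind == "blank"]))
  if (length(blanks) == 0L) {
    return(paste0(paste(csort(nt_lines(df)), collapse = "\n"), "\n"))
  }

  # ground term strings computed once
  o_ground <- term_nt(df$o, df$o_kind, df$o_dt, df$o_lang)
  s_blank <- df$s_kind == "blank"
  o_blank <- df$o_kind == "blank"
  idx_s <- split(which(s_blank), df$s[s_blank])          # triples with b as subject
  idx_o <- split(which(o_blank), df$o[o_blank])          # triples with b as object

  sig <- setNames(rep("", length(blanks)), blanks)
  marks <- setNames(rep("", length(blanks)), blanks)
  refine <- function(sig) {
    vapply(blanks, function(b) {
      is_ <- idx_s[[b]]
      out <- character(0)
      if (!is.null(is_)) {
        oo <- ifelse(o_blank[is_], paste0("[", sig[df$o[is_]], "]"),
                     o_ground[is_])
        out <- paste0("S<", df$p[is_], ">", oo)
      }
      io <- idx_o[[b]]
      if (!is.null(io)) {
        ss <- ifelse(s_blank[io], paste0("[", sig[df$s[io]], "]"),
                     paste0("<", df$s[io], ">"))
        out <- c(out, paste0("O<", df$p[io], ">", ss))
      }
      paste0(marks[b], "\x04",
             paste(csort(out), collapse = "\x02"))
    }, character(1))
  }

  n_classes <- 0L
  for (round in seq_len(2L * length(blanks) + 10L)) {
    sig <- refine(sig)
    k <- length(unique(sig))
    if (k == length(blanks)) break
    if (k == n_classes) {
      # stable but ambiguous: individualize one member of the smallest
      # ambiguous signature class, then resume refinement
      amb <- csort(sig[duplicated(sig) | duplicated(sig, fromLast = TRUE)])[1]
      pick <- csort(names(sig)[sig == amb])[1]
      marks[pick] <- paste0(marks[pick], "!")
      n_classes <- 0L
    } else {
      n_classes <- k
    }
  }
  srt <- sig[csort_order(sig)]
  canon <- setNames(paste0("b", seq_along(blanks)), names(srt))

  df$s[s_blank] <- canon[df$s[s_blank]]
  df$o[o_blank] <- canon[df$o[o_blank]]
  paste0(paste(csort(nt_lines(df)), collapse = "\n"), "\n")
}

#' Are two graphs isomorphic?
#'
#' Graph equality up to blank-node relabelling, via [canonicalize()].
#'
#' @param g1,g2 `TripleGraph` objects.
#' @return `TRUE` or `FALSE`.
#' @export
graphs_isomorphic <- function(g1, g2) {
  identical(canonicalize(g1), canonicalize(g2))
}
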