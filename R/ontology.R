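# OBO parsing and is_a graph operations.
#
# An `ontology` is a plain list of parallel, id-named structures (in the
# style of ontologyIndex): name, synonyms, parents, children, obsolete,
# xrefs, intersection_of (raw lines, consumed by the Entity-Quality layer).
# Only [Term] stanzas are interpreted; only is_a edges drive traversal;
# obsolete terms are kept for id lookup but excluded from closures.

#' Parse an OBO 1.2 flat file into an ontology
#'
#' Interprets only `[Term]` stanzas and the tags `id`, `name`, `synonym`,
#' `is_a`, `xref`, `is_obsolete` and `intersection_of`; every other tag and
#' stanza type is ignored. Trailing `{...}` qualifiers and `!` comments are
#' stripped; synonym scope markers (EXACT, BROAD, ...) are discarded.
#' `intersection_of` lines are retained verbatim for
#' [logical_definitions()]. is_a lines on obsolete terms are dropped so that
#' obsolete terms never participate in traversal.
#'
#' @param x path to an OBO file, or a character vector of OBO lines.
#' @return an object of class `ontology` with components `id` (character
#'   vector of CURIEs), `name`, `namespace` (CURIE prefix), `obsolete`
#'   (named logical), `synonyms`, `xrefs`, `parents`, `children`,
#'   `intersection_of` (named lists) and `roots` (non-obsolete ids with no
#'   parents).
#' @details Duplicate ids, is_a references to unknown ids and cycles in the
#'   is_a graph are rejected with errors naming the offending ids.
#' @examples
#' ont <- parse_obo(c("[Term]", "id: A:1", "name: root",
#'                    "[Term]", "id: A:2", "name: child", "is_a: A:1"))
#' ont$roots
#' @export
parse_obo <- function(x) {
  lines <- if (length(x) == 1L && file.exists(x)) {
    readLines(x, encoding = "UTF-8")
  } else {
    as.character(x)
  }
  lines <- trim(lines)

  # stanza boundaries: interpret only [Term]; any header ends the previous one
  stanza_starts <- grep("^\\[[^]]+\\]$", lines)
  stanza_ends <- c(stanza_starts[-1L] - 1L, length(lines))
  is_term <- lines[stanza_starts] == "[Term]"
  term_starts <- stanza_starts[is_term]
  term_ends <- stanza_ends[is_term]
  n_stanzas <- length(term_starts)

  ids <- character(0)
  name <- character(0); obsolete <- logical(0)
  synonyms <- list(); xrefs <- list(); parents <- list(); xof <- list()

  clean_value <- function(v) {
    v <- sub("\\{[^}]*\\}", "", v)          # trailing qualifier block
    v <- sub("!.*$", "", v)                  # OBO comment
    trim(v)
  }

  for (s in seq_len(n_stanzas)) {
    body <- if (term_ends[s] > term_starts[s])
      lines[seq(term_starts[s] + 1L, term_ends[s])] else character(0)
    body <- body[nzchar(body)]
    tags <- sub(":.*$", "", body)
    vals <- trim(sub("^[^:]+:", "", body))

    id <- clean_value(vals[tags == "id"][1])
    if (is.na(id) || !nzchar(id))
      stop_data("phenoprio_parse", "OBO [Term] stanza without an id")
    if (id %in% ids)
      stop_data("phenoprio_parse", "duplicate term id: %s", id,
                data = list(id = id))
    ids <- c(ids, id)
    nm <- clean_value(vals[tags == "name"][1])
    name <- c(name, if (is.na(nm)) "" else nm)
    obsolete <- c(obsolete,
                  any(tolower(clean_value(vals[tags == "is_obsolete"])) ==
                      "true"))

    syn_raw <- vals[tags == "synonym"]
    syns <- vapply(syn_raw, function(v) {
      m <- regmatches(v, regexpr('"[^"]*"', v))
      if (length(m)) substr(m, 2L, nchar(m) - 1L) else clean_value(v)
    }, character(1), USE.NAMES = FALSE)
    synonyms[[id]] <- syns

    isa <- clean_value(vals[tags == "is_a"])
    parents[[id]] <- isa[nzchar(isa)]

    xr <- clean_value(vals[tags == "xref"])
    xr <- xr[nzchar(xr)]
    # keep only the CURIE token; drop trailing descriptions
    xr <- vapply(xr, function(v) strsplit(v, '[ \t"]')[[1]][1],
                 character(1), USE.NAMES = FALSE)
    xrefs[[id]] <- xr[!is.na(xr) & nzchar(xr)]

    xof[[id]] <- clean_value(vals[tags == "intersection_of"])
  }

  if (!length(ids))
    stop_data("phenoprio_parse", "no [Term] stanzas found")
  names(name) <- ids
  names(obsolete) <- ids

  # obsolete terms never traverse
  for (id in ids[obsolete]) parents[[id]] <- character(0)

  dangling <- setdiff(unlist(parents, use.names = FALSE), ids)
  if (length(dangling))
    stop_data("phenoprio_parse", "is_a target(s) not defined: %s",
              paste(sort_c(dangling), collapse = ", "),
              data = list(missing = sort_c(dangling)))

  # Kahn's algorithm; whatever cannot be peeled is (in) a cycle
  live <- ids[!obsolete]
  indeg <- vapply(parents[live], length, integer(1))
  names(indeg) <- live
  kids <- .children_map(ids, parents)
  queue <- live[indeg == 0L]
  seen <- 0L
  while (length(queue)) {
    v <- queue[1L]; queue <- queue[-1L]; seen <- seen + 1L
    for (ch in intersect(kids[[v]], live)) {
      indeg[[ch]] <- indeg[[ch]] - 1L
      if (indeg[[ch]] == 0L) queue <- c(queue, ch)
    }
  }
  if (seen < length(live)) {
    cyc <- sort_c(names(indeg)[indeg > 0L])
    stop_data("phenoprio_cycle", "cycle in is_a graph involving: %s",
              paste(cyc, collapse = ", "), data = list(terms = cyc))
  }

  roots <- live[vapply(parents[live], length, integer(1)) == 0L]
  if (!length(roots))
    stop_data("phenoprio_parse", "ontology has no root term")

  structure(list(id = ids, name = name,
                 namespace = stats::setNames(curie_prefix(ids), ids),
                 obsolete = obsolete, synonyms = synonyms, xrefs = xrefs,
                 parents = parents, children = kids,
                 intersection_of = xof, roots = roots),
            class = "ontology")
}

.children_map <- function(ids, parents) {
  kids <- stats::setNames(vector("list", length(ids)), ids)
  for (id in ids) kids[[id]] <- character(0)
  for (id in ids) for (p in parents[[id]]) kids[[p]] <- c(kids[[p]], id)
  kids
}

#' @export
print.ontology <- function(x, ...) {
  cat(sprintf("ontology: %d terms (%d obsolete), %d roots, prefixes: %s\n",
              length(x$id), sum(x$obsolete), length(x$roots),
              paste(sort_c(unique(unname(x$namespace))), collapse = ", ")))
  invisible(x)
}

#' Serialize an ontology back to OBO flat format
#'
#' Writes the recognized tag subset (`id`, `name`, `synonym`, `is_a`,
#' `xref`, `is_obsolete`, `intersection_of`) in term-id order so that output
#' is byte-stable for a given ontology.
#'
#' @param ont an `ontology`
#' @param file optional path; when `NULL` the lines are returned invisibly.
#' @return character vector of OBO lines (invisibly when `file` is given).
#' @export
write_obo <- function(ont, file = NULL) {
  stopifnot(inherits(ont, "ontology"))
  out <- c("format-version: 1.2", "")
  for (id in ont$id) {
    out <- c(out, "[Term]", paste0("id: ", id))
    if (nzchar(ont$name[[id]])) out <- c(out, paste0("name: ", ont$name[[id]]))
    for (s in ont$synonyms[[id]])
      out <- c(out, sprintf('synonym: "%s" EXACT []', s))
    for (p in ont$parents[[id]]) out <- c(out, paste0("is_a: ", p))
    for (x in ont$xrefs[[id]]) out <- c(out, paste0("xref: ", x))
    for (i in ont$intersection_of[[id]])
      out <- c(out, paste0("intersection_of: ", i))
    if (ont$obsolete[[id]]) out <- c(out, "is_obsolete: true")
    out <- c(out, "")
  }
  if (!is.null(file)) {
    con <- file(file, open = "wb")
    on.exit(close(con))
    writeLines(out, con, useBytes = TRUE)
    return(invisible(out))
  }
  out
}

.check_term <- function(ont, id, allow_obsolete = FALSE) {
  if (!id %in% ont$id)
    stop_data("phenoprio_lookup", "unknown term id: %s", id,
              data = list(id = id))
  if (!allow_obsolete && ont$obsolete[[id]])
    stop_data("phenoprio_lookup", "term is obsolete: %s", id,
              data = list(id = id))
  invisible(id)
}

# BFS over a named list of neighbours; returns visited set (excl. start)
.reach <- function(adj, start, skip = character(0)) {
  seen <- character(0)
  frontier <- setdiff(unlist(adj[start], use.names = FALSE), skip)
  while (length(frontier)) {
    frontier <- setdiff(unique(frontier), seen)
    seen <- c(seen, frontier)
    frontier <- setdiff(unlist(adj[frontier], use.names = FALSE), skip)
  }
  seen
}

#' Transitive is_a ancestors of a term
#'
#' @param ont an `ontology`
#' @param id term CURIE; must exist and not be obsolete.
#' @param reflexive include `id` itself?
#' @return character vector of CURIEs, sorted; obsolete terms never appear.
#' @export
ancestors <- function(ont, id, reflexive = FALSE) {
  .check_term(ont, id)
  anc <- .reach(ont$parents, id, skip = ont$id[ont$obsolete])
  sort_c(if (reflexive) union(anc, id) else anc)
}

#' Transitive is_a descendants of a term
#'
#' @inheritParams ancestors
#' @return character vector of CURIEs, sorted.
#' @export
descendants <- function(ont, id, reflexive = FALSE) {
  .check_term(ont, id)
  dec <- .reach(ont$children, id, skip = ont$id[ont$obsolete])
  sort_c(if (reflexive) union(dec, id) else dec)
}

# ancestors grouped by BFS depth (list: depth 1 = direct parents, ...)
.ancestor_layers <- function(ont, id) {
  skip <- ont$id[ont$obsolete]
  layers <- list()
  seen <- id
  frontier <- setdiff(unlist(ont$parents[id], use.names = FALSE), skip)
  while (length(frontier)) {
    frontier <- setdiff(unique(frontier), seen)
    if (!length(frontier)) break
    layers[[length(layers) + 1L]] <- sort_c(frontier)
    seen <- c(seen, frontier)
    frontier <- setdiff(unlist(ont$parents[frontier], use.names = FALSE), skip)
  }
  layers
}

#' Resolve a label to a term id by exact name or synonym match
#'
#' Matching is case-insensitive and whitespace-normalized; names are tried
#' before synonyms. Labels that are already CURIEs present in the ontology
#' resolve to themselves. Ambiguity is an error carrying the candidate ids
#' (condition field `candidates`), never a silent choice.
#'
#' @param ont an `ontology`
#' @param label non-empty term label, synonym, or CURIE.
#' @return a single CURIE.
#' @export
resolve_term <- function(ont, label) {
  if (!nzchar(trim(label)))
    stop_data("phenoprio_lookup", "empty label")
  lab <- trim(label)
  if (is_curie(lab)) {
    # CURIE labels resolve by id membership only, never via name matching
    if (lab %in% ont$id) return(lab)
    stop_data("phenoprio_notfound", "no term with id '%s'", lab,
              data = list(label = lab))
  }
  key <- norm_label(label)
  hits <- ont$id[norm_label(ont$name) == key]
  if (!length(hits)) {
    syn_hit <- vapply(ont$id, function(id)
      any(norm_label(ont$synonyms[[id]]) == key), logical(1))
    hits <- ont$id[syn_hit]
  }
  if (!length(hits))
    stop_data("phenoprio_notfound", "no term matching label '%s'", label,
              data = list(label = label))
  if (length(hits) > 1L)
    stop_data("phenoprio_ambiguous",
              "label '%s' matches multiple terms: %s", label,
              paste(sort_c(hits), collapse = ", "),
              data = list(label = label, candidates = sort_c(hits)))
  hits
}
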