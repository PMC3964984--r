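# Boolean query language over gene annotations, and weighted multi-query
# ranking. Grammar: atoms KIND("label"); infix keywords and/or/not
# (case-insensitive); grouping with [ ]; `X not Y` is sugar for
# X and Not(Y); precedence not > and > or. Straight and curly quotes are
# both accepted. Evaluation is pure set semantics over the store's gene
# universe.

ATOM_KINDS <- c("SPECIES", "GO", "PHENO", "PATHWAY", "IP", "OMIM", "REGION")

# atom kind -> annotation namespace(s) searched
.atom_namespaces <- list(GO = "GO", PHENO = c("PHENO_A", "PHENO_B"),
                         PATHWAY = "PATHWAY", IP = "MOTIF", OMIM = "DISEASE")

#' Query AST node constructors
#'
#' Build query abstract syntax trees programmatically instead of via
#' [parse_query()]. `q_and`/`q_or` take two or more child nodes, `q_not`
#' exactly one; `q_atom` takes an atom kind (one of SPECIES, GO, PHENO,
#' PATHWAY, IP, OMIM, REGION) and a non-empty label.
#'
#' @param kind atom kind string
#' @param label atom label (term name, synonym, CURIE, species name, or
#'   `chrom:start-end` for REGION)
#' @param ... child nodes
#' @param x child node
#' @return a `query_ast` node
#' @export
q_atom <- function(kind, label) {
  kind <- toupper(kind)
  if (!kind %in% ATOM_KINDS)
    stop_data("phenoprio_query", "unknown atom kind: %s", kind)
  if (!nzchar(trim(label)))
    stop_data("phenoprio_query", "empty atom label")
  structure(list(op = "atom", kind = kind, label = label),
            class = "query_ast")
}

#' @rdname q_atom
#' @export
q_and <- function(...) {
  ch <- list(...)
  if (length(ch) < 2L) stop_data("phenoprio_query", "And needs >= 2 children")
  structure(list(op = "and", children = ch), class = "query_ast")
}

#' @rdname q_atom
#' @export
q_or <- function(...) {
  ch <- list(...)
  if (length(ch) < 2L) stop_data("phenoprio_query", "Or needs >= 2 children")
  structure(list(op = "or", children = ch), class = "query_ast")
}

#' @rdname q_atom
#' @export
q_not <- function(x) {
  structure(list(op = "not", children = list(x)), class = "query_ast")
}

# ---- tokenizer -------------------------------------------------------------

.QUOTE_PAIRS <- c('"' = '"', "'" = "'",
                  "“" = "”", "‘" = "’")

.tokenize_query <- function(text) {
  chars <- strsplit(text, "", fixed = TRUE)[[1]]
  n <- length(chars)
  i <- 1L
  toks <- list()
  push <- function(type, value, pos) {
    toks[[length(toks) + 1L]] <<- list(type = type, value = value, pos = pos)
  }
  while (i <= n) {
    ch <- chars[i]
    if (grepl("^[ \t\r\n]$", ch)) { i <- i + 1L; next }
    if (ch %in% c("[", "]", "(", ")")) {
      push(ch, ch, i); i <- i + 1L; next
    }
    if (ch %in% names(.QUOTE_PAIRS)) {
      close_ch <- .QUOTE_PAIRS[[ch]]
      j <- i + 1L
      while (j <= n && chars[j] != close_ch) j <- j + 1L
      if (j > n)
        stop_data("phenoprio_query",
                  "unterminated quote starting at position %d", i)
      push("string", paste(chars[seq(i + 1L, length.out = j - i - 1L)],
                           collapse = ""), i)
      i <- j + 1L; next
    }
    if (grepl("^[A-Za-z_]$", ch)) {
      j <- i
      while (j <= n && grepl("^[A-Za-z_0-9]$", chars[j])) j <- j + 1L
      word <- paste(chars[i:(j - 1L)], collapse = "")
      lw <- tolower(word)
      if (lw %in% c("and", "or", "not")) push(lw, word, i)
      else push("word", word, i)
      i <- j; next
    }
    stop_data("phenoprio_query", "unexpected character '%s' at position %d",
              ch, i)
  }
  toks
}

# ---- recursive-descent parser ----------------------------------------------

#' Parse a Boolean annotation query
#'
#' @param text query string, e.g.
#'   `[SPECIES("Mus musculus") and GO("nervous system development")] not
#'   IP("Notch domain")`
#' @return a `query_ast`
#' @export
parse_query <- function(text) {
  if (!nzchar(trim(text)))
    stop_data("phenoprio_query", "empty query")
  toks <- .tokenize_query(text)
  pos <- 1L
  peek <- function() if (pos <= length(toks)) toks[[pos]] else NULL
  advance <- function() { t <- toks[[pos]]; pos <<- pos + 1L; t }
  expect <- function(type) {
    t <- peek()
    if (is.null(t) || t$type != type)
      stop_data("phenoprio_query", "expected '%s' at position %s", type,
                if (is.null(t)) "end of query" else t$pos)
    advance()
  }

  parse_or <- function() {
    left <- parse_and()
    kids <- list(left)
    while (!is.null(peek()) && peek()$type == "or") {
      advance()
      kids[[length(kids) + 1L]] <- parse_and()
    }
    if (length(kids) == 1L) kids[[1L]] else do.call(q_or, kids)
  }
  # `and` and infix `not` (sugar for `and not`) bind at the same level
  parse_and <- function() {
    kids <- list(parse_unary())
    repeat {
      t <- peek()
      if (is.null(t)) break
      if (t$type == "and") {
        advance()
        kids[[length(kids) + 1L]] <- parse_unary()
      } else if (t$type == "not") {
        advance()
        kids[[length(kids) + 1L]] <- q_not(parse_unary())
      } else break
    }
    if (length(kids) == 1L) kids[[1L]] else do.call(q_and, kids)
  }
  parse_unary <- function() {
    t <- peek()
    if (!is.null(t) && t$type == "not") {
      advance()
      return(q_not(parse_unary()))
    }
    parse_primary()
  }
  parse_primary <- function() {
    t <- peek()
    if (is.null(t))
      stop_data("phenoprio_query", "unexpected end of query")
    if (t$type == "[") {
      advance()
      inner <- parse_or()
      expect("]")
      return(inner)
    }
    if (t$type == "word") {
      advance()
      kind <- toupper(t$value)
      if (!kind %in% ATOM_KINDS)
        stop_data("phenoprio_query",
                  "unknown atom kind '%s' at position %d", t$value, t$pos)
      expect("(")
      lab <- expect("string")
      expect(")")
      if (!nzchar(trim(lab$value)))
        stop_data("phenoprio_query", "empty label at position %d", lab$pos)
      return(q_atom(kind, lab$value))
    }
    stop_data("phenoprio_query", "unexpected token '%s' at position %d",
              t$value, t$pos)
  }

  ast <- parse_or()
  if (!is.null(peek()))
    stop_data("phenoprio_query", "trailing input at position %d", peek()$pos)
  ast
}

#' Serialize a query AST back to query-language text
#'
#' `parse_query(deparse_query(ast))` reproduces `ast` structurally.
#' @param ast a `query_ast`
#' @return a single string
#' @export
deparse_query <- function(ast) {
  switch(ast$op,
    atom = sprintf('%s("%s")', ast$kind, ast$label),
    not = sprintf("not %s", .dep_child(ast$children[[1L]], "not")),
    and = paste(vapply(ast$children, .dep_child, character(1), level = "and"),
                collapse = " and "),
    or = paste(vapply(ast$children, .dep_child, character(1), level = "or"),
               collapse = " or "))
}

.dep_child <- function(node, level) {
  txt <- deparse_query(node)
  # brackets both preserve precedence and keep nested same-op nodes from
  # flattening on reparse
  needs_group <- switch(level,
    or = node$op == "or",
    and = node$op %in% c("and", "or"),
    not = node$op %in% c("and", "or"))
  if (needs_group) paste0("[", txt, "]") else txt
}

#' @export
print.query_ast <- function(x, ...) {
  cat(deparse_query(x), "\n")
  invisible(x)
}

# ---- evaluation ------------------------------------------------------------

.parse_region_label <- function(label) {
  m <- regmatches(label, regexec("^\\s*([^:]+):([0-9]+)-([0-9]+)\\s*$", label))[[1]]
  if (length(m) != 4L)
    stop_data("phenoprio_query",
              "REGION label must be 'chrom:start-end', got '%s'", label)
  list(chrom = m[2], start = as.numeric(m[3]), end = as.numeric(m[4]))
}

.eval_atom <- function(node, store, ontologies) {
  if (node$kind == "SPECIES") {
    g <- store$genes
    return(sort_c(g$gene_id[tolower(g$species) == tolower(trim(node$label))]))
  }
  if (node$kind == "REGION") {
    r <- .parse_region_label(node$label)
    return(genes_in_region(store, r$chrom, r$start, r$end))
  }
  nss <- intersect(.atom_namespaces[[node$kind]], names(ontologies))
  if (!length(nss))
    stop_data("phenoprio_query",
              "no ontology supplied for atom %s(\"%s\")", node$kind,
              node$label)
  hits <- list()
  for (ns in nss) {
    id <- tryCatch(resolve_term(ontologies[[ns]], node$label),
                   phenoprio_notfound = function(e) NULL)
    if (!is.null(id)) hits[[ns]] <- id
  }
  if (!length(hits))
    stop_data("phenoprio_notfound",
              "atom %s(\"%s\") does not resolve in namespace(s) %s",
              node$kind, node$label, paste(nss, collapse = ", "))
  if (length(hits) > 1L)
    stop_data("phenoprio_ambiguous",
              "atom %s(\"%s\") resolves in multiple namespaces: %s",
              node$kind, node$label, paste(names(hits), collapse = ", "),
              data = list(candidates = unlist(hits)))
  ns <- names(hits)[1L]
  genes_with_term(store, ontologies[[ns]], hits[[1L]], ns, propagate = TRUE)
}

#' Evaluate a query AST against an annotation store
#'
#' Atoms retrieve gene sets (term atoms with true-path propagation; SPECIES
#' filters by species; REGION by coordinate overlap); `and` intersects,
#' `or` unions, and `not` complements within the store's full gene universe
#' (all species; scope explicitly with `SPECIES(...)` when needed).
#'
#' @param ast a `query_ast` (or query string, parsed on the fly)
#' @param store an `annotation_store`
#' @param ontologies named list, namespace -> `ontology`
#' @return sorted character vector of gene ids
#' @export
evaluate_query <- function(ast, store, ontologies) {
  if (is.character(ast)) ast <- parse_query(ast)
  universe <- store$genes$gene_id
  rec <- function(node) {
    switch(node$op,
      atom = .eval_atom(node, store, ontologies),
      and = Reduce(intersect, lapply(node$children, rec)),
      or = Reduce(union, lapply(node$children, rec)),
      not = setdiff(universe, rec(node$children[[1L]])))
  }
  sort_c(unique(rec(ast)))
}

#' Bundle queries with positive weights
#'
#' @param queries list of `query_ast` nodes (or query strings)
#' @param weights positive numeric vector, one per query (default all 1)
#' @return object of class `query_set`
#' @export
query_set <- function(queries, weights = rep(1, length(queries))) {
  if (!length(queries))
    stop_data("phenoprio_query", "query set needs >= 1 query")
  if (length(weights) != length(queries) || any(weights <= 0) ||
      any(!is.finite(weights)))
    stop_data("phenoprio_query", "weights must be positive and finite")
  queries <- lapply(queries, function(q)
    if (is.character(q)) parse_query(q) else q)
  structure(list(queries = queries, weights = as.numeric(weights)),
            class = "query_set")
}

#' Read a weighted query set from TSV (`weight \\t expression`, headered)
#' @param file path
#' @return a `query_set`
#' @export
read_query_set <- function(file) {
  tab <- read_tsv(file)
  if (!all(c("weight", "expression") %in% names(tab)))
    stop_data("phenoprio_format",
              "query file must have columns: weight, expression")
  query_set(as.list(tab$expression), as.numeric(tab$weight))
}

#' Rank genes by summed weights of satisfied queries
#'
#' Each query is evaluated once; a gene's score is the sum of the weights
#' of the queries whose result contains it. With all weights 1 the score is
#' the number of conditions met. Genes matching no query are omitted. Ties
#' are broken by ascending gene id for determinism.
#'
#' @param qs a `query_set`
#' @param store an `annotation_store`
#' @param ontologies named list, namespace -> `ontology`
#' @param universe optional character vector restricting the candidate
#'   genes considered (default: all genes in the store)
#' @return data.frame of class `ranked_candidates`: columns `gene_id`,
#'   `score`, `matched` (comma-separated 1-based query indices), ordered by
#'   score descending then gene id ascending.
#' @export
rank_genes <- function(qs, store, ontologies, universe = NULL) {
  stopifnot(inherits(qs, "query_set"))
  sets <- lapply(qs$queries, evaluate_query, store = store,
                 ontologies = ontologies)
  if (!is.null(universe)) sets <- lapply(sets, intersect, universe)
  genes <- sort_c(unique(unlist(sets, use.names = FALSE)))
  if (!length(genes)) {
    out <- data.frame(gene_id = character(0), score = numeric(0),
                      matched = character(0), stringsAsFactors = FALSE)
    class(out) <- c("ranked_candidates", "data.frame")
    return(out)
  }
  hit <- vapply(sets, function(s) genes %in% s,
                logical(length(genes)))
  hit <- matrix(hit, nrow = length(genes))
  score <- as.numeric(hit %*% qs$weights)
  matched <- apply(hit, 1L, function(row)
    paste(which(row), collapse = ","))
  out <- data.frame(gene_id = genes, score = score, matched = matched,
                    stringsAsFactors = FALSE)
  out <- out[out$score > 0, , drop = FALSE]
  out <- out[order_c(-out$score, out$gene_id), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("ranked_candidates", "data.frame")
  out
}

#' Per-query gene counts and pairwise overlaps
#'
#' Evaluates every query of the set (weights ignored) and reports the
#' result-set sizes plus the full matrix of pairwise intersection sizes.
#'
#' @inheritParams rank_genes
#' @return list with `counts` (integer vector, one per query) and
#'   `overlap` (square matrix; entry i,j = size of intersection of query i
#'   and query j results; diagonal = counts).
#' @export
annotation_distribution <- function(qs, store, ontologies) {
  stopifnot(inherits(qs, "query_set"))
  sets <- lapply(qs$queries, evaluate_query, store = store,
                 ontologies = ontologies)
  k <- length(sets)
  counts <- vapply(sets, length, integer(1))
  overlap <- matrix(0L, k, k)
  for (i in seq_len(k)) for (j in seq_len(k))
    overlap[i, j] <- length(intersect(sets[[i]], sets[[j]]))
  list(counts = counts, overlap = overlap)
}
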