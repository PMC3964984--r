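# Entity-Quality cross-species phenotype mapping.
#
# A phenotype term is decomposed into a quality (how it is abnormal, from a
# quality ontology) and one or more anatomical entities (what is affected,
# from a species-specific anatomy ontology). Terms of two species' phenotype
# ontologies are related when their qualities agree (identical or one an
# is_a ancestor of the other) and their entities are linked through a
# species-neutral bridge anatomy whose terms cross-reference both sides.
# Terms without a usable definition inherit the mappings of their closest
# annotated ancestor; as a last resort a manually curated keyword index
# relates phenotypes of the same organ or function, at a lower weight.

#' Extract Entity-Quality logical definitions from OBO intersection lines
#'
#' The first term-only `intersection_of` value of a stanza is taken as the
#' quality (the genus); relation-bearing values (`relation CURIE`) supply
#' the affected entities.
#'
#' @param ont an `ontology` parsed with [parse_obo()]
#' @return object of class `logical_definitions`: a named list mapping a
#'   phenotype CURIE to `list(quality =, entities =)`.
#' @export
logical_definitions <- function(ont) {
  stopifnot(inherits(ont, "ontology"))
  defs <- list()
  for (id in ont$id) {
    raw <- ont$intersection_of[[id]]
    if (!length(raw)) next
    toks <- strsplit(trim(raw), "[ \t]+")
    genus <- vapply(toks, length, integer(1)) == 1L
    quality <- if (any(genus)) toks[genus][[1]][1] else NA_character_
    entities <- vapply(toks[!genus], function(t) t[[length(t)]], character(1))
    if (is.na(quality) || !length(entities)) next
    defs[[id]] <- list(quality = quality, entities = unname(entities))
  }
  structure(defs, class = "logical_definitions")
}

#' Read logical definitions from a TSV sidecar
#'
#' Expected columns: `term_id`, `quality_id`, `entity_id` (comma-separated
#' list), headered. When merged over OBO-derived definitions via
#' [merge_definitions()], the TSV wins on conflict.
#'
#' @param file path to the TSV
#' @return a `logical_definitions` object
#' @export
read_logical_definitions <- function(file) {
  tab <- read_tsv(file)
  need <- c("term_id", "quality_id", "entity_id")
  if (!all(need %in% names(tab)))
    stop_data("phenoprio_format", "definition TSV must have columns: %s",
              paste(need, collapse = ", "))
  defs <- list()
  for (i in seq_len(nrow(tab))) {
    ents <- trim(strsplit(tab$entity_id[i], ",")[[1]])
    defs[[tab$term_id[i]]] <- list(quality = trim(tab$quality_id[i]),
                                   entities = ents[nzchar(ents)])
  }
  structure(defs, class = "logical_definitions")
}

#' Merge two sets of logical definitions (second one wins on conflict)
#' @param base,override `logical_definitions` objects
#' @return a `logical_definitions` object
#' @export
merge_definitions <- function(base, override) {
  out <- unclass(base)
  for (id in names(override)) out[[id]] <- override[[id]]
  structure(out, class = "logical_definitions")
}

#' Build the cross-species anatomy bridge from a bridge ontology
#'
#' An anatomy pair (a, b) is bridged iff some bridge-ontology term carries
#' cross-references to both: to `a` in `anatomy_a`'s prefix set and to `b`
#' in `anatomy_b`'s. Pairs contributed by distinct bridge terms are unioned.
#' Cross-references with unrecognized prefixes, or to ids absent from their
#' anatomy ontology, are skipped with a warning.
#'
#' @param anatomy_a,anatomy_b species-specific anatomy ontologies
#' @param bridge the species-neutral bridge ontology
#' @return object of class `anatomy_bridge`: a data.frame with columns `a`
#'   and `b`, unique rows, sorted.
#' @export
build_bridge <- function(anatomy_a, anatomy_b, bridge) {
  pref_a <- unique(unname(anatomy_a$namespace))
  pref_b <- unique(unname(anatomy_b$namespace))
  pa <- character(0); pb <- character(0)
  skipped <- character(0)
  for (id in bridge$id) {
    xr <- bridge$xrefs[[id]]
    if (!length(xr)) next
    px <- curie_prefix(xr)
    xa <- xr[px %in% pref_a]
    xb <- xr[px %in% pref_b]
    unknown <- xr[!px %in% c(pref_a, pref_b)]
    bad_a <- xa[!xa %in% anatomy_a$id]
    bad_b <- xb[!xb %in% anatomy_b$id]
    skipped <- c(skipped, unknown, bad_a, bad_b)
    xa <- setdiff(xa, bad_a); xb <- setdiff(xb, bad_b)
    if (length(xa) && length(xb)) {
      grid <- expand.grid(a = xa, b = xb, stringsAsFactors = FALSE,
                          KEEP.OUT.ATTRS = FALSE)
      pa <- c(pa, grid$a); pb <- c(pb, grid$b)
    }
  }
  if (length(skipped))
    warning(sprintf("bridge xref(s) skipped (unknown prefix or id): %s",
                    paste(sort_c(unique(skipped)), collapse = ", ")))
  pairs <- unique(data.frame(a = pa, b = pb, stringsAsFactors = FALSE))
  pairs <- pairs[order_c(pairs$a, pairs$b), , drop = FALSE]
  rownames(pairs) <- NULL
  structure(list(pairs = pairs,
                 keys = unique(c(paste(pairs$a, pairs$b, sep = "\r"),
                                 paste(pairs$b, pairs$a, sep = "\r")))),
            class = "anatomy_bridge")
}

#' @export
print.anatomy_bridge <- function(x, ...) {
  cat(sprintf("anatomy_bridge: %d pairs\n", nrow(x$pairs)))
  invisible(x)
}

#' Are two anatomy terms bridged?
#'
#' Symmetric: the orientation of the arguments does not matter.
#' @param bridge an `anatomy_bridge`
#' @param a,b anatomy CURIEs (vectorized, recycled)
#' @return logical vector
#' @export
is_bridged <- function(bridge, a, b) {
  paste(a, b, sep = "\r") %in% bridge$keys
}

#' Do two Entity-Quality definitions describe matching phenotypes?
#'
#' TRUE iff the qualities are identical or one is an is_a ancestor of the
#' other in the quality ontology, AND at least one entity of `def_a` is
#' bridged to at least one entity of `def_b` (existential entity matching).
#'
#' @param def_a,def_b lists with fields `quality` and `entities`
#' @param quality_ont the quality ontology
#' @param bridge an `anatomy_bridge`
#' @return TRUE or FALSE
#' @export
eq_match <- function(def_a, def_b, quality_ont, bridge) {
  qa <- def_a$quality; qb <- def_b$quality
  q_ok <- qa == qb ||
    (qa %in% quality_ont$id && !quality_ont$obsolete[[qa]] &&
       qb %in% ancestors(quality_ont, qa)) ||
    (qb %in% quality_ont$id && !quality_ont$obsolete[[qb]] &&
       qa %in% ancestors(quality_ont, qb))
  if (!q_ok) return(FALSE)
  grid <- expand.grid(a = def_a$entities, b = def_b$entities,
                      stringsAsFactors = FALSE, KEEP.OUT.ATTRS = FALSE)
  any(is_bridged(bridge, grid$a, grid$b))
}

#' Read a curated keyword index from YAML
#'
#' Format: one mapping per keyword, `keyword: [term ids]`, each list mixing
#' phenotype terms from both species' ontologies. Listed terms must exist
#' in one of the supplied ontologies.
#'
#' @param x path to a YAML file, or a named list `keyword -> character
#'   vector of term ids`
#' @param ontologies list of ontologies used to validate term ids
#' @return object of class `keyword_index` (named list keyword -> ids)
#' @export
read_keyword_index <- function(x, ontologies = list()) {
  idx <- if (is.character(x) && length(x) == 1L) yaml::read_yaml(x) else x
  if (!length(idx))
    stop_data("phenoprio_format", "keyword index is empty")
  idx <- lapply(idx, function(v) sort_c(unique(as.character(v))))
  if (length(ontologies)) {
    known <- unlist(lapply(ontologies, `[[`, "id"), use.names = FALSE)
    bad <- setdiff(unlist(idx, use.names = FALSE), known)
    if (length(bad))
      stop_data("phenoprio_lookup", "keyword index names unknown terms: %s",
                paste(sort_c(bad), collapse = ", "),
                data = list(terms = sort_c(bad)))
  }
  structure(idx, class = "keyword_index")
}

# stage-1 targets: target terms whose definition eq-matches def.
# Equivalent to filtering all targets through eq_match(), but prefilters on
# the compatible-quality set (q itself plus its ancestors and descendants)
# so only entity bridging is tested per candidate.
.eq_targets <- function(def, tgt_defs, quality_ont, bridge) {
  if (is.null(def) || !length(tgt_defs)) return(character(0))
  q <- def$quality
  rel <- q
  if (q %in% quality_ont$id && !quality_ont$obsolete[[q]])
    rel <- unique(c(q, ancestors(quality_ont, q),
                    descendants(quality_ont, q)))
  tgt_q <- vapply(tgt_defs, `[[`, character(1), "quality")
  cand <- names(tgt_defs)[tgt_q %in% rel]
  hit <- vapply(cand, function(t) {
    grid <- expand.grid(a = def$entities, b = tgt_defs[[t]]$entities,
                        stringsAsFactors = FALSE, KEEP.OUT.ATTRS = FALSE)
    any(is_bridged(bridge, grid$a, grid$b))
  }, logical(1))
  sort_c(cand[hit])
}

#' Map a phenotype term into the other species' phenotype ontology
#'
#' Three-stage cascade, stopping at the first stage that yields at least
#' one mapping:
#' \enumerate{
#'   \item \strong{eq_exact} (weight 1): target terms whose Entity-Quality
#'     definition matches the source term's ([eq_match()]).
#'   \item \strong{eq_inherited} (weight 1): the source's is_a ancestors are
#'     walked breadth-first by increasing depth; at the first depth where
#'     any ancestor has stage-1 mappings, the union of those ancestors'
#'     targets is returned (closest-annotated-parent propagation; ties in
#'     depth are unioned, never broken arbitrarily).
#'   \item \strong{keyword} (weight `w_kw`): target terms sharing at least
#'     one curated keyword with the source.
#' }
#' The keyword stage is down-weighted (`w_kw`, default 0.5) to reflect its
#' lower precision relative to the Entity-Quality stages.
#'
#' @param source source phenotype CURIE
#' @param src_ont,tgt_ont the two phenotype ontologies
#' @param src_defs,tgt_defs `logical_definitions` for each side
#' @param quality_ont the quality ontology
#' @param bridge an `anatomy_bridge`
#' @param keywords a `keyword_index` (optional; `NULL` disables stage 3)
#' @param w_kw positive weight multiplier for keyword mappings, < 1
#' @return data.frame with columns `source`, `target`, `method` (one of
#'   `eq_exact`, `eq_inherited`, `keyword`) and `weight`, sorted by target;
#'   zero rows when all stages fail.
#' @export
map_term <- function(source, src_ont, tgt_ont, src_defs, tgt_defs,
                     quality_ont, bridge, keywords = NULL, w_kw = 0.5) {
  .check_term(src_ont, source)
  stopifnot(w_kw > 0)
  mk <- function(targets, method, weight) {
    data.frame(source = rep(source, length(targets)),
               target = sort_c(targets),
               method = rep(method, length(targets)),
               weight = rep(weight, length(targets)),
               stringsAsFactors = FALSE)
  }

  t1 <- .eq_targets(src_defs[[source]], tgt_defs, quality_ont, bridge)
  if (length(t1)) return(mk(t1, "eq_exact", 1.0))

  for (layer in .ancestor_layers(src_ont, source)) {
    hits <- unlist(lapply(layer, function(a)
      .eq_targets(src_defs[[a]], tgt_defs, quality_ont, bridge)),
      use.names = FALSE)
    if (length(hits)) return(mk(unique(hits), "eq_inherited", 1.0))
  }

  if (!is.null(keywords)) {
    has_src <- vapply(keywords, function(v) source %in% v, logical(1))
    kw_targets <- intersect(
      unlist(unclass(keywords)[has_src], use.names = FALSE),
      tgt_ont$id)
    kw_targets <- setdiff(kw_targets, source)
    if (length(kw_targets)) return(mk(unique(kw_targets), "keyword", w_kw))
  }

  mk(character(0), character(0), numeric(0))
}
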