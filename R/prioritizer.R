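# Disease-to-candidate-gene prioritization: translate a clinical phenotype
# description (terms of the species-A phenotype ontology) into a weighted
# query set over the model species' phenotype annotations, then rank
# candidate genes, optionally restricted to a chromosomal interval.

#' Read disease descriptions from an hpoa-like TSV
#'
#' Columns: `disease_id`, `term_id`, `frequency` (optional qualifier,
#' may be empty), headered, tab-delimited.
#'
#' @param file path
#' @return data.frame with those three character columns
#' @export
read_diseases <- function(file) {
  tab <- read_tsv(file)
  if (!all(c("disease_id", "term_id") %in% names(tab)))
    stop_data("phenoprio_format",
              "disease file must have columns: disease_id, term_id")
  if (!"frequency" %in% names(tab)) tab$frequency <- ""
  tab[, c("disease_id", "term_id", "frequency")]
}

#' Specificity weights of phenotype features across a disease corpus
#'
#' A feature that recurs across many diseases says little about any one of
#' them. For each term t, the corpus frequency is
#' f(t) = (diseases annotated to t or one of its descendants) / corpus size,
#' and the specificity weight is the information content -log2(f(t)).
#' f is clamped from below at 1/(2 * corpus size) so unseen terms get a
#' finite weight. Annotation is propagated: a disease annotated to a leaf
#' counts for every ancestor of that leaf.
#'
#' @param corpus disease data.frame as returned by [read_diseases()]
#' @param ont the species-A phenotype ontology
#' @return data.frame of class `feature_weights` with columns `term`,
#'   `freq`, `weight`, one row per non-obsolete term of `ont`.
#' @export
feature_weights <- function(corpus, ont) {
  diseases <- unique(corpus$disease_id)
  n_d <- length(diseases)
  if (!n_d) stop_data("phenoprio_domain", "disease corpus is empty")
  counts <- stats::setNames(numeric(length(ont$id)), ont$id)
  for (d in diseases) {
    terms <- unique(corpus$term_id[corpus$disease_id == d])
    terms <- intersect(terms, ont$id[!ont$obsolete])
    cov <- unique(unlist(lapply(terms, ancestors, ont = ont,
                                reflexive = TRUE), use.names = FALSE))
    counts[cov] <- counts[cov] + 1
  }
  live <- ont$id[!ont$obsolete]
  f <- pmax(counts[live] / n_d, 1 / (2 * n_d))
  out <- data.frame(term = live, freq = unname(f),
                    weight = unname(-log2(f)), stringsAsFactors = FALSE)
  class(out) <- c("feature_weights", "data.frame")
  out
}

#' Translate one disease description into a weighted query set
#'
#' Each phenotype feature of the disease is mapped into the model species'
#' phenotype ontology with the Entity-Quality cascade ([map_term()]) and
#' becomes one query: a PHENO atom per mapped target, combined with `or`
#' when a feature maps to several targets (the feature fires if any mapped
#' target's annotation matches). The query weight is the feature's
#' specificity weight times the mapping-method weight (1 for the
#' Entity-Quality stages, `w_kw` for keyword fallback). Features with no
#' mapping at any stage are dropped and reported, not fatal. Disease-side
#' frequency qualifiers are carried through to the optional
#' `frequency_multiplier` hook and otherwise ignored.
#'
#' @param disease data.frame rows of one disease (columns `disease_id`,
#'   `term_id`, optional `frequency`)
#' @param src_ont,tgt_ont,src_defs,tgt_defs,quality_ont,bridge,keywords,w_kw
#'   passed to [map_term()]
#' @param weights `feature_weights` for the corpus (or `NULL` for uniform
#'   specificity 1)
#' @param frequency_multiplier optional `function(frequency_label)` ->
#'   positive multiplier applied to that feature's query weight
#' @return list with `query_set` (a [query_set()] or `NULL` when nothing
#'   maps), `features` (data.frame: term, method, specificity,
#'   method_weight, weight), and `dropped` (unmappable feature CURIEs)
#' @export
disease_to_queryset <- function(disease, src_ont, tgt_ont, src_defs,
                                tgt_defs, quality_ont, bridge,
                                keywords = NULL, weights = NULL,
                                w_kw = 0.5, frequency_multiplier = NULL) {
  terms <- unique(disease$term_id)
  freq_of <- if ("frequency" %in% names(disease))
    stats::setNames(disease$frequency, disease$term_id)[terms]
  else stats::setNames(rep("", length(terms)), terms)
  spec_w <- function(t) {
    if (is.null(weights)) return(1)
    w <- weights$weight[match(t, weights$term)]
    if (is.na(w)) 1 else w
  }

  queries <- list(); wts <- numeric(0)
  feat <- list(); dropped <- character(0)
  for (t in sort_c(terms)) {
    maps <- map_term(t, src_ont, tgt_ont, src_defs, tgt_defs, quality_ont,
                     bridge, keywords, w_kw)
    if (!nrow(maps)) { dropped <- c(dropped, t); next }
    atoms <- lapply(maps$target, function(tg) q_atom("PHENO", tg))
    qnode <- if (length(atoms) == 1L) atoms[[1L]] else do.call(q_or, atoms)
    w <- spec_w(t) * maps$weight[1L]
    if (!is.null(frequency_multiplier))
      w <- w * frequency_multiplier(freq_of[[t]])
    if (w <= 0) { dropped <- c(dropped, t); next }
    queries[[length(queries) + 1L]] <- qnode
    wts <- c(wts, w)
    feat[[length(feat) + 1L]] <- data.frame(
      term = t, method = maps$method[1L], specificity = spec_w(t),
      method_weight = maps$weight[1L], weight = w,
      n_targets = nrow(maps), stringsAsFactors = FALSE)
  }
  list(query_set = if (length(queries)) query_set(queries, wts) else NULL,
       features = if (length(feat)) do.call(rbind, feat) else
         data.frame(term = character(0), method = character(0),
                    specificity = numeric(0), method_weight = numeric(0),
                    weight = numeric(0), n_targets = integer(0)),
       dropped = dropped)
}

#' Prioritize candidate genes for a disease
#'
#' Builds the disease's weighted query set ([disease_to_queryset()]) and
#' ranks model-species genes with [rank_genes()]. Without a region the
#' candidate universe is every gene of `model_species`; with a region
#' (on the source species' genome) it is the model-species orthologs of
#' the genes overlapping that interval. Region genes without orthologs,
#' and candidates without any model-phenotype annotation, are surfaced in
#' `unscorable` rather than silently dropped.
#'
#' @param disease one disease's rows (see [disease_to_queryset()])
#' @param store an `annotation_store` holding both species
#' @param ontologies named list, namespace -> `ontology`; must contain
#'   `PHENO_B` (the model species' phenotype namespace)
#' @param model_species species label of the annotated model organism
#' @param region optional `list(chrom =, start =, end =)` restricting
#'   candidates (source-species coordinates)
#' @inheritParams disease_to_queryset
#' @return object of class `prioritization`: list with `disease_id`,
#'   `status` (`"ok"` or `"unanalyzable"`), `ranked` (a
#'   `ranked_candidates` data.frame), `universe` (candidate gene ids),
#'   `unscorable` (list with `no_ortholog` region genes and `no_phenotype`
#'   candidates), `features`, `dropped`.
#' @export
prioritize <- function(disease, store, ontologies, model_species,
                       src_ont, tgt_ont, src_defs, tgt_defs, quality_ont,
                       bridge, keywords = NULL, weights = NULL,
                       w_kw = 0.5, region = NULL,
                       frequency_multiplier = NULL) {
  qs <- disease_to_queryset(disease, src_ont, tgt_ont, src_defs, tgt_defs,
                            quality_ont, bridge, keywords, weights, w_kw,
                            frequency_multiplier)
  disease_id <- disease$disease_id[1L]
  no_ortholog <- character(0)
  if (is.null(region)) {
    universe <- sort_c(store$genes$gene_id[store$genes$species ==
                                             model_species])
  } else {
    region_genes <- genes_in_region(store, region$chrom, region$start,
                                    region$end)
    universe <- orthologs(store, region_genes, model_species)
    with_partner <- region_genes[vapply(region_genes, function(g)
      length(orthologs(store, g, model_species)) > 0L, logical(1))]
    no_ortholog <- setdiff(region_genes, with_partner)
  }
  annotated <- unique(store$associations$gene_id[
    store$associations$namespace == "PHENO_B"])
  no_phenotype <- setdiff(universe, annotated)

  if (is.null(qs$query_set)) {
    empty <- data.frame(gene_id = character(0), score = numeric(0),
                        matched = character(0), stringsAsFactors = FALSE)
    class(empty) <- c("ranked_candidates", "data.frame")
    out <- list(disease_id = disease_id, status = "unanalyzable",
                ranked = empty,
                universe = universe,
                unscorable = list(no_ortholog = no_ortholog,
                                  no_phenotype = sort_c(no_phenotype)),
                features = qs$features, dropped = qs$dropped)
    class(out) <- "prioritization"
    return(out)
  }
  ranked <- rank_genes(qs$query_set, store, ontologies, universe = universe)
  out <- list(disease_id = disease_id, status = "ok", ranked = ranked,
              universe = universe,
              unscorable = list(no_ortholog = no_ortholog,
                                no_phenotype = sort_c(no_phenotype)),
              features = qs$features, dropped = qs$dropped)
  class(out) <- "prioritization"
  out
}

#' @export
print.prioritization <- function(x, ...) {
  cat(sprintf("prioritization of %s [%s]: %d scored / %d candidates, %d feature(s) used, %d dropped\n",
              x$disease_id, x$status, nrow(x$ranked), length(x$universe),
              nrow(x$features), length(x$dropped)))
  if (nrow(x$ranked)) {
    print(utils::head(as.data.frame(x$ranked), 10L))
  }
  invisible(x)
}
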