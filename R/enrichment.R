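# Hypergeometric enrichment / depletion over any annotation namespace,
# multiple-testing corrections, and conditional probabilities between
# annotation terms.

#' One-sided hypergeometric tail probability
#'
#' For a study list of size `n` drawn from a reference of size `N` of which
#' `K` carry the term, and `k` study genes carrying it:
#' `direction = "enriched"` gives P(X >= k), `"depleted"` gives P(X <= k),
#' with X ~ Hypergeometric(N, K, n). Computed exactly via the stable
#' log-space tail routines of [stats::phyper()].
#'
#' @param k observed count in the study list
#' @param n study-list size
#' @param K reference count carrying the term
#' @param N reference size
#' @param direction `"enriched"` or `"depleted"`
#' @return a probability in (0, 1]
#' @export
hypergeom_tail <- function(k, n, K, N, direction = c("enriched", "depleted")) {
  direction <- match.arg(direction)
  if (any(N < 0) || any(K < 0) || any(K > N) || any(n < 0) || any(n > N) ||
      any(k < 0) || any(k > pmin(n, K)))
    stop_data("phenoprio_domain",
              "hypergeometric bounds violated: need 0 <= K <= N, 0 <= n <= N, 0 <= k <= min(n, K)")
  if (direction == "enriched") {
    exp(stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE, log.p = TRUE))
  } else {
    exp(stats::phyper(k, K, N - K, n, lower.tail = TRUE, log.p = TRUE))
  }
}

#' Benjamini-Hochberg step-up adjusted p-values
#'
#' Standard step-up FDR adjustment: sort ascending, take the running
#' minimum of `p_(j) * m / j` from the largest rank down, clip at 1, and
#' return in the input order (delegates to [stats::p.adjust()]).
#'
#' @param p numeric vector of p-values in \[0, 1\]
#' @return adjusted p-values, same length and order
#' @export
bh_fdr <- function(p) {
  if (any(is.na(p)) || any(p < 0) || any(p > 1))
    stop_data("phenoprio_domain", "p-values must lie in [0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' Bonferroni-adjusted p-values
#'
#' Family-wise error control: each p-value is multiplied by the number of
#' tests and clipped at 1 (delegates to [stats::p.adjust()]).
#'
#' @inheritParams bh_fdr
#' @return adjusted p-values, same length and order
#' @export
bonferroni <- function(p) {
  if (any(is.na(p)) || any(p < 0) || any(p > 1))
    stop_data("phenoprio_domain", "p-values must lie in [0, 1]")
  stats::p.adjust(p, method = "bonferroni")
}

#' Term enrichment and depletion of a study list against a reference
#'
#' For every term of the namespace with at least one (propagated)
#' annotation in the reference, counts study (`k`/`n`) and reference
#' (`K`/`N`) genes carrying the term under the true-path rule, calls the
#' direction from the observed proportions (`enriched` when k/n >= K/N,
#' else `depleted`), computes the matching one-sided hypergeometric tail,
#' and corrects over the m terms actually tested in the namespace
#' (Bonferroni and Benjamini-Hochberg).
#'
#' @param study character vector of gene ids; must be a subset of
#'   `reference`
#' @param reference character vector of gene ids (e.g. a genome, an array,
#'   or a custom list)
#' @param store an `annotation_store`
#' @param ont the namespace's `ontology`
#' @param namespace annotation namespace tested
#' @return data.frame with columns `term`, `name`, `k`, `n`, `K`, `N`,
#'   `direction`, `p`, `p_bonf`, `p_bh`, sorted by `p` then term.
#' @export
enrich <- function(study, reference, store, ont, namespace) {
  study <- unique(study); reference <- unique(reference)
  if (!length(reference))
    stop_data("phenoprio_domain", "reference set is empty")
  extra <- setdiff(study, reference)
  if (length(extra))
    stop_data("phenoprio_domain",
              "study list is not a subset of the reference; offending gene(s): %s",
              paste(sort_c(extra), collapse = ", "),
              data = list(genes = sort_c(extra)))

  a <- store$associations
  a <- a[a$namespace == namespace & a$gene_id %in% reference, , drop = FALSE]
  # propagated term set per annotated term: a term is "tested" when it or a
  # descendant carries >= 1 reference annotation, i.e. its propagated
  # reference count is positive
  direct_terms <- unique(a$term_id)
  tested <- unique(unlist(lapply(direct_terms, function(t)
    ancestors(ont, t, reflexive = TRUE)), use.names = FALSE))
  tested <- sort_c(tested)
  n <- length(study); N <- length(reference)
  rows <- lapply(tested, function(t) {
    g <- genes_with_term(store, ont, t, namespace, propagate = TRUE)
    K <- length(intersect(g, reference))
    k <- length(intersect(g, study))
    direction <- if (n > 0 && k / n >= K / N) "enriched" else "depleted"
    p <- hypergeom_tail(k, n, K, N, direction)
    data.frame(term = t, name = ont$name[[t]], k = k, n = n, K = K, N = N,
               direction = direction, p = p, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$p_bonf <- bonferroni(out$p)
  out$p_bh <- bh_fdr(out$p)
  out <- out[order_c(out$p, out$term), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Conditional probabilities between two annotation terms
#'
#' With GA and GB the (propagated) gene sets of the two terms, returns
#' P(A|B) = |GA n GB| / |GB| and P(B|A) = |GA n GB| / |GA|, plus the
#' underlying counts. An empty conditioning set is an explicit error, not a
#' silent NaN.
#'
#' @param term_a,term_b term CURIEs (or labels resolved via
#'   [resolve_term()])
#' @param ns_a,ns_b their annotation namespaces
#' @param store an `annotation_store`
#' @param ontologies named list, namespace -> `ontology`
#' @return list with `p_a_given_b`, `p_b_given_a`, `n_a`, `n_b`, `n_both`
#' @export
conditional_probability <- function(term_a, ns_a, term_b, ns_b, store,
                                    ontologies) {
  ia <- resolve_term(ontologies[[ns_a]], term_a)
  ib <- resolve_term(ontologies[[ns_b]], term_b)
  ga <- genes_with_term(store, ontologies[[ns_a]], ia, ns_a, propagate = TRUE)
  gb <- genes_with_term(store, ontologies[[ns_b]], ib, ns_b, propagate = TRUE)
  if (!length(gb))
    stop_data("phenoprio_domain",
              "P(%s | %s) undefined: no gene annotated with %s", ia, ib, ib)
  if (!length(ga))
    stop_data("phenoprio_domain",
              "P(%s | %s) undefined: no gene annotated with %s", ib, ia, ia)
  both <- length(intersect(ga, gb))
  list(p_a_given_b = both / length(gb),
       p_b_given_a = both / length(ga),
       n_a = length(ga), n_b = length(gb), n_both = both)
}
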