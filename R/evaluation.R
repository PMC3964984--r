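# Benchmark machinery: rank known disease genes inside windows of varying
# width around their true locus and compare the achieved ranks with the
# analytic chance expectation for genes picked uniformly at random within
# the same candidate regions.

#' Candidate-region size profile
#'
#' Holds the per-case candidate-region gene counts n_j that feed the
#' chance-expectation null. R_i, the number of regions with at least i
#' genes, is derived.
#'
#' @param n integer vector of region gene counts, all >= 1
#' @return object of class `region_profile` with fields `n` and `R`
#'   (`R[i]` = number of regions with at least i genes; non-increasing)
#' @export
region_profile <- function(n) {
  n <- as.numeric(n)
  if (length(n) && any(n < 1))
    stop_data("phenoprio_domain", "region gene counts must be >= 1")
  max_n <- if (length(n)) max(n) else 0
  R <- vapply(seq_len(max_n), function(i) sum(n >= i), numeric(1))
  structure(list(n = n, R = R), class = "region_profile")
}

#' Expected number of correct genes at each rank under the chance null
#'
#' Under the null that each region's genes are ordered uniformly at
#' random, the true gene of a region with n_j candidates occupies any
#' given rank i <= n_j with probability 1/n_j. The expected number of
#' correct genes found at rank i across the profile is therefore
#' E_i = sum over regions j with n_j >= i of 1/n_j,
#' and the cumulative top-k expectation is C_k = sum_{i<=k} E_i.
#' Summing E_i over all ranks recovers the number of regions exactly
#' (each region's true gene lands somewhere).
#'
#' @param profile a `region_profile`
#' @param max_rank number of ranks to report
#' @return data.frame with columns `rank`, `expected` (E_i) and
#'   `cumulative` (C_k)
#' @export
chance_expectation <- function(profile, max_rank) {
  stopifnot(inherits(profile, "region_profile"), max_rank >= 1)
  ranks <- seq_len(max_rank)
  e <- vapply(ranks, function(i) sum(1 / profile$n[profile$n >= i]),
              numeric(1))
  data.frame(rank = ranks, expected = e, cumulative = cumsum(e))
}

#' Simulate true-gene ranks under the uniform-ordering null
#'
#' For each replicate and each region of the profile, draws the rank of
#' the region's true gene uniformly from 1..n_j. Used to cross-validate
#' [chance_expectation()] by Monte-Carlo.
#'
#' @param profile a `region_profile`
#' @param reps number of replicates
#' @return integer matrix, `reps` rows x one column per region, of
#'   simulated ranks
#' @export
simulate_null_ranks <- function(profile, reps) {
  k <- length(profile$n)
  m <- matrix(0L, nrow = reps, ncol = k)
  for (j in seq_len(k))
    m[, j] <- sample.int(profile$n[j], reps, replace = TRUE)
  m
}

# conservative competition rank: worst rank within the tie group.
# scores: named numeric over the whole universe (0 = unscored).
.worst_tie_rank <- function(scores, gene) {
  s <- scores[[gene]]
  sum(scores > s) + sum(scores == s)
}

#' Benchmark prioritization against known disease genes
#'
#' For every (disease, true gene) case and every window width w, the
#' candidate region is the interval of width w centered on the true
#' gene's midpoint (configurable offset), on its chromosome; the disease
#' is prioritized within that region and the rank of the true gene's
#' model-species ortholog(s) is recorded. Tied scores are resolved
#' conservatively: the true gene takes the worst rank within its tie
#' group, and a true gene scoring 0 takes the last rank of the universe.
#' Cases whose query set is empty are flagged unanalyzable and excluded
#' from rank statistics but counted in the reported fraction; so are
#' cases whose true gene lacks coordinates or a model-species ortholog in
#' the region.
#'
#' @param cases data.frame with columns `disease_id`, `true_gene`
#'   (source-species gene id)
#' @param diseases disease corpus data.frame (see [read_diseases()])
#' @param store,ontologies,model_species,src_ont,tgt_ont,src_defs,tgt_defs,quality_ont,bridge,keywords,weights,w_kw
#'   as in [prioritize()]
#' @param windows numeric vector of window widths in base pairs
#' @param offset_fraction window center offset as a fraction of the width
#'   (0 = centered on the gene midpoint)
#' @return object of class `benchmark_result`: list with `table` (one row
#'   per case x window: disease_id, true_gene, window, region_size =
#'   candidate-universe size, rank, analyzable), `profiles` (named list of
#'   `region_profile`, one per window, over analyzable cases) and
#'   `unanalyzable_fraction`.
#' @export
run_benchmark <- function(cases, diseases, store, ontologies, model_species,
                          src_ont, tgt_ont, src_defs, tgt_defs, quality_ont,
                          bridge, keywords = NULL, weights = NULL,
                          w_kw = 0.5, windows = c(5e6, 1e7, 5e7, 1e8),
                          offset_fraction = 0) {
  g <- store$genes
  rows <- list()
  # query sets are region-independent: build and evaluate once per disease,
  # then restrict scores to each window's universe
  for (ci in seq_len(nrow(cases))) {
    did <- cases$disease_id[ci]
    true_gene <- cases$true_gene[ci]
    d <- diseases[diseases$disease_id == did, , drop = FALSE]
    qs <- disease_to_queryset(d, src_ont, tgt_ont, src_defs, tgt_defs,
                              quality_ont, bridge, keywords, weights, w_kw)
    gi <- match(true_gene, g$gene_id)
    has_coord <- !is.na(gi) && !is.na(g$chrom[gi])
    analyzable_q <- !is.null(qs$query_set)
    scores_all <- NULL
    if (analyzable_q) {
      full <- rank_genes(qs$query_set, store, ontologies)
      scores_all <- stats::setNames(full$score, full$gene_id)
    }
    for (w in windows) {
      row <- list(disease_id = did, true_gene = true_gene, window = w,
                  region_size = NA_real_, rank = NA_real_,
                  analyzable = FALSE)
      if (has_coord) {
        mid <- (g$start[gi] + g$end[gi]) / 2 + offset_fraction * w
        region_genes <- genes_in_region(store, g$chrom[gi],
                                        max(1, mid - w / 2), mid + w / 2)
        universe <- orthologs(store, region_genes, model_species)
        true_models <- orthologs(store, true_gene, model_species)
        row$region_size <- length(universe)
        if (analyzable_q && length(universe) &&
            length(intersect(true_models, universe))) {
          scores <- stats::setNames(rep(0, length(universe)), universe)
          have <- intersect(universe, names(scores_all))
          scores[have] <- scores_all[have]
          rank_ <- min(vapply(intersect(true_models, universe),
                              function(m) .worst_tie_rank(scores, m),
                              numeric(1)))
          row$rank <- rank_
          row$analyzable <- TRUE
        }
      }
      rows[[length(rows) + 1L]] <- row
    }
  }
  tab <- do.call(rbind, lapply(rows, function(r)
    data.frame(r, stringsAsFactors = FALSE)))
  profiles <- lapply(stats::setNames(windows, format(windows, scientific = FALSE,
                                                     trim = TRUE)),
                     function(w) {
    sub <- tab[tab$window == w & tab$analyzable, , drop = FALSE]
    region_profile(sub$region_size)
  })
  # a case counts as unanalyzable when no window produced a rank
  per_case <- tapply(tab$analyzable, tab$disease_id, any)
  structure(list(table = tab, profiles = profiles,
                 unanalyzable_fraction = mean(!per_case)),
            class = "benchmark_result")
}

#' Summarize achieved ranks against the chance curve
#'
#' Tabulates, for each cutoff k, the fraction of analyzable cases whose
#' true gene ranked within the top k, next to the fraction expected by
#' chance (cumulative chance expectation divided by the number of
#' regions).
#'
#' @param table a benchmark rank table restricted to one window (or any
#'   data.frame with columns `rank`, `region_size`, `analyzable`)
#' @param ks integer cutoffs
#' @return data.frame with columns `k`, `observed`, `chance`, `n_cases`;
#'   zero rows when no case is analyzable.
#' @export
rank_summary <- function(table, ks = c(1, 5, 10, 20, 50)) {
  sub <- table[table$analyzable, , drop = FALSE]
  if (!nrow(sub))
    return(data.frame(k = numeric(0), observed = numeric(0),
                      chance = numeric(0), n_cases = numeric(0)))
  prof <- region_profile(sub$region_size)
  ce <- chance_expectation(prof, max(ks))
  data.frame(k = ks,
             observed = vapply(ks, function(k) mean(sub$rank <= k),
                               numeric(1)),
             chance = ce$cumulative[ks] / length(prof$n),
             n_cases = nrow(sub))
}
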