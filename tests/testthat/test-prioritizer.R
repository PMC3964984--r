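# Disease feature weighting, query generation, candidate prioritization

test_that("feature weights are -log2 of propagated corpus frequency, clamped", {
  ont <- parse_obo(c("format-version: 1.2", "",
                     "[Term]", "id: PA:1", "name: root", "",
                     "[Term]", "id: PA:2", "name: everywhere", "is_a: PA:1", "",
                     "[Term]", "id: PA:3", "name: half", "is_a: PA:1", "",
                     "[Term]", "id: PA:4", "name: unseen", "is_a: PA:1", ""))
  corpus <- data.frame(
    disease_id = c("d1", "d2", "d3", "d4", "d1", "d2"),
    term_id = c("PA:2", "PA:2", "PA:2", "PA:2", "PA:3", "PA:3"),
    frequency = "", stringsAsFactors = FALSE)
  w <- feature_weights(corpus, ont)
  wt <- stats::setNames(w$weight, w$term)
  expect_identical(wt[["PA:2"]], 0)          # f = 1
  expect_identical(wt[["PA:3"]], 1)          # f = 1/2
  expect_identical(wt[["PA:4"]], -log2(1 / 8))  # clamp at 1/(2*4)
  expect_identical(wt[["PA:1"]], 0)          # root covered by every disease
})

test_that("feature weights equal a brute-force per-disease descendant test", {
  fx <- get_fixture()
  ont <- fx$ontologies$PHENO_A
  w <- feature_weights(fx$diseases, ont)
  d_ids <- unique(fx$diseases$disease_id)
  set.seed(77)
  for (t in sample(ont$id, 25L)) {
    below <- descendants(ont, t, reflexive = TRUE)
    cnt <- sum(vapply(d_ids, function(d)
      any(fx$diseases$term_id[fx$diseases$disease_id == d] %in% below),
      logical(1)))
    f <- max(cnt / length(d_ids), 1 / (2 * length(d_ids)))
    expect_equal(w$weight[w$term == t], -log2(f), tolerance = 1e-12)
  }
})

test_that("query weights are the product of specificity and method weight", {
  fx <- get_fixture()
  w <- feature_weights(fx$diseases, fx$ontologies$PHENO_A)
  wt <- stats::setNames(w$weight, w$term)
  did <- fx$ledger$planted$disease_id[
    fx$ledger$planted$n_mapped == max(as.integer(fx$ledger$planted$n_mapped))][1L]
  dis <- fx$diseases[fx$diseases$disease_id == did, ]
  qs <- disease_to_queryset(dis, fx$ontologies$PHENO_A,
                            fx$ontologies$PHENO_B, fx$src_defs, fx$tgt_defs,
                            fx$quality_ont, fx$bridge, fx$keywords, w,
                            w_kw = 0.5)
  expect_gt(nrow(qs$features), 0L)
  for (i in seq_len(nrow(qs$features))) {
    f <- qs$features[i, ]
    expect_equal(f$weight, wt[[f$term]] *
                   (if (f$method == "keyword") 0.5 else 1),
                 tolerance = 1e-12)
    expect_identical(qs$query_set$weights[i], f$weight)
  }
  # keyword-mapped features are down-weighted relative to their specificity
  kwf <- qs$features[qs$features$method == "keyword", ]
  if (nrow(kwf))
    expect_true(all(kwf$method_weight == 0.5))
  # unmappable features are reported as dropped, not fatal
  all_terms <- unique(dis$term_id)
  expect_setequal(c(qs$features$term, qs$dropped), all_terms)
})

test_that("a fully unmappable disease yields an unanalyzable outcome", {
  fx <- get_fixture()
  unm <- fx$ledger$planted$disease_id[fx$ledger$planted$n_mapped == "0"][1L]
  expect_false(is.na(unm))
  dis <- fx$diseases[fx$diseases$disease_id == unm, ]
  pr <- prioritize(dis, fx$store, fx$ontologies, "mouse",
                   fx$ontologies$PHENO_A, fx$ontologies$PHENO_B,
                   fx$src_defs, fx$tgt_defs, fx$quality_ont, fx$bridge,
                   fx$keywords)
  expect_identical(pr$status, "unanalyzable")
  expect_identical(nrow(pr$ranked), 0L)
})

test_that("the planted causal gene ranks first with its ledger score", {
  fx <- get_fixture()
  w <- feature_weights(fx$diseases, fx$ontologies$PHENO_A)
  led <- fx$ledger$planted
  mapped <- led[led$n_mapped != "0", ]
  set.seed(20)
  for (i in sample(seq_len(nrow(mapped)), 8L)) {
    dis <- fx$diseases[fx$diseases$disease_id == mapped$disease_id[i], ]
    pr <- prioritize(dis, fx$store, fx$ontologies, "mouse",
                     fx$ontologies$PHENO_A, fx$ontologies$PHENO_B,
                     fx$src_defs, fx$tgt_defs, fx$quality_ont, fx$bridge,
                     fx$keywords, w, w_kw = fx$config$w_kw)
    expect_identical(pr$status, "ok")
    expect_identical(pr$ranked$gene_id[1L], mapped$model_gene[i])
    expect_equal(pr$ranked$score[1L],
                 as.numeric(mapped$expected_score[i]), tolerance = 1e-9)
    # strictly above the runner-up: the planted profile is unique
    if (nrow(pr$ranked) > 1L)
      expect_gt(pr$ranked$score[1L], pr$ranked$score[2L])
  }
})

test_that("region constraints shrink the universe without changing scores", {
  fx <- get_fixture()
  w <- feature_weights(fx$diseases, fx$ontologies$PHENO_A)
  led <- fx$ledger$planted
  mapped <- led[led$n_mapped != "0", ]
  row <- mapped[3L, ]
  dis <- fx$diseases[fx$diseases$disease_id == row$disease_id, ]
  g <- fx$store$genes[fx$store$genes$gene_id == row$true_gene, ]
  mid <- (g$start + g$end) / 2
  region <- list(chrom = g$chrom, start = max(1, mid - 5e5),
                 end = mid + 5e5)
  unc <- prioritize(dis, fx$store, fx$ontologies, "mouse",
                    fx$ontologies$PHENO_A, fx$ontologies$PHENO_B,
                    fx$src_defs, fx$tgt_defs, fx$quality_ont, fx$bridge,
                    fx$keywords, w)
  con <- prioritize(dis, fx$store, fx$ontologies, "mouse",
                    fx$ontologies$PHENO_A, fx$ontologies$PHENO_B,
                    fx$src_defs, fx$tgt_defs, fx$quality_ont, fx$bridge,
                    fx$keywords, w, region = region)
  expect_true(length(con$universe) < length(unc$universe))
  expect_identical(con$ranked$gene_id[1L], row$model_gene)
  # scores identical on the shared candidates; only the universe shrinks
  shared <- intersect(con$ranked$gene_id, unc$ranked$gene_id)
  expect_identical(
    stats::setNames(con$ranked$score, con$ranked$gene_id)[shared],
    stats::setNames(unc$ranked$score, unc$ranked$gene_id)[shared])
  # region genes without orthologs are surfaced, not dropped
  region_genes <- genes_in_region(fx$store, region$chrom, region$start,
                                  region$end)
  no_orth <- region_genes[vapply(region_genes, function(x)
    length(orthologs(fx$store, x, "mouse")) == 0L, logical(1))]
  expect_setequal(con$unscorable$no_ortholog, no_orth)
})

test_that("sharing an extra feature never lowers a candidate's standing", {
  # two genes, one matching k features and one matching the same k plus
  # one more, under equal weights: the latter must score higher
  fx <- get_fixture()
  w <- feature_weights(fx$diseases, fx$ontologies$PHENO_A)
  led <- fx$ledger$planted
  mapped <- led[as.integer(led$n_mapped) >= 3L, ]
  dis <- fx$diseases[fx$diseases$disease_id == mapped$disease_id[1L], ]
  qs <- disease_to_queryset(dis, fx$ontologies$PHENO_A,
                            fx$ontologies$PHENO_B, fx$src_defs, fx$tgt_defs,
                            fx$quality_ont, fx$bridge, fx$keywords,
                            weights = NULL)   # uniform specificity
  rk <- rank_genes(qs$query_set, fx$store, fx$ontologies)
  n_matched <- vapply(strsplit(rk$matched, ","), length, integer(1))
  expect_identical(order(-rk$score),
                   order(-n_matched))  # uniform weights: score = #matched
})
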