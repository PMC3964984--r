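# Query language parsing, set-semantics evaluation, weighted ranking

test_that("a complex bracketed query parses into the expected tree", {
  q <- parse_query(paste0(
    '[SPECIES("Mus musculus") and PATHWAY("Signaling by NOTCH") and ',
    'GO("nervous system development")] not IP("Notch domain")'))
  expect_identical(q$op, "and")
  expect_length(q$children, 2L)
  inner <- q$children[[1L]]
  expect_identical(inner$op, "and")
  expect_identical(vapply(inner$children, `[[`, character(1), "kind"),
                   c("SPECIES", "PATHWAY", "GO"))
  neg <- q$children[[2L]]
  expect_identical(neg$op, "not")
  expect_identical(neg$children[[1L]]$kind, "IP")
  expect_identical(neg$children[[1L]]$label, "Notch domain")
})

test_that("single atoms, curly quotes and case-insensitive keywords parse", {
  a <- parse_query('GO("x")')
  expect_identical(a$op, "atom")
  expect_identical(a$label, "x")
  b <- parse_query("go(“heart development”) AND pheno(‘y’)")
  expect_identical(b$op, "and")
  expect_identical(b$children[[1L]]$kind, "GO")
  expect_identical(b$children[[1L]]$label, "heart development")
})

test_that("precedence is not > and > or", {
  q <- parse_query('GO("a") or GO("b") and not GO("c")')
  expect_identical(q$op, "or")
  rhs <- q$children[[2L]]
  expect_identical(rhs$op, "and")
  expect_identical(rhs$children[[2L]]$op, "not")
})

test_that("malformed queries fail with positioned errors", {
  expect_error(parse_query('GO("a" and GO("b")'), class = "phenoprio_query")
  expect_error(parse_query('[GO("a") or GO("b")'), "expected",
               class = "phenoprio_query")
  expect_error(parse_query('FOO("a")'), "unknown atom kind",
               class = "phenoprio_query")
  expect_error(parse_query('GO("")'), "empty label",
               class = "phenoprio_query")
  expect_error(parse_query("   "), class = "phenoprio_query")
})

test_that("random ASTs survive a deparse/parse round trip", {
  rs <- random_store(55)
  set.seed(55)
  for (i in seq_len(100)) {
    ast <- random_ast(sample(1:4, 1L), rs$store, rs$ontologies)
    expect_true(ast_equal(parse_query(deparse_query(ast)), ast),
                info = deparse_query(ast))
  }
})

test_that("evaluation matches the per-gene predicate oracle on random ASTs", {
  total <- 0L
  for (seed in c(61, 62)) {
    rs <- random_store(seed, n_genes = 50L)
    set.seed(seed + 100L)
    genes <- rs$store$genes$gene_id
    for (i in seq_len(100)) {
      ast <- random_ast(sample(1:3, 1L), rs$store, rs$ontologies)
      got <- evaluate_query(ast, rs$store, rs$ontologies)
      brute <- genes[vapply(genes, gene_satisfies, logical(1), ast = ast,
                            store = rs$store, onts = rs$ontologies)]
      expect_setequal(got, brute)
      total <- total + 1L
    }
  }
  expect_identical(total, 200L)
})

test_that("basic laws hold: noncontradiction, De Morgan, or-union growth", {
  rs <- random_store(63)
  x <- q_atom("GO", rs$ontologies$GO$id[2L])
  y <- q_atom("PHENO", rs$ontologies$PHENO_B$id[2L])
  expect_identical(
    evaluate_query(q_and(x, q_not(x)), rs$store, rs$ontologies),
    character(0))
  lhs <- evaluate_query(q_not(q_and(x, y)), rs$store, rs$ontologies)
  rhs <- evaluate_query(q_or(q_not(x), q_not(y)), rs$store, rs$ontologies)
  expect_setequal(lhs, rhs)
  a <- evaluate_query(x, rs$store, rs$ontologies)
  b <- evaluate_query(y, rs$store, rs$ontologies)
  u <- evaluate_query(q_or(x, y), rs$store, rs$ontologies)
  expect_gte(length(u), max(length(a), length(b)))
  expect_setequal(u, union(a, b))
})

test_that("De Morgan and monotonicity hold on random ASTs", {
  rs <- random_store(64)
  set.seed(64)
  for (i in seq_len(30)) {
    a <- random_ast(2L, rs$store, rs$ontologies)
    b <- random_ast(2L, rs$store, rs$ontologies)
    lhs <- evaluate_query(q_not(q_and(a, b)), rs$store, rs$ontologies)
    rhs <- evaluate_query(q_or(q_not(a), q_not(b)), rs$store, rs$ontologies)
    expect_setequal(lhs, rhs)
    base <- evaluate_query(a, rs$store, rs$ontologies)
    expect_true(all(base %in%
                      evaluate_query(q_or(a, b), rs$store, rs$ontologies)))
    expect_true(all(evaluate_query(q_and(a, b), rs$store, rs$ontologies)
                    %in% base))
  }
})

test_that("unresolvable and ambiguous atom labels raise informative errors", {
  rs <- random_store(65)
  expect_error(
    evaluate_query(q_atom("GO", "no such process"), rs$store,
                   rs$ontologies),
    class = "phenoprio_notfound")
  # same name in both phenotype vocabularies -> ambiguity across
  # namespaces is an error, not a silent union
  onts <- rs$ontologies
  onts$PHENO_B <- parse_obo(c("format-version: 1.2", "",
                              "[Term]", "id: PB:9001", "name: term 2", ""))
  onts$PHENO_A <- parse_obo(c("format-version: 1.2", "",
                              "[Term]", "id: PA:9001", "name: term 2", ""))
  g <- data.frame(gene_id = "g", species = "mouse", symbol = "s",
                  chrom = "", start = "", end = "", stringsAsFactors = FALSE)
  st <- annotation_store(g)
  expect_error(evaluate_query(q_atom("PHENO", "term 2"), st, onts),
               class = "phenoprio_ambiguous")
})

test_that("rank orders by summed weights then gene id, and matches brute force", {
  rs <- random_store(66, n_genes = 50L)
  set.seed(66)
  for (rep in seq_len(10)) {
    k <- sample(2:4, 1L)
    qs <- query_set(lapply(seq_len(k), function(i)
      random_ast(2L, rs$store, rs$ontologies)),
      weights = round(runif(k, 0.5, 3), 2))
    rk <- rank_genes(qs, rs$store, rs$ontologies)
    sets <- lapply(qs$queries, evaluate_query, store = rs$store,
                   ontologies = rs$ontologies)
    for (g in rs$store$genes$gene_id) {
      sc <- sum(qs$weights[vapply(sets, function(s) g %in% s, logical(1))])
      if (sc > 0) {
        expect_identical(rk$score[rk$gene_id == g], sc)
      } else {
        expect_false(g %in% rk$gene_id)
      }
    }
    expect_true(all(diff(rk$score) <= 0))
    ties <- split(rk$gene_id, rk$score)
    for (tg in ties)
      expect_identical(tg, sort(tg, method = "radix"))
  }
})

test_that("with uniform weights the score is the number of conditions met", {
  rs <- random_store(67)
  x <- q_atom("GO", rs$ontologies$GO$roots[1L])
  y <- q_atom("SPECIES", "mouse")
  rk <- rank_genes(query_set(list(x, y)), rs$store, rs$ontologies)
  both <- intersect(evaluate_query(x, rs$store, rs$ontologies),
                    evaluate_query(y, rs$store, rs$ontologies))
  expect_true(all(rk$score[rk$gene_id %in% both] == 2))
  expect_true(all(rk$score[!rk$gene_id %in% both] == 1))
  expect_true(all(rk$matched[rk$gene_id %in% both] == "1,2"))
})

test_that("annotation_distribution reports counts and pairwise overlaps", {
  rs <- random_store(68)
  x <- q_atom("SPECIES", "human"); y <- q_atom("SPECIES", "mouse")
  d <- annotation_distribution(query_set(list(x, y, x)), rs$store,
                               rs$ontologies)
  expect_identical(d$overlap[1, 2], 0L)           # disjoint species
  expect_identical(d$overlap[1, 3], d$counts[1])  # identical queries
  expect_identical(diag(d$overlap), d$counts)
  sets <- lapply(list(x, y, x), evaluate_query, store = rs$store,
                 ontologies = rs$ontologies)
  for (i in 1:3) for (j in 1:3)
    expect_identical(d$overlap[i, j],
                     length(intersect(sets[[i]], sets[[j]])))
})
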