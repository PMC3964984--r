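# Shared fixtures and independent brute-force oracles. The oracles are
# deliberately naive (matrix closure, exhaustive enumeration, per-gene
# predicate loops) and never call the code paths they check.

`%||%` <- function(a, b) if (is.null(a)) b else a

# ---- cached generated fixture (built once per test run) --------------------

.fx_cache <- new.env(parent = emptyenv())

get_fixture <- function(key = "default", cfg = NULL) {
  if (is.null(.fx_cache[[key]])) {
    if (is.null(cfg)) cfg <- fixture_config(seed = 101L)
    dir <- file.path(tempdir(), paste0("phenoprio-fx-", key))
    if (!dir.exists(dir)) generate_fixture(cfg, dir)
    .fx_cache[[key]] <- load_fixture(dir)
  }
  .fx_cache[[key]]
}

# ---- random DAG ontologies -------------------------------------------------

# returns list(lines = OBO text, ids, edges = data.frame(child, parent))
random_dag_obo <- function(n, seed, prefix = "T", p_two_parents = 0.3) {
  set.seed(seed)
  ids <- sprintf("%s:%04d", prefix, seq_len(n))
  child <- character(0); parent <- character(0)
  lines <- c("format-version: 1.2", "")
  for (i in seq_len(n)) {
    lines <- c(lines, "[Term]", paste0("id: ", ids[i]),
               paste0("name: term ", i))
    if (i > 1L) {
      k <- if (i > 2L && runif(1) < p_two_parents) 2L else 1L
      ps <- sample(seq_len(i - 1L), min(k, i - 1L))
      lines <- c(lines, paste0("is_a: ", ids[ps]))
      child <- c(child, rep(ids[i], length(ps)))
      parent <- c(parent, ids[ps])
    }
    lines <- c(lines, "")
  }
  list(lines = lines, ids = ids,
       edges = data.frame(child = child, parent = parent,
                          stringsAsFactors = FALSE))
}

# boolean-matrix transitive closure by repeated squaring (reachability
# oracle for ancestors())
reach_closure <- function(ids, edges) {
  n <- length(ids)
  m <- matrix(FALSE, n, n, dimnames = list(ids, ids))
  if (nrow(edges))
    m[cbind(edges$child, edges$parent)] <- TRUE
  repeat {
    m2 <- m | ((m %*% m) > 0)
    if (identical(m2, m)) break
    m <- m2
  }
  m
}

# ---- random annotation stores ----------------------------------------------

# small two-species store over two random ontologies (GO and PHENO_B)
random_store <- function(seed, n_genes = 40L, n_go = 15L, n_pb = 15L,
                         ann_per_gene = 4L) {
  set.seed(seed)
  go <- parse_obo(random_dag_obo(n_go, seed + 1L, prefix = "GO")$lines)
  pb <- parse_obo(random_dag_obo(n_pb, seed + 2L, prefix = "PB")$lines)
  half <- n_genes %/% 2L
  ids <- c(sprintf("HG%04d", seq_len(half)),
           sprintf("MG%04d", seq_len(n_genes - half)))
  species <- rep(c("human", "mouse"), c(half, n_genes - half))
  genes <- data.frame(
    gene_id = ids, species = species, symbol = paste0("s", seq_len(n_genes)),
    chrom = sample(c("chr1", "chr2"), n_genes, replace = TRUE),
    start = as.character(st <- sample.int(1e6, n_genes)),
    end = as.character(st + sample.int(5e4, n_genes)),
    stringsAsFactors = FALSE)
  k <- n_genes * ann_per_gene
  assoc <- rbind(
    data.frame(gene_id = sample(ids, k, replace = TRUE),
               term_id = sample(go$id, k, replace = TRUE),
               namespace = "GO", stringsAsFactors = FALSE),
    data.frame(gene_id = sample(ids, k, replace = TRUE),
               term_id = sample(pb$id, k, replace = TRUE),
               namespace = "PHENO_B", stringsAsFactors = FALSE))
  assoc <- unique(assoc)
  n_orth <- min(half, n_genes - half)
  orth <- data.frame(gene_id_1 = sprintf("HG%04d", seq_len(n_orth)),
                     gene_id_2 = sprintf("MG%04d", seq_len(n_orth)),
                     stringsAsFactors = FALSE)
  onts <- list(GO = go, PHENO_B = pb)
  list(store = annotation_store(genes, assoc, orth, onts),
       ontologies = onts)
}

# per-gene predicate oracle for query evaluation: a gene satisfies a term
# atom when one of its annotations has the query term among its reflexive
# ancestors (no descendants() involved)
gene_satisfies <- function(gene, ast, store, onts) {
  if (ast$op == "atom") {
    if (ast$kind == "SPECIES") {
      sp <- store$genes$species[store$genes$gene_id == gene]
      return(tolower(sp) == tolower(ast$label))
    }
    if (ast$kind == "REGION") {
      g <- store$genes[store$genes$gene_id == gene, ]
      m <- regmatches(ast$label,
                      regexec("^([^:]+):([0-9]+)-([0-9]+)$", ast$label))[[1]]
      return(!is.na(g$chrom) && g$chrom == m[2] &&
               g$start <= as.numeric(m[4]) && g$end >= as.numeric(m[3]))
    }
    ns <- if (ast$kind == "GO") "GO" else "PHENO_B"
    ont <- onts[[ns]]
    a <- store$associations
    terms <- a$term_id[a$gene_id == gene & a$namespace == ns]
    return(any(vapply(terms, function(t)
      ast$label %in% ancestors(ont, t, reflexive = TRUE), logical(1))))
  }
  kids <- vapply(ast$children, gene_satisfies, logical(1), gene = gene,
                 store = store, onts = onts)
  switch(ast$op, and = all(kids), or = any(kids), not = !kids[1L])
}

# random query ASTs over a random store's vocabulary
random_ast <- function(depth, store, onts) {
  if (depth <= 0L || runif(1) < 0.35) {
    kind <- sample(c("GO", "PHENO", "SPECIES"), 1L)
    label <- switch(kind,
      GO = sample(onts$GO$id, 1L),
      PHENO = sample(onts$PHENO_B$id, 1L),
      SPECIES = sample(c("human", "mouse"), 1L))
    return(q_atom(kind, label))
  }
  op <- sample(c("and", "or", "not"), 1L)
  if (op == "not") return(q_not(random_ast(depth - 1L, store, onts)))
  k <- sample(2:3, 1L)
  kids <- lapply(seq_len(k), function(i) random_ast(depth - 1L, store, onts))
  do.call(if (op == "and") q_and else q_or, kids)
}

ast_equal <- function(a, b) {
  if (a$op != b$op) return(FALSE)
  if (a$op == "atom") return(a$kind == b$kind && a$label == b$label)
  if (length(a$children) != length(b$children)) return(FALSE)
  all(vapply(seq_along(a$children), function(i)
    ast_equal(a$children[[i]], b$children[[i]]), logical(1)))
}

# exhaustive hypergeometric tail by enumerating all C(N, n) draws
hyper_tail_enum <- function(k, n, K, N, direction) {
  ref <- c(rep(1L, K), rep(0L, N - K))
  if (n == 0L) {
    x <- 0L
    return(if (direction == "enriched") as.numeric(x >= k)
           else as.numeric(x <= k))
  }
  draws <- utils::combn(N, n)
  xs <- apply(draws, 2L, function(ix) sum(ref[ix]))
  if (direction == "enriched") mean(xs >= k) else mean(xs <= k)
}
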