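# Entity-Quality cascade: bridge construction, definition matching,
# closest-annotated-parent propagation, keyword fallback

mini_ont <- function(prefix, n, parent_of = NULL) {
  lines <- c("format-version: 1.2", "")
  for (i in seq_len(n)) {
    lines <- c(lines, "[Term]", sprintf("id: %s:%d", prefix, i),
               sprintf("name: %s term %d", prefix, i))
    if (i > 1L) {
      p <- if (is.null(parent_of)) i - 1L else parent_of[i]
      lines <- c(lines, sprintf("is_a: %s:%d", prefix, p))
    }
    lines <- c(lines, "")
  }
  parse_obo(lines)
}

bridge_from_xrefs <- function(xrefs_per_term, anat_a, anat_b) {
  lines <- c("format-version: 1.2", "")
  for (i in seq_along(xrefs_per_term)) {
    lines <- c(lines, "[Term]", sprintf("id: UB:%d", i),
               sprintf("name: bridge %d", i),
               if (i > 1L) "is_a: UB:1",
               paste0("xref: ", xrefs_per_term[[i]]), "")
  }
  build_bridge(anat_a, anat_b, parse_obo(lines))
}

test_that("bridge pairs come from bridge terms cross-referencing both sides", {
  aa <- mini_ont("FMA", 5); ab <- mini_ont("MA", 5)
  br <- bridge_from_xrefs(list(character(0), c("FMA:2", "MA:3")), aa, ab)
  expect_identical(br$pairs, data.frame(a = "FMA:2", b = "MA:3",
                                        stringsAsFactors = FALSE))
  expect_true(is_bridged(br, "FMA:2", "MA:3"))
  expect_true(is_bridged(br, "MA:3", "FMA:2"))  # symmetric
  expect_false(is_bridged(br, "FMA:2", "MA:2"))

  empty <- bridge_from_xrefs(list(character(0)), aa, ab)
  expect_identical(nrow(empty$pairs), 0L)
})

test_that("unknown xref prefixes or ids are skipped with a warning, not an error", {
  aa <- mini_ont("FMA", 3); ab <- mini_ont("MA", 3)
  expect_warning(
    br <- bridge_from_xrefs(list(c("FMA:2", "MA:2", "ZFA:9", "FMA:99")),
                            aa, ab),
    "skipped")
  expect_identical(br$pairs$a, "FMA:2")
})

test_that("bridge equals brute-force triple enumeration on random xref sets", {
  set.seed(31)
  aa <- mini_ont("FMA", 20); ab <- mini_ont("MA", 20)
  xr <- lapply(seq_len(60), function(i) {
    c(if ((na <- sample(0:2, 1))) sprintf("FMA:%d", sample(20, na)),
      if ((nb <- sample(0:2, 1))) sprintf("MA:%d", sample(20, nb)))
  })
  br <- bridge_from_xrefs(xr, aa, ab)
  expected <- character(0)
  for (x in xr) {
    x <- as.character(x)
    fa <- x[startsWith(x, "FMA")]; mb <- x[startsWith(x, "MA:")]
    for (a in fa) for (b in mb) expected <- c(expected, paste(a, b))
  }
  got <- paste(br$pairs$a, br$pairs$b)
  expect_setequal(got, unique(expected))
})

test_that("eq_match follows the quality-relatedness and entity-bridging rule", {
  q <- mini_ont("PQ", 4)          # chain PQ:1 <- PQ:2 <- PQ:3 <- PQ:4
  aa <- mini_ont("FMA", 4); ab <- mini_ont("MA", 4)
  br <- bridge_from_xrefs(list(c("FMA:2", "MA:2")), aa, ab)
  d <- function(qu, e) list(quality = qu, entities = e)

  # identical quality, bridged entities
  expect_true(eq_match(d("PQ:3", "FMA:2"), d("PQ:3", "MA:2"), q, br))
  # ancestor/descendant quality in either direction
  expect_true(eq_match(d("PQ:4", "FMA:2"), d("PQ:2", "MA:2"), q, br))
  expect_true(eq_match(d("PQ:2", "FMA:2"), d("PQ:4", "MA:2"), q, br))
  # unbridged entity
  expect_false(eq_match(d("PQ:3", "FMA:3"), d("PQ:3", "MA:3"), q, br))
  # disjoint qualities (siblings would need a branching ontology; unknown id
  # behaves as unrelated)
  expect_false(eq_match(d("PQ:9", "FMA:2"), d("PQ:3", "MA:2"), q, br))
  # multi-entity definitions match existentially
  expect_true(eq_match(d("PQ:3", c("FMA:1", "FMA:2")),
                       d("PQ:3", c("MA:4", "MA:2")), q, br))
})

test_that("eq_match with equal qualities is symmetric under argument swap", {
  fx <- get_fixture()
  defs_a <- fx$src_defs; defs_b <- fx$tgt_defs
  set.seed(5)
  for (ta in sample(names(defs_a), 20L)) {
    for (tb in sample(names(defs_b), 5L)) {
      da <- defs_a[[ta]]; db <- defs_b[[tb]]
      if (da$quality != db$quality) next
      expect_identical(eq_match(da, db, fx$quality_ont, fx$bridge),
                       eq_match(db, da, fx$quality_ont, fx$bridge))
    }
  }
})

# a small hand-built cascade world:
#   PA:1 root, PA:2 is_a PA:1 (has def), PA:3 is_a PA:2 (no def),
#   PA:4 is_a PA:1 (no def anywhere, keyword only), PA:5 is_a PA:1 (nothing)
cascade_world <- function() {
  pa <- parse_obo(c(
    "format-version: 1.2", "",
    "[Term]", "id: PA:1", "name: root a", "",
    "[Term]", "id: PA:2", "name: defined parent", "is_a: PA:1",
    "intersection_of: PQ:2", "intersection_of: inheres_in FMA:2", "",
    "[Term]", "id: PA:3", "name: undefined child", "is_a: PA:2", "",
    "[Term]", "id: PA:4", "name: keyword only", "is_a: PA:1", "",
    "[Term]", "id: PA:5", "name: unmappable", "is_a: PA:1", ""))
  pb <- parse_obo(c(
    "format-version: 1.2", "",
    "[Term]", "id: PB:1", "name: root b", "",
    "[Term]", "id: PB:2", "name: target", "is_a: PB:1",
    "intersection_of: PQ:2", "intersection_of: inheres_in MA:2", "",
    "[Term]", "id: PB:3", "name: kw target one", "is_a: PB:1", "",
    "[Term]", "id: PB:4", "name: kw target two", "is_a: PB:1", ""))
  q <- mini_ont("PQ", 3)
  aa <- mini_ont("FMA", 3); ab <- mini_ont("MA", 3)
  br <- bridge_from_xrefs(list(c("FMA:2", "MA:2")), aa, ab)
  kw <- read_keyword_index(list(muscle = c("PA:4", "PB:3", "PB:4")),
                           list(pa, pb))
  list(pa = pa, pb = pb, q = q, br = br, kw = kw,
       src_defs = logical_definitions(pa),
       tgt_defs = logical_definitions(pb))
}

test_that("the cascade fires eq_exact, then closest-annotated-parent, then keyword", {
  w <- cascade_world()
  mt <- function(t) map_term(t, w$pa, w$pb, w$src_defs, w$tgt_defs, w$q,
                             w$br, w$kw, w_kw = 0.5)
  m2 <- mt("PA:2")
  expect_identical(m2$target, "PB:2")
  expect_identical(m2$method, "eq_exact")
  expect_identical(m2$weight, 1.0)

  m3 <- mt("PA:3")            # no definition: inherits from PA:2
  expect_identical(m3$target, "PB:2")
  expect_identical(m3$method, "eq_inherited")
  expect_identical(m3$weight, 1.0)

  m4 <- mt("PA:4")            # keyword fallback, down-weighted
  expect_identical(m4$target, c("PB:3", "PB:4"))
  expect_identical(unique(m4$method), "keyword")
  expect_identical(unique(m4$weight), 0.5)

  expect_identical(nrow(mt("PA:5")), 0L)
})

test_that("a mapping never mixes methods and keyword weight stays below 1", {
  fx <- get_fixture()
  set.seed(8)
  for (t in sample(fx$ontologies$PHENO_A$id, 60L)) {
    m <- map_term(t, fx$ontologies$PHENO_A, fx$ontologies$PHENO_B,
                  fx$src_defs, fx$tgt_defs, fx$quality_ont, fx$bridge,
                  fx$keywords, w_kw = 0.5)
    if (!nrow(m)) next
    expect_length(unique(m$method), 1L)
    expect_identical(!duplicated(m$target), rep(TRUE, nrow(m)))
    if (unique(m$method) == "keyword") {
      expect_true(all(m$weight < 1))
    } else {
      expect_true(all(m$weight == 1))
    }
    expect_identical(m$target, sort(m$target, method = "radix"))
  }
})

test_that("stage-1 map_term equals a brute-force eq_match filter over targets", {
  fx <- get_fixture()
  defs <- fx$src_defs
  set.seed(17)
  for (t in sample(names(defs), 25L)) {
    m <- map_term(t, fx$ontologies$PHENO_A, fx$ontologies$PHENO_B,
                  fx$src_defs, fx$tgt_defs, fx$quality_ont, fx$bridge,
                  fx$keywords)
    brute <- names(fx$tgt_defs)[vapply(fx$tgt_defs, function(db)
      eq_match(defs[[t]], db, fx$quality_ont, fx$bridge), logical(1))]
    if (length(brute)) {
      expect_identical(m$target, sort(brute, method = "radix"))
      expect_identical(unique(m$method), "eq_exact")
    } else if (nrow(m)) {
      expect_true(unique(m$method) %in% c("eq_inherited", "keyword"))
    }
  }
})

test_that("TSV logical definitions override OBO-derived ones", {
  w <- cascade_world()
  tsv <- file.path(tempdir(), "defs-override.tsv")
  writeLines(c("term_id\tquality_id\tentity_id",
               "PA:2\tPQ:3\tFMA:1,FMA:3",
               "PA:5\tPQ:2\tFMA:2"), tsv)
  over <- read_logical_definitions(tsv)
  merged <- merge_definitions(w$src_defs, over)
  expect_identical(merged[["PA:2"]]$quality, "PQ:3")
  expect_identical(merged[["PA:2"]]$entities, c("FMA:1", "FMA:3"))
  expect_identical(merged[["PA:5"]]$entities, "FMA:2")
  # PA:5 now eq-matches PB:2 at stage 1
  m5 <- map_term("PA:5", w$pa, w$pb, merged, w$tgt_defs, w$q, w$br, w$kw)
  expect_identical(m5$target, "PB:2")
  expect_identical(m5$method, "eq_exact")
})
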