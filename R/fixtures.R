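# Seeded synthetic-universe generator. Builds, from a single seed, every
# input the engine consumes: a quality ontology, two species anatomy
# ontologies linked by a bridge ontology, two phenotype ontologies carrying
# planted Entity-Quality correspondences, a curated keyword index, genes
# with coordinates, phenotype/GO annotations, an orthology map, and a
# disease corpus in which each disease's causal gene is planted so its
# model-species ortholog carries the annotations the disease's features map
# to. A ledger records the planted truth (correspondences, causal genes,
# expected engine scores) computed by construction-side bookkeeping, so
# engine results can be checked against the generator rather than against
# the engine itself.
#
# Structural guarantees (see the methods vignette): every mappable disease
# carries one private leaf feature annotated to its causal gene alone;
# feature blocks are disjoint across diseases; decoy genes share individual
# features but never a complete profile; background annotations avoid
# disease-target subtrees. Together these make the causal gene the strict
# top scorer of its disease whenever the description is noise-free.

#' Fixture generator configuration
#'
#' Defaults describe a small but structurally complete universe: layered
#' phenotype DAGs (depth 5), 80% of eligible terms carrying logical
#' definitions, a 90%-coverage anatomy bridge, two species of 150 genes
#' laid out one per 100 kb in 20 kb spans, 3 background annotations per
#' gene, and 40 five-feature diseases with disjoint feature sets.
#'
#' @param seed integer RNG seed; the entire universe is a deterministic
#'   function of it
#' @param n_pheno_terms shared (non-private) terms per phenotype ontology;
#'   must exceed `n_diseases * (features_per_disease - 1)` plus the root
#'   and the orphan reserve
#' @param n_quality_terms,n_go_terms sizes of the quality and GO-like
#'   ontologies
#' @param def_coverage fraction of eligible phenotype terms carrying an
#'   Entity-Quality logical definition (planted pairwise across species)
#' @param bridge_coverage fraction of shared anatomy concepts
#'   cross-referenced by the bridge ontology
#' @param keyword_coverage fraction of eligible phenotype terms listed in
#'   the curated keyword index
#' @param n_keywords number of curated keywords
#' @param genes_per_species genes per species
#' @param genes_per_chrom genes laid consecutively on each chromosome
#' @param gene_spacing,gene_length base-pair layout (start-to-start
#'   spacing and gene span)
#' @param annotations_per_gene background annotations drawn per gene
#' @param ortholog_coverage fraction of gene indices with a 1:1 ortholog
#' @param n_diseases,features_per_disease disease corpus shape; each
#'   mappable disease gets one private feature plus
#'   `features_per_disease - 1` drawn from the shared pool
#' @param n_unmappable diseases planted with only unmappable (orphan)
#'   features, exercising the unanalyzable path
#' @param noise_q probability a disease feature is replaced by a random
#'   term unrelated to the causal gene
#' @param decoy_share_rate probability a non-causal model gene shares any
#'   one disease feature annotation (never all of them)
#' @param w_kw keyword-stage weight multiplier
#' @return a `fixture_config` list
#' @export
fixture_config <- function(seed = 1L,
                           n_pheno_terms = 260L,
                           n_quality_terms = 12L,
                           n_go_terms = 30L,
                           def_coverage = 0.8,
                           bridge_coverage = 0.9,
                           keyword_coverage = 0.6,
                           n_keywords = 12L,
                           genes_per_species = 150L,
                           genes_per_chrom = 50L,
                           gene_spacing = 1e5,
                           gene_length = 2e4,
                           annotations_per_gene = 3L,
                           ortholog_coverage = 0.95,
                           n_diseases = 40L,
                           features_per_disease = 5L,
                           n_unmappable = 2L,
                           noise_q = 0,
                           decoy_share_rate = 0.1,
                           w_kw = 0.5) {
  cfg <- as.list(environment())
  fracs <- c("def_coverage", "bridge_coverage", "keyword_coverage",
             "ortholog_coverage", "noise_q", "decoy_share_rate")
  for (f in fracs)
    if (cfg[[f]] < 0 || cfg[[f]] > 1)
      stop_data("phenoprio_config", "%s must lie in [0, 1]", f)
  counts <- c("n_pheno_terms", "n_quality_terms", "n_go_terms", "n_keywords",
              "genes_per_species", "n_diseases", "features_per_disease")
  for (f in counts)
    if (cfg[[f]] < 1)
      stop_data("phenoprio_config", "%s must be >= 1", f)
  n_pool <- n_pheno_terms - 1L - features_per_disease  # minus root, orphans
  if ((n_diseases - n_unmappable) * (features_per_disease - 1L) > n_pool)
    stop_data("phenoprio_config",
              "infeasible config: %d diseases x %d shared features exceed the %d eligible phenotype terms",
              n_diseases - n_unmappable, features_per_disease - 1L, n_pool)
  if (n_diseases > genes_per_species)
    stop_data("phenoprio_config",
              "infeasible config: more diseases than genes per species")
  structure(cfg, class = "fixture_config")
}

# random layered DAG over ids[1..n]; id 1 is the root. Orphan indices hang
# directly off the root; leaf indices get one random non-special parent and
# are never chosen as parents themselves (so they stay leaves).
.gen_dag <- function(ids, depth = 5L, orphan_idx = integer(0),
                     leaf_idx = integer(0)) {
  n <- length(ids)
  special <- c(orphan_idx, leaf_idx)
  eligible_parent <- !(seq_len(n) %in% special)
  level <- integer(n)
  parents <- stats::setNames(vector("list", n), ids)
  parents[[1L]] <- character(0)
  for (i in seq_len(n)[-1L]) {
    if (i %in% orphan_idx) {
      level[i] <- 1L
      parents[[i]] <- ids[1L]
      next
    }
    if (i %in% leaf_idx) {
      pool <- which(eligible_parent & seq_len(n) < i)
      p <- if (length(pool) > 1L) sample(pool, 1L) else pool[1L]
      level[i] <- level[p] + 1L
      parents[[i]] <- ids[p]
      next
    }
    lvl <- sample.int(depth, 1L)
    pool <- which(level == lvl - 1L & seq_len(n) < i & eligible_parent)
    if (!length(pool))
      pool <- which(level < lvl & seq_len(n) < i & eligible_parent)
    if (!length(pool)) pool <- 1L
    npar <- min(length(pool), sample(c(1L, 1L, 2L), 1L))
    ps <- if (length(pool) == 1L) pool else sample(pool, npar)
    level[i] <- max(level[ps]) + 1L
    parents[[i]] <- ids[ps]
  }
  list(parents = parents, level = level)
}

.ont_lines <- function(ids, names_, parents, synonyms = NULL, xrefs = NULL,
                       xof = NULL) {
  out <- c("format-version: 1.2", "")
  for (i in seq_along(ids)) {
    id <- ids[i]
    out <- c(out, "[Term]", paste0("id: ", id), paste0("name: ", names_[i]))
    if (!is.null(synonyms) && length(synonyms[[id]]))
      out <- c(out, sprintf('synonym: "%s" EXACT []', synonyms[[id]]))
    out <- c(out, paste0("is_a: ", parents[[id]]))
    if (!is.null(xrefs) && length(xrefs[[id]]))
      out <- c(out, paste0("xref: ", xrefs[[id]]))
    if (!is.null(xof) && length(xof[[id]]))
      out <- c(out, paste0("intersection_of: ", xof[[id]]))
    out <- c(out, "")
  }
  out
}

# reflexive-transitive closure over raw parent lists; generator-side
# bookkeeping, fixed-point iteration independent of the ontology object
.closure_up <- function(ids, parents) {
  clo <- stats::setNames(as.list(ids), ids)
  repeat {
    changed <- FALSE
    for (id in ids) {
      add <- setdiff(unique(unlist(clo[parents[[id]]], use.names = FALSE)),
                     clo[[id]])
      if (length(add)) {
        clo[[id]] <- c(clo[[id]], add)
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  clo
}

# descendant closure (reflexive) keyed by id, from parent lists
.closure_down <- function(ids, parents) {
  kids <- stats::setNames(rep(list(character(0)), length(ids)), ids)
  for (id in ids) for (p in parents[[id]])
    kids[[p]] <- c(kids[[p]], id)
  .closure_up(ids, kids)   # same fixed point with edges reversed
}

.write_lines <- function(lines, path) {
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(lines, con, useBytes = TRUE)
}

#' Generate the complete synthetic universe on disk
#'
#' Writes, under `dir`: the seven OBO ontologies (`quality.obo`,
#' `anatomy_a.obo`, `anatomy_b.obo`, `bridge.obo`, `pheno_a.obo`,
#' `pheno_b.obo`, `go.obo`; phenotype ontologies embed their logical
#' definitions as `intersection_of` lines), `keywords.yaml`, the store
#' TSVs (`genes.tsv`, `associations.tsv`, `orthology.tsv`), the disease
#' corpus (`diseases.tsv`) and benchmark cases (`cases.tsv`), a
#' `fixture.yaml` echoing the configuration, and a `ledger/` directory
#' holding the planted truth: `planted.tsv` (causal gene, mappable-feature
#' count and expected engine score per disease, computed by construction),
#' `eq_pairs.tsv` (planted term correspondences and whether their anatomy
#' concept is bridged) and `counts.tsv` (table sizes). Output is
#' byte-deterministic given the seed.
#'
#' @param config a [fixture_config()]
#' @param dir output directory (created if absent)
#' @return `dir`, invisibly
#' @export
generate_fixture <- function(config, dir) {
  stopifnot(inherits(config, "fixture_config"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  if (!dir.exists(file.path(dir, "ledger")))
    dir.create(file.path(dir, "ledger"))
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old_seed))
    assign(".Random.seed", old_seed, envir = globalenv()))
  set.seed(config$seed, kind = "Mersenne-Twister")

  np <- config$n_pheno_terms
  nd <- config$n_diseases
  n_orph <- config$features_per_disease
  orphan_idx <- seq(np - n_orph + 1L, np)
  private_idx <- seq(np + 1L, np + nd)          # one private leaf / disease
  n_total <- np + nd
  regular_idx <- setdiff(seq_len(np)[-1L], orphan_idx)

  # --- quality ontology ----------------------------------------------------
  q_ids <- sprintf("PQ:%07d", seq_len(config$n_quality_terms))
  q_dag <- .gen_dag(q_ids, depth = 3L)
  .write_lines(.ont_lines(q_ids, c("quality", paste("quality", q_ids[-1L])),
                          q_dag$parents),
               file.path(dir, "quality.obo"))

  # --- anatomy + bridge ----------------------------------------------------
  # shared concepts serve the planted pairwise definitions (one distinct
  # concept each); the last nd concepts are reserved for private features
  n_def <- round(config$def_coverage * length(regular_idx))
  n_anat_reg <- max(30L, n_def + 10L)
  n_anat <- n_anat_reg + nd
  a_ids <- sprintf("AH:%07d", seq_len(n_anat))
  b_ids <- sprintf("AM:%07d", seq_len(n_anat))
  a_dag <- .gen_dag(a_ids, depth = 4L)
  b_dag <- .gen_dag(b_ids, depth = 4L)
  .write_lines(.ont_lines(a_ids, c("body", paste("organ A", a_ids[-1L])),
                          a_dag$parents),
               file.path(dir, "anatomy_a.obo"))
  .write_lines(.ont_lines(b_ids, c("body", paste("organ B", b_ids[-1L])),
                          b_dag$parents),
               file.path(dir, "anatomy_b.obo"))
  bridged_concepts <- sort(c(
    sample.int(n_anat_reg, round(config$bridge_coverage * n_anat_reg)),
    seq(n_anat_reg + 1L, n_anat)))
  u_ids <- sprintf("UB:%07d", seq_along(bridged_concepts))
  u_parents <- stats::setNames(c(list(character(0)),
                                 rep(list(u_ids[1L]),
                                     length(u_ids) - 1L)), u_ids)
  u_xrefs <- stats::setNames(lapply(bridged_concepts, function(k)
    c(a_ids[k], b_ids[k])), u_ids)
  .write_lines(.ont_lines(u_ids, paste("anatomical structure", u_ids),
                          u_parents, xrefs = u_xrefs),
               file.path(dir, "bridge.obo"))

  # --- phenotype ontologies with planted E-Q definitions -------------------
  pa_ids <- sprintf("PA:%07d", seq_len(n_total))
  pb_ids <- sprintf("PB:%07d", seq_len(n_total))
  pa_dag <- .gen_dag(pa_ids, depth = 5L, orphan_idx = orphan_idx,
                     leaf_idx = private_idx)
  pb_dag <- .gen_dag(pb_ids, depth = 5L, orphan_idx = orphan_idx,
                     leaf_idx = private_idx)

  def_idx <- sort(c(sample(regular_idx, n_def), private_idx))
  # concept assignment: regular planted defs draw distinct shared concepts;
  # private defs take the reserved (always bridged) tail, in order
  reg_def_idx <- setdiff(def_idx, private_idx)
  def_concept <- stats::setNames(integer(0), character(0))
  def_concept[as.character(reg_def_idx)] <-
    sample.int(n_anat_reg, length(reg_def_idx))
  def_concept[as.character(private_idx)] <- seq(n_anat_reg + 1L, n_anat)
  def_quality <- stats::setNames(
    sample(q_ids, length(def_idx), replace = TRUE), def_idx)

  pa_xof <- stats::setNames(vector("list", n_total), pa_ids)
  pb_xof <- stats::setNames(vector("list", n_total), pb_ids)
  for (i in def_idx) {
    k <- as.character(i)
    pa_xof[[pa_ids[i]]] <- c(def_quality[[k]],
                             paste("inheres_in", a_ids[def_concept[[k]]]))
    pb_xof[[pb_ids[i]]] <- c(def_quality[[k]],
                             paste("inheres_in", b_ids[def_concept[[k]]]))
  }
  pa_syn <- stats::setNames(vector("list", n_total), pa_ids)
  pa_syn[[pa_ids[2L]]] <- "clinical sign 2"
  .write_lines(.ont_lines(pa_ids,
                          c("phenotypic abnormality",
                            paste("clinical phenotype", pa_ids[-1L])),
                          pa_dag$parents, synonyms = pa_syn, xof = pa_xof),
               file.path(dir, "pheno_a.obo"))
  .write_lines(.ont_lines(pb_ids,
                          c("model phenotype",
                            paste("model phenotype", pb_ids[-1L])),
                          pb_dag$parents, xof = pb_xof),
               file.path(dir, "pheno_b.obo"))

  # --- keyword index (private and orphan terms never listed) ---------------
  kw_names <- sprintf("kw%02d", seq_len(config$n_keywords))
  kw_pa <- regular_idx[stats::runif(length(regular_idx)) <
                         config$keyword_coverage]
  kw_pb <- regular_idx[stats::runif(length(regular_idx)) <
                         config$keyword_coverage]
  kw_of <- function(i) (i %% config$n_keywords) + 1L
  kw_index <- stats::setNames(lapply(seq_len(config$n_keywords), function(k) {
    sort_c(c(pa_ids[kw_pa[kw_of(kw_pa) == k]],
             pb_ids[kw_pb[kw_of(kw_pb) == k]]))
  }), kw_names)
  kw_index <- kw_index[vapply(kw_index, length, integer(1)) > 0L]
  yaml::write_yaml(kw_index, file.path(dir, "keywords.yaml"))

  # --- GO-like ontology ----------------------------------------------------
  go_ids <- sprintf("GO:%07d", seq_len(config$n_go_terms))
  go_dag <- .gen_dag(go_ids, depth = 4L)
  .write_lines(.ont_lines(go_ids, c("biological process",
                                    paste("process", go_ids[-1L])),
                          go_dag$parents),
               file.path(dir, "go.obo"))

  # --- genes, coordinates, orthology ---------------------------------------
  ng <- config$genes_per_species
  mk_genes <- function(prefix, sym_prefix, chrom_prefix, species) {
    idx <- seq_len(ng)
    chrom_i <- (idx - 1L) %/% config$genes_per_chrom
    pos_i <- (idx - 1L) %% config$genes_per_chrom
    start <- pos_i * config$gene_spacing + 1
    data.frame(gene_id = sprintf("%s%06d", prefix, idx),
               species = species,
               symbol = sprintf("%s%d", sym_prefix, idx),
               chrom = sprintf("%s%d", chrom_prefix, chrom_i + 1L),
               start = format(start, scientific = FALSE, trim = TRUE),
               end = format(start + config$gene_length - 1,
                            scientific = FALSE, trim = TRUE),
               stringsAsFactors = FALSE)
  }
  genes <- rbind(mk_genes("HG", "GA", "chr", "human"),
                 mk_genes("MG", "GB", "mchr", "mouse"))
  has_orth <- which(stats::runif(ng) < config$ortholog_coverage)
  if (length(has_orth) < nd)
    stop_data("phenoprio_config",
              "infeasible config: fewer orthologous genes than diseases")
  orthology <- data.frame(gene_id_1 = sprintf("HG%06d", has_orth),
                          gene_id_2 = sprintf("MG%06d", has_orth),
                          stringsAsFactors = FALSE)
  mouse_ids <- sprintf("MG%06d", seq_len(ng))

  # --- construction-side mapping cascade (generator bookkeeping) -----------
  is_bridged_c <- seq_len(n_anat) %in% bridged_concepts
  fires <- function(i) {
    k <- as.character(i)
    i %in% def_idx && is_bridged_c[def_concept[[k]]]
  }
  map_by_construction <- function(i) {
    if (fires(i)) return(list(method = "eq_exact", targets = pb_ids[i]))
    seen <- pa_ids[i]
    frontier <- pa_dag$parents[[pa_ids[i]]]
    while (length(frontier)) {
      frontier <- setdiff(unique(frontier), seen)
      if (!length(frontier)) break
      layer_idx <- match(frontier, pa_ids)
      hit <- layer_idx[vapply(layer_idx, fires, logical(1))]
      if (length(hit))
        return(list(method = "eq_inherited", targets = sort_c(pb_ids[hit])))
      seen <- c(seen, frontier)
      frontier <- unlist(pa_dag$parents[frontier], use.names = FALSE)
    }
    if (i %in% kw_pa) {
      tg <- pb_ids[kw_pb[kw_of(kw_pb) == kw_of(i)]]
      if (length(tg)) return(list(method = "keyword", targets = sort_c(tg)))
    }
    list(method = NA_character_, targets = character(0))
  }

  # --- disease corpus with planted causal genes ----------------------------
  dis_ids <- sprintf("DIS%06d", seq_len(nd))
  causal_idx <- sample(has_orth, nd)
  causal_h <- sprintf("HG%06d", causal_idx)
  causal_m <- sprintf("MG%06d", causal_idx)
  unmappable <- seq_len(config$n_unmappable)

  feature_pool <- sample(regular_idx)          # disjoint blocks per disease
  pool_ptr <- 0L
  freq_levels <- c("", "frequent", "occasional", "rare")

  assoc_chunks <- list()
  add_assoc <- function(gene, term, ns) {
    if (!length(gene) || !length(term)) return(invisible(NULL))
    assoc_chunks[[length(assoc_chunks) + 1L]] <<-
      data.frame(gene_id = gene, term_id = term, namespace = ns,
                 stringsAsFactors = FALSE)
  }

  disease_rows <- list()
  written_features <- list()
  feature_map <- list()    # per disease: term -> construction mapping
  causal_terms <- list()   # per disease: PHENO_B terms given to the causal

  n_shared <- config$features_per_disease - 1L
  for (d in seq_len(nd)) {
    if (d %in% unmappable) {
      feats <- orphan_idx
    } else {
      shared <- if (n_shared > 0L)
        feature_pool[pool_ptr + seq_len(n_shared)] else integer(0)
      pool_ptr <- pool_ptr + n_shared
      feats <- c(private_idx[d], shared)
    }
    maps <- lapply(feats, map_by_construction)
    names(maps) <- pa_ids[feats]
    ann <- character(0)
    for (t in names(maps)) {
      if (is.na(maps[[t]]$method)) next
      ann <- c(ann, maps[[t]]$targets[1L])
    }
    ann <- unique(ann)
    add_assoc(rep(causal_m[d], length(ann)), ann, "PHENO_B")
    causal_terms[[d]] <- ann
    written <- pa_ids[feats]
    flip <- stats::runif(length(written)) < config$noise_q
    if (any(flip)) {
      repl <- sample(setdiff(regular_idx, feats), sum(flip))
      written[flip] <- pa_ids[repl]
      for (t in setdiff(written, names(maps)))
        maps[[t]] <- map_by_construction(match(t, pa_ids))
    }
    written <- unique(written)
    written_features[[d]] <- written
    feature_map[[d]] <- maps
    disease_rows[[d]] <- data.frame(
      disease_id = dis_ids[d], term_id = written,
      frequency = sample(freq_levels, length(written), replace = TRUE),
      stringsAsFactors = FALSE)
  }
  diseases <- do.call(rbind, disease_rows)

  # decoy sharing: non-causal model genes pick up individual feature
  # annotations, but never a complete profile and never a private feature
  private_pb <- pb_ids[private_idx]
  for (d in seq_len(nd)) {
    terms <- setdiff(causal_terms[[d]], private_pb)
    if (!length(terms)) next
    share <- matrix(stats::runif(ng * length(terms)) <
                      config$decoy_share_rate, nrow = ng)
    share[causal_idx[d], ] <- FALSE
    full <- rowSums(share) == length(terms)
    share[full, length(terms)] <- FALSE
    for (j in seq_along(terms)) {
      hit <- which(share[, j])
      add_assoc(mouse_ids[hit], rep(terms[j], length(hit)), "PHENO_B")
    }
  }

  # background annotations avoid disease-target subtrees so the planted
  # uniqueness cannot be undone by chance
  pb_clo_down <- .closure_down(pb_ids, pb_dag$parents)
  target_subtrees <- unique(unlist(
    pb_clo_down[unique(unlist(causal_terms, use.names = FALSE))],
    use.names = FALSE))
  bg_pool_pb <- setdiff(pb_ids[-1L], target_subtrees)
  for (g in seq_len(ng)) {
    if (length(bg_pool_pb)) {
      k <- min(config$annotations_per_gene, length(bg_pool_pb))
      add_assoc(rep(mouse_ids[g], k), sample(bg_pool_pb, k), "PHENO_B")
    }
    add_assoc(rep(sprintf("HG%06d", g), config$annotations_per_gene),
              sample(go_ids[-1L], config$annotations_per_gene,
                     replace = TRUE), "GO")
    add_assoc(rep(mouse_ids[g], config$annotations_per_gene),
              sample(go_ids[-1L], config$annotations_per_gene,
                     replace = TRUE), "GO")
  }
  associations <- unique(do.call(rbind, assoc_chunks))
  associations <- associations[order_c(associations$gene_id,
                                       associations$namespace,
                                       associations$term_id), , drop = FALSE]
  rownames(associations) <- NULL

  # --- ledger: expected scores by construction -----------------------------
  pa_clo_up <- .closure_up(pa_ids, pa_dag$parents)
  cover_count <- stats::setNames(numeric(n_total), pa_ids)
  for (d in seq_len(nd)) {
    cov <- unique(unlist(pa_clo_up[written_features[[d]]],
                         use.names = FALSE))
    cover_count[cov] <- cover_count[cov] + 1
  }
  spec_weight <- -log2(pmax(cover_count / nd, 1 / (2 * nd)))

  planted_rows <- lapply(seq_len(nd), function(d) {
    maps <- feature_map[[d]]
    causal_ann <- unique(
      associations$term_id[associations$gene_id == causal_m[d] &
                             associations$namespace == "PHENO_B"])
    n_mapped <- 0L; score <- 0
    for (t in written_features[[d]]) {
      m <- maps[[t]]
      if (is.na(m$method)) next
      w <- spec_weight[[t]] * (if (m$method == "keyword") config$w_kw else 1)
      if (w <= 0) next
      n_mapped <- n_mapped + 1L
      subtree <- unique(unlist(pb_clo_down[m$targets], use.names = FALSE))
      if (length(intersect(causal_ann, subtree)))
        score <- score + w
    }
    data.frame(disease_id = dis_ids[d], true_gene = causal_h[d],
               model_gene = causal_m[d],
               n_features = length(written_features[[d]]),
               n_mapped = n_mapped,
               expected_score = format(score, digits = 17),
               stringsAsFactors = FALSE)
  })
  planted_tab <- do.call(rbind, planted_rows)

  eq_pairs <- data.frame(
    pa = pa_ids[def_idx], pb = pb_ids[def_idx],
    bridged = ifelse(is_bridged_c[def_concept[as.character(def_idx)]],
                     "true", "false"),
    stringsAsFactors = FALSE)

  # --- write the store and ledger ------------------------------------------
  write_tsv(genes, file.path(dir, "genes.tsv"))
  write_tsv(associations, file.path(dir, "associations.tsv"))
  write_tsv(orthology, file.path(dir, "orthology.tsv"))
  write_tsv(diseases, file.path(dir, "diseases.tsv"))
  write_tsv(data.frame(disease_id = dis_ids, true_gene = causal_h,
                       stringsAsFactors = FALSE),
            file.path(dir, "cases.tsv"))
  write_tsv(planted_tab, file.path(dir, "ledger", "planted.tsv"))
  write_tsv(eq_pairs, file.path(dir, "ledger", "eq_pairs.tsv"))
  write_tsv(data.frame(table = c("genes", "associations", "orthology",
                                 "diseases"),
                       rows = c(nrow(genes), nrow(associations),
                                nrow(orthology), nrow(diseases)),
                       stringsAsFactors = FALSE),
            file.path(dir, "ledger", "counts.tsv"))
  yaml::write_yaml(unclass(config), file.path(dir, "fixture.yaml"))
  invisible(dir)
}

#' Load a generated fixture directory into engine objects
#'
#' @param dir directory written by [generate_fixture()]
#' @return list with `config`, `ontologies` (named: GO, PHENO_A, PHENO_B),
#'   `quality_ont`, `anatomy_a`, `anatomy_b`, `bridge` (built
#'   `anatomy_bridge`), `src_defs`, `tgt_defs`, `keywords`, `store`,
#'   `diseases`, `cases`, `ledger` (list: planted, eq_pairs, counts)
#' @export
load_fixture <- function(dir) {
  quality_ont <- parse_obo(file.path(dir, "quality.obo"))
  anatomy_a <- parse_obo(file.path(dir, "anatomy_a.obo"))
  anatomy_b <- parse_obo(file.path(dir, "anatomy_b.obo"))
  bridge_ont <- parse_obo(file.path(dir, "bridge.obo"))
  pheno_a <- parse_obo(file.path(dir, "pheno_a.obo"))
  pheno_b <- parse_obo(file.path(dir, "pheno_b.obo"))
  go <- parse_obo(file.path(dir, "go.obo"))
  onts <- list(GO = go, PHENO_A = pheno_a, PHENO_B = pheno_b)
  store <- load_store(file.path(dir, "genes.tsv"),
                      file.path(dir, "associations.tsv"),
                      file.path(dir, "orthology.tsv"),
                      ontologies = onts)
  list(config = yaml::read_yaml(file.path(dir, "fixture.yaml")),
       ontologies = onts,
       quality_ont = quality_ont,
       anatomy_a = anatomy_a, anatomy_b = anatomy_b,
       bridge = build_bridge(anatomy_a, anatomy_b, bridge_ont),
       src_defs = logical_definitions(pheno_a),
       tgt_defs = logical_definitions(pheno_b),
       keywords = read_keyword_index(file.path(dir, "keywords.yaml"),
                                     list(pheno_a, pheno_b)),
       store = store,
       diseases = read_diseases(file.path(dir, "diseases.tsv")),
       cases = read_tsv(file.path(dir, "cases.tsv")),
       ledger = list(
         planted = read_tsv(file.path(dir, "ledger", "planted.tsv")),
         eq_pairs = read_tsv(file.path(dir, "ledger", "eq_pairs.tsv")),
         counts = read_tsv(file.path(dir, "ledger", "counts.tsv"))))
}
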