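# Gene/annotation/orthology store and the three retrieval primitives that
# sequential refinement chains together: term-based gene retrieval with
# true-path propagation, orthology hops, and chromosomal-region lookup.

VALID_NAMESPACES <- c("GO", "PHENO_A", "PHENO_B", "PATHWAY", "MOTIF",
                      "DISEASE")

#' Construct an annotation store from in-memory tables
#'
#' @param genes data.frame with columns `gene_id`, `species`, `symbol`,
#'   `chrom`, `start`, `end` (the last three may be empty strings / NA for
#'   genes without coordinates; coordinates are 1-based inclusive).
#' @param associations data.frame with columns `gene_id`, `term_id`,
#'   `namespace`.
#' @param orthology data.frame with columns `gene_id_1`, `gene_id_2`;
#'   unordered cross-species pairs.
#' @param ontologies optional named list (namespace -> `ontology`) used to
#'   validate that association terms exist and carry the namespace's prefix.
#' @return object of class `annotation_store`. All referential errors found
#'   during validation are collected and reported together.
#' @export
annotation_store <- function(genes, associations = NULL, orthology = NULL,
                             ontologies = NULL) {
  genes <- as.data.frame(genes, stringsAsFactors = FALSE)
  need <- c("gene_id", "species", "symbol", "chrom", "start", "end")
  if (!all(need %in% names(genes)))
    stop_data("phenoprio_format", "gene table must have columns: %s",
              paste(need, collapse = ", "))
  if (is.null(associations))
    associations <- data.frame(gene_id = character(0), term_id = character(0),
                               namespace = character(0),
                               stringsAsFactors = FALSE)
  if (is.null(orthology))
    orthology <- data.frame(gene_id_1 = character(0),
                            gene_id_2 = character(0), stringsAsFactors = FALSE)

  errs <- character(0)
  dup <- unique(genes$gene_id[duplicated(genes$gene_id)])
  if (length(dup))
    errs <- c(errs, sprintf("duplicate gene id(s): %s",
                            paste(sort_c(dup), collapse = ", ")))

  blank <- function(x) is.na(x) | !nzchar(trim(as.character(x)))
  has_coord <- !blank(genes$chrom) & !blank(genes$start) & !blank(genes$end)
  partial <- (!blank(genes$chrom) | !blank(genes$start) | !blank(genes$end)) &
    !has_coord
  if (any(partial))
    errs <- c(errs, sprintf("incomplete coordinates for gene(s): %s",
                            paste(sort_c(genes$gene_id[partial]),
                                  collapse = ", ")))
  start <- suppressWarnings(as.numeric(genes$start))
  end <- suppressWarnings(as.numeric(genes$end))
  bad_num <- has_coord & (is.na(start) | is.na(end))
  if (any(bad_num))
    errs <- c(errs, sprintf("malformed coordinate for gene(s): %s",
                            paste(sort_c(genes$gene_id[bad_num]),
                                  collapse = ", ")))
  bad_ord <- has_coord & !bad_num & start > end
  if (any(bad_ord))
    errs <- c(errs, sprintf("start > end for gene(s): %s",
                            paste(sort_c(genes$gene_id[bad_ord]),
                                  collapse = ", ")))

  unknown_g <- setdiff(associations$gene_id, genes$gene_id)
  if (length(unknown_g))
    errs <- c(errs, sprintf("association(s) to unknown gene(s): %s",
                            paste(sort_c(unknown_g), collapse = ", ")))
  bad_ns <- setdiff(unique(associations$namespace), VALID_NAMESPACES)
  if (length(bad_ns))
    errs <- c(errs, sprintf("unknown annotation namespace(s): %s",
                            paste(sort_c(bad_ns), collapse = ", ")))
  if (!is.null(ontologies)) {
    for (ns in intersect(unique(associations$namespace), names(ontologies))) {
      terms <- associations$term_id[associations$namespace == ns]
      missing <- setdiff(terms, ontologies[[ns]]$id)
      if (length(missing))
        errs <- c(errs, sprintf("namespace %s association(s) to unknown term(s): %s",
                                ns, paste(sort_c(unique(missing)),
                                          collapse = ", ")))
    }
  }

  sp <- stats::setNames(genes$species, genes$gene_id)
  known1 <- orthology$gene_id_1 %in% genes$gene_id
  known2 <- orthology$gene_id_2 %in% genes$gene_id
  unknown_o <- setdiff(c(orthology$gene_id_1[!known1],
                         orthology$gene_id_2[!known2]), character(0))
  if (length(unknown_o))
    errs <- c(errs, sprintf("orthology pair(s) naming unknown gene(s): %s",
                            paste(sort_c(unique(unknown_o)), collapse = ", ")))
  same <- known1 & known2 &
    sp[orthology$gene_id_1] == sp[orthology$gene_id_2]
  if (any(same))
    errs <- c(errs, sprintf("orthology pair(s) within one species: %s",
                            paste(paste(orthology$gene_id_1[same],
                                        orthology$gene_id_2[same], sep = "~"),
                                  collapse = ", ")))

  if (length(errs))
    stop_data("phenoprio_store", "invalid annotation store:\n  %s",
              paste(errs, collapse = "\n  "), data = list(problems = errs))

  genes$start <- ifelse(has_coord, start, NA_real_)
  genes$end <- ifelse(has_coord, end, NA_real_)
  genes$chrom <- ifelse(blank(genes$chrom), NA_character_,
                        trim(as.character(genes$chrom)))
  rownames(genes) <- NULL
  structure(list(genes = genes,
                 associations = as.data.frame(associations,
                                              stringsAsFactors = FALSE),
                 orthology = as.data.frame(orthology,
                                           stringsAsFactors = FALSE)),
            class = "annotation_store")
}

#' Load an annotation store from headered TSV files
#'
#' Dialects: genes `gene_id  species  symbol  chrom  start  end` (the
#' coordinate columns may be empty); associations `gene_id  term_id
#' namespace`; orthology `gene_id_1  gene_id_2`. All tab-delimited, UTF-8.
#'
#' @param genes_file,associations_file,orthology_file paths; the latter two
#'   may be `NULL`.
#' @inheritParams annotation_store
#' @return an `annotation_store`
#' @export
load_store <- function(genes_file, associations_file = NULL,
                       orthology_file = NULL, ontologies = NULL) {
  annotation_store(
    genes = read_tsv(genes_file),
    associations = if (!is.null(associations_file))
      read_tsv(associations_file),
    orthology = if (!is.null(orthology_file)) read_tsv(orthology_file),
    ontologies = ontologies)
}

#' @export
print.annotation_store <- function(x, ...) {
  cat(sprintf(
    "annotation_store: %d genes (%s), %d associations, %d orthology pairs\n",
    nrow(x$genes),
    paste(sort_c(unique(x$genes$species)), collapse = "/"),
    nrow(x$associations), nrow(x$orthology)))
  invisible(x)
}

#' Genes annotated to a term, optionally propagated down the ontology
#'
#' With `propagate = TRUE` (the true-path rule) a gene qualifies when it is
#' annotated to `term` or to any is_a descendant of `term`, so querying a
#' high-level term captures genes annotated at finer granularity.
#'
#' @param store an `annotation_store`
#' @param ont the ontology of the namespace
#' @param term query CURIE (must exist in `ont`)
#' @param namespace annotation namespace to search
#' @param propagate apply the true-path rule?
#' @return sorted character vector of gene ids
#' @export
genes_with_term <- function(store, ont, term, namespace, propagate = TRUE) {
  .check_term(ont, term)
  terms <- if (propagate) descendants(ont, term, reflexive = TRUE) else term
  a <- store$associations
  sort_c(unique(a$gene_id[a$namespace == namespace & a$term_id %in% terms]))
}

#' Orthologs of a gene set in a target species
#'
#' Union of orthology partners of the input genes restricted to
#' `target_species`; input genes without partners contribute nothing.
#'
#' @param store an `annotation_store`
#' @param genes character vector of gene ids
#' @param target_species species label present in the store
#' @return sorted character vector of gene ids
#' @export
orthologs <- function(store, genes, target_species) {
  if (!target_species %in% store$genes$species)
    stop_data("phenoprio_lookup", "unknown species: %s", target_species)
  o <- store$orthology
  partners <- c(o$gene_id_2[o$gene_id_1 %in% genes],
                o$gene_id_1[o$gene_id_2 %in% genes])
  sp <- stats::setNames(store$genes$species, store$genes$gene_id)
  sort_c(unique(partners[sp[partners] == target_species]))
}

#' Genes overlapping a chromosomal interval
#'
#' Coordinates are 1-based closed intervals; a gene matches when its
#' interval overlaps the query interval (shared boundary base pairs count).
#' Genes lacking coordinates never match. Strand is ignored.
#'
#' @param store an `annotation_store`
#' @param chrom chromosome name
#' @param start,end 1-based inclusive query interval, `start <= end`
#' @return sorted character vector of gene ids
#' @export
genes_in_region <- function(store, chrom, start, end) {
  stopifnot(start <= end)
  g <- store$genes
  hit <- !is.na(g$chrom) & g$chrom == chrom &
    g$start <= end & g$end >= start
  sort_c(g$gene_id[hit])
}

#' Export region-query results as BED
#'
#' Converts the store's 1-based closed coordinates to BED's 0-based
#' half-open convention at the boundary.
#'
#' @inheritParams genes_in_region
#' @param file output path
#' @return the matching gene ids, invisibly
#' @export
write_region_bed <- function(store, chrom, start, end, file) {
  ids <- genes_in_region(store, chrom, start, end)
  g <- store$genes[match(ids, store$genes$gene_id), , drop = FALSE]
  lines <- sprintf("%s\t%d\t%d\t%s", g$chrom, as.integer(g$start) - 1L,
                   as.integer(g$end), g$gene_id)
  con <- file(file, open = "wb")
  on.exit(close(con))
  writeLines(lines, con, useBytes = TRUE)
  invisible(ids)
}
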