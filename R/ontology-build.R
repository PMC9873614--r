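#' @title Compiling taxonomies into the ontology schema
#' @description
#' The build renders each taxonomy as a collection of OWL individuals (one
#' per cluster, linked by the transitive \code{subcluster_of} relation and
#' retaining all original metadata), generates classes for leaves and
#' flagged nodes via the exemplar has-value pattern, reifies NS-Forest
#' marker sets as intermediate classes annotated with their F-beta score,
#' renders cross-species homology groups pairwise, and links clusters to
#' their source datasets. Fragments built per stage are merged into one
#' canonical document.
#' @name ontology-build
NULL

# collision-checked identifier minting: same id from two different sources
# is a hard error (e.g. two metadata keys slugging to the same local id)
new_mint_registry <- function() new.env(parent = emptyenv())

mint_checked <- function(registry, kind, taxonomy_id, name, config) {
  id <- mint_identifier(kind, taxonomy_id, name, config)
  source_key <- paste(kind, taxonomy_id, name, sep = "\r")
  prev <- registry[[id]]
  if (!is.null(prev) && !identical(prev, source_key))
    stop_ccn("MINT_COLLISION",
             "identifier %s minted from two different sources", id)
  registry[[id]] <- source_key
  id
}

# annotation property carrying one retained metadata column; collision of
# two distinct keys on one slug is a hard error via the registry
meta_prop_id <- function(key, config, registry = NULL) {
  p <- paste0(config$namespace, ":meta-", slugify(key))
  if (!is.null(registry)) {
    source_key <- paste0("meta\r", key)
    prev <- registry[[p]]
    if (!is.null(prev) && !identical(prev, source_key))
      stop_ccn("MINT_COLLISION",
               "metadata keys '%s' and '%s' mint the same identifier %s",
               sub("^meta\r", "", prev), key, p)
    registry[[p]] <- source_key
  }
  p
}

#' Base fragment: relation vocabulary declarations
#'
#' Declares the fixed object/annotation properties with their
#' characteristics: \code{subcluster_of} transitive, the homology relation
#' symmetric, and the exemplar property chain
#' (\code{has_exemplar o subcluster_of -> has_exemplar}) that lets a
#' reasoner propagate class membership up the cluster hierarchy.
#'
#' @param config build configuration.
#' @export
vocabulary_fragment <- function(config = default_config()) {
  v <- config$vocabulary
  obj <- unlist(v[c("subcluster_of", "has_exemplar",
                    "has_characterizing_marker_set", "has_part",
                    "has_soma_location", "in_taxon",
                    "in_historical_homology_relationship_with", "bearer_of",
                    "has_source_dataset")])
  ann <- unlist(v[c("fbeta_confidence_score", "label", "definition", "synonym",
                    "entity_role", "accession", "aligned_alias",
                    "cluster_confidence", "source_url", "title", "inferred")])
  doc <- ontology_document(prefixes = config$prefixes, iri = config$ontology_iri)
  doc <- declare(doc, unname(obj), "object_property")
  doc <- declare(doc, unname(ann), "annotation_property")
  doc <- declare(doc, v$cell, "class")
  add_axioms(doc,
    ax_transitive(v$subcluster_of),
    ax_symmetric(v$in_historical_homology_relationship_with),
    ax_property_chain(c(v$has_exemplar, v$subcluster_of), v$has_exemplar),
    ax_annotation(v$label, v$cell, "cell"),
    ax_annotation(v$label, v$has_exemplar, v$has_exemplar_label))
}

#' Build the individual layer for one taxonomy
#'
#' One OWL individual per cluster node; a direct \code{subcluster_of}
#' assertion per parent link (transitivity is left to the reasoner, so only
#' n - roots assertions are emitted); every retained metadata key/value and
#' the division-confidence measure become annotations on the individual.
#'
#' @param tx a validated \code{\link{taxonomy}}.
#' @param config build configuration.
#' @param registry mint registry shared across fragments.
#' @return list: \code{fragment} (ontology document),
#'   \code{individual_index} named vector accession -> individual CURIE.
#' @export
build_individuals <- function(tx, config = default_config(),
                              registry = new_mint_registry()) {
  v <- config$vocabulary
  acc <- taxonomy_accessions(tx)
  ind <- vapply(acc, function(a)
    mint_checked(registry, "individual", tx$taxonomy_id, a, config),
    character(1))
  doc <- ontology_document(prefixes = config$prefixes, iri = config$ontology_iri)
  doc <- declare(doc, unname(ind), "individual")
  axs <- list()
  meta_props <- character(0)
  for (nd in tx$nodes) {
    i <- ind[[nd$accession]]
    axs <- c(axs, list(
      ax_annotation(v$accession, i, nd$accession),
      ax_annotation(v$entity_role, i, "taxonomy_node"),
      ax_annotation(v$label, i,
                    if (nzchar(nd$preferred_alias)) nd$preferred_alias
                    else nd$accession)))
    if (nzchar(nd$aligned_alias))
      axs <- c(axs, list(ax_annotation(v$aligned_alias, i, nd$aligned_alias)))
    for (syn in nd$additional_aliases)
      axs <- c(axs, list(ax_annotation(v$synonym, i, syn)))
    if (!is.na(nd$parent_accession))
      axs <- c(axs, list(ax_obj_assertion(v$subcluster_of, i,
                                          ind[[nd$parent_accession]])))
    if (!is.na(nd$confidence))
      axs <- c(axs, list(ax_annotation(v$cluster_confidence, i, nd$confidence)))
    for (k in names(nd$metadata)) {
      p <- meta_prop_id(k, config, registry)
      if (!(p %in% meta_props)) {
        meta_props <- c(meta_props, p)
        axs <- c(axs, list(ax_annotation(v$label, p, k)))
      }
      axs <- c(axs, list(ax_annotation(p, i, as.character(nd$metadata[[k]]))))
    }
  }
  if (length(meta_props)) doc <- declare(doc, meta_props, "annotation_property")
  list(fragment = add_axioms(doc, axs),
       individual_index = ind)
}

# which nodes of a taxonomy get a class: every leaf plus every flagged node,
# minus curation-excluded ones
classed_accessions <- function(tx, curation = list()) {
  excl <- vapply(curation, function(r) if (r$exclude) r$cluster_accession
                 else NA_character_, character(1))
  excl <- excl[!is.na(excl)]
  flagged <- vapply(tx$nodes, `[[`, logical(1), "flagged_for_class")
  cand <- union(taxonomy_leaves(tx),
                taxonomy_accessions(tx)[flagged])
  canonical_sort(setdiff(cand, excl))
}

#' Expand naming templates for one cluster node
#'
#' Produces the class label, definition and synonym list from the
#' configured patterns. Anchor-species terms keep their alias; non-anchor
#' terms whose alias was transferred by cross-species alignment are wrapped
#' as \code{"(<anchor> <alias>)-like (<species>)"} so the name does not
#' imply properties that may not hold in that species. A node with no
#' usable alias falls back to its accession; the label is never empty.
#'
#' @param node a \code{\link{cluster_node}}.
#' @param tx the taxonomy it belongs to.
#' @param curation_record optional \code{\link{curated_class_record}}.
#' @param naming naming configuration (see
#'   \code{\link{default_naming_config}}); \code{anchor_species} must name
#'   the anchor species' common name.
#' @return list(label, definition, synonyms).
#' @export
expand_templates <- function(node, tx, curation_record = NULL,
                             naming = default_naming_config()) {
  anchor_species <- naming$anchor_species %||% "Mouse"
  species_name <- unname(naming$species_common_names[tx$species]) %||%
    tx$species
  if (is.na(species_name)) species_name <- tx$species
  region_acr <- unname(naming$region_acronyms[tx$brain_region]) %||%
    tx$brain_region
  if (is.na(region_acr)) region_acr <- tx$brain_region
  region_name <- unname(naming$region_names[tx$brain_region]) %||%
    tx$brain_region
  if (is.na(region_name)) region_name <- tx$brain_region
  alias <- if (nzchar(node$preferred_alias)) node$preferred_alias
           else if (nzchar(node$aligned_alias)) node$aligned_alias
           else node$accession
  env <- c(alias = alias, aligned_alias = node$aligned_alias,
           anchor_species = anchor_species,
           species_common_name = species_name,
           region_acronym = region_acr, region_name = region_name,
           accession = node$accession)
  pattern <- if (!tx$is_anchor && nzchar(node$aligned_alias))
    naming$aligned_label else naming$anchor_label
  label <- fill_template(pattern, env)
  definition <- fill_template(naming$definition, env)
  synonyms <- canonical_sort(unique(c(
    node$preferred_alias[nzchar(node$preferred_alias)],
    node$aligned_alias[nzchar(node$aligned_alias)],
    node$additional_aliases,
    curation_record$extra_synonyms %||% character(0))))
  list(label = label, definition = definition, synonyms = synonyms)
}

fill_template <- function(pattern, env) {
  out <- pattern
  for (k in names(env))
    out <- gsub(paste0("{", k, "}"), env[[k]], out, fixed = TRUE)
  left <- regmatches(out, gregexpr("\\{[a-z_]+\\}", out))[[1]]
  if (length(left))
    stop_ccn("UNBOUND_PLACEHOLDER", "unbound placeholder(s) %s in pattern '%s'",
             paste(left, collapse = ", "), pattern)
  out
}

#' Build the class layer for one taxonomy
#'
#' A class is generated for every leaf node and every flagged node whose
#' curation record does not set \code{exclude}. Each class is defined by
#' exactly one exemplar equivalence axiom
#' \code{EquivalentClasses(c, cell and has_exemplar value i)} pointing at
#' the node's individual; curated parents become asserted SubClassOf
#' axioms; soma location, species, morphology and projection context are
#' asserted as existential restrictions. Labels are checked unique across
#' the fragment.
#'
#' @inheritParams build_individuals
#' @param curation list of \code{\link{curated_class_record}} for this
#'   taxonomy.
#' @param individual_index from \code{\link{build_individuals}}.
#' @return list: \code{fragment}, \code{class_index} (named vector
#'   accession -> class CURIE).
#' @export
build_classes <- function(tx, curation = list(),
                          individual_index,
                          config = default_config(),
                          registry = new_mint_registry()) {
  v <- config$vocabulary
  cur_by_acc <- stats::setNames(curation, vapply(curation, `[[`, character(1),
                                                 "cluster_accession"))
  acc_ok <- taxonomy_accessions(tx)
  flagged <- acc_ok[vapply(tx$nodes, `[[`, logical(1), "flagged_for_class")]
  eligible <- union(taxonomy_leaves(tx), flagged)
  report <- new_report()
  for (a in intersect(setdiff(names(cur_by_acc), eligible), acc_ok))
    report <- add_finding(report, "CURATION_NOT_CLASSED", a,
                          "curation row for a non-flagged internal node",
                          "WARNING")
  classed <- classed_accessions(tx, curation)
  nodes_by_acc <- stats::setNames(tx$nodes, acc_ok)
  cls <- vapply(classed, function(a)
    mint_checked(registry, "class", tx$taxonomy_id, a, config), character(1))
  doc <- ontology_document(prefixes = config$prefixes, iri = config$ontology_iri)
  doc <- declare(doc, unname(cls), "class")
  ext <- character(0)
  axs <- list()
  labels_seen <- character(0)
  for (a in classed) {
    nd <- nodes_by_acc[[a]]
    cr <- cur_by_acc[[a]]
    cid <- cls[[a]]
    nm <- expand_templates(nd, tx, cr, config$naming)
    if (nm$label %in% names(labels_seen))
      stop_ccn("LABEL_COLLISION", "label '%s' generated for both %s and %s",
               nm$label, labels_seen[[nm$label]], cid)
    labels_seen[nm$label] <- cid
    axs <- c(axs, list(
      ax_equivalent(cid, ce_and(ce_class(v$cell),
                                ce_value(v$has_exemplar,
                                         individual_index[[a]]))),
      ax_annotation(v$label, cid, nm$label),
      ax_annotation(v$definition, cid, nm$definition),
      ax_annotation(v$accession, cid, a),
      ax_annotation(v$entity_role, cid, "cell_type_class")))
    for (syn in nm$synonyms)
      axs <- c(axs, list(ax_annotation(v$synonym, cid, syn)))
    if (!is.na(tx$brain_region)) {
      ext <- c(ext, tx$brain_region)
      axs <- c(axs, list(ax_subclass(cid, ce_some(v$has_soma_location,
                                                  tx$brain_region))))
    }
    if (!is.na(tx$species)) {
      ext <- c(ext, tx$species)
      axs <- c(axs, list(ax_subclass(cid, ce_some(v$in_taxon, tx$species))))
    }
    if (!is.null(cr)) {
      for (p in cr$parent_class_ids) {
        ext <- c(ext, p)
        axs <- c(axs, list(ax_subclass(cid, ce_class(p))))
      }
      if (!is.na(cr$morphology_term)) {
        ext <- c(ext, cr$morphology_term)
        axs <- c(axs, list(ax_subclass(cid, ce_some(v$bearer_of,
                                                    cr$morphology_term))))
      }
      if (!is.na(cr$projection_term)) {
        ext <- c(ext, cr$projection_term)
        axs <- c(axs, list(ax_subclass(cid, ce_some(v$bearer_of,
                                                    cr$projection_term))))
      }
    }
  }
  if (length(ext)) doc <- declare(doc, unique(ext), "class")
  list(fragment = add_axioms(doc, axs),
       class_index = cls, report = report)
}

#' Reify NS-Forest marker sets as annotated intermediate classes
#'
#' Each marker row becomes its own marker-set class S (so a cluster can
#' carry several marker sets from competing methods):
#' \code{SubClassOf(S, has_part some g)} per gene,
#' \code{SubClassOf(C, has_characterizing_marker_set some S)}, and the
#' F-beta score as a direct \code{fbeta_confidence_score} annotation on S.
#' By design no EquivalentClasses axiom is emitted from markers and
#' location: marker-based equivalence would misclassify rare types and
#' would not admit alternative marker sets.
#'
#' @param marker_sets list of \code{\link{marker_set}}.
#' @param class_index accession -> class CURIE for the owning taxonomy.
#' @param taxonomy_id owning taxonomy (for identifier minting).
#' @param gene_list optional data.frame (identifier, symbol) used to label
#'   gene classes.
#' @return list: \code{fragment}, \code{report} (marker sets for clusters
#'   without a class, skipped in lenient mode).
#' @export
build_marker_axioms <- function(marker_sets, class_index, taxonomy_id,
                                gene_list = NULL,
                                config = default_config(),
                                registry = new_mint_registry(),
                                strict = config$strict) {
  v <- config$vocabulary
  doc <- ontology_document(prefixes = config$prefixes, iri = config$ontology_iri)
  report <- new_report()
  axs <- list()
  ms_ids <- character(0)
  genes <- character(0)
  seq_by_cluster <- integer(0)
  for (ms in marker_sets) {
    a <- ms$cluster_accession
    if (!(a %in% names(class_index))) {
      if (strict)
        stop_ccn("MARKERS_NO_CLASS", "marker set for %s, which has no class", a)
      report <- add_finding(report, "MARKERS_NO_CLASS", a,
                            "marker set for a cluster with no generated class; skipped",
                            "WARNING")
      next
    }
    k <- if (a %in% names(seq_by_cluster)) seq_by_cluster[[a]] + 1L else 1L
    seq_by_cluster[a] <- k
    sid <- mint_checked(registry, "marker_set", taxonomy_id,
                        sprintf("%s-set-%d", a, k), config)
    ms_ids <- c(ms_ids, sid)
    genes <- c(genes, ms$genes)
    axs <- c(axs, list(
      ax_subclass(class_index[[a]],
                  ce_some(v$has_characterizing_marker_set, sid)),
      ax_annotation(v$fbeta_confidence_score, sid, ms$fbeta),
      ax_annotation(v$entity_role, sid, "marker_set_class"),
      ax_annotation(v$label, sid,
                    sprintf("%s marker set %d for %s", ms$method, k, a))))
    for (g in ms$genes)
      axs <- c(axs, list(ax_subclass(sid, ce_some(v$has_part, g))))
  }
  if (length(ms_ids)) doc <- declare(doc, ms_ids, "class")
  genes <- unique(genes)
  if (length(genes)) {
    doc <- declare(doc, genes, "class")
    if (!is.null(gene_list)) {
      sym <- stats::setNames(gene_list$symbol, gene_list$identifier)
      for (g in intersect(genes, names(sym)))
        axs <- c(axs, list(ax_annotation(v$label, g, unname(sym[g]))))
    }
  }
  list(fragment = add_axioms(doc, axs), report = report)
}

#' Render homology groups pairwise
#'
#' Each group of k resolvable member classes yields choose(k, 2) axioms
#' \code{SubClassOf(A, in_historical_homology_relationship_with some B)},
#' one per unordered pair in a canonical direction (lexicographically
#' smaller class on the left); the relation itself is declared symmetric in
#' the vocabulary fragment.
#'
#' @param groups list of \code{\link{homology_group}}.
#' @param class_indexes named list: taxonomy_id -> class index.
#' @return list: \code{fragment}, \code{report} (groups with < 2 resolvable
#'   members, dropped).
#' @export
build_homology_axioms <- function(groups, class_indexes,
                                  config = default_config()) {
  v <- config$vocabulary
  doc <- ontology_document(prefixes = config$prefixes, iri = config$ontology_iri)
  report <- new_report()
  axs <- list()
  for (g in groups) {
    ids <- character(0)
    for (i in seq_len(nrow(g$members))) {
      ci <- class_indexes[[g$members$taxonomy_id[i]]]
      a <- g$members$cluster_accession[i]
      if (!is.null(ci) && a %in% names(ci)) ids <- c(ids, ci[[a]])
    }
    if (length(ids) < 2L) {
      report <- add_finding(report, "HOMOLOGY_UNRESOLVED", g$group_id,
                            "fewer than 2 members resolve to generated classes; group dropped",
                            "WARNING")
      next
    }
    ids <- canonical_sort(ids)
    for (i in seq_len(length(ids) - 1L))
      for (j in seq(i + 1L, length(ids)))
        axs <- c(axs, list(ax_subclass(
          ids[i], ce_some(v$in_historical_homology_relationship_with, ids[j]))))
  }
  list(fragment = add_axioms(doc, axs), report = report)
}

#' Link cluster individuals to their source datasets
#'
#' One individual per dataset record (with source-URL and title
#' annotations) and, depending on \code{config$dataset_link_level}, a link
#' assertion from every cluster individual of the taxonomy
#' (\code{"cluster"}) or from its root individuals only
#' (\code{"taxonomy"}).
#'
#' @param datasets list of \code{\link{dataset_record}}.
#' @param taxonomies named list of taxonomies.
#' @param individual_indexes named list: taxonomy_id -> individual index.
#' @export
build_dataset_links <- function(datasets, taxonomies, individual_indexes,
                                config = default_config(),
                                registry = new_mint_registry()) {
  v <- config$vocabulary
  doc <- ontology_document(prefixes = config$prefixes, iri = config$ontology_iri)
  axs <- list()
  ids <- character(0)
  for (ds in datasets) {
    if (!(ds$taxonomy_id %in% names(taxonomies)))
      stop_ccn("UNKNOWN_TAXONOMY", "dataset %s references unknown taxonomy %s",
               ds$dataset_id, ds$taxonomy_id)
    did <- mint_checked(registry, "dataset", "", ds$dataset_id, config)
    ids <- c(ids, did)
    axs <- c(axs, list(
      ax_annotation(v$source_url, did, ds$source_url),
      ax_annotation(v$entity_role, did, "dataset"),
      ax_annotation(v$label, did,
                    if (nzchar(ds$title)) ds$title else ds$dataset_id)))
    ind <- individual_indexes[[ds$taxonomy_id]]
    targets <- if (config$dataset_link_level == "cluster") names(ind)
               else {
                 parents <- taxonomy_parents(taxonomies[[ds$taxonomy_id]])
                 names(parents)[is.na(parents)]
               }
    for (a in targets)
      axs <- c(axs, list(ax_obj_assertion(v$has_source_dataset, ind[[a]], did)))
  }
  if (length(ids)) doc <- declare(doc, ids, "individual")
  add_axioms(doc, axs)
}

#' Fragment declaring imports-stub terms
#'
#' Grouping classes and context terms come from a small self-contained stub
#' table instead of network imports. Parent links become asserted
#' SubClassOf (or subproperty) axioms; grouping-class definitions are kept
#' as structured data for the structural classifier and recorded as a
#' definition annotation — deliberately not as EquivalentClasses, so no
#' equivalence axiom in the build mentions location or marker restrictions.
#'
#' @param stub data.frame from \code{\link{parse_imports_stub}}.
#' @export
imports_stub_fragment <- function(stub, config = default_config()) {
  v <- config$vocabulary
  doc <- ontology_document(prefixes = config$prefixes, iri = config$ontology_iri)
  cls <- stub$id[stub$kind == "class"]
  prp <- stub$id[stub$kind == "object_property"]
  if (length(cls)) doc <- declare(doc, cls, "class")
  if (length(prp)) doc <- declare(doc, prp, "object_property")
  axs <- list()
  for (i in seq_len(nrow(stub))) {
    id <- stub$id[i]
    axs <- c(axs, list(ax_annotation(v$label, id, stub$label[i]),
                       ax_annotation(v$entity_role, id, "imported")))
    if (nzchar(stub$parent[i]) && stub$kind[i] == "class")
      axs <- c(axs, list(ax_subclass(id, ce_class(stub$parent[i]))))
    conj <- stub$conjuncts[[i]]
    if (length(conj))
      axs <- c(axs, list(ax_annotation(v$definition, id,
                                       render_conjuncts(conj))))
  }
  add_axioms(doc, axs)
}

render_conjuncts <- function(conj) {
  paste(vapply(conj, function(cj)
    if (cj$type == "named") cj$id
    else paste(cj$property, "some", cj$filler), character(1)),
    collapse = " | ")
}
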