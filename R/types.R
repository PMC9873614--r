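#' Cluster node of a cell-type taxonomy
#'
#' One node of the hierarchical clustering: an accessioned cluster of
#' single-cell (or single-nucleus) transcriptomes, with its aliases, its
#' parent link, the flag marking it for class generation, the dendrogram
#' height retained as a confidence measure for the division into sibling
#' subclusters, and every remaining input column preserved verbatim in
#' \code{metadata}.
#'
#' @param accession unique accession within the taxonomy.
#' @param preferred_alias,aligned_alias display aliases (may be empty).
#' @param additional_aliases character vector of further synonyms.
#' @param parent_accession accession of the enclosing cluster, or \code{NA}
#'   for a root.
#' @param flagged_for_class was this node flagged for class generation?
#' @param confidence division confidence in [0, 1] (dendrogram height), or
#'   \code{NA}.
#' @param metadata named character list of retained input columns.
#' @export
cluster_node <- function(accession, preferred_alias = "", aligned_alias = "",
                         additional_aliases = character(0),
                         parent_accession = NA_character_,
                         flagged_for_class = FALSE, confidence = NA_real_,
                         metadata = list()) {
  stopifnot(is.character(accession), length(accession) == 1L, nzchar(accession))
  if (!is.na(confidence) && (confidence < 0 || confidence > 1))
    stop_ccn("CONFIDENCE_RANGE", "confidence %s outside [0,1] for node %s",
             format(confidence), accession)
  structure(list(
    accession = accession,
    preferred_alias = preferred_alias %||% "",
    aligned_alias = aligned_alias %||% "",
    additional_aliases = as.character(additional_aliases),
    parent_accession = as.character(parent_accession),
    flagged_for_class = isTRUE(flagged_for_class),
    confidence = as.numeric(confidence),
    metadata = metadata
  ), class = "cluster_node")
}

#' A hierarchical cell-type taxonomy
#'
#' A forest of \code{\link{cluster_node}}s with a taxonomy id, the species
#' and brain region the clustering was computed in, and an anchor flag
#' (\code{TRUE} for the species whose aliases anchor cross-species naming,
#' e.g. mouse in a mouse/human/marmoset cortical atlas).
#'
#' @param taxonomy_id stable identifier for the clustering.
#' @param species taxon term CURIE (e.g. \code{"NCBITaxon:10090"}).
#' @param brain_region anatomy term CURIE (e.g. \code{"UBERON:0001384"}).
#' @param nodes list of \code{\link{cluster_node}}.
#' @param is_anchor anchor-species flag.
#' @export
taxonomy <- function(taxonomy_id, species, brain_region, nodes,
                     is_anchor = FALSE) {
  acc <- vapply(nodes, `[[`, character(1), "accession")
  if (anyDuplicated(acc))
    stop_ccn("DUP_ACCESSION", "duplicate accession(s) in %s: %s", taxonomy_id,
             paste(unique(acc[duplicated(acc)]), collapse = ", "))
  tx <- structure(list(taxonomy_id = taxonomy_id, species = species,
                       brain_region = brain_region, nodes = nodes,
                       is_anchor = isTRUE(is_anchor)),
                  class = "ccn_taxonomy")
  parents <- taxonomy_parents(tx)
  known <- !is.na(parents) & !(parents %in% acc)
  if (any(known))
    stop_ccn("UNKNOWN_PARENT", "unknown parent accession(s): %s",
             paste(parents[known], collapse = ", "))
  cyc <- find_parent_cycle(parents)
  if (!is.null(cyc))
    stop_ccn("CYCLE", "parent links form a cycle: %s",
             paste(cyc, collapse = " -> "))
  if (!any(is.na(parents)))
    stop_ccn("NO_ROOT", "taxonomy %s has no root node", taxonomy_id)
  tx
}

# named vector accession -> parent accession (NA for roots)
taxonomy_parents <- function(tx) {
  stats::setNames(vapply(tx$nodes, `[[`, character(1), "parent_accession"),
                  vapply(tx$nodes, `[[`, character(1), "accession"))
}

taxonomy_accessions <- function(tx)
  vapply(tx$nodes, `[[`, character(1), "accession")

taxonomy_leaves <- function(tx) {
  parents <- taxonomy_parents(tx)
  setdiff(names(parents), parents[!is.na(parents)])
}

# returns the cycle path (accessions) or NULL
find_parent_cycle <- function(parents) {
  state <- stats::setNames(integer(length(parents)), names(parents))
  for (start in names(parents)) {
    if (state[[start]] != 0L) next
    path <- character(0)
    n <- start
    while (!is.na(n) && n %in% names(parents)) {
      if (state[[n]] == 2L) break
      if (state[[n]] == 1L) return(c(path[which(path == n):length(path)], n))
      state[[n]] <- 1L
      path <- c(path, n)
      n <- parents[[n]]
    }
    state[path] <- 2L
  }
  NULL
}

#' @export
print.ccn_taxonomy <- function(x, ...) {
  parents <- taxonomy_parents(x)
  cat(sprintf("<taxonomy %s> %d nodes (%d roots, %d leaves), species %s, region %s%s\n",
              x$taxonomy_id, length(x$nodes), sum(is.na(parents)),
              length(taxonomy_leaves(x)), x$species, x$brain_region,
              if (x$is_anchor) ", anchor" else ""))
  invisible(x)
}

#' NS-Forest marker set for a cluster
#'
#' A minimal combination of marker genes sufficient to distinguish the
#' cluster from all others in the same taxonomy, with the F-beta score of
#' the marker-based classifier as a confidence measure.
#'
#' @param cluster_accession accession of the characterised cluster.
#' @param genes non-empty, duplicate-free vector of gene CURIEs.
#' @param fbeta F-beta classification accuracy in [0, 1].
#' @param method marker-selection method label.
#' @export
marker_set <- function(cluster_accession, genes, fbeta, method = "NS-Forest") {
  if (length(genes) == 0L)
    stop_ccn("EMPTY_MARKERS", "marker set for %s has no genes", cluster_accession)
  if (anyDuplicated(genes))
    stop_ccn("DUP_MARKERS", "duplicate genes in marker set for %s",
             cluster_accession)
  if (is.na(fbeta) || fbeta < 0 || fbeta > 1)
    stop_ccn("FBETA_RANGE", "fbeta %s outside [0,1] for %s",
             format(fbeta), cluster_accession)
  structure(list(cluster_accession = cluster_accession,
                 genes = as.character(genes), fbeta = as.numeric(fbeta),
                 method = method),
            class = "ccn_marker_set")
}

#' Curated class annotation for a cluster
#'
#' Manual curation attached to a cluster slated for class generation:
#' parent cell-ontology classes, morphology and projection terms, classical
#' marker genes, extra synonyms, and an exclusion flag suppressing class
#' generation for over-general groupings (e.g. "all cells").
#'
#' @export
curated_class_record <- function(cluster_accession,
                                 parent_class_ids = character(0),
                                 morphology_term = NA_character_,
                                 projection_term = NA_character_,
                                 classical_marker_genes = character(0),
                                 extra_synonyms = character(0),
                                 exclude = FALSE) {
  structure(list(cluster_accession = cluster_accession,
                 parent_class_ids = as.character(parent_class_ids),
                 morphology_term = as.character(morphology_term),
                 projection_term = as.character(projection_term),
                 classical_marker_genes = as.character(classical_marker_genes),
                 extra_synonyms = as.character(extra_synonyms),
                 exclude = isTRUE(exclude)),
            class = "ccn_curation_record")
}

#' Cross-species homology group
#'
#' A set of clusters from at least two different taxonomies hypothesised to
#' correspond to the same cell type; rendered pairwise with the symmetric
#' historical-homology relation at build time.
#'
#' @param group_id group identifier.
#' @param members data.frame with columns \code{taxonomy_id},
#'   \code{cluster_accession}.
#' @export
homology_group <- function(group_id, members) {
  stopifnot(is.data.frame(members),
            all(c("taxonomy_id", "cluster_accession") %in% names(members)))
  if (nrow(members) < 2L)
    stop_ccn("SINGLETON_HOMOLOGY", "homology group %s has < 2 members", group_id)
  if (anyDuplicated(members$taxonomy_id))
    stop_ccn("HOMOLOGY_SAME_TAXONOMY",
             "homology group %s repeats a taxonomy", group_id)
  structure(list(group_id = group_id,
                 members = members[, c("taxonomy_id", "cluster_accession")]),
            class = "ccn_homology_group")
}

#' Dataset record linking a taxonomy to its source expression data
#' @export
dataset_record <- function(dataset_id, taxonomy_id, source_url, title = "") {
  if (!nzchar(source_url))
    stop_ccn("EMPTY_URL", "dataset %s has an empty source URL", dataset_id)
  structure(list(dataset_id = dataset_id, taxonomy_id = taxonomy_id,
                 source_url = source_url, title = title),
            class = "ccn_dataset_record")
}
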