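#' Relation vocabulary used by the ontology schema
#'
#' The schema rests on a small, fixed set of OWL object and annotation
#' properties: a transitive \code{subcluster_of} between cluster individuals,
#' a \code{has_exemplar} link from a cell-type class to its defining cluster,
#' \code{has_characterizing_marker_set}/\code{has_part} for NS-Forest marker
#' sets, context relations (\code{has_soma_location}, \code{in_taxon},
#' \code{bearer_of}), a symmetric cross-species
#' \code{in_historical_homology_relationship_with}, and the
#' \code{fbeta_confidence_score} annotation carrying marker-set classification
#' accuracy. All identifiers are CURIEs resolved through the prefix map in
#' \code{\link{default_config}}.
#'
#' @param has_exemplar_label rendered label for the exemplar property; the
#'   canonical identifier is fixed, only the display label is configurable.
#' @return named list of identifiers with class \code{ccn_vocabulary}.
#' @export
default_vocabulary <- function(has_exemplar_label = "has_exemplar") {
  v <- list(
    subcluster_of = "CTO:subcluster_of",
    has_exemplar = "CTO:has_exemplar",
    has_characterizing_marker_set = "CTO:has_characterizing_marker_set",
    has_part = "CTO:has_part",
    has_soma_location = "CTO:has_soma_location",
    in_taxon = "CTO:in_taxon",
    in_historical_homology_relationship_with =
      "CTO:in_historical_homology_relationship_with",
    bearer_of = "CTO:bearer_of",
    fbeta_confidence_score = "CTO:fbeta_confidence_score",
    cell = "CL:0000000",
    # annotation vocabulary used for rendering and bookkeeping
    label = "rdfs:label",
    definition = "CTO:definition",
    synonym = "CTO:synonym",
    entity_role = "CTO:entity_role",
    accession = "CTO:accession",
    aligned_alias = "CTO:aligned_alias",
    cluster_confidence = "CTO:cluster_confidence",
    source_url = "CTO:source_url",
    title = "CTO:title",
    has_source_dataset = "CTO:has_source_dataset",
    inferred = "CTO:inferred",
    has_exemplar_label = has_exemplar_label
  )
  ids <- unlist(v[setdiff(names(v), "has_exemplar_label")])
  if (anyDuplicated(ids) || any(!nzchar(ids)))
    stop_ccn("VOCAB_INVALID", "vocabulary identifiers must be distinct and non-empty")
  structure(v, class = "ccn_vocabulary")
}

#' Default build configuration
#'
#' Holds the prefix map, the build namespace, identifier-minting policy and
#' naming templates. Everything a release build needs to be reproducible sits
#' in this one object; \code{\link{read_config}} loads overrides from YAML-less
#' JSON so release configs can be versioned alongside inputs.
#'
#' @param namespace prefix (CURIE prefix) under which generated entities are
#'   minted.
#' @export
default_config <- function(namespace = "ONT") {
  list(
    namespace = namespace,
    ontology_iri = "http://purl.example.org/ccn2ont/ontology",
    prefixes = c(
      ONT = "http://purl.example.org/ccn2ont/",
      CTO = "http://purl.example.org/ccn2ont/vocab#",
      CL = "http://purl.obolibrary.org/obo/CL_",
      UBERON = "http://purl.obolibrary.org/obo/UBERON_",
      PATO = "http://purl.obolibrary.org/obo/PATO_",
      NCBITaxon = "http://purl.obolibrary.org/obo/NCBITaxon_",
      GENE = "http://identifiers.org/gene/",
      STUB = "http://purl.example.org/stub#",
      FIX = "http://purl.example.org/fix#",
      rdfs = "http://www.w3.org/2000/01/rdf-schema#",
      xsd = "http://www.w3.org/2001/XMLSchema#"
    ),
    id_policy = "slug",        # "slug" | "numeric"
    id_digits = 7L,
    alias_delimiter = "|",
    gene_match_case_insensitive = FALSE,
    strict = FALSE,
    dataset_link_level = "cluster",   # "cluster" | "taxonomy"
    naming = default_naming_config(),
    vocabulary = default_vocabulary()
  )
}

#' Default naming templates
#'
#' Label patterns follow the cross-species aliasing convention: terms in the
#' anchor species (the taxonomy whose aliases anchor names across species,
#' typically mouse) keep their alias; terms in other species whose alias was
#' transferred by alignment are rendered \code{"(Mouse Sncg)-like (Marmoset)"}
#' so the name does not imply marker expression that may not hold.
#'
#' @export
default_naming_config <- function() {
  list(
    anchor_label = "{alias} ({species_common_name} {region_acronym})",
    aligned_label = "({anchor_species} {aligned_alias})-like ({species_common_name})",
    definition = paste0(
      "A cell type of the {species_common_name} {region_name} defined by ",
      "hierarchical clustering of single-cell transcriptomes ",
      "(cluster {accession})."),
    species_common_names = c(
      "NCBITaxon:10090" = "Mouse",
      "NCBITaxon:9606" = "Human",
      "NCBITaxon:9483" = "Marmoset"),
    region_acronyms = c("UBERON:0001384" = "M1"),
    region_names = c("UBERON:0001384" = "primary motor cortex")
  )
}

#' Read a build configuration from a JSON file
#'
#' Unknown keys are rejected; given keys override \code{\link{default_config}}.
#' @param path JSON file.
#' @export
read_config <- function(path) {
  cfg <- default_config()
  if (is.null(path)) return(cfg)
  user <- jsonlite::read_json(path, simplifyVector = TRUE)
  bad <- setdiff(names(user), names(cfg))
  if (length(bad))
    stop_ccn("CONFIG_KEY", "unknown configuration key(s): %s",
             paste(bad, collapse = ", "))
  for (k in names(user)) {
    if (k %in% c("naming")) {
      for (k2 in names(user[[k]])) cfg[[k]][[k2]] <- user[[k]][[k2]]
    } else if (k == "prefixes") {
      cfg$prefixes[names(user$prefixes)] <- unlist(user$prefixes)
    } else cfg[[k]] <- user[[k]]
  }
  cfg
}

#' Mint a deterministic identifier for a generated entity
#'
#' Minting is a pure function of its inputs: the same (kind, taxonomy,
#' accession) triple always yields the same CURIE and distinct inputs yield
#' distinct CURIEs, so rebuilds are diff-stable. The default policy embeds a
#' kind code and slugs of the taxonomy id and accession; the \code{"numeric"}
#' policy (OBO-style zero-padded local ids) is applied batch-wise by
#' \code{\link{mint_numeric_ids}}.
#'
#' @param kind one of \code{"class"}, \code{"individual"},
#'   \code{"marker_set"}, \code{"dataset"}.
#' @param taxonomy_id taxonomy the entity belongs to ("" for global entities).
#' @param name accession or other unique local name.
#' @param config build configuration (\code{\link{default_config}}).
#' @return a CURIE string.
#' @export
mint_identifier <- function(kind, taxonomy_id, name, config = default_config()) {
  stopifnot(is.character(kind), length(kind) == 1L, nzchar(name))
  code <- c(class = "cc", individual = "ic", marker_set = "ms",
            dataset = "ds")[[kind]]
  if (is.null(code)) stop_ccn("MINT_KIND", "unknown entity kind '%s'", kind)
  local <- paste(c(code, if (nzchar(taxonomy_id)) slugify(taxonomy_id),
                   slugify(name)), collapse = "-")
  paste0(config$namespace, ":", local)
}

#' Assign zero-padded numeric local identifiers in sorted-accession order
#'
#' @param kind entity kind (see \code{\link{mint_identifier}}).
#' @param keys character vector of (taxonomy, accession) keys; sorted
#'   internally so assignment does not depend on input order.
#' @param config build configuration.
#' @param offset starting number (previous mints in the same build).
#' @return named character vector: key -> CURIE.
#' @export
mint_numeric_ids <- function(kind, keys, config = default_config(), offset = 0L) {
  if (anyDuplicated(keys))
    stop_ccn("MINT_COLLISION", "duplicate minting keys: %s",
             paste(unique(keys[duplicated(keys)]), collapse = ", "))
  keys_sorted <- canonical_sort(keys)
  ids <- sprintf("%s:%s", config$namespace,
                 formatC(seq_along(keys_sorted) + offset,
                         width = config$id_digits, flag = "0"))
  stats::setNames(ids, keys_sorted)[keys]
}
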