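#' @title End-to-end build pipeline
#' @description
#' Orchestration of the full compile: validate inputs, build the
#' individual / class / marker / homology / dataset fragments, merge,
#' reason, and serialize, with a content summary and QC report written
#' alongside the ontology. The command functions mirror the CLI
#' (\code{build}, \code{validate}, \code{export-graph}, \code{stats},
#' \code{synth}) and return the process exit status: 0 ok, 1 validation or
#' QC failure, 2 usage error.
#' @name pipeline
NULL

#' Compile validated inputs into a merged ontology
#'
#' @param taxonomies list of taxonomies.
#' @param marker_sets named list: taxonomy_id -> list of marker sets.
#' @param curation named list: taxonomy_id -> list of curation records.
#' @param homology list of homology groups.
#' @param gene_list data.frame (identifier, symbol) or NULL.
#' @param datasets list of dataset records.
#' @param stub imports-stub data.frame or NULL.
#' @param config build configuration.
#' @return list: \code{ontology} (merged document), \code{hierarchy}
#'   (reasoned \code{\link{inferred_hierarchy}}), \code{class_indexes},
#'   \code{individual_indexes}, \code{report} (builder findings).
#' @export
build_ontology <- function(taxonomies, marker_sets = list(),
                           curation = list(), homology = list(),
                           gene_list = NULL, datasets = list(),
                           stub = NULL, config = default_config()) {
  tx_ids <- vapply(taxonomies, `[[`, character(1), "taxonomy_id")
  names(taxonomies) <- tx_ids
  anchor <- Filter(function(t) t$is_anchor, taxonomies)
  if (length(anchor))
    config$naming$anchor_species <-
      unname(config$naming$species_common_names[anchor[[1]]$species]) %||%
      anchor[[1]]$species
  registry <- new_mint_registry()
  fragments <- list(vocabulary_fragment(config))
  report <- new_report()
  individual_indexes <- list(); class_indexes <- list()
  for (tx in taxonomies) {
    bi <- build_individuals(tx, config, registry)
    bc <- build_classes(tx, curation[[tx$taxonomy_id]] %||% list(),
                        bi$individual_index, config, registry)
    report <- rbind(report, bc$report)
    fragments <- c(fragments, list(bi$fragment, bc$fragment))
    individual_indexes[[tx$taxonomy_id]] <- bi$individual_index
    class_indexes[[tx$taxonomy_id]] <- bc$class_index
    ms <- marker_sets[[tx$taxonomy_id]] %||% list()
    if (length(ms)) {
      bm <- build_marker_axioms(ms, bc$class_index, tx$taxonomy_id,
                                gene_list, config, registry)
      report <- rbind(report, bm$report)
      fragments <- c(fragments, list(bm$fragment))
    }
  }
  if (length(homology)) {
    bh <- build_homology_axioms(homology, class_indexes, config)
    report <- rbind(report, bh$report)
    fragments <- c(fragments, list(bh$fragment))
  }
  if (length(datasets))
    fragments <- c(fragments, list(
      build_dataset_links(datasets, taxonomies, individual_indexes,
                          config, registry)))
  if (!is.null(stub) && nrow(stub))
    fragments <- c(fragments, list(imports_stub_fragment(stub, config)))
  doc <- merge_ontologies(fragments)
  hierarchy <- reason_ontology(doc, stub, config)
  list(ontology = doc, hierarchy = hierarchy,
       class_indexes = class_indexes,
       individual_indexes = individual_indexes,
       report = report, config = config)
}

#' Load a build-manifest input bundle from disk
#'
#' The manifest (JSON) names, per taxonomy, the dendrogram, nomenclature,
#' marker and curation files, plus shared gene list, homology, imports
#' stub and dataset tables; paths are relative to the manifest.
#'
#' @param manifest_path path to manifest.json.
#' @param config build configuration.
#' @export
load_inputs <- function(manifest_path, config = default_config()) {
  man <- jsonlite::read_json(manifest_path, simplifyVector = FALSE)
  base <- dirname(manifest_path)
  rel <- function(p) file.path(base, p)
  gene_list <- if (!is.null(man$gene_list)) parse_gene_list(rel(man$gene_list))
  taxonomies <- list(); marker_sets <- list(); curation <- list()
  report <- new_report()
  for (mt in man$taxonomies) {
    tx <- parse_dendrogram(rel(mt$dendrogram),
                           taxonomy_id = mt$taxonomy_id,
                           species = mt$species,
                           brain_region = mt$brain_region,
                           is_anchor = isTRUE(mt$is_anchor))
    if (!is.null(mt$nomenclature))
      tx <- parse_nomenclature_table(rel(mt$nomenclature), tx,
                                     config = config)
    taxonomies[[tx$taxonomy_id]] <- tx
    if (!is.null(mt$markers)) {
      pm <- parse_marker_table(rel(mt$markers), gene_list, config = config)
      marker_sets[[tx$taxonomy_id]] <- pm$marker_sets
      report <- rbind(report, pm$report)
    }
    if (!is.null(mt$curation)) {
      pc <- parse_curation_table(rel(mt$curation), config = config)
      curation[[tx$taxonomy_id]] <- pc$records
      report <- rbind(report, pc$report)
    }
  }
  homology <- list()
  if (!is.null(man$homology)) {
    ph <- parse_homology_table(rel(man$homology))
    homology <- ph$groups
    report <- rbind(report, ph$report)
  }
  stub <- if (!is.null(man$imports_stub))
    parse_imports_stub(rel(man$imports_stub), config)
  datasets <- if (!is.null(man$datasets))
    parse_dataset_table(rel(man$datasets)) else list()
  list(taxonomies = taxonomies, marker_sets = marker_sets,
       curation = curation, homology = homology, gene_list = gene_list,
       stub = stub, datasets = datasets, report = report)
}

log_msg <- function(level, msg, ...) {
  message(sprintf("[%s] %s", level, sprintf(msg, ...)))
}

run_guarded <- function(expr) {
  tryCatch(expr, ccn2ont_error = function(e) {
    log_msg("ERROR", "%s", conditionMessage(e))
    1L
  })
}

#' Run the full build from a manifest directory
#'
#' validate -> build -> merge -> reason -> serialize; writes
#' \code{ontology.ofn}, \code{ontology.obo}, \code{summary.json},
#' \code{validation_report.tsv}, \code{qc_report.tsv} and a run manifest
#' (input file hashes) into \code{out_dir}. Identical inputs produce
#' byte-identical outputs.
#'
#' @param manifest_path manifest.json of the input bundle.
#' @param out_dir output directory (created).
#' @param config_path optional JSON configuration overriding the defaults.
#' @param strict exit nonzero on any validation or QC failure.
#' @return integer exit status, invisibly.
#' @export
cmd_build <- function(manifest_path, out_dir, config_path = NULL,
                      strict = FALSE) {
  status <- run_guarded({
    config <- read_config(config_path)
    inputs <- load_inputs(manifest_path, config)
    vrep <- validate_inputs(inputs$taxonomies, inputs$marker_sets,
                            inputs$curation, inputs$homology,
                            inputs$gene_list)
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_report(rbind(inputs$report, vrep),
                 file.path(out_dir, "validation_report.tsv"))
    if (any(vrep$severity == "ERROR")) {
      for (i in seq_len(nrow(vrep)))
        log_msg(vrep$severity[i], "[%s] %s: %s", vrep$code[i],
                vrep$entity[i], vrep$message[i])
      if (strict || any(vrep$code %in% c("CYCLE", "DUP_ACCESSION",
                                         "UNKNOWN_PARENT")))
        return(1L)
    }
    built <- build_ontology(inputs$taxonomies, inputs$marker_sets,
                            inputs$curation, inputs$homology,
                            inputs$gene_list, inputs$datasets,
                            inputs$stub, config)
    doc <- merge_inferred(built$ontology, built$hierarchy, config)
    write_functional_syntax(doc, file.path(out_dir, "ontology.ofn"))
    write_obo(built$ontology, built$hierarchy,
              file.path(out_dir, "ontology.obo"), config)
    summ <- content_summary(built$ontology, config)
    write_lines_utf8(jsonlite::toJSON(unclass(summ), auto_unbox = TRUE),
                     file.path(out_dir, "summary.json"))
    qc <- qc_report(built$ontology, built$hierarchy, config = config)
    write_report(qc, file.path(out_dir, "qc_report.tsv"))
    inputs_used <- list.files(dirname(manifest_path), full.names = TRUE)
    inputs_used <- inputs_used[!dir.exists(inputs_used)]
    manifest <- data.frame(
      file = basename(inputs_used),
      md5 = vapply(inputs_used, function(f)
        as.character(tools::md5sum(f)), character(1)),
      stringsAsFactors = FALSE)
    write_tsv(manifest[canonical_order(manifest$file), , drop = FALSE],
              file.path(out_dir, "run_manifest.tsv"))
    log_msg("INFO", "build complete: %d entities, %d axioms",
            nrow(doc$entities), length(doc$axioms))
    if (strict && any(qc$severity == "ERROR")) 1L else 0L
  })
  invisible(status)
}

#' Validate an input bundle without building
#' @rdname cmd_build
#' @export
cmd_validate <- function(manifest_path, config_path = NULL) {
  status <- run_guarded({
    config <- read_config(config_path)
    inputs <- load_inputs(manifest_path, config)
    vrep <- rbind(inputs$report,
                  validate_inputs(inputs$taxonomies, inputs$marker_sets,
                                  inputs$curation, inputs$homology,
                                  inputs$gene_list))
    for (i in seq_len(nrow(vrep)))
      log_msg(vrep$severity[i], "[%s] %s: %s", vrep$code[i], vrep$entity[i],
              vrep$message[i])
    if (any(vrep$severity == "ERROR")) 1L else 0L
  })
  invisible(status)
}

#' Project a serialized ontology to property-graph tables
#'
#' Reads the functional-syntax ontology, re-derives the inferred hierarchy
#' from it, applies tag rules and writes \code{nodes.tsv} /
#' \code{edges.tsv} (and optionally a statement script).
#'
#' @param ontology_path .ofn file from \code{\link{cmd_build}}.
#' @param out_dir output directory.
#' @param tag_rules_path optional JSON tag-rule file.
#' @param stub_path optional imports stub (for structural placement).
#' @param script also emit the statement script.
#' @rdname cmd_build
#' @export
cmd_export_graph <- function(ontology_path, out_dir, tag_rules_path = NULL,
                             stub_path = NULL, config_path = NULL,
                             script = FALSE) {
  status <- run_guarded({
    config <- read_config(config_path)
    doc <- parse_functional_syntax(ontology_path)
    stub <- if (!is.null(stub_path)) parse_imports_stub(stub_path, config)
    hierarchy <- reason_ontology(doc, stub, config)
    graph <- project_graph(doc, hierarchy, config)
    if (!is.null(tag_rules_path)) {
      rules <- read_tag_rules(tag_rules_path)
      graph <- apply_tags(graph, rules, hierarchy, doc, config)
    }
    emit_graph(graph, out_dir, if (script) "script" else "tables")
    log_msg("INFO", "graph exported: %d nodes, %d edges",
            nrow(graph$nodes), nrow(graph$edges))
    0L
  })
  invisible(status)
}

#' Print the content summary of a serialized ontology
#' @rdname cmd_build
#' @export
cmd_stats <- function(ontology_path, config_path = NULL) {
  status <- run_guarded({
    config <- read_config(config_path)
    doc <- parse_functional_syntax(ontology_path)
    print(content_summary(doc, config))
    0L
  })
  invisible(status)
}

#' Generate a synthetic input bundle
#' @param seed integer seed.
#' @param n_leaves_anchor,n_leaves_other,max_depth,flag_fraction shape
#'   arguments passed to \code{\link{generate_fixture_set}}.
#' @rdname cmd_build
#' @export
cmd_synth <- function(seed, out_dir, n_leaves_anchor = 12L,
                      n_leaves_other = 9L, max_depth = 4L,
                      flag_fraction = 0.5) {
  status <- run_guarded({
    generate_fixture_set(as.integer(seed), out_dir,
                         n_leaves_anchor = as.integer(n_leaves_anchor),
                         n_leaves_other = as.integer(n_leaves_other),
                         max_depth = as.integer(max_depth),
                         flag_fraction = as.numeric(flag_fraction))
    log_msg("INFO", "fixture set written to %s", out_dir)
    0L
  })
  invisible(status)
}
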