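#' @title Content summaries and quality control
#' @description
#' Release-style content summaries (how many individuals are taxonomy
#' nodes, how many classes are cell types vs marker-set reifications vs
#' imported context terms) computed from the role annotations the builder
#' attaches to every generated entity, plus automated quality-control
#' checks over the reasoned ontology.
#' @name stats-qc
NULL

#' Summarise the content of a built ontology
#'
#' Counts are computed from entity-role annotations and namespace prefix
#' matching: a "cell type class" is a generated class carrying an exemplar
#' equivalence axiom, which distinguishes it from marker-set reification
#' classes and imported stubs.
#'
#' @param doc ontology document.
#' @param config build configuration (namespace prefix).
#' @return named list of counts with class \code{content_summary}.
#' @export
content_summary <- function(doc, config = default_config()) {
  v <- config$vocabulary
  roles <- annotation_map(doc, v$entity_role)
  inds <- entities_of_kind(doc, "individual")
  classes <- entities_of_kind(doc, "class")
  ns <- paste0(config$namespace, ":")
  hom <- sum(vapply(axioms_of_type(doc, "SubClassOf"), function(a)
    a$sup$type == "Some" &&
      a$sup$property == v$in_historical_homology_relationship_with,
    logical(1)))
  structure(list(
    individuals_total = length(inds),
    taxonomy_node_individuals = sum(roles[inds] == "taxonomy_node",
                                    na.rm = TRUE),
    dataset_individuals = sum(roles[inds] == "dataset", na.rm = TRUE),
    classes_total = length(classes),
    namespace_classes = sum(startsWith(classes, ns)),
    cell_type_classes = length(names(exemplar_map(doc, config))),
    marker_set_classes = sum(roles[classes] == "marker_set_class",
                             na.rm = TRUE),
    homology_axioms = hom
  ), class = "content_summary")
}

#' @export
print.content_summary <- function(x, ...) {
  for (k in names(x)) cat(sprintf("%-28s %d\n", k, x[[k]]))
  invisible(x)
}

#' Quality-control report over a reasoned ontology
#'
#' Checks: exemplar uniqueness in both directions (one equivalence axiom
#' per class, one class per exemplar individual), subcluster acyclicity,
#' F-beta scores in [0, 1], label uniqueness, every cell-type class having
#' at least one marker set (or an explicit waiver), absence of the
#' rejected EquivalentClasses pattern over marker-set or soma-location
#' restrictions, and orphan cell-type classes with no superclass in the
#' reasoned hierarchy. Returns one finding per line; strict mode turns any
#' failure into a hard error.
#'
#' @param doc ontology document.
#' @param hierarchy inferred hierarchy (may be NULL: orphan check skipped).
#' @param marker_waivers accessions allowed to lack a marker set.
#' @param strict hard-error on any finding.
#' @export
qc_report <- function(doc, hierarchy = NULL, marker_waivers = character(0),
                      config = default_config(), strict = FALSE) {
  v <- config$vocabulary
  report <- new_report()
  eqs <- axioms_of_type(doc, "EquivalentClasses")
  # exemplar uniqueness, both directions
  per_class <- table(vapply(eqs, `[[`, character(1), "id"))
  for (cid in names(per_class)[per_class > 1L])
    report <- add_finding(report, "MULTIPLE_EQUIVALENCE", cid,
                          "class carries more than one equivalence axiom")
  # collect every (class, exemplar) pair, not just one per class, so a
  # class with two equivalence axioms still exposes a shared exemplar
  ex_pairs <- do.call(rbind, lapply(eqs, function(ax) {
    e <- ax$expr
    if (e$type != "And") return(NULL)
    vals <- Filter(function(a) a$type == "Value" &&
                     a$property == v$has_exemplar, e$args)
    if (!length(vals)) return(NULL)
    data.frame(class = ax$id,
               exemplar = vapply(vals, `[[`, character(1), "individual"),
               stringsAsFactors = FALSE)
  }))
  ex <- exemplar_map(doc, config)
  if (!is.null(ex_pairs)) {
    for (i in unique(ex_pairs$exemplar)) {
      cls <- unique(ex_pairs$class[ex_pairs$exemplar == i])
      if (length(cls) > 1L)
        report <- add_finding(report, "SHARED_EXEMPLAR", i,
                              sprintf("exemplar referenced by several classes: %s",
                                      paste(canonical_sort(cls),
                                            collapse = ", ")))
    }
  }
  # subcluster acyclicity
  cyc <- tryCatch({ subcluster_closure(doc, config); NULL },
                  ccn2ont_CYCLE = function(e) conditionMessage(e))
  if (!is.null(cyc))
    report <- add_finding(report, "CYCLE", "", cyc)
  # fbeta range
  fb <- annotation_map(doc, v$fbeta_confidence_score)
  vals <- suppressWarnings(as.numeric(fb))
  for (i in which(is.na(vals) | vals < 0 | vals > 1))
    report <- add_finding(report, "FBETA_RANGE", names(fb)[i],
                          sprintf("fbeta_confidence_score '%s' outside [0,1]",
                                  fb[i]))
  # label uniqueness among classes
  labels <- annotation_map(doc, v$label)
  labels <- labels[names(labels) %in% entities_of_kind(doc, "class")]
  dup <- unique(labels[duplicated(labels)])
  for (d in dup)
    report <- add_finding(report, "LABEL_COLLISION", d,
                          sprintf("label shared by: %s",
                                  paste(canonical_sort(
                                    names(labels)[labels == d]),
                                    collapse = ", ")))
  # every cell-type class has >= 1 marker set or a waiver
  with_markers <- unique(vapply(
    Filter(function(a) a$sup$type == "Some" &&
             a$sup$property == v$has_characterizing_marker_set,
           axioms_of_type(doc, "SubClassOf")),
    `[[`, character(1), "sub"))
  acc <- annotation_map(doc, v$accession)
  for (cid in setdiff(names(ex), with_markers)) {
    cid_acc <- if (cid %in% names(acc)) acc[[cid]] else ""
    if (!(cid_acc %in% marker_waivers))
      report <- add_finding(report, "NO_MARKER_SET", cid,
                            "cell-type class without a characterizing marker set",
                            "WARNING")
  }
  # rejected design: equivalence over markers/location
  for (ax in eqs) {
    props <- equivalence_properties(ax$expr)
    bad <- intersect(props, c(v$has_characterizing_marker_set,
                              v$has_soma_location))
    if (length(bad))
      report <- add_finding(report, "FORBIDDEN_EQUIVALENCE", ax$id,
                            sprintf("EquivalentClasses axiom mentions %s",
                                    paste(bad, collapse = ", ")))
  }
  # orphans: cell-type classes with no superclass at all in the hierarchy
  if (!is.null(hierarchy)) {
    with_sup <- unique(hierarchy$pairs$sub)
    for (cid in setdiff(names(ex), with_sup))
      report <- add_finding(report, "ORPHAN_CLASS", cid,
                            "cell-type class with no superclass", "WARNING")
  }
  if (strict && any(report$severity == "ERROR"))
    stop_ccn("QC", "quality control failed: %d finding(s); first: [%s] %s",
             nrow(report), report$code[1], report$message[1])
  report
}

# all property identifiers mentioned in restrictions of an expression
equivalence_properties <- function(e) {
  switch(e$type,
    Class = character(0),
    And = unique(unlist(lapply(e$args, equivalence_properties))),
    Some = c(e$property, equivalence_properties(e$filler)),
    Value = e$property)
}

#' Write a QC report as structured text (one finding per line)
#' @param report data.frame from \code{\link{qc_report}}.
#' @param path output path.
#' @export
write_report <- function(report, path) {
  lines <- sprintf("%s\t%s\t%s\t%s", report$severity, report$code,
                   report$entity, report$message)
  write_lines_utf8(c("severity\tcode\tentity\tmessage", lines), path)
}
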