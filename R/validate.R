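#' Validate the full input bundle before building
#'
#' Cross-checks every invariant the build relies on and reports all
#' violations with machine-readable codes rather than stopping at the first:
#' duplicate or unknown accessions, parent-link cycles, F-beta scores
#' outside [0, 1], marker genes absent from the reference gene list,
#' curation rows pointing at nodes that will not get a class, homology
#' groups that are too small or repeat a taxonomy, malformed term
#' identifiers. The report is empty exactly when all invariants hold.
#'
#' @param taxonomies list of \code{\link{taxonomy}} objects.
#' @param marker_sets named list: taxonomy_id -> list of
#'   \code{\link{marker_set}}.
#' @param curation named list: taxonomy_id -> list of
#'   \code{\link{curated_class_record}}.
#' @param homology list of \code{\link{homology_group}}.
#' @param gene_list data.frame (identifier, symbol) or NULL to skip gene
#'   checks.
#' @param strict escalate any violation to a hard error.
#' @return data.frame report (code, severity, entity, message).
#' @export
validate_inputs <- function(taxonomies, marker_sets = list(),
                            curation = list(), homology = list(),
                            gene_list = NULL, strict = FALSE) {
  report <- new_report()
  tx_ids <- vapply(taxonomies, `[[`, character(1), "taxonomy_id")
  if (anyDuplicated(tx_ids))
    report <- add_finding(report, "DUP_TAXONOMY", "",
                          "duplicate taxonomy identifiers")
  by_id <- stats::setNames(taxonomies, tx_ids)

  for (tx in taxonomies) {
    acc <- taxonomy_accessions(tx)
    dup <- unique(acc[duplicated(acc)])
    for (d in dup)
      report <- add_finding(report, "DUP_ACCESSION", d,
                            sprintf("duplicate accession in %s", tx$taxonomy_id))
    parents <- taxonomy_parents(tx)
    missing <- parents[!is.na(parents) & !(parents %in% acc)]
    for (i in seq_along(missing))
      report <- add_finding(report, "UNKNOWN_PARENT", names(missing)[i],
                            sprintf("parent accession '%s' does not exist",
                                    missing[[i]]))
    cyc <- find_parent_cycle(parents[is.na(parents) | parents %in% acc])
    if (!is.null(cyc))
      report <- add_finding(report, "CYCLE", cyc[1],
                            sprintf("parent links form a cycle: %s",
                                    paste(cyc, collapse = " -> ")))
    for (nd in tx$nodes)
      if (!is.na(nd$confidence) && (nd$confidence < 0 || nd$confidence > 1))
        report <- add_finding(report, "CONFIDENCE_RANGE", nd$accession,
                              sprintf("confidence %s outside [0,1]",
                                      format(nd$confidence)))
  }

  for (tid in names(marker_sets)) {
    if (!(tid %in% tx_ids)) {
      report <- add_finding(report, "UNKNOWN_TAXONOMY", tid,
                            "marker sets reference an unloaded taxonomy")
      next
    }
    acc <- taxonomy_accessions(by_id[[tid]])
    for (ms in marker_sets[[tid]]) {
      if (!(ms$cluster_accession %in% acc))
        report <- add_finding(report, "UNKNOWN_ACCESSION", ms$cluster_accession,
                              sprintf("marker set for unknown cluster in %s", tid))
      if (is.na(ms$fbeta) || ms$fbeta < 0 || ms$fbeta > 1)
        report <- add_finding(report, "FBETA_RANGE", ms$cluster_accession,
                              sprintf("fbeta %s outside [0,1]", format(ms$fbeta)))
      if (length(ms$genes) == 0L)
        report <- add_finding(report, "EMPTY_MARKERS", ms$cluster_accession,
                              "marker set without genes")
      if (!is.null(gene_list)) {
        unknown <- setdiff(ms$genes, gene_list$identifier)
        if (length(unknown))
          report <- add_finding(report, "UNKNOWN_GENE", ms$cluster_accession,
                                sprintf("gene(s) absent from reference list: %s",
                                        paste(unknown, collapse = ", ")))
      }
    }
  }

  for (tid in names(curation)) {
    if (!(tid %in% tx_ids)) {
      report <- add_finding(report, "UNKNOWN_TAXONOMY", tid,
                            "curation references an unloaded taxonomy")
      next
    }
    acc <- taxonomy_accessions(by_id[[tid]])
    for (cr in curation[[tid]]) {
      if (!(cr$cluster_accession %in% acc))
        report <- add_finding(report, "UNKNOWN_ACCESSION", cr$cluster_accession,
                              sprintf("curation row for unknown cluster in %s",
                                      tid))
      terms <- c(cr$parent_class_ids,
                 cr$morphology_term[!is.na(cr$morphology_term)],
                 cr$projection_term[!is.na(cr$projection_term)])
      bad <- terms[nzchar(terms) & !is_curie(terms)]
      if (length(bad))
        report <- add_finding(report, "BAD_TERM_ID", cr$cluster_accession,
                              sprintf("malformed term identifier(s): %s",
                                      paste(bad, collapse = ", ")))
    }
  }

  for (hg in homology) {
    if (nrow(hg$members) < 2L)
      report <- add_finding(report, "SINGLETON_HOMOLOGY", hg$group_id,
                            "homology group has < 2 members")
    if (anyDuplicated(hg$members$taxonomy_id))
      report <- add_finding(report, "HOMOLOGY_SAME_TAXONOMY", hg$group_id,
                            "homology group members are not pairwise distinct taxonomies")
    for (i in seq_len(nrow(hg$members))) {
      tid <- hg$members$taxonomy_id[i]
      a <- hg$members$cluster_accession[i]
      if (!(tid %in% tx_ids)) {
        report <- add_finding(report, "UNKNOWN_TAXONOMY", hg$group_id,
                              sprintf("member taxonomy '%s' is not loaded", tid))
      } else if (!(a %in% taxonomy_accessions(by_id[[tid]]))) {
        report <- add_finding(report, "UNKNOWN_ACCESSION", hg$group_id,
                              sprintf("member %s/%s does not exist", tid, a))
      }
    }
  }

  if (strict && nrow(report))
    stop_ccn("VALIDATION", "input validation failed with %d violation(s); first: [%s] %s",
             nrow(report), report$code[1], report$message[1])
  report
}
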